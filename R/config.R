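#' Simulation configuration for synthetic two-channel smFRET/SPT movies
#'
#' Collects every parameter of the synthetic TIRF experiment: acquisition
#' geometry, receptor photophysics, diffusion and interconversion kinetics,
#' and camera model. Defaults reproduce the live-cell acquisition settings
#' of the emulated experiment: 159 nm effective pixel size, 40 ms frame
#' interval, a 512 x 256 px frame split into side-by-side 256 x 256 px
#' donor and acceptor halves, and sparse receptor density after
#' photobleaching recovery.
#'
#' @param field_size integer(2), (height, width) in px of ONE channel.
#' @param pixel_size effective pixel size in nm.
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames.
#' @param emitter_density emitters per square micron of one channel field.
#'   Emitters are born at staggered frames (see `birth`), so this is the
#'   total density of emitters appearing over the whole movie.
#' @param D_monomer,D_dimer 2-D diffusion coefficients in um^2/s.
#' @param k_off dimer dissociation rate in 1/s (dwell times ~ Exp(k_off)).
#' @param p_internalize probability that a dissociation event removes both
#'   signals at once (pathway 2: the complex leaves the TIRF field); with
#'   probability 1 - p_internalize the emitter continues as a donor-labelled
#'   monomer (pathway 1).
#' @param confinement_radius radius in nm of a reflecting circular corral
#'   centred at the emitter's birth position, or `NULL` for free diffusion.
#' @param E_true FRET efficiency of the dimer state (0..1).
#' @param photons_donor expected photons per frame emitted by an unquenched
#'   donor under donor excitation.
#' @param photons_acceptor expected photons per frame of the acceptor under
#'   direct (acceptor) excitation; scales the direct-excitation crosstalk
#'   and, in ALEX mode, the acceptor-excitation intensity.
#' @param leak_alpha_true donor emission leakage fraction into the acceptor
#'   channel (alpha).
#' @param direct_delta_true acceptor direct-excitation fraction under donor
#'   excitation (delta), relative to `photons_acceptor`.
#' @param gamma_true detection-efficiency/quantum-yield imbalance (gamma).
#' @param bleach_rate_donor,bleach_rate_acceptor single-step photobleaching
#'   rates in 1/s.
#' @param background_mean expected background photons per pixel per frame.
#' @param psf_sigma Gaussian PSF standard deviation in nm.
#' @param camera_gain ADU per photon.
#' @param camera_baseline camera offset in ADU.
#' @param seed integer seed; the same seed reproduces every output
#'   bit-identically.
#' @param f_dimer fraction of emitters born as FRET-capable dimers; the rest
#'   are donor-only monomers.
#' @param f_dark_acceptor_dimer fraction of emitters that carry dimer
#'   mobility but donor-only photophysics (incompletely labelled dimers).
#' @param f_acceptor_only fraction of emitters carrying only an acceptor
#'   (visible under direct/ALEX excitation; used for delta calibration).
#' @param alex logical; alternate donor/acceptor excitation frame by frame
#'   (odd frames donor excitation, even frames acceptor excitation).
#' @param chan_dx_nm,chan_dy_nm,chan_theta_deg,chan_scale misalignment of the
#'   acceptor channel relative to the donor channel (translation, rotation
#'   about the channel centre, isotropic scale), used to exercise channel
#'   registration.
#' @param birth `"staggered"` (birth frames uniform over the movie, the
#'   steady influx after photobleaching recovery) or `"start"` (all emitters
#'   present from frame 1).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_frames = 100, emitter_density = 0.02, seed = 7)
#' cfg$frame_interval
#' @export
sim_config <- function(field_size = c(256L, 256L),
                       pixel_size = 159,
                       frame_interval = 0.040,
                       n_frames = 2000L,
                       emitter_density = 0.05,
                       D_monomer = 0.109,
                       D_dimer = 0.066,
                       k_off = 1 / 1.13,
                       p_internalize = 0.7,
                       confinement_radius = NULL,
                       E_true = 0.90,
                       photons_donor = 600,
                       photons_acceptor = 600,
                       leak_alpha_true = 0.05,
                       direct_delta_true = 0,
                       gamma_true = 1.0,
                       bleach_rate_donor = 0.05,
                       bleach_rate_acceptor = 0.05,
                       background_mean = 2,
                       psf_sigma = 150,
                       camera_gain = 2,
                       camera_baseline = 100,
                       seed = 1L,
                       f_dimer = 0.5,
                       f_dark_acceptor_dimer = 0,
                       f_acceptor_only = 0,
                       alex = FALSE,
                       chan_dx_nm = 0,
                       chan_dy_nm = 0,
                       chan_theta_deg = 0,
                       chan_scale = 1,
                       birth = c("staggered", "start")) {
  cfg <- list(
    field_size = as.integer(field_size), pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    emitter_density = emitter_density, D_monomer = D_monomer,
    D_dimer = D_dimer, k_off = k_off, p_internalize = p_internalize,
    confinement_radius = confinement_radius, E_true = E_true,
    photons_donor = photons_donor, photons_acceptor = photons_acceptor,
    leak_alpha_true = leak_alpha_true, direct_delta_true = direct_delta_true,
    gamma_true = gamma_true, bleach_rate_donor = bleach_rate_donor,
    bleach_rate_acceptor = bleach_rate_acceptor,
    background_mean = background_mean, psf_sigma = psf_sigma,
    camera_gain = camera_gain, camera_baseline = camera_baseline,
    seed = as.integer(seed), f_dimer = f_dimer,
    f_dark_acceptor_dimer = f_dark_acceptor_dimer,
    f_acceptor_only = f_acceptor_only, alex = isTRUE(alex),
    chan_dx_nm = chan_dx_nm, chan_dy_nm = chan_dy_nm,
    chan_theta_deg = chan_theta_deg, chan_scale = chan_scale,
    birth = match.arg(birth)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c(
    "pixel_size", "frame_interval", "emitter_density", "D_monomer",
    "D_dimer", "k_off", "p_internalize", "E_true", "photons_donor",
    "photons_acceptor", "leak_alpha_true", "direct_delta_true",
    "gamma_true", "bleach_rate_donor", "bleach_rate_acceptor",
    "background_mean", "psf_sigma", "camera_gain", "camera_baseline",
    "f_dimer", "f_dark_acceptor_dimer", "f_acceptor_only", "chan_scale"
  )
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a finite numeric scalar")
    }
    if (v < 0 && !f %in% c("chan_scale")) {
      stop("config field '", f, "' must be non-negative")
    }
  }
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$E_true > 1) stop("E_true must be in [0, 1]")
  if (cfg$p_internalize > 1) stop("p_internalize must be in [0, 1]")
  if (cfg$f_dimer + cfg$f_dark_acceptor_dimer + cfg$f_acceptor_only > 1 + 1e-12) {
    stop("emitter class fractions must sum to at most 1")
  }
  if (length(cfg$field_size) != 2L || any(cfg$field_size < 16L)) {
    stop("field_size must be two integers >= 16")
  }
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(cfg$confinement_radius)) {
    if (!is.numeric(cfg$confinement_radius) || cfg$confinement_radius <= 0 ||
        !is.finite(cfg$confinement_radius)) {
      stop("confinement_radius must be a positive finite number or NULL")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic smFRET/SPT movie configuration\n")
  cat(sprintf("  field: %d x %d px per channel, %.0f nm px, %d frames @ %.0f ms\n",
              x$field_size[1], x$field_size[2], x$pixel_size, x$n_frames,
              1000 * x$frame_interval))
  cat(sprintf("  density %.3g /um^2, D(dimer) %.3g, D(monomer) %.3g um^2/s, k_off %.3g /s\n",
              x$emitter_density, x$D_dimer, x$D_monomer, x$k_off))
  cat(sprintf("  E_true %.2f, photons D/A %.0f/%.0f, alpha %.3g, delta %.3g, gamma %.3g\n",
              x$E_true, x$photons_donor, x$photons_acceptor,
              x$leak_alpha_true, x$direct_delta_true, x$gamma_true))
  cat(sprintf("  seed %d, %s births, ALEX %s\n", x$seed, x$birth,
              if (x$alex) "on" else "off"))
  invisible(x)
}

#' Write / read a simulation configuration as a flat key-value text file
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  keys <- names(cfg)
  fmt <- function(v) {
    if (is.null(v)) "NULL" else paste(format(v, digits = 17), collapse = ",")
  }
  lines <- vapply(keys, function(k) paste0(k, " = ", fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1]])
    val <- trimws(paste(p[-1], collapse = "="))
    out[[key]] <- if (val == "NULL") {
      NULL
    } else if (val %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else if (key == "birth") {
      val
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  do.call(sim_config, out)
}
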