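#' Simulate ground-truth emitter state trajectories
#'
#' Draws per-emitter birth frames, monomer/dimer identity, exponential dimer
#' dwell times, single-step photobleaching times, the dissociation pathway,
#' and 2-D Brownian (optionally corral-confined) positions. Association
#' events are not simulated: emitters are born in their initial state, and
#' the FRET analysis starts at FRET appearance.
#'
#' Dimer dwell times are drawn from Exp(`k_off`) in continuous time and
#' discretised to whole frames (`ceiling(dwell / frame_interval)` FRET
#' frames). At dissociation, with probability `p_internalize` both signals
#' vanish (pathway 2); otherwise the emitter continues as a donor-labelled
#' monomer with `D_monomer` (pathway 1). Positions take independent Gaussian
#' steps of variance `2 * D * frame_interval` per axis, reflected at the
#' confinement boundary when `confinement_radius` is set. Emitters that
#' leave the field are marked lost from that frame on.
#'
#' @param config a [sim_config()].
#' @param n_emitters override the emitter count implied by
#'   `emitter_density` (used for calibration-scale runs).
#' @return An object of class `sim_truth`: a list with `states` (one row
#'   per visible emitter-frame: `frame`, `emitter_id`, `x_um`, `y_um`,
#'   `state`, `donor_bleached`, `acceptor_bleached`, and the expected photon
#'   rates `rate_dd`, `rate_ad`, `rate_aa`), `per_emitter` (birth frame,
#'   species, continuous dwell time, dissociation frame, pathway, bleach and
#'   field-exit frames) and the generating `config`.
#' @examples
#' cfg <- sim_config(n_frames = 50, emitter_density = 0.01, seed = 2)
#' truth <- simulate_state_trajectories(cfg)
#' head(truth$states)
#' @export
simulate_state_trajectories <- function(config, n_emitters = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  px_um <- config$pixel_size / 1000
  h_um <- config$field_size[1] * px_um
  w_um <- config$field_size[2] * px_um
  dt <- config$frame_interval
  nf <- config$n_frames
  n <- if (is.null(n_emitters)) {
    round(config$emitter_density * h_um * w_um)
  } else {
    as.integer(n_emitters)
  }
  species_levels <- c("dimer", "dark_dimer", "acceptor_only", "monomer")
  probs <- c(config$f_dimer, config$f_dark_acceptor_dimer,
             config$f_acceptor_only, 0)
  probs[4] <- max(0, 1 - sum(probs))
  bleach_frame <- function(rate, birth) {
    p <- 1 - exp(-rate * dt)
    if (p <= 0) rep(Inf, length(birth)) else birth + 1L + rgeom(length(birth), p)
  }

  per <- data.frame(
    emitter_id = seq_len(n),
    species = if (n) sample(species_levels, n, replace = TRUE, prob = probs) else character(),
    birth_frame = if (n == 0) integer() else if (config$birth == "staggered") {
      sample.int(nf, n, replace = TRUE)
    } else {
      rep(1L, n)
    },
    stringsAsFactors = FALSE
  )
  is_dimeric <- per$species %in% c("dimer", "dark_dimer")
  per$dwell_s <- rep(NA_real_, n)
  if (any(is_dimeric)) {
    per$dwell_s[is_dimeric] <- if (config$k_off > 0) {
      rexp(sum(is_dimeric), rate = config$k_off)
    } else {
      Inf
    }
  }
  n_dimer_frames <- ifelse(is.finite(per$dwell_s),
                           pmax(1, ceiling(per$dwell_s / dt)), Inf)
  diss <- per$birth_frame + n_dimer_frames  # first post-dimer frame
  per$dissociation_frame <- ifelse(is_dimeric & is.finite(diss) & diss <= nf,
                                   diss, NA_integer_)
  per$pathway <- rep(NA_integer_, n)
  has_diss <- !is.na(per$dissociation_frame)
  if (any(has_diss)) {
    per$pathway[has_diss] <- ifelse(runif(sum(has_diss)) < config$p_internalize,
                                    2L, 1L)
  }
  per$donor_bleach_frame <- ifelse(per$species == "acceptor_only", Inf,
                                   bleach_frame(config$bleach_rate_donor, per$birth_frame))
  per$acceptor_bleach_frame <- ifelse(per$species %in% c("dimer", "acceptor_only"),
                                      bleach_frame(config$bleach_rate_acceptor, per$birth_frame),
                                      Inf)
  per$left_field_frame <- rep(NA_integer_, n)

  R_um <- if (is.null(config$confinement_radius)) NULL else config$confinement_radius / 1000
  rows <- vector("list", n)
  for (e in seq_len(n)) {
    b <- per$birth_frame[e]
    last <- nf
    if (!is.na(per$dissociation_frame[e]) && per$pathway[e] == 2L) {
      last <- per$dissociation_frame[e] - 1L  # internalised: rows stop
    }
    nfr <- last - b + 1L
    if (nfr < 1L) next
    frames <- b:last
    dimeric_frames <- if (is_dimeric[e]) {
      frames < ifelse(is.na(per$dissociation_frame[e]),
                      Inf, per$dissociation_frame[e]) &
        is_dimeric[e]
    } else {
      rep(FALSE, nfr)
    }
    D <- ifelse(dimeric_frames, config$D_dimer, config$D_monomer)
    sd_step <- sqrt(2 * D * dt)  # per axis; step i moves frame i -> i+1
    x <- numeric(nfr)
    y <- numeric(nfr)
    x[1] <- runif(1, 0, w_um)
    y[1] <- runif(1, 0, h_um)
    if (nfr > 1) {
      dx <- rnorm(nfr - 1, 0, sd_step[-nfr])
      dy <- rnorm(nfr - 1, 0, sd_step[-nfr])
      if (is.null(R_um)) {
        x[-1] <- x[1] + cumsum(dx)
        y[-1] <- y[1] + cumsum(dy)
      } else {
        cx <- x[1]; cy <- y[1]
        for (i in 2:nfr) {
          xn <- x[i - 1] + dx[i - 1]
          yn <- y[i - 1] + dy[i - 1]
          r <- sqrt((xn - cx)^2 + (yn - cy)^2)
          while (r > R_um) {  # radial reflection at the corral wall
            f <- (2 * R_um - r) / r
            xn <- cx + (xn - cx) * f
            yn <- cy + (yn - cy) * f
            r <- abs(2 * R_um - r)
          }
          x[i] <- xn
          y[i] <- yn
        }
      }
    }
    out <- which(x < 0 | x >= w_um | y < 0 | y >= h_um)
    if (length(out)) {
      per$left_field_frame[e] <- frames[out[1]]
      keep <- seq_len(out[1] - 1L)
      if (!length(keep)) next
      frames <- frames[keep]; x <- x[keep]; y <- y[keep]
      dimeric_frames <- dimeric_frames[keep]
      nfr <- length(keep)
    }
    donor_bleached <- frames >= per$donor_bleach_frame[e]
    acceptor_bleached <- frames >= per$acceptor_bleach_frame[e]
    state <- ifelse(dimeric_frames, "dimer", "monomer")
    has_donor <- per$species[e] != "acceptor_only"
    has_acceptor <- (per$species[e] == "dimer" & dimeric_frames) |
      per$species[e] == "acceptor_only"
    E_eff <- ifelse(per$species[e] == "dimer" & dimeric_frames &
                      !acceptor_bleached & !donor_bleached,
                    config$E_true, 0)
    rate_dd <- ifelse(has_donor & !donor_bleached,
                      config$photons_donor * (1 - E_eff), 0)
    rate_ad <- config$gamma_true * config$photons_donor * E_eff +
      config$leak_alpha_true * rate_dd +
      config$direct_delta_true * config$photons_acceptor *
        (has_acceptor & !acceptor_bleached)
    rate_aa <- config$photons_acceptor * (has_acceptor & !acceptor_bleached)
    rows[[e]] <- data.frame(
      frame = frames, emitter_id = per$emitter_id[e], x_um = x, y_um = y,
      state = state, donor_bleached = donor_bleached,
      acceptor_bleached = acceptor_bleached,
      rate_dd = rate_dd, rate_ad = rate_ad, rate_aa = rate_aa,
      stringsAsFactors = FALSE
    )
  }
  states <- if (n && length(rows)) {
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  } else {
    data.frame(frame = integer(), emitter_id = integer(), x_um = numeric(),
               y_um = numeric(), state = character(),
               donor_bleached = logical(), acceptor_bleached = logical(),
               rate_dd = numeric(), rate_ad = numeric(), rate_aa = numeric())
  }
  if (!is.null(states) && nrow(states)) {
    states <- states[order(states$frame, states$emitter_id), ]
    rownames(states) <- NULL
  }
  structure(list(states = states, per_emitter = per, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d emitters, %d emitter-frames over %d frames\n",
              nrow(x$per_emitter), nrow(x$states), x$config$n_frames))
  tab <- table(x$per_emitter$species)
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Map donor-channel coordinates into the acceptor channel
#'
#' Applies the configured acceptor-channel misalignment (rotation about the
#' channel centre, isotropic scale, then translation).
#'
#' @param config a [sim_config()].
#' @param x_um,y_um donor-channel coordinates in micrometres.
#' @return a list with transformed `x_um`, `y_um`.
#' @keywords internal
donor_to_acceptor_coords <- function(config, x_um, y_um) {
  px_um <- config$pixel_size / 1000
  cx <- config$field_size[2] * px_um / 2
  cy <- config$field_size[1] * px_um / 2
  th <- config$chan_theta_deg * pi / 180
  s <- config$chan_scale
  xr <- cx + s * (cos(th) * (x_um - cx) - sin(th) * (y_um - cy)) +
    config$chan_dx_nm / 1000
  yr <- cy + s * (sin(th) * (x_um - cx) + cos(th) * (y_um - cy)) +
    config$chan_dy_nm / 1000
  list(x_um = xr, y_um = yr)
}

#' Render a synthetic two-channel movie from ground-truth states
#'
#' Each rendered frame is a single image whose left half is the donor
#' channel and right half the acceptor channel. Every emitter's expected
#' photon rate is spread as a pixel-integrated symmetric 2-D Gaussian PSF;
#' per-pixel photon counts are Poisson draws of signal plus background,
#' scaled by the camera gain and offset by the baseline (16-bit clamped).
#' In ALEX mode, odd frames are donor-excitation frames and even frames
#' acceptor-excitation frames.
#'
#' Rendering is reproducible: the RNG is seeded from `config$seed` and the
#' first rendered frame index, so rendering the same frame range of the
#' same truth twice is bit-identical, and a movie can be rendered in
#' chunks (`frames = 1:200`, `201:400`, ...) without holding it in memory.
#'
#' @param truth a `sim_truth` from [simulate_state_trajectories()].
#' @param config the generating [sim_config()] (frame counts must agree).
#' @param frames integer vector of consecutive frame indices to render
#'   (default all).
#' @return integer array `(height, 2 * width, n_frames)` of class
#'   `fretspt_movie`, with attributes `pixel_size_nm`, `channel_split`
#'   (first column of the acceptor half), `frames`, `camera_gain`,
#'   `camera_baseline`, `psf_sigma_nm` and `frame_interval_s`.
#' @export
render_movie <- function(truth, config = truth$config, frames = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  if (max(truth$states$frame, 0) > config$n_frames) {
    stop("truth and config disagree on the frame count")
  }
  if (is.null(frames)) frames <- seq_len(config$n_frames)
  frames <- as.integer(frames)
  if (length(frames) && any(diff(frames) != 1L)) {
    stop("frames must be consecutive")
  }
  px_um <- config$pixel_size / 1000
  h <- config$field_size[1]
  w <- config$field_size[2]
  st <- truth$states[truth$states$frame %in% frames, , drop = FALSE]
  if (nrow(st)) {
    bad <- st$x_um < 0 | st$x_um >= w * px_um | st$y_um < 0 | st$y_um >= h * px_um
    if (any(bad)) stop("emitter positions outside the field; truth must mark them lost")
  }
  acc <- donor_to_acceptor_coords(config, st$x_um, st$y_um)
  donor_exc <- if (config$alex) st$frame %% 2L == 1L else rep(TRUE, nrow(st))
  rec_frame <- c(st$frame, st$frame)
  rec_x <- c(st$x_um / px_um, acc$x_um / px_um + w)
  rec_y <- c(st$y_um / px_um, acc$y_um / px_um)
  rec_rate <- c(ifelse(donor_exc, st$rate_dd, 0),
                ifelse(donor_exc, st$rate_ad, st$rate_aa))
  keep <- rec_rate > 0
  set.seed(as.integer(((config$seed %% 1000003) * 2011 +
                         (if (length(frames)) frames[1] else 0L)) %% 2147483647))
  arr <- render_frames_cpp(h, 2L * w, length(frames),
                           rec_frame[keep] - (if (length(frames)) frames[1] else 1L) + 1L,
                           rec_x[keep], rec_y[keep], rec_rate[keep],
                           config$psf_sigma / config$pixel_size,
                           config$background_mean, config$camera_gain,
                           config$camera_baseline)
  structure(arr,
            pixel_size_nm = config$pixel_size, channel_split = w + 1L,
            frames = frames, camera_gain = config$camera_gain,
            camera_baseline = config$camera_baseline,
            psf_sigma_nm = config$psf_sigma,
            frame_interval_s = config$frame_interval,
            alex = config$alex,
            class = "fretspt_movie")
}

#' Simulate a complete ground-truthed movie
#'
#' Convenience wrapper: [simulate_state_trajectories()] followed by
#' [render_movie()].
#'
#' @inheritParams simulate_state_trajectories
#' @return list with `truth` (class `sim_truth`) and `movie`
#'   (class `fretspt_movie`).
#' @export
simulate_movie <- function(config, n_emitters = NULL) {
  truth <- simulate_state_trajectories(config, n_emitters = n_emitters)
  list(truth = truth, movie = render_movie(truth, config))
}

#' Simulate a fiducial-bead calibration movie
#'
#' Bright stationary emitters visible in both channels, the acceptor-channel
#' copy displaced by the configured channel misalignment. Used to exercise
#' [register_channels()].
#'
#' @param config a [sim_config()]; `chan_dx_nm`, `chan_dy_nm`,
#'   `chan_theta_deg` and `chan_scale` define the misalignment to recover.
#' @param n_beads number of beads.
#' @param photons expected photons per bead per frame in each channel.
#' @param n_frames number of calibration frames.
#' @return list with `movie` (class `fretspt_movie`) and `beads`
#'   (data.frame of true donor-channel bead positions in um).
#' @export
simulate_bead_movie <- function(config, n_beads = 12, photons = 5000,
                                n_frames = 20) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  px_um <- config$pixel_size / 1000
  h_um <- config$field_size[1] * px_um
  w_um <- config$field_size[2] * px_um
  margin <- 10 * px_um
  beads <- data.frame(
    bead_id = seq_len(n_beads),
    x_um = runif(n_beads, margin, w_um - margin),
    y_um = runif(n_beads, margin, h_um - margin)
  )
  frames <- rep(seq_len(n_frames), each = n_beads)
  states <- data.frame(
    frame = frames,
    emitter_id = rep(beads$bead_id, n_frames),
    x_um = rep(beads$x_um, n_frames),
    y_um = rep(beads$y_um, n_frames),
    state = "monomer", donor_bleached = FALSE, acceptor_bleached = FALSE,
    rate_dd = photons, rate_ad = photons, rate_aa = 0,
    stringsAsFactors = FALSE
  )
  cfg <- config
  cfg$n_frames <- as.integer(n_frames)
  cfg$alex <- FALSE
  truth <- structure(list(states = states,
                          per_emitter = data.frame(emitter_id = beads$bead_id),
                          config = cfg),
                     class = "sim_truth")
  list(movie = render_movie(truth, cfg), beads = beads)
}
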