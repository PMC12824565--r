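#' Simulate smFRET intensity traces without imaging
#'
#' Generates donor/acceptor intensity time series directly from the
#' photophysical model (Poisson photon statistics plus Gaussian
#' aperture/readout noise), bypassing rendering, detection and tracking.
#' Used to calibrate and test trace vetting, correction-factor estimation
#' and FRET-efficiency recovery in isolation.
#'
#' Trace types: `"dimer"` -- FRET until an exponential acceptor loss
#' (dissociation), then pathway 1 (donor continues until donor bleach) or
#' pathway 2 (both vanish); `"two_dimer"` -- the summed intensities of two
#' colocalized dimers, producing multi-step acceptor bleaching (an endocytic
#' punctum stand-in); `"donor_only"` -- donor-only emitter (alpha
#' calibration); `"acceptor_only"` -- acceptor-only emitter, ALEX mode
#' (delta calibration).
#'
#' @param config a [sim_config()]; photophysics and rates are taken from it
#'   (`alex = TRUE` adds an `I_AA` series).
#' @param n_traces number of traces.
#' @param type trace type, see Details.
#' @param n_frames trace length in frames.
#' @param noise_sd Gaussian noise sd added to every channel sample
#'   (aperture-summed background/readout noise); default
#'   `10 * sqrt(background_mean)`.
#' @param seed RNG seed (default `config$seed`).
#' @return list with `traces` (list of [fret_trace()]) and `truth`
#'   (data.frame: `trace_id`, `type`, `acceptor_loss_frame`, `pathway`,
#'   `donor_end_frame`; for two-dimer puncta also the two individual loss
#'   frames `loss_frame_1`, `loss_frame_2`).
#' @export
simulate_intensity_traces <- function(config, n_traces,
                                      type = c("dimer", "two_dimer",
                                               "donor_only", "acceptor_only"),
                                      n_frames = 150, noise_sd = NULL,
                                      seed = config$seed) {
  validate_sim_config(config)
  type <- match.arg(type)
  set.seed(seed)
  dt <- config$frame_interval
  if (is.null(noise_sd)) noise_sd <- 10 * sqrt(config$background_mean)
  nz <- function(n) rnorm(n, 0, noise_sd)

  one_dimer_rates <- function() {
    loss <- if (config$k_off > 0) {
      1L + ceiling(rexp(1, config$k_off) / dt)
    } else {
      Inf
    }
    if (config$bleach_rate_acceptor > 0) {
      ab <- 1L + ceiling(rexp(1, config$bleach_rate_acceptor) / dt)
      loss <- min(loss, ab)
    }
    pathway <- if (runif(1) < config$p_internalize) 2L else 1L
    don_end <- if (config$bleach_rate_donor > 0) {
      1L + ceiling(rexp(1, config$bleach_rate_donor) / dt)
    } else {
      Inf
    }
    if (is.finite(loss) && pathway == 2L) don_end <- min(don_end, loss)
    f <- seq_len(n_frames)
    fret_on <- f < loss
    don_on <- f < don_end
    acc_present <- fret_on  # pathway-1 partner leaves; bleach also removes it
    rdd <- config$photons_donor * ifelse(fret_on, 1 - config$E_true, 1) * don_on
    rad <- config$gamma_true * config$photons_donor * config$E_true *
      (fret_on & don_on) +
      config$leak_alpha_true * rdd +
      config$direct_delta_true * config$photons_acceptor * acc_present
    raa <- config$photons_acceptor * acc_present
    list(rdd = rdd, rad = rad, raa = raa,
         loss = if (is.finite(loss) && loss <= n_frames) loss else NA_integer_,
         pathway = if (is.finite(loss) && loss <= n_frames) pathway else NA_integer_,
         don_end = if (is.finite(don_end) && don_end <= n_frames) don_end else NA_integer_)
  }

  traces <- vector("list", n_traces)
  truth <- data.frame(trace_id = seq_len(n_traces), type = type,
                      acceptor_loss_frame = NA_integer_,
                      pathway = NA_integer_, donor_end_frame = NA_integer_,
                      loss_frame_1 = NA_integer_, loss_frame_2 = NA_integer_)
  for (i in seq_len(n_traces)) {
    f <- seq_len(n_frames)
    if (type == "dimer") {
      r <- one_dimer_rates()
      truth$acceptor_loss_frame[i] <- r$loss
      truth$pathway[i] <- r$pathway
      truth$donor_end_frame[i] <- r$don_end
      rdd <- r$rdd; rad <- r$rad; raa <- r$raa
    } else if (type == "two_dimer") {
      r1 <- one_dimer_rates()
      r2 <- one_dimer_rates()
      truth$acceptor_loss_frame[i] <- suppressWarnings(
        max(r1$loss, r2$loss, na.rm = TRUE))
      truth$loss_frame_1[i] <- r1$loss
      truth$loss_frame_2[i] <- r2$loss
      rdd <- r1$rdd + r2$rdd; rad <- r1$rad + r2$rad; raa <- r1$raa + r2$raa
    } else if (type == "donor_only") {
      don_end <- if (config$bleach_rate_donor > 0) {
        1L + ceiling(rexp(1, config$bleach_rate_donor) / dt)
      } else {
        Inf
      }
      truth$donor_end_frame[i] <-
        if (is.finite(don_end) && don_end <= n_frames) don_end else NA_integer_
      rdd <- config$photons_donor * (f < don_end)
      rad <- config$leak_alpha_true * rdd
      raa <- rep(0, n_frames)
    } else {  # acceptor_only
      ab <- if (config$bleach_rate_acceptor > 0) {
        1L + ceiling(rexp(1, config$bleach_rate_acceptor) / dt)
      } else {
        Inf
      }
      truth$acceptor_loss_frame[i] <-
        if (is.finite(ab) && ab <= n_frames) ab else NA_integer_
      on <- f < ab
      rdd <- rep(0, n_frames)
      rad <- config$direct_delta_true * config$photons_acceptor * on
      raa <- config$photons_acceptor * on
    }
    I_DD <- rpois(n_frames, rdd) + nz(n_frames)
    I_AD <- rpois(n_frames, rad) + nz(n_frames)
    I_AA <- if (config$alex) rpois(n_frames, raa) + nz(n_frames) else NULL
    traces[[i]] <- fret_trace(f, I_DD, I_AD, I_AA,
                              frame_interval = dt)
  }
  list(traces = traces, truth = truth)
}

#' Photon budget needed for a target acceptor-channel SNR
#'
#' SNR is defined as the FRET-sensitized acceptor signal divided by its
#' per-frame noise sd (Poisson plus aperture noise):
#' `SNR = g*E*N / sqrt(g*E*N + noise_sd^2)`.
#'
#' @param snr target SNR.
#' @param E FRET efficiency.
#' @param gamma detection imbalance factor.
#' @param noise_sd Gaussian noise sd per frame.
#' @return required donor photon budget (photons/frame).
#' @export
photons_for_snr <- function(snr, E = 0.9, gamma = 1, noise_sd = 10) {
  x <- (snr^2 + snr * sqrt(snr^2 + 4 * noise_sd^2)) / 2  # solves x^2 = s^2(x + n^2)
  x / (gamma * E)
}
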