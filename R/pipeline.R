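#' Analysis options for the smFRET/SPT pipeline
#'
#' @param max_disp maximum frame-to-frame displacement for tracking (um).
#' @param max_gap gap-closing limit in frames.
#' @param min_length minimum trajectory length in frames.
#' @param pair_radius_nm donor/acceptor pairing radius.
#' @param search_radius_nm donor concatenation radius at acceptor loss.
#' @param merge_radius_nm spatial-overlap radius for coordinate merging.
#' @param W,k anti-correlation window (frames) and threshold (noise sds).
#' @param theta confined-motion deviation threshold.
#' @param min_overlap minimum candidate trace length in frames.
#' @param alpha,delta fixed correction factors (live-cell mode has no ALEX
#'   frames to calibrate delta natively; `NULL` estimates alpha from
#'   donor-only traces and sets delta to 0).
#' @param extend_frames frames appended past the acceptor trajectory end so
#'   the loss step is visible to change-point detection.
#' @return list of class `fret_options`.
#' @export
fret_options <- function(max_disp = 1.1, max_gap = 3L, min_length = 20L,
                         pair_radius_nm = 250, search_radius_nm = 250,
                         merge_radius_nm = 250, W = 5, k = 2, theta = 0.3,
                         min_overlap = 10L, alpha = NULL, delta = NULL,
                         extend_frames = 10L) {
  structure(as.list(environment()), class = "fret_options")
}

#' Run the smFRET/SPT analysis on localization tables
#'
#' The full trajectory-level pipeline: per-channel tracking with gap
#' closing and minimum-length filtering, donor/acceptor pairing through
#' the channel transform, FRET-trace construction (acceptor-guided donor
#' photometry during FRET, donor-trajectory concatenation after acceptor
#' loss), vetting by single-step photobleaching and anti-correlation,
#' correction-factor estimation, corrected FRET efficiencies, trajectory
#' segmentation with pathway classification, MSD diffusion fits with
#' motion classification, jump angles, and the dimer-lifetime fit.
#'
#' @param locs localization data.frame from [localize_movie()].
#' @param transform a [channel_transform()] (acceptor -> donor).
#' @param frame_interval frame interval in s.
#' @param opts a [fret_options()].
#' @return object of class `fretspt_analysis`.
#' @export
analyze_localizations <- function(locs, transform = channel_transform(),
                                  frame_interval = 0.040,
                                  opts = fret_options()) {
  don_locs <- locs[locs$channel == "donor" & locs$excitation == "donor", ]
  acc_locs <- locs[locs$channel == "acceptor" & locs$excitation == "donor", ]
  last_frame <- if (nrow(locs)) max(locs$frame) else 0L
  don_trajs <- filter_trajectories(
    link_trajectories(don_locs, opts$max_disp, opts$max_gap),
    opts$min_length)
  acc_trajs <- filter_trajectories(
    link_trajectories(acc_locs, opts$max_disp, opts$max_gap),
    opts$min_length)

  pr <- pair_trajectories(don_trajs, acc_trajs, transform,
                          opts$pair_radius_nm)
  am <- pr$acceptor_trajs_mapped

  build_trace <- function(aid) {
    arows <- am[am$traj_id == aid, ]
    arows <- arows[order(arows$frame), ]
    f0 <- min(arows$frame)
    f1 <- min(max(arows$frame) + opts$extend_frames, last_frame)
    frames <- f0:f1
    idx <- match(frames, arows$frame)
    I_AD <- arows$photons[idx]
    I_AD[frames > max(arows$frame)] <- 0
    I_AD <- fill_gaps(I_AD)
    I_DD <- arows$idd_photons[idx]
    did <- pr$pairs$donor_id[match(aid, pr$pairs$acceptor_id)]
    dcoords <- NULL
    if (!is.na(did)) {
      drows <- don_trajs[don_trajs$traj_id == did, ]
      di <- match(frames, drows$frame)
      # donor detections fill frames without acceptor-guided photometry
      # (notably after acceptor loss when the donor is tracked through)
      fillable <- is.na(I_DD) & !is.na(di)
      I_DD[fillable] <- drows$photons[di[fillable]]
      dcoords <- drows
    }
    tr <- fret_trace(frames, I_DD, I_AD, NULL, coords = NULL,
                     donor_traj_id = if (is.na(did)) NA_integer_ else did,
                     acceptor_traj_id = aid,
                     frame_interval = frame_interval)
    acc_df <- data.frame(frame = arows$frame, x_um = arows$x_um,
                         y_um = arows$y_um,
                         precision_nm = arows$precision_nm)
    if (!is.null(dcoords)) {
      tr$coords <- merge_repeated_localizations(
        dcoords[, c("frame", "x_um", "y_um", "precision_nm")], acc_df,
        opts$merge_radius_nm)
    } else {
      tr$coords <- cbind(acc_df, source = "acceptor")
    }
    tr$acceptor_loss_frame <- max(arows$frame) + 1L  # spatial estimate
    tr <- concatenate_donor(tr, don_trajs, opts$search_radius_nm,
                            opts$max_gap)
    tr$I_DD <- fill_gaps(tr$I_DD)
    tr$acceptor_loss_frame <- NA_integer_
    tr <- vet_fret_trace(tr, W = opts$W, k = opts$k,
                         min_overlap = opts$min_overlap)
    tr
  }
  aids <- unique(am$traj_id)
  traces <- lapply(aids, build_trace)
  names(traces) <- aids
  accepted <- Filter(function(tr) isTRUE(tr$accepted), traces)

  # donor-only traces (no acceptor partner): alpha calibration
  donor_only <- lapply(pr$donor_only_ids, function(did) {
    drows <- don_trajs[don_trajs$traj_id == did, ]
    drows <- drows[order(drows$frame), ]
    frames <- min(drows$frame):max(drows$frame)
    idx <- match(frames, drows$frame)
    fret_trace(frames, fill_gaps(drows$photons[idx]),
               fill_gaps(drows$iad_photons[idx]),
               donor_traj_id = did, frame_interval = frame_interval)
  })

  est <- function(alpha, delta, gamma) {
    estimate_correction_factors(donor_only, list(), accepted, W = opts$W,
                                alpha = alpha, delta = delta, gamma = gamma)
  }
  factors <- tryCatch(est(opts$alpha, opts$delta, NULL), error = function(e) {
    warning("gamma defaulted to 1: ", conditionMessage(e))
    tryCatch(est(opts$alpha, opts$delta, 1), error = function(e2) {
      warning("alpha defaulted to 0: ", conditionMessage(e2))
      est(alpha = if (is.null(opts$alpha)) 0 else opts$alpha,
          delta = opts$delta, gamma = 1)
    })
  })

  accepted <- lapply(accepted, compute_fret_efficiency, factors = factors)
  E_values <- unlist(lapply(accepted, function(tr) {
    e <- tr$E
    e[is.finite(e)]
  }))

  segments <- lapply(accepted, function(tr) {
    tryCatch(segment_trajectory(tr, max_gap = opts$max_gap),
             error = function(e) NULL)
  })
  segments <- segments[!vapply(segments, is.null, TRUE)]

  seg_stats <- lapply(segments, function(s) {
    fit_one <- function(co) {
      if (nrow(co) < 5) return(NULL)
      m <- tryCatch(compute_msd(co, frame_interval),
                    error = function(e) NULL)
      if (is.null(m) || nrow(m) < 4) return(NULL)
      ff <- tryCatch(fit_msd(m, "free"), error = function(e) NULL)
      if (is.null(ff)) return(NULL)
      cl <- classify_motion(m, ff, theta = opts$theta)
      list(D = ff$D, sigma_dyn_nm = ff$sigma_dyn_nm,
           motion_class = cl$motion_class,
           angles = tryCatch(compute_jump_angles(co),
                             error = function(e) numeric()))
    }
    list(fret = fit_one(s$fret_segment),
         donor = fit_one(s$donor_only_segment),
         pathway = s$pathway, duration = s$fret_duration_s)
  })
  pull <- function(kind, field) {
    unlist(lapply(seg_stats, function(z) {
      v <- z[[kind]][[field]]
      if (is.null(v)) NULL else v
    }))
  }
  D_fret <- pull("fret", "D")
  D_donor <- pull("donor", "D")
  durations <- vapply(seg_stats, function(z) z$duration, 0)
  pathways <- vapply(seg_stats, function(z) z$pathway, 0L)
  res <- list(
    n_localizations = nrow(locs),
    n_donor_trajs = length(unique(don_trajs$traj_id)),
    n_acceptor_trajs = length(unique(acc_trajs$traj_id)),
    traces = traces, accepted_ids = names(accepted),
    n_candidates = length(traces), n_accepted = length(accepted),
    rejection_reasons = table(vapply(traces, function(tr)
      if (isTRUE(tr$accepted)) "accepted" else tr$reason, "")),
    factors = factors, E_values = E_values,
    segments = segments, durations_s = durations, pathways = pathways,
    D_fret = D_fret, D_donor = D_donor,
    confined_fret = mean(pull("fret", "motion_class") == "confined"),
    confined_donor = mean(pull("donor", "motion_class") == "confined"),
    angles_fret = pull("fret", "angles"),
    angles_donor = pull("donor", "angles"),
    frame_interval = frame_interval, opts = opts
  )
  class(res) <- "fretspt_analysis"
  res
}

#' @export
print.fretspt_analysis <- function(x, ...) {
  cat("smFRET/SPT analysis\n")
  cat(sprintf("  %d localizations -> %d donor + %d acceptor trajectories\n",
              x$n_localizations, x$n_donor_trajs, x$n_acceptor_trajs))
  cat(sprintf("  %d FRET candidates, %d accepted\n", x$n_candidates,
              x$n_accepted))
  if (length(x$D_fret)) {
    cat(sprintf("  median D: FRET %.3f, donor-only %.3f um^2/s\n",
                median(x$D_fret), median(x$D_donor)))
  }
  if (length(x$pathways)) {
    cat(sprintf("  pathway-1 fraction %.2f\n", mean(x$pathways == 1L)))
  }
  invisible(x)
}

#' Simulate a movie and run the full pipeline on it
#'
#' Generates ground truth and a rendered movie (in chunks, to bound
#' memory), registers the channels from a simulated fiducial-bead movie,
#' localizes every frame, and runs [analyze_localizations()].
#'
#' @param config a [sim_config()].
#' @param opts a [fret_options()].
#' @param chunk_frames frames rendered and localized per chunk.
#' @param register estimate the channel transform from a simulated bead
#'   movie (default); otherwise use the exact configured transform.
#' @param verbose progress messages.
#' @return list: `analysis` (class `fretspt_analysis`), `truth`
#'   (`sim_truth`), `transform`, `locs`.
#' @export
simulate_and_analyze <- function(config, opts = fret_options(),
                                 chunk_frames = 250L, register = TRUE,
                                 verbose = FALSE) {
  transform <- if (register &&
                   (config$chan_dx_nm != 0 || config$chan_dy_nm != 0 ||
                    config$chan_theta_deg != 0 || config$chan_scale != 1)) {
    register_channels(simulate_bead_movie(config)$movie)
  } else if (register) {
    channel_transform()
  } else {
    exact_transform(config)
  }
  truth <- simulate_state_trajectories(config)
  starts <- seq(1L, config$n_frames, by = chunk_frames)
  locs <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    fr <- starts[si]:min(starts[si] + chunk_frames - 1L, config$n_frames)
    mv <- render_movie(truth, config, frames = fr)
    locs[[si]] <- localize_movie(mv, transform = transform)
    if (verbose) message("chunk ", si, "/", length(starts), " done")
  }
  locs <- do.call(rbind, locs)
  analysis <- analyze_localizations(locs, transform,
                                    config$frame_interval, opts)
  list(analysis = analysis, truth = truth, transform = transform,
       locs = locs)
}

# Exact acceptor->donor transform implied by the simulator configuration.
exact_transform <- function(config) {
  px_um <- config$pixel_size / 1000
  cx <- config$field_size[2] * px_um / 2
  cy <- config$field_size[1] * px_um / 2
  th <- config$chan_theta_deg * pi / 180
  s <- config$chan_scale
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Ai <- solve(R)
  b_fwd <- c(cx, cy) - R %*% c(cx, cy) +
    c(config$chan_dx_nm, config$chan_dy_nm) / 1000
  channel_transform(Ai, as.numeric(-Ai %*% b_fwd))
}

#' Pool several per-movie analyses into study-level estimates
#'
#' Pools FRET-efficiency frames, FRET-segment durations, diffusion
#' coefficients, motion classes and pathway labels across movies, then
#' fits the study-level E-histogram Gaussian and lifetime exponential and
#' runs the FRET vs donor-only Mann-Whitney comparison.
#'
#' @param analyses list of `fretspt_analysis` objects.
#' @param frame_interval frame interval in s.
#' @return object of class `fretspt_study`.
#' @export
pool_analyses <- function(analyses, frame_interval = 0.040) {
  E <- unlist(lapply(analyses, `[[`, "E_values"))
  durations <- unlist(lapply(analyses, `[[`, "durations_s"))
  D_fret <- unlist(lapply(analyses, `[[`, "D_fret"))
  D_donor <- unlist(lapply(analyses, `[[`, "D_donor"))
  pathways <- unlist(lapply(analyses, `[[`, "pathways"))
  angles_fret <- unlist(lapply(analyses, `[[`, "angles_fret"))
  angles_donor <- unlist(lapply(analyses, `[[`, "angles_donor"))
  e_fit <- tryCatch(
    fit_gaussian_histogram(E[E > -0.5 & E < 1.5], bins = 40,
                           range = c(-0.2, 1.3)),
    error = function(e) NULL)
  lt <- tryCatch(fit_lifetime(durations, frame_interval),
                 error = function(e) NULL)
  cmp <- tryCatch(compare_groups(D_fret, D_donor), error = function(e) NULL)
  structure(list(
    n_movies = length(analyses), n_accepted = sum(vapply(analyses, `[[`, 0L,
                                                         "n_accepted")),
    E_values = E, e_fit = e_fit, durations_s = durations, lifetime = lt,
    D_fret = D_fret, D_donor = D_donor, comparison = cmp,
    pathway1_fraction = mean(pathways == 1L),
    confined_fret = mean(unlist(lapply(analyses, function(a)
      rep(a$confined_fret, length(a$D_fret))) ), na.rm = TRUE),
    confined_donor = mean(unlist(lapply(analyses, function(a)
      rep(a$confined_donor, length(a$D_donor))) ), na.rm = TRUE),
    angles_fret = angles_fret, angles_donor = angles_donor
  ), class = "fretspt_study")
}

#' @export
print.fretspt_study <- function(x, ...) {
  cat(sprintf("smFRET/SPT study: %d movies, %d accepted FRET traces\n",
              x$n_movies, x$n_accepted))
  if (!is.null(x$e_fit)) {
    cat(sprintf("  FRET efficiency peak: %.3f +/- %.3f (Gaussian fit, n=%d frames)\n",
                x$e_fit$mean, x$e_fit$sd, x$e_fit$n))
  }
  if (!is.null(x$lifetime)) {
    cat(sprintf("  dimer lifetime tau: %.3f +/- %.3f s (n=%d)\n",
                x$lifetime$tau_s, x$lifetime$tau_stderr_s, x$lifetime$n_traces))
  }
  if (length(x$D_fret)) {
    cat(sprintf("  median D: FRET %.4f (confined %.0f%%), donor-only %.4f (confined %.0f%%) um^2/s\n",
                median(x$D_fret), 100 * x$confined_fret,
                median(x$D_donor), 100 * x$confined_donor))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  Mann-Whitney FRET vs donor-only: p = %.3g (%s)\n",
                x$comparison$p_value, x$comparison$significance))
  }
  cat(sprintf("  pathway-1 fraction: %.2f\n", x$pathway1_fraction))
  invisible(x)
}
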