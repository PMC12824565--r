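#' Construct a FRET trace
#'
#' A paired donor/acceptor intensity time series on a shared frame axis,
#' the central smFRET analysis object. `I_DD` is the donor emission under
#' donor excitation, `I_AD` the acceptor emission under donor excitation
#' (the FRET-sensitized channel) and `I_AA`, when present, the acceptor
#' emission under direct acceptor excitation (ALEX mode).
#'
#' @param frames integer frame axis (consecutive).
#' @param I_DD,I_AD,I_AA photon intensity series aligned with `frames`
#'   (`I_AA` may be `NULL` in live-cell single-excitation mode).
#' @param coords optional data.frame (`frame`, `x_um`, `y_um`) of the
#'   trajectory positions in donor-channel coordinates.
#' @param donor_traj_id,acceptor_traj_id provenance ids.
#' @param frame_interval frame interval in s.
#' @return object of class `fret_trace`.
#' @export
fret_trace <- function(frames, I_DD, I_AD, I_AA = NULL, coords = NULL,
                       donor_traj_id = NA_integer_,
                       acceptor_traj_id = NA_integer_,
                       frame_interval = 0.040) {
  stopifnot(length(frames) == length(I_DD), length(I_DD) == length(I_AD))
  if (!is.null(I_AA)) stopifnot(length(I_AA) == length(frames))
  structure(list(frames = as.integer(frames), I_DD = I_DD, I_AD = I_AD,
                 I_AA = I_AA, coords = coords,
                 donor_traj_id = donor_traj_id,
                 acceptor_traj_id = acceptor_traj_id,
                 frame_interval = frame_interval,
                 acceptor_loss_frame = NA_integer_,
                 accepted = NA, reason = NA_character_, E = NULL),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("fret_trace: %d frames (%d..%d), donor traj %s, acceptor traj %s\n",
              length(x$frames), min(x$frames), max(x$frames),
              x$donor_traj_id, x$acceptor_traj_id))
  cat(sprintf("  acceptor loss frame: %s; accepted: %s%s\n",
              x$acceptor_loss_frame, x$accepted,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Pair donor and acceptor trajectories into FRET candidates
#'
#' Acceptor trajectories are mapped into donor coordinates through the
#' channel transform; each is paired with the donor trajectory whose
#' time-overlapping positions lie, on average, within `pair_radius_nm`.
#' Pairing is one-to-one: candidates are assigned in order of increasing
#' mean distance. Donor trajectories without an acceptor partner are
#' reported as donor-only (alpha calibration); acceptor trajectories
#' without a donor partner as acceptor-only (delta calibration).
#'
#' @param donor_trajs,acceptor_trajs trajectory data.frames
#'   ([link_trajectories()] output) for each channel.
#' @param transform a [channel_transform()] (acceptor -> donor).
#' @param pair_radius_nm maximum mean distance for a pair.
#' @return list with `pairs` (data.frame `acceptor_id`, `donor_id`,
#'   `mean_dist_nm`, `n_overlap`), `donor_only_ids`, `acceptor_only_ids`,
#'   and `acceptor_trajs_mapped` (acceptor rows with donor-frame
#'   coordinates).
#' @export
pair_trajectories <- function(donor_trajs, acceptor_trajs, transform,
                              pair_radius_nm = 250) {
  am <- acceptor_trajs
  if (nrow(am)) {
    mp <- apply_transform(transform, am$x_um, am$y_um)
    am$x_um <- mp$x
    am$y_um <- mp$y
  }
  aids <- unique(am$traj_id)
  dids <- unique(donor_trajs$traj_id)
  cand <- list()
  for (a in aids) {
    arows <- am[am$traj_id == a, ]
    for (d in dids) {
      drows <- donor_trajs[donor_trajs$traj_id == d, ]
      common <- intersect(arows$frame, drows$frame)
      if (length(common) < 3) next
      ai <- match(common, arows$frame)
      di <- match(common, drows$frame)
      dist_nm <- 1000 * sqrt(mean((arows$x_um[ai] - drows$x_um[di])^2 +
                                    (arows$y_um[ai] - drows$y_um[di])^2))
      if (dist_nm <= pair_radius_nm) {
        cand[[length(cand) + 1L]] <- data.frame(
          acceptor_id = a, donor_id = d, mean_dist_nm = dist_nm,
          n_overlap = length(common))
      }
    }
  }
  pairs <- data.frame(acceptor_id = integer(), donor_id = integer(),
                      mean_dist_nm = numeric(), n_overlap = integer())
  acc_associated <- integer()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    # any donor that ever co-moves with an acceptor is excluded from the
    # donor-only (alpha calibration) class, even if it loses the pairing
    acc_associated <- unique(cand$donor_id)
    # deterministic tie-break: distance, then lower trajectory ids
    cand <- cand[order(cand$mean_dist_nm, cand$donor_id, cand$acceptor_id), ]
    used_a <- used_d <- integer()
    for (r in seq_len(nrow(cand))) {
      if (cand$acceptor_id[r] %in% used_a || cand$donor_id[r] %in% used_d) next
      pairs <- rbind(pairs, cand[r, ])
      used_a <- c(used_a, cand$acceptor_id[r])
      used_d <- c(used_d, cand$donor_id[r])
    }
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       donor_only_ids = setdiff(dids, acc_associated),
       acceptor_only_ids = setdiff(aids, pairs$acceptor_id),
       acceptor_trajs_mapped = am)
}

#' Detect abrupt mean shifts in an intensity time series
#'
#' Binary-segmentation change-point detection with a BIC-style penalty.
#' The noise level is estimated from the median absolute first difference,
#' which is insensitive to the steps themselves, and a split is accepted
#' when it reduces the residual sum of squares by more than
#' `pen_mult * sigma^2 * log(n)`; a constant-plus-noise series therefore
#' yields no change points.
#'
#' @param series numeric intensity series (length >= 10).
#' @param min_size minimum segment length.
#' @param pen_mult penalty multiplier.
#' @return data.frame with one row per change point: `index` (first index
#'   of the new segment), `before_mean`, `after_mean`.
#' @examples
#' x <- c(rep(1000, 50), rep(0, 50)) + rnorm(100, 0, 30)
#' detect_intensity_steps(x)
#' @export
detect_intensity_steps <- function(series, min_size = 3, pen_mult = 3) {
  n <- length(series)
  if (n < 10) stop("series shorter than 10 frames")
  sigma <- max(median(abs(diff(series))) / (sqrt(2) * 0.6744898), 1e-9)
  pen <- pen_mult * sigma^2 * log(n)
  cps <- integer()
  best_split <- function(lo, hi) {
    x <- series[lo:hi]
    m <- length(x)
    if (m < 2 * min_size) return(NULL)
    cs <- cumsum(x)
    tot <- cs[m]
    i <- min_size:(m - min_size)
    nl <- i
    nr <- m - i
    # SSE reduction of splitting at i equals n_l*n_r/m * (mean_l - mean_r)^2
    gain <- (cs[i] - nl * tot / m)^2 * m / (nl * nr)
    bi <- which.max(gain)
    list(gain = gain[bi], at = lo + i[bi])  # first index of right segment
  }
  recurse <- function(lo, hi) {
    sp <- best_split(lo, hi)
    if (is.null(sp) || sp$gain <= pen) return(invisible())
    cps <<- c(cps, sp$at)
    recurse(lo, sp$at - 1L)
    recurse(sp$at, hi)
  }
  recurse(1L, n)
  cps <- sort(cps)
  if (!length(cps)) {
    return(data.frame(index = integer(), before_mean = numeric(),
                      after_mean = numeric()))
  }
  bounds <- c(1L, cps, n + 1L)
  segmeans <- vapply(seq_len(length(bounds) - 1L), function(k) {
    mean(series[bounds[k]:(bounds[k + 1L] - 1L)])
  }, 0)
  data.frame(index = cps,
             before_mean = segmeans[seq_along(cps)],
             after_mean = segmeans[seq_along(cps) + 1L])
}

#' Vet a candidate FRET trace
#'
#' Acceptance requires (a) exactly one downward step to background in the
#' acceptor (FRET-sensitized) series, defining the acceptor loss frame;
#' (b) at most one downward step in the donor series; and (c)
#' anti-correlation: the donor intensity rises by at least `k` noise
#' standard deviations across the acceptor loss -- or, symmetrically, a
#' donor decrease coincides with an acceptor increase at FRET onset -- or
#' donor and acceptor vanish together (the simultaneous-loss termination,
#' a pathway-2 candidate). Traces from multi-complex puncta fail (a)/(b)
#' through their multi-step photobleaching.
#'
#' @param trace a [fret_trace()].
#' @param W anti-correlation window in frames.
#' @param k required donor change in units of the donor noise sd.
#' @param bg_frac a downward step counts as "to background" when the final
#'   level is below `bg_frac` times the pre-step level.
#' @param min_overlap minimum trace length in frames.
#' @param pen_mult change-point penalty passed to
#'   [detect_intensity_steps()].
#' @param min_step_frac photobleaching steps are quantal, so detected mean
#'   shifts smaller than this fraction of the series' peak segment level
#'   are ignored as drift/noise rather than counted as steps.
#' @return the trace with `accepted`, `reason` and `acceptor_loss_frame`
#'   set.
#' @export
vet_fret_trace <- function(trace, W = 5, k = 2, bg_frac = 0.25,
                           min_overlap = 10, pen_mult = 3,
                           min_step_frac = 0.25) {
  stopifnot(inherits(trace, "fret_trace"))
  n <- length(trace$frames)
  if (n < min_overlap) {
    trace$accepted <- FALSE
    trace$reason <- "too_short"
    return(trace)
  }
  acc <- trace$I_AD
  don <- trace$I_DD
  sizable <- function(st) {
    if (!nrow(st)) return(st)
    lvl <- max(abs(c(st$before_mean, st$after_mean)))
    st[abs(st$after_mean - st$before_mean) >= min_step_frac * lvl, ,
       drop = FALSE]
  }
  steps_a <- sizable(detect_intensity_steps(acc, pen_mult = pen_mult))
  down_a <- steps_a[steps_a$after_mean < steps_a$before_mean, , drop = FALSE]
  up_a <- steps_a[steps_a$after_mean >= steps_a$before_mean, , drop = FALSE]
  steps_d <- sizable(detect_intensity_steps(don, pen_mult = pen_mult))
  down_d <- steps_d[steps_d$after_mean < steps_d$before_mean, , drop = FALSE]

  if (nrow(down_a) != 1L) {
    trace$accepted <- FALSE
    trace$reason <- if (nrow(down_a) > 1L) "multi_step" else "no_anticorrelation"
    return(trace)
  }
  peak_a <- max(steps_a$before_mean, steps_a$after_mean)
  tail_level <- down_a$after_mean[1]
  sig_a <- max(median(abs(diff(acc))) / (sqrt(2) * 0.6744898), 1e-9)
  to_bg <- tail_level < max(bg_frac * peak_a, 3 * sig_a)
  if (!to_bg) {
    trace$accepted <- FALSE
    trace$reason <- "no_anticorrelation"
    return(trace)
  }
  if (nrow(down_d) > 1L) {
    trace$accepted <- FALSE
    trace$reason <- "multi_step"
    return(trace)
  }
  loss_idx <- down_a$index[1]
  trace$acceptor_loss_frame <- trace$frames[loss_idx]

  sig_d <- max(median(abs(diff(don)), na.rm = TRUE) / (sqrt(2) * 0.6744898),
               1e-9)
  pre <- don[max(1, loss_idx - W):(loss_idx - 1)]
  post <- don[loss_idx:min(n, loss_idx + W - 1)]
  donor_rise <- mean(post, na.rm = TRUE) - mean(pre, na.rm = TRUE) >=
    k * sig_d
  # symmetric criterion at FRET onset: donor falls while acceptor rises
  onset_anticorr <- FALSE
  if (nrow(up_a) >= 1L && nrow(down_d) == 1L) {
    onset_anticorr <- any(abs(up_a$index - down_d$index[1]) <= W)
  }
  # simultaneous loss: donor is at background right after the acceptor loss
  both_lost <- mean(post, na.rm = TRUE) < 3 * sig_d
  if (donor_rise || onset_anticorr || both_lost) {
    trace$accepted <- TRUE
    trace$reason <- NA_character_
    trace$both_lost <- both_lost && !donor_rise
  } else {
    trace$accepted <- FALSE
    trace$reason <- "no_anticorrelation"
  }
  trace
}

#' Concatenate the continuing donor trajectory after acceptor loss
#'
#' Among donor trajectories with a localization within `max_gap` frames of
#' the acceptor loss and within `search_radius_nm` of the last FRET
#' position, the nearest is appended to the trace's donor series and
#' coordinates (only its frames from the loss on). If none qualifies the
#' trace ends at donor loss (pathway-2 candidate).
#'
#' @param trace a [fret_trace()] with `acceptor_loss_frame` set.
#' @param donor_trajs donor-channel trajectory data.frame.
#' @param search_radius_nm search radius (default the 250 nm concatenation
#'   radius).
#' @param max_gap maximum frames between acceptor loss and donor start.
#' @return the trace, extended in place; the id of the appended donor
#'   trajectory is recorded in `concatenated_donor_id`.
#' @export
concatenate_donor <- function(trace, donor_trajs, search_radius_nm = 250,
                              max_gap = 3L) {
  stopifnot(inherits(trace, "fret_trace"))
  lf <- trace$acceptor_loss_frame
  if (is.na(lf)) return(trace)
  li <- match(lf, trace$frames)
  ref_idx <- max(1L, li - 1L)
  if (is.null(trace$coords) || !nrow(trace$coords)) return(trace)
  ci <- match(trace$frames[ref_idx], trace$coords$frame)
  if (is.na(ci)) ci <- which.min(abs(trace$coords$frame - lf))
  x0 <- trace$coords$x_um[ci]
  y0 <- trace$coords$y_um[ci]
  # donor trajectories active near the loss frame and position
  near <- donor_trajs[donor_trajs$frame >= lf - 1L &
                        donor_trajs$frame <= lf + max_gap &
                        !(donor_trajs$traj_id %in%
                            c(trace$donor_traj_id,
                              trace$concatenated_donor_id)), , drop = FALSE]
  if (!nrow(near)) return(trace)
  near$dist_nm <- 1000 * sqrt((near$x_um - x0)^2 + (near$y_um - y0)^2)
  near <- near[near$dist_nm <= search_radius_nm, , drop = FALSE]
  if (!nrow(near)) return(trace)
  per_id <- tapply(near$dist_nm, near$traj_id, min)
  pick <- as.integer(names(per_id)[order(per_id, as.integer(names(per_id)))][1])
  drows <- donor_trajs[donor_trajs$traj_id == pick, ]
  drows <- drows[order(drows$frame), ]
  # fill donor intensities on frames the trace already spans
  ei <- match(trace$frames, drows$frame)
  fillable <- is.na(trace$I_DD) & !is.na(ei)
  trace$I_DD[fillable] <- drows$photons[ei[fillable]]
  new_frames <- if (max(drows$frame) > max(trace$frames)) {
    seq(max(trace$frames) + 1L, max(drows$frame))
  } else {
    integer()
  }
  if (length(new_frames)) {
    idx <- match(new_frames, drows$frame)
    I_DD_new <- drows$photons[idx]
    I_DD_new <- fill_gaps(I_DD_new)
    trace$frames <- c(trace$frames, new_frames)
    trace$I_DD <- c(trace$I_DD, I_DD_new)
    trace$I_AD <- c(trace$I_AD, rep(0, length(new_frames)))
    if (!is.null(trace$I_AA)) {
      trace$I_AA <- c(trace$I_AA, rep(0, length(new_frames)))
    }
  }
  add_coords <- data.frame(frame = drows$frame, x_um = drows$x_um,
                           y_um = drows$y_um,
                           precision_nm = if ("precision_nm" %in% names(drows))
                             drows$precision_nm else NA_real_,
                           source = "donor")
  add_coords <- add_coords[!add_coords$frame %in% trace$coords$frame, ]
  trace$coords <- rbind(trace$coords, add_coords)
  trace$coords <- trace$coords[order(trace$coords$frame), ]
  trace$concatenated_donor_id <- pick
  trace
}

# Linear interpolation over interior NAs; leading/trailing NAs -> 0.
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2) {
    out <- rep(0, length(x))
    out[idx] <- x[idx]
    return(out)
  }
  out <- approx(seq_along(x)[idx], x[idx], xout = seq_along(x),
                rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Estimate the smFRET correction factors
#'
#' `alpha` (donor emission leakage into the acceptor channel) is the mean
#' over donor-only traces of `mean(I_AD) / mean(I_DD)`. `delta` (acceptor
#' direct excitation by the donor laser) is the mean over acceptor-only
#' traces of `mean(I_AD) / mean(I_AA)` and requires ALEX data. `gamma`
#' (detection-efficiency / quantum-yield imbalance) is estimated tracewise
#' from accepted FRET traces as the ratio of the acceptor drop to the donor
#' rise across the acceptor photobleaching/loss step, after alpha/delta
#' correction. `beta` (excitation imbalance, ALEX only) is set so that
#' dual-labelled calibration traces have stoichiometry 0.5. Each factor is
#' averaged across traces for global use and reported with its
#' across-trace standard deviation.
#'
#' @param donor_only_traces,acceptor_only_traces,fret_traces lists of
#'   [fret_trace()] objects. `fret_traces` must be vetted, with
#'   `acceptor_loss_frame` set.
#' @param W window in frames on each side of the acceptor loss for the
#'   gamma step ratio.
#' @param min_traces minimum traces per calibration class.
#' @param delta,alpha,gamma override a factor instead of estimating it
#'   (e.g. delta imported from an ALEX calibration run when live-cell data
#'   carry no `I_AA`).
#' @return object of class `correction_factors`: list with `alpha`,
#'   `delta`, `gamma`, `beta` and `*_sd`, `n_*` entries.
#' @export
estimate_correction_factors <- function(donor_only_traces = list(),
                                        acceptor_only_traces = list(),
                                        fret_traces = list(), W = 5,
                                        min_traces = 5,
                                        alpha = NULL, delta = NULL,
                                        gamma = NULL) {
  out <- list(alpha = NA_real_, alpha_sd = NA_real_, n_alpha = 0L,
              delta = NA_real_, delta_sd = NA_real_, n_delta = 0L,
              gamma = NA_real_, gamma_sd = NA_real_, n_gamma = 0L,
              beta = NA_real_, beta_sd = NA_real_, n_beta = 0L)
  if (is.null(alpha)) {
    if (length(donor_only_traces) < min_traces) {
      stop("insufficient donor-only calibration traces for alpha")
    }
    a <- vapply(donor_only_traces, function(tr) {
      mean(tr$I_AD, na.rm = TRUE) / mean(tr$I_DD, na.rm = TRUE)
    }, 0)
    a <- a[is.finite(a)]
    out$alpha <- mean(a)
    out$alpha_sd <- sd(a)
    out$n_alpha <- length(a)
  } else {
    out$alpha <- alpha
  }
  if (is.null(delta)) {
    if (length(acceptor_only_traces) >= min_traces &&
        all(vapply(acceptor_only_traces,
                   function(tr) !is.null(tr$I_AA), TRUE))) {
      d <- vapply(acceptor_only_traces, function(tr) {
        mean(tr$I_AD, na.rm = TRUE) / mean(tr$I_AA, na.rm = TRUE)
      }, 0)
      d <- d[is.finite(d)]
      out$delta <- mean(d)
      out$delta_sd <- sd(d)
      out$n_delta <- length(d)
    } else if (length(acceptor_only_traces)) {
      stop("insufficient acceptor-only (ALEX) calibration traces for delta")
    } else {
      out$delta <- 0  # live-cell single-excitation mode without calibration
    }
  } else {
    out$delta <- delta
  }
  fr <- Filter(function(tr) isTRUE(tr$accepted) && !is.na(tr$acceptor_loss_frame) &&
                 !isTRUE(tr$both_lost), fret_traces)
  if (!is.null(gamma)) {
    out$gamma <- gamma
  } else if (length(fr)) {
    g <- vapply(fr, function(tr) {
      li <- match(tr$acceptor_loss_frame, tr$frames)
      pre <- max(1L, li - W):(li - 1L)
      post <- li:min(length(tr$frames), li + W - 1L)
      iaa_pre <- if (is.null(tr$I_AA)) 0 else mean(tr$I_AA[pre], na.rm = TRUE)
      iaa_post <- if (is.null(tr$I_AA)) 0 else mean(tr$I_AA[post], na.rm = TRUE)
      fc_pre <- mean(tr$I_AD[pre], na.rm = TRUE) -
        out$alpha * mean(tr$I_DD[pre], na.rm = TRUE) - out$delta * iaa_pre
      fc_post <- mean(tr$I_AD[post], na.rm = TRUE) -
        out$alpha * mean(tr$I_DD[post], na.rm = TRUE) - out$delta * iaa_post
      dd <- mean(tr$I_DD[post], na.rm = TRUE) - mean(tr$I_DD[pre], na.rm = TRUE)
      (fc_pre - fc_post) / dd
    }, 0)
    g <- g[is.finite(g) & g > 0]
    if (length(g) >= min_traces) {
      out$gamma <- mean(g)
      out$gamma_sd <- sd(g)
      out$n_gamma <- length(g)
    }
  }
  if (is.na(out$gamma)) {
    if (length(fr)) stop("insufficient accepted FRET traces for gamma")
    out$gamma <- 1
  }
  stopifnot(out$gamma > 0)
  alex_tr <- Filter(function(tr) !is.null(tr$I_AA), fr)
  if (length(alex_tr) >= min_traces) {
    b <- vapply(alex_tr, function(tr) {
      li <- match(tr$acceptor_loss_frame, tr$frames)
      pre <- seq_len(max(1L, li - 1L))
      idd <- mean(tr$I_DD[pre], na.rm = TRUE)
      iad <- mean(tr$I_AD[pre], na.rm = TRUE)
      iaa <- mean(tr$I_AA[pre], na.rm = TRUE)
      fc <- iad - out$alpha * idd - out$delta * iaa
      iaa / (out$gamma * idd + fc)  # beta making S = 0.5
    }, 0)
    b <- b[is.finite(b) & b > 0]
    out$beta <- mean(b)
    out$beta_sd <- sd(b)
    out$n_beta <- length(b)
  }
  structure(out, class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat("smFRET correction factors (tracewise means +/- across-trace sd)\n")
  cat(sprintf("  alpha = %.4f +/- %.4f (n=%d)\n", x$alpha, x$alpha_sd, x$n_alpha))
  cat(sprintf("  delta = %.4f +/- %.4f (n=%d)\n", x$delta, x$delta_sd, x$n_delta))
  cat(sprintf("  gamma = %.4f +/- %.4f (n=%d)\n", x$gamma, x$gamma_sd, x$n_gamma))
  cat(sprintf("  beta  = %.4f +/- %.4f (n=%d)\n", x$beta, x$beta_sd, x$n_beta))
  invisible(x)
}

#' Corrected FRET efficiency
#'
#' `F_corr = I_AD - alpha * I_DD - delta * I_AA` (the `I_AA` term is
#' dropped without ALEX data), and `E = F_corr / (gamma * I_DD + F_corr)`.
#' Values are reported unclipped; frames where the denominator is not
#' positive are returned as `NA` and flagged, and are excluded from
#' histograms.
#'
#' @param trace a [fret_trace()], or a plain list with `I_DD`, `I_AD` and
#'   optionally `I_AA`.
#' @param factors a `correction_factors` object (or list with `alpha`,
#'   `delta`, `gamma`).
#' @return for a `fret_trace`: the trace with per-frame `E` filled in
#'   (only frames before the acceptor loss, when known) and an
#'   `invalid_frames` attribute on `E`; otherwise the numeric E vector.
#' @examples
#' fx <- list(alpha = 0.05, delta = 0.1, gamma = 1.2)
#' compute_fret_efficiency(list(I_DD = 300, I_AD = 700, I_AA = 500), fx)
#' @export
compute_fret_efficiency <- function(trace, factors) {
  stopifnot(factors$gamma > 0, factors$alpha >= 0)
  ev <- function(idd, iad, iaa) {
    fc <- iad - factors$alpha * idd -
      (if (is.null(iaa)) 0 else factors$delta * iaa)
    den <- factors$gamma * idd + fc
    e <- ifelse(den > 0, fc / den, NA_real_)
    attr(e, "invalid_frames") <- which(!(den > 0))
    e
  }
  if (inherits(trace, "fret_trace")) {
    sel <- if (!is.na(trace$acceptor_loss_frame)) {
      trace$frames < trace$acceptor_loss_frame
    } else {
      rep(TRUE, length(trace$frames))
    }
    E <- rep(NA_real_, length(trace$frames))
    e <- ev(trace$I_DD[sel], trace$I_AD[sel],
            if (is.null(trace$I_AA)) NULL else trace$I_AA[sel])
    E[sel] <- e
    attr(E, "invalid_frames") <- which(sel)[attr(e, "invalid_frames")]
    trace$E <- E
    trace
  } else {
    ev(trace$I_DD, trace$I_AD, trace$I_AA)
  }
}

#' ALEX stoichiometry
#'
#' `S = (gamma * I_DD + F_corr) / (gamma * I_DD + F_corr + I_AA / beta)`.
#'
#' @inheritParams compute_fret_efficiency
#' @return numeric S vector (or the trace with `S` filled in).
#' @export
compute_stoichiometry <- function(trace, factors) {
  iaa <- if (inherits(trace, "fret_trace")) trace$I_AA else trace$I_AA
  if (is.null(iaa)) stop("ALEX data required: trace has no I_AA")
  stopifnot(factors$beta > 0)
  idd <- trace$I_DD
  iad <- trace$I_AD
  fc <- iad - factors$alpha * idd - factors$delta * iaa
  num <- factors$gamma * idd + fc
  s <- num / (num + iaa / factors$beta)
  if (inherits(trace, "fret_trace")) {
    trace$S <- s
    trace
  } else {
    s
  }
}

#' Least-squares Gaussian fit to a histogram
#'
#' Histograms `values` and fits `A * exp(-(x - mean)^2 / (2 * sd^2))` to
#' the bin counts by Levenberg-Marquardt least squares.
#'
#' @param values numeric sample (>= 30 values).
#' @param bins number of histogram bins.
#' @param range histogram range (default data range).
#' @return list of class `gaussian_hist_fit`: `mean`, `sd`, `amplitude`,
#'   standard errors `mean_se`, `sd_se`, `r_squared`, and the histogram
#'   (`mids`, `counts`).
#' @export
fit_gaussian_histogram <- function(values, bins = 40, range = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 30) stop("need at least 30 values")
  if (sd(values) == 0) stop("degenerate sample: all values identical")
  if (is.null(range)) range <- base::range(values)
  brk <- seq(range[1], range[2], length.out = bins + 1L)
  h <- hist(values, breaks = brk, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(A = max(h$counts), mu = mean(values), s = sd(values))
  ft <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = start,
                      control = nls.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(ft)) {
    stop("Gaussian histogram fit failed to converge; counts: ",
         paste(h$counts, collapse = " "))
  }
  cf <- coef(ft)
  se <- tryCatch(sqrt(diag(vcov(ft))), error = function(e) rep(NA_real_, 3))
  r2 <- 1 - sum(residuals(ft)^2) / sum((df$y - mean(df$y))^2)
  structure(list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
                 amplitude = unname(cf["A"]),
                 mean_se = unname(se[2]), sd_se = unname(se[3]),
                 r_squared = r2, mids = h$mids, counts = h$counts,
                 n = length(values)),
            class = "gaussian_hist_fit")
}

#' @export
print.gaussian_hist_fit <- function(x, ...) {
  cat(sprintf("Gaussian histogram fit: mean %.4f +/- %.4f, sd %.4f +/- %.4f (n=%d, R^2=%.3f)\n",
              x$mean, x$mean_se, x$sd, x$sd_se, x$n, x$r_squared))
  invisible(x)
}

#' @export
plot.gaussian_hist_fit <- function(x, ...) {
  plot(x$mids, x$counts, type = "h", xlab = "value", ylab = "count", ...)
  xx <- seq(min(x$mids), max(x$mids), length.out = 200)
  lines(xx, x$amplitude * exp(-(xx - x$mean)^2 / (2 * x$sd^2)), col = 2)
  invisible(x)
}
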