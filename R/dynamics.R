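#' Time-averaged mean squared displacement of a trajectory segment
#'
#' For each lag `n`, the mean over all frame pairs `(i, i + n)` with both
#' endpoints localized of the squared 2-D displacement. Pairs with a
#' missing endpoint (gap frames) are excluded; per-lag pair counts are
#' returned for use as fit weights.
#'
#' @param coords data.frame with `frame`, `x_um`, `y_um` (frames need not
#'   be consecutive; gaps are handled by pair exclusion).
#' @param frame_interval frame interval in s.
#' @param max_lag maximum lag in frames (default: span - 1).
#' @return data.frame of class `msd_curve`: `lag_frames`, `lag_s`, `msd`
#'   (um^2), `n_pairs`; lags with no pairs are omitted.
#' @examples
#' co <- data.frame(frame = 1:4, x_um = 0:3, y_um = 0)
#' compute_msd(co, frame_interval = 1)  # MSD 1, 4, 9
#' @export
compute_msd <- function(coords, frame_interval = 0.040, max_lag = NULL) {
  if (nrow(coords) < 5) stop("segment too short: need >= 5 positions")
  coords <- coords[order(coords$frame), ]
  f <- coords$frame
  if (anyDuplicated(f)) stop("duplicate frames in segment")
  span <- max(f) - min(f)
  if (is.null(max_lag)) max_lag <- span
  out <- list()
  for (n in seq_len(max_lag)) {
    j <- match(f + n, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (coords$x_um[j[ok]] - coords$x_um[ok])^2 +
      (coords$y_um[j[ok]] - coords$y_um[ok])^2
    out[[length(out) + 1L]] <- data.frame(lag_frames = n,
                                          lag_s = n * frame_interval,
                                          msd = mean(d2),
                                          n_pairs = sum(ok))
  }
  res <- do.call(rbind, out)
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Fit a diffusion model to an MSD curve
#'
#' Free model: `MSD(t) = 4 D t + 4 sigma^2`, weighted least squares over
#' the first four lags (weights = per-lag pair counts); `D` is always
#' reported from this first-four-point fit. Confined model:
#' `MSD(t) = L^2 (1 - exp(-t / tau_c)) + 4 sigma^2`, fit over a longer lag
#' range (default up to half the available lags). A negative intercept
#' leaves `D` reported but the dynamic localization precision flagged not
#' estimable (`sigma_dyn_nm = NA`).
#'
#' @param msd an [compute_msd()] curve.
#' @param model `"free"` or `"confined"`.
#' @param n_lags number of lags for the free fit (default 4).
#' @param max_lag_confined last lag for the confined fit (default half the
#'   segment's available lags, minimum 4).
#' @return list of class `msd_fit`: for free, `D` (um^2/s), `sigma_dyn_nm`,
#'   `intercept`, `rss`, `fitted`; for confined additionally `L_um`,
#'   `tau_c_s`.
#' @export
fit_msd <- function(msd, model = c("free", "confined"), n_lags = 4,
                    max_lag_confined = NULL) {
  model <- match.arg(model)
  if (nrow(msd) < n_lags) stop("need at least ", n_lags, " lags")
  if (model == "free") {
    d <- msd[seq_len(n_lags), ]
    if (all(d$msd == d$msd[1])) stop("singular fit: all lags equal")
    ft <- lm(msd ~ lag_s, data = d, weights = d$n_pairs)
    slope <- unname(coef(ft)[2])
    icpt <- unname(coef(ft)[1])
    D <- slope / 4
    sigma_dyn <- if (icpt >= 0) 1000 * sqrt(icpt / 4) else NA_real_
    structure(list(model = "free", D = D, sigma_dyn_nm = sigma_dyn,
                   intercept = icpt, rss = sum(residuals(ft)^2),
                   fitted = predict(ft, newdata = msd), lags = d$lag_s),
              class = "msd_fit")
  } else {
    if (is.null(max_lag_confined)) {
      max_lag_confined <- max(4, floor(nrow(msd) / 2))
    }
    d <- msd[msd$lag_frames <= max_lag_confined, ]
    if (all(d$msd == d$msd[1])) stop("singular fit: all lags equal")
    L0 <- sqrt(max(d$msd))
    t0 <- d$lag_s[min(which(d$msd >= 0.63 * max(d$msd)))]
    ft <- tryCatch(
      minpack.lm::nlsLM(
        msd ~ L^2 * (1 - exp(-lag_s / tau)) + 4 * s2,
        data = d, weights = d$n_pairs,
        start = list(L = L0, tau = max(t0, d$lag_s[1]), s2 = 0),
        lower = c(1e-6, 1e-6, -Inf),
        control = nls.control(maxiter = 200, warnOnly = TRUE)
      ),
      error = function(e) NULL
    )
    if (is.null(ft)) stop("confined MSD fit failed")
    cf <- coef(ft)
    s2 <- unname(cf["s2"])
    structure(list(model = "confined", L_um = abs(unname(cf["L"])),
                   tau_c_s = unname(cf["tau"]),
                   sigma_dyn_nm = if (s2 >= 0) 1000 * sqrt(s2) else NA_real_,
                   intercept = 4 * s2, rss = sum(residuals(ft)^2),
                   fitted = predict(ft, newdata = msd), lags = d$lag_s),
              class = "msd_fit")
  }
}

#' @export
print.msd_fit <- function(x, ...) {
  if (x$model == "free") {
    cat(sprintf("MSD fit (free): D = %.4g um^2/s, sigma_dyn = %s nm\n",
                x$D, if (is.na(x$sigma_dyn_nm)) "not estimable"
                else sprintf("%.1f", x$sigma_dyn_nm)))
  } else {
    cat(sprintf("MSD fit (confined): L = %.3f um, tau_c = %.3f s\n",
                x$L_um, x$tau_c_s))
  }
  invisible(x)
}

#' Classify a segment's motion as free or confined
#'
#' Default criterion: free diffusion grows proportionally with lag, so the
#' long-lag MSD is predicted by scaling the lag-1 MSD (the least
#' confinement-biased mobility estimate: under strong confinement even the
#' first-four-lag fit is already saturated). The pair-count-weighted
#' relative shortfall of the observed long-lag MSD below that proportional
#' prediction is the confinement deviation; the segment is called confined
#' when it exceeds `theta`. An MSD exactly proportional to lag is
#' therefore always free. The localization-noise intercept inflates the
#' lag-1 prediction and biases the deviation slightly upward for free
#' motion, which the default `theta` accommodates. The criterion and
#' `theta` are recorded in the result.
#'
#' @param msd an [compute_msd()] curve.
#' @param free_fit the free-model [fit_msd()] of the same curve (computed
#'   here when omitted; reported alongside, not used by the default
#'   criterion).
#' @param theta deviation threshold.
#' @param lag_range frames of the long-lag window (default lag 5 up to
#'   min(10, available)).
#' @return list: `motion_class` (`"free"` or `"confined"`), `deviation`,
#'   `theta`.
#' @export
classify_motion <- function(msd, free_fit = NULL, theta = 0.6,
                            lag_range = NULL) {
  if (is.null(lag_range)) lag_range <- 5:min(10, max(msd$lag_frames))
  sel <- msd$lag_frames %in% lag_range
  if (!any(sel) || msd$msd[1] <= 0) {
    return(list(motion_class = "free", deviation = 0, theta = theta))
  }
  pred <- msd$msd[1] * msd$lag_frames[sel]
  w <- msd$n_pairs[sel]
  dev <- 1 - sum(w * msd$msd[sel]) / sum(w * pred)
  list(motion_class = if (dev > theta) "confined" else "free",
       deviation = dev, theta = theta)
}

#' Jump angles of a trajectory segment
#'
#' The angle between consecutive displacement vectors, folded to
#' [0, 180] degrees. Only displacements between consecutive frames are
#' used; pairs spanning gap frames are excluded, and zero-length
#' displacements are skipped (count recorded in the `n_skipped`
#' attribute).
#'
#' @param coords data.frame with `frame`, `x_um`, `y_um`.
#' @return numeric vector of angles in degrees, attribute `n_skipped`.
#' @export
compute_jump_angles <- function(coords) {
  if (nrow(coords) < 3) stop("need >= 3 positions")
  coords <- coords[order(coords$frame), ]
  f <- coords$frame
  dx <- diff(coords$x_um)
  dy <- diff(coords$y_um)
  consecutive <- diff(f) == 1L
  angles <- numeric()
  skipped <- 0L
  for (i in seq_len(length(dx) - 1L)) {
    if (!consecutive[i] || !consecutive[i + 1L]) next
    n1 <- sqrt(dx[i]^2 + dy[i]^2)
    n2 <- sqrt(dx[i + 1L]^2 + dy[i + 1L]^2)
    if (n1 == 0 || n2 == 0) {
      skipped <- skipped + 1L
      next
    }
    cosang <- (dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]) / (n1 * n2)
    angles <- c(angles, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  attr(angles, "n_skipped") <- skipped
  angles
}

#' Histogram jump angles as relative frequencies
#'
#' @param angles vector of angles in degrees (0..180).
#' @param bins number of bins (default 18 bins of 10 degrees).
#' @return data.frame `mid_deg`, `rel_freq` (normalized to sum 1).
#' @export
jump_angle_histogram <- function(angles, bins = 18) {
  brk <- seq(0, 180, length.out = bins + 1L)
  h <- hist(as.numeric(angles), breaks = brk, plot = FALSE)
  data.frame(mid_deg = h$mids, rel_freq = h$counts / sum(h$counts))
}

#' Fit a single-exponential decay to FRET-segment durations
#'
#' Durations longer than `max_s` (default 10 s) are excluded, the rest are
#' histogrammed at a bin width of `bin_frames` frame intervals, and
#' `A * exp(-t / tau)` is fit to the counts by least squares. The first
#' populated bin is excluded by default to mitigate the censoring imposed
#' by the minimum trajectory length.
#'
#' @param durations_s FRET-segment durations in seconds.
#' @param frame_interval frame interval in s.
#' @param bin_frames histogram bin width in frames.
#' @param exclude_first_bin drop the first populated bin before fitting.
#' @param max_s exclusion threshold in s.
#' @param min_n minimum number of retained durations.
#' @return object of class `lifetime_fit`: `tau_s`, `tau_stderr_s`,
#'   `n_traces`, `breaks`, `counts`, `excluded_long`, `note`.
#' @export
fit_lifetime <- function(durations_s, frame_interval = 0.040,
                         bin_frames = 2L, exclude_first_bin = TRUE,
                         max_s = 10, min_n = 30) {
  durations_s <- durations_s[is.finite(durations_s)]
  keep <- durations_s <= max_s
  excluded_long <- sum(!keep)
  x <- durations_s[keep]
  if (length(x) < min_n) stop("need at least ", min_n, " durations")
  bw <- bin_frames * frame_interval
  brk <- seq(0, max(x) + bw, by = bw)
  h <- hist(x, breaks = brk, plot = FALSE)
  df <- data.frame(t = h$mids, y = h$counts)
  pop <- which(df$y > 0)
  if (length(pop) < 3) stop("fewer than 3 populated histogram bins")
  lo <- pop[1] + if (exclude_first_bin) 1L else 0L
  df <- df[lo:nrow(df), ]
  if (sum(df$y > 0) < 3) stop("fewer than 3 populated histogram bins after exclusion")
  ft <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                      start = list(A = max(df$y), tau = mean(x)),
                      control = nls.control(maxiter = 200)),
    error = function(e) stop("lifetime fit failed: ", conditionMessage(e))
  )
  cf <- coef(ft)
  se <- tryCatch(sqrt(diag(vcov(ft)))["tau"], error = function(e) NA_real_)
  structure(list(tau_s = unname(cf["tau"]), tau_stderr_s = unname(se),
                 n_traces = length(x), breaks = h$breaks, counts = h$counts,
                 excluded_long = excluded_long,
                 note = sprintf("durations > %g s excluded (%d); first bin %s",
                                max_s, excluded_long,
                                if (exclude_first_bin) "excluded" else "included")),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("lifetime_fit: tau = %.3f +/- %.3f s (n = %d; %s)\n",
              x$tau_s, x$tau_stderr_s, x$n_traces, x$note))
  invisible(x)
}

#' @export
plot.lifetime_fit <- function(x, ...) {
  mids <- (head(x$breaks, -1) + tail(x$breaks, -1)) / 2
  plot(mids, x$counts, type = "h", xlab = "FRET duration (s)",
       ylab = "count", ...)
  xx <- seq(0, max(mids), length.out = 200)
  A <- max(x$counts)
  lines(xx, A * exp(-xx / x$tau_s), col = 2)
  invisible(x)
}

#' Compare two diffusion-coefficient samples (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, with the significance
#' band convention n.s. (p > 0.05), * (p < 0.05), ** (p < 0.01),
#' *** (p < 0.001). For identical samples the normal-approximation p-value
#' is reported (> 0.99 rather than exactly 1).
#'
#' @param d_coeffs_A,d_coeffs_B numeric samples (n >= 5 each).
#' @return list: `U`, `p_value`, `significance`, `n_A`, `n_B`,
#'   `median_A`, `median_B`.
#' @export
compare_groups <- function(d_coeffs_A, d_coeffs_B) {
  d_coeffs_A <- d_coeffs_A[is.finite(d_coeffs_A)]
  d_coeffs_B <- d_coeffs_B[is.finite(d_coeffs_B)]
  if (length(d_coeffs_A) < 5 || length(d_coeffs_B) < 5) {
    stop("need at least 5 values per group")
  }
  wt <- suppressWarnings(wilcox.test(d_coeffs_A, d_coeffs_B,
                                     alternative = "two.sided",
                                     exact = FALSE))
  p <- wt$p.value
  sig <- if (p > 0.05) "n.s." else if (p >= 0.01) "*" else if (p >= 0.001) "**" else "***"
  list(U = unname(wt$statistic), p_value = p, significance = sig,
       n_A = length(d_coeffs_A), n_B = length(d_coeffs_B),
       median_A = median(d_coeffs_A), median_B = median(d_coeffs_B))
}
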