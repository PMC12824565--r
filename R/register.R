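#' Affine channel transform
#'
#' Maps acceptor-channel coordinates (um) into donor-channel coordinates:
#' `donor = A %*% c(x, y) + b`.
#'
#' @param A 2x2 linear part.
#' @param b length-2 offset in um.
#' @param rms_residual_nm fit residual (NA for a manually built transform).
#' @param n_fiducials number of beads used in the fit.
#' @return object of class `channel_transform`.
#' @export
channel_transform <- function(A = diag(2), b = c(0, 0),
                              rms_residual_nm = NA_real_,
                              n_fiducials = NA_integer_) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("transform is not invertible")
  structure(list(A = A, b = as.numeric(b),
                 rms_residual_nm = rms_residual_nm,
                 n_fiducials = n_fiducials),
            class = "channel_transform")
}

#' @export
print.channel_transform <- function(x, ...) {
  cat("channel_transform (acceptor -> donor)\n")
  cat(sprintf("  A = [%.6f %.6f; %.6f %.6f], b = (%.4f, %.4f) um\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b[1], x$b[2]))
  if (!is.na(x$rms_residual_nm)) {
    cat(sprintf("  rms residual %.2f nm over %d fiducials\n",
                x$rms_residual_nm, x$n_fiducials))
  }
  invisible(x)
}

#' Apply or invert a channel transform
#'
#' @param tf a [channel_transform()].
#' @param x,y acceptor-channel coordinates in um.
#' @return `apply_transform`: list with donor-channel `x`, `y`;
#'   `invert_transform`: the inverse `channel_transform`.
#' @export
apply_transform <- function(tf, x, y) {
  stopifnot(inherits(tf, "channel_transform"))
  list(x = tf$A[1, 1] * x + tf$A[1, 2] * y + tf$b[1],
       y = tf$A[2, 1] * x + tf$A[2, 2] * y + tf$b[2])
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  Ai <- solve(tf$A)
  channel_transform(Ai, -as.numeric(Ai %*% tf$b),
                    rms_residual_nm = tf$rms_residual_nm,
                    n_fiducials = tf$n_fiducials)
}

#' Write / read a channel transform as a 6-coefficient text file
#'
#' @param tf a [channel_transform()].
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  writeLines(format(c(tf$A[1, 1], tf$A[1, 2], tf$A[2, 1], tf$A[2, 2],
                      tf$b[1], tf$b[2]), digits = 17), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- as.numeric(readLines(path))
  channel_transform(matrix(v[1:4], 2, 2, byrow = TRUE), v[5:6])
}

# Average per-frame bead localizations into one position per bead by
# greedy spatial clustering (beads are stationary and well separated).
cluster_beads <- function(locs, radius_um = 0.5) {
  if (!nrow(locs)) return(locs[0, ])
  centers <- list()
  members <- list()
  for (r in seq_len(nrow(locs))) {
    hit <- 0L
    for (k in seq_along(centers)) {
      if (sum((centers[[k]] - c(locs$x_um[r], locs$y_um[r]))^2) < radius_um^2) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centers[[length(centers) + 1L]] <- c(locs$x_um[r], locs$y_um[r])
      members[[length(members) + 1L]] <- r
    } else {
      members[[hit]] <- c(members[[hit]], r)
      idx <- members[[hit]]
      centers[[hit]] <- c(mean(locs$x_um[idx]), mean(locs$y_um[idx]))
    }
  }
  data.frame(
    x_um = vapply(members, function(i) mean(locs$x_um[i]), 0),
    y_um = vapply(members, function(i) mean(locs$y_um[i]), 0),
    n = lengths(members)
  )
}

#' Register the acceptor channel onto the donor channel
#'
#' Localizes fiducial beads in both halves of a calibration movie, averages
#' localizations over frames, matches beads across channels by mutual
#' nearest neighbours, and fits a full 2-D affine transform by least
#' squares.
#'
#' @param bead_movie a `fretspt_movie` of fiducial beads (both channels).
#' @param params optional [detect_params()]; defaults use the movie's PSF.
#' @param min_frames minimum per-frame detections for a bead average.
#' @param max_residual_nm warn when the rms residual exceeds this gate.
#' @return a [channel_transform()] mapping acceptor to donor coordinates.
#' @export
register_channels <- function(bead_movie, params = NULL, min_frames = 3,
                              max_residual_nm = 20) {
  locs <- localize_movie(bead_movie, params = params,
                         transform = channel_transform())
  don <- cluster_beads(locs[locs$channel == "donor", ])
  acc <- cluster_beads(locs[locs$channel == "acceptor", ])
  don <- don[don$n >= min_frames, , drop = FALSE]
  acc <- acc[acc$n >= min_frames, , drop = FALSE]
  if (nrow(don) < 3 || nrow(acc) < 3) {
    stop("fewer than 3 beads localized per channel")
  }
  # Mutual nearest neighbours.
  d2 <- outer(don$x_um, acc$x_um, "-")^2 + outer(don$y_um, acc$y_um, "-")^2
  nn_da <- apply(d2, 1, which.min)
  nn_ad <- apply(d2, 2, which.min)
  mutual <- which(nn_ad[nn_da] == seq_len(nrow(don)))
  if (length(mutual) < 3) stop("fewer than 3 matched beads")
  dx <- don$x_um[mutual]; dy <- don$y_um[mutual]
  ax <- acc$x_um[nn_da[mutual]]; ay <- acc$y_um[nn_da[mutual]]
  if (abs(cor(ax, ay)) > 0.999) stop("matched beads are collinear")
  fx <- lm(dx ~ ax + ay)
  fy <- lm(dy ~ ax + ay)
  A <- rbind(coef(fx)[c("ax", "ay")], coef(fy)[c("ax", "ay")])
  b <- c(coef(fx)[1], coef(fy)[1])
  res <- sqrt(mean(residuals(fx)^2 + residuals(fy)^2)) * 1000
  if (res > max_residual_nm) {
    warning(sprintf("registration rms residual %.1f nm exceeds %.1f nm",
                    res, max_residual_nm))
  }
  channel_transform(A, b, rms_residual_nm = res,
                    n_fiducials = length(mutual))
}
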