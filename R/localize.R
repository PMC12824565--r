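#' Spot-detection and fitting parameters
#'
#' @param psf_sigma_px expected PSF standard deviation in pixels (start
#'   value; sigma is fit freely unless `fix_sigma` is given).
#' @param k_sd detection threshold: candidates must exceed
#'   mean + `k_sd` * sd of the band-pass-filtered frame.
#' @param fit_window odd window edge length in px for the Gaussian fit.
#' @param fix_sigma fix the PSF sigma (px) instead of fitting it, or `NULL`.
#' @param overlap `"joint"` (fit candidate pairs closer than one fit
#'   window as a two-Gaussian mixture; the default, preserving recall in
#'   denser fields) or `"drop"` (discard the dimmer of the two).
#' @param min_photons discard fits with fewer photons (suppresses
#'   noise-blip fits on near-empty frames).
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(psf_sigma_px = 1.0, k_sd = 4, fit_window = NULL,
                          fix_sigma = NULL, overlap = c("joint", "drop"),
                          min_photons = 50) {
  if (is.null(fit_window)) fit_window <- 2L * ceiling(3 * psf_sigma_px) + 1L
  fit_window <- as.integer(fit_window)
  if (fit_window %% 2L == 0L) fit_window <- fit_window + 1L
  structure(list(psf_sigma_px = psf_sigma_px, k_sd = k_sd,
                 fit_window = fit_window, fix_sigma = fix_sigma,
                 overlap = match.arg(overlap), min_photons = min_photons),
            class = "detect_params")
}

empty_locs <- function() {
  data.frame(frame = integer(), channel = character(), x_um = numeric(),
             y_um = numeric(), photons = numeric(), bg = numeric(),
             sigma_nm = numeric(), precision_nm = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect and localize single-molecule spots in one channel frame
#'
#' Candidate pixels are found by a difference-of-Gaussians band-pass
#' followed by 8-connected local maxima above a significance threshold;
#' each candidate is refined by Levenberg-Marquardt least squares of a
#' pixel-integrated symmetric 2-D Gaussian plus constant background.
#' Fits that fail to converge, run to the window edge, or return
#' non-positive amplitude are discarded. Candidates closer than one fit
#' window are either reduced to the brighter one or fit jointly as a
#' mixture, per `params$overlap`.
#'
#' @param frame_image numeric matrix, one channel of one frame, photon units.
#' @param channel `"donor"` or `"acceptor"` (recorded in the output).
#' @param params a [detect_params()].
#' @param pixel_size_nm pixel size in nm.
#' @param frame frame index recorded in the output.
#' @return data.frame with columns `frame`, `channel`, `x_um`, `y_um`
#'   (coordinates of the PSF centre relative to the channel origin, the
#'   pixel `(i, j)` spanning `[j, j+1) x [i, i+1)` pixel units), `photons`,
#'   `bg` (photons/px), `sigma_nm`, `precision_nm`.
#' @export
detect_spots <- function(frame_image, channel = "donor",
                         params = detect_params(), pixel_size_nm = 159,
                         frame = 1L) {
  if (!is.matrix(frame_image)) stop("frame_image must be a 2-D matrix")
  w <- params$fit_window
  if (w > min(dim(frame_image))) stop("fit window larger than image")
  cand <- dog_maxima_cpp(frame_image, params$psf_sigma_px,
                         2 * params$psf_sigma_px, params$k_sd)
  if (nrow(cand) == 0L) return(empty_locs())
  val <- frame_image[cbind(cand[, 1], cand[, 2])]
  ord <- order(-val, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  val <- val[ord]

  # Overlap handling: pairs closer than one fit window.
  joint_groups <- list()
  if (nrow(cand) > 1L) {
    d2 <- as.matrix(dist(cand))
    close <- d2 < w & upper.tri(d2)
    if (any(close)) {
      drop_idx <- integer()
      pairs <- which(close, arr.ind = TRUE)
      if (params$overlap == "drop") {
        drop_idx <- unique(pairs[, 2])  # dimmer member (sorted by brightness)
      } else {
        used <- rep(FALSE, nrow(cand))
        for (r in seq_len(nrow(pairs))) {
          i <- pairs[r, 1]; j <- pairs[r, 2]
          if (!used[i] && !used[j]) {
            joint_groups[[length(joint_groups) + 1L]] <-
              cand[c(i, j), , drop = FALSE]
            used[c(i, j)] <- TRUE
          }
        }
        drop_idx <- which(used)
      }
      if (length(drop_idx)) {
        keep <- setdiff(seq_len(nrow(cand)), drop_idx)
        cand <- cand[keep, , drop = FALSE]
      }
    }
  }

  hw <- (w - 1L) %/% 2L
  fit_one <- function(ci, cj) {
    i0 <- min(max(ci - hw, 1L), nrow(frame_image) - w + 1L)
    j0 <- min(max(cj - hw, 1L), ncol(frame_image) - w + 1L)
    i1 <- i0 + w - 1L; j1 <- j0 + w - 1L
    win <- frame_image[i0:i1, j0:j1]
    fixed <- !is.null(params$fix_sigma)
    s0 <- if (fixed) params$fix_sigma else params$psf_sigma_px
    ft <- fit_gauss2d_cpp(win, cj - j0 + 0.5, ci - i0 + 0.5, s0, !fixed)
    x <- ft[1]; y <- ft[2]; N <- ft[3]; bg <- ft[4]; sg <- ft[5]
    if (ft[6] != 1 || N <= params$min_photons || N <= 0) return(NULL)
    if (x < 0.5 || x > w - 0.5 || y < 0.5 || y > w - 0.5) return(NULL)
    if (sg < 0.3 || sg > 3 * params$psf_sigma_px) return(NULL)
    c(x_px = (j0 - 1L) + x, y_px = (i0 - 1L) + y, photons = N,
      bg = max(bg, 0), sigma_px = sg)
  }
  fits <- lapply(seq_len(nrow(cand)),
                 function(r) fit_one(cand[r, 1], cand[r, 2]))
  if (length(joint_groups)) {
    for (g in joint_groups) {
      jf <- fit_joint_pair(frame_image, g, w, params)
      fits <- c(fits, jf)
    }
  }
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) return(empty_locs())
  m <- do.call(rbind, fits)
  px_um <- pixel_size_nm / 1000
  prec <- estimate_precision(m[, "photons"], m[, "bg"],
                             m[, "sigma_px"] * pixel_size_nm, pixel_size_nm)
  data.frame(frame = frame, channel = channel,
             x_um = m[, "x_px"] * px_um, y_um = m[, "y_px"] * px_um,
             photons = m[, "photons"], bg = m[, "bg"],
             sigma_nm = m[, "sigma_px"] * pixel_size_nm,
             precision_nm = prec, stringsAsFactors = FALSE)
}

# Two-Gaussian mixture fit (shared, fixed sigma and common background) for
# overlapping candidate pairs; returns a list of fits, NULLs on failure.
fit_joint_pair <- function(img, rows, w, params) {
  ci <- round(mean(rows[, 1])); cj <- round(mean(rows[, 2]))
  hw <- (w - 1L) %/% 2L + ceiling(max(dist(rows)) / 2)
  i0 <- max(1L, ci - hw); i1 <- min(nrow(img), ci + hw)
  j0 <- max(1L, cj - hw); j1 <- min(ncol(img), cj + hw)
  win <- img[i0:i1, j0:j1]
  s0 <- params$psf_sigma_px
  ft <- fit_gauss2d_pair_cpp(win,
                             rows[1, 2] - j0 + 0.5, rows[1, 1] - i0 + 0.5,
                             rows[2, 2] - j0 + 0.5, rows[2, 1] - i0 + 0.5,
                             s0)
  if (ft[8] != 1) return(list(NULL))
  bg <- max(ft[7], 0)
  mk <- function(x, y, n) {
    if (n <= params$min_photons || n <= 0) return(NULL)
    if (x < -0.5 || x > ncol(win) + 0.5 || y < -0.5 || y > nrow(win) + 0.5) {
      return(NULL)
    }
    c(x_px = (j0 - 1L) + x, y_px = (i0 - 1L) + y, photons = n,
      bg = bg, sigma_px = s0)
  }
  list(mk(ft[1], ft[2], ft[5]), mk(ft[3], ft[4], ft[6]))
}

#' Per-localization precision estimate
#'
#' Static localization precision of a least-squares Gaussian fit from the
#' photon count, background level, PSF width and pixel size (Mortensen-style
#' estimate with the excess-noise-free LS prefactor 16/9). Monotonically
#' decreasing in the photon count and increasing in the background.
#'
#' @param photons background-subtracted integrated photon count.
#' @param background background photons per pixel (its variance under
#'   Poisson statistics).
#' @param sigma_nm PSF standard deviation in nm.
#' @param pixel_nm pixel size in nm.
#' @return precision in nm.
#' @export
estimate_precision <- function(photons, background, sigma_nm, pixel_nm) {
  if (any(photons <= 0)) stop("photons must be positive")
  sa2 <- (sigma_nm / pixel_nm)^2 + 1 / 12  # px^2, pixelation-corrected
  v <- sa2 / photons * (16 / 9 + 8 * pi * sa2 * background / photons)
  sqrt(v) * pixel_nm
}

#' Localize every frame of a two-channel movie
#'
#' Converts each frame to photon units and applies the [detect_spots()]
#' detection scheme (band-pass candidates, pixel-integrated Gaussian fits,
#' brighter-of-overlapping-pair selection) across both channel halves in a
#' single pass, assigning detections to the donor or acceptor channel by
#' the channel split. The PSF radius is data-driven:
#' sigma is fit freely for the first `n_calib` accepted spots, then fixed at
#' their median for all subsequent frames. For every acceptor-channel
#' detection under donor excitation, the donor-channel intensity at the
#' registered donor position is also measured by fixed-position photometry
#' and returned as `idd_photons` / `idd_bg`; this recovers the quenched
#' donor signal during FRET even when it is too dim for independent
#' detection.
#'
#' @param movie a `fretspt_movie` (or integer array with the same
#'   attributes).
#' @param params a [detect_params()].
#' @param transform a [channel_transform()] mapping acceptor coordinates
#'   into donor coordinates (identity by default).
#' @param n_calib number of free-sigma fits used to fix the PSF radius.
#' @param verbose print progress.
#' @return data.frame of localizations (columns of [detect_spots()] plus
#'   `excitation`, and `idd_photons`, `idd_bg` on acceptor rows).
#' @export
localize_movie <- function(movie, params = NULL, transform = NULL,
                           n_calib = 200L, verbose = FALSE) {
  px_nm <- attr(movie, "pixel_size_nm")
  split <- attr(movie, "channel_split")
  gain <- attr(movie, "camera_gain")
  base <- attr(movie, "camera_baseline")
  frames <- attr(movie, "frames")
  alex <- isTRUE(attr(movie, "alex"))
  if (is.null(frames)) frames <- seq_len(dim(movie)[3])
  if (is.null(params)) {
    params <- detect_params(psf_sigma_px = attr(movie, "psf_sigma_nm") / px_nm)
  }
  if (is.null(transform)) transform <- channel_transform()
  itf <- invert_transform(transform)
  px_um <- px_nm / 1000
  w <- params$fit_window
  hw <- (w - 1L) %/% 2L
  sig_samples <- numeric()
  fix_sig <- params$fix_sigma
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    full <- adu_to_photons(movie[, , fi, drop = TRUE], gain, base)
    donor_exc <- !alex || f %% 2L == 1L
    cand <- dog_maxima_cpp(full, params$psf_sigma_px,
                           2 * params$psf_sigma_px, params$k_sd)
    if (nrow(cand) == 0L) next
    # overlapping candidates: joint mixture fit or drop the dimmer one
    joint_groups <- list()
    if (nrow(cand) > 1L) {
      val <- full[cbind(cand[, 1], cand[, 2])]
      ord <- order(-val, cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      d2 <- as.matrix(dist(cand))
      close <- d2 < w & upper.tri(d2)
      if (any(close)) {
        pairs <- which(close, arr.ind = TRUE)
        if (params$overlap == "joint") {
          used <- rep(FALSE, nrow(cand))
          for (r in seq_len(nrow(pairs))) {
            i <- pairs[r, 1]; j <- pairs[r, 2]
            if (!used[i] && !used[j]) {
              joint_groups[[length(joint_groups) + 1L]] <-
                cand[c(i, j), , drop = FALSE]
              used[c(i, j)] <- TRUE
            }
          }
          drop_idx <- which(used)
        } else {
          drop_idx <- unique(pairs[, 2])
        }
        if (length(drop_idx)) cand <- cand[-drop_idx, , drop = FALSE]
      }
    }
    nr <- nrow(cand)
    m <- matrix(NA_real_, nr, 10)
    kept <- logical(nr)
    for (r in seq_len(nr)) {
      ci <- cand[r, 1]; cj <- cand[r, 2]
      # shift the window inside the image near borders
      i0 <- min(max(ci - hw, 1L), nrow(full) - w + 1L)
      j0 <- min(max(cj - hw, 1L), ncol(full) - w + 1L)
      i1 <- i0 + w - 1L; j1 <- j0 + w - 1L
      fixed <- !is.null(fix_sig)
      ft <- fit_gauss2d_cpp(full[i0:i1, j0:j1], cj - j0 + 0.5, ci - i0 + 0.5,
                            if (fixed) fix_sig else params$psf_sigma_px,
                            !fixed)
      if (ft[6] != 1 || ft[3] <= params$min_photons || ft[3] <= 0) next
      if (ft[1] < 0.5 || ft[1] > w - 0.5 || ft[2] < 0.5 || ft[2] > w - 0.5) next
      if (ft[5] < 0.3 || ft[5] > 3 * params$psf_sigma_px) next
      kept[r] <- TRUE
      m[r, 1] <- (j0 - 1L) + ft[1]   # x_px in full frame
      m[r, 2] <- (i0 - 1L) + ft[2]
      m[r, 3] <- ft[3]               # photons
      m[r, 4] <- max(ft[4], 0)       # bg
      m[r, 5] <- ft[5]               # sigma_px
    }
    m <- m[kept, , drop = FALSE]
    if (length(joint_groups)) {
      jp <- params
      if (!is.null(fix_sig)) jp$psf_sigma_px <- fix_sig
      for (g in joint_groups) {
        jf <- fit_joint_pair(full, g, w, jp)
        for (ft in jf) {
          if (is.null(ft)) next
          m <- rbind(m, c(ft["x_px"], ft["y_px"], ft["photons"], ft["bg"],
                          ft["sigma_px"], NA, NA, NA, NA, NA))
        }
      }
    }
    if (!nrow(m)) next
    is_acc <- m[, 1] >= split - 1L   # 0-based px >= split-1 -> acceptor half
    # channel-relative coordinates
    m[is_acc, 1] <- m[is_acc, 1] - (split - 1L)
    if (is.null(fix_sig)) {
      sig_samples <- c(sig_samples, m[m[, 3] >= 100, 5])
      if (length(sig_samples) >= n_calib) {
        fix_sig <- median(sig_samples)
      }
    }
    sig_px <- if (is.null(fix_sig)) params$psf_sigma_px else fix_sig
    don_img <- full[, seq_len(split - 1L), drop = FALSE]
    acc_img <- full[, split:ncol(full), drop = FALSE]
    for (r in seq_len(nrow(m))) {
      if (is_acc[r] && donor_exc) {
        dc <- apply_transform(transform, m[r, 1] * px_um, m[r, 2] * px_um)
        ph <- measure_intensity(don_img, dc$x / px_um, dc$y / px_um, sig_px)
        m[r, 7] <- ph[1]; m[r, 8] <- ph[2]
      } else if (!is_acc[r] && donor_exc) {
        ac <- apply_transform(itf, m[r, 1] * px_um, m[r, 2] * px_um)
        ph <- measure_intensity(acc_img, ac$x / px_um, ac$y / px_um, sig_px)
        m[r, 9] <- ph[1]; m[r, 10] <- ph[2]
      }
    }
    m[, 6] <- f
    rows[[fi]] <- cbind(m, is_acc, donor_exc)
    if (verbose && fi %% 200 == 0) {
      message("localized frame ", fi, "/", length(frames))
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- empty_locs()
    out$excitation <- character()
    for (cc in c("idd_photons", "idd_bg", "iad_photons", "iad_bg")) {
      out[[cc]] <- numeric()
    }
    return(out)
  }
  m <- do.call(rbind, rows)
  prec <- estimate_precision(m[, 3], m[, 4], m[, 5] * px_nm, px_nm)
  res <- data.frame(
    frame = as.integer(m[, 6]),
    channel = ifelse(m[, 11] == 1, "acceptor", "donor"),
    x_um = m[, 1] * px_um, y_um = m[, 2] * px_um,
    photons = m[, 3], bg = m[, 4], sigma_nm = m[, 5] * px_nm,
    precision_nm = prec,
    excitation = ifelse(m[, 12] == 1, "donor", "acceptor"),
    idd_photons = m[, 7], idd_bg = m[, 8],
    iad_photons = m[, 9], iad_bg = m[, 10],
    stringsAsFactors = FALSE
  )
  res <- res[order(res$frame, res$channel, res$x_um), ]
  rownames(res) <- NULL
  res
}

#' Fixed-position photometry in one channel frame
#'
#' Linear least squares of `pixel = bg + N * PSF` over a window centred on a
#' known position, with the PSF pixel-integrated at fixed width. Used to
#' read out the donor intensity at the acceptor's registered position while
#' FRET quenches the donor below the detection threshold.
#'
#' @param frame_image channel frame in photon units.
#' @param x_px,y_px position in pixel units (channel origin, pixel `j`
#'   spanning `[j, j+1)`).
#' @param sigma_px PSF sigma in px.
#' @param half_window photometry window half-size in px.
#' @return numeric `c(photons, bg)`; `NA`s if the window leaves the image.
#' @export
measure_intensity <- function(frame_image, x_px, y_px, sigma_px,
                              half_window = NULL) {
  if (is.null(half_window)) half_window <- ceiling(3 * sigma_px) + 1L
  cj <- floor(x_px) + 1L
  ci <- floor(y_px) + 1L
  i0 <- ci - half_window; i1 <- ci + half_window
  j0 <- cj - half_window; j1 <- cj + half_window
  if (i0 < 1L || j0 < 1L || i1 > nrow(frame_image) || j1 > ncol(frame_image)) {
    return(c(NA_real_, NA_real_))
  }
  win <- frame_image[i0:i1, j0:j1]
  photometry_cpp(win, x_px - (j0 - 1L), y_px - (i0 - 1L), sigma_px)
}
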