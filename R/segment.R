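#' Merge repeated donor/acceptor localizations of the same molecule
#'
#' Per frame, donor and (registered) acceptor localizations closer than
#' `merge_radius_nm` are replaced by their inverse-variance
#' (precision-weighted) mean position; unmatched localizations pass
#' through.
#'
#' @param donor_locs,acceptor_locs data.frames with `frame`, `x_um`,
#'   `y_um` and optionally `precision_nm`; acceptor coordinates must
#'   already be in donor-channel coordinates.
#' @param merge_radius_nm merge radius.
#' @return data.frame `frame`, `x_um`, `y_um`, `precision_nm`, `source`
#'   (`"merged"`, `"donor"` or `"acceptor"`).
#' @export
merge_repeated_localizations <- function(donor_locs, acceptor_locs,
                                         merge_radius_nm = 250) {
  getp <- function(df) {
    if ("precision_nm" %in% names(df) && !all(is.na(df$precision_nm))) {
      df$precision_nm
    } else {
      rep(1, nrow(df))
    }
  }
  dp <- getp(donor_locs)
  ap <- getp(acceptor_locs)
  out <- list()
  frames <- sort(unique(c(donor_locs$frame, acceptor_locs$frame)))
  for (f in frames) {
    di <- which(donor_locs$frame == f)
    ai <- which(acceptor_locs$frame == f)
    used_d <- logical(length(di))
    used_a <- logical(length(ai))
    if (length(di) && length(ai)) {
      d2 <- outer(donor_locs$x_um[di], acceptor_locs$x_um[ai], "-")^2 +
        outer(donor_locs$y_um[di], acceptor_locs$y_um[ai], "-")^2
      lim2 <- (merge_radius_nm / 1000)^2
      repeat {
        m <- which(d2 == min(d2), arr.ind = TRUE)[1, , drop = TRUE]
        if (d2[m[1], m[2]] > lim2) break
        id <- di[m[1]]; ia <- ai[m[2]]
        wd <- 1 / dp[id]^2
        wa <- 1 / ap[ia]^2
        out[[length(out) + 1L]] <- data.frame(
          frame = f,
          x_um = (wd * donor_locs$x_um[id] + wa * acceptor_locs$x_um[ia]) / (wd + wa),
          y_um = (wd * donor_locs$y_um[id] + wa * acceptor_locs$y_um[ia]) / (wd + wa),
          precision_nm = sqrt(1 / (wd + wa)),
          source = "merged")
        used_d[m[1]] <- TRUE
        used_a[m[2]] <- TRUE
        d2[m[1], ] <- Inf
        d2[, m[2]] <- Inf
        if (all(used_d) || all(used_a)) break
      }
    }
    for (k in which(!used_d)) {
      id <- di[k]
      out[[length(out) + 1L]] <- data.frame(
        frame = f, x_um = donor_locs$x_um[id], y_um = donor_locs$y_um[id],
        precision_nm = dp[id], source = "donor")
    }
    for (k in which(!used_a)) {
      ia <- ai[k]
      out[[length(out) + 1L]] <- data.frame(
        frame = f, x_um = acceptor_locs$x_um[ia], y_um = acceptor_locs$y_um[ia],
        precision_nm = ap[ia], source = "acceptor")
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      precision_nm = numeric(), source = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$x_um), ]
  rownames(res) <- NULL
  res
}

#' Split an accepted FRET trace into FRET and donor-only segments
#'
#' Frames with a spatially matched acceptor localization up to the
#' intensity-derived acceptor loss frame form the FRET segment; donor
#' frames from the acceptor loss on form the donor-only segment. Where the
#' spatial support (last acceptor localization) and the intensity change
#' point disagree by no more than `max_gap` frames, the intensity change
#' point wins, being the primary acceptance signal.
#'
#' @param trace an accepted [fret_trace()] with coordinates and
#'   `acceptor_loss_frame` set.
#' @param merged_coords optional coordinate data.frame from
#'   [merge_repeated_localizations()]; defaults to `trace$coords`.
#' @param max_gap tolerated spatial/intensity disagreement in frames.
#' @param min_msd_positions FRET segments shorter than this are flagged
#'   `too_short_for_diffusion` (kept for lifetime statistics).
#' @return object of class `segmented_trajectory`: list with `trace_id`,
#'   `fret_segment`, `donor_only_segment` (data.frames `frame`, `x_um`,
#'   `y_um`), `pathway`, `fret_duration_s`, `flags`.
#' @export
segment_trajectory <- function(trace, merged_coords = NULL, max_gap = 3L,
                               min_msd_positions = 5L) {
  stopifnot(inherits(trace, "fret_trace"))
  if (!isTRUE(trace$accepted)) stop("trace must be accepted before segmentation")
  if (is.na(trace$acceptor_loss_frame)) stop("acceptor_loss_frame unknown")
  co <- if (is.null(merged_coords)) trace$coords else merged_coords
  if (is.null(co) || !nrow(co)) stop("trace carries no coordinates")
  lf <- trace$acceptor_loss_frame
  acc_frames <- co$frame[co$source %in% c("acceptor", "merged")]
  if (length(acc_frames)) {
    last_acc <- max(acc_frames)
    # intensity change point wins when the two disagree by <= max_gap
    if (abs((last_acc + 1L) - lf) > max_gap) lf <- last_acc + 1L
  }
  fret_seg <- co[co$frame < lf, c("frame", "x_um", "y_um")]
  don_seg <- co[co$frame >= lf & co$source %in% c("donor", "merged"),
                c("frame", "x_um", "y_um")]
  rownames(fret_seg) <- rownames(don_seg) <- NULL
  flags <- character()
  if (nrow(fret_seg) < min_msd_positions) {
    flags <- c(flags, "too_short_for_diffusion")
  }
  dur <- if (nrow(fret_seg)) {
    (max(fret_seg$frame) - min(fret_seg$frame) + 1L) * trace$frame_interval
  } else {
    0
  }
  seg <- structure(
    list(trace_id = trace$acceptor_traj_id, fret_segment = fret_seg,
         donor_only_segment = don_seg, pathway = NA_integer_,
         fret_duration_s = dur, frame_interval = trace$frame_interval,
         acceptor_loss_frame = lf, flags = flags),
    class = "segmented_trajectory")
  classify_pathway(seg, max_gap = max_gap)
}

#' Classify the termination pathway of a segmented trajectory
#'
#' Pathway 1: the donor persists after acceptor loss (dimer dissociation,
#' the donor-only segment is non-empty). Pathway 2: donor and acceptor
#' vanish within `max_gap` frames of each other (the complex leaves the
#' TIRF field); the donor-only segment is emptied in that case so that
#' `pathway == 2` iff the donor-only segment is empty.
#'
#' @param seg a `segmented_trajectory`.
#' @param max_gap frames within which a joint disappearance counts as
#'   simultaneous.
#' @return the segmented trajectory with `pathway` set.
#' @export
classify_pathway <- function(seg, max_gap = 3L) {
  stopifnot(inherits(seg, "segmented_trajectory"))
  d <- seg$donor_only_segment
  persists <- nrow(d) > 0 &&
    (max(d$frame) - seg$acceptor_loss_frame) >= max_gap
  if (persists) {
    seg$pathway <- 1L
  } else {
    seg$pathway <- 2L
    seg$donor_only_segment <- d[0, , drop = FALSE]
  }
  seg
}

#' @export
print.segmented_trajectory <- function(x, ...) {
  cat(sprintf(
    "segmented_trajectory (trace %s): %d FRET frames (%.2f s), %d donor-only frames, pathway %d%s\n",
    x$trace_id, nrow(x$fret_segment), x$fret_duration_s,
    nrow(x$donor_only_segment), x$pathway,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Export segmented trajectories as CSV
#'
#' @param segs list of `segmented_trajectory` objects.
#' @param path file path.
#' @export
write_segments_csv <- function(segs, path) {
  rows <- lapply(segs, function(s) {
    rbind(
      if (nrow(s$fret_segment)) {
        cbind(trace_id = s$trace_id, segment = "fret", s$fret_segment)
      },
      if (nrow(s$donor_only_segment)) {
        cbind(trace_id = s$trace_id, segment = "donor_only",
              s$donor_only_segment)
      }
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
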