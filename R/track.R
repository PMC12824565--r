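#' Link per-frame localizations into trajectories
#'
#' Frame-to-frame assignment is solved per frame pair as a linear assignment
#' problem (Hungarian algorithm) on squared displacements, with birth/death
#' dummy costs of `max_disp^2` so unmatched particles are allowed. Track
#' ends and starts separated by at most `max_gap` skipped frames and by at
#' most `max_disp * sqrt(gap + 1)` are then merged in a second assignment
#' stage (gap closing). Gap frames carry no interpolated coordinates.
#'
#' @param locs data.frame of localizations for ONE channel (columns `frame`,
#'   `x_um`, `y_um`, and any others, which are carried through).
#' @param max_disp maximum frame-to-frame displacement in um.
#' @param max_gap maximum number of consecutive missed frames to close.
#' @return the input rows with a `traj_id` column, ordered by trajectory and
#'   frame. Every input localization appears in exactly one trajectory.
#' @examples
#' locs <- data.frame(frame = 1:5, x_um = 0.01 * (1:5), y_um = 0)
#' link_trajectories(locs, max_disp = 1, max_gap = 3)
#' @export
link_trajectories <- function(locs, max_disp = 1.1, max_gap = 3L) {
  stopifnot(max_disp > 0, max_gap >= 0)
  if (!nrow(locs)) {
    locs$traj_id <- integer(0)
    return(locs)
  }
  if (length(unique(locs$channel)) > 1) {
    stop("link_trajectories expects a single channel; split first")
  }
  locs <- locs[order(locs$frame, locs$x_um, locs$y_um), , drop = FALSE]
  rownames(locs) <- NULL
  dup <- duplicated(locs[, c("frame", "x_um", "y_um")])
  if (any(dup)) stop("duplicate localization (same frame and coordinates)")

  BIG <- 1e12
  md2 <- max_disp^2
  frames_present <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)

  # Each track: vector of row indices; active tracks end at frame `endf`.
  tracks <- lapply(by_frame[[1]], function(i) i)
  track_end <- rep(frames_present[1], length(tracks))
  for (k in seq_along(frames_present)[-1]) {
    f1 <- frames_present[k]
    f0 <- frames_present[k - 1]
    new_rows <- by_frame[[as.character(f1)]]
    if (f1 - f0 != 1L) {
      # nothing detected in between: all current tracks go inactive;
      # handled by gap closing later
      tracks <- c(tracks, lapply(new_rows, function(i) i))
      track_end <- c(track_end, rep(f1, length(new_rows)))
      next
    }
    act <- which(track_end == f0)
    n <- length(act)
    m <- length(new_rows)
    if (n == 0L) {
      tracks <- c(tracks, lapply(new_rows, function(i) i))
      track_end <- c(track_end, rep(f1, length(new_rows)))
      next
    }
    ex <- vapply(tracks[act], function(tr) locs$x_um[tr[length(tr)]], 0)
    ey <- vapply(tracks[act], function(tr) locs$y_um[tr[length(tr)]], 0)
    d2 <- outer(ex, locs$x_um[new_rows], "-")^2 +
      outer(ey, locs$y_um[new_rows], "-")^2
    link_cost <- ifelse(d2 <= md2, d2, BIG)
    size <- n + m
    cost <- matrix(BIG, size, size)
    if (m) cost[seq_len(n), seq_len(m)] <- link_cost
    for (i in seq_len(n)) cost[i, m + i] <- md2          # death
    for (j in seq_len(m)) cost[n + j, j] <- md2          # birth
    if (n && m) cost[n + seq_len(m), m + seq_len(n)] <- 0 # slack block
    asg <- lap_cpp(cost)
    matched_new <- rep(FALSE, m)
    for (i in seq_len(n)) {
      j <- asg[i]
      if (j <= m && link_cost[i, j] < BIG) {
        tracks[[act[i]]] <- c(tracks[[act[i]]], new_rows[j])
        track_end[act[i]] <- f1
        matched_new[j] <- TRUE
      }
    }
    for (j in which(!matched_new)) {
      tracks[[length(tracks) + 1L]] <- new_rows[j]
      track_end <- c(track_end, f1)
    }
  }

  # Gap closing between completed track ends and starts.
  if (max_gap > 0L && length(tracks) > 1L) {
    endf <- vapply(tracks, function(tr) locs$frame[tr[length(tr)]], 0)
    staf <- vapply(tracks, function(tr) locs$frame[tr[1]], 0)
    ex <- vapply(tracks, function(tr) locs$x_um[tr[length(tr)]], 0)
    ey <- vapply(tracks, function(tr) locs$y_um[tr[length(tr)]], 0)
    sx <- vapply(tracks, function(tr) locs$x_um[tr[1]], 0)
    sy <- vapply(tracks, function(tr) locs$y_um[tr[1]], 0)
    nt <- length(tracks)
    gap <- outer(staf, endf, "-") - 1L  # gap[j, i]: start j after end i
    gap <- t(gap)                       # [i, j]
    d2 <- outer(ex, sx, "-")^2 + outer(ey, sy, "-")^2
    lim2 <- md2 * (gap + 1)
    feas <- gap >= 1 & gap <= max_gap & d2 <= lim2
    diag(feas) <- FALSE
    if (any(feas)) {
      cost <- matrix(BIG, 2L * nt, 2L * nt)
      cc <- ifelse(feas, d2, BIG)
      cost[seq_len(nt), seq_len(nt)] <- cc
      for (i in seq_len(nt)) cost[i, nt + i] <- md2
      for (j in seq_len(nt)) cost[nt + j, j] <- md2
      cost[nt + seq_len(nt), nt + seq_len(nt)] <- 0
      asg <- lap_cpp(cost)
      succ <- rep(NA_integer_, nt)
      for (i in seq_len(nt)) {
        j <- asg[i]
        if (j <= nt && feas[i, j]) succ[i] <- j
      }
      # Chain-merge: follow successor links from chain heads.
      has_pred <- rep(FALSE, nt)
      has_pred[succ[!is.na(succ)]] <- TRUE
      merged <- list()
      for (i in which(!has_pred)) {
        chain <- tracks[[i]]
        j <- succ[i]
        while (!is.na(j)) {
          chain <- c(chain, tracks[[j]])
          j <- succ[j]
        }
        merged[[length(merged) + 1L]] <- chain
      }
      tracks <- merged
    }
  }

  first_frame <- vapply(tracks, function(tr) locs$frame[tr[1]], 0)
  first_x <- vapply(tracks, function(tr) locs$x_um[tr[1]], 0)
  ord <- order(first_frame, first_x)
  tracks <- tracks[ord]
  out_rows <- unlist(tracks)
  res <- locs[out_rows, , drop = FALSE]
  res$traj_id <- rep(seq_along(tracks), lengths(tracks))
  res <- res[, c("traj_id", setdiff(names(res), "traj_id"))]
  rownames(res) <- NULL
  res
}

#' Remove trajectories shorter than a minimum span
#'
#' @param trajs data.frame with `traj_id` and `frame` columns.
#' @param min_length minimum number of frames spanned (first to last frame
#'   inclusive) for a trajectory to be retained.
#' @param verbose report the number of removed trajectories.
#' @return the retained rows; the number of removed trajectories is
#'   attached as attribute `n_removed`.
#' @export
filter_trajectories <- function(trajs, min_length = 20L, verbose = FALSE) {
  stopifnot(min_length >= 1)
  if (!nrow(trajs)) {
    attr(trajs, "n_removed") <- 0L
    return(trajs)
  }
  span <- tapply(trajs$frame, trajs$traj_id,
                 function(f) max(f) - min(f) + 1L)
  keep_ids <- names(span)[span >= min_length]
  removed <- length(span) - length(keep_ids)
  if (verbose) message(removed, " trajectories below minimum length removed")
  out <- trajs[trajs$traj_id %in% as.integer(keep_ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  out
}

#' Write trajectories as CSV
#'
#' @param trajs trajectory data.frame from [link_trajectories()].
#' @param path file path.
#' @export
write_trajectories_csv <- function(trajs, path) {
  cols <- intersect(c("traj_id", "channel", "frame", "x_um", "y_um",
                      "photons", "precision_nm"), names(trajs))
  write.csv(trajs[, cols], path, row.names = FALSE)
  invisible(path)
}
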