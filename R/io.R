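#' Write / read localization tables as CSV
#'
#' Columns: frame, channel, x_um, y_um, photons, bg, sigma_nm,
#' precision_nm (guided-photometry columns are carried when present).
#'
#' @param locs localization data.frame from [localize_movie()] or
#'   [detect_spots()].
#' @param path file path.
#' @export
write_localizations_csv <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Export a FRET trace as CSV plus a metadata sidecar
#'
#' The CSV holds per-frame columns `frame`, `I_DD`, `I_AD`, `I_AA`, `E`,
#' `S`, `segment_label` (`fret` before the acceptor loss, `donor_only`
#' after). The sidecar (same path with extension `.meta.txt`) records the
#' trajectory ids, acceptor loss frame, acceptance flag and rejection
#' reason as `key = value` lines.
#'
#' @param trace a [fret_trace()].
#' @param path CSV file path.
#' @export
write_fret_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fret_trace"))
  n <- length(trace$frames)
  lab <- if (!is.na(trace$acceptor_loss_frame)) {
    ifelse(trace$frames < trace$acceptor_loss_frame, "fret", "donor_only")
  } else {
    rep("fret", n)
  }
  df <- data.frame(
    frame = trace$frames, I_DD = trace$I_DD, I_AD = trace$I_AD,
    I_AA = if (is.null(trace$I_AA)) NA_real_ else trace$I_AA,
    E = if (is.null(trace$E)) NA_real_ else trace$E,
    S = if (is.null(trace$S)) NA_real_ else trace$S,
    segment_label = lab
  )
  write.csv(df, path, row.names = FALSE)
  meta <- c(
    paste0("donor_traj_id = ", trace$donor_traj_id),
    paste0("acceptor_traj_id = ", trace$acceptor_traj_id),
    paste0("acceptor_loss_frame = ", trace$acceptor_loss_frame),
    paste0("accepted = ", trace$accepted),
    paste0("reason = ", trace$reason)
  )
  writeLines(meta, paste0(sub("\\.csv$", "", path), ".meta.txt"))
  invisible(path)
}

#' Write the lifetime fit report and histogram
#'
#' @param fit a [fit_lifetime()] result.
#' @param path_txt report text file.
#' @param path_csv histogram CSV (`bin_left_s`, `bin_right_s`, `count`).
#' @export
write_lifetime_report <- function(fit, path_txt, path_csv) {
  stopifnot(inherits(fit, "lifetime_fit"))
  writeLines(c(
    sprintf("tau_s = %.6g", fit$tau_s),
    sprintf("tau_stderr_s = %.6g", fit$tau_stderr_s),
    sprintf("n_traces = %d", fit$n_traces),
    fit$note
  ), path_txt)
  write.csv(data.frame(bin_left_s = head(fit$breaks, -1),
                       bin_right_s = tail(fit$breaks, -1),
                       count = fit$counts),
            path_csv, row.names = FALSE)
  invisible(path_txt)
}

#' Write a jump-angle histogram as CSV
#'
#' @param angles output of [compute_jump_angles()].
#' @param path file path.
#' @param bins histogram bins over 0..180 degrees.
#' @export
write_jump_angles_csv <- function(angles, path, bins = 18) {
  write.csv(jump_angle_histogram(angles, bins), path, row.names = FALSE)
  invisible(path)
}
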