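# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures.

# A small, fast configuration for movie-level tests.
tiny_config <- function(n_frames = 60L, seed = 101L, emitter_density = 0.02,
                        ...) {
  sim_config(field_size = c(128L, 128L), n_frames = n_frames,
             emitter_density = emitter_density, seed = seed, ...)
}

# Constructed single-dimer FRET trace with known loss and donor fate.
# Intensities are exact Poisson means plus Gaussian noise of sd `noise`.
constructed_trace <- function(n = 100, loss = 50, donor_end = NULL,
                              N = 600, E = 0.9, gamma = 1, alpha = 0,
                              noise = 10, seed = 1) {
  set.seed(seed)
  f <- seq_len(n)
  fret_on <- f < loss
  don_on <- if (is.null(donor_end)) rep(TRUE, n) else f < donor_end
  I_DD <- N * ifelse(fret_on, 1 - E, 1) * don_on + rnorm(n, 0, noise)
  I_AD <- gamma * N * E * (fret_on & don_on) +
    alpha * N * ifelse(fret_on, 1 - E, 1) * don_on + rnorm(n, 0, noise)
  fret_trace(f, I_DD, I_AD, frame_interval = 0.04)
}

# A straight-line trajectory data.frame (one localization per frame).
line_traj <- function(frames, x0 = 0, y0 = 0, dx = 0.01, dy = 0,
                      traj_id = 1L, photons = 600, precision_nm = 20) {
  k <- seq_along(frames) - 1
  data.frame(traj_id = traj_id, channel = "donor", frame = frames,
             x_um = x0 + k * dx, y_um = y0 + k * dy, photons = photons,
             precision_nm = precision_nm)
}

# Random-walk coordinates with a given diffusion coefficient.
walk_coords <- function(n, D, dt = 0.04, sigma_loc_um = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  x <- cumsum(c(0, rnorm(n - 1, 0, sd_step)))
  y <- cumsum(c(0, rnorm(n - 1, 0, sd_step)))
  if (sigma_loc_um > 0) {
    x <- x + rnorm(n, 0, sigma_loc_um)
    y <- y + rnorm(n, 0, sigma_loc_um)
  }
  data.frame(frame = seq_len(n), x_um = x, y_um = y)
}

# Brute-force all-pairs time-averaged MSD, independent of compute_msd.
msd_brute_force <- function(coords, dt) {
  coords <- coords[order(coords$frame), ]
  n <- nrow(coords)
  sums <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      lag <- coords$frame[b] - coords$frame[a]
      d2 <- (coords$x_um[b] - coords$x_um[a])^2 +
        (coords$y_um[b] - coords$y_um[a])^2
      key <- as.character(lag)
      if (is.null(sums[[key]])) sums[[key]] <- c(0, 0)
      sums[[key]] <- sums[[key]] + c(d2, 1)
    }
  }
  lags <- sort(as.integer(names(sums)))
  data.frame(lag_frames = lags,
             lag_s = lags * dt,
             msd = vapply(as.character(lags), function(k)
               sums[[k]][1] / sums[[k]][2], 0),
             n_pairs = vapply(as.character(lags), function(k)
               as.integer(sums[[k]][2]), 0L))
}

# Match localizations to truth positions within a radius; returns counts.
match_to_truth <- function(locs, truth_xy, radius_um) {
  tp <- 0L
  fp <- 0L
  used <- rep(FALSE, nrow(truth_xy))
  for (r in seq_len(nrow(locs))) {
    if (nrow(truth_xy)) {
      d <- sqrt((truth_xy$x_um - locs$x_um[r])^2 +
                  (truth_xy$y_um - locs$y_um[r])^2)
      j <- which.min(d)
      if (d[j] <= radius_um && !used[j]) {
        tp <- tp + 1L
        used[j] <- TRUE
        next
      }
    }
    fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = nrow(truth_xy) - tp)
}
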