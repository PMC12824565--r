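render_single_spot <- function(N = 1200, bg = 2, x_px = 20.3, y_px = 17.6,
                               size = 40, sigma_px = 150 / 159, seed = 1,
                               extra = NULL) {
  set.seed(seed)
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  pixint <- function(p, c, s) {
    0.5 * (erf((p + 1 - c) / (s * sqrt(2))) - erf((p - c) / (s * sqrt(2))))
  }
  img <- matrix(bg, size, size)
  spots <- rbind(c(x_px, y_px, N), extra)
  for (r in seq_len(nrow(spots))) {
    img <- img + spots[r, 3] *
      outer(pixint(0:(size - 1), spots[r, 2], sigma_px),
            pixint(0:(size - 1), spots[r, 1], sigma_px))
  }
  matrix(rpois(size * size, img), size, size)
}

test_that("a blank frame yields no localizations at default settings", {
  set.seed(2)
  img <- matrix(rpois(64 * 64, 2), 64, 64)
  locs <- detect_spots(img, "donor", detect_params(psf_sigma_px = 150 / 159))
  expect_equal(nrow(locs), 0L)
})

test_that("a single emitter is localized within 0.1 px of truth", {
  img <- render_single_spot(N = 1200, seed = 3)  # SNR ~ 10 at the peak
  locs <- detect_spots(img, "donor", detect_params(psf_sigma_px = 150 / 159),
                       pixel_size_nm = 159)
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$x_um / 0.159 - 20.3), 0.1)
  expect_lt(abs(locs$y_um / 0.159 - 17.6), 0.1)
  expect_lt(abs(locs$photons - 1200) / 1200, 0.2)
})

test_that("two emitters 10 px apart are both recovered within 0.5 px", {
  img <- render_single_spot(N = 1500, x_px = 14.2, y_px = 20.1, seed = 4,
                            extra = rbind(c(24.2, 20.1, 1500)))
  locs <- detect_spots(img, "donor", detect_params(psf_sigma_px = 150 / 159),
                       pixel_size_nm = 159)
  expect_equal(nrow(locs), 2L)
  got <- locs[order(locs$x_um), ]
  expect_lt(abs(got$x_um[1] / 0.159 - 14.2), 0.5)
  expect_lt(abs(got$x_um[2] / 0.159 - 24.2), 0.5)
})

test_that("precision estimate behaves as the Mortensen formula should", {
  p1 <- estimate_precision(500, 2, 150, 159)
  p2 <- estimate_precision(5000, 2, 150, 159)
  p3 <- estimate_precision(50000, 2, 150, 159)
  expect_true(p1 > p2 && p2 > p3)       # monotone in photons
  expect_lt(p3, 5)                      # -> 0 in the bright limit
  expect_gt(estimate_precision(500, 8, 150, 159), p1)  # worse with bg
  expect_error(estimate_precision(0, 2, 150, 159), "positive")
})

test_that("estimated precision predicts the real localization scatter", {
  errs <- numeric(60)
  precs <- numeric(60)
  for (i in 1:60) {
    img <- render_single_spot(N = 800, x_px = 20 + (i %% 10) / 10,
                              seed = 100 + i)
    locs <- detect_spots(img, "donor",
                         detect_params(psf_sigma_px = 150 / 159),
                         pixel_size_nm = 159)
    if (nrow(locs) != 1) next
    errs[i] <- (locs$x_um / 0.159 - (20 + (i %% 10) / 10)) * 159
    precs[i] <- locs$precision_nm
  }
  keep <- precs > 0
  rms <- sqrt(mean(errs[keep]^2))
  expect_lt(rms / mean(precs[keep]), 1.3)
  expect_gt(rms / mean(precs[keep]), 1 / 1.3)
})

test_that("detection recall and precision reach 0.95 on sparse bright movies", {
  cfg <- sim_config(field_size = c(256L, 256L), n_frames = 30,
                    emitter_density = 0.1, f_dimer = 0, birth = "start",
                    bleach_rate_donor = 0, D_monomer = 0.05, seed = 21)
  sim <- simulate_movie(cfg)
  locs <- localize_movie(sim$movie)
  don <- locs[locs$channel == "donor", ]
  st <- sim$truth$states
  tp <- fp <- fn <- 0L
  for (f in unique(st$frame)) {
    m <- match_to_truth(don[don$frame == f, ],
                        st[st$frame == f & st$rate_dd > 100,
                           c("x_um", "y_um")], 0.159)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
  }
  expect_gt(tp / (tp + fn), 0.95)  # recall
  expect_gt(tp / (tp + fp), 0.95)  # precision
})

test_that("localization is unbiased to < 5 nm across pixel phases", {
  errs <- numeric(0)
  for (i in 1:80) {
    phase <- (i - 1) / 80
    img <- render_single_spot(N = 1500, x_px = 20 + phase, seed = 500 + i)
    locs <- detect_spots(img, "donor",
                         detect_params(psf_sigma_px = 150 / 159),
                         pixel_size_nm = 159)
    if (nrow(locs) == 1) {
      errs <- c(errs, (locs$x_um / 0.159 - (20 + phase)) * 159)
    }
  }
  expect_gt(length(errs), 60)
  expect_lt(abs(mean(errs)), 5)
})

test_that("transforms invert to numerical identity", {
  tf <- channel_transform(matrix(c(1.001, 0.01, -0.01, 0.999), 2, 2),
                          c(0.05, -0.03))
  fwd <- apply_transform(tf, c(1, 5, 20), c(2, 8, 30))
  back <- apply_transform(invert_transform(tf), fwd$x, fwd$y)
  expect_lt(max(abs(back$x - c(1, 5, 20))), 1e-9)
  expect_lt(max(abs(back$y - c(2, 8, 30))), 1e-9)
  expect_error(channel_transform(matrix(0, 2, 2)), "invertible")
})

test_that("bead registration recovers identity, translation and affine", {
  cfg0 <- sim_config(field_size = c(256L, 256L), seed = 41)
  bm <- simulate_bead_movie(cfg0, n_beads = 10)
  tf <- register_channels(bm$movie)
  expect_lt(max(abs(tf$A - diag(2))), 1e-3)
  expect_lt(sqrt(sum(tf$b^2)) * 1000, 10)  # < 10 nm residual offset
  expect_gte(tf$n_fiducials, 3)

  cfg1 <- sim_config(field_size = c(256L, 256L), seed = 42,
                     chan_dx_nm = 300, chan_dy_nm = -150)
  tf1 <- register_channels(simulate_bead_movie(cfg1, n_beads = 10)$movie)
  # the recovered acceptor->donor translation undoes the applied shift
  expect_lt(abs(tf1$b[1] * 1000 + 300), 10)
  expect_lt(abs(tf1$b[2] * 1000 - 150), 10)

  cfg2 <- sim_config(field_size = c(256L, 256L), seed = 43,
                     chan_theta_deg = 0.5, chan_scale = 1.001)
  tf2 <- register_channels(simulate_bead_movie(cfg2, n_beads = 12)$movie)
  expect_lt(tf2$rms_residual_nm, 10)
  # applying the fit to truth bead positions lands on donor positions
  beads <- simulate_bead_movie(cfg2, n_beads = 12)$beads
  acc <- fretspt:::donor_to_acceptor_coords(cfg2, beads$x_um, beads$y_um)
  back <- apply_transform(tf2, acc$x_um, acc$y_um)
  expect_lt(1000 * sqrt(mean((back$x - beads$x_um)^2 +
                               (back$y - beads$y_um)^2)), 10)
})

test_that("registration errors out with too few beads", {
  cfg <- sim_config(field_size = c(128L, 128L), seed = 44)
  bm <- simulate_bead_movie(cfg, n_beads = 2)
  expect_error(register_channels(bm$movie), "3")
})

test_that("guided photometry recovers a known flux at a known position", {
  img <- render_single_spot(N = 900, x_px = 20.3, y_px = 17.6, seed = 7)
  ph <- measure_intensity(img, 20.3, 17.6, 150 / 159)
  expect_lt(abs(ph[1] - 900) / 900, 0.15)
  expect_lt(abs(ph[2] - 2), 1)
})
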