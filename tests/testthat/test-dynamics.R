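test_that("MSD of a uniform drift enumerates all displacement pairs", {
  co <- data.frame(frame = 1:5, x_um = c(0, 1, 2, 3, 4), y_um = 0)
  m <- compute_msd(co, frame_interval = 1)
  # hand enumeration: lag n has squared displacement n^2 from every pair
  expect_equal(m$msd, c(1, 4, 9, 16))
  expect_equal(m$n_pairs, c(4L, 3L, 2L, 1L))
  expect_error(compute_msd(co[1:4, ], 1), "5 positions")
})

test_that("a stationary segment has zero MSD at all lags", {
  co <- data.frame(frame = 1:10, x_um = 2, y_um = 3)
  m <- compute_msd(co, 0.04)
  expect_true(all(m$msd == 0))
})

test_that("compute_msd equals the brute-force all-pairs oracle exactly", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    co <- walk_coords(n, D = runif(1, 0.01, 0.3))
    # punch random gaps
    co <- co[sort(sample(n, max(5, n - sample(0:4, 1)))), ]
    m <- compute_msd(co, 0.04)
    b <- msd_brute_force(co, 0.04)
    expect_equal(m$msd, b$msd, tolerance = 1e-12)
    expect_equal(m$n_pairs, b$n_pairs)
  }
})

test_that("free-model fit recovers a noiseless closed form exactly", {
  lag_s <- (1:6) * 0.04
  msd <- data.frame(lag_frames = 1:6, lag_s = lag_s,
                    msd = 4 * 0.1 * lag_s + 4 * 0.02^2, n_pairs = 10)
  class(msd) <- c("msd_curve", "data.frame")
  ft <- fit_msd(msd, "free")
  expect_equal(ft$D, 0.1, tolerance = 1e-9)
  expect_equal(ft$sigma_dyn_nm, 20, tolerance = 1e-6)
})

test_that("negative intercepts leave D reported and sigma not estimable", {
  lag_s <- (1:5) * 0.04
  msd <- data.frame(lag_frames = 1:5, lag_s = lag_s,
                    msd = 4 * 0.05 * lag_s - 0.001, n_pairs = 5)
  class(msd) <- c("msd_curve", "data.frame")
  ft <- fit_msd(msd, "free")
  expect_equal(ft$D, 0.05, tolerance = 1e-9)
  expect_true(is.na(ft$sigma_dyn_nm))
  flat <- data.frame(lag_frames = 1:4, lag_s = lag_s[1:4], msd = rep(1, 4),
                     n_pairs = 2)
  expect_error(fit_msd(flat, "free"), "singular")
})

test_that("median fitted D over short free segments is within 10%", {
  set.seed(51)
  Dhat <- vapply(1:500, function(i) {
    co <- walk_coords(20, D = 0.1, sigma_loc_um = 0.02)
    fit_msd(compute_msd(co, 0.04), "free")$D
  }, 0)
  expect_lt(abs(median(Dhat) - 0.1) / 0.1, 0.1)
})

test_that("confined motion prefers the confined model and is classified", {
  cfg <- sim_config(field_size = c(512L, 512L), n_frames = 40,
                    D_monomer = 0.1, f_dimer = 0, birth = "start",
                    confinement_radius = 150, bleach_rate_donor = 0,
                    seed = 52)
  truth <- simulate_state_trajectories(cfg, n_emitters = 80)
  n_conf <- 0L
  n_free_resid_worse <- 0L
  n <- 0L
  for (e in unique(truth$states$emitter_id)) {
    co <- truth$states[truth$states$emitter_id == e,
                       c("frame", "x_um", "y_um")]
    if (nrow(co) < 30) next
    m <- compute_msd(co, 0.04)
    ff <- fit_msd(m, "free")
    fc <- tryCatch(fit_msd(m, "confined"), error = function(e) NULL)
    if (is.null(fc)) next
    n <- n + 1L
    sel <- seq_len(min(nrow(m), 20))
    rss_free <- sum((m$msd[sel] - (4 * ff$D * m$lag_s[sel] + ff$intercept))^2)
    rss_conf <- sum((m$msd[sel] - fc$fitted[sel])^2)
    if (rss_conf < rss_free) n_free_resid_worse <- n_free_resid_worse + 1L
    if (classify_motion(m, ff)$motion_class == "confined") n_conf <- n_conf + 1L
  }
  expect_gt(n, 50)
  expect_gte(n_free_resid_worse / n, 0.85)
  expect_gte(n_conf / n, 0.85)
})

test_that("free Brownian segments are rarely called confined", {
  set.seed(53)
  calls <- vapply(1:200, function(i) {
    co <- walk_coords(20, D = 0.1, sigma_loc_um = 0.02)
    m <- compute_msd(co, 0.04)
    classify_motion(m)$motion_class
  }, "")
  expect_lte(mean(calls == "confined"), 0.15)
})

test_that("an exactly linear MSD is classified free", {
  lag_s <- (1:12) * 0.04
  msd <- data.frame(lag_frames = 1:12, lag_s = lag_s, msd = 4 * 0.08 * lag_s,
                    n_pairs = 20)
  class(msd) <- c("msd_curve", "data.frame")
  expect_equal(classify_motion(msd)$motion_class, "free")
})

test_that("jump angles fold to collinear and reversal limits", {
  fwd <- data.frame(frame = 1:5, x_um = 1:5, y_um = 0)
  expect_true(all(abs(compute_jump_angles(fwd)) < 1e-9))
  alt <- data.frame(frame = 1:6, x_um = c(0, 1, 0, 1, 0, 1), y_um = 0)
  expect_true(all(abs(compute_jump_angles(alt) - 180) < 1e-9))
  gap <- data.frame(frame = c(1, 2, 4, 5), x_um = 1:4, y_um = 0)
  expect_length(compute_jump_angles(gap), 0)  # gap-spanning pairs excluded
})

test_that("free-diffusion jump angles are uniform on [0, 180]", {
  set.seed(54)
  co <- walk_coords(10002, D = 0.1)
  ang <- compute_jump_angles(co)
  expect_gte(length(ang), 10000 - 2)
  h <- jump_angle_histogram(ang)
  expect_equal(sum(h$rel_freq), 1, tolerance = 1e-12)
  counts <- h$rel_freq * length(ang)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("the lifetime fit recovers a known exponential and applies exclusions", {
  set.seed(55)
  x <- rexp(5000, 1)
  x <- ceiling(x / 0.04) * 0.04  # frame discretization
  ft <- fit_lifetime(x, frame_interval = 0.04)
  expect_lt(abs(ft$tau_s - 1) / 1, 0.05)
  expect_equal(ft$n_traces, sum(x <= 10))

  expect_error(fit_lifetime(rep(0.5, 100), 0.04), "bins")

  mix <- c(rep(0.5, 3000), rep(12, 50))
  set.seed(56)
  mix[1:3000] <- ceiling(rexp(3000, 2) / 0.04) * 0.04
  ftm <- fit_lifetime(c(mix[1:3000], rep(12, 50)), 0.04)
  expect_equal(ftm$n_traces, 3000L)
  expect_equal(ftm$excluded_long, 50L)
})

test_that("lifetime discretization bias stays below one frame interval", {
  set.seed(57)
  dt <- 0.04
  tau <- 10 * dt
  x <- rexp(20000, 1 / tau)
  cont_mean <- mean(x)          # continuous-time oracle
  disc <- ceiling(x / dt) * dt
  ft <- fit_lifetime(disc, frame_interval = dt, max_s = 10,
                     exclude_first_bin = TRUE)
  expect_lt(abs(ft$tau_s - cont_mean), dt)
})

test_that("Mann-Whitney comparison reports bands and handles identical samples", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  cmpi <- compare_groups(a, a)
  expect_gt(cmpi$p_value, 0.99)
  expect_equal(cmpi$significance, "n.s.")
  expect_error(compare_groups(1:3, 1:10), "5")

  set.seed(58)
  DA <- vapply(1:200, function(i)
    fit_msd(compute_msd(walk_coords(25, 0.066), 0.04), "free")$D, 0)
  DB <- vapply(1:200, function(i)
    fit_msd(compute_msd(walk_coords(25, 0.109), 0.04), "free")$D, 0)
  cmp <- compare_groups(DA, DB)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$significance, "***")
})

test_that("the Mann-Whitney type-I error rate is nominal", {
  set.seed(59)
  rej <- vapply(1:1000, function(i) {
    compare_groups(rnorm(100), rnorm(100))$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
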