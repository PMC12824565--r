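test_that("pairing matches co-moving trajectories and respects the radius gate", {
  don <- line_traj(1:30, x0 = 10, y0 = 10)
  acc <- line_traj(1:30, x0 = 10.05, y0 = 10, traj_id = 5L)  # 50 nm away
  pr <- pair_trajectories(don, acc, channel_transform(), 250)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$donor_id, 1L)
  expect_equal(pr$pairs$acceptor_id, 5L)

  far <- line_traj(1:30, x0 = 10.4, y0 = 10, traj_id = 6L)   # 400 nm away
  pr2 <- pair_trajectories(don, far, channel_transform(), 250)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(pr2$acceptor_only_ids, 6L)
})

test_that("the nearer of two donor candidates wins, verified exhaustively", {
  d1 <- line_traj(1:30, x0 = 10.08, y0 = 10, traj_id = 1L)  # 80 nm
  d2 <- line_traj(1:30, x0 = 10.20, y0 = 10, traj_id = 2L)  # 200 nm
  acc <- line_traj(1:30, x0 = 10, y0 = 10, traj_id = 9L)
  pr <- pair_trajectories(rbind(d1, d2), acc, channel_transform(), 250)
  # exhaustive check: mean distances
  expect_lt(80, 200)
  expect_equal(pr$pairs$donor_id, 1L)
  # the loser is acceptor-associated, hence not alpha-calibration material
  expect_false(2L %in% pr$donor_only_ids)
})

test_that("change-point detection finds constructed steps and nothing else", {
  set.seed(20)
  flat <- rnorm(100, 1000, 30)
  expect_equal(nrow(detect_intensity_steps(flat)), 0L)

  step <- c(rep(1000, 50), rep(0, 50)) + rnorm(100, 0, 30)
  cp <- detect_intensity_steps(step)
  expect_equal(nrow(cp), 1L)
  expect_lte(abs(cp$index - 51), 1)
  expect_gt(cp$before_mean, 900)
  expect_lt(cp$after_mean, 100)

  stair <- c(rep(1000, 40), rep(500, 30), rep(0, 30)) + rnorm(100, 0, 30)
  cp2 <- detect_intensity_steps(stair)
  expect_equal(nrow(cp2), 2L)

  expect_error(detect_intensity_steps(rnorm(9)), "10")
})

test_that("vetting accepts a dissociation trace and pins the loss frame", {
  tr <- constructed_trace(n = 100, loss = 50, seed = 21)
  v <- vet_fret_trace(tr)
  expect_true(v$accepted)
  expect_lte(abs(v$acceptor_loss_frame - 50), 1)
  expect_false(isTRUE(v$both_lost))
})

test_that("multi-step puncta and flat traces are rejected with reasons", {
  set.seed(22)
  # two acceptors bleaching sequentially (endocytic punctum behaviour)
  n <- 100
  I_AD <- c(rep(1080, 40), rep(540, 30), rep(0, 30)) + rnorm(n, 0, 12)
  I_DD <- c(rep(120, 40), rep(660, 30), rep(1200, 30)) + rnorm(n, 0, 12)
  punctum <- fret_trace(1:n, I_DD, I_AD)
  vp <- vet_fret_trace(punctum)
  expect_false(vp$accepted)
  expect_equal(vp$reason, "multi_step")

  flat <- fret_trace(1:n, rnorm(n, 500, 10), rnorm(n, 500, 10))
  vf <- vet_fret_trace(flat)
  expect_false(vf$accepted)
  expect_equal(vf$reason, "no_anticorrelation")

  short <- fret_trace(1:5, rep(1, 5), rep(1, 5))
  vs <- vet_fret_trace(short)
  expect_equal(vs$reason, "too_short")
})

test_that("simultaneous donor and acceptor loss is accepted as a pathway-2 candidate", {
  tr <- constructed_trace(n = 100, loss = 50, donor_end = 50, seed = 23)
  v <- vet_fret_trace(tr)
  expect_true(v$accepted)
  expect_true(v$both_lost)
})

test_that("donor concatenation picks the nearest candidate inside 250 nm", {
  tr <- constructed_trace(n = 60, loss = 50, seed = 24)
  tr$acceptor_loss_frame <- 50L
  tr$coords <- data.frame(frame = 1:49, x_um = 10, y_um = 10,
                          precision_nm = 20, source = "acceptor")
  near <- line_traj(50:80, x0 = 10.10, y0 = 10, traj_id = 7L)   # 100 nm
  far <- line_traj(50:80, x0 = 10.2, y0 = 10, traj_id = 8L)     # 200 nm
  out <- concatenate_donor(tr, rbind(near, far))
  expect_equal(out$concatenated_donor_id, 7L)
  expect_equal(max(out$frames), 80L)

  none <- line_traj(50:80, x0 = 10.4, y0 = 10, traj_id = 9L)    # 400 nm
  out2 <- concatenate_donor(tr, none)
  expect_null(out2$concatenated_donor_id)
})

test_that("correction factors are recovered from constructed and simulated traces", {
  # exact ratio: I_AD = 0.1 * I_DD
  donly <- lapply(1:6, function(i) {
    fret_trace(1:50, rep(1000, 50), rep(100, 50))
  })
  f <- estimate_correction_factors(donor_only_traces = donly, gamma = 1)
  expect_equal(f$alpha, 0.1, tolerance = 1e-12)

  expect_error(estimate_correction_factors(donor_only_traces = donly[1:3]),
               "alpha")

  # zero-crosstalk simulation recovers alpha = delta = 0 within noise
  cfg0 <- sim_config(leak_alpha_true = 0, direct_delta_true = 0,
                     alex = TRUE, bleach_rate_donor = 0, seed = 25)
  sd0 <- simulate_intensity_traces(cfg0, 20, "donor_only", noise_sd = 3)
  sa0 <- simulate_intensity_traces(cfg0, 20, "acceptor_only", noise_sd = 3,
                                   seed = 26)
  f0 <- estimate_correction_factors(sd0$traces, sa0$traces, gamma = 1)
  expect_lt(abs(f0$alpha), 0.01)
  expect_lt(abs(f0$delta), 0.01)

  # gamma recovery from the acceptor-bleach step across 50 traces
  cfgg <- sim_config(gamma_true = 1.2, k_off = 1 / 1.13,
                     bleach_rate_donor = 0, p_internalize = 0,
                     leak_alpha_true = 0.05, seed = 27)
  sg <- simulate_intensity_traces(cfgg, 80, "dimer", n_frames = 120,
                                  noise_sd = 8)
  vetted <- lapply(sg$traces, vet_fret_trace)
  acc <- Filter(function(tr) isTRUE(tr$accepted) && !isTRUE(tr$both_lost),
                vetted)
  expect_gte(length(acc), 50)
  dcal <- simulate_intensity_traces(cfgg, 10, "donor_only", noise_sd = 8,
                                    seed = 28)
  fg <- estimate_correction_factors(dcal$traces, list(), acc)
  expect_lt(abs(fg$gamma - 1.2) / 1.2, 0.1)
})

test_that("alpha and delta are recovered to 0.01 across the crosstalk grid", {
  for (a in c(0, 0.05, 0.1)) {
    for (d in c(0, 0.05, 0.1)) {
      cfg <- sim_config(leak_alpha_true = a, direct_delta_true = d,
                        alex = TRUE, bleach_rate_donor = 0,
                        bleach_rate_acceptor = 0,
                        seed = 100 + round(1000 * a + 100 * d))
      sd <- simulate_intensity_traces(cfg, 25, "donor_only", noise_sd = 2)
      sa <- simulate_intensity_traces(cfg, 25, "acceptor_only", noise_sd = 2,
                                      seed = cfg$seed + 1)
      f <- estimate_correction_factors(sd$traces, sa$traces, gamma = 1)
      expect_lt(abs(f$alpha - a), 0.01)
      expect_lt(abs(f$delta - d), 0.01)
    }
  }
})

test_that("corrected FRET efficiency matches hand-evaluated algebra", {
  fx <- list(alpha = 0.05, delta = 0.1, gamma = 1.2)
  e <- compute_fret_efficiency(list(I_DD = 300, I_AD = 700, I_AA = 500), fx)
  # F = 700 - 0.05*300 - 0.1*500 = 635; E = 635 / (1.2*300 + 635)
  expect_equal(as.numeric(e), 635 / 995, tolerance = 1e-12)

  f0 <- list(alpha = 0, delta = 0, gamma = 1)
  expect_equal(as.numeric(compute_fret_efficiency(
    list(I_DD = 500, I_AD = 0, I_AA = NULL), f0)), 0)
  expect_equal(as.numeric(compute_fret_efficiency(
    list(I_DD = 400, I_AD = 400, I_AA = NULL), f0)), 0.5)

  # ten random tuples against an independent inline oracle
  set.seed(29)
  for (i in 1:10) {
    idd <- runif(1, 100, 1000)
    iad <- runif(1, 0, 1000)
    iaa <- runif(1, 0, 1000)
    al <- runif(1, 0, 0.2)
    de <- runif(1, 0, 0.2)
    ga <- runif(1, 0.5, 2)
    oracle <- (iad - al * idd - de * iaa) /
      (ga * idd + iad - al * idd - de * iaa)
    got <- compute_fret_efficiency(
      list(I_DD = idd, I_AD = iad, I_AA = iaa),
      list(alpha = al, delta = de, gamma = ga))
    expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  }
})

test_that("E is invariant under joint intensity rescaling and flags bad frames", {
  fx <- list(alpha = 0.05, delta = 0, gamma = 1.2)
  e1 <- compute_fret_efficiency(list(I_DD = 300, I_AD = 700, I_AA = NULL), fx)
  e2 <- compute_fret_efficiency(list(I_DD = 3000, I_AD = 7000, I_AA = NULL), fx)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-12)

  bad <- compute_fret_efficiency(list(I_DD = 10, I_AD = -100, I_AA = NULL), fx)
  expect_true(is.na(as.numeric(bad)[1]))
  expect_equal(attr(bad, "invalid_frames"), 1L)
})

test_that("stoichiometry covers its limiting cases and needs ALEX data", {
  fx <- list(alpha = 0, delta = 0, gamma = 1, beta = 1)
  expect_equal(compute_stoichiometry(
    list(I_DD = 500, I_AD = 500, I_AA = 0), fx), 1)
  expect_equal(compute_stoichiometry(
    list(I_DD = 0, I_AD = 0, I_AA = 800), fx), 0)
  expect_equal(compute_stoichiometry(
    list(I_DD = 500, I_AD = 500, I_AA = 1000), fx), 0.5)
  expect_error(compute_stoichiometry(
    list(I_DD = 1, I_AD = 1, I_AA = NULL), fx), "ALEX")
})

test_that("Gaussian histogram fitting recovers a known distribution", {
  set.seed(33)
  v <- rnorm(500, 0.9, 0.05)
  ft <- fit_gaussian_histogram(v)
  expect_lt(abs(ft$mean - 0.9), 0.01)
  expect_lt(abs(ft$sd - 0.05), 0.015)
  expect_gt(ft$r_squared, 0.9)

  expect_error(fit_gaussian_histogram(rep(1, 100)), "identical")
  expect_error(fit_gaussian_histogram(rnorm(10)), "30")

  bimodal <- c(rnorm(400, 0.2, 0.03), rnorm(400, 0.8, 0.03))
  fb <- fit_gaussian_histogram(bimodal)
  expect_lt(fb$r_squared, 0.5)  # single Gaussian flagged by poor fit
})

test_that("FRET trace CSV export writes per-frame data and sidecar metadata", {
  tr <- constructed_trace(n = 60, loss = 30, seed = 34)
  tr <- vet_fret_trace(tr)
  tr <- compute_fret_efficiency(tr, list(alpha = 0, delta = 0, gamma = 1))
  path <- tempfile(fileext = ".csv")
  write_fret_trace_csv(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 60L)
  expect_true(all(c("I_DD", "I_AD", "E", "segment_label") %in% names(back)))
  expect_equal(sum(back$segment_label == "fret"),
               tr$acceptor_loss_frame - 1L)
  meta <- readLines(paste0(sub("\\.csv$", "", path), ".meta.txt"))
  expect_true(any(grepl("accepted = TRUE", meta)))
})
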