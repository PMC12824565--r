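test_that("configuration rejects non-finite and out-of-range values", {
  expect_error(sim_config(k_off = -1), "non-negative")
  expect_error(sim_config(E_true = 1.5), "E_true")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(D_monomer = NaN), "finite")
  expect_error(sim_config(confinement_radius = -5), "confinement_radius")
})

test_that("config round-trips through the key-value text format", {
  cfg <- sim_config(n_frames = 77, k_off = 0.5, confinement_radius = 150,
                    alex = TRUE, seed = 9)
  path <- tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_frames, 77L)
  expect_equal(cfg2$k_off, 0.5)
  expect_equal(cfg2$confinement_radius, 150)
  expect_true(cfg2$alex)
})

test_that("zero dissociation and bleach rates keep every dimer dimeric", {
  cfg <- tiny_config(k_off = 0, bleach_rate_donor = 0,
                     bleach_rate_acceptor = 0, f_dimer = 1,
                     birth = "start")
  truth <- simulate_state_trajectories(cfg, n_emitters = 30)
  expect_true(all(is.na(truth$per_emitter$dissociation_frame)))
  expect_true(all(truth$states$state == "dimer"))
  expect_false(any(truth$states$donor_bleached))
})

test_that("zero diffusion freezes all positions", {
  cfg <- tiny_config(D_monomer = 0, D_dimer = 0, birth = "start")
  truth <- simulate_state_trajectories(cfg, n_emitters = 10)
  for (e in unique(truth$states$emitter_id)) {
    rows <- truth$states[truth$states$emitter_id == e, ]
    expect_equal(diff(range(rows$x_um)), 0)
    expect_equal(diff(range(rows$y_um)), 0)
  }
})

test_that("dimer dwell times are exponential with the configured mean", {
  cfg <- sim_config(k_off = 1.0, frame_interval = 0.04, n_frames = 5,
                    f_dimer = 1, birth = "start", seed = 77,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0)
  truth <- simulate_state_trajectories(cfg, n_emitters = 10000)
  dw <- truth$per_emitter$dwell_s
  expect_length(dw, 10000)
  # continuous draws, before frame discretization
  expect_lt(abs(mean(dw) - 1.0), 0.02)
  ks <- ks.test(dw, "pexp", rate = 1.0)
  expect_gt(ks$p.value, 0.01)
})

test_that("free-monomer ensemble MSD matches 4*D*t within 3 SE", {
  D <- 0.1
  dt <- 0.04
  cfg <- sim_config(field_size = c(512L, 512L), n_frames = 11,
                    D_monomer = D, f_dimer = 0, birth = "start",
                    bleach_rate_donor = 0, seed = 5)
  truth <- simulate_state_trajectories(cfg, n_emitters = 4000)
  st <- truth$states
  for (lag in c(1, 5, 10)) {
    a <- st[st$frame == 1, ]
    b <- st[st$frame == 1 + lag, ]
    common <- intersect(a$emitter_id, b$emitter_id)
    d2 <- (b$x_um[match(common, b$emitter_id)] - a$x_um[match(common, a$emitter_id)])^2 +
      (b$y_um[match(common, b$emitter_id)] - a$y_um[match(common, a$emitter_id)])^2
    se <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - 4 * D * lag * dt), 3 * se)
  }
})

test_that("confined ensemble MSD plateaus below the reflecting-disk bound", {
  R_nm <- 200
  cfg <- sim_config(field_size = c(512L, 512L), n_frames = 60,
                    D_monomer = 0.1, f_dimer = 0, birth = "start",
                    confinement_radius = R_nm, bleach_rate_donor = 0,
                    seed = 6)
  truth <- simulate_state_trajectories(cfg, n_emitters = 500)
  st <- truth$states
  a <- st[st$frame == 1, ]
  b <- st[st$frame == 50, ]
  common <- intersect(a$emitter_id, b$emitter_id)
  d2 <- (b$x_um[match(common, b$emitter_id)] - a$x_um[match(common, a$emitter_id)])^2 +
    (b$y_um[match(common, b$emitter_id)] - a$y_um[match(common, a$emitter_id)])^2
  plateau <- mean(d2)
  expect_lt(plateau, (R_nm / 1000)^2)
  # and it has actually plateaued: far below the free expectation
  expect_lt(plateau, 0.5 * 4 * 0.1 * 49 * 0.04)
})

test_that("pathway draws follow the internalization probability", {
  cfg <- sim_config(n_frames = 400, k_off = 1, p_internalize = 0.7,
                    f_dimer = 1, birth = "start", seed = 8,
                    field_size = c(512L, 512L))
  truth <- simulate_state_trajectories(cfg, n_emitters = 2000)
  pw <- truth$per_emitter$pathway
  frac2 <- mean(pw[!is.na(pw)] == 2L)
  expect_lt(abs(frac2 - 0.7), 0.03)
})

test_that("rendering an empty field gives a flat baseline image", {
  cfg <- tiny_config(emitter_density = 0, background_mean = 0, n_frames = 2)
  truth <- simulate_state_trajectories(cfg, n_emitters = 0)
  mv <- render_movie(truth, cfg)
  expect_true(all(mv == cfg$camera_baseline))
})

test_that("rendered photon flux matches the truth rate within Poisson error", {
  cfg <- sim_config(field_size = c(64L, 64L), n_frames = 1,
                    emitter_density = 0, background_mean = 0,
                    D_monomer = 0, f_dimer = 0, birth = "start", seed = 12)
  truth <- simulate_state_trajectories(cfg, n_emitters = 0)
  # place one bright stationary monomer mid-field by hand
  N <- 20000
  truth$states <- data.frame(
    frame = 1L, emitter_id = 1L, x_um = 32 * 0.159, y_um = 32 * 0.159,
    state = "monomer", donor_bleached = FALSE, acceptor_bleached = FALSE,
    rate_dd = N, rate_ad = 0, rate_aa = 0)
  mv <- render_movie(truth, cfg)
  img <- (mv[, 1:64, 1] - cfg$camera_baseline) / cfg$camera_gain
  win <- img[25:39, 25:39]  # 15 x 15 px around the emitter
  expect_lt(abs(sum(win) - N), 4 * sqrt(N))
})

test_that("full frames are 256 x 512 with the channel split at column 256", {
  cfg <- sim_config(n_frames = 1, emitter_density = 0.01, seed = 4)
  truth <- simulate_state_trajectories(cfg)
  mv <- render_movie(truth, cfg)
  expect_equal(dim(mv), c(256L, 512L, 1L))
  expect_equal(attr(mv, "channel_split"), 257L)
})

test_that("identical seeds reproduce movies bit-identically, different seeds differ", {
  cfg <- tiny_config(n_frames = 10)
  m1 <- simulate_movie(cfg)
  m2 <- simulate_movie(cfg)
  expect_identical(m1$movie[, , ], m2$movie[, , ])
  expect_identical(m1$truth$states, m2$truth$states)
  cfg2 <- tiny_config(n_frames = 10, seed = 202L)
  m3 <- simulate_movie(cfg2)
  expect_false(identical(m1$movie[, , ], m3$movie[, , ]))
})

test_that("movies and truth tables round-trip through TIFF and CSV", {
  cfg <- tiny_config(n_frames = 4)
  sim <- simulate_movie(cfg)
  tp <- tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, tp)
  back <- read_movie_tiff(tp)
  expect_identical(as.integer(back), as.integer(sim$movie))
  cp <- tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, cp)
  tt <- read_truth_csv(cp)
  expect_equal(nrow(tt), nrow(sim$truth$states))
  expect_true(all(c("frame", "emitter_id", "x_um", "state", "pathway")
                  %in% names(tt)))
})

test_that("trace-level simulator reproduces photophysics rates", {
  cfg <- sim_config(photons_donor = 1000, E_true = 0.8, gamma_true = 1.1,
                    leak_alpha_true = 0.05, k_off = 0,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                    seed = 30)
  sim <- simulate_intensity_traces(cfg, 50, "dimer", n_frames = 60,
                                   noise_sd = 1)
  idd <- mean(vapply(sim$traces, function(tr) mean(tr$I_DD), 0))
  iad <- mean(vapply(sim$traces, function(tr) mean(tr$I_AD), 0))
  expect_lt(abs(idd - 200) / 200, 0.05)       # (1-E) * N
  expect_lt(abs(iad - (1.1 * 800 + 0.05 * 200)) / 890, 0.05)
})
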