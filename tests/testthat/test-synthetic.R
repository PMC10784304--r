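test_that("schedule counts follow the design proportions exactly", {
  p1 <- paradigm_config("1-target")
  sc <- make_schedule(p1, 1, seed = 2)
  expect_equal(sum(sc$level_db == 70), 14)
  expect_equal(sum(sc$level_db == 60), 56)
  expect_equal(unname(table(sc$role)[["target"]]), 14)

  p2 <- paradigm_config("2-target")
  sc <- make_schedule(p2, 1, seed = 2)
  expect_equal(as.integer(table(sc$level_db)), c(14L, 42L, 14L))
  expect_equal(sum(sc$role == "frequent"), 42)
  # sessions 1-10 target 70 dB, 11-20 target 50 dB
  expect_equal(unique(sc$level_db[sc$role == "target"]), 70)
  sc2 <- make_schedule(p2, 15, seed = 2)
  expect_equal(unique(sc2$level_db[sc2$role == "target"]), 50)
})

test_that("largest-remainder rounding apportions awkward fractions", {
  # 10 trials at 0.45/0.35/0.2 -> floors 4/3/2, the extra trial goes to
  # the first of the tied 0.5 remainders
  p <- paradigm_config(trials_per_session = 10,
                       proportions = c(`50` = 0.45, `60` = 0.35, `70` = 0.2),
                       target_levels = rep(70, 20))
  sc <- make_schedule(p, 1, seed = 1)
  expect_equal(as.integer(table(sc$level_db)), c(5L, 3L, 2L))
})

test_that("zero target proportion yields zero target rows", {
  p <- paradigm_config(proportions = c(`60` = 1), target_levels = rep(70, 20))
  sc <- make_schedule(p, 1, seed = 1)
  expect_equal(sum(sc$role == "target"), 0)
})

test_that("schedules and sessions are seed-deterministic", {
  p <- paradigm_config()
  expect_identical(make_schedule(p, 2, seed = 77), make_schedule(p, 2, seed = 77))
  sim <- simulation_config(seed = 5)
  sc <- make_schedule(p, 1, seed = 1)
  r1 <- simulate_session(sc, sim, participant = 2)
  r2 <- simulate_session(sc, sim, participant = 2)
  expect_identical(r1$data, r2$data)
})

test_that("invalid configurations are rejected", {
  expect_error(paradigm_config(proportions = c(`60` = 0.5, `70` = 0.4)),
               "sum to 1")
  expect_error(simulation_config(habituation = 0), "habituation")
  expect_error(simulation_config(noise_rms_uv = -1), "non-negative")
  expect_error(erp_template(1, 400, -5, 1, 0:10), "width")
})

test_that("erp_template peaks at its latency and integrates analytically", {
  t <- seq(0, 1000, by = 0.05)
  w <- erp_template(7, 400, 60, 1, t)
  expect_equal(max(w), 7)
  expect_equal(t[which.max(w)], 400)
  expect_equal(erp_template(0, 400, 60, 1, t), numeric(length(t)))
  # quadrature oracle vs closed form A*w*sqrt(2*pi)
  quad <- sum(w) * 0.05
  expect_equal(quad, 7 * 60 * sqrt(2 * pi), tolerance = 0.01)
  # negative polarity mirrors
  expect_equal(erp_template(7, 400, 60, -1, t), -w)
})

test_that("scalp topography is 1 at the centre and decays as expected", {
  m <- biosemi64_montage()
  w <- scalp_topography(m, "Cz")
  expect_equal(w[["Cz"]], 1)
  expect_true(all(w >= 0 & w <= 1))
  # frontal channels stay below 0.3 under the default spread
  expect_lt(max(w[frontal17_channels()]), 0.3)
  expect_gt(mean(w[roi47_channels()]), mean(w[frontal17_channels()]))
  # infinite spread limit: all weights -> 1
  w_inf <- scalp_topography(m, "Cz", spread = 1e6)
  expect_true(all(abs(w_inf - 1) < 1e-9))
  expect_error(scalp_topography(m, "XX9"), "unknown")
})

test_that("noiseless single-trial session reproduces the summed templates", {
  ev <- one_trial_events()
  sim <- noiseless_sim()
  rec <- simulate_session(ev, sim, participant = 1)
  # epoch [0, 1000) ms at Cz
  got <- rec$data["Cz", (256 + 1):(256 + 256)]
  t_ms <- (0:255) / 256 * 1000
  expect_equal(unname(got), expected_target_cz(t_ms), tolerance = 1e-6)
  # before onset the noiseless recording is silent
  expect_lt(max(abs(rec$data[, 1:200])), 1e-6)
})

test_that("habituation h = 1 leaves amplitudes session-independent", {
  p <- paradigm_config()
  sim <- noiseless_sim(habituation = 1)
  sc1 <- make_schedule(p, 1, seed = 3)
  sc9 <- make_schedule(p, 9, seed = 3)
  r1 <- simulate_session(sc1, sim, 1)
  r9 <- simulate_session(sc9, sim, 1)
  a1 <- max(r1$data["Cz", ])
  a9 <- max(r9$data["Cz", ])
  expect_equal(a1, a9, tolerance = 1e-9)
  # and h < 1 shrinks later sessions
  simh <- noiseless_sim(habituation = 0.9)
  expect_lt(max(simulate_session(sc9, simh, 1)$data["Cz", ]),
            max(simulate_session(sc1, simh, 1)$data["Cz", ]))
})

test_that("simulation is linear in component amplitude at fixed seeds", {
  p <- paradigm_config(trials_per_session = 10)
  sc <- make_schedule(p, 1, seed = 4)
  comps <- default_erp_components()
  comps2 <- comps
  comps2$amp_target_uv <- 2 * comps$amp_target_uv
  comps2$amp_nontarget_uv <- 2 * comps$amp_nontarget_uv
  simA <- simulation_config(components = comps, seed = 6, participant_sdlog = 0)
  sim2A <- simulation_config(components = comps2, seed = 6, participant_sdlog = 0)
  simErp <- noiseless_sim(seed = 6, level_gain = simA$level_gain,
                          habituation = simA$habituation)
  simErp$components <- comps
  rA <- simulate_session(sc, simA, 1)
  r2A <- simulate_session(sc, sim2A, 1)
  rE <- simulate_session(sc, simErp, 1)
  expect_equal(r2A$data - rA$data, rE$data, tolerance = 1e-8)
})

test_that("background noise has a 1/f spectrum over 0.5-30 Hz", {
  p <- paradigm_config(trials_per_session = 60)
  sc <- make_schedule(p, 1, seed = 8)
  sim <- simulation_config(seed = 31,
                           components = within(default_erp_components(), {
                             amp_target_uv <- 0; amp_nontarget_uv <- 0
                           }),
                           alpha_amp_uv = 0, white_rms_uv = 0)
  rec <- simulate_session(sc, sim, 1)
  sp <- stats::spec.pgram(stats::ts(rec$data["Cz", ], frequency = 256),
                          spans = 15, plot = FALSE, taper = 0)
  sel <- sp$freq >= 0.5 & sp$freq <= 30
  fit <- stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel]))
  slope <- unname(coef(fit)[2])
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("ensemble average of noisy target epochs converges to the template", {
  n_tr <- 200
  ev <- event_table(onset_sample = 256 * seq_len(n_tr),
                    level_db = 70, role = "target",
                    trial_index = seq_len(n_tr), session_id = 1)
  sim <- simulation_config(level_gain = c(`50` = 1, `60` = 1, `70` = 1),
                           noise_rms_uv = 5, alpha_amp_uv = 0,
                           white_rms_uv = 0, participant_sdlog = 0,
                           habituation = 1, seed = 13)
  rec <- simulate_session(ev, sim, 1)
  eps <- sapply(ev$onset_sample, function(o) rec$data["Cz", (o + 1):(o + 256)])
  avg <- rowMeans(eps)
  t_ms <- (0:255) / 256 * 1000
  expect_lt(max(abs(avg - expected_target_cz(t_ms))), 3 * 5 / sqrt(n_tr))
})

test_that("simulate_study produces the full design with ground truth", {
  p <- paradigm_config(n_sessions = 2, trials_per_session = 6)
  sim <- simulation_config(n_participants = 3, seed = 21, noise_rms_uv = 1)
  st <- simulate_study(p, sim)
  expect_length(st$participants, 3)
  expect_length(st$participants[[1]], 2)
  expect_equal(nrow(st$participants[[2]][[1]]$events), 6)
  expect_length(st$ground_truth$participant_factors, 3)
  expect_gt(sd(st$ground_truth$participant_factors), 0)
  st2 <- simulate_study(p, sim)
  expect_identical(st$participants[[3]][[2]]$recording$data,
                   st2$participants[[3]][[2]]$recording$data)
})
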