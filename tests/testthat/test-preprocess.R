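make_ramp_recording <- function(n = 80 * 256) {
  # each sample's value equals its 0-based index, on every channel
  recording(matrix(rep(0:(n - 1), each = 64), 64, n))
}

test_that("startle-trial removal drops the first n trials per session", {
  p <- paradigm_config()
  ev <- make_schedule(p, 1, seed = 1)
  out <- drop_initial_trials(ev, 5)
  expect_equal(nrow(out), 65)
  expect_equal(sort(out$trial_index), 6:70)
  id0 <- as.data.frame(drop_initial_trials(ev, 0))
  ref <- as.data.frame(ev)
  rownames(ref) <- NULL
  expect_identical(id0, ref)
  expect_warning(res <- drop_initial_trials(ev, 100), "removed")
  expect_equal(nrow(res), 0)
})

test_that("band-pass rejects DC, passes the band centre, kills 64 Hz", {
  rate <- 256
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  probe <- function(x) {
    rec <- recording(matrix(rep(x, each = 64), 64, length(x)), rate = rate)
    bandpass(rec)$data[48, ]   # Cz row
  }
  # DC gain 0: steady-state output of a constant input decays to zero
  y <- probe(rep(1, length(t)))
  expect_lt(max(abs(y[(30 * rate):(60 * rate)])), 1e-3)
  # geometric band centre sqrt(0.1 * 8) ~ 0.894 Hz: gain ~ 1
  f0 <- sqrt(0.1 * 8)
  y <- probe(sin(2 * pi * f0 * t))
  g <- sqrt(mean(y[(30 * rate):(60 * rate)]^2)) / sqrt(0.5)
  expect_equal(g, 1, tolerance = 0.01)
  # 64 Hz: gain < 0.05
  y <- probe(sin(2 * pi * 64 * t))
  g <- sqrt(mean(y[(30 * rate):(60 * rate)]^2)) / sqrt(0.5)
  expect_lt(g, 0.05)
})

test_that("band-pass validates its corner frequencies", {
  rec <- recording(matrix(0, 64, 512))
  expect_error(bandpass(rec, low = 0, high = 8), "low")
  expect_error(bandpass(rec, low = 8, high = 0.1), "low")
  expect_error(bandpass(rec, low = 0.1, high = 200), "rate/2")
})

test_that("epoch extraction is sample-exact with the documented window", {
  rec <- make_ramp_recording()
  p <- paradigm_config()
  ev <- drop_initial_trials(make_schedule(p, 1, seed = 1), 5)
  ep <- extract_epochs(rec, ev)
  expect_equal(dim(ep$data), c(65, 64, 256))
  # first sample of each epoch sits at onset - round(0.1 * rate) = onset - 26
  expect_equal(unname(ep$data[, 1, 1]), ev$onset_sample - 26)
  expect_equal(length(ep$times_ms), 256)
  expect_lt(abs(ep$times_ms[1] - (-26 / 256 * 1000)), 1e-9)
  # a window outside the recording names the trial
  late <- event_table(ncol(rec$data) - 10, 60, "nontarget", 1, 1)
  expect_error(extract_epochs(rec, late), "trial 1")
})

test_that("baseline correction zeroes the baseline and is shift-invariant", {
  p <- paradigm_config(trials_per_session = 12)
  sc <- make_schedule(p, 1, seed = 2)
  rec <- simulate_session(sc, simulation_config(seed = 3), 1)
  ep <- extract_epochs(rec, sc)
  bc <- baseline_correct(ep)
  sel <- bc$times_ms >= -100 & bc$times_ms < 0
  bl <- apply(bc$data[, , sel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # constant epochs become identically zero
  const <- ep; const$data[] <- 5.5
  expect_lt(max(abs(baseline_correct(const)$data)), 1e-12)
  # adding a per-trial offset changes nothing after correction
  shifted <- ep; shifted$data <- shifted$data + 3.21
  expect_equal(baseline_correct(shifted)$data, bc$data, tolerance = 1e-12)
})

test_that("decimation keeps every factor-th sample and rescales the rate", {
  p <- paradigm_config(trials_per_session = 8)
  sc <- make_schedule(p, 1, seed = 2)
  rec <- simulate_session(sc, simulation_config(seed = 3), 1)
  ep <- baseline_correct(extract_epochs(rec, sc))
  dec <- decimate_epochs(ep, 8)
  expect_equal(dim(dec$data)[3], 32)
  expect_equal(dec$rate, 32)
  expect_equal(dec$data[, , 1], ep$data[, , 1])
  expect_equal(dec$data[, , 2], ep$data[, , 9])
  expect_identical(decimate_epochs(ep, 1), ep)
  expect_error(decimate_epochs(ep, 7), "divisible")
  const <- ep; const$data[] <- 2
  expect_true(all(decimate_epochs(const, 8)$data == 2))
})

test_that("channel selection restricts to the canonical subsets", {
  p <- paradigm_config(trials_per_session = 6)
  sc <- make_schedule(p, 1, seed = 2)
  rec <- simulate_session(sc, noiseless_sim(), 1)
  ep <- extract_epochs(rec, sc)
  expect_equal(select_channels(ep, "roi47")$channels, roi47_channels())
  expect_equal(select_channels(ep, "cz")$channels, "Cz")
  expect_identical(select_channels(ep, "all64"), ep)
  expect_error(select_channels(ep, c("Cz", "Nope")), "Nope")
})

test_that("vectorization is channel-major and invertible", {
  p <- paradigm_config(trials_per_session = 10)
  sc <- make_schedule(p, 1, seed = 2)
  rec <- simulate_session(sc, simulation_config(seed = 3), 1)
  dec <- decimate_epochs(baseline_correct(extract_epochs(rec, sc)), 8)
  fm <- vectorize_epochs(dec, binary = FALSE)
  expect_equal(ncol(fm$x), 64 * 32)
  # channel-major: columns 33-64 are channel 2's samples
  expect_equal(unname(fm$x[, 33:64]), unname(dec$data[, 2, ]))
  # inverse reshape recovers the array
  expect_equal(unname(feature_array(fm)), unname(dec$data))
  # frequent trials drop in binary mode
  fb <- vectorize_epochs(dec, binary = TRUE)
  expect_equal(nrow(fb$x), sum(dec$labels != "frequent"))
  expect_setequal(levels(fb$labels), c("target", "nontarget"))
  # cz-only features have 32 columns
  fc <- vectorize_epochs(select_channels(dec, "cz"))
  expect_equal(ncol(fc$x), 32)
})

test_that("channel selection commutes with vectorization", {
  p <- paradigm_config(trials_per_session = 10)
  sc <- make_schedule(p, 1, seed = 5)
  rec <- simulate_session(sc, simulation_config(seed = 5), 1)
  dec <- decimate_epochs(baseline_correct(extract_epochs(rec, sc)), 8)
  direct <- vectorize_epochs(select_channels(dec, "roi47"))
  full <- vectorize_epochs(dec)
  cols <- oddvol:::feature_columns(full, "roi47")
  expect_equal(direct$x, full$x[, cols])
})

test_that("the full chain is deterministic and recovers the P300 latency", {
  p <- paradigm_config()
  sc <- make_schedule(p, 1, seed = 6)
  rec <- simulate_session(sc, noiseless_sim(), 1)
  pp1 <- preprocess_session(rec, sc)
  pp2 <- preprocess_session(rec, sc)
  expect_identical(pp1$features$x, pp2$features$x)
  # noiseless Cz target average peaks within one downsampled sample
  # (31.25 ms) of the configured 400-ms P300 latency
  dec <- decimate_epochs(select_channels(
    baseline_correct(extract_epochs(bandpass(rec), drop_initial_trials(sc, 5))),
    "cz"), 8)
  avg <- colMeans(dec$data[dec$labels == "target", 1, ])
  t_peak <- dec$times_ms[which.max(avg)]
  expect_lte(abs(t_peak - 400), 1000 / 32)
})
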