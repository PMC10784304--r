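make_epochs <- function(trials = 6, seed = 1, noise = simulation_config(seed = seed),
                        paradigm = paradigm_config(trials_per_session = trials)) {
  sc <- make_schedule(paradigm, 1, seed = seed)
  rec <- simulate_session(sc, noise, 1)
  baseline_correct(extract_epochs(rec, sc))
}

test_that("condition averages behave as arithmetic means", {
  ep <- make_epochs(trials = 10, seed = 3)
  avg <- condition_average(ep, "target")
  sel <- which(ep$labels == "target")
  expect_equal(unname(avg[5, ]), unname(colMeans(ep$data[sel, 5, ])))
  expect_equal(attr(avg, "n_trials"), length(sel))
  expect_error(condition_average(ep, "bogus"), "no trials")
  # single trial averages to itself
  one <- ep; one$data <- ep$data[1, , , drop = FALSE]
  one$labels <- "target"; one$level_db <- 70; one$trial_index <- 1L
  expect_equal(unname(condition_average(one, "target")[,]),
               unname(ep$data[1, , ]))
  # mean of c and -c is zero
  pm <- ep
  pm$data <- ep$data[c(1, 1), , , drop = FALSE]
  pm$data[2, , ] <- -pm$data[1, , ]
  pm$labels <- c("target", "target"); pm$level_db <- c(70, 70)
  pm$trial_index <- 1:2
  expect_lt(max(abs(condition_average(pm, "target"))), 1e-12)
})

test_that("noiseless target average at Cz equals the target template", {
  p <- paradigm_config()
  sc <- make_schedule(p, 1, seed = 4)
  rec <- simulate_session(sc, noiseless_sim(), 1)
  ep <- extract_epochs(rec, sc)   # no filtering, no baseline shift needed
  avg <- condition_average(ep, "target")
  tsel <- ep$times_ms >= 0
  expect_equal(unname(avg["Cz", tsel]),
               expected_target_cz(ep$times_ms[tsel]), tolerance = 1e-6)
})

test_that("block amplitudes honour the 20-ms timestamp grid", {
  ep <- make_epochs(trials = 8, seed = 5)
  erp <- condition_average(ep, "target")
  bm <- block_amplitudes(erp, 20)
  expect_equal(ncol(bm), 50)
  spb <- attr(bm, "samples_per_block")
  expect_true(all(spb %in% c(5, 6)))
  expect_equal(sum(spb), 256)
  # weighted block mean equals the waveform mean
  expect_equal(unname(as.vector(bm %*% spb) / 256),
               unname(rowMeans(erp[,])), tolerance = 1e-9)
  # constant waveform -> constant blocks; ramp -> increasing blocks
  cst <- erp; cst[] <- 3.3
  expect_true(all(abs(block_amplitudes(cst, 20) - 3.3) < 1e-12))
  rmp <- erp; rmp[] <- rep(seq_len(256), each = nrow(erp))
  expect_true(all(diff(block_amplitudes(rmp, 20)[1, ]) > 0))
  expect_error(block_amplitudes(erp, 1), "sample period")
})

test_that("wilcoxon signed-rank matches hand results and handles degeneracy", {
  # all positive differences, n = 7: W+ = 28
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(res$statistic, 28)
  # x = y: degenerate, p = 1
  expect_warning(res <- wilcoxon_signed_rank(rep(2, 5), rep(2, 5)), "zero")
  expect_equal(res$p.value, 1)
  # spec'd instance: differences (1, -2, 3, -4, 5)
  d <- c(1, -2, 3, -4, 5)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$statistic, 9)  # ranks 1,3,5 positive
  expect_equal(res$p.value, enum_wilcoxon_p(d))
})

test_that("exact wilcoxon p equals full 2^n enumeration, ties included", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # duplicated |d| -> ties
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p.value, enum_wilcoxon_p(d), tolerance = 1e-12,
                 info = paste("d =", paste(d, collapse = ",")))
  }
})

test_that("exact wilcoxon agrees with stats::wilcox.test when tie-free", {
  set.seed(7)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n), 3)
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample normal approximation is close to the exact tail", {
  set.seed(11)
  d <- rnorm(26) + 0.4            # just above the exact-method cutoff
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("significance map flags the simulated P300 and not identical input", {
  # strong-effect simulation, 8 participants, 4 sessions each
  p <- paradigm_config(n_sessions = 4)
  sim <- simulation_config(seed = 17, n_participants = 8)
  proc <- process_study(paradigm = p, sim = sim, pipe = pipeline_config())
  tb <- lapply(seq_along(proc$participants), function(i)
    block_amplitudes(oddvol:::participant_erp(proc$participants[[i]], "target")))
  nb <- lapply(seq_along(proc$participants), function(i)
    block_amplitudes(oddvol:::participant_erp(proc$participants[[i]], "nontarget")))
  expect_error(significance_map(tb[1:2], nb[1:2]), "3 participants")
  map <- significance_map(tb, nb)
  expect_equal(dim(map$p), c(64, 50))
  expect_true(all(map$p > 0 & map$p <= 1, na.rm = TRUE))
  # at least one significant block at Cz inside 340-460 ms
  starts <- map$block_start_ms
  win <- which(starts >= 340 - 20 & starts + 20 <= 460 + 20)
  czp <- map$p["Cz", win]
  expect_true(any(czp < 0.05))
  # identical conditions: nothing significant
  null_map <- significance_map(tb, tb)
  expect_true(all(null_map$p >= 0.99))
})

test_that("peak amplitude finds the windowed maximum", {
  p <- paradigm_config()
  sc <- make_schedule(p, 1, seed = 4)
  rec <- simulate_session(sc, noiseless_sim(), 1)
  erp <- condition_average(extract_epochs(rec, sc), "target")
  pk <- peak_amplitude(erp)
  t_ms <- attr(erp, "times_ms")
  expect_equal(pk, max(expected_target_cz(t_ms[t_ms >= 300 & t_ms <= 500])),
               tolerance = 1e-6)
  # a window that excludes the peak returns the boundary maximum
  pk_early <- peak_amplitude(erp, window_ms = c(500, 700))
  expect_lt(pk_early, pk)
  expect_error(peak_amplitude(erp, window_ms = c(2000, 3000)), "outside")
  expect_error(peak_amplitude(erp, channel = "QQ1"), "unknown")
})

test_that("habituation shows up as a smaller latter-half peak", {
  p <- paradigm_config()
  sim <- noiseless_sim(habituation = 0.9)
  pk <- function(s) {
    sc <- make_schedule(p, s, seed = 4)
    rec <- simulate_session(sc, sim, 1)
    peak_amplitude(condition_average(extract_epochs(rec, sc), "target"))
  }
  expect_lt(pk(15), pk(2))
})
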