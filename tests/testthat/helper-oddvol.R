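# shared fixtures and independent oracles, all built in code

# a noise-free simulation: ERP components only
noiseless_sim <- function(seed = 1, components = default_erp_components(),
                          level_gain = c(`50` = 1, `60` = 1, `70` = 1),
                          habituation = 1, participant_sdlog = 0) {
  simulation_config(components = components, level_gain = level_gain,
                    habituation = habituation, noise_rms_uv = 0,
                    alpha_amp_uv = 0, white_rms_uv = 0,
                    participant_sdlog = participant_sdlog, seed = seed)
}

# single-trial event table: one target at 70 dB, onset after 1 s
one_trial_events <- function(rate = 256) {
  event_table(onset_sample = rate, level_db = 70, role = "target",
              trial_index = 1, session_id = 1, rate = rate)
}

# expected noiseless Cz trace for a target trial of the default
# components at unit gains, evaluated on t (ms after onset)
expected_target_cz <- function(t_ms, comps = default_erp_components(),
                               montage = biosemi64_montage()) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    w <- scalp_topography(montage, comps$center[i], comps$spread[i])[["Cz"]]
    out <- out + w * erp_template(comps$amp_target_uv[i], comps$latency_ms[i],
                                  comps$width_ms[i], comps$polarity[i], t_ms)
  }
  out
}

# brute-force two-sided Wilcoxon signed-rank p over all 2^n sign flips:
# P(|W+ - mu| >= |w_obs - mu|) under random signs
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    w <- sum(r[signs])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) count <- count + 1
  }
  count / 2^n
}

# brute-force exact Friedman permutation p: enumerate every combination
# of within-row rank permutations and compare T = sum_j (R_j - mean)^2
enum_friedman_p <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  ranks <- t(apply(x, 1, rank))
  perms <- all_perms(k)
  t_stat <- function(R) sum((R - sum(R) / k)^2)
  t_obs <- t_stat(colSums(ranks))
  ids <- rep(1, n)
  total <- nrow(perms)^n
  count <- 0
  repeat {
    R <- colSums(do.call(rbind, lapply(seq_len(n), function(i)
      ranks[i, perms[ids[i], ]])))
    if (t_stat(R) >= t_obs - 1e-9) count <- count + 1
    j <- 1
    while (j <= n) {
      ids[j] <- ids[j] + 1
      if (ids[j] <= nrow(perms)) break
      ids[j] <- 1; j <- j + 1
    }
    if (j > n) break
  }
  count / total
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# small synthetic feature matrix with two labelled classes
toy_features <- function(n_per_class = 20, d = 6, sep = 0, seed = 1,
                         channels = paste0("ch", seq_len(3)),
                         times = seq_len(d / 3)) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
  labs <- rep(c("target", "nontarget"), each = n_per_class)
  x[labs == "target", ] <- x[labs == "target", ] + sep
  feature_matrix(x, labs,
                 data.frame(participant = "P01", session = 1L,
                            trial = seq_len(2 * n_per_class)),
                 channels, times)
}
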