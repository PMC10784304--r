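#' Oddball paradigm configuration
#'
#' Defines the trial/session structure and the stimulus-level
#' proportions of an auditory sound-level oddball study. Two standard
#' designs are provided: `"1-target"` (80 % standards at 60 dB,
#' 20 % targets at 70 dB) and `"2-target"` (60 % frequent standards at
#' 60 dB, 20 % at 50 dB, 20 % at 70 dB, with the target level switching
#' from 70 dB in sessions 1-10 to 50 dB in sessions 11-20).
#'
#' @param design `"1-target"` or `"2-target"` (sets defaults for
#'   `proportions` and `target_levels`).
#' @param n_sessions number of sessions (default 20).
#' @param trials_per_session trials per session (default 70).
#' @param trial_period_s trial duration in seconds (default 1: 100-ms
#'   stimulus + 900-ms rest).
#' @param stimulus_duration_ms auditory stimulus duration (default 100).
#' @param proportions named numeric vector mapping level (dB) to its
#'   fraction of trials; must sum to 1.
#' @param target_levels integer vector of length `n_sessions` giving the
#'   target level of each session.
#' @param rate sampling rate of the EEG the schedule refers to.
#' @return Object of class `paradigm_config`.
#' @export
paradigm_config <- function(design = c("2-target", "1-target"),
                            n_sessions = 20, trials_per_session = 70,
                            trial_period_s = 1, stimulus_duration_ms = 100,
                            proportions = NULL, target_levels = NULL,
                            rate = 256) {
  design <- match.arg(design)
  if (is.null(proportions)) {
    proportions <- if (design == "1-target") c(`60` = 0.8, `70` = 0.2)
    else c(`50` = 0.2, `60` = 0.6, `70` = 0.2)
  }
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("stimulus proportions must sum to 1")
  if (is.null(target_levels)) {
    target_levels <- if (design == "1-target") rep(70, n_sessions)
    else rep(c(70, 50), c(ceiling(n_sessions / 2), floor(n_sessions / 2)))
  }
  if (length(target_levels) != n_sessions)
    stop("target_levels must have one entry per session")
  structure(list(design = design, n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 trial_period_s = trial_period_s,
                 stimulus_duration_ms = stimulus_duration_ms,
                 proportions = proportions,
                 target_levels = target_levels, rate = rate),
            class = "paradigm_config")
}

# largest-remainder apportionment of n trials to the level fractions
largest_remainder_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

role_for_level <- function(level, target_level, design) {
  if (level == target_level) return("target")
  if (design == "2-target" && level == 60) return("frequent")
  "nontarget"
}

#' Generate a pseudorandom stimulus schedule for one session
#'
#' Per-session level counts follow the configured proportions exactly
#' (largest-remainder rounding), the presentation order is a seeded
#' uniform shuffle, and roles follow the session's target level.
#' Trials start after a one-second lead-in and are spaced exactly one
#' trial period apart.
#'
#' @param paradigm a [paradigm_config()].
#' @param session_id session index (selects the target level).
#' @param seed integer RNG seed for the shuffle.
#' @return An [event_table()].
#' @export
make_schedule <- function(paradigm, session_id, seed = 1) {
  stopifnot(inherits(paradigm, "paradigm_config"))
  if (session_id < 1 || session_id > paradigm$n_sessions)
    stop("session_id out of range")
  levels_db <- as.numeric(names(paradigm$proportions))
  counts <- largest_remainder_counts(paradigm$proportions,
                                     paradigm$trials_per_session)
  seq_levels <- rep(levels_db, counts)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  seq_levels <- seq_levels[sample.int(length(seq_levels))]
  tgt <- paradigm$target_levels[session_id]
  roles <- vapply(seq_levels, role_for_level, "", target_level = tgt,
                  design = paradigm$design)
  period <- round(paradigm$trial_period_s * paradigm$rate)
  onsets <- period * seq_along(seq_levels)   # 1-s lead-in, 0-based
  event_table(onsets, seq_levels, roles,
              seq_along(seq_levels), session_id, rate = paradigm$rate)
}

#' ERP component template
#'
#' Gaussian bump `polarity * amplitude * exp(-(t - latency)^2 / (2 w^2))`
#' evaluated on a time axis in ms.
#'
#' @param amplitude_uv peak amplitude in microvolts (>= 0).
#' @param latency_ms peak latency in ms after stimulus onset.
#' @param width_ms Gaussian width (standard deviation) in ms; must be
#'   positive.
#' @param polarity +1 or -1.
#' @param times_ms time axis in ms.
#' @return Numeric waveform, same length as `times_ms`.
#' @export
erp_template <- function(amplitude_uv, latency_ms, width_ms, polarity = 1,
                         times_ms) {
  if (width_ms <= 0) stop("width_ms must be positive")
  polarity * amplitude_uv *
    exp(-((times_ms - latency_ms)^2) / (2 * width_ms^2))
}

#' Default simulated ERP components
#'
#' An auditory N1 (negative, 100 ms, 30 ms width, 2 uV for both roles,
#' fronto-central) and a P300 (positive, 400 ms, 60 ms width, 8 uV for
#' targets vs 1 uV for nontargets, centro-parietal).
#'
#' @return data.frame of component parameters.
#' @export
default_erp_components <- function() {
  data.frame(
    name = c("N1", "P300"),
    polarity = c(-1, 1),
    latency_ms = c(100, 400),
    width_ms = c(30, 60),
    amp_target_uv = c(2, 8),
    amp_nontarget_uv = c(2, 1),
    center = c("FCz", "Cz"),
    spread = c(0.18, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All generator parameters for synthetic oddball EEG.
#'
#' @param components data.frame of ERP components (see
#'   [default_erp_components()]); `amp_nontarget_uv` also applies to
#'   frequent standards.
#' @param level_gain named vector of multiplicative ERP gains per
#'   stimulus level, modelling loudness-dependent evoked potentials.
#' @param habituation per-session amplitude decay factor `h` in (0, 1]:
#'   session s is scaled by `h^(s-1)`.
#' @param noise_rms_uv RMS of the 1/f^alpha background noise in uV.
#' @param noise_alpha spectral exponent of the background noise.
#' @param alpha_amp_uv amplitude of the 10-Hz alpha rhythm component.
#' @param alpha_freq_hz alpha rhythm frequency.
#' @param white_rms_uv RMS of the additive white noise floor.
#' @param n_participants number of simulated participants.
#' @param participant_sdlog lognormal sd of the per-participant
#'   multiplicative amplitude factor.
#' @param seed master seed; participant and session seeds derive from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(components = default_erp_components(),
                              level_gain = c(`50` = 0.7, `60` = 1, `70` = 1.3),
                              habituation = 0.99,
                              noise_rms_uv = 15, noise_alpha = 1,
                              alpha_amp_uv = 3, alpha_freq_hz = 10,
                              white_rms_uv = 2,
                              n_participants = 10,
                              participant_sdlog = 0.2, seed = 1) {
  if (habituation <= 0 || habituation > 1)
    stop("habituation must be in (0, 1]")
  if (noise_rms_uv < 0 || white_rms_uv < 0 || alpha_amp_uv < 0)
    stop("noise amplitudes must be non-negative")
  if (any(components$width_ms <= 0)) stop("component widths must be positive")
  structure(list(components = components, level_gain = level_gain,
                 habituation = habituation, noise_rms_uv = noise_rms_uv,
                 noise_alpha = noise_alpha, alpha_amp_uv = alpha_amp_uv,
                 alpha_freq_hz = alpha_freq_hz, white_rms_uv = white_rms_uv,
                 n_participants = as.integer(n_participants),
                 participant_sdlog = participant_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# -- hierarchical seeding ----------------------------------------------------
# Lehmer-style mixing keeps every derived seed a valid 32-bit integer and
# makes any (participant, session) cell regenerable in isolation.
derive_seed <- function(master, ...) {
  s <- as.double(master %% 2147483647L)
  for (i in c(...)) s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(s)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

participant_factor <- function(sim, participant) {
  old <- local_seed(derive_seed(sim$seed, 7L, participant))
  on.exit(restore_seed(old))
  exp(rnorm(1, mean = 0, sd = sim$participant_sdlog))
}

# 1/f^alpha Gaussian noise of length n, unit RMS, via spectral shaping
pink_noise <- function(n, alpha, rate) {
  nf <- n %/% 2
  freqs <- c(1, seq_len(nf)) * rate / n       # DC slot reuses the first bin
  mag <- freqs^(-alpha / 2)
  mag[1] <- 0                                  # no DC
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, mag[2:(nf + 1)]),
                  argument = c(0, phases))
  full <- if (n %% 2 == 1) {
    c(spec, Conj(rev(spec[2:(nf + 1)])))
  } else {
    c(spec[1:nf], Re(spec[nf + 1]), Conj(rev(spec[2:nf])))
  }
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

#' Simulate one session of continuous oddball EEG
#'
#' Background noise (1/f^alpha + alpha rhythm + white floor) plus, at
#' each scheduled onset, the ERP components scaled by scalp topography,
#' level gain, role gain (target vs nontarget/frequent amplitude),
#' habituation `h^(session-1)` and the participant factor.
#'
#' @param schedule an [event_table()] for the session.
#' @param sim a [simulation_config()].
#' @param participant participant index (determines the participant
#'   amplitude factor).
#' @param seed RNG seed for this session's noise (defaults to a seed
#'   derived from `sim$seed`, the participant and the session).
#' @param montage electrode montage (default 64-channel).
#' @param rate sampling rate in Hz.
#' @return An [recording()] of duration `last onset + 1 s`.
#' @export
simulate_session <- function(schedule, sim, participant = 1, seed = NULL,
                             montage = biosemi64_montage(), rate = 256) {
  stopifnot(inherits(schedule, "event_table"),
            inherits(sim, "simulation_config"))
  session_id <- schedule$session_id[1]
  if (is.null(seed)) seed <- derive_seed(sim$seed, participant, session_id)
  n_ch <- length(montage$channel_names)
  n <- max(schedule$onset_sample) + rate       # last onset + 1 s
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  data <- matrix(0, n_ch, n)
  if (sim$noise_rms_uv > 0)
    for (ci in seq_len(n_ch))
      data[ci, ] <- sim$noise_rms_uv * pink_noise(n, sim$noise_alpha, rate)
  if (sim$alpha_amp_uv > 0) {
    t_s <- (seq_len(n) - 1) / rate
    for (ci in seq_len(n_ch))
      data[ci, ] <- data[ci, ] + sim$alpha_amp_uv *
        sin(2 * pi * sim$alpha_freq_hz * t_s + runif(1, 0, 2 * pi))
  }
  if (sim$white_rms_uv > 0)
    data <- data + matrix(rnorm(n_ch * n, sd = sim$white_rms_uv), n_ch, n)

  pf <- participant_factor(sim, participant)
  hab <- sim$habituation^(session_id - 1)
  comps <- sim$components
  topo <- lapply(seq_len(nrow(comps)), function(i)
    scalp_topography(montage, comps$center[i], comps$spread[i]))
  warned <- FALSE
  for (tr in seq_len(nrow(schedule))) {
    lev <- schedule$level_db[tr]
    lg <- sim$level_gain[[as.character(lev)]]
    if (is.null(lg)) lg <- 1
    is_target <- schedule$role[tr] == "target"
    for (i in seq_len(nrow(comps))) {
      amp <- if (is_target) comps$amp_target_uv[i] else comps$amp_nontarget_uv[i]
      amp <- amp * lg * hab * pf
      if (amp == 0) next
      sup_ms <- comps$latency_ms[i] + 6 * comps$width_ms[i]
      if (!warned && sup_ms > 1000 * diff_period(schedule, rate)) {
        warning("ERP component support exceeds the trial period; ",
                "overlapping responses are summed linearly")
        warned <- TRUE
      }
      len <- min(ceiling(sup_ms / 1000 * rate), n - schedule$onset_sample[tr])
      t_ms <- (seq_len(len) - 1) / rate * 1000
      wave <- erp_template(amp, comps$latency_ms[i], comps$width_ms[i],
                           comps$polarity[i], t_ms)
      idx <- schedule$onset_sample[tr] + seq_len(len)   # 0-based onset
      data[, idx] <- data[, idx] + outer(topo[[i]], wave)
    }
  }
  recording(data, rate = rate, montage = montage, session_id = session_id,
            participant_id = sprintf("P%02d", participant))
}

diff_period <- function(schedule, rate) {
  if (nrow(schedule) > 1) min(diff(schedule$onset_sample)) / rate else Inf
}

#' Simulate a complete multi-participant study
#'
#' Generates schedules and recordings for every participant and session,
#' with all seeds derived deterministically from the master seed, plus a
#' ground-truth record of the generating parameters.
#'
#' @param paradigm a [paradigm_config()].
#' @param sim a [simulation_config()].
#' @param participants which participants to generate (default all).
#' @param sessions which sessions to generate (default all).
#' @return Object of class `oddball_study`: a list with `participants`
#'   (nested lists of `$events` / `$recording`) and `ground_truth`.
#' @export
simulate_study <- function(paradigm, sim,
                           participants = seq_len(sim$n_participants),
                           sessions = seq_len(paradigm$n_sessions)) {
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(sim, "simulation_config"))
  out <- lapply(participants, function(p) {
    lapply(sessions, function(s) {
      sched <- make_schedule(paradigm, s, seed = derive_seed(sim$seed, 3L, p, s))
      list(events = sched,
           recording = simulate_session(sched, sim, participant = p,
                                        rate = paradigm$rate))
    })
  })
  names(out) <- sprintf("P%02d", participants)
  for (i in seq_along(out)) names(out[[i]]) <- paste0("S", sessions)
  structure(list(participants = out,
                 ground_truth = list(
                   paradigm = paradigm, sim = sim,
                   participant_factors = vapply(participants,
                     function(p) participant_factor(sim, p), 0))),
            class = "oddball_study")
}

#' @export
print.oddball_study <- function(x, ...) {
  np <- length(x$participants)
  ns <- length(x$participants[[1]])
  cat(sprintf("<oddball_study> %d participants x %d sessions (%s design)\n",
              np, ns, x$ground_truth$paradigm$design))
  invisible(x)
}
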