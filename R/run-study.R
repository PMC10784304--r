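#' Preprocess a whole study into classification features and ERP sums
#'
#' Runs the preprocessing chain over every participant and session.
#' When `study` is an `oddball_study` (materialised recordings) its
#' sessions are used directly; when `paradigm`/`sim` configs are given
#' instead, each session is simulated, preprocessed and discarded in
#' turn, so arbitrarily long studies fit in memory.
#'
#' Features are always built on all 64 channels; channel subsets are
#' taken per condition by [run_condition()] (column subsetting commutes
#' with vectorization). Per session and condition, full-rate
#' baseline-corrected ERP means are retained for ERP analysis.
#'
#' @param study an `oddball_study` from [simulate_study()], or NULL.
#' @param paradigm,sim configs for streaming simulation (used when
#'   `study` is NULL).
#' @param pipe a [pipeline_config()]; its `channel_set` is ignored
#'   (features keep all channels).
#' @param participants,sessions subsets to process (streaming mode).
#' @return Object of class `oddball_study_features`.
#' @export
process_study <- function(study = NULL, paradigm = NULL, sim = NULL,
                          pipe = pipeline_config(),
                          participants = NULL, sessions = NULL) {
  pipe$channel_set <- "all64"
  if (!is.null(study)) {
    stopifnot(inherits(study, "oddball_study"))
    plist <- lapply(study$participants, function(sess_list) {
      process_participant(lapply(sess_list, identity), pipe)
    })
  } else {
    stopifnot(inherits(paradigm, "paradigm_config"),
              inherits(sim, "simulation_config"))
    if (is.null(participants)) participants <- seq_len(sim$n_participants)
    if (is.null(sessions)) sessions <- seq_len(paradigm$n_sessions)
    plist <- lapply(participants, function(p) {
      sess_list <- lapply(sessions, function(s) {
        sched <- make_schedule(paradigm, s,
                               seed = derive_seed(sim$seed, 3L, p, s))
        list(events = sched,
             recording = simulate_session(sched, sim, participant = p,
                                          rate = paradigm$rate))
      })
      process_participant(sess_list, pipe)
    })
    names(plist) <- sprintf("P%02d", participants)
  }
  structure(list(participants = plist, pipe = pipe),
            class = "oddball_study_features")
}

process_participant <- function(sess_list, pipe) {
  feats <- list(); erp <- list()
  for (si in seq_along(sess_list)) {
    pp <- preprocess_session(sess_list[[si]]$recording,
                             sess_list[[si]]$events, pipe)
    feats[[si]] <- pp$features
    ep <- pp$epochs
    erp[[si]] <- list(
      session = ep$session_id,
      target = condition_mean_safe(ep, "target"),
      nontarget = condition_mean_safe(ep, "nontarget"))
  }
  x <- do.call(rbind, lapply(feats, function(f) f$x))
  labs <- unlist(lapply(feats, function(f) as.character(f$labels)))
  lev <- unlist(lapply(feats, function(f) f$level_db))
  grp <- do.call(rbind, lapply(feats, function(f) f$groups))
  f1 <- feats[[1]]
  list(features = feature_matrix(x, labs, grp, f1$channels, f1$times_ms, lev),
       erp = erp)
}

condition_mean_safe <- function(ep, cond) {
  if (!any(ep$labels == cond)) return(NULL)
  list(mean = condition_average(ep, cond), n = sum(ep$labels == cond))
}

# participant-level condition average over a session range, from the
# per-session means retained by process_study
participant_erp <- function(pfeat, condition, session_range = NULL) {
  acc <- NULL; ntot <- 0; tmpl <- NULL
  for (e in pfeat$erp) {
    if (!is.null(session_range) &&
        (e$session < session_range[1] || e$session > session_range[2])) next
    cm <- e[[condition]]
    if (is.null(cm)) next
    if (is.null(acc)) {
      acc <- cm$mean * cm$n
      tmpl <- cm$mean
    } else acc <- acc + cm$mean * cm$n
    ntot <- ntot + cm$n
  }
  if (ntot == 0) stop("no '", condition, "' trials in the session range")
  m <- acc / ntot
  structure(m, times_ms = attr(tmpl, "times_ms"), n_trials = ntot,
            condition = condition, rate = attr(tmpl, "rate"),
            class = c("erp_waveform", "matrix", "array"))
}

#' ERP analysis of a processed study
#'
#' Per-participant condition averages, 20-ms block amplitudes and the
#' across-participant target-vs-nontarget significance map, plus the
#' participant-mean Cz peak amplitude (300-500 ms window).
#'
#' @param proc an `oddball_study_features` from [process_study()].
#' @param session_range optional length-2 session window.
#' @param block_ms block width for the significance map.
#' @return List with `map` (a `pvalue_map`; `NULL` with fewer than 3
#'   participants), `grand` (per-condition grand averages), and
#'   `peak_uv` (mean over participants of the target Cz peak
#'   amplitude).
#' @export
erp_analysis <- function(proc, session_range = NULL, block_ms = 20) {
  stopifnot(inherits(proc, "oddball_study_features"))
  tg <- lapply(proc$participants, participant_erp, condition = "target",
               session_range = session_range)
  ng <- lapply(proc$participants, participant_erp, condition = "nontarget",
               session_range = session_range)
  tb <- lapply(tg, block_amplitudes, block_ms = block_ms)
  nb <- lapply(ng, block_amplitudes, block_ms = block_ms)
  map <- if (length(tb) >= 3) significance_map(tb, nb) else NULL
  peaks <- vapply(tg, peak_amplitude, 0)
  list(map = map,
       grand = list(target = grand_average(tg),
                    nontarget = grand_average(ng)),
       peak_uv = mean(peaks), peaks = peaks)
}

#' Run a complete simulated study end to end
#'
#' simulate -> preprocess -> ERP analysis -> nested-CV classification at
#' the requested trial-averaging levels -> aggregated accuracy table
#' with a Friedman test over the averaging levels.
#'
#' @param paradigm a [paradigm_config()].
#' @param sim a [simulation_config()].
#' @param pipe a [pipeline_config()].
#' @param cv a [cv_config()].
#' @param channel_set channel subset for classification.
#' @param ks trial-averaging levels (default 1:5).
#' @param session_range optional session window.
#' @return Object of class `oddball_study_report`: list with `table`
#'   (an [aggregate_table()]), `friedman`, `erp`, `itr` (Wolpaw ITR at
#'   the single-trial mean accuracy), and the configs.
#' @export
run_study <- function(paradigm = paradigm_config(),
                      sim = simulation_config(),
                      pipe = pipeline_config(), cv = cv_config(),
                      channel_set = "all64", ks = 1:5,
                      session_range = NULL) {
  proc <- process_study(paradigm = paradigm, sim = sim, pipe = pipe)
  res <- lapply(ks, function(k)
    run_condition(proc, channel_set, k, session_range, cv))
  names(res) <- paste0("k", ks)
  tab <- aggregate_table(res)
  fri <- if (length(ks) >= 2) friedman_rank_test(tab$body) else NULL
  erp <- erp_analysis(proc, session_range)
  itr <- if ("k1" %in% names(res) && tab$average[["k1"]] >= 0.5)
    wolpaw_itr(tab$average[["k1"]],
               selections_per_minute = 60 / paradigm$trial_period_s)
  else NULL
  structure(list(table = tab, friedman = fri, erp = erp, itr = itr,
                 channel_set = channel_set, ks = ks,
                 session_range = session_range,
                 manifest = list(paradigm = unclass(paradigm),
                                 sim = unclass(sim)[names(sim) != "components"],
                                 components = sim$components,
                                 pipe = unclass(pipe), cv = unclass(cv))),
            class = "oddball_study_report")
}

#' @export
print.oddball_study_report <- function(x, ...) {
  cat("== simulated oddball study ==\n")
  cat("channel set:", x$channel_set, "\n")
  print(x$table)
  if (!is.null(x$friedman))
    cat(sprintf("Friedman over averaging levels: Q = %.2f, p = %.4g (%s)\n",
                x$friedman$statistic, x$friedman$p.value, x$friedman$method))
  cat(sprintf("target Cz peak amplitude (participant mean): %.2f uV\n",
              x$erp$peak_uv))
  if (!is.null(x$itr))
    cat(sprintf("single-trial ITR: %.3f bits/selection, %.2f bits/min\n",
                x$itr$bits_per_selection, x$itr$bits_per_minute))
  invisible(x)
}
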