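#' Nested cross-validation configuration
#'
#' @param outer_folds outer CV folds (default 5, accuracy estimation).
#' @param inner_folds inner CV folds (default 4, cost selection).
#' @param cost_grid candidate soft-margin costs; default the 10 decades
#'   from 1e-6 to 1e3.
#' @param seed RNG seed for fold assignment and trial-averaging shuffles.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 4,
                      cost_grid = 10^seq(-6, 3), seed = 1) {
  if (length(cost_grid) < 1) stop("cost grid must be nonempty")
  if (outer_folds < 2 || inner_folds < 2) stop("folds must be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 cost_grid = sort(cost_grid), seed = as.integer(seed)),
            class = "cv_config")
}

#' Pseudorandom within-class trial averaging
#'
#' Within each class, trials are shuffled (seeded) and partitioned into
#' disjoint groups of `k`; each group's feature rows are averaged into
#' one exemplar carrying the class label. Remainder trials
#' (`count %% k`) are discarded. `k = 1` is the identity up to row
#' order.
#'
#' @param features a [feature_matrix()].
#' @param k trials per averaged exemplar (>= 1).
#' @param seed RNG seed for the shuffle.
#' @return A [feature_matrix()] of averaged exemplars.
#' @export
group_average_trials <- function(features, k = 1, seed = 1) {
  stopifnot(inherits(features, "feature_matrix"), k >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rows <- list(); labs <- character(0)
  for (cls in levels(droplevels(features$labels))) {
    ix <- which(features$labels == cls)
    if (length(ix) < k)
      stop("class '", cls, "' has ", length(ix), " trials; need >= ", k)
    ix <- ix[sample.int(length(ix))]
    ng <- length(ix) %/% k
    for (g in seq_len(ng)) {
      gi <- ix[((g - 1) * k + 1):(g * k)]
      rows[[length(rows) + 1]] <- colMeans(features$x[gi, , drop = FALSE])
      labs <- c(labs, cls)
    }
  }
  x <- do.call(rbind, rows)
  feature_matrix(x, labs,
                 data.frame(participant = rep(features$groups$participant[1],
                                              nrow(x)),
                            session = NA_integer_, trial = NA_integer_),
                 features$channels, features$times_ms)
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls; equals ordinary accuracy when the
#' classes are equally frequent.
#'
#' @param truth true labels (both classes must occur).
#' @param pred predicted labels.
#' @return Value in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- unique(truth)
  if (length(classes) < 2)
    stop("truth contains a single class; balanced accuracy undefined")
  mean(vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), 0))
}

# seeded stratified fold assignment: within each class, shuffled trials
# are dealt round-robin over folds
stratified_folds <- function(labels, k, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    ix <- which(labels == cls)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Nested cross-validated classification accuracy
#'
#' Stratified seeded outer split; within each outer training set, a
#' stratified inner CV scores every cost in the grid by mean inner
#' balanced accuracy; the best cost (ties broken toward the smallest,
#' i.e. strongest regularization) is refit on the full outer training
#' set and scored on the held-out outer fold. The result is the mean of
#' the outer-fold balanced accuracies.
#'
#' @param features a [feature_matrix()] (averaged exemplars or single
#'   trials).
#' @param cv a [cv_config()].
#' @return Object of class `accuracy_result`: list with
#'   `balanced_accuracy`, `fold_accuracy`, `chosen_cost`, `n`,
#'   `participant_id`.
#' @export
nested_cv <- function(features, cv = cv_config()) {
  stopifnot(inherits(features, "feature_matrix"), inherits(cv, "cv_config"))
  x <- features$x
  labels <- droplevels(features$labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (min(table(labels)) < cv$outer_folds)
    stop("need at least outer_folds exemplars per class")
  outer <- stratified_folds(labels, cv$outer_folds, cv$seed)
  # one linear Gram matrix (intercept folded in as +1) serves every
  # cost value and fold; each dual fit is then O(n^2) per sweep
  K <- tcrossprod(x) + 1
  yy <- ifelse(labels == levels(labels)[2], 1, -1)
  fit_alpha <- function(tr, C, seed) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    dcd_gram_svm(K[tr, tr, drop = FALSE], yy[tr], C, 200L, 1e-3)$alpha
  }
  score_on <- function(te, tr, alpha)
    as.numeric(K[te, tr, drop = FALSE] %*% (alpha * yy[tr]))
  acc_of <- function(te, tr, alpha)
    balanced_accuracy(labels[te],
                      factor(levels(labels)[(score_on(te, tr, alpha) > 0) + 1L],
                             levels = levels(labels)))
  fold_acc <- numeric(cv$outer_folds)
  chosen <- numeric(cv$outer_folds)
  for (of in seq_len(cv$outer_folds)) {
    tr <- which(outer != of); te <- which(outer == of)
    if (nlevels(droplevels(labels[te])) < 2 ||
        nlevels(droplevels(labels[tr])) < 2)
      stop("degenerate outer fold: a class is missing")
    inner <- stratified_folds(labels[tr], cv$inner_folds,
                              derive_seed(cv$seed, 11L, of))
    grid_acc <- vapply(cv$cost_grid, function(C) {
      accs <- vapply(seq_len(cv$inner_folds), function(inf) {
        itr <- tr[inner != inf]; ite <- tr[inner == inf]
        if (nlevels(droplevels(labels[ite])) < 2) return(NA_real_)
        alpha <- fit_alpha(itr, C, derive_seed(cv$seed, 13L, of, inf))
        acc_of(ite, itr, alpha)
      }, 0)
      mean(accs, na.rm = TRUE)
    }, 0)
    best <- cv$cost_grid[which.max(grid_acc)]  # ties -> smallest (grid sorted)
    chosen[of] <- best
    alpha <- fit_alpha(tr, best, derive_seed(cv$seed, 17L, of))
    fold_acc[of] <- acc_of(te, tr, alpha)
  }
  structure(list(balanced_accuracy = mean(fold_acc),
                 fold_accuracy = fold_acc, chosen_cost = chosen,
                 n = nrow(x),
                 participant_id = features$groups$participant[1]),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %s: balanced accuracy %.3f (folds: %s)\n",
              x$participant_id, x$balanced_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

# column indices of a channel subset within an all-channel feature matrix
feature_columns <- function(features, channel_set) {
  want <- resolve_channel_set(channel_set)
  miss <- setdiff(want, features$channels)
  if (length(miss))
    stop("channels not in features: ", paste(miss, collapse = ", "))
  ns <- length(features$times_ms)
  unlist(lapply(match(want, features$channels),
                function(ci) (ci - 1L) * ns + seq_len(ns)))
}

subset_features <- function(features, channel_set = NULL, rows = NULL) {
  x <- features$x; labs <- features$labels; grp <- features$groups
  lev <- features$level_db
  chans <- features$channels
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]; labs <- labs[rows]
    grp <- grp[rows, , drop = FALSE]; lev <- lev[rows]
  }
  if (!is.null(channel_set)) {
    cols <- feature_columns(features, channel_set)
    x <- x[, cols, drop = FALSE]
    chans <- resolve_channel_set(channel_set)
  }
  feature_matrix(x, labs, grp, chans, features$times_ms, lev)
}

#' Classification accuracy for one study condition
#'
#' For each participant of a processed study: restrict trials to a
#' session range, restrict features to a channel set, average trials in
#' pseudorandom groups of `k`, and run nested CV.
#'
#' @param proc a processed study from [process_study()].
#' @param channel_set `"all64"`, `"roi47"`, `"cz"` or a label vector.
#' @param k trial-averaging level (1-5 in the standard analysis).
#' @param session_range length-2 vector of first and last session.
#' @param cv a [cv_config()].
#' @return List of `accuracy_result`, one per participant.
#' @export
run_condition <- function(proc, channel_set = "all64", k = 1,
                          session_range = NULL, cv = cv_config()) {
  stopifnot(inherits(proc, "oddball_study_features"))
  lapply(seq_along(proc$participants), function(pi) {
    pf <- proc$participants[[pi]]$features
    rows <- if (is.null(session_range)) seq_len(nrow(pf$x))
    else which(pf$groups$session >= session_range[1] &
                 pf$groups$session <= session_range[2])
    fm <- subset_features(pf, channel_set, rows)
    fm <- group_average_trials(fm, k, seed = derive_seed(cv$seed, 19L, pi, k))
    nested_cv(fm, cv)
  })
}

#' Assemble per-participant accuracies into a participants x k matrix
#'
#' @param results_by_k named list: one element per trial-averaging level
#'   `k`, each a list of `accuracy_result` (as from [run_condition()]).
#' @return Numeric matrix, participants x k levels.
#' @export
accuracy_matrix <- function(results_by_k) {
  cols <- lapply(results_by_k, function(res)
    vapply(res, function(r) r$balanced_accuracy, 0))
  m <- do.call(cbind, cols)
  colnames(m) <- names(results_by_k)
  rownames(m) <- vapply(results_by_k[[1]],
                        function(r) as.character(r$participant_id), "")
  m
}
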