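# Repeated random train/validation/test evaluation with averaged ROC.

#' Split configuration
#'
#' @param ratios (train, validation, test) fractions, positive, summing
#'   to 1 (default `c(0.70, 0.15, 0.15)`).
#' @param n_trials number of repeated trials (default 30).
#' @param stratified stratify splits by class (default TRUE; unstratified
#'   draws that empty a class in the training set are redrawn with a
#'   warning).
#' @param base_seed integer; trial `t` uses seed `base_seed + t`.
#' @return A `split_config` list.
#' @export
split_config <- function(ratios = c(0.70, 0.15, 0.15), n_trials = 30L,
                         stratified = TRUE, base_seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stopf("ratios must be 3 positive fractions summing to 1")
  list(ratios = ratios, n_trials = as.integer(n_trials),
       stratified = isTRUE(stratified), base_seed = as.integer(base_seed))
}

# validation/test sizes take the floors of their exact allocations (at
# least 1 each so every trial can validate and test); the training set
# absorbs the remainder (69 -> 49/10/10 at 70/15/15).
split_sizes <- function(n, ratios) {
  nv <- max(1L, floor(n * ratios[2]))
  nt <- max(1L, floor(n * ratios[3]))
  if (n - nv - nt < 1L) stopf("too few subjects (%d) for a split", n)
  c(train = n - nv - nt, val = nv, test = nt)
}

#' Random train/validation/test partition for one trial
#'
#' Disjoint exhaustive partition of `1..n`, stratified by class by default,
#' deterministic given `(config, trial)`.
#'
#' @param n subject count (`>= 10`).
#' @param labels 0/1 labels, both classes present.
#' @param config a [split_config()].
#' @param trial trial index (1-based).
#' @return List of index vectors `train`, `val`, `test`.
#' @export
random_split <- function(n, labels, config = split_config(), trial = 1L) {
  if (n < 10) stopf("need at least 10 subjects")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  seed <- config$base_seed + as.integer(trial)
  if (config$stratified) {
    with_seed(seed, {
      parts <- list(train = integer(), val = integer(), test = integer())
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        sz <- split_sizes(length(idx), config$ratios)
        parts$train <- c(parts$train, idx[seq_len(sz[1])])
        parts$val <- c(parts$val, idx[sz[1] + seq_len(sz[2])])
        parts$test <- c(parts$test, idx[sz[1] + sz[2] + seq_len(sz[3])])
      }
      lapply(parts, sort)
    })
  } else {
    sz <- split_sizes(n, config$ratios)
    attempt <- 0L
    repeat {
      parts <- with_seed(derive_seed(seed, attempt), {
        idx <- sample(n)
        list(train = sort(idx[seq_len(sz[1])]),
             val = sort(idx[sz[1] + seq_len(sz[2])]),
             test = sort(idx[sz[1] + sz[2] + seq_len(sz[3])]))
      })
      if (length(unique(labels[parts$train])) == 2) return(parts)
      attempt <- attempt + 1L
      warning("unstratified split emptied a class in training; redrawn")
    }
  }
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (higher score = more positive)
#' and integrates by the trapezoidal rule; with tied scores this equals the
#' rank-sum concordance statistic with ties counted 1/2.
#'
#' @param scores real-valued decision scores.
#' @param labels 0/1 labels, both classes present.
#' @return List with `fpr`, `tpr` (curve points from (0,0) to (1,1)) and
#'   `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stopf("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))            # tie groups of equal score
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Vertically average ROC curves onto a common FPR grid
#'
#' Each trial's TPR is step-interpolated (staircase, last value carried
#' forward) onto `seq(0, 1, grid_step)` and averaged pointwise.
#'
#' @param trials list of `roc_and_auc()` results.
#' @param grid_step FPR grid spacing (default 0.01).
#' @return List with `fpr` (the grid) and `tpr` (averaged).
#' @export
average_roc <- function(trials, grid_step = 0.01) {
  if (!length(trials)) stopf("need at least one trial curve")
  grid <- seq(0, 1, by = grid_step)
  mat <- vapply(trials, function(tr) {
    stats::approx(tr$fpr, tr$tpr, xout = grid, method = "constant",
                  f = 0, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  list(fpr = grid, tpr = rowMeans(mat))
}

#' Summarize repeated-trial ROC performance
#'
#' Mean trial AUC with a 95 percent percentile interval over trials, the
#' operating point maximizing Youden's J (TPR - FPR) on the averaged curve
#' (the upper-left reading), and the confusion matrix aggregated over all
#' test predictions at the `f > 0` decision.
#'
#' @param trial_aucs numeric vector of per-trial AUCs (`>= 2`).
#' @param avg_curve an [average_roc()] result.
#' @param confusion optional aggregated 2x2 confusion matrix
#'   (rows = truth positive/negative, columns = predicted).
#' @return An object of class `roc_summary`.
#' @export
summarize_trials <- function(trial_aucs, avg_curve, confusion = NULL) {
  if (length(trial_aucs) < 2) stopf("need >= 2 trials for an interval")
  ci <- unname(stats::quantile(trial_aucs, c(0.025, 0.975), type = 7))
  j <- avg_curve$tpr - avg_curve$fpr
  op <- which.max(j)
  # AUC of the averaged curve itself, by trapezoid on the grid
  mauc <- sum(diff(avg_curve$fpr) *
                (utils::head(avg_curve$tpr, -1) +
                   utils::tail(avg_curve$tpr, -1)) / 2)
  structure(list(fpr_grid = avg_curve$fpr, mean_tpr = avg_curve$tpr,
                 trial_aucs = trial_aucs,
                 auc_mean = mean(trial_aucs), auc_ci = ci,
                 mean_curve_auc = mauc,
                 sensitivity = avg_curve$tpr[op],
                 specificity = 1 - avg_curve$fpr[op],
                 confusion = confusion),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> %d trials: AUC %.3f (95%% CI [%.3f, %.3f])\n",
              length(x$trial_aucs), x$auc_mean, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  operating point: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  if (!is.null(x$confusion)) {
    cat("  aggregated test confusion (rows = truth):\n")
    print(x$confusion)
  }
  invisible(x)
}

default_pipeline_config <- function() {
  list(ng_list = c(16, 32, 64, 96), kernel = "haar",
       include_clinical = TRUE, prune_threshold = 0.85,
       k = 20L, bins = 4L, scheme = "backward",
       ratios = c(0.70, 0.15, 0.15), n_trials = 30L, stratified = TRUE,
       base_seed = 1L, hidden = c(10L, 7L, 5L), goal = 1e-3,
       max_epochs = 1000L, max_val_fail = 6L,
       selection_inside_trial = FALSE)
}

#' Run the full classification pipeline
#'
#' End-to-end orchestration: feature extraction (when given a subject
#' cohort), max-normalization, correlation pruning, mRMR reduction to `k`
#' features, then `n_trials` repeated trials of {random 70/15/15 split,
#' Levenberg-Marquardt training with validation early stopping, scoring of
#' the test subset}, summarized by the averaged ROC. By default feature
#' selection is performed once on the full table before the trials
#' (mirroring a selection-before-split workflow, which leaks test
#' information into the choice of features and optimistically biases test
#' AUC); set `selection_inside_trial = TRUE` to re-run pruning and mRMR on
#' each trial's training subset only, giving an unbiased test evaluation.
#'
#' @param x a subject cohort (list from [generate_cohort()]) or an
#'   assembled [feature_table()].
#' @param config named list overriding the defaults: `ng_list`, `kernel`,
#'   `include_clinical`, `prune_threshold`, `k`, `bins`, `scheme`,
#'   `ratios`, `n_trials`, `stratified`, `base_seed`, `hidden`, `goal`,
#'   `max_epochs`, `max_val_fail`, `selection_inside_trial`.
#' @param progress print per-stage progress messages?
#' @return An object of class `rtn_run`: the `roc_summary`, the selection
#'   result(s), per-trial AUC table and the resolved configuration.
#' @export
run_pipeline <- function(x, config = list(), progress = FALSE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  table <- if (inherits(x, "feature_table")) x
           else assemble_feature_table(x, ng_list = cfg$ng_list,
                                       kernel = cfg$kernel,
                                       include_clinical = cfg$include_clinical,
                                       progress = progress)
  labels <- attr(table, "labels")
  norm <- normalize_table(table)
  sc <- split_config(cfg$ratios, cfg$n_trials, cfg$stratified, cfg$base_seed)

  selection <- NULL
  if (!cfg$selection_inside_trial) {
    pruned <- prune_correlated(norm, cfg$prune_threshold)
    selection <- mrmr_rank(pruned, k = cfg$k, bins = cfg$bins,
                           scheme = cfg$scheme)
  }
  curves <- vector("list", cfg$n_trials)
  aucs <- numeric(cfg$n_trials)
  conf <- matrix(0L, 2, 2,
                 dimnames = list(truth = c("pos", "neg"),
                                 predicted = c("pos", "neg")))
  trial_selected <- vector("list", cfg$n_trials)
  for (t in seq_len(cfg$n_trials)) {
    if (progress) message(sprintf("trial %d/%d", t, cfg$n_trials))
    sp <- random_split(nrow(norm), labels, sc, t)
    if (cfg$selection_inside_trial) {
      sub <- norm[sp$train, , drop = FALSE]
      pruned_t <- prune_correlated(sub, cfg$prune_threshold)
      sel_t <- mrmr_rank(pruned_t, k = cfg$k, bins = cfg$bins,
                         scheme = cfg$scheme)
      feats <- sel_t$selected
      trial_selected[[t]] <- feats
    } else {
      feats <- selection$selected
    }
    X <- as.matrix(norm[, feats, drop = FALSE])
    net <- train_mlp(X[sp$train, , drop = FALSE], labels[sp$train],
                     validation = list(x = X[sp$val, , drop = FALSE],
                                       y = labels[sp$val]),
                     seed = derive_seed(cfg$base_seed, 500L + t),
                     hidden = cfg$hidden, goal = cfg$goal,
                     max_epochs = cfg$max_epochs,
                     max_val_fail = cfg$max_val_fail)
    sctest <- score_and_classify(net, X[sp$test, , drop = FALSE])
    curves[[t]] <- roc_and_auc(sctest$score, labels[sp$test])
    aucs[t] <- curves[[t]]$auc
    truth <- labels[sp$test]
    conf[1, 1] <- conf[1, 1] + sum(truth == 1 & sctest$label == 1)
    conf[1, 2] <- conf[1, 2] + sum(truth == 1 & sctest$label == 0)
    conf[2, 1] <- conf[2, 1] + sum(truth == 0 & sctest$label == 1)
    conf[2, 2] <- conf[2, 2] + sum(truth == 0 & sctest$label == 0)
  }
  avg <- average_roc(curves)
  summ <- summarize_trials(aucs, avg, conf)
  structure(list(summary = summ, selection = selection,
                 trial_selected = if (cfg$selection_inside_trial)
                   trial_selected else NULL,
                 trials = data.frame(trial = seq_len(cfg$n_trials),
                                     auc = aucs),
                 config = cfg, n_subjects = nrow(norm)),
            class = "rtn_run")
}

#' @export
print.rtn_run <- function(x, ...) {
  cat(sprintf("<rtn_run> %d subjects, %d trials (%s selection)\n",
              x$n_subjects, nrow(x$trials),
              if (x$config$selection_inside_trial) "per-trial" else "full-table"))
  print(x$summary)
  invisible(x)
}

#' @export
summary.rtn_run <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) print(object$selection)
  invisible(object)
}

#' @export
plot.rtn_run <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$fpr_grid, s$mean_tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Averaged ROC over %d trials (AUC %.2f)",
                                length(s$trial_aucs), s$auc_mean), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Permute the class labels of a feature table
#'
#' Utility for null-behaviour checks: returns the same table with labels
#' randomly permuted under the given seed.
#'
#' @param table a [feature_table()].
#' @param seed permutation seed.
#' @return The permuted `feature_table`.
#' @export
permute_labels <- function(table, seed = 1L) {
  lb <- attr(table, "labels")
  attr(table, "labels") <- with_seed(seed, sample(lb))
  table
}

#' Persist a pipeline run
#'
#' Writes `summary.json` (AUC mean/CI, operating point, confusion),
#' `trials.csv` (per-trial AUCs), `roc_mean.csv` (averaged curve) and
#' `selection.json` into `dir`.
#'
#' @param run an [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- run$summary
  jsonlite::write_json(
    list(auc_mean = s$auc_mean, auc_ci = s$auc_ci,
         sensitivity = s$sensitivity, specificity = s$specificity,
         trial_aucs = s$trial_aucs,
         confusion = as.vector(s$confusion),
         config = run$config[c("ng_list", "kernel", "include_clinical",
                               "prune_threshold", "k", "n_trials",
                               "base_seed", "selection_inside_trial")]),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(fpr = s$fpr_grid, tpr = s$mean_tpr),
                   file.path(dir, "roc_mean.csv"), row.names = FALSE)
  if (!is.null(run$selection))
    jsonlite::write_json(
      list(selected = run$selection$selected,
           relevance = unname(run$selection$relevance),
           dropped_pairs = run$selection$dropped_pairs),
      file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
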