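# independent AUC oracle: pair counting with ties at 1/2
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

test_that("split sizes reproduce the 69 -> 49/10/10 allocation", {
  labels <- c(rep(1, 35), rep(0, 34))
  cfg <- split_config(base_seed = 3)
  sp <- random_split(69, labels, cfg, trial = 1)
  expect_equal(lengths(sp), c(train = 49L, val = 10L, test = 10L))
  expect_setequal(c(sp$train, sp$val, sp$test), 1:69)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  # stratification keeps both classes in every subset
  for (part in sp) expect_equal(sort(unique(labels[part])), c(0, 1))
  # determinism per (config, trial)
  expect_identical(sp, random_split(69, labels, cfg, trial = 1))
  expect_false(identical(sp, random_split(69, labels, cfg, trial = 2)))
})

test_that("unstratified splits partition exhaustively", {
  labels <- rep(c(0, 1), 10)
  cfg <- split_config(stratified = FALSE, base_seed = 4)
  sp <- random_split(20, labels, cfg, trial = 1)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:20)
  expect_equal(lengths(sp), c(train = 14L, val = 3L, test = 3L))
})

test_that("trapezoid AUC equals rank-sum concordance, ties included", {
  expect_equal(roc_and_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_and_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  r <- roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, auc_concordance(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(r$auc, 0.75)
  for (s in 1:40) {
    set.seed(s)
    n <- sample(6:25, 1)
    labels <- c(0, 1, sample(c(0, 1), n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.1), n, TRUE)   # heavy ties
    expect_equal(roc_and_auc(scores, labels)$auc,
                 auc_concordance(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_and_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC flips under label exchange and ignores monotone transforms", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(8:20, 1)
    labels <- c(0, 1, sample(c(0, 1), n - 2, TRUE))
    scores <- rnorm(n)
    a <- roc_and_auc(scores, labels)$auc
    expect_equal(a + roc_and_auc(scores, 1 - labels)$auc, 1,
                 tolerance = 1e-12)
    expect_equal(roc_and_auc(exp(3 * scores) + 2, labels)$auc, a,
                 tolerance = 1e-12)
  }
})

test_that("vertical ROC averaging interpolates and preserves single curves", {
  r <- roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  avg1 <- average_roc(list(r))
  # at every grid point the averaged curve equals the staircase value
  expect_equal(avg1$tpr[avg1$fpr == 0], 0.5)    # TPR after one threshold
  expect_equal(avg1$tpr[avg1$fpr == 1], 1)
  expect_equal(average_roc(list(r, r))$tpr, avg1$tpr)
  # averaging a perfect and a chance curve lands strictly between
  perfect <- roc_and_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  chance <- roc_and_auc(rep(1, 4), c(0, 0, 1, 1))
  avg <- average_roc(list(perfect, chance))
  trap <- sum(diff(avg$fpr) * (head(avg$tpr, -1) + tail(avg$tpr, -1)) / 2)
  expect_gt(trap, 0.5)
  expect_lt(trap, 1)
})

test_that("trial summaries compute percentile CIs and the Youden point", {
  perfect <- roc_and_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  s <- summarize_trials(rep(1, 5), average_roc(list(perfect)))
  expect_equal(s$auc_ci, c(1, 1))
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  aucs <- seq(0.6, 0.99, length.out = 30)
  s2 <- summarize_trials(aucs, average_roc(list(perfect)))
  expect_equal(s2$auc_ci,
               unname(quantile(aucs, c(0.025, 0.975), type = 7)))
  expect_equal(s2$auc_mean, mean(aucs))
})

test_that("the end-to-end pipeline is deterministic and conserves predictions", {
  coh <- tiny_cohort(6, 6, grid = c(12, 12, 12), seed = 20)
  cfg <- list(ng_list = 8, n_trials = 5, base_seed = 77)
  run1 <- run_pipeline(coh, cfg)
  run2 <- run_pipeline(coh, cfg)
  expect_identical(run1$summary$trial_aucs, run2$summary$trial_aucs)
  expect_identical(run1$summary$mean_tpr, run2$summary$mean_tpr)
  expect_identical(run1$selection$selected, run2$selection$selected)
  # confusion totals = test-set size x trials
  n_test <- sum(radiotexnet:::split_sizes(6, c(0.7, 0.15, 0.15))["test"] * 2)
  expect_equal(sum(run1$summary$confusion), n_test * 5)
  expect_length(run1$selection$selected, 20)
})

test_that("clinical covariates can be toggled and both runs complete", {
  coh <- tiny_cohort(6, 6, grid = c(12, 12, 12), seed = 22)
  with_c <- run_pipeline(coh, list(ng_list = 8, n_trials = 3, base_seed = 5,
                                   include_clinical = TRUE))
  without_c <- run_pipeline(coh, list(ng_list = 8, n_trials = 3, base_seed = 5,
                                      include_clinical = FALSE))
  expect_false(any(grepl("Clinic", without_c$selection$selected)))
  expect_s3_class(with_c$summary, "roc_summary")
  expect_s3_class(without_c$summary, "roc_summary")
})

test_that("per-trial selection mode re-selects inside each trial", {
  coh <- tiny_cohort(6, 6, grid = c(12, 12, 12), seed = 23)
  run <- run_pipeline(coh, list(ng_list = 8, n_trials = 3, base_seed = 6,
                                selection_inside_trial = TRUE, k = 10))
  expect_null(run$selection)
  expect_length(run$trial_selected, 3)
  expect_true(all(lengths(run$trial_selected) == 10))
})

test_that("widening the class texture gap does not lower the mean AUC", {
  mk_run <- function(gap) {
    pos <- class_spec(mean_hu = 30, sd_hu = 25, corr_len = 1.2 + gap,
                      mask_radii = c(4, 4, 4), smoking_prob = 0.5)
    neg <- class_spec(mean_hu = 30, sd_hu = 25, corr_len = 1.2,
                      mask_radii = c(4, 4, 4), smoking_prob = 0.5)
    coh <- generate_cohort(10, 10, pos, neg, grid = c(14, 14, 14), seed = 31)
    run_pipeline(coh, list(ng_list = 8, n_trials = 8, base_seed = 44,
                           ratios = c(0.6, 0.2, 0.2),
                           include_clinical = FALSE))
    }
  aucs <- vapply(c(0, 1.5, 3), function(g) mk_run(g)$summary$auc_mean, 0)
  expect_lte(aucs[1], aucs[2] + 0.1)
  expect_lte(aucs[2], aucs[3] + 0.1)
})

test_that("run artifacts persist as JSON and CSV", {
  coh <- tiny_cohort(5, 5, grid = c(12, 12, 12), seed = 24)
  run <- run_pipeline(coh, list(ng_list = 8, n_trials = 3, base_seed = 9))
  dir <- tempfile()
  write_run(run, dir)
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  expect_equal(s$auc_mean, run$summary$auc_mean)
  expect_equal(nrow(utils::read.csv(file.path(dir, "trials.csv"))), 3)
  sel <- jsonlite::read_json(file.path(dir, "selection.json"),
                             simplifyVector = TRUE)
  expect_equal(sel$selected, run$selection$selected)
})
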