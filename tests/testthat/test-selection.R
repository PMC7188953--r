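mk_table <- function(X, labels) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  feature_table(X, labels)
}

test_that("max-normalization scales by the absolute maximum and is idempotent", {
  tab <- mk_table(cbind(c(2, 4), c(-3, 1), c(0, 0)), c(0, 1))
  norm <- normalize_table(tab)
  expect_equal(norm$f1, c(0.5, 1))
  expect_equal(norm$f2, c(-1, 1 / 3))
  expect_equal(norm$f3, c(0, 0))
  expect_equal(attr(norm, "zero_columns"), "f3")
  expect_equal(as.matrix(normalize_table(norm)), as.matrix(norm))
})

test_that("Pearson relevance matches the closed form and guards constants", {
  y <- c(0, 0, 1, 1)
  expect_equal(pearson_relevance(y, y), 1)
  expect_equal(pearson_relevance(1 - y, y), -1)
  expect_equal(pearson_relevance(rep(3, 4), y), 0)
  x <- c(0.1, 0.4, 0.35, 0.8)
  # closed-form: sum(dx dy) / sqrt(sum dx^2 sum dy^2)
  dx <- x - mean(x); dy <- y - mean(y)
  expect_equal(pearson_relevance(x, y), sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)))
  expect_equal(pearson_relevance(x, y), 0.6475761, tolerance = 1e-6)
})

test_that("equal-frequency discretization bins at quantiles", {
  expect_equal(discretize_equal_frequency(c(1, 2, 3, 4), 2), c(1L, 1L, 2L, 2L))
  expect_equal(length(unique(discretize_equal_frequency(rep(5, 10), 4))), 1L)
  set.seed(51)
  u <- runif(1000)
  lab <- discretize_equal_frequency(u, 4)
  expect_true(all(abs(tabulate(lab, 4) - 250) <= 1))
  expect_error(discretize_equal_frequency(u, 1), "bins")
})

test_that("plug-in mutual information matches hand computation", {
  y <- rep(c(0, 1), 50)
  expect_equal(mutual_information(rep(1, 100), y), 0)
  expect_equal(mutual_information(y, y), 1)            # MI = entropy = 1 bit
  # joint counts {(0,0):4, (0,1):1, (1,0):1, (1,1):4}
  x <- c(rep(0, 5), rep(1, 5))
  z <- c(rep(0, 4), 1, 0, rep(1, 4))
  hand <- 2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25)
  expect_equal(mutual_information(x, z), hand)
  expect_equal(mutual_information(z, x), hand)          # symmetry
  expect_equal(mutual_information(x, z), 0.2780719, tolerance = 1e-6)
})

test_that("correlation pruning keeps exactly one of each collinear group", {
  set.seed(52)
  base <- rnorm(30)
  y <- rep(c(0, 1), 15)
  X <- cbind(base, base, rnorm(30), base * 2 + 1e-9 * rnorm(30))
  tab <- mk_table(X, y)
  pruned <- prune_correlated(tab, 0.85)
  # f1, f2, f4 are mutually collinear -> one survivor, f3 untouched
  expect_equal(ncol(pruned), 2)
  expect_true("f3" %in% colnames(pruned))
  log <- attr(pruned, "dropped_pairs")
  expect_equal(nrow(log), 2)
  # moderate correlation is untouched
  X2 <- cbind(c(1, 2, 3, 4, 6, 5), c(1, 2, 4, 3, 5, 6))
  tab2 <- mk_table(X2, c(0, 0, 0, 1, 1, 1))
  expect_lt(abs(cor(X2)[1, 2]), 0.95)
  pr2 <- prune_correlated(tab2, 0.95)
  expect_equal(ncol(pr2), 2)
})

test_that("mRMR excludes the redundant duplicate and keeps the complement", {
  set.seed(53)
  y <- rep(c(0L, 1L), 20)
  f1 <- as.numeric(y)
  f2 <- f1
  f3 <- rnorm(40)
  tab <- mk_table(cbind(f1, f2, f3), y)
  sel <- mrmr_rank(tab, k = 2)
  expect_setequal(sel$selected, c("f1", "f3"))
  # exhaustive set-objective check: {f1,f3} must beat {f1,f2}
  D <- radiotexnet:::discretize_table(tab, 4)
  obj <- function(S) {
    rel <- mean(vapply(S, function(f) mutual_information(D[, f], y), 0))
    prs <- utils::combn(S, 2)
    red <- mean(vapply(seq_len(ncol(prs)), function(k)
      mutual_information(D[, prs[1, k]], D[, prs[2, k]]), 0))
    rel - red
  }
  expect_gt(obj(c("f1", "f3")), obj(c("f1", "f2")))
})

test_that("mRMR edge cases: identity selection and zero redundancy weight", {
  set.seed(54)
  y <- rep(c(0L, 1L), 15)
  X <- matrix(rnorm(30 * 5), 30)
  X[, 1] <- X[, 1] + y          # strongest
  X[, 2] <- X[, 2] + 0.5 * y
  tab <- mk_table(X, y)
  sel_all <- mrmr_rank(tab, k = 5)
  expect_setequal(sel_all$selected, paste0("f", 1:5))
  # redundancy weight 0 -> pure MI-relevance top-k
  sel0 <- mrmr_rank(tab, k = 3, redundancy_weight = 0)
  D <- radiotexnet:::discretize_table(tab, 4)
  rel <- vapply(seq_len(5), function(jj) mutual_information(D[, jj], y), 0)
  topk <- paste0("f", order(-rel)[1:3])
  expect_setequal(sel0$selected, topk)
  # selection is deterministic
  expect_identical(mrmr_rank(tab, k = 3), mrmr_rank(tab, k = 3))
  expect_warning(mrmr_rank(tab, k = 9), "exceeds")
})

test_that("forward-selection variant runs and respects k", {
  set.seed(55)
  y <- rep(c(0L, 1L), 15)
  X <- matrix(rnorm(30 * 6), 30)
  X[, 1] <- y + 0.1 * rnorm(30)
  tab <- mk_table(X, y)
  sel <- mrmr_rank(tab, k = 3, scheme = "forward")
  expect_length(sel$selected, 3)
  expect_true("f1" %in% sel$selected)
})

test_that("the MI map is symmetric with entropies on the diagonal", {
  set.seed(56)
  X <- cbind(rnorm(2000), rnorm(2000), rnorm(2000))
  X <- cbind(X, X[, 1])
  tab <- mk_table(X, rep(c(0, 1), 1000))
  M <- mi_map(tab, bins = 4)
  expect_equal(dim(M), c(4, 4))
  expect_equal(M, t(M))
  expect_true(all(M >= 0))
  expect_equal(M[1, 4], M[1, 1])        # duplicate column: MI = entropy
  expect_equal(M[1, 1], 2, tolerance = 1e-6)   # 4 equal bins -> 2 bits
  # independent columns: small plug-in bias only
  expect_lt(M[1, 2], 0.05)
  expect_lt(M[2, 3], 0.05)
})

test_that("the combined selection pipeline finds planted signal", {
  set.seed(57)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * 30), n)
  X[, 3] <- y * 2 + 0.3 * rnorm(n)
  X[, 7] <- X[, 3] + 1e-6 * rnorm(n)    # collinear copy must be pruned
  tab <- mk_table(X, y)
  sel <- select_features(tab, k = 5)
  expect_length(sel$selected, 5)
  expect_true(xor("f3" %in% sel$selected, "f7" %in% sel$selected))
  expect_gte(max(abs(sel$relevance)), 0.5)
  # report ordering is by descending |relevance|
  expect_true(all(diff(abs(sel$relevance)) <= 1e-12))
})
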