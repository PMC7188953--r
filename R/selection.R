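# Feature selection: max-normalization, Pearson relevance, correlation
# pruning, discretized mutual information, and mRMR reduction.

#' Max-normalize a feature table
#'
#' Divides every column by its maximum absolute entry so columns lie in
#' `[-1, 1]` with max |value| = 1. All-zero columns are left untouched and
#' recorded in the `zero_columns` attribute. Idempotent.
#'
#' @param table a [feature_table()].
#' @return The normalized `feature_table`.
#' @export
normalize_table <- function(table) {
  mx <- vapply(table, function(col) max(abs(col)), 0)
  zero <- mx == 0
  out <- table
  for (jj in which(!zero)) out[[jj]] <- out[[jj]] / mx[jj]
  attr(out, "zero_columns") <- colnames(table)[zero]
  out
}

#' Pearson relevance of a feature against the class target
#'
#' Pearson correlation between a feature column and the 0/1 target vector;
#' a constant column returns 0 rather than NA.
#'
#' @param column numeric feature values.
#' @param target 0/1 labels (both classes present).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_relevance <- function(column, target) {
  if (stats::sd(column) == 0 || stats::sd(target) == 0) return(0)
  stats::cor(column, target)
}

#' Equal-frequency discretization
#'
#' Bins a column at its `k/bins` quantiles. A value exactly on an interior
#' cut point goes to the higher bin; duplicated cut points (heavily tied
#' data) collapse, so at most `bins` distinct labels are produced and a
#' constant column yields a single label.
#'
#' @param column numeric values.
#' @param bins bin count, `>= 2`.
#' @return Integer bin labels in `1..bins`.
#' @export
discretize_equal_frequency <- function(column, bins = 4L) {
  if (bins < 2) stopf("bins must be >= 2")
  br <- unique(stats::quantile(column, probs = seq_len(bins - 1) / bins,
                               type = 7, names = FALSE))
  findInterval(column, br) + 1L
}

#' Plug-in mutual information between two discrete vectors
#'
#' `sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` over the empirical joint
#' distribution, in bits. Symmetric and non-negative; `MI(x, x)` equals the
#' empirical entropy of `x`.
#'
#' @param x,y equal-length discrete label vectors.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  xf <- as.integer(factor(x)); yf <- as.integer(factor(y))
  nx <- max(xf); ny <- max(yf)
  joint <- tabulate(xf + (yf - 1L) * nx, nx * ny) / length(x)
  px <- rowSums(matrix(joint, nx, ny))
  py <- colSums(matrix(joint, nx, ny))
  J <- matrix(joint, nx, ny)
  pos <- J > 0
  sum(J[pos] * log2(J[pos] / outer(px, py)[pos]))
}

# column-discretized matrix for MI computations
discretize_table <- function(table, bins) {
  vapply(table, discretize_equal_frequency, integer(nrow(table)),
         bins = bins)
}

# pairwise MI over the columns of a discretized matrix (bits)
mi_matrix <- function(D) {
  m <- ncol(D)
  M <- matrix(0, m, m, dimnames = list(colnames(D), colnames(D)))
  for (a in seq_len(m)) {
    M[a, a] <- mutual_information(D[, a], D[, a])
    if (a < m) for (b in (a + 1):m) {
      M[a, b] <- M[b, a] <- mutual_information(D[, a], D[, b])
    }
  }
  M
}

#' Pairwise mutual-information map of a feature table
#'
#' Symmetric matrix of plug-in MI (bits) over equal-frequency-discretized
#' columns, with per-feature entropies on the diagonal.
#'
#' @param table a [feature_table()].
#' @param bins discretization bin count.
#' @return A symmetric named matrix.
#' @export
mi_map <- function(table, bins = 4L) {
  mi_matrix(discretize_table(table, bins))
}

#' Prune highly correlated feature pairs
#'
#' Scans feature pairs with `|Pearson| > threshold` in descending |corr|
#' order; from each pair still intact, the member with lower |relevance| is
#' dropped (ties: the later column). Transitively collinear groups collapse
#' to a single survivor, and no surviving pair exceeds the threshold.
#'
#' @param table a [feature_table()].
#' @param threshold correlation threshold in `(0, 1]` (default 0.85).
#' @param relevance per-column relevance; defaults to [pearson_relevance()]
#'   against the table's labels.
#' @return The pruned `feature_table`, with a `dropped_pairs` attribute
#'   logging (dropped, kept, corr) rows.
#' @export
prune_correlated <- function(table, threshold = 0.85, relevance = NULL) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0,1]")
  lb <- attr(table, "labels")
  if (is.null(relevance))
    relevance <- vapply(table, pearson_relevance, 0, target = lb)
  C <- suppressWarnings(stats::cor(as.matrix(table)))
  C[!is.finite(C)] <- 0
  m <- ncol(table)
  iu <- which(upper.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  log <- data.frame(dropped = character(), kept = character(),
                    corr = numeric())
  alive <- rep(TRUE, m)
  if (nrow(iu)) {
    ord <- order(-abs(C[iu]))
    iu <- iu[ord, , drop = FALSE]
    for (r in seq_len(nrow(iu))) {
      a <- iu[r, 1]; b <- iu[r, 2]
      if (!alive[a] || !alive[b]) next
      drop <- if (abs(relevance[a]) < abs(relevance[b])) a
              else if (abs(relevance[a]) > abs(relevance[b])) b
              else max(a, b)
      keep <- if (drop == a) b else a
      alive[drop] <- FALSE
      log <- rbind(log, data.frame(dropped = colnames(table)[drop],
                                   kept = colnames(table)[keep],
                                   corr = C[a, b]))
    }
  }
  out <- table[, alive, drop = FALSE]
  attr(out, "dropped_pairs") <- log
  out
}

#' mRMR feature ranking by backward deselection
#'
#' Iteratively deselects features until `k` remain, at each step removing
#' the feature whose removal maximizes the mRMR objective of the remaining
#' set: mean MI-relevance with the target minus mean pairwise MI redundancy
#' (difference scheme). Ties drop the feature with lower |Pearson
#' relevance|, then the later column. The final list is ordered by
#' descending |Pearson relevance| for reporting. A forward-selection variant
#' (`scheme = "forward"`) greedily adds the feature maximizing
#' `I(f; target) - mean I(f; selected)`.
#'
#' @param table a pruned, normalized [feature_table()].
#' @param target 0/1 labels; defaults to the table's `labels` attribute.
#' @param k number of features to keep (default 20).
#' @param bins MI discretization bins.
#' @param scheme `"backward"` (default) or `"forward"`.
#' @param redundancy_weight scales the redundancy term; 0 reduces the
#'   ranking to pure MI-relevance top-k.
#' @return An object of class `selection_result`: list with `selected`,
#'   `relevance` (Pearson), `mi_relevance` (bits), `scheme` and
#'   `dropped_pairs` (carried from pruning when present).
#' @export
mrmr_rank <- function(table, target = NULL, k = 20L, bins = 4L,
                      scheme = c("backward", "forward"),
                      redundancy_weight = 1) {
  scheme <- match.arg(scheme)
  target <- target %||% attr(table, "labels")
  m <- ncol(table)
  pear <- vapply(table, pearson_relevance, 0, target = target)
  if (k >= m) {
    if (k > m) warning("k exceeds available features; returning all")
    sel <- order(-abs(pear))
    return(selection_result(colnames(table)[sel], pear[sel],
                            mi_rel = NULL, scheme = scheme, table = table))
  }
  D <- discretize_table(table, bins)
  rel <- vapply(seq_len(m), function(jj) mutual_information(D[, jj], target), 0)
  M <- mi_matrix(D)
  diag(M) <- 0
  w <- redundancy_weight
  if (scheme == "backward") {
    alive <- rep(TRUE, m)
    rowsum_alive <- rowSums(M)
    rel_sum <- sum(rel)
    pair_sum <- sum(M[upper.tri(M)])
    n_alive <- m
    while (n_alive > k) {
      cand <- which(alive)
      m2 <- n_alive - 1
      rel_part <- (rel_sum - rel[cand]) / m2
      red_part <- if (m2 >= 2)
        (pair_sum - rowsum_alive[cand]) / (m2 * (m2 - 1) / 2) else 0
      obj <- rel_part - w * red_part
      best <- max(obj)
      tied <- cand[obj >= best - 1e-12]
      drop <- tied[order(abs(pear[tied]), -tied)][1]
      alive[drop] <- FALSE
      rel_sum <- rel_sum - rel[drop]
      pair_sum <- pair_sum - rowsum_alive[drop]
      rowsum_alive[alive] <- rowsum_alive[alive] - M[alive, drop]
      n_alive <- n_alive - 1
    }
    sel <- which(alive)
  } else {
    sel <- integer(0)
    remaining <- seq_len(m)
    first <- remaining[order(-rel, seq_len(m))][1]
    sel <- first; remaining <- setdiff(remaining, first)
    while (length(sel) < k) {
      score <- rel[remaining] -
        w * rowMeans(M[remaining, sel, drop = FALSE])
      best <- max(score)
      tied <- remaining[score >= best - 1e-12]
      add <- tied[order(-abs(pear[tied]), tied)][1]
      sel <- c(sel, add)
      remaining <- setdiff(remaining, add)
    }
  }
  ord <- sel[order(-abs(pear[sel]))]
  selection_result(colnames(table)[ord], pear[ord], rel[ord],
                   scheme = scheme, table = table)
}

selection_result <- function(selected, relevance, mi_rel, scheme, table) {
  structure(list(selected = selected,
                 relevance = stats::setNames(relevance, selected),
                 mi_relevance = if (!is.null(mi_rel))
                   stats::setNames(mi_rel, selected) else NULL,
                 scheme = scheme,
                 dropped_pairs = attr(table, "dropped_pairs")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features (%s mRMR), |corr| range [%.2f, %.2f]\n",
              length(x$selected), x$scheme,
              min(abs(x$relevance)), max(abs(x$relevance))))
  for (i in seq_along(x$selected))
    cat(sprintf("  %2d. %-32s corr=% .3f\n", i, x$selected[i],
                x$relevance[i]))
  invisible(x)
}

#' Normalize, prune and rank in one call
#'
#' The full filter-selection pipeline: max-normalization, |corr| > threshold
#' pruning, then mRMR reduction to `k` features.
#'
#' @param table a [feature_table()].
#' @param k,bins,scheme passed to [mrmr_rank()].
#' @param threshold passed to [prune_correlated()].
#' @return A `selection_result`.
#' @export
select_features <- function(table, k = 20L, threshold = 0.85, bins = 4L,
                            scheme = "backward") {
  norm <- normalize_table(table)
  pruned <- prune_correlated(norm, threshold)
  mrmr_rank(pruned, k = k, bins = bins, scheme = scheme)
}
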