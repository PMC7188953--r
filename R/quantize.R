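#' Quantized volume container
#'
#' Integer gray levels `1..Ng` at mask voxels, with the Lloyd-Max decision
#' boundaries and centroids (HU) that produced them. Tests and the texture
#' oracle can also construct one directly from a level array.
#'
#' @param levels 3D integer array with values in `1..ng` at mask voxels
#'   (values outside the mask are ignored).
#' @param mask a [roi_mask()].
#' @param ng level count.
#' @param boundaries,centroids optional quantizer parameters.
#' @param mse_trace optional per-iteration MSE trace.
#' @return An object of class `quantized_volume`.
#' @export
quantized_volume <- function(levels, mask, ng, boundaries = numeric(),
                             centroids = numeric(), mse_trace = numeric()) {
  levels <- as.array(levels)
  if (!identical(dim(levels), dim(mask$flags)))
    stopf("levels and mask shapes differ")
  lv <- levels[mask$flags]
  if (any(lv < 1 | lv > ng)) stopf("within-mask levels must lie in [1, ng]")
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, mask = mask, ng = as.integer(ng),
                 boundaries = boundaries, centroids = centroids,
                 mse_trace = mse_trace,
                 n_occupied = length(unique(lv))),
            class = "quantized_volume")
}

#' @export
print.quantized_volume <- function(x, ...) {
  cat(sprintf("<quantized_volume> Ng=%d (%d occupied), %d mask voxels\n",
              x$ng, x$n_occupied, x$mask$voxel_count))
  invisible(x)
}

#' Lloyd-Max adaptive gray-level quantization
#'
#' Quantizes within-mask intensities to `ng` levels by the Lloyd-Max
#' algorithm: starting from an equal-count (quantile) split, alternately
#' assign each value to its nearest centroid and recompute centroids as
#' conditional means, until the largest centroid movement falls below `tol`
#' or `max_iter` is reached. The within-mask quantization MSE is
#' non-increasing across iterations. Values exactly on a decision boundary
#' go to the higher level. Levels that empty out are re-seeded
#' deterministically by splitting the most populous level at its median.
#' If the ROI holds fewer distinct values than `ng`, each distinct value
#' gets its own level and the remaining levels stay unoccupied.
#'
#' @param volume a [vox_volume()].
#' @param mask an aligned [roi_mask()].
#' @param ng number of gray levels, `>= 2`.
#' @param tol convergence tolerance on centroid movement; default
#'   `1e-6 *` the within-mask intensity range.
#' @param max_iter iteration cap (default 200).
#' @return A [quantized_volume()].
#' @export
lloyd_max_quantize <- function(volume, mask, ng, tol = NULL, max_iter = 200L) {
  check_aligned(volume, mask)
  if (ng < 2) stopf("ng must be >= 2")
  v <- volume$data[mask$flags]
  distinct <- sort(unique(v))
  lev_arr <- array(1L, dim(volume$data))

  if (length(distinct) <= ng) {
    lev <- match(v, distinct)
    cen <- distinct
    b <- if (length(distinct) > 1)
      (utils::head(distinct, -1) + utils::tail(distinct, -1)) / 2
    else numeric()
    lev_arr[mask$flags] <- lev
    return(quantized_volume(lev_arr, mask, ng, boundaries = b,
                            centroids = cen, mse_trace = 0))
  }

  rng <- diff(range(v))
  if (is.null(tol)) tol <- 1e-6 * rng
  sv <- sort(v)
  n <- length(sv)
  grp <- ceiling(seq_len(n) / (n / ng))
  grp[grp > ng] <- ng
  cen <- as.numeric(tapply(sv, grp, mean))
  cen <- sort(cen)
  trace <- numeric()
  lev <- NULL
  for (it in seq_len(max_iter)) {
    # enforce strictly increasing centroids (coincident ones collapse a level;
    # the empty-level reseed below recovers it)
    cen <- sort(cen)
    b <- (utils::head(cen, -1) + utils::tail(cen, -1)) / 2
    lev <- findInterval(v, b) + 1L   # value on a boundary -> higher level
    counts <- tabulate(lev, ng)
    guard <- 0L
    while (any(counts == 0) && guard < ng) {
      guard <- guard + 1L
      e <- which(counts == 0)[1]
      p <- which.max(counts)
      vp <- v[lev == p]
      med <- stats::median(vp)
      lo <- vp[vp <= med]; hi <- vp[vp > med]
      if (length(hi) == 0) { counts[e] <- -1L; next }  # unsplittable mass
      cen[p] <- mean(lo); cen[e] <- mean(hi)
      cen <- sort(cen)
      b <- (utils::head(cen, -1) + utils::tail(cen, -1)) / 2
      lev <- findInterval(v, b) + 1L
      counts <- tabulate(lev, ng)
    }
    new_cen <- cen
    for (g in which(tabulate(lev, ng) > 0)) new_cen[g] <- mean(v[lev == g])
    trace <- c(trace, mean((v - new_cen[lev])^2))
    moved <- max(abs(new_cen - cen))
    cen <- new_cen
    if (moved < tol) break
  }
  b <- (utils::head(cen, -1) + utils::tail(cen, -1)) / 2
  lev <- findInterval(v, b) + 1L
  lev_arr[mask$flags] <- lev
  quantized_volume(lev_arr, mask, ng, boundaries = b, centroids = cen,
                   mse_trace = trace)
}
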