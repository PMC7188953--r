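# Texture matrix engines. All four families merge the 13 unique distance-1
# 3D directions into a single matrix per family (not per-direction
# averaging), and use only within-mask voxels; voxels outside the mask break
# co-occurrences, runs, zones and neighborhoods.

NGTDM_EPS <- 1e-12

# valid index range along one axis for a shifted comparison (empty when the
# axis is too short for the offset)
axis_range <- function(n, off) {
  lo <- max(1L, 1L - off)
  hi <- min(n, n - off)
  if (lo > hi) integer(0) else lo:hi
}

# Index pairs (linear) of within-mask voxels at a given offset.
offset_pairs <- function(lev, flags, off) {
  d <- dim(flags)
  xs <- axis_range(d[1], off[1])
  ys <- axis_range(d[2], off[2])
  zs <- axis_range(d[3], off[3])
  if (!length(xs) || !length(ys) || !length(zs))
    return(list(a = integer(), b = integer()))
  fa <- flags[xs, ys, zs, drop = FALSE]
  fb <- flags[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
  both <- fa & fb
  la <- lev[xs, ys, zs, drop = FALSE][both]
  lb <- lev[xs + off[1], ys + off[2], zs + off[3], drop = FALSE][both]
  list(a = la, b = lb)
}

#' Gray-level co-occurrence matrix and features
#'
#' Accumulates symmetric co-occurrences of quantized gray levels over all 13
#' unique 3D direction offsets at distance 1 (both voxels within the mask)
#' into one `Ng x Ng` matrix normalized to sum 1, then derives 9 features:
#' Energy, Contrast, Entropy, Homogeneity, Correlation, SumAverage,
#' Variance, Dissimilarity, AutoCorrelation.
#'
#' @param qvol a [quantized_volume()].
#' @return Named numeric vector of 9 features.
#' @export
glcm_features <- function(qvol) {
  P <- glcm_matrix(qvol)
  glcm_derive(P)
}

glcm_matrix <- function(qvol) {
  ng <- qvol$ng
  acc <- numeric(ng * ng)
  for (k in seq_len(nrow(directions13()))) {
    pr <- offset_pairs(qvol$levels, qvol$mask$flags, directions13()[k, ])
    if (!length(pr$a)) next
    acc <- acc + tabulate(pr$a + (pr$b - 1L) * ng, ng * ng) +
      tabulate(pr$b + (pr$a - 1L) * ng, ng * ng)
  }
  tot <- sum(acc)
  if (tot == 0) stopf("GLCM: no valid within-mask voxel pair")
  matrix(acc / tot, ng, ng)
}

glcm_derive <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P)
  mu <- sum(seq_len(ng) * pi_)
  sg2 <- sum((seq_len(ng) - mu)^2 * pi_)
  pos <- P > 0
  corr <- if (sg2 > 0) sum(P * (i - mu) * (j - mu)) / sg2 else 0
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Entropy = -sum(P[pos] * log2(P[pos])),
    Homogeneity = sum(P / (1 + abs(i - j))),
    Correlation = corr,
    SumAverage = sum((i + j) * P) / 2,
    Variance = sg2,
    Dissimilarity = sum(abs(i - j) * P),
    AutoCorrelation = sum(i * j * P))
}

#' Gray-level run-length matrix and features
#'
#' Maximal same-level runs of within-mask voxels are accumulated over the 13
#' unique 3D directions (voxels outside the mask break runs) into one
#' `Ng x Lmax` matrix, then 13 features are derived: SRE, LRE, GLN, RLN, RP,
#' LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV. RP is the run count
#' divided by `13 * voxel_count` (one count per voxel per direction).
#'
#' @param qvol a [quantized_volume()].
#' @return Named numeric vector of 13 features.
#' @export
glrlm_features <- function(qvol) {
  R <- glrlm_matrix(qvol)
  glrlm_derive(R, qvol$mask$voxel_count)
}

glrlm_matrix <- function(qvol) {
  lev <- qvol$levels; flags <- qvol$mask$flags
  d <- dim(flags)
  idx <- which(flags, arr.ind = TRUE)
  lin <- which(flags)
  lv <- lev[lin]
  run_lev <- integer(); run_len <- integer()
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    prev <- sweep(idx, 2, off)
    pin <- prev[, 1] >= 1 & prev[, 1] <= d[1] &
           prev[, 2] >= 1 & prev[, 2] <= d[2] &
           prev[, 3] >= 1 & prev[, 3] <= d[3]
    plin <- prev[pin, 1] + (prev[pin, 2] - 1L) * d[1] +
            (prev[pin, 3] - 1L) * d[1] * d[2]
    same <- logical(nrow(idx))
    same[pin] <- flags[plin] & lev[plin] == lv[pin]
    cur <- idx[!same, , drop = FALSE]      # run starts
    rl <- lv[!same]
    len <- rep(1L, nrow(cur))
    active <- rep(TRUE, nrow(cur))
    while (any(active)) {
      nxt <- sweep(cur, 2, -off)
      nin <- active & nxt[, 1] >= 1 & nxt[, 1] <= d[1] &
             nxt[, 2] >= 1 & nxt[, 2] <= d[2] &
             nxt[, 3] >= 1 & nxt[, 3] <= d[3]
      cont <- nin
      if (any(nin)) {
        nlin <- nxt[nin, 1] + (nxt[nin, 2] - 1L) * d[1] +
                (nxt[nin, 3] - 1L) * d[1] * d[2]
        cont[nin] <- flags[nlin] & lev[nlin] == rl[nin]
      }
      len[cont] <- len[cont] + 1L
      cur[cont, ] <- nxt[cont, , drop = FALSE]
      active <- cont
    }
    run_lev <- c(run_lev, rl)
    run_len <- c(run_len, len)
  }
  if (!length(run_lev)) stopf("GLRLM: empty mask")
  R <- matrix(0, qvol$ng, max(run_len))
  tab <- table(factor(run_lev, levels = seq_len(qvol$ng)),
               factor(run_len, levels = seq_len(max(run_len))))
  R[] <- as.numeric(tab)
  R
}

glrlm_derive <- function(R, voxel_count) {
  nr <- sum(R)
  p <- R / nr
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mi <- sum(seq_len(nrow(p)) * pi_)
  mj <- sum(seq_len(ncol(p)) * pj_)
  c(SRE = sum(p / j^2),
    LRE = sum(p * j^2),
    GLN = sum(pi_^2),
    RLN = sum(pj_^2),
    RP = nr / (13 * voxel_count),
    LGRE = sum(p / i^2),
    HGRE = sum(p * i^2),
    SRLGE = sum(p / (i^2 * j^2)),
    SRHGE = sum(p * i^2 / j^2),
    LRLGE = sum(p * j^2 / i^2),
    LRHGE = sum(p * i^2 * j^2),
    GLV = sum(p * (i - mi)^2),
    RLV = sum(p * (j - mj)^2))
}

#' Gray-level size-zone matrix and features
#'
#' Zones are 26-connected components of equal quantized level within the
#' mask (connected components of the same-level adjacency graph). The zone
#' counts by (level, size) yield 13 features: SZE, LZE, GLN, ZSN, ZP, LGZE,
#' HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV. ZP is the zone count divided
#' by the mask voxel count.
#'
#' @param qvol a [quantized_volume()].
#' @return Named numeric vector of 13 features.
#' @export
glszm_features <- function(qvol) {
  z <- glszm_zones(qvol)
  glszm_derive(z$level, z$size, qvol$ng, qvol$mask$voxel_count)
}

# zones as (level, size) pairs via igraph connected components
glszm_zones <- function(qvol) {
  lev <- qvol$levels; flags <- qvol$mask$flags
  lin <- which(flags)
  n <- length(lin)
  vid <- integer(length(flags))
  vid[lin] <- seq_len(n)
  ea <- integer(); eb <- integer()
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    d <- dim(flags)
    xs <- axis_range(d[1], off[1])
    ys <- axis_range(d[2], off[2])
    zs <- axis_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    sub <- function(a, ox, oy, oz) a[xs + ox, ys + oy, zs + oz, drop = FALSE]
    both <- sub(flags, 0, 0, 0) & sub(flags, off[1], off[2], off[3]) &
      sub(lev, 0, 0, 0) == sub(lev, off[1], off[2], off[3])
    if (!any(both)) next
    la <- sub(vid_arr <- array(vid, d), 0, 0, 0)[both]
    lb <- sub(vid_arr, off[1], off[2], off[3])[both]
    ea <- c(ea, la); eb <- c(eb, lb)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(ea, eb))
  comp <- igraph::components(g)
  first <- !duplicated(comp$membership)
  zone_level <- integer(comp$no)
  zone_level[comp$membership[first]] <- lev[lin][first]
  list(level = zone_level, size = as.integer(comp$csize))
}

glszm_derive <- function(zone_level, zone_size, ng, voxel_count) {
  nz <- length(zone_size)
  Smax <- max(zone_size)
  Z <- matrix(0, ng, Smax)
  tab <- table(factor(zone_level, levels = seq_len(ng)),
               factor(zone_size, levels = seq_len(Smax)))
  Z[] <- as.numeric(tab)
  p <- Z / nz
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mi <- sum(seq_len(ng) * pi_)
  mj <- sum(seq_len(Smax) * pj_)
  c(SZE = sum(p / j^2),
    LZE = sum(p * j^2),
    GLN = sum(pi_^2),
    ZSN = sum(pj_^2),
    ZP = nz / voxel_count,
    LGZE = sum(p / i^2),
    HGZE = sum(p * i^2),
    SZLGE = sum(p / (i^2 * j^2)),
    SZHGE = sum(p * i^2 / j^2),
    LZLGE = sum(p * j^2 / i^2),
    LZHGE = sum(p * i^2 * j^2),
    GLV = sum(p * (i - mi)^2),
    ZSV = sum(p * (j - mj)^2))
}

#' Neighborhood gray-tone difference features
#'
#' For each voxel with at least one within-mask 26-neighbor, the absolute
#' difference between its level and the mean level of its within-mask
#' neighbors is accumulated per level, giving the classic five features:
#' Coarseness, Contrast, Busyness, Complexity, Strength. Denominators are
#' guarded with `1e-12`; Coarseness is capped at `1e12`.
#'
#' @param qvol a [quantized_volume()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(qvol) {
  t <- ngtdm_table(qvol)
  ngtdm_derive(t$s, t$n, qvol$ng)
}

# per-level counts n_i and accumulated deviations s_i
ngtdm_table <- function(qvol) {
  lev <- qvol$levels; flags <- qvol$mask$flags
  d <- dim(flags)
  S <- array(0, d); C <- array(0L, d)
  for (k in seq_len(nrow(offsets26()))) {
    off <- offsets26()[k, ]
    xs <- axis_range(d[1], off[1])
    ys <- axis_range(d[2], off[2])
    zs <- axis_range(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    nb_in <- flags[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    nb_lev <- lev[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    add_s <- as.vector(nb_in * nb_lev)
    add_c <- as.vector(nb_in)
    S[xs, ys, zs] <- as.vector(S[xs, ys, zs]) + add_s
    C[xs, ys, zs] <- as.vector(C[xs, ys, zs]) + add_c
  }
  valid <- flags & C > 0
  ng <- qvol$ng
  n_i <- numeric(ng); s_i <- numeric(ng)
  if (any(valid)) {
    lv <- lev[valid]
    dev <- abs(lv - S[valid] / C[valid])
    n_i <- tabulate(lv, ng)
    s_i <- as.numeric(tapply(dev, factor(lv, levels = seq_len(ng)), sum,
                             default = 0))
  }
  list(n = n_i, s = s_i)
}

ngtdm_derive <- function(s_i, n_i, ng) {
  N <- sum(n_i)
  eps <- NGTDM_EPS
  if (N == 0)
    return(c(Coarseness = 1 / eps, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  p_i <- n_i / N
  lev <- seq_len(ng)
  occ <- p_i > 0
  ngp <- sum(occ)
  coarse <- min(1 / eps, 1 / (eps + sum(p_i * s_i)))
  if (ngp <= 1)
    return(c(Coarseness = coarse, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  io <- lev[occ]; po <- p_i[occ]; so <- s_i[occ]
  dif2 <- outer(io, io, `-`)^2
  contrast <- sum(outer(po, po) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / N
  ip <- io * po
  busy_den <- sum(abs(outer(ip, ip, `-`)))
  busyness <- if (busy_den < eps) 0 else sum(po * so) / busy_den
  psum <- outer(po, po, `+`)
  complexity <- sum(abs(outer(io, io, `-`)) *
                      (outer(po * so, po * so, `+`)) / (N * psum))
  strength_num <- sum(psum * dif2)
  strength <- strength_num / (eps + sum(s_i))
  c(Coarseness = coarse, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
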