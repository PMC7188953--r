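#' Brute-force texture feature oracle
#'
#' Independent reference implementation of the four texture families by
#' literal enumeration: explicit loops over all voxel pairs (GLCM), run
#' walks (GLRLM), flood-filled zones (GLSZM) and neighborhoods (NGTDM).
#' Written separately from the vectorized engine in order to cross-check it
#' on small volumes; it is O(voxels x neighbors) with R-level loops and not
#' meant for production-size ROIs.
#'
#' @param qvol a [quantized_volume()].
#' @param family one of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"NGTDM"`.
#' @return Named numeric vector matching the corresponding engine function.
#' @export
texture_oracle <- function(qvol, family) {
  lev <- qvol$levels; msk <- qvol$mask$flags
  d <- dim(msk)
  ng <- qvol$ng
  inb <- function(x, y, z)
    x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]

  switch(toupper(family),
    GLCM = {
      M <- matrix(0, ng, ng)
      for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
        if (!msk[x, y, z]) next
        for (o in seq_len(nrow(offs))) {
          nx <- x + offs[o, 1]; ny <- y + offs[o, 2]; nz <- z + offs[o, 3]
          if (inb(nx, ny, nz) && msk[nx, ny, nz])
            M[lev[x, y, z], lev[nx, ny, nz]] <-
              M[lev[x, y, z], lev[nx, ny, nz]] + 1
        }
      }
      if (sum(M) == 0) stopf("oracle GLCM: no voxel pair")
      oracle_glcm_features(M / sum(M))
    },
    GLRLM = {
      half <- offs[apply(offs, 1, function(v) {
        nz <- v[v != 0]; nz[1] > 0
      }), , drop = FALSE]
      runs <- list()
      for (o in seq_len(nrow(half))) {
        dx <- half[o, 1]; dy <- half[o, 2]; dz <- half[o, 3]
        for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
          if (!msk[x, y, z]) next
          px <- x - dx; py <- y - dy; pz <- z - dz
          starts_run <- !(inb(px, py, pz) && msk[px, py, pz] &&
                            lev[px, py, pz] == lev[x, y, z])
          if (!starts_run) next
          len <- 1L
          cx <- x + dx; cy <- y + dy; cz <- z + dz
          while (inb(cx, cy, cz) && msk[cx, cy, cz] &&
                 lev[cx, cy, cz] == lev[x, y, z]) {
            len <- len + 1L
            cx <- cx + dx; cy <- cy + dy; cz <- cz + dz
          }
          runs[[length(runs) + 1L]] <- c(lev[x, y, z], len)
        }
      }
      rl <- do.call(rbind, runs)
      R <- matrix(0, ng, max(rl[, 2]))
      for (r in seq_len(nrow(rl))) R[rl[r, 1], rl[r, 2]] <- R[rl[r, 1], rl[r, 2]] + 1
      oracle_glrlm_features(R, sum(msk))
    },
    GLSZM = {
      seen <- array(FALSE, d)
      zl <- integer(); zs <- integer()
      for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
        if (!msk[x, y, z] || seen[x, y, z]) next
        g <- lev[x, y, z]
        queue <- matrix(c(x, y, z), 1)
        seen[x, y, z] <- TRUE
        size <- 0L
        while (nrow(queue) > 0) {
          v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
          size <- size + 1L
          for (o in seq_len(nrow(offs))) {
            nx <- v[1] + offs[o, 1]; ny <- v[2] + offs[o, 2]; nz <- v[3] + offs[o, 3]
            if (inb(nx, ny, nz) && msk[nx, ny, nz] && !seen[nx, ny, nz] &&
                lev[nx, ny, nz] == g) {
              seen[nx, ny, nz] <- TRUE
              queue <- rbind(queue, c(nx, ny, nz))
            }
          }
        }
        zl <- c(zl, g); zs <- c(zs, size)
      }
      oracle_glszm_features(zl, zs, ng, sum(msk))
    },
    NGTDM = {
      n_i <- numeric(ng); s_i <- numeric(ng)
      for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
        if (!msk[x, y, z]) next
        nb <- numeric()
        for (o in seq_len(nrow(offs))) {
          nx <- x + offs[o, 1]; ny <- y + offs[o, 2]; nz <- z + offs[o, 3]
          if (inb(nx, ny, nz) && msk[nx, ny, nz])
            nb <- c(nb, lev[nx, ny, nz])
        }
        if (length(nb) == 0) next
        g <- lev[x, y, z]
        n_i[g] <- n_i[g] + 1
        s_i[g] <- s_i[g] + abs(g - mean(nb))
      }
      oracle_ngtdm_features(n_i, s_i, ng)
    },
    stopf("unknown texture family: %s", family))
}

# Independent feature formula implementations (kept separate from the
# engine's derive functions on purpose).

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  out <- c(Energy = 0, Contrast = 0, Entropy = 0, Homogeneity = 0,
           Correlation = 0, SumAverage = 0, Variance = 0,
           Dissimilarity = 0, AutoCorrelation = 0)
  marg <- rowSums(P)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * marg[i]
  var <- 0
  for (i in 1:ng) var <- var + (i - mu)^2 * marg[i]
  num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    out["Energy"] <- out["Energy"] + p^2
    out["Contrast"] <- out["Contrast"] + (i - j)^2 * p
    if (p > 0) out["Entropy"] <- out["Entropy"] - p * log2(p)
    out["Homogeneity"] <- out["Homogeneity"] + p / (1 + abs(i - j))
    out["SumAverage"] <- out["SumAverage"] + (i + j) * p / 2
    out["Dissimilarity"] <- out["Dissimilarity"] + abs(i - j) * p
    out["AutoCorrelation"] <- out["AutoCorrelation"] + i * j * p
    num <- num + (i - mu) * (j - mu) * p
  }
  out["Variance"] <- var
  out["Correlation"] <- if (var > 0) num / var else 0
  out
}

oracle_glrlm_features <- function(R, nvox) {
  nr <- sum(R)
  p <- R / nr
  ng <- nrow(p); lm <- ncol(p)
  f <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = nr / (13 * nvox),
         LGRE = 0, HGRE = 0, SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0,
         GLV = 0, RLV = 0)
  mi <- 0; mj <- 0
  for (i in 1:ng) for (j in 1:lm) {
    mi <- mi + i * p[i, j]; mj <- mj + j * p[i, j]
  }
  for (i in 1:ng) {
    f["GLN"] <- f["GLN"] + sum(p[i, ])^2
  }
  for (j in 1:lm) {
    f["RLN"] <- f["RLN"] + sum(p[, j])^2
  }
  for (i in 1:ng) for (j in 1:lm) {
    q <- p[i, j]
    f["SRE"] <- f["SRE"] + q / j^2
    f["LRE"] <- f["LRE"] + q * j^2
    f["LGRE"] <- f["LGRE"] + q / i^2
    f["HGRE"] <- f["HGRE"] + q * i^2
    f["SRLGE"] <- f["SRLGE"] + q / (i^2 * j^2)
    f["SRHGE"] <- f["SRHGE"] + q * i^2 / j^2
    f["LRLGE"] <- f["LRLGE"] + q * j^2 / i^2
    f["LRHGE"] <- f["LRHGE"] + q * i^2 * j^2
    f["GLV"] <- f["GLV"] + q * (i - mi)^2
    f["RLV"] <- f["RLV"] + q * (j - mj)^2
  }
  f
}

oracle_glszm_features <- function(zone_level, zone_size, ng, nvox) {
  nz <- length(zone_size)
  lm <- max(zone_size)
  Z <- matrix(0, ng, lm)
  for (k in seq_len(nz)) Z[zone_level[k], zone_size[k]] <-
    Z[zone_level[k], zone_size[k]] + 1
  p <- Z / nz
  f <- c(SZE = 0, LZE = 0, GLN = 0, ZSN = 0, ZP = nz / nvox,
         LGZE = 0, HGZE = 0, SZLGE = 0, SZHGE = 0, LZLGE = 0, LZHGE = 0,
         GLV = 0, ZSV = 0)
  mi <- 0; mj <- 0
  for (i in 1:ng) for (j in 1:lm) {
    mi <- mi + i * p[i, j]; mj <- mj + j * p[i, j]
  }
  for (i in 1:ng) f["GLN"] <- f["GLN"] + sum(p[i, ])^2
  for (j in 1:lm) f["ZSN"] <- f["ZSN"] + sum(p[, j])^2
  for (i in 1:ng) for (j in 1:lm) {
    q <- p[i, j]
    f["SZE"] <- f["SZE"] + q / j^2
    f["LZE"] <- f["LZE"] + q * j^2
    f["LGZE"] <- f["LGZE"] + q / i^2
    f["HGZE"] <- f["HGZE"] + q * i^2
    f["SZLGE"] <- f["SZLGE"] + q / (i^2 * j^2)
    f["SZHGE"] <- f["SZHGE"] + q * i^2 / j^2
    f["LZLGE"] <- f["LZLGE"] + q * j^2 / i^2
    f["LZHGE"] <- f["LZHGE"] + q * i^2 * j^2
    f["GLV"] <- f["GLV"] + q * (i - mi)^2
    f["ZSV"] <- f["ZSV"] + q * (j - mj)^2
  }
  f
}

oracle_ngtdm_features <- function(n_i, s_i, ng) {
  eps <- 1e-12
  N <- sum(n_i)
  if (N == 0)
    return(c(Coarseness = 1 / eps, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  p_i <- n_i / N
  coarse <- min(1 / eps, 1 / (eps + sum(p_i * s_i)))
  occ <- which(p_i > 0)
  if (length(occ) <= 1)
    return(c(Coarseness = coarse, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  ngp <- length(occ)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in occ) for (j in occ) {
    contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
    complexity <- complexity + abs(i - j) *
      (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (N * (p_i[i] + p_i[j]))
    strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
  }
  contrast <- contrast / (ngp * (ngp - 1)) * sum(s_i) / N
  busyness <- if (busy_den < eps) 0 else sum(p_i * s_i) / busy_den
  strength <- strength / (eps + sum(s_i))
  c(Coarseness = coarse, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
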