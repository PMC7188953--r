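# Single-level separable 3D discrete wavelet transform with per-subband
# reconstruction. Orthogonal kernels with periodized boundaries give exact
# perfect reconstruction and energy preservation; odd dimensions are padded
# by symmetric half-sample extension (duplicate the last slice), recorded in
# original_shape and cropped on inversion.

wavelet_lowpass <- function(kernel) {
  switch(kernel,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    coif1 = c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854),
    stopf("unknown wavelet kernel: %s", kernel))
}

wavelet_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# Orthogonal periodized analysis matrix for even signal length n:
# first n/2 rows low-pass, last n/2 rows high-pass.
dwt_matrix <- function(n, h) {
  g <- wavelet_highpass(h)
  L <- length(h)
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    cols <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (m in seq_len(L)) {
      W[k, cols[m]] <- W[k, cols[m]] + h[m]
      W[n / 2 + k, cols[m]] <- W[n / 2 + k, cols[m]] + g[m]
    }
  }
  W
}

axis_apply <- function(a, axis, M) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  dp2 <- c(nrow(M), dp[2], dp[3])
  aperm(array(M %*% matrix(ap, dp[1]), dp2), order(perm))
}

subband_labels <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' Single-level 3D wavelet decomposition into 8 subbands
#'
#' Applies a separable single-level orthogonal 3D discrete wavelet transform.
#' Subband labels give the filter applied along the (x, y, z) axes in order:
#' `LLH` is low-pass along x and y and high-pass along z. Odd dimensions are
#' extended by duplicating the final slice before the transform; the original
#' shape is recorded so reconstructions crop back exactly.
#'
#' @param volume a [vox_volume()] or 3D array.
#' @param kernel wavelet family: `"haar"` (default, alias `"db1"`), `"db2"`
#'   or `"coif1"`.
#' @return An object of class `subband_set`: a named list of 8 coefficient
#'   blocks plus `kernel_name`, `original_shape` and `padded_shape`.
#' @export
dwt3_subbands <- function(volume, kernel = "haar") {
  a <- if (inherits(volume, "vox_volume")) volume$data else as.array(volume)
  d0 <- dim(a)
  h <- wavelet_lowpass(kernel)
  if (any(d0 < length(h)))
    stopf("volume dimensions %s smaller than the %s filter support (%d)",
          paste(d0, collapse = "x"), kernel, length(h))
  for (ax in 1:3) {                       # symmetric half-sample pad to even
    if (dim(a)[ax] %% 2 == 1) {
      idx <- lapply(dim(a), seq_len)
      idx[[ax]] <- c(idx[[ax]], dim(a)[ax])
      a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
  }
  dp <- dim(a)
  for (ax in 1:3) a <- axis_apply(a, ax, dwt_matrix(dp[ax], h))
  half <- dp / 2
  take <- function(flags) {              # flags: TRUE = high-pass half
    idx <- lapply(1:3, function(ax)
      if (flags[ax]) (half[ax] + 1):dp[ax] else 1:half[ax])
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  bands <- lapply(subband_labels(), function(lab)
    take(strsplit(lab, "")[[1]] == "H"))
  names(bands) <- subband_labels()
  structure(list(subbands = bands, kernel_name = kernel,
                 original_shape = d0, padded_shape = dp),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> kernel %s, original %s, 8 blocks of %s\n",
              x$kernel_name, paste(x$original_shape, collapse = "x"),
              paste(dim(x$subbands[[1]]), collapse = "x")))
  invisible(x)
}

idwt3 <- function(subbands) {
  dp <- subbands$padded_shape
  half <- dp / 2
  a <- array(0, dp)
  for (lab in subband_labels()) {
    flags <- strsplit(lab, "")[[1]] == "H"
    idx <- lapply(1:3, function(ax)
      if (flags[ax]) (half[ax] + 1):dp[ax] else 1:half[ax])
    a[idx[[1]], idx[[2]], idx[[3]]] <- subbands$subbands[[lab]]
  }
  h <- wavelet_lowpass(subbands$kernel_name)
  for (ax in 1:3) a <- axis_apply(a, ax, t(dwt_matrix(dp[ax], h)))
  d0 <- subbands$original_shape
  a[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

#' Reconstruct a single wavelet subband image
#'
#' Inverts the 3D transform with every subband except `label` zeroed,
#' yielding a volume of the original shape. By linearity the 8 subband
#' reconstructions sum to the original volume.
#'
#' @param subbands a [dwt3_subbands()] result.
#' @param label one of `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`.
#' @return A 3D array of the original shape.
#' @export
reconstruct_subband <- function(subbands, label) {
  if (!label %in% subband_labels()) stopf("unknown subband label: %s", label)
  keep <- subbands
  for (lab in subband_labels())
    if (lab != label) keep$subbands[[lab]][] <- 0
  idwt3(keep)
}
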