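# Shared fixtures: all built in code, nothing read from disk.

# quantized volume straight from a level array (full mask by default)
make_qvol <- function(lev, msk = NULL, ng = max(lev)) {
  lev <- as.array(lev)
  if (is.null(msk)) msk <- array(TRUE, dim(lev))
  quantized_volume(lev, roi_mask(msk), ng)
}

# random small quantized volume for property tests
rand_qvol <- function(seed, max_dim = 5L, max_ng = 4L, p_mask = 0.8) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  ng <- sample(2:max_ng, 1)
  lev <- array(sample.int(ng, prod(d), replace = TRUE), d)
  msk <- array(stats::runif(prod(d)) < p_mask, d)
  if (sum(msk) < 3) msk[1:3] <- TRUE
  make_qvol(lev, msk, ng)
}

engine_features <- function(qv, family) {
  switch(family,
         GLCM = glcm_features(qv), GLRLM = glrlm_features(qv),
         GLSZM = glszm_features(qv), NGTDM = ngtdm_features(qv))
}

# hand-crafted minimal NIfTI-1 file (int16) with explicit scl_slope/inter,
# used to pin down the format's affine intensity rule
write_nifti_scaled <- function(path, data_int, dim3, slope, inter,
                               pixdim = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(3L, dim3, 1L, 1L, 1L, 1L)), con, size = 2)
  writeBin(raw(14), con)
  writeBin(4L, con, size = 2)          # datatype int16
  writeBin(16L, con, size = 2)         # bitpix
  writeBin(0L, con, size = 2)
  writeBin(c(0, pixdim, 1, 1, 1, 1), con, size = 4)
  writeBin(352, con, size = 4)         # vox_offset
  writeBin(slope, con, size = 4)
  writeBin(inter, con, size = 4)
  writeBin(raw(348 - 120 - 4), con)
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1), con)
  writeBin(raw(4), con)
  writeBin(as.integer(data_int), con, size = 2)
  invisible(path)
}

# minimal NRRD (raw encoding, little endian)
write_nrrd_raw <- function(path, a, spacing = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004", "type: float", "dimension: 3",
           paste("sizes:", paste(dim(a), collapse = " ")),
           paste("spacings:", paste(spacing, collapse = " ")),
           "endian: little", "encoding: raw", "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(a), con, size = 4, endian = "little")
  invisible(path)
}

# small two-class cohort for pipeline-level tests
tiny_cohort <- function(n_pos = 6, n_neg = 6, grid = c(12, 12, 12),
                        seed = 5) {
  specs <- default_class_specs()
  specs$pos$mask_radii <- c(4, 3, 3)
  specs$neg$mask_radii <- c(4, 3, 3)
  generate_cohort(n_pos, n_neg, specs$pos, specs$neg, grid = grid,
                  seed = seed)
}
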