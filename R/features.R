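# Per-subject radiomic feature vectors and the cohort feature table.

GLOBAL_CODES <- c("max", "min", "range", "mean", "entropy", "variance",
                  "skew", "kurt")

#' Histogram-based global features
#'
#' Eight first-order statistics of the within-mask intensities: max, min,
#' range, mean, entropy, variance, skewness and kurtosis. Moments are
#' population moments; kurtosis is non-excess (Gaussian -> 3). Entropy is
#' `-sum p log2 p` over the occupancy distribution of the quantized levels,
#' which makes it the only global feature that depends on Ng. A constant ROI
#' yields range, variance, entropy, skewness and kurtosis of 0.
#'
#' @param volume a [vox_volume()].
#' @param mask an aligned [roi_mask()].
#' @param qvol the [quantized_volume()] providing the entropy levels.
#' @return Named numeric vector of 8 features.
#' @export
global_features <- function(volume, mask, qvol) {
  check_aligned(volume, mask)
  v <- volume$data[mask$flags]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  p <- tabulate(qvol$levels[mask$flags], qvol$ng) / mask$voxel_count
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  stats::setNames(
    c(max(v), min(v), diff(range(v)), m, ent, m2, skew, kurt),
    GLOBAL_CODES)
}

#' Feature name grammar
#'
#' Image features render as `<Family>.<code> @ rawNg=<ng>` or
#' `<Family>.<code> @ WT(<subband>) Ng=<ng>`; clinical covariates render as
#' `<Name> @ Clinic`. `parse_feature_name()` inverts the rendering.
#'
#' @param family feature family (`Global`, `GLCM`, `GLRLM`, `GLSZM`,
#'   `NGTDM`, or `Clinic`).
#' @param feature short feature code (for `Clinic`, the covariate name).
#' @param volume_tag `"raw"` or a subband label for wavelet versions.
#' @param ng quantization level count (ignored for `Clinic`).
#' @return A single feature-name string.
#' @export
feature_name <- function(family, feature, volume_tag = "raw", ng = NA) {
  if (family == "Clinic") return(paste0(feature, " @ Clinic"))
  if (volume_tag == "raw")
    sprintf("%s.%s @ rawNg=%d", family, feature, as.integer(ng))
  else
    sprintf("%s.%s @ WT(%s) Ng=%d", family, feature, volume_tag,
            as.integer(ng))
}

#' @rdname feature_name
#' @param name a rendered feature name.
#' @return For `parse_feature_name()`, a list with `family`, `feature`,
#'   `volume_tag` and `ng`.
#' @export
parse_feature_name <- function(name) {
  if (grepl(" @ Clinic$", name))
    return(list(family = "Clinic",
                feature = sub(" @ Clinic$", "", name),
                volume_tag = NA_character_, ng = NA_integer_))
  m <- regmatches(name,
    regexec("^([A-Za-z]+)\\.([A-Za-z]+) @ (rawNg=([0-9]+)|WT\\(([LH]{3})\\) Ng=([0-9]+))$",
            name))[[1]]
  if (length(m) == 0) stopf("unparseable feature name: %s", name)
  if (m[5] != "")
    list(family = m[2], feature = m[3], volume_tag = "raw",
         ng = as.integer(m[5]))
  else
    list(family = m[2], feature = m[3], volume_tag = m[6],
         ng = as.integer(m[7]))
}

# 48 features for one (volume version, Ng) block
block_features <- function(version_vol, mask, ng) {
  qv <- lloyd_max_quantize(version_vol, mask, ng)
  c(global_features(version_vol, mask, qv),
    glcm_features(qv), glrlm_features(qv), glszm_features(qv),
    ngtdm_features(qv))
}

block_feature_names <- function(volume_tag, ng) {
  fams <- list(Global = GLOBAL_CODES,
               GLCM = names(glcm_derive(matrix(1))),
               GLRLM = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                         "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"),
               GLSZM = c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                         "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"),
               NGTDM = c("Coarseness", "Contrast", "Busyness", "Complexity",
                         "Strength"))
  unlist(lapply(names(fams), function(f)
    vapply(fams[[f]], feature_name, "", family = f,
           volume_tag = volume_tag, ng = ng)), use.names = FALSE)
}

#' Extract the full radiomic feature vector for one subject
#'
#' Crops to the ROI bounding box, builds the 9 volume versions (the raw ROI
#' plus the 8 single-level wavelet subband reconstructions), and for every
#' version and every Ng in `ng_list` quantizes with Lloyd-Max and emits the
#' 48-feature block (8 global + 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM).
#' Total image features: `48 * length(ng_list) * 9` (1,728 at the default
#' `ng_list` of 16, 32, 64, 96). Feature order is version (raw, then
#' subbands LLL..HHH), then Ng, then family.
#'
#' @param volume a [vox_volume()].
#' @param mask an aligned [roi_mask()].
#' @param ng_list quantization level counts (default `c(16, 32, 64, 96)`).
#' @param kernel wavelet kernel passed to [dwt3_subbands()].
#' @param include_wavelet if `FALSE`, only the raw volume is used
#'   (`48 * length(ng_list)` features; 192 at the default `ng_list`).
#' @return Named numeric feature vector.
#' @export
extract_feature_vector <- function(volume, mask, ng_list = c(16, 32, 64, 96),
                                   kernel = "haar", include_wavelet = TRUE) {
  roi <- extract_roi(volume, mask, pad = 0L)
  versions <- list(raw = roi$volume$data)
  if (include_wavelet) {
    sb <- dwt3_subbands(roi$volume$data, kernel)
    for (lab in subband_labels())
      versions[[lab]] <- reconstruct_subband(sb, lab)
  }
  out <- numeric(0)
  for (tag in names(versions)) {
    vv <- vox_volume(versions[[tag]], roi$volume$spacing)
    for (ng in ng_list) {
      fv <- block_features(vv, roi$mask, ng)
      names(fv) <- block_feature_names(tag, ng)
      out <- c(out, fv)
    }
  }
  out
}

#' Assemble the cohort feature table
#'
#' Rows are subjects, columns the full image feature vector plus (by
#' default) the clinical covariates age (years), gender (male = 1) and
#' smoking (ever = 1). Race is retained as row metadata but excluded from
#' the features. Labels are attached as an attribute (positive class = 1).
#'
#' @param subjects list of subjects as produced by [generate_cohort()]: each
#'   has `volume`, `mask`, `clinical` and `label`.
#' @param ng_list,kernel passed to [extract_feature_vector()].
#' @param include_clinical append the three clinical covariates?
#' @param progress print a progress line per subject?
#' @return A `feature_table`: data.frame of features with attributes
#'   `labels`, `subject_ids`, `race` and `manifest` (kernel, ng_list,
#'   feature order).
#' @export
assemble_feature_table <- function(subjects, ng_list = c(16, 32, 64, 96),
                                   kernel = "haar", include_clinical = TRUE,
                                   progress = FALSE) {
  if (length(subjects) < 2) stopf("need at least 2 subjects")
  labels <- vapply(subjects, function(s) as.integer(s$label), 0L)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  ids <- vapply(subjects, function(s) s$clinical$subject_id, "")
  if (anyDuplicated(ids)) stopf("duplicate subject ids")
  rows <- lapply(seq_along(subjects), function(i) {
    if (progress) message(sprintf("extracting %s (%d/%d)", ids[i], i,
                                  length(subjects)))
    s <- subjects[[i]]
    extract_feature_vector(s$volume, s$mask, ng_list, kernel)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  if (include_clinical) {
    clin <- cbind(
      vapply(subjects, function(s) as.numeric(s$clinical$age), 0),
      vapply(subjects, function(s) as.numeric(s$clinical$gender), 0),
      vapply(subjects, function(s) as.numeric(s$clinical$smoking), 0))
    colnames(clin) <- c(feature_name("Clinic", "Age"),
                        feature_name("Clinic", "Gender"),
                        feature_name("Clinic", "Smoking"))
    X <- cbind(X, clin)
  }
  feature_table(X, labels,
                race = vapply(subjects, function(s) s$clinical$race, ""),
                manifest = list(kernel = kernel, ng_list = ng_list))
}

#' Feature table container
#'
#' @param X numeric matrix or data.frame, subjects x named features.
#' @param labels integer 0/1 class labels, one per row.
#' @param race optional per-subject race metadata.
#' @param manifest optional provenance list (kernel, ng_list, ...).
#' @return An object of class `feature_table` (a data.frame).
#' @export
feature_table <- function(X, labels, race = NULL, manifest = list()) {
  X <- as.data.frame(as.matrix(X), check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(colnames(X))) stopf("duplicate feature names")
  if (nrow(X) != length(labels)) stopf("one label per row required")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (anyNA(X)) stopf("feature table contains missing values")
  structure(X, labels = as.integer(labels), race = race,
            manifest = manifest,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  lb <- attr(x, "labels")
  cat(sprintf("<feature_table> %d subjects x %d features (%d positive / %d negative)\n",
              nrow(x), ncol(x), sum(lb == 1), sum(lb == 0)))
  invisible(x)
}

# keep attributes through column subsetting
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "labels") <- if (missing(i)) attr(x, "labels")
                           else attr(x, "labels")[i]
    attr(out, "race") <- if (missing(i) || is.null(attr(x, "race")))
      attr(x, "race") else attr(x, "race")[i]
    attr(out, "manifest") <- attr(x, "manifest")
    class(out) <- c("feature_table", "data.frame")
  }
  out
}

#' Write a feature table as CSV plus a JSON manifest
#'
#' @param table a [feature_table()].
#' @param path CSV output path; the manifest is written alongside with a
#'   `.manifest.json` suffix.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(subject_id = rownames(table), as.data.frame(table),
              label = attr(table, "labels"))
  utils::write.csv(df, path, row.names = FALSE)
  man <- attr(table, "manifest") %||% list()
  man$feature_order <- colnames(table)
  jsonlite::write_json(man, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path with `subject_id` and `label` columns plus named
#'   feature columns; a `.manifest.json` alongside is read when present.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("subject_id", "label") %in% colnames(df)))
    stopf("feature CSV needs subject_id and label columns: %s", path)
  labels <- as.integer(df$label)
  ids <- df$subject_id
  X <- as.matrix(df[, setdiff(colnames(df), c("subject_id", "label")),
                    drop = FALSE])
  rownames(X) <- ids
  man_path <- sub("\\.csv$", ".manifest.json", path)
  man <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else list()
  feature_table(X, labels, manifest = man)
}
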