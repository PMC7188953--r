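# Volume/mask input-output. NIfTI goes through RNifti (which applies the
# format's scl_slope/scl_inter intensity rule on read); NRRD is parsed by a
# minimal reader below (attached raw/gzip encodings, 3D only).

#' Read a 3D image volume
#'
#' Reads a NIfTI-1 (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) file into a
#' [vox_volume()]. Intensities are preserved exactly up to the format's own
#' affine intensity rule (NIfTI slope/intercept); no resampling or windowing
#' is applied. Non-3D images and non-finite voxels are rejected.
#'
#' @param path path to a NIfTI or NRRD file.
#' @return A [vox_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    out <- read_nrrd(path)
  } else {
    img <- RNifti::readNifti(path)
    a <- array(as.numeric(img), dim(img))   # plain array, scaling applied
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
    if (length(dim(a)) != 3L)
      stopf("expected a 3D image, got %dD: %s", length(dim(a)), path)
    sp <- RNifti::pixdim(img)[1:3]
    out <- list(data = a, spacing = sp, origin = c(0, 0, 0))
  }
  if (!all(is.finite(out$data)))
    stopf("image contains NaN/Inf voxels: %s", path)
  vox_volume(out$data, out$spacing, out$origin)
}

#' Read a binary ROI mask aligned to a reference volume
#'
#' Any nonzero voxel is foreground. The mask grid must match the reference
#' volume's grid exactly; an all-zero mask is an error.
#'
#' @param path path to a NIfTI or NRRD mask file.
#' @param reference the [vox_volume()] the mask annotates.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, reference) {
  v <- read_volume(path)
  if (!identical(dim(v$data), dim(reference$data)))
    stopf("mask shape (%s) does not match reference (%s)",
          paste(dim(v$data), collapse = "x"),
          paste(dim(reference$data), collapse = "x"))
  if (all(v$data == 0)) stopf("empty mask: %s", path)
  roi_mask(v$data != 0)
}

#' Write a volume or mask as NIfTI
#'
#' @param x a [vox_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  a <- if (inherits(x, "roi_mask")) array(as.integer(x$flags), dim(x$flags))
       else x$data
  sp <- if (inherits(x, "roi_mask")) c(1, 1, 1) else x$spacing
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- minimal NRRD reader -----------------------------------------------------

nrrd_type_map <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stopf("not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  ndim <- as.integer(fields[["dimension"]] %||% stopf("NRRD missing dimension"))
  if (ndim != 3L) stopf("expected a 3D NRRD, got %dD: %s", ndim, path)
  sizes <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  tinfo <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(tinfo)) stopf("unsupported NRRD type: %s", fields[["type"]])
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- if (grepl("big", fields[["endian"]] %||% "little")) "big" else "little"
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = 2^31 - 1)
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stopf("unsupported NRRD encoding: %s", enc)
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) != n) stopf("NRRD payload truncated: %s", path)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  else if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    vecs <- lapply(rows, function(r)
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]]))
    if (length(vecs) == 3L)
      spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), 0)
  }
  list(data = array(as.double(vals), sizes), spacing = spacing,
       origin = c(0, 0, 0))
}

#' Write a synthetic cohort to disk
#'
#' Writes each subject's volume and mask as NIfTI and the clinical table as
#' CSV with header `subject_id,age,gender,smoking,race,label`.
#'
#' @param cohort a list of subjects from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return The clinical CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$clinical$subject_id, age = s$clinical$age,
               gender = s$clinical$gender, smoking = s$clinical$smoking,
               race = s$clinical$race, label = s$label)
  }))
  for (s in cohort) {
    write_volume(s$volume, file.path(dir, paste0(s$clinical$subject_id, "_vol.nii.gz")))
    write_volume(s$mask, file.path(dir, paste0(s$clinical$subject_id, "_mask.nii.gz")))
  }
  p <- file.path(dir, "clinical.csv")
  utils::write.csv(clin, p, row.names = FALSE)
  invisible(p)
}
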