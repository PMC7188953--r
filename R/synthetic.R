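#' Class specification for the synthetic tumor-phantom generator
#'
#' Describes one class of synthetic tumors: the within-mask intensity
#' distribution (`mean_hu`, `sd_hu`, in Hounsfield units), the texture
#' correlation length (`corr_len`, in voxels; the width of the Gaussian
#' smoothing kernel applied to white noise), the ellipsoidal mask semi-axes
#' (`mask_radii`, voxels), and the clinical covariate distributions
#' (smoking probability, age mean/SD in years, male probability, race
#' category probabilities).
#'
#' @param mean_hu within-mask mean intensity (HU).
#' @param sd_hu within-mask intensity SD (HU), `>= 0`.
#' @param corr_len texture correlation length in voxels, `> 0`.
#' @param mask_radii ellipsoid semi-axes in voxels, each `>= 2`.
#' @param smoking_prob probability of positive smoking history, in `[0, 1]`.
#' @param age_mean,age_sd age distribution parameters (years).
#' @param male_prob probability of male gender, in `[0, 1]`.
#' @param race_probs named probabilities over race categories (sum to 1).
#' @return An object of class `class_spec`.
#' @seealso [default_class_specs()] for the packaged two-class conditions.
#' @export
class_spec <- function(mean_hu, sd_hu, corr_len, mask_radii,
                       smoking_prob = 0.5, age_mean = 60, age_sd = 10,
                       male_prob = 0.5,
                       race_probs = c(Asian = 1 / 3, Caucasian = 1 / 3,
                                      Other = 1 / 3)) {
  if (sd_hu < 0) stopf("sd_hu must be >= 0")
  if (corr_len <= 0) stopf("corr_len must be > 0")
  if (length(mask_radii) != 3L || any(mask_radii < 2))
    stopf("mask_radii must be 3 values, each >= 2 voxels")
  if (smoking_prob < 0 || smoking_prob > 1) stopf("smoking_prob must be in [0,1]")
  if (male_prob < 0 || male_prob > 1) stopf("male_prob must be in [0,1]")
  structure(list(mean_hu = mean_hu, sd_hu = sd_hu, corr_len = corr_len,
                 mask_radii = as.numeric(mask_radii),
                 smoking_prob = smoking_prob, age_mean = age_mean,
                 age_sd = age_sd, male_prob = male_prob,
                 race_probs = race_probs / sum(race_probs)),
            class = "class_spec")
}

#' Default two-class synthetic study conditions
#'
#' The packaged stand-in for a two-class cohort of peripherally located lung
#' tumors. The positive ("small-cell-like") class has coarser texture
#' (longer correlation length), higher mean radiodensity and a smoking
#' prevalence of 34/35; the negative ("adenocarcinoma-like") class has finer
#' texture, lower density and smoking prevalence 9/34. Age, gender and race
#' distributions follow the same two-group demographic pattern.
#'
#' @return A list with `class_spec` elements `pos` and `neg`.
#' @export
default_class_specs <- function() {
  list(
    pos = class_spec(mean_hu = 45, sd_hu = 30, corr_len = 2.5,
                     mask_radii = c(6, 5, 5), smoking_prob = 34 / 35,
                     age_mean = 66.91, age_sd = 9.75, male_prob = 24 / 35,
                     race_probs = c(Asian = 7, Caucasian = 26, Other = 2) / 35),
    neg = class_spec(mean_hu = 20, sd_hu = 18, corr_len = 1.2,
                     mask_radii = c(6, 5, 5), smoking_prob = 9 / 34,
                     age_mean = 58.55, age_sd = 11.94, male_prob = 12 / 34,
                     race_probs = c(Asian = 16, Caucasian = 15, Other = 3) / 34)
  )
}

# Separable Gaussian smoothing of a 3D array (truncated kernel, zero-padded
# boundary). The field is affinely rescaled afterwards, so boundary scaling
# effects are absorbed.
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  smooth_axis <- function(x, axis) {
    n <- d[axis]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - half):(j + half)
      ok <- idx >= 1 & idx <= n
      K[idx[ok], j] <- K[idx[ok], j] + k[ok]
    }
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    yp <- array(crossprod(K, matrix(xp, dp[1])), dp)
    aperm(yp, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

#' Generate one textured synthetic tumor volume
#'
#' Builds a Gaussian random field (seeded white noise convolved with an
#' isotropic Gaussian kernel of width `corr_len`), rescales it inside an
#' ellipsoidal mask to the target within-mask mean/SD, and sets the
#' background to air-like -1000 HU. Feature extraction uses only within-mask
#' voxels, so the background value is inert.
#'
#' @param spec a [class_spec()].
#' @param grid integer length-3 grid shape; each dimension must be at least
#'   twice the corresponding mask radius.
#' @param seed integer seed; fixes all randomness.
#' @param spacing voxel size (mm), carried as metadata.
#' @return A list with elements `volume` ([vox_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_textured_volume <- function(spec, grid, seed,
                                     spacing = c(0.76, 0.76, 1)) {
  grid <- as.integer(grid)
  if (length(grid) != 3L) stopf("grid must be 3 dimensions")
  if (any(grid < 2 * spec$mask_radii))
    stopf("grid %s too small for mask radii %s",
          paste(grid, collapse = "x"), paste(spec$mask_radii, collapse = ","))
  centre <- (grid + 1) / 2
  cx <- (seq_len(grid[1]) - centre[1]) / spec$mask_radii[1]
  cy <- (seq_len(grid[2]) - centre[2]) / spec$mask_radii[2]
  cz <- (seq_len(grid[3]) - centre[3]) / spec$mask_radii[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  flags <- r2 <= 1
  field <- with_seed(seed, array(stats::rnorm(prod(grid)), grid))
  field <- gauss_smooth3(field, spec$corr_len)
  inside <- field[flags]
  mu <- mean(inside)
  sd0 <- stats::sd(inside)
  vol <- array(-1000, grid)
  if (spec$sd_hu == 0 || sd0 == 0) {
    vol[flags] <- spec$mean_hu
  } else {
    vol[flags] <- (inside - mu) / sd0 * spec$sd_hu + spec$mean_hu
  }
  list(volume = vox_volume(vol, spacing = spacing),
       mask = roi_mask(flags))
}

#' Generate a two-class synthetic cohort
#'
#' Positive-class subjects come first, then negatives, with labels 1 and 0.
#' Clinical covariates are drawn per class: smoking Bernoulli(smoking_prob),
#' age Normal(age_mean, age_sd), gender Bernoulli(male_prob) (male = 1),
#' race from `race_probs`. Fully reproducible from `seed`.
#'
#' @param n_pos,n_neg subject counts per class, each `>= 1`.
#' @param spec_pos,spec_neg [class_spec()] objects (defaults:
#'   [default_class_specs()]).
#' @param grid 3D grid shape for every subject.
#' @param seed integer base seed.
#' @return A list of subjects, each a list with `volume`, `mask`, `clinical`
#'   (subject_id, age, gender, smoking, race) and `label`.
#' @export
generate_cohort <- function(n_pos, n_neg,
                            spec_pos = default_class_specs()$pos,
                            spec_neg = default_class_specs()$neg,
                            grid = c(20, 20, 20), seed = 1L) {
  if (n_pos < 1 || n_neg < 1) stopf("need at least one subject per class")
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  clin <- with_seed(derive_seed(seed, 7L), {
    lapply(seq_len(n), function(i) {
      sp <- if (labels[i] == 1L) spec_pos else spec_neg
      list(subject_id = sprintf("S%03d", i),
           age = round(stats::rnorm(1, sp$age_mean, sp$age_sd), 1),
           gender = as.integer(stats::runif(1) < sp$male_prob),
           smoking = as.integer(stats::runif(1) < sp$smoking_prob),
           race = sample(names(sp$race_probs), 1, prob = sp$race_probs))
    })
  })
  lapply(seq_len(n), function(i) {
    sp <- if (labels[i] == 1L) spec_pos else spec_neg
    vm <- generate_textured_volume(sp, grid, derive_seed(seed, 100L + i))
    list(volume = vm$volume, mask = vm$mask, clinical = clin[[i]],
         label = labels[i])
  })
}
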