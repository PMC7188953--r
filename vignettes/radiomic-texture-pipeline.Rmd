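---
title: "Radiomic texture features and neural-network classification of lung tumor subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture features and neural-network classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiotexnet)
```

## The problem and the model

Small cell lung cancer (SCLC) and non-small cell adenocarcinoma look
similar on CT; their treatment and prognosis differ sharply. The premise of
CT radiomics is that the difference lives in quantitative image statistics
of the segmented tumor — texture, intensity distribution, multi-scale
structure — rather than in anything a reader can point at. radiotexnet
implements that premise as a fixed pipeline:

1. **ROI extraction.** A 3D CT volume (Hounsfield units) plus an aligned
   binary tumor mask. Features use only within-mask voxels; intensities
   stay in raw CT numbers with no windowing or resampling.
2. **Gray-level quantization.** Lloyd-Max adaptive quantization of the
   within-mask intensities at each level count Ng in {16, 32, 64, 96}.
3. **Texture matrices.** Gray-level co-occurrence (GLCM, 9 features),
   run-length (GLRLM, 13), size-zone (GLSZM, 13) and neighborhood
   gray-tone difference (NGTDM, 5) matrices, each merging all 13 unique
   distance-1 directions of the 3D lattice into a single matrix. Together
   with 8 histogram-based global features this gives 48 features per
   (volume version, Ng) block.
4. **Wavelet expansion.** A single-level separable 3D discrete wavelet
   transform splits the ROI volume into 8 subbands (LLL ... HHH); each
   subband is reconstructed alone and re-enters step 2 as its own volume
   version. With the raw volume that is 9 versions x 4 Ng x 48 = 1,728
   image features, plus age, gender and smoking = 1,731.
5. **Feature selection.** Max-normalization of each feature column,
   removal of one member of every feature pair with |Pearson| > 0.85, and
   minimal-redundancy-maximal-relevance (mRMR) reduction to 20 features
   using plug-in mutual information on 4-bin equal-frequency
   discretizations.
6. **Classification.** A 20-10-7-5-2 fully connected network, tanh on all
   hidden and output nodes, trained by Levenberg-Marquardt on +/-1 two-node
   targets with an MSE goal of 1e-3, at most 1000 epochs, and validation
   early stopping. The decision score is the difference of the two output
   nodes, thresholded at 0.
7. **Evaluation.** 30 repeated random 70/15/15 train/validation/test
   splits; per-trial test ROC/AUC; vertical averaging of the 30 curves onto
   a common FPR grid; mean AUC with a percentile 95% interval; sensitivity
   and specificity at the Youden-optimal point of the averaged curve.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `ng_list` | 16, 32, 64, 96 | gray levels | per-block quantization depths |
| `quantize tol` | 1e-6 x intensity range | HU | centroid-movement stop |
| `quantize max_iter` | 200 | iterations | cap; convergence is typically < 30 |
| `wavelet kernel` | `haar` | — | `db2`, `coif1` also available |
| `prune_threshold` | 0.85 | \|Pearson\| | collinearity cut |
| `k` | 20 | features | mRMR output size |
| `bins` | 4 | — | MI discretization |
| `ratios` | 0.70/0.15/0.15 | fractions | train/validation/test |
| `n_trials` | 30 | trials | repeated splits |
| `goal` | 1e-3 | MSE | LM training target |
| `max_epochs` | 1000 | epochs | LM cap |
| `mu0`, factor, cap | 1e-3, 10, 1e10 | — | LM damping schedule |
| `max_val_fail` | 6 | epochs | consecutive validation increases |

## Numerical and design choices

**Quantizer.** Initialization is the equal-count (quantile) split, making
the quantizer fully deterministic; both Lloyd steps are monotone, so the
within-mask MSE trace never increases (asserted in tests). A value exactly
on a decision boundary goes to the higher level. If a level empties, the
most populous level is split at its median. ROIs with fewer distinct values
than Ng get one level per distinct value; the remaining levels stay
unoccupied, which is the natural degenerate limit on small or constant
ROIs.

**Wavelet kernel.** The feature definitions do not depend on a specific
orthogonal family, and no single family is canonical for this pipeline; we
default to Haar (db1) because it is the shortest orthogonal kernel, exact
for the small ROI sizes the pipeline targets, and makes the subband
algebra transparent. Transforms use periodized filtering after padding odd
dimensions by duplicating the final slice (symmetric half-sample
extension); the original shape is recorded and reconstructions crop back,
so decompose-then-invert is exact to machine precision and the 8 subband
reconstructions sum to the original volume. Energy is preserved exactly on
even-length axes. The kernel name is carried in every feature-table
manifest.

**Quantizing subbands.** Each reconstructed subband volume is quantized
independently (its own Lloyd-Max fit) because subband intensities occupy
their own dynamic range; reusing raw-volume boundaries would collapse most
high-pass voxels into one or two levels.

**Texture conventions.** All four families use one direction-merged matrix
(not per-direction averages). Run percentage divides the run count by
13 x voxel count (one run membership per voxel per direction) and zone
percentage by the voxel count, so both live in (0, 1]. NGTDM denominators
are guarded with 1e-12 and Coarseness is capped at 1e12; a constant or
single-voxel ROI hits the caps rather than producing NaN. The 8 global
features are emitted once per (version, Ng) block even though only the
quantization-based entropy depends on Ng; this keeps the per-block count at
48 and the bookkeeping uniform. Moments are population moments; kurtosis is
non-excess; a zero-variance ROI reports skewness and kurtosis of 0.

**mRMR scheme.** The reduction is backward: at each step the feature whose
removal maximizes the remaining set's objective — mean MI-relevance to the
target minus mean pairwise MI redundancy — is deselected until 20 remain.
We chose the set-level objective over the common per-feature score
`I(f; y) − mean I(f; g)` deliberately: the per-feature rule removes
low-relevance *independent* features before touching a perfectly redundant
duplicate pair (the duplicate's shared relevance props both copies up),
whereas the set objective correctly discards one duplicate first. Ties drop
the lower-|Pearson| then later column, so selection is deterministic. The
final 20 are reported in descending |Pearson relevance|. A forward variant
(`scheme = "forward"`) is provided for comparison, and
`redundancy_weight = 0` reduces either scheme to plain MI-relevance
ranking.

**MI estimation.** Plug-in mutual information on 4-bin equal-frequency
discretizations (the binary target is used as-is). The plug-in estimator is
positively biased at small n (about 0.03 bits at n = 2000 for independent
4-bin variables, larger at cohort sizes); this bias is shared by all
features and cancels in rankings, which is all the selection uses.

**Split sizes.** Validation and test take the floors of their exact
allocations (at least 1 each) and training absorbs the remainder: 69
subjects at 70/15/15 give 49/10/10. Splits are stratified by class by
default, because at cohort sizes around 10 test subjects an unstratified
draw can empty a class and leave the per-trial ROC undefined.

**Levenberg-Marquardt.** The Jacobian of all residuals with respect to all
339 parameters is assembled analytically by per-output backpropagation
(verified against central finite differences to < 1e-6); steps solve
`(J'J + mu I) delta = J'e` and are accepted only if training MSE
decreases. The damping schedule (mu0 = 1e-3, factor 10, cap 1e10) and
`max_val_fail = 6` follow common practice for this optimizer; none of
these values is critical — they gate step size, not the optimum. With a
validation set the returned parameters are the best-validation ones.

## The synthetic cohort: what it emulates and what it does not

No patient CT cohort ships with the package, so a two-class phantom
generator stands in. Each subject is an ellipsoidal "tumor" (semi-axes in
voxels) on an air-valued (-1000 HU) background; the within-mask texture is
a Gaussian random field — seeded white noise convolved with an isotropic
Gaussian kernel of width `corr_len`, affinely rescaled to a target mean/SD
in HU. The packaged class conditions mirror a two-group cohort of
peripherally located tumors: the positive class has coarser texture
(`corr_len` 2.5 vs 1.2 voxels), higher density (45 vs 20 HU) and wider
spread (30 vs 18 HU), smoking prevalence 34/35 vs 9/34, age 66.9 +/- 9.8 vs
58.6 +/- 11.9 years, and the corresponding gender/race frequencies. These
effect sizes are the package's own choice of a "strong-signal" condition —
no quantitative inter-class texture description exists to copy — so
cohort-level results are property checks (high AUC under signal, chance
under permuted labels), not reproductions of any published cohort value.

The generator deliberately does **not** simulate lungs, vasculature,
nodule spiculation, respiratory or reconstruction artifacts, scanner
kernels, or segmentation error. Passing the pipeline's tests therefore
shows the machinery is correct and well-behaved, not that the published
discrimination performance transfers to clinical data.

## Selection leakage and the evaluation modes

By default, feature selection runs once on the full table before the 30
trials — the workflow typical of this literature. Because the test
subjects of every trial participated in selection, test AUC under this
mode is optimistically biased. `selection_inside_trial = TRUE` re-runs
pruning and mRMR on each trial's training subset only, giving an unbiased
test evaluation; this is the mode used for the package's own property
checks. The null (label-permuted) check additionally averages over several
independent permutations: a cohort with strong latent class structure
gives any *single* permutation a chance label imbalance across the latent
clusters, so single-permutation null AUCs scatter widely around 0.5 even
without leakage; averaging over permutations estimates the mean of that
distribution.

## Validation problem sizes

The packaged checks run at deliberately reduced scale: feature-count
arithmetic on one subject with a ~32^3 ROI at the full default
configuration; engine-versus-oracle equivalence on 50 random volumes up to
5^3 at Ng <= 4 (agreement to 1e-10); and the end-to-end property checks on
a 40-subject cohort on 20^3 grids with `ng_list = c(16, 32)` — on ~500-voxel
synthetic ROIs, 64 or 96 gray levels are near-degenerate (close to one
level per distinct value), so the two finer depths carry no additional
information there.

```{r, eval = FALSE}
coh <- generate_cohort(n_pos = 20, n_neg = 20, seed = 1)
tab <- assemble_feature_table(coh, ng_list = c(16, 32))
run <- run_pipeline(tab, config = list(n_trials = 30, base_seed = 1,
                                       selection_inside_trial = TRUE))
print(run)
plot(run)
```

## Known limitations

* The wavelet family used by the original formulation of this pipeline is
  unknowable; kernel-for-kernel feature values will differ across choices,
  which is why the kernel is configurable and recorded.
* Plug-in MI at cohort-scale n is biased; only rankings are consumed.
* The LM trainer is exact but dense: it scales as (parameters)^2 per epoch
  and is intended for networks of this size, not larger ones.
* Anisotropic voxels are used as-is (features are spacing-agnostic);
  no isotropic resampling is performed.
* Multi-component masks are treated as one ROI; no morphological cleaning
  is applied.
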