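as_vol <- function(v) vox_volume(array(v, c(length(v), 1, 1)))
full_mask <- function(n) roi_mask(array(TRUE, c(n, 1, 1)))

test_that("global features cover the degenerate and two-point cases", {
  v <- as_vol(rep(4, 8)); m <- full_mask(8)
  q <- lloyd_max_quantize(v, m, 4)
  g <- global_features(v, m, q)
  expect_equal(unname(g[c("range", "variance", "entropy", "skew", "kurt")]),
               c(0, 0, 0, 0, 0))
  v2 <- as_vol(c(-2, -2, 2, 2)); m2 <- full_mask(4)
  q2 <- lloyd_max_quantize(v2, m2, 2)
  g2 <- global_features(v2, m2, q2)
  expect_equal(unname(g2["mean"]), 0)
  expect_equal(unname(g2["range"]), 4)
  expect_equal(unname(g2["entropy"]), 1)   # one bit
  expect_equal(unname(g2["max"]), 2)
  expect_equal(unname(g2["min"]), -2)
})

test_that("entropy of an equal-mass three-level quantization is log2(3)", {
  v <- as_vol(c(1, 2, 3, 4, 5, 6)); m <- full_mask(6)
  q <- lloyd_max_quantize(v, m, 3)
  expect_equal(tabulate(q$levels[m$flags], 3), c(2L, 2L, 2L))
  g <- global_features(v, m, q)
  expect_equal(unname(g["entropy"]), log2(3))
})

test_that("population moments match direct computation on a skewed sample", {
  set.seed(41)
  vals <- rexp(50, 1 / 10)
  v <- as_vol(vals); m <- full_mask(50)
  q <- lloyd_max_quantize(v, m, 4)
  g <- global_features(v, m, q)
  mu <- mean(vals); m2 <- mean((vals - mu)^2)
  expect_equal(unname(g["variance"]), m2)
  expect_equal(unname(g["skew"]), mean((vals - mu)^3) / m2^1.5)
  expect_equal(unname(g["kurt"]), mean((vals - mu)^4) / m2^2)
})

test_that("feature names render and parse through the grammar", {
  n1 <- feature_name("GLSZM", "ZSN", "HHH", 32)
  expect_equal(n1, "GLSZM.ZSN @ WT(HHH) Ng=32")
  n2 <- feature_name("GLSZM", "ZP", "raw", 16)
  expect_equal(n2, "GLSZM.ZP @ rawNg=16")
  n3 <- feature_name("Clinic", "Smoking")
  expect_equal(n3, "Smoking @ Clinic")
  for (nm in c(n1, n2, n3)) {
    p <- parse_feature_name(nm)
    re <- if (p$family == "Clinic") feature_name("Clinic", p$feature)
          else feature_name(p$family, p$feature, p$volume_tag, p$ng)
    expect_identical(re, nm)
  }
  expect_error(parse_feature_name("nonsense"), "unparseable")
})

test_that("feature-vector counts follow the 48 x |ng| x 9 arithmetic", {
  sp <- default_class_specs()$pos
  sp$mask_radii <- c(3, 3, 3)
  vm <- generate_textured_volume(sp, c(10, 10, 10), seed = 14)
  fv1 <- extract_feature_vector(vm$volume, vm$mask, ng_list = 8,
                                include_wavelet = FALSE)
  expect_length(fv1, 48)
  fv2 <- extract_feature_vector(vm$volume, vm$mask, ng_list = c(8, 16))
  expect_length(fv2, 48 * 2 * 9)
  expect_false(anyDuplicated(names(fv2)) > 0)
  parsed <- lapply(names(fv2), parse_feature_name)
  expect_true(all(vapply(parsed, function(p)
    p$volume_tag %in% c("raw", "LLL", "LLH", "LHL", "LHH",
                        "HLL", "HLH", "HHL", "HHH"), TRUE)))
})

test_that("global features repeat across Ng blocks except entropy", {
  sp <- default_class_specs()$neg
  sp$mask_radii <- c(3, 3, 3)
  vm <- generate_textured_volume(sp, c(10, 10, 10), seed = 15)
  fv <- extract_feature_vector(vm$volume, vm$mask, ng_list = c(4, 8),
                               include_wavelet = FALSE)
  for (code in setdiff(radiotexnet:::GLOBAL_CODES, "entropy")) {
    a <- fv[feature_name("Global", code, "raw", 4)]
    b <- fv[feature_name("Global", code, "raw", 8)]
    expect_equal(unname(a), unname(b))
  }
  expect_false(
    fv[feature_name("Global", "entropy", "raw", 4)] ==
      fv[feature_name("Global", "entropy", "raw", 8)])
})

test_that("the cohort table appends clinical covariates and keeps labels", {
  coh <- tiny_cohort(3, 2, grid = c(10, 10, 10), seed = 16)
  tab <- assemble_feature_table(coh, ng_list = 8)
  expect_equal(ncol(tab), 48 * 9 + 3)
  expect_equal(attr(tab, "labels"), c(1L, 1L, 1L, 0L, 0L))
  expect_true(all(c("Age @ Clinic", "Gender @ Clinic", "Smoking @ Clinic")
                  %in% colnames(tab)))
  tab2 <- assemble_feature_table(coh, ng_list = 8, include_clinical = FALSE)
  expect_equal(ncol(tab2), 48 * 9)
  # permuting subjects permutes rows, values unchanged
  perm <- c(4, 2, 5, 1, 3)
  tab3 <- assemble_feature_table(coh[perm], ng_list = 8)
  expect_equal(as.matrix(tab3), as.matrix(tab)[perm, ])
  expect_equal(attr(tab3, "labels"), attr(tab, "labels")[perm])
})

test_that("degenerate cohorts are rejected", {
  coh <- tiny_cohort(3, 2, grid = c(10, 10, 10), seed = 16)
  expect_error(assemble_feature_table(coh[1:3], ng_list = 8), "both classes")
  dup <- coh
  dup[[2]]$clinical$subject_id <- dup[[1]]$clinical$subject_id
  expect_error(assemble_feature_table(dup, ng_list = 8), "duplicate")
})

test_that("feature tables round-trip through CSV with their manifest", {
  coh <- tiny_cohort(2, 2, grid = c(10, 10, 10), seed = 17)
  tab <- assemble_feature_table(coh, ng_list = 8)
  p <- file.path(tempdir(), "table.csv")
  write_feature_table(tab, p)
  back <- utils::read.csv(p, check.names = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(back$label, attr(tab, "labels"))
  man <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", p),
                             simplifyVector = TRUE)
  expect_equal(man$kernel, "haar")
  expect_equal(man$feature_order, colnames(tab))
})
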