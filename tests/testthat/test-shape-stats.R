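test_that("PC retention follows the cumulative-variance rule", {
  arr <- make_variance_array(c(0.80, 0.16, 0.04))
  m <- fit_pca(arr, threshold = 0.96)
  expect_identical(m$retained_m, 2L)
  expect_equal(m$variances[1:3] / sum(m$variances[1:3]),
               c(0.80, 0.16, 0.04), tolerance = 1e-8)

  m_all <- fit_pca(arr, threshold = 1.0)
  expect_identical(m_all$retained_m, length(m_all$variances))

  eq <- fit_pca(make_variance_array(rep(1, 10), n = 30, V = 6),
                threshold = 0.96)
  expect_identical(eq$retained_m, 10L)   # 9/10 < 0.96

  expect_error(fit_pca(arr, threshold = 0), class = "invalid_parameter")
  expect_error(fit_pca(arr, threshold = 1.5), class = "invalid_parameter")
})

test_that("shape model components are orthonormal, variances descending", {
  res <- tiny_cohort(n_per_group = 6, noise_sd = 0.03, seed = 10)
  m <- fit_pca(gpa(as_corresponded(res$cohort)))
  k <- length(m$variances)
  expect_equal(m$components %*% t(m$components), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$variances) <= 1e-12))
})

test_that("score normalization yields unit variance and flags constants", {
  set.seed(4)
  s <- cbind(rnorm(20, sd = 2), rnorm(20, sd = 0.3))
  ns <- normalize_scores(s)
  expect_equal(apply(ns$scores, 2, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(ns$sds, apply(s, 2, sd))
  already <- scale(s, center = FALSE, scale = apply(s, 2, sd))
  expect_equal(normalize_scores(already)$scores, unclass(already),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(normalize_scores(cbind(s[, 1], 5)), class = "zero_variance")
})

test_that("covariate design uses k-1 dummies and detects collinearity", {
  cov <- data.frame(genotype = rep(c("WT", "VAR"), each = 6),
                    sex = rep(c("M", "F"), 6),
                    litter = rep(c("L1", "L2", "L3"), 4))
  d <- covariate_design(cov, genotype_levels = c("WT", "VAR"))
  # intercept + (2-1) sex + (3-1) litter
  expect_identical(ncol(d$nuisance), 4L)
  expect_equal(sort(unique(d$genotype)), c(0, 1))

  # genotype aliased with sex -> collinear
  cov2 <- data.frame(genotype = rep(c("WT", "VAR"), each = 4),
                     sex = rep(c("M", "F"), each = 4))
  expect_error(covariate_design(cov2, genotype_levels = c("WT", "VAR")),
               class = "collinear_design")
})

test_that("partial R2 hits its exact boundary cases", {
  n <- 12
  g <- rep(c(0, 1), each = n / 2)
  cov <- data.frame(genotype = ifelse(g == 1, "VAR", "WT"))
  design <- covariate_design(cov, genotype_levels = c("WT", "VAR"))

  # Y exactly linear in genotype -> R2 = 1
  y_lin <- cbind(2 * g - 1, -3 * (2 * g - 1))
  expect_equal(partial_effect(y_lin, design)$partial_R2, 1, tolerance = 1e-12)

  # Y orthogonal to the centered genotype -> R2 = 0
  y_orth <- cbind(rep(c(1, -1), n / 2), rep(c(-1, 1), n / 2))
  expect_equal(partial_effect(y_orth, design)$partial_R2, 0, tolerance = 1e-12)
})

test_that("partial R2 equals the brute-force SSE oracle on a small design", {
  set.seed(11)
  n <- 8
  cov <- data.frame(genotype = rep(c("WT", "VAR"), 4),
                    litter = rep(c("L1", "L2"), each = 4))
  design <- covariate_design(cov, genotype_levels = c("WT", "VAR"))
  Y <- matrix(rnorm(n * 2), n, 2)
  fit <- partial_effect(Y, design)
  expect_equal(fit$partial_R2,
               oracle_partial_r2(Y, design$genotype, design$nuisance),
               tolerance = 1e-12)
})

test_that("residualization path matches the oracle on random instances", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    m <- sample(1:4, 1)
    cov <- data.frame(genotype = sample(rep(c("WT", "VAR"), length.out = n)),
                      sex = sample(c("M", "F"), n, replace = TRUE),
                      litter = sample(paste0("L", 1:2), n, replace = TRUE))
    design <- tryCatch(covariate_design(cov, genotype_levels = c("WT", "VAR")),
                       craniomorph_error = function(e) NULL)
    if (is.null(design)) next
    Y <- matrix(rnorm(n * m), n, m)
    expect_equal(partial_effect(Y, design)$partial_R2,
                 oracle_partial_r2(Y, design$genotype, design$nuisance),
                 tolerance = 1e-10)
  }
})

test_that("partial R2 is invariant to nuisance rescaling and label flips", {
  set.seed(13)
  n <- 16
  cov <- data.frame(genotype = sample(rep(c("WT", "VAR"), each = 8)),
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    litter = rep(c("L1", "L2"), 8))
  Y <- matrix(rnorm(n * 3), n, 3)
  d1 <- covariate_design(cov, genotype_levels = c("WT", "VAR"))
  f1 <- partial_effect(Y, d1)

  d_scaled <- d1
  d_scaled$nuisance[, 2] <- 17 * d_scaled$nuisance[, 2]
  f2 <- partial_effect(Y, d_scaled)
  expect_equal(f1$partial_R2, f2$partial_R2, tolerance = 1e-12)

  d_flip <- covariate_design(cov, genotype_levels = c("VAR", "WT"))
  f3 <- partial_effect(Y, d_flip)
  expect_equal(f1$partial_R2, f3$partial_R2, tolerance = 1e-12)
  expect_equal(f1$coefficients, -f3$coefficients, tolerance = 1e-12)
  expect_true(f1$partial_R2 >= 0 && f1$partial_R2 <= 1)
})

test_that("permutation p-values follow the +1 formula, floor, and tie rule", {
  # Y an exact function of genotype: observed R2 = 1 beats every permutation
  # that breaks the group split, so p sits at the 1/(B+1) floor
  n <- 44
  cov <- data.frame(genotype = rep(c("WT", "VAR"), c(20, 24)))
  design <- covariate_design(cov, genotype_levels = c("WT", "VAR"))
  y <- cbind(design$genotype - mean(design$genotype))
  pt <- permutation_test(y, design, n_permutations = 999, seed = 21)
  expect_equal(pt$p, 0.001, tolerance = 1e-12)
  expect_gte(pt$p, 1 / (pt$n_permutations + 1))

  # observed at or below every permuted value (ties count as >=) -> p near 1;
  # the orthogonal construction leaves observed and tied permutations at
  # float-noise level (~1e-33), so assert at that scale
  cov8 <- data.frame(genotype = rep(c("WT", "VAR"), each = 4))
  design8 <- covariate_design(cov8, genotype_levels = c("WT", "VAR"))
  y0 <- cbind(rep(c(1, -1), 4))    # orthogonal to the genotype contrast
  pt0 <- permutation_test(y0, design8, n_permutations = 200, seed = 22)
  expect_lt(pt0$observed_R2, 1e-20)
  expect_gte(pt0$p, 0.8)
  expect_equal(pt0$p, (1 + sum(pt0$permuted_R2 >= pt0$observed_R2)) / 201)

  # reported p always equals the formula applied to the permuted values
  set.seed(23)
  Y <- matrix(rnorm(n * 3), n, 3)
  pt2 <- permutation_test(Y, design, n_permutations = 150, seed = 24)
  expect_equal(pt2$p, (1 + sum(pt2$permuted_R2 >= pt2$observed_R2)) / 151)
  # deterministic given the seed
  pt3 <- permutation_test(Y, design, n_permutations = 150, seed = 24)
  expect_identical(pt2$p, pt3$p)
})

test_that("per-vertex effects localize a noiseless outward bump", {
  tm <- make_template(8)
  patch <- vertex_patch(tm, 30, rings = 2)
  spec <- cohort_spec(n_per_group = 6, genotype_effect_amplitude = 0.05,
                      effect_patch = patch, litter_count = 1, noise_sd = 0,
                      sex_effect_amplitude = 0,
                      apply_similarity_transforms = FALSE, seed = 31)
  coh <- generate_cohort(tm, spec)
  al <- gpa(as_corresponded(coh))
  model <- fit_pca(al, threshold = 1.0)
  design <- covariate_design(coh$covariates, genotype_levels = c("WT", "VAR"))
  pv <- per_vertex_effects(model, design)
  nd <- normal_displacement(al$mean_shape, tm$faces, pv$coefficient_field)

  expect_true(all(nd[patch] > 0))               # outward on the patch
  out <- setdiff(seq_len(nrow(tm$vertices)), patch)
  expect_lt(max(abs(nd[out])), max(abs(nd[patch])) / 5)
  expect_true(which.max(pv$per_vertex_R2) %in% patch)
  expect_true(all(pv$per_vertex_R2 >= 0 & pv$per_vertex_R2 <= 1))
})

test_that("null per-vertex R2 centers near the analytic expectation", {
  tm <- make_template(8)
  vals <- vapply(1:12, function(r) {
    spec <- cohort_spec(n_per_group = 12, genotype_effect_amplitude = 0,
                        litter_count = 2, litter_sd = 0, noise_sd = 0.02,
                        apply_similarity_transforms = FALSE, seed = 600 + r)
    coh <- generate_cohort(tm, spec)
    model <- fit_pca(gpa(as_corresponded(coh)), threshold = 0.96)
    design <- covariate_design(coh$covariates,
                               genotype_levels = c("WT", "VAR"))
    mean(per_vertex_effects(model, design)$per_vertex_R2)
  }, numeric(1))
  n <- 24
  q <- 3  # intercept + sex + litter dummies
  expect_lt(abs(mean(vals) - 1 / (n - q - 1)), 0.01)
})

test_that("back-projection with all components reproduces the PC-space fit", {
  res <- tiny_cohort(n_per_group = 6, amplitude = 0.04, noise_sd = 0.02,
                     seed = 33)
  al <- gpa(as_corresponded(res$cohort))
  model <- fit_pca(al, threshold = 1.0)
  design <- covariate_design(res$cohort$covariates,
                             genotype_levels = c("WT", "VAR"))
  norm <- normalize_scores(model$scores)
  fit <- partial_effect(norm$scores, design)
  # fitted values pushed to vertex space and projected back are unchanged
  W <- model$components[seq_len(model$retained_m), , drop = FALSE]
  fitted_un <- sweep(fit$fitted, 2, norm$sds, "*")
  roundtrip <- (fitted_un %*% W) %*% t(W)
  expect_equal(roundtrip, fitted_un, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("normal displacement projects exactly and flips with orientation", {
  tm <- make_template(6)
  nrm <- vertex_normals(tm)
  expect_equal(normal_displacement(tm$vertices, tm$faces, nrm),
               rep(1, nrow(nrm)), tolerance = 1e-10)

  # field orthogonal to every normal by construction -> zero displacement
  tangent <- cbind(-nrm[, 2], nrm[, 1], 0)
  expect_lt(max(abs(normal_displacement(tm$vertices, tm$faces, tangent))),
            1e-12)

  set.seed(41)
  field <- matrix(rnorm(nrow(nrm) * 3), ncol = 3)
  nd <- normal_displacement(tm$vertices, tm$faces, field)
  flipped <- tm$faces[, c(1, 3, 2)]
  expect_equal(normal_displacement(tm$vertices, flipped, field), -nd,
               tolerance = 1e-12)
})
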