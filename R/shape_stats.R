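flatten_shapes <- function(shapes) {
  # N x V x 3 -> N x 3V in (x1, y1, z1, x2, ...) order
  n <- dim(shapes)[1L]
  t(apply(shapes, 1L, function(s) as.vector(t(s))))
}

#' Principal-component shape model of an aligned cohort
#'
#' PCA of the flattened aligned shapes about their mean.  Components with
#' numerically zero variance are dropped; `retained_m` is the smallest number
#' of leading components whose cumulative variance fraction reaches
#' `threshold` (default 0.96).
#'
#' @param aligned a `cm_aligned` from [gpa()], or an `N x V x 3` array.
#' @param threshold variance fraction to retain, in (0, 1].
#' @return object of class `cm_shape_model`: `mean_shape` (`V x 3`),
#'   `components` (orthonormal `m x 3V`, all nonzero-variance components),
#'   `variances` (descending), `retained_m`, `variance_threshold`, and
#'   `scores` (`N x retained_m` projections on the retained axes).
#' @export
fit_pca <- function(aligned, threshold = 0.96) {
  threshold <- check_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    cm_stop("threshold must be in (0, 1]", "invalid_parameter")
  }
  shapes <- if (inherits(aligned, "cm_aligned")) aligned$shapes else aligned
  n <- dim(shapes)[1L]
  if (n < 2L) cm_stop("PCA needs at least 2 shapes", "invalid_parameter")
  x <- flatten_shapes(shapes)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  keep <- vars > max(vars) * 1e-12          # drop numerically-null axes
  vars <- vars[keep]
  frac <- cumsum(vars) / sum(vars)
  retained_m <- which(frac >= threshold - 1e-12)[1L]
  V <- dim(shapes)[2L]
  structure(list(
    mean_shape = matrix(pc$center, V, 3L, byrow = TRUE),
    components = t(pc$rotation[, keep, drop = FALSE]),
    variances = vars,
    retained_m = retained_m,
    variance_threshold = threshold,
    scores = pc$x[, seq_len(retained_m), drop = FALSE]
  ), class = "cm_shape_model")
}

#' @export
print.cm_shape_model <- function(x, ...) {
  cat(sprintf("<cm_shape_model> %d components, %d retained (>= %.0f%% variance)\n",
              length(x$variances), x$retained_m, 100 * x$variance_threshold))
  invisible(x)
}

#' Scale principal-component scores to unit variance per component
#'
#' @param scores `N x m` score matrix.
#' @return list with `scores` (unit-variance columns) and `sds` (the column
#'   standard deviations divided out, needed to de-normalize later).
#' @export
normalize_scores <- function(scores) {
  scores <- as.matrix(scores)
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds < 1e-300)) {
    cm_stop("zero-variance score column: cannot normalize", "zero_variance")
  }
  list(scores = sweep(scores, 2L, sds, "/"), sds = sds)
}

#' Dummy-coded covariate design for a genotype contrast
#'
#' Builds the genotype contrast (0 = reference, 1 = variant) and the nuisance
#' design block: an intercept plus k-1 binary dummy columns for each
#' categorical nuisance factor (sex, litter).  Errors if the combined design
#' is rank deficient or the genotype lies in the span of the nuisance block.
#'
#' @param covariates data.frame with columns `genotype` and any of `sex`,
#'   `litter`.
#' @param genotype_levels length-2 character vector `(reference, variant)`;
#'   defaults to the sorted unique labels.
#' @param nuisance_factors names of nuisance columns to dummy-code.
#' @return object of class `cm_covariates`: list with `genotype` (numeric
#'   0/1 vector), `nuisance` (N x q matrix including intercept), and levels.
#' @export
covariate_design <- function(covariates, genotype_levels = NULL,
                             nuisance_factors = c("sex", "litter")) {
  stopifnot(is.data.frame(covariates), "genotype" %in% names(covariates))
  labels <- as.character(covariates$genotype)
  genotype_levels <- genotype_levels %||% sort(unique(labels))
  if (length(genotype_levels) != 2L || !all(labels %in% genotype_levels)) {
    cm_stop("genotype must be a two-level contrast with declared levels",
            "invalid_label")
  }
  g <- as.numeric(labels == genotype_levels[2L])
  n <- length(g)
  nuisance <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (f in intersect(nuisance_factors, names(covariates))) {
    fac <- factor(covariates[[f]])
    if (nlevels(fac) < 2L) next
    mm <- stats::model.matrix(~fac)[, -1L, drop = FALSE]  # k-1 dummies
    colnames(mm) <- paste0(f, levels(fac)[-1L])
    nuisance <- cbind(nuisance, mm)
  }
  if (qr(nuisance)$rank < ncol(nuisance)) {
    cm_stop("nuisance design is rank deficient", "collinear_design")
  }
  gr <- stats::lm.fit(nuisance, g)$residuals
  if (sum(gr^2) < 1e-10 * max(sum(g^2), 1)) {
    cm_stop("genotype contrast is collinear with the nuisance block",
            "collinear_design")
  }
  structure(list(genotype = g, nuisance = nuisance,
                 genotype_levels = genotype_levels),
            class = "cm_covariates")
}

#' Partial effect of the genotype contrast on PC scores
#'
#' Double residualization (Frisch-Waugh): both the response block `Y` and the
#' genotype contrast are residualized on the nuisance design, then the
#' residual `Y` is regressed on the residual genotype.  With a single
#' contrast the partial-least-squares step coincides with least squares.
#' The partial effect size is the variance explained across all (normalized)
#' PC columns: `partial_R2 = ||fitted||^2 / ||Y_residual||^2`, identical to
#' `(SSE_reduced - SSE_full) / SSE_reduced`.
#'
#' @param Y `N x m` response matrix (normalized PC scores).
#' @param covariates a [covariate_design()].
#' @return list: `partial_R2`, `coefficients` (length-m genotype coefficient
#'   vector in PC-score space, per unit contrast), `Y_residual`,
#'   `genotype_residual`, `fitted`.
#' @export
partial_effect <- function(Y, covariates) {
  stopifnot(inherits(covariates, "cm_covariates"))
  Y <- as.matrix(Y)
  qn <- qr(covariates$nuisance)
  Yr <- qr.resid(qn, Y)
  gr <- qr.resid(qn, covariates$genotype)
  ssg <- sum(gr^2)
  if (ssg < 1e-12) {
    cm_stop("genotype contrast is collinear with the nuisance block",
            "collinear_design")
  }
  beta <- as.vector(crossprod(gr, Yr)) / ssg
  fitted <- outer(gr, beta)
  ssy <- sum(Yr^2)
  r2 <- if (ssy > 0) sum(fitted^2) / ssy else 0
  list(partial_R2 = r2, coefficients = beta, Y_residual = Yr,
       genotype_residual = gr, fitted = fitted)
}

#' Freedman-Lane permutation test of the global partial effect
#'
#' Permutes the nuisance-residualized genotype vector and recomputes the
#' partial R-squared for each permutation — including re-residualization of
#' the permuted vector on the nuisance design, so every permuted statistic is
#' computed exactly as the observed one and the nuisance structure (sex,
#' litter) is preserved under the null.
#' `p = (1 + #\{R2_perm >= R2_obs\}) / (1 + B)`, so the smallest attainable
#' p-value is `1 / (B + 1)`.
#'
#' @param Y `N x m` normalized score matrix.
#' @param covariates a [covariate_design()].
#' @param n_permutations number of permutations B (paper-scale default 10000).
#' @param seed integer seed (named substream `"perm"`).
#' @return list: `p`, `observed_R2`, `n_permutations`, `permuted_R2`.
#' @export
permutation_test <- function(Y, covariates, n_permutations = 10000L,
                             seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  fit <- partial_effect(Y, covariates)
  Yr <- fit$Y_residual
  gr <- fit$genotype_residual
  n <- length(gr)
  ssy <- sum(Yr^2)
  qn <- qr(covariates$nuisance)
  perm_r2 <- with_substream(seed, "perm", {
    G <- vapply(seq_len(n_permutations), function(b) gr[sample.int(n)],
                numeric(n))
    Gt <- qr.resid(qn, G)            # re-residualize every permuted contrast
    colSums((crossprod(Yr, Gt))^2) / (colSums(Gt^2) * ssy)
  })
  p <- (1 + sum(perm_r2 >= fit$partial_R2)) / (1 + n_permutations)
  list(p = p, observed_R2 = fit$partial_R2, n_permutations = n_permutations,
       permuted_R2 = perm_r2)
}

#' Per-vertex partial effects by reversing the PC projection
#'
#' Back-projects the (de-normalized) full-model and nuisance-only residuals
#' from PC space to vertex space through the retained components, then pools
#' the three coordinates of each vertex:
#' `R2[v] = (SSE_reduced[v] - SSE_full[v]) / SSE_reduced[v]`.
#' The genotype coefficient vector is back-projected the same way, giving the
#' shape change per unit genotype contrast at every vertex in aligned-shape
#' units.
#'
#' @param model a `cm_shape_model` from [fit_pca()].
#' @param covariates a [covariate_design()].
#' @return list: `per_vertex_R2` (length V), `coefficient_field` (`V x 3`).
#' @export
per_vertex_effects <- function(model, covariates) {
  stopifnot(inherits(model, "cm_shape_model"))
  m <- model$retained_m
  norm <- normalize_scores(model$scores)
  fit <- partial_effect(norm$scores, covariates)
  W <- model$components[seq_len(m), , drop = FALSE]   # m x 3V
  if (ncol(norm$scores) != m) {
    cm_stop("score/model dimension mismatch", "invalid_parameter")
  }
  denorm <- function(x) sweep(as.matrix(x), 2L, norm$sds, "*")
  E_red <- denorm(fit$Y_residual) %*% W
  E_full <- denorm(fit$Y_residual - fit$fitted) %*% W
  V <- ncol(W) / 3L
  pool <- function(E) colSums(matrix(colSums(E^2), 3L, V))
  sse_red <- pool(E_red)
  sse_full <- pool(E_full)
  r2 <- ifelse(sse_red > 1e-300, (sse_red - sse_full) / sse_red, 0)
  coef_flat <- as.vector((fit$coefficients * norm$sds) %*% W)
  list(per_vertex_R2 = r2,
       coefficient_field = matrix(coef_flat, ncol = 3L, byrow = TRUE))
}

#' Signed displacement along outward surface normals
#'
#' Projects a per-vertex displacement field onto the outward unit normals of
#' the mean shape: positive values are outward (protrusion, drawn red),
#' negative inward (depression, drawn blue).
#'
#' @param mean_shape `V x 3` vertex coordinates (typically the GPA mean).
#' @param faces `F x 3` triangle indices with outward orientation.
#' @param coefficient_field `V x 3` displacement field.
#' @return signed numeric vector of length V.
#' @export
normal_displacement <- function(mean_shape, faces, coefficient_field) {
  mesh <- cm_mesh(mean_shape, faces)
  if (nrow(coefficient_field) != nrow(mean_shape)) {
    cm_stop("coefficient field length mismatch", "invalid_parameter")
  }
  rowSums(as.matrix(coefficient_field) * vertex_normals(mesh))
}

#' Full genotype effect analysis of an aligned cohort
#'
#' Runs the statistical core end to end: PCA retention, score normalization,
#' global partial-R2 with Freedman-Lane permutation test, per-vertex effects,
#' and the signed normal-displacement map (when template faces are
#' available).
#'
#' @param aligned a `cm_aligned` from [gpa()] carrying its covariates, or an
#'   array plus an explicit `covariates` data.frame.
#' @param covariates data.frame with `genotype` (+ optional `sex`, `litter`);
#'   defaults to the cohort covariates stored in `aligned`.
#' @param genotype_levels `(reference, variant)` labels.
#' @param threshold PC variance-retention fraction (default 0.96).
#' @param n_permutations permutation count (default 10000).
#' @param seed integer seed.
#' @return object of class `cm_effect`: `global_partial_R2`, `global_p`,
#'   `n_permutations`, `retained_m`, `per_vertex_R2`, `coefficient_field`,
#'   `normal_displacement` (NULL without faces), `model`, `seed`.
#' @export
fit_genotype_effect <- function(aligned, covariates = NULL,
                                genotype_levels = NULL, threshold = 0.96,
                                n_permutations = 10000L, seed = 1L) {
  covariates <- covariates %||% aligned$covariates
  if (is.null(covariates)) {
    cm_stop("no covariate table available", "invalid_parameter")
  }
  design <- covariate_design(covariates, genotype_levels = genotype_levels)
  model <- fit_pca(aligned, threshold = threshold)
  norm <- normalize_scores(model$scores)
  perm <- permutation_test(norm$scores, design,
                           n_permutations = n_permutations, seed = seed)
  vert <- per_vertex_effects(model, design)
  nd <- NULL
  if (inherits(aligned, "cm_aligned") && !is.null(aligned$template)) {
    nd <- normal_displacement(aligned$mean_shape, aligned$template$faces,
                              vert$coefficient_field)
  }
  structure(list(global_partial_R2 = perm$observed_R2, global_p = perm$p,
                 n_permutations = perm$n_permutations,
                 retained_m = model$retained_m,
                 per_vertex_R2 = vert$per_vertex_R2,
                 coefficient_field = vert$coefficient_field,
                 normal_displacement = nd, model = model, seed = seed),
            class = "cm_effect")
}

#' @export
print.cm_effect <- function(x, ...) {
  cat(sprintf(paste0("<cm_effect> global partial R2 = %.4f, ",
                     "p = %.4g (%d permutations, %d PCs retained)\n"),
              x$global_partial_R2, x$global_p, x$n_permutations, x$retained_m))
  invisible(x)
}
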