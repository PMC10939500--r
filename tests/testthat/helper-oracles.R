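# Independent oracles and small fixtures used across test files.

# Brute-force partial R2: explicit normal-equation fits of the full design
# [nuisance | genotype] vs the nuisance-only design,
# R2 = (SSE_reduced - SSE_full) / SSE_reduced.  Shares no code with
# partial_effect().
oracle_partial_r2 <- function(Y, g, nuisance) {
  Y <- as.matrix(Y)
  sse <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, Y))
    sum((Y - X %*% beta)^2)
  }
  sse_red <- sse(nuisance)
  sse_full <- sse(cbind(nuisance, g))
  (sse_red - sse_full) / sse_red
}

# Dense-grid Procrustes oracle for two centered, unit-size planar shapes
# embedded at z = 0: minimum summed squared distance over in-plane rotations
# of shape b (both orientations, since a proper 3D rotation can realize an
# in-plane reflection of a planar shape).
oracle_planar_procrustes <- function(a, b, n_grid = 100000L) {
  best <- Inf
  angles <- seq(0, 2 * pi, length.out = n_grid)
  for (flip in c(1, -1)) {
    bf <- b
    bf[, 2] <- flip * bf[, 2]
    ca <- cos(angles); sa <- sin(angles)
    # ||a - bf R(theta)||^2 expanded: const - 2 trace(R' bf' a)
    m <- crossprod(bf, a)   # 3x3, planar so only 2x2 block matters
    tr <- ca * (m[1, 1] + m[2, 2]) + sa * (m[1, 2] - m[2, 1])
    d2 <- sum(a^2) + sum(bf^2) - 2 * max(tr)
    best <- min(best, d2)
  }
  sqrt(max(best, 0))
}

# deterministic planar shape at z = 0, centered, unit centroid size
planar_shape <- function(coords2d) {
  x <- cbind(coords2d, 0)
  x <- sweep(x, 2, colMeans(x))
  x / sqrt(sum(x^2))
}

# aligned-cohort array with exactly prescribed component variances:
# orthonormal axes Q (3V x k) and orthogonalized score columns rescaled to
# exact sds, so prcomp recovers `vars` up to float error.
make_variance_array <- function(vars, n = 24L, V = 6L, seed = 42L) {
  k <- length(vars)
  stopifnot(3L * V >= k, n > k + 1L)
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(3 * V * k), 3 * V, k)))
  S <- matrix(rnorm(n * k), n, k)
  S <- sweep(S, 2, colMeans(S))
  S <- qr.Q(qr(S)) * sqrt(n - 1)            # orthogonal, unit-variance columns
  S <- sweep(S, 2, sqrt(vars), "*")
  X <- S %*% t(Q)
  arr <- array(0, c(n, V, 3L))
  for (i in seq_len(n)) arr[i, , ] <- matrix(X[i, ], V, 3L, byrow = TRUE)
  arr
}

# small synthetic cohort shortcut used by several files
tiny_cohort <- function(n_per_group = 8L, amplitude = 0, noise_sd = 0.02,
                        litter_count = 2L, seed = 1L, resolution = 8L, ...) {
  tm <- make_template(resolution)
  patch <- vertex_patch(tm, 30L, rings = 2L)
  spec <- cohort_spec(n_per_group = n_per_group,
                      genotype_effect_amplitude = amplitude,
                      effect_patch = patch,
                      litter_count = litter_count, noise_sd = noise_sd,
                      seed = seed, ...)
  list(template = tm, patch = patch, cohort = generate_cohort(tm, spec))
}
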