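make_landmarks <- function(coords, names = paste0("L", seq_len(nrow(coords)))) {
  cm_landmarks(names, coords)
}

test_that("rigid initialization recovers exact and constructed transforms", {
  tm <- make_template(6)
  idx <- craniomorph:::template_landmark_indices(tm)
  src <- make_landmarks(tm$vertices[idx, ])

  fit <- rigid_initialize(src, src)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$scale, 1, tolerance = 1e-10)
  expect_lt(attr(fit, "rmse"), 1e-12)

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  truth <- cm_transform(rotation = rot90, translation = c(1, -2, 0.5),
                        scale = 2)
  tgt <- make_landmarks(apply_transform(src$coordinates, truth), src$names)
  fit <- rigid_initialize(src, tgt)
  expect_equal(fit$rotation, truth$rotation, tolerance = 1e-8)
  expect_equal(fit$translation, truth$translation, tolerance = 1e-8)
  expect_equal(fit$scale, truth$scale, tolerance = 1e-8)
  expect_lt(attr(fit, "rmse"), 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("degenerate or mismatched landmark configurations are rejected", {
  lin <- make_landmarks(cbind(1:4, 0, 0))
  expect_error(rigid_initialize(lin, lin), class = "degenerate_configuration")
  two <- make_landmarks(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(rigid_initialize(two, two), class = "degenerate_configuration")
  a <- make_landmarks(diag(3), c("a", "b", "c"))
  b <- make_landmarks(diag(3), c("a", "b", "d"))
  expect_error(rigid_initialize(a, b), class = "landmark_mismatch")
})

test_that("identity target registers to near-zero residual", {
  tm <- make_template(8)
  fit <- nonrigid_register(tm, tm, iterations = 5)
  expect_lt(fit$final_residual,
            1e-6 * craniomorph:::bbox_diagonal(tm$vertices))
  expect_true(fit$converged)
})

test_that("infinite smoothing bandwidth collapses to a global translation", {
  tm <- make_template(6)
  shifted <- cm_mesh(sweep(tm$vertices, 2, c(0.3, -0.1, 0.2), "+"), tm$faces)
  fit <- nonrigid_register(tm, shifted, iterations = 1, sigma_init = 1e8,
                           sigma_final = 1e8, step = 1)
  disp <- fit$mapped - tm$vertices
  spread <- apply(disp, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-8)
})

test_that("registration is equivariant under rigid motion of the target", {
  tm <- make_template(6)
  lm_idx <- craniomorph:::template_landmark_indices(tm)
  spec <- cohort_spec(n_per_group = 1, noise_sd = 0.01, decorrespond = TRUE,
                      apply_similarity_transforms = FALSE, seed = 4)
  coh <- generate_cohort(tm, spec)
  target <- coh$meshes[[1]]
  tlm <- coh$template_landmarks
  slm <- coh$landmarks[[1]]

  run <- function(tgt, lms) {
    init <- rigid_initialize(tlm, lms)
    nonrigid_register(tm, tgt, init, iterations = 10)$mapped
  }
  m1 <- run(target, slm)

  rot <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)  # axis permutation, det +1
  motion <- cm_transform(rotation = rot, translation = c(2, -1, 3), scale = 1)
  target2 <- cm_mesh(apply_transform(target$vertices, motion), target$faces)
  slm2 <- cm_landmarks(slm$names, apply_transform(slm$coordinates, motion))
  m2 <- run(target2, slm2)

  scale_ref <- max(abs(m2))
  expect_lt(max(abs(m2 - apply_transform(m1, motion))), 1e-6 * scale_ref)
})

test_that("residuals are non-increasing across nearly all iterations", {
  tm <- make_template(8)
  drops <- unlist(lapply(1:4, function(s) {
    spec <- cohort_spec(n_per_group = 1, noise_sd = 0.02, decorrespond = TRUE,
                        seed = s)
    coh <- generate_cohort(tm, spec)
    init <- rigid_initialize(coh$template_landmarks, coh$landmarks[[1]])
    fit <- nonrigid_register(tm, coh$meshes[[1]], init, iterations = 15)
    diff(fit$residuals) <= 1e-12
  }))
  expect_gte(mean(drops), 0.95)
})

test_that("build_cohort reproduces ground truth when correspondence is intact", {
  res <- tiny_cohort(n_per_group = 2, amplitude = 0.05, noise_sd = 0.01,
                     seed = 8, apply_similarity_transforms = TRUE)
  cc <- build_cohort(res$cohort, iterations = 10)
  # mapped vertices land on the target surface near (not exactly at) the true
  # corresponding vertices; the error scale is set by noise and smoothing
  med_edge <- median(edge_lengths(res$template))
  for (i in 1:4) {
    err <- mean(sqrt(rowSums((cc$coordinates[i, , ] -
                              res$cohort$coordinates[i, , ])^2)))
    expect_lt(err, med_edge / 2)
  }
  expect_identical(dim(cc$coordinates)[1], 4L)

  # with all perturbations off the recovery is exact up to float error
  clean <- tiny_cohort(n_per_group = c(1, 0), amplitude = 0, noise_sd = 0,
                       seed = 9, apply_similarity_transforms = TRUE)
  cc0 <- build_cohort(clean$cohort, iterations = 5)
  expect_lt(max(abs(cc0$coordinates[1, , ] - clean$cohort$coordinates[1, , ])),
            1e-8)
})

test_that("single-specimen cohorts and missing files are handled", {
  res <- tiny_cohort(n_per_group = c(1, 0), noise_sd = 0, seed = 3)
  cc <- build_cohort(res$cohort, iterations = 3)
  expect_identical(dim(cc$coordinates)[1], 1L)

  d <- withr::local_tempdir()
  manifest <- write_cohort(res$cohort, d)
  mf <- read_manifest(manifest)
  unlink(mf$mesh_path[1])
  expect_error(read_manifest(manifest), "S001", class = "io_error")
})
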