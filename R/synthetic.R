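#' Specification of a synthetic shape cohort
#'
#' Captures the statistical structure the downstream analysis assumes: a
#' localized genotype bump along outward normals, a smooth sex effect, smooth
#' per-litter random displacement fields, iid vertex noise, and optional
#' arbitrary similarity transforms and de-correspondence (remesh + vertex
#' shuffle) per specimen.
#'
#' @param n_per_group specimens per genotype group; a scalar (balanced) or a
#'   length-2 vector `c(n_reference, n_variant)` such as the 20 + 24 design.
#' @param genotype_effect_amplitude peak outward displacement (vertex units)
#'   of the genotype bump on `effect_patch`.
#' @param effect_patch integer vector of template vertex indices (a connected
#'   patch) supporting the genotype effect.
#' @param sex_effect_amplitude amplitude of the smooth sex displacement field.
#' @param litter_count number of litters (>= 1), assigned round-robin within
#'   each genotype group so litters span both groups.
#' @param litter_sd per-vertex standard deviation of the smooth per-litter
#'   random field.
#' @param noise_sd sd of iid Gaussian noise added to every vertex coordinate.
#' @param apply_similarity_transforms randomly rotate/translate/scale each
#'   specimen.
#' @param decorrespond remesh (midpoint subdivision) and randomly reorder
#'   vertices so specimens no longer share the template topology.
#' @param seed master seed; all randomness flows from it via named substreams.
#' @return object of class `cm_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L,
                        genotype_effect_amplitude = 0,
                        effect_patch = integer(0),
                        sex_effect_amplitude = 0,
                        litter_count = 1L,
                        litter_sd = 0,
                        noise_sd = 0,
                        apply_similarity_transforms = TRUE,
                        decorrespond = FALSE,
                        seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (length(n_per_group) != 2L) {
    cm_stop("n_per_group must have length 1 or 2", "invalid_parameter")
  }
  n_per_group <- vapply(seq_along(n_per_group), function(i)
    check_count(n_per_group[i], "n_per_group"), integer(1))
  structure(list(
    n_per_group = n_per_group,
    genotype_effect_amplitude = check_number(genotype_effect_amplitude,
                                             "genotype_effect_amplitude"),
    effect_patch = as.integer(effect_patch),
    sex_effect_amplitude = check_number(sex_effect_amplitude,
                                        "sex_effect_amplitude"),
    litter_count = check_count(litter_count, "litter_count", min = 1L),
    litter_sd = check_number(litter_sd, "litter_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    apply_similarity_transforms = check_flag(apply_similarity_transforms,
                                             "apply_similarity_transforms"),
    decorrespond = check_flag(decorrespond, "decorrespond"),
    seed = check_count(seed, "seed")
  ), class = "cm_cohort_spec")
}

# landmark vertices: poles plus coordinate extremes, deduplicated
template_landmark_indices <- function(template) {
  v <- template$vertices
  idx <- unique(c(which.max(v[, 3L]), which.min(v[, 3L]),
                  which.max(v[, 1L]), which.min(v[, 1L]),
                  which.max(v[, 2L]), which.min(v[, 2L]),
                  which.max(v[, 1L] + v[, 2L]), which.min(v[, 1L] + v[, 2L])))
  sort(idx)
}

#' Generate a synthetic corresponded cohort with ground truth
#'
#' Each specimen's shape is `template + genotype * bump + sex * sex_field +
#' litter_field + noise`, optionally followed by a random similarity
#' transform and de-correspondence.  The genotype bump is a smoothly tapered
#' outward-normal displacement supported exactly on `spec$effect_patch`.
#' Genotype, sex, and litter labels are returned as a covariate table;
#' ground truth (per-specimen transforms, correspondence maps, and the true
#' genotype effect field) supports parameter-recovery studies.
#'
#' @param template a [cm_mesh] (see [make_template()]).
#' @param spec a [cohort_spec()].
#' @return object of class `cm_cohort`: list with `coordinates`
#'   (`N x V x 3` true corresponded coordinates), `meshes` (per-specimen
#'   [cm_mesh], de-corresponded if requested), `landmarks` (per-specimen
#'   [cm_landmarks] in specimen frame), `template_landmarks`, `covariates`
#'   (data.frame: specimen_id, genotype, sex, litter), and `ground_truth`.
#' @export
generate_cohort <- function(template, spec) {
  stopifnot(inherits(template, "cm_mesh"), inherits(spec, "cm_cohort_spec"))
  n0 <- spec$n_per_group[1L]; n1 <- spec$n_per_group[2L]
  N <- n0 + n1
  if (N == 0L) cm_stop("empty cohort: n_per_group is zero", "empty_cohort")
  if (spec$genotype_effect_amplitude != 0 && length(spec$effect_patch) == 0L) {
    cm_stop("nonzero genotype amplitude requires a non-empty effect_patch",
            "invalid_parameter")
  }
  V <- nrow(template$vertices)
  if (length(spec$effect_patch) &&
      (min(spec$effect_patch) < 1L || max(spec$effect_patch) > V)) {
    cm_stop("effect_patch indices out of range", "invalid_parameter")
  }

  normals <- vertex_normals(template)

  # design: genotype blocks, litters round-robin within block, sexes alternate
  genotype <- c(rep("WT", n0), rep("VAR", n1))
  litter <- c(if (n0) paste0("L", ((seq_len(n0) - 1L) %% spec$litter_count) + 1L),
              if (n1) paste0("L", ((seq_len(n1) - 1L) %% spec$litter_count) + 1L))
  sex <- c(if (n0) rep_len(c("M", "F"), n0), if (n1) rep_len(c("F", "M"), n1))
  covariates <- data.frame(
    specimen_id = sprintf("S%03d", seq_len(N)),
    genotype = genotype, sex = sex, litter = litter,
    stringsAsFactors = FALSE
  )

  # genotype effect: tapered bump along outward normals, zero off the patch
  effect_field <- matrix(0, V, 3L)
  if (length(spec$effect_patch)) {
    prof <- patch_profile(template, spec$effect_patch)
    effect_field <- spec$genotype_effect_amplitude * prof * normals
  }

  # sex effect: smooth deterministic field along normals
  xs <- template$vertices[, 1L]
  sex_field <- spec$sex_effect_amplitude *
    sin(pi * (xs - min(xs)) / diff(range(xs))) * normals

  # litter effects: smooth random fields on a coarse Gaussian spatial basis
  litter_fields <- rep(list(matrix(0, V, 3L)), spec$litter_count)
  if (spec$litter_sd > 0) {
    with_substream(spec$seed, "litter", {
      centers <- template$vertices[sample.int(V, min(10L, V)), , drop = FALSE]
      d2 <- outer(rowSums(template$vertices^2), rowSums(centers^2), "+") -
        2 * template$vertices %*% t(centers)
      phi <- exp(-pmax(d2, 0) / (2 * 0.5^2))
      phi <- phi / sqrt(rowSums(phi^2))     # unit row norm => per-vertex sd = litter_sd
      for (l in seq_len(spec$litter_count)) {
        coefs <- matrix(rnorm(ncol(phi) * 3L, sd = spec$litter_sd), ncol = 3L)
        litter_fields[[l]] <- phi %*% coefs
      }
    })
  }

  noise <- if (spec$noise_sd > 0) {
    with_substream(spec$seed, "noise",
                   array(rnorm(N * V * 3L, sd = spec$noise_sd), c(V, 3L, N)))
  } else array(0, c(V, 3L, N))

  transforms <- if (spec$apply_similarity_transforms) {
    with_substream(spec$seed, "transforms",
                   lapply(seq_len(N), function(i) random_transform()))
  } else rep(list(cm_transform()), N)

  lm_idx <- template_landmark_indices(template)
  lm_names <- paste0("LM", seq_along(lm_idx))

  g_num <- as.numeric(genotype == "VAR")
  s_num <- as.numeric(sex == "F")
  lit_num <- as.integer(sub("^L", "", litter))

  coords <- array(NA_real_, c(N, V, 3L),
                  dimnames = list(covariates$specimen_id, NULL, NULL))
  meshes <- vector("list", N)
  landmarks <- vector("list", N)
  correspondence <- vector("list", N)

  decor_perms <- if (spec$decorrespond) {
    # subdivided meshes share vertex count; draw all permutations up front
    Vd <- V + nrow(mesh_edges(template))
    with_substream(spec$seed, "decorrespond",
                   lapply(seq_len(N), function(i)
                     list(vp = sample.int(Vd), fp = sample.int(4L * nrow(template$faces)))))
  } else NULL

  for (i in seq_len(N)) {
    shape <- template$vertices +
      g_num[i] * effect_field +
      s_num[i] * sex_field +
      litter_fields[[lit_num[i]]] +
      noise[, , i]
    shape <- apply_transform(shape, transforms[[i]])
    coords[i, , ] <- shape
    landmarks[[i]] <- cm_landmarks(lm_names, shape[lm_idx, , drop = FALSE])
    if (spec$decorrespond) {
      fine <- subdivide_mesh(cm_mesh(shape, template$faces, units = template$units))
      vp <- decor_perms[[i]]$vp          # vp[new] = old
      inv <- integer(length(vp)); inv[vp] <- seq_along(vp)   # inv[old] = new
      fverts <- fine$vertices[vp, , drop = FALSE]
      ffaces <- matrix(inv[fine$faces], ncol = 3L)[decor_perms[[i]]$fp, , drop = FALSE]
      meshes[[i]] <- cm_mesh(fverts, ffaces, units = template$units)
      correspondence[[i]] <- inv[seq_len(V)]   # template vertex v -> mesh vertex
    } else {
      meshes[[i]] <- cm_mesh(shape, template$faces, units = template$units)
      correspondence[[i]] <- seq_len(V)
    }
  }

  structure(list(
    template = template,
    coordinates = coords,
    meshes = meshes,
    landmarks = landmarks,
    template_landmarks = cm_landmarks(lm_names,
                                      template$vertices[lm_idx, , drop = FALSE]),
    covariates = covariates,
    ground_truth = list(transforms = transforms,
                        correspondence = correspondence,
                        effect_field = effect_field,
                        landmark_indices = lm_idx),
    spec = spec
  ), class = "cm_cohort")
}

#' Write a cohort to disk as OBJ meshes, landmark CSVs, and a manifest
#'
#' @param cohort a `cm_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- cohort$covariates
  mesh_paths <- sprintf("%s.obj", cov$specimen_id)
  lm_paths <- sprintf("%s_landmarks.csv", cov$specimen_id)
  for (i in seq_len(nrow(cov))) {
    write_obj(cohort$meshes[[i]], file.path(dir, mesh_paths[i]))
    write_landmarks_csv(cohort$landmarks[[i]], file.path(dir, lm_paths[i]))
  }
  write_obj(cohort$template, file.path(dir, "template.obj"))
  write_landmarks_csv(cohort$template_landmarks,
                      file.path(dir, "template_landmarks.csv"))
  manifest <- data.frame(specimen_id = cov$specimen_id,
                         mesh_path = mesh_paths,
                         landmark_path = lm_paths,
                         genotype = cov$genotype, sex = cov$sex,
                         litter = cov$litter, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(landmark_indices = gt$landmark_indices,
         effect_field = gt$effect_field,
         transforms = lapply(gt$transforms, function(tr)
           list(rotation = tr$rotation, translation = tr$translation,
                scale = tr$scale))),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(mpath)
}

#' Simulate droplet-digital PCR counts for a two-allele duplex assay
#'
#' `total_molecules` template molecules, a fraction `allele_fraction` of them
#' allele 1 (FAM) and the rest allele 2 (HEX), are distributed uniformly at
#' random over `droplets` partitions.  A droplet is FAM-positive if it holds
#' at least one allele-1 molecule and HEX-positive if it holds at least one
#' allele-2 molecule (double positives count in both channels).
#'
#' @param total_molecules total template molecule count.
#' @param allele_fraction probability a molecule is allele 1, in `[0, 1]`.
#' @param droplets number of droplets (>= 1).
#' @param seed integer seed.
#' @return a [droplet_counts()] object.
#' @export
simulate_ddpcr <- function(total_molecules, allele_fraction, droplets, seed = 1L) {
  total_molecules <- check_count(total_molecules, "total_molecules")
  droplets <- check_count(droplets, "droplets", min = 1L)
  if (!is.numeric(allele_fraction) || length(allele_fraction) != 1L ||
      is.na(allele_fraction) || allele_fraction < 0 || allele_fraction > 1) {
    cm_stop("allele_fraction must be in [0, 1]", "invalid_parameter")
  }
  with_substream(seed, "ddpcr", {
    n1 <- rbinom(1L, total_molecules, allele_fraction)
    n2 <- total_molecules - n1
    occupied <- function(n) {
      if (n == 0L) return(0L)
      length(unique(sample.int(droplets, n, replace = TRUE)))
    }
    droplet_counts(droplets, occupied(n1), occupied(n2))
  })
}
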