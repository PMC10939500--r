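#' Least-squares similarity alignment of two landmark sets
#'
#' Orthogonal Procrustes fit: the similarity transform (proper rotation,
#' translation, isotropic scale) minimizing the summed squared distances from
#' transformed template landmarks to target landmarks.  Landmarks are matched
#' by name; both sets must share at least 3 non-collinear landmarks.
#'
#' @param template_landmarks,target_landmarks [cm_landmarks] objects with the
#'   same names.
#' @return a [cm_transform] with attributes `rmse` (root-mean-square residual
#'   after alignment).
#' @export
rigid_initialize <- function(template_landmarks, target_landmarks) {
  stopifnot(inherits(template_landmarks, "cm_landmarks"),
            inherits(target_landmarks, "cm_landmarks"))
  if (!setequal(template_landmarks$names, target_landmarks$names)) {
    cm_stop("landmark name sets differ", "landmark_mismatch")
  }
  k <- length(template_landmarks$names)
  if (k < 3L) cm_stop("need at least 3 landmarks", "degenerate_configuration")
  x <- template_landmarks$coordinates
  y <- target_landmarks$coordinates[match(template_landmarks$names,
                                          target_landmarks$names), , drop = FALSE]
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2L, mx); yc <- sweep(y, 2L, my)
  if (svd(xc)$d[2L] < 1e-10 * max(svd(xc)$d[1L], 1e-300)) {
    cm_stop("landmarks are collinear: similarity fit is degenerate",
            "degenerate_configuration")
  }
  # Umeyama similarity fit
  s <- svd(crossprod(yc, xc))         # t(yc) %*% xc = U D t(V)
  d <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  rot <- s$u %*% d %*% t(s$v)
  scale <- sum(diag(d) * s$d) / sum(xc^2)
  trans <- my - scale * as.vector(rot %*% mx)
  out <- cm_transform(rotation = rot, translation = trans, scale = scale)
  resid <- apply_transform(x, out) - y
  attr(out, "rmse") <- sqrt(mean(rowSums(resid^2)))
  out
}

# closest points on a target surface for a matrix of query points
closest_on_surface <- function(points, target) {
  if (nrow(target$faces) == 0L) cm_stop("empty target surface", "invalid_mesh")
  cpp_closest_on_mesh(points, target$vertices, target$faces)
}

#' Non-rigid registration of a template onto a target surface
#'
#' Iterative closest-point refinement with spatial smoothing: at each
#' iteration every (transformed) template vertex is pulled a fraction `step`
#' toward its nearest point on the target surface, after Gaussian smoothing
#' of the raw displacement field over edge-graph (geodesic approximation)
#' distances on the template.  The smoothing bandwidth is annealed
#' geometrically from `sigma_init` to `sigma_final`, so early iterations move
#' the template near-rigidly and later iterations recover local detail.
#' Deterministic given its inputs.
#'
#' @param template a [cm_mesh].
#' @param target a [cm_mesh] (any topology; queries are point-to-triangle).
#' @param init_transform a [cm_transform] applied to the template first
#'   (typically from [rigid_initialize()]).
#' @param iterations number of update iterations.
#' @param sigma_init,sigma_final smoothing bandwidths in template edge-length
#'   units (scaled internally by the mean edge length).
#' @param step fraction of the smoothed displacement applied per iteration,
#'   in (0, 1].
#' @return list with `mapped` (V x 3 registered vertex positions, template
#'   topology), `residuals` (mean vertex-to-surface distance per iteration),
#'   `final_residual`, and `converged` (FALSE if the residual failed to
#'   decrease over a 5-iteration patience window).
#' @export
nonrigid_register <- function(template, target, init_transform = cm_transform(),
                              iterations = 30L, sigma_init = 8,
                              sigma_final = 0.8, step = 0.5) {
  stopifnot(inherits(template, "cm_mesh"), inherits(target, "cm_mesh"),
            inherits(init_transform, "cm_transform"))
  iterations <- check_count(iterations, "iterations", min = 1L)
  sigma_init <- check_number(sigma_init, "sigma_init")
  sigma_final <- check_number(sigma_final, "sigma_final")
  step <- check_number(step, "step")
  if (sigma_init <= 0 || sigma_final <= 0 || step <= 0 || step > 1) {
    cm_stop("sigma and step parameters must be positive (step <= 1)",
            "invalid_parameter")
  }
  if (nrow(target$faces) == 0L) cm_stop("empty target surface", "invalid_mesh")

  x <- apply_transform(template$vertices, init_transform)
  # geodesic approximation: shortest paths on the (transformed) edge graph
  scaled <- cm_mesh(x, template$faces)
  g <- mesh_graph(scaled, weighted = TRUE)
  gd <- igraph::distances(g)
  unit <- mean(edge_lengths(scaled))
  sigmas <- exp(seq(log(sigma_init), log(sigma_final),
                    length.out = iterations)) * unit

  residuals <- numeric(iterations)
  for (it in seq_len(iterations)) {
    cp <- closest_on_surface(x, target)
    residuals[it] <- mean(cp$distance)
    disp <- cp$points - x
    w <- exp(-gd^2 / (2 * sigmas[it]^2))
    w <- w / rowSums(w)
    x <- x + step * (w %*% disp)
  }
  cp <- closest_on_surface(x, target)
  final_residual <- mean(cp$distance)

  converged <- TRUE
  patience <- 5L
  if (iterations > patience) {
    tail_window <- residuals[(iterations - patience):iterations]
    if (min(tail_window) > min(residuals[1:(iterations - patience)]) *
        (1 + 1e-9)) {
      converged <- FALSE
    }
  }
  list(mapped = x, residuals = c(residuals, final_residual),
       final_residual = final_residual, converged = converged)
}

#' Register every specimen in a manifest to the template
#'
#' Runs [rigid_initialize()] (from per-specimen landmark files) followed by
#' [nonrigid_register()] for each manifest row, producing the corresponded
#' cohort: every specimen expressed in the template's vertex topology.
#'
#' @param manifest a `cm_manifest` from [read_manifest()], or a `cm_cohort`
#'   from [generate_cohort()] (registered in memory, no files needed).
#' @param template a [cm_mesh]; for a `cm_cohort` defaults to its own template.
#' @param template_landmarks [cm_landmarks] on the template (defaults to the
#'   cohort's when a `cm_cohort` is given).
#' @param ... registration parameters passed to [nonrigid_register()].
#' @return object of class `cm_corresponded`: `coordinates` (`N x V x 3`),
#'   `specimen_id`, `covariates`, `template`, and per-specimen `diagnostics`
#'   (final residual, convergence flag, rigid RMSE).
#' @export
build_cohort <- function(manifest, template = NULL, template_landmarks = NULL,
                         ...) {
  if (inherits(manifest, "cm_cohort")) {
    cohort <- manifest
    template <- template %||% cohort$template
    template_landmarks <- template_landmarks %||% cohort$template_landmarks
    ids <- cohort$covariates$specimen_id
    covariates <- cohort$covariates
    get_specimen <- function(i) list(mesh = cohort$meshes[[i]],
                                     landmarks = cohort$landmarks[[i]],
                                     id = ids[i])
    n <- length(ids)
  } else if (inherits(manifest, "cm_manifest")) {
    if (is.null(template) || is.null(template_landmarks)) {
      cm_stop("template and template_landmarks are required with a manifest",
              "invalid_parameter")
    }
    ids <- manifest$specimen_id
    covariates <- as.data.frame(manifest)[, c("specimen_id", "genotype",
                                              "sex", "litter")]
    get_specimen <- function(i) {
      if (!file.exists(manifest$mesh_path[i])) {
        cm_stop(paste0("cannot load mesh for specimen ", ids[i]), "io_error")
      }
      list(mesh = read_obj(manifest$mesh_path[i]),
           landmarks = read_landmarks_csv(manifest$landmark_path[i]),
           id = ids[i])
    }
    n <- nrow(manifest)
  } else {
    cm_stop("manifest must be a cm_manifest or cm_cohort", "invalid_parameter")
  }

  V <- nrow(template$vertices)
  coords <- array(NA_real_, c(n, V, 3L), dimnames = list(ids, NULL, NULL))
  diagnostics <- data.frame(specimen_id = ids, rigid_rmse = NA_real_,
                            final_residual = NA_real_, converged = NA)
  for (i in seq_len(n)) {
    sp <- get_specimen(i)
    init <- tryCatch(rigid_initialize(template_landmarks, sp$landmarks),
                     error = function(e) {
                       cm_stop(paste0("rigid initialization failed for specimen ",
                                      sp$id, ": ", conditionMessage(e)),
                               "registration_error")
                     })
    fit <- nonrigid_register(template, sp$mesh, init, ...)
    coords[i, , ] <- fit$mapped
    diagnostics$rigid_rmse[i] <- attr(init, "rmse")
    diagnostics$final_residual[i] <- fit$final_residual
    diagnostics$converged[i] <- fit$converged
  }
  structure(list(coordinates = coords, specimen_id = ids,
                 covariates = covariates, template = template,
                 diagnostics = diagnostics),
            class = "cm_corresponded")
}

#' Treat a generated cohort's true coordinates as a corresponded cohort
#'
#' When a synthetic cohort is generated without de-correspondence its true
#' vertex coordinates already share the template topology; this adapter skips
#' the (expensive, unnecessary) registration stage.
#'
#' @param cohort a `cm_cohort`.
#' @return a `cm_corresponded`.
#' @export
as_corresponded <- function(cohort) {
  stopifnot(inherits(cohort, "cm_cohort"))
  structure(list(coordinates = cohort$coordinates,
                 specimen_id = cohort$covariates$specimen_id,
                 covariates = cohort$covariates,
                 template = cohort$template,
                 diagnostics = NULL),
            class = "cm_corresponded")
}
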