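#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the vertices to their
#' centroid — the size measure removed by Procrustes scaling.
#'
#' @param shape numeric `V x 3` matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(shape) {
  shape <- as.matrix(shape)
  if (!all(is.finite(shape))) cm_stop("non-finite coordinates", "invalid_parameter")
  cs <- sqrt(sum(sweep(shape, 2L, colMeans(shape))^2))
  if (cs < 1e-300) {
    cm_stop("zero centroid size: all vertices coincident", "degenerate_shape")
  }
  cs
}

# proper rotation R (det +1) minimizing || X %*% R - M ||_F
opa_rotation <- function(x, m) {
  s <- svd(crossprod(x, m))
  d <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% d %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Removes position, scale, and orientation from a corresponded cohort:
#' every shape is centered, scaled to unit centroid size, and rotated
#' (proper rotations only — reflections are disallowed, bones are chiral) to
#' the evolving mean, which is itself renormalized to unit size each round.
#' Iterates until the mean moves less than `tol` or `max_iter` is reached.
#'
#' @param cohort a `cm_corresponded` (from [build_cohort()] or
#'   [as_corresponded()]) or an `N x V x 3` array.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   mean shape.
#' @param max_iter iteration cap.
#' @return object of class `cm_aligned`: `shapes` (`N x V x 3`, each with
#'   centroid at the origin and unit centroid size), `centroid_sizes`
#'   (original sizes), `mean_shape` (`V x 3`, coordinate-wise mean of the
#'   aligned shapes), `iterations`, `specimen_id`, `covariates`, `template`.
#' @export
gpa <- function(cohort, tol = 1e-10, max_iter = 100L) {
  if (inherits(cohort, "cm_corresponded")) {
    arr <- cohort$coordinates
    ids <- cohort$specimen_id
    covariates <- cohort$covariates
    template <- cohort$template
  } else {
    arr <- cohort
    ids <- dimnames(arr)[[1L]]
    covariates <- NULL
    template <- NULL
  }
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3L] == 3L)
  n <- dim(arr)[1L]
  if (n < 1L) cm_stop("empty cohort", "empty_cohort")
  tol <- check_number(tol, "tol")
  max_iter <- check_count(max_iter, "max_iter", min = 1L)

  sizes <- numeric(n)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    x <- arr[i, , ]
    x <- sweep(x, 2L, colMeans(x))
    sizes[i] <- tryCatch(centroid_size(x), error = function(e) {
      cm_stop(paste0("degenerate shape for specimen ",
                     if (!is.null(ids)) ids[i] else i), "degenerate_shape")
    })
    shapes[[i]] <- x / sizes[i]
  }

  mean_shape <- Reduce(`+`, shapes) / n
  mean_shape <- mean_shape / centroid_size(mean_shape)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) shapes[[i]] <- shapes[[i]] %*% opa_rotation(shapes[[i]], mean_shape)
    new_mean <- Reduce(`+`, shapes) / n
    new_mean <- new_mean / centroid_size(new_mean)
    change <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (change < tol || iterations >= max_iter) break
  }

  out <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) out[i, , ] <- shapes[[i]]
  structure(list(shapes = out, centroid_sizes = sizes,
                 mean_shape = Reduce(`+`, shapes) / n,
                 iterations = iterations, specimen_id = ids,
                 covariates = covariates, template = template),
            class = "cm_aligned")
}

#' @export
print.cm_aligned <- function(x, ...) {
  cat(sprintf("<cm_aligned> %d shapes x %d vertices (GPA, %d iterations)\n",
              dim(x$shapes)[1L], dim(x$shapes)[2L], x$iterations))
  invisible(x)
}

#' Full Procrustes distance between two aligned shapes
#'
#' @param a,b `V x 3` matrices (assumed centered, unit size).
#' @return root summed squared distance after optimal rotation of `a` to `b`.
#' @export
procrustes_distance <- function(a, b) {
  sqrt(sum((a %*% opa_rotation(a, b) - b)^2))
}
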