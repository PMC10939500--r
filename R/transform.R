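#' Similarity transform (rotation, translation, isotropic scale)
#'
#' Represents `x -> scale * x %*% t(rotation) + translation` with a proper
#' rotation (determinant +1).
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector.
#' @param scale positive scalar.
#' @return object of class `cm_transform`.
#' @export
cm_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                         scale = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0) {
    cm_stop("rotation must be a 3x3 proper orthogonal matrix",
            "invalid_parameter")
  }
  scale <- check_number(scale, "scale")
  if (scale <= 0) cm_stop("scale must be > 0", "invalid_parameter")
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale),
            class = "cm_transform")
}

#' Apply a similarity transform to a point set
#'
#' @param points numeric `n x 3` matrix.
#' @param transform a [cm_transform].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(points, transform) {
  points <- as.matrix(points)
  sweep(transform$scale * points %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

#' @export
print.cm_transform <- function(x, ...) {
  cat(sprintf("<cm_transform> scale %.4g, translation (%.4g, %.4g, %.4g)\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# random proper rotation via QR of a Gaussian matrix (Haar-ish; adequate here)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

random_transform <- function(scale_range = c(0.9, 1.1), translation_sd = 0.5) {
  cm_transform(rotation = random_rotation(),
               translation = rnorm(3, sd = translation_sd),
               scale = runif(1, scale_range[1], scale_range[2]))
}
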