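#' Triangle mesh container
#'
#' A minimal triangulated-surface container used throughout the package:
#' `vertices` is a numeric `V x 3` matrix of coordinates and `faces` an
#' integer `F x 3` matrix of 1-based vertex indices with consistent
#' counter-clockwise winding (outward normals).  `units` is an opaque length
#' unit label carried through I/O (default `"um"`); no conversion is ever
#' attempted.
#'
#' @param vertices numeric `V x 3` matrix.
#' @param faces integer `F x 3` matrix of 1-based indices.
#' @param units length unit label.
#' @return an object of class `cm_mesh`.
#' @export
cm_mesh <- function(vertices, faces, units = "um") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) cm_stop("vertices must be V x 3", "invalid_mesh")
  if (ncol(faces) != 3L) cm_stop("faces must be F x 3", "invalid_mesh")
  if (!all(is.finite(vertices))) cm_stop("non-finite vertex coordinates", "invalid_mesh")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    cm_stop("face indices out of range", "invalid_mesh")
  }
  structure(list(vertices = vertices, faces = faces, units = units),
            class = "cm_mesh")
}

#' @export
print.cm_mesh <- function(x, ...) {
  cat(sprintf("<cm_mesh> %d vertices, %d faces (units: %s)\n",
              nrow(x$vertices), nrow(x$faces), x$units))
  invisible(x)
}

#' Generate the bone-like template surface
#'
#' Builds a closed genus-0 surface standing in for a segmented cranial bone:
#' a latitude/longitude sphere triangulation flattened anisotropically
#' (half-axes 1.0, 0.65, 0.45) with a smooth midline ridge, giving an
#' elongated, dorsoventrally flattened shell roughly 2 length units long.
#' Deterministic for fixed `resolution`; vertex count grows as
#' `(resolution - 1) * 2 * resolution + 2`.
#'
#' @param resolution integer >= 3; number of latitude bands (longitude bands
#'   are twice this).
#' @return a [cm_mesh] with outward-oriented faces.
#' @examples
#' tm <- make_template(8)
#' nrow(tm$vertices)
#' @export
make_template <- function(resolution) {
  resolution <- check_count(resolution, "resolution")
  if (resolution < 3L) {
    cm_stop("resolution must be >= 3", "invalid_parameter")
  }
  nlat <- resolution
  nlon <- 2L * resolution

  idx <- function(i, j) 1L + (i - 1L) * nlon + (j %% nlon) + 1L
  npole <- 1L
  spole <- (nlat - 1L) * nlon + 2L

  theta <- pi * seq_len(nlat - 1L) / nlat
  phi <- 2 * pi * (0:(nlon - 1L)) / nlon
  v <- matrix(0, spole, 3L)
  v[npole, ] <- c(0, 0, 1)
  v[spole, ] <- c(0, 0, -1)
  for (i in seq_len(nlat - 1L)) {
    v[idx(i, 0:(nlon - 1L)), ] <- cbind(sin(theta[i]) * cos(phi),
                                        sin(theta[i]) * sin(phi),
                                        cos(theta[i]))
  }

  faces <- vector("list", nlat)
  j <- 0:(nlon - 1L)
  faces[[1L]] <- cbind(npole, idx(1L, j), idx(1L, j + 1L))
  if (nlat > 2L) {
    for (i in seq_len(nlat - 2L)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
      faces[[i + 1L]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
    }
  }
  faces[[nlat]] <- cbind(spole, idx(nlat - 1L, j + 1L), idx(nlat - 1L, j))
  f <- do.call(rbind, faces)
  dimnames(f) <- NULL

  # flatten into a bone-like shell and raise a smooth midline ridge
  v <- v %*% diag(c(1.0, 0.65, 0.45))
  v[, 3L] <- v[, 3L] + 0.18 * exp(-(v[, 2L] / 0.25)^2 - (v[, 1L] / 0.7)^2)

  m <- cm_mesh(v, f)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    n / pmax(len, .Machine$double.eps)
  } else {
    n  # magnitude = 2 * face area (area weighting for free)
  }
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized per vertex.
#'
#' @param mesh a [cm_mesh].
#' @return numeric `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE)
  V <- nrow(mesh$vertices)
  n <- matrix(0, V, 3L)
  for (k in 1:3) {
    n[, 1L] <- n[, 1L] + tabulate2(mesh$faces[, k], fn[, 1L], V)
    n[, 2L] <- n[, 2L] + tabulate2(mesh$faces[, k], fn[, 2L], V)
    n[, 3L] <- n[, 3L] + tabulate2(mesh$faces[, k], fn[, 3L], V)
  }
  len <- sqrt(rowSums(n^2))
  if (any(len < 1e-300)) {
    cm_stop("degenerate vertex star: zero normal", "degenerate_mesh")
  }
  n / len
}

# weighted tabulate: sum w over bins (empty bins contribute 0)
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Euler characteristic of a mesh (V - E + F)
#'
#' Equals 2 for a closed genus-0 surface.
#'
#' @param mesh a [cm_mesh].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Edge lengths of a mesh
#'
#' @param mesh a [cm_mesh].
#' @return numeric vector, one length per unique undirected edge.
#' @export
edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                mesh$vertices[e[, 2L], , drop = FALSE])^2))
}

bbox_diagonal <- function(vertices) {
  r <- apply(vertices, 2L, range)
  sqrt(sum((r[2L, ] - r[1L, ])^2))
}

mesh_graph <- function(mesh, weighted = TRUE) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (weighted) {
    igraph::E(g)$weight <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                                         mesh$vertices[e[, 2L], , drop = FALSE])^2))
  }
  g
}

#' Connected vertex patch grown from a seed vertex
#'
#' Breadth-first k-ring neighborhood on the mesh edge graph; used to define
#' the support of localized synthetic effects.
#'
#' @param mesh a [cm_mesh].
#' @param seed_vertex 1-based vertex index.
#' @param rings number of edge rings to grow (0 = the seed alone).
#' @return sorted integer vector of vertex indices (always includes the seed).
#' @export
vertex_patch <- function(mesh, seed_vertex, rings = 2L) {
  seed_vertex <- check_count(seed_vertex, "seed_vertex", min = 1L)
  rings <- check_count(rings, "rings")
  if (seed_vertex > nrow(mesh$vertices)) {
    cm_stop("seed_vertex out of range", "invalid_parameter")
  }
  g <- mesh_graph(mesh, weighted = FALSE)
  d <- igraph::distances(g, v = seed_vertex)
  sort(which(d[1L, ] <= rings))
}

#' Dilate a vertex patch by k edge rings
#'
#' @param mesh a [cm_mesh].
#' @param patch integer vector of vertex indices.
#' @param rings number of rings to add.
#' @return sorted integer vector containing `patch` and its ring neighbors.
#' @export
dilate_patch <- function(mesh, patch, rings = 1L) {
  rings <- check_count(rings, "rings")
  g <- mesh_graph(mesh, weighted = FALSE)
  d <- igraph::distances(g, v = patch)
  sort(which(apply(d, 2L, min) <= rings))
}

# Smooth taper over a patch: BFS depth from the patch boundary, normalized to
# max 1 at the patch interior.  Zero outside the patch by construction.
patch_profile <- function(mesh, patch) {
  V <- nrow(mesh$vertices)
  prof <- numeric(V)
  outside <- setdiff(seq_len(V), patch)
  if (length(outside) == 0L) {
    prof[] <- 1
    return(prof)
  }
  g <- mesh_graph(mesh, weighted = FALSE)
  d <- igraph::distances(g, v = outside, to = patch)
  depth <- apply(d, 2L, min)          # >= 1 inside the patch
  prof[patch] <- depth / max(depth)
  prof
}

#' Midpoint subdivision of a triangle mesh
#'
#' Splits every triangle into four by inserting edge midpoints.  The original
#' vertices keep their indices (`1:V`); this exact containment is what the
#' synthetic de-correspondence pipeline uses as ground truth.
#'
#' @param mesh a [cm_mesh].
#' @return a finer [cm_mesh].
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  V <- nrow(v)
  e <- mesh_edges(mesh)
  key <- function(a, b) pmin(a, b) * (V + 1L) + pmax(a, b)
  mid_index <- V + seq_len(nrow(e))
  names(mid_index) <- as.character(key(e[, 1L], e[, 2L]))
  mid <- (v[e[, 1L], , drop = FALSE] + v[e[, 2L], , drop = FALSE]) / 2
  m12 <- mid_index[as.character(key(f[, 1L], f[, 2L]))]
  m23 <- mid_index[as.character(key(f[, 2L], f[, 3L]))]
  m31 <- mid_index[as.character(key(f[, 3L], f[, 1L]))]
  newf <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  dimnames(newf) <- NULL
  cm_mesh(rbind(v, mid), newf, units = mesh$units)
}
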