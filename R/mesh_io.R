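#' Read a Wavefront OBJ surface
#'
#' Parses `v` (vertex) and `f` (face) records; normal (`vn`), texture (`vt`)
#' and all other record types are ignored.  OBJ face indices are 1-based and
#' may carry `/vt/vn` suffixes, which are stripped.  Faces with more than
#' three corners are fan-triangulated by default.
#'
#' @param path path to an ASCII OBJ file.
#' @param strict if `TRUE`, non-triangular faces raise an error instead of
#'   being fan-triangulated.
#' @param units unit label to attach (metadata only).
#' @return a [cm_mesh].
#' @export
read_obj <- function(path, strict = FALSE, units = "um") {
  if (!file.exists(path)) cm_stop(paste0("no such file: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  vlines <- integer(0)
  verts <- list()
  faces <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    tok <- strsplit(s, "[[:space:]]+")[[1]]
    if (tok[1] == "v") {
      if (length(tok) < 4L) {
        cm_stop(sprintf("line %d: vertex record needs 3 coordinates", ln),
                "parse_error")
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) {
        cm_stop(sprintf("line %d: non-numeric vertex coordinate", ln),
                "parse_error")
      }
      verts[[length(verts) + 1L]] <- xyz
    } else if (tok[1] == "f") {
      ids <- suppressWarnings(as.integer(sub("/.*$", "", tok[-1])))
      if (length(ids) < 3L || anyNA(ids) || any(ids < 1L)) {
        cm_stop(sprintf("line %d: malformed face record", ln), "parse_error")
      }
      if (length(ids) > 3L && strict) {
        cm_stop(sprintf("line %d: non-triangular face in strict mode", ln),
                "parse_error")
      }
      # fan triangulation for polygons
      for (k in 2:(length(ids) - 1L)) {
        faces[[length(faces) + 1L]] <- ids[c(1L, k, k + 1L)]
      }
    }
  }
  if (length(verts) == 0L) cm_stop("no vertex records found", "parse_error")
  v <- do.call(rbind, verts)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0L, 3L)
  if (nrow(f) > 0L && max(f) > nrow(v)) {
    cm_stop("face index exceeds vertex count", "parse_error")
  }
  cm_mesh(v, f, units = units)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a [cm_mesh].
#' @param path output path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, digits = 9L) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("v %%.%dg %%.%dg %%.%dg", digits, digits, digits)
  writeLines(sprintf(fmt, mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces)) {
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
  }
  invisible(path)
}

#' Read a fiducial landmark CSV
#'
#' Expects a header containing `name,x,y,z` (case-insensitive; extra columns
#' ignored).  Landmarks are returned in file order.
#'
#' @param path CSV path.
#' @return a `cm_landmarks` object: list with `names` and `coordinates`
#'   (`k x 3`).
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) cm_stop(paste0("no such file: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(names(df))
  need <- c("name", "x", "y", "z")
  if (!all(need %in% cols)) {
    cm_stop("landmark CSV must have columns name,x,y,z", "parse_error")
  }
  nm <- as.character(df[[which(cols == "name")[1]]])
  xyz <- cbind(df[[which(cols == "x")[1]]],
               df[[which(cols == "y")[1]]],
               df[[which(cols == "z")[1]]])
  if (!is.numeric(xyz) || anyNA(xyz) || !all(is.finite(xyz))) {
    cm_stop("non-numeric landmark coordinate", "parse_error")
  }
  if (anyDuplicated(nm)) cm_stop("duplicate landmark names", "parse_error")
  cm_landmarks(nm, xyz)
}

#' Construct a landmark set
#'
#' @param names unique landmark labels.
#' @param coordinates numeric `k x 3` matrix.
#' @return object of class `cm_landmarks`.
#' @export
cm_landmarks <- function(names, coordinates) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L || length(names) != nrow(coordinates)) {
    cm_stop("coordinates must be k x 3 aligned with names", "invalid_parameter")
  }
  if (anyDuplicated(names)) cm_stop("duplicate landmark names", "invalid_parameter")
  if (!all(is.finite(coordinates))) {
    cm_stop("non-finite landmark coordinates", "invalid_parameter")
  }
  structure(list(names = as.character(names), coordinates = coordinates),
            class = "cm_landmarks")
}

#' Write a landmark set as CSV (name,x,y,z)
#'
#' @param landmarks a `cm_landmarks`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  df <- data.frame(name = landmarks$names,
                   x = landmarks$coordinates[, 1L],
                   y = landmarks$coordinates[, 2L],
                   z = landmarks$coordinates[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# signed diverging blue-white-red map, symmetric about 0
diverging_rgb <- function(field) {
  m <- max(abs(field))
  t <- if (m > 0) field / m else field * 0   # in [-1, 1]
  r <- ifelse(t >= 0, 255, round(255 * (1 + t)))
  b <- ifelse(t <= 0, 255, round(255 * (1 - t)))
  g <- round(255 * (1 - abs(t)))
  cbind(r = as.integer(r), g = as.integer(g), b = as.integer(b))
}

#' Write a per-vertex scalar field as CSV plus a colored PLY surface
#'
#' Emits (a) a CSV of `vertex_index,value` (fixed 6-decimal format) and (b)
#' an ASCII PLY with per-vertex RGB colors from a signed diverging map
#' centered at zero: blue for negative (inward), white at zero, red for
#' positive (outward).
#'
#' @param mesh a [cm_mesh].
#' @param field numeric vector of length `V`.
#' @param path output path stem; `.csv` and `.ply` are appended.
#' @return named character vector of the two paths, invisibly.
#' @export
write_vertex_field <- function(mesh, field, path) {
  V <- nrow(mesh$vertices)
  if (length(field) != V || !all(is.finite(field))) {
    cm_stop("field must be a finite vector of length V", "invalid_parameter")
  }
  csv_path <- paste0(path, ".csv")
  ply_path <- paste0(path, ".ply")
  writeLines(c("vertex_index,value",
               sprintf("%d,%.6f", seq_len(V), field)), csv_path)

  rgb <- diverging_rgb(field)
  con <- file(ply_path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", V),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L], rgb[, 1L], rgb[, 2L], rgb[, 3L]), con)
  if (nrow(mesh$faces)) {
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                       mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
  invisible(c(csv = csv_path, ply = ply_path))
}

#' Read a cohort manifest CSV
#'
#' Columns: `specimen_id, mesh_path, landmark_path, genotype, sex, litter`.
#' Relative paths are resolved against the manifest's directory.  Loading is
#' fail-fast: duplicate specimen ids, unresolvable paths, or genotype / sex /
#' litter labels outside the declared sets raise errors.
#'
#' @param path manifest CSV path.
#' @param genotype_levels declared genotype labels (first = reference); if
#'   `NULL`, the labels found are used (sorted, first = reference).
#' @param sex_levels,litter_levels optional declared label sets.
#' @param check_paths verify that mesh/landmark files exist.
#' @return a `data.frame` of class `cm_manifest`.
#' @export
read_manifest <- function(path, genotype_levels = NULL, sex_levels = NULL,
                          litter_levels = NULL, check_paths = TRUE) {
  if (!file.exists(path)) cm_stop(paste0("no such file: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "mesh_path", "genotype", "sex", "litter")
  if (!all(need %in% names(df))) {
    cm_stop(paste("manifest must have columns:", paste(need, collapse = ", ")),
            "parse_error")
  }
  if (anyDuplicated(df$specimen_id)) {
    cm_stop("duplicate specimen_id in manifest", "parse_error")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$mesh_path <- resolve(df$mesh_path)
  if ("landmark_path" %in% names(df)) df$landmark_path <- resolve(df$landmark_path)
  check_levels <- function(values, levels, what) {
    if (!is.null(levels) && !all(values %in% levels)) {
      bad <- setdiff(unique(values), levels)
      cm_stop(sprintf("undeclared %s label(s): %s", what,
                      paste(bad, collapse = ", ")), "invalid_label")
    }
  }
  check_levels(df$genotype, genotype_levels, "genotype")
  check_levels(df$sex, sex_levels, "sex")
  check_levels(df$litter, litter_levels, "litter")
  if (check_paths) {
    missing <- !file.exists(df$mesh_path)
    if (any(missing)) {
      cm_stop(paste("missing mesh file for specimen:",
                    paste(df$specimen_id[missing], collapse = ", ")),
              "io_error")
    }
  }
  attr(df, "genotype_levels") <- genotype_levels %||% sort(unique(df$genotype))
  class(df) <- c("cm_manifest", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
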