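#' Triangulated surface meshes
#'
#' `triangle_mesh()` constructs the package's mesh container: an indexed
#' triangle soup with vertex coordinates in millimetres, optional per-vertex
#' RGB colours (each channel in `[0, 1]`) and optional integer per-vertex
#' labels (`0` = background skin, `> 0` = wound region id). This is the
#' geometric substrate from which wound surface area is measured.
#'
#' @param vertices Numeric matrix (or data frame) with one row per vertex and
#'   three columns (x, y, z), in millimetres.
#' @param faces Integer matrix with one row per triangle and three columns of
#'   1-based vertex indices.
#' @param colors Optional numeric matrix, one RGB row per vertex, channels in
#'   `[0, 1]`.
#' @param labels Optional integer vector, one label per vertex.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `colors`, `labels`.
#' @examples
#' sq <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'   faces    = rbind(c(1, 2, 3), c(1, 3, 4))
#' )
#' surface_area(sq)  # 1 mm^2 = 0.01 cm^2
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    bp_abort("`vertices` must have three columns (x, y, z in mm).",
             "bp_error_input")
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) {
    bp_abort("`faces` must have three columns of vertex indices.",
             "bp_error_input")
  }
  n <- nrow(vertices)
  if (nrow(faces) > 0L &&
      (anyNA(faces) || min(faces) < 1L || max(faces) > n)) {
    bp_abort("face indices must lie in 1..n_vertices.", "bp_error_input")
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (nrow(colors) != n || ncol(colors) != 3L) {
      bp_abort("`colors` must be an n_vertices x 3 RGB matrix.",
               "bp_error_input")
    }
    if (anyNA(colors) || min(colors) < 0 || max(colors) > 1) {
      bp_abort("colour channels must lie in [0, 1].", "bp_error_input")
    }
    dimnames(colors) <- NULL
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) {
      bp_abort("`labels` must have one entry per vertex.", "bp_error_input")
    }
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(
    list(vertices = vertices, faces = faces, colors = colors, labels = labels),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d faces%s%s\n",
    n_vertices(x), n_faces(x),
    if (!is.null(x$colors)) ", per-vertex colours" else "",
    if (!is.null(x$labels)) {
      sprintf(", labels (%d wound vertices)", sum(x$labels > 0L))
    } else ""
  ))
  cat(sprintf("  total surface area: %.4f cm^2\n", surface_area(x)))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh A `triangle_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-triangle areas
#'
#' Area of each face as half the magnitude of the cross product of two edge
#' vectors. Vertex units are millimetres, so areas are in square millimetres.
#'
#' @param mesh A [triangle_mesh()].
#' @return Numeric vector of face areas (mm^2), all `>= 0`.
#' @export
face_areas <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n_faces(mesh) == 0L) return(numeric(0))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

#' Wound (or whole-mesh) surface area in cm^2
#'
#' Sums triangle areas over a face subset (the whole mesh when `faces` is
#' `NULL`) and converts mm^2 to cm^2. This is the single place where the
#' mm -> cm unit boundary is crossed; everything upstream stays in scanner
#' millimetres.
#'
#' @param mesh A [triangle_mesh()].
#' @param faces Optional integer vector of face indices. An empty subset
#'   returns 0 with a warning.
#' @return Area in cm^2.
#' @export
surface_area <- function(mesh, faces = NULL) {
  a <- face_areas(mesh)
  if (is.null(faces)) return(sum(a) / 100)
  faces <- as.integer(faces)
  if (length(faces) == 0L) {
    bp_warn("empty face subset: surface area is 0.", "bp_warning_empty_subset")
    return(0)
  }
  if (anyNA(faces) || min(faces) < 1L || max(faces) > n_faces(mesh)) {
    bp_abort("face subset contains out-of-range indices.", "bp_error_input")
  }
  sum(a[faces]) / 100
}

#' Mesh hygiene: drop degenerate faces and unreferenced vertices
#'
#' Removes numerically collapsed triangles (area `<= area_epsilon`, which
#' covers faces repeating a vertex), drops vertices no remaining face
#' references, and re-indexes faces, colours and labels consistently. Scanner
#' artifact removal happens upstream of this package; this pass only
#' guarantees the invariants the area computations rely on.
#'
#' @param mesh A [triangle_mesh()].
#' @param area_epsilon Faces with area at or below this (mm^2) are removed.
#'   The default `1e-8` is far below structured-light scanner resolution and
#'   removes only numerically collapsed faces.
#' @return A cleaned `triangle_mesh`.
#' @export
validate_mesh <- function(mesh, area_epsilon = 1e-8) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  keep <- face_areas(mesh) > area_epsilon
  f <- mesh$faces[keep, , drop = FALSE]
  if (nrow(f) == 0L) {
    bp_abort("no valid faces remain after cleaning.", "bp_error_empty_mesh")
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  triangle_mesh(
    vertices = mesh$vertices[used, , drop = FALSE],
    faces    = matrix(remap[f], ncol = 3L),
    colors   = if (!is.null(mesh$colors)) mesh$colors[used, , drop = FALSE],
    labels   = if (!is.null(mesh$labels)) mesh$labels[used]
  )
}

#' Extract a face subset as a standalone mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param faces Nonempty integer vector of face indices to keep.
#' @return A `triangle_mesh` containing exactly those faces, with vertices
#'   re-indexed; its total [surface_area()] equals
#'   `surface_area(mesh, faces)`.
#' @export
submesh <- function(mesh, faces) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  faces <- as.integer(faces)
  if (length(faces) == 0L) {
    bp_abort("empty face selection.", "bp_error_empty_selection")
  }
  if (anyNA(faces) || min(faces) < 1L || max(faces) > n_faces(mesh)) {
    bp_abort("face selection contains out-of-range indices.", "bp_error_input")
  }
  f <- mesh$faces[faces, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  triangle_mesh(
    vertices = mesh$vertices[used, , drop = FALSE],
    faces    = matrix(remap[f], ncol = 3L),
    colors   = if (!is.null(mesh$colors)) mesh$colors[used, , drop = FALSE],
    labels   = if (!is.null(mesh$labels)) mesh$labels[used]
  )
}
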