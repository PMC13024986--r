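#' Wound region-of-interest selections
#'
#' An ROI selection is the computational analogue of the manual perimeter
#' delineation a segmenter performs in a mesh editor: a set of face indices
#' identified as wound, together with how the selection was made and its
#' surface area. The area is always recomputed from the mesh at construction,
#' never cached from elsewhere.
#'
#' @param mesh A [triangle_mesh()].
#' @param face_indices Nonempty integer vector of selected faces.
#' @param source How the selection was made: `"labels"`, `"color_rule"` or
#'   `"boundary_loop"`.
#' @param label_value Wound label id used, when label-driven.
#' @param labels Optional induced per-vertex labelling (from the colour
#'   pathway).
#' @return An object of class `roi_selection` with elements `face_indices`,
#'   `source`, `label_value`, `area_cm2` and optionally `labels`.
#' @export
roi_selection <- function(mesh, face_indices,
                          source = c("labels", "color_rule", "boundary_loop"),
                          label_value = NULL, labels = NULL) {
  source <- match.arg(source)
  face_indices <- sort(unique(as.integer(face_indices)))
  if (length(face_indices) == 0L) {
    bp_abort("empty ROI selection.", "bp_error_empty_selection")
  }
  structure(
    list(face_indices = face_indices,
         source = source,
         label_value = label_value,
         area_cm2 = surface_area(mesh, face_indices),
         labels = labels),
    class = "roi_selection"
  )
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> %d faces, %.4f cm^2 (source: %s)\n",
              length(x$face_indices), x$area_cm2, x$source))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roi_selection <- function(x, ...) {
  tibble(face_index = x$face_indices)
}

#' @exportS3Method generics::glance
glance.roi_selection <- function(x, ...) {
  tibble(n_faces = length(x$face_indices), area_cm2 = x$area_cm2,
         source = x$source)
}

#' Select wound faces from vertex labels
#'
#' Turns a per-vertex wound labelling (e.g. from a label sidecar, a colour
#' rule, or the synthetic generator) into a face-level ROI. Under the
#' conservative default `all_vertices` rule a face is wound only when all
#' three of its vertices carry `label_value`, so boundary-straddling
#' triangles are never counted as wound; `majority` includes faces with at
#' least two labelled vertices.
#'
#' @param mesh A labelled [triangle_mesh()].
#' @param label_value Integer wound region id (default 1).
#' @param inclusion_rule `"all_vertices"` (default) or `"majority"`.
#' @return A [roi_selection()].
#' @export
roi_from_labels <- function(mesh, label_value = 1L,
                            inclusion_rule = c("all_vertices", "majority")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  inclusion_rule <- match.arg(inclusion_rule)
  if (is.null(mesh$labels)) {
    bp_abort("mesh has no vertex labels; attach a label sidecar first.",
             "bp_error_config")
  }
  hit <- matrix(mesh$labels[mesh$faces] == as.integer(label_value),
                ncol = 3L)
  nhit <- rowSums(hit)
  sel <- which(nhit >= if (inclusion_rule == "all_vertices") 3L else 2L)
  if (length(sel) == 0L) {
    bp_abort(sprintf("no face selected for label %d.", label_value),
             "bp_error_empty_selection")
  }
  roi_selection(mesh, sel, source = "labels",
                label_value = as.integer(label_value))
}

#' Select wound faces by a per-vertex colour rule
#'
#' Scores every vertex by a weighted sum of its RGB channels and calls it
#' wound-positive when the score is on the chosen side of `threshold` — a
#' simple linear colour classifier standing in for texture-guided manual
#' delineation. Faces are then selected under the `all_vertices` rule on the
#' induced vertex labelling, which is returned with the selection so the
#' label pathway can reproduce it exactly.
#'
#' @param mesh A coloured [triangle_mesh()].
#' @param channel_weights Numeric RGB weight triple; the default
#'   `c(1, -1, -1)` separates red wound tones from skin tones.
#' @param threshold Score cut in the units of `channel_weights %*% rgb`.
#' @param polarity `"above"`: vertices scoring strictly above `threshold`
#'   are wound; `"below"`: strictly below.
#' @return A [roi_selection()] whose `labels` element holds the induced
#'   per-vertex labelling (1 = wound, 0 = skin).
#' @export
roi_from_color <- function(mesh, channel_weights = c(1, -1, -1),
                           threshold = 0, polarity = c("above", "below")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  polarity <- match.arg(polarity)
  if (is.null(mesh$colors)) {
    bp_abort("mesh has no vertex colours; cannot apply a colour rule.",
             "bp_error_config")
  }
  score <- as.vector(mesh$colors %*% as.numeric(channel_weights))
  pos <- if (polarity == "above") score > threshold else score < threshold
  if (all(pos) || !any(pos)) {
    bp_warn(sprintf(
      "degenerate colour threshold: %s vertices are wound-positive.",
      if (all(pos)) "all" else "no"),
      "bp_warning_degenerate_threshold")
  }
  labels <- as.integer(pos)
  if (!any(pos)) {
    bp_abort("colour rule selected no vertices.", "bp_error_empty_selection")
  }
  hit <- matrix(labels[mesh$faces] == 1L, ncol = 3L)
  sel <- which(rowSums(hit) == 3L)
  if (length(sel) == 0L) {
    bp_abort("colour rule selected no complete face.",
             "bp_error_empty_selection")
  }
  roi_selection(mesh, sel, source = "color_rule", label_value = 1L,
                labels = labels)
}

# faces adjacent iff they share an edge (vertex adjacency would merge
# patches touching at a single point)
face_edge_adjacency <- function(mesh, face_set) {
  f <- mesh$faces[face_set, , drop = FALSE]
  ea <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(ea[, 1L], ea[, 2L]), pmax(ea[, 1L], ea[, 2L]))
  owner <- rep.int(seq_along(face_set), 3L)
  grp <- split(owner, key)
  grp <- grp[lengths(grp) > 1L]
  if (length(grp) == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, lapply(grp, function(g) {
    cbind(g[1L], g[-1L])
  }))
}

#' Edge-connected components of a face set
#'
#' Partitions a face set into components in which neighbouring faces share a
#' full edge. Supports multi-wound scans: separately delineated patches on
#' one mesh come back as separate components. Components are ordered by
#' decreasing surface area, ties broken by the smallest contained face
#' index, so the ordering is deterministic.
#'
#' @param mesh A [triangle_mesh()].
#' @param face_set Integer vector of face indices (may be empty).
#' @return A list of integer face-index vectors; empty input gives an empty
#'   list.
#' @export
mesh_components <- function(mesh, face_set) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  face_set <- sort(unique(as.integer(face_set)))
  if (length(face_set) == 0L) return(list())
  if (min(face_set) < 1L || max(face_set) > n_faces(mesh)) {
    bp_abort("face set contains out-of-range indices.", "bp_error_input")
  }
  adj <- face_edge_adjacency(mesh, face_set)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(face_set) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comps <- split(face_set, memb)
  areas <- vapply(comps, function(fs) sum(face_areas(mesh)[fs]), 0)
  first <- vapply(comps, min, 0L)
  ord <- order(-areas, first)
  unname(comps[ord])
}

#' Suppress small components and merge the survivors into one ROI
#'
#' Noise-speckle suppression: keeps only components whose surface area
#' reaches `min_area_cm2` and unions them into a single selection.
#'
#' @param components List of face-index vectors, as produced by
#'   [mesh_components()].
#' @param mesh The [triangle_mesh()] the components refer to.
#' @param min_area_cm2 Minimum component area (cm^2) to keep; `0` keeps all.
#' @param source Provenance tag forwarded to the returned selection.
#' @return A [roi_selection()] over the union of surviving components.
#' @export
filter_components <- function(components, mesh, min_area_cm2 = 0,
                              source = "labels") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  areas <- vapply(components, function(fs) surface_area(mesh, fs), 0)
  keep <- components[areas >= min_area_cm2]
  if (length(keep) == 0L) {
    bp_abort(sprintf(
      "all %d components fall below min_area_cm2 = %g.",
      length(components), min_area_cm2), "bp_error_empty_selection")
  }
  roi_selection(mesh, unlist(keep), source = source)
}

#' Select wound faces inside a boundary vertex loop
#'
#' Optional seed-fill pathway mirroring a manual perimeter trace: starting
#' from `seed_face`, faces are flood-filled across shared edges without ever
#' crossing an edge whose two endpoints are consecutive vertices of the
#' closed `loop_vertices` polyline. The result is converted to a vertex
#' labelling, so downstream behaviour is identical to the label pathway.
#'
#' @param mesh A [triangle_mesh()].
#' @param loop_vertices Integer vector of vertex indices forming a closed
#'   boundary loop (first vertex implicitly follows the last).
#' @param seed_face Face index strictly inside the loop.
#' @return A [roi_selection()] with the induced labelling in `labels`.
#' @export
roi_from_boundary_loop <- function(mesh, loop_vertices, seed_face) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  loop_vertices <- as.integer(loop_vertices)
  if (length(loop_vertices) < 3L) {
    bp_abort("boundary loop needs at least 3 vertices.", "bp_error_input")
  }
  nxt <- c(loop_vertices[-1L], loop_vertices[1L])
  blocked <- paste(pmin(loop_vertices, nxt), pmax(loop_vertices, nxt))

  f <- mesh$faces
  ea <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(ea[, 1L], ea[, 2L]), pmax(ea[, 1L], ea[, 2L]))
  owner <- rep.int(seq_len(nrow(f)), 3L)
  open <- !(key %in% blocked)
  grp <- split(owner[open], key[open])
  grp <- grp[lengths(grp) > 1L]
  edges <- if (length(grp)) {
    do.call(rbind, lapply(grp, function(g) cbind(g[1L], g[-1L])))
  } else matrix(integer(0), ncol = 2L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(f) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  sel <- which(memb == memb[as.integer(seed_face)])
  labels <- integer(n_vertices(mesh))
  labels[unique(as.vector(f[sel, ]))] <- 1L
  roi_selection(mesh, sel, source = "boundary_loop", label_value = 1L,
                labels = labels)
}

#' Export an ROI as CSV
#'
#' Writes the selected face indices one per row, preceded by a `#` summary
#' line carrying the selection source and area, so a selection can be
#' archived next to its mesh.
#'
#' @param roi A [roi_selection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(roi, path) {
  stopifnot(inherits(roi, "roi_selection"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source=%s area_cm2=%.6f n_faces=%d",
                     roi$source, roi$area_cm2, length(roi$face_indices)), con)
  writeLines("face_index", con)
  writeLines(as.character(roi$face_indices), con)
  invisible(path)
}
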