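#' Read a triangulated surface mesh from PLY, OBJ or STL
#'
#' Reads the three mesh formats commonly exported by 3D scanning suites.
#' PLY is read in both ASCII and binary (little/big endian) dialects, with
#' per-vertex `red`/`green`/`blue` properties mapped to colour channels in
#' `[0, 1]` and an optional scalar `label` property mapped to vertex labels.
#' OBJ vertex lines may carry the common 6-number extension
#' (`v x y z r g b`). STL (ASCII or binary) carries geometry only, so the
#' resulting mesh has no colours or labels; exactly coincident STL corner
#' vertices are merged into shared indexed vertices. Polygonal faces are
#' fan-triangulated. Vertex units are taken to be millimetres throughout.
#'
#' @param path Path to the mesh file.
#' @param format Optional format hint, one of `"ply"`, `"obj"`, `"stl"`;
#'   by default the file extension decides.
#' @return A [triangle_mesh()].
#' @seealso [write_mesh()], [read_vertex_labels()]
#' @export
read_mesh <- function(path, format = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    bp_abort(sprintf("cannot read mesh file '%s': no such file.", path),
             "bp_error_input")
  }
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    bp_abort(sprintf("unsupported mesh format '%s' (use PLY, OBJ or STL).",
                     fmt), "bp_error_format")
  )
}

#' Write a mesh to PLY, OBJ or STL
#'
#' Writes ASCII dialects only, for diffability. PLY and OBJ carry per-vertex
#' colours when the mesh has them; STL is geometry-only. Vertex labels are
#' never embedded (no standard slot exists in these formats) — use
#' [write_vertex_labels()] for the sidecar CSV.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format Optional format override; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    bp_abort(sprintf("unsupported mesh format '%s' (use PLY, OBJ or STL).",
                     fmt), "bp_error_format")
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- PLY ---------------------------------------------------------------

ply_type_table <- list(
  char    = list(size = 1L, what = "integer", signed = TRUE),
  int8    = list(size = 1L, what = "integer", signed = TRUE),
  uchar   = list(size = 1L, what = "integer", signed = FALSE),
  uint8   = list(size = 1L, what = "integer", signed = FALSE),
  short   = list(size = 2L, what = "integer", signed = TRUE),
  int16   = list(size = 2L, what = "integer", signed = TRUE),
  ushort  = list(size = 2L, what = "integer", signed = FALSE),
  uint16  = list(size = 2L, what = "integer", signed = FALSE),
  int     = list(size = 4L, what = "integer", signed = TRUE),
  int32   = list(size = 4L, what = "integer", signed = TRUE),
  uint    = list(size = 4L, what = "integer", signed = TRUE),
  uint32  = list(size = 4L, what = "integer", signed = TRUE),
  float   = list(size = 4L, what = "double",  signed = TRUE),
  float32 = list(size = 4L, what = "double",  signed = TRUE),
  double  = list(size = 8L, what = "double",  signed = TRUE),
  float64 = list(size = 8L, what = "double",  signed = TRUE)
)

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  end_pos <- grepRaw("end_header", raw)
  if (length(end_pos) == 0L) {
    bp_abort(sprintf("'%s' is not a PLY file (no end_header).", path),
             "bp_error_format")
  }
  nl <- which(raw == as.raw(10L))
  body_start <- min(nl[nl > end_pos]) + 1L
  header <- strsplit(rawToChar(raw[seq_len(body_start - 1L)]), "\r?\n")[[1]]
  if (!grepl("^ply", header[1])) {
    bp_abort(sprintf("'%s' is not a PLY file.", path), "bp_error_format")
  }
  fmt_line <- strsplit(trimws(grep("^format", header, value = TRUE)[1]),
                       "\\s+")[[1]]
  dialect <- fmt_line[2]
  endian <- if (identical(dialect, "binary_big_endian")) "big" else "little"

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], is_list = TRUE,
               count_type = tok[3], item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], is_list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  if (identical(dialect, "ascii")) {
    vals <- parse_ply_ascii(rawToChar(raw[body_start:length(raw)]), elements)
  } else {
    vals <- parse_ply_binary(raw, body_start, elements, endian)
  }
  ply_to_mesh(vals, elements)
}

parse_ply_ascii <- function(txt, elements) {
  tok <- scan(text = txt, what = character(), quiet = TRUE)
  vals <- list()
  i <- 1L
  for (el in elements) {
    has_list <- any(vapply(el$props, `[[`, TRUE, "is_list"))
    if (!has_list) {
      np <- length(el$props)
      m <- matrix(as.numeric(tok[seq.int(i, length.out = el$count * np)]),
                  ncol = np, byrow = TRUE)
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      vals[[el$name]] <- list(scalars = m)
      i <- i + el$count * np
    } else {
      # assume the single list property layout used for faces
      rows <- vector("list", el$count)
      for (r in seq_len(el$count)) {
        cnt <- as.integer(tok[i])
        rows[[r]] <- as.integer(tok[seq.int(i + 1L, length.out = cnt)])
        i <- i + 1L + cnt
      }
      vals[[el$name]] <- list(lists = rows)
    }
  }
  vals
}

read_bin_column <- function(raw, base, count, stride, offset, type, endian) {
  ti <- ply_type_table[[type]]
  if (is.null(ti)) {
    bp_abort(sprintf("unsupported PLY property type '%s'.", type),
             "bp_error_format")
  }
  idx <- rep.int((seq_len(count) - 1L) * stride, rep.int(ti$size, count)) +
    base + offset + seq_len(ti$size)
  readBin(raw[idx], what = ti$what, n = count, size = ti$size,
          signed = if (ti$what == "integer") ti$signed else TRUE,
          endian = endian)
}

parse_ply_binary <- function(raw, body_start, elements, endian) {
  vals <- list()
  p <- body_start - 1L  # bytes consumed so far
  for (el in elements) {
    has_list <- any(vapply(el$props, `[[`, TRUE, "is_list"))
    if (!has_list) {
      sizes <- vapply(el$props, function(pr) ply_type_table[[pr$type]]$size, 1L)
      stride <- sum(sizes)
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      m <- matrix(0, nrow = el$count, ncol = length(el$props))
      for (k in seq_along(el$props)) {
        m[, k] <- read_bin_column(raw, p, el$count, stride, offs[k],
                                  el$props[[k]]$type, endian)
      }
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      vals[[el$name]] <- list(scalars = m)
      p <- p + el$count * stride
    } else {
      pr <- el$props[[which(vapply(el$props, `[[`, TRUE, "is_list"))[1]]]
      csz <- ply_type_table[[pr$count_type]]$size
      isz <- ply_type_table[[pr$item_type]]$size
      first <- read_bin_column(raw, p, 1L, csz, 0L, pr$count_type, endian)
      stride <- csz + first * isz
      counts <- read_bin_column(raw, p, el$count, stride, 0L,
                                pr$count_type, endian)
      if (any(counts != first)) {
        bp_abort("binary PLY with mixed polygon sizes is not supported.",
                 "bp_error_format")
      }
      cols <- matrix(0L, nrow = el$count, ncol = first)
      for (k in seq_len(first)) {
        cols[, k] <- read_bin_column(raw, p, el$count, stride,
                                     csz + (k - 1L) * isz,
                                     pr$item_type, endian)
      }
      vals[[el$name]] <- list(lists = asplit(cols, 1L))
      p <- p + el$count * stride
    }
  }
  vals
}

fan_triangulate <- function(rows) {
  # rows: list of integer vectors (0-based polygon vertex indices)
  tri <- lapply(rows, function(ix) {
    if (length(ix) < 3L) return(NULL)
    cbind(ix[1L], ix[seq(2L, length(ix) - 1L)], ix[seq(3L, length(ix))])
  })
  do.call(rbind, tri) + 1L
}

ply_to_mesh <- function(vals, elements) {
  if (is.null(vals$vertex) || is.null(vals$face)) {
    bp_abort("PLY file lacks vertex or face elements.", "bp_error_format")
  }
  vm <- vals$vertex$scalars
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vm))) {
    bp_abort("PLY vertex element lacks x/y/z properties.", "bp_error_format")
  }
  colors <- NULL
  if (all(c("red", "green", "blue") %in% colnames(vm))) {
    ctypes <- vapply(
      elements$vertex$props[match(c("red", "green", "blue"),
                                  vapply(elements$vertex$props, `[[`, "",
                                         "name"))],
      function(p) p$type, "")
    colors <- vm[, c("red", "green", "blue"), drop = FALSE]
    if (any(ctypes %in% c("uchar", "uint8"))) colors <- colors / 255
    colors <- pmin(pmax(colors, 0), 1)
  }
  labels <- if ("label" %in% colnames(vm)) as.integer(vm[, "label"])
  triangle_mesh(
    vertices = vm[, need, drop = FALSE],
    faces    = fan_triangulate(vals$face$lists),
    colors   = colors,
    labels   = labels
  )
}

write_ply <- function(mesh, path) {
  has_col <- !is.null(mesh$colors)
  header <- c(
    "ply", "format ascii 1.0",
    "comment written by burnplanimetry",
    sprintf("element vertex %d", n_vertices(mesh)),
    "property float x", "property float y", "property float z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    sprintf("element face %d", n_faces(mesh)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  v <- mesh$vertices
  vlines <- if (has_col) {
    cc <- round(mesh$colors * 255)
    sprintf("%.9g %.9g %.9g %d %d %d", v[, 1], v[, 2], v[, 3],
            cc[, 1], cc[, 2], cc[, 3])
  } else {
    sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$faces - 1L
  flines <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(header, vlines, flines), path)
}

# ---- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L) {
    bp_abort(sprintf("'%s' is not a usable OBJ file.", path),
             "bp_error_format")
  }
  vtok <- lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"), as.numeric)
  nnum <- lengths(vtok)
  verts <- do.call(rbind, lapply(vtok, function(x) x[1:3]))
  colors <- NULL
  if (all(nnum >= 6L)) {
    colors <- do.call(rbind, lapply(vtok, function(x) x[4:6]))
    colors <- pmin(pmax(colors, 0), 1)
  }
  ftok <- strsplit(trimws(sub("^f", "", flines)), "\\s+")
  fidx <- lapply(ftok, function(x) as.integer(sub("/.*$", "", x)) - 1L)
  triangle_mesh(verts, fan_triangulate(fidx), colors = colors)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  vlines <- if (!is.null(mesh$colors)) {
    cc <- mesh$colors
    sprintf("v %.9g %.9g %.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3],
            cc[, 1], cc[, 2], cc[, 3])
  } else {
    sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$faces
  flines <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c("# written by burnplanimetry", vlines, flines), path)
}

# ---- STL ---------------------------------------------------------------

merge_coincident_vertices <- function(tri_vertices) {
  key <- sprintf("%.17g|%.17g|%.17g",
                 tri_vertices[, 1], tri_vertices[, 2], tri_vertices[, 3])
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(vertices = tri_vertices[first, , drop = FALSE],
       faces = matrix(idx, ncol = 3L, byrow = TRUE))
}

read_stl <- function(path) {
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    raw <- readBin(path, "raw", n = sz)
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * ntri &&
        !grepl("^\\s*solid", rawToChar(raw[1:5]))) {
      is_binary <- TRUE
    } else if (!is.na(ntri) && sz == 84 + 50 * ntri &&
               !any(grepRaw("facet", raw, all = FALSE) > 0)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    raw <- readBin(path, "raw", n = sz)
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    stride <- 50L
    base <- 84L
    coords <- matrix(0, nrow = 3L * ntri, ncol = 3L)
    for (vtx in 0:2) {
      for (ax in 0:2) {
        off <- 12L + vtx * 12L + ax * 4L
        idx <- rep.int((seq_len(ntri) - 1L) * stride, rep.int(4L, ntri)) +
          base + off + seq_len(4L)
        coords[seq(vtx + 1L, by = 3L, length.out = ntri), ax + 1L] <-
          readBin(raw[idx], "double", n = ntri, size = 4L, endian = "little")
      }
    }
    mv <- merge_coincident_vertices(coords)
    return(triangle_mesh(mv$vertices, mv$faces))
  }
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    bp_abort(sprintf("'%s' is not a usable STL file.", path),
             "bp_error_format")
  }
  coords <- do.call(rbind, lapply(
    strsplit(trimws(sub("^\\s*vertex", "", vlines)), "\\s+"),
    function(x) as.numeric(x[1:3])))
  mv <- merge_coincident_vertices(coords)
  triangle_mesh(mv$vertices, mv$faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nn[nn == 0] <- 1
  blocks <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n  outer loop\n",
           "    vertex %.9g %.9g %.9g\n    vertex %.9g %.9g %.9g\n",
           "    vertex %.9g %.9g %.9g\n  endloop\nendfacet"),
    nx / nn, ny / nn, nz / nn,
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(c("solid burnplanimetry", blocks, "endsolid burnplanimetry"),
             path)
}

# ---- label sidecar -----------------------------------------------------

#' Vertex-label sidecar files
#'
#' None of PLY/OBJ/STL standardises integer vertex labels, so wound
#' delineations travel in a sidecar CSV with columns `vertex_index`
#' (1-based) and `label` (`0` = background skin, `> 0` = wound region).
#' `write_vertex_labels()` writes one row per vertex;
#' `read_vertex_labels()` reads the CSV; `attach_vertex_labels()` applies it
#' to a mesh (vertices absent from the sidecar default to label 0).
#'
#' @param mesh A [triangle_mesh()].
#' @param path CSV path.
#' @param labels A data frame with columns `vertex_index`, `label`, or a
#'   path to such a CSV.
#' @return `read_vertex_labels()` returns a tibble; the others return the
#'   path / labelled mesh.
#' @export
write_vertex_labels <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  lab <- mesh$labels %||% integer(n_vertices(mesh))
  readr::write_csv(tibble(vertex_index = seq_len(n_vertices(mesh)),
                          label = as.integer(lab)), path)
  invisible(path)
}

#' @rdname write_vertex_labels
#' @export
read_vertex_labels <- function(path) {
  if (!file.exists(path)) {
    bp_abort(sprintf("cannot read label sidecar '%s'.", path),
             "bp_error_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df))) {
    bp_abort("label sidecar must have columns vertex_index, label.",
             "bp_error_schema")
  }
  as_tibble(df[, c("vertex_index", "label")])
}

#' @rdname write_vertex_labels
#' @export
attach_vertex_labels <- function(mesh, labels) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.character(labels)) labels <- read_vertex_labels(labels)
  idx <- as.integer(labels$vertex_index)
  if (anyNA(idx) || min(idx) < 1L || max(idx) > n_vertices(mesh)) {
    bp_abort("label sidecar indexes vertices outside the mesh.",
             "bp_error_input")
  }
  lab <- integer(n_vertices(mesh))
  lab[idx] <- as.integer(labels$label)
  mesh$labels <- lab
  mesh
}
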