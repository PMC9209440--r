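#' Construct a triangulated surface patch
#'
#' Builds the package's basic mesh container from a vertex matrix and a face
#' index matrix, merging duplicate vertices and dropping degenerate faces.
#' Scans of the pubic symphyseal articular face are open surface patches:
#' a mesh with no boundary (a closed solid) is rejected.
#'
#' @param vertices numeric matrix with three columns (x, y, z in mm).
#' @param faces integer matrix with three columns of 1-based vertex indices.
#' @param provenance free-text source tag carried along with the mesh.
#' @param side which side of the body the scan comes from.
#' @param merge_tol vertices closer than this (mm) are merged; the default
#'   1e-6 mm is far below scanner resolution and only removes duplicates
#'   introduced by serialization formats such as STL.
#' @return an object of class \code{triangle_mesh}: a list with elements
#'   \code{vertices}, \code{faces}, \code{provenance}, \code{side}.
#' @export
triangle_mesh <- function(vertices, faces, provenance = "", side = "unknown",
                          merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinate")
  side <- match.arg(side, c("left", "right", "unknown"))

  # merge duplicate vertices within tolerance
  if (nrow(vertices) > 0L && merge_tol > 0) {
    key <- paste(round(vertices[, 1] / merge_tol),
                 round(vertices[, 2] / merge_tol),
                 round(vertices[, 3] / merge_tol))
    first <- !duplicated(key)
    if (any(!first)) {
      map <- match(key, key[first])
      vertices <- vertices[first, , drop = FALSE]
      if (nrow(faces) > 0L) {
        faces <- matrix(map[faces], ncol = 3L)
        storage.mode(faces) <- "integer"
      }
    }
  }

  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range")

  # drop degenerate faces: repeated indices or (near-)zero area
  dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  area <- face_areas(vertices, faces)
  bad <- dup | area <= 1e-12
  if (any(bad)) {
    message(sum(bad), " degenerate face(s) dropped")
    faces <- faces[!bad, , drop = FALSE]
  }
  if (nrow(faces) == 0L) stop("empty mesh: no faces after cleaning")

  # drop vertices not referenced by any face
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3L)
    storage.mode(faces) <- "integer"
  }

  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = provenance, side = side),
                 class = "triangle_mesh")
  if (n_boundary_edges(m) == 0L)
    stop("mesh is a closed solid, not an open surface patch")
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, side =", x$side, "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# undirected edge keys (double-valued, collision-free for < ~3e7 vertices)
edge_keys <- function(faces, nv) {
  a <- as.double(pmin(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)]))
  b <- as.double(pmax(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)]))
  a * (nv + 1) + b
}

n_boundary_edges <- function(mesh) {
  k <- edge_keys(mesh$faces, nrow(mesh$vertices))
  ks <- sort(k)
  n <- length(ks)
  same_prev <- c(FALSE, ks[-1] == ks[-n])
  same_next <- c(ks[-1] == ks[-n], FALSE)
  sum(!same_prev & !same_next)
}

#' Load a triangulated surface from STL or PLY
#'
#' Reads ASCII or binary STL, and ASCII or binary little-endian PLY
#' (vertex/face elements; extra vertex properties are ignored). Duplicate
#' vertices within 1e-6 mm are merged and degenerate faces dropped, as in
#' \code{\link{triangle_mesh}}.
#'
#' @param path file to read.
#' @param format \code{"auto"} (from extension and content), \code{"stl"}
#'   or \code{"ply"}.
#' @param side side tag to attach to the loaded mesh.
#' @return a \code{\link{triangle_mesh}}.
#' @export
load_mesh <- function(path, format = c("auto", "stl", "ply"),
                      side = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("stl", "ply")) ext else {
      head4 <- readBin(path, "raw", 4L)
      if (identical(rawToChar(head4), "ply\n") ||
          identical(rawToChar(head4[1:3]), "ply")) "ply" else "stl"
    }
  }
  geo <- if (format == "stl") read_stl(path) else read_ply(path)
  triangle_mesh(geo$vertices, geo$faces,
                provenance = basename(path), side = side)
}

read_stl <- function(path) {
  size <- file.size(path)
  raw <- readBin(path, "raw", size)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (ntri > 0 && size == 84 + 50 * as.double(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    idx <- rep(seq(84L, by = 50L, length.out = ntri), each = 48L) + 1:48
    vals <- readBin(raw[idx], "numeric", size = 4L, n = 12L * ntri,
                    endian = "little")
    per_tri <- matrix(vals, ncol = 12L, byrow = TRUE)  # normal + 3 vertices
    verts <- matrix(t(per_tri[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("vertex", txt, fixed = TRUE, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("cannot parse ASCII STL: ", path)
    nums <- scan(text = gsub("vertex", "", vlines, fixed = TRUE),
                 quiet = TRUE)
    verts <- matrix(nums, ncol = 3L, byrow = TRUE)
  }
  nf <- nrow(verts) / 3L
  list(vertices = verts,
       faces = matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
}

read_ply <- function(path) {
  size <- file.size(path)
  raw <- readBin(path, "raw", size)
  # header is text up to (and including) the end_header line
  nl <- which(raw == as.raw(10L))
  hdr_lines <- character()
  hdr_end <- 0L
  prev <- 0L
  for (p in nl) {
    line <- rawToChar(raw[(prev + 1L):p])
    line <- sub("[\r\n]+$", "", line)
    hdr_lines <- c(hdr_lines, line)
    prev <- p
    if (line == "end_header") { hdr_end <- p; break }
  }
  if (hdr_end == 0L || hdr_lines[1] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", hdr_lines, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format: ", fmt_line)

  # element/property layout
  elements <- list()
  cur <- NULL
  for (line in hdr_lines) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (tok[2] == "list") list(list = TRUE, count_type = tok[3],
                                   item_type = tok[4], name = tok[5])
        else list(list = FALSE, type = tok[2], name = tok[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY must contain vertex and face elements")

  ply_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

  nv <- elements$vertex$count
  nf <- elements$face$count
  vprops <- elements$vertex$props
  vnames <- vapply(vprops, `[[`, "", "name")
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z")

  if (!binary) {
    body <- rawToChar(raw[(hdr_end + 1L):size])
    toks <- scan(text = body, what = character(), quiet = TRUE)
    k <- length(vprops)
    vt <- as.numeric(toks[seq_len(nv * k)])
    vm <- matrix(vt, ncol = k, byrow = TRUE)
    verts <- vm[, xyz, drop = FALSE]
    ft <- as.numeric(toks[-seq_len(nv * k)])
    faces <- matrix(0L, nf, 3L)
    pos <- 1L
    for (i in seq_len(nf)) {
      cnt <- ft[pos]
      if (cnt != 3) stop("only triangular PLY faces are supported")
      faces[i, ] <- as.integer(ft[pos + 1:3]) + 1L
      pos <- pos + 1L + cnt
    }
  } else {
    offset <- hdr_end
    types <- vapply(vprops, function(p)
      if (p$list) stop("list property in vertex element unsupported")
      else p$type, "")
    sizes <- ply_size[types]
    if (anyNA(sizes)) stop("unknown PLY property type")
    stride <- sum(sizes)
    if (length(unique(types)) == 1L && types[1] %in%
        c("float", "float32", "double", "float64")) {
      n_all <- nv * length(vprops)
      vals <- readBin(raw[offset + seq_len(nv * stride)], "numeric",
                      size = sizes[1], n = n_all, endian = "little")
      vm <- matrix(vals, ncol = length(vprops), byrow = TRUE)
      verts <- vm[, xyz, drop = FALSE]
    } else {
      # mixed-type vertex properties: extract the x/y/z byte columns
      starts <- cumsum(c(0L, sizes))[-(length(sizes) + 1L)]
      verts <- matrix(0, nv, 3L)
      for (d in 1:3) {
        p <- xyz[d]
        sz <- sizes[p]
        col_idx <- rep(seq(0L, by = stride, length.out = nv),
                       each = sz) + starts[p] + seq_len(sz)
        verts[, d] <- readBin(raw[offset + col_idx], "numeric",
                              size = sz, n = nv, endian = "little")
      }
    }
    offset <- offset + nv * stride
    fp <- elements$face$props[[1]]
    if (!fp$list) stop("PLY face element must use a list property")
    csz <- ply_size[[fp$count_type]]
    isz <- ply_size[[fp$item_type]]
    fstride <- csz + 3L * isz
    cnt1 <- readBin(raw[offset + seq_len(csz)], "integer", size = csz,
                    signed = csz > 2L, endian = "little")
    if (cnt1 != 3L) stop("only triangular PLY faces are supported")
    if (size - offset < as.double(nf) * fstride)
      stop("truncated PLY face data")
    iidx <- rep(seq(0L, by = fstride, length.out = nf), each = 3L * isz) +
      csz + seq_len(3L * isz)
    idx <- readBin(raw[offset + iidx], "integer", size = isz,
                   n = 3L * nf, endian = "little")
    counts <- readBin(raw[offset + rep(seq(0L, by = fstride,
                                           length.out = nf), each = csz) +
                            seq_len(csz)],
                      "integer", size = csz, signed = csz > 2L, n = nf,
                      endian = "little")
    if (any(counts != 3L)) stop("only triangular PLY faces are supported")
    faces <- matrix(idx, ncol = 3L, byrow = TRUE) + 1L
  }
  list(vertices = verts, faces = faces)
}

#' Write a mesh to STL or PLY
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @param path output file; parent directory must exist.
#' @param format \code{"stl"} or \code{"ply"} (default from the extension).
#' @param binary write the binary variant of the format. Binary PLY stores
#'   double-precision coordinates; binary STL is single precision by
#'   definition of the format.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply")) stop("cannot infer format from: ", path)
    format <- ext
  }
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "stl") {
    tri <- array(t(v[t(f), ]), dim = c(3, 3, nrow(f)))  # xyz x corner x face
    e1 <- tri[, 2, ] - tri[, 1, ]
    e2 <- tri[, 3, ] - tri[, 1, ]
    nrm <- rbind(e1[2, ] * e2[3, ] - e1[3, ] * e2[2, ],
                 e1[3, ] * e2[1, ] - e1[1, ] * e2[3, ],
                 e1[1, ] * e2[2, ] - e1[2, ] * e2[1, ])
    len <- sqrt(colSums(nrm^2))
    len[len == 0] <- 1
    nrm <- sweep(nrm, 2, len, "/")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(c(charToRaw("symphage binary STL"),
                 raw(80 - nchar("symphage binary STL"))), con)
      writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
      block <- rbind(nrm, tri[, 1, ], tri[, 2, ], tri[, 3, ])
      for (i in seq_len(nrow(f))) {
        writeBin(block[, i], con, size = 4L, endian = "little")
        writeBin(as.integer(0L), con, size = 2L, endian = "little")
      }
    } else {
      corners <- matrix(t(v[t(f), ]), nrow = 3)  # xyz x (3*nface)
      vtx <- sprintf("      vertex %.9g %.9g %.9g",
                     corners[1, ], corners[2, ], corners[3, ])
      out <- c("solid symphage",
               as.vector(rbind(
                 sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[1, ], nrm[2, ], nrm[3, ]),
                 "    outer loop",
                 matrix(vtx, nrow = 3),
                 "    endloop",
                 "  endfacet")),
               "endsolid symphage")
      writeLines(out, path)
    }
  } else {
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      hdr <- c("ply", "format binary_little_endian 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header")
      writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
      writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(f[i, ] - 1L, con, size = 4L, endian = "little")
      }
    } else {
      hdr <- c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header")
      vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
      fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
      writeLines(c(hdr, vl, fl), path)
    }
  }
  invisible(path)
}

#' Mirror a mesh across the y-z plane
#'
#' Right-sided symphyseal scans are mirrored to the left side before feature
#' extraction so that one model serves both sides. The reflection negates x
#' and flips face winding so outward normals keep their orientation; the side
#' tag is swapped. The choice of mirroring plane is immaterial downstream
#' because pose canonicalization follows.
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @return the mirrored \code{triangle_mesh}.
#' @export
mirror_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh$side <- switch(mesh$side, left = "right", right = "left", "unknown")
  mesh
}

#' Boundary loops of an open surface patch
#'
#' Every boundary edge (an edge used by exactly one face) is assigned to a
#' closed loop. The loop with the greatest total edge length is designated
#' the outer rim; the remaining loops are interior holes (bone porosity).
#'
#' @param mesh a \code{\link{triangle_mesh}}; must be edge-manifold (each
#'   edge in at most two faces), otherwise an error names the offending edge.
#' @return an object of class \code{boundary_loops}: list with \code{loops}
#'   (each a closed cycle of vertex indices, first vertex not repeated) and
#'   \code{outer_index}.
#' @export
boundary_loops <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  # directed edges as they appear in faces
  tail <- as.vector(f[, c(1, 2, 3)])
  head <- as.vector(f[, c(2, 3, 1)])
  key <- pmin(tail, head) * (nv + 1) + pmax(tail, head)
  cnt <- table_counts(key)
  if (any(cnt$n > 2L)) {
    bad <- cnt$key[which(cnt$n > 2L)[1]]
    stop(sprintf("non-manifold edge (%d, %d): used by more than two faces",
                 bad %/% (nv + 1), bad %% (nv + 1)))
  }
  boundary <- key %in% cnt$key[cnt$n == 1L]
  bt <- tail[boundary]
  bh <- head[boundary]
  if (length(bt) == 0L) stop("mesh has no boundary: closed solid")

  used <- logical(length(bt))
  loops <- list()
  next_edge <- function(vtx) {
    cand <- which(bt == vtx & !used)
    if (length(cand) == 0L) NA_integer_ else cand[1]
  }
  for (e0 in seq_along(bt)) {
    if (used[e0]) next
    loop <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      loop <- c(loop, bt[e])
      nxt <- next_edge(bh[e])
      if (is.na(nxt)) {
        if (bh[e] == loop[1]) break
        stop("boundary walk dead-ended: inconsistent patch topology")
      }
      e <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }

  per <- vapply(loops, function(l) {
    p <- mesh$vertices[l, , drop = FALSE]
    q <- p[c(2:nrow(p), 1L), , drop = FALSE]
    sum(sqrt(rowSums((p - q)^2)))
  }, 0)
  structure(list(loops = loops, outer_index = which.max(per)),
            class = "boundary_loops")
}

table_counts <- function(key) {
  ks <- sort(key)
  first <- !duplicated(ks)
  u <- ks[first]
  n <- diff(c(which(first), length(ks) + 1L))
  list(key = u, n = n)
}

#' @export
print.boundary_loops <- function(x, ...) {
  cat("boundary_loops:", length(x$loops), "loop(s), outer =", x$outer_index,
      "(", length(x$loops) - 1L, "interior hole(s) )\n")
  invisible(x)
}
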