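#' Put a scan in the canonical articular-surface frame
#'
#' Centers the vertex cloud at the origin and rotates it so the principal
#' axes of the vertex scatter align with (x, y, z) in decreasing-variance
#' order: x runs along the longest extent of the surface, the x-y plane
#' holds the articular face, and z carries the surface relief. Two sign
#' conventions make the frame deterministic: +z is chosen so the
#' area-weighted mean face normal points up (articular face towards the
#' viewer), and +x so the skewness of the x-coordinates is nonnegative;
#' y completes a right-handed frame.
#'
#' @param mesh a \code{\link{triangle_mesh}} with at least 3 non-collinear
#'   vertices.
#' @return an object of class \code{aligned_mesh}: the transformed
#'   \code{triangle_mesh} in \code{$mesh}, the applied \code{$rotation}
#'   (3x3, proper) and \code{$translation} (applied before rotation), and
#'   \code{$extents} = (x_range, y_range, z_range) in mm.
#' @export
canonicalize_pose <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  cov <- crossprod(vc) / nrow(vc)
  eg <- eigen(cov, symmetric = TRUE)
  # eigen() returns decreasing eigenvalues; x = largest scatter
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-12)
    stop("degenerate vertex scatter: cannot define the articular plane")
  R <- t(eg$vectors)
  if (det(R) < 0) R[3, ] <- -R[3, ]

  rot <- vc %*% t(R)
  # +z: area-weighted mean face normal points up
  if (mean_normal_z(rot, mesh$faces) < 0)
    R <- diag(c(1, -1, -1)) %*% R      # 180 deg about x
  rot <- vc %*% t(R)
  # +x: nonnegative skewness of x
  if (sum(rot[, 1]^3) < 0)
    R <- diag(c(-1, -1, 1)) %*% R      # 180 deg about z
  rot <- vc %*% t(R)

  out <- mesh
  out$vertices <- rot
  structure(list(mesh = out, rotation = R, translation = -ctr,
                 extents = apply(rot, 2, function(x) diff(range(x)))),
            class = "aligned_mesh")
}

mean_normal_z <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  # z-component of the (area-scaled) face normals
  sum(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @export
print.aligned_mesh <- function(x, ...) {
  cat("aligned_mesh: extents (mm) =",
      paste(sprintf("%.2f", x$extents), collapse = " x "), "\n")
  print(x$mesh)
  invisible(x)
}

#' Rasterization settings
#'
#' @param cell_size grid spacing in mm. The default 0.1 mm gives sufficient
#'   resolution for bulge segmentation on symphyseal scans.
#' @param min_coverage_fraction fraction of a cell that must be covered by
#'   the surface's x-y projection for the cell to count as valid. The
#'   default 1 with \code{supersample = 1} reduces to center coverage:
#'   a cell is valid iff its center is covered.
#' @param supersample number of sample points per cell side; values above 1
#'   enable fractional coverage tests.
#' @return a \code{raster_config} list.
#' @export
raster_config <- function(cell_size = 0.1, min_coverage_fraction = 1,
                          supersample = 1L) {
  stopifnot(cell_size > 0, min_coverage_fraction > 0,
            min_coverage_fraction <= 1, supersample >= 1)
  structure(list(cell_size = cell_size,
                 min_coverage_fraction = min_coverage_fraction,
                 supersample = as.integer(supersample)),
            class = "raster_config")
}

#' Project an aligned surface onto a regular height grid
#'
#' Top view: each grid cell covered by the x-y projection of at least one
#' triangle receives the largest z among the ray-triangle intersections
#' along +z at the cell center, so overhangs resolve to the visible surface.
#' Cells with no intersection are invalid and carry \code{NA}, never a
#' number that enters statistics. The grid spans the mesh x-y bounding box.
#'
#' @param aligned an \code{\link{canonicalize_pose}} result.
#' @param cfg a \code{\link{raster_config}}.
#' @return an object of class \code{height_grid}: list with \code{z}
#'   (ny x nx matrix, rows = y), \code{valid} (logical matrix),
#'   \code{cell_size} and \code{origin} (x, y of the center of cell
#'   \code{[1, 1]}).
#' @export
rasterize_surface <- function(aligned, cfg = raster_config()) {
  stopifnot(inherits(aligned, "aligned_mesh"), inherits(cfg, "raster_config"))
  v <- aligned$mesh$vertices
  f <- aligned$mesh$faces
  xr <- range(v[, 1]); yr <- range(v[, 2])
  if (cfg$cell_size > diff(xr) || cfg$cell_size > diff(yr))
    stop("cell_size exceeds a bounding-box dimension")
  nx <- max(1L, as.integer(ceiling(diff(xr) / cfg$cell_size)))
  ny <- max(1L, as.integer(ceiling(diff(yr) / cfg$cell_size)))
  res <- cpp_rasterize(v, f - 1L, xr[1], yr[1], cfg$cell_size, nx, ny,
                       cfg$supersample, cfg$min_coverage_fraction)
  if (!any(res$valid)) stop("no valid cells: surface missed the grid")
  structure(list(z = res$z, valid = res$valid, cell_size = cfg$cell_size,
                 origin = c(xr[1] + cfg$cell_size / 2,
                            yr[1] + cfg$cell_size / 2)),
            class = "height_grid")
}

#' @export
print.height_grid <- function(x, ...) {
  cat("height_grid:", nrow(x$z), "x", ncol(x$z), "cells of",
      x$cell_size, "mm,", sum(x$valid), "valid\n")
  invisible(x)
}

#' Fill interior holes of a surface patch
#'
#' Each interior boundary loop is triangulated by a fan from its centroid,
#' leaving the outer rim untouched; the result has exactly one boundary
#' loop. Hole filling is not part of the feature-extraction path (the hole
#' count is itself a feature); it is provided for workflows that need a
#' watertight articular patch.
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @return a \code{triangle_mesh} with one boundary loop. If the mesh has
#'   no interior loops it is returned unchanged with a warning.
#' @export
fill_holes <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  bl <- boundary_loops(mesh)
  interior <- setdiff(seq_along(bl$loops), bl$outer_index)
  if (length(interior) == 0L) {
    warning("no interior boundary loops to fill")
    return(mesh)
  }
  v <- mesh$vertices
  newf <- list()
  for (li in interior) {
    loop <- bl$loops[[li]]
    ctr <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, ctr)
    ci <- nrow(v)
    nxt <- c(loop[-1], loop[1])
    # loop vertices are stored in boundary-edge direction (tail order);
    # fan triangles reverse it so winding matches the surrounding faces
    newf[[length(newf) + 1L]] <- cbind(nxt, loop, ci)
  }
  faces <- rbind(mesh$faces, do.call(rbind, newf))
  storage.mode(faces) <- "integer"
  out <- mesh
  out$vertices <- v
  out$faces <- faces
  rownames(out$vertices) <- NULL
  out
}

#' Write / read a height grid as plain text
#'
#' The text form is a whitespace-delimited matrix with \code{NA} for invalid
#' cells, preceded by a comment header carrying the cell size and origin.
#'
#' @param grid a \code{height_grid}.
#' @param path file path.
#' @return \code{path} (writer) or a \code{height_grid} (reader), invisibly.
#' @export
write_height_grid <- function(grid, path) {
  stopifnot(inherits(grid, "height_grid"))
  hdr <- sprintf("# height_grid cell_size=%.17g origin=%.17g,%.17g",
                 grid$cell_size, grid$origin[1], grid$origin[2])
  z <- grid$z
  z[!grid$valid] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_height_grid
#' @export
read_height_grid <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "cell_size=([-0-9.eE+]+) origin=([-0-9.eE+]+),([-0-9.eE+]+)", hdr))[[1]]
  if (length(m) != 4L) stop("not a height_grid file: ", path)
  z <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(z) <- NULL
  structure(list(z = z, valid = !is.na(z),
                 cell_size = as.numeric(m[2]),
                 origin = as.numeric(m[3:4])),
            class = "height_grid")
}

#' Export a height grid as a 16-bit grayscale image
#'
#' Valid heights are min-max scaled to (0, 1]; invalid cells are 0. Requires
#' the \pkg{png} package.
#'
#' @param grid a \code{height_grid}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_grid_image <- function(grid, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for image export")
  z <- grid$z
  rng <- range(z[grid$valid])
  span <- if (diff(rng) > 0) diff(rng) else 1
  img <- matrix(0, nrow(z), ncol(z))
  # keep the lowest valid height above the invalid level
  img[grid$valid] <- (z[grid$valid] - rng[1]) / span * (1 - 2 / 65535) +
    2 / 65535
  png::writePNG(img[nrow(img):1, , drop = FALSE], path)
  invisible(path)
}
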