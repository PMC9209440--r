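#' Feature-extraction settings
#'
#' Tunable parameters of the six-feature extraction. Defaults follow the
#' published ariaDNE kernel scale and the morphology of the symphyseal face:
#' ridge-and-furrow relief on young surfaces has a wavelength of roughly
#' 3-5 mm, so a 2 mm Gaussian baseline removes global shape while keeping
#' the billows, and residuals above 0.1 mm mark bulging cells.
#'
#' @param dne_bandwidth_fraction Gaussian kernel bandwidth for the local
#'   surface descriptors, as a fraction of the bounding-box diagonal.
#' @param kernel_cutoff neighbors beyond \code{kernel_cutoff} bandwidths are
#'   ignored (the Gaussian weight there is below 2e-3).
#' @param smoothing_sigma mm; sigma of the Gaussian baseline used by the
#'   bulge segmentation.
#' @param residual_threshold mm; a cell is foreground when its height
#'   exceeds the smoothed baseline by more than this.
#' @param uncertain_band_deg ellipses whose major axis lies within this many
#'   degrees of 45 degrees have uncertain orientation and count neither as
#'   horizontal nor vertical.
#' @param eccentricity_min ellipses below this eccentricity are
#'   circular-like and carry no orientation.
#' @param major_axis_min,area_min mm and mm^2; ellipses below either bound
#'   are small and are omitted from the orientation counts.
#' @return a \code{feature_config} list.
#' @export
feature_config <- function(dne_bandwidth_fraction = 0.08,
                           kernel_cutoff = 2.5,
                           smoothing_sigma = 2.0,
                           residual_threshold = 0.1,
                           uncertain_band_deg = 10,
                           eccentricity_min = 0.8,
                           major_axis_min = 3.0,
                           area_min = 1.5) {
  stopifnot(dne_bandwidth_fraction > 0, kernel_cutoff > 0,
            smoothing_sigma > 0, residual_threshold > 0,
            uncertain_band_deg > 0, uncertain_band_deg < 45,
            eccentricity_min > 0, eccentricity_min < 1,
            major_axis_min > 0, area_min > 0)
  structure(list(dne_bandwidth_fraction = dne_bandwidth_fraction,
                 kernel_cutoff = kernel_cutoff,
                 smoothing_sigma = smoothing_sigma,
                 residual_threshold = residual_threshold,
                 uncertain_band_deg = uncertain_band_deg,
                 eccentricity_min = eccentricity_min,
                 major_axis_min = major_axis_min,
                 area_min = area_min),
            class = "feature_config")
}

local_geometry <- function(aligned, cfg) {
  stopifnot(inherits(aligned, "aligned_mesh"),
            inherits(cfg, "feature_config"))
  v <- aligned$mesh$vertices
  if (nrow(v) < 10L) stop("too few vertices for local surface descriptors")
  h <- cfg$dne_bandwidth_fraction * sqrt(sum(aligned$extents^2))
  na <- cpp_vertex_normals_areas(v, aligned$mesh$faces - 1L)
  res <- cpp_local_geometry(v, na$normals, na$areas, h, cfg$kernel_cutoff,
                            4L)
  if (res$too_few > 0L)
    stop(res$too_few, " vertex/vertices with fewer than 4 weighted ",
         "neighbors: increase dne_bandwidth_fraction")
  res
}

#' Per-vertex local Dirichlet normal energy
#'
#' Kernel-weighted estimate of the Dirichlet energy of the normal map in the
#' spirit of ariaDNE: neighbors are weighted by a Gaussian kernel whose
#' bandwidth is a fraction of the bounding-box diagonal, the local normal is
#' fitted by weighted PCA of neighbor positions, and the energy is the
#' area-weighted variation of neighbor normals about that fitted normal.
#' A flat surface has zero energy everywhere; the standard deviation of
#' these values over the articular face is model feature x1.
#'
#' @param aligned a \code{\link{canonicalize_pose}} result holding the
#'   articular surface only (no extended area).
#' @param cfg a \code{\link{feature_config}}.
#' @return numeric vector of nonnegative per-vertex energies.
#' @export
local_dne <- function(aligned, cfg = feature_config()) {
  local_geometry(aligned, cfg)$dne
}

#' Per-vertex local mean curvature
#'
#' Mean curvature from a kernel-weighted quadric fit in the local tangent
#' frame, using the same neighborhood scheme as \code{\link{local_dne}}.
#' Values are signed: positive where the surface bulges along the outward
#' normal. The standard deviation over the face is model feature x2.
#'
#' @inheritParams local_dne
#' @return numeric vector of per-vertex curvatures (1/mm).
#' @export
local_curvature <- function(aligned, cfg = feature_config()) {
  local_geometry(aligned, cfg)$curvature
}

#' Segment disjointed bulging regions of a height grid
#'
#' The local discrepancy of the profile height is the residual of each cell
#' against a masked Gaussian-smoothed baseline (invalid cells are excluded
#' from the smoothing support). Cells whose residual exceeds the threshold
#' form the foreground, and its 8-connected components are the bulging
#' regions.
#'
#' @param grid a \code{\link{rasterize_surface}} result.
#' @param cfg a \code{\link{feature_config}}.
#' @return a \code{region_map}: list with \code{labels} (integer matrix,
#'   0 = background/invalid), \code{n_regions}, \code{cell_size},
#'   \code{origin}.
#' @export
segment_bulges <- function(grid, cfg = feature_config()) {
  stopifnot(inherits(grid, "height_grid"), inherits(cfg, "feature_config"))
  if (!any(grid$valid)) stop("all-invalid height grid")
  baseline <- cpp_masked_gaussian(grid$z, grid$valid,
                                  cfg$smoothing_sigma / grid$cell_size)
  resid <- grid$z - baseline
  fg <- grid$valid & !is.na(resid) & resid > cfg$residual_threshold
  labels <- cpp_label8(fg)
  structure(list(labels = labels, n_regions = max(labels),
                 cell_size = grid$cell_size, origin = grid$origin),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map:", x$n_regions, "bulging region(s) on a",
      nrow(x$labels), "x", ncol(x$labels), "grid\n")
  invisible(x)
}

#' Fit moment ellipses to segmented regions
#'
#' Each region is approximated by the ellipse matching its second central
#' moments: axis lengths are 4 sqrt(eigenvalues) of the moment matrix of the
#' member-cell centers (the standard image-moment ellipse), orientation is
#' the principal eigenvector's angle to +x in [0, 180), and area is the cell
#' count times the cell area. The square-cell extent term (cell^2/12) is
#' added to the moment matrix diagonal so one-cell-wide regions keep a
#' positive minor axis. Regions of fewer than 3 cells are skipped.
#'
#' @param regions a \code{\link{segment_bulges}} result.
#' @return a data frame of class \code{ellipse_regions} with columns
#'   \code{centroid_x}, \code{centroid_y}, \code{major_axis_length},
#'   \code{minor_axis_length}, \code{orientation_deg}, \code{eccentricity},
#'   \code{area}.
#' @export
fit_ellipses <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  cs <- regions$cell_size
  lab <- regions$labels
  idx <- which(lab > 0L, arr.ind = TRUE)
  out <- list()
  skipped <- 0L
  if (length(idx)) {
    x <- regions$origin[1] + (idx[, 2] - 1) * cs
    y <- regions$origin[2] + (idx[, 1] - 1) * cs
    lv <- lab[idx]
    for (l in sort(unique(lv))) {
      sel <- lv == l
      n <- sum(sel)
      if (n < 3L) { skipped <- skipped + 1L; next }
      xs <- x[sel]; ys <- y[sel]
      mx <- mean(xs); my <- mean(ys)
      cxx <- mean((xs - mx)^2) + cs^2 / 12
      cyy <- mean((ys - my)^2) + cs^2 / 12
      cxy <- mean((xs - mx) * (ys - my))
      eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
      major <- 4 * sqrt(eg$values[1])
      minor <- 4 * sqrt(max(eg$values[2], 0))
      ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
      ang <- ang %% 180
      out[[length(out) + 1L]] <- data.frame(
        centroid_x = mx, centroid_y = my,
        major_axis_length = major, minor_axis_length = minor,
        orientation_deg = ang,
        eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
        area = n * cs^2)
    }
  }
  if (skipped > 0L) message(skipped, " region(s) of fewer than 3 cells skipped")
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
               major_axis_length = numeric(0), minor_axis_length = numeric(0),
               orientation_deg = numeric(0), eccentricity = numeric(0),
               area = numeric(0))
  class(df) <- c("ellipse_regions", "data.frame")
  df
}

#' Classify ellipse orientation
#'
#' Labels each ellipse and counts the oriented ones. Label priority (an
#' omitted ellipse is omitted, so the order cannot change the counts):
#' \emph{small} if the major axis is shorter than \code{major_axis_min} or
#' the area is below \code{area_min}; else \emph{circular_like} if the
#' eccentricity is below \code{eccentricity_min}; else \emph{uncertain} if
#' the acute angle of the major axis to the x-axis (folded to [0, 90]) lies
#' within \code{uncertain_band_deg} of 45 degrees; else \emph{horizontal}
#' (angle below the band) or \emph{vertical} (above it).
#'
#' @param ellipses an \code{\link{fit_ellipses}} result (or any data frame
#'   with the same columns).
#' @param cfg a \code{\link{feature_config}}.
#' @return list with \code{x3} (total count), \code{x4} (horizontal),
#'   \code{x5} (vertical) and \code{labels} (factor, one per ellipse).
#' @export
classify_ellipses <- function(ellipses, cfg = feature_config()) {
  stopifnot(inherits(cfg, "feature_config"))
  lv <- c("horizontal", "vertical", "circular_like", "small", "uncertain")
  n <- nrow(ellipses)
  if (n == 0L)
    return(list(x3 = 0L, x4 = 0L, x5 = 0L,
                labels = factor(character(0), levels = lv)))
  alpha <- ellipses$orientation_deg %% 180
  alpha <- ifelse(alpha > 90, 180 - alpha, alpha)
  lab <- rep("uncertain", n)
  lab[alpha < 45 - cfg$uncertain_band_deg] <- "horizontal"
  lab[alpha > 45 + cfg$uncertain_band_deg] <- "vertical"
  lab[ellipses$eccentricity < cfg$eccentricity_min] <- "circular_like"
  lab[ellipses$major_axis_length < cfg$major_axis_min |
        ellipses$area < cfg$area_min] <- "small"
  labels <- factor(lab, levels = lv)
  list(x3 = n, x4 = sum(labels == "horizontal"),
       x5 = sum(labels == "vertical"), labels = labels)
}

#' Count holes in a surface scan
#'
#' The number of interior boundary loops of the patch: the total number of
#' boundary loops minus the outer rim. Holes in symphyseal scans reflect
#' bone porosity, which increases with age; this count is model feature x6.
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @return nonnegative integer.
#' @export
count_holes <- function(mesh) {
  length(boundary_loops(mesh)$loops) - 1L
}

#' Extract the six surface features of a symphyseal scan
#'
#' Composes the full feature pipeline on an articular-surface mesh:
#' pose canonicalization, per-vertex Dirichlet normal energy and mean
#' curvature (features x1 and x2 are their standard deviations), 0.1 mm
#' height-grid rasterization, bulge segmentation, moment-ellipse fitting and
#' orientation classification (x3 total, x4 horizontal, x5 vertical), and
#' the mesh hole count (x6). Right-sided scans are mirrored to the left side
#' first.
#'
#' @param mesh a \code{\link{triangle_mesh}} of the articular surface only.
#' @param cfg a \code{\link{feature_config}}.
#' @param raster_cfg a \code{\link{raster_config}}.
#' @return a named numeric vector of class \code{feature_vector} with
#'   elements x1..x6 and the configurations attached as attributes.
#' @export
extract_features <- function(mesh, cfg = feature_config(),
                             raster_cfg = raster_config()) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (mesh$side == "right") mesh <- mirror_mesh(mesh)
  x6 <- count_holes(mesh)
  aligned <- canonicalize_pose(mesh)
  geo <- local_geometry(aligned, cfg)
  grid <- rasterize_surface(aligned, raster_cfg)
  regions <- segment_bulges(grid, cfg)
  cls <- classify_ellipses(fit_ellipses(regions), cfg)
  fv <- c(x1 = stats::sd(geo$dne), x2 = stats::sd(geo$curvature),
          x3 = as.numeric(cls$x3), x4 = as.numeric(cls$x4),
          x5 = as.numeric(cls$x5), x6 = as.numeric(x6))
  attr(fv, "feature_config") <- cfg
  attr(fv, "raster_config") <- raster_cfg
  class(fv) <- "feature_vector"
  fv
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("feature_vector:\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Extract features for a set of scans into a feature table
#'
#' Runs \code{\link{extract_features}} on each mesh and binds the results
#' with the scan metadata into the feature-table contract used by model
#' fitting and cross-validation.
#'
#' @param meshes named list of \code{\link{triangle_mesh}} objects; names
#'   are the scan ids.
#' @param info optional data frame with columns \code{scan_id},
#'   \code{individual_id}, \code{side} and optionally \code{age} (e.g. the
#'   truth table of \code{\link{generate_cohort}}). When omitted, each scan
#'   is its own individual.
#' @param cfg a \code{\link{feature_config}}.
#' @param raster_cfg a \code{\link{raster_config}}.
#' @return a feature table data frame.
#' @export
extract_feature_table <- function(meshes, info = NULL,
                                  cfg = feature_config(),
                                  raster_cfg = raster_config()) {
  stopifnot(is.list(meshes), length(meshes) > 0L,
            !is.null(names(meshes)), all(nzchar(names(meshes))))
  fvs <- lapply(meshes, extract_features, cfg = cfg,
                raster_cfg = raster_cfg)
  tab <- as.data.frame(do.call(rbind, lapply(fvs, unclass)))
  tab <- cbind(data.frame(scan_id = names(meshes),
                          stringsAsFactors = FALSE), tab)
  rownames(tab) <- NULL
  if (is.null(info)) {
    tab$individual_id <- tab$scan_id
    tab$side <- vapply(meshes, `[[`, "", "side")
  } else {
    m <- match(tab$scan_id, info$scan_id)
    if (anyNA(m)) stop("info lacks rows for: ",
                       paste(tab$scan_id[is.na(m)], collapse = ", "))
    tab$individual_id <- info$individual_id[m]
    tab$side <- info$side[m]
    if ("age" %in% names(info)) tab$age <- info$age[m]
  }
  cols <- c("scan_id", "individual_id", "side", paste0("x", 1:6),
            intersect("age", names(tab)))
  tab[, cols]
}

#' Write / read a feature table
#'
#' Tab-delimited text with columns \code{scan_id}, \code{individual_id},
#' \code{side}, \code{x1}..\code{x6} and optionally \code{age}; the file is
#' the contract between feature extraction and model fitting.
#'
#' @param tab data frame with the columns above.
#' @param path file path.
#' @return \code{path} (writer) or the data frame (reader).
#' @export
write_feature_table <- function(tab, path) {
  need <- c("scan_id", "individual_id", "side", paste0("x", 1:6))
  if (!all(need %in% names(tab)))
    stop("feature table must contain: ", paste(need, collapse = ", "))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("scan_id", "individual_id", "side", paste0("x", 1:6))
  if (!all(need %in% names(tab)))
    stop("feature table must contain: ", paste(need, collapse = ", "))
  tab
}
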