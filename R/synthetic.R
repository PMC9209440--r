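#' Specification of a synthetic symphyseal-like surface
#'
#' Describes one generated surface patch: a rectangular base carrying a
#' sinusoidal ridge field (the billowing of young faces), negative Gaussian
#' pits, white surface roughness, and punched holes (porosity). This is the
#' minimal generative family that exercises every feature extractor; it
#' makes no claim of anatomical realism.
#'
#' @param true_age years in [18, 92]; carried into the ground-truth record.
#' @param extent (length, width) of the patch in mm.
#' @param ridge_amplitude mm; amplitude of the sinusoidal ridges.
#' @param ridge_wavelength mm; crest-to-crest distance (default 4 mm, within
#'   the segmentation baseline's pass-band).
#' @param ridge_angle_deg orientation of the ridge crest lines to +x;
#'   90 means crests run across the patch width (transverse billows appear
#'   as vertically elongated regions in the canonical frame).
#' @param n_pits count of Gaussian depressions.
#' @param pit_depth mm; depth of each pit.
#' @param pit_sigma mm; Gaussian radius of each pit.
#' @param n_holes count of punched holes (interior vertex stars removed).
#' @param noise_mm standard deviation of white vertex roughness.
#' @param mesh_resolution mm; vertex spacing of the grid triangulation.
#' @param seed integer seed.
#' @return a \code{surface_spec} list.
#' @export
surface_spec <- function(true_age = 40, extent = c(35, 15),
                         ridge_amplitude = 0.5, ridge_wavelength = 4,
                         ridge_angle_deg = 90, n_pits = 0L,
                         pit_depth = 0.3, pit_sigma = 0.8,
                         n_holes = 0L, noise_mm = 0.01,
                         mesh_resolution = 0.5, seed = 1L) {
  stopifnot(length(extent) == 2L, all(extent > 0), ridge_amplitude >= 0,
            ridge_wavelength > 0, n_pits >= 0, pit_depth >= 0,
            pit_sigma > 0, n_holes >= 0, noise_mm >= 0,
            mesh_resolution > 0, mesh_resolution < min(extent) / 10)
  structure(list(true_age = true_age, extent = extent,
                 ridge_amplitude = ridge_amplitude,
                 ridge_wavelength = ridge_wavelength,
                 ridge_angle_deg = ridge_angle_deg,
                 n_pits = as.integer(n_pits), pit_depth = pit_depth,
                 pit_sigma = pit_sigma, n_holes = as.integer(n_holes),
                 noise_mm = noise_mm, mesh_resolution = mesh_resolution,
                 seed = as.integer(seed)),
            class = "surface_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic symphyseal-like surface
#'
#' Triangulates z(x, y) = ridge field + pit field + roughness on a regular
#' grid over the patch extent and punches \code{n_holes} interior holes by
#' removing whole vertex stars. Hole sites keep at least three grid cells
#' between each other and two from the patch boundary so each removal
#' creates one separate interior loop; sites are re-sampled when the
#' constraints fail, with an error after 100 attempts.
#'
#' @param spec a \code{\link{surface_spec}}.
#' @return list with \code{mesh} (a \code{\link{triangle_mesh}}, side
#'   \code{"left"}) and \code{truth} (the planted ground-truth record).
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  res <- spec$mesh_resolution
  nx <- as.integer(round(spec$extent[1] / res))
  ny <- as.integer(round(spec$extent[2] / res))
  xs <- seq(0, by = res, length.out = nx + 1L)
  ys <- seq(0, by = res, length.out = ny + 1L)
  X <- matrix(xs, nx + 1L, ny + 1L)
  Y <- matrix(ys, nx + 1L, ny + 1L, byrow = TRUE)

  theta <- spec$ridge_angle_deg * pi / 180
  s <- -X * sin(theta) + Y * cos(theta)   # coordinate across the crests
  Z <- spec$ridge_amplitude * sin(2 * pi * s / spec$ridge_wavelength)

  truth <- list(spec = spec, n_holes = spec$n_holes, n_pits = spec$n_pits,
                n_ridges = floor((abs(sin(theta)) * spec$extent[1] +
                                    abs(cos(theta)) * spec$extent[2]) /
                                   spec$ridge_wavelength))

  with_seed(spec$seed, {
    if (spec$n_pits > 0L) {
      margin <- 3 * spec$pit_sigma
      px <- stats::runif(spec$n_pits, margin, spec$extent[1] - margin)
      py <- stats::runif(spec$n_pits, margin, spec$extent[2] - margin)
      for (p in seq_len(spec$n_pits)) {
        d2 <- (X - px[p])^2 + (Y - py[p])^2
        Z <- Z - spec$pit_depth * exp(-d2 / (2 * spec$pit_sigma^2))
      }
      truth$pit_centers <- cbind(x = px, y = py)
    }
    if (spec$noise_mm > 0)
      Z <- Z + stats::rnorm(length(Z), sd = spec$noise_mm)

    hole_ij <- NULL
    if (spec$n_holes > 0L) {
      if (nx < 8L || ny < 8L) stop("patch too small to punch holes")
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        hi <- sample(3:(nx - 1L), spec$n_holes, replace = TRUE)
        hj <- sample(3:(ny - 1L), spec$n_holes, replace = TRUE)
        if (spec$n_holes == 1L ||
            min(as.matrix(stats::dist(cbind(hi, hj),
                                      method = "maximum"))[
              upper.tri(diag(spec$n_holes))]) >= 3) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place non-overlapping holes in 100 attempts")
      hole_ij <- cbind(hi, hj)
      truth$hole_sites <- cbind(x = xs[hi], y = ys[hj])
    }
  })

  vid <- function(i, j) (j - 1L) * (nx + 1L) + i   # i along x, j along y
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  v00 <- vid(i, j); v10 <- vid(i + 1L, j)
  v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  if (!is.null(hole_ij)) {
    drop_v <- vid(hole_ij[, 1], hole_ij[, 2])
    keep <- !(faces[, 1] %in% drop_v | faces[, 2] %in% drop_v |
                faces[, 3] %in% drop_v)
    faces <- faces[keep, , drop = FALSE]
  }
  verts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  mesh <- triangle_mesh(verts, faces,
                        provenance = sprintf("synthetic(seed=%d)", spec$seed),
                        side = "left")
  list(mesh = mesh, truth = truth)
}

#' Default age-to-morphology map
#'
#' Linear trends over 18 to 92 years emulating symphyseal aging: ridge
#' amplitude falls from 0.8 to 0.05 mm (billows flatten), pits rise from 0
#' to 15 and holes from 0 to 10 (porosity), roughness rises from 0.01 to
#' 0.08 mm (irregularity).
#'
#' @param age years.
#' @return list with \code{ridge_amplitude}, \code{n_pits}, \code{n_holes},
#'   \code{noise_mm}.
#' @export
default_aging_map <- function(age) {
  t <- pmin(pmax((age - 18) / (92 - 18), 0), 1)
  list(ridge_amplitude = 0.8 + t * (0.05 - 0.8),
       n_pits = as.integer(round(15 * t)),
       n_holes = as.integer(round(10 * t)),
       noise_mm = 0.01 + t * (0.08 - 0.01))
}

#' Specification of a synthetic cohort
#'
#' @param n_individuals number of individuals.
#' @param age_sampler \code{"uniform_18_92"} draws integer ages uniformly;
#'   \code{"table2_categories"} allocates individuals to the six age
#'   categories of the reference sample (18-29, 30-39, ..., 70+) in
#'   proportion 33:87:90:95:80:98 by largest remainder, then draws ages
#'   uniformly within each category (70+ spans 70-92).
#' @param bilateral_fraction fraction of individuals contributing both a
#'   left and a right scan; the reference sample had 104 of 374.
#' @param aging_map function age -> generator parameters, see
#'   \code{\link{default_aging_map}}.
#' @param mesh_resolution,extent forwarded to \code{\link{surface_spec}}.
#' @param noise_seed integer seed for the whole cohort.
#' @return a \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_individuals,
                        age_sampler = c("uniform_18_92",
                                        "table2_categories"),
                        bilateral_fraction = 104 / 374,
                        aging_map = default_aging_map,
                        mesh_resolution = 0.5, extent = c(35, 15),
                        noise_seed = 1L) {
  age_sampler <- match.arg(age_sampler)
  stopifnot(n_individuals >= 1, bilateral_fraction >= 0,
            bilateral_fraction <= 1, is.function(aging_map))
  structure(list(n_individuals = as.integer(n_individuals),
                 age_sampler = age_sampler,
                 bilateral_fraction = bilateral_fraction,
                 aging_map = aging_map,
                 mesh_resolution = mesh_resolution, extent = extent,
                 noise_seed = as.integer(noise_seed)),
            class = "cohort_spec")
}

sample_ages <- function(n, sampler) {
  if (sampler == "uniform_18_92") return(sample(18:92, n, replace = TRUE))
  counts <- c(33, 87, 90, 95, 80, 98)       # reference bone counts
  lo <- c(18, 30, 40, 50, 60, 70)
  hi <- c(29, 39, 49, 59, 69, 92)
  share <- n * counts / sum(counts)
  k <- floor(share)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(share - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  ages <- unlist(lapply(seq_along(k), function(c)
    if (k[c] > 0) sample(lo[c]:hi[c], k[c], replace = TRUE) else integer(0)))
  sample(ages)  # shuffle category order
}

#' Generate a synthetic cohort of symphyseal-like scans
#'
#' Draws an age per individual, maps it through the aging map to a
#' \code{\link{surface_spec}}, and generates one scan (or two with
#' independent roughness for bilateral individuals, the second mirrored to
#' the right side). Ridge orientation is drawn uniformly over [0, 180) per
#' individual so that both oriented ellipse counts vary across the cohort.
#' The truth table is compatible with the feature-table contract and carries
#' the planted generator parameters.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{meshes} (named list of \code{triangle_mesh}) and
#'   \code{truth} (data frame with scan_id, individual_id, side, age and the
#'   planted parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_individuals
  plan <- with_seed(spec$noise_seed, {
    ages <- sample_ages(n, spec$age_sampler)
    n_bi <- round(spec$bilateral_fraction * n)
    bilateral <- seq_len(n) %in% sample(seq_len(n), n_bi)
    seeds <- sample.int(.Machine$integer.max - 1L, n + n_bi)
    # ridge orientation varies across individuals so that both oriented
    # ellipse features (x4 and x5) carry variation in the cohort
    angles <- stats::runif(n, 0, 180)
    list(ages = ages, bilateral = bilateral, seeds = seeds,
         angles = angles)
  })

  meshes <- list()
  rows <- list()
  scan_seed <- 0L
  for (i in seq_len(n)) {
    age <- plan$ages[i]
    pars <- spec$aging_map(age)
    sides <- if (plan$bilateral[i]) c("left", "right") else "left"
    for (side in sides) {
      scan_seed <- scan_seed + 1L
      sp <- surface_spec(true_age = age, extent = spec$extent,
                         ridge_amplitude = pars$ridge_amplitude,
                         ridge_angle_deg = plan$angles[i],
                         n_pits = pars$n_pits, n_holes = pars$n_holes,
                         noise_mm = pars$noise_mm,
                         mesh_resolution = spec$mesh_resolution,
                         seed = plan$seeds[scan_seed])
      g <- generate_surface(sp)
      mesh <- g$mesh
      if (side == "right") mesh <- mirror_mesh(mesh)
      scan_id <- sprintf("ind%04d_%s", i, substr(side, 1, 1))
      meshes[[scan_id]] <- mesh
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = scan_id, individual_id = sprintf("ind%04d", i),
        side = side, age = age,
        ridge_amplitude = pars$ridge_amplitude, n_pits = pars$n_pits,
        n_holes = pars$n_holes, noise_mm = pars$noise_mm,
        seed = plan$seeds[scan_seed], stringsAsFactors = FALSE)
    }
  }
  list(meshes = meshes, truth = do.call(rbind, rows))
}

#' Simulate a feature table with a known linear age relation
#'
#' Generates plausible feature columns and sets
#' age = offset + sum(slopes * x) + Gaussian noise, so model fitting and
#' cross-validation can be checked against known coefficients and a known
#' noise level.
#'
#' @param n rows (scans); each row is its own individual.
#' @param slopes named numeric vector over any of x1..x6 (unnamed features
#'   get slope 0).
#' @param offset intercept in years.
#' @param noise_sd residual standard deviation in years.
#' @param seed integer seed.
#' @return a feature table data frame with an \code{age} column.
#' @export
simulate_feature_table <- function(n, slopes = c(x3 = 2), offset = 20,
                                   noise_sd = 8, seed = 1L) {
  with_seed(seed, {
    tab <- data.frame(
      scan_id = sprintf("scan%05d", seq_len(n)),
      individual_id = sprintf("ind%05d", seq_len(n)),
      side = "left",
      x1 = abs(stats::rnorm(n, 2e-6, 1e-6)),
      x2 = abs(stats::rnorm(n, 0.05, 0.02)),
      x3 = stats::rpois(n, 20),
      x4 = stats::rpois(n, 3),
      x5 = stats::rpois(n, 8),
      x6 = stats::rpois(n, 4),
      stringsAsFactors = FALSE)
    full <- stats::setNames(numeric(6), paste0("x", 1:6))
    full[names(slopes)] <- slopes
    tab$age <- offset + as.vector(as.matrix(tab[, names(full)]) %*% full) +
      stats::rnorm(n, sd = noise_sd)
    tab
  })
}
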