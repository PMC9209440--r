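test_that("a flat plane has zero local energy and curvature everywhere", {
  al <- as_aligned(grid_mesh(extent = c(10, 6), res = 0.4))
  expect_lt(max(abs(local_dne(al))), 1e-8)
  expect_lt(max(abs(local_curvature(al))), 1e-8)
})

test_that("tighter spheres have uniformly larger local energy", {
  cap1 <- as_aligned(sphere_cap_mesh(r = 4, rho = 2.5, res = 0.25))
  cap2 <- as_aligned(sphere_cap_mesh(r = 8, rho = 2.5, res = 0.25))
  # identical tessellation pattern, so vertices correspond one-to-one
  interior <- {
    v <- cap1$mesh$vertices
    ctr <- colMeans(v)
    (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2 < 1.5^2
  }
  e1 <- local_dne(cap1)
  e2 <- local_dne(cap2)
  expect_true(all(e1[interior] > e2[interior]))
})

test_that("energy spread grows with ridge amplitude", {
  sds <- vapply(c(0.1, 0.3, 0.5), function(A) {
    al <- as_aligned(grid_mesh(function(x, y) A * sin(x),
                               extent = c(12, 6), res = 0.3))
    stats::sd(local_dne(al))
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("sphere-cap mean curvature is close to 1/r away from the rim", {
  for (r in c(4, 6)) {
    al <- as_aligned(sphere_cap_mesh(r = r, rho = 2.5, res = 0.2))
    v <- al$mesh$vertices
    ctr <- colMeans(v)
    interior <- (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2 < 1.2^2
    k <- local_curvature(al)
    expect_equal(median(k[interior]), 1 / r, tolerance = 0.1)
    expect_true(all(abs(k[interior] - 1 / r) < 0.1 / r + 0.02))
  }
})

test_that("curvature flips sign under z-reflection", {
  m <- grid_mesh(function(x, y) 0.4 * sin(x) * cos(0.8 * y),
                 extent = c(10, 6), res = 0.3)
  # reflect coordinates only: the winding (hence the normal field) is kept,
  # so what bulged along the normal now dents, and the sign must flip
  refl <- m
  refl$vertices[, 3] <- -refl$vertices[, 3]
  k1 <- local_curvature(as_aligned(m))
  k2 <- local_curvature(as_aligned(refl))
  expect_equal(k2, -k1, tolerance = 1e-6)
})

test_that("a too-small bandwidth raises an increase-bandwidth error", {
  al <- as_aligned(grid_mesh(extent = c(10, 6), res = 0.5))
  expect_error(local_dne(al, feature_config(dne_bandwidth_fraction = 1e-4)),
               "bandwidth")
})

test_that("a constant grid yields no bulging regions", {
  z <- matrix(1.7, 60, 80)
  seg <- segment_bulges(grid_from_matrix(z), feature_config())
  expect_equal(seg$n_regions, 0L)
})

test_that("five planted Gaussian bumps segment into five regions", {
  nx <- 300; ny <- 160; cs <- 0.1
  xc <- (seq_len(nx) - 0.5) * cs
  yc <- (seq_len(ny) - 0.5) * cs
  z <- matrix(0, ny, nx)
  centers <- cbind(x = c(5, 12, 19, 26, 15), y = c(4, 12, 5, 11, 7))
  for (b in seq_len(nrow(centers)))
    z <- z + 0.5 * exp(-(outer(yc, xc, function(y, x)
      (x - centers[b, 1])^2 + (y - centers[b, 2])^2)) / (2 * 0.6^2))
  seg <- segment_bulges(grid_from_matrix(z, cs), feature_config())
  expect_equal(seg$n_regions, 5L)
})

test_that("bumps merge inside the smoothing support and separate outside it", {
  two_bumps <- function(d) {
    nx <- 260; ny <- 100; cs <- 0.1
    xc <- (seq_len(nx) - 0.5) * cs
    yc <- (seq_len(ny) - 0.5) * cs
    x1 <- 13 - d / 2; x2 <- 13 + d / 2
    z <- matrix(0, ny, nx)
    for (cx in c(x1, x2))
      z <- z + 0.5 * exp(-(outer(yc, xc, function(y, x)
        (x - cx)^2 + (y - 5)^2)) / (2 * 0.5^2))
    segment_bulges(grid_from_matrix(z, cs), feature_config())$n_regions
  }
  expect_equal(two_bumps(1), 1L)
  expect_equal(two_bumps(6), 2L)
})

test_that("moment ellipses match the closed form for a rectangle", {
  lab <- matrix(0L, 40, 60)
  lab[10:20, 15:45] <- 1L     # 31 cells along x, 11 along y
  e <- fit_ellipses(regions_from_matrix(lab, cell_size = 0.1))
  expect_equal(nrow(e), 1L)
  expect_lt(abs(e$orientation_deg - 0) %% 180, 1e-6)
  expect_equal(e$major_axis_length / e$minor_axis_length, 31 / 11,
               tolerance = 1e-9)
  expect_equal(e$area, 31 * 11 * 0.01)

  rot <- fit_ellipses(regions_from_matrix(t(lab), cell_size = 0.1))
  expect_equal(rot$orientation_deg, 90)
})

test_that("a circular region has near-zero eccentricity", {
  n <- 61
  lab <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 < 25^2) lab[i, j] <- 1L
  e <- fit_ellipses(regions_from_matrix(lab))
  expect_lt(e$eccentricity, 0.1)
})

test_that("tiny regions are skipped with a logged count", {
  lab <- matrix(0L, 20, 20)
  lab[3, 3:4] <- 1L            # 2 cells: below the 3-cell floor
  lab[10:14, 10:14] <- 2L
  expect_message(e <- fit_ellipses(regions_from_matrix(lab)), "skipped")
  expect_equal(nrow(e), 1L)
})

test_that("ellipse classification follows the published threshold rules", {
  mk <- function(major, minor, orient, area) data.frame(
    centroid_x = 0, centroid_y = 0, major_axis_length = major,
    minor_axis_length = minor, orientation_deg = orient,
    eccentricity = sqrt(1 - (minor / major)^2), area = area)
  cfg <- feature_config()

  # eccentricity 0.79, major 10 mm, area 20 mm^2, alpha 80 deg -> circular
  e <- mk(10, 10 * sqrt(1 - 0.79^2), 80, 20)
  expect_equal(as.character(classify_ellipses(e, cfg)$labels), "circular_like")
  # small overrides everything
  expect_equal(as.character(classify_ellipses(mk(2.9, 0.5, 80, 20),
                                              cfg)$labels), "small")
  expect_equal(as.character(classify_ellipses(mk(10, 1, 80, 1.4),
                                              cfg)$labels), "small")
  # oriented labels on clear cases
  expect_equal(as.character(classify_ellipses(mk(10, 1, 10, 20),
                                              cfg)$labels), "horizontal")
  expect_equal(as.character(classify_ellipses(mk(10, 1, 100, 20),
                                              cfg)$labels), "vertical")
  expect_equal(as.character(classify_ellipses(mk(10, 1, 45, 20),
                                              cfg)$labels), "uncertain")
})

test_that("classification agrees with a direct transcription of the rules", {
  oracle <- function(major, minor, orient, area, ecc) {
    alpha <- orient %% 180
    if (alpha > 90) alpha <- 180 - alpha
    if (major < 3 || area < 1.5) return("small")
    if (ecc < 0.8) return("circular_like")
    if (abs(alpha - 45) <= 10) return("uncertain")
    if (alpha < 45) "horizontal" else "vertical"
  }
  set.seed(99)
  n <- 1000
  major <- stats::runif(n, 0.5, 12)
  minor <- major * stats::runif(n, 0.05, 1)
  e <- data.frame(centroid_x = 0, centroid_y = 0,
                  major_axis_length = major, minor_axis_length = minor,
                  orientation_deg = stats::runif(n, 0, 180),
                  eccentricity = sqrt(1 - (minor / major)^2),
                  area = stats::runif(n, 0.2, 30))
  got <- classify_ellipses(e, feature_config())
  want <- mapply(oracle, major, minor, e$orientation_deg, e$area,
                 e$eccentricity)
  expect_equal(as.character(got$labels), unname(want))
  expect_equal(got$x4, sum(want == "horizontal"))
  expect_equal(got$x5, sum(want == "vertical"))
  expect_equal(got$x3, n)
})

test_that("hole counts recover the planted ground truth", {
  expect_equal(count_holes(disc_mesh(radius = 4, res = 0.5)), 0L)
  g <- generate_surface(surface_spec(n_holes = 7L, noise_mm = 0.02,
                                     seed = 21))
  expect_equal(count_holes(g$mesh), 7L)
  expect_equal(count_holes(fill_holes(g$mesh)), 0L)
})

test_that("a featureless flat square gives the all-zero feature vector", {
  g <- generate_surface(surface_spec(ridge_amplitude = 0, n_pits = 0L,
                                     n_holes = 0L, noise_mm = 0))
  fv <- extract_features(g$mesh)
  expect_equal(as.vector(unclass(fv)), rep(0, 6))
})

test_that("ridges and holes are recovered from a constructed fixture", {
  g <- generate_surface(surface_spec(ridge_amplitude = 0.5,
                                     ridge_wavelength = 35 / 6,
                                     ridge_angle_deg = 90,
                                     n_holes = 4L, noise_mm = 0.01,
                                     seed = 13))
  fv <- extract_features(g$mesh)
  expect_equal(fv[["x6"]], 4)
  expect_gte(fv[["x3"]], 6)
  # transverse ridges are elongated across the patch: vertical majority
  expect_gt(fv[["x5"]], fv[["x4"]])
})

test_that("feature extraction is deterministic", {
  g <- generate_surface(surface_spec(n_pits = 4L, n_holes = 2L,
                                     noise_mm = 0.03, seed = 4))
  expect_identical(unclass(extract_features(g$mesh)),
                   unclass(extract_features(g$mesh)))
})

test_that("all six features are invariant under rigid motion", {
  g <- generate_surface(surface_spec(ridge_amplitude = 0.4, n_pits = 3L,
                                     n_holes = 2L, noise_mm = 0.02,
                                     seed = 17))
  ref <- unclass(extract_features(g$mesh))
  set.seed(123)
  for (i in 1:20) {
    fv <- unclass(extract_features(rigid_transform(g$mesh)))
    expect_equal(fv[3:6], ref[3:6])            # counts exact
    expect_equal(fv[1:2], ref[1:2], tolerance = 1e-6)
  }
})

test_that("oriented counts never exceed the total ellipse count", {
  set.seed(31)
  for (i in 1:6) {
    g <- generate_surface(surface_spec(ridge_amplitude = stats::runif(1, 0, 0.8),
                                       n_pits = sample(0:10, 1),
                                       n_holes = sample(0:5, 1),
                                       noise_mm = stats::runif(1, 0, 0.06),
                                       seed = i))
    fv <- extract_features(g$mesh)
    expect_lte(fv[["x4"]] + fv[["x5"]], fv[["x3"]])
    expect_true(all(fv[c("x1", "x2")] >= 0))
  }
})

test_that("feature tables survive the text contract round-trip", {
  coh <- generate_cohort(cohort_spec(3, bilateral_fraction = 1 / 3,
                                     noise_seed = 2))
  tab <- extract_feature_table(coh$meshes, coh$truth)
  expect_equal(nrow(tab), length(coh$meshes))
  expect_true(all(c("scan_id", "individual_id", "side", "age") %in%
                    names(tab)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$x1, tab$x1, tolerance = 1e-12)
  expect_equal(back$scan_id, tab$scan_id)
})
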