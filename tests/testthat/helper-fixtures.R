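# Fixtures are built in code: regular-grid triangulations of analytic
# surfaces, optionally masked to a sub-region (disc, cut corner, ...).

grid_mesh <- function(fz = function(x, y) 0 * x, extent = c(10, 6),
                      res = 0.5, keep = NULL, side = "left") {
  nx <- round(extent[1] / res)
  ny <- round(extent[2] / res)
  xs <- seq(0, by = res, length.out = nx + 1)
  ys <- seq(0, by = res, length.out = ny + 1)
  X <- matrix(xs, nx + 1, ny + 1)
  Y <- matrix(ys, nx + 1, ny + 1, byrow = TRUE)
  Z <- fz(X, Y)
  v <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
             cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  if (!is.null(keep)) {
    cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
    cy <- (v[f[, 1], 2] + v[f[, 2], 2] + v[f[, 3], 2]) / 3
    f <- f[keep(cx, cy), , drop = FALSE]
  }
  triangle_mesh(v, f, provenance = "fixture", side = side)
}

disc_mesh <- function(radius = 5, res = 0.4, fz = function(x, y) 0 * x) {
  grid_mesh(fz, extent = c(2.2 * radius, 2.2 * radius), res = res,
            keep = function(cx, cy)
              (cx - 1.1 * radius)^2 + (cy - 1.1 * radius)^2 < radius^2)
}

# spherical cap of radius r over a base disc of radius rho, dome up
sphere_cap_mesh <- function(r = 5, rho = 3, res = 0.25) {
  ctr <- 1.1 * rho
  grid_mesh(function(x, y) {
    d2 <- pmin((x - ctr)^2 + (y - ctr)^2, (0.999 * r)^2)
    sqrt(r^2 - d2)
  }, extent = c(2.2 * rho, 2.2 * rho), res = res,
  keep = function(cx, cy) (cx - ctr)^2 + (cy - ctr)^2 < rho^2)
}

# hand-built aligned_mesh wrapper bypassing pose canonicalization,
# for oracles that need a known frame and normal orientation
as_aligned <- function(mesh) {
  structure(list(mesh = mesh, rotation = diag(3),
                 translation = c(0, 0, 0),
                 extents = apply(mesh$vertices, 2,
                                 function(x) diff(range(x)))),
            class = "aligned_mesh")
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(mesh, rot = random_rotation(),
                            shift = stats::rnorm(3, sd = 20)) {
  mesh$vertices <- mesh$vertices %*% t(rot) +
    matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# height_grid built directly from a matrix (rows = y, cols = x)
grid_from_matrix <- function(z, cell_size = 0.1, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(z)
  structure(list(z = z, valid = valid, cell_size = cell_size,
                 origin = c(cell_size / 2, cell_size / 2)),
            class = "height_grid")
}

# region_map built directly from a label matrix
regions_from_matrix <- function(labels, cell_size = 0.1) {
  structure(list(labels = labels, n_regions = max(labels),
                 cell_size = cell_size, origin = c(0, 0)),
            class = "region_map")
}

expect_mesh_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a$vertices), nrow(b$vertices))
  expect_equal(nrow(a$faces), nrow(b$faces))
  ka <- order(a$vertices[, 1], a$vertices[, 2], a$vertices[, 3])
  kb <- order(b$vertices[, 1], b$vertices[, 2], b$vertices[, 3])
  expect_lt(max(abs(a$vertices[ka, ] - b$vertices[kb, ])), tol)
  # face sets compared as sorted index triples after vertex reordering
  ra <- integer(nrow(a$vertices)); ra[ka] <- seq_along(ka)
  rb <- integer(nrow(b$vertices)); rb[kb] <- seq_along(kb)
  fa <- t(apply(matrix(ra[a$faces], ncol = 3), 1, sort))
  fb <- t(apply(matrix(rb[b$faces], ncol = 3), 1, sort))
  fa <- fa[order(fa[, 1], fa[, 2], fa[, 3]), , drop = FALSE]
  fb <- fb[order(fb[, 1], fb[, 2], fb[, 3]), , drop = FALSE]
  expect_identical(fa, fb)
}
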