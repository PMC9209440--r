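// Geometry kernels: top-view rasterization, kernel-weighted local surface
// descriptors (Dirichlet normal energy, mean curvature), masked separable
// Gaussian smoothing and 8-connected labeling of raster foregrounds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rasterization: for every sample point covered by a triangle's x-y
// projection, keep the largest z among plane intersections (top view).
// Supersampling (s x s points per cell) supports fractional cell coverage.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rasterize(const arma::mat& V, const arma::imat& F,
                   double xmin, double ymin, double cell,
                   int nx, int ny, int super, double min_cov) {
  const int s = super < 1 ? 1 : super;
  const int NX = nx * s, NY = ny * s;
  const double sub = cell / s;
  arma::mat zbest(NY, NX);
  zbest.fill(-arma::datum::inf);
  std::vector<char> hit((size_t)NX * NY, 0);

  const double eps = 1e-12;
  for (arma::uword f = 0; f < F.n_rows; ++f) {
    const arma::uword a = F(f, 0), b = F(f, 1), c = F(f, 2);
    const double ax = V(a,0), ay = V(a,1), az = V(a,2);
    const double bx = V(b,0), by = V(b,1), bz = V(b,2);
    const double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    const double lox = std::min(ax, std::min(bx, cx));
    const double hix = std::max(ax, std::max(bx, cx));
    const double loy = std::min(ay, std::min(by, cy));
    const double hiy = std::max(ay, std::max(by, cy));
    // sample index range overlapping the triangle bbox
    int i0 = (int)std::floor((lox - xmin) / sub - 0.5);
    int i1 = (int)std::ceil ((hix - xmin) / sub - 0.5);
    int j0 = (int)std::floor((loy - ymin) / sub - 0.5);
    int j1 = (int)std::ceil ((hiy - ymin) / sub - 0.5);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0);
    i1 = std::min(i1, NX - 1); j1 = std::min(j1, NY - 1);
    if (i0 > i1 || j0 > j1) continue;
    const double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
    if (std::fabs(d) < eps) continue; // zero-area projection
    for (int i = i0; i <= i1; ++i) {
      const double px = xmin + (i + 0.5) * sub;
      for (int j = j0; j <= j1; ++j) {
        const double py = ymin + (j + 0.5) * sub;
        const double w1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        const double w2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        const double w3 = 1.0 - w1 - w2;
        const double tol = 1e-9;
        if (w1 < -tol || w2 < -tol || w3 < -tol) continue;
        const double z = w1 * az + w2 * bz + w3 * cz;
        if (z > zbest(j, i)) zbest(j, i) = z;
        hit[(size_t)i * NY + j] = 1;
      }
    }
  }

  NumericMatrix z(ny, nx);
  LogicalMatrix valid(ny, nx);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      int cov = 0;
      double zm = -arma::datum::inf;
      for (int a = 0; a < s; ++a) {
        for (int bb = 0; bb < s; ++bb) {
          const int I = i * s + a, J = j * s + bb;
          if (hit[(size_t)I * NY + J]) {
            ++cov;
            if (zbest(J, I) > zm) zm = zbest(J, I);
          }
        }
      }
      const double frac = (double)cov / (s * s);
      if (cov > 0 && frac >= min_cov - 1e-12) {
        valid(j, i) = true;
        z(j, i) = zm;
      } else {
        valid(j, i) = false;
        z(j, i) = NA_REAL;
      }
    }
  }
  return List::create(_["z"] = z, _["valid"] = valid);
}

// ---------------------------------------------------------------------------
// Per-vertex normals (area-weighted) and Voronoi-style vertex areas
// (one third of incident face areas).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_vertex_normals_areas(const arma::mat& V, const arma::imat& F) {
  const arma::uword n = V.n_rows;
  arma::mat N(n, 3, arma::fill::zeros);
  arma::vec A(n, arma::fill::zeros);
  for (arma::uword f = 0; f < F.n_rows; ++f) {
    const arma::uword a = F(f,0), b = F(f,1), c = F(f,2);
    const arma::rowvec e1 = V.row(b) - V.row(a);
    const arma::rowvec e2 = V.row(c) - V.row(a);
    arma::rowvec fn(3);
    fn(0) = e1(1)*e2(2) - e1(2)*e2(1);
    fn(1) = e1(2)*e2(0) - e1(0)*e2(2);
    fn(2) = e1(0)*e2(1) - e1(1)*e2(0);
    const double area2 = arma::norm(fn, 2); // twice the area
    N.row(a) += fn; N.row(b) += fn; N.row(c) += fn;
    const double a3 = area2 / 6.0;          // area / 3
    A(a) += a3; A(b) += a3; A(c) += a3;
  }
  for (arma::uword i = 0; i < n; ++i) {
    const double len = arma::norm(N.row(i), 2);
    if (len > 0) N.row(i) /= len;
  }
  return List::create(_["normals"] = N, _["areas"] = A);
}

// ---------------------------------------------------------------------------
// Kernel-weighted local surface descriptors. For each vertex p:
//   weights  w_j = exp(-|q_j - p|^2 / h^2) * a_j  (Gaussian x vertex area),
//            truncated at |q_j - p| > cutoff * h;
//   n_hat    smallest-eigenvalue direction of the weighted scatter of
//            neighbor positions, sign-aligned with the vertex normal;
//   dne      sum_j w_j |n_j - n_hat|^2 / sum_j w_j  (variation of the
//            normal map about the local fitted normal);
//   curv     mean curvature of the weighted least-squares quadric
//            w = a u^2 + b uv + c v^2 + d u + e v in the tangent frame,
//            sign positive where the surface bulges along n_hat.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_local_geometry(const arma::mat& V, const arma::mat& N,
                        const arma::vec& A, double h, double cutoff,
                        int min_neighbors) {
  const arma::uword n = V.n_rows;
  const double r = cutoff * h, r2 = r * r, h2 = h * h;

  // spatial hash on a grid of bin size r: candidates within 27 bins
  arma::rowvec lo = arma::min(V, 0);
  auto bin_of = [&](arma::uword i, int d) {
    return (long)std::floor((V(i, d) - lo(d)) / r);
  };
  std::map<std::tuple<long,long,long>, std::vector<arma::uword>> bins;
  for (arma::uword i = 0; i < n; ++i)
    bins[std::make_tuple(bin_of(i,0), bin_of(i,1), bin_of(i,2))].push_back(i);

  arma::vec dne(n, arma::fill::zeros), curv(n, arma::fill::zeros);
  int too_few = 0;
  std::vector<arma::uword> idx;
  idx.reserve(256);

  for (arma::uword i = 0; i < n; ++i) {
    idx.clear();
    const long bx = bin_of(i,0), by = bin_of(i,1), bz = bin_of(i,2);
    for (long dx = -1; dx <= 1; ++dx)
      for (long dy = -1; dy <= 1; ++dy)
        for (long dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(std::make_tuple(bx+dx, by+dy, bz+dz));
          if (it == bins.end()) continue;
          for (arma::uword j : it->second) {
            const double ddx = V(j,0)-V(i,0), ddy = V(j,1)-V(i,1),
                         ddz = V(j,2)-V(i,2);
            if (ddx*ddx + ddy*ddy + ddz*ddz <= r2) idx.push_back(j);
          }
        }
    if ((int)idx.size() - 1 < min_neighbors) { ++too_few; continue; }

    const arma::uword m = idx.size();
    arma::vec w(m);
    arma::mat Q(m, 3);
    for (arma::uword k = 0; k < m; ++k) {
      const arma::uword j = idx[k];
      Q.row(k) = V.row(j) - V.row(i);
      const double d2 = arma::dot(Q.row(k), Q.row(k));
      w(k) = std::exp(-d2 / h2) * A(j);
    }
    const double wsum = arma::accu(w);
    if (wsum <= 0) { ++too_few; continue; }

    // weighted scatter of positions -> local fitted normal
    arma::rowvec mu = (w.t() * Q) / wsum;
    arma::mat C(3, 3, arma::fill::zeros);
    for (arma::uword k = 0; k < m; ++k) {
      const arma::rowvec d = Q.row(k) - mu;
      C += w(k) * (d.t() * d);
    }
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, C);
    arma::vec nh = evec.col(0);
    if (arma::dot(nh, N.row(i).t()) < 0) nh = -nh;

    // Dirichlet normal energy: weighted variation of neighbor normals
    double e = 0.0;
    for (arma::uword k = 0; k < m; ++k) {
      const arma::rowvec d = N.row(idx[k]) - nh.t();
      e += w(k) * arma::dot(d, d);
    }
    dne(i) = e / wsum;

    // tangent frame
    arma::vec t1 = evec.col(2), t2 = evec.col(1);
    // quadric fit w = a u^2 + b uv + c v^2 + d u + e v
    arma::mat X(m, 5);
    arma::vec y(m);
    for (arma::uword k = 0; k < m; ++k) {
      const double u = arma::dot(Q.row(k), t1.t());
      const double v = arma::dot(Q.row(k), t2.t());
      X(k,0) = u*u; X(k,1) = u*v; X(k,2) = v*v; X(k,3) = u; X(k,4) = v;
      y(k) = arma::dot(Q.row(k), nh.t());
    }
    arma::mat Xw = X.each_col() % w;
    arma::mat G = Xw.t() * X;
    arma::vec g = Xw.t() * y;
    G.diag() += 1e-10 * (arma::trace(G) / 5.0 + 1e-30);
    arma::vec beta;
    if (!arma::solve(beta, G, g, arma::solve_opts::likely_sympd)) continue;
    const double fa = beta(0), fb = beta(1), fc = beta(2),
                 fd = beta(3), fe = beta(4);
    const double denom = std::pow(1.0 + fd*fd + fe*fe, 1.5);
    // mean curvature of z = f(u,v); sign flipped so a dome (surface
    // bulging along n_hat) is positive
    curv(i) = -((1.0 + fe*fe) * 2.0*fa - 2.0*fd*fe*fb +
                (1.0 + fd*fd) * 2.0*fc) / (2.0 * denom);
  }
  return List::create(_["dne"] = dne, _["curvature"] = curv,
                      _["too_few"] = too_few);
}

// ---------------------------------------------------------------------------
// Masked separable Gaussian smoothing: baseline = K*(z.m) / K*(m), the
// normalized convolution over valid cells only.
// ---------------------------------------------------------------------------

static void blur_1d(arma::mat& M, const arma::vec& k, bool along_rows) {
  const int rad = ((int)k.n_elem - 1) / 2;
  arma::mat out(M.n_rows, M.n_cols, arma::fill::zeros);
  if (along_rows) { // convolve each column (down rows)
    for (arma::uword c = 0; c < M.n_cols; ++c)
      for (int i = 0; i < (int)M.n_rows; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t) {
          const int ii = i + t;
          if (ii < 0 || ii >= (int)M.n_rows) continue;
          s += k(t + rad) * M(ii, c);
        }
        out(i, c) = s;
      }
  } else {
    for (arma::uword rI = 0; rI < M.n_rows; ++rI)
      for (int j = 0; j < (int)M.n_cols; ++j) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t) {
          const int jj = j + t;
          if (jj < 0 || jj >= (int)M.n_cols) continue;
          s += k(t + rad) * M(rI, jj);
        }
        out(rI, j) = s;
      }
  }
  M = out;
}

// [[Rcpp::export]]
NumericMatrix cpp_masked_gaussian(const NumericMatrix& zR,
                                  const LogicalMatrix& validR,
                                  double sigma_cells) {
  const int nr = zR.nrow(), nc = zR.ncol();
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma_cells));
  arma::vec k(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    k(t + rad) = std::exp(-0.5 * (t * t) / (sigma_cells * sigma_cells));
  k /= arma::accu(k);

  arma::mat zm(nr, nc, arma::fill::zeros), m(nr, nc, arma::fill::zeros);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (validR(i, j)) { zm(i, j) = zR(i, j); m(i, j) = 1.0; }

  blur_1d(zm, k, true);  blur_1d(zm, k, false);
  blur_1d(m,  k, true);  blur_1d(m,  k, false);

  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = (validR(i, j) && m(i, j) > 1e-12)
                    ? zm(i, j) / m(i, j) : NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected labeling of a logical foreground (stack flood fill).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& fg) {
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (fg(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.emplace_back(ni, nj);
            }
          }
      }
    }
  return lab;
}
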