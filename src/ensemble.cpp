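// Compiled kernels for ensemble construction and forward prediction.
// Everything here is called ~1e5 times per fit, once per Monte-Carlo
// chi-square evaluation, so the inner loops use raw arrays rather than
// vector-algebra temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void cross3d(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3d(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Signed dihedral (degrees, IUPAC convention) for points p1-p2-p3-p4.
static double dihedral4(const double *p1, const double *p2, const double *p3,
                        const double *p4) {
  double b1[3], b2[3], b3[3], c1[3], c2[3], cc[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  cross3d(b1, b2, c1);
  cross3d(b2, b3, c2);
  cross3d(c1, c2, cc);
  double x = dot3d(c1, c2);
  double y = dot3d(cc, b2) / std::sqrt(dot3d(b2, b2));
  return std::atan2(y, x) * 180.0 / M_PI;
}

// Build Cartesian conformers from a z-matrix by natural extension.
//
// parent/aref/dref are 0-based indices into already-placed rows.
// `lengths` is one bond length per row (Angstrom); cosA/sinA and
// cosD/sinD are n_conf x n_rows matrices holding the cosine/sine of the
// bond angles and reference dihedrals (precomputed by the caller: most
// columns are constant across conformers, so their trig is evaluated
// once).  Row k is placed so that
//   |X_k - X_parent| = length_k
//   angle(X_k, parent, aref) = angle_k
//   dihedral(X_k, parent, aref, dref) = dihedral_k  (IUPAC sign).
// Returns an n_rows x 3 x n_conf array.
// [[Rcpp::export]]
NumericVector nerf_build_cpp(const IntegerVector &parent,
                             const IntegerVector &aref,
                             const IntegerVector &dref,
                             const NumericVector &lengths,
                             const NumericMatrix &cosA,
                             const NumericMatrix &sinA,
                             const NumericMatrix &cosD,
                             const NumericMatrix &sinD) {
  const int n_rows = parent.size();
  const int n_conf = cosA.nrow();
  NumericVector out(static_cast<R_xlen_t>(n_rows) * 3 * n_conf);
  out.attr("dim") = IntegerVector::create(n_rows, 3, n_conf);
  std::vector<double> X(3 * n_rows);  // atom-major scratch: x,y,z per atom
  const double *cA = REAL(cosA), *sA = REAL(sinA);
  const double *cD = REAL(cosD), *sD = REAL(sinD);

  for (int c = 0; c < n_conf; ++c) {
    for (int k = 0; k < n_rows; ++k) {
      double *xk = &X[3 * k];
      R_xlen_t at = static_cast<R_xlen_t>(k) * n_conf + c;
      if (k == 0) {
        xk[0] = xk[1] = xk[2] = 0.0;
      } else if (k == 1) {
        xk[0] = lengths[1]; xk[1] = 0.0; xk[2] = 0.0;
      } else if (k == 2) {
        const double *C = &X[3 * parent[2]];
        const double *B = &X[3 * aref[2]];
        double bc[3];
        double nb = 0;
        for (int q = 0; q < 3; ++q) { bc[q] = C[q] - B[q]; nb += bc[q] * bc[q]; }
        nb = std::sqrt(nb);
        double ct = cA[at], st = sA[at], L = lengths[2];
        xk[0] = C[0] + L * (-bc[0] / nb * ct);
        xk[1] = C[1] + L * (-bc[1] / nb * ct + st);
        xk[2] = C[2] + L * (-bc[2] / nb * ct);
      } else {
        const double *C = &X[3 * parent[k]];
        const double *B = &X[3 * aref[k]];
        const double *A = &X[3 * dref[k]];
        double bc[3], ab[3], n[3], m[3];
        double nb = 0;
        for (int q = 0; q < 3; ++q) {
          bc[q] = C[q] - B[q];
          ab[q] = B[q] - A[q];
          nb += bc[q] * bc[q];
        }
        nb = 1.0 / std::sqrt(nb);
        for (int q = 0; q < 3; ++q) bc[q] *= nb;
        cross3d(ab, bc, n);
        double nn = dot3d(n, n);
        if (nn < 1e-24) stop("degenerate z-matrix reference frame at row %d", k + 1);
        nn = 1.0 / std::sqrt(nn);
        for (int q = 0; q < 3; ++q) n[q] *= nn;
        cross3d(n, bc, m);
        double r = lengths[k];
        double d0 = -r * cA[at];
        double d1 = r * sA[at] * cD[at];
        double d2 = r * sA[at] * sD[at];
        for (int q = 0; q < 3; ++q)
          xk[q] = C[q] + bc[q] * d0 + m[q] * d1 + n[q] * d2;
      }
    }
    double *o = REAL(out) + static_cast<R_xlen_t>(c) * 3 * n_rows;
    for (int k = 0; k < n_rows; ++k) {
      o[k] = X[3 * k];
      o[k + n_rows] = X[3 * k + 1];
      o[k + 2 * n_rows] = X[3 * k + 2];
    }
  }
  return out;
}

static inline const double *slice_ptr(const NumericVector &coords, int n_atoms,
                                      int c) {
  return &coords[static_cast<R_xlen_t>(c) * 3 * n_atoms];
}

static void check_cube(const NumericVector &coords, int *n_atoms, int *n_conf) {
  IntegerVector dim = coords.attr("dim");
  if (dim.size() != 3 || dim[1] != 3) stop("coords must be an atoms x 3 x n array");
  *n_atoms = dim[0];
  *n_conf = dim[2];
}

// Dihedral angles (degrees) for atom quadruples across all conformers.
// quads is n_quads x 4, 0-based atom indices; returns n_conf x n_quads.
// [[Rcpp::export]]
NumericMatrix measure_dihedrals_cpp(const NumericVector &coords,
                                    const IntegerMatrix &quads) {
  int n_atoms, n_conf;
  check_cube(coords, &n_atoms, &n_conf);
  const int n_q = quads.nrow();
  NumericMatrix out(n_conf, n_q);
  for (int c = 0; c < n_conf; ++c) {
    const double *s = slice_ptr(coords, n_atoms, c);
    for (int q = 0; q < n_q; ++q) {
      double p[4][3];
      for (int v = 0; v < 4; ++v) {
        int a = quads(q, v);
        p[v][0] = s[a]; p[v][1] = s[a + n_atoms]; p[v][2] = s[a + 2 * n_atoms];
      }
      out(c, q) = dihedral4(p[0], p[1], p[2], p[3]);
    }
  }
  return out;
}

// Ensemble-averaged r^-6 sums between spin groups.
//
// atom_idx: 0-based coordinate rows of every proton belonging to a spin
// group; grp_idx: 0-based group id per proton.  Returns the matrix
// A[g,h] = < sum_{a in g, b in h, a != b} r_ab^-6 >_ensemble (Angstrom^-6);
// the diagonal holds intra-group ordered pair sums.  min_r reports the
// smallest proton-proton distance seen so callers can reject coincident
// spins.
// [[Rcpp::export]]
List r6_pairs_cpp(const NumericVector &coords, const IntegerVector &atom_idx,
                  const IntegerVector &grp_idx, const int n_grp,
                  const bool precise = true, const double r_floor = 0.0) {
  int n_atoms, n_conf;
  check_cube(coords, &n_atoms, &n_conf);
  const int n_at = atom_idx.size();
  const int n_pair = n_at * (n_at - 1) / 2;
  // flatten the pair loop: index arrays and one accumulator slot per pair
  std::vector<int> ii(n_pair), jj(n_pair), slot(n_pair);
  {
    int p = 0;
    for (int i = 0; i < n_at; ++i)
      for (int j = i + 1; j < n_at; ++j, ++p) {
        ii[p] = i; jj[p] = j;  // proton-order indices into the gather
        slot[p] = grp_idx[i] * n_grp + grp_idx[j];
      }
  }
  std::vector<double> acc(n_grp * n_grp, 0.0);
  const double floor2 = r_floor * r_floor;
  double min_r2 = std::numeric_limits<double>::infinity();
  int min_p = -1;
  if (precise) {
    std::vector<double> px(n_at), py(n_at), pz(n_at);
    for (int c = 0; c < n_conf; ++c) {
      const double *sx = slice_ptr(coords, n_atoms, c);
      const double *sy = sx + n_atoms;
      const double *sz = sy + n_atoms;
      for (int i = 0; i < n_at; ++i) {
        px[i] = sx[atom_idx[i]]; py[i] = sy[atom_idx[i]];
        pz[i] = sz[atom_idx[i]];
      }
      for (int p = 0; p < n_pair; ++p) {
        double dx = px[ii[p]] - px[jj[p]];
        double dy = py[ii[p]] - py[jj[p]];
        double dz = pz[ii[p]] - pz[jj[p]];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < min_r2) { min_r2 = r2; min_p = p; }
        if (r2 < floor2) r2 = floor2;  // van-der-Waals contact floor
        double ir = 1.0 / r2;
        acc[slot[p]] += ir * ir * ir;
      }
    }
  } else {
    // Monte-Carlo hot path: pair distances in single precision (their
    // error is orders of magnitude below the ensemble sampling noise);
    // accumulation stays in double
    std::vector<float> fx(n_at), fy(n_at), fz(n_at);
    for (int c = 0; c < n_conf; ++c) {
      const double *sx = slice_ptr(coords, n_atoms, c);
      const double *sy = sx + n_atoms;
      const double *sz = sy + n_atoms;
      for (int i = 0; i < n_at; ++i) {
        fx[i] = static_cast<float>(sx[atom_idx[i]]);
        fy[i] = static_cast<float>(sy[atom_idx[i]]);
        fz[i] = static_cast<float>(sz[atom_idx[i]]);
      }
      const float floor2f = static_cast<float>(floor2);
      for (int p = 0; p < n_pair; ++p) {
        float dx = fx[ii[p]] - fx[jj[p]];
        float dy = fy[ii[p]] - fy[jj[p]];
        float dz = fz[ii[p]] - fz[jj[p]];
        float r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < min_r2) { min_r2 = r2; min_p = p; }
        if (r2 < floor2f) r2 = floor2f;  // van-der-Waals contact floor
        float ir = 1.0f / r2;
        acc[slot[p]] += static_cast<double>(ir) * ir * ir;
      }
    }
  }
  NumericMatrix A(n_grp, n_grp);
  for (int g = 0; g < n_grp; ++g)
    for (int h = 0; h < n_grp; ++h) {
      double v = (acc[g * n_grp + h] + acc[h * n_grp + g]) / n_conf;
      if (g == h) v = 2.0 * acc[g * n_grp + g] / n_conf;
      A(g, h) = v;
    }
  int min_a = 0, min_b = 0;
  if (min_p >= 0) {
    // recover proton indices of the closest pair
    int p = 0;
    bool found = false;
    for (int i = 0; i < n_at && !found; ++i)
      for (int j = i + 1; j < n_at; ++j, ++p)
        if (p == min_p) { min_a = i; min_b = j; found = true; break; }
  }
  return List::create(_["A"] = A, _["min_r"] = std::sqrt(min_r2),
                      _["min_pair"] = IntegerVector::create(min_a, min_b));
}

// Per-conformer steric alignment tensor from the molecular van-der-Waals
// surface, projected on C-H bond vectors.
//
// Each heavy atom's vdW sphere surface contributes its exact second moment
// (centre outer product plus r^2/3 on the diagonal), weighted by surface
// area (r^2) -- the closed-form limit of uniform surface-point sampling,
// exactly rotation-covariant.  The gyration tensor is made traceless and
// divided by its isotropic moment (scale-invariant anisotropy); the RDC
// projection for a bond is b_hat' S b_hat.  Returns n_conf x n_pairs.
// [[Rcpp::export]]
NumericMatrix rdc_project_cpp(const NumericVector &coords,
                              const IntegerVector &heavy_idx,
                              const NumericVector &radii,
                              const IntegerMatrix &ch_pairs) {
  int n_atoms, n_conf;
  check_cube(coords, &n_atoms, &n_conf);
  const int n_h = heavy_idx.size();
  const int n_p = ch_pairs.nrow();
  NumericMatrix out(n_conf, n_p);
  for (int c = 0; c < n_conf; ++c) {
    const double *s = slice_ptr(coords, n_atoms, c);
    double W = 0, mu[3] = {0, 0, 0};
    double M[6] = {0, 0, 0, 0, 0, 0};  // xx, yy, zz, xy, xz, yz
    for (int i = 0; i < n_h; ++i) {
      int a = heavy_idx[i];
      double x = s[a], y = s[a + n_atoms], z = s[a + 2 * n_atoms];
      double r = radii[i], w = r * r, iso = w * r * r / 3.0;
      mu[0] += w * x; mu[1] += w * y; mu[2] += w * z;
      M[0] += w * x * x + iso;
      M[1] += w * y * y + iso;
      M[2] += w * z * z + iso;
      M[3] += w * x * y; M[4] += w * x * z; M[5] += w * y * z;
      W += w;
    }
    for (int q = 0; q < 3; ++q) mu[q] /= W;
    double G[6];
    G[0] = M[0] / W - mu[0] * mu[0];
    G[1] = M[1] / W - mu[1] * mu[1];
    G[2] = M[2] / W - mu[2] * mu[2];
    G[3] = M[3] / W - mu[0] * mu[1];
    G[4] = M[4] / W - mu[0] * mu[2];
    G[5] = M[5] / W - mu[1] * mu[2];
    double tr = G[0] + G[1] + G[2];
    G[0] -= tr / 3.0; G[1] -= tr / 3.0; G[2] -= tr / 3.0;
    // scale-invariant: deviatoric part over the isotropic moment, so more
    // anisotropic conformers align (and contribute) more strongly
    if (tr > 1e-14) for (int q = 0; q < 6; ++q) G[q] /= tr;
    for (int p = 0; p < n_p; ++p) {
      int ic = ch_pairs(p, 0), ih = ch_pairs(p, 1);
      double b[3] = {s[ih] - s[ic], s[ih + n_atoms] - s[ic + n_atoms],
                     s[ih + 2 * n_atoms] - s[ic + 2 * n_atoms]};
      double nb = std::sqrt(dot3d(b, b));
      for (int q = 0; q < 3; ++q) b[q] /= nb;
      out(c, p) = b[0] * b[0] * G[0] + b[1] * b[1] * G[1] +
                  b[2] * b[2] * G[2] +
                  2 * (b[0] * b[1] * G[3] + b[0] * b[2] * G[4] +
                       b[1] * b[2] * G[5]);
    }
  }
  return out;
}

// Fused forward-prediction kernel for the Monte-Carlo hot path: builds
// each conformer by natural extension and immediately accumulates the
// spin-pair r^-6 sums, the scalar-coupling dihedrals and the steric-
// alignment RDC projections from the in-cache coordinates, without ever
// materialising the full ensemble coordinate array.
// [[Rcpp::export]]
List forward_cpp(const IntegerVector &parent, const IntegerVector &aref,
                 const IntegerVector &dref, const NumericVector &lengths,
                 const NumericMatrix &cosA, const NumericMatrix &sinA,
                 const NumericMatrix &cosD, const NumericMatrix &sinD,
                 const IntegerVector &atom_idx, const IntegerVector &grp_idx,
                 const int n_grp, const IntegerMatrix &quads,
                 const IntegerVector &heavy_idx, const NumericVector &radii,
                 const IntegerMatrix &ch_pairs, const double r_floor = 0.0) {
  const int n_rows = parent.size();
  const int n_conf = cosA.nrow();
  const int n_at = atom_idx.size();
  const int n_pair = n_at * (n_at - 1) / 2;
  const int n_q = quads.nrow();
  const int n_h = heavy_idx.size();
  const int n_p = ch_pairs.nrow();
  const double *cA = REAL(cosA), *sA = REAL(sinA);
  const double *cD = REAL(cosD), *sD = REAL(sinD);

  std::vector<double> X(3 * n_rows);
  std::vector<int> ii(n_pair), jj(n_pair), slot(n_pair);
  {
    int p = 0;
    for (int i = 0; i < n_at; ++i)
      for (int j = i + 1; j < n_at; ++j, ++p) {
        ii[p] = atom_idx[i]; jj[p] = atom_idx[j];
        slot[p] = grp_idx[i] * n_grp + grp_idx[j];
      }
  }
  std::vector<double> acc(n_grp * n_grp, 0.0);
  const double floor2 = r_floor * r_floor;
  double min_r2 = std::numeric_limits<double>::infinity();
  NumericMatrix dih(n_conf, n_q);
  std::vector<double> rdc_sum(n_p, 0.0);

  for (int c = 0; c < n_conf; ++c) {
    // --- natural-extension build (same placement rule as nerf_build_cpp)
    for (int k = 0; k < n_rows; ++k) {
      double *xk = &X[3 * k];
      R_xlen_t at = static_cast<R_xlen_t>(k) * n_conf + c;
      if (k == 0) {
        xk[0] = xk[1] = xk[2] = 0.0;
      } else if (k == 1) {
        xk[0] = lengths[1]; xk[1] = 0.0; xk[2] = 0.0;
      } else if (k == 2) {
        const double *C = &X[3 * parent[2]];
        const double *B = &X[3 * aref[2]];
        double bc[3];
        double nb = 0;
        for (int q = 0; q < 3; ++q) { bc[q] = C[q] - B[q]; nb += bc[q] * bc[q]; }
        nb = std::sqrt(nb);
        double ct = cA[at], st = sA[at], L = lengths[2];
        xk[0] = C[0] + L * (-bc[0] / nb * ct);
        xk[1] = C[1] + L * (-bc[1] / nb * ct + st);
        xk[2] = C[2] + L * (-bc[2] / nb * ct);
      } else {
        const double *C = &X[3 * parent[k]];
        const double *B = &X[3 * aref[k]];
        const double *A = &X[3 * dref[k]];
        double bc[3], ab[3], n[3], m[3];
        double nb = 0;
        for (int q = 0; q < 3; ++q) {
          bc[q] = C[q] - B[q];
          ab[q] = B[q] - A[q];
          nb += bc[q] * bc[q];
        }
        nb = 1.0 / std::sqrt(nb);
        for (int q = 0; q < 3; ++q) bc[q] *= nb;
        cross3d(ab, bc, n);
        double nn = dot3d(n, n);
        if (nn < 1e-24) stop("degenerate z-matrix reference frame at row %d", k + 1);
        nn = 1.0 / std::sqrt(nn);
        for (int q = 0; q < 3; ++q) n[q] *= nn;
        cross3d(n, bc, m);
        double r = lengths[k];
        double d0 = -r * cA[at];
        double d1 = r * sA[at] * cD[at];
        double d2 = r * sA[at] * sD[at];
        for (int q = 0; q < 3; ++q)
          xk[q] = C[q] + bc[q] * d0 + m[q] * d1 + n[q] * d2;
      }
    }
    // --- spin-pair r^-6 sums (with van-der-Waals contact floor)
    for (int p = 0; p < n_pair; ++p) {
      const double *a = &X[3 * ii[p]];
      const double *b = &X[3 * jj[p]];
      double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < min_r2) min_r2 = r2;
      if (r2 < floor2) r2 = floor2;
      double ir = 1.0 / r2;
      acc[slot[p]] += ir * ir * ir;
    }
    // --- coupling dihedrals
    for (int q = 0; q < n_q; ++q)
      dih(c, q) = dihedral4(&X[3 * quads(q, 0)], &X[3 * quads(q, 1)],
                            &X[3 * quads(q, 2)], &X[3 * quads(q, 3)]);
    // --- steric alignment tensor + C-H projections
    if (n_p > 0) {
      double W = 0, mu[3] = {0, 0, 0};
      double M[6] = {0, 0, 0, 0, 0, 0};
      for (int i = 0; i < n_h; ++i) {
        const double *x0 = &X[3 * heavy_idx[i]];
        double r = radii[i], w = r * r, iso = w * r * r / 3.0;
        mu[0] += w * x0[0]; mu[1] += w * x0[1]; mu[2] += w * x0[2];
        M[0] += w * x0[0] * x0[0] + iso;
        M[1] += w * x0[1] * x0[1] + iso;
        M[2] += w * x0[2] * x0[2] + iso;
        M[3] += w * x0[0] * x0[1];
        M[4] += w * x0[0] * x0[2];
        M[5] += w * x0[1] * x0[2];
        W += w;
      }
      for (int q = 0; q < 3; ++q) mu[q] /= W;
      double G[6];
      G[0] = M[0] / W - mu[0] * mu[0];
      G[1] = M[1] / W - mu[1] * mu[1];
      G[2] = M[2] / W - mu[2] * mu[2];
      G[3] = M[3] / W - mu[0] * mu[1];
      G[4] = M[4] / W - mu[0] * mu[2];
      G[5] = M[5] / W - mu[1] * mu[2];
      double tr = G[0] + G[1] + G[2];
      G[0] -= tr / 3.0; G[1] -= tr / 3.0; G[2] -= tr / 3.0;
      if (tr > 1e-14) for (int q = 0; q < 6; ++q) G[q] /= tr;
      for (int p = 0; p < n_p; ++p) {
        const double *xc = &X[3 * ch_pairs(p, 0)];
        const double *xh = &X[3 * ch_pairs(p, 1)];
        double b[3] = {xh[0] - xc[0], xh[1] - xc[1], xh[2] - xc[2]};
        double nb = std::sqrt(dot3d(b, b));
        for (int q = 0; q < 3; ++q) b[q] /= nb;
        rdc_sum[p] += b[0] * b[0] * G[0] + b[1] * b[1] * G[1] +
                      b[2] * b[2] * G[2] +
                      2 * (b[0] * b[1] * G[3] + b[0] * b[2] * G[4] +
                           b[1] * b[2] * G[5]);
      }
    }
  }
  NumericMatrix A(n_grp, n_grp);
  for (int g = 0; g < n_grp; ++g)
    for (int h = 0; h < n_grp; ++h) {
      double v = (acc[g * n_grp + h] + acc[h * n_grp + g]) / n_conf;
      if (g == h) v = 2.0 * acc[g * n_grp + g] / n_conf;
      A(g, h) = v;
    }
  NumericVector rdc_mean(n_p);
  for (int p = 0; p < n_p; ++p) rdc_mean[p] = rdc_sum[p] / n_conf;
  return List::create(_["A"] = A, _["min_r"] = std::sqrt(min_r2),
                      _["dih"] = dih, _["rdc_mean"] = rdc_mean);
}

// Traceless deviatoric gyration tensor of an arbitrary point cloud
// (used by steric_alignment_tensor on explicit point sets).
// [[Rcpp::export]]
arma::mat gyration_tensor_cpp(const arma::mat &points) {
  arma::rowvec mu = arma::mean(points, 0);
  arma::mat centred = points.each_row() - mu;
  arma::mat G = (centred.t() * centred) / static_cast<double>(points.n_rows);
  double tr = arma::trace(G) / 3.0;
  G(0, 0) -= tr; G(1, 1) -= tr; G(2, 2) -= tr;
  return G;
}

// TRUE per conformer when any non-excluded heavy-atom pair is closer than
// min_dist.  excl is the n_heavy x n_heavy exclusion mask (1-2/1-3 pairs).
// [[Rcpp::export]]
LogicalVector clash_any_cpp(const NumericVector &coords,
                            const IntegerVector &heavy_idx,
                            const LogicalMatrix &excl, const double min_dist) {
  int n_atoms, n_conf;
  check_cube(coords, &n_atoms, &n_conf);
  const int n_h = heavy_idx.size();
  const double d2 = min_dist * min_dist;
  LogicalVector out(n_conf);
  std::vector<double> px(n_h), py(n_h), pz(n_h);
  for (int c = 0; c < n_conf; ++c) {
    const double *s = slice_ptr(coords, n_atoms, c);
    for (int i = 0; i < n_h; ++i) {
      int a = heavy_idx[i];
      px[i] = s[a]; py[i] = s[a + n_atoms]; pz[i] = s[a + 2 * n_atoms];
    }
    bool hit = false;
    for (int i = 0; i < n_h && !hit; ++i) {
      for (int j = i + 1; j < n_h; ++j) {
        if (excl(i, j)) continue;
        double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        if (dx * dx + dy * dy + dz * dz < d2) { hit = true; break; }
      }
    }
    out[c] = hit;
  }
  return out;
}
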