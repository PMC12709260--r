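// Numerical core: backbone geometry, dihedral-space Monte Carlo sampling,
// Debye scattering sums, Shrake-Rupley surface areas, Kabsch RMSD.
// All O(n^2)-per-frame loops live here; R wrappers own validation and units.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// ideal backbone geometry (Angstrom / degrees), Engh-Huber-like values
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double B_C_O = 1.231, B_N_H = 1.010, B_CA_CB = 1.530;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.5, A_C_N_H = 119.0, A_N_CA_CB = 110.5;
static const double D_CB = -122.6; // C-N-CA-CB improper, L-chirality

// Place atom D given A-B-C, bond |CD|, angle B-C-D, dihedral A-B-C-D.
static arma::rowvec nerf(const arma::rowvec& A, const arma::rowvec& B,
                         const arma::rowvec& C, double bond, double angle_deg,
                         double dihedral_deg) {
  double theta = angle_deg * DEG, chi = dihedral_deg * DEG;
  arma::rowvec bc = arma::normalise(C - B);
  arma::rowvec ab = B - A;
  arma::rowvec n = arma::normalise(arma::cross(ab, bc));
  arma::rowvec m = arma::cross(n, bc);
  arma::rowvec d2(3);
  d2(0) = -bond * std::cos(theta);
  d2(1) = bond * std::sin(theta) * std::cos(chi);
  d2(2) = bond * std::sin(theta) * std::sin(chi);
  return C + d2(0) * bc + d2(1) * m + d2(2) * n;
}

struct BackboneFrame {
  arma::mat N, H, CA, CB, C, O; // each L x 3; H/CB rows may be unused
};

// Build backbone + amide H + carbonyl O + CB from (phi, psi) in degrees.
// phi[0] and psi[L-1] only orient terminal H/O placement.
static BackboneFrame build_backbone(const arma::vec& phi, const arma::vec& psi,
                                    const LogicalVector& has_h,
                                    const LogicalVector& has_cb) {
  int L = phi.n_elem;
  BackboneFrame f;
  f.N.set_size(L, 3); f.H.set_size(L, 3); f.CA.set_size(L, 3);
  f.CB.set_size(L, 3); f.C.set_size(L, 3); f.O.set_size(L, 3);
  f.H.fill(arma::datum::nan); f.CB.fill(arma::datum::nan);

  // residue 1 in a canonical frame
  f.N.row(0) = arma::rowvec({0.0, 0.0, 0.0});
  f.CA.row(0) = arma::rowvec({B_N_CA, 0.0, 0.0});
  double th = A_N_CA_C * DEG;
  f.C.row(0) = f.CA.row(0) +
    arma::rowvec({-B_CA_C * std::cos(th), B_CA_C * std::sin(th), 0.0});

  for (int i = 1; i < L; ++i) {
    f.N.row(i) = nerf(f.N.row(i - 1), f.CA.row(i - 1), f.C.row(i - 1),
                      B_C_N, A_CA_C_N, psi(i - 1));
    f.CA.row(i) = nerf(f.CA.row(i - 1), f.C.row(i - 1), f.N.row(i),
                       B_N_CA, A_C_N_CA, 180.0); // omega fixed trans
    f.C.row(i) = nerf(f.C.row(i - 1), f.N.row(i), f.CA.row(i),
                      B_CA_C, A_N_CA_C, phi(i));
  }
  for (int i = 0; i < L; ++i) {
    // carbonyl O anti to the next amide N (psi + 180 about CA-C)
    f.O.row(i) = nerf(f.N.row(i), f.CA.row(i), f.C.row(i),
                      B_C_O, A_CA_C_O, psi(i) + 180.0);
    if (has_cb[i])
      f.CB.row(i) = nerf(f.C.row(i), f.N.row(i), f.CA.row(i),
                         B_CA_CB, A_N_CA_CB, D_CB);
    if (has_h[i]) {
      if (i == 0)
        f.H.row(i) = nerf(f.C.row(i), f.CA.row(i), f.N.row(i),
                          B_N_H, A_C_N_CA, 180.0);
      else // in the peptide plane, trans to the i-1 carbonyl O
        f.H.row(i) = nerf(f.O.row(i - 1), f.C.row(i - 1), f.N.row(i),
                          B_N_H, A_C_N_H, 180.0);
    }
  }
  return f;
}

// Pack per-atom-type rows into one matrix in per-residue order
// N, [H], CA, [CB], C, O — the package's fixed topology order.
static arma::mat pack_frame(const BackboneFrame& f, const LogicalVector& has_h,
                            const LogicalVector& has_cb) {
  int L = f.N.n_rows, n = 0;
  for (int i = 0; i < L; ++i) n += 4 + (has_h[i] ? 1 : 0) + (has_cb[i] ? 1 : 0);
  arma::mat X(n, 3);
  int k = 0;
  for (int i = 0; i < L; ++i) {
    X.row(k++) = f.N.row(i);
    if (has_h[i]) X.row(k++) = f.H.row(i);
    X.row(k++) = f.CA.row(i);
    if (has_cb[i]) X.row(k++) = f.CB.row(i);
    X.row(k++) = f.C.row(i);
    X.row(k++) = f.O.row(i);
  }
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_build_chain(const arma::vec& phi, const arma::vec& psi,
                          const LogicalVector& has_h,
                          const LogicalVector& has_cb) {
  return pack_frame(build_backbone(phi, psi, has_h, has_cb), has_h, has_cb);
}

static double mass_weighted_rg(const arma::mat& X, const arma::vec& m) {
  arma::rowvec com = (m.t() * X) / arma::accu(m);
  arma::mat D = X.each_row() - com;
  return std::sqrt(arma::accu(m % arma::sum(arma::square(D), 1)) /
                   arma::accu(m));
}

// [[Rcpp::export]]
double cpp_rg(const arma::mat& X, const arma::vec& m) {
  return mass_weighted_rg(X, m);
}

// Any heavy-atom pair from residues >= min_sep apart closer than cutoff?
// heavy_res: residue index (0-based) per heavy-atom row of Xh.
static bool has_clash(const arma::mat& Xh, const arma::ivec& heavy_res,
                      double cutoff, int min_sep) {
  int n = Xh.n_rows;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(heavy_res(j) - heavy_res(i)) < min_sep) continue;
      double dx = Xh(i, 0) - Xh(j, 0), dy = Xh(i, 1) - Xh(j, 1),
             dz = Xh(i, 2) - Xh(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) return true;
    }
  return false;
}

// Single-replica Markov chain over (phi, psi): single-residue redraws from a
// Gaussian basin mixture, hard-sphere clash rejection, optional Metropolis
// bias U = spring * (Rg - target)^2 in kBT. Uses R's RNG (seed from R side).
// Frames are recorded every `stride` accepted moves -> autocorrelated chain.
// [[Rcpp::export]]
List cpp_sample_replica(int n_frames, int stride, const arma::vec& w,
                        const arma::mat& centers_phi_psi, double sigma,
                        double rg_target, double rg_spring, bool use_rg_bias,
                        double clash_cutoff, const LogicalVector& has_h,
                        const LogicalVector& has_cb, const arma::vec& masses,
                        const arma::ivec& heavy_idx, const arma::ivec& heavy_res,
                        int max_attempts) {
  int L = has_h.size();
  int nb = w.n_elem;
  arma::vec cw = arma::cumsum(w);
  arma::vec phi(L), psi(L);

  auto draw_basin = [&]() {
    double u = R::runif(0.0, 1.0);
    for (int k = 0; k < nb; ++k) if (u <= cw(k)) return k;
    return nb - 1;
  };
  auto wrap = [](double a) {
    while (a > 180.0) a -= 360.0;
    while (a <= -180.0) a += 360.0;
    return a;
  };

  arma::uvec hidx(heavy_idx.n_elem);
  for (arma::uword i = 0; i < heavy_idx.n_elem; ++i) hidx(i) = heavy_idx(i);

  // initial clash-free state: mixture draws, falling back to an extended
  // chain (always clash-free) that burn-in then relaxes into the basins
  arma::mat X;
  double rg = 0.0;
  bool ok = false;
  int init_budget = std::max(100, max_attempts / 100);
  for (int attempt = 0; attempt < init_budget && !ok; ++attempt) {
    for (int i = 0; i < L; ++i) {
      int k = draw_basin();
      phi(i) = wrap(R::rnorm(centers_phi_psi(k, 0), sigma));
      psi(i) = wrap(R::rnorm(centers_phi_psi(k, 1), sigma));
    }
    X = pack_frame(build_backbone(phi, psi, has_h, has_cb), has_h, has_cb);
    ok = !has_clash(X.rows(hidx), heavy_res, clash_cutoff, 2);
  }
  if (!ok) {
    phi.fill(-120.0); psi.fill(130.0);
    X = pack_frame(build_backbone(phi, psi, has_h, has_cb), has_h, has_cb);
    if (has_clash(X.rows(hidx), heavy_res, clash_cutoff, 2))
      stop("no clash-free initial conformation found within attempt budget");
  }
  rg = mass_weighted_rg(X, masses);

  int natoms = X.n_rows;
  arma::cube coords(natoms, 3, n_frames);
  arma::mat phis(L, n_frames), psis(L, n_frames);
  arma::vec rgs(n_frames);

  long proposed = 0, accepted = 0;
  int recorded = 0, acc_since = 0;
  long stale = 0;
  while (recorded < n_frames) {
    if (stale > (long)max_attempts)
      stop("zero acceptance over the attempt budget; relax clash_cutoff or rg_spring");
    ++proposed; ++stale;
    int r = (int)std::floor(R::runif(0.0, 1.0) * L);
    if (r >= L) r = L - 1;
    int k = draw_basin();
    double old_phi = phi(r), old_psi = psi(r);
    phi(r) = wrap(R::rnorm(centers_phi_psi(k, 0), sigma));
    psi(r) = wrap(R::rnorm(centers_phi_psi(k, 1), sigma));
    arma::mat Xp = pack_frame(build_backbone(phi, psi, has_h, has_cb),
                              has_h, has_cb);
    bool reject = has_clash(Xp.rows(hidx), heavy_res, clash_cutoff, 2);
    double rg_new = reject ? rg : mass_weighted_rg(Xp, masses);
    if (!reject && use_rg_bias) {
      double dU = rg_spring * std::pow(rg_new - rg_target, 2) -
                  rg_spring * std::pow(rg - rg_target, 2);
      if (dU > 0.0 && R::runif(0.0, 1.0) > std::exp(-dU)) reject = true;
    }
    if (reject) {
      phi(r) = old_phi; psi(r) = old_psi;
      continue;
    }
    X = Xp; rg = rg_new;
    ++accepted; ++acc_since; stale = 0;
    if (acc_since == stride) {
      coords.slice(recorded) = X;
      phis.col(recorded) = phi;
      psis.col(recorded) = psi;
      rgs(recorded) = rg;
      ++recorded;
      acc_since = 0;
    }
  }
  return List::create(_["coords"] = coords, _["phi"] = phis, _["psi"] = psis,
                      _["rg"] = rgs,
                      _["acceptance"] = (double)accepted / (double)proposed);
}

// Debye sum: I(q) = sum_ij f_i(q) f_j(q) sinc(q r_ij); feff is natoms x nq.
// [[Rcpp::export]]
arma::vec cpp_debye(const arma::mat& X, const arma::mat& feff,
                    const arma::vec& q) {
  int n = X.n_rows, nq = q.n_elem;
  arma::vec I(nq, arma::fill::zeros);
  for (int k = 0; k < nq; ++k) I(k) = arma::accu(arma::square(feff.col(k)));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        double qr = q(k) * r;
        double s = (qr < 1e-12) ? 1.0 : std::sin(qr) / qr;
        I(k) += 2.0 * feff(i, k) * feff(j, k) * s;
      }
    }
  return I;
}

// [[Rcpp::export]]
arma::mat cpp_debye_ensemble(const arma::cube& coords, const arma::mat& feff,
                             const arma::vec& q) {
  int nf = coords.n_slices;
  arma::mat out(q.n_elem, nf);
  for (int f = 0; f < nf; ++f) out.col(f) = cpp_debye(coords.slice(f), feff, q);
  return out;
}

// Weighted histogram of all pairwise distances; breaks strictly increasing.
// [[Rcpp::export]]
arma::vec cpp_pair_hist(const arma::mat& X, const arma::vec& wt,
                        const arma::vec& breaks) {
  int n = X.n_rows, nb = breaks.n_elem - 1;
  arma::vec h(nb, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < breaks(0) || r >= breaks(nb)) continue;
      int lo = 0, hi = nb; // last break index <= r
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (breaks(mid) <= r) lo = mid; else hi = mid;
      }
      h(lo) += wt(i) * wt(j);
    }
  return h;
}

// Shrake-Rupley: golden-spiral sphere points; per-atom accessible area.
// [[Rcpp::export]]
arma::vec cpp_shrake_rupley(const arma::mat& X, const arma::vec& radii,
                            double probe, int n_points) {
  int n = X.n_rows;
  arma::mat sph(n_points, 3);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    double z = 1.0 - 2.0 * (p + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * p;
    sph(p, 0) = r * std::cos(th);
    sph(p, 1) = r * std::sin(th);
    sph(p, 2) = z;
  }
  arma::vec er = radii + probe;
  arma::vec area(n, arma::fill::zeros);
  double maxr = er.max();
  for (int i = 0; i < n; ++i) {
    // neighbours that can occlude atom i's expanded sphere
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X(j, 0) - X(i, 0), dy = X(j, 1) - X(i, 1),
             dz = X(j, 2) - X(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = er(i) + er(j);
      if (d2 < lim * lim) nb.push_back(j);
    }
    (void)maxr;
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = X(i, 0) + er(i) * sph(p, 0);
      double py = X(i, 1) + er(i) * sph(p, 1);
      double pz = X(i, 2) + er(i) * sph(p, 2);
      bool free_pt = true;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double dx = px - X(j, 0), dy = py - X(j, 1), dz = pz - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < er(j) * er(j)) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area(i) = 4.0 * M_PI * er(i) * er(i) * acc / n_points;
  }
  return area;
}

static double kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  arma::mat Ac = A.each_row() - arma::mean(A, 0);
  arma::mat Bc = B.each_row() - arma::mean(B, 0);
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  double e = arma::accu(arma::square(Ac)) + arma::accu(arma::square(Bc));
  double msd = (e - 2.0 * (s(0) + s(1) + d * s(2))) / A.n_rows;
  return std::sqrt(std::max(0.0, msd));
}

// [[Rcpp::export]]
arma::vec cpp_rmsd_to_ref(const arma::cube& coords, const arma::mat& ref,
                          const arma::uvec& sel) {
  int nf = coords.n_slices;
  arma::vec out(nf);
  arma::mat R = ref.rows(sel);
  for (int f = 0; f < nf; ++f) out(f) = kabsch_rmsd(coords.slice(f).rows(sel), R);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_rmsd_matrix(const arma::cube& coords, const arma::uvec& sel) {
  int nf = coords.n_slices;
  arma::mat M(nf, nf, arma::fill::zeros);
  std::vector<arma::mat> frames(nf);
  for (int f = 0; f < nf; ++f) frames[f] = coords.slice(f).rows(sel);
  for (int i = 0; i < nf; ++i)
    for (int j = i + 1; j < nf; ++j)
      M(i, j) = M(j, i) = kabsch_rmsd(frames[i], frames[j]);
  return M;
}

// Per-pair minimum over frames of CA-CA distances; ca cube is nres x 3 x nf.
// [[Rcpp::export]]
arma::mat cpp_min_dist_map(const arma::cube& ca) {
  int L = ca.n_rows, nf = ca.n_slices;
  arma::mat M(L, L);
  M.fill(arma::datum::inf);
  for (int f = 0; f < nf; ++f) {
    const arma::mat& X = ca.slice(f);
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j) {
        double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
               dz = X(i, 2) - X(j, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < M(i, j)) { M(i, j) = d; M(j, i) = d; }
      }
  }
  M.diag().zeros();
  return M;
}

// Backbone dihedrals for every frame: phi(i) = C(i-1)-N(i)-CA(i)-C(i),
// psi(i) = N(i)-CA(i)-C(i)-N(i+1). Indices are 0-based rows of each frame.
// [[Rcpp::export]]
List cpp_dihedrals(const arma::cube& coords, const arma::uvec& n_idx,
                   const arma::uvec& ca_idx, const arma::uvec& c_idx) {
  int L = n_idx.n_elem, nf = coords.n_slices;
  arma::mat phi(L, nf), psi(L, nf);
  phi.fill(arma::datum::nan); psi.fill(arma::datum::nan);
  auto dihe = [](const arma::rowvec& a, const arma::rowvec& b,
                 const arma::rowvec& c, const arma::rowvec& d) {
    arma::rowvec b1 = b - a, b2 = c - b, b3 = d - c;
    arma::rowvec n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
    arma::rowvec m = arma::cross(n1, arma::normalise(b2));
    return -std::atan2(arma::dot(m, n2), arma::dot(n1, n2)) / DEG;
  };
  for (int f = 0; f < nf; ++f) {
    const arma::mat& X = coords.slice(f);
    for (int i = 0; i < L; ++i) {
      if (i > 0)
        phi(i, f) = dihe(X.row(c_idx(i - 1)), X.row(n_idx(i)),
                         X.row(ca_idx(i)), X.row(c_idx(i)));
      if (i < L - 1)
        psi(i, f) = dihe(X.row(n_idx(i)), X.row(ca_idx(i)),
                         X.row(c_idx(i)), X.row(n_idx(i + 1)));
    }
  }
  return List::create(_["phi"] = phi, _["psi"] = psi);
}

// Ensemble Debye sum via type-pair distance histograms: atoms sharing one
// effective form factor are a "type"; pair distances accumulate into bins
// of width dr per type pair, and the Debye transform runs once per group.
// Exact up to the binning error O((q dr)^2 / 24).
// [[Rcpp::export]]
arma::mat cpp_debye_hist_groups(const arma::cube& coords,
                                const arma::ivec& type_id, int n_types,
                                const arma::mat& f_types, const arma::vec& q,
                                const List& group_frames, double dr) {
  int natoms = coords.n_rows, nq = q.n_elem, ng = group_frames.size();
  int npairs_t = n_types * (n_types + 1) / 2;
  auto tp = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return a * n_types - a * (a - 1) / 2 + (b - a);
  };
  // self term, identical for every frame
  arma::vec selfI(nq, arma::fill::zeros);
  for (int i = 0; i < natoms; ++i)
    for (int k = 0; k < nq; ++k)
      selfI(k) += f_types(type_id(i), k) * f_types(type_id(i), k);

  arma::mat out(nq, ng);
  for (int g = 0; g < ng; ++g) {
    IntegerVector fr = group_frames[g]; // 1-based frame numbers
    // first pass: max distance for bin count
    double dmax = 0;
    std::vector<arma::mat> frames(fr.size());
    for (int t = 0; t < fr.size(); ++t)
      frames[t] = coords.slice(fr[t] - 1);
    for (size_t t = 0; t < frames.size(); ++t) {
      const arma::mat& X = frames[t];
      for (int i = 0; i < natoms; ++i)
        for (int j = i + 1; j < natoms; ++j) {
          double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
                 dz = X(i, 2) - X(j, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > dmax) dmax = d2;
        }
    }
    int nb = (int)std::floor(std::sqrt(dmax) / dr) + 1;
    arma::mat H(nb, npairs_t, arma::fill::zeros);
    for (size_t t = 0; t < frames.size(); ++t) {
      const arma::mat& X = frames[t];
      for (int i = 0; i < natoms; ++i) {
        double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
        int ti = type_id(i);
        for (int j = i + 1; j < natoms; ++j) {
          double dx = xi - X(j, 0), dy = yi - X(j, 1), dz = zi - X(j, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          int b = (int)(r / dr);
          H(b, tp(ti, type_id(j))) += 1.0;
        }
      }
    }
    arma::vec I(nq, arma::fill::zeros);
    for (int pi = 0, a = 0; a < n_types; ++a)
      for (int b2 = a; b2 < n_types; ++b2, ++pi) {
        for (int bin = 0; bin < nb; ++bin) {
          double w = H(bin, pi);
          if (w == 0.0) continue;
          double r = (bin + 0.5) * dr;
          for (int k = 0; k < nq; ++k) {
            double qr = q(k) * r;
            double s = (qr < 1e-12) ? 1.0 : std::sin(qr) / qr;
            I(k) += 2.0 * w * f_types(a, k) * f_types(b2, k) * s;
          }
        }
      }
    out.col(g) = (I / fr.size()) + selfI;
  }
  return out;
}

// Shrake-Rupley with contiguous neighbour buffers and early exit.
// [[Rcpp::export]]
arma::vec cpp_shrake_rupley_fast(const arma::mat& X, const arma::vec& radii,
                                 double probe, int n_points) {
  int n = X.n_rows;
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    double z = 1.0 - 2.0 * (p + 0.5) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * p;
    px[p] = rr * std::cos(th);
    py[p] = rr * std::sin(th);
    pz[p] = z;
  }
  arma::vec er = radii + probe;
  arma::vec area(n, arma::fill::zeros);
  std::vector<double> nx, ny, nz, nr2;
  for (int i = 0; i < n; ++i) {
    double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), ri = er(i);
    nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + er(j);
      if (d2 < lim * lim) {
        nx.push_back(dx); ny.push_back(dy); nz.push_back(dz);
        nr2.push_back(er(j) * er(j));
      }
    }
    // closest neighbours first: they occlude most points, so the early
    // exit fires sooner
    int m = nx.size();
    std::vector<int> ord(m);
    for (int t = 0; t < m; ++t) ord[t] = t;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double da = nx[a] * nx[a] + ny[a] * ny[a] + nz[a] * nz[a];
      double db = nx[b] * nx[b] + ny[b] * ny[b] + nz[b] * nz[b];
      return da < db;
    });
    std::vector<double> ox(m), oy(m), oz(m), or2(m);
    for (int t = 0; t < m; ++t) {
      ox[t] = nx[ord[t]]; oy[t] = ny[ord[t]]; oz[t] = nz[ord[t]];
      or2[t] = nr2[ord[t]];
    }
    nx = ox; ny = oy; nz = oz; nr2 = or2;
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double sx = ri * px[p], sy = ri * py[p], sz = ri * pz[p];
      bool free_pt = true;
      for (int t = 0; t < m; ++t) {
        double dx = sx - nx[t], dy = sy - ny[t], dz = sz - nz[t];
        if (dx * dx + dy * dy + dz * dz < nr2[t]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area(i) = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
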