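// Dynamics core: toy-chain / 2D-potential energies with analytic gradients,
// restraint energies and exact forces (Cartesian-harmonic, RMSD with a
// moving reference, centre, orientation angle), and a BAOAB Langevin
// integrator.  Units: Angstrom, kcal/mol, ps, amu; KCAL converts
// kcal/mol/amu to Angstrom^2/ps^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KCAL = 418.4;          // (Angstrom/ps)^2 * amu per kcal/mol
static const double RAD2DEG = 57.29577951308232;

// ---------------------------------------------------------------------------
// model terms

struct ChainModel {
  arma::mat bonds;      // i j r0 k          (0-based after parse)
  arma::mat angles;     // i j k theta0 ka   (theta0 rad)
  arma::mat torsions;   // i j k l n kt phi0 (phi0 rad)
  arma::mat contacts;   // i j depth r0 width
  arma::mat tethers;    // i j k dx dy dz    (j = -1: static anchor at d)
  arma::mat rep_pairs;  // i j
  double rep_eps = 0.0, rep_rc = 0.0;
  bool has_pot2d = false;
  arma::vec p2_amps;
  arma::mat p2_centers; // M x 2
  arma::mat p2_precs;   // M x 4 (rows a11 a12 a21 a22)
  double p2_kconf = 0.0, p2_kz = 0.0;
  arma::vec p2_conf_center;
  double contact_scale = 1.0;
};

static arma::mat get_mat(const List& m, const char* nm) {
  if (!m.containsElementNamed(nm)) return arma::mat(0, 0);
  SEXP s = m[nm];
  if (Rf_isNull(s)) return arma::mat(0, 0);
  NumericMatrix x(s);
  arma::mat out(x.begin(), x.nrow(), x.ncol());
  return out;
}

static ChainModel parse_model(const List& model) {
  ChainModel cm;
  cm.bonds = get_mat(model, "bonds");
  cm.angles = get_mat(model, "angles");
  cm.torsions = get_mat(model, "torsions");
  cm.contacts = get_mat(model, "contacts");
  cm.tethers = get_mat(model, "tethers");
  cm.rep_pairs = get_mat(model, "rep_pairs");
  if (model.containsElementNamed("rep_eps"))
    cm.rep_eps = as<double>(model["rep_eps"]);
  if (model.containsElementNamed("rep_rc"))
    cm.rep_rc = as<double>(model["rep_rc"]);
  if (model.containsElementNamed("contact_scale"))
    cm.contact_scale = as<double>(model["contact_scale"]);
  if (model.containsElementNamed("p2_amps") &&
      !Rf_isNull(SEXP(model["p2_amps"]))) {
    cm.has_pot2d = true;
    cm.p2_amps = as<arma::vec>(model["p2_amps"]);
    cm.p2_centers = get_mat(model, "p2_centers");
    cm.p2_precs = get_mat(model, "p2_precs");
    cm.p2_kconf = as<double>(model["p2_kconf"]);
    cm.p2_kz = as<double>(model["p2_kz"]);
    cm.p2_conf_center = as<arma::vec>(model["p2_conf_center"]);
  }
  return cm;
}

// dihedral angle (radians), IUPAC convention, plus gradient wrt the 4 atoms
static double dihedral_grad(const arma::rowvec3& r1, const arma::rowvec3& r2,
                            const arma::rowvec3& r3, const arma::rowvec3& r4,
                            arma::rowvec3& g1, arma::rowvec3& g2,
                            arma::rowvec3& g3, arma::rowvec3& g4) {
  arma::rowvec3 b1 = r2 - r1, b2 = r3 - r2, b3 = r4 - r3;
  arma::rowvec3 n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
  double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
  double b2n = std::sqrt(arma::dot(b2, b2));
  // IUPAC sign (cis = 0, trans = 180), matching the R-level dihedral():
  // phi = atan2((n1 x n2).b2hat, n1.n2)
  double phi = std::atan2(arma::dot(arma::cross(n1, n2), b2 / b2n),
                          arma::dot(n1, n2));
  g1 = -(b2n / n1sq) * n1;
  g4 = (b2n / n2sq) * n2;
  double f12 = arma::dot(b1, b2) / (b2n * b2n);
  double f32 = arma::dot(b3, b2) / (b2n * b2n);
  g2 = -g1 - f12 * g1 + f32 * g4;
  g3 = -g4 + f12 * g1 - f32 * g4;
  return phi;
}

// model energy and gradient (gradient ADDED into grad)
static double chain_energy(const ChainModel& cm, const arma::mat& x,
                           arma::mat& grad) {
  double U = 0.0;
  // bonds: 1/2 k (r - r0)^2
  for (arma::uword b = 0; b < cm.bonds.n_rows; ++b) {
    int i = (int)cm.bonds(b, 0), j = (int)cm.bonds(b, 1);
    double r0 = cm.bonds(b, 2), k = cm.bonds(b, 3);
    arma::rowvec3 d = x.row(i) - x.row(j);
    double r = arma::norm(d);
    U += 0.5 * k * (r - r0) * (r - r0);
    arma::rowvec3 g = k * (r - r0) * d / std::max(r, 1e-12);
    grad.row(i) += g;
    grad.row(j) -= g;
  }
  // angles: 1/2 ka (theta - theta0)^2
  for (arma::uword a = 0; a < cm.angles.n_rows; ++a) {
    int i = (int)cm.angles(a, 0), j = (int)cm.angles(a, 1),
        k = (int)cm.angles(a, 2);
    double th0 = cm.angles(a, 3), ka = cm.angles(a, 4);
    arma::rowvec3 rij = x.row(i) - x.row(j);
    arma::rowvec3 rkj = x.row(k) - x.row(j);
    double nij = arma::norm(rij), nkj = arma::norm(rkj);
    double cth = arma::dot(rij, rkj) / (nij * nkj);
    cth = std::min(1.0 - 1e-12, std::max(-1.0 + 1e-12, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(1.0 - cth * cth);
    U += 0.5 * ka * (th - th0) * (th - th0);
    double pref = -ka * (th - th0) / sth;  // dU/dcos
    arma::rowvec3 gi = pref * (rkj / (nij * nkj) - cth * rij / (nij * nij));
    arma::rowvec3 gk = pref * (rij / (nij * nkj) - cth * rkj / (nkj * nkj));
    grad.row(i) += gi;
    grad.row(k) += gk;
    grad.row(j) -= gi + gk;
  }
  // torsions: kt * (1 - cos(n*(phi - phi0)))
  for (arma::uword tq = 0; tq < cm.torsions.n_rows; ++tq) {
    int i = (int)cm.torsions(tq, 0), j = (int)cm.torsions(tq, 1),
        k = (int)cm.torsions(tq, 2), l = (int)cm.torsions(tq, 3);
    double n = cm.torsions(tq, 4), kt = cm.torsions(tq, 5),
           p0 = cm.torsions(tq, 6);
    arma::rowvec3 g1, g2, g3, g4;
    double phi = dihedral_grad(x.row(i), x.row(j), x.row(k), x.row(l),
                               g1, g2, g3, g4);
    U += kt * (1.0 - std::cos(n * (phi - p0)));
    double dU = kt * n * std::sin(n * (phi - p0));
    grad.row(i) += dU * g1;
    grad.row(j) += dU * g2;
    grad.row(k) += dU * g3;
    grad.row(l) += dU * g4;
  }
  // contacts: -scale * depth * exp(-(r-r0)^2 / (2 w^2))
  for (arma::uword c = 0; c < cm.contacts.n_rows; ++c) {
    int i = (int)cm.contacts(c, 0), j = (int)cm.contacts(c, 1);
    double D = cm.contacts(c, 2) * cm.contact_scale,
           r0 = cm.contacts(c, 3), w = cm.contacts(c, 4);
    if (D == 0.0) continue;
    arma::rowvec3 d = x.row(i) - x.row(j);
    double r = arma::norm(d);
    double e = std::exp(-(r - r0) * (r - r0) / (2.0 * w * w));
    U += -D * e;
    double dU = D * e * (r - r0) / (w * w);  // dU/dr
    arma::rowvec3 g = dU * d / std::max(r, 1e-12);
    grad.row(i) += g;
    grad.row(j) -= g;
  }
  // soft-core repulsion: eps * (1 - (r/rc)^2)^3 for r < rc
  if (cm.rep_eps > 0.0 && cm.rep_pairs.n_rows > 0) {
    double rc2 = cm.rep_rc * cm.rep_rc;
    for (arma::uword p = 0; p < cm.rep_pairs.n_rows; ++p) {
      int i = (int)cm.rep_pairs(p, 0), j = (int)cm.rep_pairs(p, 1);
      arma::rowvec3 d = x.row(i) - x.row(j);
      double r2 = arma::dot(d, d);
      if (r2 >= rc2) continue;
      double u = 1.0 - r2 / rc2;
      U += cm.rep_eps * u * u * u;
      // dU/dr2 = -3 eps u^2 / rc2 ; grad = 2 * dU/dr2 * d
      arma::rowvec3 g = (-6.0 * cm.rep_eps * u * u / rc2) * d;
      grad.row(i) += g;
      grad.row(j) -= g;
    }
  }
  // tethers: 1/2 k |ri - rj - d|^2   (j = -1: 1/2 k |ri - d|^2)
  for (arma::uword tt = 0; tt < cm.tethers.n_rows; ++tt) {
    int i = (int)cm.tethers(tt, 0), j = (int)cm.tethers(tt, 1);
    double k = cm.tethers(tt, 2);
    arma::rowvec3 d = {cm.tethers(tt, 3), cm.tethers(tt, 4),
                       cm.tethers(tt, 5)};
    arma::rowvec3 dev = (j >= 0) ? arma::rowvec3(x.row(i) - x.row(j) - d)
                                 : arma::rowvec3(x.row(i) - d);
    U += 0.5 * k * arma::dot(dev, dev);
    grad.row(i) += k * dev;
    if (j >= 0) grad.row(j) -= k * dev;
  }
  // 2D multi-well potential acting on atom 0 (x, y), z confined
  if (cm.has_pot2d) {
    arma::rowvec2 r = {x(0, 0), x(0, 1)};
    for (arma::uword m = 0; m < cm.p2_amps.n_elem; ++m) {
      arma::rowvec2 dc = r - cm.p2_centers.row(m);
      arma::mat22 P = {{cm.p2_precs(m, 0), cm.p2_precs(m, 1)},
                       {cm.p2_precs(m, 2), cm.p2_precs(m, 3)}};
      arma::rowvec2 Pd = dc * P;
      double e = std::exp(-0.5 * arma::dot(Pd, dc));
      U += cm.p2_amps(m) * e;
      arma::rowvec2 g = -cm.p2_amps(m) * e * Pd;
      grad(0, 0) += g(0);
      grad(0, 1) += g(1);
    }
    arma::rowvec2 dcf = r - arma::rowvec2{cm.p2_conf_center(0),
                                          cm.p2_conf_center(1)};
    U += 0.5 * cm.p2_kconf * arma::dot(dcf, dcf);
    grad(0, 0) += cm.p2_kconf * dcf(0);
    grad(0, 1) += cm.p2_kconf * dcf(1);
    U += 0.5 * cm.p2_kz * x(0, 2) * x(0, 2);
    grad(0, 2) += cm.p2_kz * x(0, 2);
  }
  return U;
}

// ---------------------------------------------------------------------------
// restraints

struct RestraintC {
  int kind = 0;              // 1 cart, 2 rmsd, 3 center, 4 orient
  arma::uvec sel;            // 0-based
  double k = 0.0;
  arma::mat ref;             // cart static ref / rmsd target / orient refcoords
  std::vector<arma::mat> frames;  // cart frame schedule
  arma::vec frame_times;
  double r0_a = 0.0, r0_b = 0.0, t0 = 0.0, t1 = 0.0;  // rmsd schedule
  bool r0_linear = false;
  arma::vec cref;            // center
  arma::vec qref;            // orient reference quaternion (w x y z)
  // scratch outputs
  mutable double last_rms = NA_REAL, last_r0 = NA_REAL,
                 last_theta = NA_REAL;
};

static std::vector<RestraintC> parse_restraints(const List& restraints) {
  std::vector<RestraintC> out;
  for (int ri = 0; ri < restraints.size(); ++ri) {
    List r(restraints[ri]);
    RestraintC rc;
    rc.kind = as<int>(r["kind"]);
    IntegerVector sel(r["sel"]);
    rc.sel.set_size(sel.size());
    for (int s = 0; s < sel.size(); ++s) rc.sel(s) = sel[s] - 1;
    rc.k = as<double>(r["k"]);
    if (r.containsElementNamed("ref") && !Rf_isNull(SEXP(r["ref"])))
      rc.ref = get_mat(r, "ref");
    if (r.containsElementNamed("frames") && !Rf_isNull(SEXP(r["frames"]))) {
      List fl(r["frames"]);
      for (int f = 0; f < fl.size(); ++f) {
        NumericMatrix fm(SEXP(fl[f]));
        rc.frames.push_back(arma::mat(fm.begin(), fm.nrow(), fm.ncol()));
      }
      rc.frame_times = as<arma::vec>(r["frame_times"]);
    }
    if (rc.kind == 2) {
      rc.r0_a = as<double>(r["r0_start"]);
      rc.r0_b = as<double>(r["r0_end"]);
      rc.t0 = as<double>(r["t_start"]);
      rc.t1 = as<double>(r["t_end"]);
      rc.r0_linear = rc.t1 > rc.t0;
    }
    if (rc.kind == 3) rc.cref = as<arma::vec>(r["cref"]);
    if (rc.kind == 4) rc.qref = as<arma::vec>(r["qref"]);
    out.push_back(rc);
  }
  return out;
}

// quaternion helpers (w, x, y, z)
static arma::vec4 quat_mul(const arma::vec4& a, const arma::vec4& b) {
  arma::vec4 q;
  q(0) = a(0) * b(0) - a(1) * b(1) - a(2) * b(2) - a(3) * b(3);
  q(1) = a(0) * b(1) + a(1) * b(0) + a(2) * b(3) - a(3) * b(2);
  q(2) = a(0) * b(2) - a(1) * b(3) + a(2) * b(0) + a(3) * b(1);
  q(3) = a(0) * b(3) + a(1) * b(2) - a(2) * b(1) + a(3) * b(0);
  return q;
}

// Horn quaternion matrix from S_ab = sum_i x_i[a] y_i[b]
static arma::mat44 horn_matrix(const arma::mat33& S) {
  double Sxx = S(0, 0), Sxy = S(0, 1), Sxz = S(0, 2);
  double Syx = S(1, 0), Syy = S(1, 1), Syz = S(1, 2);
  double Szx = S(2, 0), Szy = S(2, 1), Szz = S(2, 2);
  arma::mat44 N;
  N(0, 0) = Sxx + Syy + Szz;
  N(0, 1) = N(1, 0) = Syz - Szy;
  N(0, 2) = N(2, 0) = Szx - Sxz;
  N(0, 3) = N(3, 0) = Sxy - Syx;
  N(1, 1) = Sxx - Syy - Szz;
  N(1, 2) = N(2, 1) = Sxy + Syx;
  N(1, 3) = N(3, 1) = Szx + Sxz;
  N(2, 2) = -Sxx + Syy - Szz;
  N(2, 3) = N(3, 2) = Syz + Szy;
  N(3, 3) = -Sxx - Syy + Szz;
  return N;
}

// restraint energy; forces SUBTRACTED as gradient added into grad
static double restraint_energy(const RestraintC& rc, const arma::mat& x,
                               double t, arma::mat& grad) {
  const arma::uvec& sel = rc.sel;
  int n = sel.n_elem;
  switch (rc.kind) {
  case 1: {  // cartesian harmonic, possibly frame-advancing reference
    const arma::mat* ref = &rc.ref;
    if (!rc.frames.empty()) {
      int idx = 0;
      for (arma::uword f = 0; f < rc.frame_times.n_elem; ++f)
        if (t >= rc.frame_times(f) - 1e-12) idx = (int)f;
      ref = &rc.frames[idx];
    }
    double U = 0.0;
    for (int s = 0; s < n; ++s) {
      arma::rowvec3 d = x.row(sel(s)) - ref->row(s);
      U += 0.5 * rc.k * arma::dot(d, d);
      grad.row(sel(s)) += rc.k * d;
    }
    return U;
  }
  case 2: {  // 1/2 k (RMS - r0)^2 after optimal superposition
    arma::mat X(n, 3), Y = rc.ref;
    for (int s = 0; s < n; ++s) X.row(s) = x.row(sel(s));
    arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
    X.each_row() -= cx;
    Y.each_row() -= cy;
    arma::mat33 H = X.t() * Y;  // minimise |R X - Y|
    arma::mat U33, V33;
    arma::vec sv;
    arma::svd(U33, sv, V33, arma::mat(H));
    double d = arma::det(V33 * U33.t()) < 0 ? -1.0 : 1.0;
    arma::mat33 R = V33 * arma::diagmat(arma::vec3{1, 1, d}) * U33.t();
    arma::mat Xr = X * R.t();
    double msd = arma::accu(arma::square(Xr - Y)) / n;
    double rms = std::sqrt(std::max(msd, 0.0));
    double r0;
    if (rc.r0_linear) {
      double f = (t - rc.t0) / (rc.t1 - rc.t0);
      f = std::min(1.0, std::max(0.0, f));
      r0 = rc.r0_a + f * (rc.r0_b - rc.r0_a);
    } else r0 = rc.r0_a;
    rc.last_rms = rms;
    rc.last_r0 = r0;
    double U = 0.5 * rc.k * (rms - r0) * (rms - r0);
    if (rms > 1e-10) {
      // envelope theorem: optimal R, t are stationary, so the gradient is
      // the partial derivative at the aligned coordinates, rotated back
      double pref = rc.k * (rms - r0) / (n * rms);
      arma::mat G = pref * (Xr - Y) * R;  // back to mobile frame
      for (int s = 0; s < n; ++s) grad.row(sel(s)) += G.row(s);
    }
    return U;
  }
  case 3: {  // centre restraint
    arma::rowvec3 c = arma::zeros<arma::rowvec>(3);
    for (int s = 0; s < n; ++s) c += x.row(sel(s));
    c /= n;
    arma::rowvec3 d = c - arma::rowvec3{rc.cref(0), rc.cref(1), rc.cref(2)};
    double U = 0.5 * rc.k * arma::dot(d, d);
    arma::rowvec3 g = rc.k * d / n;
    for (int s = 0; s < n; ++s) grad.row(sel(s)) += g;
    return U;
  }
  case 4: {  // orientation-angle restraint: 1/2 k theta_deg^2
    arma::mat X(n, 3), Y = rc.ref;
    for (int s = 0; s < n; ++s) X.row(s) = x.row(sel(s));
    arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
    X.each_row() -= cx;
    Y.each_row() -= cy;
    arma::mat33 S = X.t() * Y;  // S_ab = sum_i x[a] y[b]
    arma::mat44 N = horn_matrix(S);
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, arma::mat(N));
    arma::vec4 q = evec.col(3);                 // largest eigenvalue
    arma::vec4 p = quat_mul(q, rc.qref);        // relative rotation
    double w = p(0), v = std::sqrt(p(1) * p(1) + p(2) * p(2) + p(3) * p(3));
    double sw = (w >= 0) ? 1.0 : -1.0;
    double theta = 2.0 * std::atan2(v, sw * w);  // radians, [0, pi]
    double theta_deg = theta * RAD2DEG;
    rc.last_theta = theta_deg;
    double U = 0.5 * rc.k * theta_deg * theta_deg;
    if (v < 1e-9) return U;  // theta ~ 0: quadratic minimum, zero force
    // dtheta/dp
    double denom = w * w + v * v;
    arma::vec4 dth_dp;
    dth_dp(0) = -2.0 * v * sw / denom;
    for (int c = 1; c < 4; ++c)
      dth_dp(c) = 2.0 * sw * w * p(c) / (v * denom);
    // dtheta/dq via p = q x qref (linear in q)
    arma::vec4 dth_dq;
    for (int c = 0; c < 4; ++c) {
      arma::vec4 e = arma::zeros<arma::vec>(4);
      e(c) = 1.0;
      dth_dq(c) = arma::dot(dth_dp, quat_mul(e, rc.qref));
    }
    // dq/dx via first-order eigenvector perturbation of N
    double pref = rc.k * theta_deg * RAD2DEG;  // dU/dtheta_rad
    arma::mat Gc(n, 3, arma::fill::zeros);
    arma::vec4 proj;  // sum_m v_m (v_m^T dN q) / (l3 - lm) projected on dth
    for (int s = 0; s < n; ++s) {
      for (int a = 0; a < 3; ++a) {
        // dS: row a of S gets y_i; build dN and contract
        arma::mat33 dS(arma::fill::zeros);
        dS.row(a) = Y.row(s);
        arma::mat44 dN = horn_matrix(dS);
        arma::vec4 dNq = dN * q;
        double dth = 0.0;
        for (int m = 0; m < 3; ++m) {
          double gap = eval(3) - eval(m);
          if (std::abs(gap) < 1e-10) continue;
          double coef = arma::dot(evec.col(m), dNq) / gap;
          dth += coef * arma::dot(dth_dq, evec.col(m));
        }
        Gc(s, a) = pref * dth;
      }
    }
    // account for centring: subtract the mean gradient
    arma::rowvec gmean = arma::mean(Gc, 0);
    Gc.each_row() -= gmean;
    for (int s = 0; s < n; ++s) grad.row(sel(s)) += Gc.row(s);
    return U;
  }
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// exported: single-point energies and forces

// [[Rcpp::export]]
List cpp_energy_forces(List model, NumericMatrix coords, List restraints,
                       double t) {
  ChainModel cm = parse_model(model);
  arma::mat x(coords.begin(), coords.nrow(), coords.ncol());
  arma::mat gm(x.n_rows, 3, arma::fill::zeros);
  double Um = chain_energy(cm, x, gm);
  std::vector<RestraintC> rs = parse_restraints(restraints);
  arma::mat gr(x.n_rows, 3, arma::fill::zeros);
  arma::vec Ur(rs.size(), arma::fill::zeros);
  arma::vec rms(rs.size()), r0(rs.size()), theta(rs.size());
  rms.fill(NA_REAL); r0.fill(NA_REAL); theta.fill(NA_REAL);
  for (size_t i = 0; i < rs.size(); ++i) {
    Ur(i) = restraint_energy(rs[i], x, t, gr);
    rms(i) = rs[i].last_rms;
    r0(i) = rs[i].last_r0;
    theta(i) = rs[i].last_theta;
  }
  arma::mat Ftot = -(gm + gr);
  return List::create(_["U_model"] = Um, _["U_restraints"] = Ur,
                      _["forces"] = Ftot, _["forces_model"] = -gm,
                      _["forces_restraints"] = -gr, _["rms"] = rms,
                      _["r0"] = r0, _["theta"] = theta);
}

// ---------------------------------------------------------------------------
// exported: BAOAB Langevin run

// [[Rcpp::export]]
List cpp_run(List model, NumericMatrix coords0, SEXP vel0, List restraints,
             NumericVector mass, double temperature, double friction,
             double dt, int nsteps, double t0, int save_every,
             IntegerVector collect, int equil_steps) {
  ChainModel cm = parse_model(model);
  std::vector<RestraintC> rs = parse_restraints(restraints);
  arma::mat x(coords0.begin(), coords0.nrow(), coords0.ncol());
  int natoms = x.n_rows;
  arma::vec m(mass.begin(), mass.size());
  const double kB = 0.0019872041;
  arma::mat v(natoms, 3);
  if (Rf_isNull(vel0)) {
    for (int i = 0; i < natoms; ++i) {
      double s = std::sqrt(KCAL * kB * temperature / m(i));
      for (int c = 0; c < 3; ++c) v(i, c) = s * norm_rand();
    }
  } else {
    NumericMatrix vv(vel0);
    v = arma::mat(vv.begin(), vv.nrow(), vv.ncol());
  }
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  arma::vec sig = arma::sqrt(KCAL * kB * temperature / m);

  arma::uvec col_idx(collect.size());
  for (int i = 0; i < collect.size(); ++i) col_idx(i) = collect[i] - 1;
  arma::mat sum_pos(col_idx.n_elem, 3, arma::fill::zeros);
  arma::mat sum_rforce(col_idx.n_elem, 3, arma::fill::zeros);
  long nsamp = 0;

  // initial force
  arma::mat grad(natoms, 3, arma::fill::zeros);
  double Um = chain_energy(cm, x, grad);
  arma::mat grad_r(natoms, 3, arma::fill::zeros);
  double Ur = 0.0;
  for (auto& r : rs) Ur += restraint_energy(r, x, t0, grad_r);
  arma::mat F = -(grad + grad_r);

  int nsave = (save_every > 0) ? (nsteps / save_every + 1) : 1;
  std::vector<arma::mat> frames;
  std::vector<double> times;
  frames.reserve(nsave);
  arma::mat logm(std::max(1, nsave), 5, arma::fill::zeros);
  int nlog = 0;  // columns: time U_model U_restraint rms r0
  if (save_every > 0) {
    frames.push_back(x);
    times.push_back(t0);
    logm(nlog, 0) = t0; logm(nlog, 1) = Um; logm(nlog, 2) = Ur;
    logm(nlog, 3) = rs.empty() ? NA_REAL : rs[0].last_rms;
    logm(nlog, 4) = rs.empty() ? NA_REAL : rs[0].last_r0;
    ++nlog;
  }

  for (int step = 0; step < nsteps; ++step) {
    double tnew = t0 + (step + 1) * dt;
    // B
    for (int i = 0; i < natoms; ++i)
      v.row(i) += 0.5 * dt * KCAL / m(i) * F.row(i);
    // A
    x += 0.5 * dt * v;
    // O
    for (int i = 0; i < natoms; ++i)
      for (int c = 0; c < 3; ++c)
        v(i, c) = c1 * v(i, c) + c2 * sig(i) * norm_rand();
    // A
    x += 0.5 * dt * v;
    // force at new positions / time
    grad.zeros();
    Um = chain_energy(cm, x, grad);
    grad_r.zeros();
    Ur = 0.0;
    for (auto& r : rs) Ur += restraint_energy(r, x, tnew, grad_r);
    F = -(grad + grad_r);
    // B
    for (int i = 0; i < natoms; ++i)
      v.row(i) += 0.5 * dt * KCAL / m(i) * F.row(i);

    if (!x.is_finite())
      stop("dynamics blew up at t = %f ps: non-finite coordinates; "
           "reduce the timestep or soften the stiffest term", tnew);

    if (step + 1 > equil_steps) {
      ++nsamp;
      for (arma::uword s = 0; s < col_idx.n_elem; ++s) {
        sum_pos.row(s) += x.row(col_idx(s));
        sum_rforce.row(s) += -grad_r.row(col_idx(s));
      }
    }
    if (save_every > 0 && (step + 1) % save_every == 0) {
      frames.push_back(x);
      times.push_back(tnew);
      logm(nlog, 0) = tnew; logm(nlog, 1) = Um; logm(nlog, 2) = Ur;
      logm(nlog, 3) = rs.empty() ? NA_REAL : rs[0].last_rms;
      logm(nlog, 4) = rs.empty() ? NA_REAL : rs[0].last_r0;
      ++nlog;
    }
  }

  List fr(frames.size());
  for (size_t i = 0; i < frames.size(); ++i)
    fr[i] = wrap(frames[i]);
  arma::mat mean_pos = nsamp > 0 ? arma::mat(sum_pos / nsamp) : sum_pos;
  arma::mat mean_rf = nsamp > 0 ? arma::mat(sum_rforce / nsamp) : sum_rforce;
  return List::create(
      _["frames"] = fr,
      _["times"] = wrap(times),
      _["coords"] = wrap(x),
      _["vel"] = wrap(v),
      _["mean_pos"] = wrap(mean_pos),
      _["mean_restraint_force"] = wrap(mean_rf),
      _["nsamples"] = (double)nsamp,
      _["log"] = wrap(nlog > 0 ? arma::mat(logm.rows(0, nlog - 1))
                               : arma::mat(0, 5)));
}

// [[Rcpp::export]]
double cpp_dihedral(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  arma::rowvec3 a = {p1[0], p1[1], p1[2]}, b = {p2[0], p2[1], p2[2]},
                c = {p3[0], p3[1], p3[2]}, d = {p4[0], p4[1], p4[2]};
  arma::rowvec3 g1, g2, g3, g4;
  return dihedral_grad(a, b, c, d, g1, g2, g3, g4) * RAD2DEG;
}
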