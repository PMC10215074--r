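// Quasi-static knee core: Grood-Suntay transform, ligament and contact
// energies with analytic gradients, and the 5-DOF per-step equilibrium solve.
// Units: mm, N, kg; angles in radians internally, degrees at the R boundary.
// Frame convention (both bones): x anterior, y proximal, z lateral (right knee).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double DEG = M_PI / 180.0;
// lever arm (mm) converting moment residuals to force units for the 5 N contract
static const double MOMENT_LEVER = 40.0;

struct Surface {
  double y0, cx, ax, az, xc, zc;   // height s(x,z) = y0 + cx*x + ax*(x-xc)^2 + az*(z-zc)^2
  double xrange, zrange;           // working half-extents about (xc, zc)
};

struct Model {
  int nl;
  mat lo, li;                      // nl x 3 attachment points (femoral / tibial frame)
  vec k, L0, epsl;
  mat sc;                          // 2 x 3 femoral sphere centres (lateral, medial)
  vec sR;                          // 2 sphere radii
  Surface surf[2];
  double kc, pexp, penmax;
  mat33 tib_rot;                   // tibial component rotation (insert surface frame)
  double mass, grav;               // kg, m/s^2
  vec3 com;                        // tibial frame, mm
  vec3 gdir;                       // unit vector along gravity, femoral frame
};

static Model parse_model(const Rcpp::List& L) {
  Model M;
  M.lo = Rcpp::as<mat>(L["lig_origin"]);
  M.li = Rcpp::as<mat>(L["lig_insertion"]);
  M.nl = (int)M.lo.n_rows;
  M.k = Rcpp::as<vec>(L["lig_k"]);
  M.L0 = Rcpp::as<vec>(L["lig_L0"]);
  M.epsl = Rcpp::as<vec>(L["lig_epsl"]);
  M.sc = Rcpp::as<mat>(L["sphere_center"]);
  M.sR = Rcpp::as<vec>(L["sphere_radius"]);
  mat sp = Rcpp::as<mat>(L["surface"]);   // 2 x 8: y0 cx ax az xc zc xrange zrange
  for (int c = 0; c < 2; ++c) {
    M.surf[c].y0 = sp(c,0); M.surf[c].cx = sp(c,1);
    M.surf[c].ax = sp(c,2); M.surf[c].az = sp(c,3);
    M.surf[c].xc = sp(c,4); M.surf[c].zc = sp(c,5);
    M.surf[c].xrange = sp(c,6); M.surf[c].zrange = sp(c,7);
  }
  M.kc = Rcpp::as<double>(L["contact_k"]);
  M.pexp = Rcpp::as<double>(L["contact_exp"]);
  M.penmax = Rcpp::as<double>(L["pen_max"]);
  M.tib_rot = Rcpp::as<mat>(L["tib_rot"]);
  M.mass = Rcpp::as<double>(L["mass"]);
  M.grav = Rcpp::as<double>(L["gravity"]);
  M.com = Rcpp::as<vec>(L["com"]);
  M.gdir = Rcpp::as<vec>(L["gravity_dir"]);
  return M;
}

static mat33 rotz(double t) {
  mat33 R; double c = cos(t), s = sin(t);
  R = {{c,-s,0},{s,c,0},{0,0,1}}; return R;
}
static mat33 rotx(double t) {
  mat33 R; double c = cos(t), s = sin(t);
  R = {{1,0,0},{0,c,-s},{0,s,c}}; return R;
}
static mat33 roty(double t) {
  mat33 R; double c = cos(t), s = sin(t);
  R = {{c,0,s},{0,1,0},{-s,0,c}}; return R;
}
static mat33 drotx(double t) {
  mat33 R; double c = cos(t), s = sin(t);
  R = {{0,0,0},{0,-s,-c},{0,c,-s}}; return R;
}
static mat33 droty(double t) {
  mat33 R; double c = cos(t), s = sin(t);
  R = {{-s,0,c},{0,0,0},{-c,0,-s}}; return R;
}

// Kinematic state for fixed flexion fe and free q = (ap, lm, pd, ei, vv),
// translations mm, rotations rad. Mobile Euler z-x-y realises Grood-Suntay:
// flexion about femoral z, varus about the floating axis, external about tibial y.
struct Kin {
  mat33 R;        // tibia -> femur rotation
  vec3 d;         // femoral-frame offset of tibial origin
  mat33 dR[5];    // dR/dq_j (zero for translations)
  mat dd;         // 3 x 5, dd/dq_j
};

static void kin_state(double fe, const vec& q, Kin& K) {
  double a = -fe, b = q(4), c = -q(3);          // z, x, y angles
  mat33 Rz = rotz(a), Rx = rotx(b), Ry = roty(c);
  K.R = Rz * Rx * Ry;
  mat33 dR_vv = Rz * drotx(b) * Ry;
  mat33 dR_ei = -(Rz * Rx * droty(c));
  K.dR[0].zeros(); K.dR[1].zeros(); K.dR[2].zeros();
  K.dR[3] = dR_ei; K.dR[4] = dR_vv;

  vec3 yhat = {0,1,0};
  vec3 e1 = {0,0,1};
  vec3 e3 = K.R * yhat;
  vec3 de3_ei = dR_ei * yhat, de3_vv = dR_vv * yhat;
  // u = e3 x e1 = (e3.y, -e3.x, 0)
  vec3 u = {e3(1), -e3(0), 0};
  double n = norm(u);
  vec3 e2 = u / n;
  auto de2_of = [&](const vec3& de3) -> vec3 {
    vec3 du = {de3(1), -de3(0), 0};
    return du / n - u * dot(u, du) / (n*n*n);
  };
  vec3 de2_ei = de2_of(de3_ei), de2_vv = de2_of(de3_vv);

  double ap = q(0), lm = q(1), pd = q(2);
  K.d = lm * e1 + ap * e2 + pd * e3;
  K.dd.set_size(3,5);
  K.dd.col(0) = e2;
  K.dd.col(1) = e1;
  K.dd.col(2) = e3;
  K.dd.col(3) = ap * de2_ei + pd * de3_ei;
  K.dd.col(4) = ap * de2_vv + pd * de3_vv;
}

// Blankevoort-style piecewise force (N) and its strain-energy integral (N, x L0 -> N mm)
static double lig_force(double k, double epsl, double eps) {
  if (eps <= 0) return 0.0;
  if (eps <= 2*epsl) return k * eps * eps / (4.0 * epsl);
  return k * (eps - epsl);
}
static double lig_energy_density(double k, double epsl, double eps) {
  if (eps <= 0) return 0.0;
  if (eps <= 2*epsl) return k * eps*eps*eps / (12.0 * epsl);
  double F2 = k * 8.0*epsl*epsl*epsl / (12.0 * epsl);  // value at 2 epsl
  return F2 + 0.5*k*((eps-epsl)*(eps-epsl) - epsl*epsl);
}

struct EvalOut {
  vec len, strain, force;
  vec pen;              // per compartment
  mat fvec;             // 3 x 2, contact force on femur, femoral frame
  mat cpt;              // 3 x 2, contact point, femoral frame
  bool range_ok;
  double energy;
  vec grad;             // 5, N and N mm/rad
};

// Potential energy and analytic gradient wrt q (ap,lm,pd mm; ei,vv rad)
static double energy(const Model& M, double fe, const vec& q, vec& grad, EvalOut* out) {
  Kin K;
  kin_state(fe, q, K);
  double E = 0.0;
  grad.zeros(5);
  if (out) {
    out->len.set_size(M.nl); out->strain.set_size(M.nl); out->force.set_size(M.nl);
    out->pen.zeros(2); out->fvec.zeros(3,2); out->cpt.zeros(3,2);
    out->range_ok = true;
  }

  // gravity: E = W * height, height = -gdir . p
  double W = M.mass * M.grav;
  vec3 comf = K.R * M.com + K.d;
  E += -W * dot(M.gdir, comf);
  for (int j = 0; j < 5; ++j) {
    vec3 dp = K.dR[j] * M.com + vec3(K.dd.col(j));
    grad(j) += -W * dot(M.gdir, dp);
  }

  // ligaments
  for (int i = 0; i < M.nl; ++i) {
    vec3 pt = M.li.row(i).t();
    vec3 pf = K.R * pt + K.d;
    vec3 o = M.lo.row(i).t();
    vec3 r = pf - o;
    double L = norm(r);
    double eps = L / M.L0(i) - 1.0;
    double f = lig_force(M.k(i), M.epsl(i), eps);
    E += M.L0(i) * lig_energy_density(M.k(i), M.epsl(i), eps);
    if (L > 1e-12 && f > 0) {
      vec3 uhat = r / L;
      for (int j = 0; j < 5; ++j) {
        vec3 dp = K.dR[j] * pt + vec3(K.dd.col(j));
        grad(j) += f * dot(uhat, dp);
      }
    }
    if (out) { out->len(i) = L; out->strain(i) = eps; out->force(i) = f; }
  }

  // contact, per compartment: sphere centre mapped to the tibial component
  // (insert) frame, vertical-gap elastic law evaluated there
  for (int c = 0; c < 2; ++c) {
    const Surface& S = M.surf[c];
    vec3 sc = M.sc.row(c).t();
    vec3 ct = M.tib_rot.t() * (K.R.t() * (sc - K.d));
    double x = ct(0), z = ct(2);
    if (out && (std::abs(x - S.xc) > S.xrange || std::abs(z - S.zc) > S.zrange))
      out->range_ok = false;
    double s = S.y0 + S.cx*x + S.ax*(x-S.xc)*(x-S.xc) + S.az*(z-S.zc)*(z-S.zc);
    double gap = ct(1) - M.sR(c) - s;
    if (gap < 0) {
      double pen = -gap;
      if (out && pen > M.penmax) out->range_ok = false;
      double fmag = M.kc * std::pow(pen, M.pexp);
      E += M.kc * std::pow(pen, M.pexp + 1.0) / (M.pexp + 1.0);
      double sx = S.cx + 2.0*S.ax*(x-S.xc);
      double sz = 2.0*S.az*(z-S.zc);
      // dE/dq = kc pen^p * dpen/dq, pen = -gap
      for (int j = 0; j < 5; ++j) {
        vec3 dct = M.tib_rot.t() * (K.dR[j].t() * (sc - K.d) - K.R.t() * vec3(K.dd.col(j)));
        double dgap = dct(1) - sx*dct(0) - sz*dct(2);
        grad(j) += fmag * (-dgap);
      }
      if (out) {
        out->pen(c) = pen;
        // energy-consistent force on femur: fmag * (-sx, 1, -sz) in insert coords
        vec3 ft = M.tib_rot * vec3({-fmag*sx, fmag, -fmag*sz});
        out->fvec.col(c) = K.R * ft;
        vec3 nrm = {-sx, 1, -sz}; nrm /= norm(nrm);
        vec3 cp_t = M.tib_rot * (ct - M.sR(c) * nrm);
        out->cpt.col(c) = K.R * cp_t + K.d;
      }
    }
  }

  if (out) { out->energy = E; out->grad = grad; }
  return E;
}

static double resid_norm(const vec& g) {
  double s = g(0)*g(0) + g(1)*g(1) + g(2)*g(2);
  double m3 = g(3)/MOMENT_LEVER, m4 = g(4)/MOMENT_LEVER;
  return std::sqrt(s + m3*m3 + m4*m4);
}

static void fd_hessian(const Model& M, double fe, const vec& q, mat& H) {
  static const vec h = {1e-4, 1e-4, 1e-4, 1e-6, 1e-6};
  vec gp(5), gm(5);
  H.set_size(5,5);
  for (int j = 0; j < 5; ++j) {
    vec qp = q, qm = q;
    qp(j) += h(j); qm(j) -= h(j);
    energy(M, fe, qp, gp, nullptr);
    energy(M, fe, qm, gm, nullptr);
    H.col(j) = (gp - gm) / (2.0*h(j));
  }
  H = 0.5*(H + H.t());
}

// Damped Newton on the potential-energy gradient; FD Hessian of the analytic
// gradient, reused across iterations (and warm-started steps) and refreshed
// when progress stalls; Armijo backtracking with a residual-decrease fallback
// near the energy-resolution floor; Levenberg regularisation when not PD.
static void solve5(const Model& M, double fe, vec& q, double tol, int maxit,
                   double& res, bool& conv, int& iters,
                   mat& H, bool& haveH) {
  vec g(5);
  double E = energy(M, fe, q, g, nullptr);
  res = resid_norm(g);
  conv = false;
  int it = 0, since_refresh = haveH ? 4 : 100;
  for (; it < maxit; ++it) {
    if (res < tol) { conv = true; break; }
    if (!haveH || since_refresh >= 8) {
      fd_hessian(M, fe, q, H);
      haveH = true; since_refresh = 0;
    }
    double lambda = 0.0;
    vec p;
    for (int k = 0; k < 12; ++k) {
      mat Hr = H + lambda * eye(5,5);
      bool ok = solve(p, Hr, -g, solve_opts::no_approx);
      if (ok && dot(p, g) < 0) break;
      lambda = (lambda == 0.0) ? std::max(1e-4, 1e-6*std::abs(H.diag().max())) : lambda*10.0;
      p.reset();
    }
    if (p.n_elem == 0) p = -g / std::max(1.0, norm(g));
    double step = 1.0, gTp = dot(g, p);
    bool moved = false;
    for (int ls = 0; ls < 30; ++ls) {
      vec qn = q + step * p;
      vec gn(5);
      double En = energy(M, fe, qn, gn, nullptr);
      double rn = resid_norm(gn);
      // Armijo on energy, or (at the double-precision energy floor) a
      // plain residual decrease
      if (En <= E + 1e-4 * step * gTp || En < E || rn < 0.5 * res) {
        q = qn; E = En; g = gn; res = rn; moved = true; break;
      }
      step *= 0.5;
    }
    ++since_refresh;
    if (!moved) {
      if (since_refresh > 1) { since_refresh = 100; continue; }  // stale H: refresh
      break;
    }
    if (norm(p) * step < 1e-13) break;
  }
  if (res < tol) conv = true;
  iters = it;
}

static vec q_to_internal(const vec& q_user) {
  vec q = q_user;  // (ap, lm, pd, ei_deg, vv_deg)
  q(3) *= DEG; q(4) *= DEG;
  return q;
}
static vec q_to_user(const vec& q) {
  vec u = q; u(3) /= DEG; u(4) /= DEG; return u;
}

// [[Rcpp::export]]
Rcpp::List cpp_eval(Rcpp::List model, double fe_deg, Rcpp::NumericVector q5) {
  Model M = parse_model(model);
  vec q = q_to_internal(Rcpp::as<vec>(q5));
  vec g(5);
  EvalOut out;
  double E = energy(M, fe_deg * DEG, q, g, &out);
  vec gu = g;  // report rotation components per radian
  return Rcpp::List::create(
    Rcpp::Named("length") = out.len,
    Rcpp::Named("strain") = out.strain,
    Rcpp::Named("force") = out.force,
    Rcpp::Named("penetration") = out.pen,
    Rcpp::Named("contact_force") = out.fvec,
    Rcpp::Named("contact_point") = out.cpt,
    Rcpp::Named("range_ok") = out.range_ok,
    Rcpp::Named("energy") = E,
    Rcpp::Named("gradient") = gu,
    Rcpp::Named("residual") = resid_norm(g));
}

// [[Rcpp::export]]
Rcpp::List cpp_solve(Rcpp::List model, double fe_deg, Rcpp::NumericVector q5,
                     double tol = 1e-5, int maxit = 200) {
  Model M = parse_model(model);
  vec q = q_to_internal(Rcpp::as<vec>(q5));
  double res; bool conv; int iters;
  mat H; bool haveH = false;
  solve5(M, fe_deg * DEG, q, tol, maxit, res, conv, iters, H, haveH);
  return Rcpp::List::create(
    Rcpp::Named("q") = q_to_user(q),
    Rcpp::Named("residual") = res,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("iterations") = iters);
}

// [[Rcpp::export]]
Rcpp::List cpp_trace(Rcpp::List model, int t, double fe_start, double fe_end,
                     Rcpp::NumericVector q5_init, double tol = 1e-5,
                     int maxit = 200, bool warm = true) {
  Model M = parse_model(model);
  vec q0 = q_to_internal(Rcpp::as<vec>(q5_init));
  mat pose(t, 6), strains(t, M.nl);
  vec resid(t);
  Rcpp::LogicalVector conv(t);
  vec q = q0;
  mat H; bool haveH = false;
  for (int i = 0; i < t; ++i) {
    double fe = fe_start + (fe_end - fe_start) * (t == 1 ? 0.0 : (double)i / (t - 1));
    if (!warm) { q = q0; haveH = false; }
    double res; bool cv; int iters;
    solve5(M, fe * DEG, q, tol, maxit, res, cv, iters, H, haveH);
    vec g(5); EvalOut out;
    energy(M, fe * DEG, q, g, &out);
    vec qu = q_to_user(q);
    pose(i,0) = fe; pose(i,1) = qu(0); pose(i,2) = qu(1); pose(i,3) = qu(2);
    pose(i,4) = qu(3); pose(i,5) = qu(4);
    strains.row(i) = out.strain.t();
    resid(i) = res;
    conv(i) = cv;
  }
  return Rcpp::List::create(
    Rcpp::Named("pose") = pose,
    Rcpp::Named("strain") = strains,
    Rcpp::Named("residual") = resid,
    Rcpp::Named("converged") = conv);
}
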