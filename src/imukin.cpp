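// Performance core: rotation algebra, forward kinematics, per-frame
// Levenberg-Marquardt inverse kinematics with warm starts, and the
// complementary-filter loops. Quaternions are scalar-first (w,x,y,z) and
// represent sensor-to-earth (or segment-to-ground) rotations: v_earth = q v q*.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

typedef arma::vec::fixed<3> vec3;
typedef arma::vec::fixed<4> vec4;
typedef arma::mat::fixed<3, 3> mat33;

static inline vec4 qmul(const vec4 &a, const vec4 &b) {
  vec4 r;
  r(0) = a(0) * b(0) - a(1) * b(1) - a(2) * b(2) - a(3) * b(3);
  r(1) = a(0) * b(1) + a(1) * b(0) + a(2) * b(3) - a(3) * b(2);
  r(2) = a(0) * b(2) - a(1) * b(3) + a(2) * b(0) + a(3) * b(1);
  r(3) = a(0) * b(3) + a(1) * b(2) - a(2) * b(1) + a(3) * b(0);
  return r;
}

static inline vec4 qnorm(vec4 q) {
  double n = arma::norm(q);
  return q / n;
}

static inline mat33 quat2mat(const vec4 &q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat33 R;
  R(0, 0) = 1 - 2 * (y * y + z * z);
  R(0, 1) = 2 * (x * y - w * z);
  R(0, 2) = 2 * (x * z + w * y);
  R(1, 0) = 2 * (x * y + w * z);
  R(1, 1) = 1 - 2 * (x * x + z * z);
  R(1, 2) = 2 * (y * z - w * x);
  R(2, 0) = 2 * (x * z - w * y);
  R(2, 1) = 2 * (y * z + w * x);
  R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

// Shepperd-style branch selection, w >= 0 on output.
static inline vec4 mat2quat(const mat33 &R) {
  vec4 q;
  double tr = R(0, 0) + R(1, 1) + R(2, 2);
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q(0) = 0.25 * s;
    q(1) = (R(2, 1) - R(1, 2)) / s;
    q(2) = (R(0, 2) - R(2, 0)) / s;
    q(3) = (R(1, 0) - R(0, 1)) / s;
  } else if (R(0, 0) > R(1, 1) && R(0, 0) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(0, 0) - R(1, 1) - R(2, 2)) * 2.0;
    q(0) = (R(2, 1) - R(1, 2)) / s;
    q(1) = 0.25 * s;
    q(2) = (R(0, 1) + R(1, 0)) / s;
    q(3) = (R(0, 2) + R(2, 0)) / s;
  } else if (R(1, 1) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(1, 1) - R(0, 0) - R(2, 2)) * 2.0;
    q(0) = (R(0, 2) - R(2, 0)) / s;
    q(1) = (R(0, 1) + R(1, 0)) / s;
    q(2) = 0.25 * s;
    q(3) = (R(1, 2) + R(2, 1)) / s;
  } else {
    double s = std::sqrt(1.0 + R(2, 2) - R(0, 0) - R(1, 1)) * 2.0;
    q(0) = (R(1, 0) - R(0, 1)) / s;
    q(1) = (R(0, 2) + R(2, 0)) / s;
    q(2) = (R(1, 2) + R(2, 1)) / s;
    q(3) = 0.25 * s;
  }
  if (q(0) < 0) q = -q;
  return qnorm(q);
}

static inline mat33 rotz(double a) {
  mat33 R;
  double c = std::cos(a), s = std::sin(a);
  R.zeros();
  R(0, 0) = c; R(0, 1) = -s;
  R(1, 0) = s; R(1, 1) = c;
  R(2, 2) = 1;
  return R;
}
static inline mat33 rotx(double a) {
  mat33 R;
  double c = std::cos(a), s = std::sin(a);
  R.zeros();
  R(0, 0) = 1;
  R(1, 1) = c; R(1, 2) = -s;
  R(2, 1) = s; R(2, 2) = c;
  return R;
}
static inline mat33 roty(double a) {
  mat33 R;
  double c = std::cos(a), s = std::sin(a);
  R.zeros();
  R(0, 0) = c; R(0, 2) = s;
  R(1, 1) = 1;
  R(2, 0) = -s; R(2, 2) = c;
  return R;
}

// Rodrigues for a unit axis
static inline mat33 axis_angle(const vec3 &u, double a) {
  mat33 K;
  K.zeros();
  K(0, 1) = -u(2); K(0, 2) = u(1);
  K(1, 0) = u(2);  K(1, 2) = -u(0);
  K(2, 0) = -u(1); K(2, 1) = u(0);
  mat33 I = arma::eye(3, 3);
  return I + std::sin(a) * K + (1 - std::cos(a)) * (K * K);
}

// rotation-vector (axis * angle) of R, angle in [0, pi]
static inline vec3 logvee(const mat33 &R) {
  vec4 q = mat2quat(R);
  double vn = std::sqrt(q(1) * q(1) + q(2) * q(2) + q(3) * q(3));
  vec3 out;
  if (vn < 1e-14) {
    out.zeros();
    return out;
  }
  double ang = 2.0 * std::atan2(vn, q(0));
  out(0) = q(1) / vn * ang;
  out(1) = q(2) / vn * ang;
  out(2) = q(3) / vn * ang;
  return out;
}

// ---------------------------------------------------------------------------
// Kinematic model, flattened by R/model.R (model_arrays):
//   parent : 0-based parent segment index, -1 for root
//   jtype  : 0 weld, 1 pin, 2 ball (intrinsic Z-X-Y), free6 rotation == ball
//   qidx   : 3 x S, 0-based coordinate indices (-1 unused; pin uses row 0)
//   axis   : 3 x S pin axes (parent/segment frame)
//   Rfix   : 3x3xS fixed rotation offsets (root carries ground alignment)
//   tfix   : 3 x S joint centre in parent segment frame (root: ground frame)
//   tidx   : 3 root translation coordinate indices (-1 if absent)
// Segments arrive in topological order (parent before child).
// ---------------------------------------------------------------------------
struct Model {
  int S;
  arma::ivec parent, jtype;
  arma::imat qidx;
  arma::mat axis;
  arma::cube Rfix;
  arma::mat tfix;
  arma::ivec tidx;
};

static Model parse_model(const List &m) {
  Model M;
  M.parent = as<arma::ivec>(m["parent"]);
  M.jtype = as<arma::ivec>(m["jtype"]);
  M.qidx = as<arma::imat>(m["qidx"]);
  M.axis = as<arma::mat>(m["axis"]);
  NumericVector rf = m["Rfix"];
  M.S = M.parent.n_elem;
  M.Rfix = arma::cube(REAL(rf), 3, 3, M.S);
  M.tfix = as<arma::mat>(m["tfix"]);
  M.tidx = as<arma::ivec>(m["tidx"]);
  return M;
}

static void fk_orient(const Model &M, const double *q, arma::cube &R) {
  for (int s = 0; s < M.S; ++s) {
    mat33 Rj;
    switch ((int)M.jtype(s)) {
    case 0:
      Rj = arma::eye(3, 3);
      break;
    case 1:
      Rj = axis_angle(M.axis.col(s), q[M.qidx(0, s)]);
      break;
    default:
      Rj = rotz(q[M.qidx(0, s)]) * rotx(q[M.qidx(1, s)]) * roty(q[M.qidx(2, s)]);
    }
    mat33 loc = M.Rfix.slice(s) * Rj;
    if (M.parent(s) < 0)
      R.slice(s) = loc;
    else
      R.slice(s) = R.slice(M.parent(s)) * loc;
  }
}

static void fk_pos(const Model &M, const double *q, const arma::cube &R,
                   arma::mat &p) {
  for (int s = 0; s < M.S; ++s) {
    if (M.parent(s) < 0) {
      vec3 t = M.tfix.col(s);
      for (int k = 0; k < 3; ++k)
        if (M.tidx(k) >= 0) t(k) += q[M.tidx(k)];
      p.col(s) = t;
    } else {
      p.col(s) = p.col(M.parent(s)) + R.slice(M.parent(s)) * M.tfix.col(s);
    }
  }
}

// [[Rcpp::export]]
NumericVector fk_orient_cpp(List m, NumericMatrix Q) {
  Model M = parse_model(m);
  int n = Q.nrow();
  NumericVector out(9 * M.S * n);
  out.attr("dim") = IntegerVector::create(3, 3, M.S, n);
  arma::cube R(3, 3, M.S);
  arma::rowvec q(Q.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < Q.ncol(); ++j) q(j) = Q(i, j);
    fk_orient(M, q.memptr(), R);
    std::copy(R.memptr(), R.memptr() + 9 * M.S, out.begin() + (size_t)9 * M.S * i);
  }
  return out;
}

// [[Rcpp::export]]
List fk_sensors_cpp(List m, IntegerVector sens_seg, NumericVector Roff,
                    NumericMatrix spos, NumericMatrix Q) {
  Model M = parse_model(m);
  int n = Q.nrow(), K = sens_seg.size();
  arma::cube Roffc(REAL(Roff), 3, 3, K);
  arma::mat sp = as<arma::mat>(spos);
  NumericVector oq(4 * K * n);
  oq.attr("dim") = IntegerVector::create(4, K, n);
  NumericVector op(3 * K * n);
  op.attr("dim") = IntegerVector::create(3, K, n);
  arma::cube R(3, 3, M.S);
  arma::mat p(3, M.S);
  arma::rowvec q(Q.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < Q.ncol(); ++j) q(j) = Q(i, j);
    fk_orient(M, q.memptr(), R);
    fk_pos(M, q.memptr(), R, p);
    for (int k = 0; k < K; ++k) {
      int s = sens_seg[k];
      mat33 Rs = R.slice(s) * Roffc.slice(k);
      vec4 qq = mat2quat(Rs);
      vec3 pp = p.col(s) + R.slice(s) * sp.col(k);
      for (int c = 0; c < 4; ++c) oq[(size_t)4 * (K * i + k) + c] = qq(c);
      for (int c = 0; c < 3; ++c) op[(size_t)3 * (K * i + k) + c] = pp(c);
    }
  }
  return List::create(_["q"] = oq, _["pos"] = op);
}

// ---------------------------------------------------------------------------
// Inverse kinematics.  Residual vector stacks, for each active sensor i,
// sqrt(w_i) * log( (R_i^meas)^T R_seg(q) R_off_i )  in R^3, so that the
// squared norm equals sum_i w_i * theta_i^2 (theta in radians).
// ---------------------------------------------------------------------------
static inline arma::vec clampv(arma::vec x, const arma::vec &lo,
                               const arma::vec &hi) {
  for (arma::uword i = 0; i < x.n_elem; ++i)
    x(i) = std::min(hi(i), std::max(lo(i), x(i)));
  return x;
}

struct IKProblem {
  const Model *M;
  arma::ivec sseg;      // segment index per sensor
  arma::cube Roff;      // offsets
  std::vector<mat33> Rmeas;  // measured rotations, active sensors only
  std::vector<int> act;      // active sensor indices
  arma::vec sw;              // sqrt(weight) per active sensor
  arma::ivec free_idx;       // free coordinate indices (0-based)
  arma::vec qfull;           // full coordinate vector (frozen coords kept)
};

static void ik_resid(IKProblem &P, const arma::vec &p, arma::cube &Rwork,
                     arma::vec &r) {
  for (arma::uword j = 0; j < P.free_idx.n_elem; ++j)
    P.qfull(P.free_idx(j)) = p(j);
  fk_orient(*P.M, P.qfull.memptr(), Rwork);
  for (size_t a = 0; a < P.act.size(); ++a) {
    int k = P.act[a];
    mat33 E = P.Rmeas[a].t() * (Rwork.slice(P.sseg(k)) * P.Roff.slice(k));
    vec3 v = logvee(E);
    r(3 * a) = P.sw(a) * v(0);
    r(3 * a + 1) = P.sw(a) * v(1);
    r(3 * a + 2) = P.sw(a) * v(2);
  }
}

// [[Rcpp::export]]
List ik_solve_cpp(List m, IntegerVector sens_seg, NumericVector Roff,
                  NumericVector qmeas, NumericVector w, NumericVector q0,
                  IntegerVector free_idx, NumericVector lb, NumericVector ub,
                  List control) {
  Model M = parse_model(m);
  int K = sens_seg.size();
  IntegerVector qd = qmeas.attr("dim");
  int n = qd[2];
  int nc = q0.size();
  int maxit = as<int>(control["max_iter"]);
  double cost_tol = as<double>(control["cost_tol"]);
  double step_tol = as<double>(control["step_tol"]);
  double lambda0 = as<double>(control["lambda0"]);
  double fd_h = as<double>(control["fd_h"]);

  IKProblem P;
  P.M = &M;
  P.sseg = as<arma::ivec>(sens_seg);
  P.Roff = arma::cube(REAL(Roff), 3, 3, K);
  P.free_idx = as<arma::ivec>(free_idx);
  P.qfull = as<arma::vec>(q0);
  int nf = P.free_idx.n_elem;
  arma::vec vlb = as<arma::vec>(lb), vub = as<arma::vec>(ub);

  NumericMatrix Qout(n, nc), Theta(n, K);
  NumericVector Cost(n);
  IntegerVector Iters(n);
  LogicalVector Conv(n);
  std::fill(Theta.begin(), Theta.end(), NA_REAL);

  arma::cube Rwork(3, 3, M.S);
  arma::vec p(nf);
  for (int j = 0; j < nf; ++j) p(j) = P.qfull(P.free_idx(j));
  p = clampv(p, vlb, vub);

  const double *qm = REAL(qmeas);

  for (int i = 0; i < n; ++i) {
    // measured rotations for this frame; NaN quaternions drop the term
    P.act.clear();
    P.Rmeas.clear();
    std::vector<double> sws;
    for (int k = 0; k < K; ++k) {
      const double *qp = qm + (size_t)4 * (K * i + k);
      if (!std::isfinite(qp[0])) continue;
      vec4 qk;
      for (int c = 0; c < 4; ++c) qk(c) = qp[c];
      if (w[k] > 0) {
        P.act.push_back(k);
        P.Rmeas.push_back(quat2mat(qnorm(qk)));
        sws.push_back(std::sqrt(w[k]));
      }
    }
    P.sw = arma::vec(sws);
    int na = P.act.size();
    bool conv = false;
    int it = 0;
    double cost = 0.0;

    if (na > 0) {
      int nr = 3 * na;
      arma::vec r(nr), rtry(nr), rph(nr);
      ik_resid(P, p, Rwork, r);
      cost = arma::dot(r, r);
      double lambda = lambda0;
      int small_decrease = 0;
      arma::mat J(nr, nf);
      for (it = 0; it < maxit; ++it) {
        if (cost < 1e-24) { conv = true; break; }
        // forward-difference Jacobian
        for (int j = 0; j < nf; ++j) {
          arma::vec ph = p;
          ph(j) += fd_h;
          ik_resid(P, ph, Rwork, rph);
          J.col(j) = (rph - r) / fd_h;
        }
        arma::vec g = J.t() * r;
        // active set: coordinates pinned at a bound with the gradient pushing
        // outward are frozen for this iteration (and ignored in the KKT test)
        std::vector<arma::uword> freep;
        for (int j = 0; j < nf; ++j) {
          bool pinned = (p(j) <= vlb(j) + 1e-12 && g(j) > 0) ||
                        (p(j) >= vub(j) - 1e-12 && g(j) < 0);
          if (!pinned) freep.push_back(j);
        }
        arma::uvec fidx(freep);
        if (fidx.n_elem == 0 || arma::norm(g(fidx), "inf") < 1e-10) {
          conv = true;
          break;
        }
        arma::mat Jf = J.cols(fidx);
        arma::vec gf = g(fidx);
        arma::mat A = Jf.t() * Jf;
        bool accepted = false;
        double prev = cost;
        for (int tries = 0; tries < 12; ++tries) {
          arma::mat H = A;
          H.diag() += lambda * (A.diag() + 1e-12);
          arma::vec dltf;
          if (!arma::solve(dltf, H, -gf, arma::solve_opts::fast)) {
            lambda *= 10;
            continue;
          }
          arma::vec dlt(nf, arma::fill::zeros);
          dlt(fidx) = dltf;
          arma::vec pn = clampv(p + dlt, vlb, vub);
          ik_resid(P, pn, Rwork, rtry);
          double cn = arma::dot(rtry, rtry);
          if (cn < cost) {
            double stepn = arma::norm(pn - p, "inf");
            p = pn;
            r = rtry;
            cost = cn;
            lambda = std::max(lambda / 3.0, 1e-12);
            accepted = true;
            if (stepn < step_tol) { conv = true; }
            break;
          }
          lambda *= 10;
        }
        if (!accepted) { conv = true; break; }  // no descent direction left
        if (conv) break;
        if (prev - cost < cost_tol * (cost + cost_tol)) { conv = true; break; }
        // repeated marginal decreases: constrained optimum being ground out
        small_decrease = (prev - cost < 1e-7 * (cost + 1e-12)) ?
          small_decrease + 1 : 0;
        if (small_decrease >= 3) { conv = true; break; }
      }
    } else {
      conv = true;
    }

    for (arma::uword j = 0; j < P.free_idx.n_elem; ++j)
      P.qfull(P.free_idx(j)) = p(j);
    for (int c = 0; c < nc; ++c) Qout(i, c) = P.qfull(c);
    // theta for every sensor present in the frame (including zero-weight ones)
    fk_orient(M, P.qfull.memptr(), Rwork);
    for (int k = 0; k < K; ++k) {
      const double *qp = qm + (size_t)4 * (K * i + k);
      if (!std::isfinite(qp[0])) continue;
      vec4 qk;
      for (int c = 0; c < 4; ++c) qk(c) = qp[c];
      mat33 E = quat2mat(qnorm(qk)).t() * (Rwork.slice(P.sseg(k)) * P.Roff.slice(k));
      double arg = (arma::trace(E) - 1.0) / 2.0;
      arg = std::min(1.0, std::max(-1.0, arg));
      Theta(i, k) = std::acos(arg);
    }
    Cost[i] = cost;
    Iters[i] = it;
    Conv[i] = conv;
    // warm start next frame from p
  }
  return List::create(_["q"] = Qout, _["theta"] = Theta, _["cost"] = Cost,
                      _["iterations"] = Iters, _["converged"] = Conv);
}

// ---------------------------------------------------------------------------
// Complementary filters.  Accelerometers measure specific force: a static,
// level sensor reads (0, 0, +9.81).  Earth frame: Z up, X = horizontal
// magnetic field at initialisation.
// ---------------------------------------------------------------------------

static vec4 madgwick_update(const vec4 &q0v, const vec3 &g, vec3 a, vec3 m,
                            double dt, double beta, bool use_mag) {
  // predictor: gyro integration; corrector: normalised gradient step on the
  // accel/mag objective, evaluated at the predicted state so the measurement
  // and the state refer to the same instant
  vec4 om;
  om(0) = 0; om(1) = g(0); om(2) = g(1); om(3) = g(2);
  vec4 q = qnorm(q0v + 0.5 * qmul(q0v, om) * dt);
  double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  double an = arma::norm(a);
  if (beta > 0 && an > 0) {
    a /= an;
    arma::vec F;
    arma::mat J;
    double mn = use_mag ? arma::norm(m) : 0.0;
    if (use_mag && mn > 0) {
      m /= mn;
      vec3 h = quat2mat(q) * m;  // field in earth frame
      double bx = std::sqrt(h(0) * h(0) + h(1) * h(1));
      double bz = h(2);
      F.set_size(6);
      J.set_size(6, 4);
      F(0) = 2 * (q1 * q3 - q0 * q2) - a(0);
      F(1) = 2 * (q0 * q1 + q2 * q3) - a(1);
      F(2) = 2 * (0.5 - q1 * q1 - q2 * q2) - a(2);
      F(3) = 2 * bx * (0.5 - q2 * q2 - q3 * q3) + 2 * bz * (q1 * q3 - q0 * q2) - m(0);
      F(4) = 2 * bx * (q1 * q2 - q0 * q3) + 2 * bz * (q0 * q1 + q2 * q3) - m(1);
      F(5) = 2 * bx * (q0 * q2 + q1 * q3) + 2 * bz * (0.5 - q1 * q1 - q2 * q2) - m(2);
      J(0, 0) = -2 * q2; J(0, 1) = 2 * q3; J(0, 2) = -2 * q0; J(0, 3) = 2 * q1;
      J(1, 0) = 2 * q1;  J(1, 1) = 2 * q0; J(1, 2) = 2 * q3;  J(1, 3) = 2 * q2;
      J(2, 0) = 0;       J(2, 1) = -4 * q1; J(2, 2) = -4 * q2; J(2, 3) = 0;
      J(3, 0) = -2 * bz * q2;
      J(3, 1) = 2 * bz * q3;
      J(3, 2) = -4 * bx * q2 - 2 * bz * q0;
      J(3, 3) = -4 * bx * q3 + 2 * bz * q1;
      J(4, 0) = -2 * bx * q3 + 2 * bz * q1;
      J(4, 1) = 2 * bx * q2 + 2 * bz * q0;
      J(4, 2) = 2 * bx * q1 + 2 * bz * q3;
      J(4, 3) = -2 * bx * q0 + 2 * bz * q2;
      J(5, 0) = 2 * bx * q2;
      J(5, 1) = 2 * bx * q3 - 4 * bz * q1;
      J(5, 2) = 2 * bx * q0 - 4 * bz * q2;
      J(5, 3) = 2 * bx * q1;
    } else {
      F.set_size(3);
      J.set_size(3, 4);
      F(0) = 2 * (q1 * q3 - q0 * q2) - a(0);
      F(1) = 2 * (q0 * q1 + q2 * q3) - a(1);
      F(2) = 2 * (0.5 - q1 * q1 - q2 * q2) - a(2);
      J(0, 0) = -2 * q2; J(0, 1) = 2 * q3; J(0, 2) = -2 * q0; J(0, 3) = 2 * q1;
      J(1, 0) = 2 * q1;  J(1, 1) = 2 * q0; J(1, 2) = 2 * q3;  J(1, 3) = 2 * q2;
      J(2, 0) = 0;       J(2, 1) = -4 * q1; J(2, 2) = -4 * q2; J(2, 3) = 0;
    }
    arma::vec step = J.t() * F;
    double sn = arma::norm(step);
    // a vanishing gradient means the state already satisfies the
    // accelerometer/magnetometer objective: normalising it would inject a
    // full-size step in a round-off-determined direction
    if (sn > 1e-9) {
      step /= sn;
      for (int c = 0; c < 4; ++c) q(c) -= beta * step(c) * dt;
      q = qnorm(q);
    }
  }
  return q;
}

static void mahony_update(vec4 &q, const vec3 &g, vec3 a, vec3 m, double dt,
                          double kp, double ki, vec3 &integ, bool use_mag) {
  // predictor: gyro integration (plus the running bias correction);
  // corrector: PI feedback on the direction errors at the predicted state
  vec4 om0;
  om0(0) = 0;
  om0(1) = g(0) + integ(0);
  om0(2) = g(1) + integ(1);
  om0(3) = g(2) + integ(2);
  q = qnorm(q + 0.5 * qmul(q, om0) * dt);
  double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  vec3 gy;
  gy.zeros();
  double an = arma::norm(a);
  if ((kp > 0 || ki > 0) && an > 0) {
    a /= an;
    vec3 v;  // estimated gravity direction in sensor frame
    v(0) = 2 * (q1 * q3 - q0 * q2);
    v(1) = 2 * (q0 * q1 + q2 * q3);
    v(2) = q0 * q0 - q1 * q1 - q2 * q2 + q3 * q3;
    vec3 e = arma::cross(a, v);
    double mn = use_mag ? arma::norm(m) : 0.0;
    if (use_mag && mn > 0) {
      m /= mn;
      vec3 h = quat2mat(q) * m;
      double bx = std::sqrt(h(0) * h(0) + h(1) * h(1));
      double bz = h(2);
      vec3 wv;  // estimated field direction in sensor frame
      wv(0) = 2 * bx * (0.5 - q2 * q2 - q3 * q3) + 2 * bz * (q1 * q3 - q0 * q2);
      wv(1) = 2 * bx * (q1 * q2 - q0 * q3) + 2 * bz * (q0 * q1 + q2 * q3);
      wv(2) = 2 * bx * (q0 * q2 + q1 * q3) + 2 * bz * (0.5 - q1 * q1 - q2 * q2);
      e += arma::cross(m, wv);
    }
    if (ki > 0) integ += ki * e * dt;
    gy = kp * e;
    vec4 om;
    om(0) = 0; om(1) = gy(0); om(2) = gy(1); om(3) = gy(2);
    q = qnorm(q + 0.5 * qmul(q, om) * dt);
  }
}

// [[Rcpp::export]]
NumericMatrix madgwick_filter_cpp(NumericVector t, NumericMatrix gyro,
                                  NumericMatrix accel, NumericMatrix mag,
                                  NumericVector q0, double beta,
                                  int mag_divisor, bool use_mag, int start) {
  int n = t.size();
  NumericMatrix Q(n, 4);
  vec4 q;
  for (int c = 0; c < 4; ++c) q(c) = q0[c];
  q = qnorm(q);
  for (int i = 0; i <= std::min(start, n - 1); ++i)
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
  long step = 0;
  for (int i = start + 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    vec3 g, a, m;
    for (int c = 0; c < 3; ++c) {
      g(c) = 0.5 * (gyro(i - 1, c) + gyro(i, c));
      a(c) = accel(i, c);
      m(c) = mag(i, c);
    }
    bool um = use_mag && (mag_divisor <= 1 || (step % mag_divisor) == 0);
    q = madgwick_update(q, g, a, m, dt, beta, um);
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
    ++step;
  }
  return Q;
}

// [[Rcpp::export]]
List mahony_filter_cpp(NumericVector t, NumericMatrix gyro,
                       NumericMatrix accel, NumericMatrix mag,
                       NumericVector q0, double kp, double ki,
                       int mag_divisor, bool use_mag, int start) {
  int n = t.size();
  NumericMatrix Q(n, 4), B(n, 3);
  vec4 q;
  for (int c = 0; c < 4; ++c) q(c) = q0[c];
  q = qnorm(q);
  vec3 integ;
  integ.zeros();
  for (int i = 0; i <= std::min(start, n - 1); ++i)
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
  long step = 0;
  for (int i = start + 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    vec3 g, a, m;
    for (int c = 0; c < 3; ++c) {
      g(c) = 0.5 * (gyro(i - 1, c) + gyro(i, c));
      a(c) = accel(i, c);
      m(c) = mag(i, c);
    }
    bool um = use_mag && (mag_divisor <= 1 || (step % mag_divisor) == 0);
    mahony_update(q, g, a, m, dt, kp, ki, integ, um);
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
    for (int c = 0; c < 3; ++c) B(i, c) = -integ(c);  // gyro-bias estimate
    ++step;
  }
  return List::create(_["q"] = Q, _["bias"] = B);
}

// [[Rcpp::export]]
NumericMatrix gyro_filter_cpp(NumericVector t, NumericMatrix gyro,
                              NumericVector q0, int start) {
  int n = t.size();
  NumericMatrix Q(n, 4);
  vec4 q;
  for (int c = 0; c < 4; ++c) q(c) = q0[c];
  q = qnorm(q);
  for (int i = 0; i <= std::min(start, n - 1); ++i)
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
  for (int i = start + 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    vec4 om;
    om(0) = 0;
    for (int c = 0; c < 3; ++c) om(c + 1) = 0.5 * (gyro(i - 1, c) + gyro(i, c));
    q = qnorm(q + 0.5 * qmul(q, om) * dt);
    for (int c = 0; c < 4; ++c) Q(i, c) = q(c);
  }
  return Q;
}

// [[Rcpp::export]]
NumericVector madgwick_step_cpp(NumericVector q, NumericVector gyro,
                                NumericVector accel, NumericVector mag,
                                double dt, double beta, bool use_mag) {
  vec4 qq;
  vec3 g, a, m;
  for (int c = 0; c < 4; ++c) qq(c) = q[c];
  for (int c = 0; c < 3; ++c) {
    g(c) = gyro[c];
    a(c) = accel[c];
    m(c) = mag[c];
  }
  vec4 out = madgwick_update(qnorm(qq), g, a, m, dt, beta, use_mag);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List mahony_step_cpp(NumericVector q, NumericVector gyro, NumericVector accel,
                     NumericVector mag, double dt, double kp, double ki,
                     NumericVector integ, bool use_mag) {
  vec4 qq;
  vec3 g, a, m, ig;
  for (int c = 0; c < 4; ++c) qq(c) = q[c];
  for (int c = 0; c < 3; ++c) {
    g(c) = gyro[c];
    a(c) = accel[c];
    m(c) = mag[c];
    ig(c) = integ[c];
  }
  qq = qnorm(qq);
  mahony_update(qq, g, a, m, dt, kp, ki, ig, use_mag);
  return List::create(_["q"] = NumericVector(qq.begin(), qq.end()),
                      _["integral"] = NumericVector(ig.begin(), ig.end()));
}
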