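// Interior-point solver for the package's linear programs.
//
// Both SVM formulations are LPs in the standard inequality form
//     min c'z   s.t.  A z >= b,  z >= 0,
// solved here by an infeasible primal-dual Mehrotra predictor-corrector
// method on the KKT system
//     A z - s = b,  A'y + w = c,  z.w = 0,  s.y = 0,  (z,s,y,w) >= 0.
// Each Newton step reduces to the normal equations
//     (A D A' + diag(s/y)) dy = rhs,   D = diag(z/w).
// The driver is shared; what differs between backends is how the normal
// matrix is formed and factorized:
//   * DenseOp:      explicit A, dense Cholesky of A D A' + E  (n_con small);
//   * JointSvmOp:   the multiclass joint-penalty SVM, where the hinge block
//     is dense per class and the 2m(c-1) box rows (|beta_jk| <= t_j) are
//     eliminated feature-by-feature through a Schur complement, leaving an
//     n(c-1) x n(c-1) dense system.

// warn level 1: suppress runtime "approx solution" chatter from the
// endgame triangular solves; those iterates are vetted by the
// best-iterate safeguard and the independent feasibility recheck
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LPOperator {
  uword nvar = 0, ncon = 0;
  virtual vec multA(const vec& z) const = 0;
  virtual vec multAt(const vec& y) const = 0;
  // prepare (A D A' + diag(ed))^{-1}
  virtual bool factorize(const vec& d, const vec& ed) = 0;
  virtual vec solveNE(const vec& rhs) const = 0;
  // optional projection removing the null component of +/- split variable
  // pairs (a cost-reducing, feasibility-preserving move; keeps the split
  // columns from drifting jointly to infinity)
  virtual void normalizePrimal(vec&) const {}
  virtual ~LPOperator() = default;
};

// ---------------------------------------------------------------- dense ----

struct DenseOp : public LPOperator {
  const mat& A;
  mat R;  // Cholesky factor of the normal matrix
  explicit DenseOp(const mat& A_) : A(A_) {
    ncon = A.n_rows;
    nvar = A.n_cols;
  }
  vec multA(const vec& z) const override { return A * z; }
  vec multAt(const vec& y) const override { return A.t() * y; }
  bool factorize(const vec& d, const vec& ed) override {
    mat As = A.each_row() % sqrt(d).t();
    mat M = As * As.t();
    M.diag() += ed;
    double ridge = 1e-14 * (1.0 + trace(M) / M.n_rows);
    for (int attempt = 0; attempt < 12; ++attempt) {
      if (chol(R, M, "lower")) return true;
      M.diag() += ridge;
      ridge *= 100.0;
    }
    return false;
  }
  vec solveNE(const vec& rhs) const override {
    vec u = solve(trimatl(R), rhs);
    return solve(trimatu(R.t()), u);
  }
};

// ---------------------------------------------- multiclass joint-penalty ----
//
// Variable layout (flat):  U (m*K) | V (m*K) | bp (K) | bm (K) | XI (n*K) | t (m)
// Constraint layout:       hinge H (n*K) | box minus Bm (m*K) | box plus Bp (m*K)
// with beta = U - V, hinge rows
//     y_ik (sum_j beta_jk x_ij + bp_k - bm_k) + xi_ik >= 1
// and box rows  t_j - beta_jk >= 0,  t_j + beta_jk >= 0.

struct JointSvmOp : public LPOperator {
  const mat& X;     // n x m transformed abundances
  const mat& Y;     // n x K (+/-1 one-against-rest encoding)
  uword n, m, K;
  // per-iteration workspace.  The box block for feature j is
  //   K_j = dt_j 11' + blockdiag_k [[a+e1, -a], [-a, a+e2]],  a = duv_jk,
  // inverted in closed form (2x2 inverses + Sherman-Morrison on the rank-one
  // t_j coupling); all intermediate quantities are positive, which keeps the
  // elimination stable when the t duals spread over many orders of magnitude.
  mat duv;                  // m x K, dU + dV
  vec dt;                   // m
  mat b11, b12, b22;        // m x K, per-class 2x2 inverse entries / det
  mat hmat;                 // 2K x m, Binv * 1
  vec fac;                  // m, dt / (1 + dt * 1'Binv 1)
  mat wdiag, phi;           // m x K: a*e1*e2/det and a*(e1-e2)/det
  mat e1m, e2m, detm;       // m x K: box diagonal scalings and determinants
  mat S_R;                  // Cholesky factor of the nK x nK Schur complement

  JointSvmOp(const mat& X_, const mat& Y_) : X(X_), Y(Y_) {
    n = X.n_rows;
    m = X.n_cols;
    K = Y.n_cols;
    nvar = 2 * m * K + 2 * K + n * K + m;
    ncon = n * K + 2 * m * K;
  }

  // views into a flat variable vector
  struct VarView {
    mat U, V, XI;
    vec bp, bm, t;
  };
  VarView splitVar(const vec& z) const {
    VarView v;
    uword o = 0;
    v.U = reshape(z.subvec(o, o + m * K - 1), m, K); o += m * K;
    v.V = reshape(z.subvec(o, o + m * K - 1), m, K); o += m * K;
    v.bp = z.subvec(o, o + K - 1); o += K;
    v.bm = z.subvec(o, o + K - 1); o += K;
    v.XI = reshape(z.subvec(o, o + n * K - 1), n, K); o += n * K;
    v.t = z.subvec(o, o + m - 1);
    return v;
  }
  struct ConView {
    mat H, Bm, Bp;
  };
  ConView splitCon(const vec& y) const {
    ConView c;
    uword o = 0;
    c.H = reshape(y.subvec(o, o + n * K - 1), n, K); o += n * K;
    c.Bm = reshape(y.subvec(o, o + m * K - 1), m, K); o += m * K;
    c.Bp = reshape(y.subvec(o, o + m * K - 1), m, K);
    return c;
  }
  vec joinCon(const mat& H, const mat& Bm, const mat& Bp) const {
    vec out(ncon);
    out.subvec(0, n * K - 1) = vectorise(H);
    out.subvec(n * K, n * K + m * K - 1) = vectorise(Bm);
    out.subvec(n * K + m * K, ncon - 1) = vectorise(Bp);
    return out;
  }
  vec joinVar(const mat& U, const mat& V, const vec& bp, const vec& bm,
              const mat& XI, const vec& t) const {
    vec out(nvar);
    uword o = 0;
    out.subvec(o, o + m * K - 1) = vectorise(U); o += m * K;
    out.subvec(o, o + m * K - 1) = vectorise(V); o += m * K;
    out.subvec(o, o + K - 1) = bp; o += K;
    out.subvec(o, o + K - 1) = bm; o += K;
    out.subvec(o, o + n * K - 1) = vectorise(XI); o += n * K;
    out.subvec(o, o + m - 1) = t;
    return out;
  }

  void normalizePrimal(vec& z) const override {
    VarView v = splitVar(z);
    mat s = 0.9 * min(v.U, v.V);
    v.U -= s;
    v.V -= s;
    vec sb = 0.9 * min(v.bp, v.bm);
    v.bp -= sb;
    v.bm -= sb;
    z = joinVar(v.U, v.V, v.bp, v.bm, v.XI, v.t);
  }

  vec multA(const vec& z) const override {
    VarView v = splitVar(z);
    mat F = X * (v.U - v.V);                       // n x K
    F.each_row() += (v.bp - v.bm).t();
    mat H = Y % F + v.XI;
    mat Bm = v.V - v.U;  Bm.each_col() += v.t;
    mat Bp = v.U - v.V;  Bp.each_col() += v.t;
    return joinCon(H, Bm, Bp);
  }

  vec multAt(const vec& y) const override {
    ConView c = splitCon(y);
    mat G2 = X.t() * (Y % c.H);                    // m x K
    mat atU = G2 - c.Bm + c.Bp;
    mat atV = -G2 + c.Bm - c.Bp;
    vec atbp = sum(Y % c.H, 0).t();
    vec att = sum(c.Bm + c.Bp, 1);
    return joinVar(atU, atV, atbp, -atbp, c.H, att);
  }

  bool factorize(const vec& d, const vec& ed) override {
    VarView dv = splitVar(d);
    ConView ev = splitCon(ed);
    duv = dv.U + dv.V;
    dt = dv.t;

    // per-feature box blocks: closed-form inverse pieces
    b11.set_size(m, K);
    b12.set_size(m, K);
    b22.set_size(m, K);
    wdiag.set_size(m, K);
    phi.set_size(m, K);
    e1m.set_size(m, K);
    e2m.set_size(m, K);
    detm.set_size(m, K);
    hmat.set_size(2 * K, m);
    fac.set_size(m);
    for (uword j = 0; j < m; ++j) {
      double s = 0.0;
      for (uword k = 0; k < K; ++k) {
        double a = duv(j, k);
        double e1 = ev.Bm(j, k), e2 = ev.Bp(j, k);
        double det = a * (e1 + e2) + e1 * e2;
        if (det < 1e-300) det = 1e-300;
        b11(j, k) = (a + e2) / det;
        b12(j, k) = a / det;
        b22(j, k) = (a + e1) / det;
        hmat(2 * k, j) = (2.0 * a + e2) / det;
        hmat(2 * k + 1, j) = (2.0 * a + e1) / det;
        s += (4.0 * a + e1 + e2) / det;
        // duv - duv^2 G has the subtraction-free form a e1 e2/det + fac phi^2
        wdiag(j, k) = a * e1 * e2 / det;
        phi(j, k) = a * (e1 - e2) / det;
        e1m(j, k) = e1;
        e2m(j, k) = e2;
        detm(j, k) = det;
      }
      fac(j) = dt(j) / (1.0 + dt(j) * s);
    }

    // Schur complement over the hinge block
    mat S(n * K, n * K);
    for (uword k = 0; k < K; ++k) {
      for (uword kp = k; kp < K; ++kp) {
        vec wvec = fac % phi.col(k) % phi.col(kp);
        if (kp == k) wvec += wdiag.col(k);
        mat W = (X.each_row() % wvec.t()) * X.t();   // n x n
        W %= Y.col(k) * Y.col(kp).t();
        if (kp == k) {
          W += (dv.bp(k) + dv.bm(k)) * (Y.col(k) * Y.col(k).t());
          W.diag() += dv.XI.col(k) + ev.H.col(k);
        }
        S.submat(k * n, kp * n, (k + 1) * n - 1, (kp + 1) * n - 1) = W;
        if (kp != k)
          S.submat(kp * n, k * n, (kp + 1) * n - 1, (k + 1) * n - 1) = W.t();
      }
    }
    double ridge = 1e-14 * (1.0 + trace(S) / S.n_rows);
    for (int attempt = 0; attempt < 12; ++attempt) {
      if (chol(S_R, S, "lower")) return true;
      S.diag() += ridge;
      ridge *= 100.0;
    }
    return false;
  }

  // apply the closed-form K_j^{-1} to a stacked (minus,plus) box vector
  void applyBoxInv(uword j, const double* x, double* out) const {
    double hx = 0.0;
    for (uword k = 0; k < 2 * K; ++k) hx += hmat(k, j) * x[k];
    double f = fac(j) * hx;
    for (uword k = 0; k < K; ++k) {
      out[2 * k] = b11(j, k) * x[2 * k] + b12(j, k) * x[2 * k + 1] -
                   f * hmat(2 * k, j);
      out[2 * k + 1] = b12(j, k) * x[2 * k] + b22(j, k) * x[2 * k + 1] -
                       f * hmat(2 * k + 1, j);
    }
  }

  vec solveNE(const vec& rhs) const override {
    ConView r = splitCon(rhs);

    // fold the box rows into the hinge right-hand side
    mat qa(m, K);                     // q_k' K_j^{-1} rhs_Bj, subtraction-free
    mat alphaStore(2 * K, m);
    std::vector<double> rb(2 * K), al(2 * K);
    for (uword j = 0; j < m; ++j) {
      double hx = 0.0;
      for (uword k = 0; k < K; ++k) {
        rb[2 * k] = r.Bm(j, k);
        rb[2 * k + 1] = r.Bp(j, k);
        hx += hmat(2 * k, j) * rb[2 * k] + hmat(2 * k + 1, j) * rb[2 * k + 1];
      }
      applyBoxInv(j, rb.data(), al.data());
      for (uword k = 0; k < K; ++k) {
        alphaStore(2 * k, j) = al[2 * k];
        alphaStore(2 * k + 1, j) = al[2 * k + 1];
        qa(j, k) = (e1m(j, k) * rb[2 * k + 1] - e2m(j, k) * rb[2 * k] -
                    fac(j) * hx * (e1m(j, k) - e2m(j, k))) / detm(j, k);
      }
    }
    mat rH = r.H - Y % (X * (duv % qa));

    vec dyH = solve(trimatl(S_R), vectorise(rH));
    dyH = solve(trimatu(S_R.t()), dyH);
    mat DyH = reshape(dyH, n, K);

    // back-substitute the box multipliers
    mat R2 = duv % (X.t() * (Y % DyH));            // m x K
    mat DBm(m, K), DBp(m, K);
    for (uword j = 0; j < m; ++j) {
      for (uword k = 0; k < K; ++k) {
        rb[2 * k] = -R2(j, k);
        rb[2 * k + 1] = R2(j, k);
      }
      applyBoxInv(j, rb.data(), al.data());
      for (uword k = 0; k < K; ++k) {
        DBm(j, k) = alphaStore(2 * k, j) - al[2 * k];
        DBp(j, k) = alphaStore(2 * k + 1, j) - al[2 * k + 1];
      }
    }
    return joinCon(DyH, DBm, DBp);
  }
};

// --------------------------------------------------------------- driver ----

// solve the normal equations with one round of iterative refinement, using
// the exact operator products (the factorized form loses accuracy when the
// complementarity scalings spread over many orders of magnitude)
vec solveRefined(const LPOperator& op, const vec& d, const vec& ed,
                 const vec& rhs) {
  vec dy = op.solveNE(rhs);
  for (int pass = 0; pass < 2; ++pass) {
    vec resid = rhs - (op.multA(d % op.multAt(dy)) + ed % dy);
    double rel = norm(resid, "inf") / (1.0 + norm(rhs, "inf"));
    if (rel < 1e-11) break;
    dy += op.solveNE(resid);
  }
  return dy;
}

double stepLength(const vec& x, const vec& dx) {
  double a = 1.0;
  for (uword i = 0; i < x.n_elem; ++i)
    if (dx(i) < 0) a = std::min(a, -x(i) / dx(i));
  return a;
}

struct IpmResult {
  vec z, y, w, s;
  int status = 1;     // 0 optimal, 1 iteration limit, 2 infeasible, 3 unbounded
  int iterations = 0;
  double accuracy = datum::inf;   // best max(rel primal, rel dual, rel gap)
};

IpmResult mehrotra(LPOperator& op, const vec& b, const vec& c,
                   double tol, int max_iter, int verbose = 0) {
  const uword p = op.nvar, nc = op.ncon;
  double sc = std::max(1.0, std::max(norm(b, "inf"), norm(c, "inf")));
  double s0 = std::sqrt(sc);

  IpmResult res;
  vec z(p, fill::value(s0)), w(p, fill::value(s0));
  vec y(nc, fill::value(s0)), s(nc, fill::value(s0));
  double bn = 1.0 + norm(b, "inf"), cn = 1.0 + norm(c, "inf");
  double best = datum::inf;
  int best_iter = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    res.iterations = iter;
    vec rp = b - op.multA(z) + s;
    vec rd = c - op.multAt(y) - w;
    double zw = dot(z, w), sy = dot(s, y);
    double mu = (zw + sy) / (p + nc);
    double obj = dot(c, z);
    double rpn = norm(rp, "inf") / bn;
    double rdn = norm(rd, "inf") / cn;
    double gap = (zw + sy) / (1.0 + std::abs(obj));
    double score = std::max(rpn, std::max(rdn, gap));
    if (score < best) {
      best = score;
      best_iter = iter;
      res.z = z; res.y = y; res.w = w; res.s = s;
    }
    // endgame safeguard: with extreme-conditioned factorizations the
    // directions can stop making progress (or blow the iterates up); give
    // up after a stretch without improvement and report the best iterate
    if (iter - best_iter > 20) break;
    if (verbose && iter % verbose == 0)
      Rcpp::Rcout << "it " << iter << " rp " << rpn << " rd " << rdn
                  << " gap " << gap << " obj " << obj << " ynorm "
                  << norm(y, "inf") << " wnorm " << norm(w, "inf")
                  << " znorm " << norm(z, "inf") << std::endl;
    if (score < tol) break;
    if (norm(y, "inf") + norm(w, "inf") > 1e11 * s0) { res.status = 2; break; }
    if (norm(z, "inf") + norm(s, "inf") > 1e11 * s0 && obj < -1e9 * sc) {
      res.status = 3;
      break;
    }

    vec d = clamp(z / w, 1e-14, 1e14);
    vec ed = clamp(s / y, 1e-14, 1e14);
    if (!op.factorize(d, ed)) { res.status = 1; break; }

    // affine (predictor) direction
    vec rc1 = -z % w;
    vec rc2 = -s % y;
    vec rhs = rp + rc2 / y - op.multA(d % (rc1 / z - rd));
    vec dy = solveRefined(op, d, ed, rhs);
    vec dz = d % (op.multAt(dy) + rc1 / z - rd);
    vec dw = (rc1 - w % dz) / z;
    vec ds = (rc2 - s % dy) / y;

    double ap = std::min(1.0, std::min(stepLength(z, dz), stepLength(s, ds)));
    double ad = std::min(1.0, std::min(stepLength(y, dy), stepLength(w, dw)));
    double mu_aff = (dot(z + ap * dz, w + ad * dw) +
                     dot(s + ap * ds, y + ad * dy)) / (p + nc);
    double sigma = std::pow(std::max(mu_aff, 0.0) / mu, 3.0);
    sigma = std::min(sigma, 1.0);

    // corrector direction (same factorization)
    rc1 = sigma * mu - z % w - dz % dw;
    rc2 = sigma * mu - s % y - ds % dy;
    rhs = rp + rc2 / y - op.multA(d % (rc1 / z - rd));
    dy = solveRefined(op, d, ed, rhs);
    dz = d % (op.multAt(dy) + rc1 / z - rd);
    dw = (rc1 - w % dz) / z;
    ds = (rc2 - s % dy) / y;

    ap = std::min(1.0, 0.9995 * std::min(stepLength(z, dz), stepLength(s, ds)));
    ad = std::min(1.0, 0.9995 * std::min(stepLength(y, dy), stepLength(w, dw)));
    z += ap * dz;
    s += ap * ds;
    y += ad * dy;
    w += ad * dw;
    op.normalizePrimal(z);
  }
  res.accuracy = best;
  if (best < 100 * tol) res.status = 0;
  if (res.z.n_elem == 0) { res.z = z; res.y = y; res.w = w; res.s = s; }
  return res;
}

const char* statusName(int code) {
  switch (code) {
    case 0: return "optimal";
    case 2: return "infeasible";
    case 3: return "unbounded";
    default: return "numerical_failure";
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List ipm_solve_dense(const arma::mat& A, const arma::vec& b,
                           const arma::vec& cost, double tol = 1e-9,
                           int max_iter = 200) {
  DenseOp op(A);
  IpmResult r = mehrotra(op, b, cost, tol, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("variables") = r.z,
      Rcpp::Named("dual") = r.y,
      Rcpp::Named("objective") = dot(cost, r.z),
      Rcpp::Named("status") = std::string(statusName(r.status)),
      Rcpp::Named("iterations") = r.iterations,
      Rcpp::Named("accuracy") = r.accuracy);
}

// [[Rcpp::export]]
Rcpp::List ipm_solve_joint_svm(const arma::mat& X, const arma::mat& Y,
                               double lam, double eps, double tol = 1e-9,
                               int max_iter = 200, int verbose = 0) {
  JointSvmOp op(X, Y);
  uword m = X.n_cols, n = X.n_rows, K = Y.n_cols;
  vec cost(op.nvar, fill::zeros);
  uword o = 0;
  cost.subvec(o, 2 * m * K - 1).fill(eps); o += 2 * m * K;      // u, v
  cost.subvec(o, o + 2 * K - 1).fill(eps); o += 2 * K;          // intercepts
  cost.subvec(o, o + n * K - 1).fill(1.0); o += n * K;          // slacks
  cost.subvec(o, o + m - 1).fill(lam);                          // row bounds t
  vec b(op.ncon, fill::zeros);
  b.subvec(0, n * K - 1).fill(1.0);                             // hinge rhs

  IpmResult r = mehrotra(op, b, cost, tol, max_iter, verbose);
  JointSvmOp::VarView v = op.splitVar(r.z);
  mat B = v.U - v.V;
  vec beta0 = v.bp - v.bm;
  double obj_true = accu(v.XI) + lam * accu(v.t);
  return Rcpp::List::create(
      Rcpp::Named("B") = B,
      Rcpp::Named("beta0") = beta0,
      Rcpp::Named("xi") = v.XI,
      Rcpp::Named("t") = v.t,
      Rcpp::Named("objective") = obj_true,
      Rcpp::Named("status") = std::string(statusName(r.status)),
      Rcpp::Named("iterations") = r.iterations,
      Rcpp::Named("accuracy") = r.accuracy);
}
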