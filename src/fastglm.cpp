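// Fast weighted GLM fitting and the cluster-bootstrap engine for the
// TE/CDE mediation estimator.
//
// Point estimation uses double-precision IRLS (cpp_irls / cpp_wls) on
// column subsets of one shared design matrix. The bootstrap engine
// re-estimates the whole TE/CDE pipeline on every person-level
// resample; a resample enters the fits as per-row frequency weights
// (likelihood-identical to stacking the resampled rows), so no row
// copies are ever made. Inside the engine the IRLS runs in single
// precision on column-scaled copies of the design: bootstrap
// replicates only feed standard errors, for which the ~1e-4 relative
// coefficient error of the float path is negligible, and the float
// path roughly halves both memory traffic and floating-point work.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double WEIGHT_FLOOR = 1e-10;
static const double COEF_BOUND = 50.0; // |beta| beyond this flags separation

struct IrlsFit {
  arma::vec beta;
  arma::vec eta;
  bool converged;
  int iterations;
  double score_norm;
  double loglik;
  bool separated;
};

// Weighted logistic IRLS, double precision.
// Convergence: relative deviance change < tol (glm-style).
static IrlsFit irls_core(const arma::mat& Xs, const arma::vec& y,
                         const arma::vec& w, const arma::vec& start,
                         double tol, int maxit) {
  const arma::uword p = Xs.n_cols;
  IrlsFit out;
  out.beta = start.n_elem == p ? start : arma::vec(p, arma::fill::zeros);
  out.converged = false;
  out.separated = false;
  double dev_old = R_PosInf;
  arma::vec eta = Xs * out.beta, mu, score;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec v = mu % (1.0 - mu);
    v.transform([](double x) { return x < WEIGHT_FLOOR ? WEIGHT_FLOOR : x; });
    arma::vec W = w % v;
    score = Xs.t() * (w % (y - mu));
    out.score_norm = arma::norm(score, "inf");
    double dev = -2.0 * arma::accu(w % (y % arma::log(mu + 1e-300) +
                                        (1.0 - y) % arma::log(1.0 - mu + 1e-300)));
    if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
      out.converged = true;
      break;
    }
    dev_old = dev;
    arma::mat Xh = Xs.each_col() % arma::sqrt(W);
    arma::mat XtWX = Xh.t() * Xh;
    arma::vec rhs = XtWX * out.beta + score;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, rhs, arma::solve_opts::likely_sympd);
    if (!ok) {
      out.separated = true; // rank deficiency / degenerate weights
      break;
    }
    out.beta = beta_new;
    eta = Xs * out.beta;
    if (arma::norm(out.beta, "inf") > COEF_BOUND) {
      out.separated = true;
      break;
    }
  }
  out.iterations = std::min(it, maxit);
  mu = 1.0 / (1.0 + arma::exp(-eta));
  out.loglik = arma::accu(w % (y % arma::log(mu + 1e-300) +
                               (1.0 - y) % arma::log(1.0 - mu + 1e-300)));
  out.eta = eta;
  return out;
}

// [[Rcpp::export]]
List cpp_irls(const arma::mat& X, const arma::uvec& cols, const arma::vec& y,
              const arma::vec& w, Nullable<NumericVector> start = R_NilValue,
              double tol = 1e-10, int maxit = 100) {
  arma::mat Xs = X.cols(cols);
  arma::vec st;
  if (start.isNotNull()) st = as<arma::vec>(start.get());
  IrlsFit f = irls_core(Xs, y, w, st, tol, maxit);
  return List::create(_["coef"] = f.beta, _["eta"] = f.eta,
                      _["converged"] = f.converged,
                      _["iterations"] = f.iterations,
                      _["score_norm"] = f.score_norm, _["loglik"] = f.loglik,
                      _["separated"] = f.separated);
}

struct WlsFit {
  arma::vec beta;
  arma::vec eta;
  double sigma;
  bool ok;
};

// Weighted least squares with weighted residual s.d. (frequency weights).
static WlsFit wls_core(const arma::mat& Xs, const arma::vec& y,
                       const arma::vec& w) {
  WlsFit out;
  arma::vec sw = arma::sqrt(w);
  arma::mat Xh = Xs.each_col() % sw;
  arma::mat XtWX = Xh.t() * Xh;
  arma::vec rhs = Xs.t() * (w % y);
  out.ok = arma::solve(out.beta, XtWX, rhs, arma::solve_opts::likely_sympd);
  if (!out.ok) return out;
  out.eta = Xs * out.beta;
  arma::vec res = y - out.eta;
  double wsum = arma::accu(w);
  double dfree = wsum - static_cast<double>(Xs.n_cols);
  if (dfree < 1.0) dfree = 1.0;
  out.sigma = std::sqrt(arma::accu(w % arma::square(res)) / dfree);
  return out;
}

// [[Rcpp::export]]
List cpp_wls(const arma::mat& X, const arma::uvec& cols, const arma::vec& y,
             const arma::vec& w) {
  arma::mat Xs = X.cols(cols);
  WlsFit f = wls_core(Xs, y, w);
  return List::create(_["coef"] = f.beta, _["eta"] = f.eta,
                      _["sigma"] = f.sigma, _["ok"] = f.ok);
}

// ---------------------------------------------------------------------
// Single-precision machinery for the bootstrap engine
// ---------------------------------------------------------------------

// Orthonormalise a model block once in double precision (economy QR)
// and hand the float IRLS the Q factor: X'WX in the Q basis is almost
// perfectly conditioned for any reasonable W, which keeps the float
// Cholesky stable even when raw columns are near-collinear (age and
// squared age inside a narrow age stratum, say). eta is basis
// invariant; original-basis coefficients come back through R.
struct QBlock {
  arma::fmat Q;   // float orthonormal basis
  arma::mat R;    // double triangular factor
};

static QBlock qr_to_float(const arma::mat& X) {
  QBlock out;
  arma::mat Qd, Rd;
  arma::qr_econ(Qd, Rd, X);
  out.Q = arma::conv_to<arma::fmat>::from(Qd);
  out.R = Rd;
  return out;
}

// Newton step size is measured on eta (basis invariant); separation is
// flagged when the linear predictor runs away.
static bool irls_f32(const arma::fmat& Xs, const arma::fvec& y,
                     const arma::fvec& w, arma::fvec& beta, arma::fvec& eta,
                     int maxit = 8, float step_tol = 2e-3f) {
  if (beta.n_elem != Xs.n_cols) beta.zeros(Xs.n_cols);
  eta = Xs * beta;
  float last_step = 1e30f;
  for (int it = 1; it <= maxit; ++it) {
    arma::fvec mu = 1.0f / (1.0f + arma::exp(-eta));
    arma::fvec v = mu % (1.0f - mu);
    v.transform([](float x) { return x < 1e-6f ? 1e-6f : x; });
    arma::fvec W = w % v;
    arma::fvec score = Xs.t() * (w % (y - mu));
    arma::fmat Xh = Xs.each_col() % arma::sqrt(W);
    arma::fmat XtWX = Xh.t() * Xh;
    arma::fvec rhs = XtWX * beta + score;
    arma::fvec beta_new;
    if (!arma::solve(beta_new, XtWX, rhs, arma::solve_opts::likely_sympd))
      return false;
    last_step = arma::norm(beta_new - beta, "inf");
    beta = beta_new;
    eta = Xs * beta;
    if (arma::norm(eta, "inf") > 30.0f) return false; // separation drift
    if (last_step < step_tol) return true;
  }
  return last_step < 1e-2f; // accept a near-converged fit
}

static bool wls_f32(const arma::fmat& Xs, const arma::fvec& y,
                    const arma::fvec& w, arma::fvec& eta, float& sigma) {
  arma::fmat Xh = Xs.each_col() % arma::sqrt(w);
  arma::fmat XtWX = Xh.t() * Xh;
  arma::fvec rhs = Xs.t() * (w % y);
  arma::fvec beta;
  if (!arma::solve(beta, XtWX, rhs, arma::solve_opts::likely_sympd))
    return false;
  eta = Xs * beta;
  float wsum = arma::accu(w);
  float dfree = wsum - static_cast<float>(Xs.n_cols);
  if (dfree < 1.0f) dfree = 1.0f;
  sigma = std::sqrt(arma::accu(w % arma::square(y - eta)) / dfree);
  return true;
}

static inline arma::vec plogis_d(const arma::vec& eta) {
  return 1.0 / (1.0 + arma::exp(-eta));
}

struct ScaledDesign {
  arma::fmat X;
  arma::vec scales;
};

// Cluster (person-level) bootstrap of the full TE/CDE mediation
// estimator. draws: n_persons x B matrix of resampled person indices
// (0-based); person: 0-based person index per row of X. Each column of
// draws defines one replicate's frequency weights. Returns a B x 10
// matrix: te_rd, cde_rd, pct_mediation, or_te, or_cde, prev_unexp_te,
// prev_unexp_cde, paf_te, paf_cde, ok.
// [[Rcpp::export]]
NumericMatrix cpp_boot_mediation(
    const arma::mat& X, const arma::uvec& cols_den, const arma::uvec& cols_num,
    const arma::uvec& cols_te, const arma::uvec& cols_cde,
    const arma::uvec& cols_mden, const arma::uvec& cols_mnum,
    const arma::vec& a, const arma::vec& y, const arma::vec& m,
    int exp_te, int exp_cde, const arma::uvec& person, int n_persons,
    const IntegerMatrix& draws, const List& starts, int maxit = 20) {
  const int B = draws.ncol();
  const arma::uword n = X.n_rows;

  QBlock den = qr_to_float(X.cols(cols_den));
  QBlock num = qr_to_float(X.cols(cols_num));
  QBlock te = qr_to_float(X.cols(cols_te));
  QBlock cde = qr_to_float(X.cols(cols_cde));
  QBlock mden = qr_to_float(X.cols(cols_mden));
  QBlock mnum = qr_to_float(X.cols(cols_mnum));

  // warm starts, moved to the Q basis (beta_Q = R * beta)
  arma::fvec st_den = arma::conv_to<arma::fvec>::from(
      den.R * as<arma::vec>(starts["den"]));
  arma::fvec st_num = arma::conv_to<arma::fvec>::from(
      num.R * as<arma::vec>(starts["num"]));
  arma::fvec st_te = arma::conv_to<arma::fvec>::from(
      te.R * as<arma::vec>(starts["out_te"]));
  arma::fvec st_cde = arma::conv_to<arma::fvec>::from(
      cde.R * as<arma::vec>(starts["out_cde"]));

  arma::fvec af = arma::conv_to<arma::fvec>::from(a);
  arma::fvec yf = arma::conv_to<arma::fvec>::from(y);
  arma::fvec mf = arma::conv_to<arma::fvec>::from(m);
  arma::vec ad = a, yd = y;

  NumericMatrix out(B, 10);
  arma::vec mult(n_persons);
  arma::fvec w(n);

  for (int b = 0; b < B; ++b) {
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
    mult.zeros();
    for (int i = 0; i < draws.nrow(); ++i) mult(draws(i, b)) += 1.0;
    for (arma::uword r = 0; r < n; ++r)
      w(r) = static_cast<float>(mult(person(r)));

    for (int k = 0; k < 10; ++k) out(b, k) = NA_REAL;
    out(b, 9) = 0.0;

    arma::fvec beta_den = st_den, beta_num = st_num;
    arma::fvec eta_den, eta_num;
    if (!irls_f32(den.Q, af, w, beta_den, eta_den, maxit)) continue;
    if (!irls_f32(num.Q, af, w, beta_num, eta_num, maxit)) continue;
    arma::fvec mu_den = 1.0f / (1.0f + arma::exp(-eta_den));
    arma::fvec mu_num = 1.0f / (1.0f + arma::exp(-eta_num));
    arma::fvec sw_a = (af % mu_num + (1.0f - af) % (1.0f - mu_num)) /
                      (af % mu_den + (1.0f - af) % (1.0f - mu_den));

    // total effect
    arma::fvec w_te = w % sw_a;
    arma::fvec beta_te = st_te, eta_te;
    if (!irls_f32(te.Q, yf, w_te, beta_te, eta_te, maxit)) continue;
    arma::vec beta_te_orig = arma::solve(
        arma::trimatu(te.R), arma::conv_to<arma::vec>::from(beta_te));
    double bA = beta_te_orig(exp_te);
    arma::vec eta_te_d = arma::conv_to<arma::vec>::from(eta_te);
    arma::vec w_te_d = arma::conv_to<arma::vec>::from(w_te);
    double wsum = arma::accu(w_te_d);
    double r1 = arma::accu(w_te_d % plogis_d(eta_te_d + (1.0 - ad) * bA)) / wsum;
    double r0 = arma::accu(w_te_d % plogis_d(eta_te_d - ad * bA)) / wsum;
    double prev_tot = arma::accu(w_te_d % yd) / wsum;
    double te_rd = 100.0 * (r1 - r0);
    double or_te = (r1 / (1.0 - r1)) / (r0 / (1.0 - r0));
    double paf_te = 100.0 * (prev_tot - r0) / prev_tot;

    // mediator weights + controlled direct effect
    arma::fvec eta_md, eta_mn;
    float s_md, s_mn;
    if (!wls_f32(mden.Q, mf, w, eta_md, s_md)) continue;
    if (!wls_f32(mnum.Q, mf, w, eta_mn, s_mn)) continue;
    if (s_md < 1e-6f || s_mn < 1e-6f) continue;
    arma::fvec q = arma::square(mf - eta_md) / (2.0f * s_md * s_md) -
                   arma::square(mf - eta_mn) / (2.0f * s_mn * s_mn);
    arma::fvec sw_m = (s_md / s_mn) * arma::exp(q);
    arma::fvec w_cde = w_te % sw_m;
    arma::fvec beta_cde = st_cde, eta_cde;
    if (!irls_f32(cde.Q, yf, w_cde, beta_cde, eta_cde, maxit)) continue;
    arma::vec beta_cde_orig = arma::solve(
        arma::trimatu(cde.R), arma::conv_to<arma::vec>::from(beta_cde));
    double bA2 = beta_cde_orig(exp_cde);
    arma::vec eta_cde_d = arma::conv_to<arma::vec>::from(eta_cde);
    arma::vec w_cde_d = arma::conv_to<arma::vec>::from(w_cde);
    double wsumc = arma::accu(w_cde_d);
    double r1c = arma::accu(w_cde_d % plogis_d(eta_cde_d + (1.0 - ad) * bA2)) / wsumc;
    double r0c = arma::accu(w_cde_d % plogis_d(eta_cde_d - ad * bA2)) / wsumc;
    double prev_totc = arma::accu(w_cde_d % yd) / wsumc;
    double cde_rd = 100.0 * (r1c - r0c);

    out(b, 0) = te_rd;
    out(b, 1) = cde_rd;
    out(b, 2) = te_rd != 0.0 ? 100.0 * (te_rd - cde_rd) / te_rd : NA_REAL;
    out(b, 3) = or_te;
    out(b, 4) = (r1c / (1.0 - r1c)) / (r0c / (1.0 - r0c));
    out(b, 5) = 100.0 * r0;
    out(b, 6) = 100.0 * r0c;
    out(b, 7) = paf_te;
    out(b, 8) = 100.0 * (prev_totc - r0c) / prev_totc;
    out(b, 9) = 1.0;
  }
  colnames(out) = CharacterVector::create(
      "te_rd", "cde_rd", "pct_mediation", "or_te", "or_cde", "prev_unexp_te",
      "prev_unexp_cde", "paf_te", "paf_cde", "ok");
  return out;
}
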