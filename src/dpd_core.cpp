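// Core numerical kernels: intensity filters with analytic derivative
// recursions, per-observation density power divergence loss terms with
// their eta-derivatives, and the Brownian-bridge supremum simulator.
//
// Family codes: 1 = poisson, 2 = negbin (r known, counts failures),
//               3 = geometric counting total trials (support {1,2,...}).
// Form codes:   1 = ingarch11 (d,a,b), 2 = intgarch11 (d,a,b1,b2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double XCAP = 1e8;   // intensity clamp for runaway iterates

// conditional mean x -> (B' , B'') of the family, in mean parametrisation
static inline void bderivs(double x, int fam, double r,
                           double &Bp, double &Bpp) {
  if (fam == 1) {            // poisson: B = B' = B'' = e^eta = x
    Bp = x; Bpp = x;
  } else if (fam == 2) {     // negbin: q = x/(x+r)
    Bp  = x * (x + r) / r;
    Bpp = x * (2.0 * x + r) * (x + r) / (r * r);
  } else {                   // geometric trials: p = 1/x, x > 1
    Bp  = x * (x - 1.0);
    Bpp = x * (x - 1.0) * (2.0 * x - 1.0);
  }
}

static inline double logpmf(int yv, double x, int fam, double r) {
  if (fam == 1) return R::dpois(yv, x, 1);
  if (fam == 2) return R::dnbinom(yv, r, r / (r + x), 1);
  double p = 1.0 / x;        // geometric trials at mean x
  if (yv < 1) return R_NegInf;
  return std::log(p) + (yv - 1.0) * std::log1p(-p);
}

struct LossTerm {
  double loss, u, w;   // loss value, d loss / d x, d^2 loss / d x^2
  bool trunc_fail;
};

// Per-observation DPD loss and its first two derivatives in the
// conditional mean x.  For alpha > 0 the sum over the support is either
// closed form (geometric) or adaptively truncated (poisson / negbin).
static LossTerm dpd_term(int yv, double x, double alpha, int fam, double r,
                         double tol, bool closed_form) {
  LossTerm out; out.trunc_fail = false;
  double Bp, Bpp;
  bderivs(x, fam, r, Bp, Bpp);
  const double mu = x;
  const double lp = logpmf(yv, x, fam, r);

  double lpe, lppe;  // d loss / d eta, d^2 loss / d eta^2
  if (alpha == 0.0) {
    out.loss = -lp;
    lpe  = mu - yv;
    lppe = Bp;
  } else {
    double S = 0.0, T1 = 0.0, T2 = 0.0;  // sum p^{1+a}, and (y-mu)-moments
    if (fam == 3 && closed_form) {
      const double p  = 1.0 / x;
      const double s  = std::exp((1.0 + alpha) * std::log(p));
      const double q1 = std::exp((1.0 + alpha) * std::log1p(-p));
      const double om = 1.0 - q1;
      const double M0 = s / om;
      const double M1 = s / (om * om);            // sum p^{1+a} y
      const double M2 = s * (1.0 + q1) / (om * om * om);  // sum p^{1+a} y^2
      S  = M0;
      T1 = M1 - mu * M0;
      T2 = M2 - 2.0 * mu * M1 + mu * mu * M0;
    } else {
      // adaptive truncation over the support
      double var;
      int ymin;
      double psucc = 0.0;
      if (fam == 1)      { var = x;                     ymin = 0; }
      else if (fam == 2) { var = x * (1.0 + x / r);     ymin = 0;
                           psucc = r / (r + x); }
      else               { var = x * (x - 1.0);         ymin = 1;
                           psucc = 1.0 / x; }
      const double sd = std::sqrt(var);
      int ylo = ymin;
      if (mu > 60.0) {
        ylo = (int) std::floor(mu - 10.0 * sd - 30.0);
        if (ylo < ymin) ylo = ymin;
      }
      const double yhi = mu + 50.0 * sd + 100.0;
      double p  = std::exp(logpmf(ylo, x, fam, r));
      double mass = 0.0;
      int yy = ylo;
      for (;;) {
        const double p1a = p * std::pow(p, alpha);
        const double dev = yy - mu;
        S  += p1a;
        T1 += p1a * dev;
        T2 += p1a * dev * dev;
        mass += p;
        if (yy > mu && mass > 1.0 - tol && p1a < tol * S) break;
        if (yy > yhi) { out.trunc_fail = true; break; }
        // pmf recursion p(y+1)/p(y)
        if (fam == 1)      p *= x / (yy + 1.0);
        else if (fam == 2) p *= (yy + r) / (yy + 1.0) * (1.0 - psucc);
        else               p *= (1.0 - psucc);
        ++yy;
        if (p <= 0.0) break;
      }
    }
    const double pYa = std::exp(alpha * lp);
    const double dev = yv - mu;
    out.loss = S - (1.0 + 1.0 / alpha) * pYa;
    lpe  = (1.0 + alpha) * (T1 - pYa * dev);
    lppe = (1.0 + alpha) * ((1.0 + alpha) * T2 - Bp * S
                            - alpha * pYa * dev * dev + pYa * Bp);
  }
  out.u = lpe / Bp;
  out.w = lppe / (Bp * Bp) - lpe * Bpp / (Bp * Bp * Bp);
  return out;
}

// Scalar loss term (and d/d eta) used by the R-level dpd_loss_term().
// [[Rcpp::export]]
List dpd_term_cpp(int y, double x, double alpha, int fam, double r,
                  double tol, bool closed_form) {
  LossTerm lt = dpd_term(y, x, alpha, fam, r, tol, closed_form);
  double Bp, Bpp;
  bderivs(x, fam, r, Bp, Bpp);
  return List::create(_["loss"] = lt.loss,
                      _["dloss_deta"] = lt.u * Bp,
                      _["dloss_dx"] = lt.u,
                      _["trunc_fail"] = lt.trunc_fail);
}

// Intensity filter with optional gradient / Hessian recursions.
// order: 0 = x only, 1 = + grad, 2 = + hess.
// [[Rcpp::export]]
List ingarch_filter_cpp(IntegerVector y, NumericVector theta, int form,
                        int l, double x_init, int order) {
  const int n = y.size();
  const int d = theta.size();
  arma::vec th(theta.begin(), d);
  arma::vec x(n);
  arma::mat G;
  arma::cube H;
  if (order >= 1) G.zeros(n, d);
  if (order >= 2) H.zeros(d, d, n);

  arma::vec g(d, arma::fill::zeros), gprev(d, arma::fill::zeros);
  arma::mat Hm(d, d, arma::fill::zeros), Hprev(d, d, arma::fill::zeros);
  arma::vec z(d);
  x(0) = x_init;
  for (int t = 1; t < n; ++t) {
    const double yp = (double) y[t - 1];
    z(0) = 1.0; z(1) = x(t - 1);
    if (form == 1) z(2) = yp;
    else { z(2) = std::max(yp - l, 0.0); z(3) = std::min(yp, (double) l); }
    double xt = arma::dot(th, z);
    bool clamp = false;
    if (xt > XCAP) { xt = XCAP; clamp = true; }
    x(t) = xt;
    if (order >= 1) {
      g = z + th(1) * gprev;
      if (clamp) g.zeros();
      G.row(t) = g.t();
      if (order >= 2) {
        Hm = th(1) * Hprev;
        Hm.col(1) += gprev;
        Hm.row(1) += gprev.t();
        if (clamp) Hm.zeros();
        H.slice(t) = Hm;
        Hprev = Hm;
      }
      gprev = g;
    }
  }
  List out = List::create(_["x"] = x);
  if (order >= 1) out["grad"] = G;
  if (order >= 2) out["hess"] = H;
  return out;
}

// One-pass bundle: objective, per-t score rows, mean loss Hessian.
// order: 0 = value only, 1 = + n x d score matrix, 2 = + J (mean Hessian).
// [[Rcpp::export]]
List dpd_bundle_cpp(IntegerVector y, NumericVector theta, double alpha,
                    int fam, double r, int form, int l, double x_init,
                    int order, double tol, bool closed_form) {
  const int n = y.size();
  const int d = theta.size();
  arma::vec th(theta.begin(), d);
  arma::mat G;
  if (order >= 1) G.zeros(n, d);
  arma::mat J(d, d, arma::fill::zeros);
  arma::vec xs(n);

  arma::vec g(d, arma::fill::zeros), gprev(d, arma::fill::zeros);
  arma::mat Hm(d, d, arma::fill::zeros), Hprev(d, d, arma::fill::zeros);
  arma::vec z(d, arma::fill::zeros);
  double value = 0.0;
  bool tfail = false;
  double xprev = x_init;
  for (int t = 0; t < n; ++t) {
    double xt;
    if (t == 0) {
      xt = x_init;
      g.zeros();
      Hm.zeros();
    } else {
      const double yp = (double) y[t - 1];
      z(0) = 1.0; z(1) = xprev;
      if (form == 1) z(2) = yp;
      else { z(2) = std::max(yp - l, 0.0); z(3) = std::min(yp, (double) l); }
      xt = arma::dot(th, z);
      bool clamp = false;
      if (xt > XCAP) { xt = XCAP; clamp = true; }
      g = z + th(1) * gprev;
      Hm = th(1) * Hprev;
      Hm.col(1) += gprev;
      Hm.row(1) += gprev.t();
      if (clamp) { g.zeros(); Hm.zeros(); }
    }
    xs(t) = xt;
    double xeff = xt;
    bool floored = false;
    if (fam == 3 && xeff < 1.0 + 1e-8) { xeff = 1.0 + 1e-8; floored = true; }
    LossTerm lt = dpd_term(y[t], xeff, alpha, fam, r, tol, closed_form);
    if (lt.trunc_fail) tfail = true;
    if (floored) { lt.u = 0.0; lt.w = 0.0; }  // flat in the clamped zone
    value += lt.loss;
    if (order >= 1) G.row(t) = lt.u * g.t();
    if (order >= 2) {
      J += lt.w * (g * g.t()) + lt.u * Hm;
    }
    xprev = xt;
    gprev = g;
    Hprev = Hm;
  }
  value /= n;
  List out = List::create(_["value"] = value, _["x"] = xs,
                          _["trunc_fail"] = tfail);
  if (order >= 1) out["score"] = G;
  if (order >= 2) out["J"] = J / n;
  return out;
}

// Supremum over [0,1] of the squared norm of a dim-dimensional standard
// Brownian bridge, one value per replicate.  Uses R's RNG (set.seed).
// [[Rcpp::export]]
NumericVector bb_sup_cpp(int dim, int grid, int reps) {
  NumericVector out(reps);
  std::vector<double> W((size_t) dim * grid);
  const double sc = 1.0 / std::sqrt((double) grid);
  for (int rep = 0; rep < reps; ++rep) {
    for (int j = 0; j < dim; ++j) {
      double s = 0.0;
      double *wj = &W[(size_t) j * grid];
      for (int i = 0; i < grid; ++i) {
        s += norm_rand() * sc;
        wj[i] = s;
      }
    }
    double mx = 0.0;
    for (int i = 0; i < grid; ++i) {
      const double frac = (double) (i + 1) / grid;
      double ss = 0.0;
      for (int j = 0; j < dim; ++j) {
        const double *wj = &W[(size_t) j * grid];
        const double b = wj[i] - frac * wj[grid - 1];
        ss += b * b;
      }
      if (ss > mx) mx = ss;
    }
    out[rep] = mx;
  }
  return out;
}
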