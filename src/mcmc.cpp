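// Gibbs-within-Metropolis sampler for the multilevel multivariate mixed
// model with a Student-t observation level:
//
//   Y = X B + Z U + E,   rows of E ~ multivariate-t_p(0, Sigma_e, nu)
//
// U stacks crossed Gaussian random intercepts for specimen and lot, each
// with its own scale/correlation decomposition Sigma = D * Omega * D.
// Priors: B ~ N(0, sd_b^2) elementwise, D diagonals ~ half-Cauchy(c_scale),
// Omega ~ LKJ(eta), nu ~ Gamma(nu_shape, nu_rate) truncated at nu > 2.
//
// Sampler design, in the service of good mixing:
//  * the t likelihood is handled by its Gamma scale-mixture representation
//    (per-row weights w), making B, U and w conjugate Gibbs updates;
//  * random-effect scale parameters are updated with their U block
//    integrated out (the group marginal is Gaussian given w), after which
//    U is redrawn — a collapsed update that avoids the usual scale/effect
//    funnel;
//  * scalar scales and nu move by univariate slice sampling on log
//    coordinates; correlation matrices move by adaptive random-walk
//    Metropolis on their off-diagonals with positive-definite rejection
//    (adaptation during warmup only, so post-warmup draws target the
//    exact posterior);
//  * interweaving moves resample likelihood-invariant translations:
//    intercept vs. random-intercept means, and each lot effect vs. its
//    member specimens' effects (the variance-exchange direction between
//    the two crossed factors).
// R's RNG is used throughout, so set.seed() on the R side governs the run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::cube;

static double rnorm1() { return R::rnorm(0.0, 1.0); }

static vec randn_vec(int p) {
  vec z(p);
  for (int j = 0; j < p; ++j) z[j] = rnorm1();
  return z;
}

static vec mvn_from_precision(const vec& rhs, const mat& prec) {
  // sample x ~ N(prec^{-1} rhs, prec^{-1})
  mat Rch = arma::chol(prec);               // upper: prec = Rch' Rch
  vec mu = arma::solve(prec, rhs);
  return mu + arma::solve(arma::trimatu(Rch), randn_vec(rhs.n_elem));
}

// weighted Gaussian log-likelihood of rows V (m x p) with covariance
// Sigma / w_i  (w = 1 for random effects)
static double gauss_loglik(const mat& V, const vec& w, const mat& Sigma) {
  mat L;
  if (!arma::chol(L, Sigma, "lower")) return -arma::datum::inf;
  double ldet = 2.0 * arma::sum(arma::log(L.diag()));
  mat S = arma::solve(arma::trimatl(L), V.t()); // p x m
  vec q = arma::sum(arma::square(S), 0).t();
  double p = (double)V.n_cols;
  return -0.5 * V.n_rows * ldet + 0.5 * p * arma::sum(arma::log(w)) -
         0.5 * arma::dot(w, q);
}

// log-likelihood of a random-effect scale matrix SigU with the group
// effects integrated out: per group g the residual rows are
// N(u_g, SigE / w_i) with u_g ~ N(0, SigU). Given the per-group weight
// sums sw and weighted residual sums sr (rows of length p), the terms of
// the Gaussian marginal that depend on SigU are
//   -1/2 log|SigU| - 1/2 log|A_g| + 1/2 m_g' A_g^{-1} m_g,
// with A_g = sw_g SigEinv + SigU^{-1}, m_g = SigEinv sr_g.
static double marginal_re_loglik(const mat& SigU, const mat& SigEinv,
                                 const vec& sw, const mat& sr) {
  mat SigUinv;
  if (!arma::inv_sympd(SigUinv, SigU)) return -arma::datum::inf;
  double sign, ldU;
  arma::log_det(ldU, sign, SigU);
  if (sign <= 0) return -arma::datum::inf;
  double tot = 0.0;
  for (arma::uword g = 0; g < sw.n_elem; ++g) {
    mat A = sw[g] * SigEinv + SigUinv;
    double ldA;
    arma::log_det(ldA, sign, A);
    if (sign <= 0) return -arma::datum::inf;
    vec m = SigEinv * sr.row(g).t();
    tot += -0.5 * ldU - 0.5 * ldA + 0.5 * arma::dot(m, arma::solve(A, m));
  }
  return tot;
}

static mat make_sigma(const vec& d, const mat& O) {
  return arma::diagmat(d) * O * arma::diagmat(d);
}

static double log_half_cauchy(const vec& d, double scale) {
  double s = 0.0;
  for (arma::uword j = 0; j < d.n_elem; ++j)
    s += -std::log1p((d[j] / scale) * (d[j] / scale));
  return s;
}

static double lkj_logdens(const mat& O, double eta) {
  double sign, val;
  if (!arma::log_det(val, sign, O) || sign <= 0) return -arma::datum::inf;
  return (eta - 1.0) * val;
}

// log p(nu | w) up to a constant: truncated Gamma prior + Gamma mixture
static double nu_logpost(double nu, const vec& w, double shape, double rate) {
  if (nu <= 2.0) return -arma::datum::inf;
  double n = (double)w.n_elem;
  double h = nu / 2.0;
  double s = (shape - 1.0) * std::log(nu) - rate * nu;
  s += n * (h * std::log(h) - std::lgamma(h));
  s += (h - 1.0) * arma::sum(arma::log(w)) - h * arma::sum(w);
  return s;
}

// symmetric off-diagonal random-walk proposal for a correlation matrix
static mat propose_corr(const mat& O, double step) {
  mat prop = O;
  for (arma::uword a = 0; a < O.n_rows; ++a)
    for (arma::uword b = a + 1; b < O.n_cols; ++b) {
      double v = O(a, b) + step * rnorm1();
      prop(a, b) = v;
      prop(b, a) = v;
    }
  return prop;
}

// univariate slice sampler (Neal 2003: stepping out + shrinkage) on an
// unbounded coordinate; logf is the log target up to a constant
template <class F>
static double slice_1d(const F& logf, double x0, double w0, int max_steps) {
  double f0 = logf(x0);
  double y = f0 - R::rexp(1.0);
  double u = R::runif(0.0, 1.0);
  double L = x0 - w0 * u, Rr = L + w0;
  int j = (int)std::floor(R::runif(0.0, 1.0) * max_steps);
  int k2 = max_steps - 1 - j;
  while (j-- > 0 && logf(L) > y) L -= w0;
  while (k2-- > 0 && logf(Rr) > y) Rr += w0;
  for (int tries = 0; tries < 100; ++tries) {
    double x1 = R::runif(0.0, 1.0) * (Rr - L) + L;
    if (logf(x1) > y) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

struct AdaptStep {
  double ls;      // log step size
  int n_acc, n_try;
  AdaptStep(double s0) : ls(std::log(s0)), n_acc(0), n_try(0) {}
  double step() const { return std::exp(ls); }
  void update(bool acc, int iter, bool adapting, double target) {
    ++n_try; if (acc) ++n_acc;
    if (adapting) ls += (1.0 / std::sqrt((double)iter + 1.0)) *
                        ((acc ? 1.0 : 0.0) - target);
  }
};

// [[Rcpp::export]]
List fit_mcmc_cpp(const arma::mat& Y, const arma::mat& X,
                  const arma::ivec& spec_idx, const arma::ivec& lot_idx,
                  int n_spec, int n_lot,
                  int n_warmup, int n_save,
                  double sd_b, double c_scale, double lkj_eta,
                  double nu_shape, double nu_rate) {
  const int n = Y.n_rows, p = Y.n_cols, k = X.n_cols;
  const uvec sidx = arma::conv_to<uvec>::from(spec_idx);
  const uvec lidx = arma::conv_to<uvec>::from(lot_idx);
  // lot membership of each specimen (the crossed design assigns every
  // specimen to exactly one lot)
  std::vector<int> lot_of_spec(n_spec, 0);
  for (int i = 0; i < n; ++i) lot_of_spec[spec_idx[i]] = lot_idx[i];
  std::vector<std::vector<int>> specs_in_lot(n_lot);
  for (int g = 0; g < n_spec; ++g) specs_in_lot[lot_of_spec[g]].push_back(g);

  // ---- initial state -------------------------------------------------
  mat XtX0 = X.t() * X;
  XtX0.diag() += 1e-8 * arma::trace(XtX0) / k + 1e-12;
  mat B = arma::solve(XtX0, X.t() * Y);
  mat Us(n_spec, p, arma::fill::zeros), Ul(n_lot, p, arma::fill::zeros);
  mat resid0 = Y - X * B;
  // method-of-moments start for the variance decomposition: group means
  // of the OLS residuals estimate the random-intercept scales
  mat sm(n_spec, p, arma::fill::zeros);
  vec sn(n_spec, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    sm.row(spec_idx[i]) += resid0.row(i);
    sn[spec_idx[i]] += 1.0;
  }
  sm.each_col() /= sn;
  mat resid1 = resid0 - sm.rows(arma::conv_to<uvec>::from(spec_idx));
  mat lm(n_lot, p, arma::fill::zeros);
  vec ln(n_lot, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    lm.row(lot_idx[i]) += resid1.row(i);
    ln[lot_idx[i]] += 1.0;
  }
  lm.each_col() /= ln;
  mat resid2 = resid1 - lm.rows(arma::conv_to<uvec>::from(lot_idx));
  vec ds = arma::stddev(sm, 0, 0).t();
  vec dl = arma::stddev(lm, 0, 0).t();
  vec de = arma::stddev(resid2, 0, 0).t();
  ds.elem(arma::find(ds < 0.05)).fill(0.05);
  dl.elem(arma::find(dl < 0.05)).fill(0.05);
  de.elem(arma::find(de < 1e-3)).fill(1e-3);
  mat Os(p, p, arma::fill::eye), Ol(p, p, arma::fill::eye),
      Oe(p, p, arma::fill::eye);
  double nu = 10.0;
  vec w(n, arma::fill::ones);

  // ---- storage -------------------------------------------------------
  cube B_dr(k, p, n_save), Us_dr(n_spec, p, n_save), Ul_dr(n_lot, p, n_save);
  mat ds_dr(n_save, p), dl_dr(n_save, p), de_dr(n_save, p);
  cube Os_dr(p, p, n_save), Ol_dr(p, p, n_save), Oe_dr(p, p, n_save);
  vec nu_dr(n_save);

  AdaptStep st_os(0.15), st_ol(0.25), st_oe(0.05);
  const double tgt = 0.3;
  const int n_rep = 5;   // Metropolis sweeps per Gibbs iteration

  const int n_iter = n_warmup + n_save;
  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_warmup;
    mat SigE = make_sigma(de, Oe);
    mat SigEinv = arma::inv_sympd(SigE);

    // ---- w | rest ----------------------------------------------------
    {
      mat R0 = Y - X * B - Us.rows(sidx) - Ul.rows(lidx);
      mat S = R0 * SigEinv;        // n x p
      vec q = arma::sum(S % R0, 1);
      for (int i = 0; i < n; ++i)
        w[i] = R::rgamma((nu + p) / 2.0, 2.0 / (nu + q[i]));
    }

    // ---- B | rest (matrix-normal Gibbs) -------------------------------
    {
      mat Ystar = Y - Us.rows(sidx) - Ul.rows(lidx);
      mat Xw = X.each_col() % w;
      mat XtWX = X.t() * Xw;
      mat prec = arma::kron(SigEinv, XtWX);
      prec.diag() += 1.0 / (sd_b * sd_b);
      vec rhs = arma::vectorise(Xw.t() * Ystar * SigEinv);
      B = arma::reshape(mvn_from_precision(rhs, prec), k, p);
    }

    // ---- specimen block: (D, Omega) with U_spec marginalised, then U --
    {
      mat r2 = Y - X * B - Ul.rows(lidx);
      mat sr(n_spec, p, arma::fill::zeros);
      vec sw(n_spec, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        sr.row(spec_idx[i]) += w[i] * r2.row(i);
        sw[spec_idx[i]] += w[i];
      }
      for (int j = 0; j < p; ++j) {
        vec dloc = ds;
        auto logf = [&](double t) {
          dloc[j] = std::exp(t);
          return marginal_re_loglik(make_sigma(dloc, Os), SigEinv, sw, sr) +
                 log_half_cauchy(dloc, c_scale) + t;
        };
        ds[j] = std::exp(slice_1d(logf, std::log(ds[j]), 1.0, 8));
      }
      for (int rep = 0; rep < n_rep; ++rep) {
        {
          mat prop = propose_corr(Os, st_os.step());
          double ld = lkj_logdens(prop, lkj_eta);
          bool acc = false;
          if (std::isfinite(ld)) {
            double la =
              marginal_re_loglik(make_sigma(ds, prop), SigEinv, sw, sr) -
              marginal_re_loglik(make_sigma(ds, Os), SigEinv, sw, sr) +
              ld - lkj_logdens(Os, lkj_eta);
            acc = std::log(R::runif(0, 1)) < la;
          }
          if (acc) Os = prop;
          st_os.update(acc, it, adapting, tgt);
        }
      }
      mat SigSinv = arma::inv_sympd(make_sigma(ds, Os));
      for (int g = 0; g < n_spec; ++g) {
        mat prec = SigSinv + sw[g] * SigEinv;
        Us.row(g) = mvn_from_precision(SigEinv * sr.row(g).t(), prec).t();
      }
    }

    // ---- lot block, same construction ---------------------------------
    {
      mat r3 = Y - X * B - Us.rows(sidx);
      mat lr(n_lot, p, arma::fill::zeros);
      vec lw(n_lot, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        lr.row(lot_idx[i]) += w[i] * r3.row(i);
        lw[lot_idx[i]] += w[i];
      }
      for (int j = 0; j < p; ++j) {
        vec dloc = dl;
        auto logf = [&](double t) {
          dloc[j] = std::exp(t);
          return marginal_re_loglik(make_sigma(dloc, Ol), SigEinv, lw, lr) +
                 log_half_cauchy(dloc, c_scale) + t;
        };
        dl[j] = std::exp(slice_1d(logf, std::log(dl[j]), 1.5, 8));
      }
      for (int rep = 0; rep < n_rep; ++rep) {
        {
          mat prop = propose_corr(Ol, st_ol.step());
          double ld = lkj_logdens(prop, lkj_eta);
          bool acc = false;
          if (std::isfinite(ld)) {
            double la =
              marginal_re_loglik(make_sigma(dl, prop), SigEinv, lw, lr) -
              marginal_re_loglik(make_sigma(dl, Ol), SigEinv, lw, lr) +
              ld - lkj_logdens(Ol, lkj_eta);
            acc = std::log(R::runif(0, 1)) < la;
          }
          if (acc) Ol = prop;
          st_ol.update(acc, it, adapting, tgt);
        }
      }
      mat SigLinv = arma::inv_sympd(make_sigma(dl, Ol));
      for (int g = 0; g < n_lot; ++g) {
        mat prec = SigLinv + lw[g] * SigEinv;
        Ul.row(g) = mvn_from_precision(SigEinv * lr.row(g).t(), prec).t();
      }
    }

    // ---- interweaving: resample the common location shared by the
    // intercept row of B and the random-intercept means (the likelihood
    // is invariant under the shift when X's first column is all ones)
    if (arma::all(arma::abs(X.col(0) - 1.0) < 1e-12)) {
      mat SigSinv = arma::inv_sympd(make_sigma(ds, Os));
      mat SigLinv = arma::inv_sympd(make_sigma(dl, Ol));
      {
        mat prec = (double)n_spec * SigSinv;
        prec.diag() += 1.0 / (sd_b * sd_b);
        vec rhs = SigSinv * arma::sum(Us, 0).t() -
                  B.row(0).t() / (sd_b * sd_b);
        vec delta = mvn_from_precision(rhs, prec);
        B.row(0) += delta.t();
        Us.each_row() -= delta.t();
      }
      {
        mat prec = (double)n_lot * SigLinv;
        prec.diag() += 1.0 / (sd_b * sd_b);
        vec rhs = SigLinv * arma::sum(Ul, 0).t() -
                  B.row(0).t() / (sd_b * sd_b);
        vec delta = mvn_from_precision(rhs, prec);
        B.row(0) += delta.t();
        Ul.each_row() -= delta.t();
      }
      // per-lot interweaving: a shift between a lot's effect and the
      // effects of its member specimens also leaves the likelihood
      // unchanged; resampling it from the priors' conditional moves
      // variance freely between the two grouping factors
      for (int g = 0; g < n_lot; ++g) {
        const std::vector<int>& mem = specs_in_lot[g];
        if (mem.empty()) continue;
        mat prec = (double)mem.size() * SigSinv + SigLinv;
        vec su(p, arma::fill::zeros);
        for (int sidx2 : mem) su += Us.row(sidx2).t();
        vec rhs = SigSinv * su - SigLinv * Ul.row(g).t();
        vec delta = mvn_from_precision(rhs, prec);
        Ul.row(g) += delta.t();
        for (int sidx2 : mem) Us.row(sidx2) -= delta.t();
      }
    }

    // ---- error scale/correlation and nu -------------------------------
    {
      mat R1 = Y - X * B - Us.rows(sidx) - Ul.rows(lidx);
      for (int j = 0; j < p; ++j) {
        vec dloc = de;
        auto logf = [&](double t) {
          dloc[j] = std::exp(t);
          return gauss_loglik(R1, w, make_sigma(dloc, Oe)) +
                 log_half_cauchy(dloc, c_scale) + t;
        };
        de[j] = std::exp(slice_1d(logf, std::log(de[j]), 0.3, 8));
      }
      {
        auto logf = [&](double t) {
          return nu_logpost(2.0 + std::exp(t), w, nu_shape, nu_rate) + t;
        };
        nu = 2.0 + std::exp(slice_1d(logf, std::log(nu - 2.0), 1.0, 8));
      }
      for (int rep = 0; rep < n_rep; ++rep) {
        {
          mat prop = propose_corr(Oe, st_oe.step());
          double ld = lkj_logdens(prop, lkj_eta);
          bool acc = false;
          if (std::isfinite(ld)) {
            double la = gauss_loglik(R1, w, make_sigma(de, prop)) -
                        gauss_loglik(R1, w, make_sigma(de, Oe)) +
                        ld - lkj_logdens(Oe, lkj_eta);
            acc = std::log(R::runif(0, 1)) < la;
          }
          if (acc) Oe = prop;
          st_oe.update(acc, it, adapting, tgt);
        }
      }
    }

    // ---- store ---------------------------------------------------------
    if (it >= n_warmup) {
      int s = it - n_warmup;
      B_dr.slice(s) = B;
      Us_dr.slice(s) = Us;
      Ul_dr.slice(s) = Ul;
      ds_dr.row(s) = ds.t(); dl_dr.row(s) = dl.t(); de_dr.row(s) = de.t();
      Os_dr.slice(s) = Os; Ol_dr.slice(s) = Ol; Oe_dr.slice(s) = Oe;
      nu_dr[s] = nu;
    }
  }

  // d and nu updates are slice moves (always accepted); only the
  // correlation-matrix random walks have acceptance rates to report
  NumericVector acc = NumericVector::create(
      _["d_spec"] = 1.0,
      _["omega_spec"] = (double)st_os.n_acc / st_os.n_try,
      _["d_lot"] = 1.0,
      _["omega_lot"] = (double)st_ol.n_acc / st_ol.n_try,
      _["d_err"] = 1.0,
      _["omega_err"] = (double)st_oe.n_acc / st_oe.n_try,
      _["nu"] = 1.0);

  return List::create(
      _["B"] = B_dr, _["U_spec"] = Us_dr, _["U_lot"] = Ul_dr,
      _["d_spec"] = ds_dr, _["d_lot"] = dl_dr, _["d_err"] = de_dr,
      _["omega_spec"] = Os_dr, _["omega_lot"] = Ol_dr, _["omega_err"] = Oe_dr,
      _["nu"] = nu_dr, _["acceptance"] = acc);
}
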