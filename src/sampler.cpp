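// Adaptive Metropolis-within-Gibbs sampler for negative binomial areal
// models with optional ICAR random effects / spatially varying
// coefficients.
//
// Blocks per iteration:
//   * fixed effects beta: per-coordinate adaptive random walk during the
//     first part of burn-in, then a joint random-walk proposal using the
//     empirical posterior covariance (Haario-style adaptive Metropolis,
//     target acceptance ~0.23; per-coordinate target ~0.44);
//   * each ICAR field: single-site random-walk Metropolis with the ICAR
//     full-conditional prior term in the acceptance ratio, followed by
//     per-component recentring (sum-to-zero constraint);
//   * each field precision tau: random walk on log(tau) against the
//     PC (type-2 Gumbel) prior and the ICAR quadratic form, rank n - c;
//   * NB dispersion k: random walk on log(k) against a Gamma prior.
// All proposal scales adapt in batches of 50 during burn-in only, so the
// post-burn-in kernel satisfies detailed balance.  Uses R's RNG, so runs
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double nb_ll(double y, double eta, double k) {
  if (eta > 50.0 || !std::isfinite(eta)) return -1e300;  // mu absurdly large
  double mu = std::exp(eta);
  return R::lgammafn(y + k) - R::lgammafn(k) - R::lgammafn(y + 1.0) +
         k * std::log(k / (k + mu)) + y * (eta - std::log(k + mu));
}

static inline double adapt_step(int batch) {
  double d = 1.0 / std::sqrt((double)batch);
  return d < 0.25 ? d : 0.25;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericVector y, NumericMatrix X, NumericMatrix FX,
                   List nb, IntegerVector comp, int ncomp,
                   double pc_lambda, double fixed_var,
                   double disp_shape, double disp_rate,
                   int n_iter, int n_burnin, int thin,
                   NumericVector beta_init, double k_init, double tau_init,
                   bool update_k) {
  const int n = y.size();
  const int P = X.ncol();
  const int nf = FX.ncol();  // number of ICAR fields (0, 1 or P)

  // neighbour structure
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    nbr[i].assign(v.begin(), v.end());
    for (size_t t = 0; t < nbr[i].size(); ++t) nbr[i][t] -= 1;  // 0-based
  }
  std::vector<int> cmp(comp.begin(), comp.end());  // 1-based labels
  std::vector<int> csize(ncomp, 0);
  for (int i = 0; i < n; ++i) csize[cmp[i] - 1]++;

  // state
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<std::vector<double>> fld(nf, std::vector<double>(n, 0.0));
  std::vector<double> tau(nf, tau_init);
  double k = k_init;

  // linear predictor
  std::vector<double> eta(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int p = 0; p < P; ++p) e += beta[p] * X(i, p);
    eta[i] = e;
  }

  // proposal scales
  std::vector<double> s_beta(P);
  for (int p = 0; p < P; ++p) {
    double m = 0.0, m2 = 0.0;
    for (int i = 0; i < n; ++i) { m += X(i, p); m2 += X(i, p) * X(i, p); }
    m /= n; m2 = m2 / n - m * m;
    double sdx = m2 > 0 ? std::sqrt(m2) : 1.0;
    s_beta[p] = 0.1 / sdx;
  }
  std::vector<double> s_fld(nf, 0.1), s_tau(nf, 0.5), s_scl(nf, 0.5);
  double s_k = 0.3, s_joint = 1.0;

  // adaptive joint proposal for beta
  std::vector<double> bmean(P, 0.0);
  std::vector<std::vector<double>> bcov(P, std::vector<double>(P, 0.0));
  std::vector<std::vector<double>> chol(P, std::vector<double>(P, 0.0));
  bool have_chol = false;
  int cov_n = 0;
  const int joint_start = std::min(n_burnin / 2, 1000);

  // acceptance bookkeeping
  std::vector<int> acc_beta(P, 0), try_beta(P, 0);
  std::vector<int> acc_fld(nf, 0), try_fld(nf, 0);
  std::vector<int> acc_tau(nf, 0), try_tau(nf, 0);
  std::vector<int> acc_scl(nf, 0), try_scl(nf, 0);
  int acc_k = 0, try_k = 0, acc_joint = 0, try_joint = 0;
  std::vector<int> b_acc_beta(P, 0), b_try_beta(P, 0);
  std::vector<int> b_acc_fld(nf, 0), b_try_fld(nf, 0);
  std::vector<int> b_acc_tau(nf, 0), b_try_tau(nf, 0);
  std::vector<int> b_acc_scl(nf, 0), b_try_scl(nf, 0);
  int b_acc_k = 0, b_try_k = 0, b_acc_joint = 0, b_try_joint = 0;
  int batch = 0;

  // storage
  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix out_beta(n_keep, P);
  NumericMatrix out_tau(n_keep, std::max(nf, 1));
  NumericVector out_k(n_keep);
  std::vector<NumericMatrix> out_fld;
  for (int f = 0; f < nf; ++f) out_fld.push_back(NumericMatrix(n_keep, n));
  int keep = 0;

  RNGScope scope;

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_burnin;
    const bool joint_ok = have_chol && it > joint_start;

    // ---- fixed effects ----
    if (!joint_ok) {
      for (int p = 0; p < P; ++p) {
        double delta = s_beta[p] * norm_rand();
        double d = 0.0;
        for (int i = 0; i < n; ++i)
          d += nb_ll(y[i], eta[i] + delta * X(i, p), k) -
               nb_ll(y[i], eta[i], k);
        double bn = beta[p] + delta;
        d += -0.5 * (bn * bn - beta[p] * beta[p]) / fixed_var;
        ++try_beta[p]; ++b_try_beta[p];
        if (std::log(unif_rand()) < d) {
          beta[p] = bn;
          for (int i = 0; i < n; ++i) eta[i] += delta * X(i, p);
          ++acc_beta[p]; ++b_acc_beta[p];
        }
      }
    } else {
      std::vector<double> z(P), delta(P, 0.0);
      for (int p = 0; p < P; ++p) z[p] = norm_rand();
      for (int p = 0; p < P; ++p) {
        double v = 0.0;
        for (int q = 0; q <= p; ++q) v += chol[p][q] * z[q];
        delta[p] = s_joint * v;
      }
      double d = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = 0.0;
        for (int p = 0; p < P; ++p) de += delta[p] * X(i, p);
        d += nb_ll(y[i], eta[i] + de, k) - nb_ll(y[i], eta[i], k);
      }
      for (int p = 0; p < P; ++p) {
        double bn = beta[p] + delta[p];
        d += -0.5 * (bn * bn - beta[p] * beta[p]) / fixed_var;
      }
      ++try_joint; ++b_try_joint;
      if (std::log(unif_rand()) < d) {
        for (int p = 0; p < P; ++p) beta[p] += delta[p];
        // recompute eta from scratch to avoid incremental drift
        for (int i = 0; i < n; ++i) {
          double e = 0.0;
          for (int p = 0; p < P; ++p) e += beta[p] * X(i, p);
          for (int f = 0; f < nf; ++f) e += fld[f][i] * FX(i, f);
          eta[i] = e;
        }
        ++acc_joint; ++b_acc_joint;
      }
    }

    // accumulate empirical covariance of beta during burn-in
    if (adapting && it > 50) {
      ++cov_n;
      double w = 1.0 / cov_n;
      std::vector<double> dm(P);
      for (int p = 0; p < P; ++p) {
        dm[p] = beta[p] - bmean[p];
        bmean[p] += w * dm[p];
      }
      for (int p = 0; p < P; ++p)
        for (int q = 0; q <= p; ++q) {
          double upd = dm[p] * (beta[q] - bmean[q]);
          bcov[p][q] += (upd - bcov[p][q]) * w;
          bcov[q][p] = bcov[p][q];
        }
    }

    // ---- ICAR fields ----
    for (int f = 0; f < nf; ++f) {
      double tf = tau[f];
      for (int i = 0; i < n; ++i) {
        double xfi = FX(i, f);
        double b0 = fld[f][i];
        double b1 = b0 + s_fld[f] * norm_rand();
        int ni = nbr[i].size();
        double m = 0.0;
        for (int t = 0; t < ni; ++t) m += fld[f][nbr[i][t]];
        m /= ni;
        double d = nb_ll(y[i], eta[i] + (b1 - b0) * xfi, k) -
                   nb_ll(y[i], eta[i], k) -
                   0.5 * tf * ni * ((b1 - m) * (b1 - m) -
                                    (b0 - m) * (b0 - m));
        ++try_fld[f]; ++b_try_fld[f];
        if (std::log(unif_rand()) < d) {
          eta[i] += (b1 - b0) * xfi;
          fld[f][i] = b1;
          ++acc_fld[f]; ++b_acc_fld[f];
        }
      }
      // per-component recentring (sum-to-zero constraint)
      std::vector<double> cm(ncomp, 0.0);
      for (int i = 0; i < n; ++i) cm[cmp[i] - 1] += fld[f][i];
      for (int c = 0; c < ncomp; ++c) cm[c] /= csize[c];
      for (int i = 0; i < n; ++i) {
        double delta = cm[cmp[i] - 1];
        fld[f][i] -= delta;
        eta[i] -= delta * FX(i, f);
      }

      // ---- tau_f ----
      double S = 0.0;
      for (int i = 0; i < n; ++i)
        for (size_t t = 0; t < nbr[i].size(); ++t) {
          int j = nbr[i][t];
          if (j > i) {
            double df = fld[f][i] - fld[f][j];
            S += df * df;
          }
        }
      double lt0 = std::log(tau[f]);
      double lt1 = lt0 + s_tau[f] * norm_rand();
      double t0 = tau[f], t1 = std::exp(lt1);
      double rank = 0.5 * (n - ncomp);
      double d = rank * (lt1 - lt0) - 0.5 * S * (t1 - t0) +
                 (-1.5 * (lt1 - lt0) - pc_lambda *
                  (1.0 / std::sqrt(t1) - 1.0 / std::sqrt(t0))) +
                 (lt1 - lt0);  // log-scale Jacobian
      ++try_tau[f]; ++b_try_tau[f];
      if (std::log(unif_rand()) < d) {
        tau[f] = t1;
        ++acc_tau[f]; ++b_acc_tau[f];
      }

      // joint (field, tau) rescaling move: tau' from a log random walk,
      // field' = field * sqrt(tau/tau').  The ICAR quadratic form is
      // invariant and the rank and Jacobian terms cancel exactly, so the
      // acceptance ratio reduces to the NB likelihood ratio, the PC prior
      // ratio and the proposal Jacobian.  This decouples the precision
      // from the sticky single-site field updates.
      lt0 = std::log(tau[f]);
      lt1 = lt0 + s_scl[f] * norm_rand();
      t1 = std::exp(lt1);
      double g = std::sqrt(tau[f] / t1);
      d = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = (g - 1.0) * fld[f][i] * FX(i, f);
        d += nb_ll(y[i], eta[i] + de, k) - nb_ll(y[i], eta[i], k);
      }
      d += -1.5 * (lt1 - lt0) - pc_lambda *
             (1.0 / std::sqrt(t1) - 1.0 / std::sqrt(tau[f])) +
           (lt1 - lt0);
      ++try_scl[f]; ++b_try_scl[f];
      if (std::log(unif_rand()) < d) {
        for (int i = 0; i < n; ++i) {
          eta[i] += (g - 1.0) * fld[f][i] * FX(i, f);
          fld[f][i] *= g;
        }
        tau[f] = t1;
        ++acc_scl[f]; ++b_acc_scl[f];
      }
    }

    // ---- dispersion k ----
    if (update_k) {
      double lk0 = std::log(k), lk1 = lk0 + s_k * norm_rand();
      double k1 = std::exp(lk1);
      double d = 0.0;
      for (int i = 0; i < n; ++i)
        d += nb_ll(y[i], eta[i], k1) - nb_ll(y[i], eta[i], k);
      d += (disp_shape - 1.0) * (lk1 - lk0) - disp_rate * (k1 - k) +
           (lk1 - lk0);  // Jacobian
      ++try_k; ++b_try_k;
      if (std::log(unif_rand()) < d) { k = k1; ++acc_k; ++b_acc_k; }
    }

    // ---- adaptation (burn-in only), batches of 50 ----
    if (adapting && it % 50 == 0) {
      ++batch;
      double step = adapt_step(batch);
      for (int p = 0; p < P; ++p) {
        if (b_try_beta[p] > 0) {
          double r = (double)b_acc_beta[p] / b_try_beta[p];
          s_beta[p] *= std::exp(r > 0.44 ? step : -step);
        }
        b_acc_beta[p] = b_try_beta[p] = 0;
      }
      for (int f = 0; f < nf; ++f) {
        if (b_try_fld[f] > 0) {
          double r = (double)b_acc_fld[f] / b_try_fld[f];
          s_fld[f] *= std::exp(r > 0.44 ? step : -step);
        }
        if (b_try_tau[f] > 0) {
          double r = (double)b_acc_tau[f] / b_try_tau[f];
          s_tau[f] *= std::exp(r > 0.44 ? step : -step);
        }
        if (b_try_scl[f] > 0) {
          double r = (double)b_acc_scl[f] / b_try_scl[f];
          s_scl[f] *= std::exp(r > 0.44 ? step : -step);
        }
        b_acc_fld[f] = b_try_fld[f] = 0;
        b_acc_tau[f] = b_try_tau[f] = 0;
        b_acc_scl[f] = b_try_scl[f] = 0;
      }
      if (b_try_k > 0) {
        double r = (double)b_acc_k / b_try_k;
        s_k *= std::exp(r > 0.44 ? step : -step);
        b_acc_k = b_try_k = 0;
      }
      if (b_try_joint > 0) {
        double r = (double)b_acc_joint / b_try_joint;
        s_joint *= std::exp(r > 0.23 ? step : -step);
        b_acc_joint = b_try_joint = 0;
      }
      // refresh Cholesky of (2.38^2/P) * (cov + eps I)
      if (it >= joint_start && cov_n > 10 * P) {
        std::vector<std::vector<double>> Aq(P, std::vector<double>(P));
        double sc = 2.38 * 2.38 / P;
        for (int p = 0; p < P; ++p)
          for (int q = 0; q < P; ++q)
            Aq[p][q] = sc * (bcov[p][q] + (p == q ? 1e-8 : 0.0));
        bool ok = true;
        for (int p = 0; p < P && ok; ++p) {
          for (int q = 0; q <= p; ++q) {
            double s = Aq[p][q];
            for (int r2 = 0; r2 < q; ++r2) s -= chol[p][r2] * chol[q][r2];
            if (p == q) {
              if (s <= 0) { ok = false; break; }
              chol[p][q] = std::sqrt(s);
            } else {
              chol[p][q] = s / chol[q][q];
            }
          }
        }
        if (ok) have_chol = true;
      }
    }

    // ---- storage ----
    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      for (int p = 0; p < P; ++p) out_beta(keep, p) = beta[p];
      for (int f = 0; f < nf; ++f) {
        out_tau(keep, f) = tau[f];
        for (int i = 0; i < n; ++i) out_fld[f](keep, i) = fld[f][i];
      }
      out_k[keep] = k;
      ++keep;
    }
  }

  double beta_try_tot = 0.0, beta_acc_tot = 0.0;
  for (int p = 0; p < P; ++p) {
    beta_try_tot += try_beta[p];
    beta_acc_tot += acc_beta[p];
  }
  NumericVector acc_f(nf), acc_t(nf);
  for (int f = 0; f < nf; ++f) {
    acc_f[f] = try_fld[f] ? (double)acc_fld[f] / try_fld[f] : NA_REAL;
    acc_t[f] = try_tau[f] ? (double)acc_tau[f] / try_tau[f] : NA_REAL;
  }
  List fields_out(nf);
  for (int f = 0; f < nf; ++f) fields_out[f] = out_fld[f];

  return List::create(
    _["beta"] = out_beta,
    _["tau"] = out_tau,
    _["k"] = out_k,
    _["fields"] = fields_out,
    _["accept"] = List::create(
      _["beta_single"] = beta_try_tot > 0 ? beta_acc_tot / beta_try_tot
                                          : NA_REAL,
      _["beta_joint"] = try_joint ? (double)acc_joint / try_joint : NA_REAL,
      _["fields"] = acc_f,
      _["tau"] = acc_t,
      _["k"] = try_k ? (double)acc_k / try_k : NA_REAL));
}
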