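// Dominant-marker F_ST outlier scan: multinomial-Dirichlet (beta) model with
// reversible-jump MCMC over locus-specific effects, plus permutation kernels
// for the covariation and differentiation tests.  All randomness goes
// through R's RNG so set.seed() controls every draw.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// reflect a proposal into (lo, hi)
static inline double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  for (int it = 0; it < 100 && (x < lo || x > hi); ++it) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return clampd(x, lo, hi);
}

// log binomial likelihood of the band-absence count given allele freq q and
// inbreeding fis: P(absence) = q^2 + fis*q*(1-q)
static inline double binom_ll(int a, int n, double q, double fis) {
  double g = q * q + fis * q * (1.0 - q);
  return a * std::log(g) + (n - a) * std::log1p(-g);
}

struct ScanState {
  int J, L;
  std::vector<double> q, lq, l1q;     // J*L, column-major [j + J*i]
  std::vector<double> qbar;           // L
  std::vector<double> beta, fis;      // J
  std::vector<double> alpha;          // L
  std::vector<int> incl;              // L
};

static inline double theta_of(double alpha, double beta) {
  double s = clampd(alpha + beta, -12.0, 12.0);   // logit F_ST
  return std::exp(-s);                            // (1-FST)/FST
}

// beta-prior loglik of plot freqs at locus i for a given alpha value
static double locus_beta_ll(const ScanState &S, int i, double a_i) {
  double ll = 0.0;
  const int J = S.J;
  for (int j = 0; j < J; ++j) {
    double th = theta_of(a_i, S.beta[j]);
    double a = th * S.qbar[i], b = th * (1.0 - S.qbar[i]);
    ll += (a - 1.0) * S.lq[j + J * i] + (b - 1.0) * S.l1q[j + J * i]
          - R::lbeta(a, b);
  }
  return ll;
}

// [[Rcpp::export]]
List scan_mcmc_cpp(IntegerMatrix A, IntegerMatrix Nn,
                   int nout, int thin, int npilot, int pilot_len, int burnin,
                   double prior_odds, double fis_lo, double fis_hi,
                   double alpha_sd, double beta_mu, double beta_sd) {
  const int J = A.nrow(), L = A.ncol();
  const double QLO = 1e-4, QHI = 1.0 - 1e-4;
  ScanState S;
  S.J = J; S.L = L;
  S.q.resize(J * L); S.lq.resize(J * L); S.l1q.resize(J * L);
  S.qbar.resize(L); S.alpha.assign(L, 0.0); S.incl.assign(L, 0);
  S.beta.assign(J, beta_mu);
  double fmid = 0.5 * (fis_lo + fis_hi);
  S.fis.assign(J, clampd(fmid, fis_lo + 1e-6, fis_hi - 1e-6));

  // init from observed absence proportions (dominant: q ~ sqrt(prop))
  for (int i = 0; i < L; ++i) {
    double tot = 0, atot = 0;
    for (int j = 0; j < J; ++j) { tot += Nn(j, i); atot += A(j, i); }
    S.qbar[i] = clampd(std::sqrt((atot + 0.5) / (tot + 1.0)), 0.02, 0.98);
    for (int j = 0; j < J; ++j) {
      double qh = std::sqrt((A(j, i) + 0.5) / (Nn(j, i) + 1.0));
      double v = clampd(qh, QLO, QHI);
      S.q[j + J * i] = v;
      S.lq[j + J * i] = std::log(v);
      S.l1q[j + J * i] = std::log1p(-v);
    }
  }

  // proposal scales: q, qbar, beta, fis, alpha
  double sc[5] = {0.2, 0.1, 0.3, 0.2, 0.5};
  long acc[5], att[5];
  const double log_excl_odds = std::log(prior_odds);

  NumericMatrix alpha_s(nout, L);
  IntegerMatrix incl_s(nout, L);
  int isamp = 0;

  RNGScope scope;

  auto iterate = [&](bool record) {
    // 1. plot allele frequencies q_ij
    for (int i = 0; i < L; ++i) {
      double a_i = S.incl[i] ? S.alpha[i] : 0.0;
      for (int j = 0; j < J; ++j) {
        int idx = j + J * i;
        ++att[0];
        double qo = S.q[idx];
        double qn = reflect(qo + sc[0] * norm_rand(), QLO, QHI);
        double th = theta_of(a_i, S.beta[j]);
        double a = th * S.qbar[i], b = th * (1.0 - S.qbar[i]);
        double lqn = std::log(qn), l1qn = std::log1p(-qn);
        double lr = binom_ll(A(j, i), Nn(j, i), qn, S.fis[j])
                  - binom_ll(A(j, i), Nn(j, i), qo, S.fis[j])
                  + (a - 1.0) * (lqn - S.lq[idx])
                  + (b - 1.0) * (l1qn - S.l1q[idx]);
        if (std::log(unif_rand()) < lr) {
          S.q[idx] = qn; S.lq[idx] = lqn; S.l1q[idx] = l1qn; ++acc[0];
        }
      }
    }
    // 2. ancestral frequencies qbar_i (uniform prior)
    for (int i = 0; i < L; ++i) {
      ++att[1];
      double a_i = S.incl[i] ? S.alpha[i] : 0.0;
      double qo = S.qbar[i];
      double qn = reflect(qo + sc[1] * norm_rand(), QLO, QHI);
      double lr = 0.0;
      for (int j = 0; j < J; ++j) {
        double th = theta_of(a_i, S.beta[j]);
        lr += th * (qn - qo) * S.lq[j + J * i]
            + th * (qo - qn) * S.l1q[j + J * i]
            - R::lbeta(th * qn, th * (1.0 - qn))
            + R::lbeta(th * qo, th * (1.0 - qo));
      }
      if (std::log(unif_rand()) < lr) { S.qbar[i] = qn; ++acc[1]; }
    }
    // 3. population effects beta_j (normal prior)
    for (int j = 0; j < J; ++j) {
      ++att[2];
      double bo = S.beta[j];
      double bn = bo + sc[2] * norm_rand();
      double lr = R::dnorm(bn, beta_mu, beta_sd, 1)
                - R::dnorm(bo, beta_mu, beta_sd, 1);
      for (int i = 0; i < L; ++i) {
        double a_i = S.incl[i] ? S.alpha[i] : 0.0;
        double thn = theta_of(a_i, bn), tho = theta_of(a_i, bo);
        double qb = S.qbar[i];
        lr += (thn - tho) * (qb * S.lq[j + J * i]
                             + (1.0 - qb) * S.l1q[j + J * i])
            - R::lbeta(thn * qb, thn * (1.0 - qb))
            + R::lbeta(tho * qb, tho * (1.0 - qb));
      }
      if (std::log(unif_rand()) < lr) { S.beta[j] = bn; ++acc[2]; }
    }
    // 4. inbreeding coefficients fis_j (uniform prior on [fis_lo, fis_hi])
    for (int j = 0; j < J; ++j) {
      ++att[3];
      double fo = S.fis[j];
      double fn = reflect(fo + sc[3] * norm_rand(), fis_lo, fis_hi);
      double lr = 0.0;
      for (int i = 0; i < L; ++i)
        lr += binom_ll(A(j, i), Nn(j, i), S.q[j + J * i], fn)
            - binom_ll(A(j, i), Nn(j, i), S.q[j + J * i], fo);
      if (std::log(unif_rand()) < lr) { S.fis[j] = fn; ++acc[3]; }
    }
    // 5. random-walk update of included alphas
    for (int i = 0; i < L; ++i) {
      if (!S.incl[i]) continue;
      ++att[4];
      double ao = S.alpha[i];
      double an = ao + sc[4] * norm_rand();
      double lr = locus_beta_ll(S, i, an) - locus_beta_ll(S, i, ao)
                + R::dnorm(an, 0.0, alpha_sd, 1)
                - R::dnorm(ao, 0.0, alpha_sd, 1);
      if (std::log(unif_rand()) < lr) { S.alpha[i] = an; ++acc[4]; }
    }
    // 6. reversible-jump toggle; alpha proposed from its prior, so the
    //    acceptance ratio is the likelihood ratio times the inclusion odds
    for (int i = 0; i < L; ++i) {
      if (!S.incl[i]) {
        double an = alpha_sd * norm_rand();
        double lr = locus_beta_ll(S, i, an) - locus_beta_ll(S, i, 0.0)
                  - log_excl_odds;
        if (std::log(unif_rand()) < lr) { S.incl[i] = 1; S.alpha[i] = an; }
      } else {
        double lr = locus_beta_ll(S, i, 0.0) - locus_beta_ll(S, i, S.alpha[i])
                  + log_excl_odds;
        if (std::log(unif_rand()) < lr) { S.incl[i] = 0; S.alpha[i] = 0.0; }
      }
    }
    if (record) {
      for (int i = 0; i < L; ++i) {
        alpha_s(isamp, i) = S.incl[i] ? S.alpha[i] : 0.0;
        incl_s(isamp, i) = S.incl[i];
      }
      ++isamp;
    }
  };

  // pilot runs: adapt proposal scales toward 25-45% acceptance
  NumericMatrix pilot_rates(npilot, 5);
  for (int p = 0; p < npilot; ++p) {
    for (int k = 0; k < 5; ++k) { acc[k] = 0; att[k] = 0; }
    for (int t = 0; t < pilot_len; ++t) iterate(false);
    for (int k = 0; k < 5; ++k) {
      double r = att[k] > 0 ? (double)acc[k] / att[k] : 0.35;
      pilot_rates(p, k) = r;
      if (r < 0.25) sc[k] *= 0.8;
      else if (r > 0.45) sc[k] *= 1.2;
      sc[k] = clampd(sc[k], 1e-3, 10.0);
    }
  }
  // burn-in + sampling
  for (int k = 0; k < 5; ++k) { acc[k] = 0; att[k] = 0; }
  for (int t = 0; t < burnin; ++t) iterate(false);
  for (int s = 0; s < nout; ++s) {
    for (int t = 0; t < thin - 1; ++t) iterate(false);
    iterate(true);
  }
  NumericVector rates(5), scales(5);
  for (int k = 0; k < 5; ++k) {
    rates[k] = att[k] > 0 ? (double)acc[k] / att[k] : NA_REAL;
    scales[k] = sc[k];
  }
  rates.names() = CharacterVector::create("q", "qbar", "beta", "fis", "alpha");
  scales.names() = rates.names();
  return List::create(_["alpha_samples"] = alpha_s,
                      _["incl_samples"] = incl_s,
                      _["beta"] = NumericVector(S.beta.begin(), S.beta.end()),
                      _["fis"] = NumericVector(S.fis.begin(), S.fis.end()),
                      _["acceptance"] = rates,
                      _["scales"] = scales,
                      _["pilot_rates"] = pilot_rates);
}

// covariation C for one (x, y) pairing
static double cov_C(const std::vector<double> &x, const std::vector<double> &y) {
  double num = 0.0, den = 0.0;
  const int n = (int)x.size();
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      num += dx * dy;
      den += std::fabs(dx) * std::fabs(dy);
    }
  if (den == 0.0) return NA_REAL;
  return num / den;
}

// [[Rcpp::export]]
NumericVector perm_C_stats(NumericVector x, NumericVector y, int B) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yp(n);
  NumericVector out(B);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    IntegerVector idx = Rcpp::sample(n, n, false);   // R RNG, 1-based
    for (int i = 0; i < n; ++i) yp[i] = y[idx[i] - 1];
    out[b] = cov_C(xv, yp);
  }
  return out;
}

// delta for a plot-by-variant count table held as flat vectors
static double delta_counts(const std::vector<double> &cnt, int J, int V) {
  std::vector<double> nj(J, 0.0), tot(V, 0.0);
  double N = 0.0;
  for (int j = 0; j < J; ++j)
    for (int v = 0; v < V; ++v) {
      nj[j] += cnt[j + J * v];
      tot[v] += cnt[j + J * v];
      N += cnt[j + J * v];
    }
  double delta = 0.0;
  for (int j = 0; j < J; ++j) {
    double D = 0.0;
    for (int v = 0; v < V; ++v) {
      double pj = cnt[j + J * v] / nj[j];
      double pc = (tot[v] - cnt[j + J * v]) / (N - nj[j]);
      D += std::fabs(pj - pc);
    }
    delta += (nj[j] / N) * 0.5 * D;
  }
  return delta;
}

// [[Rcpp::export]]
NumericVector perm_delta_stats(IntegerVector variant, IntegerVector plot,
                               int J, int V, int B) {
  const int n = variant.size();
  NumericVector out(B);
  std::vector<double> cnt(J * V);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    IntegerVector idx = Rcpp::sample(n, n, false);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i)
      cnt[plot[idx[i] - 1] + J * variant[i]] += 1.0;
    out[b] = delta_counts(cnt, J, V);
  }
  return out;
}
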