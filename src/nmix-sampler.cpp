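// Marginalized binomial N-mixture likelihood with a HOF (two-logistic product)
// abundance surface, and an adaptive random-walk Metropolis sampler over the
// joint posterior {M, a, b, c, d} x 2 periods + shared detection p.
//
// The latent abundance N at each station-period is summed out over
// N = max(y) .. K_trunc.  Binomial-coefficient sums per (station, N) do not
// depend on the parameters, so they are tabulated once per dataset; each
// likelihood evaluation is then a few flops per N.

#include <Rcpp.h>
using namespace Rcpp;

static inline double ilogit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct SiteTab {
  int maxy, K, nk;
  double sumy;
  std::vector<double> lchoose_sum; // indexed N - maxy
};

class NmixLL {
public:
  std::vector<SiteTab> sites;
  std::vector<double> lgam; // lgamma(N + 1), N = 0..Kmax
  mutable std::vector<double> buf;

  NmixLL(const IntegerVector& y, const IntegerVector& ss, const IntegerVector& se,
         const IntegerVector& Ktr) {
    int S = ss.size(), Kmax = 0;
    sites.resize(S);
    for (int s = 0; s < S; ++s) {
      SiteTab& st = sites[s];
      st.maxy = 0; st.sumy = 0; st.nk = se[s] - ss[s]; st.K = Ktr[s];
      for (int k = ss[s]; k < se[s]; ++k) {
        if (y[k] > st.maxy) st.maxy = y[k];
        st.sumy += y[k];
      }
      if (st.K < st.maxy) stop("K_trunc smaller than the largest count at a station");
      if (st.K > Kmax) Kmax = st.K;
      st.lchoose_sum.resize(st.K - st.maxy + 1);
      for (int N = st.maxy; N <= st.K; ++N) {
        double b = 0;
        for (int k = ss[s]; k < se[s]; ++k) b += R::lchoose(N, y[k]);
        st.lchoose_sum[N - st.maxy] = b;
      }
    }
    lgam.resize(Kmax + 1);
    for (int N = 0; N <= Kmax; ++N) lgam[N] = std::lgamma(N + 1.0);
  }

  // log P(y_site | lam, p), N marginalized by truncated summation
  double site_ll(int s, double lam, double p) const {
    const SiteTab& st = sites[s];
    if (lam <= 0) return (st.maxy == 0) ? 0.0 : R_NegInf; // N = 0 almost surely
    double llam = std::log(lam);
    double lp = (p >= 1.0) ? 0.0 : std::log(p);
    double lq = (p >= 1.0) ? R_NegInf : std::log1p(-p);
    double m = R_NegInf;
    buf.resize(st.K - st.maxy + 1);
    for (int N = st.maxy; N <= st.K; ++N) {
      double nfail = st.nk * (double)N - st.sumy;
      double t = N * llam - lam - lgam[N] + st.lchoose_sum[N - st.maxy] + st.sumy * lp;
      if (nfail > 0) t += nfail * lq;          // p = 1 with N > maxy is impossible
      else if (nfail < -1e-9) t = R_NegInf;    // cannot happen for valid N range
      buf[N - st.maxy] = t;
      if (t > m) m = t;
    }
    if (!R_finite(m)) return R_NegInf;
    double s0 = 0;
    for (double t : buf) if (R_finite(t)) s0 += std::exp(t - m);
    return m + std::log(s0);
  }
};

// [[Rcpp::export]]
double nmix_loglik_cpp(IntegerVector y, double lam, double p, int K_trunc) {
  IntegerVector ss = IntegerVector::create(0);
  IntegerVector se = IntegerVector::create(y.size());
  IntegerVector K = IntegerVector::create(K_trunc);
  NmixLL L(y, ss, se, K);
  return L.site_ll(0, lam, p);
}

// theta layout: logM[2], a[2], b[2], c[2], d[2], logit p
// (index: 0 logM_h, 1 logM_m, 2 a_h, 3 a_m, 4 b_h, 5 b_m, 6 c_h, 7 c_m,
//  8 d_h, 9 d_m, 10 logit p)
static double log_posterior(const std::vector<double>& th, const NmixLL& L,
                            const IntegerVector& per, const NumericVector& x,
                            double M_scale, double shape_sd) {
  double M[2] = {std::exp(th[0]), std::exp(th[1])};
  double p = ilogit(th[10]);
  double ll = 0;
  int S = per.size();
  for (int s = 0; s < S; ++s) {
    int i = per[s] - 1;
    double lam = M[i] * ilogit(-(th[2 + i] + th[4 + i] * x[s]))
                      * ilogit(-(th[6 + i] - th[8 + i] * x[s]));
    ll += L.site_ll(s, lam, p);
    if (!R_finite(ll)) return R_NegInf;
  }
  // priors: M half-normal(M_scale) with log-scale Jacobian; shapes N(0, shape_sd);
  // p uniform(0,1) with logit Jacobian
  double lprior = 0;
  for (int i = 0; i < 2; ++i) lprior += R::dnorm(M[i], 0.0, M_scale, 1) + th[i];
  for (int j = 2; j < 10; ++j) lprior += R::dnorm(th[j], 0.0, shape_sd, 1);
  lprior += th[10] - 2.0 * std::log1p(std::exp(th[10]));
  return ll + lprior;
}

// One adaptive-Metropolis chain.  Covariance (Haario) and global scale
// (acceptance-targeted, 0.234) adapt during warm-up only; after warm-up the
// proposal is frozen and every thin-th state is retained.
// [[Rcpp::export]]
List run_nmix_chain_cpp(NumericVector th0, IntegerVector y, IntegerVector ss,
                        IntegerVector se, IntegerVector per, NumericVector x,
                        IntegerVector Ktr, double M_scale, double shape_sd,
                        int n_warm, int n_keep, int thin) {
  const int d = 11;
  if (th0.size() != d) stop("theta must have length 11");
  NmixLL L(y, ss, se, Ktr);
  std::vector<double> th(th0.begin(), th0.end());
  double lp = log_posterior(th, L, per, x, M_scale, shape_sd);
  if (!R_finite(lp)) stop("initial state has zero posterior density");
  NumericMatrix keep(n_keep, d);
  NumericVector lp_keep(n_keep);

  std::vector<double> mu(th), S(d * d, 0.0), Lc(d * d, 0.0);
  for (int i = 0; i < d; ++i) S[i * d + i] = 0.01;
  auto chol_update = [&]() {
    std::vector<double> A(S);
    for (int i = 0; i < d; ++i) A[i * d + i] += 1e-6;
    for (int i = 0; i < d; ++i) for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= Lc[i * d + k] * Lc[j * d + k];
      Lc[i * d + j] = (i == j) ? std::sqrt(std::max(s, 1e-12)) : s / Lc[j * d + j];
    }
  };
  chol_update();

  int n_tot = n_warm + n_keep * thin, acc = 0;
  std::vector<double> z(d), prop(d), dv(d);
  double sc0 = 2.38 / std::sqrt((double)d);
  double lsc = 0.0; // adapted log scale factor
  GetRNGstate();
  for (int t = 1; t <= n_tot; ++t) {
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    double sc = sc0 * std::exp(lsc);
    for (int i = 0; i < d; ++i) {
      double s = 0;
      for (int k = 0; k <= i; ++k) s += Lc[i * d + k] * z[k];
      prop[i] = th[i] + sc * s;
    }
    double lpp = log_posterior(prop, L, per, x, M_scale, shape_sd);
    double alpha = R_finite(lpp) ? std::min(1.0, std::exp(lpp - lp)) : 0.0;
    if (R::unif_rand() < alpha) { th = prop; lp = lpp; ++acc; }
    if (t <= n_warm) {
      lsc += 0.05 * (alpha - 0.234) / std::sqrt(t / 50.0 + 1.0);
      double w = 1.0 / (t + 10.0);
      for (int i = 0; i < d; ++i) dv[i] = th[i] - mu[i];
      for (int i = 0; i < d; ++i) mu[i] += w * dv[i];
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j) S[i * d + j] += w * (dv[i] * dv[j] - S[i * d + j]);
      if (t % 100 == 0) chol_update();
    } else if ((t - n_warm) % thin == 0) {
      int r = (t - n_warm) / thin - 1;
      for (int i = 0; i < d; ++i) keep(r, i) = th[i];
      lp_keep[r] = lp;
    }
  }
  PutRNGstate();
  return List::create(_["draws"] = keep, _["lp"] = lp_keep,
                      _["accept"] = (double)acc / n_tot);
}
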