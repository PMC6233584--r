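// Zero-inflated Poisson log-normal mixed model, fitted by EM.
//
// Per gene j, neighbour counts C_l are modelled as
//   C_l ~ p * delta_0 + (1 - p) * Poisson(N_l * exp(mu + eps_l)),
//   eps_l ~ Normal(0, psi),
// where p is the dropout probability shared across the neighbourhood, mu a
// gene-level log-rate location and psi the over-dispersion variance. The
// integral over eps uses Gauss-Hermite quadrature (nodes passed in from R;
// nodes with numerically null weight are skipped).
//
// EM structure: one quadrature pass computes, for every neighbour l, the
// marginal density g_l and the per-observation gradient / Hessian
// statistics of log g_l in (mu, eta), eta = log s, s = sqrt(2 psi). These
// do not depend on the E-step responsibilities, so the E-step, the
// closed-form p update and a Levenberg-regularized Newton ascent step on
// (mu, eta) (step halving keeps the Q-function from decreasing) all reuse
// the same pass. Convergence of the weakly identified dropout direction is
// slow for plain EM, so cycles are accelerated with SQUAREM-style
// extrapolation: two EM steps define a secant step; the extrapolated point
// is re-stabilized with one further EM step and kept only if it does not
// lower the observed-data log-likelihood. The recorded log-likelihood
// trace is therefore monotone by construction.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MU_LO = -30.0, MU_HI = 10.0;
static const double ETA_LO = -9.0, ETA_HI = 1.7;  // s in [1.2e-4, 5.5]

struct GeneData {
  const double* c;      // counts, length L
  const double* lgc;    // lgamma(c + 1)
  const double* N;      // depths
  int L;
  const double* z;      // quadrature nodes (truncated)
  const double* w;      // quadrature weights
  int K;
  double logisp;        // log(1/sqrt(pi))
};

struct EMState { double p, mu, eta; };

// Per-observation statistics from one quadrature pass at (mu, eta).
struct ObsStats {
  std::vector<double> logg;            // log g_l (density incl. 1/sqrt(pi))
  std::vector<double> dm, de;          // d log g_l / d mu, / d eta
  std::vector<double> hmm, hme, hee;   // second derivatives of log g_l
  void resize(int L) {
    logg.resize(L); dm.resize(L); de.resize(L);
    hmm.resize(L); hme.resize(L); hee.resize(L);
  }
};

static void full_pass(const GeneData& d, double mu, double eta, ObsStats& st) {
  const double s = std::exp(eta);
  std::vector<double> ez(d.K), szk(d.K);
  for (int k = 0; k < d.K; ++k) {
    szk[k] = s * d.z[k];
    ez[k] = std::exp(szk[k]);
  }
  for (int l = 0; l < d.L; ++l) {
    const double a = d.N[l] * std::exp(mu), la = std::log(a);
    const double cl = d.c[l];
    double g = 0, gm = 0, ge = 0, gmm = 0, gme = 0, gee = 0;
    for (int k = 0; k < d.K; ++k) {
      const double nu = a * ez[k];
      double P;
      if (cl == 0.0) {
        if (nu > 745.0) continue;               // exp(-nu) underflows
        P = d.w[k] * std::exp(-nu);
      } else {
        const double lp = -nu + cl * (la + szk[k]) - d.lgc[l];
        if (lp < -745.0) continue;
        P = d.w[k] * std::exp(lp);
      }
      const double um = cl - nu;                // d logPois / d mu
      const double ue = um * szk[k];            // d logPois / d eta
      g   += P;
      gm  += P * um;
      ge  += P * ue;
      gmm += P * (um * um - nu);
      gme += P * (um * ue - nu * szk[k]);
      gee += P * (ue * ue - nu * szk[k] * szk[k] + ue);
    }
    const double gs = std::max(g, 1e-300);
    st.logg[l] = std::log(gs) + d.logisp;
    const double dm = gm / gs, de = ge / gs;
    st.dm[l] = dm;           st.de[l] = de;
    st.hmm[l] = gmm / gs - dm * dm;
    st.hme[l] = gme / gs - dm * de;
    st.hee[l] = gee / gs - de * de;
  }
}

// observed-data log-likelihood; optionally also the E-step dropout
// responsibilities
static double obs_ll(const GeneData& d, const ObsStats& st, double p,
                     double* r) {
  double ll = 0.0;
  for (int l = 0; l < d.L; ++l) {
    if (d.c[l] == 0) {
      const double gdens = std::exp(st.logg[l]);
      const double mix = std::max(p + (1.0 - p) * gdens, 1e-300);
      ll += std::log(mix);
      if (r) r[l] = p / mix;
    } else {
      ll += std::log(1.0 - p) + st.logg[l];
      if (r) r[l] = 0.0;
    }
  }
  return ll;
}

// One EM map application: E-step at `state`/`stats`, closed-form p update,
// one regularized Newton ascent step on (mu, eta). On return `state` is
// the new iterate and `stats` holds the pass at the new (mu, eta).
static void em_step(const GeneData& d, EMState& state, ObsStats& stats,
                    ObsStats& scratch, std::vector<double>& r,
                    std::vector<double>& wt, double p_cap) {
  obs_ll(d, stats, state.p, r.data());
  double rsum = 0.0;
  for (int l = 0; l < d.L; ++l) { rsum += r[l]; wt[l] = 1.0 - r[l]; }
  state.p = std::min(p_cap, std::max(0.0, rsum / d.L));

  double g0 = 0, g1 = 0, a = 0, b = 0, cc = 0, h0 = 0;
  for (int l = 0; l < d.L; ++l) {
    g0 += wt[l] * stats.dm[l];
    g1 += wt[l] * stats.de[l];
    a  -= wt[l] * stats.hmm[l];
    b  -= wt[l] * stats.hme[l];
    cc -= wt[l] * stats.hee[l];
    h0 += wt[l] * stats.logg[l];
  }
  if (std::max(std::fabs(g0), std::fabs(g1)) <= 1e-10) return;

  double lam = 0.0;
  const double tr = std::max(1e-8, std::fabs(a) + std::fabs(cc));
  for (int reg = 0; reg < 30; ++reg) {
    if (a + lam > 1e-12 &&
        (a + lam) * (cc + lam) - b * b > 1e-20 * tr * tr) break;
    lam = (lam == 0.0) ? 1e-4 * tr : lam * 10.0;
  }
  const double det = (a + lam) * (cc + lam) - b * b;
  double dmu  = ((cc + lam) * g0 - b * g1) / det;
  double deta = (-b * g0 + (a + lam) * g1) / det;
  const double nrm = std::max(std::fabs(dmu), std::fabs(deta));
  if (nrm > 2.0) { dmu *= 2.0 / nrm; deta *= 2.0 / nrm; }
  double step = 1.0;
  for (int half = 0; half < 20; ++half) {
    const double mu1 = std::min(MU_HI, std::max(MU_LO, state.mu + step * dmu));
    const double eta1 = std::min(ETA_HI,
                                 std::max(ETA_LO, state.eta + step * deta));
    full_pass(d, mu1, eta1, scratch);
    double h1 = 0.0;
    for (int l = 0; l < d.L; ++l) h1 += wt[l] * scratch.logg[l];
    if (h1 >= h0 - 1e-12) {
      state.mu = mu1; state.eta = eta1;
      std::swap(stats, scratch);
      return;
    }
    step *= 0.5;
  }
  // no ascent found: keep the current point (stats unchanged)
}

// [[Rcpp::export(name = ".zip_pmm_em")]]
List zip_pmm_em(NumericMatrix counts, NumericVector depths,
                NumericVector gh_z, NumericVector gh_w,
                double tol = 1e-6, int max_iter = 500, double p_cap = 0.99,
                bool want_trace = false) {
  const int L = counts.nrow(), G = counts.ncol();
  if (depths.size() != L) stop("depths length must equal nrow(counts)");
  for (int l = 0; l < L; ++l)
    if (depths[l] <= 0) stop("depths must be positive");

  // drop quadrature nodes whose weight is numerically null
  double wmax = 0.0;
  for (int k = 0; k < gh_w.size(); ++k) wmax = std::max(wmax, gh_w[k]);
  std::vector<double> z, w;
  for (int k = 0; k < gh_w.size(); ++k) {
    if (gh_w[k] > 1e-14 * wmax) { z.push_back(gh_z[k]); w.push_back(gh_w[k]); }
  }
  const int K = (int)z.size();
  const double logisp = -0.5 * std::log(M_PI);

  std::vector<double> N(depths.begin(), depths.end());
  NumericVector p_out(G), mu_out(G), psi_out(G), ll_out(G);
  IntegerVector it_out(G);
  LogicalVector conv_out(G), degen_out(G);
  NumericMatrix lambda_hat(L, G);
  std::fill(lambda_hat.begin(), lambda_hat.end(), NA_REAL);
  List traces(want_trace ? G : 0);

  std::vector<double> c(L), lgc(L), r(L), wt(L);
  ObsStats s0, s1, s2, s3, scratch;
  s0.resize(L); s1.resize(L); s2.resize(L); s3.resize(L); scratch.resize(L);

  for (int j = 0; j < G; ++j) {
    int nz = 0;
    double mu0_num = 0.0; int mu0_den = 0;
    for (int l = 0; l < L; ++l) {
      c[l] = counts(l, j);
      lgc[l] = std::lgamma(c[l] + 1.0);
      if (c[l] == 0) ++nz;
      else { mu0_num += std::log(c[l] / N[l]); ++mu0_den; }
    }
    GeneData d{c.data(), lgc.data(), N.data(), L, z.data(), w.data(), K,
               logisp};

    if (nz == L) {                       // degenerate: nothing but zeros
      p_out[j] = p_cap;
      mu_out[j] = -18.0;                 // rate floor, ~1.5e-2 RPM
      psi_out[j] = 0.5;
      ll_out[j] = 0.0;
      it_out[j] = 0; conv_out[j] = true; degen_out[j] = true;
      const double lam = std::exp(mu_out[j] + psi_out[j] / 2.0);
      for (int l = 0; l < L; ++l) lambda_hat(l, j) = lam;
      if (want_trace) traces[j] = NumericVector::create(0.0);
      continue;
    }

    EMState st0{0.5 * nz / (double)L,
                std::min(MU_HI, std::max(MU_LO, mu0_num / mu0_den)),
                0.0};                    // s = 1, psi0 = 0.5
    full_pass(d, st0.mu, st0.eta, s0);
    double ll0 = obs_ll(d, s0, st0.p, nullptr);

    std::vector<double> trace;
    if (want_trace) trace.push_back(ll0);
    int iter = 0;
    bool converged = false;
    while (iter < max_iter) {
      // two plain EM steps
      EMState st1 = st0; s1 = s0;
      em_step(d, st1, s1, scratch, r, wt, p_cap);
      ++iter;
      const double ll1 = obs_ll(d, s1, st1.p, nullptr);
      if (want_trace) trace.push_back(ll1);
      if (std::fabs(ll1 - ll0) < tol) {
        st0 = st1; s0 = s1; ll0 = ll1; converged = true; break;
      }
      EMState st2 = st1; s2 = s1;
      em_step(d, st2, s2, scratch, r, wt, p_cap);
      ++iter;
      const double ll2 = obs_ll(d, s2, st2.p, nullptr);
      if (want_trace) trace.push_back(ll2);
      if (std::fabs(ll2 - ll1) < tol) {
        st0 = st2; s0 = s2; ll0 = ll2; converged = true; break;
      }

      // SQUAREM extrapolation, stabilized by one EM step; accepted only
      // if it does not lower the likelihood
      const double rp = st1.p - st0.p, rm = st1.mu - st0.mu,
                   re = st1.eta - st0.eta;
      const double vp = (st2.p - st1.p) - rp, vm = (st2.mu - st1.mu) - rm,
                   ve = (st2.eta - st1.eta) - re;
      const double vn = std::sqrt(vp * vp + vm * vm + ve * ve);
      EMState stn = st2; s3 = s2; double lln = ll2;
      if (vn > 1e-14 && iter + 2 <= max_iter) {
        double alpha = -std::sqrt(rp * rp + rm * rm + re * re) / vn;
        if (alpha > -1.0) alpha = -1.0;
        EMState sq{st0.p - 2.0 * alpha * rp + alpha * alpha * vp,
                   st0.mu - 2.0 * alpha * rm + alpha * alpha * vm,
                   st0.eta - 2.0 * alpha * re + alpha * alpha * ve};
        sq.p = std::min(p_cap, std::max(0.0, sq.p));
        sq.mu = std::min(MU_HI, std::max(MU_LO, sq.mu));
        sq.eta = std::min(ETA_HI, std::max(ETA_LO, sq.eta));
        full_pass(d, sq.mu, sq.eta, s3);
        em_step(d, sq, s3, scratch, r, wt, p_cap);
        iter += 2;
        const double llsq = obs_ll(d, s3, sq.p, nullptr);
        if (llsq >= ll2 - 1e-10) { stn = sq; lln = llsq; }
        else { s3 = s2; }
      }
      if (want_trace && lln != ll2) trace.push_back(lln);
      st0 = stn; s0 = s3; ll0 = lln;
    }

    const double s = std::exp(st0.eta);
    const double psi = 0.5 * s * s;
    p_out[j] = st0.p; mu_out[j] = st0.mu; psi_out[j] = psi;
    ll_out[j] = ll0; it_out[j] = std::min(iter, max_iter);
    conv_out[j] = converged; degen_out[j] = false;
    if (want_trace) traces[j] = wrap(trace);

    // posterior mean of lambda = exp(mu + eps) for zero counts,
    // marginalized over the dropout indicator
    const double lam_prior = std::exp(st0.mu + psi / 2.0);
    for (int l = 0; l < L; ++l) {
      if (c[l] != 0) continue;
      double gq = 0.0, m0 = 0.0;
      const double aa = N[l] * std::exp(st0.mu);
      for (int k = 0; k < K; ++k) {
        const double nu = aa * std::exp(s * z[k]);
        if (nu > 745.0) continue;
        const double P0 = w[k] * std::exp(-nu);
        gq += P0;
        m0 += P0 * std::exp(st0.mu + s * z[k]);
      }
      const double gdens = std::exp(logisp) * std::max(gq, 1e-300);
      const double cond_mean = gq > 0 ? m0 / std::max(gq, 1e-300) : lam_prior;
      const double rl = st0.p / std::max(st0.p + (1.0 - st0.p) * gdens,
                                         1e-300);
      lambda_hat(l, j) = rl * lam_prior + (1.0 - rl) * cond_mean;
    }
  }

  return List::create(_["p"] = p_out, _["mu"] = mu_out, _["psi"] = psi_out,
                      _["loglik"] = ll_out, _["iterations"] = it_out,
                      _["converged"] = conv_out, _["degenerate"] = degen_out,
                      _["lambda_hat"] = lambda_hat, _["trace"] = traces);
}
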