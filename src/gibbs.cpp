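#include <Rcpp.h>
using namespace Rcpp;

// Truncated stick-breaking Dirichlet-process binomial mixture sampler.
//
// Data: alt/dep are N x S read counts. Each usable cell (i,s) contributes a
// binomial likelihood alt ~ Binom(dep, theta_{ks} * c_{is}) where theta_{ks}
// is the CCF of component k in sample s and c_{is} is the purity/copy-number
// conversion factor expected_vaf(1, m_i, rho_s, CNt_i, CNn)/1. The factors
// take few distinct values, so cells carry an index `cidx` into the vector
// `uc` of unique factors (-1 marks cells excluded from the likelihood).
//
// Sweep: (1) component CCFs by griddy Gibbs on `grid`, (2) assignments from
// the categorical full conditional, (3) stick weights Beta posteriors,
// (4) concentration alpha ~ Gamma. Uses R's RNG, so set.seed() in the caller
// makes runs reproducible.

static inline double clamp_p(double p) {
  if (p < 1e-9) return 1e-9;
  if (p > 1.0 - 1e-9) return 1.0 - 1e-9;
  return p;
}

// [[Rcpp::export]]
List gibbs_dp_binom(IntegerMatrix alt, IntegerMatrix dep, IntegerMatrix cidx,
                    NumericVector uc, int K, int n_iter, int burn_in, int thin,
                    double alpha_shape, double alpha_rate, NumericVector grid,
                    IntegerVector z_init) {
  const int N = alt.nrow(), S = alt.ncol(), U = uc.size(), G = grid.size();
  const double theta_max = grid[G - 1];

  std::vector<int> z(z_init.begin(), z_init.end());
  std::vector<double> theta(K * S, 0.5);
  std::vector<double> logw(K, -std::log((double)K));
  std::vector<double> V(K, 0.5);
  double alpha = 1.0;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericVector theta_out(n_keep * K * S);
  IntegerMatrix z_out(n_keep, N);
  NumericVector alpha_out(n_keep);

  std::vector<double> sumA(K * S * U), sumD(K * S * U);
  std::vector<double> lp(K * S * U), l1(K * S * U);
  std::vector<double> gl(G), comp_ll(K);
  std::vector<int> nk(K);

  int kept = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- component locations: griddy Gibbs ---------------------------------
    std::fill(sumA.begin(), sumA.end(), 0.0);
    std::fill(sumD.begin(), sumD.end(), 0.0);
    std::fill(nk.begin(), nk.end(), 0);
    for (int i = 0; i < N; ++i) {
      int k = z[i];
      ++nk[k];
      for (int s = 0; s < S; ++s) {
        int u = cidx(i, s);
        if (u < 0) continue;
        int id = (k * S + s) * U + u;
        sumA[id] += alt(i, s);
        sumD[id] += dep(i, s) - alt(i, s);
      }
    }
    for (int k = 0; k < K; ++k) {
      for (int s = 0; s < S; ++s) {
        if (nk[k] == 0) {  // unoccupied: draw from the (uniform) prior
          theta[k * S + s] = R::runif(0.0, theta_max);
          continue;
        }
        double best = R_NegInf;
        for (int g = 0; g < G; ++g) {
          double ll = 0.0;
          for (int u = 0; u < U; ++u) {
            int id = (k * S + s) * U + u;
            if (sumA[id] == 0.0 && sumD[id] == 0.0) continue;
            double p = clamp_p(grid[g] * uc[u]);
            ll += sumA[id] * std::log(p) + sumD[id] * std::log1p(-p);
          }
          gl[g] = ll;
          if (ll > best) best = ll;
        }
        double tot = 0.0;
        for (int g = 0; g < G; ++g) { gl[g] = std::exp(gl[g] - best); tot += gl[g]; }
        double r = R::runif(0.0, tot), acc = 0.0;
        int pick = G - 1;
        for (int g = 0; g < G; ++g) { acc += gl[g]; if (r <= acc) { pick = g; break; } }
        theta[k * S + s] = grid[pick];
      }
    }

    // --- assignments -------------------------------------------------------
    for (int k = 0; k < K; ++k)
      for (int s = 0; s < S; ++s)
        for (int u = 0; u < U; ++u) {
          double p = clamp_p(theta[k * S + s] * uc[u]);
          lp[(k * S + s) * U + u] = std::log(p);
          l1[(k * S + s) * U + u] = std::log1p(-p);
        }
    for (int i = 0; i < N; ++i) {
      double best = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double ll = logw[k];
        for (int s = 0; s < S; ++s) {
          int u = cidx(i, s);
          if (u < 0) continue;
          int id = (k * S + s) * U + u;
          ll += alt(i, s) * lp[id] + (dep(i, s) - alt(i, s)) * l1[id];
        }
        comp_ll[k] = ll;
        if (ll > best) best = ll;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { comp_ll[k] = std::exp(comp_ll[k] - best); tot += comp_ll[k]; }
      double r = R::runif(0.0, tot), acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { acc += comp_ll[k]; if (r <= acc) { pick = k; break; } }
      z[i] = pick;
    }

    // --- stick weights and concentration -----------------------------------
    std::fill(nk.begin(), nk.end(), 0);
    for (int i = 0; i < N; ++i) ++nk[z[i]];
    int tail = N;
    double cum = 0.0, sum_log1mV = 0.0;
    for (int k = 0; k < K; ++k) {
      tail -= nk[k];
      double v = (k == K - 1) ? 1.0 : R::rbeta(1.0 + nk[k], alpha + tail);
      if (v > 1.0 - 1e-12) v = 1.0 - 1e-12;
      if (k == K - 1) v = 1.0;
      V[k] = v;
      logw[k] = std::log(v < 1.0 ? v : 1.0 - 1e-15) + cum;
      if (k < K - 1) {
        cum += std::log1p(-v);
        sum_log1mV += std::log1p(-v);
      }
    }
    alpha = R::rgamma(alpha_shape + K - 1, 1.0 / (alpha_rate - sum_log1mV));

    // --- record ------------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      for (int k = 0; k < K; ++k)
        for (int s = 0; s < S; ++s)
          theta_out[(kept * K + k) * S + s] = theta[k * S + s];
      for (int i = 0; i < N; ++i) z_out(kept, i) = z[i] + 1;  // 1-based
      alpha_out[kept] = alpha;
      ++kept;
    }
  }

  theta_out.attr("dim") = IntegerVector::create(S, K, n_keep);
  return List::create(_["theta"] = theta_out, _["z"] = z_out,
                      _["alpha"] = alpha_out, _["n_keep"] = kept);
}
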