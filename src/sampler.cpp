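// Reversible-jump MCMC over per-gene changepoint configurations and
// phase-specific parent sets.  The regression coefficients and noise
// variance of each phase are marginalised analytically, so the chain state
// is (k, xi, Pa_1..Pa_{k+1}, lambda, Lambda, delta2).  Phase likelihoods
// are computed from precomputed cumulative cross-products, making every
// evaluation O(s^3) regardless of replication depth.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline int popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { c += (int)(x & 1); x >>= 1; } return c;
#endif
}

struct Chain {
  // data
  arma::cube cum;          // q x q x n cumulative cross-products (slice t-1 = through transition t)
  arma::vec rows_cum;      // cumulative usable row counts
  int n, p, q;

  // configuration
  int iters, kmax, smax_eff, enum_limit;
  double cc, v_frac, chi, zeta, rho;
  double alpha, beta, upsilon0, gamma0, alpha_delta, beta_delta;
  bool use_lik, sample_hyper;
  int delta2_update;   // 0 fixed, 1 Metropolis, 2 prior refresh

  // state
  std::vector<int> xi;             // interior changepoints, sorted
  std::vector<uint64_t> pa;        // one mask per phase
  std::vector<arma::mat> G;        // per-phase cross-products
  std::vector<double> rowsM;       // per-phase row counts
  std::vector<double> ml;          // per-phase log marginal at current delta2
  double lambda, Lambda, delta2;

  // enumeration proposal support
  bool enum_mode;
  std::vector<uint64_t> subsets;   // all masks with popcount <= smax_eff

  // bookkeeping
  std::vector<int> prop_count, acc_count;

  double a0() const { return upsilon0 / 2.0; }
  double b0() const { return gamma0 / 2.0; }

  void phase_bounds(int h, int& a, int& b) const {
    a = (h == 0) ? 2 : xi[h - 1];
    b = (h == (int)xi.size()) ? n + 1 : xi[h];
  }

  arma::mat cross_of(int a, int b) const {
    return cum.slice(b - 2) - cum.slice(a - 2);
  }
  double rows_of(int a, int b) const {
    return rows_cum[b - 2] - rows_cum[a - 2];
  }

  // log marginal likelihood of a phase from its cross-products
  double log_ml(const arma::mat& Gm, double M, uint64_t mask, double g) const {
    if (!use_lik) return 0.0;
    if (M < 0.5) return -arma::datum::inf;
    int s = popcnt(mask);
    int r = s + 1;
    arma::uvec idx(r);
    idx[0] = 0;
    int c = 1;
    for (int j = 0; j < p; ++j) if (mask & (1ULL << j)) idx[c++] = j + 1;
    arma::mat A = Gm.submat(idx, idx);
    arma::vec v(r);
    for (int i = 0; i < r; ++i) v[i] = Gm(idx[i], q - 1);
    double yty = Gm(q - 1, q - 1);
    arma::vec betav;
    bool ok = arma::solve(betav, A, v, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      A.diag() += 1e-8 * arma::trace(A) / r + 1e-300;
      if (!arma::solve(betav, A, v, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx))
        return -arma::datum::inf;
    }
    double yPy = arma::dot(v, betav);
    double Q = yty - g / (1.0 + g) * yPy;
    double floorQ = 1e-12 * std::max(yty, 1.0);
    if (Q < floorQ) Q = floorQ;
    return -0.5 * M * LOG2PI - 0.5 * r * std::log1p(g) +
      a0() * std::log(b0()) - std::lgamma(a0()) +
      std::lgamma(a0() + M / 2.0) -
      (a0() + M / 2.0) * std::log(b0() + Q / 2.0);
  }

  double log_ml(int a, int b, uint64_t mask, double g) const {
    return log_ml(cross_of(a, b), rows_of(a, b), mask, g);
  }

  // unnormalised truncated-Poisson log pmf terms (normaliser cancels in
  // every ratio taken at a fixed mean)
  static double lpois(int k, double mean) {
    return k * std::log(mean) - std::lgamma(k + 1.0);
  }
  double lp_k(int k) const { return lpois(k, lambda); }
  double lp_s(int s) const { return lpois(s, Lambda); }

  // log normaliser of the truncated Poisson over parent-set sizes; it must
  // be carried explicitly because birth/death moves change the number of
  // phases, so it does not cancel in their acceptance ratios
  double lZs;
  void refresh_lZs() {
    double mx = -arma::datum::inf;
    for (int s = 0; s <= smax_eff; ++s) mx = std::max(mx, lp_s(s));
    double acc = 0.0;
    for (int s = 0; s <= smax_eff; ++s) acc += std::exp(lp_s(s) - mx);
    lZs = mx + std::log(acc);
  }

  double sprior(uint64_t mask) const {
    int s = popcnt(mask);
    return lp_s(s) - lZs - R::lchoose((double)p, (double)s);
  }

  // move-type probabilities at count k
  void move_probs(int k, double& b, double& d, double& v, double& w) const {
    b = (k < kmax) ? cc * std::min(1.0, std::exp(lp_k(k + 1) - lp_k(k))) : 0.0;
    d = (k > 0) ? cc * std::min(1.0, std::exp(lp_k(k - 1) - lp_k(k))) : 0.0;
    double rem = 1.0 - b - d;
    v = (k > 0) ? v_frac * rem : 0.0;
    w = rem - v;
  }

  // regression sub-move probabilities as a function of the phase size s;
  // unavailable mass folds into the exchange move, then into a null move
  void sub_probs(int s, double& padd, double& prem, double& pexch, double& pnull) const {
    bool av_add = s < std::min(smax_eff, p);
    bool av_rem = s > 0;
    bool av_exch = (s > 0 && s < p);
    padd = av_add ? chi : 0.0;
    prem = av_rem ? zeta : 0.0;
    double folded = rho + (chi - padd) + (zeta - prem);
    pexch = av_exch ? folded : 0.0;
    pnull = 1.0 - padd - prem - pexch;
  }

  // ------------------------------------------------------------------
  // parent-set proposal for a phase: exact restricted-posterior
  // enumeration when the subset count is small, otherwise an independence
  // (Bernoulli) proposal with inclusion odds from single-parent
  // marginal-likelihood gains, truncated to |S| <= smax_eff
  struct PaProposal {
    bool enumerated;
    // enumeration branch
    const std::vector<uint64_t>* subsets;
    arma::vec lw;     // log weights, normalised so that logsumexp = 0
    // bernoulli branch
    arma::vec pj;
    double logZ;
    int smax_eff, p;

    double logdens(uint64_t mask) const {
      if (enumerated) {
        for (size_t i = 0; i < subsets->size(); ++i)
          if ((*subsets)[i] == mask) return lw[i];
        return -arma::datum::inf;
      }
      if (popcnt(mask) > smax_eff) return -arma::datum::inf;
      double ld = -logZ;
      for (int j = 0; j < p; ++j) {
        if (mask & (1ULL << j)) ld += std::log(pj[j]);
        else ld += std::log1p(-pj[j]);
      }
      return ld;
    }

    uint64_t sample(double& ld) const {
      if (enumerated) {
        double u = unif_rand(), acc = 0.0;
        size_t i = 0;
        for (; i < subsets->size(); ++i) {
          acc += std::exp(lw[i]);
          if (u <= acc) break;
        }
        if (i >= subsets->size()) i = subsets->size() - 1;
        ld = lw[i];
        return (*subsets)[i];
      }
      for (int tries = 0; tries < 100000; ++tries) {
        uint64_t mask = 0;
        for (int j = 0; j < p; ++j)
          if (unif_rand() < pj[j]) mask |= (1ULL << j);
        if (popcnt(mask) <= smax_eff) { ld = logdens(mask); return mask; }
      }
      ld = logdens(0);  // unreachable in practice
      return 0;
    }
  };

  PaProposal make_proposal(const arma::mat& Gm, double M) const {
    PaProposal pr;
    pr.smax_eff = smax_eff;
    pr.p = p;
    if (enum_mode) {
      pr.enumerated = true;
      pr.subsets = &subsets;
      size_t m = subsets.size();
      pr.lw.set_size(m);
      for (size_t i = 0; i < m; ++i)
        pr.lw[i] = sprior(subsets[i]) + log_ml(Gm, M, subsets[i], delta2);
      double mx = pr.lw.max();
      double lse = mx + std::log(arma::accu(arma::exp(pr.lw - mx)));
      pr.lw -= lse;
    } else {
      pr.enumerated = false;
      double ml0 = log_ml(Gm, M, 0ULL, delta2);
      double pri = std::min(0.5, std::max(1e-3, Lambda / p));
      double lo = std::log(pri / (1.0 - pri));
      pr.pj.set_size(p);
      for (int j = 0; j < p; ++j) {
        double o = (log_ml(Gm, M, 1ULL << j, delta2) - ml0) + lo;
        double pjv = 1.0 / (1.0 + std::exp(-o));
        pr.pj[j] = std::min(0.95, std::max(0.01, pjv));
      }
      double tot = arma::accu(pr.pj);
      double cap = 0.9 * smax_eff;
      if (tot > cap) pr.pj *= cap / tot;
      // Poisson-binomial P(sum <= smax_eff)
      std::vector<double> dp(smax_eff + 1, 0.0);
      dp[0] = 1.0;
      for (int j = 0; j < p; ++j) {
        for (int s = smax_eff; s >= 1; --s)
          dp[s] = dp[s] * (1.0 - pr.pj[j]) + dp[s - 1] * pr.pj[j];
        dp[0] *= (1.0 - pr.pj[j]);
      }
      double Z = 0.0;
      for (double x : dp) Z += x;
      pr.logZ = std::log(Z);
    }
    return pr;
  }

  // ------------------------------------------------------------------
  void refresh_phase(int h) {
    int a, b;
    phase_bounds(h, a, b);
    G[h] = cross_of(a, b);
    rowsM[h] = rows_of(a, b);
    ml[h] = log_ml(G[h], rowsM[h], pa[h], delta2);
  }

  bool do_birth(double bk) {
    int k = (int)xi.size();
    int freeN = (n - 2) - k;
    if (freeN <= 0) return false;
    int r = (int)(unif_rand() * freeN);
    if (r >= freeN) r = freeN - 1;
    int tau = -1, seen = 0;
    size_t ptr = 0;
    for (int pos = 3; pos <= n; ++pos) {
      while (ptr < xi.size() && xi[ptr] < pos) ++ptr;
      if (ptr < xi.size() && xi[ptr] == pos) continue;
      if (seen++ == r) { tau = pos; break; }
    }
    int h = 0;
    while (h < k && xi[h] < tau) ++h;   // phase h spans (prev, next) around tau
    int a, b;
    phase_bounds(h, a, b);

    arma::mat G1 = cross_of(a, tau), G2 = cross_of(tau, b);
    double M1 = rows_of(a, tau), M2 = rows_of(tau, b);
    PaProposal p1 = make_proposal(G1, M1), p2 = make_proposal(G2, M2);
    double lq1, lq2;
    uint64_t pa1 = p1.sample(lq1), pa2 = p2.sample(lq2);
    double ml1 = log_ml(G1, M1, pa1, delta2);
    double ml2 = log_ml(G2, M2, pa2, delta2);
    PaProposal pm = make_proposal(G[h], rowsM[h]);
    double lq_old = pm.logdens(pa[h]);

    double dk1 = cc * std::min(1.0, std::exp(lp_k(k) - lp_k(k + 1)));
    double lacc =
      (lp_k(k + 1) - lp_k(k)) +
      (-R::lchoose((double)(n - 2), (double)(k + 1)) + R::lchoose((double)(n - 2), (double)k)) +
      (sprior(pa1) + ml1 + sprior(pa2) + ml2) - (sprior(pa[h]) + ml[h]) +
      std::log(dk1) - std::log(bk) + std::log((double)freeN) - std::log((double)(k + 1)) +
      lq_old - lq1 - lq2;

    if (std::log(unif_rand()) < lacc) {
      xi.insert(xi.begin() + h, tau);
      pa[h] = pa1; pa.insert(pa.begin() + h + 1, pa2);
      G[h] = G1; G.insert(G.begin() + h + 1, G2);
      rowsM[h] = M1; rowsM.insert(rowsM.begin() + h + 1, M2);
      ml[h] = ml1; ml.insert(ml.begin() + h + 1, ml2);
      return true;
    }
    return false;
  }

  bool do_death(double dk) {
    int k = (int)xi.size();
    int j = (int)(unif_rand() * k);
    if (j >= k) j = k - 1;
    arma::mat Gm = G[j] + G[j + 1];
    double Mm = rowsM[j] + rowsM[j + 1];
    PaProposal pm = make_proposal(Gm, Mm);
    double lqm;
    uint64_t pam = pm.sample(lqm);
    double mlm = log_ml(Gm, Mm, pam, delta2);
    PaProposal pl = make_proposal(G[j], rowsM[j]);
    PaProposal prr = make_proposal(G[j + 1], rowsM[j + 1]);
    double lq1 = pl.logdens(pa[j]);
    double lq2 = prr.logdens(pa[j + 1]);

    double bk1 = cc * std::min(1.0, std::exp(lp_k(k) - lp_k(k - 1)));
    double lacc =
      (lp_k(k - 1) - lp_k(k)) +
      (-R::lchoose((double)(n - 2), (double)(k - 1)) + R::lchoose((double)(n - 2), (double)k)) +
      (sprior(pam) + mlm) - (sprior(pa[j]) + ml[j] + sprior(pa[j + 1]) + ml[j + 1]) +
      std::log(bk1) - std::log(dk) +
      std::log((double)k) - std::log((double)((n - 2) - (k - 1))) +
      lq1 + lq2 - lqm;

    if (std::log(unif_rand()) < lacc) {
      xi.erase(xi.begin() + j);
      pa[j] = pam; pa.erase(pa.begin() + j + 1);
      G[j] = Gm; G.erase(G.begin() + j + 1);
      rowsM[j] = Mm; rowsM.erase(rowsM.begin() + j + 1);
      ml[j] = mlm; ml.erase(ml.begin() + j + 1);
      return true;
    }
    return false;
  }

  bool do_shift() {
    int k = (int)xi.size();
    int j = (int)(unif_rand() * k);
    if (j >= k) j = k - 1;
    int prev = (j == 0) ? 2 : xi[j - 1];
    int next = (j == k - 1) ? n + 1 : xi[j + 1];
    int lo = prev + 1, hi = next - 1;
    int count = hi - lo;           // excludes the current position
    if (count <= 0) return false;
    int r = (int)(unif_rand() * count);
    if (r >= count) r = count - 1;
    int tau = lo + r;
    if (tau >= xi[j]) ++tau;       // skip current
    arma::mat G1 = cross_of(prev, tau), G2 = cross_of(tau, next);
    double M1 = rows_of(prev, tau), M2 = rows_of(tau, next);
    double ml1 = log_ml(G1, M1, pa[j], delta2);
    double ml2 = log_ml(G2, M2, pa[j + 1], delta2);
    double lacc = ml1 + ml2 - ml[j] - ml[j + 1];
    if (std::log(unif_rand()) < lacc) {
      xi[j] = tau;
      G[j] = G1; G[j + 1] = G2;
      rowsM[j] = M1; rowsM[j + 1] = M2;
      ml[j] = ml1; ml[j + 1] = ml2;
      return true;
    }
    return false;
  }

  bool do_regression() {
    int k = (int)xi.size();
    int h = (int)(unif_rand() * (k + 1));
    if (h > k) h = k;
    int s = popcnt(pa[h]);
    double padd, prem, pexch, pnull;
    sub_probs(s, padd, prem, pexch, pnull);
    double u = unif_rand();
    if (u < padd) {
      // edge addition
      int nonp = p - s;
      int r = (int)(unif_rand() * nonp);
      if (r >= nonp) r = nonp - 1;
      int j = -1, seen = 0;
      for (int b = 0; b < p; ++b)
        if (!(pa[h] & (1ULL << b)) && seen++ == r) { j = b; break; }
      uint64_t mask2 = pa[h] | (1ULL << j);
      double ml2 = log_ml(G[h], rowsM[h], mask2, delta2);
      double padd2, prem2, pexch2, pnull2;
      sub_probs(s + 1, padd2, prem2, pexch2, pnull2);
      double lacc = (lp_s(s + 1) - lp_s(s)) +
        (-R::lchoose((double)p, (double)(s + 1)) + R::lchoose((double)p, (double)s)) +
        ml2 - ml[h] +
        std::log(prem2 / (s + 1.0)) - std::log(padd / (double)nonp);
      if (std::log(unif_rand()) < lacc) { pa[h] = mask2; ml[h] = ml2; return true; }
      return false;
    } else if (u < padd + prem) {
      // edge removal
      int r = (int)(unif_rand() * s);
      if (r >= s) r = s - 1;
      int j = -1, seen = 0;
      for (int b = 0; b < p; ++b)
        if ((pa[h] & (1ULL << b)) && seen++ == r) { j = b; break; }
      uint64_t mask2 = pa[h] & ~(1ULL << j);
      double ml2 = log_ml(G[h], rowsM[h], mask2, delta2);
      double padd2, prem2, pexch2, pnull2;
      sub_probs(s - 1, padd2, prem2, pexch2, pnull2);
      double lacc = (lp_s(s - 1) - lp_s(s)) +
        (-R::lchoose((double)p, (double)(s - 1)) + R::lchoose((double)p, (double)s)) +
        ml2 - ml[h] +
        std::log(padd2 / (double)(p - s + 1)) - std::log(prem / (double)s);
      if (std::log(unif_rand()) < lacc) { pa[h] = mask2; ml[h] = ml2; return true; }
      return false;
    } else if (u < padd + prem + pexch) {
      // exchange one parent for one non-parent (dimension preserved)
      int r1 = (int)(unif_rand() * s);
      if (r1 >= s) r1 = s - 1;
      int r2 = (int)(unif_rand() * (p - s));
      if (r2 >= p - s) r2 = p - s - 1;
      int jout = -1, jin = -1, seen = 0;
      for (int b = 0; b < p; ++b)
        if ((pa[h] & (1ULL << b)) && seen++ == r1) { jout = b; break; }
      seen = 0;
      for (int b = 0; b < p; ++b)
        if (!(pa[h] & (1ULL << b)) && seen++ == r2) { jin = b; break; }
      uint64_t mask2 = (pa[h] & ~(1ULL << jout)) | (1ULL << jin);
      double ml2 = log_ml(G[h], rowsM[h], mask2, delta2);
      double lacc = ml2 - ml[h];
      if (std::log(unif_rand()) < lacc) { pa[h] = mask2; ml[h] = ml2; return true; }
      return false;
    }
    return false;  // null move
  }

  void update_hyper() {
    int k = (int)xi.size();
    lambda = R::rgamma(alpha + k, beta / (1.0 + beta));
    if (lambda < 1e-8) lambda = 1e-8;
    int sumS = 0;
    for (uint64_t m : pa) sumS += popcnt(m);
    Lambda = R::rgamma(alpha + sumS, beta / (1.0 + (k + 1) * beta));
    if (Lambda < 1e-8) Lambda = 1e-8;
    refresh_lZs();
    if (delta2_update == 2) {
      // refresh from the inverse-Gamma prior
      delta2 = 1.0 / R::rgamma(alpha_delta, 1.0 / beta_delta);
      if (use_lik) {
        for (size_t h = 0; h < ml.size(); ++h)
          ml[h] = log_ml(G[h], rowsM[h], pa[h], delta2);
      }
    } else if (delta2_update == 1) {
      // Metropolis step on the marginalised score
      double prop = delta2 * std::exp(0.5 * norm_rand());
      double lacc = (std::log(prop) - std::log(delta2)) +      // Hastings (log-normal walk)
        (-(alpha_delta + 1.0) * std::log(prop) - beta_delta / prop) -
        (-(alpha_delta + 1.0) * std::log(delta2) - beta_delta / delta2);
      std::vector<double> ml_new(ml.size());
      if (use_lik) {
        for (size_t h = 0; h < ml.size(); ++h) {
          ml_new[h] = log_ml(G[h], rowsM[h], pa[h], prop);
          lacc += ml_new[h] - ml[h];
        }
      }
      if (std::log(unif_rand()) < lacc) {
        delta2 = prop;
        if (use_lik) ml = ml_new;
      }
    }
  }
};


// Debug/validation hook: unnormalised log posterior of a full state under
// the chain's scoring (fixed hyperparameter values).
// [[Rcpp::export(name = ".chain_score")]]
double chain_score(arma::cube cum, arma::vec rows_cum, int n, int p, List opts,
                   IntegerVector cps, NumericVector pa_masks) {
  Chain ch;
  ch.cum = cum; ch.rows_cum = rows_cum;
  ch.n = n; ch.p = p; ch.q = p + 2;
  ch.kmax = as<int>(opts["k_max"]);
  ch.smax_eff = std::min(as<int>(opts["s_max"]), p);
  ch.use_lik = true;
  ch.upsilon0 = as<double>(opts["upsilon0"]);
  ch.gamma0 = as<double>(opts["gamma0"]);
  ch.lambda = as<double>(opts["lambda_cp"]);
  ch.Lambda = as<double>(opts["Lambda_par"]);
  ch.delta2 = as<double>(opts["delta2"]);
  ch.refresh_lZs();
  int k = cps.size();
  // normalised truncated-Poisson prior on k
  double mx = -arma::datum::inf;
  for (int j = 0; j <= ch.kmax; ++j) mx = std::max(mx, ch.lp_k(j));
  double z = 0.0;
  for (int j = 0; j <= ch.kmax; ++j) z += std::exp(ch.lp_k(j) - mx);
  double val = ch.lp_k(k) - (mx + std::log(z)) - R::lchoose((double)(n - 2), (double)k);
  std::vector<int> bounds;
  bounds.push_back(2);
  for (int i = 0; i < k; ++i) bounds.push_back(cps[i]);
  bounds.push_back(n + 1);
  for (int h = 0; h <= k; ++h) {
    uint64_t mask = (uint64_t)pa_masks[h];
    val += ch.sprior(mask) + ch.log_ml(bounds[h], bounds[h + 1], mask, ch.delta2);
  }
  return val;
}

// [[Rcpp::export(name = ".run_chain")]]
List run_chain(arma::cube cum, arma::vec rows_cum, int n, int p, List opts) {
  Chain ch;
  ch.cum = cum;
  ch.rows_cum = rows_cum;
  ch.n = n; ch.p = p; ch.q = p + 2;
  ch.iters = as<int>(opts["iterations"]);
  ch.kmax = as<int>(opts["k_max"]);
  ch.smax_eff = std::min(as<int>(opts["s_max"]), p);
  ch.enum_limit = as<int>(opts["enum_limit"]);
  ch.cc = as<double>(opts["c"]);
  ch.v_frac = as<double>(opts["v_frac"]);
  ch.chi = as<double>(opts["chi"]);
  ch.zeta = as<double>(opts["zeta"]);
  ch.rho = as<double>(opts["rho"]);
  ch.alpha = as<double>(opts["alpha"]);
  ch.beta = as<double>(opts["beta"]);
  ch.upsilon0 = as<double>(opts["upsilon0"]);
  ch.gamma0 = as<double>(opts["gamma0"]);
  ch.alpha_delta = as<double>(opts["alpha_delta"]);
  ch.beta_delta = as<double>(opts["beta_delta"]);
  ch.use_lik = as<bool>(opts["likelihood"]);
  ch.delta2_update = as<int>(opts["delta2_update"]);
  ch.sample_hyper = as<bool>(opts["sample_hyper"]);
  ch.lambda = as<double>(opts["lambda_cp"]);
  ch.Lambda = as<double>(opts["Lambda_par"]);
  ch.delta2 = as<double>(opts["delta2"]);

  if (p > 52) stop("at most 52 candidate regulators are supported");
  if (n > 64) stop("at most 64 time points are supported by the sampler");

  // enumeration table when the subset space is small
  double total = 0;
  for (int s = 0; s <= ch.smax_eff; ++s) total += R::choose((double)p, (double)s);
  ch.enum_mode = total <= ch.enum_limit;
  if (ch.enum_mode) {
    for (uint64_t m = 0; m < (1ULL << p); ++m)
      if (popcnt(m) <= ch.smax_eff) ch.subsets.push_back(m);
  }

  ch.refresh_lZs();

  // initial state: no changepoints, empty parent set
  ch.xi.clear();
  ch.pa.assign(1, 0ULL);
  ch.G.assign(1, ch.cross_of(2, n + 1));
  ch.rowsM.assign(1, ch.rows_of(2, n + 1));
  ch.ml.assign(1, ch.log_ml(ch.G[0], ch.rowsM[0], 0ULL, ch.delta2));

  IntegerVector k_rec(ch.iters), move_rec(ch.iters);
  LogicalVector acc_rec(ch.iters);
  NumericVector lam_rec(ch.iters), Lam_rec(ch.iters), d2_rec(ch.iters);
  List cp_rec(ch.iters);
  NumericMatrix pa_rec(ch.iters, ch.kmax + 1);
  std::fill(pa_rec.begin(), pa_rec.end(), NA_REAL);
  ch.prop_count.assign(5, 0);
  ch.acc_count.assign(5, 0);

  for (int it = 0; it < ch.iters; ++it) {
    int k = (int)ch.xi.size();
    double b, d, v, w;
    ch.move_probs(k, b, d, v, w);
    double u = unif_rand();
    int move; bool acc;
    if (u < b) { move = 1; acc = ch.do_birth(b); }
    else if (u < b + d) { move = 2; acc = ch.do_death(d); }
    else if (u < b + d + v) { move = 3; acc = ch.do_shift(); }
    else { move = 4; acc = ch.do_regression(); }
    ch.prop_count[move - 1]++;
    if (acc) ch.acc_count[move - 1]++;

    if (ch.sample_hyper) ch.update_hyper();

    k_rec[it] = (int)ch.xi.size();
    move_rec[it] = move;
    acc_rec[it] = acc;
    lam_rec[it] = ch.lambda;
    Lam_rec[it] = ch.Lambda;
    d2_rec[it] = ch.delta2;
    cp_rec[it] = IntegerVector(ch.xi.begin(), ch.xi.end());
    for (size_t h = 0; h < ch.pa.size(); ++h)
      pa_rec(it, h) = (double)ch.pa[h];

    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["k"] = k_rec, _["move"] = move_rec, _["accepted"] = acc_rec,
    _["lambda"] = lam_rec, _["Lambda"] = Lam_rec, _["delta2"] = d2_rec,
    _["cp"] = cp_rec, _["pa"] = pa_rec,
    _["proposed"] = IntegerVector(ch.prop_count.begin(), ch.prop_count.end()),
    _["accepted_n"] = IntegerVector(ch.acc_count.begin(), ch.acc_count.end())
  );
}
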