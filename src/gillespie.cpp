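// Exact Gillespie engine for the multiclonal competition process.
//
// Events: per-cell death at rate mu, clonotype division at rate
// Lambda_i = n_i * sum_{q in Q_i, c_q > 0} gamma_q / c_q, and thymic arrival
// of a fresh clonotype (n_theta cells, pattern Bernoulli(p) per pMHC,
// redrawn if empty) at rate theta. Caches are updated incrementally: an
// event in clonotype i touches c_q only for q in Q_i, and only clonotypes
// sharing those q have their share sums refreshed. Two RNG streams
// (dynamics, thymus) keep replicate designs reproducible.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Engine {
  int M;
  std::vector<double> gamma;
  double mu, theta, p;
  int n_theta;

  std::vector<std::vector<int> > Q;   // per-clonotype sorted pMHC (0-based)
  std::vector<long long> n;           // cells per clonotype (0 = extinct)
  std::vector<double> lamfac;         // sum_{q in Q_i, c_q>0} gamma_q / c_q
  std::vector<double> t_birth, t_ext; // fates (t_ext = NA while alive)
  std::vector<long long> max_size;

  std::vector<long long> c;                 // per-pMHC recogniser cell totals
  std::vector<std::vector<int> > members;   // per-pMHC live clonotype indices
  std::vector<int> live, pos_in_live;

  long long ntot = 0, sum_phi = 0;
  long long deaths = 0, divisions = 0, arrivals = 0;

  std::mt19937_64 rng_dyn, rng_thy;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::vector<char> mark;  // scratch for emigrant pattern draws

  Engine(int M_, const std::vector<double>& gamma_, double mu_, double theta_,
         int n_theta_, double p_, int seed_dyn, int seed_thy)
      : M(M_), gamma(gamma_), mu(mu_), theta(theta_), p(p_),
        n_theta(n_theta_), c(M_, 0), members(M_),
        rng_dyn((unsigned long long)(long long)seed_dyn * 2654435761ULL + 1ULL),
        rng_thy((unsigned long long)(long long)seed_thy * 2654435761ULL + 3ULL),
        mark(M_, 0) {}

  // add a clonotype with n_new cells and the given pattern at time t
  int register_clone(const std::vector<int>& pattern, long long n_new,
                     double t) {
    int g = (int)Q.size();
    Q.push_back(pattern);
    n.push_back(n_new);
    t_birth.push_back(t);
    t_ext.push_back(NA_REAL);
    max_size.push_back(n_new);
    double lf = 0.0;
    for (int q : pattern) {
      long long cold = c[q], cnew = cold + n_new;
      if (cold > 0) {
        double delta = gamma[q] * (1.0 / (double)cnew - 1.0 / (double)cold);
        for (int j : members[q]) lamfac[j] += delta;
      }
      c[q] = cnew;
      members[q].push_back(g);
      lf += gamma[q] / (double)cnew;
    }
    lamfac.push_back(lf);
    pos_in_live.push_back((int)live.size());
    live.push_back(g);
    ntot += n_new;
    sum_phi += (long long)pattern.size();
    return g;
  }

  void remove_from_members(int g) {
    for (int q : Q[g]) {
      std::vector<int>& m = members[q];
      for (size_t k = 0; k < m.size(); ++k)
        if (m[k] == g) { m[k] = m.back(); m.pop_back(); break; }
    }
  }

  void extinguish(int g, double t) {
    t_ext[g] = t;
    sum_phi -= (long long)Q[g].size();
    remove_from_members(g);
    int pos = pos_in_live[g];
    int last = live.back();
    live[pos] = last;
    pos_in_live[last] = pos;
    live.pop_back();
    pos_in_live[g] = -1;
    lamfac[g] = 0.0;
  }

  void death(int g, double t) {
    --n[g]; --ntot; ++deaths;
    for (int q : Q[g]) {
      long long cold = c[q], cnew = cold - 1;
      c[q] = cnew;
      double delta = (cnew > 0)
        ? gamma[q] * (1.0 / (double)cnew - 1.0 / (double)cold)
        : -gamma[q] / (double)cold;  // last recognising cell: stimulus lost
      for (int j : members[q]) lamfac[j] += delta;
    }
    if (n[g] == 0) extinguish(g, t);
  }

  void division(int g) {
    ++n[g]; ++ntot; ++divisions;
    if (n[g] > max_size[g]) max_size[g] = n[g];
    for (int q : Q[g]) {
      long long cold = c[q], cnew = cold + 1;
      c[q] = cnew;
      double delta = gamma[q] * (1.0 / (double)cnew - 1.0 / (double)cold);
      for (int j : members[q]) lamfac[j] += delta;
    }
  }

  std::vector<int> draw_pattern() {
    std::binomial_distribution<int> binom(M, p);
    int k = 0;
    do { k = binom(rng_thy); } while (k == 0);
    std::vector<int> pat;
    pat.reserve(k);
    if (k >= M) {
      for (int q = 0; q < M; ++q) pat.push_back(q);
      return pat;
    }
    std::uniform_int_distribution<int> pick(0, M - 1);
    while ((int)pat.size() < k) {
      int q = pick(rng_thy);
      if (!mark[q]) { mark[q] = 1; pat.push_back(q); }
    }
    for (int q : pat) mark[q] = 0;
    std::sort(pat.begin(), pat.end());
    return pat;
  }

  void thymic_arrival(double t) {
    ++arrivals;
    register_clone(draw_pattern(), n_theta, t);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_gillespie_run(List patterns, NumericVector gamma_, double mu,
                       double theta, int n_theta, double p,
                       IntegerVector n_init, double t_max, double record_dt,
                       int seed_dynamics, int seed_thymus,
                       bool check_caches = false) {
  const int M = gamma_.size();
  std::vector<double> gam(gamma_.begin(), gamma_.end());
  Engine eng(M, gam, mu, theta, n_theta, p, seed_dynamics, seed_thymus);

  const int N0 = patterns.size();
  if (n_init.size() != N0) stop("length(n_init) must match length(patterns)");
  for (int i = 0; i < N0; ++i) {
    IntegerVector pr = patterns[i];
    std::vector<int> pat(pr.size());
    for (int k = 0; k < pr.size(); ++k) {
      pat[k] = pr[k] - 1;  // R patterns are 1-based
      if (pat[k] < 0 || pat[k] >= M) stop("pMHC index out of range");
    }
    if (n_init[i] < 1) stop("initial counts must be >= 1");
    eng.register_clone(pat, n_init[i], 0.0);
  }

  const int R = (int)std::floor(t_max / record_dt + 1e-9) + 1;
  NumericVector rec_t(R), rec_phibar(R), rec_cbar(R);
  NumericVector rec_n(R), rec_N(R);
  NumericVector rec_deaths(R), rec_divs(R), rec_arr(R);
  int next_rec = 0;
  auto record_state = [&](int k) {
    rec_t[k] = k * record_dt;
    rec_n[k] = (double)eng.ntot;
    rec_N[k] = (double)eng.live.size();
    rec_phibar[k] = eng.live.empty()
      ? NA_REAL : (double)eng.sum_phi / (double)eng.live.size();
    rec_cbar[k] = (double)eng.sum_phi / (double)M;
    rec_deaths[k] = (double)eng.deaths;
    rec_divs[k] = (double)eng.divisions;
    rec_arr[k] = (double)eng.arrivals;
  };

  double t = 0.0;
  record_state(next_rec++);  // t = 0
  std::vector<double> rate_buf;
  long long iter = 0;
  while (true) {
    if (++iter % 4096 == 0) Rcpp::checkUserInterrupt();
    // total rate, computed fresh each event from the cached share sums
    const size_t nlive = eng.live.size();
    rate_buf.resize(nlive);
    double S = theta;
    for (size_t k = 0; k < nlive; ++k) {
      int g = eng.live[k];
      double r = (double)eng.n[g] * (mu + eng.lamfac[g]);
      rate_buf[k] = r;
      S += r;
    }
    if (S <= 0.0) {  // absorbing: no cells and no thymic input
      while (next_rec < R) record_state(next_rec++);
      t = t_max;
      break;
    }
    double dt = -std::log(1.0 - eng.unif(eng.rng_dyn)) / S;
    double tn = t + dt;
    while (next_rec < R && next_rec * record_dt <= tn)
      record_state(next_rec++);  // state is constant on [t, t + dt)
    if (tn >= t_max) { t = t_max; break; }
    t = tn;
    double u = eng.unif(eng.rng_dyn) * S;
    if (u < theta) {
      eng.thymic_arrival(t);
    } else {
      u -= theta;
      size_t k = 0;
      for (; k < nlive; ++k) {
        if (u < rate_buf[k]) break;
        u -= rate_buf[k];
      }
      if (k == nlive) k = nlive - 1;  // roundoff guard
      int g = eng.live[k];
      double rd = mu * (double)eng.n[g];
      if (u < rd) eng.death(g, t); else eng.division(g);
    }
  }

  // final state
  const size_t nlive = eng.live.size();
  IntegerVector fin_id(nlive);
  NumericVector fin_n(nlive), fin_Lambda(nlive);
  std::vector<int> live_sorted(eng.live);
  std::sort(live_sorted.begin(), live_sorted.end());
  double S_final = theta;
  for (size_t k = 0; k < nlive; ++k) {
    int g = live_sorted[k];
    fin_id[k] = g + 1;
    fin_n[k] = (double)eng.n[g];
    fin_Lambda[k] = (double)eng.n[g] * eng.lamfac[g];
    S_final += (double)eng.n[g] * (mu + eng.lamfac[g]);
  }
  NumericVector fin_c(M);
  for (int q = 0; q < M; ++q) fin_c[q] = (double)eng.c[q];

  // fates
  const int ncl = (int)eng.Q.size();
  IntegerVector f_id(ncl), f_phi(ncl);
  NumericVector f_birth(ncl), f_ext(ncl), f_max(ncl);
  for (int g = 0; g < ncl; ++g) {
    f_id[g] = g + 1;
    f_phi[g] = (int)eng.Q[g].size();
    f_birth[g] = eng.t_birth[g];
    f_ext[g] = eng.t_ext[g];
    f_max[g] = (double)eng.max_size[g];
  }

  List out = List::create(
    Named("trajectory") = List::create(
      Named("t") = rec_t, Named("n_total") = rec_n,
      Named("N_surviving") = rec_N, Named("phi_bar") = rec_phibar,
      Named("C_bar") = rec_cbar, Named("deaths") = rec_deaths,
      Named("divisions") = rec_divs, Named("thymic_arrivals") = rec_arr),
    Named("fates") = List::create(
      Named("clonotype_id") = f_id, Named("t_birth") = f_birth,
      Named("t_extinction") = f_ext, Named("phi") = f_phi,
      Named("max_size") = f_max),
    Named("final") = List::create(
      Named("t") = t, Named("id") = fin_id, Named("n") = fin_n,
      Named("Lambda") = fin_Lambda, Named("c") = fin_c,
      Named("S") = S_final),
    Named("tallies") = NumericVector::create(
      Named("deaths") = (double)eng.deaths,
      Named("divisions") = (double)eng.divisions,
      Named("thymic_arrivals") = (double)eng.arrivals));

  if (check_caches) {
    // scratch recomputation of every cache from counts + patterns
    std::vector<long long> c2(M, 0);
    long long sp = 0, nt = 0;
    for (int g : eng.live) {
      for (int q : eng.Q[g]) c2[q] += eng.n[g];
      sp += (long long)eng.Q[g].size();
      nt += eng.n[g];
    }
    long long cdiff = 0;
    for (int q = 0; q < M; ++q)
      cdiff = std::max(cdiff, std::llabs(c2[q] - eng.c[q]));
    double lam_rel = 0.0;
    for (int g : eng.live) {
      double lf = 0.0;
      for (int q : eng.Q[g]) if (c2[q] > 0) lf += gam[q] / (double)c2[q];
      double ref = std::max(1.0, std::fabs(lf));
      lam_rel = std::max(lam_rel, std::fabs(lf - eng.lamfac[g]) / ref);
    }
    out["cache_check"] = List::create(
      Named("max_c_diff") = (double)cdiff,
      Named("max_lambda_rel_diff") = lam_rel,
      Named("sum_phi_diff") = (double)(sp - eng.sum_phi),
      Named("ntot_diff") = (double)(nt - eng.ntot));
  }
  return out;
}
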