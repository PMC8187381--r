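// Compiled simulation engine. Consumes R's RNG stream (unif_rand) in
// exactly the same order as the pure-R engine in R/engine_r.R, so that a
// run from a given seed is bit-identical across the two engines. Any
// change to the draw order here must be mirrored there (and in the
// documented draw order in the methods vignette).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  int n, m, M;
  double benefit, cost, extra_cost, threshold, delta, mu;
  int ostracism_type;
  double s_policy; // -1 encodes "fusion" (S_i = f_i)
  double e_p, e_x;
  bool mutate_fusion;
};

struct Pop {
  std::vector<double> fusion, payoff;
  std::vector<int> rule_s, rule_u, rule_d, personal_rep;
  std::vector<int> n_pos, n_neu, n_neg;
  int group_rep;
};

inline double perceived_rep(double f_obs, double f_tgt, int r_tgt,
                            int r_group) {
  if (f_obs == 0.0) return (double)r_tgt;
  return (1.0 - f_tgt) * (double)r_tgt + f_tgt * (double)r_group;
}

inline int clamp_rep(int x) { return x > 5 ? 5 : (x < -5 ? -5 : x); }

// Contribution ratio; defined=false encodes the undefined (NA) case.
inline double ctr_of(const Pop &p, int i, bool &defined) {
  int den = p.n_pos[i] + p.n_neu[i] + p.n_neg[i];
  if (den == 0) { defined = false; return 0.0; }
  defined = true;
  return (double)(p.n_pos[i] + p.n_neu[i]) / (double)den;
}

// Full gated hypocrisy check. Draw order: check gate; perception gate
// (+ replacement value if it fires); execution gate only for a perceived
// hypocrite. Mirrors check_ostracism() in R.
inline bool check_ostracism(double f_i, double f_j, double ctr_i,
                            bool ctr_i_def, double ctr_j, bool ctr_j_def,
                            const Params &par) {
  if (f_i < par.threshold || f_i <= 0.0 || f_j <= 0.0) return false;
  if (unif_rand() >= f_i) return false;
  double perceived = ctr_j;
  bool perceived_def = ctr_j_def;
  if (unif_rand() < par.e_p) {
    perceived = unif_rand(); // noise fabricates a value even where the
    perceived_def = true;    // true ratio is still undefined
  }
  if (!(ctr_i_def && perceived_def)) return false;
  if (!(f_j >= f_i && perceived < ctr_i)) return false;
  return unif_rand() >= par.e_x;
}

// Partner selection: in-group gate draw (always consumed), then one
// index draw. Empty in-group falls back to the global draw.
inline int select_partner(int i, const Pop &p, const Params &par,
                          std::vector<int> &buf) {
  double s_i = (par.s_policy < 0.0) ? p.fusion[i] : par.s_policy;
  bool in_group = unif_rand() < s_i;
  if (in_group) {
    buf.clear();
    for (int j = 0; j < par.n; ++j)
      if (j != i && p.fusion[j] >= p.fusion[i]) buf.push_back(j);
    if (!buf.empty()) {
      int t = (int)(unif_rand() * (double)buf.size());
      return buf[t];
    }
  }
  int t = (int)(unif_rand() * (double)(par.n - 1));
  return (t >= i) ? t + 1 : t; // 0-based: skip the donor
}

} // namespace

// [[Rcpp::export]]
List cpp_run_sim(List params, List init_pop, bool record_trajectory) {
  Params par;
  par.n = as<int>(params["n_agents"]);
  par.m = as<int>(params["games_per_gen"]);
  par.M = as<int>(params["generations"]);
  par.benefit = as<double>(params["benefit"]);
  par.cost = as<double>(params["cost"]);
  par.extra_cost = as<double>(params["extra_cost"]);
  par.threshold = as<double>(params["threshold"]);
  par.delta = as<double>(params["delta"]);
  par.mu = as<double>(params["mutation_rate"]);
  par.ostracism_type = as<int>(params["ostracism_type"]);
  par.s_policy = as<double>(params["s_policy_code"]);
  par.e_p = as<double>(params["err_perception"]);
  par.e_x = as<double>(params["err_execution"]);
  par.mutate_fusion = as<bool>(params["mutate_fusion"]);

  const int n = par.n;
  Pop pop;
  {
    NumericVector f = init_pop["fusion"], po = init_pop["payoff"];
    IntegerVector rs = init_pop["rule_s"], ru = init_pop["rule_u"],
                  rd = init_pop["rule_d"], pr = init_pop["personal_rep"],
                  np = init_pop["n_pos"], nu = init_pop["n_neu"],
                  ng = init_pop["n_neg"];
    pop.fusion.assign(f.begin(), f.end());
    pop.payoff.assign(po.begin(), po.end());
    pop.rule_s.assign(rs.begin(), rs.end());
    pop.rule_u.assign(ru.begin(), ru.end());
    pop.rule_d.assign(rd.begin(), rd.end());
    pop.personal_rep.assign(pr.begin(), pr.end());
    pop.n_pos.assign(np.begin(), np.end());
    pop.n_neu.assign(nu.begin(), nu.end());
    pop.n_neg.assign(ng.begin(), ng.end());
    pop.group_rep = as<int>(init_pop["group_rep"]);
  }

  RNGScope scope;

  const bool inter_ostracism =
      par.ostracism_type == 1 || par.ostracism_type == 3;
  const bool repro_ostracism =
      par.ostracism_type == 2 || par.ostracism_type == 3;

  double cum_donations = 0.0, cum_games = 0.0, cum_fusion_sum = 0.0;
  int gen_count = 0;

  int rec_len = record_trajectory ? par.M : 0;
  NumericVector tr_coop(rec_len), tr_fusion(rec_len), tr_payoff(rec_len);
  IntegerVector tr_group(rec_len), tr_donations(rec_len);

  std::vector<int> buf;
  buf.reserve(n);
  Pop child = pop; // shape only; overwritten each generation
  std::vector<bool> keep(n);
  std::vector<double> w(n);
  std::vector<double> ctr(n);
  std::vector<char> ctr_def(n);

  for (int gen = 0; gen < par.M; ++gen) {
    int donations = 0;
    for (int g = 0; g < par.m; ++g) {
      int i = (int)(unif_rand() * (double)n);
      int j = select_partner(i, pop, par, buf);
      double view_self = perceived_rep(pop.fusion[i], pop.fusion[i],
                                       pop.personal_rep[i], pop.group_rep);
      double view_other = perceived_rep(pop.fusion[i], pop.fusion[j],
                                        pop.personal_rep[j], pop.group_rep);
      bool ostracised = false;
      if (inter_ostracism) {
        bool di, dj;
        double ci = ctr_of(pop, i, di), cj = ctr_of(pop, j, dj);
        ostracised = check_ostracism(pop.fusion[i], pop.fusion[j], ci, di,
                                     cj, dj, par);
      }
      bool donated = false;
      if (!ostracised) {
        int bit;
        if (view_other > view_self + par.delta)
          bit = pop.rule_u[i];
        else if (view_other < view_self - par.delta)
          bit = pop.rule_d[i];
        else
          bit = pop.rule_s[i];
        donated = bit != 0;
      }
      bool fused = pop.fusion[i] > 0.0;
      if (donated) {
        pop.personal_rep[i] = clamp_rep(pop.personal_rep[i] + 1);
        if (fused) {
          pop.group_rep = clamp_rep(pop.group_rep + 1);
          pop.n_pos[i] += 1;
        }
        double cost = par.cost +
            (pop.fusion[i] >= par.threshold ? par.extra_cost : 0.0);
        pop.payoff[i] -= cost;
        pop.payoff[j] += par.benefit;
        ++donations;
      } else {
        bool penal = view_other >= view_self;
        if (penal) pop.personal_rep[i] = clamp_rep(pop.personal_rep[i] - 1);
        if (ostracised) {
          if (fused) pop.n_neu[i] += 1; // legitimate from G's perspective
        } else if (penal) {
          if (fused) {
            pop.group_rep = clamp_rep(pop.group_rep - 1);
            pop.n_neg[i] += 1;
          }
        } else {
          if (fused) pop.n_neu[i] += 1;
        }
        pop.payoff[j] += 0.0; // keep payoff update symmetric with R engine
      }
    }

    // metrics over the parent population, before replacement
    long double fsum = 0.0L;
    for (int k = 0; k < n; ++k) fsum += pop.fusion[k];
    cum_donations += (double)donations;
    cum_games += (double)par.m;
    cum_fusion_sum += (double)fsum;
    ++gen_count;

    if (record_trajectory) {
      tr_coop[gen] = cum_games > 0 ? cum_donations / cum_games : NA_REAL;
      tr_fusion[gen] = cum_fusion_sum / ((double)gen_count * (double)n);
      long double psum = 0.0L;
      for (int k = 0; k < n; ++k) psum += pop.payoff[k];
      tr_payoff[gen] = (double)(psum / (long double)n);
      tr_group[gen] = pop.group_rep;
      tr_donations[gen] = donations;
    }

    // selection, reproduction, mutation, reset
    double minp = pop.payoff[0];
    for (int k = 1; k < n; ++k) minp = std::min(minp, pop.payoff[k]);
    double shift = minp < 0.0 ? -minp : 0.0;
    for (int k = 0; k < n; ++k) w[k] = pop.payoff[k] + shift;
    for (int k = 0; k < n; ++k) {
      bool d;
      ctr[k] = ctr_of(pop, k, d);
      ctr_def[k] = d ? 1 : 0;
    }

    for (int i = 0; i < n; ++i) {
      int parent;
      bool restricted = false;
      if (repro_ostracism && pop.fusion[i] >= par.threshold &&
          pop.fusion[i] > 0.0) {
        std::fill(keep.begin(), keep.end(), true);
        bool any_excluded = false;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          if (check_ostracism(pop.fusion[i], pop.fusion[j], ctr[i],
                              ctr_def[i] != 0, ctr[j], ctr_def[j] != 0,
                              par)) {
            keep[j] = false;
            any_excluded = true;
          }
        }
        restricted = any_excluded;
      }
      // roulette walk over the candidate set in index order; the total is
      // accumulated in long double to match R's sum()
      buf.clear();
      if (restricted) {
        for (int k = 0; k < n; ++k)
          if (keep[k]) buf.push_back(k);
        if (buf.empty())
          for (int k = 0; k < n; ++k) buf.push_back(k);
      } else {
        for (int k = 0; k < n; ++k) buf.push_back(k);
      }
      long double tot = 0.0L;
      for (size_t k = 0; k < buf.size(); ++k) tot += w[buf[k]];
      double total = (double)tot;
      double u = unif_rand();
      if (total <= 0.0) {
        parent = buf[(int)(u * (double)buf.size())];
      } else {
        double r = u * total, acc = 0.0;
        parent = buf.back();
        for (size_t k = 0; k < buf.size(); ++k) {
          acc += w[buf[k]];
          if (r < acc) { parent = buf[k]; break; }
        }
      }
      int rs = pop.rule_s[parent], ru = pop.rule_u[parent],
          rd = pop.rule_d[parent];
      double f = pop.fusion[parent];
      if (unif_rand() < par.mu) rs = 1 - rs;
      if (unif_rand() < par.mu) ru = 1 - ru;
      if (unif_rand() < par.mu) rd = 1 - rd;
      if (par.mutate_fusion && unif_rand() < par.mu) f = unif_rand();
      child.rule_s[i] = rs;
      child.rule_u[i] = ru;
      child.rule_d[i] = rd;
      child.fusion[i] = f;
      child.personal_rep[i] = 0;
      child.payoff[i] = 0.0;
      child.n_pos[i] = child.n_neu[i] = child.n_neg[i] = 0;
    }
    child.group_rep = 0;
    std::swap(pop, child);

    if ((gen & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }

  List final_pop = List::create(
      _["fusion"] = NumericVector(pop.fusion.begin(), pop.fusion.end()),
      _["rule_s"] = IntegerVector(pop.rule_s.begin(), pop.rule_s.end()),
      _["rule_u"] = IntegerVector(pop.rule_u.begin(), pop.rule_u.end()),
      _["rule_d"] = IntegerVector(pop.rule_d.begin(), pop.rule_d.end()),
      _["personal_rep"] =
          IntegerVector(pop.personal_rep.begin(), pop.personal_rep.end()),
      _["payoff"] = NumericVector(pop.payoff.begin(), pop.payoff.end()),
      _["n_pos"] = IntegerVector(pop.n_pos.begin(), pop.n_pos.end()),
      _["n_neu"] = IntegerVector(pop.n_neu.begin(), pop.n_neu.end()),
      _["n_neg"] = IntegerVector(pop.n_neg.begin(), pop.n_neg.end()),
      _["group_rep"] = pop.group_rep);

  List metrics = List::create(
      _["cum_donations"] = cum_donations, _["cum_games"] = cum_games,
      _["cum_fusion_sum"] = cum_fusion_sum, _["gen_count"] = gen_count);

  List traj = R_NilValue;
  if (record_trajectory) {
    traj = List::create(_["avg_coop"] = tr_coop, _["avg_fusion"] = tr_fusion,
                        _["mean_payoff"] = tr_payoff,
                        _["group_rep"] = tr_group,
                        _["donations"] = tr_donations);
  }
  return List::create(_["metrics"] = metrics, _["trajectory"] = traj,
                      _["final_pop"] = final_pop);
}
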