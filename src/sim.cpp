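#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven simulation of one mRNA: telegraph (ON/OFF) gated initiation,
// codon-by-codon elongation with steric exclusion, optional frameshift hazard
// inside the insert, optional cap-independent (RAN) initiation at the insert,
// and an initiation shut-off at t_drug (harringtonine).
//
// Uses R's RNG throughout, so results are governed by set.seed() on the R side.
//
// Conventions:
//  - a ribosome's `pos` is the number of codons it has completed (0 on entry);
//    completing codon j uses rate step_rate[j-1]
//  - exclusion: |pos_a - pos_b| >= footprint at all times
//  - a non-frameshifted, non-RAN ribosome terminates on completing ch1_stop;
//    frameshifted and RAN ribosomes terminate on completing codon L
//  - deterministic mode replaces exponential dwells by exact 1/rate dwells
//    (initiation and telegraph stay stochastic); intended for analytic tests

struct Rib {
  int pos;
  bool fs, ran;
  int idx;          // row in the output record
  double next_det;  // scheduled step time (deterministic mode)
};

// [[Rcpp::export]]
List sim_rna_cpp(int L,
                 NumericVector step_rate,   // length L
                 NumericVector fs_hazard,   // length L, per-codon fs probability
                 LogicalVector is_ep1,      // length L
                 LogicalVector is_ep2,      // length L
                 int ch1_stop,
                 int ran_start,             // codon index; RAN ribosome enters at pos ran_start-1
                 double k_on, double k_off, double k_init, double p_ran,
                 int footprint,
                 double t_start, double t_end, double t_drug,
                 bool deterministic) {
  if (step_rate.size() != L) stop("step_rate length mismatch");

  std::vector<Rib> ribs;           // ordered front-first (largest pos first)
  std::vector<double> init_t, end_t;
  std::vector<int> fs_codon;
  std::vector<int> fs_flag, ran_flag;
  std::vector<int> comp_rib, comp_ch;
  std::vector<double> comp_t;
  std::vector<double> toggles;

  double p_on = (k_on + k_off > 0.0) ? k_on / (k_on + k_off) : 1.0;
  bool on = (unif_rand() < p_on);
  bool init_state = on;
  double t = t_start;
  int ran_pos0 = ran_start - 1;

  auto blocked = [&](size_t i) -> bool {
    if (footprint <= 0) return false;  // exclusion off: fully independent
    if (i == 0) return false;
    return (ribs[i - 1].pos - (ribs[i].pos + 1)) < footprint;
  };
  auto record_step = [&](size_t i, double now) {
    Rib &r = ribs[i];
    r.pos += 1;
    int p = r.pos;
    if (!r.fs && !r.ran && fs_hazard[p - 1] > 0.0 &&
        unif_rand() < fs_hazard[p - 1]) {
      r.fs = true;
      fs_flag[r.idx] = 1;
      fs_codon[r.idx] = p;
    }
    if (is_ep1[p - 1] && !r.ran) {
      comp_rib.push_back(r.idx); comp_ch.push_back(1); comp_t.push_back(now);
    }
    if ((r.fs || r.ran) && is_ep2[p - 1]) {
      comp_rib.push_back(r.idx); comp_ch.push_back(2); comp_t.push_back(now);
    }
    int stp = (r.fs || r.ran) ? L : ch1_stop;
    if (p >= stp) {
      end_t[r.idx] = now;
      ribs.erase(ribs.begin() + i);
    } else {
      r.next_det = now + 1.0 / step_rate[p];
    }
  };
  auto do_init = [&](double now, bool ran, int pos0) {
    Rib r;
    r.pos = pos0; r.fs = false; r.ran = ran;
    r.idx = (int)init_t.size();
    r.next_det = now + 1.0 / step_rate[pos0];
    init_t.push_back(now);
    end_t.push_back(NA_REAL);
    fs_codon.push_back(NA_INTEGER);
    fs_flag.push_back(0);
    ran_flag.push_back(ran ? 1 : 0);
    // keep front-first order
    size_t i = 0;
    while (i < ribs.size() && ribs[i].pos > pos0) ++i;
    ribs.insert(ribs.begin() + i, r);
  };

  long guard = 0;
  const long guard_max = 200000000L;
  while (true) {
    if (++guard > guard_max) stop("event budget exceeded");
    bool init_ok = on && t < t_drug && k_init > 0.0 &&
                   (ribs.empty() || ribs.back().pos >= footprint);
    bool ran_ok = p_ran > 0.0 && t < t_drug;
    if (ran_ok) {
      for (size_t i = 0; i < ribs.size(); ++i)
        if (std::abs(ribs[i].pos - ran_pos0) < footprint) { ran_ok = false; break; }
    }
    double r_tog = on ? k_off : k_on;
    double r_init = init_ok ? k_init : 0.0;
    double r_ran = ran_ok ? p_ran : 0.0;

    if (!deterministic) {
      double total = r_tog + r_init + r_ran;
      for (size_t i = 0; i < ribs.size(); ++i)
        if (!blocked(i)) total += step_rate[ribs[i].pos];
      if (total <= 0.0) break;
      t += exp_rand() / total;
      if (t >= t_end) break;
      double u = unif_rand() * total;
      if (u < r_tog) {
        on = !on; toggles.push_back(t);
      } else if (u < r_tog + r_init) {
        if (t <= t_drug) do_init(t, false, 0);
      } else if (u < r_tog + r_init + r_ran) {
        if (t <= t_drug) do_init(t, true, ran_pos0);
      } else {
        double acc = r_tog + r_init + r_ran;
        for (size_t i = 0; i < ribs.size(); ++i) {
          if (blocked(i)) continue;
          acc += step_rate[ribs[i].pos];
          if (u < acc) { record_step(i, t); break; }
        }
      }
    } else {
      double total_exp = r_tog + r_init + r_ran;
      double t_exp = (total_exp > 0.0) ? t + exp_rand() / total_exp : R_PosInf;
      double t_det = R_PosInf; int which = -1;
      for (size_t i = 0; i < ribs.size(); ++i) {
        if (blocked(i)) continue;
        double cand = std::max(ribs[i].next_det, t);
        if (cand < t_det) { t_det = cand; which = (int)i; }
      }
      double t_next = std::min(t_exp, t_det);
      if (!R_FINITE(t_next) || t_next >= t_end) break;
      if (t_det <= t_exp) {
        t = t_det;
        record_step((size_t)which, t);
      } else {
        t = t_exp;
        double u = unif_rand() * total_exp;
        if (u < r_tog) { on = !on; toggles.push_back(t); }
        else if (u < r_tog + r_init) { if (t <= t_drug) do_init(t, false, 0); }
        else { if (t <= t_drug) do_init(t, true, ran_pos0); }
      }
    }
  }

  // positions of ribosomes still attached at t_end
  std::vector<int> alive_idx, alive_pos;
  for (size_t i = 0; i < ribs.size(); ++i) {
    alive_idx.push_back(ribs[i].idx);
    alive_pos.push_back(ribs[i].pos);
  }

  return List::create(
    _["init_time"] = wrap(init_t),
    _["end_time"] = wrap(end_t),
    _["fs"] = wrap(fs_flag),
    _["ran"] = wrap(ran_flag),
    _["fs_codon"] = wrap(fs_codon),
    _["comp_rib"] = wrap(comp_rib),   // 0-based row into the ribosome record
    _["comp_ch"] = wrap(comp_ch),
    _["comp_time"] = wrap(comp_t),
    _["toggle_times"] = wrap(toggles),
    _["init_state_on"] = init_state,
    _["alive_idx"] = wrap(alive_idx),
    _["alive_pos"] = wrap(alive_pos));
}
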