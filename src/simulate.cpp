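// Event-driven Monte Carlo core for MS2 transcription-site simulation.
//
// Initiation, gene-state switching, termination and (by default) single
// nucleotide elongation steps are all single rate-limiting (exponential)
// events; per-nucleotide steps may instead be deterministic (1/v waits).
// Steric exclusion: a trailing polymerase never approaches an elongating
// leader closer than the footprint, and initiation is blocked while the
// promoter-proximal footprint is occupied. Exponential clocks are redrawn
// on rate changes and blocked arrivals are discarded (exact thinning).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Pol {
  int pos;            // nt position of active site, 0..G
  int speed_idx;      // 0 = low, 1 = high (two-speed modes)
  double init_time;
  double next_time;   // next step attempt (elongating) or release (terminating)
  double next_switch; // next own-speed switch (independent mode), else +inf
  int phase;          // 0 elongating, 1 terminating
  double bleach_L;    // loops rendered dark by a bleach event
};

struct GeneProc {
  // type: 0 constant, 1 discrete CTMC, 2 continuum telegraph + ladder
  int type;
  double rate;                 // current initiation rate
  int state;                   // discrete: 0..K-1; continuum: ladder level
  bool on;                     // continuum telegraph state
  NumericVector rates;         // discrete state rates
  NumericMatrix Q;             // discrete generator
  double k_on, k_off, step_ts, p_up;
  NumericVector levels;
  double next_event;
};

double draw_exp(double rate) {
  if (rate <= 0.0) return INF;
  return R::exp_rand() / rate;
}

void gene_schedule(GeneProc& g, double t) {
  if (g.type == 0) { g.next_event = INF; return; }
  if (g.type == 1) {
    g.next_event = t + draw_exp(-g.Q(g.state, g.state));
  } else {
    double tot = g.on ? (g.k_off + 1.0 / g.step_ts) : g.k_on;
    g.next_event = t + draw_exp(tot);
  }
}

void gene_update_rate(GeneProc& g) {
  if (g.type == 0) return;
  if (g.type == 1) { g.rate = g.rates[g.state]; return; }
  g.rate = g.on ? g.levels[g.state] : 0.0;
}

// fire one gene-process event at time t
void gene_fire(GeneProc& g, double t) {
  if (g.type == 1) {
    double u = unif_rand() * (-g.Q(g.state, g.state));
    int K = g.rates.size();
    double acc = 0.0;
    int nxt = g.state;
    for (int j = 0; j < K; ++j) {
      if (j == g.state) continue;
      acc += g.Q(g.state, j);
      if (u <= acc) { nxt = j; break; }
    }
    g.state = nxt;
  } else {
    if (!g.on) {
      g.on = true;                      // re-enter at the level it left
    } else {
      double tot = g.k_off + 1.0 / g.step_ts;
      if (unif_rand() * tot < g.k_off) {
        g.on = false;
      } else {
        // reflecting ladder step: proposals off the ends hold in place
        int n = g.levels.size();
        if (unif_rand() < g.p_up) { if (g.state < n - 1) g.state++; }
        else                      { if (g.state > 0) g.state--; }
      }
    }
  }
  gene_update_rate(g);
  gene_schedule(g, t);
}

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int transcript_nt, double array_offset_nt, double array_length_nt,
              double n_loops, double footprint_nt, double term_mean_s,
              int elong_mode,      // 0 const, 1 global two-speed, 2 independent
              double v_const, double v_low, double v_high,
              double elong_switch_ts, bool step_deterministic,
              int init_type,       // 0 const, 1 discrete, 2 continuum
              double init_rate, NumericVector state_rates, NumericMatrix Q,
              double k_on, double k_off, NumericVector levels,
              double ladder_step_ts, double p_up,
              double frame_interval_s, int n_frames, double burn_in_s,
              double bleach_time_s, bool record_events,
              bool term_deterministic) {
  const int G = transcript_nt;
  const int fp = (int)std::ceil(footprint_nt);
  double t = -burn_in_s;
  const double t_end = (double)n_frames * frame_interval_s;

  GeneProc g;
  g.type = init_type; g.rates = state_rates; g.Q = Q;
  g.k_on = k_on; g.k_off = k_off; g.step_ts = ladder_step_ts; g.p_up = p_up;
  g.levels = levels;
  if (init_type == 0) { g.rate = init_rate; g.state = 0; g.on = true; }
  else if (init_type == 1) {
    g.state = (int)std::floor(unif_rand() * state_rates.size());
    if (g.state >= state_rates.size()) g.state = state_rates.size() - 1;
    gene_update_rate(g);
  } else {
    // stationary warm start: on w.p. k_on/(k_on+k_off), uniform ladder level
    double pon = (k_on + k_off) > 0 ? k_on / (k_on + k_off) : 1.0;
    g.on = unif_rand() < pon;
    g.state = (int)std::floor(unif_rand() * levels.size());
    if (g.state >= levels.size()) g.state = levels.size() - 1;
    gene_update_rate(g);
  }
  gene_schedule(g, t);

  int gspeed_idx = unif_rand() < 0.5 ? 0 : 1;   // global two-speed state
  double t_gspeed = (elong_mode == 1) ? t + draw_exp(1.0 / elong_switch_ts) : INF;

  auto pol_speed = [&](const Pol& p) -> double {
    if (elong_mode == 0) return v_const;
    int idx = (elong_mode == 1) ? gspeed_idx : p.speed_idx;
    return idx == 0 ? v_low : v_high;
  };
  auto step_wait = [&](double v) -> double {
    return step_deterministic ? 1.0 / v : draw_exp(v);
  };
  auto loop_sig = [&](double pos) -> double {
    double f = (pos - array_offset_nt) / array_length_nt;
    if (f < 0) f = 0; if (f > 1) f = 1;
    return n_loops * f;
  };

  std::vector<Pol> pols;            // ordered by initiation time (front first)
  pols.reserve(256);
  double t_init = t + draw_exp(g.rate);
  int frame_idx = 0;
  double t_frame = frame_interval_s; // first observation
  bool bleach_pending = std::isfinite(bleach_time_s);
  double t_bleach = bleach_pending ? bleach_time_s : INF;

  NumericVector sig(n_frames), rate_at(n_frames);
  IntegerVector state_at(n_frames), inits(n_frames), resident(n_frames);
  IntegerVector cum_init(n_frames), cum_rel(n_frames);
  std::vector<double> rel_times, transit_times, init_times;
  long long n_init_total = 0, n_rel_total = 0;
  int frame_init_count = 0;

  auto promoter_blocked = [&]() -> bool {
    for (int i = (int)pols.size() - 1; i >= 0; --i) {
      if (pols[i].phase == 0) return pols[i].pos < fp;
    }
    return false;
  };
  // nearest elongating leader position ahead of index i (or G + fp if none)
  auto leader_pos = [&](int i) -> int {
    for (int j = i - 1; j >= 0; --j)
      if (pols[j].phase == 0) return pols[j].pos;
    return G + fp + 1;
  };

  while (frame_idx < n_frames) {
    // next event
    double tn = t_frame;
    int kind = 0, who = -1;          // 0 frame, 1 init, 2 gene, 3 gspeed,
                                     // 4 pol step/release, 5 pol speed switch, 6 bleach
    if (t_init < tn) { tn = t_init; kind = 1; }
    if (g.next_event < tn) { tn = g.next_event; kind = 2; }
    if (t_gspeed < tn) { tn = t_gspeed; kind = 3; }
    if (t_bleach < tn) { tn = t_bleach; kind = 6; }
    for (int i = 0; i < (int)pols.size(); ++i) {
      if (pols[i].next_time < tn) { tn = pols[i].next_time; kind = 4; who = i; }
      if (pols[i].next_switch < tn) { tn = pols[i].next_switch; kind = 5; who = i; }
    }
    t = tn;

    switch (kind) {
    case 0: {  // frame observation
      double s = 0.0;
      int res = 0;
      for (const Pol& p : pols) {
        double Lp = p.phase == 1 ? n_loops : loop_sig((double)p.pos);
        s += std::max(Lp - p.bleach_L, 0.0);
        ++res;
      }
      sig[frame_idx] = s;
      rate_at[frame_idx] = g.rate;
      state_at[frame_idx] = (g.type == 2 && !g.on) ? 0 : g.state + 1;
      inits[frame_idx] = frame_init_count;
      resident[frame_idx] = res;
      cum_init[frame_idx] = (int)n_init_total;
      cum_rel[frame_idx] = (int)n_rel_total;
      frame_init_count = 0;
      ++frame_idx;
      t_frame += frame_interval_s;
      break;
    }
    case 1: {  // initiation attempt
      if (!promoter_blocked()) {
        Pol p;
        p.pos = 0;
        p.speed_idx = (elong_mode == 2) ? (unif_rand() < 0.5 ? 0 : 1) : gspeed_idx;
        p.init_time = t;
        p.phase = 0;
        p.bleach_L = 0.0;
        p.next_time = t + step_wait(elong_mode == 0 ? v_const
                       : ((elong_mode == 1 ? gspeed_idx : p.speed_idx) ? v_high : v_low));
        p.next_switch = (elong_mode == 2) ? t + draw_exp(1.0 / elong_switch_ts) : INF;
        pols.push_back(p);
        ++n_init_total;
        if (t > 0 && t <= t_end) {
          ++frame_init_count;
          if (record_events) init_times.push_back(t);
        }
      }
      t_init = t + draw_exp(g.rate);
      break;
    }
    case 2: {  // gene-state process event
      gene_fire(g, t);
      t_init = t + draw_exp(g.rate);   // memoryless redraw at new rate
      break;
    }
    case 3: {  // global elongation speed switch
      gspeed_idx = 1 - gspeed_idx;
      t_gspeed = t + draw_exp(1.0 / elong_switch_ts);
      for (Pol& p : pols)
        if (p.phase == 0) p.next_time = t + step_wait(pol_speed(p));
      break;
    }
    case 4: {  // polymerase step attempt or release
      Pol& p = pols[who];
      if (p.phase == 1) {
        ++n_rel_total;
        if (t > 0 && t <= t_end && record_events) rel_times.push_back(t);
        pols.erase(pols.begin() + who);
      } else {
        bool blocked = (leader_pos(who) - p.pos) <= fp;
        if (!blocked) {
          p.pos += 1;
          if (p.pos >= G) {
            p.phase = 1;
            double tt = t - p.init_time;
            if (t > 0 && t <= t_end && record_events) transit_times.push_back(tt);
            p.next_time = t + (term_mean_s <= 0 ? 0.0 :
                               (term_deterministic ? term_mean_s
                                                   : draw_exp(1.0 / term_mean_s)));
            p.next_switch = INF;
            continue;
          }
        }
        p.next_time = t + step_wait(pol_speed(p));
      }
      break;
    }
    case 5: {  // independent-mode speed switch
      Pol& p = pols[who];
      p.speed_idx = 1 - p.speed_idx;
      p.next_switch = t + draw_exp(1.0 / elong_switch_ts);
      if (p.phase == 0) p.next_time = t + step_wait(pol_speed(p));
      break;
    }
    case 6: {  // photobleach: all currently synthesized loops go dark
      for (Pol& p : pols) {
        double Lp = p.phase == 1 ? n_loops : loop_sig((double)p.pos);
        p.bleach_L = Lp;
      }
      t_bleach = INF;
      break;
    }
    }
  }

  return List::create(
    _["signal"] = sig, _["rate"] = rate_at, _["state"] = state_at,
    _["initiations"] = inits, _["resident"] = resident,
    _["cum_initiations"] = cum_init, _["cum_releases"] = cum_rel,
    _["release_times"] = wrap(rel_times),
    _["transit_times"] = wrap(transit_times),
    _["init_times"] = wrap(init_times));
}

// Initiation events alone (no elongation bookkeeping): used for cheap
// steady-state cytoplasmic pools where only production times matter.
// [[Rcpp::export(name = ".sim_init_events")]]
NumericVector sim_init_events(int init_type, double init_rate,
                              NumericVector state_rates, NumericMatrix Q,
                              double k_on, double k_off, NumericVector levels,
                              double ladder_step_ts, double p_up,
                              double duration_s, double burn_in_s) {
  GeneProc g;
  g.type = init_type; g.rates = state_rates; g.Q = Q;
  g.k_on = k_on; g.k_off = k_off; g.step_ts = ladder_step_ts; g.p_up = p_up;
  g.levels = levels;
  double t = -burn_in_s;
  if (init_type == 0) { g.rate = init_rate; g.state = 0; g.on = true; }
  else if (init_type == 1) {
    g.state = (int)std::floor(unif_rand() * state_rates.size());
    if (g.state >= state_rates.size()) g.state = state_rates.size() - 1;
    gene_update_rate(g);
  } else {
    double pon = (k_on + k_off) > 0 ? k_on / (k_on + k_off) : 1.0;
    g.on = unif_rand() < pon;
    g.state = (int)std::floor(unif_rand() * levels.size());
    if (g.state >= levels.size()) g.state = levels.size() - 1;
    gene_update_rate(g);
  }
  gene_schedule(g, t);
  std::vector<double> ev;
  double t_init = t + draw_exp(g.rate);
  while (true) {
    if (t_init < g.next_event) {
      t = t_init;
      if (t > duration_s) break;
      if (t > 0) ev.push_back(t);
      t_init = t + draw_exp(g.rate);
    } else {
      t = g.next_event;
      if (t > duration_s) break;
      gene_fire(g, t);
      t_init = t + draw_exp(g.rate);
    }
  }
  return wrap(ev);
}
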