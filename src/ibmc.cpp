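// Individual-based Monte Carlo epidemic core.
//
// N structureless agents diffuse on a periodic square of side L with fixed
// step length delta_R per MC step tau (D = delta_R^2 / (4 tau)).  Susceptible
// agents within r_infect of an infectious agent are infected with probability
// p_infect per infectious neighbour per step (or once per contact entry, see
// infection_mode).  Disease course: incubation (not infectious) -> infectious
// -> immune (waning) or dead; vaccination grants a delayed, waning immunity
// window.  All randomness comes from a private xoshiro256++ stream seeded
// from the user seed, so a fixed seed gives a bit-identical trajectory.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

// ---- PRNG: splitmix64 seeding + xoshiro256++ -------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal, Box-Muller (polar form avoided: trig is fine at event rate)
  double norm() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// Truncated-normal duration: resample until above the positive floor.
// sd == 0 degenerates to the mean exactly.
double draw_duration(Xoshiro &rng, double mean, double sd, double floor_ = 0.1) {
  if (sd <= 0.0) return mean;
  for (;;) {
    double d = mean + sd * rng.norm();
    if (d > floor_) return d;
  }
}

// ---- agent states ----------------------------------------------------------

enum Status { HEALTHY = 0, INCUBATING = 1, INFECTIOUS = 2, IMMUNE = 3, DEAD = 4 };

const double T_INF = 1e30;  // "no scheduled event"

struct Params {
  int    N;
  double L, r_infect, p_infect, p_fatal, p_vacc;
  double t_incubation_mean, t_incubation_sd;
  double t_infect_mean, t_infect_sd;
  double t_vacc_mean, t_vacc_sd;
  double t_infect_immune_mean, t_infect_immune_sd;
  double t_vacc_immune_mean, t_vacc_immune_sd;
  double tau, delta_R, t_end;
  int    infection_mode;     // 0 = per_step, 1 = per_contact_entry
  bool   revaccinate;
};

Params read_params(const List &p) {
  Params q;
  q.N = as<int>(p["N"]);
  q.L = as<double>(p["L"]);
  q.r_infect = as<double>(p["r_infect"]);
  q.p_infect = as<double>(p["p_infect"]);
  q.p_fatal  = as<double>(p["p_fatal"]);
  q.p_vacc   = as<double>(p["p_vacc"]);
  NumericVector ti = p["t_incubation"], tf = p["t_infect"], tv = p["t_vacc"],
                tii = p["t_infect_immune"], tvi = p["t_vacc_immune"];
  q.t_incubation_mean = ti[0];    q.t_incubation_sd = ti[1];
  q.t_infect_mean = tf[0];        q.t_infect_sd = tf[1];
  q.t_vacc_mean = tv[0];          q.t_vacc_sd = tv[1];
  q.t_infect_immune_mean = tii[0]; q.t_infect_immune_sd = tii[1];
  q.t_vacc_immune_mean = tvi[0];  q.t_vacc_immune_sd = tvi[1];
  q.tau = as<double>(p["tau"]);
  q.delta_R = as<double>(p["delta_R"]);
  q.t_end = as<double>(p["t_end"]);
  std::string mode = as<std::string>(p["infection_mode"]);
  q.infection_mode = (mode == "per_contact_entry") ? 1 : 0;
  q.revaccinate = as<bool>(p["revaccinate_on_waning"]);
  return q;
}

struct Pop {
  std::vector<double> x, y;
  std::vector<int>    state;       // Status
  std::vector<int>    vaccinated;  // bookkeeping flag (cyan class)
  std::vector<int>    fated;       // fated to die, decided at infection onset
  std::vector<double> ev_time;     // next state-machine event (T_INF if none)
  std::vector<double> vstart, vend;  // vaccine-immunity window
  double t;                        // current time (days)
  long long k;                     // current MC step index
  int n_incub, n_infectious, n_dead;
  int ever_infected;
  double peak_infectious;          // max simultaneous infectious count
  double extinction_time;          // first time with no incubating/infectious, -1 if never
  Xoshiro rng;
};

inline double wrap(double v, double L) {
  if (v >= L) v -= L; else if (v < 0.0) v += L;
  return v;
}

// protected = any active immunity window (infection-derived status, or
// vaccine window covering the current time)
inline bool is_protected(const Pop &P, int i) {
  if (P.state[i] == IMMUNE) return true;
  if (P.state[i] == HEALTHY && P.t >= P.vstart[i] && P.t < P.vend[i]) return true;
  return false;
}

inline bool is_susceptible(const Pop &P, int i) {
  return P.state[i] == HEALTHY && !(P.t >= P.vstart[i] && P.t < P.vend[i]);
}

void infect_agent(Pop &P, const Params &q, int i, double t_now) {
  double d1 = draw_duration(P.rng, q.t_incubation_mean, q.t_incubation_sd);
  P.state[i] = INCUBATING;
  P.ev_time[i] = t_now + d1;
  P.fated[i] = (P.rng.unif() < q.p_fatal) ? 1 : 0;
  P.n_incub++;
  P.ever_infected++;
}

// fire all state-machine events scheduled at or before t for agent i
void fire_events(Pop &P, const Params &q, int i, double t) {
  while (P.ev_time[i] <= t) {
    switch (P.state[i]) {
    case INCUBATING: {  // incubation over -> infectious
      double t0 = P.ev_time[i];
      double d2 = draw_duration(P.rng, q.t_infect_mean, q.t_infect_sd);
      P.state[i] = INFECTIOUS;
      P.n_incub--; P.n_infectious++;
      if (P.fated[i]) {
        P.ev_time[i] = t0 + P.rng.unif() * d2;  // death inside infectious period
      } else {
        P.ev_time[i] = t0 + d2;
      }
      break;
    }
    case INFECTIOUS: {
      double t0 = P.ev_time[i];
      P.n_infectious--;
      if (P.fated[i]) {
        P.state[i] = DEAD;
        P.ev_time[i] = T_INF;
        P.n_dead++;
      } else {  // recover with waning infection-derived immunity
        P.state[i] = IMMUNE;
        P.ev_time[i] = t0 + draw_duration(P.rng, q.t_infect_immune_mean,
                                          q.t_infect_immune_sd);
      }
      break;
    }
    case IMMUNE: {  // infection-derived immunity waned
      P.state[i] = HEALTHY;
      // with booster renewal, pick the window-renewal event back up (it may
      // lie in the past if the window expired during the disease course)
      P.ev_time[i] = (q.revaccinate && P.vaccinated[i]) ? P.vend[i] : T_INF;
      break;
    }
    case HEALTHY: {  // only reachable when revaccination renews waned windows
      if (q.revaccinate && P.vaccinated[i] && P.ev_time[i] >= P.vend[i]) {
        double t0 = P.ev_time[i];
        P.vstart[i] = t0 + draw_duration(P.rng, q.t_vacc_mean, q.t_vacc_sd);
        P.vend[i] = P.vstart[i] + draw_duration(P.rng, q.t_vacc_immune_mean,
                                                q.t_vacc_immune_sd);
        P.ev_time[i] = P.vend[i];
      } else {
        P.ev_time[i] = T_INF;
      }
      break;
    }
    default:
      P.ev_time[i] = T_INF;
    }
  }
}

Pop init_pop(const Params &q, uint64_t seed) {
  Pop P;
  int N = q.N;
  P.x.resize(N); P.y.resize(N);
  P.state.assign(N, HEALTHY);
  P.vaccinated.assign(N, 0);
  P.fated.assign(N, 0);
  P.ev_time.assign(N, T_INF);
  P.vstart.assign(N, T_INF);
  P.vend.assign(N, T_INF);
  P.t = 0.0; P.k = 0;
  P.n_incub = P.n_infectious = P.n_dead = 0;
  P.ever_infected = 0;
  P.peak_infectious = 0.0;
  P.extinction_time = -1.0;
  P.rng.seed(seed);

  for (int i = 0; i < N; ++i) {
    P.x[i] = P.rng.unif() * q.L;
    P.y[i] = P.rng.unif() * q.L;
  }
  // index case: one randomly selected agent enters incubation at t = 0
  int idx = (int)(P.rng.unif() * N);
  if (idx >= N) idx = N - 1;
  infect_agent(P, q, idx, 0.0);
  // remaining healthy agents vaccinate independently with probability p_vacc
  for (int i = 0; i < N; ++i) {
    if (i == idx) continue;
    if (P.rng.unif() < q.p_vacc) {
      P.vaccinated[i] = 1;
      P.vstart[i] = draw_duration(P.rng, q.t_vacc_mean, q.t_vacc_sd);
      P.vend[i] = P.vstart[i] + draw_duration(P.rng, q.t_vacc_immune_mean,
                                              q.t_vacc_immune_sd);
      if (q.revaccinate) P.ev_time[i] = P.vend[i];
    }
  }
  return P;
}

// 4096 precomputed unit directions; one RNG word selects a direction.
struct DirTable {
  std::vector<double> cx, cy;
  DirTable() : cx(4096), cy(4096) {
    for (int i = 0; i < 4096; ++i) {
      double a = (2.0 * M_PI * i) / 4096.0;
      cx[i] = std::cos(a); cy[i] = std::sin(a);
    }
  }
};
static const DirTable DIRS;

// cell list over susceptible agents (cell size >= r_infect)
struct CellList {
  int ncx;
  double cell;
  std::vector<int> head, nxt, used;

  void setup(double L, double r_infect, int N) {
    ncx = (int)std::floor(L / r_infect);
    if (ncx < 1) ncx = 1;
    if (ncx > 4096) ncx = 4096;
    cell = L / ncx;
    head.assign((size_t)ncx * ncx, -1);
    nxt.assign(N, -1);
    used.clear();
    used.reserve(N);
  }

  inline int cell_of(double x, double y) const {
    int cx = (int)(x / cell), cy = (int)(y / cell);
    if (cx >= ncx) cx = ncx - 1;
    if (cy >= ncx) cy = ncx - 1;
    return cy * ncx + cx;
  }

  void clear_used() {
    for (int c : used) head[c] = -1;
    used.clear();
  }

  void insert(int i, double x, double y) {
    int c = cell_of(x, y);
    if (head[c] == -1) used.push_back(c);
    nxt[i] = head[c];
    head[c] = i;
  }
};

// advance nsteps MC steps (movement + infection + events)
void advance(Pop &P, const Params &q, long long nsteps,
             CellList &cl, std::unordered_set<int64_t> *prev_pairs) {
  const int N = q.N;
  const double L = q.L, dR = q.delta_R, r2 = q.r_infect * q.r_infect;
  const double half = 0.5 * L;
  std::vector<int> newly;
  std::unordered_set<int64_t> cur_pairs;

  for (long long s = 0; s < nsteps; ++s) {
    P.k++;
    double t_new = P.k * q.tau;

    bool extinct = (P.n_incub + P.n_infectious == 0);
    if (!extinct) {
      // 1) move all non-dead agents one step of length delta_R
      for (int i = 0; i < N; ++i) {
        if (P.state[i] == DEAD) continue;
        int d = (int)(P.rng.next() >> 52);  // 12 bits -> direction table
        P.x[i] = wrap(P.x[i] + dR * DIRS.cx[d], L);
        P.y[i] = wrap(P.y[i] + dR * DIRS.cy[d], L);
      }

      // 2) synchronous infection sweep on post-move positions
      if (P.n_infectious > 0 && q.p_infect > 0.0) {
        cl.clear_used();
        for (int i = 0; i < N; ++i)
          if (is_susceptible(P, i)) cl.insert(i, P.x[i], P.y[i]);

        newly.clear();
        if (q.infection_mode == 1) cur_pairs.clear();
        for (int i = 0; i < N; ++i) {
          if (P.state[i] != INFECTIOUS) continue;
          int cx = (int)(P.x[i] / cl.cell), cy = (int)(P.y[i] / cl.cell);
          if (cx >= cl.ncx) cx = cl.ncx - 1;
          if (cy >= cl.ncx) cy = cl.ncx - 1;
          for (int ox = -1; ox <= 1; ++ox) {
            int ccx = cx + ox;
            if (ccx < 0) ccx += cl.ncx; else if (ccx >= cl.ncx) ccx -= cl.ncx;
            for (int oy = -1; oy <= 1; ++oy) {
              int ccy = cy + oy;
              if (ccy < 0) ccy += cl.ncx; else if (ccy >= cl.ncx) ccy -= cl.ncx;
              for (int j = cl.head[ccy * cl.ncx + ccx]; j != -1; j = cl.nxt[j]) {
                if (P.state[j] != HEALTHY) continue;  // already hit this sweep
                double dx = P.x[i] - P.x[j];
                double dy = P.y[i] - P.y[j];
                if (dx > half) dx -= L; else if (dx < -half) dx += L;
                if (dy > half) dy -= L; else if (dy < -half) dy += L;
                if (dx * dx + dy * dy > r2) continue;
                bool trial = true;
                if (q.infection_mode == 1) {
                  int64_t key = (int64_t)i * N + j;
                  cur_pairs.insert(key);
                  if (prev_pairs->count(key)) trial = false;  // still in range
                }
                if (trial && P.rng.unif() < q.p_infect) newly.push_back(j);
              }
            }
          }
        }
        // fire the infections after the sweep (synchronous update, index order)
        for (size_t m = 0; m < newly.size(); ++m)
          if (P.state[newly[m]] == HEALTHY) infect_agent(P, q, newly[m], t_new);
        if (q.infection_mode == 1) prev_pairs->swap(cur_pairs);
      }

      // 3) scheduled transitions, agent-index order
      for (int i = 0; i < N; ++i)
        if (P.ev_time[i] <= t_new) fire_events(P, q, i, t_new);

      P.t = t_new;
      if (P.n_infectious > P.peak_infectious) P.peak_infectious = P.n_infectious;
      if (P.n_incub + P.n_infectious == 0 && P.extinction_time < 0)
        P.extinction_time = P.t;
    } else {
      // epidemic extinct: no movement or infection can matter; jump to the
      // next scheduled event (or the end of this advance call)
      double tmin = T_INF;
      for (int i = 0; i < N; ++i)
        if (P.ev_time[i] < tmin) tmin = P.ev_time[i];
      long long k_ev = (tmin >= T_INF) ? (P.k + nsteps)
                     : (long long)std::ceil(tmin / q.tau - 1e-9);
      long long k_stop = P.k - 1 + (nsteps - s);  // last step of this call
      if (k_ev > k_stop) k_ev = k_stop;
      if (k_ev < P.k) k_ev = P.k;
      s += (k_ev - P.k);       // consume the skipped steps
      P.k = k_ev;
      t_new = P.k * q.tau;
      for (int i = 0; i < N; ++i)
        if (P.ev_time[i] <= t_new) fire_events(P, q, i, t_new);
      P.t = t_new;
    }
  }
}

}  // namespace

// counts of the five exclusive reporting classes + vaccinated bookkeeping
static IntegerVector class_counts(const Pop &P) {
  int healthy = 0, incub = 0, infectious = 0, immune = 0, dead = 0, vacc = 0;
  int N = (int)P.state.size();
  for (int i = 0; i < N; ++i) {
    switch (P.state[i]) {
    case INCUBATING: incub++; break;
    case INFECTIOUS: infectious++; break;
    case DEAD: dead++; break;
    case IMMUNE: immune++; break;
    default:
      if (P.t >= P.vstart[i] && P.t < P.vend[i]) immune++; else healthy++;
    }
    if (P.vaccinated[i]) vacc++;
  }
  return IntegerVector::create(healthy, incub, infectious, immune, dead, vacc);
}

static List pop_to_list(const Pop &P) {
  int N = (int)P.state.size();
  NumericVector x(N), y(N), ev(N), vs(N), ve(N);
  IntegerVector st(N), vc(N), fd(N);
  for (int i = 0; i < N; ++i) {
    x[i] = P.x[i]; y[i] = P.y[i];
    st[i] = P.state[i]; vc[i] = P.vaccinated[i]; fd[i] = P.fated[i];
    ev[i] = P.ev_time[i]; vs[i] = P.vstart[i]; ve[i] = P.vend[i];
  }
  // stash the 64-bit RNG state losslessly as pairs of 32-bit halves
  IntegerVector rng_lo(4), rng_hi(4);
  for (int i = 0; i < 4; ++i) {
    rng_lo[i] = (int32_t)(P.rng.s[i] & 0xffffffffULL);
    rng_hi[i] = (int32_t)(P.rng.s[i] >> 32);
  }
  return List::create(
    _["x"] = x, _["y"] = y, _["state"] = st, _["vaccinated"] = vc,
    _["fated"] = fd, _["ev_time"] = ev, _["vacc_start"] = vs, _["vacc_end"] = ve,
    _["t"] = P.t, _["k"] = (double)P.k,
    _["n_incubating"] = P.n_incub, _["n_infectious"] = P.n_infectious,
    _["n_dead"] = P.n_dead, _["ever_infected"] = P.ever_infected,
    _["peak_infectious"] = P.peak_infectious,
    _["extinction_time"] = P.extinction_time,
    _["rng_lo"] = rng_lo, _["rng_hi"] = rng_hi);
}

static Pop pop_from_list(const List &l) {
  Pop P;
  NumericVector x = l["x"], y = l["y"], ev = l["ev_time"],
                vs = l["vacc_start"], ve = l["vacc_end"];
  IntegerVector st = l["state"], vc = l["vaccinated"], fd = l["fated"],
                rng_lo = l["rng_lo"], rng_hi = l["rng_hi"];
  int N = x.size();
  P.x.assign(x.begin(), x.end());
  P.y.assign(y.begin(), y.end());
  P.state.assign(st.begin(), st.end());
  P.vaccinated.assign(vc.begin(), vc.end());
  P.fated.assign(fd.begin(), fd.end());
  P.ev_time.assign(ev.begin(), ev.end());
  P.vstart.assign(vs.begin(), vs.end());
  P.vend.assign(ve.begin(), ve.end());
  P.t = as<double>(l["t"]);
  P.k = (long long)as<double>(l["k"]);
  P.n_incub = as<int>(l["n_incubating"]);
  P.n_infectious = as<int>(l["n_infectious"]);
  P.n_dead = as<int>(l["n_dead"]);
  P.ever_infected = as<int>(l["ever_infected"]);
  P.peak_infectious = as<double>(l["peak_infectious"]);
  P.extinction_time = as<double>(l["extinction_time"]);
  for (int i = 0; i < 4; ++i)
    P.rng.s[i] = ((uint64_t)(uint32_t)rng_hi[i] << 32) | (uint32_t)rng_lo[i];
  return P;
}

// [[Rcpp::export]]
List ibmc_cpp_init(List params, double seed) {
  Params q = read_params(params);
  Pop P = init_pop(q, (uint64_t)seed);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List ibmc_cpp_advance(List pop, List params, double nsteps) {
  Params q = read_params(params);
  Pop P = pop_from_list(pop);
  CellList cl;
  cl.setup(q.L, q.r_infect, q.N);
  std::unordered_set<int64_t> pairs;
  advance(P, q, (long long)nsteps, cl, &pairs);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List ibmc_cpp_run(List params, double seed, double record_stride) {
  Params q = read_params(params);
  Pop P = init_pop(q, (uint64_t)seed);
  CellList cl;
  cl.setup(q.L, q.r_infect, q.N);
  std::unordered_set<int64_t> pairs;

  long long nsteps = (long long)std::ceil(q.t_end / q.tau - 1e-9);
  long long rec_every = (long long)std::llround(record_stride / q.tau);
  if (rec_every < 1) rec_every = 1;
  long long nrec = nsteps / rec_every + 2;

  NumericVector time(nrec);
  NumericMatrix counts(nrec, 6);
  int row = 0;
  {
    IntegerVector c0 = class_counts(P);
    time[row] = 0.0;
    for (int j = 0; j < 6; ++j) counts(row, j) = c0[j];
    row++;
  }
  long long done = 0;
  while (done < nsteps) {
    long long todo = std::min(rec_every, nsteps - done);
    advance(P, q, todo, cl, &pairs);
    done = P.k;
    if (done % rec_every == 0 || done >= nsteps) {
      if (row < nrec) {
        IntegerVector cc = class_counts(P);
        time[row] = P.t;
        for (int j = 0; j < 6; ++j) counts(row, j) = cc[j];
        row++;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (row < nrec) {
    time = NumericVector(time.begin(), time.begin() + row);
    counts = counts(Range(0, row - 1), Range(0, 5));
  }
  colnames(counts) = CharacterVector::create("healthy", "incubating",
    "infectious", "immune", "dead", "vaccinated");
  return List::create(
    _["time"] = time, _["counts"] = counts,
    _["peak_infectious"] = P.peak_infectious,
    _["ever_infected"] = P.ever_infected,
    _["extinction_time"] = P.extinction_time,
    _["n_dead"] = P.n_dead,
    _["final"] = pop_to_list(P));
}

// [[Rcpp::export]]
NumericVector ibmc_cpp_sample_durations(double n, double mean, double sd,
                                        double seed, double floor_) {
  Xoshiro rng;
  rng.seed((uint64_t)seed);
  int m = (int)n;
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = draw_duration(rng, mean, sd, floor_);
  return out;
}
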