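// Daily-time-step engine for the parental sex-role simulation.
//
// The population is held in structure-of-arrays form; individuals are removed
// by swap-and-pop, clutches live in a free-listed pool and carry copies of
// both parental genomes so that no back-references to (possibly dead) parents
// are needed.  All randomness comes from an internal xoshiro256++ stream
// seeded from a single user integer, which makes trajectories bitwise
// reproducible independently of R's global RNG.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++
// ---------------------------------------------------------------------------

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline int below(int n) { return (int)(unif() * n); }        // 0..n-1
  inline double cauchy(double scale) {
    return scale * std::tan(M_PI * (unif() - 0.5));
  }
};

// sexes and states
enum { FEMALE = 0, MALE = 1 };
enum { JUV = 0, PRE = 1, SEARCH = 2, CARE = 3 };

// ---------------------------------------------------------------------------
// Elementary model functions (shared by engine and exported kernels)
// ---------------------------------------------------------------------------

static inline double surv_fun(double ttot, double B) {
  if (ttot <= 0.0) return 0.0;
  return ttot * ttot / (ttot * ttot + B * B);
}

static inline int mutate_care_kernel(int a, Rng& rng) {
  return (rng.unif() < 0.5) ? std::max(0, a - 1) : a + 1;
}

static inline double mutate_cont_kernel(double a, double scale, double cap,
                                        Rng& rng) {
  double e = rng.cauchy(scale);
  if (e > cap) e = cap;
  if (e < -cap) e = -cap;
  return a + e;
}

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------

struct Params {
  double mort[2][4];       // sex x state mortality per day
  double B, sigma, gamma, mu, cauchy_scale, eps_max;
  double kappa, alpha, beta;
  int maturation[2], premating[2];
  int clutch_size;
  bool mate_choice;
  bool orn_floor;          // clamp ornament allele at 0
  double survival_scale;   // proportionality constant of offspring survival
  int init_careF, init_careM;
  double init_pref, init_orn;
  int n0_per_sex;
  int hist_max;            // top bin (values above are clamped into it)

  static Params from_list(const List& p) {
    Params q;
    NumericMatrix m = p["mortality"];  // 2 x 4, rows F/M, cols juv/pre/search/care
    for (int s = 0; s < 2; ++s)
      for (int st = 0; st < 4; ++st) q.mort[s][st] = m(s, st);
    q.B = p["B"]; q.sigma = p["sigma"]; q.gamma = p["gamma"];
    q.mu = p["mu"]; q.cauchy_scale = p["cauchy_scale"]; q.eps_max = p["eps_max"];
    q.kappa = p["kappa"]; q.alpha = p["alpha"]; q.beta = p["beta"];
    IntegerVector mat = p["maturation_days"], pre = p["premating_days"];
    q.maturation[0] = mat[0]; q.maturation[1] = mat[1];
    q.premating[0] = pre[0]; q.premating[1] = pre[1];
    q.clutch_size = p["clutch_size"];
    q.mate_choice = p["mate_choice"];
    q.orn_floor = p["ornament_floor"];
    q.survival_scale = p["survival_scale"];
    q.init_careF = p["init_careF"]; q.init_careM = p["init_careM"];
    q.init_pref = p["init_pref"]; q.init_orn = p["init_orn"];
    q.n0_per_sex = p["n0_per_sex"];
    q.hist_max = p["hist_max"];
    return q;
  }
};

// ---------------------------------------------------------------------------
// Clutch pool
// ---------------------------------------------------------------------------

struct Clutch {
  // parental genomes, copied at mating time
  double m_careF, m_careM, m_pref, m_orn;
  double f_careF, f_careM, f_pref, f_orn;
  int intendedF, intendedM;
  int realizedF, realizedM;  // -1 until finalized
  int remaining;             // parents still to finish/die
  int mating_day;
  int probeF, probeM;        // probe slots of phantom parents, -1 if real
  bool used;
  int next_free;
};

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------

struct Engine {
  Params par;
  Rng rng;
  int day;
  bool extinct;
  int next_id;

  // individuals (SoA)
  std::vector<int> id;
  std::vector<uint8_t> sex, state;
  std::vector<int> dl;                  // days left in state
  std::vector<int> careF, careM;
  std::vector<double> pref, orn;
  std::vector<int> clutch;              // index into clutches, -1
  std::vector<int> probe;               // probe slot, -1 for real individuals

  // clutches
  std::vector<Clutch> clutches;
  int free_head;
  std::vector<int> due;                 // clutches resolvable today

  // probe bookkeeping
  std::vector<double> probe_credit;
  int probes_alive;

  // interval counters
  long iv_matings, iv_recruits, iv_deaths;
  long iv_search_days_f, iv_search_days_m;

  // recorded summaries (one row per recording event)
  std::vector<double> rec;              // flattened rows, REC_NCOL columns
  std::vector<int> rec_hist_f, rec_hist_m;
  static const int REC_NCOL = 23;

  // ring log of realized care in resolved real clutches
  std::vector<int> log_rf, log_rm, log_day;
  size_t log_cap, log_pos;
  bool log_full;

  // scratch
  std::vector<int> fpool, mpool;

  Engine(const Params& p, uint64_t seed)
    : par(p), rng(seed), day(0), extinct(false), next_id(1),
      free_head(-1), probes_alive(0),
      iv_matings(0), iv_recruits(0), iv_deaths(0),
      iv_search_days_f(0), iv_search_days_m(0),
      log_cap(20000), log_pos(0), log_full(false) {
    log_rf.resize(log_cap); log_rm.resize(log_cap); log_day.resize(log_cap);
  }

  int size() const { return (int)id.size(); }

  void add_individual(int sx, int st, int d, int cF, int cM,
                      double pr, double orn_, int probe_slot) {
    id.push_back(next_id++);
    sex.push_back((uint8_t)sx);
    state.push_back((uint8_t)st);
    dl.push_back(d);
    careF.push_back(cF); careM.push_back(cM);
    pref.push_back(pr); orn.push_back(orn_);
    clutch.push_back(-1);
    probe.push_back(probe_slot);
  }

  void init_adults() {
    for (int s = 0; s < 2; ++s)
      for (int i = 0; i < par.n0_per_sex; ++i)
        add_individual(s, SEARCH, 0, par.init_careF, par.init_careM,
                       par.init_pref, par.init_orn, -1);
  }

  int alloc_clutch() {
    if (free_head >= 0) {
      int ci = free_head;
      free_head = clutches[ci].next_free;
      return ci;
    }
    clutches.push_back(Clutch());
    return (int)clutches.size() - 1;
  }

  void free_clutch(int ci) {
    clutches[ci].used = false;
    clutches[ci].next_free = free_head;
    free_head = ci;
  }

  // parent of sex s stopped caring (death or completion) on current day
  void finalize_care(int ci, int sx, bool by_death) {
    Clutch& c = clutches[ci];
    if (sx == FEMALE) {
      if (c.realizedF >= 0) return;
      c.realizedF = by_death
        ? std::min(day - c.mating_day, c.intendedF) : c.intendedF;
    } else {
      if (c.realizedM >= 0) return;
      c.realizedM = by_death
        ? std::min(day - c.mating_day, c.intendedM) : c.intendedM;
    }
    if (--c.remaining == 0) due.push_back(ci);
  }

  void remove_individual(int i) {
    int last = size() - 1;
    if (i != last) {
      id[i] = id[last]; sex[i] = sex[last]; state[i] = state[last];
      dl[i] = dl[last]; careF[i] = careF[last]; careM[i] = careM[last];
      pref[i] = pref[last]; orn[i] = orn[last];
      clutch[i] = clutch[last]; probe[i] = probe[last];
    }
    id.pop_back(); sex.pop_back(); state.pop_back(); dl.pop_back();
    careF.pop_back(); careM.pop_back(); pref.pop_back(); orn.pop_back();
    clutch.pop_back(); probe.pop_back();
  }

  // phase 1: per-individual survival check; males pay the ornament cost
  void apply_mortality() {
    for (int i = size() - 1; i >= 0; --i) {
      double m = par.mort[sex[i]][state[i]];
      double surv = 1.0 - m;
      if (sex[i] == MALE && par.beta > 0.0) {
        double cost = 1.0 - par.beta * orn[i] * orn[i];
        if (cost < 0.0) cost = 0.0;  // clamped; warning raised at R level
        surv *= cost;
      }
      if (rng.unif() < 1.0 - surv) {
        if (state[i] == CARE && clutch[i] >= 0)
          finalize_care(clutch[i], sex[i], true);
        if (probe[i] >= 0) --probes_alive;
        ++iv_deaths;
        remove_individual(i);
      }
    }
  }

  // phase 2: clocks and state transitions
  void advance_states() {
    int n = size();
    for (int i = 0; i < n; ++i) {
      switch (state[i]) {
      case JUV:
        if (--dl[i] == 0) {
          state[i] = PRE; dl[i] = par.premating[sex[i]];
          if (dl[i] == 0) state[i] = SEARCH;
        }
        break;
      case PRE:
        if (--dl[i] == 0) state[i] = SEARCH;
        break;
      case SEARCH:
        break;
      case CARE:
        if (dl[i] == 0) {
          // transition day: care already finalized unless intended care was 0
          if (clutch[i] >= 0) {
            finalize_care(clutch[i], sex[i], false);
            clutch[i] = -1;
          }
          state[i] = PRE; dl[i] = par.premating[sex[i]];
          if (dl[i] == 0) state[i] = SEARCH;
        } else if (--dl[i] == 0) {
          // last intended care day; clear the link now (the slot may be
          // freed when the clutch resolves later today)
          if (clutch[i] >= 0) finalize_care(clutch[i], sex[i], false);
          clutch[i] = -1;
        }
        break;
      }
    }
  }

  void make_offspring(const Clutch& c) {
    double g[4];
    const double mg[4] = { c.m_careF, c.m_careM, c.m_pref, c.m_orn };
    const double fg[4] = { c.f_careF, c.f_careM, c.f_pref, c.f_orn };
    for (int l = 0; l < 4; ++l)
      g[l] = (rng.unif() < 0.5) ? mg[l] : fg[l];
    if (par.mu > 0.0) {
      for (int l = 0; l < 2; ++l)
        if (rng.unif() < par.mu)
          g[l] = mutate_care_kernel((int)g[l], rng);
      for (int l = 2; l < 4; ++l)
        if (rng.unif() < par.mu)
          g[l] = mutate_cont_kernel(g[l], par.cauchy_scale, par.eps_max, rng);
      if (par.orn_floor && g[3] < 0.0) g[3] = 0.0;
    }
    int sx = (rng.unif() < 0.5) ? FEMALE : MALE;
    add_individual(sx, JUV, par.maturation[sx],
                   (int)g[0], (int)g[1], g[2], g[3], -1);
  }

  // phase 3: resolve clutches whose last carer stopped today
  void resolve_clutches() {
    if (due.empty()) return;
    int N = size();  // all living individuals on the day of resolution
    double dens = 1.0 / (1.0 + par.gamma * N);
    for (size_t k = 0; k < due.size(); ++k) {
      int ci = due[k];
      Clutch& c = clutches[ci];
      double ttot = (double)c.realizedF + (double)c.realizedM +
        par.sigma * (double)c.realizedF * (double)c.realizedM;
      double p = surv_fun(ttot, par.B) * dens * par.survival_scale;
      bool phantom = (c.probeF >= 0 || c.probeM >= 0);
      if (c.probeF >= 0) probe_credit[c.probeF] += par.clutch_size * p;
      if (c.probeM >= 0) probe_credit[c.probeM] += par.clutch_size * p;
      if (!phantom) {
        log_rf[log_pos] = c.realizedF; log_rm[log_pos] = c.realizedM;
        log_day[log_pos] = day;
        if (++log_pos == log_cap) { log_pos = 0; log_full = true; }
        for (int j = 0; j < par.clutch_size; ++j)
          if (rng.unif() < p) { make_offspring(c); ++iv_recruits; }
      }
      free_clutch(ci);
    }
    due.clear();
  }

  // phase 4: the daily mating market
  void mating_round() {
    fpool.clear(); mpool.clear();
    int n = size();
    for (int i = 0; i < n; ++i)
      if (state[i] == SEARCH)
        (sex[i] == FEMALE ? fpool : mpool).push_back(i);
    iv_search_days_f += (long)fpool.size();
    iv_search_days_m += (long)mpool.size();
    // females are processed in uniformly random order
    for (int k = (int)fpool.size() - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(fpool[k], fpool[j]);
    }
    for (size_t k = 0; k < fpool.size(); ++k) {
      if (mpool.empty()) break;
      int f = fpool[k];
      int mj = rng.below((int)mpool.size());
      int m = mpool[mj];
      mpool[mj] = mpool.back(); mpool.pop_back();  // one encounter per day
      bool accept = true;
      if (par.mate_choice) {
        double a = 1.0 / (1.0 + par.kappa *
                          std::exp(par.alpha * (pref[f] - orn[m])));
        accept = rng.unif() < a;
      }
      if (!accept) continue;  // both leave today's pool but stay in search
      int ci = alloc_clutch();
      Clutch& c = clutches[ci];
      c.m_careF = careF[f]; c.m_careM = careM[f];
      c.m_pref = pref[f];  c.m_orn = orn[f];
      c.f_careF = careF[m]; c.f_careM = careM[m];
      c.f_pref = pref[m];  c.f_orn = orn[m];
      c.intendedF = careF[f]; c.intendedM = careM[m];
      c.realizedF = -1; c.realizedM = -1;
      c.remaining = 2; c.mating_day = day;
      c.probeF = probe[f]; c.probeM = probe[m];
      c.used = true;
      state[f] = CARE; dl[f] = careF[f]; clutch[f] = ci;
      state[m] = CARE; dl[m] = careM[m]; clutch[m] = ci;
      ++iv_matings;
    }
  }

  void record() {
    int n = size();
    double nf = 0, nm = 0;
    double cnt[2][4] = {{0, 0, 0, 0}, {0, 0, 0, 0}};
    double sF = 0, sF2 = 0, sM = 0, sM2 = 0, sp = 0, so = 0;
    size_t hb = (size_t)par.hist_max + 1;
    std::vector<int> hf(hb, 0), hm(hb, 0);
    for (int i = 0; i < n; ++i) {
      cnt[sex[i]][state[i]] += 1;
      if (sex[i] == FEMALE) {
        nf += 1;
        double v = careF[i];
        sF += v; sF2 += v * v; sp += pref[i];
        hf[std::min(careF[i], par.hist_max)] += 1;
      } else {
        nm += 1;
        double v = careM[i];
        sM += v; sM2 += v * v; so += orn[i];
        hm[std::min(careM[i], par.hist_max)] += 1;
      }
    }
    double mF = nf > 0 ? sF / nf : NA_REAL;
    double vF = nf > 1 ? (sF2 - sF * sF / nf) / (nf - 1) : NA_REAL;
    double mM = nm > 0 ? sM / nm : NA_REAL;
    double vM = nm > 1 ? (sM2 - sM * sM / nm) / (nm - 1) : NA_REAL;
    double row[REC_NCOL] = {
      (double)day, (double)n, nf, nm,
      cnt[0][JUV], cnt[1][JUV], cnt[0][PRE], cnt[1][PRE],
      cnt[0][SEARCH], cnt[1][SEARCH], cnt[0][CARE], cnt[1][CARE],
      mF, vF, mM, vM,
      nf > 0 ? sp / nf : NA_REAL, nm > 0 ? so / nm : NA_REAL,
      (double)iv_matings, (double)iv_recruits, (double)iv_deaths,
      (double)iv_search_days_f, (double)iv_search_days_m
    };
    rec.insert(rec.end(), row, row + REC_NCOL);
    rec_hist_f.insert(rec_hist_f.end(), hf.begin(), hf.end());
    rec_hist_m.insert(rec_hist_m.end(), hm.begin(), hm.end());
    iv_matings = iv_recruits = iv_deaths = 0;
    iv_search_days_f = iv_search_days_m = 0;
  }

  void step_day() {
    ++day;
    apply_mortality();
    advance_states();
    resolve_clutches();
    mating_round();
    if (size() == 0) extinct = true;
  }

  // run n_days, recording every record_every days; stops early on extinction
  void run(int n_days, int record_every) {
    for (int d = 0; d < n_days; ++d) {
      step_day();
      bool recorded = record_every > 0 && day % record_every == 0;
      if (recorded) record();
      if (extinct) {
        if (record_every > 0 && !recorded) record();
        break;
      }
    }
  }

  void inject_probes(int sx, int careT, int n_probe,
                     double pref_val, double orn_val) {
    for (int i = 0; i < n_probe; ++i) {
      probe_credit.push_back(0.0);
      add_individual(sx, SEARCH, 0, careT, careT, pref_val, orn_val,
                     (int)probe_credit.size() - 1);
      ++probes_alive;
    }
  }
};

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_pop_new(List params, double seed) {
  Params p = Params::from_list(params);
  Engine* e = new Engine(p, (uint64_t)seed);
  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_pop_init_adults(SEXP ep) {
  XPtr<Engine> e(ep);
  e->init_adults();
}

// [[Rcpp::export]]
void cpp_pop_set_individuals(SEXP ep, IntegerVector sex, IntegerVector state,
                             IntegerVector days_left, IntegerVector careF,
                             IntegerVector careM, NumericVector pref,
                             NumericVector orn) {
  XPtr<Engine> e(ep);
  for (int i = 0; i < sex.size(); ++i)
    e->add_individual(sex[i], state[i], days_left[i], careF[i], careM[i],
                      pref[i], orn[i], -1);
}

// [[Rcpp::export]]
void cpp_pop_run(SEXP ep, int n_days, int record_every) {
  XPtr<Engine> e(ep);
  e->run(n_days, record_every);
}

// phase: 1 mortality, 2 advance, 3 resolve, 4 mating, 0 full day
// [[Rcpp::export]]
void cpp_pop_step_phase(SEXP ep, int phase) {
  XPtr<Engine> e(ep);
  switch (phase) {
  case 0: e->step_day(); break;
  case 1: ++e->day; e->apply_mortality(); break;
  case 2: e->advance_states(); break;
  case 3: e->resolve_clutches(); break;
  case 4: e->mating_round(); if (e->size() == 0) e->extinct = true; break;
  default: stop("unknown phase");
  }
}

// [[Rcpp::export]]
DataFrame cpp_pop_individuals(SEXP ep) {
  XPtr<Engine> e(ep);
  int n = e->size();
  IntegerVector id(n), sex(n), state(n), dl(n), cF(n), cM(n), cl(n), pr(n);
  NumericVector p(n), o(n);
  for (int i = 0; i < n; ++i) {
    id[i] = e->id[i]; sex[i] = e->sex[i]; state[i] = e->state[i];
    dl[i] = e->dl[i]; cF[i] = e->careF[i]; cM[i] = e->careM[i];
    p[i] = e->pref[i]; o[i] = e->orn[i];
    cl[i] = e->clutch[i]; pr[i] = e->probe[i];
  }
  return DataFrame::create(
    _["id"] = id, _["sex"] = sex, _["state"] = state,
    _["days_left"] = dl, _["careF"] = cF, _["careM"] = cM,
    _["pref"] = p, _["orn"] = o, _["clutch"] = cl, _["probe"] = pr);
}

// [[Rcpp::export]]
DataFrame cpp_pop_clutches(SEXP ep) {
  XPtr<Engine> e(ep);
  std::vector<int> idx, iF, iM, rF, rM, rem, mday;
  for (size_t i = 0; i < e->clutches.size(); ++i) {
    const Clutch& c = e->clutches[i];
    if (!c.used) continue;
    idx.push_back((int)i);
    iF.push_back(c.intendedF); iM.push_back(c.intendedM);
    rF.push_back(c.realizedF); rM.push_back(c.realizedM);
    rem.push_back(c.remaining); mday.push_back(c.mating_day);
  }
  return DataFrame::create(
    _["clutch"] = wrap(idx), _["intendedF"] = wrap(iF),
    _["intendedM"] = wrap(iM), _["realizedF"] = wrap(rF),
    _["realizedM"] = wrap(rM), _["remaining"] = wrap(rem),
    _["mating_day"] = wrap(mday));
}

// [[Rcpp::export]]
List cpp_pop_state(SEXP ep) {
  XPtr<Engine> e(ep);
  return List::create(
    _["day"] = e->day, _["n"] = e->size(), _["extinct"] = e->extinct,
    _["probes_alive"] = e->probes_alive);
}

// [[Rcpp::export]]
List cpp_pop_records(SEXP ep, bool clear) {
  XPtr<Engine> e(ep);
  int ncol = Engine::REC_NCOL;
  int nrow = (int)(e->rec.size() / ncol);
  NumericMatrix m(nrow, ncol);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j) m(i, j) = e->rec[i * ncol + j];
  int hb = e->par.hist_max + 1;
  IntegerMatrix hf(nrow, hb), hm(nrow, hb);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < hb; ++j) {
      hf(i, j) = e->rec_hist_f[(size_t)i * hb + j];
      hm(i, j) = e->rec_hist_m[(size_t)i * hb + j];
    }
  if (clear) {
    e->rec.clear(); e->rec_hist_f.clear(); e->rec_hist_m.clear();
  }
  return List::create(_["summary"] = m, _["hist_f"] = hf, _["hist_m"] = hm);
}

// [[Rcpp::export]]
DataFrame cpp_pop_clutch_log(SEXP ep) {
  XPtr<Engine> e(ep);
  size_t n = e->log_full ? e->log_cap : e->log_pos;
  IntegerVector rf(n), rm(n), d(n);
  // oldest first
  size_t start = e->log_full ? e->log_pos : 0;
  for (size_t i = 0; i < n; ++i) {
    size_t k = (start + i) % e->log_cap;
    rf[i] = e->log_rf[k]; rm[i] = e->log_rm[k]; d[i] = e->log_day[k];
  }
  return DataFrame::create(_["day"] = d, _["realizedF"] = rf,
                           _["realizedM"] = rm);
}

// [[Rcpp::export]]
void cpp_pop_inject_probes(SEXP ep, int sex, int careT, int n_probe,
                           double pref_val, double orn_val) {
  XPtr<Engine> e(ep);
  e->inject_probes(sex, careT, n_probe, pref_val, orn_val);
}

// [[Rcpp::export]]
NumericVector cpp_pop_probe_credits(SEXP ep) {
  XPtr<Engine> e(ep);
  return wrap(e->probe_credit);
}

// ---------------------------------------------------------------------------
// Stand-alone genetics kernels (same code paths as the engine)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_mutate_care(IntegerVector allele, double seed) {
  Rng rng((uint64_t)seed);
  IntegerVector out(allele.size());
  for (int i = 0; i < allele.size(); ++i)
    out[i] = mutate_care_kernel(allele[i], rng);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mutate_continuous(NumericVector allele, double scale,
                                    double cap, double seed) {
  Rng rng((uint64_t)seed);
  NumericVector out(allele.size());
  for (int i = 0; i < allele.size(); ++i)
    out[i] = mutate_cont_kernel(allele[i], scale, cap, rng);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_assign_sex(int n, double seed) {
  Rng rng((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (rng.unif() < 0.5) ? 0 : 1;
  return out;
}

// Mendelian transmission plus mutation for n children of one parental pair.
// mother/father: numeric length-4 genomes (careF, careM, pref, orn).
// [[Rcpp::export]]
NumericMatrix cpp_make_children(NumericVector mother, NumericVector father,
                                int n, double mu, double cauchy_scale,
                                double eps_max, bool orn_floor, double seed) {
  Rng rng((uint64_t)seed);
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double g[4];
    for (int l = 0; l < 4; ++l)
      g[l] = (rng.unif() < 0.5) ? mother[l] : father[l];
    if (mu > 0.0) {
      for (int l = 0; l < 2; ++l)
        if (rng.unif() < mu) g[l] = mutate_care_kernel((int)g[l], rng);
      for (int l = 2; l < 4; ++l)
        if (rng.unif() < mu)
          g[l] = mutate_cont_kernel(g[l], cauchy_scale, eps_max, rng);
      if (orn_floor && g[3] < 0.0) g[3] = 0.0;
    }
    for (int l = 0; l < 4; ++l) out(i, l) = g[l];
  }
  return out;
}
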