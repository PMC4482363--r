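// Particle engine: Brownian motion in a nested sphere geometry plus
// radius-gated reactions on a uniform spatial hash.  All randomness comes
// from a xoshiro256++ stream seeded from the R-supplied integers, so a run
// is a pure function of (population, parameters, seed).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256++
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t a, uint64_t b) {
    uint64_t x = a * 0x9E3779B97f4A7C15ULL + b + 0x243F6A8885A308D3ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia polar method; one cached value
  bool has_cache = false;
  double cache = 0.0;
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f; has_cache = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Codes (kept in sync with R/agents.R)
// ---------------------------------------------------------------------------
enum AType {
  T_NUC_IMPORT = 0, T_NUC_EXPORT = 1, T_IL1RI_TILRR = 2, T_IL1RI = 3,
  T_CYTO_SITE = 4, T_TX_SITE = 5, T_MYD88 = 6, T_IRAK = 7, T_TRAF = 8,
  T_TAK = 9, T_RAS = 10, T_PI3K = 11, T_AKT = 12, T_IKK = 13, T_IKB = 14,
  T_NFKB = 15, T_IL8 = 16, T_CASP3 = 17, T_NDISS = 18, T_ADISS = 19,
  T_PHOS = 20
};

enum AState {
  S_INACTIVE = 0, S_ACTIVE = 1, S_ACTIVE_TILRR = 2, S_ACTIVE_ACP = 3,
  S_IKB_FREE = 10, S_IKB_BOUND_NFKB = 11, S_IKB_BOUND_CYTO = 12,
  S_IKB_TRANSCRIBED = 13, S_IKB_PHOSPHO = 14,
  S_CYTO_UNOCC = 20, S_CYTO_BOUND = 21, S_CYTO_INACTIVE = 22,
  S_NFKB_FREE = 30, S_NFKB_BOUND = 31,
  S_IL8_ACTIVE = 40, S_IL8_TRANSCRIBED = 41,
  S_DEAD = 99
};

// Observable columns
enum Col {
  C_TIME = 0, C_IKB_TOTAL, C_IKB_CYTO, C_IKB_PHOS, C_IKB_FREE, C_IKB_NFKB,
  C_IKB_NUC, C_NFKB_FREE, C_NFKB_NUC, C_NFKB_CPLX, C_IL8, C_CASP3,
  C_RECEPT, C_MYD88, C_IRAK, C_IKK, C_AKT, C_ADISS,
  C_EV_PHOS, C_EV_DEG, C_EV_PASSIVE, C_EV_ACTIVE_REL, C_EV_REBIND,
  C_EV_IMPORT, C_EV_EXPORT, C_EV_TX, C_EV_SYN_IKB, C_EV_SYN_IL8,
  C_EV_NDISS, C_EV_ASSOC, C_EV_PHOS_CYTOBOUND, C_NCOL
};

// ---------------------------------------------------------------------------
// Spatial hash grid (head/next linked lists over a cubic lattice)
// ---------------------------------------------------------------------------
struct Grid {
  double h, origin;
  int n;                      // cells per axis
  std::vector<int> head, nxt;
  void init(double cell_radius, double cell_size, int n_agents) {
    h = cell_size;
    origin = -cell_radius;
    n = (int)std::ceil(2.0 * cell_radius / h) + 1;
    if (n > 64) {                // cap lattice memory for huge domains
      n = 64;
      h = 2.0 * cell_radius / 63.0;
    }
    head.assign((size_t)n * n * n, -1);
    nxt.assign(n_agents, -1);
  }
  inline int axis(double v) const {
    int i = (int)std::floor((v - origin) / h);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
  inline int cell(double x, double y, double z) const {
    return (axis(x) * n + axis(y)) * n + axis(z);
  }
  void clear() { std::fill(head.begin(), head.end(), -1); }
  void insert(int i, double x, double y, double z) {
    int c = cell(x, y, z);
    nxt[i] = head[c];
    head[c] = i;
  }
};

// ---------------------------------------------------------------------------
// Engine state
// ---------------------------------------------------------------------------
struct Engine {
  // population (capacity n_max; alive flag)
  int n_max = 0;
  std::vector<int> type, state, partner, hits, alive;
  std::vector<double> px, py, pz, timer; // timer in steps
  std::vector<int> stamp;                // last step the agent reacted in
  // slot types are fixed for the whole run: synthesis reuses pre-typed
  // spare slots, so per-type index lists stay valid throughout
  std::vector<std::vector<int>> by_type;
  std::vector<int> free_ikb, free_il8;

  // geometry
  double Rc = 10.0, Rn = 4.0, shell = 0.2;

  // motion
  double D = 1.0, dt = 0.5, sd_step = 1.0;

  // parameters
  double r_myd88_tilrr = 0, r_myd88_plain = 0, r_pi3k_tilrr = 0,
         r_pi3k_plain = 0, r_cascade = 0, r_cascade_mid = 0, r_ras = 0,
         r_akt = 0, r_casp = 0,
         r_tak_act = 0, r_ikk_act = 0,
         r_phospho = 0, r_basal = 0, r_assoc = 0, r_ndiss = 0, r_kon = 0,
         r_arel = 0, r_adiss = 0, r_import = 0, r_export = 0, r_tx_ikb = 0,
         r_tx_il8 = 0;
  double p_koff = 0;          // per-step passive unbinding probability
  double p_deact = 0;         // per-step cascade deactivation probability
  double p_deact_adiss = 0;
  double p_casp_basal = 0;
  int m_hits = 1;
  int n_adiss_active = 0;
  int pikb_lag_steps = 0, tx_steps = 0, transcribed_steps = 1;
  int burst_ikb = 0, burst_il8 = 0;
  bool sw_cyto_dissoc = true, sw_nfkb_dissoc = true, sw_cyto_binding = true,
       allow_ikb_import = true;
  int release_level = 1;      // 0 passive-only, 1 40-50, 2 90-100
  int stim_start = -1, stim_end = -1;
  double dose = 0.0;

  // bookkeeping
  long long ev_phos = 0, ev_deg = 0, ev_passive = 0, ev_active_rel = 0,
            ev_rebind = 0, ev_import = 0, ev_export = 0, ev_tx = 0,
            ev_syn_ikb = 0, ev_syn_il8 = 0, ev_ndiss = 0, ev_assoc = 0,
            ev_phos_cytobound = 0;
  bool overflow = false;

  // one grid per mobile target type (queries scan only that type) plus a
  // finer static grid over the immobile cytoskeleton sites
  std::vector<Grid> grid_type;
  Grid grid_sites;
  Xoshiro rng;
  int step_now = -1;

  // geometric lifetime draw for a per-step hazard p: steps until the event
  double draw_life(double p) {
    if (p <= 0) return 0;                      // 0 = no scheduled event
    if (p >= 1) return 1;
    return 1 + std::floor(std::log(rng.unif()) / std::log1p(-p));
  }

  // ---- helpers -----------------------------------------------------------
  static inline double rad(double x, double y, double z) {
    return std::sqrt(x * x + y * y + z * z);
  }
  inline bool in_nucleus(int i) const { return rad(px[i], py[i], pz[i]) < Rn; }

  inline bool mobile(int i) const {
    int t = type[i];
    if (t <= T_TX_SITE) return false;          // receptors/sites fixed
    int s = state[i];
    if (t == T_IKB && (s == S_IKB_BOUND_CYTO || s == S_IKB_BOUND_NFKB))
      return false;                            // carried or anchored
    return true;
  }

  // reflect a cytoplasmic (rmin=Rn) or nuclear (rmax=Rn) point radially
  void confine(int i, double rmin, double rmax) {
    double r = rad(px[i], py[i], pz[i]);
    for (int it = 0; it < 8; ++it) {
      if (r >= rmin && r <= rmax) return;
      double target = r;
      if (r > rmax) target = 2.0 * rmax - r;
      else if (r < rmin) target = 2.0 * rmin - r;
      if (target < rmin || target > rmax)
        target = 0.5 * (rmin + rmax);          // pathological long jump
      if (r < 1e-12) {                         // at origin: push along +z
        px[i] = 0; py[i] = 0; pz[i] = target;
      } else {
        double f = target / r;
        px[i] *= f; py[i] *= f; pz[i] *= f;
      }
      r = rad(px[i], py[i], pz[i]);
    }
  }

  // explicit compartment side for shuttling species (avoids boundary
  // ambiguity right at the envelope after transport); 1 = nucleus
  std::vector<uint8_t> side_nuc;

  void move_all() {
    for (int t = T_MYD88; t <= T_PHOS; ++t) {
      for (int i : by_type[t]) {
        if (!alive[i] || !mobile(i)) continue;
        px[i] += sd_step * rng.norm();
        py[i] += sd_step * rng.norm();
        pz[i] += sd_step * rng.norm();
        if (t == T_IKB || t == T_NFKB || t == T_IL8) {
          // shuttling species: confined to whichever side of the envelope
          // they are on; crossing happens only through transport receptors
          if (side_nuc[i]) confine(i, 0.0, Rn);
          else confine(i, Rn, Rc);
        } else {
          confine(i, Rn, Rc);                  // cytoplasmic proteins
        }
      }
    }
    // carried partners share the carrier's position
    for (int i : by_type[T_NFKB]) {
      if (alive[i] && state[i] == S_NFKB_BOUND && partner[i] >= 0) {
        int j = partner[i];
        px[j] = px[i]; py[j] = py[i]; pz[j] = pz[i];
        side_nuc[j] = side_nuc[i];
      }
    }
  }

  // ---- agent creation / removal -----------------------------------------
  int spawn(int t, int s, double x, double y, double z, bool nuc) {
    std::vector<int> &pool = (t == T_IL8) ? free_il8 : free_ikb;
    if (pool.empty()) { overflow = true; return -1; }
    int i = pool.back();
    pool.pop_back();
    state[i] = s; px[i] = x; py[i] = y; pz[i] = z;
    partner[i] = -1; timer[i] = 0; hits[i] = 0; alive[i] = 1;
    stamp[i] = -1; side_nuc[i] = nuc ? 1 : 0;
    return i;
  }
  void kill(int i) {
    alive[i] = 0; state[i] = S_DEAD; partner[i] = -1;
    if (type[i] == T_IL8) free_il8.push_back(i); else free_ikb.push_back(i);
  }

  // ---- pair search -------------------------------------------------------
  // nearest alive, unreacted agent in `g` within radius satisfying pred;
  // optionally reports the squared distance of the match
  template <typename Pred>
  int nearest(const Grid &g, double x, double y, double z, double radius,
              Pred pred, double *d2_out = nullptr) {
    int range = (int)std::ceil(radius / g.h);
    int cx = g.axis(x), cy = g.axis(y), cz = g.axis(z);
    double best_d2 = radius * radius;
    int best = -1;
    for (int ix = std::max(0, cx - range); ix <= std::min(g.n - 1, cx + range); ++ix)
      for (int iy = std::max(0, cy - range); iy <= std::min(g.n - 1, cy + range); ++iy)
        for (int iz = std::max(0, cz - range); iz <= std::min(g.n - 1, cz + range); ++iz) {
          int c = (ix * g.n + iy) * g.n + iz;
          for (int j = g.head[c]; j >= 0; j = g.nxt[j]) {
            if (!alive[j] || stamp[j] == step_now) continue;
            if (!pred(j)) continue;
            double dx = px[j] - x, dy = py[j] - y, dz = pz[j] - z;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best_d2 ||
                (d2 == best_d2 && best >= 0 && rng.unif() < 0.5)) {
              best_d2 = d2;
              best = j;
            }
          }
        }
    if (d2_out) *d2_out = best_d2;
    return best;
  }
};

// The move_all above needs side_nuc sized; everything is wired in run().

// ---------------------------------------------------------------------------
// main entry
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List abm_run_cpp(List pop, List geom, List par, int n_steps, int record_every,
                 int seed1, int seed2) {
  Engine E;

  // population arrays arrive full length: alive agents plus pre-typed
  // spare slots (alive = 0) that synthesis will fill
  IntegerVector type = pop["type"], state = pop["state"],
                partner = pop["partner"], hits = pop["hits"],
                alive = pop["alive"];
  NumericVector x = pop["x"], y = pop["y"], z = pop["z"], timer = pop["timer"];

  E.n_max = type.size();
  E.type.assign(E.n_max, 0); E.state.assign(E.n_max, S_DEAD);
  E.partner.assign(E.n_max, -1); E.hits.assign(E.n_max, 0);
  E.alive.assign(E.n_max, 0); E.stamp.assign(E.n_max, -1);
  E.px.assign(E.n_max, 0); E.py.assign(E.n_max, 0); E.pz.assign(E.n_max, 0);
  E.timer.assign(E.n_max, 0);
  E.side_nuc.assign(E.n_max, 0);
  E.by_type.assign(21, std::vector<int>());
  for (int i = 0; i < E.n_max; ++i) {
    E.type[i] = type[i]; E.state[i] = state[i];
    E.partner[i] = (partner[i] == NA_INTEGER || partner[i] < 0)
                       ? -1 : partner[i] - 1; // R 1-based
    E.hits[i] = hits[i]; E.alive[i] = alive[i];
    E.px[i] = x[i]; E.py[i] = y[i]; E.pz[i] = z[i]; E.timer[i] = timer[i];
    E.by_type[E.type[i]].push_back(i);
  }
  for (int i = E.n_max - 1; i >= 0; --i) {
    if (E.alive[i]) continue;
    if (E.type[i] == T_IL8) E.free_il8.push_back(i);
    else if (E.type[i] == T_IKB) E.free_ikb.push_back(i);
  }

  E.Rc = as<double>(geom["cell_radius"]);
  E.Rn = as<double>(geom["nucleus_radius"]);
  E.shell = as<double>(geom["membrane_thickness"]);

  E.D = as<double>(par["D"]);
  E.dt = as<double>(par["dt"]);
  E.sd_step = std::sqrt(2.0 * E.D * E.dt);

  auto P = [&](const char *k) { return as<double>(par[k]); };
  E.r_myd88_tilrr = P("r_myd88_tilrr"); E.r_myd88_plain = P("r_myd88_plain");
  E.r_pi3k_tilrr = P("r_pi3k_tilrr"); E.r_pi3k_plain = P("r_pi3k_plain");
  E.r_cascade = P("r_cascade"); E.r_cascade_mid = P("r_cascade_mid");
  E.r_tak_act = P("r_tak_act"); E.r_ikk_act = P("r_ikk_act");
  E.r_ras = P("r_ras"); E.r_akt = P("r_akt");
  E.r_casp = P("r_casp"); E.r_phospho = P("r_phospho");
  E.r_basal = P("r_basal"); E.r_assoc = P("r_assoc");
  E.r_ndiss = P("r_ndiss"); E.r_kon = P("r_kon"); E.r_arel = P("r_arel");
  E.r_adiss = P("r_adiss"); E.r_import = P("r_import");
  E.r_export = P("r_export"); E.r_tx_ikb = P("r_tx_ikb");
  E.r_tx_il8 = P("r_tx_il8");

  double koff = P("koff_per_min");
  E.p_koff = 1.0 - std::exp(-koff * E.dt / 60.0);
  E.p_deact = 1.0 - std::exp(-P("k_deact_per_min") * E.dt / 60.0);
  E.p_deact_adiss = 1.0 - std::exp(-P("k_deact_adiss_per_min") * E.dt / 60.0);
  E.p_casp_basal = 1.0 - std::exp(-P("k_casp_basal_per_min") * E.dt / 60.0);
  E.m_hits = as<int>(par["m_hits"]);
  E.pikb_lag_steps = (int)std::lround(P("pikb_lag_min") * 60.0 / E.dt);
  E.tx_steps = (int)std::lround(P("tx_time_min") * 60.0 / E.dt);
  E.burst_ikb = as<int>(par["burst_ikb"]);
  E.burst_il8 = as<int>(par["burst_il8"]);
  E.sw_cyto_dissoc = as<bool>(par["dissociate_from_cytoskeleton"]);
  E.sw_nfkb_dissoc = as<bool>(par["dissociate_from_nfkb"]);
  E.sw_cyto_binding = as<bool>(par["cytoskeleton_binding"]);
  E.allow_ikb_import = as<bool>(par["allow_ikb_import"]);
  E.release_level = as<int>(par["release_level"]);
  E.stim_start = (int)std::lround(P("stim_start_min") * 60.0 / E.dt);
  E.stim_end = (int)std::lround(P("stim_end_min") * 60.0 / E.dt);
  E.dose = P("dose");

  E.rng.seed((uint64_t)(uint32_t)seed1, (uint64_t)(uint32_t)seed2);

  // schedule lifetimes for states that arrived without one (fresh builds;
  // exponential memorylessness makes a redraw equivalent on warm starts)
  for (int i = 0; i < E.n_max; ++i) {
    if (!E.alive[i] || E.timer[i] > 0) continue;
    int t = E.type[i], s = E.state[i];
    if (t == T_IKB && s == S_IKB_BOUND_CYTO && E.sw_cyto_dissoc)
      E.timer[i] = E.draw_life(E.p_koff);
    else if (t == T_MYD88 && (s == S_ACTIVE_TILRR || s == S_ACTIVE_ACP))
      E.timer[i] = E.draw_life(E.p_deact);
    else if (t >= T_IRAK && t <= T_IKK && s == S_ACTIVE)
      E.timer[i] = E.draw_life(E.p_deact);
    else if (t == T_ADISS && s == S_ACTIVE)
      E.timer[i] = E.draw_life(E.p_deact_adiss);
    else if (t == T_CASP3 && s == S_INACTIVE)
      E.timer[i] = E.draw_life(E.p_casp_basal);
  }

  for (int i : E.by_type[T_ADISS])
    if (E.alive[i] && E.state[i] == S_ACTIVE) ++E.n_adiss_active;

  // side flags from initial radial position
  for (int i = 0; i < E.n_max; ++i)
    if (E.alive[i])
      E.side_nuc[i] =
          (Engine::rad(E.px[i], E.py[i], E.pz[i]) < E.Rn) ? 1 : 0;

  // grids: a fine static one over cytoskeleton sites, coarse per-type
  // ones (rebuilt each step) over the mobile protein types
  E.grid_sites.init(E.Rc, 0.5, E.n_max);
  for (int i = 0; i < E.n_max; ++i)
    if (E.alive[i] && E.type[i] == T_CYTO_SITE)
      E.grid_sites.insert(i, E.px[i], E.py[i], E.pz[i]);
  E.grid_type.resize(21);
  for (int t = T_MYD88; t <= T_PHOS; ++t)
    if (t != T_NDISS && t != T_PHOS)
      E.grid_type[t].init(E.Rc, 1.0, E.n_max);

  // recording
  int n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, C_NCOL);
  int rec_row = 0;

  auto record = [&](int step) {
    double t_min = step * E.dt / 60.0;
    std::vector<double> v(C_NCOL, 0.0);
    v[C_TIME] = t_min;
    for (int i = 0; i < E.n_max; ++i) {
      if (!E.alive[i]) continue;
      int t = E.type[i], s = E.state[i];
      switch (t) {
      case T_IKB:
        v[C_IKB_TOTAL] += 1;
        if (s == S_IKB_BOUND_CYTO) v[C_IKB_CYTO] += 1;
        else if (s == S_IKB_PHOSPHO) v[C_IKB_PHOS] += 1;
        else if (s == S_IKB_FREE) v[C_IKB_FREE] += 1;
        else if (s == S_IKB_BOUND_NFKB) v[C_IKB_NFKB] += 1;
        if (E.side_nuc[i]) v[C_IKB_NUC] += 1;
        break;
      case T_NFKB:
        if (s == S_NFKB_FREE) v[C_NFKB_FREE] += 1;
        else v[C_NFKB_CPLX] += 1;
        if (E.side_nuc[i]) v[C_NFKB_NUC] += 1;
        break;
      case T_IL8: v[C_IL8] += 1; break;
      case T_CASP3: if (s == S_ACTIVE) v[C_CASP3] += 1; break;
      case T_IL1RI_TILRR: case T_IL1RI:
        if (s == S_ACTIVE) v[C_RECEPT] += 1; break;
      case T_MYD88:
        if (s == S_ACTIVE_TILRR || s == S_ACTIVE_ACP) v[C_MYD88] += 1; break;
      case T_IRAK: if (s == S_ACTIVE) v[C_IRAK] += 1; break;
      case T_IKK: if (s == S_ACTIVE) v[C_IKK] += 1; break;
      case T_AKT: if (s == S_ACTIVE) v[C_AKT] += 1; break;
      case T_ADISS: if (s == S_ACTIVE) v[C_ADISS] += 1; break;
      default: break;
      }
    }
    v[C_EV_PHOS] = (double)E.ev_phos; v[C_EV_DEG] = (double)E.ev_deg;
    v[C_EV_PASSIVE] = (double)E.ev_passive;
    v[C_EV_ACTIVE_REL] = (double)E.ev_active_rel;
    v[C_EV_REBIND] = (double)E.ev_rebind;
    v[C_EV_IMPORT] = (double)E.ev_import; v[C_EV_EXPORT] = (double)E.ev_export;
    v[C_EV_TX] = (double)E.ev_tx; v[C_EV_SYN_IKB] = (double)E.ev_syn_ikb;
    v[C_EV_SYN_IL8] = (double)E.ev_syn_il8; v[C_EV_NDISS] = (double)E.ev_ndiss;
    v[C_EV_ASSOC] = (double)E.ev_assoc;
    v[C_EV_PHOS_CYTOBOUND] = (double)E.ev_phos_cytobound;
    for (int c = 0; c < C_NCOL; ++c) rec(rec_row, c) = v[c];
    ++rec_row;
  };

  // phosphorylation effect shared by IKK and the basal phosphorylator
  auto phosphorylate = [&](int j) {
    if (E.state[j] == S_IKB_BOUND_CYTO) { ++E.ev_phos_cytobound; return; }
    if (E.state[j] == S_IKB_BOUND_NFKB && E.partner[j] >= 0) {
      int nf = E.partner[j];
      E.state[nf] = S_NFKB_FREE; E.partner[nf] = -1;
    }
    E.partner[j] = -1;
    E.state[j] = S_IKB_PHOSPHO;
    E.timer[j] = E.pikb_lag_steps;
    ++E.ev_phos;
  };

  auto release_site = [&](int site, long long &counter) {
    int ik = E.partner[site];
    E.state[site] = S_CYTO_UNOCC; E.partner[site] = -1;
    if (ik >= 0) {
      E.state[ik] = S_IKB_FREE; E.partner[ik] = -1; E.timer[ik] = 0;
      // released at the site position (no teleporting)
      E.px[ik] = E.px[site]; E.py[ik] = E.py[site]; E.pz[ik] = E.pz[site];
      E.side_nuc[ik] = 0;
    }
    ++counter;
  };

  bool active_release_on = E.sw_cyto_dissoc && E.release_level > 0;
  int ras_src = as<int>(par["ras_source_type"]); // T_PI3K or T_MYD88

  record(0);

  for (int step = 0; step < n_steps; ++step) {
    E.step_now = step;

    // -- stimulation protocol --------------------------------------------
    if (step == E.stim_start && E.dose > 0) {
      // exact-count dosing: activate round(dose * n) receptors, chosen by
      // a seeded shuffle (a controlled stimulation level)
      std::vector<int> rec;
      for (int t : {T_IL1RI_TILRR, T_IL1RI})
        for (int i : E.by_type[t])
          if (E.alive[i]) rec.push_back(i);
      int n_on = (int)std::lround(E.dose * rec.size());
      for (int k = 0; k < n_on && k < (int)rec.size(); ++k) {
        int j = k + (int)(E.rng.unif() * (rec.size() - k));
        if (j >= (int)rec.size()) j = rec.size() - 1;
        std::swap(rec[k], rec[j]);
        E.state[rec[k]] = S_ACTIVE;
      }
    }
    if (step == E.stim_end) {
      for (int t : {T_IL1RI_TILRR, T_IL1RI})
        for (int i : E.by_type[t])
          if (E.alive[i]) E.state[i] = S_INACTIVE;
    }

    // -- movement ---------------------------------------------------------
    E.move_all();

    // -- rebuild per-type target grids ------------------------------------
    for (int t = T_MYD88; t <= T_PHOS; ++t) {
      if (t == T_NDISS || t == T_PHOS) continue; // initiator-only types
      E.grid_type[t].clear();
      for (int i : E.by_type[t])
        if (E.alive[i]) E.grid_type[t].insert(i, E.px[i], E.py[i], E.pz[i]);
    }

    // convenience lambdas -------------------------------------------------
    auto fire2 = [&](int a, int b) { E.stamp[a] = step; E.stamp[b] = step; };
    auto cat_act = [&](int a_type, int a_state_any, int b_type, double radius,
                       int b_new_state) {
      // a_state_any: 1 = any active state (MyD88 has two)
      if (radius <= 0) return;
      for (int i : E.by_type[a_type]) {
        if (!E.alive[i] || E.stamp[i] == step) continue;
        int s = E.state[i];
        bool act = a_state_any ? (s == S_ACTIVE || s == S_ACTIVE_TILRR ||
                                  s == S_ACTIVE_ACP)
                               : (s == S_ACTIVE);
        if (!act) continue;
        int j = E.nearest(E.grid_type[b_type], E.px[i], E.py[i], E.pz[i],
                          radius,
                          [&](int k) { return E.state[k] == S_INACTIVE; });
        if (j >= 0) {
          E.state[j] = b_new_state;
          E.timer[j] = E.draw_life(E.p_deact); // scheduled deactivation
          fire2(i, j);
        }
      }
    };
    // per-type initiator loop with inline body
    auto for_type = [&](int t, auto body) {
      for (int i : E.by_type[t]) {
        if (!E.alive[i] || E.stamp[i] == step) continue;
        body(i);
      }
    };

    // 1-4: receptor -> adapters (affinity-scaled radii already folded in)
    for (int t : {T_IL1RI_TILRR, T_IL1RI})
    for (int i : E.by_type[t]) {
      if (!E.alive[i] || E.state[i] != S_ACTIVE) continue;
      bool til = (t == T_IL1RI_TILRR);
      double rm = til ? E.r_myd88_tilrr : E.r_myd88_plain;
      double rp = til ? E.r_pi3k_tilrr : E.r_pi3k_plain;
      // one reaction per receptor per step: pick MyD88 first, else PI3K
      int j = -1;
      if (rm > 0)
        j = E.nearest(E.grid_type[T_MYD88], E.px[i], E.py[i], E.pz[i], rm,
                      [&](int k) { return E.state[k] == S_INACTIVE; });
      if (j >= 0) {
        E.state[j] = til ? S_ACTIVE_TILRR : S_ACTIVE_ACP;
        E.timer[j] = E.draw_life(E.p_deact);
        fire2(i, j);
        continue;
      }
      if (rp > 0) {
        j = E.nearest(E.grid_type[T_PI3K], E.px[i], E.py[i], E.pz[i], rp,
                      [&](int k) { return E.state[k] == S_INACTIVE; });
        if (j >= 0) {
          E.state[j] = S_ACTIVE;
          E.timer[j] = E.draw_life(E.p_deact);
          fire2(i, j);
        }
      }
    }

    // 5-8: MyD88 -> IRAK -> TRAF -> TAK -> IKK
    cat_act(T_MYD88, 1, T_IRAK, E.r_cascade, S_ACTIVE);
    cat_act(T_IRAK, 0, T_TRAF, E.r_cascade_mid, S_ACTIVE);
    cat_act(T_TRAF, 0, T_TAK, E.r_tak_act, S_ACTIVE);
    cat_act(T_TAK, 0, T_IKK, E.r_ikk_act, S_ACTIVE);

    // 9-10: PI3K branch (Ras placement configurable: R folds the branch
    // choice into which catalyst drives Ras)
    cat_act(ras_src, ras_src == T_MYD88 ? 1 : 0, T_RAS, E.r_ras, S_ACTIVE);
    cat_act(T_RAS, 0, T_AKT, E.r_akt, S_ACTIVE);

    // 18: active receptor complexes prime the actin dissociators
    // (multi-hit activation: the release machinery needs repeated
    // receptor-proximal contacts before switching on)
    if (active_release_on && E.r_adiss > 0) {
      for (int rt : {T_IL1RI_TILRR, T_IL1RI})
      for_type(rt, [&](int i) {
        if (E.state[i] != S_ACTIVE) return;
        int j = E.nearest(E.grid_type[T_ADISS], E.px[i], E.py[i], E.pz[i],
                          E.r_adiss,
                          [&](int k) { return E.state[k] == S_INACTIVE; });
        if (j >= 0) {
          if (++E.hits[j] >= E.m_hits) {
            E.state[j] = S_ACTIVE;
            E.timer[j] = E.draw_life(E.p_deact_adiss);
            ++E.n_adiss_active;
          }
          fire2(i, j);
        }
      });
    }

    // 11: Akt suppresses active Caspase-3
    if (E.r_casp > 0) {
      for_type(T_AKT, [&](int i) {
        if (E.state[i] != S_ACTIVE) return;
        int j = E.nearest(E.grid_type[T_CASP3], E.px[i], E.py[i], E.pz[i],
                          E.r_casp,
                          [&](int k) { return E.state[k] == S_ACTIVE; });
        if (j >= 0) {
          E.state[j] = S_INACTIVE;
          E.timer[j] = E.draw_life(E.p_casp_basal);
          fire2(i, j);
        }
      });
    }

    // 12: IKK phosphorylates free and NF-kB-bound IkB (never cyto-bound)
    auto ikb_substrate = [&](int k) {
      return !E.side_nuc[k] &&
             (E.state[k] == S_IKB_FREE || E.state[k] == S_IKB_BOUND_NFKB);
    };
    if (E.r_phospho > 0) {
      for_type(T_IKK, [&](int i) {
        if (E.state[i] != S_ACTIVE) return;
        int j = E.nearest(E.grid_type[T_IKB], E.px[i], E.py[i], E.pz[i],
                          E.r_phospho, ikb_substrate);
        if (j >= 0) { phosphorylate(j); fire2(i, j); }
      });
    }

    // 13: basal turnover by the IkB phosphorylator
    if (E.r_basal > 0) {
      for_type(T_PHOS, [&](int i) {
        int j = E.nearest(E.grid_type[T_IKB], E.px[i], E.py[i], E.pz[i],
                          E.r_basal, ikb_substrate);
        if (j >= 0) { phosphorylate(j); fire2(i, j); }
      });
    }

    // 15: spontaneous NFkB:IkB dissociation (dissociator agents)
    if (E.sw_nfkb_dissoc && E.r_ndiss > 0) {
      for_type(T_NDISS, [&](int i) {
        int j = E.nearest(E.grid_type[T_NFKB], E.px[i], E.py[i], E.pz[i],
                          E.r_ndiss,
                          [&](int k) { return E.state[k] == S_NFKB_BOUND; });
        if (j >= 0) {
          int ik = E.partner[j];
          E.state[j] = S_NFKB_FREE; E.partner[j] = -1;
          if (ik >= 0) { E.state[ik] = S_IKB_FREE; E.partner[ik] = -1; }
          fire2(i, j);
          ++E.ev_ndiss;
        }
      });
    }

    // 14: NFkB + IkB association (either compartment)
    if (E.r_assoc > 0) {
      for_type(T_NFKB, [&](int i) {
        if (E.state[i] != S_NFKB_FREE) return;
        int j = E.nearest(E.grid_type[T_IKB], E.px[i], E.py[i], E.pz[i],
                          E.r_assoc,
                          [&](int k) {
                            return E.state[k] == S_IKB_FREE &&
                                   E.side_nuc[k] == E.side_nuc[i];
                          });
        if (j >= 0) {
          E.state[i] = S_NFKB_BOUND; E.state[j] = S_IKB_BOUND_NFKB;
          E.partner[i] = j; E.partner[j] = i;
          E.px[j] = E.px[i]; E.py[j] = E.py[i]; E.pz[j] = E.pz[i];
          fire2(i, j);
          ++E.ev_assoc;
        }
      });
    }

    // 16: IkB binding to cytoskeleton sites
    if (E.sw_cyto_binding && E.r_kon > 0) {
      for_type(T_IKB, [&](int i) {
        if (E.state[i] != S_IKB_FREE || E.side_nuc[i]) return;
        int j = E.nearest(E.grid_sites, E.px[i], E.py[i], E.pz[i], E.r_kon,
                          [&](int k) { return E.state[k] == S_CYTO_UNOCC; });
        if (j >= 0) {
          E.state[i] = S_IKB_BOUND_CYTO; E.state[j] = S_CYTO_BOUND;
          E.partner[i] = j; E.partner[j] = i;
          E.px[i] = E.px[j]; E.py[i] = E.py[j]; E.pz[i] = E.pz[j];
          E.timer[i] = E.sw_cyto_dissoc ? E.draw_life(E.p_koff) : 0;
          fire2(i, j);
          ++E.ev_rebind;
        }
      });
    }

    // 17: active release by activated dissociators.  Iterated from the
    // occupied-site side (the smaller, shrinking set): each bound site
    // takes the nearest free active dissociator within the release radius.
    if (active_release_on && E.r_arel > 0 && E.n_adiss_active > 0) {
      for (int j : E.by_type[T_CYTO_SITE]) {
        if (E.state[j] != S_CYTO_BOUND || E.stamp[j] == step) continue;
        int i = E.nearest(E.grid_type[T_ADISS], E.px[j], E.py[j], E.pz[j],
                          E.r_arel,
                          [&](int k) { return E.state[k] == S_ACTIVE; });
        if (i >= 0) {
          int ik = E.partner[j];
          release_site(j, E.ev_active_rel);
          if (ik >= 0) E.stamp[ik] = step;
          fire2(i, j);
        }
      }
    }

    // 19: nuclear import (transport receptors on the nuclear membrane)
    if (E.r_import > 0) {
      for_type(T_NUC_IMPORT, [&](int i) {
        double d2a = 0, d2b = 0;
        int j = E.nearest(E.grid_type[T_NFKB], E.px[i], E.py[i], E.pz[i],
                          E.r_import, [&](int k) {
                            return !E.side_nuc[k] &&
                                   E.state[k] == S_NFKB_FREE;
                          }, &d2a);
        if (E.allow_ikb_import) {
          int jb = E.nearest(E.grid_type[T_IKB], E.px[i], E.py[i], E.pz[i],
                             E.r_import, [&](int k) {
                               return !E.side_nuc[k] &&
                                      E.state[k] == S_IKB_FREE;
                             }, &d2b);
          if (jb >= 0 && (j < 0 || d2b < d2a)) j = jb;
        }
        if (j >= 0) {
          double rr = Engine::rad(E.px[i], E.py[i], E.pz[i]);
          double f = (E.Rn - 0.4) / (rr > 1e-9 ? rr : 1.0);
          E.px[j] = E.px[i] * f; E.py[j] = E.py[i] * f; E.pz[j] = E.pz[i] * f;
          E.side_nuc[j] = 1;
          fire2(i, j);
          ++E.ev_import;
        }
      });
    }

    // 20: nuclear export (complexes, free IkB, IL-8)
    if (E.r_export > 0) {
      for_type(T_NUC_EXPORT, [&](int i) {
        double d2a = 0, d2b = 0, d2c = 0;
        int j = E.nearest(E.grid_type[T_NFKB], E.px[i], E.py[i], E.pz[i],
                          E.r_export, [&](int k) {
                            return E.side_nuc[k] &&
                                   E.state[k] == S_NFKB_BOUND;
                          }, &d2a);
        {
          int jb = E.nearest(E.grid_type[T_IKB], E.px[i], E.py[i], E.pz[i],
                             E.r_export, [&](int k) {
                               return E.side_nuc[k] &&
                                      E.state[k] == S_IKB_FREE;
                             }, &d2b);
          if (jb >= 0 && (j < 0 || d2b < d2a)) { j = jb; d2a = d2b; }
          int jc = E.nearest(E.grid_type[T_IL8], E.px[i], E.py[i], E.pz[i],
                             E.r_export, [&](int k) {
                               return E.side_nuc[k] &&
                                      E.state[k] == S_IL8_ACTIVE;
                             }, &d2c);
          if (jc >= 0 && (j < 0 || d2c < d2a)) j = jc;
        }
        if (j >= 0) {
          double rr = Engine::rad(E.px[i], E.py[i], E.pz[i]);
          double f = (E.Rn + 0.4) / (rr > 1e-9 ? rr : 1.0);
          E.px[j] = E.px[i] * f; E.py[j] = E.py[i] * f; E.pz[j] = E.pz[i] * f;
          E.side_nuc[j] = 0;
          if (E.type[j] == T_NFKB && E.partner[j] >= 0) {
            int ik = E.partner[j];
            E.px[ik] = E.px[j]; E.py[ik] = E.py[j]; E.pz[ik] = E.pz[j];
            E.side_nuc[ik] = 0;
          }
          fire2(i, j);
          ++E.ev_export;
        }
      });
    }

    // 21: transcription initiation (site engages free nuclear NFkB)
    for (int i : E.by_type[T_TX_SITE]) {
      if (!E.alive[i] || E.stamp[i] == step) continue;
      if (E.timer[i] > 0) continue; // busy
      double rtx = (E.hits[i] == 0) ? E.r_tx_ikb : E.r_tx_il8; // hits = gene
      if (rtx <= 0) continue;
      int j = E.nearest(E.grid_type[T_NFKB], E.px[i], E.py[i], E.pz[i], rtx,
                        [&](int k) {
                          return E.state[k] == S_NFKB_FREE && E.side_nuc[k];
                        });
      if (j >= 0) {
        E.timer[i] = E.tx_steps;
        E.stamp[i] = step;
        E.stamp[j] = step; // NFkB stays free (catalytic engagement)
        ++E.ev_tx;
      }
    }

    // -- unary updates (scheduled events: geometric lifetimes drawn at
    //    the state change, counted down here) ------------------------------
    for (int i : E.by_type[T_IKB]) {
      if (!E.alive[i]) continue;
      int s = E.state[i];
      if (s == S_IKB_BOUND_CYTO) {
        if (E.timer[i] > 0 && E.stamp[i] != step && --E.timer[i] <= 0) {
          int site = E.partner[i];
          if (site >= 0) release_site(site, E.ev_passive);
        }
      } else if (s == S_IKB_PHOSPHO) {
        if (--E.timer[i] <= 0) { E.kill(i); ++E.ev_deg; }
      } else if (s == S_IKB_TRANSCRIBED) {
        if (--E.timer[i] <= 0) E.state[i] = S_IKB_FREE;
      }
    }
    for (int i : E.by_type[T_IL8])
      if (E.alive[i] && E.state[i] == S_IL8_TRANSCRIBED && --E.timer[i] <= 0)
        E.state[i] = S_IL8_ACTIVE;
    for (int i : E.by_type[T_MYD88]) {
      int s = E.state[i];
      if (E.alive[i] && (s == S_ACTIVE_TILRR || s == S_ACTIVE_ACP) &&
          E.timer[i] > 0 && --E.timer[i] <= 0)
        E.state[i] = S_INACTIVE;
    }
    for (int t : {T_IRAK, T_TRAF, T_TAK, T_RAS, T_PI3K, T_AKT, T_IKK})
      for (int i : E.by_type[t])
        if (E.alive[i] && E.state[i] == S_ACTIVE && E.timer[i] > 0 &&
            --E.timer[i] <= 0)
          E.state[i] = S_INACTIVE;
    for (int i : E.by_type[T_ADISS])
      if (E.alive[i] && E.state[i] == S_ACTIVE && E.timer[i] > 0 &&
          --E.timer[i] <= 0) {
        E.state[i] = S_INACTIVE;
        --E.n_adiss_active;
      }
    for (int i : E.by_type[T_CASP3])
      if (E.alive[i] && E.state[i] == S_INACTIVE && E.timer[i] > 0 &&
          --E.timer[i] <= 0)
        E.state[i] = S_ACTIVE;
    for (int i : E.by_type[T_TX_SITE]) {
      if (!E.alive[i]) continue;
      if (E.timer[i] > 0 && --E.timer[i] <= 0) {
        // burst of gene product at the site position
        int gene_il8 = E.hits[i];
        int burst = gene_il8 ? E.burst_il8 : E.burst_ikb;
        for (int b = 0; b < burst; ++b) {
          int ni = E.spawn(gene_il8 ? T_IL8 : T_IKB,
                           gene_il8 ? S_IL8_TRANSCRIBED : S_IKB_TRANSCRIBED,
                           E.px[i], E.py[i], E.pz[i], true);
          if (ni >= 0) {
            E.timer[ni] = 2; // visible as nascent for one full step
            if (gene_il8) ++E.ev_syn_il8; else ++E.ev_syn_ikb;
          }
        }
      }
    }

    if ((step + 1) % record_every == 0) record(step + 1);
    if (step % 4000 == 0) Rcpp::checkUserInterrupt();
  }

  // final population back to R (1-based partners)
  int n_alive = 0;
  for (int i = 0; i < E.n_max; ++i) n_alive += E.alive[i];
  IntegerVector ft(E.n_max), fs(E.n_max), fp(E.n_max), fh(E.n_max),
      fa(E.n_max);
  NumericVector fx(E.n_max), fy(E.n_max), fz(E.n_max), ftm(E.n_max);
  for (int i = 0; i < E.n_max; ++i) {
    ft[i] = E.type[i]; fs[i] = E.state[i];
    fp[i] = E.partner[i] < 0 ? NA_INTEGER : E.partner[i] + 1;
    fh[i] = E.hits[i]; fa[i] = E.alive[i];
    fx[i] = E.px[i]; fy[i] = E.py[i]; fz[i] = E.pz[i]; ftm[i] = E.timer[i];
  }

  return List::create(
      _["record"] = rec, _["n_recorded"] = rec_row,
      _["overflow"] = E.overflow, _["n_alive"] = n_alive,
      _["population"] = List::create(
          _["type"] = ft, _["state"] = fs, _["partner"] = fp, _["hits"] = fh,
          _["alive"] = fa, _["x"] = fx, _["y"] = fy, _["z"] = fz,
          _["timer"] = ftm));
}

// ---------------------------------------------------------------------------
// standalone grid matcher used by find_pairs(); identical pairing semantics
// to the engine (initiators in index order, nearest available target, exact
// distance ties broken by the seeded stream)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix match_pairs_cpp(NumericVector ax, NumericVector ay,
                              NumericVector az, NumericVector bx,
                              NumericVector by, NumericVector bz,
                              double radius, double domain_radius, int seed1,
                              int seed2) {
  int na = ax.size(), nb = bx.size();
  if (radius <= 0 || na == 0 || nb == 0) return IntegerMatrix(0, 2);
  Xoshiro rng;
  rng.seed((uint64_t)(uint32_t)seed1, (uint64_t)(uint32_t)seed2);
  double h = std::max(radius, domain_radius / 64.0);
  Grid g;
  g.init(domain_radius, h, nb);
  for (int j = 0; j < nb; ++j) g.insert(j, bx[j], by[j], bz[j]);
  std::vector<char> used(nb, 0);
  std::vector<std::pair<int, int>> out;
  for (int i = 0; i < na; ++i) {
    int range = 1;
    int cx = g.axis(ax[i]), cy = g.axis(ay[i]), cz = g.axis(az[i]);
    double best_d2 = radius * radius;
    int best = -1;
    for (int ix = std::max(0, cx - range); ix <= std::min(g.n - 1, cx + range); ++ix)
      for (int iy = std::max(0, cy - range); iy <= std::min(g.n - 1, cy + range); ++iy)
        for (int iz = std::max(0, cz - range); iz <= std::min(g.n - 1, cz + range); ++iz) {
          int c = (ix * g.n + iy) * g.n + iz;
          for (int j = g.head[c]; j >= 0; j = g.nxt[j]) {
            if (used[j]) continue;
            double dx = bx[j] - ax[i], dy = by[j] - ay[i], dz = bz[j] - az[i];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best_d2 || (d2 == best_d2 && best >= 0 && rng.unif() < 0.5)) {
              best_d2 = d2;
              best = j;
            }
          }
        }
    if (best >= 0) {
      used[best] = 1;
      out.push_back(std::make_pair(i + 1, best + 1));
    }
  }
  IntegerMatrix m(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    m(k, 0) = out[k].first;
    m(k, 1) = out[k].second;
  }
  return m;
}

// Brownian displacement sampler sharing the engine's RNG, exposed so the
// motion law can be property-tested on the exact stream the engine uses.
// [[Rcpp::export]]
NumericMatrix brownian_steps_cpp(int n, double D, double dt, int seed1,
                                 int seed2) {
  Xoshiro rng;
  rng.seed((uint64_t)(uint32_t)seed1, (uint64_t)(uint32_t)seed2);
  double sd = std::sqrt(2.0 * D * dt);
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) m(i, k) = sd * rng.norm();
  return m;
}
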