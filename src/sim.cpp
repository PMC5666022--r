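// Lattice world and sub-model update rules for the droplet-growth model.
//
// Conventions: y decreases downward from the rod; an agent is "inactive"
// once settled into the structure and "active" while walking on it.  All
// randomness goes through R's RNG (unif_rand), so set.seed() on the R side
// makes every trajectory reproducible.  Maps are rebuilt per sub-step call;
// populations stay small (<= one agent per inflow step), so this is cheap
// and keeps each sub-model a pure function of the world state.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// pack a lattice site into one 64-bit key
static inline long long skey(int x, int y) {
  return (((long long)(unsigned int)x) << 32) | (long long)(unsigned int)y;
}

enum Variant { TM = 0, NTM = 1, TM_STABLE = 2, TM_UNSTABLE = 3 };
enum Pattern { PAT_UNDEF = 0, PAT_STABLE = 1, PAT_UNSTABLE = 2 };

struct Ag {
  int id, x, y;
  int state;    // 0 active, 1 inactive
  double thr;   // weight threshold (meaningful when inactive)
  double wt;    // borne weight (0 for active agents)
  bool up;      // climbed on a warning signal during the current step
  int pat;      // last local-pattern estimate
};

struct World {
  int rx, ry;              // rod site
  int t;
  int next_id;
  double n_entered, n_drop, n_eq4;
  std::vector<Ag> a;
};

struct Maps {
  std::unordered_map<long long, int> inact;                       // site -> agent index
  std::unordered_map<int, std::vector<int>> icol;                 // x -> sorted ys (inactive)
  std::unordered_map<long long, int> occ;                         // site -> occupant count
  std::unordered_map<int, std::vector<std::pair<int, int>>> occol; // x -> sorted (y, count)
};

static Maps build_maps(const World& w, bool need_occ) {
  Maps m;
  for (size_t i = 0; i < w.a.size(); ++i) {
    const Ag& ag = w.a[i];
    if (ag.state == 1) {
      m.inact[skey(ag.x, ag.y)] = (int)i;
      m.icol[ag.x].push_back(ag.y);
    }
    if (need_occ) m.occ[skey(ag.x, ag.y)] += 1;
  }
  for (auto& kv : m.icol) std::sort(kv.second.begin(), kv.second.end());
  if (need_occ) {
    for (auto& kv : m.occ) {
      int x = (int)(kv.first >> 32);
      int y = (int)(kv.first & 0xffffffffLL);
      m.occol[x].push_back(std::make_pair(y, kv.second));
    }
    for (auto& kv : m.occol) std::sort(kv.second.begin(), kv.second.end());
  }
  return m;
}

static inline int runif_int(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// ---- sub-models ------------------------------------------------------------

static void do_spawn(World& w, int phi, const std::vector<int>& ex,
                     const std::vector<int>& ey) {
  int ne = (int)ex.size();
  for (int i = 0; i < phi; ++i) {
    int e = ne == 1 ? 0 : runif_int(ne);
    Ag ag;
    ag.id = w.next_id++;
    ag.x = ex[e]; ag.y = ey[e];
    ag.state = 0; ag.thr = 0.0; ag.wt = 0.0; ag.up = false; ag.pat = PAT_UNDEF;
    w.a.push_back(ag);
    w.n_entered += 1;
  }
}

// One synchronous move per active agent against start-of-step occupancy.
// Moving into a site with no inactive occupant (and not the rod) settles the
// agent; simultaneous settlers on one site are resolved by a uniform winner,
// losers stay active on that site.
static void do_move_down(World& w, double py, double pxp, double pxm,
                         double thr0) {
  Maps m = build_maps(w, false);
  std::vector<int> act;
  for (size_t i = 0; i < w.a.size(); ++i)
    if (w.a[i].state == 0) act.push_back((int)i);

  std::unordered_map<long long, std::vector<int>> settlers;
  std::vector<long long> settle_keys;
  for (int i : act) {
    Ag& ag = w.a[i];
    double u = unif_rand();
    int tx = ag.x, ty = ag.y;
    if (u < py) ty -= 1;
    else if (u < py + pxp) tx += 1;
    else tx -= 1;
    if (ty > w.ry) continue; // never above the rod row (defensive; directions cannot raise y)
    ag.x = tx; ag.y = ty;
    bool has_inact = m.inact.count(skey(tx, ty)) > 0;
    bool rod_row = (ty == w.ry);
    if (!has_inact && !rod_row) {
      long long k = skey(tx, ty);
      if (!settlers.count(k)) settle_keys.push_back(k);
      settlers[k].push_back(i);
    }
  }
  // deterministic group order regardless of hash layout
  std::sort(settle_keys.begin(), settle_keys.end());
  for (long long k : settle_keys) {
    std::vector<int>& grp = settlers[k];
    int win = grp.size() == 1 ? grp[0] : grp[runif_int((int)grp.size())];
    Ag& ag = w.a[win];
    ag.state = 1;
    ag.thr = thr0;
    ag.wt = 0.0;
    ag.pat = PAT_UNDEF;
  }
}

// Removal of inactive agents left dangling at the end of a horizontal
// structure: no inactive agent (nor the rod) within |dx| <= 1 one row above.
// One synchronous pass against start-of-pass occupancy; not a droplet.
static std::vector<int> do_eq4(World& w) {
  Maps m = build_maps(w, false);
  std::vector<int> doomed_idx, doomed_id;
  for (size_t i = 0; i < w.a.size(); ++i) {
    Ag& ag = w.a[i];
    if (ag.state != 1) continue;
    bool sup = false;
    for (int dx = -1; dx <= 1 && !sup; ++dx)
      if (m.inact.count(skey(ag.x + dx, ag.y + 1))) sup = true;
    if (!sup && std::abs(w.rx - ag.x) <= 1 && w.ry == ag.y + 1) sup = true;
    if (!sup) { doomed_idx.push_back((int)i); doomed_id.push_back(ag.id); }
  }
  for (int j = (int)doomed_idx.size() - 1; j >= 0; --j)
    w.a.erase(w.a.begin() + doomed_idx[j]);
  w.n_eq4 += (double)doomed_id.size();
  return doomed_id;
}

// Weight borne by each inactive agent: every occupant (active or inactive)
// of an occupied site s in the 3-wide column strictly below a supporter in
// row r contributes n(s)/m_r(s), where the multiplicity m_r(s) is the number
// of inactive agents in row r whose supporting area contains s (i.e. within
// |dx| <= 1 of s).  Sharing is lateral, within a supporting row: each row's
// cut through the structure bears the full load inside its areas, split
// among that row's overlapping supporters.  Active agents bear no weight.
struct SiteRec { int x, y, n, n_rows; };

static void do_weights(World& w, std::vector<SiteRec>* sites_out) {
  Maps m = build_maps(w, true);
  // rows: y -> sorted xs of inactive agents
  std::unordered_map<int, std::vector<int>> rows;
  for (const auto& ag : w.a)
    if (ag.state == 1) rows[ag.y].push_back(ag.x);
  for (auto& kv : rows) std::sort(kv.second.begin(), kv.second.end());
  // number of inactive agents in row ry with x within [sx-1, sx+1]
  auto m_row = [&](int ry, int sx) -> int {
    auto it = rows.find(ry);
    if (it == rows.end()) return 0;
    const std::vector<int>& xs = it->second;
    return (int)(std::upper_bound(xs.begin(), xs.end(), sx + 1) -
                 std::lower_bound(xs.begin(), xs.end(), sx - 1));
  };
  for (auto& ag : w.a) ag.wt = 0.0;
  for (auto& ag : w.a) {
    if (ag.state != 1) continue;
    double wsum = 0.0;
    for (int dx = -1; dx <= 1; ++dx) {
      auto oc = m.occol.find(ag.x + dx);
      if (oc == m.occol.end()) continue;
      for (const auto& pr : oc->second) {
        if (pr.first >= ag.y) break; // ys ascending; need strictly below
        wsum += (double)pr.second / (double)m_row(ag.y, ag.x + dx);
      }
    }
    ag.wt = wsum;
  }
  if (sites_out) {
    for (const auto& kv : m.occ) {
      SiteRec r;
      r.x = (int)(kv.first >> 32);
      r.y = (int)(kv.first & 0xffffffffLL);
      r.n = kv.second;
      // number of distinct supporting rows whose areas cover this site
      int nr = 0;
      for (const auto& rv : rows)
        if (rv.first > r.y && m_row(rv.first, r.x) > 0) ++nr;
      r.n_rows = nr;
      sites_out->push_back(r);
    }
    std::sort(sites_out->begin(), sites_out->end(),
              [](const SiteRec& a, const SiteRec& b) {
                return a.x != b.x ? a.x < b.x : a.y < b.y;
              });
  }
}

// Warning signal: an inactive agent with weight >= threshold - 1 signals;
// the active agent directly beneath climbs one site, uniformly among the
// three up-sites that hold an inactive agent (the rod counts as occupied).
static void do_warning(World& w) {
  Maps m = build_maps(w, false);
  for (auto& ag : w.a) ag.up = false;
  for (auto& j : w.a) {
    if (j.state != 0) continue;
    auto it = m.inact.find(skey(j.x, j.y + 1));
    if (it == m.inact.end()) continue;
    const Ag& k = w.a[it->second];
    if (!(k.wt >= k.thr - 1.0)) continue;
    int ty = j.y + 1;
    if (ty > w.ry) continue;
    int cx[3] = { j.x, j.x + 1, j.x - 1 };
    std::vector<int> occd;
    for (int c = 0; c < 3; ++c) {
      bool o = m.inact.count(skey(cx[c], ty)) > 0 ||
               (cx[c] == w.rx && ty == w.ry);
      if (o) occd.push_back(c);
    }
    if (occd.empty()) continue;
    int pick = occd.size() == 1 ? occd[0] : occd[runif_int((int)occd.size())];
    j.x = cx[pick];
    j.y = ty;
    j.up = true;
  }
}

// Threshold coordination: an inactive agent with a climbing (moved-up)
// active agent within Chebyshev distance 1 adapts its threshold according
// to the local pattern estimated at the previous step.  Variant gating:
// TM both rules, TM_STABLE raise-only, TM_UNSTABLE collapse-only.
static void do_coord(World& w, int variant) {
  if (variant == NTM) return;
  std::unordered_set<long long> ups;
  for (const auto& j : w.a)
    if (j.state == 0 && j.up) ups.insert(skey(j.x, j.y));
  if (ups.empty()) return;
  for (auto& k : w.a) {
    if (k.state != 1 || k.pat == PAT_UNDEF) continue;
    bool near = false;
    for (int dx = -1; dx <= 1 && !near; ++dx)
      for (int dy = -1; dy <= 1 && !near; ++dy)
        if (ups.count(skey(k.x + dx, k.y + dy))) near = true;
    if (!near) continue;
    if (k.pat == PAT_UNSTABLE && (variant == TM || variant == TM_UNSTABLE))
      k.thr = k.wt;
    else if (k.pat == PAT_STABLE && (variant == TM || variant == TM_STABLE))
      k.thr += 1.0;
  }
}

// Local pattern: stable iff another inactive agent sits in the same row at
// |dx| = 1.  The rod is not a lateral neighbour.
static void do_pattern(World& w) {
  Maps m = build_maps(w, false);
  for (auto& k : w.a) {
    if (k.state != 1) continue;
    bool lat = m.inact.count(skey(k.x - 1, k.y)) > 0 ||
               m.inact.count(skey(k.x + 1, k.y)) > 0;
    k.pat = lat ? PAT_STABLE : PAT_UNSTABLE;
  }
}

// Fall: each breached supporter (threshold <= weight), taken in random
// order and re-checked at processing time, sheds every occupant of its
// supporting area; the trigger survives with weight 0, and supporters of
// any removed agent have their weight reset to 0.  All removals within a
// step merge into one droplet event.
struct FallResult { int size; int trigger; };

static FallResult do_fall(World& w) {
  FallResult res; res.size = 0; res.trigger = NA_INTEGER;
  std::vector<int> cand;
  for (size_t i = 0; i < w.a.size(); ++i)
    if (w.a[i].state == 1 && w.a[i].thr <= w.a[i].wt) cand.push_back((int)i);
  if (cand.empty()) return res;
  for (int i = (int)cand.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(cand[i], cand[j]);
  }
  std::vector<char> dead(w.a.size(), 0);
  for (int ci : cand) {
    Ag& k = w.a[ci];
    if (dead[ci]) continue;
    if (!(k.thr <= k.wt)) continue; // breach may have been relieved by an earlier fall
    if (res.trigger == NA_INTEGER) res.trigger = k.id;
    // the set supported by k: inactive agents reachable downward from k
    // through support links (|dx| <= 1, one row down), k itself excluded
    std::unordered_map<long long, int> inact_live;
    for (size_t i = 0; i < w.a.size(); ++i)
      if (!dead[i] && w.a[i].state == 1)
        inact_live[skey(w.a[i].x, w.a[i].y)] = (int)i;
    std::vector<int> rem;
    std::unordered_set<long long> rem_sites;
    std::vector<std::pair<int, int>> frontier;
    frontier.push_back(std::make_pair(k.x, k.y));
    std::unordered_set<long long> seen;
    seen.insert(skey(k.x, k.y));
    while (!frontier.empty()) {
      std::pair<int, int> cur = frontier.back();
      frontier.pop_back();
      for (int dx = -1; dx <= 1; ++dx) {
        int nx = cur.first + dx, ny = cur.second - 1;
        long long kk = skey(nx, ny);
        if (seen.count(kk)) continue;
        auto it = inact_live.find(kk);
        if (it == inact_live.end()) continue;
        seen.insert(kk);
        dead[it->second] = 1;
        rem.push_back(it->second);
        rem_sites.insert(kk);
        frontier.push_back(std::make_pair(nx, ny));
      }
    }
    // riders: active agents standing on a removed agent's site fall too
    for (size_t i = 0; i < w.a.size(); ++i) {
      if (dead[i] || w.a[i].state != 0) continue;
      if (rem_sites.count(skey(w.a[i].x, w.a[i].y))) {
        dead[i] = 1;
        rem.push_back((int)i);
      }
    }
    res.size += (int)rem.size();
    // co-supporters of removed agents lose their load
    for (size_t i = 0; i < w.a.size(); ++i) {
      if (dead[i] || w.a[i].state != 1) continue;
      Ag& s = w.a[i];
      for (int ri : rem) {
        const Ag& r = w.a[ri];
        if (std::abs(s.x - r.x) <= 1 && s.y > r.y) { s.wt = 0.0; break; }
      }
    }
    k.wt = 0.0;
  }
  std::vector<Ag> keep;
  keep.reserve(w.a.size());
  for (size_t i = 0; i < w.a.size(); ++i)
    if (!dead[i]) keep.push_back(w.a[i]);
  w.a.swap(keep);
  w.n_drop += (double)res.size;
  return res;
}

// ---- R <-> C++ world conversion -------------------------------------------

static World world_from_list(List lst) {
  World w;
  IntegerVector rod = lst["rod"];
  w.rx = rod[0]; w.ry = rod[1];
  w.t = as<int>(lst["t"]);
  w.next_id = as<int>(lst["next_id"]);
  w.n_entered = as<double>(lst["n_entered"]);
  w.n_drop = as<double>(lst["n_removed_droplet"]);
  w.n_eq4 = as<double>(lst["n_removed_eq4"]);
  DataFrame ad = as<DataFrame>(lst["agents"]);
  IntegerVector id = ad["id"], x = ad["x"], y = ad["y"];
  CharacterVector st = ad["state"], pat = ad["last_pattern"];
  NumericVector thr = ad["threshold"], wt = ad["weight"];
  LogicalVector up = ad["moved_up"];
  int n = id.size();
  w.a.reserve(n);
  for (int i = 0; i < n; ++i) {
    Ag ag;
    ag.id = id[i]; ag.x = x[i]; ag.y = y[i];
    ag.state = (st[i] == "inactive") ? 1 : 0;
    ag.thr = thr[i]; ag.wt = wt[i];
    ag.up = up[i] == TRUE;
    std::string p = as<std::string>(pat[i]);
    ag.pat = p == "stable" ? PAT_STABLE : (p == "unstable" ? PAT_UNSTABLE : PAT_UNDEF);
    w.a.push_back(ag);
  }
  return w;
}

static List world_to_list(const World& w) {
  int n = (int)w.a.size();
  IntegerVector id(n), x(n), y(n);
  CharacterVector st(n), pat(n);
  NumericVector thr(n), wt(n);
  LogicalVector up(n);
  for (int i = 0; i < n; ++i) {
    const Ag& ag = w.a[i];
    id[i] = ag.id; x[i] = ag.x; y[i] = ag.y;
    st[i] = ag.state == 1 ? "inactive" : "active";
    thr[i] = ag.thr; wt[i] = ag.wt; up[i] = ag.up;
    pat[i] = ag.pat == PAT_STABLE ? "stable"
           : (ag.pat == PAT_UNSTABLE ? "unstable" : "undefined");
  }
  DataFrame ad = DataFrame::create(
    _["id"] = id, _["x"] = x, _["y"] = y, _["state"] = st,
    _["threshold"] = thr, _["weight"] = wt, _["moved_up"] = up,
    _["last_pattern"] = pat, _["stringsAsFactors"] = false);
  List out = List::create(
    _["rod"] = IntegerVector::create(w.rx, w.ry),
    _["t"] = w.t, _["next_id"] = w.next_id,
    _["n_entered"] = w.n_entered,
    _["n_removed_droplet"] = w.n_drop,
    _["n_removed_eq4"] = w.n_eq4,
    _["agents"] = ad);
  out.attr("class") = "ant_world";
  return out;
}

// ---- exported step functions ----------------------------------------------

// [[Rcpp::export]]
List cpp_spawn(List world, int phi, IntegerMatrix entry) {
  World w = world_from_list(world);
  std::vector<int> ex(entry.nrow()), ey(entry.nrow());
  for (int i = 0; i < entry.nrow(); ++i) { ex[i] = entry(i, 0); ey[i] = entry(i, 1); }
  do_spawn(w, phi, ex, ey);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_move_down(List world, double prob_y_minus, double prob_x_plus,
                   double prob_x_minus, double threshold0) {
  World w = world_from_list(world);
  do_move_down(w, prob_y_minus, prob_x_plus, prob_x_minus, threshold0);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_remove_unsupported(List world) {
  World w = world_from_list(world);
  std::vector<int> ids = do_eq4(w);
  return List::create(_["world"] = world_to_list(w),
                      _["removed_ids"] = wrap(ids));
}

// [[Rcpp::export]]
List cpp_compute_weights(List world) {
  World w = world_from_list(world);
  std::vector<SiteRec> sites;
  do_weights(w, &sites);
  int ns = (int)sites.size();
  IntegerVector sx(ns), sy(ns), sn(ns), sm(ns);
  for (int i = 0; i < ns; ++i) {
    sx[i] = sites[i].x; sy[i] = sites[i].y;
    sn[i] = sites[i].n; sm[i] = sites[i].n_rows;
  }
  DataFrame sd = DataFrame::create(_["x"] = sx, _["y"] = sy,
                                   _["n_agents"] = sn, _["n_supporter_rows"] = sm);
  return List::create(_["world"] = world_to_list(w), _["sites"] = sd);
}

// [[Rcpp::export]]
List cpp_warning_signal(List world) {
  World w = world_from_list(world);
  do_warning(w);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_threshold_coordination(List world, int variant) {
  World w = world_from_list(world);
  do_coord(w, variant);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_local_pattern(List world) {
  World w = world_from_list(world);
  do_pattern(w);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_fall(List world) {
  World w = world_from_list(world);
  FallResult fr = do_fall(w);
  return List::create(_["world"] = world_to_list(w),
                      _["size"] = fr.size, _["trigger_id"] = fr.trigger);
}

// ---- full trial loop -------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_trial(int phi, double prob_y_minus, double prob_x_plus,
                   double prob_x_minus, double threshold0, int time_length,
                   int variant, IntegerMatrix entry, int rod_x, int rod_y,
                   bool keep_metrics) {
  World w;
  w.rx = rod_x; w.ry = rod_y; w.t = 0; w.next_id = 1;
  w.n_entered = 0; w.n_drop = 0; w.n_eq4 = 0;
  std::vector<int> ex(entry.nrow()), ey(entry.nrow());
  for (int i = 0; i < entry.nrow(); ++i) { ex[i] = entry(i, 0); ey[i] = entry(i, 1); }

  std::vector<int> ev_t, ev_size, ev_trig;
  std::vector<int> eq_t, eq_id;
  std::vector<int> mt, mni, mna, mw, mh;

  for (int t = 1; t <= time_length; ++t) {
    w.t = t;
    do_spawn(w, phi, ex, ey);
    do_move_down(w, prob_y_minus, prob_x_plus, prob_x_minus, threshold0);
    std::vector<int> rm = do_eq4(w);
    for (int id : rm) { eq_t.push_back(t); eq_id.push_back(id); }
    do_weights(w, nullptr);
    do_warning(w);
    if (variant != NTM) {
      do_coord(w, variant);
      do_pattern(w);
    }
    FallResult fr = do_fall(w);
    if (fr.size > 0) {
      ev_t.push_back(t); ev_size.push_back(fr.size); ev_trig.push_back(fr.trigger);
    }
    if (keep_metrics) {
      int ni = 0, na = 0, xmin = 0, xmax = 0, ymin = 0;
      bool any = false;
      for (const auto& ag : w.a) {
        if (ag.state == 1) {
          ++ni;
          if (!any) { xmin = xmax = ag.x; ymin = ag.y; any = true; }
          else {
            if (ag.x < xmin) xmin = ag.x;
            if (ag.x > xmax) xmax = ag.x;
            if (ag.y < ymin) ymin = ag.y;
          }
        } else ++na;
      }
      mt.push_back(t);
      mni.push_back(ni); mna.push_back(na);
      mw.push_back(any ? xmax - xmin + 1 : 0);
      mh.push_back(any ? w.ry - ymin : 0);
    }
  }

  DataFrame events = DataFrame::create(
    _["t"] = wrap(ev_t), _["size"] = wrap(ev_size),
    _["trigger_id"] = wrap(ev_trig));
  DataFrame eq4 = DataFrame::create(_["t"] = wrap(eq_t), _["id"] = wrap(eq_id));
  List out = List::create(
    _["events"] = events, _["eq4_removals"] = eq4,
    _["world"] = world_to_list(w));
  if (keep_metrics) {
    out["metrics"] = DataFrame::create(
      _["t"] = wrap(mt), _["n_inactive"] = wrap(mni),
      _["n_active"] = wrap(mna), _["width"] = wrap(mw),
      _["height"] = wrap(mh));
  }
  return out;
}
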