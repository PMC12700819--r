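#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time 1D lattice loop-extrusion engine.
// Update order per step: unload -> enforce targets (load / ramp-down
// unload) -> translocate extruders in a random permutation, each leg
// independently. Blocked steps are lost; lattice ends are hard walls.
// CTCF stalling: a leg of a CTCF-respecting species stepping onto a
// correctly oriented site stalls there permanently with prob q.

struct Engine {
  int L;
  std::vector<int> left, right, species, uid;
  std::vector<char> sl, sr;            // stalled flags
  std::vector<int> occ;                // site -> extruder slot, -1 free
  std::vector<int> load_time;
  int next_uid = 0;

  Engine(int L_) : L(L_), occ(L_, -1) {}

  int n() const { return (int)left.size(); }

  void place(int sp, int a, int b, int t) {
    left.push_back(a); right.push_back(b); species.push_back(sp);
    sl.push_back(0); sr.push_back(0);
    uid.push_back(next_uid++); load_time.push_back(t);
    occ[a] = n() - 1; occ[b] = n() - 1;
  }

  void remove(int i) {
    occ[left[i]] = -1; occ[right[i]] = -1;
    int last = n() - 1;
    if (i != last) {
      left[i] = left[last]; right[i] = right[last];
      species[i] = species[last]; sl[i] = sl[last]; sr[i] = sr[last];
      uid[i] = uid[last]; load_time[i] = load_time[last];
      occ[left[i]] = i; occ[right[i]] = i;
    }
    left.pop_back(); right.pop_back(); species.pop_back();
    sl.pop_back(); sr.pop_back(); uid.pop_back(); load_time.pop_back();
  }
};

static inline int rint_below(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List run_extrusion_cpp(int L, int n_steps,
                       NumericVector p, NumericVector p_unload,
                       LogicalVector respects_ctcf, NumericVector q_stall,
                       NumericMatrix targets,
                       IntegerVector ctcf_site, IntegerVector ctcf_orient,
                       IntegerVector init_left, IntegerVector init_right,
                       IntegerVector init_species,
                       LogicalVector init_sl, LogicalVector init_sr,
                       int stride, bool record_bridges,
                       bool quench) {
  int n_species = p.size();
  Engine eng(L);
  // CTCF stall probability by direction of motion onto the site:
  // orientation +1 stalls legs moving in the decreasing-index direction,
  // -1 stalls legs moving in the increasing-index direction.
  std::vector<char> stall_dec(L, 0), stall_inc(L, 0);
  for (int k = 0; k < ctcf_site.size(); ++k) {
    int s = ctcf_site[k];
    if (s < 0 || s >= L) stop("CTCF site out of lattice bounds");
    if (ctcf_orient[k] > 0) stall_dec[s] = 1;
    else stall_inc[s] = 1;
  }

  for (int i = 0; i < init_left.size(); ++i) {
    int a = init_left[i], b = init_right[i];
    if (a < 0 || b >= L || a > b) stop("invalid initial extruder state");
    if (eng.occ[a] >= 0 || eng.occ[b] >= 0)
      stop("initial occupancy conflict");
    eng.place(init_species[i], a, b, 0);
    eng.sl[eng.n() - 1] = init_sl[i];
    eng.sr[eng.n() - 1] = init_sr[i];
  }

  std::vector<int> fr_frame, fr_uid, fr_species, fr_left, fr_right;
  std::vector<char> fr_sl, fr_sr;
  std::vector<double> episodes;
  std::vector<int> br_left, br_right, br_off;
  br_off.push_back(0);

  std::vector<int> perm;
  std::vector<int> count(n_species, 0);
  for (int i = 0; i < eng.n(); ++i) count[eng.species[i]]++;

  auto snapshot = [&](int t) {
    for (int i = 0; i < eng.n(); ++i) {
      fr_frame.push_back(t); fr_uid.push_back(eng.uid[i]);
      fr_species.push_back(eng.species[i]);
      fr_left.push_back(eng.left[i]); fr_right.push_back(eng.right[i]);
      fr_sl.push_back(eng.sl[i]); fr_sr.push_back(eng.sr[i]);
    }
  };
  snapshot(0);

  for (int t = 1; t <= n_steps; ++t) {
    if (!quench) {
      // 1. stochastic unloading
      for (int i = eng.n() - 1; i >= 0; --i) {
        if (unif_rand() < p_unload[eng.species[i]]) {
          episodes.push_back(t - eng.load_time[i]);
          count[eng.species[i]]--;
          eng.remove(i);
        }
      }
      // 2. enforce targets: ramp-down by random unload, then load
      for (int sp = 0; sp < n_species; ++sp) {
        double traw = targets(t - 1, sp);
        int tgt = (int)std::floor(traw);
        double frac = traw - tgt;
        if (frac > 0 && unif_rand() < frac) tgt++;
        if (tgt > L / 2)
          stop("target count %d exceeds available site pairs", tgt);
        while (count[sp] > tgt) {
          // remove a uniformly random extruder of this species
          int pick = rint_below(count[sp]);
          for (int i = 0; i < eng.n(); ++i) {
            if (eng.species[i] == sp && pick-- == 0) {
              count[sp]--; eng.remove(i); break;
            }
          }
        }
        int guard = 0;
        while (count[sp] < tgt) {
          int site = -1;
          for (int tries = 0; tries < 100; ++tries) {
            int s = rint_below(L - 1);
            if (eng.occ[s] < 0 && eng.occ[s + 1] < 0) { site = s; break; }
          }
          if (site < 0) {
            for (int s = 0; s + 1 < L; ++s)
              if (eng.occ[s] < 0 && eng.occ[s + 1] < 0) { site = s; break; }
          }
          if (site < 0)
            stop("no free adjacent site pair for loading (species %d)", sp);
          eng.place(sp, site, site + 1, t);
          count[sp]++;
          if (++guard > L) stop("loading failed to reach target");
        }
      }
      // 3. translocation in random permutation order
      perm.resize(eng.n());
      for (int i = 0; i < eng.n(); ++i) perm[i] = i;
      for (int i = eng.n() - 1; i > 0; --i) {
        int j = rint_below(i + 1);
        std::swap(perm[i], perm[j]);
      }
      for (int k = 0; k < (int)perm.size(); ++k) {
        int i = perm[k];
        int sp = eng.species[i];
        double ps = p[sp];
        // left leg moves in the decreasing-index direction
        if (!eng.sl[i] && ps > 0 && unif_rand() < ps) {
          int dest = eng.left[i] - 1;
          if (dest >= 0 && eng.occ[dest] < 0) {
            double q = (respects_ctcf[sp] && stall_dec[dest]) ?
                       q_stall[sp] : 0.0;
            bool stall = q > 0 && unif_rand() < q;
            eng.occ[eng.left[i]] = -1;
            eng.left[i] = dest; eng.occ[dest] = i;
            if (stall) eng.sl[i] = 1;
          }
        }
        // right leg moves in the increasing-index direction
        if (!eng.sr[i] && ps > 0 && unif_rand() < ps) {
          int dest = eng.right[i] + 1;
          if (dest < L && eng.occ[dest] < 0) {
            double q = (respects_ctcf[sp] && stall_inc[dest]) ?
                       q_stall[sp] : 0.0;
            bool stall = q > 0 && unif_rand() < q;
            eng.occ[eng.right[i]] = -1;
            eng.right[i] = dest; eng.occ[dest] = i;
            if (stall) eng.sr[i] = 1;
          }
        }
      }
    }
    if (record_bridges) {
      for (int i = 0; i < eng.n(); ++i) {
        br_left.push_back(eng.left[i]);
        br_right.push_back(eng.right[i]);
      }
      br_off.push_back((int)br_left.size());
    }
    if (t % stride == 0 || t == n_steps) snapshot(t);
  }

  List frames = List::create(
    _["frame"] = wrap(fr_frame), _["uid"] = wrap(fr_uid),
    _["species"] = wrap(fr_species), _["left"] = wrap(fr_left),
    _["right"] = wrap(fr_right),
    _["left_stalled"] = LogicalVector(fr_sl.begin(), fr_sl.end()),
    _["right_stalled"] = LogicalVector(fr_sr.begin(), fr_sr.end()));
  List fin = List::create(
    _["left"] = wrap(eng.left), _["right"] = wrap(eng.right),
    _["species"] = wrap(eng.species),
    _["left_stalled"] = LogicalVector(eng.sl.begin(), eng.sl.end()),
    _["right_stalled"] = LogicalVector(eng.sr.begin(), eng.sr.end()));
  List out = List::create(
    _["frames"] = frames, _["episodes"] = wrap(episodes),
    _["final"] = fin);
  if (record_bridges) {
    out["bridge_left"] = wrap(br_left);
    out["bridge_right"] = wrap(br_right);
    out["bridge_offsets"] = wrap(br_off);
  }
  return out;
}
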