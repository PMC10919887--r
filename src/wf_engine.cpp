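// Forward-time Wright-Fisher engine for the ZW sex-determining locus.
//
// Haplotypes are stored sparsely as sorted (position, base) difference
// vectors against the reference.  Sex is emergent: an individual is female
// iff at least one haplotype is fully functional (W-class).  Recombination
// between homologs is suppressed linearly in their divergence d:
//   r = r0 * max(0, 1 - c * d), per-meiosis crossover probability L * r.
// All randomness comes from R's RNG (seed with set.seed before calling).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<int> pos;   // 0-based, sorted
  std::vector<int> base;  // codes 1..4
  bool functional;
};

struct Ind {
  Hap h[2];
  bool female;
  int d;  // cached divergence between h[0] and h[1]; -1 = not computed
};

// lof lookup: lof[(p * 4) + (b - 1)] for position p, base code b
inline bool hap_functional(const Hap &h, const std::vector<char> &lof) {
  for (size_t i = 0; i < h.pos.size(); ++i) {
    if (lof[(size_t)h.pos[i] * 4 + (h.base[i] - 1)]) return false;
  }
  return true;
}

// number of positions where the two copies carry different bases
int hap_diff(const Hap &a, const Hap &b) {
  size_t i = 0, j = 0;
  int d = 0;
  while (i < a.pos.size() && j < b.pos.size()) {
    if (a.pos[i] < b.pos[j]) { ++d; ++i; }
    else if (a.pos[i] > b.pos[j]) { ++d; ++j; }
    else { if (a.base[i] != b.base[j]) ++d; ++i; ++j; }
  }
  d += (int)(a.pos.size() - i) + (int)(b.pos.size() - j);
  return d;
}

// gamete = left of `a` (pos < bp) + right of `b` (pos >= bp)
void crossover_into(Hap &g, const Hap &a, const Hap &b, int bp) {
  g.pos.clear(); g.base.clear();
  for (size_t i = 0; i < a.pos.size() && a.pos[i] < bp; ++i) {
    g.pos.push_back(a.pos[i]); g.base.push_back(a.base[i]);
  }
  size_t j = 0;
  while (j < b.pos.size() && b.pos[j] < bp) ++j;
  for (; j < b.pos.size(); ++j) {
    g.pos.push_back(b.pos[j]); g.base.push_back(b.base[j]);
  }
}

// apply one point mutation at `p` to a uniformly chosen base among the
// three alternatives to the current base; reversion to reference deletes
// the entry
void mutate_site(Hap &g, int p, const IntegerVector &ref) {
  // locate p in g.pos (sorted)
  std::vector<int>::iterator it = std::lower_bound(g.pos.begin(), g.pos.end(), p);
  size_t idx = (size_t)(it - g.pos.begin());
  bool present = (it != g.pos.end() && *it == p);
  int cur = present ? g.base[idx] : ref[p];
  // pick one of the three non-current bases
  int k = (int)(unif_rand() * 3.0);
  if (k > 2) k = 2;
  int nb = 0, seen = 0;
  for (int b = 1; b <= 4; ++b) {
    if (b == cur) continue;
    if (seen == k) { nb = b; break; }
    ++seen;
  }
  if (nb == ref[p]) {
    if (present) { g.pos.erase(it); g.base.erase(g.base.begin() + idx); }
  } else if (present) {
    g.base[idx] = nb;
  } else {
    g.pos.insert(it, p);
    g.base.insert(g.base.begin() + idx, nb);
  }
}

}  // namespace

// [[Rcpp::export(name = ".wf_run_cpp")]]
List wf_run_cpp(IntegerVector ref, LogicalMatrix lof_mat,
                double mu, double r0, double cc,
                int two_n, int generations, int record_every,
                int init_site, int init_base,
                bool autosomal, bool multi_crossover) {
  const int L = ref.size();
  const int N = two_n / 2;
  const double mu_total = mu * L;

  // flatten LOF table (rows = base 1..4, cols = positions)
  std::vector<char> lof((size_t)L * 4, 0);
  for (int p = 0; p < L; ++p)
    for (int b = 0; b < 4; ++b)
      lof[(size_t)p * 4 + b] = (lof_mat(b, p) == TRUE) ? 1 : 0;

  RNGScope scope;

  // initial state: ceil(N/2) females W/Z, rest males Z/Z
  std::vector<Ind> pop(N), next(N);
  const int n_f0 = (N + 1) / 2;
  for (int i = 0; i < N; ++i) {
    Hap z; z.pos.push_back(init_site); z.base.push_back(init_base);
    z.functional = false;
    if (i < n_f0) {
      pop[i].h[0] = Hap(); pop[i].h[0].functional = true;
      pop[i].h[1] = z;
      pop[i].female = true;
    } else {
      pop[i].h[0] = z; pop[i].h[1] = z;
      pop[i].female = false;
    }
    pop[i].d = -1;
  }

  std::vector<int> females, males;
  std::vector<int> rec_gen, rec_w, rec_lof_sites;

  int status = 0;  // 0 = completed, 1 = extinct_single_sex
  int gen = 0;
  Hap gam;

  for (gen = 0; gen < generations; ++gen) {
    females.clear(); males.clear();
    for (int i = 0; i < N; ++i) (pop[i].female ? females : males).push_back(i);

    if (record_every > 0 && gen % record_every == 0) {
      int nw = 0;
      std::vector<int> lofpos;
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 2; ++c) {
          const Hap &h = pop[i].h[c];
          if (h.functional) ++nw;
          for (size_t k = 0; k < h.pos.size(); ++k)
            if (lof[(size_t)h.pos[k] * 4 + (h.base[k] - 1)]) lofpos.push_back(h.pos[k]);
        }
      std::sort(lofpos.begin(), lofpos.end());
      lofpos.erase(std::unique(lofpos.begin(), lofpos.end()), lofpos.end());
      rec_gen.push_back(gen); rec_w.push_back(nw);
      rec_lof_sites.push_back((int)lofpos.size());
    }

    if (!autosomal && (females.empty() || males.empty())) { status = 1; break; }
    if (autosomal) { females.resize(0); males.resize(0); }

    for (int k = 0; k < N; ++k) {
      int mi, fi;
      if (autosomal) {
        mi = (int)(unif_rand() * N); if (mi >= N) mi = N - 1;
        fi = (int)(unif_rand() * N); if (fi >= N) fi = N - 1;
      } else {
        mi = females[(int)(unif_rand() * females.size()) % females.size()];
        fi = males[(int)(unif_rand() * males.size()) % males.size()];
      }
      int parent[2] = {mi, fi};
      for (int c = 0; c < 2; ++c) {
        Ind &par = pop[parent[c]];
        if (par.d < 0) par.d = hap_diff(par.h[0], par.h[1]);
        double supp = 1.0 - cc * par.d;
        double pr = (supp > 0.0) ? L * r0 * supp : 0.0;
        if (pr > 1.0) pr = 1.0;
        Hap &child = next[k].h[c];

        bool done = false;
        if (par.d > 0 && pr > 0.0) {
          int ncross = 0;
          if (multi_crossover) {
            ncross = (int)R::rpois(pr);
          } else {
            ncross = (unif_rand() < pr) ? 1 : 0;
          }
          if (ncross > 0) {
            int a = (unif_rand() < 0.5) ? 0 : 1;
            if (ncross == 1) {
              int bp = 1 + (int)(unif_rand() * (L - 1));
              if (bp > L - 1) bp = L - 1;
              crossover_into(child, par.h[a], par.h[1 - a], bp);
            } else {
              // multiple crossovers: alternate source at each breakpoint
              std::vector<int> bps(ncross);
              for (int m = 0; m < ncross; ++m) {
                int bp = 1 + (int)(unif_rand() * (L - 1));
                if (bp > L - 1) bp = L - 1;
                bps[m] = bp;
              }
              std::sort(bps.begin(), bps.end());
              child.pos.clear(); child.base.clear();
              int seg_start = 0, src = a;
              for (int m = 0; m <= ncross; ++m) {
                int seg_end = (m == ncross) ? L : bps[m];
                const Hap &s = par.h[src];
                for (size_t q = 0; q < s.pos.size(); ++q)
                  if (s.pos[q] >= seg_start && s.pos[q] < seg_end) {
                    child.pos.push_back(s.pos[q]); child.base.push_back(s.base[q]);
                  }
                seg_start = seg_end; src = 1 - src;
              }
            }
            done = true;
          }
        }
        if (!done) {
          child = par.h[(unif_rand() < 0.5) ? 0 : 1];
        }

        if (mu_total > 0.0) {
          int nmut = (int)R::rpois(mu_total);
          for (int m = 0; m < nmut; ++m) {
            int p = (int)(unif_rand() * L); if (p >= L) p = L - 1;
            mutate_site(child, p, ref);
          }
        }
        child.functional = hap_functional(child, lof);
      }
      next[k].female = next[k].h[0].functional || next[k].h[1].functional;
      next[k].d = -1;
    }
    pop.swap(next);
  }

  // export final population
  List hap_pos(2 * N), hap_base(2 * N);
  LogicalVector female(N);
  for (int i = 0; i < N; ++i) {
    female[i] = pop[i].female;
    for (int c = 0; c < 2; ++c) {
      hap_pos[2 * i + c] = IntegerVector(pop[i].h[c].pos.begin(), pop[i].h[c].pos.end());
      hap_base[2 * i + c] = IntegerVector(pop[i].h[c].base.begin(), pop[i].h[c].base.end());
    }
  }

  List traj = R_NilValue;
  if (record_every > 0) {
    traj = List::create(
      _["generation"] = IntegerVector(rec_gen.begin(), rec_gen.end()),
      _["w_count"] = IntegerVector(rec_w.begin(), rec_w.end()),
      _["lof_site_count"] = IntegerVector(rec_lof_sites.begin(), rec_lof_sites.end()));
  }

  return List::create(
    _["status"] = status,
    _["generation"] = gen,
    _["hap_pos"] = hap_pos,
    _["hap_base"] = hap_base,
    _["female"] = female,
    _["trajectory"] = traj);
}
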