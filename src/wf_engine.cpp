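// Forward-in-time diploid Wright-Fisher engine with infinite-sites
// mutation on [1, L], Poisson recombination, backward migration
// (each offspring draws its parental deme), and a scheduled demography
// (found / resize / set_migration / remove / sample_and_stop events).
//
// Haplotypes are sorted vectors of mutated positions; the position is
// its own mutation identifier (redraw on collision against the live
// registry). Fixed and lost mutations are purged periodically so the
// registry only tracks segregating variation.

#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;

struct Deme {
  bool active = false;
  std::vector<Hap> haps;  // 2 per individual
  int size() const { return (int)haps.size() / 2; }
};

// event type codes (match R side)
enum EvType { EV_FOUND = 0, EV_RESIZE = 1, EV_MIG = 2, EV_REMOVE = 3,
              EV_SAMPLE = 4 };

static void make_gamete(const Hap& h1, const Hap& h2, Hap& out, int L,
                        double lam_rec, double lam_mut,
                        std::mt19937_64& rng,
                        std::unordered_set<int>& occupied) {
  std::poisson_distribution<int> prec(lam_rec);
  std::poisson_distribution<int> pmut(lam_mut);
  std::uniform_int_distribution<int> coin(0, 1);
  out.clear();
  int k = lam_rec > 0 ? prec(rng) : 0;
  int start = coin(rng);
  if (k == 0) {
    out = (start == 0) ? h1 : h2;
  } else {
    std::uniform_int_distribution<int> ubp(1, L - 1);
    std::vector<int> bp(k);
    for (int i = 0; i < k; ++i) bp[i] = ubp(rng);
    std::sort(bp.begin(), bp.end());
    bp.push_back(L);  // sentinel: last segment ends at L (inclusive)
    // segment i covers positions (prev, bp[i]]; haplotype alternates
    int prev = 0;
    int which = start;
    for (size_t i = 0; i < bp.size(); ++i) {
      const Hap& h = (which == 0) ? h1 : h2;
      Hap::const_iterator lo =
          std::upper_bound(h.begin(), h.end(), prev);
      Hap::const_iterator hi =
          std::upper_bound(h.begin(), h.end(), bp[i]);
      out.insert(out.end(), lo, hi);
      prev = bp[i];
      which = 1 - which;
    }
  }
  int nm = lam_mut > 0 ? pmut(rng) : 0;
  if (nm > 0) {
    std::uniform_int_distribution<int> upos(1, L);
    for (int i = 0; i < nm; ++i) {
      int pos;
      do { pos = upos(rng); } while (occupied.count(pos));
      occupied.insert(pos);
      Hap::iterator it = std::lower_bound(out.begin(), out.end(), pos);
      out.insert(it, pos);
    }
  }
}

static void purge(std::vector<Deme>& demes,
                  std::unordered_set<int>& occupied) {
  std::unordered_map<int, long> cnt;
  long total = 0;
  for (const Deme& d : demes) {
    if (!d.active) continue;
    total += (long)d.haps.size();
    for (const Hap& h : d.haps)
      for (int pos : h) ++cnt[pos];
  }
  std::unordered_set<int> fixed;
  std::unordered_set<int> segregating;
  for (std::unordered_map<int, long>::iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    if (it->second >= total) fixed.insert(it->first);
    else segregating.insert(it->first);
  }
  if (!fixed.empty()) {
    for (Deme& d : demes) {
      if (!d.active) continue;
      for (Hap& h : d.haps) {
        Hap keep;
        keep.reserve(h.size());
        for (int pos : h)
          if (!fixed.count(pos)) keep.push_back(pos);
        h.swap(keep);
      }
    }
  }
  occupied.swap(segregating);
}

// [[Rcpp::export]]
List wf_engine(int n_demes, int L, double mu, double rec,
               IntegerVector ev_gen, IntegerVector ev_type,
               IntegerVector ev_deme, IntegerVector ev_other,
               IntegerVector ev_n, NumericVector ev_rate,
               double seed, int sample_n = 0, int purge_every = 200) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double lam_mut = mu * (double)L;
  double lam_rec = rec * (double)(L - 1);

  std::vector<Deme> cur(n_demes), nxt(n_demes);
  std::vector<int> target(n_demes, 0);
  // migration[d] = list of (source deme, backward rate)
  std::vector<std::vector<std::pair<int, double> > > mig(n_demes);
  std::unordered_set<int> occupied;

  int n_ev = ev_gen.size();
  int ei = 0;
  // events must arrive sorted by generation
  for (int i = 1; i < n_ev; ++i)
    if (ev_gen[i] < ev_gen[i - 1])
      stop("events must be sorted by generation");

  // generation-0 events: de-novo founding of the ancestral deme(s)
  while (ei < n_ev && ev_gen[ei] == 0) {
    if (ev_type[ei] != EV_FOUND || ev_other[ei] != -1)
      stop("generation-0 events must found demes de novo");
    int d = ev_deme[ei];
    cur[d].active = true;
    cur[d].haps.assign(2 * (size_t)ev_n[ei], Hap());
    target[d] = ev_n[ei];
    ++ei;
  }
  if (ei == 0) stop("no generation-0 founding event");

  int stop_gen = -1;
  for (int i = 0; i < n_ev; ++i)
    if (ev_type[i] == EV_SAMPLE) stop_gen = ev_gen[i];
  if (stop_gen < 1) stop("schedule lacks a sample_and_stop event");

  std::vector<std::pair<int, int> > founded;  // (deme, source) this gen
  for (int g = 1; g <= stop_gen; ++g) {
    founded.clear();
    while (ei < n_ev && ev_gen[ei] == g) {
      int d = ev_deme[ei];
      switch (ev_type[ei]) {
      case EV_FOUND: {
        int src = ev_other[ei];
        if (src < 0 || !cur[src].active)
          stop("founding from an inactive deme");
        if (ev_n[ei] > cur[src].size())
          stop("deme size underflow: founders exceed source size");
        target[d] = ev_n[ei];
        founded.push_back(std::make_pair(d, src));
        break;
      }
      case EV_RESIZE:
        target[d] = ev_n[ei];
        break;
      case EV_MIG: {
        int o = ev_other[ei];
        double r = ev_rate[ei];
        // symmetric edge, backward convention, replace existing entry
        for (int a = 0; a < 2; ++a) {
          int from = a == 0 ? d : o, to = a == 0 ? o : d;
          bool hit = false;
          for (size_t q = 0; q < mig[from].size(); ++q)
            if (mig[from][q].first == to) { mig[from][q].second = r; hit = true; }
          if (!hit) mig[from].push_back(std::make_pair(to, r));
        }
        break;
      }
      case EV_REMOVE:
        cur[d].active = false;
        // drop migration edges touching d
        for (int o = 0; o < n_demes; ++o) {
          std::vector<std::pair<int, double> > keep;
          for (size_t q = 0; q < mig[o].size(); ++q)
            if (mig[o][q].first != d) keep.push_back(mig[o][q]);
          mig[o].swap(keep);
        }
        mig[d].clear();
        break;
      case EV_SAMPLE:
        break;  // handled after reproduction below
      default:
        stop("unknown event type");
      }
      ++ei;
    }

    // reproduce: existing active demes at their target size,
    // newly founded demes from their source (gamete buffers are
    // reused across generations to avoid per-gamete allocation)
    for (int d = 0; d < n_demes; ++d) nxt[d].active = false;
    for (int d = 0; d < n_demes; ++d) {
      int fsrc = -1;
      for (size_t q = 0; q < founded.size(); ++q)
        if (founded[q].first == d) fsrc = founded[q].second;
      if (!cur[d].active && fsrc < 0) continue;
      int nsz = target[d];
      nxt[d].active = true;
      nxt[d].haps.resize(2 * (size_t)nsz);
      for (int i = 0; i < nsz; ++i) {
        int src = d;
        if (fsrc >= 0) {
          src = fsrc;
        } else if (!mig[d].empty()) {
          double u = U(rng);
          double acc = 0.0;
          for (size_t q = 0; q < mig[d].size(); ++q) {
            acc += mig[d][q].second;
            if (u < acc) { src = mig[d][q].first; break; }
          }
          if (!cur[src].active) src = d;  // edge set before source exists
        }
        const Deme& sd = cur[src];
        std::uniform_int_distribution<int> up(0, sd.size() - 1);
        for (int gidx = 0; gidx < 2; ++gidx) {
          int par = up(rng);
          make_gamete(sd.haps[2 * par], sd.haps[2 * par + 1],
                      nxt[d].haps[2 * (size_t)i + gidx], L, lam_rec,
                      lam_mut, rng, occupied);
        }
      }
    }
    for (int d = 0; d < n_demes; ++d) {
      cur[d].active = nxt[d].active;
      cur[d].haps.swap(nxt[d].haps);
    }
    if (g % purge_every == 0) purge(cur, occupied);
  }

  purge(cur, occupied);

  // sample individuals (all, or the first sample_n per deme -- individuals
  // are exchangeable so a prefix is a uniform sample)
  std::vector<int> deme_of;
  std::vector<std::pair<int, int> > pick;  // (deme, individual index)
  for (int d = 0; d < n_demes; ++d) {
    if (!cur[d].active) continue;
    int nsz = cur[d].size();
    int take = (sample_n > 0 && sample_n < nsz) ? sample_n : nsz;
    for (int i = 0; i < take; ++i) {
      pick.push_back(std::make_pair(d, i));
      deme_of.push_back(d);
    }
  }
  int n_ind = (int)pick.size();
  // segregating positions among the sampled individuals
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < n_ind; ++i) {
    const Deme& d = cur[pick[i].first];
    for (int h = 0; h < 2; ++h)
      for (int pos : d.haps[2 * pick[i].second + h]) ++cnt[pos];
  }
  std::vector<int> positions;
  for (std::unordered_map<int, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second > 0 && it->second < 2 * n_ind)
      positions.push_back(it->first);
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> col;
  for (size_t j = 0; j < positions.size(); ++j) col[positions[j]] = (int)j;

  IntegerMatrix dos(n_ind, (int)positions.size());
  for (int i = 0; i < n_ind; ++i) {
    const Deme& d = cur[pick[i].first];
    for (int h = 0; h < 2; ++h)
      for (int pos : d.haps[2 * pick[i].second + h]) {
        std::unordered_map<int, int>::iterator it = col.find(pos);
        if (it != col.end()) dos(i, it->second) += 1;
      }
  }
  return List::create(_["dosages"] = dos,
                      _["positions"] = wrap(positions),
                      _["deme"] = wrap(deme_of));
}
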