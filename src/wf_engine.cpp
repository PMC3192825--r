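// Forward-in-time Wright-Fisher engine for one simulated window.
//
// Discrete generations, diploid, soft selection (fixed N), recombination
// drawn from a piecewise-constant genetic map (hotspot model), infinite-
// sites mutation at continuous positions, per-site fitness factors
// (1 + h s) heterozygous / (1 + s) homozygous combined multiplicatively
// and clamped at zero. Haplotypes are shared copy-on-write between
// generations: a gamete without crossover or mutation reuses its parent
// haplotype, which keeps the inner loop close to memcpy speed. Haplotype
// entries carry their own (single-precision) position so range queries
// and fitness merges never chase pointers into the mutation registry.
//
// All rates arriving here are already rescaled (lambda folded into mu, r,
// s and into N and times by the R wrapper).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <memory>
#include <unordered_map>
#include <unordered_set>
#include <vector>

namespace {

struct RNG {
  uint64_t s0, s1;
  double spare_normal = 0.0;
  bool has_spare = false;

  explicit RNG(uint64_t seed) {
    uint64_t z = seed;
    auto mix = [](uint64_t& z) {  // splitmix64 expansion of the seed
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z);
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {  // xorshift128+
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  double expo(double mean) { return -mean * std::log(1.0 - unif()); }
  int poisson(double lam) {  // Knuth; lambdas here are small (< ~20)
    if (lam <= 0) return 0;
    double limit = std::exp(-lam), prod = unif();
    int k = 0;
    while (prod > limit) {
      prod *= unif();
      ++k;
    }
    return k;
  }
  double normal() {
    if (has_spare) {
      has_spare = false;
      return spare_normal;
    }
    double u = 1.0 - unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), t = 6.283185307179586 * v;
    spare_normal = r * std::sin(t);
    has_spare = true;
    return r * std::cos(t);
  }
  double gamma(double shape, double scale) {  // Marsaglia-Tsang
    if (shape < 1.0) {
      double u = 1.0 - unif();
      return gamma(shape + 1.0, scale) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal(), v = 1.0 + c * x;
      if (v <= 0) continue;
      v = v * v * v;
      double u = 1.0 - unif();
      if (std::log(u) < 0.5 * x * x + d - d * v + d * std::log(v)) {
        return d * v * scale;
      }
    }
  }
};

struct Entry {
  float pos;
  uint32_t id;
};
inline bool operator<(const Entry& a, const Entry& b) {
  return a.pos < b.pos || (a.pos == b.pos && a.id < b.id);
}
inline bool pos_less(const Entry& e, float p) { return e.pos < p; }

struct Hap {
  std::vector<Entry> mut;  // all mutations, sorted by (position, id)
  std::vector<Entry> sel;  // subset with s != 0, same order
  double fit = 1.0;        // product over sel of max(1 + h s, 0)
};
using HapPtr = std::shared_ptr<Hap>;

struct Ind {
  HapPtr a, b;
  double w;  // diploid fitness, fixed at birth
};

struct FixRec {
  uint32_t id;
  double gen;  // absolute generation of fixation
};

struct Engine {
  // layout -----------------------------------------------------------
  double L;
  std::vector<double> feat_start, feat_end;
  std::vector<int> feat_type;  // 0 intergenic, 1 intron, 2 exon
  std::vector<int> exon_cum;   // cumulative exonic bp before feature
  // recombination map ------------------------------------------------
  std::vector<double> seg_start, seg_end, seg_cum;
  double morgans;  // expected crossovers per meiosis
  // mutation / selection --------------------------------------------
  double mu_total;
  bool window_positive;
  double pos_fraction, s_pos;
  bool use_gamma;
  double gamma_shape, gamma_scale;
  double intron_frac, s_intron;
  double h;
  bool any_selection;
  // registry ---------------------------------------------------------
  std::vector<double> mpos, ms;
  std::vector<int> mclass;  // 0 intergenic, 1 intron, 2 syn, 3 nonsyn
  RNG rng;
  std::vector<double> bp;  // crossover scratch

  explicit Engine(uint64_t seed) : rng(seed) {}

  double het_factor(double s) const {
    double f = 1.0 + h * s;
    return f > 0 ? f : 0.0;
  }

  uint32_t new_mutation() {
    double p = rng.unif() * L;
    int f = int(std::upper_bound(feat_end.begin(), feat_end.end(), p) -
                feat_end.begin());
    int cls = 0;
    double s = 0.0;
    switch (feat_type[f]) {
      case 2: {  // exon: third codon positions synonymous-neutral
        int off = exon_cum[f] + int(p - feat_start[f]);
        if (off % 3 == 2) {
          cls = 2;
        } else {
          cls = 3;
          if (window_positive && rng.unif() < pos_fraction) {
            s = s_pos;
          } else if (use_gamma) {
            s = -rng.gamma(gamma_shape, gamma_scale);
          }
        }
        break;
      }
      case 1:
        cls = 1;
        if (intron_frac > 0 && rng.unif() < intron_frac) s = -s_intron;
        break;
      default:
        cls = 0;
    }
    mpos.push_back(p);
    ms.push_back(s);
    mclass.push_back(cls);
    return uint32_t(mpos.size()) - 1;
  }

  double map_position() {
    double u = rng.unif();
    size_t i = std::upper_bound(seg_cum.begin(), seg_cum.end(), u) -
               seg_cum.begin();
    if (i >= seg_cum.size()) i = seg_cum.size() - 1;
    double lo_mass = i == 0 ? 0.0 : seg_cum[i - 1];
    double span = seg_cum[i] - lo_mass;
    double frac = span > 0 ? (u - lo_mass) / span : 0.5;
    return seg_start[i] + frac * (seg_end[i] - seg_start[i]);
  }

  // copy entries with pos in [lo, hi) from src to dst
  static void copy_range(const std::vector<Entry>& src, float lo, float hi,
                         std::vector<Entry>& dst) {
    auto it0 = std::lower_bound(src.begin(), src.end(), lo, pos_less);
    auto it1 = std::lower_bound(src.begin(), src.end(), hi, pos_less);
    dst.insert(dst.end(), it0, it1);
  }

  HapPtr gamete(const Ind& par) {
    int nx = morgans > 0 ? rng.poisson(morgans) : 0;
    int nm = rng.poisson(mu_total);
    bool first_a = rng.unif() < 0.5;
    if (nx == 0 && nm == 0) return first_a ? par.a : par.b;
    const Hap* src[2] = {first_a ? par.a.get() : par.b.get(),
                         first_a ? par.b.get() : par.a.get()};
    HapPtr out = std::make_shared<Hap>();
    if (nx == 0) {
      out->mut = src[0]->mut;
      out->sel = src[0]->sel;
      out->fit = src[0]->fit;
    } else {
      bp.resize(nx);
      for (int i = 0; i < nx; ++i) bp[i] = map_position();
      std::sort(bp.begin(), bp.end());
      out->mut.reserve(src[0]->mut.size() + 4);
      float lo = -1.0f;
      int cur = 0;
      for (int i = 0; i <= nx; ++i) {
        float hi = i < nx ? float(bp[i]) : float(L) + 1.0f;
        copy_range(src[cur]->mut, lo, hi, out->mut);
        if (any_selection) copy_range(src[cur]->sel, lo, hi, out->sel);
        cur ^= 1;
        lo = hi;
      }
      if (any_selection) {
        out->fit = 1.0;
        for (const Entry& e : out->sel) out->fit *= het_factor(ms[e.id]);
      }
    }
    for (int i = 0; i < nm; ++i) {
      uint32_t id = new_mutation();
      Entry e{float(mpos[id]), id};
      out->mut.insert(
          std::upper_bound(out->mut.begin(), out->mut.end(), e), e);
      if (any_selection && ms[id] != 0.0) {
        out->sel.insert(
            std::upper_bound(out->sel.begin(), out->sel.end(), e), e);
        out->fit *= het_factor(ms[id]);
      }
    }
    return out;
  }

  double ind_fitness(const HapPtr& a, const HapPtr& b) const {
    double w = a->fit * b->fit;
    if (w <= 0) return 0.0;
    if (a == b) {  // identical haplotypes: everything homozygous
      w = 1.0;
      for (const Entry& e : a->sel) {
        double whom = 1.0 + ms[e.id];
        w *= whom > 0 ? whom : 0.0;
      }
      return w;
    }
    const auto& A = a->sel;
    const auto& B = b->sel;
    size_t i = 0, j = 0;
    while (i < A.size() && j < B.size()) {
      if (A[i].id == B[j].id) {
        double s = ms[A[i].id];
        double whet = het_factor(s), whom = 1.0 + s;
        if (whom < 0) whom = 0;
        if (whet <= 0) return 0.0;
        w *= whom / (whet * whet);
        ++i;
        ++j;
      } else if (A[i] < B[j]) {
        ++i;
      } else {
        ++j;
      }
    }
    return w;
  }
};

struct Pop {
  std::vector<Ind> inds;
  std::unordered_set<uint32_t> active;  // ids segregating at last sweep
  std::unordered_set<uint32_t> pending; // fixed, recorded, not yet removed
  std::vector<FixRec> fixed;
  long n_lost = 0;
};

// one Wright-Fisher generation: children sampled from `parent`
void next_generation(Engine& E, const Pop& parent, Pop& child, int N_child) {
  const auto& P = parent.inds;
  int Np = int(P.size());
  child.inds.clear();
  child.inds.reserve(N_child);
  if (!E.any_selection) {
    for (int i = 0; i < N_child; ++i) {
      const Ind& mo = P[int(E.rng.unif() * Np)];
      const Ind& fa = P[int(E.rng.unif() * Np)];
      child.inds.push_back(Ind{E.gamete(mo), E.gamete(fa), 1.0});
    }
    return;
  }
  std::vector<double> cw(Np);
  double tot = 0.0;
  for (int i = 0; i < Np; ++i) {
    tot += P[i].w;
    cw[i] = tot;
  }
  auto pick = [&]() -> const Ind& {
    if (tot <= 0) return P[int(E.rng.unif() * Np)];
    double u = E.rng.unif() * tot;
    int k = int(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
    if (k >= Np) k = Np - 1;
    return P[k];
  };
  for (int i = 0; i < N_child; ++i) {
    HapPtr ga = E.gamete(pick());
    HapPtr gb = E.gamete(pick());
    double w = E.ind_fitness(ga, gb);
    child.inds.push_back(Ind{std::move(ga), std::move(gb), w});
  }
}

// frequency tally, fixation detection, loss bookkeeping. Removal of fixed
// mutations from the haplotypes is batched (a fixed mutation can never be
// lost again, and multiplies every fitness equally, so deferring its
// removal is exact); `force_remove` flushes the batch at phase boundaries.
void purge(Engine& E, Pop& pop, double gen_now, std::vector<int>& counts,
           std::vector<uint32_t>& touched, bool force_remove) {
  int twoN = int(pop.inds.size()) * 2;
  touched.clear();
  counts.resize(E.mpos.size(), 0);
  std::unordered_map<const Hap*, int> copies;
  copies.reserve(pop.inds.size() * 2);
  for (const auto& ind : pop.inds) {
    ++copies[ind.a.get()];
    ++copies[ind.b.get()];
  }
  for (const auto& kv : copies) {
    for (const Entry& e : kv.first->mut) {
      if (counts[e.id] == 0) touched.push_back(e.id);
      counts[e.id] += kv.second;
    }
  }
  std::unordered_set<uint32_t> now_active;
  now_active.reserve(touched.size());
  for (uint32_t id : touched) {
    if (counts[id] == twoN) {
      if (!pop.pending.count(id)) {
        pop.fixed.push_back(FixRec{id, gen_now});
        pop.pending.insert(id);
      }
    } else if (counts[id] > 0) {
      now_active.insert(id);
    }
  }
  for (uint32_t id : pop.active) {
    if (!now_active.count(id) && !pop.pending.count(id)) ++pop.n_lost;
  }
  pop.active.swap(now_active);
  if (!pop.pending.empty() && (force_remove || pop.pending.size() >= 16)) {
    const auto& gone = pop.pending;
    std::unordered_map<const Hap*, HapPtr> rebuilt;
    for (auto& ind : pop.inds) {
      for (HapPtr* hp : {&ind.a, &ind.b}) {
        const Hap* key = hp->get();
        auto it = rebuilt.find(key);
        if (it != rebuilt.end()) {
          *hp = it->second;
          continue;
        }
        HapPtr nh = std::make_shared<Hap>();
        nh->mut.reserve(key->mut.size());
        for (const Entry& e : key->mut) {
          if (!gone.count(e.id)) nh->mut.push_back(e);
        }
        nh->fit = 1.0;
        for (const Entry& e : key->sel) {
          if (!gone.count(e.id)) {
            nh->sel.push_back(e);
            nh->fit *= E.het_factor(E.ms[e.id]);
          }
        }
        rebuilt[key] = nh;
        *hp = nh;
      }
      // removing shared fixed factors rescales all fitnesses equally
      if (E.any_selection) ind.w = E.ind_fitness(ind.a, ind.b);
    }
    pop.pending.clear();
  }
  for (uint32_t id : touched) counts[id] = 0;  // reset scratch
}

}  // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
Rcpp::List wf_simulate(
    double L, Rcpp::NumericVector feat_start, Rcpp::NumericVector feat_end,
    Rcpp::IntegerVector feat_type, Rcpp::IntegerVector exon_cum,
    Rcpp::NumericVector seg_start, Rcpp::NumericVector seg_end,
    Rcpp::NumericVector seg_cum, double morgans, double mu_total,
    bool window_positive, double pos_fraction, double s_pos, bool use_gamma,
    double gamma_shape, double gamma_mean, double intron_frac,
    double s_intron, double h, int N_anc, int N_h, int N_c, int t_burn,
    int t_split, int bn_N, int bn_start, int bn_end, int n_sample_h,
    int n_sample_c, int purge_every, double seed) {
  Engine E(static_cast<uint64_t>(seed));
  E.L = L;
  E.feat_start = std::vector<double>(feat_start.begin(), feat_start.end());
  E.feat_end = std::vector<double>(feat_end.begin(), feat_end.end());
  E.feat_type = std::vector<int>(feat_type.begin(), feat_type.end());
  E.exon_cum = std::vector<int>(exon_cum.begin(), exon_cum.end());
  E.seg_start = std::vector<double>(seg_start.begin(), seg_start.end());
  E.seg_end = std::vector<double>(seg_end.begin(), seg_end.end());
  E.seg_cum = std::vector<double>(seg_cum.begin(), seg_cum.end());
  E.morgans = morgans;
  E.mu_total = mu_total;
  E.window_positive = window_positive;
  E.pos_fraction = pos_fraction;
  E.s_pos = s_pos;
  E.use_gamma = use_gamma;
  E.gamma_shape = gamma_shape;
  E.gamma_scale = gamma_shape > 0 ? gamma_mean / gamma_shape : 0.0;
  E.intron_frac = intron_frac;
  E.s_intron = s_intron;
  E.h = h;
  E.any_selection = (window_positive && pos_fraction > 0) || use_gamma ||
                    (intron_frac > 0 && s_intron > 0);

  std::vector<int> counts;
  std::vector<uint32_t> touched;
  double total_gens = double(t_burn + t_split);

  // ---- burn-in: panmictic ancestral population -----------------------
  Pop anc, tmp;
  anc.inds.reserve(N_anc);
  HapPtr empty = std::make_shared<Hap>();
  for (int i = 0; i < N_anc; ++i) anc.inds.push_back(Ind{empty, empty, 1.0});
  for (int g = 1; g <= t_burn; ++g) {
    next_generation(E, anc, tmp, N_anc);
    std::swap(anc.inds, tmp.inds);
    if (g % purge_every == 0 || g == t_burn) {
      purge(E, anc, double(g), counts, touched, g == t_burn);
    }
    if (g % 512 == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<FixRec> anc_fixed = std::move(anc.fixed);
  anc.fixed.clear();
  long seg_split = long(anc.active.size());

  // ---- split into the two descendant populations ---------------------
  Pop hum, chp;
  hum.active = anc.active;
  chp.active = anc.active;
  if (t_split > 0) {
    next_generation(E, anc, hum, N_h);
    next_generation(E, anc, chp, N_c);
    anc.inds.clear();
    anc.active.clear();
    for (int g = 2; g <= t_split; ++g) {
      int before_present = t_split - g;
      int Nh_now =
          (bn_N > 0 && before_present < bn_start && before_present >= bn_end)
              ? bn_N
              : N_h;
      next_generation(E, hum, tmp, Nh_now);
      std::swap(hum.inds, tmp.inds);
      next_generation(E, chp, tmp, N_c);
      std::swap(chp.inds, tmp.inds);
      if (g % purge_every == 0 || g == t_split) {
        purge(E, hum, double(t_burn + g), counts, touched,
              g == t_split);
        purge(E, chp, double(t_burn + g), counts, touched,
              g == t_split);
      }
      if (g % 512 == 0) Rcpp::checkUserInterrupt();
    }
    if (t_split == 1) {
      purge(E, hum, double(t_burn + 1), counts, touched, true);
      purge(E, chp, double(t_burn + 1), counts, touched, true);
    }
  } else {
    hum.inds = std::move(anc.inds);  // calibration mode: no demography
  }

  // ---- outputs -------------------------------------------------------
  auto sample_pop = [&](const Pop& pop, int n_hap) {
    Rcpp::List out(n_hap);
    int N = int(pop.inds.size());
    std::vector<int> idx(N);  // sample whole individuals w/o replacement
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < N - 1 && i < (n_hap + 1) / 2; ++i) {
      int j = i + int(E.rng.unif() * (N - i));
      std::swap(idx[i], idx[j]);
    }
    for (int k = 0; k < n_hap; ++k) {
      const Ind& ind = pop.inds[idx[k / 2]];
      const Hap* hp = (k % 2 == 0) ? ind.a.get() : ind.b.get();
      Rcpp::IntegerVector ids(hp->mut.size());
      for (size_t m = 0; m < hp->mut.size(); ++m) ids[m] = hp->mut[m].id;
      out[k] = ids;
    }
    return out;
  };
  auto freq_of = [&](const Pop& pop) {
    std::unordered_map<uint32_t, int> cnt;
    for (const auto& ind : pop.inds) {
      for (const Hap* hp : {ind.a.get(), ind.b.get()}) {
        for (const Entry& e : hp->mut) ++cnt[e.id];
      }
    }
    std::vector<int> ids, n;
    ids.reserve(cnt.size());
    n.reserve(cnt.size());
    for (const auto& kv : cnt) {
      ids.push_back(int(kv.first));
      n.push_back(kv.second);
    }
    return Rcpp::List::create(Rcpp::Named("id") = Rcpp::wrap(ids),
                              Rcpp::Named("count") = Rcpp::wrap(n));
  };
  auto fix_frame = [&](const std::vector<FixRec>& fx) {
    Rcpp::IntegerVector id(fx.size());
    Rcpp::NumericVector gbp(fx.size());
    for (size_t i = 0; i < fx.size(); ++i) {
      id[i] = int(fx[i].id);
      gbp[i] = total_gens - fx[i].gen;  // generations before present
    }
    return Rcpp::List::create(Rcpp::Named("id") = id,
                              Rcpp::Named("gen_before_present") = gbp);
  };

  int n_sh = std::min(n_sample_h, int(hum.inds.size()) * 2);
  int n_sc = t_split > 0 ? std::min(n_sample_c, int(chp.inds.size()) * 2) : 0;

  return Rcpp::List::create(
      Rcpp::Named("mut") = Rcpp::List::create(
          Rcpp::Named("pos") = Rcpp::wrap(E.mpos),
          Rcpp::Named("class") = Rcpp::wrap(E.mclass),
          Rcpp::Named("s") = Rcpp::wrap(E.ms)),
      Rcpp::Named("freq_h") = freq_of(hum),
      Rcpp::Named("freq_c") =
          t_split > 0 ? freq_of(chp)
                      : Rcpp::List::create(
                            Rcpp::Named("id") = Rcpp::IntegerVector(0),
                            Rcpp::Named("count") = Rcpp::IntegerVector(0)),
      Rcpp::Named("sample_h") = sample_pop(hum, n_sh),
      Rcpp::Named("sample_c") = t_split > 0
                                    ? Rcpp::List(sample_pop(chp, n_sc))
                                    : Rcpp::List(0),
      Rcpp::Named("fixed_h") = fix_frame(hum.fixed),
      Rcpp::Named("fixed_c") = fix_frame(chp.fixed),
      Rcpp::Named("fixed_anc") = fix_frame(anc_fixed),
      Rcpp::Named("bookkeeping") = Rcpp::List::create(
          Rcpp::Named("n_generated") = double(E.mpos.size()),
          Rcpp::Named("n_fixed_anc") = double(anc_fixed.size()),
          Rcpp::Named("n_fixed_h") = double(hum.fixed.size()),
          Rcpp::Named("n_fixed_c") = double(chp.fixed.size()),
          Rcpp::Named("n_lost_anc") = double(anc.n_lost),
          Rcpp::Named("n_lost_h") = double(hum.n_lost),
          Rcpp::Named("n_lost_c") = double(chp.n_lost),
          Rcpp::Named("n_seg_h") = double(hum.active.size()),
          Rcpp::Named("n_seg_c") = double(chp.active.size()),
          Rcpp::Named("n_seg_split") = double(seg_split)),
      Rcpp::Named("two_N_h") = int(hum.inds.size()) * 2);
}
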