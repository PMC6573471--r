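// Core generation cycle of the trap-model TE invasion simulator.
//
// Populations are vectors of haplotypes (2N sorted integer vectors of
// occupied genomic sites, individual i owning haplotypes 2i and 2i+1).
// All randomness goes through R's RNG so that set.seed() in R makes every
// simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Hap;

// -------------------------------------------------------------------------
// genome architecture

struct Arch {
  int nchrom;
  std::vector<int> start;    // global offset of chromosome start
  std::vector<int> len;      // chromosome length in bp
  std::vector<int> clen;     // cluster length (at chromosome start)
  std::vector<int> rlen;     // reference-region length (at chromosome end)
  std::vector<double> rr;    // recombination rate, cM/Mb
  std::vector<int> crec;     // 1 if crossovers may fall inside the cluster
  int total;                 // total genome size in bp
};

static Arch arch_from_list(List a) {
  Arch A;
  NumericVector len = a["length_bp"];
  NumericVector clen = a["cluster_len_bp"];
  NumericVector rlen = a["ref_len_bp"];
  NumericVector rr = a["recomb_rate"];
  LogicalVector cr = a["cluster_recombining"];
  A.nchrom = len.size();
  double off = 0;
  for (int i = 0; i < A.nchrom; i++) {
    A.start.push_back((int)off);
    A.len.push_back((int)len[i]);
    A.clen.push_back((int)clen[i]);
    A.rlen.push_back((int)rlen[i]);
    A.rr.push_back(rr[i]);
    A.crec.push_back(cr[i] ? 1 : 0);
    off += len[i];
    if (off > 2147483646.0)
      stop("total genome size exceeds the supported maximum (2^31-2 bp)");
  }
  A.total = (int)off;
  return A;
}

static inline int chrom_of(const Arch& A, int s) {
  int lo = 0, hi = A.nchrom - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (A.start[mid] <= s) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// 0 = GENOMIC, 1 = CLUSTER, 2 = REFERENCE
static inline int site_class(const Arch& A, int s) {
  int c = chrom_of(A, s);
  int off = s - A.start[c];
  if (off < A.clen[c]) return 1;
  if (off >= A.len[c] - A.rlen[c]) return 2;
  return 0;
}

// -------------------------------------------------------------------------
// gamete formation: per chromosome, Poisson crossovers (no interference),
// uniform breakpoints over the recombining part, random starting haplotype.
// A non-recombining cluster excludes breakpoints from the cluster interval
// and does not contribute to the map length.

static void copy_range(const Hap& h, int from, int to, Hap& out) {
  Hap::const_iterator lo = std::lower_bound(h.begin(), h.end(), from);
  Hap::const_iterator hi = std::lower_bound(lo, h.end(), to);
  out.insert(out.end(), lo, hi);
}

static void make_gamete(const Hap& h0, const Hap& h1, const Arch& A, Hap& out) {
  out.clear();
  const Hap* haps[2] = { &h0, &h1 };
  for (int c = 0; c < A.nchrom; c++) {
    int s = A.start[c], e = s + A.len[c];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    double rec_bp = A.crec[c] ? (double)A.len[c] : (double)(A.len[c] - A.clen[c]);
    double lambda = A.rr[c] * (rec_bp / 1e6) / 100.0;
    int nco = (lambda > 0) ? (int)R::rpois(lambda) : 0;
    if (nco == 0) {
      copy_range(*haps[cur], s, e, out);
      continue;
    }
    std::vector<int> bps(nco);
    int rstart = A.crec[c] ? s : s + A.clen[c];
    for (int j = 0; j < nco; j++) {
      int b = rstart + (int)(unif_rand() * rec_bp);
      if (b >= e) b = e - 1;
      bps[j] = b;
    }
    std::sort(bps.begin(), bps.end());
    int seg = s;
    for (int j = 0; j < nco; j++) {
      copy_range(*haps[cur], seg, bps[j], out);
      cur ^= 1;
      seg = bps[j];
    }
    copy_range(*haps[cur], seg, e, out);
  }
}

// -------------------------------------------------------------------------
// excision and transposition on a gamete (applied only for active parents)

// each non-reference site removed independently with probability v
static void excise(Hap& g, const Arch& A, double v) {
  if (v <= 0 || g.empty()) return;
  Hap keep;
  keep.reserve(g.size());
  for (size_t i = 0; i < g.size(); i++) {
    int s = g[i];
    if (site_class(A, s) == 2) { keep.push_back(s); continue; }
    if (unif_rand() >= v) keep.push_back(s);
  }
  g.swap(keep);
}

// Poisson(u * k) new insertions, k = non-reference copies on the gamete;
// uniform target site; draws landing on an occupied site are discarded.
static int transpose(Hap& g, const Arch& A, double u) {
  if (u <= 0) return 0;
  int k = 0;
  for (size_t i = 0; i < g.size(); i++)
    if (site_class(A, g[i]) != 2) k++;
  if (k == 0) return 0;
  int nnew = (int)R::rpois(u * (double)k);
  int added = 0;
  for (int j = 0; j < nnew; j++) {
    int s = (int)(unif_rand() * (double)A.total);
    if (s >= A.total) s = A.total - 1;
    Hap::iterator it = std::lower_bound(g.begin(), g.end(), s);
    if (it != g.end() && *it == s) continue;  // collision: discarded
    g.insert(it, s);
    added++;
  }
  return added;
}

// -------------------------------------------------------------------------
// fitness: model 0 = linear w=1-x*n, 1 = exponential w=1-x*n^t,
// 2 = cluster-neutral w=1-x*n_genomic; floored at 0.
// n counts all non-reference copies (cluster copies included except in
// the cluster-neutral model).

static inline double fitness_w(int n_nonref, int n_genomic,
                               double x, double t, int model) {
  double w;
  if (model == 2)      w = 1.0 - x * (double)n_genomic;
  else if (model == 1) w = 1.0 - x * std::pow((double)n_nonref, t);
  else                 w = 1.0 - x * (double)n_nonref;
  return (w < 0.0) ? 0.0 : w;
}

// -------------------------------------------------------------------------
// per-generation population summaries

struct GenStats {
  double total_copies, mean_n, mean_cluster, mean_ref, frac_cluster, mean_w;
  int fixed_cluster;
  int seg_cluster, seg_genomic, seg_ref;
  bool seg_valid;
};

static void compute_stats(const std::vector<Hap>& pop, const Arch& A,
                          double x, double t, int model, bool full,
                          GenStats& S, std::vector<double>& w,
                          std::vector<int>& ncl) {
  int N = (int)pop.size() / 2;
  w.assign(N, 0.0);
  ncl.assign(N, 0);
  double tot = 0, totcl = 0, totref = 0, sumw = 0;
  int withcl = 0;
  for (int i = 0; i < N; i++) {
    int n_tot = 0, n_cl = 0, n_ref = 0;
    for (int h = 0; h < 2; h++) {
      const Hap& hp = pop[2 * i + h];
      n_tot += (int)hp.size();
      for (size_t j = 0; j < hp.size(); j++) {
        int c = site_class(A, hp[j]);
        if (c == 1) n_cl++; else if (c == 2) n_ref++;
      }
    }
    int n_nonref = n_tot - n_ref;
    int n_gen = n_nonref - n_cl;
    double wi = fitness_w(n_nonref, n_gen, x, t, model);
    w[i] = wi;
    ncl[i] = n_cl;
    tot += n_tot; totcl += n_cl; totref += n_ref; sumw += wi;
    if (n_cl > 0) withcl++;
  }
  S.total_copies = tot;
  S.mean_n = tot / N;
  S.mean_cluster = totcl / N;
  S.mean_ref = totref / N;
  S.frac_cluster = (double)withcl / N;
  S.mean_w = sumw / N;

  // fixed cluster sites: cluster sites present on every haplotype;
  // incremental intersection with early exit keeps this cheap.
  std::vector<int> cand;
  for (size_t j = 0; j < pop[0].size(); j++)
    if (site_class(A, pop[0][j]) == 1) cand.push_back(pop[0][j]);
  for (size_t h = 1; h < pop.size() && !cand.empty(); h++) {
    const Hap& hp = pop[h];
    std::vector<int> keep;
    for (size_t j = 0; j < cand.size(); j++)
      if (std::binary_search(hp.begin(), hp.end(), cand[j]))
        keep.push_back(cand[j]);
    cand.swap(keep);
  }
  S.fixed_cluster = (int)cand.size();

  S.seg_valid = full;
  S.seg_cluster = S.seg_genomic = S.seg_ref = 0;
  if (full) {
    std::vector<int> buf;
    buf.reserve((size_t)tot);
    for (size_t h = 0; h < pop.size(); h++)
      buf.insert(buf.end(), pop[h].begin(), pop[h].end());
    std::sort(buf.begin(), buf.end());
    int twoN = (int)pop.size();
    size_t i = 0;
    while (i < buf.size()) {
      size_t j = i;
      while (j < buf.size() && buf[j] == buf[i]) j++;
      if ((int)(j - i) < twoN) {
        int c = site_class(A, buf[i]);
        if (c == 1) S.seg_cluster++;
        else if (c == 2) S.seg_ref++;
        else S.seg_genomic++;
      }
      i = j;
    }
  }
}

// fitness-proportional parent choice via binary search on cumulative weights
static inline int pick_parent(const std::vector<double>& cumw) {
  double r = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), r) - cumw.begin());
}

static std::vector<Hap> pop_from_list(List pop0) {
  int n = pop0.size();
  std::vector<Hap> pop(n);
  for (int i = 0; i < n; i++) {
    IntegerVector h = pop0[i];
    pop[i].assign(h.begin(), h.end());
    std::sort(pop[i].begin(), pop[i].end());
  }
  return pop;
}

static List pop_to_list(const std::vector<Hap>& pop) {
  List out(pop.size());
  for (size_t i = 0; i < pop.size(); i++)
    out[i] = IntegerVector(pop[i].begin(), pop[i].end());
  return out;
}

// one full generation cycle: (1) fitness-proportional parents, (2) one
// recombinant gamete per parent, (3) excisions, (4) novel insertions,
// (5) zygote = union of gametes; silencing (steps 3-4 skipped) is a
// property of the diploid parent carrying >=1 cluster insertion.
static int do_step(std::vector<Hap>& pop, std::vector<Hap>& next,
                   const Arch& A, double u, double v,
                   const std::vector<double>& cumw,
                   const std::vector<int>& ncl) {
  int N = (int)pop.size() / 2;
  next.assign(2 * N, Hap());
  int novel = 0;
  for (int i = 0; i < N; i++) {
    for (int h = 0; h < 2; h++) {
      int par = pick_parent(cumw);
      Hap& g = next[2 * i + h];
      make_gamete(pop[2 * par], pop[2 * par + 1], A, g);
      if (ncl[par] == 0) {           // active parent: TE transposes/excises
        excise(g, A, v);
        novel += transpose(g, A, u);
      }
    }
  }
  pop.swap(next);
  return novel;
}

// -------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
List cpp_run_invasion(List arch, List pop0, double u, double v, double x,
                      double t, int model, int generations,
                      double stop_total_copies, int post_fixation_generations,
                      int full_stats_interval, bool return_population) {
  Arch A = arch_from_list(arch);
  std::vector<Hap> pop = pop_from_list(pop0);
  std::vector<Hap> scratch;
  int N = (int)pop.size() / 2;
  if (N < 1) stop("population is empty");

  std::vector<double> w;
  std::vector<int> ncl;
  GenStats S;

  std::vector<double> r_gen, r_mean_n, r_mean_cl, r_mean_ref, r_frac,
      r_meanw, r_novel;
  std::vector<int> r_fixed, r_segc, r_segg, r_segr;
  std::vector<int> r_segvalid;

  int status = 0;  // 0 completed, 1 lost, 2 extinct
  int first_fix = -1;

  for (int g = 0; g <= generations; g++) {
    bool full = (full_stats_interval <= 1) || (g % full_stats_interval == 0);
    if (g > 0) {
      if (S.mean_w <= 0.0) { status = 2; break; }
      std::vector<double> cumw(N);
      double acc = 0;
      for (int i = 0; i < N; i++) { acc += w[i]; cumw[i] = acc; }
      int novel = do_step(pop, scratch, A, u, v, cumw, ncl);
      r_novel.push_back((double)novel / N);
    } else {
      r_novel.push_back(NA_REAL);
    }
    compute_stats(pop, A, x, t, model, full, S, w, ncl);
    r_gen.push_back(g);
    r_mean_n.push_back(S.mean_n);
    r_mean_cl.push_back(S.mean_cluster);
    r_mean_ref.push_back(S.mean_ref);
    r_frac.push_back(S.frac_cluster);
    r_meanw.push_back(S.mean_w);
    r_fixed.push_back(S.fixed_cluster);
    r_segvalid.push_back(S.seg_valid ? 1 : 0);
    r_segc.push_back(S.seg_valid ? S.seg_cluster : NA_INTEGER);
    r_segg.push_back(S.seg_valid ? S.seg_genomic : NA_INTEGER);
    r_segr.push_back(S.seg_valid ? S.seg_ref : NA_INTEGER);

    if (S.total_copies <= 0) { status = 1; break; }
    if (S.mean_w < 0.1) { status = 2; break; }
    if (S.total_copies > stop_total_copies) { status = 0; break; }
    if (S.fixed_cluster > 0 && first_fix < 0) first_fix = g;
    if (first_fix >= 0 && post_fixation_generations >= 0 &&
        g - first_fix >= post_fixation_generations) { status = 0; break; }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List rec = List::create(
      _["generation"] = wrap(r_gen),
      _["mean_n"] = wrap(r_mean_n),
      _["mean_cluster"] = wrap(r_mean_cl),
      _["mean_ref"] = wrap(r_mean_ref),
      _["frac_cluster"] = wrap(r_frac),
      _["fixed_cluster"] = wrap(r_fixed),
      _["seg_cluster"] = wrap(r_segc),
      _["seg_genomic"] = wrap(r_segg),
      _["seg_ref"] = wrap(r_segr),
      _["mean_w"] = wrap(r_meanw),
      _["novel_per_ind"] = wrap(r_novel));

  List out = List::create(_["records"] = rec, _["status"] = status);
  if (return_population) out["population"] = pop_to_list(pop);
  return out;
}

// [[Rcpp::export]]
List cpp_step_generation(List arch, List pop0, double u, double v, double x,
                         double t, int model) {
  Arch A = arch_from_list(arch);
  std::vector<Hap> pop = pop_from_list(pop0);
  std::vector<Hap> scratch;
  int N = (int)pop.size() / 2;
  std::vector<double> w;
  std::vector<int> ncl;
  GenStats S;
  compute_stats(pop, A, x, t, model, false, S, w, ncl);
  double tw = 0;
  for (int i = 0; i < N; i++) tw += w[i];
  if (tw <= 0) stop("all individuals have zero fitness (population extinct)");
  std::vector<double> cumw(N);
  double acc = 0;
  for (int i = 0; i < N; i++) { acc += w[i]; cumw[i] = acc; }
  int novel = do_step(pop, scratch, A, u, v, cumw, ncl);
  return List::create(_["population"] = pop_to_list(pop),
                      _["novel_insertions"] = novel);
}

// [[Rcpp::export]]
IntegerVector cpp_make_gamete(List arch, IntegerVector hap1,
                              IntegerVector hap2) {
  Arch A = arch_from_list(arch);
  Hap h0(hap1.begin(), hap1.end()), h1(hap2.begin(), hap2.end());
  std::sort(h0.begin(), h0.end());
  std::sort(h1.begin(), h1.end());
  Hap out;
  make_gamete(h0, h1, A, out);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_apply_excision(List arch, IntegerVector gamete,
                                 bool parent_active, double v) {
  Arch A = arch_from_list(arch);
  Hap g(gamete.begin(), gamete.end());
  std::sort(g.begin(), g.end());
  if (parent_active) excise(g, A, v);
  return IntegerVector(g.begin(), g.end());
}

// [[Rcpp::export]]
List cpp_apply_transposition(List arch, IntegerVector gamete,
                             bool parent_active, double u) {
  Arch A = arch_from_list(arch);
  Hap g(gamete.begin(), gamete.end());
  std::sort(g.begin(), g.end());
  int added = parent_active ? transpose(g, A, u) : 0;
  return List::create(_["gamete"] = IntegerVector(g.begin(), g.end()),
                      _["n_new"] = added);
}

// [[Rcpp::export]]
IntegerVector cpp_classify_sites(List arch, NumericVector sites) {
  Arch A = arch_from_list(arch);
  int n = sites.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    double s = sites[i];
    if (s < 0 || s >= A.total) stop("site index out of range");
    out[i] = site_class(A, (int)s);
  }
  return out;
}
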