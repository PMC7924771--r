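// Core engine: sequential coalescent-with-recombination simulation along the
// genome, waypointed particle filter (plain and lookahead variants), event
// records with fixed-lag harvesting of sufficient statistics, and the data
// simulator.  Genealogies are stored as fixed-size index arrays (2n-1 nodes);
// all stochastic draws go through R's RNG so a single set.seed() call makes a
// run bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// continued-fraction exp for small |x|; relative error < 1e-10 for |x| < 0.03
static inline double fexp(double x) {
  if (std::fabs(x) < 0.03) return 1.0 + 2.0 * x / (2.0 - x + x * x / 6.0);
  return std::exp(x);
}

// ---------------------------------------------------------------------------
// Demography: piecewise epochs with coalescence rate C(u) = 1/(2 Ne(u)),
// optionally exponentially growing within an epoch (simulation only).
// Epochs are half-open [bnd[e], bnd[e+1]); the last extends to +Inf.
// ---------------------------------------------------------------------------

struct Demography {
  std::vector<double> bnd, crate, growth;
  double rho, mu;
  int E;

  void init(const List& m) {
    NumericVector b = m["epoch_start"], c = m["coal_rate"], g = m["growth"];
    E = b.size();
    bnd.assign(b.begin(), b.end());
    crate.assign(c.begin(), c.end());
    growth.assign(g.begin(), g.end());
    rho = as<double>(m["rho"]);
    mu = as<double>(m["mu"]);
    if (E < 1 || E > 64) stop("between 1 and 64 epochs are supported");
    if (growth[E - 1] != 0.0) stop("final epoch must have zero growth rate");
  }

  int epoch_of(double u) const {
    int e = (int)(std::upper_bound(bnd.begin(), bnd.end(), u) - bnd.begin()) - 1;
    return e < 0 ? 0 : e;
  }
  double epoch_end(int e) const { return e + 1 < E ? bnd[e + 1] : R_PosInf; }
  double C(double u) const {
    int e = epoch_of(u);
    double c = crate[e];
    if (growth[e] != 0.0) c *= std::exp(growth[e] * (u - bnd[e]));
    return c;
  }
  // integral of C over [u1,u2], both inside epoch e
  double C_int(int e, double u1, double u2) const {
    double g = growth[e];
    if (g == 0.0) return crate[e] * (u2 - u1);
    return crate[e] / g * (std::exp(g * (u2 - bnd[e])) - std::exp(g * (u1 - bnd[e])));
  }
  // u >= u1 in epoch e with C_int(e,u1,u) == H (caller guarantees solvable)
  double C_inv(int e, double u1, double H) const {
    double g = growth[e];
    if (g == 0.0) return u1 + H / crate[e];
    double a = std::exp(g * (u1 - bnd[e])) + H * g / crate[e];
    return bnd[e] + std::log(a) / g;
  }
};

static Demography demography_from(const List& m) {
  Demography d;
  d.init(m);
  return d;
}

// ---------------------------------------------------------------------------
// Genealogy: rooted binary tree over n tips (ages 0), nodes 0..2n-2,
// internal nodes carry coalescence ages.  Root's branch extends to +Inf and
// attracts no recombination; b_u = 1 above the root.
// ---------------------------------------------------------------------------

struct Tree {
  int n, root;
  std::vector<int> parent, ch1, ch2;
  std::vector<double> tm;

  int nn() const { return 2 * n - 1; }

  double B() const {
    double s = 0;
    for (int v = 0; v < nn(); v++)
      if (v != root) s += tm[parent[v]] - tm[v];
    return s;
  }

  // descendant tip bitmask per node
  void desc_masks(std::vector<uint64_t>& d) const {
    d.assign(nn(), 0);
    // tips first, then internal nodes in increasing age order (children precede parents)
    std::vector<int> ord(nn());
    for (int v = 0; v < nn(); v++) ord[v] = v;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return tm[a] < tm[b]; });
    for (int v : ord) {
      if (v < n) d[v] = (uint64_t)1 << v;
      else d[v] = d[ch1[v]] | d[ch2[v]];
    }
  }

  // integral of b_u over each epoch (finite part, up to the root)
  void b_epoch_integral(const Demography& dem, std::vector<double>& out) const {
    out.assign(dem.E, 0.0);
    for (int v = 0; v < nn(); v++) {
      if (v == root) continue;
      double a = tm[v], b = tm[parent[v]];
      int e = dem.epoch_of(a);
      while (a < b) {
        double ee = std::min(dem.epoch_end(e), b);
        out[e] += ee - a;
        a = ee;
        e++;
      }
    }
  }
};

static void sample_stationary(Tree& t, int n, const Demography& dem) {
  t.n = n;
  t.parent.assign(t.nn(), -1);
  t.ch1.assign(t.nn(), -1);
  t.ch2.assign(t.nn(), -1);
  t.tm.assign(t.nn(), 0.0);
  std::vector<int> act(n);
  for (int i = 0; i < n; i++) act[i] = i;
  int k = n, nxt = n;
  double u = 0.0;
  while (k > 1) {
    double mult = k * (k - 1) / 2.0;
    double H = R::exp_rand();
    int e = dem.epoch_of(u);
    double cur = u;
    for (;;) {
      double end = dem.epoch_end(e);
      if (!std::isfinite(end)) { u = dem.C_inv(e, cur, H / mult); break; }
      double seg = mult * dem.C_int(e, cur, end);
      if (H < seg) { u = dem.C_inv(e, cur, H / mult); break; }
      H -= seg;
      cur = end;
      e++;
    }
    int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) j++;
    int a = act[i], b = act[j], p = nxt++;
    t.tm[p] = u;
    t.ch1[p] = a; t.ch2[p] = b;
    t.parent[a] = p; t.parent[b] = p;
    // keep act compact
    if (i > j) std::swap(i, j);
    act[i] = p;
    act[j] = act[k - 1];
    k--;
  }
  t.root = t.nn() - 1;
  t.parent[t.root] = -1;
}

// Sample the re-coalescence time tau for a lineage detached at height nu, at
// instantaneous rate b_u(tree) * C(u) where b_u counts the original tree's
// contemporary branches (1 above the root).  Accumulates the per-epoch
// coalescence opportunity  int_nu^tau b_u du  into coal_opp, and reports the
// number of contemporary branches at tau (for the uniform branch choice).
static double sample_recoal(const Tree& t, double nu, const Demography& dem,
                            std::vector<double>& coal_opp, int& k_at_tau) {
  std::vector<double> it;
  it.reserve(t.n - 1);
  for (int v = t.n; v < t.nn(); v++) it.push_back(t.tm[v]);
  std::sort(it.begin(), it.end());
  coal_opp.assign(dem.E, 0.0);
  double H = R::exp_rand();
  double cur = nu;
  int e = dem.epoch_of(nu);
  int m = (int)(std::upper_bound(it.begin(), it.end(), cur) - it.begin());
  for (;;) {
    int k = t.n - m; if (k < 1) k = 1;
    double nt = (m < (int)it.size()) ? it[m] : R_PosInf;
    double ee = dem.epoch_end(e);
    double end = std::min(nt, ee);
    double seg = std::isfinite(end) ? k * dem.C_int(e, cur, end) : R_PosInf;
    if (H < seg) {
      double tau = dem.C_inv(e, cur, H / k);
      coal_opp[e] += k * (tau - cur);
      k_at_tau = k;
      return tau;
    }
    coal_opp[e] += k * (end - cur);
    H -= seg;
    if (nt <= ee) { m++; if (nt == ee) e++; }
    else e++;
    cur = end;
  }
}

// choose uniformly among the branches of t spanning height tau (k of them);
// returns the node whose parent branch spans tau, or root if tau is above it
static int choose_branch_at(const Tree& t, double tau, int k) {
  (void)k;
  if (tau >= t.tm[t.root]) return t.root;
  int cand[128], nc = 0;
  for (int v = 0; v < t.nn(); v++) {
    if (v == t.root) continue;
    if (t.tm[v] <= tau && tau < t.tm[t.parent[v]]) cand[nc++] = v;
  }
  if (nc == 0) return t.root; // tau numerically at the root's age
  int pick = (int)(R::unif_rand() * nc); if (pick >= nc) pick = nc - 1;
  return cand[pick];
}

// SMC'-type tree surgery: lineage above (b, nu) detaches and re-attaches on
// branch 'target' at height tau.  target == b means a silent event (no-op).
// Returns the index of the removed/recreated internal node (or -1 if silent).
static int apply_surgery(Tree& t, int b, double nu, int target, double tau) {
  if (target == b) return -1;
  int p = t.parent[b];
  int sib = (t.ch1[p] == b) ? t.ch2[p] : t.ch1[p];
  int gp = t.parent[p];
  // remove p
  if (gp == -1) {
    t.parent[sib] = -1;
    t.root = sib;
  } else {
    if (t.ch1[gp] == p) t.ch1[gp] = sib; else t.ch2[gp] = sib;
    t.parent[sib] = gp;
  }
  // resolve the landing lineage after removal
  int tgt = target;
  if (tgt == p) tgt = sib;                      // landed on p's old branch segment
  if (tau >= t.tm[t.root]) tgt = t.root;        // above the (possibly new) root
  int q = t.parent[tgt];
  // re-insert p as the new coalescence node at tau
  t.tm[p] = tau;
  t.ch1[p] = b; t.ch2[p] = tgt;
  t.parent[b] = p; t.parent[tgt] = p;
  t.parent[p] = q;
  if (q == -1) t.root = p;
  else { if (t.ch1[q] == tgt) t.ch1[q] = p; else t.ch2[q] = p; }
  return p;
}

// uniform point on the tree under branch-length measure: (branch node, height)
static void sample_point(const Tree& t, double B, int& branch, double& nu) {
  double u = R::unif_rand() * B, acc = 0;
  for (int v = 0; v < t.nn(); v++) {
    if (v == t.root) continue;
    double len = t.tm[t.parent[v]] - t.tm[v];
    if (u < acc + len) { branch = v; nu = t.tm[v] + (u - acc); return; }
    acc += len;
  }
  // numerical edge: return the last branch
  for (int v = t.nn() - 1; v >= 0; v--)
    if (v != t.root) { branch = v; nu = t.tm[v] + 0.5 * (t.tm[t.parent[v]] - t.tm[v]); return; }
}

// ---------------------------------------------------------------------------
// Emission: infinite-sites pattern likelihoods.  P(A | g, mu) = mu * (total
// length of branches whose observed descendant set equals A's carrier set).
// ---------------------------------------------------------------------------

static double match_len_phased(const Tree& t, const std::vector<uint64_t>& desc,
                               uint64_t carriers, uint64_t missing) {
  uint64_t obs = (((uint64_t)1 << t.n) - 1) & ~missing;
  double s = 0;
  for (int v = 0; v < t.nn(); v++) {
    if (v == t.root) continue;
    if ((desc[v] & obs) == (carriers & obs)) s += t.tm[t.parent[v]] - t.tm[v];
  }
  return s;
}

// genotypes: per-individual 0/1/2 alt-allele dosage, -1 = missing
static double match_len_unphased(const Tree& t, const std::vector<uint64_t>& desc,
                                 const int* geno, int nind) {
  double s = 0;
  for (int v = 0; v < t.nn(); v++) {
    if (v == t.root) continue;
    bool ok = true;
    for (int j = 0; j < nind; j++) {
      if (geno[j] < 0) continue;
      int d = (int)((desc[v] >> (2 * j)) & 1) + (int)((desc[v] >> (2 * j + 1)) & 1);
      if (d != geno[j]) { ok = false; break; }
    }
    if (ok) s += t.tm[t.parent[v]] - t.tm[v];
  }
  return s;
}

// ---------------------------------------------------------------------------
// Masks: disjoint half-open observed intervals with prefix sums.
// ---------------------------------------------------------------------------

struct Mask {
  std::vector<double> st, en, cum; // cum[i] = observed length before st[i]
  double L;
  bool full;

  void init(NumericVector s, NumericVector e, double L_) {
    L = L_;
    full = (s.size() == 0);
    st.assign(s.begin(), s.end());
    en.assign(e.begin(), e.end());
    cum.assign(st.size(), 0.0);
    for (size_t i = 1; i < st.size(); i++) cum[i] = cum[i - 1] + (en[i - 1] - st[i - 1]);
  }
  // observed length before position x
  double before(double x) const {
    if (full) return x;
    int i = (int)(std::upper_bound(st.begin(), st.end(), x) - st.begin()) - 1;
    if (i < 0) return 0.0;
    return cum[i] + std::min(x, en[i]) - st[i];
  }
  double obslen(double a, double b) const {
    if (full) return b - a;
    return before(b) - before(a);
  }
};

// ---------------------------------------------------------------------------
// Event records: one recombination (+ its re-coalescence) per record, with
// per-epoch opportunity contributions, linked backwards into shared chains.
// ---------------------------------------------------------------------------

struct Record {
  double locus, span_len, nu, tau;
  int epoch_nu, epoch_tau;
  int prev, refcount;
  uint64_t harvested;
  bool changed_tree;
  int stamp;
  double pend;
  std::vector<double> span_opp; // per-epoch int b_u du of the pre-event tree (per bp)
  std::vector<double> coal_opp; // per-epoch int_nu^tau b_u du
};

struct RecordArena {
  std::vector<Record> rec;
  std::vector<int> freelist;
  int E;
  uint64_t allmask;
  long peak_live = 0, live = 0;

  void init(int E_) {
    E = E_;
    allmask = (E >= 64) ? ~(uint64_t)0 : (((uint64_t)1 << E) - 1);
    rec.clear(); freelist.clear(); live = 0; peak_live = 0;
  }
  int alloc() {
    int i;
    if (!freelist.empty()) { i = freelist.back(); freelist.pop_back(); }
    else { i = (int)rec.size(); rec.push_back(Record()); }
    Record& r = rec[i];
    r.prev = -1; r.refcount = 0; r.harvested = 0; r.stamp = -1; r.pend = 0;
    live++; if (live > peak_live) peak_live = live;
    return i;
  }
  void decref(int i) {
    while (i != -1 && --rec[i].refcount == 0) {
      int p = rec[i].prev;
      rec[i].span_opp.clear(); rec[i].span_opp.shrink_to_fit();
      rec[i].coal_opp.clear(); rec[i].coal_opp.shrink_to_fit();
      freelist.push_back(i);
      live--;
      i = p;
    }
  }
  bool full_harvested(int i) const { return rec[i].harvested == allmask; }
};

// ---------------------------------------------------------------------------
// Observation digest for the lookahead likelihood: per-lineage next-singleton
// loci and greedily fixed cherries with their supporting doubleton loci.
// ---------------------------------------------------------------------------

struct Cherry {
  int a, b;                       // haplotype labels
  std::vector<double> support;    // supporting doubleton loci, increasing
};

struct Digest {
  int n;
  std::vector<std::vector<double>> singles; // per lineage unit (hap or individual)
  std::vector<Cherry> cherries;

  // phased digest: units are haplotypes
  void build_phased(int n_, const std::vector<double>& loci,
                    const std::vector<uint64_t>& carriers,
                    const std::vector<uint64_t>& missing) {
    n = n_;
    singles.assign(n, {});
    cherries.clear();
    std::vector<int> used(n, 0);
    int maxch = n / 2;
    for (size_t j = 0; j < loci.size(); j++) {
      uint64_t c = carriers[j];
      int pc = 0, bits[64], nb = 0;
      for (int i = 0; i < n; i++)
        if ((c >> i) & 1) { pc++; if (nb < 64) bits[nb++] = i; }
      (void)missing;
      if (pc == 1) singles[bits[0]].push_back(loci[j]);
      else if (pc == 2) {
        int a = bits[0], b = bits[1];
        bool found = false;
        for (auto& ck : cherries)
          if ((ck.a == a && ck.b == b)) { ck.support.push_back(loci[j]); found = true; break; }
        if (!found) {
          // incompatible with a fixed cherry (shares exactly one leaf) -> discard
          bool clash = used[a] || used[b];
          if (!clash && (int)cherries.size() < maxch) {
            Cherry ck; ck.a = a; ck.b = b; ck.support.push_back(loci[j]);
            cherries.push_back(ck);
            used[a] = used[b] = 1;
          }
        }
      }
    }
  }

  // unphased digest: units are individuals; singleton = lone het individual,
  // cherries from lone hom-alt individuals (the individual's own pair) or
  // greedily assigned pairs for two-het doubletons
  void build_unphased(int n_, const std::vector<double>& loci, const IntegerMatrix& geno) {
    n = n_;
    int nind = n / 2;
    singles.assign(nind, {});
    cherries.clear();
    std::vector<int> used(n, 0);
    int maxch = n / 2;
    for (int j = 0; j < geno.ncol(); j++) {
      int het = -1, het2 = -1, hom = -1, nhet = 0, nhom = 0;
      for (int i = 0; i < nind; i++) {
        int g = geno(i, j);
        if (g == 1) { nhet++; if (het < 0) het = i; else het2 = i; }
        else if (g == 2) { nhom++; hom = i; }
      }
      if (nhet == 1 && nhom == 0) singles[het].push_back(loci[j]);
      else if (nhom == 1 && nhet == 0) {
        int a = 2 * hom, b = 2 * hom + 1;
        bool found = false;
        for (auto& ck : cherries)
          if (ck.a == a && ck.b == b) { ck.support.push_back(loci[j]); found = true; break; }
        if (!found && !used[a] && !used[b] && (int)cherries.size() < maxch) {
          Cherry ck; ck.a = a; ck.b = b; ck.support.push_back(loci[j]);
          cherries.push_back(ck); used[a] = used[b] = 1;
        }
      } else if (nhet == 2 && nhom == 0) {
        // support any fixed cherry pairing one hap of each individual
        bool found = false;
        for (auto& ck : cherries)
          if ((ck.a / 2 == het && ck.b / 2 == het2) || (ck.a / 2 == het2 && ck.b / 2 == het)) {
            ck.support.push_back(loci[j]); found = true; break;
          }
        if (!found) {
          int a = -1, b = -1;
          for (int h = 2 * het; h < 2 * het + 2 && a < 0; h++) if (!used[h]) a = h;
          for (int h = 2 * het2; h < 2 * het2 + 2 && b < 0; h++) if (!used[h]) b = h;
          if (a >= 0 && b >= 0 && (int)cherries.size() < maxch) {
            Cherry ck; ck.a = a; ck.b = b; ck.support.push_back(loci[j]);
            cherries.push_back(ck); used[a] = used[b] = 1;
          }
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Lookahead likelihood terms (shared by the engine and the R-level debug
// entry points).  All rates are per bp; distances in bp.
// ---------------------------------------------------------------------------

// p(first singleton on lineage i at distance s | l, l'), or the censored
// variant p(no singleton up to s).  rho_i, mu_i, mu_i' are total rates.
static double singleton_term(double rho_i, double mu_i, double mu_ip,
                             double s, bool censored) {
  double d = rho_i + mu_i - mu_ip;
  double E2 = fexp(-(rho_i + mu_i) * s);
  double scale = rho_i + mu_i + mu_ip;
  if (std::fabs(d) < 1e-9 * (scale > 0 ? scale : 1.0)) {
    // removable singularity at rho_i + mu_i == mu_i'
    if (censored) return E2 * (1.0 + rho_i * s);
    return E2 * (mu_i + rho_i * (rho_i + mu_i) * s);
  }
  double E1 = fexp(-mu_ip * s);
  if (censored) return (rho_i * E1 + (mu_i - mu_ip) * E2) / d;
  return (rho_i * mu_ip * E1 + (mu_i - mu_ip) * (rho_i + mu_i) * E2) / d;
}

static double cherry_present_term(double s2, double rhoC, int n) {
  double q = 2.0 / (3.0 * (n - 1));
  double e = fexp(-rhoC * s2);
  return e + q * (1.0 - e);
}

static double cherry_absent_term(double s1, double rhoCp, int n) {
  double q = 2.0 / (3.0 * (n - 1));
  return q * (1.0 - fexp(-rhoCp * s1));
}

// [[Rcpp::export]]
double cpp_singleton_term(double rho_i, double mu_i, double mu_ip, double s, bool censored) {
  return singleton_term(rho_i, mu_i, mu_ip, s, censored);
}

// ---------------------------------------------------------------------------
// Exported primitives (R-facing reference operations use these)
// ---------------------------------------------------------------------------

static Tree tree_from(const List& tl) {
  Tree t;
  IntegerVector p = tl["parent"];
  NumericVector tm = tl["time"];
  t.n = (p.size() + 1) / 2;
  t.parent.assign(p.begin(), p.end());
  t.tm.assign(tm.begin(), tm.end());
  t.ch1.assign(t.nn(), -1);
  t.ch2.assign(t.nn(), -1);
  t.root = -1;
  for (int v = 0; v < t.nn(); v++) {
    if (t.parent[v] < 0) { t.root = v; continue; }
    int q = t.parent[v];
    if (t.ch1[q] == -1) t.ch1[q] = v; else t.ch2[q] = v;
  }
  return t;
}

static List tree_to(const Tree& t) {
  IntegerVector p(t.nn());
  NumericVector tm(t.nn());
  for (int v = 0; v < t.nn(); v++) { p[v] = t.parent[v]; tm[v] = t.tm[v]; }
  return List::create(_["parent"] = p, _["time"] = tm);
}

// [[Rcpp::export]]
List cpp_sample_tree(int n, List model) {
  Demography dem = demography_from(model);
  Tree t;
  sample_stationary(t, n, dem);
  return tree_to(t);
}

// [[Rcpp::export]]
NumericVector cpp_b_epoch_integral(List tree, List model) {
  Demography dem = demography_from(model);
  Tree t = tree_from(tree);
  std::vector<double> out;
  t.b_epoch_integral(dem, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_apply_recomb(List tree, int branch, double nu, List model) {
  Demography dem = demography_from(model);
  Tree t = tree_from(tree);
  std::vector<double> coal_opp;
  int k_at_tau;
  double tau = sample_recoal(t, nu, dem, coal_opp, k_at_tau);
  int target = choose_branch_at(t, tau, k_at_tau);
  bool changed = (target != branch);
  if (changed) apply_surgery(t, branch, nu, target, tau);
  return List::create(_["tree"] = tree_to(t), _["branch"] = branch + 1,
                      _["nu"] = nu, _["tau"] = tau, _["target"] = target + 1,
                      _["changed_tree"] = changed,
                      _["epoch_nu"] = dem.epoch_of(nu) + 1,
                      _["epoch_tau"] = dem.epoch_of(tau) + 1,
                      _["coal_opp"] = NumericVector(coal_opp.begin(), coal_opp.end()));
}

// deterministic replay of a recorded recombination/re-coalescence
// [[Rcpp::export]]
List cpp_surgery(List tree, int branch, double nu, int target, double tau) {
  Tree t = tree_from(tree);
  if (target != branch) apply_surgery(t, branch, nu, target, tau);
  return tree_to(t);
}

// [[Rcpp::export]]
double cpp_match_len(List tree, double carriers, double missing) {
  Tree t = tree_from(tree);
  std::vector<uint64_t> d;
  t.desc_masks(d);
  return match_len_phased(t, d, (uint64_t)carriers, (uint64_t)missing);
}

// [[Rcpp::export]]
double cpp_match_len_unphased(List tree, IntegerVector geno) {
  Tree t = tree_from(tree);
  std::vector<uint64_t> d;
  t.desc_masks(d);
  std::vector<int> g(geno.begin(), geno.end());
  return match_len_unphased(t, d, g.data(), (int)g.size());
}

// [[Rcpp::export]]
double cpp_coal_hazard(List tree, double nu, double tau, List model) {
  // int_nu^tau b_u(tree) C(u) du, with b_u = 1 above the root
  Demography dem = demography_from(model);
  Tree t = tree_from(tree);
  std::vector<double> it;
  for (int v = t.n; v < t.nn(); v++) it.push_back(t.tm[v]);
  std::sort(it.begin(), it.end());
  double H = 0, cur = nu;
  int e = dem.epoch_of(nu);
  int m = (int)(std::upper_bound(it.begin(), it.end(), cur) - it.begin());
  while (cur < tau) {
    int k = t.n - m; if (k < 1) k = 1;
    double nt = (m < (int)it.size()) ? it[m] : R_PosInf;
    double end = std::min(std::min(nt, dem.epoch_end(e)), tau);
    H += k * dem.C_int(e, cur, end);
    if (end == tau) break;
    if (nt <= dem.epoch_end(e)) { m++; if (nt == dem.epoch_end(e)) e++; }
    else e++;
    cur = end;
  }
  return H;
}

// ---------------------------------------------------------------------------
// The particle filter engine
// ---------------------------------------------------------------------------

struct Particle {
  Tree t;
  double logw, logv, logh;
  int newest;              // record chain head
  double span_start;       // locus where the current tree began
  double Bcur;
  std::vector<double> span_opp; // per-epoch per-bp recombination opportunity of current tree
};

struct Engine {
  Demography dem;
  Mask mask;
  int n, N, E, nind;
  double L;
  bool lookahead, unphased, vb_mode, track_life;
  double ess_frac;
  int atoms, atom_refresh, harvest_stride;
  double log_eta_rho;
  std::vector<double> log_eta_coal;
  std::vector<double> lags;

  // observations
  std::vector<double> site_loci;
  std::vector<uint64_t> site_carriers, site_missing;
  IntegerMatrix geno;

  std::vector<double> waypoints;
  std::vector<Particle> part;
  RecordArena arena;

  // digest state
  Digest digest;
  std::vector<size_t> single_ptr; // per unit: index of next future singleton
  std::vector<size_t> cherry_ptr; // per cherry: index of next future support

  // lookahead atoms: per unit, atom TBL values
  std::vector<std::vector<double>> atom_l;

  // harvested sufficient statistics (weight-normalized expectations)
  std::vector<double> r_cnt, r_opp, c_cnt, c_opp;
  // node lifetime stats per epoch (for correlation distances)
  std::vector<double> life_sum;
  std::vector<long> life_cnt;
  std::vector<double> node_birth_buf; // per particle x node, creation locus
  int nn;

  // diagnostics
  std::vector<double> ess_w_tr, ess_v_tr, cumll_tr;
  std::vector<int> resampled_tr;
  double logw_off;

  std::vector<int> harvest_visited;
  int harvest_stamp = 0;

  double node_birth(int i, int v) const { return node_birth_buf[(size_t)i * nn + v]; }
  void set_node_birth(int i, int v, double x) { node_birth_buf[(size_t)i * nn + v] = x; }

  void init(const List& obs, const List& model, const List& config) {
    dem = demography_from(model);
    E = dem.E;
    n = as<int>(obs["n"]);
    nind = n / 2;
    L = as<double>(obs["L"]);
    NumericVector loci = obs["loci"];
    site_loci.assign(loci.begin(), loci.end());
    unphased = as<bool>(config["unphased"]);
    if (!unphased) {
      NumericVector ca = obs["carriers"], mi = obs["missing"];
      site_carriers.resize(ca.size());
      site_missing.resize(mi.size());
      for (int j = 0; j < ca.size(); j++) {
        site_carriers[j] = (uint64_t)ca[j];
        site_missing[j] = (uint64_t)mi[j];
      }
    } else {
      geno = as<IntegerMatrix>(obs["genotypes"]); // nind x m
    }
    NumericVector ms = obs["mask_start"], me = obs["mask_end"];
    mask.init(ms, me, L);

    N = as<int>(config["N"]);
    lookahead = as<bool>(config["lookahead"]);
    ess_frac = as<double>(config["ess_frac"]);
    atoms = as<int>(config["atoms"]);
    atom_refresh = as<int>(config["atom_refresh"]);
    harvest_stride = as<int>(config["harvest_stride"]);
    vb_mode = as<bool>(config["vb_mode"]);
    log_eta_rho = std::log(as<double>(config["eta_rho"]));
    NumericVector ec = config["eta_coal"];
    log_eta_coal.resize(E);
    for (int e = 0; e < E; e++) log_eta_coal[e] = std::log(ec[e]);
    NumericVector lg = config["lags"];
    lags.assign(lg.begin(), lg.end());
    NumericVector wp = config["waypoints"];
    waypoints.assign(wp.begin(), wp.end());
    track_life = as<bool>(config["track_life"]);

    arena.init(E);
    r_cnt.assign(E, 0); r_opp.assign(E, 0); c_cnt.assign(E, 0); c_opp.assign(E, 0);
    life_sum.assign(E, 0); life_cnt.assign(E, 0);
    logw_off = 0;

    // digest
    if (lookahead) {
      if (!unphased) digest.build_phased(n, site_loci, site_carriers, site_missing);
      else digest.build_unphased(n, site_loci, geno);
      single_ptr.assign(digest.singles.size(), 0);
      cherry_ptr.assign(digest.cherries.size(), 0);
      atom_l.assign(digest.singles.size(), {});
    }

    // particles
    part.resize(N);
    nn = 2 * n - 1;
    if (track_life) node_birth_buf.assign((size_t)N * nn, 0.0);
    for (int i = 0; i < N; i++) {
      Particle& p = part[i];
      sample_stationary(p.t, n, dem);
      p.logw = -std::log((double)N);
      p.logv = p.logw;
      p.logh = 0;
      p.newest = -1;
      p.span_start = 0;
      p.Bcur = p.t.B();
      p.t.b_epoch_integral(dem, p.span_opp);
    }
  }

  // --- weights -------------------------------------------------------------

  double lse_logw(bool use_v) const {
    double mx = R_NegInf;
    for (auto& p : part) mx = std::max(mx, use_v ? p.logv : p.logw);
    if (!std::isfinite(mx)) return R_NegInf;
    double s = 0;
    for (auto& p : part) s += std::exp((use_v ? p.logv : p.logw) - mx);
    return mx + std::log(s);
  }

  double ess_of(bool use_v) const {
    double mx = R_NegInf;
    for (auto& p : part) mx = std::max(mx, use_v ? p.logv : p.logw);
    if (!std::isfinite(mx)) return 0;
    double s1 = 0, s2 = 0;
    for (auto& p : part) {
      double w = std::exp((use_v ? p.logv : p.logw) - mx);
      s1 += w; s2 += w * w;
    }
    return s1 * s1 / s2;
  }

  void norm_weights(std::vector<double>& wn) const {
    wn.resize(N);
    double l = lse_logw(false);
    for (int i = 0; i < N; i++) wn[i] = std::exp(part[i].logw - l);
  }

  void renormalize() {
    // keep log-weights in a numerically safe band
    double mx = R_NegInf;
    for (auto& p : part) mx = std::max(mx, p.logw);
    if (std::isfinite(mx) && std::fabs(mx) > 200) {
      logw_off += mx;
      for (auto& p : part) p.logw -= mx;
    }
    double mv = R_NegInf;
    for (auto& p : part) mv = std::max(mv, p.logv);
    if (std::isfinite(mv) && std::fabs(mv) > 200)
      for (auto& p : part) p.logv -= mv;
  }

  // --- resampling ----------------------------------------------------------

  void systematic_counts(const std::vector<double>& wn, double u0, std::vector<int>& cnt) const {
    cnt.assign(N, 0);
    double cum = 0;
    int k = 0;
    for (int i = 0; i < N; i++) {
      cum += wn[i];
      while (k < N && (k + u0) / N < cum) { cnt[i]++; k++; }
    }
    while (k < N) { cnt[N - 1]++; k++; } // guard against fp shortfall
  }

  void resample() {
    std::vector<double> vn(N);
    double lv = lse_logw(lookahead);
    for (int i = 0; i < N; i++)
      vn[i] = std::exp((lookahead ? part[i].logv : part[i].logw) - lv);
    std::vector<int> cnt;
    systematic_counts(vn, R::unif_rand(), cnt);

    double lw_mean = lse_logw(false) - std::log((double)N); // log(mean w)
    std::vector<Particle> np;
    np.reserve(N);
    std::vector<double> nb;
    if (track_life) nb.resize((size_t)N * nn);
    int outi = 0;
    for (int i = 0; i < N; i++) {
      if (cnt[i] == 0) {
        if (part[i].newest != -1) arena.decref(part[i].newest);
        continue;
      }
      if (part[i].newest != -1) arena.rec[part[i].newest].refcount += cnt[i] - 1;
      for (int k = 0; k < cnt[i]; k++) {
        np.push_back(part[i]);
        Particle& q = np.back();
        if (lookahead) {
          // w <- N^-1 w_i / vtilde_i ; v <- N^-1
          q.logw = -std::log((double)N) + part[i].logw - std::log(vn[i]);
          q.logv = -std::log((double)N);
        } else {
          q.logw = lw_mean;
        }
        if (track_life)
          std::copy(node_birth_buf.begin() + (size_t)i * nn,
                    node_birth_buf.begin() + (size_t)(i + 1) * nn,
                    nb.begin() + (size_t)outi * nn);
        outi++;
      }
    }
    part.swap(np);
    if (track_life) node_birth_buf.swap(nb);
  }

  // --- advancing -----------------------------------------------------------

  void tree_changed(Particle& p, double locus) {
    p.Bcur = p.t.B();
    p.t.b_epoch_integral(dem, p.span_opp);
    p.span_start = locus;
  }

  // advance one particle from a to b (no observation sites strictly inside)
  void advance(Particle& p, int pi, double a, double b) {
    double pos = a;
    for (;;) {
      double rate = dem.rho * p.Bcur;
      double d = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
      if (pos + d >= b) {
        p.logw -= dem.mu * p.Bcur * mask.obslen(pos, b);
        break;
      }
      double locus = pos + d;
      p.logw -= dem.mu * p.Bcur * mask.obslen(pos, locus);
      // recombination event
      int branch; double nu;
      sample_point(p.t, p.Bcur, branch, nu);
      int ri = arena.alloc();
      Record& r = arena.rec[ri];
      int k_at_tau;
      double tau = sample_recoal(p.t, nu, dem, r.coal_opp, k_at_tau);
      int target = choose_branch_at(p.t, tau, k_at_tau);
      r.locus = locus;
      r.span_len = locus - p.span_start;
      r.nu = nu; r.tau = tau;
      r.epoch_nu = dem.epoch_of(nu);
      r.epoch_tau = dem.epoch_of(tau);
      r.span_opp = p.span_opp;
      r.changed_tree = (target != branch);
      r.prev = p.newest;
      r.refcount = 1; // pointed to by the particle; prev keeps its refcount
      p.newest = ri;
      if (r.changed_tree) {
        apply_surgery(p.t, branch, nu, target, tau);
        tree_changed(p, locus);
      } else {
        p.span_start = locus; // same tree, new span for opportunity bookkeeping
      }
      if (vb_mode) p.logw += log_eta_rho + log_eta_coal[r.epoch_tau];
      pos = locus;
      (void)pi;
    }
  }

  // emission log-factor for site j on particle p's current tree
  double site_logfactor(const Particle& p, int j) {
    std::vector<uint64_t> d;
    p.t.desc_masks(d);
    double len;
    if (!unphased) len = match_len_phased(p.t, d, site_carriers[j], site_missing[j]);
    else {
      std::vector<int> g(nind);
      for (int i = 0; i < nind; i++) g[i] = geno(i, j);
      len = match_len_unphased(p.t, d, g.data(), nind);
    }
    return (len > 0) ? std::log(dem.mu * len) : R_NegInf;
  }

  int dead_sites = 0;

  // Apply a site's emission factors across the ensemble.  If the pattern is
  // topologically impossible for every live particle the whole ensemble
  // would die; the site's factor is then skipped (the site is treated as
  // unobserved) and the event counted, rather than aborting the run.
  void apply_site(int j) {
    std::vector<double> sf(N);
    bool alive = false;
    for (int i = 0; i < N; i++) {
      sf[i] = site_logfactor(part[i], j);
      if (std::isfinite(sf[i] + part[i].logw)) alive = true;
    }
    if (!alive) { dead_sites++; return; }
    for (int i = 0; i < N; i++) part[i].logw += sf[i];
  }

  // --- lookahead -----------------------------------------------------------

  void refresh_atoms() {
    // per-unit quantile atoms of the ensemble TBL (or TBL-sum) distribution,
    // weighted by the resampling weights v
    int U = (int)digest.singles.size();
    double lv = lse_logw(lookahead);
    std::vector<std::pair<double, double>> lw(N);
    for (int u = 0; u < U; u++) {
      for (int i = 0; i < N; i++) {
        double l;
        if (!unphased) l = part[i].t.tm[part[i].t.parent[u]];
        else l = part[i].t.tm[part[i].t.parent[2 * u]] + part[i].t.tm[part[i].t.parent[2 * u + 1]];
        double w = std::exp((lookahead ? part[i].logv : part[i].logw) - lv);
        lw[i] = { l, w };
      }
      std::sort(lw.begin(), lw.end());
      int A = std::min(atoms, N);
      atom_l[u].assign(A, 0.0);
      double tot = 0;
      for (auto& x : lw) tot += x.second;
      double cum = 0;
      int ai = 0;
      for (int i = 0; i < N && ai < A; i++) {
        cum += lw[i].second;
        while (ai < A && cum >= (ai + 0.5) / A * tot) atom_l[u][ai++] = lw[i].first;
      }
      while (ai < A) atom_l[u][ai++] = lw[N - 1].first;
    }
  }

  // advance digest pointers past locus s; compute per-unit distances
  void digest_at(double s, std::vector<double>& sdist, std::vector<int>& scens,
                 std::vector<double>& mu_eff) {
    int U = (int)digest.singles.size();
    sdist.resize(U); scens.resize(U); mu_eff.resize(U);
    for (int u = 0; u < U; u++) {
      auto& v = digest.singles[u];
      while (single_ptr[u] < v.size() && v[single_ptr[u]] <= s) single_ptr[u]++;
      double d; int c;
      if (single_ptr[u] < v.size()) { d = v[single_ptr[u]] - s; c = 0; }
      else { d = L - s; c = 1; }
      sdist[u] = d; scens[u] = c;
      mu_eff[u] = (d > 0) ? dem.mu * mask.obslen(s, s + d) / d : dem.mu;
    }
    for (size_t k = 0; k < digest.cherries.size(); k++) {
      auto& sup = digest.cherries[k].support;
      while (cherry_ptr[k] < sup.size() && sup[cherry_ptr[k]] <= s) cherry_ptr[k]++;
    }
  }

  double log_h(const Particle& p, double s, const std::vector<double>& sdist,
               const std::vector<int>& scens, const std::vector<double>& mu_eff) {
    int U = (int)digest.singles.size();
    double lbar = 0;
    for (int i = 0; i < n; i++) lbar += p.t.tm[p.t.parent[i]];
    lbar /= n;
    double hmix = 0;
    for (int mix = 0; mix < 2; mix++) {
      double rhoP = (mix == 0) ? dem.rho : 0.5 * dem.rho;
      double val = 1.0;
      for (int u = 0; u < U; u++) {
        double l;
        if (!unphased) l = p.t.tm[p.t.parent[u]];
        else l = p.t.tm[p.t.parent[2 * u]] + p.t.tm[p.t.parent[2 * u + 1]];
        double rho_i = 2.0 * l * rhoP * (n - 1) / (double)n;
        double mu_i = mu_eff[u] * l;
        const std::vector<double>& al = atom_l[u];
        double term = 0;
        for (double lp : al)
          term += singleton_term(rho_i, mu_i, mu_eff[u] * lp, sdist[u], scens[u] != 0);
        val *= term / (double)al.size();
      }
      if (n >= 3) {
        for (size_t k = 0; k < digest.cherries.size(); k++) {
          auto& ck = digest.cherries[k];
          if (cherry_ptr[k] >= ck.support.size()) continue; // no future support
          double s1 = ck.support[cherry_ptr[k]] - s;
          double s2 = ck.support.back() - s;
          bool present = (p.t.parent[ck.a] == p.t.parent[ck.b]);
          if (present) {
            double l = p.t.tm[p.t.parent[ck.a]]; // both TBLs equal the cherry height
            double rhoC = 4.0 * l * rhoP * (n - 2) / (double)n;
            val *= cherry_present_term(s2, rhoC, n);
          } else {
            double rhoCp = (n - 1) * lbar * rhoP;
            val *= cherry_absent_term(s1, rhoCp, n);
          }
        }
      }
      hmix += 0.5 * val;
    }
    return std::log(hmix);
  }

  // --- harvesting ----------------------------------------------------------

  void harvest(double s, bool final_h) {
    std::vector<double> wn;
    norm_weights(wn);
    harvest_visited.clear();
    harvest_stamp++;
    for (int i = 0; i < N; i++) {
      int r = part[i].newest;
      while (r != -1 && !arena.full_harvested(r)) {
        Record& rr = arena.rec[r];
        if (rr.stamp != harvest_stamp) {
          rr.stamp = harvest_stamp;
          rr.pend = 0;
          harvest_visited.push_back(r);
        }
        rr.pend += wn[i];
        r = rr.prev;
      }
    }
    for (int ri : harvest_visited) {
      Record& r = arena.rec[ri];
      for (int e = 0; e < E; e++) {
        if ((r.harvested >> e) & 1) continue;
        if (!final_h && r.locus > s - lags[e]) continue;
        r_opp[e] += r.pend * r.span_opp[e] * r.span_len;
        c_opp[e] += r.pend * r.coal_opp[e];
        if (r.epoch_nu == e) r_cnt[e] += r.pend;
        if (r.epoch_tau == e) c_cnt[e] += r.pend;
        r.harvested |= ((uint64_t)1 << e);
      }
    }
    // Detach fully-harvested prefixes oldest-first (reverse visit order):
    // a record is then never reclaimed before the sweep reaches it, because
    // its first-visited child (or its particle) still holds a reference.
    for (auto it = harvest_visited.rbegin(); it != harvest_visited.rend(); ++it) {
      Record& r = arena.rec[*it];
      if (arena.full_harvested(*it) && r.prev != -1) {
        arena.decref(r.prev);
        r.prev = -1;
      }
    }
    if (final_h) {
      // tail span of each particle's current tree
      for (int i = 0; i < N; i++) {
        for (int e = 0; e < E; e++)
          r_opp[e] += wn[i] * part[i].span_opp[e] * (L - part[i].span_start);
      }
    }
  }

  // --- node lifetimes (correlation distances) ------------------------------
  // We track these with a light wrapper around advance(): the removed node's
  // age must be read before surgery, so advance() is specialised below.

  // --- main loop -----------------------------------------------------------

  List run(bool return_final_trees, const std::vector<double>& track_loci) {
    int K = (int)waypoints.size();
    ess_w_tr.reserve(K); ess_v_tr.reserve(K);
    resampled_tr.reserve(K); cumll_tr.reserve(K);

    // sites are waypoints; map waypoint index -> site index (or -1)
    std::vector<int> site_at(K, -1);
    {
      size_t j = 0;
      for (int k = 0; k < K; k++) {
        while (j < site_loci.size() && site_loci[j] < waypoints[k]) j++;
        if (j < site_loci.size() && site_loci[j] == waypoints[k]) site_at[k] = (int)j;
      }
    }
    // sites at locus 0 (waypoint 0) are emitted against the initial trees
    if (K > 0 && site_at[0] >= 0) apply_site(site_at[0]);

    std::vector<double> sdist, mu_eff;
    std::vector<int> scens;
    if (lookahead) {
      refresh_atoms();
      digest_at(waypoints[0], sdist, scens, mu_eff);
      for (auto& p : part) {
        p.logh = log_h(p, waypoints[0], sdist, scens, mu_eff);
        p.logv = p.logw + p.logh; // h^{s0}(x)/h^{pre}(empty)=h, applied to initial state
      }
    }

    // posterior tracking
    std::vector<double> trk_B(track_loci.size(), 0.0), trk_T(track_loci.size(), 0.0);
    size_t trk_i = 0;

    int low_ess_run = 0;
    for (int k = 0; k + 1 < K; k++) {
      double s0 = waypoints[k], s1 = waypoints[k + 1];
      double ew = ess_of(false);
      double ev = lookahead ? ess_of(true) : ew;
      ess_w_tr.push_back(ew);
      ess_v_tr.push_back(ev);
      cumll_tr.push_back(logw_off + lse_logw(false));

      // posterior summaries at tracked loci
      while (trk_i < track_loci.size() && track_loci[trk_i] <= s0) {
        std::vector<double> wn;
        norm_weights(wn);
        double mb = 0, mt = 0;
        for (int i = 0; i < N; i++) {
          mb += wn[i] * part[i].Bcur;
          mt += wn[i] * part[i].t.tm[part[i].t.root];
        }
        trk_B[trk_i] = mb; trk_T[trk_i] = mt;
        trk_i++;
      }

      bool trigger = (lookahead ? ev : ew) < ess_frac * N;
      resampled_tr.push_back(trigger ? 1 : 0);
      if (trigger) {
        resample();
        if (lookahead) refresh_atoms();
        low_ess_run = ((lookahead ? ev : ew) < 1 + 1e-6) ? low_ess_run + 1 : 0;
        if (low_ess_run > 2)
          Rcpp::warning("particle degeneracy: ESS stuck at 1 after resampling");
      }

      if (!std::isfinite(lse_logw(false))) {
        int dead = 0;
        for (auto& p : part) if (!std::isfinite(p.logw)) dead++;
        stop("total particle weight underflowed to zero at locus %.0f "
             "(%d/%d particles dead); increase the particle count",
             s0, dead, N);
      }

      std::vector<double> logw_pre;
      if (lookahead) {
        logw_pre.resize(N);
        for (int i = 0; i < N; i++) logw_pre[i] = part[i].logw;
      }
      for (int i = 0; i < N; i++) {
        if (track_life) advance_tracked(part[i], i, s0, s1);
        else advance(part[i], i, s0, s1);
      }
      if (site_at[k + 1] >= 0) apply_site(site_at[k + 1]);

      if (lookahead) {
        // v gets the same prior/emission/eta increment as w, times the ratio
        // h^{s_{j+1}}(x_{s_{j+1}}) / h^{s_j}(x_{s_j}); at s_K the lookahead
        // factor is empty (h = 1)
        if (atom_refresh > 0 && (k % atom_refresh) == atom_refresh - 1) refresh_atoms();
        digest_at(s1, sdist, scens, mu_eff);
        for (int i = 0; i < N; i++) {
          Particle& p = part[i];
          double lh = (k + 2 == K) ? 0.0 : log_h(p, s1, sdist, scens, mu_eff);
          // a particle killed by a zero-probability pattern is dead in v too
          if (!std::isfinite(p.logw)) p.logv = R_NegInf;
          else p.logv += (p.logw - logw_pre[i]) + (lh - p.logh);
          p.logh = lh;
        }
      }
      if (harvest_stride > 0 && (k % harvest_stride) == harvest_stride - 1)
        harvest(s1, false);
      renormalize();
      if ((k & 255) == 0) Rcpp::checkUserInterrupt();
    }
    // final trace entries at s_K
    ess_w_tr.push_back(ess_of(false));
    ess_v_tr.push_back(lookahead ? ess_of(true) : ess_of(false));
    resampled_tr.push_back(0);
    double loglik = logw_off + lse_logw(false);
    cumll_tr.push_back(loglik);

    if (dead_sites > 0)
      Rcpp::warning("%d site(s) were incompatible with every particle and "
                    "were skipped; consider more particles", dead_sites);

    harvest(L, true);

    // outputs
    std::vector<double> wn;
    norm_weights(wn);
    NumericVector fB(N), fT(N), fW(N);
    for (int i = 0; i < N; i++) {
      fB[i] = part[i].Bcur;
      fT[i] = part[i].t.tm[part[i].t.root];
      fW[i] = wn[i];
    }
    List final_trees = R_NilValue;
    if (return_final_trees) {
      List lt(N);
      for (int i = 0; i < N; i++) lt[i] = tree_to(part[i].t);
      final_trees = lt;
    }
    List stats = List::create(
      _["recomb_count"] = NumericVector(r_cnt.begin(), r_cnt.end()),
      _["recomb_opp"] = NumericVector(r_opp.begin(), r_opp.end()),
      _["coal_count"] = NumericVector(c_cnt.begin(), c_cnt.end()),
      _["coal_opp"] = NumericVector(c_opp.begin(), c_opp.end()));
    List life = List::create(
      _["sum"] = NumericVector(life_sum.begin(), life_sum.end()),
      _["count"] = NumericVector(life_cnt.begin(), life_cnt.end()));
    return List::create(
      _["loglik"] = loglik,
      _["ess_w"] = NumericVector(ess_w_tr.begin(), ess_w_tr.end()),
      _["ess_v"] = NumericVector(ess_v_tr.begin(), ess_v_tr.end()),
      _["resampled"] = IntegerVector(resampled_tr.begin(), resampled_tr.end()),
      _["cum_loglik"] = NumericVector(cumll_tr.begin(), cumll_tr.end()),
      _["stats"] = stats,
      _["node_life"] = life,
      _["final_B"] = fB, _["final_tmrca"] = fT, _["final_w"] = fW,
      _["final_trees"] = final_trees,
      _["dead_sites"] = dead_sites,
      _["peak_records"] = (double)arena.peak_live);
  }

  // advance with node-lifetime tracking (duplicated logic kept in sync with
  // advance(); the removed node's age must be read before surgery)
  void advance_tracked(Particle& p, int pi, double a, double b) {
    double pos = a;
    for (;;) {
      double rate = dem.rho * p.Bcur;
      double d = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
      if (pos + d >= b) {
        p.logw -= dem.mu * p.Bcur * mask.obslen(pos, b);
        break;
      }
      double locus = pos + d;
      p.logw -= dem.mu * p.Bcur * mask.obslen(pos, locus);
      int branch; double nu;
      sample_point(p.t, p.Bcur, branch, nu);
      int ri = arena.alloc();
      Record& r = arena.rec[ri];
      int k_at_tau;
      double tau = sample_recoal(p.t, nu, dem, r.coal_opp, k_at_tau);
      int target = choose_branch_at(p.t, tau, k_at_tau);
      r.locus = locus;
      r.span_len = locus - p.span_start;
      r.nu = nu; r.tau = tau;
      r.epoch_nu = dem.epoch_of(nu);
      r.epoch_tau = dem.epoch_of(tau);
      r.span_opp = p.span_opp;
      r.changed_tree = (target != branch);
      r.prev = p.newest;
      r.refcount = 1;
      p.newest = ri;
      if (r.changed_tree) {
        int removed = p.t.parent[branch];
        double removed_age = p.t.tm[removed];
        int e = dem.epoch_of(removed_age);
        life_sum[e] += locus - node_birth(pi, removed);
        life_cnt[e] += 1;
        apply_surgery(p.t, branch, nu, target, tau);
        set_node_birth(pi, removed, locus);
        tree_changed(p, locus);
      } else {
        p.span_start = locus;
      }
      if (vb_mode) p.logw += log_eta_rho + log_eta_coal[r.epoch_tau];
      pos = locus;
    }
  }
};

// [[Rcpp::export]]
List cpp_run_filter(List obs, List model, List config) {
  Engine eng;
  eng.init(obs, model, config);
  bool ret_trees = as<bool>(config["return_final_trees"]);
  NumericVector tl = config["track_loci"];
  std::vector<double> track(tl.begin(), tl.end());
  return eng.run(ret_trees, track);
}

// initial-state debug hook: sample the initial ensemble, compute the digest
// at locus 0 and each particle's lookahead log-likelihood (for cross-checks
// against the R-level implementation)
// [[Rcpp::export]]
List cpp_lookahead_debug(List obs, List model, List config) {
  Engine eng;
  eng.init(obs, model, config);
  if (!eng.lookahead) stop("lookahead disabled");
  eng.refresh_atoms();
  std::vector<double> sdist, mu_eff;
  std::vector<int> scens;
  eng.digest_at(0.0, sdist, scens, mu_eff);
  int N = eng.N;
  NumericVector lh(N);
  List trees(N);
  for (int i = 0; i < N; i++) {
    lh[i] = eng.log_h(eng.part[i], 0.0, sdist, scens, mu_eff);
    trees[i] = tree_to(eng.part[i].t);
  }
  List ch(eng.digest.cherries.size());
  for (size_t k = 0; k < eng.digest.cherries.size(); k++) {
    auto& c = eng.digest.cherries[k];
    ch[k] = List::create(_["a"] = c.a + 1, _["b"] = c.b + 1,
                         _["support"] = NumericVector(c.support.begin(), c.support.end()));
  }
  List atoms(eng.atom_l.size());
  for (size_t u = 0; u < eng.atom_l.size(); u++)
    atoms[u] = NumericVector(eng.atom_l[u].begin(), eng.atom_l[u].end());
  return List::create(_["log_h"] = lh, _["trees"] = trees,
                      _["sdist"] = NumericVector(sdist.begin(), sdist.end()),
                      _["censored"] = IntegerVector(scens.begin(), scens.end()),
                      _["mu_eff"] = NumericVector(mu_eff.begin(), mu_eff.end()),
                      _["cherries"] = ch, _["atoms"] = atoms);
}

// ---------------------------------------------------------------------------
// Data simulator: one realisation of the jump process with Poisson mutation
// dropping (infinite sites).  Returns variant loci and carrier masks plus a
// per-window mean TMRCA track.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(int n, double L, List model, double window) {
  Demography dem = demography_from(model);
  Tree t;
  sample_stationary(t, n, dem);
  std::vector<double> loci;
  std::vector<double> masks;
  int nwin = (int)std::ceil(L / window);
  std::vector<double> tmrca_acc(nwin, 0.0);

  double pos = 0;
  long n_events = 0;
  std::vector<uint64_t> desc;
  while (pos < L) {
    double B = t.B();
    double rate = dem.rho * B;
    double d = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
    double seg_end = std::min(pos + d, L);
    // mutations on [pos, seg_end)
    double lambda = dem.mu * B * (seg_end - pos);
    int nm = (int)R::rpois(lambda);
    if (nm > 0) {
      t.desc_masks(desc);
      for (int m = 0; m < nm; m++) {
        double lo = pos + R::unif_rand() * (seg_end - pos);
        int branch; double nu;
        sample_point(t, B, branch, nu);
        loci.push_back(lo);
        masks.push_back((double)desc[branch]);
      }
    }
    // TMRCA accumulation (length-weighted within windows)
    {
      double a = pos, root_t = t.tm[t.root];
      while (a < seg_end) {
        int w = (int)(a / window);
        double we = std::min((w + 1) * window, seg_end);
        tmrca_acc[w] += root_t * (we - a);
        a = we;
      }
    }
    if (seg_end >= L) break;
    // recombination
    int branch; double nu;
    sample_point(t, B, branch, nu);
    std::vector<double> co;
    int k_at_tau;
    double tau = sample_recoal(t, nu, dem, co, k_at_tau);
    int target = choose_branch_at(t, tau, k_at_tau);
    if (target != branch) apply_surgery(t, branch, nu, target, tau);
    n_events++;
    pos = seg_end;
  }
  for (int w = 0; w < nwin; w++) {
    double we = std::min((double)(w + 1) * window, L);
    tmrca_acc[w] /= (we - w * window);
  }
  // sort by locus (mutations within a segment were appended unsorted in locus
  // only across the Poisson draws)
  std::vector<size_t> ord(loci.size());
  for (size_t i = 0; i < ord.size(); i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return loci[a] < loci[b]; });
  NumericVector ol(loci.size()), om(loci.size());
  for (size_t i = 0; i < ord.size(); i++) { ol[i] = loci[ord[i]]; om[i] = masks[ord[i]]; }
  return List::create(_["loci"] = ol, _["carriers"] = om,
                      _["tmrca"] = NumericVector(tmrca_acc.begin(), tmrca_acc.end()),
                      _["n_recomb"] = (double)n_events);
}

// [[Rcpp::export]]
NumericVector cpp_fast_exp(NumericVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); i++) out[i] = fexp(x[i]);
  return out;
}
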