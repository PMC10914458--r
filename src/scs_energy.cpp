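#include <Rcpp.h>
using namespace Rcpp;

// Sequence encoding: 1..20 canonical (alphabetical one-letter order),
// 0 = gap, -1 = unknown.  Gap/X contacts contribute the mean potential value
// over the 20 amino acids (row mean / grand mean).

static inline double pot(const NumericMatrix &U, const NumericVector &rowmean,
                         double grandmean, int a, int b) {
  if (a > 0 && b > 0) return U(a - 1, b - 1);
  if (a > 0) return rowmean[a - 1];
  if (b > 0) return rowmean[b - 1];
  return grandmean;
}

static void pot_means(const NumericMatrix &U, NumericVector &rowmean,
                      double &grandmean) {
  double g = 0.0;
  for (int i = 0; i < 20; ++i) {
    double s = 0.0;
    for (int j = 0; j < 20; ++j) s += U(i, j);
    rowmean[i] = s / 20.0;
    g += s;
  }
  grandmean = g / 400.0;
}

// [[Rcpp::export]]
double contact_energy_cpp(IntegerVector seq, IntegerMatrix pairs,
                          NumericMatrix U) {
  NumericVector rowmean(20);
  double grandmean;
  pot_means(U, rowmean, grandmean);
  double e = 0.0;
  for (int k = 0; k < pairs.nrow(); ++k)
    e += pot(U, rowmean, grandmean, seq[pairs(k, 0) - 1], seq[pairs(k, 1) - 1]);
  return e;
}

// [[Rcpp::export]]
NumericVector decoy_energies_cpp(IntegerVector seq, IntegerVector di,
                                 IntegerVector dj, IntegerVector dk, int M,
                                 NumericMatrix U) {
  NumericVector rowmean(20);
  double grandmean;
  pot_means(U, rowmean, grandmean);
  NumericVector E(M);
  int n = di.size();
  for (int t = 0; t < n; ++t)
    E[dk[t] - 1] += pot(U, rowmean, grandmean, seq[di[t] - 1], seq[dj[t] - 1]);
  return E;
}

struct StabState {
  // native adjacency (CSR over sites) and decoy adjacency (CSR over sites,
  // carrying decoy index + partner site per entry)
  std::vector<int> nat_ptr, nat_nb;
  std::vector<int> dec_ptr, dec_k, dec_nb;
  IntegerMatrix pairs;
  IntegerVector di, dj, dk;
  int L, M;
  double T, sU, lnM;
  NumericMatrix U;
  NumericVector rowmean;
  double grandmean;

  StabState(List sm)
      : pairs(as<IntegerMatrix>(as<List>(sm["cmap"])["pairs"])),
        di(as<IntegerVector>(sm["decoy_i"])),
        dj(as<IntegerVector>(sm["decoy_j"])),
        dk(as<IntegerVector>(sm["decoy_k"])),
        U(as<NumericMatrix>(as<List>(sm["potential"])["U"])), rowmean(20) {
    L = as<int>(sm["L"]);
    M = as<int>(sm["M"]);
    T = as<double>(sm["T"]);
    sU = as<double>(sm["s_U"]);
    lnM = std::log((double)M);
    pot_means(U, rowmean, grandmean);
    std::vector<std::vector<int>> nat(L);
    for (int k = 0; k < pairs.nrow(); ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      nat[i].push_back(j);
      nat[j].push_back(i);
    }
    nat_ptr.assign(L + 1, 0);
    for (int i = 0; i < L; ++i) nat_ptr[i + 1] = nat_ptr[i] + nat[i].size();
    nat_nb.reserve(nat_ptr[L]);
    for (int i = 0; i < L; ++i)
      nat_nb.insert(nat_nb.end(), nat[i].begin(), nat[i].end());
    std::vector<std::vector<std::pair<int,int>>> dec(L);
    for (int t = 0; t < di.size(); ++t) {
      int i = di[t] - 1, j = dj[t] - 1, k = dk[t] - 1;
      dec[i].push_back(std::make_pair(k, j));
      dec[j].push_back(std::make_pair(k, i));
    }
    dec_ptr.assign(L + 1, 0);
    for (int i = 0; i < L; ++i) dec_ptr[i + 1] = dec_ptr[i] + dec[i].size();
    dec_k.reserve(dec_ptr[L]);
    dec_nb.reserve(dec_ptr[L]);
    for (int i = 0; i < L; ++i)
      for (size_t t = 0; t < dec[i].size(); ++t) {
        dec_k.push_back(dec[i][t].first);
        dec_nb.push_back(dec[i][t].second);
      }
  }

  double p(int a, int b) const { return pot(U, rowmean, grandmean, a, b); }

  void full_energies(const std::vector<int> &seq, double &Enat,
                     std::vector<double> &E) const {
    Enat = 0.0;
    std::fill(E.begin(), E.end(), 0.0);
    for (int k = 0; k < pairs.nrow(); ++k)
      Enat += p(seq[pairs(k, 0) - 1], seq[pairs(k, 1) - 1]);
    for (int t = 0; t < di.size(); ++t)
      E[dk[t] - 1] += p(seq[di[t] - 1], seq[dj[t] - 1]);
  }

  // dG from current native energy and decoy-energy vector (REM with freezing)
  double dg(double Enat, const std::vector<double> &E) const {
    double mean = 0.0;
    for (int k = 0; k < M; ++k) mean += E[k];
    mean /= M;
    double s2 = 0.0;
    for (int k = 0; k < M; ++k) s2 += (E[k] - mean) * (E[k] - mean);
    s2 = M > 1 ? s2 / (M - 1) : 0.0;
    double Tf = std::sqrt(s2 / (2.0 * lnM));
    double Gmisf = (T < Tf) ? mean - std::sqrt(2.0 * s2 * lnM)
                            : mean - s2 / (2.0 * T) - T * lnM;
    double Gunf = -T * sU * L;
    double m = std::min(Gunf, Gmisf);
    double Gnon = m - T * std::log(std::exp((m - Gunf) / T) +
                                   std::exp((m - Gmisf) / T));
    return Enat - Gnon;
  }

  double apply_mut(std::vector<int> &seq, std::vector<double> &E, double Enat,
                   int site, int aa_new) const {
    int aa_old = seq[site];
    for (int t = nat_ptr[site]; t < nat_ptr[site + 1]; ++t) {
      int j = nat_nb[t];
      Enat += p(aa_new, seq[j]) - p(aa_old, seq[j]);
    }
    for (int t = dec_ptr[site]; t < dec_ptr[site + 1]; ++t) {
      int j = dec_nb[t];
      E[dec_k[t]] += p(aa_new, seq[j]) - p(aa_old, seq[j]);
    }
    seq[site] = aa_new;
    return Enat;
  }
};

static inline double log_fitness_from_dg(double dg, double T) {
  // log of the two-state native occupancy 1/(1+exp(dg/T)), stable for any
  // dg/T (log f = -log1p(e^{dg/T}) = -dg/T - log1p(e^{-dg/T}) when dg/T > 0)
  double x = dg / T;
  if (x > 0) return -x - std::log1p(std::exp(-x));
  return -std::log1p(std::exp(x));
}

// Moran fixation probability from lr = log(f_old/f_new); stable for the
// near-lethal limits where fitness ratios over/underflow
static inline double moran_fix_lr(double lr, double Ne) {
  if (Ne <= 1.0) return 1.0;
  if (std::fabs(lr) < 1e-14) return 1.0 / Ne;
  if (lr > 0) {
    // deleterious: P = e^{(1-Ne)lr} (1 - e^{-lr}) / (1 - e^{-Ne lr})
    double num = -std::expm1(-lr);
    double den = -std::expm1(std::max(-700.0, -Ne * lr));
    return std::exp((1.0 - Ne) * lr) * num / den;
  }
  // advantageous: P = (1 - e^{lr}) / (1 - e^{Ne lr})
  double num = -std::expm1(lr);
  double den = -std::expm1(std::max(-700.0, Ne * lr));
  return num / den;
}

struct ScsWalker {
  const StabState &S;
  std::vector<int> seq;
  std::vector<double> E;
  double Enat, dg_cur;
  std::vector<double> cum;
  double tot;
  int kind;           // 0 neutral, 1 fitness
  double thr, Ne;
  bool record;
  std::vector<int> decisions;
  std::vector<double> rec_dg_old, rec_dg_new, rec_u;
  long n_prop = 0, n_acc = 0;

  ScsWalker(const StabState &S_, const std::vector<int> &seq0,
            const NumericVector &rates, int kind_, double thr_, double Ne_,
            bool record_)
      : S(S_), seq(seq0), E(S_.M, 0.0), kind(kind_), thr(thr_), Ne(Ne_),
        record(record_) {
    S.full_energies(seq, Enat, E);
    dg_cur = S.dg(Enat, E);
    cum.resize(S.L);
    tot = 0.0;
    for (int i = 0; i < S.L; ++i) { tot += rates[i]; cum[i] = tot; }
  }

  // one proposal: consumes exactly three uniforms (site, residue, acceptance)
  // regardless of model so neutral/fitness share a proposal stream
  bool propose() {
    double u_site = unif_rand() * tot;
    int site = std::lower_bound(cum.begin(), cum.end(), u_site) - cum.begin();
    if (site >= S.L) site = S.L - 1;
    int aa_old = seq[site];
    int off = 1 + (int)(unif_rand() * 19.0);
    if (off > 19) off = 19;
    int aa_new = ((aa_old - 1) + off) % 20 + 1;
    double u = unif_rand();
    double Enat_old = Enat, dg_old = dg_cur;
    Enat = S.apply_mut(seq, E, Enat, site, aa_new);
    double dg_new = S.dg(Enat, E);
    bool accept;
    if (kind == 0) {
      accept = dg_new <= thr;
    } else {
      double lr = log_fitness_from_dg(dg_old, S.T) -
                  log_fitness_from_dg(dg_new, S.T);
      // origination-process scaling: Ne * P_fix equals 1 in the neutral
      // limit, so the fitness model collapses onto the neutral one as T -> 0
      double pacc = std::min(1.0, Ne * moran_fix_lr(lr, Ne));
      accept = u < pacc;
    }
    if (accept) {
      dg_cur = dg_new;
    } else {
      S.apply_mut(seq, E, Enat, site, aa_old);   // exact reverse deltas
      Enat = Enat_old;
      dg_cur = dg_old;
    }
    if (record) {
      decisions.push_back(accept ? 1 : 0);
      rec_dg_old.push_back(dg_old);
      rec_dg_new.push_back(dg_new);
      rec_u.push_back(u);
    }
    ++n_prop;
    if (accept) ++n_acc;
    return accept;
  }

  int branch(double blen) {
    int nev = (int)R::rpois(blen * tot);
    int acc = 0;
    for (int ev = 0; ev < nev; ++ev)
      if (propose()) ++acc;
    return acc;
  }
};

// Evolve sequences over a rooted tree under an SCS model.
//
// edge_parent/edge_child: preorder edge list (ape node ids, root = ntip+1);
// lengths in attempted substitutions per site.  Returns sequences for every
// node (rows indexed by node id), per-node dG, realized substitutions per
// edge, and the concatenated acceptance-decision stream when requested.
// [[Rcpp::export]]
List evolve_scs_tree_cpp(IntegerVector seq0, IntegerVector edge_parent,
                         IntegerVector edge_child, NumericVector edge_length,
                         int n_nodes, int root, NumericVector rates, List sm,
                         int kind, double dG_threshold, double Ne,
                         int burnin_accepts = 0,
                         bool record_decisions = false) {
  StabState S(sm);
  std::vector<int> rootseq(seq0.begin(), seq0.end());

  RNGScope scope;

  // burn-in: proposals at the root until `burnin_accepts` acceptances
  if (burnin_accepts > 0) {
    ScsWalker w(S, rootseq, rates, kind, dG_threshold, Ne, record_decisions);
    int got = 0;
    long cap = 200L * burnin_accepts + 1000L;
    long tries = 0;
    while (got < burnin_accepts && tries < cap) {
      if (w.propose()) ++got;
      ++tries;
    }
    rootseq = w.seq;
  }

  IntegerMatrix node_seq(n_nodes, S.L);
  NumericVector node_dg(n_nodes, NA_REAL);
  IntegerVector realized(edge_parent.size());
  std::vector<int> all_decisions;
  std::vector<double> all_dg_old, all_dg_new, all_u;

  // store root state
  {
    ScsWalker w0(S, rootseq, rates, kind, dG_threshold, Ne, false);
    node_dg[root - 1] = w0.dg_cur;
  }
  for (int j = 0; j < S.L; ++j) node_seq(root - 1, j) = rootseq[j];

  for (int e = 0; e < edge_parent.size(); ++e) {
    int par = edge_parent[e] - 1, chi = edge_child[e] - 1;
    std::vector<int> pseq(S.L);
    for (int j = 0; j < S.L; ++j) pseq[j] = node_seq(par, j);
    ScsWalker w(S, pseq, rates, kind, dG_threshold, Ne, record_decisions);
    realized[e] = w.branch(edge_length[e]);
    for (int j = 0; j < S.L; ++j) node_seq(chi, j) = w.seq[j];
    node_dg[chi] = w.dg_cur;
    if (record_decisions) {
      all_decisions.insert(all_decisions.end(), w.decisions.begin(),
                           w.decisions.end());
      all_dg_old.insert(all_dg_old.end(), w.rec_dg_old.begin(),
                        w.rec_dg_old.end());
      all_dg_new.insert(all_dg_new.end(), w.rec_dg_new.begin(),
                        w.rec_dg_new.end());
      all_u.insert(all_u.end(), w.rec_u.begin(), w.rec_u.end());
    }
  }

  return List::create(
      _["node_seq"] = node_seq, _["node_dg"] = node_dg,
      _["realized"] = realized,
      _["decisions"] = IntegerVector(all_decisions.begin(),
                                     all_decisions.end()),
      _["prop_dg_old"] = NumericVector(all_dg_old.begin(), all_dg_old.end()),
      _["prop_dg_new"] = NumericVector(all_dg_new.begin(), all_dg_new.end()),
      _["prop_u"] = NumericVector(all_u.begin(), all_u.end()));
}

// Incremental-vs-full consistency probe: perform `steps` random mutations
// with incremental updates, returning incremental and freshly recomputed dG
// after every step.
// [[Rcpp::export]]
List dg_increment_probe_cpp(IntegerVector seq0, List sm, int steps) {
  StabState S(sm);
  std::vector<int> seq(seq0.begin(), seq0.end());
  std::vector<double> E(S.M, 0.0);
  double Enat;
  S.full_energies(seq, Enat, E);

  RNGScope scope;
  NumericVector dg_inc(steps), dg_full(steps);
  std::vector<double> E2(S.M, 0.0);
  for (int s = 0; s < steps; ++s) {
    int site = (int)(unif_rand() * S.L);
    if (site >= S.L) site = S.L - 1;
    int off = 1 + (int)(unif_rand() * 19.0);
    if (off > 19) off = 19;
    int aa_new = ((seq[site] - 1) + off) % 20 + 1;
    Enat = S.apply_mut(seq, E, Enat, site, aa_new);
    dg_inc[s] = S.dg(Enat, E);
    double Ef;
    S.full_energies(seq, Ef, E2);
    dg_full[s] = S.dg(Ef, E2);
  }
  return List::create(_["dg_incremental"] = dg_inc, _["dg_full"] = dg_full);
}
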