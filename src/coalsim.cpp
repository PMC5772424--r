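// Coalescent simulation engine: piecewise-exponential demography over one or
// more demes (no migration; demes merge at fixed event times), generalized
// stepwise mutation for microsatellites, infinite-sites mutation for mtDNA,
// plus the per-dataset microsatellite summary-statistic kernel.
//
// Time runs backward from the sampling point (t = 0) in generations.  Deme
// sizes are passed already scaled to gene-copy numbers G(t); with k lineages
// the pairwise coalescence rate is k(k-1)/2 / G(t).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

struct Segment {
  double t0, t1, g0, r; // G(t) = g0 * exp(r * (t - t0)) on [t0, t1)
};

// Draw the time of the next coalescence in one deme, starting at time t with
// total pair rate c = k(k-1)/2, by integrating the hazard across segments.
// Returns R_PosInf if the hazard available before the deme's description ends
// is exhausted (the deme then disappears in a later merge event).
static double draw_coal_time(const std::vector<Segment>& segs, double t,
                             double c) {
  double E = R::exp_rand();
  for (size_t i = 0; i < segs.size(); ++i) {
    const Segment& s = segs[i];
    if (s.t1 <= t) continue;
    double start = std::max(t, s.t0);
    if (s.r == 0.0) {
      double rate = c / s.g0;
      if (!std::isfinite(s.t1)) return start + E / rate;
      double cap = rate * (s.t1 - start);
      if (E < cap) return start + E / rate;
      E -= cap;
    } else {
      // finite segment (growth segments always have finite t1)
      double a = c / (s.g0 * s.r);
      double e0 = std::exp(-s.r * (start - s.t0));
      double e1 = std::exp(-s.r * (s.t1 - s.t0));
      double cap = a * (e0 - e1); // positive for either sign of r
      if (E < cap) {
        double eu = e0 - E / a;
        return s.t0 - std::log(eu) / s.r;
      }
      E -= cap;
    }
  }
  return R_PosInf;
}

struct Demography {
  int n_demes;
  std::vector<std::vector<Segment> > segs;
  std::vector<double> m_time;
  std::vector<int> m_from, m_to;
};

static Demography unpack_demography(const NumericMatrix& segments,
                                    const NumericMatrix& merges,
                                    double copy_scale) {
  Demography d;
  int nd = 0;
  for (int i = 0; i < segments.nrow(); ++i)
    nd = std::max(nd, (int)segments(i, 0) + 1);
  d.n_demes = nd;
  d.segs.resize(nd);
  for (int i = 0; i < segments.nrow(); ++i) {
    Segment s;
    s.t0 = segments(i, 1);
    s.t1 = segments(i, 2);
    s.g0 = copy_scale * segments(i, 3);
    s.r = segments(i, 4);
    d.segs[(int)segments(i, 0)].push_back(s);
  }
  for (int k = 0; k < nd; ++k)
    std::sort(d.segs[k].begin(), d.segs[k].end(),
              [](const Segment& a, const Segment& b) { return a.t0 < b.t0; });
  for (int i = 0; i < merges.nrow(); ++i) {
    d.m_time.push_back(merges(i, 0));
    d.m_from.push_back((int)merges(i, 1));
    d.m_to.push_back((int)merges(i, 2));
  }
  return d;
}

// Core genealogy simulation.  leaf_deme is 0-based; leaves are nodes
// 0..n-1, internal nodes n..2n-2 created in coalescence (time) order so the
// root is node 2n-2.  Fills parent (-1 at root) and node times.
static void sim_genealogy_core(const Demography& d,
                               const IntegerVector& leaf_deme,
                               std::vector<int>& parent,
                               std::vector<double>& time) {
  int n = leaf_deme.size();
  parent.assign(2 * n - 1, -1);
  time.assign(2 * n - 1, 0.0);
  std::vector<std::vector<int> > active(d.n_demes);
  for (int i = 0; i < n; ++i) {
    int dm = leaf_deme[i];
    if (dm < 0 || dm >= d.n_demes) stop("leaf assigned to unknown deme");
    active[dm].push_back(i);
  }
  int next_node = n, n_active = n;
  size_t merge_ptr = 0;
  double t = 0.0;
  if (n == 1) return;
  while (n_active > 1) {
    double best = R_PosInf;
    int best_deme = -1;
    for (int k = 0; k < d.n_demes; ++k) {
      int m = active[k].size();
      if (m < 2) continue;
      double c = 0.5 * m * (m - 1);
      double tk = draw_coal_time(d.segs[k], t, c);
      if (tk < best) { best = tk; best_deme = k; }
    }
    double tm = merge_ptr < d.m_time.size() ? d.m_time[merge_ptr] : R_PosInf;
    if (best < tm) {
      std::vector<int>& lin = active[best_deme];
      int m = lin.size();
      int i = (int)(unif_rand() * m); if (i == m) i = m - 1;
      int j = (int)(unif_rand() * (m - 1)); if (j == m - 1) j = m - 2;
      if (j >= i) j += 1;
      int node = next_node++;
      parent[lin[i]] = node;
      parent[lin[j]] = node;
      time[node] = best;
      int a = std::min(i, j), b = std::max(i, j);
      lin.erase(lin.begin() + b);
      lin.erase(lin.begin() + a);
      lin.push_back(node);
      n_active -= 1;
      t = best;
    } else if (std::isfinite(tm)) {
      t = tm;
      while (merge_ptr < d.m_time.size() && d.m_time[merge_ptr] <= t) {
        int from = d.m_from[merge_ptr], to = d.m_to[merge_ptr];
        std::vector<int>& src = active[from];
        active[to].insert(active[to].end(), src.begin(), src.end());
        src.clear();
        ++merge_ptr;
      }
    } else {
      stop("non-coalescing demography: lineages stranded in demes that never merge");
    }
  }
}

// [[Rcpp::export]]
List rcpp_sim_genealogy(NumericMatrix segments, NumericMatrix merges,
                        IntegerVector leaf_deme, double copy_scale) {
  Demography d = unpack_demography(segments, merges, copy_scale);
  std::vector<int> parent;
  std::vector<double> time;
  sim_genealogy_core(d, leaf_deme, parent, time);
  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(time),
                      _["n"] = (int)leaf_deme.size());
}

// GSM mutation on a genealogy: per-branch mutation count Poisson(mu * len),
// each mutation steps +/- k with geometric magnitude P(k) = (1-p) p^(k-1).
static void mutate_microsat_core(const std::vector<int>& parent,
                                 const std::vector<double>& time, int n,
                                 double mu, double p_gsm,
                                 std::vector<int>& allele) {
  int nn = 2 * n - 1;
  allele.assign(nn, 0);
  if (n == 1 || mu <= 0.0) return;
  for (int id = nn - 2; id >= 0; --id) { // parents have larger ids
    double len = time[parent[id]] - time[id];
    int m = (int)R::rpois(mu * len);
    int net = 0;
    for (int k = 0; k < m; ++k) {
      int step = 1;
      if (p_gsm > 0.0) step += (int)R::rgeom(1.0 - p_gsm);
      net += (unif_rand() < 0.5) ? step : -step;
    }
    allele[id] = allele[parent[id]] + net;
  }
}

// [[Rcpp::export]]
IntegerVector rcpp_mutate_microsat(IntegerVector parent, NumericVector time,
                                   int n, double mu, double p_gsm) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(time.begin(), time.end());
  std::vector<int> allele;
  mutate_microsat_core(par, tim, n, mu, p_gsm, allele);
  return IntegerVector(allele.begin(), allele.begin() + n);
}

// Infinite-sites mutation: returns the n x S presence matrix of derived
// alleles (S = total mutation count; every column is polymorphic because no
// branch subtends all n tips).
static IntegerMatrix mutate_sites_core(const std::vector<int>& parent,
                                       const std::vector<double>& time,
                                       int n, double mu_seq) {
  int nn = 2 * n - 1;
  std::vector<int> nmut(nn, 0);
  int S = 0;
  if (n > 1 && mu_seq > 0.0) {
    for (int id = 0; id < nn - 1; ++id) {
      double len = time[parent[id]] - time[id];
      nmut[id] = (int)R::rpois(mu_seq * len);
      S += nmut[id];
    }
  }
  IntegerMatrix out(n, S);
  if (S == 0) return out;
  std::vector<std::vector<int> > sites(nn);
  int next_site = 0;
  for (int id = nn - 2; id >= 0; --id) {
    sites[id] = sites[parent[id]];
    for (int k = 0; k < nmut[id]; ++k) sites[id].push_back(next_site++);
    if (id < n)
      for (size_t k = 0; k < sites[id].size(); ++k) out(id, sites[id][k]) = 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix rcpp_mutate_sites(IntegerVector parent, NumericVector time,
                                int n, double mu_seq) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(time.begin(), time.end());
  return mutate_sites_core(par, tim, n, mu_seq);
}

// Simulate a full multi-locus microsatellite dataset: one independent
// genealogy per locus, GSM mutations, allele sizes as offsets from the
// ancestral repeat number.  mu holds one per-locus rate per locus.
// [[Rcpp::export]]
IntegerMatrix rcpp_sim_microsat_matrix(NumericMatrix segments,
                                       NumericMatrix merges,
                                       IntegerVector leaf_deme,
                                       double copy_scale, int n_loci,
                                       NumericVector mu, double p_gsm) {
  if (mu.size() != n_loci) stop("one mutation rate per locus required");
  Demography d = unpack_demography(segments, merges, copy_scale);
  int n = leaf_deme.size();
  IntegerMatrix out(n, n_loci);
  std::vector<int> parent, allele;
  std::vector<double> time;
  for (int l = 0; l < n_loci; ++l) {
    sim_genealogy_core(d, leaf_deme, parent, time);
    mutate_microsat_core(parent, time, n, mu[l], p_gsm, allele);
    for (int i = 0; i < n; ++i) out(i, l) = allele[i];
  }
  return out;
}

// Fast path for the mtDNA experiments: simulate one haploid locus and return
// (H, S, pi) without materializing the site matrix in R.
// [[Rcpp::export]]
NumericVector rcpp_sim_mtdna_stats(NumericMatrix segments, NumericMatrix merges,
                                   IntegerVector leaf_deme, double copy_scale,
                                   double mu_seq) {
  Demography d = unpack_demography(segments, merges, copy_scale);
  int n = leaf_deme.size();
  std::vector<int> parent;
  std::vector<double> time;
  sim_genealogy_core(d, leaf_deme, parent, time);
  IntegerMatrix sites = mutate_sites_core(parent, time, n, mu_seq);
  int S = sites.ncol();
  // pi from per-site derived counts; H by distinct rows
  double pi = 0.0;
  for (int s = 0; s < S; ++s) {
    int c = 0;
    for (int i = 0; i < n; ++i) c += sites(i, s);
    pi += (double)c * (n - c);
  }
  pi /= 0.5 * n * (n - 1);
  std::map<std::vector<int>, int> seen;
  for (int i = 0; i < n; ++i) {
    std::vector<int> row(S);
    for (int s = 0; s < S; ++s) row[s] = sites(i, s);
    seen[row] += 1;
  }
  return NumericVector::create(_["H"] = (double)seen.size(),
                               _["S"] = (double)S, _["pi"] = pi);
}

// ---------------------------------------------------------------------------
// Microsatellite summary statistics.
//
// Per locus and per grouping: number of alleles K, Nei's unbiased expected
// heterozygosity H = n/(n-1) (1 - sum p_i^2), allelic size range R, and
// Garza-Williamson M = K / (R + 1).  F_ST uses one-way ANOVA variance
// components on allele-presence indicators (ratio-of-sums over alleles and
// loci).  Missing alleles are NA and excluded per locus.

struct KHRM { double K, H, R, M; int n; };

static KHRM khrm_from_counts(const std::map<int, int>& cnt, int n) {
  KHRM s; s.n = n;
  if (n < 1 || cnt.empty()) { s.K = NA_REAL; s.H = NA_REAL; s.R = NA_REAL; s.M = NA_REAL; return s; }
  s.K = (double)cnt.size();
  double sum_p2 = 0.0;
  int amin = cnt.begin()->first, amax = cnt.rbegin()->first;
  for (std::map<int, int>::const_iterator it = cnt.begin(); it != cnt.end(); ++it) {
    double p = (double)it->second / n;
    sum_p2 += p * p;
  }
  s.H = (n > 1) ? ((double)n / (n - 1)) * (1.0 - sum_p2) : NA_REAL;
  s.R = (double)(amax - amin);
  s.M = s.K / (s.R + 1.0);
  return s;
}

// F_ST variance components for one locus restricted to a set of groups;
// accumulates numerator (sigma2_a) and denominator (sigma2_a + sigma2_w).
static void fst_components(const std::vector<std::map<int, int> >& gcnt,
                           const std::vector<int>& gn,
                           const std::vector<int>& use, double& num,
                           double& den) {
  int r = use.size();
  double N = 0.0, sum_n2 = 0.0;
  int r_eff = 0;
  for (int u = 0; u < r; ++u) {
    if (gn[use[u]] > 0) { N += gn[use[u]]; sum_n2 += (double)gn[use[u]] * gn[use[u]]; ++r_eff; }
  }
  if (r_eff < 2 || N <= r_eff) return;
  double n_c = (N - sum_n2 / N) / (r_eff - 1);
  std::map<int, double> tot;
  for (int u = 0; u < r; ++u)
    for (std::map<int, int>::const_iterator it = gcnt[use[u]].begin();
         it != gcnt[use[u]].end(); ++it)
      tot[it->first] += it->second;
  for (std::map<int, double>::const_iterator al = tot.begin(); al != tot.end(); ++al) {
    int a = al->first;
    double pbar = al->second / N;
    double ssa = 0.0, ssw = 0.0;
    for (int u = 0; u < r; ++u) {
      int ng = gn[use[u]];
      if (ng == 0) continue;
      std::map<int, int>::const_iterator it = gcnt[use[u]].find(a);
      double p = it == gcnt[use[u]].end() ? 0.0 : (double)it->second / ng;
      ssa += ng * (p - pbar) * (p - pbar);
      ssw += ng * p * (1.0 - p);
    }
    double msa = ssa / (r_eff - 1);
    double msw = ssw / (N - r_eff);
    double s2a = (msa - msw) / n_c;
    num += s2a;
    den += s2a + msw;
  }
}

static double mean_of(const std::vector<double>& x) {
  double s = 0.0; int m = 0;
  for (size_t i = 0; i < x.size(); ++i) if (!ISNAN(x[i])) { s += x[i]; ++m; }
  return m ? s / m : NA_REAL;
}
static double sd_of(const std::vector<double>& x) {
  double mu = mean_of(x), s = 0.0; int m = 0;
  if (ISNAN(mu)) return NA_REAL;
  for (size_t i = 0; i < x.size(); ++i)
    if (!ISNAN(x[i])) { s += (x[i] - mu) * (x[i] - mu); ++m; }
  return m > 1 ? std::sqrt(s / (m - 1)) : NA_REAL;
}

// Returns, in order:
//   pooled K_mean K_sd H_mean H_sd R_mean R_sd M_mean M_sd            (8)
//   per-group means of K, H, R, M (group-major: K H R M per group)    (4*r)
//   fst_global                                                        (1)
//   pairwise fst (upper triangle, row-major)                          (r(r-1)/2)
// For a single group only the pooled block is returned.
// [[Rcpp::export]]
NumericVector rcpp_microsat_stats(IntegerMatrix alleles, IntegerVector group,
                                  int n_groups) {
  int n = alleles.nrow(), L = alleles.ncol();
  int r = n_groups;
  std::vector<double> pK(L), pH(L), pR(L), pM(L);
  std::vector<std::vector<double> > gK(r, std::vector<double>(L)),
      gH(r, std::vector<double>(L)), gR(r, std::vector<double>(L)),
      gM(r, std::vector<double>(L));
  double fst_num = 0.0, fst_den = 0.0;
  int npair = r * (r - 1) / 2;
  std::vector<double> pair_num(npair, 0.0), pair_den(npair, 0.0);
  for (int l = 0; l < L; ++l) {
    std::map<int, int> pooled;
    std::vector<std::map<int, int> > gcnt(r);
    std::vector<int> gn(r, 0);
    int ntot = 0;
    for (int i = 0; i < n; ++i) {
      int a = alleles(i, l);
      if (a == NA_INTEGER) continue;
      int g = group[i];
      pooled[a] += 1;
      gcnt[g][a] += 1;
      gn[g] += 1;
      ++ntot;
    }
    KHRM ps = khrm_from_counts(pooled, ntot);
    pK[l] = ps.K; pH[l] = ps.H; pR[l] = ps.R; pM[l] = ps.M;
    for (int g = 0; g < r; ++g) {
      KHRM gs = khrm_from_counts(gcnt[g], gn[g]);
      gK[g][l] = gs.K; gH[g][l] = gs.H; gR[g][l] = gs.R; gM[g][l] = gs.M;
    }
    if (r > 1) {
      std::vector<int> all(r);
      for (int g = 0; g < r; ++g) all[g] = g;
      fst_components(gcnt, gn, all, fst_num, fst_den);
      int p = 0;
      for (int g1 = 0; g1 < r; ++g1)
        for (int g2 = g1 + 1; g2 < r; ++g2, ++p) {
          std::vector<int> two; two.push_back(g1); two.push_back(g2);
          fst_components(gcnt, gn, two, pair_num[p], pair_den[p]);
        }
    }
  }
  int len = 8 + (r > 1 ? 4 * r + 1 + npair : 0);
  NumericVector out(len);
  out[0] = mean_of(pK); out[1] = sd_of(pK);
  out[2] = mean_of(pH); out[3] = sd_of(pH);
  out[4] = mean_of(pR); out[5] = sd_of(pR);
  out[6] = mean_of(pM); out[7] = sd_of(pM);
  if (r > 1) {
    int k = 8;
    for (int g = 0; g < r; ++g) {
      out[k++] = mean_of(gK[g]);
      out[k++] = mean_of(gH[g]);
      out[k++] = mean_of(gR[g]);
      out[k++] = mean_of(gM[g]);
    }
    out[k++] = fst_den > 0.0 ? fst_num / fst_den : NA_REAL;
    for (int p = 0; p < npair; ++p)
      out[k++] = pair_den[p] > 0.0 ? pair_num[p] / pair_den[p] : NA_REAL;
  }
  return out;
}

// Product-Gaussian kernel density (log scale, log-sum-exp) of the cloud Z
// with per-dimension bandwidths h, evaluated at the rows of Y.
// [[Rcpp::export]]
NumericVector rcpp_kde_logdens(NumericMatrix Z, NumericVector h,
                               NumericMatrix Y) {
  int m = Z.nrow(), d = Z.ncol(), q = Y.nrow();
  double lognorm = -std::log((double)m);
  for (int j = 0; j < d; ++j) lognorm -= std::log(h[j] * std::sqrt(2.0 * M_PI));
  NumericVector out(q);
  std::vector<double> s(m);
  for (int y = 0; y < q; ++y) {
    double mx = R_NegInf;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        double u = (Y(y, j) - Z(i, j)) / h[j];
        acc -= 0.5 * u * u;
      }
      s[i] = acc;
      if (acc > mx) mx = acc;
    }
    double sum = 0.0;
    for (int i = 0; i < m; ++i) sum += std::exp(s[i] - mx);
    out[y] = std::log(sum) + mx + lognorm;
  }
  return out;
}
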