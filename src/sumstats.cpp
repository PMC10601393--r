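#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// The DIYABC-style microsatellite summary-statistic battery, computed in one
// pass over a dataset held as per-locus 2 x n_ind allele matrices (NA =
// missing; an individual with any missing allele at a locus is dropped at
// that locus). Feature order (n populations, C = n(n-1)/2):
//   NAL_i, HET_i, VAR_i, MGW_i                  (4n, grouped by statistic)
//   NAL2/HET2/VAR2/FST/DAS/DM2 per pair i<j     (6C, grouped by statistic)
//   LIK i->j for every ordered pair             (n(n-1))
//   AML target|parent pair for every triple     (n * C(n-1,2))
// Per-locus statistics are averaged over the loci where they are defined;
// a feature whose every locus is degenerate comes back NA.

struct PopLoc {
  std::map<int, int> cnt;   // allele -> gene-copy count
  std::map<int, int> het;   // allele -> heterozygous individuals carrying it
  int ninds = 0;            // fully genotyped individuals
  double mean = 0.0;
};

struct OneStats { double k, het, var, mgw; bool ok; };

static OneStats one_from_counts(const std::map<int, int> &cnt, int ncop) {
  OneStats s; s.ok = ncop >= 2;
  if (!s.ok) { s.k = s.het = s.var = s.mgw = 0; return s; }
  double sp2 = 0, mean = 0;
  int k = 0, mn = 0, mx = 0;
  bool first = true;
  for (std::map<int, int>::const_iterator it = cnt.begin(); it != cnt.end(); ++it) {
    double p = (double)it->second / ncop;
    sp2 += p * p;
    mean += p * it->first;
    ++k;
    if (first) { mn = mx = it->first; first = false; }
    else { if (it->first < mn) mn = it->first; if (it->first > mx) mx = it->first; }
  }
  double ss = 0;
  for (std::map<int, int>::const_iterator it = cnt.begin(); it != cnt.end(); ++it)
    ss += it->second * (it->first - mean) * (it->first - mean);
  s.k = k;
  s.het = (double)ncop / (ncop - 1) * (1.0 - sp2);
  s.var = ss / (ncop - 1);
  s.mgw = (double)k / ((mx - mn) + 1.0);
  return s;
}

// golden-section maximisation of the (concave) mixture log-likelihood in a
static double aml_opt(const std::vector<std::vector<double>> &nt,
                      const std::vector<std::vector<double>> &p1,
                      const std::vector<std::vector<double>> &p2) {
  double sep = 0.0;
  for (size_t l = 0; l < p1.size(); ++l)
    for (size_t a = 0; a < p1[l].size(); ++a)
      sep += (p1[l][a] - p2[l][a]) * (p1[l][a] - p2[l][a]);
  if (sep < 1e-15) return 0.5;  // parents indistinguishable: undefined
  struct LL {
    const std::vector<std::vector<double>> &nt, &p1, &p2;
    double operator()(double a) const {
      double ll = 0.0;
      for (size_t l = 0; l < nt.size(); ++l)
        for (size_t j = 0; j < nt[l].size(); ++j)
          if (nt[l][j] > 0) {
            double m = a * p1[l][j] + (1.0 - a) * p2[l][j];
            ll += nt[l][j] * std::log(m > 1e-12 ? m : 1e-12);
          }
      return ll;
    }
  } f = {nt, p1, p2};
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = 0.0, hi = 1.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = f(x1), f2 = f(x2);
  while (hi - lo > 1e-5) {
    if (f1 < f2) { lo = x1; x1 = x2; f1 = f2; x2 = lo + gr * (hi - lo); f2 = f(x2); }
    else { hi = x2; x2 = x1; f2 = f1; x1 = hi - gr * (hi - lo); f1 = f(x1); }
  }
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
NumericVector sumstats_cpp(List gmats, IntegerVector pop, int npop) {
  int nloc = gmats.size();
  int nind = pop.size();
  int npair = npop * (npop - 1) / 2;
  int ntrip = (npop >= 3) ? npop * (npop - 1) * (npop - 2) / 2 : 0;
  int nfeat = 4 * npop + 6 * npair + npop * (npop - 1) + ntrip;
  NumericVector out(nfeat);

  // per locus, per pop tallies; raw pointers hoisted for the O(pairs) loops
  std::vector<std::vector<PopLoc>> tab(nloc, std::vector<PopLoc>(npop));
  std::vector<const int*> gp(nloc);
  for (int l = 0; l < nloc; ++l) {
    IntegerMatrix g = gmats[l];
    if (g.nrow() != 2 || g.ncol() != nind)
      stop("locus %d: genotype matrix must be 2 x n_individuals", l + 1);
    gp[l] = INTEGER(gmats[l]);
    for (int i = 0; i < nind; ++i) {
      int a1 = g(0, i), a2 = g(1, i);
      if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
      PopLoc &pl = tab[l][pop[i] - 1];
      pl.cnt[a1]++; pl.cnt[a2]++; pl.ninds++;
      if (a1 != a2) { pl.het[a1]++; pl.het[a2]++; }
    }
    for (int p = 0; p < npop; ++p) {
      PopLoc &pl = tab[l][p];
      double m = 0; int n = 2 * pl.ninds;
      if (n > 0) {
        for (std::map<int, int>::iterator it = pl.cnt.begin(); it != pl.cnt.end(); ++it)
          m += (double)it->second * it->first;
        pl.mean = m / n;
      }
    }
  }

  int o = 0;
  // ---- one-sample: NAL, HET, VAR, MGW ----------------------------------
  std::vector<std::vector<double>> acc(4, std::vector<double>(npop, 0.0));
  std::vector<int> nval(npop, 0);
  for (int p = 0; p < npop; ++p)
    for (int l = 0; l < nloc; ++l) {
      OneStats s = one_from_counts(tab[l][p].cnt, 2 * tab[l][p].ninds);
      if (s.ok) { acc[0][p] += s.k; acc[1][p] += s.het; acc[2][p] += s.var; acc[3][p] += s.mgw; nval[p]++; }
    }
  for (int st = 0; st < 4; ++st)
    for (int p = 0; p < npop; ++p)
      out[o++] = nval[p] > 0 ? acc[st][p] / nval[p] : NA_REAL;

  // ---- two-sample ------------------------------------------------------
  std::vector<double> nal2(npair, 0), het2(npair, 0), var2(npair, 0),
      das(npair, 0), dm2(npair, 0), fstn(npair, 0), fstd(npair, 0);
  std::vector<int> npool(npair, 0), ndas(npair, 0), ndm2(npair, 0);
  std::vector<bool> fany(npair, false);
  int pr = 0;
  for (int i = 0; i < npop; ++i)
    for (int j = i + 1; j < npop; ++j, ++pr) {
      for (int l = 0; l < nloc; ++l) {
        const PopLoc &A = tab[l][i], &B = tab[l][j];
        std::map<int, int> pool(A.cnt);
        for (std::map<int, int>::const_iterator it = B.cnt.begin(); it != B.cnt.end(); ++it)
          pool[it->first] += it->second;
        int ncop = 2 * (A.ninds + B.ninds);
        OneStats s = one_from_counts(pool, ncop);
        if (s.ok) { nal2[pr] += s.k; het2[pr] += s.het; var2[pr] += s.var; npool[pr]++; }
        // Weir-Cockerham variance components, r = 2
        double n1 = A.ninds, n2 = B.ninds;
        if (n1 >= 1 && n2 >= 1 && n1 + n2 >= 3) {
          double nbar = (n1 + n2) / 2.0;
          double nc = (n1 + n2) - (n1 * n1 + n2 * n2) / (n1 + n2);
          for (std::map<int, int>::const_iterator it = pool.begin(); it != pool.end(); ++it) {
            int al = it->first;
            std::map<int, int>::const_iterator f;
            double p1 = ((f = A.cnt.find(al)) != A.cnt.end()) ? f->second / (2.0 * n1) : 0.0;
            double p2 = ((f = B.cnt.find(al)) != B.cnt.end()) ? f->second / (2.0 * n2) : 0.0;
            double h1 = ((f = A.het.find(al)) != A.het.end()) ? f->second / n1 : 0.0;
            double h2 = ((f = B.het.find(al)) != B.het.end()) ? f->second / n2 : 0.0;
            double pbar = (n1 * p1 + n2 * p2) / (n1 + n2);
            double s2 = (n1 * (p1 - pbar) * (p1 - pbar) + n2 * (p2 - pbar) * (p2 - pbar)) / nbar;
            double hbar = (n1 * h1 + n2 * h2) / (n1 + n2);
            double inner = pbar * (1.0 - pbar) - s2 / 2.0;
            double av = nbar / nc * (s2 - (inner - hbar / 4.0) / (nbar - 1.0));
            double bv = nbar / (nbar - 1.0) * (inner - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
            double cv = hbar / 2.0;
            fstn[pr] += av; fstd[pr] += av + bv + cv;
            fany[pr] = true;
          }
        }
        // DM2
        if (A.ninds > 0 && B.ninds > 0) {
          double d = A.mean - B.mean;
          dm2[pr] += d * d; ndm2[pr]++;
        }
      }
      // DAS over inter-population individual pairs and loci
      double dsum = 0; long dn = 0;
      std::vector<int> ia, ib;
      for (int a = 0; a < nind; ++a) {
        if (pop[a] == i + 1) ia.push_back(a);
        else if (pop[a] == j + 1) ib.push_back(a);
      }
      for (int l = 0; l < nloc; ++l) {
        const int *g = gp[l];
        for (size_t ak = 0; ak < ia.size(); ++ak) {
          int a1 = g[2 * ia[ak]], a2 = g[2 * ia[ak] + 1];
          if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
          for (size_t bk = 0; bk < ib.size(); ++bk) {
            int b1 = g[2 * ib[bk]], b2 = g[2 * ib[bk] + 1];
            if (b1 == NA_INTEGER || b2 == NA_INTEGER) continue;
            // multiset intersection of {a1,a2} and {b1,b2}, halved
            int sh;
            if (a1 == a2) sh = (b1 == a1) + (b2 == a1);
            else sh = ((a1 == b1 || a1 == b2) ? 1 : 0) + ((a2 == b1 || a2 == b2) ? 1 : 0);
            dsum += 1.0 - sh / 2.0;
            ++dn;
          }
        }
      }
      das[pr] = dn > 0 ? dsum / dn : NA_REAL;
      ndas[pr] = dn > 0;
    }
  for (pr = 0; pr < npair; ++pr) out[o++] = npool[pr] ? nal2[pr] / npool[pr] : NA_REAL;
  for (pr = 0; pr < npair; ++pr) out[o++] = npool[pr] ? het2[pr] / npool[pr] : NA_REAL;
  for (pr = 0; pr < npair; ++pr) out[o++] = npool[pr] ? var2[pr] / npool[pr] : NA_REAL;
  // a pair with no allelic variation at any locus carries no
  // differentiation signal: report 0 rather than an undefined ratio
  for (pr = 0; pr < npair; ++pr)
    out[o++] = (fany[pr] && fstd[pr] != 0.0) ? fstn[pr] / fstd[pr] : 0.0;
  for (pr = 0; pr < npair; ++pr) out[o++] = ndas[pr] ? das[pr] : NA_REAL;
  for (pr = 0; pr < npair; ++pr) out[o++] = ndm2[pr] ? dm2[pr] / ndm2[pr] : NA_REAL;

  // ---- LIK: assignment log-likelihood, ordered pairs -------------------
  // unseen-allele floor: 1/(2 n_Y + k), k = distinct alleles at the locus
  std::vector<int> ktot(nloc, 0);
  for (int l = 0; l < nloc; ++l) {
    std::map<int, int> all;
    for (int p = 0; p < npop; ++p)
      for (std::map<int, int>::iterator it = tab[l][p].cnt.begin(); it != tab[l][p].cnt.end(); ++it)
        all[it->first] += it->second;
    ktot[l] = all.size();
  }
  for (int i = 0; i < npop; ++i)
    for (int j = 0; j < npop; ++j) {
      if (i == j) continue;
      double liksum = 0; int nix = 0;
      for (int a = 0; a < nind; ++a) {
        if (pop[a] != i + 1) continue;
        double ll = 0; int nl = 0;
        for (int l = 0; l < nloc; ++l) {
          const int *g = gp[l];
          int a1 = g[2 * a], a2 = g[2 * a + 1];
          if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
          const PopLoc &Y = tab[l][j];
          int nY = 2 * Y.ninds;
          if (nY == 0) continue;
          double floorp = 1.0 / (nY + ktot[l]);
          std::map<int, int>::const_iterator f;
          double pa = ((f = Y.cnt.find(a1)) != Y.cnt.end()) ? (double)f->second / nY : floorp;
          double pb = ((f = Y.cnt.find(a2)) != Y.cnt.end()) ? (double)f->second / nY : floorp;
          ll += (a1 == a2) ? std::log(pa * pa) : std::log(2.0 * pa * pb);
          ++nl;
        }
        if (nl > 0) { liksum += ll / nl; ++nix; }
      }
      out[o++] = nix > 0 ? liksum / nix : NA_REAL;
    }

  // ---- AML: ML admixture coefficient per (target, parent pair) ---------
  if (npop >= 3) {
    for (int tpop = 0; tpop < npop; ++tpop)
      for (int i = 0; i < npop; ++i) {
        if (i == tpop) continue;
        for (int j = i + 1; j < npop; ++j) {
          if (j == tpop) continue;
          std::vector<std::vector<double>> nt(nloc), q1(nloc), q2(nloc);
          for (int l = 0; l < nloc; ++l) {
            const PopLoc &T = tab[l][tpop], &P1 = tab[l][i], &P2 = tab[l][j];
            if (T.ninds == 0 || P1.ninds == 0 || P2.ninds == 0) continue;
            std::map<int, int> uni(T.cnt);
            for (std::map<int, int>::const_iterator it = P1.cnt.begin(); it != P1.cnt.end(); ++it) uni[it->first] += 0;
            for (std::map<int, int>::const_iterator it = P2.cnt.begin(); it != P2.cnt.end(); ++it) uni[it->first] += 0;
            for (std::map<int, int>::iterator it = uni.begin(); it != uni.end(); ++it) {
              int al = it->first;
              std::map<int, int>::const_iterator f;
              nt[l].push_back(((f = T.cnt.find(al)) != T.cnt.end()) ? f->second : 0);
              q1[l].push_back(((f = P1.cnt.find(al)) != P1.cnt.end()) ? f->second / (2.0 * P1.ninds) : 0.0);
              q2[l].push_back(((f = P2.cnt.find(al)) != P2.cnt.end()) ? f->second / (2.0 * P2.ninds) : 0.0);
            }
          }
          out[o++] = aml_opt(nt, q1, q2);
        }
      }
  }
  return out;
}
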