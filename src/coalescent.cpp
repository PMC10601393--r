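#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Backward-time structured coalescent for one microsatellite locus under the
// generalized stepwise mutation model (GSM). Populations exchange lineages
// only at instantaneous events (splits, admixtures); within a population of
// diploid size Ne each lineage pair coalesces at rate 1/(2Ne) per generation.
// Mutations are dropped on the realised genealogy as a Poisson process and
// change repeat count by +/- s, s ~ Geometric: Pr(s=k) = (1-P) P^(k-1), k>=1;
// P = 0 is the strict stepwise model. Allele states are confined to
// [win_lo, win_hi] by reflection at the boundaries.
//
// events: list of lists with fields
//   kind : 0 = split (merge derived pops into ancestor), 1 = admixture
//   time : generations before present (strictly increasing across events)
//   from : integer vector of source pops (1-based); admixture has exactly one
//   dest : pop receiving lineages (split ancestor / admixture source1)
//   dest2: admixture source2 (ignored for splits)
//   ra   : probability a lineage moves to dest rather than dest2 (admixture)

struct CoalEvent {
  int kind;
  double time;
  std::vector<int> from;
  int dest, dest2;
  double ra;
};

// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector copies, NumericVector ne, List events,
                   double mu, double P, int ancestral, int win_lo, int win_hi,
                   bool log_steps = false) {
  int npop = copies.size();
  int ntip = 0;
  for (int p = 0; p < npop; ++p) ntip += copies[p];
  if (ntip == 0) return List::create(_["alleles"] = IntegerVector(0),
                                     _["steps"] = IntegerVector(0));

  std::vector<CoalEvent> evs;
  for (int i = 0; i < events.size(); ++i) {
    List e = events[i];
    CoalEvent ev;
    ev.kind = as<int>(e["kind"]);
    ev.time = as<double>(e["time"]);
    IntegerVector fr = e["from"];
    for (int j = 0; j < fr.size(); ++j) ev.from.push_back(fr[j] - 1);
    ev.dest = as<int>(e["dest"]) - 1;
    ev.dest2 = e.containsElementNamed("dest2") ? as<int>(e["dest2"]) - 1 : -1;
    ev.ra = e.containsElementNamed("ra") ? as<double>(e["ra"]) : 1.0;
    evs.push_back(ev);
  }

  int nnode = 2 * ntip - 1;
  std::vector<int> parent(nnode, -1);
  std::vector<double> ntime(nnode, 0.0);
  std::vector<std::vector<int>> act(npop);
  int id = 0;
  for (int p = 0; p < npop; ++p)
    for (int c = 0; c < copies[p]; ++c) act[p].push_back(id++);

  int nact = ntip, nxt = ntip;
  double t = 0.0;
  size_t ei = 0;

  while (nact > 1) {
    double rate = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)act[p].size();
      if (k > 1.0) rate += k * (k - 1.0) / 2.0 / (2.0 * ne[p]);
    }
    double tev = (ei < evs.size()) ? evs[ei].time : R_PosInf;
    double w = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (!R_FINITE(w) && !R_FINITE(tev))
      stop("coalescent cannot complete: %d lineages stranded with zero rate", nact);
    if (t + w < tev) {
      t += w;
      // pick population proportional to its pair rate
      double u = R::unif_rand() * rate, acc = 0.0;
      int pp = -1;
      for (int p = 0; p < npop; ++p) {
        double k = (double)act[p].size();
        if (k > 1.0) {
          acc += k * (k - 1.0) / 2.0 / (2.0 * ne[p]);
          if (u <= acc) { pp = p; break; }
        }
      }
      if (pp < 0) { for (int p = npop - 1; p >= 0; --p) if (act[p].size() > 1) { pp = p; break; } }
      int k = act[pp].size();
      int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = act[pp][i], b = act[pp][j];
      parent[a] = nxt; parent[b] = nxt; ntime[nxt] = t;
      if (i > j) std::swap(i, j);
      act[pp][i] = nxt;
      act[pp].erase(act[pp].begin() + j);
      ++nxt; --nact;
    } else {
      t = tev;
      const CoalEvent &ev = evs[ei];
      if (ev.kind == 0) {
        for (size_t f = 0; f < ev.from.size(); ++f) {
          std::vector<int> &src = act[ev.from[f]];
          act[ev.dest].insert(act[ev.dest].end(), src.begin(), src.end());
          src.clear();
        }
      } else {
        std::vector<int> &src = act[ev.from[0]];
        for (size_t l = 0; l < src.size(); ++l) {
          if (R::unif_rand() < ev.ra) act[ev.dest].push_back(src[l]);
          else act[ev.dest2].push_back(src[l]);
        }
        src.clear();
      }
      ++ei;
    }
  }

  // drop mutations root-down; parent index always exceeds child index
  std::vector<int> allele(nnode);
  allele[nnode - 1] = ancestral;
  std::vector<int> steps;
  for (int v = nnode - 2; v >= 0; --v) {
    double br = ntime[parent[v]] - ntime[v];
    int x = allele[parent[v]];
    int nmut = (int)R::rpois(mu * br);
    for (int m = 0; m < nmut; ++m) {
      int s = 1;
      if (P > 0.0) s += (int)R::rgeom(1.0 - P);
      if (log_steps) steps.push_back(s);
      if (R::unif_rand() < 0.5) x += s; else x -= s;
      while (x < win_lo || x > win_hi) {
        if (x < win_lo) x = 2 * win_lo - x;
        else x = 2 * win_hi - x;
      }
    }
    allele[v] = x;
  }

  IntegerVector out(ntip);
  for (int v = 0; v < ntip; ++v) out[v] = allele[v];
  return List::create(_["alleles"] = out,
                      _["steps"] = wrap(steps),
                      _["tmrca"] = t);
}
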