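#include <Rcpp.h>
using namespace Rcpp;

// Event-driven simulation of a single protein searching for its target site
// under pseudo-first-order conditions (the searching protein never depletes
// probe or competitor). States: free in solution, or nonspecifically bound at
// (species, site, orientation). The target is site `m` of the probe duplex in
// orientation 0; reaching it (by direct association, sliding, or transfer
// landing) absorbs the trajectory. Wrong-orientation sites are pure traps.
//
// Rates:
//   free -> bound:      k_on_N per site-orientation, weighted by the duplex
//                       concentration of that species
//   bound -> free:      k_off_N
//   bound -> bound':    intersegment transfer at k_IT_N * (phi L D + phi M C),
//                       destination site-orientation drawn proportionally to
//                       concentration, uniformly within the duplex
//   slide +/- 1 site:   D1 per direction (bp^2/s == 1/s on a 1-bp lattice),
//                       reflecting duplex ends
//
// Returns first-passage times and censoring flags. Uses R's RNG so that
// set.seed() in R makes runs reproducible.

// [[Rcpp::export]]
List gillespie_fpt_cpp(int n_traj, int L, int M, int m, int phi,
                       double D1, double k_off, double k_IT, double k_on,
                       double D_tot, double C_tot, double max_time) {
  NumericVector fpt(n_traj);
  LogicalVector censored(n_traj);

  const double conc_probe = phi * L * D_tot;   // site-orientation concentration
  const double conc_comp  = phi * M * C_tot;
  const double conc_tot   = conc_probe + conc_comp;
  const double r_assoc    = k_on * conc_tot;
  const double r_transfer = k_IT * conc_tot;
  const int target_site = m - 1;               // 0-based

  for (int traj = 0; traj < n_traj; ++traj) {
    double t = 0.0;
    bool bound = false, done = false, cens = false;
    int species = 0, site = 0, orient = 0;     // valid when bound

    while (!done) {
      double total;
      if (!bound) {
        total = r_assoc;
      } else {
        int len = (species == 0) ? L : M;
        double r_slide = 0.0;
        if (len > 1) r_slide = (site == 0 || site == len - 1) ? D1 : 2.0 * D1;
        total = k_off + r_transfer + r_slide;
      }
      if (total <= 0.0) { cens = true; break; }
      t += R::exp_rand() / total;
      if (t > max_time) { cens = true; break; }

      double u = unif_rand() * total;
      if (!bound) {
        // association: pick species by concentration, site/orientation uniform
        if (u < r_assoc) {
          double v = unif_rand() * conc_tot;
          if (v < conc_probe) {
            species = 0;
            site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
            orient = (int)(unif_rand() * phi); if (orient >= phi) orient = phi - 1;
          } else {
            species = 1;
            site = (int)(unif_rand() * M); if (site >= M) site = M - 1;
            orient = (int)(unif_rand() * phi); if (orient >= phi) orient = phi - 1;
          }
          bound = true;
        }
      } else {
        int len = (species == 0) ? L : M;
        if (u < k_off) {
          bound = false;
        } else if (u < k_off + r_transfer) {
          double v = unif_rand() * conc_tot;
          if (v < conc_probe) {
            species = 0;
            site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
          } else {
            species = 1;
            site = (int)(unif_rand() * M); if (site >= M) site = M - 1;
          }
          orient = (int)(unif_rand() * phi); if (orient >= phi) orient = phi - 1;
        } else {
          // sliding step, reflecting ends
          if (site == 0) site = 1;
          else if (site == len - 1) site = len - 2;
          else site += (unif_rand() < 0.5) ? -1 : 1;
        }
      }
      if (bound && species == 0 && site == target_site && orient == 0)
        done = true;
    }
    fpt[traj] = cens ? max_time : t;
    censored[traj] = cens;
  }
  return List::create(_["fpt"] = fpt, _["censored"] = censored);
}
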