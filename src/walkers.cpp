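#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time random walk on a ring of M lattice sites with
// site-dependent left/right hop probabilities (Fick-Jacobs rates times the
// step duration). Displacement is unwrapped through a winding counter so
// the mean-squared displacement is free of the ring periodicity.
//
// Walker-major loop order: each walker consumes the R RNG stream
// sequentially, so results are bitwise reproducible under set.seed().
//
// p_left, p_right: per-site hop probabilities (p_left + p_right <= 0.5
// enforced on the R side). start_sites: 1-based initial site per walker.
// report_steps: ascending step counts at which displacement^2 is
// accumulated. Returns matrix [n_report x 2]: sum and sum of squares of
// the squared displacement (in units of lattice spacing^2).
// [[Rcpp::export]]
NumericMatrix walk_ring(NumericVector p_left, NumericVector p_right,
                        IntegerVector start_sites,
                        IntegerVector report_steps) {
  const int M = p_left.size();
  const int n_walk = start_sites.size();
  const int n_rep = report_steps.size();
  const long max_step = report_steps[n_rep - 1];
  NumericMatrix acc(n_rep, 2);
  std::vector<double> pl(p_left.begin(), p_left.end());
  std::vector<double> pr(p_right.begin(), p_right.end());

  GetRNGstate();
  for (int w = 0; w < n_walk; w++) {
    int site = start_sites[w] - 1;
    long wind = 0;          // net number of ring traversals (in sites)
    const long x0 = site;
    int rep = 0;
    for (long s = 1; s <= max_step; s++) {
      const double u = unif_rand();
      if (u < pl[site]) {
        site--;
        if (site < 0) { site = M - 1; wind -= M; }
      } else if (u < pl[site] + pr[site]) {
        site++;
        if (site == M) { site = 0; wind += M; }
      }
      while (rep < n_rep && report_steps[rep] == s) {
        const double dx = (double)(site + wind - x0);
        const double d2 = dx * dx;
        acc(rep, 0) += d2;
        acc(rep, 1) += d2 * d2;
        rep++;
      }
    }
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return acc;
}
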