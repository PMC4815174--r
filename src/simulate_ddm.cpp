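#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of a two-boundary Wiener diffusion.
// Uses R's RNG (norm_rand) so set.seed() governs reproducibility.
// Trials that have not been absorbed after max_time are resampled;
// the number of resampled walks is returned alongside the trials.
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double a, double v, double z, double s,
                      double ter, double dt, double max_time) {
  NumericVector rt(n);
  IntegerVector upper(n);
  int resampled = 0;
  const double sddt = s * std::sqrt(dt);
  const double vdt = v * dt;
  const int max_steps = (int)(max_time / dt);
  for (int i = 0; i < n; ++i) {
    bool done = false;
    while (!done) {
      double x = z;
      for (int step = 1; step <= max_steps; ++step) {
        x += vdt + sddt * norm_rand();
        if (x >= a) {
          rt[i] = step * dt + ter;
          upper[i] = 1;
          done = true;
          break;
        }
        if (x <= 0.0) {
          rt[i] = step * dt + ter;
          upper[i] = 0;
          done = true;
          break;
        }
      }
      if (!done) ++resampled;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper,
                      _["resampled"] = resampled);
}
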