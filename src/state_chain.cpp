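#include <Rcpp.h>
using namespace Rcpp;

// Evolve the three-state (1 = inactive, 2 = coast, 3 = burst) locomotor
// chain frame by frame. At each frame the chain leaves its current state
// with probability frame_dt / dwell(state, illum); on a switch the target
// state is drawn from the illumination-conditional occupancy weights with
// the burst weight multiplied by the startle kernel for that frame.
//
// occ, dwell: 3 x 2 matrices (rows = states, cols = light / dark).
// illum_dark: 0 for light, 1 for dark, per frame.
// burst_mult: per-frame burst weight multiplier (>= 1 with no startle).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".state_chain")]]
IntegerVector state_chain(int n_frames, double frame_dt,
                          NumericMatrix occ, NumericMatrix dwell,
                          IntegerVector illum_dark,
                          NumericVector burst_mult, int init_state) {
  IntegerVector out(n_frames);
  int state = init_state;  // 1-based
  for (int t = 0; t < n_frames; ++t) {
    int il = illum_dark[t];
    double p_sw = frame_dt / dwell(state - 1, il);
    if (p_sw > 1.0) p_sw = 1.0;
    if (R::runif(0.0, 1.0) < p_sw) {
      double w1 = occ(0, il);
      double w2 = occ(1, il);
      double w3 = occ(2, il) * burst_mult[t];
      double tot = w1 + w2 + w3;
      double u = R::runif(0.0, 1.0) * tot;
      if (u < w1) state = 1;
      else if (u < w1 + w2) state = 2;
      else state = 3;
    }
    out[t] = state;
  }
  return out;
}
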