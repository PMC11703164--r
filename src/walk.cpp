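#include <Rcpp.h>
using namespace Rcpp;

// Bounded 2-D walk with persistent heading and wall reflection.
//
// All randomness (step lengths, turn increments) is generated on the R side
// so the kernel is a deterministic fold. Reflection flips the offending
// heading component and re-takes the full step from the previous position,
// which preserves the step magnitude exactly -- the per-syllable velocity
// estimator must recover the generating speed to machine precision on
// noiseless input.
//
// step:  per-frame step length (cm), length T-1 (steps into frames 2..T)
// turn:  heading increment (radians), length T-1
// x0,y0: starting position; h0: starting heading; side: arena side (cm)
// [[Rcpp::export(name = ".bounded_walk")]]
List bounded_walk(NumericVector step, NumericVector turn,
                  double x0, double y0, double h0, double side) {
  int n = step.size();
  NumericVector x(n + 1), y(n + 1), heading(n + 1);
  x[0] = x0; y[0] = y0; heading[0] = h0;
  double h = h0;
  for (int t = 0; t < n; ++t) {
    h += turn[t];
    double dx = step[t] * std::cos(h);
    double dy = step[t] * std::sin(h);
    double nx = x[t] + dx;
    double ny = y[t] + dy;
    if (nx < 0.0 || nx > side) {      // reflect: flip x-component of heading
      nx = x[t] - dx;
      h = M_PI - h;
    }
    if (ny < 0.0 || ny > side) {
      ny = y[t] - dy;
      h = -h;
    }
    // pathological fallback (step longer than arena); clamp, exactness lost
    if (nx < 0.0) nx = 0.0; else if (nx > side) nx = side;
    if (ny < 0.0) ny = 0.0; else if (ny > side) ny = side;
    x[t + 1] = nx; y[t + 1] = ny; heading[t + 1] = h;
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = heading);
}
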