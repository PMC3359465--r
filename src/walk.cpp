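#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear conformational potential shared by both models.
// Segments (U(B1) = 0 by convention, Bslope = U_barrier / 1.5):
//   [B1, TP-1.5)    : slope A            (drift ramp)
//   [TP-1.5, TP)    : slope +Bslope      (uphill barrier flank)
//   [TP, TP+1.5]    : slope -Bslope      (downhill barrier flank)
//   (TP+1.5, B2]    : slope A (model 1) or -A (model 2, mirror-symmetric)
// The outer segments are extrapolated beyond [B1, B2] so half-step
// evaluations at the reflecting edges stay defined.
static inline double u_pot(double x, double b1, double tp, double A,
                           double bslope, int model) {
  double u_tpm = (tp - 1.5 - b1) * A; // U(TP - 1.5)
  if (x < tp - 1.5)
    return (x - b1) * A;
  if (x < tp)
    return u_tpm + (x - (tp - 1.5)) * bslope;
  if (x <= tp + 1.5)
    return u_tpm + 1.5 * bslope - (x - tp) * bslope;
  double a_out = (model == 1) ? A : -A;
  return u_tpm + (x - (tp + 1.5)) * a_out;
}

// Oriented potential difference deciding the step from integer node x:
// centred difference U(x+1/2) - U(x-1/2), except next to the threshold,
// where the barrier-crossing jump (TP -+ 1 -> TP +- 1) is gated by the
// uphill half-step into the barrier peak.
static inline double du_at(int x, double b1, int tp, double A,
                           double bslope, int model) {
  if (x == tp - 1)
    return u_pot(tp, b1, tp, A, bslope, model) -
           u_pot(tp - 0.5, b1, tp, A, bslope, model);
  if (x == tp + 1)
    return u_pot(tp + 0.5, b1, tp, A, bslope, model) -
           u_pot(tp, b1, tp, A, bslope, model);
  return u_pot(x + 0.5, b1, tp, A, bslope, model) -
         u_pot(x - 0.5, b1, tp, A, bslope, model);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int model, double n_steps_d, int tp, int b1_init, int b2_init,
              int b_max, double u_barrier, double fd, double drift_step,
              double drift_max, int slow_period, bool record_paths) {
  R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  double bslope = u_barrier / 1.5;
  int b1 = b1_init, b2 = b2_init;
  int drift_lvl = 0;                       // model 2: A = drift_lvl * drift_step
  int lvl_max = (int)std::lround(drift_max / drift_step);
  double A = (model == 1) ? fd : 0.0;
  int rc = tp - 1;

  IntegerVector states(n_steps);
  IntegerVector rc_path, b2_path;
  NumericVector drift_path;
  if (record_paths) {
    rc_path = IntegerVector(n_steps);
    if (model == 1) b2_path = IntegerVector(n_steps);
    else drift_path = NumericVector(n_steps);
  }

  for (R_xlen_t i = 0; i < n_steps; ++i) {
    double du = du_at(rc, (double)b1, tp, A, bslope, model);
    double p = 0.5 - du / 4.0;             // probability of RC -> RC + 1
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    int dir = (unif_rand() < p) ? 1 : -1;
    int target = rc + dir;
    if (target == tp) target += dir;       // threshold node is not occupiable
    if (target >= b1 && target <= b2) rc = target; // else reflect (= stay)

    if ((i + 1) % slow_period == 0) {      // slow membrane-density process
      if (model == 1) {
        if (unif_rand() < 0.5) {           // shrink both half-spaces
          if (b2 - 1 >= 2) { b1 += 1; b2 -= 1; }
        } else {                            // expand both half-spaces
          if (b2 + 1 <= b_max) { b1 -= 1; b2 += 1; }
        }
        if (rc > b2) rc = b2;
        if (rc < b1) rc = b1;
      } else {
        int dl = (unif_rand() < 0.5) ? 1 : -1;
        if (std::abs(drift_lvl + dl) <= lvl_max) drift_lvl += dl;
        A = drift_lvl * drift_step;
      }
    }

    states[i] = (rc > tp) ? 1 : 0;
    if (record_paths) {
      rc_path[i] = rc;
      if (model == 1) b2_path[i] = b2; else drift_path[i] = A;
    }
  }

  List out = List::create(_["states"] = states);
  if (record_paths) {
    out["rc"] = rc_path;
    if (model == 1) out["b2"] = b2_path; else out["drift"] = drift_path;
  }
  return out;
}

// Run-length encoding of a 0/1 state vector: (state, duration) pairs.
// [[Rcpp::export(name = ".rle_core")]]
List rle_core(IntegerVector states) {
  R_xlen_t n = states.size();
  std::vector<int> st, dur;
  int cur = states[0], len = 1;
  for (R_xlen_t i = 1; i < n; ++i) {
    if (states[i] == cur) { ++len; }
    else { st.push_back(cur); dur.push_back(len); cur = states[i]; len = 1; }
  }
  st.push_back(cur); dur.push_back(len);
  return List::create(_["state"] = wrap(st), _["duration"] = wrap(dur));
}

// Mean rescaled range R/S over disjoint windows of each requested size.
// Per window: subtract the window mean, cumulate, R = max - min of the
// cumulated deviate, S = population standard deviation. Windows with
// S = 0 are skipped; NaN is returned if none survive at a given size.
// [[Rcpp::export(name = ".rs_core")]]
NumericVector rs_core(NumericVector x, IntegerVector window_sizes) {
  R_xlen_t n = x.size();
  int nw = window_sizes.size();
  NumericVector out(nw);
  for (int j = 0; j < nw; ++j) {
    int w = window_sizes[j];
    R_xlen_t k = n / w;
    double acc = 0.0;
    R_xlen_t used = 0;
    for (R_xlen_t b = 0; b < k; ++b) {
      const double* seg = &x[b * w];
      double m = 0.0;
      for (int t = 0; t < w; ++t) m += seg[t];
      m /= w;
      double cum = 0.0, cmax = 0.0, cmin = 0.0, ss = 0.0;
      for (int t = 0; t < w; ++t) {
        double d = seg[t] - m;
        ss += d * d;
        cum += d;
        if (cum > cmax) cmax = cum;
        if (cum < cmin) cmin = cum;
      }
      double s = std::sqrt(ss / w);
      if (s > 0.0) { acc += (cmax - cmin) / s; ++used; }
    }
    out[j] = used > 0 ? acc / used : R_NaN;
  }
  return out;
}
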