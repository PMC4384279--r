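#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact (direct-method) stochastic simulation of the leaky two-state
// auto-regulatory gene circuit and its two variants.
//
// variant 0 (baseline):  D0 ->(g1) D1, D1 ->(g0) D0, D1+P ->(f n) D0+P,
//                        D1 ->(l1) D1+P, D0 ->(l0) D0+P, P ->(d n) 0.
// variant 1 (slow TF binding): the feedback binding sequesters one product
//   molecule; D1+P ->(f n) D0·P (bound), D0·P ->(k_off) D0 + P, and g1
//   returns only the unbound D0 to D1. With k_off much faster than every
//   other rate the bound episodes vanish and the baseline catalytic flip is
//   recovered.
// variant 2 (two-stage): promoter switching as baseline with protein
//   feedback; Ds ->(ls) Ds+M, M ->(k_p) M+P, M ->(d_m) 0, P ->(d n) 0.
//
// Uses R's RNG (reproducible via set.seed on the R side). Accumulates a
// time-weighted product-count histogram over [burn_in, t_end], a log of
// maximal constant-promoter segments (start time, promoter state, number of
// product-synthesis events fired inside the segment), and per-channel event
// counters; optionally stores the full event path.

// [[Rcpp::export]]
List ssa_gillespie(double gamma1, double gamma0, double f,
                   double lambda1, double lambda0, double d,
                   double t_end, double burn_in, int variant,
                   double k_off, double k_p, double d_m,
                   bool store_path) {
  const int NCH = 8;
  std::vector<double> a(NCH, 0.0);
  std::vector<double> nch(NCH, 0.0);

  int s = 0;        // promoter state: 0 = D0, 1 = D1
  int bound = 0;    // variant 1: one product sequestered on the DNA
  long n = 0;       // product (protein) copy number
  long m = 0;       // mRNA copy number (variant 2)

  std::vector<double> hist;
  hist.reserve(256);
  std::vector<double> seg_start, seg_synth_v;
  std::vector<int> seg_state;
  seg_start.push_back(0.0);
  seg_state.push_back(s);
  double seg_synth = 0.0;

  std::vector<double> p_time, p_count, p_mrna;
  std::vector<int> p_state;
  if (store_path) {
    p_time.push_back(0.0); p_state.push_back(s); p_count.push_back(0.0);
    if (variant == 2) p_mrna.push_back(0.0);
  }

  double t = 0.0;
  while (t < t_end) {
    // propensities
    if (variant == 0) {
      a[0] = (s == 0) ? gamma1 : 0.0;
      a[1] = (s == 1) ? gamma0 : 0.0;
      a[2] = (s == 1) ? f * n : 0.0;
      a[3] = (s == 1) ? lambda1 : 0.0;
      a[4] = (s == 0) ? lambda0 : 0.0;
      a[5] = d * n;
      a[6] = a[7] = 0.0;
    } else if (variant == 1) {
      a[0] = (s == 0 && !bound) ? gamma1 : 0.0;
      a[1] = (s == 1) ? gamma0 : 0.0;
      a[2] = (s == 1) ? f * n : 0.0;       // association, sequesters one P
      a[3] = (s == 1) ? lambda1 : 0.0;
      a[4] = (s == 0) ? lambda0 : 0.0;
      a[5] = d * n;
      a[6] = (s == 0 && bound) ? k_off : 0.0;  // dissociation, releases P
      a[7] = 0.0;
    } else {
      a[0] = (s == 0) ? gamma1 : 0.0;
      a[1] = (s == 1) ? gamma0 : 0.0;
      a[2] = (s == 1) ? f * n : 0.0;
      a[3] = (s == 1) ? lambda1 : 0.0;     // transcription
      a[4] = (s == 0) ? lambda0 : 0.0;
      a[5] = d * n;                        // protein degradation
      a[6] = k_p * m;                      // translation
      a[7] = d_m * m;                      // mRNA degradation
    }
    double a0 = 0.0;
    for (int i = 0; i < NCH; ++i) a0 += a[i];

    double t_next;
    if (a0 <= 0.0) {
      t_next = t_end;
    } else {
      double u;
      do { u = unif_rand(); } while (u <= 0.0);
      t_next = t + (-std::log(u)) / a0;
    }
    double t_clip = (t_next < t_end) ? t_next : t_end;
    // time-weighted occupancy of the current count level over [burn_in, t_end]
    double lo = (t > burn_in) ? t : burn_in;
    if (t_clip > lo) {
      if ((size_t)n >= hist.size()) hist.resize(n + 1, 0.0);
      hist[n] += t_clip - lo;
    }
    if (a0 <= 0.0 || t_next >= t_end) break;
    t = t_next;

    // pick channel
    double r = unif_rand() * a0, acc = 0.0;
    int ch = NCH - 1;
    for (int i = 0; i < NCH; ++i) {
      acc += a[i];
      if (r <= acc) { ch = i; break; }
    }
    nch[ch] += 1.0;

    int s_before = s;
    switch (ch) {
      case 0: s = 1; break;                       // activation D0 -> D1
      case 1: s = 0; bound = 0; break;            // basal deactivation
      case 2:                                     // feedback deactivation
        s = 0;
        if (variant == 1) { bound = 1; --n; }     // sequestration
        break;
      case 3: if (variant == 2) ++m; else ++n; seg_synth += (variant == 2) ? 0.0 : 1.0; break;
      case 4: if (variant == 2) ++m; else ++n; seg_synth += (variant == 2) ? 0.0 : 1.0; break;
      case 5: --n; break;
      case 6:
        if (variant == 1) { bound = 0; ++n; }     // dissociation releases P
        else { ++n; seg_synth += 1.0; }           // translation
        break;
      case 7: --m; break;
    }
    if (s != s_before) {
      seg_synth_v.push_back(seg_synth);
      seg_synth = 0.0;
      seg_start.push_back(t);
      seg_state.push_back(s);
    }
    if (store_path) {
      p_time.push_back(t); p_state.push_back(s); p_count.push_back((double)n);
      if (variant == 2) p_mrna.push_back((double)m);
    }
  }
  seg_synth_v.push_back(seg_synth);

  List out = List::create(
    _["hist_weights"] = NumericVector(hist.begin(), hist.end()),
    _["seg_start"] = NumericVector(seg_start.begin(), seg_start.end()),
    _["seg_state"] = IntegerVector(seg_state.begin(), seg_state.end()),
    _["seg_synth"] = NumericVector(seg_synth_v.begin(), seg_synth_v.end()),
    _["channel_counts"] = NumericVector(nch.begin(), nch.end()),
    _["final_state"] = IntegerVector::create(s, bound),
    _["final_count"] = (double)n,
    _["final_mrna"] = (double)m);
  if (store_path) {
    out["path_time"] = NumericVector(p_time.begin(), p_time.end());
    out["path_state"] = IntegerVector(p_state.begin(), p_state.end());
    out["path_count"] = NumericVector(p_count.begin(), p_count.end());
    if (variant == 2)
      out["path_mrna"] = NumericVector(p_mrna.begin(), p_mrna.end());
  }
  return out;
}
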