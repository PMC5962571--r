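#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for a one-species birth-death process with a piecewise-constant
// production rate. `breaks`/`rates` define the schedule on [0, duration):
// rate rates[i] applies on [breaks[i], breaks[i+1]) with breaks[0] == 0.
// Degradation propensity is p * n. Snapshot times must be ascending and lie
// in [0, duration]. The state is right-continuous: a snapshot that coincides
// with an event time records the post-event count.
//
// Piecewise-constant rates make the process time-homogeneous within each
// segment, so plain Gillespie applies; a tentative event falling beyond the
// segment end is discarded and the clock restarts at the boundary
// (memorylessness of the exponential makes this exact).
// [[Rcpp::export]]
IntegerVector ssa_schedule_cpp(int n0, double p, NumericVector breaks,
                               NumericVector rates, double duration,
                               NumericVector snap_times) {
  const int nseg = breaks.size();
  if (rates.size() != nseg) stop("breaks and rates must have equal length");
  const int S = snap_times.size();
  IntegerVector out(S);
  double t = 0.0;
  long n = n0;
  int seg = 0, si = 0;
  // locate starting segment (breaks[0] should be 0, but be safe)
  while (seg + 1 < nseg && breaks[seg + 1] <= t) ++seg;
  for (;;) {
    const double segend = (seg + 1 < nseg) ? std::min(breaks[seg + 1], duration)
                                           : duration;
    const double k = rates[seg];
    const double a = k + p * (double)n;
    const double te = (a > 0.0) ? t + R::exp_rand() / a : R_PosInf;
    if (te < segend) {
      while (si < S && snap_times[si] < te) out[si++] = (int)n;
      t = te;
      if (R::unif_rand() * a < k) ++n; else --n;
    } else {
      while (si < S && snap_times[si] < segend) out[si++] = (int)n;
      t = segend;
      if (t >= duration) {
        while (si < S) out[si++] = (int)n;
        break;
      }
      ++seg;
    }
  }
  return out;
}

// Log-likelihood of phase-binned count histograms under the analytic
// CME solution: within each phase the count is Poisson with mean m(t), and
// the phase distribution is the uniform mixture of Poisson(m) over the
// quadrature nodes supplied in m_list. Counts equal to n_max are treated as
// the folded tail bin P(X >= n_max); this guards log(0) for extreme counts.
//
// m            : mean m(t) at the quadrature nodes of all phases, stacked
// group_len[f] : number of quadrature nodes belonging to phase f
// counts_list[f]  : distinct observed count values in phase f, ascending
// weights_list[f] : number of cells observed at each count value
//
// The Poisson pmfs are evaluated by the recurrence
// P(c+1) = P(c) * m / (c+1) starting from P(0) = exp(-m), giving one exp()
// per quadrature node instead of one dpois() per (node, count) pair.
// [[Rcpp::export]]
double phase_mixture_loglik_cpp(NumericVector m, IntegerVector group_len,
                                List counts_list, List weights_list,
                                int n_max) {
  const int F = group_len.size();
  double ll = 0.0;
  int off = 0;
  for (int f = 0; f < F; ++f) {
    const int G = group_len[f];
    IntegerVector cs = counts_list[f];
    NumericVector w = weights_list[f];
    const int J = cs.size();
    if (G == 0 || J == 0) { off += G; continue; }
    int cmax = -1;
    bool any_tail = false;
    for (int j = 0; j < J; ++j) {
      if (cs[j] >= n_max) any_tail = true;
      else if (cs[j] > cmax) cmax = cs[j];
    }
    std::vector<double> acc(J, 0.0);
    double tail_acc = 0.0;
    for (int g = 0; g < G; ++g) {
      const double mm = m[off + g];
      double pc = std::exp(-mm);
      int j = 0;
      for (int c = 0; c <= cmax; ++c) {
        if (c > 0) pc *= mm / (double)c;
        if (j < J && cs[j] == c) acc[j++] += pc;
      }
      if (any_tail) tail_acc += R::ppois((double)(n_max - 1), mm, 0, 0);
    }
    for (int j = 0; j < J; ++j) {
      double pmf = (cs[j] >= n_max ? tail_acc : acc[j]) / (double)G;
      if (pmf < 1e-300) pmf = 1e-300;
      ll += w[j] * std::log(pmf);
    }
    off += G;
  }
  return ll;
}
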