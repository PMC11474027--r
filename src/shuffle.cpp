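#include <Rcpp.h>
using namespace Rcpp;

// Null distribution accumulator for the pseudo-event shuffle test.
// q:       a session-long value vector (binned spike counts on the step
//          grid, or a dF/F sample vector)
// centers: n_shuffles x n_events matrix of 1-based positions into q,
//          chosen so that every position + offset stays in range
// offsets: integer offsets (grid units) of each analysis bin relative
//          to the pseudo-event position
// Returns the n_shuffles x n_bins matrix of per-shuffle means over the
// pseudo events: null[s, b] = mean_j q[centers(s, j) + offsets[b]].
// [[Rcpp::export]]
NumericMatrix shuffle_null_means(NumericVector q, IntegerMatrix centers,
                                 IntegerVector offsets) {
  const int n_shuf = centers.nrow();
  const int n_ev = centers.ncol();
  const int n_bins = offsets.size();
  const int qn = q.size();
  NumericMatrix out(n_shuf, n_bins);
  std::vector<double> acc(n_bins);
  const double* qp = REAL(q);
  for (int s = 0; s < n_shuf; ++s) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < n_ev; ++j) {
      const int c = centers(s, j) - 1;
      for (int b = 0; b < n_bins; ++b) {
        const int idx = c + offsets[b];
        if (idx >= 0 && idx < qn) acc[b] += qp[idx];
      }
    }
    for (int b = 0; b < n_bins; ++b) out(s, b) = acc[b] / n_ev;
  }
  return out;
}

// Spike counts in half-open sliding windows [edges[i], edges[i] + width)
// over a sorted spike-time vector; used to grid a session for the
// shuffle null. Returns one count per edge.
// [[Rcpp::export]]
NumericVector sliding_counts(NumericVector spikes, NumericVector edges,
                             double width) {
  const int n = spikes.size();
  const int m = edges.size();
  NumericVector out(m);
  int lo = 0, hi = 0;
  for (int i = 0; i < m; ++i) {
    const double a = edges[i], b = edges[i] + width;
    while (lo < n && spikes[lo] < a) ++lo;
    if (hi < lo) hi = lo;
    while (hi < n && spikes[hi] < b) ++hi;
    out[i] = hi - lo;
  }
  return out;
}
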