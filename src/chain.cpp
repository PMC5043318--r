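#include <Rcpp.h>
using namespace Rcpp;

// Sample an index from a cumulative distribution (last entry ~ 1).
static inline int sample_cum(const double *cum, int k) {
  double u = unif_rand();
  for (int j = 0; j < k - 1; ++j) {
    if (u <= cum[j]) return j;
  }
  return k - 1;
}

// Simulate a first-order Markov chain over k states.
// cumprob: k x k row-wise cumulative transition probabilities; a row of
// zeros marks a dead end, on which the chain restarts from init_cum.
// Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
IntegerVector simulate_chain_cpp(NumericMatrix cumprob,
                                 NumericVector init_cum, int n) {
  int k = cumprob.nrow();
  if (k < 1 || n < 1) stop("need at least one state and one step");
  IntegerVector out(n);
  std::vector<double> row(k);
  int s = sample_cum(init_cum.begin(), k);
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    double total = cumprob(s, k - 1);
    if (total <= 0.0) {
      // dead-end state: redraw from the initial distribution
      s = sample_cum(init_cum.begin(), k);
    } else {
      for (int j = 0; j < k; ++j) row[j] = cumprob(s, j);
      s = sample_cum(row.data(), k);
    }
    out[t] = s + 1;
  }
  return out;
}

// Pooled CV* of mean-normalized recurrence intervals, computed directly
// on an integer state sequence. membership(i, u) says whether state i+1
// carries unit u; intervals are positional differences between
// consecutive occurrences minus `sub` (0 = positional convention).
// Population s.d. over the pooled normalized values divided by their
// mean. Returns NA if no unit yields a usable interval.
// [[Rcpp::export]]
double pooled_cv_seq_cpp(IntegerVector states, LogicalMatrix membership,
                         bool include_singletons = true, int sub = 0) {
  int n = states.size();
  int k = membership.nrow();
  int m = membership.ncol();
  double sum = 0.0, sumsq = 0.0;
  long cnt = 0;
  std::vector<double> iv;
  for (int u = 0; u < m; ++u) {
    iv.clear();
    int last = -1;
    for (int t = 0; t < n; ++t) {
      int s = states[t] - 1;
      if (s < 0 || s >= k) stop("state index out of range");
      if (membership(s, u)) {
        if (last >= 0) iv.push_back((double)(t - last - sub));
        last = t;
      }
    }
    size_t ni = iv.size();
    if (ni == 0) continue;
    if (ni == 1 && !include_singletons) continue;
    double mu = 0.0;
    for (size_t i = 0; i < ni; ++i) mu += iv[i];
    mu /= ni;
    if (mu <= 0.0) continue;
    for (size_t i = 0; i < ni; ++i) {
      double v = iv[i] / mu;
      sum += v;
      sumsq += v * v;
      ++cnt;
    }
  }
  if (cnt == 0) return NA_REAL;
  double mean = sum / cnt;
  double var = sumsq / cnt - mean * mean;
  if (var < 0) var = 0;
  return std::sqrt(var) / mean;
}
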