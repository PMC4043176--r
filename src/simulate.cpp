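#include <Rcpp.h>
using namespace Rcpp;

// Event-driven stochastic applause bout, SIR-style. Starting stage: each
// susceptible individual has hazard lambda * (I+R) (or lambda * (I+R)^2 for
// the quadratic variant) per second, so the waiting time to the next start
// is exponential with the summed rate; the literal-proportion variant uses
// the total rate lambda * S * (I+R) instead. Stopping stage: after each
// clap the individual stops with probability
// gamma1 + gamma2 * R + gamma3 * n / n_max (clamped to [0,1]) or claps
// again after a Normal(interval_mean, interval_sd) wait truncated below at
// interval_min. Uses R's RNG throughout so set.seed() gives reproducible
// bouts.

static std::vector<double> starts_internal(int n, double lambda,
                                           bool quadratic, bool literal,
                                           int n0) {
  std::vector<double> t(n, 0.0);
  for (int k = n0; k < n; ++k) {
    double frac = (double)k / n;               // I + R before this start
    double per = quadratic ? lambda * frac * frac : lambda * frac;
    double rate = literal ? per * (double)(n - k) / n : per * (double)(n - k);
    t[k] = t[k - 1] + R::rexp(1.0 / rate);
  }
  return t;
}

static double clap_interval(double imean, double isd, double imin) {
  double T = R::rnorm(imean, isd);
  while (T < imin) T = R::rnorm(imean, isd);
  return T;
}

// indexed binary min-heap over next-clap times: pop/update in O(log n)
struct ClapHeap {
  std::vector<int> heap;          // heap of individual indices
  std::vector<int> pos;           // position of individual in heap, -1 if out
  std::vector<double> key;        // next-clap times
  ClapHeap(const std::vector<double>& times) : key(times) {
    int n = times.size();
    heap.resize(n); pos.resize(n);
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
    for (int i = n / 2 - 1; i >= 0; --i) sift_down(i);
  }
  bool less(int a, int b) const {
    return key[heap[a]] < key[heap[b]] ||
      (key[heap[a]] == key[heap[b]] && heap[a] < heap[b]);
  }
  void swap_at(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void sift_down(int i) {
    int n = heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && less(l, m)) m = l;
      if (r < n && less(r, m)) m = r;
      if (m == i) break;
      swap_at(i, m); i = m;
    }
  }
  int top() const { return heap[0]; }
  void increase_top(double t) { key[heap[0]] = t; sift_down(0); }
  void remove_top() {
    pos[heap[0]] = -1;
    heap[0] = heap.back(); pos[heap[0]] = 0;
    heap.pop_back();
    if (!heap.empty()) sift_down(0);
  }
  bool empty() const { return heap.empty(); }
};

static void stops_internal(const std::vector<double>& start_times,
                           double gamma1, double gamma2, double gamma3,
                           int n_max, double imean, double isd, double imin,
                           std::vector<std::vector<double> >& claps) {
  int n = start_times.size();
  claps.assign(n, std::vector<double>());
  std::vector<int> nclap(n, 0);
  int stopped = 0;
  ClapHeap q(start_times);
  while (!q.empty()) {
    int i = q.top();
    double t = q.key[i];
    nclap[i]++;
    claps[i].push_back(t);
    double Rfrac = (double)stopped / n;
    double p = gamma1 + gamma2 * Rfrac + gamma3 * (double)nclap[i] / n_max;
    if (p > 1.0) p = 1.0;
    if (p < 0.0) p = 0.0;
    if (unif_rand() < p) {
      ++stopped;
      q.remove_top();
    } else {
      q.increase_top(t + clap_interval(imean, isd, imin));
    }
  }
}

// [[Rcpp::export]]
NumericVector sim_starts_cpp(int n, double lambda, bool quadratic,
                             bool literal, int n0) {
  std::vector<double> t = starts_internal(n, lambda, quadratic, literal, n0);
  return wrap(t);
}

// [[Rcpp::export]]
List sim_stops_cpp(NumericVector start_times, double gamma1, double gamma2,
                   double gamma3, int n_max, double interval_mean,
                   double interval_sd, double interval_min) {
  std::vector<double> st(start_times.begin(), start_times.end());
  std::vector<std::vector<double> > claps;
  stops_internal(st, gamma1, gamma2, gamma3, n_max, interval_mean,
                 interval_sd, interval_min, claps);
  List out(st.size());
  for (size_t i = 0; i < claps.size(); ++i) out[i] = wrap(claps[i]);
  return out;
}

// Whole-ensemble summaries without materialising bouts: one row per run
// with columns N, start_spread, stop_spread, length, mean_claps,
// first_stop. Audience sizes are recycled across runs.
// [[Rcpp::export]]
NumericMatrix sim_ensemble_cpp(int n_runs, IntegerVector sizes, double lambda,
                               bool quadratic, bool literal, int n0,
                               double gamma1, double gamma2, double gamma3,
                               int n_max, double interval_mean,
                               double interval_sd, double interval_min) {
  NumericMatrix out(n_runs, 6);
  colnames(out) = CharacterVector::create("N", "start_spread", "stop_spread",
                                          "length", "mean_claps", "first_stop");
  for (int r = 0; r < n_runs; ++r) {
    int n = sizes[r % sizes.size()];
    std::vector<double> st = starts_internal(n, lambda, quadratic, literal, n0);
    std::vector<std::vector<double> > claps;
    stops_internal(st, gamma1, gamma2, gamma3, n_max, interval_mean,
                   interval_sd, interval_min, claps);
    double first_stop = R_PosInf, last_stop = 0.0;
    long total_claps = 0;
    for (int i = 0; i < n; ++i) {
      double stp = claps[i].back();
      if (stp < first_stop) first_stop = stp;
      if (stp > last_stop) last_stop = stp;
      total_claps += claps[i].size();
    }
    out(r, 0) = n;
    out(r, 1) = st[n - 1] - st[0];
    out(r, 2) = last_stop - first_stop;
    out(r, 3) = last_stop - st[0];
    out(r, 4) = (double)total_claps / n;
    out(r, 5) = first_stop;
  }
  return out;
}
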