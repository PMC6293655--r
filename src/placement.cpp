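#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Draw one integer uniformly from 1..n using R's RNG stream.
static inline long long runif_int(long long n) {
  double u = unif_rand();
  long long r = (long long)(u * (double)n) + 1;
  if (r > n) r = n;
  return r;
}

// Assign each of n elements to a run with probability proportional to the
// weights encoded as a cumulative sum (cumw). Returns 1-based run indices.
// [[Rcpp::export]]
IntegerVector cpp_assign_runs(int n, NumericVector cumw) {
  int J = cumw.size();
  double total = cumw[J - 1];
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * total;
    int idx = std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
    if (idx >= J) idx = J - 1;
    out[i] = idx + 1;
  }
  return out;
}

// Floyd's algorithm: k distinct integers from 1..n, returned sorted.
static std::vector<long long> sample_distinct_sorted(long long n, int k) {
  std::vector<long long> out;
  out.reserve(k);
  std::unordered_set<long long> seen;
  seen.reserve((size_t)(k * 2));
  for (long long t = n - k + 1; t <= n; ++t) {
    long long r = runif_int(t);
    if (seen.count(r)) {
      seen.insert(t);
      out.push_back(t);
    } else {
      seen.insert(r);
      out.push_back(r);
    }
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Place elements into accessible runs. Within each run the non-overlapping
// starts are drawn by the order-statistics (stars-and-bars) construction,
// which is uniform over the feasible left-to-right configurations of the
// element lengths committed to that run. Elements assigned to a run keep
// their input order as the left-to-right order.
//
// run_start: absolute (linearized) start of each run; run_len: its length;
// elem_len: element lengths; assign: 1-based run index per element.
// Returns sorted absolute starts/ends, plus ok=FALSE if a run was
// oversubscribed (caller should have checked feasibility).
// [[Rcpp::export]]
List cpp_place_in_runs(NumericVector run_start, NumericVector run_len,
                       NumericVector elem_len, IntegerVector assign) {
  int J = run_start.size(), k = elem_len.size();
  std::vector<int> cnt(J, 0);
  for (int i = 0; i < k; ++i) cnt[assign[i] - 1]++;
  std::vector<int> offs(J + 1, 0);
  for (int j = 0; j < J; ++j) offs[j + 1] = offs[j] + cnt[j];
  std::vector<int> by_run(k);
  {
    std::vector<int> cur(offs.begin(), offs.end() - 1);
    for (int i = 0; i < k; ++i) by_run[cur[assign[i] - 1]++] = i;
  }
  NumericVector start(k), end(k);
  int pos = 0;
  for (int j = 0; j < J; ++j) {
    int kj = cnt[j];
    if (kj == 0) continue;
    double sumL = 0.0;
    for (int t = offs[j]; t < offs[j + 1]; ++t) sumL += elem_len[by_run[t]];
    double D = run_len[j] - sumL;
    if (D < 0) return List::create(_["ok"] = false);
    long long N = (long long)(D + 0.5) + kj;
    std::vector<long long> v = sample_distinct_sorted(N, kj);
    double cum = 0.0;
    for (int i = 0; i < kj; ++i) {
      double gap = (double)(v[i] - (i + 1));
      double L = elem_len[by_run[offs[j] + i]];
      start[pos] = run_start[j] + gap + cum;
      end[pos] = start[pos] + L;
      cum += L;
      ++pos;
    }
  }
  return List::create(_["ok"] = true, _["start"] = start, _["end"] = end);
}

// Total base overlap of two sorted, internally non-overlapping interval
// lists in a shared linear coordinate space.
// [[Rcpp::export]]
double cpp_overlap_sorted(NumericVector as, NumericVector ae,
                          NumericVector bs, NumericVector be) {
  int na = as.size(), nb = bs.size();
  int i = 0, j = 0;
  double total = 0.0;
  while (i < na && j < nb) {
    double lo = as[i] > bs[j] ? as[i] : bs[j];
    double hi = ae[i] < be[j] ? ae[i] : be[j];
    if (hi > lo) total += hi - lo;
    if (ae[i] < be[j]) ++i; else ++j;
  }
  return total;
}
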