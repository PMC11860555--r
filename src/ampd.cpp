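#include <Rcpp.h>
using namespace Rcpp;

// Local-maxima scalogram peak selection (AMPD).
//
// For scales k = 1..ceil(n/2)-1, the scalogram row k holds 0 where x[i] is a
// strict local maximum over (i-k, i+k) (both comparison points in range) and
// alpha + U(0,1) elsewhere (alpha = 1). The optimal scale lambda is the row
// with the smallest sum; peaks are the columns whose entries are zero at
// every scale 1..lambda (equivalently, zero standard deviation down the
// truncated column, since the random fills are almost surely distinct).
//
// The uniform draws come from R's RNG, consumed row-major over *all*
// positions, so a plain-R reimplementation with the same seed reproduces the
// matrix entry-for-entry.
// [[Rcpp::export]]
IntegerVector ampd_core_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 3) stop("series too short for scalogram peak detection");
  const int L = (int)std::ceil(n / 2.0) - 1;
  if (L < 1) stop("series too short for scalogram peak detection");
  std::vector<unsigned char> is_max((size_t)L * n);
  std::vector<double> gamma(L, 0.0);
  for (int k = 1; k <= L; ++k) {
    double g = 0.0;
    unsigned char *row = &is_max[(size_t)(k - 1) * n];
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();  // drawn for every entry to keep a fixed stream
      bool m = (i - k >= 0) && (i + k < n) &&
               (x[i] > x[i - k]) && (x[i] > x[i + k]);
      row[i] = m ? 1 : 0;
      if (!m) g += 1.0 + u;
    }
    gamma[k - 1] = g;
  }
  int lambda = 1;
  double best = gamma[0];
  for (int k = 2; k <= L; ++k) {
    if (gamma[k - 1] < best) { best = gamma[k - 1]; lambda = k; }
  }
  std::vector<int> peaks;
  for (int i = 0; i < n; ++i) {
    bool all_max = true;
    for (int k = 1; k <= lambda; ++k) {
      if (!is_max[(size_t)(k - 1) * n + i]) { all_max = false; break; }
    }
    if (all_max) peaks.push_back(i + 1);  // 1-based
  }
  return wrap(peaks);
}
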