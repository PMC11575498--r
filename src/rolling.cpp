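#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average-tie ranks of buf[0..w-1] into rank[0..w-1].
static void rank_avg(const double* buf, int w, std::vector<int>& ord,
                     double* rank) {
  for (int i = 0; i < w; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [buf](int a, int b) { return buf[a] < buf[b]; });
  int i = 0;
  while (i < w) {
    int j = i;
    while (j + 1 < w && buf[ord[j + 1]] == buf[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }
}

// Centered rolling-window Spearman correlation, step 1 sample.
// Window of w samples covers ceil((w-1)/2) samples back and floor((w-1)/2)
// forward of the center; undefined (NA) at edges and where either window
// has zero variance.
// [[Rcpp::export]]
NumericVector cpp_rolling_spearman(NumericVector x, NumericVector y, int w) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (w < 3) stop("window must cover at least 3 samples");
  NumericVector out(n, NA_REAL);
  if (w > n) return out;
  int kb = (w - 1 + 1) / 2;  // ceil((w-1)/2)
  int kf = (w - 1) - kb;
  std::vector<int> ord(w);
  std::vector<double> rx(w), ry(w), bx(w), by(w);
  const double m = 0.5 * (w + 1);
  for (int i = kb; i + kf < n; ++i) {
    const int s = i - kb;
    for (int j = 0; j < w; ++j) { bx[j] = x[s + j]; by[j] = y[s + j]; }
    rank_avg(bx.data(), w, ord, rx.data());
    rank_avg(by.data(), w, ord, ry.data());
    double sxx = 0, syy = 0, sxy = 0;
    for (int j = 0; j < w; ++j) {
      double dx = rx[j] - m, dy = ry[j] - m;
      sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
    }
    if (sxx > 0 && syy > 0) out[i] = sxy / std::sqrt(sxx * syy);
  }
  return out;
}

// Rank all length-w circular windows of x (starts 0..L-1) into R (L x w,
// row-major) and their rank standard deviations (about the fixed mean
// (w+1)/2) into sd.
static void circ_rank_windows(const NumericVector& x, int w,
                              std::vector<double>& R, std::vector<double>& sd) {
  int L = x.size();
  std::vector<int> ord(w);
  std::vector<double> buf(w);
  const double m = 0.5 * (w + 1);
  for (int s = 0; s < L; ++s) {
    for (int j = 0; j < w; ++j) buf[j] = x[(s + j) % L];
    rank_avg(buf.data(), w, ord, &R[(size_t)s * w]);
    double ss = 0;
    for (int j = 0; j < w; ++j) {
      double d = R[(size_t)s * w + j] - m;
      ss += d * d;
    }
    sd[s] = std::sqrt(ss);
  }
}

// Pooled shuffled MCV values for the data-sliding significance test.
// al/ar: participant A's left/right hand speeds within the moment;
// bl/br: participant B's. For each cut in `cuts`, A's two series are slid
// jointly (rotation by the cut), the four between-participant rolling
// Spearman correlations are recomputed, and their pointwise maximum over
// defined pairings is appended to the pool. A window of the slid series is
// a circular window of the original, so ranks are precomputed once.
// [[Rcpp::export]]
NumericVector cpp_slide_mcv_pool(NumericVector al, NumericVector ar,
                                 NumericVector bl, NumericVector br,
                                 int w, IntegerVector cuts) {
  int L = al.size();
  if (ar.size() != L || bl.size() != L || br.size() != L)
    stop("all four series must have equal length");
  if (w < 3) stop("window must cover at least 3 samples");
  if (w > L) stop("window longer than the moment");
  int ncenters = L - w + 1;

  std::vector<double> RAL((size_t)L * w), RAR((size_t)L * w);
  std::vector<double> sAL(L), sAR(L);
  circ_rank_windows(al, w, RAL, sAL);
  circ_rank_windows(ar, w, RAR, sAR);

  // B is never slid: only the L-w+1 plain windows are needed.
  std::vector<double> RBL((size_t)ncenters * w), RBR((size_t)ncenters * w);
  std::vector<double> sBL(ncenters), sBR(ncenters);
  {
    std::vector<int> ord(w);
    std::vector<double> buf(w);
    const double m = 0.5 * (w + 1);
    for (int s = 0; s < ncenters; ++s) {
      for (int j = 0; j < w; ++j) buf[j] = bl[s + j];
      rank_avg(buf.data(), w, ord, &RBL[(size_t)s * w]);
      for (int j = 0; j < w; ++j) buf[j] = br[s + j];
      rank_avg(buf.data(), w, ord, &RBR[(size_t)s * w]);
      double ssl = 0, ssr = 0;
      for (int j = 0; j < w; ++j) {
        double dl = RBL[(size_t)s * w + j] - m;
        double dr = RBR[(size_t)s * w + j] - m;
        ssl += dl * dl; ssr += dr * dr;
      }
      sBL[s] = std::sqrt(ssl);
      sBR[s] = std::sqrt(ssr);
    }
  }

  const double m = 0.5 * (w + 1);
  const double wm2 = w * m * m;
  std::vector<double> pool;
  pool.reserve((size_t)cuts.size() * ncenters);
  for (int ci = 0; ci < cuts.size(); ++ci) {
    int cut = cuts[ci];
    if (cut < 0 || cut > L) stop("cut out of range");
    for (int s = 0; s < ncenters; ++s) {
      int sa = (s + cut) % L;
      const double* pa[2] = { &RAL[(size_t)sa * w], &RAR[(size_t)sa * w] };
      const double sdA[2] = { sAL[sa], sAR[sa] };
      const double* pb[2] = { &RBL[(size_t)s * w], &RBR[(size_t)s * w] };
      const double sdB[2] = { sBL[s], sBR[s] };
      double best = NA_REAL;
      bool any = false;
      for (int ha = 0; ha < 2; ++ha) {
        if (sdA[ha] <= 0) continue;
        for (int hb = 0; hb < 2; ++hb) {
          if (sdB[hb] <= 0) continue;
          double dot = 0;
          for (int j = 0; j < w; ++j) dot += pa[ha][j] * pb[hb][j];
          double rho = (dot - wm2) / (sdA[ha] * sdB[hb]);
          if (!any || rho > best) { best = rho; any = true; }
        }
      }
      if (any) pool.push_back(best);
    }
  }
  return wrap(pool);
}
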