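#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 12 co-occurrence statistics from a normalized Q x Q joint histogram.
// Gray levels are indexed 0..Q-1; entropy uses the natural log; a GLCM with
// zero marginal variance gets correlation 0.
static void haralick12_core(const double *p, int Q, double *out) {
  double energy = 0, contrast = 0, homogeneity = 0, entropy = 0,
         autocorr = 0, dissim = 0, maxp = 0, mu_a = 0, mu_b = 0;
  for (int b = 0; b < Q; ++b) {
    for (int a = 0; a < Q; ++a) {
      double v = p[a + b * Q];
      if (v <= 0) continue;
      energy += v * v;
      contrast += (double)(a - b) * (a - b) * v;
      homogeneity += v / (1.0 + std::abs(a - b));
      entropy -= v * std::log(v);
      autocorr += (double)a * b * v;
      dissim += std::abs(a - b) * v;
      if (v > maxp) maxp = v;
      mu_a += a * v;
      mu_b += b * v;
    }
  }
  double var_a = 0, var_b = 0, corr_num = 0, shade = 0, tendency = 0,
         variance = 0;
  double mu = 0.5 * (mu_a + mu_b);
  for (int b = 0; b < Q; ++b) {
    for (int a = 0; a < Q; ++a) {
      double v = p[a + b * Q];
      if (v <= 0) continue;
      var_a += (a - mu_a) * (a - mu_a) * v;
      var_b += (b - mu_b) * (b - mu_b) * v;
      corr_num += (a - mu_a) * (b - mu_b) * v;
      double s = a + b - mu_a - mu_b;
      shade += s * s * s * v;
      tendency += s * s * v;
      variance += (a - mu) * (a - mu) * v;
    }
  }
  double sd = std::sqrt(var_a) * std::sqrt(var_b);
  double correlation = (sd > 1e-12) ? corr_num / sd : 0.0;
  out[0] = energy;
  out[1] = contrast;
  out[2] = correlation;
  out[3] = homogeneity;
  out[4] = entropy;
  out[5] = autocorr;
  out[6] = dissim;
  out[7] = shade;
  out[8] = tendency;
  out[9] = maxp;
  out[10] = variance;
  out[11] = 0.5 * (mu_a + mu_b);
}

// [[Rcpp::export]]
NumericVector cpp_haralick(NumericMatrix probs) {
  int Q = probs.nrow();
  NumericVector out(12);
  haralick12_core(probs.begin(), Q, out.begin());
  return out;
}

// Per-pixel appearance vectors over a reflect-padded quantized image.
// imgq: padded image with values 0..Q-1; rows/cols: 1-based pixel positions
// in the padded frame; one GLCM per (dr, dc) offset, 12 features each.
// [[Rcpp::export]]
NumericMatrix cpp_appearance(IntegerMatrix imgq, int Q, IntegerVector dr,
                             IntegerVector dc, int radius, bool symmetric,
                             IntegerVector rows, IntegerVector cols) {
  int J = dr.size();
  int n = rows.size();
  int nr = imgq.nrow();
  NumericMatrix out(n, 12 * J);
  std::vector<double> counts((size_t)Q * Q);
  std::vector<double> feats(12);
  const int *img = imgq.begin();
  for (int i = 0; i < n; ++i) {
    int r0 = rows[i] - 1 - radius, r1 = rows[i] - 1 + radius;
    int c0 = cols[i] - 1 - radius, c1 = cols[i] - 1 + radius;
    for (int j = 0; j < J; ++j) {
      std::fill(counts.begin(), counts.end(), 0.0);
      int ddr = dr[j], ddc = dc[j];
      double npair = 0;
      int ra = std::max(r0, r0 - ddr), rb = std::min(r1, r1 - ddr);
      int ca = std::max(c0, c0 - ddc), cb = std::min(c1, c1 - ddc);
      for (int c = ca; c <= cb; ++c) {
        for (int r = ra; r <= rb; ++r) {
          int a = img[r + c * nr];
          int b = img[(r + ddr) + (c + ddc) * nr];
          counts[a + (size_t)b * Q] += 1.0;
          if (symmetric) counts[b + (size_t)a * Q] += 1.0;
          npair += symmetric ? 2.0 : 1.0;
        }
      }
      if (npair > 0)
        for (size_t k = 0; k < counts.size(); ++k) counts[k] /= npair;
      haralick12_core(counts.data(), Q, feats.data());
      for (int u = 0; u < 12; ++u) out(i, 12 * j + u) = feats[u];
    }
  }
  return out;
}

// Discrete AdaBoost with depth-1 decision stumps.  ysign in {-1, +1}.
// A stump is h(x) = polarity * sign(x[feature] - threshold), sign(0) = -1.
// Ties in weighted error break toward the lowest feature index, then the
// lowest threshold position, then polarity +1, so training is deterministic.
// [[Rcpp::export]]
List cpp_adaboost(NumericMatrix X, IntegerVector ysign, int n_rounds) {
  int n = X.nrow(), p = X.ncol();
  // per-feature sort orders, computed once
  std::vector<std::vector<int> > ord(p);
  for (int f = 0; f < p; ++f) {
    ord[f].resize(n);
    for (int i = 0; i < n; ++i) ord[f][i] = i;
    const double *col = &X(0, f);
    std::stable_sort(ord[f].begin(), ord[f].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<double> w(n, 1.0 / n);
  std::vector<int> bf, bpol;
  std::vector<double> bthr, balpha;
  for (int round = 0; round < n_rounds; ++round) {
    double best_err = std::numeric_limits<double>::infinity();
    int best_f = -1, best_pol = 1;
    double best_thr = 0;
    for (int f = 0; f < p; ++f) {
      const double *col = &X(0, f);
      const std::vector<int> &o = ord[f];
      // err of (pol=+1, thr below all): every +1 correct, every -1 wrong
      double wneg = 0;
      for (int i = 0; i < n; ++i)
        if (ysign[i] < 0) wneg += w[i];
      // threshold after sorted position k (0..n): x <= thr -> -1 side
      double run = wneg;  // err for pol +1 with k = 0
      for (int k = 0; k <= n; ++k) {
        if (k > 0) {
          int i = o[k - 1];
          // moving sample i to the "-1" side of the stump
          run += (ysign[i] > 0) ? w[i] : -w[i];
        }
        // skip thresholds that fall between equal values
        if (k > 0 && k < n && col[o[k - 1]] == col[o[k]]) continue;
        double thr;
        if (k == 0)
          thr = col[o[0]] - 1.0;
        else if (k == n)
          thr = col[o[n - 1]] + 1.0;
        else
          thr = 0.5 * (col[o[k - 1]] + col[o[k]]);
        double e_pos = run, e_neg = 1.0 - run;
        if (e_pos < best_err - 1e-15) {
          best_err = e_pos; best_f = f; best_thr = thr; best_pol = 1;
        }
        if (e_neg < best_err - 1e-15) {
          best_err = e_neg; best_f = f; best_thr = thr; best_pol = -1;
        }
      }
    }
    if (best_f < 0) break;
    double err = std::min(std::max(best_err, 1e-12), 1.0 - 1e-12);
    if (err >= 0.5 - 1e-12 && round > 0) break;  // no usable weak learner left
    double alpha = 0.5 * std::log((1.0 - err) / err);
    bf.push_back(best_f + 1);
    bthr.push_back(best_thr);
    bpol.push_back(best_pol);
    balpha.push_back(alpha);
    // reweight and renormalize
    const double *col = &X(0, best_f);
    double wsum = 0;
    for (int i = 0; i < n; ++i) {
      int h = (col[i] > best_thr) ? best_pol : -best_pol;
      w[i] *= std::exp(-alpha * ysign[i] * h);
      wsum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;
    if (best_err <= 1e-12) break;  // perfect separation
  }
  return List::create(_["feature"] = wrap(bf), _["threshold"] = wrap(bthr),
                      _["polarity"] = wrap(bpol), _["alpha"] = wrap(balpha));
}

static void edt_1d(const double *f, double *d, int n, double step) {
  // Felzenszwalb-Huttenlocher lower envelope of parabolas, grid step in mm
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    if (f[v[k]] == std::numeric_limits<double>::infinity()) {
      v[k] = q;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == std::numeric_limits<double>::infinity()) {
      d[q] = std::numeric_limits<double>::infinity();
      continue;
    }
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance transform to the TRUE cells of `sites`,
// with anisotropic physical spacing (mm) per axis.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix sites, double spacing_row,
                         double spacing_col) {
  int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix D(nr, nc);
  const double INF = std::numeric_limits<double>::infinity();
  // pass 1: along rows (vertical), per column
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = sites(r, c) ? 0.0 : INF;
    edt_1d(f.data(), d.data(), nr, spacing_row);
    for (int r = 0; r < nr; ++r) D(r, c) = d[r];
  }
  // pass 2: along columns (horizontal), per row
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = D(r, c);
    edt_1d(f.data(), d.data(), nc, spacing_col);
    for (int c = 0; c < nc; ++c) D(r, c) = d[c];
  }
  return D;
}
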