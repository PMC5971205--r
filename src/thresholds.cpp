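#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Histogram thresholding kernels shared by the global (whole-frame) and the
// local (sliding-window) entry points, so both paths are the same algorithm.
//
// Both selectors return the index k of the last *background* bin, i.e. the
// optimal split is {0..k} vs {k+1..L-1}. Ties are broken toward the lower
// index. A return of -1 signals a degenerate histogram (< 2 occupied bins).

static int otsu_index(const std::vector<double>& h, const std::vector<double>& val) {
    const int L = (int)h.size();
    double total = 0.0, mu_total = 0.0;
    int occupied = 0;
    for (int g = 0; g < L; ++g) {
        total += h[g];
        mu_total += val[g] * h[g];
        if (h[g] > 0) ++occupied;
    }
    if (occupied < 2) return -1;

    double w0 = 0.0, sum0 = 0.0, best = -1.0;
    int best_k = -1;
    for (int k = 0; k < L - 1; ++k) {
        w0 += h[k];
        sum0 += val[k] * h[k];
        double w1 = total - w0;
        if (w0 <= 0.0 || w1 <= 0.0) continue;
        double mu0 = sum0 / w0;
        double mu1 = (mu_total - sum0) / w1;
        double d = mu0 - mu1;
        double between = w0 * w1 * d * d;  // unnormalized between-class variance
        if (between > best) {              // strict '>' keeps the lowest tied k
            best = between;
            best_k = k;
        }
    }
    return best_k;
}

// Shannon-entropy fuzzy measure (Huang & Wang 1995): membership of gray g to
// its class is u = 1 / (1 + |g - mu_class| / C) with C the gray-level range;
// the threshold minimizes sum_g h(g) * S(u(g)), S the binary Shannon entropy.
static inline double shannon(double u) {
    if (u <= 0.0 || u >= 1.0) return 0.0;
    return -u * std::log(u) - (1.0 - u) * std::log(1.0 - u);
}

static int huang_index(const std::vector<double>& h, const std::vector<double>& val) {
    const int L = (int)h.size();
    int first = -1, last = -1;
    for (int g = 0; g < L; ++g)
        if (h[g] > 0) { if (first < 0) first = g; last = g; }
    if (first < 0 || first == last) return -1;
    const double C = val[last] - val[first];

    std::vector<double> cw(L), cs(L);  // cumulative count and first moment
    double w = 0.0, s = 0.0;
    for (int g = 0; g < L; ++g) {
        w += h[g]; s += val[g] * h[g];
        cw[g] = w; cs[g] = s;
    }
    const double W = cw[L - 1], S = cs[L - 1];

    double best = R_PosInf;
    int best_k = -1;
    for (int k = first; k < last; ++k) {
        double w0 = cw[k], w1 = W - w0;
        if (w0 <= 0.0 || w1 <= 0.0) continue;
        double mu0 = cs[k] / w0;
        double mu1 = (S - cs[k]) / w1;
        double E = 0.0;
        for (int g = first; g <= last; ++g) {
            if (h[g] <= 0) continue;
            double mu = (g <= k) ? mu0 : mu1;
            double u = 1.0 / (1.0 + std::fabs(val[g] - mu) / C);
            E += h[g] * shannon(u);
        }
        if (E < best - 1e-12) {  // strict improvement keeps the lowest tied k
            best = E;
            best_k = k;
        }
    }
    return best_k;
}

// [[Rcpp::export]]
int cpp_hist_threshold(NumericVector hist, NumericVector values, std::string method) {
    std::vector<double> h(hist.begin(), hist.end());
    std::vector<double> val(values.begin(), values.end());
    if (method == "otsu") return otsu_index(h, val);
    if (method == "huang") return huang_index(h, val);
    stop("unknown threshold method '%s'", method.c_str());
}

// Per-pixel local threshold on a pre-binned image. `bins` holds 0-based bin
// indices (0..nbins-1). For every pixel the histogram of the window (clamped
// at the borders, so edge windows are truncated) is thresholded with the
// requested method; the pixel is foreground when its own bin exceeds the
// background split. Windows whose dynamic range (in fine bins) is below
// `min_range_bins` are treated as object-free and classed background (a
// histogram method always splits even a pure-noise window somewhere, so a
// minimum-contrast gate is required for fields that are not fully covered
// by objects); the caller derives the gate from the frame contrast and the
// noise scale. Degenerate windows (a single occupied bin) yield background.
// Huang windows are re-binned to `huang_bins` levels to keep the O(L^2)
// entropy scan tractable per pixel.
// [[Rcpp::export]]
LogicalMatrix cpp_local_threshold(IntegerMatrix bins, int nbins, int window,
                                  std::string method, double min_range_bins = 0.0,
                                  int huang_bins = 64) {
    const int nr = bins.nrow(), nc = bins.ncol();
    const int half = window / 2;
    const bool use_huang = (method == "huang");
    if (!use_huang && method != "otsu")
        stop("unknown threshold method '%s'", method.c_str());
    const int L = use_huang ? huang_bins : nbins;
    // integer shrink factor mapping fine bins onto the working histogram
    const int shrink = (nbins + L - 1) / L;
    const double min_range = min_range_bins;

    LogicalMatrix out(nr, nc);
    std::vector<double> h((size_t)L);
    // representative value of each working bin: its center on the fine scale
    std::vector<double> val((size_t)L);
    for (int b = 0; b < L; ++b) val[b] = b * shrink + 0.5 * (shrink - 1);

    for (int j = 0; j < nc; ++j) {
        const int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
        for (int i = 0; i < nr; ++i) {
            const int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
            std::fill(h.begin(), h.end(), 0.0);
            int bmin = nbins, bmax = 0;
            for (int cc = c0; cc <= c1; ++cc) {
                for (int rr = r0; rr <= r1; ++rr) {
                    const int b = bins(rr, cc);
                    h[(size_t)(b / shrink)] += 1.0;
                    if (b < bmin) bmin = b;
                    if (b > bmax) bmax = b;
                }
            }
            if (bmax - bmin < min_range) { out(i, j) = false; continue; }
            const int k = use_huang ? huang_index(h, val) : otsu_index(h, val);
            out(i, j) = (k >= 0) && (bins(i, j) / shrink > k);
        }
    }
    return out;
}

// 8-connected component labeling by breadth-first search.
// Labels are consecutive positive integers in scan order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    int next = 0;
    std::queue<std::pair<int, int> > q;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            lab(i, j) = ++next;
            q.push(std::make_pair(i, j));
            while (!q.empty()) {
                int ci = q.front().first, cj = q.front().second;
                q.pop();
                for (int dj = -1; dj <= 1; ++dj) {
                    for (int di = -1; di <= 1; ++di) {
                        int ni = ci + di, nj = cj + dj;
                        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
                        if (mask(ni, nj) && lab(ni, nj) == 0) {
                            lab(ni, nj) = next;
                            q.push(std::make_pair(ni, nj));
                        }
                    }
                }
            }
        }
    }
    return lab;
}
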