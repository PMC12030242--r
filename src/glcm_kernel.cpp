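#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Eight Haralick-style statistics of one normalized co-occurrence matrix,
// accumulated from a sparse list of touched cells. Gray levels are the
// integer values 0..G-1; MEA/VAR are taken over the i-marginal.
static void glcm_stats(const std::vector<int>& cells, const double* P, int G,
                       double* out) {
    double mea = 0.0, mu_i = 0.0, mu_j = 0.0;
    for (int idx : cells) {
        int i = idx / G, j = idx % G;
        double p = P[idx];
        mu_i += i * p;
        mu_j += j * p;
    }
    mea = mu_i;
    double var_i = 0.0, var_j = 0.0, var = 0.0;
    double hom = 0.0, con = 0.0, dis = 0.0, ent = 0.0, sem = 0.0, cov = 0.0;
    for (int idx : cells) {
        int i = idx / G, j = idx % G;
        double p = P[idx];
        double di = i - mu_i, dj = j - mu_j, dd = (double)(i - j);
        var   += (i - mea) * (i - mea) * p;
        var_i += di * di * p;
        var_j += dj * dj * p;
        cov   += di * dj * p;
        hom   += p / (1.0 + dd * dd);
        con   += dd * dd * p;
        dis   += std::fabs(dd) * p;
        if (p > 0.0) ent -= p * std::log(p);
        sem   += p * p;
    }
    double cor = 0.0;
    if (var_i > 1e-14 && var_j > 1e-14) cor = cov / std::sqrt(var_i * var_j);
    out[0] = mea; out[1] = var; out[2] = hom; out[3] = con;
    out[4] = dis; out[5] = ent; out[6] = sem; out[7] = cor;
}

// Sliding-window GLCM features for one quantized band.
//
// q        : integer matrix of gray levels in 0..G-1
// mask     : logical matrix; a window is evaluated when its center pixel is
//            masked and the full window fits inside the raster
// win      : odd window size
// dx, dy   : offset; pixel (r, c) is paired with (r + dy, c + dx)
// symmetric: also count the reversed pair
// per_pixel: return one row of 8 features per evaluated center
//            (plus center row/col, 0-based); otherwise the unweighted mean
//            over all evaluated windows and the window count.
// [[Rcpp::export]]
List cpp_window_texture(IntegerMatrix q, LogicalMatrix mask, int win,
                        int dx, int dy, int G, bool symmetric,
                        bool per_pixel) {
    int nr = q.nrow(), nc = q.ncol(), half = win / 2;
    if (nr < win || nc < win)
        stop("raster smaller than the texture window");
    std::vector<double> P((size_t)G * G, 0.0);
    std::vector<int> touched;
    touched.reserve(2 * win * win);

    std::vector<double> feat_rows;
    std::vector<int> centers_r, centers_c;
    double sums[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    double out[8];
    long n_windows = 0;

    for (int r = half; r < nr - half; ++r) {
        for (int c = half; c < nc - half; ++c) {
            if (!mask(r, c)) continue;
            touched.clear();
            int npairs = 0;
            int r0 = r - half, r1 = r + half, c0 = c - half, c1 = c + half;
            for (int wr = r0; wr <= r1; ++wr) {
                int pr = wr + dy;
                if (pr < r0 || pr > r1) continue;
                for (int wc = c0; wc <= c1; ++wc) {
                    int pc = wc + dx;
                    if (pc < c0 || pc > c1) continue;
                    int a = q(wr, wc), b = q(pr, pc);
                    int idx = a * G + b;
                    if (P[idx] == 0.0) touched.push_back(idx);
                    P[idx] += 1.0;
                    ++npairs;
                    if (symmetric) {
                        int idx2 = b * G + a;
                        if (P[idx2] == 0.0) touched.push_back(idx2);
                        P[idx2] += 1.0;
                        ++npairs;
                    }
                }
            }
            if (npairs == 0) continue;
            double w = 1.0 / npairs;
            for (int idx : touched) P[idx] *= w;
            glcm_stats(touched, P.data(), G, out);
            for (int idx : touched) P[idx] = 0.0;
            ++n_windows;
            if (per_pixel) {
                for (int k = 0; k < 8; ++k) feat_rows.push_back(out[k]);
                centers_r.push_back(r);
                centers_c.push_back(c);
            } else {
                for (int k = 0; k < 8; ++k) sums[k] += out[k];
            }
        }
    }

    if (per_pixel) {
        int n = (int)centers_r.size();
        NumericMatrix F(n, 8);
        IntegerVector rr(n), cc(n);
        for (int s = 0; s < n; ++s) {
            for (int k = 0; k < 8; ++k) F(s, k) = feat_rows[(size_t)s * 8 + k];
            rr[s] = centers_r[s];
            cc[s] = centers_c[s];
        }
        return List::create(_["features"] = F, _["row"] = rr, _["col"] = cc,
                            _["n_windows"] = n);
    }
    NumericVector m(8);
    if (n_windows > 0)
        for (int k = 0; k < 8; ++k) m[k] = sums[k] / n_windows;
    return List::create(_["mean"] = m, _["n_windows"] = (double)n_windows);
}

// Window means of a raw band at every full-window center (no masking);
// returned as an (nr - win + 1) x (nc - win + 1) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_window_mean(NumericMatrix x, int win) {
    int nr = x.nrow(), nc = x.ncol(), half = win / 2;
    if (nr < win || nc < win)
        stop("raster smaller than the window");
    int mr = nr - win + 1, mc = nc - win + 1;
    // column-wise running sums, then row-wise
    NumericMatrix colsum(mr, nc);
    for (int c = 0; c < nc; ++c) {
        double s = 0.0;
        for (int r = 0; r < win; ++r) s += x(r, c);
        colsum(0, c) = s;
        for (int r = 1; r < mr; ++r) {
            s += x(r + win - 1, c) - x(r - 1, c);
            colsum(r, c) = s;
        }
    }
    NumericMatrix out(mr, mc);
    double denom = (double)win * win;
    for (int r = 0; r < mr; ++r) {
        double s = 0.0;
        for (int c = 0; c < win; ++c) s += colsum(r, c);
        out(r, 0) = s / denom;
        for (int c = 1; c < mc; ++c) {
            s += colsum(r, c + win - 1) - colsum(r, c - 1);
            out(r, c) = s / denom;
        }
    }
    return out;
}
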