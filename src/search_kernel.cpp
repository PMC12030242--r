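#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Texture-index family codes (must match families() on the R side):
// arity 2: 1 RTI Ti/Tj, 2 DTI Ti-Tj, 3 ATI Ti+Tj,
//          4 NDTI (Ti-Tj)/(Ti+Tj), 5 RDTI 1/Ti-1/Tj, 6 RATI 1/Ti+1/Tj
// arity 3: 7 RTTI Ti/Tj/Tk, 8 DTTI Ti-Tj-Tk,
//          9 NDTTI (Ti-Tj-Tk)/(Ti+Tj+Tk),
//          10 RDTTI 1/Ti-1/Tj-1/Tk, 11 RATTI 1/Ti+1/Tj+1/Tk
static inline double ti_eval(int fam, double a, double b, double c) {
    switch (fam) {
    case 1:  return a / b;
    case 2:  return a - b;
    case 3:  return a + b;
    case 4:  return (a - b) / (a + b);
    case 5:  return 1.0 / a - 1.0 / b;
    case 6:  return 1.0 / a + 1.0 / b;
    case 7:  return a / b / c;
    case 8:  return a - b - c;
    case 9:  return (a - b - c) / (a + b + c);
    case 10: return 1.0 / a - 1.0 / b - 1.0 / c;
    case 11: return 1.0 / a + 1.0 / b + 1.0 / c;
    }
    return NA_REAL;
}

// Exhaustive correlation search of one texture-index family over all ordered
// feature tuples (repetition allowed). For each tuple the index is evaluated
// per sample; samples with non-finite values are dropped; tuples retaining
// fewer than min_used samples, or with zero variance in either variable, are
// invalid (NA in the tensor). Returns the |r| tensor and the arg-max tuple
// (ties resolved to the lexicographically first tuple by label order).
// [[Rcpp::export]]
List cpp_search_family(NumericMatrix F, NumericVector y, int fam, int arity,
                       int min_used) {
    int n = F.nrow(), K = F.ncol();
    if (y.size() != n) stop("feature table and target length differ");
    size_t ncells = 1;
    for (int a = 0; a < arity; ++a) ncells *= (size_t)K;
    NumericVector tensor(ncells, NA_REAL);

    double best_abs = -1.0;
    int bi = -1, bj = -1, bk = -1, best_n = 0;
    double best_r = NA_REAL;
    bool any_valid = false;
    std::vector<double> xi(n), xj(n), xk(n);

    int Kk = (arity == 3) ? K : 1;
    for (int i = 0; i < K; ++i) {
        for (int s = 0; s < n; ++s) xi[s] = F(s, i);
        for (int j = 0; j < K; ++j) {
            for (int s = 0; s < n; ++s) xj[s] = F(s, j);
            for (int k = 0; k < Kk; ++k) {
                if (arity == 3)
                    for (int s = 0; s < n; ++s) xk[s] = F(s, k);
                int m = 0;
                double sx = 0, sxx = 0, sy = 0, syy = 0, sxy = 0;
                for (int s = 0; s < n; ++s) {
                    double v = ti_eval(fam, xi[s], xj[s],
                                       arity == 3 ? xk[s] : 0.0);
                    if (!std::isfinite(v)) continue;
                    double t = y[s];
                    ++m;
                    sx += v; sxx += v * v;
                    sy += t; syy += t * t;
                    sxy += v * t;
                }
                // tensor layout matches an R array dim c(K,K[,K]):
                // linear index i + K*j (+ K*K*k), 0-based
                size_t cell = (size_t)i + (size_t)K * j +
                              (arity == 3 ? (size_t)K * K * k : 0);
                if (m < min_used) continue;
                double vx = m * sxx - sx * sx, vy = m * syy - sy * sy;
                if (vx <= 1e-12 * m * m || vy <= 1e-12 * m * m) continue;
                double r = (m * sxy - sx * sy) / std::sqrt(vx * vy);
                if (r > 1.0) r = 1.0;
                if (r < -1.0) r = -1.0;
                tensor[cell] = std::fabs(r);
                any_valid = true;
                if (std::fabs(r) > best_abs) {
                    best_abs = std::fabs(r);
                    best_r = r;
                    bi = i; bj = j; bk = (arity == 3) ? k : NA_INTEGER;
                    best_n = m;
                }
            }
        }
    }
    if (!any_valid)
        stop("search failed: no tuple produced a valid correlation");
    return List::create(_["tensor"] = tensor,
                        _["i"] = bi + 1, _["j"] = bj + 1,
                        _["k"] = (arity == 3) ? bk + 1 : NA_INTEGER,
                        _["r"] = best_r, _["n_used"] = best_n);
}
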