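#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Numerical slack for count-vs-requirement comparisons.  The same slack is
// used by the R reference (brute-force) implementation so both sides make
// identical inclusion decisions.
static const double EPS_SLACK = 1e-9;

namespace {

struct Grids {
    const double *grid;   // sorted unique labeled scores
    const double *labPre; // prefix sums of combined labeled weights, len U+1
    const double *pathPre;
    const double *benPre;
    int U;
    const double *unl;    // sorted unlabeled scores
    int M;
    double lo, hi;        // observed score range (labeled + unlabeled)

    // index range [l, r) of values x with |x - s| <= e.  Binary search gives
    // the approximate range; the ends are then adjusted with direct distance
    // comparisons so inclusion matches abs(x - s) <= e exactly (the window
    // half-widths are themselves such distances, and s - e recomputed in
    // floating point may fall on the wrong side of a defining point).
    static inline void distRange(const double *x, int n, double s, double e,
                                 int &l, int &r) {
        l = std::lower_bound(x, x + n, s - e) - x;
        while (l > 0 && s - x[l - 1] <= e) --l;
        while (l < n && s - x[l] > e) ++l;
        r = std::upper_bound(x, x + n, s + e) - x;
        while (r < n && x[r] - s <= e) ++r;
        while (r > l && x[r - 1] - s > e) --r;
    }
    // weighted labeled count in the closed window of half-width e around s
    inline double labCount(double s, double e) const {
        int l, r;
        distRange(grid, U, s, e, l, r);
        return (r > l) ? labPre[r] - labPre[l] : 0.0;
    }
    inline void classCounts(double s, double e, double &p, double &bn) const {
        int l, r;
        distRange(grid, U, s, e, l, r);
        if (r > l) { p = pathPre[r] - pathPre[l]; bn = benPre[r] - benPre[l]; }
        else { p = 0.0; bn = 0.0; }
    }
    inline double unlCount(double s, double e) const {
        int l, r;
        distRange(unl, M, s, e, l, r);
        return (double)(r - l);
    }
    // fraction of the window [s-eps, s+eps] lying inside the observed range
    inline double winFrac(double s, double eps) const {
        if (eps <= 0.0) return 1.0;
        double inside = std::min(s + eps, hi) - std::max(s - eps, lo);
        if (inside < 0.0) inside = 0.0;
        return inside / (2.0 * eps);
    }
    inline bool ok(double s, double eps, double minLab, double minUnl,
                   bool edgeScale) const {
        double f = edgeScale ? winFrac(s, eps) : 1.0;
        if (labCount(s, eps) + EPS_SLACK < minLab * f) return false;
        if (minUnl > 0.0 &&
            unlCount(s, eps) + EPS_SLACK < minUnl * f) return false;
        return true;
    }
    // smallest candidate half-width strictly greater than eps, one array
    static inline double nextIn(const double *x, int n, double s, double eps) {
        double best = R_PosInf;
        int l, r;
        distRange(x, n, s, eps, l, r);
        if (r < n) best = std::min(best, x[r] - s);
        if (l > 0) best = std::min(best, s - x[l - 1]);
        return best;
    }
    // largest candidate <= eps, one array (-1 when none)
    static inline double prevIn(const double *x, int n, double s, double eps) {
        double best = -1.0;
        int l, r;
        distRange(x, n, s, eps, l, r);
        if (r > l) {
            if (x[r - 1] > s) best = std::max(best, x[r - 1] - s);
            if (x[l] < s) best = std::max(best, s - x[l]);
            if (x[l] <= s && x[r - 1] >= s) best = std::max(best, 0.0);
        }
        return best;
    }
    // candidates are distances from s to observed labeled/unlabeled scores
    inline double nextCandidate(double s, double eps) const {
        return std::min(nextIn(grid, U, s, eps), nextIn(unl, M, s, eps));
    }
    inline double prevCandidate(double s, double eps) const {
        return std::max(prevIn(grid, U, s, eps), prevIn(unl, M, s, eps));
    }
};

// outward greedy expansion over labeled grid cells: minimal candidate
// half-width whose closed window holds >= minLab combined labeled weight
double epsLabeledAt(const Grids &G, int t, double minLab,
                    const double *cw /* combined weights */) {
    double s = G.grid[t];
    double acc = cw[t];
    double eps = 0.0;
    int a = t, b = t;
    while (acc + EPS_SLACK < minLab) {
        double dl = (a > 0) ? s - G.grid[a - 1] : R_PosInf;
        double dr = (b < G.U - 1) ? G.grid[b + 1] - s : R_PosInf;
        if (!R_FINITE(dl) && !R_FINITE(dr)) return R_PosInf; // infeasible
        if (dl <= dr) { --a; acc += cw[a]; eps = std::max(eps, dl); }
        else          { ++b; acc += cw[b]; eps = std::max(eps, dr); }
    }
    return eps;
}

// outward expansion over the unlabeled array for the fraction constraint
double epsUnlabeledAt(const Grids &G, double s, double minUnl) {
    if (minUnl <= 0.0) return 0.0;
    // start from points equal to s
    int a = std::lower_bound(G.unl, G.unl + G.M, s) - G.unl;
    int b = (std::upper_bound(G.unl, G.unl + G.M, s) - G.unl) - 1;
    double acc = (double)(b - a + 1);
    double eps = 0.0;
    while (acc + EPS_SLACK < minUnl) {
        double dl = (a > 0) ? s - G.unl[a - 1] : R_PosInf;
        double dr = (b < G.M - 1) ? G.unl[b + 1] - s : R_PosInf;
        if (!R_FINITE(dl) && !R_FINITE(dr)) return R_PosInf;
        if (dl <= dr) { --a; acc += 1.0; eps = std::max(eps, dl); }
        else          { ++b; acc += 1.0; eps = std::max(eps, dr); }
    }
    return eps;
}

// Edge-scaled half-width: bisect the monotone joint predicate on [0, hiEps],
// then snap to the candidate grid of observed distances.
double epsScaledAt(const Grids &G, double s, double hiEps, double minLab,
                   double minUnl) {
    if (G.ok(s, 0.0, minLab, minUnl, true)) return 0.0;
    double loE = 0.0, hiE = hiEps;
    for (int it = 0; it < 100; ++it) {
        double mid = 0.5 * (loE + hiE);
        if (mid <= loE || mid >= hiE) break;
        if (G.ok(s, mid, minLab, minUnl, true)) hiE = mid; else loE = mid;
    }
    // snap: locate the candidate nearest the bisected infimum, then walk to
    // the smallest candidate where the predicate actually holds
    double cand = G.prevCandidate(s, hiE);
    if (cand < 0.0) cand = 0.0;
    if (!G.ok(s, cand, minLab, minUnl, true)) {
        while (!G.ok(s, cand, minLab, minUnl, true)) {
            double nxt = G.nextCandidate(s, cand);
            if (!R_FINITE(nxt)) return R_PosInf;
            cand = nxt;
        }
    } else {
        // predicate holds at cand; walk down while it still holds
        while (cand > 0.0) {
            double prv = G.prevCandidate(s, std::nextafter(cand, 0.0));
            if (prv < 0.0 || prv >= cand) break;
            if (G.ok(s, prv, minLab, minUnl, true)) cand = prv; else break;
        }
    }
    return cand;
}

} // namespace

// Local posterior curve on the grid of unique labeled scores.
//
// grid:        sorted unique labeled scores (evaluation points)
// pathW, benW: per-grid-cell pathogenic / benign weights (resample counts)
// unlab:       sorted unlabeled scores
// epsUnl:      optional precomputed unlabeled-constraint half-widths
// minLab:      required combined labeled weight per window
// minUnl:      required unlabeled count per window
// w:           benign weight used in the posterior
// edgeScale:   proportionally scale requirements for range-truncated windows
// lo, hi:      observed score range
// [[Rcpp::export]]
List cpp_local_curve(NumericVector grid, NumericVector pathW,
                     NumericVector benW, NumericVector unlab,
                     NumericVector epsUnl, double minLab, double minUnl,
                     double w, bool edgeScale, double lo, double hi) {
    int U = grid.size(), M = unlab.size();
    if (U == 0) stop("empty score grid");
    std::vector<double> cw(U), labPre(U + 1, 0.0), pathPre(U + 1, 0.0),
        benPre(U + 1, 0.0);
    for (int i = 0; i < U; ++i) {
        cw[i] = pathW[i] + benW[i];
        labPre[i + 1] = labPre[i] + cw[i];
        pathPre[i + 1] = pathPre[i] + pathW[i];
        benPre[i + 1] = benPre[i] + benW[i];
    }
    Grids G{REAL(grid), labPre.data(), pathPre.data(), benPre.data(), U,
            REAL(unlab), M, lo, hi};

    bool haveEpsUnl = (epsUnl.size() == U);
    NumericVector eps(U), nP(U), nB(U), post(U);
    for (int t = 0; t < U; ++t) {
        double s = grid[t];
        double eL = epsLabeledAt(G, t, minLab, cw.data());
        double eU = haveEpsUnl ? epsUnl[t] : epsUnlabeledAt(G, s, minUnl);
        double e = std::max(eL, eU);
        if (!R_FINITE(e)) {
            if (!edgeScale)
                stop("window requirements unsatisfiable at score %g "
                     "(labeled >= %g, unlabeled >= %g)", s, minLab, minUnl);
            e = std::max(s - lo, hi - s); // full-range window candidate
            if (!G.ok(s, e, minLab, minUnl, true))
                stop("window requirements unsatisfiable at score %g even at "
                     "full range (labeled >= %g, unlabeled >= %g)",
                     s, minLab, minUnl);
        }
        if (edgeScale && (s - e < lo || s + e > hi)) {
            // truncated window: requirements shrink, so a smaller width
            // may already satisfy them
            e = epsScaledAt(G, s, e, minLab, minUnl);
        }
        double p, b;
        G.classCounts(s, e, p, b);
        eps[t] = e; nP[t] = p; nB[t] = b;
        double denom = p + w * b;
        post[t] = (denom > 0.0) ? p / denom : NA_REAL;
    }
    return List::create(_["epsilon"] = eps, _["n_pathogenic"] = nP,
                        _["n_benign"] = nB, _["posterior"] = post);
}

// Precompute the unlabeled-constraint half-widths for a fixed unlabeled set
// (they do not change across bootstrap replicates).
// [[Rcpp::export]]
NumericVector cpp_unlab_eps(NumericVector grid, NumericVector unlab,
                            double minUnl) {
    int U = grid.size(), M = unlab.size();
    Grids G{REAL(grid), NULL, NULL, NULL, U, REAL(unlab), M, 0.0, 0.0};
    NumericVector out(U);
    for (int t = 0; t < U; ++t)
        out[t] = epsUnlabeledAt(G, grid[t], minUnl);
    return out;
}

// Column-wise type-7 quantiles of a replicate-by-score matrix.
// [[Rcpp::export]]
NumericMatrix cpp_col_quantiles(NumericMatrix m, NumericVector probs) {
    int n = m.nrow(), p = m.ncol(), q = probs.size();
    NumericMatrix out(q, p);
    if (n == 0) stop("empty matrix");
    std::vector<double> col(n);
    for (int j = 0; j < p; ++j) {
        for (int i = 0; i < n; ++i) col[i] = m(i, j);
        for (int k = 0; k < q; ++k) {
            double h = (n - 1) * probs[k];
            int ilo = (int)std::floor(h);
            double frac = h - ilo;
            std::nth_element(col.begin(), col.begin() + ilo, col.end());
            double vlo = col[ilo];
            double vhi = vlo;
            if (frac > 0.0 && ilo + 1 < n) {
                vhi = *std::min_element(col.begin() + ilo + 1, col.end());
            }
            out(k, j) = vlo + frac * (vhi - vlo);
        }
    }
    return out;
}

// Nearest-neighbour removal distances: for each query in order, remove the
// closest remaining unlabeled value and record its distance.
// [[Rcpp::export]]
NumericVector cpp_distcurve(NumericVector queries, NumericVector unlabeled) {
    int n = queries.size();
    std::multiset<double> pool(unlabeled.begin(), unlabeled.end());
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        if (pool.empty()) stop("unlabeled set exhausted after %d removals", i);
        double q = queries[i];
        std::multiset<double>::iterator hi = pool.lower_bound(q);
        std::multiset<double>::iterator best;
        if (hi == pool.end()) best = std::prev(hi);
        else if (hi == pool.begin()) best = hi;
        else {
            std::multiset<double>::iterator lo = std::prev(hi);
            best = (q - *lo <= *hi - q) ? lo : hi;
        }
        out[i] = std::fabs(*best - q);
        pool.erase(best);
    }
    return out;
}
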