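#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact proximal operator of lam * TV(x) = lam * sum_t |x[t] - x[t-1]|,
// i.e. 1-D total-variation denoising of y. Single forward sweep that keeps
// the running dual variable inside [-lam, lam] and emits a constant segment
// whenever a jump becomes unavoidable (Condat-style direct algorithm).
static void tv_denoise_1d(const double *y, double *x, int n, double lam) {
    if (n <= 0) return;
    if (lam <= 0.0 || n == 1) {
        for (int i = 0; i < n; ++i) x[i] = y[i];
        return;
    }
    int k = 0, seg_start = 0;        // current position / start of open segment
    int last_lo = 0, last_hi = 0;    // last positions where the dual touched +lam / -lam
    double u_lo = lam, u_hi = -lam;  // dual sums for the lower / upper envelope
    double v_lo = y[0] - lam, v_hi = y[0] + lam;  // candidate segment values
    const double two_lam = 2.0 * lam;
    for (;;) {
        while (k == n - 1) {  // right boundary: flush what remains
            if (u_lo < 0.0) {        // lower candidate too high: negative jump
                do { x[seg_start++] = v_lo; } while (seg_start <= last_lo);
                k = seg_start; last_lo = k;
                v_lo = y[k];
                u_lo = lam;
                u_hi = v_lo + u_lo - v_hi;
            } else if (u_hi > 0.0) { // upper candidate too low: positive jump
                do { x[seg_start++] = v_hi; } while (seg_start <= last_hi);
                k = seg_start; last_hi = k;
                v_hi = y[k];
                u_hi = -lam;
                u_lo = v_hi + u_hi - v_lo;
            } else {
                v_lo += u_lo / (k - seg_start + 1);
                do { x[seg_start++] = v_lo; } while (seg_start <= k);
                return;
            }
            if (seg_start >= n) return;
        }
        u_lo += y[k + 1] - v_lo;
        if (u_lo < -lam) {           // negative jump at last_lo
            do { x[seg_start++] = v_lo; } while (seg_start <= last_lo);
            k = seg_start; last_lo = k; last_hi = k;
            v_lo = y[k]; v_hi = v_lo + two_lam;
            u_lo = lam; u_hi = -lam;
            continue;
        }
        u_hi += y[k + 1] - v_hi;
        if (u_hi > lam) {            // positive jump at last_hi
            do { x[seg_start++] = v_hi; } while (seg_start <= last_hi);
            k = seg_start; last_lo = k; last_hi = k;
            v_hi = y[k]; v_lo = v_hi - two_lam;
            u_lo = lam; u_hi = -lam;
            continue;
        }
        ++k;
        if (u_lo >= lam) {           // lower envelope touches the bound
            last_lo = k;
            v_lo += (u_lo - lam) / (k - seg_start + 1);
            u_lo = lam;
        }
        if (u_hi <= -lam) {          // upper envelope touches the bound
            last_hi = k;
            v_hi += (u_hi + lam) / (k - seg_start + 1);
            u_hi = -lam;
        }
    }
}

// [[Rcpp::export(name = ".tv_prox_cpp")]]
NumericVector tv_prox_cpp(NumericVector y, double lam) {
    int n = y.size();
    NumericVector out(n);
    tv_denoise_1d(y.begin(), out.begin(), n, lam);
    return out;
}

// causal convolution of s with kernel h, truncated to length T
static void conv_fwd(const double *s, const double *h, double *out, int T, int L) {
    for (int t = 0; t < T; ++t) {
        double acc = 0.0;
        int kmax = t < L - 1 ? t : L - 1;
        for (int k = 0; k <= kmax; ++k) acc += h[k] * s[t - k];
        out[t] = acc;
    }
}

// adjoint: correlation of r with h
static void conv_adj(const double *r, const double *h, double *out, int T, int L) {
    for (int t = 0; t < T; ++t) {
        double acc = 0.0;
        int kmax = L - 1 < T - 1 - t ? L - 1 : T - 1 - t;
        for (int k = 0; k <= kmax; ++k) acc += h[k] * r[t + k];
        out[t] = acc;
    }
}

static double objective(const std::vector<double> &res, const double *s,
                        int T, double lam) {
    double f = 0.0;
    for (int t = 0; t < T; ++t) f += res[t] * res[t];
    f *= 0.5;
    for (int t = 1; t < T; ++t) f += lam * std::fabs(s[t] - s[t - 1]);
    return f;
}

// FISTA for 0.5*||y - H s||^2 + lam*TV(s); monotone variant: an accelerated
// step that would raise the objective is replaced by a plain proximal
// gradient step from the previous iterate (which cannot increase it) and the
// momentum is restarted.
// [[Rcpp::export(name = ".fista_tv_cpp")]]
List fista_tv_cpp(NumericVector y, NumericVector h, double lam,
                  int max_iter, double tol) {
    int T = y.size(), L = h.size();
    double l1 = 0.0;
    for (int k = 0; k < L; ++k) l1 += std::fabs(h[k]);
    double Lip = l1 * l1;  // ||H||_2^2 <= ||h||_1^2 for causal convolution
    if (Lip <= 0.0) Lip = 1.0;
    double step = 1.0 / Lip;

    std::vector<double> x(T, 0.0), x_prev(T, 0.0), z(T, 0.0);
    std::vector<double> hz(T), res(T), grad(T), cand(T), tmp(T);
    std::vector<double> trace;
    trace.reserve(max_iter + 1);

    conv_fwd(x.data(), h.begin(), hz.data(), T, L);
    for (int t = 0; t < T; ++t) res[t] = hz[t] - y[t];
    double obj = objective(res, x.data(), T, lam);
    trace.push_back(obj);

    double tk = 1.0;
    for (int t = 0; t < T; ++t) z[t] = x[t];
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
        // gradient step at the extrapolated point z
        conv_fwd(z.data(), h.begin(), hz.data(), T, L);
        for (int t = 0; t < T; ++t) res[t] = hz[t] - y[t];
        conv_adj(res.data(), h.begin(), grad.data(), T, L);
        for (int t = 0; t < T; ++t) tmp[t] = z[t] - step * grad[t];
        tv_denoise_1d(tmp.data(), cand.data(), T, lam * step);

        conv_fwd(cand.data(), h.begin(), hz.data(), T, L);
        for (int t = 0; t < T; ++t) res[t] = hz[t] - y[t];
        double obj_cand = objective(res, cand.data(), T, lam);

        if (obj_cand > obj) {
            // fall back to an ISTA step from the last accepted iterate
            conv_fwd(x.data(), h.begin(), hz.data(), T, L);
            for (int t = 0; t < T; ++t) res[t] = hz[t] - y[t];
            conv_adj(res.data(), h.begin(), grad.data(), T, L);
            for (int t = 0; t < T; ++t) tmp[t] = x[t] - step * grad[t];
            tv_denoise_1d(tmp.data(), cand.data(), T, lam * step);
            conv_fwd(cand.data(), h.begin(), hz.data(), T, L);
            for (int t = 0; t < T; ++t) res[t] = hz[t] - y[t];
            obj_cand = objective(res, cand.data(), T, lam);
            if (obj_cand > obj) {  // numerically converged; keep x
                trace.push_back(obj);
                break;
            }
            tk = 1.0;
            for (int t = 0; t < T; ++t) { x_prev[t] = x[t]; x[t] = cand[t]; z[t] = x[t]; }
        } else {
            double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
            double mom = (tk - 1.0) / tk1;
            for (int t = 0; t < T; ++t) {
                double xn = cand[t];
                z[t] = xn + mom * (xn - x[t]);
                x_prev[t] = x[t];
                x[t] = xn;
            }
            tk = tk1;
        }
        trace.push_back(obj_cand);
        double rel = std::fabs(obj - obj_cand) / std::max(1.0, std::fabs(obj));
        obj = obj_cand;
        if (rel < tol) { ++it; break; }
    }

    NumericVector activity(x.begin(), x.end());
    NumericVector tr(trace.begin(), trace.end());
    return List::create(_["activity"] = activity,
                        _["objective_trace"] = tr,
                        _["iterations"] = it,
                        _["objective"] = obj);
}

// Column-wise FISTA over a T x V matrix with per-column lambda.
// [[Rcpp::export(name = ".fista_tv_mat_cpp")]]
List fista_tv_mat_cpp(NumericMatrix Y, NumericVector h, NumericVector lam,
                      int max_iter, double tol) {
    int T = Y.nrow(), V = Y.ncol();
    NumericMatrix activity(T, V);
    IntegerVector iters(V);
    NumericVector final_obj(V);
    double worst_increase = 0.0;
    for (int v = 0; v < V; ++v) {
        NumericVector yv = Y(_, v);
        List fit = fista_tv_cpp(yv, h, lam[v], max_iter, tol);
        NumericVector a = fit["activity"];
        for (int t = 0; t < T; ++t) activity(t, v) = a[t];
        iters[v] = fit["iterations"];
        final_obj[v] = fit["objective"];
        NumericVector tr = fit["objective_trace"];
        for (int i = 1; i < tr.size(); ++i) {
            double inc = tr[i] - tr[i - 1];
            if (inc > worst_increase) worst_increase = inc;
        }
    }
    return List::create(_["activity"] = activity,
                        _["iterations"] = iters,
                        _["objective"] = final_obj,
                        _["max_objective_increase"] = worst_increase);
}
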