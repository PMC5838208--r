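#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Full EM loop for a univariate Gaussian mixture.
//
// Responsibilities are computed in log space (log-sum-exp) so that samples in
// the far tails of every component do not underflow to 0/0. The M-step
// sufficient statistics (sum r, sum r*x, sum r*x^2) are accumulated inside
// the E-step pass, so each iteration is a single sweep over the data.
//
// Convergence: relative change of the log-likelihood below `tol`. sigma is
// clamped at sigma_floor; a component whose mixing weight drops below w_floor
// flags `collapsed` and returns early (the R wrapper restarts from a jittered
// initialization).
// `temper` is the deterministic-annealing inverse temperature: E-step
// responsibilities are proportional to (w_k phi_k)^temper, which smooths the
// likelihood surface for temper < 1 (Ueda-Nakano DAEM); temper = 1 is plain
// EM. The recorded log-likelihood is always the untempered one.
// [[Rcpp::export]]
List em_gauss1d_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                    NumericVector w0, double tol, int max_iter,
                    double sigma_floor, double w_floor, double temper = 1.0) {
    const int n = x.size();
    const int K = mu0.size();
    const double LOG2PI = std::log(2.0 * M_PI);

    std::vector<double> mu(mu0.begin(), mu0.end());
    std::vector<double> sg(sigma0.begin(), sigma0.end());
    std::vector<double> w(w0.begin(), w0.end());

    std::vector<double> lognorm(K), inv2s2(K), logd(K);
    std::vector<double> Nk(K), sumx(K), sumxx(K);
    std::vector<double> ll_trace;
    ll_trace.reserve(128);

    bool converged = false;
    bool collapsed = false;
    double ll_prev = R_NegInf;
    int iters = 0;

    auto loglik_only = [&]() {
        for (int k = 0; k < K; ++k) {
            lognorm[k] = std::log(w[k]) - std::log(sg[k]) - 0.5 * LOG2PI;
            inv2s2[k] = 0.5 / (sg[k] * sg[k]);
        }
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
            double mx = R_NegInf;
            for (int k = 0; k < K; ++k) {
                double d = x[i] - mu[k];
                logd[k] = lognorm[k] - d * d * inv2s2[k];
                if (logd[k] > mx) mx = logd[k];
            }
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += std::exp(logd[k] - mx);
            ll += mx + std::log(s);
        }
        return ll;
    };

    for (int it = 0; it < max_iter; ++it) {
        for (int k = 0; k < K; ++k) {
            lognorm[k] = std::log(w[k]) - std::log(sg[k]) - 0.5 * LOG2PI;
            inv2s2[k] = 0.5 / (sg[k] * sg[k]);
            Nk[k] = 0.0; sumx[k] = 0.0; sumxx[k] = 0.0;
        }
        // E-step + log-likelihood of the current parameters, with fused
        // accumulation of the M-step sufficient statistics
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
            double mx = R_NegInf;
            for (int k = 0; k < K; ++k) {
                double d = x[i] - mu[k];
                logd[k] = lognorm[k] - d * d * inv2s2[k];
                if (logd[k] > mx) mx = logd[k];
            }
            double s = 0.0;
            for (int k = 0; k < K; ++k) {
                double e = std::exp(logd[k] - mx);
                s += e;
                logd[k] = (temper == 1.0) ? e
                    : std::exp(temper * (logd[k] - mx));
            }
            ll += mx + std::log(s);
            double st = 0.0;
            for (int k = 0; k < K; ++k) st += logd[k];
            const double inv_s = 1.0 / st;
            const double xi = x[i];
            for (int k = 0; k < K; ++k) {
                double r = logd[k] * inv_s;
                Nk[k] += r;
                sumx[k] += r * xi;
                sumxx[k] += r * xi * xi;
            }
        }
        ll_trace.push_back(ll);
        iters = it + 1;

        if (it > 0 && std::fabs(ll - ll_prev) <
                          tol * (std::fabs(ll_prev) + tol)) {
            converged = true;
            break;  // parameters already consistent with the recorded ll
        }
        ll_prev = ll;

        // M-step
        for (int k = 0; k < K; ++k) {
            if (Nk[k] / n < w_floor) { collapsed = true; break; }
            double m = sumx[k] / Nk[k];
            double s2 = sumxx[k] / Nk[k] - m * m;
            if (s2 < 0) s2 = 0;
            mu[k] = m;
            sg[k] = std::max(std::sqrt(s2), sigma_floor);
            w[k] = Nk[k] / n;
        }
        if (collapsed) break;
    }

    // If the loop ended on max_iter the last M-step updated the parameters
    // after the last recorded ll; append the ll of the returned parameters.
    if (!converged && !collapsed) ll_trace.push_back(loglik_only());

    return List::create(
        _["mu"] = NumericVector(mu.begin(), mu.end()),
        _["sigma"] = NumericVector(sg.begin(), sg.end()),
        _["w"] = NumericVector(w.begin(), w.end()),
        _["loglik"] = ll_trace.back(),
        _["trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
        _["iterations"] = iters,
        _["converged"] = converged,
        _["collapsed"] = collapsed);
}
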