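#include <Rcpp.h>
using namespace Rcpp;

// Density of the first-passage time of a drifted Brownian motion (diffusion
// coefficient 1) through the LOWER of two absorbing boundaries {0, a}, start
// point w*a, drift v, evaluated at decision time t (non-decision time already
// subtracted).  Dual series representation with automatic small-time /
// large-time switching; `eps` is the truncation error of the standardized
// density.

static double f_std(double tt, double w, double eps) {
    // standardized density f(tt | v=0, a=1, w) at normalized time tt = t/a^2
    double kl, ks;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    double p = 0.0;
    if (ks < kl) {
        int K = (int)std::ceil(ks);
        int lo = (int)-std::floor((K - 1) / 2.0);
        int hi = (int)std::ceil((K - 1) / 2.0);
        for (int k = lo; k <= hi; ++k) {
            double wk = w + 2.0 * k;
            p += wk * std::exp(-wk * wk / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    return p;
}

static double wiener_lpdf_one(double rt, int upper, double v, double a,
                              double t0, double zr, double eps) {
    double t = rt - t0;
    if (t <= 0.0) return R_NegInf;
    double vv = v, w = zr;
    if (upper) {          // upper-boundary density by reflection
        vv = -v;
        w = 1.0 - zr;
    }
    double tt = t / (a * a);
    double p = f_std(tt, w, eps);
    if (p <= 0.0) return R_NegInf;
    return std::log(p) - std::log(a * a) - vv * a * w - vv * vv * t / 2.0;
}

// [[Rcpp::export]]
NumericVector wiener_lpdf_cpp(NumericVector rt, IntegerVector upper, double v,
                              double a, double t0, double zr, double eps) {
    int n = rt.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = wiener_lpdf_one(rt[i], upper[i], v, a, t0, zr, eps);
    return out;
}

// [[Rcpp::export]]
double wiener_negll_cpp(NumericVector rt, IntegerVector upper, double v,
                        double a, double t0, double zr, double eps) {
    int n = rt.size();
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
        double l = wiener_lpdf_one(rt[i], upper[i], v, a, t0, zr, eps);
        if (!R_FINITE(l)) return R_PosInf;
        s -= l;
    }
    return s;
}

// Euler-Maruyama walk between absorbing boundaries.  Uses R's RNG so that
// set.seed() governs reproducibility.  choice: 1 = upper boundary, 0 = lower.
// A discrete-time walk only observes the process at step ends, so it misses
// excursions across a boundary inside a step; the Broadie-Glasserman-Kou
// continuity correction compensates by pulling both absorbing boundaries
// inward by beta * sigma * sqrt(dt), beta = -zeta(1/2)/sqrt(2*pi), and the
// crossing is attributed to the middle of its step.
// [[Rcpp::export]]
List ddm_simulate_cpp(int n, double v, double a, double t0, double zr,
                      double dt, int max_steps, bool correct) {
    IntegerVector choice(n);
    NumericVector rt(n);
    double sdt = std::sqrt(dt);
    double shift = correct ? 0.5826 * sdt : 0.0;
    double hi = a - shift, lo = shift;
    double toff = correct ? 0.5 * dt : 0.0;
    if (hi <= lo) { hi = a; lo = 0.0; shift = 0.0; toff = 0.0; }
    for (int i = 0; i < n; ++i) {
        double x = zr * a;
        int step = 0;
        while (step < max_steps) {
            x += v * dt + sdt * norm_rand();
            ++step;
            if (x >= hi) { choice[i] = 1; break; }
            if (x <= lo) { choice[i] = 0; break; }
        }
        if (step >= max_steps && x < hi && x > lo) {
            choice[i] = (x >= a / 2.0) ? 1 : 0;
        }
        rt[i] = step * dt - toff + t0;
    }
    return List::create(_["choice"] = choice, _["rt"] = rt);
}

// Single evidence path, returned at dt resolution including the crossing
// step; used by the synthetic trajectory generator.
// [[Rcpp::export]]
List ddm_path_cpp(double v, double a, double zr, double dt, int max_steps) {
    std::vector<double> path;
    path.reserve(1024);
    double x = zr * a;
    path.push_back(x);
    double sdt = std::sqrt(dt);
    int choice = -1;
    int step = 0;
    while (step < max_steps) {
        x += v * dt + sdt * norm_rand();
        ++step;
        if (x >= a) { x = a; choice = 1; }
        else if (x <= 0.0) { x = 0.0; choice = 0; }
        path.push_back(x);
        if (choice >= 0) break;
    }
    if (choice < 0) choice = (x >= a / 2.0) ? 1 : 0;
    return List::create(_["path"] = NumericVector(path.begin(), path.end()),
                        _["choice"] = choice,
                        _["decision_time"] = step * dt);
}

// Template-match counts for sample entropy: B = matches of length m,
// A = matches of length m+1, Chebyshev distance <= r, self-matches excluded.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
    int n = x.size();
    long long A = 0, B = 0;
    int nm = n - m;          // number of m-length templates
    for (int i = 0; i < nm; ++i) {
        for (int j = i + 1; j < nm; ++j) {
            double d = 0.0;
            for (int k = 0; k < m; ++k) {
                double dd = std::fabs(x[i + k] - x[j + k]);
                if (dd > d) d = dd;
            }
            if (d <= r) {
                ++B;
                if (i + m < n && j + m < n) {
                    double dd = std::fabs(x[i + m] - x[j + m]);
                    if (std::max(d, dd) <= r) ++A;
                }
            }
        }
    }
    return List::create(_["A"] = (double)A, _["B"] = (double)B);
}
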