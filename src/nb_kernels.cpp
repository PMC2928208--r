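#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Negative binomial parametrized by mean l*mu and dispersion phi:
//   var = l*mu * (1 + l*mu*phi); phi == 0 is the Poisson limit.
// All kernels work in log space; Eq-3 style Monte-Carlo averages over the
// empirical prior use streaming log-sum-exp.

static inline double xlogy(double x, double y) {
    return x > 0.0 ? x * std::log(y) : 0.0;
}

static inline double nb_logpmf1(double u, double l, double mu, double phi) {
    double lm = l * mu;
    if (phi <= 0.0) {
        // Poisson limit
        return -lm + xlogy(u, lm) - std::lgamma(u + 1.0);
    }
    double r = 1.0 / phi;
    // small integer u: incremental product form avoids cancellation in the
    // lgamma difference when r is huge (near-Poisson dispersions)
    double lgratio;
    if (u <= 64.0) {
        lgratio = 0.0;
        for (int k = 0; k < (int)u; ++k) lgratio += std::log(r + (double)k);
    } else {
        lgratio = std::lgamma(u + r) - std::lgamma(r);
    }
    return lgratio - std::lgamma(u + 1.0)
         - r * std::log1p(lm / r) + xlogy(u, lm / (r + lm));
}

// [[Rcpp::export]]
NumericVector cpp_nb_log_pmf(NumericVector u, NumericVector l,
                             NumericVector mu, NumericVector phi) {
    R_xlen_t n = u.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = nb_logpmf1(u[i], l[i], mu[i], phi[i]);
    return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo marginal log-likelihood for one model:
//   log P(D_c|M) = sum_q log [ (1/|Theta_q|) sum_s prod_{i in E_q} P(u_ic) ]
// counts: tuples x samples; sets: list of 1-based sample index vectors;
// mu, phi: S x m matrices of empirical prior draws (columns = model sets).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_marginal_loglik(IntegerMatrix counts, NumericVector libsizes,
                                  List sets, NumericMatrix mu,
                                  NumericMatrix phi) {
    const int T = counts.nrow();
    const int S = mu.nrow();
    const int m = sets.size();
    if (S < 1) stop("empty prior sample (|Theta_q| must be >= 1)");
    if (phi.nrow() != S || mu.ncol() != m || phi.ncol() != m)
        stop("prior dimensions do not match the model");
    const int UMAX = 256;

    // per-set sample indices (0-based)
    std::vector<std::vector<int>> idx(m);
    for (int q = 0; q < m; ++q) {
        IntegerVector v = sets[q];
        idx[q].resize(v.size());
        for (int k = 0; k < v.size(); ++k) idx[q][k] = v[k] - 1;
    }

    // lgamma(u + r_s) - lgamma(r_s) tables laid out [u][s] so the inner
    // loop over prior draws is contiguous; shared across sets when the
    // dispersion columns coincide (the default joint construction)
    bool shared_phi = true;
    for (int q = 1; q < m && shared_phi; ++q)
        for (int s = 0; s < S; ++s)
            if (phi(s, q) != phi(s, 0)) { shared_phi = false; break; }
    int nq_tab = shared_phi ? 1 : m;
    std::vector<std::vector<double>> tab(nq_tab);   // [u * S + s]
    std::vector<std::vector<double>> rr(nq_tab), lgr(nq_tab);
    for (int q = 0; q < nq_tab; ++q) {
        tab[q].assign((size_t)UMAX * S, 0.0);
        rr[q].resize(S); lgr[q].resize(S);
        for (int s = 0; s < S; ++s) {
            double ph = phi(s, q);
            if (ph <= 0.0) { rr[q][s] = -1.0; lgr[q][s] = 0.0; continue; }
            double r = 1.0 / ph;
            rr[q][s] = r;
            lgr[q][s] = std::lgamma(r);
            double acc = 0.0;
            for (int u = 1; u < UMAX; ++u) {
                acc += std::log(r + (double)(u - 1));
                tab[q][(size_t)u * S + s] = acc;
            }
        }
    }

    // per (set, sample-in-set): c0[s] and clog[s], contiguous in s
    std::vector<std::vector<std::vector<double>>> c0(m), clog(m);
    for (int q = 0; q < m; ++q) {
        int ni = (int)idx[q].size();
        c0[q].assign(ni, std::vector<double>(S));
        clog[q].assign(ni, std::vector<double>(S));
        for (int k = 0; k < ni; ++k) {
            double li = libsizes[idx[q][k]];
            for (int s = 0; s < S; ++s) {
                double ph = phi(s, q), lm = li * mu(s, q);
                if (ph <= 0.0) {
                    c0[q][k][s] = -lm;
                    clog[q][k][s] = std::log(lm);
                } else {
                    double r = 1.0 / ph;
                    c0[q][k][s] = -r * std::log1p(lm / r);
                    clog[q][k][s] = std::log(lm / (r + lm));
                }
            }
        }
    }

    NumericVector out(T);
    std::vector<double> w(S);
    const double logS = std::log((double)S);
    for (int t = 0; t < T; ++t) {
        double total = 0.0;
        for (int q = 0; q < m; ++q) {
            int ni = (int)idx[q].size();
            int tq = shared_phi ? 0 : q;
            std::fill(w.begin(), w.end(), 0.0);
            double base = 0.0;  // -sum_i lgamma(u+1), constant over s
            for (int k = 0; k < ni; ++k) {
                int u = counts(t, idx[q][k]);
                base -= std::lgamma((double)u + 1.0);
                const double *pc0 = c0[q][k].data();
                const double *pcl = clog[q][k].data();
                double du = (double)u;
                if (u < UMAX) {
                    const double *pt = &tab[tq][(size_t)u * S];
                    for (int s = 0; s < S; ++s)
                        w[s] += pt[s] + pc0[s] + du * pcl[s];
                } else {
                    const double *pr = rr[tq].data();
                    const double *pl = lgr[tq].data();
                    for (int s = 0; s < S; ++s) {
                        double lgterm = pr[s] < 0.0 ? 0.0
                            : std::lgamma(du + pr[s]) - pl[s];
                        w[s] += lgterm + pc0[s] + du * pcl[s];
                    }
                }
            }
            double mx = w[0];
            for (int s = 1; s < S; ++s) if (w[s] > mx) mx = w[s];
            double sume = 0.0;
            if (std::isfinite(mx)) {
                for (int s = 0; s < S; ++s) {
                    double d = w[s] - mx;
                    if (d > -745.0) sume += std::exp(d);
                }
                total += mx + std::log(sume) - logS + base;
            } else {
                total += -std::numeric_limits<double>::infinity();
            }
        }
        out[t] = total;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Quasi-likelihood dispersion estimation (per tuple)
// ---------------------------------------------------------------------------

// NB deviance-style statistic at dispersion phi with fixed group means
static double ql_deviance(const std::vector<int> &u, const std::vector<double> &l,
                          const std::vector<int> &grp,
                          const std::vector<double> &mug, double phi) {
    double dev = 0.0;
    size_t n = u.size();
    if (phi <= 0.0) {  // Poisson limit
        for (size_t i = 0; i < n; ++i) {
            double fit = l[i] * mug[grp[i]];
            dev += xlogy((double)u[i], (double)u[i] / fit) - ((double)u[i] - fit);
        }
        return 2.0 * dev;
    }
    double r = 1.0 / phi;
    for (size_t i = 0; i < n; ++i) {
        double fit = l[i] * mug[grp[i]];
        double ui = (double)u[i];
        dev += xlogy(ui, ui / fit) - (ui + r) * std::log((ui + r) / (fit + r));
    }
    return 2.0 * dev;
}

// [[Rcpp::export]]
double cpp_ql_deviance(IntegerVector u, NumericVector l, IntegerVector group,
                       NumericVector mu_groups, double phi) {
    size_t n = u.size();
    std::vector<int> uu(n), gg(n);
    std::vector<double> ll(n);
    for (size_t i = 0; i < n; ++i) { uu[i] = u[i]; ll[i] = l[i]; gg[i] = group[i] - 1; }
    std::vector<double> mg(mu_groups.begin(), mu_groups.end());
    return ql_deviance(uu, ll, gg, mg, phi);
}

// ML estimate of a common mean (per unit library size) for counts u with
// library sizes l at fixed dispersion phi; root of the score equation.
static double nb_mean_mle(const std::vector<int> &u, const std::vector<double> &l,
                          double phi) {
    size_t n = u.size();
    double su = 0.0, sl = 0.0, mx = 0.0;
    for (size_t i = 0; i < n; ++i) {
        su += u[i]; sl += l[i];
        double ratio = (double)u[i] / l[i];
        if (ratio > mx) mx = ratio;
    }
    if (su <= 0.0) return 0.0;
    if (phi <= 0.0) return su / sl;  // Poisson MLE
    double r = 1.0 / phi;
    // score * mu:  h(mu) = sum_i [ u_i - (u_i + r) * l_i * mu / (r + l_i * mu) ]
    auto h = [&](double m) {
        double s = 0.0;
        for (size_t i = 0; i < n; ++i)
            s += (double)u[i] - ((double)u[i] + r) * l[i] * m / (r + l[i] * m);
        return s;
    };
    double hi = mx > 0.0 ? mx : 1.0;
    int guard = 0;
    while (h(hi) > 0.0 && guard++ < 200) hi *= 2.0;
    double lo = 0.0;
    for (int it = 0; it < 200; ++it) {
        double mid = 0.5 * (lo + hi);
        if (h(mid) > 0.0) lo = mid; else hi = mid;
        if (hi - lo < 1e-12 * hi) break;
    }
    return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_nb_mean_mle(IntegerVector u, NumericVector l, double phi) {
    std::vector<int> uu(u.begin(), u.end());
    std::vector<double> ll(l.begin(), l.end());
    return nb_mean_mle(uu, ll, phi);
}

struct DispFit {
    double phi;
    std::vector<double> mug;
    int iterations;
    bool converged;
    int reason;  // 0 = root found, 1 = clamped at phi_min, 2 = clamped at
                 // phi_max, 3 = max iterations
};

// Alternate (a) 1-D root of the quasi-likelihood equation (deviance = n - 1)
// in phi at fixed group means and (b) NB ML refit of the group means at
// fixed phi, until phi stabilises.
static DispFit fit_dispersion(const std::vector<int> &u,
                              const std::vector<double> &l,
                              const std::vector<int> &grp, int ngroups,
                              double phi_min, double phi_max, double tol,
                              int max_iter) {
    size_t n = u.size();
    DispFit fit;
    fit.mug.assign(ngroups, 0.0);
    std::vector<int> gn(ngroups, 0);
    bool allzero = true;
    for (size_t i = 0; i < n; ++i) {
        fit.mug[grp[i]] += (double)u[i] / l[i];
        gn[grp[i]] += 1;
        if (u[i] > 0) allzero = false;
    }
    for (int g = 0; g < ngroups; ++g)
        fit.mug[g] = gn[g] > 0 ? fit.mug[g] / gn[g] : 0.0;
    if (allzero) {
        fit.phi = phi_min; fit.iterations = 0; fit.converged = true; fit.reason = 1;
        return fit;
    }
    double target = (double)n - 1.0;
    double phi = phi_min;
    fit.reason = 3;
    bool conv = false;
    int it = 0;
    for (; it < max_iter; ++it) {
        // (a) solve deviance(phi) = target; deviance is non-increasing in phi
        double dlo = ql_deviance(u, l, grp, fit.mug, phi_min);
        double nphi;
        int reason;
        if (dlo <= target) {
            nphi = phi_min; reason = 1;
        } else if (ql_deviance(u, l, grp, fit.mug, phi_max) >= target) {
            nphi = phi_max; reason = 2;
        } else {
            double a = phi_min, b = phi_max;
            for (int k = 0; k < 200; ++k) {
                double mid = std::sqrt(a * b);  // log-scale bisection
                if (ql_deviance(u, l, grp, fit.mug, mid) > target) a = mid;
                else b = mid;
                if (b - a < 1e-10 * b) break;
            }
            nphi = std::sqrt(a * b); reason = 0;
        }
        // (b) ML group means at fixed phi
        for (int g = 0; g < ngroups; ++g) {
            std::vector<int> ug; std::vector<double> lg;
            for (size_t i = 0; i < n; ++i)
                if (grp[i] == g) { ug.push_back(u[i]); lg.push_back(l[i]); }
            fit.mug[g] = nb_mean_mle(ug, lg, nphi);
        }
        double delta = std::fabs(nphi - phi) / std::max(phi, 1e-6);
        phi = nphi; fit.reason = reason;
        if (it > 0 && delta < tol) { conv = true; ++it; break; }
    }
    fit.phi = phi;
    fit.iterations = it;
    fit.converged = conv;
    return fit;
}

// [[Rcpp::export]]
List cpp_fit_dispersion(IntegerVector u, NumericVector l, IntegerVector group,
                        int ngroups, double phi_min, double phi_max,
                        double tol, int max_iter) {
    size_t n = u.size();
    std::vector<int> uu(n), gg(n);
    std::vector<double> ll(n);
    for (size_t i = 0; i < n; ++i) { uu[i] = u[i]; ll[i] = l[i]; gg[i] = group[i] - 1; }
    DispFit f = fit_dispersion(uu, ll, gg, ngroups, phi_min, phi_max, tol, max_iter);
    CharacterVector reasons = CharacterVector::create(
        "root", "deviance below target at phi_min", "clamped at phi_max",
        "max iterations");
    return List::create(_["phi"] = f.phi,
                        _["mu"] = NumericVector(f.mug.begin(), f.mug.end()),
                        _["iterations"] = f.iterations,
                        _["converged"] = f.converged,
                        _["reason"] = as<std::string>(reasons[f.reason]));
}

// ---------------------------------------------------------------------------
// Empirical prior construction: for each sampled tuple, fit the dispersion
// under the replicate structure (once, shared across models by default; or
// per model set when per_set is TRUE), then ML per-set means for every set
// of every model.
// tuple_idx, group, and set indices are 1-based.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_priors(IntegerMatrix counts, NumericVector libsizes,
                      IntegerVector group, int ngroups, List models,
                      IntegerVector tuple_idx, double phi_min, double phi_max,
                      double tol, int max_iter, double mu_floor,
                      bool per_set) {
    const int S = tuple_idx.size();
    const int n = counts.ncol();
    const int nmod = models.size();
    std::vector<std::vector<std::vector<int>>> msets(nmod);
    for (int j = 0; j < nmod; ++j) {
        List sets = models[j];
        msets[j].resize(sets.size());
        for (int q = 0; q < sets.size(); ++q) {
            IntegerVector v = sets[q];
            msets[j][q].resize(v.size());
            for (int k = 0; k < v.size(); ++k) msets[j][q][k] = v[k] - 1;
        }
    }
    List mu_out(nmod), phi_out(nmod);
    std::vector<NumericMatrix> mus, phis;
    for (int j = 0; j < nmod; ++j) {
        mus.push_back(NumericMatrix(S, (int)msets[j].size()));
        phis.push_back(NumericMatrix(S, (int)msets[j].size()));
    }
    NumericVector phi_shared(S);
    IntegerVector disp_iters(S);

    std::vector<int> uu(n), gg(n);
    std::vector<double> ll(n);
    for (int i = 0; i < n; ++i) { ll[i] = libsizes[i]; gg[i] = group[i] - 1; }

    for (int s = 0; s < S; ++s) {
        int t = tuple_idx[s] - 1;
        for (int i = 0; i < n; ++i) uu[i] = counts(t, i);
        DispFit f = fit_dispersion(uu, ll, gg, ngroups, phi_min, phi_max,
                                   tol, max_iter);
        phi_shared[s] = f.phi;
        disp_iters[s] = f.iterations;
        for (int j = 0; j < nmod; ++j) {
            for (size_t q = 0; q < msets[j].size(); ++q) {
                const std::vector<int> &set = msets[j][q];
                double phq = f.phi;
                if (per_set) {
                    // restrict counts and replicate structure to this set
                    std::vector<int> us, gs, gmap(ngroups, -1);
                    std::vector<double> ls;
                    int ng = 0;
                    for (size_t k = 0; k < set.size(); ++k) {
                        int i = set[k];
                        if (gmap[gg[i]] < 0) gmap[gg[i]] = ng++;
                        us.push_back(uu[i]); ls.push_back(ll[i]);
                        gs.push_back(gmap[gg[i]]);
                    }
                    DispFit fq = fit_dispersion(us, ls, gs, ng, phi_min,
                                                phi_max, tol, max_iter);
                    phq = fq.phi;
                }
                std::vector<int> us; std::vector<double> ls;
                for (size_t k = 0; k < set.size(); ++k) {
                    us.push_back(uu[set[k]]); ls.push_back(ll[set[k]]);
                }
                double m = nb_mean_mle(us, ls, phq);
                mus[j](s, (int)q) = m > mu_floor ? m : mu_floor;
                phis[j](s, (int)q) = phq;
            }
        }
    }
    for (int j = 0; j < nmod; ++j) { mu_out[j] = mus[j]; phi_out[j] = phis[j]; }
    return List::create(_["mu"] = mu_out, _["phi"] = phi_out,
                        _["phi_shared"] = phi_shared,
                        _["iterations"] = disp_iters);
}
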