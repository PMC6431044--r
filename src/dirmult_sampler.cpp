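#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared Polya-urn growth: one iteration grows a count vector one
// molecule at a time, drawing gene g with probability proportional to
// alpha_g + y_g.  The marginal distribution of the counts at any running
// total t is Dirichlet-multinomial(t, alpha_g), so the running
// log-likelihood recorded at each requested total is distributed as the
// log-likelihood of a DM draw of that size.  A single uniform deviate per
// molecule both picks the base-vs-reinforcement branch and the gene.
//
// The log-likelihood splits into a size term depending only on the
// running total,
//   log t! + log G(alpha) - log G(t + alpha),
// evaluated directly at the requested totals (the same expression used
// for observed likelihoods), plus a per-gene part accumulated along the
// path as the product of (y + alpha_g) / (y + 1) factors.  The product is
// flushed into log space only when it nears the double range, so the hot
// loop performs one multiplication, not one log, per molecule.

namespace {

struct UrnSpec {
    std::vector<double> ag;     // alpha_g
    std::vector<double> thresh; // Walker alias acceptance thresholds
    std::vector<int> alias;     // Walker alias table
    double alpha;
    double inv_alpha_n;         // N / alpha, maps u in [0, alpha) to cells

    explicit UrnSpec(const NumericVector& alpha_g) {
        const int N = alpha_g.size();
        ag.resize(N);
        double acc = 0.0;
        for (int g = 0; g < N; ++g) {
            if (alpha_g[g] <= 0) stop("alpha_g must be strictly positive");
            acc += alpha_g[g];
            ag[g] = alpha_g[g];
        }
        alpha = acc;
        inv_alpha_n = N / alpha;

        // Walker alias construction: O(1) base-distribution draws.
        thresh.assign(N, 1.0);
        alias.assign(N, 0);
        std::vector<double> scaled(N);
        std::vector<int> small, large;
        for (int g = 0; g < N; ++g) {
            scaled[g] = ag[g] * inv_alpha_n;
            (scaled[g] < 1.0 ? small : large).push_back(g);
        }
        while (!small.empty() && !large.empty()) {
            int s = small.back();
            small.pop_back();
            int l = large.back();
            thresh[s] = scaled[s];
            alias[s] = l;
            scaled[l] -= 1.0 - scaled[s];
            if (scaled[l] < 1.0) {
                large.pop_back();
                small.push_back(l);
            }
        }
    }

    // A single uniform deviate u in [0, alpha + t - 1) drives the urn
    // step at running total t: u < alpha draws from the base measure
    // (alias table), otherwise a previously drawn molecule is copied.
    int draw_gene(double u, int t, const std::vector<int>& hist) const {
        if (u < alpha) {
            double x = u * inv_alpha_n;
            int cell = static_cast<int>(x);
            if (cell >= static_cast<int>(ag.size())) cell = ag.size() - 1;
            return (x - cell < thresh[cell]) ? cell : alias[cell];
        }
        int idx = static_cast<int>(u - alpha);
        if (idx > t - 2) idx = t - 2;
        return hist[idx];
    }

    std::vector<double> size_terms(const IntegerVector& utotals) const {
        std::vector<double> out(utotals.size());
        const double lga = std::lgamma(alpha);
        for (int j = 0; j < utotals.size(); ++j) {
            const double t = utotals[j];
            out[j] = std::lgamma(t + 1.0) + lga - std::lgamma(t + alpha);
        }
        return out;
    }
};

class RunningLoglik {
    double ll_ = 0.0;
    double prod_ = 1.0;

public:
    void reset() {
        ll_ = 0.0;
        prod_ = 1.0;
    }
    void add_factor(double num, double den) {
        prod_ *= num / den;
        if (prod_ < 1e-100 || prod_ > 1e100) {
            ll_ += std::log(prod_);
            prod_ = 1.0;
        }
    }
    double value() const { return ll_ + std::log(prod_); }
};

}  // namespace

// Draw R urn paths; at each requested total (ascending, unique) record
// the log-likelihood and tally it against the sorted observed
// log-likelihoods for barcodes sharing that total.  Returns, per total,
// the per-barcode count of iterations with simulated logL <= observed
// (ties counted, with a small tolerance because the simulated gene term
// is accumulated incrementally while the observed one is computed
// directly).
// [[Rcpp::export]]
List cpp_urn_tally(IntegerVector utotals, List obs_sorted,
                   NumericVector alpha_g, int n_iters) {
    const int n_tot = utotals.size();
    if (n_tot == 0) stop("no totals requested");
    const int t_max = utotals[n_tot - 1];
    UrnSpec spec(alpha_g);
    const std::vector<double> size_term = spec.size_terms(utotals);
    const int N = alpha_g.size();

    std::vector<std::vector<int>> tally(n_tot);
    std::vector<NumericVector> obs(n_tot);
    for (int j = 0; j < n_tot; ++j) {
        obs[j] = as<NumericVector>(obs_sorted[j]);
        tally[j].assign(obs[j].size(), 0);
    }

    std::vector<double> cnt(N);
    std::vector<int> hist(t_max);
    RunningLoglik rl;

    for (int iter = 0; iter < n_iters; ++iter) {
        std::fill(cnt.begin(), cnt.end(), 0.0);
        rl.reset();
        int next = 0;
        for (int t = 1; t <= t_max; ++t) {
            double u = unif_rand() * (spec.alpha + t - 1);
            int g = spec.draw_gene(u, t, hist);
            double y = cnt[g];
            rl.add_factor(y + spec.ag[g], y + 1.0);
            cnt[g] = y + 1.0;
            hist[t - 1] = g;
            if (t == utotals[next]) {
                double ll = size_term[next] + rl.value();
                const NumericVector& v = obs[next];
                double eps = 1e-6 + 1e-9 * std::fabs(ll);
                int lo = std::lower_bound(v.begin(), v.end(), ll - eps) -
                         v.begin();
                if (lo < v.size()) ++tally[next][lo];
                ++next;
                if (next == n_tot) break;
            }
        }
        if (iter % 256 == 0) checkUserInterrupt();
    }

    List out(n_tot);
    for (int j = 0; j < n_tot; ++j) {
        IntegerVector rb(obs[j].size());
        int acc = 0;
        for (int k = 0; k < rb.size(); ++k) {
            acc += tally[j][k];
            rb[k] = acc;
        }
        out[j] = rb;
    }
    return out;
}

// Same urn growth, but returning the sampled log-likelihoods themselves
// (one row per requested total, one column per iteration); used for
// distributional verification against the naive sampler.
// [[Rcpp::export]]
NumericMatrix cpp_urn_sample(IntegerVector utotals, NumericVector alpha_g,
                             int n_iters) {
    const int n_tot = utotals.size();
    if (n_tot == 0) stop("no totals requested");
    const int t_max = utotals[n_tot - 1];
    UrnSpec spec(alpha_g);
    const std::vector<double> size_term = spec.size_terms(utotals);
    const int N = alpha_g.size();

    NumericMatrix out(n_tot, n_iters);
    std::vector<double> cnt(N);
    std::vector<int> hist(t_max);
    RunningLoglik rl;

    for (int iter = 0; iter < n_iters; ++iter) {
        std::fill(cnt.begin(), cnt.end(), 0.0);
        rl.reset();
        int next = 0;
        for (int t = 1; t <= t_max; ++t) {
            double u = unif_rand() * (spec.alpha + t - 1);
            int g = spec.draw_gene(u, t, hist);
            double y = cnt[g];
            rl.add_factor(y + spec.ag[g], y + 1.0);
            cnt[g] = y + 1.0;
            hist[t - 1] = g;
            if (t == utotals[next]) {
                out(next, iter) = size_term[next] + rl.value();
                ++next;
                if (next == n_tot) break;
            }
        }
        if (iter % 256 == 0) checkUserInterrupt();
    }
    return out;
}

// Independent Dirichlet-multinomial count draws, one urn per barcode.
// Returns the gene index (1-based) of every sampled molecule,
// concatenated across barcodes in order; pairing with
// rep(seq_along(totals), totals) yields sparse triplets.
// [[Rcpp::export]]
IntegerVector cpp_rdirmult_genes(IntegerVector totals, NumericVector alpha_g) {
    R_xlen_t n_mol = 0;
    int t_max = 0;
    for (int b = 0; b < totals.size(); ++b) {
        if (totals[b] < 0) stop("totals must be non-negative");
        n_mol += totals[b];
        if (totals[b] > t_max) t_max = totals[b];
    }
    UrnSpec spec(alpha_g);

    IntegerVector out(n_mol);
    std::vector<int> hist(std::max(t_max, 1));
    R_xlen_t pos = 0;
    for (int b = 0; b < totals.size(); ++b) {
        const int tb = totals[b];
        for (int t = 1; t <= tb; ++t) {
            double u = unif_rand() * (spec.alpha + t - 1);
            int g = spec.draw_gene(u, t, hist);
            hist[t - 1] = g;
            out[pos++] = g + 1;
        }
        if (b % 256 == 0) checkUserInterrupt();
    }
    return out;
}

// Multivariate hypergeometric downsampling of each column of a sparse
// matrix to round(fraction * column total) molecules, via sequential
// univariate hypergeometric draws over the column's nonzero entries.
// [[Rcpp::export]]
NumericVector cpp_downsample_columns(NumericVector x, IntegerVector p,
                                     double fraction) {
    NumericVector newx(x.size());
    const int ncol = p.size() - 1;
    for (int j = 0; j < ncol; ++j) {
        double total = 0.0;
        for (int k = p[j]; k < p[j + 1]; ++k) total += x[k];
        double ndraw = R::fround(fraction * total, 0);
        double left = total;
        for (int k = p[j]; k < p[j + 1]; ++k) {
            if (ndraw <= 0) break;
            double take;
            if (left - x[k] <= 0) {
                take = ndraw;
            } else {
                take = R::rhyper(x[k], left - x[k], ndraw);
            }
            newx[k] = take;
            ndraw -= take;
            left -= x[k];
        }
    }
    return newx;
}
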