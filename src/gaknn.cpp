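#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Leave-one-out kNN fitness kernel and the GA search loop live here: a
// single pool collection evaluates on the order of 1e6 chromosomes, far
// beyond what an interpreted inner loop sustains. All randomness is drawn
// from R's RNG stream so set.seed() governs the search end to end.

namespace {

// Gather the chromosome's feature block into a contiguous samples x d
// scratch array (P[s*d + j]) so the distance loop streams memory.
inline void gather(const double* X, int nGenes, int nSamples,
                   const int* genes, int d, double* P) {
    for (int s = 0; s < nSamples; ++s) {
        const double* col = X + (std::size_t)s * nGenes;
        double* row = P + (std::size_t)s * d;
        for (int j = 0; j < d; ++j) row[j] = col[genes[j]];
    }
}

// Leave-one-out kNN correct-classification count for one chromosome.
// Labels are 0/1, k odd. Ties at the k-th neighbour are broken by stable
// (distance, sample index) order: candidates are scanned in index order
// and displace an incumbent only on a strictly smaller distance.
// Returns -1 as soon as the error count exceeds max_errors (lets the GA
// discard a mutant that cannot match its parent without finishing the
// evaluation); pass max_errors >= nSamples for an exact count.
int loo_correct_count(const double* P, int d, int nSamples,
                      const int* labels, int k, int max_errors,
                      double* drow, double* kd, int* kl) {
    int errors = 0;
    for (int i = 0; i < nSamples; ++i) {
        const double* pi = P + (std::size_t)i * d;
        for (int j = 0; j < nSamples; ++j) {
            const double* pj = P + (std::size_t)j * d;
            double s = 0.0;
            for (int t = 0; t < d; ++t) {
                double diff = pi[t] - pj[t];
                s += diff * diff;
            }
            drow[j] = s;
        }
        int filled = 0;
        for (int j = 0; j < nSamples; ++j) {
            if (j == i) continue;
            double v = drow[j];
            if (filled < k) {
                int pos = filled++;
                while (pos > 0 && kd[pos - 1] > v) {
                    kd[pos] = kd[pos - 1]; kl[pos] = kl[pos - 1]; --pos;
                }
                kd[pos] = v; kl[pos] = labels[j];
            } else if (v < kd[k - 1]) {
                int pos = k - 1;
                while (pos > 0 && kd[pos - 1] > v) {
                    kd[pos] = kd[pos - 1]; kl[pos] = kl[pos - 1]; --pos;
                }
                kd[pos] = v; kl[pos] = labels[j];
            }
        }
        int votes = 0;
        for (int j = 0; j < k; ++j) votes += kl[j];
        int pred = (2 * votes > k) ? 1 : 0;
        if (pred != labels[i] && ++errors > max_errors) return -1;
    }
    return nSamples - errors;
}

struct Workspace {
    std::vector<double> P, drow, kd;
    std::vector<int> kl;
    void init(int nSamples, int d, int k) {
        P.resize((std::size_t)nSamples * d);
        drow.resize(nSamples);
        kd.resize(k);
        kl.resize(k);
    }
};

inline int sample_int(int n) {  // uniform on 0..n-1 via R's RNG
    int v = (int)(unif_rand() * n);
    return v >= n ? n - 1 : v;
}

inline bool contains(const int* genes, int d, int g) {
    for (int j = 0; j < d; ++j) if (genes[j] == g) return true;
    return false;
}

inline int draw_replacement(const int* pool, int nPool, const int* genes, int d) {
    for (;;) {
        int g = pool[sample_int(nPool)];
        if (!contains(genes, d, g)) return g;
    }
}

void random_chromosome(const int* pool, int nPool, int* genes, int d) {
    int filled = 0;
    while (filled < d) {
        int g = pool[sample_int(nPool)];
        if (!contains(genes, filled, g)) genes[filled++] = g;
    }
    std::sort(genes, genes + d);
}

// Mutate `parent` into `child`: each position replaced with probability
// `rate` by a uniformly drawn pool gene not already present; if no
// position mutates, one random position is forced to change.
void mutate(const int* parent, int* child, int d, const int* pool, int nPool,
            double rate) {
    std::copy(parent, parent + d, child);
    bool any = false;
    for (int j = 0; j < d; ++j) {
        if (unif_rand() < rate) {
            child[j] = draw_replacement(pool, nPool, child, d);
            any = true;
        }
    }
    if (!any) {
        int j = sample_int(d);
        child[j] = draw_replacement(pool, nPool, child, d);
    }
    std::sort(child, child + d);
}

struct SearchResult {
    std::vector<int> genes;
    double fitness;
    bool success;
    long cycles;
    long evals;
};

// One GA search: hill-climbing population; returns the first chromosome
// whose leave-one-out fitness reaches `cutoff`, or failure after
// `max_cycles` mutation cycles.
SearchResult ga_search(const double* X, int nGenes, int nSamples,
                       const int* labels, const int* pool, int nPool,
                       int d, int k, double cutoff, int pop_size,
                       long max_cycles, double rate, Workspace& ws) {
    SearchResult res;
    res.genes.resize(d);
    res.fitness = -1.0;
    res.success = false;
    res.cycles = 0;
    res.evals = 0;

    std::vector<int> popGenes((std::size_t)pop_size * d);
    std::vector<int> popCorrect(pop_size);
    std::vector<int> child(d);
    const int need = (int)std::ceil(cutoff * nSamples - 1e-9);

    for (int m = 0; m < pop_size; ++m) {
        int* g = popGenes.data() + (std::size_t)m * d;
        random_chromosome(pool, nPool, g, d);
        gather(X, nGenes, nSamples, g, d, ws.P.data());
        popCorrect[m] = loo_correct_count(ws.P.data(), d, nSamples, labels, k,
                                          nSamples, ws.drow.data(),
                                          ws.kd.data(), ws.kl.data());
        ++res.evals;
        if (popCorrect[m] >= need) {
            std::copy(g, g + d, res.genes.begin());
            res.fitness = (double)popCorrect[m] / nSamples;
            res.success = true;
            return res;
        }
    }
    for (long cyc = 0; cyc < max_cycles; ++cyc) {
        res.cycles = cyc + 1;
        for (int m = 0; m < pop_size; ++m) {
            int* g = popGenes.data() + (std::size_t)m * d;
            mutate(g, child.data(), d, pool, nPool, rate);
            gather(X, nGenes, nSamples, child.data(), d, ws.P.data());
            // A mutant survives only with at least the parent's correct
            // count, so evaluation may stop once that is impossible.
            int max_err = nSamples - popCorrect[m];
            int cc = loo_correct_count(ws.P.data(), d, nSamples, labels, k,
                                       max_err, ws.drow.data(), ws.kd.data(),
                                       ws.kl.data());
            ++res.evals;
            if (cc >= popCorrect[m]) {  // hill climbing: keep the better
                std::copy(child.begin(), child.end(), g);
                popCorrect[m] = cc;
            }
            if (popCorrect[m] >= need) {
                std::copy(g, g + d, res.genes.begin());
                res.fitness = (double)popCorrect[m] / nSamples;
                res.success = true;
                return res;
            }
        }
    }
    return res;
}

void check_inputs(const NumericMatrix& X, const IntegerVector& labels, int k) {
    if (labels.size() != X.ncol())
        stop("labels length must equal the number of samples");
    if (k < 1 || k % 2 == 0) stop("k must be odd and >= 1");
    if (X.ncol() < k + 1) stop("need at least k + 1 samples");
    for (int i = 0; i < labels.size(); ++i)
        if (labels[i] != 0 && labels[i] != 1) stop("labels must be 0/1");
}

}  // namespace

// [[Rcpp::export(name = ".loo_fitness_batch")]]
NumericVector loo_fitness_batch(NumericMatrix X, IntegerMatrix chromosomes,
                                IntegerVector labels, int k) {
    check_inputs(X, labels, k);
    int d = chromosomes.nrow(), m = chromosomes.ncol();
    int nGenes = X.nrow(), nSamples = X.ncol();
    Workspace ws;
    ws.init(nSamples, d, k);
    std::vector<int> genes(d);
    NumericVector out(m);
    for (int c = 0; c < m; ++c) {
        for (int j = 0; j < d; ++j) {
            int g = chromosomes(j, c) - 1;  // 1-based from R
            if (g < 0 || g >= nGenes) stop("gene index out of range");
            genes[j] = g;
        }
        gather(REAL(X), nGenes, nSamples, genes.data(), d, ws.P.data());
        int cc = loo_correct_count(ws.P.data(), d, nSamples, labels.begin(),
                                   k, nSamples, ws.drow.data(), ws.kd.data(),
                                   ws.kl.data());
        out[c] = (double)cc / nSamples;
    }
    return out;
}

// [[Rcpp::export(name = ".ga_search_cpp")]]
List ga_search_cpp(NumericMatrix X, IntegerVector labels, IntegerVector pool,
                   int d, int k, double cutoff, int pop_size,
                   double max_cycles, double mutation_rate) {
    check_inputs(X, labels, k);
    std::vector<int> pool0(pool.size());
    for (int i = 0; i < pool.size(); ++i) pool0[i] = pool[i] - 1;
    Workspace ws;
    ws.init(X.ncol(), d, k);
    SearchResult r = ga_search(REAL(X), X.nrow(), X.ncol(), labels.begin(),
                               pool0.data(), (int)pool0.size(), d, k, cutoff,
                               pop_size, (long)max_cycles, mutation_rate, ws);
    IntegerVector genes(d);
    for (int j = 0; j < d; ++j) genes[j] = r.genes[j] + 1;
    return List::create(_["success"] = r.success, _["genes"] = genes,
                        _["fitness"] = r.fitness, _["cycles"] = (double)r.cycles,
                        _["evals"] = (double)r.evals);
}

// [[Rcpp::export(name = ".ga_collect_pool_cpp")]]
List ga_collect_pool_cpp(NumericMatrix X, IntegerVector labels,
                         IntegerVector pool, int d, int k, double cutoff,
                         int n_solutions, int pop_size, double max_cycles,
                         double mutation_rate, double min_success_rate,
                         int rate_check_after) {
    check_inputs(X, labels, k);
    std::vector<int> pool0(pool.size());
    for (int i = 0; i < pool.size(); ++i) pool0[i] = pool[i] - 1;
    Workspace ws;
    ws.init(X.ncol(), d, k);

    IntegerMatrix chroms(d, n_solutions);
    NumericVector fitness(n_solutions);
    long searches = 0, exhausted = 0;
    double evals = 0;
    int got = 0;
    while (got < n_solutions) {
        SearchResult r = ga_search(REAL(X), X.nrow(), X.ncol(), labels.begin(),
                                   pool0.data(), (int)pool0.size(), d, k,
                                   cutoff, pop_size, (long)max_cycles,
                                   mutation_rate, ws);
        ++searches;
        evals += (double)r.evals;
        if (r.success) {
            for (int j = 0; j < d; ++j) chroms(j, got) = r.genes[j] + 1;
            fitness[got] = r.fitness;
            ++got;
        } else {
            ++exhausted;
        }
        if (searches >= rate_check_after &&
            (double)got / (double)searches < min_success_rate) {
            stop("GA success rate %.4f after %ld searches is below the floor "
                 "%.4f; consider lowering the fitness cutoff",
                 (double)got / (double)searches, searches, min_success_rate);
        }
        if (searches % 64 == 0) checkUserInterrupt();
    }
    return List::create(_["chromosomes"] = chroms, _["fitness"] = fitness,
                        _["n_searches"] = (double)searches,
                        _["n_exhausted"] = (double)exhausted,
                        _["n_evals"] = evals);
}
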