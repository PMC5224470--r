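#include <Rcpp.h>
using namespace Rcpp;

// Emit a nucleotide sequence (0=A,1=C,2=G,3=T) from a mixture of two Markov
// chains of the same order r. At each position the next base is drawn from the
// host chain's transition row with probability alpha, otherwise from the alien
// chain's row. alpha = 1 collapses to a single-chain emitter. Transition rows
// are passed as cumulative probabilities (4^r x 4, row-major contexts in
// lexicographic order). Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerVector emit_mixture_chain(NumericMatrix cum_host, NumericMatrix cum_alien,
                                 double alpha, int length, int order,
                                 int init_context) {
    const int ncxt = cum_host.nrow();
    if (cum_alien.nrow() != ncxt)
        stop("host and alien models must have the same order");
    IntegerVector out(length);
    int ctx = init_context; // 0-based index into context rows
    const int ctx_mod = (order > 0) ? ncxt / 4 : 1;

    int pos = 0;
    // seed the first min(order, length) bases from the initial context digits
    if (order > 0) {
        for (int i = 0; i < order && i < length; ++i) {
            int shift = 1;
            for (int j = 0; j < order - 1 - i; ++j) shift *= 4;
            out[i] = (ctx / shift) % 4;
        }
        pos = order < length ? order : length;
    }
    for (; pos < length; ++pos) {
        const NumericMatrix &cum = (alpha >= 1.0 || unif_rand() < alpha)
            ? cum_host : cum_alien;
        double u = unif_rand();
        int b = 0;
        while (b < 3 && u > cum(ctx, b)) ++b;
        out[pos] = b;
        ctx = (order > 0) ? (ctx % ctx_mod) * 4 + b : 0;
    }
    return out;
}
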