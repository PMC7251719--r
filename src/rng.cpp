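#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finalizer: bijective 64-bit mixer with good avalanche.
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

//' Counter-based uniform random numbers keyed by (seed, id, stream, counter)
//'
//' Generates U(0,1) variates from a stateless counter-based generator
//' (chained splitmix64 mixing). The draw for a given key is independent of
//' call order and batch size, which is what makes per-woman common random
//' numbers and the parallel-universe contract reproducible.
//'
//' @param seed master seed (non-negative, below 2^31)
//' @param id per-unit identifier vector (e.g. woman id)
//' @param stream small integer separating draw purposes
//' @param counter draw index vector within (id, stream)
//' @return numeric vector of uniforms, length max(length(id), length(counter))
//' @keywords internal
// [[Rcpp::export]]
NumericVector stream_unif_cpp(double seed, NumericVector id, int stream,
                              NumericVector counter) {
  R_xlen_t ni = id.size(), nc = counter.size();
  R_xlen_t n = ni > nc ? ni : nc;
  if (ni == 0 || nc == 0) return NumericVector(0);
  NumericVector out(n);
  uint64_t base = sm64(static_cast<uint64_t>(seed) ^ 0x8A5CD789635D2DFFULL);
  uint64_t smix = sm64(base ^ (static_cast<uint64_t>(stream) << 32));
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t k = sm64(smix ^ static_cast<uint64_t>(id[i % ni]));
    k = sm64(k ^ static_cast<uint64_t>(counter[i % nc]));
    // 53-bit mantissa, offset keeps u strictly inside (0, 1)
    out[i] = (static_cast<double>(k >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
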