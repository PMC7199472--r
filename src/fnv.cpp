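#include <Rcpp.h>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

// FNV-1a, 64-bit: the fixed, published non-cryptographic hash used for
// record placement. Never seeded per process, so partition assignment is
// reproducible across runs and machines.
static uint64_t fnv1a64(const char *s) {
  uint64_t h = 14695981039346656037ULL;
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    h ^= (uint64_t)(*p);
    h *= 1099511628211ULL;
  }
  return h;
}

// [[Rcpp::export(name = ".fnv1a64_mod")]]
IntegerVector fnv1a64_mod(CharacterVector keys, int m) {
  if (m < 1) stop("modulus must be >= 1");
  R_xlen_t n = keys.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (keys[i] == NA_STRING) stop("key is NA at position %d", (int)(i + 1));
    const char *s = Rf_translateCharUTF8(STRING_ELT(keys, i));
    out[i] = (int)(fnv1a64(s) % (uint64_t)m);
  }
  return out;
}

// [[Rcpp::export(name = ".fnv1a64_hex")]]
CharacterVector fnv1a64_hex(CharacterVector keys) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (keys[i] == NA_STRING) stop("key is NA at position %d", (int)(i + 1));
    const char *s = Rf_translateCharUTF8(STRING_ELT(keys, i));
    std::snprintf(buf, sizeof(buf), "%016llx",
                  (unsigned long long)fnv1a64(s));
    out[i] = buf;
  }
  return out;
}
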