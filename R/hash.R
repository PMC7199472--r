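#' Stable record-placement hash
#'
#' Hashes key strings with the published 64-bit FNV-1a function over their
#' UTF-8 bytes. The hash is fixed (never per-process randomized), so the
#' partition assignment it drives is identical across runs, processes and
#' machines — the property a deterministic hash partitioner needs.
#'
#' @param keys Character vector of keys.
#' @param mod Optional positive integer. When given, returns
#'   `hash(key) %% mod` as an integer vector in `0:(mod - 1)` (the partition
#'   index space); when `NULL`, returns the full 64-bit hash as a 16-digit
#'   lower-case hex string.
#' @return Integer vector (with `mod`) or character vector of hex digests.
#' @examples
#' stable_hash("chr1")
#' stable_hash(c("chr1", "chr2"), mod = 14)
#' @export
stable_hash <- function(keys, mod = NULL) {
  keys <- as.character(keys)
  if (is.null(mod)) {
    .fnv1a64_hex(keys)
  } else {
    mod <- as.integer(mod)
    stopifnot(length(mod) == 1L, !is.na(mod), mod >= 1L)
    .fnv1a64_mod(keys, mod)
  }
}
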