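# internal helpers

# Deterministic 32-bit substream seeds. Keeps every derived seed in
# [1, 2^31 - 2] so set.seed() never overflows; the multiplier is the
# Lehmer/Park-Miller constant.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 8191) %% 2147483647 + 1)
}

abort_msat <- function(msg, class = "msatabc_error") {
  rlang::abort(msg, class = class)
}

# pairs (i < j) of population indices, lexicographic
pop_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  t(utils::combn(n, 2))
}
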