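#' Deterministic per-CpG seed derivation
#'
#' Rows of a beta matrix are processed independently (possibly on several
#' workers), so each CpG is paired with its own RNG seed derived from the
#' global seed and the row index alone. The derivation is a double-round
#' Lehmer (minstd, multiplier 48271, modulus 2^31 - 1) mix, which keeps all
#' arithmetic exact in doubles and the result inside the 32-bit signed range.
#' Because the seed depends only on `(global_seed, cpg_index)`, results are
#' identical for any worker count and any scheduling order.
#'
#' @param global_seed Non-negative integer seed for the whole run.
#' @param cpg_index Zero-based row index of the CpG in the input matrix.
#' @param cpg_id Optional CpG identifier; accepted for call-site clarity but
#'   not used in the derivation (the seed must not depend on identifier
#'   spelling, only on position).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_cpg_seed(42, 0)
#' derive_cpg_seed(42, 1) # distinct from index 0
#' @export
derive_cpg_seed <- function(global_seed, cpg_index, cpg_id = NULL) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L, global_seed >= 0,
            is.numeric(cpg_index), length(cpg_index) == 1L, cpg_index >= 0)
  mix31(mix31(global_seed) + cpg_index)
}

# Lehmer/minstd step applied twice for dispersion; 48271 * 2^31 < 2^53 so the
# products are exact in double arithmetic.
mix31 <- function(x) {
  x <- (x %% 2147483646) + 1
  x <- (48271 * x) %% 2147483647
  x <- (48271 * x) %% 2147483647
  as.integer(x)
}

# sub-seed for restart r of component count k in model selection
subseed <- function(seed, k, r) {
  mix31(mix31(seed + 7919 * k) + r)
}
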