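# Internal helpers shared across modules.

# Deterministically derive `n` independent sub-seeds from one master seed, so
# each pipeline stage consumes its own RNG substream and adding a stage never
# perturbs earlier stages' draws.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Run `expr` under `seed` when given, otherwise in the ambient RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_whole <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

stop_sb <- function(msg, class) {
  rlang::abort(msg, class = paste0("streambeta_", class))
}

# Column-major lower-triangle pair indices: (2,1),(3,1),...,(n,n-1).
# This single ordering is shared by unfold(), mantel(), mrm() and hier_part().
lower_pair_index <- function(n) {
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

sample_sd <- function(x) stats::sd(x)
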