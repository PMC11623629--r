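# Internal helpers shared across modules.

# Deterministic substream seed derived from a root seed and a stream name.
# All simulators draw their randomness through named substreams of one root
# seed, so that adding a stage never perturbs the draws of another.
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  # keep all intermediates below 2^53 so double arithmetic is exact
  as.integer((((root %% 2147483647) * 69069) %% 2147483647 + h * 2654435 +
                1013904223) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

stop_input <- function(...) stop(..., call. = FALSE)

# Fisher z-averaged mean of correlations, back-transformed.
fisher_mean <- function(r) {
  tanh(mean(atanh(r)))
}
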