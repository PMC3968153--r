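#' Derive a child RNG seed from a root seed
#'
#' Deterministic counter scheme used everywhere the package needs several
#' independent random streams (per tested set, per simulation replicate,
#' per method family) from one root seed: child = (root + 1000003 * index)
#' mod (2^31 - 1). The scheme is worker-independent, so parallel and
#' serial study runs see identical streams.
#'
#' @param root Integer root seed.
#' @param index Non-negative integer counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root, index) {
  as.integer((as.double(root) + 1000003 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncation rule shared by all spectral computations: eigenvalues below
# 1e-10 * max are float noise from rank deficiency and are dropped.
active_eigenvalues <- function(vals, rel_tol = 1e-10) {
  vals <- sort(vals, decreasing = TRUE)
  vals[vals > rel_tol * max(vals, 0)]
}
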