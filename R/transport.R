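# Exact discrete Wasserstein-1. The solver (successive-shortest-path
# min-cost flow on 2^40-scaled integer masses) lives in src/transport.cpp;
# the induced mass-rounding perturbation of the optimum is bounded by
# n*max_cost/2^40, far below the 1e-8 tolerance the curvature tests demand.

#' Exact Wasserstein-1 distance between two discrete distributions
#'
#' Solves the transportation problem `min sum(cost * plan)` subject to the
#' marginal constraints, by successive shortest augmenting paths on the
#' bipartite residual network.
#'
#' @param a,b Nonnegative mass vectors summing to the same total.
#' @param cost `length(a) x length(b)` nonnegative cost matrix.
#' @return The optimal transport cost.
#' @export
wasserstein1 <- function(a, b, cost) {
  stopifnot(all(a >= 0), all(b >= 0))
  cost <- matrix(cost, length(a), length(b))
  if (!all(is.finite(cost))) stop("non-finite transport cost (disconnected supports?)")
  .cpp_wasserstein1(as.numeric(a), as.numeric(b), cost)
}
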