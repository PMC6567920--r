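#' Probabilistic sensitivity analysis
#'
#' Propagates Latin Hypercube parameter draws (see [sample_lhs()]) through
#' the decision model and the micro-costing to an iteration-level
#' (cost, effect) table per strategy. Within an iteration every strategy is
#' evaluated on the same parameter draw (common random numbers), so
#' strategies sharing a test see the identical accuracy value. Effect is
#' the expected number of true positives (continuous, expected-value tree);
#' cost is the algorithm's annual micro-costed total.
#'
#' @param params a [model_parameters()] object.
#' @param strategies named list of [algorithm_spec()]s (default: the three
#'   built-in algorithms plus the do-nothing baseline).
#' @param n_iter iterations (default `params$n_iterations`).
#' @param seed integer seed (default `params$seed`).
#' @param overhead_per_patient passed to [algorithm_annual_cost()].
#' @return object of class `psa_table`: list with `draws` (the LHS table),
#'   `cost` and `effect` (n_iter x n_strategy data.frames), `strategies`,
#'   `n_iter`, `seed`.
#' @export
run_psa <- function(params, strategies = pcd_algorithms(include_baseline = TRUE),
                    n_iter = params$n_iterations, seed = params$seed,
                    overhead_per_patient = 0) {
  stopifnot(length(strategies) >= 1)
  draws <- sample_lhs(params, n_iter, seed)
  v <- as.list(draws)
  cost <- list(); effect <- list()
  for (s in names(strategies)) {
    alg <- strategies[[s]]
    counts <- classify_algorithm(alg, params, v)
    cb <- algorithm_annual_cost(alg, params, v = v,
                                overhead_per_patient = overhead_per_patient)
    effect[[s]] <- rep_len(counts$tp, n_iter)
    cost[[s]] <- rep_len(cb$total_annual, n_iter)
    if (any(!is.finite(cost[[s]])) || any(!is.finite(effect[[s]]))) {
      bad <- which(!is.finite(cost[[s]]) | !is.finite(effect[[s]]))[1]
      stop(sprintf("propagation failed for '%s' at iteration %d; draw: %s",
                   s, bad,
                   paste(sprintf("%s=%g", names(draws), unlist(draws[bad, ])),
                         collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(draws = draws,
                 cost = as.data.frame(cost, check.names = FALSE),
                 effect = as.data.frame(effect, check.names = FALSE),
                 strategies = names(strategies), n_iter = n_iter,
                 seed = seed),
            class = "psa_table")
}

#' @export
print.psa_table <- function(x, ...) {
  cat(sprintf("<psa_table> %d iterations, %d strategies (%s), seed %d\n",
              x$n_iter, length(x$strategies),
              paste(x$strategies, collapse = ", "), x$seed))
  invisible(x)
}

#' Summarize a PSA table
#'
#' Per-strategy mean and 95% percentile interval (type-7 linear
#' interpolation, not a normal approximation) of cost and effect.
#'
#' @param psa a `psa_table` from [run_psa()].
#' @return data.frame with one row per strategy: mean and 2.5/97.5
#'   percentiles of cost and effect.
#' @export
summarize_draws <- function(psa) {
  stopifnot(inherits(psa, "psa_table"), psa$n_iter >= 2)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    type = 7)
  rows <- lapply(psa$strategies, function(s) {
    cq <- qs(psa$cost[[s]]); eq <- qs(psa$effect[[s]])
    data.frame(strategy = s,
               cost_mean = mean(psa$cost[[s]]),
               cost_lo = cq[1], cost_hi = cq[2],
               effect_mean = mean(psa$effect[[s]]),
               effect_lo = eq[1], effect_hi = eq[2])
  })
  do.call(rbind, rows)
}

#' Persist a PSA table as CSV
#'
#' One row per iteration: the seed, every parameter draw, then
#' `cost_<strategy>` and `effect_<strategy>` columns.
#'
#' @param psa a `psa_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  cost <- psa$cost; effect <- psa$effect
  names(cost) <- paste0("cost_", names(cost))
  names(effect) <- paste0("effect_", names(effect))
  out <- cbind(data.frame(iteration = seq_len(psa$n_iter), seed = psa$seed),
               psa$draws, cost, effect)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
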