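#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)`, in EUR per additional case
#' identified. A zero effect difference is signalled as an error rather than
#' returning an infinity.
#'
#' @param cost_a,cost_b annual costs of the two strategies (EUR/yr).
#' @param effect_a,effect_b annual effects (cases identified/yr).
#' @return the ICER (EUR/case).
#' @examples
#' icer(209000, 136000, 313, 273) # 1825
#' @export
icer <- function(cost_a, cost_b, effect_a, effect_b) {
  if (any(effect_a == effect_b))
    stop("ICER undefined: zero effect difference", call. = FALSE)
  (cost_a - cost_b) / (effect_a - effect_b)
}

#' Cost-effectiveness ratio estimators over PSA iterations
#'
#' Two estimators of a ratio of Monte-Carlo means are in circulation and
#' they do not agree: the ratio of means `mean(cost)/mean(effect)` and the
#' mean of per-iteration ratios `mean(cost_i/effect_i)`. Both are returned,
#' with a percentile interval on the per-iteration ratios. Iterations with a
#' zero effect difference are excluded from the mean of ratios and counted.
#'
#' @param d_cost,d_effect per-iteration incremental cost and effect vectors
#'   (vs a comparator; use the raw cost/effect columns for a CER vs
#'   do-nothing).
#' @return list with `ratio_of_means`, `mean_of_ratios`, `ci` (2.5/97.5
#'   percentiles of the per-iteration ratios), `n_excluded`.
#' @export
ratio_estimates <- function(d_cost, d_effect) {
  stopifnot(length(d_cost) == length(d_effect))
  ok <- d_effect != 0
  ratios <- d_cost[ok] / d_effect[ok]
  list(ratio_of_means = mean(d_cost) / mean(d_effect),
       mean_of_ratios = mean(ratios),
       ci = stats::quantile(ratios, c(0.025, 0.975), names = FALSE),
       n_excluded = sum(!ok))
}

#' Dominance pruning and the cost-effectiveness frontier
#'
#' Orders strategies by effect and prunes: simple dominance first (a
#' strategy is dominated if another costs no more and delivers at least as
#' much effect, with at least one strict inequality; exact ties are broken
#' against the lexicographically later name), then extended dominance
#' (iterative removal of strategies whose ICER relative to the previous
#' frontier member is not strictly below the next member's, i.e. enforcing
#' strictly increasing ICERs along the frontier). ICERs are computed between
#' adjacent surviving frontier members.
#'
#' @param strategies data.frame with columns `name`, `cost`, `effect` (one
#'   row per strategy, the do-nothing baseline included), or a named list
#'   of `c(cost, effect)` pairs.
#' @return data.frame sorted by increasing effect with columns `name`,
#'   `cost`, `effect`, `dominance` (one of `"on_frontier"`,
#'   `"simply_dominated"`, `"extendedly_dominated"`) and `icer` (vs the
#'   previous frontier member; `NA` for the cheapest member and for
#'   dominated strategies).
#' @export
build_frontier <- function(strategies) {
  if (!is.data.frame(strategies)) {
    strategies <- data.frame(
      name = names(strategies),
      cost = vapply(strategies, `[`, numeric(1), 1),
      effect = vapply(strategies, `[`, numeric(1), 2))
  }
  stopifnot(nrow(strategies) >= 2,
            all(c("name", "cost", "effect") %in% names(strategies)))
  df <- strategies[order(strategies$effect, strategies$cost,
                         strategies$name), ]
  df$dominance <- "on_frontier"
  df$icer <- NA_real_
  # simple dominance (ties resolved lexicographically: the earlier name wins)
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      no_worse <- df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i]
      strictly <- df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i]
      tie <- df$cost[j] == df$cost[i] && df$effect[j] == df$effect[i]
      if ((no_worse && strictly) || (tie && df$name[j] < df$name[i])) {
        df$dominance[i] <- "simply_dominated"
        break
      }
    }
  }
  # extended dominance: enforce strictly increasing ICERs along the frontier
  repeat {
    idx <- which(df$dominance == "on_frontier")
    if (length(idx) < 3) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1)) {
      lo <- idx[k - 1]; mid <- idx[k]; hi <- idx[k + 1]
      icer_mid <- (df$cost[mid] - df$cost[lo]) / (df$effect[mid] - df$effect[lo])
      icer_hi <- (df$cost[hi] - df$cost[mid]) / (df$effect[hi] - df$effect[mid])
      if (icer_mid >= icer_hi) {
        df$dominance[mid] <- "extendedly_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  idx <- which(df$dominance == "on_frontier")
  if (length(idx) > 1)
    for (k in 2:length(idx))
      df$icer[idx[k]] <- icer(df$cost[idx[k]], df$cost[idx[k - 1]],
                              df$effect[idx[k]], df$effect[idx[k - 1]])
  rownames(df) <- NULL
  df
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold \eqn{\lambda} on the grid, the
#' fraction of PSA iterations in which the strategy's incremental net
#' monetary benefit versus the comparator is non-negative:
#' \eqn{\lambda \Delta e - \Delta c \ge 0} (ties count as cost-effective).
#'
#' @param psa a `psa_table` from [run_psa()].
#' @param strategy,comparator strategy names present in the table.
#' @param wtp_grid numeric vector of thresholds (EUR/case), non-empty.
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, strategy, comparator, wtp_grid) {
  stopifnot(inherits(psa, "psa_table"))
  if (!length(wtp_grid)) stop("empty WTP grid", call. = FALSE)
  for (s in c(strategy, comparator))
    if (!s %in% psa$strategies)
      stop(sprintf("strategy '%s' not in PSA table", s), call. = FALSE)
  d_cost <- psa$cost[[strategy]] - psa$cost[[comparator]]
  d_eff <- psa$effect[[strategy]] - psa$effect[[comparator]]
  prob <- vapply(wtp_grid,
                 function(l) mean(l * d_eff - d_cost >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' One-way (tornado) sensitivity analysis of an ICER
#'
#' Re-evaluates the deterministic model with each uncertain parameter set to
#' its 95% CI endpoints in turn (all other parameters at best estimate) and
#' records the ICER of `strategy` versus `comparator` at both endpoints.
#' Entries are sorted by descending span; point-mass parameters have zero
#' span and sort last.
#'
#' @param params a [model_parameters()] object.
#' @param strategy,comparator [algorithm_spec()]s for the ICER pair.
#' @param overhead_per_patient passed to [algorithm_annual_cost()].
#' @return data.frame with columns `parameter`, `low`, `high` (the endpoint
#'   values used), `icer_at_low`, `icer_at_high`, `span`.
#' @export
tornado <- function(params, strategy, comparator, overhead_per_patient = 0) {
  specs <- param_specs(params)
  base <- best_estimates(params)
  eval_icer <- function(v) {
    ca <- classify_algorithm(strategy, params, v)
    cb <- classify_algorithm(comparator, params, v)
    costa <- algorithm_annual_cost(strategy, params, v = v,
                                   overhead_per_patient = overhead_per_patient)
    costb <- algorithm_annual_cost(comparator, params, v = v,
                                   overhead_per_patient = overhead_per_patient)
    icer(costa$total_annual, costb$total_annual, ca$tp, cb$tp)
  }
  rows <- lapply(specs, function(s) {
    if (s$family == "point" || !is.finite(s$ci_low)) {
      lo <- hi <- s$best
    } else {
      lo <- s$ci_low; hi <- s$ci_high
    }
    v <- base
    v[[s$name]] <- lo; icer_lo <- eval_icer(v)
    v[[s$name]] <- hi; icer_hi <- eval_icer(v)
    data.frame(parameter = s$name, low = lo, high = hi,
               icer_at_low = icer_lo, icer_at_high = icer_hi,
               span = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  out
}
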