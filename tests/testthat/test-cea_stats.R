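test_that("ICER arithmetic and the zero-difference guard", {
  expect_equal(icer(200, 100, 50, 40), 10)
  expect_equal(icer(500, 500, 30, 20), 0)
  expect_error(icer(200, 100, 40, 40), "zero effect difference")
  # frontier ICER from the published summary means; the publication's own
  # headline figure (2097) averages per-iteration ratios instead and is
  # deliberately not asserted here
  expect_equal(icer(209000, 136000, 313, 273), 1825)
})

test_that("both ratio estimators exist and coincide when degenerate", {
  est <- ratio_estimates(rep(2000, 50), rep(4, 50))
  expect_equal(est$ratio_of_means, 500)
  expect_equal(est$mean_of_ratios, 500)
  expect_equal(est$ci, c(500, 500))
  expect_equal(est$n_excluded, 0L)
  # zero effect-difference iterations are excluded and counted
  est2 <- ratio_estimates(c(100, 100, 100), c(1, 0, 2))
  expect_equal(est2$n_excluded, 1L)
  expect_equal(est2$mean_of_ratios, mean(c(100, 50)))
})

test_that("the frontier reproduces the published dominance structure", {
  front <- build_frontier(data.frame(
    name = c("Do nothing", "nNO+HSVM", "nNO+TEM", "nNO/HSVM+TEM"),
    cost = c(0, 136000, 150000, 209000),
    effect = c(0, 273, 198, 313)))
  get <- function(nm, col) front[front$name == nm, col]
  expect_equal(get("nNO+TEM", "dominance"), "simply_dominated")
  expect_true(is.na(get("nNO+TEM", "icer")))
  expect_equal(front$name[front$dominance == "on_frontier"],
               c("Do nothing", "nNO+HSVM", "nNO/HSVM+TEM"))
  expect_equal(get("nNO+HSVM", "icer"), 136000 / 273, tolerance = 1e-9)
  expect_equal(get("nNO/HSVM+TEM", "icer"), 1825)
  # frontier ICERs strictly increase
  icers <- front$icer[front$dominance == "on_frontier"]
  expect_true(all(diff(na.omit(icers)) > 0))
})

test_that("ties and collinear strategies are pruned deterministically", {
  tie <- build_frontier(data.frame(name = c("b_strategy", "a_strategy"),
                                   cost = c(100, 100), effect = c(10, 10)))
  expect_equal(tie$dominance[tie$name == "a_strategy"], "on_frontier")
  expect_equal(tie$dominance[tie$name == "b_strategy"], "simply_dominated")
  # equal ICERs along a collinear triple: the middle one falls to the
  # strict-increase rule, and the surviving ICER is unchanged either way
  col3 <- build_frontier(data.frame(name = c("lo", "mid", "hi"),
                                    cost = c(0, 100, 200),
                                    effect = c(0, 10, 20)))
  expect_equal(col3$dominance[col3$name == "mid"], "extendedly_dominated")
  expect_equal(col3$icer[col3$name == "hi"], 10)
})

test_that("extended dominance removes kinked-out middle strategies", {
  # mid's ICER (20) exceeds hi's ICER from mid (5): classic extended case
  front <- build_frontier(data.frame(name = c("lo", "mid", "hi"),
                                     cost = c(0, 200, 250),
                                     effect = c(0, 10, 20)))
  expect_equal(front$dominance[front$name == "mid"], "extendedly_dominated")
  expect_equal(front$icer[front$name == "hi"], 12.5)
})

test_that("the acceptability curve is the INMB exceedance fraction", {
  # degenerate PSA: delta cost 2000, delta effect 1 everywhere -> step at 2000
  psa <- fake_psa(cost = list(base = rep(0, 10), new = rep(2000, 10)),
                  effect = list(base = rep(0, 10), new = rep(1, 10)))
  cc <- ceac(psa, "new", "base", c(0, 1000, 1999, 2000, 2001, 5000))
  expect_equal(cc$probability, c(0, 0, 0, 1, 1, 1)) # ties count as CE
  # lambda = 0 reduces to the fraction of cost-saving iterations
  psa2 <- fake_psa(cost = list(base = rep(0, 4), new = c(-5, -1, 3, 8)),
                   effect = list(base = rep(0, 4), new = rep(1, 4)))
  expect_equal(ceac(psa2, "new", "base", 0)$probability, 0.5)
  expect_error(ceac(psa2, "new", "base", numeric(0)), "empty")
  expect_error(ceac(psa2, "missing", "base", 1), "missing")
})

test_that("a symmetric INMB distribution crosses 0.5 at its centre", {
  set.seed(12)
  n <- 4000
  d_cost <- 2000 + rnorm(n, sd = 300) # symmetric about 2000, d_effect = 1
  psa <- fake_psa(cost = list(base = rep(0, n), new = d_cost),
                  effect = list(base = rep(0, n), new = rep(1, n)))
  pr <- ceac(psa, "new", "base", 2000)$probability
  expect_lt(abs(pr - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the CEAC is non-decreasing when every iteration gains effect", {
  set.seed(33)
  n <- 500
  psa <- fake_psa(cost = list(base = rep(0, n), new = rnorm(n, 1000, 800)),
                  effect = list(base = rep(0, n), new = runif(n, 0.1, 2)))
  cc <- ceac(psa, "new", "base", seq(0, 5000, by = 50))
  expect_true(all(diff(cc$probability) >= 0))
})

test_that("tornado entries are endpoint evaluations sorted by span", {
  p <- default_parameters()
  algs <- pcd_algorithms()
  torn <- tornado(p, algs[["nNO/HSVM+TEM"]], algs[["nNO+HSVM"]])
  expect_equal(torn$span, sort(torn$span, decreasing = TRUE))
  expect_equal(torn$span, abs(torn$icer_at_high - torn$icer_at_low))
  # zero-width (point) parameters have zero span and sort last
  expect_equal(torn$span[torn$parameter == "brushing_time"], 0)
  # parameters unused by the pair leave the ICER untouched: compare a TEM
  # maintenance row for a pair that never performs TEM
  torn2 <- tornado(p, algs[["nNO+HSVM"]],
                   pcd_algorithms(include_baseline = TRUE)[["Do nothing"]])
  expect_equal(torn2$span[torn2$parameter == "tem_maintenance"], 0)
  expect_equal(torn2$span[torn2$parameter == "tem_capital"], 0)
  # HSVM sensitivity over (0.89, 1.00) moves the frontier ICER
  expect_gt(torn$span[torn$parameter == "hsvm_sens"], 0)
  # endpoint evaluations reproduce a direct deterministic model call
  v <- best_estimates(p); v$hsvm_sens <- 0.89
  ca <- classify_algorithm(algs[["nNO/HSVM+TEM"]], p, v)
  cb <- classify_algorithm(algs[["nNO+HSVM"]], p, v)
  costa <- algorithm_annual_cost(algs[["nNO/HSVM+TEM"]], p, v = v)
  costb <- algorithm_annual_cost(algs[["nNO+HSVM"]], p, v = v)
  expect_equal(torn$icer_at_low[torn$parameter == "hsvm_sens"],
               (costa$total_annual - costb$total_annual) / (ca$tp - cb$tp))
})
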