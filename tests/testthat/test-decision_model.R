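test_that("Bayes posteriors match the 2x2 enumeration oracle", {
  # degenerate cases
  expect_equal(posterior_positive(0.5, 1, 1), 1)
  expect_equal(posterior_positive(0, 0.95, 0.94), 0)
  expect_equal(posterior_negative(0.5, 1, 1), 0)
  expect_equal(posterior_negative(1, 0.95, 0.94), 1)
  # frozen values computed with enum_posterior (4 d.p.)
  expect_equal(round(posterior_positive(0.32, 0.95, 0.94), 4), 0.8817)
  expect_equal(round(posterior_negative(0.32, 0.95, 0.94), 4), 0.0244)
  set.seed(41)
  for (i in 1:25) {
    pr <- runif(1); se <- runif(1); sp <- runif(1, 0.01, 0.99)
    expect_equal(posterior_positive(pr, se, sp),
                 enum_posterior(pr, se, sp, "pos"), tolerance = 1e-12)
    expect_equal(posterior_negative(pr, se, sp),
                 enum_posterior(pr, se, sp, "neg"), tolerance = 1e-12)
  }
  expect_error(posterior_positive(0.5, 1.2, 0.9), "0,1")
  # 0/0 (prior 0, perfectly specific test) resolves to 0, not NaN
  expect_equal(posterior_positive(0, 1, 1), 0)
  expect_equal(posterior_negative(1, 1, 0), 0)
})

test_that("sequential classification matches frozen expected-value examples", {
  co <- list(n = 1000, prevalence = 0.32)
  expect_counts_equal(classify_sequential(co, c(1, 1), c(1, 1)),
                      list(tp = 320, fp = 0, tn = 680, fn = 0))
  expect_counts_equal(classify_sequential(co, c(0.95, 0.94), c(1.00, 0.92)),
                      list(tp = 304, fp = 3.264, tn = 676.736, fn = 16))
  expect_counts_equal(classify_sequential(co, c(0.95, 0.94), c(0.74, 0.91)),
                      list(tp = 224.96, fp = 3.672, tn = 676.328, fn = 95.04))
})

test_that("sequential tree expansion equals chained Bayes posteriors", {
  grid <- random_probs(40, seed = 7)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    direct <- classify_sequential(list(n = 1000, prevalence = g[["prev"]]),
                                  c(g[["sa"]], g[["qa"]]),
                                  c(g[["sb"]], g[["qb"]]))
    chained <- chain_sequential(1000, g[["prev"]], g[["sa"]], g[["qa"]],
                                g[["sb"]], g[["qb"]])
    expect_counts_equal(direct, chained, tol = 1e-9)
  }
})

test_that("parallel-arbiter classification matches frozen examples", {
  co <- list(n = 1000, prevalence = 0.32)
  expect_counts_equal(
    classify_parallel_arbiter(co, c(1, 1), c(1, 1), c(1, 1)),
    list(tp = 320, fp = 0, tn = 680, fn = 0))
  expect_counts_equal(
    classify_parallel_arbiter(co, c(0.95, 0.94), c(1.00, 0.92),
                              c(0.74, 0.91)),
    list(tp = 315.84, fp = 11.244, tn = 668.756, fn = 4.16), tol = 5e-4)
  # a useless arbiter is never consulted when the first-line pair agrees
  expect_counts_equal(
    classify_parallel_arbiter(co, c(1, 1), c(1, 1), c(0.5, 0.5)),
    list(tp = 320, fp = 0, tn = 680, fn = 0))
})

test_that("counts conserve cohort size and prevalence split", {
  grid <- random_probs(60, seed = 11)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    co <- list(n = 1000, prevalence = g[["prev"]])
    for (counts in list(
      classify_sequential(co, c(g[["sa"]], g[["qa"]]),
                          c(g[["sb"]], g[["qb"]])),
      classify_parallel_arbiter(co, c(g[["sa"]], g[["qa"]]),
                                c(g[["sb"]], g[["qb"]]),
                                c(g[["sr"]], g[["qr"]])))) {
      expect_equal(counts$tp + counts$fp + counts$tn + counts$fn, 1000,
                   tolerance = 1e-9)
      expect_equal(counts$tp + counts$fn, 1000 * g[["prev"]],
                   tolerance = 1e-9)
      expect_equal(counts$fp + counts$tn, 1000 * (1 - g[["prev"]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("tp grows with sensitivity, fp shrinks with specificity", {
  co <- list(n = 1000, prevalence = 0.3)
  base <- c(sa = 0.8, qa = 0.85, sb = 0.7, qb = 0.9, sr = 0.75, qr = 0.8)
  eps <- 0.05
  for (s_arg in c("sa", "sb", "sr")) {
    up <- base; up[s_arg] <- up[s_arg] + eps
    expect_gte(
      classify_parallel_arbiter(co, c(up[["sa"]], up[["qa"]]),
                                c(up[["sb"]], up[["qb"]]),
                                c(up[["sr"]], up[["qr"]]))$tp,
      classify_parallel_arbiter(co, c(base[["sa"]], base[["qa"]]),
                                c(base[["sb"]], base[["qb"]]),
                                c(base[["sr"]], base[["qr"]]))$tp)
  }
  for (q_arg in c("qa", "qb", "qr")) {
    up <- base; up[q_arg] <- up[q_arg] + eps
    expect_lte(
      classify_parallel_arbiter(co, c(up[["sa"]], up[["qa"]]),
                                c(up[["sb"]], up[["qb"]]),
                                c(up[["sr"]], up[["qr"]]))$fp,
      classify_parallel_arbiter(co, c(base[["sa"]], base[["qa"]]),
                                c(base[["sb"]], base[["qb"]]),
                                c(base[["sr"]], base[["qr"]]))$fp)
  }
  # sequential: both sensitivities raise tp, both specificities lower fp
  expect_gt(classify_sequential(co, c(0.9, 0.9), c(0.8, 0.9))$tp,
            classify_sequential(co, c(0.8, 0.9), c(0.8, 0.9))$tp)
  expect_lt(classify_sequential(co, c(0.9, 0.95), c(0.8, 0.9))$fp,
            classify_sequential(co, c(0.9, 0.9), c(0.8, 0.9))$fp)
})

test_that("net metrics reproduce the published accuracy table rows", {
  m <- net_metrics(classification_counts(198, 2, 678, 122))
  expect_equal(m$net_sensitivity, 0.619, tolerance = 1e-3)
  expect_equal(m$net_specificity, 0.997, tolerance = 5e-4)
  expect_equal(m$ppv, 0.990, tolerance = 1e-3)
  expect_equal(m$npv, 0.8475, tolerance = 1e-4)
  m2 <- net_metrics(classification_counts(273, 0, 680, 47))
  expect_equal(round(100 * m2$net_sensitivity), 85)
  expect_equal(m2$net_specificity, 1)
  expect_equal(m2$ppv, 1)
  expect_equal(round(100 * m2$npv), 94)
  m3 <- net_metrics(classification_counts(1, 1, 1, 1))
  expect_equal(unlist(unclass(m3)), c(net_sensitivity = 0.5,
                                      net_specificity = 0.5,
                                      ppv = 0.5, npv = 0.5))
  expect_warning(net_metrics(classification_counts(0, 0, 1, 1)), "PPV")
})

test_that("test volumes follow the branch probabilities", {
  p <- default_parameters()
  algs <- pcd_algorithms()
  v_seq <- test_volumes(algs[["nNO+HSVM"]], p)
  expect_equal(v_seq$nno, 1000)
  expect_equal(v_seq$hsvm, 344.8) # 320*0.95 + 680*0.06
  v_par <- test_volumes(algs[["nNO/HSVM+TEM"]], p)
  expect_equal(v_par$nno, 1000)
  expect_equal(v_par$hsvm, 1000)
  expect_equal(v_par$tem, 104.672) # 320*0.05 + 680*0.1304
  # perfect screen: confirmatory volume = diseased mass
  v_perf <- test_volumes(algs[["nNO+HSVM"]], p,
                         v = list(nno_sens = 1, nno_spec = 1))
  expect_equal(v_perf$hsvm, 320)
})

test_that("conditional second-stage accuracies override the marginals", {
  p <- default_parameters()
  p$hsvm <- test_accuracy(
    p$hsvm$sensitivity, p$hsvm$specificity,
    conditional_sensitivity = dist_spec("hsvm_cond_sens", "point", 0.9,
                                        probability = TRUE),
    conditional_specificity = dist_spec("hsvm_cond_spec", "point", 0.8,
                                        probability = TRUE))
  counts <- classify_algorithm(pcd_algorithms()[["nNO+HSVM"]], p)
  expect_equal(counts$tp, 320 * 0.95 * 0.9)
  expect_equal(counts$fp, 680 * 0.06 * 0.2)
  # first-line (marginal) use is unaffected in the parallel arm
  par <- classify_algorithm(pcd_algorithms()[["nNO/HSVM+TEM"]], p)
  expect_equal(par$tp, 315.84)
})

test_that("the do-nothing baseline misses every case at zero cost", {
  p <- default_parameters()
  baseline <- pcd_algorithms(include_baseline = TRUE)[["Do nothing"]]
  counts <- classify_algorithm(baseline, p)
  expect_counts_equal(counts, list(tp = 0, fp = 0, tn = 680, fn = 320))
  expect_equal(algorithm_annual_cost(baseline, p)$total_annual, 0)
})
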