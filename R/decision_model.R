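#' Posterior probability of disease after a positive test
#'
#' Bayes' theorem for a dichotomous test:
#' \deqn{P(D|T+) = \frac{\pi \cdot se}{\pi \cdot se + (1-\pi)(1-sp)}}
#' where \eqn{\pi} is the pre-test probability, \eqn{se} the sensitivity and
#' \eqn{sp} the specificity. Vectorized over all arguments.
#'
#' A zero denominator with a zero numerator (e.g. prior 0 with a perfectly
#' specific test) returns 0; a zero denominator with positive numerator is
#' impossible and a genuine 0/0-free degenerate call errors.
#'
#' @param prior pre-test probability of disease, in \eqn{[0,1]}.
#' @param sensitivity,specificity test accuracy, in \eqn{[0,1]}.
#' @return posterior probability of disease given a positive result.
#' @examples
#' posterior_positive(0.32, 0.95, 0.94) # 0.8817
#' @export
posterior_positive <- function(prior, sensitivity, specificity) {
  check_prob(prior, sensitivity, specificity)
  num <- prior * sensitivity
  den <- num + (1 - prior) * (1 - specificity)
  ifelse_zero(num, den)
}

#' Posterior probability of disease after a negative test
#'
#' The rearranged Bayes formula
#' \eqn{P(D|T-) = \pi(1-se) / (\pi(1-se) + (1-\pi) sp)}.
#'
#' @inheritParams posterior_positive
#' @return posterior probability of disease given a negative result.
#' @examples
#' posterior_negative(0.32, 0.95, 0.94) # 0.0244
#' @export
posterior_negative <- function(prior, sensitivity, specificity) {
  check_prob(prior, sensitivity, specificity)
  num <- prior * (1 - sensitivity)
  den <- num + (1 - prior) * specificity
  ifelse_zero(num, den)
}

check_prob <- function(...) {
  for (x in list(...))
    if (any(x < 0 | x > 1)) stop("probabilities must lie in [0,1]",
                                 call. = FALSE)
  invisible(TRUE)
}

ifelse_zero <- function(num, den) {
  out <- num / den
  zero <- den == 0
  if (any(zero)) {
    if (any(num[zero] != 0))
      stop("zero denominator with non-zero numerator in Bayes update",
           call. = FALSE)
    out[zero] <- 0
  }
  out
}

#' Diagnostic algorithm topology
#'
#' Describes how the tests of a [model_parameters()] object are combined:
#' `sequential` (screen, then confirm positives only), `parallel_arbiter`
#' (two first-line tests on everyone; an arbiter settles discordant pairs)
#' or `none` (the do-nothing baseline: no tests, zero cost, zero effect).
#' Test slots are names of tests in the parameter set (`"nno"`, `"hsvm"`,
#' `"tem"`).
#'
#' @param name display name of the algorithm.
#' @param topology `"sequential"`, `"parallel_arbiter"` or `"none"`.
#' @param first_test,second_test screen and confirmatory test (sequential).
#' @param test_a,test_b,arbiter first-line pair and arbiter (parallel).
#' @return object of class `algorithm_spec`.
#' @seealso [pcd_algorithms()] for the three built-in strategies.
#' @export
algorithm_spec <- function(name,
                           topology = c("sequential", "parallel_arbiter",
                                        "none"),
                           first_test = NULL, second_test = NULL,
                           test_a = NULL, test_b = NULL, arbiter = NULL) {
  topology <- match.arg(topology)
  if (topology == "sequential" && (is.null(first_test) || is.null(second_test)))
    stop("sequential topology needs first_test and second_test", call. = FALSE)
  if (topology == "parallel_arbiter" &&
      (is.null(test_a) || is.null(test_b) || is.null(arbiter)))
    stop("parallel_arbiter topology needs test_a, test_b and arbiter",
         call. = FALSE)
  structure(list(name = name, topology = topology, first_test = first_test,
                 second_test = second_test, test_a = test_a, test_b = test_b,
                 arbiter = arbiter),
            class = "algorithm_spec")
}

tests_of <- function(alg) {
  switch(alg$topology,
         sequential = c(alg$first_test, alg$second_test),
         parallel_arbiter = c(alg$test_a, alg$test_b, alg$arbiter),
         none = character(0))
}

#' Built-in PCD diagnostic algorithms
#'
#' The three strategies compared throughout: `"nNO+TEM"` and `"nNO+HSVM"`
#' (nNO screening, confirmation of positives by TEM or HSVM respectively)
#' and `"nNO/HSVM+TEM"` (nNO and HSVM in parallel on every referral, TEM
#' arbitrating discordant pairs). `include_baseline` prepends the
#' do-nothing strategy.
#'
#' @param include_baseline prepend the `"Do nothing"` baseline?
#' @return named list of [algorithm_spec()] objects.
#' @export
pcd_algorithms <- function(include_baseline = FALSE) {
  algs <- list(
    "nNO+TEM" = algorithm_spec("nNO+TEM", "sequential",
                               first_test = "nno", second_test = "tem"),
    "nNO+HSVM" = algorithm_spec("nNO+HSVM", "sequential",
                                first_test = "nno", second_test = "hsvm"),
    "nNO/HSVM+TEM" = algorithm_spec("nNO/HSVM+TEM", "parallel_arbiter",
                                    test_a = "nno", test_b = "hsvm",
                                    arbiter = "tem"))
  if (include_baseline)
    algs <- c(list("Do nothing" = algorithm_spec("Do nothing", "none")), algs)
  algs
}

#' Expected classification counts
#'
#' Container for the expected numbers of true/false positives/negatives
#' (reals, not rounded) for one algorithm applied to one cohort.
#'
#' @param tp,fp,tn,fn expected persons in each cell (vectors allowed).
#' @return object of class `classification_counts` (a list of the four
#'   cells).
#' @export
classification_counts <- function(tp, fp, tn, fn) {
  if (any(tp < 0 | fp < 0 | tn < 0 | fn < 0))
    stop("classification counts must be non-negative", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "classification_counts")
}

#' @export
print.classification_counts <- function(x, ...) {
  cat(sprintf("<classification_counts> TP=%g FP=%g TN=%g FN=%g (n=%g)\n",
              x$tp[1], x$fp[1], x$tn[1], x$fn[1],
              x$tp[1] + x$fp[1] + x$tn[1] + x$fn[1]))
  invisible(x)
}

# per-person cell probabilities, vectorized; the expected-value expansion of
# the probability tree under conditional independence given disease status
seq_cell_fractions <- function(prev, s1, q1, s2, q2) {
  tp <- prev * s1 * s2
  fp <- (1 - prev) * (1 - q1) * (1 - q2)
  list(tp = tp, fp = fp, tn = (1 - prev) - fp, fn = prev - tp)
}

par_cell_fractions <- function(prev, sa, qa, sb, qb, sr, qr) {
  disc_d <- sa * (1 - sb) + (1 - sa) * sb        # discordant | diseased
  disc_h <- (1 - qa) * qb + qa * (1 - qb)        # discordant | healthy
  tp <- prev * (sa * sb + disc_d * sr)
  fp <- (1 - prev) * ((1 - qa) * (1 - qb) + disc_h * (1 - qr))
  list(tp = tp, fp = fp, tn = (1 - prev) - fp, fn = prev - tp)
}

# resolve (sens, spec) pairs for an accuracy argument: a test_accuracy (best
# estimates or draws), or a numeric c(sens, spec)
acc_values <- function(test, v = NULL, conditional = FALSE) {
  if (inherits(test, "test_accuracy")) {
    se <- test$sensitivity; sp <- test$specificity
    if (conditional) {
      if (!is.null(test$conditional_sensitivity))
        se <- test$conditional_sensitivity
      if (!is.null(test$conditional_specificity))
        sp <- test$conditional_specificity
    }
    list(sens = spec_value(se, v), spec = spec_value(sp, v))
  } else if (is.numeric(test) && length(test) == 2) {
    list(sens = unname(test[1]), spec = unname(test[2]))
  } else stop("test accuracy must be a test_accuracy or c(sens, spec)",
              call. = FALSE)
}

cohort_values <- function(cohort, v = NULL) {
  if (inherits(cohort, "cohort_spec"))
    list(n = cohort$n_referrals, prev = spec_value(cohort$prevalence, v))
  else list(n = cohort$n, prev = cohort$prevalence)
}

#' Classify a cohort under sequential two-test screening
#'
#' Expected-value classification of `cohort` when `test1` screens everyone
#' and `test2` is applied only to screen-positives; a final PCD call
#' requires both tests positive, a negative screen exits as non-PCD. Test
#' outcomes are conditionally independent given disease status. If `test2`
#' is a [test_accuracy()] with conditional (post-positive-screen) accuracy
#' values those are used for the second stage.
#'
#' The same counts follow from chaining Bayes posteriors (the posterior
#' after a positive screen becomes the prior of the confirmatory test);
#' both derivations agree to numerical precision and the chained form is
#' exercised in the test-suite.
#'
#' @param cohort a [cohort_spec()] or `list(n=, prevalence=)`.
#' @param test1,test2 [test_accuracy()] objects or numeric `c(sens, spec)`.
#' @param v optional named list of parameter values (draw vectors) that
#'   override best estimates.
#' @return a [classification_counts()] in expected persons.
#' @examples
#' classify_sequential(list(n = 1000, prevalence = 0.32),
#'                     c(0.95, 0.94), c(0.74, 0.91))
#' @export
classify_sequential <- function(cohort, test1, test2, v = NULL) {
  co <- cohort_values(cohort, v)
  a1 <- acc_values(test1, v)
  a2 <- acc_values(test2, v, conditional = TRUE)
  check_prob(co$prev, a1$sens, a1$spec, a2$sens, a2$spec)
  f <- seq_cell_fractions(co$prev, a1$sens, a1$spec, a2$sens, a2$spec)
  classification_counts(f$tp * co$n, f$fp * co$n, f$tn * co$n, f$fn * co$n)
}

#' Classify a cohort under parallel testing with an arbiter
#'
#' Both first-line tests are applied to every referral. Concordant positive
#' pairs are called PCD, concordant negative pairs non-PCD, and discordant
#' pairs are settled by the arbiter's result. Expected-value counts under
#' conditional independence given disease status.
#'
#' @inheritParams classify_sequential
#' @param test_a,test_b first-line tests.
#' @param arbiter confirmatory test for discordant pairs.
#' @return a [classification_counts()] in expected persons.
#' @export
classify_parallel_arbiter <- function(cohort, test_a, test_b, arbiter,
                                      v = NULL) {
  co <- cohort_values(cohort, v)
  aa <- acc_values(test_a, v); ab <- acc_values(test_b, v)
  ar <- acc_values(arbiter, v, conditional = TRUE)
  check_prob(co$prev, aa$sens, aa$spec, ab$sens, ab$spec, ar$sens, ar$spec)
  f <- par_cell_fractions(co$prev, aa$sens, aa$spec, ab$sens, ab$spec,
                          ar$sens, ar$spec)
  classification_counts(f$tp * co$n, f$fp * co$n, f$tn * co$n, f$fn * co$n)
}

#' Classify a cohort under any algorithm topology
#'
#' Dispatches on the [algorithm_spec()] topology; the `none` baseline
#' returns an all-negative classification (every diseased person missed).
#'
#' @param algorithm an [algorithm_spec()].
#' @param params a [model_parameters()] object supplying test accuracies
#'   and the cohort.
#' @param v optional named list of parameter draws overriding best
#'   estimates (vectorized).
#' @return a [classification_counts()].
#' @export
classify_algorithm <- function(algorithm, params, v = NULL) {
  co <- cohort_values(params$cohort, v)
  switch(algorithm$topology,
    none = classification_counts(tp = 0 * co$prev, fp = 0 * co$prev,
                                 tn = (1 - co$prev) * co$n,
                                 fn = co$prev * co$n),
    sequential = classify_sequential(params$cohort,
                                     params[[algorithm$first_test]],
                                     params[[algorithm$second_test]], v),
    parallel_arbiter = classify_parallel_arbiter(params$cohort,
                                                 params[[algorithm$test_a]],
                                                 params[[algorithm$test_b]],
                                                 params[[algorithm$arbiter]],
                                                 v))
}

#' Net accuracy metrics of an algorithm's final call
#'
#' Net sensitivity `tp/(tp+fn)`, net specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`, computed from expected classification counts. A zero
#' denominator yields `NaN` with a warning naming the metric rather than a
#' silent 0.
#'
#' @param counts a [classification_counts()].
#' @return object of class `net_accuracy`: list with `net_sensitivity`,
#'   `net_specificity`, `ppv`, `npv`.
#' @examples
#' net_metrics(classification_counts(198, 2, 678, 122))
#' @export
net_metrics <- function(counts) {
  stopifnot(inherits(counts, "classification_counts"))
  ratio <- function(num, den, what) {
    if (any(den == 0)) warning(sprintf("%s undefined: zero denominator", what),
                               call. = FALSE)
    num / den
  }
  structure(list(
    net_sensitivity = ratio(counts$tp, counts$tp + counts$fn,
                            "net sensitivity"),
    net_specificity = ratio(counts$tn, counts$tn + counts$fp,
                            "net specificity"),
    ppv = ratio(counts$tp, counts$tp + counts$fp, "PPV"),
    npv = ratio(counts$tn, counts$tn + counts$fn, "NPV")),
    class = "net_accuracy")
}

#' @export
print.net_accuracy <- function(x, ...) {
  cat(sprintf(paste0("<net_accuracy> sens=%.1f%% spec=%.1f%% ",
                     "PPV=%.1f%% NPV=%.1f%%\n"),
              100 * x$net_sensitivity[1], 100 * x$net_specificity[1],
              100 * x$ppv[1], 100 * x$npv[1]))
  invisible(x)
}

#' Expected number of each test performed by an algorithm
#'
#' Sequential: the screen is applied to all `n` referrals and the
#' confirmatory test to the expected screen-positives. Parallel: both
#' first-line tests to all `n`, the arbiter to the expected discordant
#' pairs. Drives the micro-costing.
#'
#' @inheritParams classify_algorithm
#' @return named list mapping test name to expected tests/year (vectors when
#'   `v` holds draws).
#' @export
test_volumes <- function(algorithm, params, v = NULL) {
  co <- cohort_values(params$cohort, v)
  n <- co$n; prev <- co$prev
  switch(algorithm$topology,
    none = stats::setNames(list(), character(0)),
    sequential = {
      a1 <- acc_values(params[[algorithm$first_test]], v)
      pos1 <- n * (prev * a1$sens + (1 - prev) * (1 - a1$spec))
      out <- list(n + 0 * prev, pos1)
      names(out) <- c(algorithm$first_test, algorithm$second_test)
      out
    },
    parallel_arbiter = {
      aa <- acc_values(params[[algorithm$test_a]], v)
      ab <- acc_values(params[[algorithm$test_b]], v)
      disc <- n * (prev * (aa$sens * (1 - ab$sens) + (1 - aa$sens) * ab$sens) +
                   (1 - prev) * ((1 - aa$spec) * ab$spec +
                                 aa$spec * (1 - ab$spec)))
      out <- list(n + 0 * prev, n + 0 * prev, disc)
      names(out) <- c(algorithm$test_a, algorithm$test_b, algorithm$arbiter)
      out
    })
}
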