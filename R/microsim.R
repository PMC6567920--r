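#' Simulate disease states of a referral cohort
#'
#' Patient-level synthetic data: i.i.d. Bernoulli disease indicators at the
#' stated prevalence.
#'
#' @param n number of patients.
#' @param prevalence probability of disease.
#' @param seed integer seed.
#' @return logical vector of length `n`, `TRUE` = diseased.
#' @export
generate_cohort <- function(n, prevalence, seed) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  stats::runif(n) < prevalence
}

# one reproducible uniform stream per (seed, test); strategies added later
# reuse the same streams, so adding one never perturbs another's draws
test_stream <- function(n, seed, test) {
  offset <- c(nno = 1L, hsvm = 2L, tem = 3L)[[test]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) %% 1000000L) * 101L + offset)
  stats::runif(n)
}

#' Patient-level simulation of a diagnostic algorithm
#'
#' Brute-force oracle for the analytic decision model: each administered
#' test's outcome is drawn independently given the patient's disease state
#' (positive with probability sensitivity if diseased, 1 - specificity if
#' healthy), and the final call follows the algorithm's decision rule
#' exactly — sequential arms never administer the confirmatory test after a
#' negative screen; the parallel arm calls the arbiter only on discordant
#' first-line pairs. Conditional (post-positive-screen) accuracy overrides
#' in the parameter set are honoured identically to the analytic model.
#'
#' Uniform streams are derived per (seed, test), so all algorithms evaluated
#' at the same seed share their underlying test draws.
#'
#' @param disease logical vector from [generate_cohort()].
#' @param algorithm an [algorithm_spec()].
#' @param params a [model_parameters()] object (accuracies used at best
#'   estimates unless `v` overrides them).
#' @param seed integer seed for the test-outcome streams.
#' @param v optional named list of scalar parameter overrides.
#' @return list with integer `counts` (a [classification_counts()]),
#'   `volumes` (tests administered per test name), `call` (logical final
#'   calls) and `results` (per-test outcome vectors, `NA` where a test was
#'   not administered).
#' @export
simulate_algorithm <- function(disease, algorithm, params, seed, v = NULL) {
  n <- length(disease)
  draw_test <- function(test, idx, conditional = FALSE) {
    a <- acc_values(params[[test]], v, conditional = conditional)
    check_prob(a$sens, a$spec)
    u <- test_stream(n, seed, test)[idx]
    ifelse(disease[idx], u < a$sens, u < 1 - a$spec)
  }
  results <- list()
  if (algorithm$topology == "sequential") {
    t1 <- algorithm$first_test; t2 <- algorithm$second_test
    r1 <- draw_test(t1, seq_len(n))
    r2 <- rep(NA, n)
    pos <- which(r1)
    r2[pos] <- draw_test(t2, pos, conditional = TRUE)
    call <- r1 & !is.na(r2) & r2
    results[[t1]] <- r1; results[[t2]] <- r2
    volumes <- stats::setNames(list(n, length(pos)), c(t1, t2))
  } else if (algorithm$topology == "parallel_arbiter") {
    ta <- algorithm$test_a; tb <- algorithm$test_b; tr <- algorithm$arbiter
    ra <- draw_test(ta, seq_len(n))
    rb <- draw_test(tb, seq_len(n))
    rr <- rep(NA, n)
    disc <- which(ra != rb)
    rr[disc] <- draw_test(tr, disc, conditional = TRUE)
    call <- (ra & rb) | (!is.na(rr) & rr)
    results[[ta]] <- ra; results[[tb]] <- rb; results[[tr]] <- rr
    volumes <- stats::setNames(list(n, n, length(disc)), c(ta, tb, tr))
  } else {
    call <- rep(FALSE, n)
    volumes <- stats::setNames(list(), character(0))
  }
  counts <- classification_counts(
    tp = sum(disease & call), fp = sum(!disease & call),
    tn = sum(!disease & !call), fn = sum(disease & !call))
  list(counts = counts, volumes = volumes, call = call, results = results)
}

#' Export a simulated cohort patient-by-patient
#'
#' Debugging/teaching view of one [simulate_algorithm()] run: patient id,
#' disease state, each test's result (empty where not administered) and the
#' final call.
#'
#' @param disease logical disease vector.
#' @param sim result of [simulate_algorithm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(disease, sim, path) {
  df <- data.frame(patient = seq_along(disease),
                   disease = ifelse(disease, "PCD", "nonPCD"))
  for (t in names(sim$results))
    df[[t]] <- ifelse(is.na(sim$results[[t]]), "",
                      ifelse(sim$results[[t]], "+", "-"))
  df$call <- ifelse(sim$call, "PCD", "nonPCD")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
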