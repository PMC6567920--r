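#' Fixed and variable cost components of one test
#'
#' Micro-costing decomposition at point values:
#' fixed annual cost = `capital_cost / equipment_lifespan +
#' annual_maintenance` (straight-line annualization, no discounting);
#' variable cost per test = `consumables + operator_rate * test_duration +
#' physician_rate * sampling_time`.
#'
#' @param cost a [test_cost_params()] object.
#' @param v optional named list of parameter values (draw vectors).
#' @param include_sampling bill the physician brushing term? Set `FALSE`
#'   when the test reuses a brushing already billed to another test.
#' @return list with `fixed_annual` (EUR/yr) and `variable_per_test`
#'   (EUR/test); vectors when `v` holds draws.
#' @examples
#' p <- default_parameters()
#' annual_cost_components(p$nno_cost) # fixed 3966.67, variable 27.50
#' @export
annual_cost_components <- function(cost, v = NULL, include_sampling = TRUE) {
  stopifnot(inherits(cost, "test_cost_params"))
  g <- function(field) spec_value(cost[[field]], v)
  lifespan <- g("equipment_lifespan")
  if (any(lifespan <= 0)) stop("equipment lifespan must be > 0",
                               call. = FALSE)
  fixed <- g("capital_cost") / lifespan + g("annual_maintenance")
  variable <- g("consumables") + g("operator_rate") * g("test_duration")
  if (include_sampling)
    variable <- variable + g("physician_rate") * g("sampling_time")
  list(fixed_annual = fixed, variable_per_test = variable)
}

#' Annual micro-costed budget of a diagnostic algorithm
#'
#' Sums, over every test type the algorithm can use, its fixed annual cost
#' plus variable cost times expected test volume. One brushing is billed per
#' sampled patient: in the parallel arm the arbiter (TEM) works on the
#' brushing already taken for HSVM, so the arbiter's physician sampling term
#' is suppressed whenever the first-line pair already includes a
#' brushing-based test. An optional per-patient overhead (EUR/referral,
#' default 0) lets users add site costs the unit prices do not carry.
#'
#' @param algorithm an [algorithm_spec()].
#' @param params a [model_parameters()] object (cost blocks looked up as
#'   `<test>_cost`).
#' @param volumes expected tests/year per test, as from [test_volumes()];
#'   computed if omitted.
#' @param v optional named list of parameter draws.
#' @param overhead_per_patient flat EUR per referral added to the total.
#' @return object of class `cost_breakdown`: per-test data (`fixed_annual`,
#'   `variable_per_test`, `tests_performed`, `subtotal`) and `total_annual`.
#' @export
algorithm_annual_cost <- function(algorithm, params, volumes = NULL,
                                  v = NULL, overhead_per_patient = 0) {
  tests <- tests_of(algorithm)
  if (is.null(volumes)) volumes <- test_volumes(algorithm, params, v)
  if (!setequal(names(volumes), tests))
    stop("volumes do not match the algorithm's tests", call. = FALSE)
  brushing_based <- c("hsvm", "tem")
  # arbiter shares the brushing taken by a first-line brushing-based test
  shared_brushing <- algorithm$topology == "parallel_arbiter" &&
    algorithm$arbiter %in% brushing_based &&
    any(c(algorithm$test_a, algorithm$test_b) %in% brushing_based)
  per_test <- list()
  total <- 0
  for (t in tests) {
    cp <- params[[paste0(t, "_cost")]]
    if (is.null(cp)) stop(sprintf("no cost parameters for test '%s'", t),
                          call. = FALSE)
    comp <- annual_cost_components(
      cp, v,
      include_sampling = !(shared_brushing && t == algorithm$arbiter))
    sub <- comp$fixed_annual + comp$variable_per_test * volumes[[t]]
    per_test[[t]] <- list(fixed_annual = comp$fixed_annual,
                          variable_per_test = comp$variable_per_test,
                          tests_performed = volumes[[t]], subtotal = sub)
    total <- total + sub
  }
  n <- params$cohort$n_referrals
  if (algorithm$topology != "none")
    total <- total + overhead_per_patient * n
  structure(list(algorithm = algorithm$name, per_test = per_test,
                 total_annual = total), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s: total %.2f EUR/yr\n", x$algorithm,
              x$total_annual[1]))
  for (t in names(x$per_test)) {
    pt <- x$per_test[[t]]
    cat(sprintf("  %-5s fixed %.2f + %.2f x %.1f tests = %.2f\n", t,
                pt$fixed_annual[1], pt$variable_per_test[1],
                pt$tests_performed[1], pt$subtotal[1]))
  }
  invisible(x)
}
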