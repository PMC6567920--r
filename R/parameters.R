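#' Diagnostic accuracy of a single test
#'
#' Bundles the sensitivity and specificity of one diagnostic test, each as a
#' [dist_spec()]. Optional conditional variants describe the test's accuracy
#' when it is used as a second-stage confirmatory test after a positive
#' screen (accuracy conditional on screen-positivity can differ from the
#' marginal accuracy when test errors are correlated in reality); they
#' default to `NULL`, meaning the marginal values are reused.
#'
#' @param sensitivity,specificity [dist_spec()] objects (probability-typed).
#' @param conditional_sensitivity,conditional_specificity optional
#'   [dist_spec()] overrides for post-positive-screen use.
#' @return object of class `test_accuracy`.
#' @export
test_accuracy <- function(sensitivity, specificity,
                          conditional_sensitivity = NULL,
                          conditional_specificity = NULL) {
  for (s in list(sensitivity, specificity)) {
    stopifnot(inherits(s, "dist_spec"))
    if (s$best < 0 || s$best > 1)
      stop(sprintf("parameter '%s': accuracy best estimate outside [0,1]",
                   s$name), call. = FALSE)
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 conditional_sensitivity = conditional_sensitivity,
                 conditional_specificity = conditional_specificity),
            class = "test_accuracy")
}

#' Annual referral cohort
#'
#' @param n_referrals persons referred for diagnostic work-up per year.
#' @param prevalence [dist_spec()] for the disease prevalence among
#'   referrals (probability-typed).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_referrals, prevalence) {
  stopifnot(n_referrals >= 1, inherits(prevalence, "dist_spec"))
  structure(list(n_referrals = as.numeric(n_referrals),
                 prevalence = prevalence),
            class = "cohort_spec")
}

#' Micro-costing parameters for one test
#'
#' Every field is a [dist_spec()]. Fixed annual cost is
#' `capital_cost / equipment_lifespan + annual_maintenance`; variable cost
#' per test is `consumables + operator_rate * test_duration +
#' physician_rate * sampling_time` (the physician term covers the nasal
#' brushing where one is needed; use point-zero specs for tests without a
#' physician sampling step).
#'
#' @param capital_cost equipment purchase price (EUR).
#' @param equipment_lifespan straight-line depreciation horizon (years).
#' @param annual_maintenance maintenance contract (EUR/year).
#' @param consumables per-test consumables (EUR/test).
#' @param operator_rate operator wage (EUR/hour).
#' @param test_duration hands-on analysis time (hours/test).
#' @param physician_rate physician wage for sampling (EUR/hour).
#' @param sampling_time brushing time (hours/test).
#' @return object of class `test_cost_params`.
#' @export
test_cost_params <- function(capital_cost, equipment_lifespan,
                             annual_maintenance, consumables, operator_rate,
                             test_duration, physician_rate, sampling_time) {
  out <- structure(list(capital_cost = capital_cost,
                        equipment_lifespan = equipment_lifespan,
                        annual_maintenance = annual_maintenance,
                        consumables = consumables,
                        operator_rate = operator_rate,
                        test_duration = test_duration,
                        physician_rate = physician_rate,
                        sampling_time = sampling_time),
                   class = "test_cost_params")
  for (s in out) {
    stopifnot(inherits(s, "dist_spec"))
    if (s$best < 0)
      stop(sprintf("parameter '%s': cost parameters must be non-negative",
                   s$name), call. = FALSE)
  }
  if (out$equipment_lifespan$best <= 0)
    stop("equipment lifespan must be > 0", call. = FALSE)
  out
}

#' Full model parameter set
#'
#' The container consumed by the deterministic model, the PSA engine and the
#' microsimulation: a cohort, the accuracy of the three tests, their cost
#' parameters, and execution settings.
#'
#' @param cohort a [cohort_spec()].
#' @param nno,hsvm,tem [test_accuracy()] objects.
#' @param nno_cost,hsvm_cost,tem_cost [test_cost_params()] objects.
#' @param n_iterations default PSA iteration count.
#' @param seed default integer seed.
#' @return object of class `model_parameters`.
#' @seealso [default_parameters()] for the shipped best-evidence values.
#' @export
model_parameters <- function(cohort, nno, hsvm, tem,
                             nno_cost, hsvm_cost, tem_cost,
                             n_iterations = 3000, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(nno, "test_accuracy"), inherits(hsvm, "test_accuracy"),
            inherits(tem, "test_accuracy"),
            inherits(nno_cost, "test_cost_params"),
            inherits(hsvm_cost, "test_cost_params"),
            inherits(tem_cost, "test_cost_params"),
            n_iterations >= 1)
  structure(list(cohort = cohort, nno = nno, hsvm = hsvm, tem = tem,
                 nno_cost = nno_cost, hsvm_cost = hsvm_cost,
                 tem_cost = tem_cost,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "model_parameters")
}

# every dist_spec in a parameter set, flattened
all_specs <- function(params) {
  out <- list(params$cohort$prevalence)
  for (t in c("nno", "hsvm", "tem")) {
    ta <- params[[t]]
    out <- c(out, list(ta$sensitivity, ta$specificity),
             Filter(Negate(is.null),
                    list(ta$conditional_sensitivity,
                         ta$conditional_specificity)))
  }
  for (t in c("nno_cost", "hsvm_cost", "tem_cost"))
    out <- c(out, unclass(params[[t]]))
  out
}

#' Unique uncertain-parameter specifications of a model
#'
#' Flattens a [model_parameters()] object into the named list of distinct
#' [dist_spec()]s (shared parameters such as the physician rate appear
#' once). This defines the column set of LHS draw tables.
#'
#' @param params a [model_parameters()] object.
#' @return named list of `dist_spec` objects.
#' @export
param_specs <- function(params) {
  specs <- all_specs(params)
  nms <- vapply(specs, `[[`, character(1), "name")
  keep <- !duplicated(nms)
  specs <- specs[keep]
  names(specs) <- nms[keep]
  specs
}

#' Best-estimate values of every model parameter
#'
#' @param params a [model_parameters()] object.
#' @return named list of scalars (one per unique parameter).
#' @export
best_estimates <- function(params) {
  lapply(param_specs(params), `[[`, "best")
}

#' Replace every distribution by a point mass at its best estimate
#'
#' Useful for deterministic runs and for the degenerate-PSA identity checks.
#'
#' @param params a [model_parameters()] object.
#' @return a [model_parameters()] object with all families set to `point`.
#' @export
as_point_parameters <- function(params) {
  pointify <- function(s) {
    if (is.null(s)) return(NULL)
    dist_spec(s$name, "point", s$best, probability = s$probability)
  }
  walk <- function(x) {
    if (inherits(x, "dist_spec")) return(pointify(x))
    if (is.list(x)) {
      cl <- class(x)
      x <- lapply(x, function(e) if (is.list(e) || inherits(e, "dist_spec"))
        walk(e) else e)
      class(x) <- cl
      return(x)
    }
    x
  }
  walk(params)
}

# look up a parameter value in a named list of draws (vectors) falling back
# to the spec's best estimate
spec_value <- function(spec, v = NULL) {
  if (!is.null(v) && spec$name %in% names(v)) v[[spec$name]] else spec$best
}

#' Best-evidence default parameter set
#'
#' The shipped parameter table: a referral cohort of 1000 persons/year with
#' PCD prevalence 0.32 (normal, SD 0.028), meta-analytic accuracy estimates
#' for nNO during velum closure (sens 0.95, spec 0.94), HSVM (sens 1.00 with
#' sampling mean 0.99, spec 0.92) and TEM (sens 0.74, spec 0.91), and
#' market-value micro-costing inputs for each test. The physician rate and
#' the 0.2 h brushing time are shared between HSVM and TEM, which both work
#' on a nasal brushing; nNO needs no brushing.
#'
#' @param n_referrals cohort size per year (default 1000).
#' @param n_iterations default PSA iterations (default 3000).
#' @param seed default seed.
#' @return a [model_parameters()] object.
#' @export
default_parameters <- function(n_referrals = 1000, n_iterations = 3000,
                               seed = 1L) {
  p <- function(...) dist_spec(..., probability = TRUE)
  prevalence <- p("prevalence", "normal", 0.32, 0.25, 0.39, sd = 0.028)

  nno <- test_accuracy(p("nno_sens", "beta", 0.95, 0.91, 0.97),
                       p("nno_spec", "beta", 0.94, 0.88, 0.97))
  # best estimate 1.00 sits on the beta boundary; the published sampling
  # distribution uses mean 0.99
  hsvm <- test_accuracy(p("hsvm_sens", "beta", 1.00, 0.89, 1.00, mean = 0.99),
                        p("hsvm_spec", "beta", 0.92, 0.86, 0.96))
  tem <- test_accuracy(p("tem_sens", "beta", 0.74, 0.66, 0.83),
                       p("tem_spec", "beta", 0.91, 0.86, 0.96))

  d <- dist_spec
  physician <- d("physician_rate", "gamma", 50, 30, 70)
  brushing <- d("brushing_time", "point", 0.2)
  no_physician <- d("nno_no_physician", "point", 0)
  no_sampling <- d("nno_no_sampling", "point", 0)

  nno_cost <- test_cost_params(
    capital_cost = d("nno_capital", "gamma", 40000, 36000, 44000),
    equipment_lifespan = d("nno_lifespan", "normal", 15, 13, 17, sd = 1),
    annual_maintenance = d("nno_maintenance", "gamma", 1300, 1100, 1500),
    consumables = d("nno_consumables", "gamma", 15, 9, 21),
    operator_rate = d("nno_operator_rate", "gamma", 25, 10, 35),
    test_duration = d("nno_duration", "normal", 0.5, 0.3, 0.7, sd = 0.1),
    physician_rate = no_physician, sampling_time = no_sampling)

  hsvm_cost <- test_cost_params(
    capital_cost = d("hsvm_capital", "gamma", 5000, 3000, 7000),
    equipment_lifespan = d("hsvm_lifespan", "normal", 15, 10, 20, sd = 2),
    annual_maintenance = d("hsvm_maintenance", "point", 0),
    consumables = d("hsvm_consumables", "gamma", 30, 26, 34),
    operator_rate = d("hsvm_operator_rate", "gamma", 25, 10, 35),
    test_duration = d("hsvm_duration", "normal", 2, 1.6, 2.4, sd = 0.2),
    physician_rate = physician, sampling_time = brushing)

  tem_cost <- test_cost_params(
    capital_cost = d("tem_capital", "gamma", 100000, 90000, 110000),
    equipment_lifespan = d("tem_lifespan", "normal", 30, 20, 40, sd = 5),
    annual_maintenance = d("tem_maintenance", "gamma", 2000, 1300, 2600),
    consumables = d("tem_consumables", "gamma", 120, 90, 140),
    operator_rate = d("tem_operator_rate", "gamma", 25, 10, 35),
    test_duration = d("tem_duration", "lognormal", 10, 6, 18,
                      median = 10, gsd = 1.3),
    physician_rate = physician, sampling_time = brushing)

  model_parameters(
    cohort = cohort_spec(n_referrals, prevalence),
    nno = nno, hsvm = hsvm, tem = tem,
    nno_cost = nno_cost, hsvm_cost = hsvm_cost, tem_cost = tem_cost,
    n_iterations = n_iterations, seed = seed)
}

spec_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  keep <- s[c("name", "family", "best", "ci_low", "ci_high", "sd", "median",
              "gsd", "mean", "probability")]
  keep[!vapply(keep, function(x) is.numeric(x) && !is.finite(x), logical(1))]
}

spec_from_list <- function(l) {
  g <- function(k, default = NA_real_) if (is.null(l[[k]])) default else l[[k]]
  dist_spec(l$name, l$family, l$best, g("ci_low"), g("ci_high"), g("sd"),
            g("median"), g("gsd"), g("mean"),
            probability = isTRUE(l$probability))
}

#' Write a model configuration file
#'
#' Serializes a [model_parameters()] object to JSON: one block per
#' parameter with keys `family`, `best`, `ci_low`, `ci_high`, `sd`,
#' `median`, `gsd` (plus `mean`/`probability` where relevant). The shipped
#' default configuration (`system.file("extdata", "default_config.json",
#' package = "pcdcea")`) reproduces the best-evidence table verbatim.
#'
#' @param params a [model_parameters()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  ta_list <- function(ta)
    Filter(Negate(is.null),
           list(sensitivity = spec_to_list(ta$sensitivity),
                specificity = spec_to_list(ta$specificity),
                conditional_sensitivity =
                  spec_to_list(ta$conditional_sensitivity),
                conditional_specificity =
                  spec_to_list(ta$conditional_specificity)))
  cfg <- list(
    cohort = list(n_referrals = params$cohort$n_referrals,
                  prevalence = spec_to_list(params$cohort$prevalence)),
    tests = list(nno = ta_list(params$nno), hsvm = ta_list(params$hsvm),
                 tem = ta_list(params$tem)),
    costs = lapply(params[c("nno_cost", "hsvm_cost", "tem_cost")],
                   function(cp) lapply(unclass(cp), spec_to_list)),
    n_iterations = params$n_iterations,
    seed = params$seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a model configuration file
#'
#' Inverse of [write_config()]. Validation errors name the offending
#' parameter block.
#'
#' @param path JSON configuration path.
#' @return a [model_parameters()] object.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- setdiff(c("cohort", "tests", "costs"), names(cfg))
  if (length(need))
    stop("config missing top-level keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  ta_from <- function(l)
    test_accuracy(spec_from_list(l$sensitivity),
                  spec_from_list(l$specificity),
                  if (!is.null(l$conditional_sensitivity))
                    spec_from_list(l$conditional_sensitivity),
                  if (!is.null(l$conditional_specificity))
                    spec_from_list(l$conditional_specificity))
  cp_from <- function(l) do.call(test_cost_params, lapply(l, spec_from_list))
  model_parameters(
    cohort = cohort_spec(cfg$cohort$n_referrals,
                         spec_from_list(cfg$cohort$prevalence)),
    nno = ta_from(cfg$tests$nno), hsvm = ta_from(cfg$tests$hsvm),
    tem = ta_from(cfg$tests$tem),
    nno_cost = cp_from(cfg$costs$nno_cost),
    hsvm_cost = cp_from(cfg$costs$hsvm_cost),
    tem_cost = cp_from(cfg$costs$tem_cost),
    n_iterations = if (is.null(cfg$n_iterations)) 3000 else cfg$n_iterations,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
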