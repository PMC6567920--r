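#' Describe one uncertain model parameter
#'
#' A `dist_spec` captures one row of the model's parameter table: a
#' distribution family, a deterministic best estimate, and the information
#' needed to reconstruct the 95% uncertainty interval. Probability-typed
#' parameters (prevalence, sensitivities, specificities) are constrained to
#' \eqn{[0,1]} and their draws are truncated to that range.
#'
#' Families:
#' \describe{
#'   \item{`point`}{degenerate; CI fields ignored, every draw equals `best`.}
#'   \item{`normal`}{mean `best`; `sd` used if supplied, otherwise derived
#'     from the CI half-width divided by 1.959964.}
#'   \item{`lognormal`}{parameterised by `median` and geometric standard
#'     deviation `gsd` (> 1).}
#'   \item{`beta`, `gamma`}{mean fixed at `mean` (default `best`); the
#'     remaining shape freedom is used to reproduce the 95% CI as closely as
#'     a two-parameter family allows (root-finding, residual reported).}
#' }
#'
#' @param name parameter name (column name in draw tables).
#' @param family one of `"beta"`, `"gamma"`, `"normal"`, `"lognormal"`,
#'   `"point"`.
#' @param best best (deterministic) estimate, in the parameter's units.
#' @param ci_low,ci_high 95% interval endpoints; ignored for `point`.
#' @param sd optional standard deviation (normal only).
#' @param median,gsd lognormal location (median) and geometric SD (> 1).
#' @param mean optional distribution mean used for fitting when it must
#'   differ from `best` (e.g. a probability with best estimate exactly 1,
#'   where a beta mean of 1 is degenerate). Defaults to `best`.
#' @param probability logical; constrain the parameter (and its draws) to
#'   \eqn{[0,1]}.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("nno_sens", "beta", 0.95, 0.91, 0.97, probability = TRUE)
#' dist_spec("brushing_time", "point", 0.2)
#' @export
dist_spec <- function(name, family = c("beta", "gamma", "normal", "lognormal",
                                       "point"),
                      best, ci_low = NA_real_, ci_high = NA_real_,
                      sd = NA_real_, median = NA_real_, gsd = NA_real_,
                      mean = NA_real_, probability = FALSE) {
  family <- match.arg(family)
  spec <- structure(
    list(name = as.character(name), family = family, best = as.numeric(best),
         ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
         sd = as.numeric(sd), median = as.numeric(median),
         gsd = as.numeric(gsd),
         mean = if (is.na(mean)) as.numeric(best) else as.numeric(mean),
         probability = isTRUE(probability)),
    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

#' Validate a distribution specification
#'
#' Checks the `dist_spec` invariants: CI brackets the best estimate,
#' probability parameters lie in \eqn{[0,1]}, lognormal `gsd > 1`, and the
#' family has the information it needs. Errors name the offending parameter.
#'
#' @param spec a [dist_spec()].
#' @return `spec`, invisibly.
#' @export
validate_dist_spec <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  nm <- spec$name
  fail <- function(msg) stop(sprintf("parameter '%s': %s", nm, msg),
                             call. = FALSE)
  if (!is.finite(spec$best)) fail("best estimate must be finite")
  if (spec$family != "point") {
    has_ci <- is.finite(spec$ci_low) && is.finite(spec$ci_high)
    if (spec$family == "lognormal") {
      if (!is.finite(spec$median) || !is.finite(spec$gsd))
        fail("lognormal requires median and gsd")
      if (spec$gsd <= 1) fail("lognormal gsd must be > 1")
    } else if (spec$family == "normal") {
      if (!is.finite(spec$sd) && !has_ci)
        fail("normal requires sd or a 95% CI")
      if (is.finite(spec$sd) && spec$sd <= 0) fail("sd must be > 0")
    } else {
      if (!has_ci) fail(sprintf("%s requires a 95% CI", spec$family))
    }
    if (has_ci) {
      if (spec$ci_low > spec$ci_high) fail("ci_low exceeds ci_high")
      if (spec$ci_low > spec$best || spec$best > spec$ci_high)
        fail("95% CI does not bracket the best estimate")
    }
  }
  if (spec$probability) {
    vals <- c(spec$best, spec$mean,
              if (is.finite(spec$ci_low)) spec$ci_low,
              if (is.finite(spec$ci_high)) spec$ci_high)
    if (any(vals < 0 | vals > 1))
      fail("probability-typed values must lie in [0,1]")
  }
  if (spec$family == "beta" && (spec$mean <= 0 || spec$mean >= 1))
    fail("beta mean must lie strictly inside (0,1); supply mean= for boundary best estimates")
  if (spec$family == "gamma" && spec$mean <= 0) fail("gamma mean must be > 0")
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  ci <- if (is.finite(x$ci_low)) sprintf(" (%g-%g)", x$ci_low, x$ci_high) else ""
  cat(sprintf("<dist_spec> %s: %s %g%s%s\n", x$name, x$family, x$best, ci,
              if (x$probability) " [probability]" else ""))
  invisible(x)
}

z975 <- stats::qnorm(0.975)  # 1.959964

# 1-D fit of the free concentration parameter so that the (0.025, 0.975)
# quantiles reproduce the stated CI as closely as the family allows, with the
# mean held fixed. Returns list(par, residual).
fit_two_param_ci <- function(qfun, mean, ci_low, ci_high) {
  obj <- function(logk) {
    q <- qfun(c(0.025, 0.975), exp(logk))
    (q[1] - ci_low)^2 + (q[2] - ci_high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-3), log(1e8)))
  list(k = exp(opt$minimum), residual = sqrt(opt$objective))
}

#' Fit a sampling distribution to a parameter specification
#'
#' Turns a [dist_spec()] into a `fitted_dist`: an object exposing
#' `quantile(u)` for \eqn{u \in (0,1)}, the analytic mean, and the residual
#' distance between the fitted (0.025, 0.975) quantiles and the stated CI.
#' For beta and gamma the mean is matched exactly (to within root-finding
#' precision) and the spread is fitted to the CI; for the normal family the
#' stated `sd` wins over the CI; the lognormal is exact in (median, gsd).
#'
#' Probability-typed parameters get a truncated quantile function: `u` is
#' mapped into the feasible quantile range of \eqn{[0,1]} before inversion,
#' so draws never leave the unit interval.
#'
#' @param spec a [dist_spec()].
#' @return an object of class `fitted_dist` with elements `spec`, `family`,
#'   `par` (named parameter vector), `mean`, `residual`, and function
#'   `quantile`.
#' @examples
#' fd <- fit_distribution(dist_spec("tem_dur", "lognormal", 10,
#'                                  median = 10, gsd = 1.3))
#' fd$quantile(0.5) # 10
#' @export
fit_distribution <- function(spec) {
  validate_dist_spec(spec)
  par <- c(); resid <- 0; mn <- spec$mean
  qraw <- switch(spec$family,
    point = {
      mn <- spec$best
      function(u) rep(spec$best, length(u))
    },
    normal = {
      sd <- if (is.finite(spec$sd)) spec$sd else
        (spec$ci_high - spec$ci_low) / (2 * z975)
      par <- c(mean = mn, sd = sd)
      if (is.finite(spec$ci_low)) {
        q <- stats::qnorm(c(0.025, 0.975), mn, sd)
        resid <- sqrt(sum((q - c(spec$ci_low, spec$ci_high))^2))
      }
      function(u) stats::qnorm(u, mn, sd)
    },
    lognormal = {
      mu <- log(spec$median); sig <- log(spec$gsd)
      mn <- exp(mu + sig^2 / 2)
      par <- c(meanlog = mu, sdlog = sig)
      function(u) stats::qlnorm(u, mu, sig)
    },
    beta = {
      m <- mn
      fit <- fit_two_param_ci(function(p, k) stats::qbeta(p, m * k, (1 - m) * k),
                              m, spec$ci_low, spec$ci_high)
      par <- c(shape1 = m * fit$k, shape2 = (1 - m) * fit$k)
      resid <- fit$residual
      function(u) stats::qbeta(u, par[["shape1"]], par[["shape2"]])
    },
    gamma = {
      m <- mn
      fit <- fit_two_param_ci(function(p, k) stats::qgamma(p, shape = k,
                                                           scale = m / k),
                              m, spec$ci_low, spec$ci_high)
      par <- c(shape = fit$k, scale = m / fit$k)
      resid <- fit$residual
      function(u) stats::qgamma(u, shape = par[["shape"]], scale = par[["scale"]])
    })
  qfun <- qraw
  if (spec$probability && spec$family %in% c("normal", "lognormal", "gamma")) {
    # renormalize u into the quantile range feasible for [0,1]
    pfun <- switch(spec$family,
      normal = function(x) stats::pnorm(x, par[["mean"]], par[["sd"]]),
      lognormal = function(x) stats::plnorm(x, par[["meanlog"]], par[["sdlog"]]),
      gamma = function(x) stats::pgamma(x, shape = par[["shape"]],
                                        scale = par[["scale"]]))
    p0 <- pfun(0); p1 <- pfun(1)
    qfun <- function(u) pmin(1, pmax(0, qraw(p0 + u * (p1 - p0))))
  }
  structure(list(spec = spec, family = spec$family, par = par, mean = mn,
                 residual = resid, quantile = qfun),
            class = "fitted_dist")
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("<fitted_dist> %s [%s] mean=%g residual=%.3g\n",
              x$spec$name, x$family, x$mean, x$residual))
  if (length(x$par))
    cat("  par:", paste(names(x$par), signif(x$par, 6), sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Latin Hypercube sample of the uncertain parameters
#'
#' Draws `n_iter` stratified samples from every distribution in `specs`.
#' Each parameter's \eqn{(0,1)} scale is cut into `n_iter` equal-probability
#' strata; exactly one uniform is drawn in each stratum and the strata are
#' independently permuted per parameter, then mapped through the fitted
#' quantile function. The same seed reproduces the table bitwise.
#'
#' @param specs a list of [dist_spec()] objects (or a [model_parameters()]
#'   object, whose unique parameter set is used).
#' @param n_iter number of iterations (rows), >= 1.
#' @param seed integer seed; mandatory, no wall-clock default.
#' @return a `data.frame` with `n_iter` rows, one column per parameter name.
#' @export
sample_lhs <- function(specs, n_iter, seed) {
  if (inherits(specs, "model_parameters")) specs <- param_specs(specs)
  stopifnot(n_iter >= 1, length(specs) >= 1)
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  fits <- lapply(specs, fit_distribution)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  us <- lapply(fits, function(f)
    (sample.int(n_iter) - stats::runif(n_iter)) / n_iter)
  cols <- Map(function(f, u) f$quantile(u), fits, us)
  nms <- vapply(specs, function(s) s$name, character(1))
  names(cols) <- nms
  names(us) <- nms
  out <- as.data.frame(cols, check.names = FALSE)
  # stratified uniforms retained for audit: draw i of parameter j lies in
  # stratum floor(u_ij * n_iter) of its marginal
  attr(out, "lhs_u") <- as.data.frame(us, check.names = FALSE)
  out
}
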