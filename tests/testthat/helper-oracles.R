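# Independent oracles and small builders shared across the test files.

# enumeration of the 2x2 joint probability table (disease x test result);
# posteriors computed as conditional probabilities from the joint cells,
# independently of the closed-form Bayes implementation
enum_posterior <- function(prior, sens, spec, result = c("pos", "neg")) {
  result <- match.arg(result)
  joint <- matrix(c(prior * sens,          prior * (1 - sens),
                    (1 - prior) * (1 - spec), (1 - prior) * spec),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("D", "H"), c("pos", "neg")))
  joint["D", result] / sum(joint[, result])
}

# sequential classification derived by chaining Bayes posteriors (the
# posterior after the screen becomes the prior of the confirmatory test);
# an algebraically distinct route from the probability-tree product used in
# classify_sequential
chain_sequential <- function(n, prev, s1, q1, s2, q2) {
  ppos1 <- prev * s1 + (1 - prev) * (1 - q1)
  post1 <- posterior_positive(prev, s1, q1)
  postn1 <- posterior_negative(prev, s1, q1)
  ppos2 <- post1 * s2 + (1 - post1) * (1 - q2)
  post2 <- posterior_positive(post1, s2, q2)
  postn2 <- posterior_negative(post1, s2, q2)
  tp <- n * ppos1 * ppos2 * post2
  fp <- n * ppos1 * ppos2 * (1 - post2)
  fn <- n * ((1 - ppos1) * postn1 + ppos1 * (1 - ppos2) * postn2)
  tn <- n * ((1 - ppos1) * (1 - postn1) + ppos1 * (1 - ppos2) * (1 - postn2))
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# random valid accuracy/prevalence grids for property tests
random_probs <- function(n, seed, lo = 0.05, hi = 0.99) {
  set.seed(seed)
  matrix(runif(n * 7, lo, hi), ncol = 7,
         dimnames = list(NULL, c("prev", "sa", "qa", "sb", "qb", "sr", "qr")))
}

# hand-built psa_table with known increments (for CEAC / estimator tests)
fake_psa <- function(cost, effect) {
  stopifnot(identical(names(cost), names(effect)))
  structure(list(draws = data.frame(row = seq_along(cost[[1]])),
                 cost = as.data.frame(cost, check.names = FALSE),
                 effect = as.data.frame(effect, check.names = FALSE),
                 strategies = names(cost), n_iter = length(cost[[1]]),
                 seed = 0L),
            class = "psa_table")
}

expect_counts_equal <- function(counts, expected, tol = 1e-9) {
  for (cell in c("tp", "fp", "tn", "fn"))
    expect_equal(counts[[cell]], expected[[cell]], tolerance = tol)
}

# binomial 3-SE band check of a simulated fraction against an analytic one
expect_within_3se <- function(frac_sim, frac_true, n, label = "") {
  se <- sqrt(pmax(frac_true * (1 - frac_true), 1e-12) / n)
  expect_lt(abs(frac_sim - frac_true), 3 * se + 1e-12,
            label = sprintf("%s |%g - %g|", label, frac_sim, frac_true))
}
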