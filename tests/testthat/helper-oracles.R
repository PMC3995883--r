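# Independent oracles used across the suite. These deliberately use
# brute-force or closed-form routes distinct from the package internals.

# AUC by explicit pair counting with half credit for ties
brute_auc <- function(case_scores, ctrl_scores) {
  pairs <- outer(case_scores, ctrl_scores, function(a, b) {
    (a < b) + 0.5 * (a == b)
  })
  mean(pairs)
}

# Trapezoidal area under (1 - spec, sens) points
trapezoid_auc <- function(sens, spec) {
  x <- 1 - spec
  ord <- order(x, sens)
  x <- c(0, x[ord], 1)
  y <- c(0, sens[ord], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Exhaustive Youden search over all midpoint thresholds
# (positive = score strictly below threshold); returns every maximizer.
exhaustive_youden <- function(scores, is_case) {
  vals <- sort(unique(scores))
  th <- c(vals[1] - 0.5,
          if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2,
          vals[length(vals)] + 0.5)
  j <- vapply(th, function(t) {
    mean(scores[is_case] < t) + mean(scores[!is_case] >= t) - 1
  }, numeric(1))
  list(thresholds = th, j = j, best = th[j == max(j)], jmax = max(j))
}

# Bounded-normal moments by adaptive quadrature (plus boundary masses
# for the censored family) -- independent of the closed-form route.
quadrature_moments <- function(mu, sigma, lower, upper, type) {
  if (type == "truncated") {
    z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma),
                          lower, upper, rel.tol = 1e-12)$value
    m <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                          lower, upper, rel.tol = 1e-12)$value / z
    e2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma),
                           lower, upper, rel.tol = 1e-12)$value / z
  } else {
    p_lo <- stats::pnorm(lower, mu, sigma)
    p_hi <- stats::pnorm(upper, mu, sigma, lower.tail = FALSE)
    mi <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                           lower, upper, rel.tol = 1e-12)$value
    e2i <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma),
                            lower, upper, rel.tol = 1e-12)$value
    m <- lower * p_lo + upper * p_hi + mi
    e2 <- lower^2 * p_lo + upper^2 * p_hi + e2i
  }
  c(mean = m, sd = sqrt(e2 - m^2))
}

# First-order partial correlation by the closed-form recursion
partial_r_recursion <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Two-covariate partial correlation via the recursion applied twice
partial_r_two_covariates <- function(x, y, z1, z2) {
  r <- function(a, b) stats::cor(a, b)
  rxy_1 <- partial_r_recursion(r(x, y), r(x, z1), r(y, z1))
  rxz2_1 <- partial_r_recursion(r(x, z2), r(x, z1), r(z2, z1))
  ryz2_1 <- partial_r_recursion(r(y, z2), r(y, z1), r(z2, z1))
  partial_r_recursion(rxy_1, rxz2_1, ryz2_1)
}

# Small well-formed cohort data.frame for I/O tests
make_test_records <- function(n = 3) {
  data.frame(
    id = sprintf("T%03d", seq_len(n)),
    age = rep(c(60, 70, 80), length.out = n),
    education_years = rep(c(12, 8, 0), length.out = n),
    education_level = rep(c("higher", "middle", "illiterate"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    group = rep(c("NC", "MCI", "AD"), length.out = n),
    mmse = rep(c(29, 26, 15), length.out = n),
    adl = rep(c(10, 12, 20), length.out = n),
    cdr_global = rep(c(0, 0.5, 1), length.out = n),
    cdr_memory = rep(c(0, 0.5, 1), length.out = n),
    his = rep(c(1, 2, 3), length.out = n),
    hamd17 = rep(c(3, 5, 2), length.out = n),
    isr = rep(c(32, 15, 5), length.out = n),
    dsr = rep(c(28, 10, 1), length.out = n),
    dsr_retest = rep(c(NA, 11, NA), length.out = n),
    stringsAsFactors = FALSE
  )
}
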