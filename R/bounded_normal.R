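# Moment-matched normals on a bounded score range.
#
# Bounded integer scores (story recall 0-56, MMSE 0-30) cannot follow an
# untruncated normal when the printed group SD is large relative to the
# distance from the bounds. Two latent-normal families are supported:
#
#   * truncated: the latent normal conditioned on [lower, upper] -- a
#     smooth density, right model for groups away from the floor/ceiling;
#   * censored: the latent normal clipped to [lower, upper] -- probability
#     mass AT the bounds, the right model for severe floor effects (many
#     zero scores with a thin right tail), where a truncated normal cannot
#     reach a coefficient of variation above 1.
#
# All tail computations are done in log space so extreme latent parameters
# (the moment match can need |mu| many SDs outside the range) stay stable.

# log(exp(lx) - exp(ly)) for lx > ly
logspace_sub <- function(lx, ly) lx + log1p(-exp(ly - lx))

# log P(lower < X < upper) for X ~ N(mu, sigma), stable in both tails
log_z_interval <- function(al, be) {
  if (al >= 0) {
    logspace_sub(stats::pnorm(al, lower.tail = FALSE, log.p = TRUE),
                 stats::pnorm(be, lower.tail = FALSE, log.p = TRUE))
  } else if (be <= 0) {
    logspace_sub(stats::pnorm(be, log.p = TRUE),
                 stats::pnorm(al, log.p = TRUE))
  } else {
    log(stats::pnorm(be) - stats::pnorm(al))
  }
}

#' Moments of a truncated or censored normal
#'
#' Exact mean and SD of a latent `N(mu, sigma)` restricted to
#' `[lower, upper]` by truncation (conditioning) or censoring (clipping).
#'
#' @param mu,sigma latent normal parameters (`sigma > 0`).
#' @param lower,upper range bounds.
#' @param type `"truncated"` or `"censored"`.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
bounded_normal_moments <- function(mu, sigma, lower, upper,
                                   type = c("truncated", "censored")) {
  type <- match.arg(type)
  stopifnot(sigma > 0, lower < upper)
  al <- (lower - mu) / sigma
  be <- (upper - mu) / sigma
  lz <- log_z_interval(al, be)
  d_al <- exp(stats::dnorm(al, log = TRUE) - lz)
  d_be <- exp(stats::dnorm(be, log = TRUE) - lz)
  m_tr <- mu + sigma * (d_al - d_be)
  v_tr <- sigma^2 * (1 + al * d_al - be * d_be - (d_al - d_be)^2)
  v_tr <- max(v_tr, 0)
  if (type == "truncated") {
    return(c(mean = m_tr, sd = sqrt(v_tr)))
  }
  p_lo <- stats::pnorm(al)
  p_hi <- stats::pnorm(be, lower.tail = FALSE)
  z <- exp(lz)
  m <- lower * p_lo + upper * p_hi + z * m_tr
  ex2 <- lower^2 * p_lo + upper^2 * p_hi + z * (v_tr + m_tr^2)
  c(mean = m, sd = sqrt(max(ex2 - m^2, 0)))
}

# Solve mean(mu | sigma) = target for fixed sigma; the bounded-normal mean
# is strictly increasing in mu with limits (lower, upper), so an expanding
# bracket plus uniroot always works for feasible targets.
.solve_mu <- function(target_mean, sigma, lower, upper, type) {
  f <- function(mu) {
    bounded_normal_moments(mu, sigma, lower, upper, type)[["mean"]] - target_mean
  }
  lo <- target_mean - sigma
  hi <- target_mean + sigma
  for (i in 1:60) {
    if (f(lo) < 0) break
    lo <- target_mean - sigma * 2^i
  }
  for (i in 1:60) {
    if (f(hi) > 0) break
    hi <- target_mean + sigma * 2^i
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

solve_bounded_normal <- function(target_mean, target_sd, lower = 0,
                                 upper = 56,
                                 type = c("truncated", "censored"),
                                 tol = 1e-6) {
  type <- match.arg(type)
  if (!(lower < target_mean && target_mean < upper)) {
    stop("target mean must lie strictly inside [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  if (target_sd <= 0) stop("target SD must be positive", call. = FALSE)
  half <- (upper - lower) / 2
  if (target_sd >= half) {
    stop(sprintf(
      "infeasible target: no distribution on [%g, %g] has SD >= %g (the two-point maximum)",
      lower, upper, half), call. = FALSE)
  }

  # Along the mean-matched path the achieved SD grows with the latent
  # sigma, from 0 towards the family's supremum; bracket in log(sigma).
  g <- function(ls) {
    sigma <- exp(ls)
    mu <- .solve_mu(target_mean, sigma, lower, upper, type)
    bounded_normal_moments(mu, sigma, lower, upper, type)[["sd"]] - target_sd
  }
  ls_lo <- log(target_sd) - 2
  ls_hi <- log(target_sd) + 2
  ls_cap_lo <- log((upper - lower) * 1e-9)
  ls_cap_hi <- log((upper - lower) * 1e5)
  while (g(ls_lo) > 0 && ls_lo > ls_cap_lo) ls_lo <- ls_lo - 2
  while (g(ls_hi) < 0 && ls_hi < ls_cap_hi) ls_hi <- ls_hi + 2
  if (g(ls_hi) < 0 || g(ls_lo) > 0) {
    stop(sprintf(
      "infeasible target: a %s normal on [%g, %g] cannot achieve mean %g with SD %g",
      type, lower, upper, target_mean, target_sd), call. = FALSE)
  }
  ls <- stats::uniroot(g, c(ls_lo, ls_hi), tol = 1e-13)$root
  sigma <- exp(ls)
  mu <- .solve_mu(target_mean, sigma, lower, upper, type)
  mom <- bounded_normal_moments(mu, sigma, lower, upper, type)
  if (abs(mom[["mean"]] - target_mean) > tol || abs(mom[["sd"]] - target_sd) > tol) {
    stop(sprintf(
      "infeasible target: best %s-normal match on [%g, %g] reaches mean %.6g, SD %.6g (target %g, %g)",
      type, lower, upper, mom[["mean"]], mom[["sd"]], target_mean, target_sd),
      call. = FALSE)
  }
  list(mu = mu, sigma = sigma, lower = lower, upper = upper, type = type,
       achieved_mean = mom[["mean"]], achieved_sd = mom[["sd"]])
}

#' Latent parameters matching target moments under truncation
#'
#' Finds `(mu, sigma)` such that `N(mu, sigma)` truncated to
#' `[lower, upper]` has the requested mean and SD (within `1e-6`).
#' Raises a feasibility error when no truncated normal can achieve the
#' target — in particular whenever the target coefficient of variation
#' relative to the nearer bound exceeds the family's exponential-tail
#' limit, as happens for severe floor effects; see [solve_censnorm()].
#'
#' @param target_mean,target_sd desired moments of the bounded score.
#' @param lower,upper score range (default 0--56).
#' @return List with `mu`, `sigma`, the range, `type`, and the achieved
#'   moments.
#' @seealso [solve_censnorm()], [bounded_normal_moments()]
#' @export
solve_truncnorm <- function(target_mean, target_sd, lower = 0, upper = 56) {
  solve_bounded_normal(target_mean, target_sd, lower, upper, "truncated")
}

#' Latent parameters matching target moments under censoring
#'
#' As [solve_truncnorm()] but the latent normal is clipped, not
#' conditioned: draws below `lower` (above `upper`) become exactly
#' `lower` (`upper`). The point mass at the floor lets the censored
#' family reach large SDs at small means (e.g. a score distribution with
#' mean 1.6 and SD 4.6 on 0--56, dominated by zeros), which no truncated
#' normal can represent.
#'
#' @inheritParams solve_truncnorm
#' @return List with `mu`, `sigma`, the range, `type`, and the achieved
#'   moments.
#' @export
solve_censnorm <- function(target_mean, target_sd, lower = 0, upper = 56) {
  solve_bounded_normal(target_mean, target_sd, lower, upper, "censored")
}

#' Quantile function of a truncated or censored normal
#'
#' Truncated quantiles are computed in log space so that extreme latent
#' parameters — which the moment match routinely produces — stay
#' accurate; censored quantiles clip the ordinary normal quantile.
#'
#' @param u probabilities in (0, 1).
#' @param mu,sigma latent normal parameters.
#' @param lower,upper range bounds.
#' @param type `"truncated"` or `"censored"`.
#' @return Numeric vector of quantiles in `[lower, upper]`.
#' @export
qbounded_normal <- function(u, mu, sigma, lower, upper,
                            type = c("truncated", "censored")) {
  type <- match.arg(type)
  if (type == "censored") {
    return(pmin(pmax(stats::qnorm(u, mu, sigma), lower), upper))
  }
  al <- (lower - mu) / sigma
  be <- (upper - mu) / sigma
  if (al >= 0) {
    # both bounds in the upper tail: work with log survival probabilities
    lq_hi <- stats::pnorm(al, lower.tail = FALSE, log.p = TRUE)
    lq_lo <- stats::pnorm(be, lower.tail = FALSE, log.p = TRUE)
    lq <- lq_hi + log1p(u * expm1(lq_lo - lq_hi))
    z <- stats::qnorm(lq, lower.tail = FALSE, log.p = TRUE)
  } else if (be <= 0) {
    lq_lo <- stats::pnorm(al, log.p = TRUE)
    lq_hi <- stats::pnorm(be, log.p = TRUE)
    lq <- lq_hi + log1p((1 - u) * expm1(lq_lo - lq_hi))
    z <- stats::qnorm(lq, log.p = TRUE)
  } else {
    p_lo <- stats::pnorm(al)
    p_hi <- stats::pnorm(be)
    z <- stats::qnorm(p_lo + u * (p_hi - p_lo))
  }
  mu + sigma * z
}

#' Draw from a truncated or censored normal
#'
#' Inverse-CDF sampling through [qbounded_normal()].
#'
#' @param n number of draws.
#' @inheritParams qbounded_normal
#' @return Numeric vector of length `n` in `[lower, upper]`.
#' @export
rbounded_normal <- function(n, mu, sigma, lower, upper,
                            type = c("truncated", "censored")) {
  type <- match.arg(type)
  if (type == "censored") {
    return(pmin(pmax(stats::rnorm(n, mu, sigma), lower), upper))
  }
  qbounded_normal(stats::runif(n), mu, sigma, lower, upper, type)
}
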