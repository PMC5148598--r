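## Univariate generalized Waring distribution (UGWD).
##
## The UGWD(a, k, rho) is the beta-negative-binomial count distribution that
## arises from the Poisson-gamma-betaII hierarchy: Y|lambda ~ Poisson(lambda),
## lambda|v ~ Gamma(a, scale = v), v ~ BetaII(rho, k).  All probability mass
## work is done in log space with lgamma() so that parameters and counts up
## to ~1e4 do not overflow.

check_ugwd_params <- function(a, k, rho) {
  if (!is.numeric(a) || !is.numeric(k) || !is.numeric(rho))
    stop("UGWD parameters must be numeric", call. = FALSE)
  if (anyNA(a) || anyNA(k) || anyNA(rho) ||
      any(!is.finite(a)) || any(!is.finite(k)) || any(!is.finite(rho)))
    stop("UGWD parameters must be finite", call. = FALSE)
  if (any(a <= 0) || any(k <= 0) || any(rho <= 0))
    stop("UGWD parameters 'a', 'k' and 'rho' must be strictly positive",
         call. = FALSE)
  invisible(TRUE)
}

#' Probability mass of the univariate generalized Waring distribution
#'
#' Density (probability mass) of the UGWD with shape parameters `a`, `k` and
#' tail exponent `rho`, the beta-negative-binomial distribution with
#' \deqn{f(y) = \frac{\Gamma(a+\rho)\Gamma(k+\rho)}{\Gamma(a+k+\rho)\Gamma(\rho)}
#'   \frac{(a)_y (k)_y}{(a+k+\rho)_y \, y!}, \quad y = 0, 1, 2, \ldots}
#' where \eqn{(\alpha)_y} is the Pochhammer symbol (rising factorial).
#' Computation is carried out entirely through `lgamma()` so that large
#' arguments do not overflow.  The mass function is symmetric in `a` and `k`,
#' has mean \eqn{ak/(\rho-1)} when \eqn{\rho > 1}, and a power-law tail
#' \eqn{f(y) \sim C\,y^{-(\rho+1)}}.
#'
#' @param x vector of non-negative integer counts.
#' @param a,k positive shape parameters (recycled against `x`; `a` may vary
#'   per observation as in the regression model).
#' @param rho positive tail parameter; the mean exists for `rho > 1` and the
#'   variance for `rho > 2`.
#' @param log logical; if `TRUE`, log-probabilities are returned.
#' @return numeric vector of (log-)probabilities.
#' @seealso [rugwd()], [ugwd_moments()]
#' @examples
#' dugwd(0:5, a = 1, k = 1, rho = 2)      # equals 4/((y+1)(y+2)(y+3))
#' sum(dugwd(0:2000, a = 2, k = 3, rho = 5))
#' @export
dugwd <- function(x, a, k, rho, log = FALSE) {
  check_ugwd_params(a, k, rho)
  if (!is.numeric(x) || anyNA(x))
    stop("'x' must be numeric without missing values", call. = FALSE)
  if (any(x < 0) || any(x != floor(x)))
    stop("'x' must contain non-negative integers", call. = FALSE)
  n <- max(length(x), length(a), length(k), length(rho))
  x <- rep_len(x, n); a <- rep_len(a, n)
  k <- rep_len(k, n); rho <- rep_len(rho, n)
  lp <- ugwd_lpmf(x, a, k, rho)
  if (log) lp else exp(lp)
}

## Log mass kernel (no validation).  Written entirely in lbeta() terms of
## small magnitude so that no large-lgamma cancellation occurs even for
## parameters or counts of order 1e4 and beyond:
##   ln f = [lbeta(a+y, k+rho) - lbeta(a, k+rho)]   # (a)_y / (a+k+rho)_y
##        + [lbeta(a+rho, k) - lbeta(rho, k)]       # normalizing constant
##        - ln(k+y) - lbeta(k, y+1)                 # (k)_y / y!
## The pair (a, k) is ordered first so the a<->k symmetry of the mass
## function holds exactly in floating point.
ugwd_lpmf <- function(x, a, k, rho) {
  aa <- pmin(a, k); k <- pmax(a, k); a <- aa
  lbeta(a + x, k + rho) - lbeta(a, k + rho) +
    lbeta(a + rho, k) - lbeta(rho, k) -
    log(k + x) - lbeta(k, x + 1)
}

#' Moments and variance components of the UGWD
#'
#' Mean, variance and the three-way decomposition of the variance of a
#' UGWD(a, k, rho) into the components attributable to randomness (the
#' Poisson stage), liability (the gamma mixing stage, external factors) and
#' proneness (the beta mixing stage, internal factors):
#' \deqn{\mu = \frac{ak}{\rho-1}, \quad
#'   \mathrm{Var} = \mu + \frac{k+1}{\rho-2}\mu + \mu^2\frac{k+\rho-1}{k(\rho-2)}.}
#' The mean exists only for `rho > 1` and the variance only for `rho > 2`;
#' non-existent moments are returned as `NA` rather than raised as errors.
#'
#' @inheritParams dugwd
#' @return a list with elements `mean`, `variance`, `randomness`,
#'   `liability`, `proneness` (vectors if `a` is a vector).  The three
#'   components sum to `variance` when it exists.
#' @examples
#' ugwd_moments(a = 2, k = 3, rho = 5)
#' ugwd_moments(a = 1, k = 1, rho = 2)   # mean 1, infinite variance
#' @export
ugwd_moments <- function(a, k, rho) {
  check_ugwd_params(a, k, rho)
  n <- max(length(a), length(k), length(rho))
  a <- rep_len(a, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  mu <- ifelse(rho > 1, a * k / (rho - 1), NA_real_)
  comp <- ugwd_partition(mu, k, rho)
  list(mean = unname(mu),
       variance = unname(comp[, "randomness"] + comp[, "liability"] +
                           comp[, "proneness"]),
       randomness = unname(comp[, "randomness"]),
       liability = unname(comp[, "liability"]),
       proneness = unname(comp[, "proneness"]))
}

## Variance components at mean mu (mu = a k / (rho - 1)); rows where the
## variance does not exist (rho <= 2 or mu undefined) are NA.
ugwd_partition <- function(mu, k, rho) {
  n <- max(length(mu), length(k), length(rho))
  mu <- rep_len(mu, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  ok <- !is.na(mu) & rho > 2
  r <- l <- p <- rep(NA_real_, n)
  r[ok] <- mu[ok]
  l[ok] <- (k[ok] + 1) / (rho[ok] - 2) * mu[ok]
  p[ok] <- mu[ok]^2 * (k[ok] + rho[ok] - 1) / (k[ok] * (rho[ok] - 2))
  cbind(randomness = r, liability = l, proneness = p)
}

#' Random generation from the UGWD
#'
#' Draws are generated by the exact two-stage beta-negative-binomial route:
#' `p ~ Beta(rho, k)` then `Y ~ NegBinomial(size = a, prob = p)`.  This is
#' distributionally identical to the three-stage Poisson-gamma-betaII
#' genesis of the model (see [rugwd_latent()]) but needs no rejection step.
#'
#' @inheritParams dugwd
#' @param n number of draws.
#' @param seed optional integer; if supplied the R random seed is set first,
#'   making the draws reproducible.
#' @return integer-valued numeric vector of length `n`.
#' @examples
#' mean(rugwd(1e4, a = 2, k = 3, rho = 5, seed = 1))  # close to 1.5
#' @export
rugwd <- function(n, a, k, rho, seed = NULL) {
  check_ugwd_params(a, k, rho)
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("'n' must be a single non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(numeric(0))
  p <- stats::rbeta(n, shape1 = rep_len(rho, n), shape2 = rep_len(k, n))
  stats::rnbinom(n, size = rep_len(a, n), prob = p)
}

#' Latent-hierarchy generation from the UGWD
#'
#' Samples the full Poisson-gamma-betaII hierarchy underlying the model:
#' `v ~ BetaII(rho, k)` (a beta-prime draw), `lambda ~ Gamma(a, scale = v)`,
#' `y ~ Poisson(lambda)`.  Marginally `y` follows UGWD(a, k, rho); the
#' latent draws are returned so that the liability (`lambda`) and proneness
#' (`v`) stages can be inspected.  Used as a cross-check oracle for
#' [rugwd()].
#'
#' @inheritParams rugwd
#' @return a data frame with columns `v`, `lambda`, `y`.
#' @export
rugwd_latent <- function(n, a, k, rho, seed = NULL) {
  check_ugwd_params(a, k, rho)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L)
    return(data.frame(v = numeric(0), lambda = numeric(0), y = numeric(0)))
  ## beta-prime: v = (1-p)/p with p ~ Beta(rho, k)
  v <- stats::rgamma(n, shape = rep_len(k, n)) /
    stats::rgamma(n, shape = rep_len(rho, n))
  lambda <- stats::rgamma(n, shape = rep_len(a, n), scale = v)
  y <- stats::rpois(n, lambda)
  data.frame(v = v, lambda = lambda, y = y)
}
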