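## Maximum-likelihood fitting of the generalized Waring regression model.
##
## The conditional model is Y_i ~ UGWD(a_i, k, rho) with log link on the
## mean: mu_i = exp(x_i' beta + offset_i) and a_i = mu_i (rho - 1) / k.
## Two parameterizations are used internally:
##   * natural   theta = (beta, k, rho), constrained k > 0, rho > 1;
##   * log-scale theta = (beta, k0, rho0) with k = exp(k0), rho = 1 + exp(rho0),
##     which is unconstrained and guarantees the mean exists.

BIG_NEGLL <- 1e10

## Negative weighted log-likelihood.  `fixk` freezes k (not estimated).
gw_negll <- function(par, y, X, offset, weights, fixk = NULL,
                     logscale = FALSE) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  if (is.null(fixk)) {
    k <- par[p + 1L]; rho <- par[p + 2L]
  } else {
    k <- fixk; rho <- par[p + 1L]
  }
  if (logscale) {
    if (is.null(fixk)) k <- exp(k)
    rho <- 1 + exp(rho)
  }
  if (!all(is.finite(c(beta, k, rho))) || k <= 0 || rho <= 1)
    return(BIG_NEGLL)
  eta <- drop(X %*% beta) + offset
  ## reject absurd regions where lgamma cancellation turns to noise
  if (max(eta) > 25 || k > 1e8 || rho > 1e8) return(BIG_NEGLL)
  mu <- exp(eta)
  a <- mu * (rho - 1) / k
  ll <- ugwd_lpmf(y, a, k, rho)
  ## a log-probability can never be positive; positives are rounding garbage
  if (any(ll > 1e-6)) return(BIG_NEGLL)
  val <- -sum(weights * ll)
  if (!is.finite(val)) BIG_NEGLL else val
}

## Analytic gradient of gw_negll (same argument conventions).
gw_negll_grad <- function(par, y, X, offset, weights, fixk = NULL,
                          logscale = FALSE) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  if (is.null(fixk)) {
    kpar <- par[p + 1L]; rpar <- par[p + 2L]
  } else {
    kpar <- NULL; rpar <- par[p + 1L]
  }
  k <- if (is.null(fixk)) kpar else fixk
  rho <- rpar
  if (logscale) {
    if (is.null(fixk)) k <- exp(k)
    rho <- 1 + exp(rho)
  }
  if (!all(is.finite(c(beta, k, rho))) || k <= 0 || rho <= 1)
    return(rep(0, length(par)))
  eta <- drop(X %*% beta) + offset
  if (max(eta) > 25 || k > 1e8 || rho > 1e8)
    return(rep(0, length(par)))
  mu <- exp(eta)
  a <- mu * (rho - 1) / k
  s <- a + k + rho + y
  dl_da <- digamma(a + rho) + digamma(a + y) - digamma(a) - digamma(s)
  gbeta <- drop(crossprod(X, weights * dl_da * a))
  grho <- sum(weights * (digamma(a + rho) + digamma(k + rho) -
                           digamma(rho) - digamma(s) + dl_da * mu / k))
  if (is.null(fixk)) {
    gk <- sum(weights * (digamma(k + rho) + digamma(k + y) - digamma(k) -
                           digamma(s) - dl_da * a / k))
    if (logscale) {
      gk <- gk * k
      grho <- grho * (rho - 1)
    }
    g <- c(gbeta, gk, grho)
  } else {
    if (logscale) grho <- grho * (rho - 1)
    g <- c(gbeta, grho)
  }
  if (!all(is.finite(g))) g[] <- 0
  -g
}

#' Control parameters for [gw()] fitting
#'
#' @param maxit maximum iterations per optimization stage.
#' @param gradtol gradient tolerance for the Newton-type stage.
#' @param reltol relative convergence tolerance for the simplex stage.
#' @param factr `"L-BFGS-B"` accuracy factor (see [stats::optim()]).
#' @param kmin,rhomin lower bounds for `k` and `rho - 1` in the bounded
#'   quasi-Newton stage.
#' @param trace integer; positive values print optimizer progress.
#' @return a named list, to be passed as the `control` argument of [gw()].
#' @export
gw_control <- function(maxit = 500L, gradtol = 1e-6, reltol = 1e-10,
                       factr = 1e7, kmin = 1e-5, rhomin = 1e-5,
                       trace = 0L) {
  list(maxit = as.integer(maxit), gradtol = gradtol, reltol = reltol,
       factr = factr, kmin = kmin, rhomin = rhomin, trace = as.integer(trace))
}

## Core fitting engine on prepared (y, X, offset, weights).
## method NULL = full three-stage strategy: (A) Newton-type on the log
## scale, (B) Nelder-Mead on the log scale, then (C) L-BFGS-B on the
## natural scale from the better of A/B; SEs come from C's Hessian.
gw_engine <- function(y, X, offset, weights, kstart = 1, rostart = 2,
                      betastart = NULL, fixk = NULL, method = NULL,
                      control = gw_control(), hessian = TRUE) {
  p <- ncol(X)
  if (kstart <= 0) stop("'kstart' must be positive", call. = FALSE)
  if (rostart <= 1) stop("'rostart' must exceed 1", call. = FALSE)
  if (!is.null(fixk) && fixk <= 0)
    stop("fixed 'k' must be positive", call. = FALSE)

  if (is.null(betastart)) {
    betastart <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, weights = weights,
                                      offset = offset,
                                      family = stats::poisson())$coefficients),
      error = function(e) NULL)
    if (is.null(betastart) || anyNA(betastart)) {
      betastart <- numeric(p)
      betastart[1L] <- log(stats::weighted.mean(y, weights) + 0.5)
    }
  }
  if (length(betastart) != p)
    stop("'betastart' must have one value per design column", call. = FALSE)

  fn_log <- function(par) gw_negll(par, y, X, offset, weights, fixk, TRUE)
  gr_log <- function(par) gw_negll_grad(par, y, X, offset, weights, fixk, TRUE)
  fn_nat <- function(par) gw_negll(par, y, X, offset, weights, fixk, FALSE)
  gr_nat <- function(par) gw_negll_grad(par, y, X, offset, weights, fixk, FALSE)

  start_log <- if (is.null(fixk)) c(betastart, log(kstart), log(rostart - 1))
               else c(betastart, log(rostart - 1))
  ndisp <- length(start_log) - p

  run_nlm <- function(start) {
    f <- function(par) {
      v <- fn_log(par)
      attr(v, "gradient") <- gr_log(par)
      v
    }
    res <- suppressWarnings(
      stats::nlm(f, start, gradtol = control$gradtol,
                 iterlim = control$maxit, hessian = FALSE,
                 print.level = min(control$trace, 2L)))
    list(par = res$estimate, value = res$minimum,
         convergence = if (res$code %in% c(1L, 2L, 3L)) 0L else res$code,
         hessian = NULL, method = "nlm")
  }
  run_nm <- function(start) {
    res <- suppressWarnings(
      stats::optim(start, fn_log, method = "Nelder-Mead",
                   control = list(maxit = max(control$maxit, 200L * ndisp),
                                  reltol = control$reltol,
                                  trace = control$trace)))
    list(par = res$par, value = res$value, convergence = res$convergence,
         hessian = NULL, method = "Nelder-Mead")
  }
  run_lbfgsb <- function(start_nat) {
    lower <- c(rep(-Inf, p),
               if (is.null(fixk)) control$kmin,
               1 + control$rhomin)
    res <- suppressWarnings(
      stats::optim(start_nat, fn_nat, gr = gr_nat, method = "L-BFGS-B",
                   lower = lower, hessian = hessian,
                   control = list(maxit = control$maxit,
                                  factr = control$factr,
                                  trace = control$trace)))
    list(par = res$par, value = res$value, convergence = res$convergence,
         hessian = res$hessian, method = "L-BFGS-B")
  }
  to_nat <- function(par_log) {
    out <- par_log
    if (is.null(fixk)) {
      out[p + 1L] <- exp(par_log[p + 1L])
      out[p + 2L] <- 1 + exp(par_log[p + 2L])
    } else out[p + 1L] <- 1 + exp(par_log[p + 1L])
    out
  }

  se_scale <- "natural"
  if (is.null(method)) {
    stA <- run_nlm(start_log)
    stB <- run_nm(if (stA$value < BIG_NEGLL) stA$par else start_log)
    best <- if (stA$value <= stB$value) stA else stB
    fit <- run_lbfgsb(to_nat(best$par))
    ## keep the better point if the refit drifted
    if (best$value < fit$value - 1e-8) {
      fit2 <- run_lbfgsb(to_nat(best$par))
      if (fit2$value < fit$value) fit <- fit2
    }
    method_label <- "L-BFGS-B"
  } else {
    method <- match.arg(method, c("nlm", "Nelder-Mead", "L-BFGS-B"))
    fit <- switch(method,
                  "nlm" = run_nlm(start_log),
                  "Nelder-Mead" = run_nm(start_log),
                  "L-BFGS-B" = run_lbfgsb(
                    if (is.null(fixk)) c(betastart, kstart, rostart)
                    else c(betastart, rostart)))
    method_label <- method
    if (method != "L-BFGS-B") {
      se_scale <- "log"
      if (hessian) {
        H <- tryCatch(stats::optimHess(fit$par, fn_log, gr_log),
                      error = function(e) NULL)
        fit$hessian <- H
      }
    }
  }

  par_nat <- if (identical(se_scale, "log")) to_nat(fit$par) else fit$par
  beta <- par_nat[seq_len(p)]
  if (is.null(fixk)) {
    k <- par_nat[p + 1L]; rho <- par_nat[p + 2L]
  } else {
    k <- fixk; rho <- par_nat[p + 1L]
  }

  vcov <- NULL
  se <- rep(NA_real_, length(par_nat))
  if (hessian && !is.null(fit$hessian)) {
    vcov <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (!is.null(vcov)) {
      dvc <- diag(vcov)
      se <- ifelse(dvc > 0, sqrt(dvc), NA_real_)
      if (anyNA(se))
        warning("Hessian not positive definite; some SEs unavailable",
                call. = FALSE)
    } else {
      warning("singular Hessian; standard errors unavailable", call. = FALSE)
    }
  }

  loglik <- -fn_nat(if (is.null(fixk)) c(beta, k, rho) else c(beta, rho))
  if (fit$convergence != 0L)
    warning("gw fit did not converge (code ", fit$convergence, ")",
            call. = FALSE)
  list(beta = beta, k = k, rho = rho, fixk = fixk,
       se = se, se_scale = se_scale, vcov = vcov,
       loglik = loglik, converged = fit$convergence,
       method = method_label, value = fit$value)
}

#' Fit a generalized Waring regression model
#'
#' Fits the generalized Waring regression model (GWRM), a beta-negative-
#' binomial regression for overdispersed counts: conditional on covariates
#' `x`, the response follows a univariate generalized Waring distribution
#' UGWD(\eqn{a_x}, k, \eqn{\rho}) with log-linear mean
#' \eqn{\mu_x = e^{x'\beta}} and \eqn{a_x = \mu_x(\rho-1)/k}.  Unlike the
#' negative binomial model, the GWRM separates overdispersion into a
#' liability component (external factors, via the gamma stage) and a
#' proneness component (stable individual differences, via the beta stage);
#' see [partvar()].
#'
#' Estimation is by maximum likelihood.  The default strategy runs a
#' Newton-type minimization ([stats::nlm()]) and a Nelder-Mead simplex
#' search on the unconstrained parameterization
#' \eqn{k = e^{k_0}, \rho = 1 + e^{\rho_0}} (which guarantees that the mean
#' exists), then refits from the better of the two with bounded
#' quasi-Newton (`"L-BFGS-B"`) on the natural scale; standard errors for
#' all parameters, including `k` and `rho`, come from the final numeric
#' Hessian.  If `method` selects `"nlm"` or `"Nelder-Mead"` alone, standard
#' errors are reported for \eqn{(\beta, k_0, \rho_0)} and only point
#' estimates are translated to `k` and `rho`.
#'
#' @param formula a symbolic model formula; `offset(...)` terms are
#'   supported and enter the linear predictor with coefficient 1.
#' @param data a data frame containing the model variables.
#' @param weights optional non-negative case weights multiplying each
#'   observation's log-likelihood contribution.
#' @param k optional positive value fixing the dispersion parameter `k`
#'   (then not estimated).
#' @param subset,na.action standard model-frame arguments; rows with
#'   missing values in used variables are dropped (with a message).
#' @param kstart,rostart starting values for `k` and `rho`.
#' @param betastart optional starting values for the regression
#'   coefficients; by default a Poisson log-linear fit supplies them.
#' @param offset optional numeric offset (alternative to `offset()` in the
#'   formula).
#' @param control a list from [gw_control()].
#' @param method `NULL` for the default multi-stage strategy, or one of
#'   `"nlm"`, `"Nelder-Mead"`, `"L-BFGS-B"` to use a single optimizer.
#' @param hessian logical; compute the Hessian-based covariance matrix.
#' @param model,x,y logicals; whether to return the model frame, design
#'   matrix and response.
#' @param ... unused.
#' @return an object of class `"gw"` with components including
#'   `coefficients`, `betaII` (the `k` and `ro` estimates), `se`, `vcov`,
#'   `loglik`, `aic`, `bic`, `df.residual`, `converged` (0 = success) and
#'   `method`.  Methods are provided for `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `residuals`, `fitted`, `add1`, `drop1`
#'   and `extractAIC`, plus [partvar()] and [gw_envelope()].
#' @examples
#' sim <- gw_simulate(500, beta = c(0.6, 1.1), k = 2, rho = 5,
#'                    covariates = list(xbin = list(type = "binary", prob = 0.4)),
#'                    seed = 7)
#' fit <- gw(y ~ xbin, data = sim$data)
#' summary(fit)
#' partvar(fit, newdata = data.frame(xbin = c(0, 1)))
#' @export
gw <- function(formula, data, weights, k = NULL, subset, na.action,
               kstart = 1, rostart = 2, betastart = NULL, offset,
               control = gw_control(), method = NULL, hessian = TRUE,
               model = TRUE, x = FALSE, y = TRUE, ...) {
  call <- match.call()
  if (missing(data)) data <- environment(formula)
  mf <- match.call(expand.dots = FALSE)
  m <- match(c("formula", "data", "subset", "weights", "na.action",
               "offset"), names(mf), 0L)
  mf <- mf[c(1L, m)]
  mf$drop.unused.levels <- TRUE
  mf[[1L]] <- quote(stats::model.frame)
  mf <- eval(mf, parent.frame())

  n_before <- if (is.data.frame(data)) nrow(data) else NA_integer_
  n <- nrow(mf)
  if (n == 0L) stop("no rows left after removing missing values",
                    call. = FALSE)
  if (!is.na(n_before) && n < n_before)
    message(n_before - n, " row(s) with missing values removed")

  mt <- attr(mf, "terms")
  Y <- stats::model.response(mf)
  if (!is.numeric(Y) || any(Y < 0) || any(Y != floor(Y)))
    stop("response must consist of non-negative integer counts",
         call. = FALSE)
  X <- stats::model.matrix(mt, mf)
  w <- stats::model.weights(mf)
  if (is.null(w)) w <- rep(1, n)
  if (any(w < 0)) stop("negative weights not allowed", call. = FALSE)
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- rep(0, n)

  eng <- gw_engine(Y, X, off, w, kstart = kstart, rostart = rostart,
                   betastart = betastart, fixk = k, method = method,
                   control = control, hessian = hessian)

  p <- ncol(X)
  npar <- p + if (is.null(k)) 2L else 1L
  coefs <- stats::setNames(eng$beta, colnames(X))
  disp_names <- if (is.null(k)) c("k", "ro") else "ro"
  se <- stats::setNames(eng$se, c(colnames(X),
                                  if (identical(eng$se_scale, "log"))
                                    sub("^k$", "log(k)",
                                        sub("^ro$", "log(ro-1)", disp_names))
                                  else disp_names))
  lp <- drop(X %*% eng$beta) + off
  fit <- list(coefficients = coefs,
              betaII = c(k = eng$k, ro = eng$rho),
              k_fixed = !is.null(k),
              se = se, se_scale = eng$se_scale, vcov = eng$vcov,
              loglik = eng$loglik,
              aic = -2 * eng$loglik + 2 * npar,
              bic = -2 * eng$loglik + log(n) * npar,
              npar = npar, df.residual = n - npar, nobs = n,
              converged = eng$converged, method = eng$method,
              linear.predictors = lp, fitted.values = exp(lp),
              prior.weights = w, offset = off,
              terms = mt, xlevels = stats::.getXlevels(mt, mf),
              contrasts = attr(X, "contrasts"),
              na.action = attr(mf, "na.action"),
              call = call, control = control)
  if (model) fit$model <- mf
  if (x) fit$x <- X
  if (y) fit$y <- Y
  class(fit) <- "gw"
  fit
}

#' Assemble a GWRM object from known parameter values
#'
#' Builds a minimal `"gw"` object from externally given coefficients and
#' dispersion parameters (for example, estimates published in a report), so
#' that [predict.gw()] and [partvar()] can be applied to new data without
#' access to the original fit.
#'
#' @param formula right-hand-side model formula for the mean.
#' @param coefficients named or positional coefficient vector matching the
#'   columns of `model.matrix(formula, data)`.
#' @param k,rho dispersion parameter values (`rho > 1`).
#' @param data optional data frame used to fix factor levels.
#' @return an object of class `"gw"` supporting prediction and variance
#'   partition (no likelihood-based components).
#' @examples
#' m <- as_gw(~ badh, coefficients = c(0.6581, 1.162),
#'            k = 1.567578, rho = 6.852336,
#'            data = data.frame(badh = c(0, 1)))
#' predict(m, newdata = data.frame(badh = c(0, 1)))
#' @export
as_gw <- function(formula, coefficients, k, rho, data = NULL) {
  check_ugwd_params(1, k, rho)
  if (rho <= 1) stop("'rho' must exceed 1", call. = FALSE)
  mt <- if (is.null(data)) stats::terms(formula)
        else stats::terms(formula, data = data)
  mt <- stats::delete.response(mt)
  xlev <- NULL
  if (!is.null(data)) {
    mf <- stats::model.frame(mt, data)
    xlev <- stats::.getXlevels(mt, mf)
    X <- stats::model.matrix(mt, mf)
    if (length(coefficients) != ncol(X))
      stop("coefficient length does not match the design implied by 'formula'",
           call. = FALSE)
    names(coefficients) <- colnames(X)
  }
  structure(list(coefficients = coefficients,
                 betaII = c(k = k, ro = rho),
                 k_fixed = FALSE, npar = length(coefficients) + 2L,
                 terms = mt, xlevels = xlev, contrasts = NULL,
                 converged = 0L, method = "external"),
            class = "gw")
}
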