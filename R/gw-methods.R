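## Standard methods on "gw" fits, mirroring the glm()-style toolbox.

#' @export
print.gw <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("\nCall: ", paste(deparse(x$call), collapse = "\n"), "\n\n")
  cat("Coefficients:\n")
  print.default(format(stats::coef(x), digits = digits), print.gap = 2,
                quote = FALSE)
  cat("\nbetaII (k, ro):\n")
  print.default(format(x$betaII, digits = digits), print.gap = 2,
                quote = FALSE)
  if (!is.null(x$df.residual))
    cat("\nDegrees of Freedom:", x$df.residual, "Residual\n")
  cat("Code of convergence:", x$converged, "\n")
  cat("Method:", x$method, "\n")
  invisible(x)
}

#' Summarize a GWRM fit
#'
#' Wald tests for the regression coefficients (`z = estimate/SE`, two-sided
#' normal p-values), the dispersion block for `k` and `rho` (reported
#' without p-values), and the fit block (log-likelihood, AIC, BIC, residual
#' degrees of freedom, convergence code and method).
#'
#' @param object a fitted [gw()] model.
#' @param ... unused.
#' @return an object of class `"summary.gw"`.
#' @export
summary.gw <- function(object, ...) {
  est <- stats::coef(object)
  p <- length(est)
  se <- object$se[seq_len(p)]
  z <- est / se
  pv <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  coefs <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
                 `Pr(>|z|)` = pv)
  disp_se <- object$se[-seq_len(p)]
  disp <- cbind(Estimate = object$betaII,
                `Std. Error` = if (identical(object$se_scale, "natural") &&
                                   !object$k_fixed)
                  disp_se else rep(NA_real_, length(object$betaII)))
  rownames(disp) <- names(object$betaII)
  out <- list(call = object$call, coefficients = coefs, betaII = disp,
              se_scale = object$se_scale, se_log = disp_se,
              k_fixed = object$k_fixed,
              loglik = object$loglik, aic = object$aic, bic = object$bic,
              df.residual = object$df.residual,
              converged = object$converged, method = object$method)
  class(out) <- "summary.gw"
  out
}

#' @export
print.summary.gw <- function(x, digits = 4L, ...) {
  cat("\nCall: ", paste(deparse(x$call), collapse = "\n"), "\n\n")
  cat("Coefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, signif.stars = FALSE)
  cat("\nFit:\n")
  fitline <- c(`log-likelihood` = x$loglik, AIC = x$aic, BIC = x$bic,
               df = x$df.residual)
  print(round(fitline))
  cat("\nbetaII:\n")
  print(format(x$betaII, digits = 7L), quote = FALSE)
  if (identical(x$se_scale, "log"))
    cat("(SEs available for log(k) and log(ro-1) only:",
        paste(format(x$se_log, digits = 4L), collapse = ", "), ")\n")
  cat("\nDegrees of Freedom:", x$df.residual, "Residual\n")
  cat("Code of convergence:", x$converged, "\n")
  cat("Method:", x$method, "\n")
  invisible(x)
}

#' @export
coef.gw <- function(object, ...) object$coefficients

#' @export
vcov.gw <- function(object, ...) {
  if (is.null(object$vcov)) return(NULL)
  nm <- names(object$se)
  dimnames(object$vcov) <- list(nm, nm)
  object$vcov
}

#' @export
logLik.gw <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.gw <- function(object, ...) object$nobs

#' @export
fitted.gw <- function(object, ...) object$fitted.values

#' @export
family.gw <- function(object, ...) {
  structure(list(family = "generalized Waring", link = "log"),
            class = "family")
}

#' @export
extractAIC.gw <- function(fit, scale = 0, k = 2, ...) {
  c(fit$npar, -2 * fit$loglik + k * fit$npar)
}

#' Predict from a GWRM fit
#'
#' @param object a fitted [gw()] model (or [as_gw()] object).
#' @param newdata optional data frame of covariate values; if omitted the
#'   fitted values are returned.  Any `offset()` term in the model formula
#'   is re-evaluated on `newdata`.
#' @param type `"response"` for predicted means \eqn{\mu = e^{x'\beta +
#'   \mathrm{offset}}}, `"link"` for the linear predictor.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gw <- function(object, newdata = NULL,
                       type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$linear.predictors))
      stop("no fitted values stored; supply 'newdata'", call. = FALSE)
    lp <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass,
                             xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
    beta <- stats::coef(object)
    if (ncol(X) != length(beta))
      stop("'newdata' design does not match the fitted coefficients",
           call. = FALSE)
    off <- stats::model.offset(mf)
    if (is.null(off)) off <- rep(0, nrow(X))
    lp <- drop(X %*% beta) + off
  }
  if (type == "link") lp else exp(lp)
}
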