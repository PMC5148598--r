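## Residuals for GWRM fits and the normal plot with simulated envelope.

## Residual kernel on raw components; used by residuals.gw() and by the
## envelope bootstrap (which works on refitted replicates).
gw_resid <- function(y, mu, k, rho, type) {
  switch(type,
    response = y - mu,
    pearson = {
      if (rho <= 2)
        stop("Pearson residuals undefined: estimated rho <= 2 ",
             "(infinite variance)", call. = FALSE)
      v <- rowSums(ugwd_partition(mu, k, rho))
      (y - mu) / sqrt(v)
    },
    deviance = {
      lsat <- ifelse(y == 0, 0,
                     dugwd(y, pmax(y, 1e-12) * (rho - 1) / k, k, rho,
                           log = TRUE))
      lfit <- dugwd(y, mu * (rho - 1) / k, k, rho, log = TRUE)
      d <- 2 * (lsat - lfit)
      ## mu = y is not exactly the per-observation argmax in mu, so d can
      ## be marginally negative when mu-hat is very close to y; clamp.
      sign(y - mu) * sqrt(pmax(d, 0))
    },
    stop("unknown residual type: ", type, call. = FALSE))
}

#' Residuals of a GWRM fit
#'
#' Pearson residuals \eqn{(y-\hat\mu)/\sqrt{\hat V}} (with \eqn{\hat V} the
#' three-component model variance, requiring \eqn{\hat\rho > 2}), deviance
#' residuals \eqn{\mathrm{sign}(y-\hat\mu)\sqrt{d_i}} with
#' \eqn{d_i = 2[\ln f(y_i \mid \mu = y_i) - \ln f(y_i \mid \mu = \hat\mu_i)]}
#' holding \eqn{(\hat k, \hat\rho)} fixed (so that \eqn{D = \sum_i d_i} is
#' the deviance statistic; at \eqn{y_i = 0} the saturated term is the limit
#' \eqn{\mu \to 0^+}, i.e. 0), or raw response residuals
#' \eqn{y - \hat\mu}.
#'
#' With `envelope = TRUE` the function instead returns the simulated
#' normal-plot envelope of [gw_envelope()].
#'
#' @param object a fitted [gw()] model.
#' @param type `"pearson"` (default), `"deviance"` or `"response"`.
#' @param envelope logical; compute a simulated envelope instead of the
#'   plain residual vector.
#' @param rep,seed,parallel,ncores passed to [gw_envelope()] when
#'   `envelope = TRUE`.
#' @param ... unused.
#' @return a numeric vector in the original row order, or a
#'   `"gw_envelope"` object when `envelope = TRUE`.
#' @export
residuals.gw <- function(object, type = c("pearson", "deviance", "response"),
                         envelope = FALSE, rep = 19L, seed = NULL,
                         parallel = TRUE, ncores = 2L, ...) {
  type <- match.arg(type)
  if (envelope)
    return(gw_envelope(object, type = type, rep = rep, seed = seed,
                       parallel = parallel, ncores = ncores))
  y <- gw_response(object)
  gw_resid(y, stats::fitted(object), object$betaII[["k"]],
           object$betaII[["ro"]], type)
}

gw_response <- function(object) {
  if (!is.null(object[["y"]])) return(object[["y"]])
  if (!is.null(object[["model"]]))
    return(stats::model.response(object[["model"]]))
  stop("fit carries neither 'y' nor the model frame; refit with y = TRUE",
       call. = FALSE)
}

gw_design <- function(object) {
  if (!is.null(object[["x"]])) return(object[["x"]])
  if (!is.null(object[["model"]]))
    return(stats::model.matrix(object$terms, object[["model"]],
                               contrasts.arg = object$contrasts))
  stop("fit carries no design information; refit with model = TRUE",
       call. = FALSE)
}

#' Simulated normal-plot envelope for GWRM residuals
#'
#' Parametric-bootstrap envelope: `rep` response vectors are simulated from
#' the fitted model at the observed covariates, the model is refitted to
#' each, and the per-rank minimum and maximum of the sorted replicate
#' residuals form the envelope.  With the default `rep = 19` the largest
#' absolute residual of correctly specified data escapes the envelope with
#' probability about 1 in 20 (5%).  Refitting each replicate (rather than
#' reusing the original estimates) lets the band reflect estimation noise.
#'
#' Replicates draw per-replicate seeds derived from `seed`, so the result
#' is identical whether computed serially or in parallel, and envelopes
#' with larger `rep` under the same `seed` nest the smaller ones.  A
#' replicate whose refit fails is re-simulated under the next derived seed,
#' up to 3 attempts.
#'
#' @param object a converged [gw()] fit (with model frame stored).
#' @param type residual type, as in [residuals.gw()].
#' @param rep number of simulated replicates (default 19).
#' @param seed integer seed for the bootstrap.
#' @param parallel logical; fork the replicates over `ncores` workers.
#' @param ncores number of workers when `parallel = TRUE`.
#' @return an object of class `"gw_envelope"`: list with
#'   `ordered_residuals`, normal `reference_quantiles`, per-rank `lower`
#'   and `upper` bounds, `n_outside`, `rep`, `seed` and `type`.  A `plot`
#'   method draws the normal plot with the envelope band.
#' @export
gw_envelope <- function(object, type = c("pearson", "deviance", "response"),
                        rep = 19L, seed = NULL, parallel = TRUE,
                        ncores = 2L) {
  type <- match.arg(type)
  if (!inherits(object, "gw") || is.null(object$converged) ||
      object$converged != 0L)
    stop("'object' must be a converged gw fit", call. = FALSE)
  if (rep < 1L) stop("'rep' must be at least 1", call. = FALSE)
  y <- gw_response(object)
  X <- gw_design(object)
  n <- length(y)
  mu <- stats::fitted(object)
  k <- object$betaII[["k"]]; rho <- object$betaII[["ro"]]
  a <- mu * (rho - 1) / k
  w <- object$prior.weights; off <- object$offset
  fixk <- if (object$k_fixed) k else NULL

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  base_seeds <- sample.int(.Machine$integer.max - 1e8L, rep)

  one_rep <- function(i) {
    for (attempt in 0:2) {
      set.seed(base_seeds[i] + attempt * 10007L)
      ysim <- rugwd(n, a, k, rho)
      eng <- tryCatch(suppressWarnings(
        gw_engine(ysim, X, off, w,
                  kstart = k, rostart = rho,
                  betastart = stats::coef(object), fixk = fixk,
                  method = "L-BFGS-B", control = object$control %||%
                    gw_control(), hessian = FALSE)),
        error = function(e) NULL)
      if (is.null(eng) || eng$converged != 0L) next
      musim <- exp(drop(X %*% eng$beta) + off)
      r <- tryCatch(gw_resid(ysim, musim, eng$k, eng$rho, type),
                    error = function(e) NULL)
      if (is.null(r) || anyNA(r)) next
      return(sort(r))
    }
    stop("envelope replicate ", i, " failed to refit after 3 attempts",
         call. = FALSE)
  }

  sims <- if (parallel && ncores > 1L &&
              .Platform$OS.type == "unix") {
    out <- parallel::mclapply(seq_len(rep), one_rep, mc.cores = ncores)
    err <- vapply(out, inherits, logical(1), "try-error")
    if (any(err)) stop(attr(out[[which(err)[1]]], "condition")$message,
                       call. = FALSE)
    out
  } else lapply(seq_len(rep), one_rep)

  simmat <- do.call(rbind, sims)
  lower <- apply(simmat, 2L, min)
  upper <- apply(simmat, 2L, max)
  obs <- sort(gw_resid(y, mu, k, rho, type))
  structure(list(type = type,
                 ordered_residuals = obs,
                 reference_quantiles = stats::qnorm(stats::ppoints(n)),
                 lower = lower, upper = upper,
                 n_outside = sum(obs < lower | obs > upper),
                 rep = as.integer(rep), seed = as.integer(seed)),
            class = "gw_envelope")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gw_envelope <- function(x, ...) {
  cat("Simulated envelope (", x$rep, " replicates) for ", x$type,
      " residuals\n", sep = "")
  cat(length(x$ordered_residuals), "residuals,", x$n_outside,
      "outside the envelope\n")
  invisible(x)
}

#' Normal plot of residuals with simulated envelope
#'
#' @param x a [gw_envelope()] object.
#' @param main,xlab,ylab usual plot labels.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.gw_envelope <- function(x, main = "Simulated envelope",
                             xlab = "Normal order statistics",
                             ylab = paste(x$type, "residuals"), ...) {
  q <- x$reference_quantiles
  ylim <- range(x$lower, x$upper, x$ordered_residuals)
  graphics::plot(q, x$ordered_residuals, ylim = ylim, main = main,
                 xlab = xlab, ylab = ylab, pch = 1, ...)
  graphics::polygon(c(q, rev(q)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("grey60", alpha.f = 0.4),
                    border = NA)
  graphics::lines(q, x$lower, lty = 2)
  graphics::lines(q, x$upper, lty = 2)
  graphics::points(q, x$ordered_residuals, pch = 1)
  invisible(x)
}
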