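## Inference on GWRM fits: variance partition, likelihood-ratio tests,
## single-term scans and stepwise selection.

#' Partition of the variance into randomness, liability and proneness
#'
#' Splits the conditional variance of a generalized Waring regression model
#' into its three sources for each covariate pattern: randomness
#' \eqn{\mu} (the Poisson stage), liability \eqn{\mu(k+1)/(\rho-2)}
#' (differing exposures to risk, external factors) and proneness
#' \eqn{\mu^2(k+\rho-1)/(k(\rho-2))} (stable individual differences,
#' internal factors).  The partition exists only when \eqn{\hat\rho > 2}
#' (finite variance).
#'
#' @param object a fitted [gw()] model with \eqn{\hat\rho > 2}.
#' @param newdata optional data frame of covariate patterns; defaults to
#'   the fitting data.
#' @param ... unused.
#' @return an object of class `"gw_partvar"`: a list with data frames
#'   `Abs.Variance` and `Prop.Variance` (columns `Randomness`, `Liability`,
#'   `Proneness`; proportions sum to 1 per row) plus vectors `mu` and
#'   `total`.
#' @export
partvar <- function(object, ...) UseMethod("partvar")

#' @rdname partvar
#' @export
partvar.gw <- function(object, newdata = NULL, ...) {
  k <- object$betaII[["k"]]
  rho <- object$betaII[["ro"]]
  if (rho <= 2)
    stop("variance partition undefined: estimated rho <= 2 ",
         "(infinite variance)", call. = FALSE)
  if (rho <= 2.001)
    warning("estimated rho is barely above 2; the variance is nearly ",
            "infinite and the partition is numerically fragile",
            call. = FALSE)
  mu <- if (is.null(newdata)) stats::fitted(object)
        else predict.gw(object, newdata, type = "response")
  comp <- ugwd_partition(mu, k, rho)
  total <- rowSums(comp)
  abs_df <- data.frame(Randomness = comp[, "randomness"],
                       Liability = comp[, "liability"],
                       Proneness = comp[, "proneness"])
  prop_df <- abs_df / total
  structure(list(Abs.Variance = abs_df, Prop.Variance = prop_df,
                 mu = mu, total = total, k = k, rho = rho),
            class = "gw_partvar")
}

#' @export
print.gw_partvar <- function(x, digits = 7L, max_rows = 10L, ...) {
  n <- nrow(x$Abs.Variance)
  show <- seq_len(min(n, max_rows))
  cat("Absolute variance components:\n")
  print(format(x$Abs.Variance[show, , drop = FALSE], digits = digits),
        quote = FALSE)
  cat("\nProportion of each component:\n")
  print(format(x$Prop.Variance[show, , drop = FALSE], digits = digits),
        quote = FALSE)
  if (n > max_rows) cat("... (", n - max_rows, " more rows)\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test between nested GWRM fits
#'
#' Twice the log-likelihood difference between two nested fits, referred to
#' the upper tail of a chi-squared distribution with degrees of freedom
#' equal to the difference in the number of free parameters.
#'
#' @param object,object2 two [gw()] fits of nested mean models on the same
#'   data (same rows, offset and weights).
#' @return an object of class `"htest"`.
#' @export
lrt <- function(object, object2) {
  if (!inherits(object, "gw") || !inherits(object2, "gw"))
    stop("'lrt' expects two gw fits", call. = FALSE)
  if (!identical(object$nobs, object2$nobs))
    stop("fits use different numbers of observations", call. = FALSE)
  small <- if (object$npar <= object2$npar) object else object2
  big <- if (object$npar <= object2$npar) object2 else object
  t_small <- attr(stats::terms(small$terms), "term.labels")
  t_big <- attr(stats::terms(big$terms), "term.labels")
  if (!all(t_small %in% t_big))
    stop("models are not nested: ",
         paste(setdiff(t_small, t_big), collapse = ", "),
         " not in the larger model", call. = FALSE)
  df <- big$npar - small$npar
  stat <- max(0, 2 * (big$loglik - small$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = c(LRT = stat), parameter = c(df = df),
                 p.value = p,
                 method = "Likelihood ratio test for nested GWRM fits",
                 data.name = paste(deparse(stats::formula(small$terms)),
                                   "vs", deparse(stats::formula(big$terms)))),
            class = "htest")
}

## Refit `object` with an updated formula; candidate data are taken from
## `data` if given, else from re-evaluating the original call.
gw_update <- function(object, new_formula, data = NULL, env = parent.frame()) {
  call <- object$call
  call$formula <- new_formula
  if (!is.null(data)) call$data <- data
  eval(call, env)
}

scan_one <- function(object, term, add, criterion, data, env) {
  f_old <- stats::formula(object$terms)
  f_new <- stats::update.formula(f_old, if (add)
    stats::as.formula(paste(". ~ . +", term))
    else stats::as.formula(paste(". ~ . -", term)))
  fit <- tryCatch(suppressWarnings(suppressMessages(
    gw_update(object, f_new, data, env))), error = function(e) NULL)
  if (is.null(fit) || fit$converged != 0L)
    return(list(fit = fit, ok = FALSE))
  list(fit = fit, ok = TRUE)
}

crit_value <- function(fit, criterion) {
  switch(criterion, AIC = fit$aic, BIC = fit$bic, LRT = -2 * fit$loglik)
}

## Shared engine for add1/drop1: one refit per candidate term.
gw_scan <- function(object, terms, add, criterion, data, env) {
  criterion <- match.arg(criterion, c("AIC", "BIC", "LRT"))
  rows <- lapply(terms, function(tm) {
    sc <- scan_one(object, tm, add, criterion, data, env)
    if (is.null(sc$fit))
      return(data.frame(term = tm, df = NA_integer_, value = NA_real_,
                        LRT = NA_real_, `Pr(Chi)` = NA_real_,
                        converged = FALSE, check.names = FALSE))
    fit <- sc$fit
    ddf <- abs(fit$npar - object$npar)
    stat <- 2 * abs(fit$loglik - object$loglik)
    data.frame(term = tm, df = ddf,
               value = crit_value(fit, criterion),
               LRT = stat,
               `Pr(Chi)` = if (ddf > 0)
                 stats::pchisq(stat, ddf, lower.tail = FALSE) else NA_real_,
               converged = sc$ok, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- data.frame(term = "<none>", df = 0L,
                     value = crit_value(object, criterion),
                     LRT = NA_real_, `Pr(Chi)` = NA_real_, converged = TRUE,
                     check.names = FALSE)
  out <- rbind(base, out)
  names(out)[names(out) == "value"] <- criterion
  if (criterion != "LRT") out$LRT <- NULL
  if (criterion %in% c("AIC", "BIC")) out$`Pr(Chi)` <- NULL
  out[order(out[[criterion]]), ]
}

#' Single-term additions to a GWRM fit
#'
#' Refits the model once per candidate term in `scope` and tabulates the
#' chosen criterion; candidates whose refit fails to converge are kept in
#' the table and flagged rather than dropped.
#'
#' @param object a fitted [gw()] model.
#' @param scope a right-hand-side formula (or character vector) of
#'   candidate terms.
#' @param criterion `"AIC"`, `"BIC"` or `"LRT"`.
#' @param data optional data frame holding the scope variables (defaults to
#'   re-evaluating the fit's `data` argument).
#' @param ... unused.
#' @return a data frame sorted by the criterion, one row per candidate plus
#'   a `<none>` row for the current model.
#' @export
add1.gw <- function(object, scope, criterion = c("AIC", "BIC", "LRT"),
                    data = NULL, ...) {
  criterion <- match.arg(criterion)
  terms <- scope_terms(scope)
  have <- attr(stats::terms(object$terms), "term.labels")
  terms <- setdiff(terms, have)
  gw_scan(object, terms, add = TRUE, criterion = criterion, data = data,
          env = parent.frame())
}

#' Single-term deletions from a GWRM fit
#'
#' @inheritParams add1.gw
#' @param scope optional terms to consider dropping; defaults to all terms
#'   in the model.
#' @return a data frame sorted by the criterion (see [add1.gw()]).
#' @export
drop1.gw <- function(object, scope = NULL, criterion = c("AIC", "BIC", "LRT"),
                     data = NULL, ...) {
  criterion <- match.arg(criterion)
  have <- attr(stats::terms(object$terms), "term.labels")
  terms <- if (is.null(scope)) have else intersect(scope_terms(scope), have)
  gw_scan(object, terms, add = FALSE, criterion = criterion, data = data,
          env = parent.frame())
}

scope_terms <- function(scope) {
  if (is.character(scope)) return(scope)
  if (inherits(scope, "formula"))
    return(attr(stats::terms(scope), "term.labels"))
  stop("'scope' must be a formula or a character vector of terms",
       call. = FALSE)
}

#' Stepwise GWRM model selection by AIC or BIC
#'
#' Greedy single-term stepwise search: at each round every admissible
#' addition (within `scope`) and deletion is refitted and the move that
#' most improves the criterion is taken; the search stops when no move
#' strictly improves it.  Ties within `1e-8` are resolved in favour of the
#' smaller model.  The search is deterministic given the data.
#'
#' @param object the starting [gw()] fit.
#' @param scope right-hand-side formula (or character vector) giving the
#'   admissible terms.
#' @param direction `"both"`, `"forward"` or `"backward"`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param data optional data frame holding the scope variables.
#' @param trace logical; print each step.
#' @return the selected `"gw"` fit, with the search history as a data frame
#'   in `$step_trace` (every candidate evaluated, with criterion values and
#'   convergence flags).
#' @export
step_gw <- function(object, scope, direction = c("both", "forward",
                                                 "backward"),
                    criterion = c("AIC", "BIC"), data = NULL, trace = FALSE) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  env <- parent.frame()
  all_terms <- if (missing(scope) || is.null(scope)) character(0)
               else scope_terms(scope)
  current <- object
  history <- list()
  step_no <- 0L
  repeat {
    step_no <- step_no + 1L
    have <- attr(stats::terms(current$terms), "term.labels")
    cands <- list()
    if (direction %in% c("both", "forward"))
      for (tm in setdiff(all_terms, have))
        cands[[paste("+", tm)]] <- list(term = tm, add = TRUE)
    if (direction %in% c("both", "backward"))
      for (tm in have)
        cands[[paste("-", tm)]] <- list(term = tm, add = FALSE)
    if (!length(cands)) break
    cur_val <- crit_value(current, criterion)
    best <- NULL; best_val <- Inf; best_move <- ""
    for (nm in names(cands)) {
      cd <- cands[[nm]]
      sc <- scan_one(current, cd$term, cd$add, criterion, data, env)
      val <- if (sc$ok) crit_value(sc$fit, criterion) else NA_real_
      history[[length(history) + 1L]] <-
        data.frame(step = step_no, move = nm, criterion = criterion,
                   value = val, converged = sc$ok)
      if (!sc$ok || is.na(val)) next
      ## smaller criterion wins; ties (within 1e-8) go to the smaller model
      if (is.null(best) || val < best_val - 1e-8 ||
          (abs(val - best_val) <= 1e-8 && sc$fit$npar < best$npar)) {
        best <- sc$fit; best_val <- val; best_move <- nm
      }
    }
    accept <- !is.null(best) &&
      (best_val < cur_val - 1e-8 ||
       (abs(best_val - cur_val) <= 1e-8 && best$npar < current$npar))
    if (!accept) break
    if (trace)
      cat(sprintf("Step %d: %s  %s = %.4f\n", step_no, best_move,
                  criterion, best_val))
    current <- best
  }
  current$step_trace <- if (length(history)) do.call(rbind, history)
                        else data.frame(step = integer(0), move = character(0),
                                        criterion = character(0),
                                        value = numeric(0),
                                        converged = logical(0))
  current
}
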