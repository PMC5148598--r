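## Dataset reading and JSON serialization of fits.

#' Read a count-regression dataset
#'
#' Reads a table with a header row, auto-detecting comma-separated (CSV)
#' versus whitespace-delimited layout.  Character columns become factors.
#' If `response` is given the column is validated as non-negative integer
#' counts, with offending line numbers reported.
#'
#' @param path file path.
#' @param response optional name of the count response column to validate.
#' @param required optional character vector of column names that must be
#'   present.
#' @return a data frame.
#' @export
read_count_data <- function(path, response = NULL, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty data file: ", path, call. = FALSE)
  df <- if (grepl(",", first))
    utils::read.csv(path, stringsAsFactors = TRUE)
  else
    utils::read.table(path, header = TRUE, stringsAsFactors = TRUE)
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  missing_cols <- setdiff(c(required, response), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(response)) {
    v <- df[[response]]
    vv <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(vv) & !is.na(v))
    if (length(bad))
      stop("non-numeric count in column '", response, "' at data line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    bad <- which(!is.na(vv) & (vv < 0 | vv != floor(vv)))
    if (length(bad))
      stop("column '", response, "' must hold non-negative integers; ",
           "violation at data line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "),
           call. = FALSE)
    df[[response]] <- as.integer(vv)
  }
  df
}

#' Serialize a GWRM fit to JSON
#'
#' Writes every reproducible component of the fit (formula, coefficients,
#' dispersion parameters, covariance with labels in row-major order,
#' likelihood and information criteria, convergence metadata, factor
#' levels) so that the fit can be reloaded with [gw_from_json()] and used
#' for prediction and variance partition.
#'
#' @param object a fitted [gw()] model.
#' @param file optional path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `file`.
#' @export
gw_to_json <- function(object, file = NULL) {
  stopifnot(inherits(object, "gw"))
  vc <- object$vcov
  out <- list(
    class = "gw",
    formula = paste(deparse(stats::formula(object$terms)), collapse = " "),
    coefficients = as.list(stats::coef(object)),
    k = object$betaII[["k"]], ro = object$betaII[["ro"]],
    k_fixed = object$k_fixed,
    se = as.list(object$se), se_scale = object$se_scale,
    vcov = if (is.null(vc)) NULL else
      list(labels = names(object$se), values = as.numeric(t(vc))),
    loglik = object$loglik, aic = object$aic, bic = object$bic,
    npar = object$npar, df_residual = object$df.residual,
    nobs = object$nobs, converged = object$converged,
    method = object$method,
    xlevels = object$xlevels)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Reload a GWRM fit from JSON
#'
#' @param file path to (or string of) JSON written by [gw_to_json()].
#' @return a `"gw"` object supporting `predict`, `partvar`, `coef`,
#'   `logLik` and `summary` (no stored data, so residuals and envelopes
#'   require the original dataset).
#' @export
gw_from_json <- function(file) {
  src <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (!identical(src$class, "gw"))
    stop("not a serialized gw fit", call. = FALSE)
  coefs <- unlist(src$coefficients)
  f <- stats::as.formula(src$formula)
  mt <- stats::delete.response(stats::terms(f))
  se <- unlist(src$se)
  vc <- NULL
  if (!is.null(src$vcov)) {
    d <- length(src$vcov$labels)
    vc <- matrix(src$vcov$values, d, d, byrow = TRUE,
                 dimnames = list(src$vcov$labels, src$vcov$labels))
  }
  xlev <- src$xlevels
  if (!is.null(xlev) && !length(xlev)) xlev <- NULL
  structure(list(coefficients = coefs,
                 betaII = c(k = src$k, ro = src$ro),
                 k_fixed = isTRUE(src$k_fixed),
                 se = se, se_scale = src$se_scale, vcov = vc,
                 loglik = src$loglik, aic = src$aic, bic = src$bic,
                 npar = src$npar, df.residual = src$df_residual,
                 nobs = src$nobs, converged = src$converged,
                 method = src$method,
                 terms = mt, xlevels = xlev, contrasts = NULL,
                 call = quote(gw_from_json())),
            class = "gw")
}

#' Write a variance partition to CSV
#'
#' @param x a [partvar()] result.
#' @param file output path.
#' @return the written data frame, invisibly.
#' @export
partvar_to_csv <- function(x, file) {
  stopifnot(inherits(x, "gw_partvar"))
  df <- data.frame(mu = x$mu,
                   randomness = x$Abs.Variance$Randomness,
                   liability = x$Abs.Variance$Liability,
                   proneness = x$Abs.Variance$Proneness,
                   total_variance = x$total,
                   prop_randomness = x$Prop.Variance$Randomness,
                   prop_liability = x$Prop.Variance$Liability,
                   prop_proneness = x$Prop.Variance$Proneness)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Serialize an envelope to JSON
#'
#' @param x a [gw_envelope()] result.
#' @param file optional path.
#' @return JSON string (invisibly when written to file).
#' @export
envelope_to_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "gw_envelope"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
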