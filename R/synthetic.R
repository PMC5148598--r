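## Synthetic regression data with the exact structure the GWRM assumes,
## plus two canned fixtures emulating the shapes of common case studies
## (a health-survey table and a goals-by-exposure table).

draw_covariate <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$type))
    stop("each covariate spec must be a list with a 'type' field",
         call. = FALSE)
  switch(spec$type,
    binary = stats::rbinom(n, 1L, spec$prob %||% 0.5),
    uniform = stats::runif(n, spec$min %||% 0, spec$max %||% 1),
    uniform_int = sample(seq.int(spec$min %||% 1L, spec$max %||% 10L),
                         n, replace = TRUE),
    categorical = factor(sample(spec$levels, n, replace = TRUE,
                                prob = spec$probs %||% NULL),
                         levels = spec$levels),
    stop("unknown covariate type: ", spec$type, call. = FALSE))
}

#' Simulate a dataset from the generalized Waring regression model
#'
#' Covariates are drawn per the profile, the mean is
#' \eqn{\mu_i = e^{x_i'\beta + \mathrm{offset}_i}}, and responses are drawn
#' from UGWD(\eqn{\mu_i(\rho-1)/k}, k, \eqn{\rho}) via [rugwd()], i.e. the
#' exact data-generating process the model assumes.
#'
#' @param n number of rows.
#' @param beta coefficient vector: intercept first, then one value per
#'   design column generated by the covariate profile (factors are
#'   dummy-coded against their first level).
#' @param k,rho dispersion parameters of the data-generating process
#'   (`k > 0`, `rho > 1`).
#' @param covariates named list of covariate specifications; each element
#'   is a list with a `type` field: `"binary"` (field `prob`), `"uniform"`
#'   (`min`, `max`), `"uniform_int"` (`min`, `max`) or `"categorical"`
#'   (`levels`, optional `probs`).
#' @param offset optional list `list(column = <name>, log = TRUE)` naming a
#'   generated column used as exposure: `log(column)` enters the linear
#'   predictor with coefficient 1 (and the column is excluded from `beta`).
#' @param response name of the response column (default `"y"`).
#' @param seed optional integer seed.
#' @return a list with `data` (a data frame: covariates, exposure column if
#'   any, and the response) and `truth` (all generating parameters,
#'   suitable for JSON serialization).
#' @examples
#' sim <- gw_simulate(200, beta = c(0.5, 1), k = 2, rho = 5,
#'                    covariates = list(x = list(type = "binary", prob = 0.5)),
#'                    seed = 1)
#' head(sim$data)
#' @export
gw_simulate <- function(n, beta, k, rho,
                        covariates = list(), offset = NULL,
                        response = "y", seed = NULL) {
  check_ugwd_params(1, k, rho)
  if (rho <= 1) stop("'rho' must exceed 1", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  df <- as.data.frame(lapply(covariates, draw_covariate, n = n),
                      optional = TRUE)
  if (!length(covariates)) df <- data.frame(row.names = seq_len(n))

  off <- rep(0, n)
  model_cols <- names(covariates)
  if (!is.null(offset)) {
    if (is.null(offset$column) || !offset$column %in% names(df))
      stop("offset column not found in the covariate profile", call. = FALSE)
    off <- if (isTRUE(offset$log) || is.null(offset$log))
      log(df[[offset$column]]) else df[[offset$column]]
    model_cols <- setdiff(model_cols, offset$column)
  }
  X <- if (length(model_cols))
    stats::model.matrix(stats::reformulate(model_cols), df)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(beta) != ncol(X))
    stop("'beta' must have length ", ncol(X),
         " (intercept + dummy-coded covariates); got ", length(beta),
         call. = FALSE)
  mu <- exp(drop(X %*% beta) + off)
  df[[response]] <- rugwd(n, mu * (rho - 1) / k, k, rho)

  truth <- list(n = n, beta = stats::setNames(as.numeric(beta), colnames(X)),
                k = k, rho = rho,
                offset = if (is.null(offset)) NULL else offset$column,
                response = response, seed = seed)
  list(data = df, truth = truth)
}

#' Canned synthetic fixtures
#'
#' Two ready-made dataset shapes for examples and tests:
#' \describe{
#'   \item{`badhealth_like`}{health-survey shape: a binary bad-health
#'     indicator (prevalence 0.11), an integer age uniform on 20--60 with
#'     zero true effect, and counts generated with
#'     \eqn{\beta = (0.66, 1.16, 0)}, `k = 1.57`, `rho = 6.85`.  Columns
#'     `numvisit`, `badh`, `age`.}
#'   \item{`goals_like`}{sport shape: a 3-level playing position (reference
#'     `"defender"`), an integer exposure `Matches` uniform on 1--38 whose
#'     log enters as offset, and counts generated with
#'     \eqn{\beta = (-3.8, 0.9, 2.0)} for (intercept, midfielder, forward),
#'     `k = 1.2`, `rho = 4`.  Columns `Goals`, `Position`, `Matches`.}
#' }
#' The generating values are arbitrary defaults inspired by published
#' estimates for data of these shapes; they are not the real datasets.
#'
#' @param name `"badhealth_like"` or `"goals_like"`.
#' @param n number of rows (defaults: 1127 and 400).
#' @param seed optional integer seed.
#' @return a list with `data` and `truth`, as in [gw_simulate()].
#' @export
gw_fixture <- function(name = c("badhealth_like", "goals_like"), n = NULL,
                       seed = NULL) {
  name <- match.arg(name)
  if (name == "badhealth_like") {
    n <- n %||% 1127L
    sim <- gw_simulate(n, beta = c(0.66, 1.16, 0), k = 1.57, rho = 6.85,
                       covariates = list(
                         badh = list(type = "binary", prob = 0.11),
                         age = list(type = "uniform_int", min = 20L,
                                    max = 60L)),
                       response = "numvisit", seed = seed)
    sim$data <- sim$data[, c("numvisit", "badh", "age")]
  } else {
    n <- n %||% 400L
    sim <- gw_simulate(n, beta = c(-3.8, 0.9, 2.0), k = 1.2, rho = 4,
                       covariates = list(
                         Position = list(type = "categorical",
                                         levels = c("defender", "midfielder",
                                                    "forward"),
                                         probs = c(0.4, 0.4, 0.2)),
                         Matches = list(type = "uniform_int", min = 1L,
                                        max = 38L)),
                       offset = list(column = "Matches", log = TRUE),
                       response = "Goals", seed = seed)
    sim$data <- sim$data[, c("Goals", "Position", "Matches")]
  }
  sim
}
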