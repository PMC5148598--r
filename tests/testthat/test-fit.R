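# Maximum-likelihood fitting of the regression model.

test_that("analytic gradient matches central finite differences", {
  sim <- sim_binary(n = 400, seed = 3)
  X <- model.matrix(~xbin, sim$data)
  y <- sim$data$y
  off <- rep(0, nrow(X)); w <- rep(1, nrow(X))
  for (logscale in c(FALSE, TRUE)) {
    par <- if (logscale) c(0.4, 0.9, log(1.3), log(4.1)) else
      c(0.4, 0.9, 1.3, 5.1)
    g <- gwaring:::gw_negll_grad(par, y, X, off, w, logscale = logscale)
    fn <- function(p) gwaring:::gw_negll(p, y, X, off, w, logscale = logscale)
    h <- 1e-6
    gn <- vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- h
      (fn(par + e) - fn(par - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn) / pmax(abs(gn), 1)), 1e-4)
  }
})

test_that("negative log-likelihood agrees with the pointwise mass function", {
  sim <- sim_binary(n = 200, seed = 5)
  X <- model.matrix(~xbin, sim$data)
  y <- sim$data$y
  par <- c(0.5, 1.0, 1.6, 6.1)
  val <- gwaring:::gw_negll(par, y, X, rep(0, 200), rep(1, 200))
  mu <- exp(drop(X %*% par[1:2]))
  ref <- -sum(dugwd(y, mu * (par[4] - 1) / par[3], par[3], par[4], log = TRUE))
  expect_equal(val, ref, tolerance = 1e-10)
})

test_that("fitting recovers the generating parameters", {
  sim <- sim_binary(n = 1500, seed = 11)
  fit <- gw(y ~ xbin, data = sim$data)
  expect_identical(fit$converged, 0L)
  est <- c(coef(fit), fit$betaII)
  truth <- c(0.66, 1.16, 1.57, 6.85)
  expect_true(all(abs(est - truth) / fit$se < 4))
  expect_gt(fit$betaII[["ro"]], 1)
  # identities
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(fit$bic, -2 * fit$loglik + log(fit$nobs) * fit$npar)
  expect_identical(fit$npar, length(coef(fit)) + 2L)
  expect_identical(fit$df.residual, fit$nobs - fit$npar)
  # likelihood improved over the start point (kstart = 1, rostart = 2)
  X <- model.matrix(~xbin, sim$data)
  bs <- glm.fit(X, sim$data$y, family = poisson())$coefficients
  ll0 <- -gwaring:::gw_negll(c(bs, 1, 2), sim$data$y, X,
                             rep(0, 1500), rep(1, 1500))
  expect_gte(fit$loglik, ll0)
})

test_that("log-scale and natural-scale optimizers reach the same optimum", {
  sim <- sim_binary(n = 800, seed = 13)
  f_default <- gw(y ~ xbin, data = sim$data)
  f_nlm <- gw(y ~ xbin, data = sim$data, method = "nlm")
  expect_lt(abs(f_default$loglik - f_nlm$loglik), 1e-4)
  # single-stage log-scale methods report no SEs for k and rho
  expect_identical(f_nlm$se_scale, "log")
  expect_true(all(is.na(summary(f_nlm)$betaII[, "Std. Error"])))
  expect_false(anyNA(summary(f_default)$betaII[, "Std. Error"]))
})

test_that("fixing k at its estimate reproduces the fit with one fewer parameter", {
  sim <- sim_binary(n = 800, seed = 17)
  fit <- gw(y ~ xbin, data = sim$data)
  fitk <- gw(y ~ xbin, data = sim$data, k = fit$betaII[["k"]])
  expect_identical(fitk$npar, fit$npar - 1L)
  expect_equal(coef(fitk), coef(fit), tolerance = 1e-3)
  expect_equal(fitk$betaII[["ro"]], fit$betaII[["ro"]], tolerance = 1e-2)
})

test_that("weights scale the log-likelihood without moving the estimates", {
  sim <- sim_binary(n = 400, seed = 19)
  f1 <- gw(y ~ xbin, data = sim$data)
  f2 <- gw(y ~ xbin, data = sim$data, weights = rep(2, 400))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-4)
  expect_identical(f2$nobs, 400L)
})

test_that("design handling: shapes, offsets, missing rows, validation", {
  fx <- gw_fixture("badhealth_like", seed = 23)
  expect_identical(names(fx$data), c("numvisit", "badh", "age"))
  expect_identical(nrow(fx$data), 1127L)
  fit <- fast_gw(numvisit ~ badh, data = fx$data)
  expect_identical(length(coef(fit)), 2L)
  expect_identical(fit$df.residual, 1123L)

  fit0 <- fast_gw(numvisit ~ 1, data = fx$data)
  expect_identical(fit0$df.residual, 1124L)

  # categorical with reference level and a log offset
  gl <- gw_fixture("goals_like", n = 300, seed = 29)
  fitg <- fast_gw(Goals ~ Position + offset(log(Matches)), data = gl$data)
  expect_identical(names(coef(fitg)),
                   c("(Intercept)", "Positionmidfielder", "Positionforward"))

  # missing rows are dropped with a message
  dd <- fx$data; dd$badh[1:3] <- NA
  expect_message(gw(numvisit ~ badh, data = dd, method = "L-BFGS-B"),
                 "3 row")

  # invalid responses are rejected
  dd2 <- fx$data; dd2$numvisit[1] <- -1
  expect_error(gw(numvisit ~ badh, data = dd2), "non-negative integer")
  dd3 <- fx$data; dd3$numvisit <- dd3$numvisit + 0.5
  expect_error(gw(numvisit ~ badh, data = dd3), "non-negative integer")
})

test_that("Wald summary satisfies its identities", {
  sim <- sim_binary(n = 600, seed = 31)
  fit <- gw(y ~ xbin, data = sim$data)
  sm <- summary(fit)
  cf <- sm$coefficients
  expect_equal(unname(cf[, "z value"] * cf[, "Std. Error"]),
               unname(cf[, "Estimate"]))
  expect_equal(unname(cf[, "Pr(>|z|)"]),
               unname(2 * pnorm(abs(cf[, "z value"]), lower.tail = FALSE)))
  expect_output(print(sm), "Code of convergence")
})
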