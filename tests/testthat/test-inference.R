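# Prediction, variance partition, LRT, single-term scans, stepwise search.

test_that("prediction contracts: link, response, offsets, unseen levels", {
  m0 <- as_gw(~x1, coefficients = c(0, 0), k = 2, rho = 5,
              data = data.frame(x1 = 0))
  nd <- data.frame(x1 = c(-2, 0, 3.5))
  expect_equal(unname(predict(m0, nd)), rep(1, 3))
  expect_equal(unname(predict(m0, nd, type = "link")), rep(0, 3))

  m1 <- as_gw(~x1 + offset(off), coefficients = c(0.3, 0.7), k = 2, rho = 5,
              data = data.frame(x1 = 0, off = 0))
  nd1 <- data.frame(x1 = c(0, 1), off = 0)
  nd2 <- data.frame(x1 = c(0, 1), off = log(2))
  expect_equal(predict(m1, nd2), 2 * predict(m1, nd1))

  mf <- as_gw(~grp, coefficients = c(0.1, 0.5), k = 2, rho = 5,
              data = data.frame(grp = factor(c("a", "b"))))
  expect_error(predict(mf, data.frame(grp = "c")), "level")
})

test_that("partvar agrees with the moments oracle and normalizes", {
  sim <- sim_binary(n = 700, seed = 37)
  fit <- fast_gw(y ~ xbin, data = sim$data)
  pv <- partvar(fit, newdata = data.frame(xbin = c(0, 1)))
  expect_equal(rowSums(pv$Prop.Variance), c(1, 1), tolerance = 1e-10)
  expect_equal(rowSums(pv$Abs.Variance), pv$total)
  k <- fit$betaII[["k"]]; rho <- fit$betaII[["ro"]]
  mo <- ugwd_moments(a = pv$mu * (rho - 1) / k, k = k, rho = rho)
  expect_equal(pv$total, mo$variance, tolerance = 1e-10)
  expect_equal(pv$Abs.Variance$Proneness, mo$proneness, tolerance = 1e-10)
})

test_that("partvar is undefined for rho <= 2 and monotone in mu", {
  mbad <- as_gw(~x1, coefficients = c(0, 1), k = 2, rho = 1.8,
                data = data.frame(x1 = 0))
  expect_error(partvar(mbad, data.frame(x1 = 0)), "rho <= 2")

  # larger mu shifts variance share from randomness toward proneness
  m <- as_gw(~x1, coefficients = c(0, 1), k = 2, rho = 5,
             data = data.frame(x1 = 0))
  pv <- partvar(m, data.frame(x1 = c(0, 1, 2, 3)))
  expect_true(all(diff(pv$Prop.Variance$Randomness) < 0))
  expect_true(all(diff(pv$Prop.Variance$Proneness) > 0))
})

test_that("likelihood-ratio test contracts hold", {
  sim <- sim_noise(n = 800, seed = 41)
  f0 <- fast_gw(y ~ 1, data = sim$data)
  f1 <- fast_gw(y ~ xbin, data = sim$data)
  self <- lrt(f1, f1)
  expect_equal(unname(self$statistic), 0)
  expect_equal(self$p.value, 1)

  lr <- lrt(f0, f1)
  expect_identical(unname(lr$parameter), 1L)
  expect_lt(lr$p.value, 1e-6)   # xbin is informative

  # invariant to affine recoding of the shared covariate
  d2 <- sim$data; d2$xbin <- 10 * d2$xbin - 3
  f0b <- fast_gw(y ~ 1, data = d2)
  f1b <- fast_gw(y ~ xbin, data = d2)
  expect_equal(unname(lrt(f0b, f1b)$statistic), unname(lr$statistic),
               tolerance = 1e-4)

  f2 <- fast_gw(y ~ znoise, data = sim$data)
  expect_error(lrt(f1, f2), "not nested")
})

test_that("add1/drop1 scan single terms consistently", {
  sim <- sim_noise(n = 800, seed = 43)
  f0 <- fast_gw(y ~ 1, data = sim$data)
  f1 <- fast_gw(y ~ xbin, data = sim$data)

  tab_add <- add1(f0, ~ xbin + znoise, data = sim$data)
  expect_setequal(tab_add$term, c("<none>", "xbin", "znoise"))
  expect_lt(tab_add$AIC[tab_add$term == "xbin"],
            tab_add$AIC[tab_add$term == "<none>"])

  tab_drop <- drop1(f1, data = sim$data)
  expect_equal(tab_drop$AIC[tab_drop$term == "xbin"], f0$aic,
               tolerance = 1e-4)

  tab_lrt <- drop1(f1, criterion = "LRT", data = sim$data)
  expect_true(all(c("LRT", "Pr(Chi)") %in% names(tab_lrt)))
})

test_that("stepwise search keeps the informative term and drops noise", {
  sim <- sim_noise(n = 2000, seed = 47)
  f0 <- fast_gw(y ~ 1, data = sim$data)
  sel <- step_gw(f0, scope = ~ xbin + znoise, direction = "both",
                 criterion = "AIC", data = sim$data)
  terms_sel <- attr(terms(sel$terms), "term.labels")
  expect_identical(terms_sel, "xbin")
  expect_true(is.data.frame(sel$step_trace) && nrow(sel$step_trace) > 0)

  # empty scope: unchanged model
  sel0 <- step_gw(f0, scope = NULL, direction = "forward", data = sim$data)
  expect_identical(attr(terms(sel0$terms), "term.labels"), character(0))

  # BIC penalty >= AIC penalty for n with log(n) > 2: never a strict superset
  selb <- step_gw(f0, scope = ~ xbin + znoise, direction = "both",
                  criterion = "BIC", data = sim$data)
  terms_bic <- attr(terms(selb$terms), "term.labels")
  expect_true(all(terms_bic %in% terms_sel))
})

test_that("LRT of a truly null covariate has approximately nominal size", {
  set.seed(53)
  seeds <- sample.int(1e6, 200)
  pvals <- vapply(seeds, function(s) {
    sim <- gw_simulate(2000, beta = c(0.6, 0), k = 2, rho = 6,
                       covariates = list(z = list(type = "uniform",
                                                  min = -1, max = 1)),
                       seed = s)
    f0 <- fast_gw(y ~ 1, data = sim$data, hessian = FALSE)
    f1 <- fast_gw(y ~ z, data = sim$data, hessian = FALSE)
    lrt(f0, f1)$p.value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # binomial 95% band around 0.05 with 200 replicates
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})
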