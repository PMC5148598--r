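# Distribution core: probability mass, moments, generation.

test_that("pmf matches the partial-fraction closed form and a Pochhammer oracle", {
  # UGWD(1, 1, 2) has the closed form f(y) = 4 / ((y+1)(y+2)(y+3))
  y <- 0:1000
  f <- dugwd(y, a = 1, k = 1, rho = 2)
  closed <- 4 / ((y + 1) * (y + 2) * (y + 3))
  expect_lt(max(abs(f - closed) / closed), 1e-12)
  expect_equal(dugwd(0, 1, 1, 2, log = TRUE), log(2 / 3), tolerance = 1e-12)

  # independent brute-force oracle: Pochhammer ratios in plain arithmetic
  poch <- function(alpha, r) if (r == 0) 1 else prod(alpha + 0:(r - 1))
  a <- 2; k <- 3; rho <- 4; yv <- 5
  oracle <- gamma(a + rho) * gamma(k + rho) / (gamma(a + k + rho) * gamma(rho)) *
    poch(a, yv) * poch(k, yv) / (poch(a + k + rho, yv) * factorial(yv))
  expect_equal(dugwd(yv, a, k, rho), oracle, tolerance = 1e-12)
})

test_that("pmf is normalized, exactly symmetric in a and k, and power-law tailed", {
  for (pars in list(c(2, 3, 5), c(0.5, 4, 2.5), c(1.57, 6.85, 3))) {
    y <- 0:20000
    s <- cumsum(dugwd(y, pars[1], pars[2], pars[3]))
    expect_true(all(diff(s) >= 0) && all(s <= 1 + 1e-12))
    expect_gte(s[length(s)], 0.999)
  }
  y <- 0:50
  expect_identical(dugwd(y, 2.3, 7.1, 4, log = TRUE),
                   dugwd(y, 7.1, 2.3, 4, log = TRUE))
  # f(y) * y^(rho+1) stabilizes to a positive constant; the approach is
  # O(1/y) with a constant growing with a + k + rho, so the window where
  # 1% constancy holds starts later for larger parameters
  r1 <- dugwd(1e3, 1, 1, 2) * 1e3^3
  r2 <- dugwd(1e4, 1, 1, 2) * 1e4^3
  expect_gt(r2, 0)
  expect_lt(abs(r1 / r2 - 1), 0.01)
  r3 <- dugwd(1e4, 2, 3, 5) * 1e4^6
  r4 <- dugwd(1e5, 2, 3, 5) * 1e5^6
  expect_gt(r4, 0)
  expect_lt(abs(r3 / r4 - 1), 0.01)
})

test_that("moments match truncated-sum oracles and flag undefined cases", {
  m <- ugwd_moments(a = 2, k = 3, rho = 5)
  y <- 0:200000
  f <- dugwd(y, 2, 3, 5)
  mu_num <- sum(y * f); var_num <- sum(y^2 * f) - mu_num^2
  expect_equal(m$mean, 2 * 3 / 4, tolerance = 1e-12)
  expect_equal(m$mean, mu_num, tolerance = 1e-6)
  expect_equal(m$variance, var_num, tolerance = 1e-6)
  expect_equal(m$randomness + m$liability + m$proneness, m$variance)

  # rho = 2: mean exists, variance does not (heavy tail)
  m2 <- ugwd_moments(1, 1, 2)
  expect_equal(m2$mean, 1)
  expect_true(is.na(m2$variance))
  m3 <- ugwd_moments(1, 1, 0.5)
  expect_true(is.na(m3$mean))
})

test_that("component proportions reproduce the published partition", {
  mu <- 1.931035; k <- 1.567578; rho <- 6.852336
  m <- ugwd_moments(a = mu * (rho - 1) / k, k = k, rho = rho)
  props <- c(m$randomness, m$liability, m$proneness) / m$variance
  expect_equal(props, c(0.2930119, 0.1550451, 0.551943), tolerance = 5e-4)
})

test_that("the negative binomial limiting cases are approached", {
  mu <- 2
  # NegbinI: k = rho = c -> infinity with mu fixed => NB(size = mu, prob = 1/2)
  y <- 0:50
  target1 <- dnbinom(y, size = mu, prob = 0.5)
  d1 <- sapply(c(1e2, 1e4), function(cc)
    max(abs(dugwd(y, mu * (cc - 1) / cc, cc, cc) - target1)))
  expect_lt(d1[2], d1[1])
  expect_lt(d1[2], 1e-3)
  # NegbinII: rho -> infinity, mu/k bounded => NB(size = k, mean = mu)
  k <- 3
  target2 <- dnbinom(y, size = k, mu = mu)
  d2 <- sapply(c(1e2, 1e4), function(rr)
    max(abs(dugwd(y, mu * (rr - 1) / k, k, rr) - target2)))
  expect_lt(d2[2], d2[1])
  expect_lt(d2[2], 1e-3)
})

test_that("random generation is reproducible and matches moments", {
  expect_length(rugwd(0, 2, 3, 5), 0)
  expect_identical(rugwd(50, 2, 3, 5, seed = 4), rugwd(50, 2, 3, 5, seed = 4))
  expect_error(rugwd(10, -1, 3, 5), "positive")

  x <- rugwd(1e5, 2, 3, 5, seed = 42)
  m <- ugwd_moments(2, 3, 5)
  se <- sqrt(m$variance / 1e5)
  expect_lt(abs(mean(x) - m$mean), 3 * se)
})

test_that("two-stage and latent-hierarchy samplers agree in distribution", {
  n <- 1e5
  x1 <- rugwd(n, 2, 3, 5, seed = 7)
  x2 <- rugwd_latent(n, 2, 3, 5, seed = 8)$y
  brks <- c(0:9, Inf)
  t1 <- table(cut(x1, c(-Inf, brks)))
  t2 <- table(cut(x2, c(-Inf, brks)))
  keep <- (t1 + t2) > 10
  chi <- suppressWarnings(chisq.test(rbind(t1[keep], t2[keep])))
  expect_gt(chi$p.value, 1e-3)
})
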