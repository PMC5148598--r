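# Shared fixtures: small simulated datasets built fresh per test run.

sim_binary <- function(n = 800, beta = c(0.66, 1.16), k = 1.57, rho = 6.85,
                       prob = 0.3, seed = 11) {
  gw_simulate(n, beta = beta, k = k, rho = rho,
              covariates = list(xbin = list(type = "binary", prob = prob)),
              seed = seed)
}

# one informative binary covariate plus a pure-noise continuous one
sim_noise <- function(n = 2000, seed = 21) {
  gw_simulate(n, beta = c(0.6, 1.1, 0), k = 2, rho = 6,
              covariates = list(
                xbin = list(type = "binary", prob = 0.4),
                znoise = list(type = "uniform", min = -1, max = 1)),
              seed = seed)
}

fast_gw <- function(formula, data, ...) {
  suppressWarnings(suppressMessages(
    gw(formula, data = data, method = "L-BFGS-B", ...)))
}
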