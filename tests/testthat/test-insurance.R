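# Expected claims quadrature, premium rules, and portfolio balance.

ip_default <- insurance_params(p0 = 100, lambda_risk = 0.5,
                               rho_incentive = 2, gamma_premium = 0.5)

test_that("expected claims agree with analytic integrals", {
  unif <- health_risk_model(list(family = "uniform", min = 0, max = 1),
                            claim_cost = function(q, theta) theta)
  expect_equal(expected_claims(unif, 1), 0.5, tolerance = 1e-10)

  const <- health_risk_model(list(family = "uniform", min = 0, max = 1),
                             claim_cost = list(form = "constant", k = 7))
  expect_equal(expected_claims(const, 3), 7, tolerance = 1e-10)

  sq <- health_risk_model(list(family = "uniform", min = 0, max = 1),
                          claim_cost = function(q, theta) theta^2)
  expect_equal(expected_claims(sq, 1), 1 / 3, tolerance = 1e-10)

  # truncated normal mean: m + s * (phi(a') - phi(b')) / Z
  m <- 0.5; s <- 0.2; lo <- 0; hi <- 1
  a_ <- (lo - m) / s; b_ <- (hi - m) / s
  z <- pnorm(b_) - pnorm(a_)
  analytic <- m + s * (dnorm(a_) - dnorm(b_)) / z
  tn <- health_risk_model(list(family = "truncnorm", mean = m, sd = s,
                               lower = lo, upper = hi),
                          claim_cost = function(q, theta) theta)
  expect_equal(expected_claims(tn, 1), analytic, tolerance = 1e-9)
})

test_that("expected claims reject non-normalized densities and bad costs", {
  broken <- structure(list(density = function(theta) rep(2, length(theta)),
                           support = c(0, 1),
                           claim_cost = function(q, theta) theta),
                      class = "health_risk_model")
  expect_error(expected_claims(broken, 1), "not normalized")
  neg <- health_risk_model(list(family = "uniform", min = 0, max = 1),
                           claim_cost = function(q, theta) theta - 10)
  expect_error(expected_claims(neg, 1), "nonnegative")
})

test_that("adverse-selection premium is linear in expected claims", {
  expect_equal(adverse_selection_premium(200, insurance_params(
    p0 = 100, lambda_risk = 0.5)), 200)
  expect_equal(adverse_selection_premium(123, insurance_params(
    p0 = 55, lambda_risk = 0)), 55)
  e <- seq(0, 100, by = 10)
  p <- adverse_selection_premium(e, ip_default)
  expect_true(all(diff(p) > 0))
  expect_error(adverse_selection_premium(-1, ip_default), "expected")
})

test_that("premium step: fixed point, hand Euler, closed-form ODE match", {
  expect_equal(premium_step(80, 80, ip_default, 0.1), 80)
  expect_equal(premium_step(100, 200, ip_default, 1), 150)

  # dt = 1e-3 path over t in [0, 5] vs P(t) = E + (P0 - E) exp(-gamma t)
  dt <- 1e-3
  expected <- 60
  p <- 100
  times <- seq(0, 5, by = dt)
  path <- numeric(length(times))
  path[1] <- p
  for (k in 2:length(times)) {
    p <- premium_step(p, expected, ip_default, dt)
    path[k] <- p
  }
  exact <- oracle_premium_path(100, expected, ip_default$gamma_premium, times)
  expect_lt(max(abs(path - exact) / exact), 1e-3)
  # monotone approach to the fixed point
  expect_true(all(diff(path) < 0))
  expect_true(all(path > expected))

  clipped <- premium_step(1, -1000, ip_default, 1)
  expect_equal(as.numeric(clipped), 0)
  expect_true(isTRUE(attr(clipped, "clipped")))
})

test_that("risk-adjusted premium: hand value and zero clip flag", {
  ip <- insurance_params(p0 = 100, lambda_risk = 1, rho_incentive = 2)
  expect_equal(risk_adjusted_premium(50, 10, ip), 130)
  expect_equal(risk_adjusted_premium(0, 0,
    insurance_params(p0 = 100, lambda_risk = 0)), 100)
  clipped <- risk_adjusted_premium(0, 1000, ip)
  expect_equal(as.numeric(clipped), 0)
  expect_true(isTRUE(attr(clipped, "clipped")))
})

test_that("portfolio balance: residual, closed-form solve, idempotence", {
  ids <- c("a", "b")
  P <- setNames(c(10, 20), ids)
  E <- setNames(c(15, 15), ids)
  I <- setNames(c(1, 1), ids)
  expect_equal(portfolio_balance_residual(P, I, E), 0)
  expect_equal(portfolio_balance_residual(E, I, E), 0)

  P2 <- setNames(c(40, 10), ids)
  I2 <- setNames(c(2, 1), ids)
  sol <- solve_base_premium(P2, I2, E)
  expect_lte(abs(portfolio_balance_residual(sol$premiums, I2, E)), 1e-9)
  sol2 <- solve_base_premium(sol$premiums, I2, E)
  expect_equal(sol2$shift, 0, tolerance = 1e-12)
  expect_equal(sol2$premiums, sol$premiums)

  expect_error(portfolio_balance_residual(numeric(0), numeric(0),
                                          numeric(0)), "empty")
  expect_error(solve_base_premium(P, setNames(c(0, 0), ids), E), "exposure")
  expect_error(portfolio_balance_residual(P, I, setNames(c(1, 1), c("a", "x"))),
               "ids")
})
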