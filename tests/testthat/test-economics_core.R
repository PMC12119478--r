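# Consumer/provider primitives and market clearing.

cp_default <- consumer_params(a = 10, b = 2, c = 1, income = 1000,
                              lambda_consumer = 1)

test_that("quadratic utility: zero consumption, hand value, concavity", {
  cp <- consumer_params(a = 10, b = 2, c = 0)
  expect_equal(utility(0, 123, cp_default), 1 * 123)
  expect_equal(utility(2, 0, cp), 10 * 2 - 1 * 4)  # 16
  y <- 50
  expect_lte(utility(1, y, cp_default) + utility(3, y, cp_default),
             2 * utility(2, y, cp_default))
  expect_error(utility(-1, 0, cp_default), "q")
})

test_that("optimal consumption: closed form, boundary, monotonicity, FOC", {
  expect_equal(optimal_consumption(4, 0, cp_default), 3)
  expect_equal(optimal_consumption(10, 0, cp_default), 0)  # p = a/lambda
  ps <- seq(0, 12, by = 0.5)
  qs <- vapply(ps, optimal_consumption, numeric(1), p_dot = 0,
               cp = cp_default)
  expect_true(all(diff(qs) <= 1e-12))
  pd <- seq(-2, 2, by = 0.25)
  qd <- vapply(pd, function(x) optimal_consumption(4, x, cp_default),
               numeric(1))
  expect_true(all(diff(qd) <= 1e-12))
  # interior optima satisfy the first-order condition to machine precision
  set.seed(101)
  for (i in 1:25) {
    cp <- consumer_params(a = runif(1, 5, 20), b = runif(1, 0.5, 5),
                          lambda_consumer = runif(1, 0.5, 2))
    p <- runif(1, 0, 3)
    q <- optimal_consumption(p, 0, cp)
    if (q > 0) {
      expect_equal(consumption_foc_residual(q, p, 0, cp), 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("exponential demand and elasticity oracles", {
  dp <- demand_params(d0 = 100, epsilon = log(2))
  expect_equal(demand_response(1, dp), 50)
  expect_equal(demand_response(0, dp), 100)
  expect_equal(demand_response(7, demand_params(d0 = 42, epsilon = 0)), 42)
  expect_error(demand_response(-1, dp), "p")

  # exponential: elasticity is -epsilon * p
  dp2 <- demand_params(d0 = 100, epsilon = 0.3)
  for (p in c(0.5, 2, 5)) {
    expect_equal(price_elasticity(function(x) demand_response(x, dp2), p,
                                  h = 1e-5),
                 -0.3 * p, tolerance = 1e-6)
  }
  # constant demand is inelastic
  expect_equal(price_elasticity(function(x) 25, 3), 0)
  # linear demand q = A - B p
  A <- 80; B <- 4; p <- 7
  expect_equal(price_elasticity(function(x) A - B * x, p, h = 1e-5),
               -B * p / (A - B * p), tolerance = 1e-6)
  expect_error(price_elasticity(function(x) 0, 1), "zero")
})

test_that("provider profit, marginal cost, and the profit-maximum FOC", {
  pp <- provider_params(c0 = 1, c1 = 1, c2 = 0)
  expect_equal(provider_profit(5, 2, pp), 10 - 3)
  expect_equal(provider_profit(3, 0, provider_params(c0 = 0)), 0)
  pp2 <- provider_params(c0 = 2, c1 = 1, c2 = 0.75)
  expect_equal(marginal_cost(3, pp2), 1 + 2 * 0.75 * 3)
  # brute-force grid argmax satisfies |MC - p| <= grid resolution x slope
  p <- 6
  res <- 1e-3
  qs <- seq(0, 10, by = res)
  profits <- provider_profit(p, qs, pp2)
  q_hat <- qs[which.max(profits)]
  expect_lte(abs(marginal_cost(q_hat, pp2) - p), 2 * pp2$c2 * res + 1e-9)
  expect_equal(provider_supply(p, pp2), (p - 1) / (2 * 0.75))
  expect_error(provider_supply(1, provider_params(c2 = 0)), "convex")
})

test_that("market clearing by bisection: analytic, degenerate, residual", {
  p_eq <- market_clearing_price(function(p) 100 - p, function(p) p,
                                c(0, 100), tol = 1e-10)
  expect_equal(p_eq, 50, tolerance = 1e-8)
  # degenerate: demand identical to supply -> bracket midpoint
  expect_equal(market_clearing_price(function(p) 10, function(p) 10,
                                     c(2, 6)), 4)
  expect_error(market_clearing_price(function(p) 10, function(p) 1,
                                     c(0, 5)), "sign")
  # residual within tolerance on randomized monotone pairs
  set.seed(202)
  for (i in 1:20) {
    d0 <- runif(1, 50, 150); eps <- runif(1, 0.01, 0.2)
    s_slope <- runif(1, 0.5, 3)
    dem <- function(p) d0 * exp(-eps * p)
    sup <- function(p) s_slope * p
    tol <- 1e-7
    p_eq <- market_clearing_price(dem, sup, c(0, 200), tol = tol)
    expect_lte(abs(dem(p_eq) - sup(p_eq)), tol)
  }
})

test_that("moral hazard: endpoints, monotonicity, overconsumption", {
  cp <- cp_default
  q_star <- 3
  expect_equal(moral_hazard_demand(1, q_star, cp), q_star)
  expect_equal(moral_hazard_demand(0, q_star, cp), cp$a / cp$b)
  alphas <- seq(0, 1, by = 0.1)
  qs <- vapply(alphas, moral_hazard_demand, numeric(1), q_star = q_star,
               cp = cp)
  expect_true(all(diff(qs) <= 1e-12))    # nonincreasing in coverage
  expect_true(all(qs >= q_star - 1e-12)) # never below the uninsured optimum
  expect_error(moral_hazard_demand(1.2, q_star, cp), "coverage")
  expect_error(moral_hazard_demand(0.5, 6, cp), "satiation")
})

test_that("effective price subtracts the subsidy and flags negatives", {
  expect_equal(effective_price(10, 0), 10)
  expect_equal(effective_price(10, 3), 7)
  p_eff <- effective_price(2, 5)
  expect_equal(as.numeric(p_eff), -3)
  expect_true(isTRUE(attr(p_eff, "negative")))
  expect_null(attr(effective_price(10, 3), "negative"))
})
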