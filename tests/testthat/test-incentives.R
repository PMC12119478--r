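# Incentive function, elasticity, and constrained allocation.

test_that("incentive value: zero betas, hand sum, linearity in weights", {
  ip0 <- incentive_params(beta1 = 0, beta2 = 0, beta3 = 0)
  expect_equal(incentive_value(4, ip0), 0)

  ip <- incentive_params(beta1 = 1, beta2 = 1, beta3 = 1,
                         rebate_fn = list(form = "constant", k = 2),
                         benefit_fn = list(form = "constant", k = 3),
                         adherence_fn = list(form = "constant", k = 5))
  expect_equal(incentive_value(1, ip), 10)

  ip_b <- function(b1) incentive_params(
    beta1 = b1, beta2 = 2, beta3 = 0.5,
    rebate_fn = list(form = "linear", k = 2),
    benefit_fn = list(form = "sqrt", k = 1),
    adherence_fn = list(form = "constant", k = 4))
  q <- 9
  v1 <- incentive_value(q, ip_b(1))
  v2 <- incentive_value(q, ip_b(3))
  slope <- (v2 - v1) / 2
  expect_equal(slope, 2 * q)  # d(value)/d(beta1) = T(q)
  expect_error(incentive_value(-1, ip), "q")
})

test_that("incentive elasticity matches analytic derivatives", {
  expect_equal(incentive_elasticity(function(i) 5, 2), 0)
  k <- 0.3
  q0 <- 4
  for (i_val in c(0.5, 1, 2)) {
    expect_equal(incentive_elasticity(function(i) q0 * exp(k * i), i_val,
                                      h = 1e-5),
                 k * i_val, tolerance = 1e-6)
  }
  m <- 1.5
  i_val <- 2
  expect_equal(incentive_elasticity(function(i) q0 + m * i, i_val, h = 1e-5),
               m * i_val / (q0 + m * i_val), tolerance = 1e-6)
  expect_error(incentive_elasticity(function(i) 0, 1), "zero")
})

test_that("zero budget allocates nothing", {
  consumers <- list(list(params = consumer_params()),
                    list(params = consumer_params()))
  alloc <- allocate_incentives(consumers, incentive_params(b_max = 0))
  expect_equal(alloc$allocation, c(0, 0))
  expect_equal(attr(alloc, "total"), 0)
  expect_error(allocate_incentives(list(), incentive_params()), "empty")
})

test_that("two identical concave consumers split the budget evenly", {
  cp <- consumer_params(a = 10, b = 2, c = 1)
  mk <- function() list(params = cp, previous = 0,
                        marginal_utility = mu_consumption(cp, q0 = 1, k = 0.5))
  ip <- incentive_params(b_max = 3, delta_max = 100, lambda_min = 0,
                         grid = 0.25)
  alloc <- allocate_incentives(list(mk(), mk()), ip)
  expect_lte(abs(alloc$allocation[1] - alloc$allocation[2]), ip$grid)
  expect_equal(attr(alloc, "total"), 3, tolerance = 1e-9)
})

test_that("greedy matches exhaustive search within one grid step's utility", {
  set.seed(404)
  for (rep in 1:12) {
    n <- sample(2:3, 1)
    cps <- lapply(1:n, function(i) {
      consumer_params(a = runif(1, 6, 14), b = runif(1, 1, 4), c = 1)
    })
    q0s <- runif(n, 0.5, 2)
    ks <- runif(n, 0.2, 1)
    prev <- runif(n, 0, 0.5)
    ip <- incentive_params(b_max = runif(1, 1, 3), delta_max = 1.5,
                           lambda_min = runif(1, 0, 0.5), grid = 0.25)
    consumers <- lapply(1:n, function(i) {
      list(params = cps[[i]], previous = prev[i],
           marginal_utility = mu_consumption(cps[[i]], q0s[i], ks[i]))
    })
    mu_fns <- lapply(consumers, function(x) x$marginal_utility)
    alloc <- allocate_incentives(consumers, ip)
    best <- oracle_allocate(mu_fns, prev, ip)
    mu_max <- max(vapply(seq_len(n), function(i) {
      mu_fns[[i]](max(0, prev[i] - ip$delta_max))
    }, numeric(1)))
    expect_gte(attr(alloc, "utility_gain"),
               best - mu_max * ip$grid - 1e-9)
  }
})

test_that("allocations always respect budget, smoothness, and threshold", {
  set.seed(505)
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    cps <- lapply(1:n, function(i) {
      consumer_params(a = runif(1, 5, 15), b = runif(1, 0.5, 4),
                      c = runif(1, 0.1, 2))
    })
    prev <- runif(n, 0, 2)
    ip <- incentive_params(b_max = runif(1, 0, 5),
                           delta_max = runif(1, 0.5, 3),
                           lambda_min = runif(1, 0, 1),
                           grid = sample(c(0.1, 0.25, 0.5), 1))
    use_concave <- runif(n) < 0.5
    consumers <- lapply(1:n, function(i) {
      mu <- if (use_concave[i]) {
        mu_consumption(cps[[i]], runif(1, 0.5, 2), runif(1, 0.2, 1))
      } else {
        mu_income(cps[[i]])
      }
      list(params = cps[[i]], previous = prev[i], marginal_utility = mu)
    })
    if (sum(pmax(0, prev - ip$delta_max)) > ip$b_max + 1e-9) {
      expect_error(allocate_incentives(consumers, ip), "infeasible")
      next
    }
    alloc <- allocate_incentives(consumers, ip)
    expect_lte(attr(alloc, "total"), ip$b_max + 1e-9)
    expect_true(all(alloc$allocation >= -1e-12))
    expect_true(all(abs(alloc$allocation - prev) <= ip$delta_max + 1e-9))
    # every granted step passed the threshold: with nonincreasing marginal
    # utility, the mu at the last granted step start must have been >= lambda_min
    for (i in seq_len(n)) {
      granted <- alloc$granted[i]
      if (granted > 1e-12) {
        mu_i <- consumers[[i]]$marginal_utility
        last_start <- alloc$allocation[i] - ip$grid
        expect_gte(mu_i(last_start), ip$lambda_min - 1e-9)
      }
    }
  }
})

test_that("infeasible smoothness lower bounds raise an error", {
  consumers <- list(list(params = consumer_params(), previous = 10))
  ip <- incentive_params(b_max = 1, delta_max = 2)
  expect_error(allocate_incentives(consumers, ip), "infeasible")
})
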