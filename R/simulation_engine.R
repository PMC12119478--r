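# Coupled multi-agent time-stepping loop tying consumers, pricing,
# insurance, incentives and government policy into one trajectory.
#
# Per-tick update order (a deliberate design choice; demand must precede
# pricing and welfare must precede the policy step):
#   1. consumers choose q from the consumption rule at the current price
#      (moral-hazard-adjusted when coverage < 1),
#   2. aggregate demand (structural sum of optima, or reduced form) and
#      provider supply feed the bounded, dampened price step,
#   3. expected claims drive per-consumer premium steps (balance residual
#      recorded as a diagnostic),
#   4. incentives are allocated under budget/threshold/smoothness,
#   5. welfare is computed,
#   6. the subsidy/tax policy steps toward the welfare target.

consumer_quantity <- function(p, p_dot, cp) {
  q_star <- optimal_consumption(p, p_dot, cp)
  q_star <- min(q_star, cp$a / cp$b)  # keep marginal utility nonnegative
  if (cp$coverage < 1) {
    moral_hazard_demand(cp$coverage, q_star, cp)
  } else {
    q_star
  }
}

# Welfare of the no-intervention market-clearing equilibrium: the default
# welfare target when government$w_star is NULL.
baseline_welfare_target <- function(config) {
  dem <- function(p) {
    sum(vapply(config$consumers, function(cp) consumer_quantity(p, 0, cp),
               numeric(1)))
  }
  sup <- function(p) {
    sum(vapply(config$providers, function(pp) provider_supply(p, pp),
               numeric(1)))
  }
  hi <- max(vapply(config$consumers, function(cp) cp$a / cp$lambda_consumer,
                   numeric(1))) +
    max(vapply(config$providers, function(pp) abs(pp$c1), numeric(1))) + 10
  p_eq <- market_clearing_price(dem, sup, c(0, hi), tol = 1e-10)
  qs <- vapply(config$consumers, function(cp) consumer_quantity(p_eq, 0, cp),
               numeric(1))
  qj <- vapply(config$providers, function(pp) provider_supply(p_eq, pp),
               numeric(1))
  utils_ <- mapply(function(cp, q) utility(q, cp$income - p_eq * q, cp),
                   config$consumers, qs)
  costs <- mapply(function(pp, q) provider_cost(q, pp), config$providers, qj)
  social_welfare(utils_, costs, health_benefit(qs, config$government),
                 config$government)
}

#' Run the coupled market simulation
#'
#' Integrates the full market dynamics over `config$horizon` with step
#' `config$step`. Deterministic given the configuration (the dynamics
#' contain no noise), so two runs from the same config are bit-identical.
#'
#' @param config [scenario_config()].
#' @return An object of class `market_trajectory`: list with
#'   * `path`: `data.frame` with one row per recorded state (`t`,
#'     `price`, `mean_premium`, `subsidy`, `tax`, `total_consumption`,
#'     `total_incentive`, `welfare`),
#'   * `converged`: logical, per-step updates of price, premiums and
#'     policy all below `config$tol` at the final step,
#'   * `steps_to_convergence`: first tick index where that held (`NA` if
#'     never),
#'   * `residuals`: terminal drift residuals
#'     (`price`, `premium`, `policy`),
#'   * `balance_residual`: terminal insurer portfolio balance residual,
#'   * `audit_ok`: all per-tick component invariants held,
#'   * `w_star`: the resolved welfare target,
#'   * `config`: the input configuration.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dt <- config$step
  n_steps <- max(1L, as.integer(round(config$horizon / dt)))
  n_c <- length(config$consumers)

  gp <- config$government
  if (is.null(gp$w_star)) {
    gp$w_star <- baseline_welfare_target(config)
  }

  price <- config$pricing$p0
  price_prev <- price
  premiums <- rep(config$insurance$p0, n_c)
  policy <- list(subsidy_level = 0, tax_level = 0)
  prev_alloc <- rep(0, n_c)

  rows <- vector("list", n_steps + 1L)
  audit_ok <- TRUE
  steps_to_convergence <- NA_integer_
  last_updates <- Inf
  residuals <- c(price = NA_real_, premium = NA_real_, policy = NA_real_)
  balance_residual <- NA_real_

  for (k in 0:n_steps) {
    tick <- function(expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("tick %d (t = %.4f): %s", k, k * dt,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    p_dot <- if (k == 0) 0 else (price - price_prev) / dt

    # 1. consumption
    qs <- tick(vapply(config$consumers, function(cp) {
      consumer_quantity(price, p_dot, cp)
    }, numeric(1)))

    # 2. demand, supply
    demand <- if (config$demand_mode == "structural") {
      sum(qs)
    } else {
      tick(demand_response(price, config$demand))
    }
    supply <- tick(sum(vapply(config$providers, function(pp) {
      provider_supply(price, pp)
    }, numeric(1))))

    # 3. expected claims
    expected <- tick(vapply(qs, function(q) {
      expected_claims(config$risk, q, config$insurance$quadrature)
    }, numeric(1)))

    # 4. incentives
    alloc <- tick(allocate_incentives(
      lapply(seq_len(n_c), function(i) {
        list(params = config$consumers[[i]], previous = prev_alloc[i])
      }),
      config$incentive
    ))
    alloc_amounts <- alloc$allocation

    # 5. welfare
    utils_ <- tick(mapply(function(cp, q, inc) {
      utility(q, cp$income - price * q + inc, cp)
    }, config$consumers, qs, alloc_amounts))
    qj <- vapply(config$providers, function(pp) provider_supply(price, pp),
                 numeric(1))
    costs <- mapply(function(pp, q) provider_cost(q, pp),
                    config$providers, qj)
    welfare <- social_welfare(utils_, costs, health_benefit(qs, gp), gp)

    # audit component invariants at the recorded state
    audit_ok <- audit_ok && price >= 0 && all(premiums >= 0) &&
      attr(alloc, "total") <= config$incentive$b_max + 1e-9 &&
      all(abs(alloc_amounts - prev_alloc) <= config$incentive$delta_max + 1e-9)

    rows[[k + 1L]] <- data.frame(
      t = k * dt, price = price, mean_premium = mean(premiums),
      subsidy = policy$subsidy_level, tax = policy$tax_level,
      total_consumption = sum(qs), total_incentive = attr(alloc, "total"),
      welfare = welfare
    )

    if (k == n_steps) {
      residuals <- c(
        price = abs(config$pricing$kappa * (demand - supply) -
                      config$pricing$eta_stabilize *
                        (price - config$pricing$p_star)),
        premium = max(abs(config$insurance$gamma_premium *
                            (expected - premiums))),
        policy = max(abs(gp$beta_s * (welfare - gp$w_star)),
                     abs(gp$delta_t * (welfare - gp$w_star)))
      )
      ids <- as.character(seq_len(n_c))
      balance_residual <- portfolio_balance_residual(
        setNames(premiums, ids), setNames(rep(1, n_c), ids),
        setNames(expected, ids))
      break
    }

    # 6. dynamics
    price_next <- tick(price_step(price, demand, supply, config$pricing, dt))
    premiums_next <- tick(premium_step(premiums, expected, config$insurance,
                                       dt))
    policy_next <- tick(policy_step(policy, welfare, gp, dt))

    last_updates <- max(abs(as.numeric(price_next) - price),
                        max(abs(as.numeric(premiums_next) - premiums)),
                        abs(policy_next$subsidy_level - policy$subsidy_level),
                        abs(policy_next$tax_level - policy$tax_level))
    if (is.na(steps_to_convergence) && last_updates < config$tol) {
      steps_to_convergence <- k + 1L
    }

    price_prev <- price
    price <- as.numeric(price_next)
    premiums <- as.numeric(premiums_next)
    policy <- policy_next
    prev_alloc <- alloc_amounts
  }

  structure(list(
    path = do.call(rbind, rows),
    converged = is.finite(last_updates) && last_updates < config$tol,
    steps_to_convergence = steps_to_convergence,
    residuals = residuals,
    balance_residual = balance_residual,
    audit_ok = audit_ok,
    w_star = gp$w_star,
    config = config
  ), class = "market_trajectory")
}

#' Summarize a trajectory
#'
#' @param traj A `market_trajectory` from [run_simulation()].
#' @return List with `final_price`, `final_mean_premium`, `final_subsidy`,
#'   `final_tax`, `final_welfare`, `converged`, `steps_to_convergence`
#'   and `n_steps`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "market_trajectory"))
  if (nrow(traj$path) == 0L) stop("empty trajectory", call. = FALSE)
  last <- traj$path[nrow(traj$path), ]
  list(final_price = last$price,
       final_mean_premium = last$mean_premium,
       final_subsidy = last$subsidy,
       final_tax = last$tax,
       final_welfare = last$welfare,
       converged = traj$converged,
       steps_to_convergence = traj$steps_to_convergence,
       n_steps = nrow(traj$path) - 1L)
}

#' Export a trajectory as CSV
#'
#' @param traj A `market_trajectory`.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj$path, path, row.names = FALSE)
  invisible(path)
}

#' The shipped stable baseline scenario
#'
#' A documented configuration whose coupled dynamics reach a joint fixed
#' point: three identical consumers, two identical providers, undampened
#' price dynamics (the price converges to the market-clearing level),
#' premium adjustment toward expected claims, welfare target at the
#' no-intervention equilibrium, and no incentive program (so terminal
#' welfare equals the target and the policy instruments settle).
#'
#' @param seed Integer seed stored in the config.
#' @return A [scenario_config()].
#' @export
baseline_scenario <- function(seed = 0) {
  scenario_config(
    horizon = 60, step = 0.05, discount_rate = 0.03,
    consumers = replicate(3, consumer_params(a = 10, b = 2, c = 1,
                                             income = 1000,
                                             lambda_consumer = 1,
                                             coverage = 1),
                          simplify = FALSE),
    providers = replicate(2, provider_params(c0 = 0, c1 = 1, c2 = 0.5),
                          simplify = FALSE),
    demand = demand_params(d0 = 100, epsilon = 0.02),
    pricing = pricing_params(kappa = 0.2, eta_stabilize = 0, p_star = 5,
                             dp_max = 5, p0 = 5),
    insurance = insurance_params(p0 = 100, lambda_risk = 0.5,
                                 gamma_premium = 0.5),
    government = government_params(beta_s = 0.05, delta_t = 0.05,
                                   w_star = NULL, lambda_health = 1),
    incentive = incentive_params(b_max = 0),
    rl = rl_params(),
    risk = health_risk_model(
      distribution = list(family = "uniform", min = 0, max = 1),
      claim_cost = list(form = "scaled", scale = 50)),
    demand_mode = "structural",
    tol = 1e-6, seed = seed
  )
}
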