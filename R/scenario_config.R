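# Scenario configuration: parameter constructors, validation, (de)serialization,
# and synthetic scenario/cohort generation. Every model symbol lives in exactly
# one parameter block here. Several greek letters are reused across the model's
# equations with different meanings; fields are therefore named by role:
# lambda_risk (premium risk loading), lambda_health (welfare weight on health
# benefits), lambda_consumer (consumer budget multiplier), lambda_min
# (incentive effectiveness threshold), rho discount_rate vs rho_incentive,
# gamma_premium vs gamma_rl, eta_stabilize vs eta_lr, tax_level vs horizon,
# subsidy level vs supply quantity, coverage vs td_step.

#' Consumer preference and budget parameters
#'
#' Parameters of the quadratic consumer utility
#' \eqn{U(q, y) = a q - (b/2) q^2 + c y}, where `y` is net income, plus the
#' budget multiplier entering the first-order condition, income, and
#' insurance coverage.
#'
#' @param a Linear utility coefficient, `> 0`.
#' @param b Curvature (concavity) coefficient, `> 0`.
#' @param c Income coefficient (marginal utility of net income).
#' @param income Gross income \eqn{Y_i} (currency).
#' @param lambda_consumer Budget multiplier \eqn{\lambda_i > 0} scaling the
#'   effective price in the consumption rule.
#' @param coverage Insurance coverage share \eqn{\alpha \in [0, 1]}; `1`
#'   means full out-of-pocket exposure (no moral hazard).
#' @return An object of class `consumer_params`.
#' @export
consumer_params <- function(a = 10, b = 2, c = 1, income = 1000,
                            lambda_consumer = 1, coverage = 1) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  check_number(c, "c")
  check_number(income, "income")
  check_number(lambda_consumer, "lambda_consumer", lower = 0, strict_lower = TRUE)
  check_number(coverage, "coverage", lower = 0, upper = 1)
  structure(list(a = a, b = b, c = c, income = income,
                 lambda_consumer = lambda_consumer, coverage = coverage),
            class = "consumer_params")
}

#' Provider cost parameters
#'
#' Quadratic (convex) provider cost \eqn{C(q) = c_0 + c_1 q + c_2 q^2}, the
#' minimal convex family with a closed-form marginal cost
#' \eqn{MC(q) = c_1 + 2 c_2 q}.
#'
#' @param c0,c1,c2 Cost coefficients; `c2 >= 0` enforces convexity.
#' @return An object of class `provider_params`.
#' @export
provider_params <- function(c0 = 0, c1 = 1, c2 = 0.5) {
  check_number(c0, "c0")
  check_number(c1, "c1")
  check_number(c2, "c2", lower = 0)
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "provider_params")
}

#' Reduced-form demand parameters
#'
#' Exponential demand \eqn{D(p) = d_0 e^{-\epsilon p}}.
#'
#' @param d0 Baseline demand at zero price, `> 0`.
#' @param epsilon Price-sensitivity coefficient, `>= 0`.
#' @return An object of class `demand_params`.
#' @export
demand_params <- function(d0 = 100, epsilon = 0.02) {
  check_number(d0, "d0", lower = 0, strict_lower = TRUE)
  check_number(epsilon, "epsilon", lower = 0)
  structure(list(d0 = d0, epsilon = epsilon), class = "demand_params")
}

#' Dynamic pricing parameters
#'
#' Governs the bounded, dampened price evolution
#' \eqn{dp/dt = \kappa (D - S) - \eta (p - p^*)} with per-step changes
#' clipped to `dp_max`.
#'
#' @param kappa Price sensitivity to excess demand, `>= 0` (0 freezes the
#'   price).
#' @param eta_stabilize Dampening coefficient pulling the price towards
#'   `p_star`, `>= 0`.
#' @param p_star Long-run anchor price used by the dampening term.
#' @param dp_max Maximum permissible price change per step, `> 0`.
#' @param p0 Initial price (defaults to `p_star`).
#' @param tol Absolute per-step update magnitude below which a price path
#'   is flagged converged.
#' @return An object of class `pricing_params`.
#' @export
pricing_params <- function(kappa = 0.2, eta_stabilize = 0, p_star = 5,
                           dp_max = 5, p0 = NULL, tol = 1e-8) {
  check_number(kappa, "kappa", lower = 0)
  check_number(eta_stabilize, "eta_stabilize", lower = 0)
  check_number(p_star, "p_star")
  check_number(dp_max, "dp_max", lower = 0, strict_lower = TRUE)
  p0 <- p0 %||% p_star
  check_number(p0, "p0", lower = 0)
  check_number(tol, "tol", lower = 0, strict_lower = TRUE)
  structure(list(kappa = kappa, eta_stabilize = eta_stabilize,
                 p_star = p_star, dp_max = dp_max, p0 = p0, tol = tol),
            class = "pricing_params")
}

#' Insurance pricing parameters
#'
#' @param p0 Base premium \eqn{P_0} (currency).
#' @param lambda_risk Risk-adjustment loading on expected claims, `>= 0`.
#' @param rho_incentive Premium discount per unit of incentive, `>= 0`.
#' @param gamma_premium Premium adjustment speed, `>= 0` (0 freezes
#'   premiums).
#' @param quadrature List with `nodes` (Gauss-Legendre node count, `>= 2`)
#'   and `tol` (normalization tolerance for the risk density).
#' @return An object of class `insurance_params`.
#' @export
insurance_params <- function(p0 = 100, lambda_risk = 0.5, rho_incentive = 0,
                             gamma_premium = 0.5,
                             quadrature = list(nodes = 64, tol = 1e-6)) {
  check_number(p0, "p0", lower = 0)
  check_number(lambda_risk, "lambda_risk", lower = 0)
  check_number(rho_incentive, "rho_incentive", lower = 0)
  check_number(gamma_premium, "gamma_premium", lower = 0)
  quadrature$nodes <- quadrature$nodes %||% 64
  quadrature$tol <- quadrature$tol %||% 1e-6
  check_number(quadrature$nodes, "quadrature$nodes", lower = 2)
  check_number(quadrature$tol, "quadrature$tol", lower = 0, strict_lower = TRUE)
  structure(list(p0 = p0, lambda_risk = lambda_risk,
                 rho_incentive = rho_incentive,
                 gamma_premium = gamma_premium,
                 quadrature = quadrature),
            class = "insurance_params")
}

#' Government policy parameters
#'
#' @param beta_s Subsidy adjustment speed, `>= 0`.
#' @param delta_t Tax adjustment speed, `>= 0`.
#' @param w_star Target welfare level; `NULL` (default) means: compute the
#'   welfare of the no-intervention market-clearing equilibrium at setup
#'   and use that.
#' @param lambda_health Welfare weight on health benefits, `>= 0`.
#' @param health_benefit List with `h1`, `h2` of the concave benefit form
#'   \eqn{H(q) = \max(0, h_1 q - h_2 q^2)}.
#' @return An object of class `government_params`.
#' @export
government_params <- function(beta_s = 0.05, delta_t = 0.05, w_star = NULL,
                              lambda_health = 1,
                              health_benefit = list(h1 = 5, h2 = 0.1)) {
  check_number(beta_s, "beta_s", lower = 0)
  check_number(delta_t, "delta_t", lower = 0)
  if (!is.null(w_star)) check_number(w_star, "w_star")
  check_number(lambda_health, "lambda_health", lower = 0)
  check_number(health_benefit$h1 %||% NA_real_, "health_benefit$h1", lower = 0)
  check_number(health_benefit$h2 %||% NA_real_, "health_benefit$h2", lower = 0)
  structure(list(beta_s = beta_s, delta_t = delta_t, w_star = w_star,
                 lambda_health = lambda_health,
                 health_benefit = health_benefit),
            class = "government_params")
}

#' Incentive allocation parameters
#'
#' The incentive paid for consumption level `q` is
#' \eqn{I(q) = \beta_1 T(q) + \beta_2 R(q) + \beta_3 M(q)} where `T`, `R`,
#' `M` are nonnegative named functional forms (tax rebate, risk-adjusted
#' insurance benefit, adherence reward). Allocation is constrained by a
#' total budget `b_max`, a per-consumer smoothness bound `delta_max` on
#' the change from the previous allocation, and a marginal
#' cost-effectiveness threshold `lambda_min`.
#'
#' @param beta1,beta2,beta3 Nonnegative component weights.
#' @param rebate_fn,benefit_fn,adherence_fn Functional forms, each a list
#'   `list(form, k)` with `form` one of `"linear"` (`k*q`), `"constant"`
#'   (`k`) or `"sqrt"` (`k*sqrt(q)`).
#' @param b_max Total incentive budget, `>= 0`.
#' @param delta_max Per-consumer per-call change bound, `>= 0`.
#' @param lambda_min Minimum marginal utility per currency unit required
#'   for a grant.
#' @param grid Allocation grid step for the greedy solver, `> 0`.
#' @return An object of class `incentive_params`.
#' @export
incentive_params <- function(beta1 = 1, beta2 = 1, beta3 = 1,
                             rebate_fn = list(form = "linear", k = 1),
                             benefit_fn = list(form = "constant", k = 0),
                             adherence_fn = list(form = "constant", k = 0),
                             b_max = 10, delta_max = 5, lambda_min = 0,
                             grid = 0.25) {
  for (nm in c("beta1", "beta2", "beta3")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(b_max, "b_max", lower = 0)
  check_number(delta_max, "delta_max", lower = 0)
  check_number(lambda_min, "lambda_min")
  check_number(grid, "grid", lower = 0, strict_lower = TRUE)
  for (fn in list(rebate_fn, benefit_fn, adherence_fn)) {
    if (!fn$form %in% c("linear", "constant", "sqrt")) {
      stop("unknown incentive component form: ", fn$form, call. = FALSE)
    }
  }
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 rebate_fn = rebate_fn, benefit_fn = benefit_fn,
                 adherence_fn = adherence_fn, b_max = b_max,
                 delta_max = delta_max, lambda_min = lambda_min, grid = grid),
            class = "incentive_params")
}

#' Reinforcement-learning parameters
#'
#' Settings of the subsidy/tax lattice decision process and its
#' policy-gradient optimizer.
#'
#' @param s_grid,t_grid Numeric lattices for subsidy and tax levels.
#' @param gamma_rl Discount factor in `(0, 1)`.
#' @param eta_lr Gradient-ascent learning rate, `> 0`.
#' @param td_step TD(0) step size in `(0, 1]`.
#' @param horizon Episode length (steps), `>= 1`.
#' @param n_episodes Episodes per gradient estimate, `>= 1`.
#' @param n_iterations Gradient-ascent iterations, `>= 0`.
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(s_grid = seq(0, 2, by = 1), t_grid = seq(0, 2, by = 1),
                      gamma_rl = 0.9, eta_lr = 0.05, td_step = 0.1,
                      horizon = 10, n_episodes = 100, n_iterations = 50) {
  if (!is.numeric(s_grid) || length(s_grid) < 1L) stop("'s_grid' must be a nonempty numeric vector", call. = FALSE)
  if (!is.numeric(t_grid) || length(t_grid) < 1L) stop("'t_grid' must be a nonempty numeric vector", call. = FALSE)
  check_number(gamma_rl, "gamma_rl", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(eta_lr, "eta_lr", lower = 0, strict_lower = TRUE)
  check_number(td_step, "td_step", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(horizon, "horizon", lower = 1)
  check_number(n_episodes, "n_episodes", lower = 1)
  check_number(n_iterations, "n_iterations", lower = 0)
  structure(list(s_grid = as.numeric(s_grid), t_grid = as.numeric(t_grid),
                 gamma_rl = gamma_rl, eta_lr = eta_lr, td_step = td_step,
                 horizon = as.integer(horizon),
                 n_episodes = as.integer(n_episodes),
                 n_iterations = as.integer(n_iterations)),
            class = "rl_params")
}

#' Health-risk model: risk density and claim cost
#'
#' Describes the population distribution `f(theta)` of the latent health
#' state on an interval, and the insurer's claim cost `C(q, theta) >= 0`.
#'
#' @param distribution A list naming the density family: either
#'   `list(family = "uniform", min, max)` or
#'   `list(family = "truncnorm", mean, sd, lower, upper)`.
#' @param claim_cost Either a function `function(q, theta)` or a named
#'   form `list(form, ...)` with `form` one of `"scaled"`
#'   (`scale * theta * q`), `"constant"` (`k`), or `"power"`
#'   (`k * theta^m * q^n`).
#' @return An object of class `health_risk_model` with elements
#'   `density(theta)`, `support = c(lo, hi)`, `claim_cost(q, theta)`, and
#'   the original specs for serialization.
#' @export
health_risk_model <- function(distribution = list(family = "uniform",
                                                  min = 0, max = 1),
                              claim_cost = list(form = "scaled", scale = 50)) {
  fam <- distribution$family %||% stop("distribution needs a 'family'")
  if (fam == "uniform") {
    lo <- distribution$min %||% 0
    hi <- distribution$max %||% 1
    if (hi <= lo) stop("'distribution': max must exceed min", call. = FALSE)
    density <- function(theta) ifelse(theta >= lo & theta <= hi,
                                      1 / (hi - lo), 0)
    support <- c(lo, hi)
  } else if (fam == "truncnorm") {
    m <- distribution$mean %||% 0
    s <- distribution$sd %||% 1
    lo <- distribution$lower %||% (m - 5 * s)
    hi <- distribution$upper %||% (m + 5 * s)
    if (s <= 0) stop("'distribution': sd must be > 0", call. = FALSE)
    if (hi <= lo) stop("'distribution': upper must exceed lower", call. = FALSE)
    z <- pnorm(hi, m, s) - pnorm(lo, m, s)
    density <- function(theta) ifelse(theta >= lo & theta <= hi,
                                      stats::dnorm(theta, m, s) / z, 0)
    support <- c(lo, hi)
  } else {
    stop("unknown risk distribution family: ", fam, call. = FALSE)
  }
  cost_fn <- if (is.function(claim_cost)) {
    claim_cost
  } else {
    switch(claim_cost$form,
      scaled = {
        scale <- claim_cost$scale %||% 1
        function(q, theta) scale * theta * q
      },
      constant = {
        k <- claim_cost$k %||% 0
        function(q, theta) rep_len(k, length(theta))
      },
      power = {
        k <- claim_cost$k %||% 1
        m_ <- claim_cost$m %||% 1
        n_ <- claim_cost$n %||% 1
        function(q, theta) k * theta^m_ * q^n_
      },
      stop("unknown claim cost form: ", claim_cost$form, call. = FALSE)
    )
  }
  structure(list(density = density, support = support, claim_cost = cost_fn,
                 distribution = distribution,
                 claim_cost_spec = if (is.function(claim_cost)) NULL else claim_cost),
            class = "health_risk_model")
}

#' Full scenario configuration
#'
#' Single source of truth for a simulation run: time discretization,
#' discounting, every agent's parameters, and the RNG seed.
#'
#' @param horizon Simulated time span, `>= step`.
#' @param step Time step `dt > 0`.
#' @param discount_rate Discount rate `>= 0` per time unit.
#' @param consumers List of [consumer_params()].
#' @param providers List of [provider_params()].
#' @param demand [demand_params()].
#' @param pricing [pricing_params()].
#' @param insurance [insurance_params()].
#' @param government [government_params()].
#' @param incentive [incentive_params()].
#' @param rl [rl_params()].
#' @param risk [health_risk_model()] used for expected claims.
#' @param demand_mode `"structural"` (sum of consumer optima) or
#'   `"reduced"` (exponential reduced form).
#' @param tol Convergence tolerance on per-step state updates.
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(horizon = 20, step = 0.05, discount_rate = 0.03,
                            consumers = list(consumer_params()),
                            providers = list(provider_params()),
                            demand = demand_params(),
                            pricing = pricing_params(),
                            insurance = insurance_params(),
                            government = government_params(),
                            incentive = incentive_params(),
                            rl = rl_params(),
                            risk = health_risk_model(),
                            demand_mode = c("structural", "reduced"),
                            tol = 1e-6, seed = 0) {
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  check_number(horizon, "horizon", lower = step)
  check_number(discount_rate, "discount_rate", lower = 0)
  check_number(tol, "tol", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  demand_mode <- match.arg(demand_mode)
  stopifnot(length(consumers) >= 1L, length(providers) >= 1L)
  for (cp in consumers) {
    if (!inherits(cp, "consumer_params")) stop("'consumers' must contain consumer_params objects", call. = FALSE)
  }
  for (pp in providers) {
    if (!inherits(pp, "provider_params")) stop("'providers' must contain provider_params objects", call. = FALSE)
  }
  for (chk in list(list(demand, "demand_params", "demand"),
                   list(pricing, "pricing_params", "pricing"),
                   list(insurance, "insurance_params", "insurance"),
                   list(government, "government_params", "government"),
                   list(incentive, "incentive_params", "incentive"),
                   list(rl, "rl_params", "rl"),
                   list(risk, "health_risk_model", "risk"))) {
    if (!inherits(chk[[1]], chk[[2]])) {
      stop(sprintf("'%s' must be a %s object", chk[[3]], chk[[2]]), call. = FALSE)
    }
  }
  structure(list(horizon = horizon, step = step,
                 discount_rate = discount_rate, consumers = consumers,
                 providers = providers, demand = demand, pricing = pricing,
                 insurance = insurance, government = government,
                 incentive = incentive, rl = rl, risk = risk,
                 demand_mode = demand_mode, tol = tol,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# ---------------------------------------------------------------------------
# (De)serialization. Configs are stored as plain nested lists in YAML or
# JSON; load_config() rebuilds through the validating constructors so a
# round trip is the identity and every invariant is re-checked on load.

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  out <- list(
    horizon = config$horizon, step = config$step,
    discount_rate = config$discount_rate,
    consumers = lapply(config$consumers, strip),
    providers = lapply(config$providers, strip),
    demand = strip(config$demand), pricing = strip(config$pricing),
    insurance = strip(config$insurance),
    government = strip(config$government),
    incentive = strip(config$incentive), rl = strip(config$rl),
    risk = list(distribution = config$risk$distribution,
                claim_cost = config$risk$claim_cost_spec %||%
                  stop("configs require a named (serializable) claim cost form")),
    demand_mode = config$demand_mode, tol = config$tol, seed = config$seed
  )
  out
}

config_from_list <- function(x) {
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    do.call(ctor, args)
  }
  scenario_config(
    horizon = x$horizon %||% 20,
    step = x$step %||% 0.05,
    discount_rate = x$discount_rate %||% 0.03,
    consumers = if (is.null(x$consumers)) list(consumer_params())
                else lapply(x$consumers, function(a) build(consumer_params, a)),
    providers = if (is.null(x$providers)) list(provider_params())
                else lapply(x$providers, function(a) build(provider_params, a)),
    demand = build(demand_params, x$demand),
    pricing = build(pricing_params, x$pricing),
    insurance = build(insurance_params, x$insurance),
    government = build(government_params, x$government),
    incentive = build(incentive_params, x$incentive),
    rl = if (is.null(x$rl)) rl_params() else do.call(rl_params, x$rl),
    risk = if (is.null(x$risk)) health_risk_model()
           else health_risk_model(x$risk$distribution, x$risk$claim_cost),
    demand_mode = x$demand_mode %||% "structural",
    tol = x$tol %||% 1e-6,
    seed = x$seed %||% 0L
  )
}

#' Load a scenario configuration from YAML or JSON
#'
#' Missing sections are filled with documented defaults; every parameter
#' is re-validated through the constructors, so a malformed file fails
#' with a message naming the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. A file with only
#'   `seed` and `horizon` is valid.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config file did not parse to a mapping: ", path, call. = FALSE)
  config_from_list(raw)
}

#' Save a scenario configuration to YAML or JSON
#'
#' @param config A [scenario_config()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic cohorts.

# Inverse-CDF draw from a normal truncated to [lo, hi]; deterministic in
# the supplied uniforms so cohort generation is reproducible by seed.
rtruncnorm_inv <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Default per-group cohort distributions
#'
#' Truncated-normal cost/misdiagnosis/premium families plus a Bernoulli
#' access probability, with moments matched to the built-in reference
#' cohort's group aggregates.
#'
#' @return A named list with `control` and `ai` sublists, each holding
#'   `cost = c(mean, sd)`, `misdiagnosis = c(mean, sd)`,
#'   `premium = c(mean, sd)` and `access_prob`.
#' @export
cohort_distributions <- function() {
  list(
    control = list(cost = c(mean = 44750, sd = 4800),
                   misdiagnosis = c(mean = 18.5, sd = 1.9),
                   premium = c(mean = 1140, sd = 50),
                   access_prob = 0.25),
    ai = list(cost = c(mean = 34333.33, sd = 2500),
              misdiagnosis = c(mean = 7.55, sd = 1.0),
              premium = c(mean = 985, sd = 48),
              access_prob = 1.0)
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_control + n_ai` patient records. Within each group, cost and
#' premium are normal truncated at 0, misdiagnosis is normal truncated to
#' \[0, 100\], and access is Bernoulli. Reproducible under `seed` via a
#' dedicated RNG substream.
#'
#' @param n_control,n_ai Nonnegative record counts per group.
#' @param group_distributions Per-group parameters, see
#'   [cohort_distributions()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `patient_id`, `group`, `cost`,
#'   `misdiagnosis_pct`, `premium_per_month`, `access`.
#' @export
generate_cohort <- function(n_control, n_ai,
                            group_distributions = cohort_distributions(),
                            seed = 0) {
  check_number(n_control, "n_control", lower = 0)
  check_number(n_ai, "n_ai", lower = 0)
  n_control <- as.integer(n_control)
  n_ai <- as.integer(n_ai)
  draw_group <- function(n, group, gd, ids) {
    if (is.null(gd$cost) || is.null(gd$misdiagnosis) || is.null(gd$premium) ||
        is.null(gd$access_prob)) {
      stop("group_distributions$", group,
           " must define cost, misdiagnosis, premium, access_prob",
           call. = FALSE)
    }
    if (gd$cost[["sd"]] <= 0 || gd$misdiagnosis[["sd"]] <= 0 ||
        gd$premium[["sd"]] <= 0) {
      stop("distribution sd parameters must be > 0", call. = FALSE)
    }
    if (gd$access_prob < 0 || gd$access_prob > 1) {
      stop("access_prob must lie in [0, 1]", call. = FALSE)
    }
    if (n == 0L) {
      return(empty_cohort())
    }
    data.frame(
      patient_id = ids,
      group = rep(group, n),
      cost = rtruncnorm_inv(runif(n), gd$cost[["mean"]], gd$cost[["sd"]],
                            lo = 0),
      misdiagnosis_pct = rtruncnorm_inv(runif(n), gd$misdiagnosis[["mean"]],
                                        gd$misdiagnosis[["sd"]], 0, 100),
      premium_per_month = rtruncnorm_inv(runif(n), gd$premium[["mean"]],
                                         gd$premium[["sd"]], lo = 0),
      access = ifelse(runif(n) < gd$access_prob, "yes", "no"),
      stringsAsFactors = FALSE
    )
  }
  with_seed(substream_seed(seed, "cohort"), {
    total <- n_control + n_ai
    ids <- sprintf("S%04d", seq_len(max(total, 1L)))
    ctrl <- draw_group(n_control, "control", group_distributions$control,
                       ids[seq_len(n_control)])
    ai <- draw_group(n_ai, "ai", group_distributions$ai,
                     ids[n_control + seq_len(n_ai)])
    out <- rbind(ctrl, ai)
    rownames(out) <- NULL
    validate_cohort(out)
  })
}

empty_cohort <- function() {
  data.frame(patient_id = character(), group = character(), cost = numeric(),
             misdiagnosis_pct = numeric(), premium_per_month = numeric(),
             access = character(), stringsAsFactors = FALSE)
}

#' Built-in reference cohort
#'
#' The package's worked example: ten patients, four managed without AI
#' support (`control`) and six with the AI-driven recommendation system
#' (`ai`). Economic cells not observed for a patient are missing (`NA`),
#' never zero.
#'
#' @return A cohort `data.frame` (see [generate_cohort()] for columns).
#' @export
builtin_cohort <- function() {
  validate_cohort(data.frame(
    patient_id = sprintf("P%03d", 1:10),
    group = c("control", "ai", "ai", "control", "ai", "ai", "control",
              "ai", "ai", "control"),
    cost = c(42000, 35200, 30800, 51200, 36700, 32100, 40100, 37000,
             34200, 45700),
    misdiagnosis_pct = c(18.0, 7.0, 6.5, 19.3, 8.5, 6.8, 16.2, 9.0, 7.5, 20.5),
    premium_per_month = c(1100, 980, 920, 1200, 1020, 960, 1090, 1050,
                          980, 1170),
    access = c("yes", "yes", "yes", "no", "yes", "yes", "no", "yes",
               "yes", "no"),
    stringsAsFactors = FALSE
  ))
}

validate_cohort <- function(df, source = "cohort") {
  needed <- c("patient_id", "group", "cost", "misdiagnosis_pct",
              "premium_per_month", "access")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(source, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_group <- which(!df$group %in% c("control", "ai"))
  if (length(bad_group)) {
    stop(sprintf("%s row %d, column 'group': invalid value '%s'",
                 source, bad_group[1], df$group[bad_group[1]]), call. = FALSE)
  }
  bad_access <- which(!is.na(df$access) & !df$access %in% c("yes", "no"))
  if (length(bad_access)) {
    stop(sprintf("%s row %d, column 'access': invalid value '%s'",
                 source, bad_access[1], df$access[bad_access[1]]),
         call. = FALSE)
  }
  bad_cost <- which(!is.na(df$cost) & df$cost < 0)
  if (length(bad_cost)) {
    stop(sprintf("%s row %d, column 'cost': negative value", source,
                 bad_cost[1]), call. = FALSE)
  }
  bad_mis <- which(!is.na(df$misdiagnosis_pct) &
                     (df$misdiagnosis_pct < 0 | df$misdiagnosis_pct > 100))
  if (length(bad_mis)) {
    stop(sprintf("%s row %d, column 'misdiagnosis_pct': outside [0, 100]",
                 source, bad_mis[1]), call. = FALSE)
  }
  df[needed]
}

#' Read a cohort CSV
#'
#' Expects the header `patient_id,group,cost,misdiagnosis_pct,
#' premium_per_month,access`; empty fields are missing values.
#'
#' @param path CSV path.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", group = "character",
                                access = "character"),
                 na.strings = c("", "NA"))
  for (col in c("cost", "misdiagnosis_pct", "premium_per_month")) {
    if (col %in% names(df) && !is.numeric(df[[col]])) {
      suppressWarnings(conv <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & is.na(conv))
      if (length(bad)) {
        stop(sprintf("%s row %d, column '%s': not numeric", path, bad[1], col),
             call. = FALSE)
      }
      df[[col]] <- conv
    }
  }
  validate_cohort(df, source = path)
}

#' Write a cohort CSV
#'
#' @param records Cohort `data.frame`.
#' @param path Destination path. Missing values become empty fields.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  records <- validate_cohort(records)
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
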