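# Government: welfare accounting, subsidy/tax dynamics, first-order
# condition diagnostics, discounted policy objective.

#' Health benefit of consumption
#'
#' Concave benefit \eqn{H(q) = \max(0, h_1 q - h_2 q^2)}; the minimal
#' sensible concave family, truncated at zero.
#'
#' @param q Quantity.
#' @param gp [government_params()] (uses `health_benefit`).
#' @return Health benefit.
#' @export
health_benefit <- function(q, gp) {
  hb <- gp$health_benefit
  pmax(0, hb$h1 * q - hb$h2 * q^2)
}

#' Social welfare
#'
#' \eqn{W = \sum_i U_i - \sum_j C_j + \lambda_{health} \sum_i H_i}:
#' aggregate consumer utility, minus provider costs, plus weighted health
#' benefits.
#'
#' @param consumer_utilities,provider_costs,health_benefits Numeric
#'   vectors (possibly empty).
#' @param gp [government_params()] (uses `lambda_health`).
#' @return Welfare (real).
#' @export
social_welfare <- function(consumer_utilities, provider_costs,
                           health_benefits, gp) {
  sum(consumer_utilities) - sum(provider_costs) +
    gp$lambda_health * sum(health_benefits)
}

#' One explicit-Euler step of the subsidy/tax dynamics
#'
#' \eqn{dS/dt = \beta (W - W^*)}, \eqn{dT/dt = \delta (W - W^*)}. Both
#' instruments move in the same direction whenever welfare deviates from
#' its target — implemented literally as the model states it, and flagged
#' as a documented economic oddity (one would expect the tax to move
#' against the subsidy).
#'
#' @param state List with `subsidy_level` and `tax_level`.
#' @param w Current welfare.
#' @param gp [government_params()]; `w_star` must be resolved (non-NULL).
#' @param dt Time step, `> 0`.
#' @return Updated policy state list.
#' @export
policy_step <- function(state, w, gp, dt) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (is.null(gp$w_star)) {
    stop("'w_star' is unresolved; set it or compute a baseline first",
         call. = FALSE)
  }
  dev <- w - gp$w_star
  list(subsidy_level = state$subsidy_level + gp$beta_s * dev * dt,
       tax_level = state$tax_level + gp$delta_t * dev * dt)
}

#' First-order-condition residuals for consumer and producer
#'
#' At the welfare optimum, marginal utility equals the tax-adjusted price
#' and marginal cost equals the subsidy-adjusted price:
#' residuals \eqn{(\partial U/\partial q - (p - T),\;
#' \partial C/\partial q - (p - S))}, both zero at the optimum.
#'
#' @param p Market price.
#' @param state Policy state (list with `subsidy_level`, `tax_level`).
#' @param q_consumer,q_provider Candidate quantities.
#' @param cp [consumer_params()].
#' @param pp [provider_params()].
#' @return Named numeric vector `c(consumer = ..., producer = ...)`.
#' @export
foc_residuals <- function(p, state, q_consumer, q_provider, cp, pp) {
  c(consumer = marginal_utility(q_consumer, cp) - (p - state$tax_level),
    producer = marginal_cost(q_provider, pp) - (p - state$subsidy_level))
}

#' Discounted welfare objective
#'
#' Trapezoidal quadrature of \eqn{\int_0^T e^{-\rho t} W(t) dt} over a
#' uniformly sampled welfare path.
#'
#' @param welfare_path Numeric vector of welfare values at times
#'   `0, dt, 2 dt, ...`.
#' @param rho Discount rate, `>= 0`.
#' @param dt Time step, `> 0`.
#' @return Discounted objective value.
#' @export
discounted_objective <- function(welfare_path, rho, dt) {
  if (length(welfare_path) == 0L) stop("empty welfare path", call. = FALSE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(rho, "rho", lower = 0)
  if (length(welfare_path) == 1L) return(0)
  t <- (seq_along(welfare_path) - 1) * dt
  pracma::trapz(t, exp(-rho * t) * welfare_path)
}
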