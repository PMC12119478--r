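# Consumer and provider primitives: utility, demand, profit, marginal
# quantities, market clearing, moral hazard, effective prices. All pure
# and deterministic.

#' Quadratic consumer utility
#'
#' \eqn{U(q, y) = a q - (b/2) q^2 + c y} with `y` the net income. Concave
#' in `q` since `b > 0`.
#'
#' @param q Consumption quantity, `>= 0`.
#' @param net_income Income net of healthcare spending (currency).
#' @param cp [consumer_params()].
#' @return Utility (utils).
#' @export
utility <- function(q, net_income, cp) {
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  cp$a * q - (cp$b / 2) * q^2 + cp$c * net_income
}

#' Marginal utility of consumption
#'
#' \eqn{U'(q) = a - b q}.
#'
#' @inheritParams utility
#' @return Marginal utility.
#' @export
marginal_utility <- function(q, cp) {
  cp$a - cp$b * q
}

#' Optimal consumption under the intertemporal first-order condition
#'
#' The first-order condition equates marginal utility with the effective
#' dynamic price \eqn{\lambda_i (p + \dot p)}; for quadratic utility the
#' interior optimum is \eqn{q^* = (a - \lambda_i (p + \dot p)) / b},
#' clipped at 0 because quantities are physical.
#'
#' @param p Current price.
#' @param p_dot Price time-derivative (currency per time unit).
#' @param cp [consumer_params()].
#' @return Optimal quantity `>= 0`.
#' @export
optimal_consumption <- function(p, p_dot, cp) {
  pmax(0, (cp$a - cp$lambda_consumer * (p + p_dot)) / cp$b)
}

#' First-order-condition residual of the consumer problem
#'
#' \eqn{\partial U/\partial q - \lambda_i (p + \dot p)}; zero at interior
#' optima of [optimal_consumption()].
#'
#' @inheritParams optimal_consumption
#' @param q Candidate quantity.
#' @return Residual (utils per quantity unit).
#' @export
consumption_foc_residual <- function(q, p, p_dot, cp) {
  marginal_utility(q, cp) - cp$lambda_consumer * (p + p_dot)
}

#' Euler-equation residual (diagnostic)
#'
#' Intertemporal optimality links the growth of marginal utility to the
#' discount rate and price dynamics:
#' \eqn{d(U')/dt - \rho U' + \lambda_i \dot p}. The static consumption
#' rule is not guaranteed to satisfy it; this residual is exposed purely
#' as a diagnostic and the package never asserts it vanishes.
#'
#' @param dmu_dt Time derivative of marginal utility along the path.
#' @param mu Marginal utility at the current point.
#' @param rho Discount rate.
#' @param p_dot Price time-derivative.
#' @param cp [consumer_params()].
#' @return Residual.
#' @export
euler_residual <- function(dmu_dt, mu, rho, p_dot, cp) {
  dmu_dt - rho * mu + cp$lambda_consumer * p_dot
}

#' Reduced-form exponential demand
#'
#' \eqn{D(p) = d_0 e^{-\epsilon p}}.
#'
#' @param p Price, `>= 0`.
#' @param dp [demand_params()].
#' @return Quantity demanded.
#' @export
demand_response <- function(p, dp) {
  if (any(p < 0)) stop("'p' must be >= 0", call. = FALSE)
  dp$d0 * exp(-dp$epsilon * p)
}

#' Numerical price elasticity of demand
#'
#' Central-difference estimate of \eqn{(\partial q / \partial p)(p / q)}.
#'
#' @param demand_fn Function mapping price to quantity.
#' @param p Price at which to evaluate.
#' @param h Finite-difference step, `> 0`.
#' @return Dimensionless elasticity.
#' @export
price_elasticity <- function(demand_fn, p, h = 1e-5) {
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  q <- demand_fn(p)
  if (q == 0) stop("demand is zero at p; elasticity undefined", call. = FALSE)
  dq <- (demand_fn(p + h) - demand_fn(p - h)) / (2 * h)
  dq * p / q
}

#' Provider cost, marginal cost and profit
#'
#' Convex quadratic cost \eqn{C(q) = c_0 + c_1 q + c_2 q^2}, marginal
#' cost \eqn{MC(q) = c_1 + 2 c_2 q}, profit \eqn{\Pi = p q - C(q)}.
#'
#' @param q Quantity supplied, `>= 0`.
#' @param pp [provider_params()].
#' @return `provider_cost()`: total cost; `marginal_cost()`: marginal
#'   cost; `provider_profit()`: profit at price `p`.
#' @export
provider_cost <- function(q, pp) {
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  pp$c0 + pp$c1 * q + pp$c2 * q^2
}

#' @rdname provider_cost
#' @export
marginal_cost <- function(q, pp) {
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  pp$c1 + 2 * pp$c2 * q
}

#' @rdname provider_cost
#' @param p Market price received by the provider.
#' @export
provider_profit <- function(p, q, pp) {
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  p * q - provider_cost(q, pp)
}

#' Profit-maximizing supply at a given price
#'
#' Inverts the provider first-order condition `MC(q) = p`:
#' \eqn{q = \max(0, (p - c_1) / (2 c_2))}. For linear cost (`c2 = 0`) the
#' optimum is a corner; this function requires strictly convex cost.
#'
#' @param p Price.
#' @param pp [provider_params()] with `c2 > 0`.
#' @return Quantity supplied.
#' @export
provider_supply <- function(p, pp) {
  if (pp$c2 <= 0) stop("provider supply requires strictly convex cost (c2 > 0)", call. = FALSE)
  pmax(0, (p - pp$c1) / (2 * pp$c2))
}

#' Market-clearing price by bisection
#'
#' Finds a price where aggregate demand equals aggregate supply. Plain
#' bisection is used because it is bracket-safe for any monotone excess
#' demand, whatever the functional forms.
#'
#' @param aggregate_demand,aggregate_supply Functions of price.
#' @param bracket Length-2 numeric price interval.
#' @param tol Absolute tolerance on the excess demand at the returned
#'   price.
#' @param max_iter Iteration cap.
#' @return Clearing price with excess demand within `tol`. If demand and
#'   supply coincide at both bracket endpoints (degenerate clearing), the
#'   bracket midpoint is returned.
#' @export
market_clearing_price <- function(aggregate_demand, aggregate_supply,
                                  bracket, tol = 1e-8, max_iter = 200) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  excess <- function(p) aggregate_demand(p) - aggregate_supply(p)
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- excess(lo); e_hi <- excess(hi)
  if (abs(e_lo) <= tol && abs(e_hi) <= tol) {
    return((lo + hi) / 2)
  }
  if (abs(e_lo) <= tol) return(lo)
  if (abs(e_hi) <= tol) return(hi)
  if (sign(e_lo) == sign(e_hi)) {
    stop("excess demand does not change sign over the bracket", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    e_mid <- excess(mid)
    if (abs(e_mid) <= tol) return(mid)
    if (sign(e_mid) == sign(e_lo)) {
      lo <- mid; e_lo <- e_mid
    } else {
      hi <- mid
    }
  }
  stop("market clearing did not reach tolerance within ", max_iter,
       " bisection iterations", call. = FALSE)
}

#' Insured demand under moral hazard
#'
#' With coverage \eqn{\alpha}, the insured consumer equates marginal
#' utility to a fraction of its uninsured level:
#' \eqn{U'(q') = \alpha U'(q^*)}. For quadratic utility,
#' \eqn{q' = (a - \alpha (a - b q^*)) / b}, capped at the satiation point
#' `a/b` (beyond which marginal utility is negative and the condition has
#' no solution for small \eqn{\alpha}).
#'
#' @param coverage \eqn{\alpha \in [0, 1]}; `1` reproduces the uninsured
#'   optimum, `0` gives satiation.
#' @param q_star Uninsured optimal quantity with
#'   \eqn{U'(q^*) \ge 0}.
#' @param cp [consumer_params()].
#' @return Insured quantity `q' >= q_star`.
#' @export
moral_hazard_demand <- function(coverage, q_star, cp) {
  if (any(coverage < 0 | coverage > 1)) {
    stop("'coverage' must lie in [0, 1]", call. = FALSE)
  }
  if (any(marginal_utility(q_star, cp) < -1e-12)) {
    stop("'q_star' exceeds the satiation point a/b", call. = FALSE)
  }
  q_prime <- (cp$a - coverage * (cp$a - cp$b * q_star)) / cp$b
  pmin(q_prime, cp$a / cp$b)
}

#' Effective consumer price under a subsidy
#'
#' \eqn{p' = p - T(q)}. The result may be negative (a subsidy larger than
#' the price); this is allowed rather than floored, because a hard floor
#' would silently change welfare accounting, but the returned value
#' carries a `negative` flag attribute for auditing.
#'
#' @param p Market price.
#' @param subsidy_fn_value Subsidy amount `T(q)` at the chosen quantity.
#' @return Effective price, with attribute `negative = TRUE` when below
#'   zero.
#' @export
effective_price <- function(p, subsidy_fn_value) {
  p_eff <- p - subsidy_fn_value
  if (any(p_eff < 0)) {
    return(flagged(p_eff, negative = TRUE))
  }
  p_eff
}
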