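# Insurer: expected claims by quadrature, adverse-selection pricing,
# dynamic premium adjustment, risk-adjusted premiums with incentive
# discounts, and portfolio balance.

# Gauss-Legendre nodes are deterministic in (n, a, b); cache them so the
# simulation loop does not recompute the rule every tick.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_cached <- function(n, a, b) {
  key <- paste(n, a, b, sep = "|")
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, a, b)
  }
  .gl_cache[[key]]
}

#' Expected claim cost over the health-risk distribution
#'
#' Computes \eqn{E[C | q] = \int C(q, \theta) f(\theta) d\theta} over the
#' support of the risk density by Gauss-Legendre quadrature (smooth
#' integrands, spectral accuracy, deterministic). The density is first
#' checked to integrate to 1 within the quadrature tolerance.
#'
#' @param risk [health_risk_model()].
#' @param q Consumption/claim quantity.
#' @param quadrature List with `nodes` and `tol`; defaults to 64
#'   Gauss-Legendre nodes.
#' @return Expected claim cost (currency).
#' @export
expected_claims <- function(risk, q,
                            quadrature = list(nodes = 64, tol = 1e-6)) {
  stopifnot(inherits(risk, "health_risk_model"))
  n <- as.integer(quadrature$nodes %||% 64)
  tol <- quadrature$tol %||% 1e-6
  gl <- gauss_legendre_cached(n, risk$support[1], risk$support[2])
  f <- risk$density(gl$x)
  mass <- sum(gl$w * f)
  if (abs(mass - 1) > tol) {
    stop(sprintf(
      "risk density integrates to %.8f over its support (tolerance %g); not normalized",
      mass, tol), call. = FALSE)
  }
  cost <- risk$claim_cost(q, gl$x)
  if (any(!is.finite(cost))) {
    stop("claim cost is not finite over the risk support", call. = FALSE)
  }
  if (any(cost < 0)) {
    stop("claim cost must be nonnegative over the risk support", call. = FALSE)
  }
  sum(gl$w * cost * f)
}

#' Adverse-selection premium
#'
#' \eqn{P = P_0 + \lambda_{risk} E[C | \theta]}: the base premium plus a
#' risk loading proportional to expected claims.
#'
#' @param expected Expected claim cost, `>= 0`.
#' @param ip [insurance_params()].
#' @return Premium (currency).
#' @export
adverse_selection_premium <- function(expected, ip) {
  if (any(expected < 0)) stop("'expected' must be >= 0", call. = FALSE)
  ip$p0 + ip$lambda_risk * expected
}

#' One explicit-Euler step of the premium adjustment rule
#'
#' Discretizes \eqn{dP/dt = \gamma (E[C] - P)}:
#' \eqn{P \leftarrow P + \gamma (E - P) \Delta t}, clipped at zero
#' (negative premiums are economically meaningless; the clip is flagged).
#' The expected-claims level is an exact fixed point of the step.
#'
#' @param p Current premium.
#' @param expected Expected claim cost.
#' @param ip [insurance_params()] (uses `gamma_premium`).
#' @param dt Time step, `> 0`.
#' @return Updated premium, with attribute `clipped = TRUE` if floored.
#' @export
premium_step <- function(p, expected, ip, dt) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  p_next <- p + ip$gamma_premium * (expected - p) * dt
  if (any(p_next < 0)) {
    return(flagged(pmax(0, p_next), clipped = TRUE))
  }
  p_next
}

#' Risk-adjusted premium with behavioral incentive discount
#'
#' \eqn{P = P_0 + \lambda_{risk} E[C|\theta] - \rho_{incentive} I},
#' clipped at zero with a flag.
#'
#' @param expected_given_theta Conditional expected claim cost.
#' @param incentive Incentive amount earning a premium discount.
#' @param ip [insurance_params()].
#' @return Premium, with attribute `clipped = TRUE` if floored at 0.
#' @export
risk_adjusted_premium <- function(expected_given_theta, incentive, ip) {
  p <- ip$p0 + ip$lambda_risk * expected_given_theta -
    ip$rho_incentive * incentive
  if (any(p < 0)) {
    return(flagged(pmax(0, p), clipped = TRUE))
  }
  p
}

#' Portfolio balance residual
#'
#' Exposure-weighted gap between premium revenue and expected payouts,
#' \eqn{\sum_i P_i I_i - \sum_i E_i I_i}. Zero means the book balances.
#'
#' @param premiums Named numeric vector of per-consumer premiums.
#' @param exposures Named numeric vector of per-consumer exposure
#'   (intervention) levels, `>= 0`, same names as `premiums`.
#' @param expected Named numeric vector of per-consumer expected claims,
#'   same names.
#' @return Residual (currency).
#' @export
portfolio_balance_residual <- function(premiums, exposures, expected) {
  if (length(premiums) == 0L) stop("empty portfolio", call. = FALSE)
  if (!setequal(names(premiums), names(exposures)) ||
      !setequal(names(premiums), names(expected))) {
    stop("premiums, exposures and expected must share the same consumer ids",
         call. = FALSE)
  }
  ids <- names(premiums)
  sum(premiums[ids] * exposures[ids]) - sum(expected[ids] * exposures[ids])
}

#' Solve the base-premium shift that balances the portfolio
#'
#' The residual is linear in a uniform premium shift, so the closed form
#' `shift = residual / sum(exposures)` balances the book exactly; the
#' returned premiums are `premiums - shift`. Applying the solver twice
#' changes nothing the second time.
#'
#' @inheritParams portfolio_balance_residual
#' @return List with `shift` (amount subtracted from every premium) and
#'   `premiums` (balanced premium vector).
#' @export
solve_base_premium <- function(premiums, exposures, expected) {
  residual <- portfolio_balance_residual(premiums, exposures, expected)
  total_exposure <- sum(exposures)
  if (total_exposure == 0) {
    stop("total exposure is zero; base premium is unidentified", call. = FALSE)
  }
  shift <- residual / total_exposure
  list(shift = shift, premiums = premiums - shift)
}
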