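# Dynamic pricing: bounded, dampened price evolution and its fixed-point
# diagnostics.

#' One bounded, dampened price step
#'
#' Explicit-Euler step of
#' \eqn{dp/dt = \kappa (D - S) - \eta (p - p^*)}, with the per-step change
#' clipped to `[-dp_max, +dp_max]` and the result floored at zero. The
#' bound is interpreted per step of size `dt` (the only
#' discretization-consistent reading at fixed `dt`).
#'
#' @param p Current price.
#' @param demand,supply Quantities at the current tick.
#' @param pp [pricing_params()].
#' @param dt Time step, `> 0`.
#' @return Next price, with attributes `clipped = TRUE` when the bound
#'   was binding and `floored = TRUE` when the zero floor was.
#' @export
price_step <- function(p, demand, supply, pp, dt) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  raw_delta <- (pp$kappa * (demand - supply) -
                  pp$eta_stabilize * (p - pp$p_star)) * dt
  delta <- clip(raw_delta, -pp$dp_max, pp$dp_max)
  clipped <- !identical(delta, raw_delta)
  p_next <- p + delta
  floored <- p_next < 0
  p_next <- pmax(0, p_next)
  if (clipped || any(floored)) {
    return(flagged(p_next, clipped = clipped, floored = any(floored)))
  }
  p_next
}

#' Simulate a price path
#'
#' Iterates [price_step()] with demand and supply re-evaluated at the
#' current price each tick. The convergence flag is set when the final
#' step's update magnitude falls below `pp$tol`; at a flagged fixed point
#' the drift residual
#' \eqn{|\kappa (D(\bar p) - S(\bar p)) - \eta (\bar p - p^*)|} is at
#' most `tol / dt`.
#'
#' @param p0 Initial price, `>= 0`.
#' @param demand_fn,supply_fn Functions of price.
#' @param steps Number of steps, `>= 1`.
#' @param pp [pricing_params()].
#' @param dt Time step.
#' @return List with `path` (a `data.frame` of `t`, `price`, `demand`,
#'   `supply`, `clipped`; `steps + 1` rows), `converged`, and
#'   `residual` (the terminal drift residual).
#' @export
simulate_price_path <- function(p0, demand_fn, supply_fn, steps, pp,
                                dt = 0.01) {
  check_number(steps, "steps", lower = 1)
  check_number(p0, "p0", lower = 0)
  steps <- as.integer(steps)
  price <- numeric(steps + 1L)
  demand <- numeric(steps + 1L)
  supply <- numeric(steps + 1L)
  clipped <- logical(steps + 1L)
  price[1] <- p0
  last_update <- Inf
  for (k in seq_len(steps)) {
    demand[k] <- demand_fn(price[k])
    supply[k] <- supply_fn(price[k])
    p_next <- price_step(price[k], demand[k], supply[k], pp, dt)
    clipped[k] <- is_flagged(p_next, "clipped")
    last_update <- abs(as.numeric(p_next) - price[k])
    price[k + 1L] <- as.numeric(p_next)
  }
  demand[steps + 1L] <- demand_fn(price[steps + 1L])
  supply[steps + 1L] <- supply_fn(price[steps + 1L])
  p_bar <- price[steps + 1L]
  residual <- abs(pp$kappa * (demand[steps + 1L] - supply[steps + 1L]) -
                    pp$eta_stabilize * (p_bar - pp$p_star))
  list(
    path = data.frame(t = (0:steps) * dt, price = price, demand = demand,
                      supply = supply, clipped = clipped),
    converged = last_update < pp$tol,
    residual = residual
  )
}

#' Export a price path as CSV
#'
#' @param price_path Result of [simulate_price_path()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_price_path_csv <- function(price_path, path) {
  write.csv(price_path$path, path, row.names = FALSE)
  invisible(path)
}
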