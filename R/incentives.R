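# Incentive-based policy adjustments: the incentive function, response
# elasticity, and budget/threshold/smoothness-constrained allocation.

eval_component_fn <- function(fn, q) {
  switch(fn$form,
    linear = fn$k * q,
    constant = rep_len(fn$k, length(q)),
    sqrt = fn$k * sqrt(q),
    stop("unknown incentive component form: ", fn$form, call. = FALSE)
  )
}

#' Incentive value at a consumption level
#'
#' \eqn{I(q) = \beta_1 T(q) + \beta_2 R(q) + \beta_3 M(q)}: a weighted
#' sum of a tax rebate, a risk-adjusted insurance benefit and an
#' adherence reward, each a named nonnegative functional form.
#'
#' @param q Consumption quantity, `>= 0`.
#' @param ip [incentive_params()].
#' @return Incentive amount (currency).
#' @export
incentive_value <- function(q, ip) {
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  ip$beta1 * eval_component_fn(ip$rebate_fn, q) +
    ip$beta2 * eval_component_fn(ip$benefit_fn, q) +
    ip$beta3 * eval_component_fn(ip$adherence_fn, q)
}

#' Response elasticity of consumption to incentives
#'
#' Central-difference estimate of
#' \eqn{(\partial q / \partial I)(I / q)}.
#'
#' @param consumption_fn Function mapping incentive amount to quantity.
#' @param i_val Incentive amount at which to evaluate.
#' @param h Finite-difference step, `> 0`.
#' @return Dimensionless elasticity.
#' @export
incentive_elasticity <- function(consumption_fn, i_val, h = 1e-5) {
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  q <- consumption_fn(i_val)
  if (q == 0) stop("consumption is zero at i_val; elasticity undefined", call. = FALSE)
  dq <- (consumption_fn(i_val + h) - consumption_fn(i_val - h)) / (2 * h)
  dq * i_val / q
}

#' Marginal-utility modes for incentive allocation
#'
#' Incentives raise a consumer's net income one-for-one. Two standard
#' readings of the marginal utility of an incentive unit are provided:
#'
#' * `mu_income(cp)` — pure income effect: for quadratic utility,
#'   \eqn{\partial U / \partial I = c}, a constant.
#' * `mu_consumption(cp, q0, k)` — a configured consumption response
#'   \eqn{q(I) = q_0 + k I}, giving
#'   \eqn{\partial U / \partial I = (a - b (q_0 + k I)) k}, decreasing in
#'   `I` (concave utility of incentives).
#'
#' Either returns a function `function(i) -> utility per currency unit`
#' usable as the `marginal_utility` entry of a consumer passed to
#' [allocate_incentives()].
#'
#' @param cp [consumer_params()].
#' @param q0 Baseline consumption at zero incentive.
#' @param k Consumption response per currency unit of incentive.
#' @return A function of the current incentive amount.
#' @export
mu_income <- function(cp) {
  force(cp)
  function(i) rep_len(cp$c, length(i))
}

#' @rdname mu_income
#' @export
mu_consumption <- function(cp, q0, k) {
  force(cp); force(q0); force(k)
  function(i) (cp$a - cp$b * (q0 + k * i)) * k
}

#' Allocate incentives under budget, threshold and smoothness constraints
#'
#' Greedy marginal-utility allocation on a grid: repeatedly grant one
#' grid step of incentive to the eligible consumer with the highest
#' marginal utility per currency unit, until the budget is exhausted or
#' nobody is eligible. A consumer is eligible for a grant while (i) their
#' marginal utility at the current amount is at least `lambda_min`
#' (cost-effectiveness threshold) and (ii) the grant keeps the change
#' from the previous allocation within `delta_max` (smoothness). Ties are
#' broken by lowest consumer index. With concave marginal utilities the
#' greedy solution is optimal in the continuous limit; an exhaustive
#' search over the same grid can differ by at most one grid-step's
#' utility.
#'
#' Each consumer's allocation is boxed to
#' `[max(0, previous - delta_max), previous + delta_max]`; allocations
#' start at the lower bound (the smoothness constraint is two-sided). If
#' the lower bounds alone exceed the budget the instance is infeasible
#' and an error is raised.
#'
#' @param consumers Nonempty list; each element a list with `params`
#'   ([consumer_params()]), optional `previous` (default 0) and optional
#'   `marginal_utility` (a function of the current amount; default
#'   [mu_income()] of `params`).
#' @param ip [incentive_params()] (uses `b_max`, `delta_max`,
#'   `lambda_min`, `grid`).
#' @return An object of class `incentive_allocation`: a `data.frame` with
#'   columns `consumer`, `previous`, `allocation`, `granted` and
#'   binding-constraint flags `at_budget`, `at_threshold`,
#'   `at_smoothness`, plus attributes `total` and `utility_gain` (the
#'   discrete objective value, summed marginal utility per granted step
#'   times the step).
#' @export
allocate_incentives <- function(consumers, ip) {
  if (length(consumers) == 0L) stop("empty consumer list", call. = FALSE)
  n <- length(consumers)
  prev <- vapply(consumers, function(x) x$previous %||% 0, numeric(1))
  mu <- lapply(consumers, function(x) {
    x$marginal_utility %||% mu_income(x$params)
  })
  lower <- pmax(0, prev - ip$delta_max)
  upper <- prev + ip$delta_max
  if (sum(lower) > ip$b_max + 1e-9) {
    stop("infeasible: smoothness lower bounds exceed the incentive budget",
         call. = FALSE)
  }
  alloc <- lower
  spent <- sum(alloc)
  gain <- 0
  at_threshold <- logical(n)
  at_smoothness <- logical(n)
  repeat {
    remaining <- ip$b_max - spent
    if (remaining < ip$grid - 1e-12) break
    mu_now <- vapply(seq_len(n), function(i) mu[[i]](alloc[i]), numeric(1))
    room <- alloc + ip$grid <= upper + 1e-12
    effective <- mu_now >= ip$lambda_min - 1e-12
    at_smoothness <- at_smoothness | !room
    at_threshold <- at_threshold | (room & !effective)
    eligible <- which(room & effective)
    if (length(eligible) == 0L) break
    best <- eligible[which.max(mu_now[eligible])]
    alloc[best] <- alloc[best] + ip$grid
    spent <- spent + ip$grid
    gain <- gain + mu_now[best] * ip$grid
  }
  at_budget <- rep(ip$b_max - spent < ip$grid, n)
  out <- data.frame(
    consumer = seq_len(n), previous = prev, allocation = alloc,
    granted = alloc - lower, at_budget = at_budget,
    at_threshold = at_threshold, at_smoothness = at_smoothness
  )
  structure(out, class = c("incentive_allocation", "data.frame"),
            total = spent, utility_gain = gain)
}

#' Export an allocation as CSV
#'
#' @param allocation Result of [allocate_incentives()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_allocation_csv <- function(allocation, path) {
  write.csv(as.data.frame(allocation), path, row.names = FALSE)
  invisible(path)
}
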