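# Reinforcement-learning policy optimization over a discretized
# (subsidy, tax) decision process: tabular softmax policy, Monte-Carlo
# return estimation, likelihood-ratio (REINFORCE) policy gradient with a
# mean-return baseline, and TD(0) welfare-value updates.

#' Subsidy/tax lattice decision process
#'
#' States are points of a finite lattice `s_grid x t_grid`. Actions move
#' each instrument by one lattice cell, stay, or move back
#' (`{-1, 0, +1}` per instrument, 9 combined actions); deterministic
#' moves are clipped at the lattice bounds. A stochastic transition
#' kernel may be supplied instead. The reward of a step is the reward of
#' the state reached.
#'
#' @param s_grid,t_grid Numeric lattices for the subsidy and tax levels.
#' @param reward_fn Function `(subsidy, tax) -> real`, typically a social
#'   welfare evaluation.
#' @param gamma_rl Discount factor in `(0, 1)`.
#' @param kernel Optional stochastic transition array of dimension
#'   `n_states x n_actions x n_states`; each `(state, action)` row must
#'   sum to 1. `NULL` (default) means deterministic clipped lattice
#'   moves.
#' @param start_state Initial state index for rollouts and exact values.
#' @return An object of class `mdp_spec`.
#' @export
mdp_spec <- function(s_grid, t_grid, reward_fn, gamma_rl = 0.9,
                     kernel = NULL, start_state = 1L) {
  stopifnot(is.numeric(s_grid), is.numeric(t_grid), is.function(reward_fn))
  check_number(gamma_rl, "gamma_rl", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n_s <- length(s_grid)
  n_t <- length(t_grid)
  n_states <- n_s * n_t
  actions <- as.matrix(expand.grid(ds = c(-1L, 0L, 1L), dt = c(-1L, 0L, 1L)))
  n_actions <- nrow(actions)
  # deterministic next-state table
  next_state <- matrix(0L, n_states, n_actions)
  for (is in seq_len(n_s)) {
    for (it in seq_len(n_t)) {
      s_idx <- (it - 1L) * n_s + is
      for (a in seq_len(n_actions)) {
        is2 <- clip(is + actions[a, "ds"], 1L, n_s)
        it2 <- clip(it + actions[a, "dt"], 1L, n_t)
        next_state[s_idx, a] <- (it2 - 1L) * n_s + is2
      }
    }
  }
  if (!is.null(kernel)) {
    if (!identical(dim(kernel), c(n_states, n_actions, n_states))) {
      stop("kernel must be n_states x n_actions x n_states", call. = FALSE)
    }
    row_sums <- apply(kernel, c(1, 2), sum)
    if (any(abs(row_sums - 1) > 1e-9) || any(kernel < 0)) {
      stop("kernel rows must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  rewards <- vapply(seq_len(n_states), function(s_idx) {
    is <- (s_idx - 1L) %% n_s + 1L
    it <- (s_idx - 1L) %/% n_s + 1L
    reward_fn(s_grid[is], t_grid[it])
  }, numeric(1))
  check_number(start_state, "start_state", lower = 1, upper = n_states)
  structure(list(s_grid = s_grid, t_grid = t_grid, n_states = n_states,
                 n_actions = n_actions, actions = actions,
                 next_state = next_state, kernel = kernel,
                 rewards = rewards, gamma_rl = gamma_rl,
                 start_state = as.integer(start_state)),
            class = "mdp_spec")
}

#' Initialize tabular policy parameters
#'
#' One logit per (state, action) pair of the softmax policy.
#'
#' @param mdp [mdp_spec()].
#' @param value Initial logit value (default 0: uniform policy).
#' @return A `n_states x n_actions` numeric matrix.
#' @export
policy_init <- function(mdp, value = 0) {
  matrix(value, mdp$n_states, mdp$n_actions)
}

#' Action probabilities of the softmax policy at a state
#'
#' Strictly positive and summing to 1 for any finite logits.
#'
#' @param theta_policy Logit matrix from [policy_init()].
#' @param state State index.
#' @param mdp [mdp_spec()] (for bounds checking).
#' @return Probability vector over actions.
#' @export
policy_probabilities <- function(theta_policy, state, mdp) {
  if (state < 1L || state > mdp$n_states) {
    stop("state index off the lattice: ", state, call. = FALSE)
  }
  z <- theta_policy[state, ]
  e <- exp(z - max(z))
  e / sum(e)
}

transition <- function(mdp, state, action) {
  if (is.null(mdp$kernel)) {
    mdp$next_state[state, action]
  } else {
    sample.int(mdp$n_states, 1L, prob = mdp$kernel[state, action, ])
  }
}

rollout_impl <- function(mdp, theta_policy, horizon, start) {
  states <- integer(horizon + 1L)
  actions <- integer(horizon)
  rewards <- numeric(horizon)
  states[1] <- start
  for (t in seq_len(horizon)) {
    probs <- policy_probabilities(theta_policy, states[t], mdp)
    a <- sample.int(mdp$n_actions, 1L, prob = probs)
    s_next <- transition(mdp, states[t], a)
    actions[t] <- a
    rewards[t] <- mdp$rewards[s_next]
    states[t + 1L] <- s_next
  }
  list(states = states, actions = actions, rewards = rewards)
}

#' Sample one seeded episode
#'
#' Follows the softmax policy and the transition rule for `horizon`
#' steps; reproducible under `seed`.
#'
#' @param mdp [mdp_spec()].
#' @param theta_policy Logit matrix.
#' @param horizon Episode length, `>= 1`.
#' @param seed Integer seed.
#' @param start Start state index (default `mdp$start_state`).
#' @return List with `states` (length `horizon + 1`), `actions` and
#'   `rewards` (length `horizon`).
#' @export
rollout <- function(mdp, theta_policy, horizon, seed, start = mdp$start_state) {
  check_number(horizon, "horizon", lower = 1)
  with_seed(substream_seed(seed, "rollout"),
            rollout_impl(mdp, theta_policy, as.integer(horizon), start))
}

#' Sample a batch of seeded episodes
#'
#' @inheritParams rollout
#' @param n Number of episodes.
#' @return List of episodes.
#' @export
sample_episodes <- function(mdp, theta_policy, n, horizon, seed,
                            start = mdp$start_state) {
  check_number(n, "n", lower = 1)
  with_seed(substream_seed(seed, "rollout"), {
    lapply(seq_len(n), function(i) {
      rollout_impl(mdp, theta_policy, as.integer(horizon), start)
    })
  })
}

episode_return <- function(episode, gamma_rl) {
  h <- length(episode$rewards)
  sum(gamma_rl^(seq_len(h) - 1) * episode$rewards)
}

#' Monte-Carlo estimate of the expected discounted return
#'
#' Mean over episodes of \eqn{\sum_t \gamma^t R_t}.
#'
#' @param episodes Nonempty list of episodes from [rollout()].
#' @param gamma_rl Discount factor.
#' @return Estimated return, with attribute `se` (Monte-Carlo standard
#'   error).
#' @export
estimate_return <- function(episodes, gamma_rl) {
  if (length(episodes) == 0L) stop("empty episode list", call. = FALSE)
  g <- vapply(episodes, episode_return, numeric(1), gamma_rl = gamma_rl)
  flagged(mean(g), se = stats::sd(g) / sqrt(length(g)))
}

#' Exact expected discounted return of a policy
#'
#' Finite-horizon expectation computed by full enumeration (backward
#' recursion over the episode tree): at horizon `h`,
#' \eqn{V_h(s) = \sum_a \pi(a | s) \sum_{s'} P(s' | s, a)
#' [R(s') + \gamma V_{h-1}(s')]}. Exact for any lattice small enough to
#' enumerate, and therefore usable as a reference for the Monte-Carlo
#' estimator and for finite-difference gradient checks.
#'
#' @param mdp [mdp_spec()].
#' @param theta_policy Logit matrix.
#' @param horizon Episode length.
#' @param start Start state index.
#' @return Exact expected discounted return from `start`.
#' @export
exact_policy_value <- function(mdp, theta_policy, horizon,
                               start = mdp$start_state) {
  v <- numeric(mdp$n_states)
  for (h in seq_len(horizon)) {
    v_new <- numeric(mdp$n_states)
    for (s in seq_len(mdp$n_states)) {
      probs <- policy_probabilities(theta_policy, s, mdp)
      acc <- 0
      for (a in seq_len(mdp$n_actions)) {
        if (is.null(mdp$kernel)) {
          s2 <- mdp$next_state[s, a]
          acc <- acc + probs[a] * (mdp$rewards[s2] + mdp$gamma_rl * v[s2])
        } else {
          p2 <- mdp$kernel[s, a, ]
          acc <- acc + probs[a] *
            sum(p2 * (mdp$rewards + mdp$gamma_rl * v))
        }
      }
      v_new[s] <- acc
    }
    v <- v_new
  }
  v[start]
}

#' REINFORCE gradient estimate
#'
#' Likelihood-ratio estimator of the policy gradient with an optional
#' mean-return baseline:
#' \eqn{\hat g = \frac{1}{N} \sum_e (G_e - \bar G)
#' \sum_t \nabla_\theta \log \pi(a_t | s_t)}. The baseline preserves the
#' estimator's expectation; without it the estimator is exactly unbiased
#' for \eqn{\nabla_\theta J}.
#'
#' @param episodes Episodes generated under `theta_policy`.
#' @param theta_policy Logit matrix the episodes were sampled from.
#' @param mdp [mdp_spec()].
#' @param baseline Subtract the batch mean return (default `TRUE`).
#' @return Gradient matrix of the same shape as `theta_policy`.
#' @export
reinforce_gradient <- function(episodes, theta_policy, mdp, baseline = TRUE) {
  if (length(episodes) == 0L) stop("empty episode list", call. = FALSE)
  returns <- vapply(episodes, episode_return, numeric(1),
                    gamma_rl = mdp$gamma_rl)
  b <- if (baseline) mean(returns) else 0
  g <- matrix(0, mdp$n_states, mdp$n_actions)
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    if (max(ep$actions) > mdp$n_actions || max(ep$states) > mdp$n_states) {
      stop("episode does not match the MDP dimensions", call. = FALSE)
    }
    score <- matrix(0, mdp$n_states, mdp$n_actions)
    for (t in seq_along(ep$actions)) {
      s <- ep$states[t]
      probs <- policy_probabilities(theta_policy, s, mdp)
      score[s, ] <- score[s, ] - probs
      score[s, ep$actions[t]] <- score[s, ep$actions[t]] + 1
    }
    g <- g + score * (returns[e] - b)
  }
  g / length(episodes)
}

#' One policy-gradient ascent step
#'
#' \eqn{\theta \leftarrow \theta + \eta \hat g} with \eqn{\hat g} from
#' [reinforce_gradient()].
#'
#' @inheritParams reinforce_gradient
#' @param eta_lr Learning rate, `> 0`.
#' @return List with `theta` (updated logits) and `gradient`.
#' @export
policy_gradient_step <- function(theta_policy, episodes, mdp, eta_lr,
                                 baseline = TRUE) {
  check_number(eta_lr, "eta_lr", lower = 0, strict_lower = TRUE)
  g <- reinforce_gradient(episodes, theta_policy, mdp, baseline = baseline)
  list(theta = theta_policy + eta_lr * g, gradient = g)
}

#' Train a softmax policy by gradient ascent
#'
#' Iterates batch sampling and [policy_gradient_step()], logging the
#' exact expected return (by enumeration) and the gradient norm each
#' iteration.
#'
#' @param mdp [mdp_spec()].
#' @param rl [rl_params()].
#' @param seed Integer seed; each iteration draws from an independent
#'   substream.
#' @param theta0 Initial logits (default uniform policy).
#' @return List with `theta`, and `log` (a `data.frame` with columns
#'   `iteration`, `J`, `grad_norm`; row `iteration = 0` holds the initial
#'   exact value).
#' @export
train_policy <- function(mdp, rl, seed = 0, theta0 = policy_init(mdp)) {
  theta <- theta0
  log_rows <- list(data.frame(iteration = 0L,
                              J = exact_policy_value(mdp, theta, rl$horizon),
                              grad_norm = NA_real_))
  base_seed <- substream_seed(seed, "training")
  if (rl$n_iterations > 0) {
    for (k in seq_len(rl$n_iterations)) {
      eps <- with_seed((base_seed + k) %% 2147483647, {
        lapply(seq_len(rl$n_episodes), function(i) {
          rollout_impl(mdp, theta, rl$horizon, mdp$start_state)
        })
      })
      step <- policy_gradient_step(theta, eps, mdp, rl$eta_lr)
      theta <- step$theta
      log_rows[[k + 1L]] <- data.frame(
        iteration = k,
        J = exact_policy_value(mdp, theta, rl$horizon),
        grad_norm = sqrt(sum(step$gradient^2))
      )
    }
  }
  list(theta = theta, log = do.call(rbind, log_rows))
}

#' TD(0) welfare-value table
#'
#' @param mdp [mdp_spec()].
#' @param td_step Step size in `[0, 1]` (0 freezes the estimates).
#' @param init Initial value estimate for every state.
#' @return An object of class `value_table` with elements `w` (per-state
#'   estimates) and `td_step`.
#' @export
value_table <- function(mdp, td_step = 0.1, init = 0) {
  check_number(td_step, "td_step", lower = 0, upper = 1)
  structure(list(w = rep(init, mdp$n_states), td_step = td_step,
                 n_states = mdp$n_states),
            class = "value_table")
}

#' One TD(0) welfare-value update
#'
#' \eqn{W(s) \leftarrow W(s) + \alpha (r + \gamma W(s') - W(s))} — the
#' standard temporal-difference reading of the recursive welfare update,
#' with the bootstrapped next-state value on the right-hand side.
#'
#' @param values [value_table()].
#' @param s,s_next State indices.
#' @param r Observed reward.
#' @param gamma_rl Discount factor.
#' @return Updated [value_table()].
#' @export
td_welfare_update <- function(values, s, r, s_next, gamma_rl) {
  stopifnot(inherits(values, "value_table"))
  if (s < 1L || s > values$n_states || s_next < 1L ||
      s_next > values$n_states) {
    stop("state index off the lattice", call. = FALSE)
  }
  values$w[s] <- values$w[s] +
    values$td_step * (r + gamma_rl * values$w[s_next] - values$w[s])
  values
}

#' Build the subsidy/tax decision process from a scenario configuration
#'
#' The reward of a lattice point `(S, T)` is the social welfare at the
#' static market equilibrium induced by the first-order conditions with
#' policy in place: consumers equate marginal utility to `p - T` and
#' providers marginal cost to `p - S` (taken literally from the model's
#' optimality conditions), the price clearing the market found by
#' bisection.
#'
#' @param config [scenario_config()].
#' @return An [mdp_spec()] over `config$rl$s_grid` x `config$rl$t_grid`.
#' @export
mdp_from_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  gp <- config$government
  reward_fn <- function(subsidy, tax) {
    dem <- function(p) {
      sum(vapply(config$consumers, function(cp) {
        pmax(0, (cp$a - (p - tax)) / cp$b)
      }, numeric(1)))
    }
    sup <- function(p) {
      sum(vapply(config$providers, function(pp) {
        pmax(0, (p - subsidy - pp$c1) / (2 * pp$c2))
      }, numeric(1)))
    }
    a_max <- max(vapply(config$consumers, function(cp) cp$a, numeric(1)))
    hi <- a_max + abs(tax) + abs(subsidy) +
      max(vapply(config$providers, function(pp) abs(pp$c1), numeric(1))) + 10
    p_eq <- market_clearing_price(dem, sup, c(0, hi), tol = 1e-9)
    qs <- vapply(config$consumers, function(cp) {
      pmax(0, (cp$a - (p_eq - tax)) / cp$b)
    }, numeric(1))
    qj <- vapply(config$providers, function(pp) {
      pmax(0, (p_eq - subsidy - pp$c1) / (2 * pp$c2))
    }, numeric(1))
    utils_ <- mapply(function(cp, q) {
      utility(q, cp$income - p_eq * q, cp)
    }, config$consumers, qs)
    costs <- mapply(function(pp, q) provider_cost(q, pp),
                    config$providers, qj)
    social_welfare(utils_, costs, health_benefit(qs, gp), gp)
  }
  mdp_spec(config$rl$s_grid, config$rl$t_grid, reward_fn,
           gamma_rl = config$rl$gamma_rl)
}

#' Export learned policy and value table as JSON
#'
#' @param theta Logit matrix.
#' @param path Destination JSON path.
#' @param values Optional [value_table()].
#' @return `path`, invisibly.
#' @export
write_policy_json <- function(theta, path, values = NULL) {
  out <- list(theta = unclass(as.data.frame(theta)),
              n_states = nrow(theta), n_actions = ncol(theta))
  if (!is.null(values)) out$w_estimates <- values$w
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
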