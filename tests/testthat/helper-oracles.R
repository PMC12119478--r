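# Independent oracles used by the tests. Deliberately written without
# calling the package functions they check.

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Exact expected discounted return by full enumeration of the episode
# tree (deterministic transitions): recursive expectation over all
# action sequences.
oracle_exact_J <- function(mdp, theta, horizon, start = mdp$start_state) {
  recurse <- function(s, h) {
    if (h == 0L) return(0)
    p <- oracle_softmax(theta[s, ])
    tot <- 0
    for (a in seq_len(mdp$n_actions)) {
      s2 <- mdp$next_state[s, a]
      tot <- tot + p[a] * (mdp$rewards[s2] + mdp$gamma_rl * recurse(s2, h - 1L))
    }
    tot
  }
  recurse(start, as.integer(horizon))
}

# Central finite differences of oracle_exact_J in every logit component.
oracle_fd_gradient <- function(mdp, theta, horizon, h = 1e-5) {
  g <- matrix(0, nrow(theta), ncol(theta))
  for (s in seq_len(nrow(theta))) {
    for (a in seq_len(ncol(theta))) {
      tp <- theta; tp[s, a] <- tp[s, a] + h
      tm <- theta; tm[s, a] <- tm[s, a] - h
      g[s, a] <- (oracle_exact_J(mdp, tp, horizon) -
                    oracle_exact_J(mdp, tm, horizon)) / (2 * h)
    }
  }
  g
}

# Per-episode likelihood-ratio contribution (score times advantage),
# recomputed independently; used to estimate Monte-Carlo standard errors
# of the gradient components.
oracle_episode_grad <- function(ep, theta, advantage) {
  g <- matrix(0, nrow(theta), ncol(theta))
  for (t in seq_along(ep$actions)) {
    s <- ep$states[t]
    p <- oracle_softmax(theta[s, ])
    g[s, ] <- g[s, ] - p
    g[s, ep$actions[t]] <- g[s, ep$actions[t]] + 1
  }
  g * advantage
}

oracle_episode_return <- function(ep, gamma) {
  sum(gamma^(seq_along(ep$rewards) - 1) * ep$rewards)
}

# Exhaustive grid search for the incentive allocation problem:
# enumerates every feasible allocation on the grid (box and threshold
# feasibility per consumer, total budget) and returns the best discrete
# objective value (summed left-endpoint marginal utility per step).
oracle_allocate <- function(mu_fns, prev, ip) {
  n <- length(mu_fns)
  lower <- pmax(0, prev - ip$delta_max)
  upper <- prev + ip$delta_max
  per_consumer <- lapply(seq_len(n), function(i) {
    levels <- list(list(x = lower[i], gain = 0))
    x <- lower[i]
    gain <- 0
    repeat {
      mu_here <- mu_fns[[i]](x)
      if (x + ip$grid > upper[i] + 1e-12) break
      if (mu_here < ip$lambda_min - 1e-12) break
      gain <- gain + mu_here * ip$grid
      x <- x + ip$grid
      levels[[length(levels) + 1L]] <- list(x = x, gain = gain)
    }
    levels
  })
  best <- -Inf
  recurse <- function(i, spent, gain) {
    if (spent > ip$b_max + 1e-9) return()
    if (i > n) {
      if (gain > best) best <<- gain
      return()
    }
    for (lv in per_consumer[[i]]) {
      recurse(i + 1L, spent + lv$x, gain + lv$gain)
    }
  }
  recurse(1L, 0, 0)
  best
}

# Closed-form solution of the premium adjustment ODE with constant
# expected claims.
oracle_premium_path <- function(p0, expected, gamma, times) {
  expected + (p0 - expected) * exp(-gamma * times)
}

# The toy two-state decision process used by the RL tests: two subsidy
# levels, one tax level; reward 1 for sitting at the high-subsidy state.
toy_mdp <- function(gamma = 0.9) {
  mdp_spec(s_grid = c(0, 1), t_grid = 0,
           reward_fn = function(s, t) as.numeric(s > 0),
           gamma_rl = gamma)
}

# A frozen-dynamics configuration: every adjustment speed zero.
frozen_config <- function() {
  scenario_config(
    horizon = 1, step = 0.1,
    consumers = list(consumer_params(a = 10, b = 2, c = 1, income = 1000),
                     consumer_params(a = 8, b = 2, c = 1, income = 800)),
    providers = list(provider_params(c0 = 0, c1 = 1, c2 = 0.5)),
    pricing = pricing_params(kappa = 0, eta_stabilize = 0, p_star = 4,
                             p0 = 4),
    insurance = insurance_params(p0 = 80, gamma_premium = 0),
    government = government_params(beta_s = 0, delta_t = 0),
    incentive = incentive_params(b_max = 1, delta_max = 5, grid = 0.25),
    seed = 1
  )
}
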