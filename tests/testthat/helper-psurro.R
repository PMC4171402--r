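expit <- function(x) 1 / (1 + exp(-x))

# Canonical 5-level constant-control configuration used across the suite:
# uniform s1, flat control risk 0.3, treated risk declining log-odds
# linearly in s1 (slope -0.5). The diagonal stratum s1 = s0 = 0 has zero
# risk difference by construction, so the truth satisfies average causal
# necessity and, off the diagonal, sufficiency.
toy5_config <- function(n, seed = 1L, risk0 = 0.3,
                        risk1 = expit(qlogis(0.3) - 0.5 * 0:4), ...) {
  sim_config(n = n, k = 5, mode = "sa2", c_value = 0,
             s1_pmf = rep(0.2, 5), risk0 = risk0, risk1 = risk1,
             seed = seed, ...)
}

toy5_truth_r1 <- expit(qlogis(0.3) - 0.5 * 0:4)

# Simulate, mask and (optionally) close out a configured trial in one step.
simulate_observed <- function(config, assign_p = 0.5, closeout = FALSE) {
  cf <- simulate_counterfactual_trial(config)
  obs <- mask_to_observed(cf, assign_p, seed = config$seed + 1000L)
  if (closeout) obs <- simulate_closeout(cf, obs, config)
  attr(obs, "counterfactual") <- cf
  obs
}

# Independent brute-force oracle for the K = 3 bound polytope: enumerate
# the simplex on a fine grid and extremize each coordinate subject to the
# same constraints the linear programs impose.
brute_force_p_bounds <- function(r1, f, p_y0, f_y1_1 = NULL,
                                 monotone = FALSE, stochastic = FALSE,
                                 step = 0.01) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = g, p2 = g)
  grid$p3 <- 1 - grid$p1 - grid$p2
  grid <- grid[grid$p3 >= -1e-12, , drop = FALSE]
  P <- as.matrix(grid)
  keep <- rep(TRUE, nrow(P))
  ub <- pmin(1, f / p_y0)
  for (j in 1:3) keep <- keep & P[, j] <= ub[j] + 1e-9
  if (monotone) {
    lb <- r1 * f / p_y0
    for (j in 1:3) keep <- keep & P[, j] >= lb[j] - 1e-9
  }
  if (stochastic) {
    cdf_ref <- cumsum(f_y1_1)
    keep <- keep & P[, 1] <= cdf_ref[1] + 1e-9 &
      (P[, 1] + P[, 2]) <= cdf_ref[2] + 1e-9
  }
  P <- P[keep, , drop = FALSE]
  if (nrow(P) == 0) return(NULL)
  list(p_min = apply(P, 2, min), p_max = apply(P, 2, max))
}

# Stack two observed trials (re-deriving subject ids).
rbind_observed <- function(a, b) {
  d <- rbind(as.data.frame(a), as.data.frame(b))
  observed_trial(z = d$z, s = d$s, y = d$y, a_tau = d$a_tau,
                 closeout_s = d$closeout_s)
}

# Random finite counterfactual table on a random support of size K <= 5,
# with arbitrary joint pmf and risk maps: the fixture for the
# Bayes-identity property.
random_counterfactual <- function(n = 1000, seed = 1) {
  set.seed(seed)
  K <- sample(2:5, 1)
  pmf <- matrix(stats::rexp(K * K), K, K)
  pmf <- pmf / sum(pmf)
  cfg <- sim_config(n = n, k = K, mode = "grid", joint_s = pmf,
                    risk0 = matrix(stats::runif(K * K), K, K),
                    risk1 = matrix(stats::runif(K * K), K, K),
                    seed = seed)
  simulate_counterfactual_trial(cfg, seed = seed + 1)
}
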