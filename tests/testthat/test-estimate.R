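test_that("marginal risks are the arm-specific sample means", {
  trial <- observed_trial(z = rep(c(1, 0), c(1000, 1000)),
                          s = rep(1, 2000),
                          y = c(rep(1, 160), rep(0, 840),
                                rep(1, 300), rep(0, 700)))
  mr <- estimate_marginal_risks(trial)
  expect_equal(mr$p1, 0.16)
  expect_equal(mr$p0, 0.30)
  expect_equal(mr$n1, 1000)

  none <- observed_trial(z = rep(1, 5), s = 1:5, y = rep(0, 5))
  expect_error(estimate_marginal_risks(none), "arm 0 is empty")
  trial0 <- observed_trial(z = c(0, 1), s = c(1, 1), y = c(0, 0))
  expect_equal(estimate_marginal_risks(trial0)$p1, 0)
})

test_that("the treated risk curve is identified from the treated arm", {
  cfg <- toy5_config(200000, seed = 1)
  obs <- simulate_observed(cfg)
  surf <- estimate_r1_under_sa2(obs, cfg$support)
  expect_lt(max(abs(surf$r1 - toy5_truth_r1)), 0.01)
  expect_equal(attr(surf, "conditioning"), "sa1_sa2")
  # marginal placebo risk from the same masked data
  expect_lt(abs(estimate_marginal_risks(obs)$p0 - 0.3), 0.005)
})

test_that("a deterministic outcome gives a 0/1 risk curve", {
  set.seed(4)
  s <- sample(0:4, 400, replace = TRUE)
  trial <- observed_trial(z = rep(1, 400), s = s, y = as.integer(s >= 3))
  trial <- rbind_observed(trial, observed_trial(z = rep(0, 50),
                                                s = rep(0, 50),
                                                y = rbinom(50, 1, 0.2)))
  surf <- estimate_r1_under_sa2(trial, biomarker_support(0:4))
  expect_equal(surf$r1, c(0, 0, 0, 1, 1))
})

test_that("undefined-biomarker handling follows the cap-and-discard policy", {
  cfg <- toy5_config(50000, seed = 2,
                     a_model = list(p0 = c(0.02, 0.02), p1 = c(0.02, 0.02)))
  obs <- simulate_observed(cfg)
  expect_warning(surf <- estimate_r1_under_sa2(obs, cfg$support),
                 "discarding")
  expect_lt(max(abs(surf$r1 - toy5_truth_r1)), 0.02)

  cfg_bad <- toy5_config(20000, seed = 3,
                         a_model = list(p0 = c(0.2, 0.2), p1 = c(0.2, 0.2)))
  obs_bad <- simulate_observed(cfg_bad)
  expect_error(estimate_r1_under_sa2(obs_bad, cfg_bad$support),
               "exceeds the cap")
})

test_that("the tilt family anchors at no-selection and flags infeasible tilts", {
  # exact counts: 5 strata x 40 treated subjects, control arm half events
  s1 <- rep(0:4, each = 40)
  y1 <- rep(rep(c(1, 0), c(10, 30)), 5)
  trial <- rbind_observed(
    observed_trial(z = rep(1, 200), s = s1, y = y1),
    observed_trial(z = rep(0, 200), s = rep(0, 200),
                   y = rep(c(1, 0), each = 100)))
  sup <- biomarker_support(0:4)
  fam <- sensitivity_r0(trial, sup, beta_grid = c(0, 3))
  at0 <- fam[fam$beta == 0, ]
  # beta = 0: f(s1 | Y0 = 1) = f(s1) and r0 = P(Y0 = 1) on every stratum
  expect_equal(at0$f_y0_1, rep(0.2, 5))
  expect_equal(at0$r0, rep(0.5, 5))
  expect_true(all(at0$feasible))
  # a strong tilt concentrates mass beyond the mixture cap f(s)/P(Y0=1)
  at3 <- fam[fam$beta == 3, ]
  expect_gt(at3$f_y0_1[5], 0.2 / 0.5)
  expect_false(any(at3$feasible))
  # every implied pmf sums to 1 and risks are probabilities where feasible
  sums <- tapply(fam$f_y0_1, fam$beta, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(fam$r0 >= 0))
})

test_that("no-selection recovers the truth when cases mirror the population", {
  # toy5 control risk is flat in s1, so f(s1 | Y0 = 1) = f(s1): beta = 0
  cfg <- toy5_config(200000, seed = 5)
  obs <- simulate_observed(cfg)
  fam <- sensitivity_r0(obs, cfg$support, beta_grid = c(-1, 0, 1))
  at0 <- fam[fam$beta == 0, ]
  true_rd <- toy5_truth_r1 - 0.3
  expect_lt(max(abs(at0$rd - true_rd)), 0.01)
})

test_that("the feasible tilt set is an interval in beta", {
  for (seed in 1:10) {
    set.seed(seed)
    risk0 <- runif(5, 0.05, 0.6)
    cfg <- toy5_config(20000, seed = seed, risk0 = risk0,
                       risk1 = runif(5, 0.05, 0.5))
    obs <- simulate_observed(cfg)
    fam <- sensitivity_r0(obs, cfg$support,
                          beta_grid = seq(-4, 4, by = 0.5))
    feas <- tapply(fam$feasible, fam$beta, all)
    runs <- rle(as.vector(feas))$values
    expect_lte(sum(runs), 3)           # FALSE*, TRUE*, FALSE*: one block
    expect_lte(sum(runs == TRUE), 1)
  }
})

test_that("user-supplied scenario pmfs are accepted in place of the tilt", {
  cfg <- toy5_config(20000, seed = 6)
  obs <- simulate_observed(cfg)
  fam <- sensitivity_r0(obs, cfg$support,
                        pmf_y0_1 = list(rep(0.2, 5), c(0.1, 0.15, 0.2, 0.25, 0.3)))
  expect_equal(sort(unique(fam$beta)), c(1, 2))
  expect_equal(fam$f_y0_1[fam$beta == 2], c(0.1, 0.15, 0.2, 0.25, 0.3))
})

test_that("crossover data identify the full surface exactly", {
  cf <- random_counterfactual(n = 800, seed = 31)
  paired <- data.frame(s0 = cf$s0, y0 = cf$y0, s1 = cf$s1, y1 = cf$y1)
  surf <- estimate_from_crossover(paired)
  oracle <- oracle_risks(cf)
  expect_equal(surf$r0, oracle$r0)
  expect_equal(surf$r1, oracle$r1)

  expect_error(estimate_from_crossover(data.frame(s0 = c(1, NA), y0 = c(0, 0),
                                                  s1 = c(1, 2), y1 = c(0, 1))),
               "unpaired")
  single <- estimate_from_crossover(data.frame(s0 = 1, y0 = 1, s1 = 2, y1 = 0))
  expect_equal(nrow(single), 1)
  expect_equal(single$r0, 1)
  expect_equal(single$r1, 0)
})

test_that("bootstrap intervals are reproducible and degenerate for constants", {
  cfg <- toy5_config(4000, seed = 7)
  obs <- simulate_observed(cfg)
  const <- function(trial) c(theta = 0.5)
  ci <- bootstrap_ci(const, obs, b = 100, seed = 1)
  expect_equal(ci$lo, 0.5)
  expect_equal(ci$hi, 0.5)

  est <- function(trial) {
    s <- suppressWarnings(estimate_r1_under_sa2(trial, cfg$support))
    stats::setNames(s$r1, s$s1)
  }
  ci1 <- bootstrap_ci(est, obs, b = 120, seed = 42)
  ci2 <- bootstrap_ci(est, obs, b = 120, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lo <= ci1$estimate & ci1$estimate <= ci1$hi))
  expect_error(bootstrap_ci(est, obs, b = 10, seed = 1), "at least 100")
})
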