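test_that("identical config and seed give identical tables", {
  cfg <- toy5_config(5000, seed = 9, monotone_y = TRUE,
                     a_model = list(p0 = c(0.02, 0.05), p1 = c(0.02, 0.05)))
  t1 <- simulate_counterfactual_trial(cfg)
  t2 <- simulate_counterfactual_trial(cfg)
  expect_identical(t1, t2)
  o1 <- mask_to_observed(t1, 0.5, seed = 4)
  o2 <- mask_to_observed(t2, 0.5, seed = 4)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
})

test_that("the drawn biomarker law matches the configured pmf", {
  cfg <- toy5_config(200000, seed = 1)
  cf <- simulate_counterfactual_trial(cfg)
  emp <- table(cf$s1) / nrow(cf)
  expect_true(all(abs(emp - 0.2) < 0.005))
  expect_true(all(cf$s0 == 0))

  # grid mode: empirical joint pmf converges in sup norm
  set.seed(2)
  K <- 4
  pmf <- matrix(rexp(K * K), K, K); pmf <- pmf / sum(pmf)
  gcfg <- sim_config(n = 1e5, k = K, mode = "grid", joint_s = pmf,
                     risk0 = 0.2, risk1 = 0.1, seed = 3)
  g <- simulate_counterfactual_trial(gcfg)
  emp2 <- table(factor(g$s0, 0:3), factor(g$s1, 0:3)) / nrow(g)
  expect_lt(max(abs(emp2 - pmf)), 3 * sqrt(log(K) / 1e5))
})

test_that("comonotone coupling never produces a harmed subject", {
  cfg <- toy5_config(50000, seed = 5, monotone_y = TRUE)
  cf <- simulate_counterfactual_trial(cfg)
  expect_equal(sum(cf$y0 == 0 & cf$y1 == 1), 0)
  # and the coupling is pathwise, not merely marginal
  expect_true(all(cf$y1 <= cf$y0))
})

test_that("outcome-linked undefinedness hits its configured rate", {
  cfg <- toy5_config(100000, seed = 6,
                     a_model = list(p0 = c(0.2, 0.2), p1 = c(0.2, 0.2)))
  cf <- simulate_counterfactual_trial(cfg)
  expect_lt(abs(mean(cf$a0 == 0) - 0.2), 0.01)
  expect_lt(abs(mean(cf$a1 == 0) - 0.2), 0.01)
  expect_true(all(is.na(cf$s0[cf$a0 == 0])))
  expect_true(all(!is.na(cf$s0[cf$a0 == 1])))
})

test_that("masking realizes consistency and randomization", {
  cfg <- toy5_config(1000, seed = 2)
  cf <- simulate_counterfactual_trial(cfg)
  all1 <- mask_to_observed(cf, assign_p = 1 - 1e-12, seed = 1)
  expect_true(all(all1$z == 1))
  expect_identical(all1$s, cf$s1)
  expect_identical(as.integer(all1$y), cf$y1)

  cfg2 <- toy5_config(100000, seed = 3)
  obs <- simulate_observed(cfg2)
  expect_lt(abs(mean(obs$z) - 0.5), 0.005)
  # per-row consistency with the parent table
  cf2 <- attr(obs, "counterfactual")
  expect_identical(obs$s, ifelse(obs$z == 1, cf2$s1, cf2$s0))
  expect_identical(as.integer(obs$y), as.integer(ifelse(obs$z == 1, cf2$y1, cf2$y0)))
})

test_that("closeout reproduces s1 exactly under time constancy", {
  cfg <- toy5_config(20000, seed = 8, closeout_delta = 0)
  cf <- simulate_counterfactual_trial(cfg)
  obs <- mask_to_observed(cf, 0.5, seed = 9)
  obs <- simulate_closeout(cf, obs, cfg)
  elig <- obs$z == 0 & obs$y == 0
  expect_identical(obs$closeout_s[elig], cf$s1[elig])
  expect_true(all(is.na(obs$closeout_s[!elig])))
})

test_that("a closeout level shift moves the distribution as prescribed", {
  cfg <- toy5_config(100000, seed = 10, closeout_delta = 1)
  cf <- simulate_counterfactual_trial(cfg)
  obs <- mask_to_observed(cf, 0.5, seed = 11)
  obs <- simulate_closeout(cf, obs, cfg)
  elig <- obs$z == 0 & obs$y == 0
  # shifted-by-one with top level absorbing, against the parent s1
  expected <- pmin(cf$s1[elig] + 1, 4)
  expect_identical(obs$closeout_s[elig], expected)
})

test_that("an all-events placebo arm yields an empty closeout with warning", {
  cfg <- toy5_config(200, seed = 12, risk0 = 1, risk1 = 0.5)
  cf <- simulate_counterfactual_trial(cfg)
  obs <- mask_to_observed(cf, 0.5, seed = 13)
  expect_warning(obs <- simulate_closeout(cf, obs, cfg), "empty")
  expect_true(all(is.na(obs$closeout_s)))
})

test_that("closed-form truth matches the configured risk maps", {
  cfg <- toy5_config(1000, seed = 1)
  tr <- true_estimands(cfg)
  expect_equal(tr$r1[tr$s1 == 0], 0.3)
  expect_equal(tr$r1[tr$s1 == 4], expit(qlogis(0.3) - 2.0))
  rd <- risk_contrasts(tr, "RD")
  expect_equal(rd$value[rd$s1 == 0], 0)        # ACN holds at truth
  # null treatment: flat surface
  null_cfg <- toy5_config(1000, risk1 = 0.3)
  expect_true(all(risk_contrasts(true_estimands(null_cfg), "RD")$value == 0))
})

test_that("truth agrees with the oracle on a large simulated table", {
  cfg <- toy5_config(1e6, seed = 14)
  cf <- simulate_counterfactual_trial(cfg)
  surf <- oracle_risks(cf)
  tr <- true_estimands(cfg)
  expect_equal(surf$s1, tr$s1)
  expect_lt(max(abs(surf$r0 - tr$r0)), 0.005)
  expect_lt(max(abs(surf$r1 - tr$r1)), 0.005)
})

test_that("truth conditions on a defined biomarker when undefinedness is outcome-linked", {
  # undefined biomarker concentrated among cases shifts the conditioned
  # risks downward relative to the unconditional risk maps
  cfg <- toy5_config(1000, seed = 15,
                     a_model = list(p0 = c(0, 0.5), p1 = c(0, 0.5)))
  tr <- true_estimands(cfg)
  expect_true(all(tr$r0 < 0.3))
  expect_equal(attr(tr, "conditioning"), "general_A11")
  # and a matching large simulation agrees
  cfg_big <- toy5_config(4e5, seed = 16,
                         a_model = list(p0 = c(0, 0.5), p1 = c(0, 0.5)))
  surf <- oracle_risks(simulate_counterfactual_trial(cfg_big))
  expect_lt(max(abs(surf$r0 - tr$r0)), 0.01)
  expect_lt(max(abs(surf$r1 - tr$r1)), 0.01)
})

test_that("invalid configurations fail before any draw", {
  expect_error(toy5_config(100, risk1 = 1.2), "\\[0, 1\\]")
  expect_error(toy5_config(100, monotone_y = TRUE, risk1 = 0.4),
               "monotone_y")
  expect_error(sim_config(n = 10, k = 3, mode = "sa2",
                          s1_pmf = c(0.5, 0.5, 0.1), risk0 = 0.1, risk1 = 0.1),
               "summing to 1")
  expect_error(toy5_config(100, assign_p = 1), "assign_p")
})
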