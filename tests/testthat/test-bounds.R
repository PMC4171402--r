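test_that("the monotonicity implication test matches the textbook example", {
  trial <- observed_trial(z = rep(c(1, 0), c(1000, 1000)), s = rep(1, 2000),
                          y = c(rep(1, 160), rep(0, 840),
                                rep(1, 300), rep(0, 700)))
  mt <- test_monotonicity_implication(trial)
  expect_equal(mt$difference, -0.14)
  expect_false(mt$reject)
  # oracle: pooled one-sided normal approximation computed by hand
  pp <- 460 / 2000
  z <- (-0.14) / sqrt(pp * (1 - pp) * (2 / 1000))
  expect_equal(mt$p_value, 1 - pnorm(z))
})

test_that("identical arms give no evidence against monotonicity", {
  trial <- observed_trial(z = rep(c(1, 0), c(500, 500)), s = rep(1, 1000),
                          y = rep(rep(c(1, 0), c(150, 350)), 2))
  expect_gte(test_monotonicity_implication(trial)$p_value, 0.5)
})

test_that("small event counts switch to the exact test", {
  trial <- observed_trial(z = rep(c(1, 0), c(100, 100)), s = rep(1, 200),
                          y = c(rep(1, 10), rep(0, 90), rep(1, 3), rep(0, 97)))
  mt <- test_monotonicity_implication(trial)
  expect_equal(mt$method, "fisher_exact")
  expect_equal(mt$p_value,
               fisher.test(rbind(c(10, 90), c(3, 97)),
                           alternative = "greater")$p.value)
})

test_that("linear-programming bounds agree with brute force on 3-level supports", {
  set.seed(50)
  for (rep in 1:5) {
    risk0 <- runif(3, 0.1, 0.5)
    risk1 <- runif(3, 0.05, 0.4)
    cfg <- sim_config(n = 30000, k = 3, mode = "sa2",
                      s1_pmf = as.vector(prop.table(runif(3, 0.5, 1.5))),
                      risk0 = risk0, risk1 = risk1, seed = 50 + rep)
    obs <- simulate_observed(cfg)
    sup <- cfg$support
    r1s <- estimate_r1_under_sa2(obs, sup)
    f <- attr(r1s, "f_s1")
    p_y0 <- mean(obs$y[obs$z == 0])
    d1 <- obs[obs$z == 1, ]
    f_y1_1 <- tabulate(match(d1$s[d1$y == 1], sup$levels), 3) /
      max(1, sum(d1$y))
    r1 <- r1s$r1
    for (cons in list(character(0), "individual_monotone_y",
                      c("individual_monotone_y", "stochastic_order_s1"))) {
      b <- partial_id_bounds(obs, sup, constraints = cons)
      bf <- brute_force_p_bounds(r1, f, p_y0, f_y1_1,
                                 monotone = "individual_monotone_y" %in% cons,
                                 stochastic = "stochastic_order_s1" %in% cons,
                                 step = 0.0025)
      if (is.null(bf)) {
        # grid search found the polytope empty: the LP must agree
        expect_false(all(b$feasible))
      } else {
        expect_true(all(b$feasible))
        rd_lo_bf <- r1 - bf$p_max * p_y0 / f
        rd_hi_bf <- r1 - bf$p_min * p_y0 / f
        expect_lt(max(abs(b$rd_lo - rd_lo_bf)), 0.02)
        expect_lt(max(abs(b$rd_hi - rd_hi_bf)), 0.02)
      }
    }
  }
})

test_that("adding a constraint never widens any stratum interval", {
  cfg <- toy5_config(50000, seed = 60, risk0 = 0.1 + 0.05 * 0:4,
                     monotone_y = TRUE,
                     risk1 = expit(qlogis(0.1 + 0.05 * 0:4) - 0.5))
  obs <- simulate_observed(cfg)
  b0 <- partial_id_bounds(obs, cfg$support)
  b1 <- partial_id_bounds(obs, cfg$support, "individual_monotone_y")
  b2 <- partial_id_bounds(obs, cfg$support,
                          c("individual_monotone_y", "stochastic_order_s1"))
  expect_true(all(b1$rd_lo >= b0$rd_lo - 1e-9))
  expect_true(all(b1$rd_hi <= b0$rd_hi + 1e-9))
  expect_true(all(b2$rd_lo >= b1$rd_lo - 1e-9))
  expect_true(all(b2$rd_hi <= b1$rd_hi + 1e-9))
})

test_that("valid bounds contain the population truth", {
  # generating model satisfies outcome monotonicity pathwise, so bounds
  # built from that constraint must cover the true risk difference
  set.seed(70)
  for (rep in 1:20) {
    risk0 <- runif(5, 0.15, 0.5)
    cfg <- toy5_config(50000, seed = 70 + rep, risk0 = risk0,
                       risk1 = risk0 * runif(5, 0.3, 0.9),
                       monotone_y = TRUE)
    obs <- simulate_observed(cfg)
    b <- partial_id_bounds(obs, cfg$support, "individual_monotone_y")
    true_rd <- risk_contrasts(true_estimands(cfg), "RD")$value
    slack <- 0.02  # sampling noise in the plugged-in inputs
    expect_true(all(true_rd >= b$rd_lo - slack & true_rd <= b$rd_hi + slack))
  }
})

test_that("no control-arm events collapses bounds to the identified point", {
  trial <- observed_trial(z = rep(c(1, 0), c(200, 100)),
                          s = c(rep(0:4, 40), rep(0, 100)),
                          y = c(rbinom(200, 1, 0.3), rep(0, 100)))
  b <- partial_id_bounds(trial, biomarker_support(0:4))
  expect_equal(b$rd_lo, b$rd_hi)
  expect_equal(b$rd_lo, b$r1)
})

test_that("an equality-inducing constraint set pins the pmf to a point", {
  # all-events arms: P(Y0=1) = 1 and r1 = 1 force the monotone lower
  # bound to meet the mixture upper bound coordinate-wise
  s1 <- rep(0:1, 50)
  trial <- observed_trial(z = rep(c(1, 0), c(100, 100)),
                          s = c(s1, rep(0, 100)),
                          y = rep(1, 200))
  b <- partial_id_bounds(trial, biomarker_support(0:1),
                         "individual_monotone_y")
  expect_true(all(b$feasible))
  expect_equal(b$rd_lo, b$rd_hi)
})

test_that("an infeasible constraint set is reported, never silently relaxed", {
  # monotone_y demands more mass than mixture feasibility allows when
  # r1 = 1 everywhere but P(Y0 = 1) is small
  trial <- observed_trial(z = rep(c(1, 0), c(100, 100)),
                          s = c(rep(0:1, 50), rep(0, 100)),
                          y = c(rep(1, 100), rep(1, 10), rep(0, 90)))
  b <- partial_id_bounds(trial, biomarker_support(0:1),
                         "individual_monotone_y")
  expect_false(all(b$feasible))
  expect_match(attr(b, "violated"), "monotone")
})

test_that("a monotonicity violation is detected with high power", {
  # arm risks 0.4 under treatment vs 0.3 under control at n = 1000/arm
  rejections <- vapply(1:200, function(i) {
    cfg <- sim_config(n = 2000, k = 2, mode = "sa2", s1_pmf = c(0.5, 0.5),
                      risk0 = 0.3, risk1 = 0.4, seed = 7000 + i)
    obs <- simulate_observed(cfg)
    test_monotonicity_implication(obs)$reject
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
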