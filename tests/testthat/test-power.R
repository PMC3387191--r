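test_that("minimum detectable effect behaves like the closed form", {
  d1 <- required_effect_size(500, 500)
  # doubling both groups divides d by sqrt(2)
  expect_equal(required_effect_size(1000, 1000), d1 / sqrt(2))
  # monotone decreasing in n
  expect_lt(required_effect_size(2000, 2000), d1)
  # t refinement differs from the normal approximation by < 0.001 here
  expect_equal(required_effect_size(396, 1046, method = "t"),
               required_effect_size(396, 1046), tolerance = 1e-2)
  # more stringent alpha or power demands a larger effect
  expect_gt(required_effect_size(500, 500, alpha = 0.01), d1)
  expect_gt(required_effect_size(500, 500, power = 0.9), d1)
})

test_that("two-sample power matches power.t.test at 1:1 allocation", {
  p_pkg <- two_sample_power(0.232, 293, 293)
  p_ref <- power.t.test(n = 293, delta = 0.232)$power
  # power.t.test drops the far rejection tail (~1e-6 here)
  expect_equal(p_pkg, p_ref, tolerance = 1e-5)
})

test_that("minimal n inverts the power curve: 293 per arm at d = 0.232", {
  res <- minimal_n_for_effect(0.232)
  expect_equal(unname(res["n1"]), 293)
  expect_equal(unname(res["n_total"]), 586)
  # agrees with power.t.test up to its fractional n
  expect_equal(unname(res["n1"]),
               ceiling(power.t.test(delta = 0.232, power = 0.8)$n))
  # round trip: n from the d required at (n, n) recovers ~2n
  for (n in c(150, 400, 900)) {
    d <- required_effect_size(n, n, method = "t")
    expect_lte(abs(minimal_n_for_effect(d)[["n_total"]] - 2 * n), 2)
  }
  # quartering: doubling d roughly quarters total n
  n_small <- minimal_n_for_effect(0.4)[["n_total"]]
  n_large <- minimal_n_for_effect(0.2)[["n_total"]]
  expect_equal(n_large / n_small, 4, tolerance = 0.05)
  # unequal allocation costs total sample size
  expect_gt(minimal_n_for_effect(0.25, allocation_ratio = 3)[["n_total"]],
            minimal_n_for_effect(0.25)[["n_total"]])
})

test_that("minimum detectable OR decreases with n and score SD", {
  base <- min_detectable_or(1440, score_sd = 2, baseline_prevalence = 0.28)
  expect_gt(base, 1)
  expect_lt(min_detectable_or(5000, 2, 0.28), base)
  expect_lt(min_detectable_or(1440, 4, 0.28), base)
  # a small subgroup needs a larger OR than the whole cohort
  expect_gt(min_detectable_or(456, 2, 0.28), base)
})

test_that("simulated logistic power at the minimum detectable OR is ~0.8", {
  set.seed(4711)
  n <- 1440; prev <- 0.28; sd_score <- 2
  or_min <- min_detectable_or(n, sd_score, prev)
  beta <- log(or_min)
  rej <- replicate(500, {
    x <- rnorm(n, 0, sd_score)
    y <- rbinom(n, 1, plogis(qlogis(prev) + beta * x))
    f <- glm(y ~ x, family = binomial())
    summary(f)$coefficients["x", "Pr(>|z|)"] < 0.05
  })
  expect_gte(mean(rej), 0.75)
  expect_lte(mean(rej), 0.85)
})

test_that("power table reports one row per configuration", {
  cfg <- data.frame(label = c("a", "b"), n1 = c(396, 140),
                    n2 = c(1046, 1302))
  pt <- power_table(cfg)
  expect_equal(nrow(pt), 2L)
  expect_true(all(pt$power_at_d_min > 0.79 & pt$power_at_d_min < 0.81))
})
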