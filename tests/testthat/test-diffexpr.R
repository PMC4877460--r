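test_that("CPM normalization scales to one million", {
  expect_equal(normalize_cpm(c(5, 15), 20), c(250000, 750000))
  expect_equal(sum(normalize_cpm(c(5, 15), 20)), 1e6)
  expect_equal(normalize_cpm(rep(0, 4), 100), rep(0, 4))
  set.seed(1)
  x <- rpois(50, 30)
  expect_equal(sum(normalize_cpm(x, 1234)), 1e6 * sum(x) / 1234)
  expect_error(normalize_cpm(c(1, 2), 0), class = "miRtrend_error")
})

test_that("the low-count filter removes only pairs low in both libraries", {
  expect_false(low_count_filter(3, 8))
  expect_true(low_count_filter(3, 12))
  expect_true(low_count_filter(11, 11))
  expect_false(low_count_filter(10, 10))   # strictly more than 10 to keep
  expect_equal(low_count_filter(c(3, 3, 11, 10), c(8, 12, 11, 10)),
               c(FALSE, TRUE, TRUE, FALSE))
  # strict per-library variant
  expect_false(low_count_filter(3, 12, mode = "both"))
  expect_true(low_count_filter(11, 12, mode = "both"))
})

test_that("ac_pvalue matches hand values and the summation oracle", {
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6), 1)
  expect_equal(ac_pvalue(0, 5, 1e6, 1e6), 0.0625)   # 2 * 2^-5
  # equal-library oracle agreement on a grid (full sweep in acceptance)
  for (x in c(0, 1, 5, 10, 30)) for (y in c(0, 2, 10, 40)) {
    expect_equal(ac_pvalue(x, y, 1e6, 1e6), ac_oracle(x, y, 1e6, 1e6),
                 tolerance = 1e-12)
  }
  # unequal library sizes
  expect_equal(ac_pvalue(10, 30, 5e5, 1.5e6), ac_oracle(10, 30, 5e5, 1.5e6),
               tolerance = 1e-12)
  expect_error(ac_pvalue(-1, 2, 1, 1), class = "miRtrend_error")
  expect_error(ac_pvalue(1, 2, 0, 1), class = "miRtrend_error")
})

test_that("ac_pvalue is symmetric and monotone in the tails", {
  xy <- expand.grid(x = 0:50, y = 0:50)
  p1 <- ac_pvalue(xy$x, xy$y, 1e6, 1e6)
  p2 <- ac_pvalue(xy$y, xy$x, 1e6, 1e6)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 <= 1))
  # fixed x: p non-increasing as y moves away from x in either direction
  for (x in c(0, 5, 15, 30)) {
    p_up <- ac_pvalue(x, x:120, 1e6, 1e6)
    expect_true(all(diff(p_up) <= 1e-12))
    p_dn <- ac_pvalue(x, x:0, 1e6, 1e6)
    expect_true(all(diff(p_dn) <= 1e-12))
  }
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.005, 0.04, 0.8)), c(0.015, 0.06, 0.8))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.1, 1.3)), class = "miRtrend_error")
})

test_that("de_call applies filter, FDR and fold gate in sequence", {
  cfg <- de_config()
  r1 <- de_call(100, 100, 1e6, 1e6, cfg)
  expect_false(r1$called)
  expect_equal(r1$direction, "none")

  r2 <- de_call(20, 400, 1e6, 1e6, cfg)
  expect_true(r2$called)
  expect_equal(r2$direction, "up")
  expect_equal(r2$fold_change, 401 / 21)

  r3 <- de_call(8, 9, 1e6, 1e6, cfg)
  expect_false(r3$kept)
  expect_false(r3$called)
  expect_true(is.na(r3$q_value))

  # down direction and the B-over-A convention
  r4 <- de_call(400, 20, 1e6, 1e6, cfg)
  expect_true(r4$called)
  expect_equal(r4$direction, "down")
  expect_equal(r4$fold_change, 21 / 401)

  expect_error(de_call(1:3, 1:2, 1e6, 1e6, cfg), class = "miRtrend_error")
})

test_that("planted strong effects are called with correct direction", {
  d <- simulation_design(n_mirnas = 200, n_gradient_up = 25,
                         n_gradient_down = 25, gradient_step = 4,
                         baseline_mean = 100, seed = 17)
  sim <- simulate_counts(d)
  de <- de_table(sim$counts, "normal", "tumor")
  up <- sim$truth$class == "up_gradient"
  down <- sim$truth$class == "down_gradient"
  expect_gte(mean(de$called[up] & de$direction[up] == "up"), 0.95)
  expect_gte(mean(de$called[down] & de$direction[down] == "down"), 0.95)
})

test_that("under the null the exact test is calibrated", {
  d <- simulation_design(n_mirnas = 2000, n_gradient_up = 0,
                         n_gradient_down = 0, baseline_mean = 100, seed = 9)
  sim <- simulate_counts(d)
  de <- de_table(sim$counts, "normal", "tumor")
  frac <- mean(de$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("de_config validates thresholds", {
  expect_error(de_config(q_threshold = 0), class = "miRtrend_error")
  expect_error(de_config(fc_threshold = 0.5), class = "miRtrend_error")
  expect_error(de_config(pseudocount_cpm = 0), class = "miRtrend_error")
})
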