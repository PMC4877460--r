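test_that("venn_partition performs a consistent disjoint partition", {
  v <- venn_partition(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$tumor_only, "a")
  expect_equal(v$adjacent_only, "d")
  expect_setequal(v$shared, c("b", "c"))

  same <- venn_partition(c("x", "y"), c("y", "x"))
  expect_length(same$tumor_only, 0)
  expect_length(same$adjacent_only, 0)
  expect_setequal(same$shared, c("x", "y"))

  # set sizes reported for the three-tissue study: |T| = 86, |A| = 50,
  # 25 shared -> 61 tumor-only and 25 adjacent-only
  ids <- sprintf("mir%03d", 1:111)
  set_t <- ids[1:86]
  set_a <- c(ids[62:86], ids[87:111])
  v2 <- venn_partition(set_t, set_a)
  expect_length(v2$shared, 25)
  expect_length(v2$tumor_only, 61)
  expect_length(v2$adjacent_only, 25)
  expect_equal(length(v2$tumor_only) + length(v2$shared), length(set_t))
  expect_equal(length(v2$adjacent_only) + length(v2$shared), length(set_a))
})

de_row <- function(id, called, direction) {
  data.frame(mirna_id = id, called = called, direction = direction,
             stringsAsFactors = FALSE)
}

test_that("gradient calls demand DE in both comparisons plus monotone CPM", {
  up <- de_row("m1", TRUE, "up")
  g1 <- gradient_table(100, 250, 600, up, up)
  expect_equal(g1$class, "up_gradient")

  # non-monotone CPM: no gradient even with both comparisons up
  g2 <- gradient_table(100, 600, 250, up, up)
  expect_equal(g2$class, "none")

  # ties break monotonicity
  g3 <- gradient_table(100, 100, 600, up, up)
  expect_equal(g3$class, "none")

  # one comparison not called: no gradient
  g4 <- gradient_table(100, 250, 600, up, de_row("m1", FALSE, "none"))
  expect_equal(g4$class, "none")

  down <- de_row("m1", TRUE, "down")
  g5 <- gradient_table(600, 250, 100, down, down)
  expect_equal(g5$class, "down_gradient")

  # scale invariance
  g6 <- gradient_table(100 * 7, 250 * 7, 600 * 7, up, up)
  expect_equal(g6$class, g1$class)

  expect_error(gradient_table(1, 2, 3, up, de_row("other", TRUE, "up")),
               class = "miRtrend_error")
})

test_that("strict mode additionally gates the tumor-vs-adjacent step", {
  up <- de_row("m1", TRUE, "up")
  expect_equal(gradient_table(100, 400, 500, up, up, strict = TRUE)$class,
               "none")      # 500/400 < 2
  expect_equal(gradient_table(100, 200, 450, up, up, strict = TRUE)$class,
               "up_gradient")
})

test_that("published delta-Ct means imply a monotone down-gradient", {
  ref <- lung_ac_qpcr_dct()
  r218 <- ref[ref$target_id == "miR-218-5p", ]
  expr <- 2^(-r218$mean_dct[match(c("normal", "adjacent", "tumor"),
                                  r218$group)])
  expect_true(expr[1] > expr[2] && expr[2] > expr[3])
  down <- de_row("miR-218-5p", TRUE, "down")
  g <- gradient_table(expr[1], expr[2], expr[3], down, down)
  expect_equal(g$class, "down_gradient")
})

test_that("gradients are recovered from one simulated study", {
  d <- simulation_design(n_mirnas = 100, n_gradient_up = 3,
                         n_gradient_down = 2, gradient_step = 4,
                         baseline_mean = 100, seed = 23)
  sim <- simulate_counts(d)
  de_tn <- de_table(sim$counts, "normal", "tumor")
  de_an <- de_table(sim$counts, "normal", "adjacent")
  g <- gradient_from_counts(sim$counts, de_tn, de_an)
  expect_equal(sum(g$class == "up_gradient" &
                     sim$truth$class == "up_gradient"), 3)
  expect_equal(sum(g$class == "down_gradient" &
                     sim$truth$class == "down_gradient"), 2)
  expect_equal(sum(g$class != "none" & sim$truth$class == "null"), 0)
})

test_that("log2_expr transforms with a pseudocount", {
  expect_equal(log2_expr(c(0, 1, 3)), c(0, 1, 2))
  expect_equal(log2_expr(7, pseudocount = 1), 3)
  expect_error(log2_expr(-1), class = "miRtrend_error")
})
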