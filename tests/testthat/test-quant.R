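make_cq <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], gene = r[[2]], replicate = 1L,
               cq = as.numeric(r[[3]]), stringsAsFactors = FALSE)))
}

test_that("delta-delta-Cq arithmetic hits the textbook cases", {
  # all four Cq equal -> level 1
  cq <- make_cq(list("cal", "ACT1", 15), list("cal", "GENE", 20),
                list("s", "ACT1", 15), list("s", "GENE", 20))
  out <- relative_expression(cq, "GENE", "ACT1", "cal")
  expect_equal(out$level, c(1, 1))
  expect_equal(out$level[out$sample == "cal"], 1)  # calibrator exactly 1
  # target one cycle lower than calibrator, reference unchanged -> 2
  cq2 <- make_cq(list("cal", "ACT1", 15), list("cal", "GENE", 20),
                 list("s", "ACT1", 15), list("s", "GENE", 19))
  out2 <- relative_expression(cq2, "GENE", "ACT1", "cal")
  expect_equal(out2$level[out2$sample == "s"], 2)
})

test_that("relative expression is invariant to a constant Cq shift", {
  set.seed(21)
  cq <- do.call(rbind, lapply(c("cal", "a", "b"), function(s)
    data.frame(sample = s, gene = rep(c("ACT1", "GENE"), each = 3),
               replicate = 1:3, cq = stats::runif(6, 14, 26))))
  base <- relative_expression(cq, "GENE", "ACT1", "cal")
  shifted <- cq
  shifted$cq <- shifted$cq + 3.7
  expect_equal(relative_expression(shifted, "GENE", "ACT1", "cal")$level,
               base$level)
})

test_that("relative expression validates its inputs", {
  cq <- make_cq(list("cal", "ACT1", 15), list("cal", "GENE", 20),
                list("s", "GENE", 19))
  expect_error(relative_expression(cq, "GENE", "ACT1", "cal"),
               "reference gene")
  expect_error(relative_expression(cq, "GENE", "ACT1", "cal",
                                   efficiency = 2.5), "efficiency")
  expect_error(relative_expression(cq, "GENE", "ACT1", "cal",
                                   efficiency = 0.9), "efficiency")
  expect_error(relative_expression(cq, "GENE", "ACT1", "nope"),
               "calibrator")
})

test_that("RFU is fluorescence over density, with guards", {
  expect_equal(rfu(800, 0.8), 1000)
  expect_equal(rfu(0, 0.5), 0)
  expect_error(rfu(100, 0), "positive")
})

test_that("relative abundance normalises to the calibrator", {
  rfus <- c(ctrl = 500, over = 800, same = 500)
  ab <- relative_abundance(rfus, "ctrl")
  expect_equal(ab$level[ab$sample == "ctrl"], 1)
  expect_equal(ab$level[ab$sample == "over"], 1.6)
  expect_equal(ab$level[ab$sample == "same"], 1)
  expect_error(relative_abundance(c(a = 0, b = 2), "a"), "positive")
})

test_that("translation efficiency reproduces the reporter-strain ratios", {
  expect_equal(translation_efficiency(1, 1), 1)
  expect_equal(translation_efficiency(2.4, 1.6), 1.5)
  expect_equal(translation_efficiency(4.1, 2.7), 1.5185185, tolerance = 1e-6)
  prot <- data.frame(sample = c("a", "b"), level = c(2.4, 4.1),
                     calibrator = "cal")
  mrna <- data.frame(sample = c("a", "b"), level = c(1.6, 2.7),
                     calibrator = "cal")
  te <- translation_efficiency(prot, mrna)
  expect_equal(te$te, c(1.5, 4.1 / 2.7))
  mrna$calibrator <- "other"
  expect_error(translation_efficiency(prot, mrna), "calibrator")
})

test_that("levels and ratios are calibrator-consistent", {
  set.seed(31)
  rfus <- c(a = 420, b = 310, c = 870)
  ab1 <- relative_abundance(rfus, "a")
  ab2 <- relative_abundance(rfus, "b")
  # re-expressing multiplies all levels by one constant
  expect_equal(ab2$level / ab1$level,
               rep(ab2$level[1] / ab1$level[1], 3))
  # so percent differences between samples are unchanged
  expect_equal(percent_difference(ab1$level[2], ab1$level[3]),
               percent_difference(ab2$level[2], ab2$level[3]))
})

test_that("percent difference behaves and rounds as reported", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(2, 1), 100)
  expect_equal(percent_difference(1.690617, 1, digits = 0), 69)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("the UME6 worked example yields a 69 percent gain", {
  ex <- te_stress_gain(1.67, 2.4, 1.6, 4.1, 2.7)
  expect_equal(ex$te_induction_ctrl, 1.5)
  expect_equal(ex$te_induction_over, 4.1 / 2.7)
  expect_equal(ex$percent_gain, 69)
  bundled <- ume6_te_example()
  expect_equal(bundled$percent_gain, 69)
  expect_equal(bundled$inputs$baseline_te_ratio, 1.67)
})

test_that("replicate summary and the two-group test handle edge cases", {
  s <- replicate_summary(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 3L)
  tt <- two_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(tt$p_value, 1)
  expect_equal(tt$stars, "")
  expect_error(two_group_test(1, c(1, 2)), "replicates")
  expect_equal(significance_stars(c(0.2, 0.03, 0.005)), c("", "*", "**"))
})

test_that("the test detects a 5-sd shift with 3 replicates almost always", {
  set.seed(77)
  hits <- vapply(1:500, function(i) {
    a <- stats::rnorm(3, 0, 1)
    b <- stats::rnorm(3, 5, 1)
    two_group_test(a, b)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
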