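two_cond_plate <- function(ch800 = c(200, 180, 100, 120),
                           ch700 = c(100, 90, 100, 120)) {
  assay_plate(data.frame(
    well = c("A1", "A2", "B1", "B2"),
    condition_id = c("c1", "c1", "c2", "c2"),
    ch700 = ch700, ch800 = ch800))
}

test_that("normalization by sum follows the stated arithmetic", {
  v <- normalize_plate(two_cond_plate())
  # ratios (2,2) and (1,1); duplicate means 2 and 1; S = sum raw ch800 = 600
  expect_equal(v$value[v$condition_id == "c1"], 2 / 600)
  expect_equal(v$value[v$condition_id == "c2"], 1 / 600)
})

test_that("normalized values are invariant to 800-channel gain", {
  v1 <- normalize_plate(two_cond_plate())
  v10 <- normalize_plate(two_cond_plate(ch800 = 10 * c(200, 180, 100, 120)))
  expect_equal(v1$value, v10$value)
  # uniform 700-channel rescaling by c multiplies values by 1/c
  vc <- normalize_plate(two_cond_plate(ch700 = 4 * c(100, 90, 100, 120)))
  expect_equal(vc$value, v1$value / 4)
})

test_that("single condition with equal duplicates gives ratio over S", {
  p <- assay_plate(data.frame(well = c("A1", "A2"), condition_id = "c1",
                              ch700 = c(50, 50), ch800 = c(75, 75)))
  expect_equal(normalize_plate(p)$value, 1.5 / 150)
})

test_that("summary statistics over repeats match direct computation", {
  vals <- data.frame(condition_id = "c1", repeat_index = 1:4,
                     value = c(2, 2, 2, 2))
  s <- summarize_conditions(vals)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0)
  expect_equal(s$n, 4L)

  vals$value <- 1:4
  s <- summarize_conditions(vals)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sem, sd(1:4) / 2)
  expect_equal(round(s$sem, 4), 0.6455)

  set.seed(9)
  x <- rlnorm(7)
  s <- summarize_conditions(data.frame(condition_id = "c", repeat_index = 1:7,
                                       value = x))
  twopass <- sqrt(sum((x - mean(x))^2) / 6) / sqrt(7)
  expect_equal(s$sem, twopass, tolerance = 1e-12)

  expect_warning(
    s1 <- summarize_conditions(data.frame(condition_id = "c",
                                          repeat_index = 1, value = 5)),
    "single repeat")
  expect_true(is.na(s1$sem))
})

test_that("background subtraction and percent-of-control behave as stated", {
  s <- data.frame(condition_id = c("empty", "a", "b", "c"),
                  mean = c(1e-8, 4e-8, 1e-8, 0.5e-8),
                  sem = c(0, 0, 0, 0), n = 4L)
  expect_warning(adj <- background_subtract(s), "negative")
  expect_equal(adj$mean[adj$condition_id == "a"], 3e-8)
  expect_equal(adj$mean[adj$condition_id == "b"], 0)
  expect_equal(adj$mean[adj$condition_id == "c"], -0.5e-8)

  expect_equal(percent_of_control(3e-8, 3e-8), 100)
  expect_equal(percent_of_control(3e-8, 9e-8), 100 / 3, tolerance = 1e-12)
  expect_error(percent_of_control(1, 0), "> 0")
  expect_error(percent_of_control(1, -2), "> 0")
  withsem <- percent_of_control(50, 100, sem = 5, control_sem = 10)
  expect_equal(withsem$percent, 50)
  expect_equal(withsem$sem, 50 * sqrt(0.01 + 0.01))
})

test_that("errors for empty plates, zero sums and unknown family members", {
  p <- two_cond_plate()
  p$wells$ch800 <- 0
  expect_error(normalize_plate(p), "not positive")
  groups <- list(a = c(1, 2), b = c(2, 3))
  expect_error(
    anova_bonferroni(groups, data.frame(condition = "z", reference = "a")),
    "unknown condition")
  expect_error(anova_bonferroni(list(a = 1, b = c(1, 2)),
                                data.frame(condition = "b", reference = "a")),
               ">= 2 values")
})

test_that("two-group ANOVA F equals the squared pairwise t", {
  set.seed(21)
  for (i in 1:5) {
    g <- list(a = rnorm(4), b = rnorm(5, mean = 0.5))
    cmp <- anova_bonferroni(g, data.frame(condition = "b", reference = "a"))
    mse <- (sum((g$a - mean(g$a))^2) + sum((g$b - mean(g$b))^2)) / 7
    t_stat <- (mean(g$b) - mean(g$a)) / sqrt(mse * (1 / 4 + 1 / 5))
    expect_equal(attr(cmp, "anova_f"), t_stat^2, tolerance = 1e-12)
    # omnibus agrees with the classical equal-variance one-way test
    ow <- oneway.test(v ~ g, data.frame(v = c(g$a, g$b),
                                        g = rep(c("a", "b"), c(4, 5))),
                      var.equal = TRUE)
    expect_equal(attr(cmp, "anova_p"), unname(ow$p.value), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment scales, caps at 1, and handles degeneracy", {
  set.seed(3)
  g <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4), r = rnorm(4))
  fam <- data.frame(condition = c("a", "b", "c"), reference = "r")
  cmp <- anova_bonferroni(g, fam)
  expect_true(all(cmp$adjusted_p >= cmp$raw_p))
  expect_true(all(cmp$adjusted_p <= 1))
  expect_equal(cmp$adjusted_p, pmin(1, cmp$raw_p * 3))

  const <- list(a = c(2, 2), b = c(2, 2), r = c(2, 2))
  expect_warning(
    cmp0 <- anova_bonferroni(const, data.frame(condition = c("a", "b"),
                                               reference = "r")),
    "degenerate")
  expect_false(any(cmp0$significant))
  expect_equal(attr(cmp0, "anova_p"), 1)
})
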