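test_that("Welch test matches the closed-form statistic on a hand example", {
  a <- 1:5; b <- 2:6
  w <- welch_t_test(a, b)
  # hand-evaluated Welch formula: equal variances 2.5, n = 5 each
  se <- sqrt(2.5 / 5 + 2.5 / 5)
  df <- se^4 / ((2.5 / 5)^2 / 4 + (2.5 / 5)^2 / 4)
  expect_equal(w$t, -1 / se, tolerance = 1e-12)
  expect_equal(w$df, df, tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(-1 / se), df), tolerance = 1e-12)
})

test_that("Welch test is symmetric, antisymmetric and guards its inputs", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(welch_t_test(x, x)$t, 0)
  expect_equal(welch_t_test(x, x)$p, 1)
  y <- x + 1
  expect_equal(welch_t_test(x, y)$t, -welch_t_test(y, x)$t)
  expect_equal(welch_t_test(x, y)$p, welch_t_test(y, x)$p)
  expect_error(welch_t_test(1, x), "n >= 2")
  deg <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("one-way F reduces to the squared pooled t for two groups", {
  set.seed(8)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  an <- oneway_anova_levene(c(a, b), rep(c("x", "y"), c(12, 15)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(an$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
  expect_equal(an$df_between, 1)
  expect_equal(an$df_within, 25)
})

test_that("constant responses degrade gracefully and group sizes are
           enforced", {
  an <- oneway_anova_levene(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_true(an$degenerate)
  expect_equal(an$f, 0)
  expect_error(oneway_anova_levene(1:5, c("a", "a", "b", "b", "c")),
               "n >= 2")
})

test_that("Levene flags programmed heteroscedasticity across five groups", {
  set.seed(99)
  sds <- c(0.4, 0.5, 0.55, 0.65, 0.8)
  vals <- unlist(lapply(1:5, function(g) rnorm(800, mean = g / 10, sds[g])))
  grp <- rep(paste0("g", 1:5), each = 800)
  an <- oneway_anova_levene(vals, grp)
  expect_lt(an$levene_p, 0.001)
  expect_equal(an$df_between, 4)
  expect_equal(an$df_within, 4000 - 5)
})

test_that("the studentized maximum modulus CDF matches Monte Carlo and is
           monotone", {
  set.seed(7)
  draws <- rsmm(2e5, 3, 10)
  for (q in c(1.5, 2.5, 3.5)) {
    expect_equal(psmm(q, 3, 10), mean(draws <= q), tolerance = 0.01)
  }
  qs <- seq(0.5, 5, by = 0.5)
  p <- psmm(qs, 6, 20)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
  # more comparisons push the distribution right: adjusted p grows with k
  expect_lt(psmm(2.5, 10, 30), psmm(2.5, 3, 30))
})

test_that("Dunnett T3 adjusted p dominates the unadjusted Welch p", {
  set.seed(12)
  vals <- c(rnorm(20), rnorm(25, 0.4), rnorm(30, 0.8), rnorm(15, 1.2))
  grp <- rep(letters[1:4], c(20, 25, 30, 15))
  t3 <- dunnett_t3(vals, grp)
  expect_true(all(t3$table$p_adjusted >= t3$table$p_welch - 1e-12))
  expect_error(dunnett_t3(rnorm(10), rep(c("a", "b"), 5)), "welch_t_test")
})

test_that("Dunnett T3 adjusted p for a fixed pair grows with the number of
           groups", {
  set.seed(13)
  a <- rnorm(30); b <- rnorm(30, 0.7)
  extra1 <- rnorm(30, 5); extra2 <- rnorm(30, 10)
  p3 <- dunnett_t3(c(a, b, extra1), rep(c("a", "b", "c"), each = 30))
  p4 <- dunnett_t3(c(a, b, extra1, extra2),
                   rep(c("a", "b", "c", "d"), each = 30))
  pick <- function(x) x$table$p_adjusted[x$table$group1 == "a" &
                                           x$table$group2 == "b"]
  expect_gt(pick(p4), pick(p3))
})

test_that("the significance partition isolates well-separated groups", {
  set.seed(14)
  vals <- c(rnorm(30, 0), rnorm(30, 0.05), rnorm(30, 8))
  grp <- rep(c("low1", "low2", "high"), each = 30)
  t3 <- dunnett_t3(vals, grp)
  expect_length(t3$partition, 2)
  expect_equal(t3$partition[[1]], "high")
  expect_setequal(t3$partition[[2]], c("low1", "low2"))
})
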