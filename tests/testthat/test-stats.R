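test_that("the Bonferroni-adjusted level divides the family alpha", {
  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("Spearman handles monotone, antitone and tied data", {
  expect_equal(spearman_corr(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_corr(1:4, c(40, 30, 20, 10))$rho, -1)
  expect_equal(spearman_corr(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  # midranks: ties in y
  r <- spearman_corr(1:4, c(1, 2, 2, 3))
  expect_equal(r$rho, cor(1:4, rank(c(1, 2, 2, 3))))
  expect_error(spearman_corr(1:4, rep(2, 4)), "constant")
  expect_equal(spearman_corr(1:5, (1:5)^3)$p, 0)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(88)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    base <- spearman_corr(x, y)
    warped <- spearman_corr(exp(x), atan(y))
    expect_equal(warped$rho, base$rho)
    expect_equal(warped$p, base$p)
  }
})

test_that("exact Spearman p equals the permutation enumeration oracle", {
  set.seed(89)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(spearman_corr(x, y, method = "exact")$p,
                 oracle_spearman_p(x, y))
  }
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_corr(x, y, method = "exact")$p,
               oracle_spearman_p(x, y))
  # and the independent route in base R
  expect_equal(spearman_corr(x, y, method = "exact")$p,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
})

test_that("Wilcoxon exact p equals sign-flip enumeration for n <= 10", {
  # all-positive differences 1..6: W = 0, p = 2/2^6
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.03125)
  expect_equal(res$method, "exact")
  set.seed(90)
  for (n in c(4, 6, 8, 10)) {
    for (i in 1:5) {
      d <- round(rnorm(n), 3)
      d <- d + (d == 0)  # keep differences nonzero
      while (any(duplicated(abs(d)))) d <- d + rnorm(n, 0, 1e-4)
      got <- wilcoxon_signed_rank(d, rep(0, n))
      expect_equal(got$p, oracle_wilcoxon_p(d))
      # base R's exact two-sided p as a second, independent route
      expect_equal(got$p, wilcox.test(d, exact = TRUE)$p.value)
    }
  }
})

test_that("Wilcoxon drops zero differences and errors when all are zero", {
  a <- c(1, 2, 3, 4, 5); b <- c(1, 2, 3, 3, 3)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$n_effective, 2)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
})

test_that("the significance flag respects the adjusted level", {
  # p = 0.0625 > 0.0167: four concordant pairs cannot clear the bar
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5), c(1, 1, 1, 1),
                              alpha_adjusted = 0.0167)
  expect_equal(res$p, 0.125)
  expect_false(res$significant)
  res2 <- wilcoxon_signed_rank(c(2, 3, 4, 5), c(1, 1, 1, 1),
                               alpha_adjusted = 0.2)
  expect_true(res2$significant)
})

test_that("tied-rank normal approximation matches base R's corrections", {
  set.seed(91)
  d <- c(rep(1.5, 4), rep(-1.5, 3), 2.5, -3.5, 4.5, 1.25, -2.25,
         3.25, 0.75, -0.75, 1.1, -2.2, 3.3, 4.4, -1.1)
  got <- wilcoxon_signed_rank(d, rep(0, length(d)))
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("RM-ANOVA matches the independent sums-of-squares oracle", {
  arr <- rm_fixture()
  got <- rm_anova(arr)
  want <- oracle_rm_anova(arr)
  expect_false(any(got$gg_applied))  # fixture satisfies sphericity
  expect_equal(got$F[got$effect == "group"], want$group$F)
  expect_equal(got$F[got$effect == "time"], want$time$F)
  expect_equal(got$F[got$effect == "group:time"], want$interaction$F)
  expect_equal(got$p[got$effect == "group"], want$group$p)
  expect_equal(got$p[got$effect == "time"], want$time$p)
  expect_equal(got$p[got$effect == "group:time"], want$interaction$p)
})

test_that("RM-ANOVA sphericity diagnostics match an external reference", {
  # frozen values computed with an independent statistics library on the
  # same fixture (two-way within-subject design, GG epsilon and Mauchly)
  got <- rm_anova(rm_fixture())
  expect_equal(got$F, c(7.110986, 1.725372, 0.900601), tolerance = 1e-6)
  expect_equal(got$p, c(0.056001, 0.214859, 0.469321), tolerance = 1e-5)
  expect_equal(got$epsilon_gg[2:3], c(0.511440, 0.508221), tolerance = 1e-6)
  expect_equal(got$mauchly_p[2:3], c(0.102341, 0.525243), tolerance = 1e-5)
  expect_true(is.na(got$mauchly_p[1]))  # 2-level factor: sphericity trivial
})

test_that("GG epsilon of a 4-level effect stays within its analytic bounds", {
  set.seed(92)
  for (i in 1:25) {
    arr <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
    got <- rm_anova(arr)
    eps <- got$epsilon_gg[got$effect == "time"]
    expect_gte(eps, 1 / 3)
    expect_lte(eps, 1)
  }
})

test_that("RM-ANOVA collapses to the squared paired t-test with 2 levels", {
  set.seed(93)
  x <- matrix(rnorm(20), 10, 2)
  got <- rm_anova(array(x, c(10, 1, 2)))
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(got$effect, "time")
  expect_equal(got$F, unname(tt$statistic)^2)
  expect_equal(got$p, tt$p.value)
})

test_that("pure subject offsets give the F = 0, p = 1 boundary", {
  set.seed(94)
  arr <- array(rep(rnorm(5), 8), c(5, 2, 4))
  got <- rm_anova(arr)
  expect_equal(got$F, rep(0, 3))
  expect_equal(got$p, rep(1, 3))
})

test_that("long-format input matches the array route", {
  arr <- rm_fixture()
  df <- expand.grid(subject = 1:5, group = c("g1", "g2"),
                    time = paste0("t", 1:4))
  df$value <- as.vector(arr)
  expect_equal(rm_anova(df), rm_anova(arr))
})
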