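# statistical toolbox: gated two-group tests, nested t-test, Box-Cox,
# ANOVA + Tukey letters, categorical tests, 4PL calibration

test_that("choose_two_group_test gates on Shapiro-Wilk normality", {
  set.seed(101)
  r <- choose_two_group_test(rnorm(30), rnorm(30))
  expect_identical(r$gate, "t")
  # heavy log-normal sample: Mann-Whitney selected in >= 18/20 seeds
  mw <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    r2 <- choose_two_group_test(exp(rnorm(30, sd = 1.5)), rnorm(30, 5))
    if (r2$gate == "mann-whitney") mw <- mw + 1L
  }
  expect_gte(mw, 18L)
  # identical samples: Mann-Whitney path, p = 1 (no location shift signal)
  x <- c(1, 1, 1, 2, 2, 5, 5, 9)   # ties force the non-normal path
  r3 <- choose_two_group_test(x, x)
  expect_equal(r3$p_value, 1)
  # p invariant under label swap
  set.seed(7)
  a <- rnorm(25); b <- rnorm(25, 0.5)
  expect_equal(choose_two_group_test(a, b)$p_value,
               choose_two_group_test(b, a)$p_value)
})

test_that("nested_t_test works on cluster means", {
  # identical cluster means across groups: statistic 0, p = 1
  s <- grouped_sample(values = c(1, 3, 2, 2, 1, 3, 2, 2),
                      cluster_id = rep(c("m1", "m2", "m3", "m4"), each = 2),
                      group = rep(c("young", "old"), each = 4))
  r <- nested_t_test(s)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # balanced design: identical to Student's t on cluster means (oracle)
  set.seed(33)
  vals <- rnorm(40)
  cl <- rep(paste0("m", 1:8), each = 5)
  gr <- rep(c("young", "old"), each = 20)
  s2 <- grouped_sample(vals, cl, gr)
  r2 <- nested_t_test(s2)
  cm <- tapply(vals, cl, mean)
  oracle <- t.test(cm[paste0("m", 1:4)], cm[paste0("m", 5:8)], var.equal = TRUE)
  expect_equal(r2$statistic, unname(oracle$statistic))
  expect_equal(r2$p_value, oracle$p.value)
  expect_equal(r2$df, unname(oracle$parameter))
  # duplicating every observation within clusters changes nothing
  s3 <- grouped_sample(c(vals, vals), c(cl, cl), c(gr, gr))
  expect_equal(nested_t_test(s3)$p_value, r2$p_value)
  # < 2 clusters per group errors
  s4 <- grouped_sample(1:4, c("a", "a", "b", "c"),
                       c("young", "young", "old", "old"))
  expect_error(nested_t_test(s4), "2 clusters")
})

test_that("Box-Cox transform matches closed form and inverts", {
  expect_equal(boxcox_transform(1), 0)
  expect_equal(boxcox_transform(2), (2^-0.4242 - 1) / (-0.4242))
  expect_equal(boxcox_transform(2), 0.6006, tolerance = 2e-4)
  y <- seq(0.01, 100, length.out = 1000)
  z <- boxcox_transform(y)
  expect_true(all(diff(z) > 0))
  expect_lt(max(abs(boxcox_inverse(z) - y)), 1e-10)
  expect_error(boxcox_transform(-1), "positive")
  expect_error(boxcox_transform(2, lambda = 0), "nonzero")
})

test_that("anova_tukey separates a shifted group with distinct letters", {
  # identical constant groups: F = 0
  r0 <- anova_tukey(rep(5, 30), rep(c("a", "b", "c"), each = 10))
  expect_equal(r0$statistic, 0)
  # N(0,1), N(0,1), N(3,1): third group distinct in >= 19/20 seeds
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    r <- anova_tukey(c(rnorm(20), rnorm(20), rnorm(20, 3)),
                     rep(c("g1", "g2", "g3"), each = 20))
    distinct <- !grepl(r$letters["g3"], r$letters["g1"], fixed = TRUE) &&
      !grepl(r$letters["g3"], r$letters["g2"], fixed = TRUE)
    if (distinct) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # two groups rejected
  expect_error(anova_tukey(rnorm(20), rep(c("a", "b"), each = 10)), "3 groups")
})

test_that("categorical_test picks Fisher vs chi-square by expected counts", {
  # balanced 2x2: no association, p = 1
  r0 <- categorical_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$p_value, 1)
  # [[9,1],[1,9]]: Fisher exact; oracle by hypergeometric enumeration
  tab <- matrix(c(9, 1, 1, 9), 2)
  r <- categorical_test(tab)
  expect_identical(r$method, "Fisher's exact test")
  pr <- dhyper(0:10, 10, 10, 10)
  oracle <- sum(pr[pr <= dhyper(9, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(r$p_value, oracle, tolerance = 1e-9)
  expect_equal(round(r$p_value, 4), 0.0011)
  # large 2x3 table: chi-square with df = 2
  r2 <- categorical_test(matrix(c(30, 20, 25, 25, 20, 30), 2))
  expect_identical(r2$method, "chi-square test")
  expect_equal(r2$df, 2)
  expect_error(categorical_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("4PL fitting recovers parameters and inverts readings", {
  a <- 0.05; b <- 1.4; cc <- 12; d <- 2.4
  conc <- c(0.5, 1.5, 4, 12, 36, 108, 324)
  resp <- d + (a - d) / (1 + (conc / cc)^b)
  fit <- fit_4pl(conc, resp)
  expect_equal(c(fit$a, fit$b, fit$c, fit$d), c(a, b, cc, d), tolerance = 0.01)
  # inflection midpoint identity: y(c) = (a + d)/2
  expect_equal(predict_4pl(fit, fit$c), (fit$a + fit$d) / 2)
  # round-trip: predict then invert
  inv <- invert_4pl(fit, predict_4pl(fit, c(2, 10, 50)))
  expect_equal(inv$conc, c(2, 10, 50), tolerance = 1e-6)
  expect_identical(inv$flag, rep("ok", 3))
  # readings beyond the upper asymptote are flagged with no estimate
  out <- invert_4pl(fit, c(2.5, 0.01))
  expect_identical(out$flag, rep("out-of-range", 2))
  expect_true(all(is.na(out$conc)))
  # noisy fit still close
  set.seed(5)
  fit2 <- fit_4pl(conc, resp + rnorm(length(resp), sd = 0.01))
  expect_equal(fit2$c, cc, tolerance = 0.15)
})

test_that("nested test calibration beats the naive per-observation t-test", {
  # ICC 0.5, 5 clusters x 10 obs per group, no group effect
  set.seed(2024)
  n_sim <- 200L
  rej_nested <- rej_naive <- 0L
  for (i in seq_len(n_sim)) {
    mk <- function(g) {
      cl_eff <- rnorm(5, sd = sqrt(0.5))
      data.frame(v = rep(cl_eff, each = 10) + rnorm(50, sd = sqrt(0.5)),
                 cl = paste0(g, rep(1:5, each = 10)), g = g)
    }
    d <- rbind(mk("young"), mk("old"))
    s <- grouped_sample(d$v, d$cl, d$g)
    if (nested_t_test(s)$p_value < 0.05) rej_nested <- rej_nested + 1L
    if (t.test(d$v[d$g == "young"], d$v[d$g == "old"])$p.value < 0.05) {
      rej_naive <- rej_naive + 1L
    }
  }
  expect_gte(rej_nested / n_sim, 0.01)
  expect_lte(rej_nested / n_sim, 0.10)
  expect_gt(rej_naive / n_sim, 0.15)
})
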