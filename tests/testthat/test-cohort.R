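test_that("run_cohort pipelines a case end to end and is seed-reproducible", {
  c1 <- run_cohort(3, seed = 21)
  expect_s3_class(c1, "tka_cohort")
  expect_equal(nrow(c1), 3)
  expect_true(all(c(
    "fed", "psa", "preop_gamma", "postop_gamma", "gamma_diff",
    "preop_delta", "postop_delta", "delta_diff",
    "gamma_within", "delta_within", "notching") %in% names(c1)))
  c2 <- run_cohort(3, seed = 21)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("cohort summary percentages equal brute-force counts", {
  tbl <- data.frame(
    fed = rep(9, 93), psa = rep(0.8, 93),
    preop_gamma = rnorm(93), postop_gamma = rnorm(93),
    preop_delta = rnorm(93), postop_delta = rnorm(93),
    gamma_within = rep(c(TRUE, FALSE), c(75, 18)),
    delta_within = rep(c(TRUE, FALSE), c(89, 4)),
    notching = FALSE)
  class(tbl) <- c("tka_cohort", "data.frame")
  s <- summary(tbl)
  expect_equal(s$gamma_accuracy, 80.6)  # 75/93
  expect_equal(s$delta_accuracy, 95.7)  # 89/93
  expect_equal(s$gamma_within_n, sum(tbl$gamma_within))
  tbl$gamma_within <- TRUE
  expect_equal(summary(tbl)$gamma_accuracy, 100)
})

test_that("paired comparison screens normality and handles degeneracy", {
  x <- rnorm(30)
  res0 <- paired_compare(x, x)
  expect_equal(res0$test, "degenerate")
  expect_true(is.na(res0$p))
  set.seed(22)
  pre <- rnorm(93); post <- pre + rnorm(93, 1.2, 1.8)
  res <- paired_compare(pre, post)
  expect_true(res$test %in% c("paired t", "wilcoxon signed-rank"))
  expect_lt(res$p, 0.05)
  # heavy-tailed differences fail the screen and fall back to ranks
  set.seed(23)
  post2 <- pre + rcauchy(93) * 5
  res2 <- paired_compare(pre, post2)
  expect_true(is.finite(res2$p))
})

test_that("a shifted cohort is detected with high power", {
  set.seed(24)
  hits <- replicate(200, {
    pre <- rnorm(93)
    post <- pre + rnorm(93, 1.2, 1.8)
    paired_compare(pre, post)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("regression recovers planted effects and the intercept-only mean", {
  set.seed(25)
  df <- sample_cohort(93)
  df$gamma_diff <- 0.5 * df$dfb + rnorm(93, sd = 0.8)
  rt <- regress_abs_differences(df, response = "gamma_diff",
                                predictors = c("sex_men", "age", "bmi", "dxa",
                                               "hka", "dfb"))
  b <- rt[rt$term == "dfb", ]
  expect_lt(abs(b$B - 0.5), 2 * b$SE)
  expect_lt(b$p, 0.001)
  # standardised coefficient consistent with a z-scored refit
  z <- as.data.frame(scale(df[c("gamma_diff", "dfb", "age")]))
  fitz <- lm(gamma_diff ~ dfb + age, data = z)
  rt2 <- regress_abs_differences(df, response = "gamma_diff",
                                 predictors = c("dfb", "age"))
  expect_equal(rt2$Beta[rt2$term == "dfb"], unname(coef(fitz)["dfb"]),
               tolerance = 1e-9)
  # intercept-only fit returns the mean response
  rt0 <- regress_abs_differences(df, response = "gamma_diff",
                                 predictors = character(0))
  expect_equal(rt0$B[1], mean(df$gamma_diff))
  # CI = B +/- t_crit * SE
  tcrit <- qt(0.975, df = 93 - nrow(rt) )
  expect_equal(b$ci_upper - b$B, tcrit * b$SE, tolerance = 1e-9)
})

test_that("regression flags an ill-conditioned design instead of dropping it", {
  set.seed(26)
  df <- data.frame(y = rnorm(50), a = rnorm(50))
  df$b <- df$a * 2 + rnorm(50, sd = 1e-9)
  expect_warning(regress_abs_differences(df, response = "y",
                                         predictors = c("a", "b")),
                 "ill-conditioned")
})

test_that("default predictor sets follow the femur and tibia study designs", {
  coh <- run_cohort(40, seed = 27)
  rf <- regress_abs_differences(coh, "gamma")
  expect_setequal(setdiff(rf$term, "(Intercept)"),
                  c("sex_men", "age", "bmi", "dxa", "hka", "dfb"))
  rtb <- regress_abs_differences(coh, "delta")
  expect_setequal(setdiff(rtb$term, "(Intercept)"),
                  c("sex_men", "age", "bmi", "dxa", "hka", "tps", "tst", "ptb"))
})

test_that("paired-t sample size reproduces the design calculation", {
  expect_identical(sample_size_paired_t(0.4, 0.05, 0.95), 84L)
  # independent cross-check at another design point
  n80 <- sample_size_paired_t(0.4, 0.05, 0.80)
  ref <- ceiling(power.t.test(delta = 0.4, sd = 1, sig.level = 0.05,
                              power = 0.80, type = "paired")$n)
  expect_equal(n80, as.integer(ref))
  # monotonicity: larger effects need fewer pairs
  expect_lt(sample_size_paired_t(0.8), sample_size_paired_t(0.4))
  expect_error(sample_size_paired_t(-1))
})

test_that("dropout inflation matches the design arithmetic", {
  expect_identical(dropout_inflation(84, 0.25), 112L)
  expect_identical(dropout_inflation(50, 0), 50L)
  expect_identical(dropout_inflation(10, 0.5), 20L)
  expect_error(dropout_inflation(10, 1), "rate")
})
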