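test_that("fit_optimal recovers a closed-form log odds ratio", {
  ch <- make_binary_cohort(10000, p0 = 0.2, p1 = 0.8, seed = 2)
  m <- fit_optimal(ch)
  se <- sqrt(diag(m$vcov))[["exposure"]]
  expect_lt(abs(m$coefficients[["exposure"]] - log(16)), 3 * se)
  expect_true(is.finite(m$training_loss) && m$training_loss >= 0)
})

test_that("null predictors get slopes near zero", {
  ch <- make_gauss_cohort(20000, beta = c(0, 0, 0), seed = 5)
  m <- fit_optimal(ch)
  se <- sqrt(diag(m$vcov))[-1]
  expect_true(all(abs(m$coefficients) < 3 * se))
})

test_that("separation and rank deficiency are reported as errors", {
  df <- data.frame(x = c(-2, -1, 1, 2), outcome = c(0, 0, 1, 1))
  ch <- as_cohort(df, list(var_schema("x", "continuous")))
  expect_error(fit_optimal(ch), "separation")

  df2 <- data.frame(x = rnorm(50), outcome = rbinom(50, 1, 0.5))
  df2$x2 <- 2 * df2$x
  ch2 <- as_cohort(df2, list(var_schema("x", "continuous"),
                             var_schema("x2", "continuous")))
  expect_error(fit_optimal(ch2), "rank deficient")
})

test_that("logistic loss matches closed forms and is minimized at the MLE", {
  ch <- make_gauss_cohort(50, beta = 1, seed = 6)
  m <- fit_optimal(ch)

  # p = 0.5 for all rows -> loss = ln 2
  expect_equal(logistic_loss(m, ch, intercept = 0, coefficients = c(x1 = 0)),
               log(2))
  # single row, y = 1, p = 0.8 -> -ln 0.8
  one <- as_cohort(data.frame(x1 = 0, outcome = 1),
                   list(var_schema("x1", "continuous")))
  expect_equal(logistic_loss(m, one, intercept = qlogis(0.8),
                             coefficients = c(x1 = 0)), -log(0.8),
               tolerance = 1e-12)
  # y = 1 with p -> 1 gives vanishing loss
  expect_lt(logistic_loss(m, one, intercept = 30, coefficients = c(x1 = 0)), 1e-10)

  # MLE minimizes the training loss over random perturbations
  set.seed(42)
  for (i in 1:20) {
    d <- rnorm(length(m$coefficients) + 1, sd = 0.1)
    expect_gte(logistic_loss(m, ch, intercept = m$intercept + d[1],
                             coefficients = m$coefficients + d[-1]),
               m$training_loss)
  }
})

test_that("training loss is invariant to the categorical reference level", {
  set.seed(8)
  df <- data.frame(grp = sample(c("a", "b", "c"), 400, replace = TRUE),
                   x = rnorm(400))
  df$outcome <- rbinom(400, 1, plogis(-0.5 + (df$grp == "b") + 0.5 * df$x))
  s1 <- list(var_schema("grp", "categorical", levels = c("a", "b", "c")),
             var_schema("x", "continuous"))
  s2 <- list(var_schema("grp", "categorical", levels = c("c", "a", "b")),
             var_schema("x", "continuous"))
  l1 <- fit_optimal(as_cohort(df, s1))$training_loss
  l2 <- fit_optimal(as_cohort(df, s2))$training_loss
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("models round-trip through JSON serialization", {
  ch <- make_binary_cohort(500, seed = 7)
  m <- fit_optimal(ch)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f, ch)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(logistic_loss(m2, ch), m$training_loss, tolerance = 1e-12)
  expect_error(read_model(f, make_gauss_cohort(50, beta = 1)), "mismatch|match")
})

test_that("generalized VIF matches closed forms and car::vif", {
  ch <- make_gauss_cohort(10000, beta = c(0.5, 0.5), seed = 9)
  v <- generalized_vif(ch)
  expect_true(all(abs(v$gvif - 1) < 0.05))
  expect_false(any(v$flag))
  expect_true(all(v$gvif >= 1))

  # correlated pair: VIF ~ 1/(1 - rho^2)
  set.seed(10)
  x <- rnorm(10000); x2 <- 0.9 * x + sqrt(1 - 0.81) * rnorm(10000)
  df <- data.frame(a = x, b = x2, outcome = rbinom(10000, 1, plogis(x)))
  ch2 <- as_cohort(df, list(var_schema("a", "continuous"),
                            var_schema("b", "continuous")))
  v2 <- generalized_vif(ch2)
  expect_equal(v2$gvif, rep(1 / (1 - cor(x, x2)^2), 2), tolerance = 0.02)
  expect_true(all(v2$flag))

  # cross-check against the standard determinant-based implementation,
  # including a multi-df categorical variable
  set.seed(11)
  df3 <- data.frame(grp = sample(c("a", "b", "c"), 2000, replace = TRUE),
                    z = rnorm(2000), w = rnorm(2000))
  df3$outcome <- rbinom(2000, 1, 0.4)
  ch3 <- as_cohort(df3, list(var_schema("grp", "categorical",
                                        levels = c("a", "b", "c")),
                             var_schema("z", "continuous"),
                             var_schema("w", "continuous")))
  v3 <- generalized_vif(ch3)
  # car computes the GVIF from the coefficient covariance rather than the
  # raw design correlation, so agreement is close but not exact
  ref <- car::vif(glm(outcome ~ grp + z + w, family = binomial(), data = df3))
  expect_equal(v3$gvif, unname(ref[, "GVIF"]), tolerance = 1e-4)
  expect_equal(v3$df, unname(ref[, "Df"]))
  # df = 1 variables: GVIF collapses to the classical VIF
  expect_equal(v3$comparable[v3$df == 1], v3$gvif[v3$df == 1])
})
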