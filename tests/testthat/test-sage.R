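# Small helper: fitted model on independent normals with chosen true betas,
# plus fixed evaluation/background cohorts.
sage_fixture <- function(n = 1200, beta = c(1, 0.5, 0), seed = 21,
                         n_eval = 150, n_bg = 60) {
  ch <- make_gauss_cohort(n, beta = beta, seed = seed)
  m <- fit_optimal(ch)
  list(model = m,
       eval = vicscore:::cohort_subset(ch, seq_len(n_eval)),
       bg = vicscore:::cohort_subset(ch, n - seq_len(n_bg) + 1))
}

test_that("null players get exactly zero value and zero SE", {
  fx <- sage_fixture(beta = c(1, 0.5, 0))
  m <- fx$model
  m$coefficients[["x3"]] <- 0          # exact null player
  res <- sage_values(m, fx$eval, sage_config(eval_rows = 150, n_permutations = 30,
                                             seed = 2), background = fx$bg)
  expect_identical(res$value[["x3"]], 0)
  expect_identical(res$se[["x3"]], 0)
  expect_true(all(res$se[c("x1", "x2")] > 0))
})

test_that("exchangeable variables with equal coefficients get equal values", {
  # exact exchangeability: x2 is a duplicate column with the same coefficient,
  # so the game is symmetric and any value gap is pure Monte-Carlo noise
  set.seed(22)
  x <- rnorm(600)
  df <- data.frame(x1 = x, x2 = x, outcome = rbinom(600, 1, plogis(0.8 * x)))
  ch <- as_cohort(df, list(var_schema("x1", "continuous"),
                           var_schema("x2", "continuous")))
  enc <- vicscore:::encode_design(ch)
  m <- structure(list(intercept = -0.1, coefficients = c(x1 = 0.4, x2 = 0.4),
                      encoding = enc[c("variables", "assign", "blocks", "ref_levels")],
                      column_names = colnames(enc$X)),
                 class = "logit_model")
  ev <- vicscore:::cohort_subset(ch, 1:150)
  bg <- vicscore:::cohort_subset(ch, 501:600)
  ex <- exact_shapley(m, ev, bg)
  expect_equal(ex[["x1"]], ex[["x2"]], tolerance = 1e-12)
  res <- sage_values(m, ev, sage_config(eval_rows = 150, n_permutations = 200,
                                        seed = 3), background = bg)
  tol <- 3 * sqrt(sum(res$se^2)) + 1e-12
  expect_lt(abs(res$value[["x1"]] - res$value[["x2"]]), tol)
})

test_that("the exact enumeration oracle obeys the Shapley axioms", {
  fx <- sage_fixture(beta = c(1, 0.5, 0), seed = 23)
  m <- fx$model
  m$coefficients[["x3"]] <- 0
  ex <- exact_shapley(m, fx$eval, fx$bg)
  # null player, ordering, and positivity of real signals
  expect_equal(ex[["x3"]], 0)
  expect_gt(ex[["x1"]], ex[["x2"]])
  expect_gt(ex[["x2"]], 0)

  # efficiency: sum of values = L_empty - L_full, by brute-force recompute
  Xe <- as.matrix(fx$eval$data); Xb <- as.matrix(fx$bg$data)
  eta_full <- m$intercept + drop(Xe %*% m$coefficients)
  L_full <- mean(-(fx$eval$outcome * log(plogis(eta_full)) +
                   (1 - fx$eval$outcome) * log1p(-plogis(eta_full))))
  p0 <- mean(plogis(m$intercept + drop(Xb %*% m$coefficients)))
  L_empty <- mean(-(fx$eval$outcome * log(p0) +
                    (1 - fx$eval$outcome) * log1p(-p0)))
  expect_equal(sum(ex), L_empty - L_full, tolerance = 1e-10)

  # intercept-only model: constant game, all values zero
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(unname(exact_shapley(m0, fx$eval, fx$bg)), c(0, 0, 0))

  # single-player game: the lone variable takes the whole payoff
  fx1 <- sage_fixture(beta = 0.9, seed = 24)
  ex1 <- exact_shapley(fx1$model, fx1$eval, fx1$bg)
  X1 <- as.matrix(fx1$eval$data)
  eta1 <- fx1$model$intercept + drop(X1 %*% fx1$model$coefficients)
  L_f <- mean(-(fx1$eval$outcome * log(plogis(eta1)) +
                (1 - fx1$eval$outcome) * log1p(-plogis(eta1))))
  p01 <- mean(plogis(fx1$model$intercept +
                     drop(as.matrix(fx1$bg$data) %*% fx1$model$coefficients)))
  L_e <- mean(-(fx1$eval$outcome * log(p01) +
                (1 - fx1$eval$outcome) * log1p(-p01)))
  expect_equal(unname(ex1), L_e - L_f, tolerance = 1e-12)

  expect_error(exact_shapley(sage_fixture(beta = rep(0.1, 11), n = 600,
                                          seed = 25)$model, fx$eval, fx$bg),
               "d > 10")
})

test_that("the permutation estimator agrees with exact enumeration", {
  fx <- sage_fixture(beta = c(1, 0.5, 0, -0.7, 0.3, 0.2), seed = 26)
  ex <- exact_shapley(fx$model, fx$eval, fx$bg)
  res <- sage_values(fx$model, fx$eval,
                     sage_config(eval_rows = 150, n_permutations = 300, seed = 5),
                     background = fx$bg)
  for (v in names(ex))
    expect_lt(abs(res$value[[v]] - ex[[v]]), 3 * max(res$se[[v]], 1e-12),
              label = paste("permutation vs exact for", v))
  # Monte-Carlo efficiency: telescoping makes the identity exact
  expect_equal(sum(res$value), sum(ex), tolerance = 1e-10)
})

test_that("SE shrinks like 1/sqrt(permutation budget)", {
  fx <- sage_fixture(beta = c(0.8, -0.5, 0.3), seed = 27)
  lo <- sage_values(fx$model, fx$eval,
                    sage_config(eval_rows = 150, n_permutations = 50, seed = 6),
                    background = fx$bg)
  hi <- sage_values(fx$model, fx$eval,
                    sage_config(eval_rows = 150, n_permutations = 450, seed = 6),
                    background = fx$bg)
  ratio <- mean(lo$se / hi$se)
  expect_gt(ratio, 2)     # expected 3, allow Monte-Carlo slack
  expect_lt(ratio, 4.5)
})

test_that("model_reliance applies the absolute-value rule per VIF flag", {
  vif <- structure(data.frame(variable = c("a", "b", "c"), df = 1,
                              gvif = c(3, 1, 3), comparable = c(3, 1, 3),
                              flag = c(TRUE, FALSE, TRUE)),
                   class = c("vif_report", "data.frame"))
  mr <- model_reliance(c(a = -0.02, b = -0.02, c = 0.05),
                       c(a = 0.01, b = 0.01, c = 0.01), vif)
  expect_equal(mr$mr, c(a = 0.02, b = -0.02, c = 0.05))
  expect_equal(mr$sigma, c(a = 0.01, b = 0.01, c = 0.01))
})

test_that("ensemble importance is aligned, reproducible and order-invariant", {
  ch <- make_gauss_cohort(1000, beta = c(0.9, -0.6), seed = 28)
  ch <- split_cohort(ch, c(0.6, 0.2, 0.2), seed = 1)
  ch <- impute_training_median(ch)
  m <- fit_optimal(ch)
  vif <- generalized_vif(ch)
  ens <- sample_nearly_optimal(m, ch, sampler_config(M = 4, u = 1, seed = 2))
  val <- vicscore:::cohort_subset(ch, "validation")
  cfg <- sage_config(eval_rows = 100, background_rows = 50,
                     n_permutations = 20, seed = 4)
  imp <- ensemble_importance(ens, val, vif, cfg, template = m)
  expect_equal(dim(imp$values), c(4L, 2L))
  expect_identical(colnames(imp$values), c("x1", "x2"))
  expect_equal(imp$loss_ratio, ens$loss_ratio)
  # re-running reproduces the matrix exactly; each member's row depends only
  # on its own substream, so a member re-scored in isolation matches its row
  imp2 <- ensemble_importance(ens, val, vif, cfg, template = m)
  expect_identical(imp$values, imp2$values)
  m3 <- m
  m3$intercept <- ens$coefficients[3, 1]
  m3$coefficients <- ens$coefficients[3, -1]
  cfg3 <- cfg; cfg3$seed <- vicscore:::substream_seed(cfg$seed, "sage_model", 3)
  solo <- sage_values(m3, val, cfg3,
                      background = vicscore:::resolve_background(NULL, val, cfg))
  expect_equal(unname(imp$values[3, ]), unname(solo$value))
})
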