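imp_stub <- function(values, ses) {
  structure(list(values = values, se = ses,
                 abs_flag = setNames(rep(FALSE, ncol(values)), colnames(values)),
                 loss_ratio = rep(1.01, nrow(values)),
                 variables = colnames(values)),
            class = "importance_matrix")
}

test_that("homogeneous inputs reduce to the closed-form fixed-effect pool", {
  M <- 30
  vals <- matrix(0.4, M, 1, dimnames = list(NULL, "v"))
  ses <- matrix(0.05, M, 1, dimnames = list(NULL, "v"))
  p <- pool_random_effects(imp_stub(vals, ses))
  expect_equal(p$mean, 0.4)
  expect_equal(p$tau2, 0)
  half <- qt(0.975, M - 2) * 0.05 / sqrt(M)
  expect_equal(p$pi_lower, 0.4 - half)
  expect_equal(p$pi_upper, 0.4 + half)
  expect_true(p$significant)
})

test_that("an all-zero variable yields the degenerate zero-length PI", {
  M <- 20
  vals <- matrix(c(rep(0, M), rnorm(M, 0.3, 0.02)), M, 2,
                 dimnames = list(NULL, c("zeroed", "real")))
  ses <- matrix(c(rep(0, M), rep(0.02, M)), M, 2,
                dimnames = list(NULL, c("zeroed", "real")))
  p <- pool_random_effects(imp_stub(vals, ses))
  z <- p[p$variable == "zeroed", ]
  expect_equal(z$mean, 0)
  expect_equal(z$pi_lower, 0)
  expect_equal(z$pi_upper, 0)
  expect_false(z$significant)
})

test_that("DerSimonian-Laird pooling matches the reference meta-analysis", {
  set.seed(33)
  M <- 100
  theta <- rnorm(M, 0.5, 0.1)           # true between-model tau = 0.1
  sigma <- rep(0.05, M)
  y <- rnorm(M, theta, sigma)
  vals <- matrix(y, M, 1, dimnames = list(NULL, "v"))
  ses <- matrix(sigma, M, 1, dimnames = list(NULL, "v"))
  p <- pool_random_effects(imp_stub(vals, ses))
  expect_gt(p$tau2, 0.005); expect_lt(p$tau2, 0.02)
  expect_lt(abs(p$mean - 0.5), 0.03)

  ref <- metafor::rma(yi = y, sei = sigma, method = "DL")
  expect_equal(p$mean, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(p$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(p$se, ref$se, tolerance = 1e-10)
})

test_that("pairwise win counts follow the normal difference test", {
  expect_equal(unname(pairwise_wins(c(0.5, 0.1), c(0.1, 0.1))), c(1L, 0L))
  expect_equal(unname(pairwise_wins(c(0.3, 0.3), c(0.05, 0.05))), c(0L, 0L))
  expect_equal(unname(pairwise_wins(c(4, 3, 2, 1), rep(1e-9, 4))),
               c(3L, 2L, 1L, 0L))
  # zero-SE pairs fall back to strict value comparison
  expect_equal(unname(pairwise_wins(c(0.2, 0.1), c(0, 0))), c(1L, 0L))
  # borderline z below the cutoff is not a win
  expect_equal(unname(pairwise_wins(c(0.27, 0.1), c(0.1, 0.1))), c(0L, 0L))
})

test_that("competition ranking uses the smallest available tied rank", {
  expect_equal(unname(rank_within_model(c(3, 3, 1, 0))), c(1L, 1L, 3L, 4L))
  expect_equal(unname(rank_within_model(c(0, 0, 0))), c(1L, 1L, 1L))
  expect_equal(unname(rank_within_model(c(2, 1, 0))), c(1L, 2L, 3L))
})

test_that("ensemble ranking averages per-model ranks and filters by PI", {
  set.seed(34)
  M <- 40
  vals <- cbind(dominant = rnorm(M, 0.5, 0.01),
                mid = rnorm(M, 0.10, 0.01),
                weak = rnorm(M, 0.002, 0.004),
                negative = rnorm(M, -0.05, 0.01))
  ses <- matrix(0.005, M, 4, dimnames = list(NULL, colnames(vals)))
  imp <- imp_stub(vals, ses)
  pooled <- pool_random_effects(imp)
  rk <- ensemble_rank(imp, pooled)
  expect_equal(rk$average_rank[["dominant"]], 1)
  expect_equal(rk$ordering[1], "dominant")
  expect_identical(rk$retained,
                   rk$ordering[setNames(pooled$significant, pooled$variable)[rk$ordering]])
  expect_false("negative" %in% rk$retained)
  # never retains a variable with non-positive pooled mean
  expect_true(all(setNames(pooled$mean, pooled$variable)[rk$retained] > 0))

  # ordering is invariant to permuting the model rows
  perm <- sample(M)
  imp_p <- imp_stub(vals[perm, ], ses[perm, ])
  expect_identical(ensemble_rank(imp_p, pool_random_effects(imp_p))$ordering,
                   rk$ordering)
})

test_that("importance plots are written and degenerate variables omitted", {
  set.seed(35)
  M <- 15
  vals <- cbind(a = rnorm(M, 0.3, 0.03), b = rnorm(M, 0.05, 0.02),
                zeroed = rep(0, M))
  ses <- matrix(c(rep(0.02, 2 * M), rep(0, M)), M, 3,
                dimnames = list(NULL, colnames(vals)))
  imp <- imp_stub(vals, ses)
  pooled <- pool_random_effects(imp)
  dir <- withr::local_tempdir()
  expect_message(paths <- plot_importance(pooled, imp, dir), "not plotted")
  expect_length(paths, 2L)
  expect_true(all(file.exists(paths)))
})
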