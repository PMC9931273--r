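test_that("random forest ranking puts the informative variable first", {
  set.seed(41)
  n <- 3000
  df <- data.frame(signal = rnorm(n), noise = rnorm(n))
  df$outcome <- rbinom(n, 1, plogis(1.5 * df$signal))
  ch <- as_cohort(df, list(var_schema("signal", "continuous"),
                           var_schema("noise", "continuous")))
  r1 <- rank_by_random_forest(ch, n_trees = 100, seed = 3)
  expect_identical(r1[1], "signal")
  expect_identical(r1, rank_by_random_forest(ch, n_trees = 100, seed = 3))
})

test_that("quantile cuts land on the training quantiles", {
  set.seed(42)
  df <- data.frame(u = runif(20000), outcome = rbinom(20000, 1, 0.3))
  ch <- as_cohort(df, list(var_schema("u", "continuous")))
  cv <- derive_cuts(ch, "u")
  expect_equal(cv$cuts$u, c(0.05, 0.2, 0.8, 0.95), tolerance = 0.02)

  # degenerate distribution: duplicate cuts collapse
  df2 <- data.frame(v = c(rep(1, 200), 50), outcome = rbinom(201, 1, 0.5))
  ch2 <- as_cohort(df2, list(var_schema("v", "continuous")))
  cv2 <- derive_cuts(ch2, "v")
  expect_lte(length(cv2$cuts$v), 1L)

  df3 <- data.frame(w = rep(2, 50), outcome = rbinom(50, 1, 0.5))
  ch3 <- as_cohort(df3, list(var_schema("w", "continuous")))
  expect_error(derive_cuts(ch3, "w"), "categorization error")
})

test_that("k-means cuts are midpoints between cluster centers", {
  df <- data.frame(x = c(0:9, 100:109), outcome = rep(c(0, 1), 10))
  ch <- as_cohort(df, list(var_schema("x", "continuous")))
  cv <- derive_cuts(ch, "x", method = "kmeans", k = 2)
  expect_equal(cv$cuts$x, 54.5)
})

test_that("point scaling and largest-remainder repair follow the stated rule", {
  shifted <- list(a = c(low = 0, mid = 0.5, high = 1.0), b = c(no = 0, yes = 0.25))
  sc <- vicscore:::scale_points(shifted, cap = 100)
  expect_equal(sc$points$a, c(low = 0, mid = 40, high = 80))
  expect_equal(sc$points$b, c(no = 0, yes = 20))
  expect_equal(sum(vapply(sc$points, max, 0)), 100)

  # awkward fractions: the repair still reaches the cap exactly
  shifted2 <- list(a = c(0, 0.31), b = c(0, 0.27), c = c(0, 0.15))
  sc2 <- vicscore:::scale_points(shifted2, cap = 100)
  expect_equal(sum(vapply(sc2$points, max, 0)), 100)
  expect_true(all(unlist(sc2$points) >= 0))
})

test_that("generated scoring tables satisfy the scorecard invariants", {
  g <- generate_cohort(default_ehr_spec(2500, seed = 43))
  ch <- impute_training_median(split_cohort(g$cohort, seed = 1))
  vars <- c("ed_visits", "sodium", "renal_disease", "triage")
  cuts <- derive_cuts(ch, vars)
  tab <- suppressWarnings(assign_points(ch, vars, cuts, cap = 100))
  expect_equal(max_total(tab), 100L)
  expect_true(all(tab$table$points >= 0))
  expect_true(all(tab$table$points == round(tab$table$points)))
  for (v in vars)
    expect_equal(min(tab$table$points[tab$table$variable == v]), 0L)

  # integer score tracks the categorized logistic model's discrimination
  val <- vicscore:::cohort_subset(ch, "validation")
  sc <- score_cohort(tab, val)
  cat_tr <- vicscore:::categorize_data(vicscore:::cohort_subset(ch, "train"), vars, tab$cuts)
  cat_tr$..y <- vicscore:::cohort_subset(ch, "train")$outcome
  fit <- glm(..y ~ ., family = binomial(), data = cat_tr)
  cat_val <- vicscore:::categorize_data(val, vars, tab$cuts)
  auc_model <- auc(predict(fit, newdata = cat_val, type = "response"), val$outcome)
  expect_lt(abs(auc(sc, val$outcome) - auc_model), 0.03)
})

test_that("a single binary variable yields the degenerate 0/100 scorecard", {
  ch <- make_binary_cohort(2000, p0 = 0.2, p1 = 0.7, seed = 44)
  tab <- assign_points(ch, "exposure", derive_cuts(ch, "exposure"), cap = 100)
  expect_equal(sort(tab$table$points), c(0L, 100L))
})

test_that("the published worked-example scorecard passes the invariant checks", {
  tab <- published_scorecard()
  expect_equal(max_total(tab), 100L)
  expect_true(all(tab$table$points >= 0))
  for (v in tab$variables)
    expect_equal(min(tab$table$points[tab$table$variable == v]), 0L)

  sickest <- list(ed_visits = 5, metastatic_cancer = "Yes", age = 90,
                  sodium = 120, renal_disease = "Yes", ed_triage = "P1")
  expect_identical(compute_score(tab, sickest), 100L)
  healthiest <- list(ed_visits = 0, metastatic_cancer = "No", age = 30,
                     sodium = 140, renal_disease = "No", ed_triage = "P3 and P4")
  expect_identical(compute_score(tab, healthiest), 4L)

  # interval matching is left-closed: age 85 scores the >=85 row
  expect_identical(compute_score(tab, modifyList(healthiest, list(age = 85))),
                   19L)
  expect_error(compute_score(tab, healthiest[-1]), "no value")

  empty <- scoring_table_from_df(data.frame(variable = character(0),
                                            level = character(0),
                                            points = integer(0)))
  expect_identical(compute_score(empty, list()), 0L)
})

test_that("the parsimony curve stops growing at small AUC increments", {
  set.seed(45)
  n <- 4000
  df <- data.frame(signal = rnorm(n), noise = rnorm(n))
  df$outcome <- rbinom(n, 1, plogis(-1 + 1.6 * df$signal))
  ch <- as_cohort(df, list(var_schema("signal", "continuous"),
                           var_schema("noise", "continuous")))
  ch <- impute_training_median(split_cohort(ch, seed = 2))
  pc <- parsimony_curve(c("signal", "noise"), ch)
  expect_equal(pc$suggested, 1L)
  expect_lt(pc$curve$auc[2] - pc$curve$auc[1], 0.01)

  pc1 <- parsimony_curve("signal", ch)
  expect_equal(nrow(pc1$curve), 1L)
  expect_equal(pc1$suggested, 1L)
})

test_that("fine-tuning honours overrides and validates them", {
  g <- generate_cohort(default_ehr_spec(2500, seed = 46))
  ch <- impute_training_median(split_cohort(g$cohort, seed = 3))
  vars <- c("sodium", "renal_disease")
  tab <- suppressWarnings(assign_points(ch, vars, derive_cuts(ch, vars), cap = 100))

  # idempotence: overriding with the automatic cuts reproduces the table
  tab2 <- fine_tune(tab, list(sodium = tab$cuts$cuts$sodium), ch)
  expect_equal(tab2$table, tab$table)

  # merging two intervals drops one row and keeps the invariants
  tab3 <- fine_tune(tab, list(sodium = tab$cuts$cuts$sodium[-1]), ch)
  expect_equal(sum(tab3$table$variable == "sodium"),
               sum(tab$table$variable == "sodium") - 1L)
  expect_equal(max_total(tab3), 100L)

  expect_error(fine_tune(tab, list(sodium = c(135, 130)), ch),
               "strictly increasing")
  expect_error(fine_tune(tab, list(sodium = c(30, 31)), ch), "empty")
})

test_that("compute_score is monotone when a variable's points are monotone", {
  tab <- published_scorecard()
  base <- list(ed_visits = 0, metastatic_cancer = "No", age = 30,
               sodium = 140, renal_disease = "No", ed_triage = "P3 and P4")
  scores <- vapply(c(0, 1, 2, 3, 10), function(v)
    compute_score(tab, modifyList(base, list(ed_visits = v))), 0L)
  expect_true(all(diff(scores) >= 0))
})
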