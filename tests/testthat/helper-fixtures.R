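# Fixture builders shared across test files. Everything is generated in
# code; the only on-disk fixture is the published worked-example scorecard.

# Cohort with a single binary predictor: P(y=1 | x=1) = p1, P(y=1 | x=0) = p0.
make_binary_cohort <- function(n, p0 = 0.2, p1 = 0.8, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, ifelse(x == 1, p1, p0))
  as_cohort(data.frame(exposure = x, outcome = y),
            list(var_schema("exposure", "binary")))
}

# Cohort of independent standard-normal predictors with a logistic outcome.
make_gauss_cohort <- function(n, beta, intercept = 0, seed = 1,
                              names = paste0("x", seq_along(beta))) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), nrow = n)
  colnames(X) <- names
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  df <- as.data.frame(X)
  df$outcome <- y
  as_cohort(df, lapply(names, var_schema, vtype = "continuous"))
}

# Mark every row of a cohort as training (for fit-only tests).
all_train <- function(cohort) {
  cohort$split <- factor(rep("train", nrow(cohort$data)),
                         levels = levels(cohort$split))
  cohort
}

# The published worked-example readmission scorecard (6 variables, cap 100).
published_scorecard <- function() {
  path <- system.file("extdata", "published_readmission_scorecard.csv",
                      package = "vicscore")
  df <- read.csv(path, stringsAsFactors = FALSE)
  scoring_table_from_df(df, cap = 100)
}

# Shared study-condition runs (computed once per test session). Conditions
# are documented in the methods vignette: n = 5000, M = 100 models in the
# 5% band, SAGE on the leading 1750 validation rows of a validation-heavy
# split (the stable-evaluation-sample convention at desk scale).
study_conditions <- function(gen, seed = 7) {
  vic_score(gen$cohort, seed = seed, fractions = c(0.45, 0.35, 0.20),
            sampler = sampler_config(M = 100),
            sage = sage_config(eval_rows = 1750, background_rows = 100,
                               n_permutations = 48),
            n_resamples = 200)
}

# Full 11-variable default cohort (includes the collinear chloride column);
# used for the scorecard and sparsity checks.
shared_study_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_cohort(default_ehr_spec(5000, seed = 2024))
      cache <<- list(gen = gen, fit = study_conditions(gen))
    }
    cache
  }
})

# Plain 5-signal + 5-noise cohort (no collinear pair); used for the
# parameter-recovery / significance-filtering check, where no variable has
# a substitute inside the loss band.
shared_recovery_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_cohort(default_ehr_spec(5000, seed = 1,
                                              collinear_pair = FALSE))
      cache <<- list(gen = gen, fit = study_conditions(gen))
    }
    cache
  }
})
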