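# End-to-end workflow: split -> impute -> optimal fit -> VIF -> Rashomon
# ensemble -> per-model SAGE -> random-effects pooling -> ensemble ranking
# + significance filter -> parsimony curve -> integer scorecard -> test
# evaluation. vic_score() is the front door; run_pipeline() adds on-disk
# run artifacts and a reproducibility manifest.

#' Fit a sparse integer risk score with ensemble variable importance
#'
#' The full workflow in one call. Variables are ranked either by the
#' ShapleyVIC ensemble ranking over nearly-optimal logistic models
#' (significance-filtered by the 95% prediction interval) or by a random
#' forest baseline; a parsimony curve on the validation split picks the
#' sparsest adequate model; the integer scorecard is evaluated on the test
#' split.
#'
#' @param cohort A `cohort` (split labels assigned here when absent).
#' @param seed Root seed; all stage seeds derive from it.
#' @param fractions Train/validation/test proportions.
#' @param ranking `"shapleyvic"` or `"random_forest"`.
#' @param sampler A [sampler_config()] (its seed is overridden by `seed`).
#' @param sage A [sage_config()] (seed likewise derived).
#' @param tune Tune the sampler scale `u` on a pilot sample before the main
#'   run (default `TRUE`).
#' @param alpha Significance level for pairwise rank wins.
#' @param cuts_method Categorization method (`"quantile"` or `"kmeans"`).
#' @param cap Maximum attainable score total (default 100).
#' @param parsimony_threshold AUC-increment stopping rule (default 0.01).
#' @param n_size Override the parsimony suggestion with a fixed model size.
#' @param n_resamples Bootstrap resamples for the test AUC CI.
#' @param progress Emit progress messages.
#' @return An object of class `vic_score` with the fitted scorecard
#'   (`$scoring_table`), the importance analysis (`$pooled`, `$ranking`,
#'   `$importance`, `$ensemble`, `$vif`), the parsimony curve and the test
#'   evaluation (`$evaluation`), plus all configuration used.
#' @export
vic_score <- function(cohort, seed = 1L,
                      fractions = c(0.7, 0.1, 0.2),
                      ranking = c("shapleyvic", "random_forest"),
                      sampler = sampler_config(),
                      sage = sage_config(),
                      tune = TRUE,
                      alpha = 0.05,
                      cuts_method = "quantile",
                      cap = 100L,
                      parsimony_threshold = 0.01,
                      n_size = NULL,
                      n_resamples = 1000L,
                      progress = FALSE) {
  ranking <- match.arg(ranking)
  stopifnot(inherits(cohort, "cohort"))
  say <- function(...) if (progress) message(...)

  if (!any(cohort$split != "unassigned")) {
    say("* splitting cohort ", paste(fractions, collapse = "/"))
    cohort <- split_cohort(cohort, fractions, seed = substream_seed(seed, "split"))
  }
  cohort <- impute_training_median(cohort)
  val <- cohort_subset(cohort, "validation")
  test <- cohort_subset(cohort, "test")

  say("* fitting optimal logistic regression")
  optimal <- fit_optimal(cohort)
  vif <- generalized_vif(cohort)

  ensemble <- importance <- pooled <- rank_obj <- NULL
  if (ranking == "shapleyvic") {
    sampler$seed <- substream_seed(seed, "sampler")
    if (tune) {
      say("* tuning sampler scale u")
      sampler <- suppressWarnings(tune_scale(optimal, cohort, sampler))
    }
    say("* sampling ", sampler$M, " nearly-optimal models (u = ", sampler$u, ")")
    ensemble <- sample_nearly_optimal(optimal, cohort, sampler)

    sage$seed <- substream_seed(seed, "sage")
    tr <- cohort_subset(cohort, "train")
    bg_idx <- with_seed(substream_seed(seed, "background"),
                        sample.int(nrow(tr$data),
                                   min(sage$background_rows, nrow(tr$data))))
    background <- cohort_subset(tr, bg_idx)
    say("* SAGE importance for ", sampler$M, " models")
    importance <- ensemble_importance(ensemble, val, vif, sage,
                                      background = background,
                                      template = optimal, progress = progress)
    pooled <- pool_random_effects(importance)
    rank_obj <- ensemble_rank(importance, pooled, alpha = alpha)
    ranked_vars <- rank_obj$retained
    if (!length(ranked_vars))
      stop2("no variable had significant overall importance; nothing to score")
  } else {
    say("* random-forest variable ranking")
    ranked_vars <- rank_by_random_forest(cohort, seed = substream_seed(seed, "rf"))
  }

  say("* parsimony curve over ", length(ranked_vars), " ranked variables")
  cuts <- derive_cuts(cohort, ranked_vars, method = cuts_method,
                      seed = substream_seed(seed, "cuts"))
  curve <- parsimony_curve(ranked_vars, cohort, cuts = cuts, cap = cap,
                           threshold = parsimony_threshold)
  size <- n_size %||% curve$suggested
  final_vars <- ranked_vars[seq_len(min(size, length(ranked_vars)))]

  say("* final scorecard on ", length(final_vars), " variables")
  scoring <- suppressWarnings(assign_points(cohort, final_vars, cuts, cap = cap))
  test_scores <- score_cohort(scoring, test)
  evaluation <- evaluate_score(test_scores, test$outcome,
                               n_resamples = n_resamples,
                               seed = substream_seed(seed, "bootstrap"))

  structure(list(
    scoring_table = scoring,
    evaluation = evaluation,
    parsimony = curve,
    ranked_variables = ranked_vars,
    final_variables = final_vars,
    pooled = pooled, ranking = rank_obj, importance = importance,
    ensemble = ensemble, vif = vif, optimal = optimal,
    cohort = cohort,
    config = list(seed = seed, fractions = fractions, ranking = ranking,
                  sampler = if (ranking == "shapleyvic") sampler else NULL,
                  sage = if (ranking == "shapleyvic") sage else NULL,
                  alpha = alpha, cuts_method = cuts_method, cap = cap,
                  parsimony_threshold = parsimony_threshold)
  ), class = "vic_score")
}

#' @export
print.vic_score <- function(x, ...) {
  cat("Integer risk score (", x$config$ranking, " ranking, ",
      length(x$final_variables), " of ", length(x$cohort$schema),
      " candidate variables)\n\n", sep = "")
  print(x$scoring_table)
  cat("\nTest-set performance:\n")
  print(x$evaluation)
  invisible(x)
}

#' @export
summary.vic_score <- function(object, ...) {
  x <- object
  cat("Workflow summary\n================\n")
  n <- table(x$cohort$split)
  cat("Cohort: n =", nrow(x$cohort$data), " (train", n[["train"]],
      "/ validation", n[["validation"]], "/ test", n[["test"]], ")\n")
  cat("Optimal model training loss:", format(x$optimal$training_loss, digits = 6),
      "nats/obs\n")
  if (!is.null(x$ensemble)) {
    cat("Ensemble: M =", nrow(x$ensemble$coefficients),
        " loss ratios <=", format(max(x$ensemble$loss_ratio), digits = 4),
        " acceptance", sprintf("%.3f", x$ensemble$diagnostics$acceptance_rate), "\n")
    cat("Significant variables:", sum(x$pooled$significant), "of",
        nrow(x$pooled), "\n")
  }
  cat("Suggested size:", x$parsimony$suggested,
      " Final variables:", paste(x$final_variables, collapse = ", "), "\n")
  cat(sprintf("Test AUC %.3f (95%% CI %.3f-%.3f)\n", x$evaluation$auc,
              x$evaluation$ci["lower"], x$evaluation$ci["upper"]))
  invisible(x)
}

#' @export
coef.vic_score <- function(object, ...) {
  setNames(object$scoring_table$table$points,
           paste(object$scoring_table$table$variable,
                 object$scoring_table$table$level, sep = ":"))
}

#' Predict integer scores (or threshold classifications) for new patients
#'
#' @param object A fitted `vic_score`.
#' @param newdata Data frame with the scorecard variables (missing
#'   continuous values are filled with stored training medians).
#' @param type `"score"` for the integer total, `"class"` for the 0/1
#'   prediction at the stored optimal threshold.
#' @param ... Unused.
#' @return Integer vector of scores or classes.
#' @export
predict.vic_score <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  med <- object$cohort$medians
  for (v in intersect(names(med), names(newdata)))
    newdata[[v]][is.na(newdata[[v]])] <- med[[v]]
  sub_schema <- object$cohort$schema[object$final_variables]
  df <- newdata[names(sub_schema)]
  df$outcome <- 0L
  ch <- suppressWarnings(as_cohort(df, sub_schema))
  s <- score_cohort(object$scoring_table, ch)
  if (type == "score") s else as.integer(s >= object$evaluation$threshold)
}

#' @export
plot.vic_score <- function(x, which = c("parsimony", "importance"), ...) {
  which <- match.arg(which)
  if (which == "parsimony") {
    plot(x$parsimony, ...)
  } else {
    if (is.null(x$pooled)) stop2("no importance analysis in this fit")
    dir <- tempfile("vic_plots_")
    paths <- plot_importance(x$pooled, x$importance, dir)
    message("importance figures written to: ", paste(paths, collapse = ", "))
    invisible(paths)
  }
}

#' Run the workflow from a config and persist run artifacts
#'
#' Thin orchestration over [vic_score()]: loads the cohort and schema when
#' paths are given, runs the workflow, and writes every intermediate
#' artifact (split assignment, ensemble CSV, importance CSV, pooled CSV,
#' figures, scoring table CSV/Markdown, evaluation JSON) plus a manifest
#' (config, seeds, package version) to the output directory.
#'
#' @param config Named list (or path to a YAML file) with entries matching
#'   [vic_score()] arguments plus `cohort`/`schema`/`outcome` paths or
#'   in-memory objects and `out_dir`.
#' @return The fitted `vic_score`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop2("config must name an out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cohort <- config$cohort
  if (is.character(cohort)) {
    schema <- if (is.character(config$schema)) read_schema(config$schema)
              else validate_schema(config$schema)
    cohort <- load_cohort(cohort, schema, outcome = config$outcome %||% "outcome")
  }
  seed <- config$seed %||% 1L
  args <- config[intersect(names(config),
                           setdiff(names(formals(vic_score)), c("cohort", "sampler", "sage")))]
  sampler <- do.call(sampler_config, config$sampler %||% list())
  sage <- do.call(sage_config, config$sage %||% list())
  fit <- do.call(vic_score, c(list(cohort = cohort, sampler = sampler, sage = sage), args))

  write_split(fit$cohort, file.path(out_dir, "split.csv"))
  write_model(fit$optimal, file.path(out_dir, "optimal_model.json"))
  if (!is.null(fit$ensemble)) {
    ens <- data.frame(model_id = seq_along(fit$ensemble$loss),
                      loss = fit$ensemble$loss,
                      loss_ratio = fit$ensemble$loss_ratio)
    utils::write.csv(cbind(ens, fit$ensemble$coefficients),
                     file.path(out_dir, "ensemble.csv"), row.names = FALSE)
    jsonlite::write_json(fit$ensemble$diagnostics,
                         file.path(out_dir, "sampler_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_importance(fit$importance, file.path(out_dir, "importance.csv"))
    write_pooled(fit$pooled, fit$ranking, file.path(out_dir, "pooled.csv"))
    plot_importance(fit$pooled, fit$importance, out_dir)
  }
  write_scoring_table(fit$scoring_table, file.path(out_dir, "scoring_table.csv"),
                      file.path(out_dir, "scoring_table.md"))
  p <- open_device(file.path(out_dir, "parsimony"))
  plot(fit$parsimony); grDevices::dev.off()
  jsonlite::write_json(list(
    auc = fit$evaluation$auc, ci = as.list(fit$evaluation$ci),
    threshold = fit$evaluation$threshold,
    metrics = as.list(fit$evaluation$metrics),
    n_variables = length(fit$final_variables),
    variables = fit$final_variables
  ), file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("vicscore")),
    seed = seed, config = fit$config,
    timestamp = format(Sys.time(), tz = "UTC")
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(fit)
}

#' Compare fitted scores on a common test split
#'
#' @param fits Named list of `vic_score` objects fitted on the same cohort
#'   split (checked via the split assignment).
#' @param test Optional explicit test `cohort`; defaults to the first fit's
#'   test split.
#' @return Data frame: model, number of variables, AUC, CI, threshold
#'   metrics.
#' @export
compare_models <- function(fits, test = NULL) {
  stopifnot(length(fits) >= 1)
  splits <- lapply(fits, function(f) as.character(f$cohort$split))
  if (length(unique(splits)) > 1L)
    stop2("comparison error: fits use different cohort splits")
  test <- test %||% cohort_subset(fits[[1]]$cohort, "test")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    sc <- score_cohort(f$scoring_table, test)
    ev <- evaluate_score(sc, test$outcome, n_resamples = f$evaluation$n_resamples,
                         seed = f$evaluation$seed)
    data.frame(model = names(fits)[i] %||% paste0("model_", i),
               n_variables = length(f$final_variables),
               auc = ev$auc, ci_lower = ev$ci["lower"], ci_upper = ev$ci["upper"],
               accuracy = ev$metrics["accuracy"],
               sensitivity = ev$metrics["sensitivity"],
               specificity = ev$metrics["specificity"],
               f1 = ev$metrics["f1"], row.names = NULL)
  })
  do.call(rbind, rows)
}
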