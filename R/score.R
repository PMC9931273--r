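# Integer scorecard construction: categorize continuous predictors, refit a
# logistic model on the categorized design, shift per-variable coefficients
# so every variable has a zero reference category, scale globally so the
# maximum attainable total equals the cap, round to integers, and repair
# rounding drift by largest-remainder adjustment.

#' Rank candidate variables with a random forest
#'
#' Impurity-decrease (mean decrease in Gini) importance from a random
#' forest classifier trained on the raw, uncategorized variables; the
#' machine-learning baseline ranking for the scorecard pipeline.
#'
#' @param cohort A split `cohort`; training rows are used.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed (deterministic ranking).
#' @return Character vector of variable names in descending importance.
#' @export
rank_by_random_forest <- function(cohort, n_trees = 100L, seed = 1L) {
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort
  rf <- with_seed(substream_seed(seed, "rf_rank"),
    randomForest::randomForest(x = train$data, y = factor(train$outcome),
                               ntree = n_trees))
  imp <- rf$importance[, "MeanDecreaseGini"]
  names(sort(imp, decreasing = TRUE))
}

#' Derive categorization cut points
#'
#' Continuous variables are categorized into left-closed, right-open
#' intervals. The quantile method places interior cuts at training quantiles
#' (default 0.05, 0.2, 0.8, 0.95, giving five bins); the k-means method
#' places cuts at midpoints between sorted 1-D cluster centers. Duplicate
#' cuts and cuts outside the open interior of the training range are
#' collapsed/dropped.
#'
#' @param cohort A `cohort`; training rows are used.
#' @param variables Variables to cover (default: all).
#' @param method `"quantile"` or `"kmeans"`.
#' @param quantiles Increasing probabilities in (0,1) for the quantile method.
#' @param k Number of clusters for the k-means method.
#' @param seed Seed for k-means initialization.
#' @return An object of class `cut_vector`: per continuous variable the
#'   ordered interior cuts; per categorical variable the level order.
#' @export
derive_cuts <- function(cohort, variables = NULL,
                        method = c("quantile", "kmeans"),
                        quantiles = c(0.05, 0.2, 0.8, 0.95), k = 5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "quantile" &&
      (any(quantiles <= 0) || any(quantiles >= 1) || is.unsorted(quantiles, strictly = TRUE)))
    stop2("quantiles must be strictly increasing within (0,1)")
  if (method == "kmeans" && k < 2) stop2("k-means categorization needs k >= 2")
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort
  variables <- variables %||% names(train$schema)
  cuts <- list(); level_order <- list()
  for (v in variables) {
    vs <- train$schema[[v]]
    if (vs$vtype == "categorical") { level_order[[v]] <- vs$levels; next }
    if (vs$vtype == "binary") next
    x <- train$data[[v]]
    if (length(unique(x)) < 2L)
      stop2("categorization error: variable '", v, "' has < 2 distinct values")
    cc <- if (method == "quantile") {
      unname(quantile(x, probs = quantiles, type = 7))
    } else {
      centers <- with_seed(substream_seed(seed, "kmeans_cuts", match(v, variables)), {
        km <- kmeans(x, centers = min(k, length(unique(x))), nstart = 10)
        sort(as.vector(km$centers))
      })
      (centers[-1] + centers[-length(centers)]) / 2
    }
    cc <- sort(unique(cc))
    cc <- cc[cc > min(x) & cc <= max(x)]   # drop cuts that cannot split the data
    cuts[[v]] <- cc
  }
  structure(list(cuts = cuts, level_order = level_order,
                 method = method,
                 params = if (method == "quantile") list(quantiles = quantiles)
                          else list(k = k)),
            class = "cut_vector")
}

# Scale shifted per-variable category coefficients to integer points:
# one global factor cap / sum(per-variable maxima), round, then repair
# rounding drift on the per-variable maxima (largest-remainder order) so the
# maximum attainable total equals the cap exactly.
scale_points <- function(shifted, cap) {
  maxima <- vapply(shifted, max, 0)
  total_max <- sum(maxima)
  if (total_max <= 0) stop2("no positive coefficient spread; cannot scale points")
  s <- cap / total_max
  points <- lapply(shifted, function(x) round(s * x))

  raw_max <- s * maxima
  rounded_max <- vapply(points, max, 0)
  drift <- cap - sum(rounded_max)
  if (drift != 0) {
    vars <- names(shifted)
    rem <- raw_max - rounded_max
    ord <- order(rem, decreasing = drift > 0)
    i <- 1
    while (drift != 0 && i <= length(ord) * 2) {
      v <- vars[ord[(i - 1) %% length(ord) + 1]]
      step <- sign(drift)
      mx_idx <- which.max(points[[v]])
      if (step < 0 && points[[v]][mx_idx] <= 0) { i <- i + 1; next }
      points[[v]][mx_idx] <- points[[v]][mx_idx] + step
      drift <- drift - step
      i <- i + 1
    }
    if (drift != 0) stop2("could not repair rounding drift to reach cap ", cap)
  }
  list(points = points, scale = s)
}

interval_label <- function(lower, upper) {
  if (is.infinite(lower) && is.infinite(upper)) "any"
  else if (is.infinite(lower)) paste0("<", format(upper))
  else if (is.infinite(upper)) paste0(">=", format(lower))
  else paste0("[", format(lower), ", ", format(upper), ")")
}

# Categorize one continuous column by interior cuts ([A, B) convention).
cut_continuous <- function(x, cuts) {
  br <- c(-Inf, cuts, Inf)
  labs <- vapply(seq_len(length(br) - 1),
                 function(i) interval_label(br[i], br[i + 1]), "")
  cut(x, breaks = br, right = FALSE, labels = labs)
}

# Categorized data frame for the scorecard refit.
categorize_data <- function(cohort, variables, cuts) {
  out <- list()
  for (v in variables) {
    vs <- cohort$schema[[v]]
    out[[v]] <- switch(vs$vtype,
      continuous = cut_continuous(cohort$data[[v]], cuts$cuts[[v]] %||% numeric(0)),
      binary = factor(cohort$data[[v]], levels = c(0, 1)),
      categorical = factor(cohort$data[[v]],
                           levels = cuts$level_order[[v]] %||% vs$levels))
  }
  as.data.frame(out, optional = TRUE)
}

#' Assign integer points to categorized variables
#'
#' Fits a logistic regression on the categorized variables, shifts each
#' variable's category coefficients so its smallest is zero, scales all
#' shifted coefficients by `cap / sum(per-variable maxima)`, rounds to
#' integers, and repairs rounding drift by largest-remainder adjustment so
#' the maximum attainable total equals `cap` exactly. Categories empty in
#' training are merged into the adjacent lower interval with a warning
#' (or an error when `on_empty = "error"`, used by [fine_tune()]).
#'
#' @param cohort A split `cohort`; training rows are used for the refit.
#' @param variables Ordered variable list for the scorecard.
#' @param cuts A `cut_vector` covering the continuous variables.
#' @param cap Maximum attainable total score (default 100; must be >= the
#'   number of variables).
#' @param on_empty What to do with categories empty in training.
#' @return An object of class `scoring_table`.
#' @export
assign_points <- function(cohort, variables, cuts, cap = 100L,
                          on_empty = c("merge", "error")) {
  on_empty <- match.arg(on_empty)
  stopifnot(length(variables) >= 1)
  if (cap < length(variables))
    stop2("cap must be at least the number of variables")
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort

  # merge training-empty continuous bins into the adjacent lower interval
  cuts <- local({
    cc <- cuts
    for (v in variables) {
      if (train$schema[[v]]$vtype != "continuous") next
      repeat {
        kv <- cc$cuts[[v]] %||% numeric(0)
        if (!length(kv)) break
        tab <- table(cut_continuous(train$data[[v]], kv))
        empty <- which(tab == 0)
        if (!length(empty)) break
        k <- empty[1]
        bad <- interval_label(c(-Inf, kv)[k], c(kv, Inf)[k])
        if (on_empty == "error")
          stop2("empty training category for '", v, "': ", bad)
        warn2("merging empty training category for '", v, "': ", bad)
        cc$cuts[[v]] <- kv[-max(1L, k - 1L)]
      }
    }
    cc
  })

  cat_df <- categorize_data(train, variables, cuts)
  cat_df$..y <- train$outcome
  fit <- suppressWarnings(glm(..y ~ ., family = binomial(), data = cat_df,
                              control = list(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) stop2("refit error: categorized logistic fit did not converge")
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop2("refit error: separation in categorized fit")

  # per-variable category coefficients (reference level = 0)
  shifted <- list()
  for (v in variables) {
    levs <- levels(cat_df[[v]])
    nm <- paste0(v, levs)
    vals <- setNames(rep(0, length(levs)), levs)
    hit <- nm %in% names(cf)
    vals[levs[hit]] <- cf[nm[hit]]
    if (any(is.na(vals))) {
      warn2("inestimable category for '", v, "' treated as reference (0 points)")
      vals[is.na(vals)] <- 0
    }
    shifted[[v]] <- vals - min(vals)
  }

  scaled <- scale_points(shifted, cap)
  points <- scaled$points
  s <- scaled$scale

  rows <- do.call(rbind, lapply(variables, function(v) {
    levs <- names(points[[v]])
    vs <- train$schema[[v]]
    if (vs$vtype == "continuous") {
      kv <- cuts$cuts[[v]] %||% numeric(0)
      lower <- c(-Inf, kv); upper <- c(kv, Inf)
    } else {
      lower <- rep(NA_real_, length(levs)); upper <- rep(NA_real_, length(levs))
    }
    data.frame(variable = v, level = levs, lower = lower, upper = upper,
               points = as.integer(points[[v]]), stringsAsFactors = FALSE)
  }))

  structure(list(variables = variables, table = rows, cap = as.integer(cap),
                 cuts = cuts,
                 provenance = list(coefficients = cf, scale = s,
                                   shifted = shifted)),
            class = "scoring_table")
}

#' @export
print.scoring_table <- function(x, ...) {
  cat("Integer scoring table (max attainable total = ",
      max_total(x), ")\n", sep = "")
  for (v in x$variables) {
    rows <- x$table[x$table$variable == v, ]
    cat(v, "\n", sep = "")
    for (i in seq_len(nrow(rows)))
      cat(sprintf("  %-14s %3d\n", rows$level[i], rows$points[i]))
  }
  invisible(x)
}

#' Maximum attainable total of a scoring table
#' @param table A `scoring_table`.
#' @return Integer maximum total score.
#' @export
max_total <- function(table) {
  sum(vapply(split(table$table$points, table$table$variable), max, 0L))
}

match_points <- function(rows, value) {
  if (!all(is.na(rows$lower))) {            # continuous: [A, B) matching
    x <- as.numeric(value)
    hit <- which(x >= rows$lower & x < rows$upper)
    if (length(hit) != 1L)
      stop2("internal error: value ", value, " matched ", length(hit), " intervals")
    rows$points[hit]
  } else {
    hit <- match(as.character(value), rows$level)
    if (is.na(hit)) stop2("input error: level '", value, "' not in scoring table for '",
                          rows$variable[1], "'")
    rows$points[hit]
  }
}

#' Compute a patient's integer risk score
#'
#' Sums the points matched by the patient's value for every scorecard
#' variable; continuous intervals use the left-closed, right-open
#' convention.
#'
#' @param table A `scoring_table`.
#' @param patient Named list (or one-row data frame) providing a value for
#'   every scorecard variable.
#' @return Integer total score.
#' @export
compute_score <- function(table, patient) {
  if (is.data.frame(patient)) patient <- as.list(patient)
  total <- 0L
  for (v in table$variables) {
    if (is.null(patient[[v]]) || is.na(patient[[v]]))
      stop2("input error: no value provided for '", v, "'")
    total <- total + match_points(table$table[table$table$variable == v, ], patient[[v]])
  }
  as.integer(total)
}

#' Compute integer risk scores for every row of a cohort
#'
#' Vectorized form of [compute_score()] used for AUC evaluation.
#'
#' @param table A `scoring_table`.
#' @param cohort A `cohort` containing all scorecard variables.
#' @return Integer vector of total scores, one per row.
#' @export
score_cohort <- function(table, cohort) {
  n <- nrow(cohort$data)
  total <- integer(n)
  for (v in table$variables) {
    rows <- table$table[table$table$variable == v, ]
    x <- cohort$data[[v]]
    pts <- if (!all(is.na(rows$lower))) {
      idx <- findInterval(as.numeric(x), c(rows$lower[1], rows$upper))
      rows$points[pmin(pmax(idx, 1L), nrow(rows))]
    } else {
      rows$points[match(as.character(x), rows$level)]
    }
    if (anyNA(pts)) stop2("scoring error: unmatched value in '", v, "'")
    total <- total + pts
  }
  total
}

#' Validation-AUC parsimony curve over a ranked variable list
#'
#' Grows the scorecard one ranked variable at a time, recording the
#' validation AUC of the integer score at each step. The suggested model
#' size is the smallest i whose next step improves AUC by less than
#' `threshold` (default 0.01, the "<1%" convention); the full curve is kept
#' for manual override.
#'
#' @param ranked Ordered character vector of variables.
#' @param cohort A split `cohort` (train + validation used).
#' @param cuts Optional precomputed `cut_vector`; derived on the training
#'   split when omitted.
#' @param cap Score cap (default 100).
#' @param threshold AUC-increment stopping threshold (default 0.01).
#' @param method Categorization method when `cuts` is omitted.
#' @return An object of class `parsimony_curve`: a data frame (`step`,
#'   `variable`, `auc`), the suggested size and the threshold.
#' @export
parsimony_curve <- function(ranked, cohort, cuts = NULL, cap = 100L,
                            threshold = 0.01, method = "quantile") {
  stopifnot(length(ranked) >= 1)
  cuts <- cuts %||% derive_cuts(cohort, ranked, method = method)
  val <- cohort_subset(cohort, "validation")
  aucs <- numeric(length(ranked))
  for (i in seq_along(ranked)) {
    tab <- suppressWarnings(assign_points(cohort, ranked[seq_len(i)], cuts, cap = cap))
    aucs[i] <- auc(score_cohort(tab, val), val$outcome)
  }
  suggested <- length(ranked)
  if (length(ranked) > 1) {
    inc <- diff(aucs)
    small <- which(inc < threshold)
    if (length(small)) suggested <- small[1]
  }
  structure(list(curve = data.frame(step = seq_along(ranked), variable = ranked,
                                    auc = aucs, stringsAsFactors = FALSE),
                 suggested = suggested, threshold = threshold),
            class = "parsimony_curve")
}

#' @export
print.parsimony_curve <- function(x, ...) {
  cat("Parsimony curve (validation AUC; suggested size = ", x$suggested, ")\n",
      sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.parsimony_curve <- function(x, ...) {
  graphics::plot(x$curve$step, x$curve$auc, type = "b", pch = 16,
                 xlab = "number of variables", ylab = "validation AUC",
                 main = "Parsimony plot", ...)
  graphics::abline(v = x$suggested, lty = 2, col = "grey50")
}

#' Fine-tune scorecard cut points
#'
#' Re-categorizes selected continuous variables with user-supplied cut
#' points (e.g. clinically conventional thresholds), refits and re-assigns
#' points under the same cap. Non-overridden variables keep their automatic
#' cuts. An override that empties a training category is an error naming
#' the interval.
#'
#' @param table A `scoring_table`.
#' @param overrides Named list: variable -> strictly increasing cut vector.
#' @param cohort The training `cohort`.
#' @return A new `scoring_table`.
#' @export
fine_tune <- function(table, overrides, cohort) {
  cuts <- table$cuts
  for (v in names(overrides)) {
    ov <- overrides[[v]]
    if (is.unsorted(ov, strictly = TRUE))
      stop2("override for '", v, "' must be strictly increasing")
    if (!v %in% table$variables) stop2("'", v, "' is not in the scoring table")
    cuts$cuts[[v]] <- ov
  }
  assign_points(cohort, table$variables, cuts, cap = table$cap, on_empty = "error")
}

#' Write a scoring table as machine- and human-readable files
#'
#' @param table A `scoring_table`.
#' @param csv_path Output CSV (`variable`, `level`, `lower`, `upper`, `points`).
#' @param md_path Optional Markdown rendering using the `[A, B)` notation.
#' @export
write_scoring_table <- function(table, csv_path, md_path = NULL) {
  utils::write.csv(table$table, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    lines <- c("| Variable | Interval | Points |", "|---|---|---|")
    for (i in seq_len(nrow(table$table))) {
      r <- table$table[i, ]
      lines <- c(lines, sprintf("| %s | %s | %d |",
                                r$variable, r$level, r$points))
    }
    writeLines(lines, md_path)
  }
  invisible(csv_path)
}

#' Build a scoring table from a published-style table of rows
#'
#' Accepts a data frame with columns `variable`, `level`, `lower`, `upper`,
#' `points` (as written by [write_scoring_table()]) and wraps it as a
#' `scoring_table`, validating the scorecard invariants: nonnegative
#' integer points and at least one zero-point category per variable.
#'
#' @param df The rows.
#' @param cap Expected maximum attainable total (checked when not `NULL`).
#' @return A `scoring_table`.
#' @export
scoring_table_from_df <- function(df, cap = NULL) {
  stopifnot(all(c("variable", "level", "points") %in% names(df)))
  if (!nrow(df)) {
    return(structure(list(variables = character(0), table = df, cap = 0L,
                          cuts = NULL, provenance = list(source = "external")),
                     class = "scoring_table"))
  }
  df$lower <- df$lower %||% NA_real_
  df$upper <- df$upper %||% NA_real_
  if (any(df$points < 0) || any(df$points != round(df$points)))
    stop2("points must be nonnegative integers")
  for (v in unique(df$variable))
    if (min(df$points[df$variable == v]) != 0)
      stop2("variable '", v, "' lacks a zero-point category")
  tab <- structure(list(variables = unique(df$variable), table = df,
                        cap = NA_integer_, cuts = NULL,
                        provenance = list(source = "external")),
                   class = "scoring_table")
  tab$cap <- max_total(tab)
  if (!is.null(cap) && tab$cap != cap)
    stop2("max attainable total ", tab$cap, " != expected cap ", cap)
  tab
}
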