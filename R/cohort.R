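# Cohort container: typed predictor table + binary outcome + split labels.
# The variable schema declared here is the single source of truth for every
# downstream stage (encoding, importance, scorecard intervals).

#' Declare a candidate predictor variable
#'
#' @param name Column name in the cohort file.
#' @param vtype One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels For categorical variables, the ordered character vector of
#'   admissible levels (at least two). Ignored otherwise.
#' @param unit Optional free-text unit annotation (e.g. `"mmol/L"`).
#' @return An object of class `var_schema`.
#' @export
var_schema <- function(name, vtype = c("continuous", "binary", "categorical"),
                       levels = NULL, unit = "") {
  vtype <- match.arg(vtype)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (vtype == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop2("categorical variable '", name, "' must declare >= 2 levels")
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop2("duplicate levels for '", name, "'")
  } else {
    levels <- NULL
  }
  structure(list(name = name, vtype = vtype, levels = levels, unit = unit),
            class = "var_schema")
}

validate_schema <- function(schema) {
  if (inherits(schema, "var_schema")) schema <- list(schema)
  if (!length(schema) || !all(vapply(schema, inherits, TRUE, "var_schema")))
    stop2("schema must be a list of var_schema objects")
  nms <- vapply(schema, `[[`, "", "name")
  if (anyDuplicated(nms)) stop2("duplicate variable names in schema: ",
                                paste(nms[duplicated(nms)], collapse = ", "))
  names(schema) <- nms
  schema
}

#' Read a variable schema from a YAML or JSON config
#'
#' The file holds a list of entries with fields `name`, `vtype`, and
#' optionally `levels` and `unit`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [var_schema()] objects.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  validate_schema(lapply(raw, function(e) {
    var_schema(e$name, e$vtype, levels = e$levels, unit = e$unit %||% "")
  }))
}

new_cohort <- function(data, outcome, schema, split = NULL, medians = NULL) {
  n <- nrow(data)
  structure(list(
    data = data,
    outcome = as.integer(outcome),
    schema = schema,
    split = split %||% factor(rep("unassigned", n),
                              levels = c("train", "validation", "test", "unassigned")),
    medians = medians
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", nrow(x$data), " rows, ", length(x$schema), " candidate variables\n",
      sep = "")
  cat("Outcome prevalence: ", sprintf("%.1f%%", 100 * mean(x$outcome)), "\n", sep = "")
  tab <- table(x$split)
  cat("Splits: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(nrow(x$data), length(x$schema))

# Coerce and validate one predictor column against its schema entry.
coerce_column <- function(x, vs) {
  switch(vs$vtype,
    continuous = {
      v <- suppressWarnings(as.numeric(x))
      if (any(is.na(v) & !is.na(x) & !(x %in% c("", "NA"))))
        stop2("non-numeric value in continuous column '", vs$name, "'")
      v
    },
    binary = {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v)) stop2("missing or non-numeric value in binary column '", vs$name,
                          "' (binary columns may not contain NA)")
      if (!all(v %in% c(0, 1)))
        stop2("binary column '", vs$name, "' contains values outside {0,1}")
      as.integer(v)
    },
    categorical = factor(as.character(x), levels = vs$levels)
  )
}

#' Construct a cohort from an in-memory data frame
#'
#' @param df Data frame containing the outcome column and every schema column.
#' @param schema List of [var_schema()] objects.
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @return A `cohort` object. Rows whose categorical values are outside the
#'   declared levels are dropped; their indices are attached as attribute
#'   `"rejected_rows"`.
#' @export
as_cohort <- function(df, schema, outcome = "outcome") {
  schema <- validate_schema(schema)
  miss <- setdiff(c(names(schema), outcome), names(df))
  if (length(miss)) stop2("schema error: missing column(s): ", paste(miss, collapse = ", "))

  y <- suppressWarnings(as.numeric(df[[outcome]]))
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop2("data error: outcome column must be coded {0,1} with no missing values")

  cols <- lapply(schema, function(vs) coerce_column(df[[vs$name]], vs))
  # reject rows with undeclared categorical levels (NA introduced by factor())
  bad <- rep(FALSE, nrow(df))
  for (vs in schema) {
    if (vs$vtype == "categorical") {
      raw_na <- is.na(df[[vs$name]])
      if (any(raw_na)) stop2("data error: missing categorical value in '", vs$name,
                             "' (only continuous columns may be missing)")
      bad <- bad | is.na(cols[[vs$name]])
    }
  }
  rejected <- which(bad)
  keep <- !bad
  values <- as.data.frame(lapply(cols, `[`, keep), optional = TRUE)
  names(values) <- names(schema)
  ch <- new_cohort(values, y[keep], schema)
  attr(ch, "rejected_rows") <- rejected
  ch
}

#' Load a delimited cohort file
#'
#' Reads a CSV or TSV file with a header row, types each column against the
#' declared schema, and validates the binary outcome. Rows containing
#' categorical values outside the declared levels are rejected (reported via
#' the `"rejected_rows"` attribute).
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @inheritParams as_cohort
#' @return A `cohort` object.
#' @export
load_cohort <- function(path, schema, outcome = "outcome") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  as_cohort(df, schema, outcome = outcome)
}

#' Split a cohort into training, validation and test sets
#'
#' Simple random split without replacement. The training set receives
#' `floor(n * fractions[1])` rows, the validation set `floor(n * fractions[2])`,
#' and the test set the remainder, so the three sets always partition the
#' cohort exactly. An optional outcome-stratified mode keeps prevalence
#' balanced across splits.
#'
#' @param cohort A `cohort` object.
#' @param fractions Length-3 numeric vector of positive proportions summing
#'   to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Stratify the draw by outcome (default `FALSE`).
#' @return The cohort with `split` labels assigned.
#' @export
split_cohort <- function(cohort, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                         stratify = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop2("split error: fractions must be three positive proportions summing to 1")
  n <- nrow(cohort$data)

  assign_labels <- function(m) {
    n_tr <- floor(m * fractions[1]); n_va <- floor(m * fractions[2])
    rep(c("train", "validation", "test"), c(n_tr, n_va, m - n_tr - n_va))
  }

  lab <- character(n)
  with_seed(substream_seed(seed, "split"), {
    if (stratify) {
      for (cls in c(0L, 1L)) {
        idx <- sample(which(cohort$outcome == cls))
        lab[idx] <- assign_labels(length(idx))
      }
    } else {
      idx <- sample.int(n)
      lab[idx] <- assign_labels(n)
    }
  })
  split <- factor(lab, levels = c("train", "validation", "test", "unassigned"))
  for (s in c("train", "validation", "test")) {
    pos <- sum(cohort$outcome[split == s] == 1L)
    neg <- sum(cohort$outcome[split == s] == 0L)
    if (pos < 2L || neg < 1L)
      stop2("split error: split '", s, "' would contain ", pos,
            " outcome-positive rows (need >= 2) and ", neg, " negatives")
  }
  cohort$split <- split
  cohort
}

#' Impute missing continuous values with training-set medians
#'
#' Every missing value in a continuous column (in any split) is replaced by
#' the median of that column within the training split. The medians are
#' stored on the cohort (`$medians`) for reuse on new data.
#'
#' @param cohort A split `cohort` object.
#' @return The imputed cohort.
#' @export
impute_training_median <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (!any(cohort$split == "train"))
    stop2("imputation requires split labels (no training rows found)")
  tr <- cohort$split == "train"
  med <- list()
  for (vs in cohort$schema) {
    if (vs$vtype != "continuous") next
    x <- cohort$data[[vs$name]]
    m <- stats::median(x[tr], na.rm = TRUE)
    if (is.na(m))
      stop2("imputation error: continuous column '", vs$name,
            "' is entirely missing in the training split")
    med[[vs$name]] <- m
    if (anyNA(x)) cohort$data[[vs$name]][is.na(x)] <- m
  }
  cohort$medians <- unlist(med)
  if (anyNA(cohort$data)) stop2("missing values remain after imputation")
  cohort
}

# Subset a cohort by split label (or logical/integer index).
cohort_subset <- function(cohort, which) {
  idx <- if (is.character(which)) cohort$split %in% which else which
  new_cohort(cohort$data[idx, , drop = FALSE], cohort$outcome[idx],
             cohort$schema,
             split = droplevels_keep(cohort$split[idx]),
             medians = cohort$medians)
}

droplevels_keep <- function(f) factor(as.character(f),
  levels = c("train", "validation", "test", "unassigned"))

#' Write split assignments to a sidecar CSV
#'
#' @param cohort A split cohort.
#' @param path Output CSV path (`row_id`, `split`).
#' @export
write_split <- function(cohort, path) {
  utils::write.csv(data.frame(row_id = seq_along(cohort$outcome),
                              split = as.character(cohort$split)),
                   path, row.names = FALSE)
  invisible(path)
}
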