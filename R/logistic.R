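# Optimal logistic regression, logistic loss, and collinearity diagnostics.
# The dummy-encoded design (reference-level coding, one column block per
# variable) is shared by the fit, the Rashomon sampler and the SAGE engine.

# Build the dummy-encoded design for a cohort. Returns the n x p matrix
# (no intercept column) plus the variable -> column-block map.
encode_design <- function(cohort, variables = NULL) {
  variables <- variables %||% names(cohort$schema)
  absent <- setdiff(variables, names(cohort$data))
  if (length(absent))
    stop2("schema mismatch: variable(s) not present in cohort: ",
          paste(absent, collapse = ", "))
  df <- cohort$data[variables]
  mm <- stats::model.matrix(~ ., data = df)
  assign <- attr(mm, "assign")[-1]           # drop intercept entry
  X <- mm[, -1, drop = FALSE]
  list(
    X = X,
    variables = variables,
    assign = assign,                          # column -> index into `variables`
    blocks = split(seq_len(ncol(X)), factor(assign, levels = seq_along(variables))),
    ref_levels = lapply(cohort$schema[variables], function(vs)
      if (vs$vtype == "categorical") vs$levels[1] else NULL)
  )
}

#' Fit the optimal logistic regression on the training split
#'
#' Maximum-likelihood logistic regression on all candidate variables
#' (dummy-encoded, reference-level coding). Convergence is checked on the
#' max-norm of the score of the mean negative log-likelihood; separation
#' and rank-deficiency are detected and reported as errors naming the
#' offending columns.
#'
#' @param cohort A split `cohort`; the `"train"` rows are used (or all rows
#'   if no split has been assigned).
#' @param grad_tol Convergence tolerance on the gradient max-norm of the
#'   per-observation mean loss (default `1e-8`).
#' @return An object of class `logit_model` with the intercept, the
#'   coefficient vector aligned to the encoding, the encoding itself, the
#'   training loss (mean negative log-likelihood, nats/observation) and the
#'   MLE covariance matrix.
#' @export
fit_optimal <- function(cohort, grad_tol = 1e-8) {
  stopifnot(inherits(cohort, "cohort"))
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort
  if (length(unique(train$outcome)) < 2L)
    stop2("degenerate training split: only one outcome class present")
  enc <- encode_design(train)
  Xi <- cbind(`(Intercept)` = 1, enc$X)

  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop2("design matrix is rank deficient; aliased column(s): ",
          paste(aliased, collapse = ", "))
  }

  y <- train$outcome
  fit <- suppressWarnings(
    glm.fit(Xi, y, family = binomial(), control = list(epsilon = 1e-12, maxit = 100))
  )
  beta <- fit$coefficients
  p <- expit(drop(Xi %*% beta))
  grad <- drop(crossprod(Xi, p - y)) / nrow(Xi)
  if (max(abs(grad)) > grad_tol) {
    # non-convergence at interior ML is separation in practice
    worst <- names(beta)[which.max(abs(beta))]
    if (any(p < 1e-10 | p > 1 - 1e-10))
      stop2("fit error: separation detected (fitted probabilities at 0/1); ",
            "largest coefficient on '", worst, "'")
    stop2("fit error: gradient norm ", format(max(abs(grad))),
          " above tolerance ", format(grad_tol))
  }
  if (max(abs(beta)) > 15 && any(p < 1e-12 | p > 1 - 1e-12))
    stop2("fit error: separation detected; largest coefficient on '",
          names(beta)[which.max(abs(beta))], "'")

  W <- p * (1 - p)
  info <- crossprod(Xi * sqrt(W))
  vc <- chol2inv(chol(info))                  # inverse observed information
  dimnames(vc) <- list(names(beta), names(beta))

  model <- structure(list(
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    encoding = enc[c("variables", "assign", "blocks", "ref_levels")],
    column_names = colnames(enc$X),
    training_loss = NA_real_,
    vcov = vc,
    n_train = nrow(Xi)
  ), class = "logit_model")
  model$training_loss <- logistic_loss(model, train)
  model
}

#' @export
print.logit_model <- function(x, ...) {
  cat("Logistic regression (maximum likelihood)\n")
  cat("  variables: ", length(x$encoding$variables),
      "  columns: ", length(x$coefficients), "\n", sep = "")
  cat("  training loss: ", format(x$training_loss, digits = 6),
      " nats/observation (n = ", x$n_train, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.logit_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

# Linear predictor for a cohort under a (possibly perturbed) coefficient set.
linear_predictor <- function(model, cohort, intercept = model$intercept,
                             coefficients = model$coefficients) {
  enc <- encode_design(cohort, model$encoding$variables)
  if (!identical(colnames(enc$X), model$column_names))
    stop2("schema mismatch: cohort encoding does not match model encoding")
  drop(enc$X %*% coefficients) + intercept
}

#' Serialize a fitted logistic model to JSON
#'
#' Stores the intercept, coefficient vector, encoding (variables, column
#' names, reference levels), training loss and a schema fingerprint, so a
#' model can be reloaded and applied to compatible cohorts.
#'
#' @param model A `logit_model`.
#' @param path Output JSON path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    variables = model$encoding$variables,
    column_names = model$column_names,
    ref_levels = model$encoding$ref_levels,
    training_loss = model$training_loss,
    n_train = model$n_train,
    schema_hash = substream_seed(0L, paste(model$column_names, collapse = "|"))
  ), path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Reload a serialized logistic model
#'
#' The returned model evaluates losses and linear predictors on cohorts
#' whose encoding matches; the MLE covariance is not stored, so it cannot
#' seed a new ensemble without refitting.
#'
#' @param path JSON path written by [write_model()].
#' @param cohort A compatible `cohort` used to rebuild the encoding.
#' @return A `logit_model`.
#' @export
read_model <- function(path, cohort) {
  raw <- jsonlite::fromJSON(path)
  enc <- encode_design(cohort, raw$variables)
  if (!identical(colnames(enc$X), raw$column_names))
    stop2("cohort encoding does not match the serialized model")
  structure(list(
    intercept = raw$intercept,
    coefficients = unlist(raw$coefficients),
    encoding = enc[c("variables", "assign", "blocks", "ref_levels")],
    column_names = colnames(enc$X),
    training_loss = raw$training_loss,
    vcov = NULL,
    n_train = raw$n_train
  ), class = "logit_model")
}

#' Mean logistic loss of a model on a cohort
#'
#' Mean negative log-likelihood, `-mean(y*log(p) + (1-y)*log(1-p))`, with
#' probabilities clipped away from 0/1 by a machine-epsilon guard. The
#' per-observation mean makes the loss comparable across sample sizes.
#'
#' @param model A `logit_model`.
#' @param cohort A `cohort` whose schema matches the model encoding.
#' @param intercept,coefficients Optional replacement parameters (used by
#'   the Rashomon sampler to score candidate coefficient vectors).
#' @return Non-negative scalar loss in nats per observation.
#' @export
logistic_loss <- function(model, cohort, intercept = model$intercept,
                          coefficients = model$coefficients) {
  eta <- linear_predictor(model, cohort, intercept, coefficients)
  mean(nll_bernoulli(cohort$outcome, clip_prob(expit(eta))))
}

nll_bernoulli <- function(y, p) -(y * log(p) + (1 - y) * log1p(-p))

#' Generalized variance inflation factors for the candidate variables
#'
#' Computes each variable's generalized VIF by the determinant-ratio
#' formulation on the correlation matrix of the dummy-encoded design,
#' together with the size-adjusted comparable score `(GVIF^(1/(2 df)))^2`
#' that puts multi-level categorical variables on the same footing as 1-df
#' variables. Variables whose comparable score exceeds 2 are flagged; the
#' flag selects which variables use absolute SAGE values as model reliance.
#'
#' @param cohort A `cohort`; the training split is used when assigned.
#' @param threshold Flagging threshold on the comparable score (default 2).
#' @return A data frame of class `vif_report` with columns `variable`, `df`,
#'   `gvif`, `comparable` and `flag`.
#' @export
generalized_vif <- function(cohort, threshold = 2) {
  stopifnot(inherits(cohort, "cohort"))
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort
  if (length(train$schema) < 2L) stop2("VIF requires at least 2 variables")
  enc <- encode_design(train)
  R <- stats::cor(enc$X)
  if (!all(is.finite(R))) stop2("diagnostics error: constant column in design")
  detR <- det(R)
  if (detR < .Machine$double.eps^2)
    stop2("diagnostics error: singular predictor correlation matrix")
  vars <- enc$variables
  gvif <- df <- numeric(length(vars))
  for (i in seq_along(vars)) {
    cols <- enc$blocks[[i]]
    oth <- setdiff(seq_len(ncol(enc$X)), cols)
    df[i] <- length(cols)
    gvif[i] <- det(R[cols, cols, drop = FALSE]) *
      det(R[oth, oth, drop = FALSE]) / detR
  }
  comparable <- (gvif^(1 / (2 * df)))^2
  structure(data.frame(variable = vars, df = df, gvif = gvif,
                       comparable = comparable, flag = comparable > threshold,
                       stringsAsFactors = FALSE),
            class = c("vif_report", "data.frame"))
}
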