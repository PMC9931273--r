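# Shapley additive global importance (SAGE) for logistic models.
#
# The cooperative game: v(S) = L_empty - L_S, where L_S is the mean logistic
# loss on the evaluation rows when variables outside S are marginalized by
# substituting values drawn from a fixed background sample (the
# interventional/marginal convention). All dummy columns of one clinical
# variable act as a single Shapley player. The permutation estimator walks
# random orderings of the players and accumulates per-variable loss-drop
# increments; its telescoping structure makes the efficiency identity
# sum_j value_j = L_empty - L_full hold exactly for the estimate, and gives
# a per-variable Monte-Carlo standard error from the increment spread.
#
# The linear-predictor structure is exploited for speed: per variable j the
# contribution of the evaluation rows (E[, j]) and of the background rows
# (B[, j]) are precomputed, and L_S only needs an outer sum of the two
# partial linear predictors.

#' SAGE configuration
#'
#' @param eval_rows Number of evaluation cases (leading validation rows;
#'   default 3500).
#' @param background_rows Marginalization sample size drawn from the
#'   training split (default 512).
#' @param n_permutations Monte-Carlo permutation budget per model
#'   (default 256).
#' @param seed Integer seed.
#' @return A list of class `sage_config`.
#' @export
sage_config <- function(eval_rows = 3500L, background_rows = 512L,
                        n_permutations = 256L, seed = 1L) {
  stopifnot(eval_rows > 0, background_rows > 0, n_permutations > 0)
  structure(list(eval_rows = as.integer(eval_rows),
                 background_rows = as.integer(background_rows),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "sage_config")
}

# Per-variable partial linear predictors for a model on a cohort:
# an n x d matrix whose column j is X[, block_j] %*% beta[block_j].
partial_eta <- function(model, cohort) {
  enc <- encode_design(cohort, model$encoding$variables)
  if (!identical(colnames(enc$X), model$column_names))
    stop2("schema mismatch between model encoding and cohort")
  d <- length(model$encoding$variables)
  out <- matrix(0, nrow = nrow(enc$X), ncol = d,
                dimnames = list(NULL, model$encoding$variables))
  for (j in seq_len(d)) {
    cols <- model$encoding$blocks[[j]]
    out[, j] <- enc$X[, cols, drop = FALSE] %*% model$coefficients[cols]
  }
  out
}

# Mean loss of the marginalized predictor: eta_fix holds the intercept plus
# the in-coalition contribution per evaluation row; eta_bg the
# out-of-coalition contribution per background row.
coalition_loss <- function(eta_fix, eta_bg, y) {
  P <- expit(outer(eta_fix, eta_bg, `+`))
  mean(nll_bernoulli(y, clip_prob(rowMeans(P))))
}

# Shared setup for the permutation estimator and the exact oracle.
sage_setup <- function(model, eval_data, background) {
  E <- partial_eta(model, eval_data)
  B <- partial_eta(model, background)
  list(E = E, B = B, y = eval_data$outcome, d = ncol(E),
       variables = colnames(E), intercept = model$intercept)
}

#' Per-model SAGE values with Monte-Carlo standard errors
#'
#' Permutation-sampling Shapley estimate of each variable's contribution to
#' the reduction in mean logistic loss, with all dummy columns of a
#' categorical variable grouped as one player. Variables whose coefficient
#' block is exactly zero receive value 0 and SE 0 (null-player axiom holds
#' exactly). Deterministic given `config$seed`.
#'
#' @param model A `logit_model` (optimal or ensemble member).
#' @param eval_data Evaluation `cohort` (disjoint from training; by
#'   convention the leading validation rows).
#' @param config A [sage_config()]; `eval_rows` caps the evaluation rows
#'   used, `background_rows` the marginalization sample.
#' @param background Optional explicit background `cohort`; when omitted,
#'   `config$background_rows` rows are sampled (seeded) from `eval_data`'s
#'   companion training split attribute, or must be supplied.
#' @return A list with `value` and `se` vectors (one entry per variable).
#' @export
sage_values <- function(model, eval_data, config = sage_config(), background) {
  stopifnot(inherits(model, "logit_model"))
  if (config$background_rows < 2 && missing(background))
    stop2("config error: background sample must contain at least 2 rows")
  ev <- cohort_subset(eval_data, seq_len(min(config$eval_rows, nrow(eval_data$data))))
  bg <- resolve_background(background, eval_data, config)
  st <- sage_setup(model, ev, bg)
  d <- st$d

  null_player <- colSums(abs(st$E)) == 0 & colSums(abs(st$B)) == 0
  bg_total <- rowSums(st$B)   # per-background-row total contribution

  R <- config$n_permutations
  inc <- matrix(0, nrow = R, ncol = d, dimnames = list(NULL, st$variables))
  active <- which(!null_player)
  with_seed(substream_seed(config$seed, "sage"), {
    for (r in seq_len(R)) {
      perm <- active[sample.int(length(active))]
      eta_fix <- rep(st$intercept, length(st$y))
      eta_bg <- bg_total
      loss_prev <- coalition_loss(eta_fix, eta_bg, st$y)
      for (j in perm) {
        eta_fix <- eta_fix + st$E[, j]
        eta_bg <- eta_bg - st$B[, j]
        loss_new <- coalition_loss(eta_fix, eta_bg, st$y)
        inc[r, j] <- loss_prev - loss_new
        loss_prev <- loss_new
      }
    }
  })
  value <- colMeans(inc)
  se <- apply(inc, 2, stats::sd) / sqrt(R)
  value[null_player] <- 0
  se[null_player] <- 0
  list(value = value, se = se)
}

resolve_background <- function(background, eval_data, config) {
  if (!missing(background) && !is.null(background)) return(background)
  # fall back to a seeded subsample of the evaluation cohort's rows
  n <- nrow(eval_data$data)
  idx <- with_seed(substream_seed(config$seed, "background"),
                   sample.int(n, min(config$background_rows, n)))
  cohort_subset(eval_data, idx)
}

#' Exact Shapley values by subset enumeration (test oracle)
#'
#' Enumerates all `2^d` coalitions of the same marginalized-loss game and
#' returns exact Shapley values. Satisfies the efficiency identity
#' `sum(value) = L_empty - L_full` to machine precision. Refuses `d > 10`.
#'
#' @param model A `logit_model`.
#' @param eval_data Evaluation `cohort`.
#' @param background Background `cohort` for marginalization.
#' @return Named vector of exact Shapley values.
#' @export
exact_shapley <- function(model, eval_data, background) {
  if (length(model$encoding$variables) > 10)
    stop2("exact enumeration refused for d > 10 (2^d blow-up)")
  st <- sage_setup(model, eval_data, background)
  d <- st$d
  bg_total <- rowSums(st$B)
  nS <- 2^d
  Ls <- numeric(nS)
  for (s in 0:(nS - 1)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(d - 1))) != 0)
    eta_fix <- rep(st$intercept, length(st$y)) +
      if (length(members)) rowSums(st$E[, members, drop = FALSE]) else 0
    eta_bg <- bg_total -
      if (length(members)) rowSums(st$B[, members, drop = FALSE]) else 0
    Ls[s + 1] <- coalition_loss(eta_fix, eta_bg, st$y)
  }
  value <- setNames(numeric(d), st$variables)
  fact <- factorial(0:d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(nS - 1)) {
      if (bitwAnd(s, bit) != 0) next
      k <- sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1))) != 0)
      w <- fact[k + 1] * fact[d - k] / fact[d + 1]
      value[j] <- value[j] + w * (Ls[s + 1] - Ls[s + bit + 1])
    }
  }
  value
}

#' Apply the collinearity absolute-value rule to SAGE values
#'
#' Variables flagged by the generalized-VIF report (comparable score > 2)
#' use the absolute SAGE value as model reliance; unflagged variables keep
#' the signed value. Standard errors are unchanged.
#'
#' @param value,se SAGE value and SE vectors from [sage_values()].
#' @param vif A `vif_report` from [generalized_vif()].
#' @return A list with `mr` (model reliance) and `sigma` vectors.
#' @export
model_reliance <- function(value, se, vif) {
  flag <- setNames(vif$flag, vif$variable)[names(value)]
  if (anyNA(flag)) stop2("VIF report does not cover all variables")
  mr <- ifelse(flag, abs(value), value)
  list(mr = setNames(mr, names(value)), sigma = se)
}

#' ShapleyVIC importance matrix for a model ensemble
#'
#' Runs the SAGE permutation estimator on every ensemble member, applies the
#' VIF>2 absolute-value rule, and collects the M x d model-reliance matrix
#' with its standard errors. Per-model seeds are derived deterministically
#' from `config$seed` and the member index, so results are independent of
#' execution order.
#'
#' @param ensemble A `model_ensemble`.
#' @param eval_data Evaluation `cohort` (leading validation rows convention).
#' @param vif A `vif_report` from the optimal model's training split.
#' @param config A [sage_config()].
#' @param background Optional explicit background cohort (defaults to a
#'   seeded subsample of `eval_data`).
#' @param template A `logit_model` carrying the shared encoding (the optimal
#'   model); defaults to an encoding reconstructed from the ensemble.
#' @param progress Print a progress line every 25 models.
#' @return An object of class `importance_matrix`: matrices `values` and
#'   `se` (M x d), the `abs_flag` vector, and the carried `loss_ratio`.
#' @export
ensemble_importance <- function(ensemble, eval_data, vif, config = sage_config(),
                                background = NULL, template = NULL,
                                progress = FALSE) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  M <- nrow(ensemble$coefficients)
  template <- template %||% structure(list(
    intercept = 0, coefficients = ensemble$coefficients[1, -1],
    encoding = ensemble$encoding, column_names = ensemble$column_names
  ), class = "logit_model")
  bg <- resolve_background(background, eval_data, config)
  vars <- ensemble$encoding$variables
  d <- length(vars)
  values <- se <- matrix(NA_real_, nrow = M, ncol = d, dimnames = list(NULL, vars))
  for (i in seq_len(M)) {
    m <- ensemble_member(ensemble, i, template)
    cfg_i <- config
    cfg_i$seed <- substream_seed(config$seed, "sage_model", i)
    res <- tryCatch(sage_values(m, eval_data, cfg_i, background = bg),
                    error = function(e) stop2("model ", i, ": ", conditionMessage(e)))
    mr <- model_reliance(res$value, res$se, vif)
    values[i, ] <- mr$mr
    se[i, ] <- mr$sigma
    if (progress && i %% 25 == 0) message("  SAGE: ", i, "/", M, " models")
  }
  structure(list(values = values, se = se,
                 abs_flag = setNames(vif$flag, vif$variable)[vars],
                 loss_ratio = ensemble$loss_ratio,
                 variables = vars),
            class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat("ShapleyVIC importance matrix: ", nrow(x$values), " models x ",
      ncol(x$values), " variables\n", sep = "")
  invisible(x)
}

#' Write an importance matrix as long-format CSV
#'
#' Columns: `model_id`, `variable`, `value`, `se`, `abs_flagged`,
#' `loss_ratio`.
#'
#' @param imp An `importance_matrix`.
#' @param path Output CSV path.
#' @export
write_importance <- function(imp, path) {
  M <- nrow(imp$values); d <- ncol(imp$values)
  long <- data.frame(
    model_id = rep(seq_len(M), times = d),
    variable = rep(imp$variables, each = M),
    value = as.vector(imp$values),
    se = as.vector(imp$se),
    abs_flagged = rep(unname(imp$abs_flag), each = M),
    loss_ratio = rep(imp$loss_ratio, times = d)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
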