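# Rejection sampler for nearly-optimal ("Rashomon") logistic models.
# Candidate coefficient vectors are drawn from a multivariate normal centered
# at the MLE with covariance u * Sigma_hat (Sigma_hat = inverse observed
# information), and kept iff their re-evaluated training loss stays within
# the (1 + eps) band above the optimal loss. The scale u is the single
# exploration knob: small u concentrates near the optimum, large u pushes
# draws toward (and past) the band edge.

#' Sampler configuration
#'
#' @param M Target ensemble size (default 350).
#' @param eps Loss-band width: members must satisfy
#'   `loss <= (1 + eps) * loss_optimal` (default 0.05).
#' @param u Positive scale multiplier on the MLE covariance (default 1).
#' @param max_draws Total draw budget (default `2000 * M`).
#' @param seed Integer seed.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(M = 350L, eps = 0.05, u = 1, max_draws = NULL,
                           seed = 1L) {
  stopifnot(M >= 2L, eps > 0, u > 0)
  structure(list(M = as.integer(M), eps = eps, u = u,
                 max_draws = as.integer(max_draws %||% (2000L * as.integer(M))),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# Batch loss evaluation: columns of Theta are (intercept, beta) vectors.
batch_loss <- function(Xi, y, Theta) {
  Eta <- Xi %*% Theta
  P <- clip_prob(expit(Eta))
  colMeans(-(y * log(P) + (1 - y) * log1p(-P)))
}

#' Sample an ensemble of nearly-optimal logistic models
#'
#' Draws coefficient vectors (intercept sampled jointly with the slopes)
#' from `N(beta_hat, u * Sigma_hat)` and accepts a draw iff its training
#' loss does not exceed `(1 + eps)` times the optimal loss. Every accepted
#' member's loss is an exact re-evaluation on the training split, so the
#' band invariant holds by construction.
#'
#' @param model The optimal `logit_model` from [fit_optimal()].
#' @param cohort The cohort the model was fitted on (training split used).
#' @param config A [sampler_config()].
#' @return An object of class `model_ensemble`: coefficient matrix
#'   (`M x (p+1)`, intercept first), per-model losses and loss ratios, and
#'   sampler diagnostics (draws attempted, acceptance rate, decile occupancy
#'   of the loss band).
#' @export
sample_nearly_optimal <- function(model, cohort, config = sampler_config()) {
  stopifnot(inherits(model, "logit_model"), inherits(config, "sampler_config"))
  train <- if (any(cohort$split == "train")) cohort_subset(cohort, "train") else cohort
  enc <- encode_design(train, model$encoding$variables)
  Xi <- cbind(1, enc$X)
  y <- train$outcome
  mu <- c(model$intercept, model$coefficients)
  L <- t(chol(config$u * model$vcov))        # lower-triangular factor
  loss_opt <- model$training_loss
  cutoff <- (1 + config$eps) * loss_opt

  p <- length(mu)
  kept <- matrix(NA_real_, nrow = p, ncol = 0)
  kept_loss <- numeric(0)
  attempted <- 0L
  batch <- min(512L, config$max_draws)

  with_seed(substream_seed(config$seed, "rashomon"), {
    while (length(kept_loss) < config$M && attempted < config$max_draws) {
      b <- min(batch, config$max_draws - attempted)
      Z <- matrix(rnorm(p * b), nrow = p)
      Theta <- mu + L %*% Z
      losses <- batch_loss(Xi, y, Theta)
      ok <- losses <= cutoff
      kept <- cbind(kept, Theta[, ok, drop = FALSE])
      kept_loss <- c(kept_loss, losses[ok])
      attempted <- attempted + b
    }
  })

  if (length(kept_loss) < config$M) {
    stop2("sampler error: only ", length(kept_loss), "/", config$M,
          " models accepted after ", attempted, " draws (acceptance rate ",
          sprintf("%.3f", length(kept_loss) / attempted),
          "); decrease u or increase max_draws")
  }
  keep <- seq_len(config$M)
  coefs <- t(kept[, keep, drop = FALSE])
  colnames(coefs) <- c("(Intercept)", model$column_names)
  loss <- kept_loss[keep]
  ratio <- loss / loss_opt
  occupancy <- tabulate(pmin(
    findInterval(pmax(ratio - 1, 0) / config$eps, seq(0, 1, 0.1),
                 rightmost.closed = TRUE), 10L), nbins = 10L)

  structure(list(
    coefficients = coefs,
    loss = loss,
    loss_ratio = ratio,
    loss_optimal = loss_opt,
    encoding = model$encoding,
    column_names = model$column_names,
    config = config,
    diagnostics = list(draws_attempted = attempted,
                       acceptance_rate = length(kept_loss) / attempted,
                       band_decile_occupancy = occupancy)
  ), class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("Nearly-optimal model ensemble: M = ", nrow(x$coefficients),
      ", eps = ", x$config$eps, ", u = ", x$config$u, "\n", sep = "")
  cat("  loss ratios in [", sprintf("%.5f", min(x$loss_ratio)), ", ",
      sprintf("%.5f", max(x$loss_ratio)), "]  acceptance rate ",
      sprintf("%.3f", x$diagnostics$acceptance_rate), "\n", sep = "")
  invisible(x)
}

# Extract member i of the ensemble as a logit_model (sharing the encoding).
ensemble_member <- function(ensemble, i, template) {
  m <- template
  m$intercept <- unname(ensemble$coefficients[i, 1])
  m$coefficients <- ensemble$coefficients[i, -1]
  m$training_loss <- ensemble$loss[i]
  m
}

#' Tune the sampler scale u
#'
#' Searches an increasing grid of `u` values and returns the configuration
#' with the smallest `u` whose 50-draw pilot sample occupies every quintile
#' of the loss-ratio band `(1, 1+eps]`. Occupancy requires at least 5% of
#' the pilot draws in each quintile (3 draws at the default pilot size), so
#' a single lucky draw cannot certify an under-dispersed scale. If no grid
#' value achieves full occupancy, the best one found is returned with a
#' warning.
#'
#' @param model Optimal `logit_model`.
#' @param cohort Training cohort.
#' @param config A [sampler_config()]; its `u` is ignored in favour of the grid.
#' @param u_grid Increasing vector of candidate scales. The default grid is
#'   centred on the scale at which the expected loss excess of a draw,
#'   roughly `u * p / (2n)` in mean-loss units, matches the band width
#'   `eps * loss_optimal` — the scale that pushes draws to the band edge.
#' @param pilot Pilot sample size per grid point (default 50).
#' @return The updated `sampler_config`.
#' @export
tune_scale <- function(model, cohort, config = sampler_config(),
                       u_grid = NULL, pilot = 50L) {
  if (config$eps <= 0) stop2("tuning error: empty loss band (eps must be > 0)")
  if (is.null(u_grid)) {
    p <- length(model$coefficients) + 1
    u_star <- 2 * model$n_train * config$eps * model$training_loss / p
    u_grid <- u_star * c(0.05, 0.1, 0.2, 0.35, 0.6, 1, 1.6, 2.5, 4)
  }
  u_grid <- sort(unique(u_grid))
  best_u <- NULL; best_occ <- -1L
  for (u in u_grid) {
    cfg <- config
    cfg$u <- u
    cfg$M <- as.integer(pilot)
    cfg$max_draws <- as.integer(pilot * 400L)
    ens <- tryCatch(sample_nearly_optimal(model, cohort, cfg),
                    error = function(e) NULL)
    if (is.null(ens)) next
    q <- pmin(floor(pmax(ens$loss_ratio - 1, 0) / config$eps * 5) + 1, 5)
    need <- max(1L, ceiling(0.05 * pilot))
    occ <- sum(tabulate(q, nbins = 5L) >= need)
    if (occ > best_occ) { best_occ <- occ; best_u <- u }
    if (occ == 5L) break
  }
  if (is.null(best_u)) stop2("tuning error: no u in grid produced an ensemble")
  if (best_occ < 5L)
    warn2("tuning warning: no u in grid occupied all 5 band quintiles; ",
          "best found u = ", best_u, " (", best_occ, "/5)")
  config$u <- best_u
  config
}
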