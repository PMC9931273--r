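# Random-effects pooling of per-model importance, significance filtering,
# pairwise-win ensemble ranking, and the bar/violin visualizations.

#' Pool per-model importance by random-effects meta-analysis
#'
#' For each variable, the M (model reliance, SE) pairs are pooled with the
#' DerSimonian–Laird estimator of the between-model variance tau^2, an
#' inverse-variance weighted mean with weights `1/(se^2 + tau^2)`, and a
#' 95% prediction interval `mean +/- t(0.975, M-2) * sqrt(tau^2 + se_mean^2)`
#' for the importance of the variable to a *new* nearly-optimal model. A
#' variable is flagged significant iff the PI lower bound is positive.
#'
#' Degenerate variables whose per-model SEs are all zero (e.g. a variable
#' with zero importance in every model) are pooled by plain moments: the PI
#' collapses to a point when the values are also constant.
#'
#' @param imp An `importance_matrix` from [ensemble_importance()], or a list
#'   with `values` and `se` matrices (models x variables).
#' @param level PI coverage (default 0.95).
#' @return A data frame of class `pooled_importance` with one row per
#'   variable: `mean`, `tau2`, `se`, `pi_lower`, `pi_upper`, `significant`.
#' @export
pool_random_effects <- function(imp, level = 0.95) {
  values <- imp$values; ses <- imp$se
  M <- nrow(values)
  if (M < 2L) stop2("pooling requires M >= 2 models")
  if (anyNA(ses)) stop2("pooling error: undefined standard errors")
  tq <- qt(1 - (1 - level) / 2, df = max(M - 2L, 1L))
  one <- function(y, s) {
    if (all(s == 0)) {
      mu <- mean(y)
      tau2 <- if (M > 1) sum((y - mu)^2) / (M - 1) else 0
      se_mu <- sqrt(tau2 / M)
    } else {
      s2 <- pmax(s^2, max(s^2) * 1e-12)    # guard isolated zero SEs
      w <- 1 / s2
      yw <- sum(w * y) / sum(w)
      Q <- sum(w * (y - yw)^2)
      Cc <- sum(w) - sum(w^2) / sum(w)
      tau2 <- max(0, (Q - (M - 1)) / Cc)
      wstar <- 1 / (s2 + tau2)
      mu <- sum(wstar * y) / sum(wstar)
      se_mu <- sqrt(1 / sum(wstar))
    }
    half <- tq * sqrt(tau2 + se_mu^2)
    c(mean = mu, tau2 = tau2, se = se_mu,
      pi_lower = mu - half, pi_upper = mu + half)
  }
  res <- t(vapply(seq_len(ncol(values)),
                  function(j) one(values[, j], ses[, j]), numeric(5)))
  out <- data.frame(variable = colnames(values), res,
                    significant = res[, "pi_lower"] > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pooled_importance", "data.frame")
  out
}

#' Pairwise significant-win counts for one model
#'
#' For each ordered pair (j, k), variable j beats k iff
#' `(mr_j - mr_k) / sqrt(se_j^2 + se_k^2) > z(1 - alpha/2)` under the
#' normal approximation for the difference of two independent SAGE values.
#' Pairs where both SEs are zero are decided by strict value comparison.
#'
#' @param mr Model-reliance vector for one model.
#' @param sigma Matching SE vector.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer vector of win counts in `[0, d-1]`.
#' @export
pairwise_wins <- function(mr, sigma, alpha = 0.05) {
  stopifnot(length(mr) == length(sigma), alpha > 0, alpha < 1)
  z <- qnorm(1 - alpha / 2)
  d <- length(mr)
  diff <- outer(mr, mr, `-`)
  pooled_se <- sqrt(outer(sigma^2, sigma^2, `+`))
  win <- matrix(FALSE, d, d)
  pos <- pooled_se > 0
  win[pos] <- diff[pos] / pooled_se[pos] > z
  win[!pos] <- diff[!pos] > 0
  diag(win) <- FALSE
  setNames(rowSums(win), names(mr))
}

#' Competition ranks from win counts
#'
#' Rank 1 goes to the most important variable (largest win count); tied
#' variables share the smallest available integer, and the next distinct
#' count receives `1 + number of strictly better variables`.
#'
#' @param wins Win-count vector from [pairwise_wins()].
#' @return Integer rank vector.
#' @export
rank_within_model <- function(wins) {
  r <- vapply(wins, function(w) 1L + sum(wins > w), integer(1))
  setNames(r, names(wins))
}

#' Ensemble variable ranking with significance filtering
#'
#' Ranks the d variables within each nearly-optimal model by pairwise
#' significant wins, averages the ranks across models, orders variables by
#' ascending average rank (ties broken by higher pooled mean, then name),
#' and retains only variables whose 95% PI lies entirely above zero.
#'
#' @param imp An `importance_matrix`.
#' @param pooled The matching `pooled_importance`.
#' @param alpha Significance level for pairwise wins (default 0.05).
#' @return An object of class `ensemble_ranking`: the M x d rank matrix,
#'   per-variable average ranks, the full ordering, and the retained list.
#' @export
ensemble_rank <- function(imp, pooled, alpha = 0.05) {
  M <- nrow(imp$values); d <- ncol(imp$values)
  ranks <- matrix(NA_integer_, M, d, dimnames = dimnames(imp$values))
  for (i in seq_len(M))
    ranks[i, ] <- rank_within_model(pairwise_wins(imp$values[i, ], imp$se[i, ], alpha))
  avg <- colMeans(ranks)
  pm <- setNames(pooled$mean, pooled$variable)[colnames(ranks)]
  ord <- order(avg, -pm, colnames(ranks))
  ordering <- colnames(ranks)[ord]
  sig <- setNames(pooled$significant, pooled$variable)
  retained <- ordering[sig[ordering]]
  structure(list(ranks = ranks, average_rank = avg, ordering = ordering,
                 retained = retained, alpha = alpha),
            class = "ensemble_ranking")
}

#' @export
print.ensemble_ranking <- function(x, ...) {
  cat("Ensemble variable ranking (", nrow(x$ranks), " models):\n", sep = "")
  for (i in seq_along(x$ordering)) {
    v <- x$ordering[i]
    cat(sprintf("  %2d. %-18s avg rank %5.2f%s\n", i, v, x$average_rank[v],
                if (v %in% x$retained) "" else "  [filtered]"))
  }
  invisible(x)
}

#' Write pooled importance and ranking as CSV
#'
#' Columns: `variable`, `mean`, `tau2`, `se`, `pi_lower`, `pi_upper`,
#' `significant`, `avg_rank`, `final_rank`.
#'
#' @param pooled A `pooled_importance`.
#' @param ranking An `ensemble_ranking`.
#' @param path Output CSV path.
#' @export
write_pooled <- function(pooled, ranking, path) {
  df <- as.data.frame(pooled)
  df$avg_rank <- ranking$average_rank[df$variable]
  df$final_rank <- match(df$variable, ranking$ordering)
  df <- df[order(df$final_rank), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

open_device <- function(path_base, width = 7, height = 5) {
  if (capabilities("png")) {
    path <- paste0(path_base, ".png")
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else {
    path <- paste0(path_base, ".pdf")
    grDevices::pdf(path, width = width, height = height)
  }
  path
}

#' Bar and violin plots of ensemble variable importance
#'
#' Writes (a) a bar plot of pooled mean importance with 95% PI whiskers,
#' with non-positive means drawn grey, and (b) a violin plot of the
#' per-model importance distribution ordered by pooled mean, with per-model
#' points coloured by loss ratio. Variables with a zero-length degenerate
#' PI at zero are omitted from the plots (a message notes each omission).
#'
#' @param pooled A `pooled_importance`.
#' @param imp The matching `importance_matrix`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths of the written figure files.
#' @export
plot_importance <- function(pooled, imp, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  degenerate <- pooled$pi_lower == 0 & pooled$pi_upper == 0 & pooled$mean == 0
  for (v in pooled$variable[degenerate])
    message("plot_importance: '", v, "' has a zero-length PI at zero; not plotted")
  keep <- pooled[!degenerate, ]
  keep <- keep[order(keep$mean, decreasing = TRUE), ]

  paths <- character(0)
  # (a) bar plot with PI whiskers
  p1 <- open_device(file.path(out_dir, "importance_bar"), width = 7,
                    height = max(3, 0.35 * nrow(keep) + 1))
  op <- graphics::par(mar = c(4, 9, 2, 1))
  cols <- ifelse(keep$mean > 0, "steelblue", "grey70")
  mid <- graphics::barplot(rev(keep$mean), horiz = TRUE,
                           names.arg = rev(keep$variable), las = 1,
                           col = rev(cols), border = NA,
                           xlim = range(0, keep$pi_lower, keep$pi_upper),
                           xlab = "pooled importance (loss reduction, nats)",
                           main = "Ensemble variable importance (95% PI)")
  graphics::segments(rev(keep$pi_lower), mid, rev(keep$pi_upper), mid, lwd = 1.5)
  graphics::abline(v = 0, lty = 2)
  graphics::par(op); grDevices::dev.off()
  paths <- c(paths, p1)

  # (b) violin plot of per-model values, points coloured by loss ratio
  p2 <- open_device(file.path(out_dir, "importance_violin"), width = 7,
                    height = max(3, 0.35 * nrow(keep) + 1))
  op <- graphics::par(mar = c(4, 9, 2, 1))
  vals <- imp$values[, keep$variable, drop = FALSE]
  graphics::plot(NA, xlim = range(vals), ylim = c(0.5, nrow(keep) + 0.5),
                 yaxt = "n", ylab = "", xlab = "per-model importance (nats)",
                 main = "ShapleyVIC values across nearly-optimal models")
  graphics::axis(2, at = rev(seq_len(nrow(keep))), labels = keep$variable, las = 1)
  ramp <- grDevices::colorRamp(c("navy", "gold"))
  lr <- imp$loss_ratio
  lrn <- if (diff(range(lr)) > 0) (lr - min(lr)) / diff(range(lr)) else rep(0.5, length(lr))
  ptcol <- grDevices::rgb(ramp(lrn), maxColorValue = 255)
  jit <- with_seed(1L, runif(length(lr), -0.08, 0.08))
  for (i in seq_len(nrow(keep))) {
    yy <- nrow(keep) - i + 1
    x <- vals[, i]
    if (stats::sd(x) > 0) {
      dn <- stats::density(x)
      h <- 0.35 * dn$y / max(dn$y)
      graphics::polygon(c(dn$x, rev(dn$x)), c(yy + h, rev(yy - h)),
                        col = "grey90", border = "grey60")
    }
    graphics::points(x, yy + jit, pch = 16,
                     cex = 0.4, col = ptcol)
  }
  graphics::abline(v = 0, lty = 2)
  graphics::par(op); grDevices::dev.off()
  paths <- c(paths, p2)
  invisible(paths)
}
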