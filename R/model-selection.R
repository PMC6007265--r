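#' Akaike information criterion for least-squares fits
#'
#' The least-squares form `AIC = n * ln(RSS / n) + 2 * (k + 1)`, counting the
#' residual variance as an extra fitted parameter. The same formula is used
#' for behavioral and neural fits so that orderings are comparable.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k Number of free model parameters (excluding the noise variance).
#' @return AIC value (smaller is better). An exact fit (`rss = 0`) returns
#'   `-Inf` with a warning.
#' @export
#' @examples
#' aic_ls(1, 10, 1)  # 10 * log(0.1) + 4
aic_ls <- function(rss, n, k) {
  stopifnot(n > k, rss >= 0)
  if (any(rss == 0)) {
    warning("rss = 0: returning -Inf (exact fit)", call. = FALSE)
  }
  n * log(rss / n) + 2 * (k + 1)
}

#' Nested F-test between two fitted models
#'
#' Tests whether the full model's extra regressors reduce the residual sum of
#' squares more than chance: `F = [(RSS_r - RSS_f) / df1] / [RSS_f / (n - k_f)]`
#' with `df1 = k_f - k_r`, `df2 = n - k_f`, and p from the upper tail of the
#' F distribution.
#'
#' @param fit_reduced,fit_full `fit_result`s of nested models on the same
#'   data (checked via [is_nested()] and matching `n`).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
nested_f <- function(fit_reduced, fit_full) {
  if (!is_nested(fit_reduced$model_id, fit_full$model_id)) {
    stop(fit_reduced$model_id, " is not nested in ", fit_full$model_id,
         call. = FALSE)
  }
  if (fit_reduced$n != fit_full$n) {
    stop("fits are not on the same number of observations", call. = FALSE)
  }
  df1 <- fit_full$k - fit_reduced$k
  if (df1 <= 0) stop("full model must have more free parameters", call. = FALSE)
  df2 <- fit_full$n - fit_full$k
  f <- ((fit_reduced$rss - fit_full$rss) / df1) / (fit_full$rss / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Null-model mean squared error
#'
#' MSE between observed standardized values and an equal-length sample of
#' uniform(-1, 1) draws -- the chance-level reference the fitted models are
#' compared against.
#'
#' @param values Standardized values in [-1, 1].
#' @param seed Seed for the uniform draws.
#' @return Scalar MSE.
#' @export
null_model_mse <- function(values, seed = 1) {
  set.seed(seed)
  mean((values - stats::runif(length(values), -1, 1))^2)
}

#' Type-I error calibration of the nested F-test
#'
#' Monte-Carlo check of the F-test's size on a realized design. The reduced
#' model is made literally true: holding the trial design fixed, responses
#' are drawn as `y = X_reduced %*% theta + N(0, sigma)` (theta from the
#' reduced-model fit to the observed standardized punishments, i.e. the RT
#' coefficient is exactly zero in the generating regression), both models
#' are refitted and the nested F computed. The rejection rate at `level`
#' should sit near the nominal level.
#'
#' @param trials A `trial_table` of one participant, providing the design.
#' @param reduced,full Nested model identifiers.
#' @param n_sims Number of simulated responses.
#' @param sigma Residual standard deviation of the null generator.
#' @param level Nominal test level.
#' @param seed Seed for the response draws.
#' @return List with `rejection_rate`, `n_sims`, `level`.
#' @export
nested_f_calibration <- function(trials, reduced = "FS_unconstrained",
                                 full = "FS_RT", n_sims = 500, sigma = 0.3,
                                 level = 0.05, seed = 1) {
  if (!is_nested(reduced, full)) {
    stop(reduced, " is not nested in ", full, call. = FALSE)
  }
  Xr <- design_matrix(trials, reduced)
  Xf <- design_matrix(trials, full)
  off_r <- attr(Xr, "offset")
  off_f <- attr(Xf, "offset")
  theta <- lsfit_coef(Xr, standardize_unit(trials$punishment) - off_r)
  mu <- off_r + drop(Xr %*% theta)
  n <- nrow(Xr)
  df1 <- ncol(Xf) - ncol(Xr)
  df2 <- n - ncol(Xf)
  set.seed(seed)
  rej <- vapply(seq_len(n_sims), function(i) {
    y <- mu + stats::rnorm(n, 0, sigma)
    rss_r <- sum((y - off_r - Xr %*% lsfit_coef(Xr, y - off_r))^2)
    rss_f <- sum((y - off_f - Xf %*% lsfit_coef(Xf, y - off_f))^2)
    f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
    stats::pf(f, df1, df2, lower.tail = FALSE) < level
  }, logical(1))
  list(rejection_rate = mean(rej), n_sims = n_sims, level = level)
}

#' Compare fitted models across a cohort
#'
#' Builds the per-participant AIC and MSE tables, ranks models within each
#' participant by AIC (ties broken by registry order), summarizes the mean
#' AIC and MSE per model, and tests MSE differences across models by one-way
#' ANOVA with Bonferroni-corrected pairwise comparisons (optionally including
#' a uniform null model per participant). For neural fits, the table
#' additionally resolves by channel and window, and a mean-AIC-by-window
#' profile is returned.
#'
#' @param fits List of `fit_result`s (behavioral: one per participant x
#'   model; neural: per participant x model x channel x window).
#' @param scope `"behavioral"` or `"neural"`.
#' @param include_null Add a uniform null model MSE per participant
#'   (behavioral scope only)? The null draws use `null_seed`.
#' @param values_by_participant Named list of each participant's standardized
#'   dependent values, required when `include_null = TRUE`.
#' @param null_seed Seed for the null model draws.
#' @return Object of class `model_comparison`: list with `table` (tidy per-fit
#'   rows + aic + rank), `summary` (per model mean AIC / MSE), `anova`
#'   (one-way ANOVA of MSE across models), `posthoc` (Bonferroni pairwise
#'   p-values), and for neural scope `aic_profile` (model x window mean AIC).
#' @export
compare_models <- function(fits, scope = c("behavioral", "neural"),
                           include_null = FALSE,
                           values_by_participant = NULL, null_seed = 1) {
  scope <- match.arg(scope)
  tab <- fits_to_table(fits)
  tab$aic <- aic_ls(tab$rss, tab$n, tab$k)
  tab$model_id <- factor(tab$model_id, levels = preference_models())

  if (scope == "behavioral") {
    tab <- tab[order(tab$participant_id, tab$model_id), ]
    tab$rank <- stats::ave(tab$aic, tab$participant_id,
                           FUN = function(a) rank(a, ties.method = "first"))
  }

  mse_tab <- tab[, c("participant_id", "model_id", "mse")]
  if (include_null) {
    if (scope != "behavioral") {
      stop("the uniform null model applies to the behavioral scope",
           call. = FALSE)
    }
    if (is.null(values_by_participant)) {
      stop("values_by_participant is required when include_null = TRUE",
           call. = FALSE)
    }
    nm <- mapply(function(v, i) null_model_mse(v, seed = null_seed + i),
                 values_by_participant, seq_along(values_by_participant))
    mse_tab <- rbind(mse_tab,
                     data.frame(participant_id = names(values_by_participant),
                                model_id = "null", mse = nm))
  }
  mse_tab$model_id <- factor(mse_tab$model_id)

  summary_tab <- stats::aggregate(cbind(aic, mse) ~ model_id, data = tab, FUN = mean)
  names(summary_tab) <- c("model_id", "mean_aic", "mean_mse")

  av <- posthoc <- NULL
  if (nlevels(mse_tab$model_id) > 1 &&
      length(unique(mse_tab$participant_id)) > 1) {
    av <- stats::aov(mse ~ model_id, data = mse_tab)
    posthoc <- stats::pairwise.t.test(mse_tab$mse, mse_tab$model_id,
                                      p.adjust.method = "bonferroni")
  }

  aic_profile <- NULL
  if (scope == "neural") {
    aic_profile <- stats::aggregate(aic ~ model_id + window, data = tab,
                                    FUN = mean)
    names(aic_profile) <- c("model_id", "window", "mean_aic")
  }
  structure(list(scope = scope, table = tab, summary = summary_tab,
                 mse_table = mse_tab, anova = av, posthoc = posthoc,
                 aic_profile = aic_profile),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", x$scope, " scope)\n", sep = "")
  s <- x$summary[order(x$summary$mean_aic), ]
  print(transform(s, mean_aic = round(mean_aic, 2), mean_mse = round(mean_mse, 4)),
        row.names = FALSE)
  if (!is.null(x$anova)) {
    a <- summary(x$anova)[[1]]
    cat(sprintf("MSE one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
                a$Df[1], a$Df[2], a$`F value`[1], a$`Pr(>F)`[1]))
  }
  invisible(x)
}

#' Winning model of a comparison
#'
#' @param comparison A `model_comparison`.
#' @param window_range Neural scope: restrict to windows (0-based indices)
#'   before averaging AIC, e.g. those around the hemodynamic peak.
#' @return Model id with the lowest mean AIC.
#' @export
winning_model <- function(comparison, window_range = NULL) {
  if (!is.null(window_range) && !is.null(comparison$aic_profile)) {
    pr <- comparison$aic_profile
    pr <- pr[pr$window %in% window_range, ]
    m <- stats::aggregate(mean_aic ~ model_id, data = pr, FUN = mean)
    return(as.character(m$model_id[which.min(m$mean_aic)]))
  }
  as.character(comparison$summary$model_id[which.min(comparison$summary$mean_aic)])
}
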