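#' Percentage-bend correlation
#'
#' Wilcox's robust correlation: each margin is bent by winsorizing the
#' fraction `beta` of its most extreme deviations from a robust location
#' before the product-moment step, protecting the estimate against marginal
#' outliers. With `m = floor((1 - beta) * n + 0.5)`, the bend scale `omega`
#' is the m-th smallest absolute deviation from the median; the robust
#' location `phi` comes from the winsorized-mean step; standardized
#' deviations are clipped to [-1, 1] and correlated. The p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param beta Bending constant in (0, 0.5] (default 0.2).
#' @return Object of class `pb_cor`: list with `r`, `n`, `bending_constant`,
#'   `statistic` (t), `p`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(40); percentage_bend_correlation(x, x + rnorm(40, 0, 0.3))
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (beta <= 0 || beta > 0.5) stop("beta must lie in (0, 0.5]", call. = FALSE)
  psi_dev <- function(v) {
    m <- floor((1 - beta) * n + 0.5)
    omega <- sort(abs(v - stats::median(v)))[m]
    if (omega <= 0) {
      stop("degenerate margin: bend scale omega is zero", call. = FALSE)
    }
    z <- (v - stats::median(v)) / omega
    i1 <- sum(z < -1)
    i2 <- sum(z > 1)
    sv <- sum(v[z >= -1 & z <= 1])
    phi <- (omega * (i2 - i1) + sv) / (n - i1 - i2)
    pmin(pmax((v - phi) / omega, -1), 1)
  }
  px <- psi_dev(x)
  py <- psi_dev(y)
  r <- sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, n = n, bending_constant = beta, statistic = tstat,
                 p = 2 * stats::pt(-abs(tstat), n - 2)),
            class = "pb_cor")
}

#' @export
print.pb_cor <- function(x, ...) {
  cat(sprintf("percentage-bend correlation: r = %.3f (n = %d, beta = %g), p = %.4g\n",
              x$r, x$n, x$bending_constant, x$p))
  invisible(x)
}

#' Compare two correlation coefficients
#'
#' Fisher r-to-z transformation followed by a z-test. The default treats the
#' two correlations as independent:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`. When the
#' correlations share a sample (e.g. both computed over the same
#' participants), set `dependent = TRUE` and supply `r12`, the correlation
#' between the two non-shared variables; Steiger's Z1* is then used.
#'
#' @param r1,r2 Correlations, |r| < 1.
#' @param n1,n2 Sample sizes (> 3); for the dependent test `n1` is used.
#' @param dependent Shared-sample variant?
#' @param r12 Correlation between the non-shared variables (dependent only).
#' @return List with `z` and two-sided `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2 = n1, dependent = FALSE,
                                 r12 = NULL) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("need n > 3", call. = FALSE)
  if (!dependent) {
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12)) stop("r12 is required for the dependent test", call. = FALSE)
    n <- n1
    rbar <- (r1 + r2) / 2
    # Steiger (1980) Z1*: covariance of the two dependent correlations
    s <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
    cov12 <- s / (1 - rbar^2)^2
    z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * cov12))
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-way factorial ANOVA with Bonferroni post-hocs
#'
#' Fits `value ~ A * B`, reports type-II sums of squares for the main
#' effects and interaction (type II and the classical decomposition coincide
#' for balanced designs), and Bonferroni-corrected pairwise comparisons for
#' each factor.
#'
#' @param data Data.frame holding the response and both factors.
#' @param response Name of the response column.
#' @param factors Character vector of two factor column names.
#' @return List with `table` (effect, df, sum_sq, F, p), `posthoc` (one
#'   pairwise matrix per factor), and the fitted `lm`.
#' @export
factorial_anova <- function(data, response, factors) {
  stopifnot(length(factors) == 2)
  for (f in factors) data[[f]] <- factor(data[[f]])
  counts <- table(data[[factors[1]]], data[[factors[2]]])
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", rownames(counts)[empty[1]], " x ",
         colnames(counts)[empty[2]], call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~", factors[1], "*", factors[2]))
  fit <- stats::lm(fml, data = data)
  a2 <- car::Anova(fit, type = 2)
  resid_row <- which(rownames(a2) == "Residuals")
  tab <- data.frame(effect = rownames(a2), df = a2$Df, sum_sq = a2$`Sum Sq`,
                    F = a2$`F value`, p = a2$`Pr(>F)`)
  posthoc <- lapply(factors, function(f) {
    stats::pairwise.t.test(data[[response]], data[[f]],
                           p.adjust.method = "bonferroni")$p.value
  })
  names(posthoc) <- factors
  list(table = tab, posthoc = posthoc, fit = fit, residual_df = a2$Df[resid_row])
}

#' Predict the behavioral utility series from the neural one
#'
#' Per participant and region, a linear support-vector regression maps the
#' trialwise neural utility series (the RT-enhanced Fehr--Schmidt utility
#' evaluated at the neural fit's parameters, one series per sliding window)
#' to the behavioral utility series (same expression at the behavioral fit's
#' parameters). The model is trained on a seeded 50% holdout split and scored
#' as the squared correlation between predicted and observed values on the
#' held-out half; the reported R^2 is the maximum over windows inside the
#' punishment phase (window start >= `punishment_onset_s` after transfer
#' onset).
#'
#' @param behavior_utilities Numeric vector, one fitted utility per trial.
#' @param neural_utilities Matrix trials x windows of fitted neural
#'   utilities.
#' @param window_starts_s Window start times (seconds after transfer onset),
#'   one per column.
#' @param holdout Fraction of trials held out for testing (default 0.5).
#' @param seed Seed for the split.
#' @param punishment_onset_s Start of the punishment phase (default 5 s, the
#'   end of the transfer phase).
#' @param cost,epsilon Linear SVR hyperparameters.
#' @return List with `r_squared` (max over punishment windows), `window_index`
#'   (0-based argmax), `r_squared_by_window`, `holdout_fraction`.
#' @export
predict_behavior_from_neural <- function(behavior_utilities, neural_utilities,
                                         window_starts_s, holdout = 0.5,
                                         seed = 1, punishment_onset_s = 5,
                                         cost = 1, epsilon = 0.1) {
  n <- length(behavior_utilities)
  if (n < 8) stop("need at least 8 trials", call. = FALSE)
  stopifnot(nrow(neural_utilities) == n,
            ncol(neural_utilities) == length(window_starts_s))
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(holdout * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  r2 <- vapply(seq_along(window_starts_s), function(w) {
    xtr <- neural_utilities[train_idx, w]
    xte <- neural_utilities[test_idx, w]
    if (stats::sd(xtr) == 0 || stats::sd(xte) == 0) return(0)
    m <- e1071::svm(x = matrix(xtr, ncol = 1),
                    y = behavior_utilities[train_idx],
                    type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = TRUE)
    pred <- stats::predict(m, matrix(xte, ncol = 1))
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, behavior_utilities[test_idx])^2
  }, numeric(1))
  pun <- which(window_starts_s >= punishment_onset_s)
  if (!length(pun)) stop("no window starts inside the punishment phase",
                         call. = FALSE)
  best <- pun[which.max(r2[pun])]
  list(r_squared = r2[best], window_index = best - 1L,
       r_squared_by_window = r2, holdout_fraction = holdout)
}
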