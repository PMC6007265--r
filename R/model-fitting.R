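#' Standardize a vector to [-1, 1]
#'
#' Min--max rescaling `x -> 2 * (x - min) / (max - min) - 1`, applied per
#' participant (behavioral punishments) or per participant-channel (neural
#' window values) before fitting, so that behavioral and neural fits share a
#' dependent-variable scale. A constant vector maps to all zeros.
#'
#' @param x Numeric vector (or matrix/array, rescaled over all its values).
#' @return Rescaled object of the same shape.
#' @export
standardize_unit <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) {
    x[] <- 0
    return(x)
  }
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

# uniform multi-start ranges per parameter (the NLS objective is smooth; the
# ranges just need to bracket plausible optima)
start_range <- function(param) {
  switch(param,
         alpha = , beta = , rho = , sigma = , theta = c(-2, 2),
         c(-1, 1))
}

new_fit_result <- function(participant_id, model_id, params, rss, n, k,
                           converged, n_starts_used, method,
                           channel = NA_character_, window = NA_integer_) {
  structure(list(participant_id = participant_id, model_id = model_id,
                 params = params, rss = rss, mse = rss / n, n = n, k = k,
                 converged = converged, n_starts_used = n_starts_used,
                 method = method, channel = channel, window = window),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s | %s | rss=%.4g mse=%.4g (n=%d, k=%d)%s\n",
              x$participant_id, x$model_id, x$rss, x$mse, x$n, x$k,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$params, 5))
  invisible(x)
}

#' Collect fit results into a tidy data.frame
#'
#' @param fits A `fit_result` or list of them.
#' @return One row per fit: identifiers, rss/mse/n/k, convergence, and one
#'   column per parameter (NA where a model lacks it).
#' @export
fits_to_table <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  all_pars <- unique(unlist(lapply(fits, function(f) names(f$params))))
  get <- function(field, proto) vapply(fits, `[[`, proto, field)
  out <- data.frame(
    participant_id = get("participant_id", character(1)),
    model_id = get("model_id", character(1)),
    channel = get("channel", character(1)),
    window = get("window", integer(1)),
    rss = get("rss", numeric(1)), mse = get("mse", numeric(1)),
    n = as.integer(get("n", numeric(1))), k = as.integer(get("k", numeric(1))),
    converged = get("converged", logical(1)))
  for (p in all_pars) {
    out[[p]] <- vapply(fits, function(f) unname(f$params[p])[1], numeric(1))
  }
  rownames(out) <- NULL
  out
}

# least-squares coefficients; aliased (rank-deficient) columns get 0 so the
# fit is defined even when a regressor is degenerate on the data (e.g. a
# disadvantageous-inequality gap that is zero on every trial)
lsfit_coef <- function(X, y) {
  cf <- stats::lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  stats::setNames(cf, colnames(X))
}

# residual sum of squares and gradient for a linear-in-parameters model
rss_objective <- function(theta, X, y, off) {
  r <- y - off - drop(X %*% theta)
  sum(r^2)
}
rss_gradient <- function(theta, X, y, off) {
  r <- y - off - drop(X %*% theta)
  -2 * drop(crossprod(X, r))
}

#' Fit a preference model to one participant's punishment behavior
#'
#' The standardized punishment amounts (rescaled to [-1, 1]) are regressed on
#' the model's utility expression by nonlinear least squares with multiple
#' seeded uniform start locations (guarding against local minima; the best
#' start is kept). `FS_standard` imposes the original constraints
#' alpha >= beta, 0 <= beta < 1 through a bounded reparameterization
#' (alpha = beta + delta, delta >= 0, beta in [0, 1 - 1e-6]). For the
#' linear-in-parameters models `method = "ols"` solves the identical
#' least-squares problem in closed form; the default multi-start NLS agrees
#' with it to numerical precision.
#'
#' @param trials `trial_table` of a single participant.
#' @param model_id One of [preference_models()].
#' @param n_starts Number of random start locations (default 20).
#' @param method `"nls"` (multi-start optimizer, default) or `"ols"`
#'   (closed form; falls back to NLS for the constrained `FS_standard`).
#' @param seed Seed for the start locations.
#' @param reltol Optimizer convergence tolerance.
#' @return A `fit_result` (flagged, not an error, if no start converges).
#' @export
fit_behavior <- function(trials, model_id, n_starts = 20,
                         method = c("nls", "ols"), seed = 1, reltol = 1e-10) {
  method <- match.arg(method)
  model_id <- match.arg(model_id, preference_models())
  pid <- as.character(trials$participant_id[1])
  X <- design_matrix(trials, model_id)
  off <- attr(X, "offset")
  k <- ncol(X)
  if (nrow(X) < k + 2) stop("need at least k + 2 trials", call. = FALSE)
  y <- standardize_unit(trials$punishment)

  if (model_id == "FS_standard") {
    return(fit_fs_standard(pid, X, y, off, n_starts, seed, reltol))
  }
  if (method == "ols") {
    theta <- lsfit_coef(X, y - off)
    rss <- rss_objective(theta, X, y, off)
    return(new_fit_result(pid, model_id, theta, rss, length(y), k,
                          TRUE, 1L, "ols"))
  }
  set.seed(seed)
  ranges <- vapply(colnames(X), start_range, numeric(2))
  best <- NULL
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    theta0 <- stats::runif(k, ranges[1, ], ranges[2, ])
    opt <- try(stats::optim(theta0, rss_objective, rss_gradient,
                            X = X, y = y, off = off, method = "BFGS",
                            control = list(reltol = reltol, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) {
    theta <- stats::setNames(rep(NA_real_, k), colnames(X))
    return(new_fit_result(pid, model_id, theta, NA_real_, length(y), k,
                          FALSE, n_starts, "nls"))
  }
  theta <- stats::setNames(best$par, colnames(X))
  new_fit_result(pid, model_id, theta, best$value, length(y), k,
                 conv, n_starts, "nls")
}

# constrained Fehr-Schmidt fit: optimize (p, beta, delta) with alpha = beta + delta
fit_fs_standard <- function(pid, X, y, off, n_starts, seed, reltol) {
  obj <- function(par) {
    rss_objective(c(par[1], par[2] + par[3], par[2]), X, y, off)
  }
  grd <- function(par) {
    g <- rss_gradient(c(par[1], par[2] + par[3], par[2]), X, y, off)
    c(g[1], g[2] + g[3], g[2])  # chain rule: alpha = beta + delta
  }
  lower <- c(-Inf, 0, 0)
  upper <- c(Inf, 1 - 1e-6, Inf)
  set.seed(seed)
  best <- NULL
  conv <- FALSE
  for (s in seq_len(n_starts)) {
    par0 <- c(stats::runif(1, -1, 1), stats::runif(1, 0, 1 - 1e-6),
              stats::runif(1, 0, 2))
    opt <- try(stats::optim(par0, obj, grd, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = reltol / .Machine$double.eps,
                                           maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) {
    theta <- c(p_reward_responder = NA_real_, alpha = NA_real_, beta = NA_real_)
    return(new_fit_result(pid, "FS_standard", theta, NA_real_, length(y), 3L,
                          FALSE, n_starts, "nls"))
  }
  theta <- c(p_reward_responder = best$par[1],
             alpha = best$par[2] + best$par[3], beta = best$par[2])
  new_fit_result(pid, "FS_standard", theta, best$value, length(y), 3L,
                 conv, n_starts, "nls")
}

#' Robust linear regression with the fair weight function
#'
#' Iteratively reweighted least squares with fair weights
#' `w(r) = 1 / (1 + |r / (c * s)|)`, `c = 1.3998`, where `s` is the robust
#' residual scale MAD / 0.6745. No intercept is fitted (the utility models
#' have none). Used internally by [fit_neural()]; exported for testing.
#'
#' @param X Design matrix (no intercept column added).
#' @param y Response.
#' @param offset Known offset subtracted from `y`.
#' @param c_tuning Fair tuning constant.
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return List with `coefficients`, `rss` (unweighted residual sum of
#'   squares), `iterations`, `converged`.
#' @export
robust_fair_lm <- function(X, y, offset = 0, c_tuning = 1.3998,
                           max_iter = 50, tol = 1e-8) {
  yy <- y - offset
  rank_ok <- qr(X)$rank == ncol(X)
  beta <- lsfit_coef(X, yy)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- yy - drop(X %*% beta)
    s <- stats::mad(r, constant = 1) / 0.6745
    if (s <= .Machine$double.eps) {  # (near-)exact fit; weights undefined
      converged <- TRUE
      break
    }
    w <- 1 / (1 + abs(r / (c_tuning * s)))
    beta_new <- lsfit_coef(X * sqrt(w), yy * sqrt(w))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  r <- yy - drop(X %*% beta)
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       rss = sum(r^2), iterations = it, converged = converged,
       rank_deficient = !rank_ok)
}

#' Fit a preference model to neural window responses
#'
#' Robust multiple linear regression (fair weight function, see
#' [robust_fair_lm()]) of standardized per-trial window values on the model's
#' utility regressors, per channel (or region) and sliding window.
#' `FS_standard` is not fitted to neural data. Standardization to [-1, 1] is
#' performed per channel across all trials and windows jointly, so window
#' values remain comparable along the epoch.
#'
#' @param windows Array `[trial, channel, window]` from [extract_windows()]
#'   or [average_regions()].
#' @param trials `trial_table` of the same participant, same trial order.
#' @param model_id Any model except `FS_standard`.
#' @param channels,window_indices Optional subsets (channel names / 0-based
#'   window indices) to restrict the fit grid.
#' @param standardized Set `TRUE` if `windows` is already standardized.
#' @return List of `fit_result`s, one per channel x window cell.
#' @details Standardization is applied to each regression's dependent
#'   variable, i.e. per channel and window across trials, exactly as the
#'   punishment vector is standardized per participant in the behavioral
#'   fits. This keeps the AIC-by-window profile comparable across windows.
#' @export
fit_neural <- function(windows, trials, model_id, channels = NULL,
                       window_indices = NULL, standardized = FALSE) {
  model_id <- match.arg(model_id, setdiff(preference_models(), "FS_standard"))
  pid <- as.character(trials$participant_id[1])
  X <- design_matrix(trials, model_id)
  off <- attr(X, "offset")
  if (nrow(X) < ncol(X) + 2) stop("need at least k + 2 trials", call. = FALSE)
  ch_names <- dimnames(windows)[[2]]
  if (is.null(channels)) channels <- ch_names
  n_win <- dim(windows)[3]
  if (is.null(window_indices)) window_indices <- seq_len(n_win) - 1L
  fits <- list()
  for (ch in channels) {
    vals <- windows[, ch, , drop = TRUE]
    if (!standardized) vals <- apply(vals, 2, standardize_unit)
    for (k in window_indices) {
      y <- vals[, k + 1]
      rf <- robust_fair_lm(X, y, offset = off)
      fits[[length(fits) + 1]] <-
        new_fit_result(pid, model_id, rf$coefficients, rf$rss, length(y),
                       ncol(X), rf$converged, 1L, "robust_fair",
                       channel = ch, window = as.integer(k))
    }
  }
  fits
}
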