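#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles the task economics, cohort size, preprocessing switches and
#' fitting options consumed by [run_pipeline()].
#'
#' @param n_participants Cohort size (the study this emulates ran 48; the
#'   default keeps the demo fast).
#' @param n_trials Trials per participant.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param behavioral_only Skip all fNIRS stages?
#' @param despike Apply the MAD despiker during preprocessing (off by
#'   default)?
#' @param behavior_method `"nls"` (default) or `"ols"` fitting path for
#'   the behavioral models (identical solutions for the linear models).
#' @param n_starts Multi-start count for the behavioral NLS.
#' @param peak_windows 0-based sliding-window indices treated as the
#'   hemodynamic-peak band when declaring the neural winner (defaults to
#'   windows whose centers fall 6--8 s after transfer onset).
#' @param cfg A [task_config()].
#' @param grid A [window_grid()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_participants = 8, n_trials = 60, seed = 1,
                       behavioral_only = FALSE, despike = FALSE,
                       behavior_method = c("nls", "ols"), n_starts = 20,
                       peak_windows = NULL, cfg = task_config(),
                       grid = window_grid()) {
  behavior_method <- match.arg(behavior_method)
  if (is.null(peak_windows)) {
    centers <- grid$starts_s + grid$width_s / 2
    peak_windows <- which(centers >= 6 & centers <= 8) - 1L
  }
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 seed = seed, behavioral_only = behavioral_only,
                 despike = despike, behavior_method = behavior_method,
                 n_starts = n_starts, peak_windows = peak_windows,
                 cfg = cfg, grid = grid),
            class = "run_config")
}

# preprocess one participant's optical recording to region-level windows
preprocess_participant <- function(rec, timeline, config) {
  series <- od_to_concentration(rec)
  series <- baseline_correct(series)
  series <- detrend_channels(series)
  if (config$despike) series <- despike_channels(series)
  win <- extract_windows(series, timeline, config$grid)
  average_regions(win)
}

#' Run the full simulate / preprocess / fit / compare / correlate pipeline
#'
#' Stages: (1) simulate a seeded synthetic cohort (punishment choices, RTs
#' and, unless `behavioral_only`, optical recordings); (2) invert the
#' Beer--Lambert law, baseline-correct, detrend and window the hemodynamics,
#' averaged to dlPFC / dmPFC region series; (3) fit all nine models to each
#' participant's standardized punishments and eight models (no constrained
#' Fehr--Schmidt) to each region x window response; (4) compare models by
#' AIC/MSE with a uniform null model and run the nested F-tests of the
#' RT-enhanced Fehr--Schmidt model against its reductions; (5) relate
#' behavioral to neural preference parameters (two-way ANOVA,
#' percentage-bend correlations, correlation comparison) and predict the
#' behavioral utility series from the neural one by linear SVR per region.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, tidy CSV artifacts and a
#'   text report are written there.
#' @return List of artifacts: `trials`, `truth`, `behavioral_fits`,
#'   `behavioral_comparison`, `nested_tests`, and unless behavioral-only
#'   `neural_fits`, `neural_comparison` (dlPFC), `parameter_stats`,
#'   `correlations`, `prediction`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  cohort <- simulate_cohort(config$n_participants, seed = config$seed,
                            n_trials = config$n_trials, cfg = config$cfg,
                            optics = !config$behavioral_only)
  ids <- unique(cohort$trials$participant_id)
  trials_by_p <- split(cohort$trials, cohort$trials$participant_id)[ids]

  behavioral_fits <- list()
  for (pid in ids) {
    for (m in preference_models()) {
      behavioral_fits[[paste(pid, m)]] <-
        fit_behavior(trials_by_p[[pid]], m, n_starts = config$n_starts,
                     method = config$behavior_method,
                     seed = config$seed + match(pid, ids))
    }
  }
  std_pun <- lapply(trials_by_p, function(d) standardize_unit(d$punishment))
  behavioral_comparison <- compare_models(
    behavioral_fits, "behavioral", include_null = TRUE,
    values_by_participant = std_pun, null_seed = config$seed)

  nested_tests <- do.call(rbind, lapply(ids, function(pid) {
    fu <- behavioral_fits[[paste(pid, "FS_unconstrained")]]
    fr <- behavioral_fits[[paste(pid, "RT_only")]]
    ff <- behavioral_fits[[paste(pid, "FS_RT")]]
    rbind(data.frame(participant_id = pid, reduced = "FS_unconstrained",
                     full = "FS_RT", as.data.frame(nested_f(fu, ff))),
          data.frame(participant_id = pid, reduced = "RT_only",
                     full = "FS_RT", as.data.frame(nested_f(fr, ff))))
  }))

  artifacts <- list(config = config, trials = cohort$trials,
                    truth = cohort$truth,
                    behavioral_fits = behavioral_fits,
                    behavioral_comparison = behavioral_comparison,
                    nested_tests = nested_tests)

  if (!config$behavioral_only) {
    neural_models <- setdiff(preference_models(), "FS_standard")
    neural_fits <- list()
    windows_by_p <- list()
    for (pid in ids) {
      win <- preprocess_participant(cohort$optics[[pid]],
                                    cohort$timelines[[pid]], config)
      windows_by_p[[pid]] <- win
      for (m in neural_models) {
        neural_fits <- c(neural_fits,
                         fit_neural(win, trials_by_p[[pid]], m))
      }
    }
    dl_fits <- Filter(function(f) f$channel == "dlPFC", neural_fits)
    neural_comparison <- compare_models(dl_fits, "neural")

    artifacts$neural_fits <- neural_fits
    artifacts$windows <- windows_by_p
    artifacts$neural_comparison <- neural_comparison
    artifacts$parameter_stats <- parameter_statistics(artifacts)
    artifacts$prediction <- prediction_analysis(artifacts)
  }

  if (!is.null(out_dir)) write_artifacts(artifacts, out_dir)
  artifacts
}

# behavioral-vs-neural parameter ANOVA and percentage-bend correlations on
# the RT-enhanced Fehr-Schmidt parameters; neural parameters are taken at
# the dlPFC window with the lowest mean FS_RT AIC
parameter_statistics <- function(artifacts) {
  tab_b <- fits_to_table(artifacts$behavioral_fits)
  tab_b <- tab_b[tab_b$model_id == "FS_RT", ]
  tab_n <- fits_to_table(artifacts$neural_fits)
  tab_n <- tab_n[tab_n$model_id == "FS_RT" & tab_n$channel == "dlPFC", ]
  tab_n$aic <- aic_ls(tab_n$rss, tab_n$n, tab_n$k)
  prof <- stats::aggregate(aic ~ window, data = tab_n, FUN = mean)
  best_window <- prof$window[which.min(prof$aic)]
  tab_nb <- tab_n[tab_n$window == best_window, ]

  pars <- c("p_reward_responder", "alpha", "beta", "p_rt")
  long <- rbind(
    data.frame(data_type = "behavioral",
               parameter = rep(pars, each = nrow(tab_b)),
               participant_id = tab_b$participant_id,
               value = unlist(tab_b[pars], use.names = FALSE)),
    data.frame(data_type = "neural",
               parameter = rep(pars, each = nrow(tab_nb)),
               participant_id = tab_nb$participant_id,
               value = unlist(tab_nb[pars], use.names = FALSE)))
  anova_res <- factorial_anova(long, "value", c("data_type", "parameter"))

  ord <- match(tab_b$participant_id, tab_nb$participant_id)
  # a margin can be degenerate (many identical fitted parameters); report NA
  # rather than aborting the run
  safe_pb <- function(x, y) {
    tryCatch(percentage_bend_correlation(x, y),
             error = function(e) structure(list(r = NA_real_, n = length(x),
                                                bending_constant = 0.2,
                                                statistic = NA_real_,
                                                p = NA_real_),
                                           class = "pb_cor"))
  }
  pb_alpha <- safe_pb(tab_b$alpha, tab_nb$alpha[ord])
  pb_beta <- safe_pb(tab_b$beta, tab_nb$beta[ord])
  cmp <- if (is.na(pb_alpha$r) || is.na(pb_beta$r)) {
    list(z = NA_real_, p = NA_real_)
  } else {
    compare_correlations(pb_beta$r, pb_beta$n, pb_alpha$r, pb_alpha$n)
  }

  list(best_window = best_window, parameters_long = long, anova = anova_res,
       pb_alpha = pb_alpha, pb_beta = pb_beta, alpha_vs_beta_corr = cmp,
       behavioral_params = tab_b, neural_params = tab_nb)
}

# per-participant SVR prediction of the behavioral utility series from the
# neural ones, per region, scored on a 50% holdout
prediction_analysis <- function(artifacts) {
  ids <- unique(artifacts$trials$participant_id)
  trials_by_p <- split(artifacts$trials, artifacts$trials$participant_id)[ids]
  tab_n <- fits_to_table(artifacts$neural_fits)
  tab_n <- tab_n[tab_n$model_id == "FS_RT", ]
  tab_b <- fits_to_table(artifacts$behavioral_fits)
  tab_b <- tab_b[tab_b$model_id == "FS_RT", ]
  starts <- artifacts$config$grid$starts_s
  pars <- c("p_reward_responder", "alpha", "beta", "p_rt")

  rows <- list()
  for (pid in ids) {
    tt <- trials_by_p[[pid]]
    X <- design_matrix(tt, "FS_RT")
    bp <- tab_b[tab_b$participant_id == pid, pars]
    u_beh <- drop(X %*% as.numeric(bp))
    for (region in c("dlPFC", "dmPFC")) {
      tn <- tab_n[tab_n$participant_id == pid & tab_n$channel == region, ]
      tn <- tn[order(tn$window), ]
      u_neur <- X %*% t(as.matrix(tn[pars]))  # trials x windows
      res <- predict_behavior_from_neural(
        u_beh, u_neur, starts[tn$window + 1],
        seed = artifacts$config$seed + match(pid, ids))
      rows[[paste(pid, region)]] <-
        data.frame(participant_id = pid, region = region,
                   r_squared = res$r_squared, window_index = res$window_index)
    }
  }
  pred <- do.call(rbind, rows)
  wide <- stats::reshape(pred[, c("participant_id", "region", "r_squared")],
                         idvar = "participant_id", timevar = "region",
                         direction = "wide")
  ttest <- stats::t.test(wide$r_squared.dlPFC, wide$r_squared.dmPFC,
                         paired = TRUE)
  list(table = pred,
       mean_r2 = c(dlPFC = mean(pred$r_squared[pred$region == "dlPFC"]),
                   dmPFC = mean(pred$r_squared[pred$region == "dmPFC"])),
       paired_t = list(t = unname(ttest$statistic), p = ttest$p.value))
}

write_artifacts <- function(artifacts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(artifacts$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(artifacts$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(fits_to_table(artifacts$behavioral_fits),
                   file.path(out_dir, "behavioral_fits.csv"), row.names = FALSE)
  utils::write.csv(artifacts$behavioral_comparison$summary,
                   file.path(out_dir, "behavioral_model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(artifacts$nested_tests,
                   file.path(out_dir, "nested_f_tests.csv"), row.names = FALSE)
  if (!is.null(artifacts$neural_fits)) {
    utils::write.csv(fits_to_table(artifacts$neural_fits),
                     file.path(out_dir, "neural_fits.csv"), row.names = FALSE)
    utils::write.csv(artifacts$neural_comparison$aic_profile,
                     file.path(out_dir, "neural_aic_by_window.csv"),
                     row.names = FALSE)
    utils::write.csv(artifacts$prediction$table,
                     file.path(out_dir, "prediction_r2.csv"), row.names = FALSE)
  }
  writeLines(utils::capture.output(pipeline_report(artifacts)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' Prints the behavioral AIC ranking and winner, the distribution of the
#' recovered inequality-aversion parameters (fractions with alpha > beta and
#' beta < 0), the neural winner around the hemodynamic peak, the
#' psychometric--neurometric correlations and the region-wise prediction
#' R^2.
#'
#' @param artifacts Return value of [run_pipeline()].
#' @return `artifacts`, invisibly.
#' @export
pipeline_report <- function(artifacts) {
  cat("== Pipeline report ==\n\n-- Behavioral model comparison --\n")
  print(artifacts$behavioral_comparison)
  cat("Winning behavioral model:",
      winning_model(artifacts$behavioral_comparison), "\n\n")

  tab_b <- fits_to_table(artifacts$behavioral_fits)
  tab_b <- tab_b[tab_b$model_id == "FS_RT", ]
  cat("-- RT-enhanced Fehr-Schmidt behavioral parameters --\n")
  cat(sprintf("alpha (DI): mean %.3f, range [%.3f, %.3f]\n",
              mean(tab_b$alpha), min(tab_b$alpha), max(tab_b$alpha)))
  cat(sprintf("beta (AI):  mean %.3f, range [%.3f, %.3f]\n",
              mean(tab_b$beta), min(tab_b$beta), max(tab_b$beta)))
  cat(sprintf("alpha > beta in %.0f%% of participants; beta < 0 in %.0f%%\n\n",
              100 * mean(tab_b$alpha > tab_b$beta),
              100 * mean(tab_b$beta < 0)))

  if (!is.null(artifacts$nested_tests)) {
    nt <- artifacts$nested_tests
    for (red in unique(nt$reduced)) {
      sel <- nt[nt$reduced == red, ]
      cat(sprintf("nested F (%s vs FS_RT): median F = %.2f, %d/%d participants p < 0.05\n",
                  red, stats::median(sel$F), sum(sel$p < 0.05), nrow(sel)))
    }
    cat("\n")
  }

  if (!is.null(artifacts$neural_comparison)) {
    cat("-- Neural model comparison (dlPFC) --\n")
    cat("Winner at hemodynamic-peak windows:",
        winning_model(artifacts$neural_comparison,
                      artifacts$config$peak_windows), "\n")
    ps <- artifacts$parameter_stats
    cat(sprintf("best dlPFC window: %d (start %.2f s)\n\n", ps$best_window,
                artifacts$config$grid$starts_s[ps$best_window + 1]))
    cat("-- Psychometric-neurometric correlations --\n")
    print(ps$pb_alpha)
    print(ps$pb_beta)
    cat(sprintf("beta-vs-alpha correlation difference: z = %.2f, p = %.4g\n\n",
                ps$alpha_vs_beta_corr$z, ps$alpha_vs_beta_corr$p))
    pr <- artifacts$prediction
    cat("-- SVR prediction of behavioral from neural utility --\n")
    cat(sprintf("mean holdout R^2: dlPFC %.2f vs dmPFC %.2f (paired t p = %.4g)\n",
                pr$mean_r2["dlPFC"], pr$mean_r2["dmPFC"], pr$paired_t$p))
  } else {
    cat("(fNIRS stages skipped: behavioral-only run)\n")
  }
  invisible(artifacts)
}
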