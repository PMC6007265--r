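#' The nine social-preference models
#'
#' Registry of the competing utility models of responder behavior. All models
#' value the post-punishment payoffs X_responder and X_proposer (and, for the
#' RT-aware variants, the trial's response time):
#'
#' * `FS_unconstrained` -- Fehr--Schmidt inequity aversion,
#'   U = P * X_r - alpha * max(X_p - X_r, 0) - beta * max(X_r - X_p, 0),
#'   with alpha (aversion to disadvantageous inequality) and beta (aversion to
#'   advantageous inequality) free; beta < 0 expresses AI seeking.
#' * `FS_standard` -- the same utility under the original constraints
#'   alpha >= beta and 0 <= beta < 1.
#' * `TotalReward` -- efficiency only: U = P_total * (X_r + X_p).
#' * `RewardDifference` -- U = P_diff * (X_r - X_p).
#' * `ProposerReward` -- U = P_prop * X_p.
#' * `LinearCombination` -- U = P_resp * X_r + P_prop * X_p.
#' * `CharnessRabin` -- efficiency/reciprocity weights:
#'   U = (rho*r + sigma*s + theta*q) * X_p + (1 - rho*r - sigma*s - theta*q) * X_r
#'   with r = 1 iff X_r > X_p (AI), s = 1 iff X_r < X_p (DI), and q = -1 iff
#'   the proposer misbehaved (any transfer below 50 points).
#' * `FS_RT` -- the unconstrained Fehr--Schmidt utility minus P_RT * RT,
#'   using response time as a proxy for choice difficulty.
#' * `RT_only` -- U = P_RT * RT.
#'
#' @return Character vector of model identifiers, in registry order (used for
#'   deterministic tie-breaking in comparisons).
#' @export
preference_models <- function() {
  c("FS_unconstrained", "FS_standard", "TotalReward", "RewardDifference",
    "ProposerReward", "LinearCombination", "CharnessRabin", "FS_RT", "RT_only")
}

#' @rdname preference_models
#' @param model_id One of `preference_models()`.
#' @return `model_params()` returns the names of the model's free parameters.
#' @export
model_params <- function(model_id) {
  model_id <- match.arg(model_id, preference_models())
  switch(model_id,
         FS_unconstrained = ,
         FS_standard = c("p_reward_responder", "alpha", "beta"),
         TotalReward = "p_reward_total",
         RewardDifference = "p_reward_difference",
         ProposerReward = "p_reward_proposer",
         LinearCombination = c("p_reward_responder", "p_reward_proposer"),
         CharnessRabin = c("rho", "sigma", "theta"),
         FS_RT = c("p_reward_responder", "alpha", "beta", "p_rt"),
         RT_only = "p_rt")
}

#' Linear-in-parameters design matrix of a model
#'
#' Every model is linear in its parameters, so its utility can be written as
#' `offset + X %*% params`. For the Fehr--Schmidt family the columns are
#' X_responder, minus the DI gap max(X_p - X_r, 0) and minus the AI gap
#' max(X_r - X_p, 0) (plus minus RT for the RT-enhanced variant). The
#' Charness--Rabin model is rewritten with regressors
#' r*(X_p - X_r), s*(X_p - X_r), q*(X_p - X_r) and a fixed offset X_r.
#'
#' @param trials A `trial_table` (needs columns `transfer`, `payoff_responder`,
#'   `payoff_proposer`, `rt_s`).
#' @param model_id One of [preference_models()].
#' @return Numeric matrix (trials x parameters) with an `"offset"` attribute
#'   (numeric vector, zero for all models except Charness--Rabin).
#' @export
design_matrix <- function(trials, model_id) {
  model_id <- match.arg(model_id, preference_models())
  xr <- trials$payoff_responder
  xp <- trials$payoff_proposer
  di_gap <- pmax(xp - xr, 0)   # disadvantageous inequality
  ai_gap <- pmax(xr - xp, 0)   # advantageous inequality
  off <- numeric(length(xr))
  X <- switch(
    model_id,
    FS_unconstrained = ,
    FS_standard = cbind(p_reward_responder = xr, alpha = -di_gap, beta = -ai_gap),
    TotalReward = cbind(p_reward_total = xr + xp),
    RewardDifference = cbind(p_reward_difference = xr - xp),
    ProposerReward = cbind(p_reward_proposer = xp),
    LinearCombination = cbind(p_reward_responder = xr, p_reward_proposer = xp),
    CharnessRabin = {
      r <- as.numeric(xr > xp)
      s <- as.numeric(xr < xp)
      q <- -as.numeric(trials$transfer < 50)
      off <- xr
      cbind(rho = r * (xp - xr), sigma = s * (xp - xr), theta = q * (xp - xr))
    },
    FS_RT = cbind(p_reward_responder = xr, alpha = -di_gap, beta = -ai_gap,
                  p_rt = -trials$rt_s),
    RT_only = cbind(p_rt = trials$rt_s))
  attr(X, "offset") <- off
  X
}

#' Evaluate a model's utility on trials
#'
#' @param trials A `trial_table`.
#' @param params Named list or vector holding `model_id` (or passed via the
#'   `model_id` argument) and one value per free parameter of that model.
#' @param model_id Model identifier; defaults to `params$model_id`.
#' @return Numeric vector of utilities, one per trial.
#' @export
#' @examples
#' tt <- make_trial_table("p1", 20, 0, 1)
#' utility(tt, list(p_reward_responder = 1, alpha = 0.5, beta = 0),
#'         model_id = "FS_unconstrained")  # 50 - 0.5 * 60 = 20
utility <- function(trials, params, model_id = params$model_id) {
  if (is.null(model_id)) stop("model_id must be given", call. = FALSE)
  model_id <- match.arg(model_id, preference_models())
  wanted <- model_params(model_id)
  vals <- unlist(params[wanted])
  if (length(vals) != length(wanted) || any(is.na(vals))) {
    stop("model ", model_id, " needs parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  if (model_id == "FS_standard") {
    if (!(vals["alpha"] >= vals["beta"] && vals["beta"] >= 0 && vals["beta"] < 1)) {
      stop("FS_standard requires alpha >= beta and 0 <= beta < 1", call. = FALSE)
    }
  }
  X <- design_matrix(trials, model_id)
  drop(attr(X, "offset") + X %*% vals)
}

#' Is one model nested in another?
#'
#' A reduced model is nested in a full model when every utility function the
#' reduced model can express is also expressible by the full model. Checked
#' algebraically on a probe grid of trials: the reduced design's column space
#' (and offset difference) must lie in the span of the full design.
#'
#' @param reduced,full Model identifiers.
#' @param cfg A [task_config()] used to build the probe trials.
#' @return Logical scalar.
#' @export
#' @examples
#' is_nested("FS_unconstrained", "FS_RT")  # TRUE
#' is_nested("CharnessRabin", "FS_RT")     # FALSE
is_nested <- function(reduced, full, cfg = task_config()) {
  reduced <- match.arg(reduced, preference_models())
  full <- match.arg(full, preference_models())
  probe <- probe_trials(cfg)
  Xr <- design_matrix(probe, reduced)
  Xf <- design_matrix(probe, full)
  doff <- attr(Xr, "offset") - attr(Xf, "offset")
  aug <- cbind(Xf, Xr, doff)
  qr(aug, tol = 1e-9)$rank == qr(Xf, tol = 1e-9)$rank
}

# Deterministic grid of trials spanning AI/E/DI states and RT variation,
# used for span-based nesting checks.
probe_trials <- function(cfg = task_config()) {
  g <- expand.grid(transfer = cfg$transfer_levels,
                   punishment = c(0L, 7L, 13L, 20L, 26L, cfg$max_punishment))
  rt <- 0.5 + 6 * (seq_len(nrow(g)) %% 11) / 11
  make_trial_table("probe", g$transfer, g$punishment, rt, cfg)
}
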