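#' Specification of a synthetic responder
#'
#' A synthetic agent holds the generating utility model and the nuisance
#' parameters of the forward simulation: softmax decision noise on the
#' punishment grid, an inverted-U response-time curve over transfers, and the
#' neural coupling gains that turn trial utilities into hemodynamic
#' amplitudes (stronger in dlPFC than dmPFC channels by default).
#'
#' @param participant_id Identifier.
#' @param true_params Named list of generating utility parameters.
#' @param model_id Generating model (default the RT-enhanced Fehr--Schmidt).
#' @param choice_temperature Softmax temperature in utility units; 0 gives
#'   exact utility maximization (ties broken toward smaller punishments).
#' @param rt_curve List with `r_peak`, `r_base` (seconds), `t_peak`, `width`
#'   (points) and `ai_di_slowdown` (seconds added on unequal outcomes).
#' @param neural_gain_dlpfc,neural_gain_dmpfc Hemodynamic amplitude
#'   (concentration units) per unit of standardized utility.
#' @param noise_sd_behavior Gaussian RT jitter, seconds.
#' @param noise_sd_optical White-noise s.d. added to the optical densities.
#' @param seed Integer seed owned by this agent.
#' @return Object of class `agent_spec`.
#' @export
agent_spec <- function(participant_id = "agent01",
                       true_params = list(p_reward_responder = 0.2,
                                          alpha = 0.06, beta = -0.5,
                                          p_rt = 0.5),
                       model_id = "FS_RT",
                       choice_temperature = 0.1,
                       rt_curve = list(r_peak = 4, r_base = 1.5, t_peak = 20,
                                       width = 15, ai_di_slowdown = 0.3),
                       neural_gain_dlpfc = 5e-6,
                       neural_gain_dmpfc = 2.5e-6,
                       noise_sd_behavior = 0.35,
                       noise_sd_optical = 2,
                       seed = 1L) {
  if (choice_temperature < 0) stop("choice_temperature must be >= 0", call. = FALSE)
  if (rt_curve$r_base <= 0 || rt_curve$r_peak <= 0) {
    stop("rt_curve times must be positive", call. = FALSE)
  }
  model_id <- match.arg(model_id, preference_models())
  structure(list(participant_id = participant_id,
                 true_params = true_params, model_id = model_id,
                 choice_temperature = choice_temperature,
                 rt_curve = rt_curve,
                 neural_gain_dlpfc = neural_gain_dlpfc,
                 neural_gain_dmpfc = neural_gain_dmpfc,
                 noise_sd_behavior = noise_sd_behavior,
                 noise_sd_optical = noise_sd_optical,
                 seed = as.integer(seed)),
            class = "agent_spec")
}

#' Session timeline of trial onsets
#'
#' Trials follow a 5 s transfer phase, a 7 s response window and an
#' inter-trial interval of 5 s plus uniform jitter with mean 5 s. A 60 s
#' event-free baseline precedes the first trial. Sampling rate is 10 Hz.
#'
#' @param n_trials Number of trials.
#' @param fs Sampling rate, Hz.
#' @param transfer_phase_s,response_window_s,iti_fixed_s Phase durations (s).
#' @param iti_jitter_mean_s Mean of the uniform ITI jitter (draws from
#'   `U(0, 2 * mean)`), seconds.
#' @param baseline_s Event-free lead-in, seconds.
#' @return Object of class `session_timeline` with trial onsets in seconds.
#' @export
session_timeline <- function(n_trials = 60, fs = 10, transfer_phase_s = 5,
                             response_window_s = 7, iti_fixed_s = 5,
                             iti_jitter_mean_s = 5, baseline_s = 60) {
  jitter <- stats::runif(n_trials, 0, 2 * iti_jitter_mean_s)
  spacing <- transfer_phase_s + response_window_s + iti_fixed_s + jitter
  onsets <- baseline_s + cumsum(c(0, spacing[-n_trials]))
  duration <- baseline_s + sum(spacing)
  structure(list(onsets_s = onsets, fs = fs, n_trials = n_trials,
                 transfer_phase_s = transfer_phase_s,
                 response_window_s = response_window_s,
                 baseline_s = baseline_s, duration_s = duration),
            class = "session_timeline")
}

# Deterministic part of the response time: inverted-U over transfers plus a
# slowdown when the final distribution is unequal.
rt_deterministic <- function(transfer, unequal, rc) {
  rc$r_base + (rc$r_peak - rc$r_base) * exp(-((transfer - rc$t_peak) / rc$width)^2) +
    rc$ai_di_slowdown * unequal
}

# Utilities of every admissible punishment for one transfer. For RT-aware
# generating models the anticipated (deterministic) response time of each
# candidate outcome enters the utility, so deliberation cost is part of the
# choice, not only of the measured RT.
punishment_utilities <- function(transfer, agent, cfg) {
  p <- 0:cfg$max_punishment
  pay <- compute_payoffs(rep(transfer, length(p)), p, cfg)
  cls <- classify_inequality(pay$payoff_responder, pay$payoff_proposer)
  rt <- rt_deterministic(transfer, as.numeric(cls != "E"), agent$rt_curve)
  tt <- make_trial_table(agent$participant_id, rep(transfer, length(p)), p,
                         rt, cfg)
  utility(tt, agent$true_params, model_id = agent$model_id)
}

#' Simulate one responder decision
#'
#' Punishment is drawn by softmax over the true utilities of all admissible
#' punishments; at temperature 0 the utility-maximizing punishment is chosen
#' (ties toward the smaller amount). The response time follows an inverted-U
#' over transfers (slowest at intermediately unfair transfers), slowed further
#' on trials ending in inequality, with Gaussian jitter, clipped to the
#' response window.
#'
#' @param transfer Transfer in points.
#' @param agent An [agent_spec()].
#' @param cfg A [task_config()].
#' @return List with `punishment` (points) and `rt` (seconds). Uses the
#'   current RNG state; seed at the caller.
#' @export
simulate_choice <- function(transfer, agent, cfg = task_config()) {
  check_transfer(transfer, cfg)
  u <- punishment_utilities(transfer, agent, cfg)
  tau <- agent$choice_temperature
  if (tau == 0) {
    punishment <- which.max(u) - 1L  # which.max takes the first (smallest p) tie
  } else {
    w <- exp((u - max(u)) / tau)
    punishment <- sample(0:cfg$max_punishment, 1, prob = w / sum(w))
  }
  pay <- compute_payoffs(transfer, punishment, cfg)
  cls <- classify_inequality(pay$payoff_responder, pay$payoff_proposer)
  rt <- rt_deterministic(transfer, as.numeric(cls != "E"), agent$rt_curve) +
    stats::rnorm(1, 0, agent$noise_sd_behavior)
  rt <- min(max(rt, 0.1), cfg$response_window)
  list(punishment = as.integer(punishment), rt = rt)
}

#' Simulate a full behavioral session for one agent
#'
#' Each agent faces the same balanced transfer distribution (equal counts of
#' each level) in an agent-specific random order.
#'
#' @param agent An [agent_spec()].
#' @param cfg A [task_config()].
#' @param n_trials Number of trials (must be a multiple of the number of
#'   transfer levels).
#' @return A `trial_table`.
#' @export
simulate_session <- function(agent, cfg = task_config(), n_trials = 60) {
  set.seed(agent$seed)
  lv <- cfg$transfer_levels
  if (n_trials %% length(lv) != 0) {
    stop("n_trials must be a multiple of the number of transfer levels",
         call. = FALSE)
  }
  transfers <- sample(rep(lv, each = n_trials / length(lv)))
  dec <- lapply(transfers, simulate_choice, agent = agent, cfg = cfg)
  make_trial_table(agent$participant_id, transfers,
                   vapply(dec, `[[`, integer(1), "punishment"),
                   vapply(dec, `[[`, numeric(1), "rt"), cfg)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at `peak_s` (default
#' 6 s, mid-range of the 5--7 s peaks reported for prefrontal fNIRS), an
#' undershoot peaking at `undershoot_s`, and undershoot amplitude
#' `undershoot_ratio` of the main response. Normalized to peak amplitude 1.
#'
#' @param t_s Time points, seconds.
#' @param peak_s,undershoot_s Peak times of response and undershoot, seconds.
#' @param undershoot_ratio Undershoot / response amplitude ratio.
#' @return Numeric vector of kernel values.
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 15,
                             undershoot_ratio = 1 / 6) {
  # shape a, rate 1 => gamma density peaks at a - 1
  a1 <- peak_s + 1
  a2 <- undershoot_s + 1
  h <- stats::dgamma(t_s, shape = a1, rate = 1) -
    undershoot_ratio * stats::dgamma(t_s, shape = a2, rate = 1)
  h / max(h)
}

#' Forward fNIRS simulation for one agent
#'
#' Per trial, a neural amplitude is placed at the transfer onset and
#' convolved with the canonical double-gamma HRF to give the oxygenated
#' hemoglobin change; the deoxygenated change is -1/3 of it. dlPFC channels
#' (1--8) couple with gain `neural_gain_dlpfc` to the standardized true
#' utility of the trial. dmPFC channels (9--16) couple with the weaker gain
#' `neural_gain_dmpfc`, carry extra noise, and track an even mixture of
#' utility and choice difficulty (standardized response time) -- reflecting
#' the region's stronger involvement in conflict monitoring than in social
#' valuation. Concentrations are mapped to 760/850 nm optical densities by
#' the forward modified Beer--Lambert law, then a linear drift, a 1 Hz
#' cardiac sinusoid and white noise are added.
#'
#' @param trials `trial_table` of the agent's session.
#' @param timeline A [session_timeline()] with matching trial count.
#' @param agent An [agent_spec()].
#' @param constants [beer_lambert_constants()].
#' @param noise Set `FALSE` for a noise-free forward model (testing).
#' @return An `optical_recording`: list with `time_s` and an `od` matrix
#'   (samples x 32 columns named `ch<i>_wl760` / `ch<i>_wl850`).
#' @export
simulate_optics <- function(trials, timeline, agent,
                            constants = beer_lambert_constants(),
                            noise = TRUE) {
  if (nrow(trials) != timeline$n_trials) {
    stop("trials and timeline disagree on the number of trials", call. = FALSE)
  }
  fs <- timeline$fs
  n_samp <- ceiling((timeline$duration_s + 20) * fs)  # 20 s tail after last trial
  time_s <- (seq_len(n_samp) - 1) / fs

  u <- utility(trials, agent$true_params, model_id = agent$model_id)
  amp_dl <- standardize_unit(u)
  amp_dm <- standardize_unit(0.5 * amp_dl + 0.5 * standardize_unit(trials$rt_s))
  idx <- round(timeline$onsets_s * fs) + 1
  kern <- hrf_double_gamma(seq(0, 30, by = 1 / fs))
  conv_amp <- function(amp) {
    sticks <- numeric(n_samp)
    sticks[idx] <- amp
    stats::convolve(sticks, rev(kern), type = "open")[seq_len(n_samp)]
  }
  o2_dl <- conv_amp(amp_dl)
  o2_dm <- conv_amp(amp_dm)

  n_ch <- 16
  od <- matrix(0, n_samp, 2 * n_ch)
  colnames(od) <- as.vector(rbind(paste0("ch", 1:n_ch, "_wl760"),
                                  paste0("ch", 1:n_ch, "_wl850")))
  for (ch in seq_len(n_ch)) {
    o2 <- if (ch <= 8) agent$neural_gain_dlpfc * o2_dl
          else agent$neural_gain_dmpfc * o2_dm
    hhb <- -o2 / 3
    ods <- concentration_to_od(cbind(o2hb = o2, hhb = hhb), constants)
    if (noise) {
      sd_extra <- if (ch <= 8) 1 else 1.5  # dmPFC channels are noisier
      drift <- stats::runif(1, -10, 10) * time_s / max(time_s)
      cardiac <- stats::runif(1, 0.5, 1.5) *
        sin(2 * pi * 1 * time_s + stats::runif(1, 0, 2 * pi))
      for (w in 1:2) {
        ods[, w] <- ods[, w] + drift + cardiac +
          stats::rnorm(n_samp, 0, agent$noise_sd_optical * sd_extra)
      }
    }
    od[, paste0("ch", ch, "_wl760")] <- ods[, 1]
    od[, paste0("ch", ch, "_wl850")] <- ods[, 2]
  }
  structure(list(time_s = time_s, od = od, fs = fs, n_channels = n_ch),
            class = "optical_recording")
}

#' Simulate a cohort of synthetic participants
#'
#' Draws independent agents with Fehr--Schmidt preferences spanning the
#' behaviorally observed ranges (alpha in [-0.033, 0.153], beta in [-1, 0]),
#' simulates each agent's 60-trial session and (optionally) its optical
#' recording, and returns the generating truth for recovery tests.
#'
#' @param n_participants Number of agents.
#' @param seed Integer master seed; every agent derives its own seed from it.
#' @param n_trials Trials per agent.
#' @param cfg A [task_config()].
#' @param optics Simulate optical recordings? (Slower; behavioral studies can
#'   skip it.)
#' @param agent_overrides Named list of [agent_spec()] arguments applied to
#'   every agent (e.g. `list(choice_temperature = 0)`).
#' @return List with `trials` (stacked `trial_table`), `timelines`, `optics`
#'   (list or NULL), and `truth` (data.frame of generating parameters).
#' @export
simulate_cohort <- function(n_participants = 24, seed = 1, n_trials = 60,
                            cfg = task_config(), optics = FALSE,
                            agent_overrides = list()) {
  stopifnot(n_participants >= 1)
  set.seed(seed)
  agent_seeds <- sample.int(2^31 - 2, n_participants)
  ids <- sprintf("agent%02d", seq_len(n_participants))
  trials <- vector("list", n_participants)
  timelines <- vector("list", n_participants)
  recs <- if (optics) vector("list", n_participants) else NULL
  truth <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(agent_seeds[i])
    # preferences lie on a social-attentiveness continuum: alpha (DI
    # aversion) spans the behaviorally observed range, and only agents
    # attentive enough to enforce equality (alpha >= 0.03) also hold a
    # substantive AI-seeking beta; the rest are near-AI-neutral. All beta
    # values stay within [-1, 0].
    s <- stats::runif(1)
    alpha <- -0.033 + 0.186 * s
    pars <- list(p_reward_responder = stats::runif(1, 0.04, 0.06),
                 alpha = alpha,
                 beta = if (alpha < 0.03) stats::runif(1, -0.03, 0)
                        else stats::runif(1, -1, -0.1),
                 p_rt = stats::runif(1, 0.2, 1))
    args <- utils::modifyList(
      list(participant_id = ids[i], true_params = pars, seed = agent_seeds[i]),
      agent_overrides)
    ag <- do.call(agent_spec, args)
    trials[[i]] <- simulate_session(ag, cfg, n_trials)
    tl <- session_timeline(n_trials, fs = 10)
    timelines[[i]] <- tl
    if (optics) recs[[i]] <- simulate_optics(trials[[i]], tl, ag)
    truth[[i]] <- data.frame(participant_id = ids[i], model_id = ag$model_id,
                             as.data.frame(pars),
                             choice_temperature = ag$choice_temperature,
                             neural_gain_dlpfc = ag$neural_gain_dlpfc,
                             neural_gain_dmpfc = ag$neural_gain_dmpfc,
                             seed = agent_seeds[i])
  }
  all_trials <- do.call(rbind, trials)
  class(all_trials) <- c("trial_table", "data.frame")
  names(timelines) <- ids
  if (optics) names(recs) <- ids
  list(trials = all_trials, timelines = timelines, optics = recs,
       truth = do.call(rbind, truth))
}
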