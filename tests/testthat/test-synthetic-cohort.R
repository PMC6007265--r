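test_that("a purely self-interested agent never punishes at temperature zero", {
  ag <- agent_spec(true_params = list(p_reward_responder = 1, alpha = 0,
                                      beta = 0, p_rt = 0),
                   choice_temperature = 0)
  for (t in task_config()$transfer_levels) {
    set.seed(1)
    expect_identical(simulate_choice(t, ag)$punishment, 0L)
  }
})

test_that("a strong AI-seeker zeroes the proposer at minimal own cost", {
  ag <- agent_spec(true_params = list(p_reward_responder = 0.01, alpha = 0,
                                      beta = -1, p_rt = 0),
                   choice_temperature = 0)
  set.seed(1)
  expect_identical(simulate_choice(20, ag)$punishment, 22L)
  # oracle: exhaustive evaluation of the generating utility over p = 0..30
  pay <- compute_payoffs(rep(20, 31), 0:30)
  u <- 0.01 * pay$payoff_responder -
    0 * pmax(pay$payoff_proposer - pay$payoff_responder, 0) -
    (-1) * pmax(pay$payoff_responder - pay$payoff_proposer, 0)
  expect_identical(which.max(u) - 1L, 22L)
})

test_that("choices and sessions are reproducible under seeding", {
  ag <- agent_spec(seed = 7)
  set.seed(3); a <- simulate_choice(20, ag)
  set.seed(3); b <- simulate_choice(20, ag)
  expect_identical(a, b)
  expect_identical(simulate_session(ag), simulate_session(ag))
  c1 <- simulate_cohort(2, seed = 5, optics = TRUE)
  c2 <- simulate_cohort(2, seed = 5, optics = TRUE)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$optics[[1]]$od, c2$optics[[1]]$od)
})

test_that("response times peak at intermediate transfers and slow on inequality", {
  ag <- agent_spec(noise_sd_behavior = 0, choice_temperature = 0)
  rts <- vapply(task_config()$transfer_levels, function(t) {
    set.seed(1)
    simulate_choice(t, ag)$rt
  }, numeric(1))
  expect_equal(which.max(rts), 3L)  # slowest at transfer 20
  rc <- ag$rt_curve
  expect_gt(neuroequity:::rt_deterministic(20, 1, rc),
            neuroequity:::rt_deterministic(20, 0, rc))
  # concave around the peak: curve values decrease away from t_peak
  curve <- neuroequity:::rt_deterministic(seq(0, 50, 10), 0, rc)
  expect_true(all(diff(curve[1:3]) > 0) && all(diff(curve[3:6]) < 0))
})

test_that("session timelines space trials beyond the task phases", {
  set.seed(2)
  tl <- session_timeline(60)
  expect_length(tl$onsets_s, 60)
  expect_true(all(diff(tl$onsets_s) >= 5 + 7 + 5))
  expect_equal(tl$onsets_s[1], 60)  # baseline lead-in
})

test_that("zero gains give a flat noise-free optical recording", {
  tt <- fixture_session()
  set.seed(4); tl <- session_timeline(60)
  ag <- agent_spec("fix01", neural_gain_dlpfc = 0, neural_gain_dmpfc = 0)
  rec <- simulate_optics(tt, tl, ag, noise = FALSE)
  expect_true(all(rec$od == 0))
})

test_that("the hemodynamic kernel and forward model peak 6 s after onset", {
  t_grid <- seq(0, 30, by = 0.1)
  h <- hrf_double_gamma(t_grid)
  expect_equal(t_grid[which.max(h)], 6)
  expect_equal(max(h), 1)
  expect_lt(min(h), 0)  # undershoot present
  # single-trial forward model: O2Hb peaks at onset + 6 s
  tt <- fixture_session()
  set.seed(4); tl <- session_timeline(60)
  ag <- agent_spec("fix01", neural_gain_dlpfc = 1, neural_gain_dmpfc = 1,
                   true_params = list(p_reward_responder = 0.05, alpha = 0.08,
                                      beta = -0.4, p_rt = 0.5))
  rec <- simulate_optics(tt, tl, ag, noise = FALSE)
  conc <- od_to_concentration(rec)
  # examine the trial with the largest (positive) amplitude
  u <- standardize_unit(utility(tt, ag$true_params, model_id = "FS_RT"))
  tr <- which.max(u)
  seg <- conc$o2hb[, 1]
  win <- which(conc$time_s >= tl$onsets_s[tr] & conc$time_s <= tl$onsets_s[tr] + 8)
  peak_t <- conc$time_s[win][which.max(seg[win])]
  expect_equal(peak_t, tl$onsets_s[tr] + 6, tolerance = 0.2)
})

test_that("forward then inverse Beer-Lambert recovers the concentrations", {
  tt <- fixture_session()
  set.seed(4); tl <- session_timeline(60)
  ag <- agent_spec("fix01", true_params = list(p_reward_responder = 0.05,
                                               alpha = 0.08, beta = -0.4,
                                               p_rt = 0.5))
  rec <- simulate_optics(tt, tl, ag, noise = FALSE)
  conc <- od_to_concentration(rec)
  kern <- hrf_double_gamma(seq(0, 30, by = 0.1))
  u <- standardize_unit(utility(tt, ag$true_params, model_id = "FS_RT"))
  sticks <- numeric(length(rec$time_s))
  sticks[round(tl$onsets_s * 10) + 1] <- u
  expected <- ag$neural_gain_dlpfc *
    stats::convolve(sticks, rev(kern), type = "open")[seq_along(rec$time_s)]
  expect_equal(conc$o2hb[, 1], expected, tolerance = 1e-9)
  expect_equal(conc$hhb[, 1], -expected / 3, tolerance = 1e-9)
})

test_that("default cohorts show graded punishment and AI-seeking", {
  co <- simulate_cohort(24, seed = 2, optics = FALSE)
  tt <- co$trials
  mp <- tapply(tt$punishment, tt$transfer, mean)
  expect_true(all(diff(mp) < 0))  # punishment decreases with transfer
  expect_true(any(tt$inequality_class == "AI"))
  expect_true(all(co$truth$beta <= 0 & co$truth$beta >= -1))
  expect_true(all(co$truth$alpha >= -0.033 & co$truth$alpha <= 0.153))
  # an all-AI-seeking cohort creates AI outcomes in a sizable share of trials
  co2 <- simulate_cohort(8, seed = 3, optics = FALSE,
                         agent_overrides = list(true_params = list(
                           p_reward_responder = 0.05, alpha = 0.1,
                           beta = -0.6, p_rt = 0.5)))
  expect_gt(mean(co2$trials$inequality_class == "AI"), 0.5)
})
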