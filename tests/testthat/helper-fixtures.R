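# small deterministic fixtures shared across test files

# trial table covering AI, E and DI outcomes with varying RT
fixture_trials <- function() {
  make_trial_table("fix01",
                   transfer = c(0, 10, 20, 20, 30, 40, 50, 50),
                   punishment = c(26, 24, 22, 0, 15, 5, 0, 16),
                   rt_s = c(2.1, 3.0, 3.6, 2.2, 4.0, 2.9, 1.4, 2.5))
}

# one simulated session with moderate preferences, fixed seed
fixture_session <- function(seed = 11, ...) {
  ag <- agent_spec("fix01",
                   true_params = list(p_reward_responder = 0.05, alpha = 0.08,
                                      beta = -0.4, p_rt = 0.5),
                   seed = seed, ...)
  simulate_session(ag)
}

# independent loop-based transcription of the published percentage-bend
# estimator, used as an oracle for the vectorized implementation
pb_cor_oracle <- function(x, y, beta = 0.2) {
  n <- length(x)
  bend <- function(v) {
    med <- median(v)
    devs <- sort(abs(v - med))
    m <- floor((1 - beta) * n + 0.5)
    omega <- devs[m]
    i1 <- 0; i2 <- 0; s <- 0
    for (vi in v) {
      z <- (vi - med) / omega
      if (z < -1) i1 <- i1 + 1
      else if (z > 1) i2 <- i2 + 1
      else s <- s + vi
    }
    phi <- (omega * (i2 - i1) + s) / (n - i1 - i2)
    out <- numeric(n)
    for (i in seq_len(n)) {
      u <- (v[i] - phi) / omega
      out[i] <- if (u < -1) -1 else if (u > 1) 1 else u
    }
    out
  }
  a <- bend(x); b <- bend(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# random parameter vector for a given model, seeded
random_params <- function(model_id, seed) {
  set.seed(seed)
  pars <- as.list(stats::runif(length(model_params(model_id)), -1, 1))
  names(pars) <- model_params(model_id)
  pars
}
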