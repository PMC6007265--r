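test_that("percentage-bend correlation is exact on monotone identities", {
  set.seed(5)
  x <- rnorm(30)
  expect_equal(percentage_bend_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(percentage_bend_correlation(x, -x)$r, -1, tolerance = 1e-12)
})

test_that("percentage-bend correlation matches the loop-based oracle", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(50)
    y <- 0.4 * x + rnorm(50)
    got <- percentage_bend_correlation(x, y)
    expect_equal(got$r, pb_cor_oracle(x, y), tolerance = 1e-10)
    expect_equal(got$statistic, got$r * sqrt(48 / (1 - got$r^2)),
                 tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(got$statistic), 48), tolerance = 1e-12)
  }
})

test_that("percentage-bend correlation ignores affine rescaling and outliers", {
  set.seed(23)
  x <- rnorm(60)
  y <- x + rnorm(60, 0, 0.5)
  r0 <- percentage_bend_correlation(x, y)$r
  expect_equal(percentage_bend_correlation(3 * x + 7, 0.2 * y - 1)$r, r0,
               tolerance = 1e-12)
  # close to Pearson on clean bivariate normal data
  expect_equal(r0, cor(x, y), tolerance = 0.1)
  # a wild marginal outlier barely moves the bend estimate but drags Pearson
  y_out <- y; y_out[1] <- 50
  expect_lt(abs(percentage_bend_correlation(x, y_out)$r - r0),
            abs(cor(x, y_out) - r0))
  expect_error(percentage_bend_correlation(rep(1, 10), rnorm(10)),
               "degenerate")
})

test_that("correlation comparison implements the Fisher r-to-z test", {
  same <- compare_correlations(0.5, 40, 0.5, 40)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # direct-formula oracle at the group sizes and correlations under study
  out <- compare_correlations(0.70, 48, 0.38, 48)
  z_expected <- (atanh(0.70) - atanh(0.38)) / sqrt(1 / 45 + 1 / 45)
  expect_equal(out$z, z_expected, tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-abs(z_expected)), tolerance = 1e-12)
  # antisymmetry
  swap <- compare_correlations(0.38, 48, 0.70, 48)
  expect_equal(swap$z, -out$z)
  expect_error(compare_correlations(1, 48, 0.5, 48), "< 1")
  expect_error(compare_correlations(0.4, 3, 0.5, 48), "n > 3")
  # dependent variant needs the cross-correlation and shrinks with it
  dep <- compare_correlations(0.70, 48, 0.38, 48, dependent = TRUE, r12 = 0.5)
  expect_true(is.finite(dep$z))
  expect_error(compare_correlations(0.7, 48, 0.38, 48, dependent = TRUE),
               "r12")
})

test_that("two-way ANOVA recovers a hand-computed balanced decomposition", {
  # balanced 2x2 with 4 replicates per cell
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:4)
  set.seed(31)
  d$value <- 1 + (d$A == "a2") * 2 + (d$B == "b2") * -1 +
    (d$A == "a2" & d$B == "b2") * 0.5 + rnorm(nrow(d), 0, 0.3)
  out <- factorial_anova(d, "value", c("A", "B"))
  # brute-force sums of squares for the balanced design
  gm <- mean(d$value)
  ssa <- sum(tapply(d$value, d$A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(d$value, d$B, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(d$value, list(d$A, d$B), mean)
  ssab <- 4 * sum((cell - outer(tapply(d$value, d$A, mean),
                                tapply(d$value, d$B, mean), "+") + gm)^2)
  tab <- out$table
  expect_equal(tab$sum_sq[tab$effect == "A"], ssa, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$effect == "B"], ssb, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$effect == "A:B"], ssab, tolerance = 1e-10)
  expect_named(out$posthoc, c("A", "B"))
})

test_that("ANOVA on identical group patterns yields null F statistics", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:6)
  d$value <- ifelse(d$rep %% 2 == 0, 1, -1)  # every cell mean 0, variance > 0
  out <- factorial_anova(d, "value", c("A", "B"))
  expect_true(all(out$table$F[out$table$effect != "Residuals"] < 1e-10))
  d_bad <- d[!(d$A == "a2" & d$B == "b2"), ]
  expect_error(factorial_anova(d_bad, "value", c("A", "B")), "empty design cell")
})

test_that("SVR prediction scores perfect, noisy and degenerate predictors sanely", {
  set.seed(41)
  n <- 60
  u_beh <- rnorm(n)
  starts <- seq(0, 7.02, by = 0.18)
  # identical series in every window: near-perfect holdout prediction
  perfect <- matrix(u_beh, n, length(starts))
  res <- predict_behavior_from_neural(u_beh, perfect, starts, seed = 2)
  expect_gte(res$r_squared, 0.99)
  expect_gte(res$window_index, 28)  # punishment-phase windows only
  # pure noise: little holdout predictability even after maximization
  noise <- matrix(rnorm(n * length(starts)), n)
  r2_noise <- vapply(1:10, function(s) {
    predict_behavior_from_neural(u_beh, noise, starts, seed = s)$r_squared
  }, numeric(1))
  expect_lt(mean(r2_noise), 0.15)
  # deterministic given the seed
  expect_identical(predict_behavior_from_neural(u_beh, noise, starts, seed = 3),
                   predict_behavior_from_neural(u_beh, noise, starts, seed = 3))
  expect_error(predict_behavior_from_neural(u_beh[1:5], perfect[1:5, ], starts),
               "at least 8")
})
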