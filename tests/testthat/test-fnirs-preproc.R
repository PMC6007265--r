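test_that("Beer-Lambert inversion matches a per-sample linear-solve oracle", {
  bl <- beer_lambert_constants()
  set.seed(10)
  n <- 200
  conc <- cbind(o2hb = rnorm(n, 0, 1e-3), hhb = rnorm(n, 0, 1e-3))
  od <- concentration_to_od(conc, bl)
  # zero OD -> zero concentrations
  zero <- structure(list(time_s = 0:4 / 10,
                         od = matrix(0, 5, 2,
                                     dimnames = list(NULL, c("ch1_wl760", "ch1_wl850"))),
                         fs = 10), class = "optical_recording")
  expect_true(all(od_to_concentration(zero, bl)$o2hb == 0))
  # round trip
  rec <- structure(list(time_s = (seq_len(n) - 1) / 10,
                        od = cbind(ch1_wl760 = od[, 1], ch1_wl850 = od[, 2]),
                        fs = 10), class = "optical_recording")
  back <- od_to_concentration(rec, bl)
  expect_equal(back$o2hb[, 1], conc[, "o2hb"], tolerance = 1e-9)
  expect_equal(back$hhb[, 1], conc[, "hhb"], tolerance = 1e-9)
  # oracle: solve the printed 2x2 system sample by sample
  A <- rbind(c(1486 * 30 * 7.25, 3843 * 30 * 7.25),
             c(2526 * 30 * 6.38, 1798 * 30 * 6.38))
  oracle <- t(apply(od, 1, function(row) solve(A, row)))
  expect_equal(back$o2hb[, 1], oracle[, 1], tolerance = 1e-9)
  expect_equal(back$hhb[, 1], oracle[, 2], tolerance = 1e-9)
})

test_that("total hemoglobin stays the sum of the chromophores after preprocessing", {
  tt <- fixture_session()
  set.seed(4); tl <- session_timeline(60)
  ag <- agent_spec("fix01", seed = 11)
  rec <- simulate_optics(tt, tl, ag)
  s <- od_to_concentration(rec)
  for (step in list(baseline_correct, detrend_channels, despike_channels)) {
    s <- step(s)
    expect_equal(s$thb, s$o2hb + s$hhb, tolerance = 1e-12)
  }
})

test_that("baseline correction subtracts the first-minute mean", {
  mk <- function(x) {
    n <- length(x)
    new_series <- structure(
      list(time_s = (seq_len(n) - 1) / 10, fs = 10,
           o2hb = matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
           hhb = matrix(-x / 3, ncol = 1, dimnames = list(NULL, "ch1")),
           thb = matrix(x * 2 / 3, ncol = 1, dimnames = list(NULL, "ch1")),
           regions = c(ch1 = "dlPFC")),
      class = "chromophore_series")
  }
  const <- mk(rep(3.5, 700))
  expect_true(all(baseline_correct(const)$o2hb == 0))
  set.seed(1)
  noisy <- mk(rnorm(700, 5))
  bc <- baseline_correct(noisy)
  expect_equal(mean(bc$o2hb[1:600, 1]), 0, tolerance = 1e-12)
  # step from 0 to 1 at t = 60 s: baseline mean 0, post-step values 1
  step <- mk(c(rep(0, 600), rep(1, 100)))
  bs <- baseline_correct(step)
  expect_equal(bs$o2hb[, 1], c(rep(0, 600), rep(1, 100)))
  expect_error(baseline_correct(mk(rep(1, 100))), "shorter")
})

test_that("detrending removes exactly the least-squares line", {
  n <- 800
  t_s <- (seq_len(n) - 1) / 10
  sig <- 2 + 0.03 * t_s + sin(2 * pi * 0.05 * t_s)
  s <- structure(
    list(time_s = t_s, fs = 10,
         o2hb = matrix(sig, ncol = 1, dimnames = list(NULL, "ch1")),
         hhb = matrix(-sig / 3, ncol = 1, dimnames = list(NULL, "ch1")),
         thb = matrix(sig * 2 / 3, ncol = 1, dimnames = list(NULL, "ch1")),
         regions = c(ch1 = "dlPFC")),
    class = "chromophore_series")
  dt <- detrend_channels(s)
  # pure line maps to zero
  line_only <- s
  line_only$o2hb[] <- 2 + 0.03 * t_s
  line_only$hhb[] <- 0
  expect_equal(max(abs(detrend_channels(line_only)$o2hb)), 0, tolerance = 1e-9)
  # line + sinusoid: residual equals the lm() oracle
  oracle <- residuals(lm(sig ~ t_s))
  expect_equal(dt$o2hb[, 1], unname(oracle), tolerance = 1e-9)
})

test_that("despiking clips an injected spike but preserves the signal", {
  n <- 1000
  t_s <- (seq_len(n) - 1) / 10
  base <- sin(2 * pi * 0.02 * t_s)
  spiked <- base
  spiked[500] <- spiked[500] + 50 * mad(diff(base))
  s <- structure(
    list(time_s = t_s, fs = 10,
         o2hb = matrix(spiked, ncol = 1, dimnames = list(NULL, "ch1")),
         hhb = matrix(0, n, 1, dimnames = list(NULL, "ch1")),
         thb = matrix(spiked, ncol = 1, dimnames = list(NULL, "ch1")),
         regions = c(ch1 = "dlPFC")),
    class = "chromophore_series")
  ds <- despike_channels(s, threshold = 5)
  expect_lt(abs(ds$o2hb[500, 1] - base[500]), abs(spiked[500] - base[500]) / 5)
  keep <- setdiff(seq_len(n), 490:510)
  expect_equal(ds$o2hb[keep, 1], base[keep], tolerance = 0.05)
})

test_that("sliding windows average the configured spans from trial onset", {
  grid <- window_grid()
  expect_equal(grid$starts_s[40], 7.02, tolerance = 1e-9)  # 39 * 0.18
  n <- 1200
  t_s <- (seq_len(n) - 1) / 10
  tl <- structure(list(onsets_s = c(60, 80), fs = 10, n_trials = 2),
                  class = "session_timeline")
  mk <- function(x) structure(
    list(time_s = t_s, fs = 10,
         o2hb = matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
         hhb = matrix(0, n, 1, dimnames = list(NULL, "ch1")),
         thb = matrix(x, ncol = 1, dimnames = list(NULL, "ch1")),
         regions = c(ch1 = "dlPFC")),
    class = "chromophore_series")
  const <- extract_windows(mk(rep(1, n)), tl, grid)
  expect_equal(dim(const), c(2, 1, 40))
  expect_true(all(const == 1))
  # full-overlap window: signal 2 inside [onset, onset + 2.5), 0 after
  sig <- rep(0, n)
  sig[t_s >= 60 & t_s < 62.5] <- 2
  expect_equal(unname(extract_windows(mk(sig), tl, grid)[1, 1, 1]), 2)
  # adding a constant shifts every window mean by that constant
  set.seed(2)
  x <- rnorm(n)
  w0 <- extract_windows(mk(x), tl, grid)
  w1 <- extract_windows(mk(x + 3), tl, grid)
  expect_equal(w1, w0 + 3, tolerance = 1e-12)
  # trial running past the recording end is reported by index
  tl_bad <- structure(list(onsets_s = c(60, 115), fs = 10, n_trials = 2),
                      class = "session_timeline")
  expect_error(extract_windows(mk(x), tl_bad, grid), "2")
})

test_that("region averaging equals the brute-force channel mean", {
  set.seed(6)
  w <- array(rnorm(4 * 16 * 3), dim = c(4, 16, 3),
             dimnames = list(NULL, paste0("ch", 1:16), NULL))
  attr(w, "starts_s") <- c(0, 0.18, 0.36)
  regions <- setNames(ifelse(1:16 <= 8, "dlPFC", "dmPFC"), paste0("ch", 1:16))
  avg <- average_regions(w, regions)
  expect_equal(unname(avg[, "dlPFC", ]), unname(apply(w[, 1:8, ], c(1, 3), mean)))
  expect_equal(unname(avg[, "dmPFC", ]), unname(apply(w[, 9:16, ], c(1, 3), mean)))
  # identical channels: average equals any one of them
  w2 <- w
  for (ch in 2:8) w2[, ch, ] <- w2[, 1, ]
  expect_equal(unname(average_regions(w2, regions)[, "dlPFC", ]),
               unname(w2[, 1, ]))
  expect_error(average_regions(w, regions[-1]), "region")
})

test_that("optical recordings survive a CSV round trip", {
  tt <- fixture_session()
  set.seed(4); tl <- session_timeline(60)
  rec <- simulate_optics(tt, tl, agent_spec("fix01", seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_optical_recording(rec, path)
  back <- read_optical_recording(path)
  expect_equal(back$od, rec$od, tolerance = 1e-6)
  expect_equal(back$fs, 10, tolerance = 1e-6)
  wt <- windows_to_table(extract_windows(od_to_concentration(rec), tl,
                                         window_grid()), "fix01")
  expect_equal(nrow(wt), 60 * 16 * 40)
  expect_named(wt, c("participant_id", "trial", "channel", "window_index",
                     "window_start_s", "value"))
})
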