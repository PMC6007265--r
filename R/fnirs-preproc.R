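#' Modified Beer--Lambert constants
#'
#' Absorption coefficients and differential pathlength factors used to map
#' optical-density changes at 760 and 850 nm to oxygenated / deoxygenated
#' hemoglobin concentration changes:
#' mu_a(O2Hb) = 1486 (760 nm) / 2526 (850 nm),
#' mu_a(HHb) = 3843 (760 nm) / 1798 (850 nm),
#' DPF = 7.25 (760 nm) / 6.38 (850 nm), source--detector distance 30 mm.
#' Concentrations are expressed in the arbitrary unit system these printed
#' coefficients imply; all downstream fits standardize the data, so no molar
#' conversion is applied.
#'
#' @param mu_a 2x2 matrix of absorption coefficients, rows = chromophores
#'   (`o2hb`, `hhb`), columns = wavelengths (`wl760`, `wl850`).
#' @param dpf Differential pathlength factor per wavelength.
#' @param distance_mm Source--detector distance.
#' @return Object of class `beer_lambert_constants` carrying the 2x2 forward
#'   coefficient matrix (checked for invertibility).
#' @export
beer_lambert_constants <- function(mu_a = matrix(c(1486, 2526, 3843, 1798),
                                                 nrow = 2, byrow = TRUE,
                                                 dimnames = list(c("o2hb", "hhb"),
                                                                 c("wl760", "wl850"))),
                                   dpf = c(wl760 = 7.25, wl850 = 6.38),
                                   distance_mm = 30) {
  # rows = wavelengths, cols = chromophores: OD(lambda) = A %*% c(o2hb, hhb)
  A <- rbind(wl760 = mu_a[, "wl760"] * distance_mm * dpf["wl760"],
             wl850 = mu_a[, "wl850"] * distance_mm * dpf["wl850"])
  if (abs(det(A)) < .Machine$double.eps * max(abs(A))^2) {
    stop("Beer-Lambert coefficient matrix is singular", call. = FALSE)
  }
  structure(list(mu_a = mu_a, dpf = dpf, distance_mm = distance_mm,
                 forward = A, inverse = solve(A)),
            class = "beer_lambert_constants")
}

#' Forward modified Beer--Lambert law
#'
#' Maps chromophore concentration changes of one channel to optical-density
#' changes at both wavelengths:
#' `OD(lambda) = (mu_a_O2Hb(lambda) * dO2Hb + mu_a_HHb(lambda) * dHHb) * d * DPF(lambda)`.
#'
#' @param conc Matrix (samples x 2) with columns `o2hb`, `hhb`.
#' @param constants [beer_lambert_constants()].
#' @return Matrix (samples x 2) with columns `wl760`, `wl850`.
#' @export
concentration_to_od <- function(conc, constants = beer_lambert_constants()) {
  out <- conc[, c("o2hb", "hhb"), drop = FALSE] %*% t(constants$forward)
  colnames(out) <- c("wl760", "wl850")
  out
}

#' Invert the modified Beer--Lambert law for a whole recording
#'
#' Solves the 2x2 linear system per channel and sample for the oxygenated and
#' deoxygenated hemoglobin concentration changes, and derives total
#' hemoglobin as their sum.
#'
#' @param rec An `optical_recording` (see [simulate_optics()]) or a list with
#'   `time_s`, `fs` and an `od` matrix with `ch<i>_wl760` / `ch<i>_wl850`
#'   columns.
#' @param constants [beer_lambert_constants()].
#' @return A `chromophore_series`: list with `time_s`, `fs`, matrices `o2hb`,
#'   `hhb`, `thb` (samples x channels) and a channel-to-region map
#'   (channels 1--8 dlPFC, 9--16 dmPFC).
#' @export
od_to_concentration <- function(rec, constants = beer_lambert_constants()) {
  od <- rec$od
  ch_ids <- sort(unique(as.integer(sub("^ch(\\d+)_wl\\d+$", "\\1", colnames(od)))))
  n_ch <- length(ch_ids)
  o2 <- hh <- matrix(0, nrow(od), n_ch,
                     dimnames = list(NULL, paste0("ch", ch_ids)))
  for (j in seq_along(ch_ids)) {
    c760 <- paste0("ch", ch_ids[j], "_wl760")
    c850 <- paste0("ch", ch_ids[j], "_wl850")
    if (!all(c(c760, c850) %in% colnames(od))) {
      stop("channel ", ch_ids[j], " is missing one wavelength", call. = FALSE)
    }
    conc <- cbind(od[, c760], od[, c850]) %*% t(constants$inverse)
    o2[, j] <- conc[, 1]
    hh[, j] <- conc[, 2]
  }
  new_chromophore_series(rec$time_s, rec$fs, o2, hh, ch_ids)
}

new_chromophore_series <- function(time_s, fs, o2hb, hhb, ch_ids) {
  region <- ifelse(ch_ids <= 8, "dlPFC", "dmPFC")
  names(region) <- paste0("ch", ch_ids)
  structure(list(time_s = time_s, fs = fs, o2hb = o2hb, hhb = hhb,
                 thb = o2hb + hhb, regions = region),
            class = "chromophore_series")
}

#' @export
print.chromophore_series <- function(x, ...) {
  cat("chromophore_series:", ncol(x$o2hb), "channels x", length(x$time_s),
      sprintf("samples @ %g Hz (%.1f s)\n", x$fs, max(x$time_s)))
  invisible(x)
}

# apply f(channel_matrix) to o2hb and hhb and recompose thb
map_chromophores <- function(series, f) {
  series$o2hb <- f(series$o2hb)
  series$hhb <- f(series$hhb)
  series$thb <- series$o2hb + series$hhb
  series
}

#' Baseline correction
#'
#' Subtracts each channel's mean over the first `baseline_s` seconds from the
#' entire channel (applied to O2Hb and HHb; tHb is recomposed as their sum).
#'
#' @param series A `chromophore_series`.
#' @param baseline_s Baseline duration, seconds (default 60).
#' @return Corrected `chromophore_series`.
#' @export
baseline_correct <- function(series, baseline_s = 60) {
  n_base <- sum(series$time_s < baseline_s)
  if (max(series$time_s) < baseline_s) {
    stop("recording shorter than the ", baseline_s, " s baseline", call. = FALSE)
  }
  map_chromophores(series, function(m) {
    sweep(m, 2, colMeans(m[seq_len(n_base), , drop = FALSE]))
  })
}

#' Linear detrending
#'
#' Removes the per-channel least-squares linear trend over time.
#'
#' @param series A `chromophore_series`.
#' @return Detrended `chromophore_series`.
#' @export
detrend_channels <- function(series) {
  X <- cbind(1, series$time_s)
  map_chromophores(series, function(m) m - X %*% qr.solve(X, m))
}

#' Median/MAD despiking
#'
#' Clips samples further than `threshold` robust standard deviations (MAD of
#' the residual from a rolling median) away from that rolling median. Stands
#' in for manual motion-artifact screening; off by default in the pipeline.
#'
#' @param series A `chromophore_series`.
#' @param threshold Clipping threshold in MAD units.
#' @param window_s Rolling-median window length, seconds.
#' @return Despiked `chromophore_series`.
#' @export
despike_channels <- function(series, threshold = 5, window_s = 5) {
  k <- max(3, round(window_s * series$fs))
  if (k %% 2 == 0) k <- k + 1
  map_chromophores(series, function(m) {
    for (j in seq_len(ncol(m))) {
      med <- stats::runmed(m[, j], k, endrule = "median")
      resid <- m[, j] - med
      s <- stats::mad(resid)
      if (s <= 0) {
        # a smooth channel sits exactly on its rolling median almost
        # everywhere; scale from the nonzero residuals instead
        nz <- resid[resid != 0]
        s <- if (length(nz)) stats::mad(nz, center = 0) else 0
      }
      if (s > 0) {
        m[, j] <- med + pmin(pmax(resid, -threshold * s), threshold * s)
      }
    }
    m
  })
}

#' Sliding-window grid over the trial epoch
#'
#' Windows of `width_s` seconds, stepped every `step_s` seconds from the
#' transfer onset; window k (0-based) spans
#' `[onset + k * step_s, onset + k * step_s + width_s)`.
#'
#' @param width_s Window width, seconds (default 2.5).
#' @param step_s Step between window starts, seconds (default 0.18).
#' @param n_windows Number of windows (default 40).
#' @return Object of class `window_grid` with a `starts_s` vector.
#' @export
window_grid <- function(width_s = 2.5, step_s = 0.18, n_windows = 40) {
  stopifnot(width_s > 0, step_s > 0, n_windows >= 1)
  structure(list(width_s = width_s, step_s = step_s, n_windows = n_windows,
                 starts_s = step_s * (seq_len(n_windows) - 1)),
            class = "window_grid")
}

#' Per-trial sliding-window responses
#'
#' For every trial, channel and window, the mean of the chosen chromophore
#' over samples with timestamps in `[onset + k * step, onset + k * step + width)`.
#'
#' @param series A `chromophore_series` (typically baseline-corrected and
#'   detrended).
#' @param timeline A [session_timeline()].
#' @param grid A [window_grid()].
#' @param chromophore Which chromophore to window (default total hemoglobin).
#' @return 3-d array `[trial, channel, window]` with the window start times
#'   attached as attribute `"starts_s"`.
#' @export
extract_windows <- function(series, timeline, grid = window_grid(),
                            chromophore = c("thb", "o2hb", "hhb")) {
  chromophore <- match.arg(chromophore)
  m <- series[[chromophore]]
  t_end <- max(series$time_s)
  epoch_end <- max(grid$starts_s) + grid$width_s
  too_late <- which(timeline$onsets_s + epoch_end > t_end + 1e-9)
  if (length(too_late)) {
    stop("trial(s) ", paste(too_late, collapse = ", "),
         " extend past the end of the recording", call. = FALSE)
  }
  out <- array(NA_real_,
               dim = c(timeline$n_trials, ncol(m), grid$n_windows),
               dimnames = list(NULL, colnames(m), NULL))
  for (tr in seq_len(timeline$n_trials)) {
    for (k in seq_len(grid$n_windows)) {
      lo <- timeline$onsets_s[tr] + grid$starts_s[k]
      sel <- series$time_s >= lo - 1e-9 & series$time_s < lo + grid$width_s - 1e-9
      out[tr, , k] <- colMeans(m[sel, , drop = FALSE])
    }
  }
  attr(out, "starts_s") <- grid$starts_s
  attr(out, "regions") <- series$regions
  out
}

#' Average channels within a cortical region
#'
#' Reduces a `[trial, channel, window]` array to `[trial, region, window]`
#' by averaging homologous channels (used after establishing no hemisphere
#' differences): channels 1--8 form dlPFC, 9--16 dmPFC by default.
#'
#' @param windows Array from [extract_windows()].
#' @param regions Named character vector mapping channel names to regions;
#'   defaults to the map attached to `windows`.
#' @return Array `[trial, region, window]`, window starts preserved.
#' @export
average_regions <- function(windows, regions = attr(windows, "regions")) {
  ch <- dimnames(windows)[[2]]
  if (is.null(regions) || !all(ch %in% names(regions))) {
    stop("every channel must be mapped to a region", call. = FALSE)
  }
  regs <- unique(regions[ch])
  out <- array(NA_real_, dim = c(dim(windows)[1], length(regs), dim(windows)[3]),
               dimnames = list(NULL, regs, NULL))
  for (r in seq_along(regs)) {
    sel <- ch[regions[ch] == regs[r]]
    out[, r, ] <- apply(windows[, sel, , drop = FALSE], c(1, 3), mean)
  }
  attr(out, "starts_s") <- attr(windows, "starts_s")
  out
}

#' Write / read a windows table as tidy CSV
#'
#' @param windows Array from [extract_windows()] or [average_regions()].
#' @param participant_id Identifier recorded in the table.
#' @param path File path.
#' @return A long data.frame (participant, trial, channel, window_index,
#'   window_start_s, value); the writer returns `path` invisibly.
#' @export
windows_to_table <- function(windows, participant_id = "p1") {
  d <- dim(windows)
  starts <- attr(windows, "starts_s")
  data.frame(
    participant_id = participant_id,
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(dimnames(windows)[[2]], each = d[1]), times = d[3]),
    window_index = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
    window_start_s = rep(starts, each = d[1] * d[2]),
    value = as.vector(windows))
}

#' @rdname windows_to_table
#' @export
write_windows_table <- function(windows, participant_id, path) {
  utils::write.csv(windows_to_table(windows, participant_id), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read optical recordings as CSV
#'
#' Wide CSV with a `time_s` column followed by `ch<i>_wl760` / `ch<i>_wl850`
#' columns.
#'
#' @param rec An `optical_recording`.
#' @param path File path.
#' @return The reader returns an `optical_recording`; the writer `path`.
#' @export
write_optical_recording <- function(rec, path) {
  utils::write.csv(data.frame(time_s = rec$time_s, rec$od, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_optical_recording
#' @export
read_optical_recording <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  od <- as.matrix(d[setdiff(names(d), "time_s")])
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(time_s = d$time_s, od = od, fs = fs,
                 n_channels = ncol(od) / 2),
            class = "optical_recording")
}
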