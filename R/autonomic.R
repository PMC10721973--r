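# Autonomic stage: PPG band-pass + Pan-Tompkins-style pulse detection,
# inter-beat intervals, per-minute HR, Lomb-Scargle HRV (LF, HF, LF/HF),
# EDA low-pass + continuous-decomposition-style tonic/phasic split, and
# movement-artifact interpolation.

#' Band-pass filter a PPG recording
#'
#' Zero-phase 5th-order Butterworth band-pass (default 0.4--3.5 Hz,
#' applied as a high-pass/low-pass cascade) removing the DC/respiratory
#' drift below 0.4 Hz and high-frequency interference, leaving the pulse
#' fundamental (0.7--3 Hz for 40--180 bpm) intact.
#'
#' @param raw an \code{fk_signal} PPG stream.
#' @param band corner frequencies in Hz.
#' @param order Butterworth order of each stage.
#' @return filtered \code{fk_signal}.
#' @export
preprocess_ppg <- function(raw, band = c(0.4, 3.5), order = 5) {
  if (raw$fs < 2 * band[2])
    stop("sampling rate ", raw$fs, " Hz below twice the upper cutoff")
  x <- filter_signal(raw, "high", band[1], order = order)
  filter_signal(x, "low", band[2], order = order)
}

#' Detect pulses with a Pan-Tompkins-style detector adapted to PPG
#'
#' Stages: 5-point derivative, squaring, 150-ms moving-window
#' integration, then adaptive dual-threshold peak tracking with running
#' signal/noise level estimates (threshold = noise + 0.25 x (signal -
#' noise)) and a 250-ms refractory period. Each accepted integration
#' peak is refined to the local maximum of the filtered pulse within
#' +/-100 ms. The detector is invariant to amplitude scaling of the
#' input because all thresholds adapt proportionally.
#'
#' @param ppg preprocessed \code{fk_signal} (>= 10 s).
#' @param integ_s integration window (s).
#' @param refractory_s minimum beat spacing (s).
#' @param thr_blend signal/noise threshold blend factor.
#' @param search_s half-width of the beat-refinement window (s).
#' @param ibi_range_s physiological inter-beat-interval range; intervals
#'   outside it are flagged invalid and excluded from HRV.
#' @return an \code{fk_ibi} list: beat_times_s, ibi_s (successive
#'   differences), valid flags.
#' @export
detect_pulses <- function(ppg, integ_s = 0.15, refractory_s = 0.25,
                          thr_blend = 0.25, search_s = 0.1,
                          ibi_range_s = c(0.33, 2.0)) {
  if (signal_duration(ppg) < 10) stop("need at least 10 s of PPG")
  x <- ppg$data[, 1]
  fs <- ppg$fs
  # 5-point derivative (classic weights), squared, integrated
  d <- stats::filter(x, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  nw <- max(1, round(integ_s * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 2))
  integ[is.na(integ)] <- 0

  pk <- pracma::findpeaks(integ, minpeakdistance = max(1, round(0.2 * fs)))
  out_empty <- structure(list(beat_times_s = numeric(0), ibi_s = numeric(0),
                              valid = logical(0)), class = "fk_ibi")
  if (is.null(pk) || max(integ) <= 0) return(out_empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]

  init <- integ[seq_len(min(length(integ), round(2 * fs)))]
  spki <- max(init); npki <- mean(init)
  beats_i <- integer(0)
  last <- -Inf
  refr <- refractory_s * fs
  srch <- round(search_s * fs)
  for (j in seq_len(nrow(pk))) {
    pkv <- pk[j, 1]; pki <- pk[j, 2]
    thr <- npki + thr_blend * (spki - npki)
    if (pkv >= thr && (pki - last) > refr) {
      spki <- 0.125 * pkv + 0.875 * spki
      lo <- max(1, pki - srch); hi <- min(length(x), pki + srch)
      beats_i <- c(beats_i, lo - 1 + which.max(x[lo:hi]))
      last <- pki
    } else {
      npki <- 0.125 * pkv + 0.875 * npki
    }
  }
  beats_i <- sort(unique(beats_i))
  bt <- ppg$t0 + (beats_i - 1) / fs
  ibi <- diff(bt)
  structure(list(beat_times_s = bt, ibi_s = ibi,
                 valid = ibi > ibi_range_s[1] & ibi < ibi_range_s[2]),
            class = "fk_ibi")
}

#' @export
print.fk_ibi <- function(x, ...) {
  cat(sprintf("<fk_ibi> %d beats, %d intervals (%d valid), mean IBI %.3f s\n",
              length(x$beat_times_s), length(x$ibi_s), sum(x$valid),
              mean(x$ibi_s[x$valid])))
  invisible(x)
}

#' Heart rate per 60-s window
#'
#' HR = 60 / mean(valid IBI whose terminating beat falls in the window).
#' Windows with fewer than \code{min_intervals} valid intervals are
#' flagged invalid.
#'
#' @param ibi an \code{fk_ibi}.
#' @param duration_s analysed duration (s).
#' @param window_s window length (s).
#' @param min_intervals validity threshold.
#' @return data.frame(window_start_s, value, n_valid, valid_flag),
#'   value in bpm.
#' @export
hr_per_window <- function(ibi, duration_s, window_s = 60,
                          min_intervals = 10) {
  wins <- window_grid(duration_s, window_s)
  out <- data.frame(window_start_s = wins$window_start_s,
                    value = NA_real_, n_valid = 0L)
  if (length(ibi$ibi_s)) {
    ends <- ibi$beat_times_s[-1]           # interval ends at its 2nd beat
    wi <- window_of(ends, window_s)
    for (i in seq_len(nrow(out))) {
      sel <- wi == i & ibi$valid
      out$n_valid[i] <- sum(sel)
      if (out$n_valid[i] >= min_intervals)
        out$value[i] <- 60 / mean(ibi$ibi_s[sel])
    }
  }
  out$valid_flag <- out$n_valid >= min_intervals
  out
}

#' Lomb-Scargle periodogram of the inter-beat-interval series
#'
#' Classic normalized Lomb-Scargle with the per-frequency time offset
#' tau, evaluated for the mean-subtracted valid IBIs against their beat
#' times on a 0.005--0.5 Hz grid (step 0.0025 Hz), scaled to a one-sided
#' spectral density whose integral approximates the series variance
#' (so an evenly sampled input matches an FFT periodogram). Band powers
#' are trapezoidal integrals over LF 0.04--0.15 Hz and HF 0.15--0.4 Hz.
#'
#' @param ibi an \code{fk_ibi} spanning at least \code{min_duration_s}.
#' @param f_grid,f_step frequency grid bounds and step (Hz).
#' @param lf_hz,hf_hz integration bands (Hz).
#' @param min_duration_s minimum record span (s).
#' @return list(freq, psd, lf_power, hf_power, lf_hf_ratio); powers in
#'   s^2, ratio dimensionless.
#' @export
lomb_scargle_psd <- function(ibi, f_grid = c(0.005, 0.5), f_step = 0.0025,
                             lf_hz = c(0.04, 0.15), hf_hz = c(0.15, 0.4),
                             min_duration_s = 120) {
  tt <- ibi$beat_times_s[-1][ibi$valid]
  y <- ibi$ibi_s[ibi$valid]
  if (length(y) < 4 || diff(range(tt)) < min_duration_s)
    stop("need at least ", min_duration_s,
         " s of valid inter-beat intervals")
  y <- y - mean(y)
  freqs <- seq(f_grid[1], f_grid[2], by = f_step)
  n <- length(y)
  span <- diff(range(tt))
  p <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * tt)), sum(cos(2 * w * tt))) / (2 * w)
    ct <- cos(w * (tt - tau)); st <- sin(w * (tt - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
  psd <- 2 * p * span / n           # one-sided density, integral ~ variance
  bandpow <- function(b) {
    i <- freqs >= b[1] & freqs <= b[2]
    pracma::trapz(freqs[i], psd[i])
  }
  lf <- bandpow(lf_hz); hf <- bandpow(hf_hz)
  list(freq = freqs, psd = psd, lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

#' Low-pass filter an EDA recording
#'
#' Zero-phase Butterworth low-pass at 1 Hz; DC (the tonic level) is
#' preserved, sensor noise above 1 Hz removed.
#'
#' @param raw an \code{fk_signal} EDA stream.
#' @param lp_hz cutoff (Hz).
#' @param order Butterworth order.
#' @return filtered \code{fk_signal}.
#' @export
preprocess_eda <- function(raw, lp_hz = 1, order = 4) {
  if (lp_hz >= raw$fs / 2) return(raw)
  filter_signal(raw, "low", lp_hz, order = order)
}

#' Tonic/phasic decomposition of an EDA recording
#'
#' Continuous-decomposition-style split: the signal is deconvolved with
#' the Bateman impulse response (tau1 = 0.75 s, tau2 = 2 s) using its
#' exact differential-operator inverse with lightly smoothed derivatives
#' (a regularized inversion); the driver's sustained baseline (running
#' 10th percentile over 20-s windows, smoothed) is reconvolved to give
#' the tonic component (SCL); the phasic component is the remainder, so
#' tonic + phasic reconstructs the input exactly. Per-60-s tonic means
#' and their session min-max normalization are attached.
#'
#' @param eda preprocessed \code{fk_signal} EDA stream (uS).
#' @param tau1_s,tau2_s Bateman rise/decay constants (s).
#' @param baseline_win_s percentile-baseline window (s).
#' @param baseline_pct percentile used for the tonic driver.
#' @param smooth_s baseline smoothing window (s).
#' @param window_s SCL aggregation window (s).
#' @return list(tonic, phasic, driver, scl_per_window,
#'   scl_normalized): tonic/phasic/driver on the input grid,
#'   scl tables as data.frame(window_start_s, value).
#' @export
decompose_eda <- function(eda, tau1_s = 0.75, tau2_s = 2,
                          baseline_win_s = 20, baseline_pct = 0.10,
                          smooth_s = 10, window_s = 60) {
  y <- eda$data[, 1]
  if (all(y <= 0)) stop("EDA signal must be positive somewhere")
  fs <- eda$fs
  dt <- 1 / fs
  # smoothed derivatives (Savitzky-Golay) for the operator inverse:
  # driver = (y + (tau1+tau2) y' + tau1 tau2 y'') / (tau2 - tau1)
  k <- max(5, round(fs) * 2 + 1)
  if (k %% 2 == 0) k <- k + 1
  ys <- signal::sgolayfilt(y, p = 3, n = k)
  d1 <- signal::sgolayfilt(y, p = 3, n = k, m = 1) / dt
  d2 <- signal::sgolayfilt(y, p = 3, n = k, m = 2) / dt^2
  driver <- (ys + (tau1_s + tau2_s) * d1 + tau1_s * tau2_s * d2) /
    (tau2_s - tau1_s)

  # sustained baseline of the driver: running low percentile, smoothed
  wb <- max(1, round(baseline_win_s * fs))
  base <- zoo_rollquantile(driver, wb, baseline_pct)
  ws <- max(1, round(smooth_s * fs)); if (ws %% 2 == 0) ws <- ws + 1
  base <- as.numeric(stats::filter(c(rep(base[1], ws %/% 2), base,
                                     rep(base[length(base)], ws %/% 2)),
                                   rep(1 / ws, ws), sides = 2))
  base <- base[(ws %/% 2 + 1):(ws %/% 2 + length(driver))]

  # reconvolve the tonic driver with the (area-normalized) kernel
  kern_t <- seq(0, 8 * tau2_s, by = dt)
  kern <- exp(-kern_t / tau2_s) - exp(-kern_t / tau1_s)
  kern <- kern / sum(kern) / dt * (tau2_s - tau1_s)
  pad <- length(kern) - 1
  ext <- c(rep(base[1], pad), base)
  full <- signal::conv(ext, kern) * dt     # causal convolution
  tonic <- full[pad + seq_along(base)]
  phasic <- y - tonic

  tt <- signal_times(eda) - eda$t0
  mm <- tapply(tonic, window_of(tt, window_s), mean)
  ns <- floor(length(y) / (window_s * fs))
  scl <- data.frame(window_start_s = (seq_len(ns) - 1) * window_s,
                    value = as.numeric(mm[seq_len(ns)]))
  rng <- range(scl$value)
  scl_n <- scl
  scl_n$value <- if (diff(rng) > 0) (scl$value - rng[1]) / diff(rng)
                 else rep(0, nrow(scl))
  list(tonic = tonic, phasic = phasic, driver = driver,
       scl_per_window = scl, scl_normalized = scl_n)
}

#' Running quantile (plain implementation over centred windows)
#' @keywords internal
zoo_rollquantile <- function(x, k, p) {
  n <- length(x)
  half <- k %/% 2
  out <- numeric(n)
  # evaluate on a stride and interpolate: the baseline is slow
  stride <- max(1, half %/% 2)
  idx <- unique(c(seq(1, n, by = stride), n))
  vals <- vapply(idx, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], p, names = FALSE)
  }, numeric(1))
  stats::approx(idx, vals, xout = seq_len(n), rule = 2)$y
}

#' Interpolate movement artifacts
#'
#' For sampled streams (EDA/PPG): samples inside segments whose
#' sample-to-sample jump exceeds \code{jump_sd_mult} x the robust SD of
#' the differences, or inside flatlines longer than \code{flatline_s},
#' are replaced by linear interpolation between the flanking good
#' samples; length is unchanged. For inter-beat series: intervals
#' outside the physiological range are replaced by splitting them into
#' an integer number of locally typical intervals (recovering dropped
#' beats) so no data are lost.
#'
#' @param x an \code{fk_signal} or \code{fk_ibi}.
#' @param jump_sd_mult jump threshold in robust SDs.
#' @param flatline_s flatline duration threshold (s).
#' @param max_bad_frac error if more than this fraction is bad.
#' @return object of the same class, artifacts repaired.
#' @export
interpolate_movement_artifacts <- function(x, jump_sd_mult = 5,
                                           flatline_s = 2,
                                           max_bad_frac = 0.5) {
  if (inherits(x, "fk_ibi")) return(repair_ibi(x, max_bad_frac))
  y <- x$data[, 1]
  d <- diff(y)
  rsd <- stats::mad(d)
  bad <- rep(FALSE, length(y))
  if (rsd > 0) {
    # deviation from a running-median baseline catches both the sharp
    # edges and the plateau of a movement transient
    k <- round(4 * flatline_s * x$fs)
    if (k %% 2 == 0) k <- k + 1
    dev <- abs(y - stats::runmed(y, max(3, k), endrule = "median"))
    for (i in which(dev > jump_sd_mult * rsd))
      bad[max(1, i - 1):min(length(y), i + 1)] <- TRUE
  }
  r <- rle(d == 0)
  ends <- cumsum(r$lengths)
  for (i in which(r$values & r$lengths > flatline_s * x$fs)) {
    st <- ends[i] - r$lengths[i] + 1
    bad[st:(ends[i] + 1)] <- TRUE
  }
  if (!any(bad)) return(x)
  if (mean(bad) > max_bad_frac)
    stop("more than ", round(100 * max_bad_frac),
         "% of the record flagged bad; uncorrectable")
  good <- which(!bad)
  y[bad] <- stats::approx(good, y[good], xout = which(bad), rule = 2)$y
  raw_signal(matrix(y, ncol = 1), x$fs, x$labels, x$t0, x$unit)
}

#' @keywords internal
repair_ibi <- function(ibi, max_bad_frac = 0.5) {
  if (!length(ibi$ibi_s)) return(ibi)
  bad <- !ibi$valid
  if (!any(bad)) return(ibi)
  if (mean(bad) > max_bad_frac)
    stop("more than ", round(100 * max_bad_frac),
         "% of intervals non-physiological; uncorrectable")
  bt <- ibi$beat_times_s
  med <- stats::median(ibi$ibi_s[ibi$valid])
  new_bt <- bt[1]
  for (j in seq_along(ibi$ibi_s)) {
    iv <- ibi$ibi_s[j]
    if (bad[j] && iv > med) {
      # dropped beat(s): split into round(iv/med) equal intervals
      kk <- max(1, round(iv / med))
      new_bt <- c(new_bt, bt[j] + iv * seq_len(kk) / kk)
    } else if (bad[j] && iv <= med) {
      next                               # spurious beat: drop it
    } else {
      new_bt <- c(new_bt, bt[j + 1])
    }
  }
  new_bt <- sort(unique(new_bt))
  ibi2 <- diff(new_bt)
  structure(list(beat_times_s = new_bt, ibi_s = ibi2,
                 valid = ibi2 > 0.33 & ibi2 < 2.0), class = "fk_ibi")
}
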