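# EEG stage: notch + band-pass preprocessing, regression-based blink
# removal, 1-s epoching with three-criterion artifact screening,
# individual alpha frequency (IAF), strict alpha band, parietal
# alpha-band Global Field Power (GFP) and the MDrow drowsiness index.

#' Preprocess an EEG recording
#'
#' Zero-phase 50-Hz notch (Butterworth band-stop, bandwidth
#' \code{notch_hz / q}) followed by a zero-phase band-pass built as a
#' cascade of 4th-order high-pass (2 Hz) and low-pass (40 Hz)
#' Butterworth filters, each applied forward-backward. Length is
#' preserved.
#'
#' Scalp EEG amplitudes are treated as microvolts throughout.
#'
#' @param raw an \code{fk_signal} EEG stream (125 Hz expected; other
#'   rates accepted with a warning).
#' @param notch_hz,q notch centre frequency and quality factor.
#' @param bp_low_hz,bp_high_hz band-pass corner frequencies.
#' @param order Butterworth order of each band-pass stage.
#' @return filtered \code{fk_signal}.
#' @export
preprocess_eeg <- function(raw, notch_hz = 50, q = 30,
                           bp_low_hz = 2, bp_high_hz = 40, order = 4) {
  if (abs(raw$fs - 125) > 1e-9)
    warning("expected 125 Hz EEG, got ", raw$fs, " Hz")
  settling <- 1 / bp_low_hz
  if (signal_duration(raw) < 3 * settling)
    stop("record shorter than 3x filter settling time (",
         3 * settling, " s)")
  bw <- notch_hz / q
  x <- raw
  if (notch_hz < raw$fs / 2)
    x <- filter_signal(x, "stop", notch_hz + c(-1, 1) * bw / 2, order = 3)
  x <- filter_signal(x, "high", bp_low_hz, order = order)
  x <- filter_signal(x, "low", min(bp_high_hz, 0.95 * raw$fs / 2),
                     order = order)
  x$unit <- raw$unit
  x
}

#' Remove blink artifacts by vertical-EOG regression
#'
#' A reproducible replacement for proprietary blink-removal methods:
#' the vertical EOG derived from AFz (see [derive_veog()]) is regressed
#' out of every channel inside blink windows only. Per-channel
#' propagation coefficients are least-squares estimates pooled over all
#' blink windows; outside blink windows the signal is untouched.
#'
#' @param eeg an \code{fk_signal} EEG stream.
#' @param blinks data.frame of blink events (from [detect_blinks()]).
#' @param pad_s padding added around each blink window (s).
#' @return \code{fk_signal} with blink contributions subtracted.
#' @export
remove_blink_artifacts <- function(eeg, blinks, pad_s = 0.1) {
  if (is.null(blinks) || nrow(blinks) == 0) return(eeg)
  veog <- get_channel(derive_veog(eeg), "vEOG")
  tt <- signal_times(eeg)
  n <- length(tt)
  # window weight: 1 inside each blink, cosine ramps over pad_s at the
  # edges, so the subtracted waveform is continuous (no step artifacts)
  w <- numeric(n)
  fs <- eeg$fs
  ramp_n <- max(2, round(pad_s * fs))
  ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / (ramp_n + 1)))
  for (j in seq_len(nrow(blinks))) {
    i0 <- max(1, round((blinks$onset_s[j] - eeg$t0) * fs) + 1)
    i1 <- min(n, round((blinks$offset_s[j] - eeg$t0) * fs) + 1)
    w[i0:i1] <- 1
    lo <- max(1, i0 - ramp_n)
    w[lo:(i0 - 1)] <- pmax(w[lo:(i0 - 1)],
                           ramp[seq(ramp_n - (i0 - 1 - lo), ramp_n)])
    hi <- min(n, i1 + ramp_n)
    if (hi > i1)
      w[(i1 + 1):hi] <- pmax(w[(i1 + 1):hi],
                             rev(ramp)[seq_len(hi - i1)])
  }
  inwin <- w > 0
  if (!any(inwin)) return(eeg)
  v <- veog[inwin]
  denom <- sum(v * v)
  if (denom <= 0) return(eeg)
  x <- eeg$data
  sub <- veog[inwin] * w[inwin]
  for (c_i in seq_len(ncol(x))) {
    b <- sum(x[inwin, c_i] * v) / denom
    x[inwin, c_i] <- x[inwin, c_i] - b * sub
  }
  raw_signal(x, eeg$fs, eeg$labels, eeg$t0, eeg$unit)
}

#' Split an EEG recording into consecutive 1-s epochs
#'
#' \code{floor(duration)} non-overlapping epochs of exactly \code{fs}
#' samples; a trailing partial second is dropped. Epoch k (1-based)
#' starts at \code{t0 + (k-1)} seconds.
#'
#' @param eeg an \code{fk_signal}.
#' @param epoch_s epoch length in seconds (default 1).
#' @return an \code{fk_epochs} object: the data matrix, epoch index
#'   bounds, start times, a keep mask and per-epoch rejection reasons.
#' @export
epoch_signal <- function(eeg, epoch_s = 1) {
  len <- round(epoch_s * eeg$fs)
  n_ep <- floor(nrow(eeg$data) / len)
  if (n_ep < 1) stop("need at least ", epoch_s, " s of data to epoch")
  structure(list(
    data = eeg$data[seq_len(n_ep * len), , drop = FALSE],
    fs = eeg$fs, labels = eeg$labels, epoch_len = len, n_epochs = n_ep,
    start_s = eeg$t0 + (seq_len(n_ep) - 1) * epoch_s,
    mask = rep(TRUE, n_ep),
    reasons = vector("list", n_ep)), class = "fk_epochs")
}

#' @export
print.fk_epochs <- function(x, ...) {
  cat(sprintf("<fk_epochs> %d epochs x %d samples x %d ch; %d rejected\n",
              x$n_epochs, x$epoch_len, length(x$labels), sum(!x$mask)))
  invisible(x)
}

#' Extract one epoch as a samples-by-channels matrix
#' @param es an \code{fk_epochs}; @param k epoch index (1-based).
#' @export
epoch_data <- function(es, k) {
  i0 <- (k - 1) * es$epoch_len
  es$data[(i0 + 1):(i0 + es$epoch_len), , drop = FALSE]
}

#' Three-criterion artifact screening of 1-s epochs
#'
#' An epoch is rejected if any criterion fires on any channel:
#' \describe{
#'   \item{threshold}{absolute amplitude exceeds \code{thr_amp_uv}
#'     (default 80 uV);}
#'   \item{trend}{the absolute slope of a least-squares line fitted to
#'     the epoch exceeds \code{thr_slope_uv_s} (default 20 uV/s);}
#'   \item{step}{the largest absolute sample-to-sample difference
#'     exceeds \code{thr_step_uv} (default 25 uV).}
#' }
#' The rejected fraction is attached as attribute \code{data_loss}.
#' Raising any threshold can only decrease the rejected count.
#'
#' @param es an \code{fk_epochs} of preprocessed EEG.
#' @param thr_amp_uv,thr_slope_uv_s,thr_step_uv criterion thresholds.
#' @return the \code{fk_epochs} with \code{mask}/\code{reasons} filled
#'   and attribute \code{data_loss} (rejected / total).
#' @export
flag_artifacts <- function(es, thr_amp_uv = 80, thr_slope_uv_s = 20,
                           thr_step_uv = 25) {
  tt <- (seq_len(es$epoch_len) - 1) / es$fs
  tc <- tt - mean(tt)
  sxx <- sum(tc^2)
  for (k in seq_len(es$n_epochs)) {
    seg <- epoch_data(es, k)
    r <- character(0)
    if (max(abs(seg)) > thr_amp_uv) r <- c(r, "threshold")
    slopes <- abs(colSums(seg * tc) / sxx)      # per-channel LS slope
    if (max(slopes) > thr_slope_uv_s) r <- c(r, "trend")
    if (max(abs(diff(seg))) > thr_step_uv) r <- c(r, "step")
    es$mask[k] <- length(r) == 0
    es$reasons[[k]] <- r
  }
  attr(es, "data_loss") <- mean(!es$mask)
  es
}

#' Estimate the individual alpha frequency from eyes-closed EEG
#'
#' Welch-averaged Hanning periodogram (2-s segments, 50\% overlap,
#' 0.5-Hz resolution) averaged over the parietal channels; the IAF is
#' the frequency of maximum power in the 7--13 Hz search band. If the
#' peak is not at least 50\% above the band's median power (a genuine
#' alpha peak exceeds it several-fold; sampling fluctuation of a flat
#' spectrum stays well below) the estimate falls back to 10 Hz with
#' \code{fallback_used = TRUE}.
#'
#' @param ec_eeg preprocessed eyes-closed EEG (\code{fk_signal}),
#'   at least 30 s.
#' @param band search band in Hz.
#' @param parietal channels averaged for the spectrum.
#' @return list(iaf_hz, peak_power, search_band, fallback_used).
#' @export
estimate_iaf <- function(ec_eeg, band = c(7, 13),
                         parietal = c("Pz", "P3", "P4")) {
  if (signal_duration(ec_eeg) < 30)
    stop("need at least 30 s of valid eyes-closed data, got ",
         round(signal_duration(ec_eeg), 1), " s")
  acc <- NULL
  for (ch in parietal) {
    ps <- welch_psd(get_channel(ec_eeg, ch), ec_eeg$fs, seg_s = 2)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
  }
  pw <- acc / length(parietal)
  inb <- ps$freq >= band[1] & ps$freq <= band[2]
  fb <- ps$freq[inb]; pb <- pw[inb]
  imax <- which.max(pb)
  fallback <- pb[imax] < 1.5 * stats::median(pb)
  list(iaf_hz = if (fallback) 10.0 else fb[imax],
       peak_power = pb[imax], search_band = band,
       fallback_used = fallback)
}

#' Individualized strict alpha band
#'
#' \code{(IAF - 1, IAF + 1)} Hz: a 2-Hz band centred on the individual
#' alpha frequency, narrower than the conventional IAF +/- 2 Hz band to
#' keep neighbouring theta/beta variations out.
#'
#' @param iaf an IAF estimate (list with \code{iaf_hz}) or a numeric
#'   frequency in Hz.
#' @param halfwidth_hz half-width in Hz (default 1).
#' @return list(lo_hz, hi_hz).
#' @export
strict_alpha_band <- function(iaf, halfwidth_hz = 1) {
  f <- if (is.list(iaf)) iaf$iaf_hz else iaf
  list(lo_hz = f - halfwidth_hz, hi_hz = f + halfwidth_hz)
}

#' Per-epoch alpha-band Global Field Power
#'
#' Default method \code{"bandpower"}: for each valid epoch and each
#' parietal channel, a Hanning-windowed periodogram of the full epoch
#' (1-s epochs give 1 Hz resolution); power is summed over bins inside
#' the band (inclusive bounds) and averaged across channels.
#' Method \code{"spatial_sd"}: the epoch is band-pass filtered to the
#' band and the GFP is the time-average of the spatial standard
#' deviation across channels (vanishes for perfectly coherent activity,
#' which is why band power is the default).
#' Rejected epochs yield \code{NA}.
#'
#' @param es an \code{fk_epochs} after [flag_artifacts()].
#' @param band list(lo_hz, hi_hz) from [strict_alpha_band()].
#' @param channels channels entering the GFP.
#' @param method \code{"bandpower"} or \code{"spatial_sd"}.
#' @return numeric vector, one value (or NA) per epoch.
#' @export
alpha_gfp <- function(es, band, channels = c("Pz", "P3", "P4"),
                      method = c("bandpower", "spatial_sd")) {
  method <- match.arg(method)
  miss <- setdiff(channels, es$labels)
  if (length(miss))
    stop("requested channel(s) absent: ", paste(miss, collapse = ", "))
  ci <- match(channels, es$labels)
  out <- rep(NA_real_, es$n_epochs)
  if (method == "bandpower") {
    n <- es$epoch_len
    w <- hann(n)
    norm <- n * sum(w^2)
    freqs <- (seq_len(floor(n / 2) + 1) - 1) * es$fs / n
    bins <- which(freqs >= band$lo_hz - 1e-9 & freqs <= band$hi_hz + 1e-9)
    for (k in which(es$mask)) {
      seg <- epoch_data(es, k)[, ci, drop = FALSE]
      p <- vapply(seq_along(ci), function(j) {
        X <- stats::fft((seg[, j] - mean(seg[, j])) * w)
        sum(2 * Mod(X[bins])^2) / norm
      }, numeric(1))
      out[k] <- mean(p)
    }
  } else {
    flt <- signal::butter(4, c(band$lo_hz, band$hi_hz) / (es$fs / 2),
                          "pass")
    xf <- apply(es$data[, ci, drop = FALSE], 2,
                function(ch) signal::filtfilt(flt, ch))
    for (k in which(es$mask)) {
      i0 <- (k - 1) * es$epoch_len
      seg <- xf[(i0 + 1):(i0 + es$epoch_len), , drop = FALSE]
      out[k] <- mean(apply(seg, 1, stats::sd))
    }
  }
  out
}

#' MDrow mental drowsiness index per 60-s window
#'
#' Baseline-normalized parietal alpha-band GFP: for each 60-s window,
#' MDrow = mean GFP over the window's valid epochs divided by the mean
#' valid-epoch GFP of the first eyes-open rest (the baseline). The index
#' is dimensionless and directly comparable between participants.
#' Windows with fewer than \code{min_valid} valid epochs are flagged
#' invalid and carry no value.
#'
#' @param gfp per-epoch GFP vector (NA for rejected epochs) whose epoch
#'   k starts at \code{(k-1)} seconds.
#' @param baseline_gfp positive scalar baseline (mean eyes-open GFP).
#' @param window_s window length (s).
#' @param min_valid minimum valid epochs per window (default 30).
#' @return data.frame(window_start_s, value, n_valid, valid_flag).
#' @export
mdrow_index <- function(gfp, baseline_gfp, window_s = 60, min_valid = 30) {
  if (!is.finite(baseline_gfp) || baseline_gfp <= 0)
    stop("baseline_gfp must be positive")
  wins <- window_grid(length(gfp), window_s)
  out <- wins["window_start_s"]
  out$value <- NA_real_
  out$n_valid <- 0L
  for (i in seq_len(nrow(wins))) {
    idx <- (wins$window_start_s[i] + 1):(wins$window_end_s[i])
    v <- gfp[idx]
    out$n_valid[i] <- sum(!is.na(v))
    if (out$n_valid[i] >= min_valid)
      out$value[i] <- mean(v, na.rm = TRUE) / baseline_gfp
  }
  out$valid_flag <- out$n_valid >= min_valid
  out
}
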