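# Shared numeric helpers: zero-phase filtering, Welch/Hanning spectra,
# window grids. Filter design via signal::butter; filtering via filtfilt
# (forward-backward, zero phase).

#' Zero-phase Butterworth filter applied to every channel
#'
#' @param x an \code{fk_signal}.
#' @param type \code{"low"}, \code{"high"} or \code{"stop"}.
#' @param cutoff_hz scalar (low/high) or length-2 (stop) cutoff in Hz.
#' @param order Butterworth order.
#' @return filtered \code{fk_signal}, same length and metadata.
#' @keywords internal
filter_signal <- function(x, type, cutoff_hz, order = 4) {
  w <- cutoff_hz / (x$fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff ", paste(cutoff_hz, collapse = "-"),
         " Hz invalid for fs = ", x$fs, " Hz")
  flt <- signal::butter(order, w, type)
  y <- apply(x$data, 2, function(ch) signal::filtfilt(flt, ch))
  raw_signal(matrix(y, ncol = ncol(x$data)), x$fs, x$labels, x$t0, x$unit)
}

#' Hanning window of length n (periodic-symmetric as used for periodograms)
#' @keywords internal
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' One-sided Hanning periodogram, Parseval-consistent scaling
#'
#' Per-bin power such that the sum over all bins equals the windowed
#' signal's variance; a sinusoid on a bin contributes A^2/2 in total
#' (spread over the window's main lobe). Frequency resolution is
#' fs/length(x).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @return list(freq, power) with freq from 0 to fs/2.
#' @keywords internal
periodogram_hann <- function(x, fs) {
  n <- length(x)
  w <- hann(n)
  X <- stats::fft((x - mean(x)) * w)
  nf <- floor(n / 2) + 1
  p <- (2 * Mod(X[seq_len(nf)])^2) / (n * sum(w^2))
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[nf] <- p[nf] / 2
  list(freq = (seq_len(nf) - 1) * fs / n, power = p)
}

#' Welch average of Hanning periodograms (50% overlap)
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds.
#' @return list(freq, power) averaged over segments.
#' @keywords internal
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) stop("record shorter than one Welch segment")
  step <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = step)
  acc <- NULL
  for (s in starts) {
    pg <- periodogram_hann(x[s:(s + nseg - 1)], fs)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  list(freq = pg$freq, power = acc / length(starts))
}

#' Moving-median detrend
#' @param x numeric vector.
#' @param k odd window length in samples.
#' @return x minus its running median.
#' @keywords internal
movmed_detrend <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  x - stats::runmed(x, k, endrule = "median")
}

#' 60-s (or other) window grid over a duration
#'
#' @param duration_s total duration (s).
#' @param window_s window length (s).
#' @return data.frame(window_start_s, window_end_s), half-open windows;
#'   trailing partial window dropped.
#' @export
window_grid <- function(duration_s, window_s = 60) {
  n <- floor(duration_s / window_s + 1e-9)
  data.frame(window_start_s = (seq_len(n) - 1) * window_s,
             window_end_s = seq_len(n) * window_s)
}

#' Assign event times to half-open windows
#' @keywords internal
window_of <- function(time_s, window_s = 60) floor(time_s / window_s) + 1L

#' Evaluate a per-minute profile at sample times
#'
#' Zero-order hold: profile value i applies over the whole half-open
#' minute [60(i-1), 60i), so planted per-minute conditions stay exactly
#' aligned with the 60-s analysis windows and 15-min segments.
#' @keywords internal
profile_at <- function(profile, t) {
  idx <- pmin(length(profile), pmax(1L, floor(t / 60) + 1L))
  profile[idx]
}
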