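# Oculometric stage: vertical EOG derived from the frontal AFz channel,
# threshold-based blink detection with a MAD-adaptive threshold, and
# per-minute blink rate (EBR), duration (EBD) and amplitude (EBA).

#' Derive the vertical EOG from the AFz channel
#'
#' AFz (raw, pre-blink-removal) is low-pass filtered at 7 Hz
#' (zero-phase) and baseline-detrended with a 2-s moving median. The
#' blink potential, whose energy sits well below 7 Hz, survives largely
#' intact while alpha-band and faster EEG activity is attenuated.
#'
#' @param eeg an \code{fk_signal} containing an AFz channel.
#' @param lp_hz low-pass cutoff (Hz).
#' @param detrend_s moving-median window (s).
#' @return single-channel \code{fk_signal} labelled \code{"vEOG"}.
#' @export
derive_veog <- function(eeg, lp_hz = 7, detrend_s = 2) {
  afz <- get_channel(eeg, "AFz")
  afz <- afz - mean(afz)           # tame filter edge transients
  flt <- signal::butter(4, lp_hz / (eeg$fs / 2), "low")
  v <- signal::filtfilt(flt, afz)
  v <- movmed_detrend(v, round(detrend_s * eeg$fs))
  raw_signal(v, eeg$fs, "vEOG", eeg$t0, eeg$unit)
}

#' Detect eyeblinks on a vertical EOG trace
#'
#' Peaks above an adaptive threshold (median + \code{mad_mult} x MAD of
#' the trace) with at least \code{min_sep_s} separation are taken as
#' blink apexes. Onset and offset are found by walking out from the
#' peak to where the trace falls to \code{edge_frac} (10\%) of the peak
#' height above the local baseline (median of the surrounding 2 s).
#' Candidates violating the blink invariants (onset < peak < offset,
#' positive amplitude, duration within \code{dur_range_s}) are
#' discarded. Raising \code{mad_mult} never increases the number of
#' detections.
#'
#' @param veog single-channel \code{fk_signal} from [derive_veog()].
#' @param mad_mult threshold multiplier on the MAD.
#' @param min_sep_s minimum peak separation (s).
#' @param edge_frac onset/offset height fraction.
#' @param dur_range_s admissible blink duration range (s).
#' @return data.frame(onset_s, peak_s, offset_s, amplitude_uv,
#'   duration_s), session-relative times; empty when nothing is found.
#' @export
detect_blinks <- function(veog, mad_mult = 4, min_sep_s = 0.2,
                          edge_frac = 0.1, dur_range_s = c(0.05, 1.0)) {
  v <- get_channel(veog, "vEOG")
  fs <- veog$fs
  thr <- stats::median(v) + mad_mult * stats::mad(v)
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), amplitude_uv = numeric(0),
                      duration_s = numeric(0))
  if (!any(v > thr) || stats::mad(v) == 0) return(empty)
  pk <- pracma::findpeaks(v, minpeakheight = thr,
                          minpeakdistance = max(1, round(min_sep_s * fs)))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  res <- empty
  half_base <- round(fs)            # 1 s each side for the local baseline
  for (j in seq_len(nrow(pk))) {
    ip <- pk[j, 2]
    lo <- max(1, ip - half_base); hi <- min(length(v), ip + half_base)
    base <- stats::median(v[lo:hi])
    amp <- v[ip] - base
    if (amp <= 0) next
    lev <- base + edge_frac * amp
    io <- ip; while (io > lo && v[io - 1] > lev) io <- io - 1
    ie <- ip; while (ie < hi && v[ie + 1] > lev) ie <- ie + 1
    dur <- (ie - io) / fs
    if (io >= ip || ie <= ip) next
    if (dur <= dur_range_s[1] || dur >= dur_range_s[2]) next
    res <- rbind(res, data.frame(
      onset_s = veog$t0 + (io - 1) / fs,
      peak_s = veog$t0 + (ip - 1) / fs,
      offset_s = veog$t0 + (ie - 1) / fs,
      amplitude_uv = amp, duration_s = dur))
  }
  res
}

#' Per-minute blink features
#'
#' Blink events are assigned to the 60-s window containing their peak
#' (half-open windows: a peak exactly on a boundary belongs to the later
#' window). EBR is the count per window (blinks/min for 60-s windows),
#' EBD and EBA the mean duration and amplitude; both are missing when a
#' window holds no blinks.
#'
#' @param blinks data.frame from [detect_blinks()].
#' @param duration_s analysed duration (s), defining the window grid.
#' @param window_s window length (s).
#' @return data.frame(window_start_s, ebr, ebd_s, eba_uv, n_blinks).
#' @export
blink_features <- function(blinks, duration_s, window_s = 60) {
  wins <- window_grid(duration_s, window_s)
  out <- data.frame(window_start_s = wins$window_start_s,
                    ebr = 0, ebd_s = NA_real_, eba_uv = NA_real_,
                    n_blinks = 0L)
  if (nrow(blinks)) {
    wi <- window_of(blinks$peak_s, window_s)
    for (i in seq_len(nrow(out))) {
      sel <- wi == i
      out$n_blinks[i] <- sum(sel)
      out$ebr[i] <- sum(sel) * 60 / window_s
      if (any(sel)) {
        out$ebd_s[i] <- mean(blinks$duration_s[sel])
        out$eba_uv[i] <- mean(blinks$amplitude_uv[sel])
      }
    }
  }
  out
}
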