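#' Pipeline configuration defaults
#'
#' Central registry of every tunable constant in the pipeline, grouped by
#' stage. These are the values used by all processing functions unless
#' overridden through their arguments.
#'
#' Key entries:
#' \itemize{
#'   \item \code{eeg}: 50 Hz notch (Q = 30), 2--40 Hz band-pass, 1-s epochs,
#'     artifact thresholds (amplitude 80 uV, trend slope 20 uV/s,
#'     sample-to-sample step 25 uV), individual-alpha search band 7--13 Hz,
#'     strict alpha half-width 1 Hz, parietal channels Pz/P3/P4,
#'     1 Hz spectral resolution for the per-epoch Hanning periodogram.
#'   \item \code{ocular}: 7 Hz vertical-EOG low-pass, 2-s moving-median
#'     detrend, 4 x MAD detection threshold, 200 ms minimum peak
#'     separation, 10\%-height onset/offset rule.
#'   \item \code{ppg}: 5th-order Butterworth band-pass 0.4--3.5 Hz,
#'     pulse-adapted beat detector constants (150 ms integration window,
#'     250 ms refractory, 0.25 threshold blend), physiological
#'     inter-beat-interval range 0.33--2 s.
#'   \item \code{hrv}: Lomb-Scargle grid 0.005--0.5 Hz step 0.0025 Hz;
#'     LF band 0.04--0.15 Hz, HF band 0.15--0.4 Hz.
#'   \item \code{eda}: 1 Hz low-pass, Bateman time constants
#'     tau1 = 0.75 s / tau2 = 2 s, 20-s 10th-percentile tonic baseline.
#'   \item \code{analysis}: 60-s feature window, three 15-min segments,
#'     alpha = 0.05, KSS range 1--9, Chalder mental-subscale item range
#'     0--3 over six items.
#' }
#'
#' @return nested named list of defaults.
#' @export
fk_defaults <- function() {
  list(
    eeg = list(
      fs = 125,
      channels = c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4"),
      parietal = c("Pz", "P3", "P4"),
      notch_hz = 50, notch_q = 30,
      bp_low_hz = 2, bp_high_hz = 40, bp_order = 4,
      epoch_s = 1,
      thr_amp_uv = 80, thr_slope_uv_s = 20, thr_step_uv = 25,
      iaf_band_hz = c(7, 13), iaf_fallback_hz = 10,
      iaf_seg_s = 2, iaf_min_s = 30, iaf_prominence = 1.5,
      alpha_halfwidth_hz = 1,
      gfp_resolution_hz = 1,
      min_valid_epochs_per_window = 30
    ),
    ocular = list(
      veog_lp_hz = 7, detrend_s = 2,
      mad_mult = 4, min_sep_s = 0.2, edge_frac = 0.1,
      dur_range_s = c(0.05, 1.0)
    ),
    ppg = list(
      fs = 64, bp_hz = c(0.4, 3.5), bp_order = 5,
      integ_s = 0.15, refractory_s = 0.25, thr_blend = 0.25,
      search_s = 0.1, ibi_range_s = c(0.33, 2.0),
      min_intervals_per_window = 10
    ),
    hrv = list(
      f_grid = c(0.005, 0.5), f_step = 0.0025,
      lf_hz = c(0.04, 0.15), hf_hz = c(0.15, 0.4),
      min_duration_s = 120
    ),
    eda = list(
      fs = 4, lp_hz = 1,
      tau1_s = 0.75, tau2_s = 2,
      baseline_win_s = 20, baseline_pct = 0.10, smooth_s = 10
    ),
    artifact_interp = list(jump_sd_mult = 5, flatline_s = 2, max_bad_frac = 0.5),
    analysis = list(
      window_s = 60, n_segments = 3, segment_min = 15,
      alpha = 0.05,
      kss_range = c(1, 9),
      chalder_item_range = c(0, 3), chalder_n_items = 6,
      administrations = c("Arrival", "post_Circuit", "post_Monotonous"),
      max_invalid_window_frac = 0.5
    )
  )
}
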