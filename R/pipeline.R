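# End-to-end pipeline: per-session feature extraction (EEG, oculometric,
# autonomic, behavioral, questionnaire) and cohort-level statistics.

#' Extract all per-session features
#'
#' Runs the full single-session pipeline:
#' \enumerate{
#'   \item individual alpha frequency from the eyes-closed phase;
#'   \item alpha-GFP baseline from the first eyes-open rest (EO1),
#'     after preprocessing, blink removal and artifact screening;
#'   \item monotonous phase: blink detection on the raw frontal
#'     channel, preprocessing, blink removal, 1-s epoching with
#'     three-criterion screening, strict-alpha GFP and per-60-s MDrow;
#'   \item per-minute blink rate/duration/amplitude from the vertical
#'     EOG;
#'   \item PPG: band-pass, pulse detection, interval repair, per-minute
#'     HR and per-15-min-segment Lomb-Scargle LF/HF;
#'   \item EDA: low-pass, artifact interpolation, tonic decomposition,
#'     per-minute session-normalized SCL;
#'   \item reaction times from the alarm/button-press event pairs;
#'   \item questionnaire scoring.
#' }
#' Modalities absent from the session are skipped.
#'
#' @param session an \code{fk_session} covering the protocol phases.
#' @param gfp_method GFP estimator passed to [alpha_gfp()].
#' @return named list of feature series (see [build_feature_table()])
#'   plus \code{iaf}, \code{data_loss} and \code{questionnaire_scores}.
#' @export
extract_features <- function(session, gfp_method = "bandpower") {
  cfg <- fk_defaults()
  out <- list()

  if (!is.null(session$eeg)) {
    ec <- slice_phase(session, "EC")$eeg
    iaf <- estimate_iaf(preprocess_eeg(ec), band = cfg$eeg$iaf_band_hz,
                        parietal = cfg$eeg$parietal)
    band <- strict_alpha_band(iaf, cfg$eeg$alpha_halfwidth_hz)

    gfp_of <- function(eeg_raw) {
      blinks <- detect_blinks(derive_veog(eeg_raw))
      pp <- preprocess_eeg(eeg_raw)
      pp <- remove_blink_artifacts(pp, blinks)
      es <- flag_artifacts(epoch_signal(pp),
                           cfg$eeg$thr_amp_uv, cfg$eeg$thr_slope_uv_s,
                           cfg$eeg$thr_step_uv)
      list(gfp = alpha_gfp(es, band, cfg$eeg$parietal, gfp_method),
           es = es, blinks = blinks)
    }

    eo1 <- gfp_of(slice_phase(session, "EO1")$eeg)
    baseline <- mean(eo1$gfp, na.rm = TRUE)

    mono_eeg <- slice_phase(session, "Monotonous")$eeg
    mono <- gfp_of(mono_eeg)
    out$mdrow <- mdrow_index(mono$gfp, baseline,
                             window_s = cfg$analysis$window_s,
                             min_valid = cfg$eeg$min_valid_epochs_per_window)
    out$data_loss <- attr(mono$es, "data_loss")
    out$iaf <- iaf

    bf <- blink_features(mono$blinks, signal_duration(mono_eeg),
                         cfg$analysis$window_s)
    out$ebr <- data.frame(window_start_s = bf$window_start_s,
                          value = bf$ebr)
    out$ebd <- data.frame(window_start_s = bf$window_start_s,
                          value = bf$ebd_s)
    out$eba <- data.frame(window_start_s = bf$window_start_s,
                          value = bf$eba_uv)
  }

  if (!is.null(session$ppg)) {
    mono_ppg <- slice_phase(session, "Monotonous")$ppg
    pp <- preprocess_ppg(mono_ppg, cfg$ppg$bp_hz, cfg$ppg$bp_order)
    ibi <- detect_pulses(pp, cfg$ppg$integ_s, cfg$ppg$refractory_s,
                         cfg$ppg$thr_blend, cfg$ppg$search_s,
                         cfg$ppg$ibi_range_s)
    ibi <- interpolate_movement_artifacts(ibi)
    dur <- signal_duration(mono_ppg)
    out$hr <- hr_per_window(ibi, dur, cfg$analysis$window_s,
                            cfg$ppg$min_intervals_per_window)
    seg_len <- cfg$analysis$segment_min * 60
    n_seg <- max(1, floor(dur / seg_len))
    out$lfhf <- vapply(seq_len(n_seg), function(s) {
      sel <- ibi$beat_times_s >= (s - 1) * seg_len &
        ibi$beat_times_s < s * seg_len
      sub <- structure(list(
        beat_times_s = ibi$beat_times_s[sel],
        ibi_s = diff(ibi$beat_times_s[sel]),
        valid = NULL), class = "fk_ibi")
      sub$valid <- sub$ibi_s >= cfg$ppg$ibi_range_s[1] &
        sub$ibi_s <= cfg$ppg$ibi_range_s[2]
      tryCatch(lomb_scargle_psd(sub)$lf_hf_ratio,
               error = function(e) NA_real_)
    }, numeric(1))
  }

  if (!is.null(session$eda)) {
    mono_eda <- slice_phase(session, "Monotonous")$eda
    ed <- preprocess_eda(mono_eda, cfg$eda$lp_hz)
    ed <- interpolate_movement_artifacts(ed)
    dec <- decompose_eda(ed, cfg$eda$tau1_s, cfg$eda$tau2_s,
                         cfg$eda$baseline_win_s, cfg$eda$baseline_pct,
                         cfg$eda$smooth_s, cfg$analysis$window_s)
    out$scl <- dec$scl_normalized
  }

  rt <- session_rt(session)
  if (!is.null(rt)) out$rt <- rt$rt_s

  if (!is.null(session$questionnaires))
    out$questionnaire_scores <- score_questionnaires(session$questionnaires)
  out
}

#' Reaction times from the event table
#'
#' Each alarm is paired with the first subsequent button press carrying
#' the same payload; RT is the press time minus the alarm time. Falls
#' back to a stored \code{session$rt} table when present.
#' @param session an \code{fk_session}.
#' @return data.frame(alarm_id, alarm_time_s, rt_s) or NULL.
#' @export
session_rt <- function(session) {
  if (!is.null(session$rt)) return(session$rt)
  ev <- session$events
  al <- ev[ev$kind == "alarm", , drop = FALSE]
  if (!nrow(al)) return(NULL)
  bp <- ev[ev$kind == "button_press", , drop = FALSE]
  rt <- vapply(seq_len(nrow(al)), function(i) {
    cand <- bp$time_s[bp$payload == al$payload[i] &
                        bp$time_s > al$time_s[i]]
    if (length(cand)) min(cand) - al$time_s[i] else NA_real_
  }, numeric(1))
  data.frame(alarm_id = al$payload, alarm_time_s = al$time_s, rt_s = rt,
             stringsAsFactors = FALSE)
}

#' Cohort-level statistical analysis
#'
#' Builds the per-segment cohort table, splits participants into
#' fatigued / non-fatigued groups by their RT trend, and runs for every
#' feature the within-subject omnibus test (Shapiro-Wilk gated RM-ANOVA
#' or Friedman) with Holm-corrected pairwise post-hocs, plus the
#' Segments x Group analysis. Questionnaire scores are analysed
#' non-parametrically across the three administrations. A verdict table
#' summarises each feature as increase / decrease / no effect.
#'
#' @param features_by_participant named list (participant id ->
#'   [extract_features()] output).
#' @param alpha significance level.
#' @return list(table, groups, within, interaction, questionnaires,
#'   verdicts).
#' @export
analyze_cohort <- function(features_by_participant, alpha = 0.05) {
  feat_names <- c("mdrow", "ebr", "ebd", "eba", "hr", "lfhf", "scl", "rt")
  flists <- lapply(features_by_participant, function(f)
    f[intersect(feat_names, names(f))])
  table <- build_feature_table(flists)
  groups <- split_groups(table)

  present <- intersect(feat_names, unique(table$feature))
  within <- lapply(present, function(fn) {
    om <- tryCatch(omnibus_within(table, fn), error = function(e) NULL)
    if (is.null(om)) return(NULL)
    posthoc_pairwise_holm(table, fn, om, alpha)
  })
  names(within) <- present

  inter <- lapply(present, function(fn)
    tryCatch(interaction_anova(table, fn, groups),
             error = function(e) NULL))
  names(inter) <- present

  qres <- NULL
  qtabs <- lapply(names(features_by_participant), function(pid) {
    qs <- features_by_participant[[pid]]$questionnaire_scores
    if (is.null(qs)) return(NULL)
    qs$participant <- pid
    qs
  })
  qtabs <- do.call(rbind, qtabs)
  if (!is.null(qtabs) && nrow(qtabs)) {
    adm <- fk_defaults()$analysis$administrations
    qres <- lapply(unique(qtabs$instrument), function(inst) {
      sub <- qtabs[qtabs$instrument == inst, , drop = FALSE]
      qt <- data.frame(participant = sub$participant, feature = inst,
                       segment = match(sub$administration, adm),
                       value = sub$score, stringsAsFactors = FALSE)
      om <- tryCatch(
        omnibus_within(qt, inst, force_nonparametric = TRUE),
        error = function(e) NULL)
      if (is.null(om)) NULL else posthoc_pairwise_holm(qt, inst, om, alpha)
    })
    names(qres) <- unique(qtabs$instrument)
  }

  verdicts <- do.call(rbind, lapply(present, function(fn) {
    om <- within[[fn]]
    if (is.null(om)) return(NULL)
    dir <- "no effect"
    if (is.finite(om$p_raw) && om$p_raw < alpha) {
      m <- wide_segments(table, fn)
      dir <- if (mean(m[, 3]) > mean(m[, 1])) "increase" else "decrease"
    }
    data.frame(feature = fn, test = om$test, p = om$p_raw,
               verdict = dir, stringsAsFactors = FALSE)
  }))

  list(table = table, groups = groups, within = within,
       interaction = inter, questionnaires = qres, verdicts = verdicts)
}

#' Write feature series of one session as CSV files
#'
#' One file per feature with columns window_start_s, value (and
#' n_valid/valid_flag where tracked), matching the layout consumed by
#' [read_feature_dir()].
#'
#' @param features output of [extract_features()].
#' @param dir destination directory.
#' @return dir, invisibly.
#' @export
write_feature_dir <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fn in intersect(c("mdrow", "ebr", "ebd", "eba", "hr", "scl"),
                       names(features)))
    utils::write.csv(features[[fn]], file.path(dir, paste0(fn, ".csv")),
                     row.names = FALSE)
  if (!is.null(features$lfhf))
    utils::write.csv(data.frame(segment = seq_along(features$lfhf),
                                value = features$lfhf),
                     file.path(dir, "lfhf.csv"), row.names = FALSE)
  if (!is.null(features$rt))
    utils::write.csv(data.frame(alarm = seq_along(features$rt),
                                rt_s = features$rt),
                     file.path(dir, "rt.csv"), row.names = FALSE)
  if (!is.null(features$questionnaire_scores))
    utils::write.csv(features$questionnaire_scores,
                     file.path(dir, "questionnaires.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a feature directory written by [write_feature_dir()]
#' @param dir directory of per-feature CSVs.
#' @return named list in the [extract_features()] layout.
#' @export
read_feature_dir <- function(dir) {
  out <- list()
  for (fn in c("mdrow", "ebr", "ebd", "eba", "hr", "scl")) {
    f <- file.path(dir, paste0(fn, ".csv"))
    if (file.exists(f)) out[[fn]] <- utils::read.csv(f)
  }
  f <- file.path(dir, "lfhf.csv")
  if (file.exists(f)) out$lfhf <- utils::read.csv(f)$value
  f <- file.path(dir, "rt.csv")
  if (file.exists(f)) out$rt <- utils::read.csv(f)$rt_s
  f <- file.path(dir, "questionnaires.csv")
  if (file.exists(f))
    out$questionnaire_scores <- utils::read.csv(f, stringsAsFactors = FALSE)
  out
}
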