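# Synthetic-session simulator. Generates complete multimodal recordings
# (EEG, PPG, EDA, behavior, questionnaires) over the standard protocol
# timeline with every planted quantity recorded in a GroundTruth ledger,
# so each downstream stage has a parameter-recovery test.

#' Simulation configuration
#'
#' @param ec_s,eo_s,circuit_s,monotonous_s phase durations in seconds.
#'   Defaults: eyes-closed 60 s, each eyes-open 60 s, demanding circuit
#'   900 s, monotonous drive 2700 s (45 min).
#' @param n_alarms number of secondary-task alarms in the monotonous
#'   phase (default 9).
#' @param eeg_noise_uv pink-noise standard deviation per EEG channel (uV).
#' @param ppg_noise white-noise SD added to the pulse waveform (a.u.).
#' @param eda_noise_us white-noise SD added to the EDA trace (uS).
#' @param rt_sigma_s reaction-time Gaussian noise SD (s).
#' @param frontal_alpha_frac fraction of parietal alpha amplitude leaking
#'   to frontal channels.
#' @param ec_alpha_boost closed-eyes alpha amplitude multiplier.
#' @param phasic_rate_per_min Poisson rate of electrodermal phasic
#'   responses (per minute).
#' @param seed integer seed; every stochastic draw in the simulator flows
#'   from it.
#' @return a \code{fk_simconfig} list.
#' @export
sim_config <- function(ec_s = 60, eo_s = 60, circuit_s = 900,
                       monotonous_s = 2700, n_alarms = 9,
                       eeg_noise_uv = 3, ppg_noise = 0.02,
                       eda_noise_us = 0.01, rt_sigma_s = 0.08,
                       frontal_alpha_frac = 0.3, ec_alpha_boost = 2,
                       phasic_rate_per_min = 2, seed = 1L) {
  stopifnot(ec_s > 0, eo_s > 0, circuit_s > 0, monotonous_s > 0,
            n_alarms >= 1)
  cfg <- list(ec_s = ec_s, eo_s = eo_s, circuit_s = circuit_s,
              monotonous_s = monotonous_s, n_alarms = n_alarms,
              eeg_noise_uv = eeg_noise_uv, ppg_noise = ppg_noise,
              eda_noise_us = eda_noise_us, rt_sigma_s = rt_sigma_s,
              frontal_alpha_frac = frontal_alpha_frac,
              ec_alpha_boost = ec_alpha_boost,
              phasic_rate_per_min = phasic_rate_per_min,
              seed = as.integer(seed))
  class(cfg) <- "fk_simconfig"
  cfg
}

#' Total simulated session duration (s)
#' @param cfg a \code{fk_simconfig}.
#' @export
session_duration <- function(cfg)
  cfg$ec_s + 3 * cfg$eo_s + cfg$circuit_s + cfg$monotonous_s

#' Protocol phase intervals for a configuration
#' @keywords internal
phase_bounds <- function(cfg) {
  d <- c(EC = cfg$ec_s, EO1 = cfg$eo_s, Circuit = cfg$circuit_s,
         EO2 = cfg$eo_s, Monotonous = cfg$monotonous_s, EO3 = cfg$eo_s)
  en <- cumsum(d)
  st <- en - d
  data.frame(phase = names(d), start_s = unname(st), end_s = unname(en),
             stringsAsFactors = FALSE)
}

#' Build the protocol event timeline
#'
#' Phases run back-to-back in the fixed order EC, EO1, Circuit, EO2,
#' Monotonous, EO3. Exactly \code{n_alarms} alarm events are placed
#' inside the monotonous phase at roughly equal intervals, with each
#' interval jittered by up to +/-10\% of the mean spacing so no two
#' inter-alarm gaps are equal (avoids anticipation effects). Fully
#' deterministic given the config seed.
#'
#' @param cfg a \code{fk_simconfig}.
#' @return an event table (see [event_table()]).
#' @export
make_protocol_timeline <- function(cfg) {
  pb <- phase_bounds(cfg)
  ev <- event_table(
    time_s = c(pb$start_s, pb$end_s),
    kind = rep(c("phase_start", "phase_end"), each = nrow(pb)),
    payload = rep(pb$phase, 2))
  set.seed(cfg$seed)
  mono <- pb[pb$phase == "Monotonous", ]
  m <- (mono$end_s - mono$start_s) / (cfg$n_alarms + 1)
  repeat {
    jit <- stats::runif(cfg$n_alarms, -0.1 * m, 0.1 * m)
    t_al <- mono$start_s + m * seq_len(cfg$n_alarms) + jit
    if (!anyDuplicated(round(diff(t_al), 6))) break
  }
  al <- event_table(t_al, rep("alarm", cfg$n_alarms),
                    paste0("A", seq_len(cfg$n_alarms)))
  out <- rbind(ev, al)
  out[order(out$time_s), , drop = FALSE]
}

#' Construct a ground-truth ledger with planted fatigue dynamics
#'
#' Per-minute physiological profiles span the whole session. Defaults
#' plant the dynamics the pipeline is meant to detect: during the
#' monotonous phase the parietal alpha amplitude rises (one segment
#' earlier for the fatigued profile), blink rate rises, heart rate falls
#' slightly and tonic skin conductance drifts down; reaction times drift
#' up for the fatigued profile and down for the non-fatigued one.
#'
#' @param cfg a \code{fk_simconfig}.
#' @param group \code{"fatigued"} or \code{"not_fatigued"}.
#' @param seed integer seed for this participant.
#' @param iaf_hz individual alpha frequency; by default drawn from the
#'   0.5-Hz grid 8.5--11.5 Hz.
#' @return a \code{fk_truth} list; planted event-level quantities
#'   (blink times, beat times, artifact epochs, RT draws, tonic minute
#'   means) are filled in by the simulators.
#' @export
default_ground_truth <- function(cfg, group = c("fatigued", "not_fatigued"),
                                 seed = cfg$seed, iaf_hz = NULL) {
  group <- match.arg(group)
  set.seed(seed)
  if (is.null(iaf_hz)) iaf_hz <- sample(seq(8.5, 11.5, by = 0.5), 1)
  n_min <- ceiling(session_duration(cfg) / 60)
  pb <- phase_bounds(cfg)
  minute_mid <- (seq_len(n_min) - 0.5) * 60
  in_phase <- function(p) minute_mid >= pb$start_s[pb$phase == p] &
    minute_mid < pb$end_s[pb$phase == p]
  mono <- in_phase("Monotonous")
  mono_idx <- which(mono)
  n_mono <- length(mono_idx)
  seg <- ceiling(3 * seq_len(n_mono) / n_mono)  # 1,2,3 thirds

  alpha <- rep(4, n_min)
  if (group == "fatigued") {
    alpha[mono_idx] <- c(4, 7, 7.5)[seg]
  } else {
    alpha[mono_idx] <- c(4, 4, 7)[seg]   # rise only in the third segment
  }
  blink <- rep(12, n_min)
  blink[in_phase("EC")] <- 0    # eyes closed: no blinks
  blink[mono_idx] <- if (group == "fatigued") c(12, 15, 20)[seg]
                     else c(12, 13, 15)[seg]
  ramp01 <- if (n_mono > 1) (seq_len(n_mono) - 1) / (n_mono - 1)
            else numeric(n_mono)
  hr <- rep(72, n_min)
  hr[mono_idx] <- 72 - 4 * ramp01
  scl <- rep(3.5, n_min)
  scl[mono_idx] <- 3.5 - ramp01

  truth <- list(
    iaf_hz = iaf_hz,
    alpha_amp_profile = alpha,
    blink_rate_profile = blink,
    blink_dur_s = 0.3, blink_amp_uv = 120,
    hr_profile = hr,
    lf_power = 1.6e-3, hf_power = 0.4e-3,
    scl_profile = scl,
    rt_baseline_s = 0.8,
    rt_slope_s_per_alarm = if (group == "fatigued") 0.03 else -0.03,
    group_label = group,
    n_artifact_epochs_injected = 60L,
    seed = as.integer(seed))
  class(truth) <- "fk_truth"
  validate_ground_truth(truth, cfg)
  truth
}

#' @keywords internal
validate_ground_truth <- function(truth, cfg) {
  n_min <- ceiling(session_duration(cfg) / 60)
  for (f in c("alpha_amp_profile", "blink_rate_profile", "hr_profile",
              "scl_profile"))
    if (length(truth[[f]]) != n_min)
      stop(f, " must have one entry per simulated minute (", n_min, ")")
  if (truth$iaf_hz < 7 || truth$iaf_hz > 13)
    stop("iaf_hz outside plausible 7-13 Hz range")
  if (any(truth$hr_profile < 40 | truth$hr_profile > 120))
    stop("hr_profile outside plausible 40-120 bpm range")
  if (any(truth$blink_rate_profile < 0 | truth$blink_rate_profile > 60))
    stop("blink_rate_profile outside plausible 0-60/min range")
  if (any(truth$scl_profile < 0)) stop("scl_profile must be non-negative")
  invisible(truth)
}

#' 1/f (pink) noise via spectral shaping
#' @keywords internal
pink_noise <- function(n, sd = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

#' Raised-cosine blink template (vertical EOG morphology)
#' @param dur_s template duration (s); @param fs sampling rate (Hz).
#' @keywords internal
blink_template <- function(dur_s, fs) {
  n <- round(dur_s * fs)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# fixed per-channel propagation weights of the blink potential
.blink_weights <- c(AFz = 1, AF3 = 0.8, AF4 = 0.8, AF7 = 0.6, AF8 = 0.6,
                    Pz = 0.1, P3 = 0.08, P4 = 0.08)

#' Simulate the 8-channel EEG stream
#'
#' Pink-noise background plus a coherent sinusoidal alpha rhythm at the
#' planted individual alpha frequency (parietal-weighted, amplitude
#' following the per-minute profile, doubled during eyes-closed), blink
#' transients on frontal channels (raised-cosine templates, Poisson
#' arrivals) and injected artifact epochs cycling through the three
#' rejection criterion types (high amplitude, steep ramp, step
#' discontinuity). All planted blink peak times and artifact epochs are
#' recorded in the returned ground truth.
#'
#' @param cfg a \code{fk_simconfig}.
#' @param truth a \code{fk_truth}.
#' @return list(signal = fk_signal, truth = updated fk_truth).
#' @export
simulate_eeg <- function(cfg, truth) {
  validate_ground_truth(truth, cfg)
  set.seed(truth$seed + 1L)
  fs <- 125
  dur <- session_duration(cfg)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  chans <- fk_defaults()$eeg$channels
  pb <- phase_bounds(cfg)

  amp <- profile_at(truth$alpha_amp_profile, t)
  ec <- pb[pb$phase == "EC", ]
  amp[t >= ec$start_s & t < ec$end_s] <-
    amp[t >= ec$start_s & t < ec$end_s] * cfg$ec_alpha_boost
  alpha_src <- amp * sin(2 * pi * truth$iaf_hz * t + stats::runif(1, 0, 2 * pi))

  x <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  parietal <- fk_defaults()$eeg$parietal
  for (ch in chans) {
    w <- if (ch %in% parietal) 1 else cfg$frontal_alpha_frac
    x[, ch] <- pink_noise(n, cfg$eeg_noise_uv) + w * alpha_src
  }

  # blinks: Poisson arrivals per minute, >= 0.4 s apart
  tmpl <- truth$blink_amp_uv * blink_template(truth$blink_dur_s, fs)
  half <- floor(length(tmpl) / 2)
  blink_peaks <- numeric(0)
  for (m in seq_along(truth$blink_rate_profile)) {
    k <- stats::rpois(1, truth$blink_rate_profile[m])
    if (k == 0) next
    tp <- sort(stats::runif(k, (m - 1) * 60 + 0.3, min(m * 60, dur) - 0.3))
    tp <- tp[c(TRUE, diff(tp) > 0.4)]
    blink_peaks <- c(blink_peaks, tp)
  }
  for (tp in blink_peaks) {
    i0 <- round(tp * fs) - half
    idx <- i0:(i0 + length(tmpl) - 1)
    ok <- idx >= 1 & idx <= n
    for (ch in chans)
      x[idx[ok], ch] <- x[idx[ok], ch] + .blink_weights[[ch]] * tmpl[ok]
  }

  # injected artifact epochs (within the monotonous phase), cycling
  # deterministically through the three criterion types
  mono <- pb[pb$phase == "Monotonous", ]
  art <- data.frame(epoch_start_s = numeric(0), type = character(0))
  n_art <- truth$n_artifact_epochs_injected
  if (n_art > 0) {
    cand <- seq(mono$start_s, mono$end_s - 1)          # 1-s epoch starts
    starts <- sort(sample(cand, n_art))
    types <- rep(c("threshold", "trend", "step"), length.out = n_art)
    for (j in seq_len(n_art)) {
      i0 <- round(starts[j] * fs) + 1
      idx <- i0:(i0 + fs - 1)
      seg_t <- (seq_len(fs) - 1) / fs
      corrupt <- switch(types[j],
        threshold = 200 * sin(2 * pi * 5 * seg_t) *
          exp(-((seg_t - 0.5) / 0.15)^2),
        trend = {                    # in-epoch ramp, interior only
          r <- numeric(fs); i <- seg_t >= 0.1 & seg_t < 0.9
          r[i] <- 100 * (seg_t[i] - 0.1) / 0.8; r
        },
        step = c(numeric(fs %/% 2), rep(60, fs - fs %/% 2)))
      x[idx, "P3"] <- x[idx, "P3"] + corrupt
    }
    art <- data.frame(epoch_start_s = starts, type = types,
                      stringsAsFactors = FALSE)
  }

  truth$blink_events <- data.frame(peak_s = blink_peaks)
  truth$artifact_epochs <- art
  list(signal = raw_signal(x, fs, chans, t0 = 0, unit = "uV"),
       truth = truth)
}

#' Simulate the wristband PPG stream
#'
#' An inter-beat-interval series is generated as the base interval
#' 60/HR(t) plus two sinusoidal modulations placed at the centres of the
#' HRV bands (0.095 Hz and 0.275 Hz) whose variances equal the planted
#' \code{lf_power} and \code{hf_power}. Each beat renders a fixed
#' asymmetric pulse template at 64 Hz; beat times are recorded in the
#' ground truth.
#'
#' @inheritParams simulate_eeg
#' @return list(signal, truth) with \code{truth$beat_times_s} and
#'   \code{truth$lf_hf_planted} filled in.
#' @export
simulate_ppg <- function(cfg, truth) {
  if (any(truth$hr_profile < 40 | truth$hr_profile > 120))
    stop("hr_profile outside plausible 40-120 bpm range")
  set.seed(truth$seed + 2L)
  fs <- 64
  dur <- session_duration(cfg)
  a_lf <- sqrt(2 * truth$lf_power)
  a_hf <- sqrt(2 * truth$hf_power)
  ph <- stats::runif(2, 0, 2 * pi)
  beats <- numeric(ceiling(dur * 3))
  tb <- 0.3; k <- 0
  while (tb < dur) {
    k <- k + 1; beats[k] <- tb
    ibi <- 60 / profile_at(truth$hr_profile, tb) +
      a_lf * sin(2 * pi * 0.095 * tb + ph[1]) +
      a_hf * sin(2 * pi * 0.275 * tb + ph[2])
    tb <- tb + ibi
  }
  beats <- beats[seq_len(k)]

  # asymmetric pulse: fast rise (120 ms), slow fall (300 ms)
  rise <- 0.12; fall <- 0.30
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (tb in beats) {
    i <- max(1, ceiling((tb - rise) * fs) + 1):min(n, floor((tb + fall) * fs) + 1)
    td <- (i - 1) / fs - tb
    y[i] <- y[i] + ifelse(td < 0, 0.5 * (1 + cos(pi * td / rise)),
                          0.5 * (1 + cos(pi * td / fall)))
  }
  y <- y + 0.3 * sin(2 * pi * 0.05 * t) +            # slow baseline drift
    stats::rnorm(length(t), 0, cfg$ppg_noise)
  truth$beat_times_s <- beats
  truth$lf_hf_planted <- if (truth$hf_power > 0)
    truth$lf_power / truth$hf_power else NA_real_
  list(signal = raw_signal(y, fs, "PPG", t0 = 0, unit = "a.u."),
       truth = truth)
}

#' Bateman impulse response (electrodermal response shape)
#' @param t time vector (s); @param tau1 rise and @param tau2 decay
#'   constants (s).
#' @keywords internal
bateman <- function(t, tau1 = 0.75, tau2 = 2) {
  h <- exp(-t / tau2) - exp(-t / tau1)
  h[t < 0] <- 0
  h / max(h)
}

#' Simulate the wristband EDA stream
#'
#' Smoothly interpolated tonic level following the per-minute SCL profile
#' plus Poisson-arriving phasic responses shaped by the Bateman kernel
#' (tau1 = 0.75 s, tau2 = 2 s) and white noise, at 4 Hz. The planted
#' tonic per-minute means are recorded in the ground truth.
#'
#' @inheritParams simulate_eeg
#' @return list(signal, truth) with \code{truth$tonic_minute_means}.
#' @export
simulate_eda <- function(cfg, truth) {
  if (any(truth$scl_profile < 0)) stop("scl_profile must be non-negative")
  set.seed(truth$seed + 3L)
  fs <- 4
  dur <- session_duration(cfg)
  t <- (seq_len(round(dur * fs)) - 1) / fs
  centres <- (seq_along(truth$scl_profile) - 0.5) * 60
  tonic <- stats::spline(centres, truth$scl_profile, xout = t)$y
  n_scr <- stats::rpois(1, cfg$phasic_rate_per_min * dur / 60)
  y <- tonic
  if (n_scr > 0) {
    t_scr <- sort(stats::runif(n_scr, 0, dur - 10))
    a_scr <- stats::runif(n_scr, 0.1, 0.3)
    kern_t <- seq(0, 10, by = 1 / fs)
    kern <- bateman(kern_t, 0.75, 2)
    for (j in seq_len(n_scr)) {
      i0 <- round(t_scr[j] * fs) + 1
      idx <- i0:min(i0 + length(kern) - 1, length(y))
      y[idx] <- y[idx] + a_scr[j] * kern[seq_along(idx)]
    }
  }
  y <- y + stats::rnorm(length(y), 0, cfg$eda_noise_us)
  mm <- tapply(tonic, window_of(t, 60), mean)
  truth$tonic_minute_means <- as.numeric(mm)
  list(signal = raw_signal(y, fs, "EDA", t0 = 0, unit = "uS"),
       truth = truth)
}

#' Simulate secondary-task behavior
#'
#' For each alarm in the timeline a button press is generated at
#' alarm time + RT, where RT follows the planted linear trend
#' \code{rt_baseline_s + rt_slope_s_per_alarm * (alarm index - 1)} plus
#' Gaussian noise. The fatigued profile has non-negative slope (slowing),
#' the non-fatigued one a negative slope (practice effect).
#'
#' @param cfg a \code{fk_simconfig}.
#' @param truth a \code{fk_truth}.
#' @param events event table containing the alarm events (from
#'   [make_protocol_timeline()]).
#' @return list(events = button_press event table, rt = data.frame with
#'   alarm id/time/RT, truth = updated ledger).
#' @export
simulate_behavior <- function(cfg, truth, events) {
  set.seed(truth$seed + 4L)
  al <- events[events$kind == "alarm", , drop = FALSE]
  k <- seq_len(nrow(al))
  rt <- truth$rt_baseline_s + truth$rt_slope_s_per_alarm * (k - 1) +
    stats::rnorm(nrow(al), 0, cfg$rt_sigma_s)
  rt <- pmax(rt, 0.15)
  bp <- event_table(al$time_s + rt, rep("button_press", nrow(al)),
                    al$payload)
  truth$rt_draws_s <- rt
  list(events = bp,
       rt = data.frame(alarm_id = al$payload, alarm_time_s = al$time_s,
                       rt_s = rt, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate questionnaire answers
#'
#' Three administrations (Arrival, post_Circuit, post_Monotonous) of the
#' KSS single rating and the six mental-fatigue items. For fatigued
#' profiles the post-monotonous scores are drawn stochastically at or
#' above the arrival scores.
#' @param truth a \code{fk_truth}.
#' @return data.frame(instrument, administration, item, score).
#' @export
simulate_questionnaires <- function(truth) {
  set.seed(truth$seed + 5L)
  adm <- c("Arrival", "post_Circuit", "post_Monotonous")
  fat <- truth$group_label == "fatigued"
  kss0 <- sample(2:4, 1)
  kss <- c(kss0,
           min(9, kss0 + sample(0:2, 1)),
           min(9, kss0 + if (fat) sample(2:4, 1) else sample(0:2, 1)))
  rows <- data.frame(instrument = "KSS", administration = adm,
                     item = 1L, score = kss, stringsAsFactors = FALSE)
  base <- sample(0:1, 1)
  for (a in seq_along(adm)) {
    lev <- min(3, base + if (fat) c(0, 1, 2)[a] else c(0, 1, 1)[a])
    items <- pmin(3, pmax(0, lev + sample(-1:1, 6, replace = TRUE)))
    rows <- rbind(rows, data.frame(instrument = "Chalder_mental",
                                   administration = adm[a],
                                   item = seq_len(6), score = items,
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Simulate one complete session
#'
#' Runs the timeline, EEG, PPG, EDA, behavior and questionnaire
#' simulators in a fixed order, all seeded from \code{truth$seed}, and
#' assembles an \code{fk_session}. Identical seeds give bit-identical
#' sessions.
#'
#' @param cfg a \code{fk_simconfig}.
#' @param truth optional \code{fk_truth}; built with
#'   [default_ground_truth()] if missing.
#' @param group profile used when building a default ground truth.
#' @param modalities subset of \code{c("eeg", "ppg", "eda")} to simulate
#'   (others left NULL); trimming modalities speeds up tests that only
#'   exercise one stream.
#' @return list(session = fk_session, truth = fk_truth).
#' @export
simulate_session <- function(cfg = sim_config(), truth = NULL,
                             group = "fatigued",
                             modalities = c("eeg", "ppg", "eda")) {
  if (is.null(truth)) truth <- default_ground_truth(cfg, group)
  ev <- make_protocol_timeline(cfg)
  eeg <- ppg <- eda <- NULL
  if ("eeg" %in% modalities) {
    r <- simulate_eeg(cfg, truth); eeg <- r$signal; truth <- r$truth
  }
  if ("ppg" %in% modalities) {
    r <- simulate_ppg(cfg, truth); ppg <- r$signal; truth <- r$truth
  }
  if ("eda" %in% modalities) {
    r <- simulate_eda(cfg, truth); eda <- r$signal; truth <- r$truth
  }
  beh <- simulate_behavior(cfg, truth, ev)
  truth <- beh$truth
  qn <- simulate_questionnaires(truth)
  events <- rbind(ev, beh$events)
  events <- events[order(events$time_s), , drop = FALSE]
  ses <- fk_session(eeg = eeg, ppg = ppg, eda = eda, events = events,
                    questionnaires = qn,
                    participant_id = sprintf("P%02d", truth$seed %% 100))
  ses$rt <- beh$rt
  list(session = ses, truth = truth)
}

#' Simulate a cohort of sessions
#'
#' @param n number of participants (>= 2).
#' @param mix fraction of fatigued profiles; \code{ceiling(mix * n)}
#'   participants get the fatigued ground truth.
#' @param seed master seed; participant i uses \code{seed * 1000 + i}.
#' @param cfg a \code{fk_simconfig}.
#' @param modalities passed to [simulate_session()].
#' @return list of \code{list(session, truth)} of length n.
#' @export
simulate_cohort <- function(n, mix = 12 / 26, seed = 1L,
                            cfg = sim_config(),
                            modalities = c("eeg", "ppg", "eda")) {
  if (n < 2) stop("cohort needs at least 2 participants")
  n_fat <- ceiling(mix * n)
  groups <- c(rep("fatigued", n_fat), rep("not_fatigued", n - n_fat))
  lapply(seq_len(n), function(i) {
    tr <- default_ground_truth(cfg, groups[i], seed = seed * 1000L + i)
    out <- simulate_session(cfg, tr, modalities = modalities)
    out$session$participant_id <- sprintf("P%02d", i)
    out
  })
}
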