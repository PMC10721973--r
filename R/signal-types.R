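#' Multichannel uniformly sampled signal
#'
#' The basic container used throughout the package for EEG, PPG and EDA
#' streams: a samples-by-channels numeric matrix plus sampling rate,
#' channel labels, a session-relative start time and a unit tag.
#' Sample \code{i} (1-based) covers the half-open interval
#' \code{[t0 + (i-1)/fs, t0 + i/fs)} seconds.
#'
#' @param data numeric matrix (samples x channels) or vector (one channel).
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to
#'   \code{colnames(data)} or \code{"ch1"}, \code{"ch2"}, ...
#' @param t0 session-relative start time in seconds.
#' @param unit unit tag, e.g. \code{"uV"}, \code{"a.u."}, \code{"uS"}.
#' @return an object of class \code{fk_signal}.
#' @export
raw_signal <- function(data, fs, labels = NULL, t0 = 0, unit = "a.u.") {
  if (is.vector(data)) data <- matrix(as.numeric(data), ncol = 1)
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  }
  stopifnot(length(fs) == 1L, fs > 0)
  if (length(labels) != ncol(data))
    stop("number of labels (", length(labels), ") != number of channels (",
         ncol(data), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  colnames(data) <- labels
  structure(list(data = data, fs = as.numeric(fs),
                 labels = as.character(labels),
                 t0 = as.numeric(t0), unit = unit),
            class = "fk_signal")
}

#' @export
print.fk_signal <- function(x, ...) {
  cat(sprintf("<fk_signal> %d ch x %d samples @ %g Hz (%.1f s), t0 = %.2f s, unit = %s\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs, x$t0, x$unit))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x an \code{fk_signal}.
#' @return duration in seconds (\code{n_samples / fs}).
#' @export
signal_duration <- function(x) nrow(x$data) / x$fs

#' Sample times of a signal
#' @param x an \code{fk_signal}.
#' @return numeric vector of session-relative sample start times (s).
#' @export
signal_times <- function(x) x$t0 + (seq_len(nrow(x$data)) - 1) / x$fs

#' Extract one channel as a numeric vector
#' @param x an \code{fk_signal}.
#' @param label channel name.
#' @return numeric vector of samples.
#' @export
get_channel <- function(x, label) {
  i <- match(label, x$labels)
  if (is.na(i)) stop("channel '", label, "' not found; available: ",
                     paste(x$labels, collapse = ", "))
  x$data[, i]
}

#' Crop a signal to a time window
#'
#' Keeps samples whose start time falls in the half-open window
#' \code{[from, to)} (session-relative seconds) and rebases \code{t0}
#' so the cropped signal starts at 0 relative to \code{from}.
#'
#' @param x an \code{fk_signal}.
#' @param from,to window bounds in session-relative seconds.
#' @return cropped \code{fk_signal} with \code{t0} relative to \code{from}.
#' @export
crop_signal <- function(x, from, to) {
  tt <- signal_times(x)
  keep <- tt >= from - 1e-9 & tt < to - 1e-9
  raw_signal(x$data[keep, , drop = FALSE], x$fs, x$labels,
             t0 = if (any(keep)) tt[which(keep)[1]] - from else 0,
             unit = x$unit)
}

#' Event table constructor
#'
#' @param time_s session-relative event times in seconds.
#' @param kind one of \code{phase_start}, \code{phase_end}, \code{alarm},
#'   \code{button_press} per event.
#' @param payload phase name or alarm id per event.
#' @return a \code{data.frame} with columns \code{time_s}, \code{kind},
#'   \code{payload}, ordered by time.
#' @export
event_table <- function(time_s, kind, payload) {
  kinds <- c("phase_start", "phase_end", "alarm", "button_press")
  if (!all(kind %in% kinds))
    stop("unknown event kind(s): ", paste(setdiff(kind, kinds), collapse = ", "))
  if (any(time_s < 0)) stop("event times must be >= 0")
  ev <- data.frame(time_s = as.numeric(time_s), kind = as.character(kind),
                   payload = as.character(payload), stringsAsFactors = FALSE)
  ev[order(ev$time_s), , drop = FALSE]
}

#' Phase interval lookup
#' @param events an event table.
#' @param phase phase name.
#' @return \code{c(start, end)} in session-relative seconds.
#' @export
phase_interval <- function(events, phase) {
  st <- events$time_s[events$kind == "phase_start" & events$payload == phase]
  en <- events$time_s[events$kind == "phase_end" & events$payload == phase]
  if (length(st) != 1L || length(en) != 1L) {
    avail <- unique(events$payload[events$kind == "phase_start"])
    stop("phase '", phase, "' not found; available phases: ",
         paste(avail, collapse = ", "))
  }
  c(start = st, end = en)
}

#' Recording session container
#'
#' Bundles the three physiological streams, the event timeline, the raw
#' questionnaire answer table and the participant id.
#'
#' @param eeg,ppg,eda \code{fk_signal} streams (PPG/EDA may be NULL for
#'   EEG-only sessions).
#' @param events event table (see [event_table()]).
#' @param questionnaires data.frame with columns \code{instrument},
#'   \code{administration}, \code{item}, \code{score} (may be NULL).
#' @param participant_id identifier string.
#' @return an object of class \code{fk_session}.
#' @export
fk_session <- function(eeg, ppg = NULL, eda = NULL, events,
                       questionnaires = NULL, participant_id = "P01") {
  structure(list(eeg = eeg, ppg = ppg, eda = eda, events = events,
                 questionnaires = questionnaires,
                 participant_id = participant_id),
            class = "fk_session")
}

#' @export
print.fk_session <- function(x, ...) {
  cat("<fk_session>", x$participant_id, "\n")
  for (s in c("eeg", "ppg", "eda"))
    if (!is.null(x[[s]]))
      cat(sprintf("  %s: %d ch @ %g Hz, %.1f s\n", s, ncol(x[[s]]$data),
                  x[[s]]$fs, signal_duration(x[[s]])))
  cat("  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Restrict a session to one protocol phase
#'
#' Crops every stream to the phase's half-open interval
#' \code{[phase_start, phase_end)} and re-expresses event times relative
#' to the phase start. Slicing an already sliced phase again is a no-op
#' in duration.
#'
#' @param session an \code{fk_session}.
#' @param phase phase name (e.g. \code{"EC"}, \code{"EO1"}, \code{"Circuit"},
#'   \code{"EO2"}, \code{"Monotonous"}, \code{"EO3"}).
#' @return an \code{fk_session} restricted to the phase.
#' @export
slice_phase <- function(session, phase) {
  iv <- phase_interval(session$events, phase)
  ev <- session$events
  keep <- ev$time_s >= iv["start"] & ev$time_s <= iv["end"]
  ev <- ev[keep, , drop = FALSE]
  ev$time_s <- ev$time_s - iv["start"]
  out <- session
  for (s in c("eeg", "ppg", "eda"))
    if (!is.null(session[[s]]))
      out[[s]] <- crop_signal(session[[s]], iv["start"], iv["end"])
  out$events <- ev
  out
}
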