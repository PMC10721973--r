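# Session I/O: YAML/JSON manifests, EEG as CSV (one column per channel)
# or EDF, wristband streams as Empatica-style CSV (first row UNIX start
# timestamp, second row sampling rate, then samples), events and
# questionnaires as CSV. Includes a minimal EDF (16-bit) reader/writer
# for the EEG stream.

.required_eeg <- c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")

#' Normalize EEG channel labels to 10-20 names
#'
#' Case-insensitive matching after stripping an \code{"EEG "} prefix.
#' @keywords internal
normalize_labels <- function(labels) {
  canon <- .required_eeg
  cleaned <- sub("^EEG[ _]*", "", trimws(labels), ignore.case = TRUE)
  i <- match(tolower(cleaned), tolower(canon))
  out <- labels
  out[!is.na(i)] <- canon[i[!is.na(i)]]
  out
}

#' Write an Empatica-style CSV (start timestamp, rate, samples)
#' @keywords internal
write_empatica_csv <- function(sig, path, start_unix = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(format(start_unix, nsmall = 6), format(sig$fs)), con)
  writeLines(format(sig$data[, 1], digits = 10, trim = TRUE,
                    scientific = FALSE), con)
}

#' Read an Empatica-style CSV
#' @keywords internal
read_empatica_csv <- function(path, label, unit, t0 = 0) {
  lines <- readLines(path)
  fs <- as.numeric(lines[2])
  raw_signal(as.numeric(lines[-(1:2)]), fs, label, t0, unit)
}

#' Write an EEG recording as a minimal 16-bit EDF file
#'
#' One 1-s data record per second of signal (trailing partial second
#' dropped), physical range from the data, little-endian 16-bit samples.
#'
#' @param sig an \code{fk_signal}.
#' @param path output file.
#' @export
write_edf <- function(sig, path) {
  fs <- round(sig$fs)
  ns <- ncol(sig$data)
  n_rec <- floor(nrow(sig$data) / fs)
  x <- sig$data[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(format(256 + 256 * ns), 8); wr("", 44)
  wr(format(n_rec), 8); wr("1", 8); wr(format(ns), 4)
  for (l in sig$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(sig$unit, 8)
  for (i in seq_len(ns)) wr(format(signif(pmin_[i], 7)), 8)
  for (i in seq_len(ns)) wr(format(signif(pmax_[i], 7)), 8)
  for (i in seq_len(ns)) wr(format(dmin), 8)
  for (i in seq_len(ns)) wr(format(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(format(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  pmin_r <- as.numeric(signif(pmin_, 7)); pmax_r <- as.numeric(signif(pmax_, 7))
  gain <- (pmax_r - pmin_r) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[rows, i] - pmin_r[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file into an fk_signal
#'
#' Supports standard continuous 16-bit EDF with equal sampling rates
#' across channels. Channel labels are normalized to 10-20 names
#' (case-insensitive, \code{"EEG "} prefixes stripped).
#'
#' @param path EDF file.
#' @param t0 session-relative start time (s).
#' @param unit unit tag for the output.
#' @return an \code{fk_signal}.
#' @export
read_edf <- function(path, t0 = 0, unit = "uV") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("EDF with mixed per-channel rates not supported")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      x[((r - 1) * spr[i] + 1):(r * spr[i]), i] <-
        pmin_[i] + gain[i] * (dig - dmin[i])
    }
  }
  raw_signal(x, spr[1] / rec_dur, normalize_labels(labels), t0, unit)
}

#' Write a session (and optional ground truth) to a directory
#'
#' Emits \code{eeg.csv} (or \code{eeg.edf}), Empatica-style
#' \code{ppg.csv}/\code{eda.csv}, \code{events.csv},
#' \code{questionnaires.csv}, a YAML \code{manifest.yaml} and, when a
#' ground truth is supplied, \code{ground_truth.json}.
#'
#' @param session an \code{fk_session}.
#' @param dir output directory (created if needed).
#' @param truth optional \code{fk_truth} ledger.
#' @param eeg_format \code{"csv"} or \code{"edf"}.
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir, truth = NULL,
                          eeg_format = c("csv", "edf")) {
  eeg_format <- match.arg(eeg_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(participant_id = session$participant_id)
  if (!is.null(session$eeg)) {
    if (eeg_format == "csv") {
      f <- "eeg.csv"
      utils::write.csv(as.data.frame(session$eeg$data),
                       file.path(dir, f), row.names = FALSE)
    } else {
      f <- "eeg.edf"
      write_edf(session$eeg, file.path(dir, f))
    }
    man$eeg <- list(file = f, format = eeg_format, fs = session$eeg$fs,
                    t0 = session$eeg$t0)
  }
  for (s in c("ppg", "eda")) {
    if (is.null(session[[s]])) next
    f <- paste0(s, ".csv")
    write_empatica_csv(session[[s]], file.path(dir, f))
    man[[s]] <- list(file = f, fs = session[[s]]$fs, t0 = session[[s]]$t0)
  }
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  man$events <- "events.csv"
  if (!is.null(session$questionnaires)) {
    utils::write.csv(session$questionnaires,
                     file.path(dir, "questionnaires.csv"),
                     row.names = FALSE)
    man$questionnaires <- "questionnaires.csv"
  }
  if (!is.null(session$rt)) {
    utils::write.csv(session$rt, file.path(dir, "rt.csv"),
                     row.names = FALSE)
    man$rt <- "rt.csv"
  }
  if (!is.null(truth)) {
    tr <- truth
    class(tr) <- NULL
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Load a session from a manifest
#'
#' Reads the streams listed in a YAML or JSON manifest, normalizes the
#' EEG channel labels to the 10-20 names, validates that all eight
#' required EEG channels are present and that sampling rates match the
#' manifest, and checks that every stream fully overlaps the monotonous
#' phase when one is defined.
#'
#' @param manifest_path path to \code{manifest.yaml} / \code{.json}.
#' @return an \code{fk_session}.
#' @export
load_session <- function(manifest_path) {
  man <- if (grepl("\\.json$", manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  eeg <- ppg <- eda <- NULL
  if (!is.null(man$eeg)) {
    f <- file.path(dir, man$eeg$file)
    if (identical(man$eeg$format, "edf")) {
      eeg <- read_edf(f, t0 = man$eeg$t0 %||% 0)
    } else {
      df <- utils::read.csv(f, check.names = FALSE)
      eeg <- raw_signal(as.matrix(df), man$eeg$fs,
                        normalize_labels(names(df)),
                        t0 = man$eeg$t0 %||% 0, unit = "uV")
    }
    eeg$labels <- normalize_labels(eeg$labels)
    colnames(eeg$data) <- eeg$labels
    extra <- setdiff(eeg$labels, .required_eeg)
    if (length(extra)) {
      message("ignoring extra EEG channel(s): ",
              paste(extra, collapse = ", "))
      keep <- eeg$labels %in% .required_eeg
      eeg <- raw_signal(eeg$data[, keep, drop = FALSE], eeg$fs,
                        eeg$labels[keep], eeg$t0, eeg$unit)
    }
    miss <- setdiff(.required_eeg, eeg$labels)
    if (length(miss))
      stop("missing required EEG channel(s): ",
           paste(miss, collapse = ", "))
    if (!is.null(man$eeg$fs) && abs(eeg$fs - man$eeg$fs) > 1e-6)
      stop("EEG sampling rate ", eeg$fs,
           " Hz does not match manifest (", man$eeg$fs, " Hz)")
  }
  if (!is.null(man$ppg))
    ppg <- read_empatica_csv(file.path(dir, man$ppg$file), "PPG", "a.u.",
                             t0 = man$ppg$t0 %||% 0)
  if (!is.null(man$eda))
    eda <- read_empatica_csv(file.path(dir, man$eda$file), "EDA", "uS",
                             t0 = man$eda$t0 %||% 0)
  for (nm in c("ppg", "eda")) {
    s <- get(nm); m <- man[[nm]]
    if (!is.null(s) && !is.null(m$fs) && abs(s$fs - m$fs) > 1e-6)
      stop(toupper(nm), " sampling rate ", s$fs,
           " Hz does not match manifest (", m$fs, " Hz)")
  }
  events <- utils::read.csv(file.path(dir, man$events),
                            stringsAsFactors = FALSE)
  events <- event_table(events$time_s, events$kind, events$payload)
  qn <- if (!is.null(man$questionnaires))
    utils::read.csv(file.path(dir, man$questionnaires),
                    stringsAsFactors = FALSE) else NULL
  ses <- fk_session(eeg, ppg, eda, events, qn,
                    participant_id = man$participant_id %||% "P01")
  if (!is.null(man$rt))
    ses$rt <- utils::read.csv(file.path(dir, man$rt),
                              stringsAsFactors = FALSE)
  # streams must cover the monotonous phase entirely
  if ("Monotonous" %in% events$payload) {
    iv <- phase_interval(events, "Monotonous")
    for (nm in c("eeg", "ppg", "eda")) {
      s <- ses[[nm]]
      if (is.null(s)) next
      if (s$t0 > iv["start"] + 1e-6 ||
          s$t0 + signal_duration(s) < iv["end"] - 1e-6)
        stop(nm, " stream does not cover the Monotonous phase")
    }
  }
  ses
}

`%||%` <- function(a, b) if (is.null(a)) b else a
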