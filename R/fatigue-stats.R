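# Statistical stage: questionnaire scoring, per-participant feature
# normalization and 3 x 15-min segmentation, RT-based group split,
# Shapiro-Wilk-gated repeated-measures tests (RM-ANOVA / Friedman),
# Holm-corrected pairwise post-hocs, and the Segments x Group analysis.

#' Score questionnaire answers
#'
#' KSS: a single sleepiness rating per administration, validated to the
#' 1--9 scale. Chalder mental subscale: the sum of six items each scored
#' 0--3 (range 0--18). Every instrument must appear in all three
#' administrations (Arrival, post_Circuit, post_Monotonous).
#'
#' @param answers data.frame(instrument, administration, item, score).
#' @return data.frame(instrument, administration, score).
#' @export
score_questionnaires <- function(answers) {
  cfg <- fk_defaults()$analysis
  out <- data.frame(instrument = character(0), administration = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  for (inst in unique(answers$instrument)) {
    a <- answers[answers$instrument == inst, , drop = FALSE]
    missing_adm <- setdiff(cfg$administrations, a$administration)
    if (length(missing_adm))
      stop("instrument ", inst, " missing administration(s): ",
           paste(missing_adm, collapse = ", "))
    for (adm in cfg$administrations) {
      s <- a$score[a$administration == adm]
      if (inst == "KSS") {
        if (length(s) != 1 || s < cfg$kss_range[1] || s > cfg$kss_range[2] ||
            s != round(s))
          stop("KSS score must be a single integer in [",
               cfg$kss_range[1], ", ", cfg$kss_range[2], "], got ",
               paste(s, collapse = ","))
        sc <- s
      } else if (inst == "Chalder_mental") {
        if (length(s) != cfg$chalder_n_items)
          stop("Chalder mental subscale needs ", cfg$chalder_n_items,
               " items, got ", length(s))
        if (any(s < cfg$chalder_item_range[1] |
                s > cfg$chalder_item_range[2]))
          stop("Chalder item score out of [",
               cfg$chalder_item_range[1], ", ",
               cfg$chalder_item_range[2], "]")
        sc <- sum(s)
      } else stop("unknown instrument: ", inst)
      out <- rbind(out, data.frame(instrument = inst, administration = adm,
                                   score = sc, stringsAsFactors = FALSE))
    }
  }
  out
}

#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Assemble the per-segment cohort feature table
#'
#' For each participant the monotonous-phase feature series are reduced
#' to three segment means (segments of \code{segment_min} minutes).
#' Before averaging, RT, EBR, EBD, EBA, HR and LF/HF are z-scored across
#' the participant's own monotonous-phase values; MDrow passes through
#' unscaled (it is already baseline-normalized and comparable between
#' participants) and SCL is only session-min-max normalized upstream.
#' Invalid windows are skipped; a segment with more than 50\% invalid
#' windows is marked invalid (NA).
#'
#' @param features named list, one entry per participant, each a named
#'   list of per-window series: data.frames with
#'   \code{window_start_s}/\code{value} (and optional
#'   \code{valid_flag}) for \code{mdrow}, \code{ebr}, \code{ebd},
#'   \code{eba}, \code{hr}, \code{scl}; \code{lfhf} may instead be a
#'   length-3 per-segment vector; \code{rt} a vector of per-alarm RTs
#'   in chronological order.
#' @param n_segments number of segments (default 3).
#' @param segment_min segment length in minutes (default 15).
#' @return a \code{CohortTable} data.frame(participant, feature,
#'   segment, value).
#' @export
build_feature_table <- function(features, n_segments = 3,
                                segment_min = 15) {
  zfeat <- c("rt", "ebr", "ebd", "eba", "hr", "lfhf")
  rows <- list()
  for (pid in names(features)) {
    fl <- features[[pid]]
    for (fname in names(fl)) {
      fx <- fl[[fname]]
      if (fname == "rt") {
        v <- zscore(as.numeric(fx))
        seg <- ceiling(n_segments * seq_along(v) / length(v))
        segmean <- tapply(v, seg, mean, na.rm = TRUE)
      } else if (is.atomic(fx) && length(fx) == n_segments) {
        segmean <- if (fname %in% zfeat) zscore(as.numeric(fx))
                   else as.numeric(fx)
      } else {
        val <- fx$value
        if (!is.null(fx$valid_flag)) val[!fx$valid_flag] <- NA
        if (fname %in% zfeat) {
          ok <- !is.na(val)
          val[ok] <- zscore(val[ok])
        }
        seg <- floor(fx$window_start_s / (segment_min * 60)) + 1L
        seg[seg > n_segments] <- n_segments
        segmean <- vapply(seq_len(n_segments), function(s) {
          v <- val[seg == s]
          if (!length(v) || mean(is.na(v)) > 0.5) NA_real_
          else mean(v, na.rm = TRUE)
        }, numeric(1))
      }
      sv <- rep(NA_real_, n_segments)
      if (is.null(names(segmean))) {
        sv[seq_along(segmean)] <- as.numeric(segmean)
      } else {
        sv[as.integer(names(segmean))] <- as.numeric(segmean)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, feature = fname,
        segment = seq_len(n_segments), value = sv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Split participants into fatigued / non-fatigued groups by RT trend
#'
#' For each participant, Delta = z-scored RT mean of the third segment
#' minus that of the first. Delta > 0 (slowing over the task) assigns
#' Group 1 (fatigued); Delta <= 0 assigns Group 2 (not fatigued) --
#' only strictly positive differences count as fatigued, and exact ties
#' are logged. Participants missing an RT segment are excluded with a
#' warning.
#'
#' @param table a CohortTable from [build_feature_table()].
#' @return data.frame(participant, delta_zrt, group) with group
#'   \code{"fatigued"} / \code{"not_fatigued"}.
#' @export
split_groups <- function(table) {
  rt <- table[table$feature == "rt", , drop = FALSE]
  out <- data.frame(participant = character(0), delta_zrt = numeric(0),
                    group = character(0), stringsAsFactors = FALSE)
  for (pid in unique(rt$participant)) {
    v1 <- rt$value[rt$participant == pid & rt$segment == 1]
    v3 <- rt$value[rt$participant == pid & rt$segment == 3]
    if (!length(v1) || !length(v3) || is.na(v1) || is.na(v3)) {
      warning("participant ", pid, " missing an RT segment; excluded")
      next
    }
    d <- v3 - v1
    if (d == 0) message("participant ", pid,
                        ": RT difference exactly 0; assigned not_fatigued")
    out <- rbind(out, data.frame(
      participant = pid, delta_zrt = d,
      group = if (d > 0) "fatigued" else "not_fatigued",
      stringsAsFactors = FALSE))
  }
  out
}

#' @keywords internal
wide_segments <- function(table, feature) {
  tb <- table[table$feature == feature, , drop = FALSE]
  wide <- stats::reshape(tb[, c("participant", "segment", "value")],
                         idvar = "participant", timevar = "segment",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m[stats::complete.cases(m), , drop = FALSE]
}

#' One-way repeated-measures ANOVA via the multivariate linear model
#'
#' Returns the univariate F test of the within factor with
#' Greenhouse-Geisser correction and Mauchly's sphericity test.
#' @keywords internal
rm_anova <- function(m) {
  fit <- stats::lm(m ~ 1)
  av <- stats::anova(fit, X = ~1, test = "Spherical")
  mt <- tryCatch(stats::mauchly.test(fit, X = ~1),
                 error = function(e) list(p.value = NA_real_))
  list(F = av$F[1], df1 = av[["num Df"]][1], df2 = av[["den Df"]][1],
       p = av[["Pr(>F)"]][1], p_gg = av[["G-G Pr"]][1],
       gg_eps = attr(av, "epsilon")[1], mauchly_p = mt$p.value)
}

#' Omnibus within-subject test over the three segments
#'
#' Normality of the segment distributions is checked with Shapiro-Wilk
#' at alpha = 0.05 (the parametric branch requires all three segments to
#' pass). Normal data get a one-way repeated-measures ANOVA (with
#' Greenhouse-Geisser-corrected p used when Mauchly's sphericity test
#' fails); otherwise the Friedman test. Questionnaire-type outcomes are
#' always analysed non-parametrically.
#'
#' @param table a CohortTable.
#' @param feature feature name.
#' @param force_nonparametric set TRUE for questionnaire scores.
#' @param alpha significance level for the normality gate.
#' @return a TestResult list: feature, design, test, statistic, df,
#'   p_raw (plus parametric details when applicable).
#' @export
omnibus_within <- function(table, feature, force_nonparametric = FALSE,
                           alpha = 0.05) {
  m <- wide_segments(table, feature)
  if (nrow(m) < 3) stop("need at least 3 complete participants, got ",
                        nrow(m))
  normal <- !force_nonparametric &&
    all(apply(m, 2, function(col) {
      if (stats::sd(col) == 0) return(FALSE)
      stats::shapiro.test(col)$p.value > alpha
    }))
  if (normal) {
    ra <- rm_anova(m)
    use_gg <- is.finite(ra$mauchly_p) && ra$mauchly_p < alpha
    res <- list(feature = feature, design = "within", test = "RM-ANOVA",
                statistic = ra$F, df = c(ra$df1, ra$df2),
                p_raw = if (use_gg) ra$p_gg else ra$p,
                p_uncorrected = ra$p, p_gg = ra$p_gg,
                gg_applied = use_gg, mauchly_p = ra$mauchly_p,
                parametric = TRUE, n = nrow(m))
  } else {
    if (all(apply(m, 1, function(r) diff(range(r)) == 0))) {
      # no within-subject variation at all: null result by definition
      res <- list(feature = feature, design = "within",
                  test = "Friedman", statistic = 0,
                  df = ncol(m) - 1, p_raw = 1, parametric = FALSE,
                  n = nrow(m))
    } else {
      fr <- stats::friedman.test(m)
      res <- list(feature = feature, design = "within", test = "Friedman",
                  statistic = unname(fr$statistic),
                  df = unname(fr$parameter), p_raw = fr$p.value,
                  parametric = FALSE, n = nrow(m))
    }
  }
  class(res) <- "fk_test"
  res
}

#' Holm (step-down Bonferroni) adjustment
#'
#' p values sorted ascending; adjusted p_i = max over j <= i of
#' min(1, (m - j + 1) p_(j)), reported in the original order. Adjusted
#' values are never below the raw ones and preserve their ordering.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values in the input order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Holm-corrected pairwise post-hoc contrasts
#'
#' Gated on a significant omnibus test: otherwise the contrast table is
#' empty. The three segment pairs (1-2, 1-3, 2-3) are compared with a
#' paired t test on the parametric branch and a Wilcoxon signed-rank
#' test otherwise, and the p values are Holm-corrected.
#'
#' @param table a CohortTable.
#' @param feature feature name.
#' @param omnibus TestResult from [omnibus_within()] (or a compatible
#'   list with \code{p_raw} and \code{parametric}).
#' @param alpha omnibus significance gate.
#' @return the omnibus TestResult with a \code{contrasts} data.frame
#'   (pair, statistic, p_raw, p_holm) attached.
#' @export
posthoc_pairwise_holm <- function(table, feature, omnibus, alpha = 0.05) {
  res <- omnibus
  res$contrasts <- data.frame(pair = character(0), statistic = numeric(0),
                              p_raw = numeric(0), p_holm = numeric(0),
                              stringsAsFactors = FALSE)
  if (!is.finite(omnibus$p_raw) || omnibus$p_raw >= alpha) return(res)
  m <- wide_segments(table, feature)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  stat <- praw <- numeric(3)
  for (i in seq_along(pairs)) {
    a <- m[, pairs[[i]][1]]; b <- m[, pairs[[i]][2]]
    if (isTRUE(omnibus$parametric)) {
      tt <- stats::t.test(a, b, paired = TRUE)
      stat[i] <- unname(tt$statistic); praw[i] <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                exact = FALSE))
      stat[i] <- unname(wt$statistic); praw[i] <- wt$p.value
    }
  }
  res$contrasts <- data.frame(
    pair = vapply(pairs, function(p) paste(p, collapse = "-"),
                  character(1)),
    statistic = stat, p_raw = praw, p_holm = holm_adjust(praw),
    stringsAsFactors = FALSE)
  res
}

#' Mixed-design Segments x Group analysis
#'
#' Parametric branch: a mixed ANOVA with Segments within and Group
#' between participants (classic split-plot sums of squares), reporting
#' the interaction term. Non-parametric branch: no interaction test is
#' possible; each group gets its own Friedman omnibus with
#' Holm-corrected Wilcoxon post-hocs instead.
#'
#' @param table a CohortTable.
#' @param feature feature name.
#' @param groups data.frame(participant, group) from [split_groups()].
#' @param force_nonparametric set TRUE to skip the normality gate.
#' @param alpha significance level.
#' @return TestResult: for the parametric branch, the interaction F/p
#'   (\code{design = "interaction"}); otherwise
#'   \code{per_group} TestResults (\code{design = "per_group"}).
#' @export
interaction_anova <- function(table, feature, groups,
                              force_nonparametric = FALSE, alpha = 0.05) {
  m <- wide_segments(table, feature)
  g <- groups$group[match(rownames(m), groups$participant)]
  keep <- !is.na(g)
  m <- m[keep, , drop = FALSE]; g <- factor(g[keep])
  if (any(table(g) < 2)) stop("each group needs at least 2 members")
  normal <- !force_nonparametric &&
    all(apply(m, 2, function(col) {
      if (stats::sd(col) == 0) return(FALSE)
      stats::shapiro.test(col)$p.value > alpha
    }))
  if (normal) {
    n <- nrow(m); k <- ncol(m)
    long <- data.frame(
      value = as.vector(m),
      segment = factor(rep(seq_len(k), each = n)),
      participant = factor(rep(rownames(m), k)),
      group = factor(rep(as.character(g), k)))
    av <- stats::aov(value ~ group * segment +
                       Error(participant / segment), data = long)
    s <- summary(av)
    within_tab <- s[["Error: participant:segment"]][[1]]
    ia <- within_tab["group:segment", ]
    res <- list(feature = feature, design = "interaction",
                test = "mixed-ANOVA",
                statistic = ia[["F value"]],
                df = c(ia[["Df"]],
                       within_tab["Residuals", "Df"]),
                p_raw = ia[["Pr(>F)"]], parametric = TRUE,
                n = n, groups = table(g))
  } else {
    per <- lapply(levels(g), function(lev) {
      sub <- table[table$feature == feature &
                     table$participant %in% rownames(m)[g == lev], ,
                   drop = FALSE]
      om <- omnibus_within(sub, feature, force_nonparametric = TRUE)
      posthoc_pairwise_holm(sub, feature, om, alpha)
    })
    names(per) <- levels(g)
    res <- list(feature = feature, design = "per_group",
                test = "per-group Friedman", parametric = FALSE,
                per_group = per, n = nrow(m), groups = table(g))
  }
  class(res) <- "fk_test"
  res
}

#' @export
print.fk_test <- function(x, ...) {
  if (!is.null(x$per_group)) {
    cat(sprintf("<fk_test> %s [%s]: per-group analysis\n", x$feature,
                x$test))
    for (g in names(x$per_group)) {
      pg <- x$per_group[[g]]
      cat(sprintf("  %s: %s = %.3f, p = %.4g\n", g, pg$test,
                  pg$statistic, pg$p_raw))
    }
  } else {
    cat(sprintf("<fk_test> %s [%s, %s]: stat = %.3f, p = %.4g\n",
                x$feature, x$design, x$test, x$statistic, x$p_raw))
  }
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("  contrasts:\n")
    for (i in seq_len(nrow(x$contrasts)))
      cat(sprintf("    %s: p_holm = %.4g\n", x$contrasts$pair[i],
                  x$contrasts$p_holm[i]))
  }
  invisible(x)
}
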