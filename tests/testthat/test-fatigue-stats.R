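# Questionnaire scoring, feature-table assembly, group split and the
# repeated-measures statistical procedure.

mk_answers <- function(kss = c(3, 5, 7), chalder_level = 1) {
  adm <- c("Arrival", "post_Circuit", "post_Monotonous")
  rbind(
    data.frame(instrument = "KSS", administration = adm, item = 1L,
               score = kss),
    do.call(rbind, lapply(seq_along(adm), function(a)
      data.frame(instrument = "Chalder_mental", administration = adm[a],
                 item = 1:6, score = rep(chalder_level, 6)))))
}

test_that("questionnaire scoring validates and sums correctly", {
  sc <- score_questionnaires(mk_answers(kss = c(3, 5, 9),
                                        chalder_level = 3))
  expect_equal(sc$score[sc$instrument == "KSS"], c(3, 5, 9))
  expect_equal(sc$score[sc$instrument == "Chalder_mental"], rep(18, 3))
  expect_error(score_questionnaires(mk_answers(kss = c(0, 5, 7))), "KSS")
  bad <- mk_answers(); bad$score[bad$instrument == "Chalder_mental"][1] <- 4
  expect_error(score_questionnaires(bad), "Chalder")
  missing <- mk_answers()
  missing <- missing[missing$administration != "post_Circuit", ]
  expect_error(score_questionnaires(missing), "post_Circuit")
})

test_that("feature assembly z-scores, segments and spares MDrow", {
  win <- data.frame(window_start_s = (0:44) * 60, value = NA_real_)
  const <- win; const$value <- 5
  lin <- win; lin$value <- 0:44
  md <- win; md$value <- 1 + (0:44) / 10
  feats <- list(P1 = list(hr = const, ebr = lin, mdrow = md,
                          rt = c(0.8, 0.8, 0.8)))
  tb <- build_feature_table(feats)
  expect_equal(tb$value[tb$feature == "hr"], rep(0, 3))
  # z-score of 0..44: closed form sd = sqrt(45*46/12)/sqrt(44)... use R
  z <- (0:44 - 22) / stats::sd(0:44)
  seg <- rep(1:3, each = 15)
  expect_equal(tb$value[tb$feature == "ebr"],
               as.numeric(tapply(z, seg, mean)))
  # strictly increasing and symmetric about zero
  v <- tb$value[tb$feature == "ebr"]
  expect_true(all(diff(v) > 0))
  expect_equal(v[2], 0)
  expect_equal(v[1], -v[3])
  # MDrow untouched by any scaling
  expect_equal(tb$value[tb$feature == "mdrow"],
               as.numeric(tapply(md$value, seg, mean)))
})

test_that("segments with mostly invalid windows become NA", {
  win <- data.frame(window_start_s = (0:44) * 60, value = rnorm(45),
                    valid_flag = TRUE)
  win$valid_flag[16:27] <- FALSE      # 12/15 invalid in segment 2
  tb <- build_feature_table(list(P1 = list(hr = win)))
  expect_true(is.na(tb$value[tb$feature == "hr" & tb$segment == 2]))
  expect_false(anyNA(tb$value[tb$feature == "hr" & tb$segment != 2]))
})

test_that("the RT group split follows the sign rule", {
  tb <- data.frame(
    participant = rep(c("A", "B", "C"), each = 3),
    feature = "rt", segment = rep(1:3, 3),
    value = c(-0.2, 0, 0.2,   0.1, 0, -0.1,   0.3, 0.1, 0.3))
  g <- split_groups(tb)
  expect_equal(g$group, c("fatigued", "not_fatigued", "not_fatigued"))
  expect_equal(g$delta_zrt, c(0.4, -0.2, 0))
  # a participant with a missing segment is excluded with a warning
  tb2 <- tb; tb2$value[tb2$participant == "B" & tb2$segment == 3] <- NA
  expect_warning(g2 <- split_groups(tb2), "excluded")
  expect_equal(g2$participant, c("A", "C"))
})

test_that("planted RT slopes drive the group split reliably", {
  cfg <- sim_config()
  ev <- make_protocol_timeline(cfg)
  hits <- 0; total <- 0
  for (seed in 1:50) {
    feats <- list()
    labels <- character(0)
    for (i in 1:6) {
      grp <- if (i <= 3) "fatigued" else "not_fatigued"
      tr <- default_ground_truth(cfg, grp, seed = seed * 100 + i)
      feats[[paste0("P", i)]] <-
        list(rt = simulate_behavior(cfg, tr, ev)$rt$rt_s)
      labels <- c(labels, grp)
    }
    g <- split_groups(build_feature_table(feats))
    hits <- hits + sum(g$group == labels)
    total <- total + length(labels)
  }
  expect_gte(hits / total, 0.9)
})

test_that("identical repeated measures yield a null Friedman result", {
  tb <- data.frame(participant = rep(c("A", "B", "C", "D"), each = 3),
                   feature = "hr", segment = rep(1:3, 4),
                   value = rep(c(1, 2, 3, 4), each = 3))
  res <- omnibus_within(tb, "hr", force_nonparametric = TRUE)
  expect_equal(res$test, "Friedman")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  expect_error(omnibus_within(tb[1:6, ], "hr"), "3 complete")
})

test_that("RM-ANOVA matches the sums-of-squares oracle to 6 decimals", {
  set.seed(14)
  m <- matrix(rnorm(12), 4, 3) + outer(rnorm(4), c(0, 0.5, 1), "+")
  tb <- data.frame(participant = rep(letters[1:4], 3),
                   feature = "hr",
                   segment = rep(1:3, each = 4),
                   value = as.vector(m))
  res <- omnibus_within(tb, "hr")
  expect_equal(res$test, "RM-ANOVA")
  oracle <- rm_anova_oracle(m)
  expect_equal(res$statistic, oracle$F, tolerance = 1e-6)
  expect_equal(res$p_uncorrected, oracle$p, tolerance = 1e-6)
})

test_that("Holm adjustment equals its definitional oracle", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.20)), c(0.03, 0.04, 0.20))
  set.seed(15)
  for (i in 1:200) {
    p <- runif(3)
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_equal(adj, stats::p.adjust(p, "holm"))
    expect_true(all(adj >= p))
    # weakly order-preserving (capping at 1 can create ties)
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  }
})

test_that("post-hocs are gated on the omnibus and Holm-corrected", {
  set.seed(16)
  n <- 10
  m <- cbind(rnorm(n), rnorm(n) + 1.5, rnorm(n) + 1.6)
  tb <- data.frame(participant = rep(sprintf("p%02d", 1:n), 3),
                   feature = "hr", segment = rep(1:3, each = n),
                   value = as.vector(m))
  om <- omnibus_within(tb, "hr")
  res <- posthoc_pairwise_holm(tb, "hr", om)
  expect_equal(nrow(res$contrasts), 3)
  expect_equal(res$contrasts$p_holm,
               holm_oracle(res$contrasts$p_raw))
  # contrast p-values match the underlying paired test
  i12 <- which(res$contrasts$pair == "1-2")
  expect_equal(res$contrasts$p_raw[i12],
               stats::t.test(m[, 1], m[, 2], paired = TRUE)$p.value)
  # non-significant omnibus -> no contrasts
  gated <- posthoc_pairwise_holm(tb, "hr",
                                 list(p_raw = 0.3, parametric = TRUE))
  expect_equal(nrow(gated$contrasts), 0)
})

test_that("mixed-ANOVA interaction matches the split-plot oracle", {
  set.seed(6)
  n <- 8
  g <- rep(c("fatigued", "not_fatigued"), each = n / 2)
  m <- matrix(rnorm(n * 3, sd = 0.5), n, 3)
  m[g == "fatigued", ] <- m[g == "fatigued", ] +
    matrix(rep(c(0, 1, 2), each = n / 2), n / 2, 3)
  m[g == "not_fatigued", ] <- m[g == "not_fatigued", ] +
    matrix(rep(c(2, 1, 0), each = n / 2), n / 2, 3)
  ids <- sprintf("p%02d", 1:n)
  tb <- data.frame(participant = rep(ids, 3), feature = "rt",
                   segment = rep(1:3, each = n), value = as.vector(m))
  groups <- data.frame(participant = ids, group = g)
  res <- interaction_anova(tb, "rt", groups)
  expect_equal(res$design, "interaction")
  oracle <- mixed_anova_oracle(m, g)
  expect_equal(res$statistic, oracle$F, tolerance = 1e-6)
  expect_equal(res$p_raw, oracle$p, tolerance = 1e-6)
  expect_error(interaction_anova(tb, "rt",
                                 data.frame(participant = ids,
                                            group = c("a", rep("b", 7)))),
               "at least 2")
})

test_that("matched group profiles produce no interaction", {
  set.seed(18)
  n <- 12
  m <- outer(rnorm(n), rep(1, 3)) +
    matrix(rep(c(0, 0.5, 1), each = n), n, 3) +
    matrix(rnorm(n * 3, sd = 0.3), n, 3)
  ids <- sprintf("p%02d", 1:n)
  tb <- data.frame(participant = rep(ids, 3), feature = "rt",
                   segment = rep(1:3, each = n), value = as.vector(m))
  groups <- data.frame(participant = ids,
                       group = rep(c("fatigued", "not_fatigued"),
                                   each = n / 2))
  res <- interaction_anova(tb, "rt", groups)
  expect_gt(res$p_raw, 0.05)
})

test_that("the non-parametric branch analyses each group separately", {
  set.seed(19)
  n <- 10
  # exponential data fail Shapiro-Wilk -> per-group Friedman branch
  m <- cbind(rexp(n), rexp(n) + 2, rexp(n) + 2.2)^2
  ids <- sprintf("p%02d", 1:n)
  tb <- data.frame(participant = rep(ids, 3), feature = "mdrow",
                   segment = rep(1:3, each = n), value = as.vector(m))
  groups <- data.frame(participant = ids,
                       group = rep(c("fatigued", "not_fatigued"),
                                   each = n / 2))
  res <- interaction_anova(tb, "mdrow", groups)
  expect_equal(res$design, "per_group")
  expect_named(res$per_group, c("fatigued", "not_fatigued"))
  expect_equal(res$per_group$fatigued$test, "Friedman")
})

test_that("questionnaires always take the non-parametric branch", {
  set.seed(20)
  tb <- data.frame(participant = rep(sprintf("p%02d", 1:8), 3),
                   feature = "KSS", segment = rep(1:3, each = 8),
                   value = c(rnorm(8, 3), rnorm(8, 5), rnorm(8, 7)))
  res <- omnibus_within(tb, "KSS", force_nonparametric = TRUE)
  expect_equal(res$test, "Friedman")
})
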