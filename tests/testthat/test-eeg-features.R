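# EEG stage: filters, epoching, three-criterion screening, IAF,
# strict-alpha GFP, blink removal and the MDrow index.

fs <- 125
tsec <- function(s) (0:(s * fs - 1)) / fs

test_that("preprocessing notches the mains and keeps the passband", {
  t <- tsec(60)
  out50 <- preprocess_eeg(mk_eeg(sin(2 * pi * 50 * t)))
  expect_lt(stats::sd(out50$data[, 1]) / stats::sd(sin(2 * pi * 50 * t)),
            0.05)
  out10 <- preprocess_eeg(mk_eeg(sin(2 * pi * 10 * t)))
  expect_equal(stats::sd(out10$data[, 1]),
               stats::sd(sin(2 * pi * 10 * t)), tolerance = 0.05)
  out05 <- preprocess_eeg(mk_eeg(sin(2 * pi * 0.5 * t)))
  expect_lt(stats::sd(out05$data[, 1]) / stats::sd(sin(2 * pi * 0.5 * t)),
            0.10)
  expect_equal(nrow(out10$data), length(t))
  expect_error(preprocess_eeg(mk_eeg(rnorm(fs))), "settling")
})

test_that("epoching floors to whole seconds with k-second start times", {
  sig <- mk_eeg(rnorm(round(60.7 * fs)))
  es <- epoch_signal(sig)
  expect_equal(es$n_epochs, 60)
  expect_equal(es$epoch_len, fs)
  expect_equal(es$start_s, 0:59)
  expect_equal(epoch_signal(mk_eeg(rnorm(fs)))$n_epochs, 1)
  expect_error(epoch_signal(mk_eeg(rnorm(fs - 1))), "at least")
})

test_that("the three screening criteria fire as specified", {
  z <- numeric(fs)
  spike <- z; spike[40] <- 100
  ramp <- seq(0, 30, length.out = fs)
  x <- rbind(matrix(rep(z, 8), ncol = 8),
             matrix(rep(spike, 8), ncol = 8),
             matrix(rep(ramp, 8), ncol = 8))
  es <- flag_artifacts(epoch_signal(
    raw_signal(x, fs, fk_defaults()$eeg$channels, unit = "uV")))
  expect_true(es$mask[1])                       # all-zero epoch kept
  expect_false(es$mask[2])
  expect_true("threshold" %in% es$reasons[[2]]) # 100 uV > 80
  expect_true("step" %in% es$reasons[[2]])      # 100 uV jump > 25
  expect_false(es$mask[3])
  expect_equal(es$reasons[[3]], "trend")        # 30 uV/s slope only
  expect_equal(attr(es, "data_loss"), 2 / 3)
})

test_that("screening agrees with a brute-force evaluator and is monotone", {
  set.seed(42)
  fs_small <- 16
  n_ep <- 1000
  # mixtures straddling all three thresholds
  x <- matrix(rnorm(n_ep * fs_small * 2, sd = 30), ncol = 2)
  idx <- sample(n_ep, 300)
  for (k in idx) {
    rows <- ((k - 1) * fs_small + 1):(k * fs_small)
    kind <- k %% 3
    if (kind == 0) x[rows, 1] <- x[rows, 1] + seq(0, runif(1, 10, 40),
                                                  length.out = fs_small)
    if (kind == 1) x[sample(rows, 1), 2] <- runif(1, 60, 120)
    if (kind == 2) x[rows[8:16], 1] <- x[rows[8:16], 1] + runif(1, 15, 40)
  }
  sig <- raw_signal(x, fs_small, c("Pz", "P3"), unit = "uV")
  es <- flag_artifacts(epoch_signal(sig))
  oracle <- brute_force_flags(es)
  expect_equal(lapply(es$reasons, sort), oracle)

  loose <- flag_artifacts(epoch_signal(sig), thr_amp_uv = 120,
                          thr_slope_uv_s = 40, thr_step_uv = 50)
  expect_lte(sum(!loose$mask), sum(!es$mask))
  expect_true(all(!es$mask | loose$mask))   # kept epochs stay kept
})

test_that("rejection reasons are nonempty exactly on rejected epochs", {
  set.seed(1)
  sig <- raw_signal(matrix(rnorm(20 * 16, sd = 40), ncol = 1), 16, "Pz",
                    unit = "uV")
  es <- flag_artifacts(epoch_signal(sig))
  has_reason <- vapply(es$reasons, function(r) length(r) > 0, logical(1))
  expect_equal(has_reason, !es$mask)
})

test_that("the IAF is recovered from planted eyes-closed alpha", {
  for (f0 in c(8, 10.5)) {
    set.seed(round(10 * f0))
    t <- tsec(60)
    x <- vapply(1:8, function(i) 3 * rnorm(length(t)) +
                  4 * sin(2 * pi * f0 * t), numeric(length(t)))
    sig <- raw_signal(x, fs, fk_defaults()$eeg$channels, unit = "uV")
    est <- estimate_iaf(preprocess_eeg(sig))
    expect_false(est$fallback_used)
    expect_equal(est$iaf_hz, f0, tolerance = 0.5)
  }
})

test_that("featureless spectra trigger the 10-Hz fallback", {
  set.seed(2)
  sig <- raw_signal(matrix(rnorm(60 * fs * 8, sd = 5), ncol = 8), fs,
                    fk_defaults()$eeg$channels, unit = "uV")
  est <- estimate_iaf(preprocess_eeg(sig))
  expect_true(est$fallback_used)
  expect_equal(est$iaf_hz, 10)
  expect_error(estimate_iaf(mk_eeg(rnorm(20 * fs))), "30 s")
})

test_that("the strict alpha band is a 2-Hz band centred on the IAF", {
  b <- strict_alpha_band(list(iaf_hz = 10))
  expect_equal(c(b$lo_hz, b$hi_hz), c(9, 11))
  b2 <- strict_alpha_band(8.5)
  expect_equal(c(b2$lo_hz, b2$hi_hz), c(7.5, 9.5))
  expect_equal(b2$hi_hz - b2$lo_hz, 2)
})

test_that("band-power GFP matches a direct DFT oracle within 1%", {
  t <- tsec(8)
  set.seed(3)
  cases <- list(5 * sin(2 * pi * 10 * t),
                3 * sin(2 * pi * 9.6 * t + 1) + rnorm(length(t)),
                2 * sin(2 * pi * 10 * t) + sin(2 * pi * 6 * t))
  for (x in cases) {
    sig <- raw_signal(matrix(rep(x, 3), ncol = 3), fs,
                      c("Pz", "P3", "P4"), unit = "uV")
    es <- flag_artifacts(epoch_signal(sig), thr_amp_uv = Inf,
                         thr_slope_uv_s = Inf, thr_step_uv = Inf)
    g <- alpha_gfp(es, strict_alpha_band(10))
    oracle <- vapply(seq_len(es$n_epochs), function(k)
      dft_bandpower_oracle(epoch_data(es, k)[, 1], fs, 9, 11),
      numeric(1))
    expect_equal(g, oracle, tolerance = 0.01)
  }
  # pure on-bin sinusoid integrates to its variance A^2/2
  sig <- raw_signal(matrix(rep(5 * sin(2 * pi * 10 * t), 3), ncol = 3),
                    fs, c("Pz", "P3", "P4"), unit = "uV")
  es <- flag_artifacts(epoch_signal(sig))
  expect_equal(mean(alpha_gfp(es, strict_alpha_band(10))), 12.5,
               tolerance = 0.01 * 12.5)
})

test_that("GFP handles degenerate inputs per contract", {
  es <- flag_artifacts(epoch_signal(mk_eeg(numeric(3 * fs))))
  expect_equal(alpha_gfp(es, strict_alpha_band(10)), rep(0, 3))
  # spatial variance of identical channels is zero
  expect_equal(alpha_gfp(es, strict_alpha_band(10), method = "spatial_sd"),
               rep(0, 3))
  t <- tsec(3)
  sig <- mk_eeg(sin(2 * pi * 10 * t))
  es2 <- flag_artifacts(epoch_signal(sig))
  expect_equal(alpha_gfp(es2, strict_alpha_band(10),
                         method = "spatial_sd"), rep(0, 3),
               tolerance = 1e-10)
  expect_error(alpha_gfp(es2, strict_alpha_band(10), channels = "POz"),
               "POz")
})

test_that("MDrow is the baseline-normalized windowed GFP", {
  gfp <- rep(2.5, 180)
  md <- mdrow_index(gfp, 2.5)
  expect_equal(md$value, rep(1, 3))
  expect_true(all(md$valid_flag))
  # windows losing too many epochs are flagged invalid, not valued
  gfp2 <- gfp; gfp2[61:120] <- NA
  md2 <- mdrow_index(gfp2, 2.5)
  expect_false(md2$valid_flag[2])
  expect_true(is.na(md2$value[2]))
  expect_equal(md2$n_valid, c(60L, 0L, 60L))
  expect_error(mdrow_index(gfp, 0), "positive")
})

test_that("blink removal is local, proportional and near-complete", {
  set.seed(6)
  t <- tsec(30)
  labels <- fk_defaults()$eeg$channels
  weights <- c(1, 0.8, 0.8, 0.6, 0.6, 0.1, 0.08, 0.08)
  tmpl <- 120 * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 38)))
  peaks <- seq(2, 28, by = 2.3)
  clean <- vapply(seq_along(labels), function(i)
    2 * rnorm(length(t)) + 3 * sin(2 * pi * 10 * t + i),
    numeric(length(t)))
  x <- clean
  for (p in peaks) {
    idx <- round(p * fs) + seq_along(tmpl) - 19
    for (i in seq_along(labels))
      x[idx, i] <- x[idx, i] + weights[i] * tmpl
  }
  sig <- raw_signal(x, fs, labels, unit = "uV")
  blinks <- detect_blinks(derive_veog(sig))
  expect_gte(nrow(blinks), length(peaks) - 1)
  out <- remove_blink_artifacts(sig, blinks)
  # residual at the planted peaks below 10% of the planted amplitude
  ip <- round(peaks * fs) + 1
  for (i in seq_along(labels)) {
    resid <- abs(out$data[ip, i] - clean[ip, i])
    expect_lt(max(resid), 0.1 * 120 * weights[i] + 3 * 2)
  }
  # untouched outside blink windows: strict-alpha power change < 1%
  inwin <- rep(FALSE, length(t))
  for (j in seq_len(nrow(blinks)))
    inwin <- inwin | (t >= blinks$onset_s[j] - 0.25 &
                      t <= blinks$offset_s[j] + 0.25)
  expect_equal(out$data[!inwin, 6], x[!inwin, 6])
  expect_identical(remove_blink_artifacts(sig, blinks[0, ]), sig)
})
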