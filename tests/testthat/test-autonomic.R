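# PPG pulse detection, HR/HRV, EDA decomposition and artifact repair.

test_that("PPG band-pass rejects drift and DC, passes the pulse band", {
  fs <- 64
  t <- (0:(120 * fs - 1)) / fs
  drift <- sin(2 * pi * 0.1 * t)
  out <- preprocess_ppg(raw_signal(drift, fs, "PPG"))
  expect_lt(stats::sd(out$data[, 1]) / stats::sd(drift), 0.10)
  pulse <- sin(2 * pi * 1 * t)
  out2 <- preprocess_ppg(raw_signal(pulse, fs, "PPG"))
  expect_equal(stats::sd(out2$data[, 1]), stats::sd(pulse),
               tolerance = 0.05)
  out3 <- preprocess_ppg(raw_signal(pulse + 5, fs, "PPG"))
  expect_lt(abs(mean(out3$data[, 1])), 0.01)
  expect_error(preprocess_ppg(raw_signal(pulse, 4, "PPG")), "twice")
})

sim_ppg_only <- function(hr, seed = 1, mono_s = 300, lf = 1.6e-3,
                         hf = 0.4e-3) {
  cfg <- sim_config(ec_s = 30, eo_s = 30, circuit_s = 30,
                    monotonous_s = mono_s)
  tr <- default_ground_truth(cfg, seed = seed)
  tr$hr_profile[] <- hr
  tr$lf_power <- lf; tr$hf_power <- hf
  simulate_ppg(cfg, tr)
}

test_that("pulse detection recovers planted beats and rates", {
  out <- sim_ppg_only(60, seed = 2, lf = 0, hf = 0)
  ibi <- detect_pulses(preprocess_ppg(out$signal))
  planted <- out$truth$beat_times_s
  # all planted beats found within 20 ms (edge beats may be clipped)
  inner <- planted[planted > 2 & planted < max(planted) - 2]
  d <- vapply(inner, function(b) min(abs(ibi$beat_times_s - b)),
              numeric(1))
  expect_lt(max(d), 0.020)
  expect_equal(mean(ibi$ibi_s[ibi$valid]), 1.000, tolerance = 0.005)

  out90 <- sim_ppg_only(90, seed = 3)
  ibi90 <- detect_pulses(preprocess_ppg(out90$signal))
  expect_equal(60 / mean(ibi90$ibi_s[ibi90$valid]), 90, tolerance = 1 / 90)
})

test_that("pulse detection is amplitude-invariant and safe on silence", {
  out <- sim_ppg_only(72, seed = 5)
  pp <- preprocess_ppg(out$signal)
  b1 <- detect_pulses(pp)
  half <- raw_signal(pp$data * 0.5, pp$fs, pp$labels, pp$t0, pp$unit)
  dbl <- raw_signal(pp$data * 2, pp$fs, pp$labels, pp$t0, pp$unit)
  expect_equal(detect_pulses(half)$beat_times_s, b1$beat_times_s,
               tolerance = 1 / 64)
  expect_equal(detect_pulses(dbl)$beat_times_s, b1$beat_times_s,
               tolerance = 1 / 64)
  flat <- raw_signal(numeric(64 * 20), 64, "PPG")
  expect_equal(length(detect_pulses(flat)$beat_times_s), 0)
  expect_error(detect_pulses(raw_signal(numeric(64 * 5), 64, "PPG")),
               "10 s")
})

test_that("windowed HR follows its defining arithmetic", {
  bt <- seq(0, 180, by = 0.75)
  ibi <- structure(list(beat_times_s = bt, ibi_s = diff(bt),
                        valid = rep(TRUE, length(bt) - 1)),
                   class = "fk_ibi")
  hr <- hr_per_window(ibi, 180)
  expect_equal(hr$value, rep(80, 3))
  # sparse windows are invalid
  bt2 <- c(seq(0, 59, by = 0.8), 90, 91, 92)
  ibi2 <- structure(list(beat_times_s = bt2, ibi_s = diff(bt2),
                         valid = diff(bt2) >= 0.33 & diff(bt2) <= 2),
                    class = "fk_ibi")
  hr2 <- hr_per_window(ibi2, 120)
  expect_false(hr2$valid_flag[2])
  expect_true(is.na(hr2$value[2]))
  # non-physiological intervals are excluded from the mean
  bt3 <- c(seq(0, 30, by = 0.75), 30.2, seq(30.95, 60, by = 0.75))
  ibi3 <- structure(list(beat_times_s = bt3, ibi_s = diff(bt3),
                         valid = diff(bt3) >= 0.33 & diff(bt3) <= 2),
                    class = "fk_ibi")
  expect_equal(hr_per_window(ibi3, 60)$value, 80, tolerance = 0.01)
})

test_that("the Lomb-Scargle spectrum localizes planted modulation", {
  set.seed(8)
  bt <- cumsum(1 + 0.05 * sin(2 * pi * 0.1 * cumsum(rep(1, 300))))
  ibi <- structure(list(beat_times_s = c(0, bt),
                        ibi_s = diff(c(0, bt)),
                        valid = rep(TRUE, length(bt))),
                   class = "fk_ibi")
  sp <- lomb_scargle_psd(ibi)
  expect_equal(sp$freq[which.max(sp$psd)], 0.10, tolerance = 0.005 / 0.1)
  expect_gt(sp$lf_hf_ratio, 10)
  short <- structure(list(beat_times_s = 0:30, ibi_s = rep(1, 30),
                          valid = rep(TRUE, 30)), class = "fk_ibi")
  expect_error(lomb_scargle_psd(short), "at least")
})

test_that("Lomb-Scargle matches an FFT periodogram on even sampling", {
  set.seed(9)
  dt <- 1
  n <- 256
  tt <- (1:n) * dt
  y <- 1 + 0.04 * sin(2 * pi * 0.1 * tt) + 0.02 * sin(2 * pi * 0.3 * tt) +
    rnorm(n, 0, 0.005)
  ibi <- structure(list(beat_times_s = c(0, tt), ibi_s = y,
                        valid = rep(TRUE, n)), class = "fk_ibi")
  sp <- lomb_scargle_psd(ibi)
  lf_fft <- fft_band_oracle(y, dt, 0.04, 0.15)
  hf_fft <- fft_band_oracle(y, dt, 0.15, 0.4)
  expect_equal(sp$lf_power, lf_fft, tolerance = 0.05)
  expect_equal(sp$hf_power, hf_fft, tolerance = 0.05)
})

test_that("planted LF/HF variance ratio is recovered from the PPG", {
  out <- sim_ppg_only(70, seed = 11, mono_s = 600, lf = 1.6e-3,
                      hf = 0.4e-3)
  ibi <- detect_pulses(preprocess_ppg(out$signal))
  sp <- lomb_scargle_psd(ibi)
  expect_equal(sp$lf_hf_ratio, 4, tolerance = 1 / 4)
})

test_that("EDA low-pass keeps DC and removes fast interference", {
  fs <- 4
  t <- (0:479) / fs
  tone <- cos(2 * pi * 1.8 * t)
  out <- preprocess_eda(raw_signal(tone + 2, fs, "EDA"))
  expect_lt(stats::sd(out$data[, 1]), 0.2 * stats::sd(tone))
  expect_equal(mean(out$data[, 1]), 2, tolerance = 0.01)
  expect_equal(nrow(out$data), length(t))
})

test_that("EDA decomposition recovers tonic structure", {
  fs <- 4
  t <- (0:(600 * fs - 1)) / fs
  ramp <- seq(2, 4, length.out = length(t))
  dec <- decompose_eda(raw_signal(ramp, fs, "EDA"))
  expect_lt(sqrt(mean(dec$phasic^2)) / sqrt(mean(ramp^2)), 0.05)
  expect_equal(dec$tonic, ramp, tolerance = 0.05)
  # exact reconstruction by construction
  expect_equal(dec$tonic + dec$phasic, ramp, tolerance = 1e-9)
  # min-max normalization spans [0, 1]
  expect_equal(range(dec$scl_normalized$value), c(0, 1))
  expect_error(decompose_eda(raw_signal(rep(-1, 100), fs, "EDA")),
               "positive")
})

test_that("planted tonic minute-means are recovered within 5%", {
  cfg <- sim_config(ec_s = 30, eo_s = 30, circuit_s = 30,
                    monotonous_s = 600, phasic_rate_per_min = 2)
  tr <- default_ground_truth(cfg, seed = 19)
  out <- simulate_eda(cfg, tr)
  dec <- decompose_eda(preprocess_eda(out$signal))
  planted <- out$truth$tonic_minute_means
  rec <- dec$scl_per_window$value
  n <- min(length(planted), length(rec))
  expect_equal(rec[1:n], planted[1:n], tolerance = 0.05)
})

test_that("movement artifacts are repaired without data loss", {
  fs <- 4
  set.seed(12)
  t <- (0:(240 * fs - 1)) / fs
  clean <- 3 + 0.2 * sin(2 * pi * 0.01 * t) + rnorm(length(t), 0, 0.01)
  sig <- raw_signal(clean, fs, "EDA", unit = "uS")
  expect_identical(interpolate_movement_artifacts(sig)$data, sig$data)
  # a 2-s spike is excised and bridged
  bad <- clean
  bad[400:408] <- bad[400:408] + 5
  rep_sig <- interpolate_movement_artifacts(
    raw_signal(bad, fs, "EDA", unit = "uS"))
  expect_equal(nrow(rep_sig$data), length(clean))
  expect_lt(max(abs(rep_sig$data[, 1] - clean)), 0.3)
  # mostly-bad records (a long flatline) are uncorrectable
  wild <- raw_signal(c(clean[1:100], rep(5, 300)), fs, "EDA")
  expect_error(interpolate_movement_artifacts(wild), "uncorrectable")
})

test_that("a dropped beat is restored as two typical intervals", {
  bt <- c(seq(0, 30, by = 1), 32, seq(33, 60, by = 1))
  ibi <- structure(list(beat_times_s = bt, ibi_s = diff(bt),
                        valid = diff(bt) > 0.33 & diff(bt) < 2),
                   class = "fk_ibi")
  fixed <- interpolate_movement_artifacts(ibi)
  expect_true(all(fixed$valid))
  expect_equal(max(fixed$ibi_s), 1, tolerance = 0.01)
  expect_equal(length(fixed$ibi_s), length(ibi$ibi_s) + 1)
})
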