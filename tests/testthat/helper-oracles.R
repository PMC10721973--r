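# Independent oracles used to validate the package's implementations.
# These deliberately take the slow, literal route (explicit loops, lm(),
# textbook sums of squares, direct DFT sums) so they share no code with
# the functions under test.

# three-criterion screening, evaluated literally per epoch/channel
brute_force_flags <- function(es, thr_amp = 80, thr_slope = 20,
                              thr_step = 25) {
  tt <- (seq_len(es$epoch_len) - 1) / es$fs
  lapply(seq_len(es$n_epochs), function(k) {
    seg <- epoch_data(es, k)
    reasons <- character(0)
    for (c_i in seq_len(ncol(seg))) {
      ch <- seg[, c_i]
      if (any(abs(ch) > thr_amp)) reasons <- c(reasons, "threshold")
      sl <- unname(stats::coef(stats::lm(ch ~ tt))[2])
      if (abs(sl) > thr_slope) reasons <- c(reasons, "trend")
      if (any(abs(diff(ch)) > thr_step)) reasons <- c(reasons, "step")
    }
    sort(unique(reasons))
  })
}

# Holm step-down adjustment straight from its definition
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, max(vapply(seq_len(i), function(j)
      (m - j + 1) * p[o[j]], numeric(1))))
  adj
}

# one-way repeated-measures ANOVA F from textbook sums of squares
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# split-plot (mixed) ANOVA interaction F from sums of squares
mixed_anova_oracle <- function(m, g) {
  g <- factor(g)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  cell <- t(vapply(levels(g), function(lev)
    colMeans(m[g == lev, , drop = FALSE]), numeric(k)))
  gm <- vapply(levels(g), function(lev) mean(m[g == lev, ]), numeric(1))
  cm <- colMeans(m)
  ng <- as.vector(table(g))
  ss_int <- 0
  for (a in seq_along(levels(g)))
    for (b in seq_len(k))
      ss_int <- ss_int + ng[a] * (cell[a, b] - gm[a] - cm[b] + grand)^2
  ss_seg <- n * sum((cm - grand)^2)
  # within-subject residual: total within-subject SS minus segment & int
  subj_mean <- rowMeans(m)
  ss_within_tot <- sum((m - subj_mean)^2)
  ss_err <- ss_within_tot - ss_seg - ss_int
  df_int <- (nlevels(g) - 1) * (k - 1)
  df_err <- (n - nlevels(g)) * (k - 1)
  F <- unname((ss_int / df_int) / (ss_err / df_err))
  list(F = F, p = stats::pf(F, df_int, df_err, lower.tail = FALSE))
}

# band power by direct DFT sums (no fft), density-normalized Hanning
dft_bandpower_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xc <- (x - mean(x)) * w
  tot <- 0
  for (k in 0:(floor(n / 2))) {
    f <- k * fs / n
    if (f < lo - 1e-9 || f > hi + 1e-9) next
    re <- sum(xc * cos(-2 * pi * k * seq(0, n - 1) / n))
    im <- sum(xc * sin(-2 * pi * k * seq(0, n - 1) / n))
    tot <- tot + 2 * (re^2 + im^2) / (n * sum(w^2))
  }
  tot
}

# FFT periodogram band power for evenly sampled series, one-sided
# density scaling matching a variance-preserving integral
fft_band_oracle <- function(y, dt, lo, hi) {
  n <- length(y)
  y <- y - mean(y)
  P <- Mod(stats::fft(y))^2 / n
  freqs <- (seq_len(n) - 1) / (n * dt)
  half <- 2:(floor(n / 2) + 1)
  dens <- 2 * P[half] * dt
  f <- freqs[half]
  i <- f >= lo & f <= hi
  pracma::trapz(f[i], dens[i])
}

# short hand for a multichannel test signal
mk_eeg <- function(v, fs = 125, labels = fk_defaults()$eeg$channels) {
  raw_signal(matrix(rep(v, length(labels)), ncol = length(labels)),
             fs, labels, unit = "uV")
}
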