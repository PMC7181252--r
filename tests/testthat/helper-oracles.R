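# Independent brute-force oracles and small fixture builders used across the
# suite.  The oracles deliberately use naive summation formulas, not the
# package's vectorized/compiled code paths.

# direct DFT magnitude by summation: |sum_n x_n exp(-2*pi*i*k*n/N)|
oracle_dft_mag <- function(x, nbins = 64) {
  N <- length(x)
  sapply(0:(nbins - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)))
  })
}

# inertial MFCCs by explicit triangle and DCT summation loops
oracle_mfcc_axis <- function(x, fs = 40, n_coeff = 12, n_filters = 20,
                             log_floor = 1e-10) {
  pw <- oracle_dft_mag(x, 64)^2
  centers <- (0:63) * fs / 128
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(fs / 2), length.out = n_filters + 2))
  loge <- numeric(n_filters)
  for (j in 1:n_filters) {
    e <- 0
    for (bin in 1:64) {
      f <- centers[bin]
      w <- 0
      if (f >= pts[j] && f <= pts[j + 1] && pts[j + 1] > pts[j])
        w <- (f - pts[j]) / (pts[j + 1] - pts[j])
      if (f > pts[j + 1] && f <= pts[j + 2] && pts[j + 2] > pts[j + 1])
        w <- (pts[j + 2] - f) / (pts[j + 2] - pts[j + 1])
      e <- e + w * pw[bin]
    }
    loge[j] <- log(max(e, log_floor))
  }
  cc <- numeric(n_coeff)
  for (m in 0:(n_coeff - 1)) {
    s <- 0
    for (j in 0:(n_filters - 1))
      s <- s + loge[j + 1] * cos(pi * m * (j + 0.5) / n_filters)
    cc[m + 1] <- s * sqrt(2 / n_filters) * (if (m == 0) 1 / sqrt(2) else 1)
  }
  cc
}

# AUC as the normalized Mann-Whitney pair count, ties as half
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# valid 1-D convolution + ReLU by direct triple-loop summation (fp64)
oracle_conv1d <- function(X, W, b, L, C, K, relu = TRUE) {
  N <- nrow(X); F <- ncol(W); T <- L - K + 1
  Y <- matrix(0, N, T * F)
  for (n in 1:N) for (f in 1:F) for (t in 1:T) {
    acc <- b[f]
    for (c in 1:C) for (k in 1:K)
      acc <- acc + X[n, (c - 1) * L + t + k - 1] * W[(c - 1) * K + k, f]
    Y[n, (f - 1) * T + t] <- if (relu) max(acc, 0) else acc
  }
  Y
}

# closed-form magnitude of the digital Butterworth cascade (bilinear prewarp):
# low-pass order 2 at 15 Hz then high-pass order 3 at 0.2 Hz, fs = 40
oracle_cascade_gain <- function(f, fs = 40) {
  wl <- tan(pi * f / fs) / tan(pi * 15 / fs)
  wh <- tan(pi * 0.2 / fs) / tan(pi * f / fs)
  1 / sqrt(1 + wl^4) / sqrt(1 + wh^6)
}

# steady-state amplitude of a sinusoidal component in a filtered signal,
# estimated by quadrature projection over whole cycles in the signal's tail
tail_amplitude <- function(y, f, fs) {
  n <- length(y)
  cycles <- floor((n / 2) * f / fs)
  len <- round(cycles * fs / f)
  idx <- (n - len + 1):n
  tt <- (idx - 1) / fs
  2 * sqrt(mean(y[idx] * sin(2 * pi * f * tt))^2 +
           mean(y[idx] * cos(2 * pi * f * tt))^2)
}

# a 128 x 3 window holding the same unit sine on each axis
sine_window <- function(freq, fs = 40, n = 128) {
  x <- sin(2 * pi * freq * (0:(n - 1)) / fs)
  cbind(x, x, x)
}

# small deterministic window set: pure-tone windows at given frequencies
tone_windows <- function(freqs, labels, subject = "T01", recording = subject) {
  samples <- array(0, c(length(freqs), 128, 3))
  for (i in seq_along(freqs)) samples[i, , ] <- sine_window(freqs[i])
  fogkit:::new_fog_windows(samples, labels, seq(0, by = 32,
                                                length.out = length(freqs)),
                           rep(subject, length(freqs)),
                           rep(recording, length(freqs)), 32L, 0L,
                           length(freqs))
}

# wide-margin synthetic spectral dataset: FOG rows carry freeze-band energy,
# non-FOG rows locomotion-band energy (with mild noise)
margin_features <- function(n_per_class = 60, seed = 1) {
  fogkit:::with_seed(seed, {
    mk <- function(freq_range, n) {
      t(sapply(seq_len(n), function(i) {
        f <- runif(1, freq_range[1], freq_range[2])
        w <- sine_window(f) * runif(1, 0.6, 1.4) +
          matrix(rnorm(128 * 3, 0, 0.05), 128)
        as.numeric(fft_spectrum(w))
      }))
    }
    vals <- rbind(mk(c(0.8, 2.5), n_per_class), mk(c(5.5, 8.5), n_per_class))
    structure(list(values = vals,
                   labels = rep(c(0L, 1L), each = n_per_class),
                   subject_id = rep(c("A", "B"), n_per_class),
                   recording_id = rep(c("A", "B"), n_per_class),
                   start_index = seq(0, by = 128,
                                     length.out = 2 * n_per_class),
                   representation = "fft", context = 0L),
              class = "fog_features")
  })
}

# small simulated cohort windows, cached per test session
small_cohort_features <- local({
  cache <- NULL
  function(representation = "fft", context = 0L) {
    if (is.null(cache)) {
      recs <- simulate_cohort(cohort_spec(n_subjects = 3,
                                          recording_minutes = 3,
                                          recordings_per_subject = 1,
                                          seed = 33))
      cache <<- bind_windows(lapply(recs, preprocess_recording))
    }
    featurize(cache, representation, context)
  }
})
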