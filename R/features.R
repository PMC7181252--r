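# Feature representations computed per 128-sample analysis window:
#   * "fft"    - magnitudes of the symmetric half (64 bins) of a 128-point DFT
#                per axis (192 values), optionally stacked with up to three
#                previous windows of the same recording (contextual windows);
#   * "mazilu" - seven hand-crafted statistics per axis (21 values) including
#                the freeze index, the band-power ratio that rises during FOG;
#   * "mfcc"   - 12 mel-frequency cepstral coefficients per axis (36 values)
#                with the filterbank remapped onto the 0-20 Hz range of
#                body-worn inertial signals.
#
# Column layouts are channel-blocked (axis-major) and, for contextual stacks,
# step-major with the oldest window first, matching the network input layouts
# in nn.R.

FOG_BANDS <- list(locomotion = c(0.5, 3), freeze = c(3, 8), total = c(0.5, 8))

#' 64-bin FFT magnitude spectrum of one window
#'
#' @param window a 128 x 3 matrix (samples x axes).
#' @param fs sampling rate in Hz (bin k, 0-based, sits at `k * fs / 128`).
#' @return a 64 x 3 matrix of DFT magnitudes (bins 0-63 per axis).
#' @export
fft_spectrum <- function(window, fs = 40) {
  window <- as.matrix(window)
  if (nrow(window) != 128L || ncol(window) != 3L)
    stop("fft_spectrum expects a 128 x 3 window")
  Mod(stats::mvfft(window))[1:64, , drop = FALSE]
}

# spectra for all windows at once: returns n x 192 matrix, axis-blocked
# (columns 1-64 axis x, 65-128 axis y, 129-192 axis z)
windows_spectra <- function(ws) {
  n <- dim(ws$samples)[1]
  out <- matrix(0, n, 192)
  if (n == 0) return(out)
  for (a in 1:3) {
    # mvfft works column-wise: windows as columns
    sp <- Mod(stats::mvfft(t(ws$samples[, , a])))[1:64, , drop = FALSE]
    out[, (a - 1) * 64 + (1:64)] <- t(sp)
  }
  out
}

#' Spectral power inside a frequency band
#'
#' Sums squared magnitudes over the bins whose center frequency lies in the
#' half-open interval `[f_lo, f_hi)` (so 3 Hz belongs to the freeze band, not
#' the locomotion band).
#'
#' @param spectrum numeric vector of 64 DFT magnitudes (one axis).
#' @param band `c(f_lo, f_hi)` in Hz with `0 <= f_lo < f_hi <= fs/2`.
#' @param fs sampling rate in Hz.
#' @return non-negative scalar power.
#' @export
band_power <- function(spectrum, band, fs = 40) {
  if (band[1] >= band[2]) stop("inverted band: ", band[1], " >= ", band[2])
  if (band[1] < 0 || band[2] > fs / 2) stop("band outside [0, fs/2]")
  freqs <- (0:(length(spectrum) - 1)) * fs / 128
  sum(spectrum[freqs >= band[1] & freqs < band[2]]^2)
}

#' Hand-crafted freeze-index feature vector (7 per axis, 21 total)
#'
#' Per axis: mean, standard deviation, variance, spectral entropy of the
#' normalized 64-bin power spectrum, energy (sum of squared samples), freeze
#' index (freeze-band power 3-8 Hz over locomotion-band power 0.5-3 Hz) and
#' total band power 0.5-8 Hz.  A window with locomotion power below 1e-12
#' (e.g. quiet standing) gets freeze index 0 by convention, suppressing the
#' blow-up a near-empty denominator would cause; an all-zero spectrum has
#' entropy 0 by convention.
#'
#' @param window a 128 x 3 matrix.
#' @param fs sampling rate in Hz.
#' @return numeric vector of 21 features, axis-blocked.
#' @export
mazilu_features <- function(window, fs = 40) {
  window <- as.matrix(window)
  if (nrow(window) != 128L || ncol(window) != 3L)
    stop("mazilu_features expects a 128 x 3 window")
  spec <- fft_spectrum(window, fs)
  out <- numeric(21)
  for (a in 1:3) {
    x <- window[, a]
    s <- spec[, a]
    pw <- s^2
    tot <- sum(pw)
    ent <- if (tot <= 0) 0 else {
      p <- pw / tot
      p <- p[p > 0]
      -sum(p * log(p))
    }
    p_loc <- band_power(s, FOG_BANDS$locomotion, fs)
    p_frz <- band_power(s, FOG_BANDS$freeze, fs)
    fi <- if (p_loc < 1e-12) 0 else p_frz / p_loc
    out[(a - 1) * 7 + (1:7)] <-
      c(mean(x), stats::sd(x), stats::var(x), ent, sum(x^2), fi,
        band_power(s, FOG_BANDS$total, fs))
  }
  out
}

#' Freeze index of a single-axis window
#' @param x numeric vector of 128 samples (one axis).
#' @param fs sampling rate in Hz.
#' @export
freeze_index <- function(x, fs = 40) {
  s <- Mod(stats::fft(x))[1:64]
  p_loc <- band_power(s, FOG_BANDS$locomotion, fs)
  if (p_loc < 1e-12) return(0)
  band_power(s, FOG_BANDS$freeze, fs) / p_loc
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank matrix (n_filters x 64) spanning [0, fmax] Hz
mel_filterbank <- function(n_filters = 20L, fs = 40, nbins = 64L) {
  fmax <- fs / 2
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fmax), length.out = n_filters + 2L))
  centers <- (0:(nbins - 1)) * fs / 128
  fb <- matrix(0, n_filters, nbins)
  for (j in seq_len(n_filters)) {
    lo <- pts[j]; mid <- pts[j + 1]; hi <- pts[j + 2]
    up <- (centers - lo) / (mid - lo)
    dn <- (hi - centers) / (hi - mid)
    fb[j, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II basis (n_coeff x n)
dct_basis <- function(n_coeff, n) {
  m <- outer(0:(n_coeff - 1), 0:(n - 1),
             function(k, j) cos(pi * k * (j + 0.5) / n))
  m * sqrt(2 / n) * ifelse(0:(n_coeff - 1) == 0, 1 / sqrt(2), 1)
}

#' Inertial MFCC feature vector (12 per axis, 36 total)
#'
#' Mel-frequency cepstral coefficients adapted to low-frequency inertial
#' signals: 20 triangular filters mel-spaced over 0-20 Hz applied to the
#' 64-bin power spectrum, log energies (floored at 1e-10) and an orthonormal
#' type-II DCT, keeping coefficients c0-c11.
#'
#' @param window a 128 x 3 matrix.
#' @param fs sampling rate in Hz.
#' @param n_coeff coefficients kept per axis.
#' @param n_filters triangular filters in the bank.
#' @param log_floor lower clamp on filter energies before the log.
#' @return numeric vector of `3 * n_coeff` features, axis-blocked.
#' @export
inertial_mfcc <- function(window, fs = 40, n_coeff = 12L, n_filters = 20L,
                          log_floor = 1e-10) {
  window <- as.matrix(window)
  if (nrow(window) != 128L || ncol(window) != 3L)
    stop("inertial_mfcc expects a 128 x 3 window")
  if (n_coeff > n_filters)
    stop("n_coeff (", n_coeff, ") exceeds the number of filters (", n_filters, ")")
  fb <- mel_filterbank(n_filters, fs)
  dct <- dct_basis(n_coeff, n_filters)
  spec <- fft_spectrum(window, fs)
  out <- numeric(3 * n_coeff)
  for (a in 1:3) {
    e <- as.numeric(fb %*% spec[, a]^2)
    ce <- as.numeric(dct %*% log(pmax(e, log_floor)))
    out[(a - 1) * n_coeff + seq_len(n_coeff)] <- ce
  }
  out
}

#' Stack each window's spectrum with its k previous windows
#'
#' Builds the contextual representation: sample i pairs window i with windows
#' i-1 .. i-k of the same recording, oldest step first; the first k windows
#' of every recording are dropped, so stacks never span recordings (or
#' subjects).
#'
#' @param values n x 192 spectral matrix, ordered by `start_index` within
#'   each recording.
#' @param recording_id length-n recording identity of each row.
#' @param k number of previous windows (0-3).
#' @return list: `values` (n' x (k+1)*192, step-major), `keep` (row indices
#'   of the surviving current windows).
#' @export
stack_contextual <- function(values, recording_id, k) {
  if (k < 0) stop("k must be >= 0")
  n <- nrow(values)
  if (k == 0) return(list(values = values, keep = seq_len(n)))
  keep <- integer(0)
  for (rid in unique(recording_id)) {
    idx <- which(recording_id == rid)
    if (length(idx) > k) keep <- c(keep, idx[-seq_len(k)])
  }
  out <- matrix(0, length(keep), (k + 1) * ncol(values))
  for (s in 0:k) {
    # step s holds window (i - k + s): s = 0 oldest, s = k current
    out[, s * ncol(values) + seq_len(ncol(values))] <- values[keep - k + s, , drop = FALSE]
  }
  list(values = out, keep = keep)
}

#' Compute a feature matrix from a window set
#'
#' @param ws a `fog_windows` object.
#' @param representation `"fft"`, `"mazilu"` or `"mfcc"`.
#' @param context number of previous windows stacked with each current window
#'   (0-3; only meaningful for `"fft"`).
#' @return a `fog_features` object: `values` (N x D), `labels`, `subject_id`,
#'   `recording_id`, `start_index`, `representation`, `context`.
#' @export
featurize <- function(ws, representation = c("fft", "mazilu", "mfcc"),
                      context = 0L) {
  representation <- match.arg(representation)
  context <- as.integer(context)
  if (context < 0L || context > 3L) stop("context must be in 0..3")
  if (representation != "fft" && context != 0L)
    stop("contextual stacking is defined for the fft representation only")
  n <- dim(ws$samples)[1]
  if (representation == "fft") {
    vals <- windows_spectra(ws)
    st <- stack_contextual(vals, ws$recording_id, context)
    vals <- st$values; keep <- st$keep
  } else {
    f <- if (representation == "mazilu") mazilu_features else inertial_mfcc
    vals <- t(vapply(seq_len(n), function(i) f(ws$samples[i, , ]),
                     numeric(if (representation == "mazilu") 21 else 36)))
    if (n == 0) vals <- matrix(0, 0, if (representation == "mazilu") 21 else 36)
    keep <- seq_len(n)
  }
  structure(list(values = vals, labels = ws$labels[keep],
                 subject_id = ws$subject_id[keep],
                 recording_id = ws$recording_id[keep],
                 start_index = ws$start_index[keep],
                 representation = representation, context = context),
            class = "fog_features")
}

#' @export
print.fog_features <- function(x, ...) {
  cat(sprintf("<fog_features> %s (context %d): %d x %d, %d FOG\n",
              x$representation, x$context, nrow(x$values), ncol(x$values),
              sum(x$labels)))
  invisible(x)
}

# row subset of a feature matrix
features_subset <- function(fm, rows) {
  fm$values <- fm$values[rows, , drop = FALSE]
  fm$labels <- fm$labels[rows]
  fm$subject_id <- fm$subject_id[rows]
  fm$recording_id <- fm$recording_id[rows]
  fm$start_index <- fm$start_index[rows]
  fm
}
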