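# Signal preprocessing: polyphase resampling to the 40 Hz analysis rate,
# causal Butterworth band limiting, and sliding-window segmentation with the
# majority/purity labeling rule.

ANALYSIS_FS <- 40

# rational approximation p/q of a rate ratio with a modest denominator
rate_ratio <- function(fs_out, fs_in, max_den = 1000L) {
  r <- fs_out / fs_in
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  g <- best
  d <- gcd_int(g[1], g[2])
  c(g[1] %/% d, g[2] %/% d)
}

gcd_int <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }

# polyphase FIR resampling of one channel by rational factor p/q:
# Kaiser-windowed sinc lowpass at the tighter of the two Nyquist rates,
# mirror-padded edges, delay-compensated.
resample_channel <- function(x, p, q) {
  if (p == q) return(x)
  T <- length(x)
  half <- 10L * max(p, q)
  n <- -half:half
  fc <- 1 / max(p, q)
  h <- ifelse(n == 0, fc, sin(pi * fc * n) / (pi * n))
  h <- h * signal::kaiser(2L * half + 1L, 5)
  h <- h * p / sum(h)
  pad <- ceiling(half / p) + 1L
  if (T < pad + 2L) {  # very short input: zero-pad instead of mirroring
    xp <- c(numeric(pad), x, numeric(pad))
  } else {
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(T - pad):(T - 1)]))
  }
  up <- numeric(length(xp) * p)
  up[seq(1, length(up), by = p)] <- xp
  y <- as.numeric(stats::filter(up, h, method = "convolution", sides = 2))
  first <- pad * p + 1L
  Tout <- ceiling(T * p / q)
  idx <- first + (0:(Tout - 1)) * q
  y[idx]
}

#' Resample a recording to a new rate
#'
#' Acceleration channels go through an anti-aliased polyphase FIR resampler
#' (the 200 to 40 Hz case is a clean 1:5 decimation); the binary labels are
#' mapped by nearest-neighbor onto the decimated grid.
#'
#' @param rec a `fog_recording`.
#' @param fs_out target sampling rate in Hz (> 0).
#' @return a `fog_recording` at `fs_out`.
#' @export
resample_to <- function(rec, fs_out) {
  if (fs_out <= 0) stop("fs_out must be > 0")
  if (abs(fs_out - rec$fs) < 1e-9) return(rec)
  T <- n_samples(rec)
  if (T == 0L) {
    rec$fs <- fs_out
    return(rec)
  }
  pq <- rate_ratio(fs_out, rec$fs)
  accel <- sapply(1:3, function(a) resample_channel(rec$accel[, a], pq[1], pq[2]))
  if (is.null(dim(accel))) accel <- matrix(accel, ncol = 3)
  Tout <- nrow(accel)
  src <- pmin(T, pmax(1L, as.integer(round((0:(Tout - 1)) * rec$fs / fs_out)) + 1L))
  out <- fog_recording(rec$subject_id, fs_out, accel, rec$labels[src],
                       meta = rec$meta)
  out$meta$resampled_from <- rec$fs
  out
}

#' Band-limit a 40 Hz recording
#'
#' Applies, per axis and causally (single forward pass, filter state reset at
#' the start of the recording), a second-order Butterworth low-pass at 15 Hz
#' followed by a third-order Butterworth high-pass at 0.2 Hz, removing sensor
#' noise above the band of interest and the gravity component.  Cut-offs are
#' defined relative to the 40 Hz analysis rate, so any other rate is refused.
#' Edge transients at the start of the recording are kept, not trimmed.
#'
#' @param rec a `fog_recording` sampled at 40 Hz.
#' @return the filtered `fog_recording`; labels are unchanged.
#' @export
bandlimit <- function(rec) {
  if (abs(rec$fs - ANALYSIS_FS) > 1e-9)
    stop("bandlimit expects a 40 Hz recording; got fs = ", rec$fs)
  if (n_samples(rec) == 0L) return(rec)
  lp <- signal::butter(2, 15 / (ANALYSIS_FS / 2), "low")
  hp <- signal::butter(3, 0.2 / (ANALYSIS_FS / 2), "high")
  accel <- apply(rec$accel, 2, function(x) {
    y <- as.numeric(signal::filter(lp, x))
    as.numeric(signal::filter(hp, y))
  })
  if (is.null(dim(accel))) accel <- matrix(accel, ncol = 3)
  out <- fog_recording(rec$subject_id, rec$fs, accel, rec$labels, rec$meta)
  out$meta$bandlimited <- TRUE
  out
}

# closed-form magnitude response of the digital Butterworth cascade at
# frequency f (Hz): analog prototype evaluated at the bilinear-prewarped
# frequency.  Used as the analytic oracle for the band-limiting filters.
#' @keywords internal
butter_cascade_gain <- function(f, fs = ANALYSIS_FS) {
  wl <- tan(pi * f / fs) / tan(pi * 15 / fs)
  wh <- tan(pi * 0.2 / fs) / tan(pi * f / fs)
  1 / sqrt(1 + wl^4) / sqrt(1 + wh^6)
}

#' Segment a recording into fixed, labeled analysis windows
#'
#' Windows of `win` samples advance by `win * (1 - overlap)` samples
#' (0-based start indices, half-open spans).  A window is labeled FOG when
#' more than 50% of its samples carry the FOG annotation, non-FOG when it
#' contains no FOG sample at all; windows with any intermediate mix are
#' discarded and tallied.
#'
#' @param rec a `fog_recording` at 40 Hz.
#' @param win window length in samples.
#' @param overlap fractional overlap between consecutive windows; one of
#'   0, 0.5, 0.75.
#' @return a `fog_windows` object: `samples` (n x win x 3 array), `labels`
#'   (0/1), `start_index` (0-based), plus subject/recording identity, hop and
#'   the discard tally.  Empty (with a warning) when the recording is shorter
#'   than one window.
#' @export
window_and_label <- function(rec, win = 128L, overlap = 0.75) {
  if (abs(rec$fs - ANALYSIS_FS) > 1e-9)
    stop("window_and_label expects a 40 Hz recording; got fs = ", rec$fs)
  if (!overlap %in% c(0, 0.5, 0.75)) stop("overlap must be 0, 0.5 or 0.75")
  win <- as.integer(win)
  hop <- as.integer(round(win * (1 - overlap)))
  T <- n_samples(rec)
  rid <- rec$meta$recording_id %||% rec$subject_id
  if (T < win) {
    warning("recording ", rid, " shorter than one window; empty window set")
    return(new_fog_windows(array(0, c(0, win, 3)), integer(0), integer(0),
                           character(0), character(0), hop, 0L, 0L))
  }
  starts <- seq(0L, T - win, by = hop)
  cs <- c(0L, cumsum(rec$labels))
  nfog <- cs[starts + win + 1L] - cs[starts + 1L]
  lab <- ifelse(nfog > win / 2, 1L, ifelse(nfog == 0L, 0L, NA_integer_))
  keep <- which(!is.na(lab))
  n_disc <- length(starts) - length(keep)
  samples <- array(0, c(length(keep), win, 3))
  for (j in seq_along(keep)) {
    s0 <- starts[keep[j]]
    samples[j, , ] <- rec$accel[(s0 + 1L):(s0 + win), ]
  }
  new_fog_windows(samples, lab[keep], starts[keep],
                  rep(rec$subject_id, length(keep)), rep(rid, length(keep)),
                  hop, n_disc, length(starts))
}

new_fog_windows <- function(samples, labels, start_index, subject_id,
                            recording_id, hop, n_discarded, n_enumerated) {
  structure(list(samples = samples, labels = as.integer(labels),
                 start_index = as.integer(start_index),
                 subject_id = subject_id, recording_id = recording_id,
                 fs = ANALYSIS_FS, win = dim(samples)[2], hop = hop,
                 n_discarded = n_discarded, n_enumerated = n_enumerated),
            class = "fog_windows")
}

#' @export
print.fog_windows <- function(x, ...) {
  cat(sprintf(
    "<fog_windows> %d windows (%d samples @ %g Hz, hop %d) from %d recording(s); %d FOG, %d discarded mixed\n",
    length(x$labels), x$win, x$fs, x$hop, length(unique(x$recording_id)),
    sum(x$labels), x$n_discarded))
  invisible(x)
}

#' Concatenate window sets (e.g. across recordings or subjects)
#' @param ... `fog_windows` objects sharing `win`, `hop` and `fs`.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && !inherits(ws[[1]], "fog_windows")) ws <- ws[[1]]
  stopifnot(length(unique(sapply(ws, `[[`, "hop"))) == 1L,
            length(unique(sapply(ws, `[[`, "win"))) == 1L)
  samples <- do.call(abind3, lapply(ws, `[[`, "samples"))
  new_fog_windows(samples,
                  unlist(lapply(ws, `[[`, "labels")),
                  unlist(lapply(ws, `[[`, "start_index")),
                  unlist(lapply(ws, `[[`, "subject_id")),
                  unlist(lapply(ws, `[[`, "recording_id")),
                  ws[[1]]$hop,
                  sum(sapply(ws, `[[`, "n_discarded")),
                  sum(sapply(ws, `[[`, "n_enumerated")))
}

# bind 3-D arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  arrs <- arrs[vapply(arrs, function(a) dim(a)[1] > 0, logical(1))]
  if (!length(arrs)) return(array(0, c(0, 128, 3)))
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(sapply(arrs, function(a) dim(a)[1])), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n) out[(at + 1L):(at + n), , ] <- a
    at <- at + n
  }
  out
}

#' Preprocess one raw recording end to end
#'
#' Convenience chain: resample to 40 Hz, band-limit, window and label.
#'
#' @param rec a raw `fog_recording` (any rate).
#' @param overlap window overlap fraction (0, 0.5 or 0.75).
#' @param win window length in samples at 40 Hz.
#' @return a `fog_windows` object.
#' @export
preprocess_recording <- function(rec, overlap = 0.75, win = 128L) {
  window_and_label(bandlimit(resample_to(rec, ANALYSIS_FS)),
                   win = win, overlap = overlap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
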