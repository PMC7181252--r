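# Synthetic gait / freezing-of-gait cohort simulator.
#
# Emulates the spectral structure the detection pipeline relies on: normal
# gait concentrates power in the locomotion band (0.5-3 Hz, a fundamental plus
# harmonics), FOG episodes show low-amplitude trembling with a dominant
# frequency in 6-8 Hz, standing segments are noise only, and FOG samples are a
# ~10.5% minority of the cohort.  It makes no claim of biomechanical realism;
# see the methods vignette for what it does and does not emulate.

#' Subject profile for the gait/FOG simulator
#'
#' Per-subject generative parameters.  Defaults draw nothing; use
#' [draw_subject_profile()] for a randomized profile.
#'
#' @param subject_id subject identifier.
#' @param gait_fundamental step-cycle fundamental frequency in Hz (0.5-3).
#' @param gait_amplitude peak amplitude of the gait fundamental, in g.
#' @param fog_tremble_freq trembling frequency during FOG, in Hz (6-8).
#' @param fog_amplitude trembling amplitude in g.
#' @param noise_sd per-axis white-noise standard deviation, in g.
#' @param episode_rate expected FOG episodes per minute.
#' @param episode_duration mean FOG episode duration in seconds.
#' @param artifact_rate expected non-gait movement artifacts per minute
#'   (brief broadband bursts from unscripted daily activities; labeled
#'   non-FOG even though their power reaches into the freeze band).
#' @return a `fog_profile` list.
#' @export
subject_profile <- function(subject_id, gait_fundamental = 1.8,
                            gait_amplitude = 0.35, fog_tremble_freq = 7,
                            fog_amplitude = 0.35, noise_sd = 0.05,
                            episode_rate = 1.05, episode_duration = 6,
                            artifact_rate = 3) {
  stopifnot(gait_fundamental >= 0.5, gait_fundamental <= 3,
            fog_tremble_freq >= 6, fog_tremble_freq <= 8,
            gait_amplitude >= 0, fog_amplitude >= 0, noise_sd >= 0,
            episode_rate >= 0, episode_duration > 0, artifact_rate >= 0)
  structure(list(subject_id = as.character(subject_id),
                 gait_fundamental = gait_fundamental,
                 gait_amplitude = gait_amplitude,
                 fog_tremble_freq = fog_tremble_freq,
                 fog_amplitude = fog_amplitude,
                 noise_sd = noise_sd,
                 episode_rate = episode_rate,
                 episode_duration = episode_duration,
                 artifact_rate = artifact_rate),
            class = "fog_profile")
}

#' Draw a randomized subject profile
#'
#' Inter-subject heterogeneity (cadence, amplitudes, trembling frequency,
#' noise floor, episode statistics) is what makes leave-one-subject-out
#' evaluation genuinely harder than within-subject evaluation, so each
#' parameter is drawn from a documented range rather than fixed.
#'
#' @param subject_id subject identifier.
#' @param target_fog_fraction desired expected fraction of FOG-labeled
#'   samples for this subject (episode rate is derived from it).
#' @param fog_contrast multiplier on the FOG trembling amplitude relative to
#'   the subject's gait amplitude; 1 is the default difficulty, smaller values
#'   make FOG spectrally harder to separate.
#' @return a `fog_profile`.
#' @export
draw_subject_profile <- function(subject_id, target_fog_fraction = 0.105,
                                 fog_contrast = 1) {
  dur <- stats::runif(1, 4.5, 8)                       # mean episode length, s
  rate <- target_fog_fraction * 60 / dur               # episodes / minute
  rate <- rate * stats::runif(1, 0.85, 1.15)
  amp <- stats::runif(1, 0.25, 0.45)
  subject_profile(
    subject_id       = subject_id,
    gait_fundamental = stats::runif(1, 1.4, 2.2),
    gait_amplitude   = amp,
    fog_tremble_freq = stats::runif(1, 6, 8),
    fog_amplitude    = amp * fog_contrast * stats::runif(1, 0.8, 1.2),
    noise_sd         = stats::runif(1, 0.03, 0.08),
    episode_rate     = rate,
    episode_duration = dur,
    artifact_rate    = stats::runif(1, 2, 4))
}

#' Cohort specification for the simulator
#'
#' Defaults mirror the study conditions the pipeline targets: 21 subjects,
#' two ~20-minute unscripted sessions each, and a 10.5% FOG sample fraction.
#'
#' @param n_subjects number of subjects.
#' @param recording_minutes duration of each recording, minutes.
#' @param recordings_per_subject sessions per subject.
#' @param target_fog_fraction cohort-level fraction of FOG-labeled samples.
#' @param fog_contrast difficulty knob passed to [draw_subject_profile()].
#' @param fs sampling rate of the emitted raw recordings, Hz.
#' @param seed integer seed controlling every random draw.
#' @return a `fog_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 21L, recording_minutes = 20,
                        recordings_per_subject = 2L,
                        target_fog_fraction = 0.105, fog_contrast = 1,
                        fs = 200, seed = 20L) {
  stopifnot(n_subjects >= 1, target_fog_fraction > 0, target_fog_fraction < 1,
            recording_minutes > 0, recordings_per_subject >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 recording_minutes = recording_minutes,
                 recordings_per_subject = as.integer(recordings_per_subject),
                 target_fog_fraction = target_fog_fraction,
                 fog_contrast = fog_contrast, fs = fs,
                 seed = as.integer(seed)),
            class = "fog_cohort_spec")
}

# smooth a 0/1 envelope with a short raised-cosine to avoid onset clicks
smooth_envelope <- function(env, fs, width_s = 0.25) {
  w <- max(3L, as.integer(round(width_s * fs)))
  if (w %% 2 == 0) w <- w + 1L
  kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(env[1], w), env, rep(env[length(env)], w)),
                           kern, sides = 2))[(w + 1):(w + length(env))]
}

#' Simulate one subject recording
#'
#' A semi-Markov state machine alternates walking bouts and standing pauses;
#' FOG episodes are carved out of walking bouts (freezing manifests on
#' initiating or continuing gait, not while quietly standing).  Walking is a
#' gait fundamental plus harmonics kept inside the 0.5-3 Hz locomotion band;
#' FOG replaces most locomotion power with trembling at the subject's 6-8 Hz
#' frequency; standing is sensor noise.  The three axes share the motion
#' component with axis-specific gains, one axis carries the 1 g gravity
#' offset, and each axis adds independent Gaussian noise.
#'
#' @param profile a `fog_profile`.
#' @param duration recording length in seconds (>= 0).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a `fog_recording` with per-sample FOG labels.
#' @export
simulate_subject <- function(profile, duration, fs = 200, seed = 1L) {
  if (duration < 0) stop("duration must be >= 0")
  T <- as.integer(round(duration * fs))
  if (T == 0L)
    return(fog_recording(profile$subject_id, fs, matrix(numeric(0), 0, 3),
                         integer(0), meta = list(profile = profile)))
  with_seed(seed, {
    # --- state timeline: walking bouts with interleaved standing pauses -----
    state <- integer(T)  # 0 stand, 1 walk, 2 FOG
    t <- 0L
    while (t < T) {
      walk <- as.integer(round(fs * stats::rgamma(1, shape = 4, scale = 25 / 4)))
      walk <- max(walk, as.integer(2 * fs))
      n <- min(walk, T - t)
      state[(t + 1):(t + n)] <- 1L
      t <- t + n
      if (t < T && stats::runif(1) < 0.35) {
        stand <- as.integer(round(fs * stats::rgamma(1, shape = 2, scale = 8 / 2)))
        n <- min(max(stand, fs), T - t)
        state[(t + 1):(t + n)] <- 0L
        t <- t + n
      }
    }
    # --- FOG episodes placed inside walking bouts ---------------------------
    # Each episode carries the temporal phases seen at freeze onset: a short
    # pre-freeze transition (gait degrades, trembling ramps up; still labeled
    # non-FOG) followed by the freeze proper, whose trembling is strongest at
    # onset and decays over the episode.
    n_ep <- stats::rpois(1, profile$episode_rate * duration / 60)
    pre_fog <- numeric(T)   # pre-freeze trembling envelope (labeled non-FOG)
    fog_env <- numeric(T)   # within-episode trembling envelope
    gait_cut <- numeric(T)  # extra gait attenuation during pre-freeze
    if (n_ep > 0) {
      durs <- pmax(1.5, stats::rgamma(n_ep, shape = 3,
                                      scale = profile$episode_duration / 3))
      walk_idx <- which(state == 1L)
      for (d in durs) {
        len <- as.integer(round(d * fs))
        pre <- as.integer(round(stats::runif(1, 1.2, 2.2) * fs))
        if (len + pre >= T) next
        placed <- FALSE; tries <- 0L
        while (!placed && tries < 60L) {
          tries <- tries + 1L
          s0 <- sample(walk_idx, 1L)
          if (s0 > pre && s0 + len - 1L <= T &&
              all(state[(s0 - pre):(s0 + len - 1L)] == 1L)) {
            state[s0:(s0 + len - 1L)] <- 2L
            ramp <- seq(0, 1, length.out = pre)
            pre_fog[(s0 - pre):(s0 - 1L)] <-
              pmax(pre_fog[(s0 - pre):(s0 - 1L)], 0.45 * ramp)
            gait_cut[(s0 - pre):(s0 - 1L)] <-
              pmax(gait_cut[(s0 - pre):(s0 - 1L)], 0.6 * ramp)
            tail_lvl <- stats::runif(1, 0.35, 0.65)
            fog_env[s0:(s0 + len - 1L)] <- seq(1, tail_lvl, length.out = len)
            placed <- TRUE
          }
        }
      }
    }
    # --- non-gait movement artifacts (unscripted ADL confounds) -------------
    # brief multi-tone bursts whose power reaches into the freeze band but
    # which are single, isolated events rather than sustained episodes
    artifact <- numeric(T)
    n_art <- stats::rpois(1, profile$artifact_rate * duration / 60)
    tt <- (seq_len(T) - 1) / fs
    if (n_art > 0) {
      for (j in seq_len(n_art)) {
        alen <- as.integer(round(stats::runif(1, 0.4, 1.5) * fs))
        a0 <- sample.int(T - alen, 1L)
        span <- a0:(a0 + alen - 1L)
        if (any(state[span] == 2L)) next  # keep artifacts out of episodes
        amp <- profile$gait_amplitude * stats::runif(1, 0.5, 1.1)
        burst <- numeric(alen)
        for (h in 1:3)
          burst <- burst + stats::runif(1, 0.3, 1) *
            sin(2 * pi * stats::runif(1, 2, 11) * tt[span] +
                stats::runif(1, 0, 2 * pi))
        env <- 0.5 - 0.5 * cos(2 * pi * seq_len(alen) / (alen + 1))
        artifact[span] <- artifact[span] + amp * env * burst / 1.5
      }
    }
    # --- signal synthesis ---------------------------------------------------
    f0 <- profile$gait_fundamental
    gait <- numeric(T)
    amps <- c(1, 0.5, 0.25)
    for (h in 1:3) {
      if (h * f0 <= 3)
        gait <- gait + amps[h] * sin(2 * pi * h * f0 * tt + stats::runif(1, 0, 2 * pi))
    }
    gait <- profile$gait_amplitude * gait
    tremble <- profile$fog_amplitude *
      sin(2 * pi * profile$fog_tremble_freq * tt + stats::runif(1, 0, 2 * pi))
    env_gait <- smooth_envelope(
      pmax(0, (state == 1L) - gait_cut) + 0.3 * (state == 2L), fs)
    env_fog  <- smooth_envelope(fog_env + pre_fog, fs, width_s = 0.15)
    gains_gait <- c(1, 0.65, 0.45)
    gains_fog  <- c(0.6, 0.8, 1)
    gains_art  <- c(0.9, 0.9, 0.7)
    accel <- sapply(1:3, function(a)
      gains_gait[a] * env_gait * gait + gains_fog[a] * env_fog * tremble +
        gains_art[a] * artifact + stats::rnorm(T, 0, profile$noise_sd))
    accel[, 3] <- accel[, 3] + 1  # gravity offset on the vertical axis
    fog_recording(profile$subject_id, fs, accel, as.integer(state == 2L),
                  meta = list(profile = profile, seed = seed,
                              state_fractions = tabulate(state + 1L, 3L) / T))
  })
}

#' Simulate a full labeled cohort
#'
#' Draws one randomized profile per subject and generates the configured
#' number of recordings per subject, each with its own derived seed, so the
#' whole cohort is reproducible from `spec$seed` alone.
#'
#' @param spec a `fog_cohort_spec` from [cohort_spec()].
#' @return a list of `fog_recording`s with a `manifest` attribute
#'   (per-subject profiles, seeds, realized FOG fractions).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  recs <- list()
  profiles <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    pseed <- (spec$seed * 7919L + s * 104729L) %% 2147483647L
    prof <- with_seed(pseed,
      draw_subject_profile(sid, spec$target_fog_fraction, spec$fog_contrast))
    profiles[[sid]] <- prof
    for (r in seq_len(spec$recordings_per_subject)) {
      rseed <- (pseed + r * 7907L) %% 2147483647L
      rec <- simulate_subject(prof, spec$recording_minutes * 60, spec$fs, rseed)
      rec$meta$recording <- r
      rec$meta$recording_id <- sprintf("%s_r%d", sid, r)
      recs[[length(recs) + 1L]] <- rec
    }
  }
  frac <- cohort_fog_fraction(recs)
  if (abs(frac - spec$target_fog_fraction) > 0.05)
    warning(sprintf(
      "realized FOG fraction %.3f far from target %.3f; episode parameters may be infeasible for this duration",
      frac, spec$target_fog_fraction))
  attr(recs, "manifest") <- list(spec = spec, profiles = profiles,
                                 realized_fog_fraction = frac)
  recs
}

#' Fraction of FOG-labeled samples across a list of recordings
#' @param recs list of `fog_recording`s.
#' @export
cohort_fog_fraction <- function(recs) {
  n_fog <- sum(vapply(recs, function(r) sum(as.numeric(r$labels)), numeric(1)))
  n_tot <- sum(vapply(recs, function(r) length(r$labels), integer(1)))
  n_fog / n_tot
}
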