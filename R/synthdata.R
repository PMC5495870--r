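#' Specify a planted directed coupling between two channels
#'
#' Couplings are realized as band-limited autoregressive cross-coefficients: a
#' short tap sequence starting at `lag` samples (on the analysis-rate grid),
#' cosine-shaped at the band's centre frequency, whose gain switches from
#' `gain_pre` to `gain_post` at the condition onset. Because the coupling lives
#' in the AR structure (not as an additively mixed signal), generalized partial
#' directed coherence has a true nonzero target at the stated band.
#'
#' @param source,target Channel labels (influence flows source -> target).
#' @param band Length-2 numeric, frequency band in Hz; the tap sequence is
#'   centred on `mean(band)`.
#' @param gain_pre,gain_post Coupling gain (L2 norm of the tap vector) before
#'   and after onset.
#' @param lag Coupling lag in samples at the analysis rate.
#' @return A list of class `bn_coupling`.
#' @export
coupling <- function(source, target, band = c(5, 7),
                     gain_pre = 0, gain_post = 0.4, lag = 2) {
  stopifnot(length(band) == 2, band[1] < band[2], lag >= 1)
  structure(list(source = source, target = target, band = band,
                 gain_pre = gain_pre, gain_post = gain_post, lag = lag),
            class = "bn_coupling")
}

#' Specify a narrowband oscillatory component
#'
#' Oscillators are realized as noise-driven damped AR(2) resonances (the
#' standard stochastic model of an EEG rhythm), independent per channel and
#' trial, so they are *not* phase-locked to the onset -- in contrast to the
#' sway interference -- and carry no cross-channel structure. `amplitude` is
#' the sinusoid-equivalent peak amplitude: the process is scaled to RMS
#' `amplitude / sqrt(2)`. `bandwidth` sets the resonance damping (half-power
#' width); a deterministic sinusoid (bandwidth 0) would put the rhythm's
#' spectral pole on the unit circle, which no autoregressive analysis of
#' finite data can represent.
#'
#' @param channels Channel labels carrying the oscillation.
#' @param freq Centre frequency in Hz.
#' @param amplitude Sinusoid-equivalent amplitude in microvolts.
#' @param bandwidth Resonance bandwidth in Hz (> 0).
#' @param freq_jitter_sd Per-trial/channel standard deviation of the centre
#'   frequency (Hz).
#' @return A list of class `bn_oscillator`.
#' @export
oscillator <- function(channels, freq, amplitude, bandwidth = 1,
                       freq_jitter_sd = 0.1) {
  stopifnot(freq > 0, amplitude >= 0, bandwidth > 0)
  structure(list(channels = channels, freq = freq, amplitude = amplitude,
                 bandwidth = bandwidth, freq_jitter_sd = freq_jitter_sd),
            class = "bn_oscillator")
}

# One realization of a noise-driven AR(2) resonance, scaled to target RMS.
ar2_oscillation <- function(n, fs, freq, bandwidth, rms) {
  r <- exp(-pi * bandwidth / fs)
  a1 <- 2 * r * cos(2 * pi * freq / fs)
  a2 <- -r^2
  burn <- ceiling(2 * fs / bandwidth)      # reach stationarity first
  z <- stats::filter(stats::rnorm(n + burn), c(a1, a2),
                     method = "recursive")
  z <- as.numeric(z)[(burn + 1):(burn + n)]
  s <- stats::sd(z)
  if (s == 0) return(numeric(n))
  z * (rms / s)
}

#' Specify the platform-sway interference
#'
#' A fundamental plus decaying harmonics (amplitude / k for harmonic k), added
#' to all scalp channels only after the onset. When `phase_locked = TRUE` the
#' phase at onset is identical across trials, which is what makes the artifact
#' detectable by phase-locking analysis. The interference has a scalp
#' topography (an anterior-posterior gain gradient, stronger posteriorly, as
#' for movement-related artifacts); a spatially uniform artifact would be
#' removed exactly by common-average re-referencing, which real sway
#' contamination is not.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonic components (including the fundamental).
#' @param amplitude Amplitude of the fundamental in microvolts (at the mean
#'   topographic gain).
#' @param phase_locked Logical; identical phase at onset across trials?
#' @param topography Optional named numeric vector of per-channel gains;
#'   `NULL` selects the built-in anterior-posterior gradient.
#' @return A list of class `bn_sway`.
#' @export
sway_spec <- function(f0 = 2.6, n_harmonics = 4, amplitude = 5,
                      phase_locked = TRUE, topography = NULL) {
  stopifnot(f0 > 0, n_harmonics >= 1)
  structure(list(f0 = f0, n_harmonics = n_harmonics, amplitude = amplitude,
                 phase_locked = phase_locked, topography = topography),
            class = "bn_sway")
}

# Per-channel sway gains: anterior-posterior gradient (posterior stronger),
# mean 1 across the montage.
sway_gains <- function(sway, channel_names) {
  if (!is.null(sway$topography)) {
    g <- rep(1, length(channel_names))
    names(g) <- channel_names
    g[names(sway$topography)] <- sway$topography
    return(unname(g))
  }
  y <- channel_positions(channel_names)$y
  g <- 1 - 0.8 * (y - mean(y))          # y in [-1, 1]: Oz ~ strongest
  unname(g)
}

#' Specify ocular (blink) contamination
#'
#' Blinks are stereotyped biphasic pulses on the EOG channel, occurring as a
#' Poisson process, and propagate to scalp channels with fixed per-channel
#' coefficients (so a regression-based correction can recover them exactly in
#' expectation).
#'
#' @param blink_rate Blinks per second.
#' @param amplitude Blink amplitude on the EOG channel (microvolts).
#' @param propagation Named numeric vector of per-channel propagation
#'   coefficients, or a single number applied to every scalp channel.
#' @return A list of class `bn_eog`.
#' @export
eog_spec <- function(blink_rate = 0.2, amplitude = 100, propagation = 0.05) {
  structure(list(blink_rate = blink_rate, amplitude = amplitude,
                 propagation = propagation),
            class = "bn_eog")
}

#' Configuration of the synthetic balance-experiment generator
#'
#' Defaults emulate the study conditions of the balance experiment: 37 subjects
#' x 10 trials, 8 s epochs with the stable-to-unstable transition (onset) at
#' 3 s, acquisition at 1000 Hz intended for decimation to 100 Hz, theta (~6 Hz,
#' centro-parietal) and alpha (~10 Hz, occipito-parietal) oscillations, a
#' phase-locked 2.6 Hz sway interference with harmonics appearing after onset,
#' an onset impulse artifact, a transient post-onset alpha amplitude drop, and
#' one planted time-varying directed coupling CPz -> Cz in the theta band that
#' switches on at the onset.
#'
#' @param n_subjects,n_trials Cohort dimensions.
#' @param channel_names Scalp channel labels (default: the 11-channel subset,
#'   see [channels_subset()]; use [channels_full()] for the 32-channel layout).
#' @param fs_raw Acquisition sampling rate (Hz); must be a multiple of `fs_out`.
#' @param fs_out Analysis sampling rate (Hz) on which AR couplings are defined.
#' @param epoch_length,onset_time Epoch duration and onset time, seconds.
#' @param couplings List of [coupling()] objects.
#' @param oscillators List of [oscillator()] objects.
#' @param sway A [sway_spec()] or `NULL`.
#' @param onset_impulse_amplitude Amplitude (microvolts) of the biphasic
#'   impulse artifact at onset, 0 to disable.
#' @param alpha_drop Length-2 numeric `c(depth, duration)`: fractional
#'   amplitude reduction of alpha-band oscillators (8-13 Hz) and its duration
#'   in seconds after onset; `NULL` to disable.
#' @param noise_sd Innovation / sensor noise SD in microvolts.
#' @param eog An [eog_spec()] or `NULL` for no EOG channel.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated list of class `bn_sim_config`.
#' @export
sim_config <- function(n_subjects = 37, n_trials = 10,
                       channel_names = channels_subset(),
                       fs_raw = 1000, fs_out = 100,
                       epoch_length = 8, onset_time = 3,
                       couplings = list(coupling("CPz", "Cz", band = c(5, 7),
                                                 gain_pre = 0, gain_post = 0.4,
                                                 lag = 2)),
                       oscillators = list(
                         oscillator(intersect(c("C1", "Cz", "C2", "CP1", "CPz",
                                                "CP2"), channel_names),
                                    freq = 6, amplitude = 7.5),
                         oscillator(intersect(c("P7", "P8", "O1", "Oz", "O2"),
                                              channel_names),
                                    freq = 10, amplitude = 10)
                       ),
                       sway = sway_spec(),
                       onset_impulse_amplitude = 20,
                       alpha_drop = c(0.6, 1),
                       noise_sd = 1,
                       eog = eog_spec(),
                       seed = 1L) {
  if (fs_raw %% fs_out != 0) stop("fs_raw must be divisible by fs_out")
  if (!(onset_time > 0 && onset_time < epoch_length)) {
    stop("onset_time must lie strictly inside the epoch")
  }
  for (cp in couplings) {
    if (!all(c(cp$source, cp$target) %in% channel_names)) {
      stop("coupling references unknown channel: ", cp$source, " -> ", cp$target)
    }
  }
  for (os in oscillators) {
    if (!all(os$channels %in% channel_names)) {
      stop("oscillator references unknown channel(s)")
    }
  }
  cfg <- structure(
    list(n_subjects = n_subjects, n_trials = n_trials,
         channel_names = channel_names, fs_raw = fs_raw, fs_out = fs_out,
         epoch_length = epoch_length, onset_time = onset_time,
         couplings = couplings, oscillators = oscillators, sway = sway,
         onset_impulse_amplitude = onset_impulse_amplitude,
         alpha_drop = alpha_drop, noise_sd = noise_sd, eog = eog,
         seed = as.integer(seed)),
    class = "bn_sim_config"
  )
  # stability is checked again (with a diagnostic) inside simulate_dataset()
  cfg
}

# Band-shaped AR cross-coefficient taps: 4 taps starting at `lag`, cosine at
# the band centre under a light taper, L2-normalized to `gain`.
coupling_taps <- function(cp, gain, fs) {
  k <- 0:3
  w <- c(0.5, 1, 1, 0.5)
  raw <- w * cos(2 * pi * mean(cp$band) * k / fs)
  gain * raw / sqrt(sum(raw^2))
}

# Assemble the D x D x p coefficient cube for one condition (gain column).
coupling_cube <- function(cfg, which_gain) {
  D <- length(cfg$channel_names)
  p <- max(1, vapply(cfg$couplings, function(cp) cp$lag + 3, numeric(1)))
  A <- array(0, dim = c(D, D, p))
  for (cp in cfg$couplings) {
    g <- if (which_gain == "pre") cp$gain_pre else cp$gain_post
    if (g == 0) next
    taps <- coupling_taps(cp, g, cfg$fs_out)
    si <- match(cp$source, cfg$channel_names)
    ti <- match(cp$target, cfg$channel_names)
    A[ti, si, cp$lag + 0:3] <- A[ti, si, cp$lag + 0:3] + taps
  }
  A
}

# Spectral radius of the VAR companion matrix.
companion_radius <- function(A) {
  D <- dim(A)[1]; p <- dim(A)[3]
  Cm <- matrix(0, D * p, D * p)
  for (k in seq_len(p)) Cm[1:D, (k - 1) * D + 1:D] <- A[, , k]
  if (p > 1) Cm[(D + 1):(D * p), 1:(D * (p - 1))] <- diag(D * (p - 1))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

# Biphasic pulse of `dur` seconds (one sine period under a Hann taper).
biphasic_pulse <- function(dur, fs) {
  n <- round(dur * fs)
  tau <- seq_len(n) / n
  sin(2 * pi * tau) * 0.5 * (1 - cos(2 * pi * tau))
}

#' Simulate a synthetic multi-subject balance-experiment dataset
#'
#' Generates epoched EEG-like data with known ground truth (see
#' [sim_config()]). The brain component is a time-varying VAR process on the
#' analysis-rate grid whose only nonzero coefficients are the planted
#' cross-couplings (its innovations carry `noise_sd`, so with no couplings and
#' no other components the output is white noise of that SD). When `fs_raw >
#' fs_out` the VAR component is spline-interpolated to the acquisition rate and
#' the deterministic components (oscillators, sway, impulse, blinks) are
#' synthesized directly at `fs_raw`; decimation then recovers the planted AR
#' structure.
#'
#' @param config A [sim_config()].
#' @return A [new_recording()] with `ground_truth = config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "bn_sim_config"))
  A_pre <- coupling_cube(config, "pre")
  A_post <- coupling_cube(config, "post")
  for (cond in c("pre", "post")) {
    A <- if (cond == "pre") A_pre else A_post
    r <- companion_radius(A)
    if (r >= 1) {
      stop(sprintf(
        "unstable AR system (%s-onset coefficients, spectral radius %.3f >= 1)",
        cond, r))
    }
  }

  fs <- config$fs_raw
  up <- config$fs_raw / config$fs_out
  T_out <- round(config$epoch_length * config$fs_out)
  T_raw <- round(config$epoch_length * config$fs_raw)
  onset_out <- floor(config$onset_time * config$fs_out) + 1L
  onset_raw <- floor(config$onset_time * config$fs_raw) + 1L
  D <- length(config$channel_names)
  has_eog <- !is.null(config$eog)
  ch_names <- c(config$channel_names, if (has_eog) "EOG")
  t_raw <- (seq_len(T_raw) - 1) / fs
  post <- seq(onset_raw, T_raw)
  tau_post <- t_raw[post] - config$onset_time   # time since onset

  set.seed(config$seed)
  data <- array(0, dim = c(config$n_subjects, config$n_trials,
                           length(ch_names), T_raw))

  impulse <- if (config$onset_impulse_amplitude > 0) {
    config$onset_impulse_amplitude * biphasic_pulse(0.2, fs)
  } else numeric(0)
  blink_shape <- biphasic_pulse(0.3, fs)

  prop <- NULL
  if (has_eog) {
    prop <- config$eog$propagation
    if (is.null(names(prop))) {
      prop <- stats::setNames(rep_len(prop, D), config$channel_names)
    } else {
      full <- stats::setNames(numeric(D), config$channel_names)
      full[names(prop)] <- prop
      prop <- full
    }
  }

  for (s in seq_len(config$n_subjects)) {
    for (r in seq_len(config$n_trials)) {
      eps <- matrix(rnorm(D * T_out, sd = config$noise_sd), D, T_out)
      xb <- var_simulate_cpp(A_pre, A_post, onset_out - 1L, eps)
      x <- if (up > 1) {
        t(apply(xb, 1, function(row) {
          spline(x = (seq_len(T_out) - 1) / config$fs_out, y = row,
                 xout = t_raw, method = "natural")$y
        }))
      } else xb

      for (os in config$oscillators) {
        env <- rep(1, T_raw)
        if (!is.null(config$alpha_drop) && os$freq >= 8 && os$freq <= 13) {
          drop_idx <- which(t_raw >= config$onset_time &
                            t_raw < config$onset_time + config$alpha_drop[2])
          env[drop_idx] <- 1 - config$alpha_drop[1]
        }
        # independent realization per channel: a waveform shared across
        # channels would plant spurious cross-channel AR structure
        for (ch in os$channels) {
          f <- os$freq + rnorm(1, 0, os$freq_jitter_sd)
          ci <- match(ch, config$channel_names)
          z <- ar2_oscillation(T_raw, fs, f, os$bandwidth,
                               os$amplitude / sqrt(2))
          x[ci, ] <- x[ci, ] + env * z
        }
      }

      if (!is.null(config$sway) && config$sway$amplitude > 0) {
        sw <- numeric(length(tau_post))
        for (k in seq_len(config$sway$n_harmonics)) {
          phik <- if (config$sway$phase_locked) 0 else runif(1, 0, 2 * pi)
          sw <- sw + (config$sway$amplitude / k) *
            sin(2 * pi * k * config$sway$f0 * tau_post + phik)
        }
        gains <- sway_gains(config$sway, config$channel_names)
        x[, post] <- x[, post, drop = FALSE] + outer(gains, sw)
      }

      if (length(impulse) > 0) {
        idx <- onset_raw + seq_along(impulse) - 1L
        idx_ok <- idx <= T_raw
        x[, idx[idx_ok]] <- sweep(x[, idx[idx_ok], drop = FALSE], 2,
                                  impulse[idx_ok], "+")
      }

      if (has_eog) {
        eog_tr <- numeric(T_raw)
        n_blinks <- stats::rpois(1, config$eog$blink_rate * config$epoch_length)
        if (n_blinks > 0) {
          starts <- sort(sample.int(T_raw - length(blink_shape), n_blinks,
                                    replace = TRUE))
          for (b in starts) {
            idx <- b + seq_along(blink_shape) - 1L
            eog_tr[idx] <- eog_tr[idx] + config$eog$amplitude * blink_shape
          }
        }
        eog_tr <- eog_tr + rnorm(T_raw, sd = config$noise_sd)
        x <- x + outer(prop, eog_tr)
        x <- rbind(x, eog_tr)
      }

      data[s, r, , ] <- x
    }
  }

  new_recording(data, fs = fs, channel_names = ch_names,
                onset_sample = onset_raw,
                eog_channel = if (has_eog) "EOG" else NULL,
                ground_truth = config)
}

#' Platform displacement trace
#'
#' @param displacement 2 x samples matrix (rows: medial-lateral,
#'   anterior-posterior displacement, arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param true_release_sample Sample index of the anchor release.
#' @return An object of class `bn_platform`.
#' @export
new_platform_trace <- function(displacement, fs, true_release_sample) {
  stopifnot(is.matrix(displacement), nrow(displacement) == 2,
            all(is.finite(displacement)))
  n <- ncol(displacement)
  if (!(true_release_sample > 0 && true_release_sample < n)) {
    stop("release sample must lie strictly inside the trace")
  }
  structure(list(displacement = displacement, fs = fs,
                 true_release_sample = as.integer(true_release_sample)),
            class = "bn_platform")
}

#' Simulate a platform-motion trace with an anchor release
#'
#' Before the release the platform is held deflected by the anchor (constant
#' offset + small measurement noise); at release it swings back and oscillates
#' at the sway frequency with slowly decaying amplitude. The 30 s default trial
#' length and a release somewhere in the 5th-20th second mirror the experiment.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Trace duration in seconds.
#' @param release_time Anchor release time in seconds (must lie inside the
#'   trace).
#' @param seed Integer seed.
#' @param f0 Platform oscillation frequency (Hz).
#' @return A [new_platform_trace()] with `true_release_sample =
#'   round(release_time * fs)`.
#' @export
simulate_platform <- function(fs = 1000, duration = 30, release_time = 10,
                              seed = 1L, f0 = 2.6) {
  if (!(release_time > 0 && release_time < duration)) {
    stop("release_time must lie strictly inside the trace")
  }
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  rel <- round(release_time * fs)
  t <- (seq_len(n) - 1) / fs
  ml <- rep(2.2, n)
  ap <- numeric(n)
  post <- which(seq_len(n) > rel)
  tau <- t[post] - release_time
  ml[post] <- 2.2 * cos(2 * pi * f0 * tau) * exp(-tau / 4) +
    0.5 * sin(2 * pi * f0 * tau)
  ap[post] <- 0.3 * sin(2 * pi * f0 * tau + 1)
  noise_sd <- 0.02
  ml <- ml + rnorm(n, sd = noise_sd)
  ap <- ap + rnorm(n, sd = noise_sd)
  new_platform_trace(rbind(ml, ap), fs, rel)
}
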