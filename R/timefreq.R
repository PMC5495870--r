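#' Time-frequency map container
#'
#' @param values `time x frequency` numeric matrix.
#' @param kind One of `"amplitude"` (microvolts), `"phase"` (radians), `"pli"`
#'   (unitless in \[0, 1\]) or `"binary"` (0/1 significance).
#' @param times,freqs Strictly increasing axes (seconds, Hz).
#' @param channel Channel label (optional).
#' @return An object of class `bn_tfm`.
#' @export
new_tfm <- function(values, kind = c("amplitude", "phase", "pli", "binary"),
                    times, freqs, channel = NA_character_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times), ncol(values) == length(freqs),
            all(diff(times) > 0), all(diff(freqs) > 0))
  if (kind == "pli" && any(values < -1e-12 | values > 1 + 1e-12, na.rm = TRUE)) {
    stop("PLI values must lie in [0, 1]")
  }
  if (kind == "binary" && !all(values %in% c(0, 1) | is.na(values))) {
    stop("binary map values must be 0 or 1")
  }
  structure(list(values = values, kind = kind, times = times, freqs = freqs,
                 channel = channel),
            class = "bn_tfm")
}

#' @export
print.bn_tfm <- function(x, ...) {
  cat(sprintf("<bn_tfm:%s> %d times x %d freqs (%.2f-%.2f s, %.1f-%.1f Hz)%s\n",
              x$kind, length(x$times), length(x$freqs),
              min(x$times), max(x$times), min(x$freqs), max(x$freqs),
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]")))
  invisible(x)
}

#' @export
tidy.bn_tfm <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    value = as.vector(x$values),
    kind = x$kind,
    channel = x$channel
  )
}

#' Multi-window Gabor dictionary
#'
#' @param window_widths Gaussian window widths in seconds (support truncated at
#'   +/- 3 sigma with sigma = width / 6), sorted ascending.
#' @param hop Hop between analysis time points, seconds.
#' @param freqs Analysis frequency grid, Hz.
#' @return A list of class `bn_gabor_dict`.
#' @export
gabor_dictionary <- function(window_widths = c(0.25, 0.5, 1.0), hop = 0.05,
                             freqs = seq(0.5, 50, by = 0.5)) {
  stopifnot(length(window_widths) > 0, all(window_widths > 0), hop > 0)
  structure(list(window_widths = sort(window_widths), hop = hop, freqs = freqs),
            class = "bn_gabor_dict")
}

#' Matched multi-window Gabor transform (MGT)
#'
#' Computes Gabor coefficients of a single-channel signal under every window
#' width in the dictionary and, per time-frequency tile, keeps the width with
#' the largest amplitude (the matched window): steady oscillations are captured
#' with long windows, transients with short ones, giving each component an
#' individually suited time-frequency resolution. Amplitude is calibrated so a
#' unit sinusoid yields 1 at its ridge (windows are renormalized near the
#' epoch edges so the calibration holds there too).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param dict A [gabor_dictionary()].
#' @return List with elements `amplitude` and `phase` (both [new_tfm()]).
#' @export
mgt <- function(x, fs, dict = gabor_dictionary()) {
  n <- length(x)
  widest <- round(max(dict$window_widths) * fs)
  if (n <= widest) stop("signal must be longer than the widest window")
  freqs <- dict$freqs[dict$freqs < fs / 2]
  centers <- seq(1, n, by = max(1L, round(dict$hop * fs)))
  times <- (centers - 1) / fs

  best_amp <- matrix(-Inf, length(centers), length(freqs))
  best_phase <- matrix(0, length(centers), length(freqs))
  for (w in dict$window_widths) {
    sigma <- w * fs / 6
    half <- ceiling(3 * sigma)
    off <- -half:half
    g <- exp(-off^2 / (2 * sigma^2))
    # basis: freqs x window-length, e^{-i 2 pi f tau} g(tau)
    B <- exp(-1i * 2 * pi * outer(freqs, off / fs)) *
      matrix(g, length(freqs), length(off), byrow = TRUE)
    idx <- outer(off, centers, "+")
    valid <- idx >= 1 & idx <= n
    xs <- matrix(0, length(off), length(centers))
    xs[valid] <- x[idx[valid]]
    gsum <- as.vector(crossprod(g, valid))         # per-center window mass
    coefs <- B %*% xs                              # freqs x centers
    amp <- 2 * Mod(coefs) / matrix(gsum, length(freqs), length(centers),
                                   byrow = TRUE)
    ph <- Arg(coefs)
    amp <- t(amp); ph <- t(ph)                     # time x freq
    better <- amp > best_amp
    best_amp[better] <- amp[better]
    best_phase[better] <- ph[better]
  }
  list(
    amplitude = new_tfm(best_amp, "amplitude", times, freqs),
    phase = new_tfm(best_phase, "phase", times, freqs)
  )
}

#' Phase-locking index across trials
#'
#' `PLI(t, f) = |mean over trials of exp(i * phase)|`: 1 for perfectly
#' phase-locked oscillations, tending to 0 for uniformly distributed phases.
#' Invariant under adding a common phase constant to every trial.
#'
#' @param phase_maps List of phase [new_tfm()] maps (one per trial) with
#'   identical axes, or a 3-D array `[trial, time, freq]` of phases.
#' @param times,freqs Axes, required when `phase_maps` is an array.
#' @return A [new_tfm()] of kind `"pli"`.
#' @export
pli <- function(phase_maps, times = NULL, freqs = NULL) {
  if (is.list(phase_maps)) {
    if (length(phase_maps) < 2) stop("PLI needs >= 2 trials")
    ref <- phase_maps[[1]]
    for (m in phase_maps[-1]) {
      if (!isTRUE(all.equal(ref$times, m$times)) ||
          !isTRUE(all.equal(ref$freqs, m$freqs))) {
        stop("trial phase maps have mismatched axes")
      }
    }
    arr <- array(0, dim = c(length(phase_maps), length(ref$times),
                            length(ref$freqs)))
    for (i in seq_along(phase_maps)) arr[i, , ] <- phase_maps[[i]]$values
    times <- ref$times; freqs <- ref$freqs
    chan <- ref$channel
  } else {
    arr <- phase_maps
    if (dim(arr)[1] < 2) stop("PLI needs >= 2 trials")
    chan <- NA_character_
  }
  z <- exp(1i * arr)
  m <- apply(z, c(2, 3), mean)
  new_tfm(pmin(Mod(m), 1), "pli", times, freqs, channel = chan)
}

#' Rayleigh critical value for the phase-locking index
#'
#' Large-sample inversion of the Rayleigh test of phase uniformity:
#' `R_crit = sqrt(-log(alpha) / n)`. PLI values above it reject uniform phases
#' at level `alpha`.
#'
#' @param n_trials Number of trials entering the PLI.
#' @param alpha Significance level.
#' @return Critical PLI value.
#' @export
rayleigh_threshold <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 2, alpha > 0, alpha < 1)
  sqrt(-log(alpha) / n_trials)
}

#' Threshold a PLI map at the Rayleigh critical value
#'
#' @param pli_map A PLI [new_tfm()].
#' @param n_trials Number of trials the map was computed from.
#' @param alpha Significance level.
#' @return A binary [new_tfm()] (1 = significant phase locking).
#' @export
threshold_pli <- function(pli_map, n_trials, alpha = 0.05) {
  stopifnot(pli_map$kind == "pli")
  crit <- rayleigh_threshold(n_trials, alpha)
  new_tfm((pli_map$values > crit) * 1, "binary", pli_map$times, pli_map$freqs,
          channel = pli_map$channel)
}

#' Artifact-screening configuration for sway harmonics
#'
#' @param f0 Fundamental sway frequency, Hz.
#' @param n_harmonics Number of harmonics to check (k = 1..n).
#' @param alpha Significance level used for the underlying binary map.
#' @param guard_band Frequency guard band (Hz) around analysis bands.
#' @param window Post-onset time window (seconds) over which the significant
#'   fraction is evaluated.
#' @param min_fraction Minimum significant fraction for a harmonic to be
#'   flagged.
#' @return A list of class `bn_screen_config`.
#' @export
artifact_screen_config <- function(f0 = 2.6, n_harmonics = 4, alpha = 0.05,
                                   guard_band = 1, window = c(3.5, 8),
                                   min_fraction = 0.5) {
  stopifnot(f0 > 0, alpha > 0, alpha < 1)
  structure(list(f0 = f0, n_harmonics = n_harmonics, alpha = alpha,
                 guard_band = guard_band, window = window,
                 min_fraction = min_fraction),
            class = "bn_screen_config")
}

#' Screen a binary PLI map for phase-locked sway harmonics
#'
#' A movement artifact that is phase-locked to the onset must also have
#' phase-locked higher harmonics; each harmonic row `k * f0` is flagged when
#' its significant fraction inside the post-onset window reaches
#' `min_fraction`. An analysis band is declared contaminated when any flagged
#' harmonic lies within `guard_band` of it.
#'
#' @param binary_map A binary [new_tfm()] (output of [threshold_pli()]).
#' @param cfg An [artifact_screen_config()].
#' @param bands Named list of analysis bands (Hz).
#' @return List with `harmonics` (tibble: `k`, `freq`, `fraction`, `flagged`)
#'   and `verdicts` (tibble: `band`, `lo`, `hi`, `contaminated`).
#' @export
screen_harmonics <- function(binary_map, cfg = artifact_screen_config(),
                             bands = list(theta = c(5, 7), alpha = c(9, 11))) {
  stopifnot(binary_map$kind == "binary")
  ti <- which(binary_map$times >= cfg$window[1] &
              binary_map$times <= cfg$window[2])
  if (length(ti) == 0) stop("screening window outside the map's time axis")
  fstep <- if (length(binary_map$freqs) > 1) min(diff(binary_map$freqs)) else Inf
  ks <- seq_len(cfg$n_harmonics)
  fk <- ks * cfg$f0
  frac <- flag <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    fi <- which.min(abs(binary_map$freqs - fk[i]))
    if (abs(binary_map$freqs[fi] - fk[i]) > fstep) next  # harmonic off-grid
    frac[i] <- mean(binary_map$values[ti, fi])
    flag[i] <- frac[i] >= cfg$min_fraction
  }
  harmonics <- tibble::tibble(k = ks, freq = fk, fraction = frac,
                              flagged = as.logical(flag))
  verdicts <- purrr::imap_dfr(bands, function(b, nm) {
    contam <- any(harmonics$flagged & harmonics$freq >= b[1] - cfg$guard_band &
                  harmonics$freq <= b[2] + cfg$guard_band, na.rm = TRUE)
    tibble::tibble(band = nm, lo = b[1], hi = b[2], contaminated = contam)
  })
  list(harmonics = harmonics, verdicts = verdicts)
}
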