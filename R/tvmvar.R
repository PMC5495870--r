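#' Kalman-filter configuration for time-variant MVAR estimation
#'
#' `c1` is the adaptation rate of the (diagonal) measurement-noise covariance:
#' the per-channel residual variance is an exponentially smoothed average of
#' squared innovations with rate `c1`. `c2` is the step width of the
#' coefficient random walk (process-noise variance added to every state
#' component per time step). The study operating point is `c1 = 0.02`,
#' `c2 = 0.005`, order `p = 20` at 100 Hz.
#'
#' @param c1 Covariance-adaptation constant (> 0).
#' @param c2 Random-walk step width (> 0): the standard deviation of the
#'   per-step coefficient increment, so the process-noise covariance is
#'   `c2^2 * I`. Set `c2_is_variance = TRUE` to treat `c2` as the variance
#'   itself (`c2 * I`).
#' @param p Model order (>= 1).
#' @param init_coeffs Initial value of every AR coefficient.
#' @param init_state_cov Initial state covariance scale.
#' @param c2_is_variance Alternative reading of the step-width parameter.
#' @return A list of class `bn_kalman_config`.
#' @export
kalman_config <- function(c1 = 0.02, c2 = 0.005, p = 20,
                          init_coeffs = 0, init_state_cov = 1,
                          c2_is_variance = FALSE) {
  stopifnot(c1 > 0, c2 > 0, p >= 1)
  structure(list(c1 = c1, c2 = c2, p = as.integer(p),
                 init_coeffs = init_coeffs, init_state_cov = init_state_cov,
                 c2_is_variance = c2_is_variance),
            class = "bn_kalman_config")
}

#' Construct a time-variant MVAR model object
#'
#' Mostly used internally by [fit_kalman()]; also handy to wrap known (true)
#' coefficients for oracle computations. `A` is `[target, source, lag, time]`;
#' time-invariant input (`[target, source, lag]`) is replicated over `n_times`.
#'
#' @param A Coefficient array `[D, D, p, T]` (or `[D, D, p]` plus `n_times`).
#' @param sigma2 Residual variances: `D x T` matrix or length-D vector.
#' @param fs Sampling rate (Hz).
#' @param channel_names Channel labels.
#' @param n_times Number of time points when `A` is time-invariant.
#' @param burn_in_s Leading seconds of the trajectory considered unreliable.
#' @return An object of class `bn_tvmvar`.
#' @export
tvmvar_model <- function(A, sigma2, fs, channel_names = NULL, n_times = NULL,
                         burn_in_s = 1) {
  if (length(dim(A)) == 3) {
    if (is.null(n_times)) stop("n_times required for time-invariant A")
    A <- array(A, dim = c(dim(A), n_times))
  }
  d <- dim(A)
  if (is.vector(sigma2)) sigma2 <- matrix(sigma2, d[1], d[4])
  stopifnot(d[1] == d[2], nrow(sigma2) == d[1], ncol(sigma2) == d[4])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[1]))
  bad <- which(apply(sigma2 <= 0, 1, any))
  if (length(bad) > 0) {
    stop("zero or negative residual variance for channel(s): ",
         paste(channel_names[bad], collapse = ", "))
  }
  structure(list(A = A, sigma2 = sigma2, fs = fs, p = d[3],
                 channel_names = channel_names, burn_in_s = burn_in_s),
            class = "bn_tvmvar")
}

#' @export
print.bn_tvmvar <- function(x, ...) {
  d <- dim(x$A)
  cat(sprintf("<bn_tvmvar> D = %d channels, order p = %d, %d time points @ %g Hz\n",
              d[1], d[3], d[4], x$fs))
  invisible(x)
}

#' Fit a time-variant MVAR model by multi-trial linear Kalman filtering
#'
#' The vectorized AR coefficients evolve as a random walk; each sample is
#' regressed on the `p` previous samples of all channels; all trials update the
#' same state sequentially at each time step before time advances (so no
#' information is lost to trial averaging); the measurement-noise variance per
#' channel is adapted by exponential smoothing of squared innovations. The
#' first `burn_in_s` seconds of the coefficient trajectory are marked
#' unreliable.
#'
#' @param rec An epoched [new_recording()].
#' @param subject Subject index to fit.
#' @param config A [kalman_config()].
#' @param channels Channels to include (default: all EEG channels).
#' @param burn_in_s Burn-in duration in seconds.
#' @return A [tvmvar_model()].
#' @export
fit_kalman <- function(rec, subject = 1, config = kalman_config(),
                       channels = eeg_channels(rec), burn_in_s = 1) {
  y <- subject_cube(rec, subject, channels)  # D x T x trials
  D <- dim(y)[1]; T_n <- dim(y)[2]
  if (config$p >= T_n) stop("model order p must be smaller than the sample count")
  q <- if (isTRUE(config$c2_is_variance)) config$c2 else config$c2^2
  fit <- kalman_fit_cpp(y, config$p, config$c1, q,
                        config$init_coeffs, config$init_state_cov)
  A <- array(fit$A, dim = c(D, D, config$p, T_n))
  tvmvar_model(A, fit$sigma2, fs = rec$fs, channel_names = channels,
               burn_in_s = burn_in_s)
}

#' Per-time-point stability of a fitted tvMVAR model
#'
#' Spectral radius of the companion matrix at each (subsampled) time point; the
#' model is flagged wherever the radius reaches 1.
#'
#' @param model A [tvmvar_model()].
#' @param every Check every `every`-th time point.
#' @return A tibble with columns `time_index`, `radius`, `stable`.
#' @export
stability <- function(model, every = 10L) {
  idx <- seq(1L, dim(model$A)[4], by = every)
  r <- vapply(idx, function(t) {
    companion_radius(array(model$A[, , , t], dim(model$A)[1:3]))
  }, numeric(1))
  tibble::tibble(time_index = idx, radius = r, stable = r < 1)
}

#' Select the MVAR model order by Akaike's information criterion
#'
#' Fits stationary VAR(p) models by pooled least squares across trials and
#' computes the multivariate AIC
#' `N * log det(residual covariance) + 2 * p * D^2`.
#'
#' @param rec An epoched [new_recording()].
#' @param subject Subject index.
#' @param p_range Candidate orders.
#' @param channels Channels to include.
#' @return A list with `order` (the argmin) and `table` (tibble of `p`, `aic`).
#' @export
select_order <- function(rec, subject = 1, p_range = 1:20,
                         channels = eeg_channels(rec)) {
  y <- subject_cube(rec, subject, channels)
  D <- dim(y)[1]; T_n <- dim(y)[2]; R <- dim(y)[3]
  if (max(p_range) >= T_n / 2) stop("max(p_range) must be < samples/2")
  aic <- rep(NA_real_, length(p_range))
  for (pi in seq_along(p_range)) {
    p <- p_range[pi]
    rows <- R * (T_n - p)
    X <- matrix(0, rows, D * p)
    Y <- matrix(0, rows, D)
    row <- 1L
    for (r in seq_len(R)) {
      for (k in seq_len(p)) {
        X[row:(row + T_n - p - 1), (k - 1) * D + 1:D] <-
          t(y[, (p - k + 1):(T_n - k), r])
      }
      Y[row:(row + T_n - p - 1), ] <- t(y[, (p + 1):T_n, r])
      row <- row + T_n - p
    }
    B <- tryCatch(qr.solve(X, Y), error = function(e) NULL)
    if (is.null(B)) { warning("order ", p, " skipped (singular regression)"); next }
    Eres <- Y - X %*% B
    Sig <- crossprod(Eres) / rows
    dt <- determinant(Sig, logarithm = TRUE)
    if (dt$sign <= 0) { warning("order ", p,
                                " skipped (residual covariance not PD)"); next }
    aic[pi] <- rows * as.numeric(dt$modulus) + 2 * p * D^2
  }
  tab <- tibble::tibble(p = p_range, aic = aic)
  list(order = p_range[which.min(aic)], table = tab)
}

#' Stationary VAR coefficients by pooled least squares
#'
#' Reference (time-invariant) fit used to check the Kalman trajectory on
#' stationary data.
#'
#' @inheritParams select_order
#' @param p Model order.
#' @return List with `A` (array `[D, D, p]`) and `sigma2` (length-D residual
#'   variances).
#' @export
fit_var_ols <- function(rec, subject = 1, p = 1,
                        channels = eeg_channels(rec)) {
  y <- subject_cube(rec, subject, channels)
  D <- dim(y)[1]; T_n <- dim(y)[2]; R <- dim(y)[3]
  rows <- R * (T_n - p)
  X <- matrix(0, rows, D * p); Y <- matrix(0, rows, D); row <- 1L
  for (r in seq_len(R)) {
    for (k in seq_len(p)) {
      X[row:(row + T_n - p - 1), (k - 1) * D + 1:D] <-
        t(y[, (p - k + 1):(T_n - k), r])
    }
    Y[row:(row + T_n - p - 1), ] <- t(y[, (p + 1):T_n, r])
    row <- row + T_n - p
  }
  B <- qr.solve(X, Y)                       # (D*p) x D ; column i = channel i
  A <- array(0, dim = c(D, D, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(k - 1) * D + 1:D, ])
  Eres <- Y - X %*% B
  list(A = A, sigma2 = colSums(Eres^2) / rows)
}

#' Parametric amplitude time-frequency maps from a tvMVAR model
#'
#' At each time point the transfer matrix `H(f, t) = Abar(f, t)^{-1}` with
#' `Abar(f, t) = I - sum_k A_k(t) exp(-i 2 pi f k / fs)` yields the channel
#' auto-spectra `diag(H Sigma H*)`; the amplitude map is
#' `sqrt(2 * df * S_ii(f, t))` on the requested frequency grid. The default
#' 0-50 Hz / 0.5 Hz grid is a display grid, not a resolution claim: the
#' effective frequency resolution of the parametric spectrum (and of the PDC
#' built from the same model) is set by the model order.
#'
#' @param model A [tvmvar_model()].
#' @param freqs Frequency grid (Hz), inside `(0, fs/2)`.
#' @return A named list of [new_tfm()] amplitude maps, one per channel.
#' @export
parametric_tfm <- function(model, freqs = seq(0.5, model$fs / 2, by = 0.5)) {
  stopifnot(all(freqs > 0), all(freqs < model$fs / 2 + 1e-9))
  d <- dim(model$A)
  Acube <- array(model$A, dim = c(d[1], d[2] * d[3], d[4]))
  df <- if (length(freqs) > 1) diff(freqs[1:2]) else 1
  v <- tv_spectrum_cpp(Acube, model$sigma2, model$fs, freqs, d[3], df)
  arr <- array(v, dim = c(d[1], d[4], length(freqs)))
  times <- (seq_len(d[4]) - 1) / model$fs
  out <- lapply(seq_len(d[1]), function(i) {
    new_tfm(arr[i, , ], kind = "amplitude", times = times, freqs = freqs,
            channel = model$channel_names[i])
  })
  stats::setNames(out, model$channel_names)
}
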