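# Brute-force gPDC oracle: direct evaluation of the formula from the true
# time-invariant coefficients, independent of the package's compiled path.
gpdc_oracle <- function(A, sigma2, fs, freqs) {
  D <- dim(A)[1]; p <- dim(A)[3]
  out <- array(0, dim = c(D, D, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(D) + 0i
    for (k in seq_len(p)) {
      Abar <- Abar - A[, , k] * exp(-1i * 2 * pi * freqs[fi] * k / fs)
    }
    for (j in seq_len(D)) {
      num <- Mod(Abar[, j]) / sqrt(sigma2)
      out[, j, fi] <- num / sqrt(sum(num^2))
    }
  }
  out
}

# Simulate a stationary VAR(p) directly in R (independent of the C++ path).
var_sim_oracle <- function(A, n, sd = 1) {
  D <- dim(A)[1]; p <- dim(A)[3]
  burn <- 200
  x <- matrix(0, D, n + burn)
  for (t in (p + 1):(n + burn)) {
    acc <- rnorm(D, sd = sd)
    for (k in seq_len(p)) acc <- acc + A[, , k] %*% x[, t - k]
    x[, t] <- acc
  }
  x[, (burn + 1):(burn + n), drop = FALSE]
}

# A small rank-M nonnegative 4-mode tensor with known loadings.
planted_tensor <- function(dims, M, seed) {
  set.seed(seed)
  loadings <- lapply(dims, function(d) matrix(runif(d * M, 0.2, 1), d, M))
  X <- array(0, dim = dims)
  for (m in seq_len(M)) {
    X <- X + outer(outer(outer(loadings[[1]][, m], loadings[[2]][, m]),
                         loadings[[3]][, m]), loadings[[4]][, m])
  }
  list(X = X, loadings = loadings)
}

# Planted-coupling recovery experiment (shared by connectivity/stats tests and
# the acceptance suite): small central montage, default coupling CPz -> Cz,
# rhythm and sway generators off so the directed AR structure is the only
# planted cross-channel dependence.
recovery_experiment <- function(seed, n_subjects = 3) {
  cfg <- sim_config(n_subjects = n_subjects, n_trials = 10,
                    channel_names = c("C1", "Cz", "C2", "CP1", "CPz", "CP2"),
                    oscillators = list(), sway = NULL, seed = seed)
  rec <- simulate_dataset(cfg)
  rec <- rereference_common_average(rec)
  rec <- correct_ocular(rec)
  rec <- downsample(rec, cfg$fs_raw / cfg$fs_out)
  pdcs <- lapply(seq_len(n_subjects), function(s) {
    gpdc(fit_kalman(rec, s), freqs = seq(4, 8, 0.5))
  })
  gm <- grand_mean_pdc(pdcs)
  m <- roi_mean(gm, roi_spec(c(5, 7), analysis_intervals()$TI4, "theta TI4"))
  fi <- which(pdcs[[1]]$freqs >= 5 & pdcs[[1]]$freqs <= 7)
  cas <- lapply(pdcs, condition_ans, onset_time = 3,
                exclude = list(c(0, 1), c(3, 3.5)))
  list(
    roi = m,
    top_is_planted = m["Cz", "CPz"] == max(m),
    forward_beats_reverse = m["Cz", "CPz"] > m["CPz", "Cz"],
    bus_gt_bss = mean(sapply(cas, function(x) mean(x$ans_bus[fi]))) >
      mean(sapply(cas, function(x) mean(x$ans_bss[fi])))
  )
}
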