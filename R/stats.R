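#' Bootstrap configuration for confidence tubes
#'
#' @param n_replicates Number of bootstrap replications.
#' @param q_lo,q_hi Lower/upper quantiles defining the tube.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `bn_boot_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000, q_lo = 0.025, q_hi = 0.975,
                             seed = NULL) {
  stopifnot(q_lo > 0, q_lo < q_hi, q_hi < 1, n_replicates >= 2)
  structure(list(n_replicates = n_replicates, q_lo = q_lo, q_hi = q_hi,
                 seed = seed),
            class = "bn_boot_config")
}

#' Bootstrap confidence tube for an across-subject mean time course
#'
#' Subjects (rows) are resampled with replacement `n_replicates` times; for
#' each replicate the across-subject mean time course is computed and the tube
#' is the pointwise `[q_lo, q_hi]` quantile band of those resampled means
#' (pointwise, not simultaneous). Resampling unit is the subject, since the
#' inference is across subjects.
#'
#' @param x `subjects x time` numeric matrix of band-amplitude time courses.
#' @param cfg A [bootstrap_config()].
#' @param times Optional time axis (seconds).
#' @param condition Optional condition label.
#' @return An object of class `bn_tube` with tibble `$data` (columns `time`,
#'   `mean`, `lower`, `upper`) and the configuration.
#' @export
confidence_tube <- function(x, cfg = bootstrap_config(), times = NULL,
                            condition = NA_character_) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("confidence tube needs >= 3 subjects")
  if (is.null(times)) times <- seq_len(ncol(x))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  idx <- matrix(sample.int(n, n * cfg$n_replicates, replace = TRUE),
                nrow = cfg$n_replicates)
  W <- t(apply(idx, 1, tabulate, nbins = n)) / n   # replicate weights
  boot_means <- W %*% x                             # replicates x time
  # Hyndman-Fan type 6 quantiles: the usual percentile-bootstrap convention,
  # slightly wider than the default interpolation and closer to nominal
  # coverage at moderate replicate counts.
  lo <- apply(boot_means, 2, quantile, probs = cfg$q_lo, names = FALSE,
              type = 6)
  hi <- apply(boot_means, 2, quantile, probs = cfg$q_hi, names = FALSE,
              type = 6)
  structure(list(
    data = tibble::tibble(time = times, mean = colMeans(x),
                          lower = lo, upper = hi, condition = condition),
    config = cfg
  ), class = "bn_tube")
}

#' @export
print.bn_tube <- function(x, ...) {
  cat(sprintf("<bn_tube> %d time points, %d bootstrap replicates [%g, %g]\n",
              nrow(x$data), x$config$n_replicates, x$config$q_lo, x$config$q_hi))
  invisible(x)
}

#' @export
tidy.bn_tube <- function(x, ...) x$data

#' Pointwise overlap of two confidence tubes
#'
#' Non-overlap of the tubes at a time point indicates a significant difference
#' between the two conditions there.
#'
#' @param tube_a,tube_b [confidence_tube()] results on the same time axis.
#' @return Logical vector, `TRUE` where the intervals intersect.
#' @export
tube_overlap <- function(tube_a, tube_b) {
  if (!isTRUE(all.equal(tube_a$data$time, tube_b$data$time))) {
    stop("tubes have mismatched time axes")
  }
  tube_a$data$lower <= tube_b$data$upper & tube_b$data$lower <= tube_a$data$upper
}

#' Bonferroni-corrected paired t-tests on average node strength
#'
#' Tests, per frequency bin, whether the ANS differs between the stable (BSS)
#' and unstable (BUS) condition using a two-sided paired t-test across
#' subjects; significance is assessed at `alpha / n_bins` (Bonferroni over the
#' analyzed frequency bins).
#'
#' @param ans_bss,ans_bus `subjects x frequency-bins` matrices of ANS values.
#' @param freqs Optional frequency axis (Hz).
#' @param alpha Familywise significance level.
#' @return A tibble with columns `freq`, `mean_diff`, `statistic`, `df`,
#'   `p_value`, `significant` (Bonferroni-corrected verdict).
#' @export
paired_ttest_ans <- function(ans_bss, ans_bus, freqs = NULL, alpha = 0.05) {
  ans_bss <- as.matrix(ans_bss); ans_bus <- as.matrix(ans_bus)
  if (!all(dim(ans_bss) == dim(ans_bus))) stop("condition matrices must be paired")
  n <- nrow(ans_bss)
  if (n < 2) stop("paired t-test needs >= 2 subjects")
  nb <- ncol(ans_bss)
  if (is.null(freqs)) freqs <- seq_len(nb)
  d <- ans_bus - ans_bss
  md <- colMeans(d)
  sdd <- apply(d, 2, sd)
  tstat <- pv <- numeric(nb)
  for (j in seq_len(nb)) {
    if (sdd[j] == 0) {
      if (md[j] == 0) { tstat[j] <- 0; pv[j] <- 1 }
      else stop("exact tie: nonzero constant differences with zero variance")
    } else {
      tstat[j] <- md[j] / (sdd[j] / sqrt(n))
      pv[j] <- 2 * pt(-abs(tstat[j]), df = n - 1)
    }
  }
  tibble::tibble(freq = freqs, mean_diff = md, statistic = tstat, df = n - 1,
                 p_value = pv, significant = pv < alpha / nb)
}
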