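test_that("an exact rank-1 nonnegative tensor is recovered perfectly", {
  pt <- planted_tensor(c(6, 5, 4, 3), M = 1, seed = 1)
  fit <- parafac(pt$X, M = 1, n_restarts = 3, seed = 2)
  expect_gte(fit$fit, 0.999)
  cong <- factor_congruence(fit$loadings, pt$loadings)
  expect_gte(min(cong$congruence), 0.999)
  expect_gt(fit$core_consistency, 99)
})

test_that("planted rank-3 factors survive 5% noise", {
  ok <- sapply(1:3, function(seed) {
    pt <- planted_tensor(c(10, 9, 8, 7), M = 3, seed = seed)
    set.seed(seed + 50)
    noisy <- pt$X + rnorm(length(pt$X), sd = 0.05 * sd(pt$X))
    fit <- parafac(noisy, M = 3, n_restarts = 5, seed = seed)
    all(abs(factor_congruence(fit$loadings, pt$loadings)$congruence) >= 0.95)
  })
  expect_true(all(ok))
})

test_that("HALS reconstruction error never increases", {
  pt <- planted_tensor(c(8, 7, 6, 5), M = 2, seed = 3)
  set.seed(4)
  noisy <- pt$X + rnorm(length(pt$X), sd = 0.1 * sd(pt$X))
  fit <- parafac(noisy, M = 3, n_restarts = 2, seed = 5)
  expect_true(all(diff(fit$sse_trace) <= 1e-8 * fit$sse_trace[1]))
})

test_that("scale is absorbed into the space mode, other modes unit norm", {
  pt <- planted_tensor(c(6, 5, 4, 3), M = 2, seed = 6)
  fit <- parafac(pt$X, M = 2, n_restarts = 3, seed = 7)
  for (mode in c("time", "frequency", "subject")) {
    expect_equal(unname(sqrt(colSums(fit$loadings[[mode]]^2))), rep(1, 2),
                 tolerance = 1e-8)
  }
  norms <- sqrt(colSums(fit$loadings$space^2))
  expect_true(all(diff(norms) <= 1e-12))   # ordered by magnitude
})

test_that("re-decomposition of a reconstructed tensor is congruent >= 0.99", {
  pt <- planted_tensor(c(7, 6, 5, 4), M = 2, seed = 8)
  f1 <- parafac(pt$X, M = 2, n_restarts = 3, seed = 9)
  Xhat <- array(0, dim = dim(pt$X))
  for (m in 1:2) {
    Xhat <- Xhat + outer(outer(outer(f1$loadings$space[, m],
                                     f1$loadings$time[, m]),
                               f1$loadings$frequency[, m]),
                         f1$loadings$subject[, m])
  }
  f2 <- parafac(Xhat, M = 2, n_restarts = 3, seed = 10)
  cong <- factor_congruence(f1, f2)
  expect_gte(min(abs(cong$congruence)), 0.99)
})

test_that("unconstrained ALS also fits an exact low-rank tensor", {
  pt <- planted_tensor(c(6, 5, 4, 3), M = 2, seed = 11)
  fit <- parafac(pt$X, M = 2, n_restarts = 3, nonneg = FALSE, seed = 12)
  expect_gte(fit$fit, 0.999)
})

test_that("congruence of orthogonal factors is near zero off the match", {
  I <- diag(4)
  la <- lapply(1:4, function(i) I[, 1:2])
  lb <- lapply(1:4, function(i) I[, 3:4])
  cong <- factor_congruence(la, lb)
  expect_lt(max(abs(cong$congruence)), 1e-12)
})

test_that("greedy matching recovers a factor permutation (brute-force oracle)", {
  pt <- planted_tensor(c(8, 7, 6, 5), M = 3, seed = 13)
  perm <- c(3, 1, 2)
  lp <- lapply(pt$loadings, function(A) A[, perm])
  cong <- factor_congruence(pt$loadings, lp)
  expect_equal(unname(order(perm)[cong$factor_a]),
               as.integer(unname(cong$factor_b)))
  expect_true(all(cong$congruence > 0.999))
  # brute-force best permutation maximizes the same total congruence
  prod_cong <- function(p) {
    tot <- 1
    for (n in 1:4) {
      An <- pt$loadings[[n]]; Bn <- lp[[n]]
      for (m in 1:3) {
        a <- An[, m] / sqrt(sum(An[, m]^2)); b <- Bn[, p[m]] / sqrt(sum(Bn[, p[m]]^2))
        tot <- tot * sum(a * b)
      }
    }
    tot
  }
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- perms[[which.max(sapply(perms, prod_cong))]]
  expect_equal(as.integer(unname(cong$factor_b[order(cong$factor_a)])),
               as.integer(best))
})

test_that("the connectivity tensor vectorizes pairs row-major with self-pairs skipped", {
  vals <- array(runif(3 * 3 * 4 * 2), dim = c(3, 3, 4, 2))
  mk <- function(v) structure(list(values = v, times = seq(0, 0.3, 0.1),
                                   freqs = c(5, 6),
                                   channel_names = c("Cz", "CPz", "Oz"),
                                   burn_in_s = 0), class = "bn_pdc")
  tens <- build_pdc_tensor(list(mk(vals), mk(vals + 1)), subset = c("Cz", "CPz", "Oz"))
  labels <- sort(c("Cz", "CPz", "Oz"))
  expect_equal(dim(tens$values), c(6, 4, 2, 2))
  expect_identical(tens$pair_labels,
                   paste0(rep(labels, each = 3), "->", rep(labels, 3))[
                     rep(labels, each = 3) != rep(labels, 3)])
  # entry check: pair CPz -> Cz at time 2, freq 1, subject 1
  i <- which(tens$pair_labels == "CPz->Cz")
  expect_equal(tens$values[i, 2, 1, 1],
               vals[match("Cz", c("Cz", "CPz", "Oz")),
                    match("CPz", c("Cz", "CPz", "Oz")), 2, 1])
  # round trip through pairs_to_matrix
  m <- pairs_to_matrix(tens, tens$values[, 2, 1, 1])
  expect_equal(m["Cz", "CPz"], tens$values[i, 2, 1, 1])
  expect_true(all(diag(m) == 0))
})

test_that("tensor crops and time decimation select the stated axes", {
  vals <- array(runif(2 * 2 * 10 * 4), dim = c(2, 2, 10, 4))
  mk <- structure(list(values = vals, times = seq(0, 0.9, 0.1),
                       freqs = c(4, 6, 8, 10), channel_names = c("Cz", "CPz"),
                       burn_in_s = 0), class = "bn_pdc")
  tens <- build_pdc_tensor(list(mk), subset = c("Cz", "CPz"),
                           time_range = c(0.2, 0.8), freq_range = c(5, 9),
                           time_decim = 2)
  expect_equal(tens$times, c(0.2, 0.4, 0.6))
  expect_equal(tens$freqs, c(6, 8))
  expect_error(build_pdc_tensor(list(mk), subset = c("Cz", "XX")),
               "absent")
})

test_that("degenerate tensors are rejected", {
  expect_error(parafac(array(0, dim = c(2, 2, 2, 2))), "all-zero")
  expect_error(parafac(array(1, dim = c(2, 2, 2)))) # not 4-mode
})
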