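#' Build the 4-mode connectivity tensor (space x time x frequency x subject)
#'
#' Vectorizes each subject's directed-pair PDC maps into the space mode. Pairs
#' are ordered row-major by (source, target) over the *sorted* electrode subset
#' with self-pairs skipped, so the space mode has `D * (D - 1)` entries; the
#' ordering is recorded in `pair_labels` for reproducibility.
#'
#' @param pdc_list List of [gpdc()] results, one per subject, sharing axes.
#' @param subset Electrode subset (default: the 11 main theta/alpha network
#'   nodes, [channels_subset()]).
#' @param time_range,freq_range Optional length-2 crops (seconds / Hz) to keep
#'   the tensor desk-sized.
#' @param time_decim Keep every `time_decim`-th time point after cropping. PDC
#'   trajectories vary on the random-walk time scale, far slower than the
#'   sample grid, so decimating the time mode changes the decomposition little
#'   while cutting its cost proportionally.
#' @return An object of class `bn_pdc4`: `values` `[pair, time, freq,
#'   subject]`, `pair_labels`, axes.
#' @export
build_pdc_tensor <- function(pdc_list, subset = channels_subset(),
                             time_range = NULL, freq_range = NULL,
                             time_decim = 1L) {
  ref <- pdc_list[[1]]
  for (p in pdc_list[-1]) {
    if (!identical(dim(p$values), dim(ref$values)) ||
        !isTRUE(all.equal(p$freqs, ref$freqs))) {
      stop("subjects' PDC tensors have mismatched axes")
    }
  }
  if (!all(subset %in% ref$channel_names)) {
    stop("subset contains channels absent from the PDC tensor")
  }
  labels <- sort(subset)
  D <- length(labels)
  src <- rep(labels, each = D)
  tgt <- rep(labels, times = D)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  pair_labels <- paste0(src, "->", tgt)
  ti <- seq_along(ref$times)
  fi <- seq_along(ref$freqs)
  if (!is.null(time_range)) {
    ti <- which(ref$times >= time_range[1] & ref$times < time_range[2])
  }
  if (time_decim > 1) ti <- ti[seq(1L, length(ti), by = as.integer(time_decim))]
  if (!is.null(freq_range)) {
    fi <- which(ref$freqs >= freq_range[1] & ref$freqs <= freq_range[2])
  }
  si <- match(src, ref$channel_names)
  gi <- match(tgt, ref$channel_names)
  values <- array(0, dim = c(length(pair_labels), length(ti), length(fi),
                             length(pdc_list)))
  for (s in seq_along(pdc_list)) {
    v <- pdc_list[[s]]$values[, , ti, fi, drop = FALSE]
    values[, , , s] <- v[cbind(rep(gi, length(ti) * length(fi)),
                               rep(si, length(ti) * length(fi)),
                               rep(rep(seq_along(ti), each = length(pair_labels)),
                                   length(fi)),
                               rep(seq_along(fi),
                                   each = length(pair_labels) * length(ti)))]
  }
  structure(list(values = values, pair_labels = pair_labels,
                 sources = src, targets = tgt,
                 times = ref$times[ti], freqs = ref$freqs[fi],
                 channel_subset = labels),
            class = "bn_pdc4")
}

#' Un-vectorize one space-mode slice back into a D x D matrix
#'
#' Inverse of the pair ordering used by [build_pdc_tensor()].
#'
#' @param tensor A `bn_pdc4`.
#' @param x Numeric vector over the pair dimension (e.g. one space loading or
#'   one `[ , t, f, s]` slice).
#' @return `D x D` matrix (rows = targets, columns = sources, zero diagonal).
#' @export
pairs_to_matrix <- function(tensor, x) {
  labels <- tensor$channel_subset
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(target = labels, source = labels))
  m[cbind(match(tensor$targets, labels), match(tensor$sources, labels))] <- x
  m
}

unfold <- function(x, mode) {
  d <- dim(x)
  matrix(aperm(x, c(mode, setdiff(seq_along(d), mode))), d[mode])
}

# Khatri-Rao product of the factor matrices of all modes except `mode`,
# ordered so that unfold(x, mode) ~= A[[mode]] %*% t(kr_others(...)).
kr_others <- function(factors, mode) {
  ms <- setdiff(seq_along(factors), mode)
  W <- factors[[ms[1]]]
  for (m in ms[-1]) {
    A <- factors[[m]]
    W <- W[rep(seq_len(nrow(W)), times = nrow(A)), , drop = FALSE] *
      A[rep(seq_len(nrow(A)), each = nrow(W)), , drop = FALSE]
  }
  W
}

#' PARAFAC decomposition of the 4-mode connectivity tensor
#'
#' Alternating least squares with nonnegativity on all modes (HALS column
#' updates, which never increase the reconstruction error); plain unconstrained
#' ALS is available via `nonneg = FALSE`. Multiple random restarts are run and
#' the best-fit solution returned; the whole procedure is deterministic given
#' `seed`. After convergence the time, frequency and subject loadings are
#' normalized to unit length with the scale absorbed into the space mode, and
#' factors are ordered by decreasing magnitude. Nonnegativity is an assumption
#' motivated by PDC values being nonnegative interaction strengths.
#'
#' @param x A [build_pdc_tensor()] result or plain nonnegative 4-D array.
#' @param M Number of factors.
#' @param n_restarts Random restarts.
#' @param nonneg Impose nonnegativity on all modes?
#' @param max_iter,tol ALS iteration cap and relative fit-change tolerance.
#' @param seed Integer seed.
#' @return An object of class `bn_parafac`: `loadings` (named list of
#'   `dim x M` matrices for modes space/time/frequency/subject), `fit`
#'   (explained-variation fraction `1 - |X - Xhat| / |X|`), `sse_trace`,
#'   `converged`, `core_consistency`, `seed`.
#' @export
parafac <- function(x, M = 5, n_restarts = 10, nonneg = TRUE,
                    max_iter = 500, tol = 1e-8, seed = 1L) {
  tensor <- if (inherits(x, "bn_pdc4")) x else NULL
  X <- if (is.null(tensor)) x else tensor$values
  stopifnot(length(dim(X)) == 4, M >= 1)
  d <- dim(X)
  normX <- sqrt(sum(X^2))
  if (normX == 0) stop("degenerate all-zero tensor")
  Xn <- lapply(1:4, function(n) unfold(X, n))

  set.seed(as.integer(seed))
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    factors <- lapply(d, function(dd) {
      if (nonneg) matrix(runif(dd * M, 0.1, 1), dd, M)
      else matrix(rnorm(dd * M), dd, M)
    })
    grams <- lapply(factors, crossprod)
    sse_trace <- numeric(0)
    prev_fit <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (n in 1:4) {
        W <- kr_others(factors, n)
        XW <- Xn[[n]] %*% W
        G <- Reduce(`*`, grams[-n])
        A <- factors[[n]]
        if (nonneg) {
          for (m in seq_len(M)) {
            gmm <- max(G[m, m], 1e-12)
            a <- A[, m] + (XW[, m] - A %*% G[, m]) / gmm
            A[, m] <- pmax(a, 0)
          }
        } else {
          A <- t(solve(G + diag(1e-12, M), t(XW)))
        }
        factors[[n]] <- A
        grams[[n]] <- crossprod(A)
      }
      n <- 4
      sse <- normX^2 - 2 * sum(factors[[n]] * (Xn[[n]] %*% kr_others(factors, n))) +
        sum(Reduce(`*`, grams))
      sse <- max(sse, 0)
      sse_trace <- c(sse_trace, sse)
      fit <- 1 - sqrt(sse) / normX
      if (is.finite(prev_fit) && abs(fit - prev_fit) < tol) {
        converged <- TRUE; break
      }
      prev_fit <- fit
    }
    fit <- 1 - sqrt(tail(sse_trace, 1)) / normX
    if (is.null(best) || fit > best$fit) {
      best <- list(factors = factors, fit = fit, sse_trace = sse_trace,
                   converged = converged)
    }
  }
  if (!best$converged) {
    warning("PARAFAC did not converge within max_iter; best iterate returned")
  }

  # scale indeterminacy: unit-norm time/frequency/subject loadings, scale in space
  factors <- best$factors
  scale <- rep(1, M)
  for (n in 2:4) {
    nrm <- sqrt(colSums(factors[[n]]^2))
    nrm[nrm == 0] <- 1
    factors[[n]] <- sweep(factors[[n]], 2, nrm, "/")
    scale <- scale * nrm
  }
  factors[[1]] <- sweep(factors[[1]], 2, scale, "*")
  ord <- order(sqrt(colSums(factors[[1]]^2)), decreasing = TRUE)
  factors <- lapply(factors, function(A) A[, ord, drop = FALSE])

  names(factors) <- c("space", "time", "frequency", "subject")
  res <- structure(list(
    loadings = factors, M = M, fit = best$fit,
    sse_trace = best$sse_trace, converged = best$converged,
    core_consistency = NA_real_, seed = seed,
    axes = if (!is.null(tensor)) {
      list(pair_labels = tensor$pair_labels, times = tensor$times,
           freqs = tensor$freqs)
    } else NULL
  ), class = "bn_parafac")
  res$core_consistency <- core_consistency(X, factors, M)
  res
}

# Core consistency diagnostic: how close the least-squares Tucker core of the
# fitted loadings is to the PARAFAC superdiagonal (100 = perfect).
core_consistency <- function(X, factors, M) {
  pinv <- function(A) {
    s <- svd(A)
    keep <- s$d > max(s$d) * 1e-10
    if (!any(keep)) return(NULL)
    s$v[, keep, drop = FALSE] %*%
      (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  G <- X
  for (n in 1:4) {
    Pn <- pinv(factors[[n]])
    if (is.null(Pn)) return(NA_real_)
    d <- dim(G)
    Gu <- Pn %*% unfold(G, n)
    # fold back: unfold ordered the remaining modes increasingly
    G <- array(Gu, dim = c(M, d[-n]))
    G <- aperm(G, order(c(n, setdiff(1:4, n))))
  }
  super <- array(0, dim = rep(M, 4))
  for (m in seq_len(M)) super[m, m, m, m] <- 1
  100 * (1 - sum((G - super)^2) / M)
}

#' @export
print.bn_parafac <- function(x, ...) {
  cat(sprintf(
    "<bn_parafac> M = %d factors, fit = %.4f, core consistency = %.1f%s\n",
    x$M, x$fit, x$core_consistency,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
tidy.bn_parafac <- function(x, ...) {
  purrr::imap_dfr(x$loadings, function(A, mode) {
    tibble::tibble(
      mode = mode,
      index = rep(seq_len(nrow(A)), times = ncol(A)),
      factor = rep(seq_len(ncol(A)), each = nrow(A)),
      loading = as.vector(A)
    )
  })
}

#' @export
glance.bn_parafac <- function(x, ...) {
  tibble::tibble(M = x$M, fit = x$fit, iterations = length(x$sse_trace),
                 converged = x$converged, core_consistency = x$core_consistency)
}

#' Greedy-matched factor congruence between two PARAFAC models
#'
#' Per mode, Tucker's congruence coefficient (normalized inner product) between
#' factor columns; factors are matched greedily on the product of the per-mode
#' congruences (largest absolute product first).
#'
#' @param model_a,model_b [parafac()] fits (or plain lists of loading matrices)
#'   with the same modes and `M`.
#' @return A tibble with `factor_a`, `factor_b`, `congruence` (product over
#'   modes, in \[-1, 1\]).
#' @export
factor_congruence <- function(model_a, model_b) {
  la <- if (inherits(model_a, "bn_parafac")) model_a$loadings else model_a
  lb <- if (inherits(model_b, "bn_parafac")) model_b$loadings else model_b
  if (length(la) != length(lb)) stop("models have different numbers of modes")
  M <- ncol(la[[1]])
  if (ncol(lb[[1]]) != M) stop("models have different factor counts")
  comb <- matrix(1, M, M)
  for (n in seq_along(la)) {
    if (nrow(la[[n]]) != nrow(lb[[n]])) stop("mode dimension mismatch")
    An <- sweep(la[[n]], 2, pmax(sqrt(colSums(la[[n]]^2)), 1e-300), "/")
    Bn <- sweep(lb[[n]], 2, pmax(sqrt(colSums(lb[[n]]^2)), 1e-300), "/")
    comb <- comb * crossprod(An, Bn)
  }
  res <- tibble::tibble(factor_a = integer(0), factor_b = integer(0),
                        congruence = numeric(0))
  avail_a <- seq_len(M); avail_b <- seq_len(M)
  work <- comb
  for (i in seq_len(M)) {
    pick <- which(abs(work) == max(abs(work[avail_a, avail_b, drop = FALSE])),
                  arr.ind = TRUE)
    pick <- pick[pick[, 1] %in% avail_a & pick[, 2] %in% avail_b, , drop = FALSE][1, ]
    res <- dplyr::bind_rows(res, tibble::tibble(
      factor_a = pick[1], factor_b = pick[2], congruence = comb[pick[1], pick[2]]))
    avail_a <- setdiff(avail_a, pick[1]); avail_b <- setdiff(avail_b, pick[2])
    work[pick[1], ] <- 0; work[, pick[2]] <- 0
  }
  dplyr::arrange(res, .data$factor_a)
}
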