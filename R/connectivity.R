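#' Time-variant generalized partial directed coherence (gPDC)
#'
#' From the Fourier transform of the tvMVAR coefficients,
#' `Abar(f, t) = I - sum_k A_k(t) exp(-i 2 pi f k / fs)`, the gPDC from source
#' channel `j` to target channel `i` is
#' `pi(i <- j, t, f) = (|Abar_ij| / sigma_i) / sqrt(sum_m |Abar_mj|^2 / sigma_m^2)`,
#' i.e. PDC normalized by the model residual variances, which makes the measure
#' invariant to channel amplitude scaling. The direction convention is
#' `values[target, source, , ]` = influence of the source (column) on the
#' target (row). Raw values satisfy the column normalization
#' `sum_target pi^2 = 1`; the diagonal is kept in `values` so that the
#' normalization is checkable, and zeroed only by the network-facing accessors.
#'
#' @param model A [tvmvar_model()].
#' @param freqs Frequency grid (Hz) inside `(0, fs/2)`.
#' @return An object of class `bn_pdc` with `values` `[target, source, time,
#'   freq]`, plus axes and channel names.
#' @export
gpdc <- function(model, freqs = seq(0.5, model$fs / 2 - 0.5, by = 0.5)) {
  stopifnot(inherits(model, "bn_tvmvar"), all(freqs > 0),
            all(freqs < model$fs / 2))
  d <- dim(model$A)
  Acube <- array(model$A, dim = c(d[1], d[2] * d[3], d[4]))
  v <- tv_gpdc_cpp(Acube, model$sigma2, model$fs, freqs, d[3])
  values <- array(v, dim = c(d[1], d[1], d[4], length(freqs)))
  structure(list(values = values,
                 times = (seq_len(d[4]) - 1) / model$fs,
                 freqs = freqs,
                 channel_names = model$channel_names,
                 burn_in_s = model$burn_in_s),
            class = "bn_pdc")
}

#' @export
print.bn_pdc <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bn_pdc> %d x %d channels, %d time points, %d frequencies\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Average two or more PDC tensors (e.g. across subjects)
#'
#' @param pdc_list List of `bn_pdc` objects with identical axes.
#' @return A `bn_pdc` holding the element-wise mean (the grand mean tensor).
#' @export
grand_mean_pdc <- function(pdc_list) {
  ref <- pdc_list[[1]]
  acc <- ref$values
  for (p in pdc_list[-1]) {
    if (!identical(dim(p$values), dim(acc))) stop("PDC tensors have mismatched axes")
    acc <- acc + p$values
  }
  ref$values <- acc / length(pdc_list)
  ref
}

#' Region-of-interest specification (frequency band x time interval)
#'
#' @param band Length-2 numeric frequency band (Hz).
#' @param interval Length-2 numeric time interval (s), half-open `[lo, hi)`.
#' @param label Optional label (e.g. `"theta TI4"`).
#' @return A list of class `bn_roi`.
#' @export
roi_spec <- function(band, interval, label = NULL) {
  stopifnot(band[1] < band[2], interval[1] < interval[2])
  if (is.null(label)) {
    label <- sprintf("%g-%g Hz / %g-%g s", band[1], band[2],
                     interval[1], interval[2])
  }
  structure(list(band = band, interval = interval, label = label),
            class = "bn_roi")
}

#' The analysis time intervals after onset (TI1-TI4)
#'
#' One-second intervals starting 0.5 s after the 3 s onset, skipping the
#' 3-3.5 s window dominated by the onset motion artifact.
#'
#' @return Named list of length-2 numeric intervals (seconds).
#' @export
analysis_intervals <- function() {
  list(TI1 = c(3.5, 4.5), TI2 = c(4.5, 5.5), TI3 = c(5.5, 6.5),
       TI4 = c(6.5, 7.5))
}

#' Mean PDC within a region of interest
#'
#' Arithmetic mean over the time x frequency box, per directed pair; the
#' diagonal of the result is zero (self-influence is not part of the network).
#' Time intervals are half-open `[lo, hi)`.
#'
#' @param pdc A [gpdc()] result.
#' @param roi A [roi_spec()].
#' @return A `D x D` matrix (rows = targets, columns = sources) with attribute
#'   `"roi"`.
#' @export
roi_mean <- function(pdc, roi) {
  ti <- which(pdc$times >= roi$interval[1] & pdc$times < roi$interval[2])
  fi <- which(pdc$freqs >= roi$band[1] & pdc$freqs <= roi$band[2])
  if (length(ti) == 0 || length(fi) == 0) stop("empty ROI box")
  box <- pdc$values[, , ti, fi, drop = FALSE]
  m <- apply(box, c(1, 2), mean)
  diag(m) <- 0
  dimnames(m) <- list(target = pdc$channel_names, source = pdc$channel_names)
  attr(m, "roi") <- roi
  m
}

#' Discretize a mean-PDC matrix into a weighted directed network
#'
#' Edges below the lowest threshold are dropped; the remaining edges get
#' discretization levels 1..n assigned by half-open upward bins (with the
#' default thresholds: level 1 = \[0.08, 0.10), level 2 = \[0.10, 0.12),
#' level 3 = \[0.12, Inf)).
#'
#' @param meanmat `D x D` mean-PDC matrix (rows = targets, columns = sources,
#'   zero diagonal), e.g. from [roi_mean()].
#' @param thresholds Strictly increasing discretization bounds.
#' @return An object of class `bn_network`: list with `nodes`, `edges` (tibble
#'   `source`, `target`, `weight`, `level`) and the originating `roi` (if any).
#' @export
discretize <- function(meanmat, thresholds = c(0.08, 0.10, 0.12)) {
  stopifnot(all(diff(thresholds) > 0))
  nodes <- colnames(meanmat)
  if (is.null(nodes)) nodes <- paste0("ch", seq_len(ncol(meanmat)))
  idx <- which(meanmat >= thresholds[1] &
               row(meanmat) != col(meanmat), arr.ind = TRUE)
  edges <- tibble::tibble(
    source = nodes[idx[, 2]],
    target = nodes[idx[, 1]],
    weight = meanmat[idx],
    level = findInterval(meanmat[idx], thresholds)
  )
  edges <- dplyr::arrange(edges, dplyr::desc(.data$weight))
  structure(list(nodes = nodes, edges = edges, roi = attr(meanmat, "roi")),
            class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("<bn_network> %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges),
              if (!is.null(x$roi)) paste0(" (", x$roi$label, ")") else ""))
  if (nrow(x$edges) > 0) print(x$edges, n = 10)
  invisible(x)
}

#' @export
tidy.bn_network <- function(x, ...) x$edges

#' Node strength and average node strength of a directed weighted network
#'
#' The strength of node `i` is the sum of all incoming and outgoing weights,
#' `s_i = sum_j (w_ij + w_ji)`; the average node strength (ANS) is the mean of
#' all node strengths, `ANS = 2 * total weight / D`, a global connectedness
#' measure. Computed on the continuous (non-discretized) weights.
#'
#' @param x A `D x D` weight matrix with zero diagonal (rows = targets), or a
#'   [discretize()] network (whose edge weights are then used).
#' @return `node_strength()`: named numeric vector;
#'   `average_node_strength()`: scalar.
#' @export
node_strength <- function(x) {
  w <- as_weight_matrix(x)
  rowSums(w) + colSums(w)
}

#' @rdname node_strength
#' @export
average_node_strength <- function(x) mean(node_strength(x))

as_weight_matrix <- function(x) {
  if (inherits(x, "bn_network")) {
    w <- matrix(0, length(x$nodes), length(x$nodes),
                dimnames = list(x$nodes, x$nodes))
    if (nrow(x$edges) > 0) {
      w[cbind(match(x$edges$target, x$nodes),
              match(x$edges$source, x$nodes))] <- x$edges$weight
    }
    return(w)
  }
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (any(diag(x) != 0)) stop("weight matrix must have a zero diagonal")
  x
}

#' Per-frequency average node strength for the stable vs unstable condition
#'
#' Splits the PDC tensor at the onset, averages over time within each condition
#' (optionally excluding intervals such as the onset-artifact window), zeroes
#' the diagonal, and computes the ANS per frequency bin.
#'
#' @param pdc A [gpdc()] result.
#' @param onset_time Onset time in seconds.
#' @param exclude Optional list of time intervals (each length-2, seconds) to
#'   exclude from the averages (e.g. burn-in, onset artifact).
#' @return A tibble with columns `freq`, `ans_bss`, `ans_bus`.
#' @export
condition_ans <- function(pdc, onset_time, exclude = NULL) {
  stopifnot(onset_time > min(pdc$times), onset_time < max(pdc$times))
  keep <- rep(TRUE, length(pdc$times))
  for (iv in exclude) keep[pdc$times >= iv[1] & pdc$times < iv[2]] <- FALSE
  bss <- which(keep & pdc$times < onset_time)
  bus <- which(keep & pdc$times >= onset_time)
  if (length(bss) == 0 || length(bus) == 0) stop("a condition has no time points")
  D <- dim(pdc$values)[1]
  ans_of <- function(ti) {
    vapply(seq_along(pdc$freqs), function(fi) {
      m <- apply(pdc$values[, , ti, fi, drop = FALSE], c(1, 2), mean)
      diag(m) <- 0
      average_node_strength(m)
    }, numeric(1))
  }
  tibble::tibble(freq = pdc$freqs, ans_bss = ans_of(bss), ans_bus = ans_of(bus))
}
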