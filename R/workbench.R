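#' Pipeline configuration
#'
#' Bundles the per-stage configurations for an end-to-end run on synthetic
#' data. ROI time intervals exclude the 3-3.5 s onset-artifact window by
#' default (see [analysis_intervals()]), and the burn-in plus artifact windows
#' are excluded from the condition-wise ANS averages.
#'
#' @param sim A [sim_config()].
#' @param kalman A [kalman_config()].
#' @param gabor A [gabor_dictionary()].
#' @param screen An [artifact_screen_config()].
#' @param boot A [bootstrap_config()].
#' @param bands Named list of analysis frequency bands (Hz).
#' @param intervals Named list of analysis time intervals (s).
#' @param freqs PDC frequency grid (Hz).
#' @param thresholds Network discretization bounds.
#' @param tensor_subset Electrode subset for the connectivity tensor.
#' @param parafac_M,parafac_restarts PARAFAC factor count and restarts.
#' @param tensor_time_decim Time-mode decimation for the connectivity tensor
#'   (see [build_pdc_tensor()]).
#' @param tensor_freq_range Frequency crop (Hz) for the connectivity tensor;
#'   the default covers both analysis bands with context.
#' @param parafac_max_iter,parafac_tol ALS iteration cap and convergence
#'   tolerance for the pipeline's PARAFAC stage.
#' @param tube_channel Channel whose band-amplitude time course gets a
#'   confidence tube.
#' @param screen_channel Channel whose pooled PLI map is screened for sway
#'   harmonics (default `"Oz"`: posterior sites carry the strongest sway
#'   residual after common-average re-referencing).
#' @param alpha Significance level for the ANS tests and PLI thresholding.
#' @param seed Global seed (stage seeds are derived from it).
#' @return A list of class `bn_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            kalman = kalman_config(),
                            gabor = gabor_dictionary(),
                            screen = artifact_screen_config(),
                            boot = bootstrap_config(),
                            bands = list(theta = c(5, 7), alpha = c(9, 11)),
                            intervals = analysis_intervals(),
                            freqs = seq(0.5, 30, by = 0.5),
                            thresholds = c(0.08, 0.10, 0.12),
                            tensor_subset = NULL,
                            parafac_M = 5, parafac_restarts = 10,
                            tensor_time_decim = 10L,
                            tensor_freq_range = c(3, 13),
                            parafac_max_iter = 200,
                            parafac_tol = 1e-6,
                            tube_channel = "CPz",
                            screen_channel = "Oz",
                            alpha = 0.05,
                            seed = 1L) {
  if (is.null(tensor_subset)) {
    tensor_subset <- intersect(channels_subset(), sim$channel_names)
  }
  structure(list(sim = sim, kalman = kalman, gabor = gabor, screen = screen,
                 boot = boot, bands = bands, intervals = intervals,
                 freqs = freqs, thresholds = thresholds,
                 tensor_subset = tensor_subset, parafac_M = parafac_M,
                 parafac_restarts = parafac_restarts,
                 tensor_time_decim = as.integer(tensor_time_decim),
                 tensor_freq_range = tensor_freq_range,
                 parafac_max_iter = parafac_max_iter,
                 parafac_tol = parafac_tol,
                 tube_channel = tube_channel, screen_channel = screen_channel,
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "bn_pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains simulate -> preprocess (common average reference, ocular correction,
#' decimation) -> multi-trial Kalman tvMVAR per subject -> MGT amplitude/phase,
#' PLI with Rayleigh thresholding and harmonic screening -> gPDC -> grand-mean
#' networks per band and analysis interval -> condition-wise ANS with
#' Bonferroni-corrected paired t-tests -> band-amplitude confidence tubes ->
#' 4-mode PARAFAC of the connectivity tensor. Deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress?
#' @return A list of class `bn_report` with the per-stage results: `recording`,
#'   `models`, `pdc` (per subject), `grand_mean`, `networks` (tibble),
#'   `screening`, `ans` (per-subject tibble), `ans_test`, `tubes`, `parafac`,
#'   and a `log` tibble of stage timings and seeds.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "bn_pipeline_config"))
  sim <- config$sim
  sim$seed <- config$seed
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage,
                                              seconds = tic() - t0)
    if (verbose) message(sprintf("[%s] %.1f s", stage, tic() - t0))
  }

  t0 <- tic()
  rec <- simulate_dataset(sim)
  note("simulate", t0)

  t0 <- tic()
  rec <- rereference_common_average(rec)
  if (!is.null(rec$eog_channel)) rec <- correct_ocular(rec)
  factor <- sim$fs_raw / sim$fs_out
  if (factor > 1) rec <- downsample(rec, factor)
  note("preprocess", t0)

  onset_time <- (rec$onset_sample - 1) / rec$fs
  n_sub <- dim(rec$data)[1]
  n_tr <- dim(rec$data)[2]

  t0 <- tic()
  models <- lapply(seq_len(n_sub), function(s) fit_kalman(rec, s, config$kalman))
  note("tvmvar", t0)

  # MGT + PLI on the tube channel and harmonic screening, trials pooled over
  # subjects (n = subjects x trials phase realizations per bin)
  t0 <- tic()
  ci <- match(config$tube_channel, rec$channel_names)
  si <- match(config$screen_channel, rec$channel_names)
  phase_maps <- list(); amp_by_subject <- list()
  for (s in seq_len(n_sub)) {
    amps <- list()
    for (r in seq_len(n_tr)) {
      amps[[r]] <- mgt(rec$data[s, r, ci, ], rec$fs, config$gabor)$amplitude
      phase_maps[[length(phase_maps) + 1]] <-
        mgt(rec$data[s, r, si, ], rec$fs, config$gabor)$phase
    }
    amp_by_subject[[s]] <- amps
  }
  pli_map <- pli(phase_maps)
  binary <- threshold_pli(pli_map, n_trials = length(phase_maps),
                          alpha = config$alpha)
  screening <- screen_harmonics(binary, config$screen, bands = config$bands)
  note("timefreq", t0)

  t0 <- tic()
  pdcs <- lapply(models, gpdc, freqs = config$freqs)
  gm <- grand_mean_pdc(pdcs)
  networks <- purrr::imap_dfr(config$bands, function(b, bn) {
    purrr::imap_dfr(config$intervals, function(iv, ivn) {
      net <- discretize(roi_mean(gm, roi_spec(b, iv, paste(bn, ivn))),
                        config$thresholds)
      if (nrow(net$edges) == 0) return(tibble::tibble())
      dplyr::mutate(net$edges, band = bn, interval = ivn, .before = 1)
    })
  })
  note("connectivity", t0)

  t0 <- tic()
  exclude <- list(c(0, rec_times(rec)[1] + 1),          # burn-in (first 1 s)
                  c(onset_time, onset_time + 0.5))      # onset artifact window
  ans_tabs <- lapply(pdcs, condition_ans, onset_time = onset_time,
                     exclude = exclude)
  ans_bss <- do.call(rbind, lapply(ans_tabs, function(x) x$ans_bss))
  ans_bus <- do.call(rbind, lapply(ans_tabs, function(x) x$ans_bus))
  ans_test <- if (n_sub >= 2) {
    paired_ttest_ans(ans_bss, ans_bus, freqs = config$freqs,
                     alpha = config$alpha)
  } else NULL
  note("stats", t0)

  t0 <- tic()
  tube_times <- amp_by_subject[[1]][[1]]$times
  band_course <- function(band, s) {
    fi <- which(amp_by_subject[[s]][[1]]$freqs >= band[1] &
                amp_by_subject[[s]][[1]]$freqs <= band[2])
    rowMeans(sapply(amp_by_subject[[s]],
                    function(a) rowMeans(a$values[, fi, drop = FALSE])))
  }
  tubes <- purrr::imap(config$bands, function(b, bn) {
    courses <- t(sapply(seq_len(n_sub), band_course, band = b))
    if (n_sub >= 3) {
      cfg <- config$boot; cfg$seed <- config$seed + 1L
      confidence_tube(courses, cfg, times = tube_times, condition = bn)
    } else NULL
  })
  note("tubes", t0)

  t0 <- tic()
  tensor <- build_pdc_tensor(pdcs, subset = config$tensor_subset,
                             freq_range = config$tensor_freq_range,
                             time_decim = config$tensor_time_decim)
  fac <- parafac(tensor, M = config$parafac_M,
                 n_restarts = config$parafac_restarts,
                 max_iter = config$parafac_max_iter,
                 tol = config$parafac_tol,
                 seed = config$seed + 2L)
  note("parafac", t0)

  structure(list(
    recording = rec, models = models, pdc = pdcs, grand_mean = gm,
    networks = networks, pli = pli_map, screening = screening,
    ans = ans_tabs, ans_test = ans_test, tubes = tubes,
    tensor = tensor, parafac = fac,
    config = config, log = dplyr::bind_rows(log)
  ), class = "bn_report")
}

#' @export
print.bn_report <- function(x, ...) {
  cat("<bn_report> pipeline run, seed", x$config$seed, "\n")
  print(x$log)
  invisible(x)
}

#' Write / read a recording with the internal container
#'
#' Lossless (bit-exact) round trip of the full object, including channel names,
#' sampling rate, onset markers and any ground-truth configuration.
#'
#' @param rec A [new_recording()].
#' @param path File path.
#' @return `read_recording()` returns the `bn_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bn_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "bn_recording")) stop("file does not contain a recording")
  rec
}

#' Export a directed network as JSON or GraphML
#'
#' @param net A [discretize()] network.
#' @param path Output file path.
#' @param format `"json"` (nodes + edge list + ROI metadata) or `"graphml"`
#'   (via igraph, with `weight` and `level` edge attributes).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "bn_network"))
  if (format == "json") {
    jsonlite::write_json(list(
      nodes = net$nodes,
      edges = net$edges,
      roi = if (!is.null(net$roi)) {
        list(band = net$roi$band, interval = net$roi$interval,
             label = net$roi$label)
      } else NULL
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a directed network to an igraph object
#'
#' @param net A [discretize()] network.
#' @return An `igraph` directed graph with `weight` and `level` edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges[, c("source", "target", "weight", "level")]),
    directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
}
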