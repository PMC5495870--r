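#' Standard 10:10 channel layouts used by the balance experiment
#'
#' `channels_full()` returns the 32-name scalp montage (10:10 system) used for
#' whole-head recordings; `channels_subset()` returns the 11-electrode subset
#' covering the main nodes of the centro-parietal theta and occipito-parietal
#' alpha networks, which is the default for fast analyses and for the
#' connectivity tensor.
#'
#' @return Character vector of channel labels.
#' @export
channels_full <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "C1", "Cz", "C2", "C4", "T8",
    "CP5", "CP1", "CPz", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

#' @rdname channels_full
#' @export
channels_subset <- function() {
  c("C1", "Cz", "C2", "CP1", "CPz", "CP2", "P7", "P8", "O1", "Oz", "O2")
}

#' Schematic 2-D scalp positions for 10:10 channel labels
#'
#' Approximate top-view coordinates (nose up, x = left-right, y =
#' posterior-anterior, unit head radius) for plotting directed networks.
#'
#' @param labels Channel labels to look up (default: the full montage).
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
channel_positions <- function(labels = channels_full()) {
  pos <- c(
    Fp1 = "-0.31,0.95", Fp2 = "0.31,0.95",
    F7 = "-0.81,0.59", F3 = "-0.42,0.58", Fz = "0,0.6", F4 = "0.42,0.58", F8 = "0.81,0.59",
    FC5 = "-0.69,0.3", FC1 = "-0.23,0.31", FCz = "0,0.3", FC2 = "0.23,0.31", FC6 = "0.69,0.3",
    T7 = "-1,0", C3 = "-0.5,0", C1 = "-0.25,0", Cz = "0,0", C2 = "0.25,0", C4 = "0.5,0", T8 = "1,0",
    CP5 = "-0.69,-0.3", CP1 = "-0.23,-0.31", CPz = "0,-0.3", CP2 = "0.23,-0.31", CP6 = "0.69,-0.3",
    P7 = "-0.81,-0.59", P3 = "-0.42,-0.58", Pz = "0,-0.6", P4 = "0.42,-0.58", P8 = "0.81,-0.59",
    O1 = "-0.31,-0.95", Oz = "0,-1", O2 = "0.31,-0.95",
    EOG = "0,1.2"
  )
  unknown <- setdiff(labels, names(pos))
  if (length(unknown) > 0) {
    stop("no schematic position for channel(s): ", paste(unknown, collapse = ", "))
  }
  xy <- do.call(rbind, lapply(strsplit(pos[labels], ","), as.numeric))
  tibble::tibble(channel = labels, x = xy[, 1], y = xy[, 2])
}
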