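scalp_channel_coords <- function() {
  # approximate 2D head layout (x: left -1 .. right +1, y: posterior -1 .. anterior +1)
  rows <- list(
    Fp = list(y = 0.90, chans = c(Fp1 = -0.30, Fpz = 0, Fp2 = 0.30)),
    AF = list(y = 0.70, chans = c(AF3 = -0.35, AFz = 0, AF4 = 0.35)),
    F  = list(y = 0.50, chans = c(F7 = -0.90, F5 = -0.70, F3 = -0.45,
                                  F1 = -0.20, Fz = 0, F2 = 0.20, F4 = 0.45,
                                  F6 = 0.70, F8 = 0.90)),
    FC = list(y = 0.25, chans = c(FT7 = -0.95, FC5 = -0.70, FC3 = -0.45,
                                  FC1 = -0.20, FCz = 0, FC2 = 0.20,
                                  FC4 = 0.45, FC6 = 0.70, FT8 = 0.95)),
    C  = list(y = 0.00, chans = c(T7 = -1.00, C5 = -0.70, C3 = -0.45,
                                  C1 = -0.20, Cz = 0, C2 = 0.20, C4 = 0.45,
                                  C6 = 0.70, T8 = 1.00)),
    CP = list(y = -0.25, chans = c(TP7 = -0.95, CP5 = -0.70, CP3 = -0.45,
                                   CP1 = -0.20, CPz = 0, CP2 = 0.20,
                                   CP4 = 0.45, CP6 = 0.70, TP8 = 0.95)),
    P  = list(y = -0.50, chans = c(P7 = -0.90, P5 = -0.70, P3 = -0.45,
                                   P1 = -0.20, Pz = 0, P2 = 0.20, P4 = 0.45,
                                   P6 = 0.70, P8 = 0.90)),
    PO = list(y = -0.70, chans = c(PO7 = -0.60, PO3 = -0.30, POz = 0,
                                   PO4 = 0.30, PO8 = 0.60)),
    O  = list(y = -0.90, chans = c(O1 = -0.30, Oz = 0, O2 = 0.30))
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(channel = names(r$chans), x = unname(r$chans), y = r$y)
  })
}

#' Electrode montage of the simulated recordings
#'
#' A 59-channel scalp layout following the 10-10 system, sampled at 500 Hz,
#' with the right mastoid (`M2`) and four EOG channels recorded alongside
#' (the left mastoid is the online reference and is not stored as a
#' channel). Electrodes are grouped into nine regions of interest (ROIs),
#' the 3 x 3 grid of scalp area (frontal/central/parietal) by lateralisation
#' (left/middle/right) used for statistics.
#'
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @return An object of class `montage_spec`: list with `scalp` (59 channel
#'   names), `coords` (tibble of 2D positions), `mastoid` ("M2"),
#'   `reference` ("M1"), `eog` (4 names), `sampling_rate`, `roi` (named list
#'   of 9 electrode vectors).
#' @export
montage_spec <- function(sampling_rate = 500) {
  coords <- scalp_channel_coords()
  roi <- list(
    frontal_left   = c("F7", "F5", "F3", "FT7", "FC5", "FC3"),
    frontal_middle = c("F1", "Fz", "F2", "FC1", "FCz", "FC2"),
    frontal_right  = c("F8", "F6", "F4", "FT8", "FC6", "FC4"),
    central_left   = c("T7", "C5", "C3", "TP7", "CP5", "CP3"),
    central_middle = c("C1", "Cz", "C2", "CPz"),
    central_right  = c("T8", "C6", "C4", "TP8", "CP6", "CP4"),
    parietal_left  = c("P7", "P5", "P3", "PO7", "PO3", "O1"),
    parietal_middle = c("P1", "Pz", "P2", "POz", "Oz"),
    parietal_right = c("P8", "P6", "P4", "PO8", "PO4", "O2")
  )
  stopifnot(
    nrow(coords) == 59,
    !anyDuplicated(unlist(roi)),
    all(unlist(roi) %in% coords$channel)
  )
  structure(
    list(
      scalp = coords$channel,
      coords = coords,
      mastoid = "M2",
      reference = "M1",
      eog = c("HEOG_L", "HEOG_R", "VEOG_lo", "VEOG_up"),
      sampling_rate = sampling_rate,
      roi = roi
    ),
    class = "montage_spec"
  )
}

montage_channels <- function(montage) c(montage$scalp, montage$mastoid, montage$eog)
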