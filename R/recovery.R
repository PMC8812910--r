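#' Predicted window-mean of an injected component
#'
#' For one ground-truth component, the expected deviant-minus-standard
#' window mean (per unit injected amplitude) in a set of ROIs equals the
#' mean of the component's Gaussian time course over the in-window samples
#' times the mean topographic gain over the ROI electrodes. Used to convert
#' a measured simple effect back into an amplitude estimate.
#'
#' @param truth An `erp_ground_truth`.
#' @param component Component name (`"smmn"` or `"locmmn"`).
#' @param window Length-2 window in ms, or [window_spec()] name.
#' @param montage Montage.
#' @param rois ROI names to average over (default all nine).
#' @param times Epoch sample grid in ms (default the -100..398 ms grid at
#'   500 Hz).
#' @return Scalar gain (window-mean amplitude per uV injected).
#' @export
component_window_gain <- function(truth, component = "locmmn",
                                  window = "locmmn",
                                  montage = montage_spec(), rois = NULL,
                                  times = seq(-100, 398, by = 2)) {
  if (is.character(window)) window <- window_spec(window)
  comp <- truth$components[[component]]
  if (is.null(comp)) abort(paste0("unknown component: ", component))
  sel <- times >= window[1] & times < window[2]
  time_gain <- mean(exp(-(times[sel] - comp$latency_ms)^2 /
                          (2 * comp$sd_ms^2)))
  topo <- component_topography(comp, montage)
  if (is.null(rois)) rois <- names(montage$roi)
  roi_gain <- mean(vapply(montage$roi[rois],
                          function(ch) mean(topo[ch]), numeric(1)))
  time_gain * roi_gain
}

#' Recover an injected MMN amplitude from a cell table
#'
#' Estimates the deviance simple effect (mean deviant-minus-standard window
#' amplitude over the selected ROIs) and rescales it by the predicted
#' per-unit window gain of the injected component, yielding an estimate of
#' the injected peak amplitude in uV.
#'
#' @param cells Cell table with a `deviance` column ([deviance_cells()]).
#' @param truth Ground truth used at simulation time.
#' @param component,window,montage Passed to [component_window_gain()].
#' @param weighting `"gain"` (default) combines the per-ROI simple effects
#'   by least squares against the predicted per-ROI gains, down-weighting
#'   ROIs where the component is weak; `"flat"` divides the plain
#'   all-ROI mean effect by the mean gain.
#' @return List with `estimate_uv` (recovered amplitude), `by_roi` (per-ROI
#'   simple effects and gains) and `weighting`.
#' @export
recover_amplitude <- function(cells, truth, component = "locmmn",
                              window = "locmmn", montage = montage_spec(),
                              weighting = c("gain", "flat")) {
  weighting <- match.arg(weighting)
  by_roi <- dplyr::summarise(
    dplyr::group_by(cells, .data$area, .data$lateralisation, .data$deviance),
    amp = mean(.data$amp), .groups = "drop"
  )
  by_roi <- tidyr::pivot_wider(by_roi, names_from = "deviance",
                               values_from = "amp")
  by_roi$effect <- by_roi$deviant - by_roi$standard
  by_roi$roi <- paste(by_roi$area, by_roi$lateralisation, sep = "_")
  by_roi$gain <- vapply(by_roi$roi, function(r) {
    component_window_gain(truth, component, window, montage, rois = r)
  }, numeric(1))
  est <- if (weighting == "gain") {
    sum(by_roi$gain * by_roi$effect) / sum(by_roi$gain^2)
  } else {
    mean(by_roi$effect) / mean(by_roi$gain)
  }
  list(estimate_uv = est, by_roi = by_roi, weighting = weighting)
}
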