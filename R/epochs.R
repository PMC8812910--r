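#' Extract condition-labelled, baseline-corrected epochs
#'
#' Epochs are cut around triplet-ending events only, from -100 to 400 ms
#' relative to stimulus onset on the half-open interval `[-100, 400)` (250
#' samples at 500 Hz), and baseline-corrected by subtracting each channel's
#' mean over `[-100, 0)`. An ending is excluded when (in this order of
#' precedence):
#' \itemize{
#'   \item \strong{cover_task}: its onset falls within 3 s after a target
#'     sound or button press;
#'   \item \strong{too_close}: any other stimulus onset lies less than
#'     200 ms away (onset-to-onset, either direction);
#'   \item \strong{artifact}: any sample of its epoch window is rejected by
#'     the artifact mask.
#' }
#'
#' @param rec An `eeg_recording` (filtered and re-referenced).
#' @param mask Logical rejection mask from [gliding_window_reject()], or
#'   `NULL` for no artifact exclusion.
#' @param tmin,tmax Epoch window bounds, ms (half-open).
#' @param baseline Baseline window bounds, ms (half-open).
#' @param cover_exclusion_s Exclusion horizon after targets/presses, s.
#' @param min_neighbour_ms Minimal onset-to-onset distance to any other
#'   stimulus, ms.
#' @return An object of class `epoch_set`: list with `data` (trials x
#'   channels x samples array over the scalp channels), `times` (ms),
#'   `info` (tibble: trial, subject, block, block_group, category, side),
#'   `tallies` (inclusion/exclusion counts), `montage`, `soa_mode`.
#' @export
extract_epochs <- function(rec, mask = NULL, tmin = -100, tmax = 400,
                           baseline = c(-100, 0), cover_exclusion_s = 3,
                           min_neighbour_ms = 200) {
  sfreq <- rec$sfreq
  step <- 1000 / sfreq
  offsets <- seq(round(tmin / step), round(tmax / step) - 1L)
  times <- offsets * step
  bl_idx <- which(times >= baseline[1] & times < baseline[2])

  ev <- rec$events
  endings <- ev[ev$position == "ending", , drop = FALSE]
  onset <- endings$onset_ms
  # (b) cover task: within 3 s after a target sound or button press
  cover_ms <- sort(c(ev$onset_ms[ev$is_target],
                     (rec$press_samples - 1) / sfreq * 1000))
  excl_cover <- vapply(onset, function(t) {
    any(cover_ms <= t & t - cover_ms < cover_exclusion_s * 1000)
  }, logical(1))
  # (c) adjacent stimulus onset closer than 200 ms
  all_onsets <- sort(ev$onset_ms)
  pos <- match(onset, all_onsets)
  gap_before <- onset - ifelse(pos > 1, all_onsets[pos - 1L], -Inf)
  gap_after <- ifelse(pos < length(all_onsets), all_onsets[pos + 1L], Inf) - onset
  excl_close <- !excl_cover &
    (pmin(gap_before, gap_after) < min_neighbour_ms)
  # (a) artifact mask overlap
  start_samp <- endings$sample + offsets[1]
  excl_artifact <- rep(FALSE, nrow(endings))
  if (!is.null(mask)) {
    excl_artifact <- vapply(seq_len(nrow(endings)), function(i) {
      idx <- start_samp[i] + seq_along(offsets) - 1L
      any(idx < 1L) || any(idx > length(mask)) || any(mask[idx])
    }, logical(1))
    excl_artifact <- !excl_cover & !excl_close & excl_artifact
  }
  keep <- !excl_cover & !excl_close & !excl_artifact
  kept <- endings[keep, , drop = FALSE]
  if (nrow(kept) == 0) abort("no epochs survive the exclusion rules.")

  scalp_idx <- match(rec$montage$scalp, rec$channels)
  n_t <- length(offsets)
  data <- array(NA_real_, dim = c(nrow(kept), length(scalp_idx), n_t),
                dimnames = list(NULL, rec$montage$scalp, NULL))
  ks <- kept$sample
  for (i in seq_len(nrow(kept))) {
    seg <- rec$data[scalp_idx, ks[i] + offsets, drop = FALSE]
    data[i, , ] <- seg - rowMeans(seg[, bl_idx, drop = FALSE])
  }
  info <- tibble::tibble(
    trial = seq_len(nrow(kept)),
    subject = kept$subject,
    block = kept$block,
    block_group = group_blocks(kept$block),
    category = kept$category,
    side = kept$side
  )
  tallies <- c(total = nrow(endings), included = sum(keep),
               excluded_cover_task = sum(excl_cover),
               excluded_too_close = sum(excl_close),
               excluded_artifact = sum(excl_artifact))
  by_cat <- table(info$category)
  if (length(setdiff(unique(endings$category), names(by_cat))) > 0) {
    warn(paste0("conditions with zero surviving epochs: ",
                paste(setdiff(unique(endings$category), names(by_cat)),
                      collapse = ", ")))
  }
  structure(
    list(data = data, times = times, info = info, tallies = tallies,
         montage = rec$montage, soa_mode = rec$soa_mode),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$data)[1], "epochs x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples (",
      min(x$times), "to", max(x$times), "ms )\n")
  print(x$tallies)
  invisible(x)
}

#' Region-of-interest average waveforms
#'
#' Averages epochs within subject, ending category and block group, then
#' averages channels within each of the nine ROIs, preserving the epoch
#' sample grid.
#'
#' @param epochs An `epoch_set`.
#' @param montage Montage (defaults to the epoch set's).
#' @return A tibble of class `roi_waveforms`: `subject`, `category`,
#'   `block_group`, `roi`, `area`, `lateralisation`, `time_ms`, `amp` (uV),
#'   `n_epochs`.
#' @export
roi_waveforms <- function(epochs, montage = epochs$montage) {
  missing_ch <- setdiff(unlist(montage$roi), dimnames(epochs$data)[[2]])
  if (length(missing_ch) > 0) {
    abort(paste0("ROI electrodes missing from the recording: ",
                 paste(missing_ch, collapse = ", ")))
  }
  info <- epochs$info
  groups <- dplyr::distinct(info, .data$subject, .data$category,
                            .data$block_group)
  out <- purrr::pmap_dfr(groups, function(subject, category, block_group) {
    rows <- which(info$subject == subject & info$category == category &
                    info$block_group == block_group)
    avg <- apply(epochs$data[rows, , , drop = FALSE], c(2, 3), mean)
    purrr::imap_dfr(montage$roi, function(chans, roi_name) {
      roi_mean <- colMeans(avg[chans, , drop = FALSE])
      parts <- strsplit(roi_name, "_", fixed = TRUE)[[1]]
      tibble::tibble(
        subject = subject, category = category, block_group = block_group,
        roi = roi_name, area = parts[1], lateralisation = parts[2],
        time_ms = epochs$times, amp = roi_mean, n_epochs = length(rows)
      )
    })
  })
  class(out) <- c("roi_waveforms", class(out))
  out
}
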