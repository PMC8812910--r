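running_sd <- function(x, n) {
  # SD over every length-n window (positions 1 .. length(x)-n+1)
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  w1 <- s1[n:length(x)] - c(0, s1)[seq_len(length(x) - n + 1)]
  w2 <- s2[n:length(x)] - c(0, s2)[seq_len(length(x) - n + 1)]
  v <- (w2 - w1^2 / n) / (n - 1)
  sqrt(pmax(v, 0))
}

paint_windows <- function(n_samples, starts, width) {
  # mark all samples covered by windows starting at `starts`
  marks <- integer(n_samples + 1L)
  if (length(starts) > 0) {
    marks[starts] <- marks[starts] + 1L
    ends <- pmin(starts + width, n_samples + 1L)
    marks[ends] <- marks[ends] - 1L
  }
  cumsum(marks)[seq_len(n_samples)] > 0L
}

#' Gliding-window artifact rejection mask
#'
#' A sample is rejected iff it lies in at least one gliding window (of
#' either configured length, stepping sample by sample) in which the
#' within-window standard deviation of any channel -- including the EOG
#' channels -- exceeds the threshold. The defaults implement a 25 uV
#' threshold with 200 ms and 800 ms windows.
#'
#' @param rec An `eeg_recording`.
#' @param threshold SD threshold, uV.
#' @param windows_ms Window lengths, ms.
#' @return Logical vector (`TRUE` = rejected) of length `ncol(rec$data)`,
#'   with attribute `n_rejected`.
#' @export
gliding_window_reject <- function(rec, threshold = 25, windows_ms = c(200, 800)) {
  n_samples <- ncol(rec$data)
  mask <- logical(n_samples)
  widths <- round(windows_ms / 1000 * rec$sfreq)
  for (w in widths) {
    if (w > n_samples) next
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, ]
      sds <- running_sd(x - mean(x), w)
      bad <- which(sds > threshold)
      if (length(bad) > 0) {
        mask <- mask | paint_windows(n_samples, bad, w)
      }
    }
  }
  attr(mask, "n_rejected") <- sum(mask)
  mask
}

#' Automated bad-channel screen
#'
#' Flags channels that are flat (near-zero variance) or whose overall SD is
#' an extreme outlier relative to the scalp median, as an automated stand-in
#' for visual inspection of faulty channels.
#'
#' @param rec An `eeg_recording`.
#' @param flat_tol SD below which a channel counts as flat, uV.
#' @param outlier_factor Multiple of the median scalp SD above which a
#'   channel is flagged.
#' @return Character vector of flagged channel names (possibly empty).
#' @export
screen_bad_channels <- function(rec, flat_tol = 1e-3, outlier_factor = 8) {
  scalp_idx <- match(rec$montage$scalp, rec$channels)
  sds <- apply(rec$data[scalp_idx, , drop = FALSE], 1, sd)
  med <- stats::median(sds)
  flagged <- rec$montage$scalp[sds < flat_tol |
                                 (med > 0 & sds > outlier_factor * med)]
  flagged
}
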