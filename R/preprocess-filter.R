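blackman_window <- function(n) {
  k <- seq(0, n - 1)
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

# windowed-sinc low-pass FIR coefficients, unity DC gain
design_lowpass_fir <- function(cutoff, sfreq, taps, window = blackman_window) {
  if (taps %% 2 == 0) taps <- taps + 1L # integer group delay for zero phase
  m <- (taps - 1) / 2
  k <- seq(-m, m)
  fc <- cutoff / sfreq
  h <- 2 * fc * sinc_(2 * fc * k) * window(taps)
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

fir_frequency_response <- function(h, freqs, sfreq) {
  k <- seq_along(h) - 1
  vapply(freqs, function(f) {
    abs(sum(h * exp(-2i * pi * f * k / sfreq)))
  }, numeric(1))
}

# zero-phase FIR filtering of a samples x channels matrix by FFT convolution
fir_filter_matrix <- function(x, h) {
  n <- nrow(x)
  L <- length(h)
  m <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1, c(2, 3, 5))
  H <- fft(c(h, numeric(nfft - L)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[m + seq_len(n), , drop = FALSE]
}

#' Zero-phase FIR low-pass filter
#'
#' Filters every channel of a recording with a Blackman-windowed sinc FIR
#' low-pass (default 30 Hz cutoff, 2750 points), applied zero-phase by
#' compensating the filter's group delay. An even requested length is
#' extended by one tap so the group delay is an integer number of samples.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff Cutoff frequency, Hz.
#' @param taps Number of FIR coefficients.
#' @return The filtered recording.
#' @export
lowpass_fir <- function(rec, cutoff = 30, taps = 2750L) {
  h <- design_lowpass_fir(cutoff, rec$sfreq, taps)
  if (ncol(rec$data) < length(h)) {
    abort(sprintf("recording (%d samples) is shorter than the filter (%d taps).",
                  ncol(rec$data), length(h)))
  }
  rec$data <- t(fir_filter_matrix(t(rec$data), h))
  rownames(rec$data) <- rec$channels
  rec$filtered <- list(cutoff = cutoff, taps = length(h))
  rec
}

#' Re-reference to the algebraic mean of the mastoids
#'
#' The recording is referenced to the left mastoid (M1), so M1 is implicit
#' zero and the stored `M2` channel equals the mastoid difference. Changing
#' the reference to (M1+M2)/2 subtracts half the stored M2 from every scalp
#' channel. Calling this twice is an error.
#'
#' @param rec An `eeg_recording` with `reference_state == "as_recorded"`.
#' @return The recording re-referenced, with `reference_state`
#'   `"mastoid_mean"`.
#' @export
rereference_mastoid_mean <- function(rec) {
  if (!identical(rec$reference_state, "as_recorded")) {
    abort("recording is already re-referenced (reference_state != 'as_recorded').")
  }
  m2 <- rec$data[rec$montage$mastoid, ]
  scalp_idx <- match(rec$montage$scalp, rec$channels)
  rec$data[scalp_idx, ] <- rec$data[scalp_idx, , drop = FALSE] -
    matrix(m2 / 2, length(scalp_idx), length(m2), byrow = TRUE)
  rec$reference_state <- "mastoid_mean"
  rec
}
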