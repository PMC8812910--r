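#' Ground-truth ERP components injected into synthetic EEG
#'
#' Describes the event-related components added to every simulated stimulus:
#' an early negativity (N50) and positivity (P130) on all sounds, a
#' statistical mismatch negativity (sMMN) on low-transition-probability
#' endings, and a location MMN on deviant-location endings. Each component
#' is a Gaussian bump in time with a per-channel topographic gain map
#' normalised to 1 at its peak channel (fronto-central maximum; slight left
#' bias for the location MMN). `condition_scaling` multiplies the MMN
#' amplitudes per presentation mode, so temporal-predictability effects can
#' be injected (by default the sMMN is absent and the location MMN reduced
#' under jittered presentation).
#'
#' @param n50_amp,p130_amp Obligatory-response amplitudes, uV.
#' @param smmn_amp sMMN amplitude, uV (negative-going).
#' @param locmmn_amp Location-MMN amplitude, uV (negative-going).
#' @param smmn_latency_ms,locmmn_latency_ms Gaussian peak latencies, ms.
#' @param smmn_sd_ms,locmmn_sd_ms Gaussian widths, ms.
#' @param condition_scaling Named list of per-mode multipliers for
#'   `smmn` and `locmmn`.
#' @return A list of class `erp_ground_truth`.
#' @export
erp_ground_truth <- function(n50_amp = -1, p130_amp = 1.5,
                             smmn_amp = -2, locmmn_amp = -2,
                             smmn_latency_ms = 220, smmn_sd_ms = 25,
                             locmmn_latency_ms = 170, locmmn_sd_ms = 20,
                             condition_scaling = list(
                               isochronous = c(smmn = 1, locmmn = 1),
                               random = c(smmn = 0, locmmn = 0.6)
                             )) {
  if (smmn_amp > 0 || locmmn_amp > 0) {
    abort("MMN amplitudes must be negative-going (<= 0 uV).")
  }
  structure(
    list(
      components = list(
        n50 = list(amp = n50_amp, latency_ms = 50, sd_ms = 12,
                   peak = "FCz", left_bias = 0),
        p130 = list(amp = p130_amp, latency_ms = 130, sd_ms = 20,
                    peak = "FCz", left_bias = 0),
        smmn = list(amp = smmn_amp, latency_ms = smmn_latency_ms,
                    sd_ms = smmn_sd_ms, peak = "Fz", left_bias = 0),
        locmmn = list(amp = locmmn_amp, latency_ms = locmmn_latency_ms,
                      sd_ms = locmmn_sd_ms, peak = "FCz", left_bias = -0.08)
      ),
      condition_scaling = condition_scaling
    ),
    class = "erp_ground_truth"
  )
}

#' Noise model for synthetic EEG
#'
#' @param background_sd Standard deviation of the 1/f background per
#'   channel, uV (default 5).
#' @param spectral_exponent Exponent alpha of the 1/f^alpha power spectrum
#'   (default 1).
#' @param blink_rate Blink artifacts per minute (default 4).
#' @param blink_amp Blink amplitude on the lower vertical EOG, uV
#'   (default 150).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 5, spectral_exponent = 1,
                       blink_rate = 4, blink_amp = 150) {
  vals <- c(background_sd, spectral_exponent, blink_rate, blink_amp)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all noise parameters must be non-negative.")
  }
  structure(
    list(background_sd = background_sd, spectral_exponent = spectral_exponent,
         blink_rate = blink_rate, blink_amp = blink_amp),
    class = "noise_spec"
  )
}

# topographic gain map: gaussian over the 2D layout, normalised to 1 at `peak`
component_topography <- function(component, montage) {
  cx <- component$left_bias
  cy <- 0.35
  g <- exp(-(((montage$coords$x - cx)^2) + (montage$coords$y - cy)^2) /
             (2 * 0.7^2))
  g <- g / g[montage$coords$channel == component$peak]
  names(g) <- montage$coords$channel
  g
}

gaussian_kernel <- function(component, sfreq) {
  sd_s <- component$sd_ms / 1000
  half <- ceiling(4 * sd_s * sfreq)
  t <- (-half:half) / sfreq
  list(values = exp(-t^2 / (2 * sd_s^2)),
       offset = round(component$latency_ms / 1000 * sfreq) - half)
}

# add `kernel` scaled by `amps[i]` at sample `at[i]` into vector x (in place semantics)
add_bumps <- function(x, at, amps, kernel) {
  L <- length(kernel$values)
  for (i in seq_along(at)) {
    s <- at[i] + kernel$offset
    idx <- s:(s + L - 1L)
    keep <- idx >= 1L & idx <= length(x)
    x[idx[keep]] <- x[idx[keep]] + amps[i] * kernel$values[keep]
  }
  x
}

one_over_f_noise <- function(n_samples, n_channels, sd, alpha, sfreq) {
  if (sd == 0) return(matrix(0, n_samples, n_channels))
  if (alpha == 0) {
    return(matrix(rnorm(n_samples * n_channels, sd = sd), n_samples,
                  n_channels))
  }
  n2 <- stats::nextn(n_samples, c(2, 3, 5)) # pad to a fast FFT length
  # sample the spectrum directly: complex Gaussian bins shaped by f^(-a/2);
  # the real part of the inverse FFT is Gaussian with the target PSD shape
  spec <- matrix(complex(real = rnorm(n2 * n_channels),
                         imaginary = rnorm(n2 * n_channels)),
                 n2, n_channels)
  f <- seq(0, n2 - 1) / n2 * sfreq
  f <- pmin(f, sfreq - f) # two-sided frequency axis
  gain <- c(0, 1 / f[-1]^(alpha / 2))
  shaped <- Re(stats::mvfft(spec * gain, inverse = TRUE)) / n2
  shaped <- shaped[seq_len(n_samples), , drop = FALSE]
  shaped <- sweep(shaped, 2, apply(shaped, 2, sd), "/") * sd
  shaped
}

#' Simulate one subject's continuous EEG from a stimulus stream
#'
#' Adds parametric ERP bumps for each stimulus of the stream to a 1/f
#' background, together with blink artifacts on the vertical EOG that
#' propagate with decaying gain to anterior scalp rows. The recording is as
#' recorded against the left mastoid; 2 s of padding precede the first and
#' follow the last stimulus so that all epochs fit. Deterministic given
#' `seed`.
#'
#' @param stream A `triplet_stream` from [generate_stream()].
#' @param truth ERP ground truth ([erp_ground_truth()]).
#' @param noise Noise model ([noise_spec()]).
#' @param montage Montage ([montage_spec()]).
#' @param seed Seed for the noise and blink draws.
#' @return An object of class `eeg_recording`: list with `data`
#'   (channels x samples matrix, uV), `channels`, `sfreq`, `events` (stream
#'   events with `sample` indices), `press_samples`, `montage`,
#'   `reference_state` (`"as_recorded"`), `soa_mode`, `subject`.
#' @export
simulate_subject <- function(stream, truth = erp_ground_truth(),
                             noise = noise_spec(), montage = montage_spec(),
                             seed = 1L) {
  sfreq <- montage$sampling_rate
  pad <- 2 * sfreq
  events <- stream$events
  ev_sample <- round(events$onset_ms / 1000 * sfreq) + pad + 1L
  n_samples <- max(ev_sample) + pad
  chans <- montage_channels(montage)
  n_chan <- length(chans)
  scalp_idx <- match(montage$scalp, chans)

  with_seed_(seed, {
    data <- t(one_over_f_noise(n_samples, n_chan, noise$background_sd,
                               noise$spectral_exponent, sfreq))
    rownames(data) <- chans
    scaling <- truth$condition_scaling[[
      if (stream$cfg$soa_mode == "isochronous") "isochronous" else "random"]]
    is_stim <- !events$is_target
    is_ending <- events$position == "ending"
    comp_events <- list(
      n50 = list(at = ev_sample[is_stim], amp = 1),
      p130 = list(at = ev_sample[is_stim], amp = 1),
      smmn = list(
        at = ev_sample[is_ending &
                         events$category %in% c("stat_deviant", "double_deviant")],
        amp = scaling[["smmn"]]
      ),
      locmmn = list(
        at = ev_sample[is_ending &
                         events$category %in% c("phys_deviant", "double_deviant")],
        amp = scaling[["locmmn"]]
      )
    )
    for (nm in names(truth$components)) {
      comp <- truth$components[[nm]]
      ce <- comp_events[[nm]]
      if (length(ce$at) == 0 || comp$amp * ce$amp == 0) next
      kern <- gaussian_kernel(comp, sfreq)
      src <- add_bumps(numeric(n_samples), ce$at,
                       rep(comp$amp * ce$amp, length(ce$at)), kern)
      topo <- component_topography(comp, montage)
      active <- which(abs(src) > 0)
      if (length(active) > 0) {
        rng <- min(active):max(active)
        data[scalp_idx, rng] <- data[scalp_idx, rng] + outer(topo, src[rng])
      }
    }
    # blinks: 400 ms raised cosine, largest below the eye, decaying over
    # anterior scalp rows
    n_blinks <- rpois(1, noise$blink_rate * n_samples / sfreq / 60)
    if (n_blinks > 0 && noise$blink_amp > 0) {
      L <- round(0.4 * sfreq)
      wave <- (1 - cos(2 * pi * seq_len(L) / L)) / 2
      starts <- sort(sample.int(n_samples - L, n_blinks))
      blink_src <- numeric(n_samples)
      for (s in starts) {
        blink_src[s:(s + L - 1L)] <- blink_src[s:(s + L - 1L)] + wave
      }
      gains <- stats::setNames(numeric(n_chan), chans)
      gains["VEOG_lo"] <- 1
      gains["VEOG_up"] <- -0.6
      gains[c("HEOG_L", "HEOG_R")] <- 0.08
      y <- montage$coords$y
      gains[montage$scalp] <- 0.45 * pmax(y, 0)^2
      data <- data + outer(gains, blink_src) * noise$blink_amp
    }
    ev <- events
    ev$sample <- ev_sample
    press_samples <- round(stream$presses / 1000 * sfreq) + pad + 1L
    structure(
      list(data = data, channels = chans, sfreq = sfreq, events = ev,
           press_samples = press_samples, montage = montage,
           reference_state = "as_recorded", soa_mode = stream$cfg$soa_mode,
           subject = stream$subject),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject", x$subject, "-", nrow(x$data), "channels x",
      ncol(x$data), "samples @", x$sfreq, "Hz;",
      nrow(x$events), "events; reference:", x$reference_state, "\n")
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Generates one stream and one recording per subject. The sound
#' label-to-physical permutation is redrawn per subject, the standard side
#' of the first block alternates across subjects, and noise seeds are
#' independent, all derived from `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param cfg Stream configuration shared by the cohort (its `soa_mode`
#'   fixes the isochronicity group).
#' @param truth,noise,montage Simulation components.
#' @param seed Master seed for the cohort.
#' @return A list of `eeg_recording` objects.
#' @export
simulate_cohort <- function(n_subjects = 21L, cfg = stream_config(),
                            truth = erp_ground_truth(), noise = noise_spec(),
                            montage = montage_spec(), seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  purrr::map(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$standard_side_first_block <- if (s %% 2 == 1) "left" else "right"
    stream <- generate_stream(scfg, seed = derive_seed(seed, "paradigm", s),
                              subject = s)
    simulate_subject(stream, truth, noise, montage,
                     seed = derive_seed(seed, "noise", s))
  })
}
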