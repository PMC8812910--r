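# shared fixtures: small configurations and hand-built recordings

small_cfg <- function(n_triplets = 50L, n_blocks = 1L, mode = "random",
                      seed = 1L, targets = 0) {
  stream_config(soa_mode = mode, n_triplets_per_block = n_triplets,
                n_blocks = n_blocks, target_rate_per_min = targets,
                seed = seed)
}

quiet_noise <- function() {
  noise_spec(background_sd = 0, spectral_exponent = 0, blink_rate = 0,
             blink_amp = 0)
}

all_channels <- function(montage) c(montage$scalp, montage$mastoid, montage$eog)

# a recording built directly from a data matrix, bypassing the simulator
manual_recording <- function(data, events = NULL, press_samples = integer(0),
                             montage = montage_spec(), sfreq = 500,
                             reference_state = "as_recorded") {
  chans <- all_channels(montage)
  stopifnot(nrow(data) == length(chans))
  rownames(data) <- chans
  if (is.null(events)) {
    events <- tibble::tibble(
      onset_ms = numeric(0), block = integer(0), triplet_index = integer(0),
      position = character(0), sound = character(0), side = character(0),
      category = character(0), is_target = logical(0),
      subject = integer(0), sample = integer(0)
    )
  }
  structure(
    list(data = data, channels = chans, sfreq = sfreq, events = events,
         press_samples = press_samples, montage = montage,
         reference_state = reference_state, soa_mode = "isochronous",
         subject = 1L),
    class = "eeg_recording"
  )
}

# event row for hand-built epoching scenarios
ending_event <- function(onset_ms, category = "standard", block = 1L,
                         sfreq = 500, pad_samples = 0L) {
  tibble::tibble(
    onset_ms = onset_ms, block = block, triplet_index = 1L,
    position = "ending", sound = "E", side = "left", category = category,
    is_target = FALSE, subject = 1L,
    sample = round(onset_ms / 1000 * sfreq) + pad_samples + 1L
  )
}

# two clean endings plus optional extra events/presses on a silent record
make_epoch_fixture <- function(extra_events = NULL, presses_ms = numeric(0),
                               data_fun = NULL, duration_s = 30) {
  montage <- montage_spec()
  chans <- all_channels(montage)
  n <- duration_s * 500
  data <- matrix(0, length(chans), n)
  if (!is.null(data_fun)) data <- data_fun(data, chans)
  events <- dplyr::bind_rows(
    ending_event(5000, "standard"),
    ending_event(10000, "stat_deviant"),
    extra_events
  )
  rec <- manual_recording(data, events = events,
                          press_samples = as.integer(round(presses_ms / 2) + 1L))
  rec$reference_state <- "mastoid_mean"
  rec
}

# brute-force oracle: gliding-window rejection by direct per-window SD
reject_oracle <- function(data, sfreq, threshold, windows_ms) {
  n <- ncol(data)
  mask <- logical(n)
  for (w_ms in windows_ms) {
    w <- round(w_ms / 1000 * sfreq)
    if (w > n) next
    for (start in seq_len(n - w + 1)) {
      idx <- start:(start + w - 1)
      if (any(apply(data[, idx, drop = FALSE], 1, stats::sd) > threshold)) {
        mask[idx] <- TRUE
      }
    }
  }
  mask
}

# extract SS/df/F from a stats::aov fit with Error() strata, by term name
aov_oracle <- function(data, dv, within, between = NULL, subject = "subject") {
  d <- as.data.frame(data)
  d[[subject]] <- factor(d[[subject]])
  for (v in c(within, between)) d[[v]] <- factor(d[[v]])
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(form, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      out[[terms[i]]] <- list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
                              f = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    }
  }
  out
}

# cell-level cohort simulator for ANOVA calibration checks: balanced
# deviance x area x lateralisation x block_group table per subject
simulate_cells <- function(n_subjects, effect = 0, subject_sd = 0.5,
                           cell_sd = 0.5, prefix = "s") {
  grid <- tidyr::expand_grid(
    subject = paste0(prefix, seq_len(n_subjects)),
    deviance = c("standard", "deviant"),
    area = c("frontal", "central", "parietal"),
    lateralisation = c("left", "middle", "right"),
    block_group = 1:3
  )
  subj_eff <- stats::setNames(rnorm(n_subjects, 0, subject_sd),
                              paste0(prefix, seq_len(n_subjects)))
  grid$amp <- subj_eff[grid$subject] +
    ifelse(grid$deviance == "deviant", effect, 0) +
    rnorm(nrow(grid), 0, cell_sd)
  grid
}
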