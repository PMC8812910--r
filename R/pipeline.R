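#' Pipeline run configuration
#'
#' Flat, serialisable configuration for [run_pipeline()]. Defaults mirror
#' the full experimental design (two cohorts of 21 subjects, 6 blocks of
#' 400 triplets); reduced values are recommended for exploratory runs.
#'
#' @param n_subjects_per_group Subjects per isochronicity cohort.
#' @param n_triplets_per_block,n_blocks Stream dimensions.
#' @param target_rate_per_min Cover-task targets per minute.
#' @param background_sd,spectral_exponent,blink_rate,blink_amp Noise model.
#' @param smmn_amp,locmmn_amp Injected MMN amplitudes, uV.
#' @param smmn_noniso_scale,locmmn_noniso_scale MMN multipliers under
#'   jittered presentation.
#' @param familiarity_accuracy Per-trial probability of a correct
#'   familiarity-test response used when simulating behavioural scores.
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects_per_group = 21L,
                       n_triplets_per_block = 400L, n_blocks = 6L,
                       target_rate_per_min = 2,
                       background_sd = 5, spectral_exponent = 1,
                       blink_rate = 4, blink_amp = 150,
                       smmn_amp = -2, locmmn_amp = -2,
                       smmn_noniso_scale = 0, locmmn_noniso_scale = 0.6,
                       familiarity_accuracy = 0.5,
                       out_dir = tempfile("mmnstream_run"), seed = 1L) {
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_triplets_per_block = as.integer(n_triplets_per_block),
         n_blocks = as.integer(n_blocks),
         target_rate_per_min = target_rate_per_min,
         background_sd = background_sd,
         spectral_exponent = spectral_exponent,
         blink_rate = blink_rate, blink_amp = blink_amp,
         smmn_amp = smmn_amp, locmmn_amp = locmmn_amp,
         smmn_noniso_scale = smmn_noniso_scale,
         locmmn_noniso_scale = locmmn_noniso_scale,
         familiarity_accuracy = familiarity_accuracy,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

truth_from_config <- function(cfg) {
  erp_ground_truth(
    smmn_amp = cfg$smmn_amp, locmmn_amp = cfg$locmmn_amp,
    condition_scaling = list(
      isochronous = c(smmn = 1, locmmn = 1),
      random = c(smmn = cfg$smmn_noniso_scale,
                 locmmn = cfg$locmmn_noniso_scale)
    )
  )
}

noise_from_config <- function(cfg) {
  noise_spec(background_sd = cfg$background_sd,
             spectral_exponent = cfg$spectral_exponent,
             blink_rate = cfg$blink_rate, blink_amp = cfg$blink_amp)
}

#' Simulate, preprocess and average one subject
#'
#' Runs the per-subject chain: stimulus stream, EEG synthesis, zero-phase
#' low-pass, mastoid-mean re-referencing, gliding-window rejection, epoch
#' extraction with cover-task exclusion rules, and ROI averaging.
#'
#' @param stream A `triplet_stream`.
#' @param truth,noise,montage Simulation components.
#' @param seed Noise seed.
#' @param reject Apply the gliding-window rejection mask (default `TRUE`).
#' @return List with `waves` (ROI waveforms), `tallies`, `stream`.
#' @export
process_subject <- function(stream, truth = erp_ground_truth(),
                            noise = noise_spec(), montage = montage_spec(),
                            seed = 1L, reject = TRUE) {
  rec <- simulate_subject(stream, truth, noise, montage, seed = seed)
  rec <- lowpass_fir(rec)
  rec <- rereference_mastoid_mean(rec)
  mask <- if (reject) gliding_window_reject(rec) else NULL
  epochs <- extract_epochs(rec, mask)
  list(waves = roi_waveforms(epochs), tallies = epochs$tallies,
       stream = stream)
}

#' ROI waveforms for a whole cohort
#'
#' Sequentially simulates and processes `n_subjects` subjects (memory is
#' bounded by one recording at a time) and row-binds their ROI waveforms.
#'
#' @inheritParams simulate_cohort
#' @param reject Apply artifact rejection.
#' @return List with `waves` (all subjects' ROI waveforms) and `tallies`
#'   (matrix of per-subject exclusion counts).
#' @export
cohort_waveforms <- function(n_subjects = 21L, cfg = stream_config(),
                             truth = erp_ground_truth(),
                             noise = noise_spec(),
                             montage = montage_spec(), seed = 1L,
                             reject = TRUE) {
  res <- purrr::map(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$standard_side_first_block <- if (s %% 2 == 1) "left" else "right"
    stream <- generate_stream(scfg, seed = derive_seed(seed, "paradigm", s),
                              subject = s)
    process_subject(stream, truth, noise, montage,
                    seed = derive_seed(seed, "noise", s), reject = reject)
  })
  waves <- dplyr::bind_rows(purrr::map(res, "waves"))
  class(waves) <- c("roi_waveforms", setdiff(class(waves), "roi_waveforms"))
  list(waves = waves, tallies = do.call(rbind, purrr::map(res, "tallies")))
}

#' Run the complete simulation-to-statistics pipeline
#'
#' Generates an isochronous and a non-isochronous cohort, runs the full
#' preprocessing chain per subject, fits the within-cohort repeated-measures
#' ANOVAs for the sMMN (standards vs statistical deviants, 180--260 ms) and
#' the location MMN (standards vs location deviants, 150--220 ms), fits both
#' mixed deviance-by-isochronicity contrasts, simulates familiarity-test
#' scores and tests them against chance, and writes all tabular outputs as
#' TSV into `cfg$out_dir`. Identical seeds give identical outputs.
#'
#' @param cfg A [run_config()].
#' @return A report list of class `pipeline_report`: `predictability`,
#'   `anova` (per mode/contrast), `interaction` (per contrast),
#'   `familiarity`, `tallies`, `paths`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (cfg$n_subjects_per_group < 2) {
    abort("`n_subjects_per_group` must be >= 2 for the ANOVA stage.")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- truth_from_config(cfg)
  noise <- noise_from_config(cfg)
  montage <- montage_spec()
  modes <- c(isochronous = "isochronous", non_isochronous = "random")
  waves <- list()
  tallies <- list()
  cells <- list()
  for (m in names(modes)) {
    scfg <- stream_config(
      soa_mode = modes[[m]],
      n_triplets_per_block = cfg$n_triplets_per_block,
      n_blocks = cfg$n_blocks,
      target_rate_per_min = cfg$target_rate_per_min
    )
    cw <- cohort_waveforms(cfg$n_subjects_per_group, scfg, truth, noise,
                           montage,
                           seed = derive_seed(cfg$seed, "eeg",
                                              match(m, names(modes))))
    waves[[m]] <- cw$waves
    tallies[[m]] <- cw$tallies
    cells[[m]] <- list(
      smmn = deviance_cells(
        window_means(cw$waves, "smmn_main",
                     categories = c("standard", "stat_deviant")),
        deviant = "stat_deviant"
      ),
      locmmn = deviance_cells(
        window_means(cw$waves, "locmmn",
                     categories = c("standard", "phys_deviant")),
        deviant = "phys_deviant"
      )
    )
  }
  within <- c("deviance", "area", "lateralisation", "block_group")
  anovas <- purrr::map(cells, function(cc) {
    purrr::map(cc, function(d) {
      rm_anova(d, dv = "amp", within = active_within(d, within))
    })
  })
  interactions <- list(
    smmn = interaction_contrast(cells$isochronous$smmn,
                                cells$non_isochronous$smmn),
    locmmn = interaction_contrast(cells$isochronous$locmmn,
                                  cells$non_isochronous$locmmn)
  )
  fam <- with_seed_(derive_seed(cfg$seed, "familiarity"), {
    n_trials <- 12L * cfg$n_blocks
    scores <- stats::rbinom(cfg$n_subjects_per_group, n_trials,
                            cfg$familiarity_accuracy) / n_trials
    list(scores = scores, test = chance_test(scores))
  })
  pred <- predictability_table()
  paths <- list(
    predictability = file.path(cfg$out_dir, "predictability_table.tsv"),
    config = file.path(cfg$out_dir, "run_config.yaml")
  )
  readr::write_tsv(pred, paths$predictability)
  write_run_config(cfg, paths$config)
  for (m in names(modes)) {
    p <- file.path(cfg$out_dir, paste0("roi_waveforms_", m, ".tsv"))
    readr::write_tsv(waves[[m]], p)
    paths[[paste0("waves_", m)]] <- p
    for (contrast in names(anovas[[m]])) {
      p <- file.path(cfg$out_dir, paste0("anova_", m, "_", contrast, ".tsv"))
      readr::write_tsv(tidy(anovas[[m]][[contrast]]), p)
      paths[[paste0("anova_", m, "_", contrast)]] <- p
    }
  }
  for (contrast in names(interactions)) {
    p <- file.path(cfg$out_dir, paste0("interaction_", contrast, ".tsv"))
    readr::write_tsv(tidy(interactions[[contrast]]$anova), p)
    paths[[paste0("interaction_", contrast)]] <- p
  }
  log_path <- file.path(cfg$out_dir, "run_log.tsv")
  log_tab <- purrr::imap_dfr(tallies, function(tt, m) {
    d <- tibble::as_tibble(tt)
    d$mode <- m
    d$subject <- seq_len(nrow(d))
    d
  })
  readr::write_tsv(log_tab, log_path)
  paths$log <- log_path
  structure(
    list(predictability = pred, anova = anovas, interaction = interactions,
         familiarity = fam, tallies = tallies, waves = waves, paths = paths,
         config = cfg),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$config$n_subjects_per_group,
      "subjects/group,", x$config$n_blocks, "x",
      x$config$n_triplets_per_block, "triplets\n\n")
  for (contrast in names(x$interaction)) {
    row <- x$interaction[[contrast]]$interaction
    cat(sprintf("%s deviance x isochronicity: F(%d, %d) = %.2f, p = %.4g\n",
                contrast, row$df, row$df_error, row$statistic, row$p.value))
  }
  invisible(x)
}
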