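#' Transition table of the triplet paradigm
#'
#' Defines the Markov structure of the stream: each triplet root family
#' (AB or CD) is followed by its high-probability ending with `p_ending_high`
#' and by the alternative ending with `1 - p_ending_high` (AB -> E high / F
#' low; CD -> F high / E low). Roots follow any ending with probability
#' `p_root_given_ending` per family. Location probabilities give the chance
#' that a root sound, or a triplet ending, is presented from the block's
#' standard side.
#'
#' @param p_ending_high Probability of the high-probability ending (default 0.9).
#' @param p_root_given_ending Probability of each root family after an ending
#'   (default 0.5).
#' @param p_loc_std_root Probability that a root sound comes from the standard
#'   side (default 0.95).
#' @param p_loc_std_ending Probability that a triplet ending comes from the
#'   standard side (default 0.80).
#' @return A list of class `transition_table`.
#' @export
transition_table <- function(p_ending_high = 0.9,
                             p_root_given_ending = 0.5,
                             p_loc_std_root = 0.95,
                             p_loc_std_ending = 0.80) {
  probs <- c(p_ending_high, p_root_given_ending, p_loc_std_root,
             p_loc_std_ending)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all transition-table probabilities must lie in [0, 1].")
  }
  structure(
    list(
      p_ending_high = p_ending_high,
      p_ending_low = 1 - p_ending_high,
      p_root_given_ending = p_root_given_ending,
      p_loc_std_root = p_loc_std_root,
      p_loc_std_ending = p_loc_std_ending
    ),
    class = "transition_table"
  )
}

#' Stream configuration
#'
#' Experiment-level parameters of a triplet stream. In `"random"` (jittered,
#' non-isochronous) mode each 150 ms sound is followed by a pause drawn
#' uniformly from the integers `pause_range_ms[1]..pause_range_ms[2]` ms, so
#' the stimulus-onset asynchrony (SOA) varies over 150--450 ms with mean
#' 300 ms. In `"isochronous"` mode 220 ms sounds are followed by a fixed
#' 80 ms pause, giving a constant 300 ms SOA.
#'
#' @param soa_mode `"random"` (jittered SOA) or `"isochronous"`.
#' @param n_triplets_per_block Triplets per block (default 400). The product
#'   with each ending-category probability must be an integer.
#' @param n_blocks Number of blocks (default 6).
#' @param stim_duration_ms Sound duration; defaults to 150 ms in random mode
#'   and 220 ms in isochronous mode.
#' @param pause_range_ms Integer pause range in ms; `c(0, 300)` in random
#'   mode, `c(80, 80)` in isochronous mode.
#' @param min_separation Minimum number of intervening triplets between two
#'   low-probability-set triplets (default 3).
#' @param standard_side_first_block `"left"` or `"right"`; the standard side
#'   alternates across blocks.
#' @param target_rate_per_min Cover-task target sounds per minute (default 2).
#' @param target_hit_rate Probability that a target is followed by a simulated
#'   button press (default 0.979).
#' @param inter_block_gap_ms Silent gap inserted between blocks when blocks
#'   are laid out on one time axis (default 2000 ms).
#' @param seed Integer seed making stream generation reproducible.
#' @return A list of class `stream_config`.
#' @export
stream_config <- function(soa_mode = c("random", "isochronous"),
                          n_triplets_per_block = 400L,
                          n_blocks = 6L,
                          stim_duration_ms = NULL,
                          pause_range_ms = NULL,
                          min_separation = 3L,
                          standard_side_first_block = c("left", "right"),
                          target_rate_per_min = 2,
                          target_hit_rate = 0.979,
                          inter_block_gap_ms = 2000,
                          seed = 1L) {
  soa_mode <- match.arg(soa_mode)
  standard_side_first_block <- match.arg(standard_side_first_block)
  if (is.null(stim_duration_ms)) {
    stim_duration_ms <- if (soa_mode == "random") 150 else 220
  }
  if (is.null(pause_range_ms)) {
    pause_range_ms <- if (soa_mode == "random") c(0L, 300L) else c(80L, 80L)
  }
  if (length(pause_range_ms) != 2 || pause_range_ms[1] > pause_range_ms[2] ||
      any(pause_range_ms != round(pause_range_ms))) {
    abort("`pause_range_ms` must be two ordered integers.")
  }
  if (n_triplets_per_block < 1 || n_blocks < 1) {
    abort("`n_triplets_per_block` and `n_blocks` must be positive.")
  }
  if (target_hit_rate < 0 || target_hit_rate > 1) {
    abort("`target_hit_rate` must lie in [0, 1].")
  }
  structure(
    list(
      soa_mode = soa_mode,
      n_triplets_per_block = as.integer(n_triplets_per_block),
      n_blocks = as.integer(n_blocks),
      stim_duration_ms = stim_duration_ms,
      pause_range_ms = as.integer(pause_range_ms),
      min_separation = as.integer(min_separation),
      standard_side_first_block = standard_side_first_block,
      target_rate_per_min = target_rate_per_min,
      target_hit_rate = target_hit_rate,
      inter_block_gap_ms = inter_block_gap_ms,
      seed = as.integer(seed)
    ),
    class = "stream_config"
  )
}

# run code under a seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# per-stage seeds derived from one master seed by a fixed counter scheme
derive_seed <- function(master, stage, index = 0L) {
  offsets <- c(paradigm = 11L, eeg = 23L, noise = 37L, targets = 41L,
               familiarity = 43L, stats = 53L, misc = 59L)
  if (!stage %in% names(offsets)) abort("unknown seed stage.")
  as.integer((as.numeric(master) * 7919 + offsets[[stage]] * 104729 +
                as.numeric(index) * 1299721) %% 2147483647)
}
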