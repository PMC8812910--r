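#' Exact quota composition of one stream block
#'
#' Builds the multiset of triplets for a block so that the four
#' ending categories occur with their design probabilities exactly:
#' standards (high transition probability, standard location) 0.72,
#' statistical deviants (low TP, standard location) 0.08, location
#' deviants (high TP, deviant location) 0.18, double deviants (low TP,
#' deviant location) 0.02 under the default transition table. Counts are
#' split evenly over the AB and CD root families; odd category counts
#' are balanced so each family still holds exactly half of the triplets.
#'
#' @param cfg Stream configuration ([stream_config()]).
#' @param tt Transition table ([transition_table()]).
#' @return A tibble with one row per triplet: `root_family`, `tp`
#'   (high/low), `ending` (E/F), `ending_loc` (standard/deviant),
#'   `category`.
#' @examples
#' comp <- build_block_composition(stream_config(), transition_table())
#' table(comp$category) / nrow(comp)
#' @export
build_block_composition <- function(cfg = stream_config(),
                                    tt = transition_table()) {
  n <- cfg$n_triplets_per_block
  p_cat <- c(
    standard      = tt$p_ending_high * tt$p_loc_std_ending,
    stat_deviant  = tt$p_ending_low * tt$p_loc_std_ending,
    phys_deviant  = tt$p_ending_high * (1 - tt$p_loc_std_ending),
    double_deviant = tt$p_ending_low * (1 - tt$p_loc_std_ending)
  )
  counts <- n * p_cat
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort(paste0(
      "block size ", n, " does not yield integer category quotas; ",
      "n * p must be an integer for all four ending categories."
    ))
  }
  counts <- as.integer(round(counts))
  if (n %% 2 != 0) {
    abort("block size must be even to balance the AB/CD root families.")
  }
  base <- counts %/% 2L
  rem <- counts %% 2L
  if (sum(rem) %% 2L != 0L) {
    abort("category quotas cannot be split into equal-sized root families.")
  }
  # odd category counts: randomly assign half the extras to AB, half to CD
  fam_counts <- rbind(AB = base, CD = base)
  odd <- which(rem == 1L)
  if (length(odd) > 0) {
    to_ab <- sample(odd, length(odd) %/% 2L)
    fam_counts["AB", to_ab] <- fam_counts["AB", to_ab] + 1L
    fam_counts["CD", setdiff(odd, to_ab)] <-
      fam_counts["CD", setdiff(odd, to_ab)] + 1L
  }
  cats <- colnames(fam_counts) <- names(p_cat)
  rows <- purrr::map_dfr(c("AB", "CD"), function(fam) {
    purrr::map_dfr(cats, function(cat) {
      k <- fam_counts[fam, cat]
      if (k == 0L) return(NULL)
      tp <- if (cat %in% c("standard", "phys_deviant")) "high" else "low"
      # AB's high-probability ending is E, CD's is F
      ending <- if ((fam == "AB") == (tp == "high")) "E" else "F"
      tibble::tibble(
        root_family = fam, tp = tp, ending = ending,
        ending_loc = if (cat %in% c("standard", "stat_deviant"))
          "standard" else "deviant",
        category = cat, .rows = k
      )
    })
  })
  rows
}

low_prob_set <- function(category) category %in% c("stat_deviant", "double_deviant")

min_low_gap <- function(category) {
  idx <- which(low_prob_set(category))
  if (length(idx) < 2) return(Inf)
  min(diff(idx)) - 1L # number of intervening triplets
}

#' Pseudorandom triplet order with deviant-separation constraint
#'
#' Shuffles a block composition so that any two triplets of the
#' low-probability set (statistical and double deviants) are separated by at
#' least `cfg$min_separation` triplets from outside that set. Implemented as
#' a uniform shuffle followed by local swap-repair of violations (with
#' bounded retries and reshuffles), so the order is approximately uniform
#' among admissible orders.
#'
#' @param composition Tibble from [build_block_composition()].
#' @param cfg Stream configuration.
#' @return The composition tibble in presentation order, with a
#'   `triplet_index` column.
#' @export
arrange_stream <- function(composition, cfg = stream_config()) {
  gap_needed <- cfg$min_separation
  n <- nrow(composition)
  for (restart in seq_len(200)) {
    ord <- sample.int(n)
    cat <- composition$category[ord]
    ok <- FALSE
    for (iter in seq_len(2000)) {
      idx <- which(low_prob_set(cat))
      if (length(idx) < 2) { ok <- TRUE; break }
      gaps <- diff(idx) - 1L
      bad <- which(gaps < gap_needed)
      if (length(bad) == 0) { ok <- TRUE; break }
      # move the second member of the first violating pair elsewhere
      p <- idx[bad[1] + 1L]
      others <- setdiff(idx, p)
      cand <- which(!low_prob_set(cat))
      admissible <- cand[vapply(cand, function(q) {
        all(abs(others - q) > gap_needed)
      }, logical(1))]
      if (length(admissible) == 0) break
      q <- admissible[sample.int(length(admissible), 1)]
      tmp <- ord[p]; ord[p] <- ord[q]; ord[q] <- tmp
      cat <- composition$category[ord]
    }
    if (ok) {
      out <- composition[ord, , drop = FALSE]
      out$triplet_index <- seq_len(n)
      return(out[, c("triplet_index", setdiff(names(out), "triplet_index"))])
    }
  }
  abort("could not satisfy the deviant-separation constraint for this composition.")
}

#' Expand an ordered triplet sequence into per-sound events with locations
#'
#' Each triplet becomes three stimulus events (root1, root2, ending). The
#' block has a standard side; each root sound is presented from the deviant
#' side independently with probability `1 - tt$p_loc_std_root`, while the
#' ending's side is already fixed by its category quota (location/double
#' deviants from the deviant side, others from the standard side).
#'
#' @param sequence Ordered tibble from [arrange_stream()].
#' @param cfg Stream configuration.
#' @param tt Transition table.
#' @param standard_side `"left"` or `"right"` for this block.
#' @return A tibble with one row per sound: `triplet_index`, `position`,
#'   `sound`, `side`, `category` (roots are labelled `"root"`), `is_target`.
#' @export
assign_locations <- function(sequence, cfg = stream_config(),
                             tt = transition_table(),
                             standard_side = "left") {
  deviant_side <- if (standard_side == "left") "right" else "left"
  n <- nrow(sequence)
  root_sounds <- ifelse(sequence$root_family == "AB",
                        list(c("A", "B")), list(c("C", "D")))
  events <- tibble::tibble(
    triplet_index = rep(sequence$triplet_index, each = 3L),
    position = rep(c("root1", "root2", "ending"), times = n),
    sound = as.vector(rbind(
      ifelse(sequence$root_family == "AB", "A", "C"),
      ifelse(sequence$root_family == "AB", "B", "D"),
      sequence$ending
    )),
    category = as.vector(rbind("root", "root", sequence$category))
  )
  is_root <- events$position != "ending"
  root_dev <- runif(sum(is_root)) > tt$p_loc_std_root
  side <- character(nrow(events))
  side[is_root] <- ifelse(root_dev, deviant_side, standard_side)
  ending_dev <- rep(sequence$ending_loc == "deviant", each = 3L)[!is_root]
  side[!is_root] <- ifelse(ending_dev, deviant_side, standard_side)
  events$side <- side
  events$is_target <- FALSE
  events[, c("triplet_index", "position", "sound", "side", "category",
             "is_target")]
}

#' Insert cover-task target sounds and simulated button presses
#'
#' Target sounds are placed between triplets at roughly
#' `cfg$target_rate_per_min` per minute (the expected block duration follows
#' from the mean SOA). A fraction `hit_rate` of targets is followed by a
#' simulated button press with lognormal latency.
#'
#' @param events Sound-level events of one block (before timing).
#' @param cfg Stream configuration.
#' @param hit_rate Probability of a press per target.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters, seconds.
#' @return `events` with interleaved target rows; press latencies (ms after
#'   target onset, `NA` for misses) are kept in the `press_latency_ms`
#'   column of target rows.
#' @export
insert_targets <- function(events, cfg = stream_config(),
                           hit_rate = cfg$target_hit_rate,
                           rt_meanlog = log(0.45), rt_sdlog = 0.25) {
  events$press_latency_ms <- NA_real_
  n_triplets <- max(events$triplet_index)
  mean_soa_s <- (cfg$stim_duration_ms + mean(cfg$pause_range_ms)) / 1000
  block_min <- n_triplets * 3 * mean_soa_s / 60
  n_targets <- round(cfg$target_rate_per_min * block_min)
  if (n_targets < 1) return(events)
  boundaries <- sort(sample.int(n_triplets - 1L, min(n_targets, n_triplets - 1L)))
  targets <- tibble::tibble(
    triplet_index = boundaries, position = "target", sound = "TARGET",
    side = events$side[1], category = "target", is_target = TRUE,
    press_latency_ms = ifelse(runif(length(boundaries)) < hit_rate,
                              rlnorm(length(boundaries), rt_meanlog, rt_sdlog) * 1000,
                              NA_real_)
  )
  out <- dplyr::bind_rows(events, targets)
  # a target after triplet k sorts between triplet k and k+1
  key <- out$triplet_index + ifelse(out$is_target, 0.5,
                                    match(out$position,
                                          c("root1", "root2", "ending")) / 10)
  out[order(key), , drop = FALSE]
}

#' Assign onset times to a block's events
#'
#' In jittered mode every sound of duration `stim_duration_ms` is followed by
#' a pause drawn uniformly from the integers spanning `pause_range_ms`, so
#' consecutive onsets differ by SOA = duration + pause. In isochronous mode
#' the SOA is constant (duration + fixed pause = 300 ms by default).
#'
#' @param events Sound-level events of one block.
#' @param cfg Stream configuration.
#' @param t0 Onset of the first sound, ms.
#' @return `events` with an `onset_ms` column prepended.
#' @export
assign_timing <- function(events, cfg = stream_config(), t0 = 0) {
  n <- nrow(events)
  pauses <- if (cfg$pause_range_ms[1] == cfg$pause_range_ms[2]) {
    rep(cfg$pause_range_ms[1], n - 1L)
  } else {
    sample(seq(cfg$pause_range_ms[1], cfg$pause_range_ms[2]), n - 1L,
           replace = TRUE)
  }
  soa <- cfg$stim_duration_ms + pauses
  events$onset_ms <- t0 + c(0, cumsum(soa))
  events[, c("onset_ms", setdiff(names(events), "onset_ms"))]
}

#' Generate a complete multi-block triplet stream for one subject
#'
#' Runs the full stimulus-generation chain: exact quota composition,
#' separation-constrained shuffle, location assignment with per-block
#' alternation of the standard side, cover-task target insertion, and onset
#' timing. Blocks are laid out on one time axis separated by
#' `cfg$inter_block_gap_ms`. The label-to-physical sound assignment is a
#' per-subject permutation of the six sounds.
#'
#' @param cfg Stream configuration; `cfg$seed` (or `seed`) fixes the stream.
#' @param tt Transition table.
#' @param seed Optional seed overriding `cfg$seed`.
#' @param subject Subject identifier stored in the events.
#' @return An object of class `triplet_stream`: a list with `events` (tibble
#'   with columns `onset_ms, block, triplet_index, position, sound, side,
#'   category, is_target`), `presses` (press onset times, ms),
#'   `sound_permutation` (named physical-slot map over A--F), `standard_sides`
#'   (per block), `cfg`, `tt`.
#' @examples
#' st <- generate_stream(stream_config(n_triplets_per_block = 50, n_blocks = 1))
#' dplyr::count(st$events, category)
#' @export
generate_stream <- function(cfg = stream_config(), tt = transition_table(),
                            seed = cfg$seed, subject = 1L) {
  with_seed_(seed, {
    sides <- rep(c(cfg$standard_side_first_block,
                   setdiff(c("left", "right"), cfg$standard_side_first_block)),
                 length.out = cfg$n_blocks)
    perm <- sample.int(6L)
    names(perm) <- c("A", "B", "C", "D", "E", "F")
    t0 <- 0
    blocks <- vector("list", cfg$n_blocks)
    for (b in seq_len(cfg$n_blocks)) {
      comp <- build_block_composition(cfg, tt)
      seqd <- arrange_stream(comp, cfg)
      ev <- assign_locations(seqd, cfg, tt, standard_side = sides[b])
      ev <- insert_targets(ev, cfg)
      ev <- assign_timing(ev, cfg, t0 = t0)
      ev$block <- b
      t0 <- max(ev$onset_ms) + cfg$stim_duration_ms + cfg$inter_block_gap_ms
      blocks[[b]] <- ev
    }
    events <- dplyr::bind_rows(blocks)
    events$subject <- subject
    presses <- events$onset_ms[events$is_target] +
      events$press_latency_ms[events$is_target]
    presses <- presses[!is.na(presses)]
    events <- events[, c("onset_ms", "block", "triplet_index", "position",
                         "sound", "side", "category", "is_target",
                         "press_latency_ms", "subject")]
    structure(
      list(events = events, presses = presses, sound_permutation = perm,
           standard_sides = sides, cfg = cfg, tt = tt, subject = subject),
      class = "triplet_stream"
    )
  })
}

#' @export
print.triplet_stream <- function(x, ...) {
  cat("<triplet_stream> subject", x$subject, "-", x$cfg$soa_mode, "mode,",
      x$cfg$n_blocks, "block(s) of", x$cfg$n_triplets_per_block, "triplets\n")
  print(dplyr::count(x$events[x$events$position == "ending", ], .data$category))
  invisible(x)
}

#' Familiarity-test trials for one block
#'
#' Builds the 12-trial two-alternative forced-choice familiarity test: each
#' of the four triplet-pair combinations (ABE vs ABF, ABF vs ABE, CDF vs CDE,
#' CDE vs CDF) appears three times; the triplet ending with the
#' high-probability transition is the correct, "familiar" choice. Trial
#' order is randomised subject to no two consecutive trials sharing a root
#' family (which forces AB/CD alternation), and the correct answer is
#' counterbalanced 6/6 between first and second position. No sound in the
#' test changes location, and triplets within a trial are separated by a
#' 335 ms pause.
#'
#' @param tt Transition table (fixes which ending is high-probability).
#' @param seed Optional seed.
#' @return A tibble with 12 rows: `trial`, `first`, `second`,
#'   `correct_choice` (1 or 2), `root_family`, `inter_triplet_pause_ms`.
#' @export
make_familiarity_block <- function(tt = transition_table(), seed = NULL) {
  build <- function() {
    combos <- tibble::tibble(
      first = c("ABE", "ABF", "CDF", "CDE"),
      second = c("ABF", "ABE", "CDE", "CDF"),
      correct_choice = c(1L, 2L, 1L, 2L),
      root_family = c("AB", "AB", "CD", "CD")
    )
    trials <- combos[rep(1:4, each = 3L), ]
    ab <- trials[trials$root_family == "AB", ][sample.int(6L), ]
    cd <- trials[trials$root_family == "CD", ][sample.int(6L), ]
    first_fam <- sample(c("AB", "CD"), 1)
    interleaved <- vector("list", 12L)
    for (i in 1:6) {
      interleaved[[2 * i - 1]] <- if (first_fam == "AB") ab[i, ] else cd[i, ]
      interleaved[[2 * i]] <- if (first_fam == "AB") cd[i, ] else ab[i, ]
    }
    out <- dplyr::bind_rows(interleaved)
    out$trial <- 1:12
    out$inter_triplet_pause_ms <- 335
    out[, c("trial", "first", "second", "correct_choice", "root_family",
            "inter_triplet_pause_ms")]
  }
  if (is.null(seed)) build() else with_seed_(seed, build())
}
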