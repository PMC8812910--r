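test_that("block composition hits the category quotas exactly", {
  withr::with_seed(2, {
    comp <- build_block_composition(stream_config(), transition_table())
    counts <- table(comp$category)
    expect_equal(unname(counts[c("standard", "stat_deviant", "phys_deviant",
                                 "double_deviant")]),
                 c(288L, 32L, 72L, 8L), ignore_attr = TRUE)
    expect_equal(unname(table(comp$root_family)), c(400L, 400L) / 2,
                 ignore_attr = TRUE)
    # categories split evenly over families at even quotas
    expect_equal(sum(comp$root_family == "AB" & comp$category == "standard"), 144L)
  })
})

test_that("odd per-family quotas are balanced and invalid sizes rejected", {
  withr::with_seed(3, {
    comp50 <- build_block_composition(small_cfg(50))
    expect_equal(nrow(comp50), 50L)
    expect_equal(unname(table(comp50$root_family)), c(25L, 25L),
                 ignore_attr = TRUE)
    expect_equal(sum(comp50$category == "double_deviant"), 1L)
  })
  expect_error(build_block_composition(small_cfg(10)), "integer")
  expect_error(build_block_composition(stream_config(n_triplets_per_block = 75)),
               "integer|even")
})

test_that("low-probability triplets are separated by at least three others", {
  withr::with_seed(4, {
    for (i in 1:200) {
      comp <- build_block_composition(stream_config())
      ordered <- arrange_stream(comp, stream_config())
      idx <- which(ordered$category %in% c("stat_deviant", "double_deviant"))
      expect_true(all(diff(idx) - 1L >= 3L))
      expect_equal(sort(ordered$triplet_index), 1:400)
    }
    # a deviant-free composition needs no repair
    cfg1 <- small_cfg(50)
    comp <- build_block_composition(cfg1)
    comp$category <- "standard"
    expect_silent(arrange_stream(comp, cfg1))
  })
})

test_that("root families follow endings with empirical probability 1/2", {
  withr::with_seed(6, {
    n_ab_after <- 0L
    n_total <- 0L
    for (i in 1:60) {
      ordered <- arrange_stream(build_block_composition(stream_config()),
                                stream_config())
      fam <- ordered$root_family
      n_ab_after <- n_ab_after + sum(fam[-1] == "AB")
      n_total <- n_total + length(fam) - 1L
    }
    expect_equal(n_ab_after / n_total, 0.5, tolerance = 0.02)
  })
})

test_that("root location deviance is ~5% i.i.d. and the standard side alternates", {
  withr::with_seed(7, {
    st <- generate_stream(stream_config(n_triplets_per_block = 400,
                                        n_blocks = 6, seed = 21,
                                        target_rate_per_min = 0))
    ev <- st$events
    expect_equal(st$standard_sides,
                 rep(c("left", "right"), 3))
    roots <- ev[ev$position %in% c("root1", "root2"), ]
    dev_frac <- mean(roots$side != st$standard_sides[roots$block])
    se <- sqrt(0.05 * 0.95 / nrow(roots))
    expect_lt(abs(dev_frac - 0.05), 3 * se)
    # ending deviant-side fraction is fixed by quota: (72+8)/400 per block
    endings <- ev[ev$position == "ending", ]
    dev_end <- endings$side != st$standard_sides[endings$block]
    expect_equal(mean(dev_end), 0.20)
    expect_equal(unname(tapply(dev_end, endings$block, mean)),
                 rep(0.20, 6), ignore_attr = TRUE)
  })
})

test_that("jittered SOAs stay in 150-450 ms, are uniform, and average 300 ms", {
  withr::with_seed(8, {
    cfg <- stream_config(n_triplets_per_block = 400, n_blocks = 6,
                         target_rate_per_min = 0, seed = 5)
    st <- generate_stream(cfg)
    soas <- unlist(tapply(st$events$onset_ms, st$events$block, diff))
    expect_true(all(soas >= 150 & soas <= 450))
    expect_true(all(soas == round(soas)))
    expect_equal(mean(soas), 300, tolerance = 3 / 300)

    # uniformity of the pause distribution over the 301 integer values
    big <- assign_timing(tibble::tibble(dummy = seq_len(1e5)), cfg)
    pauses <- diff(big$onset_ms) - cfg$stim_duration_ms
    expect_gt(stats::chisq.test(table(factor(pauses, levels = 0:300)))$p.value,
              0.01)

    iso <- generate_stream(stream_config("isochronous",
                                         n_triplets_per_block = 50,
                                         n_blocks = 2,
                                         target_rate_per_min = 0, seed = 5))
    iso_soas <- unlist(tapply(iso$events$onset_ms, iso$events$block, diff))
    expect_true(all(iso_soas == 300))
  })
})

test_that("streams are reproducible byte-for-byte from the seed", {
  a <- generate_stream(stream_config(n_triplets_per_block = 50, n_blocks = 2,
                                     seed = 33))
  b <- generate_stream(stream_config(n_triplets_per_block = 50, n_blocks = 2,
                                     seed = 33))
  expect_identical(a$events, b$events)
  expect_identical(a$sound_permutation, b$sound_permutation)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(a$events, f1)
  write_events_tsv(b$events, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c <- generate_stream(stream_config(n_triplets_per_block = 50, n_blocks = 2,
                                     seed = 34))
  expect_false(identical(a$events, c$events))
})

test_that("cover-task targets and presses follow the configured rates", {
  withr::with_seed(9, {
    cfg <- stream_config(n_triplets_per_block = 400, n_blocks = 1,
                         target_rate_per_min = 2, target_hit_rate = 1)
    ev <- assign_locations(arrange_stream(build_block_composition(cfg), cfg),
                           cfg)
    with_targets <- insert_targets(ev, cfg)
    n_targets <- sum(with_targets$is_target)
    expect_equal(n_targets, round(2 * 400 * 3 * 0.3 / 60))
    expect_true(all(!is.na(with_targets$press_latency_ms[with_targets$is_target])))
    expect_true(all(diff(which(with_targets$is_target)) > 1)) # between triplets

    # hit rate scales the number of presses binomially
    cfg2 <- stream_config(n_triplets_per_block = 400, n_blocks = 1,
                          target_rate_per_min = 60, target_hit_rate = 0.979)
    hits <- 0; total <- 0
    for (i in 1:3) {
      ev2 <- insert_targets(ev, cfg2)
      hits <- hits + sum(!is.na(ev2$press_latency_ms[ev2$is_target]))
      total <- total + sum(ev2$is_target)
    }
    se <- sqrt(0.979 * 0.021 / total)
    expect_lt(abs(hits / total - 0.979), 4 * se)

    # zero rate leaves the stream unchanged
    cfg0 <- stream_config(n_triplets_per_block = 400, n_blocks = 1,
                          target_rate_per_min = 0)
    ev0 <- insert_targets(ev, cfg0)
    expect_equal(sum(ev0$is_target), 0)
    expect_equal(ev0[names(ev)], ev, ignore_attr = TRUE)
  })
})

test_that("familiarity-test blocks satisfy the design constraints", {
  withr::with_seed(10, {
    for (i in 1:50) {
      fam <- make_familiarity_block()
      expect_equal(nrow(fam), 12L)
      combos <- paste(fam$first, fam$second)
      expect_equal(sort(unique(table(combos))), 3L, ignore_attr = TRUE)
      expect_equal(length(unique(combos)), 4L)
      expect_true(all(diff(match(fam$root_family, c("AB", "CD"))) != 0))
      expect_equal(sum(fam$correct_choice == 1), 6L)
      # exactly one member of each pair carries the high-probability ending
      high <- c(AB = "E", CD = "F")
      first_high <- substr(fam$first, 3, 3) == high[fam$root_family]
      second_high <- substr(fam$second, 3, 3) == high[fam$root_family]
      expect_true(all(xor(first_high, second_high)))
      expect_equal(fam$correct_choice, unname(ifelse(first_high, 1L, 2L)))
      expect_true(all(fam$inter_triplet_pause_ms == 335))
    }
  })
})
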