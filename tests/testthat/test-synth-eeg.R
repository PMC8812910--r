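test_that("noiseless injection recovers the sMMN kernel at the Fz channel", {
  cfg <- small_cfg(50, mode = "isochronous", seed = 3)
  st <- generate_stream(cfg)
  truth <- erp_ground_truth(n50_amp = 0, p130_amp = 0, smmn_amp = -2,
                            locmmn_amp = 0)
  rec <- simulate_subject(st, truth, quiet_noise(), seed = 5)
  ev <- rec$events
  win <- 0:150 # 0-300 ms
  avg_at <- function(samples) {
    rowMeans(vapply(samples, function(s) rec$data["Fz", s + win], numeric(length(win))))
  }
  dev <- avg_at(ev$sample[ev$category == "stat_deviant"])
  std <- avg_at(ev$sample[ev$category == "standard"])
  diff_wave <- dev - std
  t_ms <- win * 2
  expect_equal(min(diff_wave), -2, tolerance = 1e-6)
  expect_true(t_ms[which.min(diff_wave)] >= 180 && t_ms[which.min(diff_wave)] <= 260)

  # all-zero ground truth with zero noise gives a flat record
  flat <- simulate_subject(st, erp_ground_truth(n50_amp = 0, p130_amp = 0,
                                                smmn_amp = 0, locmmn_amp = 0),
                           quiet_noise(), seed = 5)
  expect_equal(max(abs(flat$data)), 0)
})

test_that("component injection is linear in the ground-truth amplitudes", {
  cfg <- small_cfg(50, mode = "isochronous", seed = 4)
  st <- generate_stream(cfg)
  noise <- noise_spec(background_sd = 2, blink_rate = 2, blink_amp = 50)
  tA <- erp_ground_truth(n50_amp = -1, p130_amp = 0, smmn_amp = -2,
                         locmmn_amp = 0)
  tB <- erp_ground_truth(n50_amp = 0, p130_amp = 1.5, smmn_amp = 0,
                         locmmn_amp = -1)
  tAB <- erp_ground_truth(n50_amp = -1, p130_amp = 1.5, smmn_amp = -2,
                          locmmn_amp = -1)
  t0 <- erp_ground_truth(n50_amp = 0, p130_amp = 0, smmn_amp = 0,
                         locmmn_amp = 0)
  recs <- lapply(list(tA, tB, tAB, t0), function(tt) {
    simulate_subject(st, tt, noise, seed = 9)$data
  })
  lhs <- recs[[1]] + recs[[2]] - recs[[4]]
  expect_equal(lhs, recs[[3]], tolerance = 1e-10)
})

test_that("background noise shows an approximate 1/f^alpha spectrum", {
  withr::with_seed(31, {
    cfg <- small_cfg(50, seed = 6)
    st <- generate_stream(cfg)
    rec <- simulate_subject(
      st, erp_ground_truth(n50_amp = 0, p130_amp = 0, smmn_amp = 0,
                           locmmn_amp = 0),
      noise_spec(background_sd = 5, spectral_exponent = 1, blink_rate = 0),
      seed = 13
    )
    x <- rec$data["Cz", ]
    n <- length(x)
    spec <- Mod(fft(x))^2 / n
    f <- seq(0, n - 1) / n * rec$sfreq
    keep <- f > 0.5 & f < 100
    # average log-power in logarithmic frequency bins, then fit the slope
    bins <- cut(log10(f[keep]), 30)
    lp <- tapply(log10(spec[keep]), bins, mean)
    lf <- tapply(log10(f[keep]), bins, mean)
    slope <- stats::coef(stats::lm(lp ~ lf))[2]
    expect_equal(unname(slope), -1, tolerance = 0.3)
  })
})

test_that("blink artifacts appear on the vertical EOG and anterior channels", {
  cfg <- small_cfg(50, seed = 8)
  st <- generate_stream(cfg)
  rec <- simulate_subject(
    st, erp_ground_truth(n50_amp = 0, p130_amp = 0, smmn_amp = 0,
                         locmmn_amp = 0),
    noise_spec(background_sd = 0, blink_rate = 6, blink_amp = 150), seed = 17
  )
  expect_gt(max(rec$data["VEOG_lo", ]), 100)
  expect_gt(max(abs(rec$data["Fp1", ])), 10)
  expect_gt(max(abs(rec$data["Fp1", ])), max(abs(rec$data["Pz", ])))
  expect_equal(max(abs(rec$data["Oz", ])), 0) # posterior row unaffected
})

test_that("cohorts are reproducible, permuted per subject, and validated", {
  cfg <- small_cfg(50, n_blocks = 2, seed = 10)
  a <- simulate_cohort(2, cfg, noise = quiet_noise(), seed = 7)
  b <- simulate_cohort(2, cfg, noise = quiet_noise(), seed = 7)
  expect_equal(length(a), 2L)
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$events, b[[2]]$events)
  expect_error(simulate_cohort(1, cfg), ">= 2")

  streams <- lapply(1:6, function(s) {
    generate_stream(cfg, seed = derive_seed(99, "paradigm", s), subject = s)
  })
  perms <- vapply(streams, function(s) paste(s$sound_permutation, collapse = ""),
                  character(1))
  expect_gt(length(unique(perms)), 1L)
})

test_that("condition scaling orders the location MMN by isochronicity", {
  truth <- erp_ground_truth()
  amp_for <- function(mode) {
    cfg <- small_cfg(50, mode = mode, seed = 12)
    st <- generate_stream(cfg)
    rec <- simulate_subject(st, truth, quiet_noise(), seed = 19)
    ev <- rec$events
    win <- 75:110 # 150-220 ms
    avg <- function(cat) {
      rowMeans(vapply(ev$sample[ev$category == cat],
                      function(s) rec$data["FCz", s + win],
                      numeric(length(win))))
    }
    mean(avg("phys_deviant") - avg("standard"))
  }
  iso <- amp_for("isochronous")
  rnd <- amp_for("random")
  expect_lt(iso, rnd) # negative MMN: larger (more negative) when isochronous
  expect_lt(abs(rnd / iso - 0.6), 0.05)
})
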