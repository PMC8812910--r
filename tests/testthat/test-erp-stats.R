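test_that("blocks map onto the three pairwise block groups", {
  expect_equal(group_blocks(1:6), c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(group_blocks(7), "1..6")
  expect_error(group_blocks(0), "1..6")
})

test_that("within-subject ANOVA matches the aov projection oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:9),
                              a = c("x", "y"), b = c("p", "q", "r"),
                              g = c("u", "v", "w"))
      d$y <- rnorm(nrow(d))
      fit <- rm_anova(d, dv = "y", within = c("a", "b", "g"))
      oracle <- aov_oracle(d, "y", within = c("a", "b", "g"))
      tab <- tidy(fit)
      for (term in names(oracle)) {
        row <- tab[tab$term == term, ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$sumsq, oracle[[term]]$ss, tolerance = 1e-8)
        expect_equal(row$df, oracle[[term]]$df)
        expect_equal(row$statistic, oracle[[term]]$f, tolerance = 1e-8)
        expect_equal(row$p.value, oracle[[term]]$p, tolerance = 1e-8)
      }
    }
  })
})

test_that("mixed-design ANOVA with a between factor matches the aov oracle", {
  withr::with_seed(22, {
    for (rep in 1:3) {
      d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                              a = c("x", "y"), b = c("p", "q", "r"),
                              g = c("u", "v", "w"))
      d$grp <- ifelse(as.integer(sub("s", "", d$subject)) <= 5, "iso", "rnd")
      d$y <- rnorm(nrow(d)) + ifelse(d$grp == "iso" & d$a == "x", 0.5, 0)
      fit <- rm_anova(d, dv = "y", within = c("a", "b", "g"), between = "grp")
      oracle <- aov_oracle(d, "y", within = c("a", "b", "g"), between = "grp")
      tab <- tidy(fit)
      for (term in names(oracle)) {
        # aov orders interaction names between-first; ours too
        row <- tab[tab$term == term, ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$sumsq, oracle[[term]]$ss, tolerance = 1e-8)
        expect_equal(row$df, oracle[[term]]$df)
        expect_equal(row$statistic, oracle[[term]]$f, tolerance = 1e-8)
      }
    }
  })
})

test_that("a single two-level within factor reproduces the paired t test", {
  withr::with_seed(23, {
    d <- tidyr::expand_grid(subject = 1:12, cond = c("a", "b"))
    d$y <- rnorm(nrow(d)) + ifelse(d$cond == "b", 0.4, 0)
    fit <- rm_anova(d, dv = "y", within = "cond")
    wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
    tt <- stats::t.test(wide$a, wide$b, paired = TRUE)
    row <- tidy(fit)[tidy(fit)$term == "cond", ]
    expect_equal(row$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(row$p.value, tt$p.value, tolerance = 1e-10)
  })
})

test_that("a constant response yields zero F and p = 1", {
  d <- tidyr::expand_grid(subject = 1:6, a = c("x", "y"), b = 1:3)
  d$y <- 2.5
  fit <- rm_anova(d, dv = "y", within = c("a", "b"))
  expect_true(all(tidy(fit)$statistic == 0))
  expect_true(all(tidy(fit)$p.value == 1))
  expect_equal(fit$ss_total, 0)
})

test_that("unbalanced or degenerate designs are rejected with clear errors", {
  d <- tidyr::expand_grid(subject = 1:6, a = c("x", "y"))
  d$y <- rnorm(nrow(d))
  expect_error(rm_anova(d[-1, ], dv = "y", within = "a"), "balanced")
  expect_error(rm_anova(d[d$subject == 1, ], dv = "y", within = "a"),
               ">= 2 subjects")
  d$grp <- ifelse(d$subject == 1, "g1", "g2")
  expect_error(rm_anova(d, dv = "y", within = "a", between = "grp"),
               ">= 2 subjects")
})

test_that("expected F increases with injected effect size", {
  withr::with_seed(24, {
    mean_f <- vapply(c(0, 0.5, 1), function(eff) {
      mean(vapply(1:30, function(i) {
        cells <- simulate_cells(10, effect = eff)
        fit <- rm_anova(cells, dv = "amp",
                        within = c("deviance", "area", "lateralisation",
                                   "block_group"))
        tidy(fit)$statistic[tidy(fit)$term == "deviance"]
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(mean_f) > 0))
  })
})

test_that("Greenhouse-Geisser epsilon matches the double-centering oracle", {
  withr::with_seed(26, {
    # correlated 4-level within factor to induce non-sphericity
    n <- 14; m <- 4
    base <- rnorm(n)
    Y <- sapply(1:m, function(j) base * j + rnorm(n, sd = j))
    d <- tidyr::expand_grid(subject = 1:n, cond = letters[1:m])
    d$y <- as.vector(t(Y))
    fit <- rm_anova(d, dv = "y", within = "cond",
                    sphericity = "greenhouse-geisser")
    row <- tidy(fit)[tidy(fit)$term == "cond", ]
    # Box's epsilon from the eigenvalues of the double-centred covariance
    S <- stats::cov(Y)
    Cmat <- S - outer(rowMeans(S), rep(1, m)) -
      outer(rep(1, m), colMeans(S)) + mean(S)
    lam <- eigen(Cmat, symmetric = TRUE, only.values = TRUE)$values
    eps_oracle <- sum(lam)^2 / ((m - 1) * sum(lam^2))
    expect_equal(row$gg_epsilon, eps_oracle, tolerance = 1e-10)
    expect_lt(row$gg_epsilon, 1)
    expect_gte(row$gg_epsilon, 1 / (m - 1))
    expect_equal(row$p.value_gg,
                 stats::pf(row$statistic, row$gg_epsilon * row$df,
                           row$gg_epsilon * row$df_error, lower.tail = FALSE))
    # a two-level factor has a one-dimensional contrast space: epsilon = 1
    d2 <- tidyr::expand_grid(subject = 1:8, cond = c("a", "b"))
    d2$y <- rnorm(nrow(d2))
    fit2 <- rm_anova(d2, dv = "y", within = "cond",
                     sphericity = "greenhouse-geisser")
    expect_equal(tidy(fit2)$gg_epsilon, 1)
  })
})

test_that("window means separate windows and handle partial overlap", {
  times <- seq(-100, 398, by = 2)
  rois <- tidyr::expand_grid(
    area = c("frontal", "central", "parietal"),
    lateralisation = c("left", "middle", "right")
  )
  base <- tidyr::expand_grid(
    subject = 1:2, category = c("standard", "stat_deviant"),
    block_group = 1L, roi_i = seq_len(nrow(rois)), time_ms = times
  )
  base$area <- rois$area[base$roi_i]
  base$lateralisation <- rois$lateralisation[base$roi_i]
  base$roi <- paste(base$area, base$lateralisation, sep = "_")
  # deviants carry -2 uV strictly inside 180-260 ms, zero elsewhere
  base$amp <- ifelse(base$category == "stat_deviant" &
                       base$time_ms >= 180 & base$time_ms < 260, -2, 0)
  class(base) <- c("roi_waveforms", class(base))
  cells_main <- window_means(base, "smmn_main")
  cells_ctrl <- window_means(base, "early_neg")
  agg <- function(cells) {
    m <- tapply(cells$amp, cells$category, mean)
    unname(m["stat_deviant"] - m["standard"])
  }
  expect_equal(agg(cells_main), -2)
  expect_equal(agg(cells_ctrl), 0)

  # constant waveform gives constant cells
  const <- base
  const$amp <- 1
  class(const) <- c("roi_waveforms", class(const))
  expect_true(all(window_means(const, "locmmn")$amp == 1))

  # a step half-covering the window contributes its covered fraction
  step <- base[base$category == "standard", ]
  step$amp <- ifelse(step$time_ms >= 220, -2, 0) # covers [220, 260) of [180, 260)
  class(step) <- c("roi_waveforms", class(step))
  cells_step <- window_means(step, "smmn_main")
  expect_equal(unique(cells_step$amp), -2 * 20 / 40)
})

test_that("missing cells are reported as unbalanced", {
  times <- seq(-100, 398, by = 2)
  d <- tidyr::expand_grid(subject = 1:2, category = c("standard", "deviant"),
                          block_group = 1:2, area = "frontal",
                          lateralisation = c("left", "middle"),
                          time_ms = times)
  d$roi <- paste(d$area, d$lateralisation, sep = "_")
  d$amp <- 0
  d <- d[!(d$subject == 2 & d$category == "deviant" & d$block_group == 2 &
             d$lateralisation == "middle"), ]
  class(d) <- c("roi_waveforms", class(d))
  expect_error(window_means(d, c(0, 100)), "missing cell")
})

test_that("chance tests against 0.5 handle typical and degenerate samples", {
  withr::with_seed(25, {
    # exact equality with t.test on a regular sample
    scores <- runif(21, 0.3, 0.8)
    res <- chance_test(scores)
    tt <- stats::t.test(scores, mu = 0.5)
    expect_equal(res$statistic, unname(tt$statistic))
    expect_equal(res$p.value, tt$p.value)
    expect_equal(res$cohen_d, (mean(scores) - 0.5) / sd(scores))
    expect_false(res$degenerate)

    # all scores at chance: degenerate, t = 0, d = 0
    res0 <- chance_test(rep(0.5, 10))
    expect_true(res0$degenerate)
    expect_equal(res0$statistic, 0)
    expect_equal(res0$cohen_d, 0)
    expect_equal(res0$p.value, 1)

    # constant offset with zero variance: p -> 0
    res1 <- chance_test(rep(0.6, 10))
    expect_true(res1$degenerate)
    expect_equal(res1$p.value, 0)
    expect_gt(res1$statistic, 0)

    # type-I calibration at alpha = .05 under Bernoulli(0.5) scores
    rejections <- vapply(1:400, function(i) {
      s <- stats::rbinom(21, 72, 0.5) / 72
      chance_test(s)$p.value < 0.05
    }, logical(1))
    expect_gt(mean(rejections), 0.02)
    expect_lt(mean(rejections), 0.09)
    expect_error(chance_test(0.7), "at least 2")
  })
})
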