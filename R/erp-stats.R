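#' Map experiment blocks 1--6 to block groups 1--3
#'
#' Blocks are grouped pairwise ({1,2}, {3,4}, {5,6}) to improve the
#' signal-to-noise ratio of per-group averages.
#'
#' @param block Integer vector of block numbers in 1..6.
#' @return Integer vector of block groups in 1..3.
#' @export
group_blocks <- function(block) {
  if (any(!block %in% 1:6)) abort("block numbers must lie in 1..6.")
  as.integer(ceiling(block / 2))
}

#' Analysis time windows
#'
#' Named windows (ms, half-open) used for window-mean amplitudes: the main
#' sMMN window 180--260 ms, an earlier sMMN window 150--200 ms, the location
#' MMN window 150--220 ms, plus 0--100 ms and 100--200 ms control windows.
#'
#' @param name One of `"smmn_main"`, `"smmn_early"`, `"locmmn"`,
#'   `"early_neg"`, `"positivity"`.
#' @return Numeric length-2 vector of window bounds in ms.
#' @export
window_spec <- function(name = c("smmn_main", "smmn_early", "locmmn",
                                 "early_neg", "positivity")) {
  name <- match.arg(name)
  switch(name,
         smmn_main = c(180, 260), smmn_early = c(150, 200),
         locmmn = c(150, 220), early_neg = c(0, 100),
         positivity = c(100, 200))
}

#' Window-mean amplitudes as a factorial cell table
#'
#' Averages ROI waveforms over the samples falling in a time window
#' (half-open on the sample grid) and arranges the result as one row per
#' subject x category x block group x area x lateralisation cell.
#'
#' @param waves A `roi_waveforms` tibble.
#' @param window Length-2 numeric window in ms, or a [window_spec()] name.
#' @param categories Optional subset of ending categories to keep.
#' @return A tibble (`cell_table`): `subject`, `category`, `block_group`,
#'   `area`, `lateralisation`, `amp`.
#' @export
window_means <- function(waves, window = "locmmn", categories = NULL) {
  if (is.character(window)) window <- window_spec(window)
  sel <- waves$time_ms >= window[1] & waves$time_ms < window[2]
  if (!any(sel)) abort("the ROI waveform grid does not cover the window.")
  w <- waves[sel, , drop = FALSE]
  if (!is.null(categories)) w <- w[w$category %in% categories, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(w, .data$subject, .data$category, .data$block_group,
                    .data$area, .data$lateralisation),
    amp = mean(.data$amp), .groups = "drop"
  )
  check_balanced_cells(out)
  class(out) <- c("cell_table", class(out))
  out
}

check_balanced_cells <- function(cells) {
  full <- tidyr::expand_grid(
    subject = unique(cells$subject), category = unique(cells$category),
    block_group = unique(cells$block_group), area = unique(cells$area),
    lateralisation = unique(cells$lateralisation)
  )
  missing <- dplyr::anti_join(
    full, cells,
    by = c("subject", "category", "block_group", "area", "lateralisation")
  )
  if (nrow(missing) > 0) {
    abort(paste0(
      "unbalanced cell table; ", nrow(missing), " missing cell(s), e.g. ",
      paste(utils::capture.output(print(utils::head(missing, 3))),
            collapse = "\n")
    ))
  }
  invisible(cells)
}

#' Recode ending categories as a two-level deviance factor
#'
#' Selects the two categories entering an MMN contrast and relabels them as
#' a `deviance` factor with levels `standard` and `deviant` (e.g. standards
#' vs statistical deviants for the sMMN; standards vs location deviants for
#' the location MMN).
#'
#' @param cells A cell table from [window_means()].
#' @param standard,deviant Category labels mapped to the two levels.
#' @return The cell table with a `deviance` factor column in place of
#'   `category`.
#' @export
deviance_cells <- function(cells, standard = "standard",
                           deviant = "phys_deviant") {
  keep <- cells$category %in% c(standard, deviant)
  out <- cells[keep, , drop = FALSE]
  out$deviance <- factor(ifelse(out$category == standard, "standard", "deviant"),
                         levels = c("standard", "deviant"))
  out$category <- NULL
  out
}

# ---- balanced within / mixed ANOVA via inclusion-exclusion over means ----

# drop factors that do not vary (e.g. a single block group in short runs)
active_within <- function(data, within) {
  within[vapply(within, function(v) length(unique(data[[v]])) > 1, logical(1))]
}

# integer level codes per factor column, for fast marginal means
factor_codes <- function(df, vars) {
  lapply(stats::setNames(vars, vars), function(v) {
    f <- factor(df[[v]])
    list(ix = as.integer(f), n = nlevels(f))
  })
}

subset_means <- function(codes, value, vars) {
  if (length(vars) == 0) return(rep(mean(value), length(value)))
  k <- codes[[vars[1]]]$ix
  mult <- codes[[vars[1]]]$n
  for (v in vars[-1]) {
    k <- k + mult * (codes[[v]]$ix - 1L)
    mult <- mult * codes[[v]]$n
  }
  rs <- rowsum(value, k)
  sums <- numeric(mult)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  (sums / pmax(tabulate(k, nbins = mult), 1L))[k]
}

# pure-interaction effect per observation for term `vars` (Moebius over subsets)
term_effect <- function(codes, value, vars) {
  eff <- numeric(length(value))
  subsets <- if (length(vars) == 0) list(character(0)) else {
    unlist(lapply(0:length(vars), function(k) {
      utils::combn(vars, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  for (u in subsets) {
    sign <- (-1)^(length(vars) - length(u))
    eff <- eff + sign * subset_means(codes, value, u)
  }
  eff
}

term_df <- function(df, vars) {
  if (length(vars) == 0) return(1L)
  prod(vapply(vars, function(v) length(unique(df[[v]])) - 1L, integer(1)))
}

all_subsets <- function(vars) {
  unlist(lapply(seq_along(vars), function(k) {
    utils::combn(vars, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Repeated-measures / mixed-design analysis of variance
#'
#' Fits a fully balanced within-subject ANOVA, optionally with one
#' between-subjects factor, by direct least-squares decomposition of cell
#' means (inclusion-exclusion over marginal means). Every within-subject
#' effect is tested against its own subject-by-effect interaction stratum;
#' the between-subjects effect is tested against subjects-within-groups.
#' Effect size is reported both as classical eta squared
#' (SS_effect / SS_total) and partial eta squared.
#'
#' @param data Long data frame with one value per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional name of a between-subjects factor column.
#' @param subject Name of the subject identifier column.
#' @param sphericity `"none"` (default; uncorrected integer degrees of
#'   freedom) or `"greenhouse-geisser"`, which adds Box's epsilon per
#'   within-subject term (estimated from the pooled cell covariance via an
#'   orthonormal contrast basis) and epsilon-corrected p values.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()].
#' @examples
#' d <- tidyr::expand_grid(subject = 1:8, a = c("x", "y"), b = 1:3)
#' d$y <- rnorm(nrow(d))
#' fit <- rm_anova(d, dv = "y", within = c("a", "b"))
#' tidy(fit)
#' @export
rm_anova <- function(data, dv = "amp", within, between = NULL,
                     subject = "subject",
                     sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  df <- as.data.frame(data)
  for (v in c(within, between, subject)) {
    if (!v %in% names(df)) abort(paste0("column `", v, "` not found."))
    df[[v]] <- as.character(df[[v]])
  }
  y_raw <- df[[dv]]
  if (!is.numeric(y_raw)) abort("`dv` must be numeric.")
  # aggregate replicates to subject x cell means (skipped when already unique)
  cell_key <- do.call(paste, c(df[c(subject, between, within)], sep = "\r"))
  if (anyDuplicated(cell_key)) {
    agg <- dplyr::summarise(
      dplyr::group_by(df,
                      dplyr::across(dplyr::all_of(c(subject, between, within)))),
      .value = mean(.data[[dv]]), .groups = "drop"
    )
    agg <- as.data.frame(agg)
  } else {
    agg <- df[c(subject, between, within)]
    agg$.value <- y_raw
  }
  n_cells_w <- prod(vapply(within, function(v) length(unique(agg[[v]])),
                           integer(1)))
  subjects <- unique(agg[[subject]])
  if (nrow(agg) != length(subjects) * n_cells_w) {
    abort("design is not balanced: expected one value per subject x within-cell.")
  }
  if (!is.null(between)) {
    per_subj <- unique(agg[, c(subject, between)])
    if (nrow(per_subj) != length(subjects)) {
      abort("each subject must belong to exactly one between-group.")
    }
    g_sizes <- table(per_subj[[between]])
    if (any(g_sizes < 2)) abort("each between-group needs >= 2 subjects.")
    n_groups <- length(g_sizes)
  } else {
    if (length(subjects) < 2) abort("need >= 2 subjects.")
    n_groups <- 1L
  }
  y <- agg$.value
  codes <- factor_codes(agg, c(subject, between, within))
  ss <- function(vars) sum(term_effect(codes, y, vars)^2)
  ss_total <- sum((y - mean(y))^2)
  df_subj_within <- length(subjects) - n_groups

  effects <- list()
  # between-subjects effect and its error stratum
  ss_s <- ss(subject)
  if (!is.null(between)) {
    ss_b <- ss(between)
    ss_s_within <- ss_s - ss_b
    effects[[between]] <- list(
      term = between, ss = ss_b, df = term_df(agg, between),
      ss_err = ss_s_within, df_err = df_subj_within
    )
  } else {
    ss_s_within <- ss_s
  }
  # within effects (and their interactions with the between factor)
  for (w in all_subsets(within)) {
    ss_w_err_full <- ss(c(subject, w))
    ss_bw <- if (!is.null(between)) ss(c(between, w)) else 0
    ss_err <- ss_w_err_full - ss_bw
    df_err <- df_subj_within * term_df(agg, w)
    effects[[paste(w, collapse = ":")]] <- list(
      term = paste(w, collapse = ":"), ss = ss(w), df = term_df(agg, w),
      ss_err = ss_err, df_err = df_err
    )
    if (!is.null(between)) {
      effects[[paste(c(between, w), collapse = ":")]] <- list(
        term = paste(c(between, w), collapse = ":"), ss = ss_bw,
        df = term_df(agg, between) * term_df(agg, w),
        ss_err = ss_err, df_err = df_err
      )
    }
  }
  get_num <- function(field) unname(vapply(effects, `[[`, numeric(1), field))
  tab <- tibble::tibble(
    term = unname(vapply(effects, `[[`, character(1), "term")),
    sumsq = get_num("ss"), df = get_num("df"),
    sumsq_error = get_num("ss_err"), df_error = get_num("df_err")
  )
  ms <- tab$sumsq / tab$df
  ms_err <- tab$sumsq_error / tab$df_error
  tab$statistic <- ifelse(ms_err > 0, ms / ms_err,
                          ifelse(tab$sumsq > 0, Inf, 0))
  tab$p.value <- pf(tab$statistic, tab$df, tab$df_error, lower.tail = FALSE)
  tab$eta_sq <- if (ss_total > 0) tab$sumsq / ss_total else 0
  tab$eta_sq_partial <- ifelse(tab$sumsq + tab$sumsq_error > 0,
                               tab$sumsq / (tab$sumsq + tab$sumsq_error), 0)
  if (sphericity == "greenhouse-geisser") {
    eps_by_w <- gg_epsilons(agg, subject, between, within)
    within_part <- vapply(tab$term, function(t) {
      paste(intersect(strsplit(t, ":", fixed = TRUE)[[1]], within),
            collapse = ":")
    }, character(1))
    tab$gg_epsilon <- unname(eps_by_w[within_part])
    tab$p.value_gg <- ifelse(
      is.na(tab$gg_epsilon), NA_real_,
      pf(tab$statistic, tab$gg_epsilon * tab$df,
         tab$gg_epsilon * tab$df_error, lower.tail = FALSE)
    )
  }
  structure(
    list(table = tab, ss_total = ss_total,
         n_subjects = length(subjects), n_groups = n_groups,
         within = within, between = between,
         ss_subjects_within = ss_s_within, df_subjects_within = df_subj_within),
    class = "rm_anova"
  )
}

# orthonormal basis of the contrast space of one factor (l x (l-1)), or the
# normalised mean column when the factor is not part of the term
orthonormal_contrasts <- function(l, in_term) {
  if (!in_term) return(matrix(1 / sqrt(l), l, 1))
  qr.Q(qr(cbind(1, stats::contr.helmert(l))))[, -1, drop = FALSE]
}

# Box/Greenhouse-Geisser epsilon per within-subject term, from the pooled
# (within between-groups) covariance of the subject x within-cell matrix
gg_epsilons <- function(agg, subject, between, within) {
  for (v in within) agg[[v]] <- as.character(agg[[v]])
  levels_list <- lapply(within, function(v) sort(unique(agg[[v]])))
  names(levels_list) <- within
  # cell index: first within factor varies slowest (kronecker convention)
  key_parts <- lapply(within, function(v) agg[[v]])
  ord_key <- do.call(paste, c(key_parts, sep = "\r"))
  cell_levels <- do.call(paste, c(
    rev(expand.grid(rev(levels_list), stringsAsFactors = FALSE)),
    sep = "\r"
  ))
  subj <- agg[[subject]]
  subjects <- unique(subj)
  Y <- matrix(NA_real_, length(subjects), length(cell_levels),
              dimnames = list(subjects, NULL))
  Y[cbind(match(subj, subjects), match(ord_key, cell_levels))] <- agg$.value
  grp <- if (is.null(between)) {
    rep("all", length(subjects))
  } else {
    agg[[between]][match(subjects, subj)]
  }
  centred <- Y
  for (g in unique(grp)) {
    rows <- grp == g
    centred[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                             colMeans(Y[rows, , drop = FALSE]))
  }
  sigma <- crossprod(centred) / max(1L, length(subjects) - length(unique(grp)))
  out <- c()
  for (w in all_subsets(within)) {
    M <- Reduce(kronecker, lapply(within, function(v) {
      orthonormal_contrasts(length(levels_list[[v]]), v %in% w)
    }))
    C <- t(M) %*% sigma %*% M
    d <- ncol(M)
    denom <- d * sum(C^2)
    eps <- if (denom > 0) sum(diag(C))^2 / denom else 1
    out[paste(w, collapse = ":")] <- min(1, max(1 / d, eps))
  }
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA:", x$n_subjects, "subjects",
      if (!is.null(x$between)) paste0("in ", x$n_groups, " groups"), "\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-40s F(%d, %d) = %.2f, p = %.4g, eta^2 = %.3f\n",
                tab$term[i], tab$df[i], tab$df_error[i], tab$statistic[i],
                tab$p.value[i], tab$eta_sq[i]))
  }
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_groups = x$n_groups,
    ss_total = x$ss_total,
    method = if (is.null(x$between)) "within-subjects ANOVA" else "mixed ANOVA"
  )
}

#' Mixed-design contrast between isochronicity groups
#'
#' Combines the cell tables of the isochronous and non-isochronous cohorts,
#' fits the mixed ANOVA with isochronicity as the between-subjects factor,
#' and reports per-group simple effects of deviance.
#'
#' @param cells_iso,cells_noniso Cell tables with a `deviance` column (see
#'   [deviance_cells()]) for the two cohorts.
#' @param within Within-subject factors (default deviance x area x
#'   lateralisation x block_group).
#' @return A list of class `interaction_contrast` with elements `anova`
#'   (mixed `rm_anova`), `simple_effects` (per-group deviance `rm_anova`s),
#'   and `interaction` (the deviance-by-isochronicity row of the table).
#' @export
interaction_contrast <- function(cells_iso, cells_noniso,
                                 within = c("deviance", "area",
                                            "lateralisation", "block_group")) {
  ci <- dplyr::mutate(cells_iso, isochronicity = "isochronous",
                      subject = paste0("iso_", .data$subject))
  cn <- dplyr::mutate(cells_noniso, isochronicity = "non_isochronous",
                      subject = paste0("noniso_", .data$subject))
  combined <- dplyr::bind_rows(ci, cn)
  within <- active_within(combined, within)
  fit <- rm_anova(combined, dv = "amp", within = within,
                  between = "isochronicity")
  simple <- list(
    isochronous = rm_anova(ci, dv = "amp", within = within),
    non_isochronous = rm_anova(cn, dv = "amp", within = within)
  )
  inter_term <- paste0("isochronicity:", within[1])
  structure(
    list(anova = fit, simple_effects = simple,
         interaction = fit$table[fit$table$term == inter_term, ]),
    class = "interaction_contrast"
  )
}

#' @export
print.interaction_contrast <- function(x, ...) {
  print(x$anova)
  cat("\nSimple effects of", x$anova$within[1], "per group:\n")
  for (g in names(x$simple_effects)) {
    row <- x$simple_effects[[g]]$table
    row <- row[row$term == x$anova$within[1], ]
    cat(sprintf("  %-16s F(%d, %d) = %.2f, p = %.4g\n", g, row$df,
                row$df_error, row$statistic, row$p.value))
  }
  invisible(x)
}

#' One-sample t test of familiarity scores against chance
#'
#' Tests whether mean proportion-correct scores differ from chance (0.5 by
#' default) with a two-sided one-sample t test, reporting Cohen's d. A
#' zero-variance sample is flagged as degenerate (t is 0 when the mean
#' equals chance, infinite otherwise).
#'
#' @param scores Numeric vector of per-subject proportions.
#' @param chance Chance level (default 0.5).
#' @return A tibble: `estimate`, `statistic`, `df`, `p.value`, `cohen_d`,
#'   `degenerate`.
#' @export
chance_test <- function(scores, chance = 0.5) {
  if (length(scores) < 2) abort("need at least 2 scores.")
  m <- mean(scores)
  s <- sd(scores)
  n <- length(scores)
  if (s == 0) {
    t_stat <- if (m == chance) 0 else sign(m - chance) * Inf
    p <- if (m == chance) 1 else 0
    return(tibble::tibble(estimate = m, statistic = t_stat, df = n - 1,
                          p.value = p, cohen_d = if (m == chance) 0 else
                            sign(m - chance) * Inf,
                          degenerate = TRUE))
  }
  t_stat <- (m - chance) / (s / sqrt(n))
  tibble::tibble(
    estimate = m, statistic = t_stat, df = n - 1,
    p.value = 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE),
    cohen_d = (m - chance) / s, degenerate = FALSE
  )
}
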