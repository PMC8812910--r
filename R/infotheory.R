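#' Information content (surprisal) of an event, in bits
#'
#' The surprisal of an event with occurrence probability `p` is
#' \eqn{h = \log_2(1/p)}. Rare events carry high information content and are
#' expected to evoke larger prediction-error responses; certain events
#' (`p = 1`) carry none.
#'
#' @param p Numeric vector of probabilities in `(0, 1]`.
#' @return Numeric vector of surprisal values in bits.
#' @examples
#' information_content(c(0.9, 0.1)) # high- vs low-probability triplet ending
#' @export
information_content <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must be numeric with all values in (0, 1].")
  }
  log2(1 / p)
}

#' Shannon entropy of a discrete conditional distribution, in bits
#'
#' Computes \eqn{H = \sum_i p_i \log_2(1/p_i)} with the convention
#' \eqn{0 \log(1/0) = 0}. Used for the entropy of the triplet ending given its
#' root, where the conditional distribution over the two possible endings is
#' `{0.9, 0.1}` under the default transition table.
#'
#' @param p Numeric vector of probabilities; must sum to 1 within `tol`.
#' @param tol Tolerance on the probability sum (default `1e-8`).
#' @return Entropy in bits (scalar).
#' @examples
#' conditional_entropy(c(0.9, 0.1))
#' conditional_entropy(c(0.5, 0.5)) # one fair bit
#' @export
conditional_entropy <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    abort("`p` must be a numeric vector of non-negative probabilities.")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("probabilities sum to %.10f, not 1 (tol %g).", sum(p), tol))
  }
  pos <- p[p > 0]
  sum(pos * log2(1 / pos))
}

#' Entropy of a uniform inter-stimulus-pause distribution, in bits
#'
#' For `n_levels` equiprobable pause durations the entropy is
#' \eqn{\log_2 n}. Isochronous presentation has a single pause value and
#' therefore zero temporal entropy; jittered presentation with integer
#' millisecond pauses drawn uniformly from 0--300 ms has 301 levels.
#'
#' @param n_levels Positive integer count of equiprobable pause values.
#' @return Entropy in bits.
#' @examples
#' isi_entropy(301) # jittered 0..300 ms pause set
#' isi_entropy(1)   # isochronous
#' @export
isi_entropy <- function(n_levels) {
  if (!is.numeric(n_levels) || length(n_levels) != 1 || !is.finite(n_levels) ||
      n_levels < 1 || n_levels != round(n_levels)) {
    abort("`n_levels` must be a single integer >= 1.")
  }
  log2(n_levels)
}

#' Predictability summary of a triplet-stream design
#'
#' Collects the information-theoretic characterisation of the paradigm in one
#' tibble: surprisal of high- and low-probability triplet endings, conditional
#' entropy of the ending given the root, surprisal of standard- and
#' deviant-location endings, and the timing entropy of isochronous (0 bits)
#' and jittered presentation.
#'
#' @param tt Transition table from [transition_table()].
#' @param cfg Stream configuration from [stream_config()]; determines the
#'   number of equiprobable pause levels in jittered mode.
#' @return A tibble with columns `quantity`, `symbol`, `probability`, `bits`.
#' @examples
#' predictability_table()
#' @export
predictability_table <- function(tt = transition_table(),
                                 cfg = stream_config()) {
  n_pause_levels <- diff(cfg$pause_range_ms) + 1L
  tibble::tibble(
    quantity = c(
      "standard ending surprisal", "statistical deviant surprisal",
      "ending|root conditional entropy",
      "standard location surprisal", "deviant location surprisal",
      "timing entropy (isochronous)", "timing entropy (jittered)"
    ),
    symbol = c("h(ending)", "h(ending)", "H(ending|root)",
               "h(location)", "h(location)", "H(ISIs)", "H(ISIs)"),
    probability = c(tt$p_ending_high, tt$p_ending_low, NA,
                    tt$p_loc_std_ending, 1 - tt$p_loc_std_ending, NA, NA),
    bits = c(
      information_content(tt$p_ending_high),
      information_content(tt$p_ending_low),
      conditional_entropy(c(tt$p_ending_high, tt$p_ending_low)),
      information_content(tt$p_loc_std_ending),
      information_content(1 - tt$p_loc_std_ending),
      isi_entropy(1L),
      isi_entropy(n_pause_levels)
    )
  )
}
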