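# Expressed-gene calling from the ranked-intensity curve. Microarray
# background noise makes the transcribed/untranscribed boundary unclear; the
# ranked per-set relative expression curve is roughly sigmoidal and the end
# of its plateau (where the declining gradient is shallowest) is used as the
# cutoff.

#' Per-set expression relative to the array average
#'
#' Each probe set's mean expression over the chosen samples divided by the
#' grand mean over all sets and those samples, so that a value of 1
#' corresponds to the array average and the output averages exactly 1.
#'
#' @param expr Probe set x sample log2 expression matrix.
#' @param samples Sample (column) subset to average over; defaults to all.
#' @return Named numeric vector of relative expression values.
#' @export
relative_expression <- function(expr, samples = colnames(expr)) {
  if (length(samples) == 0) stop("sample subset must be non-empty")
  v <- rowMeans(expr[, samples, drop = FALSE])
  grand <- mean(v)
  if (!is.finite(grand) || grand <= 0) {
    stop("grand mean of expression must be positive")
  }
  v / grand
}

#' Locate the plateau end of the ranked expression curve
#'
#' Sorts the values in descending order, smooths the curve with a centred
#' moving average, takes first differences, and returns the interior rank at
#' which the absolute gradient is smallest — the point where the declining
#' curve is at its shallowest. Exact gradient ties break to the smallest
#' rank (the more stringent cutoff).
#'
#' @param values Per-set relative expression values (length >= 3 x
#'   `smoothing_window`).
#' @param smoothing_window Width of the moving average (odd; default 51).
#' @param interior Rank-fraction band searched for the minimum (default
#'   `c(0.1, 0.9)`), excluding the noisy curve ends.
#' @return List with `cutoff_rank_fraction` and `cutoff_value` (the
#'   smoothed curve value at the cutoff rank).
#' @export
find_inflection <- function(values, smoothing_window = 51,
                            interior = c(0.1, 0.9)) {
  n <- length(values)
  if (n < 3 * smoothing_window) {
    stop("need at least 3 * smoothing_window values")
  }
  s <- sort(values, decreasing = TRUE)
  sm <- as.numeric(stats::filter(s, rep(1 / smoothing_window, smoothing_window),
                                 sides = 2))
  grad <- diff(sm)                       # gradient between ranks k and k+1
  ranks <- seq_len(n - 1)
  ok <- is.finite(grad) &
    ranks / n >= interior[1] & ranks / n <= interior[2]
  if (!any(ok)) stop("interior band contains no usable ranks")
  cand <- which(ok)
  best <- cand[which.min(abs(grad[cand]))]  # first minimum = smallest rank
  list(cutoff_rank_fraction = best / n, cutoff_value = sm[best])
}

#' Call expressed probe sets
#'
#' A probe set is called expressed when its relative expression (see
#' [relative_expression()]) is at or above the cutoff, found from the
#' ranked-intensity curve with [find_inflection()] or supplied directly via
#' `override_cutoff`.
#'
#' @param expr Probe set x sample log2 expression matrix.
#' @param samples Sample subset defining the transcriptome state examined
#'   (conventionally the water-sufficient samples of one genotype).
#' @param override_cutoff Optional relative-expression cutoff to use instead
#'   of the inflection search (1 = array average). A warning is issued if it
#'   lies outside the observed value range; an empty or full call set is
#'   then permitted.
#' @param smoothing_window,interior Passed to [find_inflection()].
#' @return A list of class `expressed_calls` with `cutoff_relative_value`,
#'   `cutoff_rank_fraction`, `expressed_sets`, `relative_values` and
#'   `smoothing_window`.
#' @export
call_expressed <- function(expr, samples = colnames(expr),
                           override_cutoff = NULL,
                           smoothing_window = 51, interior = c(0.1, 0.9)) {
  rel <- relative_expression(expr, samples)
  if (is.null(override_cutoff)) {
    infl <- find_inflection(rel, smoothing_window, interior)
    cutoff <- infl$cutoff_value
    rank_fraction <- infl$cutoff_rank_fraction
  } else {
    cutoff <- override_cutoff
    if (cutoff < min(rel) || cutoff > max(rel)) {
      warning("override_cutoff lies outside the observed value range")
    }
    rank_fraction <- mean(rel >= cutoff)
  }
  structure(
    list(
      cutoff_relative_value = cutoff,
      cutoff_rank_fraction = rank_fraction,
      expressed_sets = names(rel)[rel >= cutoff],
      relative_values = rel,
      smoothing_window = smoothing_window
    ),
    class = "expressed_calls"
  )
}
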