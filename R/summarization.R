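# Masked RMA-style summarization: log2 transform, quantile normalization
# across hybridisations over the retained probes, and per-probe-set median
# polish. The classic RMA convolution background correction is deliberately
# omitted (see the methods vignette); `background_correct` is the hook where
# a model could be inserted.

#' Summarization configuration
#'
#' @param max_polish_iterations Maximum median-polish sweeps (>= 1).
#' @param polish_tolerance Convergence tolerance on the relative change of
#'   the total absolute residual between sweeps.
#' @param normalize Whether to quantile-normalize across hybridisations
#'   before summarization.
#' @return A list of class `summarization_config`.
#' @export
summarization_config <- function(max_polish_iterations = 10,
                                 polish_tolerance = 0.01,
                                 normalize = TRUE) {
  if (max_polish_iterations < 1) stop("max_polish_iterations must be >= 1")
  if (polish_tolerance <= 0) stop("polish_tolerance must be > 0")
  structure(
    list(max_polish_iterations = max_polish_iterations,
         polish_tolerance = polish_tolerance,
         normalize = isTRUE(normalize)),
    class = "summarization_config"
  )
}

# No-op background-correction hook (RMA's normal+exponential deconvolution
# would go here).
background_correct <- function(m) m

#' Quantile normalization
#'
#' Forces every column to the same distribution: the per-rank mean of the
#' column-sorted values, assigned back in each column's original rank order.
#' Ties within a column receive the mean of the reference values at their
#' tied ranks, so tied input values stay tied.
#'
#' @param m Numeric matrix (probes x hybridisations), typically log2 scale.
#' @return Matrix of the same shape; returned unchanged with a warning if
#'   there are fewer than two columns.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(5, 1, 3)))
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    warning("quantile_normalize: fewer than 2 columns; returning input unchanged")
    return(m)
  }
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    sorted <- m[o, j]
    grp <- cumsum(c(TRUE, sorted[-1] != sorted[-length(sorted)]))
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Median polish of one probe set's log2 intensities
#'
#' Fits the additive model `overall + probe + sample` by Tukey's alternating
#' median sweeps (rows first), accumulating the median of the row and column
#' effects into the overall term each sweep. The per-sample expression
#' summary is `overall + sample effect`. Iteration stops when the total
#' absolute residual changes by less than `polish_tolerance` (relative) or
#' after `max_polish_iterations` sweeps.
#'
#' @param m Numeric matrix, probes (rows) x samples (columns); must be
#'   non-empty.
#' @param config A [summarization_config()].
#' @return List with `summary` (per-sample), `overall`, `row_effects`,
#'   `col_effects`, `residuals`, `iterations`, `converged`.
#' @examples
#' median_polish(matrix(c(1, 3, 2, 4), 2, 2))$summary
#' @export
median_polish <- function(m, config = summarization_config()) {
  if (!is.matrix(m) || nrow(m) < 1 || ncol(m) < 1) {
    stop("median_polish requires a non-empty matrix")
  }
  nr <- nrow(m); nc <- ncol(m)
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  r <- m
  oldsum <- 0
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(config$max_polish_iterations)) {
    rdelta <- apply(r, 1, stats::median)
    r <- r - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(r, 2, stats::median)
    r <- sweep(r, 2, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(r))
    converged <- newsum == 0 ||
      abs(newsum - oldsum) < config$polish_tolerance * newsum
    if (converged) break
    oldsum <- newsum
  }
  list(
    summary = stats::setNames(overall + col_eff, colnames(m)),
    overall = overall,
    row_effects = stats::setNames(row_eff, rownames(m)),
    col_effects = stats::setNames(col_eff, colnames(m)),
    residuals = r, iterations = iter, converged = converged
  )
}

#' Masked RMA-style probe-set summarization
#'
#' Restricts the probe-level intensities to the mask's retained probe pairs,
#' log2-transforms, quantile-normalizes across hybridisations over those
#' probes (unless `config$normalize` is `FALSE`), and median-polishes each
#' retained probe set into one log2 expression value per sample.
#' Normalization is computed over the masked probes only, mirroring
#' summarization from a custom chip definition.
#'
#' @param intensities Probe x sample linear-scale intensity matrix.
#' @param mask A `probe_mask` from [select_probe_pairs()] or [full_mask()].
#' @param layout The [chip_layout()] shared by mask and intensities.
#' @param config A [summarization_config()].
#' @return Probe set x sample log2 expression matrix; rows are the mask's
#'   retained sets, sorted by probe_set_id.
#' @export
rma_summarize <- function(intensities, mask, layout,
                          config = summarization_config()) {
  pairs <- layout$probe_id[layout$probe_id %in% mask$retained_pairs &
                             layout$probe_id %in% rownames(intensities)]
  set_of <- stats::setNames(layout$probe_set_id, layout$probe_id)[pairs]
  sets <- sort(mask$retained_sets)
  missing <- setdiff(sets, unique(set_of))
  if (length(missing) > 0) {
    stop("retained probe set(s) with no probes in the intensity matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- log2(intensities[pairs, , drop = FALSE])
  m <- background_correct(m)
  if (config$normalize && ncol(m) >= 2) {
    m <- quantile_normalize(m)
  }
  idx <- split(seq_along(pairs), set_of)
  out <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(sets, colnames(m)))
  for (s in sets) {
    out[s, ] <- median_polish(m[idx[[s]], , drop = FALSE], config)$summary
  }
  out
}
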