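# Differential expression per treatment contrast (Welch t, BH FDR,
# fold-change gate), cross-genotype DEG overlap, responsive/perturbed
# classification against the recovery treatment, PCA QC, and relative qPCR
# quantification (2^-ddCt).

#' Two-sample t-test with degenerate-variance handling
#'
#' Two-sided unequal-variance (Welch) t-test with Welch-Satterthwaite
#' degrees of freedom; a pooled-variance variant is available. When both
#' groups have zero variance the test is degenerate: equal means give
#' `t = 0, p = 1`; different means give `p = 0` with the `degenerate` flag
#' set.
#'
#' @param group1,group2 Numeric replicate values (>= 2 each).
#' @param pooled Use the pooled-variance (equal-variance) t-test instead of
#'   Welch.
#' @return List with `t`, `p`, `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 7))
#' @export
welch_t <- function(group1, group2, pooled = FALSE) {
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 values")
  }
  v1 <- stats::var(group1)
  v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) {
    if (mean(group1) == mean(group2)) {
      return(list(t = 0, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(mean(group1) - mean(group2)) * Inf, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(group1, group2, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_i = min over j >= rank(i) of
#' p_(j) * m / j`, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Test one treatment contrast within a genotype
#'
#' For every probe set, compares the two treatment groups of a genotype:
#' group means, signed log2 fold change (group1 - group2), fold change
#' `2^|log2fc|` with direction (up/down in group1), t statistic, p-value and
#' BH q-value computed over all probe sets of the contrast.
#'
#' @param expr Probe set x sample log2 expression matrix.
#' @param sheet A [sample_sheet()].
#' @param genotype Genotype analysed.
#' @param treatment_pair Character vector of length 2 `(group1, group2)`;
#'   default water-limited versus water-sufficient.
#' @param pooled Use the pooled-variance t-test (see [welch_t()]).
#' @return A data.frame of class `contrast_result` with one row per probe
#'   set; attributes `genotype` and `treatment_pair` record the contrast.
#' @export
run_contrast <- function(expr, sheet, genotype,
                         treatment_pair = c("water_limited", "water_sufficient"),
                         pooled = FALSE) {
  stopifnot(length(treatment_pair) == 2)
  cols <- lapply(treatment_pair, function(tr) {
    ids <- active_samples(sheet, genotype, tr)$sample_id
    ids <- intersect(ids, colnames(expr))
    if (length(ids) < 2) {
      stop(sprintf("group '%s/%s' has fewer than 2 non-excluded replicates",
                   genotype, tr))
    }
    ids
  })
  m1 <- expr[, cols[[1]], drop = FALSE]
  m2 <- expr[, cols[[2]], drop = FALSE]
  n <- nrow(expr)
  t_stat <- p <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    res <- welch_t(m1[i, ], m2[i, ], pooled = pooled)
    t_stat[i] <- res$t
    p[i] <- res$p
    degenerate[i] <- res$degenerate
  }
  mean1 <- rowMeans(m1)
  mean2 <- rowMeans(m2)
  log2fc <- mean1 - mean2
  out <- data.frame(
    probe_set_id = rownames(expr),
    mean_group1 = mean1, mean_group2 = mean2,
    log2fc = log2fc, fold_change = 2^abs(log2fc),
    direction = ifelse(log2fc >= 0, "up", "down"),
    t = t_stat, p = p, q = bh_adjust(p), degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "genotype") <- genotype
  attr(out, "treatment_pair") <- treatment_pair
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Call differentially expressed probe sets
#'
#' Runs [run_contrast()] and keeps probe sets passing both gates:
#' `q <= q_max` and `fold_change > fc_min` (strict). The returned table
#' carries a contrast id and a `response_class` column initialised to
#' `unclassified` (see [classify_response()]).
#'
#' @inheritParams run_contrast
#' @param q_max FDR gate (default 0.05).
#' @param fc_min Fold-change gate, strict `>` (default 2).
#' @return A data.frame of class `deg_table`; attribute `contrast_result`
#'   holds the full per-set statistics.
#' @export
call_degs <- function(expr, sheet, genotype,
                      treatment_pair = c("water_limited", "water_sufficient"),
                      q_max = 0.05, fc_min = 2, pooled = FALSE) {
  cr <- run_contrast(expr, sheet, genotype, treatment_pair, pooled)
  keep <- cr$q <= q_max & cr$fold_change > fc_min
  out <- data.frame(
    contrast = rep(paste(genotype, treatment_pair[1], "vs",
                         treatment_pair[2], sep = "."), sum(keep)),
    probe_set_id = cr$probe_set_id[keep],
    direction = cr$direction[keep],
    log2fc = cr$log2fc[keep],
    fold_change = cr$fold_change[keep],
    p = cr$p[keep], q = cr$q[keep],
    response_class = rep("unclassified", sum(keep)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "genotype") <- genotype
  attr(out, "treatment_pair") <- treatment_pair
  attr(out, "q_max") <- q_max
  attr(out, "fc_min") <- fc_min
  attr(out, "contrast_result") <- cr
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap of two DEG tables
#'
#' Matches probe sets by id and direction, giving the common up- and
#' down-regulated genes and the genotype-specific remainders.
#'
#' @param table_a,table_b [call_degs()] tables for the same contrast
#'   definition in two genotypes.
#' @return A list with `common_up`, `common_down` (id vectors),
#'   `n_common`, `n_specific_a`, `n_specific_b`.
#' @export
overlap_degs <- function(table_a, table_b) {
  key_a <- paste(table_a$probe_set_id, table_a$direction)
  key_b <- paste(table_b$probe_set_id, table_b$direction)
  common <- intersect(key_a, key_b)
  dirs <- sub("^.* ", "", common)
  ids <- sub(" [a-z]+$", "", common)
  list(
    common_up = ids[dirs == "up"],
    common_down = ids[dirs == "down"],
    n_common = length(common),
    n_specific_a = length(setdiff(key_a, key_b)),
    n_specific_b = length(setdiff(key_b, key_a))
  )
}

#' Classify stress DEGs as dehydration-responsive or perturbed
#'
#' A stress DEG (water-limited vs water-sufficient) is `responsive` when its
#' expression returns to the pre-treatment level after re-watering and
#' `perturbed` when the change persists (a dehydration-induced state
#' change). Under the default rule, "returned" is read as non-significance
#' of the recovery-vs-water-sufficient contrast (`q > q_max` or
#' `fold_change <= fc_min`); the alternative `"stress_vs_recovery"` rule
#' instead reads significance of the water-limited-vs-recovery contrast as
#' evidence of return. Probe sets missing from the classifying contrast stay
#' `unclassified`.
#'
#' @param deg_stress A [call_degs()] table for water-limited vs
#'   water-sufficient.
#' @param contrast_rec A [run_contrast()] result: recovery vs
#'   water-sufficient for the default rule, water-limited vs recovery for
#'   the alternative rule.
#' @param q_max,fc_min Significance gates, as in [call_degs()].
#' @param rule Classification rule (see above).
#' @return `deg_stress` with `response_class` filled in.
#' @export
classify_response <- function(deg_stress, contrast_rec,
                              q_max = 0.05, fc_min = 2,
                              rule = c("recovery_ns", "stress_vs_recovery")) {
  rule <- match.arg(rule)
  idx <- match(deg_stress$probe_set_id, contrast_rec$probe_set_id)
  significant <- contrast_rec$q[idx] <= q_max &
    contrast_rec$fold_change[idx] > fc_min
  cls <- rep("unclassified", nrow(deg_stress))
  known <- !is.na(idx)
  if (rule == "recovery_ns") {
    cls[known] <- ifelse(significant[known], "perturbed", "responsive")
  } else {
    cls[known] <- ifelse(significant[known], "responsive", "perturbed")
  }
  deg_stress$response_class <- cls
  deg_stress
}

#' PCA variance fractions and sample scores
#'
#' Principal component analysis of the samples after centring each probe
#' set, the standard QC view of a designed expression experiment.
#'
#' @param expr Probe set x sample log2 expression matrix (>= 2 samples).
#' @param n_components Number of components to report (default: all).
#' @return List with `variance_fraction`, `scores` (samples x components)
#'   and `constant` (TRUE when the matrix had no variance; all fractions are
#'   then 0).
#' @export
pca_variance <- function(expr, n_components = NULL) {
  if (ncol(expr) < 2) stop("PCA requires at least 2 samples")
  x <- t(expr - rowMeans(expr))
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  v <- pr$sdev^2
  total <- sum(v)
  constant <- total <= .Machine$double.eps * length(v)
  frac <- if (constant) rep(0, length(v)) else v / total
  if (!is.null(n_components)) {
    n_components <- min(n_components, length(frac))
    frac <- frac[seq_len(n_components)]
    pr$x <- pr$x[, seq_len(n_components), drop = FALSE]
  }
  list(variance_fraction = frac, scores = pr$x, constant = constant)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Normalizes each target gene's cycle threshold to a reference
#' (housekeeping) gene per sample (`dCt = Ct_target - Ct_reference`),
#' averages per condition, subtracts the calibrator condition
#' (`ddCt = mean dCt(condition) - mean dCt(calibrator)`), and reports the
#' fold change `2^-ddCt`.
#'
#' @param ct Data.frame with columns `gene, sample, condition, ct`.
#' @param reference_gene Housekeeping gene; must be measured in every
#'   sample.
#' @param calibrator_condition Condition used as the calibrator.
#' @return Data.frame with `gene, condition, delta_delta_ct, fold_change`
#'   for every non-reference gene and condition.
#' @examples
#' ct <- data.frame(
#'   gene = c("g", "g", "actin", "actin"),
#'   sample = c("s1", "s2", "s1", "s2"),
#'   condition = c("treated", "control", "treated", "control"),
#'   ct = c(20, 18, 15, 15)
#' )
#' delta_delta_ct(ct, "actin", "control")
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator_condition) {
  required <- c("gene", "sample", "condition", "ct")
  if (!all(required %in% names(ct))) {
    stop("ct table must have columns: ", paste(required, collapse = ", "))
  }
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  targets <- ct[ct$gene != reference_gene, , drop = FALSE]
  missing <- setdiff(unique(targets$sample), ref$sample)
  if (length(missing) > 0) {
    stop("reference gene Ct missing for sample(s): ",
         paste(missing, collapse = ", "))
  }
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  targets$dct <- targets$ct - ref_ct[targets$sample]
  agg <- stats::aggregate(dct ~ gene + condition, data = targets, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(d) {
    cal <- d$dct[d$condition == calibrator_condition]
    if (length(cal) != 1) {
      stop("calibrator condition missing for gene '", d$gene[1], "'")
    }
    data.frame(
      gene = d$gene, condition = d$condition,
      delta_delta_ct = d$dct - cal,
      fold_change = 2^(-(d$dct - cal)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
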