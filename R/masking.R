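# gDNA-based probe masking: probe pairs whose genomic-DNA hybridisation
# intensity exceeds a threshold are taken as evidence that the probe matches
# the target species' sequence; the retained pairs define a genotype-specific
# custom chip definition.

layout_signature <- function(layout) {
  paste(nrow(layout), length(unique(layout$probe_set_id)))
}

#' Select probe pairs by gDNA intensity threshold
#'
#' Retains every probe pair whose gDNA intensity is strictly greater than
#' `tau`, and every probe set with at least `min_pairs_per_set` retained
#' pairs. Ties at the threshold are excluded (strict `>`).
#'
#' @param gdna_column Named numeric vector of linear-scale gDNA intensities
#'   covering all probe pairs in `layout` (a one-column slice of the matrix
#'   from [simulate_gdna()] or [read_intensities()]).
#' @param layout A [chip_layout()].
#' @param tau Intensity threshold, >= 0.
#' @param min_pairs_per_set Minimum retained pairs for a probe set to be
#'   kept (default 1: a set is lost only when all its pairs are lost).
#' @param genotype Optional genotype label recorded in the mask.
#' @return An object of class `probe_mask`: a list with `genotype`,
#'   `threshold`, `min_pairs_per_set`, `retained_pairs`, `retained_sets`
#'   and `set_pair_counts` (retained-pair count per retained set).
#' @examples
#' lay <- chip_layout(c("p1", "p2", "p3", "p4"),
#'                    c("S1", "S1", "S2", "S2"), c(0, 1, 0, 1))
#' gd <- c(p1 = 150, p2 = 50, p3 = 80, p4 = 90)
#' select_probe_pairs(gd, lay, tau = 100)
#' @export
select_probe_pairs <- function(gdna_column, layout, tau,
                               min_pairs_per_set = 1, genotype = NA_character_) {
  if (tau < 0) stop("tau must be >= 0")
  missing <- setdiff(layout$probe_id, names(gdna_column))
  if (length(missing) > 0) {
    stop("gDNA intensities missing for probe(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  v <- gdna_column[layout$probe_id]
  keep <- v > tau
  retained_pairs <- layout$probe_id[keep]
  counts <- table(factor(layout$probe_set_id[keep],
                         levels = unique(layout$probe_set_id)))
  counts <- counts[counts >= min_pairs_per_set]
  structure(
    list(
      genotype = genotype, threshold = tau,
      min_pairs_per_set = min_pairs_per_set,
      retained_pairs = retained_pairs,
      retained_sets = names(counts),
      set_pair_counts = stats::setNames(as.integer(counts), names(counts)),
      layout_signature = layout_signature(layout)
    ),
    class = "probe_mask"
  )
}

#' Sweep masking thresholds
#'
#' Computes retained probe-pair and probe-set counts for each threshold and
#' each gDNA hybridisation (genotype), the structure used to choose a
#' working threshold. Counts are non-increasing in the threshold.
#'
#' @param gdna Probe x genotype gDNA intensity matrix.
#' @param layout A [chip_layout()].
#' @param tau_list Non-empty numeric vector of thresholds.
#' @param min_pairs_per_set Passed to [select_probe_pairs()].
#' @return A data.frame with columns `genotype, tau, n_retained_sets,
#'   n_retained_pairs`, one row per genotype per threshold.
#' @export
sweep_thresholds <- function(gdna, layout, tau_list, min_pairs_per_set = 1) {
  if (length(tau_list) == 0) stop("tau_list must be non-empty")
  rows <- list()
  for (g in colnames(gdna)) {
    col <- gdna[, g]
    for (tau in sort(tau_list)) {
      m <- select_probe_pairs(col, layout, tau, min_pairs_per_set, g)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, tau = tau,
        n_retained_sets = length(m$retained_sets),
        n_retained_pairs = length(m$retained_pairs),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare the probe sets retained by two masks
#'
#' @param mask_a,mask_b [select_probe_pairs()] masks built on the same
#'   layout.
#' @return A list with `n_common_sets`, `n_specific_a`, `n_specific_b` and
#'   the corresponding probe-set id vectors.
#' @export
compare_masks <- function(mask_a, mask_b) {
  if (!identical(mask_a$layout_signature, mask_b$layout_signature)) {
    stop("masks were built on different layouts")
  }
  common <- intersect(mask_a$retained_sets, mask_b$retained_sets)
  only_a <- setdiff(mask_a$retained_sets, mask_b$retained_sets)
  only_b <- setdiff(mask_b$retained_sets, mask_a$retained_sets)
  list(
    n_common_sets = length(common),
    n_specific_a = length(only_a),
    n_specific_b = length(only_b),
    common_sets = common, specific_a = only_a, specific_b = only_b
  )
}

#' Write a custom chip definition
#'
#' Emits the layout restricted to the mask's retained probe pairs (within
#' retained probe sets), with pair indices renumbered to stay contiguous, as
#' a layout TSV. Reading the file back with [read_layout()] and summarizing
#' against a full mask is equivalent to summarizing the original layout
#' against the mask directly.
#'
#' @param mask A `probe_mask`.
#' @param layout The [chip_layout()] the mask was built on.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_custom_definition <- function(mask, layout, path) {
  keep <- layout$probe_id %in% mask$retained_pairs &
    layout$probe_set_id %in% mask$retained_sets
  sub <- as.data.frame(layout)[keep, , drop = FALSE]
  sub <- sub[order(sub$probe_set_id, sub$pair_index), , drop = FALSE]
  sub$pair_index <- as.integer(
    stats::ave(sub$pair_index, sub$probe_set_id, FUN = seq_along) - 1
  )
  write_tsv_stable(sub, path)
}

#' A mask retaining every probe pair of a layout
#'
#' Convenience for summarizing unmasked data or data already restricted to a
#' custom chip definition.
#'
#' @param layout A [chip_layout()].
#' @param genotype Optional genotype label.
#' @return A `probe_mask` retaining all pairs and sets.
#' @export
full_mask <- function(layout, genotype = NA_character_) {
  counts <- table(factor(layout$probe_set_id, levels = unique(layout$probe_set_id)))
  structure(
    list(
      genotype = genotype, threshold = 0, min_pairs_per_set = 1,
      retained_pairs = layout$probe_id,
      retained_sets = names(counts),
      set_pair_counts = stats::setNames(as.integer(counts), names(counts)),
      layout_signature = layout_signature(layout)
    ),
    class = "probe_mask"
  )
}
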