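#' @keywords internal
"_PACKAGE"

#' Treatment levels of the dehydration-stress design
#'
#' The three watering regimes of the experimental design: continuously
#' irrigated controls, a water-limited (dehydration) treatment, and a
#' recovery treatment in which irrigation is resumed after the stress.
#'
#' @return Character vector of the valid `treatment` values, in design order.
#' @export
treatments <- function() {
  c("water_sufficient", "water_limited", "recovery")
}

#' Construct and validate a chip layout
#'
#' A chip layout maps perfect-match (PM) probe pairs to probe sets, the
#' grouping summarized into one expression value per gene. Only PM probes
#' are modelled; mismatch probes play no role in the analysis.
#'
#' @param probe_id Character vector; unique probe-pair identifiers.
#' @param probe_set_id Character vector; the probe set each pair belongs to.
#' @param pair_index Integer vector; 0-based index of the pair within its
#'   probe set. Within each set the indices must be `0..k-1` with no gaps.
#' @return A `data.frame` of class `chip_layout` with the three columns.
#' @examples
#' chip_layout(c("a", "b"), c("S1", "S1"), c(0, 1))
#' @export
chip_layout <- function(probe_id, probe_set_id, pair_index) {
  layout <- data.frame(
    probe_id = as.character(probe_id),
    probe_set_id = as.character(probe_set_id),
    pair_index = as.integer(pair_index),
    stringsAsFactors = FALSE
  )
  validate_chip_layout(layout)
}

validate_chip_layout <- function(layout) {
  required <- c("probe_id", "probe_set_id", "pair_index")
  if (!all(required %in% names(layout))) {
    stop("layout must have columns: ", paste(required, collapse = ", "))
  }
  dup <- layout$probe_id[duplicated(layout$probe_id)]
  if (length(dup) > 0) {
    stop("duplicate probe_id in layout: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(layout$pair_index) || any(layout$pair_index < 0)) {
    stop("pair_index must be a non-negative integer")
  }
  by_set <- split(layout$pair_index, layout$probe_set_id)
  for (set in names(by_set)) {
    idx <- sort(by_set[[set]])
    if (!identical(idx, seq_along(idx) - 1L)) {
      stop("probe set '", set, "' has pair_index values with gaps or duplicates")
    }
  }
  class(layout) <- c("chip_layout", "data.frame")
  layout
}

#' Construct and validate a sample sheet
#'
#' Describes the hybridisations of the experiment: genotype, watering
#' treatment and biological replicate for each array. The `excluded` flag
#' supports setting aside suspected outlier arrays without deleting data.
#'
#' @param sample_id Character; unique hybridisation/sample identifiers.
#' @param genotype Character; genotype of each sample.
#' @param treatment Character; one of [treatments()].
#' @param replicate Integer >= 1; biological replicate number.
#' @param excluded Logical; whether the sample is excluded from analysis.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, genotype, treatment, replicate,
                         excluded = FALSE) {
  sheet <- data.frame(
    sample_id = as.character(sample_id),
    genotype = as.character(genotype),
    treatment = as.character(treatment),
    replicate = as.integer(replicate),
    excluded = as.logical(excluded),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "genotype", "treatment", "replicate", "excluded")
  if (!all(required %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(required, collapse = ", "))
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(sheet$treatment), treatments())
  if (length(bad) > 0) {
    stop("unknown treatment value(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(sheet$replicate) || any(sheet$replicate < 1)) {
    stop("replicate must be an integer >= 1")
  }
  if (anyNA(sheet$excluded)) {
    stop("excluded must be TRUE or FALSE")
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Active (non-excluded) samples of a sheet
#'
#' @param sheet A [sample_sheet()].
#' @param genotype Optional genotype to restrict to.
#' @param treatment Optional treatment to restrict to.
#' @return The rows of `sheet` that are not excluded (and match the filters).
#' @export
active_samples <- function(sheet, genotype = NULL, treatment = NULL) {
  keep <- !sheet$excluded
  if (!is.null(genotype)) keep <- keep & sheet$genotype %in% genotype
  if (!is.null(treatment)) keep <- keep & sheet$treatment %in% treatment
  sheet[keep, , drop = FALSE]
}

# ---- intensity / expression matrices ---------------------------------------

validate_intensity_matrix <- function(m, what = "intensity") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " matrix must be a numeric matrix")
  }
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "%s matrix has a non-positive or non-finite value at row '%s', column '%s'",
      what, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  m
}

# ---- TSV readers / writers -------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Format doubles so that read.delim recovers them bit-exactly.
format_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

write_tsv_stable <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], format_num)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read / write a chip layout TSV
#'
#' The on-disk format is a tab-delimited file with header
#' `probe_id, probe_set_id, pair_index`. The writer emits rows sorted by
#' probe set and pair index so output is byte-stable for a given layout.
#'
#' @param path File path.
#' @return `read_layout` returns a [chip_layout()]; `write_layout` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  df <- read_tsv_checked(path)
  chip_layout(df$probe_id, df$probe_set_id, df$pair_index)
}

#' @rdname read_layout
#' @param layout A [chip_layout()].
#' @export
write_layout <- function(layout, path) {
  layout <- validate_chip_layout(layout)
  ord <- order(layout$probe_set_id, layout$pair_index)
  write_tsv_stable(as.data.frame(layout)[ord, , drop = FALSE], path)
}

#' Read / write a sample sheet TSV
#'
#' Tab-delimited with header
#' `sample_id, genotype, treatment, replicate, excluded`.
#'
#' @param path File path.
#' @return `read_sample_sheet` returns a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path)
  sample_sheet(df$sample_id, df$genotype, df$treatment, df$replicate,
               as.logical(df$excluded))
}

#' @rdname read_sample_sheet
#' @param sheet A [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  ord <- order(sheet$sample_id)
  write_tsv_stable(as.data.frame(sheet)[ord, , drop = FALSE], path)
}

#' Read / write a probe-level intensity matrix TSV
#'
#' Tab-delimited with a `probe_id` column followed by one numeric column per
#' hybridisation; values are linear-scale intensities and must be strictly
#' positive. All probe ids must be present in `layout`; row order of the
#' file is preserved.
#'
#' @param path File path.
#' @param layout A [chip_layout()] the probes must belong to.
#' @return `read_intensities` returns a numeric matrix with probe-pair
#'   rownames and hybridisation colnames.
#' @export
read_intensities <- function(path, layout) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "probe_id") {
    stop("intensity TSV must start with a 'probe_id' column")
  }
  ids <- as.character(df$probe_id)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate probe_id in intensity file: ", paste(dup, collapse = ", "))
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      stop("non-numeric value in intensity column '", names(body)[j], "'")
    }
  }
  m <- as.matrix(body)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  unknown <- setdiff(ids, layout$probe_id)
  if (length(unknown) > 0) {
    stop("probe id(s) absent from layout: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  validate_intensity_matrix(m)
}

#' @rdname read_intensities
#' @param m Numeric intensity matrix (probes x hybridisations).
#' @export
write_intensities <- function(m, path) {
  validate_intensity_matrix(m)
  df <- data.frame(probe_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(df, path)
}

#' Read / write a summarized expression matrix TSV
#'
#' Tab-delimited with a `probe_set_id` column followed by one numeric
#' (log2-scale) column per sample.
#'
#' @param path File path.
#' @return `read_expression` returns a numeric matrix with probe-set
#'   rownames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "probe_set_id") {
    stop("expression TSV must start with a 'probe_set_id' column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$probe_set_id)
  if (!is.numeric(m)) stop("expression matrix body must be numeric")
  m
}

#' @rdname read_expression
#' @param expr Numeric expression matrix (probe sets x samples).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_set_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(df, path)
}
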