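# End-to-end orchestration: synthetic generation (or user TSV inputs) ->
# masking -> masked RMA -> expressed calls -> differential expression ->
# responsive/perturbed classification -> co-expression networks -> report.
# One top-level seed streams to all stochastic stages so runs are
# replayable; every report table is written deterministically.

#' Pipeline run configuration
#'
#' Collects all stage parameters. When `gdna_path` (and friends) are `NULL`
#' the run simulates its inputs with the seeded generator; otherwise the
#' TSVs are read. The defaults mirror the emulated study design: two
#' genotypes, 3/4/3 replicates for water-sufficient/water-limited/recovery,
#' 11 probe pairs per set, 90% probe retention against the heterologous
#' array, mostly <4-fold planted changes, 9 common DEGs and a 75%
#' responsive fraction.
#'
#' @param seed Top-level integer seed.
#' @param outdir Output directory for report tables.
#' @param n_sets,pairs_per_set Synthetic layout size.
#' @param genotypes Genotype names.
#' @param bind_prob Per-genotype probe retention probability.
#' @param n_de_per_genotype,n_common_de,frac_responsive,log2fc_range
#'   Planted differential expression (see [simulate_truth()]).
#' @param n_modules,module_size,module_sd Planted co-expression modules.
#' @param noise_sd Probe-level log2 noise SD.
#' @param n_water_sufficient,n_water_limited,n_recovery Replicates.
#' @param mask_threshold gDNA intensity threshold for the working mask; the
#'   default 256 is the geometric midpoint of the synthetic signal (2^10)
#'   and background (2^6) scales.
#' @param min_pairs_per_set Minimum retained pairs per kept probe set.
#' @param sweep_taus Thresholds for the sweep table (default: 12 points,
#'   geometric, spanning background to above signal).
#' @param summarization A [summarization_config()].
#' @param smoothing_window,interior Expressed-call curve parameters.
#' @param expressed_cutoff Optional override cutoff for expressed calls.
#' @param q_max,fc_min,pooled,classify_rule Differential-expression
#'   parameters (see [call_degs()] and [classify_response()]).
#' @param network_threshold,network_mode Co-expression edge rule (see
#'   [build_network()]).
#' @param tf_fraction Fraction of DEG nodes annotated as transcription
#'   factors in the simulated annotation table.
#' @param layout_path,gdna_path,rna_path,sheet_path,annotation_path
#'   Optional input TSVs; all of the first four must be given to skip
#'   simulation.
#' @param exclude_samples Sample ids to mark excluded before analysis.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("csmarray_run_"),
                       n_sets = 2000, pairs_per_set = 11,
                       genotypes = c("DipC", "TN"), bind_prob = 0.9,
                       n_de_per_genotype = 100, n_common_de = 9,
                       frac_responsive = 0.75, log2fc_range = c(1, 2),
                       n_modules = 5, module_size = 10, module_sd = 1,
                       noise_sd = 0.25,
                       n_water_sufficient = 3, n_water_limited = 4,
                       n_recovery = 3,
                       mask_threshold = 256, min_pairs_per_set = 1,
                       sweep_taus = NULL,
                       summarization = summarization_config(),
                       smoothing_window = 51, interior = c(0.1, 0.9),
                       expressed_cutoff = NULL,
                       q_max = 0.05, fc_min = 2, pooled = FALSE,
                       classify_rule = "recovery_ns",
                       network_threshold = 0.9, network_mode = "absolute",
                       tf_fraction = 0.1,
                       layout_path = NULL, gdna_path = NULL,
                       rna_path = NULL, sheet_path = NULL,
                       annotation_path = NULL,
                       exclude_samples = character(0)) {
  if (is.null(sweep_taus)) {
    sweep_taus <- round(2^seq(5, 12.5, length.out = 12), 1)
  }
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# Simulated functional annotation for network nodes: a seeded fraction of
# the DEG sets is marked as transcription factors, the rest get roles drawn
# from the controlled vocabulary.
simulate_annotations <- function(deg_sets, tf_fraction, seed) {
  set.seed(seed)
  n <- length(deg_sets)
  is_tf <- rep(FALSE, n)
  if (n > 0) is_tf[sample(n, max(1, round(tf_fraction * n)))] <- TRUE
  roles <- sample(setdiff(role_categories(), "transcription"), n, replace = TRUE)
  roles[is_tf] <- "transcription"
  data.frame(
    probe_set_id = deg_sets, name = deg_sets, is_tf = is_tf,
    role_category = roles, stringsAsFactors = FALSE
  )
}

#' Run the full pipeline
#'
#' Executes every stage on simulated or user-supplied inputs and writes the
#' report bundle to `config$outdir`: the threshold sweep table, mask
#' comparison, expressed-call summary, per-contrast DEG counts and tables
#' with responsive/perturbed classes, the cross-genotype common-DEG table,
#' the transcription-factor degree table of the merged network, PCA variance
#' fractions, and a JSON manifest of the configuration and input checksums.
#' Any stage error aborts with the stage name. Outputs are byte-identical
#' across runs with the same configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate objects and report
#'   tables.
#' @export
run_all <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  simulate <- is.null(cfg$gdna_path)
  truth <- NULL
  gdna_sim <- NULL

  inputs <- stage("inputs", {
    if (simulate) {
      layout <- simulate_layout(cfg$n_sets, cfg$pairs_per_set)
      sheet <- simulate_sample_sheet(cfg$genotypes, cfg$n_water_sufficient,
                                     cfg$n_water_limited, cfg$n_recovery)
      truth <- simulate_truth(
        layout, cfg$genotypes, cfg$n_de_per_genotype, cfg$n_common_de,
        cfg$frac_responsive, cfg$log2fc_range, cfg$n_modules,
        cfg$module_size, seed = cfg$seed + 1L
      )
      gdna_sim <- simulate_gdna(layout, cfg$genotypes, cfg$bind_prob,
                                seed = cfg$seed + 2L)
      if (length(cfg$exclude_samples) > 0) {
        sheet$excluded[sheet$sample_id %in% cfg$exclude_samples] <- TRUE
      }
      rna <- simulate_rna(layout, truth, sheet, cfg$noise_sd, cfg$module_sd,
                          probes = gdna_sim$probes, seed = cfg$seed + 3L)
      list(layout = layout, sheet = sheet, rna = rna)
    } else {
      layout <- read_layout(cfg$layout_path)
      sheet <- read_sample_sheet(cfg$sheet_path)
      if (length(cfg$exclude_samples) > 0) {
        sheet$excluded[sheet$sample_id %in% cfg$exclude_samples] <- TRUE
      }
      rna <- read_intensities(cfg$rna_path, layout)
      list(layout = layout, sheet = sheet, rna = rna)
    }
  })
  layout <- inputs$layout
  sheet <- inputs$sheet

  masks <- stage("masking", {
    gdna <- if (simulate) {
      gdna_sim$intensities
    } else {
      read_intensities(cfg$gdna_path, layout)
    }
    sweep <- sweep_thresholds(gdna, layout, cfg$sweep_taus,
                              cfg$min_pairs_per_set)
    per_genotype <- lapply(cfg$genotypes, function(g) {
      select_probe_pairs(gdna[, g], layout, cfg$mask_threshold,
                         cfg$min_pairs_per_set, g)
    })
    names(per_genotype) <- cfg$genotypes
    comparison <- compare_masks(per_genotype[[1]], per_genotype[[2]])
    list(sweep = sweep, masks = per_genotype, comparison = comparison)
  })

  expr <- stage("summarization", {
    out <- lapply(cfg$genotypes, function(g) {
      samples <- active_samples(sheet, g)$sample_id
      rma_summarize(inputs$rna[, samples, drop = FALSE],
                    masks$masks[[g]], layout, cfg$summarization)
    })
    names(out) <- cfg$genotypes
    out
  })

  expressed <- stage("expressed_calls", {
    out <- lapply(cfg$genotypes, function(g) {
      ws <- active_samples(sheet, g, "water_sufficient")$sample_id
      call_expressed(expr[[g]], ws, cfg$expressed_cutoff,
                     cfg$smoothing_window, cfg$interior)
    })
    names(out) <- cfg$genotypes
    out
  })

  de <- stage("differential", {
    contrast_pairs <- list(
      stress = c("water_limited", "water_sufficient"),
      recovery = c("recovery", "water_sufficient"),
      stress_vs_recovery = c("water_limited", "recovery")
    )
    per_genotype <- lapply(cfg$genotypes, function(g) {
      degs <- lapply(contrast_pairs, function(tp) {
        call_degs(expr[[g]], sheet, g, tp, cfg$q_max, cfg$fc_min, cfg$pooled)
      })
      classifier <- if (cfg$classify_rule == "recovery_ns") {
        attr(degs$recovery, "contrast_result")
      } else {
        attr(degs$stress_vs_recovery, "contrast_result")
      }
      degs$stress <- classify_response(degs$stress, classifier,
                                       cfg$q_max, cfg$fc_min,
                                       cfg$classify_rule)
      degs
    })
    names(per_genotype) <- cfg$genotypes
    overlap <- overlap_degs(per_genotype[[1]]$stress,
                            per_genotype[[2]]$stress)
    list(degs = per_genotype, overlap = overlap)
  })

  net <- stage("network", {
    annotations <- if (simulate || is.null(cfg$annotation_path)) {
      all_deg <- sort(unique(unlist(lapply(de$degs, function(d) {
        unlist(lapply(d, function(t) t$probe_set_id))
      }))))
      simulate_annotations(all_deg, cfg$tf_fraction, cfg$seed + 4L)
    } else {
      read_tsv_checked(cfg$annotation_path)
    }
    per_genotype <- lapply(cfg$genotypes, function(g) {
      whole_nodes <- sort(unique(unlist(
        lapply(de$degs[[g]], function(t) t$probe_set_id)
      )))
      drought_nodes <- de$degs[[g]]$stress$probe_set_id
      samples <- active_samples(sheet, g)$sample_id
      ann <- annotations[annotations$probe_set_id %in% whole_nodes, ,
                         drop = FALSE]
      ann$genotype_origin <- g
      dir_map <- stats::setNames(de$degs[[g]]$stress$direction,
                                 de$degs[[g]]$stress$probe_set_id)
      ann$direction <- unname(dir_map[ann$probe_set_id])
      whole_nodes <- intersect(whole_nodes, rownames(expr[[g]]))
      rho <- spearman_matrix(expr[[g]], whole_nodes, samples)
      whole <- build_network(rho, cfg$network_threshold, cfg$network_mode,
                             ann)
      drought_nodes <- intersect(drought_nodes, whole_nodes)
      drought <- igraph::induced_subgraph(whole, drought_nodes)
      list(whole = whole, drought = drought, drought_nodes = drought_nodes)
    })
    names(per_genotype) <- cfg$genotypes
    merged <- merge_networks(per_genotype[[1]]$drought,
                             per_genotype[[2]]$drought,
                             cfg$genotypes[1], cfg$genotypes[2])
    degrees <- lapply(cfg$genotypes, function(g) {
      degree_table(per_genotype[[g]]$whole, per_genotype[[g]]$drought_nodes)
    })
    names(degrees) <- cfg$genotypes
    list(per_genotype = per_genotype, merged = merged,
         degrees = degrees,
         merged_degrees = degree_table(merged, igraph::V(merged)$name))
  })

  pca <- stage("pca", {
    common <- intersect(rownames(expr[[1]]), rownames(expr[[2]]))
    combined <- cbind(expr[[1]][common, , drop = FALSE],
                      expr[[2]][common, , drop = FALSE])
    pca_variance(combined)
  })

  report <- stage("report", {
    write_report(cfg, inputs, masks, expressed, de, net, pca, truth)
  })

  invisible(list(
    config = cfg, layout = layout, sheet = sheet, truth = truth,
    gdna = gdna_sim, rna = inputs$rna, masks = masks, expression = expr,
    expressed = expressed, de = de, network = net, pca = pca,
    report = report
  ))
}

write_report <- function(cfg, inputs, masks, expressed, de, net, pca, truth) {
  out <- cfg$outdir
  path <- function(f) file.path(out, f)

  write_tsv_stable(masks$sweep, path("sweep_table.tsv"))
  write_tsv_stable(data.frame(
    n_common_sets = masks$comparison$n_common_sets,
    n_specific_a = masks$comparison$n_specific_a,
    n_specific_b = masks$comparison$n_specific_b
  ), path("mask_comparison.tsv"))

  expressed_summary <- do.call(rbind, lapply(cfg$genotypes, function(g) {
    e <- expressed[[g]]
    data.frame(
      genotype = g, cutoff_relative_value = e$cutoff_relative_value,
      cutoff_rank_fraction = e$cutoff_rank_fraction,
      n_expressed = length(e$expressed_sets), stringsAsFactors = FALSE
    )
  }))
  expressed_summary$n_common <- length(
    Reduce(intersect, lapply(expressed, function(e) e$expressed_sets))
  )
  write_tsv_stable(expressed_summary, path("expressed_summary.tsv"))

  deg_counts <- do.call(rbind, lapply(cfg$genotypes, function(g) {
    do.call(rbind, lapply(names(de$degs[[g]]), function(cn) {
      t <- de$degs[[g]][[cn]]
      data.frame(
        genotype = g, contrast = cn,
        n_up = sum(t$direction == "up"),
        n_down = sum(t$direction == "down"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  write_tsv_stable(deg_counts, path("deg_counts.tsv"))

  for (g in cfg$genotypes) {
    t <- de$degs[[g]]$stress
    t <- t[order(t$probe_set_id), , drop = FALSE]
    write_tsv_stable(as.data.frame(t), path(sprintf("degs_stress_%s.tsv", g)))
  }

  ov <- de$overlap
  common_df <- data.frame(
    probe_set_id = c(ov$common_up, ov$common_down),
    direction = c(rep("up", length(ov$common_up)),
                  rep("down", length(ov$common_down))),
    stringsAsFactors = FALSE
  )
  common_df <- common_df[order(common_df$probe_set_id), , drop = FALSE]
  write_tsv_stable(common_df, path("common_degs.tsv"))

  response_summary <- do.call(rbind, lapply(cfg$genotypes, function(g) {
    cls <- de$degs[[g]]$stress$response_class
    data.frame(
      genotype = g, n_stress_degs = length(cls),
      n_responsive = sum(cls == "responsive"),
      n_perturbed = sum(cls == "perturbed"),
      frac_responsive = if (length(cls) > 0) {
        sum(cls == "responsive") / length(cls)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  write_tsv_stable(response_summary, path("response_summary.tsv"))

  write_tsv_stable(net$merged_degrees, path("degree_table.tsv"))
  export_network(net$merged, path("merged_network.sif"), "sif")
  export_network(net$merged, path("merged_network.graphml"), "graphml")

  write_tsv_stable(data.frame(
    component = seq_along(pca$variance_fraction),
    variance_fraction = pca$variance_fraction
  ), path("pca_variance.tsv"))

  manifest <- list(
    package = "csmarray",
    config = cfg[setdiff(names(cfg), "summarization")],
    summarization = unclass(cfg$summarization),
    input_checksums = {
      paths <- as.character(unlist(cfg[c("layout_path", "gdna_path",
                                         "rna_path", "sheet_path",
                                         "annotation_path")]))
      paths <- paths[file.exists(paths)]
      if (length(paths) > 0) as.list(tools::md5sum(paths)) else list()
    }
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  list(
    sweep = masks$sweep, expressed_summary = expressed_summary,
    deg_counts = deg_counts, common_degs = common_df,
    response_summary = response_summary, degree_table = net$merged_degrees,
    files = list.files(out)
  )
}
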