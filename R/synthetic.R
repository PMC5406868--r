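# Synthetic data generator emulating a two-genotype cross-species
# hybridisation study: near-identical genomes, divergence-driven probe
# dropout against a heterologous array, planted differential expression
# with responsive/perturbed recovery behaviour, and co-expressed modules.

#' Simulate a chip layout
#'
#' Builds a layout with `n_sets` probe sets of `pairs_per_set` PM probe
#' pairs each, mirroring the 11-pairs-per-set structure of expression
#' GeneChips. Identifiers are deterministic.
#'
#' @param n_sets Number of probe sets (>= 1).
#' @param pairs_per_set Probe pairs per set (default 11).
#' @param seed Unused (ids are deterministic); kept for interface symmetry.
#' @return A [chip_layout()].
#' @examples
#' simulate_layout(3, 2)
#' @export
simulate_layout <- function(n_sets, pairs_per_set = 11, seed = 1) {
  if (n_sets < 1 || pairs_per_set < 1) {
    stop("n_sets and pairs_per_set must be >= 1")
  }
  sets <- sprintf("PS%06d", seq_len(n_sets))
  probe_set_id <- rep(sets, each = pairs_per_set)
  pair_index <- rep.int(seq_len(pairs_per_set) - 1L, n_sets)
  probe_id <- sprintf("%s_%02d", probe_set_id, pair_index)
  chip_layout(probe_id, probe_set_id, pair_index)
}

#' Simulate a sample sheet for the dehydration design
#'
#' Default replication mirrors the study design: three water-sufficient,
#' four water-limited and three recovery replicates per genotype. Sample ids
#' follow the `<treatment>.<genotype>.Rep<k>` convention with treatment codes
#' IR (irrigated/water-sufficient), D (dehydration/water-limited) and REC
#' (recovery).
#'
#' @param genotypes Character vector of genotype names.
#' @param n_water_sufficient,n_water_limited,n_recovery Replicates per
#'   treatment.
#' @return A [sample_sheet()].
#' @export
simulate_sample_sheet <- function(genotypes = c("DipC", "TN"),
                                  n_water_sufficient = 3,
                                  n_water_limited = 4,
                                  n_recovery = 3) {
  codes <- c(water_sufficient = "IR", water_limited = "D", recovery = "REC")
  reps <- c(water_sufficient = n_water_sufficient,
            water_limited = n_water_limited,
            recovery = n_recovery)
  rows <- do.call(rbind, lapply(genotypes, function(g) {
    do.call(rbind, lapply(treatments(), function(tr) {
      k <- reps[[tr]]
      if (k == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s.%s.Rep%d", codes[[tr]], g, seq_len(k)),
        genotype = rep(g, k), treatment = rep(tr, k),
        replicate = seq_len(k),
        excluded = rep(FALSE, k), stringsAsFactors = FALSE
      )
    }))
  }))
  sample_sheet(rows$sample_id, rows$genotype, rows$treatment,
               rows$replicate, rows$excluded)
}

#' Plant the ground truth of a simulated experiment
#'
#' Chooses which probe sets are differentially expressed in each genotype
#' (with exactly `n_common_de` shared between the two), assigns signed log2
#' fold changes, partitions each genotype's DE sets into dehydration
#' `responsive` (expression returns to the control level at recovery) versus
#' `perturbed` (the stress effect persists), and assigns co-expression
#' module membership.
#'
#' Common DE sets share their direction between genotypes; fold-change
#' magnitudes are drawn uniformly from `log2fc_range` (default 1-2, i.e.
#' 2- to 4-fold, matching a stress response of mostly small fold changes).
#'
#' @param layout A [chip_layout()].
#' @param genotypes Character vector (length 2 for a common-DE design).
#' @param n_de_per_genotype Number of DE probe sets per genotype.
#' @param n_common_de Number of DE sets shared by both genotypes.
#' @param frac_responsive Fraction of each genotype's DE sets in the
#'   responsive class (default 0.75).
#' @param log2fc_range Range of planted |log2 fold change|.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules; members share a per-sample latent factor (see
#'   [simulate_rna()]). Modules are drawn from the DE sets of alternating
#'   genotypes, overflowing into non-DE sets if needed.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression
#'   distribution of the probe sets.
#' @param seed Integer RNG seed; the truth is fully deterministic given it.
#' @return An object of class `sim_truth`: a list with elements `sets`
#'   (probe_set_id, baseline_log2, module_id), `de` (genotype, probe_set_id,
#'   direction, log2fc, response_class) and `params`.
#' @export
simulate_truth <- function(layout, genotypes = c("DipC", "TN"),
                           n_de_per_genotype = 100, n_common_de = 9,
                           frac_responsive = 0.75, log2fc_range = c(1, 2),
                           n_modules = 0, module_size = 10,
                           baseline_log2_mean = 10, baseline_log2_sd = 1,
                           seed = 1) {
  sets <- unique(layout$probe_set_id)
  n_sets <- length(sets)
  if (frac_responsive < 0 || frac_responsive > 1) {
    stop("frac_responsive must be in [0, 1]")
  }
  if (n_common_de > n_de_per_genotype || n_de_per_genotype > n_sets) {
    stop("infeasible DE counts: need n_common_de <= n_de_per_genotype <= n_sets")
  }
  n_distinct_de <- n_common_de +
    length(genotypes) * (n_de_per_genotype - n_common_de)
  if (n_distinct_de > n_sets) {
    stop("infeasible DE counts: distinct DE sets exceed the number of probe sets")
  }

  set.seed(seed)
  baseline <- stats::rnorm(n_sets, baseline_log2_mean, baseline_log2_sd)

  shuffled <- sample(sets)
  common <- shuffled[seq_len(n_common_de)]
  remaining <- shuffled[setdiff(seq_along(shuffled), seq_len(n_common_de))]
  n_specific <- n_de_per_genotype - n_common_de
  specific <- list()
  for (i in seq_along(genotypes)) {
    take <- seq_len(n_specific) + (i - 1L) * n_specific
    specific[[genotypes[i]]] <- if (n_specific > 0) remaining[take] else character(0)
  }

  common_sign <- sample(c(1, -1), n_common_de, replace = TRUE)
  de <- do.call(rbind, lapply(genotypes, function(g) {
    ids <- c(common, specific[[g]])
    sign <- c(common_sign, sample(c(1, -1), n_specific, replace = TRUE))
    mag <- stats::runif(length(ids), log2fc_range[1], log2fc_range[2])
    n_resp <- round(frac_responsive * length(ids))
    cls <- rep("perturbed", length(ids))
    cls[sample(seq_along(ids), n_resp)] <- "responsive"
    data.frame(
      genotype = rep(g, length(ids)), probe_set_id = ids,
      direction = ifelse(sign > 0, "up", "down"),
      log2fc = sign * mag, response_class = cls,
      stringsAsFactors = FALSE
    )
  }))

  module_id <- rep(NA_integer_, n_sets)
  names(module_id) <- sets
  if (n_modules > 0) {
    pools <- lapply(genotypes, function(g) c(specific[[g]], common))
    non_de <- setdiff(sets, unique(de$probe_set_id))
    used <- character(0)
    for (m in seq_len(n_modules)) {
      pool <- setdiff(pools[[(m - 1) %% length(pools) + 1]], used)
      if (length(pool) < module_size) {
        pool <- c(pool, setdiff(non_de, used))
      }
      if (length(pool) < module_size) {
        stop("infeasible module assignment: not enough unassigned probe sets")
      }
      members <- sample(pool, module_size)
      module_id[members] <- m
      used <- c(used, members)
    }
  }

  structure(
    list(
      sets = data.frame(
        probe_set_id = sets, baseline_log2 = baseline,
        module_id = unname(module_id), stringsAsFactors = FALSE
      ),
      de = de,
      params = list(
        genotypes = genotypes, n_de_per_genotype = n_de_per_genotype,
        n_common_de = n_common_de, frac_responsive = frac_responsive,
        log2fc_range = log2fc_range, n_modules = n_modules,
        module_size = module_size, seed = seed
      )
    ),
    class = "sim_truth"
  )
}

#' Simulate genomic-DNA hybridisations
#'
#' Models cross-species divergence as Bernoulli probe dropout: each probe
#' pair carries one shared uniform draw `u`, and binds the gDNA of genotype
#' `g` iff `u < bind_prob[g]`. With equal bind probabilities the two
#' genotypes therefore share an identical binding pattern (near-identical
#' genomes); lowering one probability drops probes from that genotype only.
#' Binding probes draw `affinity * 2^Normal(signal_log2_mean, signal_log2_sd)`;
#' non-binding probes draw lognormal background. Probe affinities are
#' multiplicative, shared across genotypes, and cancel in within-probe
#' contrasts (the motivation for median polish).
#'
#' @param layout A [chip_layout()].
#' @param genotypes Genotype names (one gDNA hybridisation column each).
#' @param bind_prob Per-genotype probability in (0, 1] that a probe pair
#'   hybridises; recycled to `length(genotypes)`.
#' @param affinity_log2_sd SD of log2 probe affinities.
#' @param signal_log2_mean,signal_log2_sd Lognormal signal parameters
#'   (log2 scale) for binding probes.
#' @param background_log2_mean,background_log2_sd Background parameters;
#'   `signal_log2_mean` must exceed `background_log2_mean`.
#' @param seed Integer RNG seed.
#' @return A list of class `gdna_sim` with `intensities` (probe x genotype
#'   matrix) and `probes` (data.frame: probe_id, genotype, affinity, binds).
#' @export
simulate_gdna <- function(layout, genotypes = c("DipC", "TN"),
                          bind_prob = 0.9, affinity_log2_sd = 0.5,
                          signal_log2_mean = 10, signal_log2_sd = 1,
                          background_log2_mean = 6, background_log2_sd = 1,
                          seed = 1) {
  bind_prob <- rep_len(bind_prob, length(genotypes))
  if (any(bind_prob <= 0 | bind_prob > 1)) {
    stop("bind_prob must be in (0, 1]")
  }
  if (signal_log2_mean <= background_log2_mean) {
    stop("signal_log2_mean must exceed background_log2_mean")
  }
  n <- nrow(layout)
  set.seed(seed)
  u <- stats::runif(n)                      # shared divergence stream
  affinity <- 2^stats::rnorm(n, 0, affinity_log2_sd)

  intensities <- matrix(NA_real_, n, length(genotypes),
                        dimnames = list(layout$probe_id, genotypes))
  probes <- vector("list", length(genotypes))
  for (i in seq_along(genotypes)) {
    binds <- u < bind_prob[i]
    signal <- affinity * 2^stats::rnorm(n, signal_log2_mean, signal_log2_sd)
    background <- 2^stats::rnorm(n, background_log2_mean, background_log2_sd)
    intensities[, i] <- ifelse(binds, signal, background)
    probes[[i]] <- data.frame(
      probe_id = layout$probe_id, genotype = genotypes[i],
      affinity = affinity, binds = binds, stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      intensities = validate_intensity_matrix(intensities, "gDNA"),
      probes = do.call(rbind, probes),
      params = list(
        bind_prob = stats::setNames(bind_prob, genotypes),
        signal_log2_mean = signal_log2_mean,
        signal_log2_sd = signal_log2_sd,
        background_log2_mean = background_log2_mean,
        background_log2_sd = background_log2_sd,
        affinity_log2_sd = affinity_log2_sd, seed = seed
      )
    ),
    class = "gdna_sim"
  )
}

#' Simulate RNA hybridisations
#'
#' For a binding probe pair `j` of probe set `g` in sample `s`, intensity is
#' `affinity_j * 2^(baseline_g + effect_g(genotype, treatment) + module_g(s)
#' + eps)` with `eps ~ Normal(0, noise_sd)` on the log2 scale; non-binding
#' probes draw lognormal background. The planted effect is the signed log2
#' fold change under the water-limited treatment; at recovery it is zero for
#' `responsive` sets and retained in full for `perturbed` sets. Module
#' members additionally share a per-sample latent factor
#' `Normal(0, module_sd)` which makes their profiles co-vary.
#'
#' @param layout A [chip_layout()].
#' @param truth A [simulate_truth()] object.
#' @param sheet A [sample_sheet()]; genotypes must be among the truth's.
#' @param noise_sd Probe-level log2 noise SD (0 gives the exact planted
#'   values for fully binding probes).
#' @param module_sd SD of the shared per-sample module latent factor.
#' @param probes Optional `probes` data.frame from [simulate_gdna()] giving
#'   per-genotype affinities and binding flags; if `NULL`, all probes bind
#'   with unit affinity.
#' @param background_log2_mean,background_log2_sd Background distribution
#'   for non-binding probes.
#' @param seed Integer RNG seed.
#' @return Probe x sample intensity matrix (non-excluded samples only).
#' @export
simulate_rna <- function(layout, truth, sheet, noise_sd = 0.25,
                         module_sd = 1, probes = NULL,
                         background_log2_mean = 6, background_log2_sd = 1,
                         seed = 1) {
  samples <- active_samples(sheet)
  unknown <- setdiff(unique(samples$genotype), truth$params$genotypes)
  if (length(unknown) > 0) {
    stop("sample sheet genotype(s) not in truth: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(layout)
  set_of_probe <- layout$probe_set_id
  sets <- truth$sets$probe_set_id
  baseline <- stats::setNames(truth$sets$baseline_log2, sets)
  module_of <- stats::setNames(truth$sets$module_id, sets)
  modules <- sort(unique(module_of[!is.na(module_of)]))

  set.seed(seed)
  latent <- NULL
  if (length(modules) > 0) {
    latent <- matrix(stats::rnorm(length(modules) * nrow(samples), 0, module_sd),
                     length(modules), nrow(samples),
                     dimnames = list(as.character(modules), samples$sample_id))
  }

  # per-(genotype, set) signed effect under stress
  de_key <- paste(truth$de$genotype, truth$de$probe_set_id)
  effect_wl <- stats::setNames(truth$de$log2fc, de_key)
  perturbed <- stats::setNames(truth$de$response_class == "perturbed", de_key)

  out <- matrix(NA_real_, n, nrow(samples),
                dimnames = list(layout$probe_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    g <- samples$genotype[s]
    tr <- samples$treatment[s]
    eff <- stats::setNames(rep(0, length(sets)), sets)
    key <- paste(g, sets)
    hit <- key %in% de_key
    if (tr == "water_limited") {
      eff[hit] <- effect_wl[key[hit]]
    } else if (tr == "recovery") {
      keep <- hit & perturbed[key]
      keep[is.na(keep)] <- FALSE
      eff[keep] <- effect_wl[key[keep]]
    }
    mu <- baseline + eff
    if (!is.null(latent)) {
      has_mod <- !is.na(module_of)
      mu[has_mod] <- mu[has_mod] +
        latent[as.character(module_of[has_mod]), samples$sample_id[s]]
    }
    mu_probe <- mu[set_of_probe]
    eps <- stats::rnorm(n, 0, noise_sd)
    bg <- 2^stats::rnorm(n, background_log2_mean, background_log2_sd)
    if (is.null(probes)) {
      out[, s] <- 2^(mu_probe + eps)
    } else {
      pg <- probes[probes$genotype == g, , drop = FALSE]
      aff <- stats::setNames(pg$affinity, pg$probe_id)[layout$probe_id]
      binds <- stats::setNames(pg$binds, pg$probe_id)[layout$probe_id]
      out[, s] <- ifelse(binds, aff * 2^(mu_probe + eps), bg)
    }
  }
  validate_intensity_matrix(out, "RNA")
}

#' Write the simulation truth as TSV plus a JSON parameter manifest
#'
#' @param truth A [simulate_truth()] object.
#' @param path Output TSV path (`probe_set_id, genotype, de_status, log2fc,
#'   response_class, module_id`); the parameter manifest is written beside
#'   it with extension `.params.json`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  mod <- stats::setNames(truth$sets$module_id, truth$sets$probe_set_id)
  df <- data.frame(
    probe_set_id = truth$de$probe_set_id,
    genotype = truth$de$genotype,
    de_status = truth$de$direction,
    log2fc = truth$de$log2fc,
    response_class = truth$de$response_class,
    module_id = unname(mod[truth$de$probe_set_id]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$genotype, df$probe_set_id), , drop = FALSE]
  write_tsv_stable(df, path)
  jsonlite::write_json(truth$params, sub("\\.tsv$", "", path) |>
                         paste0(".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
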