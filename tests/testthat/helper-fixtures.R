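# Shared fixtures and independent oracles used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_layout <- function() {
  chip_layout(c("p1", "p2", "p3", "p4"),
              c("S1", "S1", "S2", "S2"),
              c(0, 1, 0, 1))
}

random_layout <- function(n_sets, max_pairs = 5) {
  pairs <- sample(max_pairs, n_sets, replace = TRUE)
  chip_layout(
    probe_id = sprintf("S%03d_p%d", rep(seq_len(n_sets), pairs),
                       unlist(lapply(pairs, seq_len))),
    probe_set_id = sprintf("S%03d", rep(seq_len(n_sets), pairs)),
    pair_index = unlist(lapply(pairs, function(k) seq_len(k) - 1L))
  )
}

# Brute-force mask oracle: direct filter + group-by, independent of
# select_probe_pairs internals.
bf_select <- function(gdna, layout, tau, min_pairs = 1) {
  keep_pairs <- character(0)
  keep_sets <- character(0)
  for (set in unique(layout$probe_set_id)) {
    probes <- layout$probe_id[layout$probe_set_id == set]
    kept <- probes[gdna[probes] > tau]
    keep_pairs <- c(keep_pairs, kept)
    if (length(kept) >= min_pairs) keep_sets <- c(keep_sets, set)
  }
  list(pairs = keep_pairs, sets = keep_sets)
}

# Step-up BH definition computed directly from the formula.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Textbook Welch t-test formulas.
bf_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Spearman via Pearson correlation of average ranks.
bf_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# Noise-free two-genotype dataset used by several files: full binding, no
# modules, optional noise.
noise_free_dataset <- function(n_sets = 200, n_de = 20, n_common = 4,
                               noise_sd = 0, log2fc_range = c(1, 2),
                               seed = 42) {
  layout <- simulate_layout(n_sets, 11)
  sheet <- simulate_sample_sheet()
  truth <- simulate_truth(layout, n_de_per_genotype = n_de,
                          n_common_de = n_common,
                          log2fc_range = log2fc_range,
                          n_modules = 0, seed = seed)
  rna <- simulate_rna(layout, truth, sheet, noise_sd = noise_sd,
                      seed = seed + 1)
  list(layout = layout, sheet = sheet, truth = truth, rna = rna)
}

# Summarize one genotype of a dataset without normalization (the noise-free
# identity conditions).
summarize_genotype <- function(d, genotype, normalize = FALSE) {
  samples <- active_samples(d$sheet, genotype)$sample_id
  rma_summarize(d$rna[, samples, drop = FALSE], full_mask(d$layout),
                d$layout,
                summarization_config(normalize = normalize))
}
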