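test_that("the t-test handles identical and degenerate groups", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)

  flat <- welch_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(flat$p, 0)
  expect_true(flat$degenerate)

  flat_same <- welch_t(c(2, 2), c(2, 2))
  expect_equal(flat_same$p, 1)
  expect_false(flat_same$degenerate)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch p-values match the textbook formula", {
  set.seed(41)
  for (i in 1:100) {
    x <- rnorm(4, sd = runif(1, 0.5, 2))
    y <- rnorm(3, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    mine <- welch_t(x, y)
    ref <- bf_welch(x, y)
    expect_equal(mine$t, ref$t, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)  # m = 1: q = p

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(100, 1))
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("noise-free DEG calling recovers the planted set exactly", {
  d <- noise_free_dataset(n_sets = 200, n_de = 20, n_common = 4)
  for (g in c("DipC", "TN")) {
    samples <- active_samples(d$sheet, g)$sample_id
    expr <- rma_summarize(d$rna[, samples], full_mask(d$layout), d$layout,
                          summarization_config(normalize = FALSE))
    degs <- call_degs(expr, d$sheet, g)
    planted <- d$truth$de[d$truth$de$genotype == g, ]
    expect_setequal(degs$probe_set_id, planted$probe_set_id)
    # directions match the planted sign
    m <- merge(degs, planted, by = "probe_set_id")
    expect_identical(m$direction.x, m$direction.y)
  }
})

test_that("the fold-change gate is strict even at tiny q", {
  # planted difference of 0.9 log2 units (fold 1.866) with minute noise:
  # highly significant but below the >2-fold gate
  set.seed(43)
  sheet <- simulate_sample_sheet("G")
  samples <- active_samples(sheet, "G")$sample_id
  expr <- matrix(10, 4, length(samples),
                 dimnames = list(sprintf("S%d", 1:4), samples))
  wl <- active_samples(sheet, "G", "water_limited")$sample_id
  expr["S1", wl] <- 10.9
  expr <- expr + matrix(rnorm(length(expr), 0, 1e-4), nrow(expr))
  cr <- run_contrast(expr, sheet, "G")
  expect_lt(cr$q[cr$probe_set_id == "S1"], 0.01)
  degs <- call_degs(expr, sheet, "G")
  expect_false("S1" %in% degs$probe_set_id)
})

test_that("insufficient replicates fail naming the group", {
  d <- noise_free_dataset(n_sets = 20, n_de = 2, n_common = 0)
  expr <- summarize_genotype(d, "DipC")
  sheet <- d$sheet
  ws <- sheet$treatment == "water_sufficient" & sheet$genotype == "DipC"
  sheet$excluded[ws][1:2] <- TRUE
  expect_error(call_degs(expr, sheet, "DipC"), "DipC/water_sufficient")
})

test_that("DEG overlap matches on probe set and direction", {
  t1 <- data.frame(probe_set_id = c("A", "B", "C"),
                   direction = c("up", "down", "up"))
  t2 <- data.frame(probe_set_id = c("A", "B", "D"),
                   direction = c("up", "up", "down"))
  ov <- overlap_degs(t1, t2)
  expect_identical(ov$common_up, "A")
  expect_length(ov$common_down, 0)   # B flips direction: not common
  expect_equal(ov$n_common, 1)
  expect_equal(ov$n_specific_a, 2)
  expect_equal(ov$n_specific_b, 2)

  expect_equal(overlap_degs(t1, t1)$n_common, 3)
  empty <- data.frame(probe_set_id = character(0), direction = character(0))
  expect_equal(overlap_degs(t1, empty)$n_common, 0)
})

test_that("noise-free classification reproduces the planted classes", {
  d <- noise_free_dataset(n_sets = 150, n_de = 16, n_common = 4)
  for (g in c("DipC", "TN")) {
    samples <- active_samples(d$sheet, g)$sample_id
    expr <- rma_summarize(d$rna[, samples], full_mask(d$layout), d$layout,
                          summarization_config(normalize = FALSE))
    degs <- call_degs(expr, d$sheet, g)
    rec <- run_contrast(expr, d$sheet, g,
                        c("recovery", "water_sufficient"))
    classified <- classify_response(degs, rec)
    planted <- d$truth$de[d$truth$de$genotype == g, ]
    m <- merge(classified, planted, by = "probe_set_id")
    expect_identical(m$response_class.x, m$response_class.y)
    # every stress DEG lands in exactly one class
    expect_true(all(classified$response_class %in%
                      c("responsive", "perturbed")))

    # the alternative rule reads significance of stress-vs-recovery as return
    svr <- run_contrast(expr, d$sheet, g, c("water_limited", "recovery"))
    alt <- classify_response(degs, svr, rule = "stress_vs_recovery")
    m2 <- merge(alt, planted, by = "probe_set_id")
    expect_identical(m2$response_class.x, m2$response_class.y)
  }
})

test_that("a probe set missing from the recovery contrast stays unclassified", {
  degs <- data.frame(probe_set_id = c("A", "B"), direction = "up",
                     response_class = "unclassified",
                     stringsAsFactors = FALSE)
  rec <- data.frame(probe_set_id = "A", q = 0.9, fold_change = 1.1,
                    stringsAsFactors = FALSE)
  out <- classify_response(degs, rec)
  expect_identical(out$response_class, c("responsive", "unclassified"))
})

test_that("PCA variance fractions behave and match an eigendecomposition", {
  # variance along one direction only
  one_dir <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  colnames(one_dir) <- paste0("s", 1:4)
  res <- pca_variance(one_dir)
  expect_equal(res$variance_fraction[1], 1)
  expect_equal(sum(res$variance_fraction), 1)

  set.seed(44)
  m <- matrix(rnorm(60, 10), 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  res2 <- pca_variance(m)
  expect_equal(sum(res2$variance_fraction), 1)
  x <- t(m - rowMeans(m))
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(res2$variance_fraction[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-8)

  # sample relabeling leaves the fractions unchanged
  perm <- m[, sample(6)]
  expect_equal(pca_variance(perm)$variance_fraction,
               res2$variance_fraction, tolerance = 1e-10)

  # constant matrix is flagged with zero fractions
  flat <- matrix(5, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z")))
  res3 <- pca_variance(flat)
  expect_true(res3$constant)
  expect_equal(res3$variance_fraction, rep(0, length(res3$variance_fraction)))
})

test_that("relative qPCR quantification follows the 2^-ddCt closed form", {
  ct <- data.frame(
    gene = rep(c("target", "ref"), each = 2),
    sample = rep(c("t1", "c1"), 2),
    condition = rep(c("treated", "calibrator"), 2),
    ct = c(20, 18, 15, 15)
  )
  res <- delta_delta_ct(ct, "ref", "calibrator")
  treated <- res[res$condition == "treated", ]
  expect_equal(treated$delta_delta_ct, 2)
  expect_equal(treated$fold_change, 0.25)

  # ddCt = 0 -> fold 1
  expect_equal(res$fold_change[res$condition == "calibrator"], 1)

  ct2 <- ct
  ct2$ct <- c(20, 22, 16, 16)
  res2 <- delta_delta_ct(ct2, "ref", "calibrator")
  expect_equal(res2$delta_delta_ct[res2$condition == "treated"], -2)
  expect_equal(res2$fold_change[res2$condition == "treated"], 4)

  expect_error(
    delta_delta_ct(ct[ct$sample != "c1" | ct$gene != "ref", ],
                   "ref", "calibrator"),
    "missing for sample"
  )
})
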