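test_that("Spearman correlation handles monotone, antitone and tied data", {
  expr <- rbind(
    x = c(1, 2, 3),
    y = c(3, 5, 9),
    z = c(9, 5, 3)
  )
  colnames(expr) <- paste0("s", 1:3)
  rho <- spearman_matrix(expr)
  expect_equal(rho["x", "y"], 1)
  expect_equal(rho["x", "z"], -1)
  expect_equal(diag(rho), c(x = 1, y = 1, z = 1))
  expect_equal(rho, t(rho))

  # tied data: average ranks, checked against the rank-formula oracle
  expr2 <- rbind(a = c(1, 2, 2, 3), b = c(1, 3, 3, 5), c = c(4, 1, 3, 2))
  colnames(expr2) <- paste0("s", 1:4)
  rho2 <- spearman_matrix(expr2)
  expect_equal(rho2["a", "b"], bf_spearman(expr2["a", ], expr2["b", ]))
  expect_equal(rho2["a", "c"], bf_spearman(expr2["a", ], expr2["c", ]))

  # constant rows give NA correlations, never edges
  expr3 <- rbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  colnames(expr3) <- paste0("s", 1:3)
  rho3 <- spearman_matrix(expr3)
  expect_true(is.na(rho3["a", "flat"]))
  expect_equal(diag(rho3), c(a = 1, flat = 1))
  net <- build_network(rho3, 0.9)
  expect_equal(igraph::ecount(net), 0)

  expect_error(spearman_matrix(expr[, 1:2]), ">= 3")
})

test_that("network construction applies the threshold and mode", {
  expr <- rbind(a = 1:4, b = c(2, 4, 6, 8), c = c(10, 20, 30, 40),
                d = c(8, 6, 4, 2))
  colnames(expr) <- paste0("s", 1:4)
  rho <- spearman_matrix(expr)

  # three co-monotone nodes form a triangle; d is anti-correlated
  tri <- build_network(rho[1:3, 1:3], 0.9)
  expect_equal(igraph::ecount(tri), 3)
  expect_equal(unname(igraph::degree(tri)), c(2, 2, 2))

  # absolute mode links anti-correlated pairs, positive mode does not
  abs_net <- build_network(rho, 0.9, "absolute")
  pos_net <- build_network(rho, 0.9, "positive")
  expect_equal(igraph::ecount(abs_net), 6)  # complete graph on 4 nodes
  expect_equal(igraph::ecount(pos_net), 3)
  e <- igraph::as_data_frame(abs_net, "edges")
  expect_setequal(unique(e$sign[e$from == "d" | e$to == "d"]), "negative")

  # no self edges, no duplicate edges
  expect_false(any(igraph::which_loop(abs_net)))
  expect_false(any(igraph::which_multiple(abs_net)))

  expect_error(build_network(rho, 0), "threshold")
})

test_that("raising the threshold never adds edges", {
  set.seed(51)
  expr <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(sprintf("n%02d", 1:20), sprintf("s%d", 1:8)))
  rho <- spearman_matrix(expr)
  thresholds <- c(0.3, 0.5, 0.7, 0.9, 1.0)
  counts <- sapply(thresholds, function(th) {
    igraph::ecount(build_network(rho, th))
  })
  expect_true(all(diff(counts) <= 0))
  # threshold 1.0 on continuous noise: (almost surely) empty
  expect_equal(counts[length(counts)], 0)
})

test_that("merging networks unions nodes and edges with provenance", {
  mk <- function(ids, edges, genotype, directions = NULL) {
    corr <- diag(length(ids))
    dimnames(corr) <- list(ids, ids)
    for (e in edges) corr[e[1], e[2]] <- corr[e[2], e[1]] <- 1
    ann <- data.frame(probe_set_id = ids, genotype_origin = genotype,
                      direction = directions %||% "up",
                      stringsAsFactors = FALSE)
    build_network(corr, 0.9, annotations = ann)
  }

  # disjoint networks: counts add
  a <- mk(c("A1", "A2"), list(c("A1", "A2")), "DipC")
  b <- mk(c("B1", "B2"), list(c("B1", "B2")), "TN")
  m <- merge_networks(a, b, "DipC", "TN")
  expect_equal(igraph::vcount(m), 4)
  expect_equal(igraph::ecount(m), 2)
  expect_setequal(igraph::V(m)$genotype_origin[igraph::V(m)$name == "A1"],
                  "DipC")

  # identical networks: merged equals either, origin both
  m2 <- merge_networks(a, a, "DipC", "DipC2")
  expect_equal(igraph::vcount(m2), 2)
  expect_equal(igraph::ecount(m2), 1)
  expect_true(all(igraph::V(m2)$genotype_origin == "both"))
  expect_true(all(igraph::E(m2)$origin == "both"))

  # one shared node: origin both for it only
  c_net <- mk(c("A1", "C1"), list(c("A1", "C1")), "TN")
  m3 <- merge_networks(a, c_net, "DipC", "TN")
  v <- igraph::as_data_frame(m3, "vertices")
  expect_equal(v$genotype_origin[v$name == "A1"], "both")
  expect_setequal(v$genotype_origin[v$name != "A1"], c("DipC", "TN"))

  # conflicting direction on a shared node is flagged, not dropped
  d_net <- mk(c("A1", "D1"), list(c("A1", "D1")), "TN", c("down", "up"))
  m4 <- merge_networks(a, d_net, "DipC", "TN")
  v4 <- igraph::as_data_frame(m4, "vertices")
  expect_true(v4$direction_conflict[v4$name == "A1"])
  expect_equal(v4$direction[v4$name == "A1"], "conflict")
})

test_that("degree tables match brute-force adjacency counting", {
  # path a - b - c
  corr <- diag(3)
  dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  corr["a", "b"] <- corr["b", "a"] <- 0.95
  corr["b", "c"] <- corr["c", "b"] <- 0.95
  net <- build_network(corr, 0.9)
  tab <- degree_table(net, c("a", "b", "c"), tf_only = FALSE)
  expect_equal(tab$degree_whole[match(c("a", "b", "c"), tab$probe_set_id)],
               c(1L, 2L, 1L))

  set.seed(52)
  for (i in 1:5) {
    n <- 60
    ids <- sprintf("n%03d", 1:n)
    adj <- matrix(runif(n * n) < 0.05, n, n, dimnames = list(ids, ids))
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    corr <- diag(n) * 0 # off-diagonal container
    dimnames(corr) <- list(ids, ids)
    corr[adj] <- 0.95
    corr <- pmax(corr, t(corr))
    diag(corr) <- 1
    net <- build_network(corr, 0.9)
    sub_nodes <- sample(ids, 20)
    tab <- degree_table(net, sub_nodes, tf_only = FALSE)

    # brute force: count incident edges in the symmetric adjacency
    sym <- adj | t(adj)
    bf_whole <- rowSums(sym)
    bf_sub <- rowSums(sym[, colnames(sym) %in% sub_nodes, drop = FALSE])
    idx <- match(tab$probe_set_id, ids)
    expect_equal(tab$degree_whole, unname(as.integer(bf_whole[idx])))
    in_sub <- tab$probe_set_id %in% sub_nodes
    expect_equal(tab$degree_drought[in_sub],
                 unname(as.integer(bf_sub[idx][in_sub])))
    expect_true(all(tab$degree_drought[!in_sub] == 0))
    expect_true(all(tab$degree_drought <= tab$degree_whole))

    # handshake lemma
    expect_equal(sum(tab$degree_whole), 2 * igraph::ecount(net))
    # sorted by whole degree
    expect_true(all(diff(tab$degree_whole) <= 0))
  }

  expect_error(degree_table(net, c("a", "zz")), "not in the network")
})

test_that("degree table respects transcription-factor annotations", {
  corr <- diag(3)
  dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  corr["a", "b"] <- corr["b", "a"] <- 0.95
  ann <- data.frame(probe_set_id = c("a", "b", "c"),
                    name = c("WRKY40", "PRR7", "other"),
                    is_tf = c(TRUE, TRUE, FALSE),
                    role_category = c("transcription", "transcription",
                                      "others"),
                    stringsAsFactors = FALSE)
  net <- build_network(corr, 0.9, annotations = ann)
  tab <- degree_table(net, c("a", "b"))
  expect_setequal(tab$probe_set_id, c("a", "b"))
  expect_setequal(tab$name, c("WRKY40", "PRR7"))
})

test_that("network export round-trips and SIF rows count edges", {
  corr <- matrix(0.95, 3, 3)
  diag(corr) <- 1
  dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ann <- data.frame(probe_set_id = c("a", "b", "c"),
                    genotype_origin = "DipC", direction = "up",
                    is_tf = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  net <- build_network(corr, 0.9, annotations = ann)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 3)  # triangle -> 3 rows

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  eb <- igraph::as_data_frame(back, "edges")
  en <- igraph::as_data_frame(net, "edges")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_equal(eb$rho[order(key(eb))], en$rho[order(key(en))])
  vb <- igraph::as_data_frame(back, "vertices")
  expect_true(all(c("name", "genotype_origin", "direction", "is_tf") %in%
                    names(vb)))

  # empty network still produces valid files
  empty <- build_network(diag(2) * 0 + diag(2) |>
                           `dimnames<-`(list(c("x", "y"), c("x", "y"))), 0.9)
  export_network(empty, sif, "sif")
  expect_length(readLines(sif), 0)
  export_network(empty, gml, "graphml")
  expect_equal(igraph::vcount(import_network(gml)), 2)
})
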