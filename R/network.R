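# Spearman co-expression networks over DEG probe sets: per-genotype network
# construction, merging with provenance annotations, transcription-factor
# degree ranking, and SIF/GraphML export for Cytoscape-style tools.

#' Controlled vocabulary of node role categories
#'
#' Functional roles used to annotate network nodes in relation to the
#' dehydration response.
#'
#' @return Character vector of role names.
#' @export
role_categories <- function() {
  c("transcription", "cell wall", "lignin synthesis", "photosynthesis",
    "transporters", "hormone signalling", "osmoprotection",
    "oxidative stress", "others")
}

#' Pairwise Spearman correlation of probe sets
#'
#' Average-rank Spearman correlation between every pair of the selected
#' probe sets across the given samples. Constant rows have undefined
#' correlation; their off-diagonal entries are `NA` and never become edges.
#' The diagonal is 1.
#'
#' @param expr Probe set x sample log2 expression matrix.
#' @param sets Probe sets (rows) to correlate; default all.
#' @param samples Samples (columns) to correlate across (>= 3), typically
#'   all samples of one genotype.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(expr, sets = rownames(expr),
                            samples = colnames(expr)) {
  if (length(samples) < 3) stop("Spearman correlation requires >= 3 samples")
  m <- expr[sets, samples, drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Build a co-expression network from a correlation matrix
#'
#' Links two probe sets when their Spearman correlation passes the
#' threshold: `|rho| >= threshold` in the default `absolute` mode (so that
#' anti-correlated stress-repressed/induced pairs connect), or
#' `rho >= threshold` in `positive` mode. Self-edges are never created and
#' `NA` correlations never become edges.
#'
#' @param corr Symmetric correlation matrix from [spearman_matrix()].
#' @param threshold Correlation threshold in (0, 1] (default 0.9).
#' @param mode `"absolute"` or `"positive"` (see above).
#' @param annotations Optional data.frame keyed by `probe_set_id` with any
#'   of `name`, `genotype_origin`, `direction`, `role_category`, `is_tf`;
#'   attached as node attributes.
#' @return An undirected [igraph::graph] whose vertices are the probe sets
#'   of `corr` (isolated nodes kept) and whose edges carry `rho` and `sign`.
#' @export
build_network <- function(corr, threshold = 0.9,
                          mode = c("absolute", "positive"),
                          annotations = NULL) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- rownames(corr)
  pass <- if (mode == "absolute") abs(corr) >= threshold else corr >= threshold
  pass[is.na(pass)] <- FALSE
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  hits <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[hits[, 1]], to = ids[hits[, 2]],
    rho = corr[hits],
    sign = ifelse(corr[hits] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  vertices <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    keep <- c("probe_set_id", "name", "genotype_origin", "direction",
              "role_category", "is_tf")
    ann <- annotations[, intersect(keep, names(annotations)), drop = FALSE]
    names(ann)[names(ann) == "name"] <- "gene_name"
    vertices <- merge(vertices, ann, by.x = "name", by.y = "probe_set_id",
                      all.x = TRUE, sort = FALSE)
    vertices <- vertices[match(ids, vertices$name), , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Merge two genotype networks
#'
#' Takes the union of nodes and edges. Shared nodes get
#' `genotype_origin = "both"`; a shared node whose `direction` annotations
#' disagree between the genotypes is kept and flagged with
#' `direction_conflict = TRUE` (its direction becomes `"conflict"`). Each
#' edge records its provenance (`origin`: the first network's label, the
#' second's, or `"both"`).
#'
#' @param net_a,net_b Networks from [build_network()].
#' @param label_a,label_b Provenance labels (default the networks'
#'   `genotype_origin` annotation, else "A"/"B").
#' @return Merged undirected igraph.
#' @export
merge_networks <- function(net_a, net_b, label_a = NULL, label_b = NULL) {
  v_a <- igraph::as_data_frame(net_a, what = "vertices")
  v_b <- igraph::as_data_frame(net_b, what = "vertices")
  e_a <- igraph::as_data_frame(net_a, what = "edges")
  e_b <- igraph::as_data_frame(net_b, what = "edges")
  pick_label <- function(v, fallback) {
    if (is.null(v$genotype_origin)) return(fallback)
    u <- unique(stats::na.omit(v$genotype_origin))
    if (length(u) == 1) u else fallback
  }
  if (is.null(label_a)) label_a <- pick_label(v_a, "A")
  if (is.null(label_b)) label_b <- pick_label(v_b, "B")

  all_cols <- union(names(v_a), names(v_b))
  pad <- function(v) {
    for (col in setdiff(all_cols, names(v))) v[[col]] <- NA
    v[, all_cols, drop = FALSE]
  }
  v_a <- pad(v_a); v_b <- pad(v_b)
  shared <- intersect(v_a$name, v_b$name)
  v_only_b <- v_b[!v_b$name %in% shared, , drop = FALSE]
  vertices <- rbind(v_a, v_only_b)
  vertices$genotype_origin <- ifelse(
    vertices$name %in% shared, "both",
    ifelse(vertices$name %in% v_a$name, label_a, label_b)
  )
  vertices$direction_conflict <- FALSE
  if (!is.null(v_a$direction) && length(shared) > 0) {
    da <- stats::setNames(v_a$direction, v_a$name)[shared]
    db <- stats::setNames(v_b$direction, v_b$name)[shared]
    conflict <- shared[!is.na(da) & !is.na(db) & da != db]
    vertices$direction_conflict[vertices$name %in% conflict] <- TRUE
    vertices$direction[vertices$name %in% conflict] <- "conflict"
  }

  edge_key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  k_a <- edge_key(e_a); k_b <- edge_key(e_b)
  e_a$origin <- ifelse(k_a %in% k_b, "both", label_a)
  e_b$origin <- label_b
  edges <- rbind(e_a, e_b[!k_b %in% k_a, , drop = FALSE])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Vertex-degree table of network hubs
#'
#' Ranks nodes (by default only transcription factors, when an `is_tf`
#' annotation is present) by their number of links in the whole network and
#' in the dehydration-specific subnetwork — the induced subgraph on the
#' water-limited-contrast DEGs.
#'
#' @param network An igraph from [build_network()] or [merge_networks()].
#' @param drought_subnetwork_nodes Nodes of the dehydration-specific
#'   subnetwork; must be a subset of the network's nodes. `NULL` for none
#'   (degree 0).
#' @param tf_only Restrict rows to nodes annotated `is_tf = TRUE` (ignored
#'   when the annotation is absent).
#' @return Data.frame `probe_set_id, name, degree_whole, degree_drought`,
#'   sorted by decreasing `degree_whole` (ties by id).
#' @export
degree_table <- function(network, drought_subnetwork_nodes = NULL,
                         tf_only = TRUE) {
  ids <- igraph::V(network)$name
  if (!is.null(drought_subnetwork_nodes)) {
    extra <- setdiff(drought_subnetwork_nodes, ids)
    if (length(extra) > 0) {
      stop("drought subnetwork node(s) not in the network: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  deg_whole <- igraph::degree(network)
  deg_drought <- stats::setNames(rep(0L, length(ids)), ids)
  if (!is.null(drought_subnetwork_nodes) && length(drought_subnetwork_nodes) > 0) {
    sub <- igraph::induced_subgraph(network, drought_subnetwork_nodes)
    deg_drought[igraph::V(sub)$name] <- igraph::degree(sub)
  }
  gene_name <- igraph::vertex_attr(network, "gene_name")
  if (is.null(gene_name)) gene_name <- ids
  out <- data.frame(
    probe_set_id = ids, name = gene_name,
    degree_whole = as.integer(deg_whole),
    degree_drought = as.integer(deg_drought),
    stringsAsFactors = FALSE
  )
  is_tf <- igraph::vertex_attr(network, "is_tf")
  if (tf_only && !is.null(is_tf)) {
    out <- out[!is.na(is_tf) & as.logical(is_tf), , drop = FALSE]
  }
  out <- out[order(-out$degree_whole, out$probe_set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export / import a co-expression network
#'
#' `format = "sif"` writes simple-interaction-format rows
#' `source co target` (no header; an empty network gives an empty file).
#' `format = "graphml"` writes GraphML with the correlation, sign and all
#' node annotations as attributes; [import_network()] reads it back to an
#' equivalent graph.
#'
#' @param network An igraph network.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    e <- igraph::as_data_frame(network, what = "edges")
    lines <- if (nrow(e) > 0) sprintf("%s\tco\t%s", e$from, e$to) else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
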