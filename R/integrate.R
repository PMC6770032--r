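#' Build the miRNA-mRNA anti-correlation integration network
#'
#' For every (candidate miRNA, annotated target gene) pair, computes the
#' Spearman correlation between the two expression profiles across the
#' shared samples of the requested scope (tumor samples by default, since
#' the candidate set is tumor-derived) and retains the pair as a network
#' edge iff the correlation is negative (`rho < rho_max`, strict) and
#' significant (`p < alpha`). No magnitude threshold is applied to the
#' integration correlations; `rho_max` exists for sensitivity analysis.
#' Sample columns of the two matrices are aligned by id, never by position.
#'
#' Candidates with no annotated target are reported (not fatal); an overall
#' empty edge set triggers a warning but returns a valid (empty) network.
#'
#' @param mirna,gene Expression matrices (features x samples).
#' @param candidates Character vector of candidate miRNA ids; must all be
#'   features of `mirna`.
#' @param targets Target table (`data.frame` with `mirna`, `gene`), already
#'   restricted to the gene universe via [read_targets()].
#' @param samples Sample metadata (`sample_id`, `tissue`, ...).
#' @param alpha Significance level for edge retention (default 0.05).
#' @param scope `"tumor"` (default) or `"all"`: which samples the
#'   expression-expression correlations are computed on.
#' @param rho_max Strict upper bound on edge correlations (default 0:
#'   negative correlations only).
#' @return Object of class `integration_network` with `edges` (data frame
#'   `mirna`, `gene`, `rho`, `p`, `n`), node vectors, per-miRNA target
#'   counts, and bookkeeping fields.
#' @export
build_integration_network <- function(mirna, gene, candidates, targets,
                                      samples, alpha = 0.05,
                                      scope = c("tumor", "all"),
                                      rho_max = 0) {
  scope <- match.arg(scope)
  if (!(alpha > 0 && alpha < 1))
    stop_usage("alpha must lie in (0, 1), got %g", alpha)
  missing <- setdiff(candidates, rownames(mirna))
  if (length(missing) > 0L)
    stop_usage("candidate miRNA(s) absent from the miRNA matrix: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  scope_ids <- if (scope == "tumor")
    samples$sample_id[samples$tissue == "tumor"] else samples$sample_id
  shared <- intersect(intersect(colnames(mirna), colnames(gene)), scope_ids)
  if (length(shared) < 3L)
    stop_data("need >= 3 shared %s samples between the matrices, found %d",
              scope, length(shared))

  tab <- targets[targets$mirna %in% candidates, , drop = FALSE]
  tab <- tab[tab$gene %in% rownames(gene), , drop = FALSE]
  no_targets <- setdiff(candidates, tab$mirna)
  if (length(no_targets) > 0L)
    message(sprintf("integration: %d candidate(s) with no annotated target: %s",
                    length(no_targets),
                    paste(utils::head(no_targets, 5), collapse = ", ")))

  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    x <- mirna[tab$mirna[i], shared]
    y <- gene[tab$gene[i], shared]
    if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) next
    st <- spearman_test(x, y)
    if (st$rho < rho_max && st$p_two_sided < alpha) {
      rows[[i]] <- data.frame(mirna = tab$mirna[i], gene = tab$gene[i],
                              rho = st$rho, p = st$p_two_sided, n = st$n,
                              ties = st$ties, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(edges))
    edges <- data.frame(mirna = character(0), gene = character(0),
                        rho = numeric(0), p = numeric(0), n = integer(0),
                        ties = logical(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  if (nrow(edges) == 0L)
    warning("integration produced an empty network (no negatively-correlated significant pair)")
  structure(list(
    edges = edges,
    mirna_nodes = unique(edges$mirna),
    gene_nodes = unique(edges$gene),
    per_mirna_targets = if (nrow(edges)) table(edges$mirna) else table(character(0)),
    alpha = alpha, scope = scope, rho_max = rho_max,
    n_samples = length(shared), n_pairs_tested = nrow(tab),
    candidates_without_targets = no_targets
  ), class = "integration_network")
}

#' @export
print.integration_network <- function(x, ...) {
  cat("miRNA-mRNA integration network\n")
  cat(sprintf("  %d miRNA node(s), %d gene node(s), %d edge(s) (of %d pairs tested, alpha = %g, scope = %s)\n",
              length(x$mirna_nodes), length(x$gene_nodes), nrow(x$edges),
              x$n_pairs_tested, x$alpha, x$scope))
  invisible(x)
}

# igraph representation: bipartite, node attribute `kind`, edge attributes
# rho, p and width = |rho| (the more negative the correlation, the thicker
# the rendered link).
network_to_igraph <- function(net) {
  vertices <- data.frame(
    name = c(net$mirna_nodes, net$gene_nodes),
    kind = rep(c("mirna", "gene"),
               c(length(net$mirna_nodes), length(net$gene_nodes))),
    stringsAsFactors = FALSE
  )
  edges <- net$edges
  igraph::graph_from_data_frame(
    data.frame(from = edges$mirna, to = edges$gene,
               rho = edges$rho, p = edges$p, width = abs(edges$rho),
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = vertices)
}

#' Export an integration network
#'
#' Writes the network in a Cytoscape-ingestible format:
#' \describe{
#'   \item{`tsv`}{Edge-list table `mirna, gene, rho, p, n` (primary
#'     machine-readable output).}
#'   \item{`sif`}{`mirna  repressed-by-correlation  gene` interaction lines,
#'     plus a sidecar `*_edge_attributes.tsv` carrying rho and p.}
#'   \item{`graphml`}{GraphML with node attribute `kind` (mirna/gene) and
#'     edge attributes `rho`, `p` and `width = |rho|`.}
#' }
#'
#' @param net An `integration_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = "tsv") {
  supported <- c("tsv", "sif", "graphml")
  if (length(format) != 1L || !format %in% supported)
    stop_usage("unknown network format '%s'; supported formats: %s",
               paste(format, collapse = ","), paste(supported, collapse = ", "))
  if (format == "tsv") {
    utils::write.table(net$edges[, c("mirna", "gene", "rho", "p", "n")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(if (nrow(net$edges)) {
      paste(net$edges$mirna, "repressed-by-correlation", net$edges$gene,
            sep = "\t")
    } else character(0), path)
    attr_path <- paste0(tools::file_path_sans_ext(path),
                        "_edge_attributes.tsv")
    utils::write.table(net$edges[, c("mirna", "gene", "rho", "p")],
                       attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(network_to_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read back a GraphML network export
#'
#' Round-trip companion of [export_network()] (`format = "graphml"`):
#' returns the node table and the edge table with `rho` and `p` attributes.
#'
#' @param path GraphML file written by [export_network()].
#' @return List with `nodes` (`name`, `kind`) and `edges`
#'   (`mirna`, `gene`, `rho`, `p`).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name,
                      kind = if (igraph::gorder(g)) igraph::V(g)$kind else character(0),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(mirna = el[, 1], gene = el[, 2],
                      rho = if (igraph::gsize(g)) igraph::E(g)$rho else numeric(0),
                      p = if (igraph::gsize(g)) igraph::E(g)$p else numeric(0),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
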