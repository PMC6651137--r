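#' Induced igraph of a gene set
#'
#' @param net An `interactome`.
#' @param genes Genes on the network.
#' @return An undirected `igraph` graph on `genes` (isolated members kept).
#' @export
induced_graph <- function(net, genes) {
  stopifnot(inherits(net, "interactome"))
  genes <- sort(unique(as.character(genes)))
  if (anyNA(match(genes, net$nodes))) stop("genes not on the network")
  e <- net$edges
  keep <- e$from %in% genes & e$to %in% genes
  igraph::graph_from_data_frame(e[keep, c("from", "to")], directed = FALSE,
                                vertices = genes)
}

community_methods <- c(greedy = "greedy",
                       edge_betweenness = "edge_betweenness",
                       label_prop = "label_prop",
                       leading_eigen = "leading_eigen",
                       walktrap = "walktrap")

#' Detect topological communities with several method families
#'
#' Runs the requested community-detection families on a connected graph:
#' greedy modularity optimization, edge-betweenness removal, label propagation,
#' leading eigenvector, and short random walks (walktrap). Each partition is
#' scored with [newman_modularity()]. Stochastic methods (label propagation)
#' take the given seed.
#'
#' @param graph A connected undirected `igraph` graph.
#' @param methods Character vector among `"greedy"`, `"edge_betweenness"`,
#'   `"label_prop"`, `"leading_eigen"`, `"walktrap"`.
#' @param seed Integer seed for the stochastic methods.
#' @return A list of partitions, each of class `partition`: `membership`
#'   (named integer vector), `method`, `Q`.
#' @export
detect_communities <- function(graph, methods = names(community_methods),
                               seed = 1L) {
  stopifnot(igraph::is_igraph(graph))
  unknown <- setdiff(methods, names(community_methods))
  if (length(unknown) > 0L) {
    stop("unknown community method(s): ", paste(unknown, collapse = ", "))
  }
  lapply(methods, function(mth) {
    set.seed(as.integer(seed))
    comm <- switch(mth,
      greedy = igraph::cluster_fast_greedy(graph),
      edge_betweenness = suppressWarnings(
        igraph::cluster_edge_betweenness(graph)),
      label_prop = igraph::cluster_label_prop(graph),
      leading_eigen = suppressWarnings(igraph::cluster_leading_eigen(graph)),
      walktrap = igraph::cluster_walktrap(graph))
    membership <- stats::setNames(as.integer(igraph::membership(comm)),
                                  igraph::V(graph)$name)
    as_partition(membership, mth, graph)
  })
}

as_partition <- function(membership, method, graph) {
  structure(list(membership = membership, method = method,
                 Q = newman_modularity(graph, membership)),
            class = "partition")
}

#' @exportS3Method base::print
print.partition <- function(x, ...) {
  cat(sprintf("partition (%s): %d clusters over %d genes, Q = %.4f\n",
              x$method, length(unique(x$membership)), length(x$membership),
              x$Q))
  invisible(x)
}

#' Newman modularity of a partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j), computed in the
#' community form Q = sum_c (e_c/m - (d_c/2m)^2) where e_c is the number of
#' intra-community edges and d_c the total degree of community c. An edgeless
#' graph has Q = 0 by convention.
#'
#' @param graph An undirected `igraph` graph.
#' @param membership Named integer/character vector assigning every vertex of
#'   `graph` to a cluster.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
newman_modularity <- function(graph, membership) {
  stopifnot(igraph::is_igraph(graph))
  vn <- igraph::V(graph)$name
  if (!all(vn %in% names(membership))) {
    stop("membership must cover every vertex of the graph")
  }
  m <- igraph::ecount(graph)
  if (m == 0) return(0)
  memb <- membership[vn]
  ends <- igraph::as_edgelist(graph, names = TRUE)
  same <- memb[ends[, 1L]] == memb[ends[, 2L]]
  deg <- igraph::degree(graph)
  e_c <- tapply(rep(1L, m)[same], memb[ends[same, 1L]], sum)
  d_c <- tapply(deg, memb, sum)
  e_c_full <- stats::setNames(rep(0, length(d_c)), names(d_c))
  e_c_full[names(e_c)] <- e_c
  sum(e_c_full / m - (d_c / (2 * m))^2)
}

#' Pick the best partition by modularity
#'
#' Maximum-Q partition; ties broken first by the fewest clusters, then by the
#' order in which candidates were supplied.
#'
#' @param partitions Nonempty list of `partition` objects.
#' @return The selected `partition`.
#' @export
best_partition <- function(partitions) {
  stopifnot(length(partitions) >= 1L,
            all(vapply(partitions, inherits, logical(1), "partition")))
  Q <- vapply(partitions, `[[`, numeric(1), "Q")
  k <- vapply(partitions, function(p) length(unique(p$membership)), integer(1))
  partitions[[order(-Q, k, seq_along(partitions))[1L]]]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("empty GMT file: ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output file path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(length(gene_sets) > 0L, !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation per cluster
#'
#' For every (cluster, gene set) pair, tests the over-representation of the
#' set's genes in the cluster with the hypergeometric upper tail
#' (population = universe, successes = |set|, draws = |cluster|), then adjusts
#' the whole table with Benjamini--Hochberg to q-values.
#'
#' @param partition A `partition` over module genes.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Universe size, e.g. the interactome size; must be at least
#'   as large as any tested set or cluster.
#' @param restrict_sets If TRUE, gene sets are first intersected with the
#'   universe gene list given in `universe_genes`.
#' @param universe_genes Optional character vector of universe genes used both
#'   to restrict the sets and to define `universe` when it is missing.
#' @return Data frame: `cluster`, `set`, `cluster_size`, `set_size`, `overlap`,
#'   `p`, `q`.
#' @export
pathway_enrichment <- function(partition, gene_sets, universe = NULL,
                               restrict_sets = FALSE, universe_genes = NULL) {
  stopifnot(inherits(partition, "partition"))
  if (length(gene_sets) == 0L) stop("gene_sets must be a nonempty list")
  if (restrict_sets) {
    if (is.null(universe_genes)) stop("universe_genes required to restrict sets")
    gene_sets <- lapply(gene_sets, intersect, universe_genes)
  }
  if (is.null(universe)) {
    if (is.null(universe_genes)) stop("give universe or universe_genes")
    universe <- length(universe_genes)
  }
  clusters <- split(names(partition$membership), partition$membership)
  rows <- list()
  for (cl in names(clusters)) {
    for (nm in names(gene_sets)) {
      gs <- unique(gene_sets[[nm]])
      if (length(gs) > universe || length(clusters[[cl]]) > universe) {
        stop("universe smaller than a tested set or cluster")
      }
      ov <- length(intersect(clusters[[cl]], gs))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, set = nm,
        cluster_size = length(clusters[[cl]]), set_size = length(gs),
        overlap = ov,
        p = hypergeom_upper_tail(universe, length(gs),
                                 length(clusters[[cl]]), ov))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Evidence-type enrichment ratio of a cluster
#'
#' Ratio between the fraction of cluster genes supported by an evidence type
#' and the fraction of module genes supported by it; 1 means the cluster mirrors
#' the module-wide proportion.
#'
#' @param cluster Character vector of cluster genes (subset of `module`).
#' @param layer_support Genes supported by the evidence type (any tier).
#' @param module All module genes.
#' @return A scalar ratio; `NA` when the module has no supported gene.
#' @export
evidence_enrichment <- function(cluster, layer_support, module) {
  cluster <- unique(as.character(cluster))
  module <- unique(as.character(module))
  if (!all(cluster %in% module)) stop("cluster must be a subset of the module")
  if (length(cluster) == 0L) stop("cluster must be nonempty")
  mod_frac <- length(intersect(module, layer_support)) / length(module)
  if (mod_frac == 0) return(NA_real_)
  (length(intersect(cluster, layer_support)) / length(cluster)) / mod_frac
}
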