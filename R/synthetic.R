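#' Specification for a synthetic multi-omics benchmark
#'
#' Describes a sparse scale-free-like interactome with a planted connected
#' gene module whose induced subgraph is densified, plus three evidence layers
#' whose major/minor labels are enriched on the planted module and sprinkled
#' over the background at a low rate. Defaults are the benchmark conditions
#' used throughout the test suite: 1000 genes, a 50-gene planted module with a
#' 3x internal-edge multiplier, per-layer planted coverage of 0.6 (major) and
#' 0.2 (minor), and a 2% background evidence rate.
#'
#' @param n_genes Number of genes.
#' @param model `"preferential_attachment"` (Barabasi--Albert) or
#'   `"configuration"` (power-law degree sequence).
#' @param mean_degree Target mean degree of the graph.
#' @param planted_size Size of the planted connected module.
#' @param multiplier Internal-edge densification factor (>= 1) applied to the
#'   planted module's induced subgraph.
#' @param coverage_major,coverage_minor Per-layer probability that a planted
#'   gene is labeled major / minor.
#' @param background_rate Per-layer probability that a background gene carries
#'   any evidence label; a background evidence gene is major with probability
#'   `background_major_share`, minor otherwise.
#' @param background_major_share Major share among background evidence genes.
#' @param layer_names Names of the evidence layers.
#' @param seed Integer seed; required for the determinism contract.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           model = c("preferential_attachment", "configuration"),
                           mean_degree = 12,
                           planted_size = 50L,
                           multiplier = 3,
                           coverage_major = 0.6,
                           coverage_minor = 0.2,
                           background_rate = 0.02,
                           background_major_share = 0.3,
                           layer_names = c("G", "E", "T"),
                           seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_genes >= 10, planted_size < n_genes, multiplier >= 1,
            mean_degree > 0,
            coverage_major >= 0, coverage_minor >= 0,
            coverage_major + coverage_minor <= 1,
            background_rate >= 0, background_rate <= 1,
            background_major_share >= 0, background_major_share <= 1,
            length(layer_names) >= 1)
  structure(list(n_genes = as.integer(n_genes), model = model,
                 mean_degree = mean_degree,
                 planted_size = as.integer(planted_size),
                 multiplier = multiplier,
                 coverage_major = coverage_major,
                 coverage_minor = coverage_minor,
                 background_rate = background_rate,
                 background_major_share = background_major_share,
                 layer_names = layer_names,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic interactome with planted evidence layers
#'
#' Draws the graph from the requested model, selects a connected planted gene
#' set by snowball sampling, adds random internal edges until the planted
#' induced subgraph holds `multiplier` times its original edge count (capped at
#' the complete subgraph), and assigns tiered evidence labels layer by layer.
#' Identical specs (including the seed) yield byte-identical outputs.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_data`: `net` (an `interactome`),
#'   `layers` (list of `evidence_layer`), `truth` (planted members, internal
#'   edge counts before/after densification, the spec, per-layer label draws).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  g <- if (spec$model == "preferential_attachment") {
    igraph::sample_pa(n, m = max(1L, round(spec$mean_degree / 2)),
                      directed = FALSE)
  } else {
    # static power-law fitness model: configuration-style heavy-tailed degrees
    igraph::sample_fitness_pl(n, round(spec$mean_degree * n / 2),
                              exponent.out = 2.5)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = ids[pmin(el[, 1L], el[, 2L])],
                      to = ids[pmax(el[, 1L], el[, 2L])])
  planted_idx <- snowball_sample(g, spec$planted_size)
  planted <- sort(ids[planted_idx])
  # densify the planted induced subgraph
  inside <- edges$from %in% planted & edges$to %in% planted
  e0 <- sum(inside)
  target <- min(round(spec$multiplier * e0), choose(length(planted), 2))
  if (target > e0) {
    all_pairs <- t(utils::combn(planted, 2L))
    key <- paste(all_pairs[, 1L], all_pairs[, 2L])
    have <- paste(edges$from[inside], edges$to[inside])
    candidates <- which(!(key %in% have))
    add <- candidates[sample.int(length(candidates), target - e0)]
    edges <- rbind(edges, data.frame(from = all_pairs[add, 1L],
                                     to = all_pairs[add, 2L]))
  }
  edges$score <- sample(700:999, nrow(edges), replace = TRUE)
  net <- as_interactome(edges, min_score = 700)
  # any gene the graph model left isolated is dropped by as_interactome;
  # evidence is assigned on the realized node set
  nodes <- net$nodes
  planted <- intersect(planted, nodes)
  background <- setdiff(nodes, planted)
  layers <- lapply(spec$layer_names, function(nm) {
    u_p <- stats::runif(length(planted))
    major_p <- planted[u_p < spec$coverage_major]
    minor_p <- planted[u_p >= spec$coverage_major &
                       u_p < spec$coverage_major + spec$coverage_minor]
    u_b <- stats::runif(length(background))
    hit <- u_b < spec$background_rate
    major_b <- background[hit &
                          u_b < spec$background_rate * spec$background_major_share]
    minor_b <- background[hit & !(background %in% major_b)]
    evidence_layer(nm, major = c(major_p, major_b), minor = c(minor_p, minor_b))
  })
  names(layers) <- spec$layer_names
  structure(list(net = net, layers = layers,
                 truth = list(planted = planted,
                              internal_edges_initial = e0,
                              internal_edges_final = internal_edges(net, planted),
                              spec = spec)),
            class = "synthetic_data")
}

#' @exportS3Method base::print
print.synthetic_data <- function(x, ...) {
  cat(sprintf(
    "synthetic data: %d genes, %d edges, planted module of %d genes (%d internal edges)\n",
    length(x$net$nodes), nrow(x$net$edges), length(x$truth$planted),
    x$truth$internal_edges_final))
  invisible(x)
}

snowball_sample <- function(g, size, retries = 100L) {
  n <- igraph::vcount(g)
  if (size > n) stop("planted size exceeds the graph order")
  for (r in seq_len(retries)) {
    start <- sample.int(n, 1L)
    members <- start
    frontier <- as.integer(igraph::neighbors(g, start))
    while (length(members) < size && length(frontier) > 0L) {
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      frontier <- setdiff(unique(c(frontier,
                                   as.integer(igraph::neighbors(g, nxt)))),
                          members)
    }
    if (length(members) == size) return(members)
  }
  stop("could not grow a connected planted set of size ", size,
       " in ", retries, " attempts")
}

#' Write a synthetic benchmark to fixture files
#'
#' Produces the three plain-text inputs every other stage consumes unchanged:
#' an edge-list TSV, a tiered gene-list TSV, and a GMT whose first set is the
#' planted module (named `planted_module`) followed by random decoy sets.
#'
#' @param sim A `synthetic_data` object.
#' @param dir Output directory (created if missing).
#' @param n_decoy_sets Number of random decoy gene sets in the GMT.
#' @param decoy_size Size of each decoy set.
#' @return Named character vector of the written paths (`edges`, `gene_lists`,
#'   `gmt`, `truth`).
#' @export
write_fixture <- function(sim, dir, n_decoy_sets = 5L, decoy_size = 40L) {
  stopifnot(inherits(sim, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             gene_lists = file.path(dir, "gene_lists.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "planted_genes.txt"))
  write_edge_list(sim$net, paths[["edges"]])
  write_gene_lists(sim$layers, paths[["gene_lists"]])
  set.seed(sim$truth$spec$seed + 104729L)
  sets <- c(list(planted_module = sim$truth$planted),
            stats::setNames(lapply(seq_len(n_decoy_sets), function(i) {
              sort(sample(sim$net$nodes, min(decoy_size, length(sim$net$nodes))))
            }), sprintf("decoy_%02d", seq_len(n_decoy_sets))))
  write_gmt(sets, paths[["gmt"]])
  writeLines(sim$truth$planted, paths[["truth"]])
  paths
}
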