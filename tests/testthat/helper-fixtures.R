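# fixtures built in code; no binary data

mk_net <- function(pairs, score = 900, nodes = NULL) {
  # pairs: character vector c("a","b", "b","c", ...) taken two at a time
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  as_interactome(data.frame(from = m[, 1], to = m[, 2], score = score),
                 nodes = nodes)
}

triangle_net <- function() mk_net(c("a","b", "b","c", "a","c"))
path_net <- function() mk_net(c("a","b", "b","c"))
star_net <- function() mk_net(c("hub","l1", "hub","l2", "hub","l3"))

er_net <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) stop("empty ER draw")
  ids <- sprintf("g%03d", seq_len(n))
  as_interactome(data.frame(from = ids[el[, 1]], to = ids[el[, 2]], score = 900),
                 nodes = ids)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# independent oracle: exhaustive enumeration of the hypergeometric upper tail
enum_hyper_upper <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# independent oracle: modularity straight from the definition (1/2m) sum_ij ...
def_modularity <- function(graph, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  vn <- igraph::V(graph)$name
  memb <- membership[vn]
  m <- igraph::ecount(graph)
  if (m == 0) return(0)
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

# all set partitions of a vector (Bell-number growth; fine for <= 8 elements)
all_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- all_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

partition_membership <- function(p) {
  memb <- integer(0)
  for (i in seq_along(p)) memb[p[[i]]] <- i
  memb
}

# benchmark synthetic run shared by module-detection and pipeline tests
benchmark_scores <- function(seed = 1, spec = synthetic_spec(seed = seed)) {
  sim <- generate_synthetic(spec)
  X0 <- build_matrix(restrict_to_network(sim$layers, sim$net)$layers, sim$net)
  res <- network_diffusion(sim$net, X0)
  list(sim = sim, res = res, ranking = rank_genes(res))
}
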