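two_cliques_graph <- function() {
  # two 4-cliques joined by a single bridge edge
  cl <- function(v) t(utils::combn(v, 2))
  e <- rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)), c("a1", "b1"))
  igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
}

test_that("Newman modularity matches hand computation and the full definition", {
  # two triangles joined by one edge, natural split: Q = 2*(3/7 - (7/14)^2)
  e <- rbind(c("a1","a2"), c("a2","a3"), c("a1","a3"),
             c("b1","b2"), c("b2","b3"), c("b1","b3"), c("a1","b1"))
  g <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), c(paste0("a", 1:3), paste0("b", 1:3)))
  expect_equal(newman_modularity(g, memb), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)

  # one big cluster always scores 0
  expect_equal(newman_modularity(g, stats::setNames(rep(1, 6), names(memb))), 0,
               tolerance = 1e-12)

  # edgeless graph: 0 by convention
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("x", "y", "z")
  expect_equal(newman_modularity(g0, stats::setNames(1:3, c("x", "y", "z"))), 0)

  # random graphs, random partitions: agree with the matrix-form definition
  # and with igraph's implementation
  for (seed in 1:3) {
    set.seed(seed)
    g2 <- igraph::sample_gnp(12, 0.3)
    igraph::V(g2)$name <- sprintf("v%02d", 1:12)
    memb2 <- stats::setNames(sample(1:3, 12, replace = TRUE),
                             igraph::V(g2)$name)
    expect_equal(newman_modularity(g2, memb2), def_modularity(g2, memb2),
                 tolerance = 1e-12)
    expect_equal(newman_modularity(g2, memb2),
                 igraph::modularity(g2, memb2[igraph::V(g2)$name]),
                 tolerance = 1e-12)
  }
})

test_that("modularity is maximized by the brute-force best partition on small graphs", {
  # 6-node graph: brute force over all set partitions
  e <- rbind(c("a","b"), c("b","c"), c("a","c"), c("d","e"), c("e","f"),
             c("d","f"), c("c","d"))
  g <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
  vn <- igraph::V(g)$name
  best <- -Inf
  for (p in all_partitions(vn)) {
    best <- max(best, newman_modularity(g, partition_membership(p)))
  }
  # greedy optimizer on this easy instance reaches the brute-force optimum
  parts <- detect_communities(g, "greedy")
  expect_equal(parts[[1]]$Q, best, tolerance = 1e-12)
  expect_equal(best, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
})

test_that("every method separates two bridged cliques and returns a valid partition", {
  g <- two_cliques_graph()
  parts <- detect_communities(g, seed = 3)
  expect_length(parts, 5)
  for (p in parts) {
    memb <- p$membership
    expect_setequal(names(memb), igraph::V(g)$name)
    a_labels <- unique(memb[paste0("a", 1:4)])
    b_labels <- unique(memb[paste0("b", 1:4)])
    expect_length(a_labels, 1)
    expect_length(b_labels, 1)
    expect_false(a_labels == b_labels)
    expect_gte(p$Q, -0.5)
    expect_lte(p$Q, 1)
  }
  expect_error(detect_communities(g, "spectral_magic"), "unknown")

  # complete graph: any split has Q <= 0, single cluster ties the top
  kg <- igraph::make_full_graph(5)
  igraph::V(kg)$name <- letters[1:5]
  single <- stats::setNames(rep(1, 5), letters[1:5])
  expect_equal(newman_modularity(kg, single), 0)
  for (p in all_partitions(letters[1:5])) {
    expect_lte(newman_modularity(kg, partition_membership(p)), 1e-12)
  }
})

test_that("best partition maximizes Q with fewest-clusters tie-breaking", {
  g <- two_cliques_graph()
  vn <- igraph::V(g)$name
  mk <- function(labels, method) {
    memb <- stats::setNames(labels, vn)
    structure(list(membership = memb, method = method,
                   Q = newman_modularity(g, memb)), class = "partition")
  }
  p_split <- mk(ifelse(grepl("^a", vn), 1L, 2L), "two")
  p_single <- mk(rep(1, 8), "one")
  p_frag <- mk(match(sub("^.", "", vn), c("1", "2", "3", "4")), "four")
  out <- best_partition(list(p_frag, p_single, p_split))
  expect_equal(out$method, "two")
  # tie on Q: fewest clusters wins; then input order
  dup <- p_split; dup$method <- "two_copy"; dup$membership <- p_split$membership
  expect_equal(best_partition(list(dup, p_split))$method, "two_copy")
  expect_equal(best_partition(list(p_single))$method, "one")
})

test_that("GMT files round-trip and drive cluster enrichment", {
  sets <- list(alpha = c("a1", "a2", "a3", "a4"), beta = c("b1", "b2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back, sets)

  g <- two_cliques_graph()
  vn <- igraph::V(g)$name
  memb <- stats::setNames(ifelse(grepl("^a", vn), 1L, 2L), vn)
  part <- structure(list(membership = memb, method = "manual",
                         Q = newman_modularity(g, memb)), class = "partition")
  enr <- pathway_enrichment(part, sets, universe = 10)
  expect_equal(nrow(enr), 4)
  row_a1 <- enr[enr$cluster == "1" & enr$set == "alpha", ]
  # cluster 1 = the alpha clique: p equals the enumeration oracle
  expect_equal(row_a1$overlap, 4L)
  expect_equal(row_a1$p, enum_hyper_upper(10, 4, 4, 4), tolerance = 1e-12)
  # zero overlap is never significant
  expect_equal(enr$p[enr$cluster == "1" & enr$set == "beta"], 1)
  expect_true(all(enr$q >= enr$p - 1e-15))
  expect_error(pathway_enrichment(part, list()), "nonempty")
})

test_that("evidence enrichment compares cluster and module proportions", {
  module <- sprintf("m%02d", 1:20)
  cluster <- module[1:5]
  support_half <- module[1:10]
  expect_equal(evidence_enrichment(cluster, support_half, module), 2.0)
  # matched proportions give exactly 1
  expect_equal(evidence_enrichment(module[1:10], support_half, module),
               (5 / 10) / (10 / 20) * 2)  # fully supported cluster vs half module
  expect_equal(evidence_enrichment(cluster, module, module), 1.0)
  expect_equal(evidence_enrichment(cluster, character(0), module), NA_real_)
  expect_equal(evidence_enrichment(module[11:15], support_half, module), 0)
  expect_error(evidence_enrichment(c("zz"), support_half, module), "subset")
})
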