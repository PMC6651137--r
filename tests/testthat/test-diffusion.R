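test_that("steady state matches the direct linear solve", {
  # two-node graph, seed on one end: hand-derivable fixed point
  net <- mk_net(c("a", "b"))
  W <- normalize_adjacency(net)
  X0 <- matrix(c(1, 0), ncol = 1, dimnames = list(c("a", "b"), "G"))
  xss <- diffuse_closed_form(W, X0, alpha = 0.7)
  # oracle: dense 2x2 resolvent solve
  oracle <- solve(diag(2) - 0.7 * as.matrix(W), 0.3 * X0)
  expect_equal(as.numeric(xss), as.numeric(oracle), tolerance = 1e-12)
  expect_equal(as.numeric(xss), c(0.588235, 0.411765), tolerance = 1e-5)

  # all-zero input is a fixed point
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "G"))
  expect_equal(as.numeric(diffuse(W, zero)), c(0, 0))

  # isolated seeded node keeps only the restart term (1 - alpha) * x0
  net_iso <- mk_net(c("a", "b"), nodes = "z")
  Wi <- normalize_adjacency(net_iso)
  X0i <- matrix(c(0, 0, 1), ncol = 1, dimnames = list(net_iso$nodes, "G"))
  expect_equal(diffuse_closed_form(Wi, X0i, 0.7)["z", ], 0.3,
               ignore_attr = TRUE)
})

test_that("iterative diffusion agrees with the closed form on random graphs", {
  tol <- 1e-8
  for (seed in 1:5) {
    net <- er_net(30, 0.15, seed = seed)
    W <- normalize_adjacency(net)
    set.seed(seed + 100)
    X0 <- matrix(sample(c(0, 0.5, 1), 2 * nrow(W), replace = TRUE), ncol = 2,
                 dimnames = list(net$nodes, c("G", "E")))
    it <- diffuse(W, X0, alpha = 0.7, tol = tol)
    cf <- diffuse_closed_form(W, X0, alpha = 0.7)
    expect_lt(max(abs(it - cf)), tol * 10)
    expect_gt(attr(it, "iterations"), 1)
  }
  expect_error(diffuse(normalize_adjacency(er_net(20, 0.2)),
                       matrix(1, 20, 1), max_iter = 2),
               "did not converge")
})

test_that("diffusion is linear and monotone in the input", {
  net <- er_net(25, 0.2, seed = 9)
  W <- normalize_adjacency(net)
  n <- nrow(W)
  set.seed(11)
  X <- matrix(runif(n), ncol = 1)
  Y <- matrix(runif(n), ncol = 1)
  lhs <- diffuse_closed_form(W, 2 * X + 3 * Y, 0.7)
  rhs <- 2 * diffuse_closed_form(W, X, 0.7) + 3 * diffuse_closed_form(W, Y, 0.7)
  expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)

  # raising one entry never decreases any steady-state entry
  base <- diffuse_closed_form(W, X, 0.7)
  for (i in c(1, 7, 19)) {
    X2 <- X; X2[i, 1] <- X2[i, 1] + 1
    expect_true(all(diffuse_closed_form(W, X2, 0.7) >= base - 1e-12))
  }

  # symmetric seeds on a symmetric graph give symmetric scores
  tri <- triangle_net()
  Xs <- matrix(1, 3, 1, dimnames = list(tri$nodes, "G"))
  out <- diffuse_closed_form(normalize_adjacency(tri), Xs, 0.7)
  expect_equal(max(out) - min(out), 0, tolerance = 1e-12)
})

test_that("column normalization and composite score follow their definitions", {
  expect_equal(normalize_columns(matrix(c(2, 1, 0), ncol = 1))[, 1],
               c(1, 0.5, 0))
  Z <- matrix(0, 3, 1)
  expect_equal(normalize_columns(Z), Z)
  M <- matrix(c(2, 1, 0, 4, 2, 0), ncol = 2)
  expect_equal(unname(apply(normalize_columns(M), 2, max)), c(1, 1))

  xstar <- matrix(c(1, 0.5, 0), nrow = 1)
  y <- matrix(c(0.2, 0.1, 0.3), nrow = 1)
  expect_equal(unname(composite_score(xstar, y)), 1.5 * 0.6)
  expect_equal(unname(composite_score(0 * xstar, y)), 0)
})

test_that("top-neighbor means average the m best direct neighbors", {
  # hub with 4 leaves carrying known scores
  net <- mk_net(c("hub","n1", "hub","n2", "hub","n3", "hub","n4"))
  X <- matrix(0, length(net$nodes), 1, dimnames = list(net$nodes, "G"))
  X[c("n1", "n2", "n3", "n4"), 1] <- c(0.9, 0.5, 0.1, 0.05)
  Y <- top_neighbor_means(net, X, m = 3)
  expect_equal(Y["hub", 1], mean(c(0.9, 0.5, 0.1)))
  # leaf has a single neighbor (the hub, score 0): fewer-than-m rule
  expect_equal(Y["n1", 1], 0)
  net2 <- mk_net(c("a", "b"), nodes = "z")
  X2 <- matrix(c(0.4, 0.8, 1), ncol = 1, dimnames = list(net2$nodes, "G"))
  Y2 <- top_neighbor_means(net2, X2, m = 3)
  expect_equal(Y2["a", 1], 0.8)  # one neighbor only
  expect_equal(Y2["z", 1], 0)    # isolated
})

test_that("permutation p-values honor their invariances and bounds", {
  net <- er_net(30, 0.2, seed = 2)
  W <- normalize_adjacency(net)
  n <- length(net$nodes)

  # identical rows: every permutation reproduces the statistic, p = 1
  X0 <- matrix(0.5, n, 2, dimnames = list(net$nodes, c("G", "E")))
  p <- permutation_pvalues(W, net, X0, n_perm = 19, seed = 4)
  expect_true(all(p == 1))

  # add-one floor and seed requirement
  set.seed(5)
  X1 <- matrix(sample(c(0, 1), n, replace = TRUE), ncol = 1,
               dimnames = list(net$nodes, "G"))
  p1 <- permutation_pvalues(W, net, X1, n_perm = 19, seed = 4, statistic = "xss")
  expect_gte(min(p1), 1 / 20)
  expect_lte(max(p1), 1)
  expect_error(permutation_pvalues(W, net, X1, n_perm = 5), "seed")

  # invariance to gene relabeling: rename genes, same p in the new order
  perm_names <- sprintf("h%03d", seq_len(n))
  e2 <- net$edges
  map <- stats::setNames(perm_names, net$nodes)
  net2 <- as_interactome(data.frame(from = map[e2$from], to = map[e2$to],
                                    score = e2$score), nodes = perm_names)
  X2 <- X1[match(sub("^h", "g", net2$nodes), rownames(X1)), , drop = FALSE]
  rownames(X2) <- net2$nodes
  p2 <- permutation_pvalues(normalize_adjacency(net2), net2, X2,
                            n_perm = 19, seed = 4, statistic = "xss")
  expect_equal(unname(p2[map[names(p1)]]), unname(p1))
})

test_that("null p-values are approximately uniform", {
  # random scores with no network-correlated structure, single layer
  net <- er_net(200, 0.05, seed = 42)
  W <- normalize_adjacency(net)
  set.seed(43)
  X0 <- matrix(runif(length(net$nodes)), ncol = 1,
               dimnames = list(net$nodes, "G"))
  p <- permutation_pvalues(W, net, X0, n_perm = 100, seed = 7,
                           statistic = "xss")
  ks <- unname(suppressWarnings(stats::ks.test(p, "punif"))$statistic)
  expect_lt(ks, 0.1)
})

test_that("core extension recovers planted genes with high precision", {
  # single-layer seeded analysis: the core mixes 25 planted genes with 15
  # scattered weakly connected genes (curated cores include poorly connected
  # entries, which set the "comparable to core" score floor); non-core planted
  # genes carry minor-tier evidence
  sim <- generate_synthetic(synthetic_spec(seed = 4))
  planted <- sim$truth$planted
  set.seed(6)
  core_mod <- sample(planted, 25)
  deg <- sim$net$degree
  lowdeg <- setdiff(names(deg)[deg <= stats::quantile(deg, 0.25)], planted)
  core <- sort(c(core_mod, sample(lowdeg, 15)))
  minor_bg <- sort(sample(setdiff(sim$net$nodes, c(planted, core)), 50))
  lay <- evidence_layer("G", major = core,
                        minor = c(setdiff(planted, core), minor_bg))
  X0 <- build_matrix(list(lay), sim$net)
  res <- network_diffusion(sim$net, X0, n_perm = 500, seed = 7,
                           statistic = "xss")
  sel <- select_core_extension(res, core)
  expect_gt(length(sel), 0)
  expect_gte(length(intersect(sel, planted)) / length(sel), 0.8)
})

test_that("core extension excludes core genes and honors its thresholds", {
  net <- er_net(40, 0.15, seed = 6)
  X0 <- matrix(0, length(net$nodes), 1, dimnames = list(net$nodes, "G"))
  core <- net$nodes[1:5]
  X0[core, 1] <- 1
  res <- network_diffusion(net, X0, n_perm = 49, seed = 8, statistic = "xss")
  sel <- select_core_extension(res, core)
  expect_length(intersect(sel, core), 0)
  expect_error(select_core_extension(res, character(0)), "nonempty")
  # p_max = 0 can never select anything
  expect_length(select_core_extension(res, core, p_max = 0), 0)
})
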