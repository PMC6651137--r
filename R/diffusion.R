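#' Iterative network diffusion to steady state
#'
#' Iterates the propagation update X(t+1) = alpha * W %*% X(t) + (1 - alpha) * X0
#' from X(0) = X0 until the maximum absolute change drops below `tol`. Because
#' the spectral radius of the symmetrically normalized operator W is at most 1,
#' the iteration contracts geometrically at rate alpha and converges to the
#' unique steady state for any alpha in (0, 1).
#'
#' @param W Normalized adjacency operator from [normalize_adjacency()].
#' @param X0 Genes-by-layers input matrix (rows aligned with W).
#' @param alpha Diffusion weight in (0, 1); 0.7 balances propagation depth
#'   against locality of the seeds.
#' @param tol Convergence tolerance on the max-norm of the update step.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   residual.
#' @return The steady-state matrix Xss with attributes `iterations` and
#'   `residual`.
#' @seealso [diffuse_closed_form()] for the exact linear-solve route.
#' @export
diffuse <- function(W, X0, alpha = 0.7, tol = 1e-6, max_iter = 1e4) {
  check_diffusion_args(W, X0, alpha)
  stopifnot(tol > 0, max_iter >= 1)
  X0 <- as.matrix(X0)
  X <- X0
  seed_term <- (1 - alpha) * X0
  for (it in seq_len(max_iter)) {
    Xn <- as.matrix(alpha * (W %*% X)) + seed_term
    res <- max(abs(Xn - X))
    X <- Xn
    if (res < tol) {
      dimnames(X) <- dimnames(X0)
      attr(X, "iterations") <- it
      attr(X, "residual") <- res
      return(X)
    }
  }
  stop(sprintf("diffusion did not converge in %d iterations (residual %.3g)",
               as.integer(max_iter), res))
}

#' Closed-form steady state of network diffusion
#'
#' Solves (I - alpha * W) Xss = (1 - alpha) X0 directly. The system is
#' symmetric positive definite for alpha < 1 (all eigenvalues of W lie in
#' \[-1, 1\]), so a sparse Cholesky factorization applies and the solution is
#' exact up to numerical precision; this is the reference the iterative route
#' is checked against.
#'
#' @inheritParams diffuse
#' @return The steady-state matrix Xss (same dimnames as X0).
#' @export
diffuse_closed_form <- function(W, X0, alpha = 0.7) {
  check_diffusion_args(W, X0, alpha)
  X0 <- as.matrix(X0)
  Xss <- as.matrix(solve(diffusion_system(W, alpha), (1 - alpha) * X0))
  dimnames(Xss) <- dimnames(X0)
  Xss
}

# Cached-factorization form of (I - alpha W): one Cholesky, many solves.
diffusion_system <- function(W, alpha) {
  n <- nrow(W)
  M <- Matrix::Diagonal(n) - alpha * W
  Matrix::Cholesky(Matrix::forceSymmetric(M))
}

check_diffusion_args <- function(W, X0, alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must be a scalar in (0, 1)")
  }
  if (nrow(W) != nrow(as.matrix(X0))) {
    stop("X0 rows must match the network size")
  }
  invisible(TRUE)
}

#' Column-wise maximum normalization
#'
#' Divides each column by its maximum so that layer scores become comparable;
#' an all-zero column is left unchanged.
#'
#' @param Xss A numeric matrix of nonnegative diffusion scores.
#' @return Matrix of the same shape with column maxima equal to 1 (where the
#'   column is nonzero).
#' @export
normalize_columns <- function(Xss) {
  Xss <- as.matrix(Xss)
  mx <- apply(Xss, 2L, max)
  mx[mx == 0] <- 1
  sweep(Xss, 2L, mx, "/")
}

#' Per-layer mean of the top-scoring direct neighbors
#'
#' For each gene i and layer j, averages the m largest normalized scores
#' x*kj over the direct neighbors k of i (a gene is not its own neighbor).
#' Genes with fewer than m neighbors are averaged over all of them; isolated
#' genes score 0. Ties at the m-th place are broken by descending score then
#' lexicographic gene identifier, which leaves the mean unchanged but fixes the
#' selected set.
#'
#' @param net An `interactome`.
#' @param Xstar Column-normalized score matrix (rows aligned with `net$nodes`).
#' @param m Number of top neighbors to average (default 3).
#' @return Matrix Y of the same shape as `Xstar`.
#' @export
top_neighbor_means <- function(net, Xstar, m = 3L) {
  stopifnot(inherits(net, "interactome"), m >= 1)
  Xstar <- as.matrix(Xstar)
  stopifnot(nrow(Xstar) == length(net$nodes))
  nb <- adjacency_list(net)
  Y <- matrix(0, nrow = nrow(Xstar), ncol = ncol(Xstar),
              dimnames = dimnames(Xstar))
  for (j in seq_len(ncol(Xstar))) {
    xj <- Xstar[, j]
    Y[, j] <- vapply(nb, function(v) {
      if (length(v) == 0L) return(0)
      k <- min(m, length(v))
      xv <- xj[v]
      top <- v[order(-xv, net$nodes[v])[seq_len(k)]]
      mean(xj[top])
    }, numeric(1))
  }
  Y
}

# neighbor index list, cached on the interactome's adjacency structure
adjacency_list <- function(net) {
  A <- net$A
  n <- nrow(A)
  p <- A@p
  lapply(seq_len(n), function(j) A@i[seq.int(p[j] + 1L, length.out = p[j + 1L] - p[j])] + 1L)
}

#' Composite multi-omics diffusion score
#'
#' d_i = (sum over layers of x*ij) * (sum over layers of y*ij): the product of
#' a gene's own normalized diffusion scores and the averaged scores of its best
#' direct neighbors, so that high-scoring genes in low-scoring neighborhoods
#' (and vice versa) are down-weighted.
#'
#' @param Xstar Column-normalized score matrix.
#' @param Y Top-neighbor mean matrix from [top_neighbor_means()].
#' @return Named numeric vector d.
#' @export
composite_score <- function(Xstar, Y) {
  Xstar <- as.matrix(Xstar); Y <- as.matrix(Y)
  stopifnot(identical(dim(Xstar), dim(Y)))
  stats::setNames(rowSums(Xstar) * rowSums(Y), rownames(Xstar))
}

score_statistic <- function(net, Xss, statistic, m) {
  Xstar <- normalize_columns(Xss)
  if (statistic == "xss") {
    if (ncol(Xstar) != 1L) {
      stop("statistic 'xss' is defined for a single-layer matrix")
    }
    drop(Xss[, 1L])
  } else {
    composite_score(Xstar, top_neighbor_means(net, Xstar, m))
  }
}

#' Permutation p-values for diffusion scores
#'
#' Under the null, whole rows of X0 are shuffled across genes (a gene's
#' multi-layer evidence profile stays intact), the full scoring pipeline is
#' recomputed, and the empirical p-value uses the add-one estimator
#' p_i = (1 + #\{b : stat_i^(b) >= stat_i\}) / (1 + n_perm), so p = 0 is
#' unattainable and min p = 1/(n_perm + 1). Each permutation draws from its own
#' seed derived from `seed` plus the permutation index, so results do not
#' depend on execution order.
#'
#' @inheritParams diffuse
#' @param net The `interactome` matching `W`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; required, there is no implicit default.
#' @param statistic `"d"` for the composite multi-layer score or `"xss"` for
#'   the raw single-layer steady-state score.
#' @param m Top-neighbor count for the composite statistic.
#' @return Named numeric vector of p-values in \[1/(n_perm+1), 1\].
#' @export
permutation_pvalues <- function(W, net, X0, alpha = 0.7, n_perm = 1000L,
                                seed, statistic = c("d", "xss"), m = 3L) {
  statistic <- match.arg(statistic)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible permutation p-values")
  }
  stopifnot(n_perm >= 1)
  X0 <- as.matrix(X0)
  ch <- diffusion_system(W, alpha)
  solve_ss <- function(X) as.matrix(Matrix::solve(ch, (1 - alpha) * X))
  obs <- score_statistic(net, solve_ss(X0), statistic, m)
  n <- nrow(X0)
  exceed <- integer(n)
  for (b in seq_len(n_perm)) {
    set.seed(as.integer((seed + b) %% .Machine$integer.max))
    perm <- sample.int(n)
    stat_b <- score_statistic(net, solve_ss(X0[perm, , drop = FALSE]),
                              statistic, m)
    exceed <- exceed + (stat_b >= obs)
  }
  stats::setNames((1 + exceed) / (1 + n_perm), rownames(X0))
}

#' Run the full diffusion scoring pipeline
#'
#' Convenience wrapper: normalizes the network, diffuses X0 to steady state
#' (closed form by default), column-normalizes, computes top-neighbor means,
#' the composite score d, and (optionally) permutation p-values.
#'
#' @param net An `interactome`.
#' @param X0 Genes-by-layers evidence matrix from [build_matrix()].
#' @inheritParams permutation_pvalues
#' @param tol,max_iter Passed to [diffuse()] when `method = "iterative"`.
#' @param method `"closed_form"` (default) or `"iterative"`.
#' @return An object of class `diffusion_result`: list with `genes`, `Xss`,
#'   `Xstar`, `Y`, `d`, `p` (NULL when `n_perm = 0`), `alpha`, `statistic`,
#'   and the iteration diagnostics when the iterative route was used.
#' @export
network_diffusion <- function(net, X0, alpha = 0.7, n_perm = 0L, seed = NULL,
                              statistic = c("d", "xss"), m = 3L,
                              tol = 1e-6, max_iter = 1e4,
                              method = c("closed_form", "iterative")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  stopifnot(inherits(net, "interactome"))
  X0 <- as.matrix(X0)
  W <- normalize_adjacency(net)
  Xss <- if (method == "iterative") {
    diffuse(W, X0, alpha, tol, max_iter)
  } else {
    diffuse_closed_form(W, X0, alpha)
  }
  Xstar <- normalize_columns(Xss)
  Y <- top_neighbor_means(net, Xstar, m)
  d <- composite_score(Xstar, Y)
  p <- NULL
  if (n_perm > 0L) {
    p <- permutation_pvalues(W, net, X0, alpha, n_perm, seed, statistic, m)
  }
  structure(list(genes = net$nodes, Xss = Xss, Xstar = Xstar, Y = Y, d = d,
                 p = p, alpha = alpha, statistic = statistic, m = m,
                 iterations = attr(Xss, "iterations"),
                 residual = attr(Xss, "residual")),
            class = "diffusion_result")
}

#' @exportS3Method base::print
print.diffusion_result <- function(x, ...) {
  cat(sprintf("diffusion result: %d genes x %d layers, alpha = %g\n",
              length(x$genes), ncol(x$Xss), x$alpha))
  if (!is.null(x$p)) cat(sprintf("  %d genes with p < 0.05\n", sum(x$p < 0.05)))
  invisible(x)
}

#' Rank genes by descending composite score
#'
#' @param result A `diffusion_result`.
#' @return Character vector of gene identifiers ordered by decreasing d, ties
#'   broken lexicographically.
#' @export
rank_genes <- function(result) {
  stopifnot(inherits(result, "diffusion_result"))
  result$genes[order(-result$d, result$genes)]
}

#' Extend a core gene set by diffusion score comparability
#'
#' Selects non-core genes whose single-layer diffusion score is statistically
#' significant and comparable to the core genes' own scores. The default
#' comparability rule requires the score to reach at least the minimum score
#' observed over the core; `rule = "quantile:q"` instead requires the
#' q-quantile of core scores.
#'
#' @param result A single-layer `diffusion_result` with p-values.
#' @param core Character vector of core (seed) genes; must be nonempty.
#' @param p_max Significance cutoff on the permutation p-value.
#' @param rule `"min_core"` or `"quantile:q"` with q in \[0, 1\].
#' @return Sorted character vector of selected non-core genes.
#' @export
select_core_extension <- function(result, core, p_max = 0.05,
                                  rule = "min_core") {
  stopifnot(inherits(result, "diffusion_result"))
  if (length(core) == 0L) stop("core gene set must be nonempty")
  if (is.null(result$p)) stop("result carries no permutation p-values")
  if (ncol(result$Xss) != 1L) {
    stop("core extension is defined for a single-layer result")
  }
  score <- drop(result$Xss[, 1L])
  core <- intersect(core, result$genes)
  if (length(core) == 0L) stop("no core gene is on the network")
  cutoff <- if (identical(rule, "min_core")) {
    min(score[core])
  } else if (grepl("^quantile:", rule)) {
    q <- as.numeric(sub("^quantile:", "", rule))
    if (is.na(q) || q < 0 || q > 1) stop("invalid quantile rule: ", rule)
    stats::quantile(score[core], q, names = FALSE)
  } else {
    stop("unknown comparability rule: ", rule)
  }
  cand <- setdiff(result$genes, core)
  sort(cand[result$p[cand] < p_max & score[cand] >= cutoff])
}
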