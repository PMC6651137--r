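#' Count edges induced by a gene set
#'
#' Number of interactome edges with both endpoints in `genes` — the
#' connectivity statistic used by the network-resampling null.
#'
#' @param net An `interactome`.
#' @param genes Character vector of genes, all on the network.
#' @return Integer edge count.
#' @export
internal_edges <- function(net, genes) {
  stopifnot(inherits(net, "interactome"))
  genes <- unique(as.character(genes))
  idx <- match(genes, net$nodes)
  if (anyNA(idx)) {
    stop("genes not on the network: ",
         paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
  }
  if (length(idx) < 2L) return(0L)
  as.integer(sum(net$A[idx, idx]) / 2)
}

#' Connectivity significance of top-ranked genes by network resampling
#'
#' For each candidate module size k, compares the number of edges induced by
#' the top-k genes of the ranking against a null distribution of induced edge
#' counts over R random gene sets of size k. The default null draws within
#' degree bins matching the degree composition of the top-k set, which controls
#' for the tendency of hubs to be both high-scoring under diffusion and well
#' connected in any subset; `null = "uniform"` draws uniformly over the
#' network. Empirical p-values use the add-one estimator, so min p = 1/(R+1).
#'
#' @param net An `interactome`.
#' @param ranking Character vector of genes ordered by decreasing score (see
#'   [rank_genes()]).
#' @param k_grid Candidate module sizes; each must not exceed the ranking
#'   length.
#' @param R Number of resamples per k (at least 100 for usable p-values).
#' @param seed Integer seed; required.
#' @param null `"degree_matched"` (default) or `"uniform"`.
#' @param n_bins Number of degree-quantile bins for the degree-matched null
#'   (25 by default: in heavy-tailed degree distributions, coarse bins
#'   under-control the hub end of the spectrum).
#' @return Data frame of class `network_resampling` with columns `k`, `omega`
#'   (observed induced edges), `null_mean`, `null_sd`, `z`, `p`.
#' @export
network_resampling <- function(net, ranking, k_grid = seq(25L, 500L, by = 25L),
                               R = 999L, seed, null = c("degree_matched", "uniform"),
                               n_bins = 25L) {
  null <- match.arg(null)
  stopifnot(inherits(net, "interactome"), R >= 1)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible resampling")
  }
  ranking <- as.character(ranking)
  if (anyNA(match(ranking, net$nodes))) stop("ranking contains off-network genes")
  if (any(k_grid > length(ranking))) {
    stop("k_grid contains sizes exceeding the ranking length (",
         length(ranking), ")")
  }
  if (any(k_grid < 1)) stop("k_grid sizes must be positive")
  A <- net$A
  rank_idx <- match(ranking, net$nodes)
  deg <- net$degree
  bin <- NULL
  if (null == "degree_matched") {
    # quantile bins on degree; duplicate breaks collapse for skewed degrees
    br <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(br) < 2L) {
      rep(1L, length(deg))  # degenerate: all degrees equal
    } else {
      cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
    }
    by_bin <- split(seq_along(deg), bin)
  }
  count_edges <- function(idx) sum(A[idx, idx]) / 2
  out <- lapply(seq_along(k_grid), function(gi) {
    k <- k_grid[gi]
    top <- rank_idx[seq_len(k)]
    omega <- count_edges(top)
    set.seed(as.integer((seed + 7919 * gi) %% .Machine$integer.max))
    null_omega <- vapply(seq_len(R), function(r) {
      idx <- if (null == "uniform") {
        sample.int(length(deg), k)
      } else {
        tab <- tabulate(bin[top], nbins = length(by_bin))
        unlist(lapply(seq_along(by_bin), function(b) {
          if (tab[b] == 0L) return(integer(0))
          pool <- by_bin[[b]]
          pool[sample.int(length(pool), tab[b], replace = tab[b] > length(pool))]
        }))
      }
      count_edges(idx)
    }, numeric(1))
    sdv <- stats::sd(null_omega)
    data.frame(k = k, omega = omega,
               null_mean = mean(null_omega), null_sd = sdv,
               z = if (isTRUE(sdv > 0)) (omega - mean(null_omega)) / sdv else NA_real_,
               p = (1 + sum(null_omega >= omega)) / (1 + R))
  })
  structure(do.call(rbind, out), class = c("network_resampling", "data.frame"))
}

#' Extract a significantly connected gene module
#'
#' Chooses the module size k* from the resampling scan. The default rule
#' `"min_p"` picks the k with the smallest connectivity p-value, breaking the
#' ties that the add-one empirical estimator necessarily produces (p floors at
#' 1/(R+1)) by the largest z-score and then the smallest k — i.e. it locates
#' the connectivity peak of the scan. `rule = "max_k"` instead returns the
#' largest k passing `alpha_nr`, the maximal module under the significance
#' constraint; note that when the whole scan sits at the p floor this rule
#' degenerates to the grid maximum. The module is the top-k* slice of the
#' ranking together with its induced subgraph and connected components. When no
#' k is significant an empty module is returned with a diagnostic, not an
#' error.
#'
#' @param net An `interactome`.
#' @param ranking Gene ranking used for the resampling scan.
#' @param resampling Result of [network_resampling()] on the same ranking.
#' @param alpha_nr Significance level on the resampling p-value.
#' @param rule `"min_p"` (default) or `"max_k"`.
#' @return A list of class `gene_module`: `genes`, `k_star`, `omega`, `edges`
#'   (induced edge data frame), `components` (list of sorted character
#'   vectors, largest first), `scan` (the resampling table), `diagnostic`.
#' @export
extract_module <- function(net, ranking, resampling, alpha_nr = 0.01,
                           rule = c("min_p", "max_k")) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "interactome"), inherits(resampling, "data.frame"))
  sig <- resampling$k[resampling$p <= alpha_nr]
  if (length(sig) == 0L) {
    return(structure(list(genes = character(0), k_star = 0L, omega = 0L,
                          edges = net$edges[0, ], components = list(),
                          scan = resampling,
                          diagnostic = sprintf(
                            "no module size significant at alpha_nr = %g (min p = %g)",
                            alpha_nr, min(resampling$p))),
                     class = "gene_module"))
  }
  k_star <- if (rule == "max_k") {
    max(sig)
  } else {
    cand <- resampling[resampling$k %in% sig, , drop = FALSE]
    z <- ifelse(is.na(cand$z), -Inf, cand$z)
    cand$k[order(cand$p, -z, cand$k)[1L]]
  }
  genes <- as.character(ranking[seq_len(k_star)])
  e <- net$edges
  keep <- e$from %in% genes & e$to %in% genes
  edges <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = sort(genes))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  # largest first; ties by smallest lexicographic member
  ord <- order(-lengths(members), vapply(members, `[[`, character(1), 1L))
  structure(list(genes = genes, k_star = k_star,
                 omega = resampling$omega[match(k_star, resampling$k)],
                 edges = edges, components = members[ord],
                 scan = resampling, diagnostic = NULL),
            class = "gene_module")
}

#' @exportS3Method base::print
print.gene_module <- function(x, ...) {
  if (length(x$genes) == 0L) {
    cat("gene module: empty (", x$diagnostic, ")\n", sep = "")
  } else {
    cat(sprintf(
      "gene module: %d genes (k* = %d), %d internal edges, largest component %d genes\n",
      length(x$genes), x$k_star, nrow(x$edges), length(largest_component(x))))
  }
  invisible(x)
}

#' Largest connected component of a gene module
#'
#' @param module A `gene_module`.
#' @return Sorted character vector of member genes; empty for an empty module.
#'   Size ties are resolved in favor of the component containing the
#'   lexicographically smallest gene.
#' @export
largest_component <- function(module) {
  stopifnot(inherits(module, "gene_module"))
  if (length(module$components) == 0L) return(character(0))
  module$components[[1L]]
}
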