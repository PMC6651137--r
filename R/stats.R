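#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(population N, successes K, draws n),
#' evaluated through the stable log-space tail routine of [stats::phyper()].
#' This is the enrichment statistic used throughout: for overlap of two gene
#' sets in a universe and for core-gene enrichment among a gene's interactors.
#'
#' @param N Population size (e.g. interactome size).
#' @param K Number of successes in the population (e.g. core-set size).
#' @param n Number of draws (e.g. a gene's degree).
#' @param k Observed number of successes among the draws.
#' @return P(X >= k); equal to 1 when k = 0.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (any(c(N, K, n, k) < 0) || any(c(N, K, n, k) != floor(c(N, K, n, k)))) {
    stop("N, K, n, k must be nonnegative integers")
  }
  if (k > n) stop("k must not exceed the number of draws n")
  if (n > N) stop("n must not exceed the population size N")
  if (K > N) stop("K must not exceed the population size N")
  if (k > K) return(0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether |A intersect B| is larger than expected for two sets drawn
#' from a universe of the given size. The expected overlap is |A||B|/|U| and
#' the p-value is the hypergeometric upper tail at the observed overlap.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe_size Size of the universe both sets live in.
#' @return A list of class `overlap_test`: `size_a`, `size_b`, `universe`,
#'   `overlap`, `expected`, `p_upper`.
#' @seealso [overlap_stats()] to run the same test from printed counts alone.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  overlap_stats(length(set_a), length(set_b), universe_size,
                length(intersect(set_a, set_b)))
}

#' Overlap test from set sizes
#'
#' Same statistic as [overlap_test()] but computed from the four integers
#' (|A|, |B|, |U|, |A intersect B|), e.g. when reproducing published overlap
#' tables without the underlying gene lists.
#'
#' @param size_a,size_b Set sizes.
#' @param universe_size Universe size.
#' @param overlap Observed intersection size.
#' @return A list of class `overlap_test`; see [overlap_test()].
#' @export
overlap_stats <- function(size_a, size_b, universe_size, overlap) {
  if (size_a > universe_size || size_b > universe_size) {
    stop("set sizes must not exceed the universe size")
  }
  if (overlap > min(size_a, size_b)) {
    stop("overlap cannot exceed the smaller set size")
  }
  structure(list(size_a = size_a, size_b = size_b, universe = universe_size,
                 overlap = overlap,
                 expected = size_a * size_b / universe_size,
                 p_upper = hypergeom_upper_tail(universe_size, size_a,
                                                size_b, overlap)),
            class = "overlap_test")
}

#' @exportS3Method base::print
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap test: |A|=%d |B|=%d |U|=%d, observed %d, expected %.3g, P(X>=obs)=%.3g\n",
    x$size_a, x$size_b, x$universe, x$overlap, x$expected, x$p_upper))
  invisible(x)
}

#' Core-gene enrichment among a gene's interactors
#'
#' For a gene on the network, counts how many of its direct interactors belong
#' to a core gene set and computes the hypergeometric upper-tail probability of
#' observing that many: draws = the gene's degree, successes = core-set size,
#' population = interactome size. The tested gene is excluded from neither
#' the population nor the success count.
#'
#' @param net An `interactome`.
#' @param gene Gene identifier on the network.
#' @param core Character vector of core genes.
#' @return A list of class `neighbor_enrichment`: `gene`, `n_interactors`,
#'   `n_core_interactors`, `core_size`, `universe`, `p_upper`.
#' @export
neighbor_enrichment <- function(net, gene, core) {
  nb <- interactors(net, gene)  # errors on unknown gene
  core <- unique(as.character(core))
  k <- length(intersect(nb, core))
  structure(list(gene = gene,
                 n_interactors = length(nb),
                 n_core_interactors = k,
                 core_size = length(core),
                 universe = length(net$nodes),
                 p_upper = hypergeom_upper_tail(length(net$nodes),
                                                length(core), length(nb), k)),
            class = "neighbor_enrichment")
}

#' @exportS3Method base::print
print.neighbor_enrichment <- function(x, ...) {
  cat(sprintf(
    "%s: |I|=%d, |Ic|=%d of %d core genes (N=%d), P(X>=|Ic|)=%.3g\n",
    x$gene, x$n_interactors, x$n_core_interactors, x$core_size, x$universe,
    x$p_upper))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Benjamini--Hochberg step-up adjustment (the default), yielding q-values;
#' a strict Bonferroni option is also available.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = method)
}
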