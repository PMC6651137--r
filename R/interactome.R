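#' Read a STRING-style edge list into an interactome
#'
#' Parses a tab-separated edge list with columns (nodeA, nodeB, score), where
#' the score is an integer confidence on the STRING scale (0--1000). Duplicate
#' unordered pairs are collapsed to the record with the highest score before
#' the confidence threshold is applied; self-loops are dropped. The node set is
#' the set of endpoints of retained edges.
#'
#' @param path Path to a TSV file with three columns: two gene identifiers and
#'   an integer confidence score. A header line is detected automatically when
#'   the third field of the first line is not numeric.
#' @param min_score Minimum confidence score (inclusive) for an edge to be
#'   retained, in \[0, 1000\]. Default 700, the usual "high confidence" cutoff.
#' @return An object of class `interactome`; see [as_interactome()].
#' @export
read_edge_list <- function(path, min_score = 700) {
  stopifnot(length(path) == 1L, is.character(path))
  if (!file.exists(path)) stop("edge list file not found: ", path)
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1000) {
    stop("min_score must be a number in [0, 1000]")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty edge list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- 1L
  # a non-numeric third field on line 1 marks a header — unless there is
  # nothing after it, in which case the line itself is malformed
  if (suppressWarnings(is.na(as.numeric(parts[[1L]][3L])))) {
    if (length(parts) == 1L) stop("malformed edge list line 1: non-numeric score")
    first <- 2L
  }
  n_fields <- lengths(parts)
  bad <- which(n_fields[seq(first, length(parts))] < 3L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", bad[1L] + first - 1L,
         ": expected at least 3 tab-separated fields")
  }
  rows <- parts[seq(first, length(parts))]
  from <- vapply(rows, `[[`, character(1), 1L)
  to <- vapply(rows, `[[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
  if (anyNA(score)) {
    stop("malformed edge list line ", which(is.na(score))[1L] + first - 1L,
         ": non-numeric score")
  }
  as_interactome(data.frame(from = from, to = to, score = score,
                            stringsAsFactors = FALSE),
                 min_score = min_score)
}

#' Build an interactome from an edge data frame
#'
#' Applies the cleaning rules shared with [read_edge_list()]: self-loops are
#' removed, duplicate unordered pairs keep the highest score, and edges below
#' `min_score` are dropped after the collapse. The result stores the edges, the
#' sparse symmetric 0/1 adjacency matrix and per-node degrees. Edge scores are
#' used for thresholding only; downstream diffusion runs on the unweighted
#' adjacency.
#'
#' @param edges A data frame with columns `from`, `to`, `score`.
#' @param min_score Minimum retained confidence score.
#' @param nodes Optional character vector of additional node identifiers to
#'   retain even when no retained edge touches them (isolated nodes get an
#'   all-zero adjacency row and degree 0), keeping gene indexing stable across
#'   data layers.
#' @return A list of class `interactome` with elements `nodes` (sorted
#'   character vector), `edges` (data frame, canonical order with
#'   `from < to`), `A` (sparse symmetric `Matrix` of 0/1 with dimnames),
#'   `degree` (named integer vector), `min_score`.
#' @export
as_interactome <- function(edges, min_score = 0, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "score") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  score <- as.numeric(edges$score)
  keep <- from != to
  from <- from[keep]; to <- to[keep]; score <- score[keep]
  # canonical unordered orientation, then collapse duplicates keeping max score
  a <- pmin(from, to)
  b <- pmax(from, to)
  o <- order(a, b, -score)
  a <- a[o]; b <- b[o]; score <- score[o]
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]; b <- b[!dup]; score <- score[!dup]
  keep <- score >= min_score
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  if (length(a) == 0L) {
    stop("empty network: no edge passed the score threshold (min_score = ",
         min_score, ")")
  }
  nodes <- sort(unique(c(a, b, as.character(nodes))))
  i <- match(a, nodes)
  j <- match(b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  A <- methods::as(A, "CsparseMatrix")
  deg <- Matrix::rowSums(A)
  structure(list(nodes = nodes,
                 edges = data.frame(from = a, to = b, score = score,
                                    stringsAsFactors = FALSE),
                 A = A,
                 degree = stats::setNames(as.integer(deg), nodes),
                 min_score = min_score),
            class = "interactome")
}

#' @exportS3Method base::print
print.interactome <- function(x, ...) {
  cat("interactome:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(score >= %s)\n", format(x$min_score)))
  invisible(x)
}

#' Symmetrically normalized adjacency operator
#'
#' Computes W = D^(-1/2) A D^(-1/2) with D = diag(degree). Rows and columns of
#' isolated nodes are zero. W is symmetric, entrywise in \[0, 1\], and its
#' spectral radius is at most 1, so the diffusion update contracts for any
#' restart weight below 1.
#'
#' @param net An `interactome`.
#' @return A sparse symmetric `Matrix` with the same dimnames as `net$A`.
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "interactome"))
  d <- net$degree
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Di <- Matrix::Diagonal(x = inv)
  W <- Di %*% net$A %*% Di
  W <- Matrix::forceSymmetric(W)
  dimnames(W) <- dimnames(net$A)
  W
}

#' Direct neighbors of a gene
#'
#' @param net An `interactome`.
#' @param gene A gene identifier present in the network.
#' @return Sorted character vector of neighbor identifiers (empty for an
#'   isolated node).
#' @export
interactors <- function(net, gene) {
  stopifnot(inherits(net, "interactome"), length(gene) == 1L)
  idx <- match(gene, net$nodes)
  if (is.na(idx)) stop("unknown gene: ", gene)
  sort(net$nodes[which(net$A[idx, ] > 0)])
}

#' Write an interactome as a sorted TSV edge list
#'
#' The canonical serialization: one line per unordered edge, endpoints in
#' lexicographic order, sorted by (from, to), with a header. Re-loading the
#' file with [read_edge_list()] reproduces the same edge set.
#'
#' @param net An `interactome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  e <- net$edges[order(net$edges$from, net$edges$to), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
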