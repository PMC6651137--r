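#' Construct an evidence layer
#'
#' An evidence layer is one omics source (e.g. genomics, epigenomics,
#' transcriptomics) contributing a major-tier and a minor-tier gene set. A gene
#' listed in both tiers is kept as major.
#'
#' @param name Layer name (single string).
#' @param major,minor Character vectors of gene identifiers.
#' @return A list of class `evidence_layer` with elements `name`, `major`,
#'   `minor` (both sorted, disjoint).
#' @export
evidence_layer <- function(name, major = character(), minor = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  major <- sort(unique(as.character(major)))
  minor <- sort(unique(as.character(minor)))
  minor <- setdiff(minor, major)  # major wins
  structure(list(name = name, major = major, minor = minor),
            class = "evidence_layer")
}

#' @exportS3Method base::print
print.evidence_layer <- function(x, ...) {
  cat(sprintf("evidence layer '%s': %d major, %d minor genes\n",
              x$name, length(x$major), length(x$minor)))
  invisible(x)
}

#' Read tiered gene lists from a TSV file
#'
#' Expects columns (gene, layer, tier) with tier in \{major, minor\}. One
#' [evidence_layer()] is returned per distinct layer name; duplicated entries
#' are collapsed and a gene appearing with both tiers in the same layer is kept
#' as major.
#'
#' @param path TSV file path. A header line is detected when the third field of
#'   the first line is "tier" (case-insensitive).
#' @param layer_order Optional character vector fixing the order of the
#'   returned layers; defaults to first appearance in the file.
#' @return Named list of `evidence_layer` objects.
#' @export
read_gene_lists <- function(path, layer_order = NULL) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(parts[[1L]][3L] %||% "") == "tier") parts <- parts[-1L]
  if (length(parts) == 0L) stop("gene list file contains only a header: ", path)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop("malformed gene list line ", bad[1L],
         ": expected 3 tab-separated fields (gene, layer, tier)")
  }
  gene <- vapply(parts, `[[`, character(1), 1L)
  layer <- vapply(parts, `[[`, character(1), 2L)
  tier <- tolower(vapply(parts, `[[`, character(1), 3L))
  bad_tier <- setdiff(unique(tier), c("major", "minor"))
  if (length(bad_tier) > 0L) {
    stop("unknown tier value(s): ", paste(bad_tier, collapse = ", "),
         " (expected 'major' or 'minor')")
  }
  if (is.null(layer_order)) layer_order <- unique(layer)
  missing_layers <- setdiff(unique(layer), layer_order)
  if (length(missing_layers) > 0L) {
    stop("layers present in file but not in layer_order: ",
         paste(missing_layers, collapse = ", "))
  }
  out <- lapply(layer_order, function(l) {
    evidence_layer(l,
                   major = gene[layer == l & tier == "major"],
                   minor = gene[layer == l & tier == "minor"])
  })
  stats::setNames(out, layer_order)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write tiered gene lists to a TSV file
#'
#' Inverse of [read_gene_lists()]: one row per (gene, layer, tier), with a
#' header.
#'
#' @param layers List of `evidence_layer` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(layers, path) {
  rows <- do.call(rbind, lapply(layers, function(l) {
    rbind(
      if (length(l$major)) data.frame(gene = l$major, layer = l$name,
                                      tier = "major") else NULL,
      if (length(l$minor)) data.frame(gene = l$minor, layer = l$name,
                                      tier = "minor") else NULL
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict evidence layers to network genes
#'
#' Drops genes that do not occur in the interactome and reports initial vs
#' selected counts per layer and tier (the usual "Initial/Selected" bookkeeping
#' when external gene lists meet a high-confidence interactome).
#'
#' @param layers List of `evidence_layer` objects.
#' @param net An `interactome`.
#' @return A list with `layers` (restricted evidence layers, same order) and
#'   `report` (data frame: layer, tier, initial, selected).
#' @export
restrict_to_network <- function(layers, net) {
  stopifnot(inherits(net, "interactome"))
  layers <- as_layer_list(layers)
  restricted <- lapply(layers, function(l) {
    evidence_layer(l$name,
                   major = intersect(l$major, net$nodes),
                   minor = intersect(l$minor, net$nodes))
  })
  report <- do.call(rbind, lapply(seq_along(layers), function(i) {
    data.frame(layer = layers[[i]]$name,
               tier = c("major", "minor"),
               initial = c(length(layers[[i]]$major), length(layers[[i]]$minor)),
               selected = c(length(restricted[[i]]$major),
                            length(restricted[[i]]$minor)))
  }))
  list(layers = restricted, report = report)
}

as_layer_list <- function(layers) {
  if (inherits(layers, "evidence_layer")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "evidence_layer")))
  stats::setNames(layers, vapply(layers, `[[`, character(1), "name"))
}

#' Build the diffusion input matrix X0
#'
#' Encodes the tiered evidence as a genes-by-layers matrix with entries 1
#' (major), 0.5 (minor) and 0 (no evidence). Row order follows the interactome
#' node order so the matrix is conformable with the normalized adjacency
#' operator; column order follows the order of `layers`.
#'
#' @param layers List of `evidence_layer` objects, already restricted to the
#'   network (off-network genes are an error).
#' @param net An `interactome`.
#' @return A numeric matrix with rownames `net$nodes` and one column per layer.
#' @export
build_matrix <- function(layers, net) {
  stopifnot(inherits(net, "interactome"))
  layers <- as_layer_list(layers)
  off <- unlist(lapply(layers, function(l) setdiff(c(l$major, l$minor), net$nodes)))
  if (length(off) > 0L) {
    stop("genes not on the network (run restrict_to_network first): ",
         paste(utils::head(unique(off), 5L), collapse = ", "))
  }
  X0 <- matrix(0, nrow = length(net$nodes), ncol = length(layers),
               dimnames = list(net$nodes, names(layers)))
  for (j in seq_along(layers)) {
    X0[match(layers[[j]]$major, net$nodes), j] <- 1
    X0[match(layers[[j]]$minor, net$nodes), j] <- 0.5
  }
  X0
}
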