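#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' the package defaults filled in. Any subset of fields may be overridden by
#' the caller or by a YAML config file.
#'
#' @param ... Named overrides of the default fields.
#' @return Named list: `edges`, `gene_lists`, `gmt` (optional paths),
#'   `out_dir`, `min_score`, `layer_order`, `alpha`, `tol`, `n_perm`,
#'   `statistic`, `m`, `k_grid`, `R`, `alpha_nr`, `k_rule`, `resampling_null`,
#'   `community_methods`, `universe`, `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(edges = NULL, gene_lists = NULL, gmt = NULL, out_dir = NULL,
              min_score = 700, layer_order = NULL,
              alpha = 0.7, tol = 1e-6, n_perm = 1000L, statistic = "d", m = 3L,
              k_grid = seq(25L, 500L, by = 25L), R = 999L, alpha_nr = 0.01,
              k_rule = "min_p", resampling_null = "degree_matched",
              community_methods = names(community_methods),
              universe = "interactome", seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Run the full prioritization pipeline
#'
#' Orchestrates every stage from one configuration: load and threshold the
#' edge list, read and restrict the tiered gene lists, build the evidence
#' matrix, diffuse and score, rank, scan module sizes by network resampling,
#' extract the significantly connected module, partition its largest connected
#' component, and compute evidence-type (and, when a GMT is given, pathway)
#' enrichments. All stage outputs are written as TSVs under `out_dir` together
#' with a manifest listing every file with its MD5 hash, the seed, and the
#' parameter echo; re-running the same configuration is bit-identical.
#'
#' @param config A configuration list (see [default_config()]) or the path to
#'   a YAML file holding one.
#' @param ... Named overrides applied on top of `config`.
#' @return A result bundle (list of class `ndprio_pipeline`): `net`, `layers`,
#'   `report`, `X0`, `diffusion`, `ranking`, `resampling`, `module`, `lcc`,
#'   `partitions`, `best`, `evidence_ratios`, `pathways` (or NULL), `config`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  config <- utils::modifyList(config, list(...))
  if (is.null(config$edges) || is.null(config$gene_lists)) {
    stop("config must provide 'edges' and 'gene_lists' paths")
  }
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    message(sprintf("[ndprio] %-18s ...", name), appendLF = FALSE)
    t <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf(" %.1fs", proc.time()[["elapsed"]] - t))
    out
  }

  net <- stage("load", read_edge_list(config$edges, config$min_score))
  raw_layers <- stage("layers", read_gene_lists(config$gene_lists,
                                                config$layer_order))
  restricted <- restrict_to_network(raw_layers, net)
  X0 <- build_matrix(restricted$layers, net)
  diff_res <- stage("diffusion", network_diffusion(
    net, X0, alpha = config$alpha, n_perm = config$n_perm,
    seed = if (config$n_perm > 0) config$seed else NULL,
    statistic = config$statistic, m = config$m, tol = config$tol))
  ranking <- rank_genes(diff_res)
  k_grid <- config$k_grid[config$k_grid <= length(ranking)]
  if (length(k_grid) == 0L) stop("k_grid entirely exceeds the network size")
  resampling <- stage("resampling", network_resampling(
    net, ranking, k_grid = k_grid, R = config$R,
    seed = config$seed + 1L, null = config$resampling_null))
  module <- extract_module(net, ranking, resampling, config$alpha_nr,
                           rule = config$k_rule)
  lcc <- largest_component(module)

  partitions <- NULL; best <- NULL; evidence_ratios <- NULL; pathways <- NULL
  if (length(lcc) >= 4L) {
    g <- induced_graph(net, lcc)
    partitions <- stage("communities", detect_communities(
      g, config$community_methods, seed = config$seed + 2L))
    best <- best_partition(partitions)
    support <- lapply(restricted$layers, function(l) c(l$major, l$minor))
    clusters <- split(names(best$membership), best$membership)
    evidence_ratios <- do.call(rbind, lapply(names(clusters), function(cl) {
      data.frame(cluster = cl, layer = names(support),
                 ratio = vapply(support, function(s) {
                   evidence_enrichment(clusters[[cl]], s, module$genes)
                 }, numeric(1)), row.names = NULL)
    }))
    if (!is.null(config$gmt)) {
      sets <- read_gmt(config$gmt)
      universe <- if (identical(config$universe, "interactome")) {
        length(net$nodes)
      } else {
        config$universe
      }
      pathways <- stage("enrichment", pathway_enrichment(best, sets, universe))
    }
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_pipeline_outputs(
      config$out_dir, net, restricted, diff_res, ranking, resampling, module,
      lcc, best, evidence_ratios, pathways, config)
  }
  message(sprintf("[ndprio] pipeline done in %.1fs",
                  proc.time()[["elapsed"]] - t0))
  structure(list(net = net, layers = restricted$layers,
                 report = restricted$report, X0 = X0, diffusion = diff_res,
                 ranking = ranking, resampling = resampling, module = module,
                 lcc = lcc, partitions = partitions, best = best,
                 evidence_ratios = evidence_ratios, pathways = pathways,
                 config = config, manifest = manifest),
            class = "ndprio_pipeline")
}

#' @exportS3Method base::print
print.ndprio_pipeline <- function(x, ...) {
  cat("ndprio pipeline result\n")
  print(x$net)
  print(x$module)
  if (!is.null(x$best)) print(x$best)
  invisible(x)
}

write_pipeline_outputs <- function(out_dir, net, restricted, diff_res, ranking,
                                   resampling, module, lcc, best,
                                   evidence_ratios, pathways, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  scores <- data.frame(gene = diff_res$genes,
                       diff_res$Xss, check.names = FALSE)
  names(scores)[-1L] <- paste0("xss_", colnames(diff_res$Xss))
  xs <- diff_res$Xstar; colnames(xs) <- paste0("xstar_", colnames(xs))
  ys <- diff_res$Y; colnames(ys) <- paste0("y_", colnames(ys))
  scores <- cbind(scores, xs, ys, d = diff_res$d)
  if (!is.null(diff_res$p)) scores$p <- diff_res$p
  scores$rank <- match(scores$gene, ranking)
  paths <- c(
    edges = wtsv(net$edges[order(net$edges$from, net$edges$to), ], "network.tsv"),
    report = wtsv(restricted$report, "layer_report.tsv"),
    scores = wtsv(scores[order(scores$rank), ], "scores.tsv"),
    resampling = wtsv(as.data.frame(resampling), "resampling.tsv"),
    module = wtsv(data.frame(gene = module$genes,
                             rank = seq_along(module$genes),
                             in_lcc = module$genes %in% lcc), "module.tsv"),
    module_edges = wtsv(module$edges, "module_edges.tsv"))
  if (!is.null(best)) {
    paths <- c(paths, partition = wtsv(
      data.frame(gene = names(best$membership), cluster = best$membership),
      "partition.tsv"))
  }
  if (!is.null(evidence_ratios)) {
    paths <- c(paths, evidence = wtsv(evidence_ratios, "evidence_ratios.tsv"))
  }
  if (!is.null(pathways)) {
    paths <- c(paths, pathways = wtsv(pathways, "pathway_enrichment.tsv"))
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         bytes = unname(file.size(paths)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  echo <- config[!vapply(config, is.null, logical(1))]
  echo$k_grid <- paste(echo$k_grid, collapse = ",")
  echo$community_methods <- paste(echo$community_methods, collapse = ",")
  yaml::write_yaml(c(list(package = "ndprio",
                          version = as.character(utils::packageVersion("ndprio")),
                          r_version = as.character(getRversion())),
                     echo),
                   file.path(out_dir, "run_config.yaml"))
  manifest
}
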