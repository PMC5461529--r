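#' Node degrees of an epistasis network
#'
#' @param net An `epinet`.
#' @param include_isolated Include nodes without edges (degree 0)?
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(net, include_isolated = TRUE) {
  stopifnot(inherits(net, "epinet"))
  deg <- table(factor(c(net$edges$node_a, net$edges$node_b),
                      levels = net$nodes))
  deg <- setNames(as.integer(deg), names(deg))
  if (!include_isolated) deg <- deg[deg > 0L]
  deg
}

#' Scale-free fit of the degree distribution
#'
#' Measures how well the empirical degree distribution follows a power law:
#' the R-squared of the ordinary least-squares line of `log10 P(k)` on
#' `log10 k` over observed degrees `k >= 1` with positive frequency, where
#' `P(k)` is the fraction of non-isolated nodes with degree `k`. No
#' binning and no maximum-likelihood exponent fit are applied. Values near
#' 1 indicate a scale-free topology.
#'
#' @param net An `epinet` with at least two distinct observed degrees.
#' @return R-squared in `[0, 1]`.
#' @export
scale_free_r2 <- function(net) {
  deg <- node_degrees(net, include_isolated = FALSE)
  r2_from_degrees(deg)
}

r2_from_degrees <- function(deg) {
  deg <- deg[deg >= 1L]
  tab <- table(deg)
  if (length(tab) < 2L) {
    stop_epigain("degree distribution is degenerate (fewer than two distinct degrees); scale-free fit not assessable",
                 "epigain_error_degenerate")
  }
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  fit <- lm(log10(pk) ~ log10(k))
  # summary.lm warns on an exactly collinear ("perfect") fit; R^2 = 1 there
  suppressWarnings(summary(fit)$r.squared)
}

#' Connected components among non-isolated nodes
#'
#' @param net An `epinet`.
#' @return Number of connected components; 0 for an edgeless network.
#' @export
count_components <- function(net) {
  stopifnot(inherits(net, "epinet"))
  if (nrow(net$edges) == 0L) return(0L)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  igraph::components(g)$no
}

#' Hypergeometric enrichment of network genes in a ground-truth set
#'
#' Upper-tail probability `P(K >= k)` of drawing at least `k` ground-truth
#' genes when `n = |network genes|` genes are drawn without replacement
#' from a universe of `N` genes containing `M = |ground truth within the
#' universe|` successes.
#'
#' @param network_genes Character vector of genes in the network (must lie
#'   within `universe`).
#' @param ground_truth Character vector of known disease genes.
#' @param universe Character vector of all candidate genes (typically every
#'   gene in the post-QC [snp_gene_map()]).
#' @return p-value in `(0, 1]`.
#' @export
enrichment_pvalue <- function(network_genes, ground_truth, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop_epigain("empty universe", "epigain_error_validation")
  }
  network_genes <- unique(as.character(network_genes))
  if (!all(network_genes %in% universe)) {
    stop_epigain("network genes must be a subset of the universe",
                 "epigain_error_validation")
  }
  M <- length(intersect(ground_truth, universe))
  N <- length(universe)
  n <- length(network_genes)
  k <- length(intersect(network_genes, ground_truth))
  phyper(k - 1L, M, N - M, n, lower.tail = FALSE)
}

#' AUC of network nodes against a ground-truth gene set
#'
#' Every universe gene is scored by its degree in the network (0 when
#' absent) and the ranking is scored against ground-truth membership with
#' the mid-rank (Mann-Whitney) formula, so an edgeless network scores 0.5.
#'
#' @inheritParams enrichment_pvalue
#' @param net A gene-level `epinet`.
#' @return AUC in `[0, 1]`.
#' @export
node_auc <- function(net, ground_truth, universe) {
  stopifnot(inherits(net, "epinet"))
  universe <- unique(as.character(universe))
  scores <- setNames(numeric(length(universe)), universe)
  deg <- node_degrees(net)
  deg <- deg[names(deg) %in% universe]
  scores[names(deg)] <- deg
  pos <- universe %in% ground_truth
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop_epigain("ground truth must cover part, not none or all, of the universe",
                 "epigain_error_validation")
  }
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Correlation between gene-network degree and gene size
#'
#' Diagnostic for gene-size bias: Pearson correlation between each network
#' gene's degree and its size (mapped-SNP count). Count-based aggregation
#' of SNP networks inflates the degree of long genes; maximum aggregation
#' is designed to avoid this, driving the correlation toward zero.
#'
#' @param net A gene-level `epinet` with at least three genes.
#' @param map A [snp_gene_map()].
#' @return Pearson correlation coefficient.
#' @export
degree_size_correlation <- function(net, map) {
  stopifnot(inherits(net, "epinet"), inherits(map, "snp_gene_map"))
  deg <- node_degrees(net)
  if (length(deg) < 3L) {
    stop_epigain("need at least three network genes",
                 "epigain_error_validation")
  }
  size <- map$gene_size$n_snps[match(names(deg), map$gene_size$gene_id)]
  if (anyNA(size)) {
    stop_epigain("network genes missing from the gene map",
                 "epigain_error_validation")
  }
  if (stats::sd(deg) == 0 || stats::sd(size) == 0) {
    stop_epigain("degree or gene size has zero variance; correlation undefined",
                 "epigain_error_degenerate")
  }
  cor(deg, size)
}

#' Topology summary of one thresholded network
#'
#' @param net An `epinet`.
#' @param ground_truth,universe Optional gene sets for enrichment and AUC.
#' @return One-row tibble: `nodes`, `edges`, `components`, `r2`, `auc`,
#'   `p_value` (`NA` where not assessable or not requested).
#' @export
topology_report <- function(net, ground_truth = NULL, universe = NULL) {
  r2 <- tryCatch(scale_free_r2(net),
                 epigain_error_degenerate = function(e) NA_real_)
  auc <- NA_real_
  p <- NA_real_
  if (!is.null(ground_truth) && !is.null(universe)) {
    auc <- node_auc(net, ground_truth, universe)
    p <- enrichment_pvalue(intersect(net$nodes, universe), ground_truth,
                           universe)
  }
  tibble(nodes = n_nodes(net), edges = n_edges(net),
         components = count_components(net), r2 = r2, auc = auc,
         p_value = p)
}

#' Scan sparsity thresholds and summarise network topology
#'
#' Runs the full construction once (SNP network, gene aggregation,
#' permutation threshold unless one is supplied), then thresholds the gene
#' network at `theta * (1 + alpha)` for every `alpha` in the grid and
#' reports, per row: node, edge and component counts, the scale-free
#' R-squared, and — when a ground truth is given — node AUC and
#' hypergeometric enrichment p-value. Rows whose `r2` is a local maximum
#' along the grid are flagged in `r2_local_max` as a selection aid; the
#' function never picks a threshold itself.
#'
#' @inheritParams permutation_threshold
#' @param spec Optional precomputed `threshold_spec`; computed from `ds`
#'   when `NULL`.
#' @param alpha_grid Numeric vector of sparsity multipliers (the
#'   convention is steps of 0.1).
#' @param ground_truth Optional character vector of known disease genes.
#' @param universe Optional gene universe; defaults to all genes of `map`.
#' @return A tibble of class `epigain_scan` with one row per `alpha`.
#' @export
alpha_scan <- function(ds, map, measure = c("mi", "ig"), aggregator = "max",
                       spec = NULL, alpha_grid = seq(0, 5, by = 0.1),
                       ground_truth = NULL, universe = NULL,
                       n_permutations = 30L, seed = 1L, snp_cutoff = NULL) {
  measure <- match.arg(measure)
  if (length(alpha_grid) == 0L) {
    stop_epigain("`alpha_grid` must be non-empty", "epigain_error_validation")
  }
  snp_net <- build_snp_network(ds, measure)
  gene_net <- convert_to_gene_network(snp_net, map, aggregator,
                                      snp_cutoff = snp_cutoff)
  if (is.null(spec)) {
    spec <- permutation_threshold(ds, map, measure, aggregator,
                                  n_permutations, seed, snp_cutoff)
  }
  scan_gene_network(gene_net, spec, alpha_grid, ground_truth,
                    universe %||% map$gene_size$gene_id)
}

#' @rdname alpha_scan
#' @param net A gene-level `epinet` to threshold directly.
#' @export
scan_gene_network <- function(net, spec, alpha_grid,
                              ground_truth = NULL, universe = NULL) {
  rows <- purrr::map(alpha_grid, function(a) {
    thr <- apply_threshold(net, spec, alpha = a)
    dplyr::bind_cols(tibble(alpha = a),
                     topology_report(thr, ground_truth, universe))
  })
  out <- dplyr::bind_rows(rows)
  out$r2_local_max <- local_maxima(out$r2)
  class(out) <- c("epigain_scan", class(out))
  out
}

# flag interior (or boundary) local maxima of a possibly-NA sequence
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(logical(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1L], -Inf)
  !is.na(x) & x >= ifelse(is.na(left), -Inf, left) &
    x >= ifelse(is.na(right), -Inf, right)
}

#' Write an alpha-scan table as TSV
#'
#' Columns: `alpha`, `nodes`, `edges`, `components`, `r2`, `auc`,
#' `p_value`, `r2_local_max`.
#'
#' @param scan A tibble from [alpha_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  readr::write_tsv(scan, path, na = "NA", progress = FALSE)
  invisible(path)
}
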