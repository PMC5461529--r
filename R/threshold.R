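#' Permutation-derived network threshold
#'
#' Estimates the base significance threshold `theta` for a gene-gene
#' interaction network. The disease labels are permuted `n_permutations`
#' times (default 30); under each permutation the full pipeline is re-run
#' (all SNP-pair weights recomputed, then aggregated to gene level), each
#' gene edge's permuted weights are averaged over the replicates, and
#' `theta` is the maximum of these per-edge averages. One permuted label
#' vector per replicate is shared across all edges, which keeps the null
#' exchangeable and the result reproducible. Edges of the observed network
#' with weight above `theta * (1 + alpha)` are then deemed significant (see
#' [apply_threshold()]).
#'
#' @param ds A fully imputed, QC-filtered [genotype_dataset()].
#' @param map A [snp_gene_map()].
#' @param measure `"mi"` or `"ig"`.
#' @param aggregator Gene aggregation rule, see [convert_to_gene_network()].
#' @param n_permutations Number of label permutations (default 30).
#' @param seed Integer seed generating the permutations.
#' @param snp_cutoff SNP-level cutoff, only for `aggregator =
#'   "count_above"`.
#' @return An object of class `threshold_spec` with elements `theta`,
#'   `measure`, `aggregator`, `n_permutations`, `seed`, `permutations` (one
#'   permuted label vector per row) and `edge_means` (tibble of per-edge
#'   permutation means).
#' @export
permutation_threshold <- function(ds, map, measure = c("mi", "ig"),
                                  aggregator = "max",
                                  n_permutations = 30L, seed = 1L,
                                  snp_cutoff = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(ds, "genotype_dataset"), inherits(map, "snp_gene_map"))
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop_epigain("`n_permutations` must be a positive integer",
                 "epigain_error_validation")
  }
  if (aggregator == "count_above" && !is_scalar_number(snp_cutoff)) {
    stop_epigain("aggregator \"count_above\" needs a numeric `snp_cutoff`",
                 "epigain_error_validation")
  }
  gene <- gene_for_snp(map, snp_ids(ds))
  keep <- !is.na(gene)
  if (sum(keep) < 2L || length(unique(gene[keep])) < 2L) {
    stop_epigain("need SNPs mapped to at least two genes",
                 "epigain_error_validation")
  }
  G <- ds$genotypes[, keep, drop = FALSE]
  gene <- gene[keep]
  y <- unname(ds$phenotype)
  perms <- local_seed(seed, t(replicate(n_permutations, sample(y))))
  acc <- 0
  for (r in seq_len(n_permutations)) {
    W <- pair_weight_matrix(G, perms[r, ], measure)
    acc <- acc + aggregate_gene_matrix(W, gene, aggregator, snp_cutoff)
  }
  mean_mat <- acc / n_permutations
  ut <- which(upper.tri(mean_mat) & !is.na(mean_mat), arr.ind = TRUE)
  genes <- rownames(mean_mat)
  edge_means <- tibble(
    node_a = genes[ut[, 1L]],
    node_b = genes[ut[, 2L]],
    mean_weight = mean_mat[ut]
  )
  structure(
    list(theta = max(edge_means$mean_weight), measure = measure,
         aggregator = aggregator, n_permutations = n_permutations,
         seed = as.integer(seed), permutations = perms,
         edge_means = edge_means),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "<threshold_spec> theta = %.6g bits (%s, %s aggregation, %d permutations, seed %d)\n",
    x$theta, x$measure, x$aggregator, x$n_permutations, x$seed
  ))
  invisible(x)
}

#' Apply a sparsity-controlled significance threshold
#'
#' Retains the edges of a gene network whose weight is strictly greater
#' than `theta * (1 + alpha)` and drops nodes left isolated. `alpha`
#' controls sparsity: the base permutation threshold at `alpha = 0` can
#' still leave a huge number of edges, and scanning `alpha` upward (the
#' convention is steps of 0.1) shrinks the network monotonically; see
#' [alpha_scan()].
#'
#' @param net A gene-level `epinet`.
#' @param spec A `threshold_spec` from [permutation_threshold()] (its
#'   measure must match the network's), or a bare numeric `theta`.
#' @param alpha Non-negative sparsity multiplier.
#' @return A thresholded `epinet`; the applied `theta` and `alpha` are kept
#'   in attribute `"threshold"`.
#' @export
apply_threshold <- function(net, spec, alpha = 0) {
  stopifnot(inherits(net, "epinet"), is_scalar_number(alpha), alpha >= 0)
  if (inherits(spec, "threshold_spec")) {
    if (!identical(spec$measure, net$measure)) {
      stop_epigain(sprintf(
        "threshold was computed for measure \"%s\" but the network is \"%s\"",
        spec$measure, net$measure), "epigain_error_validation")
    }
    theta <- spec$theta
  } else {
    stopifnot(is_scalar_number(spec))
    theta <- spec
  }
  cutoff <- theta * (1 + alpha)
  edges <- net$edges[net$edges$weight > cutoff, , drop = FALSE]
  out <- as_epinet(edges, nodes = sort(unique(c(edges$node_a, edges$node_b))),
                   level = net$level, measure = net$measure)
  attr(out, "aggregator") <- attr(net, "aggregator")
  attr(out, "threshold") <- list(theta = theta, alpha = alpha)
  out
}
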