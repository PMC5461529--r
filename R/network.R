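#' Epistasis networks
#'
#' An `epinet` is a weighted undirected network whose nodes are SNPs or
#' genes and whose edge weights are disease-association strengths in bits.
#' Edges live in a tibble with columns `node_a`, `node_b`, `weight` (plus
#' provenance columns where applicable); node pairs are stored in a
#' canonical order with no self-loops.
#'
#' @param edges Tibble with columns `node_a`, `node_b`, `weight`.
#' @param nodes Character vector of node identifiers (may include isolated
#'   nodes).
#' @param level `"snp"` or `"gene"`.
#' @param measure `"mi"`, `"ig"`, or `"union"` for integrated networks.
#' @return An object of class `epinet`.
#' @export
as_epinet <- function(edges, nodes = NULL, level = "gene", measure = "mi") {
  edges <- as_tibble(edges)
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (any(edges$node_a == edges$node_b)) {
    stop_epigain("self-loops are not allowed", "epigain_error_validation")
  }
  flip <- edges$node_a > edges$node_b
  if (any(flip)) {
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
  }
  if (anyDuplicated(paste0(edges$node_a, "\r", edges$node_b))) {
    stop_epigain("duplicate edges for the same unordered node pair",
                 "epigain_error_validation")
  }
  nodes <- as.character(nodes %||% sort(unique(c(edges$node_a, edges$node_b))))
  structure(
    list(edges = edges, nodes = nodes,
         level = match.arg(level, c("snp", "gene")), measure = measure),
    class = "epinet"
  )
}

#' @export
print.epinet <- function(x, ...) {
  cat(sprintf("<epinet> level=%s measure=%s: %d nodes, %d edges\n",
              x$level, x$measure, length(x$nodes), nrow(x$edges)))
  if (!is.null(attr(x, "threshold"))) {
    th <- attr(x, "threshold")
    cat(sprintf("  thresholded at theta * (1 + alpha) = %.6g * (1 + %g)\n",
                th$theta, th$alpha))
  }
  invisible(x)
}

#' Number of edges / nodes in an epistasis network
#' @param net An `epinet`.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Build the SNP-pair epistasis network
#'
#' Computes the complete weighted graph over all `C(m, 2)` SNP pairs of a
#' fully imputed, QC-filtered dataset. The edge weight between SNPs `X1`
#' and `X2` is the association of the pair with the trait `Y`: mutual
#' information `I(X1, X2; Y)` (`measure = "mi"`) or information gain
#' `IG(X1; X2; Y)` (`measure = "ig"`; may be negative for redundant pairs).
#' Computation is chunked over column blocks so memory stays bounded for
#' thousands of SNPs.
#'
#' @param ds A [genotype_dataset()] with no missing genotypes.
#' @param measure `"mi"` or `"ig"`.
#' @return An `epinet` at SNP level.
#' @export
build_snp_network <- function(ds, measure = c("mi", "ig")) {
  measure <- match.arg(measure)
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_snps(ds) < 2L) {
    stop_epigain("need at least two SNPs to build a network",
                 "epigain_error_validation")
  }
  W <- pair_weight_matrix(ds$genotypes, ds$phenotype, measure)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  edges <- tibble(
    node_a = colnames(W)[ut[, 1L]],
    node_b = colnames(W)[ut[, 2L]],
    weight = W[ut]
  )
  as_epinet(edges, nodes = colnames(W), level = "snp", measure = measure)
}

# rebuild the symmetric weight matrix of a SNP-level epinet
snp_weight_matrix <- function(net, snps = net$nodes) {
  m <- length(snps)
  W <- matrix(NA_real_, m, m, dimnames = list(snps, snps))
  keep <- net$edges$node_a %in% snps & net$edges$node_b %in% snps
  e <- net$edges[keep, ]
  ia <- match(e$node_a, snps)
  ib <- match(e$node_b, snps)
  W[cbind(ia, ib)] <- e$weight
  W[cbind(ib, ia)] <- e$weight
  W
}

# column-wise maxima ignoring NA; all-NA columns give NA
col_maxima <- function(M) {
  if (nrow(M) == 1L) return(M[1L, ])
  suppressWarnings(do.call(pmax, c(asplit(M, 1L), list(na.rm = TRUE))))
}

# gene x gene aggregate of a SNP weight matrix; diagonal (intra-gene) is
# discarded by callers
aggregate_gene_matrix <- function(W, gene, aggregator, snp_cutoff = NULL) {
  genes <- sort(unique(gene))
  gidx <- split(seq_along(gene), gene)[genes]
  switch(
    aggregator,
    max = {
      m1 <- do.call(rbind, lapply(gidx, function(r)
        col_maxima(W[r, , drop = FALSE])))
      do.call(rbind, lapply(gidx, function(cset)
        col_maxima(t(m1[, cset, drop = FALSE]))))
    },
    min = -aggregate_gene_matrix(-W, gene, "max"),
    sum = {
      s <- rowsum(ifelse(is.na(W), 0, W), gene)
      t(rowsum(t(s), gene))
    },
    mean = {
      s <- rowsum(ifelse(is.na(W), 0, W), gene)
      s <- t(rowsum(t(s), gene))
      k <- rowsum((!is.na(W)) * 1, gene)
      k <- t(rowsum(t(k), gene))
      out <- s / k
      out[k == 0] <- NA_real_
      out
    },
    count_above = {
      ind <- (!is.na(W) & W > snp_cutoff) * 1
      s <- rowsum(ind, gene)
      t(rowsum(t(s), gene))
    }
  )
}

#' Convert a SNP epistasis network to a gene-gene interaction network
#'
#' Each unordered gene pair receives the aggregate of all SNP-pair weights
#' with one SNP in each gene; intra-gene SNP pairs are discarded. The
#' default aggregator takes the maximum, which is robust to gene size: a
#' long gene contributes its single strongest inter-gene SNP pair rather
#' than accumulating weight (or edge counts) with every mapped SNP.
#' `"count_above"` reproduces the count-based scheme used by earlier
#' SNP-network studies (number of SNP-pair edges above a SNP-level cutoff)
#' and exists mainly for the gene-size-bias diagnostic
#' ([degree_size_correlation()]). Under `"max"` the edge records which SNP
#' pair achieved the maximum (columns `snp_a`, `snp_b`).
#'
#' @param net A SNP-level `epinet` from [build_snp_network()].
#' @param map A [snp_gene_map()].
#' @param aggregator One of `"max"`, `"sum"`, `"mean"`, `"min"`,
#'   `"count_above"`.
#' @param snp_cutoff SNP-level weight cutoff, required for `"count_above"`.
#' @return An `epinet` at gene level.
#' @export
convert_to_gene_network <- function(net, map,
                                    aggregator = c("max", "sum", "mean",
                                                   "min", "count_above"),
                                    snp_cutoff = NULL) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(net, "epinet"), inherits(map, "snp_gene_map"))
  if (net$level != "snp") {
    stop_epigain("`net` must be a SNP-level network",
                 "epigain_error_validation")
  }
  if (aggregator == "count_above" && !is_scalar_number(snp_cutoff)) {
    stop_epigain("aggregator \"count_above\" needs a numeric `snp_cutoff`",
                 "epigain_error_validation")
  }
  gene <- gene_for_snp(map, net$nodes)
  mapped <- !is.na(gene)
  if (!all(mapped)) {
    inform(sprintf("%d of %d SNPs are not in the gene map; excluded",
                   sum(!mapped), length(mapped)))
  }
  snps <- net$nodes[mapped]
  gene <- gene[mapped]
  if (length(unique(gene)) < 2L) {
    stop_epigain("need SNPs mapped to at least two genes",
                 "epigain_error_validation")
  }
  W <- snp_weight_matrix(net, snps)
  A <- aggregate_gene_matrix(W, gene, aggregator, snp_cutoff)
  genes <- rownames(A)
  ut <- which(upper.tri(A) & !is.na(A), arr.ind = TRUE)
  edges <- tibble(
    node_a = genes[ut[, 1L]],
    node_b = genes[ut[, 2L]],
    weight = A[ut]
  )
  if (aggregator == "max" && nrow(edges) > 0L) {
    gidx <- split(seq_along(gene), gene)[genes]
    prov <- purrr::map2(ut[, 1L], ut[, 2L], function(i, j) {
      sub <- W[gidx[[i]], gidx[[j]], drop = FALSE]
      k <- arrayInd(which.max(sub), dim(sub))
      c(rownames(sub)[k[1L]], colnames(sub)[k[2L]])
    })
    edges$snp_a <- vapply(prov, `[`, character(1), 1L)
    edges$snp_b <- vapply(prov, `[`, character(1), 2L)
  }
  out <- as_epinet(edges, nodes = genes, level = "gene",
                   measure = net$measure)
  attr(out, "aggregator") <- aggregator
  out
}

#' Integrate thresholded MI and IG gene networks by union
#'
#' The node set is the union of node sets and the edge set the union of
#' edge sets. Each edge carries per-source weights (`weight_mi`,
#' `weight_ig`, `NA` where absent), a `source` tag in
#' `{"mi", "ig", "both"}`, and `weight` set to the larger available source
#' weight. The number of edges common to both inputs is reported in
#' `glance()` and stored as attribute `intersection_edges`.
#'
#' @param net_mi,net_ig Gene-level thresholded `epinet`s built with
#'   measures `"mi"` and `"ig"`.
#' @return A gene-level `epinet` with `measure = "union"`.
#' @export
integrate_networks <- function(net_mi, net_ig) {
  stopifnot(inherits(net_mi, "epinet"), inherits(net_ig, "epinet"))
  if (net_mi$level != "gene" || net_ig$level != "gene") {
    stop_epigain("both networks must be at gene level",
                 "epigain_error_validation")
  }
  e_mi <- dplyr::select(net_mi$edges, "node_a", "node_b", weight_mi = "weight")
  e_ig <- dplyr::select(net_ig$edges, "node_a", "node_b", weight_ig = "weight")
  edges <- dplyr::full_join(e_mi, e_ig, by = c("node_a", "node_b"))
  edges <- dplyr::mutate(
    edges,
    source = dplyr::case_when(
      !is.na(.data$weight_mi) & !is.na(.data$weight_ig) ~ "both",
      !is.na(.data$weight_mi) ~ "mi",
      TRUE ~ "ig"
    ),
    weight = pmax(.data$weight_mi, .data$weight_ig, na.rm = TRUE)
  )
  edges <- dplyr::relocate(edges, "weight", .after = "node_b")
  out <- as_epinet(edges, nodes = union(net_mi$nodes, net_ig$nodes),
                   level = "gene", measure = "union")
  attr(out, "intersection_edges") <- sum(edges$source == "both")
  out
}

#' Convert an epistasis network to an igraph graph
#'
#' @param net An `epinet`.
#' @return An undirected weighted [igraph::igraph] graph including isolated
#'   nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "epinet"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network for Cytoscape
#'
#' Writes an edge-list TSV, a SIF file (`node_a <measure> node_b`), or
#' GraphML.
#'
#' @param net An `epinet`.
#' @param path Output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  switch(
    format,
    tsv = readr::write_tsv(net$edges, path, na = "NA", progress = FALSE),
    sif = writeLines(
      paste(net$edges$node_a, net$measure, net$edges$node_b), path),
    graphml = igraph::write_graph(as_igraph(net), path, format = "graphml")
  )
  invisible(path)
}
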