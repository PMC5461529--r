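# Independent oracles: deliberately naive implementations (explicit loops,
# enumeration) kept free of the package's computational paths.

oracle_entropy <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c in counts) {
    if (c > 0) h <- h - (c / n) * log2(c / n)
  }
  h
}

# I(X;Y) by the double-sum definition sum p(x,y) log2(p(x,y)/(p(x)p(y)))
oracle_mi <- function(x, y) {
  n <- length(x)
  s <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy > 0) {
        s <- s + pxy * log2(pxy / ((sum(x == xv) / n) * (sum(y == yv) / n)))
      }
    }
  }
  s
}

oracle_mi_pair <- function(x1, x2, y) {
  oracle_mi(paste(x1, x2), y)
}

oracle_ig <- function(x1, x2, y) {
  oracle_mi_pair(x1, x2, y) - oracle_mi(x1, y) - oracle_mi(x2, y)
}

# connected-component count by breadth-first search over an edge tibble
oracle_components <- function(edges) {
  nodes <- unique(c(edges$node_a, edges$node_b))
  if (length(nodes) == 0L) return(0L)
  adj <- lapply(setNames(nm = nodes), function(v) {
    c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
  })
  seen <- character(0)
  comps <- 0L
  for (v in nodes) {
    if (v %in% seen) next
    comps <- comps + 1L
    queue <- v
    while (length(queue) > 0L) {
      u <- queue[1L]
      queue <- queue[-1L]
      if (u %in% seen) next
      seen <- c(seen, u)
      queue <- c(queue, setdiff(adj[[u]], seen))
    }
  }
  comps
}

# P(K >= k) by exhaustive enumeration of all C(N, n) draws
oracle_hypergeom_upper <- function(N, M, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d <= M) >= k)
  mean(hits)
}

# AUC as the Mann-Whitney pairwise-comparison count
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# random fully observed dataset (categories guaranteed valid, both classes)
make_dataset <- function(n, m, seed) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  y <- sample(0:1, n, replace = TRUE)
  y[1:2] <- 0:1
  genotype_dataset(g, phenotype = y)
}

# map assigning `m` SNP ids to genes with the given sizes
make_map <- function(snps, sizes) {
  stopifnot(sum(sizes) == length(snps))
  snp_gene_map(tibble::tibble(
    snp_id = snps,
    gene_id = rep(sprintf("g%02d", seq_along(sizes)), sizes)
  ))
}

epinet_from_igraph <- function(g, level = "gene", measure = "mi") {
  el <- igraph::as_edgelist(g)
  as_epinet(tibble::tibble(node_a = as.character(el[, 1L]),
                           node_b = as.character(el[, 2L]),
                           weight = 1),
            nodes = as.character(igraph::V(g)$name %||%
                                   seq_len(igraph::vcount(g))),
            level = level, measure = measure)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
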