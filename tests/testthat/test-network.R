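test_that("the SNP network is the complete weighted graph over pairs", {
  ds <- make_dataset(20, 3, seed = 1)
  net <- build_snp_network(ds, "mi")
  expect_equal(n_edges(net), 3L)
  expect_equal(net$level, "snp")

  one_snp <- genotype_dataset(ds$genotypes[, 1L, drop = FALSE],
                              phenotype = unname(ds$phenotype))
  expect_error(build_snp_network(one_snp), class = "epigain_error_validation")
})

test_that("an exact XOR pair gets a 1-bit IG edge", {
  g <- cbind(s1 = c(0L, 0L, 1L, 1L), s2 = c(0L, 1L, 0L, 1L),
             s3 = c(0L, 0L, 0L, 1L))
  ds <- genotype_dataset(g, phenotype = c(0, 1, 1, 0))
  net <- build_snp_network(ds, "ig")
  e <- net$edges
  expect_equal(e$weight[e$node_a == "s1" & e$node_b == "s2"], 1.0)
})

test_that("every network edge equals the direct pairwise computation", {
  ds <- make_dataset(40, 10, seed = 33)
  for (measure in c("mi", "ig")) {
    net <- build_snp_network(ds, measure)
    f <- if (measure == "mi") mi_pair_trait else info_gain
    for (r in sample(nrow(net$edges), 20)) {
      e <- net$edges[r, ]
      expect_equal(
        e$weight,
        f(ds$genotypes[, e$node_a], ds$genotypes[, e$node_b],
          unname(ds$phenotype)),
        tolerance = 1e-12
      )
    }
  }
})

test_that("gene aggregation summarises inter-gene SNP pairs as specified", {
  snp_net <- as_epinet(
    tibble::tibble(node_a = c("s1", "s2", "s1"),
                   node_b = c("s3", "s3", "s2"),
                   weight = c(0.2, 0.5, 0.9)),
    nodes = c("s1", "s2", "s3"), level = "snp", measure = "mi"
  )
  map <- snp_gene_map(c(s1 = "A", s2 = "A", s3 = "B"))
  agg <- function(a, ...) {
    convert_to_gene_network(snp_net, map, a, ...)$edges$weight
  }
  expect_equal(agg("max"), 0.5)   # intra-gene s1-s2 (0.9) is discarded
  expect_equal(agg("sum"), 0.7)
  expect_equal(agg("mean"), 0.35)
  expect_equal(agg("min"), 0.2)
  expect_equal(agg("count_above", snp_cutoff = 0.3), 1)
  expect_error(agg("count_above"), class = "epigain_error_validation")

  mx <- convert_to_gene_network(snp_net, map, "max")$edges
  expect_equal(c(mx$snp_a, mx$snp_b), c("s2", "s3"))  # argmax provenance
})

test_that("single-SNP genes inherit raw SNP edges; max matches brute force", {
  for (seed in 1:8) {
    ds <- make_dataset(30, 12, seed = 100 + seed)
    map <- make_map(snp_ids(ds), c(1, 3, 6, 2))
    net <- build_snp_network(ds, "mi")
    gnet <- convert_to_gene_network(net, map, "max")
    W <- tidy(net)
    lookup <- function(a, b) {
      w <- W$weight[(W$node_a == a & W$node_b == b) |
                      (W$node_a == b & W$node_b == a)]
      w
    }
    gene_of <- tibble::deframe(map$map)
    for (r in seq_len(nrow(gnet$edges))) {
      e <- gnet$edges[r, ]
      members_a <- names(gene_of)[gene_of == e$node_a]
      members_b <- names(gene_of)[gene_of == e$node_b]
      brute <- max(vapply(members_a, function(sa)
        max(vapply(members_b, function(sb) lookup(sa, sb), numeric(1))),
        numeric(1)))
      expect_equal(e$weight, brute, tolerance = 1e-12)
      expect_equal(lookup(e$snp_a, e$snp_b), e$weight)
    }
    # a singleton gene's edges are raw SNP edges
    singleton <- map$gene_size$gene_id[map$gene_size$n_snps == 1L][1L]
    s <- map$map$snp_id[map$map$gene_id == singleton]
    ge <- gnet$edges[gnet$edges$node_a == singleton |
                       gnet$edges$node_b == singleton, ]
    expect_true(all(ge$snp_a == s | ge$snp_b == s))
  }
})

test_that("the permutation threshold is deterministic and zero on constants", {
  g <- matrix(0L, 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  ds <- genotype_dataset(g, phenotype = rep(0:1, 5))
  map <- make_map(snp_ids(ds), c(2, 2))
  spec <- permutation_threshold(ds, map, "mi", n_permutations = 3, seed = 1)
  expect_equal(spec$theta, 0)

  ds2 <- make_dataset(30, 6, seed = 2)
  map2 <- make_map(snp_ids(ds2), c(2, 2, 2))
  s1 <- permutation_threshold(ds2, map2, "mi", n_permutations = 4, seed = 7)
  s2 <- permutation_threshold(ds2, map2, "mi", n_permutations = 4, seed = 7)
  expect_identical(s1$theta, s2$theta)
  expect_identical(s1$permutations, s2$permutations)
  expect_error(permutation_threshold(ds2, map2, "mi", n_permutations = 0),
               class = "epigain_error_validation")
})

test_that("theta equals explicit materialization of every permuted network", {
  ds <- make_dataset(40, 8, seed = 21)
  map <- make_map(snp_ids(ds), c(3, 4, 1))
  for (measure in c("mi", "ig")) {
    spec <- permutation_threshold(ds, map, measure, "max",
                                  n_permutations = 5, seed = 13)
    mats <- apply(spec$permutations, 1L, function(yp) {
      ds_p <- genotype_dataset(ds$genotypes, phenotype = yp)
      gnet <- convert_to_gene_network(build_snp_network(ds_p, measure),
                                      map, "max")
      e <- gnet$edges
      stats::setNames(e$weight, paste(e$node_a, e$node_b))
    })
    expect_equal(spec$theta, max(rowMeans(mats)), tolerance = 1e-12)
  }
})

test_that("thresholding is strict, drops isolates, and shrinks with alpha", {
  net <- as_epinet(
    tibble::tibble(node_a = c("A", "A"), node_b = c("B", "C"),
                   weight = c(0.4, 0.6)),
    level = "gene", measure = "mi"
  )
  thr <- apply_threshold(net, 0.25, alpha = 1.0)  # cutoff 0.5
  expect_equal(n_edges(thr), 1L)
  expect_equal(thr$nodes, c("A", "C"))
  # strictly greater: an edge exactly at the cutoff is removed
  expect_equal(n_edges(apply_threshold(net, 0.3, alpha = 1.0)), 0L)

  ds <- make_dataset(50, 10, seed = 9)
  map <- make_map(snp_ids(ds), c(2, 3, 4, 1))
  gnet <- convert_to_gene_network(build_snp_network(ds, "mi"), map, "max")
  theta <- min(gnet$edges$weight) / 2
  sizes <- vapply(seq(0, 3, by = 0.25), function(a) {
    t <- apply_threshold(gnet, theta, a)
    c(n_nodes(t), n_edges(t))
  }, integer(2))
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))
})

test_that("union integration is a tagged edge union with intersection count", {
  net <- function(pairs, measure) {
    as_epinet(tibble::tibble(node_a = pairs[, 1], node_b = pairs[, 2],
                             weight = seq_len(nrow(pairs)) / 10),
              level = "gene", measure = measure)
  }
  mi <- net(cbind(c("A", "A", "B"), c("B", "C", "C")), "mi")
  ig <- net(cbind(c("D", "D", "E", "F"), c("E", "F", "F", "G")), "ig")
  u <- integrate_networks(mi, ig)
  expect_equal(n_edges(u), 7L)
  expect_equal(attr(u, "intersection_edges"), 0L)

  u2 <- integrate_networks(mi, net(cbind(c("A", "A", "B"), c("B", "C", "C")),
                                   "ig"))
  expect_equal(n_edges(u2), 3L)
  expect_true(all(u2$edges$source == "both"))
  expect_equal(attr(u2, "intersection_edges"), 3L)

  shared <- net(cbind(c("A", "X"), c("B", "Y")), "ig")
  u3 <- integrate_networks(mi, shared)
  expect_equal(attr(u3, "intersection_edges"), 1L)
  expect_equal(n_edges(u3), 4L)
  # the union edge set does not depend on argument order
  u3r <- integrate_networks(shared, mi)
  expect_setequal(paste(u3$edges$node_a, u3$edges$node_b),
                  paste(u3r$edges$node_a, u3r$edges$node_b))

  snp_level <- as_epinet(tibble::tibble(node_a = "s1", node_b = "s2",
                                        weight = 1),
                         level = "snp", measure = "mi")
  expect_error(integrate_networks(snp_level, ig),
               class = "epigain_error_validation")
})

test_that("network exports are readable edge lists, SIF, and GraphML", {
  ds <- make_dataset(20, 5, seed = 6)
  map <- make_map(snp_ids(ds), c(2, 3))
  gnet <- convert_to_gene_network(build_snp_network(ds, "mi"), map, "max")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(gnet, tsv)
  back <- as_epinet(readr::read_tsv(tsv, show_col_types = FALSE),
                    level = "gene", measure = "mi")
  expect_equal(back$edges$weight, gnet$edges$weight)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(gnet, sif, "sif")
  expect_match(readLines(sif)[1], "^g01 mi g02$")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(gnet, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), n_edges(gnet))
})
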