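test_that("exact power-law degree data and two-point fits give R^2 = 1", {
  # counts proportional to k^-2 over k = 1..4: 144, 36, 16, 9 nodes
  degs <- rep(1:4, c(144, 36, 16, 9))
  g <- igraph::realize_degseq(degs)
  igraph::V(g)$name <- paste0("n", seq_along(degs))
  expect_equal(scale_free_r2(epinet_from_igraph(g)), 1.0, tolerance = 1e-12)

  star <- epinet_from_igraph(
    igraph::make_star(12, mode = "undirected", center = 1)
  )
  expect_equal(scale_free_r2(star), 1.0, tolerance = 1e-12)

  ring <- epinet_from_igraph(igraph::make_ring(10))  # constant degree
  expect_error(scale_free_r2(ring), class = "epigain_error_degenerate")
  expect_true(is.na(topology_report(ring)$r2))  # flagged, not fatal
})

test_that("preferential-attachment graphs look more scale-free than ER", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    er <- igraph::sample_gnp(200, 0.05)
    ba <- igraph::sample_pa(200, m = 5, directed = FALSE)
    igraph::V(er)$name <- paste0("e", 1:200)
    igraph::V(ba)$name <- paste0("b", 1:200)
    r2 <- function(g) tryCatch(scale_free_r2(epinet_from_igraph(g)),
                               epigain_error_degenerate = function(e) NA)
    if (isTRUE(r2(ba) > r2(er))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("component counts match a breadth-first-search oracle", {
  tri2 <- as_epinet(tibble::tibble(
    node_a = c("a", "b", "a", "x", "y", "x"),
    node_b = c("b", "c", "c", "y", "z", "z"),
    weight = 1
  ), level = "gene", measure = "mi")
  expect_equal(count_components(tri2), 2L)

  empty <- as_epinet(tibble::tibble(node_a = character(0),
                                    node_b = character(0),
                                    weight = numeric(0)),
                     nodes = c("a", "b"), level = "gene", measure = "mi")
  expect_equal(count_components(empty), 0L)

  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(40, 0.04)
    igraph::V(g)$name <- paste0("v", 1:40)
    net <- epinet_from_igraph(g)
    expect_equal(count_components(net), oracle_components(net$edges))
  }
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # N = 10, M = 5, n = 2, k = 2: C(5,2)/C(10,2) = 10/45
  universe <- paste0("g", 1:10)
  truth <- paste0("g", 1:5)
  expect_equal(enrichment_pvalue(c("g1", "g2"), truth, universe), 10 / 45,
               tolerance = 1e-12)
  # certain events
  expect_equal(enrichment_pvalue(truth[1:3], universe, universe), 1.0)
  expect_equal(enrichment_pvalue(c("g6", "g7"), truth, universe)
               >= enrichment_pvalue(c("g1", "g7"), truth, universe), TRUE)

  set.seed(31)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    M <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    ks <- seq(max(0, n - (N - M)), min(n, M))
    k <- ks[sample.int(length(ks), 1)]
    draw <- paste0("u", c(seq_len(k), M + seq_len(n - k)))
    expect_equal(
      enrichment_pvalue(draw, paste0("u", seq_len(M)), paste0("u", 1:N)),
      oracle_hypergeom_upper(N, M, n, k),
      tolerance = 1e-12
    )
  }
  expect_error(enrichment_pvalue("g1", truth, character(0)),
               class = "epigain_error_validation")
  expect_error(enrichment_pvalue("zzz", truth, universe),
               class = "epigain_error_validation")
})

test_that("node AUC is the mid-rank Mann-Whitney statistic over the universe", {
  universe <- paste0("g", 1:8)
  truth <- paste0("g", 1:2)
  perfect <- as_epinet(tibble::tibble(
    node_a = c("g1", "g1", "g2"), node_b = c("g2", "g3", "g4"), weight = 1
  ), level = "gene", measure = "mi")  # truth degrees 2, 2; others <= 1
  expect_equal(node_auc(perfect, truth, universe), 1.0)

  empty <- as_epinet(tibble::tibble(node_a = character(0),
                                    node_b = character(0),
                                    weight = numeric(0)),
                     level = "gene", measure = "mi")
  expect_equal(node_auc(empty, truth, universe), 0.5)
  expect_error(node_auc(empty, character(0), universe),
               class = "epigain_error_validation")
  expect_error(node_auc(empty, universe, universe),
               class = "epigain_error_validation")

  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(15, 0.25)
    igraph::V(g)$name <- paste0("g", 1:15)
    net <- epinet_from_igraph(g)
    uni <- paste0("g", 1:15)
    tr <- sample(uni, 5)
    deg <- node_degrees(net)[uni]
    auc <- node_auc(net, tr, uni)
    expect_equal(auc, oracle_auc(unname(deg), as.integer(uni %in% tr)),
                 tolerance = 1e-12)
    # invariant to strictly monotone transforms of the node score
    expect_equal(auc, oracle_auc(sqrt(unname(deg) + 1),
                                 as.integer(uni %in% tr)),
                 tolerance = 1e-12)
  }
})

test_that("scale-free R^2 ignores node labels", {
  set.seed(77)
  g <- igraph::sample_pa(60, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:60)
  net <- epinet_from_igraph(g)
  relabelled <- net
  perm <- setNames(sample(net$nodes), net$nodes)
  relabelled$edges$node_a <- unname(perm[relabelled$edges$node_a])
  relabelled$edges$node_b <- unname(perm[relabelled$edges$node_b])
  relabelled <- as_epinet(relabelled$edges, nodes = unname(perm),
                          level = "gene", measure = "mi")
  expect_equal(scale_free_r2(relabelled), scale_free_r2(net))
})

test_that("degree-size correlation flags proportionality and degeneracy", {
  prop <- as_epinet(tibble::tibble(
    node_a = c("A", "B", "B", "C", "C", "C", "D", "D", "D", "D"),
    node_b = c("x1", "x1", "x2", "x1", "x2", "x3", "x1", "x2", "x3", "x4"),
    weight = 1
  ), level = "gene", measure = "mi")
  map2 <- snp_gene_map(tibble::tibble(
    snp_id = paste0("s", 1:20),
    gene_id = rep(c("A", "B", "C", "D", "x1", "x2", "x3", "x4"),
                  c(1, 2, 3, 4, 3, 3, 2, 2))
  ))
  sub <- as_epinet(prop$edges, nodes = c("A", "B", "C", "D"),
                   level = "gene", measure = "mi")
  # restrict to the four genes of interest: degrees 1..4 vs sizes 1..4
  expect_equal(degree_size_correlation(sub, map2), 1.0)

  const <- as_epinet(tibble::tibble(node_a = c("A", "C"),
                                    node_b = c("B", "D"), weight = 1),
                     level = "gene", measure = "mi")
  expect_error(degree_size_correlation(const, map2),
               class = "epigain_error_degenerate")
})

test_that("alpha scans recompute per-cell metrics and shrink monotonically", {
  sim <- simulate_dataset(sim_config(n_cases = 40, n_controls = 40,
                                     n_snps = 30, missing_rate = 0,
                                     seed = 17))
  ds <- sim$dataset
  grid <- c(0, 0.6, 1.2)
  scan <- alpha_scan(ds, sim$map, "mi", "max", alpha_grid = grid,
                     ground_truth = sim$truth,
                     n_permutations = 3, seed = 5)
  expect_equal(scan$alpha, grid)
  expect_true(all(diff(scan$nodes) <= 0))
  expect_true(all(diff(scan$edges) <= 0))

  # per-cell recomputation from the parts
  spec <- permutation_threshold(ds, sim$map, "mi", "max",
                                n_permutations = 3, seed = 5)
  gnet <- convert_to_gene_network(build_snp_network(ds, "mi"), sim$map,
                                  "max")
  universe <- sim$map$gene_size$gene_id
  for (i in seq_along(grid)) {
    thr <- apply_threshold(gnet, spec, grid[i])
    expect_equal(scan$nodes[i], n_nodes(thr))
    expect_equal(scan$edges[i], n_edges(thr))
    expect_equal(scan$components[i], count_components(thr))
    if (!is.na(scan$auc[i])) {
      expect_equal(scan$auc[i], node_auc(thr, sim$truth, universe))
      expect_equal(scan$p_value[i],
                   enrichment_pvalue(intersect(thr$nodes, universe),
                                     sim$truth, universe))
    }
  }

  # single-alpha scan is a one-row table consistent with glance()
  one <- scan_gene_network(gnet, spec, 0.5)
  expect_equal(nrow(one), 1L)
  g1 <- glance(apply_threshold(gnet, spec, 0.5))
  expect_equal(one$edges, g1$edges)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_scan_table(scan, tsv)
  expect_equal(readLines(tsv)[1],
               "alpha\tnodes\tedges\tcomponents\tr2\tauc\tp_value\tr2_local_max")
})
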