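#' Configuration for the synthetic case-control GWAS generator
#'
#' Describes a reduced-scale case-control GWAS with planted effects. The
#' default sample sizes (188 cases, 247 controls) mirror a typical
#' moderately sized candidate-disease cohort; SNP count, allele
#' frequencies, missingness and gene-size skew are set to what passes
#' routine GWAS quality control. Planted effect sizes default to strong,
#' clearly detectable signals at these sample sizes: an additive marginal
#' log-odds of 2 per minor allele (a major-locus effect) and an XOR-type
#' epistatic log-odds contrast of 1.5 between concordant and discordant
#' dominant-coded genotype pairs, a purely epistatic model with vanishing
#' marginal effects at balanced dominant frequencies.
#'
#' @param n_cases,n_controls Retrospective sampling quotas.
#' @param n_snps Number of simulated SNPs.
#' @param maf_range Interval in `(0, 0.5]` from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param planted_maf_range Interval from which the planted (marginal and
#'   epistatic) SNPs' allele frequencies are drawn. Kept away from the rare
#'   end by default: a purely epistatic XOR signal at a very rare allele is
#'   undetectable at any effect size because discordant dominant genotypes
#'   almost never occur, so functional-SNP frequency is parameterised
#'   separately, as epistasis simulators conventionally do.
#' @param missing_rate Fraction of genotypes set missing (must stay below
#'   1/3 so simulated SNPs survive the default missingness filter).
#' @param n_marginal Number of planted marginal-effect SNPs.
#' @param marginal_effect Additive log-odds per minor allele at each
#'   planted marginal SNP.
#' @param n_epistatic_pairs Number of planted XOR-type SNP pairs.
#' @param epistasis_effect Log-odds increase when the two SNPs of a planted
#'   pair have discordant dominant-coded genotypes.
#' @param base_prevalence Disease probability at the covariate mean.
#' @param gene_size_mean,gene_size_max Gene sizes (SNPs per gene) are drawn
#'   from a long-tailed geometric distribution with this mean, capped at
#'   `gene_size_max`; genes are contiguous SNP blocks.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 188L, n_controls = 247L, n_snps = 300L,
                       maf_range = c(0.05, 0.5),
                       planted_maf_range = c(0.2, 0.4),
                       missing_rate = 0.01,
                       n_marginal = 2L, marginal_effect = 2.0,
                       n_epistatic_pairs = 2L, epistasis_effect = 1.5,
                       base_prevalence = 0.3,
                       gene_size_mean = 6, gene_size_max = 50L,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    planted_maf_range = as.numeric(planted_maf_range),
    missing_rate = missing_rate, n_marginal = as.integer(n_marginal),
    marginal_effect = marginal_effect,
    n_epistatic_pairs = as.integer(n_epistatic_pairs),
    epistasis_effect = epistasis_effect,
    base_prevalence = base_prevalence,
    gene_size_mean = gene_size_mean,
    gene_size_max = as.integer(gene_size_max), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cases >= 1L, cfg$n_controls >= 1L, cfg$n_snps >= 1L,
    length(cfg$maf_range) == 2L,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    length(cfg$planted_maf_range) == 2L,
    cfg$planted_maf_range[1] > 0, cfg$planted_maf_range[2] <= 0.5,
    cfg$planted_maf_range[1] <= cfg$planted_maf_range[2],
    cfg$missing_rate >= 0, cfg$missing_rate < 1 / 3,
    cfg$n_marginal >= 0L, cfg$n_epistatic_pairs >= 0L,
    cfg$n_marginal + 2L * cfg$n_epistatic_pairs <= cfg$n_snps,
    cfg$base_prevalence > 0, cfg$base_prevalence < 1,
    cfg$gene_size_mean >= 1, cfg$gene_size_max >= 1L
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a case-control GWAS dataset with planted effects
#'
#' Genotypes are drawn at Hardy-Weinberg proportions with per-SNP minor
#' allele frequencies from `maf_range`. The phenotype follows a logistic
#' penetrance model combining the planted additive marginal effects
#' (centred on each SNP's expected genotype) and XOR-type epistatic terms
#' (risk raised when the two SNPs' dominant-coded genotypes differ);
#' samples are then drawn retrospectively until the case and control
#' quotas are met. Missing genotypes are sprinkled uniformly at
#' `missing_rate`, and genes are contiguous SNP blocks with long-tailed
#' sizes. Planted SNP indices are mutually disjoint and recorded in the
#' `"planted"` attribute of the result.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `dataset` (a [genotype_dataset()]), `map`
#'   (a [snp_gene_map()]) and `truth` (character vector of genes
#'   containing planted SNPs; empty when nothing is planted). Attribute
#'   `"planted"` records the planted SNP ids and pairs, and attribute
#'   `"maf"` the drawn allele frequencies.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    m <- cfg$n_snps
    snps <- sprintf("snp_%04d", seq_len(m))
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    n_planted <- cfg$n_marginal + 2L * cfg$n_epistatic_pairs
    planted_idx <- if (n_planted > 0L) sample(m, n_planted) else integer(0)
    maf[planted_idx] <- runif(n_planted, cfg$planted_maf_range[1],
                              cfg$planted_maf_range[2])
    marg_idx <- utils::head(planted_idx, cfg$n_marginal)
    epi_idx <- utils::tail(planted_idx, 2L * cfg$n_epistatic_pairs)
    epi_pairs <- if (cfg$n_epistatic_pairs > 0L) {
      matrix(epi_idx, ncol = 2L, byrow = TRUE)
    } else {
      matrix(integer(0), ncol = 2L)
    }

    b0 <- qlogis(cfg$base_prevalence)
    draw_batch <- function(k) {
      G <- vapply(maf, function(p) rbinom(k, 2L, p), integer(k))
      eta <- rep(b0, k)
      for (j in marg_idx) {
        eta <- eta + cfg$marginal_effect * (G[, j] - 2 * maf[j])
      }
      if (nrow(epi_pairs) > 0L) {
        for (r in seq_len(nrow(epi_pairs))) {
          d1 <- G[, epi_pairs[r, 1L]] > 0L
          d2 <- G[, epi_pairs[r, 2L]] > 0L
          eta <- eta + cfg$epistasis_effect * ((d1 != d2) - 0.5)
        }
      }
      list(G = G, y = rbinom(k, 1L, plogis(eta)))
    }

    n_target <- cfg$n_cases + cfg$n_controls
    batch <- max(1000L, 4L * n_target)
    cases <- NULL
    controls <- NULL
    attempts <- 0L
    while (is.null(cases) || nrow(cases) < cfg$n_cases ||
           nrow(controls) < cfg$n_controls) {
      attempts <- attempts + 1L
      if (attempts > 200L) {
        stop_epigain("could not reach the requested case/control quotas; penetrance model too extreme for this configuration",
                     "epigain_error_infeasible")
      }
      b <- draw_batch(batch)
      cases <- rbind(cases, b$G[b$y == 1L, , drop = FALSE])
      controls <- rbind(controls, b$G[b$y == 0L, , drop = FALSE])
    }
    G <- rbind(cases[seq_len(cfg$n_cases), , drop = FALSE],
               controls[seq_len(cfg$n_controls), , drop = FALSE])
    y <- rep(1:0, c(cfg$n_cases, cfg$n_controls))
    if (cfg$missing_rate > 0) {
      miss <- runif(length(G)) < cfg$missing_rate
      G[miss] <- NA_integer_
    }
    dimnames(G) <- list(sprintf("sample_%04d", seq_len(nrow(G))), snps)

    sizes <- integer(0)
    while (sum(sizes) < m) {
      sizes <- c(sizes,
                 pmin(1L + rgeom(64L, 1 / cfg$gene_size_mean),
                      cfg$gene_size_max))
    }
    sizes <- sizes[cumsum(sizes) - sizes < m]
    sizes[length(sizes)] <- m - sum(utils::head(sizes, -1L))
    genes <- sprintf("gene_%03d", seq_along(sizes))
    gene_of <- rep(genes, sizes)
    map <- snp_gene_map(tibble(snp_id = snps, gene_id = gene_of))
    truth <- unique(gene_of[planted_idx])

    out <- list(
      dataset = genotype_dataset(G, phenotype = y),
      map = map,
      truth = truth
    )
    attr(out, "planted") <- list(
      marginal_snps = snps[marg_idx],
      epistatic_pairs = matrix(snps[epi_pairs], ncol = 2L)
    )
    attr(out, "maf") <- setNames(maf, snps)
    out
  })
}

#' Write a simulated fixture to disk
#'
#' Writes `genotypes.tsv` (TSV genotype dialect), `gene_map.tsv` and
#' `truth_genes.txt` into `dir`; [read_genotypes()] and
#' [read_snp_gene_map()] round-trip the files to the in-memory objects.
#'
#' @param ds A [genotype_dataset()].
#' @param map A [snp_gene_map()].
#' @param truth Character vector of true disease genes (may be empty).
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing fixture files?
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(ds, map, truth, dir, overwrite = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    truth = file.path(dir, "truth_genes.txt")
  )
  if (!overwrite && any(file.exists(paths))) {
    stop_epigain("fixture files already exist; use `overwrite = TRUE`",
                 "epigain_error_io")
  }
  write_genotypes(ds, paths[["genotypes"]], format = "tsv")
  readr::write_tsv(map$map, paths[["gene_map"]], progress = FALSE)
  writeLines(as.character(truth), paths[["truth"]])
  invisible(paths)
}
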