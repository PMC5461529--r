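#' Run the full gene-network construction pipeline
#'
#' Orchestrates QC (missingness filter, linkage-based imputation, MAF
#' filter), SNP epistasis networks for each requested measure, conversion
#' to gene-gene networks, the permutation threshold, the sparsity scan,
#' thresholding at a chosen (or flagged) `alpha`, union integration, and
#' topology reporting. All artifacts are written under `out_dir` together
#' with a machine-readable `manifest.json` (inputs, seed, package version,
#' thresholds, chosen alphas) sufficient to reproduce the run.
#'
#' Threshold selection is deliberately explicit: pass `alpha` as a named
#' vector (e.g. `c(mi = 5.0, ig = 3.7)`); when an entry is missing the
#' pipeline falls back to the scan's highest flagged local R-squared
#' maximum and says so, both in a message and in the manifest.
#'
#' @param genotypes A [genotype_dataset()] or a path readable by
#'   [read_genotypes()].
#' @param gene_map A [snp_gene_map()] or a path for [read_snp_gene_map()].
#' @param out_dir Output directory.
#' @param format Genotype file format when `genotypes` is a path.
#' @param ground_truth Optional known disease genes: character vector or a
#'   path for [read_gene_list()].
#' @param measures Association measures to run (default both).
#' @param aggregator Gene aggregation rule (default `"max"`).
#' @param n_permutations Label permutations for the threshold (default 30).
#' @param alpha_grid Sparsity grid for the scan (default 0 to 5 by 0.1).
#' @param alpha Optional named numeric vector of chosen sparsity
#'   multipliers per measure.
#' @param max_missing,min_maf QC cutoffs (defaults: 1/3, 0.05).
#' @param prescreen_top Optional integer: keep only this many SNPs by
#'   marginal mutual-information rank before the all-pairs step. This is
#'   an engineering escape hatch for very large inputs, not part of the
#'   method; when used it is recorded in the manifest.
#' @param seed Integer seed driving imputation tie-breaks and
#'   permutations.
#' @param overwrite Overwrite an existing output directory?
#' @return A list with elements `dataset`, `map`, `networks`, `thresholds`,
#'   `scans`, `chosen_alpha`, `union`, `report`, `manifest`.
#' @export
run_pipeline <- function(genotypes, gene_map, out_dir,
                         format = c("tsv", "plink_text"),
                         ground_truth = NULL,
                         measures = c("mi", "ig"), aggregator = "max",
                         n_permutations = 30L,
                         alpha_grid = seq(0, 5, by = 0.1), alpha = NULL,
                         max_missing = 1 / 3, min_maf = 0.05,
                         prescreen_top = NULL, seed = 1L,
                         overwrite = FALSE) {
  measures <- match.arg(measures, c("mi", "ig"), several.ok = TRUE)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite) {
    stop_epigain("`out_dir` exists and is non-empty; use `overwrite = TRUE`",
                 "epigain_error_io")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_path <- if (is.character(genotypes)) genotypes else NA_character_
  ds <- if (is.character(genotypes)) {
    read_genotypes(genotypes, match.arg(format))
  } else {
    genotypes
  }
  map <- if (is.character(gene_map)) read_snp_gene_map(gene_map) else gene_map
  truth <- if (is.character(ground_truth) && length(ground_truth) == 1L &&
               file.exists(ground_truth)) {
    read_gene_list(ground_truth)
  } else {
    ground_truth
  }

  n_raw <- n_snps(ds)
  ds <- filter_missingness(ds, max_missing)
  ds <- impute_linkage(ds, seed = seed)
  ds <- filter_maf(ds, min_maf)
  inform(sprintf("QC: %d of %d SNPs retained", n_snps(ds), n_raw))
  if (!is.null(prescreen_top) && prescreen_top < n_snps(ds)) {
    mm <- marginal_mi(ds$genotypes, ds$phenotype)
    keep <- rank(-mm, ties.method = "first") <= prescreen_top
    ds <- subset_snps(ds, keep)
    warn(sprintf(
      "prescreen: kept top %d SNPs by marginal MI; this shortcut is not part of the published construction",
      prescreen_top))
  }
  universe <- unique(gene_for_snp(map, snp_ids(ds)))
  universe <- universe[!is.na(universe)]

  networks <- list()
  thresholds <- list()
  scans <- list()
  chosen <- list()
  for (msr in measures) {
    snp_net <- build_snp_network(ds, msr)
    gene_net <- convert_to_gene_network(snp_net, map, aggregator)
    spec <- permutation_threshold(ds, map, msr, aggregator,
                                  n_permutations, seed)
    scan <- scan_gene_network(gene_net, spec, alpha_grid, truth, universe)
    write_scan_table(scan, file.path(out_dir, sprintf("scan_%s.tsv", msr)))
    a <- pick_alpha(alpha, msr, scan)
    thr_net <- apply_threshold(gene_net, spec, a$alpha)
    write_network(thr_net, file.path(out_dir, sprintf("gene_net_%s.tsv", msr)))
    networks[[msr]] <- list(snp = snp_net, gene = gene_net,
                            thresholded = thr_net)
    thresholds[[msr]] <- spec
    scans[[msr]] <- scan
    chosen[[msr]] <- a
  }

  union_net <- NULL
  report <- purrr::imap(networks, function(nw, msr) {
    dplyr::bind_cols(tibble(network = msr,
                            alpha = chosen[[msr]]$alpha),
                     topology_report(nw$thresholded, truth, universe))
  })
  if (all(c("mi", "ig") %in% measures)) {
    union_net <- integrate_networks(networks$mi$thresholded,
                                    networks$ig$thresholded)
    for (fmt in c("tsv", "sif", "graphml")) {
      write_network(union_net,
                    file.path(out_dir, paste0("union_net.", fmt)), fmt)
    }
    report$union <- dplyr::bind_cols(
      tibble(network = "union", alpha = NA_real_),
      topology_report(union_net, truth, universe)
    )
  }
  report <- dplyr::bind_rows(report)
  readr::write_tsv(report, file.path(out_dir, "topology_report.tsv"),
                   na = "NA", progress = FALSE)

  manifest <- list(
    package = "epigain",
    version = as.character(utils::packageVersion("epigain")),
    input = input_path, seed = as.integer(seed),
    n_samples = n_samples(ds), n_snps_post_qc = n_snps(ds),
    measures = measures, aggregator = aggregator,
    n_permutations = as.integer(n_permutations),
    max_missing = max_missing, min_maf = min_maf,
    prescreen_top = prescreen_top,
    theta = purrr::map(thresholds, "theta"),
    alpha = purrr::map(chosen, "alpha"),
    alpha_selection = purrr::map(chosen, "how"),
    intersection_edges = if (is.null(union_net)) NULL else
      attr(union_net, "intersection_edges")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(dataset = ds, map = map, networks = networks,
       thresholds = thresholds, scans = scans, chosen_alpha = chosen,
       union = union_net, report = report, manifest = manifest)
}

pick_alpha <- function(alpha, measure, scan) {
  if (!is.null(alpha) && measure %in% names(alpha)) {
    return(list(alpha = unname(alpha[[measure]]), how = "user"))
  }
  cand <- scan[scan$r2_local_max & scan$edges > 0L, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- scan[scan$edges > 0L, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- scan[1L, , drop = FALSE]
  best <- cand$alpha[which.max(cand$r2)]
  if (length(best) == 0L || is.na(best)) best <- cand$alpha[1L]
  inform(sprintf(
    "measure %s: no alpha supplied; using flagged local R-squared maximum alpha = %g (review the scan table before trusting this choice)",
    measure, best))
  list(alpha = best, how = "flagged_local_r2_max")
}
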