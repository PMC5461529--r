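#' Case-control genotype dataset
#'
#' Container for a samples-by-SNPs genotype matrix with a binary phenotype.
#' Genotypes are additive minor-allele counts in `{0, 1, 2}`; missing
#' genotypes are `NA`. The phenotype codes cases as 1 and controls as 0 and
#' must contain at least one sample of each class. All information-theoretic
#' computations in the package treat genotype codes as unordered categories,
#' so the orientation of the minor-allele coding never changes a mutual
#' information or information gain value.
#'
#' @param genotypes Integer matrix (samples x SNPs) with entries in
#'   `{0, 1, 2, NA}`, or a wide data frame in the package's TSV layout
#'   (`sample_id`, `phenotype`, then one column per SNP).
#' @param phenotype Binary vector (0 = control, 1 = case), one per sample.
#'   Ignored when `genotypes` is a data frame carrying a `phenotype` column.
#' @param sample_ids,snp_ids Optional identifier vectors; default to the
#'   matrix dimnames, or `sample_<i>` / `snp_<j>` when absent.
#'
#' @return An object of class `genotype_dataset` with elements `genotypes`
#'   (named integer matrix) and `phenotype` (integer vector).
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3)
#' ds <- genotype_dataset(g, phenotype = c(0, 1, 1))
#' n_snps(ds)
genotype_dataset <- function(genotypes, phenotype = NULL,
                             sample_ids = NULL, snp_ids = NULL) {
  if (is.data.frame(genotypes)) {
    df <- genotypes
    if (!all(c("sample_id", "phenotype") %in% names(df))) {
      stop_epigain(
        "data-frame input must have `sample_id` and `phenotype` columns",
        "epigain_error_validation"
      )
    }
    sample_ids <- as.character(df$sample_id)
    phenotype <- df$phenotype
    snp_cols <- setdiff(names(df), c("sample_id", "phenotype"))
    genotypes <- as.matrix(df[snp_cols])
    storage.mode(genotypes) <- "integer"
    snp_ids <- snp_cols
  }
  if (!is.matrix(genotypes)) {
    stop_epigain("`genotypes` must be a matrix or data frame",
                 "epigain_error_validation")
  }
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    stop_epigain(
      sprintf("%d genotype entries outside {0, 1, 2, NA}", sum(bad)),
      "epigain_error_validation"
    )
  }
  sample_ids <- as.character(sample_ids %||% rownames(genotypes) %||%
                               sprintf("sample_%d", seq_len(nrow(genotypes))))
  snp_ids <- as.character(snp_ids %||% colnames(genotypes) %||%
                            sprintf("snp_%d", seq_len(ncol(genotypes))))
  if (anyDuplicated(sample_ids)) {
    stop_epigain("duplicate sample ids", "epigain_error_validation")
  }
  if (anyDuplicated(snp_ids)) {
    stop_epigain("duplicate SNP ids", "epigain_error_validation")
  }
  if (length(sample_ids) != nrow(genotypes) ||
      length(snp_ids) != ncol(genotypes)) {
    stop_epigain("identifier lengths do not match the genotype matrix",
                 "epigain_error_validation")
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    stop_epigain("`phenotype` length must equal the number of samples",
                 "epigain_error_validation")
  }
  if (anyNA(phenotype) || !all(phenotype %in% 0:1)) {
    stop_epigain("`phenotype` must be binary 0/1 with no missing values",
                 "epigain_error_validation")
  }
  if (length(unique(phenotype)) < 2L) {
    stop_epigain("`phenotype` must contain both cases and controls",
                 "epigain_error_validation")
  }
  dimnames(genotypes) <- list(sample_ids, snp_ids)
  structure(
    list(genotypes = genotypes, phenotype = setNames(phenotype, sample_ids)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$genotypes))
  cat(sprintf(
    "<genotype_dataset> %d samples (%d cases / %d controls) x %d SNPs; %d missing genotypes (%.2f%%)\n",
    n_samples(x), sum(x$phenotype == 1L), sum(x$phenotype == 0L), n_snps(x),
    nmiss, 100 * nmiss / max(1L, length(x$genotypes))
  ))
  invisible(x)
}

#' @rdname genotype_dataset
#' @param ds A `genotype_dataset`.
#' @export
n_samples <- function(ds) nrow(ds$genotypes)

#' @rdname genotype_dataset
#' @export
n_snps <- function(ds) ncol(ds$genotypes)

#' @rdname genotype_dataset
#' @export
snp_ids <- function(ds) colnames(ds$genotypes)

#' @method as_tibble genotype_dataset
#' @export
as_tibble.genotype_dataset <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$genotypes))
  dplyr::bind_cols(
    tibble(sample_id = rownames(x$genotypes),
           phenotype = unname(x$phenotype)),
    out
  )
}

#' SNP-to-gene annotation map
#'
#' Associates each SNP with exactly one gene and records each gene's size as
#' its mapped-SNP count (the direct driver of gene-size bias in SNP-derived
#' gene networks). A SNP listed under two different genes keeps its first
#' mapping; the conflict is reported with a warning.
#'
#' @param map Data frame (or tibble) with columns `snp_id` and `gene_id`, or
#'   a named character vector `gene_id` named by `snp_id`.
#' @return An object of class `snp_gene_map` with elements `map` (tibble
#'   `snp_id`, `gene_id`) and `gene_size` (tibble `gene_id`, `n_snps`).
#' @export
snp_gene_map <- function(map) {
  if (is.character(map) && !is.null(names(map))) {
    map <- tibble(snp_id = names(map), gene_id = unname(map))
  }
  map <- as_tibble(map)
  if (!all(c("snp_id", "gene_id") %in% names(map)) || nrow(map) == 0L) {
    stop_epigain("gene map needs non-empty `snp_id` and `gene_id` columns",
                 "epigain_error_validation")
  }
  map <- dplyr::mutate(map, dplyr::across(c("snp_id", "gene_id"), as.character))
  dup <- duplicated(map$snp_id)
  if (any(dup)) {
    conflicted <- unique(map$snp_id[dup])
    warn(sprintf(
      "%d SNP(s) mapped to multiple genes; keeping the first mapping (e.g. %s)",
      length(conflicted), conflicted[1L]
    ))
    map <- map[!dup, ]
  }
  gene_size <- dplyr::count(map, .data$gene_id, name = "n_snps")
  structure(list(map = map, gene_size = gene_size), class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat(sprintf("<snp_gene_map> %d SNPs in %d genes (sizes %d-%d)\n",
              nrow(x$map), nrow(x$gene_size),
              min(x$gene_size$n_snps), max(x$gene_size$n_snps)))
  invisible(x)
}

#' @method as_tibble snp_gene_map
#' @export
as_tibble.snp_gene_map <- function(x, ...) x$map

# gene of each snp id, NA when unmapped
gene_for_snp <- function(map, snps) {
  idx <- match(snps, map$map$snp_id)
  map$map$gene_id[idx]
}
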