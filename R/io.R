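#' Read case-control genotypes
#'
#' Reads a genotype dataset from either the package's TSV dialect or
#' PLINK-style text files.
#'
#' The TSV dialect has a header row `sample_id`, `phenotype`, then one
#' column per SNP; genotypes are `0`, `1`, `2` or `NA` (any unparseable
#' token also becomes missing). For PLINK text, `path` is the `.ped` file
#' (or the common stem of a `.ped`/`.map` pair): the phenotype column coded
#' 1 (control) / 2 (case) is recoded to 0/1, allele pairs are collapsed to
#' minor-allele counts per SNP, and the `0 0` genotype becomes missing.
#' When the two alleles of a SNP are equally frequent the lexicographically
#' later allele is counted, so files produced by [write_genotypes()] from
#' minor-allele-coded data round-trip exactly.
#'
#' @param path File path.
#' @param format `"tsv"` or `"plink_text"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_text")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_ped(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_epigain(sprintf("file not found: %s", path), "epigain_error_io")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(df)[1:2])) {
    stop_epigain("TSV header must start with sample_id<TAB>phenotype",
                 "epigain_error_io")
  }
  phen <- suppressWarnings(as.integer(df$phenotype))
  if (anyNA(phen)) {
    stop_epigain("phenotype column contains non-integer tokens",
                 "epigain_error_validation")
  }
  snp_cols <- setdiff(names(df), c("sample_id", "phenotype"))
  geno <- as.matrix(df[snp_cols])
  geno[!(geno %in% c("0", "1", "2"))] <- NA  # unparseable tokens -> missing
  storage.mode(geno) <- "integer"
  genotype_dataset(geno, phenotype = phen,
                   sample_ids = df$sample_id, snp_ids = snp_cols)
}

plink_paths <- function(path) {
  stem <- sub("\\.(ped|map)$", "", path)
  list(ped = paste0(stem, ".ped"), map = paste0(stem, ".map"))
}

read_genotypes_ped <- function(path) {
  p <- plink_paths(path)
  if (!file.exists(p$ped) || !file.exists(p$map)) {
    stop_epigain(sprintf("missing .ped/.map pair for: %s", path),
                 "epigain_error_io")
  }
  map <- utils::read.table(p$map, colClasses = "character")
  snps <- map[[2L]]
  rows <- strsplit(trimws(readLines(p$ped)), "[ \t]+")
  rows <- rows[lengths(rows) > 0L]
  width <- 6L + 2L * length(snps)
  if (any(lengths(rows) != width)) {
    stop_epigain(".ped rows inconsistent with the .map SNP count",
                 "epigain_error_io")
  }
  ped <- do.call(rbind, rows)
  phen_raw <- ped[, 6L]
  if (!all(phen_raw %in% c("1", "2"))) {
    stop_epigain("PLINK phenotype must be 1 (control) or 2 (case)",
                 "epigain_error_validation")
  }
  a1 <- ped[, 6L + 2L * seq_along(snps) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_along(snps), drop = FALSE]
  geno <- matrix(NA_integer_, nrow(ped), length(snps))
  for (j in seq_along(snps)) {
    al <- c(a1[, j], a2[, j])
    obs <- setdiff(unique(al), "0")
    if (length(obs) > 2L) {
      stop_epigain(sprintf("SNP %s has more than two alleles", snps[j]),
                   "epigain_error_validation")
    }
    if (length(obs) == 0L) next  # fully missing column
    counts <- vapply(obs, function(a) sum(al == a), integer(1))
    # minor allele = less frequent; ties go to the later-sorted allele
    obs <- obs[order(counts, rank(obs))]
    minor <- obs[1L]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
    geno[miss, j] <- NA_integer_
  }
  genotype_dataset(geno, phenotype = as.integer(phen_raw == "2"),
                   sample_ids = ped[, 2L], snp_ids = snps)
}

#' Write case-control genotypes
#'
#' Writes the TSV dialect, or a PLINK-style `.ped`/`.map` pair in which
#' genotype codes 0/1/2 become allele pairs `A A` / `A B` / `B B` and
#' missing genotypes become `0 0`.
#'
#' @param ds A [genotype_dataset()].
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, format = c("tsv", "plink_text")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(ds), path, na = "NA", progress = FALSE)
    return(invisible(path))
  }
  p <- plink_paths(path)
  g <- ds$genotypes
  allele_strings <- c("A A", "A B", "B B")
  block <- matrix(allele_strings[g + 1L], nrow(g), ncol(g))
  block[is.na(g)] <- "0 0"
  lines <- paste(
    rownames(g), rownames(g), "0", "0", "0",
    ifelse(ds$phenotype == 1L, "2", "1"),
    apply(block, 1L, paste, collapse = " ")
  )
  writeLines(lines, p$ped)
  writeLines(paste("1", colnames(g), "0", seq_len(ncol(g))), p$map)
  invisible(path)
}

#' Read a SNP-to-gene map from a two-column TSV
#'
#' Columns are `snp_id` then `gene_id`; a header row is detected and
#' skipped. Mapped SNPs that are absent from a particular dataset are fine:
#' conversion to a gene network simply ignores them, and dataset SNPs absent
#' from the map are excluded from the gene network (with a message).
#'
#' @param path File path.
#' @return A [snp_gene_map()].
#' @export
read_snp_gene_map <- function(path) {
  if (!file.exists(path)) {
    stop_epigain(sprintf("file not found: %s", path), "epigain_error_io")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_epigain("empty gene map file", "epigain_error_validation")
  }
  first <- tolower(strsplit(lines[1L], "\t")[[1L]])
  if (any(grepl("snp|gene", first))) lines <- lines[-1L]
  if (length(lines) == 0L) {
    stop_epigain("gene map file has a header but no entries",
                 "epigain_error_validation")
  }
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) {
    stop_epigain("gene map rows must have two tab-separated columns",
                 "epigain_error_io")
  }
  snp_gene_map(tibble(
    snp_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L)
  ))
}

#' Read a plain gene list (one gene id per line)
#'
#' @param path File path.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop_epigain(sprintf("file not found: %s", path), "epigain_error_io")
  }
  genes <- unique(trimws(readLines(path)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    stop_epigain("empty gene list", "epigain_error_validation")
  }
  genes
}
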