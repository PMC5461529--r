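#' Quality-control filters for genotype data
#'
#' `filter_missingness()` drops SNPs whose missing-genotype fraction exceeds
#' `max_missing_fraction` (default one third, so a SNP missing in exactly a
#' third of samples is retained). `filter_maf()` drops SNPs whose minor
#' allele frequency is strictly below `min_maf` (default 0.05; a SNP at
#' exactly the cutoff is retained), with
#' `MAF = min(p, 1 - p)`, `p = (2 n2 + n1) / (2 n)` over non-missing
#' samples. Both preserve sample set and SNP order, and both are
#' idempotent.
#'
#' @param ds A [genotype_dataset()].
#' @param max_missing_fraction Largest tolerated per-SNP missing fraction.
#' @param min_maf Smallest retained minor allele frequency.
#' @return A filtered [genotype_dataset()].
#' @export
filter_missingness <- function(ds, max_missing_fraction = 1 / 3) {
  stopifnot(inherits(ds, "genotype_dataset"),
            is_scalar_number(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- colMeans(is.na(ds$genotypes))
  subset_snps(ds, frac <= max_missing_fraction)
}

#' @rdname filter_missingness
#' @export
filter_maf <- function(ds, min_maf = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"), is_scalar_number(min_maf))
  maf <- snp_maf(ds)
  subset_snps(ds, !is.na(maf) & maf >= min_maf)
}

#' @rdname filter_missingness
#' @export
snp_maf <- function(ds) {
  g <- ds$genotypes
  n_obs <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  setNames(pmin(p, 1 - p), colnames(g))
}

subset_snps <- function(ds, keep) {
  out <- ds
  out$genotypes <- ds$genotypes[, keep, drop = FALSE]
  out
}

#' Linkage-based imputation of missing genotypes
#'
#' Fills each missing genotype from the SNP's most-correlated partner SNP:
#' for SNP `s`, the partner is the SNP maximising the squared Pearson
#' correlation of genotype codes over samples complete in both; a missing
#' value in sample `i` becomes the modal genotype of `s` among samples that
#' share sample `i`'s partner genotype. When that stratum is empty (or the
#' partner is itself missing in `i`, or no informative partner exists) the
#' unconditional mode of `s` is used. Modal ties break toward the smaller
#' genotype code; partners with exactly equal correlation are ordered by a
#' seeded shuffle, making the result deterministic given `seed`. Imputation
#' always conditions on the originally observed data, never on values filled
#' earlier in the same pass, and never alters a non-missing genotype.
#'
#' @param ds A [genotype_dataset()].
#' @param seed Integer seed used only for partner tie-breaking.
#' @return A [genotype_dataset()] with no missing genotypes.
#' @export
impute_linkage <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  if (!anyNA(g)) return(ds)
  if (any(colSums(!is.na(g)) == 0L)) {
    stop_epigain("cannot impute a SNP with all genotypes missing",
                 "epigain_error_validation")
  }
  m <- ncol(g)
  todo <- which(colSums(is.na(g)) > 0L)
  out <- g
  local_seed(seed, {
    for (j in todo) {
      partner_order <- sample(setdiff(seq_len(m), j))
      r2 <- vapply(partner_order, function(k) {
        ok <- !is.na(g[, j]) & !is.na(g[, k])
        if (sum(ok) < 2L) return(NA_real_)
        sj <- g[ok, j]; sk <- g[ok, k]
        if (stats::sd(sj) == 0 || stats::sd(sk) == 0) return(NA_real_)
        cor(sj, sk)^2
      }, numeric(1))
      partner <- if (all(is.na(r2))) NA_integer_ else
        partner_order[which.max(r2)]
      fallback <- modal_genotype(g[, j])
      for (i in which(is.na(g[, j]))) {
        fill <- fallback
        if (!is.na(partner) && !is.na(g[i, partner])) {
          stratum <- !is.na(g[, j]) & !is.na(g[, partner]) &
            g[, partner] == g[i, partner]
          if (any(stratum)) fill <- modal_genotype(g[stratum, j])
        }
        out[i, j] <- fill
      }
    }
  })
  ds$genotypes <- out
  ds
}
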