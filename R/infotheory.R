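#' Plug-in entropy and mutual information in bits
#'
#' Maximum-likelihood ("plug-in") estimators over discrete genotype and
#' phenotype variables, in bits (log base 2). `shannon_entropy()` computes
#' `H = -sum(p * log2(p))` over the cells of a count vector or array with
#' the `0 * log 0 = 0` convention. `mi_single()` computes
#' `I(X; Y) = H(X) + H(Y) - H(X, Y)` between one SNP and the trait.
#' `mi_pair_trait()` computes `I(X1, X2; Y) = H(X1, X2) + H(Y) -
#' H(X1, X2, Y)`, treating the genotype pair as one variable with up to nine
#' levels. `info_gain()` computes the synergy
#' `IG(X1; X2; Y) = I(X1, X2; Y) - I(X1; Y) - I(X2; Y)`, which is negative
#' when the two SNPs carry redundant trait information and equals
#' `I(X1, X2; Y)` for a purely epistatic (XOR-type) pair whose marginal
#' effects vanish. No bias correction is applied. Inputs must be free of
#' missing values; resolve those upstream with [impute_linkage()].
#'
#' @param counts Non-negative numeric vector or array of cell counts with a
#'   positive total.
#' @param x,x1,x2 Genotype vectors (unordered discrete codes).
#' @param y Binary phenotype vector of the same length.
#' @return A single number in bits.
#' @export
#' @examples
#' shannon_entropy(c(2, 2)) # 1 bit
#' info_gain(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 1, 1, 0)) # XOR: 1 bit
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0)) {
    stop_epigain("`counts` must be non-negative and free of NA",
                 "epigain_error_validation")
  }
  n <- sum(counts)
  if (n <= 0) {
    stop_epigain("total count must be positive", "epigain_error_validation")
  }
  -sum(xlog2x(counts / n))
}

check_discrete_inputs <- function(...) {
  vs <- list(...)
  len <- unique(lengths(vs))
  if (length(len) != 1L) {
    stop_epigain("input vectors must have equal lengths",
                 "epigain_error_validation")
  }
  if (len == 0L) {
    stop_epigain("input vectors must be non-empty", "epigain_error_validation")
  }
  if (any(vapply(vs, anyNA, logical(1)))) {
    stop_epigain("missing values are not allowed; impute first",
                 "epigain_error_validation")
  }
  invisible(len)
}

joint_entropy <- function(...) shannon_entropy(table(...))

#' @rdname shannon_entropy
#' @export
mi_single <- function(x, y) {
  check_discrete_inputs(x, y)
  joint_entropy(x) + joint_entropy(y) - joint_entropy(x, y)
}

#' @rdname shannon_entropy
#' @export
mi_pair_trait <- function(x1, x2, y) {
  check_discrete_inputs(x1, x2, y)
  joint_entropy(x1, x2) + joint_entropy(y) - joint_entropy(x1, x2, y)
}

#' @rdname shannon_entropy
#' @export
info_gain <- function(x1, x2, y) {
  mi_pair_trait(x1, x2, y) - mi_single(x1, y) - mi_single(x2, y)
}
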