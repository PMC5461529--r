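# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# x * log2(x) with the 0 * log 0 = 0 convention, elementwise.
xlog2x <- function(p) {
  out <- p * log2(p)
  out[p == 0] <- 0
  out
}

# Modal value of an integer vector; ties broken toward the smaller code.
modal_genotype <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # names are sorted ascending
}

stop_epigain <- function(msg, class, ...) {
  abort(msg, class = c(class, "epigain_error"), ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
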