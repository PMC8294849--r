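#' Round half away from zero
#'
#' Deterministic commercial rounding used when converting requested
#' fractions into integer item counts (e.g. number of mobile tracks or
#' mitochondria-containing boutons), so that constructed fractions are
#' reproduced exactly. `round()` in R rounds half to even, which would make
#' counts depend on parity.
#'
#' @param x numeric vector.
#' @return integer vector, |x| rounded up at exact .5.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Allocate integer counts to proportions
#'
#' Computes per-item counts `round_half_away(p * n)` and assigns the
#' rounding remainder (positive or negative) to the lowest-index items so
#' that the counts sum exactly to `n`.
#'
#' @param p proportions, must sum to 1 (within 1e-8).
#' @param n total count.
#' @return integer vector of counts summing to `n`.
#' @keywords internal
allocate_counts <- function(p, n) {
  stopifnot(abs(sum(p) - 1) < 1e-8, n >= 0)
  k <- round_half_away(p * n)
  rem <- n - sum(k)
  i <- 1L
  while (rem != 0L) {
    k[i] <- k[i] + sign(rem)
    rem <- rem - sign(rem)
    i <- i %% length(k) + 1L
  }
  k
}

# Shared input-error signal: all user-facing validation failures raise a
# condition of class "mitodyn_error" so callers can distinguish them from
# programming errors.
mito_stop <- function(..., class = "mitodyn_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean norm of rows of a matrix
row_norms <- function(m) sqrt(rowSums(m^2))

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
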