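#' Geometric mean
#'
#' @param x numeric vector of strictly positive values.
#' @return exp(mean(log(x))).
#' @keywords internal
geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors of the same length.
#' 1 means identical partitions, 0 is the expected value under random
#' labelling.
#'
#' @param a,b label vectors (any atomic type) of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# format numbers for TSV output: integers rendered plainly, everything else
# with 17 significant digits so read(write(x)) is exact in double precision
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  int <- is.finite(x) & x == trunc(x) & abs(x) < 2^53
  out[int] <- sprintf("%.0f", x[int])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
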