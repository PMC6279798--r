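# Numerically stable log-space helpers used throughout the likelihood code.

#' Stable log(exp(a) + exp(b))
#'
#' Elementwise log-sum-exp of two vectors; `-Inf` inputs are handled exactly
#' (log of a zero mixture weight).
#'
#' @param a,b numeric vectors (recycled).
#' @return numeric vector.
#' @keywords internal
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  both_inf <- is.infinite(m) & m < 0
  out[both_inf] <- -Inf
  out
}

#' Stable log-sum-exp of a vector
#' @param x numeric vector.
#' @return scalar.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix
#' @param x numeric matrix.
#' @return numeric vector, one value per row.
#' @keywords internal
row_logsumexp <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  bad <- is.infinite(mx) & mx < 0
  mx[bad] <- 0
  out <- mx + log(rowSums(exp(x - mx)))
  out[bad] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NUCLEOTIDES <- c("A", "C", "G", "T")
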