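#' @importFrom rlang abort warn %||%
#' @importFrom stats median sd cor setNames
NULL

SPLICE_CLASSES <- c("AA", "AD", "AT", "ES", "ME", "RI")

inv_logit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

clamp01 <- function(x) {
  # in-place so matrix dims survive (pmin/pmax with a scalar drop them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used throughout the test-suite and acceptance checks to quantify how
#' well detected modules recover planted ones. 1 means identical
#' partitions (up to label permutation), 0 the expectation under random
#' labeling.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
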