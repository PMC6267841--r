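#' Exact conditional distribution of the squared treatment imbalance
#'
#' For a centre whose final block contains `r` of its `b` slots, the per-centre
#' imbalance is \eqn{\Delta = n_1/k - n_2}, where \eqn{n_1}, \eqn{n_2} are the
#' arm counts among those `r` subjects. Because the block is a uniform draw
#' from all `k`:1-balanced orderings, the arm-1 count `j` among the first `r`
#' entries is hypergeometric (population `b`, `k*b/(k+1)` arm-1 members, draw
#' size `r`), and \eqn{\Delta^2 = (j/k - (r - j))^2}. Outcomes with equal
#' \eqn{\Delta^2} are merged into one support point.
#'
#' A complete block (`r = b`) is perfectly balanced, so the distribution is a
#' point mass at 0. All support points lie in `[0, m*]` with
#' `m* = b^2/(k+1)^2`.
#'
#' @param scheme a [block_scheme()].
#' @param r number of subjects in the final block, integer in `[1, b]`.
#' @return An object of class `imbalance_distribution`: a list with the
#'   `scheme`, `r`, sorted numeric `support` (distinct \eqn{\Delta^2} values)
#'   and matching `probs`.
#' @examples
#' imbalance_distribution(block_scheme(6), 3)  # {1: 0.9, 9: 0.1}
#' @seealso [expected_imbalance()], [mean_expected_imbalance()],
#'   [max_expected_imbalance()]
#' @export
imbalance_distribution <- function(scheme, r) {
  scheme <- as_block_scheme(scheme)
  if (length(r) != 1L || !is.numeric(r) || r != round(r) ||
      r < 1 || r > scheme$b)
    stop(sprintf("'r' must be an integer in [1, %d]", scheme$b),
         call. = FALSE)
  r <- as.integer(r)
  k <- scheme$k
  j <- max(0L, r - scheme$n2):min(r, scheme$n1)
  p <- dhyper(j, scheme$n1, scheme$n2, r)
  delta2 <- (j / k - (r - j))^2
  # k^2 * delta2 = (j(1+k) - k r)^2 is integral, so merging is exact
  key <- round(k^2 * delta2)
  probs <- as.numeric(tapply(p, key, sum))
  support <- sort(unique(key)) / k^2
  structure(
    list(scheme = scheme, r = r, support = support, probs = probs),
    class = "imbalance_distribution"
  )
}

#' @export
print.imbalance_distribution <- function(x, ...) {
  cat(sprintf("Distribution of squared imbalance | r = %d (b = %d, k = %d)\n",
              x$r, x$scheme$b, x$scheme$k))
  print(data.frame(delta_sq = x$support, prob = x$probs), row.names = FALSE)
  invisible(x)
}

#' Expected squared imbalance of an incomplete block
#'
#' The mean of [imbalance_distribution()]: \eqn{E(\Delta^2 | r) = \sum_\ell
#' p(\ell | r) \ell}. For balanced allocation (`k = 1`) this equals
#' `r * (b - r) / (b - 1)`, which is maximal at `r = b/2`.
#'
#' @inheritParams imbalance_distribution
#' @return A non-negative number.
#' @examples
#' expected_imbalance(block_scheme(6), 3)  # 1.8
#' @export
expected_imbalance <- function(scheme, r) {
  d <- imbalance_distribution(scheme, r)
  sum(d$probs * d$support)
}

#' Average expected squared imbalance over final-block sizes
#'
#' Averages [expected_imbalance()] over `r = 1, ..., b`, i.e. assumes the
#' number of subjects in a centre's final block is uniform on `1..b` (the
#' complete block `r = b` contributes 0). This is the per-centre imbalance
#' used by the unequal-centres sample size formula. For `k = 1` it equals
#' `(b + 1) / 6`.
#'
#' @inheritParams imbalance_distribution
#' @return A non-negative number.
#' @examples
#' mean_expected_imbalance(block_scheme(6))  # 7/6
#' @export
mean_expected_imbalance <- function(scheme) {
  scheme <- as_block_scheme(scheme)
  mean(vapply(seq_len(scheme$b), function(r) expected_imbalance(scheme, r),
              numeric(1)))
}

#' Maximal expected squared imbalance
#'
#' [expected_imbalance()] evaluated at the worst final-block size
#' `r = b/(k+1)`, where a single-arm final block becomes possible. The upper
#' boundary sample size formula uses this most conservative value.
#'
#' @inheritParams imbalance_distribution
#' @return A non-negative number.
#' @examples
#' max_expected_imbalance(block_scheme(6))  # 1.8
#' @export
max_expected_imbalance <- function(scheme) {
  scheme <- as_block_scheme(scheme)
  expected_imbalance(scheme, scheme$n2)
}
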