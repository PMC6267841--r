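#' Permuted-block randomisation scheme
#'
#' Describes a permuted block of length `b` with a `k`:1 allocation ratio:
#' within every complete block exactly `k*b/(k+1)` subjects receive arm 1 and
#' `b/(k+1)` receive arm 2. The block length must therefore be a multiple of
#' `k + 1`.
#'
#' @param b block length, a positive integer divisible by `k + 1`.
#' @param k allocation parameter: `k` subjects on arm 1 per subject on arm 2
#'   (`k = 1` is balanced allocation).
#' @return An object of class `block_scheme` with elements `b`, `k`, and the
#'   per-block arm counts `n1 = k*b/(k+1)`, `n2 = b/(k+1)`.
#' @examples
#' block_scheme(6)        # 1:1 allocation, blocks of six
#' block_scheme(6, k = 2) # 2:1 allocation: four on arm 1, two on arm 2
#' @export
block_scheme <- function(b, k = 1L) {
  if (length(b) != 1L || !is.numeric(b) || b < 1 || b != round(b))
    stop("'b' must be a single positive integer", call. = FALSE)
  if (length(k) != 1L || !is.numeric(k) || k < 1 || k != round(k))
    stop("'k' must be a single positive integer", call. = FALSE)
  b <- as.integer(b); k <- as.integer(k)
  if (b %% (k + 1L) != 0L)
    stop(sprintf("block length b = %d is not divisible by k + 1 = %d; ",
                 b, k + 1L),
         "complete blocks cannot realise a ", k, ":1 allocation",
         call. = FALSE)
  structure(
    list(b = b, k = k, n1 = k * b %/% (k + 1L), n2 = b %/% (k + 1L)),
    class = "block_scheme"
  )
}

#' @export
print.block_scheme <- function(x, ...) {
  cat(sprintf("Permuted-block scheme: b = %d, allocation %d:1 (%d/%d per block)\n",
              x$b, x$k, x$n1, x$n2))
  invisible(x)
}

as_block_scheme <- function(x) {
  if (inherits(x, "block_scheme")) x else stop("expected a 'block_scheme'",
                                               call. = FALSE)
}

#' Enumerate all randomisation tuples of a block
#'
#' Lists every arm-label sequence of length `b` containing exactly
#' `k*b/(k+1)` entries on arm 1 -- the support of the uniform law from which
#' a permuted block is drawn. Intended for exact small-block computations and
#' as a brute-force oracle; the number of tuples, `choose(b, b/(k+1))`, grows
#' quickly, so enumeration is refused above `cap`.
#'
#' @param scheme a [block_scheme()].
#' @param cap largest block length accepted for enumeration (default 20).
#' @return An integer matrix with `choose(b, b/(k+1))` rows and `b` columns;
#'   entries are arm labels 1 or 2.
#' @examples
#' enumerate_block_tuples(block_scheme(4))      # the 6 balanced orderings
#' enumerate_block_tuples(block_scheme(3, k = 2))
#' @export
enumerate_block_tuples <- function(scheme, cap = 20L) {
  scheme <- as_block_scheme(scheme)
  if (scheme$b > cap)
    stop(sprintf("b = %d exceeds the enumeration cap (%d); ",
                 scheme$b, cap),
         "use the hypergeometric functions (imbalance_distribution) instead",
         call. = FALSE)
  pos1 <- utils::combn(scheme$b, scheme$n1)
  out <- matrix(2L, nrow = ncol(pos1), ncol = scheme$b)
  for (i in seq_len(ncol(pos1))) out[i, pos1[, i]] <- 1L
  out
}

#' Generate a block-randomised allocation sequence
#'
#' Builds an arm-label sequence of length `n` from `ceiling(n/b)` independent
#' uniformly permuted complete blocks, truncated to the first `n` entries.
#' Every complete block satisfies the `k`:1 ratio exactly; only a final
#' incomplete block (when `n` is not a multiple of `b`) can be imbalanced.
#'
#' @param scheme a [block_scheme()].
#' @param n number of subjects to allocate (positive integer).
#' @param seed optional integer seed; identical seeds give identical
#'   sequences.
#' @return An integer vector of length `n` with arm labels 1 or 2.
#' @examples
#' random_block_sequence(block_scheme(6), 9, seed = 1)
#' @export
random_block_sequence <- function(scheme, n, seed = NULL) {
  scheme <- as_block_scheme(scheme)
  if (length(n) != 1L || !is.numeric(n) || n < 1 || n != round(n))
    stop("'n' must be a single positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  b <- scheme$b
  template <- rep.int(c(1L, 2L), c(scheme$n1, scheme$n2))
  nblocks <- (n + b - 1L) %/% b
  seq_all <- unlist(lapply(seq_len(nblocks),
                           function(i) template[sample.int(b)]),
                    use.names = FALSE)
  seq_all[seq_len(n)]
}
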