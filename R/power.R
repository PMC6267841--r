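#' Monte-Carlo power estimation
#'
#' Repeats allocate -> simulate -> test: in every replicate the `N` subjects
#' are distributed over the `design$c` centres according to `scheme`
#' (multinomial schemes are redrawn each replicate), a trial is generated
#' under the design's random-intercept model, and the Wald test at
#' `design$alpha` is applied. The returned power is the rejection fraction;
#' with `mu = 0` in the design this is the empirical type-I error.
#' Replicate seeds are spawned deterministically from `seed`, so results are
#' reproducible.
#'
#' @param design a [design_spec()] (`mu = 0` allowed for null simulations).
#' @param N total sample size to simulate.
#' @param scheme subject-to-centre allocation: `"equal"`, `"unequal1"` or
#'   `"unequal2"`.
#' @param n_sim number of simulation replicates (default 10000).
#' @param seed master seed.
#' @return An object of class `power_estimate`: a list with `power`, `n_sim`,
#'   `mc_se = sqrt(power (1 - power) / n_sim)`, `alpha`, `N_used`, `scheme`
#'   and `seed`.
#' @examples
#' d <- design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 23)
#' estimate_power(d, N = 528, scheme = "unequal1", n_sim = 200, seed = 1)
#' @export
estimate_power <- function(design, N,
                           scheme = c("equal", "unequal1", "unequal2"),
                           n_sim = 10000L, seed = NULL) {
  stopifnot(inherits(design, "design_spec"),
            is.numeric(N), length(N) == 1L, N == round(N),
            is.numeric(n_sim), length(n_sim) == 1L, n_sim >= 1)
  scheme <- match.arg(scheme)
  if (N < max(4L, design$c))
    stop(sprintf("N = %d is too small for c = %d centres (need N >= max(4, c))",
                 N, design$c), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  n_sim <- as.integer(n_sim)
  rep_seeds <- sample.int(.Machine$integer.max, n_sim)
  equal_alloc <- if (scheme == "equal") allocate_equal(N, design$c)
  rejections <- 0L
  for (s in rep_seeds) {
    set.seed(s)
    alloc <- switch(scheme,
                    equal = equal_alloc,
                    unequal1 = allocate_unequal(N, design$c, 1L),
                    unequal2 = allocate_unequal(N, design$c, 2L))
    trial <- simulate_trial(design, alloc)
    if (wald_test(trial, design$alpha)$reject) rejections <- rejections + 1L
  }
  power <- rejections / n_sim
  structure(
    list(power = power, n_sim = n_sim,
         mc_se = sqrt(power * (1 - power) / n_sim),
         alpha = design$alpha, N_used = N, scheme = scheme, seed = seed),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Empirical power %.4f (MC SE %.4f) at N = %d, scheme %s, %d replicates\n",
    x$power, x$mc_se, x$N_used, x$scheme, x$n_sim))
  invisible(x)
}

#' Power over a grid of designs and sample size methods
#'
#' For each design and each sample size method, computes the method's total
#' sample size and then its Monte-Carlo power under the given allocation
#' scheme. Per-cell seeds are spawned from the master seed, so the grid is
#' reproducible and independent of evaluation order.
#'
#' @param designs a list of [design_spec()] objects (a single design is
#'   accepted).
#' @param methods character vector of methods understood by [sample_size()].
#' @param scheme allocation scheme passed to [estimate_power()].
#' @param n_sim replicates per cell.
#' @param seed master seed.
#' @return A long-format data.frame with one row per (design, method): `b`,
#'   `c`, `method`, `n_total`, `power`, `mc_se`, `n_sim`, `scheme`.
#' @export
power_grid <- function(designs, methods = c("lower", "mc_equal",
                                            "mc_unequal", "upper"),
                       scheme = "unequal1", n_sim = 10000L, seed = NULL) {
  if (inherits(designs, "design_spec")) designs <- list(designs)
  stopifnot(length(designs) >= 1, length(methods) >= 1)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(design = seq_along(designs), method = methods,
                       stringsAsFactors = FALSE)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- designs[[cells$design[i]]]
    res <- sample_size(d, cells$method[i])
    pw <- estimate_power(d, res$n_total, scheme = scheme, n_sim = n_sim,
                         seed = cell_seeds[i])
    data.frame(b = d$b, c = d$c, method = cells$method[i],
               n_total = res$n_total, power = pw$power, mc_se = pw$mc_se,
               n_sim = n_sim, scheme = scheme)
  })
  do.call(rbind, rows)
}
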