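new_sample_size_result <- function(method, n_raw, sum_expected_imbalance,
                                   design, r1_star = NA_integer_) {
  structure(
    list(method = method,
         n_total = as.integer(ceiling(n_raw)),
         n_raw = n_raw,
         sum_expected_imbalance = sum_expected_imbalance,
         r1_star = r1_star,
         design = design),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  labels <- c(lower = "lower boundary",
              mc_equal = "equal centres",
              mc_unequal = "unequal centres",
              upper = "upper boundary",
              mc_custom = "custom imbalance")
  cat(sprintf("Total sample size (%s): N = %d  (unrounded %.3f)\n",
              labels[[x$method]], x$n_total, x$n_raw))
  if (x$sum_expected_imbalance > 0)
    cat(sprintf("  sum of expected squared imbalances: %.4f\n",
                x$sum_expected_imbalance))
  if (!is.na(x$r1_star))
    cat(sprintf("  assumed final-block size r1* = %d\n", x$r1_star))
  invisible(x)
}

quantile_sum <- function(design) {
  qnorm(1 - design$alpha / 2) + qnorm(1 - design$beta)
}

#' Lower-boundary sample size (balanced allocation)
#'
#' The classical normal-approximation sample size for a two-sample comparison
#' with `k`:1 allocation,
#' \deqn{N = \frac{\sigma^2 (k+1)^2}{k}
#'       \left(\frac{q_{1-\alpha/2} + q_{1-\beta}}{\mu}\right)^2,}
#' rounded up. Under perfectly balanced allocation per centre the centre
#' effects cancel from the treatment-effect variance, so this is a lower
#' boundary for the block-randomised multi-centre trial: it ignores
#' `tau2`, `b` and `c` entirely.
#'
#' @param design a [design_spec()].
#' @return A `sample_size_result` with `method = "lower"`.
#' @examples
#' n_lower(design_spec(mu = 1, sigma2 = 16, tau2 = 16))$n_total  # 503
#' @export
n_lower <- function(design) {
  check_design_for_samplesize(design)
  k <- design$k
  n_raw <- design$sigma2 * (k + 1)^2 / k * (quantile_sum(design) / design$mu)^2
  new_sample_size_result("lower", n_raw, 0, design)
}

#' General multi-centre sample size for a given total expected imbalance
#'
#' Solves the power equation of the random-intercept Wald test for `N` when
#' the sum over centres of the expected squared imbalances,
#' `S = sum_j E(Delta^2 | r_j)`, is supplied:
#' \deqn{N = A\left(\frac{\sigma^2 (k+1)^2}{2k} +
#'   \sqrt{\frac{\sigma^4 (k+1)^4}{4k^2} +
#'         \frac{\tau^2 (k+1)^2 \mu^2 S}{(q_{1-\alpha/2}+q_{1-\beta})^2}}
#'   \right),\quad A = \left(\frac{q_{1-\alpha/2}+q_{1-\beta}}{\mu}\right)^2.}
#' With `S = 0` (or `tau2 = 0`) this collapses to [n_lower()]. The named
#' formulas [n_mc_equal()], [n_mc_unequal()] and [n_upper()] differ only in
#' how they specify `S` before recruitment.
#'
#' @param design a [design_spec()].
#' @param sum_expected_imbalance total expected squared imbalance `S` (>= 0).
#' @param method label stored in the result (internal use).
#' @param r1_star final-block size stored in the result (internal use).
#' @return A `sample_size_result`.
#' @export
n_mc_general <- function(design, sum_expected_imbalance,
                         method = "mc_custom", r1_star = NA_integer_) {
  check_design_for_samplesize(design)
  S <- sum_expected_imbalance
  if (length(S) != 1L || !is.numeric(S) || S < 0)
    stop("'sum_expected_imbalance' must be a single non-negative number",
         call. = FALSE)
  k <- design$k
  q <- quantile_sum(design)
  A <- (q / design$mu)^2
  half <- design$sigma2 * (k + 1)^2 / (2 * k)
  inner <- half^2 + design$tau2 * (k + 1)^2 * design$mu^2 * S / q^2
  n_raw <- A * (half + sqrt(inner))
  new_sample_size_result(method, n_raw, S, design, r1_star)
}

#' Sample size for unequal centre sizes
#'
#' Takes the per-centre expected squared imbalance as the average of
#' `E(Delta^2 | r)` over final-block sizes `r = 1..b` (i.e. assumes `r_j`
#' uniform on `1..b`), so `S = c * mean_expected_imbalance(b, k)`.
#'
#' @param design a [design_spec()].
#' @return A `sample_size_result` with `method = "mc_unequal"`.
#' @examples
#' d <- design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 23)
#' n_mc_unequal(d)$n_total  # 528
#' @export
n_mc_unequal <- function(design) {
  check_design_for_samplesize(design)
  S <- design$c * mean_expected_imbalance(design$scheme)
  n_mc_general(design, S, method = "mc_unequal")
}

#' Upper-boundary sample size (maximal expected imbalance)
#'
#' The most conservative calculation: every centre is assumed to stop at the
#' worst final-block size `r = b/(k+1)`, so
#' `S = c * max_expected_imbalance(b, k)`.
#'
#' @param design a [design_spec()].
#' @return A `sample_size_result` with `method = "upper"`.
#' @examples
#' d <- design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 23)
#' n_upper(d)$n_total  # 541
#' @export
n_upper <- function(design) {
  check_design_for_samplesize(design)
  S <- design$c * max_expected_imbalance(design$scheme)
  n_mc_general(design, S, method = "upper")
}

#' Sample size for equally sized centres
#'
#' When all centres are assumed equally large, the final-block size `r1` is
#' the same in every centre but depends on the very sample size being
#' computed. For each candidate `r1 = 1..b` the sample size
#' `N(r1) = n_mc_general(design, c * E(Delta^2 | r1))` is computed, and the
#' self-consistent candidate is chosen as
#' \deqn{r_1^* = \arg\min_{r_1} \left| (N(r_1)/c \bmod b) - r_1 \right|}
#' using the unrounded `N(r1)` and real-valued modulus; ties are broken
#' toward the smallest `N(r1)`.
#'
#' @param design a [design_spec()].
#' @return A `sample_size_result` with `method = "mc_equal"` and the selected
#'   `r1_star`.
#' @examples
#' d <- design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 23)
#' n_mc_equal(d)$n_total  # 525, with r1_star = 5
#' @export
n_mc_equal <- function(design) {
  check_design_for_samplesize(design)
  b <- design$b
  r1 <- seq_len(b)
  n_raw <- vapply(r1, function(r) {
    S <- design$c * expected_imbalance(design$scheme, r)
    n_mc_general(design, S)$n_raw
  }, numeric(1))
  dist <- abs((n_raw / design$c) %% b - r1)
  near <- which(dist <= min(dist) + 1e-9)
  pick <- near[which.min(n_raw[near])]
  new_sample_size_result("mc_equal", n_raw[pick],
                         design$c * expected_imbalance(design$scheme,
                                                       r1[pick]),
                         design, r1_star = r1[pick])
}

#' Compute a sample size by method name
#'
#' @param design a [design_spec()].
#' @param method one of `"lower"`, `"mc_equal"` (alias `"equal"`),
#'   `"mc_unequal"` (alias `"unequal"`), `"upper"`.
#' @return A `sample_size_result`.
#' @export
sample_size <- function(design, method = c("mc_unequal", "lower", "mc_equal",
                                           "upper", "equal", "unequal")) {
  method <- match.arg(method)
  switch(method,
         lower = n_lower(design),
         equal = , mc_equal = n_mc_equal(design),
         unequal = , mc_unequal = n_mc_unequal(design),
         upper = n_upper(design))
}

#' Sample size table over block lengths and centre counts
#'
#' Evaluates all four formulas on a grid of block lengths and centre counts,
#' keeping the other design parameters fixed. With the defaults this
#' reproduces the worked comparison for `mu = 1`, `sigma = 4`, ICC 0.5.
#'
#' @param design a [design_spec()]; its `b` and `c` are replaced by the grid.
#' @param b_values block lengths to tabulate.
#' @param c_values centre counts to tabulate.
#' @param methods subset of `c("lower", "mc_equal", "mc_unequal", "upper")`.
#' @return A data.frame with columns `b`, `c`, `method`, `n_total`, `n_raw`,
#'   `sum_expected_imbalance`, `r1_star`.
#' @examples
#' d <- design_from_icc(mu = 1, sigma = 4, icc = 0.5)
#' head(sample_size_table(d, b_values = 6, c_values = c(23, 46, 92)))
#' @export
sample_size_table <- function(design,
                              b_values = c(6L, 8L, 16L),
                              c_values = c(23L, 46L, 92L),
                              methods = c("lower", "mc_equal",
                                          "mc_unequal", "upper")) {
  check_design_for_samplesize(design)
  grid <- expand.grid(method = methods, c = c_values, b = b_values,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- design_spec(mu = design$mu, sigma2 = design$sigma2,
                     tau2 = design$tau2, alpha = design$alpha,
                     beta = design$beta, k = design$k,
                     b = grid$b[i], c = grid$c[i])
    res <- sample_size(d, grid$method[i])
    data.frame(b = grid$b[i], c = grid$c[i], method = grid$method[i],
               n_total = res$n_total, n_raw = res$n_raw,
               sum_expected_imbalance = res$sum_expected_imbalance,
               r1_star = res$r1_star)
  })
  do.call(rbind, rows)
}
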