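# Per-(arm, centre) summary of a trial dataset: counts, sums, sums of squares.
# Returns a list with 2 x c matrices n, sum, sumsq (row = arm, col = centre).
cell_summaries <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("centre", "arm", "outcome") %in% names(data)))
  c_ <- max(data$centre)
  idx <- (data$arm - 1L) * c_ + data$centre  # cell index in 1..2c
  dims <- c(2L * c_)
  n <- array(0, dims); s <- array(0, dims); s2 <- array(0, dims)
  tab <- rowsum(cbind(1, data$outcome, data$outcome^2), idx)
  at <- as.integer(rownames(tab))
  n[at] <- tab[, 1]; s[at] <- tab[, 2]; s2[at] <- tab[, 3]
  list(n = matrix(n, nrow = 2L, byrow = TRUE),
       sum = matrix(s, nrow = 2L, byrow = TRUE),
       sumsq = matrix(s2, nrow = 2L, byrow = TRUE),
       c = c_)
}

#' Treatment effect estimate
#'
#' The difference of overall arm means, \eqn{\hat\mu = \bar Y_{2..} - \bar
#' Y_{1..}}, each subject weighted equally (pooled over centres). This
#' estimator is unbiased even when some centres recruit for one arm only.
#'
#' @param data a `trial_dataset` (or any data.frame with columns `centre`,
#'   `arm`, `outcome`).
#' @return The estimated effect, a single number.
#' @export
estimate_effect <- function(data) {
  cs <- cell_summaries(data)
  N_i <- rowSums(cs$n)
  if (any(N_i == 0))
    stop("cannot estimate the treatment effect: arm ",
         which(N_i == 0)[1], " has no subjects", call. = FALSE)
  sum(cs$sum[2, ]) / N_i[2] - sum(cs$sum[1, ]) / N_i[1]
}

#' Moment estimators of the variance components
#'
#' Closed-form quadratic-form estimators of the residual and between-centre
#' variances:
#' \itemize{
#'   \item `sigma2_hat`: the average over all (arm, centre) cells with at
#'     least two subjects of the within-cell sample variance;
#'   \item `tau2_hat`: for each arm, the sample variance of the non-empty
#'     centre means around that arm's overall mean (divisor: non-empty centre
#'     count minus one), averaged over the two arms.
#' }
#' Cells with fewer than two subjects are excluded from `sigma2_hat` and the
#' divisor adjusted; empty cells are excluded from `tau2_hat`. This keeps the
#' estimators defined under multinomial centre sizes, and reduces to the
#' all-cells form when every cell is complete.
#'
#' @inheritParams estimate_effect
#' @return A named list with `sigma2_hat` and `tau2_hat` (both >= 0 by
#'   construction).
#' @export
estimate_variance_components <- function(data) {
  cs <- cell_summaries(data)
  eligible <- cs$n >= 2
  if (!any(eligible))
    stop("sigma2 estimation needs at least one (arm, centre) cell ",
         "with two or more subjects", call. = FALSE)
  cellvar <- (cs$sumsq[eligible] -
                cs$sum[eligible]^2 / cs$n[eligible]) / (cs$n[eligible] - 1)
  sigma2_hat <- mean(pmax(cellvar, 0))

  tau2_arm <- numeric(2)
  for (i in 1:2) {
    nonempty <- cs$n[i, ] > 0
    ci <- sum(nonempty)
    if (ci < 2)
      stop("tau2 estimation needs at least two non-empty centres in arm ", i,
           call. = FALSE)
    cmeans <- cs$sum[i, nonempty] / cs$n[i, nonempty]
    arm_mean <- sum(cs$sum[i, ]) / sum(cs$n[i, ])
    tau2_arm[i] <- sum((cmeans - arm_mean)^2) / (ci - 1)
  }
  list(sigma2_hat = sigma2_hat, tau2_hat = mean(tau2_arm))
}

#' Variance of the treatment effect estimator
#'
#' Under the random-intercept covariance structure
#' \eqn{\bigoplus_j (\sigma^2 I + \tau^2 J)}, the pooled mean difference has
#' \deqn{Var(\hat\mu) = \sigma^2 \frac{N}{N_1 N_2} + \tau^2 \sum_j
#'       \left(\frac{n_{1j}}{N_1} - \frac{n_{2j}}{N_2}\right)^2.}
#' Under perfectly balanced allocation the second term vanishes and the
#' variance reduces to `4 * sigma2 / N` (for 1:1 allocation).
#'
#' @param sigma2,tau2 variance components.
#' @param n1,n2 per-centre subject counts for arms 1 and 2 (equal lengths).
#' @return The variance, a positive number.
#' @export
var_mu_hat <- function(sigma2, tau2, n1, n2) {
  stopifnot(length(n1) == length(n2), all(n1 >= 0), all(n2 >= 0))
  N1 <- sum(n1); N2 <- sum(n2)
  if (N1 == 0 || N2 == 0)
    stop("both arms must contain at least one subject", call. = FALSE)
  sigma2 * (N1 + N2) / (N1 * N2) + tau2 * sum((n1 / N1 - n2 / N2)^2)
}

#' Wald test for a treatment effect in a multi-centre trial
#'
#' Estimates the effect and variance components from the data, plugs them
#' with the observed per-centre arm counts into [var_mu_hat()], and compares
#' `T = mu_hat / sqrt(Var)` with the standard normal reference. The null
#' hypothesis of no treatment effect is rejected when `|T|` exceeds
#' `qnorm(1 - alpha/2)` (strict inequality).
#'
#' @inheritParams estimate_effect
#' @param alpha two-sided significance level.
#' @return An object of class `analysis_result`: a list with `mu_hat`,
#'   `sigma2_hat`, `tau2_hat`, `var_mu_hat`, `t_stat`, `p_value`, `reject`
#'   and `alpha`.
#' @examples
#' d <- design_spec(mu = 2, sigma2 = 4, tau2 = 1, b = 6, c = 8)
#' trial <- simulate_trial(d, allocate_equal(160, 8), seed = 7)
#' wald_test(trial)
#' @export
wald_test <- function(data, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  cs <- cell_summaries(data)
  N_i <- rowSums(cs$n)
  if (any(N_i == 0))
    stop("cannot test: arm ", which(N_i == 0)[1], " has no subjects",
         call. = FALSE)
  mu_hat <- sum(cs$sum[2, ]) / N_i[2] - sum(cs$sum[1, ]) / N_i[1]
  vc <- estimate_variance_components(data)
  v <- var_mu_hat(vc$sigma2_hat, vc$tau2_hat, cs$n[1, ], cs$n[2, ])
  t_stat <- mu_hat / sqrt(v)
  p <- 2 * pnorm(-abs(t_stat))
  structure(
    list(mu_hat = mu_hat, sigma2_hat = vc$sigma2_hat,
         tau2_hat = vc$tau2_hat, var_mu_hat = v, t_stat = t_stat,
         p_value = p, reject = abs(t_stat) > qnorm(1 - alpha / 2),
         alpha = alpha),
    class = "analysis_result"
  )
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("Random-intercept Wald test (normal approximation)\n")
  cat(sprintf("  mu_hat = %.4f, SE = %.4f, T = %.3f, p = %.4g\n",
              x$mu_hat, sqrt(x$var_mu_hat), x$t_stat, x$p_value))
  cat(sprintf("  sigma2_hat = %.4f, tau2_hat = %.4f\n",
              x$sigma2_hat, x$tau2_hat))
  cat(sprintf("  H0 %s at alpha = %g\n",
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}
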