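#' Trial design specification
#'
#' Bundles the planning parameters of a two-arm multi-centre trial analysed
#' with a random-intercept model: the outcome is
#' \eqn{Y = \mu_0 + u_j + \mu 1\{arm = 2\} + \epsilon}, with centre effects
#' \eqn{u_j \sim N(0, \tau^2)} and residuals \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' The sample size formulas require `mu != 0` and `sigma2 > 0`; the simulator
#' accepts the degenerate values `mu = 0` (null-hypothesis data, type-I error
#' studies) and `sigma2 = 0` (noise-free checks).
#'
#' @param mu assumed treatment effect, in outcome units.
#' @param sigma2 residual variance \eqn{\sigma^2} (outcome units squared).
#' @param tau2 between-centre variance \eqn{\tau^2} (>= 0).
#' @param alpha two-sided type-I error rate, in (0, 1).
#' @param beta type-II error rate, in (0, 1); target power is `1 - beta`.
#' @param k allocation parameter of the `k`:1 randomisation.
#' @param b block length (multiple of `k + 1`).
#' @param c number of study centres (>= 1).
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 23)
#' @export
design_spec <- function(mu, sigma2, tau2, alpha = 0.05, beta = 0.2,
                        k = 1L, b = 6L, c = 1L) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma2), length(sigma2) == 1L, sigma2 >= 0,
            is.numeric(tau2), length(tau2) == 1L, tau2 >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
            is.numeric(c), length(c) == 1L, c >= 1, c == round(c))
  scheme <- block_scheme(b, k)  # validates b mod (k+1) = 0
  structure(
    list(mu = mu, sigma2 = sigma2, tau2 = tau2, alpha = alpha, beta = beta,
         k = scheme$k, b = scheme$b, c = as.integer(c), scheme = scheme),
    class = "design_spec"
  )
}

#' Build a design from standard deviation and intraclass correlation
#'
#' Converts the (sigma, ICC) parameterisation into variance components via
#' `sigma2 = sigma^2` and `tau2 = icc * sigma^2 / (1 - icc)`, where the ICC is
#' \eqn{\rho = \tau^2 / (\tau^2 + \sigma^2)}.
#'
#' @param mu assumed treatment effect.
#' @param sigma residual standard deviation (> 0).
#' @param icc intraclass correlation in `[0, 1)`.
#' @inheritParams design_spec
#' @return A [design_spec()].
#' @examples
#' design_from_icc(mu = 1, sigma = 4, icc = 0.5, b = 6, c = 23)  # tau2 = 16
#' @export
design_from_icc <- function(mu, sigma, icc, alpha = 0.05, beta = 0.2,
                            k = 1L, b = 6L, c = 1L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(icc), length(icc) == 1L, icc >= 0)
  if (icc >= 1)
    stop("'icc' must be below 1", call. = FALSE)
  design_spec(mu = mu, sigma2 = sigma^2, tau2 = icc * sigma^2 / (1 - icc),
              alpha = alpha, beta = beta, k = k, b = b, c = c)
}

#' Intraclass correlation of a design
#'
#' @param design a [design_spec()].
#' @return \eqn{\rho = \tau^2 / (\tau^2 + \sigma^2)} (0 when both variances
#'   vanish).
#' @export
icc <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  tot <- design$tau2 + design$sigma2
  if (tot == 0) 0 else design$tau2 / tot
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Multi-centre trial design\n")
  cat(sprintf("  effect mu = %g, sigma2 = %g, tau2 = %g (ICC = %.3f)\n",
              x$mu, x$sigma2, x$tau2, icc(x)))
  cat(sprintf("  alpha = %g (two-sided), power = %g\n", x$alpha, 1 - x$beta))
  cat(sprintf("  centres c = %d, block length b = %d, allocation %d:1\n",
              x$c, x$b, x$k))
  invisible(x)
}

# sample-size formulas need a proper alternative and residual noise
check_design_for_samplesize <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  if (design$mu == 0)
    stop("sample size calculation requires a non-zero treatment effect",
         call. = FALSE)
  if (design$sigma2 <= 0)
    stop("sample size calculation requires sigma2 > 0", call. = FALSE)
  invisible(design)
}
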