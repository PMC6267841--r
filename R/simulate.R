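new_centre_allocation <- function(n_by_centre, scheme, seed = NULL) {
  structure(
    list(n_by_centre = as.integer(n_by_centre), scheme = scheme, seed = seed),
    class = "centre_allocation"
  )
}

#' Subject-to-centre allocation
#'
#' `centre_allocation()` wraps a user-supplied vector of per-centre sample
#' sizes; `allocate_equal()` and `allocate_unequal()` construct the standard
#' schemes. Centres may receive zero subjects under the multinomial schemes;
#' they are retained (the number of centres stays fixed) and simply contribute
#' nothing downstream.
#'
#' @param n_by_centre non-negative integer vector of per-centre sample sizes.
#' @return A `centre_allocation` object with elements `n_by_centre`, `scheme`
#'   (label) and `seed`.
#' @export
centre_allocation <- function(n_by_centre) {
  stopifnot(is.numeric(n_by_centre), length(n_by_centre) >= 1,
            all(n_by_centre >= 0), all(n_by_centre == round(n_by_centre)))
  new_centre_allocation(n_by_centre, "custom")
}

#' @export
print.centre_allocation <- function(x, ...) {
  cat(sprintf("Centre allocation (%s): N = %d over %d centres\n",
              x$scheme, sum(x$n_by_centre), length(x$n_by_centre)))
  print(x$n_by_centre)
  invisible(x)
}

#' @rdname centre_allocation
#' @param N total sample size.
#' @param c number of centres (`N >= c` required for the equal scheme).
#' @details The equal scheme gives each centre `floor(N/c)` subjects and the
#'   first `N mod c` centres one extra.
#' @examples
#' allocate_equal(10, 3)  # 4, 3, 3
#' @export
allocate_equal <- function(N, c) {
  stopifnot(is.numeric(N), length(N) == 1L, N == round(N),
            is.numeric(c), length(c) == 1L, c >= 1, c == round(c))
  if (N < c)
    stop("equal allocation needs N >= c (at least one subject per centre)",
         call. = FALSE)
  n <- rep.int(N %/% c, c)
  m <- N %% c
  if (m > 0) n[seq_len(m)] <- n[seq_len(m)] + 1L
  new_centre_allocation(n, "equal")
}

#' @rdname centre_allocation
#' @param variant `1`: multinomial with equal cell probabilities `1/c`
#'   ("Unequal 1"); `2`: cell probabilities are themselves random, obtained by
#'   normalising `c` iid uniform(0, 1) weights ("Unequal 2").
#' @param seed optional integer seed for reproducibility.
#' @examples
#' allocate_unequal(100, 5, variant = 2, seed = 1)
#' @export
allocate_unequal <- function(N, c, variant = 1L, seed = NULL) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == round(N),
            is.numeric(c), length(c) == 1L, c >= 1, c == round(c))
  if (!variant %in% c(1L, 2L))
    stop("'variant' must be 1 or 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- if (variant == 1L) rep.int(1 / c, c) else {
    w <- runif(c)
    w / sum(w)
  }
  n <- as.integer(rmultinom(1L, N, p))
  new_centre_allocation(n, paste0("unequal", variant), seed)
}

#' Simulate a multi-centre trial
#'
#' Generates one trial under the random-intercept model: each centre `j`
#' receives a random effect `u_j ~ N(0, tau2)`, its `n_j` subjects are
#' allocated to arms by an independent permuted-block sequence
#' ([random_block_sequence()]), and outcomes are
#' `Y = mu0 + u_j + mu * 1{arm = 2} + eps`, `eps ~ N(0, sigma2)`.
#' Each centre draws its block sequence from its own stream derived from the
#' master seed, mirroring centre-stratified randomisation.
#'
#' @param design a [design_spec()]; `mu = 0` and `sigma2 = 0` are allowed
#'   here (null-hypothesis and noise-free data).
#' @param allocation a `centre_allocation` whose length equals `design$c`.
#' @param mu0 fixed intercept (cancels from all contrasts; default 0).
#' @param seed optional integer seed.
#' @return A data.frame of class `trial_dataset` with columns `centre`
#'   (1..c), `arm` (1 or 2) and `outcome`; the generating parameters and
#'   per-centre effects are kept in `attr(x, "truth")`.
#' @examples
#' d <- design_spec(mu = 1, sigma2 = 16, tau2 = 16, b = 6, c = 4)
#' head(simulate_trial(d, allocate_equal(40, 4), seed = 1))
#' @export
simulate_trial <- function(design, allocation, mu0 = 0, seed = NULL) {
  stopifnot(inherits(design, "design_spec"),
            inherits(allocation, "centre_allocation"))
  n <- allocation$n_by_centre
  if (length(n) != design$c)
    stop(sprintf("allocation has %d centres but the design specifies c = %d",
                 length(n), design$c), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  c_ <- design$c
  N <- sum(n)
  # master stream: per-centre randomisation seeds, centre effects, residuals
  centre_seeds <- sample.int(.Machine$integer.max, c_)
  u <- rnorm(c_, 0, sqrt(design$tau2))
  eps <- rnorm(N, 0, sqrt(design$sigma2))
  arm <- integer(N)
  pos <- 0L
  for (j in seq_len(c_)) {
    if (n[j] == 0L) next
    arm[pos + seq_len(n[j])] <-
      random_block_sequence(design$scheme, n[j], centre_seeds[j])
    pos <- pos + n[j]
  }
  centre <- rep.int(seq_len(c_), n)
  out <- data.frame(
    centre = centre,
    arm = arm,
    outcome = mu0 + u[centre] + design$mu * (arm == 2L) + eps
  )
  attr(out, "truth") <- list(mu0 = mu0, mu = design$mu,
                             sigma2 = design$sigma2, tau2 = design$tau2,
                             u_by_centre = u)
  class(out) <- c("trial_dataset", "data.frame")
  out
}
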