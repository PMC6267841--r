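ex_design <- function(b = 6, c = 23, tau2 = 16, mu = 1, k = 1)
  design_spec(mu = mu, sigma2 = 16, tau2 = tau2, alpha = 0.05, beta = 0.2,
              k = k, b = b, c = c)

test_that("lower boundary reproduces the classical two-sample size", {
  expect_equal(n_lower(ex_design())$n_total, 503L)
  # no dependence on tau2, b, c
  expect_equal(n_lower(ex_design(b = 16, c = 92, tau2 = 100))$n_total, 503L)
  expect_equal(n_lower(ex_design(tau2 = 0))$n_total, 503L)
  # 3:1 allocation inflates by (k+1)^2/(4k)
  expect_equal(n_lower(design_spec(1, 16, 16, k = 3, b = 8, c = 5))$n_total,
               670L)
  expect_error(n_lower(ex_design(mu = 0)), "non-zero treatment effect")
})

test_that("the general formula collapses and matches hand-computed values", {
  d <- ex_design()
  expect_equal(n_mc_general(d, 0)$n_raw, n_lower(d)$n_raw)
  expect_equal(n_mc_general(ex_design(tau2 = 0), 100)$n_total, 503L)
  # upper boundary b=6, c=23 via explicit S = 23 * 1.8
  expect_equal(n_mc_general(d, 23 * 1.8)$n_total, 541L)
  expect_error(n_mc_general(d, -1), "non-negative")
})

test_that("unequal-centres and upper-boundary formulas reproduce the printed grid", {
  cells <- list(list(b = 6, c = 23, unequal = 528L, upper = 541L),
                list(b = 6, c = 46, unequal = 552L, upper = 575L),
                list(b = 6, c = 92, unequal = 594L, upper = 634L),
                list(b = 8, c = 23, unequal = 535L, upper = 551L),
                list(b = 8, c = 46, unequal = 564L, upper = 592L),
                list(b = 8, c = 92, unequal = 616L, upper = 662L),
                list(b = 16, c = 23, unequal = 561L, upper = 587L),
                list(b = 16, c = 46, unequal = 610L, upper = 654L),
                list(b = 16, c = 92, unequal = 692L, upper = 762L))
  for (cell in cells) {
    d <- ex_design(b = cell$b, c = cell$c)
    expect_equal(n_mc_unequal(d)$n_total, cell$unequal)
    expect_equal(n_upper(d)$n_total, cell$upper)
  }
})

test_that("equal-centres search selects a self-consistent final-block size", {
  r6 <- n_mc_equal(ex_design(b = 6, c = 23))
  expect_equal(r6$n_total, 525L)
  expect_equal(r6$r1_star, 5L)
  r16 <- n_mc_equal(ex_design(b = 16, c = 23))
  expect_equal(r16$n_total, 586L)
  expect_equal(r16$r1_star, 9L)
  # without centre heterogeneity every candidate collapses to the lower bound
  expect_equal(n_mc_equal(ex_design(tau2 = 0))$n_total, 503L)
})

test_that("methods are ordered and monotone in the design parameters", {
  for (b in c(6, 8, 16)) for (c_ in c(23, 92)) {
    d <- ex_design(b = b, c = c_)
    lo <- n_lower(d)$n_raw
    un <- n_mc_unequal(d)$n_raw
    up <- n_upper(d)$n_raw
    expect_lte(lo, un)
    expect_lte(un, up)
    expect_lte(n_mc_equal(d)$n_raw, up + 1e-9)
  }
  # non-decreasing in tau2, c, b; non-increasing in |mu|
  n_tau <- vapply(c(0, 4, 16, 64),
                  function(t2) n_mc_unequal(ex_design(tau2 = t2))$n_raw,
                  numeric(1))
  expect_true(all(diff(n_tau) >= 0))
  n_c <- vapply(c(10, 23, 46, 92),
                function(cc) n_upper(ex_design(c = cc))$n_raw, numeric(1))
  expect_true(all(diff(n_c) >= 0))
  n_b <- vapply(c(6, 8, 16),
                function(bb) n_mc_unequal(ex_design(b = bb))$n_raw,
                numeric(1))
  expect_true(all(diff(n_b) >= 0))
  n_mu <- vapply(c(0.5, 1, 2),
                 function(m) n_mc_unequal(ex_design(mu = m))$n_raw,
                 numeric(1))
  expect_true(all(diff(n_mu) <= 0))
})

test_that("ICC parameterisation converts to variance components", {
  d <- design_from_icc(mu = 1, sigma = 4, icc = 0.5, b = 6, c = 23)
  expect_equal(d$sigma2, 16)
  expect_equal(d$tau2, 16)
  expect_equal(icc(d), 0.5)
  expect_equal(design_from_icc(1, 4, 0)$tau2, 0)
  expect_equal(design_from_icc(1, 2, 0.2)$tau2, 1)
  expect_error(design_from_icc(1, 4, 1), "below 1")
  expect_error(design_from_icc(1, -4, 0.5))
})

test_that("the sample size table covers the full method-by-design grid", {
  tab <- sample_size_table(ex_design())
  expect_equal(nrow(tab), 36L)
  expect_setequal(unique(tab$method),
                  c("lower", "mc_equal", "mc_unequal", "upper"))
  expect_true(all(tab$n_total == ceiling(tab$n_raw)))
  expect_true(all(tab$n_total[tab$method == "lower"] == 503L))
})
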