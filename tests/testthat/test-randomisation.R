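test_that("block schemes validate the divisibility constraint", {
  s <- block_scheme(6, 1)
  expect_equal(s$n1, 3L)
  expect_equal(s$n2, 3L)
  expect_equal(block_scheme(6, 2)$n1, 4L)
  expect_error(block_scheme(5, 1), "not divisible")
  expect_error(block_scheme(6, 3), "not divisible")
  expect_error(block_scheme(0, 1), "positive integer")
  expect_error(block_scheme(6, -1), "positive integer")
})

test_that("block tuple enumeration lists exactly the balanced orderings", {
  t2 <- enumerate_block_tuples(block_scheme(2))
  expect_equal(t2[order(t2[, 1]), ], rbind(c(1L, 2L), c(2L, 1L)))

  t4 <- enumerate_block_tuples(block_scheme(4))
  expect_equal(nrow(t4), 6L)
  expect_true(all(rowSums(t4 == 1) == 2))
  expect_equal(nrow(unique(t4)), 6L)

  t32 <- enumerate_block_tuples(block_scheme(3, 2))
  expect_equal(nrow(t32), 3L)
  expect_true(all(rowSums(t32 == 1) == 2))

  # cardinality contract: choose(b, b/(k+1))
  for (i in seq_len(nrow(scheme_grid(8)))) {
    g <- scheme_grid(8)[i, ]
    expect_equal(nrow(enumerate_block_tuples(block_scheme(g$b, g$k))),
                 choose(g$b, g$b / (g$k + 1)))
  }
  expect_error(enumerate_block_tuples(block_scheme(22), cap = 20),
               "enumeration cap")
})

test_that("imbalance pmf matches known small cases and rejects bad r", {
  s6 <- block_scheme(6)
  d <- imbalance_distribution(s6, 6)
  expect_equal(d$support, 0)
  expect_equal(d$probs, 1)

  d1 <- imbalance_distribution(s6, 1)
  expect_equal(d1$support, 1)
  expect_equal(d1$probs, 1)

  d3 <- imbalance_distribution(s6, 3)
  expect_equal(d3$support, c(1, 9))
  expect_equal(d3$probs, c(0.9, 0.1))

  d32 <- imbalance_distribution(block_scheme(3, 2), 1)
  expect_equal(d32$support, c(0.25, 1))
  expect_equal(d32$probs, c(2 / 3, 1 / 3))

  expect_error(imbalance_distribution(s6, 0), "integer in")
  expect_error(imbalance_distribution(s6, 7), "integer in")
})

test_that("imbalance pmfs agree with brute-force enumeration", {
  grid <- scheme_grid(10)
  for (i in seq_len(nrow(grid))) {
    s <- block_scheme(grid$b[i], grid$k[i])
    for (r in seq_len(s$b)) {
      got <- imbalance_distribution(s, r)
      want <- oracle_imbalance_pmf(s$b, s$k, r)
      expect_equal(got$support, want$support, tolerance = 1e-12)
      expect_equal(got$probs, want$probs, tolerance = 1e-12)
      expect_equal(sum(got$probs), 1, tolerance = 1e-12)
      expect_true(all(got$support >= 0 &
                        got$support <= s$b^2 / (s$k + 1)^2))
    }
  }
})

test_that("expected imbalance has the balanced-allocation closed forms", {
  s6 <- block_scheme(6)
  expect_equal(expected_imbalance(s6, 6), 0)
  expect_equal(expected_imbalance(s6, 3), 1.8)
  expect_equal(expected_imbalance(block_scheme(8), 4), 16 / 7)
  expect_equal(mean_expected_imbalance(block_scheme(2)), 0.5)
  expect_equal(mean_expected_imbalance(s6), 7 / 6)
  expect_equal(mean_expected_imbalance(block_scheme(8)), 1.5)
  expect_equal(max_expected_imbalance(block_scheme(2)), 1)
  expect_equal(max_expected_imbalance(s6), 1.8)
  expect_equal(max_expected_imbalance(block_scheme(16)), 64 / 15)

  for (b in seq(4, 20, by = 2)) {
    s <- block_scheme(b)
    ev <- vapply(1:b, function(r) expected_imbalance(s, r), numeric(1))
    expect_equal(ev, vapply(1:b, function(r) r * (b - r) / (b - 1),
                            numeric(1)))
    # symmetry and maximum at the half block
    expect_equal(ev[1:(b - 1)], rev(ev[1:(b - 1)]))
    expect_equal(which.max(ev), b / 2)
    expect_equal(mean_expected_imbalance(s), (b + 1) / 6)
  }
})

test_that("block sequences are exactly balanced per complete block", {
  s6 <- block_scheme(6)
  x <- random_block_sequence(s6, 12, seed = 11)
  expect_equal(sum(x == 1), 6L)
  expect_equal(sum(x == 2), 6L)

  y <- random_block_sequence(s6, 9, seed = 12)
  expect_equal(sum(y[1:6] == 1), 3L)
  expect_length(y, 9L)

  z <- random_block_sequence(block_scheme(6, 2), 18, seed = 3)
  expect_equal(sum(z == 1), 12L)

  expect_identical(random_block_sequence(s6, 7, seed = 99),
                   random_block_sequence(s6, 7, seed = 99))
  expect_error(random_block_sequence(s6, 0), "positive integer")
})

test_that("empirical imbalance of truncated sequences matches the exact pmf", {
  s6 <- block_scheme(6)
  nrep <- 20000
  set.seed(2024)
  seeds <- sample.int(.Machine$integer.max, nrep)
  d2 <- vapply(seeds, function(s) {
    x <- random_block_sequence(s6, 3, seed = s)
    (sum(x == 1) - sum(x == 2))^2
  }, numeric(1))
  p9 <- mean(d2 == 9)
  expect_equal(sort(unique(d2)), c(1, 9))
  expect_lt(abs(p9 - 0.1), 3 * sqrt(0.1 * 0.9 / nrep))
})
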