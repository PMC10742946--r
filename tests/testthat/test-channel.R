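test_that("free energies match the log-partition closed form", {
  # uniform profile: F = c - (1/beta) log(n positions)
  pt <- potential_table(matrix(2.5, 3, 2), beta = 1)
  expect_equal(free_energies(pt), rep(2.5 - log(3), 2))

  # two-level profile, direct evaluation of -log(exp(0) + exp(-1))
  pt <- potential_table(matrix(c(0, 1), 2, 1), beta = 1)
  expect_equal(free_energies(pt), -log(1 + exp(-1)), tolerance = 1e-12)

  # shift covariance: U + a shifts F by a
  set.seed(11)
  U <- matrix(rnorm(12), 4, 3)
  pt <- potential_table(U, beta = 0.7)
  expect_equal(free_energies(potential_table(U + 1.3, beta = 0.7)),
               free_energies(pt) + 1.3, tolerance = 1e-12)
})

test_that("canonical channels are Boltzmann, normalised and gauge invariant", {
  # symmetric two-well landscape gives the unbiased binary channel
  pt <- potential_table(matrix(0, 2, 2), beta = 3)
  expect_equal(unclass(channel_from_potentials(pt)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)

  # logistic closed form for an energy gap of 1 at beta = 1
  pt <- potential_table(matrix(c(0, 1), 2, 1), beta = 1)
  q <- channel_from_potentials(pt)
  expect_equal(q[, 1], c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-14)

  set.seed(7)
  U <- matrix(rnorm(15, sd = 3), 5, 3)
  q <- channel_from_potentials(potential_table(U, beta = 1.4))
  expect_equal(colSums(q), rep(1, 3), tolerance = 1e-12)
  expect_true(all(q > 0))
  # per-column gauge shifts leave the channel unchanged
  shift <- matrix(rep(rnorm(3, sd = 10), each = 5), 5, 3)
  q2 <- channel_from_potentials(potential_table(U + shift, beta = 1.4))
  expect_equal(unclass(q2), unclass(q), tolerance = 1e-12)

  # extreme beta*U ranges stay finite and normalised
  q3 <- channel_from_potentials(potential_table(matrix(c(0, 900, 450), 3, 1),
                                                beta = 2))
  expect_equal(sum(q3), 1)
  expect_true(all(is.finite(q3)))
})

test_that("potentials are recoverable from the channel up to a gauge constant", {
  set.seed(21)
  U <- matrix(rnorm(12), 3, 4)
  beta <- 1.7
  pt <- potential_table(U, beta)
  q <- channel_from_potentials(pt)
  U_rec <- -log(unclass(q)) / beta
  offsets <- U - U_rec
  expect_lt(max(apply(offsets, 2, function(v) diff(range(v)))), 1e-12)
  # and the free energies close the loop: q == exp(beta (F - U))
  FE <- free_energies(pt)
  expect_equal(unclass(q), exp(beta * sweep(-U, 2, FE, "+")),
               tolerance = 1e-12)
})

test_that("output distribution is the prior-mixed channel", {
  # worked three-message example (matrix-vector product oracle)
  py <- output_distribution(worked$channel, worked$prior)
  expect_equal(py, c(0.31758268, 0.39722053, 0.28519679), tolerance = 1e-12)
  expect_equal(sum(py), 1, tolerance = 1e-12)

  # identical columns: output equals that column for any prior
  qc <- channel_matrix(matrix(c(0.2, 0.5, 0.3), 3, 2))
  expect_equal(output_distribution(qc, c(0.9, 0.1)), c(0.2, 0.5, 0.3))

  # point-mass prior selects a single column
  expect_equal(output_distribution(worked$channel, c(0, 1, 0)),
               worked$channel[, 2], ignore_attr = TRUE)

  expect_error(output_distribution(worked$channel, c(0.5, 0.5)),
               "prior length")
})

test_that("posterior inverts the channel by Bayes rule", {
  expect_equal(posterior(worked$channel, rep(1 / 3, 3), 1),
               c(0.382480485689506, 0.482046834345186, 0.135472679965308),
               tolerance = 1e-12)
  expect_equal(posterior(worked$channel, worked$prior, 2),
               c(0.569024717831176, 0.072945474394287, 0.358029807774538),
               tolerance = 1e-12)
  # a point-mass prior is never revised
  expect_equal(posterior(worked$channel, c(0, 1, 0), 3), c(0, 1, 0))
})

test_that("posterior mixture reproduces the prior (Bayes consistency)", {
  for (seed in 1:25) {
    f <- generate_random_fixture(3, 4, seed)
    py <- output_distribution(f$channel, f$prior)
    mix <- Reduce(`+`, lapply(seq_len(4), function(y) {
      py[y] * posterior(f$channel, f$prior, y)
    }))
    expect_equal(mix, f$prior, tolerance = 1e-10)
    expect_equal(sum(py), 1, tolerance = 1e-12)
  }
})

test_that("input validation repairs small drift and rejects large drift", {
  expect_error(prior_vector(c(0.6, 0.6)), "sums to")
  expect_warning(p <- prior_vector(c(0.5, 0.5 + 1e-7)), "renormalised")
  expect_equal(sum(p), 1)
  expect_silent(prior_vector(c(0.5, 0.5 + 1e-10)))

  bad <- matrix(c(0.5, 0.4, 0.3, 0.7), 2, 2)  # first column sums to 0.9
  expect_error(channel_matrix(bad), "column-stochastic")
  expect_error(channel_matrix(matrix(c(-0.1, 1.1, 0.5, 0.5), 2, 2)),
               "nonnegative")
  expect_error(potential_table(matrix(c(0, Inf), 2, 1)), "finite")
  expect_error(potential_table(matrix(0, 2, 2), beta = -1), "positive")
})
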