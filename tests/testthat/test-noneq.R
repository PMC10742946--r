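test_that("strength decomposition halves the sum and difference of columns", {
  sd12 <- decompose_channel(worked$channel, 1, 2)
  expect_equal(sd12$m[1], 0.4984, tolerance = 1e-12)
  expect_equal(sd12$d[1], -0.0574, tolerance = 1e-12)
  expect_equal(sum(sd12$m), 1, tolerance = 1e-12)
  expect_equal(sum(sd12$d), 0, tolerance = 1e-12)

  # self-pair is the equilibrium point
  sd11 <- decompose_channel(worked$channel, 1, 1)
  expect_equal(sd11$d, rep(0, 3))
  expect_equal(sd11$m, worked$channel[, 1], ignore_attr = TRUE)

  # antisymmetry of d, symmetry of m under pair exchange
  sd21 <- decompose_channel(worked$channel, 2, 1)
  expect_equal(sd21$d, -sd12$d)
  expect_equal(sd21$m, sd12$m)

  # decompose/compose round-trip reproduces the two columns
  cols <- compose_strengths(sd12$m, sd12$d)
  expect_equal(cols[, 1], worked$channel[, 1], ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_equal(cols[, 2], worked$channel[, 2], ignore_attr = TRUE,
               tolerance = 1e-15)
})

test_that("compose accepts the feasible region and rejects beyond it", {
  m <- rep(1 / 3, 3)
  cols <- compose_strengths(m, c(0, 0, 0))
  expect_equal(cols, cbind(m, m), ignore_attr = TRUE)

  # boundary point: a zero entry appears and is flagged
  colsb <- compose_strengths(m, c(1 / 3, -1 / 3, 0))
  expect_equal(colsb[, 1], c(2 / 3, 0, 1 / 3), ignore_attr = TRUE)
  expect_equal(colsb[, 2], c(0, 2 / 3, 1 / 3), ignore_attr = TRUE)
  expect_true(attr(colsb, "boundary"))

  expect_error(compose_strengths(m, c(0.4, -0.4, 0)), "infeasible")
  expect_error(compose_strengths(m, c(0.1, -0.05, 0)), "sum to zero")
  expect_error(compose_strengths(c(0.5, 0.6, -0.1), c(0, 0, 0)),
               "probability vector")
})

test_that("feasible intervals follow the casewise half rule", {
  b <- feasible_interval(rep(1 / 3, 3))
  expect_equal(b$lower, rep(-1 / 3, 3))
  expect_equal(b$upper, rep(1 / 3, 3))

  b <- feasible_interval(c(0.6, 0.3, 0.1))
  expect_equal(b$lower, c(-0.4, -0.3, -0.1))
  expect_equal(b$upper, c(0.4, 0.3, 0.1))

  # a zero equilibrium strength pins d to zero
  b <- feasible_interval(c(0, 0.5, 0.5))
  expect_equal(b$lower[1], 0)
  expect_equal(b$upper[1], 0)

  expect_error(feasible_interval(c(0.5, 0.6)), "probability vector")
})

test_that("closed forms vanish at the equilibrium point for every preset", {
  for (p in two_source_presets()) {
    cf <- closed_form_I_R(p, rep(1 / 3, 3), c(0, 0, 0))
    expect_identical(cf$I, 0)
    expect_identical(cf$R, 0)
  }
})

test_that("closed forms agree with the generic channel computation", {
  cf <- closed_form_I_R(0.5, rep(1 / 3, 3), c(0.1, -0.1, 0))
  expect_equal(cf$R, 0.0619039208406224, tolerance = 1e-12)

  for (seed in 1:200) {
    s <- random_strengths(seed)
    cf <- closed_form_I_R(s$p, s$m, s$d)
    q <- channel_matrix(compose_strengths(s$m, s$d))
    prior <- c(s$p, 1 - s$p)
    expect_equal(cf$I, mutual_information(q, prior), tolerance = 1e-12)
    expect_equal(cf$R, recoverability(q, prior), tolerance = 1e-12)
  }
})

test_that("information surfaces are minimal at the origin and symmetric", {
  sw <- sweep_surface(0.8212, grid_resolution = 41L)
  origin <- sw$d1 == 0 & sw$d2 == 0
  expect_true(any(origin))
  expect_equal(sw$I[origin], 0, tolerance = 1e-14)
  expect_equal(sw$R[origin], 0, tolerance = 1e-14)
  feas <- sw$feasible
  expect_true(all(sw$I[feas] >= -1e-14))
  expect_true(all(sw$R[feas] >= -1e-14))
  expect_equal(min(sw$I[feas]), 0, tolerance = 1e-14)
  expect_equal(min(sw$R[feas]), 0, tolerance = 1e-14)

  # R is invariant under d -> -d (swapping the two source columns);
  # the grid is centred, so negation is reversal of both indices
  Rm <- matrix(sw$R, 41L, 41L)
  Rflip <- Rm[41:1, 41:1]
  keep <- !is.na(Rm) & !is.na(Rflip)
  expect_equal(Rm[keep], Rflip[keep], tolerance = 1e-9)
})

test_that("surfaces are midpoint-convex and monotone along rays", {
  for (p in two_source_presets()[c("a", "d")]) {
    sw <- sweep_surface(p, grid_resolution = 61L)
    n <- 61L
    I <- matrix(sw$I, n, n)   # d1 varies down rows, d2 across columns
    R <- matrix(sw$R, n, n)
    for (M in list(I, R)) {
      # midpoint convexity across axis-aligned neighbour triples
      h <- 2 * M[, 2:(n - 1)] - M[, 1:(n - 2)] - M[, 3:n]
      v <- 2 * M[2:(n - 1), ] - M[1:(n - 2), ] - M[3:n, ]
      expect_true(all(h[!is.na(h)] <= 1e-11))
      expect_true(all(v[!is.na(v)] <= 1e-11))
    }
    # rays from the origin: both surfaces nondecreasing in lambda
    for (dir in list(c(0.3, 0), c(0, -0.3), c(0.15, 0.15), c(-0.2, 0.1))) {
      lam <- seq(0, 1, length.out = 30)
      vals <- t(vapply(lam, function(l) {
        d12 <- l * dir
        d <- c(d12, -sum(d12))
        cf <- closed_form_I_R(p, rep(1 / 3, 3), d)
        c(cf$I, cf$R)
      }, numeric(2)))
      expect_true(all(diff(vals[, 1]) >= -1e-12))
      expect_true(all(diff(vals[, 2]) >= -1e-12))
    }
  }
})

test_that("at fixed d1 the two information measures increase together", {
  for (p in two_source_presets()) {
    for (d1 in c(0, 0.1, 0.25)) {
      b <- 1 / 3 - d1          # keep d3 = -d1-d2 feasible
      d2s <- seq(0, b - 1e-6, length.out = 40)
      vals <- t(vapply(d2s, function(d2) {
        cf <- closed_form_I_R(p, rep(1 / 3, 3), c(d1, d2, -d1 - d2))
        c(cf$I, cf$R)
      }, numeric(2)))
      ord <- order(vals[, 2])  # sort by R: I must come out sorted too
      expect_true(all(diff(vals[ord, 1]) >= -1e-10))
    }
  }
})
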