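# shared fixtures for the suite

worked <- list(channel = example_channel(), prior = example_prior())

# a feasible random (p, m, d) triple for the two-source family;
# d is scaled to 90% of the distance to the feasibility boundary
random_strengths <- function(seed, n = 3L) {
  set.seed(seed)
  m <- rgamma(n, 1)
  m <- m / sum(m)
  z <- runif(n, -1, 1)
  d <- z - mean(z)
  b <- feasible_interval(m)
  lam <- ifelse(d > 0, b$upper / d, ifelse(d < 0, b$lower / d, Inf))
  d <- 0.9 * min(lam) * d
  list(p = runif(1, 0.05, 0.95), m = m, d = d)
}
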