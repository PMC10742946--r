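#' Simulate a sequence of source and received messages
#'
#' Draws `t` i.i.d. source messages from the prior and, for each, a
#' received message from the corresponding channel column, giving the
#' joint sequence `Z = {(X_1, Y_2), (X_2, Y_3), ...}` of the sequential
#' transfer process. Pair `i` of the result holds `x[i] = X_i` and
#' `y[i] = Y_{i+1}`, the message received from it.
#'
#' Reproducibility: the master `seed` spawns fixed derived seeds for the
#' source stream (`seed + 1`) and the channel stream (`seed + 2`), so each
#' component can be regenerated in isolation.
#'
#' @inheritParams output_distribution
#' @param t Sequence length (number of transmitted messages), at least 1.
#' @param seed Integer master seed.
#' @return An object of class `"trajectory"`: a list with integer vectors
#'   `x`, `y`, and scalars `t`, `seed`.
#' @export
sample_sequences <- function(channel, prior, t, seed) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be at least 1", call. = FALSE)
  seed <- as.integer(seed)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)

  set.seed(seed + 1L)
  x <- sample.int(ncol(q), t, replace = TRUE, prob = prior)
  set.seed(seed + 2L)
  # one inverse-CDF draw per step against the column of its source message
  cum <- apply(q, 2L, cumsum)
  u <- stats::runif(t)
  y <- integer(t)
  for (xx in unique(x)) {
    idx <- x == xx
    y[idx] <- findInterval(u[idx], cum[, xx], left.open = TRUE) + 1L
  }
  structure(list(x = x, y = y, t = t, seed = seed), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of %d (source, received) pairs, seed %d\n",
              x$t, x$seed))
  show <- min(x$t, 8L)
  print(utils::head(data.frame(x = x$x, y = x$y), show))
  if (x$t > show) cat(sprintf("... %d more\n", x$t - show))
  invisible(x)
}

#' Shuffled surrogate of a trajectory
#'
#' Returns the trajectory with its source-message sequence replaced by a
#' uniformly random permutation (Fisher-Yates, via `sample()`) of the
#' original multiset, keeping the received sequence fixed. The surrogate
#' destroys the source-receiver pairing while preserving all marginal
#' statistics of the source stream, which is what makes the
#' log-probability ratio of trajectory to surrogate an estimator of
#' recoverability.
#'
#' @param traj A [sample_sequences()] trajectory.
#' @param seed Integer seed for the permutation.
#' @return A `"trajectory"` with permuted `x` and identical `y`.
#' @export
shuffle_sources <- function(traj, seed) {
  stopifnot(inherits(traj, "trajectory"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) + 3L)
  perm <- sample.int(traj$t)
  structure(list(x = traj$x[perm], y = traj$y, t = traj$t, seed = traj$seed),
            class = "trajectory")
}

#' Trajectory estimator of the recoverability
#'
#' `R'_t = (1/t) * log(P(Z) / P(Z'))`, the per-step log-probability ratio
#' of the observed trajectory `Z` to its source-shuffled surrogate `Z'`
#' under the product measure `P(Z) = prod_i P_X(X_i) q(Y_{i+1} | X_i)`.
#' The prior factors cancel exactly (the surrogate permutes the same
#' multiset of source labels), leaving the running average of channel
#' log ratios, which converges to the ensemble recoverability for long
#' trajectories.
#'
#' @param traj Observed trajectory.
#' @param shuffled Its surrogate from [shuffle_sources()] (same `y`).
#' @inheritParams output_distribution
#' @return An object of class `"estimator_trace"`: list with `times`
#'   (log-spaced checkpoints), `values` (running averages, nats), and
#'   `final`.
#' @export
recoverability_estimator <- function(traj, shuffled, channel, prior) {
  stopifnot(inherits(traj, "trajectory"), inherits(shuffled, "trajectory"))
  if (!identical(traj$y, shuffled$y)) {
    stop("trajectory and surrogate must share the received sequence",
         call. = FALSE)
  }
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  lq <- log(q)
  lp <- log(prior)
  # the surrogate permutes the same multiset of source labels, so the
  # prior factors of log P(Z) - log P(Z') cancel over the full sum;
  # assert that and keep the channel-ratio increments, which make every
  # prefix of the trace an exact running average of log-likelihood ratios
  if (all(is.finite(lp[traj$x])) &&
      abs(sum(lp[traj$x]) - sum(lp[shuffled$x])) > 1e-9) {
    stop("surrogate is not a permutation of the source sequence",
         call. = FALSE)
  }
  inc <- lq[cbind(traj$y, traj$x)] - lq[cbind(shuffled$y, shuffled$x)]
  estimator_trace(inc, denom = seq_along(inc))
}

#' Trajectory estimator of the entropy production
#'
#' `Sigma'_t = (1/t) * sum_{i=2}^{t} log(q(Y_i | X_{i-1}) / q(Y_i | X_i))`
#' along a single trajectory: at every switch from message `X_{i-1}` to
#' `X_i` the previously received `Y_i` is re-weighed under the new channel
#' column. Converges to the ensemble entropy production — and hence to the
#' recoverability — for long trajectories. Note the normalisation by `t`
#' although the sum has `t - 1` terms; the difference is O(1/t).
#'
#' @param traj Observed trajectory (length at least 2).
#' @inheritParams output_distribution
#' @return An `"estimator_trace"` (see [recoverability_estimator()]).
#' @export
entropy_production_estimator <- function(traj, channel) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$t < 2L) stop("need a trajectory of length at least 2", call. = FALSE)
  q <- as_channel(channel)
  lq <- log(q)
  i <- 2:traj$t
  # Y_i is the message received from X_{i-1}, stored as y[i-1]
  inc <- lq[cbind(traj$y[i - 1L], traj$x[i - 1L])] -
    lq[cbind(traj$y[i - 1L], traj$x[i])]
  estimator_trace(c(0, inc), denom = seq_len(traj$t))
}

# running-average trace at logarithmically spaced checkpoints
estimator_trace <- function(increments, denom) {
  n <- length(increments)
  csum <- cumsum(increments)
  checkpoints <- unique(pmin(n, c(round(10^seq(0, log10(n), length.out = 41L)), n)))
  structure(
    list(times = checkpoints,
         values = csum[checkpoints] / denom[checkpoints],
         final = csum[n] / denom[n]),
    class = "estimator_trace"
  )
}

#' @export
print.estimator_trace <- function(x, ...) {
  cat(sprintf("Estimator trace over %d steps: final %.6f nats\n",
              max(x$times), x$final))
  invisible(x)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
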