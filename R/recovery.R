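#' Log-likelihood ratio between two candidate source messages
#'
#' `l = log(q[y, x] / q[y, x_alt])` in nats: the evidence the received
#' message `y` carries for source message `x` over the alternative `x_alt`.
#' The maximum-likelihood rule recovers the message whose ratio against
#' every alternative is positive. Returns `Inf` (`-Inf`) when exactly one of
#' the two channel entries is zero; both zero is an error since the ratio is
#' undefined.
#'
#' @inheritParams output_distribution
#' @param y Received message label.
#' @param x,x_alt Source message labels (candidate and alternative).
#' @return A single number in nats, possibly infinite.
#' @export
log_likelihood_ratio <- function(channel, y, x, x_alt) {
  q <- as_channel(channel)
  y <- check_label(y, nrow(q), "received")
  x <- check_label(x, ncol(q), "source")
  x_alt <- check_label(x_alt, ncol(q), "source")
  a <- q[y, x]
  b <- q[y, x_alt]
  if (a == 0 && b == 0) {
    stop("both channel entries are zero; log ratio undefined", call. = FALSE)
  }
  log(a) - log(b)
}

#' Log posterior ratio (maximum a posteriori evidence)
#'
#' `r = log(P(x|y) / P(x_alt|y)) = l + gamma` where
#' `gamma = log(P_X(x) / P_X(x_alt))` is the prior log ratio. Requires
#' strictly positive prior mass on both candidates.
#'
#' @inheritParams log_likelihood_ratio
#' @param prior Prior over source messages.
#' @return A single number in nats, possibly infinite.
#' @export
map_log_ratio <- function(channel, prior, y, x, x_alt) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  x <- check_label(x, ncol(q), "source")
  x_alt <- check_label(x_alt, ncol(q), "source")
  if (prior[x] <= 0 || prior[x_alt] <= 0) {
    stop("posterior log ratio undefined for zero-prior messages",
         call. = FALSE)
  }
  log_likelihood_ratio(q, y, x, x_alt) + log(prior[x]) - log(prior[x_alt])
}

#' Maximum-likelihood decision for a received message
#'
#' Picks the source message maximising `q[y, x]`. Ties are broken toward
#' the lowest label, and the result carries a logical attribute `"tie"`.
#'
#' @inheritParams log_likelihood_ratio
#' @return Integer source label with attribute `tie`.
#' @export
decide_ml <- function(channel, y) {
  q <- as_channel(channel)
  y <- check_label(y, nrow(q), "received")
  scores <- q[y, ]
  best <- which.max(scores)            # which.max takes the first maximum
  structure(as.integer(best),
            tie = sum(scores == scores[best]) > 1L)
}

#' Maximum a posteriori decision for a received message
#'
#' Picks the source message maximising `q[y, x] * P_X(x)`; same tie policy
#' as [decide_ml()]. With a uniform prior the two rules coincide.
#'
#' @inheritParams map_log_ratio
#' @return Integer source label with attribute `tie`.
#' @export
decide_map <- function(channel, prior, y) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  y <- check_label(y, nrow(q), "received")
  scores <- q[y, ] * prior
  if (sum(scores) <= 0) {
    stop(sprintf("received message %d has zero probability; decision undefined", y),
         call. = FALSE)
  }
  best <- which.max(scores)
  structure(as.integer(best),
            tie = sum(scores == scores[best]) > 1L)
}

#' Recoverability of the source messages
#'
#' The ensemble average of the log-likelihood ratio between the true source
#' message and an independently drawn alternative:
#' \deqn{R = \sum_{x, x', y} P_X(x) P_X(x') \, q(y|x)
#'       \log\frac{q(y|x)}{q(y|x')}}
#' summed over all ordered pairs including `x = x'` (which contribute
#' zero). R is nonnegative, vanishes exactly when all channel columns are
#' identical, and equals the entropy production of the sequential transfer
#' process (see [entropy_production()], computed by an independent
#' summation path). When some `q[y, x'] = 0` while `q[y, x] > 0` with
#' positive prior weight on both, the value is `+Inf`.
#'
#' @inheritParams output_distribution
#' @return A single number in nats (possibly `Inf`).
#' @export
recoverability <- function(channel, prior) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  n <- ncol(q)
  total <- 0
  # loop over ordered source pairs; inner sum over y vectorised
  for (x in seq_len(n)) {
    for (xa in seq_len(n)) {
      w <- prior[x] * prior[xa]
      if (w == 0 || x == xa) next
      total <- total + w * sum(xlogx_ratio(q[, x], q[, xa]))
    }
  }
  total
}

#' Mutual information between source and received messages
#'
#' `I = sum_{x,y} P_X(x) q(y|x) log(q(y|x) / P_Y(y))` in nats, with the
#' `0 log 0 = 0` convention. Also called the information transfer rate.
#'
#' @inheritParams output_distribution
#' @return A single nonnegative number in nats.
#' @export
mutual_information <- function(channel, prior) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  py <- as.vector(q %*% prior)
  total <- 0
  for (x in seq_len(ncol(q))) {
    if (prior[x] == 0) next
    total <- total + prior[x] * sum(xlogx_ratio(q[, x], py))
  }
  total
}

#' Error information of the channel
#'
#' The averaged spurious correlation between the received message and an
#' independently drawn source message:
#' `Ie = sum_x P_X(x) KL(P_Y || q[, x])`, nonnegative, and `Inf` when some
#' channel entry is zero where `P_Y` has mass. Together with the mutual
#' information it decomposes the recoverability exactly: `R = I + Ie`.
#'
#' @inheritParams output_distribution
#' @return A single nonnegative number in nats (possibly `Inf`).
#' @export
error_information <- function(channel, prior) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  py <- as.vector(q %*% prior)
  total <- 0
  for (x in seq_len(ncol(q))) {
    if (prior[x] == 0) next
    total <- total + prior[x] * sum(xlogx_ratio(py, q[, x]))
  }
  total
}

#' Information summary of a (channel, prior) pair
#'
#' Computes recoverability, mutual information and error information in one
#' call and checks the exact decomposition `R = I + Ie`.
#'
#' @inheritParams output_distribution
#' @return A list with elements `R`, `I`, `Ie` (nats) and `units`.
#' @export
info_summary <- function(channel, prior) {
  R <- recoverability(channel, prior)
  I <- mutual_information(channel, prior)
  Ie <- error_information(channel, prior)
  if (is.finite(R) && abs(R - (I + Ie)) > 1e-10) {
    stop("internal inconsistency: R != I + Ie beyond tolerance")
  }
  list(R = R, I = I, Ie = Ie, units = "nats")
}
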