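#' Validate and normalise a prior distribution over source messages
#'
#' A prior is a plain numeric vector of probabilities over the source
#' alphabet. Entries must be nonnegative and sum to one. Small drift in the
#' normalisation (as arises from decimal input files) is repaired: drift up
#' to `1e-9` is renormalised silently, drift up to `1e-6` is renormalised
#' with a warning, anything larger is an error.
#'
#' @param probs Numeric vector of probabilities, length at least 2.
#' @return The validated (renormalised) prior vector.
#' @examples
#' prior_vector(c(0.4610, 0.0753, 0.4637))
#' @export
prior_vector <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) < 2L) {
    stop("a prior needs at least 2 source messages", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("prior probabilities must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(probs)
  drift <- abs(s - 1)
  if (drift > 1e-6) {
    stop(sprintf("prior sums to %.8f; not a probability distribution", s),
         call. = FALSE)
  }
  if (drift > 1e-9) {
    warning(sprintf("prior renormalised (drift %.2e)", drift), call. = FALSE)
  }
  probs / s
}

#' Validate a column-stochastic channel matrix
#'
#' The channel convention throughout the package is `q[y, x]`: columns index
#' source messages, rows index received messages, and every column is a
#' probability distribution over the received alphabet. The source and
#' received alphabets may differ in size.
#'
#' Normalisation drift per column follows the same repair policy as
#' [prior_vector()]: silent renormalisation below `1e-9`, warning up to
#' `1e-6`, error beyond.
#'
#' @param q Numeric matrix, `n_rcv` rows by `n_src` columns.
#' @return The validated matrix with class `"channel_matrix"`.
#' @examples
#' channel_matrix(matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2))
#' @export
channel_matrix <- function(q) {
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (nrow(q) < 2L || ncol(q) < 2L) {
    stop("a channel needs at least 2 received and 2 source messages",
         call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("channel entries must be finite and nonnegative", call. = FALSE)
  }
  cs <- colSums(q)
  drift <- abs(cs - 1)
  if (any(drift > 1e-6)) {
    bad <- which.max(drift)
    stop(sprintf("channel column %d sums to %.8f; not column-stochastic",
                 bad, cs[bad]), call. = FALSE)
  }
  if (any(drift > 1e-9)) {
    warning(sprintf("channel columns renormalised (max drift %.2e)",
                    max(drift)), call. = FALSE)
  }
  q <- sweep(q, 2L, cs, "/")
  class(q) <- c("channel_matrix", class(q))
  q
}

#' Potential landscape of the receiver
#'
#' Packages the per-source-message potential profiles `U[y, x]` (rows are
#' receiver positions, columns are source messages, in energy units) with
#' the inverse temperature `beta` of the surrounding bath. Under source
#' message `x` the receiver equilibrates to the Boltzmann distribution
#' determined by the column `U[, x]`, which is what makes the potential
#' table a generator of channel matrices (see
#' [channel_from_potentials()]).
#'
#' @param U Numeric matrix of potential values, `n_rcv` rows (positions) by
#'   `n_src` columns (source messages). All entries must be finite.
#' @param beta Inverse temperature, a single positive number (reciprocal
#'   energy units). Default 1.
#' @return An object of class `"potential_table"`: a list with elements
#'   `U` and `beta`.
#' @examples
#' pt <- potential_table(matrix(c(0, 1, 1, 0), 2, 2), beta = 1)
#' channel_from_potentials(pt)
#' @export
potential_table <- function(U, beta = 1) {
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  if (nrow(U) < 2L) {
    stop("a potential table needs at least 2 receiver positions",
         call. = FALSE)
  }
  if (any(!is.finite(U))) {
    stop("potential values must be finite", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("beta must be a single positive number", call. = FALSE)
  }
  structure(list(U = U, beta = as.numeric(beta)), class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("Potential table: %d positions x %d source messages, beta = %g\n",
              nrow(x$U), ncol(x$U), x$beta))
  print(x$U, ...)
  invisible(x)
}

#' Free energies of the potential profiles
#'
#' For each source message `x` the free energy is
#' `F_x = -(1/beta) * log(sum_y exp(-beta * U[y, x]))`, the log partition
#' sum over receiver positions. Computed with a max-shift so that large
#' `beta * U` ranges neither overflow nor underflow. Shifting a potential
#' column by a constant shifts its free energy by the same constant.
#'
#' @param potentials A [potential_table()].
#' @return Numeric vector of free energies, one per source message.
#' @export
free_energies <- function(potentials) {
  stopifnot(inherits(potentials, "potential_table"))
  U <- potentials$U
  beta <- potentials$beta
  # log-sum-exp per column, shifted by the column minimum of U
  u0 <- apply(U, 2L, min)
  lse <- log(colSums(exp(-beta * sweep(U, 2L, u0, "-"))))
  u0 - lse / beta
}

#' Canonical channel generated by a potential landscape
#'
#' Under source message `x` the receiver relaxes to the Boltzmann
#' distribution `q[y, x] = exp(beta * (F_x - U[y, x]))` over positions `y`,
#' where `F_x` is the free energy of profile `U[, x]`. This distribution is
#' the channel transition probability (the information driving force): the
#' received message is the equilibrated receiver position. Every entry is
#' strictly positive and the construction is gauge invariant — adding a
#' constant to a potential column leaves its channel column unchanged.
#'
#' @param potentials A [potential_table()].
#' @return A [channel_matrix()] with the same dimensions as `potentials$U`.
#' @export
channel_from_potentials <- function(potentials) {
  stopifnot(inherits(potentials, "potential_table"))
  U <- potentials$U
  beta <- potentials$beta
  # softmax per column with max-shift: exp(-beta U) / colsum
  E <- exp(-beta * sweep(U, 2L, apply(U, 2L, min), "-"))
  q <- sweep(E, 2L, colSums(E), "/")
  class(q) <- c("channel_matrix", class(q))
  q
}

#' Stationary distribution of the received messages
#'
#' `P_Y = q %*% P_X`: the output distribution of the channel when source
#' messages are drawn i.i.d. from the prior.
#'
#' @param channel Channel matrix `q[y, x]` (validated with
#'   [channel_matrix()] or any column-stochastic matrix).
#' @param prior Prior over source messages; must match `ncol(channel)`.
#' @return Numeric probability vector over received messages.
#' @export
output_distribution <- function(channel, prior) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  as.vector(q %*% prior)
}

#' Posterior over source messages given a received message
#'
#' Bayes inversion of the channel:
#' `P(x | y) = q[y, x] * P_X(x) / P_Y(y)`.
#'
#' @inheritParams output_distribution
#' @param y Received message label (1-based).
#' @return Numeric probability vector over source messages.
#' @export
posterior <- function(channel, prior, y) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  y <- check_label(y, nrow(q), "received")
  joint <- q[y, ] * prior
  py <- sum(joint)
  if (py <= 0) {
    stop(sprintf("received message %d has zero probability; posterior undefined", y),
         call. = FALSE)
  }
  as.vector(joint / py)
}

# -- internal helpers --------------------------------------------------------

as_channel <- function(channel) {
  if (inherits(channel, "channel_matrix")) channel else channel_matrix(channel)
}

check_label <- function(i, n, what) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    stop(sprintf("%s label must be an integer in 1..%d", what, n),
         call. = FALSE)
  }
  i
}

# x * log(x / y) with the 0 * log 0 = 0 convention; Inf when x > 0, y = 0
xlogx_ratio <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}
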