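#' Stochastic entropy production of a single potential switch
#'
#' When the source message switches from `x_prev` to `x_next` while the
#' receiver sits at position `y`, the dissipation of that single transfer
#' step is the log ratio of the two channel entries at the same received
#' message: `sigma = log(q[y, x_prev] / q[y, x_next])` (nats). It is
#' antisymmetric in the pair and vanishes when the message repeats.
#'
#' @inheritParams output_distribution
#' @param x_prev,x_next Source labels before and after the switch.
#' @param y Received message label.
#' @return A single number in nats, possibly infinite.
#' @export
stochastic_entropy_production <- function(channel, x_prev, x_next, y) {
  log_likelihood_ratio(channel, y, x_prev, x_next)
}

#' Work accounting of a single potential switch
#'
#' Switching the potential profile from `U[, x_prev]` to `U[, x_next]`
#' while the receiver is at `y` performs the stochastic work
#' `w = U[y, x_next] - U[y, x_prev]` on the receiver; the reversible part
#' is the free-energy change of the switch, `dF = F_{x_next} - F_{x_prev}`
#' (final minus initial, so that a pure gauge shift has `w = dF` and no
#' dissipation). The excess `sigma = beta * (w - dF)` is the stochastic
#' entropy production, and it coincides with the channel log ratio of
#' [stochastic_entropy_production()] because the channel is canonical.
#'
#' @param potentials A [potential_table()].
#' @param x_prev,x_next Source labels before and after the switch.
#' @param y Receiver position label.
#' @return A list with elements `w`, `dF` (energy units) and `sigma`
#'   (nats).
#' @export
stochastic_work <- function(potentials, x_prev, x_next, y) {
  stopifnot(inherits(potentials, "potential_table"))
  U <- potentials$U
  x_prev <- check_label(x_prev, ncol(U), "source")
  x_next <- check_label(x_next, ncol(U), "source")
  y <- check_label(y, nrow(U), "position")
  FE <- free_energies(potentials)
  w <- U[y, x_next] - U[y, x_prev]
  dF <- FE[x_next] - FE[x_prev]
  list(w = w, dF = dF, sigma = potentials$beta * (w - dF))
}

#' Averaged entropy production of sequential information transfer
#'
#' With consecutive source messages drawn i.i.d. from the prior, the
#' average of the stochastic entropy production is
#' \deqn{\Sigma = \sum_{x, x', y} P_X(x) P_X(x') \, q(y|x)
#'       \log\frac{q(y|x)}{q(y|x')} \ge 0,}
#' a prior-weighted sum of KL divergences between channel columns. It
#' equals the recoverability of the channel — [recoverability()] computes
#' the same quantity by a different summation order, and the two are
#' asserted to agree in the test-suite to 1e-12. `Inf` when zero channel
#' entries receive positive weight.
#'
#' @inheritParams output_distribution
#' @return A single nonnegative number in nats (possibly `Inf`).
#' @export
entropy_production <- function(channel, prior) {
  q <- as_channel(channel)
  prior <- prior_vector(prior)
  if (length(prior) != ncol(q)) {
    stop("prior length must equal the number of channel columns",
         call. = FALSE)
  }
  # row-wise (per received message) accumulation:
  # sum_y [ (sum_x P(x) q[y,x] log q[y,x]) - (sum_x P(x) q[y,x]) *
  #         (sum_x' P(x') log q[y,x']) ]
  lq <- log(q)
  lq[q == 0] <- 0                      # guarded below
  a <- as.vector((q * lq) %*% prior)   # E_x[q log q] per row
  b <- as.vector(q %*% prior)          # E_x[q] per row
  cc <- as.vector(log(q) %*% prior)    # E_x'[log q] per row; -Inf propagates
  term <- a - b * cc
  term[b == 0] <- 0                    # received messages with no mass
  total <- sum(term)
  if (is.nan(total)) Inf else total
}

#' Thermodynamic summary of a transfer process
#'
#' Collects entropy production, averaged work, mean free-energy difference
#' and the generalized Landauer margin for a channel (or the canonical
#' channel of a potential table) under an i.i.d. source prior.
#'
#' The averaged work is `W = Sigma / beta`; the averaged free-energy
#' difference over i.i.d. consecutive messages,
#' `sum_{x,x'} P(x) P(x') (F_x - F_{x'})`, vanishes by antisymmetry, so W
#' is pure dissipation. The generalized Landauer principle bounds the work
#' from below by the transferred information: `W >= I / beta`, with margin
#' `W - I / beta = Ie / beta >= 0`.
#'
#' @param x A [channel_matrix()] or a [potential_table()].
#' @param prior Prior over source messages.
#' @param beta Inverse temperature; taken from the potential table when `x`
#'   is one, else defaults to 1 (Sigma, R, I themselves are beta-free).
#' @return A list with elements `Sigma`, `R`, `I`, `Ie` (nats), `W`,
#'   `dF_avg`, `landauer_margin` (energy units) and `beta`.
#' @export
thermo_summary <- function(x, prior, beta = NULL) {
  if (inherits(x, "potential_table")) {
    if (is.null(beta)) beta <- x$beta
    FE <- free_energies(x)
    q <- channel_from_potentials(x)
  } else {
    if (is.null(beta)) beta <- 1
    q <- as_channel(x)
    FE <- NULL
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a single positive number", call. = FALSE)
  }
  prior <- prior_vector(prior)
  Sigma <- entropy_production(q, prior)
  info <- info_summary(q, prior)
  dF_avg <- if (is.null(FE)) 0 else {
    sum(outer(prior, prior) * outer(FE, FE, "-"))
  }
  list(Sigma = Sigma, R = info$R, I = info$I, Ie = info$Ie,
       W = Sigma / beta, dF_avg = dF_avg,
       landauer_margin = (Sigma - info$I) / beta, beta = beta)
}
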