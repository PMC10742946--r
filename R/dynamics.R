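#' Local-detailed-balance rate matrix for the receiver under one message
#'
#' Builds the generator `G` of the continuous-time Markov dynamics of the
#' receiver position while the source message `x` is held fixed. All pairs
#' of positions are connected with unit attempt rate; the acceptance factor
#' follows the chosen rule,
#' * `metropolis`: `r(s'|s) = min(1, exp(-beta * (U(s') - U(s))))`,
#' * `glauber`:    `r(s'|s) = 1 / (1 + exp(beta * (U(s') - U(s))))`,
#' both of which satisfy local detailed balance
#' `r(s'|s) / r(s|s') = exp(beta * (U(s) - U(s')))` exactly, so the unique
#' stationary distribution is the canonical channel column for `x`.
#' Columns of `G` sum to zero (`du/dt = G u` convention).
#'
#' Rates are in arbitrary inverse-time units; only the infinite-time limit
#' of the relaxation enters the information-transfer framework.
#'
#' @param potentials A [potential_table()].
#' @param x Source message label whose potential profile drives the
#'   receiver.
#' @param rule Rate rule, `"metropolis"` (default) or `"glauber"`.
#' @return A square rate matrix `G` with attributes `source` (the label)
#'   and `rule`.
#' @export
build_rate_matrix <- function(potentials, x, rule = c("metropolis", "glauber")) {
  stopifnot(inherits(potentials, "potential_table"))
  rule <- match.arg(rule)
  x <- check_label(x, ncol(potentials$U), "source")
  u <- potentials$U[, x]
  beta <- potentials$beta
  n <- length(u)
  dU <- outer(u, u, "-")               # dU[s2, s1] = U(s2) - U(s1)
  G <- switch(rule,
    metropolis = pmin(exp(-beta * dU), 1),
    glauber = 1 / (1 + exp(beta * dU))
  )
  diag(G) <- 0
  diag(G) <- -colSums(G)
  structure(G, source = x, rule = rule)
}

#' Relax the receiver distribution under a fixed source message
#'
#' Propagates an initial position distribution through the master equation
#' `du/dt = G u` for a time `tau`, i.e. `u_tau = expm(G * tau) %*% u0`.
#' Probability mass is conserved; as `tau` grows the distribution
#' approaches the canonical channel column of the driving message.
#'
#' @param rates Rate matrix from [build_rate_matrix()].
#' @param u0 Initial probability vector over receiver positions.
#' @param tau Nonnegative relaxation time (arbitrary units).
#' @return Probability vector over positions at time `tau`.
#' @export
relax <- function(rates, u0, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop("tau must be a single nonnegative number", call. = FALSE)
  }
  u0 <- prior_vector_positions(u0, nrow(rates))
  if (tau == 0) return(u0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(rates * tau)))
  as.vector(P %*% u0)
}

#' Coarse-grained transition kernel of one receiving period
#'
#' The kernel `K = lim_{tau -> Inf} expm(G * tau)` maps the receiver
#' position at the start of a receiving period to its position at the end.
#' Because the generator is irreducible and balanced against the canonical
#' distribution, every column of `K` equals the channel column of the
#' driving message: the end-of-period position is independent of the
#' starting one, which is exactly the memoryless channel property.
#'
#' Computed by repeated squaring of `expm(G)` (doubling `tau`) until the
#' columns agree in sup-norm within `tol`.
#'
#' @param rates Rate matrix from [build_rate_matrix()].
#' @param tol Convergence tolerance on the sup-norm spread between columns.
#'   Default `1e-10`.
#' @param max_doublings Maximum number of `tau`-doublings. Default 60.
#' @return The kernel matrix with attribute `tau_star`, the relaxation
#'   time at which convergence was reached.
#' @export
coarse_grained_kernel <- function(rates, tol = 1e-10, max_doublings = 60L) {
  K <- as.matrix(Matrix::expm(Matrix::Matrix(rates)))
  tau <- 1
  for (step in seq_len(max_doublings)) {
    spread <- max(apply(K, 1L, function(r) diff(range(r))))
    if (spread < tol) {
      return(structure(K, tau_star = tau))
    }
    K <- K %*% K
    tau <- tau * 2
  }
  stop("coarse-grained kernel did not converge; is the rate matrix irreducible?",
       call. = FALSE)
}

# like prior_vector() but for receiver-position distributions of known size
prior_vector_positions <- function(u, n) {
  u <- prior_vector(u)
  if (length(u) != n) {
    stop("distribution length does not match the number of positions",
         call. = FALSE)
  }
  u
}
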