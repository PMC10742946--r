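#' Equilibrium/nonequilibrium strength decomposition of two channel columns
#'
#' Any pair of channel columns splits into a symmetric and an antisymmetric
#' part: the equilibrium strength `m_y = (q[y, x] + q[y, x_alt]) / 2` and
#' the nonequilibrium strength `d_y = (q[y, x] - q[y, x_alt]) / 2`. The
#' point `d = 0` is the equilibrium point of the information transfer,
#' where the two source messages are indistinguishable to the receiver.
#'
#' @inheritParams log_likelihood_ratio
#' @return An object of class `"strength_decomposition"`: a list with
#'   elements `m`, `d` and `pair = c(x, x_alt)`.
#' @export
decompose_channel <- function(channel, x, x_alt) {
  q <- as_channel(channel)
  x <- check_label(x, ncol(q), "source")
  x_alt <- check_label(x_alt, ncol(q), "source")
  structure(
    list(m = (q[, x] + q[, x_alt]) / 2,
         d = (q[, x] - q[, x_alt]) / 2,
         pair = c(x, x_alt)),
    class = "strength_decomposition"
  )
}

#' @export
print.strength_decomposition <- function(x, ...) {
  cat(sprintf("Strength decomposition of source pair (%d, %d)\n",
              x$pair[1], x$pair[2]))
  print(rbind(m = x$m, d = x$d), ...)
  invisible(x)
}

#' Recompose channel columns from a strength decomposition
#'
#' Returns the two columns `(m + d, m - d)`. The strengths must be
#' feasible: `m` a probability vector, `sum(d) = 0`, and each `d_y` inside
#' the interval reported by [feasible_interval()]; otherwise one of the
#' recomposed columns would have negative entries and an error is raised.
#' Boundary strengths (a zero entry in a recomposed column) are accepted
#' and the result carries a logical attribute `"boundary"`.
#'
#' @param m Equilibrium strength vector (probability vector over received
#'   messages).
#' @param d Nonequilibrium strength vector, same length, summing to zero.
#' @param tol Feasibility tolerance. Default `1e-12`.
#' @return A matrix with two columns, the channel columns for the pair;
#'   attribute `boundary` flags zero entries.
#' @export
compose_strengths <- function(m, d, tol = 1e-12) {
  m <- as.numeric(m)
  d <- as.numeric(d)
  if (length(m) != length(d)) {
    stop("m and d must have the same length", call. = FALSE)
  }
  if (any(m < -tol) || abs(sum(m) - 1) > 1e-9) {
    stop("m must be a probability vector over received messages",
         call. = FALSE)
  }
  if (abs(sum(d)) > 1e-9) {
    stop("d must sum to zero", call. = FALSE)
  }
  bounds <- feasible_interval(m)
  if (any(d < bounds$lower - tol) || any(d > bounds$upper + tol)) {
    stop("infeasible strengths: some |d_y| exceeds its bound, a recomposed column would be negative",
         call. = FALSE)
  }
  cols <- cbind(pmax(m + d, 0), pmax(m - d, 0))
  structure(cols, boundary = any(cols <= tol))
}

#' Feasible range of the nonequilibrium strength
#'
#' Given an equilibrium strength vector `m`, the per-component bounds on
#' `d_y` that keep both recomposed columns valid probabilities:
#' `[-m_y, m_y]` when `m_y < 1/2` and `[m_y - 1, 1 - m_y]` when
#' `m_y >= 1/2`, together with the linear constraint `sum(d) = 0`.
#'
#' @param m Equilibrium strength vector.
#' @return A list with vectors `lower` and `upper` and the constraint
#'   string `sum_constraint = "sum(d) == 0"`.
#' @export
feasible_interval <- function(m) {
  m <- as.numeric(m)
  if (any(!is.finite(m)) || any(m < 0) || abs(sum(m) - 1) > 1e-9) {
    stop("m must be a probability vector", call. = FALSE)
  }
  lower <- ifelse(m < 0.5, -m, m - 1)
  upper <- ifelse(m < 0.5, m, 1 - m)
  list(lower = lower, upper = upper, sum_constraint = "sum(d) == 0")
}

#' Closed-form information measures for the two-source family
#'
#' For a channel with two source messages whose columns are `m + d` and
#' `m - d`, and prior `(p, 1 - p)`, the mutual information and the
#' recoverability have closed forms (all in nats):
#' \deqn{I = p \sum_y (m_y + d_y) \log\frac{m_y + d_y}{m_y + (2p-1) d_y}
#'       + (1-p) \sum_y (m_y - d_y) \log\frac{m_y - d_y}{m_y + (2p-1) d_y}}
#' \deqn{R = 2 p (1-p) \sum_y d_y \log\frac{m_y + d_y}{m_y - d_y}}
#' Both vanish at the equilibrium point `d = 0` and are convex in `d`. On
#' the feasibility boundary (some `m_y = |d_y|`) R diverges to `Inf`.
#'
#' @param p Prior probability of the first source message, in (0, 1).
#' @param m Equilibrium strength vector.
#' @param d Nonequilibrium strength vector (feasible; `sum(d) = 0`).
#' @return A list with elements `I` and `R` in nats.
#' @export
closed_form_I_R <- function(p, m, d) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must be a single probability in (0, 1)", call. = FALSE)
  }
  m <- as.numeric(m)
  d <- as.numeric(d)
  bounds <- feasible_interval(m)
  if (abs(sum(d)) > 1e-9 || any(d < bounds$lower - 1e-12) ||
      any(d > bounds$upper + 1e-12)) {
    stop("infeasible strengths (p, m, d)", call. = FALSE)
  }
  py <- m + (2 * p - 1) * d          # output distribution
  I <- p * sum(xlogx_ratio(m + d, py)) + (1 - p) * sum(xlogx_ratio(m - d, py))
  up <- m + d
  dn <- m - d
  active <- d != 0
  R <- if (any(active & (up <= 0 | dn <= 0))) {
    Inf
  } else {
    2 * p * (1 - p) * sum(d[active] * (log(up[active]) - log(dn[active])))
  }
  list(I = I, R = R)
}

#' Sweep the information surfaces over the nonequilibrium strengths
#'
#' Evaluates the closed-form mutual information and recoverability of the
#' two-source family on a regular `(d1, d2)` grid, with `d3 = -d1 - d2`
#' implied by the zero-sum constraint. Grid points outside the feasible
#' region (or within `eps` of its boundary, where R diverges) are masked.
#'
#' @param p Prior probability of the first source message.
#' @param m Equilibrium strength vector of length 3. Default `rep(1/3, 3)`,
#'   for which the feasible region is the hexagon
#'   `|d1|, |d2|, |d1 + d2| <= 1/3`.
#' @param grid_resolution Number of grid points per axis. Default 201.
#' @param eps Interior margin excluded next to the feasibility boundary.
#'   Default `1e-6`.
#' @return A data frame with columns `d1`, `d2`, `feasible`, `I`, `R`
#'   (`NA` outside the feasible interior).
#' @export
sweep_surface <- function(p, m = rep(1 / 3, 3), grid_resolution = 201L,
                          eps = 1e-6) {
  if (length(m) != 3L) {
    stop("sweep_surface expects 3 received messages", call. = FALSE)
  }
  bounds <- feasible_interval(m)
  grid_resolution <- as.integer(grid_resolution)
  d1 <- seq(bounds$lower[1], bounds$upper[1], length.out = grid_resolution)
  d2 <- seq(bounds$lower[2], bounds$upper[2], length.out = grid_resolution)
  g <- expand.grid(d1 = d1, d2 = d2, KEEP.OUT.ATTRS = FALSE)
  d3 <- -g$d1 - g$d2
  feas <- g$d1 >= bounds$lower[1] + eps & g$d1 <= bounds$upper[1] - eps &
    g$d2 >= bounds$lower[2] + eps & g$d2 <= bounds$upper[2] - eps &
    d3 >= bounds$lower[3] + eps & d3 <= bounds$upper[3] - eps
  # vectorised closed forms over the feasible rows
  I <- R <- rep(NA_real_, nrow(g))
  if (any(feas)) {
    D <- cbind(g$d1[feas], g$d2[feas], d3[feas])
    M <- matrix(m, nrow(D), 3, byrow = TRUE)
    up <- M + D
    dn <- M - D
    py <- M + (2 * p - 1) * D
    I[feas] <- p * rowSums(up * (log(up) - log(py))) +
      (1 - p) * rowSums(dn * (log(dn) - log(py)))
    R[feas] <- 2 * p * (1 - p) * rowSums(D * (log(up) - log(dn)))
  }
  data.frame(d1 = g$d1, d2 = g$d2, feasible = feas, I = I, R = R)
}
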