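#' Read and write channel matrices as CSV
#'
#' The CSV dialect has a header row of source labels, a first column of
#' received labels, and `"."` as decimal separator. Labels are 1-based
#' contiguous integers. Values round-trip losslessly at 17 significant
#' digits; columns are validated as stochastic on read.
#'
#' @param path File path.
#' @return `read_channel()` returns a [channel_matrix()];
#'   `write_channel()` returns `path` invisibly.
#' @export
read_channel <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) {
    stop("malformed channel file: expected received labels plus >= 2 source columns",
         call. = FALSE)
  }
  q <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(q) <- NULL
  channel_matrix(q)
}

#' @rdname read_channel
#' @param channel Channel matrix to write.
#' @export
write_channel <- function(channel, path) {
  q <- as_channel(channel)
  write_labelled_matrix(unclass(q), path)
  invisible(path)
}

#' Read and write priors as CSV or JSON
#'
#' CSV files have columns `label, probability`; JSON files map label
#' strings to probabilities. The format is chosen by file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_prior()` returns a validated prior vector ordered by
#'   label; `write_prior()` returns `path` invisibly.
#' @export
read_prior <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    probs <- as.numeric(obj[order(as.integer(names(obj)))])
  } else {
    tab <- utils::read.csv(path, comment.char = "#")
    probs <- tab[[2L]][order(as.integer(tab[[1L]]))]
  }
  prior_vector(probs)
}

#' @rdname read_prior
#' @param prior Prior vector to write.
#' @export
write_prior <- function(prior, path) {
  prior <- prior_vector(prior)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- as.list(prior)
    names(obj) <- as.character(seq_along(prior))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(label = seq_along(prior),
                 probability = format(prior, digits = 17, trim = TRUE)),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write potential tables as CSV
#'
#' Same layout as the channel CSV (positions down, source messages
#' across), preceded by a metadata comment line `# beta=<value>`.
#'
#' @param path File path.
#' @return `read_potentials()` returns a [potential_table()];
#'   `write_potentials()` returns `path` invisibly.
#' @export
read_potentials <- function(path) {
  first <- readLines(path, n = 1L)
  beta <- 1
  if (grepl("^#\\s*beta\\s*=", first)) {
    beta <- as.numeric(sub("^#\\s*beta\\s*=\\s*", "", first))
  }
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  U <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(U) <- NULL
  potential_table(U, beta = beta)
}

#' @rdname read_potentials
#' @param potentials Potential table to write.
#' @export
write_potentials <- function(potentials, path) {
  stopifnot(inherits(potentials, "potential_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beta=%s", format(potentials$beta, digits = 17)), con)
  write_labelled_matrix(potentials$U, con)
  invisible(path)
}

write_labelled_matrix <- function(m, con) {
  tab <- data.frame(seq_len(nrow(m)),
                    apply(m, 2L, format, digits = 17, trim = TRUE))
  names(tab) <- c("y", as.character(seq_len(ncol(m))))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
}

#' Worked three-message example channel and prior
#'
#' A strictly positive 3x3 channel and a three-message prior used
#' throughout the documentation and tests as the standard worked example
#' of a nonequilibrium transfer process. For this pair the recoverability,
#' mutual information and entropy production are all strictly positive and
#' `R = I + Ie = Sigma` can be checked to machine precision.
#'
#' @return `example_channel()` a [channel_matrix()]; `example_prior()` a
#'   prior vector; `two_source_presets()` a named vector of first-message
#'   prior probabilities `p` for the two-source family (presets
#'   `a`, `b`, `c`, `d`).
#' @export
example_channel <- function() {
  channel_matrix(matrix(
    c(0.4410, 0.4903, 0.0687,
      0.5558, 0.3848, 0.0594,
      0.1562, 0.3067, 0.5371),
    nrow = 3L, ncol = 3L))
}

#' @rdname example_channel
#' @export
example_prior <- function() {
  prior_vector(c(0.4610, 0.0753, 0.4637))
}

#' @rdname example_channel
#' @export
two_source_presets <- function() {
  c(a = 0.8212, b = 0.0154, c = 0.0430, d = 0.1690)
}

#' Random strictly positive channel/prior fixture
#'
#' Draws each channel column independently from a symmetric Dirichlet
#' distribution with the given concentration (via normalised gamma
#' variates), and the prior likewise. All entries are strictly positive
#' with probability one; large concentrations give near-uniform columns.
#' Deterministic for a given seed.
#'
#' @param n_src,n_rcv Alphabet sizes, both at least 2.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration parameter, positive.
#'   Default 1 (uniform over the simplex).
#' @return A list with elements `channel`, `prior`, `seed` and
#'   `concentration`.
#' @export
generate_random_fixture <- function(n_src, n_rcv, seed, concentration = 1) {
  if (n_src < 2L || n_rcv < 2L) {
    stop("need at least 2 source and 2 received messages", call. = FALSE)
  }
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  g <- matrix(stats::rgamma(n_rcv * n_src, shape = concentration),
              n_rcv, n_src)
  g[g == 0] <- .Machine$double.xmin    # guard against underflow at tiny shapes
  q <- sweep(g, 2L, colSums(g), "/")
  p <- stats::rgamma(n_src, shape = concentration)
  p[p == 0] <- .Machine$double.xmin
  list(channel = channel_matrix(q), prior = prior_vector(p / sum(p)),
       seed = as.integer(seed), concentration = concentration)
}
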