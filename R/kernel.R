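# Sub-Markovian kernels, probability vectors, and regenerative kernels.
#
# A sub-Markovian kernel K on E = {1,...,n} is a nonnegative matrix with row
# sums <= 1; the per-row deficit a(x) = 1 - sum_y K(x,y) is the one-step
# absorption probability into the cemetery state, which is never represented
# as a row/column of the matrix itself.

.TOL_STOCH <- 1e-12   # row-stochasticity slack
.TOL_DIST  <- 1e-9    # probability-vector normalisation slack

#' Construct a sub-Markovian kernel
#'
#' Wraps an `n x n` matrix of transition probabilities on the non-absorbing
#' states `1..n`. The absorption probability from state `x` is
#' `1 - sum(K[x, ])`; strict sub-Markovianity (at least one row with positive
#' absorption) is required, since for a fully Markovian kernel the
#' regenerative construction is degenerate and the QSD problem reduces to an
#' ordinary stationary distribution.
#'
#' @param mass numeric `n x n` matrix with entries in `[0, 1]` and row sums
#'   at most 1 (up to `1e-12`).
#' @param check validate invariants (default `TRUE`).
#' @return An object of class `sub_markov_kernel` with elements `mass`,
#'   `absorption` and `n_states`.
#' @examples
#' K <- sub_markov_kernel(matrix(0.3, 3, 3))
#' K$absorption
#' @export
sub_markov_kernel <- function(mass, check = TRUE) {
  mass <- as.matrix(mass)
  storage.mode(mass) <- "double"
  n <- nrow(mass)
  if (ncol(mass) != n) stop("kernel matrix must be square")
  rs <- rowSums(mass)
  absorption <- 1 - rs
  if (check) {
    if (any(mass < -.TOL_STOCH) || any(mass > 1 + .TOL_STOCH))
      stop("kernel entries must lie in [0, 1]")
    if (any(rs > 1 + .TOL_STOCH))
      stop("row sums must not exceed 1")
    if (all(rs >= 1 - .TOL_STOCH))
      stop("kernel is Markovian (all row sums equal 1); ",
           "a strictly sub-Markovian kernel is required")
  }
  # clamp away roundoff so downstream samplers see exact probabilities
  mass[mass < 0] <- 0
  absorption[absorption < 0] <- 0
  structure(
    list(mass = mass, absorption = absorption, n_states = n),
    class = "sub_markov_kernel"
  )
}

#' @export
print.sub_markov_kernel <- function(x, ...) {
  leak <- which(x$absorption > .TOL_STOCH)
  cat(sprintf("sub-Markovian kernel on %d states; %d leaking state%s\n",
              x$n_states, length(leak), if (length(leak) == 1) "" else "s"))
  cat(sprintf("total absorption mass: %.6g\n", sum(x$absorption)))
  invisible(x)
}

#' @export
dim.sub_markov_kernel <- function(x) c(x$n_states, x$n_states)

#' Validate a probability vector
#'
#' Distributions on the state space (the candidate QSD `alpha`, its one-step
#' image `beta`, stationary measures, Polyak averages) are plain numeric
#' vectors; this helper enforces nonnegativity and unit mass.
#'
#' @param probs numeric vector.
#' @param n expected length (optional).
#' @return The validated vector, renormalised only for floating-point drift.
#' @export
as_distribution <- function(probs, n = NULL) {
  probs <- as.numeric(probs)
  if (!is.null(n) && length(probs) != n)
    stop(sprintf("distribution has length %d, expected %d", length(probs), n))
  if (any(!is.finite(probs)) || any(probs < -.TOL_DIST))
    stop("distribution entries must be finite and nonnegative")
  s <- sum(probs)
  if (abs(s - 1) > .TOL_DIST)
    stop(sprintf("distribution must sum to 1 (got %.12g)", s))
  probs[probs < 0] <- 0
  probs / sum(probs)
}

#' Regenerative (resurrected) kernel K_alpha
#'
#' Given a sub-Markovian kernel `K` and a distribution `alpha` on the same
#' states, builds the Markovian kernel that follows `K` while alive and, upon
#' absorption, restarts from an independent draw of `alpha`:
#' `K_alpha(x, y) = K(x, y) + a(x) * alpha(y)` with `a(x)` the absorption
#' probability. `alpha` is the QSD of `K` exactly when `alpha` is stationary
#' for `K_alpha`.
#'
#' @param K a [sub_markov_kernel()].
#' @param alpha regeneration distribution (numeric vector of length
#'   `K$n_states`).
#' @return An object of class `regenerative_kernel` with elements `base`,
#'   `regen` and `matrix` (the row-stochastic transition matrix).
#' @examples
#' K <- loopy_chain(0.1)
#' P <- make_regenerative(K, rep(1 / 3, 3))
#' rowSums(P$matrix)
#' @export
make_regenerative <- function(K, alpha) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  alpha <- as_distribution(alpha, K$n_states)
  mat <- K$mass + outer(K$absorption, alpha)
  structure(
    list(base = K, regen = alpha, matrix = mat),
    class = "regenerative_kernel"
  )
}

#' @export
print.regenerative_kernel <- function(x, ...) {
  cat(sprintf("regenerative kernel on %d states (max row-sum deviation %.2e)\n",
              x$base$n_states, max(abs(rowSums(x$matrix) - 1))))
  invisible(x)
}

#' One-step image of a distribution under its own regenerative kernel
#'
#' Computes `beta = alpha %*% K_alpha`, the law after one step of the
#' regenerative chain started from `alpha`. The QSD is the unique fixed
#' point `beta == alpha`.
#'
#' @inheritParams make_regenerative
#' @return A probability vector of length `K$n_states`.
#' @export
one_step_distribution <- function(alpha, K) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  alpha <- as_distribution(alpha, K$n_states)
  s <- sum(alpha * K$absorption)
  beta <- drop(alpha %*% K$mass) + s * alpha
  # exactly nonnegative; normalise away last-bit drift
  beta / sum(beta)
}

#' Sample one transition of a regenerative kernel
#'
#' Performs the two-stage draw: propose the next state through the extended
#' kernel (absorb with probability `a(x)`), and on absorption resample the
#' state from the regeneration distribution. The marginal law of the result
#' is row `x` of `P$matrix`. Uses R's global random number generator.
#'
#' @param P a [make_regenerative()] kernel.
#' @param x current state in `1..n`.
#' @return Next state (integer in `1..n`).
#' @export
sample_transition <- function(P, x) {
  stopifnot(inherits(P, "regenerative_kernel"))
  n <- P$base$n_states
  if (length(x) != 1L || is.na(x) || x < 1 || x > n)
    stop("state x must lie in 1..n")
  row <- P$base$mass[x, ]
  u <- stats::runif(1)
  cs <- cumsum(row)
  y <- findInterval(u, cs) + 1L
  if (y > n) {
    # absorbed: regenerate from alpha
    y <- sample.int(n, 1L, prob = P$regen)
  }
  y
}

# ---- kernel / distribution file I/O ---------------------------------------

#' Read a sub-Markovian kernel from a delimited text file
#'
#' Accepts an `N x N` matrix of `K` entries (tab, comma or whitespace
#' delimited), optionally preceded by a header line `# states=N`. A full
#' `(N+1) x (N+1)` extended matrix whose first row/column belong to the
#' absorbing state (first row `1 0 ... 0`) is also accepted and stripped to
#' its live block.
#'
#' @param path file path.
#' @return A [sub_markov_kernel()].
#' @export
read_kernel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("^\\s*#", lines)
  lines <- lines[!header]
  sep <- if (any(grepl(",", lines))) "," else ""
  mat <- as.matrix(utils::read.table(text = lines, sep = sep, header = FALSE))
  dimnames(mat) <- NULL
  if (nrow(mat) != ncol(mat)) stop("kernel file must contain a square matrix")
  first_row_absorbing <- nrow(mat) >= 2 &&
    abs(mat[1, 1] - 1) < .TOL_STOCH && all(abs(mat[1, -1]) < .TOL_STOCH)
  if (first_row_absorbing) mat <- mat[-1, -1, drop = FALSE]
  sub_markov_kernel(mat)
}

#' Write a sub-Markovian kernel to a delimited text file
#'
#' @param K a [sub_markov_kernel()].
#' @param path output path.
#' @param extended write the full `(N+1) x (N+1)` matrix including the
#'   absorbing state as row/column 1 (default `FALSE`).
#' @export
write_kernel <- function(K, path, extended = FALSE) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  mat <- K$mass
  if (extended) {
    n <- K$n_states
    full <- matrix(0, n + 1, n + 1)
    full[1, 1] <- 1
    full[-1, -1] <- mat
    full[-1, 1] <- K$absorption
    mat <- full
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# states=%d", K$n_states), con)
  utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a distribution as single-column text
#'
#' @param path file path.
#' @return `read_distribution` returns a validated probability vector.
#' @export
read_distribution <- function(path) {
  v <- scan(path, quiet = TRUE, comment.char = "#")
  as_distribution(v)
}

#' @rdname read_distribution
#' @param probs probability vector to write.
#' @export
write_distribution <- function(probs, path) {
  writeLines(format(as.numeric(probs), digits = 17, scientific = TRUE,
                    trim = TRUE), path)
  invisible(path)
}
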