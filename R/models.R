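# Benchmark model constructors: loopy chain, absorbed M/M/1/N queue,
# SIS-type epidemic extinction chain, random sub-Markovian instances.

#' Loopy chain with uniform leak
#'
#' A fully connected chain on `m` states in which every transition
#' probability equals `(1 - eps)/m` and every state is absorbed with
#' probability `eps`. Its QSD is the uniform distribution for any `eps`.
#'
#' @param eps per-state absorption probability in `(0, 1)`.
#' @param m number of live states (default 3).
#' @return A [sub_markov_kernel()].
#' @export
loopy_chain <- function(eps, m = 3L) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1)
    stop("eps must lie strictly between 0 and 1")
  if (m < 2) stop("m must be at least 2")
  sub_markov_kernel(matrix((1 - eps) / m, m, m))
}

#' Queue drift specification
#'
#' Holds the per-state drift ratios `rho_i` of the absorbed M/M/1/N queue;
#' `rho_i > 1` biases jumps to the right. A scalar broadcasts to all states;
#' the preset `"linear-drift"` is `rho_i = 2 - 3 (i - 1) / (2 N - 4)`, whose
#' crossing of 1 near `i = 2N/3` places the QSD peak there.
#'
#' @param capacity queue capacity `N` (number of live states).
#' @param rho positive scalar or length-`N` vector, or the string
#'   `"linear-drift"`.
#' @return An object of class `queue_spec`.
#' @export
queue_spec <- function(capacity, rho = 1.25) {
  N <- as.integer(capacity)
  if (N < 3) stop("capacity must be at least 3")
  if (identical(rho, "linear-drift")) {
    i <- seq_len(N)
    rho <- 2 - 3 * (i - 1) / (2 * N - 4)
  }
  rho <- as.numeric(rho)
  if (length(rho) == 1L) rho <- rep(rho, N)
  if (length(rho) != N) stop("rho must be scalar or length N")
  if (any(rho <= 0)) stop("all drift ratios rho_i must be positive")
  structure(list(capacity = N, rho = rho), class = "queue_spec")
}

#' Absorbed M/M/1/N queue
#'
#' Discrete birth-death chain on `{1, ..., N}` with up-probability
#' `lambda_i = rho_i / (rho_i + 1)` and down-probability
#' `mu_i = 1 / (rho_i + 1)`. State 1 leaks into the absorbing empty queue
#' with probability `mu_1`; state `N` reflects to `N - 1`; every interior row
#' is stochastic, so state 1 is the only leak.
#'
#' @param spec a [queue_spec()], or a capacity `N` (then `rho` applies).
#' @param rho used only when `spec` is a number.
#' @return A [sub_markov_kernel()].
#' @examples
#' K <- mm1_queue(queue_spec(10, 1.25))
#' K$absorption[1]  # 1 / (1.25 + 1)
#' @export
mm1_queue <- function(spec, rho = 1.25) {
  if (!inherits(spec, "queue_spec")) spec <- queue_spec(spec, rho)
  N <- spec$capacity
  mu <- 1 / (spec$rho + 1)
  lam <- 1 - mu   # rho/(rho+1), written so interior rows sum to exactly 1
  mat <- matrix(0, N, N)
  mat[1, 2] <- lam[1]                      # absorption from 1 with prob mu_1
  for (i in 2:(N - 1)) {
    mat[i, i - 1] <- mu[i]
    mat[i, i + 1] <- lam[i]
  }
  mat[N, N - 1] <- 1                       # reflecting right boundary
  sub_markov_kernel(mat)
}

#' SIS-type epidemic extinction chain (synthetic benchmark)
#'
#' Discrete-time birth-death chain on the number of infected individuals
#' `{1, ..., N}` in a population of size `N`, with infection pressure
#' `beta * i * (N - i) / N` and recovery pressure `gamma * i`, uniformised by
#' a constant rate so that all rows are sub-stochastic. The only leak is
#' recovery from a single infected individual (state 1), so the QSD is the
#' classical endemic distribution conditioned on non-extinction. This model
#' is a package-native fixture, not an established benchmark from the literature.
#'
#' @param N population size (`>= 2`).
#' @param beta infection rate (positive).
#' @param gamma recovery rate (positive).
#' @param uniformization event-rate bound; defaults to the maximum total
#'   rate so that rows sum to at most 1.
#' @return A [sub_markov_kernel()].
#' @export
sis_extinction_chain <- function(N, beta, gamma, uniformization = NULL) {
  N <- as.integer(N)
  if (N < 2) stop("N must be at least 2")
  if (beta < 0 || gamma <= 0) stop("rates must be positive (beta may be 0)")
  i <- seq_len(N)
  up <- beta * i * (N - i) / N
  down <- gamma * i
  rate_bound <- max(up + down)
  if (is.null(uniformization)) uniformization <- rate_bound
  if (uniformization + 1e-12 < rate_bound) {
    bad <- which.max(up + down)
    stop(sprintf("uniformization constant %.4g below total rate %.4g at state %d",
                 uniformization, rate_bound, bad))
  }
  p_up <- up / uniformization
  p_down <- down / uniformization
  mat <- matrix(0, N, N)
  for (s in i) {
    if (s < N) mat[s, s + 1] <- p_up[s]
    if (s > 1) mat[s, s - 1] <- p_down[s]
    mat[s, s] <- 1 - p_up[s] - p_down[s]
  }
  # state 1's downward move is extinction: left out of the matrix entirely.
  # fold rounding residue of rows >= 2 into the diagonal so that only state 1
  # carries absorption mass
  resid <- 1 - rowSums(mat)
  mat[cbind(2:N, 2:N)] <- mat[cbind(2:N, 2:N)] + resid[2:N]
  sub_markov_kernel(mat)
}

#' Random strictly sub-Markovian instance
#'
#' Generates a reproducible irreducible kernel on `n` states in which exactly
#' `leak_states` rows have row sum strictly below 1. A positive cycle
#' `1 -> 2 -> ... -> n -> 1` is always present so irreducibility holds for
#' any density.
#'
#' @param n number of states.
#' @param leak_states number of leaking rows (`1..n`).
#' @param density expected fraction of additional positive entries.
#' @param seed integer seed (local to this call).
#' @return A [sub_markov_kernel()].
#' @export
random_submarkov <- function(n, leak_states = 1L, density = 0.5, seed = 1L) {
  n <- as.integer(n)
  leak_states <- as.integer(leak_states)
  if (leak_states < 1 || leak_states > n)
    stop("leak_states must lie in 1..n")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mat <- matrix(stats::runif(n * n), n, n) *
    (matrix(stats::runif(n * n), n, n) < density)
  mat[cbind(seq_len(n), c(seq_len(n)[-1], 1L))] <- stats::runif(n, 0.5, 1)
  rs <- rowSums(mat)
  mat <- mat / rs                                  # stochastic rows
  leak <- sample.int(n, leak_states)
  mat[leak, ] <- mat[leak, , drop = FALSE] * stats::runif(leak_states, 0.55, 0.9)
  sub_markov_kernel(mat)
}
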