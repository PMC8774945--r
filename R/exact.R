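# Exact reference solvers: principal left eigenvector (the QSD), stationary
# distributions of regenerative kernels, and the exact KL divergence rate.

#' Exact quasi-stationary distribution by left eigendecomposition
#'
#' The QSD of an irreducible strictly sub-Markovian kernel is the principal
#' left eigenvector of `K`, normalised to a probability vector; the associated
#' eigenvalue `lambda = sum_x alpha(x) K(x, E)` in `(0, 1)` is the one-step
#' survival probability under the QSD (Perron-Frobenius).
#'
#' @param K a [sub_markov_kernel()].
#' @param method `"eigen"` (dense eigendecomposition, default for
#'   `n <= 2000`), `"power"` (damped power iteration on `(K + I)/2`, immune to
#'   period-2 oscillation of birth-death chains), or `"auto"`.
#' @param tol residual tolerance for the power iteration.
#' @param max_iter iteration cap for the power iteration.
#' @return A list with `qsd` (probability vector) and `survival` (the
#'   eigenvalue `lambda`).
#' @examples
#' exact_qsd(loopy_chain(0.25))$qsd  # uniform for any leak probability
#' @export
exact_qsd <- function(K, method = c("auto", "eigen", "power"),
                      tol = 1e-13, max_iter = 200000L) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  method <- match.arg(method)
  if (method == "auto") method <- if (K$n_states <= 2000) "eigen" else "power"
  if (!is_irreducible(K))
    warning("kernel is not irreducible; the QSD may not be unique")
  n <- K$n_states
  if (method == "eigen") {
    e <- eigen(t(K$mass))
    # bipartite chains (e.g. birth-death with no holding) have a -lambda
    # partner of equal modulus; the Perron root is the one with maximal
    # real part among the maximal-modulus eigenvalues
    mods <- Mod(e$values)
    cand <- which(mods >= max(mods) * (1 - 1e-9))
    i <- cand[which.max(Re(e$values[cand]))]
    lambda <- e$values[i]
    v <- e$vectors[, i]
    if (abs(Im(lambda)) > 1e-9 * max(1, Mod(lambda)))
      stop("principal eigenvalue is not real; kernel may be reducible")
    lambda <- Re(lambda)
    v <- Re(v)
    if (sum(v) < 0) v <- -v
    # eigen() leaves O(eps * ||v||) noise in near-zero tail entries; only
    # material negative mass indicates a genuine sign change
    if (-sum(pmin(v, 0)) > 1e-8 * sum(pmax(v, 0)))
      warning("principal eigenvector has sign changes; kernel may be reducible")
    v[v < 0] <- 0
    alpha <- v / sum(v)
  } else {
    # damped iteration: (K + I)/2 has the same eigenvectors as K with
    # eigenvalues (lambda + 1)/2, so the period-2 modes of bipartite
    # birth-death chains no longer tie with the Perron root in modulus
    alpha <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      nxt <- 0.5 * (drop(alpha %*% K$mass) + alpha)
      nxt <- nxt / sum(nxt)
      if (max(abs(nxt - alpha)) < tol) {
        alpha <- nxt
        break
      }
      alpha <- nxt
    }
    if (it == max_iter) warning("power iteration did not converge")
    lambda <- sum(drop(alpha %*% K$mass))
  }
  list(qsd = as_distribution(alpha), survival = lambda)
}

#' Exact stationary distribution of a regenerative kernel
#'
#' Solves `mu P = mu`, `sum(mu) = 1` by a direct linear solve of the
#' rank-augmented system; falls back to power iteration if the solve is
#' ill-conditioned.
#'
#' @param P a [make_regenerative()] kernel (ergodic; guaranteed when the
#'   regeneration distribution is strictly positive).
#' @return Stationary probability vector `mu`.
#' @export
exact_stationary <- function(P) {
  stopifnot(inherits(P, "regenerative_kernel"))
  n <- P$base$n_states
  A <- rbind(t(P$matrix) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  mu <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu)) || any(mu < -1e-8)) {
    mu <- rep(1 / n, n)
    for (it in seq_len(500000L)) {
      nxt <- 0.5 * (drop(mu %*% P$matrix) + mu)
      nxt <- nxt / sum(nxt)
      if (max(abs(nxt - mu)) < 1e-14) {
        mu <- nxt
        break
      }
      mu <- nxt
    }
  }
  mu[mu < 0] <- 0
  res <- max(abs(drop(mu %*% P$matrix) - mu))
  if (res > 1e-8)
    stop(sprintf("stationary solve failed (residual %.3g); kernel may not be ergodic", res))
  as_distribution(mu)
}

#' Exact KL divergence rate between K_alpha and K_beta path measures
#'
#' For a strictly positive candidate `alpha`, computes the per-step
#' Kullback-Leibler divergence rate between the paths of the regenerative
#' chain `K_alpha` and those of `K_beta` with `beta = alpha K_alpha`:
#' `sum_{x,y} mu(x) K_alpha(x,y) log(K_alpha(x,y) / K_beta(x,y))` where `mu`
#' is the stationary law of `K_alpha`. The rate is nonnegative and vanishes
#' exactly at the QSD; its negative is the average reward maximised by the
#' actor-critic algorithm.
#'
#' @inheritParams make_regenerative
#' @return Nonnegative scalar.
#' @export
kl_rate_exact <- function(K, alpha) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  alpha <- as_distribution(alpha, K$n_states)
  if (any(alpha <= 0))
    stop("alpha must be strictly positive for the KL rate to be finite")
  Pa <- make_regenerative(K, alpha)
  beta <- one_step_distribution(alpha, K)
  Pb <- make_regenerative(K, beta)
  mu <- exact_stationary(Pa)
  A <- Pa$matrix
  B <- Pb$matrix
  pos <- A > 0
  terms <- matrix(0, nrow(A), ncol(A))
  terms[pos] <- A[pos] * log(A[pos] / B[pos])
  val <- sum(mu * rowSums(terms))
  max(val, 0)
}

#' Irreducibility check of the positive-entry transition graph
#'
#' Strong connectivity of the directed graph with an edge `x -> y` whenever
#' `K(x, y) > 0`, via forward/backward reachability from state 1.
#'
#' @param K a [sub_markov_kernel()].
#' @return Logical.
#' @export
is_irreducible <- function(K) {
  adj <- K$mass > 0
  reach <- function(a) {
    seen <- logical(nrow(a))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  all(reach(adj)) && all(reach(t(adj)))
}
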