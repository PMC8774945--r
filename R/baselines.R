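# Classical QSD estimators used as comparison baselines: the single-particle
# empirical scheme, projected stochastic approximation (with optional Polyak
# averaging), and the Fleming-Viot particle system.

#' Euclidean projection onto the probability simplex
#'
#' Sort-and-threshold algorithm: sort `v` in decreasing order, find the
#' largest `j` with `v_(j) + (1 - sum_{i<=j} v_(i)) / j > 0`, shift by the
#' corresponding multiplier and clip at zero. `O(m log m)` in the state count.
#'
#' @param v numeric vector with finite entries.
#' @return The nearest (in L2) probability vector.
#' @examples
#' simplex_project(c(1.2, -0.2))  # (1, 0)
#' @export
simplex_project <- function(v) {
  if (any(!is.finite(v))) stop("entries must be finite")
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(v)
  rho <- max(j[u + (1 - css) / j > 0])
  lambda <- (1 - css[rho]) / rho
  pmax(v + lambda, 0)
}

#' Simulate one absorbed episode
#'
#' Runs the extended chain from `X0 ~ alpha0` under the kernel plus absorbing
#' state until extinction, recording the visit counts to each live state
#' (`X_0` through `X_{tau-1}`; the visit counts sum to the extinction time).
#'
#' @param K a [sub_markov_kernel()].
#' @param alpha0 initial distribution.
#' @return List with `visit_counts` (integer vector) and `tau` (extinction
#'   time).
#' @export
run_episode <- function(K, alpha0) {
  stopifnot(inherits(K, "sub_markov_kernel"))
  n <- K$n_states
  alpha0 <- as_distribution(alpha0, n)
  cum <- t(apply(K$mass, 1, cumsum))
  counts <- integer(n)
  x <- sample.int(n, 1L, prob = alpha0)
  tau <- 0L
  repeat {
    counts[x] <- counts[x] + 1L
    tau <- tau + 1L
    y <- findInterval(stats::runif(1), cum[x, ]) + 1L
    if (y > n) break
    x <- y
  }
  list(visit_counts = counts, tau = tau)
}

# shared episode-trace recorder: log-spaced evaluation points
.eval_points <- function(n_episodes, n_points = 200L) {
  pts <- unique(round(exp(seq(log(1), log(n_episodes), length.out = n_points))))
  pts[pts >= 1 & pts <= n_episodes]
}

#' Single-particle empirical ("vanilla") scheme
#'
#' Maintains the cumulative occupation estimate
#' `alpha_n = (total visit counts) / (total time)`, starting each episode
#' from `X0 ~ alpha_n`. This cumulative-ratio form satisfies the weighted
#' empirical-average recursion
#' `alpha_{n+1} = alpha_n + (counts_{n+1} - tau_{n+1} alpha_n) / sum_{j<=n+1} tau_j`
#' exactly, stays on the simplex without projection, and converges at rate
#' `O(n^{-1/2})`.
#'
#' @param K a [sub_markov_kernel()].
#' @param n_episodes number of absorbed episodes.
#' @param seed integer seed.
#' @param reference QSD used for the error trace; computed when omitted.
#' @param form `"cumulative"` (default) or `"recursive"` (the literal
#'   recursion, kept for the algebraic-identity check; both produce the same
#'   iterates up to floating point).
#' @param alpha0 initial distribution (uniform by default).
#' @return A list of class `qsd_baseline_fit` with `alpha` (final estimate)
#'   and `trace` (`iteration`, `l2_error`).
#' @export
run_vanilla <- function(K, n_episodes, seed = 1L, reference = NULL,
                        form = c("cumulative", "recursive"), alpha0 = NULL) {
  stopifnot(inherits(K, "sub_markov_kernel"), n_episodes >= 1)
  form <- match.arg(form)
  n <- K$n_states
  if (is.null(reference)) reference <- exact_qsd(K)$qsd
  if (is.null(alpha0)) alpha0 <- rep(1 / n, n)
  alpha <- as_distribution(alpha0, n)
  set.seed(seed)
  pts <- .eval_points(n_episodes)
  ev_err <- numeric(length(pts))
  k <- 0L
  tot_counts <- numeric(n)
  tot_time <- 0
  for (ep in seq_len(n_episodes)) {
    res <- run_episode(K, alpha)
    if (form == "cumulative") {
      tot_counts <- tot_counts + res$visit_counts
      tot_time <- tot_time + res$tau
      alpha <- tot_counts / tot_time
    } else {
      tot_time <- tot_time + res$tau
      alpha <- alpha + (res$visit_counts - res$tau * alpha) / tot_time
    }
    if (k < length(pts) && ep == pts[k + 1L]) {
      k <- k + 1L
      ev_err[k] <- sqrt(sum((alpha - reference)^2))
    }
  }
  structure(list(alpha = as_distribution(alpha),
                 trace = data.frame(iteration = pts, l2_error = ev_err),
                 reference = reference),
            class = "qsd_baseline_fit")
}

#' Projected stochastic approximation, with optional Polyak averaging
#'
#' Iterates `alpha_{n+1} = Proj_simplex(alpha_n + eps_n (occ_{n+1} -
#' alpha_n))` where `occ_{n+1}` is the empirical occupation measure
#' (`visit_counts / tau`) of an episode started from `alpha_n` and `Proj` is
#' [simplex_project()]. The step sizes must satisfy the usual Robbins-Monro
#' conditions (e.g. `eps_n = n^-0.99`). `normalized = FALSE` uses raw visit
#' counts in the innovation instead; that variant is kept for comparison but
#' has no drift toward the QSD on chains whose rows are identical (the
#' post-first-step occupation is then independent of `alpha`), so the
#' normalised occupation is the default.
#'
#' @inheritParams run_vanilla
#' @param eps_n step-size schedule (see [parse_lr()]; default `"pow:0.99"`).
#' @param normalized divide visit counts by the episode length
#'   (default `TRUE`).
#' @param polyak also track the running Polyak average of the iterates.
#' @return A `qsd_baseline_fit`; when `polyak = TRUE`, `alpha_polyak` and a
#'   `polyak_error` trace column are included.
#' @export
run_projection <- function(K, n_episodes, eps_n = "pow:0.99", seed = 1L,
                           reference = NULL, normalized = TRUE,
                           polyak = FALSE, alpha0 = NULL) {
  stopifnot(inherits(K, "sub_markov_kernel"), n_episodes >= 1)
  n <- K$n_states
  eps_n <- parse_lr(eps_n)
  if (is.null(reference)) reference <- exact_qsd(K)$qsd
  if (is.null(alpha0)) alpha0 <- rep(1 / n, n)
  alpha <- as_distribution(alpha0, n)
  nu <- alpha
  set.seed(seed)
  pts <- .eval_points(n_episodes)
  ev_err <- ev_nu <- numeric(length(pts))
  k <- 0L
  for (ep in seq_len(n_episodes)) {
    res <- run_episode(K, alpha)
    innov <- if (normalized) res$visit_counts / res$tau else res$visit_counts
    alpha <- simplex_project(alpha + eps_n(ep) * (innov - alpha))
    if (polyak) nu <- nu + (alpha - nu) / ep
    if (k < length(pts) && ep == pts[k + 1L]) {
      k <- k + 1L
      ev_err[k] <- sqrt(sum((alpha - reference)^2))
      ev_nu[k] <- sqrt(sum((nu - reference)^2))
    }
  }
  trace <- data.frame(iteration = pts, l2_error = ev_err)
  out <- list(alpha = as_distribution(alpha), trace = trace,
              reference = reference)
  if (polyak) {
    out$alpha_polyak <- as_distribution(nu)
    out$trace$polyak_error <- ev_nu
  }
  structure(out, class = "qsd_baseline_fit")
}

#' Polyak (running) average of a sequence of iterates
#'
#' `nu_n = (alpha_1 + ... + alpha_n) / n`, computed incrementally; averaging
#' the stochastic-approximation iterates improves the convergence rate.
#'
#' @param alphas matrix whose rows are the iterates `alpha_k`.
#' @return Matrix of the same shape whose row `n` is `nu_n`.
#' @export
polyak_average <- function(alphas) {
  alphas <- as.matrix(alphas)
  if (nrow(alphas) < 1) stop("need at least one iterate")
  apply(alphas, 2, cumsum) / seq_len(nrow(alphas))
}

#' Fleming-Viot particle system
#'
#' `n_particles` walkers evolve synchronously under the extended kernel; any
#' walker absorbed in a step is instantly restarted at the pre-update
#' position of a uniformly chosen surviving walker (if all but one die, the
#' survivors are resampled with replacement). Returns the final-time
#' empirical law and the time average over the second half of the run, which
#' is the better QSD estimate.
#'
#' @param K a [sub_markov_kernel()].
#' @param n_particles number of walkers (>= 2).
#' @param n_steps number of synchronous update rounds.
#' @param seed integer seed.
#' @param reference QSD for the error trace; computed when omitted.
#' @return A list of class `qsd_baseline_fit` with `alpha` (time-averaged
#'   law), `alpha_final` (final empirical law) and a trace of L-infinity
#'   errors of the running time average.
#' @export
run_fleming_viot <- function(K, n_particles, n_steps, seed = 1L,
                             reference = NULL) {
  stopifnot(inherits(K, "sub_markov_kernel"), n_particles >= 2, n_steps >= 2)
  n <- K$n_states
  if (is.null(reference)) reference <- exact_qsd(K)$qsd
  set.seed(seed)
  cum <- t(apply(K$mass, 1, cumsum))     # proposal cdf, absorb past column n
  x <- sample.int(n, n_particles, replace = TRUE)
  half <- n_steps %/% 2L
  acc <- numeric(n)
  acc_steps <- 0L
  pts <- .eval_points(n_steps, 100L)
  ev <- numeric(length(pts))
  k <- 0L
  for (t in seq_len(n_steps)) {
    u <- stats::runif(n_particles)
    y <- integer(n_particles)
    for (p in seq_len(n_particles))
      y[p] <- findInterval(u[p], cum[x[p], ]) + 1L
    dead <- which(y > n)
    if (length(dead)) {
      alive <- which(y <= n)
      if (!length(alive))
        stop("all particles were absorbed in one step; increase n_particles")
      # adopt pre-update positions of uniformly chosen survivors
      y[dead] <- x[sample(alive, length(dead), replace = TRUE)]
    }
    x <- y
    if (t > half) {
      acc <- acc + tabulate(x, n)
      acc_steps <- acc_steps + 1L
    }
    if (k < length(pts) && t == pts[k + 1L]) {
      k <- k + 1L
      est <- if (acc_steps > 0) acc / (acc_steps * n_particles)
             else tabulate(x, n) / n_particles
      ev[k] <- max(abs(est - reference))
    }
  }
  avg <- acc / (acc_steps * n_particles)
  structure(list(alpha = as_distribution(avg),
                 alpha_final = tabulate(x, n) / n_particles,
                 trace = data.frame(iteration = pts, linf_error = ev),
                 reference = reference),
            class = "qsd_baseline_fit")
}

#' @export
print.qsd_baseline_fit <- function(x, ...) {
  err <- x$trace[nrow(x$trace), ncol(x$trace)]
  cat(sprintf("baseline QSD fit: %d evaluation points, final error %.4g\n",
              nrow(x$trace), err))
  invisible(x)
}
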