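# The average-reward objective: one-step reward, exact average reward, exact
# differential value function, and the analytic policy gradient together with
# its finite-difference oracle.
#
# Throughout, alpha = alpha_theta is the softmax candidate, K_alpha its
# regenerative kernel, beta = alpha K_alpha the one-step image, and the
# one-step reward is R(x, y) = -log(K_alpha(x, y) / K_beta(x, y)). The
# average reward r(theta) is the negative KL divergence rate between the path
# measures of K_alpha and K_beta; it is <= 0 with equality exactly at the QSD.

.LOG_FLOOR <- 1e-300

# shared precomputations for one (K, theta) pair
.objective_ctx <- function(K, pol) {
  alpha <- policy_distribution(pol)
  a <- K$absorption
  s <- sum(alpha * a)
  beta <- drop(alpha %*% K$mass) + s * alpha
  beta <- beta / sum(beta)
  list(K = K, alpha = alpha, a = a, s = s, beta = beta,
       Ka = K$mass + outer(a, alpha), Kb = K$mass + outer(a, beta))
}

.safe_log_ratio <- function(num, den) {
  if (any(num < .LOG_FLOOR) || any(den < .LOG_FLOOR))
    warning("probability floored at 1e-300 inside a logarithm; ",
            "the policy has effectively degenerated")
  log(pmax(num, .LOG_FLOOR)) - log(pmax(den, .LOG_FLOOR))
}

#' One-step reward of the KL-rate objective
#'
#' `R_theta(x, y) = -log(K_alpha(x, y) / K_beta(x, y))`. Identically zero at
#' the QSD, and zero whenever `x` does not leak (then row `x` of both kernels
#' equals row `x` of `K`).
#'
#' @param K a [sub_markov_kernel()].
#' @param pol a [softmax_policy()].
#' @param x,y states in `1..n` (vectorised, recycled to common length).
#' @return Numeric vector of rewards.
#' @export
reward <- function(K, pol, x, y) {
  ctx <- .objective_ctx(K, pol)
  num <- ctx$Ka[cbind(x, y)]
  den <- ctx$Kb[cbind(x, y)]
  if (any(num <= 0))
    stop("reward queried at a transition with zero probability under K_alpha")
  -.safe_log_ratio(num, den)
}

#' Exact average reward
#'
#' The negative KL divergence rate, `-kl_rate_exact(K, alpha_theta)`,
#' computed through the stationary law of `K_alpha`. Always `<= 0`, with
#' equality iff `alpha_theta` is the QSD.
#'
#' @inheritParams reward
#' @return Nonpositive scalar.
#' @export
average_reward_exact <- function(K, pol) {
  -kl_rate_exact(K, policy_distribution(pol))
}

# reward matrix (0 where K_alpha(x,y) == 0) and expected one-step reward
.reward_matrix <- function(ctx) {
  pos <- ctx$Ka > 0
  R <- matrix(0, nrow(ctx$Ka), ncol(ctx$Ka))
  R[pos] <- -(log(pmax(ctx$Ka[pos], .LOG_FLOOR)) -
                log(pmax(ctx$Kb[pos], .LOG_FLOOR)))
  R
}

#' Exact differential value function
#'
#' Solves the average-reward Bellman equation
#' `V(x) = E_{Y ~ K_alpha(x, .)}[ V(Y) + R(x, Y) - r(theta) ]` for the
#' tabular value function. The system is rank-deficient by one; the centering
#' constraint `sum_x mu_theta(x) V(x) = 0` implied by the series definition of
#' the differential value is appended to pin the solution.
#'
#' @inheritParams reward
#' @return A [tabular_value()] whose `psi` has Bellman residual below 1e-10.
#' @export
value_exact <- function(K, pol) {
  ctx <- .objective_ctx(K, pol)
  n <- K$n_states
  Pa <- ctx$Ka
  R <- .reward_matrix(ctx)
  mu <- exact_stationary(make_regenerative(K, ctx$alpha))
  Rbar <- rowSums(Pa * R)
  r <- sum(mu * Rbar)
  A <- rbind(diag(n) - Pa, mu)
  b <- c(Rbar - r, 0)
  V <- qr.solve(A, b)
  res <- max(abs((diag(n) - Pa) %*% V - (Rbar - r)))
  if (res > 1e-10)
    warning(sprintf("Bellman residual %.3g exceeds 1e-10", res))
  tabular_value(V)
}

#' Gradient of the log regenerative kernel entry
#'
#' `grad_theta log K_alpha(x, y) = a(x) * J[y, ] / K_alpha(x, y)` where `J`
#' is the softmax Jacobian; identically zero when state `x` does not leak.
#'
#' @inheritParams reward
#' @param x,y a single transition.
#' @return Numeric vector of length `n - 1`.
#' @export
grad_log_regen <- function(K, pol, x, y) {
  ctx <- .objective_ctx(K, pol)
  kxy <- ctx$Ka[x, y]
  if (kxy <= 0) stop("transition has zero probability under K_alpha")
  if (ctx$a[x] == 0) return(numeric(K$n_states - 1))
  J <- policy_jacobian(pol)
  ctx$a[x] * J[y, ] / kxy
}

# gradient of beta as an (n-1) x n matrix: column y is grad_theta beta(y).
# d beta(y) = sum_x J[x,]' K(x,y) + (J' a) alpha(y) + s J[y,]'
.grad_beta_matrix <- function(ctx, J) {
  t(J) %*% ctx$K$mass + outer(drop(crossprod(J, ctx$a)), ctx$alpha) +
    ctx$s * t(J)
}

#' Gradient of the log one-step kernel entry
#'
#' `grad_theta log K_beta(x, y) = a(x) * grad_theta beta(y) / K_beta(x, y)`
#' with `grad beta(y) = J' K[, y] + (J' a) alpha(y) + s J[y, ]`, where
#' `s = sum_x alpha(x) a(x)`. Zero when state `x` does not leak.
#'
#' @inheritParams grad_log_regen
#' @return Numeric vector of length `n - 1`.
#' @export
grad_log_onestep <- function(K, pol, x, y) {
  ctx <- .objective_ctx(K, pol)
  kxy <- ctx$Kb[x, y]
  if (kxy <= 0) stop("transition has zero probability under K_beta")
  if (ctx$a[x] == 0) return(numeric(K$n_states - 1))
  J <- policy_jacobian(pol)
  G <- .grad_beta_matrix(ctx, J)
  ctx$a[x] * G[, y] / kxy
}

#' Exact policy gradient of the average reward
#'
#' Evaluates the policy-gradient identity
#' `grad r(theta) = E[(R(X,Y) - b + V(Y) - V(X)) grad log K_alpha(X,Y)
#'                    + grad log K_beta(X,Y)]`
#' exactly, with `(X, Y) ~ mu_theta(x) K_alpha(x, y)`, `V` the exact
#' differential value and `b = r(theta)` by default. Any constant baseline
#' `b` yields the same gradient (score-function identity), which is exposed
#' for testing.
#'
#' @inheritParams reward
#' @param baseline constant `b` subtracted inside the bracket; `NULL` (the
#'   default) uses the exact average reward.
#' @return Numeric vector of length `n - 1`.
#' @export
policy_gradient_exact <- function(K, pol, baseline = NULL) {
  ctx <- .objective_ctx(K, pol)
  n <- K$n_states
  mu <- exact_stationary(make_regenerative(K, ctx$alpha))
  R <- .reward_matrix(ctx)
  Rbar <- rowSums(ctx$Ka * R)
  r <- sum(mu * Rbar)
  b <- if (is.null(baseline)) r else baseline
  V <- value_exact(K, pol)$psi
  J <- policy_jacobian(pol)
  # bracket B(x,y) = R(x,y) - b + V(y) - V(x); the a(x)/K_alpha factor of
  # grad log K_alpha cancels the K_alpha weight, leaving
  # term1_j = sum_y J[y,j] c(y), c(y) = sum_{x leaking} mu(x) a(x) B(x,y)
  leak <- which(ctx$a > 0)
  w <- mu[leak] * ctx$a[leak]
  Bm <- R[leak, , drop = FALSE] - b +
    matrix(V, length(leak), n, byrow = TRUE) - V[leak]
  cvec <- drop(crossprod(Bm, w))
  term1 <- drop(crossprod(J[, , drop = FALSE], cvec))
  # term2_j = sum_y gradbeta[j, y] d(y),
  # d(y) = sum_{x leaking} mu(x) a(x) K_alpha(x,y) / K_beta(x,y)
  G <- .grad_beta_matrix(ctx, J)
  ratio <- ctx$Ka[leak, , drop = FALSE] / ctx$Kb[leak, , drop = FALSE]
  dvec <- drop(crossprod(ratio, w))
  term2 <- drop(G %*% dvec)
  term1 + term2
}

#' Central finite-difference policy gradient (independent oracle)
#'
#' Componentwise central differences of [average_reward_exact()], used as
#' the arbiter of the analytic gradient (the closed forms for the kernel-log
#' gradients are re-derived, so they are continuously validated against this
#' oracle rather than trusted).
#'
#' @inheritParams reward
#' @param h step size (default `1e-5`).
#' @return Numeric vector of length `n - 1`.
#' @export
policy_gradient_fd <- function(K, pol, h = 1e-5) {
  theta <- pol$theta
  vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    (average_reward_exact(K, softmax_policy(up)) -
       average_reward_exact(K, softmax_policy(dn))) / (2 * h)
  }, numeric(1))
}
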