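# Softmax policy over states (the candidate QSD) and tabular value function.

#' Softmax policy: the candidate QSD
#'
#' Parametrises a strictly positive distribution on `{1, ..., n}` by `n - 1`
#' free logits with the last logit pinned to zero:
#' `alpha_theta(i) = exp(theta_i) / (exp(theta_1) + ... + exp(theta_{n-1}) + 1)`.
#' This tabular form represents any interior point of the simplex without
#' approximation error, and the pinning removes the usual softmax shift
#' degeneracy so gradients live in an `(n-1)`-dimensional chart.
#'
#' @param theta numeric vector of length `n - 1` (finite).
#' @return An object of class `softmax_policy`.
#' @export
softmax_policy <- function(theta) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) stop("logits must be finite")
  structure(list(theta = theta), class = "softmax_policy")
}

#' @export
print.softmax_policy <- function(x, ...) {
  cat(sprintf("softmax policy on %d states (last logit pinned to 0)\n",
              length(x$theta) + 1L))
  invisible(x)
}

#' Distribution induced by a softmax policy
#'
#' @param pol a [softmax_policy()].
#' @return Strictly positive probability vector of length
#'   `length(pol$theta) + 1`.
#' @export
policy_distribution <- function(pol) {
  stopifnot(inherits(pol, "softmax_policy"))
  full <- c(pol$theta, 0)
  e <- exp(full - max(full))        # log-sum-exp stabilisation
  e / sum(e)
}

#' Logits reproducing a target distribution
#'
#' Inverse of [policy_distribution()]: for a strictly positive target
#' `alpha`, returns `theta_i = log(alpha_i / alpha_n)`.
#'
#' @param alpha strictly positive probability vector.
#' @return A [softmax_policy()].
#' @export
policy_from_distribution <- function(alpha) {
  alpha <- as_distribution(alpha)
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  n <- length(alpha)
  softmax_policy(log(alpha[-n] / alpha[n]))
}

#' Jacobian of the softmax map
#'
#' Returns the `n x (n-1)` matrix `J[i, j] = d alpha_i / d theta_j =
#' alpha_i (1{i == j} - alpha_j)`. Every column sums to zero (probability
#' conservation).
#'
#' @param pol a [softmax_policy()].
#' @return Numeric matrix.
#' @export
policy_jacobian <- function(pol) {
  alpha <- policy_distribution(pol)
  n <- length(alpha)
  J <- -outer(alpha, alpha[-n])
  J[cbind(seq_len(n - 1), seq_len(n - 1))] <-
    J[cbind(seq_len(n - 1), seq_len(n - 1))] + alpha[-n]
  J
}

#' Tabular value function
#'
#' The differential value function in tabular form, `V_psi(x) = psi_x`.
#'
#' @param psi numeric vector of finite values, one per state.
#' @return An object of class `tabular_value`.
#' @export
tabular_value <- function(psi) {
  psi <- as.numeric(psi)
  if (any(!is.finite(psi))) stop("value entries must be finite")
  structure(list(psi = psi), class = "tabular_value")
}

#' @export
print.tabular_value <- function(x, ...) {
  cat(sprintf("tabular value function on %d states (range [%.4g, %.4g])\n",
              length(x$psi), min(x$psi), max(x$psi)))
  invisible(x)
}
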