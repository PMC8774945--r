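# Average-reward actor-critic for the QSD ("ac-alpha").
#
# One iteration advances B persistent chains one (or more) steps under the
# current regenerative kernel K_alpha, computes the TD error
#   delta = R(X, Y) - r_t + V(Y) - V(X)
# at the time-t parameters, and applies three simultaneous stochastic
# updates (batch means):
#   actor   theta <- theta + eta_theta * mean[ delta * grad log K_alpha(X,Y)
#                                              + grad log K_beta(X,Y) ]
#   critic  psi   <- psi   + eta_psi   * mean[ delta * e_X ]
#   reward  r     <- r     + eta_r     * mean[ delta ]
#
# The stochastic actor update is supported only on transitions leaving a
# leaking state (both kernel-log gradients carry the factor a(x)). For
# chains such as the absorbed queue whose single leaking state is rarely
# visited by the regenerative dynamics, the gradient expectation reduces to
# mu(leak) * E_{Y ~ K_alpha(leak, .)}[...]; conditioning the sampler on the
# leaking state drops the positive scale factor mu(leak) and keeps the
# gradient direction and fixed points. `conditioning = "leak"` selects this
# sampler (the form used for the queue experiments).

#' Actor-critic configuration
#'
#' @param lr_theta,lr_psi,lr_r learning-rate schedules (see [parse_lr()]).
#' @param batch_size number of parallel chains B (one sampled transition per
#'   chain per iteration).
#' @param burn_in steps each chain advances per iteration; only the last
#'   transition contributes a sample (default 1, the practical choice).
#' @param n_iterations number of gradient steps.
#' @param seed integer seed consumed by [run_actor_critic()].
#' @param eval_every record the trace every this many iterations.
#' @param conditioning `"none"` for the plain warm-start chain sampler;
#'   `"leak"` to pin the pre-transition state to the unique leaking state
#'   (requires a single-leak kernel).
#' @param theta0 initial logits (`length n - 1`), or `NULL` for zeros.
#' @param psi0 initial tabular values, or `NULL` for zeros.
#' @param r0 initial reward estimate.
#' @param track_kl also record the exact KL rate at evaluation points
#'   (costs a stationary solve; sensible only for small n).
#' @return An object of class `ac_config`.
#' @export
ac_config <- function(lr_theta = "fpow:0.1,0.2", lr_psi = 1e-4, lr_r = 1e-4,
                      batch_size = 4L, burn_in = 1L, n_iterations = 10000L,
                      seed = 1L, eval_every = 100L,
                      conditioning = c("none", "leak"),
                      theta0 = NULL, psi0 = NULL, r0 = 0,
                      track_kl = FALSE) {
  stopifnot(batch_size >= 1, n_iterations >= 1, burn_in >= 1)
  structure(list(
    lr_theta = parse_lr(lr_theta), lr_psi = parse_lr(lr_psi),
    lr_r = parse_lr(lr_r), batch_size = as.integer(batch_size),
    burn_in = as.integer(burn_in), n_iterations = as.integer(n_iterations),
    seed = as.integer(seed), eval_every = as.integer(eval_every),
    conditioning = match.arg(conditioning),
    theta0 = theta0, psi0 = psi0, r0 = r0, track_kl = isTRUE(track_kl)
  ), class = "ac_config")
}

#' Temporal-difference error
#'
#' `delta(x, y) = R_theta(x, y) - r_est + V(y) - V(x)`, the one-step Bellman
#' residual driving all three updates.
#'
#' @inheritParams reward
#' @param val a [tabular_value()].
#' @param r_est current scalar estimate of the average reward.
#' @return Numeric vector of TD errors.
#' @export
td_error <- function(K, pol, val, r_est, x, y) {
  reward(K, pol, x, y) - r_est + val$psi[y] - val$psi[x]
}

# precomputations reused across iterations (theta-independent)
.make_ac_ctx <- function(K, conditioning) {
  n <- K$n_states
  ctx <- list(n = n, mass = K$mass, a = K$absorption,
              leak = which(K$absorption > 1e-9))
  if (conditioning == "leak") {
    if (length(ctx$leak) != 1L)
      stop("conditioning = 'leak' requires exactly one leaking state")
  } else {
    ctx$cum <- t(apply(K$mass, 1, cumsum))  # proposal cdf rows of K-tilde
  }
  ctx
}

# one actor-critic iteration against a precomputed context.
# state: list(theta, psi, r_est, chain, t). Returns the updated state.
.ac_step_ctx <- function(ctx, state, cfg) {
  n <- ctx$n
  t_next <- state$t + 1L
  theta <- state$theta
  full <- c(theta, 0)
  e <- exp(full - max(full))
  alpha <- e / sum(e)
  a <- ctx$a
  s <- sum(alpha * a)
  beta <- drop(alpha %*% ctx$mass) + s * alpha
  beta <- beta / sum(beta)
  B <- cfg$batch_size

  if (cfg$conditioning == "leak") {
    lx <- ctx$leak
    krow <- ctx$mass[lx, ] + a[lx] * alpha
    ys <- sample.int(n, B, replace = TRUE, prob = krow)
    xs <- rep.int(lx, B)
    chain <- xs
  } else {
    chain <- state$chain
    xs <- integer(B)
    ys <- integer(B)
    for (b in seq_len(B)) {
      x <- chain[b]
      for (k in seq_len(cfg$burn_in)) {
        u <- stats::runif(1)
        y <- findInterval(u, ctx$cum[x, ]) + 1L
        if (y > n) y <- sample.int(n, 1L, prob = alpha)
        if (k == cfg$burn_in) {
          xs[b] <- x
          ys[b] <- y
        }
        x <- y
      }
      chain[b] <- x
    }
  }

  ax <- a[xs]
  kxy <- ctx$mass[cbind(xs, ys)]
  ka <- kxy + ax * alpha[ys]
  kb <- kxy + ax * beta[ys]
  R <- -(log(pmax(ka, .LOG_FLOOR)) - log(pmax(kb, .LOG_FLOOR)))
  delta <- R - state$r_est + state$psi[ys] - state$psi[xs]

  # actor: mean over the batch of delta * grad log K_alpha + grad log K_beta
  w1 <- delta * ax * alpha[ys] / ka        # delta-weighted score of K_alpha
  acc <- numeric(n)
  for (b in seq_len(B)) acc[ys[b]] <- acc[ys[b]] + w1[b]
  grad_full <- acc - sum(w1) * alpha
  cb <- ax / kb                            # weights of the K_beta term
  q <- beta - s * alpha                    # q(y) = (alpha K)(y)
  g <- alpha * (a - s)                     # (J' a) over all n coordinates
  ck <- drop(ctx$mass[, ys, drop = FALSE] %*% cb)
  cay <- sum(cb * alpha[ys])
  acc2 <- numeric(n)
  for (b in seq_len(B)) acc2[ys[b]] <- acc2[ys[b]] + cb[b] * alpha[ys[b]]
  grad_full <- grad_full + alpha * ck - alpha * sum(cb * q[ys]) +
    g * cay + s * acc2 - s * alpha * cay
  grad <- grad_full[-n] / B

  theta <- theta + cfg$lr_theta(t_next) * grad
  if (max(abs(theta)) > 500)
    stop("policy logits exceeded 500 in magnitude; ",
         "the actor step size appears to be diverging")
  psi <- state$psi
  etap <- cfg$lr_psi(t_next) / B
  for (b in seq_len(B)) psi[xs[b]] <- psi[xs[b]] + etap * delta[b]
  r_est <- state$r_est + cfg$lr_r(t_next) * mean(delta)
  if (!is.finite(r_est)) stop("reward estimate diverged")
  list(theta = theta, psi = psi, r_est = r_est, chain = chain, t = t_next)
}

#' One actor-critic iteration
#'
#' Advances every chain of `state`, computes the batch of TD errors at the
#' current parameters, and applies the simultaneous actor / critic / reward
#' updates. Exposed mainly for inspection and testing;
#' [run_actor_critic()] iterates the identical computation.
#'
#' @param K a [sub_markov_kernel()].
#' @param state list with elements `theta`, `psi`, `r_est`, `chain`
#'   (length-B vector of current chain states) and `t` (completed
#'   iterations).
#' @param cfg an [ac_config()].
#' @return The updated state list.
#' @export
ac_step <- function(K, state, cfg) {
  stopifnot(inherits(K, "sub_markov_kernel"), inherits(cfg, "ac_config"))
  .ac_step_ctx(.make_ac_ctx(K, cfg$conditioning), state, cfg)
}

#' Run the actor-critic algorithm for the QSD
#'
#' Learns the softmax logits of the candidate QSD by average-reward
#' actor-critic: `cfg$n_iterations` iterations of [ac_step()], with the
#' chains warm-started across iterations and the L2 error to the reference
#' QSD recorded every `cfg$eval_every` iterations.
#'
#' @param K a [sub_markov_kernel()].
#' @param cfg an [ac_config()].
#' @param reference exact QSD used for the error trace; computed via
#'   [exact_qsd()] when omitted.
#' @return A list of class `qsd_fit`: `policy` (final [softmax_policy()]),
#'   `alpha` (the learned distribution), `value`, `r_est`, and `trace`
#'   (data frame with columns `iteration`, `l2_error`, `r_est`, `kl_rate`).
#' @examples
#' \donttest{
#' K <- loopy_chain(0.1)
#' fit <- run_actor_critic(K, ac_config(n_iterations = 2000, seed = 7,
#'                                      theta0 = c(-1, 1)))
#' utils::tail(fit$trace, 2)
#' }
#' @export
run_actor_critic <- function(K, cfg, reference = NULL) {
  stopifnot(inherits(K, "sub_markov_kernel"), inherits(cfg, "ac_config"))
  n <- K$n_states
  if (is.null(reference)) reference <- exact_qsd(K)$qsd
  reference <- as_distribution(reference, n)
  theta <- if (is.null(cfg$theta0)) numeric(n - 1) else as.numeric(cfg$theta0)
  if (length(theta) != n - 1) stop("theta0 must have length n - 1")
  psi <- if (is.null(cfg$psi0)) numeric(n) else as.numeric(cfg$psi0)
  if (length(psi) != n) stop("psi0 must have length n")
  ctx <- .make_ac_ctx(K, cfg$conditioning)
  set.seed(cfg$seed)
  alpha0 <- policy_distribution(softmax_policy(theta))
  chain <- if (cfg$conditioning == "leak") {
    rep.int(ctx$leak, cfg$batch_size)
  } else {
    sample.int(n, cfg$batch_size, replace = TRUE, prob = alpha0)
  }
  state <- list(theta = theta, psi = psi, r_est = cfg$r0, chain = chain,
                t = 0L)
  n_evals <- ceiling(cfg$n_iterations / cfg$eval_every)
  ev_it <- integer(n_evals); ev_err <- ev_r <- ev_kl <- numeric(n_evals)
  k <- 0L
  for (t in seq_len(cfg$n_iterations)) {
    state <- .ac_step_ctx(ctx, state, cfg)
    if (t %% cfg$eval_every == 0L || t == cfg$n_iterations) {
      if (k > 0L && ev_it[k] == t) next
      k <- k + 1L
      al <- policy_distribution(softmax_policy(state$theta))
      ev_it[k] <- t
      ev_err[k] <- sqrt(sum((al - reference)^2))
      ev_r[k] <- state$r_est
      ev_kl[k] <- if (cfg$track_kl) kl_rate_exact(K, al) else NA_real_
    }
  }
  trace <- data.frame(iteration = ev_it[seq_len(k)],
                      l2_error = ev_err[seq_len(k)],
                      r_est = ev_r[seq_len(k)],
                      kl_rate = ev_kl[seq_len(k)])
  pol <- softmax_policy(state$theta)
  structure(list(policy = pol, alpha = policy_distribution(pol),
                 value = tabular_value(state$psi), r_est = state$r_est,
                 trace = trace, config = cfg, reference = reference),
            class = "qsd_fit")
}

#' @export
print.qsd_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("actor-critic QSD fit: %d iterations, final L2 error %.4g, r_est %.4g\n",
              last$iteration, last$l2_error, last$r_est))
  invisible(x)
}
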