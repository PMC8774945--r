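# Softmax policy, reward, value function, and the policy gradient with its
# finite-difference oracle.

test_that("policy_distribution matches the pinned softmax form", {
  expect_equal(policy_distribution(softmax_policy(c(0, 0))), rep(1 / 3, 3))
  expect_equal(policy_distribution(softmax_policy(log(2))), c(2 / 3, 1 / 3))
  # shifting free logits is NOT a symmetry (last logit pinned at 0)
  th <- c(0.4, -1.1, 0.3)
  direct <- function(th) {
    e <- exp(c(th, 0)); e / sum(e)
  }
  expect_equal(policy_distribution(softmax_policy(th + 1)), direct(th + 1))
  expect_false(isTRUE(all.equal(policy_distribution(softmax_policy(th + 1)),
                                policy_distribution(softmax_policy(th)))))
  # overflow guard
  big <- policy_distribution(softmax_policy(c(800, 0)))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
  # inverse map round-trips
  alpha <- c(0.2, 0.5, 0.3)
  expect_equal(policy_distribution(policy_from_distribution(alpha)), alpha)
})

test_that("policy_jacobian matches closed form and finite differences", {
  J0 <- policy_jacobian(softmax_policy(c(0, 0)))
  expect_equal(J0, (diag(3)[, 1:2] - 1 / 3) / 3)
  set.seed(4)
  for (rep in 1:5) {
    n <- 3 + rep
    pol <- softmax_policy(stats::rnorm(n - 1))
    J <- policy_jacobian(pol)
    expect_lt(max(abs(colSums(J))), 1e-14)   # probability conservation
    h <- 1e-6
    Jfd <- vapply(seq_len(n - 1), function(j) {
      up <- pol$theta; up[j] <- up[j] + h
      dn <- pol$theta; dn[j] <- dn[j] - h
      (policy_distribution(softmax_policy(up)) -
         policy_distribution(softmax_policy(dn))) / (2 * h)
    }, numeric(n))
    expect_lt(max(abs(J - Jfd)), 1e-8)
  }
})

test_that("reward vanishes at the QSD and off the leak", {
  # at the exact QSD the two kernels coincide: R identically 0
  K <- loopy_chain(0.5)
  pol_star <- qsd_logits(K)
  for (x in 1:3) for (y in 1:3)
    expect_lt(abs(reward(K, pol_star, x, y)), 1e-12)
  # absorbed queue: rows >= 2 do not leak, so R(x, .) = 0 for any policy
  Kq <- mm1_queue(queue_spec(8, 1.25))
  set.seed(2)
  pol <- softmax_policy(stats::rnorm(7))
  for (x in 2:8) {
    ys <- which(Kq$mass[x, ] > 0)
    expect_equal(reward(Kq, pol, rep(x, length(ys)), ys), rep(0, length(ys)))
  }
  expect_error(reward(Kq, pol, 3, 7), "zero probability")
})

test_that("reward matches a brute-force loop recomputation", {
  K <- loopy_chain(0.5)
  pol <- softmax_policy(c(1, 0))
  alpha <- policy_distribution(pol)
  # independent recomputation with explicit loops
  n <- 3
  Ka <- matrix(0, n, n)
  for (x in 1:n) for (y in 1:n)
    Ka[x, y] <- K$mass[x, y] + K$absorption[x] * alpha[y]
  beta <- numeric(n)
  for (y in 1:n) for (x in 1:n) beta[y] <- beta[y] + alpha[x] * Ka[x, y]
  Kb <- matrix(0, n, n)
  for (x in 1:n) for (y in 1:n)
    Kb[x, y] <- K$mass[x, y] + K$absorption[x] * beta[y]
  for (x in 1:n) for (y in 1:n)
    expect_equal(reward(K, pol, x, y), -log(Ka[x, y] / Kb[x, y]),
                 tolerance = 1e-12)
})

test_that("average_reward_exact is the negative KL rate and nonpositive", {
  for (inst in fixture_instances(6)) {
    r <- average_reward_exact(inst$K, inst$pol)
    expect_lte(r, 0)
    expect_equal(r, -kl_rate_exact(inst$K, policy_distribution(inst$pol)),
                 tolerance = 1e-12)
  }
})

test_that("Property-1 equivalence: zero reward iff policy is the QSD", {
  for (K in zoo_instances()) {
    if (K$n_states > 50) next
    pol_star <- qsd_logits(K)
    expect_lt(abs(average_reward_exact(K, pol_star)), 1e-10)
    # perturbed policies have strictly negative average reward
    set.seed(K$n_states)
    for (rep in 1:5) {
      pol <- softmax_policy(pol_star$theta + stats::rnorm(K$n_states - 1, sd = 0.3))
      expect_lt(average_reward_exact(K, pol), -1e-6)
    }
  }
})

test_that("value_exact solves the Bellman equation with mu-centering", {
  # at the QSD: R = 0, r = 0, so V = 0
  K <- loopy_chain(0.3)
  expect_lt(max(abs(value_exact(K, qsd_logits(K))$psi)), 1e-10)
  for (inst in fixture_instances(5)) {
    K <- inst$K; pol <- inst$pol
    alpha <- policy_distribution(pol)
    Pa <- make_regenerative(K, alpha)
    mu <- exact_stationary(Pa)
    V <- value_exact(K, pol)$psi
    n <- K$n_states
    # Bellman residual via independent entrywise recomputation
    r <- average_reward_exact(K, pol)
    resid <- vapply(1:n, function(x) {
      rhs <- 0
      for (y in 1:n) {
        if (Pa$matrix[x, y] <= 0) next
        rhs <- rhs + Pa$matrix[x, y] *
          (V[y] + reward(K, pol, x, y) - r)
      }
      V[x] - rhs
    }, numeric(1))
    expect_lt(max(abs(resid)), 1e-10)
    expect_lt(abs(sum(mu * V)), 1e-10)   # centering
  }
})

test_that("value_exact agrees with the truncated series definition", {
  # V(x) = sum_{t>=1} E[R(X_{t-1}, X_t) - r | X_0 = x], partial sums via
  # repeated application of K_alpha to the expected one-step reward
  K <- random_submarkov(4, leak_states = 2, seed = 21)
  pol <- softmax_policy(c(0.5, -0.3, 0.2))
  alpha <- policy_distribution(pol)
  Pa <- make_regenerative(K, alpha)$matrix
  Rbar <- vapply(1:4, function(x) {
    ys <- which(Pa[x, ] > 0)
    sum(Pa[x, ys] * reward(K, pol, rep(x, length(ys)), ys))
  }, numeric(1))
  r <- average_reward_exact(K, pol)
  V_series <- numeric(4)
  prop <- diag(4)
  for (t in 1:10000) {
    V_series <- V_series + drop(prop %*% (Rbar - r))
    prop <- prop %*% Pa
  }
  expect_lt(max(abs(V_series - value_exact(K, pol)$psi)), 1e-6)
})

test_that("kernel-log gradients match central finite differences", {
  h <- 1e-6
  for (inst in fixture_instances(5)) {
    K <- inst$K; pol <- inst$pol
    n <- K$n_states
    alpha <- policy_distribution(pol)
    Ka <- make_regenerative(K, alpha)$matrix
    set.seed(n)
    # a few random samplable transitions
    for (rep in 1:4) {
      x <- sample.int(n, 1)
      y <- sample.int(n, 1, prob = Ka[x, ])
      ga <- grad_log_regen(K, pol, x, y)
      gb <- grad_log_onestep(K, pol, x, y)
      fa <- fb <- numeric(n - 1)
      for (j in seq_len(n - 1)) {
        up <- pol$theta; up[j] <- up[j] + h
        dn <- pol$theta; dn[j] <- dn[j] - h
        au <- policy_distribution(softmax_policy(up))
        ad <- policy_distribution(softmax_policy(dn))
        kau <- K$mass[x, y] + K$absorption[x] * au[y]
        kad <- K$mass[x, y] + K$absorption[x] * ad[y]
        fa[j] <- (log(kau) - log(kad)) / (2 * h)
        bu <- one_step_distribution(au, K)
        bd <- one_step_distribution(ad, K)
        kbu <- K$mass[x, y] + K$absorption[x] * bu[y]
        kbd <- K$mass[x, y] + K$absorption[x] * bd[y]
        fb[j] <- (log(kbu) - log(kbd)) / (2 * h)
      }
      expect_lt(max(abs(ga - fa)), 1e-7)
      expect_lt(max(abs(gb - fb)), 1e-7)
    }
  }
  # non-leaking states have theta-independent rows: zero gradients
  Kq <- mm1_queue(queue_spec(6, 1.25))
  pol <- softmax_policy(rep(0.1, 5))
  expect_equal(grad_log_regen(Kq, pol, 3, 4), rep(0, 5))
  expect_equal(grad_log_onestep(Kq, pol, 3, 4), rep(0, 5))
})

test_that("exact policy gradient matches the FD oracle", {
  for (inst in fixture_instances(8)) {
    g <- policy_gradient_exact(inst$K, inst$pol)
    gfd <- policy_gradient_fd(inst$K, inst$pol)
    expect_lt(max(abs(g - gfd)) / max(max(abs(gfd)), 1e-8), 1e-5)
  }
})

test_that("FD gradient error shrinks quadratically in h", {
  K <- loopy_chain(0.3)
  pol <- softmax_policy(c(0.5, -0.2))
  g <- policy_gradient_exact(K, pol)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(h)
    max(abs(policy_gradient_fd(K, pol, h) - g)), numeric(1))
  # each tenfold step in h should cut the error by ~100; allow factor 10 slack
  expect_gt(errs[1] / errs[2], 10)
  expect_gt(errs[2] / errs[3], 10)
})

test_that("gradient vanishes at the optimum and is baseline-invariant", {
  for (K in list(loopy_chain(0.5), mm1_queue(queue_spec(10, 1.25)))) {
    pol_star <- qsd_logits(K)
    expect_lt(max(abs(policy_gradient_exact(K, pol_star))), 1e-8)
    expect_lt(max(abs(policy_gradient_fd(K, pol_star))), 1e-6)
  }
  # replacing r(theta) by arbitrary constants leaves the gradient unchanged
  K <- random_submarkov(5, leak_states = 2, seed = 13)
  pol <- softmax_policy(c(0.2, -0.5, 0.9, 0))
  g <- policy_gradient_exact(K, pol)
  for (b in c(0, 1, -3.7)) {
    expect_lt(max(abs(policy_gradient_exact(K, pol, baseline = b) - g)),
              1e-10)
  }
})

test_that("the K_beta score has zero stationary expectation at the optimum", {
  K <- random_submarkov(5, leak_states = 3, seed = 23)
  pol_star <- qsd_logits(K)
  alpha <- policy_distribution(pol_star)
  Pa <- make_regenerative(K, alpha)
  mu <- exact_stationary(Pa)
  n <- 5
  acc <- numeric(n - 1)
  for (x in 1:n) for (y in 1:n) {
    if (Pa$matrix[x, y] <= 0) next
    acc <- acc + mu[x] * Pa$matrix[x, y] * grad_log_onestep(K, pol_star, x, y)
  }
  expect_lt(max(abs(acc)), 1e-8)
})

test_that("full-gradient ascent drives the KL rate to zero", {
  # the KL rate is locally quadratic with an instance-dependent Hessian, so a
  # fixed step/iteration budget cannot guarantee a fixed absolute accuracy;
  # we require a large relative reduction at step 0.5 and near-optimality
  # after a longer run at a larger stable step
  for (sd in c(31, 7)) {
    K <- random_submarkov(5, leak_states = 2, seed = sd)
    kl0 <- kl_rate_exact(K, rep(0.2, 5))
    theta <- numeric(4)
    kls <- numeric(5)
    for (t in 1:500) {
      theta <- theta + 0.5 * policy_gradient_exact(K, softmax_policy(theta))
      if (t %% 100 == 0)
        kls[t / 100] <- kl_rate_exact(K, policy_distribution(softmax_policy(theta)))
    }
    expect_lt(kls[5], kl0 / 10)
    expect_true(all(diff(kls) < 0))          # still descending, no oscillation
    for (t in 1:3500)
      theta <- theta + 5 * policy_gradient_exact(K, softmax_policy(theta))
    expect_lt(kl_rate_exact(K, policy_distribution(softmax_policy(theta))),
              1e-6)
  }
})
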