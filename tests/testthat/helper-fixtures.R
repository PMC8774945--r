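# Shared fixtures: small random problem instances and policy helpers.

# deterministic pool of random (kernel, policy) pairs for property tests
fixture_instances <- function(n_cases = 10, n_range = 3:8) {
  lapply(seq_len(n_cases), function(i) {
    n <- n_range[1 + (i %% length(n_range))]
    K <- random_submarkov(n, leak_states = 1 + (i %% n), density = 0.6,
                          seed = 100 + i)
    set.seed(1000 + i)
    list(K = K, pol = softmax_policy(stats::rnorm(n - 1, sd = 0.7)))
  })
}

# logits whose softmax equals the exact QSD of K
qsd_logits <- function(K) policy_from_distribution(exact_qsd(K)$qsd)

# model-zoo instances used by the fixed-point property suite (n <= 50)
zoo_instances <- function() {
  list(
    loopy01 = loopy_chain(0.1),
    loopy05 = loopy_chain(0.5),
    loopy09 = loopy_chain(0.9),
    mm1_20 = mm1_queue(queue_spec(20, 1.25)),
    sis_20 = sis_extinction_chain(20, beta = 2, gamma = 1),
    rand_6 = random_submarkov(6, leak_states = 2, seed = 11)
  )
}
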