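---
title: "Learning quasi-stationary distributions: models, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning quasi-stationary distributions: models, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsdlearn)
```

## The problem

Many stochastic population models — epidemic chains, birth–death queues,
chemical kinetics — are *absorbed* Markov chains: the process is eventually
killed (the epidemic goes extinct, the queue empties) with probability one,
so the ordinary stationary distribution is a point mass on the cemetery
state and says nothing about the long metastable phase that precedes
extinction. The object that describes that phase is the
**quasi-stationary distribution (QSD)**: the limit law of the chain
conditioned on survival.

Formally, let $K$ be a strictly sub-Markovian kernel on the live states
$E = \{1, \dots, N\}$ (nonnegative, row sums $\le 1$, at least one row sum
$< 1$; the deficit $a(x) = 1 - K(x, E)$ is the one-step absorption
probability). The QSD $\alpha$ is the normalized principal left eigenvector
of $K$,
$$ \alpha K = \lambda \alpha, \qquad \lambda = \sum_x \alpha(x) K(x, E) \in (0, 1), $$
unique when $K$ is irreducible (Perron–Frobenius). `exact_qsd()` computes it
directly and serves as the reference for every learning algorithm in the
package.

## The regenerative kernel and the fixed point

For any distribution $\alpha$ on $E$, define the Markovian **regenerative
kernel**
$$ K_\alpha(x, y) = K(x, y) + a(x)\,\alpha(y): $$
run the chain as usual and, upon absorption, restart from a fresh draw of
$\alpha$. The central identity is that $\alpha$ is the QSD of $K$ **iff**
$\alpha$ is stationary for $K_\alpha$, i.e. iff $\alpha = \alpha K_\alpha$.
Writing $\beta = \alpha K_\alpha$ for the one-step image, the QSD is the
unique fixed point $\beta = \alpha$, and — crucially for what follows — for
a strictly sub-Markovian $K$, $\alpha = \beta$ iff $K_\alpha = K_\beta$.
(For a fully Markovian $K$ the construction is vacuous, $K_\alpha \equiv K$;
this method is *only* for absorbed chains, which is why the constructors
reject Markovian matrices.)

## From fixed point to reinforcement learning

Rather than comparing $\alpha$ and $\beta$ directly, the learning objective
compares the *path measures* of the two regenerative chains. Parametrise the
candidate by pinned softmax logits,
$$ \alpha_\theta(i) = \frac{e^{\theta_i}}{e^{\theta_1} + \cdots + e^{\theta_{N-1}} + 1},
   \qquad \theta_N \equiv 0, $$
(an exact, unconstrained chart of the open simplex), and define the one-step
reward
$$ R_\theta(x, y) = -\ln \frac{K_{\alpha_\theta}(x, y)}{K_{\beta_\theta}(x, y)} $$
and the **average reward** $r(\theta)$, the negative KL divergence rate
between the path measures of $K_{\alpha_\theta}$ and $K_{\beta_\theta}$:
$$ r(\theta) = -\sum_{x, y} \mu_\theta(x) K_{\alpha_\theta}(x, y)
   \ln \frac{K_{\alpha_\theta}(x, y)}{K_{\beta_\theta}(x, y)} \le 0, $$
with $\mu_\theta$ the stationary law of $K_{\alpha_\theta}$. The objective
is maximal — exactly zero — iff $\alpha_\theta$ is the QSD, at which point
$R \equiv 0$ and the differential value function
$$ V(x) = \sum_{t \ge 1} \mathbb{E}\left[ R(X_{t-1}, X_t) - r(\theta)
   \mid X_0 = x \right] $$
vanishes too. `average_reward_exact()`, `value_exact()` (the Bellman solve
with the $\mu_\theta$-centering $\sum_x \mu_\theta(x) V(x) = 0$ forced by the
series definition) and `kl_rate_exact()` compute these quantities exactly by
linear algebra for any model small enough to afford it.

The policy-gradient identity evaluated by `policy_gradient_exact()` is
$$ \nabla_\theta r(\theta) = \mathbb{E}\Big[
   \big(R(X, Y) - b + V(Y) - V(X)\big) \nabla_\theta \ln K_{\alpha_\theta}(X, Y)
   + \nabla_\theta \ln K_{\beta_\theta}(X, Y) \Big], $$
with $(X, Y) \sim \mu_\theta \otimes K_{\alpha_\theta}$ and any constant
baseline $b$ (the choice $b = r(\theta)$ reduces variance; invariance to $b$
is tested). Both kernel-log gradients carry the factor $a(x)$ — transitions
out of non-leaking states carry no gradient information — and are assembled
from the softmax Jacobian $J_{ij} = \alpha_i(\mathbb{1}_{i=j} - \alpha_j)$:
$$ \nabla_\theta \ln K_\alpha(x, y) = \frac{a(x)\, J[y, \cdot]}{K_\alpha(x, y)},
   \qquad
   \nabla_\theta \ln K_\beta(x, y) = \frac{a(x)}{K_\beta(x, y)}
   \Big( J^\top K[\cdot, y] + (J^\top a)\,\alpha(y) + s\, J[y, \cdot] \Big), $$
where $s = \sum_x \alpha(x) a(x)$. These closed forms were derived in-house
by the chain rule through the regenerative construction; because their
derivation is not independently documented, the package treats the central
finite-difference gradient `policy_gradient_fd()` as the arbiter of
correctness and runs the comparison in the test suite (relative error below
$10^{-5}$ across random instances), not just during development.

## The actor-critic algorithm

`run_actor_critic()` learns $\theta$, a tabular value $\psi$, and a running
reward estimate $r_t$ from sampled transitions of $K_{\alpha_\theta}$. Each
iteration advances $B$ persistent chains one step (warm start: chains keep
their states across iterations), forms the TD error at the *current*
parameters,
$$ \delta = R_\theta(X, Y) - r_t + \psi_Y - \psi_X, $$
and applies three simultaneous stochastic updates with batch means:
actor $\theta \mathrel{+}= \eta^\theta_t \,\overline{\delta\, \nabla_\theta
\ln K_\alpha + \nabla_\theta \ln K_\beta}$, critic $\psi_X \mathrel{+}=
\eta^\psi_t\, \overline{\delta}$ (tabular $\nabla_\psi V = e_X$), and reward
estimate $r_{t+1} = r_t + \eta^r_t\, \overline{\delta}$. Simultaneous (not
Gauss–Seidel) updates are used because all three update equations reference
time-$t$ quantities. The exhaustive-expectation test ties the per-sample
update to the exact gradient, so the stochastic scheme is unbiased when the
critic is exact.

### Tunable parameters

| parameter | meaning | default | note |
|---|---|---|---|
| `lr_theta` | actor step | `fpow:0.1,0.2` = $\max(t^{-0.1}, 0.2)$ | benchmark loopy setting |
| `lr_psi`, `lr_r` | critic / reward steps | $10^{-4}$ | benchmark setting |
| `batch_size` | parallel chains per iteration | 4 | 64–128 for the queue runs |
| `burn_in` | chain steps per iteration | 1 | "one step in practice" |
| `conditioning` | sampler (below) | `"none"` | `"leak"` for single-leak chains |
| `theta0` | initial logits | zeros | presets: `ramp:a,b`, `tent:h,s,m`, `mm1-ramp` |

Learning-rate indexing starts at $t = 1$. Initial chain states are drawn
from $\alpha_{\theta_0}$ (the natural choice; nothing in the method pins
it). A divergence guard aborts when $\|\theta\|_\infty > 500$, far beyond
any meaningful logit scale, rather than overflowing. Probabilities are
floored at $10^{-300}$ inside logarithms; since $\alpha_\theta > 0$ forces
$\beta(y) \ge s\,\alpha(y) > 0$, a binding floor indicates a degenerate
policy and raises a warning.

### Sampling and the single-leak reduction

The stochastic gradient is supported on transitions *out of leaking states*.
For models like the absorbed M/M/1/N queue, where only state 1 leaks and the
regenerative dynamics drift away from it (the expected return time to the
leak grows geometrically in $N$), the plain chain sampler would essentially
never produce a nonzero actor update: the unconditioned algorithm is
well-defined but learns at the rate at which the chain visits the leak. For
exactly this model structure the gradient reduces to
$$ \nabla_\theta r(\theta) = \mu_\theta(1)\, \mathbb{E}_{Y \sim K_\alpha(1, \cdot)}
   \big[ (\cdots)\, \nabla_\theta \ln K_\alpha(1, Y) + \nabla_\theta \ln K_\beta(1, Y) \big], $$
and dropping the positive scalar $\mu_\theta(1)$ rescales — but never
redirects — the gradient field, leaving the fixed points and their stability
unchanged. `conditioning = "leak"` implements this: the pre-transition state
is pinned to the unique leaking state and $Y$ is drawn from that row of
$K_\alpha$. The queue benchmarks use it; the loopy chain (every state leaks)
uses the general warm-start sampler. With the conditioned sampler the critic
only ever updates $\psi$ at the leak state; the resulting value-function
bias vanishes at the optimum (where $V \equiv 0$), so it perturbs the
transient, not the target — consistent with the error plateau at the
$2 \times 10^{-1}$ accuracy level that both queue benchmarks reach.

## Baseline estimators

* **Vanilla single-particle scheme** (`run_vanilla`): repeatedly simulate an
  absorbed episode started from the current estimate and set
  $\alpha_n = \text{(cumulative visit counts)} / \text{(cumulative time)}$.
  This cumulative-occupation form is algebraically identical to the weighted
  empirical-average recursion (tested as an identity on shared episode
  streams), stays on the simplex exactly, and converges at the known
  $O(n^{-1/2})$ rate — checked as the log–log slope of the error trace.
* **Projected stochastic approximation** (`run_projection`):
  $\alpha_{n+1} = \Theta_H[\alpha_n + \epsilon_n(\text{occ}_{n+1} - \alpha_n)]$
  with $\Theta_H$ the Euclidean simplex projection (sort-and-threshold,
  $O(m \log m)$, validated against a KKT-multiplier bisection oracle) and
  $\epsilon_n$ a Robbins–Monro schedule. **Design note:** the innovation
  uses the episode's *time-normalised* occupation $\text{counts}/\tau$. The
  raw-counts variant (kept as `normalized = FALSE`) has provably zero drift
  on any kernel with identical rows — after the first step the occupation
  law is independent of $\alpha$, and the uniform shift is annihilated by
  the projection — so it cannot converge on the loopy benchmark; the
  normalised form is the one with the cited convergence theory.
* **Polyak averaging** (`polyak_average`, or `polyak = TRUE` inside
  `run_projection`): running mean $\nu_n = \frac1n \sum_{k \le n} \alpha_k$
  starting at $k = 1$, computed incrementally. Its variance-reduction
  benefit materialises for schedules slower than $1/n$ (e.g. $n^{-0.6}$);
  with $\epsilon_n \approx n^{-0.99}$ the unaveraged iterate is already
  average-like.
* **Fleming–Viot** (`run_fleming_viot`): $N$ synchronised walkers; an
  absorbed walker adopts the pre-update position of a uniformly chosen
  survivor (simultaneous update round; survivors resampled with replacement
  if nearly all die — the sources do not fix a synchronisation convention,
  so one was chosen and documented). The QSD estimate is the time-averaged
  empirical law over the second half of the run, which dominates the
  final-time snapshot.

## Benchmark generators and what they do (not) emulate

* `loopy_chain(eps, m)`: all transitions $(1-\epsilon)/m$, uniform leak
  $\epsilon$; QSD exactly uniform for every $\epsilon$ — a toy whose value
  is that every state leaks and the truth is known in closed form.
* `mm1_queue(queue_spec(N, rho))`: absorbed birth–death queue, up-probability
  $\rho_i/(\rho_i + 1)$, down $1/(\rho_i + 1)$; only state 1 leaks; state $N$
  reflects. Constant $\rho > 1$ gives a boundary layer of QSD mass at the
  right end; the `"linear-drift"` preset $\rho_i = 2 - 3(i-1)/(2N-4)$
  crosses $\rho = 1$ near $i = 2N/3$ and peaks the QSD there. The matrix is
  built so interior rows sum to exactly 1 in floating point, keeping the
  leak unique.
* `sis_extinction_chain(N, beta, gamma)`: a package-native SIS-type epidemic
  fixture (uniformised birth–death on the infected count, infection pressure
  $\beta i (N - i)/N$, recovery $\gamma i$, extinction only from one
  infected). It mirrors the queue's single-leak structure with an interior
  endemic mode. It is a *synthetic* benchmark: a discrete-time
  uniformisation with package-chosen defaults, not a calibrated epidemic
  model — green tests on it establish algorithmic correctness, not
  epidemiological realism.
* `random_submarkov(n, leak_states, density, seed)`: reproducible irreducible
  instances with a guaranteed positive cycle and a chosen number of leaking
  rows, for property tests.

None of the generators produce time-inhomogeneous kernels, continuous state
spaces, or multiple absorbing classes; those are out of scope.

## Numerical choices

* **Perron root selection**: among the eigenvalues of maximal modulus, the
  one with the largest real part is taken — birth–death chains without
  holding probability are bipartite and carry a $-\lambda$ partner of equal
  modulus. The alternative `method = "power"` iterates on $(K + I)/2$, which
  shares eigenvectors with $K$ but shifts the period-2 mode away from the
  spectral circle.
* **Stationary distributions**: direct solve of the rank-augmented system
  $(P^\top - I; \mathbf{1}^\top)$, with a damped power-iteration fallback;
  residual tolerance $10^{-8}$ hard, $10^{-10}$ typical.
* **Tolerances**: row-stochasticity to $10^{-12}$; probability vectors to
  $10^{-9}$; Bellman residual warning at $10^{-10}$ — double-precision
  comfort margins, not statements about statistical accuracy.
* **Eigenvector cleanup**: $O(\varepsilon)$ negative noise in near-zero tail
  entries is clipped; a warning fires only when the negative mass is
  material (possible reducibility).
* **Reducibility**: the irreducibility check (strong connectivity of the
  positive-entry graph) warns and proceeds rather than failing, because
  $K_\alpha$ can be ergodic for strictly positive $\alpha$ even when $K$ is
  reducible.

## Known limitations

* The exact solvers are dense ($O(N^3)$): fine for $N$ in the low
  thousands, which covers every benchmark here; large-scale eigen-solvers
  are out of scope.
* Tabular softmax and tabular value only — no function approximation, no
  eligibility traces, no discounting, no adaptive optimisers.
* The `"leak"` conditioning requires a unique leaking state. Multi-leak
  chains whose leaks are rarely visited would need an importance-weighted
  sampler, which is not provided.
* Constant actor steps leave a noise floor: error traces plateau rather
  than converge to zero, and the plateau level scales with the step size
  and batch size. The queue benchmarks target the benchmark
  $2 \times 10^{-1}$ accuracy level, not the noise-free optimum.

## A three-line example

```{r example, eval = requireNamespace("qsdlearn", quietly = TRUE)}
K <- loopy_chain(0.1)
fit <- run_actor_critic(K, ac_config(n_iterations = 2000, seed = 7,
                                     theta0 = c(-1, 1)))
rbind(learned = round(fit$alpha, 4), exact = round(exact_qsd(K)$qsd, 4))
```
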