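---
title: "Recoverability, entropy production and the thermodynamics of noisy channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recoverability, entropy production and the thermodynamics of noisy channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infotherm)
```

## The physical model

`infotherm` treats a discrete noisy channel as a physical measurement.
A source emits messages $x \in \{1,\dots,n_\mathrm{src}\}$ i.i.d. from a
prior $P_X$. Each message exerts a potential profile $U_x(y)$ on a
receiver immersed in a heat bath at inverse temperature $\beta$; the
receiver's position $y \in \{1,\dots,n_\mathrm{rcv}\}$ relaxes to
equilibrium while the message is held, and the equilibrated position is
the received message. The channel column for message $x$ is therefore the
Boltzmann distribution

$$q(y \mid x) = e^{\beta\,[F_x - U_x(y)]}, \qquad
  F_x = -\tfrac{1}{\beta}\log \sum_y e^{-\beta U_x(y)},$$

built by `channel_from_potentials()`. Three modelling assumptions matter:

* **Timescale separation.** The receiver equilibrates fully within each
  holding period, so the transfer is memoryless: the received message
  depends only on the current source message. The relaxation module
  (below) makes this limit explicit.
* **i.i.d. source.** Consecutive source messages are independent. The
  vanishing of the average free-energy difference, and therefore the
  identification of average work with dissipation, relies on this;
  correlated sources are out of scope.
* **Discrete positions.** Potential wells are realised as discrete
  receiver positions. The source and received alphabets need not have the
  same size, and none of the results require it.

Because only potential *differences* within a column matter
(gauge invariance), any strictly positive channel can be realised by
$U_x(y) = -\tfrac{1}{\beta}\log q(y \mid x)$ plus arbitrary per-column
constants.

## Recoverability and its exact decomposition

Given the received message, how much evidence does it carry for the true
source message over a randomly redrawn one? The pointwise answer is the
log-likelihood ratio $\ell_y(x, x') = \log[q(y|x)/q(y|x')]$; the
maximum-likelihood decoder (`decide_ml()`) recovers the message whose
ratio is positive against every alternative, and the maximum a posteriori
decoder (`decide_map()`) adds the prior log ratio. Averaging $\ell$ over
the true message, an independent alternative, and the reception defines
the **recoverability**

$$R = \sum_{x, x', y} P_X(x)\, P_X(x')\, q(y|x)
      \log\frac{q(y|x)}{q(y|x')},$$

a decoder-independent property of the channel and prior
(`recoverability()`). The prior log ratio averages out, so the same $R$
results from the posterior-ratio form. Splitting the log ratio pointwise
into $i(x, y) = \log[q(y|x)/P_Y(y)]$ and
$i_e(x', y) = -\log[q(y|x')/P_Y(y)]$ gives the exact decomposition

$$R = I + I_e,$$

with $I$ the mutual information (`mutual_information()`) and $I_e$ the
error information $\sum_x P_X(x)\,\mathrm{KL}(P_Y \,\|\, q(\cdot|x))$
(`error_information()`). Both are KL divergences, hence nonnegative; the
suite verifies the identity to $10^{-10}$ across a thousand random
channels. A subtlety worth recording: the pointwise error term can be
written with either ratio orientation, but only the orientation used here
(expectation of $\log[P_Y/q]$ under the product measure) is nonnegative
and closes the identity algebraically, so that is what the package
implements.

## Entropy production equals recoverability

Switching the potential from $U_{x}$ to $U_{x'}$ while the receiver sits
at $y$ performs stochastic work $w = U_{x'}(y) - U_{x}(y)$; subtracting
the free-energy change of the switch leaves the dissipated part,

$$\sigma = \beta\,(w - \Delta F) = \log\frac{q(y|x)}{q(y|x')},$$

computed both ways by `stochastic_work()` and
`stochastic_entropy_production()`, which the tests require to agree to
$10^{-12}$. (We define $\Delta F$ as final minus initial free energy;
with that convention a pure gauge shift $U_{x'} = U_x + a$ gives
$w = \Delta F = a$ and $\sigma = 0$, the equilibrium case.) Averaging
over consecutive i.i.d. messages, the free-energy term vanishes by
antisymmetry and

$$\Sigma = \langle \sigma \rangle = R,$$

the central equivalence: information recoverability *is* the entropy
production of the transfer process. `entropy_production()` evaluates
$\Sigma$ by accumulating per received message (a different summation
order than `recoverability()`'s loop over source pairs), so the equality
is a genuine cross-check of two code paths, asserted to $10^{-12}$.
The generalized Landauer bound follows immediately from
$I_e \ge 0$: the average work obeys $W = \Sigma/\beta \ge I/\beta$, with
margin exactly $I_e/\beta$ (`thermo_summary()`).

## Nonequilibrium strengths and the information surfaces

For a pair of source messages, `decompose_channel()` splits the two
columns into the equilibrium strength $m_y$ (half-sum) and the
nonequilibrium strength $d_y$ (half-difference). Probability constraints
confine $d$ to a polytope: $-m_y \le d_y \le m_y$ where $m_y < 1/2$,
$m_y - 1 \le d_y \le 1 - m_y$ otherwise, plus $\sum_y d_y = 0$
(`feasible_interval()`, enforced by `compose_strengths()`).

For two source messages with prior $(p, 1-p)$ and three received
messages the package provides the closed forms (`closed_form_I_R()`)

$$R = 2p(1-p) \sum_y d_y \log\frac{m_y + d_y}{m_y - d_y},
\qquad
I = \sum_\pm p_\pm \sum_y (m_y \pm d_y)
    \log\frac{m_y \pm d_y}{m_y + (2p-1) d_y},$$

which the tests require to match the generic-channel computation to
$10^{-12}$ on random feasible triples. `sweep_surface()` evaluates both
on a $(d_1, d_2)$ grid with $d_3 = -d_1 - d_2$ always derived, never
supplied. Both surfaces are convex with their common minimum $0$ at the
equilibrium point $d = 0$, so both increase along every ray away from
equilibrium, and each is a monotone function of the other at fixed
$d_1$ — driving the transfer further from equilibrium buys better
recovery and faster transfer, at proportionally higher dissipation.

Numerical choices for the sweep: the default grid is $201 \times 201$
with $m = (1/3, 1/3, 1/3)$; points within $\varepsilon = 10^{-6}$ of the
feasibility boundary are masked because $R \to \infty$ as
$m_y - |d_y| \to 0$. Convexity is checked by midpoint inequalities on
axis-aligned and diagonal grid triples rather than symbolically — a
deliberate match to how the surfaces are used.

## Receiver relaxation and the memoryless limit

`build_rate_matrix()` constructs the continuous-time generator of the
receiver position under a held message from either Metropolis rates
$r = \min(1, e^{-\beta \Delta U})$ or Glauber rates
$r = 1/(1 + e^{\beta \Delta U})$, on a fully connected position graph
with unit attempt rates. Only local detailed balance,
$r(s'|s)/r(s|s') = e^{\beta[U(s) - U(s')]}$, is physically prescribed;
the topology and attempt rates are conventions, because the framework
uses only the infinite-time limit, which any irreducible LDB choice
shares. Timescales are therefore arbitrary units. `relax()` propagates a
distribution by the matrix exponential, and `coarse_grained_kernel()`
obtains the one-period kernel by squaring `expm(G)` until all columns
agree within `tol` (default $10^{-10}$), doubling the horizon each step
instead of fixing a "long enough" period by fiat. Its columns all equal
the canonical channel column — the received message is independent of the
receiver's starting position, which is precisely the memoryless channel
property assumed in the ensemble theory, and the tests confirm the
Metropolis and Glauber limits coincide.

## Trajectory estimators

`sample_sequences()` simulates the joint sequence
$Z = \{(X_i, Y_{i+1})\}_{i=1}^t$; `shuffle_sources()` builds the
surrogate $Z'$ by uniformly permuting the source sequence while keeping
the receptions. Two estimators recover the ensemble quantities from a
single trajectory:

$$R' = \frac{1}{t} \log\frac{P(Z)}{P(Z')}, \qquad
\Sigma' = \frac{1}{t} \sum_{i=2}^{t}
          \log\frac{q(Y_i | X_{i-1})}{q(Y_i | X_i)}.$$

Because the surrogate carries the same multiset of source labels, the
prior factors in $R'$ cancel over the full sum; the implementation
asserts that cancellation and accumulates the channel log ratios
directly, which makes every prefix of the returned trace an exact
running average (and zero for an uninformative channel at every length,
not just in the limit). $\Sigma'$ normalises its $(t-1)$-term sum by
$t$; the difference is $O(1/t)$. Both converge to
the same ensemble value $R = \Sigma$, with scatter shrinking as
$1/\sqrt{t}$ — the suite checks unbiasedness across 200 seeds at
$t = 10^4$, convergence within three standard errors at $t = 10^5$, and
the $\sqrt{10}$ scatter ratio between $t = 10^3$ and $t = 10^4$.

Reproducibility: a single master seed drives fixed derived seeds for the
source stream, the channel stream, and the shuffle, so each component can
be regenerated in isolation; the global RNG state is restored afterwards.

## What the synthetic ensembles do and do not show

Random test channels draw each column from a symmetric Dirichlet
distribution (`generate_random_fixture()`, default concentration 1) so
they are strictly positive, where all information quantities are finite —
the regime canonical channels always occupy, since Boltzmann weights
never vanish. Zero entries are handled by the $0 \log 0 = 0$ convention
with infinities propagated as values rather than errors, and the
degenerate extremes (identical columns, noiseless identity channel) are
tested explicitly. What these ensembles do not emulate: correlated
sources, time-varying priors, channels with structured zeros, and any
physical magnitude for rates or times — conclusions about real sensory
systems need the map from their kinetics onto a held-potential,
fully-relaxing receiver, which is an idealisation.

Validation drift on input files is repaired, not hidden: column sums may
deviate from 1 by at most $10^{-9}$ silently, by $10^{-6}$ with a
warning, and anything larger is rejected.

## Problem sizes used by the test-suite

The identity checks run on the worked three-message example plus 1000
seeded random (channel, prior) pairs; the surface checks on
$201 \times 201$ grids for each of the four bundled two-source priors;
the dynamics checks on 100 random potential tables; the trajectory
checks at $t = 10^5$ (single seed) and $200 \times t = 10^4$
(unbiasedness). These sizes keep the full suite under a minute on one
core while leaving the statistical assertions well-powered.

## Known limitations

* Infinite values of $R$, $I_e$, $\Sigma$ (channels with zeros under
  positive weight) are returned as `Inf` without a distributional
  account of how the divergence is approached.
* The estimators assume the i.i.d. source; applying them to correlated
  sequences silently estimates a different functional.
* `sweep_surface()` is specialised to three received messages, the
  smallest alphabet on which the zero-sum constraint leaves a
  two-dimensional surface.
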