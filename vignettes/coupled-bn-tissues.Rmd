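---
title: "Coupled Boolean network tissues: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled Boolean network tissues: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bntissue)
```

## The model

`bntissue` models a population of cells on a 2D periodic lattice.  Every cell
runs the same Boolean gene-regulatory program; the cells interact through a
small set of *control-kernel* (CK) genes that behave as Ising spins coupled to
their four lattice neighbors.  The package's purpose is to study how such a
tissue spontaneously breaks symmetry — how a homogeneous, "pluripotent-like"
population commits to one of several discrete cell types — and how a simple
noise-feedback mechanism lets the tissue tune itself through that transition.

### Single cells: noisy Boolean networks

A cell is a Boolean network of $n$ binary genes.  Gene $i$ reads an ordered
set of $k_i$ regulators and updates synchronously through a fixed truth
table,

$$x_i(t) = f_i\big(y_i(t-1)\big), \qquad y_i = (x_{j_1}, \dots, x_{j_{k_i}}).$$

States are indexed by their decimal encoding $s = 1 + \sum_i x_i 2^{n-i}$
(gene 1 is the most significant bit, so fixing gene 1 splits the state space
into two contiguous halves).  Random Boolean networks (RBNs) are drawn from
the Kauffman ensemble: uniform in-degree $k$, random distinct regulators and
truth-table entries that are 1 with bias $p$; the order/chaos boundary of the
ensemble lies at $k_c = 1/(2p(1-p))$, so the default demonstration network
($k = 2$, $p = 0.5$) sits at criticality.

Gene-expression noise is modeled as a whole-vector perturbation: with
probability $1-(1-q)^n$ per step the entire gene state is replaced by a
random binary vector with i.i.d. Bernoulli($q$) entries; otherwise the
deterministic update applies.  (The perturbation convention has two readings
in the source literature; we use the one that recovers deterministic dynamics
as $q \to 0$.)  Any $q \in (0,1)$ makes the chain ergodic, with a unique
stationary distribution $g_0(s)$ peaked around the deterministic attractors.
The package computes $g_0$ two ways: exactly, from the dense transition
matrix $P = (1-\rho)D + \rho\,\mathbf{1}\gamma^{\top}$ (power iteration to a
residual of $10^{-12}$; dense enumeration is capped at $n \le 12$, which is
what a 2 GB-scale dense chain allows), and by Monte Carlo visit histograms
(capped at $n \le 20$, where the deterministic next-state map is still
enumerable).

### Control kernels, pinning and mixtures

Pinning holds the first $r$ genes at one of the $2^r$ patterns $X_w$ while
the remaining genes evolve freely; noise then applies to the free genes only
(pins are absolute).  Each pin state yields a stationary distribution
$g_w^{(r)}$ supported entirely inside the block of states whose first $r$
bits equal $X_w$.  The blocks are disjoint, so
$\langle g_i^{(r)}, g_j^{(r)}\rangle = 0$ exactly for $i \ne j$ — the package
tests this as an identity, not up to tolerance, because the exact pinned
chains place strictly zero mass outside their blocks.

A *dynamic* control kernel drives the pin index by a (slow) Markov chain
$\eta_t$.  The resulting visit distribution is a mixture
$g = c_0 g_0 + \sum_w c_w g_w^{(r)}$ whose weights track the occupancy
fractions of $\eta_t$, provided switching is slow relative to the network's
mixing time; with $q = 0.1$ and $n = 6$ the perturbed chain mixes in a few
steps, so mean waiting times of 50 steps or more are comfortably "slow", and
that is what the shipped two-state test process (stay probabilities
0.98/0.99, occupancy 1/3 : 2/3) uses.

### Tissues: the multilayer Ising Hamiltonian

For a tissue of $L$ cells, each CK gene $m \le r$ defines a spin layer
$\bar{x}_{i,m} = 2x_{i,m}-1$ with energy

$$H_r = \sum_{m=1}^{r}\Big[-J\sum_{\langle ij\rangle}\bar{x}_{i,m}\bar{x}_{j,m}
 - h_0 \sum_i \bar{x}_{i,m}\bar{f}_{i,m} - h\,\bar{\psi}_m \sum_i \bar{x}_{i,m}\Big],$$

where $\langle ij \rangle$ runs over unordered nearest-neighbor bonds,
$\bar f_{i,m}$ is the spin the CK gene would take under the cell's own
Boolean update (the cell's tendency to follow its original program), and
$h\bar\psi$ is an optional external/autocrine field.  Two conventions had to
be fixed:

* **Bond counting.**  Each unordered bond is counted once with $J = 1$.
  Under this convention the $h = h_0 = 0$ layer is the standard 2D Ising
  model with $T_c \approx 2.269$, which is what the narrative of the
  self-tuning mechanism (start at $T = 2.8$, "high temperature") requires;
  a double-counted sum would double the effective coupling.  The acceptance
  suite anchors this with ordered/disordered magnetization checks at
  $T = 1.5$ and $T = 3.5$.
* **Freshness of $\bar f$.**  $\bar f$ is computed once from the state at
  the start of each MC step and frozen during the Metropolis sweep, so the
  sweep is a well-defined Metropolis chain at fixed field and detailed
  balance holds per proposal.

One hybrid MC step is: (1) freeze $\bar f$; (2) for each layer
independently, draw $N_{MC}$ distinct cells (uniformly, without replacement
within the layer) and propose single-spin flips sequentially, accepting with
$\min(1, e^{-\Delta E/T})$; (3) synchronously update the non-CK genes of
every cell under the perturbation noise, the CK genes carrying the spin
values.  Because the non-CK update reads the post-sweep CK values, the
$J = 0,\ h_0 \to \infty$ limit is an ensemble of independent cells whose CK
updates first within the step; the test suite checks the tissue against the
exact stationary distribution of that per-cell chain.  Lattices smaller than
$3\times3$ are rejected (periodic wrap-around would duplicate neighbors).

### Detecting cell types

The instantaneous population distribution $G(t)$ (fraction of cells per
decimal state) is approximated by the mixture
$\tilde G = c_0 g_0 + \sum_w c_w g_w^{(r)}$ with
$\epsilon = \lVert G - \tilde G\rVert_2 / N$, $N = 2^n$.  Three estimators
are provided:

* **Constrained least squares** — minimizes $\lVert G - \tilde G \rVert$
  subject to $c \ge 0$, $\sum c = 1$.  Solved exactly by enumerating the
  active sets (faces of the simplex) and solving each face's KKT system; for
  the $\le 5$ components used here this is both exact and fast, and the test
  suite cross-checks it against a 0.01-step grid search.
* **Spectral projection** — for the $h_0 = 0$ regime, $c_w = \langle G,
  \hat g_w\rangle$ with $\hat g_w = g_w / \langle g_w, g_w\rangle$.  The
  normalizer is the *squared* norm: with it, projections of an exact mixture
  return the mixture weights themselves and agree with the constrained LS
  fit to $10^{-6}$; a unit-norm normalizer would return
  $c_w\lVert g_w\rVert$ instead.  Raw projections are clipped to $[0,1]$
  and renormalized for reporting, and the raw values are kept.
* **NNMF** — Lee–Seung multiplicative updates (Frobenius objective, seeded
  random initialization, components normalized to unit sum) factor a
  states-by-time history into $K$ non-negative "type" distributions and
  their time-varying abundances, for regimes where the mixture ansatz with a
  known basis breaks down.  The rank $K$ is user-chosen; shipped experiments
  use $K = 2^r$.

For $r = 1$ the order parameter is the magnetization
$M_t = c_2 - c_1 \in [-1, 1]$: $\pm1$ are homogeneous populations of the two
complementary types, 0 a balanced, pluripotent-like mixture.

### Self-tuned differentiation

The feedback $dT/dt = |M_t| - \alpha T$ (one Euler step of size
$\Delta\tau$ per MC step, with a floor $T_{\min} = 0.01$ guarding the
Boltzmann factor) closes the loop between population heterogeneity and
intrinsic noise.  Starting above $T_c$ with $|M| \approx 0$, $T$ decays
until the symmetry breaks; $|M|$ then grows and $T$ settles at the fixed
point $|M|/\alpha$ below $T_c$.  With $M$ clamped, convergence is geometric
at rate $\alpha\Delta\tau$ per step — the unit tests compare the iteration
against this closed form.

## Study conditions and problem sizes

The reference configuration mirrors the full-scale study: $32\times32$
cells, $N_{MC} = 10$, $q = 0.02$, $\alpha = 0.8$, $T_0 = 2.8$,
$\Delta\tau = 5\times10^{-7}$, $8\times10^{5}$ steps, CK initialized to 1.
The package's *scaled* test configuration — used by the acceptance suite —
is $16\times16$ with $\Delta\tau = 5\times10^{-6}$ and $1.2\times10^{6}$
steps.  This choice is deliberate rather than a plain downscaling: the
temperature relaxes with ODE horizon $\tau = \alpha\,\Delta\tau\,t$, and a
horizon of $\tau \approx 6$ leaves the final temperature within about 1% of
the fixed point, while the cooling rate through $T_c$ is still slow enough
that the Kibble–Zurek correlation length at freeze-out is comparable to the
lattice size — fast quenches on a torus freeze stripe-shaped domains that
would masquerade as failed differentiation.  Ensemble checks use 20
replicates with consecutive seeds, checkpointed at $t = 2\times10^4$ (the
$M \approx 0$, still-supercritical epoch) and at the final step; each
checkpoint's tissue-mean gene state is a short time average over the most
recent recorded frames, because a single snapshot of a $16\times16$ tissue
carries sampling noise comparable to a quarter of the mode gap between the
two differentiated types.

Other problem sizes used by the tests: mixture-error runs on $20\times20$
with $t_{eq} = t_{sample} = 5\times10^3$ at $T = 1$, $h_0 = 1$; Ising
anchors on $32\times32$ with full-lattice sweeps; Monte Carlo oracle
comparisons at $10^6$ chain steps; dynamic-CK recovery over 10 seeds of
$2\times10^5$ steps.

## What the generator emulates — and what it does not

The demonstration 6-gene network is a *seeded* RBN at $(n, k, p) =
(6, 2, 0.5)$, the critical-ensemble parameters of the original model
network, whose exact truth table is not published; all shipped experiments
therefore use the seeded stand-in (any seed reproduces the qualitative
phenomenology, since orthogonality, Ising limits and the feedback mechanism
do not depend on the particular table).  Synthetic tissues are isogenic,
noise is i.i.d. across genes and cells, and interactions are
nearest-neighbor ferromagnetic with uniform $J$.  Passing tests therefore
say nothing about heterogeneous cell programs, long-range or signed
signaling, asynchronous update schemes, or inference from real expression
data — none of which the model attempts.

## Numerical choices

* Power iteration: tolerance $10^{-12}$ on the sup-norm residual, cap
  $10^6$ iterations (the perturbation makes the chains fast-mixing, so
  convergence takes tens of iterations in practice).
* Active-set LS: faces with singular KKT systems (collinear bases) are
  skipped; candidate weights are clipped at $\pm10^{-10}$ feasibility slack
  and renormalized, so reported weights satisfy the simplex constraints to
  machine precision.
* NNMF: $10^{-10}$ relative-loss stopping check every 10 iterations, cap
  2000; a small $\varepsilon$ in the update denominators prevents division
  by zero.
* Metropolis: proposals with $\Delta E \le 0$ are accepted without drawing,
  which halves RNG consumption; all randomness (R and C++ paths) flows from
  R's seeded generator, so trajectories are bit-reproducible per seed.
* The slow `mc_step()` (pure R) and the fast C++ run loop are the same
  Markov chain draw-for-draw; a test asserts bit-identical trajectories.

## Known limitations

* Dense exact chains stop at $n = 12$ genes; beyond that only Monte Carlo
  estimates are available (to $n = 20$, the limit of the enumerable
  next-state map), and tissue simulation records histograms up to $n = 16$.
* `magnetization()` and the feedback loop are defined for $r = 1$; for
  larger kernels the package reports the full weight vectors instead of a
  scalar order parameter.
* The spectral estimator assumes an orthogonal basis and is meaningless
  when $h_0 \ne 0$ (cells then spend time outside the pinned blocks); use
  the constrained LS fit there, as the annealing driver does.
* In a tissue the CK genes are never hit by the $\gamma$ perturbation —
  their only noise source is the Metropolis temperature.  Which mixture
  component dominates at large $h_0$ therefore depends on the network's own
  CK-prediction bias: a network whose CK update is strongly biased locks its
  spin layer and looks like a pinned type rather than the unpinned program.
  The quantitative statement that survives for every network is the one the
  tests check: at $J = 0$, $h_0 \gg T$ the tissue reproduces the exact
  per-cell chain in which the CK follows its own prediction and only the
  free genes are perturbed.
* Critical exponents, quasi-potential landscapes, and antiferromagnetic or
  random-field couplings are out of scope.
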