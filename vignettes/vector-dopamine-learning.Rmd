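---
title: "Learning with vector-valued dopamine in a basal-ganglia rate network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning with vector-valued dopamine in a basal-ganglia rate network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopanet)
```

## The model

`dopanet` simulates a small piece of basal ganglia learning to produce a
continuous, multidimensional output trajectory. The question it addresses is
whether dopamine — whose axonal arbors are broad and nonspecific, releasing
transmitter from many varicosities into extracellular space — can nevertheless
carry a *vector-valued* error signal that the striatum can use, rather than
only the classical scalar reward-prediction error.

The network has four populations. Thalamic units are clamped to a sinusoidal
clock code that signals the phase of the current trial. A cortical reservoir
(static recurrent weights, half excitatory, half inhibitory) provides rich,
task-locked dynamics. The striatum contains equal numbers of direct-pathway
(dSPN) and indirect-pathway (iSPN) projection neurons; it receives excitatory
cortical and thalamic afferents and inhibitory striatostriatal collaterals,
all plastic. The readout population (GPi/SNr, one unit per output dimension)
is memoryless; dSPNs inhibit it and iSPNs excite it (the indirect pathway is
collapsed onto a direct excitatory projection).

Membrane potentials in cortex and striatum follow leaky integration,
$\dot V = -V/\tau_m + \sum w\, r$ with $\tau_m = 10$ ms, integrated by
forward Euler at $dt = 1$ ms. Rates are the shifted logistic
$\phi(V) = 1/(1 + e^{-V + b})$ with $b = 2$, which keeps rates sparse when
excitation and inhibition are balanced. The loss is the instantaneous squared
error $\ell(t) = \tfrac12\sum_k (r_k^{SNr} - T_k)^2$, integrated over each
200-ms trial. Trials are concatenated with no state reset; the periodic
target kernel (below) makes that seamless.

### Three-factor plasticity and feedback alignment

Striatal afferent and collateral synapses follow a three-factor rule: an
eligibility trace $\tau_{Str}\dot p_{ji} = -p_{ji} + r_j(1-r_j)\,r_i$
(a low-pass-filtered Hebbian product, $\tau_{Str} = 10$ ms) multiplied by a
neuron-specific third factor, the local dopamine concentration. The SNc
population (one dopamine neuron per output dimension) fires the error code
$\epsilon_k = (r_k - T_k)\,r_k(1-r_k)$, and each SPN receives the mixture
$C_j = \sum_k \epsilon_k\, d_{jk}$ determined by the diffusion field (below).
The weight update is $\dot w_{ji} = -\alpha_j\, p_{ji}\, C_j$, with
$\alpha = -2.5\times10^{-2}$ for dSPNs and $+2.5\times10^{-2}$ for iSPNs,
capturing the opposite effects of D1 and D2 receptor activation. The readout
learns by the delta rule $\dot w_{kj} = -\beta\,\epsilon_k\, r_j$
($\beta = 10^{-3}$), which is the exact gradient of the instantaneous loss.

Because readout weights are plastic, feedback alignment lets the *random*
mixture matrix $D = [d_{jk}]$ stand in for the transposed readout weights
that exact gradient descent would require: over training the readout weights
align to $D$ (tracked by `alignment_trajectory()`), after which the
dopamine-gated striatal updates point along the gradient. Dale's law is
enforced throughout: after every update, weights that would cross zero are
clamped to zero (the synapse stays in the mask and may regrow). Within each
1-ms step the order is fixed: rates from current potentials, then readout and
error, then eligibility and weight updates, then the synchronous membrane
update.

### The dopamine diffusion field

Each SNc neuron releases dopamine from $N^{var} = 10$ varicosities placed
uniformly at random in the unit cube that contains the SPN positions.
Concentration decays exponentially with Euclidean distance, with length
scale $\lambda = 0.1$ cube sides, giving the fixed effective weight
$d_{jk} = \sum_v \frac{1}{\lambda} e^{-\|p_j - q_{kv}\|/\lambda}$. At
$\lambda = 0.1$ the per-varicosity kernel falls to $1/e \approx 37\%$ of its
peak over a tenth of the cube side. Small $\lambda$ starves the striatum of
feedback (the no-feedback limit); large $\lambda$ delivers the same mixture
everywhere (the homogeneous limit); in between, each SPN receives a distinct
random projection of the error, and `feedback_independence()` — the ratio of
smallest to largest singular value of row-normalized $D$, a simple
conditioning diagnostic — quantifies how non-degenerate the mixture is.

Control variants replace $D$: `homogeneous` gives every SPN the identical
scalar signal (every entry set to the mean of $D$, preserving total gain),
`shuffled` permutes the entries of $D$ elementwise once per run, `none`
disables striatal plasticity, and `ideal` feeds back the current readout
weights. For `ideal` we negate the dSPN rows of $W^\top$: with the
pathway-specific $\alpha$ signs, feeding back the *signed* weights would make
dSPN afferents ascend the gradient; the class-sign-adjusted transpose is what
reduces the rule to true-gradient learning, and is also the quantity the
positive dopamine mixture stands in for (dSPN readout weights are negative
and align in magnitude to $d_{jk}$).

### Targets and thalamic code

Each of the $d = 4$ target dimensions is an independent Gaussian-process
draw with mean 0.5 and covariance
$\sigma^2(t_1,t_2) = 0.15^2 \exp(-\delta(t_1,t_2)^2 / (2\tau_{task}^2))$,
$\tau_{task} = 20$ ms, where $\delta$ is the wrap-around distance on the
200-ms trial circle. The periodic kernel avoids discontinuities when trials
are concatenated. Targets are sampled once per run and reused for all
trials, and are not clipped to the sigmoid range. The wrapped
squared-exponential kernel is positive-semidefinite only up to numerical
tolerance on a 1-ms grid (eigenvalues can sit a few $10^{-7}$ below zero),
so sampling adds a $10^{-8}$ diagonal jitter and falls back to an
eigendecomposition with tiny negative eigenvalues clipped to zero when the
Cholesky factorization fails; substantially negative eigenvalues are an
error. Thalamic units carry $r_m = \phi(A_m\cos 2\pi t/T + B_m\sin 2\pi t/T)$
with $(A_m, B_m)$ uniform on the circle of radius 4.

### Slow dopamine and synaptic compensation

Real dopamine release, diffusion, and reuptake are not instantaneous. The
temporal dynamics are collapsed into an exponential low-pass filter with
time constant $\tau_{DA}$. Two discretizations are provided. The literal
convolution $C'(t) = \int_0^t e^{(t'-t)/\tau_{DA}} C(t')\,dt'$ has DC gain
$\approx \tau_{DA}/dt$: slow kinetics both lag and *accumulate*
concentration, and it is this form under which slow dopamine degrades
learning below the no-striatal-plasticity baseline. The unit-gain form
$C' \leftarrow \xi C' + (1-\xi)C$, $\xi = e^{-dt/\tau_{DA}}$, only lags. A
feed-forward-inhibition motif in the synapse can undo the filter: one node
tracks $A(t) = C'(t)/(1-\xi)$ and another computes
$a(t) = A(t) - \xi A(t - dt)$. Under the unit-gain convention this
reconstruction is algebraically exact ($a \equiv C$, asserted to $10^{-12}$
in the tests), which is why the compensated conditions use it; the
experiment driver `slow_dopamine_experiment()` therefore runs uncompensated
conditions with the literal filter and compensated ones with the unit-gain
form.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau_m` | 10 ms | membrane time constant (cortex, striatum) |
| `b` | 2 | sigmoid offset; sparsifies rates at balance |
| `dt` | 1 ms | Euler step; must divide the 200-ms trial |
| `tau_task` | 20 ms | target GP length scale |
| `tau_str` | 10 ms | eligibility time constant (set equal to `tau_m`, the natural choice in the online-learning derivation) |
| `alpha_d`, `alpha_i` | ∓2.5e-2 /ms | dSPN / iSPN three-factor rates |
| `beta` | 1e-3 /ms | readout delta-rule rate |
| `lambda_da` | 0.1 | dopamine diffusion scale (cube sides) |
| `n_varicosities` | 10 | release sites per SNc neuron |
| `tau_da` | `NULL` | dopamine filter constant (`NULL` = instantaneous) |

Population sizes and connection statistics are profile-driven. The `"desk"`
profile (30 thalamic, 60 cortical, 80 striatal units, 1,000 trials) is the
default and is what the test suite and the acceptance script use; `"paper"`
scales to 100 cortical and 100 striatal units and 5,000 trials. Sparse
projections connect each ordered pair with probability 0.5; the readout is
fully connected. Initial weights are uniform on $[0, w_{max}/N_{post}]$
(negated for inhibitory projections), then every neuron's incoming sum is
balanced to exactly zero by scaling up the deficient sign class.

The `w_max` values (ThalCtx 8, CtxCtx 20, ThalStr 8, CtxStr 10, StrStr 10,
StrSNr 2) and the cortical inhibitory fraction (0.5) were fixed once by a
perturbation-growth criterion on the untrained network: a $10^{-8}$
perturbation of one recurrent weight should grow to order one within a few
trials (close-to-chaotic dynamics) while striatal rates remain mostly
unsaturated. Larger weights saturate the sigmoids and quench both dynamics
and eligibility ($r(1-r) \to 0$); smaller ones make the reservoir dynamics
regular and impoverished.

## What the experiments show at reduced scale

All experiment drivers pair seeds across conditions (run *i* of every
condition shares targets, connectivity, and varicosity placement) and report
the median and quartiles of the final loss (median of the last 10 trials,
damping online-learning jitter) over ≥10 runs. At the desk scale:

- **Feedback conditions** (`compare_conditions()`): heterogeneous dopamine
  clearly outperforms the homogeneous scalar signal, whose interquartile box
  overlaps the no-striatal-plasticity control — a scalar third factor adds
  essentially nothing over readout-only ("echo-state") learning. Shuffled-D
  performs like the spatial D (only non-degeneracy matters, not spatial
  arrangement). Ideal feedback is *better* than random feedback at 1,000
  trials: true-gradient learning converges faster, and the equivalence seen
  at full scale is a statement about the converged state, not the transient.
- **Diffusion scale** (`sweep_lambda()`): the loss over
  $\lambda \in \{10^{-3}, 0.1, 100\}$ is minimized at 0.1. At
  $\lambda = 10^{-3}$ the run is numerically identical to no-feedback. At
  $\lambda = 100$ the rows of $D$ are nearly identical and learning reverts
  to the readout-only level, though its loss does not match the homogeneous
  control quantitatively: the mean-of-$D$ control carries roughly 25× the
  dopamine gain of the $\lambda = 100$ field, and at this scale that gain
  difference is visible.
- **Lesions** (`lesion_experiment()`): freezing the readout removes feedback
  alignment and raises the loss by two orders of magnitude; removing cortical
  *or* thalamic afferents alone is moderate (the two inputs are largely
  interchangeable); removing both silences the striatum and is near-maximal.
  One genuine reduced-model effect: with the readout frozen, striatal
  plasticity still corrects the *mean* output level (the Dale-law sign
  structure aligns even unshaped dopamine updates with the DC error), so the
  frozen-readout loss sits below a fully frozen network while still failing
  to learn the time-varying target.
- **Slow dopamine** (`slow_dopamine_experiment()`): with the literal filter,
  $\tau_{DA} = 200\,\mathrm{ms} \gg \tau_{task}$ drives the loss above the
  no-striatal-plasticity baseline, while $\tau_{DA} = 1$ ms is
  indistinguishable from instantaneous; enabling the synaptic high-pass
  compensation at $\tau_{DA} = 200$ ms restores the instantaneous-level
  loss exactly as the algebra predicts.
- **Spatial structure** (`correlation_vs_distance()`,
  `preferred_dimension()`): after training the heterogeneous model, firing
  rates of nearby same-class SPNs are positively correlated and the
  correlation decays to zero within about half a cube side, while every
  target dimension is preferred by some SPNs in all parts of the volume — a
  distributed representation with weak spatial clustering, induced purely by
  the dopamine field (positions enter only through $D$, never through the
  synaptic wiring). Correlations are computed within SPN class because the
  two classes receive opposite-signed plasticity from the same dopamine and
  are therefore mutually *anti*-correlated when close. At the reduced scale
  the near-distance correlation comes out around 0.25–0.32, roughly twice
  the full-scale reference level of ~0.15: with fewer neurons and our
  reservoir calibration, the dopamine-shaped component makes up a larger
  share of each SPN's rate variance.

## Numerical and design choices

- **Synchronous update, documented order.** All rates are computed from the
  current potentials before any state is advanced; plasticity uses
  current-step quantities; the eligibility trace is advanced before the
  weight update that consumes it. The compiled loop (RcppArmadillo) and a
  pure-R engine built from the exported single-step operations implement the
  identical schedule and are asserted equal to $10^{-12}$ on small instances.
- **Reproducibility.** A run is a pure function of its configuration: five
  stage seeds (targets, thalamic code, connectivity, varicosities, shuffle)
  are derived deterministically from the master seed, and no global RNG
  state leaks in or out.
- **Balancing degenerate neurons.** A neuron whose inputs are all one sign
  cannot be balanced to zero; it is left unbalanced and flagged rather than
  erroring (it does not occur at default connectivity).
- **Ties and degenerate traces.** `preferred_dimension()` breaks correlation
  ties toward the lowest dimension index; constant-rate SPNs are excluded
  from correlation analyses and counted.
- **Problem sizes.** The test suite and acceptance script run the desk
  profile: 1,000-trial runs, 10 paired seeds per condition (20 for the
  correlation pooling). These sizes were chosen as the smallest at which the
  condition orderings are stable across seeds.

## What the synthetic setting does and does not show

All inputs are generated: GP targets, a sinusoidal thalamic clock, random
sign-constrained connectivity, random varicosity fields. Passing tests show
that the learning rule, the diffusion feedback, and the compensation motif
behave as derived *within this idealized setting*. They do not speak to
biological dopamine kinetics (no reuptake, receptor saturation, or
cholinergic release), to learning in cortex, to the omitted GPe/STN loop, or
to how the brain would compute the vector-valued error that the SNc is here
simply assumed to carry.
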