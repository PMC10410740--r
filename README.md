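# dopanet

Simulation of a basal-ganglia-like recurrent rate network in which a
**vector-valued error signal, carried by dopamine and mixed by diffuse
volume transmission, drives feedback-alignment learning** in the striatum.

## The scientific problem

The striatum is thought to learn skilled movements from dopamine feedback.
The classical view treats dopamine as a single scalar (a reward-prediction
error), which is efficient for small, discrete action sets but poorly suited
to continuous, multidimensional outputs such as a reaching trajectory. A
vector-valued dopamine error — one component per output dimension — would be
far more effective, but dopaminergic axons are broad and unspecific: each
neuron releases transmitter from many varicosities, and diffusion through
extracellular space mixes the components before they reach any striatal
projection neuron (SPN).

This package implements a model showing the mixing need not be a problem.
Each SNc dopamine neuron `k` encodes one error component
`ε_k = (r_k − T_k) r_k (1 − r_k)` of a `d`-dimensional target-tracking loss
`ℓ(t) = ½ Σ_k (r_k^SNr − T_k)²`. Dopamine from `N_var` varicosities per
neuron, decaying exponentially with distance (length scale `λ`), delivers to
SPN `j` the fixed random mixture

    C_j(t) = Σ_k ε_k(t) d_jk,   d_jk = Σ_v (1/λ) exp(−‖p_j − q_kv‖/λ)

which gates a three-factor eligibility-trace plasticity rule
`ẇ_ji = −α_j p_ji C_j` in all striatal afferent and collateral synapses
(`α` has opposite signs for direct- and indirect-pathway SPNs). Because the
striatofugal readout is itself plastic (delta rule `ẇ_kj = −β ε_k r_j`),
*feedback alignment* makes the readout weights converge toward the random
mixture matrix `D = [d_jk]`, after which the mixed dopamine signal acts like
a proper error gradient. The whole network (thalamic clock input, cortical
reservoir, sign-constrained sparse connectivity with excitation–inhibition
balance, Gaussian-process targets on a periodic kernel) is simulated by
forward Euler at 1 ms resolution, with Dale's law enforced throughout
learning.

## Worked example

```r
library(dopanet)

cfg <- sim_config(seed = 1, snapshot_every = 250)
cfg
#> <sim_config> desk profile
#>   populations: Thal 30 | Ctx 60 | Str 80 (40 dSPN + 40 iSPN) | SNr/SNc 4
#>   trials: 1000 x 200 ms (dt 1 ms), tau_m 10 ms, tau_task 20 ms
#>   dopamine: variant 'heterogeneous', lambda 0.1, 10 varicosities/SNc, tau_da instantaneous
#>   seed: 1

res <- run_training(cfg)
res
#> <run_result> heterogeneous feedback, 1000 trials
#>   loss: trial 1 = 20.881, final (median last 10) = 0.092
```

The per-trial loss (the squared output error integrated over one 200-ms
presentation of the target) falls from ~21 to ~0.09 over 1,000 trials. The
feedback-alignment diagnostic — cosine similarity between the readout
weights and the class-sign-adjusted dopamine mixture matrix — rises as
learning proceeds:

```r
alignment_trajectory(res$snapshots, res$D, res$spn_class)
#> 0.623 0.689 0.700 0.705 0.708
```

Comparing feedback conditions at matched seeds (same targets, connectivity,
and varicosity placement per run):

```r
compare_conditions(sim_config(seed = 1),
                   c("heterogeneous", "homogeneous", "none"), n_runs = 5)
#> <sweep_result>
#>      condition n_runs    median         q1       q3        min       max
#>  heterogeneous      5 0.1123941 0.09226993 0.172881 0.08212935 0.3037433
#>    homogeneous      5 1.2782018 1.20541264 2.211185 0.92427683 2.2725235
#>           none      5 1.4340729 1.33900794 1.507781 0.77392141 5.0643146
```

Vector-valued (heterogeneous) dopamine learns an order of magnitude better
than the homogeneous scalar signal, which in turn performs no better than
disabling striatal plasticity entirely (`none`; only the readout learns).
Other experiment drivers sweep the diffusion scale (`sweep_lambda()`), the
varicosity count (`sweep_varicosities()`), lesion individual projections
(`lesion_experiment()`), and low-pass-filter the dopamine signal with or
without the synaptic high-pass compensation that rescues slow dopamine
(`slow_dopamine_experiment()`). Post-hoc analyses include the pairwise
SPN-rate correlation versus distance (`correlation_vs_distance()`) and the
per-SPN preferred target dimension (`preferred_dimension()`).

See `vignettes/vector-dopamine-learning.Rmd` for the full account of the
model, its parameters, and its design choices.

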