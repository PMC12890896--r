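# clforget

Simulators and diagnostics for **catastrophic forgetting in deep, wide
neural networks**. The package is for computational neuroscientists and
machine-learning theorists who want to measure *how related two tasks are*
in the geometry a network actually sees — its feature space — and to
predict, before running any training, how much sequential learning of one
task will damage another.

## The theory in brief

A ReLU network with `L` wide hidden layers maps an input `x` to last-layer
features `Φ(W, x) ∈ R^N`, read out as `f(x) = a·Φ(W, x)/√N`. Learning a
sequence of tasks `D_t = (X_t, Y_t)` under a quadratic penalty on weight
changes, in the strong-penalty zero-temperature limit, amounts to
*minimum-change interpolation*: each task is fit exactly while moving the
weights as little as possible. In that regime the entire effect of task
relations is captured by scalar order parameters built from the tasks'
feature-space geometry. With `P_i` the projector onto the span of task
`i`'s features and `V_i` the normalized minimum-norm readout ("rule
vector") of task `i`:

- `γ_feature = Tr(P1 P2)/P` — overlap of the input-feature subspaces;
- `γ_RF = V2' P12 V2` — relevant-feature similarity (`P12` is the
  symmetrized cross-projection of one task's subspace onto the other's);
- `γ_rule = V2' P12 V1` — rule similarity;
- short-term forgetting of task 1 after learning task 2 (shared readout):
  `F_{2,1} = 2(γ_RF − γ_rule)` — twice the **conflict**;
- long-term forgetting follows an exponential relaxation
  `F_{t,1} ≈ F_max (1 − e^{−(t−1)/τ_F})`, with `τ_F` falling as `γ_RF`
  grows;
- with task-dedicated readouts (multihead), the similarity score
  `γ_sim = γ_feature + cos(V1, V2) − V1'P2V1/‖V1‖²` predicts a phase
  transition at the critical load `α_c = γ_sim^{-2}` (load `α = P/N`):
  **FR** (fixed representations, `α < 1`), **OF** (overfitting — zero
  forgetting but catastrophically poor generalization on the new task,
  `1 < α < α_c`), **G** (generalization, `α > α_c`).

All order parameters are computed either from explicit random-feature
draws (`P×N` matrices) or from `P×P` Gram blocks using the exact
infinite-width arc-cosine (NNGP) kernel of the depth-`L` ReLU network —
the two paths agree to numerical precision and the kernel path is the
deterministic default.

Task relations are controlled with parametric generators: the
**target-distractor** protocol (fractions of shared stimuli, shared
targets, and flipped labels: `ρ_shared`, `ρ_target`, `ρ_flip`), input
**permutation** sequences, and class **split** sequences — all on a
synthetic Gaussian stimulus pool or on data you load (CSV/NPY/IDX).

## Worked example

```r
library(clforget)

pool   <- make_gaussian_pool(M = 1500, N0 = 120, seed = 42)
params <- td_params(rho_shared = 0.6, rho_target = 0.8, rho_flip = 0.05,
                    P = 80, T_tasks = 12, seed = 7)
seq    <- target_distractor_sequence(pool, params)

g  <- gram_set(seq[[1]]$X, seq[[2]]$X, path = "kernel", depth = 1)
op <- order_params(g, seq[[1]]$Y, seq[[2]]$Y)
op
#> <order_params> gamma_feature=0.6509  gamma_RF=0.9036  gamma_rule=0.8314  conflict=0.0722
predict_f21(op)
#> [1] 0.1443548

spec  <- feature_map_spec(depth = 1, width = 2000, input_dim = 120, seed = 1)
curve <- forgetting_curve(seq, spec, path = "kernel")
curve
#> <forgetting_curve> T=12, path=kernel, F2,1=0.1348, F_T,1=0.4837
fit_exponential(curve)
#> <exp_fit> Fmax=0.5978, tau=8.85, residual RMS=0.0658

sim <- gamma_sim(g, seq[[1]]$Y, seq[[2]]$Y)
sim
#> <sim_op> gamma_sim=0.5927 (feature 0.6509 + cosine 0.6761 - projection 0.7342)
classify_regime(alpha = 2, sim)
#> <phase_diagnosis> alpha=2, gamma_sim=0.593, alpha_c=2.85 -> OF
```

Reading the numbers: the two tasks share most relevant features
(`γ_RF ≈ 0.90`) with nearly consistent rules (`γ_rule ≈ 0.83`), so the
conflict is small and the predicted two-task forgetting (`0.144`, in units
of normalized MSE) closely matches the simulated value on the curve
(`0.135`). Forgetting then accumulates over the 12-task sequence toward an
asymptote `F_max ≈ 0.60` with time constant `τ_F ≈ 8.9` tasks. For a
multihead learner the similarity score `γ_sim ≈ 0.59` puts the critical
load at `α_c ≈ 2.85`: at load `α = 2` the learner sits in the overfitting
regime — it will not forget task 1, but its new-task generalization
degrades sharply.

Experiment drivers (`run_experiment()` with `ops-grid`,
`singlehead-curve`, `multihead-phase`, `lambda-sweep` configurations) and
a command-line wrapper (`inst/cli/clforget.R`) cover grid sweeps, phase
scans, and serialization; see the methods vignette
(`vignettes/clforget-methods.Rmd`) for the model assumptions, parameter
choices, and numerical details.

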