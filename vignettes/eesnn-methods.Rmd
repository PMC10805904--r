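---
title: "Spiking networks for cross-patient seizure detection: models, training, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking networks for cross-patient seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eesnn)
```

## The problem

Scalp EEG seizure detection is a binary classification of short
multichannel windows, and the clinically relevant variant is
*cross-patient*: the model is trained on one set of patients and must
generalize to patients it has never seen. Two obstacles dominate:
seizure windows are rare (severe class imbalance), and inter-patient
differences in baseline statistics dwarf the within-patient difference
between seizure and background.

This package implements a spiking-network detector for that setting,
together with the pipeline pieces the setting demands — class-ratio
control, seizure augmentation, patient-invariant training, and
patient-disjoint evaluation — and a synthetic cohort generator that
makes the whole pipeline testable without clinical recordings.

## Neuron and network model

The unit is the discrete leaky integrate-and-fire neuron with
*subtractive* (soft) reset. With leak `λ ∈ (0, 1]`, threshold `V_th`,
and input current `I[t]`:

* pre-reset potential: `u' = λ u[t] + I[t]`
* spike: `s[t+1] = 1` iff `u' ≥ V_th` (the boundary case fires; a fixed
  convention is needed and `≥` avoids silently dead neurons at exact
  threshold)
* update: `u[t+1] = u' − V_th s[t+1]`

so `u[t+1] + V_th s[t+1]` reconstructs the pre-reset potential exactly —
no charge is clamped away. The membrane resistance of the
continuous-time model is absorbed into the synaptic weights, and `λ` is
a direct configuration parameter (default 0.9) rather than being
derived from a time constant, since the discretization interval is a
free choice anyway. Membranes start at `u_reset` (default 0).

The network (`eesnn_config()`, `eesnn_forward()`) stacks `H`
convolutional LIF layers on the (electrode channel × time sample) grid
with stride 1 and same padding, so all layers share one spatial grid. A
feedback convolution `W1` carries the **previous step's** top-layer
spikes into layer 1's input current; deeper layers read the **same
step's** spikes from the layer below. Keeping every layer on one grid
makes the feedback a pure channel mapping, which is what makes it
well-defined as an addition to layer 1's current. A single readout
neuron accumulates `W0 · s_H` over all simulation steps without spiking
or reset; the seizure probability is the logistic of the accumulated
potential and the label-1 rule is strictly `> 0.5`, identical to the
sign of the accumulated potential.

Two EEG-time-to-simulation-step mappings are supported: `replicate`
(the whole window presented at every step; default, with 2 steps) and
`split` (the window cut into `t2` consecutive slices, one per step).
Few replicated steps are the default because a short simulation both
regularizes and keeps inference cheap; `split` preserves sample order
across steps when within-window temporal structure at the step scale
matters.

Defaults the data cannot pin down were fixed once: 5 hidden layers of
32 channels with 3×3 kernels for the general configuration, `H = 1`
with 8 channels for the desk-scale experiments here; Kaiming fan-in
initialization seeded from the configuration.

## Equilibrium training (implicit differentiation)

For constant (replicated) input, the λ-discounted average spike rates
`α[t] = Σ λ^{t−τ} s[τ] / Σ λ^{t−τ}` of the recurrent network approach a
fixed point of the clipped affine map

```
α1 = σ( (W1 α_H + F1 x̂ + b1) / (V_th − u_reset) ),   α_{l+1} = σ( (F_{l+1} α_l + b_{l+1}) / (V_th − u_reset) )
```

with `σ(x) = min(1, max(0, x))`, whenever the product of the layer
operator norms is below `(V_th − u_reset)^H` (a contraction). The
forward pass therefore needs no stored graph: we either simulate for
`T` steps (default 30) and take `α[T]` as the equilibrium surrogate, or
solve the fixed point directly by damped Picard iteration (damping 0.5,
tolerance 1e-6, at most 100 iterations; non-convergence returns the
best iterate, flagged, rather than failing the training step).

The backward pass differentiates the fixed-point equation: with
`g(a) = f(a) − a`, the adjoint solves `t(J_g) x = −t(dL/da*)` and every
parameter gradient is `t(x) · ∂f/∂θ`. The linear solve is dense (LU,
with a flagged least-squares fallback if singular) up to 512 unknowns
and a Neumann iteration above that — valid under the same contraction
that guarantees the equilibrium exists. The clip derivative is 1
strictly inside (0, 1) and 0 outside *and on the boundary*, consistent
with σ's one-sided derivatives. The readout is applied to the top-layer
average rate during training; at inference the spiking readout
accumulates over steps, which has the same sign structure.

Verification is by oracle: on networks small enough for central finite
differences (≤ 50 parameters), the analytic gradient of the full
pipeline — solve the equilibrium, run the rate chain, take the
binary-cross-entropy — agrees with finite differences to better than
1e-4 relative error, and on 100 seeded contractive networks the
simulated `α[64]` is closer to the solved fixed point than `α[8]`. The
convergence experiments use `λ = 1`, where the discount weights are
uniform and the averaged update telescopes so the residual decays like
1/t; with `λ < 1` the late spikes dominate the average and convergence
is to a neighborhood, which is why the non-leaky limit is the clean
place to test the correspondence.

## Surrogate-gradient training

The alternative trainer unrolls the network over its simulation steps
and backpropagates through both the layer and time dimensions,
replacing the Heaviside derivative with one of three standard
surrogates centered at the threshold: a boxcar of width `a` (height
`1/a`), the logistic density with scale `a`, or the arctangent
derivative `a / (2 (1 + ((π/2) a (u − V_th))^2))`. All three are even
about the threshold and integrate to 1. Defaults: arctangent with
`a = 2`; boxcar `a = 1`; logistic `a = 0.25`. The surrogate argument is
the distance of the pre-reset potential from threshold. The soft-reset
term `−V_th s` stays in the backward graph by default (a
`detach_reset` toggle removes it).

The backward pass is verified against finite differences of a *relaxed*
forward pass in which the spike is replaced by the surrogate's smooth
primitive (so the check exercises exactly the code path used for
training, with an exactly differentiable target): agreement to 1e-5
relative error on seeded small networks.

Optimization is plain Adam (lr 1e-3 default) for both trainers; all
steps are deterministic given the batch, so training is reproducible
from the seed that drives shuffling and initialization.

## Cross-patient strategies

**Gaussian seizure augmentation.** Seizure windows are flattened,
a mean vector and sample covariance are fitted across windows, and new
seizure windows are drawn from the resulting Gaussian
(`fit_stea()` / `generate_stea()`). Because the flattened dimension
usually exceeds the number of seizure windows, the covariance is
rank-deficient and gets a ridge `ε = 1e-4 · trace(Σ)/dim` by default.
Augmentation draws are labeled seizure, tagged `synthetic`, and a
pipeline guard refuses any evaluation pool containing them. The volume
rule tops the training set up to the configured seizure:non-seizure
target (default 1:5, matching the pipeline's rebalanced ratio — the
augmentation alleviates imbalance, it does not assume full 1:1
rebalancing).

**Adversarial patient invariance.** A softmax identity discriminator
reads the time-averaged top-layer channel spike rates. Training
alternates `k` discriminator steps (minimizing identity cross-entropy;
skipped with a warning when a batch holds one patient) with one
detector step whose objective adds `β` times a *confusion* term. The
confusion term is the cross-entropy of the discriminator's output
against the uniform identity distribution. We initially implemented the
sign-flipped alternative — maximizing the discriminator's own loss —
and found it unstable here: its optimum can be reached by confidently
*permuting* identities, which preserves identity information that a
freshly trained probe recovers (held-out probe accuracies ranged
0.55–0.92 against a 0.25 chance level). The uniform-target form has no
such degenerate optimum.

Two further stabilizers proved necessary for the confusion gradient to
reliably remove identity information rather than merely dodge the
current discriminator. First, the discriminator is retrained on the
full training set's features at every epoch start (150 full-batch
steps), so confusion always points away from the identity information
actually remaining. Second, because the seizure objective keeps
optimizing long after invariance peaks — probe accuracy typically
bottoms out mid-training and drifts back up — training keeps the
weights from the epoch at which the refreshed discriminator's
in-sample accuracy was lowest. With `β = 2` and discriminator lr 0.2 on
a 4-patient cohort whose identities are coded purely as per-channel
offsets, a fresh probe's held-out identity accuracy (averaged over
five random splits, since a single 70/30 split varies by ~0.2) lands
at 0.23–0.34 against 0.25 chance across seeds. Package defaults stay
conservative (`β = 0.1`, `k = 1`). Identity coded in per-patient noise
*scale* rather than offset is substantially harder to confuse away:
firing rates are nonlinear in input amplitude, and offset-style
confusion leaves a decodable residue — a known limitation.
`identity_probe()` packages the probe protocol.

**Fine-tuning.** `finetune()` continues training on an initial temporal
fraction of a test patient's segments (default fraction 20 % when used
through `make_splits()`), with a hard error if any adaptation segment
appears in the evaluation pool.

## Preprocessing and splits

EDF (16-bit) and CSV recordings are cleaned by dropping channels on an
exclusion name list (defaults `-`, `ECG`, `EKG`, `VNS`), keeping the
first of duplicate names, and flagging non-finite samples so windowing
can exclude them. Downsampling is an 8th-order zero-phase Butterworth
low-pass at 0.4× the target rate followed by integer decimation (256 →
64 Hz and 500 → 50 Hz are the motivating factors). Windows are
consecutive and non-overlapping; a window is seizure when its overlap
with an annotated interval strictly exceeds half the window (intervals
are half-open in seconds, sample indices 0-based). Rebalancing keeps
every seizure window and uniformly subsamples non-seizure windows to
5 per seizure window, seeded, never duplicating or oversampling.
Leave-one-out splits hold out each patient in turn and are verified to
partition the cohort patient-disjointly.

## The synthetic cohort

The generator (`cohort_config()`, `generate_cohort()`) emulates the
structure that matters for this pipeline: multiple patients with
patient-specific baseline statistics (per-channel constant offsets,
per-patient amplitude scales), autocorrelated AR(1) background noise, a
Poisson process of seizure episodes with gamma durations, and a shared
low-frequency oscillatory seizure signature with fixed per-channel
gains — the "common epilepsy feature" the detector should find, riding
on patient-specific nuisance it should ignore.

Defaults, chosen once: 10 patients, 4 channels, 32 Hz, 360 s records,
30 episodes/hour with mean duration 10 s (seizure fraction ≈ 8 % before
rebalancing — far above clinical rarity, deliberately, so that
desk-scale records contain enough positive windows to train and
evaluate on), signature amplitude 3 background standard deviations in
the 3–6 Hz band, offsets of unit standard deviation. Ten patients
rather than fewer because the cross-patient task needs enough baseline
diversity in training for the decision threshold to transfer to unseen
patients; with very few training patients the model separates classes
(high AUC) but mis-calibrates on new baselines.

What the generator does *not* emulate — and therefore what passing
tests do not establish about clinical data: real ictal morphology
(spike-wave complexes, evolving frequency), artifacts (muscle, eye,
electrode pop), montage effects, non-stationary baselines, and the
true rarity of seizures. Results on the synthetic cohort validate the
machinery, not clinical performance.

## Evaluation and energy

Metrics are sensitivity, specificity, their geometric mean, the
class-rebalanced accuracy `(r·TP + TN)/(r·(TP+FN) + TN + FP)`, and
rank-statistic AUC (ties at 0.5). The rebalancing weight defaults to
`r = (TN+FP)/(TP+FN)`, under which rebalanced accuracy is algebraically
the mean of sensitivity and specificity; this choice is exposed as an
override and is validated by recomputing published
sensitivity/GMean/rebalanced-accuracy triples consistently. Metrics
with an empty denominator class are reported as `NA`, never 0.

The energy model prices a dense synaptic operation (multiply-
accumulate) at 4.6 pJ and a spike-triggered accumulate at 0.9 pJ.
`count_ops()` counts dense-mode MACs for every synapse at every step,
and event-driven ACs per actually-fired presynaptic spike with exact
same-padding boundary fan-outs; the input-layer convolution (analog
input) and the readout remain MACs in both modes, and feedback synapses
count from the second step (the first has no feedback input).

`saliency()` backpropagates the seizure logit to the input window under
the surrogate relaxation, giving a signed (channel × time) importance
map.

## Numerical choices and limitations

* Heaviside at threshold fires; clip subgradient at the boundary is 0.
* Equilibrium solver: damping 0.5, tolerance 1e-6 sup-norm residual,
  100 iterations; adjoint solve dense ≤ 512 unknowns, Neumann above.
* Checkpoints are RDS bundles of weights plus configuration with a
  bit-exact round trip.
* Problem sizes in the shipped experiments are desk-scale by design
  (one hidden layer, 8 channels, 64-sample windows); the architecture
  scales, but pure-R convolution makes large configurations slow.
* The IDE trainer requires the `replicate` time setting for its
  simulated-equilibrium forward; `split` input would need a
  converging-input analysis that is out of scope.
* Energy numbers are theoretical operation counts, not hardware
  measurements.
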