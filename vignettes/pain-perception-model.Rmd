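---
title: "Kalman-filter models of pain perception: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kalman-filter models of pain perception: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painkf)
library(dplyr)
```

## The model

`painkf` simulates pain perception as Bayesian state estimation. A latent
state $x$ — the actual or potential tissue damage, on the familiar
11-point pain scale (0 = no pain, 10 = worst imaginable) — evolves in the
world as

$$x^{(k)} = A\,x^{(k-1)} + B\,\tilde u^{(k)},$$

where $\tilde u$ is the damage input (heat, force) and $A$ the true
recovery rate. The brain never sees $x$; it receives sensory input
$z^{(k)} \sim N(H x^{(k)}, R)$, truncated to $[0, 10]$ by resampling,
with $R$ the sensory-noise variance. Damage to the sensory pathway
(denervation) is modelled as a step increase of $R$.

Perception is a Kalman filter over an *internal model* with parameters
$\hat A$ (believed pain persistence) and $\hat B$ (believed gains of cue
or context inputs $u$, which predict pain without causing it):

* expected pain (prior): $\bar{\hat x}^{(k)} = \hat A \hat x^{(k-1)} +
  \hat B u^{(k)} + \varepsilon(0, Q)$, with heteroscedastic process noise
  $Q = Q_0 + \lVert u^{(k)}\rVert^2 Q_u$;
* prior variance $\bar P^{(k)} = \hat A^2 P^{(k-1)} + Q$;
* gain $K = \bar P / (\bar P + R)$; perceived pain (posterior)
  $\hat x = \bar{\hat x} + K (z - \bar{\hat x})$, with
  $P = (1-K)\bar P$.

The hierarchical variant adds a second Kalman filter that adapts
$\hat p = [\hat A, \hat B]^\top$ from the prediction error
$\hat e = \hat x - \bar{\hat x}$, whose variance is taken as
$R_p = P + \bar P$ (the sum of the covariances of the two terms forming
the error). The parameter prior is a random walk with diagonal covariance
$Q_p$; the observation row is $H_p = (1-K)[\hat x^{(k-1)}, u^{(k)}]$ (the
sensitivity of the posterior to the parameters); and the covariance
update is scaled by the state gain,
$P_p \leftarrow \bar P_p - K\,(\bar P_p H_p^\top)(H_p \bar P_p)/S$ with
$S = H_p \bar P_p H_p^\top + R_p$, so that infinite sensory noise
($K \to 0$) does not masquerade as parameter certainty. The prior state
variance gains a parameter-uncertainty term
$H_p P_p H_p^\top$, and correspondingly the hierarchical baseline process
noise shrinks to $Q_0 = 0.1^2$ (from $0.4^2$ in the single-layer model).

## Defaults and what they mean

| Parameter | Default | Units / role |
|---|---|---|
| $\hat A$ (initial) | 0.8 | unitless; < 1 = pain expected to fade |
| $\hat B$ (initial) | 0.6 per channel | pain units per cue unit |
| $H$ | 1 | state to sensory mapping |
| $R$ | $0.8^2$ | (pain units)²; sensory noise |
| $Q_0$ | $0.4^2$ single / $0.1^2$ hierarchical | baseline process noise |
| $Q_u$ | $0.4^2$ | extra process noise per squared cue unit |
| $P^{(0)}$ | $10^6$ | uninformed initial state belief |
| $Q_p$ | $0.002^2 I$ | internal-model drift and learning noise |
| $P_p^{(0)}$ | $10^6 I$ | uninformed initial parameter belief |
| cue magnitude $u$ | 3.7 | shared by all cues (cues do not differ physically) |

$R$, $Q$ and $Q_p$ jointly set the behaviour: $R$ weighs sensation
against expectation, $Q$ how quickly the expectation forgets, and $Q_p$
both the drift and the learning rate of the internal model.

## Numerical and design choices

**Sampled process noise.** The prior-mean equation carries the process
noise explicitly, so the engines draw it into $\bar{\hat x}$ by default
(`sample_process_noise = TRUE`); this, with the sensory noise, generates
the run-to-run spread that the median/IQR reporting summarises. Switching
it off yields the deterministic textbook filter used in exact tests. The
same applies to the parameter random walk (`sample_param_noise`): the
draw enters the parameters actually used at the step, which is what makes
the believed persistence a literal random walk when $R \to \infty$.

**Noise streams.** Every replicate derives four independent RNG streams
(sensory, process, parameter, individual-level draws) from
`(seed, replicate, stream)`, so toggling one noise source never shifts
another and every run is bit-reproducible from its config and seed.

**Truncated sensory sampling.** Draws outside $[0,10]$ are resampled (the
model's stated convention); after 1000 rounds any unresolved draw falls
back to inverse-CDF truncated sampling, which is distributionally
identical and guarantees termination when $Hx$ sits far outside the scale
(never the case in the shipped scenarios). A consequence worth knowing:
around $x = 0$ the truncated draws have mean
$\sigma\sqrt{2/\pi} \approx 0.64$ for $R = 0.8^2$, so a persistent belief
($\hat A = 1$) tracks this *sensory floor*, not zero — visible in the
chronic-pain and null-stimulus summaries.

**Covariance update ordering.** The gain-scaled parameter-covariance
update is implemented as $(I - K K_p H_p)\bar P_p$, i.e. covariance on
the right. Written with the covariance on the left the product is
asymmetric and — under the $K$-scaling — symmetrising afterwards does not
preserve positive semidefiniteness; in stimulated long runs the diagonal
went negative and the persistence estimate diverged. The implemented form
is the PSD-preserving expansion $\bar P_p - K (\bar P_p H_p^\top)(H_p
\bar P_p)/S$, identical in the scalar case and reducing to the standard
$(I - K_p H_p)\bar P_p$ at $K = 1$. $P_p$ is symmetrised each step
(tolerance $10^{-10}$ in the PSD property test).

**Lagged observability row.** $\bar P^{(k)}$ needs $H_p^{(k)}$, which
needs $K^{(k)}$, which needs $\bar P^{(k)}$. The variance term therefore
uses the $H_p$ computed at the end of the previous step, together with
the current parameter prior covariance $\bar P_p$; the fresh $H_p$ is
computed after the state update and used in the parameter update. The
gain varies slowly at steady state, so the one-step lag is benign (a
sensitivity check is in the test suite).

**Error indexing.** The parameter update consuming the step-$k$ error is
applied before the step-$k+1$ state prediction, so parameters used at
$k+1$ already reflect the error at $k$.

**Initial state mean.** $\hat x^{(0)} = 0$; with $P^{(0)} = 10^6$ the
first update is sensor-dominated, so the choice is immaterial (verified
by a sensitivity test).

**No internal clipping.** Only $z$ is truncated. $\hat x$ is not clipped
internally — escalation dynamics (believed persistence above 1) would be
distorted otherwise; summaries may report a clip if asked.

**Negative persistence** is rejected at configuration time; the model
never uses it.

## Initial parameter uncertainty: a stability boundary

The uninformed default $P_p^{(0)} = 10^6 I$ is *not* usable in scenarios
that drive the filter through cue trials. On a cue trial
$Q = Q_0 + u^2 Q_u \approx 2.2$, so $K \approx 0.78$; the prediction
error's true sensitivity to a gain error is $-K u$, while the parameter
filter observes through $H_p = (1-K) u$. An uncertainty-dominated update
($K_p \to 1/H_p$) then over-corrects by the factor $K/(1-K) \approx 3.4 >
2$ and the gains oscillate divergently. The scenarios therefore start
from *belief-consistent* parameter uncertainty:

* conditioning: $P_p^{(0)} = \sigma_{b_0}^2 = 0.8^2$ per cue gain — the
  covariance consistent with the gains actually being drawn from
  $N(0.9, 0.8^2)$; this produces the gradual, overlapping-to-separated
  gain differentiation the protocol is meant to show;
* pain-history and offset scenarios: $P_p^{(0)} = I$ (and $P = 1$ where a
  nerve injury defines the starting point), the converged-baseline belief
  also used by the spontaneous-neuropathic-pain sweep.

## The scenario engines and their conditions

All scenario defaults are the study conditions: 100 simulation runs for
trajectory scenarios (median and 25–75% IQR, linear-interpolation
quantiles), 28 simulated individuals for trial scenarios (mean and
inter-individual SE). Trials in the cue paradigms are discrete events:
the persistence parameter is fixed at $\hat A = 0$ (and frozen in the
hierarchical conditioning — its noise and covariance entries zeroed — so
that only the cue gains learn, trials stay independent, and the learned
quantity matches what the protocol manipulates).

* **Cue effects, single layer** — 40 test trials, balanced 2 (cue) × 2
  (heat) design with 10 trials per cell shuffled per individual; cue
  vectors orthogonal with common magnitude 3.7; gains
  $b_{placebo} \sim N(0.7, 0.5^2)$, $b_{nocebo} \sim N(1.3, 0.5^2)$,
  truncated at 0; heat levels map to damage 3.1 (47 °C) and 4.3 (48 °C).
* **Conditioning, hierarchical** — 120 conditioning trials pairing the
  placebo cue with $z \sim N(2.2, R)$ and the nocebo cue with
  $z \sim N(5.2, R)$ (truncated), initial gains from $N(0.9, 0.8^2)$
  truncated at 0, then the 40-trial test phase above.
* **Chronic pain** — cued damage impulse ($\tilde u = u = 3.7$) at step
  20 of 150, world $A = 0.9$, $B = 0.8$, belief $\hat A = 1$, contrasting
  $R = 0.8^2$ with $R = 1.8^2$; summarised by the median perceived pain
  over post-impulse steps with true damage below 0.1.
* **Neuropathic sweep (single)** — 200 baseline steps at $R = 0.8^2$
  (enough for the prior variance to reach its steady state, checked
  against the closed-form Riccati solution) then 300 steps at the swept
  $R$, for $\hat A \in \{0.9, 1.0, 1.1\}$.
* **Neuropathic sweep (hierarchical)** — post-injury runs of 1000 steps
  from $P = 1$, $P_p = I$, $\hat x^{(0)} = 0$, over $\hat A_0 \in
  \{0.9, 1.0, 1.1\}$ and $R \in \{0.8^2, 8^2, 80^2, 800^2\}$.
* **Pain-history risk** — 600 pre-injury steps with damage impulses
  every 50 steps (none in the no-stimuli history), injury 50 steps after
  the last impulse ($R \to 800^2$), 200 post-injury steps. The summary
  window is the last 25% of the post-injury period; the post-injury
  horizon is kept at 200 steps because the pain-decay time constant is
  $\approx 1/(1-\hat A)$ steps ($\approx 80$ for the no-stimuli history),
  and a much longer horizon would summarise a regime where every history
  has decayed to the sensory floor and the contrast is pure noise.
* **Offset analgesia** — damage plateaus 3.1 (T1, 49 steps), 4.3 (T2,
  49 steps), 3.1 (T3, four blocks of 25 steps); the temperature-to-damage
  map is linear, so the plateau profile is imposed exactly; no cues
  ($u = 0$); internal model matched to the world at onset
  ($\hat A_0 = A = 0.9$) with converged belief ($P = 1$, $P_p = I$). The
  first 5 steps after each temperature change are omitted from the
  interval medians. Interval levels and lengths are configurable; the
  defaults reuse the printed 47/48 °C damage anchors since only the
  qualitative undershoot is claimed.

## What the generator emulates — and what it does not

The synthetic world reproduces the *information structure* of the
paradigms: linear damage dynamics, truncated-Gaussian afferent input,
cue–outcome contingencies, denervation as a noise step. It does not
emulate peripheral physiology (sensitization, habituation, nonlinear
temperature transduction), actions or decision making, or the affective
dimension of pain. Passing tests therefore show that the *inference
model* behaves as described under its own assumptions — not that real
rating data would be fit quantitatively. Two consequences of the
truncation convention are worth repeating when comparing with intuition:
perceived pain has a floor near $0.64$ (for $R = 0.8^2$) rather than 0
under a persistent belief, and at very high $R$ the truncated input is
nearly uniform on the scale with mean 5, which slowly attracts a
persistent belief's pain level.

## Known limitations

* The parameter filter is an inconsistent (linearised, scalar-innovation)
  estimator: with uncertainty-dominated gains it over-corrects (the
  stability boundary above), and its gain magnitude is scale-dependent —
  near the sensory floor $R_p$ is small and $K_{p,A}$ is order one even
  though the actual update $K_p \hat e$ is negligible.
* Offset-analgesia recovery is complete well before the last assessment
  blocks, so the late interval medians are statistically tied; orderings
  among them are only meaningful within the Monte-Carlo resolution of
  the medians.
* Single pain dimension, linear observation, no backward smoothing — by
  construction.

## Problem sizes

The default test suite runs scaled-down scenario sizes (tens of
replicates, hundreds of steps); the acceptance checks and
`scripts/acceptance.R` use the full study conditions (100 runs, 28
individuals, $10^4$-step noise-limit runs, $10^5$ sampler draws), which
complete in a few minutes on one CPU.

```{r example}
res <- run_chronic_pain(n_replicates = 20, seed = 1)
tidy(res)
```
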