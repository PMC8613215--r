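---
title: "An active-inference account of involuntary forces in the virtual hand illusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-inference account of involuntary forces in the virtual hand illusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhisim)
library(dplyr)
```

## The phenomenon and the model

In the rubber/virtual hand illusion (RHI/VHI), synchronous visuo-tactile
stroking makes a fake hand feel like one's own. When the fake hand is
displaced from the real (hidden, locked) hand, participants not only
recalibrate perception — the classic proprioceptive drift — they also push
involuntarily *toward* the fake hand, even when instructed to stay still.
`vhisim` implements a computational account of that active component: both
perception and action descend the same precision-weighted prediction-error
objective (a free-energy bound), so a visuo-proprioceptive conflict that
cannot be fully explained away perceptually leaks into a lateral force.

The arm is reduced to one degree of freedom: the elbow angle of the left
forearm, rotating in the horizontal plane, with zero parallel to the sagittal
plane and positive rotations toward the body midline. The agent maintains a
generalized belief $\mu = (\mu^{[0]}, \mu^{[1]}, \mu^{[2]})$ over the angle
and its derivatives, plus a causal percept $\nu$, the believed horizontal
position of the virtual hand.

Two generative maps define expectations:

* **Sensory map** $g$: proprioception reports $\mu^{[0]}$ and $\mu^{[1]}$
  directly; vision of the hand is predicted by
  $g_v(\mu^{[0]}) = L\cos(\mu^{[0]} - \pi/2) + b = L\sin\mu^{[0]} + b$,
  with forearm length $L$ and a participant-specific localization bias $b$;
  and the measured virtual-hand position $s_v$ is predicted by the percept
  $\nu$ itself.
* **Dynamics map** $f$: with no task, the believed arm is a damped
  mass-spring, $f(\mu) = (\mu^{[1]},\, -\gamma\mu^{[0]}/m,\, 0)$.

Writing $\Pi$ for channel precisions (inverse variances), the objective is

$$F = \tfrac12\Big[\Pi_p(s_p-\mu^{[0]})^2 + \Pi_{\dot p}(\dot s_p-\mu^{[1]})^2
+ \kappa\,\Pi_v\big(\nu - g_v(\mu^{[0]})\big)^2 + \Pi_c(s_v-\nu)^2
+ \Pi_{\mu}\big(\mu^{[2]} + \gamma\mu^{[0]}/m\big)^2\Big].$$

The updates are exact gradient flows on $F$ plus the generalized shift:
$\dot\mu = D\mu - \partial F/\partial\mu$ and
$\dot\nu = -\partial F/\partial\nu$ (`free_energy_gradients()`), action
descends the sensory part through proprioception only,
$\dot a = -K_a \Pi_p (s_p - \mu^{[0]})$ (`action_update()`), and the
proprioceptive and visual precisions follow
$\dot\Pi = -\tfrac12 (s-g)^2 + \Pi^{-1}$, clamped at floors $e^{1}$ (visual)
and $e^{0.1}$ (proprioception) (`precision_update()`). The causality weight
$\kappa \in [0,1]$ — the believed probability that the seen hand and the
felt touches share a common source, our proxy for the ownership illusion —
scales the arm-vs-virtual-hand error channel.

The gradient-flow form is a deliberate design choice: one fixed quadratic
objective whose finite-difference gradients the implementation must
reproduce to $10^{-5}$ (this is tested on random states). Among the several
sign/indexing conventions one finds for generalized-coordinate update rules,
we adopt the one that makes the updates *exactly* the negative gradient of
$F$ (the dynamics-error shift enters through its adjoint), because it is the
only convention the objective itself can certify. For the same reason
$\kappa$ multiplies the whole quadratic term of its channel, so it weights
that error both in the posture update and in the $\nu$ update; setting
`kappa_in_nu = FALSE` restricts it to the posture update, as the attribution
of the weight to the $\nu$ flow is genuinely open.

Why this produces the observed behaviour: during stimulation the arm is
locked, so $s_p$ stays at the true angle while the virtual hand is displayed
at a lateral offset. With $\kappa > 0$ the visual error drags $\mu^{[0]}$
toward an angle that would place the hand at the virtual location
(proprioceptive drift), $\nu$ is simultaneously drawn toward the predicted
hand position (visual drift), and the resulting proprioceptive error
$s_p - \mu^{[0]}$ feeds the action flow: a sustained lateral force toward
the virtual hand, positive toward the body midline. With the hands aligned
the errors vanish identically and the force is exactly zero.

## Units and numerical choices

* **Internal unit is the metre.** User-facing lengths (`L`, `b`, condition
  offsets, `nu_cm`, drifts) are in cm, converted at the interface. The
  precision floors $e^1$ and $e^{0.1}$ and unit dynamics variances are
  meaningful for positions of order 0.1–1 (metres): in centimetres the
  visual channel's stiffness would be $10^4$ times larger, the explicit
  Euler flow at $dt = 10^{-3}$ s would be unstable, and the equilibrium
  would sit at complete drift rather than at the partial compromise the
  drift phenomenology shows.
* **Integration**: explicit Euler, $dt = 1$ ms over 40 s trials (40 000
  steps), matching the 1 kHz force sampling of the experimental setup; the
  integrator is compiled (Rcpp) and is verified step-for-step against the R
  reference `aif_step()`. All eigenvalues of the linearized flow are a few
  s$^{-1}$, so Euler at 1 ms is comfortably stable.
* **Degenerate inputs**: $\mu^{[0]}$ is clipped to
  $(-\pi/2 + 10^{-6}, \pi/2 - 10^{-6})$ to keep $g_v$ well defined; the
  third-order belief entries appearing in the shift are truncated to zero
  (the generative maps predict nothing beyond second order); only the
  proprioceptive-angle and visual precisions adapt — applying the same flow
  to the causal channel diverges under a 15 cm conflict, and floors exist
  only for the two named channels.
* **Precision flow fixed points**: $\dot\Pi = 0$ at $(s-g)^2 = 2/\Pi$;
  under persistent large error the flow decreases $\Pi$ until the floor,
  under small error $\Pi$ grows like $\sqrt{2t}$. Both regimes are exercised
  in the tests.

## Parameters

| parameter | default | unit | meaning / rationale |
|---|---|---|---|
| `L` | 44.7208 | cm | forearm length; cohort draws $\mathcal N(44.7208, 2.4807)$ (SD), from human RHI measurements |
| `b` | 0 | cm | localization bias of the predicted hand; cohort draws $\mathcal N(0, 4.2794)$ |
| `sigma_sp2` | 1 | rad² | initial proprioceptive variance; cohort draws $\mathcal N(1, 0.5)$ truncated at 0.05 |
| `m`, `gamma` | 1, 1 | model units | mass-spring dynamics prior; unspecified by the phenomenology, covered by fixed-point and symmetry tests rather than absolute values |
| `K_a` | 0.1 | – | action gain; only force sign and relative magnitude across conditions are claimed, so the gain is conventional with $\partial s_p/\partial a = 1$ |
| `kappa` | 1 | – | causality weight: 1 synchronous, 0.3 asynchronous, 0 severed |
| `sigma_v2`, `sigma_c2` | $e^{-1}$, 1 | m² | visual variance starts at its precision floor; causal channel fixed |
| `sigma_mu` | (1,1,1) | – | dynamics variances per order |
| `noise_sd_proprio` | 0.01 | rad | per-sample observation noise |
| `noise_sd_visual` | 0.1 | cm | per-sample observation noise |
| `force_scale` | 0.74 | N/unit | one-off calibration so the synchronous lateral-condition windowed mean magnitude is ≈0.04 N, the order of the human effect; every scientific claim uses sign/monotonicity only |
| `dt`, `duration` | 0.001, 40 | s | trial integration grid |

The distribution parameters above are read as standard deviations; reading
the second argument as a variance would make forearm lengths implausibly
uniform (SD 1.6 cm across adults).

## What the synthetic data emulate — and what they do not

Three generators produce data shaped like the experiment:

* `vt_events()` emulates the stimulation trains: a ball-bounce (visual)
  event roughly every 2 s (±10% uniform jitter keeps trains aperiodic) and a
  vibration delayed by $U(0, 0.1)$ s (synchronous), $U(0.1, 0.8)$ s
  (asynchronous) or a 25% / 75% mixture (`weak_asynchronous`). The true
  delay distribution of a ball falling past its bounce point is not uniform;
  uniformity is a transparent stand-in, and only the mean delay enters
  `kappa_from_synchrony()`. The two-anchor linear map (mean delay ≤ 0.1 s →
  $\kappa = 1$; ≥ 0.45 s, the ideal fully-random asynchronous mean →
  $\kappa = 0$) was chosen for transparency; its default mixing fraction
  puts the weak-asynchronous train near $\kappa \approx 0.3$, the value used
  for the experimental asynchronous group. Discrete settings are always
  available directly through `vhi_params(kappa = )`.
* `simulate_cohort()` / `kappa_sweep()` draw participants from the stated
  distributions and run every trial, recording the 10–15 s windowed mean
  force, with per-trial noise streams derived deterministically from
  (participant, condition, trial) so runs are reproducible and sweeps are
  paired across $\kappa$. Four trials per condition (one block's worth) is
  the default per-participant load.
* `synth_force_table()` produces a *synthetic* human-scale trial table
  (14 participants × 120 trials) for exercising the statistics pipeline:
  per-condition shifts of −0.039 / 0 / +0.036 N, trial noise SD 0.22 N,
  participant intercept SD 0.03 N and participant-by-condition SD 0.04 N.
  These scales were derived once from the published summary statistics of
  the human force data (the reported $F_{2,1674}$ and paired $t_{13}$ values
  imply them up to rounding) so that the pipeline runs at realistic
  signal-to-noise; the table is not, and does not substitute for, the
  recorded measurements.

Passing tests on these generators show that the *model* produces the
claimed phenomenology and that the *pipeline* recovers known effects at
realistic noise — they cannot show that real participants obey the model.
In particular the simulator has no musculoskeletal arm, no trial-to-trial
carry-over (each trial restarts from an unbiased belief), no ownership
dynamics (the illusion's strength enters only through the static $\kappa$),
and observation noise is white, whereas human force traces have strong
low-frequency structure.

## The experimental schedule

`generate_schedule()` reproduces the design counts exactly: 10 blocks × 12
trials per participant, 4 per condition per block, 120 trials per
participant (40 per condition), alternating group assignment (7/7 at
n = 14, 1680 trials). Within a block, Center trials occupy fixed positions
1, 6, 7, 12 — the design fixes Center at the beginning, middle and end of
each block to wash out carry-over, and with four Center trials per block a
symmetric double-middle placement is the natural reading — while one run of
four Left and one of four Right trials fill positions 2–5 and 8–11 in
randomized order.

## The statistics pipeline

`remove_block_offset()` centres each block's force samples (posture shifts
between blocks bias the sensor); `window_mean()` takes the half-open
10–15 s average (5000 samples at 1 kHz); `anova_location_mode()` fits the
trial-level two-way fixed-effects ANOVA — location (3, within) × mode (2,
between) with interaction — which is the parameterization whose residual
df equals $N - 6$ (1674 at 1680 trials), matching the human analysis; a
participant-level aggregation is available via `unit = "participant"`.
`posthoc_tests()` aggregates per participant and runs the directional
tests: Center vs 0 (two-tailed, with the one-tailed upper companion also
reported, since the two conventions differ exactly when the observed mean
is negative and reporting both removes the ambiguity), Right vs Center
(paired, one-tailed greater) and Left vs Center (paired, one-tailed less).
Zero-variance aggregates are resolved as exact limits: $t = 0$ with the
null p-value when the mean is zero, strict rejection ($p = 0$) when every
difference deviates in the tested direction. All implementations are tested
against explicit sums-of-squares and closed-form $t$ oracles at $10^{-10}$,
and against a permutation null calibration.

## Problem sizes used in the checks

The packaged checks run cohorts of 10 participants per group or per
$\kappa$ value with 2–4 trials per condition, 100-state gradient panels,
200-replicate null calibrations and 100-replicate power checks; these sizes
give Monte-Carlo error comfortably below the effects under test while
keeping the default suite fast. The acceptance script mirrors the 20
participant (10+10) cohort and the $\kappa \in \{0, 0.3, 0.6, 0.9\}$ sweep
at 10 participants, with the full 14-participant synthetic table for the
statistics stage.

## Known limitations

* $\kappa$ is exogenous: the model does not infer ownership from the event
  trains; `kappa_from_synchrony()` is a documented bridge, not an inference.
* The asynchronous-group attenuation the model predicts (ratio ≈ 0.7 at the
  defaults) is a model claim; human data may saturate — the virtual
  environment can sustain an implicit causal binding even under nominally
  asynchronous stimulation, which is precisely what the weak-asynchronous
  train and the $\kappa$ sweep let one explore.
* Absolute simulated Newtons inherit the `force_scale` calibration; only
  signs, orderings and ratios are meaningful across conditions.
* The one-sample Center test on a simulated cohort is a near-exact null
  (the per-participant Center force is ≈ $-0.002\,b$ N), so it rejects at
  the nominal rate across seeds; single-cohort significance claims about
  the Center condition are not stable by design.
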