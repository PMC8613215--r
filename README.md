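# vhisim

Active-inference simulation and force analysis for the virtual hand
illusion (VHI).

## What problem this addresses

In rubber/virtual hand illusion experiments, correlated visuo-tactile
stimulation makes a displaced fake hand feel like one's own. Beyond the
classic perceptual recalibration (proprioceptive drift), participants with a
locked arm produce small *involuntary lateral forces toward the fake hand*.
`vhisim` is for researchers who want to simulate that active component, to
generate virtual cohorts under the exact experimental design used with
human participants, and to run the matching force-statistics pipeline on
simulated or recorded trial tables — all without hardware.

## The model

A one-degree-of-freedom arm (elbow angle, horizontal plane) holds a
generalized belief $\mu = (\mu^{[0]}, \mu^{[1]}, \mu^{[2]})$ and a percept
$\nu$ of the virtual hand's horizontal position. Expectations come from a
visual map $g_v(\mu^{[0]}) = L\sin\mu^{[0]} + b$ and a mass-spring dynamics
prior $f(\mu) = (\mu^{[1]}, -\gamma\mu^{[0]}/m, 0)$. Perception, action and
sensory precision all descend one precision-weighted squared-error
objective

$$F = \tfrac12\big[\Pi_p e_p^2 + \Pi_{\dot p} e_{\dot p}^2 +
\kappa \Pi_v (\nu - g_v(\mu^{[0]}))^2 + \Pi_c (s_v - \nu)^2 +
\Pi_\mu e_\mu^2\big],$$

with the causality weight $\kappa \in [0,1]$ (believed probability that the
seen hand and felt touches share a source; 1 synchronous, 0.3 asynchronous)
scaling the visual conflict channel. Action follows
$\dot a = -K_a \Pi_p (s_p - \mu^{[0]})$: once the belief drifts toward the
virtual hand, the proprioceptive error turns into a lateral force toward
it — positive toward the body midline. Precisions adapt by
$\dot\Pi = -\tfrac12(s - g)^2 + \Pi^{-1}$ with floors $e^1$ (visual) and
$e^{0.1}$ (proprioception). Trials integrate 40 s at 1 kHz (compiled Euler
integrator). See the vignette
(`vignettes/virtual-hand-illusion.Rmd`) for assumptions, units and design
choices.

## Worked example

Simulate one noise-free trial with the virtual hand 15 cm toward the
midline, then a 20-participant cohort (10 synchronous, 10 asynchronous, 4
trials per condition), and analyze it:

```r
library(vhisim)

tr <- simulate_trial(offset_cm = 15, params = vhi_params(b = 0), noise = FALSE)
window_mean(tr)          # 0.03916 N, toward the virtual hand
attr(tr, "proprio_drift_cm")  # +0.266 cm: inferred hand drifts toward it

tab <- simulate_cohort(n_sync = 10, n_async = 10,
                       trials_per_condition = 4, seed = 1)
analyze_forces(tab)
```

```
<vhi_stats>
Per-condition windowed mean force:
# A tibble: 3 x 4
  condition mean_force_N sd_force_N n_trials
1 Center        -0.00609    0.00662       80
2 Left          -0.0398     0.0110        80
3 Right          0.0276     0.00784       80
<vhi_anova> trial-level, n = 240, residual df = 234
  term            df1   df2 statistic   p.value
1 location          2   234    2323.  4.43e-155
2 mode              1   234      45.4 1.26e- 10
3 location:mode     2   234      88.1 3.04e- 29
<vhi_posthoc> 20 participants
  test                 estimate statistic    df   p.value alternative
1 center_vs_zero       -0.00609     -4.03    19 7.10 e- 4 two.sided
2 center_vs_zero_upper -0.00609     -4.03    19 1.000e+ 0 greater
3 right_vs_center       0.0337      21.6     19 4.04 e-15 greater
4 left_vs_center       -0.0337     -21.6     19 4.05 e-15 less
```

Reading it: lateral forces point toward the virtual hand on both sides
(Left negative, Right positive, each ≈0.03–0.04 N), the location effect
dominates the trial-level ANOVA, and the paired directional tests confirm
Right > Center and Left < Center. Simulated trials are nearly
noise-free, so test statistics on simulated cohorts are far larger than
with human data at the same effect sizes; the Center mean here reflects
this cohort's draw of localization biases (see the vignette on why the
Center test behaves as a null across seeds). `autoplot(tr)`,
`plot_force_summary(tab)` and `plot_kappa_sweep()` draw the standard
panels.

The causality sweep shows the attenuation mechanism:

```r
summarize_sweep(kappa_sweep(c(0, 0.3, 0.6, 0.9), n_per_kappa = 10,
                            trials_per_condition = 2, seed = 1))
```

with mean |lateral force| rising from noise level at `kappa = 0` through
≈0.028 N at 0.3 to ≈0.040 N at 0.9.

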