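---
title: "Modelling levodopa response in the alternate finger tapping task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling levodopa response in the alternate finger tapping task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levotap)
```

`levotap` couples three sub-models into a single mechanistic chain from an
oral levodopa dose to the tapping frequency measured in the clinic: plasma
pharmacokinetics, an effect compartment with a Hill concentration–effect
law, and a firing-rate basal ganglia (BG) network whose winner-takes-all
dynamics set the speed of action selection. This vignette documents the
model, every tunable constant with its unit and default, the numerical
choices, the reconstruction decisions that were genuinely open, and the
known limitations — in particular, where the reconstructed network falls
short of the published frequency anchors.

## 1. Plasma pharmacokinetics

Levodopa plasma kinetics follow a two-compartment model,

$$V_1\,\dot c_1 = -(k_{21}+k_{etot})\,c_1 + k_{12}\,c_2 + i(t), \qquad
  V_2\,\dot c_2 = k_{21}\,c_1 - k_{12}\,c_2,$$

with concentrations in µg/ml (≡ mg/L), volumes in L, transfer constants in
L/min and time in minutes. The two inter-compartment constants are allowed
to differ ($k_{12} \ne k_{21}$); forcing them equal fits clinical plasma
curves poorly. $k_{etot} = k_{e1} + k_{31}$ lumps all elimination from the
central compartment, so the downstream effect compartment receives drug
without feeding back — the plasma model is self-contained.

*Oral absorption* is modelled as a constant-rate input over an absorption
window: $i(t) = \mathrm{dose}/\mathrm{duration}$ inside the window, zero
outside, so the administered amount is conserved exactly. For observed
records the window is taken as the time up to the measured concentration
peak (the period of progressive absorption), overridable in
`infusion_schedule()`. The standardised test dose is 100 mg over a 30 min
window.

*Fixed volumes.* $V_1$ and $V_2$ are standard 70-kg values, not estimated
per subject (three free constants against ~12 plasma samples is already at
the edge of what the data support). The package defaults are $V_1 = 11$ L
and $V_2 = 38$ L — a conventional central/peripheral split of levodopa's
≈ 0.7 L/kg distribution volume. Every quantitative result in the test suite
and acceptance script is, by construction, independent of this choice:
recovery studies compare against parameters simulated with the same
volumes, and the tapping-side results do not involve them at all.

*Fitting.* `fit_pk()` minimises the unweighted sum of squared residuals of
$c_1$ at the observation times over $(k_{12}, k_{21}, k_{etot})$, using
Nelder–Mead on log-transformed parameters (positivity by construction, and
the parameters span two orders of magnitude across subjects). Weighted
residuals were considered and rejected: nothing in the assay suggests a
concentration-dependent error model, and plain least squares keeps the
criterion value interpretable. The optimiser restarts from the user's
initial guess plus four deterministically jittered points (±0.5–0.8 on the
log scale) and keeps the best minimum; on noise-free synthetic data from
each of the six published parameter sets all three constants are recovered
to well under 1% from a generic unit initial guess, confirming that the
criterion has a single relevant basin. Inside the objective the linear
system is propagated by its closed-form eigen-solution (exact up to
floating point); the public `simulate_plasma()` integrates the same ODEs
with `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`, restarted at the
absorption-window edges where the input is discontinuous. The two routes
agree to ~1e-8 relative, and `simulate_plasma()` is itself cross-checked in
the tests against an independent matrix-exponential solution.

## 2. Effect compartment and Hill law

The brain ("effect") compartment receives drug from plasma one-way:

$$\dot c_3 = \frac{k_{31}}{V_3}\,c_1(t) - \frac{k_{e3}}{V_3}\,c_3, \qquad
  c_3(0) = 0,$$

followed by a pure transport delay $T$ (min),
$c_{3,delay}(t) = c_3(t - T)$, and the Hill law

$$D = D_0 + D_{max}\,
  \frac{c_{3,delay}^{\,N}}{D_{c50}^{\,N} + c_{3,delay}^{\,N}}.$$

$D \in [D_0, D_0 + D_{max}) \subset (0, 1]$ is the dimensionless
dopaminergic input handed to the network: the basal term $D_0$ stands for
endogenous dopamine, the saturating term for the levodopa effect. $D_{c50}$
(µg/ml) is the half-maximum effect-compartment concentration and the Hill
coefficient $N \ge 1$ (integer, as reported clinically) sets the steepness:
the slope at $D_{c50}$ is $N D_{max} / (4 D_{c50})$, so a subject with
$N = 8$ switches between full effect and baseline over a narrow
concentration band — the kinetic signature of wearing-off.

*The $k_{31}/V_3$ convention.* Only the ratios $k_{31}/V_3$ and
$k_{e3}/V_3$ enter the equations, and the solution is proportional to
$k_{31}/V_3$:

$$c_3(t) = \frac{k_{31}}{V_3}\int_0^t c_1(\tau)\,
  e^{-\frac{k_{e3}}{V_3}(t-\tau)}\,d\tau .$$

Rescaling $k_{31}/V_3$ and $D_{c50}$ by the same factor therefore leaves
$D(t)$ unchanged (the package tests verify this to 1e-10), so the value of
$k_{31}/V_3$ is a pure unit convention for the $c_3$/$D_{c50}$ scale. The
package fixes $k_{31}/V_3 = 0.01\ \mathrm{min^{-1}}$ for all subjects.
This specific convention is chosen so that the effect-compartment gain
$k_{31}/k_{e3}$ is of order one for the removal rates measured in the
levodopa test ($k_{e3}/V_3 \in [0.01, 0.035]\ \mathrm{min^{-1}}$): $c_3$
then lives on the same µg/ml scale as plasma, and the published per-subject
$D_{c50}$ values (0.03–0.38 µg/ml) fall inside the dynamic range of $c_3$
rather than far below it. A convention of 1.0 min⁻¹ would scale $c_3$
30–100× above the published $D_{c50}$ values and pin every subject at
saturation for the whole test.

*Numerics.* `simulate_effect()` uses an exact exponential integrator: on
each sampling interval the (linearly interpolated) plasma input gives a
closed-form update, so the solution is machine-precision accurate for the
interpolated input, unconditionally stable, and exactly linear in
$k_{31}/V_3$. The tests verify it against brute-force quadrature of the
convolution integral on randomised plasma traces (relative error < 1e-4,
limited by the oracle). The delay is a sample shift with linear
interpolation — it is a transport delay applied to an already-computed
signal, so no delay-differential solver is needed; values before the delay
has elapsed equal the drug-free initial state. Whether $T$ should be
restricted to the 15 min sampling grid is not constrained by anything in
the model; the implementation accepts any $T \ge 0$ and interpolates.

*Manual fitting, mechanised.* The effect parameters
$(k_{e3}/V_3, T, D_0, D_{max}, D_{c50}, N)$ are classically tuned by hand
because clinical tapping series contain gross outliers that derail
gradient-free optimisers. `grid_fit_effect()` mechanises that manual search
as an exhaustive, deterministic grid evaluation which returns the *full
ranked loss surface* rather than a single point estimate — near-equivalent
parameter combinations (which genuinely exist; e.g. $D_{c50}$ trades off
against $k_{31}/V_3$ exactly, and partially against $N$) remain visible.
An optional Huber loss makes the ranking robust to isolated outliers; the
tests demonstrate a corrupted sample that inflates the squared loss but
leaves the Huber ranking unchanged. The module makes no identifiability
claim.

## 3. The basal ganglia network

The network has two segregated action channels — tap down (channel 1),
lift-and-shift (channel 2) — through cortex (C), striatal Go (G) and NoGo
(N) populations, external pallidum (E), internal pallidum / substantia
nigra reticulata (I), and thalamus (T), plus a shared subthalamic unit
(STN) and a shared tonically active striatal cholinergic interneuron (H).
Every unit is a firing-rate neuron: first-order low-pass dynamics
$\tau \dot z = -z + \varphi(u)$ of the logistic activation
$\varphi(u) = 1/(1+e^{-a(u-u_0)})$, activity normalised to $[0, 1]$.
The constants are $\tau = 24$ ms, $\tau_L = 120$ ms, $a = 4$, $u_0 = 1$,
$\vartheta_G = 0.3$, $I^E = 1$, $I^I = 3$, $I^H = 1.25$, $\alpha = 1$,
$\beta = -1$, $\gamma = -1$, $\sigma = 0.1$
(`bg_params()`), and the connection weights (`bg_weights()`) are:
cortical lateral inhibition $l_{ij} = -1.2$; cortex ← sensory 1.1 (diag) /
0.2 (cross); cortex ← thalamus 4; Go ← cortex 0.48; Go ← sensory 0.9;
NoGo ← cortex 1.08; NoGo ← sensory 0.1; GPe ← NoGo −2.2; GPi ← GPe −3;
GPi ← Go −12; thalamus ← cortex 3; thalamus ← GPi −3; GPe ← STN +1;
GPi ← STN +14; hyperdirect conflict gain $k^E = 7$; STN ← GPe −1 per
channel; Go ← ChI −1; NoGo ← ChI +1. The net inputs are exactly the sums
implied by this wiring (see `step_network()` for the reference
implementation); the sign pattern is enforced by the weight validator.

Dopamine enters three ways: a contrast-enhancing term on Go
($+\alpha D$ for the stimulus-preferred channel, $-\alpha D$ otherwise —
see below), uniform inhibition $\beta D$ of NoGo, and inhibition
$\gamma D$ of the cholinergic interneuron, which in turn inhibits Go and
excites NoGo. Because the interneuron is active at rest and silenced by
dopamine, the dopaminergic and cholinergic actions are synergistic: at low
$D$ the interneuron adds a second, indirect bias toward NoGo. Clamping the
interneuron to zero (`clamp_H = TRUE`) removes most of the spread of
selection times across dopamine levels — the ablation test in the suite —
so dopamine *per se* is insufficient without the cholinergic potentiation.

Hebbian plasticity thresholds ($\vartheta_{PRE} = \vartheta_{POST} = 0.5$)
are carried in `bg_params()` for completeness but no plasticity update is
executed: tapping trials probe tonic dopamine only, and the trial durations
(seconds) are short against learning time scales.

### 3.1 Reconstruction choices

The published description of this architecture specifies the component
contracts — sigmoid static nonlinearity, first-order dynamics, the wiring
diagram and the constants above — but not every equation-level detail. The
package had to fix three such details, and each was decided by a behavioural
constraint that the alternate-tapping task itself imposes. Around forty
structural variants were simulated during development; the three choices
below are the only configuration found that yields (i) selection at
physiological speed at healthy dopamine, (ii) termination of the previous
action on stimulus reversal, and (iii) a monotone, saturating
dopamine-to-frequency curve with severe slowing at parkinsonian dopamine.

**Contrast-enhancement gate.** Dopamine must "excite only Go neurons with
high excitation". Gating the sign of $\alpha D$ on the Go unit's *output
activity* is bistable in both directions: a silent Go unit keeps
$-\alpha D$ and can never start (tapping never begins), and an active one
keeps $+\alpha D$ and can never stop (the first action never terminates).
Gating on the *sensory-related drive* $w^{GS} S_i$ versus $\vartheta_G$
resolves both: the stimulus decides which channel's Go population dopamine
boosts, and reversal withdraws the boost from the old winner. This reading
also matches the functional purpose — contrast enhancement between the
stimulus-preferred action and its rivals.

**Hyperdirect conflict signal.** A subthalamic drive proportional to total
cortical activity ($k^E \sum_i C_i$ with $k^E = 7$, $w^{ISTN} = 14$) would
clamp both GPi units at saturation whenever any action is active — nothing
could ever be selected. The STN is driven instead by the stimulus–cortex
*mismatch* $\sum_{i \ne j} S_i C_j$: zero at rest and during a settled
selection, large exactly when the stimulus demands one action while the
cortex still executes the other, i.e. at each reversal of the tapping
cycle. This is the "stop signal under response conflict" role of the
hyperdirect pathway, and with the printed gains it briefly closes both
pallidal gates at every reversal.

**The slow time constant.** The model has two time constants, 24 and
120 ms. Attaching $\tau_L$ to a low-pass on the lateral-inhibition term
makes the handover pace independent of dopamine (a flat curve at
≈ 1.3 Hz); attaching it to striatal or cortical membranes caps the healthy
tapping rate at similar values. The package attaches it to the *release*
of the subthalamic stop signal: STN activity rises with the fast constant
(the stop is prompt) and decays with $\tau_L$ (the stop lingers). The
reopening of the pallidal gate then becomes a race between the decaying
stop ($w^{ISTN}\,\mathrm{STN}(t)$) and the dopamine-dependent direct
pathway ($|w^{IG}|\,G$): strong Go activity at high $D$ overcomes the stop
almost immediately, weak Go activity at low $D$ waits several hundred
milliseconds — which is precisely the bradykinetic slowing the task
measures. The other two assignments leave no mechanism by which dopamine
could modulate the cycle period appreciably.

### 3.2 The tapping protocol

A trial starts from the settled resting state (1000 ms under no stimulus),
then presents $S = (1, 0)$: *intend the tap*. When a cortical activity
crosses the action threshold the action is considered initiated; after a
100 ms physiological dead time (movement initiation, detection and
re-afference) the stimulus is reversed, and the network — whose state is
*not* reset — selects the opposite action. The published frequency counts
and the 173 taps/min ↔ 2.89 Hz equivalence fix the convention that
frequency counts tap-down (channel 1) events: `frequency_hz` is the
reciprocal mean channel-1 cycle duration after discarding the first
(transient) cycle, and `frequency_tpm` is exactly 60× that. If fewer than
one steady cycle completes within the trial the movement is blocked and the
frequency is zero — the model's account of severe akinesia, reached below
$D \approx 0.1$.

**Action threshold calibration.** The threshold is the single free protocol
constant ("close to the maximum" cortical activity). It was calibrated
once, by sweeping 0.78–0.97 against the two published anchors —
2.89 Hz at $D = 0.55$ and 1.00 Hz at $D = 0.22$ — with everything else at
its table value. The joint anchor error is nearly flat across the sweep
(the $D = 0.22$ frequency stays within ±0.1 Hz of 1.00 throughout; the
$D = 0.55$ frequency varies by only 0.2 Hz), so the default was fixed at
0.85, which minimises the joint error on the plateau while remaining
"close to the maximum", and the same value is used at every dopamine level
thereafter. No other constant was touched during calibration.

### 3.3 Residual discrepancy with the published anchors

With the reconstruction above, the model reproduces the parkinsonian
anchor (1.07 Hz at $D = 0.22$, within the ±0.1 Hz band of the published
1.00 Hz) and the published parkinsonian frequency band (1.0–1.3 Hz across
$D \in [0.2, 0.3]$, inside the stated 1–2 Hz), with the correct monotone,
saturating curve shape. It does **not** reach the published healthy-end
values: the simulated plateau is ≈ 1.6 Hz at $D \in [0.4, 0.55]$ versus
the published ≈ 3 Hz (2.89 Hz at $D = 0.55$), and the corresponding
acceptance assertions are left failing rather than loosened.

The shortfall is structural, not a tuning miss. A 2.89 Hz alternation with
two 100 ms dead times leaves 73 ms of network time per half-cycle. In the
reconstructed network a handover traverses, serially, the collapse of the
old winner (Go flip → GPi reopening → thalamic withdrawal → cortical
decay) and the ignition of the new one (gate opening → thalamo-cortical
bootstrap → threshold tail) — about eight first-order stages at
$\tau = 24$ ms, with the printed weights giving a floor of ≈ 200 ms per
half-cycle regardless of threshold. Meanwhile the maximal dopamine-induced
spread of the stop-release race is
$\tau_L \ln\big[(|w^{IG}| G(0.55) - I^I + \ldots)/(|w^{IG}| G(0.22) - I^I +
\ldots)\big] \approx 175$ ms, versus the ≈ 327 ms the two anchors jointly
imply. Within the printed constants and any equation form tried, the
healthy-end cycle cannot be compressed to 346 ms; the published
implementation evidently achieves a more parallel handover than the
component contracts alone determine. The package documents this honestly:
the parkinsonian anchor, the band bounds and all curve-shape properties
pass; the two healthy-end magnitudes fail at their stated tolerances.

### 3.4 Numerics and noise

Integration is explicit Euler at $dt = 1$ ms ($\tau/dt = 24$, comfortably
stable); threshold crossings are located by linear interpolation between
steps. The settled state is step-size independent (halving $dt$ moves it
by < 1e-3, a suite invariant), and cycle durations are stationary to the
millisecond after the first cycle. The compiled core (Rcpp) advances
exactly the same equations as the exported pure-R `step_network()`; the
two are cross-checked step-for-step (< 1e-12) in the tests. Activities are
clamped to $[0, 1]$ after each step; with zero noise the clamp never binds
(the sigmoid already maps into $(0,1)$) but it guarantees the invariant
under injected noise.

The published noise amplitude $\sigma = 0.1$ is carried in `bg_params()`,
but the package default is `sigma_noise = 0`: the reported frequencies and
clinical replays are deterministic quantities, and noise is an opt-in
study (Gaussian input noise per unit per step, drawn from R's RNG, so
`set.seed()` gives bit-reproducible noisy runs).

## 4. Patient-level simulation and response metrics

`simulate_patient()` chains the three sub-models at the clinical sampling
times. Tapping at each sample is read from a precomputed
dopamine-to-frequency curve (40-point grid, each point an independent
12 s network simulation) by monotone linear interpolation; a direct
per-sample network run is available (`mode = "direct"`) and agrees within
the curve's grid resolution. The pre-dose baseline is the frequency at
$D = D_0$.

`response_metrics()` implements the clinical definitions: latency = first
time tapping rises ≥ 15% above baseline; the response ends at the first
later return below that band; duration = the difference; a patient is
*stable* if no return occurs within the 4 h window and *wearing-off*
otherwise. Replaying all six published parameter sets under a common
100 mg dose classifies the two unambiguous no-fluctuation subjects as
stable and all three fluctuating subjects as wearing-off; the third
group-1 subject — whose $D_{c50}$ and $k_{e3}/V_3$ sit between the groups,
i.e. a borderline case — is reported but not asserted either way.
Sensitivity sweeps confirm the expected kinetics: response duration
shrinks monotonically in $N$ and in $k_{e3}/V_3$.

## 5. Synthetic patients

`make_patient()` generates test-ready records with the clinical sampling
structure: plasma samples every 15 min to 90 min then every 30 min to 3 h,
tapping at the same times extended to 4 h. Archetypes draw from the
published parameter pools (stable: group 1 subjects 1–2; wearing-off:
group 2; borderline: group 1 subject 3), with a mild log-normal jitter
(CV 5%) on the plasma rate constants so records are not verbatim copies.
Measurement noise is multiplicative log-normal on plasma (assay-like,
default CV 5%) and additive Gaussian on taps/min (count-jitter-like,
default SD 5); neither noise model is calibrated to a real assay — the
published record does not characterise measurement error — so they should
be read as plausible magnitudes, not estimates. Identical seeds give
byte-identical records, and generation restores the caller's RNG state.

What passing tests on these records shows: that the pipeline recovers known
kinetic parameters through realistic sampling (noise-free recovery < 1%,
2% noise < 10% median), and that the stable/wearing-off classifier is
robust to the stated tapping noise (≥ 18/20 seeds). What it cannot show:
robustness to the gross outliers, dropouts, fatigue and learning effects of
real tapping series, or to model misspecification of the absorption phase
— real oral absorption is neither constant-rate nor single-window.

## 6. Problem sizes

The test suite and acceptance script use: 12–15 s tapping trials
(11–23 steady cycles per frequency estimate), a 31-point dopamine grid for
the shared curve fixture, 20 random plasma traces for the convolution
oracle, six noise-free plus twenty noisy plasma fits, and twenty seeded
synthetic patients for the classification-robustness study. These sizes
make every estimate stable to well inside its assertion tolerance; the
full suite runs in well under a minute on one core.

## 7. Known limitations

* Single oral dose, constant-rate absorption; no multi-dose regimens,
  saturable uptake or benserazide interaction.
* The network reconstruction underestimates healthy-end tapping rates
  (§3.3); relative and parkinsonian-range quantities are faithful.
* Two action channels; the state and weights are dimensioned per channel so
  more channels are possible, but nothing beyond two is tested.
* No synaptic plasticity, phasic dopamine events, dyskinesia or
  multi-action decision making; $D$ is a tonic input.
* The effect parameters are under-determined by a single tapping series
  (the loss surface is intentionally exported); no confidence intervals
  are claimed.
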