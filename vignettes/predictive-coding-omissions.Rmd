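---
title: "Predictive-coding circuits and omission-response analysis with peonr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-coding circuits and omission-response analysis with peonr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peonr` implements two connected pieces of machinery: a spiking
predictive-coding circuit that explains why some auditory-cortex neurons
fire when an expected tone is *omitted*, and the statistical pipeline that
identifies such probability encoding omission neurons (PEONs) in spike
recordings. This vignette documents the model, its parameters, the
numerical and design choices, what the synthetic-data generator does and
does not emulate, and the known limitations.

## The stimulus paradigm

All analyses revolve around oddball sequences of two pure tones (A and B)
with a fixed 5% rate of omissions (O), presented at a stimulus onset
asynchrony (SOA) of 150 ms. Conditions differ only in the A/B split:
`experiment_conditions()` returns the standard eight (Tone A at 95, 90, 85,
75, 50, 20, 10, 0 percent; Tone B filling the complement to 95%; 1,000
items each). Sequences are *count-exact*: each label occurs exactly
`round(prob * n_items)` times, in a seeded uniform random order, so every
1,000-item condition contains exactly 50 omission trials and the split-half
analysis always sees 25/25 halves. No constraint is placed on consecutive
omissions; none is needed by any analysis here, and the item order is fully
reproducible from the condition seed.

## The circuit model

Each of five frequency-tuned streams contains six leaky integrate-and-fire
neurons: a sensory input neuron (I), a prediction neuron (P), positive and
negative prediction-error neurons (PE+, PE−), and two inhibitory
interneurons (I+, I−). Membrane potentials follow

$$\tau_m \frac{dV}{dt} = -V + R_m\,(I_{exc} - I_{inh} + I_{pred} + I_{stim})$$

with $\tau_m = 30$ ms, $R_m = 1$ MΩ, a 10 mV spike threshold, reset to
0 mV, and a 2 ms refractory period. Synaptic currents rise instantaneously
by the synaptic weight on each delivered (delayed) presynaptic spike and
decay exponentially ($\tau_{exc} = 5$ ms, $\tau_{inh} = 20$ ms).

Within a module, I excites PE+ and the prediction suppresses it through
the I+ pathway; P excites PE− and the sensory input suppresses it through
the I− pathway. Sensory input is an analog 20 ms pulse
$I_{stim} = g \cdot 0.2\,\mu A$ at each trial onset, where the
receptive-field gain $g$ is 1 for the stream tuned to the tone (stream 2
for A, stream 4 for B), 0.5 for its neighbours, and 0 elsewhere. The
prediction input is a matching pulse $I_{pred} = P_{strength} \cdot
0.2\,\mu A$ delivered to P on *every* trial: the model assumes the temporal
profile of the prediction is learned elsewhere, and the circuit adjusts
only its gain. That gain, $P_{strength} \in [0, 1]$ per stream, is the
model's plastic variable: each PE+ spike adds 0.001, each PE− spike
subtracts 0.0003, with clipping at the bounds. Every simulation starts at
$P_{strength} = 0$ everywhere.

Streams interact through excitatory lateral synapses from PE+ of one
stream onto PE− of every other, with weight $1.2/(s_2-s_1)^2\,\mu A$ and
delay $5\,|s_2-s_1|$ ms. Two alternatives are provided for model
comparison: `lateral_i_to_pe` (same topology, but the sensory neuron I is
presynaptic) and `none` (no lateral synapses at all). With zero lateral
weight the lateral variant reproduces the no-lateral variant
spike-for-spike, which the test suite asserts as an identity check.

### Calibration of the intra-module synapse table

The six intra-module synaptic weights and delays are not dictated by the
circuit's published constants, so they ship as a calibrated default table
(`intra_synapse_table()`). Calibration targets the qualitative operating
regime that makes the module a predictive-coding unit, checked by
`calibrate_check()` on three-trial probe simulations:

1. an unexpected full-strength tone makes PE+ fire;
2. a fully established prediction silences PE+ via I+;
3. prediction input alone makes PE− fire when I is silent;
4. sensory input silences PE− via I− during tone delivery;
5. lateral excitatory weights at distance 1–2 (1.2 and 0.3 μA) exceed the
   intra-module inhibitory weight onto PE− (0.25 μA), so input from
   neighbouring streams can overcome local inhibition.

Two timing choices matter. The excitatory drives onto the error neurons are
delayed (I→PE+ by 3 ms, P→PE− by 6 ms) relative to the fast
interneuron pathways (0.5 ms), so inhibition arrives before excitation once
its driver is active. And the I+→PE+ weight is deliberately moderate
(0.15 μA): at intermediate prediction strengths suppression is incomplete,
leaving a small residual PE+ rate on expected tones. That residual is what
lets $P_{strength}$ settle into a *graded* equilibrium that increases with
tone probability — with complete suppression the prediction gain would
hover just above the firing threshold of P in every condition and omission
responses would carry almost no probability information.

### Numerical scheme

The whole network is integrated with forward Euler at a uniform
$dt = 0.1$ ms (membrane potentials, synaptic decays, and the
$P_{strength}$ updates). A spike is emitted when $V$ exceeds threshold at
the end of a step; deliveries are scheduled in whole steps of the synaptic
delay. The integrator is validated against the closed-form
constant-current LIF solution
$t^\* = -\tau_m \ln(1 - V_{th}/(R_m I))$ (agreement within one step) and
against a step-halving check: at $dt = 0.05$ ms trial-averaged PE− counts
change by about 1%, well under the 5% bound the tests assert. The model
itself is deterministic; all randomness lives in the stimulus sequence.

Per-spike impulse semantics are used throughout: each delivered spike
increments its synaptic current by the full weight $w$, and each PE±
spike changes $P_{strength}$ by its full step (0.001/0.0003). Under a
rate-times-dt reading the prediction gain could not plateau within a 75 s
sequence, so the impulse reading is the only one consistent with the
intended dynamics.

### Model evaluation

`probability_sweep()` runs one fresh 500-item simulation per Prob(A) value
(omissions fixed at 5%), recording the Stream-2 PE− count for every trial.
The default 5%-step grid (20 conditions) pools 500 omission trials and
4,750 trials per tone. `sweep_correlations()` reports trial-level Spearman
correlations per label (Pearson alongside, for reference; Spearman is
primary for all three labels for internal consistency). Steady prediction
strengths are trace means over the final two thirds of the simulation
(25–75 s at 500 items); the stream-2/stream-1 contrast is
$10 \log_{10}(P_2/P_1)$ dB with non-positive values floored at machine
epsilon and flagged, and the network's prediction "energy" is the plain
mean across streams. At Prob(A) = 0 no stream is ever driven, both models
have zero steady prediction, and the contrast is a floored 0/0 — benefit
comparisons therefore exclude that degenerate grid point.
`adaptation_sweep()` rescales the sensory gains by
$S_A = (1-b)e^{-p_A/a} + b$ (and symmetrically for B) over the standard
12 combinations of $a \in \{0.01, 0.05, 0.1, 0.5\}$ and
$b \in \{0.1, 0.3, 0.5\}$; the decaying-exponential form is adopted
because adaptation must weaken the drive of a frequently presented tone
and level off at the base firing factor $b$.

## The analysis pipeline

The omission response of a neuron at an expected-onset time $t$ is the
firing rate in $[t+5, t+120)$ ms minus the local baseline rate in
$[t-24, t+5)$ ms — a per-trial, baseline-corrected quantity in spikes/s
that is near zero for an unresponsive neuron. Tone responses use the same
two windows at tone onsets so the two are directly comparable. All windows
are half-open in milliseconds.

Classification is split-half to avoid double dipping. Within each
condition the 50 omission trials alternate into an odd-indexed training
set and an even-indexed testing set (25/25). On the training split a
neuron is a PEON if (1) the trial-level Spearman correlation between its
omission responses and the probability of its preferred (O_P) tone is
significant at $p < 0.05$ — the O_P tone being the tone with the positive
correlation — and (2) a one-sided Wilcoxon signed-rank test shows its
pooled omission responses are above zero in the four conditions where the
O_P tone is the standard (75–95%). Correlations are computed at the trial
level ($n = 200$ per split) rather than on the eight condition means:
condition-mean correlations of realistic size could never reach
significance at $n = 8$, so per-neuron tests must be trial-level.
Spearman p-values use the t approximation with average ranks for ties;
the Wilcoxon test uses the exact distribution for up to 25 non-zero
values and the continuity-corrected normal approximation above, with
zeros discarded.

Tone analyses subsample each condition's tone trials to 50 (every
$k$-th trial, $k = \lfloor n/50 \rfloor$) before split-matching, so
conditions with very different trial counts contribute equal power.
Buildup of the omission response over the sequence is summarized by
binning responses by sequence position (bin width 50 positions, a
configurable choice) and fitting the logistic
$FR(n) = a / (1 + e^{-b(n-c)})$ to the bin means; early tone adaptation is
fitted with $FR(n) = d + e\,e^{-fn}$ over the first 50 trials. Both use
Levenberg–Marquardt least squares with data-driven starting values, and
both recover noiseless curves to within 1% in the tests. Selectivity
indices are normalized differences, $TSI = (T_{OP} - T_{ONP})/(T_{OP} +
T_{ONP})$ and analogously OSI, invariant under uniform rate scaling.
Laminar and areal enrichment use a permutation bootstrap: each iteration
draws the observed number of PEONs without replacement and recounts per
group; two-sided p-values are twice the smaller tail, floored at
$1/n_{boot}$. Layers follow the depth bands 0–600 μm (supragranular),
600–900 μm (granular) and 900–1,400 μm (infragranular); labels are taken
as given metadata.

## The synthetic-data generator

`generate_recording()` draws each neuron as an inhomogeneous Poisson
process: a homogeneous 5 spikes/s background (urethane-anesthetized
cortex sits in the low single digits); on every tone event an additive
kernel in the 5–120 ms response window whose amplitude
$2.91 + 396.36\,e^{-2.25 n}$ (spikes/s, over presentation index $n$)
adapts rapidly onto a low plateau and is scaled by $1 - 0.5\,p$ for a tone
of probability $p$ (deviance structure); and, for planted PEONs, an
omission kernel with amplitude

$$25 \cdot \mathrm{Prob}(O_P)^2 \cdot \mathrm{logistic}(position;\ b = 0.012,\ c = 223.28)\ \text{spikes/s}.$$

The quadratic probability dependence concentrates omission responses in
the conditions where the preferred tone is the standard, which is what
gives planted *selective* and *non-selective* PEONs distinguishable
signatures; non-selective PEONs carry a second, 0.4-weighted kernel driven
by the non-preferred tone's probability, so they respond to either tone's
omission while still encoding Prob(O_P). The 25 spikes/s peak amplitude
is the generator's default signal level: against the ~15 spikes/s
single-trial noise of the response statistic at a 5 Hz background it
yields split-half detection sensitivity above 0.9, which is the regime
the planted-recovery tests certify. The logistic and exponential shape
parameters echo the fitted curves the pipeline is designed to recover, so
recovered fits are directly comparable.

Deliberate simplifications: Poisson spiking without refractoriness (exact
expectations for the calibration tests), flat response kernels by default
(an alpha shape is available), no cross-neuron correlations, no LFPs, and
layer/field labels drawn independently of response properties. Passing
tests on this generator certify the *pipeline* — estimator correctness,
calibration, and recovery power at the stated SNR — not the biological
fidelity of real recordings, which show non-Poisson variability, slow
state fluctuations (a sinusoidal baseline modulation option exists to
exercise the local-baseline correction), and correlated noise.

## Known limitations

* **The two-window response statistic has a skewed null.** The difference
  between a 115 ms window rate and a 29 ms baseline rate has mean zero but
  a left-skewed distribution for Poisson-like spiking (rare, large
  negative baseline excursions against frequent small positives), at any
  baseline rate. A one-sided signed-rank test against zero is therefore
  anticonservative — roughly 25–30% rejections at the 5% level with 100
  pooled null trials. In PEON classification this is mitigated by the
  correlation gate (criterion 1), and measured false-positive rates on
  null recordings stay below 5%. But in the selectivity classification the
  non-preferred-tone test inherits the bias, so genuinely selective
  neurons are overcalled "non-selective" and agreement with planted
  selectivity tops out near 0.8–0.85 rather than the ideal 0.9+. The
  pipeline implements the field's statistic faithfully rather than
  substituting a different test; treat selectivity labels as conservative
  in the "selective" direction.
* **Alternative-variant tone correlations are parameter-sensitive.** With
  the calibrated synapse table, the I→PE− variant reproduces the expected
  *signs* (positive Tone-A, negative Tone-B correlation) and its omission
  encoding, but the tone-correlation magnitudes depend on sub-threshold
  membrane carryover between trials and are much smaller here than under
  the original (unavailable) synaptic parameters.
* **Problem sizes.** The package's own checks run 20-condition sweeps of
  500-item sequences at dt = 0.1 ms and 200-neuron synthetic recordings;
  these sizes give stable correlations (the headline omission correlation
  varies by about ±0.02 across seeds) and tight calibration estimates
  while a full sweep completes in about a minute.
* The model does not learn the prediction's temporal profile, has no
  plasticity in the lateral weights, uses current-based synapses without
  noise, and makes no attempt to capture the gradual, prolonged temporal
  shape of real omission responses.

## Reproducibility

Every simulation and generator call is deterministic given its seed;
sweeps derive per-condition child seeds from one parent so module-level
reruns match pipeline runs. `reproduce_model_figures()` and
`reproduce_ephys_pipeline()` write their outputs with a manifest (package
version, seed, configuration hash) from which any result can be re-derived.
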