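---
title: "Methods: frequency-dependent electrical coupling and membrane resonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-dependent electrical coupling and membrane resonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gapres)
```

## The scientific problem

Electrically coupled neurons in rhythmic circuits — the pyloric dilator
(PD) pair of the crustacean stomatogastric ganglion is the canonical
case — show *subthreshold membrane resonance*: the voltage response to an
oscillatory input peaks at a non-zero frequency. The strength of their
gap-junctional coupling can itself be frequency dependent. This package
implements the computational machinery needed to study that interaction:

* ZAP (swept-sine chirp) stimulus construction and the measurement
  pipeline that turns dual recordings into impedance (`Z`),
  coupling-coefficient (`CC`) and coupling-conductance (`Gc`) frequency
  profiles with polynomial resonance fits;
* closed-form impedance theory for electrically coupled *linear
  resonator* cells;
* conductance-based (Hodgkin–Huxley style) single-compartment resonator
  cells and networks run under current clamp or ideal dual voltage
  clamp;
* ball-and-stick cable models quantifying space-clamp attenuation of
  the measured junctional conductance;
* a two-compartment bursting pair with an optionally resonant junction,
  used to ask how coupling resonance shapes burst synchrony;
* a synthetic-data generator providing dual recordings with known
  ground truth, so the whole pipeline is testable without biological
  data.

## The ZAP stimulus

The chirp is defined by its phase
$\varphi(t) = 2\pi f_{lo}\,(e^{Lt}-1)/L$ with sweep rate
$L = \log(f_{hi}/f_{lo})/t_{max}$, giving instantaneous frequency
$f(t) = f_{lo}e^{Lt}$ that runs exactly from $f_{lo}$ to $f_{hi}$ over
$t_{max}$. Defaults follow the experimental protocol: 0.1–4 Hz over
100 s, 3 nA half-range for current commands, and two lead-in sinusoid
cycles at the starting frequency that splice into the chirp with
continuous phase. Voltage commands (e.g. −60 to −30 mV from a −60 mV
hold) use `phase = "trough"` so the command starts at the holding
potential. A `sweep = "down"` variant reverses the frequency track; on
a linear system the measured profiles are unchanged, which the test
suite asserts.

```{r zap}
z <- zap_params(f_lo = 0.1, f_hi = 4, t_max = 100, amplitude = 3)
z
zap_frequency(z, c(0, 50, 100))
```

## Profile estimation: windows, not chirp-cropping

All profile quantities are magnitudes of ratios of discrete Fourier
transforms (`spectral_ratio()`): $Z_{pre} = \hat V_{pre}/\hat I_{pre}$,
$CC = \hat V_{post}/\hat V_{pre}$, $G_c = \hat I_{post}/\hat V_{pre}$,
evaluated on the DFT grid restricted to the swept band, after mean
removal. Bins where the denominator falls below $10^{-6}$ of its band
maximum are masked.

A design point worth making explicit: for a finite record of a linear
system, $\hat V(\omega) = Z(\omega)\hat I(\omega)$ holds *exactly* only
when the system state is equal at the two ends of the analysis window.
Cropping the analysis to the bare chirp segment leaves a state mismatch
(the record starts mid-oscillation at $f_{lo}$ and ends mid-oscillation
at $f_{hi}$) that shows up as a bias of a few percent at the weakly
driven top of the band. The simulation wrappers therefore embed every
protocol in a rest-to-rest envelope — a quiescent lead-in (default 5 s,
discarded only in the sense that the window starts after it), the
pre-cycles and chirp, a 0.5 s half-cosine ramp back to baseline, and a
10 s quiescent tail — and analyse the whole rest-to-rest window. For the
linear pair this makes the estimator exact to better than 0.1% across
the band; for the nonlinear cells the same envelope minimises boundary
transients. The `segment` argument of `spectral_ratio()` still allows
chirp-only analysis. For the same reason the default frequency-domain
smoothing is off: with exact windows a moving average only biases the
curved parts of a profile; `smooth_bw` (Hz) re-enables it for noisy
recordings.

Resonance summaries follow the field's convention: a sixth-degree
polynomial is least-squares fitted to amplitude versus frequency (in
Hz, linear grid, no regularisation), and the resonance frequency and
amplitude are the location and value of the fitted curve's global
maximum on the closed band, found through the real roots of the
derivative. A maximum at a band edge is flagged as "no interior
resonance". The fitted amplitude at the lowest band frequency (0.1 Hz,
the proxy for the zero-frequency value) supports normalised
comparisons (`normalize_profile()`).

One consequence, quantified by the synthetic-data module: the
polynomial peak is a *summary functional*, not the curve argmax. For
broad profiles (notably `CC`) the two can differ by ~10% even with
perfect data. Parameter-recovery experiments therefore score the
pipeline against the same functional applied to the exact closed-form
profile (`generate_experiment()` reports both this and the raw argmax),
so that recovery error measures noise and estimation, not the choice of
summary statistic.

## Linear resonator theory

The linear resonator is the standard two-variable model: a capacitive
voltage equation plus one slow restorative conductance,

$$C\dot V = -g_L V - g_1 w + I,\qquad \tau_1 \dot w = V - w,$$

whose impedance $Z(f) = [g_L + 2\pi i f C + g_1/(1 + 2\pi i f
\tau_1)]^{-1}$ is band-pass for suitable $g_1, \tau_1$. Units are nF,
µS, ms, mV, nA, so impedances come out in MΩ.
`linear_resonator_calibrate()` inverts the closed form numerically to
hit a requested (resonance frequency, peak impedance) pair; the package
default pair peaks at 15 MΩ at 0.8 and 1.2 Hz, matching the
"same maximal amplitude, distinct frequencies" configuration.

For two cells joined by an ohmic junction $G_c$, with current injected
into cell 1,

$$Z_{pre} = \frac{Z_2^{-1}+G_c}{(Z_1^{-1}+G_c)(Z_2^{-1}+G_c)-G_c^2},
\qquad Z_{post} = \frac{G_c}{(Z_1^{-1}+G_c)(Z_2^{-1}+G_c)-G_c^2},$$

and the coupling coefficient reduces to

$$CC(f) = \left\lVert \frac{G_c}{Z_2^{-1}(f)+G_c}\right\rVert,$$

which depends only on the *postjunctional* cell — the package asserts
this independence to $10^{-9}$ relative and also checks the closed
forms against adaptive-step ODE simulation. `resonance_vs_gc()`
reproduces the convergence of the pre/post resonances and the monotone
rise of the `CC` resonance with coupling strength;
`scaled_gc_cc()` evaluates the closed forms under a frequency-scaled
$G_c(f)$ to show how a resonant junction amplifies and retunes `CC`.

```{r linear}
p_lo <- linear_resonator(C = 2, gL = 0.06556, g1 = 0.01241, tau1 = 800)
p_hi <- linear_resonator(C = 2, gL = 0.06498, g1 = 0.04779, tau1 = 800)
rv <- resonance_vs_gc(p_lo, p_hi, c(0.005, 0.02, 0.1))
rv[, c("Gc", "f_Zpre", "f_Zpost", "f_CC")]
```

## Conductance-based cells and clamp experiments

Single-compartment cells carry Hodgkin–Huxley currents
$I = \bar g\,m^p h^q (V - E)$ with logistic steady states and one of
four time-constant forms (instantaneous, constant, self-referential
$a + b\,x_\infty(V)$, or sigmoid). `resonator_cell()` builds the
PD-type resonator (leak + slow inactivating Ca + hyperpolarization-
activated inward current; C = 2 nF) and its lower-frequency variant;
`follower_cell()` builds the free-running resonant follower used as a
third, unclamped neuron. Networks are integrated with fixed-step RK4
(default dt = 0.05 ms; a convergence test requires halving the step to
move voltages by < 0.01 mV). Voltage clamp is ideal: a clamped cell's
voltage follows its command algebraically and the clamp current is
reported as the residual of the current balance, a choice audited
sample-by-sample in the tests. Commands and stimuli are evaluated on
the integrator's half-step grid so the RK4 stages see exact values.

Two wrapped experiments mirror the modelling protocols:

* `coupled_zap_currentclamp()` — ZAP current into the prejunctional
  cell of a coupled pair (default $G_c$ = 20 nS), profiles for
  $Z_{pre}, Z_{post}, CC$ plus isolated $Z_1, Z_2$;
* `coupled_zap_voltageclamp()` — both cells clamped (ZAP command
  −60→−45 mV against a −60 mV hold), reporting $Z_{pre}$ and the
  coupling-current profile. With two clamped cells
  $I_{post} = G_c(V_{pre}-V_{post})$ is exactly proportional to the
  commanded difference, so the measured $G_c$ profile is flat and
  recovers the configured conductance to machine precision; adding a
  free resonant third cell coupled to both (default 20 nS each, the
  only conductance stated for the modelling work) makes the measured
  coupling current inherit that cell's resonance — the
  network-connectivity explanation for coupling-current resonance.

The text describing the three-cell experiment calls the third neuron
"identical" while the parameter table lists a distinct follower cell;
both configurations are supported (`third =` any `cell_spec`), and
either produces the interior coupling-current maximum.

## Ball-and-stick space-clamp controls

`ball_and_stick()` builds a 100 µm spherical soma plus a 1,000 µm
neurite in 101 compartments (R<sub>m</sub> = 10,000 Ω·cm²,
R<sub>a</sub> = 100 Ω·cm, C<sub>m</sub> = 1 µF/cm²), either a uniform
10 µm cylinder or a 20→0.5 µm linear taper. Axial conductances between
compartment midpoints use the frustum formula (exact for a linear
taper). Passive steady states come from a direct linear solve — a
voltage step measured at steady state needs no time stepping — and the
uniform cylinder's somatic-clamp profile matches the sealed-end
analytic solution $\cosh((L-x)/\lambda)/\cosh(L/\lambda)$ within 2%.

`apparent_gc()` places an ohmic junction (default 100 nS; results are
reported as attenuation ratios, so the value is immaterial to the
qualitative claims) at the same compartment index of two identical
cables, clamps both somas, steps one, and reports
$G_c^{app} = I_2/(V_1 - V_{hold})$. The apparent conductance falls
monotonically with junction distance for the uniform cylinder; the
taper attenuates markedly less at interior positions and more only at
the very tip. Placing the junction at mirrored indices of the two
identical cables is the only placement consistent with the stated
geometry and preserves the step-swap symmetry. The resonant variant
(`apparent_gc_profile()`) distributes the resonator channel densities
over every compartment (densities referenced to the point cell's area,
C/C<sub>m</sub> = 2×10⁻³ cm²) and confirms that space clamp adds little
frequency dependence (peak-to-flat ratio < 1.1 over the band); the
test uses 26 compartments and a 30 s sweep, which is sufficient
resolution for a smooth, sub-10% effect.

## The bursting pair and synchrony

Each bursting neuron has a soma/neurite compartment (leak + T-type Ca;
a slow calcium-spike oscillator) and an axon compartment (leak + Na +
K; fast spikes), joined by a 130 nS axial conductance, with Na activation
instantaneous. The
pair couples SN-to-SN. Integration is RK4 at dt = 0.01 ms for 25 s,
sampled at 1 kHz; both cells always start from identical initial
conditions.

Cell 2 differs from cell 1 by the printed gating-voltage shift
(b₁ = −0.0282679 mV inside the SN Ca gating functions) plus a
multiplicative scaling of the SN Ca time constants. The model's
parameter notes list scaling constants a₁ and c₁ without defining
where they enter the equations; this package realises the cell-2
difference as the b₁ shift plus a single τ-scale calibrated once by
simulation so that the isolated burst frequencies differ by 10%
(τ-scale = 1.167; c₁ = 1.125, if read as this factor, yields only
7.6%). a₁ and c₁ remain stored as inert fields.

Synchrony is measured the conventional way: sample at 1 kHz, Slow = 81 ms
centred moving average, Fast = Full − Slow, and $R^2$ = squared Pearson
correlation of each component pair over a 15 s window ending 1 s before
the simulation end. The network frequency is read from upward
midpoint-crossings of the Slow waveform.

The resonant junction model is the printed band-pass profile

$$G_c(f) = 2.625\,\bar G_c\,(e^{-0.1f} - e^{-5f}),$$

positive with a single interior maximum at $f = \ln(50)/4.9 \approx
0.80$ Hz. As printed, the peak value is ≈ 2.37 $\bar G_c$, which is
inconsistent with the accompanying claim that the factor 2.625 makes
$G_c = \bar G_c$ at the 0.75 Hz resonance; the package implements the
printed formula verbatim and offers `renormalize = TRUE` to divide by
the realised peak. The frequency dependence is applied
quasi-statically: `run_bursting_pair()` iterates simulate → measure
network frequency → set $G_c(f)$ until the frequency moves < 1%
(at most 5 simulations), reflecting the view of $G_c$ as a function of
the network rhythm rather than a temporal filter.

Network frequency is swept by scaling all SN time constants of *both*
cells by κ (`frequency_sweep()`); the default κ grid spans locked
frequencies of roughly 0.35–1.4 Hz. The methods only state that
intrinsic properties were modified, and uniform time-constant scaling
changes frequency with minimal waveform distortion. With the resonant
junction ($\bar G_c$ = 10 nS, placing the effective 20–24 nS coupling
on the steep part of the synchrony-versus-conductance curve), the
Slow-waveform $R^2$ is maximal at the network frequency closest to the
$G_c$ peak and lower at both band ends; with a constant junction the
Slow $R^2$ is flat across frequency and
increases monotonically with $\bar G_c$.

One conventional observation does not reproduce as a *stable* quantity
here: the Fast (spike-band) $R^2$. In a deterministic, phase-locked
pair the spike-level alignment within overlapping bursts is essentially
arbitrary and re-arranges discontinuously as κ changes, so Fast $R^2$
hops over values that are all small in absolute terms (below ~0.03)
without a frequency trend — consistent with the
qualitative statement that frequency does not organise spike synchrony,
but not with a "varies by less than 20% of its mean" reading, which the
test suite states honestly and which fails under these study
conditions. See the repository's test output for the exact numbers.

## Synthetic data and pipeline qualification

`synthetic_experiment()` describes a surrogate dual-recording
experiment: linear-resonator or conductance-based generator,
current-clamp or dual-voltage-clamp ZAP protocol (protocol constants as
above), additive Gaussian recording noise (defaults 0.2 mV / 0.02 nA —
plausible recording noise, chosen for the synthetic study only),
optional 0.01 Hz sinusoidal drift (off by default), and one integer
seed that governs all randomness. `generate_experiment()` returns the
four-channel trace plus ground truth; `recovery_suite()` runs
Monte-Carlo replicates across noise levels and reports bias and RMSE
of the recovered resonance frequencies and peaks. Under the default
conditions the pipeline recovers resonance frequencies well within 2%
noiseless and within 10% at 5%-of-amplitude noise (the shipped
recovery tests assert exactly these bounds).

What the generator does *not* emulate: spiking contamination (the
biological measurements were made with action potentials blocked),
electrode/series-resistance artefacts, slow nonstationarity beyond the
optional drift, and animal-to-animal variability. Passing recovery
tests therefore certify the measurement chain, not robustness to every
feature of real recordings.

## Numerical choices, in one place

* RK4 fixed step: 0.05 ms (networks), 0.01 ms (bursting pair; fast Na
  kinetics); convergence asserted by step-halving.
* Ideal clamp, no electrode model; clamp current = current-balance
  residual.
* Gates initialised at steady state for the initial voltage; protocols
  embedded in rest-to-rest envelopes (5 s lead-in, 10 s tail).
* DFT ratio on the rest-to-rest window; no taper, no smoothing by
  default; denominator floor 10⁻⁶ × band maximum; band restricted to
  the swept range.
* Degree-6 polynomial resonance fit on the linear-Hz grid; peak via
  derivative roots; ties toward the lower frequency; band-edge maxima
  flagged.
* Analytic peak search: 1000-point log grid plus golden-section
  refinement.
* Problem sizes used in the shipped tests: 20–100 s chirps, 25 s
  bursting runs, 5-point κ grids, 10-replicate recovery suites —
  chosen as the smallest sizes at which each qualitative claim is
  resolved cleanly.

## Known limitations

* The linear-resonator parameterisation is the canonical two-variable
  family; amplifying-current variants are not separately
  parameterised.
* Quasi-static $G_c(f)$ ignores any within-cycle junctional dynamics.
* The cable study is passive (plus the resonant-density variant); no
  morphological detail beyond one neurite.
* Experimental population statistics (animal means ± SD) concern
  unavailable recordings and are out of scope; the package emits
  per-trace summaries that such analyses could consume.
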