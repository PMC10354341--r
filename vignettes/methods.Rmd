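---
title: "Spectrum-shaping closed-loop neurostimulation: models, estimation and delay compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-shaping closed-loop neurostimulation: models, estimation and delay compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroloop)
```

This vignette is the package's account of the science it implements: the
closed-loop model and its assumptions, the magnitude-only identification
step, the delay compensation, the two simulated plants, and — importantly —
the numerical and design choices that were genuinely open, with the
reasons for the ones taken.

## The loop and its assumptions

The plant (brain plus stimulation and recording hardware) is modeled as

$$y(t) = y_0(t) + (g * u)(t),$$

where $y_0$ is stochastic resting activity and $g$ is the impulse response
of a linear time-invariant (LTI) system $G$. Everything downstream rests on
two assumptions: *additivity* (the stimulation response superposes on the
ongoing activity) and *small-signal linearity* of the response. Both are
exact for the linear plant and hold to better than 0.01% response-power
residual for the nonlinear cortico-thalamic plant at the default input
amplitude (see the superposition test in `test-brain-models.R`).

Closing the loop with $u = k * y$ gives $Y = Y_0 / (1 - G K)$ — note the
*positive* feedback convention. Prescribing a target filter $H$ with
$Y = (1 + H) Y_0$ and solving for the controller yields
$K = H / ((1 + H) G)$, implemented in `synthesize_controller()`. With the
exact plant model the realized closed-loop transfer equals $1 + H$ to
machine precision; every deviation in practice comes from model error,
discretization, or delay.

The default filter (`default_filter_bands()`) boosts the α band (10 Hz
natural frequency, 4 Hz width, weight $+1$) and suppresses the γ band
(40 Hz, 30 Hz width, weight $-0.5$), each band a unit-peak resonator
$c\,2\pi B s / (s^2 + 2\pi B s + (2\pi f)^2)$ whose response at its natural
frequency is exactly $c$. Weights in $(-1, \infty)$ keep $1 + H$ free of
right-half-plane zeros; the constructor does not assume this but the
synthesis checks the plant-side requirements it needs.

*A note on units:* band natural frequencies are plain frequencies in Hz;
the α and γ centers are 10 Hz and 40 Hz.

## Spectral conventions

All spectra are Welch averaged periodograms: Hann window, 1 s segments
(1 Hz bins), 50% overlap, one-sided power per bin so the bins sum to the
signal variance (`welch_psd()`). Band activities are inclusive sums of the
1 Hz bins inside 8–12 Hz (five bins) and 25–55 Hz (thirty-one bins).

Two distinct summary conventions coexist deliberately:

* **Band activity** — a *power* sum over the band's bins.
* **Mean amplitude / amplitude ratio (AR)** — an *amplitude* sum,
  $\sum_f \sqrt{S(f)}$ over all bins, with
  $\mathrm{AR} = \sum\sqrt{S_{yy}} / \sum\sqrt{S_{y_0y_0}}$.

The amplitude convention for AR is the one under which the three
calibration points of the estimation study (AR $\approx 4.5$, $2.4$,
$1.5$ at input standard deviations $0.0103$, $0.005$, $0.0025$) are
mutually consistent; the power-sum variant would place the default
protocol near AR 4.2 and is available as
`amplitude_ratio(..., type = "power")` for comparison, along with a
per-frequency variant.

## Magnitude-only model estimation

The identification step uses only what a pre-stimulus session provides: a
resting recording and a recording under known white-noise stimulation.
Because the response and the resting activity are independent, the squared
plant gain follows by spectral subtraction,

$$|\hat g(f)|^2 = \frac{S_{yy}(f) - S_{y_0y_0}(f)}{S_{uu}(f)},$$

restricted to 1–100 Hz (below 1 Hz the 1 s-segment Welch estimate carries
no information). Negative differences — pure estimator noise — are floored
at zero and counted (`extract_gain()`).

`magnitude_vector_fit()` then fits a stable minimum-phase rational
$\tilde G(s)$ to these samples. Since
$|G(i\omega)|^2 = G(s)G(-s)\big|_{s=i\omega}$ is a real rational function
of $X = \omega^2$, the fit runs classical iterative vector fitting
(barycentric least squares with pole relocation) in the variable $X$, and
the stable spectral factor is recovered by splitting the roots of the
fitted numerator and denominator of $R(-s^2)$ between the half planes.
Minimum phase plus positive gain is the canonical representative of the
magnitude data; it also reproduces the phase of minimum-phase targets,
which is what makes the fitted model usable for controller synthesis.

Choices that mattered, and why:

* **Structural DC zero (`dc_zero = TRUE`).** EEG/LFP observation chains are
  AC-coupled, and the linear plant has an exact transmission zero at
  $s = 0$ (equal input couplings within each population pair). The 1–3 Hz
  subtraction data sits below its own noise floor in every realization, so
  an unconstrained fit lets the low-frequency zero wander, which the
  relative error metric punishes brutally (factor-2+ inflation of the
  ensemble RMSE). Fitting $|g|^2 / \omega^2$ with a residue-sum-zero
  constraint pins the zero where the physics puts it.
* **Inverse-variance weighting.** The subtraction noise per bin scales as
  $\sqrt{S_{yy}^2 + S_{y_0y_0}^2} / S_{uu}$ (chi-squared spread of averaged
  periodograms); weighting rows by its reciprocal downweights the
  noise-dominated bins. A plain mean-square objective on the magnitude
  samples is available (`weighting = "amplitude"` or `"uniform"`).
* **Model order 4 by default.** The α/γ two-resonance problem is a
  fourth-order structure. Higher orders latch onto subtraction noise with
  spurious notches, and because the data residual is noise-floor dominated
  at every order, no automatic order selection can see the difference —
  the order is a modeling decision, not a tuning knob.
* **Robust relocation.** Two starts (resonances at the data's spectral
  peaks, and a log-spaced ladder), best-weighted-residual pole set across
  all iterations, and a final reflection of any right-half-plane roots
  (axis magnitude is invariant under reflection).

Accuracy is quantified as the relative complex RMSE
$100\sqrt{\langle|(\tilde G - G)/G|^2\rangle}$ over the fitting grid
(`relative_rmse()`), penalizing magnitude and phase alike. Fits whose pole
relocation has not settled are flagged, and the ensemble runner excludes
them from summary means while reporting their count — at the lowest
calibration amplitude roughly half the trials do not converge, which is
itself a finding about the protocol, not a failure of the ensemble.

## Delay compensation

Hardware and computation introduce a feedback delay $\tau$, modeled as an
integer number of 1 ms steps at the plant input. The compensator is the
one-pole/one-zero discrete stage

$$\Phi(z) = \frac{(2 - a)z - 1}{z - a}, \qquad |a| < 1,$$

which interpolates the ideal (non-causal) negative delay $z$ at $z_0 = 1$
in value and slope: $\Phi(1) = 1$, $\Phi'(1) = 1$. Its low-frequency group
delay is $-\Delta t$ — it anticipates its input by one step — and chaining
$d$ copies compensates $d$ steps. Because the chain's magnitude exceeds one
inside the control bands, each filter weight is divided by
$|\Phi_{\rm tot}|$ at the band's natural frequency before synthesis
(`rescale_filter_weights()`).

The pole $a$ trades prediction band against stability. `stability_map()`
reproduces the stable-region geometry (the admissible interval in $a$
shrinks as the delay grows; instability appears at the *lower* edge — as
$a \to 1$ the stage degenerates toward unity and the loop simply reverts
to the uncompensated delayed loop). `auto_predictor_pole()` picks $a$ by
grid search: among candidates that keep the assembled loop comfortably
stable *and* within 90% of the best achievable Nyquist margin at that
delay, it minimizes the summed relative α+γ activity error of the analytic
closed-loop spectrum — the same "match the targets without destabilizing"
principle used to tune the baselines. The stability gate adapts to the
loop's intrinsic pole floor (the $1 + H$ filter poles sit near $-0.11$ dB
at the default α bandwidth, so no controller can do better than that).

The Nyquist margin itself is the distance of the open loop
$L = G K \Phi^d z^{-d}$ to the critical point of the positive-feedback
loop ($+1$; equivalently the classical $-1$ after negating the return
ratio), evaluated on a 4096-point unit-circle grid from a state-space
realization of the chain — expanded polynomial coefficients lose several
digits beyond six delay steps, which is enough to scramble the
margin-versus-delay trend.

## Discretization and simulation

Plants are discretized by zero-order hold via the matrix exponential at
$\Delta t = 1$ ms; deployed controllers use the bilinear (Tustin) map
instead. The distinction is deliberate: ZOH is the physically correct
model of a sample-and-hold stimulation channel, but for the *controller*
its half-sample hold lag behaves like an extra 0.5 ms loop delay and
visibly distorts the realized γ-band shaping (measured suppression ratio
0.40 versus the intended 0.47); the bilinear map keeps the realized
response within the design tolerance.

Driving noise enters as independent per-step Gaussian sequences with
standard deviation $\kappa$ per channel at the 1 kHz reference rate, held
constant over each step — matching matrix-exponential stepping of the
noise-driven system. At other integration steps the per-step deviation is
scaled by $\sqrt{\Delta t_{\rm ref} / \Delta t}$ so the injected spectral
density (hence every band activity) is step-size invariant. Absolute PSD
levels depend on this convention; transfer-function ratios like the
spectral-subtraction estimate do not.

The first second of every closed-loop simulation is discarded before
spectral estimation (transient of the assembled loop; configurable).

## The two plants

**Linear two-population model.** Two excitatory/inhibitory pairs with
synaptic time constants 5/20 ms and interaction gains chosen so the pairs
resonate near 10 Hz and 34 Hz; stimulation couples into all four
populations, independent white noise drives the two excitatory ones, and
the output is the summed effective field potential. The healthy and
pathological regimes differ only in the noise variances (healthy: stronger
α-pair drive, weaker γ-pair drive). The model is AC-coupled by
construction — its DC response is exactly zero — which motivates the
fitter's structural zero. For this plant everything is analytic: transfer
function (`analytic_transfer()`), resting spectra
(`analytic_output_psd()`), and stationary covariances, which the
stochastic simulations are tested against.

**Cortico-thalamic stand-in.** The delayed nonlinear circuit is shipped as
a clearly labeled *synthetic stand-in* (registry
`inst/extdata/cortico_thalamic_standin.json`): seven populations —
superficial cortical pair, deep cortical pair, thalamic relay pair,
reticular population — coupled through `tanh` rate functions, with one
conduction delay (52 ms) on all cortico-thalamic fibers. The fast
superficial pair reuses the linear model's γ-pair gains; the delayed
cortex–relay–cortex loop produces the α resonance (loop gains tuned so the
equilibrium is linearly stable with the α peak at 10 Hz). Stimulation
enters the four cortical populations only; the observation reads the two
excitatory cortical populations. Healthy versus pathological is again a
noise-variance contrast, with the α channel injected at the thalamic relay
where the loop resonance amplifies it. Integration is classical RK4 with
the delayed state read from a ring buffer (linear interpolation at half
steps) and exogenous inputs entering every stage; with a held noise path,
halving the step changes band activities by less than 0.01%.

The reference curve for scoring fits to this plant is its *linearization
about the resting equilibrium evaluated as an exact delay system*,
$C(2\pi i f I - J_0 - J_d e^{-2\pi i f\tau})^{-1}B$ — an
infinite-dimensional response that a rational fit can only approximate, so
fit RMSEs on this plant are structurally larger (tens of percent) even
when the magnitude fit is good; the closed loop still shapes the bands
correctly, which is the point of the exercise.

## Baselines

The PI and LQG comparators track an explicit reference: an independent
pathological resting realization filtered by $1 + H$ (`make_reference()`),
so the reference carries the target band content but its own noise. Both
are wrapped in a Smith predictor (internal plant model plus a delayed
copy), which removes a known delay from the design loop exactly when the
model is exact — verified as an algebraic identity in the tests. The LQG
baseline is a proper servo: a Kalman filter on the plant, a second Kalman
filter on the generative model of the reference, and an LQR on the joint
system penalizing the tracking error — integral action alone cannot follow
an α/γ-band reference, and the AC-coupled plant makes pure integrators
wind up (both cores use a 0.5 Hz leaky integrator where relevant). Gains
are grid-searched to minimize the analytic tracking-error power subject to
closed-loop stability; a band-activity objective degenerates here because
the independent reference noise is minimized by switching the controller
off, which is not a tracking controller in any meaningful sense.

The qualitative outcome matches what one expects from the structure:
trackers follow the α band reasonably, cannot *suppress* γ (they would
have to anticorrelate with the plant's own γ noise, which tracking an
independent reference cannot do), and pay a much larger stimulation
amplitude — the spectrum-shaping controller needs no reference and
manipulates only what it can actually control.

## Problem sizes and determinism

The shipped tests and the acceptance script run the study conditions
directly: 30 s traces at 1 kHz and 50-trial ensembles (the compiled
kernels make a full 50-trial estimation study a matter of seconds).
Every stochastic path is seeded from a single master seed per run, one
stream per noise channel, so identical configurations reproduce bit
identical reports.

## Known limitations

* Single-input single-output only; no multi-electrode generalization.
* The cortico-thalamic parameters are a synthetic stand-in, not a
  transcription of any published parameter set; conclusions about that
  plant are qualitative (band directions, feasibility), not quantitative.
* Magnitude-only fitting cannot represent the plant's internal conduction
  delay; the minimum-phase surrogate underestimates phase lag at low
  frequencies when stimulating structures far from the recording site.
* The generator's noise is Gaussian, stationary and white per channel;
  real EEG has 1/f background, nonstationarity and artifacts, none of
  which the passing tests speak to.
* No plasticity or slow adaptation: the plant is assumed frozen over the
  session.
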