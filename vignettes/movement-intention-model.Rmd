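---
title: "A two-stage generative model of movement-intention EEG and its feature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage generative model of movement-intention EEG and its feature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieeg)
```

## The model

`mieeg` simulates the EEG signature of lower-limb movement intention as a
cascade of two stages, and then measures that signature with the standard
sensorimotor feature set (ERD/ERSP, MRCP).

**Primary processing.** Each small sensory assembly — one for the visual
(promoting) channel, one for interoceptive pain (preventing) — is a van der
Pol oscillator

$$\ddot Y - (\lambda - Y^2)\dot Y + p^2 Y = g\,F(t),$$

where $\lambda$ is the bifurcation parameter, $p$ the angular frequency and
$F$ the channel's external input with gain $g$. For $\lambda \le 0$ the
oscillation decays; for $\lambda > 0$ the assembly settles on a limit cycle
of amplitude $\approx 2\sqrt{\lambda}$ (exactly 2 at $\lambda = 1$, the
package default). We implement the amplitude law as $2\sqrt{\lambda}$: it is
the standard result of averaging analysis for this equation and is what
long, high-accuracy integration of the equation itself produces (at
$\lambda = 0.36$ the measured amplitude is $\approx 1.14$, close to
$2\sqrt{0.36} = 1.2$ once the first overtone is accounted for, and nowhere
near $2 \times 0.36$). The forcing enters additively on the acceleration
equation; the equation itself does not dictate a coupling form, and additive
forcing is the simplest choice that reproduces entrainment: with
same-frequency forcing the oscillator's phase converges to a fixed relation
with the input from any initial offset (an Adler-type phase pull whose rate
scales with $g\,F/(2 A p)$ — slow at 10 Hz over seconds, which is why the
entrainment test runs at 1 Hz over 20 periods).

**Advanced processing.** The entrained channel outputs are normalised to
unit RMS, scaled by salience weights, and combined as promote minus prevent,
$u_1 = u_{ev} - u_{ip}$. This drives a four-population neural mass model
(pyramidal cells, excitatory interneurons, slow and fast inhibitory
interneurons, with fast-inhibitory self-inhibition). Each population is a
critically damped second-order synapse $h(t) = G\,\omega\,t\,e^{-\omega t}$
fed through the zero-centred firing-rate sigmoid
$z(v) = 2e_0/(1+e^{-rv}) - e_0$. The simulated EEG is the pyramidal membrane
potential $v_1(t)$. Two formulation details are kept exactly as the model
family states them rather than "corrected": the external drive to the
excitatory interneurons enters as $z_2 + u_1/C_{12}$, and the auxiliary
input branch of the fast inhibitory population uses the excitatory kinetics
$G_2\omega_2$. Negative values of $z$ are meaningful (the sigmoid is centred
on zero) and are not clipped.

The RMS normalisation of the primary outputs is our own convention: nothing
links the oscillator's amplitude scale to the synaptic drive scale, so the
oscillators contribute *waveform and phase*, and the salience weights alone
set the drive magnitude.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\lambda$ | 1 | — | oscillator bifurcation parameter |
| $p$ | $2\pi\cdot 10$ | rad/s | oscillator frequency (alpha band) |
| $G_2, \omega_2$ | 3.25, 100 | mV, 1/s | excitatory kinetics |
| $G_3, \omega_3$ | 22, 50 | mV, 1/s | slow inhibitory kinetics |
| $G_4, \omega_4$ | 10, 500 | mV, 1/s | fast inhibitory kinetics |
| $C_{21}, C_{12}$ | 135, 108 | — | pyramidal/excitatory loop |
| $C_{31}=C_{13}$ | 33.75 | — | pyramidal/slow-inhibitory loop |
| $C_{41}, C_{14}$ | 40.5, 13.5 | — | pyramidal/fast-inhibitory loop |
| $C_{43}, C_{44}$ | 13.5, 13.5 | — | slow-to-fast inhibition, self-loop |
| $e_0, r$ | 2.5, 0.56 | 1/s, 1/mV | sigmoid saturation and steepness |

The connectivity and kinetic constants are the Wendling-family values for
this model class — the only physiologically grounded published set
consistent with the four-population topology; $e_0$ and $r$ are the values
stated for this application. All are overridable through `nmm_params()` or
the config file.

## The study conditions

The trial protocol is 5 sessions of 10 trials: 5 s stillness, up to 4 s
movement, 4.5 s rest, sampled at 1,000 Hz (a 10-trial session is then 135 s
long; the rest duration is a package default, chosen to complete that
timeline, not an experimental constant). Epochs run from 5 s before to 2 s
after movement onset, with −5 to −2 s as the resting baseline.

* **normal** — uniform random input on $[-0.5, 0.5]$ to both channels
  throughout; white Gaussian noise (mean 0, variance 5) to the fast
  inhibitory branch; no stimulus, no connectivity change. The condition is
  stationary, so its baseline-referenced features are noise-level by
  construction.
* **vr** — the same, plus a 10 Hz sinusoid of amplitude 0.5 superimposed on
  the visual channel from −2 s (the pre-movement intention window) onward,
  and the connectivity override $C_{12} \to 1.2\,C_{12}$ applied from the
  same moment.

Two of these choices were genuinely open and deserve their reasoning:

* **The override is evoked, not tonic.** ERD, ERSP and MRCP are all
  referenced to each condition's own baseline, so a connectivity change
  held for the whole trial cancels out of every feature in expectation.
  Induction-driven attention is an evoked process tied to the moment the
  virtual scenario engages the subject, so the override switches on at the
  stimulus onset. Mechanistically, raising $C_{12}$ by 20 % moves the model
  across a bifurcation that collapses its intrinsic ~8 Hz rhythm: post-onset
  alpha-band power drops by tens of dB relative to baseline, which is the
  ERD signature. The same switch, plus the stimulus-locked oscillation that
  survives trial averaging, deepens the negative low-frequency deflection
  that the MRCP statistic measures.
* **The stimulus rides on the visual channel only.** Induction is modelled
  as visual information; the pain channel is left untouched.

With these defaults the package's headline property holds: over 10 master
seeds of 30-trial ensembles, the vr condition gives a more negative ERD
peak, a more negative MRCP peak, and at least the normal condition's
detectability, in every seed (the acceptance suite recomputes this).

## The feature pipeline

Filtering is zero-phase (forward–backward Butterworth), so onset and
peak-time estimates carry no filter latency. The 0.1–10 Hz MRCP band is
numerically unstable as a direct order-4 band-pass design at 1,000 Hz; the
filter falls back to a high-pass/low-pass cascade of the same order when
the direct design has unstable poles.

The ERSP map uses Hanning-window STFT power on 1 s windows. Power is
averaged across trials *before* the dB conversion (the standard ERSP
convention); converting each trial separately would bias noise power by
$-10\gamma/\ln 10 \approx -2.5$ dB, the mean log of an exponential variate,
and the self-baseline property (baseline segment centred on 0 dB) would
fail. The hop defaults to 50 ms: a literal reading of "1 s windows with
200 ms overlap" gives an 800 ms hop, but onset statistics are reported at
millisecond granularity, so a finer hop is the usable default and both are
config keys. The ERD onset is the first in-band bin at or below −20 dB;
"not detected" is an explicit `NA`, never a silent zero. Onset estimates on
step-suppression fixtures are biased late by roughly $0.32 W$ for window
length $W$ (the point where the Hanning-weighted residual of the
pre-suppression signal falls below the −20 dB threshold); the recovery test
therefore uses a 0.2 s window with a 0.1 s hop, where the bias sits inside
one hop.

Epoch windows are half-open `[start, end)` and $t = 0$ maps to the onset
sample by the floor convention. The MRCP peak of an all-zero ensemble is
reported at the first sample of the search window (documented tie rule);
characteristic-frequency ties break toward the lowest frequency.

Artifact removal (EMD + ICA) is deliberately out of scope: simulated
signals are artifact-free, and real recordings should be cleaned before
entering the pipeline.

## Numerical choices

Both stages integrate with fixed-step RK4 at 1 ms (the recording sampling
interval), inputs held by zero-order hold within a step. The step guard
requires $\Delta t \cdot \max\omega \le 0.5$ (RK4's real-axis stability
reaches $\approx 2.78$, so the default $\Delta t\,\omega_4 = 0.5$ has a
wide margin), and both integrators abort with an error naming the step if
any state exceeds a magnitude bound — blow-ups are never silently clipped.
Against an adaptive reference integrator (lsoda at tolerance $10^{-10}$)
the trajectories agree to ~$10^{-5}$ relative RMS. The first 2 s of every
trial are burn-in and discarded before any feature computation. Every trial
is a pure function of `(config, master seed, trial index)`; per-trial seeds
are derived arithmetically from the master seed and stay below $2^{31}$.

## What the generator does and does not emulate

The synthetic ensembles reproduce the *mechanism-level* claims: stationary
background rhythms, entrainment of primary assemblies, evoked connectivity
change, and the resulting baseline-referenced ERD/MRCP contrasts between
conditions. They do not emulate volume conduction, inter-subject
variability, artifacts, electrode noise, or the amplitude calibration of
real recordings (the model output is in arbitrary units; real MRCPs are
5–30 µV). Passing tests therefore demonstrate internal consistency of the
model and pipeline and the direction of the induction effect — not that
real-subject effect sizes (e.g. onset times near −1.7 s or peaks near
−31 dB) are reproduced; those come from undeposited human recordings.

Problem sizes in the test and acceptance suites (30-trial ensembles, 10
master seeds, 1e6-sample variance checks) are the package's chosen
simulation scales: large enough that every directional claim is stable
across seeds, small enough to keep a full run on a laptop in well under a
minute per suite.

## Worked example

```{r example, eval = FALSE}
proto <- protocol_spec(n_sessions = 1, trials_per_session = 30)
ens_n <- generate_dataset(condition_spec("normal"), proto, seed = 1)
ens_v <- generate_dataset(condition_spec("vr"), proto, seed = 1)
ep_n <- epoch_signal(ens_n)
ep_v <- epoch_signal(ens_v)
feature_table(ep_n)
feature_table(ep_v)
```

## Known limitations

* Single channel (a Cz-equivalent); no scalp forward model.
* The vr condition's connectivity override is one global excitatory
  coupling change; the real induction effect is surely distributed.
* The detectability score is a linear discriminant, a deliberate
  placeholder for trained classifiers; the comparison surface accepts any
  fit/predict pair.
* No parameter fitting to real EEG; the model is generative only.
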