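# mieeg

Generative modelling and feature analysis of lower-limb movement-intention
EEG, for BCI and neurorehabilitation researchers who want a mechanistic,
fully reproducible testbed for pre-movement feature detection — in
particular for the question of whether virtual-reality (VR) induction makes
movement intention easier to detect from EEG.

## What it implements

**A two-stage generative model.** Small sensory assemblies (a visual
"promote" channel and a pain "prevent" channel) are van der Pol
oscillators,

    Y" − (λ − Y²) Y' + p² Y = g·F(t),

which entrain to same-frequency external input. Their outputs combine as
u₁ = u_ev − u_ip and drive a four-population neural mass model (pyramidal
cells, excitatory, slow- and fast-inhibitory interneurons with a
fast-inhibitory self-loop), each population a critically damped synapse
h(t) = G·ω·t·e^(−ωt) behind the zero-centred firing-rate sigmoid
z(v) = 2e₀/(1 + e^(−rv)) − e₀. The simulated EEG is the pyramidal membrane
potential v₁(t). The VR condition adds a 10 Hz stimulus on the visual
channel and an evoked connectivity change from the stimulus onset.

**The sensorimotor feature pipeline.** Zero-phase Butterworth filtering,
trial epoching around movement onset, Hanning-window STFT event-related
spectral perturbation (dB versus the −5..−2 s baseline), ERD onset
(−20 dB rule) and peak, characteristic frequencies of the α (8–13 Hz) and
β (14–25 Hz) bands, movement-related cortical potential (MRCP) extraction
(0.1–10 Hz), baseline power, and ERD = (E − E_b)/E_b × 100 %.

**Condition comparison.** Paired t-tests, moments and Shapiro–Wilk
normality, quantile–quantile pairing, confusion-matrix metrics
(sensitivity TP/(TP+FN), specificity TN/(TN+FP)), and a cross-validated
linear-discriminant detectability score for rest-versus-movement examples.

## Worked example

```r
library(mieeg)
proto <- protocol_spec(n_sessions = 1, trials_per_session = 30)
ens_n <- generate_dataset(condition_spec("normal"), proto, seed = 1)
ens_v <- generate_dataset(condition_spec("vr"),     proto, seed = 1)
ep_n <- epoch_signal(ens_n); ep_v <- epoch_signal(ens_v)
rbind(normal = feature_table(ep_n), vr = feature_table(ep_v))
```

```
       erd_onset_time erd_peak char_freq_alpha char_freq_beta alpha_peak_power
normal             NA   -1.678              11             18           -0.005
vr             -1.751  -30.198               9             23          -25.098
       beta_peak_power mrcp_peak mrcp_peak_time baseline_power
normal          -0.072    -0.951         -2.781          2.231
vr             -28.886    -0.991          0.612          2.207
```

The normal condition is stationary, so no ERD onset is detected (`NA`) and
its ERD peak (−1.7 dB) is baseline noise. Under VR induction the alpha
rhythm collapses from the stimulus onset: ERD is detected at −1.75 s with a
−30 dB peak, the MRCP peak deepens, and — as it should — the *baseline*
power is essentially unchanged between conditions (2.23 vs 2.21), because
induction acts only from the intention window onward. The rest-vs-movement
detectability score is at chance for the normal ensemble (0.57) and perfect
(1.00) for the VR ensemble:

```r
detectability_score(trial_band_features(ep_v, c(-4, -3)),
                    trial_band_features(ep_v, c(0, 1)), seed = 1)$accuracy
#> [1] 1
```

A command-line wrapper covers the same pipeline end to end:

```sh
Rscript inst/cli/mieeg-cli simulate --condition vr --sessions 1 --trials 10 --seed 3 --out out/vr
Rscript inst/cli/mieeg-cli run --seed 1 --out out/full
```

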