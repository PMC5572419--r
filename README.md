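# turnsig

Extracting the cranio-caudal signature of a 180° turn from wearable
orientation sensors.

Turning while walking is a demanding postural transition. Healthy adults
turn with a *cranio-caudal sequence*: the head rotates first, the trunk
follows, the pelvis last. This sequence is blunted ("en-bloc" turning) in
Parkinson's disease, in frail older adults and in recurrent fallers, which
makes its quantification clinically interesting — but it is normally
measured in camera-based motion laboratories. `turnsig` implements a
wearable-sensor alternative: head- and trunk-mounted attitude and heading
reference systems (AHRS) each output an orientation quaternion stream at
60 Hz, and the package turns those streams into a compact, physiologically
interpretable description of the turn.

## The model

For each trial the package computes the relative orientation of the head
in the trunk frame, `q_rel(t) = q_trunk*(t) ⊗ q_head(t)`, low-passes the
relative angle (zero-phase 4th-order Butterworth, 1.5 Hz default),
converts back to quaternion form and derives the relative angular velocity

```
ω = θ̇ û + û̇ sin θ + (û × û̇)(1 − cos θ)
```

whose axial (body-yaw) component `v(t)` is the velocity profile of the
head relative to the trunk. Following the Kinematic Theory of rapid human
movements, each neuromuscular command produces a lognormal velocity lobe,
and the turn is modelled as two opposing commands — the head moving away
from the trunk, then the trunk catching up:

```
v(t) ≅ D₁ Λ(t; t₀₁, μ₁, σ₁²) − D₂ Λ(t; t₀₂, μ₂, σ₂²),
Λ(t; t₀, μ, σ²) = 1 / (σ (t−t₀) √(2π)) · exp(−(ln(t−t₀) − μ)² / (2σ²))
```

with command amplitudes `D` (degrees), command times `t₀`, log time delays
`μ` and log response times `σ`. Parameters are estimated from the five
characteristic points of each lobe (onset, first inflection, peak, second
inflection, offset) via the closed-form inversion formulas, then polished
by Levenberg–Marquardt least squares. Derived metrics are
`t̄ = t₀ + e^(μ+σ²/2)` (system time delay), `s = (t̄−t₀)√(e^(σ²)−1)`
(response time) and `Vmax = D e^(−μ+σ²/2) / (σ√(2π))`. Reconstruction
quality is gated by `SNR = 10 log₁₀(∫v² / ∫(v−v̂)²) > 10 dB`. Alongside
the signature, the traditional turn metrics (step count from trunk
acceleration, mean/max trunk angular velocity) and test-retest statistics
(ICC(2,k) absolute agreement, SEM, paired Wilcoxon signed-rank for pace
robustness) are provided.

## Worked example

No public recordings of instrumented turns exist, so the package ships a
synthetic-trial generator with known ground truth:

```r
library(turnsig)

trial <- make_trial(sim_config(seed = 42))   # 60 Hz TUG turn, mild noise
row   <- extract_trial(trial)                # full pipeline, default config
row[, c("H2Tmax", "D1", "D2", "s1", "s2", "SNR", "NbSteps")]
#>   H2Tmax    D1    D2    s1   s2   SNR NbSteps
#> 1  23.93 31.45 31.25 0.31 0.23 27.28       4
```

`H2Tmax` is the peak head-to-trunk angle (degrees): this turner rotated
the head about 24° ahead of the trunk. `D1 ≈ D2` says the head-lead
command was matched by the trunk catch-up command, i.e. head and trunk
realigned by turn end. `s1`/`s2` are the response times (s) of the two
commands, `SNR` (27 dB, well above the 10 dB gate) says the two-lognormal
reconstruction fits the measured profile closely, and 4 steps were taken
during the turn. The fitted object itself follows broom conventions:

```r
fit <- row$fit[[1]]
glance(fit)        # snr_db, qc_pass, method ...
tidy(fit)          # one row per phase: D, t0, mu, sigma, tbar, s_resp, vmax
autoplot(fit)      # measured vs reconstructed profile with both lobes
```

Cohort-level robustness and reliability, as in a test-retest study:

```r
cohort  <- make_cohort(n_participants = 16, trials_per_condition = 2)
metrics <- dplyr::bind_rows(lapply(cohort, extract_trial))
velocity_effect_report(metrics)   # normal vs fast pace, Wilcoxon p per metric
reliability_report(metrics)       # ICC(2,4), 95% CI, SEM, category per metric
```

A command-line interface wrapping the same functions lives at
`system.file("cli", "turnsig.R", package = "turnsig")` with `extract`,
`simulate` and `reliability` subcommands.

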