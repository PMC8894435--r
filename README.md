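# brinleysim

Simulated multi-study Stroop data for evaluating Brinley plots and
multilevel models.

## The problem

Cognitive-aging research often asks whether older adults show a
*disproportionate* interference deficit — an Age × Trial Type interaction in
Stroop-type tasks — or whether apparent deficits are just general slowing.
The classic meta-analytic tool is the Brinley analysis: plot each study's
older-group mean RT against its younger-group mean RT, one point per
condition, and test whether one regression line or two are needed. This
package generates multi-study trial-level Stroop data whose structure is
known by construction, then analyzes the same data two ways, so the two
techniques can be judged against ground truth:

1. **Study-level Brinley mixed regression.** With trial type coded
   0 = congruent / 1 = incongruent,

   RT<sub>old,ij</sub> = β₀ + β₁·TT + β₂·RT<sub>young,ij</sub> +
   β₃·TT·RT<sub>young,ij</sub> + (b₀ᵢ + b₁ᵢ·RT<sub>young,ij</sub> + ε<sub>ij</sub>)

   fitted by full ML with per-study random intercept and slope; the full
   (with β₃) and restricted (without) models are compared by a 1-df Δχ²
   test. "Two lines necessary" (p < .05) is the Brinley evidence for a
   condition-specific age deficit.

2. **Trial-level three-level multilevel model.** Trials within participants
   within studies: `rt ~ age * trial_type + (1 | participant) + (1 | study)`,
   both factors 0/1-coded, so the fixed effects estimate the generative
   contrasts directly (interaction = the double difference).

Eight cases vary what is true in the data: a common interaction (A), an
exaggerated one (B), none (C), main effects only (D, E), all-null (F),
randomly varying interaction magnitudes (G), and interaction magnitudes that
grow systematically with a study's overall slowness (H). Trials follow an
AR(1) process (lag-1 correlation 0.60), and studies differ by random
grand-mean shifts (plus interaction-specific perturbations in G and H).
The package also renders the standard Brinley plot and a modified variant
that adds per-study segments linking the two condition means and an identity
reference line, which is what makes study-level interactions visible.

## Worked example

```r
library(brinleysim)
report <- run_case("A", seed = 42001)   # simulate -> aggregate -> fit -> compare
print(report)
```

```
Case A (seed 42001): All studies had same interaction
Delta chi-square = 3.807 on 1 df, p = 0.05103 -> restricted model preferred (one line sufficient)
Brinley verdict: one line sufficient; trial-level MLM interaction significant (p = 2.82e-242)
```

Every study in Case A was generated with a 50 ms Age × Trial Type
interaction, yet the Brinley model comparison says one line suffices, while
the trial-level model detects the interaction overwhelmingly. The restricted
fit shows why the Brinley picture looks so convincing:

```r
print(report$brinley_restricted)
```

```
Brinley mixed model (restricted, ML)
  term   predictor estimate       se      t          p
 beta0 (Intercept)   22.589 14.23337  1.587  1.125e-01
 beta1          tt   47.249  2.18734 21.601 1.758e-103
 beta2       young    1.036  0.02052 50.456  0.000e+00
  random effects: intercept var 182.74, slope var 0.0001, cov -0.08, residual var 15.17
  n = 100, df = 5, deviance = 694.99, AIC = 704.99, BIC = 718.02, marginal R2 = 0.989
```

A near-unit slope (β₂ = 1.04) explains 99% of the variance — the
between-study shifts move all points along one line, and the interaction
hides in the β₁ intercept offset. The modified plot's numeric summary shows
the interaction directly:

```r
geo <- segment_geometry(report$means)
mean(geo$slope)      # 1.51  (> 1: study-level interaction present)
mean(geo$elevation)  # 72.5  (ms above the no-age-difference line)
```

## The full analysis

`analysis/01_simulate.R` … `analysis/05_summary.R` regenerate the whole
study (all eight cases, both model families, all plots) into `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_brinley_models.R
Rscript analysis/03_trial_mlm.R
Rscript analysis/04_plots.R
Rscript analysis/05_summary.R
```

The summary table shows the headline result: of the four cases generated
*with* an interaction (A, B, G, H), the Brinley comparison detects it only
in Case H, where the interaction's magnitude varies systematically across
studies; the trial-level model detects it in all four, and correctly finds
nothing in C–F. See `vignettes/brinley-simulations.Rmd` for the generator's
assumptions, the disturbance calibration, and the numerical details of the
model comparison.

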