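# klkbarrier

Systems-level analysis of kallikrein-5 (KLK5) activity regulation in the
skin barrier, and of its dysregulation in atopic dermatitis (AD). The
package is aimed at computational biologists studying protease–inhibitor–
receptor feedback: it provides the ODE models, bifurcation machinery,
global sensitivity analysis and expression-data scoring needed to ask when
an external stimulus triggers a self-sustaining inflammation flare and why
AD skin flares at weaker stimuli than healthy skin.

## The model

Six species — LEKTI `L`, KLK5 `K`, active KLK5 `K*`, the inert complex
`C = L·K*`, PAR2 `P` and activated PAR2 `P*` (the inflammation level) —
interact through KLK5 self-activation, LEKTI capture of `K*`, and PAR2
cleavage by `K*`:

    dL/dt  = f_L(μ, P*) − k_on L K* + k_off C − δ_L L
    dK/dt  = f_K(μ, P*) − k_A K* K/(m_K + K) − δ_K K
    dK*/dt = k_A K* K/(m_K + K) − k_on L K* + k_off C − δ_K* K*
    dC/dt  = k_on L K* − k_off C − δ_C C
    dP/dt  = b_P − k_P K* P/(m_P + P) − δ_P P
    dP*/dt = k_P K* P/(m_P + P) − δ_P* P*

with production inputs `f_K = b_K + κ_K μ + α_K P*` and, for the LEKTI
feedback, either `f_L = ρ_L (b_L + κ_L μ + α_L P*)` (Model 1, positive) or
`f_L = ρ_L (b_L + κ_L μ) k_I/(k_I + α_L P*)` (Model 2, negative). The
external stimulus μ is the bifurcation parameter. Four presets contrast
healthy control (HC) with AD lesions of the system: limited LEKTI
production (`ρ_L = 0.5`) and/or pH 6.5 kinetics (faster activation, slower
complex dissociation).

The zero-inflammation state exists at every μ and loses stability at the
inflammation threshold `μ_on`; the inflamed branch persists down to the
deactivation threshold `μ_off < μ_on`. The hysteresis width
`Δμ = μ_on − μ_off` measures how persistent a flare is; if the inflamed
branch reaches μ = 0 the flare is irreversible. Steady states are
enumerated by multi-start Newton iteration and classified with the
Routh–Hurwitz criterion; eFAST variance decomposition ranks parameter
sensitivities of the steady-state inflammation level; and a bootstrap-PCA
"PAR2 score" turns a 13-probe inflammatory-gene expression panel into a
per-sample inflammation indicator that can be laid over the model's
bifurcation curves.

## Worked example

```r
library(klkbarrier)

p  <- klk_parameters("HC", variant = 1)         # nominal healthy skin
bd <- scan_mu(p, mu = seq(0, 60, length.out = 121))
glance(bd)
#>   pattern             mu_on mu_off delta_mu  n_mu max_states
#> 1 reversible_bistable  50.0   28.7     21.3   121          3
```

Healthy skin is reversibly bistable: inflammation ignites at `μ_on ≈ 50.0`,
persists until the stimulus falls below `μ_off ≈ 28.7`, and between the two
thresholds three steady states coexist (resting, saddle, inflamed). The AD
conditions flare at much weaker stimuli:

```r
glance(scan_mu(klk_parameters("AD-LEKTI", 1),    mu = seq(0, 60, length.out = 121)))
#> reversible_bistable    mu_on 20.0   mu_off 16.2
glance(scan_mu(klk_parameters("AD-pH", 1),       mu = seq(0, 60, length.out = 121)))
#> reversible_bistable    mu_on 25.0   mu_off  4.44
glance(scan_mu(klk_parameters("AD-LEKTI/pH", 1), mu = seq(0, 60, length.out = 121)))
#> irreversible_bistable  mu_on  8.29  mu_off NA     # flare never self-resolves
```

`autoplot(bd)` draws the bifurcation diagram;
`sweep_feedback_grid()` maps these patterns over the feedback-strength
plane, and `run_model_sensitivity()` ranks parameters by eFAST.

On the expression side, a synthetic cohort with known latent inflammation
validates the scoring chain end to end:

```r
cohort <- generate_cohort(seed = 1)              # 10 HC, 10 LAD, 8 NLAD
score  <- bootstrap_par2_score(cohort$data, B = 200, seed = 2)
glance(score)
#>   n_samples     B n_background hc_median lad_median
#> 1        28   200          200     -3.68       6.00
cor(score$scores$score, cohort$truth$latent, method = "spearman")
#> 0.983
score_gene_association(score$scores$score, cohort$data$x[, "SPINK5_probe"])
#>     rho sign
#>  -0.939 negative
```

The score recovers the latent inflammation level almost perfectly, healthy
controls centre well below lesional samples, and the LEKTI transcript
(*SPINK5*) anti-correlates with the score, as expected when inflamed skin
fails to produce its protease inhibitor.

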