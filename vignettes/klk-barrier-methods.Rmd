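---
title: "Feedback regulation of KLK5 activity in the skin barrier: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback regulation of KLK5 activity in the skin barrier: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological system and the model

Desquamation — the shedding of corneocytes at the skin surface — is driven
by the serine protease KLK5, whose activity must be kept in a narrow band:
too little and the cornified layer thickens, too much and the barrier is
degraded prematurely. Three mechanisms regulate extracellular KLK5 at the
granular/cornified interface: KLK5 self-activation by proteolysis, capture
of active KLK5 (KLK5\*) into an inert complex by the inhibitor LEKTI
(encoded by *SPINK5*), and cleavage-activation of the receptor PAR2 by
KLK5\*. Activated PAR2 (PAR2\*) drives inflammatory signalling, and the
package treats [PAR2\*] as the inflammation level. Atopic dermatitis (AD)
presents two measurable lesions of this system: roughly half-normal LEKTI
production, and an elevated skin pH (≈6.5 versus ≈4.5) that changes the
kinetics of KLK5 activation and of the LEKTI–KLK5\* interaction.

The package implements a six-species ODE model over
`(L, K, Kact, C, P, Pact)` — LEKTI, inactive KLK5, KLK5\*, the
LEKTI–KLK5\* complex, PAR2, PAR2\*:

* KLK5 self-activation `kA * Kact * K / (mK + K)` and PAR2 activation
  `kP * Kact * P / (mP + P)` are Michaelis–Menten in the substrate because
  both are bounded by substrate availability; the catalyst KLK5\* is not
  consumed.
* Reversible complexation `kon * L * Kact - koff * C` removes KLK5\*
  activity; the complex degrades at `deltaC`.
* Every species degrades first-order with its own rate.
* Production: `f_L` into LEKTI, `f_K` into KLK5, constant `bP` into PAR2.

The external stimulus `mu` (scratching, chemical irritation — summarised as
the basal drive on the system) enters through the production terms:

```
f_K(mu, Pact) = bK + kappaK * mu + alphaK * Pact
f_L(mu, Pact) = rhoL * (bL + kappaL * mu + alphaL * Pact)          (Model 1)
f_L(mu, Pact) = rhoL * (bL + kappaL * mu) * kI / (kI + alphaL * Pact)  (Model 2)
```

`alphaK` and `alphaL` are the feedback strengths from PAR2\* to KLK5 and
LEKTI production. Model 1 assumes the LEKTI feedback is positive (the
tissue produces more inhibitor while inflamed, buffering the flare);
Model 2 assumes it is negative (inflammation suppresses inhibitor
production, accelerating the flare). In Model 2 the feedback strength
`alphaL` multiplies PAR2\* inside a saturating inhibition with constant
`kI`, so `alphaL = 0` recovers the no-feedback limit and larger values give
stronger suppression; this keeps a single interpretable strength parameter
per feedback in both variants.

A consequence worth stating explicitly: the subspace `Kact = 0, C = 0` is
invariant, so a zero-inflammation steady state exists at every stimulus
level (`low_branch_state()` returns it in closed form). Inflammation
"outbreak" is the loss of stability of this branch, which happens when the
self-activation gain `kA * K / (mK + K)` exceeds the effective removal rate
of KLK5\*,

```
deltaKact + kon * L * deltaC / (koff + deltaC),
```

the second term being the rate of *permanent* capture: association times
the probability that a complex is degraded before it dissociates. This
expression explains every condition contrast in the package: halving LEKTI
production (AD-LEKTI) or weakening the capture channel at pH 6.5 lowers the
threshold stimulus `mu_on`, while the feedback strengths — which act only
through PAR2\*, zero on this branch — leave `mu_on` untouched and instead
control how far the inflamed branch extends to low stimulus (`mu_off`,
hence the hysteresis width `delta_mu = mu_on - mu_off`).

## Parameters

Rates are non-dimensionalised against the pH-4.5 LEKTI–KLK5\* kinetics;
`half_life_minutes()` anchors them to physical time through the calibration
that a degradation rate of 1 corresponds to a 15-minute half-life (so
`deltaK = 0.5` ↔ 30 min, `0.2` ↔ 75 min, and one time unit ≈ 21.6 min —
a documentation constant, never used in computation).

Defaults (see `klk_parameters()`): `kon = 1, koff = 1, kA = 10` at pH 4.5
versus `kon = 3, koff = 0.25, kA = 50` at pH 6.5; `deltaL = deltaC = 0.5`,
`deltaK = 1`, `deltaP = 0.5`; `rhoL = 1` (HC) or `0.5` (AD-LEKTI
conditions); `mK = 50`; `kI = 5`; `bP = 10`, `bL = 1`, `bK = 0`;
`kappaK = 0.5`; `kappaL = 0.05` (Model 1) or `0` (Model 2). Four equality
ties reflect explicit modelling assumptions and are re-applied unless the
tied name itself is overridden: `kP = kA`, `mP = mK` (KLK5 and PAR2 are
activated by the same protease, with no data to separate their kinetics)
and `deltaKact = deltaK`, `deltaPact = deltaP` (no data separating active
from inactive turnover). Two values deserve comment because they are
genuinely underdetermined:

* `koff` at pH 6.5 = 0.25. The direction (slower dissociation near neutral
  pH, where LEKTI–KLK5 complexes hold; acidic surface pH releases active
  KLK5) is established biochemistry; the magnitude was fixed at the value
  under which the threshold expression above reproduces the expected
  condition ordering — at 0.025 the stronger capture would outweigh the
  five-fold faster activation and the high-pH condition would never flare,
  which contradicts the AD phenotype the model exists to describe.
* `deltaC = 0.5` (equal to `deltaL`): the complex is LEKTI-bound and
  inert, so LEKTI-like turnover is the natural default; it is an explicit
  parameter for sensitivity exploration.

## Steady states and stability

`find_steady_states()` runs a damped Newton iteration with the analytic
Jacobian from a deterministic start set: the closed-form zero-activation
state, a saturated-activation heuristic, and a fixed log-spaced lattice of
12 starts (no RNG in the core scan, so scans are bit-reproducible by
construction). Newton is converged to `max|rhs| < 1e-12` — well below the
reported residual bound of `1e-9` — because near the transcritical point a
looser stop lets iterates stall on the slow manifold and masquerade as
extra roots; duplicates are merged at a relative tolerance of `1e-5`,
keeping the lowest-residual representative.

Stability is read from the Routh–Hurwitz criterion applied to the
characteristic polynomial (Faddeev–LeVerrier recursion, no eigensolve).
The Routh array implements both classical special cases: an all-zero row is
replaced by the derivative of the auxiliary polynomial (symmetric root
pairs; no sign change then means imaginary-axis roots, reported
`"marginal"`), and a zero pivot in a non-zero row uses an epsilon
substitution. Entries within `1e-9` of zero (relative to row scale) count
as zero. The largest eigenvalue real part is carried alongside as an
independent diagnostic, and the test suite checks verdict agreement on
1000 random matrices.

## Bifurcation scans and classification

`scan_mu()` enumerates steady states along a stimulus grid (default
`[0, 60]`; the upper bound must exceed the largest threshold of interest,
and the zero-feedback HC threshold sits near 50), warm-starting from the
previous grid point so branches are followed through folds.
`classify_pattern()` assigns one of four patterns — reversible bistability,
irreversible bistability (inflamed branch persists to zero stimulus),
continuous monostability, discontinuous monostability (a stimulus window
with no stable state; limit cycles are deliberately not sought there) —
and refines `mu_on` by bisection on the closed-form low branch's stability
and `mu_off` by bisection on inflamed-state existence, both to a relative
precision of `1e-4`, so threshold comparisons are grid-free. Diagrams that
fit none of the templates are labelled `unclassified` rather than forced:
in narrow slivers at the boundary between the monostable and bistable
regimes the model genuinely carries four coexisting states (the stable
continuation of the zero branch after a supercritical exchange, plus a
saddle-node pair), and the classifier reports rather than hides this.

`sweep_feedback_grid()` tiles `(alphaK, alphaL)` over the studied ranges
(`[0, 1]` and `[0, 0.5]` for Model 1, `[0, 10]` for Model 2; default 21×21)
and records pattern, thresholds and the maximum number of coexisting
states per cell. `production_curves()` and `total_klk5_curve()` re-express
branches on the axes used for data comparison: realized production rates
`f_K`, `f_L` against inflammation (the model-side analogue of *KLK5* and
*SPINK5* transcription versus the PAR2 score), and total KLK5-lineage
material `K + Kact + C` (what an ELISA against total KLK5 sees — higher on
the inflamed branch even though KLK5 *production* can be lower there).

## Global sensitivity (eFAST)

`run_model_sensitivity()` perturbs every positive-baseline parameter over
one order of magnitude, geometrically centred (`[b/√10, b√10]`, sampled
log-uniformly; a one-sided `[b, 10b]` switch exists). The output is the
steady-state PAR2\* reached by relaxation from an inflamed initial
condition. The upper attractor was chosen over the zero-branch attractor
after quantifying both: the zero-branch output is identically zero
wherever that branch is stable, so the output becomes a step function of
the parameters, and the resulting spectral leakage assigns first-order
sensitivity ~0.1 to a parameter that does not even enter Model 1 (`kI`) —
an order of magnitude above the inert-factor noise floor the estimator
should show. The inflamed level is continuous away from fold crossings,
restores that floor, and is the quantity whose pure scaling in `bP` and
strong dependence on `deltaPact` the analysis is meant to expose.

eFAST internals (`efast_design()`, `efast_indices()`): the factor of
interest rides the highest frequency allowed by the Nyquist condition
`n_per_curve ≥ 2·M·omega_max + 1`, the complementary set gets *distinct*
low frequencies below `omega_max / (2M)`, and indices average over two
random-phase resample curves. First-order indices sum spectral power at
the working frequency and its `M` harmonics; total-order indices subtract
the low-frequency (complementary) share. For the model runs `M = 2`: at
the 2000-evaluation budget with ~20 factors each curve has only ~47
samples, and truncating at two harmonics keeps the working frequency (and
the number of distinguishable complementary frequencies) high enough for
stable rankings; the analytic test functions use the conventional `M = 4`.
The baseline point places the feedback strengths mid-range (`alphaK = 0.5`,
`alphaL = 0.25` or `5`) and the stimulus at `mu = 20`, whose perturbation
interval `[6.3, 63]` straddles the outbreak thresholds of all four
conditions — a sensitivity analysis anchored far from the thresholds would
see none of the switching behaviour the model is about. Parameters with a
zero baseline (`bK`; `kappaL` in Model 2) cannot be perturbed
geometrically and are fixed.

## The PAR2 score

PAR2 activity is not directly measurable, but its downstream inflammatory
genes are. `bootstrap_par2_score()` summarises a fixed 13-probe panel
(ICAM1 ×3, IL8 ×2, TNFα, CSF2 ×2, IL1α ×2, IL1β ×2, CCL17; hgu133a probe
IDs in `default_panel()`) into one inflammation indicator per sample. Each
bootstrap repetition draws `n_background` non-panel probes without
replacement (with replacement would duplicate columns and degenerate the
PCA), joins the panel, runs PCA on the column-centred submatrix, picks the
component that best separates AD (lesional ∪ non-lesional) from HC by the
absolute Welch *t* statistic among the leading components (≥95% cumulative
variance, at most 10), orients it so AD scores higher, and projects
samples onto the panel-restricted weights. The score is the mean over `B`
repetitions; per-probe weight quartiles summarise the bootstrap
distribution. Defaults: `n_background = 200` (large enough for a stable
covariance, small enough that a `B = 200` desk run takes under a second)
and `B = 200` for tests with `B = 10000` the full-scale choice; the
resampling makes the axis robust to which background probes happen to
dominate any single PCA. The axis-selection statistic is a transparent
substitute for an unpublished selection rule, and both it and the search
depth are arguments. `scale_to_model()` centres scores on the HC median so
the healthy group sits at the model's zero-inflammation baseline;
`score_gene_association()` reports Spearman correlations (rank-based,
because the score is a projection with no calibrated scale).

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* the scoring stage assumes: a
one-dimensional latent inflammation level per sample — HC centred at 0
(scale 0.3), lesional AD at 2.5 (scale 0.7), non-lesional AD at 0.8 (scale
0.8), overlapping both neighbours, with desk-scale group sizes 10/10/8 —
linear probe loadings with homoscedastic Gaussian noise (sd 0.5), CCL17
carrying the largest panel loading, 2000 pure-noise background probes, and
three marker probes: *SPINK5* loading −0.8, *KLK7* +0.7, and *KLK5*
non-monotone (`0.3·z − 1.2·max(z − 1.5, 0)`: mildly rising at low
inflammation, suppressed above a threshold), so high-score samples show
low *KLK5* without a global negative correlation. Under this latent-linear
model the bootstrap-PCA score is a consistent estimator of the latent, so
recovery (rank correlation > 0.9 at `B = 200`) is a fair end-to-end check.
What the generator does *not* emulate: platform intensity distributions,
probe-level correlation structure within genes, batch effects, or the real
cohort's sample sizes — so passing tests demonstrate correctness of the
scoring machinery under its stated assumptions, not performance on
GSE5667-like data.

## Numerical choices, sizes and limitations

Integration uses `lsoda` with `atol = 1e-10`, `rtol = 1e-8` (steady-state
verification needs tight residuals). Test-suite and acceptance problem
sizes: 121-point stimulus grids for single scans, 21×21 feedback sweeps at
101 stimulus points, 11×11 per condition for the three-way comparison,
1000-matrix stability oracles, 2000-evaluation eFAST runs (the
qualitative driver-ranking checks use 6000 evaluations: at this factor
count the ranking of mid-tier parameters is not estimator-stable below
~140 samples per search curve, and a qualitative claim should be tested
where the estimator resolves it), `B = 200`
bootstrap scores — all chosen to characterise each result at desk scale.
Known limitations: no limit-cycle continuation (patterns are labelled from
steady-state structure alone), no KLK-family network beyond KLK5 (KLK7
appears only as a data column), pH only at its two preset levels, and the
four-state slivers noted above, which keep the "one to three steady
states" picture from being exact at the edge of the Model-1 feedback
range.
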