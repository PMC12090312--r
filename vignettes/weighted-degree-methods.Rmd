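---
title: "Weighted-degree connectome statistics: model, simulator and design choices"
author: "fndconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-degree connectome statistics: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fndconn)
```

## The analysis model

`fndconn` implements a case-control analysis of structural connectomes for
functional neurological disorder (FND) cohorts. Each subject contributes an
84 x 84 symmetric matrix over the Desikan-Killiany parcellation (68 cortical
+ 16 subcortical regions), weighted by mean fractional anisotropy (FA),
streamline count, or mean fiber length. The central statistic is the
**weighted degree** (node strength) of the FA-weighted graph,

$$\mathrm{WD}_i = \sum_{j \ne i} \mathrm{FA}_{ij},$$

an integrative summary of the microstructural integrity of all white matter
links originating in region $i$. Absent links (no streamlines reconstructed)
carry weight 0 and simply contribute nothing to the sum.

Group inference proceeds in three tiers:

1. **Node level.** For each region, WD is modelled by ordinary least squares
   as `WD ~ intercept + group + covariates` (patients coded 1). The group
   coefficient is tested with a Student $t$ on the residual degrees of
   freedom. Tests are *directional*: reduced and heightened integrity are
   probed as two separate one-sided families, each corrected on its own by
   Benjamini-Hochberg FDR at $q = 0.05$ across the 84 regions. Three fixed
   covariate models mirror the clinical reporting sequence: age + sex;
   age + sex + psychotropic medication; age + sex + BDI + STAI-T.
2. **Link level.** The same covariate-adjusted directional GLM is applied to
   every connection value (FA, streamline count, mean length). A link enters
   the tested family only if it is present (nonzero) in at least a threshold
   fraction (default 0.5) of the subjects of *each* group; FDR is computed
   over tested links only, and untested links are reported as absent rather
   than non-significant. Significant FA links are then restricted to those
   incident to the regions that showed WD group differences, producing a
   connectogram edge list and per-node altered-link counts out of the 83
   candidates per region.
3. **Brain-clinical correlation.** Weighted degree and each clinical
   variable (SF-36 subscales, BDI, STAI-S/T; plus illness duration, S-FMDRS
   and CGI for patients) are both residualized on the same covariates
   (age/sex, or age/sex/BDI/STAI-T), and their Pearson correlation is
   computed per region — i.e. a partial correlation, whose $p$-values use
   $n - 2 - k$ degrees of freedom for $k$ covariates. FDR is applied per
   clinical variable across the 84 regions, matching the per-variable
   sorted-$p$ curves such analyses report; a pooled family and Spearman
   correlation are available by configuration. Finally, significant
   correlations are filtered to the regions already showing group WD
   differences.

### Choices where the design was genuinely open

* **Covariates in the model, not residualize-then-test**, for the group
  comparisons: testing the group coefficient with covariates in the model
  uses the correct residual degrees of freedom. The residualization path
  exists separately in the correlation module, where adjusted *values* are
  the quantity of interest.
* **Directional families.** "Reduced" and "heightened" integrity are two
  independent one-sided FDR families rather than one two-sided family; a
  two-sided option remains available.
* **Pooled-variance $t$** throughout, as implied by OLS.
* **Medication** enters as a single any-psychotropic indicator; per-class
  covariates would demand cohort sizes these studies do not have.
* **Presence filtering** at link level defaults to 0.5 per group because FA
  is undefined on absent links; setting the threshold to 0 tests all 3486
  pairs.
* **BH-FDR** adjusted $p$-values are computed by `stats::p.adjust(method =
  "BH")`; the package's own brute-force step-up implementation serves as the
  independent oracle in the test suite, not as the production path.

## The synthetic cohort generator

Patient-level diffusion MRI data of this kind is shareable only on request,
so the package ships a generator whose defaults emulate the statistical
structure of a realistic FND case-control cohort: 85 patients vs 75
controls; demographic and clinical score moments per group matching the
published cohort table of the reference population (e.g. BDI 14.33 (9.96)
vs 4.41 (6.13); STAI-T 45.22 (12.92) vs 33.93 (7.13); age 37.55 (14.26) vs
33.13 (10.97); sex 63/22 vs 55/20 female/male).

The generative model, in order:

1. **Demographics and mood.** Age, BDI, STAI-T/S and the SF-36 subscales
   are drawn per group from *interval-censored* normals: a latent normal is
   clamped to the instrument range, leaving point masses at the floor and
   ceiling. This is how bounded questionnaires actually behave (healthy
   controls heap at BDI 0 and at SF-36 100), and it is the only way to
   reach moments such as BDI 4.41 (6.13) — no distribution shaped like a
   truncated normal on $[0, \infty)$ can have sd larger than its mean. The
   $(\mu, \sigma)$ of each latent are solved numerically so the
   post-censoring moments match the targets; one cohort moment (SF-36
   physical health, 30.59 (35.64)) exceeds what any clamped normal on
   $[0, 100]$ can reach and is matched as closely as possible (~26 sd).
2. **Connectomes.** A link-presence mask shared by all subjects is drawn at
   density 0.6. Per present link, FA is a truncated normal around 0.40
   (sd 0.08) plus per-subject shifts: $-0.001$ per year of age, $+0.005$
   for male sex, and the mood-to-brain arrows $-0.002$ per BDI point and
   $-0.001$ per STAI-T point. Because mood differs by group, these arrows
   make mood a true **mediator** (group → mood → FA): adjusting for BDI and
   STAI-T attenuates the marginal group effect, reproducing the qualitative
   "significant, then trend after mood adjustment" pattern. Values are
   clamped to $[0.01, 0.95]$. Streamline counts are over-dispersed negative
   binomials with mean proportional to FA; mean lengths are normal
   (60 mm, sd 15) on present links.
3. **Planted deficit.** Links incident to the 19 designated regions lose
   $\delta_i = d \cdot \mathrm{sd}(\mathrm{WD}_i)/k_i$ in patients
   ($k_i$ = incident present links; the sd combines link noise and the
   covariate shift variance in closed form), so the marginal standardized
   WD reduction at each planted region equals `node_effect_d` (default
   1.0). Links joining two planted regions take the mean of the two
   requirements. Unreachable effect sizes (FA would clamp) raise an error
   reporting the attainable maximum. Note a structural consequence: links
   of a planted region also contribute to its *neighbours'* WD, so strong
   planted effects produce genuine spillover at non-planted regions — the
   node-level sensitivity criteria are therefore about recovering the
   planted set, not about specificity against spillover.
4. **Clinical severity.** A latent severity axis is built from the
   **covariate-adjusted** WD of the coupled regions (default left precuneus
   + left superior parietal), standardized within group, and scaled by the
   realized inter-node correlation so that the per-region *partial*
   correlation (given age, sex, BDI, STAI-T) hits `clinical_coupling_r`
   (default $-0.5$). The adjusted scale is the right definition: raw WD is
   dominated by the mood-shared variance, and the correlation analysis that
   consumes these data adjusts for exactly those covariates. S-FMDRS is
   generated tobit-style — the latent scale is floor-censored at 0 so that
   the configured fraction (21/85) of patients scores 0. Zeros are thereby
   the *least severe* patients, which is what a score of "no motor
   symptoms" means clinically; location and scale are set so the censoring
   probability and the censored mean (8.54) match, which places the
   marginal sd at ~8.1, slightly under the 9.65 target. CGI is the same
   latent discretized to 0-7 around 2.69 (1.59); SF-36 physical
   functioning couples *positively* to the axis with group moments 64.24
   (25.12) vs 97.33 (6.06). Illness duration is log-normal (4.89 (6.08)
   years) and uncoupled by default. Medication probability follows a
   logistic in standardized BDI (mood-correlated, patients only) with no
   direct FA arrow.

Everything is reproducible: the same `(config, seed)` yields bit-identical
cohorts, and the emitted ground truth (planted regions, per-link deficits,
coupling coefficients, mediator slopes) supports recovery testing.

### What the simulator does *not* emulate

Real connectomes have spatially structured link weights, distance-dependent
presence, site and motion artefacts, correlated mood instruments, and
subject-specific masks; the generator uses a shared mask, independent link
noise and independent mood scores. Passing recovery tests therefore shows
that the *statistical machinery* behaves as claimed under the assumed
generative structure — not that the published cohort-specific counts (44 or
19 significant regions, 13/83 links, 71/37/5 correlated ROIs) would be
reproduced on clinical data, which this package does not ship.

## Numerical conventions

* Canonical node order is the packaged region table (left cortical, right
  cortical, left subcortical, right subcortical); links are enumerated
  row-major over the strict upper triangle (3486 pairs). Emitted tables
  always use region names, never bare indices.
* Asymmetric input matrices within $10^{-9}$ are symmetrized by averaging;
  beyond that they are rejected. FA tolerates $[0, 1 + 10^{-9}]$ and clamps
  to 1. Missing clinical values are empty fields on disk and `NA` in
  memory — never 0, which is a valid severity score.
* Weighted degrees computed by `rowSums` agree with a naive double loop to
  accumulation-order rounding (~$10^{-14}$); tests assert agreement at
  $10^{-12}$.
* A response fitted perfectly by the covariates (residual variance
  relatively below $10^{-20}$) returns $t = 0$, one-sided $p = 0.5$, rather
  than an unstable 0/0 ratio.
* BH ties share a rank and receive identical adjusted values; decisions are
  monotone in the input $p$-values.
* In degenerate subgroups the generator's severity axis drops constant
  covariates and falls back to centering when fewer subjects than
  covariates + 3 are available.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the statistical claims at the
sizes the claims are stated for: 500 null replicates for FDR calibration,
200 default-scenario replicates for recovery/attenuation (cohorts of
85 + 75), 1000 matrices / 10000 p-vectors / 1000 datasets for the oracle
equivalences, and one 10000-per-group cohort for generator moment and
coupling calibration. A full run of each driver script in `analysis/`
takes seconds; the complete test suite and the acceptance script each run
in about a minute.

## Known limitations

* The mood mediation at its default strength makes the *marginal* group
  effect near-global across regions (as the attenuation pattern requires);
  marginal discovery counts are therefore not comparable to published
  cohort counts and are not claimed to be.
* Partial-correlation $p$-values assume joint normality after adjustment;
  the Spearman option trades exactness for robustness.
* Link-level clinical correlations are out of scope; the correlation module
  covers node-level weighted degree only.
* The packaged region order is one canonical convention; pipelines using a
  different atlas ordering must permute their matrices to it (the
  permutation-equivariance of WD makes this safe).
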