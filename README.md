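# fndconn — weighted-degree connectome statistics for case-control diffusion MRI

`fndconn` is an R package for group analysis of structural brain
connectomes, written for studies that compare patients (here: functional
neurological disorder, FND) against healthy controls on
tractography-derived 84 x 84 Desikan-Killiany matrices. It implements the
full statistical chain downstream of connectome construction:

* the **weighted degree** (node strength) of the FA-weighted graph,
  `WD_i = Σ_{j≠i} FA_ij`, as an integrative per-region summary of white
  matter microstructural integrity;
* **covariate-adjusted directional group tests** (OLS GLM on the group
  coefficient, one-sided Student *t*) at node level (WD) and link level
  (FA, streamline count, mean fiber length), with Benjamini-Hochberg FDR at
  `q = 0.05` per family and presence filtering of absent links;
* **hierarchical restriction** of significant links to the regions showing
  WD group differences (connectogram edge lists, per-node counts out of 83);
* **partial-correlation analysis** between adjusted WD and clinical scales
  (SF-36 subscales, BDI, STAI-S/T, and for patients S-FMDRS, CGI, illness
  duration), per group and combined, FDR per variable, filtered to the
  group-difference regions;
* a **synthetic cohort generator** with planted nodal deficits,
  mood-mediated confounding (group → BDI/STAI-T → FA) and clinical severity
  coupled to the adjusted WD of designated regions, plus ground truth for
  recovery testing.

Patient-level data for such studies is typically available on request only,
so the package is organised as a simulation-backed analysis workflow: the
numbered scripts in `analysis/` generate a cohort with the published
group-level statistical structure and push it through the full pipeline.

## Worked example

```r
library(fndconn)

sim <- generate_cohort(default_scenarios()$paper_like, seed = 20260920L)
res <- test_nodes(sim$wd, sim$cohort, design_spec(c("age", "sex")))
sum(res$significant)                     # regions with reduced WD
head(res[, c("node", "t_stat", "p_adj")], 3)
```

Running the driver scripts from the repository root prints, for the default
seed (20260920):

```
$ Rscript analysis/02_node_analysis.R
[age_sex] 84/84 regions with reduced WD (q = 0.05); 19/19 planted recovered
[age_sex_medication] 84/84 regions with reduced WD (q = 0.05); 19/19 planted recovered
[age_sex_bdi_stait] 68/84 regions with reduced WD (q = 0.05); 19/19 planted recovered
```

All 19 planted regions are recovered under every covariate model; because
the generator routes part of the group difference through depression and
trait anxiety (mediation), adding BDI/STAI-T to the model shrinks the
discovery set (84 → 68 here) — the qualitative signature of mood-mediated
group effects. The link-level stage then restricts altered FA connections
to those origins:

```
$ Rscript analysis/03_link_analysis.R
[fa] 2074/3486 links tested (present in >= 50% of each group), 1755 significant
Most-affected origins (altered links out of 83 candidates):
                        node n_links n_candidates
 right_lateral_orbitofrontal      61           83
      left_lateral_occipital      55           83
```

and the clinical stage recovers the planted brain-behaviour coupling:

```
$ Rscript analysis/04_clinical_correlations.R
[FND, age_sex_bdi_stait] significant regions per variable: ... sfmdrs=2, cgi=2, sf36_physical_functioning=2 ...
Strongest severity correlates: left_precuneus, left_superior_parietal (r = -0.59, -0.4)
23 zero-severity patients excluded from the scatter data (statistics above use the full group).
```

The two regions whose adjusted WD drives the latent severity axis attain
the strongest (negative) correlations with motor-symptom severity.
`analysis/05_report.R` runs everything as one seeded pipeline
(`run_pipeline()`), writing TSV tables, a JSON summary and an
md5-checksummed MANIFEST; rerunning with the same seed reproduces every
output byte for byte.

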