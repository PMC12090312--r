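#!/usr/bin/env Rscript
# Node-level analysis: directional (patients-lower) covariate-adjusted group
# comparison of weighted degree at each of the 84 regions, under the three
# covariate models, BH-FDR at q = 0.05 per model.

library(fndconn)

SEED <- 20260920L
out <- "results/nodes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_cohort(default_scenarios()$paper_like, seed = SEED,
                       weights = "fa")
gt <- sim$ground_truth

models <- list(age_sex = c("age", "sex"),
               age_sex_medication = c("age", "sex",
                                      "medication_any_psychotropic"),
               age_sex_bdi_stait = c("age", "sex", "bdi", "stai_trait"))

for (mn in names(models)) {
  res <- test_nodes(sim$wd, sim$cohort, design_spec(models[[mn]]))
  utils::write.table(res, file.path(out, paste0("node_results_", mn, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res$node[res$significant]
  message(sprintf("[%s] %d/84 regions with reduced WD (q = 0.05); %d/%d planted recovered",
                  mn, length(sig), sum(gt$planted_nodes %in% sig),
                  length(gt$planted_nodes)))
}
message("Mood adjustment attenuates the marginal group effect because the ",
        "generator routes part of it through BDI / STAI-T (mediation).")
message("Tables written to ", out, ".")
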