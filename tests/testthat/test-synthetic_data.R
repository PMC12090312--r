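test_that("generation is deterministic in (config, seed) and seed-sensitive", {
  cfg <- generator_config(n_fnd = 8L, n_hc = 6L)
  a <- generate_cohort(cfg, seed = 101)
  b <- generate_cohort(cfg, seed = 101)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$links, b$links)
  expect_identical(a$wd, b$wd)
  expect_identical(a$ground_truth, b$ground_truth)

  c <- generate_cohort(cfg, seed = 102)
  expect_false(identical(a$links$fa, c$links$fa))
  expect_false(identical(a$cohort$bdi, c$cohort$bdi))
  expect_identical(names(a$ground_truth), names(c$ground_truth))
  expect_identical(a$ground_truth$planted_nodes,
                   c$ground_truth$planted_nodes)
})

test_that("generated connectomes satisfy every matrix invariant", {
  sim <- generate_cohort(generator_config(n_fnd = 4L, n_hc = 4L), seed = 103)
  for (kind in c("fa", "nstreamlines", "mean_length_mm")) {
    cons <- cohort_connectomes(sim, kind)  # constructor re-validates
    expect_length(cons, 8)
    for (cn in cons[c(1, 8)]) {
      expect_identical(cn$matrix, t(cn$matrix))
      expect_equal(diag(cn$matrix), rep(0, 84))
      expect_true(all(cn$matrix >= 0))
    }
  }
  fa <- sim$links$fa
  expect_true(all(fa[, sim$mask] >= 0.01 - 1e-12))
  expect_true(all(fa[, sim$mask] <= 0.95 + 1e-12))
  expect_true(all(fa[, !sim$mask] == 0))
  cnt <- sim$links$nstreamlines
  expect_true(all(cnt == round(cnt)))
  expect_true(all(cnt[, sim$mask] >= 1))
})

test_that("cohort table matches its contract and the mediation wiring", {
  sim <- generate_cohort(generator_config(), seed = 104, weights = "fa")
  co <- validate_cohort(sim$cohort)  # throws on any contract violation
  expect_equal(sum(co$group == "FND"), 85)
  expect_equal(sum(co$group == "HC"), 75)
  hc <- co$group == "HC"
  expect_true(all(is.na(co$sfmdrs[hc])))
  expect_true(all(is.na(co$cgi[hc])))
  expect_false(any(co$medication_any_psychotropic[hc]))
  expect_true(all(co$cgi[!hc] %in% 0:7))
  # mood differs by group (the mediator arm of the design)
  expect_gt(mean(co$bdi[!hc]) - mean(co$bdi[hc]), 3)
  expect_gt(mean(co$stai_trait[!hc]) - mean(co$stai_trait[hc]), 5)
})

test_that("presets cover the scenario grid and round-trip through JSON", {
  sc <- default_scenarios()
  expect_setequal(names(sc),
                  c("null", "paper_like", "strong_effect", "mediation_off"))
  expect_length(sc$null$planted_nodes, 0)
  expect_equal(sc$null$node_effect_d, 0)
  expect_length(sc$paper_like$planted_nodes, 19)
  expect_true(all(c("left_precuneus", "left_superior_parietal") %in%
                    sc$paper_like$coupled_nodes))
  expect_equal(sc$mediation_off$mediator_coupling_bdi, 0)
  expect_gt(sc$strong_effect$node_effect_d, sc$paper_like$node_effect_d)

  dir <- withr::local_tempdir()
  for (nm in names(sc)) {
    path <- file.path(dir, paste0(nm, ".json"))
    write_generator_config(sc[[nm]], path)
    back <- read_generator_config(path)
    expect_equal(back, sc[[nm]])
  }

  null_sim <- generate_cohort(sc$null, seed = 105, weights = "fa")
  expect_length(null_sim$ground_truth$planted_nodes, 0)
  expect_equal(nrow(null_sim$ground_truth$link_effects), 0)
})

test_that("an unreachable planted effect reports the attainable maximum", {
  expect_error(
    generate_cohort(generator_config(node_effect_d = 50), seed = 106,
                    weights = "fa"),
    "attainable maximum")
  expect_error(generator_config(planted_nodes = "left_nowhere"),
               "unknown region")
})

test_that("score moments, planted effect and coupling calibrate at large n", {
  sim <- bign_cohort()
  co <- sim$cohort
  gt <- sim$ground_truth
  fnd <- co$group == "FND"

  expect_lt(abs(mean(co$bdi[fnd]) - 14.33), 0.3)
  expect_lt(abs(mean(co$bdi[!fnd]) - 4.41), 0.3)
  expect_lt(abs(mean(co$age[fnd]) - 37.55), 0.5)
  expect_lt(abs(mean(co$stai_trait[!fnd]) - 33.93), 0.5)
  expect_lt(abs(mean(co$sfmdrs[fnd]) - 8.54), 0.5)
  expect_lt(abs(mean(co$cgi[fnd]) - 2.69), 0.2)
  expect_lt(abs(mean(co$sfmdrs[fnd] == 0) - 21 / 85), 0.03)

  # realized direct standardized WD deficit at the planted regions: the
  # covariate-adjusted group coefficient over the marginal within-group sd
  X <- cbind(1, as.numeric(fnd), co$age, as.numeric(co$sex == "male"),
             co$bdi, co$stai_trait)
  pidx <- match(gt$planted_nodes, colnames(sim$wd))
  beta <- qr.coef(qr(X), sim$wd[, pidx])[2, ]
  sd_pooled <- vapply(pidx, function(k)
    sqrt(mean(c(var(sim$wd[fnd, k]), var(sim$wd[!fnd, k])))), 0)
  d_realized <- -beta / sd_pooled
  expect_true(all(abs(d_realized - 1.0) < 0.1))

  # realized partial severity correlation at the coupled regions
  covs <- cbind(co$age, as.numeric(co$sex == "male"), co$bdi,
                co$stai_trait)[fnd, ]
  wd_res <- residualize(sim$wd[fnd, match(gt$coupled_nodes,
                                          colnames(sim$wd))], covs)
  sev_res <- residualize(co$sfmdrs[fnd], covs)
  r_realized <- drop(cor(wd_res, sev_res))
  expect_true(all(abs(r_realized - (-0.5)) < 0.1))

  # mediation: the marginal group effect exceeds the mood-adjusted one
  ds_marg <- design_spec(c("age", "sex"))
  ds_adj <- design_spec(c("age", "sex", "bdi", "stai_trait"))
  t_marg <- fit_group_glm(sim$wd[, pidx[1]], co, ds_marg)$t_stat
  t_adj <- fit_group_glm(sim$wd[, pidx[1]], co, ds_adj)$t_stat
  expect_lt(t_marg, t_adj)  # both negative; marginal is more extreme
  expect_gt(abs(t_marg), abs(t_adj))
})
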