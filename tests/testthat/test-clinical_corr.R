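test_that("residualize centers, annihilates covariates and is orthogonal", {
  set.seed(51)
  y <- rnorm(30)
  expect_equal(residualize(y), y - mean(y))

  age <- runif(30, 20, 60)
  expect_lt(max(abs(residualize(3 + 0.2 * age, cbind(age)))), 1e-9)

  for (rep in 1:20) {
    covs <- cbind(rnorm(30), runif(30), rbinom(30, 1, 0.4))
    r <- residualize(rnorm(30), covs)
    expect_lt(max(abs(crossprod(cbind(1, covs), r))), 1e-8)
  }
  const <- cbind(rep(2, 30))
  expect_error(residualize(y, cbind(age, age)), "rank deficient")
})

test_that("residual correlation equals closed-form partial correlation", {
  set.seed(52)
  for (rep in 1:20) {
    n <- 60
    covs <- cbind(a = rnorm(n), b = runif(n))
    x <- rnorm(n) + 0.5 * covs[, 1]
    y <- rnorm(n) + 0.3 * covs[, 2] - 0.4 * x
    r_res <- cor(residualize(x, covs), residualize(y, covs))
    # oracle: partial correlation via inversion of the correlation matrix
    cm <- solve(cor(cbind(x, y, covs)))
    r_par <- -cm[1, 2] / sqrt(cm[1, 1] * cm[2, 2])
    expect_lt(abs(r_res - r_par), 1e-9)
  }
})

test_that("a perfectly anti-coupled node attains r = -1", {
  co <- make_test_cohort(20, 20, seed = 53)
  wd <- matrix(rnorm(40 * 84, 10), 40, 84,
               dimnames = list(co$subject_id, load_region_table()$name))
  co$sfmdrs <- NA_real_
  fnd <- co$group == "FND"
  co$sfmdrs[fnd] <- -1 * wd[fnd, "left_precuneus"] + 50
  res <- correlate_wd_clinical(wd, co,
    correlation_spec("sfmdrs", group_scope = "FND", adjustment = "age_sex"))
  top <- res[1, ]
  expect_equal(top$node, "left_precuneus")
  expect_equal(top$r, -1, tolerance = 1e-6)
  expect_lt(top$p_unc, 1e-12)
  expect_true(top$significant)
})

test_that("correlations are invariant to affine rescaling of the variable", {
  sim <- generate_cohort(generator_config(n_fnd = 30L, n_hc = 30L),
                         seed = 54, weights = "fa")
  spec <- correlation_spec("sfmdrs", group_scope = "FND",
                           adjustment = "age_sex")
  base <- correlate_wd_clinical(sim$wd, sim$cohort, spec)
  resc <- sim$cohort
  resc$sfmdrs <- 100 + 7 * resc$sfmdrs
  again <- correlate_wd_clinical(sim$wd, resc, spec)
  expect_equal(again$r, base$r, tolerance = 1e-9)
  expect_equal(again$p_unc, base$p_unc, tolerance = 1e-9)
})

test_that("per-variable FDR families and scope rules are enforced", {
  sim <- generate_cohort(generator_config(n_fnd = 30L, n_hc = 30L),
                         seed = 55, weights = "fa")
  res <- correlate_wd_clinical(sim$wd, sim$cohort,
    correlation_spec(c("sfmdrs", "cgi"), group_scope = "FND",
                     adjustment = "age_sex_bdi_stait"))
  expect_equal(nrow(res), 168)
  for (v in c("sfmdrs", "cgi")) {
    sub <- res[res$variable == v, ]
    expect_equal(sub$p_adj, bh_fdr(sub$p_unc)$p_adj)
  }
  expect_error(correlation_spec("sfmdrs", group_scope = "combined"),
               "FND")
  expect_error(correlation_spec("height_cm"), "unknown clinical variable")

  const <- sim$cohort
  const$cgi <- ifelse(const$group == "FND", 3, NA)
  expect_error(correlate_wd_clinical(sim$wd, const,
    correlation_spec("cgi", group_scope = "FND", adjustment = "age_sex")),
    "constant")

  sorted <- sorted_p_curves(res)
  expect_equal(nrow(sorted), 168)
  expect_false(is.unsorted(sorted$p_unc[sorted$variable == "sfmdrs"]))
  expect_equal(sorted$rank[sorted$variable == "cgi"], 1:84)
})

test_that("combined-group correlation can be driven by group separation alone", {
  # a group difference in both WD and the score, with no within-group
  # coupling, yields a combined-group association while both within-group
  # correlations stay null (Simpson-type behaviour of pooled analyses)
  set.seed(56)
  co <- make_test_cohort(40, 40, seed = 56)
  fnd <- co$group == "FND"
  wd <- matrix(rnorm(80 * 84, 10), 80, 84,
               dimnames = list(co$subject_id, load_region_table()$name))
  wd[fnd, ] <- wd[fnd, ] - 3
  co$bdi <- rnorm(80, 10) + ifelse(fnd, 8, 0)
  spec_c <- correlation_spec("bdi", group_scope = "combined",
                             adjustment = "age_sex")
  r_comb <- correlate_wd_clinical(wd, co, spec_c)
  expect_lt(median(r_comb$r), -0.3)
  expect_gt(sum(r_comb$significant), 42)
  for (scope in c("FND", "HC")) {
    r_within <- correlate_wd_clinical(wd, co,
      correlation_spec("bdi", group_scope = scope, adjustment = "age_sex"))
    expect_equal(sum(r_within$significant), 0)
  }
})

test_that("region filtering intersects significant results with a node set", {
  sim <- generate_cohort(generator_config(n_fnd = 30L, n_hc = 30L),
                         seed = 57, weights = "fa")
  res <- correlate_wd_clinical(sim$wd, sim$cohort,
    correlation_spec(c("sfmdrs", "cgi"), group_scope = "FND",
                     adjustment = "age_sex_bdi_stait"))
  rt <- load_region_table()

  all_regions <- filter_to_regions(res, rt$name)
  expect_equal(nrow(all_regions$results), sum(res$significant))
  none <- filter_to_regions(res, character(0))
  expect_equal(nrow(none$results), 0)

  set.seed(58)
  for (rep in 1:10) {
    res$significant <- runif(nrow(res)) < 0.3
    regions <- sample(rt$name, 12)
    got <- filter_to_regions(res, regions)
    for (v in unique(res$variable)) {
      manual <- sum(res$significant & res$variable == v &
                      res$node %in% regions)
      expect_equal(got$counts$n_regions[got$counts$variable == v], manual)
    }
  }
  expect_error(filter_to_regions(res, "left_atlantis"), "unknown region")
})

test_that("zero-severity patients are excluded for plotting only", {
  sim <- generate_cohort(generator_config(), seed = 1, weights = "fa")
  ex <- exclude_zero_sfmdrs(sim$cohort)
  # zero-inflation 21/85: about 21 excluded at the default configuration
  expect_gt(ex$n_excluded, 9)
  expect_lt(ex$n_excluded, 34)
  expect_true(all(ex$cohort$sfmdrs > 0))
  expect_true(all(ex$cohort$group == "FND"))
  expect_equal(nrow(ex$cohort) + ex$n_excluded, 85)

  co <- make_test_cohort(5, 5, seed = 59)
  co$sfmdrs[co$group == "FND"] <- 1:5
  expect_equal(exclude_zero_sfmdrs(co)$n_excluded, 0)
  co$sfmdrs[co$group == "FND"] <- 0
  expect_warning(ex_all <- exclude_zero_sfmdrs(co), "S-FMDRS 0")
  expect_equal(ex_all$n_excluded, 5)
  expect_equal(nrow(ex_all$cohort), 0)
})
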