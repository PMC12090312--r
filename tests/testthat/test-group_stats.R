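test_that("bh_fdr matches the brute-force step-up definition", {
  # single p-value: adjusted value is itself
  one <- bh_fdr(0.01, 0.05)
  expect_equal(one$p_adj, 0.01)
  expect_true(one$significant)

  fixed <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05)
  oracle <- bh_oracle(c(0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(fixed$p_adj, oracle$p_adj)
  expect_equal(fixed$significant, oracle$significant)

  # step-up boundary: all p equal, p = k*q/m attained at k = m
  boundary <- bh_fdr(rep(0.04, 84), 0.05)
  expect_true(all(boundary$significant))
  expect_equal(boundary$p_adj, rep(0.04, 84))

  set.seed(31)
  for (rep in 1:500) {
    m <- sample(1:100, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))  # rounding makes ties
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)
    want <- bh_oracle(p, q)
    expect_equal(got$p_adj, want$p_adj)
    expect_identical(got$significant, want$significant)
  }

  expect_error(bh_fdr(c(0.1, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.1), 0.05), "\\[0, 1\\]")
})

test_that("bh_fdr decisions are monotone in the p-values", {
  set.seed(32)
  for (rep in 1:50) {
    p <- runif(20)
    base <- bh_fdr(p, 0.05)
    k <- sample(20, 1)
    p2 <- p
    p2[k] <- p[k] * runif(1)
    lowered <- bh_fdr(p2, 0.05)
    expect_true(all(lowered$significant[base$significant]))
  }
})

test_that("the group GLM reduces to the pooled two-sample t without covariates", {
  co <- make_test_cohort(12, 15, seed = 33)
  ds <- design_spec(character(0))
  set.seed(34)
  for (rep in 1:50) {
    y <- rnorm(27, mean = ifelse(co$group == "FND", 0.3, 0))
    fit <- fit_group_glm(y, co, ds)
    tt <- t.test(y[co$group == "FND"], y[co$group == "HC"],
                 var.equal = TRUE)
    expect_lt(abs(fit$t_stat - tt$statistic), 1e-9)
    expect_equal(fit$df, unname(tt$parameter))
  }
})

test_that("directional p-values behave at the null and under covariates", {
  co <- make_test_cohort(5, 5, seed = 35)
  y <- rep(1:5, 2)  # identical values in both groups
  fit <- fit_group_glm(y, co, design_spec(character(0)))
  expect_equal(fit$t_stat, 0)
  expect_equal(fit$p_unc, 0.5)

  # outcome perfectly explained by a covariate: group adds nothing
  fit_age <- fit_group_glm(co$age, co, design_spec("age"))
  expect_lt(abs(fit_age$t_stat), 1e-7)
  expect_lt(abs(fit_age$p_unc - 0.5), 1e-7)

  two <- fit_group_glm(co$bdi, co, design_spec(character(0),
                                               direction = "two_sided"))
  lower <- fit_group_glm(co$bdi, co, design_spec(character(0)))
  higher <- fit_group_glm(co$bdi, co, design_spec(character(0),
                                                  direction = "fnd_higher"))
  expect_equal(lower$p_unc + higher$p_unc, 1)
  expect_equal(two$p_unc, 2 * min(lower$p_unc, higher$p_unc))
})

test_that("degenerate designs fail loudly", {
  co <- make_test_cohort(6, 6, seed = 36)
  co$medication_any_psychotropic <- FALSE  # constant column
  expect_error(
    fit_group_glm(rnorm(12), co, design_spec("medication_any_psychotropic")),
    "medication_any_psychotropic")
  tiny <- make_test_cohort(2, 6, seed = 37)
  expect_error(fit_group_glm(rnorm(8), tiny, design_spec(character(0))),
               "at least 3")
  expect_error(design_spec(c("age", "age")), "unique")
  expect_error(design_spec("height"), "unknown covariate")
})

test_that("adding a covariate orthogonal to group and outcome barely moves t", {
  set.seed(38)
  n <- 2000
  co <- make_test_cohort(n / 2, n / 2, seed = 38)
  y <- rnorm(n) + ifelse(co$group == "FND", -0.2, 0)
  g <- as.numeric(co$group == "FND")
  z <- residuals(lm(rnorm(n) ~ g + y))
  co$bdi <- abs(z)  # smuggle the orthogonalised covariate into a valid slot
  co$bdi <- z - min(z)
  plain <- fit_group_glm(y, co, design_spec(character(0)))
  with_cov <- fit_group_glm(y, co, design_spec("bdi"))
  expect_lt(abs(plain$t_stat - with_cov$t_stat), 0.01)
})

test_that("node-level testing controls the family and reports structure", {
  sim <- generate_cohort(generator_config(n_fnd = 40L, n_hc = 40L,
                                          node_effect_d = 1.5),
                         seed = 39, weights = "fa")
  res <- test_nodes(sim$wd, sim$cohort, design_spec(c("age", "sex")))
  expect_equal(nrow(res), 84)
  expect_setequal(res$node, load_region_table()$name)
  expect_true(all(res$p_adj >= res$p_unc - 1e-15))
  expect_identical(res$significant, res$p_adj <= 0.05)
  expect_false(is.unsorted(res$p_unc))
  # every planted region is recovered at this effect size
  expect_true(all(sim$ground_truth$planted_nodes %in%
                    res$node[res$significant]))
})

test_that("link-level testing filters by presence and finds a planted link", {
  co <- make_test_cohort(10, 10, seed = 40)
  # identical matrices: no group difference anywhere
  same <- matrix(rep(upper_tri <- runif(3486, 0, 0.5), 20), 20,
                 byrow = TRUE)
  res_same <- test_links(same, co, design_spec(character(0)))
  expect_equal(sum(res_same$significant), 0)

  # presence filter: one subject zero at a link excludes it at threshold 1
  vals <- same
  vals[1, 5] <- 0
  res_thr <- test_links(vals, co, design_spec(character(0)),
                        presence_threshold = 1.0)
  li <- link_index()
  expect_false(res_thr$tested[res_thr$region_a ==
                                load_region_table()$name[li$i[5] + 1] &
                              res_thr$region_b ==
                                load_region_table()$name[li$j[5] + 1]])
  expect_equal(sum(!res_thr$tested), 1)

  # a planted group difference at one link attains the smallest p
  set.seed(41)
  found <- 0L
  for (rep in 1:5) {
    noise <- matrix(runif(20 * 3486, 0.3, 0.5), 20)
    noise[co$group == "FND", 77] <- noise[co$group == "FND", 77] - 0.25
    res <- test_links(noise, co, design_spec(character(0)),
                      presence_threshold = 0)
    top <- res[1, ]
    if (top$region_a == load_region_table()$name[li$i[77] + 1] &&
        top$region_b == load_region_table()$name[li$j[77] + 1])
      found <- found + 1L
  }
  expect_gte(found, 4L)
})

test_that("link restriction to node origins counts incidences correctly", {
  rt <- load_region_table()
  sk <- data.frame(region_a = rt$name[link_index()$i + 1L],
                   region_b = rt$name[link_index()$j + 1L],
                   stringsAsFactors = FALSE)
  sk$t_stat <- 0; sk$p_unc <- 0; sk$p_adj <- 0
  sk$tested <- TRUE

  sk$significant <- TRUE
  all_one <- restrict_links_to_nodes(sk, "left_precuneus")
  expect_equal(all_one$counts$n_links, 83L)
  expect_equal(all_one$counts$n_candidates, 83L)

  empty <- restrict_links_to_nodes(sk, character(0))
  expect_equal(nrow(empty$links), 0)
  expect_equal(nrow(empty$counts), 0)

  set.seed(42)
  for (rep in 1:10) {
    sk$significant <- runif(3486) < 0.1
    nodes <- sample(rt$name, 5)
    got <- restrict_links_to_nodes(sk, nodes)
    # brute-force incidence count over the significant links
    sig <- sk[sk$significant, ]
    keep <- sig$region_a %in% nodes | sig$region_b %in% nodes
    expect_equal(nrow(got$links), sum(keep))
    for (nd in nodes) {
      manual <- sum((sig$region_a == nd | sig$region_b == nd) & keep)
      expect_equal(got$counts$n_links[got$counts$node == nd], manual)
    }
  }
  expect_error(restrict_links_to_nodes(sk, "left_amygdala_oblongata"),
               "unknown region")
})
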