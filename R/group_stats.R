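#' Specify a covariate-adjusted directional group comparison
#'
#' The analysis model is an ordinary least squares GLM
#' `y ~ intercept + group + covariates` with the patient group coded 1 and
#' controls 0; the group coefficient is tested with a Student t on the
#' residual degrees of freedom. Directions are tested as separate one-sided
#' families (`fnd_lower`: reduced values in patients; `fnd_higher`:
#' heightened), each FDR-corrected on its own.
#'
#' @param covariates Character vector from `age`, `sex`,
#'   `medication_any_psychotropic`, `bdi`, `stai_trait` (order preserved).
#' @param direction `"fnd_lower"` (default), `"fnd_higher"` or `"two_sided"`.
#' @param q_fdr FDR level, default 0.05.
#' @return A `design_spec` list.
#' @export
design_spec <- function(covariates = c("age", "sex"),
                        direction = c("fnd_lower", "fnd_higher", "two_sided"),
                        q_fdr = 0.05) {
  allowed <- c("age", "sex", "medication_any_psychotropic", "bdi", "stai_trait")
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates)) stop("covariate names must be unique")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  direction <- match.arg(direction)
  stopifnot(is.numeric(q_fdr), q_fdr > 0, q_fdr < 1)
  structure(list(covariates = covariates, direction = direction,
                 q_fdr = q_fdr), class = "design_spec")
}

# design matrix: intercept, group indicator (FND = 1), covariates
build_design_matrix <- function(cohort, covariates) {
  cohort <- validate_cohort(cohort)
  X <- cbind(intercept = 1, group = as.numeric(cohort$group == "FND"))
  for (v in covariates) {
    col <- switch(v,
      sex = as.numeric(cohort$sex == "male"),
      medication_any_psychotropic =
        as.numeric(cohort$medication_any_psychotropic),
      cohort[[v]])
    if (anyNA(col)) stop("covariate ", v, " contains missing values")
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  X
}

# check full rank, naming the offending column
assert_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; offending column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(qr_x)
}

# core vectorised OLS group test: Y is n x m (or a vector), X the design
# matrix with a "group" column. Returns t and directional p per column.
ols_group_test <- function(Y, X, direction) {
  Y <- cbind(Y)
  stopifnot(nrow(Y) == nrow(X))
  assert_full_rank(X)
  fit <- stats::lm.fit(X, Y)
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  res <- cbind(fit$residuals)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  g <- which(colnames(X) == "group")
  beta_g <- cbind(fit$coefficients)[g, ]
  se <- sqrt(sigma2 * xtx_inv[g, g])
  # an outcome fitted (numerically) perfectly by the covariates leaves a
  # 0/0 statistic; such columns carry no evidence either way, so t = 0
  degenerate <- sigma2 <= 1e-20 * (colMeans(Y^2) + 1)
  t_stat <- ifelse(se > 0 & !degenerate, beta_g / se, 0)
  p <- switch(direction,
    fnd_lower  = stats::pt(t_stat, df),
    fnd_higher = stats::pt(t_stat, df, lower.tail = FALSE),
    two_sided  = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE))
  list(t_stat = unname(t_stat), p_unc = unname(p), df = df)
}

#' Covariate-adjusted group comparison of one outcome
#'
#' Fits `y ~ intercept + group + covariates` by OLS and tests the group
#' (FND vs HC) coefficient. With no covariates the t statistic is exactly
#' the classical pooled-variance two-sample t.
#'
#' @param y Numeric vector, one value per cohort row (or a matrix with one
#'   column per outcome).
#' @param cohort Validated cohort table aligned with `y`.
#' @param design A [design_spec()].
#' @return List with `t_stat`, `p_unc` (directional per `design`) and `df`.
#' @export
fit_group_glm <- function(y, cohort, design) {
  stopifnot(inherits(design, "design_spec"))
  cohort <- validate_cohort(cohort)
  if (min(table(cohort$group)) < 3)
    stop("each group needs at least 3 subjects")
  X <- build_design_matrix(cohort, design$covariates)
  ols_group_test(y, X, design$direction)
}

#' Node-level group comparison of weighted degree with FDR control
#'
#' One GLM per region; Benjamini-Hochberg correction applied across the 84
#' node p-values as a single family.
#'
#' @param wd Subjects x 84 matrix of weighted degrees, rows aligned with
#'   `cohort`; column names (region names) are used if present, otherwise
#'   taken from `region_table`.
#' @param cohort Cohort table.
#' @param design A [design_spec()].
#' @param region_table Region table; default [load_region_table()].
#' @return data.frame (one row per region, sorted by `p_unc`) with columns
#'   `node`, `t_stat`, `p_unc`, `p_adj`, `significant`, `direction_tested`.
#' @export
test_nodes <- function(wd, cohort, design, region_table = load_region_table()) {
  stopifnot(inherits(design, "design_spec"), ncol(wd) == N_REGIONS,
            nrow(wd) == nrow(cohort))
  nodes <- colnames(wd)
  if (is.null(nodes)) nodes <- region_table$name
  res <- fit_group_glm(wd, cohort, design)
  adj <- bh_fdr(res$p_unc, design$q_fdr)
  out <- data.frame(node = nodes, t_stat = res$t_stat, p_unc = res$p_unc,
                    p_adj = adj$p_adj, significant = adj$significant,
                    direction_tested = design$direction,
                    stringsAsFactors = FALSE)
  out[order(out$p_unc, out$node), , drop = FALSE]
}

#' Link-level group comparison with presence filtering and FDR control
#'
#' Each link is tested by the same covariate-adjusted GLM, but only links
#' present (nonzero) in at least `presence_threshold` of the subjects of
#' *each* group enter the tested family; FDR is computed over tested links
#' only. Untested links are returned flagged `tested = FALSE` (absent, not
#' failed). Set `presence_threshold = 0` to test all 3486 pairs.
#'
#' @param values Subjects x 3486 link-value matrix from [link_values()].
#' @param cohort Cohort table aligned with `values` rows.
#' @param design A [design_spec()].
#' @param presence_threshold Fraction in `[0, 1]`, default 0.5.
#' @param region_table Region table used to name link endpoints.
#' @return data.frame with one row per link: `region_a`, `region_b` (names,
#'   a before b in canonical node order), `tested`, `t_stat`, `p_unc`,
#'   `p_adj`, `significant`, `direction_tested`; sorted by `p_unc` among
#'   tested links, untested links last.
#' @export
test_links <- function(values, cohort, design, presence_threshold = 0.5,
                       region_table = load_region_table()) {
  stopifnot(inherits(design, "design_spec"), ncol(values) == N_LINKS,
            nrow(values) == nrow(cohort),
            presence_threshold >= 0, presence_threshold <= 1)
  cohort <- validate_cohort(cohort)
  grp <- cohort$group == "FND"
  present_frac_fnd <- colMeans(values[grp, , drop = FALSE] != 0)
  present_frac_hc <- colMeans(values[!grp, , drop = FALSE] != 0)
  tested <- present_frac_fnd >= presence_threshold &
    present_frac_hc >= presence_threshold
  if (presence_threshold == 0) tested[] <- TRUE
  li <- link_index()
  out <- data.frame(region_a = region_table$name[li$i + 1L],
                    region_b = region_table$name[li$j + 1L],
                    tested = tested, t_stat = NA_real_, p_unc = NA_real_,
                    p_adj = NA_real_, significant = FALSE,
                    direction_tested = design$direction,
                    stringsAsFactors = FALSE)
  if (any(tested)) {
    res <- fit_group_glm(values[, tested, drop = FALSE], cohort, design)
    adj <- bh_fdr(res$p_unc, design$q_fdr)
    out$t_stat[tested] <- res$t_stat
    out$p_unc[tested] <- res$p_unc
    out$p_adj[tested] <- adj$p_adj
    out$significant[tested] <- adj$significant
  }
  out[order(!out$tested, out$p_unc), , drop = FALSE]
}

#' Restrict significant links to significant node origins
#'
#' Keeps significant links with at least one endpoint in `nodes` (the
#' regions showing group differences in weighted degree) and counts, per
#' node in `nodes`, the kept links incident to it — each node has 83
#' candidate links, so counts are reported out of 83.
#'
#' @param links Result of [test_links()].
#' @param nodes Character vector of significant region names.
#' @param region_table Region table (for name validation).
#' @return List with `links` (filtered data.frame) and `counts`
#'   (data.frame `node`, `n_links`, `n_candidates` = 83).
#' @export
restrict_links_to_nodes <- function(links, nodes,
                                    region_table = load_region_table()) {
  nodes <- as.character(nodes)
  bad <- setdiff(nodes, region_table$name)
  if (length(bad)) stop("unknown region name(s): ", paste(bad, collapse = ", "))
  keep <- links$significant &
    (links$region_a %in% nodes | links$region_b %in% nodes)
  kept <- links[keep, , drop = FALSE]
  counts <- data.frame(node = nodes,
                       n_links = vapply(nodes, function(nd)
                         sum(kept$region_a == nd | kept$region_b == nd), 0L),
                       n_candidates = rep(83L, length(nodes)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(links = kept, counts = counts)
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' Adjusted p-values are `min_{k' >= k} p_(k') * m / k'` capped at 1 (the
#' standard step-up definition); a test is declared significant when its
#' adjusted p is at most `q`. Ties share a rank and receive identical
#' adjusted values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level, default 0.05.
#' @return List with `p_adj` and logical `significant`, in input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = p_adj <= q)
}
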