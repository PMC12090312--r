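CLINICAL_VARIABLES <- c("sf36_physical_health", "sf36_mental_health",
                        "sf36_general_health", "sf36_physical_functioning",
                        "bdi", "stai_trait", "stai_state",
                        "illness_duration_months", "sfmdrs", "cgi")
FND_ONLY_VARIABLES <- c("illness_duration_months", "sfmdrs", "cgi")

#' Specify a brain-clinical correlation analysis
#'
#' @param clinical_variables Variables to correlate with adjusted weighted
#'   degree. `illness_duration_months`, `sfmdrs` and `cgi` are recorded for
#'   patients only and are valid only when `group_scope = "FND"`.
#' @param group_scope `"FND"`, `"HC"` or `"combined"`.
#' @param adjustment `"age_sex"` or `"age_sex_bdi_stait"` — the covariates
#'   residualised out of both the weighted degree and the clinical variable
#'   before correlating.
#' @param q_fdr FDR level, default 0.05; one BH family per clinical variable
#'   across the 84 regions.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param pooled_family If TRUE, one BH family pooled over all variables
#'   instead of one per variable.
#' @return A `correlation_spec` list.
#' @export
correlation_spec <- function(clinical_variables,
                             group_scope = c("FND", "HC", "combined"),
                             adjustment = c("age_sex", "age_sex_bdi_stait"),
                             q_fdr = 0.05,
                             method = c("pearson", "spearman"),
                             pooled_family = FALSE) {
  group_scope <- match.arg(group_scope)
  adjustment <- match.arg(adjustment)
  method <- match.arg(method)
  bad <- setdiff(clinical_variables, CLINICAL_VARIABLES)
  if (length(bad))
    stop("unknown clinical variable(s): ", paste(bad, collapse = ", "))
  fnd_only <- intersect(clinical_variables, FND_ONLY_VARIABLES)
  if (length(fnd_only) && group_scope != "FND")
    stop(paste(fnd_only, collapse = ", "),
         " are recorded for FND patients only (group_scope must be 'FND')")
  stopifnot(q_fdr > 0, q_fdr < 1)
  structure(list(clinical_variables = as.character(clinical_variables),
                 group_scope = group_scope, adjustment = adjustment,
                 q_fdr = q_fdr, method = method,
                 pooled_family = pooled_family),
            class = "correlation_spec")
}

adjustment_covariates <- function(adjustment) {
  switch(adjustment,
         age_sex = c("age", "sex"),
         age_sex_bdi_stait = c("age", "sex", "bdi", "stai_trait"),
         stop("unknown adjustment: ", adjustment))
}

#' Residualise values on covariates by OLS
#'
#' Regresses each column of `y` on the covariate matrix (with intercept) and
#' returns the residuals, which are orthogonal to every covariate column and
#' to the intercept.
#'
#' @param y Numeric vector or matrix (rows = subjects).
#' @param covariates Numeric matrix of covariate columns (no intercept;
#'   one is added), or NULL/zero columns for centering only.
#' @return Residuals with the same shape as `y`.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- cbind(y)
  X <- cbind(intercept = rep(1, nrow(y)))
  if (!is.null(covariates) && NCOL(covariates) > 0)
    X <- cbind(X, as.matrix(covariates))
  assert_full_rank(X)
  res <- stats::lm.fit(X, y)$residuals
  if (ncol(y) == 1L) drop(res) else res
}

covariate_matrix <- function(cohort, covariate_names) {
  cols <- lapply(covariate_names, function(v)
    if (v == "sex") as.numeric(cohort$sex == "male") else cohort[[v]])
  m <- do.call(cbind, cols)
  colnames(m) <- covariate_names
  m
}

#' Correlate adjusted weighted degree with clinical variables
#'
#' For the subjects in scope, residualises both the per-region weighted
#' degrees and each clinical variable on the adjustment covariates, then
#' correlates them region by region (partial-correlation semantics). P-values
#' use a Student t with `n - 2 - n_covariates` degrees of freedom; BH-FDR is
#' applied across the 84 regions within each variable. Subjects missing a
#' variable (or any covariate) are dropped pairwise per variable.
#'
#' @param wd Subjects x 84 weighted-degree matrix aligned with `cohort`.
#' @param cohort Cohort table.
#' @param spec A [correlation_spec()].
#' @param region_table Region table.
#' @param adjust_wd_only If TRUE, residualise only the weighted degree and
#'   correlate with the raw clinical variable.
#' @return data.frame with `variable`, `node`, `r`, `p_unc`, `p_adj`,
#'   `significant`, `n_used`; within each variable sorted by `p_unc`.
#' @export
correlate_wd_clinical <- function(wd, cohort, spec,
                                  region_table = load_region_table(),
                                  adjust_wd_only = FALSE) {
  stopifnot(inherits(spec, "correlation_spec"), ncol(wd) == N_REGIONS,
            nrow(wd) == nrow(cohort))
  cohort <- validate_cohort(cohort)
  nodes <- colnames(wd)
  if (is.null(nodes)) nodes <- region_table$name
  in_scope <- switch(spec$group_scope,
                     FND = cohort$group == "FND",
                     HC = cohort$group == "HC",
                     combined = rep(TRUE, nrow(cohort)))
  covs <- adjustment_covariates(spec$adjustment)
  res_list <- lapply(spec$clinical_variables, function(v) {
    x <- cohort[[v]]
    cv <- covariate_matrix(cohort, covs)
    use <- in_scope & !is.na(x) & stats::complete.cases(cv)
    n <- sum(use)
    if (n < 5) stop("fewer than 5 usable subjects for ", v)
    xv <- x[use]
    if (stats::sd(xv) == 0) stop("variable ", v, " is constant after filtering")
    wd_res <- residualize(wd[use, , drop = FALSE], cv[use, , drop = FALSE])
    x_res <- if (adjust_wd_only) xv else residualize(xv, cv[use, , drop = FALSE])
    if (spec$method == "spearman") {
      wd_res <- apply(wd_res, 2, rank)
      x_res <- rank(x_res)
    }
    r <- drop(stats::cor(wd_res, x_res))
    df <- n - 2L - length(covs)
    if (df < 1) stop("not enough subjects for ", v, " after adjustment")
    r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    t_stat <- r_cl * sqrt(df / (1 - r_cl^2))
    p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    data.frame(variable = v, node = nodes, r = r, p_unc = p,
               n_used = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res_list)
  if (spec$pooled_family) {
    adj <- bh_fdr(out$p_unc, spec$q_fdr)
    out$p_adj <- adj$p_adj
    out$significant <- adj$significant
  } else {
    out$p_adj <- NA_real_
    out$significant <- NA
    for (v in spec$clinical_variables) {
      sel <- out$variable == v
      adj <- bh_fdr(out$p_unc[sel], spec$q_fdr)
      out$p_adj[sel] <- adj$p_adj
      out$significant[sel] <- adj$significant
    }
  }
  ord <- order(match(out$variable, spec$clinical_variables), out$p_unc,
               out$node)
  rownames(out) <- NULL
  out[ord, c("variable", "node", "r", "p_unc", "p_adj", "significant",
             "n_used")]
}

#' Sorted p-value curves per clinical variable
#'
#' @param results Output of [correlate_wd_clinical()].
#' @return data.frame `variable`, `rank` (1..84), `p_unc` sorted increasing
#'   within variable — the per-variable sorted-p curve.
#' @export
sorted_p_curves <- function(results) {
  parts <- lapply(split(results, results$variable), function(d) {
    d <- d[order(d$p_unc), , drop = FALSE]
    data.frame(variable = d$variable, rank = seq_len(nrow(d)),
               p_unc = d$p_unc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Filter significant correlations to a region set
#'
#' Keeps significant results whose region is in `regions` (typically the
#' regions previously identified as showing group differences in weighted
#' degree) and counts the kept regions per variable.
#'
#' @param results Output of [correlate_wd_clinical()].
#' @param regions Character vector of region names.
#' @param region_table Region table (name validation).
#' @return List with `results` (filtered rows) and `counts` (data.frame
#'   `variable`, `n_regions`).
#' @export
filter_to_regions <- function(results, regions,
                              region_table = load_region_table()) {
  regions <- as.character(regions)
  bad <- setdiff(regions, region_table$name)
  if (length(bad)) stop("unknown region name(s): ", paste(bad, collapse = ", "))
  kept <- results[results$significant %in% TRUE &
                    results$node %in% regions, , drop = FALSE]
  vars <- unique(results$variable)
  counts <- data.frame(variable = vars,
                       n_regions = vapply(vars, function(v)
                         sum(kept$variable == v), 0L),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(results = kept, counts = counts)
}

#' Exclude zero-severity patients for visualisation
#'
#' Patients with no motor symptoms (S-FMDRS score of exactly 0) are excluded
#' from severity scatter plots; by default statistics are still computed on
#' the full cohort — this helper only subsets for plotting.
#'
#' @param cohort Cohort table.
#' @return List with `cohort` (FND subjects with `sfmdrs > 0`) and
#'   `n_excluded`.
#' @export
exclude_zero_sfmdrs <- function(cohort) {
  cohort <- validate_cohort(cohort)
  fnd <- cohort[cohort$group == "FND", , drop = FALSE]
  keep <- !is.na(fnd$sfmdrs) & fnd$sfmdrs > 0
  if (nrow(fnd) > 0 && !any(keep))
    warning("all FND subjects have S-FMDRS 0; nothing left to plot")
  list(cohort = fnd[keep, , drop = FALSE], n_excluded = sum(!keep))
}
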