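#' Configure an end-to-end analysis run
#'
#' The three covariate models mirror the reporting sequence of the analysis:
#' age/sex, age/sex/medication, and age/sex/BDI/STAI-T.
#'
#' @param output_dir Directory for all run outputs (created if needed).
#' @param seed Integer seed controlling every random operation of the run.
#' @param scenario Name of a [default_scenarios()] preset, or pass
#'   `generator` directly.
#' @param generator Optional explicit [generator_config()] (overrides
#'   `scenario`).
#' @param input_dir Optional directory with an existing fixture set
#'   (`cohort.tsv` + `<subject>_fa.tsv` ...) to analyse instead of
#'   simulating.
#' @param q_fdr FDR level for every family.
#' @param direction Directional alternative for the group comparisons.
#' @param presence_threshold Link-presence filter for link-level tests.
#' @param weight_kinds Weight kinds to test at link level.
#' @param verbose Narrate stages, family sizes and discovery counts.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L, scenario = "paper_like",
                       generator = NULL, input_dir = NULL, q_fdr = 0.05,
                       direction = "fnd_lower", presence_threshold = 0.5,
                       weight_kinds = WEIGHT_KINDS, verbose = TRUE) {
  if (is.null(generator) && is.null(input_dir)) {
    presets <- default_scenarios()
    if (!scenario %in% names(presets))
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(presets), collapse = ", "))
    generator <- presets[[scenario]]
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 scenario = scenario, generator = generator,
                 input_dir = input_dir, q_fdr = q_fdr,
                 direction = direction,
                 presence_threshold = presence_threshold,
                 weight_kinds = weight_kinds, verbose = verbose),
            class = "run_config")
}

write_tsv <- function(d, path) {
  out <- d
  for (v in names(out)) if (is.numeric(out[[v]]))
    out[[v]] <- format(out[[v]], digits = 15, trim = TRUE, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full weighted-degree connectome analysis
#'
#' Executes, in order: cohort simulation (or loading), weighted-degree
#' computation, node-level group tests under the three covariate models,
#' link-level tests per weight kind (age/sex model), restriction of
#' significant links to significant weighted-degree origins, clinical
#' correlation analyses (HC, FND, combined) x (two adjustments), region
#' filtering, and a machine-readable JSON summary. All tables are written
#' under `config$output_dir`; a MANIFEST with checksums closes the run.
#' Re-running with an identical config and seed reproduces every output
#' byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message("[fndconn] ", ...)
  written <- character(0)
  stage <- "init"
  summary <- list(seed = config$seed, scenario = config$scenario)
  result <- tryCatch({
    rt <- load_region_table()

    stage <- "simulate"
    if (!is.null(config$input_dir)) {
      say("stage load: reading cohort and connectomes from ",
          config$input_dir)
      cohort <- read_cohort(file.path(config$input_dir, "cohort.tsv"))
      links <- list()
      for (kind in config$weight_kinds) {
        cons <- lapply(cohort$subject_id, function(id)
          read_connectome(file.path(config$input_dir,
                                    paste0(id, "_", kind, ".tsv")), kind))
        links[[kind]] <- link_values(cons)
      }
      wd <- wd_from_links(links$fa)
      colnames(wd) <- rt$name
      ground_truth <- NULL
    } else {
      say("stage simulate: scenario '", config$scenario, "', n = ",
          config$generator$n_fnd, "/", config$generator$n_hc,
          ", seed ", config$seed)
      sim <- generate_cohort(config$generator, seed = config$seed,
                             weights = config$weight_kinds)
      cohort <- sim$cohort
      links <- sim$links
      wd <- sim$wd
      ground_truth <- sim$ground_truth
      summary$n_planted_nodes <- length(ground_truth$planted_nodes)
    }
    written <- c(written, write_tsv(cohort_summary(cohort),
                                    file.path(out, "cohort_summary.tsv")))
    write_cohort(cohort, file.path(out, "cohort.tsv"))
    written <- c(written, file.path(out, "cohort.tsv"))
    write_wd_table(wd, rt, file.path(out, "wd.tsv"))
    written <- c(written, file.path(out, "wd.tsv"))

    stage <- "node tests"
    models <- list(age_sex = c("age", "sex"),
                   age_sex_medication =
                     c("age", "sex", "medication_any_psychotropic"),
                   age_sex_bdi_stait = c("age", "sex", "bdi", "stai_trait"))
    node_results <- list()
    for (mn in names(models)) {
      ds <- design_spec(models[[mn]], direction = config$direction,
                        q_fdr = config$q_fdr)
      res <- test_nodes(wd, cohort, ds, rt)
      node_results[[mn]] <- res
      say("node tests [", mn, "]: ", sum(res$significant),
          "/84 significant (", config$direction, ", q = ", config$q_fdr, ")")
      written <- c(written, write_tsv(res,
        file.path(out, paste0("node_results_", mn, ".tsv"))))
    }
    summary$significant_nodes <- lapply(node_results, function(r)
      sort(r$node[r$significant]))
    sig_nodes <- summary$significant_nodes$age_sex

    stage <- "link tests"
    ds_link <- design_spec(c("age", "sex"), direction = config$direction,
                           q_fdr = config$q_fdr)
    link_summary <- list()
    connectogram <- NULL
    for (kind in config$weight_kinds) {
      res <- test_links(links[[kind]], cohort, ds_link,
                        presence_threshold = config$presence_threshold,
                        region_table = rt)
      say("link tests [", kind, "]: ", sum(res$tested), "/", N_LINKS,
          " tested, ", sum(res$significant), " significant")
      written <- c(written, write_tsv(res,
        file.path(out, paste0("link_results_", kind, ".tsv"))))
      link_summary[[kind]] <- list(n_tested = sum(res$tested),
                                   n_significant = sum(res$significant))
      if (kind == "fa") {
        stage <- "link restriction"
        restr <- restrict_links_to_nodes(res, sig_nodes, rt)
        connectogram <- restr$links[, c("region_a", "region_b", "t_stat",
                                        "p_adj")]
        written <- c(written, write_tsv(connectogram,
          file.path(out, "connectogram_edges.tsv")))
        written <- c(written, write_tsv(restr$counts,
          file.path(out, "node_link_counts.tsv")))
        summary$fa_links_in_connectogram <- nrow(connectogram)
      }
    }
    summary$link_tests <- link_summary

    stage <- "clinical correlations"
    base_vars <- c("sf36_physical_health", "sf36_mental_health",
                   "sf36_general_health", "sf36_physical_functioning",
                   "bdi", "stai_trait", "stai_state")
    fnd_vars <- c(base_vars, "illness_duration_months", "sfmdrs", "cgi")
    corr_counts <- list()
    for (scope in c("HC", "FND", "combined")) {
      vars <- if (scope == "FND") fnd_vars else base_vars
      for (adj in c("age_sex", "age_sex_bdi_stait")) {
        cs <- correlation_spec(vars, group_scope = scope, adjustment = adj,
                               q_fdr = config$q_fdr)
        cres <- correlate_wd_clinical(wd, cohort, cs, rt)
        tag <- paste0(scope, "_", adj)
        written <- c(written, write_tsv(cres,
          file.path(out, paste0("corr_", tag, ".tsv"))))
        written <- c(written, write_tsv(sorted_p_curves(cres),
          file.path(out, paste0("sorted_p_curves_", tag, ".tsv"))))
        n_sig <- tapply(cres$significant, cres$variable, sum)
        corr_counts[[tag]] <- as.list(n_sig[vars])
        say("correlations [", tag, "]: ",
            sum(cres$significant), " significant node-variable pairs")
        if (scope == "FND" && adj == "age_sex_bdi_stait") {
          stage <- "region filtering"
          filt <- filter_to_regions(cres, sig_nodes, rt)
          written <- c(written, write_tsv(filt$results,
            file.path(out, "filtered_regions.tsv")))
          summary$filtered_region_counts <-
            stats::setNames(as.list(filt$counts$n_regions),
                            filt$counts$variable)
        }
      }
    }
    summary$correlation_significant_counts <- corr_counts
    summary$n_sfmdrs_zero_excluded_for_plots <-
      exclude_zero_sfmdrs(cohort)$n_excluded

    stage <- "report"
    summary$complete <- TRUE
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, file.path(out, "summary.json"))
    if (!is.null(ground_truth)) {
      jsonlite::write_json(ground_truth, file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <- c(written, file.path(out, "ground_truth.json"))
    }
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$file), ]
    utils::write.table(manifest, file.path(out, "MANIFEST"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("run complete: ", length(written), " tables in ", out)
    summary
  }, error = function(e) {
    summary$complete <- FALSE
    summary$failed_stage <- stage
    summary$error <- conditionMessage(e)
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out, "MANIFEST"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Group-wise demographic and clinical summary
#'
#' Per-group mean (sd) for continuous fields and counts for categorical
#' ones, with pooled-variance two-sample t p-values (continuous) and a
#' chi-square p-value for sex. With fewer than 2 subjects in a group the
#' tests are skipped with a notice.
#'
#' @param cohort Cohort table.
#' @return data.frame with columns `variable`, `fnd`, `hc`, `p_value`.
#' @export
cohort_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  fnd <- cohort[cohort$group == "FND", ]
  hc <- cohort[cohort$group == "HC", ]
  can_test <- nrow(fnd) >= 2 && nrow(hc) >= 2
  if (!can_test)
    message("cohort_summary: fewer than 2 subjects in a group; ",
            "tests skipped")
  fmt <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  rows <- list()
  rows[[1]] <- data.frame(variable = "n", fnd = as.character(nrow(fnd)),
                          hc = as.character(nrow(hc)), p_value = NA_real_)
  sex_p <- if (can_test)
    suppressWarnings(stats::chisq.test(table(cohort$group,
                                             cohort$sex))$p.value)
  else NA_real_
  rows[[2]] <- data.frame(
    variable = "sex (female/male)",
    fnd = paste0(sum(fnd$sex == "female"), "/", sum(fnd$sex == "male")),
    hc = paste0(sum(hc$sex == "female"), "/", sum(hc$sex == "male")),
    p_value = sex_p)
  rows[[3]] <- data.frame(
    variable = "medication_any_psychotropic (yes/no)",
    fnd = paste0(sum(fnd$medication_any_psychotropic), "/",
                 sum(!fnd$medication_any_psychotropic)),
    hc = paste0(sum(hc$medication_any_psychotropic), "/",
                sum(!hc$medication_any_psychotropic)),
    p_value = NA_real_)
  for (v in COHORT_NUMERIC) {
    fnd_only <- v %in% FND_ONLY_FIELDS
    p <- NA_real_
    if (!fnd_only && can_test &&
        stats::sd(cohort[[v]], na.rm = TRUE) > 0) {
      p <- stats::t.test(fnd[[v]], hc[[v]], var.equal = TRUE)$p.value
    } else if (!fnd_only && can_test) {
      p <- 1
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, fnd = fmt(fnd[[v]]),
      hc = if (fnd_only) "NA" else fmt(hc[[v]]), p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
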