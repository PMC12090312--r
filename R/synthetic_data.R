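# ---- bounded-score and truncated-normal utilities ------------------------

# mean and sd of clamp(N(mu, sigma), a, b) — interval-censored normal with
# point masses at the bounds, the natural model for bounded instrument
# scores that heap at the scale floor/ceiling (BDI 0, SF-36 100, ...)
cens_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  P_mid <- stats::pnorm(be) - stats::pnorm(al)
  d_al <- stats::dnorm(al)
  d_be <- stats::dnorm(be)
  t_al <- if (is.finite(al)) al * d_al else 0
  t_be <- if (is.finite(be)) be * d_be else 0
  m <- a * stats::pnorm(al) + b * stats::pnorm(be, lower.tail = FALSE) +
    mu * P_mid + sigma * (d_al - d_be)
  m2 <- a^2 * stats::pnorm(al) + b^2 * stats::pnorm(be, lower.tail = FALSE) +
    mu^2 * P_mid + 2 * mu * sigma * (d_al - d_be) +
    sigma^2 * (P_mid + t_al - t_be)
  c(mean = m, sd = sqrt(max(m2 - m^2, 0)))
}

# find (mu, sigma) whose censoring to [a, b] matches target moments; when
# the targets exceed what the support allows, returns the closest fit
cens_match <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- cens_moments(par[1], exp(par[2]), a, b)
    if (!all(is.finite(mo))) return(1e6)
    ((mo[1] - target_mean) / target_sd)^2 + ((mo[2] - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1]
  sigma <- min(exp(fit$par[2]), 50 * target_sd)
  ach <- cens_moments(mu, sigma, a, b)
  list(mu = mu, sigma = sigma, achieved_mean = unname(ach[1]),
       achieved_sd = unname(ach[2]))
}

# sample the censored normal directly, or from a supplied standard-normal
# latent (monotone, so correlations planted on the latent carry through)
rcensnorm <- function(n, mu, sigma, a, b, z = stats::rnorm(n)) {
  pmin(b, pmax(a, mu + sigma * z))
}

# inverse-CDF sampler for the truncated normal (used for baseline link FA)
rtruncnorm <- function(n, mu, sigma, a, b) {
  plo <- stats::pnorm(a, mu, sigma)
  phi <- stats::pnorm(b, mu, sigma)
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

# ---- cohort score moments (defaults reproduce the study's Table-1-style
# marginals; mean/sd per group, with instrument ranges) ---------------------

SCORE_MOMENTS <- list(
  age = list(fnd = c(37.55, 14.26), hc = c(33.13, 10.97), range = c(18, 90)),
  bdi = list(fnd = c(14.33, 9.96), hc = c(4.41, 6.13), range = c(0, 63)),
  stai_trait = list(fnd = c(45.22, 12.92), hc = c(33.93, 7.13),
                    range = c(20, 80)),
  stai_state = list(fnd = c(37.04, 10.91), hc = c(31.76, 7.15),
                    range = c(20, 80)),
  sf36_physical_health = list(fnd = c(30.59, 35.64), hc = c(93, 23.09),
                              range = c(0, 100)),
  sf36_mental_health = list(fnd = c(58.92, 23.17), hc = c(76.53, 13.69),
                            range = c(0, 100)),
  sf36_general_health = list(fnd = c(47.59, 20.90), hc = c(79.33, 14.67),
                             range = c(0, 100)),
  sf36_physical_functioning = list(fnd = c(64.24, 25.12), hc = c(97.33, 6.06),
                                   range = c(0, 100))
)
FEMALE_FRACTION <- c(fnd = 63 / 85, hc = 55 / 75)
SFMDRS_MOMENTS <- c(8.54, 9.65)   # marginal over all patients, zeros included
CGI_MOMENTS <- c(2.69, 1.59)
DURATION_YEARS_MOMENTS <- c(4.89, 6.08)

# the 19 planted regions of the default scenario
PAPER_LIKE_NODES <- c(
  "right_lateral_orbitofrontal", "left_insula", "right_insula",
  "right_middle_temporal", "right_transverse_temporal",
  "left_inferior_temporal", "left_superior_temporal",
  "right_superior_temporal", "left_parahippocampal", "right_postcentral",
  "left_inferior_parietal", "right_inferior_parietal",
  "left_lateral_occipital", "left_putamen", "right_putamen", "right_caudate",
  "left_superior_parietal", "left_precuneus", "right_cerebellum_cortex")

DEFAULT_COUPLED_NODES <- c("left_precuneus", "left_superior_parietal")

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the reference case-control study: 85 patients vs 75
#' controls, FA-weighted connectomes with baseline link FA 0.40 (sd 0.08) at
#' link density 0.6, 19 planted regions with a standardized weighted-degree
#' reduction of d = 1.0 in patients, age/sex effects on FA, mood scores
#' (BDI, STAI-T) that differ by group and independently lower FA (mediation
#' structure), and clinical severity negatively coupled (partial r = -0.5)
#' to the weighted degree of the left precuneus and left superior parietal
#' cortex.
#'
#' @param n_fnd,n_hc Group sizes.
#' @param baseline_fa_mean,baseline_fa_sd Per-link FA baseline.
#' @param link_density Fraction of the 3486 region pairs carrying a link.
#' @param planted_nodes Regions with a planted group deficit.
#' @param node_effect_d Standardized weighted-degree reduction at planted
#'   nodes (relative to the marginal within-group sd).
#' @param age_slope_per_year FA change per year of age.
#' @param sex_offset FA offset for male subjects.
#' @param mediator_coupling_bdi,mediator_coupling_stai FA change per BDI /
#'   STAI-T point (the mood-to-brain arrows of the mediation structure).
#' @param clinical_coupling_r Target partial correlation (given age, sex,
#'   BDI, STAI-T) between severity and weighted degree at `coupled_nodes`.
#' @param coupled_nodes Regions whose adjusted weighted degree drives the
#'   latent severity axis.
#' @param sfmdrs_zero_prob Zero-inflation probability of the motor-severity
#'   score (patients with no motor symptoms).
#' @param medication_prob Baseline probability of psychotropic medication in
#'   patients (log-odds shifted by standardized BDI so that medication is
#'   mood-correlated); controls take none.
#' @param streamline_scale,streamline_dispersion Negative-binomial mean
#'   scale (count per unit FA) and size for streamline counts.
#' @param length_mean_mm,length_sd_mm Mean fiber length distribution.
#' @param seed Default seed used when [generate_cohort()] is called without
#'   one.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_fnd = 85L, n_hc = 75L,
                             baseline_fa_mean = 0.40, baseline_fa_sd = 0.08,
                             link_density = 0.6,
                             planted_nodes = PAPER_LIKE_NODES,
                             node_effect_d = 1.0,
                             age_slope_per_year = -0.001,
                             sex_offset = 0.005,
                             mediator_coupling_bdi = -0.002,
                             mediator_coupling_stai = -0.001,
                             clinical_coupling_r = -0.5,
                             coupled_nodes = DEFAULT_COUPLED_NODES,
                             sfmdrs_zero_prob = 21 / 85,
                             medication_prob = 0.5,
                             streamline_scale = 500,
                             streamline_dispersion = 5,
                             length_mean_mm = 60, length_sd_mm = 15,
                             seed = 1L) {
  stopifnot(n_fnd >= 3, n_hc >= 3,
            link_density >= 0, link_density <= 1,
            sfmdrs_zero_prob >= 0, sfmdrs_zero_prob <= 1,
            medication_prob >= 0, medication_prob <= 1,
            abs(clinical_coupling_r) <= 1)
  rt_names <- load_region_table()$name
  bad <- setdiff(c(planted_nodes, coupled_nodes), rt_names)
  if (length(bad)) stop("unknown region name(s): ", paste(bad, collapse = ", "))
  structure(list(n_fnd = as.integer(n_fnd), n_hc = as.integer(n_hc),
                 baseline_fa_mean = baseline_fa_mean,
                 baseline_fa_sd = baseline_fa_sd,
                 link_density = link_density,
                 planted_nodes = as.character(planted_nodes),
                 node_effect_d = node_effect_d,
                 age_slope_per_year = age_slope_per_year,
                 sex_offset = sex_offset,
                 mediator_coupling_bdi = mediator_coupling_bdi,
                 mediator_coupling_stai = mediator_coupling_stai,
                 clinical_coupling_r = clinical_coupling_r,
                 coupled_nodes = as.character(coupled_nodes),
                 sfmdrs_zero_prob = sfmdrs_zero_prob,
                 medication_prob = medication_prob,
                 streamline_scale = streamline_scale,
                 streamline_dispersion = streamline_dispersion,
                 length_mean_mm = length_mean_mm,
                 length_sd_mm = length_sd_mm,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Named generator presets
#'
#' `null`: no planted effects, no mood-to-brain arrows, no clinical coupling
#' (for false-positive calibration). `paper_like`: the default configuration
#' (19 planted regions, mediation on, severity coupling on).
#' `strong_effect`: larger deficit (d = 1.5) and coupling (-0.7).
#' `mediation_off`: planted deficit without the mood-to-brain arrows.
#'
#' @return Named list of `generator_config` objects.
#' @export
default_scenarios <- function() {
  list(
    null = generator_config(planted_nodes = character(0), node_effect_d = 0,
                            mediator_coupling_bdi = 0,
                            mediator_coupling_stai = 0,
                            clinical_coupling_r = 0),
    paper_like = generator_config(),
    strong_effect = generator_config(node_effect_d = 1.5,
                                     clinical_coupling_r = -0.7),
    mediation_off = generator_config(mediator_coupling_bdi = 0,
                                     mediator_coupling_stai = 0)
  )
}

#' Write / read a generator configuration as JSON
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `path` invisibly; `read_generator_config` returns the config.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(generator_config, x)
}

# pooled within-group variance of the per-subject FA shift (closed form,
# from the configured score moments) — used to calibrate the planted deficit
shift_variance <- function(config) {
  v <- function(nm) mean(c(SCORE_MOMENTS[[nm]]$fnd[2]^2,
                           SCORE_MOMENTS[[nm]]$hc[2]^2))
  p <- FEMALE_FRACTION
  v_sex <- mean((1 - p) * p)  # male indicator variance per group
  config$age_slope_per_year^2 * v("age") +
    config$sex_offset^2 * v_sex +
    config$mediator_coupling_bdi^2 * v("bdi") +
    config$mediator_coupling_stai^2 * v("stai_trait")
}

#' Generate a synthetic case-control connectome cohort
#'
#' Reproducible given `(config, seed)`. The generative model: demographics
#' and mood scores drawn per group from interval-censored normals (scores
#' heap at the instrument floor/ceiling, as bounded questionnaires do) whose
#' post-censoring moments match the configured group means/sds; a shared
#' link-presence mask at `link_density`; per present link
#' FA ~ truncated-normal(baseline) plus age, sex and mood shifts, minus a
#' planted deficit on links incident to `planted_nodes` in patients,
#' clamped to [0.01, 0.95]; streamline counts over-dispersed and
#' proportional to FA, mean lengths normal on present links; clinical
#' severity scores driven by a latent axis coupled to the covariate-adjusted
#' weighted degree of `coupled_nodes`.
#'
#' The planted deficit is calibrated in closed form: each planted region's
#' links are lowered by `d * sd(WD) / k` (k incident present links; sd from
#' the configured variance components), so the marginal weighted-degree
#' difference at that region has standardized effect `node_effect_d`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param weights Which weight kinds to generate (`"fa"` is always
#'   required; drop the others to save memory in large-n calibration runs).
#' @return An object of class `fnd_cohort`: list with `cohort` (data.frame),
#'   `links` (named list of subjects x 3486 matrices), `wd` (subjects x 84,
#'   region names as columns), `mask` (logical length 3486), `region_table`,
#'   `ground_truth`, `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = config$seed,
                            weights = WEIGHT_KINDS) {
  stopifnot(inherits(config, "generator_config"))
  weights <- match.arg(weights, WEIGHT_KINDS, several.ok = TRUE)
  if (!"fa" %in% weights)
    stop("'fa' must be generated (weighted degree and severity depend on it)")
  set.seed(as.integer(seed))
  rt <- load_region_table()
  li <- link_index()
  n_f <- config$n_fnd
  n_h <- config$n_hc
  n <- n_f + n_h
  grp_fnd <- c(rep(TRUE, n_f), rep(FALSE, n_h))

  draw_score <- function(nm) {
    mm <- SCORE_MOMENTS[[nm]]
    pf <- cens_match(mm$fnd[1], mm$fnd[2], mm$range[1], mm$range[2])
    ph <- cens_match(mm$hc[1], mm$hc[2], mm$range[1], mm$range[2])
    c(rcensnorm(n_f, pf$mu, pf$sigma, mm$range[1], mm$range[2]),
      rcensnorm(n_h, ph$mu, ph$sigma, mm$range[1], mm$range[2]))
  }
  age <- draw_score("age")
  sex_female <- stats::runif(n) <
    ifelse(grp_fnd, FEMALE_FRACTION["fnd"], FEMALE_FRACTION["hc"])
  bdi <- draw_score("bdi")
  stai_t <- draw_score("stai_trait")
  stai_s <- draw_score("stai_state")
  med_logit <- stats::qlogis(config$medication_prob) +
    0.8 * (bdi - mean(bdi)) / stats::sd(bdi)
  medication <- grp_fnd & (stats::runif(n) < stats::plogis(med_logit))

  # link-presence mask shared by all subjects
  present <- stats::runif(N_LINKS) < config$link_density
  np <- sum(present)
  inc_i <- li$i[present] + 1L
  inc_j <- li$j[present] + 1L
  k_node <- tabulate(inc_i, N_REGIONS) + tabulate(inc_j, N_REGIONS)

  # planted deficit, closed-form calibration
  v_shift <- shift_variance(config)
  sd_wd <- sqrt(k_node * config$baseline_fa_sd^2 + k_node^2 * v_shift)
  delta_node <- numeric(N_REGIONS)
  planted_idx <- match(config$planted_nodes, rt$name)
  if (length(planted_idx) && config$node_effect_d > 0) {
    k_p <- k_node[planted_idx]
    if (any(k_p == 0))
      stop("planted region(s) with no present links: ",
           paste(rt$name[planted_idx[k_p == 0]], collapse = ", "))
    delta_node[planted_idx] <- config$node_effect_d * sd_wd[planted_idx] / k_p
    d_max <- min((config$baseline_fa_mean - 0.01) * k_p / sd_wd[planted_idx])
    if (config$node_effect_d > d_max)
      stop("requested node_effect_d = ", config$node_effect_d,
           " unreachable within FA bounds; attainable maximum ~ ",
           format(d_max, digits = 3))
  }
  # per present link: mean of the endpoint deficits (planted endpoints only)
  d_i <- delta_node[inc_i]
  d_j <- delta_node[inc_j]
  n_end <- (d_i > 0) + (d_j > 0)
  delta_present <- ifelse(n_end > 0, (d_i + d_j) / pmax(n_end, 1), 0)

  # FA: baseline truncated normal + subject-level shifts - planted deficit
  base <- matrix(rtruncnorm(n * np, config$baseline_fa_mean,
                            config$baseline_fa_sd, 0, 1), n, np)
  shift <- config$age_slope_per_year * (age - mean(age)) +
    config$sex_offset * as.numeric(!sex_female) +
    config$mediator_coupling_bdi * (bdi - mean(bdi)) +
    config$mediator_coupling_stai * (stai_t - mean(stai_t))
  base <- base + shift
  base[grp_fnd, ] <- base[grp_fnd, ] -
    matrix(delta_present, n_f, np, byrow = TRUE)
  base[base < 0.01] <- 0.01
  base[base > 0.95] <- 0.95
  fa <- matrix(0, n, N_LINKS)
  fa[, present] <- base
  subject_id <- c(sprintf("FND%03d", seq_len(n_f)),
                  sprintf("HC%03d", seq_len(n_h)))
  rownames(fa) <- subject_id
  wd <- wd_from_links(fa)
  colnames(wd) <- rt$name
  rownames(wd) <- subject_id

  # latent severity axis: covariate-adjusted WD at the coupled nodes,
  # standardized within group, so clinical_coupling_r is a partial-r target
  covs <- cbind(age = age, male = as.numeric(!sex_female), bdi = bdi,
                stai_t = stai_t)
  coupled_idx <- match(config$coupled_nodes, rt$name)
  # the axis u is the standardized mean of the coupled nodes' adjusted WD;
  # cor(u, node) = sqrt((1 + (m-1)*rbar)/m) under equicorrelation rbar, so
  # the coupling coefficient is rescaled to make the per-node partial
  # correlation hit the target
  severity_axis <- function(rows) {
    # drop covariates that are constant in the subgroup; with too few
    # subjects to adjust at all, fall back to centering
    cv <- covs[rows, , drop = FALSE]
    cv <- cv[, apply(cv, 2, stats::sd) > 0, drop = FALSE]
    if (length(rows) < ncol(cv) + 3) cv <- NULL
    wd_adj <- residualize(wd[rows, coupled_idx, drop = FALSE], cv)
    z <- scale(wd_adj)
    u <- rowMeans(z)
    m <- length(coupled_idx)
    rbar <- if (m > 1) {
      cm <- stats::cor(z)
      mean(cm[upper.tri(cm)])
    } else 0
    list(u = u / stats::sd(u),
         axis_cor = sqrt(max((1 + (m - 1) * rbar) / m, 1e-6)))
  }
  couple <- function(axis, r_target) {
    a <- max(min(r_target / axis$axis_cor, 0.99), -0.99)
    a * axis$u + sqrt(1 - a^2) * stats::rnorm(length(axis$u))
  }
  r_c <- config$clinical_coupling_r
  u_f <- severity_axis(which(grp_fnd))
  u_h <- severity_axis(which(!grp_fnd))

  # S-FMDRS: tobit-style floor censoring of a latent severity scale — a
  # score of 0 means no motor symptoms, so zeros are the least severe
  # patients, not random dropouts. Location/scale chosen so P(score = 0)
  # equals sfmdrs_zero_prob and the censored mean matches the configured
  # marginal mean; the marginal sd then lands nearby (documented).
  pi0 <- config$sfmdrs_zero_prob
  z_sev <- couple(u_f, r_c)
  if (pi0 >= 1 - 1e-12) {
    sfmdrs_f <- rep(0, n_f)
  } else if (pi0 <= 1e-12) {
    sfmdrs_f <- pmax(0, SFMDRS_MOMENTS[1] + SFMDRS_MOMENTS[2] * z_sev)
  } else {
    qz <- -stats::qnorm(pi0)
    s0 <- SFMDRS_MOMENTS[1] / (qz * stats::pnorm(qz) + stats::dnorm(qz))
    sfmdrs_f <- pmax(0, qz * s0 + s0 * z_sev)
  }
  cgi_f <- pmin(7, pmax(0, round(CGI_MOMENTS[1] +
                                   CGI_MOMENTS[2] * couple(u_f, r_c))))
  pf_mm <- SCORE_MOMENTS$sf36_physical_functioning
  pf_f_par <- cens_match(pf_mm$fnd[1], pf_mm$fnd[2], 0, 100)
  pf_h_par <- cens_match(pf_mm$hc[1], pf_mm$hc[2], 0, 100)
  sf36_pf <- c(rcensnorm(n_f, pf_f_par$mu, pf_f_par$sigma, 0, 100,
                         z = couple(u_f, -r_c)),
               rcensnorm(n_h, pf_h_par$mu, pf_h_par$sigma, 0, 100,
                         z = couple(u_h, -r_c)))
  dur_sd_log <- sqrt(log(1 + (DURATION_YEARS_MOMENTS[2] /
                                DURATION_YEARS_MOMENTS[1])^2))
  dur_mean_log <- log(DURATION_YEARS_MOMENTS[1] * 12) - dur_sd_log^2 / 2
  duration_f <- stats::rlnorm(n_f, dur_mean_log, dur_sd_log)

  cohort <- data.frame(
    subject_id = subject_id,
    group = ifelse(grp_fnd, "FND", "HC"),
    age = age,
    sex = ifelse(sex_female, "female", "male"),
    medication_any_psychotropic = medication,
    bdi = bdi, stai_state = stai_s, stai_trait = stai_t,
    sf36_physical_health = draw_score("sf36_physical_health"),
    sf36_mental_health = draw_score("sf36_mental_health"),
    sf36_general_health = draw_score("sf36_general_health"),
    sf36_physical_functioning = sf36_pf,
    sfmdrs = c(sfmdrs_f, rep(NA_real_, n_h)),
    cgi = c(cgi_f, rep(NA_real_, n_h)),
    illness_duration_months = c(duration_f, rep(NA_real_, n_h)),
    stringsAsFactors = FALSE)
  cohort <- validate_cohort(cohort)

  links <- list(fa = fa)
  if ("nstreamlines" %in% weights) {
    mu_cnt <- config$streamline_scale * base
    cnt <- matrix(0, n, N_LINKS)
    cnt[, present] <- pmax(1, stats::rnbinom(n * np,
                                             size = config$streamline_dispersion,
                                             mu = mu_cnt))
    rownames(cnt) <- subject_id
    links$nstreamlines <- cnt
  }
  if ("mean_length_mm" %in% weights) {
    len <- matrix(0, n, N_LINKS)
    len[, present] <- pmin(250, pmax(1, stats::rnorm(n * np,
                                                     config$length_mean_mm,
                                                     config$length_sd_mm)))
    rownames(len) <- subject_id
    links$mean_length_mm <- len
  }

  ground_truth <- list(
    planted_nodes = config$planted_nodes,
    node_effect_d = config$node_effect_d,
    delta_per_node = stats::setNames(delta_node[planted_idx],
                                     rt$name[planted_idx]),
    link_effects = data.frame(
      region_a = rt$name[inc_i[delta_present > 0]],
      region_b = rt$name[inc_j[delta_present > 0]],
      delta = delta_present[delta_present > 0],
      stringsAsFactors = FALSE),
    coupled_nodes = config$coupled_nodes,
    clinical_coupling_r = r_c,
    latent_coupling_coefficient =
      max(min(r_c / u_f$axis_cor, 0.99), -0.99),
    mediator_paths = list(
      bdi = config$mediator_coupling_bdi,
      stai_trait = config$mediator_coupling_stai),
    age_slope_per_year = config$age_slope_per_year,
    sex_offset = config$sex_offset,
    n_links_present = np)

  structure(list(cohort = cohort, links = links, wd = wd, mask = present,
                 region_table = rt, ground_truth = ground_truth,
                 config = config, seed = as.integer(seed)),
            class = "fnd_cohort")
}

#' Materialise subject connectome objects from a generated cohort
#'
#' @param sim An `fnd_cohort` from [generate_cohort()].
#' @param weight_kind Which weight kind to materialise.
#' @return List of `subject_connectome` objects.
#' @export
cohort_connectomes <- function(sim, weight_kind = "fa") {
  stopifnot(inherits(sim, "fnd_cohort"))
  weight_kind <- match.arg(weight_kind, WEIGHT_KINDS)
  values <- sim$links[[weight_kind]]
  if (is.null(values)) stop(weight_kind, " was not generated")
  lapply(seq_len(nrow(values)), function(s)
    subject_connectome(rownames(values)[s], weight_kind,
                       matrix_from_links(values[s, ])))
}

#' Write a generated cohort as an on-disk fixture set
#'
#' Writes `cohort.tsv`, one `<subject_id>_<weight_kind>.tsv` per subject and
#' generated weight kind, and `ground_truth.json`.
#'
#' @param sim An `fnd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "fnd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(sim$cohort, file.path(dir, "cohort.tsv"))
  for (kind in names(sim$links))
    for (cn in cohort_connectomes(sim, kind))
      write_connectome(cn, dir = dir)
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
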