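# Independent oracles and small fixtures shared across test files.

# brute-force weighted degree: explicit double loop over all node pairs
wd_oracle <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + m[i, j]
    out[i] <- s
  }
  out
}

# brute-force BH step-up: find the largest k with p_(k) <= k*q/m, reject
# the k smallest; adjusted p by the literal min-over-larger-ranks formula
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_max <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_max <- k
  reject_sorted <- seq_len(m) <= k_max
  adj_sorted <- numeric(m)
  for (k in seq_len(m))
    adj_sorted[k] <- min(1, min(ps[k:m] * m / (k:m)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  reject <- logical(m)
  reject[ord] <- reject_sorted
  list(p_adj = adj, significant = reject)
}

# random symmetric nonnegative 84x84 FA-like matrix with zero diagonal
random_fa_matrix <- function(density = 0.5) {
  m <- matrix(0, 84, 84)
  ut <- upper.tri(m)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.05, 0.9), 0)
  m[ut] <- vals
  m + t(m)
}

# minimal hand-built cohort, half FND half HC
make_test_cohort <- function(n_fnd = 10, n_hc = 10, seed = 1) {
  set.seed(seed)
  n <- n_fnd + n_hc
  grp <- c(rep("FND", n_fnd), rep("HC", n_hc))
  fnd <- grp == "FND"
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = grp,
    age = round(runif(n, 20, 60), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    medication_any_psychotropic = fnd & runif(n) < 0.5,
    bdi = round(ifelse(fnd, runif(n, 5, 30), runif(n, 0, 10)), 1),
    stai_state = round(runif(n, 25, 55), 1),
    stai_trait = round(ifelse(fnd, runif(n, 35, 60), runif(n, 25, 45)), 1),
    sf36_physical_health = round(runif(n, 20, 100), 1),
    sf36_mental_health = round(runif(n, 30, 95), 1),
    sf36_general_health = round(runif(n, 30, 95), 1),
    sf36_physical_functioning = round(runif(n, 40, 100), 1),
    sfmdrs = ifelse(fnd, round(runif(n, 0, 30), 1), NA_real_),
    cgi = ifelse(fnd, sample(0:7, n, replace = TRUE), NA_real_),
    illness_duration_months = ifelse(fnd, round(runif(n, 1, 200)), NA_real_),
    stringsAsFactors = FALSE)
}

# one moderately expensive large-n paper_like cohort, built once per test
# run and shared across test files (calibration and moment checks)
bign_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(
        generator_config(n_fnd = 10000L, n_hc = 10000L),
        seed = 7, weights = "fa")
    cache
  }
})
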