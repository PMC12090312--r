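#' Load the canonical 84-region parcellation table
#'
#' Returns the packaged Desikan-Killiany region table that fixes the node
#' indexing used throughout the package: 68 cortical regions (34 per
#' hemisphere, left then right) followed by 16 subcortical regions (8 per
#' hemisphere). Row order defines the canonical node index 0..83; all result
#' tables refer to regions by `name`, never by bare index.
#'
#' @return A data.frame with columns `index` (integer, 0..83), `name`
#'   (unique region label, e.g. `"left_precuneus"`), `hemisphere`
#'   (`"left"`/`"right"`) and `tissue_class` (`"cortical"`/`"subcortical"`).
#' @export
load_region_table <- function() {
  path <- system.file("extdata", "desikan_killiany_84.tsv", package = "fndconn",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_region_table(tab)
  tab
}

validate_region_table <- function(tab) {
  required <- c("index", "name", "hemisphere", "tissue_class")
  if (!all(required %in% names(tab)))
    stop("region table missing columns: ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  if (nrow(tab) != 84L)
    stop("region table must have exactly 84 rows, found ", nrow(tab))
  if (!identical(as.integer(tab$index), 0:83))
    stop("region indices must be contiguous 0..83 in row order")
  if (anyDuplicated(tab$name))
    stop("region names must be unique")
  n_cort <- sum(tab$tissue_class == "cortical")
  n_sub <- sum(tab$tissue_class == "subcortical")
  if (n_cort != 68L || n_sub != 16L)
    stop("region table must contain 68 cortical and 16 subcortical rows, ",
         "found ", n_cort, "/", n_sub)
  if (!all(tab$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  invisible(tab)
}

N_REGIONS <- 84L
N_LINKS <- 84L * 83L / 2L  # 3486 unordered region pairs

WEIGHT_KINDS <- c("fa", "nstreamlines", "mean_length_mm")

#' Construct a validated subject connectome
#'
#' @param subject_id Subject identifier.
#' @param weight_kind One of `"fa"`, `"nstreamlines"`, `"mean_length_mm"`.
#' @param matrix Symmetric nonnegative 84x84 matrix with zero diagonal.
#'   FA values may exceed 1 by at most 1e-9 (clamped to 1).
#' @return An object of class `subject_connectome`.
#' @export
subject_connectome <- function(subject_id, weight_kind, matrix) {
  weight_kind <- match.arg(weight_kind, WEIGHT_KINDS)
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !all(dim(m) == N_REGIONS))
    stop("connectome matrix must be numeric 84x84, got ",
         paste(dim(m), collapse = "x"))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9)
    stop("connectome matrix asymmetric beyond tolerance (max |m - t(m)| = ",
         format(asym), ")")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0))
    stop("connectome contains negative entries")
  if (weight_kind == "fa") {
    if (any(m > 1 + 1e-9))
      stop("FA entries must be <= 1 (max ", format(max(m)), ")")
    m[m > 1] <- 1
  }
  if (weight_kind == "nstreamlines") {
    if (any(abs(m - round(m)) > 1e-9))
      stop("streamline counts must be nonnegative integers")
    m <- round(m)
  }
  dimnames(m) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 weight_kind = weight_kind, matrix = m),
            class = "subject_connectome")
}

#' Read a subject connectome from delimited text
#'
#' Expects an 84x84 numeric matrix as CSV or TSV (delimiter auto-detected),
#' optionally preceded by a header row of region names. The subject id is
#' taken from the filename pattern `<subject_id>_<weight_kind>.<ext>` unless
#' given explicitly.
#'
#' @param path File path.
#' @param weight_kind Weight kind stored in the file.
#' @param subject_id Optional explicit subject id.
#' @return A `subject_connectome`.
#' @export
read_connectome <- function(path, weight_kind, subject_id = NULL) {
  weight_kind <- match.arg(weight_kind, WEIGHT_KINDS)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !all(grepl("^[-+0-9.eE ]*$",
                           strsplit(first, sep, fixed = TRUE)[[1]]))
  m <- as.matrix(utils::read.table(path, sep = sep, header = has_header))
  if (is.null(subject_id)) {
    base <- sub("\\.[^.]+$", "", basename(path))
    subject_id <- sub(paste0("_", weight_kind, "$"), "", base)
  }
  subject_connectome(subject_id, weight_kind, m)
}

#' Write a subject connectome to delimited text
#'
#' @param x A `subject_connectome`.
#' @param dir Output directory; the file is named
#'   `<subject_id>_<weight_kind>.tsv`. Alternatively pass `path` directly.
#' @param path Optional explicit file path (overrides `dir`).
#' @param region_names Optional character vector of 84 region names written
#'   as header.
#' @return The file path, invisibly.
#' @export
write_connectome <- function(x, dir = ".", path = NULL, region_names = NULL) {
  stopifnot(inherits(x, "subject_connectome"))
  if (is.null(path))
    path <- file.path(dir, paste0(x$subject_id, "_", x$weight_kind, ".tsv"))
  m <- x$matrix
  if (!is.null(region_names)) {
    stopifnot(length(region_names) == N_REGIONS)
    colnames(m) <- region_names
  }
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(region_names))
  invisible(path)
}

COHORT_NUMERIC <- c("age", "bdi", "stai_state", "stai_trait",
                    "sf36_physical_health", "sf36_mental_health",
                    "sf36_general_health", "sf36_physical_functioning",
                    "sfmdrs", "cgi", "illness_duration_months")
FND_ONLY_FIELDS <- c("sfmdrs", "cgi", "illness_duration_months")

#' Validate a cohort metadata table
#'
#' Enforces the cohort contract: unique subject ids; `group` in
#' `{FND, HC}`; `sex` in `{female, male}`; no missing group/age/sex; the
#' clinical fields `sfmdrs`, `cgi` and `illness_duration_months` missing (NA)
#' for every healthy control. Enumerations are normalised case-insensitively.
#'
#' @param cohort A data.frame.
#' @return The normalised cohort data.frame, invisibly usable.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject_id", "group", "age", "sex",
                "medication_any_psychotropic", COHORT_NUMERIC)
  miss <- setdiff(required, names(cohort))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  cohort$subject_id <- as.character(cohort$subject_id)
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id values")
  grp <- toupper(trimws(as.character(cohort$group)))
  if (!all(grp %in% c("FND", "HC")))
    stop("unknown group label(s): ",
         paste(unique(grp[!grp %in% c("FND", "HC")]), collapse = ", "))
  cohort$group <- grp
  sx <- tolower(trimws(as.character(cohort$sex)))
  if (!all(sx %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  cohort$sex <- sx
  cohort$medication_any_psychotropic <-
    as.logical(cohort$medication_any_psychotropic)
  for (v in COHORT_NUMERIC) cohort[[v]] <- as.numeric(cohort[[v]])
  if (anyNA(cohort$age) || anyNA(cohort$group) || anyNA(cohort$sex))
    stop("group, age and sex must be complete")
  hc <- cohort$group == "HC"
  for (v in FND_ONLY_FIELDS) {
    bad <- hc & !is.na(cohort[[v]])
    if (any(bad))
      stop("healthy controls must have missing ", v, " (subjects: ",
           paste(cohort$subject_id[bad], collapse = ", "), ")")
  }
  neg <- c("bdi", "sfmdrs", "illness_duration_months")
  for (v in neg) if (any(cohort[[v]] < 0, na.rm = TRUE))
    stop(v, " must be nonnegative")
  if (any(cohort$cgi < 0 | cohort$cgi > 7, na.rm = TRUE))
    stop("cgi must lie in 0..7")
  cohort
}

#' Read a cohort table from delimited text
#'
#' Missing clinical values are encoded as empty fields (or NA) in the file
#' and as `NA` in memory; `0` is a valid score and never used as a missing
#' marker.
#'
#' @param path CSV or TSV file with a header.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  cohort <- utils::read.table(path, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE,
                              na.strings = c("", "NA"))
  validate_cohort(cohort)
}

#' Write a cohort table to TSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  for (v in names(out)) if (is.numeric(out[[v]]))
    out[[v]] <- format(out[[v]], digits = 17, trim = TRUE, scientific = FALSE)
  out[is.na(cohort)] <- ""
  out[out == "NA"] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
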