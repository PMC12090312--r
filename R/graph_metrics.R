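#' Canonical link index for the 84-node graph
#'
#' Enumerates all 3486 unordered region pairs in row-major order over the
#' strict upper triangle: (0,1), (0,2), ..., (0,83), (1,2), ... This order is
#' fixed so that link-level result tables are comparable across runs.
#'
#' @return A data.frame with integer columns `i` and `j` (0-based node
#'   indices, `i < j`) and 3486 rows.
#' @export
link_index <- function() {
  idx <- which(upper.tri(matrix(0, N_REGIONS, N_REGIONS)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  data.frame(i = as.integer(idx[ord, "row"] - 1L),
             j = as.integer(idx[ord, "col"] - 1L))
}

# subjects x 3486 row extraction: upper triangle of m in canonical order
upper_tri_values <- function(m) {
  li <- link_index()
  m[cbind(li$i + 1L, li$j + 1L)]
}

# inverse of upper_tri_values: symmetric matrix from a length-3486 vector
matrix_from_links <- function(values) {
  stopifnot(length(values) == N_LINKS)
  li <- link_index()
  m <- matrix(0, N_REGIONS, N_REGIONS)
  m[cbind(li$i + 1L, li$j + 1L)] <- values
  m + t(m)
}

#' Weighted degree (node strength) of a connectome
#'
#' For each region i, sums the weights of all links incident to i:
#' WD_i = sum_{j != i} w_ij. On FA-weighted graphs this is the integrative
#' local microstructural-integrity summary used throughout the package.
#' Absent links carry weight 0 and contribute nothing.
#'
#' @param connectome A `subject_connectome`.
#' @return Named list with `subject_id` and `values`, a numeric vector of
#'   length 84 in canonical node order.
#' @export
weighted_degree <- function(connectome) {
  stopifnot(inherits(connectome, "subject_connectome"))
  v <- rowSums(connectome$matrix)
  list(subject_id = connectome$subject_id, values = unname(v))
}

#' Link-value table for a set of connectomes
#'
#' @param connectomes List of `subject_connectome`, all of the same weight
#'   kind.
#' @return A subjects x 3486 numeric matrix in canonical link order, with
#'   subject ids as row names.
#' @export
link_values <- function(connectomes) {
  stopifnot(length(connectomes) > 0)
  kinds <- unique(vapply(connectomes, `[[`, "", "weight_kind"))
  if (length(kinds) != 1L)
    stop("mixed weight kinds: ", paste(kinds, collapse = ", "))
  out <- t(vapply(connectomes, function(x) upper_tri_values(x$matrix),
                  numeric(N_LINKS)))
  rownames(out) <- vapply(connectomes, `[[`, "", "subject_id")
  out
}

#' Weighted degree from a link-value matrix
#'
#' Equivalent to applying [weighted_degree()] subject by subject: each link
#' contributes its weight to both endpoints.
#'
#' @param values Subjects x 3486 matrix in canonical link order.
#' @return Subjects x 84 matrix of weighted degrees.
#' @export
wd_from_links <- function(values) {
  values <- rbind(values)
  stopifnot(ncol(values) == N_LINKS)
  li <- link_index()
  inc <- matrix(0, N_LINKS, N_REGIONS)
  inc[cbind(seq_len(N_LINKS), li$i + 1L)] <- 1
  inc[cbind(seq_len(N_LINKS), li$j + 1L)] <- 1
  values %*% inc
}

#' Export weighted degrees as TSV with region-name header
#'
#' @param wd Subjects x 84 matrix (row names = subject ids).
#' @param region_table Region table from [load_region_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wd_table <- function(wd, region_table, path) {
  stopifnot(ncol(wd) == N_REGIONS)
  out <- data.frame(subject_id = rownames(wd),
                    format(wd, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
  names(out) <- c("subject_id", region_table$name)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
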