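#' Sites-by-samples presence/absence matrix
#'
#' The central analysis container: one row per variant site, one column per
#' sample, entries 0 (absent), 1 (present) or `NA` (missing, typically after
#' depth masking). Site coordinates are carried alongside so windowed and
#' interval-based operations need no external lookup.
#'
#' @param presence integer matrix (sites x samples) with entries 0, 1 or `NA`.
#' @param site_ids character vector of unique site identifiers, one per row.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column.
#' @param positions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `svtype`, one row per site.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(presence, site_ids, sample_ids, positions) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (nrow(presence) != length(site_ids))
    stop("presence has ", nrow(presence), " rows but ", length(site_ids),
         " site ids")
  if (ncol(presence) != length(sample_ids))
    stop("presence has ", ncol(presence), " columns but ", length(sample_ids),
         " sample ids")
  vals <- presence[!is.na(presence)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("presence entries must be 0, 1 or NA")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  positions <- as.data.frame(positions)
  stopifnot(all(c("chrom", "start", "end") %in% names(positions)),
            nrow(positions) == nrow(presence))
  dimnames(presence) <- list(site_ids, sample_ids)
  structure(list(presence = presence,
                 site_ids = as.character(site_ids),
                 sample_ids = as.character(sample_ids),
                 positions = positions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_sites(x), " sites x ", n_samples(x),
      " samples\n", sep = "")
  miss <- mean(is.na(x$presence))
  cat(sprintf("  missing entries: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites (rows) in a genotype matrix
#' @param x a `genotype_matrix`.
#' @export
n_sites <- function(x) nrow(x$presence)

#' Number of samples (columns) in a genotype matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) ncol(x$presence)

#' Subset a genotype matrix by site index
#' @param x a `genotype_matrix`.
#' @param i integer or logical index over sites.
#' @export
subset_sites <- function(x, i) {
  genotype_matrix(x$presence[i, , drop = FALSE],
                  x$site_ids[i], x$sample_ids,
                  x$positions[i, , drop = FALSE])
}

#' Convert SV records to a binary genotype matrix
#'
#' Repackages the per-sample carrier calls of an [sv_records] set into a
#' [genotype_matrix], preserving record order and coordinates.
#'
#' @param records an `sv_records` object.
#' @return a `genotype_matrix` with one row per record.
#' @export
to_binary_matrix <- function(records) {
  stopifnot(inherits(records, "sv_records"))
  genotype_matrix(records$carriers,
                  records$sites$site_id,
                  records$sample_ids,
                  records$sites[, c("chrom", "start", "end", "svtype")])
}

#' Write a genotype matrix as TSV
#' @param x a `genotype_matrix`.
#' @param path output file.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- cbind(site_id = x$site_ids, x$positions,
              as.data.frame(x$presence, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
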