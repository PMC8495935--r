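#' Filter configuration for the SV quality cascade
#'
#' Defaults encode the study design: paired-end support of at least 4
#' ("more than 3"), a PRECISE breakpoint, no break-end (BND) records, sizes
#' between 50 bp and 100 kb inclusive, at most 20% missing genotypes per
#' site, and a minor-allele frequency of at least 0.05.
#'
#' @param min_pe_support minimum paired-end read support (keep if
#'   `pe_support >= min_pe_support`).
#' @param require_precise drop records without a PRECISE breakpoint flag.
#' @param drop_bnd drop BND / unknown-architecture records.
#' @param min_size_bp,max_size_bp inclusive size bounds in bp.
#' @param max_missing_fraction remove sites whose missing fraction is
#'   strictly greater than this.
#' @param min_maf keep sites whose minor-carrier frequency is `>= min_maf`.
#' @param maf_denominator `"panel"` divides the minor carrier count by the
#'   panel size (so 0.05 on 347 samples means at least 18 carriers);
#'   `"nonmissing"` divides by the nonmissing count at the site.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_pe_support = 4, require_precise = TRUE,
                          drop_bnd = TRUE, min_size_bp = 50,
                          max_size_bp = 100000, max_missing_fraction = 0.20,
                          min_maf = 0.05,
                          maf_denominator = c("panel", "nonmissing")) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 0.5, min_size_bp <= max_size_bp)
  structure(list(min_pe_support = min_pe_support,
                 require_precise = require_precise,
                 drop_bnd = drop_bnd,
                 min_size_bp = min_size_bp,
                 max_size_bp = max_size_bp,
                 max_missing_fraction = max_missing_fraction,
                 min_maf = min_maf,
                 maf_denominator = match.arg(maf_denominator)),
            class = "filter_config")
}

#' Fraction of missing genotype calls at a site
#' @param x site vector of 0/1/`NA` calls.
#' @return missing entries / total samples, in `[0, 1]`.
#' @export
site_missing_fraction <- function(x) {
  if (!length(x)) stop("site has no samples")
  mean(is.na(x))
}

#' Minor-carrier count at a site
#'
#' The number of genotypes carrying the rarer state, computed over
#' nonmissing calls: `min(#present, #absent)`.
#'
#' @param x site vector of 0/1/`NA` calls.
#' @export
minor_carrier_count <- function(x) {
  m <- sum(!is.na(x))
  if (m == 0) stop("all calls missing at site")
  ones <- sum(x, na.rm = TRUE)
  min(ones, m - ones)
}

#' Minimum carrier count implied by a MAF threshold
#'
#' The smallest integer `c` with `c / n_samples >= min_maf`, i.e.
#' `ceiling(min_maf * n_samples)`. With 347 samples and a 5% threshold this
#' is 18 carriers.
#'
#' @param n_samples panel size.
#' @param min_maf frequency threshold.
#' @export
maf_threshold_count <- function(n_samples, min_maf) {
  stopifnot(n_samples >= 1)
  as.integer(ceiling(min_maf * n_samples))
}

#' Apply the staged SV filter cascade
#'
#' Stages are applied in fixed order: paired-end support, breakpoint
#' precision, BND removal, size bounds, per-site missingness, and (last,
#' optional) minor-allele frequency. The site frequency spectrum uses the
#' pre-MAF survivor set, so both sets are returned together with a
#' per-stage, per-svtype tally of survivors.
#'
#' @param records an [sv_records] set (depth masking already applied by
#'   [read_sv_vcf]).
#' @param config a [filter_config].
#' @param apply_maf include the MAF stage in the returned `records`
#'   (the tally always includes its column).
#' @return list with `records` (final survivors), `pre_maf` (survivors
#'   before the MAF stage) and `tally` (a `filter_tally` data.frame,
#'   svtype x stage, plus size summaries as attributes).
#' @export
filter_cascade <- function(records, config = filter_config(),
                           apply_maf = TRUE) {
  stopifnot(inherits(records, "sv_records"))
  s <- records$sites
  n <- nrow(s)
  keep <- rep(TRUE, n)
  stage_keep <- list()

  keep <- keep & s$pe_support >= config$min_pe_support
  stage_keep$pair_end <- keep
  if (config$require_precise) keep <- keep & s$precise
  stage_keep$precise <- keep
  if (config$drop_bnd) keep <- keep & !s$svtype %in% c("BND", "unknown")
  stage_keep$bnd <- keep
  size_ok <- !is.na(s$length_bp) &
    s$length_bp >= config$min_size_bp & s$length_bp <= config$max_size_bp
  keep <- keep & (size_ok | s$svtype %in% c("BND", "unknown"))
  stage_keep$size <- keep
  if (n > 0) {
    missfrac <- rowMeans(is.na(records$carriers))
    keep <- keep & missfrac <= config$max_missing_fraction
  }
  stage_keep$missing <- keep
  pre_maf <- subset_records(records, which(stage_keep$missing))

  maf_keep <- keep
  if (n > 0) {
    idx <- which(keep)
    for (i in idx) {
      x <- records$carriers[i, ]
      m <- sum(!is.na(x))
      if (m == 0) { maf_keep[i] <- FALSE; next }
      minor <- minor_carrier_count(x)
      denom <- if (config$maf_denominator == "panel") length(x) else m
      maf_keep[i] <- (minor / denom) >= config$min_maf
    }
  }
  stage_keep$maf <- maf_keep

  final <- subset_records(records,
                          which(if (apply_maf) maf_keep else keep))
  tally <- build_tally(s, stage_keep)
  list(records = final, pre_maf = pre_maf, tally = tally)
}

subset_records <- function(records, i) {
  sv_records(records$sites[i, , drop = FALSE],
             records$carriers[i, , drop = FALSE],
             records$depths[i, , drop = FALSE],
             records$sample_ids)
}

# Survivor counts per stage per svtype, Table-1 shaped, with size summaries
# of the final survivor set attached as attributes.
build_tally <- function(sites, stage_keep) {
  types <- c("DEL", "DUP", "INV", "BND")
  tycol <- sites$svtype
  tycol[tycol == "unknown"] <- "BND"
  stages <- c("no_filters", names(stage_keep))
  tab <- matrix(0L, length(types) + 1, length(stages),
                dimnames = list(c("Total", types), stages))
  count_by <- function(keep) {
    tt <- table(factor(tycol[keep], levels = types))
    c(sum(keep), as.integer(tt))
  }
  tab[, "no_filters"] <- count_by(rep(TRUE, nrow(sites)))
  for (st in names(stage_keep)) tab[, st] <- count_by(stage_keep[[st]])
  out <- as.data.frame(tab)
  final <- stage_keep[[length(stage_keep)]]
  sizes <- sites$length_bp[final]
  sizes <- sizes[!is.na(sizes)]
  attr(out, "size_summary") <- if (length(sizes)) {
    c(min = min(sizes), max = max(sizes), median = stats::median(sizes))
  } else c(min = NA_real_, max = NA_real_, median = NA_real_)
  class(out) <- c("filter_tally", "data.frame")
  out
}

#' Write a filter tally as TSV
#' @param tally a `filter_tally`.
#' @param path output file.
#' @export
write_tally_tsv <- function(tally, path) {
  df <- cbind(svtype = rownames(tally), as.data.frame(tally))
  ss <- attr(tally, "size_summary")
  df$min_size <- c(ss["min"], rep(NA, nrow(df) - 1))
  df$max_size <- c(ss["max"], rep(NA, nrow(df) - 1))
  df$median_size <- c(ss["median"], rep(NA, nrow(df) - 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
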