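#' Overlap deletion sites with gene and CDS intervals
#'
#' A site is "within" a feature when its `[start, end]` interval intersects
#' the feature interval by at least 1 bp (both 1-based inclusive). Sites on
#' chromosomes absent from the annotation get `in_gene = in_cds = FALSE`;
#' this is reported once per call.
#'
#' @param gmat a [genotype_matrix].
#' @param features list with `genes` and `cds` `GRanges`, as returned by
#'   [read_gene_annotation].
#' @param ann optional character vector of snpEff-style `ANN` strings, one
#'   per site, parsed by [parse_impact].
#' @param containment require full containment of the site in the feature
#'   instead of any overlap.
#' @return data.frame with `site_id`, `in_gene`, `in_cds`,
#'   `overlapped_gene_ids` (comma-separated) and `impact_class`.
#' @export
overlap_features <- function(gmat, features, ann = NULL,
                             containment = FALSE) {
  pos <- gmat$positions
  gr <- GenomicRanges::GRanges(pos$chrom,
                               IRanges::IRanges(pos$start, pos$end))
  seen <- unique(c(as.character(GenomicRanges::seqnames(features$genes)),
                   as.character(GenomicRanges::seqnames(features$cds))))
  absent <- setdiff(unique(pos$chrom), seen)
  if (length(absent))
    message("no annotation for chromosome(s): ",
            paste(absent, collapse = ", "))
  type <- if (containment) "within" else "any"
  # disjoint seqlevels are the already-reported "no annotation" case
  hits_g <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, features$genes, type = type))
  hits_c <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, features$cds, type = type))
  in_gene <- seq_along(gr) %in% S4Vectors::queryHits(hits_g)
  in_cds <- seq_along(gr) %in% S4Vectors::queryHits(hits_c)

  gene_ids <- rep("", length(gr))
  if (length(hits_g)) {
    meta <- S4Vectors::mcols(features$genes)
    idcol <- intersect(c("ID", "Name", "gene_id"), colnames(meta))[1]
    ids <- if (!is.na(idcol)) as.character(meta[[idcol]]) else
      paste0("gene", seq_along(features$genes))
    by_q <- split(ids[S4Vectors::subjectHits(hits_g)],
                  S4Vectors::queryHits(hits_g))
    gene_ids[as.integer(names(by_q))] <-
      vapply(by_q, function(v) paste(unique(v), collapse = ","), "")
  }
  impact <- if (is.null(ann)) rep("none", length(gr)) else parse_impact(ann)
  data.frame(site_id = gmat$site_ids, in_gene = in_gene, in_cds = in_cds,
             overlapped_gene_ids = gene_ids, impact_class = impact,
             stringsAsFactors = FALSE)
}

#' Parse snpEff ANN strings into a single impact class
#'
#' Each `ANN` entry is pipe-delimited with the impact in the third field
#' (HIGH, MODERATE, LOW or MODIFIER); a site's class is the most severe
#' impact over its comma-separated entries. Empty, missing or unparseable
#' strings yield `"none"`.
#'
#' @param ann character vector of ANN strings.
#' @return character vector in `{"high","moderate","low","modifier","none"}`.
#' @export
parse_impact <- function(ann) {
  sev <- c(high = 4, moderate = 3, low = 2, modifier = 1)
  vapply(ann, function(s) {
    if (is.na(s) || !nzchar(s)) return("none")
    entries <- strsplit(s, ",", fixed = TRUE)[[1]]
    classes <- vapply(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(f) < 3) return(NA_character_)
      tolower(f[3])
    }, NA_character_)
    classes <- classes[classes %in% names(sev)]
    if (!length(classes)) return("none")
    names(which.max(sev[classes]))
  }, "", USE.NAMES = FALSE)
}

#' Per-chromosome deletion summary
#'
#' Counts, density, size range, genic/CDS overlap and high+moderate impact
#' tallies per chromosome, with percentages of the grand total.
#'
#' @param gmat a [genotype_matrix] of deletions.
#' @param overlaps data.frame from [overlap_features].
#' @param chrom_lengths optional data.frame (`chrom`, `length`); density per
#'   100 kb is omitted (`NA`) for chromosomes without a length.
#' @return data.frame with one row per chromosome.
#' @export
per_chromosome_summary <- function(gmat, overlaps, chrom_lengths = NULL) {
  if (n_sites(gmat) == 0)
    return(data.frame(chrom = character(), n = integer(),
                      pct = numeric(), per_100kb = numeric(),
                      min_size = integer(), max_size = integer(),
                      n_genic = integer(), pct_genic = numeric(),
                      n_cds = integer(), pct_cds = numeric(),
                      n_impact = integer()))
  pos <- gmat$positions
  stopifnot(nrow(overlaps) == nrow(pos))
  size <- pos$end - pos$start + 1L
  impact_hit <- overlaps$impact_class %in% c("high", "moderate")
  chroms <- sort(unique(pos$chrom))
  total <- nrow(pos)
  rows <- lapply(chroms, function(ch) {
    i <- pos$chrom == ch
    len <- if (!is.null(chrom_lengths) && ch %in% chrom_lengths$chrom)
      chrom_lengths$length[match(ch, chrom_lengths$chrom)] else NA_real_
    data.frame(chrom = ch, n = sum(i),
               pct = 100 * sum(i) / total,
               per_100kb = if (is.na(len)) NA_real_ else
                 sum(i) / (len / 1e5),
               min_size = min(size[i]), max_size = max(size[i]),
               n_genic = sum(overlaps$in_gene[i]),
               pct_genic = 100 * sum(overlaps$in_gene[i]) / total,
               n_cds = sum(overlaps$in_cds[i]),
               pct_cds = 100 * sum(overlaps$in_cds[i]) / total,
               n_impact = sum(impact_hit[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
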