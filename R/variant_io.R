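#' Structural-variant record set
#'
#' A compact columnar container for the rows of a multi-sample SV VCF:
#' per-site fields (coordinates, type, length, breakpoint precision,
#' paired-end support) plus aligned carrier and depth matrices, one column
#' per panel sample. Carrier calls are 0 (absent), 1 (present, any alternate
#' allele) or `NA` (missing).
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `start`, `end`,
#'   `svtype`, `length_bp`, `precise`, `pe_support`, `flagged`.
#' @param carriers integer matrix, sites x samples, entries 0/1/`NA`.
#' @param depths integer matrix, sites x samples, non-negative (`NA` allowed
#'   when the VCF carries no depth field).
#' @param sample_ids character vector of sample names.
#' @return an object of class `sv_records`.
#' @export
sv_records <- function(sites, carriers, depths, sample_ids) {
  sites <- as.data.frame(sites)
  need <- c("site_id", "chrom", "start", "end", "svtype", "length_bp",
            "precise", "pe_support", "flagged")
  stopifnot(all(need %in% names(sites)))
  carriers <- as.matrix(carriers); storage.mode(carriers) <- "integer"
  depths <- as.matrix(depths); storage.mode(depths) <- "integer"
  stopifnot(nrow(carriers) == nrow(sites), nrow(depths) == nrow(sites),
            ncol(carriers) == length(sample_ids),
            ncol(depths) == length(sample_ids))
  non_bnd <- !sites$svtype %in% c("BND", "unknown")
  if (any(non_bnd & sites$end < sites$start))
    stop("end < start for a non-BND record: ",
         sites$site_id[which(non_bnd & sites$end < sites$start)[1]])
  structure(list(sites = sites, carriers = carriers, depths = depths,
                 sample_ids = as.character(sample_ids)),
            class = "sv_records")
}

#' @export
print.sv_records <- function(x, ...) {
  cat("sv_records: ", nrow(x$sites), " sites x ", length(x$sample_ids),
      " samples\n", sep = "")
  print(table(x$sites$svtype))
  invisible(x)
}

# Pull a single INFO tag value (or NA) out of raw INFO strings.
info_tag <- function(info, tag) {
  out <- rep(NA_character_, length(info))
  hit <- regexpr(paste0("(^|;)", tag, "=[^;]*"), info)
  val <- regmatches(info, hit)
  out[hit > 0] <- sub(paste0("^;?", tag, "="), "", unlist(val))
  out
}

info_flag <- function(info, flag) {
  grepl(paste0("(^|;)", flag, "($|;)"), info)
}

#' Read a multi-sample SV VCF with depth-based genotype masking
#'
#' Parses an svtools/LUMPY-style VCF (INFO tags `SVTYPE`, `END`, `SVLEN`,
#' `PE`, flags `PRECISE`/`IMPRECISE`) into an [sv_records] set. Any sample
#' whose read depth at a site is below `min_depth` is set to missing
#' regardless of its genotype call; genotype calls carrying any alternate
#' allele map to present, homozygous reference to absent, uncalled to
#' missing. Depth is taken from FORMAT `DP` when present, otherwise from the
#' sum of `AD`; when neither exists the depth filter passes.
#'
#' @param path VCF file (plain or bgzipped).
#' @param min_depth minimum per-sample read depth for a nonmissing call
#'   (default 10).
#' @return an `sv_records` object. Records with an unrecognised `SVTYPE` are
#'   retained with `svtype = "unknown"` and `flagged = TRUE`.
#' @export
read_sv_vcf <- function(path, min_depth = 10) {
  stopifnot(min_depth >= 0)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  sample_ids <- colnames(vcf@gt)[-1]
  ns <- length(sample_ids)
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_sv_records(sample_ids))
  }
  info <- fix[, "INFO"]
  chrom <- fix[, "CHROM"]
  start <- as.integer(fix[, "POS"])
  svtype <- info_tag(info, "SVTYPE")
  known <- c("DEL", "DUP", "INV", "BND")
  flagged <- is.na(svtype) | !svtype %in% known
  svtype[flagged] <- "unknown"
  end <- suppressWarnings(as.integer(info_tag(info, "END")))
  end[is.na(end)] <- start[is.na(end)]
  svlen <- suppressWarnings(as.integer(info_tag(info, "SVLEN")))
  length_bp <- ifelse(!is.na(svlen), abs(svlen), end - start + 1L)
  length_bp[svtype %in% c("BND", "unknown")] <- NA_integer_
  pe <- suppressWarnings(as.integer(info_tag(info, "PE")))
  pe[is.na(pe)] <- 0L
  precise <- info_flag(info, "PRECISE") & !info_flag(info, "IMPRECISE")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), ncol = ns)
  alleles <- gsub("[|/]", "", gt)
  carriers <- matrix(NA_integer_, nrow(fix), ns)
  called <- !is.na(gt) & !grepl("\\.", gt)
  carriers[called & grepl("[1-9]", alleles)] <- 1L
  carriers[called & !grepl("[1-9]", alleles)] <- 0L

  fmt <- vcf@gt[, 1]
  depths <- matrix(NA_integer_, nrow(fix), ns)
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                            as.numeric = TRUE))
    depths <- matrix(as.integer(dp), nrow(fix), ns)
  } else if (any(grepl("(^|:)AD(:|$)", fmt))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    depths <- matrix(vapply(ad, function(s) {
      if (is.na(s)) return(NA_integer_)
      sum(suppressWarnings(as.integer(strsplit(s, ",")[[1]])), na.rm = TRUE)
    }, integer(1)), nrow(fix), ns)
  }
  # depth masking: a known depth below threshold overrides the call
  low <- !is.na(depths) & depths < min_depth
  carriers[low] <- NA_integer_

  site_id <- paste(chrom, start, end, svtype, sep = "_")
  sv_records(data.frame(site_id = site_id, chrom = chrom, start = start,
                        end = end, svtype = svtype, length_bp = length_bp,
                        precise = precise, pe_support = pe,
                        flagged = flagged, stringsAsFactors = FALSE),
             carriers, depths, sample_ids)
}

empty_sv_records <- function(sample_ids) {
  sv_records(data.frame(site_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        svtype = character(), length_bp = integer(),
                        precise = logical(), pe_support = integer(),
                        flagged = logical(), stringsAsFactors = FALSE),
             matrix(integer(), 0, length(sample_ids)),
             matrix(integer(), 0, length(sample_ids)),
             sample_ids)
}

#' Write SV records as a plain-text VCF
#'
#' Emits an svtools-flavoured VCF (INFO `SVTYPE`, `END`, `SVLEN`, `PE`,
#' `PRECISE`/`IMPRECISE`; FORMAT `GT:DP`) that [read_sv_vcf] reads back to an
#' identical record set. Deletion `SVLEN` is written with a negative sign per
#' convention.
#'
#' @param records an `sv_records` object.
#' @param path output file.
#' @param contigs optional data.frame (`chrom`, `length`) for contig header
#'   lines.
#' @export
write_sv_vcf <- function(records, path, contigs = NULL) {
  stopifnot(inherits(records, "sv_records"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svpopgen",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Number of paired-end reads supporting the variant\">",
           "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise structural variant\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variant\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$chrom, as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", records$sample_ids),
                      collapse = "\t"))
  s <- records$sites
  n <- nrow(s)
  body <- character(n)
  if (n > 0) {
    svlen <- ifelse(s$svtype == "DEL", -s$length_bp, s$length_bp)
    info <- paste0("SVTYPE=", ifelse(s$svtype == "unknown", "UNK", s$svtype),
                   ";END=", s$end,
                   ifelse(is.na(svlen), "", paste0(";SVLEN=", svlen)),
                   ";PE=", s$pe_support,
                   ifelse(s$precise, ";PRECISE", ";IMPRECISE"))
    gt <- matrix("./.", n, length(records$sample_ids))
    gt[which(records$carriers == 0L)] <- "0/0"
    gt[which(records$carriers == 1L)] <- "0/1"
    dp <- matrix(".", n, length(records$sample_ids))
    dp[!is.na(records$depths)] <- records$depths[!is.na(records$depths)]
    cells <- matrix(paste0(gt, ":", dp), n)
    alt <- paste0("<", ifelse(s$svtype == "unknown", "UNK", s$svtype), ">")
    body <- paste(s$chrom, s$start, s$site_id, "N", alt, ".", "PASS",
                  info, "GT:DP",
                  apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene and CDS intervals from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @return list with `genes` and `cds`, each a `GRanges` (1-based inclusive).
#'   CDS intervals falling outside every gene are tolerated but reported with
#'   a message.
#' @export
read_gene_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  genes <- gr[!is.na(gr$type) & gr$type == "gene"]
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(cds) && length(genes)) {
    orphans <- sum(IRanges::countOverlaps(cds, genes, type = "within") == 0)
    if (orphans > 0)
      message(orphans, " CDS interval(s) not contained in any gene")
  }
  list(genes = genes, cds = cds)
}

#' Read a sample metadata table
#'
#' Accepts a tab- or comma-delimited table with a `sample_id` column and
#' optional `country`, `region`, `race` and `cluster` columns; absent or
#' empty origin fields become `"Unknown"`.
#'
#' @param path delimited text file.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"sample_id" %in% names(md)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[anyDuplicated(md$sample_id)])
  for (col in c("country", "region", "race")) {
    if (!col %in% names(md)) md[[col]] <- "Unknown"
    md[[col]][is.na(md[[col]]) | md[[col]] == ""] <- "Unknown"
  }
  if ("cluster" %in% names(md)) md$cluster <- as.integer(md$cluster)
  md
}
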