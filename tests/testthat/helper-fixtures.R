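# Shared fixture builders: everything generated in code, no stored binaries.

# A genotype matrix from a plain integer matrix (NA = missing).
gm_fixture <- function(m, chrom = "Chr01", start = NULL, svtype = "DEL") {
  m <- as.matrix(m)
  ns <- nrow(m)
  if (is.null(start))
    start <- as.integer(seq(1000, by = 1000, length.out = ns))
  end <- start + 400L
  ids <- if (ns == 0) character(0) else
    paste(chrom, start, end, svtype, sep = "_")
  genotype_matrix(m, ids,
                  sprintf("S%03d", seq_len(ncol(m))),
                  data.frame(chrom = rep(chrom, ns), start = start,
                             end = end, svtype = rep(svtype, ns)))
}

# An sv_records set from a site table plus carrier/depth matrices.
records_fixture <- function(sites, carriers, depths = NULL) {
  n <- nrow(sites)
  ns <- ncol(carriers)
  if (is.null(depths)) depths <- matrix(30L, n, ns)
  defaults <- data.frame(svtype = rep("DEL", n),
                         precise = rep(TRUE, n),
                         pe_support = rep(10L, n),
                         flagged = rep(FALSE, n))
  for (col in names(defaults))
    if (is.null(sites[[col]])) sites[[col]] <- defaults[[col]]
  if (is.null(sites$end)) sites$end <- sites$start + 499L
  if (is.null(sites$length_bp))
    sites$length_bp <- sites$end - sites$start + 1L
  if (is.null(sites$site_id))
    sites$site_id <- paste(sites$chrom, sites$start, sites$end,
                           sites$svtype, sep = "_")
  sv_records(sites, carriers, depths, sprintf("S%03d", seq_len(ns)))
}

# Write a small SV VCF with explicit per-sample GT:DP cells.
write_vcf_fixture <- function(path, rows, samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"p\">",
           "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"pr\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"im\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

# A GFF3 file from a features data.frame (chrom, type, start, end, id).
write_gff_fixture <- function(path, features) {
  write_gff3(features, path)
}

# Small well-separated SNP panel for clustering tests.
snp_panel_fixture <- function(k, sizes, n_snp = 300, sep = 0.4, seed = 1) {
  cfg <- simulation_config(n_samples = sum(sizes), k_clusters = k,
                           cluster_sizes = sizes,
                           n_background_sites = 0, n_specific_sites = 0,
                           n_snp_sites = n_snp,
                           snp_cluster_separation = sep,
                           missing_rate = 0, seed = seed)
  simulate_panel(cfg)
}
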