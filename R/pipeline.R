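#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline]. All
#' thresholds are surfaced here; nothing downstream is hard-coded.
#'
#' @param sv_vcf,snp_vcf,gff,metadata,chrom_lengths input file paths
#'   (`snp_vcf`, `gff`, `chrom_lengths` may be `NULL` to skip the stages
#'   that need them).
#' @param out_dir output directory.
#' @param min_depth per-sample depth below which a call is missing.
#' @param filter a [filter_config].
#' @param window_bp window size for diversity and the abundance scan.
#' @param ld_max_dist_bp,ld_bin_width_bp LD profile settings.
#' @param k_range candidate cluster counts for the silhouette scan.
#' @param specificity a [specificity_config].
#' @param seed seed recorded in the run summary and used for clustering.
#' @export
pipeline_config <- function(sv_vcf, snp_vcf = NULL, gff = NULL,
                            metadata = NULL, chrom_lengths = NULL,
                            out_dir = "results/pipeline",
                            min_depth = 10,
                            filter = filter_config(),
                            window_bp = 500000,
                            ld_max_dist_bp = 500000,
                            ld_bin_width_bp = 100,
                            k_range = 2:15,
                            specificity = specificity_config(),
                            seed = 1) {
  structure(list(sv_vcf = sv_vcf, snp_vcf = snp_vcf, gff = gff,
                 metadata = metadata, chrom_lengths = chrom_lengths,
                 out_dir = out_dir, min_depth = min_depth, filter = filter,
                 window_bp = window_bp, ld_max_dist_bp = ld_max_dist_bp,
                 ld_bin_width_bp = ld_bin_width_bp, k_range = k_range,
                 specificity = specificity, seed = seed),
            class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full SV population-genetics pipeline
#'
#' filter -> annotate -> spectrum -> diversity -> LD -> cluster ->
#' specificity, writing every stage's TSV plus a machine-readable JSON run
#' summary under `config$out_dir`. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param config a [pipeline_config].
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(seed = config$seed,
                  parameters = list(
                    min_depth = config$min_depth,
                    window_bp = config$window_bp,
                    ld_bin_width_bp = config$ld_bin_width_bp))

  records <- stage_try("filter", {
    recs <- read_sv_vcf(config$sv_vcf, min_depth = config$min_depth)
    if (nrow(recs$sites) == 0) stop("SV VCF has no records")
    filter_cascade(recs, config$filter)
  })
  write_tally_tsv(records$tally, out("filter_tally.tsv"))
  write_sv_vcf(records$records, out("filtered_sv.vcf"))
  summary$n_sites_pre_maf <- nrow(records$pre_maf$sites)
  summary$n_sites_final <- nrow(records$records$sites)

  chrom_lengths <- if (!is.null(config$chrom_lengths))
    utils::read.table(config$chrom_lengths, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL

  gmat_pre <- to_binary_matrix(records$pre_maf)
  gmat <- to_binary_matrix(records$records)
  write_matrix_tsv(gmat, out("genotype_matrix.tsv"))

  overlaps <- NULL
  if (!is.null(config$gff)) {
    overlaps <- stage_try("annotate", {
      features <- read_gene_annotation(config$gff)
      ov <- overlap_features(gmat, features)
      utils::write.table(ov, out("overlaps.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(per_chromosome_summary(gmat, ov, chrom_lengths),
                         out("per_chromosome.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ov
    })
  }

  sfs <- stage_try("sfs", observed_sfs(gmat_pre))
  write_sfs_tsv(sfs, out("sfs.tsv"))
  summary$theta_w <- sfs$theta_w
  summary$sfs_fit_p <- tryCatch(sfs_fit_statistic(sfs)$p,
                                error = function(e) NA_real_)

  win_sv <- stage_try("pi", window_pi(gmat_pre, config$window_bp,
                                      chrom_lengths = chrom_lengths))
  utils::write.table(win_sv, out("window_pi_sv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  snp <- NULL
  if (!is.null(config$snp_vcf)) {
    snp <- stage_try("snp", read_snp_vcf(config$snp_vcf))
    win_snp <- window_pi(snp, config$window_bp, mode = "dosage",
                         chrom_lengths = chrom_lengths)
    utils::write.table(win_snp, out("window_pi_snp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    corr <- tryCatch(diversity_correlation(win_sv, win_snp),
                     error = function(e) list(r = NA, p = NA))
    summary$pi_correlation <- corr[c("r", "p")]
  }

  ld_sum <- stage_try("ld", {
    strata <- if (is.null(overlaps)) "all" else c("all", "genic", "cds")
    res <- list()
    for (st in strata) {
      sub <- stratify_sites(gmat, overlaps %||% NULL, st)
      if (n_sites(sub) < 2) next
      prof <- decay_profile(sub, config$ld_max_dist_bp,
                            config$ld_bin_width_bp, stratum = st)
      utils::write.table(prof, out(paste0("ld_profile_", st, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res[[st]] <- if (nrow(prof)) ld_half(prof) else NA_real_
    }
    res
  })
  summary$ld_half_bp <- ld_sum

  if (!is.null(snp)) {
    clus <- stage_try("cluster", {
      mat <- encode_snp_matrix(snp$dosage)
      rownames(mat) <- snp$sample_ids
      scan <- silhouette_scan(mat, config$k_range, seed = config$seed)
      assignment <- assign_clusters(mat, scan$chosen_k,
                                    seed = config$seed)
      pca <- pca_coords(mat, n_components = min(10, ncol(mat),
                                                nrow(mat)))
      utils::write.table(
        data.frame(k = as.integer(names(scan$silhouette_by_k)),
                   silhouette = scan$silhouette_by_k),
        out("silhouette.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = names(assignment$cluster),
                   cluster = assignment$cluster),
        out("clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        cbind(sample_id = rownames(pca$coords),
              as.data.frame(round(pca$coords, 4))),
        out("pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      list(scan = scan, assignment = assignment)
    })
    summary$chosen_k <- clus$scan$chosen_k

    spec <- stage_try("specificity", {
      res <- classify_cluster_specific(gmat, clus$assignment,
                                       config$specificity)
      utils::write.table(res, out("cluster_specific.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      scan <- windowed_abundance_scan(gmat, clus$assignment,
                                      config$window_bp, chrom_lengths)
      utils::write.table(scan, out("window_abundance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(res = res, scan = scan)
    })
    summary$n_specific <- sum(spec$res$is_specific)
    summary$n_significant_windows <- sum(spec$scan$significant,
                                         na.rm = TRUE)
  }

  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
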