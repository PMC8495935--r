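#' Simulation configuration for synthetic SV panels
#'
#' The defaults mirror the study design this pipeline targets: 347
#' genotypes in 8 clusters of sizes 43, 44, 37, 31, 40, 58, 55 and 39;
#' 1,000 deletion presence/absence sites of which 50 are planted
#' cluster-specific at 90% dominance; a neutral 1/i background spectrum;
#' 2,000 cluster-informative SNP sites; 5% independent missingness and a
#' mean read depth of 30 (the study's average coverage).
#'
#' @param n_samples panel size.
#' @param k_clusters latent cluster count.
#' @param cluster_sizes integer sizes summing to `n_samples`.
#' @param n_background_sites neutral deletion sites (this is the segregating
#'   site count S feeding the spectrum).
#' @param n_specific_sites planted cluster-specific deletion sites.
#' @param specific_dominance target share of a specific site's carriers in
#'   its focal cluster.
#' @param specific_carrier_range inclusive range of total carriers at a
#'   planted specific site.
#' @param n_snp_sites SNP sites for the structure analysis.
#' @param snp_cluster_separation magnitude of per-cluster allele-frequency
#'   shifts (on the frequency scale) that makes SNPs cluster-informative.
#' @param missing_rate independent per-entry missingness probability.
#' @param depth_mean mean of the per-entry Poisson read depth.
#' @param genome data.frame (`chrom`, `length`) giving the coordinate space.
#' @param ld_block optional list (`r2_half_bp`, `n_sites`, `chrom_length`)
#'   for [simulate_ld_decay].
#' @param seed RNG seed; every draw derives from it.
#' @export
simulation_config <- function(n_samples = 347,
                              k_clusters = 8,
                              cluster_sizes = c(43, 44, 37, 31, 40, 58, 55,
                                                39),
                              n_background_sites = 950,
                              n_specific_sites = 50,
                              specific_dominance = 0.9,
                              specific_carrier_range = c(15, 30),
                              n_snp_sites = 2000,
                              snp_cluster_separation = 0.35,
                              missing_rate = 0.05,
                              depth_mean = 30,
                              genome = data.frame(
                                chrom = sprintf("Chr%02d", 1:10),
                                length = rep(5e6, 10)),
                              ld_block = NULL,
                              seed = 1) {
  stopifnot(length(cluster_sizes) == k_clusters,
            sum(cluster_sizes) == n_samples,
            all(cluster_sizes > 0),
            specific_dominance > 0, specific_dominance <= 1,
            missing_rate >= 0, missing_rate < 1,
            depth_mean > 0)
  structure(list(n_samples = n_samples, k_clusters = k_clusters,
                 cluster_sizes = cluster_sizes,
                 n_background_sites = n_background_sites,
                 n_specific_sites = n_specific_sites,
                 specific_dominance = specific_dominance,
                 specific_carrier_range = specific_carrier_range,
                 n_snp_sites = n_snp_sites,
                 snp_cluster_separation = snp_cluster_separation,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 genome = genome, ld_block = ld_block, seed = seed),
            class = "simulation_config")
}

# Origin flavour for the metadata table: one dominant country per cluster,
# loosely following the panel's geography.
cluster_origins <- function(k) {
  pool <- data.frame(
    country = c("Ethiopia", "Sudan", "Kenya", "Nigeria", "India",
                "Tanzania", "United States", "Ethiopia", "Mali", "China"),
    region = c("Eastern Africa", "Eastern Africa", "Eastern Africa",
               "Western Africa", "Asia", "Eastern Africa", "North America",
               "Eastern Africa", "Western Africa", "Asia"),
    race = c("Unknown", "Caudatum", "Guinea", "Guinea", "Durra",
             "Caudatum", "Unknown", "Durra", "Guinea", "Unknown"),
    stringsAsFactors = FALSE)
  pool[((seq_len(k) - 1) %% nrow(pool)) + 1, ]
}

#' Simulate a full SV + SNP panel with known truth
#'
#' Background deletion sites draw a minor-carrier count `i` with
#' probability proportional to `1/i` over `1..floor(n/2)` and place the
#' carriers uniformly across samples (exchangeable null, ignoring
#' clusters). Planted specific sites put a `specific_dominance` share of
#' their carriers in a focal cluster and spread the rest uniformly over the
#' other samples. SNP sites get per-cluster allele-frequency shifts of
#' magnitude `snp_cluster_separation`. Missingness is independent per
#' entry; read depths are Poisson. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config].
#' @return list with `sv_records`, `sv_matrix` (a [genotype_matrix]),
#'   `snp` (list: `dosage`, `positions`), `metadata`, `truth` (per-site
#'   labels and planted parameters) and `config`.
#' @export
simulate_panel <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_samples
  k <- config$k_clusters
  cl <- rep(seq_len(k), config$cluster_sizes)
  sample_ids <- sprintf("S%03d", seq_len(n))
  origins <- cluster_origins(k)
  metadata <- data.frame(sample_id = sample_ids,
                         country = origins$country[cl],
                         region = origins$region[cl],
                         race = origins$race[cl],
                         cluster = cl, stringsAsFactors = FALSE)

  n_bg <- config$n_background_sites
  n_sp <- config$n_specific_sites
  n_sites <- n_bg + n_sp

  # missingness is drawn first so carrier counts can be planted on each
  # site's nonmissing genotypes: the realized minor-carrier spectrum then
  # equals the drawn one (masking a planted carrier set would thin and
  # fold the spectrum away from its nominal 1/i shape near the upper bins)
  miss <- if (config$missing_rate > 0)
    matrix(stats::runif(n_sites * n) < config$missing_rate, n_sites, n)
  else matrix(FALSE, n_sites, n)

  pres <- matrix(0L, n_sites, n)
  label <- c(rep("background", n_bg), rep("specific", n_sp))
  focal <- rep(NA_integer_, n_sites)
  planted_minor <- integer(n_sites)

  if (n_bg > 0) {
    for (s in seq_len(n_bg)) {
      avail <- which(!miss[s, ])
      fold <- floor(length(avail) / 2)
      prob <- 1 / seq_len(fold)
      cnt <- sample.int(fold, 1, prob = prob / sum(prob))
      pres[s, sample(avail, cnt)] <- 1L
      planted_minor[s] <- cnt
    }
  }
  if (n_sp > 0) {
    rng <- config$specific_carrier_range
    for (j in seq_len(n_sp)) {
      s <- n_bg + j
      fc <- ((j - 1) %% k) + 1
      total <- sample(seq(rng[1], rng[2]), 1)
      in_focal <- round(config$specific_dominance * total)
      focal_members <- which(cl == fc & !miss[s, ])
      others <- which(cl != fc & !miss[s, ])
      if (in_focal > length(focal_members))
        stop("infeasible carrier placement at specific site ", j,
             ": ", in_focal, " carriers requested in cluster ", fc,
             " with ", length(focal_members), " available genotypes")
      pres[s, sample(focal_members, in_focal)] <- 1L
      n_out <- total - in_focal
      if (n_out > 0) pres[s, sample(others, n_out)] <- 1L
      focal[s] <- fc
      planted_minor[s] <- total
    }
  }
  pres[miss] <- NA_integer_

  # coordinates: chromosome by length-weighted draw, start uniform,
  # log-uniform deletion sizes of 51 bp .. 10 kb
  chrom_i <- sample.int(nrow(config$genome), n_sites, replace = TRUE,
                        prob = config$genome$length)
  len <- round(exp(stats::runif(n_sites, log(51), log(10000))))
  start <- floor(stats::runif(n_sites, 1,
                              config$genome$length[chrom_i] - len))
  ord <- order(chrom_i, start)
  chrom <- config$genome$chrom[chrom_i][ord]
  start <- start[ord]; len <- len[ord]
  pres <- pres[ord, , drop = FALSE]
  label <- label[ord]; focal <- focal[ord]
  planted_minor <- planted_minor[ord]
  end <- start + len - 1L

  depths <- matrix(stats::rpois(n_sites * n, config$depth_mean),
                   n_sites, n)

  svtype <- rep("DEL", n_sites)
  site_id <- paste(chrom, start, end, svtype, sep = "_")
  sites <- data.frame(site_id = site_id, chrom = chrom, start = start,
                      end = end, svtype = svtype, length_bp = len,
                      precise = rep(TRUE, n_sites),
                      pe_support = 4L + stats::rpois(n_sites, 6),
                      flagged = rep(FALSE, n_sites),
                      stringsAsFactors = FALSE)
  records <- sv_records(sites, pres, depths, sample_ids)
  gmat <- to_binary_matrix(records)

  # cluster-informative SNPs: base frequency plus a Rademacher shift per
  # (site, cluster), clamped away from fixation
  n_snp <- config$n_snp_sites
  snp <- NULL
  if (n_snp > 0) {
    p0 <- stats::runif(n_snp, 0.2, 0.8)
    shift <- matrix(sample(c(-1, 1), n_snp * k, replace = TRUE) *
                      config$snp_cluster_separation, n_snp, k)
    pfreq <- pmin(pmax(p0 + shift, 0.02), 0.98)
    dos <- matrix(NA_integer_, n_snp, n)
    for (c in seq_len(k)) {
      idx <- which(cl == c)
      dos[, idx] <- stats::rbinom(n_snp * length(idx), 2, pfreq[, c])
    }
    if (config$missing_rate > 0) {
      dos[matrix(stats::runif(n_snp * n) < config$missing_rate,
                 n_snp, n)] <- NA_integer_
    }
    snp_chrom_i <- sample.int(nrow(config$genome), n_snp, replace = TRUE,
                              prob = config$genome$length)
    snp_start <- floor(stats::runif(n_snp, 1,
                                    config$genome$length[snp_chrom_i]))
    sord <- order(snp_chrom_i, snp_start)
    snp <- list(dosage = dos[sord, , drop = FALSE],
                positions = data.frame(
                  chrom = config$genome$chrom[snp_chrom_i][sord],
                  start = snp_start[sord], end = snp_start[sord],
                  stringsAsFactors = FALSE),
                sample_ids = sample_ids)
  }

  truth <- data.frame(site_id = site_id, label = label,
                      focal_cluster = focal,
                      planted_minor_count = planted_minor,
                      stringsAsFactors = FALSE)
  list(sv_records = records, sv_matrix = gmat, snp = snp,
       metadata = metadata, truth = truth, config = config)
}

#' Simulate an LD-decay genotype matrix
#'
#' Sites along one chromosome share a per-sample latent haplotype chain
#' whose retention probability decays with distance, so that the expected
#' r-squared between two sites at distance `d` is
#' `exp(-d * log(2) / r2_half_bp)` — an exponential decay with the
#' configured half-distance. The analytic half-distance is attached as the
#' `analytic_half_bp` attribute.
#'
#' @param config a [simulation_config] with `ld_block` set
#'   (`r2_half_bp`, `n_sites`, `chrom_length`).
#' @return a [genotype_matrix] of presence/absence sites.
#' @export
simulate_ld_decay <- function(config = simulation_config(
  ld_block = list(r2_half_bp = 10000, n_sites = 500,
                  chrom_length = 150000))) {
  lb <- config$ld_block
  if (is.null(lb)) stop("ld_block must be set in the config")
  set.seed(config$seed)
  n <- config$n_samples
  m <- lb$n_sites
  pos <- sort(floor(stats::runif(m, 1, lb$chrom_length)))
  x <- matrix(0L, m, n)
  x[1, ] <- stats::rbinom(n, 1, 0.5)
  for (j in 2:m) {
    d <- pos[j] - pos[j - 1]
    # corr decays as exp(-d ln2 / (2 h)) so that r2 = corr^2 halves at h
    rho <- exp(-d * log(2) / (2 * lb$r2_half_bp))
    keep <- stats::rbinom(n, 1, rho) == 1
    x[j, ] <- ifelse(keep, x[j - 1, ], stats::rbinom(n, 1, 0.5))
  }
  site_id <- paste("ChrLD", pos, pos + 99L, "DEL", sep = "_")
  gm <- genotype_matrix(x, site_id, sprintf("S%03d", seq_len(n)),
                        data.frame(chrom = "ChrLD", start = pos,
                                   end = pos + 99L, svtype = "DEL"))
  attr(gm, "analytic_half_bp") <- lb$r2_half_bp
  gm
}

#' Simulate a synthetic gene annotation
#'
#' Non-overlapping gene intervals tiled at a target genome fraction, each
#' with one interior CDS, written in GFF3. Purely synthetic plumbing so the
#' annotation-dependent stages can run on simulated panels.
#'
#' @param genome data.frame (`chrom`, `length`).
#' @param gene_fraction target fraction of the genome inside genes.
#' @param gene_length_bp mean gene length.
#' @param seed RNG seed.
#' @return data.frame of features (`chrom`, `type`, `start`, `end`, `id`).
#' @export
simulate_annotation <- function(genome, gene_fraction = 0.3,
                                gene_length_bp = 3000, seed = 1) {
  set.seed(seed)
  rows <- list()
  gid <- 0
  for (r in seq_len(nrow(genome))) {
    chrom <- genome$chrom[r]; len <- genome$length[r]
    n_genes <- round(gene_fraction * len / gene_length_bp)
    if (n_genes < 1) next
    starts <- sort(sample.int(len - gene_length_bp * 2, n_genes))
    prev_end <- 0
    for (s in starts) {
      glen <- max(200, round(stats::rnorm(1, gene_length_bp,
                                          gene_length_bp / 4)))
      if (s <= prev_end) next
      ge <- min(s + glen - 1, len)
      cs <- s + round(0.2 * glen)
      ce <- min(cs + round(0.4 * glen), ge)
      gid <- gid + 1
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, type = c("gene", "CDS"),
        start = c(s, cs), end = c(ge, ce),
        id = sprintf("SYNG%05d", gid), stringsAsFactors = FALSE)
      prev_end <- ge
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic annotation as GFF3
#' @param features data.frame from [simulate_annotation].
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsvpopgen\t%s\t%d\t%d\t.\t+\t.\tID=%s%s",
                     features$chrom, features$type, features$start,
                     features$end,
                     ifelse(features$type == "CDS",
                            paste0(features$id, ".cds"), features$id),
                     ifelse(features$type == "CDS",
                            paste0(";Parent=", features$id), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated SNP set as a plain-text VCF
#' @param snp list with `dosage`, `positions`, `sample_ids`.
#' @param path output file.
#' @export
write_snp_vcf <- function(snp, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svpopgen",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", snp$sample_ids), collapse = "\t"))
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(snp$dosage), ncol(snp$dosage))
  ok <- !is.na(snp$dosage)
  gt[ok] <- gtcode[snp$dosage[ok] + 1L]
  body <- paste(snp$positions$chrom, snp$positions$start,
                paste0("snp", seq_len(nrow(snp$dosage))),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated panel to disk
#'
#' Emits the SV VCF, SNP VCF, metadata TSV, truth TSV and a synthetic GFF3
#' so the whole pipeline can run from files.
#'
#' @param panel list from [simulate_panel].
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sv_vcf = file.path(dir, "sv.vcf"),
             snp_vcf = file.path(dir, "snp.vcf"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             gff = file.path(dir, "annotation.gff3"),
             chrom_lengths = file.path(dir, "chrom_lengths.tsv"))
  write_sv_vcf(panel$sv_records, paths["sv_vcf"],
               contigs = panel$config$genome)
  if (!is.null(panel$snp)) write_snp_vcf(panel$snp, paths["snp_vcf"])
  utils::write.table(panel$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- simulate_annotation(panel$config$genome,
                             seed = panel$config$seed)
  write_gff3(ann, paths["gff"])
  utils::write.table(panel$config$genome, paths["chrom_lengths"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
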