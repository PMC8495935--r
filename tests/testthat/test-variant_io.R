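test_that("depth masking turns low-coverage calls missing at the 10x boundary", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- c(
    "Chr01\t100\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600;PE=5;PRECISE\tGT:DP\t0/1:9\t0/1:10\t0/0:30",
    "Chr01\t2000\tsv2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=2500;PE=5;PRECISE\tGT:DP\t./.:30\t1/1:30\t0/0:11")
  write_vcf_fixture(path, rows)
  r <- read_sv_vcf(path, min_depth = 10)
  expect_equal(nrow(r$sites), 2)
  # depth 9 -> missing despite the 0/1 call; depth 10 passes
  expect_true(is.na(r$carriers[1, 1]))
  expect_equal(r$carriers[1, 2], 1L)
  expect_equal(r$carriers[1, 3], 0L)
  # uncalled genotype is missing; any alt allele is present
  expect_true(is.na(r$carriers[2, 1]))
  expect_equal(r$carriers[2, 2], 1L)
  expect_equal(r$sites$svtype, c("DEL", "DEL"))
  expect_true(all(r$sites$precise))
  expect_equal(r$sites$pe_support, c(5L, 5L))
  expect_equal(r$sites$length_bp, c(501L, 501L))
})

test_that("raising min_depth never converts a missing call to nonmissing", {
  panel <- simulate_panel(simulation_config(
    n_samples = 30, k_clusters = 2, cluster_sizes = c(15, 15),
    n_background_sites = 40, n_specific_sites = 0, n_snp_sites = 0,
    missing_rate = 0.1, depth_mean = 12, seed = 11))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(panel$sv_records, path)
  prev <- read_sv_vcf(path, min_depth = 0)
  for (d in c(5, 10, 15)) {
    cur <- read_sv_vcf(path, min_depth = d)
    expect_true(all(is.na(cur$carriers[is.na(prev$carriers)])))
    prev <- cur
  }
})

test_that("empty VCF body yields an empty record set", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, character(0))
  r <- read_sv_vcf(path)
  expect_s3_class(r, "sv_records")
  expect_equal(nrow(r$sites), 0)
  expect_equal(length(r$sample_ids), 3)
  expect_equal(dim(to_binary_matrix(r)$presence), c(0L, 3L))
})

test_that("unknown SVTYPE is retained, flagged, and carries no length", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- "Chr01\t100\tsv1\tN\t<WEIRD>\t.\tPASS\tSVTYPE=WEIRD;END=600;PE=5;PRECISE\tGT:DP\t0/1:30\t0/0:30\t0/0:30"
  write_vcf_fixture(path, rows)
  r <- read_sv_vcf(path)
  expect_equal(r$sites$svtype, "unknown")
  expect_true(r$sites$flagged)
  expect_true(is.na(r$sites$length_bp))
})

test_that("SVLEN is preferred over END-derived length when present", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- "Chr01\t100\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600;SVLEN=-480;PE=5;PRECISE\tGT:DP\t0/1:30\t0/0:30\t0/0:30"
  write_vcf_fixture(path, rows)
  expect_equal(read_sv_vcf(path)$sites$length_bp, 480L)
})

test_that("writing and re-reading a record set preserves every field", {
  panel <- simulate_panel(simulation_config(
    n_samples = 20, k_clusters = 2, cluster_sizes = c(10, 10),
    n_background_sites = 30, n_specific_sites = 2, n_snp_sites = 0,
    specific_carrier_range = c(5, 8), missing_rate = 0.08, seed = 3))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(panel$sv_records, path, contigs = panel$config$genome)
  back <- read_sv_vcf(path, min_depth = 0)
  orig <- panel$sv_records
  expect_equal(back$sites, orig$sites, ignore_attr = TRUE)
  expect_identical(unname(back$carriers), unname(orig$carriers))
  expect_identical(unname(back$depths), unname(orig$depths))
  expect_equal(back$sample_ids, orig$sample_ids)
})

test_that("matrix conversion preserves order, calls, and carrier totals", {
  carriers <- rbind(c(1L, 0L, NA), c(0L, 0L, 0L), c(1L, 1L, NA),
                    c(NA, 1L, 0L), c(1L, 0L, 0L))
  recs <- records_fixture(
    data.frame(chrom = rep("Chr01", 5),
               start = c(100L, 900L, 1500L, 2200L, 4000L)),
    carriers)
  gm <- to_binary_matrix(recs)
  # hand counts on the fixture
  expect_equal(unname(rowSums(gm$presence, na.rm = TRUE)),
               c(1, 0, 2, 1, 1))
  expect_equal(unname(colSums(gm$presence, na.rm = TRUE)), c(3, 2, 0))
  expect_equal(sum(gm$presence, na.rm = TRUE),
               sum(recs$carriers, na.rm = TRUE))
  expect_equal(gm$positions$start, recs$sites$start)
})

test_that("gene annotation reader returns gene and CDS interval sets", {
  path <- withr::local_tempfile(fileext = ".gff3")
  feats <- data.frame(
    chrom = c("Chr01", "Chr01", "Chr01", "Chr02", "Chr02"),
    type = c("gene", "CDS", "gene", "gene", "CDS"),
    start = c(1000L, 1200L, 5000L, 300L, 400L),
    end = c(2000L, 1500L, 6000L, 900L, 600L),
    id = c("g1", "g1", "g2", "g3", "g3"))
  write_gff_fixture(path, feats)
  ann <- read_gene_annotation(path)
  expect_equal(length(ann$genes), 3)
  expect_equal(length(ann$cds), 2)
  expect_equal(GenomicRanges::start(ann$genes)[1], 1000)
  # empty annotation
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p2)
  ann2 <- read_gene_annotation(p2)
  expect_equal(length(ann2$genes), 0)
  expect_equal(length(ann2$cds), 0)
})

test_that("metadata reader tolerates unknowns and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcountry\tregion\trace",
               "S001\tEthiopia\tEastern Africa\tDurra",
               "S002\t\tAsia\t", "S003\tSudan\tEastern Africa\tCaudatum"),
             path)
  md <- read_metadata(path)
  expect_equal(nrow(md), 3)
  expect_equal(md$country[2], "Unknown")
  expect_equal(md$race[2], "Unknown")
  # country tally matches a hand count
  expect_equal(sort(table(md$country), decreasing = TRUE)[["Ethiopia"]], 1)
  writeLines(c("sample_id,country", "S001,Mali", "S001,Chad"), path)
  expect_error(read_metadata(path), "duplicate")
})
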