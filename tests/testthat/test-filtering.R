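test_that("site missing fraction and minor carrier count follow their definitions", {
  expect_equal(site_missing_fraction(c(1L, 0L, NA, 0L)), 0.25)
  expect_equal(site_missing_fraction(c(1L, 0L, 1L)), 0)
  # 70 of 347 missing sits just over the 20% removal threshold
  x <- c(rep(NA, 70), rep(0L, 277))
  expect_gt(site_missing_fraction(x), 0.20)
  expect_equal(site_missing_fraction(x), 70 / 347)

  expect_equal(minor_carrier_count(c(rep(1L, 19), rep(0L, 267),
                                     rep(NA, 61))), 19)
  expect_equal(minor_carrier_count(c(rep(1L, 200), rep(0L, 100))), 100)
  expect_equal(minor_carrier_count(c(0L, 0L, 0L)), 0)
  expect_error(minor_carrier_count(c(NA, NA)), "missing")
})

test_that("MAF threshold arithmetic matches the carrier-count equivalence", {
  expect_equal(maf_threshold_count(347, 0.05), 18L)
  expect_equal(maf_threshold_count(100, 0.05), 5L)
  # at MAF 0.5 the required count exceeds the largest possible minor bin
  expect_equal(maf_threshold_count(347, 0.5), 174L)
  expect_gt(maf_threshold_count(347, 0.5), floor(347 / 2))
})

# one record per elimination reason plus two survivors
cascade_fixture <- function() {
  sites <- data.frame(
    chrom = rep("Chr01", 8),
    start = as.integer(seq(1000, by = 10000, length.out = 8)),
    svtype = c("DEL", "DEL", "BND", "DEL", "DEL", "DEL", "DEL", "DUP"),
    precise = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    pe_support = c(3L, 10L, 10L, 10L, 10L, 10L, 10L, 10L))
  sites$end <- sites$start + c(500L, 500L, 0L, 30L, 500L, 500L, 500L,
                               800L) - 1L
  n <- 10
  carriers <- matrix(0L, 8, n)
  carriers[, 1:3] <- 1L            # 3 of 10 carriers: MAF 0.3, passes
  carriers[5, 4:6] <- NA           # 30% missing: fails missing stage
  carriers[6, ] <- c(1L, rep(0L, 9))  # 1 of 10 carriers: fails MAF 0.05? no - 0.1 passes
  carriers[6, 1:3] <- 0L           # 0 carriers -> minor count 0, fails MAF
  records_fixture(sites, carriers)
}

test_that("the filter cascade applies stages in order with a hand-checked tally", {
  recs <- cascade_fixture()
  out <- filter_cascade(recs, filter_config(min_maf = 0.05))
  tally <- out$tally
  # hand count: record 1 fails PE, 2 fails precision, 3 is BND,
  # 4 is 30 bp (size), 5 has 30% missing, 6 has zero carriers (MAF);
  # records 7 (DEL) and 8 (DUP) survive everything
  expect_equal(tally["Total", "no_filters"], 8)
  expect_equal(tally["Total", "pair_end"], 7)
  expect_equal(tally["Total", "precise"], 6)
  expect_equal(tally["Total", "bnd"], 5)
  expect_equal(tally["Total", "size"], 4)
  expect_equal(tally["Total", "missing"], 3)
  expect_equal(tally["Total", "maf"], 2)
  expect_equal(out$records$sites$svtype, c("DEL", "DUP"))
  expect_equal(nrow(out$pre_maf$sites), 3)
  # per-svtype counts sum to the total at every stage
  for (st in names(tally))
    expect_equal(sum(tally[-1, st]), tally["Total", st])
})

test_that("each stage shrinks the survivor set and the cascade is idempotent", {
  panel <- simulate_panel(simulation_config(
    n_samples = 40, k_clusters = 2, cluster_sizes = c(20, 20),
    n_background_sites = 60, n_specific_sites = 0, n_snp_sites = 0,
    missing_rate = 0.15, seed = 5))
  recs <- panel$sv_records
  # perturb some records so several stages bite
  recs$sites$pe_support[1:5] <- 2L
  recs$sites$precise[6:10] <- FALSE
  recs$sites$length_bp[11:13] <- 20L
  out <- filter_cascade(recs)
  counts <- as.integer(out$tally["Total", ])
  expect_true(all(diff(counts) <= 0))
  again <- filter_cascade(out$records)
  expect_equal(again$records$sites, out$records$sites,
               ignore_attr = TRUE)
  expect_identical(again$records$carriers, out$records$carriers)
})

test_that("empty input yields empty output and zero tallies", {
  recs <- records_fixture(
    data.frame(chrom = character(), start = integer(), end = integer(),
               svtype = character(), precise = logical(),
               pe_support = integer(), length_bp = integer(),
               site_id = character(), flagged = logical()),
    matrix(integer(), 0, 4))
  out <- filter_cascade(recs)
  expect_equal(nrow(out$records$sites), 0)
  expect_true(all(as.matrix(out$tally) == 0))
})

test_that("size bounds are inclusive and the MAF denominator switch works", {
  sites <- data.frame(chrom = rep("Chr01", 3),
                      start = c(1000L, 5000L, 9000L),
                      svtype = rep("DEL", 3))
  sites$end <- sites$start + c(50L, 100000L, 100001L) - 1L
  carriers <- matrix(0L, 3, 20)
  carriers[, 1] <- 1L
  carriers[, 15:20] <- NA  # 14 nonmissing, 1 carrier
  recs <- records_fixture(sites, carriers)
  cfg <- filter_config(max_missing_fraction = 0.5, min_maf = 0.05)
  out <- filter_cascade(recs, cfg)
  # 50 bp and 100 kb kept, 100,001 bp dropped
  expect_equal(out$tally["Total", "size"], 2)
  # panel denominator: 1/20 = 0.05 >= 0.05 keeps the sites
  expect_equal(out$tally["Total", "maf"], 2)
  cfg2 <- filter_config(max_missing_fraction = 0.5, min_maf = 0.05,
                        maf_denominator = "nonmissing")
  out2 <- filter_cascade(recs, cfg2)
  # nonmissing denominator: 1/14 = 0.071 also passes
  expect_equal(out2$tally["Total", "maf"], 2)
  cfg3 <- filter_config(max_missing_fraction = 0.5, min_maf = 0.08)
  # 1/20 = 0.05 < 0.08 now fails under the panel denominator
  expect_equal(filter_cascade(recs, cfg3)$tally["Total", "maf"], 0)
})
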