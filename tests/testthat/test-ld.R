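test_that("pairwise r2 matches the D-squared haplotype formula", {
  x <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  y <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  pA <- mean(x); pB <- mean(y); pAB <- mean(x & y)
  D <- pAB - pA * pB
  r2_hand <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(pairwise_r2(x, y), r2_hand)
  expect_equal(round(pairwise_r2(x, y), 4), 0.5556)

  expect_equal(pairwise_r2(x, x), 1)
  expect_equal(pairwise_r2(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)), 0)
  # monomorphic on the shared nonmissing set -> undefined
  expect_true(is.na(pairwise_r2(c(1L, 1L, NA, NA), c(NA, NA, 1L, 0L))))
})

test_that("pairwise r2 is symmetric and invariant to 0/1 label swaps", {
  set.seed(12)
  for (rep in 1:20) {
    x <- sample(c(0L, 1L, NA), 15, replace = TRUE, prob = c(.4, .4, .2))
    y <- sample(c(0L, 1L, NA), 15, replace = TRUE, prob = c(.4, .4, .2))
    r <- pairwise_r2(x, y)
    expect_identical(r, pairwise_r2(y, x))
    if (!is.na(r)) {
      expect_equal(pairwise_r2(1L - x, y), r)
      expect_equal(pairwise_r2(x, 1L - y), r)
    }
  }
})

test_that("the decay profile bins pairs by distance with brute-force means", {
  set.seed(13)
  m <- matrix(sample(c(0L, 1L), 60, replace = TRUE), 6, 10)
  starts <- c(100L, 250L, 900L, 1000L, 5000L, 200000L)
  gm <- gm_fixture(m, start = starts)
  prof <- decay_profile(gm, max_dist_bp = 100000, bin_width_bp = 100)
  # brute force over all 15 pairs
  brute <- data.frame()
  for (i in 1:5) for (j in (i + 1):6) {
    d <- abs(starts[j] - starts[i])
    if (d > 100000) next
    r2 <- pairwise_r2(m[i, ], m[j, ])
    if (is.na(r2)) next
    brute <- rbind(brute, data.frame(bin = max(1, ceiling(d / 100)),
                                     r2 = r2))
  }
  agg <- aggregate(r2 ~ bin, brute, mean)
  expect_equal(prof$bin_mid, (agg$bin - 0.5) * 100)
  expect_equal(prof$mean_r2, agg$r2)
  expect_equal(sum(prof$n_pairs), nrow(brute))
})

test_that("cross-chromosome pairs are excluded and identical sites give r2 one", {
  m <- rbind(rep(c(0L, 1L), 5), rep(c(0L, 1L), 5))
  gm <- genotype_matrix(m, c("a", "b"), sprintf("S%d", 1:10),
                        data.frame(chrom = c("Chr01", "Chr02"),
                                   start = c(100L, 200L),
                                   end = c(200L, 300L),
                                   svtype = "DEL"))
  expect_equal(nrow(decay_profile(gm)), 0)
  gm2 <- gm_fixture(m, start = c(100L, 250L))
  prof <- decay_profile(gm2)
  expect_equal(prof$mean_r2, 1)
  expect_equal(prof$bin_mid, 150)
})

test_that("the half-decay distance is the first bin midpoint at half maximum", {
  prof <- structure(data.frame(bin_mid = c(50, 150, 250, 350),
                               n_pairs = 10,
                               mean_r2 = c(0.4, 0.3, 0.2, 0.1)),
                    class = c("ld_profile", "data.frame"))
  expect_equal(ld_half(prof), 250)
  flat <- prof; flat$mean_r2 <- rep(0.4, 4)
  expect_true(is.na(ld_half(flat)))
})

test_that("simulated exponential LD decay is recovered near its half-distance", {
  gm <- simulate_ld_decay(simulation_config(seed = 21,
    ld_block = list(r2_half_bp = 10000, n_sites = 500,
                    chrom_length = 150000)))
  prof <- decay_profile(gm, max_dist_bp = 50000, bin_width_bp = 1000)
  half <- ld_half(prof)
  target <- attr(gm, "analytic_half_bp") + prof$bin_mid[1]
  expect_lt(abs(half - target), 2 * 1000)
  # uncorrelated sites give near-zero mean r2
  gm0 <- simulate_ld_decay(simulation_config(seed = 22,
    ld_block = list(r2_half_bp = 1, n_sites = 100,
                    chrom_length = 100000)))
  prof0 <- decay_profile(gm0, max_dist_bp = 50000, bin_width_bp = 5000)
  expect_lt(max(prof0$mean_r2[prof0$bin_mid > 5000]), 0.05)
})

test_that("stratification subsets sites by annotation overlap", {
  m <- matrix(rep(c(0L, 1L), 25), 10, 5)
  gm <- gm_fixture(m)
  overlaps <- data.frame(site_id = gm$site_ids,
                         in_gene = c(rep(TRUE, 3), rep(FALSE, 7)),
                         in_cds = rep(FALSE, 10))
  expect_equal(n_sites(stratify_sites(gm, overlaps, "all")), 10)
  expect_equal(n_sites(stratify_sites(gm, overlaps, "genic")), 3)
  expect_message(out <- stratify_sites(gm, overlaps, "cds"), "empty")
  expect_equal(n_sites(out), 0)
})
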