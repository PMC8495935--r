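# The benchmark site: carriers 1,2,1,0,2,19,0,1 across eight clusters with
# 32,31,31,30,35,53,44,30 nonmissing genotypes (347-sample panel, cluster
# sizes 43,44,37,31,40,58,55,39).
worked_example_site <- function() {
  sizes <- c(43, 44, 37, 31, 40, 58, 55, 39)
  nm <- c(32, 31, 31, 30, 35, 53, 44, 30)
  obs <- c(1, 2, 1, 0, 2, 19, 0, 1)
  cl <- rep(1:8, sizes)
  x <- rep(NA_integer_, sum(sizes))
  for (c in 1:8) {
    idx <- which(cl == c)
    x[idx[seq_len(nm[c])]] <- 0L
    x[idx[seq_len(obs[c])]] <- 1L
  }
  list(x = x, cluster = cl, obs = obs, nm = nm)
}

test_that("per-cluster counts reproduce the benchmark site", {
  we <- worked_example_site()
  cc <- carrier_counts_by_cluster(we$x, we$cluster)
  expect_equal(cc$observed, c(1L, 2L, 1L, 0L, 2L, 19L, 0L, 1L))
  expect_equal(cc$nonmissing, c(32L, 31L, 31L, 30L, 35L, 53L, 44L, 30L))
  # no carriers, and a single-cluster panel
  cc0 <- carrier_counts_by_cluster(rep(0L, 10), rep(1:2, 5))
  expect_equal(cc0$observed, c(0L, 0L))
  cc1 <- carrier_counts_by_cluster(c(1L, 0L, NA), rep(1L, 3))
  expect_equal(cc1$observed, 1L)
  expect_equal(cc1$nonmissing, 2L)
})

test_that("goodness-of-fit test reproduces the benchmark p-value", {
  g <- gof_test(c(1, 2, 1, 0, 2, 19, 0, 1),
                c(32, 31, 31, 30, 35, 53, 44, 30))
  expect_equal(g$p, 4.314e-9, tolerance = 0.001)
  expect_equal(g$df, 7)

  # carriers exactly proportional to cluster sizes
  g0 <- gof_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(g0$chi2, 0)
  expect_equal(g0$p, 1)

  # two clusters: closed-form chi-square with one degree of freedom
  g2 <- gof_test(c(2, 0), c(10, 10))
  expect_equal(g2$chi2, 2)
  expect_equal(g2$p, stats::pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(g2$p, 4), 0.1573)
  # two-cluster case equals the binomial-proportion chi-square
  obs <- c(7, 3); nm <- c(12, 18)
  g3 <- gof_test(obs, nm)
  pt <- suppressWarnings(stats::prop.test(7, 10, p = 12 / 30,
                                          correct = FALSE))
  expect_equal(g3$chi2, unname(pt$statistic))

  expect_error(gof_test(c(0, 0), c(5, 5)), "no carriers")
  expect_error(gof_test(c(1, 0), c(5, 0)), "nonmissing")
})

test_that("dominant fraction picks the benchmark cluster at 73 percent", {
  d <- dominant_fraction(c(1, 2, 1, 0, 2, 19, 0, 1))
  expect_equal(d$cluster, 6)
  expect_equal(round(100 * d$fraction), 73)
  expect_equal(dominant_fraction(c(5, 0, 0)),
               list(cluster = 1L, fraction = 1))
  # ties resolve to the lowest cluster index
  expect_equal(dominant_fraction(c(3, 3))$cluster, 1)
  expect_error(dominant_fraction(c(0, 0)), "no carriers")
})

test_that("the permutation null is deterministic and matches exact tail probabilities", {
  cfg <- specificity_config(seed = 99)
  we <- worked_example_site()
  hits <- permutation_test(sum(we$obs), we$nm, 6, cfg)
  expect_equal(hits, 0L)
  expect_identical(permutation_test(sum(we$obs), we$nm, 6, cfg), hits)

  # all samples in one cluster: every permutation trivially exceeds
  expect_equal(permutation_test(5, 20, 1, cfg), 100L)

  # exact hypergeometric oracle: focal count ~ Hypergeom, threshold share
  exact_tail <- function(total, nm, focal, thr) {
    need <- ceiling(thr * total)
    sum(stats::dhyper(need:min(total, nm[focal]), nm[focal],
                      sum(nm) - nm[focal], total))
  }
  cases <- list(list(total = 1, nm = c(5, 5), focal = 1),
                list(total = 4, nm = c(6, 6, 8), focal = 2),
                list(total = 12, nm = c(30, 20, 10), focal = 1),
                list(total = 7, nm = c(10, 40), focal = 1))
  for (cs in cases) {
    p_exact <- exact_tail(cs$total, cs$nm, cs$focal, 0.70)
    big <- specificity_config(n_permutations = 1000, seed = 7)
    rate <- permutation_test(cs$total, cs$nm, cs$focal, big) / 1000
    # binomial 99% bound on 1000 draws
    bound <- 2.576 * sqrt(p_exact * (1 - p_exact) / 1000)
    expect_lt(abs(rate - p_exact), max(bound, 0.01))
  }
})

test_that("classification conjunction works on the benchmark and a uniform site", {
  we <- worked_example_site()
  uniform <- rep(NA_integer_, 347)
  cl <- we$cluster
  for (c in 1:8) {
    idx <- which(cl == c)
    uniform[idx] <- 0L
    uniform[idx[seq_len(round(length(idx) * 0.3))]] <- 1L
  }
  gm <- gm_fixture(rbind(we$x, uniform), start = c(1000L, 2000L))
  res <- classify_cluster_specific(gm, cl, specificity_config(seed = 4))
  expect_true(res$is_specific[1])
  expect_equal(res$stage[1], "specific")
  expect_equal(res$dominant_cluster[1], 6)
  expect_false(res$is_specific[2])
  expect_equal(res$perm_exceedances[1], 0L)
})

test_that("classification is invariant to cluster relabeling", {
  panel <- simulate_panel(simulation_config(
    n_samples = 60, k_clusters = 3, cluster_sizes = c(25, 20, 15),
    n_background_sites = 30, n_specific_sites = 5, n_snp_sites = 0,
    specific_carrier_range = c(8, 12), missing_rate = 0.02, seed = 44))
  cl <- panel$metadata$cluster
  relabel <- c(3L, 1L, 2L)[cl]
  cfg <- specificity_config(seed = 1)
  a <- classify_cluster_specific(panel$sv_matrix, cl, cfg)
  b <- classify_cluster_specific(panel$sv_matrix, relabel, cfg)
  expect_equal(a$is_specific, b$is_specific)
  expect_equal(a$gof_p, b$gof_p)
  expect_equal(c(3L, 1L, 2L)[a$dominant_cluster[!is.na(a$dominant_cluster)]],
               b$dominant_cluster[!is.na(b$dominant_cluster)])
})

test_that("a proportional null keeps the specific-site rate at or below alpha", {
  panel <- simulate_panel(simulation_config(
    n_background_sites = 400, n_specific_sites = 0, n_snp_sites = 0,
    seed = 45))
  res <- classify_cluster_specific(panel$sv_matrix,
                                   panel$metadata$cluster,
                                   specificity_config(seed = 2))
  expect_lte(mean(res$is_specific), 0.05)
})

test_that("the windowed abundance scan flags only constructed hot windows", {
  # 100 windows of 10 kb; sites evenly spread; one window gets all its
  # carriers in cluster 1
  n <- 40
  cl <- rep(1:4, each = 10)
  ns <- 100
  m <- matrix(0L, ns, n)
  starts <- as.integer(seq(5000, by = 10000, length.out = ns))
  set.seed(6)
  for (i in 1:ns) m[i, sample(n, 8)] <- 1L       # proportional background
  m[42, ] <- c(rep(1L, 10), rep(0L, 30))          # hot window: cluster 1 only
  gm <- gm_fixture(m, start = starts)
  scan <- windowed_abundance_scan(gm, cl, window_bp = 10000)
  expect_equal(nrow(scan), ns)
  expect_true(scan$significant[42])
  # chi2 for the hot window matches hand arithmetic on its counts
  cc <- carrier_counts_by_cluster(m[42, ], cl)
  g <- gof_test(cc$observed, cc$nonmissing)
  expect_equal(scan$chi2[42], g$chi2)
  expect_lt(scan$p[42], 0.05 / sum(!is.na(scan$p)))
  # proportional windows are not significant
  expect_lte(sum(scan$significant, na.rm = TRUE), 2)
  # empty matrix
  empty <- windowed_abundance_scan(gm_fixture(matrix(0L, 0, n)), cl)
  expect_equal(nrow(empty), 0)
})
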