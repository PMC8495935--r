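#' Configuration for the cluster-specific deletion screen
#'
#' Defaults follow the study design: a goodness-of-fit screen at alpha =
#' 0.05 (uncorrected), a 70% single-cluster dominance requirement, and a
#' 100-permutation null with specificity declared when fewer than 5% of
#' permutations reach the dominance threshold in the focal cluster.
#'
#' @param dominance_threshold minimum share of carriers in a single cluster.
#' @param n_permutations permutations per site.
#' @param permutation_alpha maximum tolerated permutation exceedance rate.
#' @param gof_alpha significance level of the goodness-of-fit screen.
#' @param gof_correction `"none"` or `"bonferroni"` (over tested sites).
#' @param permutation_scope `"focal"` monitors the observed dominant
#'   cluster; `"any"` counts permutations where any cluster reaches the
#'   threshold.
#' @param seed RNG seed for the permutations.
#' @export
specificity_config <- function(dominance_threshold = 0.70,
                               n_permutations = 100,
                               permutation_alpha = 0.05,
                               gof_alpha = 0.05,
                               gof_correction = c("none", "bonferroni"),
                               permutation_scope = c("focal", "any"),
                               seed = 1) {
  stopifnot(dominance_threshold > 0, dominance_threshold < 1,
            n_permutations >= 1, permutation_alpha > 0,
            permutation_alpha < 1, gof_alpha > 0, gof_alpha < 1)
  structure(list(dominance_threshold = dominance_threshold,
                 n_permutations = n_permutations,
                 permutation_alpha = permutation_alpha,
                 gof_alpha = gof_alpha,
                 gof_correction = match.arg(gof_correction),
                 permutation_scope = match.arg(permutation_scope),
                 seed = seed),
            class = "specificity_config")
}

#' Per-cluster carrier and nonmissing counts at a site
#'
#' @param x site vector of 0/1/`NA` calls.
#' @param cluster integer cluster label per sample (1..k, every sample
#'   labeled).
#' @return list with `observed` (carriers per cluster) and `nonmissing`.
#' @export
carrier_counts_by_cluster <- function(x, cluster) {
  stopifnot(length(x) == length(cluster), !any(is.na(cluster)))
  k <- max(cluster)
  lev <- factor(cluster, levels = seq_len(k))
  observed <- as.integer(tapply(!is.na(x) & x == 1L, lev, sum,
                                default = 0L))
  nonmissing <- as.integer(tapply(!is.na(x), lev, sum, default = 0L))
  list(observed = observed, nonmissing = nonmissing)
}

#' Chi-square goodness of fit of carriers against cluster sizes
#'
#' Expected carriers per cluster are proportional to the exact nonmissing
#' counts: `E_c = sum(O) * N_c / sum(N)`. The statistic
#' `sum((O - E)^2 / E)` is referred to a chi-square distribution with
#' (clusters - 1) degrees of freedom.
#'
#' @param observed per-cluster carrier counts (sum >= 1).
#' @param nonmissing per-cluster nonmissing counts (all >= 1).
#' @return list with `chi2`, `df`, `p`.
#' @export
gof_test <- function(observed, nonmissing) {
  stopifnot(length(observed) == length(nonmissing))
  if (sum(observed) < 1) stop("no carriers at site")
  if (any(nonmissing < 1)) stop("a cluster has no nonmissing genotypes")
  expected <- sum(observed) * nonmissing / sum(nonmissing)
  if (any(expected == 0)) stop("zero expected count")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Dominant cluster and its carrier fraction
#'
#' @param observed per-cluster carrier counts (sum >= 1). Ties resolve to
#'   the lowest cluster index.
#' @return list with `cluster` and `fraction`.
#' @export
dominant_fraction <- function(observed) {
  if (sum(observed) < 1) stop("no carriers at site")
  i <- which.max(observed)
  list(cluster = i, fraction = observed[i] / sum(observed))
}

#' Permutation null for single-cluster dominance
#'
#' Each permutation re-places the observed number of carriers uniformly
#' without replacement among the nonmissing genotype slots of the site and
#' checks whether the focal cluster (or any cluster, per `config`) holds at
#' least the dominance-threshold share. Deterministic given `config$seed`.
#'
#' @param observed_total total carriers at the site.
#' @param nonmissing per-cluster nonmissing counts.
#' @param focal_cluster index of the observed dominant cluster.
#' @param config a [specificity_config].
#' @return integer exceedance count out of `config$n_permutations`.
#' @export
permutation_test <- function(observed_total, nonmissing, focal_cluster,
                             config = specificity_config()) {
  stopifnot(observed_total >= 1, observed_total <= sum(nonmissing))
  set.seed(config$seed)
  thr <- config$dominance_threshold
  if (config$permutation_scope == "focal") {
    # placing the carriers uniformly without replacement makes the focal
    # cluster's count hypergeometric; drawing it directly keeps the result
    # invariant to how the other clusters are labeled
    x <- stats::rhyper(config$n_permutations, nonmissing[focal_cluster],
                       sum(nonmissing) - nonmissing[focal_cluster],
                       observed_total)
    return(sum(x / observed_total >= thr))
  }
  slots <- rep(seq_along(nonmissing), nonmissing)
  hits <- 0L
  for (b in seq_len(config$n_permutations)) {
    drawn <- slots[sample.int(length(slots), observed_total)]
    if (max(tabulate(drawn, length(nonmissing))) / observed_total >= thr)
      hits <- hits + 1L
  }
  hits
}

#' Classify cluster-specific sites
#'
#' Per site: chi-square goodness-of-fit screen at `gof_alpha` (optionally
#' Bonferroni-corrected over tested sites), then the dominance-fraction
#' screen, then the permutation null; a site is specific when all three
#' pass. Sites failing an earlier stage are reported with the stage at
#' which they stopped.
#'
#' @param gmat a [genotype_matrix].
#' @param assignment a `cluster_assignment` (or integer vector of labels).
#' @param config a [specificity_config].
#' @return data.frame, one row per site: counts, `chi2`, `gof_p`,
#'   `dominant_cluster`, `dominant_fraction`, `perm_exceedances`,
#'   `is_specific`, `stage`.
#' @export
classify_cluster_specific <- function(gmat, assignment,
                                      config = specificity_config()) {
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else as.integer(assignment)
  stopifnot(length(cl) == n_samples(gmat))
  ns <- n_sites(gmat)
  k <- max(cl)
  obs_m <- matrix(0L, ns, k)
  nm_m <- matrix(0L, ns, k)
  chi2 <- gof_p <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    cc <- carrier_counts_by_cluster(gmat$presence[i, ], cl)
    obs_m[i, ] <- cc$observed
    nm_m[i, ] <- cc$nonmissing
    if (sum(cc$observed) >= 1 && all(cc$nonmissing >= 1)) {
      g <- gof_test(cc$observed, cc$nonmissing)
      chi2[i] <- g$chi2
      gof_p[i] <- g$p
    }
  }
  tested <- !is.na(gof_p)
  alpha <- if (config$gof_correction == "bonferroni")
    config$gof_alpha / sum(tested) else config$gof_alpha

  dom_cl <- dom_fr <- rep(NA_real_, ns)
  perm <- rep(NA_integer_, ns)
  stage <- character(ns)
  specific <- rep(FALSE, ns)
  cutoff <- config$permutation_alpha * config$n_permutations
  for (i in seq_len(ns)) {
    if (!tested[i]) { stage[i] <- "no_carriers"; next }
    if (gof_p[i] >= alpha) { stage[i] <- "gof"; next }
    d <- dominant_fraction(obs_m[i, ])
    dom_cl[i] <- d$cluster
    dom_fr[i] <- d$fraction
    if (d$fraction < config$dominance_threshold) {
      stage[i] <- "dominance"; next
    }
    site_config <- config
    site_config$seed <- config$seed + i
    perm[i] <- permutation_test(sum(obs_m[i, ]), nm_m[i, ], d$cluster,
                                site_config)
    if (perm[i] < cutoff) {
      stage[i] <- "specific"; specific[i] <- TRUE
    } else stage[i] <- "permutation"
  }
  data.frame(site_id = gmat$site_ids,
             observed = I(apply(obs_m, 1, paste, collapse = ",")),
             total_carriers = rowSums(obs_m),
             chi2 = chi2, gof_p = gof_p,
             dominant_cluster = dom_cl, dominant_fraction = dom_fr,
             perm_exceedances = perm, is_specific = specific,
             stage = stage, stringsAsFactors = FALSE)
}

#' Windowed deletion-abundance scan across clusters
#'
#' Per 500-kb (default) window: per-cluster carrier calls are summed over
#' the window's sites, expressed as cluster-size-weighted abundance
#' percentages, and tested for homogeneity against nonmissing-proportional
#' expectations with a chi-square goodness-of-fit test. Windows are
#' Bonferroni-corrected over the number of testable windows (those with at
#' least one carrier).
#'
#' @param gmat a [genotype_matrix].
#' @param assignment a `cluster_assignment` or integer label vector.
#' @param window_bp window size (default 500 kb).
#' @param chrom_lengths optional data.frame (`chrom`, `length`).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return data.frame: window coordinates, per-cluster weighted abundance
#'   percentages (`abund_1..k`), `chi2`, `p`, `significant`.
#' @export
windowed_abundance_scan <- function(gmat, assignment, window_bp = 500000,
                                    chrom_lengths = NULL, alpha = 0.05) {
  stopifnot(window_bp > 0)
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else as.integer(assignment)
  if (n_sites(gmat) == 0)
    return(data.frame(chrom = character(), window_start = integer(),
                      window_end = integer(), chi2 = numeric(),
                      p = numeric(), significant = logical()))
  k <- max(cl)
  pos <- gmat$positions
  rows <- list()
  for (ch in sort(unique(pos$chrom))) {
    on_ch <- which(pos$chrom == ch)
    last <- if (!is.null(chrom_lengths) && ch %in% chrom_lengths$chrom)
      chrom_lengths$length[match(ch, chrom_lengths$chrom)]
    else max(pos$start[on_ch])
    for (ws in seq(1, last, by = window_bp)) {
      we <- ws + window_bp - 1
      in_win <- on_ch[pos$start[on_ch] >= ws & pos$start[on_ch] <= we]
      obs <- nm <- rep(0L, k)
      for (i in in_win) {
        cc <- carrier_counts_by_cluster(gmat$presence[i, ], cl)
        obs <- obs + cc$observed
        nm <- nm + cc$nonmissing
      }
      chi2 <- p <- NA_real_
      abund <- rep(NA_real_, k)
      if (sum(obs) >= 1 && all(nm >= 1)) {
        g <- gof_test(obs, nm)
        chi2 <- g$chi2; p <- g$p
        w <- obs / nm
        abund <- 100 * w / sum(w)
      }
      row <- data.frame(chrom = ch, window_start = ws, window_end = we,
                        n_sites = length(in_win), chi2 = chi2, p = p)
      for (c in seq_len(k)) row[[paste0("abund_", c)]] <- abund[c]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  n_tested <- sum(!is.na(out$p))
  out$significant <- !is.na(out$p) & out$p < alpha / max(n_tested, 1)
  attr(out, "bonferroni_threshold") <- alpha / max(n_tested, 1)
  out
}
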