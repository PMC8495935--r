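#' Watterson's estimator of theta
#'
#' `S` segregating sites divided by the harmonic number
#' `H(n-1) = sum_{j=1}^{n-1} 1/j`. Here `n` is the number of genotypes
#' (presence/absence coding, one observation per genotype), so a 347-sample
#' panel uses `H(346)`.
#'
#' @param S number of segregating sites (>= 0).
#' @param n sample size (>= 2).
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(S >= 0)
  S / sum(1 / seq_len(n - 1))
}

#' Neutral expected counts per frequency bin
#'
#' Under the standard neutral model the expected number of segregating
#' sites with derived-allele count `i` is `theta_w / i`.
#'
#' @param theta_w Watterson's theta (>= 0).
#' @param bins integer vector of bin indices.
#' @export
expected_neutral_sfs <- function(theta_w, bins) {
  stopifnot(theta_w >= 0, all(bins >= 1))
  theta_w / bins
}

#' Observed minor-carrier site frequency spectrum
#'
#' Each site contributes one count to the bin equal to its minor-carrier
#' count (over nonmissing calls); bins run 1..floor(n/2) so a 347-sample
#' panel has a maximum bin of 173. Monomorphic (minor count 0) sites are
#' excluded. Watterson's theta is computed from the sites entering the
#' spectrum and the neutral expectation `theta_w / i` attached.
#'
#' @param gmat a [genotype_matrix].
#' @param folded_expectation use the folded textbook form
#'   `theta_w * (1/i + 1/(n-i))` (halved at `i = n/2`) instead of the plain
#'   unfolded `theta_w / i`.
#' @return object of class `sfs` with fields `n_samples`, `bins`,
#'   `observed`, `S`, `theta_w`, `expected`.
#' @export
observed_sfs <- function(gmat, folded_expectation = FALSE) {
  n <- n_samples(gmat)
  if (n < 2) stop("need at least 2 samples")
  bins <- seq_len(floor(n / 2))
  pres <- gmat$presence
  ones <- rowSums(pres == 1L, na.rm = TRUE)
  nm <- rowSums(!is.na(pres))
  if (any(nm == 0)) stop("site with all calls missing")
  minor <- pmin(ones, nm - ones)
  folds <- floor(nm / 2)[minor > 0]
  minor <- minor[minor > 0]
  observed <- tabulate(minor, nbins = max(bins))
  S <- length(minor)
  # how many sites can express each bin, given their nonmissing counts:
  # with no missing data this is S everywhere
  coverage <- vapply(bins, function(b) sum(folds >= b), numeric(1))
  theta_w <- watterson_theta(S, n)
  expected <- if (folded_expectation) {
    e <- theta_w * (1 / bins + 1 / (n - bins))
    if (n %% 2 == 0) e[bins == n / 2] <- theta_w / (n / 2)
    e
  } else expected_neutral_sfs(theta_w, bins)
  structure(list(n_samples = n, bins = bins, observed = observed,
                 S = S, theta_w = theta_w, expected = expected,
                 coverage = coverage,
                 folded_expectation = folded_expectation),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("site frequency spectrum: S =", x$S, "sites, n =", x$n_samples,
      "genotypes\n")
  cat(sprintf("  theta_w = %.2f; bins 1..%d\n", x$theta_w, max(x$bins)))
  invisible(x)
}

#' Chi-square fit of an observed spectrum to its neutral expectation
#'
#' The neutral `theta_w / i` expectation is renormalised to bin
#' probabilities over the spectrum's attainable support: a site with `m`
#' nonmissing genotypes can only express minor counts up to `floor(m/2)`,
#' so the reference mass in bin `i` is proportional to `coverage[i] / i`
#' where `coverage[i]` counts the sites whose folded support reaches bin
#' `i` (with no missing data this is exactly the `1/i` shape, and
#' `theta_w` cancels in the normalisation either way). Tail bins are pooled
#' until every pooled expected count is at least 5, and the usual
#' `sum((O - E)^2 / E)` statistic is referred to a chi-square with
#' pooled-bins-minus-one degrees of freedom.
#'
#' @param sfs an `sfs` object.
#' @param min_expected pooling threshold for expected counts (default 5).
#' @return list with `chi2`, `df`, `p`, `n_pooled_bins` and a data.frame
#'   `ratio` of per-bin observed/expected ratios.
#' @export
sfs_fit_statistic <- function(sfs, min_expected = 5) {
  stopifnot(inherits(sfs, "sfs"))
  obs <- sfs$observed
  coverage <- sfs$coverage %||% rep(sfs$S, length(sfs$bins))
  mass <- coverage / sfs$bins
  prob <- mass / sum(mass)
  exp_counts <- sfs$S * prob

  # pool from the tail: walk bins in order, opening a new pool once the
  # current one holds expected mass >= min_expected; the final short pool is
  # merged backwards
  pool <- integer(length(obs))
  cur <- 1L; acc <- 0
  for (i in seq_along(obs)) {
    pool[i] <- cur
    acc <- acc + exp_counts[i]
    if (acc >= min_expected && i < length(obs)) { cur <- cur + 1L; acc <- 0 }
  }
  if (acc < min_expected && cur > 1L) pool[pool == cur] <- cur - 1L
  O <- tapply(obs, pool, sum)
  E <- tapply(exp_counts, pool, sum)
  if (length(O) < 2) stop("fewer than 2 pooled bins")
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, n_pooled_bins = length(O),
       ratio = data.frame(bin = sfs$bins, observed = obs,
                          expected = exp_counts,
                          ratio = ifelse(exp_counts > 0, obs / exp_counts,
                                         NA_real_)))
}

#' Write a spectrum as TSV
#' @param sfs an `sfs` object.
#' @param path output file.
#' @export
write_sfs_tsv <- function(sfs, path) {
  utils::write.table(
    data.frame(bin = sfs$bins, observed = sfs$observed,
               expected = sfs$expected),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
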