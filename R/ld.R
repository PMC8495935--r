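#' Pairwise r-squared between two sites
#'
#' Squared Pearson correlation of the 0/1 vectors over samples nonmissing in
#' both sites (pairwise-complete). Returns `NA` when fewer than 2 shared
#' samples remain or either site is monomorphic on the shared set.
#'
#' @param x,y site vectors of 0/1/`NA` calls.
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Distance-binned LD decay profile
#'
#' All intra-chromosome site pairs with distance (difference of start
#' positions) at most `max_dist_bp` are binned into `bin_width_bp` distance
#' classes and the mean r-squared per bin reported. Pairs undefined under
#' [pairwise_r2] (monomorphic on the shared nonmissing set) are skipped.
#'
#' @param gmat a [genotype_matrix].
#' @param max_dist_bp maximum pair distance (default 500 kb).
#' @param bin_width_bp distance bin width (default 100 bp, the figure
#'   convention); bin `k` covers `((k-1)*w, k*w]` with midpoint
#'   `(k - 0.5) * w`; zero-distance pairs fall in bin 1.
#' @param stratum label stored on the profile (`all`, `genic`, `cds`).
#' @return data.frame of class `ld_profile`: `bin_mid`, `n_pairs`,
#'   `mean_r2`, with `bin_width_bp` and `stratum` attributes.
#' @export
decay_profile <- function(gmat, max_dist_bp = 500000, bin_width_bp = 100,
                          stratum = "all") {
  stopifnot(max_dist_bp > 0, bin_width_bp > 0)
  pos <- gmat$positions
  dists <- numeric(0)
  r2s <- numeric(0)
  for (ch in unique(pos$chrom)) {
    i <- which(pos$chrom == ch)
    if (length(i) < 2) next
    pres <- gmat$presence[i, , drop = FALSE]
    r2 <- suppressWarnings(stats::cor(t(pres),
                                      use = "pairwise.complete.obs"))^2
    d <- abs(outer(pos$start[i], pos$start[i], "-"))
    ut <- upper.tri(d)
    keep <- ut & d <= max_dist_bp & !is.na(r2)
    dists <- c(dists, d[keep])
    r2s <- c(r2s, r2[keep])
  }
  if (!length(dists)) {
    out <- data.frame(bin_mid = numeric(), n_pairs = integer(),
                      mean_r2 = numeric())
  } else {
    bin <- pmax(1L, as.integer(ceiling(dists / bin_width_bp)))
    out <- data.frame(
      bin_mid = (sort(unique(bin)) - 0.5) * bin_width_bp,
      n_pairs = as.integer(table(bin)),
      mean_r2 = as.numeric(tapply(r2s, bin, mean)))
  }
  attr(out, "bin_width_bp") <- bin_width_bp
  attr(out, "stratum") <- stratum
  class(out) <- c("ld_profile", "data.frame")
  out
}

#' Rolling mean over an LD profile
#'
#' Optional smoothing for plotting parity with moving-average decay curves.
#'
#' @param profile an `ld_profile`.
#' @param k window size in bins (odd).
#' @export
rolling_profile <- function(profile, k = 5) {
  sm <- stats::filter(profile$mean_r2, rep(1 / k, k), sides = 2)
  out <- profile
  out$mean_r2 <- ifelse(is.na(sm), profile$mean_r2, as.numeric(sm))
  out
}

#' Half-decay distance of an LD profile
#'
#' The smallest bin midpoint at which the mean r-squared has dropped to half
#' of the profile's maximum bin mean, or `NA` if never reached within the
#' profile's range.
#'
#' @param profile an `ld_profile`.
#' @export
ld_half <- function(profile) {
  if (!nrow(profile)) stop("empty profile")
  mx <- max(profile$mean_r2)
  i <- which(profile$mean_r2 <= mx / 2)
  if (!length(i)) return(NA_real_)
  profile$bin_mid[min(i)]
}

#' Restrict a genotype matrix to an annotation stratum
#'
#' @param gmat a [genotype_matrix].
#' @param overlaps data.frame from [overlap_features] (same site order).
#' @param stratum `"all"` (identity), `"genic"` or `"cds"`.
#' @export
stratify_sites <- function(gmat, overlaps,
                           stratum = c("all", "genic", "cds")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") return(gmat)
  stopifnot(nrow(overlaps) == n_sites(gmat))
  keep <- if (stratum == "genic") overlaps$in_gene else overlaps$in_cds
  if (!any(keep)) message("stratum '", stratum, "' is empty")
  subset_sites(gmat, which(keep))
}
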