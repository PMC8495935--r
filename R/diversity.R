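#' Per-site nucleotide diversity for presence/absence calls
#'
#' Average pairwise difference among nonmissing calls at one site:
#' `2 * c1 * c0 / (m * (m - 1))` for `c1` carriers and `c0` non-carriers out
#' of `m` nonmissing genotypes. Sites with fewer than 2 nonmissing calls
#' return `NA`.
#'
#' @param x site vector of 0/1/`NA` calls.
#' @export
site_pi <- function(x) {
  m <- sum(!is.na(x))
  if (m < 2) return(NA_real_)
  c1 <- sum(x, na.rm = TRUE)
  2 * c1 * (m - c1) / (m * (m - 1))
}

#' Per-site nucleotide diversity for diploid dosage calls
#'
#' Allele-level average pairwise difference: with `A = ploidy * m` sampled
#' alleles of which `a` are the alternate, `2 * a * (A - a) / (A * (A - 1))`.
#'
#' @param d site vector of alternate-allele dosages (0..ploidy, `NA`
#'   missing).
#' @param ploidy ploidy (default 2).
#' @export
site_pi_dosage <- function(d, ploidy = 2) {
  m <- sum(!is.na(d))
  if (m < 2) return(NA_real_)
  A <- ploidy * m
  a <- sum(d, na.rm = TRUE)
  2 * a * (A - a) / (A * (A - 1))
}

#' Windowed nucleotide diversity
#'
#' Sums per-site diversity over the sites whose start position falls in each
#' window and divides by the window length in bp. Windows tile each
#' chromosome from position 1; the default step equals the window size
#' (non-overlapping).
#'
#' @param gmat a [genotype_matrix] (binary mode) or a list with `dosage`
#'   (sites x samples) and `positions` for SNP dosage mode.
#' @param window_bp window size in bp (default 500 kb).
#' @param step_bp step between window starts (default `window_bp`).
#' @param mode `"binary"` uses [site_pi]; `"dosage"` uses [site_pi_dosage].
#' @param chrom_lengths optional data.frame (`chrom`, `length`); windows
#'   extend to the chromosome length, otherwise to the last site.
#' @return data.frame: `chrom`, `window_start`, `window_end`, `pi`,
#'   `n_sites`.
#' @export
window_pi <- function(gmat, window_bp = 500000, step_bp = window_bp,
                      mode = c("binary", "dosage"), chrom_lengths = NULL) {
  stopifnot(window_bp > 0, step_bp > 0)
  mode <- match.arg(mode)
  if (mode == "binary") {
    pos <- gmat$positions
    pis <- apply(gmat$presence, 1, site_pi)
  } else {
    pos <- gmat$positions
    pis <- apply(gmat$dosage, 1, site_pi_dosage)
  }
  skipped <- sum(is.na(pis))
  if (skipped > 0)
    message(skipped, " site(s) with <2 nonmissing calls skipped")
  out <- list()
  for (ch in sort(unique(pos$chrom))) {
    i <- which(pos$chrom == ch & !is.na(pis))
    last <- if (!is.null(chrom_lengths) && ch %in% chrom_lengths$chrom)
      chrom_lengths$length[match(ch, chrom_lengths$chrom)]
    else max(pos$start[pos$chrom == ch])
    starts <- seq(1, last, by = step_bp)
    for (ws in starts) {
      we <- ws + window_bp - 1
      in_win <- i[pos$start[i] >= ws & pos$start[i] <= we]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, window_start = ws, window_end = we,
        pi = sum(pis[in_win]) / window_bp, n_sites = length(in_win))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), window_start = integer(),
                      window_end = integer(), pi = numeric(),
                      n_sites = integer()))
  do.call(rbind, out)
}

#' Correlation between two windowed diversity tracks
#'
#' Pearson correlation of per-window diversity values paired on
#' (chromosome, window start), with a two-sided p-value.
#'
#' @param win_a,win_b data.frames from [window_pi].
#' @return list with `r`, `p` and `n_windows`.
#' @export
diversity_correlation <- function(win_a, win_b) {
  key_a <- paste(win_a$chrom, win_a$window_start)
  key_b <- paste(win_b$chrom, win_b$window_start)
  common <- intersect(key_a, key_b)
  a <- win_a$pi[match(common, key_a)]
  b <- win_b$pi[match(common, key_b)]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 paired windows")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a diversity track")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_windows = length(a))
}
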