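#' Read a multi-sample SNP VCF as a dosage matrix
#'
#' Biallelic genotypes are coded as alternate-allele dosage 0/1/2 (`NA`
#' missing). Returned sites x samples, with positions attached.
#'
#' @param path VCF file.
#' @return list with `dosage` (sites x samples), `positions` and
#'   `sample_ids`.
#' @export
read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  sample_ids <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), ncol = length(sample_ids))
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  called <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- gsub("[|/]", "", gt)
  dos[called] <- nchar(gsub("0", "", alleles[called]))
  list(dosage = dos,
       positions = data.frame(chrom = fix[, "CHROM"],
                              start = as.integer(fix[, "POS"]),
                              end = as.integer(fix[, "POS"]),
                              stringsAsFactors = FALSE),
       sample_ids = sample_ids)
}

#' Encode a SNP dosage matrix for clustering
#'
#' Drops monomorphic sites and mean-imputes missing dosages per site,
#' returning the samples x sites numeric matrix that the clustering and PCA
#' steps consume.
#'
#' @param dosage sites x samples numeric matrix of 0/1/2 dosages with `NA`
#'   missing.
#' @return samples x sites numeric matrix.
#' @export
encode_snp_matrix <- function(dosage) {
  dosage <- as.matrix(dosage)
  keep <- apply(dosage, 1, function(x) {
    v <- x[!is.na(x)]
    length(v) > 0 && length(unique(v)) > 1
  })
  dosage <- dosage[keep, , drop = FALSE]
  imputed <- t(apply(dosage, 1, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }))
  t(imputed)
}

#' Scan candidate k by average silhouette width
#'
#' Runs k-means (multiple restarts, fixed seed) for each candidate `k` and
#' records the average silhouette width on Euclidean distances; the chosen
#' `k` maximises the width (smallest `k` on ties).
#'
#' @param mat samples x sites numeric matrix from [encode_snp_matrix].
#' @param k_range candidate cluster counts (default 2..15).
#' @param seed RNG seed.
#' @param nstart k-means restarts per k (default 25).
#' @return list with `silhouette_by_k` (named numeric) and `chosen_k`.
#' @export
silhouette_scan <- function(mat, k_range = 2:15, seed = 1, nstart = 25) {
  stopifnot(all(k_range >= 2), all(k_range <= nrow(mat) - 1))
  if (nrow(unique(mat)) < max(k_range))
    stop("matrix has fewer distinct rows than the largest candidate k")
  d <- stats::dist(mat)
  widths <- vapply(k_range, function(k) {
    set.seed(seed + k)
    km <- stats::kmeans(mat, centers = k, nstart = nstart, iter.max = 50)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1))
  names(widths) <- k_range
  list(silhouette_by_k = widths,
       chosen_k = k_range[which.max(widths)])
}

#' Assign samples to k clusters
#'
#' k-means with multiple restarts; labels are renumbered by decreasing
#' cluster size so runs are comparable. Deterministic given `seed`.
#'
#' @param mat samples x sites numeric matrix.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param nstart restarts (default 25).
#' @param max_retry re-initialisations allowed if k-means degenerates.
#' @return list of class `cluster_assignment` with `cluster` (named integer
#'   vector in 1..k), `k` and `sizes`.
#' @export
assign_clusters <- function(mat, k, seed = 1, nstart = 25, max_retry = 5) {
  stopifnot(k >= 2, k <= nrow(mat))
  if (k == nrow(mat)) {
    # degenerate but well-defined: every sample is its own cluster
    cl <- seq_len(k)
    names(cl) <- rownames(mat) %||% paste0("S", seq_len(nrow(mat)))
    return(structure(list(cluster = cl, k = k, sizes = rep(1L, k)),
                     class = "cluster_assignment"))
  }
  km <- NULL
  for (attempt in 0:max_retry) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(mat, centers = k, nstart = nstart,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", k,
                        " nonempty clusters after retries")
  sizes <- table(km$cluster)
  relabel <- order(-as.integer(sizes), as.integer(names(sizes)))
  new_label <- integer(k)
  new_label[as.integer(names(sizes))[relabel]] <- seq_len(k)
  cl <- new_label[km$cluster]
  names(cl) <- rownames(mat) %||% paste0("S", seq_len(nrow(mat)))
  structure(list(cluster = cl, k = k,
                 sizes = as.integer(table(cl))),
            class = "cluster_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal-component coordinates
#'
#' Centered (unscaled) PCA of the sample x site matrix.
#'
#' @param mat samples x sites numeric matrix.
#' @param n_components components to return.
#' @return list with `coords` (samples x components) and `variance_fraction`.
#' @export
pca_coords <- function(mat, n_components = 10) {
  stopifnot(n_components <= min(dim(mat)))
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(coords = p$x[, seq_len(nc), drop = FALSE],
       variance_fraction = vf[seq_len(nc)])
}
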