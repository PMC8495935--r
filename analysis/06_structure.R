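#!/usr/bin/env Rscript
# Population structure from SNPs: dosage encoding, silhouette-selected
# k-means, and PCA coordinates. The panel plants eight clusters, so the
# silhouette curve should peak at k = 8 and the assignment should match
# the planted labels.

suppressMessages(library(svpopgen))

snp <- read_snp_vcf("results/panel/snp.vcf")
md <- read_metadata("results/panel/metadata.tsv")
mat <- encode_snp_matrix(snp$dosage)
rownames(mat) <- snp$sample_ids

scan <- silhouette_scan(mat, 2:10, seed = 1, nstart = 10)
assignment <- assign_clusters(mat, scan$chosen_k, seed = 1)
pca <- pca_coords(mat, 5)

write.table(data.frame(k = as.integer(names(scan$silhouette_by_k)),
                       silhouette = scan$silhouette_by_k),
            "results/silhouette.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = names(assignment$cluster),
                       cluster = assignment$cluster),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(sample_id = rownames(pca$coords),
                  as.data.frame(round(pca$coords, 4))),
            "results/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Average silhouette width by k:\n")
print(round(scan$silhouette_by_k, 3))
cat("Chosen k =", scan$chosen_k, "(planted: 8); cluster sizes:",
    assignment$sizes, "\n")
agree <- table(assignment$cluster, md$cluster)
cat("Samples concordant with planted clusters (one-to-one blocks):",
    sum(apply(agree, 1, max)), "of", length(assignment$cluster), "\n")
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
            100 * pca$variance_fraction[1],
            100 * pca$variance_fraction[2]))
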