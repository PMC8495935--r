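#!/usr/bin/env Rscript
# Build the synthetic study panel: 347 genotypes in eight clusters of sizes
# 43/44/37/31/40/58/55/39, 950 neutral deletion sites plus 50 planted
# cluster-specific deletions (90% dominance), 2000 cluster-informative
# SNPs, 5% missingness, mean depth 30. Everything downstream reads the
# files this writes.

suppressMessages(library(svpopgen))

cfg <- simulation_config(seed = 1)
panel <- simulate_panel(cfg)
paths <- write_panel(panel, "results/panel")

cat("Simulated panel written to results/panel/:\n")
cat("  ", n_sites(panel$sv_matrix), "SV sites x",
    n_samples(panel$sv_matrix), "samples;",
    sum(panel$truth$label == "specific"), "planted specific sites\n")
cat("  ", nrow(panel$snp$dosage), "SNP sites;",
    sprintf("%.1f%% missing entries\n",
            100 * mean(is.na(panel$sv_matrix$presence))))
cat("  files:", paste(basename(paths), collapse = ", "), "\n")
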