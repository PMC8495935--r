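---
title: "Methods: structural-variant population analysis on presence/absence panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopgen)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design decisions taken
where the method description left room.

## Data model

All SV analyses run on a **presence/absence genotype matrix**: sites ×
samples with entries 0 (variant absent), 1 (present — heterozygous and
homozygous alternate calls are collapsed, dosage is not retained) and `NA`
(missing). Missingness has two sources: uncalled genotypes in the VCF and
depth masking — any per-sample call with read depth below `min_depth`
(default 10×) is set missing regardless of its genotype, because
low-coverage SV genotypes are unreliable. Coordinates are 1-based
inclusive throughout, matching VCF and GFF3.

SNP analyses use alternate-allele **dosage** (0/1/2), because diploid SNP
genotypes carry allele-level information that presence/absence would
discard.

## Filter cascade

Stages run in a fixed order, each a subset of the last, tallied per SV
type: paired-end support ≥ 4; PRECISE breakpoint flag; removal of BND
(break-end) records, which mark rearrangements of unknown architecture and
carry no length semantics; size within [50 bp, 100 kb] inclusive at both
ends; per-site missing fraction ≤ 0.20 (a site is removed only when
*strictly* above 20%); and finally minor-allele frequency ≥ 0.05. Two
points were genuinely open:

* **MAF denominator.** "At least 18 carriers out of 347" is
  `ceiling(0.05 × 347)`, i.e. the panel size, so the default divides the
  minor-carrier count by the panel size; `maf_denominator = "nonmissing"`
  switches to the per-site nonmissing count.
* **MAF stage placement.** The spectrum and diversity analyses use the
  pre-MAF survivor set (rare variants carry most of the frequency signal);
  `filter_cascade()` therefore returns both sets and always tallies the
  MAF column.

## Site frequency spectrum and neutrality

With presence/absence coding there is one observation per genotype, so a
panel of n = 347 genotypes folds at bin ⌊n/2⌋ = 173: each segregating site
contributes one count at its minor-carrier bin. Watterson's estimator uses
the genotype count, θ̂w = S / Σ_{j=1}^{n−1} 1/j, and the neutral expectation
in bin i is θ̂w/i, taken in its plain unfolded form (the folded textbook
alternative θ̂w(1/i + 1/(n−i)) is available via `folded_expectation`). Over
the full unfolded range 1..n−1 these expectations sum exactly to S — the
harmonic identity the estimator is built on.

`sfs_fit_statistic()` turns the visual observed-vs-expected comparison into
a χ² test. Two numerical choices matter:

* **Support awareness.** A site with m nonmissing genotypes can only
  express minor counts up to ⌊m/2⌋. The reference probability for bin i is
  therefore proportional to `coverage[i]/i`, where `coverage[i]` counts the
  sites whose folded support reaches bin i. With no missing data this is
  exactly the 1/i shape; with missing data it prevents the upper bins
  (which many sites cannot reach) from registering as spurious deficit.
  θ̂w cancels in the normalisation either way.
* **Tail pooling.** Bins are pooled from the tail until every pooled
  expected count is ≥ 5, the usual validity rule for the χ² approximation;
  the statistic uses pooled-bins − 1 degrees of freedom.

## Windowed diversity

Per-site π is the average pairwise difference among nonmissing calls,
2c₁c₀/(m(m−1)); per window it is the sum of site values divided by the
window length in bp (not by callable sites — the window-length convention
makes windows comparable when site density varies). Windows tile each
chromosome from position 1 with step = window by default (500 kb); sites
are assigned by start position. SNP windows use the allele-level analogue
with 2m sampled alleles. The SV/SNP comparison is a plain Pearson
correlation over windows paired on (chromosome, start).

## LD decay

r² is the squared Pearson correlation of the two 0/1 site vectors over
samples nonmissing in *both* (pairwise-complete, as PLINK behaves); pairs
monomorphic on the shared set are undefined and skipped. Pairs are
intra-chromosomal with a 500-kb distance cap, binned at 100 bp (the
figure-level "moving average" convention; `rolling_profile()` adds an
optional rolling mean for plotting). LD½ is the smallest bin midpoint at
which the bin mean falls to half the *maximum* bin mean — the literal
"decayed to half of its maximum value", where the maximum is the largest
bin mean rather than the shortest-distance bin.

The decay generator plants a per-sample latent haplotype chain whose
retention probability falls with distance so that E[r²](d) =
exp(−d·ln2/`r2_half_bp`). Recovery checks run at 1-kb bins: near the half
point the decay loses only ~0.002 r² per 100 bp, below the bin-mean
sampling noise at realistic panel sizes, so "recovered within one bin" is
only a meaningful statement at the coarser resolution; the default profile
bin stays at 100 bp.

## Population structure

Dosages are mean-imputed per site (the standard neutral choice for
k-means), monomorphic sites dropped, and k-means run with 25 restarts
(10 in the bulk recovery checks) for each candidate k ∈ 2..15; the average
silhouette width on Euclidean distances selects k, ties to the smaller k.
Cluster labels are renumbered by decreasing size so runs are comparable.
Silhouette is computed on the full dosage matrix, not a PCA reduction —
with ~10³ sites the distance matrix is cheap and reduction would add a
tuning knob.

## Cluster-specific deletions

The screen is a three-stage conjunction per site:

1. **Goodness of fit.** Expected carriers per cluster are proportional to
   the *exact* per-cluster nonmissing counts (e.g. 32/286), not rounded
   percentages — only the exact convention reproduces the benchmark
   p-value of 4.314 × 10⁻⁹. χ² with (clusters − 1) df, α = 0.05
   uncorrected by default (the study corrected only the window scan;
   `gof_correction = "bonferroni"` is available).
2. **Dominance.** The top cluster must hold ≥ 70% of carriers; ties break
   to the lowest index.
3. **Permutation null.** Carriers are re-placed uniformly without
   replacement among the site's nonmissing genotype slots; the site passes
   when fewer than 5% of 100 permutations give the *focal* (observed
   dominant) cluster ≥ 70% of carriers. Monitoring the focal cluster is
   what the benchmark describes; `permutation_scope = "any"` monitors all
   clusters. For the focal criterion the permuted focal count is
   hypergeometric, so it is drawn directly — statistically identical,
   cheaper, and invariant to how the other clusters are labeled.

The windowed abundance scan sums per-cluster carrier and nonmissing calls
over 500-kb windows, expresses cluster abundances weighted by nonmissing
totals, tests homogeneity with the same χ² construction, and applies
Bonferroni across testable windows (those with ≥ 1 carrier).

## The synthetic panel generator

`simulation_config()` defaults *are* the study conditions: 347 genotypes,
eight clusters of sizes 43, 44, 37, 31, 40, 58, 55, 39; 1,000 deletion
sites (950 neutral background + 50 planted specific at 90% dominance with
15–30 carriers each); 2,000 cluster-informative SNPs; 5% missingness;
Poisson(30) depths, matching the panel's ~30× coverage. The genome is ten
5-Mb chromosomes — long enough for 100 half-megabase windows while keeping
desk-scale runtimes. Background carrier placement ignores cluster labels
(an exchangeable null), so the specificity false-positive rate is directly
interpretable. The background site count *is* the segregating-site count
S; no separate θ scale knob is kept, since a second multiplicative control
of S would be redundant.

One ordering decision matters for the spectrum. The generator draws each
site's missingness mask first and then plants the minor-carrier count
(drawn ∝ 1/i over the site's attainable range 1..⌊m/2⌋) among the
*nonmissing* genotypes. Masking an already-placed carrier set instead
would binomially thin the counts and compress the spectrum's upper bins
(the attainable fold drops from 173 to ≈165 at 5% missingness), so the
realized spectrum would systematically miss its nominal shape near the
fold no matter how large S is. With mask-first planting, the observed
spectrum equals the drawn one by construction, and the support-aware fit
statistic closes the loop.

SNP cluster structure uses a per-(site, cluster) allele-frequency shift of
±`snp_cluster_separation` (default 0.35 on the frequency scale, clamped to
[0.02, 0.98]) around a Uniform(0.2, 0.8) base frequency. At the default,
between-cluster centroid separation is comparable to the within-cluster
noise radius in aggregate over 2,000 sites — enough for silhouette
selection to recover the planted k reliably, which is what "well-separated"
means operationally here.

### What the generator does not emulate

No coalescent ancestry, recombination map, or shared drift between SNPs
and deletions: SNP structure and deletion placement are independent, so
the SV/SNP diversity correlation is near zero by construction, and LD
between panel deletions is sampling noise unless the dedicated decay
generator is used. Missingness is independent per entry, not
depth-correlated or sample-biased. Passing tests therefore demonstrate
that the statistics behave correctly under their own assumptions — not
that real panels satisfy those assumptions.

## Problem sizes and degenerate inputs

Simulation-backed checks use S = 5,000 sites (20 seeds) for the spectrum
fit, the default 1,000-site panel for specificity recovery, 10 seeds each
for silhouette-k (k ∈ {2, 8}, candidates 2..10) and LD½ recovery — sizes
at which the measured rates are stable yet a full run stays within a few
minutes on one core.

Degenerate inputs are defined rather than accidental: empty VCFs give
empty record sets; all-missing sites error in spectrum construction and
are skipped (with a message) in diversity; monomorphic pairs are skipped
in LD; k = n assigns every sample its own cluster; zero-carrier windows
are excluded from the Bonferroni denominator; infeasible planted-carrier
requests error with the offending site's parameters.

## Known limitations

Heterozygous and homozygous deletions are indistinguishable downstream of
reading; the permutation count (100) bounds how small an empirical
p-value can be resolved; the window scan treats sites independently
(linked deletions inflate its χ² just as they do in the original
construction); and the specificity screen's false-discovery behaviour is
driven by low-carrier background sites (2–5 carriers landing in one small
cluster), which a MAF-filtered input largely removes.
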