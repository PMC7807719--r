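# tsswitch

Genome-wide analysis of transcript start site (TSS) and transcript end site
(TES) heterogeneity across cell-fate transitions, from strand-specific
per-base 5′/3′ end-count tracks (TSS-seq / TES-seq).

During developmental transitions such as yeast gametogenesis, many genes do
not simply change how much they are transcribed but *where* transcription
starts and ends: an upstream alternative promoter can be induced while the
canonical (main) promoter is silenced, internal promoters inside ORFs can
produce truncated protein isoforms, and chromatin-factor mutants can
de-repress main promoters that upstream transcription normally keeps off.
`tsswitch` implements the complete analysis chain for these questions:

1. **Cluster calling.** Single-nucleotide end positions are normalized to
   tags per million (TPM = count / library size × 10⁶) and grouped by
   distance: positions ≤ 5 nt apart form per-sample tag clusters
   (single-position clusters kept at ≥ 3 TPM); clusters reaching ≥ 1 TPM in
   one or more samples are merged across samples (span gap ≤ 20 nt) and
   trimmed to the interval carrying the pooled signal's cumulative mass
   between the 0.05 and 0.95 quantiles. Each consensus cluster carries an
   apex (position of maximal pooled signal) and per-sample TPM and raw
   counts.
2. **Artifact filters.** 3′-end sites overlapping or within 5 nt upstream of
   a genomic poly(A) tract ((A)₂₀ with ≤ 8 mismatches) are removed before
   TES clustering (internal oligo-dT priming). TSS clusters whose base-wise
   raw counts correlate with a matched non-decapping control (Spearman
   r > 0.5, p < 0.05 over the cluster ± 5 bp) are flagged as non-capped
   spurious 5′ ends.
3. **Gene assignment.** Clusters are assigned to the closest
   non-overlapping gene in the same orientation: directly within 100 bp of
   the ORF start/end, or up to 1 kb away when every 30-bp sliding window of
   mRNA coverage between cluster and ORF has median coverage > 0 (TES side
   additionally: window median ≥ 5% of the gene-body median and window max
   ≤ 5× the gene-body max). Apex-to-codon distances define 5′/3′ UTR
   lengths; apexes inside the ORF are internal clusters.
4. **Main/alternative classification and switching.** Per transition, the
   main cluster is the highest-TPM cluster (≥ 1 TPM) at the reference
   timepoint; other clusters at ≥ 1 TPM are alternatives. Alternative usage
   is alt/(alt+main). Differential expression per cluster
   (median-of-ratios normalization, Welch t on log₂ counts, BH adjustment;
   a DESeq2-style table can be imported instead) feeds the event calls: a
   *switching event* is an upstream alternative induced ≥ 2-fold
   (FDR < 0.05) whose TPM reaches the main cluster's; the main TSS
   *response* is down/up/unchanged by the same two-fold/FDR rule.
5. **Internal isoforms.** Internal TSSs induced ≥ 2-fold (relaxed) are
   screened for truncated ORFs: the longest AUG→stop frame ≥ 300 nt on the
   sense strand between apex and annotated stop, with expression ≥ 1/3 of
   the full-length isoform (stringent), plus the leader length to the first
   in-frame AUG.
6. **Determinants of main-TSS repression.** For genes with a significantly
   induced upstream alternative, OLS regression of the main cluster's log₂
   fold change on the alternative's level (log₂ TPM), the log₂ apex-to-apex
   distance, and a nucleosome-occupancy-change covariate, reporting
   semi-partial correlations sr (the unique contribution of each
   predictor), plus Pearson/Kolmogorov–Smirnov comparisons around the 80-bp
   proximal/distal distance split.
7. **Mutant de-repression.** Mutant clusters are mapped onto control
   clusters by overlap; per gene, raw main vs summed-alternative counts in
   control and mutant are stacked over replicates into 2×2×K contingency
   tables and tested with the Cochran–Mantel–Haenszel statistic
   (continuity-corrected, χ² with 1 df). De-repressed genes have
   BH-adjusted p < 0.05, a larger main proportion in the mutant, and a main
   TSS that is repressed under upstream alternative transcription in
   control cells.

A synthetic-data generator (`simulate_dataset()`, `simulate_mutant_pair()`)
plants all of these events with known ground truth — clustered
single-nucleotide ends around promoter/terminator anchors, negative-binomial
replicate noise, poly(A) priming artifacts, spurious non-decapped clusters —
so the entire pipeline is validated end to end without external data.

## Worked example

```r
library(tsswitch)

sim <- simulate_dataset(n_genes = 40, n_internal = 5, n_priming = 5,
                        n_spurious = 3, seed = 1)
bundle <- run_pipeline(sim$tss_tracks, sim$sample_info, sim$config,
                       sim$genes, sim$rna_coverage, genome = sim$genome,
                       tes_tracks = sim$tes_tracks,
                       nondecapped = sim$nondecapped,
                       occupancy = sim$occupancy)

bundle$tss_clusters
#> <site_clusters> 385 TSS consensus clusters, 12 samples

table(bundle$assignments$category)
#> internal upstream
#>        5       80

table(bundle$gene_events$response, useNA = "ifany")
#>      down unchanged        up      <NA>
#>         4         6         3        27
sum(bundle$gene_events$any_switch)
#> [1] 7
```

385 consensus clusters are called from the 12 libraries (4 timepoints × 3
replicates; most clusters are background transcriptome). 85 of them are
assigned to the 40 genes — one main and one alternative promoter per gene,
plus 5 internal TSSs. Among genes whose upstream alternative is
significantly induced, 4 show main-promoter repression (the LUTI-like
pattern), 3 co-activation, 6 no main response; 7 genes pass the full
switching definition (alternative ≥ 2-fold up and at least as expressed as
the main). Per-gene usage ratios quantify the same shift continuously:

```r
head(subset(bundle$usage, timepoint == "t3",
            c(gene_id, main_tpm, alt_tpm, alt_usage, alt_usage_change)), 4)
#>    gene_id  main_tpm   alt_tpm alt_usage alt_usage_change
#> 4  gene001  9.716411 80.369504 0.8921428       0.76519214
#> 8  gene002 40.796856 48.040851 0.5407709       0.32801612
#> 12 gene003 12.189383 59.338426 0.8295854       0.72271619
#> 16 gene004 28.639979  3.332614 0.1042335       0.01781431
```

gene001 moves from main-dominated to 89% alternative usage across the
transition (+0.77), while gene004 is essentially unchanged. The determinant
regression on this small cohort:

```r
bundle$regression
#> Determinant regression (n = 13)
#> R^2 = 0.4532, adjusted R^2 = 0.2709
#>               term estimate       sr      p
#> 1        alt_level   -2.845 -0.14320 0.5755
#> 2    pair_distance   -0.108 -0.03536 0.8891
#> 3 occupancy_change   -2.680 -0.61740 0.0336
```

All three planted determinants enter with negative coefficients; at n = 13
only the occupancy covariate's unique contribution (sr = −0.62) is
individually significant — the cohort-scale validation below uses 164
records per fit.

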