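---
title: "Methods: TSS/TES heterogeneity analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS/TES heterogeneity analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsswitch)
```

# The problem

5′- and 3′-end sequencing protocols (TSS-seq, TES-seq) map the first or
last templated nucleotide of each mRNA molecule, giving strand-specific
per-base count tracks. Across a cell-fate transition, genes can shift their
promoter or terminator usage rather than (or in addition to) their overall
output: an upstream alternative promoter may rise while the canonical
promoter falls — in the extreme producing a 5′-extended, translationally
inert transcript that represses the downstream promoter in *cis* (the
LUTI mechanism) — and promoters inside ORFs can produce N-terminally
truncated isoforms. `tsswitch` turns raw end-count tracks plus an ORF
annotation into cluster-, gene- and cohort-level answers to these
questions. This vignette documents the model, every tunable parameter, the
numerical decisions, and what the synthetic validation does and does not
establish.

# Coordinate conventions

All internal coordinates are 0-based half-open; bedGraph input is already
0-based, GFF3 converts at the reader/writer boundary. A TSS "site" is the
single base of the 5′-most nucleotide of a read, a TES site the 3′-most
templated base. Strand determines direction everywhere: "downstream" means
increasing coordinates on `+`, decreasing on `-`. These conventions remove
every off-by-one ambiguity between the two file formats and make the
minus-strand code an exact mirror of the plus-strand code (the test suite
asserts reflection symmetry for UTR lengths, ORF scans and leader lengths).

# Cluster calling

Counts are normalized to tags per million within each library
(`normalize_tpm()`); the library size is the total of counted ends over
both strands of a sample.

**Per-sample tag clusters** (`call_tag_clusters()`): nonzero positions on
one contig/strand are grouped transitively whenever consecutive positions
are at most `max_dist = 5` nt apart. A group of exactly one position is
kept only at `singleton_floor_tpm = 3` TPM or more; the threshold is
inclusive, and it is a threshold on normalized signal, matching the
distance-clustering mode of CAGE-style cluster callers.

**Consensus clusters** (`aggregate_clusters()`): per-sample clusters with
at least `tpm_threshold = 1` TPM in one or more samples are merged across
samples when their untrimmed spans are within `max_dist = 20` nt (span gap,
transitively — span distance was chosen over midpoint distance, which the
distance parameter alone does not disambiguate). Each merged cluster is
trimmed on the pooled (position-wise summed) TPM signal: walking positions
5′→3′, the trimmed interval runs from the first position whose cumulative
mass strictly exceeds `q_low = 0.05` of the total to the first position
whose cumulative mass reaches `q_up = 0.95`. On twenty equal-TPM positions
this keeps exactly the central 90% of mass; the interval always retains at
least `q_up − q_low` of the mass, never widens the cluster, and contains
the apex. The apex is the position of maximal pooled TPM inside the
trimmed interval, ties broken 5′-most — a fixed tie-break so reruns are
bit-identical. Per-sample TPM and raw counts are re-accumulated over the
trimmed interval; raw counts feed the count-based tests downstream.

# Artifact filters

**Internal priming** (`find_polyA_tracts()`, `filter_internal_priming()`):
oligo-dT priming on genomic A-stretches fabricates 3′ ends. Windows of 20
nt with ≤ 8 mismatches to the strand-appropriate homopolymer are merged
into maximal tracts; a 3′-end site is removed when a tract overlaps it or
begins within 5 nt downstream (transcript direction). Removal happens on
the raw track, before TES cluster calling, so artifact positions never
contribute to the library-size denominator of downstream TES TPM.

**Spurious TSSs** (`flag_spurious_tss()`): genuine capped 5′ ends vanish
when the decapping step of the protocol is omitted, so signal that
*survives* in a non-decapping control is not a capped 5′ end. Over the
cluster ± 5 bp, the base-wise raw counts (raw, not TPM — the evidence is
the shared positional fingerprint, not the scale) of the decapped
reference sample and the control are compared by Spearman correlation with
average ranks for ties and the large-sample t approximation for the
p-value; a cluster is spurious at r > 0.5 and p < 0.05. A constant vector
on either side leaves r undefined and the cluster is kept: a spurious call
requires positive evidence, and in particular an all-zero control window
can never remove a cluster. The reference defaults to the first sample of
the reference timepoint and is configurable.

# Gene assignment

Each cluster is assigned to at most one gene — the closest non-overlapping
gene in the same orientation (apex-to-ORF-start for TSSs, apex-to-ORF-end
for TESs; equidistant ties break to the 5′-most gene start). Within 100 bp
the assignment is unconditional. Between 100 and 1000 bp, a 30-bp window
slides at 1-nt steps (the strictest reading; the window width is fixed,
the step configurable) across the mRNA coverage between cluster and ORF;
every window must have median coverage > 0. On the TES side two further
criteria guard against walking across an expression discontinuity: every
window median must reach 5% of the gene-body median and no window maximum
may exceed 5× the gene-body maximum. Windows are truncated at the gene
boundary; a region shorter than one window is a single truncated window.
Apexes inside a same-strand ORF are internal assignments; clusters
overlapping genes only on the opposite strand are left unassigned
(antisense signal is out of scope). 5′ UTR length is the distance from the
TSS apex to the first base of the start codon; 3′ UTR length from one past
the last stop-codon base to the TES apex.

The TSS far-tier uses only the median > 0 criterion; the 5%/5× criteria
apply to TESs only, where they are stated — read-through past a terminator
changes level, whereas upstream of a promoter there is no body signal to
compare against.

# Usage, differential expression, and events

Per transition (a named reference timepoint plus ordered transition
timepoints; labels are configuration, not code), the **main** cluster of a
gene is the highest-TPM cluster at the reference with ≥ 1 TPM (ties:
5′-most apex); every other cluster with ≥ 1 TPM at any transition
timepoint is **alternative**. Genes without a definable main are excluded
from usage statistics for that transition rather than imputed. Alternative
usage is alt/(alt + main) with the per-gene alternative TPM summed over
alternatives (pairwise variants are exposed for the pair-level analyses);
0/0 is recorded as missing. The usage ratio is invariant under any common
rescaling of a gene's clusters, so proportional co-induction leaves it
unchanged — only genuine redistribution moves it.

**Differential expression** is deliberately simple and pluggable:
median-of-ratios size factors (the median over clusters with positive
geometric mean of count/geometric-mean), log₂ fold change of
pseudo-counted condition means (pseudo-count 0.5 on the normalized scale),
a two-sided Welch t-test on log₂(normalized + 0.5) replicate values, and
Benjamini–Hochberg adjustment per comparison. The negative-binomial GLM
machinery of dedicated DE engines is intentionally not reimplemented: the
contribution here is the downstream usage analysis, and
`import_de_table()` accepts an externally computed table (cluster, log2fc,
padj) in its place. Significance is always the paired rule |log₂FC| ≥ 1
and FDR < 0.05.

**Events.** For each (gene, upstream external alternative) pair:
the *main response* at a timepoint where the alternative is significantly
up is down / up / unchanged by the same rule on the main cluster; a
*switching event* additionally requires the alternative's TPM to reach the
main's at that timepoint (dominance ratio 1, configurable — raising it can
only shrink the switch set); *co-downregulation* is both sides
significantly down. Timepoint-level events aggregate to the transition as
"any timepoint fired". When a gene has several upstream alternatives each
pair is evaluated separately and the gene-level call is the OR.

# Internal TSSs and truncated ORFs

A cluster is internal iff its apex lies in `[orf_start, orf_end)`.
*Relaxed* internal candidates are significantly up at ≥ 1 transition
timepoint. *Stringent* candidates additionally reach one third of the main
promoter cluster's TPM at a timepoint where they fired — the comparison is
on TSS-cluster TPM, chosen over mRNA-level quantities for internal
consistency since both sides then come from the same assay — and must
support a predicted ORF of ≥ 300 nt. ORF prediction scans the
transcript-sense sequence from the apex to the annotated stop, all three
frames of the sense strand only (matching forward-only ORF-finder
semantics), and reports the longest AUG→stop ORF entirely inside that
window, stop codon included in the length; candidates can therefore sit in
a different frame than the annotation, but never extend past the annotated
stop. The leader length to the first in-frame AUG approximates how much
5′ leader a truncated isoform would carry; an apex exactly on an in-frame
AUG has leader 0.

# Determinant regression

For genes whose upstream alternative is ≥ 2-fold up in the aggregated
comparison (one transition timepoint versus the reference; which timepoint
represents a transition is configuration — where two phrasings of the same
design disagree, both are supported and the choice is explicit), one
qualifying alternative per gene is chosen at random under the run seed so
multi-alternative genes contribute once. Records carry the apex-to-apex
distance (entering the model as log₂ nt; a raw-nt variant is exposed), the
alternative's log₂(TPM + 0.5) after transition (the pseudo-count is
documented because the log of a TPM can otherwise be undefined), the main
cluster's TPM before transition, the main cluster's log₂ fold change (the
response), and a per-gene nucleosome-occupancy-change covariate supplied
externally (its computation from chromatin data is out of scope; the
generator plants it with a negative effect). The 80-bp proximal/distal
split, Pearson and two-sample KS comparisons, and percentile subsetting
(nearest-rank percentiles, both comparisons inclusive) reproduce the
descriptive analyses; `fit_multiple_regression()` fits OLS and reports per
predictor the coefficient, its t-test p (which is exactly the test of the
semi-partial correlation), and sr computed as the correlation between the
response and the predictor's residual on the other predictors. The test
suite verifies sr² against the R² drop when the predictor is removed, to
1e-8, and rejects collinear designs by condition number.

# Mutant de-repression

Mutant-sample clusters are mapped to control clusters by ≥ 1 bp same-strand
overlap (largest overlap wins, ties 5′-most); mutant-only clusters are
retained and assigned to genes de novo. Per gene, raw counts (not TPM —
the stratified test needs counts) of the main cluster versus the sum of
all alternatives form one 2×2 table per replicate, replicates paired by
index across genotypes. The CMH statistic is
(|Σₖ(aₖ − Eₖ)| − ½)² / ΣₖVₖ with hypergeometric mean and variance from
each stratum's margins, χ² with 1 df; the continuity correction is on by
default and, as in the conventional implementation, is applied only when
the pooled deviation can absorb it. Degenerate strata (zero row or column
margin) are dropped with a warning. A single stratum reduces to the
Yates-corrected 2×2 χ² up to the factor (n−1)/n that separates the
hypergeometric from the Pearson variance. Across genes, BH adjustment
(chosen for consistency with the DE module) defines
increased-relative-expression (padj < 0.05 and larger pooled main
proportion in the mutant); de-repression additionally requires that in
control cells the gene's main TSS was significantly down while an upstream
alternative was up — so de-repressed genes are a subset of
increased-relative-expression genes by construction, and the relative
main-usage reported for plots is TPM-based while the test is count-based.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions every recovery bound is measured under.

* **Geometry.** Genes sit on one contig with 1.1 kb padding per side
  (ORF-to-ORF ≥ 2.2 kb) so assignment windows never compete; ORFs are
  ATG + non-stop codons + stop, mirrored for minus-strand genes. Main TSS
  offsets are drawn around 75 nt upstream of the ATG and TES offsets
  around 170 nt downstream of the stop — the genomic medians observed in
  budding yeast — and alternative spacings mix a proximal (36–79 nt) and a
  distal (80–400 nt) regime around the 80-bp analysis threshold. The
  proximal floor of 36 nt keeps planted pairs above the consensus merge
  reach (20 nt span gap given ~12-nt positional profiles); real tandem
  promoters closer than that would genuinely merge into one cluster under
  these clustering parameters, for any implementation.
* **Classes and trajectories.** Three planted classes at equal fractions:
  *repressed* (main 80→10 TPM, alternative 10→80 TPM over a geometric ramp
  — the LUTI-like switch), *coactivated* (main 30→240, alternative 10→80;
  the alternative never overtakes the main), *neutral* (flat 40/5). These
  are the expression scales of strongly regulated meiotic genes; 8-fold
  ramps are conservative relative to the orders-of-magnitude inductions of
  the strongest developmental regulons. Internal-TSS carriers are drawn
  from the neutral class so the one-third stringent criterion has a stable
  denominator, with strong (6→48 TPM) and weak (1.5→12 TPM) variants on
  either side of it.
* **Counts.** Per cluster, timepoint and replicate the expected total is
  TPM × library_size/10⁶ (default 2×10⁶ counted ends), drawn negative
  binomially (variance m + 0.05·m²; Poisson at dispersion 0) and spread
  over a geometric positional profile (decay 0.5, ~12 nt) downstream of
  the anchor — few-nt-wide clusters like real promoter signals. The rest
  of the transcriptome is emulated by 300 flat "ballast" clusters in a
  spacer region that top each library up to 10⁶ expected TPM: they pin the
  realised TPM scale, keep library-size fluctuation at the few-percent
  level, and — critically — give median-of-ratios normalization the
  mostly-unchanged majority it assumes; without them the size factors
  absorb the planted global induction, as they would on any real dataset
  consisting only of regulated genes.
* **Artifacts.** Priming artifacts are an (A)₂₀ tract planted 300 nt past
  a gene's stop with a 3′-end site 3 nt upstream of it; accidental A/T
  tracts arising by chance near a *true* TES anchor are disrupted at
  construction time, so "all planted artifacts removed, no true sites
  removed" is an exact property of the planted design rather than a
  statistical statement. Spurious promoters are mid-ORF clusters mirrored
  into the non-decapping control with the same positional profile; genuine
  clusters have an all-zero control window.
* **Mutant pairs.** `simulate_mutant_pair()` plants de-repressed genes in
  the repressed state in control (main 6, alternative 24 TPM) and
  multiplies the mutant's main expectation by the effect size. Replicate
  noise acts on each gene's total output (negative binomial) with a
  binomial main/alternative split within each replicate — read sampling —
  so that under exchangeability (effect 1) the conditional model of the
  stratified test holds and its type-I error is nominal. With fully
  independent per-cluster noise the within-stratum proportion is
  extra-binomially variable and the CMH test is anti-conservative; that
  regime is retained in the time-course generator, whose Welch test does
  not condition on margins.
* **Regression records.** `simulate_determinant_records()` draws
  independent unit-variance predictors and a response with coefficients
  (−0.4, −0.3, −0.2) and noise set to a generating R² of 0.27, for
  parameter-recovery checks at the cohort size of one aggregated
  comparison (164 records).

**What the validation shows — and does not.** Passing recovery bounds on
these cohorts demonstrates that the implementation applies its stated
rules exactly (the oracle-equivalence tests), that the chain of rules
recovers planted events at realistic depth and noise (≥ 85–95% per class,
FDR ≤ 10%, null false-call rates within calibration), and that reruns are
byte-identical. It does not demonstrate robustness to features the
generator does not emulate: overlapping or nested genes, introns, mapping
artifacts other than the two modelled ones, promoter sequence composition,
batch effects, or dispersion heterogeneity between genes. Real-data use
should treat the thresholds as the tested defaults, not as universally
optimal.

# Numerical choices and degenerate inputs

* Quantile trimming uses strictly-greater on the lower bound and
  at-least on the upper bound of cumulative mass; on symmetric mass this
  trims symmetrically and it never produces an empty interval (the bounds
  collapse to the apex position in the degenerate single-position case).
* All tie-breaks (apex, main definition, closest gene, cluster mapping)
  resolve 5′-most on the relevant strand, making every output
  deterministic; the only randomness in the pipeline, the
  single-alternative choice per gene in the determinant table, derives
  from the configured seed and a per-gene offset so it is stable under
  record reordering.
* Zero library sizes, empty tracks, all-zero control windows, genes
  without a definable main, strata with empty margins, and windows
  extending past contig ends are all defined cases (error, empty result,
  keep, exclude, drop-with-warning, truncate, respectively) exercised in
  the unit tests.
* Problem sizes in the validation suite — 1000 random tracks for the
  clustering oracles, 500 window-walk and 500 ORF-scan cases, a 300-gene
  event cohort, 10⁴ CMH stacks, 100 regression seeds, 400-gene mutant
  cohorts — were chosen so each recovery estimate has a standard error
  comfortably below the margin to its bound while the whole suite stays
  inexpensive on a single CPU.

# Session info

```{r}
sessionInfo()
```
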