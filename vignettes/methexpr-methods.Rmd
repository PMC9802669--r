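---
title: "Methods: methylome-transcriptome comparative analysis with planted truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-transcriptome comparative analysis with planted truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`methexpr` implements a comparative methylome-transcriptome pipeline for a
two-genotype x two-stage design (a wild and a cultivated accession sampled at
two seed developmental stages, three biological replicates per group), plus a
synthetic-data generator that plants known differentially methylated regions
(DMRs), differentially expressed genes (DEGs), co-expression modules, and
methylation-expression anti-correlation, so that every stage of the pipeline
can be validated against ground truth. The package starts from per-cytosine
count reports and gene-level count matrices; read trimming, alignment and
transcript quantification are out of scope.

## Methylcytosine calling

A cytosine's context is read from the two bases downstream in its strand's
5'-to-3' direction: CG if the next base is G, CHG if the base after next is G,
CHH otherwise (H is A, T or C); minus-strand cytosines appear as G on the
reference and are read towards decreasing coordinates, complemented. CG sites
are kept strand-specific - no symmetric CpG collapsing - because the report
format is strand-resolved. Sites whose two-base window runs off the chromosome
end get context `NA` and are excluded from context-stratified statistics
(counted in a QC field).

A site is considered only when covered by at least 4 reads in **every**
compared sample. The caller tests, per sample, `m` methylated out of `n` reads
against the null that an unmethylated cytosine produces a methylated call with
probability `error_rate` (bisulfite non-conversion plus sequencing error):
`p = P(X >= m | X ~ Binomial(n, error_rate))`, methylated iff `p < 1e-4`.
The error rate is a required, explicit parameter (default 0.01, a typical
plant WGBS non-conversion figure); `estimate_error_rate()` derives it from a
user-designated unmethylated control sequence when one is available. The
per-site methylation level is `m / n`.

Two definitions of "average methylation" coexist in the literature; both are
exposed. Summaries (`summarize_methylome()`) report the **mean of per-site
levels**, matching a per-site "percentage of reads giving a methylation call";
DMR statistics use **pooled reads** (sum m / sum n), because the Fisher test
operates on pooled counts and the difference statistic should match the
quantity tested.

## DMR detection

DMRs are detected per context between two samples (biological replicates are
pooled per group first). The window rule is site-count based: a window is 5
consecutive shared same-context sites (step one site). Base-pair windows were
the main alternative; site-count windows adapt to site density and guarantee
the minimum-site rule by construction, a common convention in bisulfite
pipelines. A window passes when the pooled level difference is strictly
greater than 0.1 **and** the two-sided Fisher exact p-value on the pooled 2x2
table is at most 0.05. Overlapping passing windows on one site run are
collapsed greedily into a single candidate, validating each extended union
against the same two criteria, so no site run is double-counted and every
emitted candidate itself satisfies the thresholds.

Nearby candidates (gap at most 100 bp; the notion of "nearby" is not
standardised, so the gap is a config knob) are **joined** when the full
spanning region - all shared covered context sites from the upstream start to
the downstream end - again passes both criteria; otherwise they remain
independent. Joining repeats left-to-right to a fixed point, which makes the
operation idempotent. Direction is hyper/hypo relative to the focal sample A
by the sign of the pooled difference.

No multiple-testing correction is applied at the window level - the rule is
deliberately the plain `p <= 0.05` cutoff - so genome-wide scans of truly
null material will flag roughly the nominal fraction of windows. The planted
recovery tests therefore score the false-discovery fraction against matched
null regions (same context and site count as the planted DMRs, no effect)
rather than against every called region.

## Expression analysis

FPKM is `1e9 * C / (N_s * L_g)` with `N_s` the sample's counted-fragment
total (total-mapped reads are unavailable without alignments) and `L_g` the
gene length. Genes must reach FPKM >= 1 in at least one sample of the
compared groups to be tested, and a DEG additionally needs fold change >= 2
(on group mean FPKM with a 0.01 floor) and Benjamini-Hochberg adjusted
p <= 0.001. BH was chosen because the upstream convention says only "adjusted
P-value"; the expression filter is applied per comparison.

The differential test is a transparent substitute for the published
count-based package the original analysis delegated to: pooling counts within
each group, the gene's group-A count, conditional on its total, is Binomial
with probability `N_A / (N_A + N_B)` under the null, and an exact two-sided
binomial test is applied. This keeps the stage bespoke and oracle-checkable.
It ignores biological replicate dispersion (as did the original tool), which
is why the DEG thresholds - especially the fold-change cutoff - carry most of
the false-positive control; the planted-DEG recovery test verifies that the
combination keeps null calls at or below 1% under the generator's dispersion.

Clustering uses per-gene z-scores of log2(FPKM + 1), Lloyd's algorithm with
k-means++ seeding under a fixed seed, several restarts keeping the best
within-cluster sum of squares, Euclidean distance, default k = 9. Ties go to
the lowest cluster index; an emptied cluster is re-seeded from the farthest
point. Sample-level overviews use hierarchical clustering on 1 - Pearson
correlation (average linkage) and PCA on the same normalised matrix.

## Co-expression

The network is the mathematical core of weighted co-expression analysis:
unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (default soft power 6) on
log2(FPKM + 1) profiles, and the topological overlap matrix
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with unit
diagonal. Block-wise machinery and tree-cut module detection are deliberately
out of scope: the downstream use is neighbour selection around a seed gene
set at similarity >= 0.2. "Expression similarity" is interpreted as TOM (the
similarity the threshold is quoted against); raw adjacency is exposed as an
option.

## Integration

A gene is DMR-associated when its genic region - body plus strand-aware 2 kb
upstream, clipped to the chromosome - overlaps a DMR by at least 1 bp (the
overlap fraction is configurable; any-overlap is the default reading). DEG
enrichment among DMR-associated genes is
`fold = (k/n) / (K/N)` with the hypergeometric upper tail `P(X >= k)`
(observed k included, the standard over-representation tail). The
hyper/hypo-by-up/down cross-tab counts each (DMR, DEG) pair once and reports
hyper fractions with empty classes as missing, not zero. Genome-scale
methylation-expression coupling is summarised in 1 Mb windows sliding 200 kb:
per-window mean site-level methylation against per-window mean
log10(FPKM + 0.01) of genes anchored by body midpoint, correlated by Pearson
with the t-transform p-value. Term enrichment treats the annotation as flat
gene-to-term pairs (no ontology propagation) with the same hypergeometric
tail and a BH q-value.

## The synthetic world

The generator emulates the study design, not any particular genome: uniform
random chromosomes (default 2 x 2 Mb), 400 non-overlapping genes of 1-5 kb,
two genotypes x two stages, three RNA-seq and three bisulfite replicates per
group, Poisson coverage (mean 30) with binomial methylation noise above an
additive error floor of 0.01 - the simplest model consistent with bisulfite
count data, and exactly the caller's null.

Context baselines default to CG 0.70, CHG 0.35, CHH 0.08, ordinary figures
for a methylation-rich plant seed genome. On top of the baselines sits a
deterministic sinusoidal "landscape" per chromosome (amplitude 0.15, two
periods), shared by both genotypes, and gene baseline expression is damped by
`exp(-6 * landscape)` at the gene midpoint. This is the device that plants
the genome-scale anti-correlation between windowed methylation and
expression, emulating heterochromatin-like domains; without regional
variation the windowed correlation would be undefined noise.

Planted DMRs are runs of 8 consecutive same-context sites (so the >= 5-site
rule can detect them by construction; placement fails loudly if the genome
cannot host them), shifted by +-0.4 in the focal genotype and clamped to
[0, 1]; a hyper CG-DMR at baseline 0.7 therefore saturates at level 1.0 and
realises a difference of ~0.3. Matched null regions - same context and site
count, no shift - are recorded in the truth tables as the negative controls
for false-discovery scoring. Inside planted and null intervals the landscape
is zeroed so the realised effect equals the configured one exactly. A
configurable fraction of genes (default 0.2) is anti-correlated: promoter
(2 kb upstream) methylation shifted up with expression divided by the DEG
fold in the focal genotype, or the reverse. Planted DEGs (fold 4, >= the 2x
threshold) are placed on genes with baseline mean >= 20 so that the
expression filter cannot hide them; counts are negative binomial with
dispersion 0.05, a low value appropriate for inbred-line biological
replicates. Module genes share a per-sample latent log-factor (sd 0.6),
giving within-module correlations around 0.85 at the default noise level.

All randomness flows from one seed through a counter-derived stream per
output file, so each file is individually reproducible and two runs of the
same config are byte-identical.

What a green test does **not** establish: the generator has no spatial
autocorrelation of methylation beyond the landscape, no bimodal per-site CG
methylation, no M-bias or coverage biases, no isoform structure, no
batch effects, and replicate dispersion far below what field samples show.
Green recovery tests validate the pipeline's logic and thresholds, not its
behaviour on any real dataset.

## Numerical choices

Fisher and binomial two-sided p-values are exact, computed from the unimodal
pmf by locating the opposite-tail cutoff with binary search (O(log n) per
table) and summing tails with `phyper`/`pbinom`; equality of probabilities
uses a 1 + 1e-7 relative guard, the same convention as `stats::fisher.test`.
Degenerate 2x2 margins return p = 1. Constant expression profiles are
dropped from correlation-based stages with a warning; z-scoring maps them to
zero vectors in clustering. Window tracks report empty windows as missing
(NA), never zero. Coordinates are 1-based inclusive internally; BED/BEDGRAPH
outputs convert to 0-based half-open.

## Pipeline

`run_subcommand()` exposes stages `simulate`, `callmc`, `dmr`, `deg`,
`cluster`, `network`, `integrate`, and `all`, driven by a YAML config whose
defaults are exactly the thresholds above, so a bare run applies the
standard rules. Every invocation writes a JSON manifest with the package
version, seed, per-stage row counts, the config hash and per-file MD5
checksums. A thin command-line front end lives at
`inst/cli/methexpr-cli.R` (exit codes: 0 ok, 2 config error, 3 missing
input, 4 runtime failure).

## Known limitations

- The DMR scan controls no family-wise or false-discovery rate; its
  operating characteristics are inherited from the plain threshold rule.
- The DEG test ignores biological overdispersion; with noisy field
  replicates it would be anti-conservative, and a dispersion-aware test
  should be substituted.
- The upstream-region definition uses the annotated gene start only; UTR
  structure is not modelled.
- Window geometry (site-count DMR windows, bp summary windows) and the
  100 bp merge gap are conventions, exposed as configuration, not claims
  about optimal values.
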