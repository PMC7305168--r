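---
title: "Methods and design of methtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of methtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methtx` quantifies the transcriptional consequences of global DNA
methylation loss: derepression of silenced gene programs, reactivation of
transposable elements (TEs), activation of genes near derepressed ERVs,
and cryptic transcription initiation from methylated CpG-rich sites
inside gene bodies. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic benchmark does and
does not demonstrate.

## Coordinates and methylation summarisation

All internal interval tables are 0-based half-open (BED convention); GTF
(1-based closed) and the methylation-caller dialects are converted on
read. A CpG is keyed by the 0-based position of its C on the plus strand;
when a caller reports the two strands separately, counts at the C and the
opposite-strand G are summed into one CpG before the depth filter is
applied. This strand merge is our choice — per-CpG scoring is the unit of
every downstream analysis, and merging first makes the depth filter act
on the quantity actually analysed. Chromosome names are matched by exact
string equality; stripping a `chr` prefix is an explicit flag, never a
silent normalisation, because silent renaming hides annotation
mismatches.

Depth filters follow the two library types: `min_depth = 8` for
MspI-based reduced-representation data, `min_depth = 5` per replicate for
whole-genome data, with replicates then pooled by summing methylated and
total counts (`pool_replicates()`), so pooled percentages are
count-weighted. Feature and window means are CpG-weighted — every covered
CpG counts once regardless of its depth — because the analyses average
the methylation of individual CpGs, not of reads. Undefined means (too
few CpGs) propagate as `NA`, never as 0: zero is a valid methylation
value.

Window analyses tile each chromosome from coordinate 0 (a deterministic
anchor; nothing in the method requires annotation-linked windows) in 1 kb
windows requiring at least 3 CpGs. Window classes are high (> 50%),
medium (10–50%, both boundaries included, the literal reading of the
strict `> 50%` and `< 10%` bounds), low (< 10%). De novo methylated
windows are those < 5% in the early (pre-implantation) state and
strictly > 50% in the late state.

## The DMR caller

The published contract is three criteria: at least three differentially
methylated CpGs (DMCs), methylation difference > 20 percentage points,
adjusted p < 0.001. The engine behind them is ours and deliberately
simple: per-CpG two-sided Fisher exact tests on pooled
methylated/unmethylated counts (a DMC has p < 0.01 and |Δ| > 20 points),
candidate regions are maximal runs of DMCs at most 250 bp apart, the
region p is a direction-signed Stouffer combination of its DMC p-values,
and Benjamini–Hochberg adjustment runs across candidates. The 250 bp
clustering distance and the Stouffer combination are replaceable design
choices; the three published criteria are enforced exactly on the output.
On label-permuted null data the caller returns zero DMRs in ≥ 95% of 100
seeded runs (tested).

## Promoter classes and gene groups

The CpG ratio is the standard observed/expected form,
`n_CpG · L / (n_C · n_G)` per 500 bp window advanced in 20 bp steps
across TSS ± 1 kb — the established convention behind the 0.45/0.65
thresholds. N bases are excluded from all counts and from the window
length; a final partial window (< 500 bp) is not evaluated, since the
thresholds are calibrated for 500 bp; CpGs are counted on the given
strand and attributed to the window containing their C. HCP requires one
window with ratio > 0.65 and GC > 55%; LCP requires no window above
0.45; the rest are ICP. Upregulated genes split into group 1 (LCP),
group 2 (ICP/HCP, wild-type promoter methylation < 30% over −1000..+500
from the TSS) and group 3 (ICP/HCP, ≥ 30%, boundary inclusive).

## The differential-expression engine

The engine is a documented minimal stand-in, not a clone of any
established package: median-of-ratios size factors (features nonzero in
all samples; library-size fallback under 100 such features), group means
on normalised counts, `log2fc = log2((m_B + 0.5)/(m_A + 0.5))` (the 0.5
pseudocount bounds fold changes of sparse features for the > 3-fold
rules), and a delta-method Wald statistic under NB variance
`m + α·m²`. There is no dispersion-trend or fold-change shrinkage, no
independent filtering, no outlier handling.

The dispersion estimate needed one genuine design decision. A raw
per-feature method-of-moments estimate from 3 + 3 replicates has ~4
degrees of freedom, which makes the Wald z behave like a t(4): the null
rate of p < 0.001 would be ~2–3%, twenty times nominal. We therefore
bound each feature's estimate below by a common dispersion — the 10%
trimmed mean of the method-of-moments values over features with
normalised mean ≥ 5, where the estimator is informative (low-count
features blow the moment estimator up and would inflate an untrimmed
mean). Features with genuinely high dispersion keep their own larger
estimate. This is a common-dispersion stabiliser in the spirit of the
simplest NB tools, not empirical-Bayes shrinkage. Measured on a
50,000-feature simulated null it yields an empirical rate of p < 0.001
of ~0.0012 (the acceptance suite asserts the [0.0002, 0.003] band), and
a planted 8-fold effect at 3 vs 3 replicates is recovered ≥ 95% of the
time at the gene policy.

Calling policies are data, not code: genes and TE copies at fold
change > 3 with BH-adjusted p < 0.001; TE families at fold change > 2,
adjusted p < 0.001; exons at fold change > 3 with *raw* p < 0.001 — the
exon threshold is taken at face value as unadjusted, as printed.

One caveat worth recording: "rescaling one sample is absorbed by its
size factor" holds exactly for fold changes and calls, but not for
p-values — the geometric-mean reference of median-of-ratios includes the
rescaled sample, so all normalised counts shift by a common factor and
the Poisson term of the NB variance is not scale-free. The tests assert
fold-change/call invariance and p-value order preservation.

## TE quantification

Fractional family counting gives every alignment weight `1/n_hits`; an
alignment overlapping ≥ 1 bp of a copy assigns its weight to that copy's
family, split equally when one alignment touches copies of several
families; alignments touching no TE go to an explicit `unassigned` sink
(the apportioning of a read hitting both TE and non-TE space is not
specified anywhere authoritative; the sink keeps mass conservation
auditable — total mass per sample equals the number of distinct reads,
to 1e-6). Copy-level counting uses unique reads only; a unique read
spanning two adjacent copies increments both (documented, rare).
Family-level differential expression is normalised by total read mass
(assigned + unassigned) rather than median-of-ratios: the family matrix
is a composition of a few rows within a fixed total, where
median-of-ratios would misread a composition shift as a depth change.

ERV-proximal genes are those whose TSS lies strictly within 20 kb of an
upregulated ERV copy — TSS-to-interval nearest-edge distance,
strand-ignored, since only the TSS side is named by the 20 kb rule. The
comparison set is a seeded random sample of genes near any ERV, and the
report carries fold-change distributions, Wilcoxon contrasts and the
fraction of each set called up. LTR strand metaplots merge family copies
separated by < 8 kb, anchor at the element's oriented start, and average
per-strand coverage in 50 bp bins over ±5 kb, flipping minus-strand
elements.

## The cryptic-initiation caller

Candidate isoforms have ≥ 1 upregulated exon at the exon policy. The
seven criteria are applied in order: (i) the percentage of upregulated
exons is < 100; (ii) exon 1 is not upregulated; (iii) no isoform of the
same gene has 100% upregulated exons; (iv) with < 5 upregulated exons
they must be consecutive; (v) with ≥ 5, at most one non-upregulated exon
may sit strictly inside the upregulated span (the literal reading of "a
gap of one exon is tolerated"); (vi) the mean linear fold change of
upregulated exons exceeds 3× that of the remaining exons (arithmetic
mean of linear fold changes — the aggregation is not specified upstream;
`agg = median` is available); (vii) the mean FPKM of upregulated exons,
in the upregulated condition (our choice of condition; configurable),
exceeds that of the rest.

Two manual steps in the original procedure are replaced by deterministic
rules, for reproducibility: one isoform per gene is kept by most
upregulated exons, then longest transcript, then lexicographic id — which
also makes output independent of input order (tested); and instead of
manual curation against browser tracks, the initiation position is
defined as the genomic 5' start of the 5'-most upregulated exon and the
call is dropped when that position ± 50 bp overlaps a TE copy (other
than simple repeats/low-complexity) or a provided alternative-promoter
annotation. Criterion (iii) is evaluated over all annotated isoforms
with counted exons, expressed or not. Every candidate carries its full
criterion trace so borderline rejections can be audited.

## The synthetic benchmark

The generator plants every phenomenon the pipeline measures, at a desk
scale chosen so the full suite runs in minutes on one CPU: two 5 Mb
chromosomes, 300 genes on a regular slot grid (one representative and up
to one exon-skipped isoform each), ~160 TE copies from eight families,
20 germline DMRs, 30 de novo windows, 20 cryptic-initiation genes plus
two TE-overlap decoys, 20 derepressed genes (8-fold; split across
germline-like methylated-HCP, 2C-like unmethylated-HCP and LCP promoter
kinds), 12 reactivated ERV copies (10-fold; eight of them forced
adjacent to derepressed genes so ERV-proximal effects exist by
construction). Methylomes: four states (wild type, Dnmt1-null,
Dnmt3a/b-double-null, ICM-like reference) × two replicates, depth
truncated-NB with mean 12 (a realistic whole-genome depth), per-CpG
beta-binomial with precision 100. Counts: three genotypes × three
replicates, log-normal baselines (meanlog log 300, sdlog 0.7 — an
expressed-gene range in which the planted folds, not expression floors,
are the quantity under test), NB dispersion 0.05, mild log-normal size
factors.

Promoter classes are realised by sequence construction: HCP promoters
get a CpG-island block (GC 0.65, no CpG depletion) that is also emitted
in the CGI annotation; ICP promoters an intermediate block (GC 0.48,
55% CpG retention); LCP promoters a strongly depleted block (5%
retention); background sequence retains 30% of iid CpGs, mimicking
genomic CpG depletion. The classifier recovers the constructed classes
essentially exactly (≥ 95% asserted; observed 100%).

Methylation means per CpG follow a precedence of region classes
(germline DMR > retained TE family > CGI > de novo window > background).
The two hypomethylated states share a per-1 kb-window latent landscape,
uniform on [0.18, 0.58]; the wild type draws an independent landscape on
[0.65, 0.95]; the Dnmt1-null scales the wild-type means uniformly by
0.25 — germline DMRs included, which is what makes imprints collapse in
the Dnmt1-null (to ~12.5%) while the double-null retains them at ~50%.
The double-null copies the ICM-like means except at retained young ERV
families (85% vs 75% in the reference) and germline DMRs. The landscape
floor of 0.18 is an analytic margin: at the default depth, precision and
CpG density (~13 CpGs per window; planted de novo windows additionally
carry a guaranteed dozen CpGs by construction), the probability that any
non-planted window's observed mean drops below the 5% de novo bound is
far below one event per genome, so the de novo filter recovers the
planted set exactly rather than probabilistically. The shared landscape
is also what the DKO-ICM window correlation (r ≈ 0.95 observed, > 0.9
asserted) measures — it is a property of the construction, not a claim
about effect sizes in real embryos.

What the benchmark does *not* emulate: read-level bisulfite chemistry,
alignment and mapping bias (multi-mapping is abstracted to an `n_hits`
count), non-CpG methylation, isoform-level expression estimation,
dispersion heterogeneity across features, batch structure, and the
scale of a real genome. Passing tests therefore demonstrate the
correctness and calibration of the implementations under the stated
statistical model, not genome-scale performance on real libraries.

## Problem sizes and runtime

The default study (`sim_config()`) is sized for interactive use: ~10 s
simulation, ~15 s full pipeline. The test suite runs the default study
once and otherwise uses reduced configurations (one 2.5–3.5 Mb
chromosome, 75–105 genes) — in particular the twenty replicate
simulations behind the cryptic-caller sensitivity check keep the planted
conditions (20 genes, 10-fold, 3 vs 3) on the smaller genome. The null
calibration uses 50,000 features. The whole suite completes in about two
minutes on one CPU; `scripts/acceptance.R` in about one.

## Known limitations

The Wald engine is anticonservative for features whose true dispersion
far exceeds the common floor; it is meant as a threshold-faithful
stand-in, not a replacement for a mature NB framework. The DMR regioner
(250 bp, Stouffer) is a stand-in for more elaborate segmentation models.
The cryptic caller inherits the resolution of exon-level counting: an
initiation site inside an exon is reported at the exon boundary. FPKM
conservation holds per construction only under library-size factors.
Coverage-profile extraction for LTR metaplots is O(elements × bins) and
intended for hundreds, not millions, of elements.
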