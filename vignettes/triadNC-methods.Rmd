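---
title: "Models and methods behind triadNC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triadNC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadNC)
```

triadNC implements the downstream integration layer of a
parent–parent–hybrid (triad) epigenomics study: an allopolyploid maternal
line (AACC), a diploid paternal line (AA) and their F1 allotriploid
hybrid (AAC), profiled for mRNA and lncRNA expression, small-RNA
clusters, DNA methylation and chromatin accessibility. This vignette
explains the statistical models, the rules and their boundary behaviour,
the synthetic-data generator used for validation, and the design
decisions taken where the methodology was genuinely open.

## Coordinates and data model

All interval logic runs on `GRanges` (1-based, closed — the Bioconductor
convention). BED input/output converts at the file boundary through
rtracklayer; GFF3 is native 1-based. Every distance rule in the package
is defined on the *gap in bases between interval edges*, which is
representation-independent: a cluster is proximal to a gene when the gap
is strictly below 2,000 bases, whatever convention stores the intervals.
Unstranded features participate in overlap tests on both strands.

Expression lives in an `expression_matrix`: a feature-by-sample value
matrix (unit-tagged TPM, RPM or raw counts), ordered sample metadata
(generation maternal/paternal/hybrid/insilico, replicate index) and
optional per-feature subgenome tags. Methylation is a per-cytosine count
table in the Bismark CX-report dialect (chrom, 1-based position, strand,
context, methylated/unmethylated read counts) — counts rather than
ratios, because both the weighted level and the differential test operate
on raw reads.

## Expression-pattern classification

Four pairwise comparisons drive the classifier: hybrid vs maternal
(HvsM), hybrid vs paternal (HvsP), maternal vs paternal (MvsP), and
hybrid vs mid-parent (HvsMPV). The mid-parent expectation (MPV) is an
in-silico hybrid: either the arithmetic mean of depth-normalized parental
replicate pairs (mean mode) or an exact 1:1 read-level mixture obtained
by multivariate-hypergeometric subsampling of each parental library to
half the target depth (pooled-count mode, which conserves total depth
exactly and is deterministic given its seed).

The built-in differential test operates on log2(CPM + 1). Two engines sit
behind the same record shape: a per-feature Welch t-test, and the default
limma moderated t (pooled empirical-Bayes variance), which is the
standard choice at two to three replicates — with per-feature variances
estimated from two degrees of freedom, a single outlying replicate
otherwise erases real four-fold changes. Externally computed DE tables
(e.g. a count-model result) can be substituted wherever a comparison
table is consumed. A comparison is *significant* when the BH-adjusted
p-value is below 0.05 **and** |log2FC| ≥ 1.5 (1.0 for small RNAs). The
HvsMPV comparison alone uses a 0.5 fold-change floor: it screens for
*deviation from additivity*, an equivalence-style question for which a
1.5-fold floor would be backwards — a dominant hybrid deviates from the
mid-parent by only half the parental gap.

Labels are assigned by a fixed cascade — no-change (nothing significant),
transgressive-up/-down (both hybrid-parent tests significant, hybrid
outside the parental range), additive (MvsP significant, HvsMPV not,
hybrid between the parents), ELD-M / ELD-P (hybrid indistinguishable from
one parent, different from the other), else ambiguous. Two refinements
make the cascade robust where test verdicts are uninformative:

* **Adaptive closeness guards.** On the log2 scale the arithmetic
  mid-parent sits `g + 1 - log2(1 + 2^g)` below the high parent for a
  parental gap of `g` log2 units — only 0.68 for a four-fold gap, inside
  every fold-change gate. Additivity therefore also requires the HvsMPV
  point estimate below the midpoint between the additive and the nearest
  dominant hypothesis (computed per feature from the observed gap, applied
  one-sided), and an ELD call requires the hybrid actually close to the
  retained parent.
* **Nearest-hypothesis refinement** (`call_patterns(refine = TRUE)`,
  default). For features with significantly different parents whose call
  landed in the confusable set (additive / ELD / ambiguous), the final
  label is whichever hypothesis — mid-parent value, maternal level,
  paternal level — lies closest to the observed hybrid mean. The
  twelve-bin sign code is always recorded unmodified, so a strictly
  verdict-based grouping can be recomputed post hoc.

The twelve-bin code itself is an explicit lookup over the realizable sign
triples of (HvsM, HvsP, MvsP): bins I–VI for maternal-high parents,
VII–XII mirrored; triples that are internally inconsistent (for example
both hybrid tests firing while the parents are indistinguishable) carry
the code `none` and are resolved by the cascade alone.

## Subgenome dosage response

Relative dosage across AACC / AAC / AA is (1/2, 2/3, 1) for the A
subgenome and (1/2, 1/3, 0) for C. `correlate_dosage()` computes the
product-moment correlation and its two-sided t-test on n − 2 degrees of
freedom. Two input modes exist because they answer different needs:
`mode = "mean"` correlates the three per-generation replicate means —
faithful to the three-value worked example, but with one degree of
freedom the t-test is essentially powerless (p = 0.16 even at r = 0.97),
so FDR-gated calling cannot work; `mode = "replicate"` repeats the dosage
per replicate (nine points) and is the recommended calling mode. A
feature is dosage-dependent when R² > 0.64 (strictly) and BH FDR < 0.05
(strictly), with the sign of r separating positive from negative
responders; zero-variance features are unclassifiable and excluded from
the BH family, which is formed per subgenome. Reported two-decimal values
of r and R² use truncation, not rounding, which is the convention that
reproduces the published pair (0.96, 0.93) from the full-precision
(0.9685, 0.9380).

## ncRNA annotation rules

All comparator strictness follows the wording of the underlying rules:

* candidate lncRNAs must be **longer than** 200 nt (exactly 200 fails)
  and have maximal TPM **at least** 0.5; rejection reasons are recorded
  in a fixed rule order, and a missing coding-potential verdict is an
  error, never a silent pass;
* genic/proximal/distal uses ≥ 1 bp overlap, then gap **strictly below**
  2 kb (a gap of exactly 2,000 bases is distal);
* replicate ACR peaks merge only when they overlap by **more than**
  50 bp (exactly 50 does not merge); merged output is the union of each
  cross-replicate support component with at least two replicates;
* ACR-lncRNAs need **more than** half the lncRNA locus covered by ACR
  bases, measured from the lncRNA side, in at least two replicates
  (exactly one half fails); the lncRNA-side reading was chosen because
  the defining phrase takes the lncRNA as subject, and the fraction is
  configurable;
* novel ACR-lncRNAs: hybrid TPM **strictly above** 0.5 with both parents
  **strictly below** 0.1;
* activated phasiRNA loci: hybrid reads **strictly above** 1 with both
  parental counts exactly 0 (silenced is the mirror). Raw counts, not
  RPM — a zero-read clause is only meaningful for counts;
* TE association: ≥ 1 bp overlap (no fraction is defined for it in the
  source methodology; the threshold is exposed in the configuration),
  superfamily from the largest overlap, ties to the earliest genomic
  position.

## Methylation

The weighted level of a region is Σ methylated / Σ total over cytosines
with read depth ≥ 5 — a count-weighted ratio, not a mean of site ratios,
so deeply covered sites dominate and the level of a union of regions is
the count-weighted mean of the parts (a tested conservation law).
Metaprofiles pool counts into 2-kb flanks in 100-bp bins and a body
rescaled to 20 bins, flipping bins for minus-strand features; pooling all
bins reproduces the global weighted level of the profiled windows.
Regions shorter than the body bin count contribute flanks only and are
counted in a `skipped_bodies` attribute.

The DMR caller tiles each context into 200-bp bins; a bin is tested when
both groups hold at least five valid cytosines (so both readings of the
five-cytosine rule — per-site depth and per-bin site count — are
enforced). Pooled methylated/unmethylated counts form a 2×2 table tested
by a two-sided Fisher exact test; the underlying upstream tool does not
document its statistic, so the test sits behind a single function and is
straightforward to swap. BH runs per context across tested bins, and a
DMR needs padj < 0.01 **and** a level difference strictly above 0.3 /
0.2 / 0.1 (CG / CHG / CHH). Symmetric CG sites are not merged across
strands (the CX input is per-strand); direction is reported as hyper when
group 2 gained methylation.

## Integration layers

Cis pairs use inclusive "within" gates (edge gap ≤ 5 kb for lncRNAs,
≤ 2 kb for phasiRNA loci; overlap = distance 0); trans co-expression
requires R² strictly above 0.81 at a gap strictly above 5 kb or across
chromosomes, so the cis and trans territories partition the qualifying
pairs. Pair correlations are computed on log2(value + 1) at replicate
level — consistent with the DE transform — and summaries split at r = 0.
Signal metaprofiles assign each weighted interval to bins in proportion
to the overlapped fraction of the interval, conserving total weight
within the profiled windows.

Fuzzy c-means (fuzzifier m = 2) standardizes profiles per feature, starts
from a seeded random membership matrix, and alternates centroid and
membership updates; the objective sequence is returned and is
non-increasing by construction. Ties in the hard assignment go to the
lowest cluster index. The implementation is in-package because the
objective trace and seeded initialization are part of the contract; tests
cross-check it against an independent implementation of the same
algorithm.

## The synthetic-data generator

The generator emulates the study design at desk scale, with one RNG
stream per sub-generator derived from the master seed so extending one
generator never perturbs another's draws.

* **Annotation**: one chromosome, features laid out on a 10-kb slot grid.
  Genes carry three 600-bp exons; lncRNAs are placed to *realize* their
  planted class (antisense over an exon, fully intronic, sense-
  overlapping, or intergenic > 2 kb from any gene); siRNA clusters are
  planted genic / proximal (500-bp gap) / distal; half the TEs overlap
  lincRNAs; true ACRs span lncRNAs (planted ACR-lncRNAs) or sit in free
  slots. Placement is deterministic given the seed, so positional truth
  recovers exactly.
* **Expression**: negative-binomial counts (dispersion 0.05, a typical
  biological-replicate value for controlled plant material) around
  planted generation means; 3 replicates; planted effect 2.0 log2 units.
  Parental differences are split symmetrically (±effect/2 around the
  baseline, random high parent) and the transgressive classes mirror each
  other, so expected library composition is equal across generations —
  without this, total-count normalization compresses every planted fold
  change and no classifier can recover the labels. Library depths vary
  ±20% around the target; baseline means span 16–512 counts.
* **Dosage series**: means proportional (or affinely decreasing) in the
  subgenome dosage vector, log-normal multiplicative noise of 0.25 log2
  units per replicate; dosage-independent features have flat means.
* **Methylation**: beta-binomial per-site counts (concentration 100 —
  mild overdispersion, keeping the pooled-count Fisher test
  near-calibrated) around context baselines CG 0.3 / CHG 0.25 / CHH 0.08,
  coverage ~30×; planted bins shift group 2 upward by 0.5 / 0.35 / 0.2.
* **ACRs**: true peaks appear in all replicates with ≤ 20 bp uniform
  boundary jitter; decoys appear in exactly one replicate on a
  non-overlapping grid, so the merge rule must eliminate them.

What passing recovery tests does and does not show: the generator plants
clean, single-cause signals with independent noise; real data add mapping
artefacts, shared batch structure, partially redundant homeologs,
unbalanced classes and unknown effect-size spectra. Recovery rates here
certify the *rules and statistics*, not field performance. The measured
pattern-recovery balanced accuracy across twelve probe seeds is
0.87–0.93 (mean 0.91): the additive-versus-high-parent-dominance boundary
is only 0.68 log2 units wide at a four-fold parental gap, so a few
features per run genuinely sit on the wrong side of the noise, and seeds
at the low end of that range can fall just short of a 90% bar.

## Numerical choices and degenerate inputs

Zero-variance rows: Welch p is 1 for equal means and 0 otherwise; limma
NaNs are mapped to p = 1. Fisher p-values are clamped to 1 (the exact
test can exceed 1 by floating error). Correlations of constant vectors
are NA, reported as unclassifiable rather than errors. BH adjustment is
monotone in rank and capped at 1; it is *not* idempotent (re-adjusting
multiplies by n/rank again), which its documentation states explicitly.
Fuzzy c-means gives membership 1 to a feature coinciding with a centroid.
The pooled-count hybrid requires integer counts and refuses to subsample
beyond the available depth.

## Problem sizes

The bundled validation runs use 300 features × 9 samples for pattern
recovery, 200 features for dosage, 60–340 bins × 3 contexts × ~10 sites
for methylation, and ≤ 500-feature instances for the brute-force oracle
comparisons — sizes chosen so the whole suite, including the quadratic
oracles, completes in a few minutes on a single core while keeping every
planted class populated with ≥ 45 members.

## Known limitations

Homeolog assignment of features to subgenomes is consumed as an input
tag, never inferred. The DE engine is a moderated linear model on
transformed values, not a count GLM; for production use on real counts a
count-model table can be passed through the same record shape. The DMR
test pools reads within groups (appropriate for single pooled libraries
per line, not for replicate-level WGBS designs). The twelve-bin grouping
of expression patterns is one defensible mapping of sign patterns to
named classes; the recorded bin codes allow any alternative grouping
without recomputation.
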