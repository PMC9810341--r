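---
title: "Methods: chromatin priming analysis from pseudobulk multi-ome counts"
author: "chromprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin priming analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromprime)
```

# Overview

`chromprime` analyses *chromatin priming*: the state in which a gene's
regulatory regions are accessible while the gene is lowly or not
expressed, so that an external stimulus (an inflammatory environment,
a cytokine) can induce transcription without chromatin remodelling.
The package takes pseudobulk counts — expression and promoter ATAC
reads aggregated within cell type × condition — and classifies genes
by the joint behaviour of expression and chromatin accessibility (CA)
across a control/disease contrast. Everything downstream of counting
is implemented here; read alignment, peak calling, cell clustering and
annotation are upstream concerns and out of scope.

All genomic coordinates are 0-based half-open (the BED convention),
because every interchange format the package reads or writes is
BED-like. Chromosome names are opaque strings; no "chr" normalisation
is attempted. SNP tables must declare their coordinate base (0 or 1)
explicitly — variant tables ship in both conventions and guessing is
worse than asking.

# Promoter activity scores

Accessibility at a promoter is summarised as RPKM: count divided by
region length in kb and library total in millions. The RPKM constant is
used deliberately — the normalisation must remove both region-length
and depth effects so that promoter accessibility is comparable to
normalised expression, and RPKM is the conventional scale for that.
Scores are zero exactly when counts are zero, and invariant under joint
rescaling of counts and totals.

The promoter of a `+` strand gene with TSS $t$ and length $L$ is
$[\max(0, t-L), t)$; for a `-` strand gene the window is mirrored in
genome space, $[t+1, t+1+L)$, clipped at the chromosome end. Windows
truncated by a chromosome boundary are flagged rather than silently
shortened, because a truncated window has a smaller length and its
RPKM is still well defined.

**Promoter-length selection.** Candidate lengths (default 2000, 1000,
500 bp — a window *around* the TSS is sometimes also examined in this
kind of analysis, but its extent is convention-dependent, so it is not
in the default candidate list; the list is an argument) are scored per
pseudobulk group by the Spearman correlation between gene-wise promoter
accessibility and expression. Spearman is the right choice because the
two scales are not linearly related and both are heavy-tailed; only the
monotone association matters. The selected length maximises the mean
correlation across groups, with equal group weights — the simplest
aggregation that still uses all groups — and ties resolve to the
smallest candidate, which is the most specific window. Fewer than three
complete gene pairs in any group is an error, not a silent `NA`: a
correlation over two points is meaningless.

# Differential evidence

Fold changes use a pseudocount on the RPKM scale,
$M = \log_2\frac{A_{dis}+\pi}{A_{ctr}+\pi}$ with $\pi = 1$ by default.
The pseudocount bounds $|M|$ for low-count features and makes
$M = 0$ exact when both sides are zero.

**Exact test.** Replicate columns are summed within condition and the
pooled counts are compared with an exact two-sided binomial test:
conditional on $C_a + C_b$, the null places $C_a \sim
\mathrm{Binomial}(C_a + C_b,\; N_a/(N_a+N_b))$, and the two-sided
p-value sums the probabilities of all outcomes no more likely than the
observed one. The computation runs in log space (tail probabilities of
large pooled counts underflow doubles otherwise) and is floored at the
smallest positive double so p-values remain in $(0, 1]$. A feature
with zero counts on both sides is untestable and reports $p = 1$ with
a flag. This test treats pooled counts as Poisson-like and is
therefore anticonservative when biological replicate variability is
present — that is a known property, and it is why classification
combines the test with an effect-size cutoff (below). A seeded
label-permutation alternative (`method = "permutation"`) is provided
for designs with enough replicates for permutation to have resolution.

**Promoter-mark enrichment.** For histone-mark comparisons at
promoters the package uses the z-score route: standardise the
fold-change vector against the all-promoter distribution,
$z = (M - \bar M)/s_M$, and take $p = 2\Phi(-|z|)$. This is a
reconstruction of a published region-enrichment tool's statistic from
its documented downstream formula; the standardisation reference (all
scored features) is the one choice consistent with that formula. A
zero-spread $M$ vector is an error — there is no distribution to
standardise against.

**Multiple testing** is Benjamini–Hochberg throughout (step-up,
$q_{(i)} = \min_{j \ge i} n p_{(j)}/j$, capped at 1), delegated to
`stats::p.adjust` and verified in the tests against a literal
implementation of the definition.

# Priming-type classification

With $\alpha$ the adjusted-p cutoff and $\tau_e, \tau_a$ the
effect-size cutoffs, "expression up" means $q_e < \alpha$ and
$M_e > \tau_e$; "CA unchanged" means failure of
($q_a < \alpha$ and $|M_a| > \tau_a$). The truth table is: Type1 =
expression up, CA up; Type2 = expression up, CA unchanged; Type3 =
expression down, CA unchanged; Type4 = expression down, CA down.
Three deliberate interpretations:

* **"No change" is non-significance, not equivalence.** No equivalence
  margin is available for these data, so "unchanged" is defined as
  failing the change criterion. This is the pragmatic reading used in
  practice, and it is stated openly: genes with weak true changes will
  land in the "unchanged" classes.
* **Discordant genes stay unclassified.** Expression up with CA down
  (or vice versa) fits none of the four classes; forcing such genes
  into Type4 would silently change that class's meaning.
* **Effect-size default $\tau_e = \tau_a = 1$ (two-fold).** Published
  thresholds in this space are ambiguous between $\log_2(1.5) \approx
  0.585$ and $1.5$ on the log2 scale; neither is tied to the typing
  step itself (they appear as volcano-plot filters). The package
  defaults to the field's most common effect-size filter, two-fold,
  for a statistical reason: with overdispersed counts and few
  pseudo-replicates the exact test's q-values are anticonservative, so
  the $|M|$ cutoff carries the specificity of the classification. At
  negative-binomial dispersion around 10 and two replicates per
  condition, the log2-ratio noise SD for an unchanged gene is roughly
  0.45–0.7, which makes 0.585 unspecific and 1.5 insensitive to
  four-fold effects; 1.0 separates both. Both cutoffs are arguments.

**Subtypes.** Type1 and Type2 are split by baseline (control) promoter
accessibility, ranked within the type and cut at the within-type
median: low-baseline Type1 genes are Type1a (chromatin opens with
induction), high-baseline Type1b (partially primed); high-baseline
Type2 genes are Type2a (fully primed), low-baseline Type2b. The split
statistic is baseline accessibility only — the type-level expression
direction is already fixed, so ranking on expression again would add
nothing. Published descriptions do not state whether the within-type
split is a median, a fixed threshold, or visual clustering; the median
is the minimal assumption-free reading, and the split quantile is an
argument. Exact-median ties go to the "high" subtype; a singleton type
is split against the global baseline median and flagged with a
warning.

# The synthetic multi-ome generator

The generator exists so every downstream stage is testable with known
truth. It emulates:

* **Counts**: negative binomial per gene × sample with mean/size
  parameterisation — the standard overdispersed model for sequencing
  counts. Default size (dispersion) 10, library $10^6$ reads, two
  pseudo-replicates per condition (pseudobulk aggregates of many cells
  stand in for replicates; two is the minimum that gives
  within-condition information).
* **Planted classes**: 100 genes per type among 2,000 by default, with
  disease effects applied multiplicatively (fold 4 for both assays) on
  type-determined baseline means. Baselines use a low/high pair (20
  and 2,000 expected counts per replicate, spanning lowly and highly
  accessible promoters at realistic pseudobulk depth) and their
  geometric mean (200) as the intermediate level. Type1a starts low in
  both assays; Type1b starts at intermediate CA; Type2a/2b hold CA
  fixed at high/low; Type3 holds CA at intermediate; Type4 reduces CA
  from intermediate by the fold change. Null genes share a lognormal
  baseline between expression and CA (with lognormal jitter), which
  plants the cross-gene accessibility–expression correlation that
  promoter-length selection relies on.
* **Window structure**: the CA signal lies entirely inside the true
  promoter window (500 bp by default). Wider candidate windows add
  per-gene Poisson background (per-gene lognormal rates around 0.5
  reads/bp, independent of expression), so widening the window dilutes
  the rank correlation; narrower windows thin the signal binomially
  (reads uniform within the true window). This is the mechanism by
  which automatic selection can recover the generating window — and a
  mirrored fixture with the signal spread over 2 kb must select 2 kb.
* **SNP scenarios**: per-cell-type peak sets placed uniformly on a toy
  genome (defaults: two 1-Mb chromosomes, 200 peaks of 1 kb per set,
  500 SNPs — sized so the overlap statistic takes enough distinct
  values for a 199-shuffle permutation p to be informative). A SNP is
  planted inside the target set's peak union with probability
  $\min(1, (f-1)\,c)$ where $c$ is the union's coverage fraction, so
  $f = 1$ is *exactly* uniform placement and large $f$ drives nearly
  all SNPs into target peaks.
* **ABC scenarios**: elements on one chromosome with wide-lognormal
  decoy activities (spanning orders of magnitude, as enhancer signal
  does) and uniformly strong planted elements, six per planted gene,
  active only in the disease condition, with high raw contacts.
  Because scores are normalised per gene, a single dominant element
  would *concentrate* score mass and reduce the retained-link count;
  several comparable planted links are what produces the intended gain
  of retained links in disease.

What the generator does **not** emulate: cell-level structure
(droplets, doublets, ambient contamination), fragment-level ATAC
placement, linkage disequilibrium among SNPs, genomic covariates (GC,
mappability, blacklists), and real biological correlation structure
beyond the planted one. Passing tests therefore demonstrate that the
implementation recovers what it is defined to recover under its own
statistical model — not that the model captures every property of real
multi-ome data.

# SNP enrichment

The observed statistic counts *distinct* SNPs overlapping at least one
peak (a SNP inside two overlapping peaks counts once; pair counting is
available via `count = "pairs"`, since figure conventions differ on
this). The null shuffles the **peaks**, not the SNPs — each peak is
repositioned uniformly over its chromosome's valid start positions,
preserving widths; shuffled peaks may overlap each other, as no
exclusion constraint is stated for this kind of control. The empirical
p-value uses the add-one estimator, which is valid (never
anticonservative in expectation) and cannot return zero. LD-aware
matched-variant nulls are a non-goal; the shuffle control tests
positional enrichment only, and inputs must already share a coordinate
system (no liftOver).

The shuffle loop uses a sorted-union/`findInterval` point-membership
fast path rather than rebuilding overlap objects per shuffle; the
tests assert its equality with the general overlap engine on random
fixtures.

# ABC scoring

Element activity is the geometric mean $\sqrt{\mathrm{ATAC} \times
\mathrm{H3K27ac}}$; contact is taken from a contact table when the
pair is covered (normalised per gene row to its maximum, putting table
values on the same $(0,1]$ scale as the fallback) and otherwise from a
power law $\min(1, (d_0/d)^\gamma)$ with defaults $d_0 = 5$ kb,
$\gamma = 1$. Candidates are elements within a 5-Mb window centred on
the TSS. None of the four values is dictated by the data this package
targets, so all are arguments with these documented defaults. Scores
are normalised per gene and links with $S > 0.05$ are retained; when
every candidate product is zero the scores are undefined (`NA`), never
divided through. The per-gene histogram of retained links includes
genes at $n = 0$ and is invariant under global activity rescaling, a
direct consequence of the ratio definition.

# Pipelines, determinism, and numerics

The two file-driven pipelines (`run_typing`, `run_snp`) exchange only
flat TSV/BED files, so every intermediate is diffable in tests. Every
output carries the package version, the seed, and an MD5 hash of the
config in `#` header lines; re-running with the same config and seed
reproduces every output byte-identically. A single global seed fans
out to per-stage seeds by fixed offsets (kept below $2^{31}$), so
stages are individually reproducible. Seeded operations save and
restore the caller's RNG state.

Numerical choices worth knowing: the exact test works in log space
with a floor at the smallest positive double; BH is delegated to
`stats::p.adjust`; Spearman uses mid-ranks and returns a flagged `NA`
(never a number) for constant input; promoter-length ties break to the
smallest length; bookended intervals (end = start) never merge or
overlap, per half-open semantics.

Problem sizes used in the shipped tests and acceptance script — 2,000
genes (100 per planted type), 100 selection runs, 200 null SNP
datasets at $B = 199$, 1,000 random ABC fixtures — were chosen to give
the property checks stable margins at desk scale.

# Known limitations

* The exact binomial test ignores replicate-level overdispersion;
  classification compensates with the effect-size cutoff, but q-values
  for high-count features should not be over-read. A
  negative-binomial GLM route is intentionally out of scope.
* The z-score enrichment statistic assumes approximate normality of
  the fold-change distribution across features.
* The shuffle null conditions on peak widths and chromosomes only; it
  does not match GC, accessibility background, or LD structure.
* The ABC implementation is a declared simplification (geometric-mean
  activity, row-max contact normalisation, power-law fallback); it is
  not the published pipeline with quantile normalisation and
  blacklisting.
* Subtype splits are relative (within-type median), so labels are not
  comparable across runs with different gene universes.
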