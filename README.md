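# chromprime

Analysis of **chromatin priming** from pseudobulk multi-ome counts:
joint classification of genes by differential expression and promoter
chromatin accessibility (CA), promoter activity scoring with data-driven
promoter-length selection, promoter-mark enrichment statistics,
SNP-in-open-chromatin enrichment against shuffle nulls, and a simplified
activity-by-contact (ABC) enhancer–gene linking score.

## The scientific problem

In inflammatory disease models, glial cells such as oligodendrocyte
precursor cells switch on immune gene programs. A recurring observation
is that many of these genes are *primed*: their promoters are already
accessible to transposase (open chromatin) in control cells even though
the genes are not yet expressed, so induction does not require chromatin
opening. Distinguishing genes that open their chromatin upon induction
from genes that were primed all along requires looking at expression and
accessibility **jointly**, per gene, across conditions.

`chromprime` implements that joint analysis for pseudobulk data (counts
aggregated within cell type × condition), together with the surrounding
machinery needed to run and validate it end to end on synthetic data
with planted ground truth — no external download required.

## The model

**Promoter activity.** For region $r$ with length $L_r$ (bp), count
$C_{rg}$ in pseudobulk group $g$ with library total $N_g$, the activity
score is RPKM:

$$A_{rg} = \frac{C_{rg}}{(L_r/10^3)\,(N_g/10^6)}.$$

Promoters are the window upstream of the TSS (strand-mirrored); the
window length is chosen by maximising the mean Spearman correlation
between promoter accessibility and gene expression across pseudobulk
groups, over candidate lengths (2 kb, 1 kb, 500 bp by default).

**Differential evidence.** Disease-vs-control fold changes use a
pseudocount, $M = \log_2\frac{A_{dis}+\pi}{A_{ctr}+\pi}$ (default
$\pi = 1$ RPKM). Significance comes from an exact two-sided binomial
test on pooled condition counts (conditioning on $C_a + C_b$ with
success probability $N_a/(N_a+N_b)$), or from a seeded
label-permutation test; p-values are Benjamini–Hochberg adjusted.
Promoter-mark (CUT&RUN-style) comparisons use the z-score route:
standardise $M$ against the all-promoter distribution and take
$p = 2\,\Phi(-|z|)$.

**Priming types.** With $q$ the adjusted p-value and
$\tau$ the effect-size cutoffs:

| Label | Expression | Accessibility | Baseline CA in control |
|-------|------------|---------------|------------------------|
| Type1a | up | up | low (below within-type median) |
| Type1b | up | up | high |
| Type2a | up | unchanged | high (at/above median) — *primed* |
| Type2b | up | unchanged | low |
| Type3 | down | unchanged | — |
| Type4 | down | down | — |

"Up"/"down" mean $q < \alpha$ and $|M| > \tau$ in the corresponding
direction; "unchanged" is the failure of that conjunction. Discordant
genes (e.g. expression up, accessibility down) stay unclassified.

**SNP enrichment.** For a variant set and a peak set, the observed
statistic $O$ counts distinct SNPs inside peaks; the null repositions
the peaks uniformly (width- and chromosome-preserving) $B$ times,
giving $E$ (null mean), fold $O/E$, and the add-one empirical p-value
$(1 + \#\{O_{null} \ge O\})/(B+1)$, BH-adjusted across peak sets.

**ABC links.** Element activity is the geometric mean of ATAC and
H3K27ac RPKM; contact comes from a contact table (normalised per gene
to its row maximum) or a power-law distance fallback. The score is
normalised per gene, $S_{eg} = A_e C_{eg} / \sum_{e'} A_{e'} C_{e'g}$,
and links with $S > 0.05$ are retained.

## Worked example

```r
library(chromprime)

mo <- generate_multiome(synth_config(seed = 1))   # 2,000 genes, 100 per planted type
de <- differential_counts(mo$expression, mo$groups, "disease", "ctrl")
da <- differential_counts(mo$atac,       mo$groups, "disease", "ctrl")
types <- classify_genes(de, da, setNames(da$A_den, da$feature))
summary(types)
#> Priming-type tally:
#>   191 Type1
#>   213 Type2
#>   126 Type3
#>   96 Type4
recovery_report(types, mo$truth)
#> recovery_report over 2000 gene(s)
#>   macro recall: 0.928
#>   null false-classification rate: 0.038
```

The tally is the per-comparison count of genes in each priming class
(e.g. 191 genes induced with chromatin opening, 213 induced without CA
change); the recovery report compares assignments against the
generator's planted truth — 92.8% of planted genes recovered, 3.8% of
null genes spuriously classified.

```r
sel <- select_promoter_length(simulate_window_counts(mo, c(2000, 1000, 500)),
                              score_regions(mo$expression))
sel
#> Promoter-length selection (Spearman rho, mean over groups):
#>      500 bp: rho = 0.5380
#>     1000 bp: rho = 0.2972
#>     2000 bp: rho = 0.1498
#> selected: 500 bp
```

The accessibility–expression correlation is highest at the window that
actually carries the signal, so `"auto"` selection picks 500 bp.

```r
sc <- generate_snp_scenario(enrichment_fold = 5, seed = 2)
multi_set_report(sc$snps, sc$peak_sets, genome = attr(sc$snps, "genome"),
                 B = 199, seed = 2)
#>   set   O     E   fold     p    q   B n_snps
#> 1 ct1 231 48.05 4.8075 0.005 0.02 199    500
#> 2 ct2  52 47.23 1.1010 0.255 0.51 199    500
#> ...
```

The planted cell type shows ~4.8-fold more SNP hits than its shuffle
expectation at the permutation floor p = 1/200; the other sets sit at
fold ≈ 1.

File-driven pipelines (`run_typing()`, `run_snp()`) and a shell front
end (`exec/chromprime` with `typing`, `snp`, and `fixtures`
subcommands) wire the same steps over BED/TSV files on disk; see the
vignette.

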