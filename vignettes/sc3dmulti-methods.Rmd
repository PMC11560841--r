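---
title: "Models and methods behind sc3dmulti"
author: "sc3dmulti Developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sc3dmulti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

sc3dmulti reimplements, as a tested pipeline, the statistics used to analyse
joint single-cell chromatin-conformation + DNA-methylation (snm3C-seq-like)
data: per-cell contact-distance classification, pseudobulk loop calling with
an empirical FDR, summary-statistic differential loops, super-interactive
promoters, insulation-score domain boundaries and their chi-square
differential test, A/B compartment eigenvectors and saddle strength,
methylation feature matrices, 3C gene scores, meta-cell construction and
the loop-versus-methylation cross-correlation lag analysis, and regulatory
overlap statistics. Everything is exercised on a synthetic cohort with
planted structure; no external data are needed.

# The statistical models

## Contact-distance decay and conformation classes

Cis contact distances are histogrammed into 143 logarithmic bins: bin 1
holds distances below 1 kb (read as $2^{10}$ bp so the base-2 ladder is
exact) and bin $k \ge 2$ covers $[2^{10+(k-2)/8}, 2^{10+(k-1)/8})$ bp, an
exponent step of 0.125 in base 2. Bins 1--37 are treated as noise and bins
beyond 141 as out of range, leaving bins 38--141 as valid. With
$p_m$ the fraction of valid contacts in bins 38--89 (~23 kb--2 Mb) and
$p_l$ the fraction in bins 90--141 (2 Mb up), cells are classified by
$r = \log_2(p_m/p_l)$: short-range enriched (SE) for $r > 0.4$, long-range
enriched (LE) for $r < -0.4$, intermediate (INT) otherwise. The printed
definition of INT is internally contradictory as published; we take the
closed complement interval $[-0.4, 0.4]$, with ties classed INT.

Conformation clusters use Lloyd k-means (k = 10) on L1-normalized valid-bin
profiles. Initial centers are profiles at evenly spaced ranks of the $r$
ordering, which makes the procedure deterministic and invariant to input
order; labels are renumbered so cluster 1 has the highest mean $r$.
Cluster-pair similarity counts draw 1,000 random cross-cluster cell pairs
and count Pearson correlations above 0.8.

## Per-cell matrices: Q, E, T

Per chromosome, a cell's binned contacts are imputed scHiCluster-style:
box-filter convolution of half-width `pad` (2 at 10 kb and 25 kb, 1 at
100 kb), row normalization, then a random walk with restart probability
0.5. The stated iterative rule (stop when the total absolute change falls
below $10^{-2}$, at most 20 sweeps) converges geometrically at rate 0.5;
the default implementation solves its fixed point
$Q = \rho\,(I - (1-\rho)P)^{-1}$ directly, which agrees with the iteration
to well below its own tolerance (tested) and is what makes 300-cell runs
affordable on one CPU. The result is symmetrized and restricted to the
imputation band (5.05 Mb at 10 kb, 10.05 Mb at 25 kb).

`E` is the per-diagonal z-score of $\log(1+Q)$ (population SD; constant
diagonals map to 0), measuring enrichment against the global
distance-decay background. `T` subtracts from `E` the mean over the local
ring of Chebyshev radius strictly between 3 and 5 bins (radius 4 at 10 kb,
i.e. >30 kb and <50 kb), measuring enrichment against the local
neighbourhood. Shuffling each diagonal of `E` (and recomputing `T` from the
shuffled `E`) yields the null cells for the empirical FDR.

Pseudobulks store, per pixel, the mean and mean of squares of Q, E and T
across cells, which is all the downstream statistics need.

## Loop calling, empirical FDR and differential loops

The pseudobulk t statistic $t = \bar{x} / \sqrt{(\overline{x^2} -
\bar{x}^2)/n}$ (variance floored at $10^{-12}$) quantifies the deviation of
E and T from zero. For every candidate pixel (50 kb--5 Mb) the empirical
FDR compares observed to shuffled t:
$\mathrm{FDR}(x) = \min\!\big(1, \frac{\#\{t_\mathrm{shuf} \ge x\}/N_s}
{\#\{t_\mathrm{obs} \ge x\}/N_o}\big)$, made monotone by a running minimum
over less stringent cutoffs. Loops additionally require mean E > 0 and
HiCCUPS-style fold changes of the O/E-normalized pseudobulk Q: >1.33
against the donut (radii 2--5, centre row/column excluded) and lower-left
quadrant, >1.2 against the horizontal and vertical strips (offsets 2--5),
with empty backgrounds reported as infinite fold change. Both FDRs must be
below 0.01.

Because imputation smears a focal loop into a flat-topped blob and
per-diagonal z-scoring tilts extremum statistics toward larger distances,
called pixels are merged into 8-connected clusters whose rounded centroid
is reported as the loop summit (statistics are carried from the maximum-t
member).

Differential loops between cell groups use one-way ANOVA recovered from
the pseudobulk summaries: $SSB = \sum_g n_g m_g^2 - N\bar{m}^2$,
$SSW = \sum_g n_g(\overline{x^2}_g - m_g^2)$, $F =
(SSB/(G-1))/(SSW/(N-G))$, computed for both Q and T. $\log F$ (offset
$10^{-12}$) is z-scored across tested loops and loops with both z above
$\Phi^{-1}(0.85) = 1.036$ are differential -- roughly the top 5% under
normality.

## SIPs and cumulative loop scores

A promoter's cumulative loop score sums the strengths (pseudobulk mean E at
the summit; a count-of-loops alternative is available) of loops with an
anchor within 5 kb of the TSS (inclusive; 5,001 bp is out). Scores are
modelled by a half-Gaussian with mean 0 and the sample SD of the scores;
promoters with $p = 2(1-\Phi(x/\sigma)) < 0.001$ are super-interactive.

## Domains and differential boundaries

The insulation score of bin $b$ is the raw mean of Q over pairs
$(i, j)$ with $b - w \le i \le b < j \le b + w$ ($w$ = 10 bins at 25 kb),
clipped at chromosome ends; no log-ratio normalization is applied (the
1.2 fold-change threshold below therefore applies to raw means -- a
documented, configurable choice). Per-cell boundaries are strict local
minima of the cell's own insulation profile deeper than both flanking
maxima by 2% of the profile range; the per-cell caller is deliberately
pluggable since the differential framework consumes only binary calls.

For each 25-kb bin, an $n \times 2$ group-by-(boundary, not) table gives a
Pearson chi-square (bins with a zero margin are excluded). P values are BH
adjusted genome wide; candidate peaks are local chi-square maxima with
FDR < $10^{-3}$, merged when closer than 5 bins (keeping the higher
statistic), and must further pass genome-wide z-scored chi-square > 1.960,
insulation max/min fold change > 1.2 and boundary-probability range >
0.05.

## Compartments

At 1 Mb, the O/E matrix (each diagonal divided by its mean) is correlated
bin against bin; among the top three eigenvectors of the correlation
matrix, the one with the highest |Pearson correlation| with GC content is
the compartment track, signed so the correlation is positive (positive =
A). Within each compartment the bins with assignment strengths in the top
20th percentile enter the saddle sums, and
strength $= (\Sigma AA + \Sigma BB)/(\Sigma AB + \Sigma BA)$; AA/BB
dominance is each homotypic sum over the four-sum total (the published
"total O/E signal" is ambiguous about unselected bins; the four-sum
denominator keeps dominances and cross fractions summing to one).
Pseudobulks under 30 million contacts are flagged, not dropped. A/B
transitions between the earliest and latest age use the package's own
eigenvectors (the original analysis used an external differential
caller at 100 kb -- an explicit substitution); transition-bin mCG is
normalized by subtracting the earliest age and compared AB-vs-BA with
two-sided Wilcoxon rank-sum tests.

## Methylome features and 3CGS

Cell QC is the exact printed conjunction: mCCC < 0.03, global mCG > 0.5,
global mCH < 0.2, cis contacts > 100,000, all strict. Methylation features
are count fractions over gene bodies (expanded 2 kb both sides, clipped at
chromosome bounds) and fixed-width bins, split by CG/CH context; features
with mean coverage below 10 are dropped and entries with coverage below 5
imputed as the sample's mean over adequately covered entries (idempotent by
construction). The 3C gene score (3CGS) of a gene sums off-diagonal imputed
10-kb contacts in the upper triangle with at least one end in the TSS--TES
bin span, restricted to the imputation band (long genes are truncated at
the band and flagged). The TSS/TES bins are min/max-normalized so minus
strand genes score identically.

## Meta-cells and the cross-correlation lag

Meta-cells pool each cell with its 19 nearest embedding neighbours
(self-included; distance ties broken by cell id). Pairs sharing more than
five members are deduplicated by repeatedly removing, from the
worst-overlapping pair, the member with the larger total overlap (ties by
id) -- the published procedure does not specify the removal rule, so this
deterministic instantiation is documented as ours. Meta-cell mCG is the
pooled count fraction (not the mean of member fractions), loop strength
the mean imputed Q, and pseudotime the mean of members.

For each loop whose strength is negatively correlated with its mean
anchor mCG at zero shift, the cross-correlation
$r(s) = \mathrm{cor}(x_t, y_{t-s})$ is evaluated for shifts $s$ (in
meta-cell rank steps) over the overlapping segment (both series
standardized, minimum 10 points), and the argmin shift is recorded. A
negative shift means methylation must be moved backward to align, i.e. the
interaction changes before the methylation; a left-skewed shift
distribution therefore indicates conformation leading methylation.

## Regulatory overlap statistics

Loop-connected DMRs overlap (>=1 bp) a loop anchor of the matching cell
type. Motif enrichment extends foreground DMRs 250 bp from their edges and
background DMRs 250 bp from their centres (the two printed conventions),
requires >=1 bp overlap with motif hits, and uses the upper-tail
hypergeometric p with fold $(x/n)/(K/N)$. Fine-mapped SNPs (PIP > 0.1)
versus background SNPs form a 2x2 table with odds ratio $ad/bc$ and a
Fisher exact p; per locus, a hit is any retained SNP in the annotation.
SNP--gene links require the SNP in a DMR overlapping one anchor and a TSS
within 5 kb of the *other* anchor (the 5-kb figure is borrowed from the
SIP rule; the source only says "connected through chromatin loops").
Heritability-enrichment differences between two annotations with block
jackknife SEs use $t = (e_1-e_2)/\sqrt{se_1^2+se_2^2}$ with
$2 \times 200 - 2 = 398$ degrees of freedom, two sided.

# The synthetic world

The generator states one explicit world and the tests measure recovery
against its ledger. Defaults: one 20-Mb toy chromosome (large enough for
twenty 1-Mb compartment bins and the 5-Mb loop range while staying
desk-scale); two cell types of 150 cells along a pseudotime axis; log-normal
contact counts (meanlog $\log 2\times10^5$, sdlog 0.25 -- a realistic depth
above the 100k QC floor, with occasional QC failures by design).

Each contact is drawn from a mixture. With probability `pi_short` it is
short range (log-uniform 25 kb--2 Mb, entirely inside the "median" distance
bins), otherwise long range (log-uniform 2 Mb--span, entirely inside the
"long" bins); this makes the expected class of a type an analytic function
of the mixture, recorded in the truth ledger. A fraction `weights$domain`
(0.7, matching the intra-TAD share of short-range contacts in mammalian
Hi-C) of short-range contacts respects the cell's domain segmentation,
drawn per cell from the planted 25-kb boundaries and their per-type
presence probabilities; within-segment distances are capped at 0.8x the
segment length because an uncapped draw piles contacts into corner dots.
A fraction `comp_amplitude` of long-range contacts joins two same-sign
compartment blocks. Blocks alternate sign with irregular lengths
(0.7-1.6x the 2-Mb nominal size): a strictly periodic checkerboard is
invisible to per-diagonal O/E normalization because homogeneous diagonals
absorb their own enrichment, just as real compartments would be if they
were perfectly periodic. Homotypic pairs are drawn with probability
proportional to 1/distance so the enrichment is spread across diagonals
like the decay, and must be >= 2 Mb apart so they stay in the long-range
regime; compartment strength then grows monotonically with the amplitude.
GC content is elevated in A blocks, which is what signs the eigenvector.

Planted loops are focal: both anchors uniform in their 10-kb bin, with
extra rate $(\mathrm{fold}-1) \times \mathrm{catchment} \times$ the
analytic per-pixel background. The catchment constant (75) expresses
planted strength at the level the loop caller measures: pad-2 box
smoothing spreads a focal pixel over a 5x5 block, restart-0.5 RWR halves
the focal excess again, and the donut ring sits partly inside the smear,
so a raw single-pixel enrichment of $(\mathrm{fold}-1) \times 75$ yields a
measured donut fold change of about 2 for a fold-3 loop -- comfortably
above the 1.33 threshold -- while a fold-1 (absent) loop measures 1.0.
Loop intensity follows a logistic onset along pseudotime (width 0.08), so
"gained" loops are absent in early cells and present in late ones.

The methylome emits allc-style records on a fixed site layout per 10-kb
bin (two CG sites whose bin total follows the configured coverage law,
exactly; two CH and one CCC site at their global levels). Anchor-bin mCG
decreases by a logistic of amplitude 0.3 whose midpoint lags the loop
onset by `lag_delta` pseudotime units -- the planted temporal offset that
the meta-cell cross-correlation must recover with a negative sign.

What the generator does **not** emulate: trans contacts, read-level
bisulfite chemistry, copy-number or mappability artifacts, batch effects,
realistic gene/DMR/motif genomic structure (annotations are placed
uniformly with planted overlaps), or multiple chromosomes. A green
recovery test therefore establishes that the statistics recover the
structure they model under honest sampling noise -- not that they are
robust to artifacts absent from this world.

# Numerical choices and degenerate inputs

* Closed-form RWR versus the 20-sweep iteration: differences are below the
  iteration's own $10^{-2}$ tolerance; both are exposed.
* Variance floors: $10^{-12}$ in the pseudobulk t; $\log(F + 10^{-12})$
  so $F = 0$ cannot crash the differential selection; zero-SD score sets
  are an error for SIPs.
* Empty matrices impute to zero with a warning; zero-background fold
  changes and zero-margin contingency bins carry documented sentinels
  (infinity, exclusion with a log entry).
* k-means uses deterministic rank-based initialization so cluster labels
  are reproducible and input-order invariant; duplicate profiles collapse
  the effective k.
* Cross-correlation ties in the argmin resolve to the smallest |shift|,
  then the negative one.
* All seeds derive from one master seed through a fixed affine map kept
  below $2^{31}$; identical seed and configuration reproduce a cohort
  byte for byte.

# Known limitations

* One chromosome per cohort; the CLI and pipeline assume it.
* Loop detection power falls with distance (the background per pixel
  shrinks); past ~1.5 Mb at the default depth recovery is no longer
  guaranteed at fold 3.
* Differential comparisons between groups with very different global
  contact-distance mixtures conflate conformation shift with local
  differences; recovery experiments therefore compare age groups with
  matched mixtures, as the original age-group design does.
* The saddle dominance denominator and the INT interval follow documented
  readings of ambiguous published definitions.
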