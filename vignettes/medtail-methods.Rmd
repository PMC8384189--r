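---
title: "Models and methods behind medtail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medtail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtail)
```

# Scope

`medtail` packages the quantitative analyses used to dissect the
separation of the Mediator coactivator's tail module from its core in
budding yeast: spike-in normalized differential nascent transcription,
derivation of concordantly regulated gene sets across a deletion and an
acute-depletion strain, and ChEC-seq-style cleavage-fragment scoring of
factor occupancy at upstream activating sequences (UASs). Because the
interesting guarantees are statistical (false-discovery control,
parameter recovery, signal/background separation), the package ships a
synthetic-data generator with complete ground truth; every stage is
exercised end to end on simulated data by the test suite and the
`analysis/` drivers.

# Spike-in size factors

Cultures are mixed with a fixed proportion of labeled cells from a second
species before RNA extraction (a 1:4 spike-in ratio motivates the
generator's default `spikein_fraction = 0.2`). Because the spike-in
content per experimental cell is constant, spike-in counts estimate
relative library depth even when the experimental genome undergoes a
global transcriptional shift — exactly the situation a deregulated
coactivator can create, where total-count normalization would erase real
signal.

`size_factors_median_of_ratios()` implements the median-of-ratios
estimator restricted to spike-in genes: with counts $k_{ij}$ and
per-gene geometric means $g_i = (\prod_j k_{ij})^{1/m}$,
$$\widehat{sf}_j = \operatorname{median}_{i\,:\,g_i > 0} \; k_{ij} / g_i.$$
Genes with a zero in any sample are excluded rather than pseudocounted —
that is the estimator's standard positive-geometric-mean rule, and it
keeps the estimator scale-equivariant. Two deliberate conventions:

* With an even number of usable genes the median is the arithmetic
  midpoint of the two central ratios. (Reference implementations midpoint
  on the log scale; the difference is far below the estimator's sampling
  error, and the arithmetic midpoint is R's own `median()`.)
* The factors are reported as raw medians, not rescaled to unit geometric
  mean. Every downstream statistic is provably invariant to a common
  rescaling, so rescaling would only obscure the estimator's output.

For fragment (ChEC) libraries, `chec_scale_factors()` uses the
reciprocal of each sample's spike-in fragment count, with the overall
constant fixed by a mean-1 convention; the cited track-scaling procedure
does not print its constant, and all within-sample statistics are
unaffected by the choice.

# Differential transcription

`wald_test_two_group()` is a deliberately transparent two-group
negative-binomial Wald test with externally fixed size factors. On
normalized counts with group means $\mu_A$, $\mu_B$ (each offset by a
pseudocount), the effect is $\widehat{lfc} = \log_2(\mu_B/\mu_A)$ with
$$se^2 = \frac{1}{\ln^2 2}\left(\frac{v_A}{n_A\mu_A^2} +
\frac{v_B}{n_B\mu_B^2}\right),$$
$v$ being the within-group variance floored at the NB moment value
$\bar w \mu + \alpha \mu^2$ ($\bar w$ = mean reciprocal size factor of the
group). Two-sided normal p-values are BH-adjusted across tested genes;
genes with all-zero counts in both groups are flagged `low_count` and
excluded from the BH denominator. There is no fold-change shrinkage and
no independent filtering: significance calls are meant to be auditable
from the formula above.

Two numerical choices deserve explanation:

* **Size-factor-aware forms.** The moment estimator subtracts
  $\bar w \mu$ (not $\mu$) as the shot-noise term, and the pseudocount is
  $0.5 \cdot \mathrm{mean}(1/sf)$ rather than a bare $0.5$. With unit size
  factors these reduce to the familiar forms; their purpose is to make
  `log2fc` and `p` *exactly* invariant under a common rescaling of all
  size factors, which the test suite asserts at `1e-12` tolerance.
* **Pooled dispersion floor.** With 3 replicates per group, the per-gene
  moment estimate of $\alpha$ has ~4 degrees of freedom. Chance
  underestimates of the variance inflate Wald statistics enough to break
  BH false-discovery control (in an all-null simulation at 2,000 genes,
  ~2% of genes reach padj < 0.05). A $t$ reference would repair the null
  at the cost of essentially all power at BH-corrected thresholds.
  `estimate_dispersion(pool_floor = TRUE)` instead floors every gene's
  dispersion at the genome-wide 5% trimmed mean of the per-gene
  estimates. This borrows strength across genes in the most conservative
  possible way — a single global floor, no per-gene shrinkage toward a
  fitted mean-dispersion trend — and restores the null (measured
  fraction padj < 0.05 of about $10^{-4}$) while keeping ~45% power and
  unbiased fold-change recovery at true $|lfc| = 1$, dispersion 0.05,
  $n = 3$ per group.

# Concordant gene sets

`concordant_union()` builds the union of genes significant
(padj < 0.05) in either of two contrasts and retains those whose fold
change has the same nonzero sign in *both* — direction, not dual
significance, is the filter, which is what makes a weakly powered acute
depletion informative alongside a chronic deletion. Genes with a zero
fold change in either contrast (sign undefined) are dropped as
discordant and logged; genes absent from one table are dropped and
counted separately. The four categories always sum to the union size,
and the test suite asserts that conservation on 1,000 random contrasts.

Reported fractions follow the conventions of the published analyses:
Venn overlaps as a percentage of each set, class composition (CR vs
TFIID-dependent) over *annotated* members only, the fraction of a set
below a 2-fold change with a strict inequality, and all percentages
rounded half-up to one decimal.

# Cleavage-fragment scoring

`fragment_coverage()` accumulates each fragment's full span into
per-base coverage (cut-end pileup is an option, not the default — full
spans mirror the track-building tools the published analyses used), bins
it (default 10 bp, bin mean), and normalizes per million fragments, by a
spike-in scale, or not at all. `window_signal()` sums bin values over a
window with partial bins weighted by overlap fraction; it agrees with a
per-bp brute-force recount to $10^{-9}$.

`upstream_tesr_scores()` computes, per gene, signal in the 500 bp
strand-aware window upstream of the TSS and in the 500 bp window centred
on the TES (the TES region is nucleosome-depleted but not factor-bound,
so it serves as a within-sample accessibility background), and reports
$\log_2((U + pc)/(T + pc))$. The pseudocount (default 1 normalized unit)
is a package choice — the source analyses do not state how zero-TESR
genes were handled — and it is the only thing that breaks exact
invariance of the ratio to global track rescaling, which the tests
therefore assert with $pc = 0$. The TES window of a minus-strand gene is
the exact strand mirror of the plus-strand window
(`[tes - 250 + 1, tes + 250 + 1)`), so mirrored genes with mirrored
fragments score identically.

Group comparisons use the two-sided Mann-Whitney test: exact when both
groups have at most 8 untied values, normal approximation with tie
correction otherwise; more than two groups are compared pairwise with
Holm correction.

`size_filtered_profile()` retains fragments of at most 80 bp —
short cleavage fragments are most plausibly protected by a single bound
factor such as TBP — removes duplicate spans (only on this path,
mirroring the published tool flags: tracks keep duplicates, the
short-fragment profile drops them), CPM-normalizes by the retained
count, and averages strand-oriented 2 kb TSS windows across a gene
group in 10 bp bins. Profile averaging commutes with gene-group
partitioning, and a gene-group's profile peak recovers the simulator's
footprint offset within one bin.

# The synthetic-data generator

The generator emulates the features downstream methods rely on, and
nothing more:

* **Annotation**: non-overlapping genes with at least 1 kb of clear
  flank on both strands of a small genome, plus a spike-in genome on
  chromosomes distinguished by a name prefix (assignment by chromosome
  name, never by alignment). Coordinates are 0-based half-open
  everywhere, including on disk (BED), so no shifting happens at any
  boundary. Class labels default to 20% CR / 65% TFIID-dependent / 15%
  unannotated, with TATA-box probability 0.8 for CR and 0.1 for
  TFIID-dependent genes, echoing the reported enrichment of TATA
  elements among CR promoters.
* **Counts**: $k_{ij} \sim NB(d_j q_i 2^{lfc_i x_j}, \alpha_i)$ with
  variance $\mu + \alpha\mu^2$ — the same parameterization the test
  assumes. Spike-in genes have $lfc_i = 0$ exactly. Default effects put
  $|lfc| = 1$ in 10% of genes, negative at CR genes and positive at
  TFIID-dependent genes, the down-in-CR / up-in-TFIID pattern
  characteristic of tail disruption. Base abundances are log-normal
  (median 100 counts, $\sigma_{\log} = 1$); depth factors default to
  log-normal with $\sigma_{\log} = 0.3$.
* **Fragments**: a `bound_factor` library places fragment midpoints
  uniformly in each gene's UAS window (default
  `[TSS - 300, TSS - 100)`, strand-aware) atop uniform background; a
  `free_mnase` library is background-only with a 2x density boost in TES
  regions (they are nucleosome-depleted, hence more accessible to free
  nuclease); a `tbp_like` library centres short fragments at a fixed
  promoter offset (default -60 bp, Gaussian jitter 10 bp). Lengths come
  from a two-component truncated-normal mixture whose short mode is
  capped at 80 bp. A Bernoulli `spikein_fraction` of fragments (default
  0.2) lands uniformly on the spike-in chromosomes.
* **Reproducibility**: one master seed expands into named child streams
  (`child_seed()`), one per sample / factor / parameter block, so adding
  a sample or another fragment library never perturbs data already
  generated, and identical configurations reproduce byte-identical
  files.

What the generator does *not* emulate — read-level error, mappability,
GC bias, RNA decay and buffering, replicate-specific batch structure,
correlated gene programs — bounds what passing tests show: they validate
the estimators and the bookkeeping under the stated model, not
robustness to artefacts that alignment and QC pipelines handle upstream
of this package.

# Problem sizes and degenerate inputs

The shipped drivers and tests run at desk scale by choice: a few hundred
genes on megabase chromosomes, 3 replicates per condition, tens of
thousands of fragments; statistical checks use 2,000 genes and 5-20
seeds, sizes at which the quantities being asserted (null
false-discovery fraction, recovery bias, rank-sum separation) are
already stable to well within their acceptance bands.

Degenerate inputs are handled explicitly rather than by crashing: empty
annotations and empty fragment sets produce valid empty outputs (with a
warning where normalization is undefined); windows and fragments
crossing chromosome ends are clipped and flagged; genes with undefined
sign or missing partners in the concordance filter are dropped into
named, counted categories; an empty gene set yields `NA` percentages,
never division by zero.

# Known limitations

* The Wald test is two-group only; multi-factor designs, interaction
  terms, shrinkage estimators and outlier moderation are out of scope.
* The pooled dispersion floor trades power for false-discovery control
  at very small replicate numbers; with many replicates
  (`pool_floor = FALSE`) the raw moment estimator is preferable.
* Enrichment scores depend mildly on the pseudocount at weakly covered
  genes; both the pseudocount and the window geometry are parameters.
* The ChEC scale-factor constant is a convention (mean 1); only ratios
  between samples are meaningful.
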