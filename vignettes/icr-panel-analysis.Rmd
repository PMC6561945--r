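---
title: "Immune panel profiling with ICRpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune panel profiling with ICRpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ICRpanel)
```

# Scope

`ICRpanel` implements the analysis chain for targeted immune expression
panels profiled on paired tumor biopsies: count normalization, ssGSEA
immune deconvolution, Immunologic Constant of Rejection (ICR) scoring
and consensus classification, paired/unpaired differential expression,
annotation-category enrichment, and enrichment-score fold-change
summaries. This vignette documents the statistical models, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open.

# Normalization model

Raw nCounter-style counts carry three nuisance factors: per-sample
assay efficiency, non-specific background, and distributional
differences between samples. The chain addresses them in order:

1. **Housekeeping scaling.** Each sample is scaled by
   $f_s = G^{*} / G_s$ with $G_s$ the geometric mean of the
   housekeeping probes in sample $s$ and $G^{*}$ the geometric mean of
   all $G_s$. The log factors sum to zero, so the cohort's overall
   scale is preserved. A housekeeping count of zero makes the geometric
   mean undefined and is treated as an error, not silently imputed.
2. **Background subtraction.** Per sample, the background is the mean
   of the negative-control probes (a `mean + 2 sd` variant is available
   for a stricter floor). It is subtracted from endogenous and
   housekeeping probes with clamping at zero; clamped cells are counted
   in the normalization report. Control rows pass through unchanged.
3. **Quantile normalization.** Every column is forced to the reference
   distribution of per-rank means over the column-sorted matrix. Tied
   values within a column receive the mean of the reference values over
   the tied ranks — the convention of the canonical algorithm. The step
   assumes that most genes do not change between samples; with only a
   small signature shifted (tens of genes out of 770) the distortion of
   true effects is small.
4. **log2 transform** with pseudocount 1, so clamped zeros map to 0 and
   no value is $-\infty$.

The stage order (housekeeping before background) is configurable; the
two orders differ only subtly because background estimates are scaled
along with the counts. Only endogenous genes are carried into the
output expression matrix.

One property worth stating precisely: multiplying a single sample's
counts by a constant $c$ is absorbed by the housekeeping factors *up to
the global reference* — $G^{*}$ itself moves by $c^{1/n}$, so the two
runs' linear-scale outputs are exact multiples of one another and every
contrast (fold change, score difference) is unchanged, but the log2
matrices differ by a near-constant offset of $\log_2(c)/n$. The test
suite asserts the exact multiplicative form.

For data deposited post-normalization, `asNormalizedExpression()`
wraps a matrix directly (optionally applying only the log2 step) and
the whole downstream chain runs unchanged.

# ssGSEA

For each sample, genes are ranked by expression (highest expression =
highest rank; ties broken by first-occurrence gene order so the
transform is a deterministic permutation). The score of set $S$ walks
the genes in decreasing rank and accumulates

$$ES = \sum_i \left[ P_{\text{in}}(i) - P_{\text{out}}(i) \right],$$

where $P_{\text{in}}$ is the cumulative fraction of in-set weight
($\text{rank}^\alpha$, $\alpha = 0.25$ by default) and $P_{\text{out}}$
the cumulative fraction of out-of-set genes. The score is positive when
members concentrate at top ranks, depends on expression only through
within-sample ranks (so it is invariant under any strictly monotone
per-sample transform), and equals an independent brute-force
cumulative-sum oracle to 1e-12 in the tests. Scores over a matrix are
optionally divided by the global range (max − min), matching the
common implementation default; the 1×1 degenerate matrix skips this.

Two conventions to be aware of:

- Set members absent from the matrix are dropped with a warning, not
  treated as bottom-ranked. Sets with fewer than 3 genes present are
  excluded (configurable), mirroring the usual practice of not scoring
  nearly-empty signatures.
- Reversing all ranks negates the score exactly only in the unweighted
  case ($\alpha = 0$) or for singleton sets; for $\alpha > 0$ the rank
  weights break exact antisymmetry. The tests assert the property in
  the cases where it genuinely holds.

Row-wise z-scores for display use the population standard deviation
(divisor $n$); constant rows are emitted as zeros with a warning.

# ICR score and classification

The ICR signature is 20 transcripts in four functional categories
(CXCR3/CCR5 chemokines, Th1 signaling, effector, regulatory). Two
distinct summaries are computed and kept separate:

- the **ICR score** — the mean log2 expression of the present ICR
  genes per sample, used for classification and the boxplot-style
  contrasts; it is linear (scoring `expr + c` gives `scores + c`);
- the **ICR enrichment score** — ssGSEA of the pooled set, used only in
  the forest-plot fold-change summaries.

Classification runs consensus clustering on the samples' 20-gene ICR
profiles: in each repetition a fraction (default 0.8) of samples is
drawn without replacement, Ward-linkage ("ward.D2") clustered on
Euclidean distances and cut at each $k$ in $2..maxK$ (default 7);
consensus$(i,j)$ = co-clustering count / co-sampling count. Final
assignments at each $k$ come from Ward clustering of $1 -$ consensus.
With full sampling the procedure degenerates, by construction, to the
0/1 co-membership matrix of a single Ward clustering — a property the
tests exploit as an oracle. The repetition default is 5000; the test
suite and the acceptance script use 200, which is already stable for
cohorts of this size (16–18 samples).

Classes are fixed at $k = 3$: clusters are ordered by the mean
z-scored ICR score of their members and labelled Low / Medium / High.
Z-scoring is applied to the per-sample score vector (not per gene
before averaging); this is an interpretation choice — the alternative
changes only the ordering statistic, not the clusters. Ties in cluster
means are broken by cluster size, then index, with a message. The scan
over $k$ is retained in the result object for diagnostics but no
automatic $k$ selection is performed.

# Differential expression

Log2 expression is tested gene-by-gene: a classical paired t-test on
per-patient (post − pre) differences for the treatment contrast
(all response groups included), and a two-sample t-test for CR vs NR at
a fixed timepoint (partial responders excluded, as the two extreme
phenotypes are being contrasted). The unpaired default is the
pooled-variance (Student) statistic: with group sizes as small as 2,
Welch degrees of freedom collapse and p-values of the magnitude seen in
published panel studies are only reproducible under pooling; Welch
remains available by flag. Genes with zero variance are kept in the
tables with $p = 1$ and a `degenerate` flag rather than dropped, so
result tables stay rectangular.

Fold changes follow the anti-log convention: $2^{\Delta \bar{x}}$ for
log2 expression, $e^{\Delta \overline{ES}}$ for enrichment scores, so
$FC(A,B) \cdot FC(B,A) = 1$ exactly. The enrichment-score fold change
is reported with the exponentiated t-based 95% CI of the mean
difference (the raw CI is emitted alongside, since either convention
appears in forest plots); 95% is the only level consistent with
marking significance at two-tailed $p < 0.05$.

BH q-values use the step-up rule over a configurable universe $m$
(default: the number of non-degenerate genes actually tested).
Published q-values from small panel studies often imply a filtered
universe that is not described; rather than guessing, the universe is
a parameter. DEG selection uses two-tailed $p < 0.05$, ordered from
high to low fold change, with an optional FDR ≤ 0.25 annotation.

# Enrichment summaries

Category over-representation of a DEG list is the one-sided
hypergeometric upper tail over the endogenous panel as background —
the standard choice where no test is otherwise specified; it equals
exhaustive subset enumeration on small instances in the tests. The
per-signature "net change" statistic counts genes with
$FC \ge 1.5$ and $FC \le 1/1.5$ (non-strict by default, strictness
configurable) and reports $100 (n_{up} - n_{down}) / n_{genes}$;
inversely regulated genes cancel. The 15% cut-off is a display mask
only — values are always retained in the data table.

# The synthetic generator

`generateDataset()` emulates the study design the package targets:
8 patients (2 CR, 1 PR, 5 NR), one pre and one post biopsy each, a
770-gene endogenous panel headed by the 20 real ICR symbols, 40
housekeeping, 8 negative-control and 6 positive-control probes. Counts
are negative binomial (mean/size parameterization, size = 10) around
lognormal per-gene baselines (meanlog 5, sdlog 1.2 on the natural-log
count scale — a median of ~150 counts with a realistic dynamic range),
times lognormal library factors (CV 0.1). Housekeeping probes sit
higher (meanlog 6.5, sdlog 0.3) and negative controls an order of
magnitude below the endogenous median. Two effects are injected on the
log2 scale: +2 on the ICR genes in responder (CR and PR)
post-treatment samples — the PR is modelled as responder-like after
treatment — and +1 on a designated 15-gene antigen-presentation set in
CR samples at both timepoints, reflecting a pre-activated baseline
microenvironment in eventual complete responders. Twelve disjoint
leukocyte signatures (5–30 genes) are drawn from the endogenous panel;
ground truth records which are perturbed. Identical seeds give
bitwise-identical datasets, and the caller's RNG state is untouched.

What the generator does *not* emulate: gene–gene correlation beyond
the injected sets, FFPE degradation artefacts, probe-specific
hybridization efficiency, batch/cartridge effects, or the real panel's
gene-level baseline profile. Passing tests therefore demonstrate that
the statistics recover known effects under a clean count model — not
that any particular biological conclusion transfers to real data.

Problem sizes in the test-suite simulations (770 × 16 pipelines,
200 consensus repetitions, 10-seed recovery loops) were chosen as the
smallest sizes at which the checked properties are stable.

# Known limitations

- Consensus clustering is re-implemented on `stats::hclust`; it follows
  the standard subsampling algorithm but is not a wrapper around any
  particular published package, so numerical results can differ from
  other implementations in tie situations.
- The unpaired pooled t-test with $n = 2$ vs $n = 5$ is fragile by
  nature; the package reports it faithfully but small-cohort q-values
  should be read as descriptive.
- The quantile step slightly shrinks injected effects when many genes
  move at once; with signature-sized effects the bias is small (the
  recovery test bounds it at ±0.3 log2 for a 2-log2 effect) but it
  grows with the fraction of perturbed genes.
- RCC (binary nCounter) input is out of scope; counts enter as
  delimited text.
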