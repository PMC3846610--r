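---
title: "Identifying pattern genes with cosine-geometry statistics"
author: "PatternGenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying pattern genes with cosine-geometry statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatternGenes)
```

## The problem

Across a series of samples — tissues, cell types, developmental time
points — most genes drift; a minority show *modularised* behaviour that is
biologically informative: **specific** genes expressed in essentially one
sample (candidate markers), **selective** genes enriched in a small set of
samples, **housekeeping** genes expressed near-uniformly everywhere
(candidate reference genes for qPCR normalisation), and **repressed** genes
expressed everywhere *except* a few samples. PatternGenes scores
nonnegative expression profiles for all four behaviours and classifies a
whole genes-by-samples matrix at once.

The input is any matrix of nonnegative, comparably scaled expression values
(summarised microarray intensities, TPM/FPKM, normalised counts). The
methods are rank-free and unit-free: every statistic is invariant to
multiplying a profile by a positive constant.

## The statistics

A profile over $n$ samples is the vector $X = (x_1, \dots, x_n)$,
$x_i \ge 0$. Its one-sample projection $X_i$ equals $X$ at position $i$ and
0 elsewhere.

**SPM (specificity).** The cosine of the angle between $X_i$ and $X$:
$$\mathrm{SPM}_i \;=\; \frac{X_i \cdot X}{|X_i|\,|X|} \;=\;
\frac{x_i}{\sqrt{\sum_j x_j^2}} .$$
$\mathrm{SPM}_i \in [0,1]$; it is 1 exactly when sample $i$ carries all
expression, and $1/\sqrt{n}$ for a uniform profile. The SPM profile
$X_{\mathrm{SPM}}$ lies on the unit sphere: $\sum_i \mathrm{SPM}_i^2 = 1$,
so at most one sample can exceed $\sqrt{0.5}$.

**DPM (dispersion).** The standard deviation of the SPM profile rescaled to
the unit interval:
$$\mathrm{DPM} \;=\; s(X_{\mathrm{SPM}})\,\sqrt{n},$$
with $s$ the sample standard deviation (divisor $n-1$). The $\sqrt{n}$
factor is the unique affine scaling under which a uniform profile scores
exactly 0 and a single-sample spike scores exactly 1 for every $n$ — the
property that makes DPM comparable across profiles of different length and
level, and the reason we prefer it over the population-SD variant (divisor
$n$), which caps below 1. Low DPM is the housekeeping criterion; because it
is computed on SPM rather than raw values, it works regardless of a gene's
absolute expression level.

**CTM (contribution).** SPM generalised to a subset $S$ of $k$ samples: the
cosine between the projection of $X$ onto $S$ and $X$,
$$\mathrm{CTM}(S) \;=\; \sqrt{\textstyle\sum_{i \in S} \mathrm{SPM}_i^2}
\;=\; \frac{\|X_S\|_2}{\|X\|_2}.$$
It reduces to $\mathrm{SPM}_i$ for a singleton, is 1 on the full set, and
never decreases as samples are added. This form also reproduces, from the
published per-sample SPM values alone, every printed worked example of a
multi-sample enrichment equal to 1.0 (e.g. $\sqrt{0.66^2 + 0.47^2 + 0.59^2}
\approx 1.00$); `ctmFromSpm()` exposes exactly that computation.

**RPM (repression).** The profile is split into a candidate repressed group
$R$ (the $k$ lowest-expression samples) and the remaining expression group:
$$\mathrm{RPM} \;=\;
\frac{\max_{i \in R} \mathrm{SPM}_i}{\min_{j \notin R} \mathrm{SPM}_j}.$$
The profile norm cancels, so RPM is a pure expression ratio; it is 0 when
the repressed samples are exactly silent and approaches 1 as the groups
merge. When the expression group itself contains a zero the ratio is
undefined — the gene is then not "expressed everywhere else", and the
statistic refuses to pretend otherwise (see *Degenerate inputs*).

**The proportion baseline.** The conventional fractional measure
$r_i = x_i / \sum_j x_j$ and its subset sum
$\mathrm{SUM}(S) = \sum_{i \in S} r_i$ are provided for comparison
(`expressionFraction()`, `fractionSum()`). Since the Euclidean norm never
exceeds the L1 norm, $\mathrm{SPM}_i \ge r_i$ always: the cosine measures
respond more strongly to concentrated expression, which is why the SPM/CTM
route detects specific and selective genes that the proportion route
misses. The synthetic benchmark below makes this claim testable.

## Classification rules and their defaults

`classifyPatterns()` evaluates four rules per gene, **independently** — a
gene may carry several calls, and real data do produce, for example, genes
specific in one compendium and selective in another. Defaults
(`patternThresholds()`) are the quick-search criteria used for
pattern-gene retrieval:

| class        | rule (defaults)                                             |
|--------------|-------------------------------------------------------------|
| specific     | some sample with $\mathrm{SPM} > 0.9$                       |
| housekeeping | $\mathrm{DPM} < 0.3$ (all samples reported)                 |
| selective    | some $k \in [2,6]$: top-$k$ SPMs all $> 0.3$ and $\mathrm{CTM} > 0.9$ |
| repressed    | some $k \in [1,6]$: bottom-$k$ SPMs all $< 0.1$ and $\mathrm{RPM} < 0.2$ |

Details that matter in practice:

* **Strict inequalities.** All comparisons are strict, so a statistic
  exactly at its cut-off never calls. This is pinned by unit tests on
  profiles with exactly representable statistics (e.g. $(9,4,1,1,1)$ has
  $\mathrm{SPM}_1 = 9/10$ exactly).
* **Candidate subsets.** Selective rules scan the top-$k$ samples ranked by
  SPM descending, repressed rules the bottom-$k$ ascending; at equal $k$
  the top-$k$ subset maximises CTM, so no other subset needs scanning for
  the CTM clause. Ties in SPM are broken by original column order (stable),
  so output is deterministic.
* **Which $k$ is reported.** The smallest qualifying $k$ — the most
  parsimonious sample set; `reportAllK = TRUE` lists every qualifying $k$.
* **Zeros and the repressed rule.** For a given $k$, a zero-expression
  sample left in the expression group makes RPM undefined; that $k$ simply
  fails and the scan proceeds, absorbing the zeros into the candidate group
  as $k$ grows. A gene whose zeros outnumber the largest allowed $k$ has no
  defined RPM at any $k$: it is skipped for this class with a log record in
  `skippedGenes()`. A consequence worth knowing: a gene expressed in a
  single sample of a small series earns *both* a specific call and a
  repressed call (on the complementary samples) — the rules are
  independent, and both descriptions are arithmetically true. We chose the
  absorb-and-continue rule over skipping at the first undefined $k$ because
  the skip rule would discard precisely the paradigm repressed genes (a few
  exactly-silent samples) whenever $k_{\min}$ is below the number of zeros.
* **Degenerate matrices.** When $n \le k_{\max}$ the $k$ ranges are clipped
  to $n - 1$ with a warning. All-zero profiles and profiles with missing
  cells are skipped with a log record, never fatal. Housekeeping imposes no
  minimum expression level by default (the criterion is DPM-only), though
  good reference genes should also be well expressed — filter on row means
  first if that matters for your use.

## Preprocessing

`preprocessExpression()` applies, in a fixed, documented order:

1. **Detection-call zeroing** — cells flagged Absent or Marginal in an
   A/M/P call matrix are set to 0;
2. **missing-cell policy** — rows containing missing cells are dropped
   (default) or imputed with 0 (`missing = "zero"`);
3. **replicate averaging** — arithmetic mean per replicate group,
   first-appearance column order;
4. **probeset collapse** — per gene, keep the probeset whose profile has
   the largest standard deviation (divisor $n-1$), ties to the first in
   table order.

Zeroing before collapse means collapse ranks probesets on the values
classification will actually see; whether the original curated datasets
zeroed calls before or after replicate averaging is not recorded, so this
order is an explicit assumption of the package. `validateExpressionMatrix()`
warns (never blocks) on matrices with fewer than 5 samples, all-zero rows,
or negative values. No cross-sample normalisation (quantile scaling, batch
correction) is performed — columns are assumed comparably scaled, and
negative values (e.g. log-ratios) are rejected unless explicitly clamped
(`clampNegatives`), because silent clamping hides data-scale mistakes.

Input can come from delimited text (`readExpressionTable()`, strict about
ragged rows, duplicate labels and non-numeric cells) or from a GEO SOFT GDS
full-table export (`readGDS()`, which also harvests subset annotations as a
candidate replicate grouping).

## The synthetic benchmark

`simulatePatternMatrix()` plants known pattern genes so every statistic and
rule is testable without downloads. Defaults, chosen once as a realistic
small compendium: 12 samples; 100 genes per class (all five classes,
including unpatterned); background level 100; 20-fold enrichment for
specific/selective genes (within the dynamic range typical of tissue
panels); multiplicative lognormal noise with CV 0.05 (mean 1), the scale of
technical replicate scatter on summarised intensities; 3 enriched samples
per selective gene; 2 exactly-zero samples per repressed gene. The noise
model is lognormal because expression intensities are nonnegative and
right-skewed; zero cells stay exactly zero.

What the generator does *not* emulate: probe effects, batch structure,
correlated genes, heavy-tailed biological outliers, or partial repression
(use `repressedFloor` for the latter). Passing recovery tests on this
benchmark therefore demonstrates the correctness of the statistics and the
classifier logic under the stated noise model — not performance on any
particular real platform.

The test suite uses the benchmark at these sizes: a 400-gene matrix (100
per pattern class, 12 samples, fold 20, CV 0.05, fixed seed) must yield
≥ 95% recovery of every planted class, with each call on exactly the
planted samples; a 160-gene sweep over CV ∈ {0, 0.05, 0.2, 0.5} checks that
recovery is perfect without noise and degrades monotonically within
sampling error; and on the planted selective genes the fraction passing
CTM > 0.9 must exceed the fraction passing SUM > 0.9 at the same planted
subsets — the sensitivity ordering stated above, observed end to end.

## Worked example

```{r example}
m <- rbind(
  spike  = c(0, 0, 50, 0, 0, 0, 0),
  steady = c(9, 10, 11, 10, 9, 10, 10),
  duo    = c(40, 42, 0, 1, 0, 1, 0),
  dark   = c(0, 30, 31, 29, 30, 30, 30))
colnames(m) <- paste0("T", 1:7)

cs <- classifyPatterns(m, datasetId = "demo")
as.data.frame(cs)
```

`spike` is specific in T3 (SPM = 1) — and also repressed at $k = 6$ on the
complementary samples, the dual label discussed above. `steady` is
housekeeping (DPM ≈ 0.07); it additionally qualifies as selective at
$k = 6$ because six of seven near-equal samples inevitably carry more than
90% of the expression mass — on short series, interpret selective calls
with $k$ close to $n$ accordingly. `duo` is selective on its two high
samples (CTM ≈ 1) and repressed on its three silent ones; `dark` is
repressed in T1 (RPM = 0), plus a near-$n$ selective call of the same kind
as `steady`'s. Eight arithmetically true calls from four genes: on
series this short the independent rules overlap freely; they separate
cleanly once $n$ is comfortably larger than the default $k_{\max}$ of 6.

## Known limitations

* The classifier tests marginal rules per gene; it does not model
  correlation between genes, compare profiles across datasets, or score the
  consistency of conflicting calls from heterogeneous datasets.
* DPM treats all deviation from uniformity alike; it cannot distinguish one
  outlying sample from broad variability (pair it with SPM to tell these
  apart).
* Thresholds are conventions, not fitted quantities; no p-values or FDR are
  attached to calls.
* On short sample series ($n \le 7$) the default $k$ ranges reach $n - 1$,
  where "selective in $k$ of $n$" and "near-uniform" blur (see the worked
  example); the clip warning flags this.
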