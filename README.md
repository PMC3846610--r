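# PatternGenes

Quantitative identification of **pattern genes** — genes with modularised
expression across a series of samples or conditions — from nonnegative
genes × samples expression matrices. Four classes are scored and called:

- **specific**: expressed in essentially one sample (marker candidates);
- **selective**: enriched in a small set of *k* samples;
- **housekeeping**: near-uniform everywhere (reference-gene candidates);
- **repressed**: expressed everywhere *except* a few samples.

## The statistics

For a profile `X = (x1, …, xn)`, `xi ≥ 0`:

- **SPM** (specificity measure): the cosine between the one-sample
  projection `Xi` and `X`:
  `SPM_i = (Xi · X) / (|Xi||X|) = xi / sqrt(Σ xj²)` — 1 when sample *i*
  carries all expression, `1/sqrt(n)` when uniform; `Σ SPM_i² = 1`.
- **DPM** (dispersion measure): `sd(SPM profile) × sqrt(n)` (divisor
  `n − 1`) — exactly 0 for a uniform profile, exactly 1 for a
  single-sample spike, for every `n`.
- **CTM** (contribution measure): for a sample subset `S`,
  `CTM = sqrt(Σ_{i∈S} SPM_i²)` — the cosine between the projection of `X`
  onto `S` and `X`; reduces to SPM for singletons, 1 on the full set.
- **RPM** (repression measure): with the `k` lowest-expression samples as
  candidate repressed group, `RPM = max SPM(repressed) / min SPM(expressed)`
  — 0 for exact silencing, undefined if the expression group contains a
  zero.
- Baselines `r_i = xi / Σ xj` and `SUM = Σ_{i∈S} r_i` are included for
  comparison; `SPM_i ≥ r_i` always, which is why the cosine route is the
  more sensitive detector of concentrated expression.

Default classification criteria (all strict inequalities): specific
`SPM > 0.9`; housekeeping `DPM < 0.3`; selective `k = 2–6`, each top-k
`SPM > 0.3`, `CTM > 0.9`; repressed `k = 1–6`, each bottom-k `SPM < 0.1`,
`RPM < 0.2`.

## Worked example

```r
library(PatternGenes)
m <- rbind(
  spike  = c(0, 0, 50, 0, 0, 0, 0),
  steady = c(9, 10, 11, 10, 9, 10, 10),
  duo    = c(40, 42, 0, 1, 0, 1, 0),
  dark   = c(0, 30, 31, 29, 30, 30, 30))
colnames(m) <- paste0("T", 1:7)

cs <- classifyPatterns(m, datasetId = "demo")
cs
#> PatternCallSet for dataset 'demo'
#>   8 call(s) over 4 gene(s): specific 1, selective 3, housekeeping 1, repressed 3
head(as.data.frame(cs)[, c("gene", "pattern", "k", "samples", "dpm", "ctm", "rpm")], 5)
#>     gene      pattern k              samples    dpm   ctm rpm
#> 1  spike     specific 1                   T3     NA    NA  NA
#> 2  spike    repressed 6    T1,T2,T4,T5,T6,T7     NA    NA   0
#> 3 steady    selective 6    T3,T2,T4,T6,T7,T1     NA 0.939  NA
#> 4 steady housekeeping 7 T1,T2,T3,T4,T5,T6,T7 0.0699    NA  NA
#> 5    duo    selective 2                T2,T1     NA 1.000  NA
```

`spike` has SPM = 1 in T3 (specific), and — because the four rules are
evaluated independently — also reads as repressed on the complementary
samples. `steady`'s DPM of 0.07 marks it housekeeping. `duo` concentrates
its mass in two samples (CTM = 1.0 at k = 2). Row 8 (not shown) calls
`dark` repressed in T1 with RPM = 0: its T1 expression is exactly zero
while every other sample is high. Genes whose statistics are undefined
(all-zero profiles, too many zeros for the repressed rule) are skipped with
a reason in `skippedGenes(cs)`.

The same pipeline runs from the shell via the installed script:

```sh
pattern-genes synth --out-matrix m.tsv --out-truth t.tsv --seed 1
pattern-genes call --input m.tsv --output report.tsv --dataset-id sim
pattern-genes stats --input m.tsv --gene specific_001
```

`readGDS()` ingests GEO SOFT GDS full tables (values, A/M/P detection
calls, probeset→gene map, subset groupings), and
`preprocessExpression()` applies the standard cleaning order: A/M/P
zeroing → missing-cell policy → replicate averaging → probeset collapse by
maximal standard deviation. `simulatePatternMatrix()` generates matrices
with planted pattern genes and truth labels; `plantedRecovery()` scores a
classification against them. See the methods vignette
(`vignettes/pattern-gene-identification.Rmd`) for the model, design
decisions and limitations.

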