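# ihcsub

IHC-based expression subtyping of pancreatic ductal adenocarcinoma (PDAC).

Bulk transcriptomics splits PDAC into a **classical/progenitor** and a
**basal-like/squamous** subtype, the latter with worse prognosis and
chemoresistance — but sequencing is rarely feasible on the small
EUS-FNAB biopsies through which most advanced PDAC is diagnosed.
`ihcsub` implements a practical surrogate: four immunohistochemistry
markers (CK5/6, p63 — basal/squamous axis; GATA6, HNF4a —
classical/progenitor axis) are scored on the Allred scale, collapsed to
four grades, and clustered into three expression patterns (Classical,
Transitional, Basal-like) whose association with histology and overall
survival the package quantifies. It is aimed at pathologists and
biostatisticians who want the full pipeline — scoring, clustering,
rule-based prediction, exact tests, survival models, bulk-expression
signature scoring — as tested, scriptable code.

## The model in brief

* **Allred scoring.** Per marker, intensity `i ∈ {0..3}` plus proportion
  `p ∈ {0..5}` gives a total `t = i + p ∈ {0, 2..8}` (intensity 0 iff
  proportion 0), collapsed to grades: `0–2 → 0`, `3–5 → 1+`, `6–7 → 2+`,
  `8 → 3+`.
* **Patterns.** Ward minimum-variance clustering (merge cost
  ΔESS, Lance–Williams recurrence, deterministic tie-breaks) of the
  standardized n×4 grade matrix, cut at k = 3; clusters are labelled by
  their mean composite score `(CK5/6 + p63) − (GATA6 + HNF4a)`:
  highest → Basal-like, lowest → Classical.
* **Screening rules.** Basal-like: `CK5/6 = 3+` ∨ `(CK5/6 ≥ 2+ ∧ p63 ≥ 2+)`
  ∨ `(CK5/6 ≥ 2+ ∧ squamous-differentiation histology)`.
  Classical: `GATA6 = 3+ ∧ HNF4a = 3+`. Not-basal: `CK5/6 = 0 ∨ p63 = 0`.
  `CK5/6 = 2+` with poorly-differentiated histology and no firing rule is
  an explicit *equivocal* state.
* **Statistics.** Fisher / Freeman–Halton exact tests (probability-mass
  two-sided criterion, compiled enumeration with Monte Carlo fallback),
  Kaplan–Meier, log-rank and Gehan–Wilcoxon tests, Cox proportional
  hazards (Efron/Breslow ties) with the fixed covariate codings
  age ≥ 70, sex, stage III/IV, squamous differentiation, and expression
  type (Transitional + Basal-like vs Classical).
* **Signature scoring.** counts → log2 CPM → per-gene z-scores; signature
  score = Σz(up) − Σz(down); the custom five-gene score uses
  up = {TP63, KRT5, KRT6A}, down = {GATA6, HNF4A}; median
  dichotomization; log2 fold-change ranking.
* **Synthetic world.** A seeded generator emulates the 190-case reference
  cohort (patterns 85/85/20, histology conditional on pattern, printed
  stage/sex/age marginals, exponential survival with hazard ratios
  1 / 1.9 / 3.5 and ~40% censoring), plus a deterministic 190-case
  calibration cohort reproducing the printed tables exactly, and a
  negative-binomial expression generator with effects on the five
  signature genes only.

## Worked example

```r
library(ihcsub)

co <- generate_cohort(seed = 5)          # 190 synthetic cases, 85/85/20
res <- cluster_cohort(co, k = 3)         # Ward on standardized grades
table(res$assignment$pattern)
#>    classical transitional   basal_like
#>           84           86           20

adjusted_rand_index(co$latent_pattern, res$assignment$pattern)
#> [1] 0.9805195

rep <- run_pipeline(seed = 5)            # simulate -> cluster -> classify
rep                                      # -> associate -> survive
#> <pipeline_report> seed 5, n = 190
#>   pattern sizes: classical=84, transitional=86, basal_like=20
#>   clustering vs latent ARI: 0.981
#>   basal rule: sens 1.000 spec 1.000 (0 equivocal)
#>   histology x pattern exact p = 5.545e-30
#>   stage x pattern exact p = 0.8115
#>   sex x pattern exact p = 0.2103
#>   age_group x pattern exact p = 0.9334
#>   log-rank p = 0.0002568, Wilcoxon p = 0.001778
```

The histology×pattern association is overwhelming (squamous
differentiation is confined to the basal-like pattern by construction),
stage/sex/age are independent of pattern, and the injected hazard
ratios (1 / 1.9 / 3.5) drive the significant log-rank test.

On the packaged calibration tables the exact tests reproduce the
reference cohort's printed p-values:

```r
fisher_exact_rxc(ihcsub_fixture("table2_sex"))$p_value    # 0.3594039
fisher_exact_rxc(ihcsub_fixture("table2_stage"))$p_value  # 0.4760819
```

A command-line interface wraps the same steps
(`inst/cli/ihcsub`, or `ihcsub_main()` from R):

```sh
Rscript -e 'ihcsub::ihcsub_main()' simulate --seed 7 --out cohort.csv
Rscript -e 'ihcsub::ihcsub_main()' cluster  --input cohort.csv --k 3 --out patterns.csv --newick tree.nwk
Rscript -e 'ihcsub::ihcsub_main()' report   --seed 7 --out report.json
```

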