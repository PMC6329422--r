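# ctclqol

Psychometric development and scoring tools for a patient-reported
quality-of-life (QoL) instrument for mycosis fungoides / Sézary syndrome
cutaneous T-cell lymphoma (MF/SS-CTCL). The package is aimed at
measurement scientists working on patient-reported outcomes: it implements
the full Rasch-based evaluation pipeline used to turn a 14-item candidate
bank into a validated 12-item instrument, together with an exact scorer for
the published instrument and a synthetic-response generator so that every
stage is testable without patient data.

## The model

Items are rated on five ordered categories. The response process is an
adjacent-category (Rasch) polytomous model: the probability that person
*n* answers item *i* in category *k* (counting from 0) is

```
P(X_ni = k) ∝ exp( k·(θ_n − δ_i) − Σ_{j≤k} τ_gj )
```

where `θ_n` is the person's latent interference with QoL (logits), `δ_i`
the item difficulty, and `τ_g1..τ_g4` the Andrich thresholds of the item's
rating-scale group `g`. Three variants differ only in how thresholds are
shared: the Rating Scale Model (RSM, one threshold set for all items), the
Grouped Rating Scale Model (G-RSM, one set per group — here
frequency-worded vs intensity-worded items), and the Partial Credit Model
(PCM, one set per item). Estimation is joint (unconditional) maximum
likelihood with alternating Newton updates, mean-zero item difficulties,
sum-to-zero thresholds within each group, and the conventional 0.3
score-point inward nudge for extreme raw scores.

On top of the calibration the package provides the nine-stage evaluation:
model comparison (G-RSM vs RSM likelihood ratio, df = 3 for two groups of
five-category items), infit/outfit item fit with iterative purging at the
1.33 mean-square cutoff, principal-components analysis of standardized
residuals, threshold ordering and category response curves, person/item
separation reliability and test-retest correlation, test information,
a person-to-item (Wright) map, convergent/discriminant validity (Steiger's
z for dependent correlations), and differential item functioning flagged
when a between-group contrast exceeds 1.0 logit at alpha = .05.

## Worked example

```r
library(ctclqol)

# full nine-stage evaluation on a simulated study-scale sample (n = 126)
pl <- run_pipeline(list(simulate = TRUE, seed = 2026))
pl
#> <qol_pipeline> 126 persons | 12 -> 12 items | LRT chi2=48.48 (df=3, p=0.000)
#>   person reliability 0.900 | item reliability 0.980 | first contrast 1.62 | 57.2% variance explained
```

The grouped model improves significantly on the single rating scale
(chi-square 48.5 on 3 df), no item exceeds the 1.33 misfit cutoff (12 of
12 retained), person separation reliability is 0.90, and the first
residual contrast (1.62) stays below the conventional concern level of 2,
supporting a unidimensional interference construct for this simulated
sample.

Scoring a single respondent on the published instrument (codes 1–5,
`0` = "Does not apply" on the two items that offer it):

```r
published_score(c(2, 1, 3, 1, 4, 4, 0, 2, 1, 0, 2, 1))
#>   person_id raw scaled                   band
#> 1     P0001  17     89 No to low interference
```

The raw total is the sum of the 12 item codes ("Does not apply" counts 0,
the two reverse-worded items contribute `6 − code`); the scaled score
(mean 100, SD 15 on the development sample) and its qualitative band come
from the embedded published conversion tables. `build_score_table(fit)`
constructs the same kind of table from any new calibration.

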