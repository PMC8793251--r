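# psaugment

Augmented analysis of PSA response endpoints in prostate-cancer trials.

## The problem

Trials in metastatic castration-resistant prostate cancer (mCRPC) routinely
report a *PSA response rate*: the proportion of patients whose
prostate-specific antigen fell from baseline by more than a threshold *d*
(commonly 30% or 50%). The continuous percentage changes — the bars of the
waterfall plot — are dichotomised into responder indicators
*S<sub>i</sub>* = 1{*Y<sub>i</sub>* > *d*}, and everything but the binary
status is discarded: a patient with a 90% decline counts the same as one
with a 31% decline. That lost information translates directly into wider
confidence intervals and larger trials than necessary.

`psaugment` implements, side by side:

* the **standard analysis** — p̂ = Σ*S<sub>i</sub>*/n with an exact
  Clopper–Pearson 95% interval from beta quantiles; and
* the **augmented analysis** — a latent-normal model of the continuous
  data. The percentage reductions are mapped to the positive post/baseline
  PSA ratio *R<sub>i</sub>* = 1 − *Y<sub>i</sub>*/100, Box–Cox transformed
  with the exponent λ chosen by profile likelihood (λ = 0 meaning log), and
  fitted by normal maximum likelihood. The response probability is read off
  the fitted CDF at the transformed threshold,
  p̂ = Φ((*d*<sub>λ</sub> − μ̂)/σ̂), with a delta-method Wald interval:
  SE(p̂) = φ(u)·√(1 + u²/2)/√n, u = (*d*<sub>λ</sub> − μ̂)/σ̂.

Two efficiency metrics compare them: the percentage reduction in CI width,
100(*l*<sub>st</sub> − *l*<sub>aug</sub>)/*l*<sub>st</sub>, and the
**implied sample size** — how many patients the standard analysis would
have needed for its interval to be as narrow as the augmented one, reported
as the percentage increase 100(*n*<sub>imp</sub> − *n*)/*n*.

The package also ships a synthetic waterfall-data generator with
closed-form ground truth (latent log-normal PSA ratios, optional bar
clipping), batch re-analysis of corpora of arms with a clipped-bar
sensitivity analysis, and a Monte Carlo harness for coverage and
efficiency studies. The intended users are trial statisticians evaluating
responder endpoints and methodologists studying dichotomisation loss.

## Worked example

```r
library(psaugment)

arm <- generate_arm(synthetic_arm_config(
  n = 30, mu_log = -1.2, sigma_log = 1.1, threshold = 50, seed = 2203
))
standard  <- standard_analysis(arm)
augmented <- augmented_analysis(arm)
standard
#> standard analysis (n = 30): p-hat = 73.3%, 95% CI (54.1, 87.7%), width 0.336
augmented
#> augmented analysis (n = 30): p-hat = 77.6%, 95% CI (65.5, 89.8%), width 0.243
#>   Box-Cox lambda = 0.10 on the ratio scale
compare_analyses(standard, augmented)
#> CI width reduction: 27.7%
#> Implied sample size: 56.7 (continuous mode), a 88.9% increase
```

The two point estimates agree closely (73.3% vs 77.6% — both target the
same response rate), but the augmented interval is 27.7% narrower: the
standard analysis would have needed about 57 patients instead of 30 to
match it. On real re-analysed mCRPC arms this kind of gain is typical
rather than exceptional.

For a whole corpus:

```r
corp <- generate_corpus(78, seed = 1, dir = "corpus")
reanalyse_corpus("corpus/manifest.csv")
```

A thin CLI over the same functions is installed at
`inst/scripts/psaresponse.R` (subcommands `analyse`, `compare`, `corpus`,
`simulate-corpus`, `sensitivity`, `waterfall`).

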