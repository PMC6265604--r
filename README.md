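# mrmcsize

Power and sample-size planning for **multireader multicase (MRMC)**
diagnostic studies — the standard design in radiology research, where
several readers interpret the same cases under two competing tests
(e.g. imaging modalities) and performance is summarised per reader by an
accuracy outcome such as the ROC AUC.

## The model

Planning is based on the Obuchowski–Rockette (OR) correlated-error ANOVA
model for the reader-performance estimates
\(\hat\theta_{ij}\) (test *i* = 1, 2; reader *j* = 1, …, *r*):

\[
\hat\theta_{ij} = \mu + \tau_i + R_j + (\tau R)_{ij} + \epsilon_{ij},
\]

with reader effects \(R_j \sim N(0, \sigma_R^2)\), test-by-reader
interactions \((\tau R)_{ij} \sim N(0, \sigma_{TR}^2)\), and errors of
variance \(\sigma_\epsilon^2\) that are *equicovariant* because readers
share cases: Cov1 (same reader, different tests), Cov2 (same test,
different readers), Cov3 (different both). Error variance and
covariances shrink proportionally to 1/cases, so pilot estimates from a
study with `c_star` cases are rescaled by `c_star / c` when sizing a
study with `c` cases.

Three inference situations are supported, each with its own test
statistic and approximate nonnull distribution:

| inference | model | reference distribution |
|---|---|---|
| readers and cases random | M1 | noncentral F, Satterthwaite df2 |
| readers fixed            | M2 | noncentral chi-squared, 1 df |
| cases fixed              | M3 | noncentral F, df2 = r − 1, conservative within-reader variance bound |

Power is the tail mass of the noncentral distribution beyond the central
critical value, with noncentrality \(\lambda = (r d^2/2)/E(\text{denominator})\)
for effect size *d*. Noninferiority hypotheses (margin *M*, level α) are
sized as nonequivalence tests at level 2α with effect size
\(d_{inf} + M\). Besides the fully crossed factorial design, split-plot
designs (readers nested in test, cases nested in test or reader) are
powered from the same factorial parameter estimates.

## Worked example

The classic pilot data set for MRMC sizing: five radiologists comparing
spin-echo versus cine MRI for aortic dissection on 114 cases
(45 abnormal / 69 normal). An OR analysis of that study gives the
parameter estimates used below.

```r
library(mrmcsize)

vd <- or_params(var_TR = 0.00020040, var_error = 0.00080229,
                cov1 = 0.00034661, cov2 = 0.00034407,
                cov3 = 0.00023903, c_star = 114)

or_power(vd, readers = 7, cases = 148, hyp = hypothesis(0.05, 0.05))
#> MRMC power (factorial design, both random; model M1)
#>   readers = 7, cases = 148, effect size = 0.05, alpha = 0.05
#>   lambda = 8.439, df1 = 1, df2 = 29.140, critical = 4.1812
#>   power = 0.802
```

A study with 7 readers and 148 cases has 80% power to detect an AUC
difference of 0.05 at α = 0.05, generalising to both the reader and the
case population. The minimal case counts reaching 80% power per reader
count (`<N/A>`: not reachable within 2000 cases, because the
test-by-reader variability caps achievable power):

```r
or_sample_size(vd, hyp = hypothesis(0.05, 0.05), readers = 3:6)
#> Sample size results (factorial design, both random)
#>   nonequivalence test, effect size = 0.05, alpha = 0.05; target power = 0.8, case cap = 2000
#>    readers      cases  achieved power
#>          3      <N/A>
#>          4        361           0.800
#>          5        213           0.800
#>          6        170           0.802
```

The Monte Carlo simulator draws accuracy matrices from the exact
multivariate normal law the model implies and replays the corresponding
test, as an empirical check of the analytic power:

```r
simulate_power(vd, readers = 7, cases = 148, d = 0.05,
               model = "M1", n_reps = 10000, seed = 1)$rate
#> [1] 0.798   # analytic value: 0.802
```

Configuration-file driven runs (YAML or JSON) and text/CSV/JSON reports
are available through `load_run_config()` / `run_sizing()` /
`write_report()`, or from a shell via
`Rscript inst/cli/mrmcsize.R samplesize --config study.yaml`.

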