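---
title: "Sizing multireader multicase studies under the Obuchowski-Rockette model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing multireader multicase studies under the Obuchowski-Rockette model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcsize)
```

## The planning problem

A multireader multicase (MRMC) study asks several readers (typically
radiologists) to interpret the same set of cases under each of two
diagnostic tests, summarises each reader-test combination by an accuracy
outcome (most often the ROC AUC), and asks whether the tests differ.
Sizing such a study is harder than sizing a conventional trial because
two sampling layers — readers and cases — both contribute variability,
and because every reader reading the same cases induces correlation
between the accuracy estimates.

`mrmcsize` computes analytic power and minimal case counts under the
Obuchowski–Rockette (OR) model, the de facto standard analysis model for
these studies, and ships a Monte Carlo simulator of the same model that
serves as an independent empirical check of every analytic formula.

## The model and its parameters

For tests $i = 1, 2$ and readers $j = 1, \dots, r$,

$$\hat\theta_{ij} = \mu + \tau_i + R_j + (\tau R)_{ij} + \epsilon_{ij},$$

with $R_j \sim N(0, \sigma_R^2)$, $(\tau R)_{ij} \sim N(0,
\sigma_{TR}^2)$, all mutually independent, and errors with variance
$\sigma_\epsilon^2$ and equicovariance structure: $\mathrm{Cov}_1$
between tests within a reader, $\mathrm{Cov}_2$ between readers within a
test, $\mathrm{Cov}_3$ between different readers under different tests.
The constraints $\mathrm{Cov}_1 \ge \mathrm{Cov}_3$, $\mathrm{Cov}_2 \ge
\mathrm{Cov}_3 \ge 0$ are enforced at construction
(`or_params()` / `validate_or_params()`), along with
$\sigma_\epsilon^2 \ge \mathrm{Cov}_1 + \mathrm{Cov}_2 - \mathrm{Cov}_3$
— a consequence of the error's decomposition into case-driven and
within-reader components, which guarantees the within-reader variance
bound used for fixed-case inference is non-negative — and positive
semidefiniteness of the implied joint covariance of the accuracy
estimates.

The parameters in practice come from an OR analysis of pilot data
(error covariances estimated by jackknife, bootstrap or DeLong's method
— such estimation from raw ratings is deliberately outside this
package: the covariances are *inputs*). Equivalently, correlations
$r_i = \mathrm{Cov}_i/\sigma_\epsilon^2$ may be supplied
(`or_params_from_corr()`); only $r_1$ and the difference $r_2 - r_3$
affect any result. Dorfman–Berbaum–Metz pseudovalue variance components
convert through `dbm_to_or()`, and moment estimators from either
method's mean squares are available (`dbm_var_tr_from_mean_squares()`,
`or_var_tr_from_mean_squares()`); negative moment estimates are
returned with a warning rather than silently truncated, so the user
decides.

### Case-count scaling

The error variance and covariances are treated as inversely proportional
to the case count at a fixed abnormal-to-normal mix, while $\sigma_R^2$
and $\sigma_{TR}^2$ are case-count invariant. Pilot estimates tied to
`c_star` cases are therefore multiplied by $c^*/c$ before power is
computed for $c$ cases (`scale_error_params()`). Re-weighting pilot
estimates to a *different* abnormal-to-normal mix requires resampling
raw data and is not supported; planned studies inherit the pilot's mix.

## Power

For two tests every statistic has numerator $\mathrm{MS}(T) =
\frac{r}{2}(\bar\theta_{1\cdot} - \bar\theta_{2\cdot})^2$, so the
noncentrality is generically $\lambda = (r d^2/2) / E(\text{denom})$
with $d$ the difference of expected accuracies. The three inference
situations differ only in the denominator and reference distribution:

* **Both random (M1).** Denominator $\sigma_{TR}^2 +
  \frac{c^*}{c}[\sigma_\epsilon^2 - \mathrm{Cov}_1 +
  (r-1)\max(\mathrm{Cov}_2 - \mathrm{Cov}_3, 0)]$; noncentral F with
  a Satterthwaite-type df2 obtained by replacing the interaction mean
  square in the data-analytic df formula by its expectation. The
  truncation $\max(\cdot, 0)$ is applied exactly where the estimate-based
  formulas apply it — to the $\mathrm{Cov}_2 - \mathrm{Cov}_3$ term in
  both $\lambda$ and df2, never to $\mathrm{Cov}_1$ — so df2 collapses
  to $r - 1$ exactly when $\mathrm{Cov}_2 \le \mathrm{Cov}_3$.
* **Readers fixed (M2).** Same denominator without $\sigma_{TR}^2$;
  noncentral $\chi^2_1$. Since the denominator only shrinks,
  $\lambda_{M2} \ge \lambda_{M1}$ always: fixing readers buys power at
  the cost of generalisability.
* **Cases fixed (M3).** Errors become independent within-reader noise
  $\sigma_w^2$, not estimable without replicated readings; the
  conservative upper bound $\hat\sigma_w^2 =
  \frac{c^*}{c}[\sigma_\epsilon^2 - \mathrm{Cov}_1 -
  \max(\mathrm{Cov}_2 - \mathrm{Cov}_3, 0)]$ is used, with df2
  $= r - 1$.

Tail probabilities are evaluated with R's `pf()`/`pchisq()` noncentral
routines against the central `qf()`/`qchisq()` critical values; at
$\lambda = 0$ power equals $\alpha$ to machine precision. Degenerate
all-zero denominators raise an error rather than returning an infinite
$\lambda$.

**Noninferiority.** A one-sided noninferiority test at level $\alpha$
with margin $M > 0$ and effect $d_{inf} > -M$ is sized as the
nonequivalence test at level $2\alpha$ with effect $d_{inf} + M$ — the
confidence-interval duality argument; for power values of practical
interest the approximation error is negligible. No separate one-sided
noncentral computation is attempted, so the $(\alpha = 0.025,
d_{inf} = 0.02, M = 0.03)$ table is *identical* to the $(\alpha = 0.05,
d = 0.05)$ one, which the tests assert row-for-row.

## Study designs

Factorial pilot estimates also size the split-plot designs
(`map_factorial_params()`, `lambda_df_for_design()`). Nesting deletes
the covariances whose sharing disappears: cases nested in test forces
$\mathrm{Cov}_1 = \mathrm{Cov}_3 = 0$; cases nested in reader forces
$\mathrm{Cov}_2 = \mathrm{Cov}_3 = 0$ (df2 then collapses to $r-1$ by
the truncation). When readers are nested in test, the
reader-within-test variance is interpreted — and estimated — as
$\sigma_R^2 + \sigma_{TR}^2$, and $\mathrm{Cov}_1$ plays no role.

Three conventions here were genuinely open and are fixed as follows:

* **Case counts.** `cases` is the total for the factorial and
  case-nested-in-test designs — in the latter each arm rests on
  `cases / 2`, hence an error scale of $2c^*/c$ — and per reader for
  case-nested-in-reader. These follow from each case being imaged under
  only one test (with equal split), and are isolated in one function so
  they can be revised.
* **Reader-nested $\lambda$.** With $r$ readers *per test*, the
  noncentrality uses the total reader count $t\,r$ in its numerator over
  $E(\text{denom}) = \sigma^2_{R(T)} + \tilde\sigma_\epsilon^2 +
  (r-1)\widetilde{\mathrm{Cov}}_2 - r\widetilde{\mathrm{Cov}}_3$, with
  Satterthwaite df2 giving the reader-within-test mean square $t(r-1)$
  degrees of freedom. This convention is anchored to the published
  reference computation for this design (0.80 power at 10 readers per
  test and 135 cases on the reference parameter set); we note that a
  first-principles variance calculation for the difference of two
  unpaired test means yields half this $\lambda$ (power ≈ 0.53 there),
  and we deliberately follow the published convention rather than that
  derivation.
* **Inference situations.** Non-factorial designs are powered for
  random readers and cases only; fixed-reader/fixed-case variants of
  the split plots have no published reference formulas and are refused
  explicitly. The mixed split-plot (block) design supports parameter
  mapping only.

## Sample-size search

`min_cases_for_power()` finds the smallest integer case count reaching
the target power, by bisection followed by a mandatory minimality
certificate (re-checking `c - 1`): power is expected but not proven
monotone in `c`, since df2 moves with `c` as well. A linear-scan oracle
in the test suite confirms the bisection on random fixtures. The search
floor is 2 cases (the smallest count for which the formulas are
defined); the cap defaults to 2000. When even the cap falls short the
row reports `<N/A>` — with few readers this is structural, because as
$c \to \infty$, $\lambda \to r d^2 / (2\sigma_{TR}^2)$ and power
plateaus below the target whenever the test-by-reader variability is
large relative to the effect.

## Conjectured inputs

Without pilot data, two helpers supply defensible parameter values:

* `obuchowski_error_variance(auc, n1, ratio)` — the binormal
  approximation $\frac{0.0099}{n_1} e^{-a^2/2}[(5a^2+8) + (a^2+8)/R]$
  with $a = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$. The $\sqrt 2$ (rather
  than a literal factor 2, which a typeset exponent loss can suggest) is
  the form that reproduces the published reference values. The paired
  `c_star` must be $n_1(1+R)$.
* `var_tr_from_range(range95)` — from a conjectured middle-95% range of
  between-test true-accuracy differences across readers:
  $\sigma_{TR}^2 = \frac{1}{2}(\mathrm{range}/3.92)^2$, using the
  identity that $\sigma_{TR}^2$ is half the variance of those
  differences and the normality of the true accuracies
  ($3.92 = 2 \times 1.96$). This is the reading consistent with the
  published conversion table, which the tests reproduce row-for-row.

Typical conjecture scales, for orientation: across twenty published
ROC MRMC data sets, $r_1$ ranged from about 0.35 to 0.59 and
$r_2 - r_3$ stayed within ±0.02 of zero; the fixture generator
(`generate_fixture_params()`) draws from these ranges.

## The simulator and what passing tests show

`simulate_power()` draws accuracy matrices directly from the exact
$2r$-dimensional normal law the chosen model implies
(`or_covariance_matrix()`: diagonal $\sigma_R^2 + \sigma_{TR}^2 +
\sigma_\epsilon^2$; same reader across tests $\sigma_R^2 +
\mathrm{Cov}_1$; same test across readers $\mathrm{Cov}_2$; otherwise
$\mathrm{Cov}_3$ — with the documented deletions for M2/M3), applies the
matching test with the *true* scaled covariances, and reports the
rejection fraction. Error terms are pre-scaled by $c^*/c$, consistent
with the proportionality assumption, so `cases` enters the simulation
only through that scale. Replicates are vectorised (one Cholesky factor,
one $n \times 2r$ normal draw), making $10^4$ replicates a matter of
seconds; the test suite checks size at $d = 0$ and power at the
reference settings within three binomial standard errors at that
replicate count, and the sample covariance of simulated vectors
entrywise against the model matrix.

Because simulation operates at the accuracy-outcome level — the OR
model's own law — agreement between simulator and formulas validates
the distributional algebra (noncentrality, Satterthwaite df,
truncation, scaling), *not* the model's adequacy for real rating data.
Features of real studies that the generator does not emulate: rating-
level discreteness and the resulting estimation error in the
covariances (the tests receive true values, justified asymptotically
for moderate case counts), unequal reader skill distributions beyond a
normal law, case-mix drift between pilot and planned study, and any
departure from the $1/c$ covariance scaling.

## Numerical choices and limitations

* Two tests only; `t = 2` is a named constant so the df formulas read
  like their published forms.
* Case counts are integers; no fractional interpolation.
* Printed three-decimal reference values are matched by computing from
  unrounded inputs and rounding once at the end.
* The implied-covariance PSD check runs at a small panel size inside
  validation (eigenvalue tolerance $10^{-10}$ relative); `chol_psd()`
  falls back to an eigendecomposition for exactly singular matrices.
* Problem sizes in the shipped tests: searches capped at 2000 cases as
  in the reference tables, Monte Carlo at $10^4$ replicates for the
  calibration checks and 3–4 × 10³ elsewhere.
* Known limitations: no covariance estimation from ratings, no
  abnormal:normal ratio re-adjustment, no power for the mixed
  split-plot design, no confidence-interval machinery for completed
  studies — this package sizes future ones.
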