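#' Hypothesis specification for an MRMC power analysis
#'
#' Two kinds of hypotheses are supported.  A *nonequivalence* test rejects
#' the null of equal expected accuracies in favour of a two-sided
#' difference of size \code{effect_size}.  A *noninferiority* test, with
#' standard test S and new test N, tests \eqn{H_0: E(\hat\theta_S) -
#' E(\hat\theta_N) \ge M} one-sided at level \code{alpha}; for planning
#' purposes this is carried out exactly as a nonequivalence test at level
#' \eqn{2\alpha} with effect size \eqn{d_{inf} + M}, the approximation
#' being negligible for power values of practical interest.
#'
#' @param effect_size difference of expected accuracies between tests.
#'   For noninferiority this is \eqn{d_{inf} = E(\hat\theta_N) -
#'   E(\hat\theta_S)} and must exceed \code{-margin}.
#' @param alpha significance level in (0, 1).
#' @param kind \code{"nonequivalence"} or \code{"noninferiority"}.
#' @param margin noninferiority margin \eqn{M > 0}; required when
#'   \code{kind = "noninferiority"}, disallowed otherwise.
#' @return An object of class \code{"or_hypothesis"} holding the inputs
#'   plus the *effective* two-sided effect size and alpha used in the
#'   power formulas.
#' @examples
#' hypothesis(effect_size = 0.05, alpha = 0.05)
#' hypothesis(effect_size = 0.02, alpha = 0.025,
#'            kind = "noninferiority", margin = 0.03)
#' @export
hypothesis <- function(effect_size, alpha = 0.05,
                       kind = c("nonequivalence", "noninferiority"),
                       margin = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(effect_size)) stop("'effect_size' must be finite")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (kind == "noninferiority") {
    if (is.null(margin) || !is.finite(margin) || margin <= 0)
      stop("noninferiority requires a positive 'margin'")
    if (effect_size <= -margin)
      stop("noninferiority effect size must exceed -margin ",
           "(otherwise the null hypothesis is true)")
    eff_d <- effect_size + margin
    eff_alpha <- 2 * alpha
    if (eff_alpha >= 1) stop("'alpha' too large for the 2*alpha mapping")
  } else {
    if (!is.null(margin))
      stop("'margin' only applies to noninferiority hypotheses")
    eff_d <- effect_size
    eff_alpha <- alpha
  }
  structure(list(kind = kind, effect_size = effect_size, alpha = alpha,
                 margin = margin, effective_d = eff_d,
                 effective_alpha = eff_alpha),
            class = "or_hypothesis")
}

#' Rescale error variance and covariances to a planned case count
#'
#' The OR error variance and covariances are inversely proportional to
#' the number of cases each reader evaluates (for a fixed
#' abnormal-to-normal ratio), while the reader and test-by-reader
#' variances stay constant.  Pilot estimates obtained with \code{c_star}
#' cases are therefore multiplied by \code{c_star / c} before power is
#' computed for \code{c} cases.
#'
#' @param params an [or_params] object.
#' @param cases planned case count \eqn{c \ge 1}.
#' @return A list like \code{params} with \code{var_error}, \code{cov1},
#'   \code{cov2}, \code{cov3} scaled; \code{scale} records the applied
#'   factor.
#' @export
scale_error_params <- function(params, cases) {
  if (!is.finite(cases) || cases < 1) stop("'cases' must be at least 1")
  s <- params$c_star / cases
  out <- params
  out$var_error <- params$var_error * s
  out$cov1 <- params$cov1 * s
  out$cov2 <- params$cov2 * s
  out$cov3 <- params$cov3 * s
  out$scale <- s
  out
}

# Number of tests (modalities) compared; the methodology is developed for
# head-to-head comparisons only.
N_TESTS <- 2L

#' Noncentrality and denominator df, readers and cases random (M1)
#'
#' For the random-readers random-cases model the F statistic compares the
#' test mean square against \eqn{\mathrm{MS}(T{*}R) +
#' r\max(\widehat{\mathrm{Cov}}_2-\widehat{\mathrm{Cov}}_3, 0)}.  Its
#' nonnull distribution is approximately noncentral F with
#' \deqn{\lambda = \frac{r d^2/2}{\sigma_{TR}^2 + \frac{c^*}{c}\left[
#'   \sigma_\epsilon^2 - \mathrm{Cov}_1 +
#'   (r-1)\max(\mathrm{Cov}_2-\mathrm{Cov}_3,0)\right]}}
#' and Satterthwaite-type denominator degrees of freedom obtained by
#' replacing the mean square in the data-analytic df formula by its
#' expectation.  \code{df1 = t - 1 = 1}.
#'
#' @param params an [or_params] object (pilot-scale).
#' @param readers number of readers \eqn{r \ge 2}.
#' @param cases planned case count \eqn{c \ge 1}.
#' @param d effect size (difference of expected accuracies).
#' @return List with \code{lambda}, \code{df1}, \code{df2} and the scaled
#'   parameter snapshot.
#' @export
lambda_df_m1 <- function(params, readers, cases, d) {
  check_rc(readers, cases)
  sp <- scale_error_params(params, cases)
  trunc23 <- max(sp$cov2 - sp$cov3, 0)
  denom <- params$var_TR + sp$var_error - sp$cov1 + (readers - 1) * trunc23
  inner <- params$var_TR + sp$var_error - sp$cov1 - trunc23
  if (denom <= 0) stop("degenerate input: M1 denominator is not positive")
  df2 <- denom^2 / (inner^2 / ((N_TESTS - 1) * (readers - 1)))
  list(lambda = readers * d^2 / 2 / denom, df1 = N_TESTS - 1L, df2 = df2,
       scaled = sp)
}

#' Noncentrality, readers fixed (M2)
#'
#' With fixed readers there are no reader or test-by-reader variance
#' parameters; the chi-squared statistic has approximate noncentral
#' chi-squared (1 df) nonnull distribution with
#' \deqn{\lambda = \frac{r d^2/2}{\frac{c^*}{c}\left[\sigma_\epsilon^2 -
#'   \mathrm{Cov}_1 + (r-1)\max(\mathrm{Cov}_2-\mathrm{Cov}_3,0)\right]}.}
#'
#' @inheritParams lambda_df_m1
#' @return List with \code{lambda}, \code{df1} and the scaled snapshot.
#' @export
lambda_m2 <- function(params, readers, cases, d) {
  check_rc(readers, cases)
  sp <- scale_error_params(params, cases)
  denom <- sp$var_error - sp$cov1 + (readers - 1) * max(sp$cov2 - sp$cov3, 0)
  if (denom <= 0) stop("degenerate input: M2 denominator is not positive")
  list(lambda = readers * d^2 / 2 / denom, df1 = N_TESTS - 1L, scaled = sp)
}

#' Noncentrality and df, cases fixed (M3)
#'
#' With fixed cases the errors are independent within-reader noise with
#' variance \eqn{\sigma_w^2}, which cannot be estimated without replicated
#' readings.  The conservative upper bound
#' \deqn{\hat\sigma_w^2 = \frac{c^*}{c}\left[\sigma_\epsilon^2 -
#'   \mathrm{Cov}_1 - \max(\mathrm{Cov}_2-\mathrm{Cov}_3,0)\right]}
#' is used instead (non-negative whenever the covariance constraints
#' hold), giving \eqn{\lambda = (r d^2/2)/(\sigma_{TR}^2 +
#' \hat\sigma_w^2)} with \code{df2 = r - 1}.
#'
#' @inheritParams lambda_df_m1
#' @return List with \code{lambda}, \code{df1}, \code{df2},
#'   \code{var_w_bound} and the scaled snapshot.
#' @export
lambda_df_m3 <- function(params, readers, cases, d) {
  check_rc(readers, cases)
  sp <- scale_error_params(params, cases)
  var_w <- sp$var_error - sp$cov1 - max(sp$cov2 - sp$cov3, 0)
  denom <- params$var_TR + var_w
  if (denom <= 0) stop("degenerate input: M3 denominator is not positive")
  list(lambda = readers * d^2 / 2 / denom, df1 = N_TESTS - 1L,
       df2 = (N_TESTS - 1) * (readers - 1), var_w_bound = var_w,
       scaled = sp)
}

check_rc <- function(readers, cases) {
  if (!is.finite(readers) || readers < 2)
    stop("'readers' must be at least 2")
  if (!is.finite(cases) || cases < 1)
    stop("'cases' must be at least 1")
  invisible(TRUE)
}

#' Tail power of a noncentral F test
#'
#' \eqn{\Pr(F_{df_1, df_2; \lambda} > F_{1-\alpha; df_1, df_2})}: the
#' probability that an F statistic with noncentral distribution exceeds
#' the central-F critical value.  Equals \code{alpha} when
#' \code{lambda = 0} and increases strictly with \code{lambda}.
#'
#' @param lambda noncentrality parameter \eqn{\ge 0}.
#' @param df1,df2 numerator / denominator degrees of freedom.
#' @param alpha significance level in (0, 1).
#' @return Power in \[0, 1\].
#' @export
power_noncentral_f <- function(lambda, df1, df2, alpha) {
  if (!is.finite(lambda) || lambda < 0) stop("'lambda' must be >= 0")
  if (!is.finite(df1) || df1 < 1 || !is.finite(df2) || df2 <= 0)
    stop("invalid degrees of freedom")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Tail power of a noncentral chi-squared test
#'
#' \eqn{\Pr(\chi^2_{df_1; \lambda} > \chi^2_{1-\alpha; df_1})}; the
#' fixed-readers analogue of [power_noncentral_f()] (critical value
#' 3.8416 at one degree of freedom and \eqn{\alpha = 0.05}).
#'
#' @inheritParams power_noncentral_f
#' @return Power in \[0, 1\].
#' @export
power_noncentral_chi2 <- function(lambda, df1, alpha) {
  if (!is.finite(lambda) || lambda < 0) stop("'lambda' must be >= 0")
  if (!is.finite(df1) || df1 < 1) stop("invalid degrees of freedom")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df1)
  stats::pchisq(crit, df1, ncp = lambda, lower.tail = FALSE)
}

#' Power of an MRMC study under the OR model
#'
#' Central dispatcher: selects the noncentrality/df formulas for the
#' requested design and inference situation, applies the noninferiority
#' mapping (effective effect size \eqn{d_{inf} + M} at level
#' \eqn{2\alpha}) where applicable, and evaluates the noncentral F or
#' chi-squared tail probability.
#'
#' Inference situations for the factorial design:
#' \describe{
#'   \item{\code{both_random}}{readers and cases random (model M1);
#'     noncentral F with Satterthwaite df2.}
#'   \item{\code{readers_fixed}}{readers fixed, cases random (M2);
#'     noncentral chi-squared, 1 df.}
#'   \item{\code{cases_fixed}}{readers random, cases fixed (M3);
#'     noncentral F with \code{df2 = r - 1} and the conservative
#'     within-reader variance bound.}
#' }
#' Non-factorial designs support \code{both_random} only; see
#' [lambda_df_for_design()] for their conventions.
#'
#' @param params an [or_params] object.
#' @param readers readers (per test for \code{reader_nested_in_test},
#'   total otherwise).
#' @param cases planned case count (total cases for \code{factorial} and
#'   \code{case_nested_in_test}; cases per reader for
#'   \code{case_nested_in_reader}).
#' @param hyp an [hypothesis] object (or a plain effect size, in which
#'   case \code{alpha} is used).
#' @param inference one of \code{"both_random"}, \code{"readers_fixed"},
#'   \code{"cases_fixed"}.
#' @param design study design, see [design_context()].
#' @param alpha significance level, used only when \code{hyp} is numeric.
#' @return An object of class \code{"or_power"}: list with \code{power},
#'   \code{lambda}, \code{df1}, \code{df2} (\code{NA} for the chi-squared
#'   reference), \code{critical_value}, \code{model}, the scaled
#'   parameter snapshot and the call configuration.
#' @examples
#' vd <- or_params(var_TR = 0.00020040, var_error = 0.00080229,
#'                 cov1 = 0.00034661, cov2 = 0.00034407,
#'                 cov3 = 0.00023903, c_star = 114)
#' or_power(vd, readers = 7, cases = 148, hyp = hypothesis(0.05, 0.05))
#' @export
or_power <- function(params, readers, cases, hyp,
                     inference = c("both_random", "readers_fixed",
                                   "cases_fixed"),
                     design = "factorial", alpha = 0.05) {
  inference <- match.arg(inference)
  if (is.numeric(hyp)) hyp <- hypothesis(effect_size = hyp, alpha = alpha)
  stopifnot(inherits(hyp, "or_hypothesis"))
  d <- hyp$effective_d
  a <- hyp$effective_alpha

  if (design != "factorial") {
    if (inference != "both_random")
      stop(sprintf(
        "design '%s' with inference '%s' is not supported: ",
        design, inference),
        "non-factorial designs are powered for random readers and cases only")
    ld <- lambda_df_for_design(design_context(design, readers, cases),
                               params, d)
    model <- paste0("M1[", design, "]")
  } else {
    ld <- switch(inference,
                 both_random  = lambda_df_m1(params, readers, cases, d),
                 readers_fixed = lambda_m2(params, readers, cases, d),
                 cases_fixed  = lambda_df_m3(params, readers, cases, d))
    model <- switch(inference, both_random = "M1", readers_fixed = "M2",
                    cases_fixed = "M3")
  }

  if (is.null(ld$df2)) {
    crit <- stats::qchisq(1 - a, ld$df1)
    pow <- power_noncentral_chi2(ld$lambda, ld$df1, a)
    df2 <- NA_real_
  } else {
    crit <- stats::qf(1 - a, ld$df1, ld$df2)
    pow <- power_noncentral_f(ld$lambda, ld$df1, ld$df2, a)
    df2 <- ld$df2
  }
  structure(list(power = pow, lambda = ld$lambda, df1 = ld$df1, df2 = df2,
                 critical_value = crit, model = model,
                 scaled_params = ld$scaled, design = design,
                 inference = inference, readers = readers, cases = cases,
                 hypothesis = hyp),
            class = "or_power")
}

#' @export
print.or_power <- function(x, ...) {
  cat(sprintf("MRMC power (%s design, %s; model %s)\n",
              x$design, gsub("_", " ", x$inference), x$model))
  cat(sprintf("  readers = %d, cases = %d, effect size = %g, alpha = %g",
              x$readers, x$cases, x$hypothesis$effect_size,
              x$hypothesis$alpha))
  if (x$hypothesis$kind == "noninferiority")
    cat(sprintf(" (noninferiority, margin = %g)", x$hypothesis$margin))
  cat("\n")
  if (is.na(x$df2))
    cat(sprintf("  lambda = %.3f, df1 = %d (chi-squared), critical = %.4f\n",
                x$lambda, x$df1, x$critical_value))
  else
    cat(sprintf("  lambda = %.3f, df1 = %d, df2 = %.3f, critical = %.4f\n",
                x$lambda, x$df1, x$df2, x$critical_value))
  cat(sprintf("  power = %.3f\n", x$power))
  invisible(x)
}
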