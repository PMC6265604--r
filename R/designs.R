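#' Study design and inference context
#'
#' Five study designs are recognised.  In the factorial design every
#' reader reads every case under both tests.  In the split-plot designs
#' some factor is nested: readers within test (each reader works under
#' one test only), cases within test (each case imaged under one test),
#' or cases within reader (each reader has their own case sample).  The
#' mixed split-plot design (reader-and-case blocks) is recognised for
#' parameter mapping but has no power formulas here.
#'
#' Case-count conventions: \code{cases} is the total case count for the
#' factorial and case-nested-in-test designs (in the latter each test arm
#' receives \code{cases / 2}), and the per-reader case count for the
#' case-nested-in-reader design.  For the reader-nested-in-test design,
#' \code{readers} is the number of readers *per test*.
#'
#' @param design one of \code{"factorial"}, \code{"reader_nested_in_test"},
#'   \code{"case_nested_in_test"}, \code{"case_nested_in_reader"},
#'   \code{"mixed_split_plot"}.
#' @param readers readers (per test for \code{reader_nested_in_test}).
#' @param cases case count (convention above).
#' @param inference inference situation; non-factorial designs support
#'   \code{"both_random"} only.
#' @return An object of class \code{"design_context"}.
#' @export
design_context <- function(design = c("factorial", "reader_nested_in_test",
                                      "case_nested_in_test",
                                      "case_nested_in_reader",
                                      "mixed_split_plot"),
                           readers, cases,
                           inference = "both_random") {
  design <- match.arg(design)
  if (!is.finite(readers) || readers < 2) stop("'readers' must be >= 2")
  if (!is.finite(cases) || cases < 2) stop("'cases' must be >= 2")
  if (design != "factorial" && inference != "both_random")
    stop(sprintf("design '%s' supports inference 'both_random' only",
                 design))
  structure(list(design = design, readers = readers, cases = cases,
                 inference = inference),
            class = "design_context")
}

#' Map factorial OR estimates onto another study design
#'
#' Parameter estimates from a factorial pilot study can size any of the
#' split-plot designs.  Nesting removes the covariances whose
#' reader/case sharing no longer occurs: cases nested in test forces
#' \code{cov1 = cov3 = 0} (no case is read under both tests); cases
#' nested in reader forces \code{cov2 = cov3 = 0} (no case is shared
#' between readers).  When readers are nested in test, the
#' reader-nested-within-test variance has the same interpretation as the
#' sum of the factorial reader and test-by-reader variances and is
#' estimated by that sum; \code{cov1} plays no role since no reader works
#' under both tests.  The mixed split-plot design reuses all five
#' factorial parameters unchanged.
#'
#' @param params an [or_params] object with factorial-design estimates.
#' @param design target design (see [design_context()]).
#' @return A list of design-adapted parameters.  For
#'   \code{reader_nested_in_test} the reader variance is returned as
#'   \code{var_R_nested}; for the others the [or_params] structure is
#'   kept.
#' @examples
#' vd <- or_params(var_R = 0.00153913, var_TR = 0.00020040,
#'                 var_error = 0.00080229, cov1 = 0.00034661,
#'                 cov2 = 0.00034407, cov3 = 0.00023903, c_star = 114)
#' map_factorial_params(vd, "case_nested_in_test")
#' @export
map_factorial_params <- function(params, design) {
  switch(design,
    factorial = params,
    mixed_split_plot = params,
    case_nested_in_test = {
      out <- params
      out$cov1 <- 0
      out$cov3 <- 0
      out
    },
    case_nested_in_reader = {
      out <- params
      out$cov2 <- 0
      out$cov3 <- 0
      out
    },
    reader_nested_in_test = list(
      var_R_nested = params$var_R + params$var_TR,
      var_error = params$var_error,
      cov2 = params$cov2, cov3 = params$cov3,
      c_star = params$c_star),
    stop(sprintf("unknown design '%s'", design)))
}

#' Noncentrality and df for a supported study design
#'
#' Applies the generic recipe: write the test statistic's numerator as
#' \eqn{\mathrm{MS}(T) = \frac{r}{2}(\hat\theta_{1\cdot} -
#' \hat\theta_{2\cdot})^2}, replace the means by their expectations and
#' divide by the expected denominator.  Per design (error terms scaled by
#' \code{c_star/c} with the design's case-count convention; \eqn{r} below
#' is \code{ctx$readers}):
#' \itemize{
#' \item \code{factorial}: delegates to [lambda_df_m1()].
#' \item \code{case_nested_in_test}: M1 formulas with \code{cov1 = cov3 =
#'   0} and each test arm resting on \code{cases / 2} cases (scale factor
#'   \code{2 c_star / cases}).
#' \item \code{case_nested_in_reader}: M1 formulas with \code{cov2 = cov3
#'   = 0}; \code{cases} is per reader.  The Satterthwaite df collapses to
#'   \code{r - 1}.
#' \item \code{reader_nested_in_test}: \eqn{\lambda = (t r d^2/2) /
#'   E(\mathrm{denom})} with \eqn{E(\mathrm{denom}) = \sigma^2_{R(T)} +
#'   \tilde\sigma_\epsilon^2 + (r-1)\widetilde{\mathrm{Cov}}_2 -
#'   r\widetilde{\mathrm{Cov}}_3} (tilde = scaled), where \eqn{r} is the
#'   number of readers per test and the total reader count \eqn{t r}
#'   enters the numerator; df2 is the Satterthwaite form with the
#'   reader-within-test mean square carrying \eqn{t(r-1)} degrees of
#'   freedom.
#' }
#'
#' @param ctx a [design_context()].
#' @param params factorial-scale [or_params] (mapped internally).
#' @param d effect size.
#' @return List with \code{lambda}, \code{df1}, \code{df2}, scaled
#'   snapshot.
#' @export
lambda_df_for_design <- function(ctx, params, d) {
  stopifnot(inherits(ctx, "design_context"))
  r <- ctx$readers; cases <- ctx$cases
  mp <- map_factorial_params(params, ctx$design)
  switch(ctx$design,
    factorial = lambda_df_m1(params, r, cases, d),
    case_nested_in_test = {
      # each test's accuracy estimate rests on cases/2 cases
      lambda_df_m1_scaled(mp, r, scale = mp$c_star / (cases / 2), d = d)
    },
    case_nested_in_reader = {
      lambda_df_m1_scaled(mp, r, scale = mp$c_star / cases, d = d)
    },
    reader_nested_in_test = {
      s <- mp$c_star / cases
      ve <- mp$var_error * s; c2 <- mp$cov2 * s; c3 <- mp$cov3 * s
      e_denom <- mp$var_R_nested + ve + (r - 1) * c2 - r * c3
      if (e_denom <= 0)
        stop("degenerate input: nested-design denominator is not positive")
      e_ms_r <- mp$var_R_nested + ve - c2
      df2 <- e_denom^2 / (e_ms_r^2 / (N_TESTS * (r - 1)))
      list(lambda = N_TESTS * r * d^2 / 2 / e_denom,
           df1 = N_TESTS - 1L, df2 = df2,
           scaled = list(var_R_nested = mp$var_R_nested, var_error = ve,
                         cov2 = c2, cov3 = c3, scale = s))
    },
    mixed_split_plot =
      stop("power formulas for the mixed split-plot design are not ",
           "available; only parameter mapping is supported"))
}

# M1 lambda/df2 with an explicit scale factor instead of c_star/cases;
# used by the case-nested designs whose case-count conventions differ.
lambda_df_m1_scaled <- function(params, readers, scale, d) {
  if (!is.finite(readers) || readers < 2) stop("'readers' must be >= 2")
  ve <- params$var_error * scale
  c1 <- params$cov1 * scale; c2 <- params$cov2 * scale
  c3 <- params$cov3 * scale
  trunc23 <- max(c2 - c3, 0)
  denom <- params$var_TR + ve - c1 + (readers - 1) * trunc23
  inner <- params$var_TR + ve - c1 - trunc23
  if (denom <= 0) stop("degenerate input: denominator is not positive")
  df2 <- denom^2 / (inner^2 / ((N_TESTS - 1) * (readers - 1)))
  sp <- params
  sp$var_error <- ve; sp$cov1 <- c1; sp$cov2 <- c2; sp$cov3 <- c3
  sp$scale <- scale
  list(lambda = readers * d^2 / 2 / denom, df1 = N_TESTS - 1L, df2 = df2,
       scaled = sp)
}
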