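#' Obuchowski-Rockette model parameters
#'
#' Bundles the variance components and error covariances of the
#' Obuchowski-Rockette (OR) two-way correlated-error ANOVA model for
#' reader-performance outcomes, together with the pilot case count the
#' error terms correspond to.  The model for the accuracy estimate
#' \eqn{\hat\theta_{ij}} of reader \eqn{j} under test \eqn{i} is
#' \deqn{\hat\theta_{ij} = \mu + \tau_i + R_j + (\tau R)_{ij} + \epsilon_{ij},}
#' with reader effects \eqn{R_j \sim N(0, \sigma_R^2)}, test-by-reader
#' interactions \eqn{(\tau R)_{ij} \sim N(0, \sigma_{TR}^2)} and
#' equicovariant errors with variance \eqn{\sigma_\epsilon^2} and three
#' covariances: \code{cov1} (different test, same reader), \code{cov2}
#' (same test, different reader) and \code{cov3} (different test,
#' different reader).
#'
#' The error variance and covariances are tied to the number of cases each
#' reader evaluated: when power is computed for a planned study with a
#' different case count they are rescaled by \code{c_star / c}
#' (see [scale_error_params()]).
#'
#' @param var_R reader variance \eqn{\sigma_R^2} (squared accuracy units).
#'   Only required for the reader-nested-within-test design; defaults to 0.
#' @param var_TR test-by-reader interaction variance \eqn{\sigma_{TR}^2}.
#' @param var_error error variance \eqn{\sigma_\epsilon^2}; must be positive.
#' @param cov1,cov2,cov3 error covariances (see Description).
#' @param c_star positive integer: total number of cases per reader-test
#'   combination underlying the error variance/covariances (pilot case
#'   count, or the case count a conjectured error variance corresponds to).
#' @param strict logical; if \code{TRUE} (default) constraint violations
#'   are errors, otherwise they are warnings and the object is returned
#'   with a \code{waived} attribute.
#'
#' @return An object of class \code{"or_params"}: a named list with the
#'   seven fields above.
#'
#' @examples
#' ## Van Dyke study estimates (thoracic aortic dissection, spin-echo vs
#' ## cine MRI; 5 readers, 114 cases)
#' van_dyke <- or_params(var_R = 0.00153913, var_TR = 0.00020040,
#'                       var_error = 0.00080229, cov1 = 0.00034661,
#'                       cov2 = 0.00034407, cov3 = 0.00023903, c_star = 114)
#' or_correlations(van_dyke)
#' @seealso [or_params_from_corr()], [validate_or_params()], [dbm_to_or()]
#' @export
or_params <- function(var_TR, var_error, cov1, cov2, cov3, c_star,
                      var_R = 0, strict = TRUE) {
  for (nm in c("var_R", "var_TR", "var_error", "cov1", "cov2", "cov3",
               "c_star")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (c_star < 1 || c_star != round(c_star))
    stop("'c_star' must be a positive integer")
  p <- structure(list(var_R = var_R, var_TR = var_TR, var_error = var_error,
                      cov1 = cov1, cov2 = cov2, cov3 = cov3,
                      c_star = as.integer(c_star)),
                 class = "or_params")
  rep <- validate_or_params(p, strict = strict)
  if (!rep$ok) attr(p, "waived") <- rep$violations
  p
}

#' @export
print.or_params <- function(x, ...) {
  cat("Obuchowski-Rockette model parameters\n")
  cat(sprintf("  Var(R)     = %.8f\n", x$var_R))
  cat(sprintf("  Var(T*R)   = %.8f\n", x$var_TR))
  cat(sprintf("  Var(Error) = %.8f\n", x$var_error))
  cat(sprintf("  Cov1 = %.8f  Cov2 = %.8f  Cov3 = %.8f\n",
              x$cov1, x$cov2, x$cov3))
  r <- or_correlations(x)
  cat(sprintf("  r1   = %.3f       r2   = %.3f       r3   = %.3f\n",
              r$r1, r$r2, r$r3))
  cat(sprintf("  cases underlying error terms (c*) = %d\n", x$c_star))
  invisible(x)
}

#' Construct OR parameters from error correlations
#'
#' The error covariances can equivalently be specified as correlations
#' \eqn{r_i = \mathrm{Cov}_i / \sigma_\epsilon^2}.  Correlations are often
#' preferred for conjectured inputs because simulation studies have found
#' them stable across case sample sizes, while the covariances scale with
#' the case count.  Only the difference \code{r2 - r3} enters the power
#' formulas, so any pair with the conjectured difference gives identical
#' results.
#'
#' @inheritParams or_params
#' @param r1,r2,r3 error correlations in \[0, 1\].
#' @return An \code{"or_params"} object with \code{covi = ri * var_error}.
#' @examples
#' or_params_from_corr(var_TR = 0.0001, var_error = 0.000977,
#'                     r1 = 0.35, r2 = 0.30, r3 = 0.25, c_star = 200)
#' @export
or_params_from_corr <- function(var_TR, var_error, r1, r2, r3, c_star,
                                var_R = 0, strict = TRUE) {
  cv <- cov_from_corr(r1 = r1, r2 = r2, r3 = r3, var_error = var_error)
  or_params(var_R = var_R, var_TR = var_TR, var_error = var_error,
            cov1 = cv[["cov1"]], cov2 = cv[["cov2"]], cov3 = cv[["cov3"]],
            c_star = c_star, strict = strict)
}

#' Convert error correlations to covariances
#'
#' @param r1,r2,r3 error correlations, each in \[0, 1\].
#' @param var_error error variance \eqn{\sigma_\epsilon^2 > 0}.
#' @return Named numeric vector \code{c(cov1, cov2, cov3)} with
#'   \code{covi = ri * var_error}.
#' @seealso [corr_from_cov()], its inverse.
#' @export
cov_from_corr <- function(r1, r2, r3, var_error) {
  if (!is.finite(var_error) || var_error <= 0)
    stop("'var_error' must be positive")
  r <- c(r1 = r1, r2 = r2, r3 = r3)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("correlations must lie in [0, 1]")
  c(cov1 = r1 * var_error, cov2 = r2 * var_error, cov3 = r3 * var_error)
}

#' Error correlations of an OR parameter set
#'
#' @param params an [or_params] object (or any list with \code{var_error},
#'   \code{cov1}, \code{cov2}, \code{cov3}).
#' @return Named list with \code{r1}, \code{r2}, \code{r3}, where
#'   \code{ri = covi / var_error}.
#' @export
or_correlations <- function(params) {
  if (!is.finite(params$var_error) || params$var_error <= 0)
    stop("'var_error' must be positive to form correlations")
  list(r1 = params$cov1 / params$var_error,
       r2 = params$cov2 / params$var_error,
       r3 = params$cov3 / params$var_error)
}

#' @rdname or_correlations
#' @export
corr_from_cov <- or_correlations

#' Convert Dorfman-Berbaum-Metz variance components to OR parameters
#'
#' The DBM method analyses jackknife pseudovalues with a
#' test-by-reader-by-case mixed ANOVA; it is equivalent to a special case
#' of the OR method, and its pseudovalue-scale variance components map
#' onto the OR parameters as
#' \deqn{\sigma_\epsilon^2 = (\sigma_C^2+\sigma_{TC}^2+\sigma_{RC}^2+
#'   \sigma_{TRC}^2)/c,\quad
#'   \mathrm{Cov}_1 = (\sigma_C^2+\sigma_{RC}^2)/c,\quad
#'   \mathrm{Cov}_2 = (\sigma_C^2+\sigma_{TC}^2)/c,\quad
#'   \mathrm{Cov}_3 = \sigma_C^2/c,}
#' with the reader and test-by-reader components passing through
#' unchanged.  The output satisfies the OR covariance constraints by
#' construction.
#'
#' @param var_R,var_TR reader and test-by-reader variance components.
#' @param var_C,var_TC,var_RC,var_TRC case, test-by-case, reader-by-case
#'   and test-by-reader-by-case pseudovalue variance components (all
#'   \eqn{\ge 0}).
#' @param c case count of the study the DBM components were estimated
#'   from; becomes \code{c_star} of the result.
#' @return An [or_params] object.
#' @examples
#' dbm_to_or(var_R = 0.0015, var_TR = 0.0002, var_C = 0.3, var_TC = 0.1,
#'           var_RC = 0.2, var_TRC = 0.6, c = 114)
#' @export
dbm_to_or <- function(var_R, var_TR, var_C, var_TC, var_RC, var_TRC, c) {
  comps <- c(var_R = var_R, var_TR = var_TR, var_C = var_C,
             var_TC = var_TC, var_RC = var_RC, var_TRC = var_TRC)
  if (any(!is.finite(comps)) || any(comps < 0))
    stop("all DBM variance components must be finite and non-negative")
  if (!is.finite(c) || c < 1) stop("'c' must be at least 1")
  var_error <- (var_C + var_TC + var_RC + var_TRC) / c
  if (var_error == 0) {
    warning("all case-indexed DBM components are zero; ",
            "the implied OR error variance is degenerate")
    # degenerate but representable: keep a zero-variance placeholder out of
    # or_params (which requires var_error > 0)
    return(structure(list(var_R = var_R, var_TR = var_TR, var_error = 0,
                          cov1 = 0, cov2 = 0, cov3 = 0,
                          c_star = as.integer(c), degenerate = TRUE),
                     class = "or_params"))
  }
  or_params(var_R = var_R, var_TR = var_TR, var_error = var_error,
            cov1 = (var_C + var_RC) / c,
            cov2 = (var_C + var_TC) / c,
            cov3 = var_C / c,
            c_star = c)
}

#' Test-by-reader variance from DBM pseudovalue mean squares
#'
#' Unbiased moment estimator \eqn{[\mathrm{MS}(T{*}R) -
#' \mathrm{MS}(T{*}R{*}C)]/c} of the test-by-reader interaction variance
#' from the pseudovalue-scale mean squares of a DBM analysis.  The
#' estimate can be negative; it is returned as is with a warning so the
#' caller can decide whether to truncate.
#'
#' @param ms_tr test-by-reader pseudovalue mean square.
#' @param ms_trc test-by-reader-by-case pseudovalue mean square.
#' @param c case count.
#' @return Estimated \eqn{\sigma_{TR}^2} (possibly negative).
#' @export
dbm_var_tr_from_mean_squares <- function(ms_tr, ms_trc, c) {
  if (!is.finite(c) || c < 1) stop("'c' must be at least 1")
  out <- (ms_tr - ms_trc) / c
  if (out < 0)
    warning("negative test-by-reader variance estimate; ",
            "consider truncating to zero")
  out
}

#' Test-by-reader variance from an OR-scale mean square
#'
#' Inverts the moment identity \eqn{E[\mathrm{MS}(T{*}R)] = \sigma_{TR}^2 +
#' \sigma_\epsilon^2 - \mathrm{Cov}_1 - \mathrm{Cov}_2 + \mathrm{Cov}_3}
#' to recover \eqn{\sigma_{TR}^2} from the test-by-reader mean square of
#' an OR analysis of the accuracy outcomes.
#'
#' @param ms_tr_or OR-scale test-by-reader mean square.
#' @param var_error,cov1,cov2,cov3 OR error variance and covariances.
#' @return Estimated \eqn{\sigma_{TR}^2} (possibly negative, with warning).
#' @export
or_var_tr_from_mean_squares <- function(ms_tr_or, var_error, cov1, cov2,
                                        cov3) {
  out <- ms_tr_or - var_error + cov1 + cov2 - cov3
  if (out < 0)
    warning("negative test-by-reader variance estimate; ",
            "consider truncating to zero")
  out
}

#' Obuchowski's conjectured error variance for ROC AUC outcomes
#'
#' When no pilot estimate is available, the error variance of a reader's
#' empirical AUC can be conjectured from the anticipated mean AUC and case
#' counts via
#' \deqn{\mathrm{var}(\mathrm{error}) = \frac{0.0099}{n_1}
#'   e^{-a^2/2}\left[(5a^2+8) + (a^2+8)/R\right],\qquad
#'   a = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC}),}
#' where \eqn{n_1} is the number of abnormal (diseased) cases and
#' \eqn{R = n_0/n_1} the normal-to-abnormal case ratio.  The value is the
#' binormal-model approximation to the variance of the empirical AUC;
#' lower AUC gives a larger variance and hence more conservative sample
#' sizes.  When feeding the result into power computations, the pilot
#' case count must be set to \eqn{n_1 (1 + R)}, the total case count the
#' conjecture corresponds to.
#'
#' @param auc anticipated mean AUC of the two tests, in (0.5, 1).
#' @param n1 number of abnormal cases (\eqn{\ge 1}).
#' @param ratio normal-to-abnormal case ratio \eqn{R = n_0/n_1 > 0}.
#' @return Conjectured error variance (squared AUC units).
#' @examples
#' obuchowski_error_variance(auc = 0.92, n1 = 45, ratio = 69 / 45) # 0.00109
#' obuchowski_error_variance(auc = 0.85, n1 = 100, ratio = 1)      # 0.000977
#' @export
obuchowski_error_variance <- function(auc, n1, ratio) {
  if (!is.finite(auc) || auc <= 0.5 || auc >= 1)
    stop("'auc' must lie strictly between 0.5 and 1")
  if (!is.finite(n1) || n1 < 1) stop("'n1' must be at least 1")
  if (!is.finite(ratio) || ratio <= 0) stop("'ratio' must be positive")
  a <- sqrt(2) * stats::qnorm(auc)
  (0.0099 / n1) * exp(-a^2 / 2) * ((5 * a^2 + 8) + (a^2 + 8) / ratio)
}

#' Test-by-reader variance from a range of between-test differences
#'
#' The test-by-reader interaction variance equals half the variance of the
#' test1 minus test2 differences in true reader accuracies.  Under the
#' model's normality assumption the middle 95% of those differences spans
#' \eqn{3.92\sqrt{2\,\sigma_{TR}^2}} (3.92 = 2 x 1.96), so a researcher
#' who can bound that range can conjecture
#' \deqn{\sigma_{TR}^2 = \frac{1}{2}\left(\frac{\mathrm{range}}{3.92}
#'   \right)^2 .}
#'
#' @param range95 width of the middle 95% of the anticipated between-test
#'   true-accuracy differences across readers (\eqn{\ge 0}).
#' @return Conjectured \eqn{\sigma_{TR}^2}.
#' @examples
#' var_tr_from_range(0.10)  # 0.00033
#' @export
var_tr_from_range <- function(range95) {
  if (!is.finite(range95) || range95 < 0)
    stop("'range95' must be non-negative")
  (range95 / 3.92)^2 / 2
}

#' Validate OR model parameters
#'
#' Checks the covariance-ordering constraints \eqn{\mathrm{Cov}_1 \ge
#' \mathrm{Cov}_3}, \eqn{\mathrm{Cov}_2 \ge \mathrm{Cov}_3},
#' \eqn{\mathrm{Cov}_3 \ge 0}, the bound \eqn{\sigma_\epsilon^2 \ge
#' \mathrm{Cov}_1 + \mathrm{Cov}_2 - \mathrm{Cov}_3} (which guarantees a
#' non-negative within-reader variance bound), that correlations lie in
#' \[0, 1\], and positive semidefiniteness of the implied covariance
#' matrix of the accuracy estimates for a small reader panel.
#'
#' @param params an [or_params] object.
#' @param strict if \code{TRUE}, violations raise an error; otherwise
#'   each violation is a warning.
#' @param tol numeric slack for the inequality checks.
#' @return Invisibly (strict) or visibly (lenient), a list with \code{ok}
#'   and a character vector \code{violations}.
#' @export
validate_or_params <- function(params, strict = TRUE, tol = 1e-12) {
  v <- character(0)
  p <- params
  if (p$var_R < 0)      v <- c(v, "Var(R) >= 0")
  if (p$var_TR < 0)     v <- c(v, "Var(T*R) >= 0")
  if (p$var_error <= 0) v <- c(v, "Var(Error) > 0")
  if (p$cov3 < -tol)           v <- c(v, "Cov3 >= 0")
  if (p$cov1 < p$cov3 - tol)   v <- c(v, "Cov1 >= Cov3")
  if (p$cov2 < p$cov3 - tol)   v <- c(v, "Cov2 >= Cov3")
  if (p$var_error > 0) {
    if (p$cov1 > p$var_error + tol)
      v <- c(v, "Cov1 <= Var(Error) (r1 <= 1)")
    if (p$cov2 > p$var_error + tol)
      v <- c(v, "Cov2 <= Var(Error) (r2 <= 1)")
    if (p$var_error - p$cov1 - p$cov2 + p$cov3 < -tol)
      v <- c(v, "Var(Error) >= Cov1 + Cov2 - Cov3")
  }
  if (length(v) == 0 && params$var_error > 0) {
    sig <- or_covariance_matrix(params, readers = 3, model = "M1")
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev)))
      v <- c(v, "implied accuracy covariance matrix is not positive semidefinite")
  }
  rep <- list(ok = length(v) == 0, violations = v)
  if (!rep$ok) {
    msg <- paste("OR parameter constraint(s) violated:",
                 paste(v, collapse = "; "))
    if (strict) stop(msg) else warning(msg)
  }
  if (strict) invisible(rep) else rep
}
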