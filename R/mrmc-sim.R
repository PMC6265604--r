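#' Covariance matrix of the accuracy estimates implied by the OR model
#'
#' Joint covariance of \code{vec(theta)} for a panel of \code{readers}
#' readers under two tests, ordered (test 1 readers 1..r, test 2 readers
#' 1..r).  Under the random-readers random-cases model (M1) the entries
#' are: diagonal \eqn{\sigma_R^2 + \sigma_{TR}^2 + \sigma_\epsilon^2};
#' same reader, different test \eqn{\sigma_R^2 + \mathrm{Cov}_1}; same
#' test, different reader \eqn{\mathrm{Cov}_2}; different both
#' \eqn{\mathrm{Cov}_3}.  With fixed readers (M2) the reader and
#' test-by-reader variances drop out of every entry.  With fixed cases
#' (M3) the errors are independent with within-reader variance
#' \eqn{\sigma_w^2} (taken as the conservative bound
#' \eqn{\sigma_\epsilon^2 - \mathrm{Cov}_1 -
#' \max(\mathrm{Cov}_2-\mathrm{Cov}_3, 0)} unless supplied), so only the
#' same-reader cross-test entry \eqn{\sigma_R^2} survives off the
#' diagonal.
#'
#' @param params an [or_params] object (error terms on the scale of the
#'   case count being simulated; see [scale_error_params()]).
#' @param readers panel size \eqn{r \ge 2}.
#' @param model \code{"M1"}, \code{"M2"} or \code{"M3"}.
#' @param var_w within-reader variance for M3; defaults to the
#'   conservative bound.
#' @return Symmetric positive semidefinite \code{2r x 2r} matrix.
#' @export
or_covariance_matrix <- function(params, readers,
                                 model = c("M1", "M2", "M3"),
                                 var_w = NULL) {
  model <- match.arg(model)
  if (!is.finite(readers) || readers < 2) stop("'readers' must be >= 2")
  r <- as.integer(readers)
  p <- params
  ent <- switch(model,
    M1 = list(diag = p$var_R + p$var_TR + p$var_error,
              same_reader = p$var_R + p$cov1,
              same_test = p$cov2, neither = p$cov3),
    M2 = list(diag = p$var_error, same_reader = p$cov1,
              same_test = p$cov2, neither = p$cov3),
    M3 = {
      if (is.null(var_w))
        var_w <- p$var_error - p$cov1 - max(p$cov2 - p$cov3, 0)
      if (var_w < 0)
        stop("negative within-reader variance for model M3")
      list(diag = p$var_R + p$var_TR + var_w,
           same_reader = p$var_R, same_test = 0, neither = 0)
    })
  n <- 2L * r
  test_of <- rep(1:2, each = r)
  reader_of <- rep(seq_len(r), times = 2)
  sig <- matrix(ent$neither, n, n)
  same_test <- outer(test_of, test_of, "==")
  same_reader <- outer(reader_of, reader_of, "==")
  sig[same_test & !same_reader] <- ent$same_test
  sig[!same_test & same_reader] <- ent$same_reader
  diag(sig) <- ent$diag
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300))
    stop("parameter combination implies a non-positive-semidefinite ",
         "covariance matrix (check Cov1/Cov2/Cov3 against Var(Error))")
  sig
}

#' Monte Carlo rejection rate of the OR tests
#'
#' Empirical oracle for the analytic power formulas: draws accuracy
#' matrices from the exact multivariate normal law implied by the chosen
#' model (with the error terms pre-scaled by \code{c_star/cases}), applies
#' the matching test with the *true* (scaled) covariances, and returns
#' the rejection fraction.  At \code{d = 0} the rate estimates the test's
#' size; at \code{d != 0} its power.
#'
#' @param params an [or_params] object (pilot scale).
#' @param readers,cases study dimensions; \code{cases} enters only
#'   through the \code{c_star/cases} scaling.
#' @param d true difference of expected accuracies.
#' @param model \code{"M1"}, \code{"M2"} or \code{"M3"}.
#' @param alpha significance level.
#' @param n_reps number of Monte Carlo replicates.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return List with \code{rate}, binomial \code{se}, \code{n_reps},
#'   \code{rejections} and the configuration.
#' @examples
#' vd <- or_params(var_TR = 0.00020040, var_error = 0.00080229,
#'                 cov1 = 0.00034661, cov2 = 0.00034407,
#'                 cov3 = 0.00023903, c_star = 114)
#' simulate_power(vd, readers = 7, cases = 148, d = 0.05,
#'                n_reps = 2000, seed = 1)
#' @export
simulate_power <- function(params, readers, cases, d,
                           model = c("M1", "M2", "M3"), alpha = 0.05,
                           n_reps = 10000, seed = NULL) {
  model <- match.arg(model)
  if (!is.finite(n_reps) || n_reps < 1) stop("'n_reps' must be >= 1")
  check_rc(readers, cases)
  r <- as.integer(readers)
  sp <- scale_error_params(params, cases)
  sig <- or_covariance_matrix(sp, r, model)
  if (!is.null(seed)) set.seed(seed)
  mu <- c(rep(0, r), rep(d, r))  # d = E(theta_2.) - E(theta_1.)
  cf <- chol_psd(sig)
  z <- matrix(stats::rnorm(n_reps * 2 * r), nrow = n_reps)
  x <- sweep(z %*% cf, 2, mu, "+")
  th1 <- x[, seq_len(r), drop = FALSE]
  th2 <- x[, r + seq_len(r), drop = FALSE]
  m1 <- rowMeans(th1); m2 <- rowMeans(th2)
  ms_t <- r / 2 * (m1 - m2)^2
  diffs <- th1 - th2
  # for t = 2 the interaction mean square is half the sample variance of
  # the per-reader between-test differences
  ms_tr <- apply(diffs, 1, stats::var) / 2
  rej <- switch(model,
    M1 = {
      denom <- ms_tr + r * max(sp$cov2 - sp$cov3, 0)
      f <- ms_t / denom
      df2 <- denom^2 / (ms_tr^2 / (r - 1))
      f > stats::qf(1 - alpha, 1, df2)
    },
    M2 = {
      denom <- sp$var_error - sp$cov1 +
        (r - 1) * max(sp$cov2 - sp$cov3, 0)
      (ms_t / denom) > stats::qchisq(1 - alpha, 1)
    },
    M3 = (ms_t / ms_tr) > stats::qf(1 - alpha, 1, r - 1))
  k <- sum(rej)
  rate <- k / n_reps
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps),
       rejections = k, n_reps = n_reps, model = model,
       readers = r, cases = cases, d = d, alpha = alpha)
}

# Cholesky-like factor tolerant of a semidefinite matrix (pivoting, then
# unpivot); rank-deficient directions get zero rows.
chol_psd <- function(sig) {
  cf <- tryCatch(chol(sig), error = function(e) NULL)
  if (!is.null(cf)) return(cf)
  e <- eigen(sig, symmetric = TRUE)
  val <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(val), nrow = length(val)))
}

#' Random valid OR parameter sets
#'
#' Draws parameter sets spanning magnitudes typical of published ROC
#' MRMC studies: error correlations \eqn{r_1 \in [0.35, 0.59]} (the range
#' reported across 20 studies with AUC outcomes), \eqn{r_2 - r_3 \in
#' [0, 0.14]}, test-by-reader variances spanning the conjecture table
#' (middle-95% ranges of 0.01 to 0.15 in true-accuracy differences), and
#' error variances of a few times \eqn{10^{-4}}.  Every draw satisfies
#' the model constraints and yields a positive semidefinite accuracy
#' covariance, so the sets can serve directly as simulation fixtures.
#'
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @return List of \code{n} [or_params] objects (empty list for
#'   \code{n = 0}).
#' @export
generate_fixture_params <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(list())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      var_error <- stats::runif(1, 5e-4, 2e-3)
      r1 <- stats::runif(1, 0.35, 0.59)
      r3 <- stats::runif(1, 0.05, 0.35)
      r2 <- r3 + stats::runif(1, 0, 0.14)
      if (r1 + r2 - r3 > 1) next  # keep the within-reader bound positive
      p <- tryCatch(
        or_params(var_R = stats::runif(1, 5e-4, 3e-3),
                  var_TR = var_tr_from_range(stats::runif(1, 0.01, 0.15)),
                  var_error = var_error,
                  cov1 = r1 * var_error, cov2 = r2 * var_error,
                  cov3 = r3 * var_error,
                  c_star = sample(50:250, 1)),
        error = function(e) NULL)
      if (!is.null(p)) break
    }
    out[[i]] <- p
  }
  out
}
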