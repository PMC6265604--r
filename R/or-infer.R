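#' Test and test-by-reader mean squares of an accuracy matrix
#'
#' Two-way ANOVA mean squares of a \eqn{t \times r} matrix of
#' reader-performance estimates (rows = tests, columns = readers),
#' \deqn{\mathrm{MS}(T) = r \sum_i (\bar\theta_{i\cdot} -
#'   \bar\theta_{\cdot\cdot})^2 / (t-1), \qquad
#'   \mathrm{MS}(T{*}R) = \sum_{ij} (\theta_{ij} - \bar\theta_{i\cdot} -
#'   \bar\theta_{\cdot j} + \bar\theta_{\cdot\cdot})^2 / [(t-1)(r-1)].}
#' For \eqn{t = 2}, \eqn{\mathrm{MS}(T) = \frac{r}{2}(\bar\theta_{1\cdot}
#' - \bar\theta_{2\cdot})^2}.
#'
#' @param theta numeric \code{2 x r} matrix of accuracy estimates
#'   (\eqn{r \ge 2}), finite entries.
#' @return List with \code{ms_t} and \code{ms_tr}, both \eqn{\ge 0}.
#' @examples
#' mean_squares(rbind(c(0.9, 0.8), c(0.85, 0.75)))
#' @export
mean_squares <- function(theta) {
  theta <- check_accuracy_matrix(theta)
  r <- ncol(theta)
  row_m <- rowMeans(theta)
  col_m <- colMeans(theta)
  grand <- mean(theta)
  ms_t <- r * sum((row_m - grand)^2) / (nrow(theta) - 1)
  resid <- theta - outer(row_m, rep(1, r)) -
    outer(rep(1, nrow(theta)), col_m) + grand
  ms_tr <- sum(resid^2) / ((nrow(theta) - 1) * (r - 1))
  list(ms_t = ms_t, ms_tr = ms_tr)
}

check_accuracy_matrix <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) != 2)
    stop("accuracy matrix must have exactly 2 rows (tests)")
  if (ncol(theta) < 2)
    stop("accuracy matrix must have at least 2 columns (readers)")
  if (any(!is.finite(theta)))
    stop("accuracy matrix entries must be finite")
  theta
}

#' OR F test, readers and cases random
#'
#' The random-readers random-cases F statistic
#' \deqn{F = \frac{\mathrm{MS}(T)}{\mathrm{MS}(T{*}R) +
#'   r \max(\widehat{\mathrm{Cov}}_2 - \widehat{\mathrm{Cov}}_3, 0)}}
#' with Satterthwaite-type denominator degrees of freedom
#' \deqn{df_2 = \frac{[\mathrm{MS}(T{*}R) + r\max(\widehat{\mathrm{Cov}}_2
#'   - \widehat{\mathrm{Cov}}_3,0)]^2}{\mathrm{MS}(T{*}R)^2/[(t-1)(r-1)]}.}
#' The covariance estimates are inputs: in data analysis they come from
#' resampling the rating data (jackknife, bootstrap, DeLong), which is
#' outside this package's scope; the Monte Carlo oracle passes true
#' values.
#'
#' @param theta \code{2 x r} accuracy matrix.
#' @param cov2,cov3 error covariance estimates on the scale of
#'   \code{theta}'s case count.
#' @param alpha significance level.
#' @return List with \code{statistic}, \code{df1}, \code{df2},
#'   \code{p_value}, \code{reject}.
#' @export
or_f_test_m1 <- function(theta, cov2, cov3, alpha = 0.05) {
  theta <- check_accuracy_matrix(theta)
  r <- ncol(theta)
  ms <- mean_squares(theta)
  denom <- ms$ms_tr + r * max(cov2 - cov3, 0)
  if (denom <= 0) stop("degenerate denominator in the M1 F test")
  f <- ms$ms_t / denom
  df2 <- denom^2 / (ms$ms_tr^2 / ((nrow(theta) - 1) * (r - 1)))
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  list(statistic = f, df1 = 1, df2 = df2, p_value = p,
       reject = f > stats::qf(1 - alpha, 1, df2))
}

#' OR chi-squared test, readers fixed
#'
#' \deqn{\chi^2 = \frac{(t-1)\,\mathrm{MS}(T)}{\hat\sigma_\epsilon^2 -
#'   \widehat{\mathrm{Cov}}_1 + (r-1)\max(\widehat{\mathrm{Cov}}_2 -
#'   \widehat{\mathrm{Cov}}_3, 0)},} referred to a chi-squared
#' distribution with \eqn{t - 1 = 1} degree of freedom.
#'
#' @inheritParams or_f_test_m1
#' @param var_error,cov1 error variance and covariance estimates.
#' @return List with \code{statistic}, \code{df1}, \code{p_value},
#'   \code{reject}.
#' @export
chi2_test_m2 <- function(theta, var_error, cov1, cov2, cov3,
                         alpha = 0.05) {
  theta <- check_accuracy_matrix(theta)
  r <- ncol(theta)
  ms <- mean_squares(theta)
  denom <- var_error - cov1 + (r - 1) * max(cov2 - cov3, 0)
  if (denom <= 0) stop("degenerate denominator in the M2 chi-squared test")
  x2 <- (nrow(theta) - 1) * ms$ms_t / denom
  p <- stats::pchisq(x2, 1, lower.tail = FALSE)
  list(statistic = x2, df1 = 1, p_value = p,
       reject = x2 > stats::qchisq(1 - alpha, 1))
}

#' Conventional F test, cases fixed
#'
#' With independent errors the conventional repeated-measures ANOVA
#' statistic \eqn{F = \mathrm{MS}(T) / \mathrm{MS}(T{*}R)} on
#' \eqn{(t-1, (t-1)(r-1))} degrees of freedom applies; for two tests it
#' is the square of the paired t statistic on the reader outcomes.
#'
#' @inheritParams or_f_test_m1
#' @return List with \code{statistic}, \code{df1}, \code{df2},
#'   \code{p_value}, \code{reject}.
#' @export
f_test_m3 <- function(theta, alpha = 0.05) {
  theta <- check_accuracy_matrix(theta)
  r <- ncol(theta)
  ms <- mean_squares(theta)
  if (ms$ms_tr <= 0)
    stop("degenerate test: the test-by-reader mean square is zero")
  f <- ms$ms_t / ms$ms_tr
  df2 <- (nrow(theta) - 1) * (r - 1)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  list(statistic = f, df1 = 1, df2 = df2, p_value = p,
       reject = f > stats::qf(1 - alpha, 1, df2))
}

#' Read an accuracy matrix from CSV
#'
#' Expects a CSV with two rows (tests) and one column per reader; an
#' optional first column of row labels is detected and dropped.
#'
#' @param path file path.
#' @return A numeric \code{2 x r} matrix.
#' @export
read_accuracy_matrix <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (ncol(raw) > 1 && !is.numeric(raw[[1]])) {
    rn <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  } else rn <- NULL
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (!is.null(rn)) rownames(m) <- rn
  check_accuracy_matrix(m)
}
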