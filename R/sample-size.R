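#' Minimal case count achieving a target power
#'
#' Smallest integer case count \code{c} in \code{[min_cases, max_cases]}
#' whose power reaches \code{target_power} for the given reader count.
#' A bisection narrows the range and a final check against \code{c - 1}
#' certifies minimality (power is not formally monotone in \code{c}
#' because the denominator degrees of freedom also change, so the
#' certificate is mandatory).  If even \code{max_cases} falls short the
#' result is \code{NA} ("<N/A>" in text reports).
#'
#' @param params an [or_params] object.
#' @param readers reader count.
#' @param hyp an [hypothesis] object or a plain effect size.
#' @param target_power target power in (effective alpha, 1).
#' @param inference,design as in [or_power()].
#' @param min_cases,max_cases search bounds (defaults 2 and 2000).
#' @param alpha used only when \code{hyp} is numeric.
#' @return List with \code{min_cases} (integer or \code{NA}) and
#'   \code{achieved_power} (power at \code{min_cases}, or at
#'   \code{max_cases} when \code{NA}).
#' @examples
#' vd <- or_params(var_TR = 0.00020040, var_error = 0.00080229,
#'                 cov1 = 0.00034661, cov2 = 0.00034407,
#'                 cov3 = 0.00023903, c_star = 114)
#' min_cases_for_power(vd, readers = 5, hyp = hypothesis(0.05, 0.05))
#' @export
min_cases_for_power <- function(params, readers, hyp, target_power = 0.8,
                                inference = "both_random",
                                design = "factorial",
                                min_cases = 2, max_cases = 2000,
                                alpha = 0.05) {
  if (is.numeric(hyp)) hyp <- hypothesis(effect_size = hyp, alpha = alpha)
  if (!is.finite(target_power) || target_power <= hyp$effective_alpha ||
      target_power >= 1)
    stop("'target_power' must lie in (effective alpha, 1)")
  if (min_cases > max_cases) stop("'min_cases' must not exceed 'max_cases'")
  pw <- function(c) or_power(params, readers, c, hyp,
                             inference = inference, design = design)$power
  p_hi <- pw(max_cases)
  if (p_hi < target_power)
    return(list(min_cases = NA_integer_, achieved_power = p_hi))
  p_lo <- pw(min_cases)
  if (p_lo >= target_power)
    return(list(min_cases = as.integer(min_cases), achieved_power = p_lo))
  lo <- min_cases  # power < target
  hi <- max_cases  # power >= target
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  # minimality certificate: power is expected (not proven) monotone in c,
  # so walk down if c - 1 also reaches the target
  while (hi > min_cases && pw(hi - 1) >= target_power) hi <- hi - 1
  list(min_cases = as.integer(hi), achieved_power = pw(hi))
}

#' Case sample-size table over a range of reader counts
#'
#' For each reader count, the minimal case count reaching the target
#' power (see [min_cases_for_power()]).  Mirrors the "sample size
#' results" section of MRMC sizing reports: one row per reader count,
#' with the minimal case count or \code{NA} when the cap is insufficient.
#'
#' @inheritParams min_cases_for_power
#' @param readers integer vector of reader counts (default \code{3:10}).
#' @return A data frame of class \code{"or_sample_size_table"} with
#'   columns \code{readers}, \code{min_cases}, \code{achieved_power};
#'   design, inference, hypothesis, target and parameter snapshot are
#'   attached as attributes.
#' @examples
#' vd <- or_params(var_TR = 0.00020040, var_error = 0.00080229,
#'                 cov1 = 0.00034661, cov2 = 0.00034407,
#'                 cov3 = 0.00023903, c_star = 114)
#' or_sample_size(vd, hyp = hypothesis(0.05, 0.05), readers = 5:7)
#' @export
or_sample_size <- function(params, hyp, target_power = 0.8,
                           readers = 3:10, inference = "both_random",
                           design = "factorial", min_cases = 2,
                           max_cases = 2000, alpha = 0.05) {
  if (is.numeric(hyp)) hyp <- hypothesis(effect_size = hyp, alpha = alpha)
  if (any(readers < 2)) stop("all reader counts must be >= 2")
  rows <- lapply(readers, function(r) {
    res <- tryCatch(
      min_cases_for_power(params, r, hyp, target_power,
                          inference = inference, design = design,
                          min_cases = min_cases, max_cases = max_cases),
      error = function(e) list(min_cases = NA_integer_,
                               achieved_power = NA_real_,
                               reason = conditionMessage(e)))
    data.frame(readers = r, min_cases = res$min_cases,
               achieved_power = res$achieved_power)
  })
  out <- do.call(rbind, rows)
  structure(out,
            class = c("or_sample_size_table", "data.frame"),
            design = design, inference = inference, hypothesis = hyp,
            target_power = target_power, max_cases = max_cases,
            params = params)
}

#' @export
print.or_sample_size_table <- function(x, ...) {
  hyp <- attr(x, "hypothesis")
  cat(sprintf("Sample size results (%s design, %s)\n",
              attr(x, "design"), gsub("_", " ", attr(x, "inference"))))
  cat(sprintf("  %s test, effect size = %g, alpha = %g",
              hyp$kind, hyp$effect_size, hyp$alpha))
  if (hyp$kind == "noninferiority")
    cat(sprintf(", margin = %g", hyp$margin))
  cat(sprintf("; target power = %g, case cap = %d\n",
              attr(x, "target_power"), as.integer(attr(x, "max_cases"))))
  cat(sprintf("  %8s  %9s  %14s\n", "readers", "cases", "achieved power"))
  for (i in seq_len(nrow(x))) {
    cs <- if (is.na(x$min_cases[i])) "<N/A>" else
      sprintf("%d", x$min_cases[i])
    ap <- if (is.na(x$min_cases[i])) "" else
      sprintf("%.3f", x$achieved_power[i])
    cat(sprintf("  %8d  %9s  %14s\n", x$readers[i], cs, ap))
  }
  invisible(x)
}

#' Power over a grid of (readers, cases) settings
#'
#' Direct power evaluation without any search, for the "power for
#' specified reader and case sample sizes" mode.
#'
#' @param params an [or_params] object.
#' @param grid data frame with columns \code{readers} and \code{cases}
#'   (may be empty).
#' @inheritParams or_power
#' @return A list of [or_power] results, one per grid row; evaluation
#'   errors are stored in place of the result.
#' @export
power_for_grid <- function(params, grid, hyp, inference = "both_random",
                           design = "factorial", alpha = 0.05) {
  stopifnot(is.data.frame(grid),
            all(c("readers", "cases") %in% names(grid)))
  lapply(seq_len(nrow(grid)), function(i)
    tryCatch(or_power(params, grid$readers[i], grid$cases[i], hyp,
                      inference = inference, design = design,
                      alpha = alpha),
             error = function(e) e))
}
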