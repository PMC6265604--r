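#' Load a run configuration from YAML or JSON
#'
#' A configuration file mirrors the sizing workflow step by step:
#' \preformatted{
#' title: Van Dyke factorial sizing
#' design: factorial            # step 1
#' inference: both_random       # step 2
#' hypothesis:                  # step 4
#'   kind: nonequivalence
#'   effect_size: 0.05
#'   alpha: 0.05
#' parameters:                  # steps 3A/3B
#'   var_R: 0.00153913
#'   var_TR: 0.00020040
#'   var_error: 0.00080229
#'   cov1: 0.00034661
#'   cov2: 0.00034407
#'   cov3: 0.00023903
#'   c_star: 114
#' search:                      # step 5 (sample-size mode)
#'   target_power: 0.8
#'   readers_min: 3
#'   readers_max: 10
#'   max_cases: 2000
#' }
#' Correlations \code{r1, r2, r3} may replace \code{cov1..cov3}
#' (exclusively), and a \code{dbm:} block with the pseudovalue variance
#' components (\code{var_R, var_TR, var_C, var_TC, var_RC, var_TRC, c})
#' may replace \code{parameters:}.  A \code{grid:} list of
#' \code{\{readers, cases\}} pairs requests direct power evaluation
#' instead of a search.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated configuration of class \code{"run_config"}.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  as_run_config(cfg)
}

run_config_keys <- c("title", "design", "inference", "hypothesis",
                     "parameters", "dbm", "search", "grid", "seed")

#' @rdname load_run_config
#' @param cfg a named list with the fields described above.
#' @export
as_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s; valid keys are: %s",
                 paste(unknown, collapse = ", "),
                 paste(run_config_keys, collapse = ", ")))
  if (is.null(cfg$design)) cfg$design <- "factorial"
  if (is.null(cfg$inference)) cfg$inference <- "both_random"

  h <- cfg$hypothesis
  if (is.null(h$effect_size)) stop("hypothesis: 'effect_size' is required")
  if (is.null(h$kind)) h$kind <- "nonequivalence"
  if (is.null(h$alpha)) h$alpha <- 0.05
  hyp <- hypothesis(effect_size = h$effect_size, alpha = h$alpha,
                    kind = h$kind, margin = h$margin)

  if (!is.null(cfg$dbm)) {
    if (!is.null(cfg$parameters))
      stop("supply either 'parameters' or 'dbm', not both")
    dd <- cfg$dbm
    params <- dbm_to_or(var_R = dd$var_R, var_TR = dd$var_TR,
                        var_C = dd$var_C, var_TC = dd$var_TC,
                        var_RC = dd$var_RC, var_TRC = dd$var_TRC,
                        c = dd$c)
    provenance <- "converted from DBM variance components"
  } else {
    pp <- cfg$parameters
    if (is.null(pp)) stop("config requires a 'parameters' or 'dbm' block")
    has_corr <- !is.null(pp$r1)
    has_cov <- !is.null(pp$cov1)
    if (has_corr && has_cov)
      stop("supply either covariances (cov1..cov3) or correlations ",
           "(r1..r3), not both")
    if (is.null(pp$var_R)) pp$var_R <- 0
    if (has_corr) {
      params <- or_params_from_corr(var_R = pp$var_R, var_TR = pp$var_TR,
                                    var_error = pp$var_error,
                                    r1 = pp$r1, r2 = pp$r2, r3 = pp$r3,
                                    c_star = pp$c_star)
      provenance <- "covariances derived from supplied correlations"
    } else {
      params <- or_params(var_R = pp$var_R, var_TR = pp$var_TR,
                          var_error = pp$var_error, cov1 = pp$cov1,
                          cov2 = pp$cov2, cov3 = pp$cov3,
                          c_star = pp$c_star)
      provenance <- "covariances supplied directly"
    }
  }

  structure(list(title = cfg$title %||% "MRMC sizing run",
                 design = cfg$design, inference = cfg$inference,
                 hypothesis = hyp, params = params,
                 provenance = provenance,
                 search = cfg$search, grid = cfg$grid,
                 seed = cfg$seed),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a sizing run
#'
#' Runs either a minimal-case search over a reader range (when the config
#' has a \code{search} block) or direct power evaluation over a
#' \code{grid}.  The report echoes the inputs and the derived error
#' correlations so every printed number can be recomputed from the report
#' alone.
#'
#' @param config a \code{"run_config"} (see [load_run_config()]).
#' @return An object of class \code{"mrmc_report"}.
#' @export
run_sizing <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  corr <- or_correlations(p)
  if (!is.null(config$grid)) {
    grid <- if (is.data.frame(config$grid))
      config$grid[, c("readers", "cases")]
    else
      do.call(rbind, lapply(config$grid, function(g)
        data.frame(readers = g$readers, cases = g$cases)))
    res <- power_for_grid(p, grid, config$hypothesis,
                          inference = config$inference,
                          design = config$design)
    grid$power <- vapply(res, function(x)
      if (inherits(x, "error")) NA_real_ else x$power, numeric(1))
    out <- list(mode = "power", grid = grid, results = res)
  } else {
    s <- config$search %||% list()
    tbl <- or_sample_size(p, config$hypothesis,
                          target_power = s$target_power %||% 0.8,
                          readers = (s$readers_min %||% 3):
                                    (s$readers_max %||% 10),
                          inference = config$inference,
                          design = config$design,
                          max_cases = s$max_cases %||% 2000)
    out <- list(mode = "samplesize", table = tbl)
  }
  structure(c(list(title = config$title, design = config$design,
                   inference = config$inference,
                   hypothesis = config$hypothesis,
                   params = p, correlations = corr,
                   provenance = config$provenance),
              out),
            class = "mrmc_report")
}

#' @export
print.mrmc_report <- function(x, ...) {
  cat(strrep("=", 60), "\n", x$title, "\n", strrep("=", 60), "\n",
      sep = "")
  cat(sprintf("design: %s | inference: %s\n", x$design,
              gsub("_", " ", x$inference)))
  h <- x$hypothesis
  cat(sprintf("%s test: effect size = %g, alpha = %g", h$kind,
              h$effect_size, h$alpha))
  if (h$kind == "noninferiority") cat(sprintf(", margin = %g", h$margin))
  cat("\n\nOR variance components, covariances, and correlations\n")
  cat(sprintf("  (%s)\n", x$provenance))
  print(x$params)
  cat("\n")
  if (x$mode == "samplesize") {
    print(x$table)
  } else {
    cat("power results\n")
    cat(sprintf("  %8s  %9s  %9s\n", "readers", "cases", "power"))
    for (i in seq_len(nrow(x$grid)))
      cat(sprintf("  %8d  %9d  %9.3f\n", x$grid$readers[i],
                  x$grid$cases[i], x$grid$power[i]))
  }
  invisible(x)
}

#' Write a sizing report to file
#'
#' @param report an \code{"mrmc_report"}.
#' @param path output path.
#' @param format \code{"text"} (the printed report; \code{NA} rows render
#'   as \code{<N/A>}), \code{"csv"} (the result table only) or
#'   \code{"json"} (full report including parameter echo).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("text", "csv", "json")) {
  format <- match.arg(format)
  tab <- if (report$mode == "samplesize")
    as.data.frame(report$table) else report$grid
  switch(format,
    text = {
      txt <- utils::capture.output(print(report))
      writeLines(txt, path)
    },
    csv = utils::write.csv(tab, path, row.names = FALSE, na = "<N/A>"),
    json = {
      h <- report$hypothesis
      jsonlite::write_json(
        list(title = report$title, design = report$design,
             inference = report$inference,
             hypothesis = list(kind = h$kind,
                               effect_size = h$effect_size,
                               alpha = h$alpha, margin = h$margin),
             parameters = unclass(report$params),
             correlations = report$correlations,
             mode = report$mode, results = tab),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    })
  invisible(path)
}
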