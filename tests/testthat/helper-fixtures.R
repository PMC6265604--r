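# Van Dyke study OR estimates (5 readers, 114 cases, ROC AUC outcome):
# the standard worked example for MRMC sizing.  var_R is only needed for
# the reader-nested design.
van_dyke <- function(var_R = 0.00153913) {
  or_params(var_R = var_R, var_TR = 0.00020040, var_error = 0.00080229,
            cov1 = 0.00034661, cov2 = 0.00034407, cov3 = 0.00023903,
            c_star = 114)
}

# brute-force two-way ANOVA mean squares via lm(), as an independent
# oracle for mean_squares()
anova_mean_squares <- function(theta) {
  df <- data.frame(y = as.vector(theta),
                   test = factor(rep(seq_len(nrow(theta)), ncol(theta))),
                   reader = factor(rep(seq_len(ncol(theta)),
                                       each = nrow(theta))))
  tab <- anova(lm(y ~ test + reader, data = df))
  list(ms_t = tab["test", "Mean Sq"], ms_tr = tab["Residuals", "Mean Sq"])
}

# exhaustive linear-scan oracle for the minimal-case search
linear_scan_min_cases <- function(params, readers, hyp, target = 0.8,
                                  inference = "both_random",
                                  max_cases = 500) {
  for (c in 2:max_cases) {
    p <- or_power(params, readers, c, hyp, inference = inference)$power
    if (p >= target) return(c)
  }
  NA_integer_
}
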