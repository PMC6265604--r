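vd <- van_dyke()

test_that("case-count scaling multiplies error terms by c*/c and leaves
           reader variances alone", {
  sp <- scale_error_params(vd, 148)
  expect_equal(sp$var_error, 0.00080229 * 114 / 148)
  expect_equal(sp$cov1, 0.00034661 * 114 / 148)
  expect_equal(sp$var_TR, vd$var_TR)
  expect_equal(sp$var_R, vd$var_R)
  # identity at c = c*
  expect_equal(scale_error_params(vd, 114)$var_error, vd$var_error)
  # error terms vanish in the infinite-case limit
  expect_lt(scale_error_params(vd, 1e9)$var_error, 1e-9)
  expect_error(scale_error_params(vd, 0), "at least 1")
})

test_that("M1/M2/M3 noncentralities and df2 reproduce the Van Dyke worked
           example at r=7, c=148, d=0.05", {
  m1 <- lambda_df_m1(vd, 7, 148, 0.05)
  expect_equal(round(m1$lambda, 3), 8.439)
  expect_equal(round(m1$df2, 3), 29.140)
  m2 <- lambda_m2(vd, 7, 148, 0.05)
  expect_equal(round(m2$lambda, 3), 10.461)
  expect_null(m2$df2)
  m3 <- lambda_df_m3(vd, 7, 148, 0.05)
  expect_equal(round(m3$lambda, 3), 18.598)
  expect_equal(m3$df2, 6)
  # unscaled within-reader bound: direct arithmetic on the estimates
  expect_equal(vd$var_error - vd$cov1 - max(vd$cov2 - vd$cov3, 0),
               0.00035064, tolerance = 1e-10)
  expect_equal(m3$var_w_bound, 0.00035064 * 114 / 148, tolerance = 1e-10)
})

test_that("null effect gives zero noncentrality, and truncation collapses
           df2 to r-1 when Cov2 <= Cov3", {
  expect_equal(lambda_df_m1(vd, 7, 148, 0)$lambda, 0)
  expect_equal(lambda_m2(vd, 7, 148, 0)$lambda, 0)
  expect_equal(lambda_df_m3(vd, 7, 148, 0)$lambda, 0)
  eq <- vd; eq$cov2 <- eq$cov3
  expect_equal(lambda_df_m1(eq, 7, 148, 0.05)$df2, 6)
  lt <- vd; lt$cov2 <- lt$cov3  # boundary of the constraint region
  expect_equal(lambda_df_m1(lt, 5, 200, 0.03)$df2, 4)
})

test_that("noncentral tail powers hit the worked-example values and the
           lambda = 0 calibration", {
  expect_equal(round(power_noncentral_f(8.439, 1, 29.14, 0.05), 3), 0.802)
  expect_equal(round(power_noncentral_f(18.598, 1, 6, 0.05), 3), 0.945)
  expect_equal(round(power_noncentral_chi2(10.461, 1, 0.05), 3), 0.899)
  # critical values quoted alongside
  expect_equal(round(qf(0.95, 1, 29.14), 5), 4.18122)
  expect_equal(qchisq(0.95, 1), 3.8416, tolerance = 1e-4)
  # power at lambda = 0 equals alpha
  for (a in c(0.01, 0.05, 0.2)) {
    expect_equal(power_noncentral_f(0, 1, 20, a), a, tolerance = 1e-12)
    expect_equal(power_noncentral_chi2(0, 1, a), a, tolerance = 1e-12)
  }
  # strictly increasing in lambda
  lams <- seq(0, 30, by = 2)
  pows <- vapply(lams, power_noncentral_f, numeric(1), df1 = 1,
                 df2 = 15, alpha = 0.05)
  expect_true(all(diff(pows) > 0))
  # F converges to chi-squared as df2 grows
  expect_equal(power_noncentral_f(10.461, 1, 1e6, 0.05),
               power_noncentral_chi2(10.461, 1, 0.05), tolerance = 1e-3)
  expect_error(power_noncentral_f(-1, 1, 10, 0.05), "lambda")
  expect_error(power_noncentral_f(1, 1, 10, 1.5), "alpha")
})

test_that("noncentrality ordering lambda_M2, lambda_M3 >= lambda_M1 holds
           across random fixtures", {
  for (p in generate_fixture_params(8, seed = 99)) {
    for (r in c(4, 8)) {
      l1 <- lambda_df_m1(p, r, 150, 0.04)$lambda
      l2 <- lambda_m2(p, r, 150, 0.04)$lambda
      l3 <- lambda_df_m3(p, r, 150, 0.04)$lambda
      expect_gte(l2, l1)
      expect_gte(l3, l1)
      expect_gte(lambda_df_m1(p, r, 150, 0.04)$df2, r - 1)
    }
  }
})

test_that("power rises with case count and effect size, and plateaus below
           one when the interaction variance dominates", {
  cases <- c(50, 100, 200, 400, 800)
  pows <- vapply(cases, function(c)
    or_power(vd, 5, c, hypothesis(0.05, 0.05))$power, numeric(1))
  expect_true(all(diff(pows) > 0))
  ds <- c(0.01, 0.03, 0.05, 0.08)
  powd <- vapply(ds, function(d)
    or_power(vd, 5, 200, hypothesis(d, 0.05))$power, numeric(1))
  expect_true(all(diff(powd) > 0))
  # c -> Inf: lambda tends to r d^2 / (2 var_TR); with 3 readers and
  # d = 0.05 the ceiling power stays below 0.8 (the "<N/A>" mechanism)
  lam_inf <- 3 * 0.05^2 / 2 / vd$var_TR
  expect_equal(lambda_df_m1(vd, 3, 1e9, 0.05)$lambda, lam_inf,
               tolerance = 1e-6)
  expect_lt(or_power(vd, 3, 1e6, hypothesis(0.05, 0.05))$power, 0.8)
})

test_that("noninferiority maps to a nonequivalence test at doubled alpha and
           shifted effect size", {
  ni <- or_power(vd, 7, 148,
                 hypothesis(0.02, 0.025, kind = "noninferiority",
                            margin = 0.03))
  ne <- or_power(vd, 7, 148, hypothesis(0.05, 0.05))
  expect_equal(ni$power, ne$power, tolerance = 1e-12)
  expect_equal(ni$lambda, ne$lambda, tolerance = 1e-12)
  expect_equal(ni$critical_value, ne$critical_value, tolerance = 1e-12)
  # boundary of the null: effective d -> 0, power -> effective alpha
  b <- or_power(vd, 7, 148,
                hypothesis(-0.03 + 1e-12, 0.025, kind = "noninferiority",
                           margin = 0.03))
  expect_equal(b$power, 0.05, tolerance = 1e-6)
  expect_error(hypothesis(-0.03, 0.025, kind = "noninferiority",
                          margin = 0.03), "exceed")
  expect_error(hypothesis(0.02, 0.025, kind = "noninferiority"),
               "margin")
  expect_error(hypothesis(0.05, 0.05, margin = 0.03), "noninferiority")
})

test_that("degenerate all-zero denominators raise rather than return
           infinite noncentrality", {
  degen <- van_dyke()
  degen$var_TR <- 0
  degen$var_error <- 1e-9
  degen$cov1 <- 1e-9; degen$cov2 <- 0; degen$cov3 <- 0
  expect_error(lambda_df_m1(degen, 5, 100, 0.05), "degenerate")
  expect_error(lambda_m2(degen, 5, 100, 0.05), "degenerate")
})
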