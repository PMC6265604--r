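test_that("covariance/correlation conversion round-trips and matches the
           Van Dyke estimates", {
  vd <- van_dyke()
  corr <- or_correlations(vd)
  expect_equal(round(corr$r1, 2), 0.43)
  expect_equal(round(corr$r2 - corr$r3, 3), 0.131)

  cv <- cov_from_corr(corr$r1, corr$r2, corr$r3, vd$var_error)
  expect_equal(unname(cv[["cov1"]]), vd$cov1, tolerance = 1e-12)
  expect_equal(unname(cv[["cov2"]]), vd$cov2, tolerance = 1e-12)
  expect_equal(unname(cv[["cov3"]]), vd$cov3, tolerance = 1e-12)

  # r = 0 gives zero covariance; r = 1 gives the error variance back
  z <- cov_from_corr(0, 0, 0, 0.001)
  expect_true(all(z == 0))
  p1 <- or_params(var_TR = 1e-4, var_error = 2e-3, cov1 = 2e-3,
                  cov2 = 2e-3, cov3 = 2e-3, c_star = 100)
  expect_equal(or_correlations(p1)$r1, 1)

  # direct arithmetic: cov2 - cov3 for quoted correlation difference
  cv2 <- cov_from_corr(0.432, 0.429, 0.298, 0.00080229)
  expect_equal(unname(cv2[["cov2"]] - cv2[["cov3"]]), 0.131 * 0.00080229,
               tolerance = 1e-12)

  # round trip identity across random fixtures
  for (p in generate_fixture_params(10, seed = 42)) {
    corr <- or_correlations(p)
    cv <- cov_from_corr(corr$r1, corr$r2, corr$r3, p$var_error)
    expect_equal(unname(cv), c(p$cov1, p$cov2, p$cov3), tolerance = 1e-12)
  }

  expect_error(cov_from_corr(0.4, 0.3, 0.2, -1), "positive")
  expect_error(or_correlations(list(var_error = 0, cov1 = 0, cov2 = 0,
                                    cov3 = 0)), "positive")
})

test_that("DBM components convert to OR parameters that satisfy the model
           constraints", {
  # only the shared case effect: all covariance classes coincide
  p <- dbm_to_or(var_R = 0, var_TR = 0, var_C = 1, var_TC = 0,
                 var_RC = 0, var_TRC = 0, c = 10)
  expect_equal(p$var_error, 0.1)
  expect_equal(p$cov1, 0.1)
  expect_equal(p$cov2, 0.1)
  expect_equal(p$cov3, 0.1)

  # all case-indexed components zero: degenerate, flagged
  expect_warning(
    d0 <- dbm_to_or(var_R = 0.001, var_TR = 0.0002, var_C = 0,
                    var_TC = 0, var_RC = 0, var_TRC = 0, c = 50),
    "degenerate")
  expect_true(isTRUE(d0$degenerate))

  # random valid components always produce valid OR parameters with the
  # within-reader bound var_error - cov1 - cov2 + cov3 = var_TRC / c
  set.seed(7)
  for (i in 1:20) {
    comps <- runif(4, 0.01, 1)
    cc <- sample(20:200, 1)
    p <- dbm_to_or(var_R = runif(1, 0, 0.01), var_TR = runif(1, 0, 0.001),
                   var_C = comps[1], var_TC = comps[2], var_RC = comps[3],
                   var_TRC = comps[4], c = cc)
    expect_true(validate_or_params(p)$ok)
    expect_gte(p$cov1, p$cov3)
    expect_gte(p$cov2, p$cov3)
    expect_gte(p$cov3, 0)
    expect_equal(p$var_error - p$cov1 - p$cov2 + p$cov3, comps[4] / cc,
                 tolerance = 1e-12)
    corr <- or_correlations(p)
    expect_true(all(unlist(corr) >= 0 & unlist(corr) <= 1))
  }
  expect_error(dbm_to_or(0, 0, 1, 1, 1, 1, c = 0), "at least 1")
})

test_that("mean-square moment estimators invert their expectations", {
  # pseudovalue scale: [MS(T*R) - MS(T*R*C)] / c
  expect_equal(dbm_var_tr_from_mean_squares(2, 2, 529), 0)
  expect_equal(dbm_var_tr_from_mean_squares(2, 1, 529), 1 / 529)
  expect_warning(neg <- dbm_var_tr_from_mean_squares(1, 2, 529),
                 "negative")
  expect_lt(neg, 0)

  # OR scale: E[MS(T*R)] = var_TR + var_error - cov1 - cov2 + cov3
  vd <- van_dyke()
  ms <- vd$var_TR + vd$var_error - vd$cov1 - vd$cov2 + vd$cov3
  expect_equal(or_var_tr_from_mean_squares(ms, vd$var_error, vd$cov1,
                                           vd$cov2, vd$cov3),
               vd$var_TR, tolerance = 1e-12)
  expect_warning(
    neg <- or_var_tr_from_mean_squares(0, vd$var_error, vd$cov1, vd$cov2,
                                       vd$cov3),
    "negative")
  expect_lt(neg, 0)
})

test_that("Obuchowski's conjectured error variance reproduces published
           values and its monotonicity", {
  expect_equal(signif(obuchowski_error_variance(0.92, 45, 69 / 45), 3),
               0.00109)
  expect_equal(signif(obuchowski_error_variance(0.85, 100, 1), 3),
               0.000977)
  # 1/n1 proportionality
  expect_equal(obuchowski_error_variance(0.9, 90, 1.5),
               obuchowski_error_variance(0.9, 45, 1.5) / 2,
               tolerance = 1e-12)
  # strictly decreasing in AUC
  grid <- seq(0.55, 0.99, by = 0.02)
  vals <- vapply(grid, obuchowski_error_variance, numeric(1),
                 n1 = 50, ratio = 1)
  expect_true(all(diff(vals) < 0))
  expect_error(obuchowski_error_variance(0.4, 50, 1), "between")
  expect_error(obuchowski_error_variance(1, 50, 1), "between")
})

test_that("test-by-reader variance from a conjectured 95% range matches the
           published conversion table", {
  ranges <- seq(0.01, 0.15, by = 0.01)
  published <- c(0.00000, 0.00001, 0.00003, 0.00005, 0.00008, 0.00012,
                 0.00016, 0.00021, 0.00026, 0.00033, 0.00039, 0.00047,
                 0.00055, 0.00064, 0.00073)
  expect_equal(round(vapply(ranges, var_tr_from_range, numeric(1)), 5),
               published)
  expect_equal(var_tr_from_range(0), 0)
  expect_error(var_tr_from_range(-0.1), "non-negative")
})

test_that("validation flags each violated constraint by name", {
  expect_true(validate_or_params(van_dyke())$ok)
  bad3 <- van_dyke(); bad3$cov3 <- -1e-4
  expect_error(validate_or_params(bad3), "Cov3 >= 0")
  bad1 <- van_dyke(); bad1$cov1 <- bad1$cov3 / 2
  expect_error(validate_or_params(bad1), "Cov1 >= Cov3")
  badw <- van_dyke(); badw$var_error <- badw$cov1 + badw$cov2
  badw$cov3 <- 0; badw$cov1 <- badw$cov1 * 2
  expect_error(validate_or_params(badw))
  # lenient mode reports instead of raising
  rep <- suppressWarnings(validate_or_params(bad3, strict = FALSE))
  expect_false(rep$ok)
  expect_match(rep$violations, "Cov3", all = FALSE)
  # constructor honours strict flag
  expect_error(or_params(var_TR = 1e-4, var_error = 1e-3, cov1 = 1e-4,
                         cov2 = 1e-4, cov3 = 2e-4, c_star = 100),
               "Cov1 >= Cov3")
})
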