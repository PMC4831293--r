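test_that("dose assignment follows the midpoint and open-interval rules", {
  cat24 <- parity_catalog()
  mem <- assign_doses(paritymeta:::.get_report(cat24, "memon_2002"))
  # ladder 1-2, 3-4, 5-6, 7-8, 9-10, >=11: midpoints, then 11 + 1/2
  expect_equal(mem$dose, c(0, 1.5, 3.5, 5.5, 7.5, 9.5, 11.5))
  expect_equal(mem$rule_used[1], "reference_zero")
  expect_equal(mem$rule_used[7], "open_ended")
  # single values pass through; an open top after a single value gets width 1
  xh <- assign_doses(paritymeta:::.get_report(cat24, "xhaard_2014"))
  expect_equal(xh$dose, c(0, 1, 2, 3.5))
  expect_equal(xh$rule_used[2], "single_value")
  # open-ended with no bounded neighbor: width 1, with a warning
  lone <- make_report("lone", rr = 1.4, lcl = 1.0, ucl = 1.96,
                      lower = 2, upper = NA)
  expect_warning(d <- assign_doses(lone), "no bounded neighbor")
  expect_equal(d$dose, c(0, 2.5))
  # idempotent and order-preserving
  expect_identical(suppressWarnings(assign_doses(lone)),
                   suppressWarnings(assign_doses(lone)))
  expect_true(all(diff(mem$dose) > 0))
})

test_that("the restricted cubic spline basis has the Harrell properties", {
  kn <- c(1, 2, 4)
  # zero nonlinear term up to the first knot
  expect_equal(rcs_basis(c(0, 0.5, 1), kn)[, "b2"], c(0, 0, 0))
  # plug-in arithmetic at the last knot
  b2_k3 <- ((4 - 1)^3 - (4 - 2)^3 * (4 - 1) / (4 - 2)) / (4 - 1)^2
  expect_equal(rcs_basis(4, kn)[, "b2"], c(b2 = b2_k3))
  # linear beyond the last knot: vanishing second differences
  x <- seq(4.5, 8, by = 0.25)
  b2 <- rcs_basis(x, kn)[, "b2"]
  expect_equal(max(abs(diff(diff(b2)))), 0, tolerance = 1e-10)
  expect_error(rcs_basis(1, c(2, 2, 3)), "domain")
})

test_that("the within-study GLS slope matches explicit matrix arithmetic", {
  # one category: slope = y / d, se = se / d
  one <- make_report("one", rr = 1.5, lcl = 1.2, ucl = 1.875,
                     lower = 2, upper = 2)
  fit <- study_linear_trend(one)
  e <- log_effect_from_ci(1.5, 1.2, 1.875)
  expect_equal(fit[["slope"]], e$y / 2, tolerance = 1e-12)
  expect_equal(fit[["se"]], e$se / 2, tolerance = 1e-12)
  # exactly linear log RRs are recovered exactly
  beta <- 0.12
  d <- c(1, 2, 3.5)
  lin <- make_report("lin", rr = exp(beta * d), lcl = exp(beta * d - 0.3),
                     ucl = exp(beta * d + 0.3),
                     lower = c(1, 2, 3), upper = c(1, 2, 4))
  expect_equal(study_linear_trend(lin)[["slope"]], beta, tolerance = 1e-10)
  # full covariance: compare against the spelled-out GLS solve
  C <- matrix(c(0.04, 0.01, 0.008,
                0.01, 0.06, 0.012,
                0.008, 0.012, 0.09), 3, 3)
  y <- log(c(1.1, 1.4, 1.3))
  o <- oracle_gls_slope(y, d, C)
  toy <- make_report("toy", rr = c(1.1, 1.4, 1.3),
                     lcl = exp(y - Z95 * sqrt(diag(C))),
                     ucl = exp(y + Z95 * sqrt(diag(C))),
                     lower = c(1, 2, 3), upper = c(1, 2, 4))
  fit3 <- study_linear_trend(toy, doses = d, covariance = C)
  expect_equal(fit3[["slope"]], o[["slope"]], tolerance = 1e-12)
  expect_equal(fit3[["se"]], o[["se"]], tolerance = 1e-12)
  # diagonal covariance reduces GLS to weighted least squares through 0
  se_d <- c(0.2, 0.25, 0.3)
  wls <- sum(y * d / se_d^2) / sum(d^2 / se_d^2)
  fit_d <- study_linear_trend(toy, doses = d, covariance = diag(se_d^2))
  expect_equal(fit_d[["slope"]], wls, tolerance = 1e-12)
  # singular covariance is a numeric error
  expect_error(study_linear_trend(toy, doses = d,
                                  covariance = matrix(0.1, 3, 3)),
               "singular")
})

test_that("doubling every dose halves every slope exactly", {
  cat24 <- parity_catalog()
  for (id in c("memon_2002", "rossing_2000", "galanti_1995")) {
    r <- paritymeta:::.get_report(cat24, id)
    d <- assign_doses(r)$dose[-1]
    f1 <- study_linear_trend(r, doses = d)
    f2 <- study_linear_trend(r, doses = 2 * d)
    expect_equal(f2[["slope"]], f1[["slope"]] / 2, tolerance = 1e-12)
    expect_equal(f2[["se"]], f1[["se"]] / 2, tolerance = 1e-12)
  }
})

test_that("hamling pseudo-counts recover a crude table exactly", {
  # true 2x4 table; crude ORs and Woolf CIs computed from it
  A <- c(40, 30, 20, 25)  # cases: ref + 3 exposure levels
  B <- c(60, 45, 25, 15)  # controls
  or <- (A[-1] / B[-1]) / (A[1] / B[1])
  se <- sqrt(1 / A[-1] + 1 / B[-1] + 1 / A[1] + 1 / B[1])
  rep_c <- make_report("crude", rr = or, lcl = exp(log(or) - Z95 * se),
                       ucl = exp(log(or) + Z95 * se),
                       lower = 1:3, upper = 1:3,
                       total_cases = sum(A), total_subjects = sum(B))
  h <- hamling_counts(rep_c)
  expect_true(h$converged)
  expect_equal(h$ref_cases, A[1], tolerance = 1e-6)
  expect_equal(h$ref_noncases, B[1], tolerance = 1e-6)
  expect_equal(h$cases, A[-1], tolerance = 1e-6)
  expect_equal(h$noncases, B[-1], tolerance = 1e-6)
  # the defining reproduction properties hold for any returned table
  or_fit <- (h$cases / h$noncases) / (h$ref_cases / h$ref_noncases)
  v_fit <- 1 / h$cases + 1 / h$noncases + 1 / h$ref_cases + 1 / h$ref_noncases
  expect_equal(or_fit, or, tolerance = 1e-8)
  expect_equal(v_fit, se^2, tolerance = 1e-8)
  expect_equal(h$ref_cases + sum(h$cases), sum(A), tolerance = 1e-6)
  expect_equal(h$ref_noncases + sum(h$noncases), sum(B), tolerance = 1e-6)
})

test_that("greenland-longnecker covariance matches the shared-control closed form", {
  A <- c(40, 30, 20, 25)
  B <- c(60, 45, 25, 15)
  or <- (A[-1] / B[-1]) / (A[1] / B[1])
  se <- sqrt(1 / A[-1] + 1 / B[-1] + 1 / A[1] + 1 / B[1])
  rep_c <- make_report("crude", rr = or, lcl = exp(log(or) - Z95 * se),
                       ucl = exp(log(or) + Z95 * se),
                       lower = 1:3, upper = 1:3,
                       total_cases = sum(A), total_subjects = sum(B),
                       n_cases = A, n_denominator = B)
  g <- gl_counts(rep_c)
  expect_equal(g$ref_cases, A[1], tolerance = 1e-9)
  expect_equal(g$cases, A[-1], tolerance = 1e-9)
  C <- reconstruct_covariance(rep_c, "gl_counts")
  # crude log odds ratios sharing a control group: cov = 1/a0 + 1/b0
  off <- 1 / A[1] + 1 / B[1]
  expect_equal(C[1, 2], off, tolerance = 1e-6)
  expect_equal(C[1, 3], off, tolerance = 1e-6)
  expect_equal(diag(C), se^2, tolerance = 1e-10, ignore_attr = TRUE)
  # independence method keeps only the diagonal
  Ci <- reconstruct_covariance(rep_c, "independent")
  expect_equal(Ci, diag(se^2), ignore_attr = TRUE)
})

test_that("trend pooling recovers a common slope and the knots sit in range", {
  tr <- dose_trend(parity_catalog())
  all_doses <- unlist(lapply(parity_catalog(), function(r) {
    if (sum(!r$categories$is_reference) == 0) return(NULL)
    assign_doses(r)$dose[-1]
  }))
  expect_true(all(tr$knots >= min(all_doses) & tr$knots <= max(all_doses)))
  expect_equal(nrow(tr$per_study), 22)  # two reports print only a parous row
  expect_gt(tr$rr_per_birth, 0)
  expect_gte(tr$spline$lr_stat, 0)
  # equal-precision slopes pool to their mean
  r1 <- make_report("r1", rr = exp(0.1 * 1:2), lcl = exp(0.1 * 1:2 - 0.3),
                    ucl = exp(0.1 * 1:2 + 0.3), lower = 1:2, upper = 1:2)
  r2 <- make_report("r2", rr = exp(0.2 * 1:2), lcl = exp(0.2 * 1:2 - 0.3),
                    ucl = exp(0.2 * 1:2 + 0.3), lower = 1:2, upper = 1:2)
  # two distinct doses cannot identify the spline; the linear fit survives
  expect_message(
    tr2 <- dose_trend(as_catalog(r1, r2), method = "fixed",
                      knot_quantiles = c(0.1, 0.5, 0.9)),
    "not identifiable")
  expect_null(tr2$spline)
  s1 <- study_linear_trend(r1)[["slope"]]
  s2 <- study_linear_trend(r2)[["slope"]]
  expect_equal(tr2$pooled$y, (s1 + s2) / 2, tolerance = 1e-10)
})

test_that("pronounced curvature is flagged and exact linearity is not", {
  # steep early rise that flattens: strongly nonlinear, tiny uncertainty
  d <- c(1, 2, 3, 5)
  curve_y <- log(c(2.0, 2.6, 2.8, 2.9))
  nl <- make_report("nl", rr = exp(curve_y), lcl = exp(curve_y - 0.05),
                    ucl = exp(curve_y + 0.05), lower = d, upper = d)
  nl2 <- make_report("nl2", rr = exp(curve_y * 1.05),
                     lcl = exp(curve_y * 1.05 - 0.05),
                     ucl = exp(curve_y * 1.05 + 0.05), lower = d, upper = d)
  tr_nl <- dose_trend(as_catalog(nl, nl2), method = "fixed")
  expect_lt(tr_nl$spline$p_nonlinear, 0.05)
  expect_lt(tr_nl$spline$p_wald, 0.05)
  # exactly linear data: zero likelihood-ratio statistic
  d2 <- c(1, 2, 3, 4.5)
  lin1 <- make_report("lin1", rr = exp(0.1 * d2), lcl = exp(0.1 * d2 - 0.2),
                      ucl = exp(0.1 * d2 + 0.2), lower = d2, upper = d2)
  lin2 <- make_report("lin2", rr = exp(0.1 * d2), lcl = exp(0.1 * d2 - 0.3),
                      ucl = exp(0.1 * d2 + 0.3), lower = d2, upper = d2)
  tr_lin <- dose_trend(as_catalog(lin1, lin2), method = "fixed")
  expect_equal(tr_lin$spline$lr_stat, 0, tolerance = 1e-9)
  expect_equal(tr_lin$spline$p_nonlinear, 1, tolerance = 1e-4)
})

test_that("the spline curve prediction is anchored at dose zero", {
  tr <- dose_trend(parity_catalog())
  curve_tab <- predict(tr, doses = c(0, 1, 2.5))
  expect_equal(curve_tab$rr[1], 1)
  expect_equal(curve_tab$lcl[1], 1)
  expect_true(all(curve_tab$lcl <= curve_tab$rr & curve_tab$rr <= curve_tab$ucl))
})
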