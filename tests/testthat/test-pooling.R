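test_that("fixed-effects pooling handles the degenerate cases", {
  e1 <- data.frame(report_id = "a", y = 0.3, se = 0.1)
  p1 <- meta_pool(e1, method = "fixed")
  expect_equal(p1$y, 0.3)
  expect_equal(p1$se, 0.1)
  expect_equal(p1$Q, 0)
  expect_equal(p1$i2, 0)
  expect_equal(p1$p_het, 1)
  # duplicating a study halves the variance, not the estimate
  p2 <- meta_pool(rbind(e1, e1), method = "fixed")
  expect_equal(p2$y, 0.3)
  expect_equal(p2$se, 0.1 / sqrt(2))
  expect_error(meta_pool(e1[0, ]), "no-data")
  expect_error(meta_pool(e1, method = "random"), "insufficient-data")
})

test_that("equal-precision effects pool to their plain mean under both models", {
  e <- data.frame(y = c(-0.2, 0.1, 0.4), se = 0.15)
  for (m in c("fixed", "random")) {
    p <- meta_pool(e, method = m)
    expect_equal(p$y, mean(e$y), tolerance = 1e-12)
  }
})

test_that("pooling matches the spelled-out arithmetic oracle to 1e-12", {
  for (seed in 1:8) {
    for (k in 2:4) {
      e <- random_effects(k, seed * 100 + k)
      pf <- meta_pool(e, method = "fixed")
      of <- oracle_pool_fixed(e$y, e$se)
      expect_equal(pf$y, of$y, tolerance = 1e-12)
      expect_equal(pf$se, of$se, tolerance = 1e-12)
      expect_equal(pf$Q, of$Q, tolerance = 1e-12)
      expect_equal(pf$i2, of$i2, tolerance = 1e-12)
      pr <- meta_pool(e, method = "random")
      or <- oracle_pool_dl(e$y, e$se)
      expect_equal(pr$y, or$y, tolerance = 1e-12)
      expect_equal(pr$se, or$se, tolerance = 1e-12)
      expect_equal(pr$tau2, or$tau2, tolerance = 1e-12)
    }
  }
})

test_that("DerSimonian-Laird arithmetic matches a hand-computed three-study case", {
  e <- data.frame(y = c(0.0, 0.5, 1.0), se = c(0.1, 0.2, 0.3))
  # step-by-step: w = 100, 25, 11.111...; sum w = 136.111...
  w <- c(100, 25, 1 / 0.09)
  yp <- sum(w * e$y) / sum(w)
  Q <- sum(w * (e$y - yp)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (e$se^2 + tau2)
  p <- meta_pool(e, method = "random")
  expect_equal(p$tau2, tau2, tolerance = 1e-12)
  expect_equal(p$y, sum(ws * e$y) / sum(ws), tolerance = 1e-12)
  expect_gt(p$tau2, 0)
  # truncation: homogeneous inputs give tau2 = 0 and the fixed answer
  eh <- data.frame(y = c(0.2, 0.2, 0.2), se = c(0.1, 0.2, 0.3))
  ph <- meta_pool(eh, method = "random")
  expect_equal(ph$tau2, 0)
  expect_equal(ph$y, meta_pool(eh, method = "fixed")$y, tolerance = 1e-12)
})

test_that("pooling agrees with metafor as an independent implementation", {
  skip_if_not_installed("metafor")
  for (seed in c(5, 17)) {
    e <- random_effects(12, seed)
    pf <- meta_pool(e, method = "fixed")
    mf <- metafor::rma(yi = e$y, sei = e$se, method = "FE")
    expect_equal(pf$y, as.numeric(mf$beta), tolerance = 1e-10)
    expect_equal(pf$se, mf$se, tolerance = 1e-10)
    expect_equal(pf$Q, mf$QE, tolerance = 1e-10)
    pr <- meta_pool(e, method = "random")
    mr <- metafor::rma(yi = e$y, sei = e$se, method = "DL")
    expect_equal(pr$y, as.numeric(mr$beta), tolerance = 1e-10)
    expect_equal(pr$tau2, mr$tau2, tolerance = 1e-10)
  }
})

test_that("pooled estimates obey the bracketing and precision invariants", {
  for (seed in 1:10) {
    e <- random_effects(6, seed)
    pf <- meta_pool(e, method = "fixed")
    pr <- meta_pool(e, method = "random")
    expect_gte(pf$y, min(e$y)); expect_lte(pf$y, max(e$y))
    expect_gte(pr$y, min(e$y)); expect_lte(pr$y, max(e$y))
    expect_lte(pf$se, min(e$se))
    expect_gte(pr$se, pf$se)
    # inverting every relative risk inverts the pooled one exactly
    en <- e; en$y <- -en$y
    pn <- meta_pool(en, method = "random")
    expect_equal(pn$y, -pr$y, tolerance = 1e-12)
    expect_equal(pn$Q, pr$Q, tolerance = 1e-10)
    expect_equal(pn$i2, pr$i2, tolerance = 1e-10)
    expect_equal(pn$tau2, pr$tau2, tolerance = 1e-12)
    expect_equal(pn$se, pr$se, tolerance = 1e-12)
  }
})

test_that("the automatic model switch follows the 50% I-squared rule", {
  homog <- data.frame(y = c(0.1, 0.1, 0.1, 0.1), se = 0.2)
  expect_equal(meta_pool(homog)$model, "fixed")
  # well-separated effects with tight intervals: I2 far above 50%
  heterog <- data.frame(y = c(-0.8, 0, 0.8, 1.6), se = 0.05)
  ph <- meta_pool(heterog)
  expect_gt(ph$i2, 50)
  expect_equal(ph$model, "random")
  expect_gt(ph$tau2, 0)
  # the reported I2 is the fixed-effects one either way
  expect_equal(ph$i2, meta_pool(heterog, method = "fixed")$i2)
})

test_that("leave-one-out returns one complement fit per report", {
  e <- random_effects(5, 42)
  loo <- leave_one_out(e, method = "fixed")
  expect_equal(nrow(loo), 5)
  expect_equal(loo$k, rep(4L, 5))
  for (i in 1:5) {
    expect_equal(loo$rr[i],
                 meta_pool(e[-i, ], method = "fixed")$rr, tolerance = 1e-12)
  }
  # two studies: each omission returns the other unchanged
  e2 <- e[1:2, ]
  loo2 <- leave_one_out(e2)
  expect_equal(loo2$rr, exp(rev(e2$y)), tolerance = 1e-12)
  expect_error(leave_one_out(e[1, , drop = FALSE]), "insufficient-data")
})

test_that("subgroup strata reproduce the catalog's group sizes", {
  cat24 <- parity_catalog()
  ks <- function(g) vapply(subgroup_pool(cat24, g), `[[`, integer(1), "k")
  expect_equal(ks("design"),
               c(case_control = 14L, prospective = 10L))
  expect_equal(ks("quality"), c(high = 14L, low = 9L))
  expect_equal(ks("region")[c("Europe", "America", "Asia", "Oceania",
                              "International")],
               c(Europe = 8L, America = 8L, Asia = 5L, Oceania = 2L,
                 International = 1L))
  expect_equal(ks("control_type"),
               c(hospital_based = 4L, population_based = 9L))
  expect_equal(ks("adjustment"), c(adjusted = 19L, unadjusted = 5L))
  # a single-report stratum still pools (to itself)
  intl <- subgroup_pool(cat24, "region")$International
  expect_equal(intl$rr, 1.2, tolerance = 1e-12)
  # printed interval recovered up to the rounding of its point estimate
  expect_equal(intl$ci, c(1.00, 1.40), tolerance = 0.02)
})

test_that("a constant grouping reproduces the overall pooled fit", {
  cat24 <- parity_catalog()
  overall <- meta_pool(contrast_effects(cat24), method = "fixed")
  adj <- subgroup_pool(cat24, "adjustment", method = "fixed")
  merged <- meta_pool(rbind(adj$adjusted$effects, adj$unadjusted$effects),
                      method = "fixed")
  expect_equal(merged$y, overall$y, tolerance = 1e-12)
})
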