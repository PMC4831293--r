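#' Assign a numeric parity dose to each exposure category
#'
#' The reference (nulliparous) category anchors dose 0.  A single-valued
#' category `[k, k]` is assigned `k`; a bounded range `[a, b]` its midpoint
#' `(a + b) / 2`; an open-ended top category `[a, +)` is treated as an
#' interval of the same width `w` as the adjacent (next-lower) bounded
#' category, hence dose `a + w/2`.  When that neighbor is single-valued
#' (width 0), or no bounded neighbor exists, the width defaults to one live
#' birth (the latter case with a warning).
#'
#' @param report A `study_report`.
#' @return A data frame with one row per category (reference first):
#'   `label`, `lower`, `upper`, `dose`, `rule_used`.
#' @examples
#' doses <- assign_doses(parity_catalog()[[6]])  # 1-2, 3-4, ..., >=11 ladder
#' doses$dose
#' @export
assign_doses <- function(report) {
  cats <- report$categories
  ref <- cats[cats$is_reference, , drop = FALSE]
  non <- cats[!cats$is_reference, , drop = FALSE]
  out <- data.frame(label = c(ref$category_label, non$category_label),
                    lower = c(ref$lower, non$lower),
                    upper = c(ref$upper, non$upper),
                    dose = NA_real_, rule_used = NA_character_,
                    stringsAsFactors = FALSE)
  out$dose[1L] <- 0
  out$rule_used[1L] <- "reference_zero"
  for (i in seq_len(nrow(non))) {
    lo <- non$lower[i]; up <- non$upper[i]
    row <- i + 1L
    if (!is.na(up)) {
      if (lo == up) {
        out$dose[row] <- lo
        out$rule_used[row] <- "single_value"
      } else {
        out$dose[row] <- (lo + up) / 2
        out$rule_used[row] <- "midpoint"
      }
    } else {
      w <- if (i > 1L && !is.na(non$upper[i - 1L]))
        non$upper[i - 1L] - non$lower[i - 1L] else NA_real_
      if (is.na(w)) {
        warning("open-ended category with no bounded neighbor in report '",
                report$report_id, "'; using width 1")
        w <- 1
      } else if (w == 0) {
        w <- 1
      }
      out$dose[row] <- lo + w / 2
      out$rule_used[row] <- "open_ended"
    }
  }
  if (is.unsorted(out$dose, strictly = TRUE))
    stop("validation error in report '", report$report_id,
         "': assigned doses are not strictly increasing")
  out
}

#' Restricted cubic spline basis with three knots
#'
#' Harrell's truncated-power parameterization: `b1` is the dose itself and
#' `b2` the single nonlinear term
#' `[(d-k1)+^3 - (d-k2)+^3 (k3-k1)/(k3-k2) + (d-k3)+^3 (k2-k1)/(k3-k2)] /
#' (k3-k1)^2`, which is zero up to the first knot and linear beyond the
#' last, so the fitted curve is constrained linear in both tails.
#'
#' @param dose Numeric vector of doses.
#' @param knots Three strictly increasing knot locations.
#' @return A matrix with columns `b1`, `b2`.
#' @export
rcs_basis <- function(dose, knots) {
  if (length(knots) != 3L || is.unsorted(knots, strictly = TRUE))
    stop("domain error: knots must be three strictly increasing values")
  k1 <- knots[1L]; k2 <- knots[2L]; k3 <- knots[3L]
  pos3 <- function(x) pmax(x, 0)^3
  b2 <- (pos3(dose - k1) - pos3(dose - k2) * (k3 - k1) / (k3 - k2) +
           pos3(dose - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(b1 = dose, b2 = b2)
}

# Generalized least squares through the origin (the reference category
# anchors log RR = 0 at dose 0): beta = (X'C^-1 X)^-1 X'C^-1 y.
.gls_origin <- function(y, X, C) {
  X <- as.matrix(X)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("numeric error: singular covariance"))
  A <- crossprod(X, Ci %*% X)
  b <- crossprod(X, Ci %*% y)
  beta <- solve(A, b)
  list(beta = drop(beta), vcov = solve(A),
       rss = drop(crossprod(y, Ci %*% y) - crossprod(beta, b)))
}

#' Within-study linear dose-response slope
#'
#' Generalized least squares of the non-reference log relative risks on dose
#' with no intercept (the nulliparous reference pins the curve to the origin).
#'
#' @param report A `study_report` with at least one non-reference category.
#' @param doses Optional dose vector for the non-reference categories;
#'   defaults to [assign_doses()].
#' @param covariance A covariance matrix for the log RRs, or a method name
#'   passed to [reconstruct_covariance()].
#' @return Named vector: `slope` (log RR per live birth) and `se`.
#' @export
study_linear_trend <- function(report, doses = NULL,
                               covariance = "independent") {
  cats <- report$categories[!report$categories$is_reference, , drop = FALSE]
  if (nrow(cats) == 0L)
    stop("no-data error: report '", report$report_id,
         "' has no non-reference category")
  if (is.null(doses)) {
    d <- assign_doses(report)
    doses <- d$dose[-1L]
  }
  C <- if (is.matrix(covariance)) covariance
  else reconstruct_covariance(report, covariance)
  eff <- .effects_from_rows(cats, report_id = report$report_id)
  fit <- .gls_origin(eff$y, cbind(doses), C)
  c(slope = unname(fit$beta[1L]), se = sqrt(fit$vcov[1L, 1L]))
}

#' Dose-response trend across study reports
#'
#' Two-stage dose-response meta-analysis of summarized data.  Stage one fits
#' each report's generalized-least-squares trend through the origin on the
#' assigned doses (see [assign_doses()]), under a chosen covariance model
#' for the report's correlated log relative risks.  Stage two pools the
#' per-study linear slopes with [meta_pool()], and pools the two restricted
#' cubic spline coefficients (knots at fixed percentiles of the pooled dose
#' distribution) by fixed-effects multivariate inverse variance over the
#' reports that can identify both coefficients (at least two non-reference
#' categories, full-rank basis).  Departure from linearity is judged by a
#' likelihood-ratio-type test: the difference in generalized residual sums
#' of squares between the linear and spline fits over the spline-eligible
#' reports, referred to a chi-square with one degree of freedom, with the
#' Wald test on the nonlinear coefficient as cross-check.
#'
#' @param catalog A `parity_catalog`.
#' @param covariance `"independent"` (default), `"gl_counts"`, or
#'   `"hamling"`; see [reconstruct_covariance()].
#' @param method Pooling rule for the linear slopes, passed to
#'   [meta_pool()].
#' @param knot_quantiles Percentiles of the pooled (unweighted) non-reference
#'   dose distribution at which the three spline knots sit.
#' @return An object of class `dose_trend`: `per_study` (slope table),
#'   `pooled` (a `meta_pool` of the slopes), `rr_per_birth`, `ci`,
#'   `p_linear`, `knots`, `spline` (pooled coefficients, covariance,
#'   `lr_stat`, `p_nonlinear`, Wald cross-check, reports used).  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' tr <- dose_trend(parity_catalog())
#' tr
#' @export
dose_trend <- function(catalog, covariance = c("independent", "gl_counts",
                                               "hamling"),
                       method = "auto", knot_quantiles = c(0.1, 0.5, 0.9)) {
  covariance <- match.arg(covariance)
  stopifnot(inherits(catalog, "parity_catalog"))
  usable <- Filter(function(r) sum(!r$categories$is_reference) >= 1L, catalog)
  if (length(usable) < 2L)
    stop("insufficient-data error: dose-response needs >= 2 reports with ",
         "category ladders")
  prep <- lapply(usable, function(r) {
    d <- assign_doses(r)
    cats <- r$categories[!r$categories$is_reference, , drop = FALSE]
    list(report = r, dose = d$dose[-1L],
         y = .effects_from_rows(cats, r$report_id)$y,
         C = reconstruct_covariance(r, covariance))
  })
  per_study <- do.call(rbind, lapply(prep, function(p) {
    fit <- study_linear_trend(p$report, p$dose, p$C)
    data.frame(report_id = p$report$report_id, slope = fit[["slope"]],
               se = fit[["se"]], n_categories = length(p$dose),
               dose_min = min(p$dose), dose_max = max(p$dose),
               stringsAsFactors = FALSE)
  }))
  rownames(per_study) <- NULL
  slopes <- data.frame(report_id = per_study$report_id,
                       contrast_label = "per live birth",
                       y = per_study$slope, se = per_study$se,
                       stringsAsFactors = FALSE)
  pooled <- meta_pool(slopes, method = method)
  p_linear <- 2 * stats::pnorm(abs(pooled$y / pooled$se), lower.tail = FALSE)
  all_doses <- unlist(lapply(prep, `[[`, "dose"))
  knots <- unname(stats::quantile(all_doses, knot_quantiles, type = 7))
  # the spline stage needs more structure than the linear trend; when the
  # catalog cannot identify it, report the linear fit alone
  spline <- tryCatch(.fit_spline_stage(prep, knots), error = function(e) {
    message("spline stage not identifiable: ", conditionMessage(e))
    NULL
  })
  structure(list(
    per_study = per_study, pooled = pooled,
    rr_per_birth = pooled$rr, ci = pooled$ci, p_linear = p_linear,
    knots = knots, spline = spline, covariance = covariance
  ), class = "dose_trend")
}

.fit_spline_stage <- function(prep, knots) {
  if (length(unique(knots)) != 3L || is.unsorted(knots, strictly = TRUE))
    stop("identifiability error: knots are not three distinct dose values")
  eligible <- Filter(function(p) {
    length(p$dose) >= 2L && qr(rcs_basis(p$dose, knots))$rank == 2L
  }, prep)
  if (length(eligible) < 2L)
    stop("identifiability error: fewer than 2 reports can identify the ",
         "spline coefficients")
  if (length(unique(unlist(lapply(eligible, `[[`, "dose")))) < 3L)
    stop("identifiability error: fewer than 3 distinct dose values")
  acc <- function(model_X) {
    A <- matrix(0, ncol(model_X[[1L]]), ncol(model_X[[1L]]))
    b <- numeric(ncol(model_X[[1L]]))
    yty <- 0
    per <- vector("list", length(eligible))
    for (i in seq_along(eligible)) {
      p <- eligible[[i]]
      X <- model_X[[i]]
      Ci <- solve(p$C)
      A <- A + crossprod(X, Ci %*% X)
      b <- b + drop(crossprod(X, Ci %*% p$y))
      yty <- yty + drop(crossprod(p$y, Ci %*% p$y))
      per[[i]] <- list(beta = NULL)
    }
    beta <- solve(A, b)
    list(beta = drop(beta), vcov = solve(A), rss = yty - sum(beta * b))
  }
  X_spl <- lapply(eligible, function(p) rcs_basis(p$dose, knots))
  X_lin <- lapply(eligible, function(p) cbind(b1 = p$dose))
  fit_spl <- acc(X_spl)
  fit_lin <- acc(X_lin)
  lr <- max(0, fit_lin$rss - fit_spl$rss)
  wald_z <- unname(fit_spl$beta[2L] / sqrt(fit_spl$vcov[2L, 2L]))
  list(coef = stats::setNames(fit_spl$beta, c("b1", "b2")),
       vcov = fit_spl$vcov,
       lr_stat = lr,
       p_nonlinear = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
       wald_z = wald_z,
       p_wald = 2 * stats::pnorm(abs(wald_z), lower.tail = FALSE),
       k = length(eligible),
       report_ids = vapply(eligible, function(p) p$report$report_id,
                           character(1)))
}

#' @export
print.dose_trend <- function(x, digits = 3, ...) {
  cat(sprintf("Dose-response trend over %d reports (%s covariance)\n",
              nrow(x$per_study), x$covariance))
  cat(sprintf("  RR per live birth: %.*f (95%% CI %.*f-%.*f), p = %.*f (%s-effects)\n",
              digits, x$rr_per_birth, digits, x$ci[1], digits, x$ci[2],
              digits, x$p_linear, x$pooled$model))
  cat(sprintf("  Heterogeneity of slopes: I2 = %.1f%%, p = %.2g\n",
              x$pooled$i2, x$pooled$p_het))
  if (is.null(x$spline)) {
    cat("  Spline: not identifiable on this catalog\n")
  } else {
    cat(sprintf("  Spline (knots %.2f/%.2f/%.2f, k = %d): LR = %.*f, p-nonlinear = %.*f\n",
                x$knots[1], x$knots[2], x$knots[3], x$spline$k,
                digits, x$spline$lr_stat, digits, x$spline$p_nonlinear))
  }
  invisible(x)
}

#' @export
summary.dose_trend <- function(object, ...) {
  print(object)
  cat("\nPer-study slopes (log RR per live birth):\n")
  tab <- object$per_study
  tab[c("slope", "se")] <- lapply(tab[c("slope", "se")], round, 4)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.dose_trend <- function(object, ...) {
  if (is.null(object$spline)) return(c(slope = object$pooled$y))
  c(slope = object$pooled$y, object$spline$coef)
}

#' Predicted dose-response curve from the pooled spline
#'
#' @param object A `dose_trend` fit.
#' @param doses Doses at which to evaluate the curve; defaults to a grid in
#'   0.1-birth steps over the observed dose range.
#' @param ... Unused.
#' @return A data frame `dose`, `rr`, `lcl`, `ucl` (relative to dose 0).
#' @export
predict.dose_trend <- function(object, doses = NULL, ...) {
  if (is.null(object$spline))
    stop("no spline fit available for this catalog")
  if (is.null(doses))
    doses <- seq(0, max(object$per_study$dose_max), by = 0.1)
  X <- rcs_basis(doses, object$knots)
  eta <- drop(X %*% object$spline$coef)
  se <- sqrt(pmax(0, rowSums((X %*% object$spline$vcov) * X)))
  data.frame(dose = doses, rr = exp(eta),
             lcl = exp(eta - .Z95 * se), ucl = exp(eta + .Z95 * se))
}

#' @export
plot.dose_trend <- function(x, ...) {
  curve_tab <- predict(x)
  plot(curve_tab$dose, curve_tab$rr, type = "l", log = "y",
       xlab = "Parity (live births)", ylab = "Relative risk",
       ylim = range(curve_tab$lcl, curve_tab$ucl), ...)
  lines(curve_tab$dose, curve_tab$lcl, lty = 2)
  lines(curve_tab$dose, curve_tab$ucl, lty = 2)
  abline(h = 1, col = "grey50")
  rug(x$knots)
  invisible(x)
}
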