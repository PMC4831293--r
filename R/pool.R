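#' Pool log effects across study reports
#'
#' Fits the inverse-variance meta-analytic model to a set of log relative
#' risks.  Under `method = "fixed"` the studies are weighted by `1/se^2`;
#' under `method = "random"` the DerSimonian-Laird moment estimate of the
#' between-study variance tau^2 is added to each study variance before
#' re-weighting.  The default `method = "auto"` applies the conventional
#' switch: the fixed-effects model unless the fixed-effects I-squared
#' exceeds 50% (substantial heterogeneity), in which case the random-effects
#' model is reported.  Heterogeneity is summarized by Cochran's Q (always
#' computed from the fixed-effects weights), its chi-square p-value on k-1
#' degrees of freedom, and `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param effects A log-effect data frame (columns `y`, `se`, and optionally
#'   `report_id`, `contrast_label`), as built by [contrast_effects()] or
#'   [log_effect_from_ci()].
#' @param method `"auto"`, `"fixed"`, or `"random"`.
#' @return An object of class `meta_pool` with components `k`, `y`, `se`
#'   (pooled log RR and its standard error), `rr`, `ci` (95% interval on the
#'   ratio scale), `Q`, `df`, `p_het`, `i2`, `tau2`, `model` (the model
#'   actually reported), `weights` (normalized percentage weights under the
#'   reported model), and the input `effects`.  Methods: `print`, `summary`,
#'   `coef`, `confint`, `residuals`, `plot`.
#' @examples
#' pool <- meta_pool(contrast_effects(parity_catalog(), "parity1"),
#'                   method = "fixed")
#' pool
#' @export
meta_pool <- function(effects, method = c("auto", "fixed", "random")) {
  method <- match.arg(method)
  effects <- .check_effects(effects)
  k <- nrow(effects)
  if (method == "random" && k < 2L)
    stop("insufficient-data error: random-effects pooling needs k >= 2")
  fx <- .pool_fixed(effects$y, effects$se)
  model <- switch(method,
                  fixed = "fixed",
                  random = "random",
                  auto = if (fx$i2 > 50) "random" else "fixed")
  if (model == "random" && k >= 2L) {
    fit <- .pool_dl(effects$y, effects$se)
  } else {
    model <- "fixed"
    fit <- fx
    fit$tau2 <- 0
  }
  w <- 1 / (effects$se^2 + fit$tau2)
  structure(list(
    k = k, y = fit$y, se = fit$se,
    rr = exp(fit$y),
    ci = exp(fit$y + c(-1, 1) * .Z95 * fit$se),
    Q = fx$Q, df = fx$df, p_het = fx$p_het, i2 = fx$i2,
    tau2 = fit$tau2, model = model,
    weights = 100 * w / sum(w),
    effects = effects
  ), class = "meta_pool")
}

.check_effects <- function(effects) {
  if (!is.data.frame(effects) || !all(c("y", "se") %in% names(effects)))
    stop("effects must be a data frame with columns 'y' and 'se'")
  if (nrow(effects) == 0L) stop("no-data error: empty effect set")
  if (any(!is.finite(effects$y)) || any(!is.finite(effects$se)) ||
      any(effects$se <= 0))
    stop("domain error: every effect needs finite y and se > 0")
  if (is.null(effects$report_id))
    effects$report_id <- sprintf("effect_%d", seq_len(nrow(effects)))
  effects
}

.pool_fixed <- function(y, se) {
  w <- 1 / se^2
  yp <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yp)^2)
  df <- length(y) - 1L
  list(y = yp, se = sqrt(1 / sum(w)), Q = Q, df = df,
       p_het = if (df == 0L) 1 else stats::pchisq(Q, df, lower.tail = FALSE),
       i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
       tau2 = 0)
}

.pool_dl <- function(y, se) {
  w <- 1 / se^2
  yp <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yp)^2)
  df <- length(y) - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(y = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
}

#' @export
print.meta_pool <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled RR (%s-effects, k = %d): %.*f (95%% CI %.*f-%.*f)\n",
              x$model, x$k, digits, x$rr, digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("Heterogeneity: Q = %.*f (df = %d, p = %.*f), I2 = %.1f%%, tau2 = %.4f\n",
              digits, x$Q, x$df, digits, x$p_het, x$i2, x$tau2))
  invisible(x)
}

#' @export
summary.meta_pool <- function(object, ...) {
  tab <- forest_table(object)
  structure(list(pool = object, table = tab), class = "summary.meta_pool")
}

#' @export
print.summary.meta_pool <- function(x, ...) {
  print(x$pool)
  cat("\nStudy-level contrasts:\n")
  tab <- x$table
  tab[c("rr", "lcl", "ucl", "weight")] <-
    lapply(tab[c("rr", "lcl", "ucl", "weight")], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.meta_pool <- function(object, ...) c(log_rr = object$y)

#' @export
confint.meta_pool <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$y + c(-1, 1) * z * object$se, nrow = 1,
              dimnames = list("log_rr",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' @export
residuals.meta_pool <- function(object, ...) {
  r <- (object$effects$y - object$y) /
    sqrt(object$effects$se^2 + object$tau2)
  names(r) <- object$effects$report_id
  r
}

#' Forest-plot data table for a pooled analysis
#'
#' @param pool A `meta_pool` object.
#' @return A data frame with one row per study (`report_id`, `label`, `rr`,
#'   `lcl`, `ucl`, `weight` in percent) plus a final pooled row.
#' @export
forest_table <- function(pool) {
  stopifnot(inherits(pool, "meta_pool"))
  e <- pool$effects
  rbind(
    data.frame(report_id = e$report_id,
               label = if (is.null(e$contrast_label)) "" else e$contrast_label,
               rr = exp(e$y),
               lcl = exp(e$y - .Z95 * e$se),
               ucl = exp(e$y + .Z95 * e$se),
               weight = pool$weights, stringsAsFactors = FALSE),
    data.frame(report_id = "POOLED",
               label = sprintf("%s-effects", pool$model),
               rr = pool$rr, lcl = pool$ci[1], ucl = pool$ci[2],
               weight = 100, stringsAsFactors = FALSE)
  )
}

#' @export
plot.meta_pool <- function(x, xlab = "Relative risk", ...) {
  tab <- forest_table(x)
  n <- nrow(tab)
  ylim <- c(0.5, n + 0.5)
  xlim <- range(tab$lcl, tab$ucl)
  plot(NA, xlim = xlim, ylim = ylim, log = "x", yaxt = "n",
       xlab = xlab, ylab = "", ...)
  ys <- rev(seq_len(n))
  segments(tab$lcl, ys, tab$ucl, ys)
  points(tab$rr, ys, pch = c(rep(15, n - 1L), 18),
         cex = c(0.4 + tab$weight[-n] / 40, 1.4))
  abline(v = 1, lty = 2, col = "grey50")
  axis(2, at = ys, labels = tab$report_id, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Subgroup pooled analyses of the parous-vs-nulliparous contrast
#'
#' Stratifies the catalog by one report-level grouping, pools the parous
#' contrast within each non-empty stratum with [meta_pool()], and returns
#' one fit per stratum.  `control_type` is defined only over case-control
#' reports with population- or hospital-based controls (a pooled re-analysis
#' of several case-control studies belongs to neither stratum); unscored
#' reports are omitted from the `quality` grouping.
#'
#' @param catalog A `parity_catalog`.
#' @param by One of `"design"`, `"quality"`, `"region"`, `"control_type"`,
#'   `"adjustment"`.
#' @param method Pooling rule passed to [meta_pool()].
#' @param collapse Category-collapse method passed to [parous_contrast()].
#' @return A named list of `meta_pool` fits, classed `subgroup_pool`.
#' @export
subgroup_pool <- function(catalog, by = c("design", "quality", "region",
                                          "control_type", "adjustment"),
                          method = "auto", collapse = "iv") {
  by <- match.arg(by)
  stopifnot(inherits(catalog, "parity_catalog"))
  labels <- switch(by,
    design = vapply(catalog, function(r) r$design, character(1)),
    quality = classify_quality(catalog),
    region = vapply(catalog, function(r) r$region, character(1)),
    control_type = vapply(catalog, function(r) {
      if (r$design != "case_control") NA_character_
      else switch(r$design_detail, population_cc = "population_based",
                  hospital_cc = "hospital_based", NA_character_)
    }, character(1)),
    adjustment = ifelse(vapply(catalog, function(r) isTRUE(r$adjusted),
                               logical(1)), "adjusted", "unadjusted"))
  keep <- !is.na(labels)
  effects <- do.call(rbind, lapply(catalog[keep], parous_contrast,
                                   method = collapse))
  fits <- lapply(split(effects, labels[keep]), meta_pool, method = method)
  structure(fits, class = "subgroup_pool", grouping = by)
}

#' @export
print.subgroup_pool <- function(x, ...) {
  cat("Subgroup pooling by", attr(x, "grouping"), "\n")
  tab <- do.call(rbind, lapply(names(x), function(g) {
    p <- x[[g]]
    data.frame(stratum = g, k = p$k, rr = round(p$rr, 3),
               lcl = round(p$ci[1], 3), ucl = round(p$ci[2], 3),
               i2 = round(p$i2, 1), p_het = round(p$p_het, 3),
               model = p$model, stringsAsFactors = FALSE)
  }))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the effect set k times, omitting one report at a time, to show
#' whether any single report drives the pooled estimate.
#'
#' @param effects A log-effect data frame with at least two rows.
#' @param method Pooling rule passed to [meta_pool()].
#' @return A data frame with one row per omission: `omitted`, `k`, `rr`,
#'   `lcl`, `ucl`, `i2`, `model`.
#' @export
leave_one_out <- function(effects, method = "auto") {
  effects <- .check_effects(effects)
  if (nrow(effects) < 2L)
    stop("insufficient-data error: leave-one-out needs k >= 2")
  out <- lapply(seq_len(nrow(effects)), function(i) {
    p <- meta_pool(effects[-i, , drop = FALSE], method = method)
    data.frame(omitted = effects$report_id[i], k = p$k, rr = p$rr,
               lcl = p$ci[1], ucl = p$ci[2], i2 = p$i2, model = p$model,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
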