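# 97.5% normal quantile used throughout; printed CIs dominate any error
# beyond the sixth decimal, but 1.959964 keeps round-trips exact.
.Z95 <- stats::qnorm(0.975)

#' Convert a printed relative risk and 95% CI to a log effect
#'
#' The universal currency of pooling: the natural-log relative risk
#' `y = log(rr)` with standard error recovered from the printed interval,
#' `se = (log(ucl) - log(lcl)) / (2 * 1.959964)`, assuming the interval was
#' computed on the log scale (Woolf-type), as is standard for ratio
#' measures.
#'
#' @param rr,lcl,ucl Relative risk and its 95% confidence bounds (all > 0,
#'   `lcl <= rr <= ucl`, `lcl < ucl`).
#' @param report_id,contrast_label Optional identifiers carried along.
#' @return A one-row data frame with columns `report_id`, `contrast_label`,
#'   `y`, `se` (a "log effect").
#' @examples
#' log_effect_from_ci(2.09, 1.05, 4.15)
#' @export
log_effect_from_ci <- function(rr, lcl, ucl, report_id = "",
                               contrast_label = "") {
  if (any(c(rr, lcl, ucl) <= 0) || any(!is.finite(c(rr, lcl, ucl))))
    stop("domain error: rr, lcl, ucl must be positive and finite")
  if (lcl == ucl)
    stop("degenerate-interval error: lcl == ucl gives zero-width CI")
  if (lcl > rr || rr > ucl)
    stop("domain error: bounds must satisfy lcl <= rr <= ucl")
  data.frame(report_id = report_id, contrast_label = contrast_label,
             y = log(rr), se = (log(ucl) - log(lcl)) / (2 * .Z95),
             stringsAsFactors = FALSE)
}

# vectorized inner version of log_effect_from_ci over category rows
.effects_from_rows <- function(rows, report_id = "") {
  rr <- rows$rr; lcl <- rows$lcl; ucl <- rows$ucl
  if (any(rr <= 0 | lcl <= 0 | ucl <= 0) || anyNA(c(rr, lcl, ucl)))
    stop("domain error: rr, lcl, ucl must be positive and finite")
  if (any(lcl == ucl))
    stop("degenerate-interval error: lcl == ucl gives zero-width CI")
  if (any(lcl > rr | rr > ucl))
    stop("domain error: bounds must satisfy lcl <= rr <= ucl")
  structure(list(report_id = rep_len(report_id, length(rr)),
                 contrast_label = rows$category_label,
                 y = log(rr), se = (log(ucl) - log(lcl)) / (2 * .Z95)),
            class = "data.frame", row.names = seq_along(rr))
}

#' Collapse several exposure categories into one contrast
#'
#' When a report prints only per-category relative risks, the categories must
#' be combined into a single contrast against the shared reference group.
#' The default collapses by fixed-effects inverse variance (weights
#' `1/se^2`), which treats the category estimates as independent and ignores
#' their shared-reference correlation; `method = "hamling"` instead
#' reconstructs pseudo-counts for every category constrained to the report's
#' case/non-case margins (see [hamling_counts()]), aggregates the selected
#' categories' pseudo-cells, and recomputes the contrast and its Woolf
#' variance from the aggregated table, which does account for the shared
#' reference group.
#'
#' @param report A `study_report`.
#' @param selector Optional logical vector or predicate function over the
#'   non-reference category rows; default selects all of them.
#' @param method `"iv"` (inverse variance, default) or `"hamling"`.
#' @return A one-row log-effect data frame; `contrast_label` records the
#'   collapsed labels.
#' @export
combine_categories <- function(report, selector = NULL,
                               method = c("iv", "hamling")) {
  method <- match.arg(method)
  cats <- report$categories[!report$categories$is_reference, , drop = FALSE]
  keep <- if (is.null(selector)) rep(TRUE, nrow(cats))
  else if (is.function(selector)) vapply(seq_len(nrow(cats)), function(i)
    isTRUE(selector(cats[i, ])), logical(1))
  else as.logical(selector)
  cats <- cats[keep, , drop = FALSE]
  if (nrow(cats) == 0L)
    stop("no-data error: no category passes the selector in report '",
         report$report_id, "'")
  label <- paste(cats$category_label, collapse = "+")
  eff <- .effects_from_rows(cats, report_id = report$report_id)
  if (nrow(eff) == 1L || method == "iv") {
    if (nrow(eff) == 1L) {
      eff$contrast_label <- label
      return(eff)
    }
    w <- 1 / eff$se^2
    return(data.frame(report_id = report$report_id, contrast_label = label,
                      y = sum(w * eff$y) / sum(w), se = sqrt(1 / sum(w)),
                      stringsAsFactors = FALSE))
  }
  h <- hamling_counts(report)
  idx <- match(cats$category_label, h$label)
  if (anyNA(idx)) stop("internal: category labels not found in pseudo-counts")
  A <- sum(h$cases[idx]); B <- sum(h$noncases[idx])
  y <- log((A / B) / (h$ref_cases / h$ref_noncases))
  se <- sqrt(1 / A + 1 / B + 1 / h$ref_cases + 1 / h$ref_noncases)
  data.frame(report_id = report$report_id, contrast_label = label,
             y = y, se = se, stringsAsFactors = FALSE)
}

#' Parous-versus-nulliparous contrast for one report
#'
#' Uses the report's printed all-parous row when one exists; otherwise
#' collapses every non-reference parity category with
#' [combine_categories()].
#'
#' @inheritParams combine_categories
#' @return A one-row log-effect data frame.
#' @export
parous_contrast <- function(report, method = c("iv", "hamling")) {
  method <- match.arg(method)
  if (!is.null(report$parous_row)) {
    p <- report$parous_row
    return(log_effect_from_ci(p$rr, p$lcl, p$ucl,
                              report_id = report$report_id,
                              contrast_label = "Parous"))
  }
  combine_categories(report, method = method)
}

#' Parity-k-versus-nulliparous contrast for one report
#'
#' Returns the log effect of the category exactly equal to `k` live births
#' (parity range `[k, k]`), or `NULL` when the report prints no such
#' category.
#'
#' @param report A `study_report`.
#' @param k Parity count (integer >= 1).
#' @return A one-row log-effect data frame, or `NULL`.
#' @export
parity_contrast <- function(report, k) {
  cats <- report$categories
  hit <- !cats$is_reference & cats$lower == k & !is.na(cats$upper) &
    cats$upper == k
  if (!any(hit)) return(NULL)
  .effects_from_rows(cats[hit, , drop = FALSE], report_id = report$report_id)
}

#' Build one log effect per report for a chosen contrast
#'
#' @param catalog A `parity_catalog`.
#' @param contrast `"parous"` (default) or `"parity1"`, `"parity2"`, ...
#'   selecting reports that print a category exactly equal to k live births.
#' @param method Collapse method passed to [parous_contrast()].
#' @return A log-effect data frame, one row per eligible report.
#' @export
contrast_effects <- function(catalog, contrast = "parous",
                             method = c("iv", "hamling")) {
  method <- match.arg(method)
  stopifnot(inherits(catalog, "parity_catalog"))
  if (contrast == "parous") {
    out <- lapply(catalog, parous_contrast, method = method)
  } else if (grepl("^parity[0-9]+$", contrast)) {
    k <- as.integer(sub("^parity", "", contrast))
    out <- lapply(catalog, parity_contrast, k = k)
  } else stop("unknown contrast '", contrast, "'")
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("no-data error: no report supports contrast '", contrast, "'")
  rownames(out) <- NULL
  out
}
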