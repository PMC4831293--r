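# Pseudo-count reconstruction of the 2 x K table behind a set of printed
# category relative risks.  Two routes:
#   * Hamling-type: match each category's RR and CI exactly, constraining the
#     implied cell totals to the report's printed case/non-case margins
#     (per-category counts not needed).
#   * Greenland-Longnecker-type: match the adjusted RRs and the crude
#     per-category margins (needs per-category denominators and total cases).
# Both yield the reference-cell sizes that drive the covariance between
# log RRs sharing the reference group.

.noncase_total <- function(report) {
  if (report$design == "case_control") report$total_subjects
  else report$total_subjects - report$total_cases
}

#' Hamling pseudo-counts for a report's category ladder
#'
#' Reconstructs a pseudo 2 x K table whose category-specific odds ratios and
#' Woolf variances reproduce the printed RR/CI pairs, with the reference
#' cells chosen so that the implied totals match the report's case and
#' non-case margins.  Given candidate reference cells (a0, b0), each
#' category's cells follow in closed form from its RR and variance; the two
#' margin constraints then determine (a0, b0), solved here by a nested
#' one-dimensional root search (b0 matches the case margin for each a0, a0
#' then matches the non-case margin).  The margin system can admit two
#' nearby solutions; when it does, the one with the larger reference cells
#' is returned (the weakest implied shared-reference correlation, i.e. the
#' choice closest to treating the categories as independent).  Reports whose
#' printed margins are not exactly compatible with the intervals (rounding,
#' covariate adjustment) yield the closest achievable table and are flagged
#' `converged = FALSE`.
#'
#' @param report A `study_report` with at least one non-reference category.
#' @return A list: `label`, `cases`, `noncases` (per category),
#'   `ref_cases`, `ref_noncases`, `converged`.
#' @references Hamling et al. (2008) Statistics in Medicine 27:954-970.
#' @export
hamling_counts <- function(report) {
  cats <- report$categories[!report$categories$is_reference, , drop = FALSE]
  if (nrow(cats) == 0L)
    stop("no-data error: report '", report$report_id,
         "' has no non-reference category")
  or <- cats$rr
  v <- ((log(cats$ucl) - log(cats$lcl)) / (2 * .Z95))^2
  n_case <- report$total_cases
  n_non <- .noncase_total(report)
  if (is.na(n_case) || is.na(n_non) || n_non <= 0)
    stop("hamling pseudo-counts need total cases and non-cases for report '",
         report$report_id, "'")
  cells <- function(a0, b0) {
    ci <- v - 1 / a0 - 1 / b0
    if (any(ci <= 0)) return(NULL)
    ri <- or * a0 / b0
    B <- (1 + 1 / ri) / ci
    list(A = ri * B, B = B)
  }
  # feasibility needs 1/a0 + 1/b0 < min(v)
  a0_min <- 1.0001 / min(v)
  if (a0_min >= n_case)
    stop("convergence error: hamling system infeasible for report '",
         report$report_id, "' (margins too small for the printed precision)")
  # inner solve: b0 matching the case margin for a given a0 (monotone in b0)
  b0_for <- function(a0) {
    b0_lo <- 1.0001 / (min(v) - 1 / a0)
    f <- function(b0) {
      cl <- cells(a0, b0)
      if (is.null(cl)) return(NA_real_)
      a0 + sum(cl$A) - n_case
    }
    lo <- b0_lo
    hi <- max(2 * b0_lo, 1e3 * n_non)
    f_lo <- f(lo * 1.0001); f_hi <- f(hi)
    if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0)
      return(NA_real_)
    stats::uniroot(f, c(lo * 1.0001, hi), tol = 1e-12)$root
  }
  noncase_gap <- function(a0) {
    b0 <- b0_for(a0)
    if (is.na(b0)) return(NA_real_)
    cl <- cells(a0, b0)
    b0 + sum(cl$B) - n_non
  }
  grid <- exp(seq(log(a0_min * 1.001), log(n_case * 0.9999),
                  length.out = 201L))
  gaps <- vapply(grid, noncase_gap, numeric(1))
  ok <- which(is.finite(gaps))
  if (length(ok) == 0L) {
    # printed margins incompatible with the interval precision (adjusted
    # models, rounding): return the closest achievable table instead
    obj <- function(par) {
      cl <- cells(exp(par[1L]), exp(par[2L]))
      if (is.null(cl))
        return(1e6 + sum(pmax(0, 1 / exp(par[1L]) + 1 / exp(par[2L]) -
                                 min(v))) * 1e6)
      log((exp(par[1L]) + sum(cl$A)) / n_case)^2 +
        log((exp(par[2L]) + sum(cl$B)) / n_non)^2
    }
    start <- log(c(4, 4) / min(v))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    a0 <- exp(opt$par[1L]); b0 <- exp(opt$par[2L])
    cl <- cells(a0, b0)
    if (is.null(cl))
      stop("convergence error: hamling system infeasible for report '",
           report$report_id, "'")
    return(list(label = cats$category_label, cases = cl$A, noncases = cl$B,
                ref_cases = a0, ref_noncases = b0, converged = FALSE))
  }
  roots <- c()
  for (i in ok[-length(ok)]) {
    if (!is.finite(gaps[i + 1L])) next
    if (gaps[i] == 0) roots <- c(roots, grid[i])
    else if (gaps[i] * gaps[i + 1L] < 0)
      roots <- c(roots, stats::uniroot(noncase_gap,
                                       c(grid[i], grid[i + 1L]),
                                       tol = 1e-11)$root)
  }
  if (length(roots) > 0L) {
    a0 <- max(roots)   # largest reference cells among exact solutions
    converged <- TRUE
  } else {
    a0 <- grid[ok[which.min(abs(gaps[ok]))]]
    opt <- stats::optimize(function(x) {
      g <- noncase_gap(x)
      if (is.finite(g)) abs(g) else sqrt(.Machine$double.xmax)
    }, c(max(a0_min * 1.001, a0 / 1.5), min(n_case * 0.9999, a0 * 1.5)))
    a0 <- opt$minimum
    converged <- FALSE
  }
  b0 <- b0_for(a0)
  cl <- cells(a0, b0)
  list(label = cats$category_label, cases = cl$A, noncases = cl$B,
       ref_cases = a0, ref_noncases = b0, converged = converged)
}

#' Greenland-Longnecker fitted table for a report's category ladder
#'
#' Finds fitted case counts consistent with the printed (possibly
#' covariate-adjusted) relative risks and the crude margins: per-category
#' denominators (control counts for case-control reports, person-time for
#' cohorts) and the total case count.  With the denominators held fixed the
#' reference-cell case count follows in closed form from the total-case
#' margin, and the fitted table yields the shared-reference covariance.
#'
#' @param report A `study_report` whose categories carry `n_cases` and
#'   `n_denominator` (per-category denominators; person-time or subjects).
#' @return A list: `label`, `cases` (fitted), `denominator`, `ref_cases`,
#'   `ref_denominator`, `type` (`"odds"` or `"rate"`).
#' @references Greenland & Longnecker (1992) American Journal of
#'   Epidemiology 135:1301-1309.
#' @export
gl_counts <- function(report) {
  cats <- report$categories
  ref <- cats[cats$is_reference, , drop = FALSE]
  non <- cats[!cats$is_reference, , drop = FALSE]
  if (nrow(non) == 0L)
    stop("no-data error: report '", report$report_id,
         "' has no non-reference category")
  if (anyNA(c(cats$n_cases, cats$n_denominator)))
    stop("gl_counts needs per-category case and denominator counts for ",
         "report '", report$report_id, "'")
  or <- non$rr
  n_tot <- sum(cats$n_cases)
  # case-control: denominators are control counts and the fitted odds ratio
  # holds them fixed; cohort: denominators are person-time and the fitted
  # rate ratio scales cases against them.  Either way the reference-cell
  # case count follows in closed form from the total-case margin.
  type <- if (report$design == "case_control") "odds" else "rate"
  n0 <- ref$n_denominator
  ni <- non$n_denominator
  a0 <- n_tot / (1 + sum(or * ni / n0))
  ai <- or * a0 * ni / n0
  list(label = non$category_label, cases = ai, denominator = ni,
       ref_cases = a0, ref_denominator = n0, type = type)
}

#' Covariance of a report's non-reference log relative risks
#'
#' The printed category contrasts of one report all share its reference
#' group and are therefore positively correlated.  `"independent"` ignores
#' this and returns the diagonal of printed variances; `"gl_counts"` and
#' `"hamling"` reconstruct the correlation from a fitted/pseudo 2 x K table
#' (see [gl_counts()], [hamling_counts()]) and rescale it to the printed
#' variances, which preserves the (adjusted) precision of each contrast
#' while restoring the shared-reference covariance.
#'
#' @param report A `study_report`.
#' @param method `"independent"`, `"gl_counts"`, or `"hamling"`.
#' @return A symmetric positive-definite covariance matrix, one row/column
#'   per non-reference category (ladder order).
#' @export
reconstruct_covariance <- function(report,
                                   method = c("independent", "gl_counts",
                                              "hamling")) {
  method <- match.arg(method)
  cats <- report$categories[!report$categories$is_reference, , drop = FALSE]
  if (nrow(cats) == 0L)
    stop("no-data error: report '", report$report_id,
         "' has no non-reference category")
  se <- (log(cats$ucl) - log(cats$lcl)) / (2 * .Z95)
  n <- length(se)
  if (method == "independent" || n == 1L) {
    C <- diag(se^2, nrow = n)
  } else if (method == "gl_counts") {
    g <- gl_counts(report)
    if (g$type == "rate") {
      v_star <- 1 / g$cases + 1 / g$ref_cases
      c_star <- 1 / g$ref_cases
    } else {
      v_star <- 1 / g$cases + 1 / g$denominator + 1 / g$ref_cases +
        1 / g$ref_denominator
      c_star <- 1 / g$ref_cases + 1 / g$ref_denominator
    }
    C <- .corr_rescale(v_star, c_star, se)
  } else {
    h <- hamling_counts(report)
    v_star <- 1 / h$cases + 1 / h$noncases + 1 / h$ref_cases +
      1 / h$ref_noncases
    c_star <- 1 / h$ref_cases + 1 / h$ref_noncases
    C <- .corr_rescale(v_star, c_star, se)
  }
  dimnames(C) <- list(cats$category_label, cats$category_label)
  C
}

# Build cov from reconstructed correlation applied to printed variances;
# clamp the correlation so the result stays positive definite.
.corr_rescale <- function(v_star, c_star, se) {
  n <- length(se)
  C <- diag(se^2, nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- min(0.95, max(0, c_star / sqrt(v_star[i] * v_star[j])))
      C[i, j] <- C[j, i] <- r * se[i] * se[j]
    }
  }
  C
}
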