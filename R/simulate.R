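#' Configuration for a synthetic study catalog
#'
#' Describes a simulated literature with known truth.  The defaults mirror
#' the structure of the published literature the package ships: about two
#' dozen reports, a 14:10 case-control:cohort mix, case counts between a few
#' dozen and a couple of thousand, a nulliparous reference plus a short
#' parity ladder, and a modest between-study standard deviation on the log
#' relative-risk scale.
#'
#' @param n_studies Number of study reports to generate.
#' @param design_mix Proportion of case-control (vs cohort) reports.
#' @param true_curve The true dose-response on the log-RR scale: `"null"`
#'   (no association), `list(type = "linear", beta = ...)` (log RR per live
#'   birth), or `list(type = "spline", b = c(b1, b2), knots = c(k1, k2, k3))`.
#' @param tau2 Between-study variance of the study-level log-RR deviation.
#' @param category_template List of parity ranges `c(lower, upper)` (upper
#'   `NA` for open-ended), reference `c(0, 0)` first.
#' @param baseline_risk Cohort baseline incidence per person-year among the
#'   nulliparous.
#' @param cases_per_study Length-2 range for each study's expected case
#'   count.
#' @param selection Optional probability in (0, 1] of suppressing a study
#'   whose parous contrast is not significantly positive (one-sided
#'   publication selection); `NULL` for no selection.
#' @param seed Integer seed; all randomness in [simulate_catalog()] flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 24, design_mix = 14 / 24,
                       true_curve = "null", tau2 = 0.02,
                       category_template = list(c(0, 0), c(1, 1), c(2, 2),
                                                c(3, NA)),
                       baseline_risk = 1e-4,
                       cases_per_study = c(50, 1500),
                       selection = NULL, seed = 1L) {
  if (n_studies < 1) stop("n_studies must be >= 1")
  if (design_mix < 0 || design_mix > 1) stop("design_mix must be in [0, 1]")
  if (tau2 < 0) stop("tau2 must be >= 0")
  if (!is.null(selection) && (selection <= 0 || selection > 1))
    stop("selection must be in (0, 1]")
  if (is.character(true_curve)) true_curve <- list(type = true_curve)
  if (!true_curve$type %in% c("null", "linear", "spline"))
    stop("unknown true_curve type '", true_curve$type, "'")
  structure(list(n_studies = n_studies, design_mix = design_mix,
                 true_curve = true_curve, tau2 = tau2,
                 category_template = category_template,
                 baseline_risk = baseline_risk,
                 cases_per_study = cases_per_study,
                 selection = selection, seed = seed),
            class = "sim_config")
}

.true_log_rr <- function(curve, dose) {
  switch(curve$type,
         null = rep(0, length(dose)),
         linear = curve$beta * dose,
         spline = drop(rcs_basis(dose, curve$knots) %*% curve$b))
}

# Dose at which each template category sits, by the same assignment rule
# used for real reports.
.template_doses <- function(template) {
  lo <- vapply(template, `[`, numeric(1), 1L)
  up <- vapply(template, `[`, numeric(1), 2L)
  dose <- numeric(length(lo))
  for (i in seq_along(lo)) {
    if (!is.na(up[i])) {
      dose[i] <- (lo[i] + up[i]) / 2
    } else {
      w <- if (i > 1L && !is.na(up[i - 1L])) up[i - 1L] - lo[i - 1L] else NA
      if (is.na(w) || w == 0) w <- 1
      dose[i] <- lo[i] + w / 2
    }
  }
  dose
}

#' Generate a synthetic study catalog with known truth
#'
#' Draws `n_studies` reports under the configured design mix, true
#' dose-response curve, and between-study heterogeneity.  Case-control
#' reports draw exposure multinomially among cases and an equal number of
#' controls (case probabilities tilted by the true category odds ratios);
#' cohort reports draw Poisson case counts against per-category person-time.
#' Category relative risks and Woolf (log-normal) 95% intervals are computed
#' from the realized counts, so [log_effect_from_ci()] inverts them exactly,
#' and the counts are retained in `n_cases` / `n_denominator`.  Zero cells
#' are resampled a bounded number of times, then the study size is inflated
#' with a message.  The generating truth (per-study deviation, true curve)
#' is attached as `attr(catalog, "truth")`.
#'
#' @param config A [sim_config()].
#' @return A `parity_catalog` with a `truth` attribute; deterministic given
#'   `config$seed`.
#' @examples
#' cat_null <- simulate_catalog(sim_config(n_studies = 6, seed = 7))
#' attr(cat_null, "truth")$u
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  regions <- c("Europe", "America", "Asia", "Oceania")
  reports <- vector("list", config$n_studies)
  truth_u <- numeric(config$n_studies)
  designs <- character(config$n_studies)
  max_attempts <- 60L * config$n_studies
  attempts <- 0L
  i <- 1L
  while (i <= config$n_studies) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("selection too aggressive: could not retain ", config$n_studies,
           " studies in ", max_attempts, " draws")
    design <- if (stats::runif(1) < config$design_mix) "case_control"
    else "prospective"
    u <- stats::rnorm(1, 0, sqrt(config$tau2))
    id <- sprintf("sim_%03d", i)
    rep_i <- .simulate_report(id, design, u, config)
    if (!is.null(config$selection)) {
      eff <- parous_contrast(rep_i)
      z <- eff$y / eff$se
      nonsig <- z < stats::qnorm(0.95)  # not significantly positive
      if (nonsig && stats::runif(1) < config$selection) next
    }
    reports[[i]] <- rep_i
    truth_u[i] <- u
    designs[i] <- design
    i <- i + 1L
  }
  catalog <- structure(reports, class = "parity_catalog")
  attr(catalog, "truth") <- list(
    u = stats::setNames(truth_u,
                        vapply(reports, `[[`, character(1), "report_id")),
    design = designs, true_curve = config$true_curve, tau2 = config$tau2,
    config = config)
  catalog
}

.simulate_report <- function(id, design, u, config) {
  template <- config$category_template
  doses <- .template_doses(template)
  log_rr_true <- .true_log_rr(config$true_curve, doses) + u
  log_rr_true[1L] <- 0  # reference category defines the baseline
  rr_true <- exp(log_rr_true)
  n_cat <- length(template)
  # realistic parity mix: a fifth nulliparous, the rest spread down-weighted
  # toward high parity
  pi0 <- c(0.2, 0.8 * (0.5 ^ seq_len(n_cat - 1L)) /
             sum(0.5 ^ seq_len(n_cat - 1L)))
  target_cases <- round(stats::runif(1, config$cases_per_study[1L],
                                     config$cases_per_study[2L]))
  inflate <- 1
  for (attempt in seq_len(12L)) {
    if (attempt %in% c(6L, 9L, 12L)) {
      inflate <- inflate * 4
      message("zero cell in simulated report ", id,
              "; widening counts x", inflate)
    }
    n_cases <- target_cases * inflate
    if (design == "case_control") {
      p_case <- pi0 * rr_true / sum(pi0 * rr_true)
      a <- drop(stats::rmultinom(1, n_cases, p_case))
      b <- drop(stats::rmultinom(1, n_cases, pi0))
      if (any(a == 0) || any(b == 0)) next
      rr <- (a / a[1L]) / (b / b[1L])
      se <- sqrt(1 / a + 1 / b + 1 / a[1L] + 1 / b[1L])
      se[1L] <- 0
      denom <- b
      total_subjects <- sum(b)
    } else {
      n_subj <- n_cases / (config$baseline_risk * sum(pi0 * rr_true))
      pt <- pi0 * n_subj
      a <- stats::rpois(n_cat, config$baseline_risk * rr_true * pt)
      if (any(a == 0)) next
      rr <- (a / pt) / (a[1L] / pt[1L])
      se <- sqrt(1 / a + 1 / a[1L])
      se[1L] <- 0
      denom <- round(pt, 1)
      total_subjects <- round(n_subj)
    }
    lo <- vapply(template, `[`, numeric(1), 1L)
    up <- vapply(template, `[`, numeric(1), 2L)
    label <- ifelse(lo == 0 & !is.na(up) & up == 0, "Nulliparous",
                    ifelse(is.na(up), paste0(">=", lo),
                           ifelse(lo == up, as.character(lo),
                                  paste0(lo, "-", up))))
    is_ref <- seq_len(n_cat) == 1L
    one <- function(x) rep_len(x, n_cat)
    rows <- structure(list(
      report_id = one(id), author_year = one(paste("Synthetic", id)),
      design = one(design),
      design_detail = one(if (design == "case_control") "population_cc"
                          else "cohort"),
      region = one(sample(c("Europe", "America", "Asia", "Oceania"), 1L)),
      nos_score = one(sample(5:9, 1L)),
      adjusted = one(stats::runif(1) < 0.8),
      total_cases = one(sum(a)), total_subjects = one(total_subjects),
      category_label = label, lower = lo, upper = up,
      is_reference = is_ref,
      rr = ifelse(is_ref, 1, rr),
      lcl = ifelse(is_ref, 1, exp(log(rr) - .Z95 * se)),
      ucl = ifelse(is_ref, 1, exp(log(rr) + .Z95 * se)),
      n_cases = a, n_denominator = denom
    ), class = "data.frame", row.names = seq_len(n_cat))
    # the generator guarantees the report invariants; build directly rather
    # than re-validating every draw
    return(structure(list(
      report_id = id, author_year = rows$author_year[1L],
      design = design, design_detail = rows$design_detail[1L],
      region = rows$region[1L], nos_score = rows$nos_score[1L],
      adjusted = rows$adjusted[1L], total_cases = sum(a),
      total_subjects = total_subjects, parous_row = NULL,
      categories = rows
    ), class = "study_report"))
  }
  stop("could not avoid zero cells in simulated report ", id,
       " after bounded retries")
}
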