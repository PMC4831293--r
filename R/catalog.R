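#' @keywords internal
#' @importFrom graphics abline axis lines points segments rug
"_PACKAGE"

# CSV schema shared by read_catalog() and write_catalog(); one row per
# exposure category, report-level metadata repeated on every row.
.catalog_cols <- c(
  "report_id", "author_year", "design", "design_detail", "region",
  "nos_score", "adjusted", "total_cases", "total_subjects",
  "category_label", "lower", "upper", "is_reference", "rr", "lcl", "ucl",
  "n_cases", "n_denominator"
)

.designs        <- c("prospective", "case_control")
.design_details <- c("cohort", "nested_cc", "case_cohort", "population_cc",
                     "hospital_cc", "pooled_cc")
.regions        <- c("Europe", "America", "Asia", "Oceania", "International")

#' Read a study catalog from CSV
#'
#' Parses a catalog of summarized study reports, one row per exposure
#' category.  Each report must contain exactly one reference category
#' (nulliparous, with `rr = lcl = ucl = 1` and parity range `0--0`).  A row
#' labelled `"Parous"` is the study's own printed all-parous contrast and is
#' kept apart from the parity-category ladder.  Open-ended upper bounds
#' ("3 or more births") are encoded as an empty/`NA` `upper` field.
#'
#' @param path Path to a CSV file following the documented schema (see the
#'   package README): `report_id, author_year, design, design_detail, region,
#'   nos_score, adjusted, total_cases, total_subjects, category_label, lower,
#'   upper, is_reference, rr, lcl, ucl, n_cases, n_denominator`.
#' @return An object of class `parity_catalog`: a list of `study_report`
#'   objects.  Each `study_report` carries the report-level metadata, an
#'   optional one-row `parous_row` data frame, and a `categories` data frame
#'   (reference row first, then parity categories in ascending order).
#' @seealso [parity_catalog()] for the packaged catalog,
#'   [write_catalog()] for the inverse operation.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.catalog_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("catalog schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[.catalog_cols]
  num <- function(col) {
    x <- raw[[col]]
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0L) {
      stop("catalog parse error: row ", bad[1L] + 1L, ", column '", col,
           "': not numeric ('", x[bad[1L]], "')")
    }
    out
  }
  lgl <- function(col) {
    x <- toupper(raw[[col]])
    out <- rep(NA, nrow(raw))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad) > 0L) {
      stop("catalog parse error: row ", bad[1L] + 1L, ", column '", col,
           "': not logical ('", raw[[col]][bad[1L]], "')")
    }
    out
  }
  d <- data.frame(
    report_id      = raw$report_id,
    author_year    = raw$author_year,
    design         = raw$design,
    design_detail  = raw$design_detail,
    region         = raw$region,
    nos_score      = num("nos_score"),
    adjusted       = lgl("adjusted"),
    total_cases    = num("total_cases"),
    total_subjects = num("total_subjects"),
    category_label = raw$category_label,
    lower          = num("lower"),
    upper          = num("upper"),
    is_reference   = lgl("is_reference"),
    rr             = num("rr"),
    lcl            = num("lcl"),
    ucl            = num("ucl"),
    n_cases        = num("n_cases"),
    n_denominator  = num("n_denominator"),
    stringsAsFactors = FALSE
  )
  reports <- lapply(split(d, factor(d$report_id, levels = unique(d$report_id))),
                    .build_report)
  structure(unname(reports), class = "parity_catalog")
}

.build_report <- function(rows) {
  id <- rows$report_id[1L]
  meta_cols <- c("author_year", "design", "design_detail", "region",
                 "nos_score", "adjusted", "total_cases", "total_subjects")
  for (col in meta_cols) {
    vals <- unique(rows[[col]])
    if (length(vals[!is.na(vals)]) > 1L) {
      stop("validation error in report '", id,
           "': inconsistent metadata column '", col, "'")
    }
  }
  is_parous <- !rows$is_reference & tolower(rows$category_label) == "parous"
  parous_row <- if (any(is_parous)) rows[is_parous, , drop = FALSE] else NULL
  cats <- rows[!is_parous, , drop = FALSE]
  report <- structure(list(
    report_id      = id,
    author_year    = rows$author_year[1L],
    design         = rows$design[1L],
    design_detail  = rows$design_detail[1L],
    region         = rows$region[1L],
    nos_score      = rows$nos_score[1L],
    adjusted       = rows$adjusted[1L],
    total_cases    = rows$total_cases[1L],
    total_subjects = rows$total_subjects[1L],
    parous_row     = parous_row,
    categories     = cats
  ), class = "study_report")
  validate_report(report)
  report
}

#' Validate a single study report
#'
#' Checks the report-level and category-level invariants: known design and
#' region codes, Newcastle-Ottawa score in 0--9, exactly one reference
#' category with unit relative risk and parity range 0--0, positive and
#' correctly ordered confidence bounds (`0 < lcl <= rr <= ucl`), and
#' non-overlapping, ascending parity ranges.
#'
#' @param report A `study_report` object.
#' @return The report, invisibly, if valid; otherwise an error naming the
#'   offending report and field.
#' @export
validate_report <- function(report) {
  id <- report$report_id
  fail <- function(...) stop("validation error in report '", id, "': ", ...)
  if (!report$design %in% .designs)
    fail("unknown design '", report$design, "'")
  if (!report$design_detail %in% .design_details)
    fail("unknown design_detail '", report$design_detail, "'")
  if (!report$region %in% .regions)
    fail("unknown region '", report$region, "'")
  if (!is.na(report$nos_score) &&
      (report$nos_score < 0 || report$nos_score > 9 ||
       report$nos_score != round(report$nos_score)))
    fail("nos_score must be an integer in [0, 9]")
  cats <- report$categories
  all_rows <- rbind(cats, report$parous_row)
  if (sum(cats$is_reference) != 1L)
    fail("expected exactly one reference category, found ",
         sum(cats$is_reference))
  ref <- cats[cats$is_reference, ]
  if (any(c(ref$rr, ref$lcl, ref$ucl) != 1) || ref$lower != 0 ||
      !identical(ref$upper, 0))
    fail("reference category must have rr = lcl = ucl = 1 and range 0-0")
  nonref <- all_rows[!all_rows$is_reference, , drop = FALSE]
  for (i in seq_len(nrow(nonref))) {
    r <- nonref[i, ]
    if (any(is.na(c(r$rr, r$lcl, r$ucl))) ||
        any(c(r$rr, r$lcl, r$ucl) <= 0))
      fail("category '", r$category_label, "': rr/lcl/ucl must be positive")
    if (r$lcl > r$rr || r$rr > r$ucl)
      fail("category '", r$category_label,
           "': confidence bounds must satisfy lcl <= rr <= ucl")
    if (is.na(r$lower) || r$lower < 0)
      fail("category '", r$category_label, "': lower bound must be >= 0")
    if (!is.na(r$upper) && r$upper < r$lower)
      fail("category '", r$category_label, "': upper bound below lower bound")
  }
  ladder <- cats[!cats$is_reference, , drop = FALSE]
  if (nrow(ladder) > 1L) {
    lo <- ladder$lower
    up <- ladder$upper
    if (is.unsorted(lo, strictly = TRUE))
      fail("parity categories must be in strictly ascending order")
    for (i in seq_len(nrow(ladder) - 1L)) {
      if (is.na(up[i]))
        fail("open-ended category '", ladder$category_label[i],
             "' must be the highest category")
      if (up[i] >= lo[i + 1L])
        fail("overlapping parity ranges at category '",
             ladder$category_label[i + 1L], "'")
    }
  }
  invisible(report)
}

#' Write a study catalog to CSV
#'
#' Inverse of [read_catalog()]: emits one row per exposure category using the
#' same schema, so that `read_catalog(write_catalog(x, f))` round-trips
#' field for field.
#'
#' @param catalog A `parity_catalog` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "parity_catalog"))
  flat <- do.call(rbind, lapply(catalog, function(rep) {
    rows <- rep$categories
    if (!is.null(rep$parous_row)) {
      ref_at <- which(rows$is_reference)
      rows <- rbind(rows[seq_len(ref_at), , drop = FALSE],
                    rep$parous_row,
                    if (ref_at < nrow(rows))
                      rows[(ref_at + 1L):nrow(rows), , drop = FALSE])
    }
    rows
  }))
  utils::write.csv(flat[.catalog_cols], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' The packaged catalog of parity and thyroid-cancer study reports
#'
#' Loads the transcribed table of 24 analyzable study reports (23 published
#' studies; one study reporting separate estimates for women aged under and
#' over 45 contributes two reports) with their parity-category relative
#' risks, 95% confidence intervals, design and quality metadata.
#'
#' @return A `parity_catalog` of 24 `study_report`s.
#' @examples
#' cat24 <- parity_catalog()
#' length(cat24)
#' @export
parity_catalog <- function() {
  read_catalog(system.file("extdata", "parity_thyroid_catalog.csv",
                           package = "paritymeta", mustWork = TRUE))
}

#' Classify study quality from the Newcastle-Ottawa score
#'
#' Applies the conventional cut: reports scoring seven or more of the nine
#' Newcastle-Ottawa points are high quality, six or less low quality.
#'
#' @param x A `study_report`, a `parity_catalog`, or a numeric vector of
#'   Newcastle-Ottawa scores.
#' @return A character vector of `"high"` / `"low"` (`NA` for unscored
#'   reports).
#' @export
classify_quality <- function(x) {
  scores <- if (inherits(x, "study_report")) x$nos_score
  else if (inherits(x, "parity_catalog"))
    vapply(x, function(r) r$nos_score, numeric(1))
  else as.numeric(x)
  ifelse(is.na(scores), NA_character_, ifelse(scores >= 7, "high", "low"))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s (%s, %s, %s; NOS %s)\n",
              x$report_id, x$author_year, x$design, x$region,
              ifelse(is.na(x$nos_score), "-", x$nos_score)))
  n_cat <- sum(!x$categories$is_reference)
  cat(sprintf("  %d parity categories%s; %s cases / %s subjects\n", n_cat,
              if (!is.null(x$parous_row)) " + printed parous contrast" else "",
              x$total_cases, x$total_subjects))
  invisible(x)
}

#' @export
print.parity_catalog <- function(x, ...) {
  cat(sprintf("<parity_catalog> %d study reports (%d prospective, %d case-control)\n",
              length(x),
              sum(vapply(x, function(r) r$design == "prospective", logical(1))),
              sum(vapply(x, function(r) r$design == "case_control", logical(1)))))
  invisible(x)
}

#' @export
as.data.frame.parity_catalog <- function(x, ...) {
  do.call(rbind, lapply(x, function(rep) {
    rows <- rbind(rep$categories, rep$parous_row)
    rownames(rows) <- NULL
    rows
  }))
}

# Pull one report by id.
.get_report <- function(catalog, id) {
  hit <- which(vapply(catalog, function(r) r$report_id == id, logical(1)))
  if (length(hit) != 1L) stop("report '", id, "' not found in catalog")
  catalog[[hit]]
}
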