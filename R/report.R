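# Report drivers tying the stages together.  These are the programmatic
# front end: they accept a catalog (or a CSV path), run the requested
# analyses, and optionally write plot-ready TSV tables and a JSON manifest.

.as_catalog <- function(input) {
  if (inherits(input, "parity_catalog")) return(input)
  if (is.character(input) && length(input) == 1L) return(read_catalog(input))
  stop("input must be a parity_catalog or a CSV path")
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

.pool_record <- function(p) {
  list(k = p$k, rr = signif(p$rr, 6), lcl = signif(p$ci[1], 6),
       ucl = signif(p$ci[2], 6), i2 = signif(p$i2, 6),
       tau2 = signif(p$tau2, 6), p_het = signif(p$p_het, 6),
       model = p$model)
}

#' Pool one contrast from a catalog
#'
#' Selects the requested contrast for every eligible report (the printed
#' parous row or the category collapse for `"parous"`; only reports with an
#' exactly matching single-parity category for `"parity1"`, `"parity2"`,
#' ...), pools it, and optionally writes the forest-plot data table and a
#' JSON summary.
#'
#' @param input A `parity_catalog` or a catalog CSV path.
#' @param contrast `"parous"` or `"parityk"`; see [contrast_effects()].
#' @param model Pooling rule passed to [meta_pool()].
#' @param collapse Category-collapse method for the parous contrast.
#' @param outdir Optional output directory for `forest_<contrast>.tsv` and
#'   `pool_<contrast>.json`.
#' @return The `meta_pool` fit, invisibly when writing.
#' @export
run_pool <- function(input, contrast = "parous", model = "auto",
                     collapse = "iv", outdir = NULL) {
  catalog <- .as_catalog(input)
  pool <- meta_pool(contrast_effects(catalog, contrast, method = collapse),
                    method = model)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(forest_table(pool),
               file.path(outdir, paste0("forest_", contrast, ".tsv")))
    jsonlite::write_json(.pool_record(pool),
                         file.path(outdir, paste0("pool_", contrast, ".json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(pool))
  }
  pool
}

#' Full analysis report over a catalog
#'
#' Runs the complete pipeline in one pass: overall parous-vs-nulliparous
#' pooling, the parity-1/2/3 contrasts, all five subgroup tables,
#' leave-one-out sensitivity, both funnel-asymmetry tests, and the linear +
#' spline dose-response trend.  A failing stage is recorded under `errors`
#' in the manifest and the remaining stages still run.
#'
#' @param input A `parity_catalog` or a catalog CSV path.
#' @param outdir Optional directory; when given, writes plot-ready TSV
#'   tables (forest, funnel, leave-one-out, per-study slopes, spline curve
#'   in 0.1-birth steps) and `manifest.json` with every statistic at six
#'   significant digits.
#' @param model Pooling rule passed to [meta_pool()].
#' @param collapse Category-collapse method for the parous contrast.
#' @param covariance Covariance method for the dose-response stage.
#' @param verbose Log each stage with [message()].
#' @return The manifest, an invisible named list.
#' @export
run_full_report <- function(input, outdir = NULL, model = "auto",
                            collapse = "iv", covariance = "independent",
                            verbose = TRUE) {
  catalog <- .as_catalog(input)
  say <- function(...) if (verbose) message("[paritymeta] ", ...)
  manifest <- list(manifest_version = "1.0", errors = list())
  out_tables <- list()
  stage <- function(name, fun) {
    say("stage: ", name)
    tryCatch(fun(), error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      say("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
  }

  effects <- stage("effects", function()
    contrast_effects(catalog, "parous", method = collapse))

  overall <- stage("overall", function() {
    p <- meta_pool(effects, method = model)
    manifest$overall <<- .pool_record(p)
    out_tables[["forest_parous.tsv"]] <<- forest_table(p)
    p
  })

  stage("parity_contrasts", function() {
    # catalogs need not print every single-parity category; absent contrasts
    # are simply not reported
    manifest$parity <<- Filter(Negate(is.null),
                               lapply(stats::setNames(1:3,
                                                      paste0("parity", 1:3)),
                                      function(k) {
      tryCatch({
        eff <- contrast_effects(catalog, paste0("parity", k))
        .pool_record(meta_pool(eff, method = model))
      }, error = function(e) NULL)
    }))
  })

  stage("subgroups", function() {
    groupings <- c("design", "quality", "region", "control_type",
                   "adjustment")
    manifest$subgroups <<- lapply(stats::setNames(groupings, groupings),
                                  function(g) {
      lapply(subgroup_pool(catalog, g, method = model, collapse = collapse),
             .pool_record)
    })
  })

  stage("leave_one_out", function() {
    loo <- leave_one_out(effects, method = model)
    manifest$leave_one_out <<- list(
      min_rr = signif(min(loo$rr), 6),
      min_omitted = loo$omitted[which.min(loo$rr)],
      max_rr = signif(max(loo$rr), 6),
      max_omitted = loo$omitted[which.max(loo$rr)])
    out_tables[["leave_one_out.tsv"]] <<- loo
  })

  stage("publication_bias", function() {
    eg <- egger_test(effects)
    bg <- begg_test(effects)
    manifest$bias <<- list(
      egger = list(intercept = signif(eg$intercept, 6),
                   p = signif(eg$p_value, 6)),
      begg = list(S = bg$S, tau = signif(bg$tau, 6),
                  p = signif(bg$p_value, 6)))
    out_tables[["funnel.tsv"]] <<- funnel_table(effects)
  })

  stage("dose_response", function() {
    tr <- dose_trend(catalog, covariance = covariance, method = model)
    manifest$trend <<- list(
      k = nrow(tr$per_study),
      rr_per_birth = signif(tr$rr_per_birth, 6),
      lcl = signif(tr$ci[1], 6), ucl = signif(tr$ci[2], 6),
      p_linear = signif(tr$p_linear, 6),
      p_het = signif(tr$pooled$p_het, 6),
      model = tr$pooled$model,
      knots = signif(tr$knots, 6))
    if (!is.null(tr$spline)) {
      manifest$trend <<- c(manifest$trend, list(
        spline_b1 = signif(tr$spline$coef[["b1"]], 6),
        spline_b2 = signif(tr$spline$coef[["b2"]], 6),
        lr_stat = signif(tr$spline$lr_stat, 6),
        p_nonlinear = signif(tr$spline$p_nonlinear, 6),
        p_wald_nonlinear = signif(tr$spline$p_wald, 6)))
      out_tables[["spline_curve.tsv"]] <<- predict(tr)
    }
    out_tables[["trend_per_study.tsv"]] <<- tr$per_study
  })

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out_tables))
      .write_tsv(out_tables[[nm]], file.path(outdir, nm))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote ", length(out_tables) + 1L, " files to ", outdir)
  }
  invisible(manifest)
}
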