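#' Run the complete analysis pipeline
#'
#' Orchestrates the stages in their canonical order: ingest (or generate) a
#' cohort, rescale/center and build the polynomial design, screen for
#' influential cases, estimate the full and null models and apply the
#' chi-square likelihood-ratio gate, then -- only when the gate passes --
#' fit the whole catalogue, prune redundant models, compute Akaike weights
#' and the confidence set, and interpret the full model's response surface
#' when it is in the confidence set.  When the gate fails the pipeline stops
#' there and records the decision (the catalogue comparison is not run).
#'
#' @param data A `"cohort"`, a `"prepared_data"`, or a CSV path (read via
#'   [read_cohort()]).  Exactly one of `data` and `synth` must be given.
#' @param synth A `"synth_config"`; the cohort is generated.
#' @param mode `"cross_sectional"` (baseline outcome) or `"longitudinal"`
#'   (follow-up outcome with the baseline outcome as free covariate).
#' @param read_config Passed to [read_cohort()] when `data` is a path.
#' @param rescale Apply POMS rescaling during preparation.
#' @param alpha Level of the LR gate.
#' @param level Confidence-set level.
#' @param threshold Redundancy log-likelihood threshold.
#' @param resolution Surface grid resolution.
#' @param outdir Optional output directory; comparison table (CSV), fit
#'   results (JSON), surface grid (CSV), influence report (CSV) and a run
#'   manifest (JSON) are written there.
#' @return A list of class `"poly_analysis"`: `prepared`, `influence`,
#'   `gate`, `stopped` (gate failed), `fits`, `comparison`, `surface`
#'   (grid + RSA coefficients + shape classification, when computed),
#'   `manifest`.
#' @export
run_analysis <- function(data = NULL, synth = NULL,
                         mode = c("cross_sectional", "longitudinal"),
                         read_config = list(), rescale = TRUE,
                         alpha = 0.05, level = 0.95, threshold = 1,
                         resolution = 50L, outdir = NULL) {
  mode <- match.arg(mode)
  if (is.null(data) == is.null(synth))
    stop("supply exactly one of 'data' and 'synth'")
  if (!is.null(synth)) data <- generate_cohort(synth)
  if (is.character(data)) data <- read_cohort(data, read_config)
  prepared <- if (inherits(data, "prepared_data")) data
              else build_design(data, rescale = rescale)

  longitudinal <- mode == "longitudinal"
  outcome <- if (longitudinal) "L2" else "L1"
  influence <- flag_influential(prepared, outcome = "L1")

  catalog <- build_catalog(prepared, longitudinal = longitudinal)
  full <- fit_spec(catalog[["Full Model"]], prepared, outcome)
  null <- fit_spec(catalog[["Null Model"]], prepared, outcome)
  gate <- lr_gate(full, null, alpha = alpha)

  manifest <- list(
    package_version = as.character(utils::packageVersion("polycomp")),
    mode = mode, outcome = outcome, alpha = alpha, level = level,
    threshold = threshold, resolution = resolution,
    n_obs = nrow(prepared), n_complete = sum(!is.na(prepared[[outcome]])),
    synth_config = if (!is.null(synth)) {
      s <- unclass(synth); s$coef <- as.list(s$coef); s
    },
    range_box = as.list(range_box_of(prepared)),
    gate = gate)

  result <- list(prepared = prepared, influence = influence, gate = gate,
                 stopped = !gate$proceed, fits = NULL, comparison = NULL,
                 surface = NULL, manifest = manifest)
  class(result) <- "poly_analysis"

  if (gate$proceed) {
    fits <- fit_catalog(catalog, prepared, outcome)
    comparison <- compare_models(fits, catalog, level = level,
                                 threshold = threshold)
    result$fits <- fits
    result$comparison <- comparison
    in_set <- comparison$model[comparison$in_confidence_set]
    if ("Full Model" %in% in_set) {
      grid <- predict_grid(fits[["Full Model"]], range_box_of(prepared),
                           resolution = resolution)
      result$surface <- list(
        grid = grid,
        rsa = rsa_coefficients(fits[["Full Model"]]$coefficients),
        shape = classify_shape(fits[["Full Model"]], range_box_of(prepared)))
    }
  }

  if (!is.null(outdir)) write_analysis(result, outdir)
  result
}

write_analysis <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$influence),
                   file.path(outdir, "influence.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(result$comparison))
    export_comparison(result$comparison,
                      csv = file.path(outdir, "comparison.csv"),
                      json = file.path(outdir, "comparison.json"))
  if (!is.null(result$fits))
    fits_to_json(result$fits, file.path(outdir, "fits.json"))
  if (!is.null(result$surface))
    utils::write.csv(as.data.frame(result$surface$grid),
                     file.path(outdir, "surface_grid.csv"), row.names = FALSE)
  invisible(outdir)
}

#' @export
print.poly_analysis <- function(x, ...) {
  cat("Polynomial competing-hypotheses analysis\n")
  cat(sprintf("  outcome: %s | n = %d (complete %d)\n",
              x$manifest$outcome, x$manifest$n_obs, x$manifest$n_complete))
  nf <- sum(x$influence$flagged)
  cat(sprintf("  influence screen: %d case(s) flagged\n", nf))
  cat(sprintf("  LR gate: chi2(%d) = %.2f, p = %.4g -> %s\n",
              x$gate$df, x$gate$statistic, x$gate$p,
              if (x$gate$proceed) "proceed" else "stop"))
  if (x$stopped) {
    cat("  Gate failed: full model explains no significant variance; model\n")
    cat("  comparison not run.\n")
    return(invisible(x))
  }
  print(x$comparison)
  if (!is.null(x$surface)) {
    cat("\nResponse-surface parameters of the Full Model:\n")
    print(round(x$surface$rsa, 4))
    cat(sprintf("Shape: E %s, N %s, interaction %s\n",
                x$surface$shape$E$label, x$surface$shape$N$label,
                x$surface$shape$interaction))
  }
  invisible(x)
}
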