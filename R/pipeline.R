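#' Run the full pipeline: simulate, fit, derive, infer
#'
#' Executes the complete analysis on a synthetic study (or on a
#' pre-built [simulate_study()] bundle): fits every vulnerability
#' curve, builds per-accession mean curves, summarises the trait table,
#' and runs the inference chain for each requested response. When
#' `config$out_dir` is set, all artifacts are written there
#' (fitted-curve table, mean-curve tables, trait table, one JSON model
#' report per response, and a plain-text log with version and seed).
#'
#' @param config a [run_config()].
#' @param bundle optional `study_bundle`; by default one is simulated
#'   from [default_profiles()] with `config$seed` and `config$noise_sd`.
#' @return list with `bundle`, `fits` (data.frame), `mean_curves`
#'   (named list of `mean_vc`), `trait_summary`, `anova`, `posthoc`,
#'   `reports` (named list of `model_report`), `seed`.
#' @export
run_study <- function(config = run_config(), bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(bundle)) {
    sim_cfg <- simulation_config(noise_sd = config$noise_sd, seed = config$seed)
    bundle <- simulate_study(default_profiles(), sim_cfg)
  }
  fits <- fit_curves(bundle$series)

  grid <- seq(-0.2, min(fits$P88, na.rm = TRUE) - 0.2, by = -0.1)
  mean_curves <- lapply(split(bundle$series, vapply(bundle$series, `[[`,
                                                    "", "accession")),
                        function(sl) {
    f <- attr(fit_curves(sl), "fits")
    mean_curve(f, grid)
  })

  an <- one_way_anova(fits$P50, fits$accession)
  ph <- newman_keuls(fits$P50, fits$accession, alpha = config$alpha)

  reports <- lapply(config$responses, function(resp) {
    run_inference_chain(bundle$traits, response = resp,
                        candidates = config$candidates, alpha = config$alpha)
  })
  names(reports) <- config$responses

  out <- list(bundle = bundle, fits = fits, mean_curves = mean_curves,
              trait_summary = aggregate_by_accession(bundle$traits),
              anova = an, posthoc = ph, reports = reports,
              seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(signif10_df(fits), file.path(od, "fitted_curves.csv"),
                     row.names = FALSE)
    for (acc in names(mean_curves)) {
      utils::write.csv(signif10_df(as.data.frame(mean_curves[[acc]])),
                       file.path(od, paste0("mean_curve_", acc, ".csv")),
                       row.names = FALSE)
    }
    write_trait_csv(signif10_df(bundle$traits), file.path(od, "traits.csv"))
    for (resp in names(reports)) {
      write_report(reports[[resp]],
                   file.path(od, paste0("report_", resp, ".json")),
                   seed = config$seed)
    }
    writeLines(c(
      paste("xylemvc version:", as.character(utils::packageVersion("xylemvc"))),
      paste("R version:", R.version.string),
      paste("seed:", config$seed),
      paste("responses:", paste(config$responses, collapse = ", ")),
      paste("curves fitted:", nrow(fits)),
      paste("stems with traits:", nrow(bundle$traits))
    ), file.path(od, "run.log"))
  }
  out
}
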