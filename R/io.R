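#' Write conductance series to CSV
#'
#' One row per measurement, columns `curve_id, accession, pressure_MPa,
#' K`. The `K_max` reference is written as the first (least negative)
#' pressure row of each curve, at the reference pressure recorded in
#' `ref_pressure`.
#'
#' @param series_list list of [conductance_series()].
#' @param path output file.
#' @param ref_pressure pressure (MPa) at which the reference row is
#'   written; must be less negative than any measurement pressure.
#' @export
write_conductance_csv <- function(series_list, path, ref_pressure = -0.01) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(curve_id = s$curve_id, accession = s$accession,
               pressure_MPa = c(ref_pressure, s$points$pressure_MPa),
               K = c(s$K_max, s$points$K), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read conductance series from CSV
#'
#' Expects exactly the columns `curve_id, accession, pressure_MPa, K`
#' (comma separator, period decimal, UTF-8). Within each curve the row
#' with the least negative pressure is taken as the `K_max` reference;
#' the remaining rows are the measurement points. Validation problems
#' are reported with their line numbers.
#'
#' @param path CSV file.
#' @return named list of [conductance_series()].
#' @export
read_conductance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("curve_id", "accession", "pressure_MPa", "K")
  if (!identical(sort(names(df)), sort(need))) {
    stop("conductance CSV must have exactly the columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character(0)
  bad_p <- which(!is.finite(df$pressure_MPa) | df$pressure_MPa > 0)
  if (length(bad_p)) {
    problems <- c(problems, sprintf("line %d: pressure must be finite and <= 0 MPa",
                                    line_no[bad_p]))
  }
  bad_k <- which(!is.finite(df$K) | df$K < 0)
  if (length(bad_k)) {
    problems <- c(problems, sprintf("line %d: K must be finite and >= 0",
                                    line_no[bad_k]))
  }
  if (length(problems)) {
    stop("invalid conductance CSV:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  out <- lapply(split(df, df$curve_id), function(d) {
    d <- d[order(d$pressure_MPa, decreasing = TRUE), ]
    conductance_series(d$curve_id[1], d$accession[1],
                       d$pressure_MPa[-1], d$K[-1], K_max = d$K[1])
  })
  out[unique(df$curve_id)]
}

#' Write / read a per-stem trait table
#'
#' Columns: `stem_id, accession, <trait acronyms>, P50, P12, P88`.
#' Unknown extra columns on read are kept with a warning (they are
#' ignored by the modelling unless listed as candidates).
#'
#' @param traits trait table (data.frame).
#' @param path CSV file.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("stem_id", "accession")
  if (!all(need %in% names(df))) {
    stop("trait CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  known <- c(need, "D", "D_H", "D_MAX", "T_V", "TS_ratio", "implosion", "V_D",
             "V_G", "P_LIG", "P_FW_F_A", "T_PM", "D_PC", "A_PITH",
             "P50", "P12", "P88")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("unknown trait columns kept but not modelled by default: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df
}

#' Serialize a model report to JSON
#'
#' The JSON carries the AIC trail, coefficients, LMG shares, Pearson
#' table, seed and package version, with numbers written at 10
#' significant digits so identical runs produce byte-identical files.
#'
#' @param report a `model_report` from [run_inference_chain()].
#' @param path output JSON file.
#' @param seed seed recorded in the report (may be `NULL`).
#' @export
write_report <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "model_report"))
  payload <- list(
    software = list(package = "xylemvc",
                    version = as.character(utils::packageVersion("xylemvc"))),
    seed = seed,
    response = report$response,
    n = report$n,
    standardized = report$standardized,
    alpha = report$alpha,
    candidates = report$candidates,
    vif = as.list(signif10(report$vif)),
    aic_trail = data.frame(step = report$aic_trail$step,
                           AIC = signif10(report$aic_trail$AIC)),
    aic_final = signif10(report$aic_final),
    final_terms = report$final_terms,
    coefficients = signif10_df(report$coefficients),
    robust_weights = signif10(report$robust_weights),
    robust_converged = report$robust_converged,
    r_squared = signif10(report$r_squared),
    lmg_shares = as.list(signif10(report$lmg_shares)),
    pearson = signif10_df(report$pearson)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

signif10 <- function(x) signif(x, 10)
signif10_df <- function(d) {
  d[] <- lapply(d, function(col) if (is.numeric(col)) signif10(col) else col)
  d
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run configuration
#'
#' A serializable description of one pipeline run; round-trips through
#' YAML losslessly.
#'
#' @param responses subset of `c("P50", "P12", "P88")` to model.
#' @param candidates candidate predictor columns.
#' @param alpha significance level.
#' @param seed integer seed used for every source of randomness.
#' @param noise_sd conductance noise (see [simulation_config()]).
#' @param out_dir output directory or `NULL`.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(responses = c("P50", "P12", "P88"),
                       candidates = c("T_PM", "implosion", "T_V", "V_G",
                                      "P_LIG", "P_FW_F_A", "D_PC", "D_H"),
                       alpha = 0.05, seed = 1L, noise_sd = 0.05,
                       out_dir = NULL) {
  responses <- match.arg(responses, c("P50", "P12", "P88"), several.ok = TRUE)
  structure(list(responses = responses, candidates = candidates,
                 alpha = alpha, seed = as.integer(seed),
                 noise_sd = noise_sd, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}
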