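#' Run configuration
#'
#' Bundles the tunables shared by the fitting and selection routines.
#'
#' @param alpha Significance level for "significant improvement" in model
#'   selection (default 0.05).
#' @param bootstrap_draws Bootstrap draws for single-chemical EC50
#'   confidence intervals (default 999).
#' @param multistart Multi-start budget for the mixture optimizer
#'   (default 16).
#' @param seed Optional integer seed recorded with the configuration.
#' @param aggregation Observation unit for the mixture SS objective:
#'   `"treatment_mean"` (default) or `"replicate"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, bootstrap_draws = 999L, multistart = 16L,
                       seed = NULL,
                       aggregation = c("treatment_mean", "replicate")) {
  stopifnot(alpha > 0, alpha < 1, bootstrap_draws >= 0, multistart >= 1)
  structure(list(alpha = alpha, bootstrap_draws = as.integer(bootstrap_draws),
                 multistart = as.integer(multistart), seed = seed,
                 aggregation = match.arg(aggregation)),
            class = "run_config")
}

#' Read a quantal bioassay dataset from CSV
#'
#' Expects one row per replicate well with two concentration columns (by
#' default `conc_ag_ugL` and `conc_zno_mgL`; any pair can be named via
#' `conc_cols`), `replicate`, `n_exposed`, `n_immobile`, and optionally
#' `treatment_id`. Malformed rows are reported with their row numbers. A
#' header-only file yields an empty dataset with a warning.
#'
#' @param path CSV path.
#' @param conc_cols Names of the two concentration columns in the file.
#' @param units Length-2 unit labels attached to the dataset.
#' @return A [quantal_dataset()].
#' @export
read_dataset <- function(path, conc_cols = c("conc_ag_ugL", "conc_zno_mgL"),
                         units = c("ug/L", "mg/L")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(conc_cols %in% names(df))) {
    # fall back to generic names
    if (all(c("conc1", "conc2") %in% names(df))) conc_cols <- c("conc1", "conc2")
    else stop_raytox("CSV lacks concentration columns %s",
                     paste(conc_cols, collapse = ", "),
                     class = "raytox_schema_error")
  }
  if (nrow(df) == 0L) {
    warning("header-only file: returning an empty dataset")
    empty <- data.frame(conc1 = numeric(), conc2 = numeric(),
                        replicate = integer(), n_exposed = integer(),
                        n_immobile = integer(), treatment_id = character(),
                        percent_mobile = numeric())
    return(structure(empty, units = units,
                     class = c("quantal_dataset", "data.frame")))
  }
  names(df)[match(conc_cols, names(df))] <- c("conc1", "conc2")
  quantal_dataset(df, units = units)
}

#' Write a quantal dataset to CSV
#'
#' Inverse of [read_dataset()]: emits `treatment_id`, the two concentration
#' columns under `conc_cols` names, `replicate`, `n_exposed`, `n_immobile`.
#'
#' @param dataset A [quantal_dataset()].
#' @param path Output CSV path.
#' @param conc_cols Column names used for the two concentrations.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          conc_cols = c("conc_ag_ugL", "conc_zno_mgL")) {
  out <- data.frame(treatment_id = dataset$treatment_id,
                    c1 = dataset$conc1, c2 = dataset$conc2,
                    replicate = dataset$replicate,
                    n_exposed = dataset$n_exposed,
                    n_immobile = dataset$n_immobile,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- conc_cols
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-chemical dilution series from CSV
#'
#' Schema: `chemical`, `conc`, `unit`, `replicate`, `n_exposed`,
#' `n_immobile`. When the file holds several chemicals, `chemical` selects
#' one.
#'
#' @param path CSV path.
#' @param chemical Optional chemical name to filter on.
#' @return Data frame suitable for [fit_single()], with a `unit` attribute.
#' @export
read_single_series <- function(path, chemical = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("chemical", "conc", "unit", "replicate", "n_exposed", "n_immobile")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_raytox("CSV is missing columns: %s", paste(miss, collapse = ", "),
                class = "raytox_schema_error")
  }
  if (!is.null(chemical)) df <- df[df$chemical == chemical, , drop = FALSE]
  bad <- which(df$conc < 0)
  if (length(bad)) {
    stop_raytox("negative concentration in row(s) %s",
                paste(bad, collapse = ", "), class = "raytox_validation_error")
  }
  attr(df, "unit") <- if (nrow(df)) df$unit[1] else ""
  df
}

#' Serialize mixture parameters to JSON
#'
#' @param params A [mixture_params()].
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_params_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "mixture_params"))
  obj <- list(u_max = params$u_max, beta = params$beta, ec50 = params$ec50,
              units = params$units,
              deviation = unclass(params$deviation))
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read mixture parameters from JSON
#'
#' @param path Path to a document written by [write_params_json()].
#' @return A [mixture_params()].
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dv <- obj$deviation
  mixture_params(obj$u_max, obj$beta, obj$ec50, units = obj$units,
                 deviation = deviation_spec(dv$base, dv$kind,
                                            a = dv$a %||% 0,
                                            b_dr = dv$b_dr %||% 0,
                                            b_dl = dv$b_dl %||% 0,
                                            lead_index = dv$lead_index %||% 1L))
}

#' Report a model selection to ledger files
#'
#' Writes the selection table as CSV and JSON, a predicted-vs-observed
#' table per treatment group under the best model, and -- when the best
#' model carries a DR or DL deviation -- a switch-locus summary (the
#' toxic-unit ratio and native-unit concentration ratio at which the
#' deviation changes sign).
#'
#' @param selection A [select_model()] result.
#' @param dataset The fitted [quantal_dataset()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a list with the output paths and the in-memory tables.
#' @export
report_selection <- function(selection, dataset, dir = ".",
                             prefix = "selection") {
  stopifnot(inherits(selection, "model_selection"),
            inherits(dataset, "quantal_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- selection_table(selection)
  csv_path <- file.path(dir, paste0(prefix, "_ledger.csv"))
  json_path <- file.path(dir, paste0(prefix, "_ledger.json"))
  utils::write.csv(tab, csv_path, row.names = FALSE)

  best_fit <- selection$fits[[selection$best]]
  agg <- aggregate_treatments(dataset)
  agg$predicted <- predict_surface(best_fit$params,
                                   cbind(agg$conc1, agg$conc2),
                                   base = best_fit$base)
  agg$group <- sub("_.*$", "", agg$treatment_id)
  pv_path <- file.path(dir, paste0(prefix, "_pred_vs_obs.csv"))
  utils::write.csv(agg[, c("group", "treatment_id", "conc1", "conc2",
                           "percent_mobile", "predicted")],
                   pv_path, row.names = FALSE)

  switch_summary <- NULL
  if (best_fit$kind %in% c("DR", "DL")) {
    sl <- switch_locus(best_fit$params$deviation, best_fit$params$ec50)
    switch_summary <- unclass(sl)
  }
  stepwise <- lapply(selection$stepwise, unclass)
  jsonlite::write_json(
    list(table = tab, best = selection$best, alpha = selection$alpha,
         stepwise = stepwise, switch = switch_summary),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(ledger_csv = csv_path, ledger_json = json_path,
                 pred_vs_obs_csv = pv_path, table = tab,
                 pred_vs_obs = agg, switch = switch_summary))
}
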