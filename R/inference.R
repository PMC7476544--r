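#' Quantal bioassay dataset
#'
#' Validates and classes a replicate-level table of quantal observations.
#' Each row is one replicate well: the concentration of each mixture
#' component (zero allowed, including both-zero controls), the number of
#' animals exposed and the number immobilized after the exposure window.
#'
#' @param df Data frame with columns `conc1`, `conc2`, `replicate`,
#'   `n_exposed`, `n_immobile`, and optionally `treatment_id`.
#' @param units Length-2 character vector of concentration unit labels.
#' @return A `quantal_dataset` (a validated data frame with a `units`
#'   attribute). A `percent_mobile` column is added.
#' @export
quantal_dataset <- function(df, units = c("", "")) {
  req <- c("conc1", "conc2", "replicate", "n_exposed", "n_immobile")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_raytox("dataset is missing columns: %s", paste(miss, collapse = ", "),
                class = "raytox_schema_error")
  }
  bad <- which(df$conc1 < 0 | df$conc2 < 0)
  if (length(bad)) {
    stop_raytox("negative concentration in row(s) %s",
                paste(bad, collapse = ", "), class = "raytox_validation_error")
  }
  bad <- which(df$n_exposed <= 0 | df$n_immobile < 0 |
                 df$n_immobile > df$n_exposed)
  if (length(bad)) {
    stop_raytox("invalid counts (need 0 <= n_immobile <= n_exposed, n_exposed > 0) in row(s) %s",
                paste(bad, collapse = ", "), class = "raytox_validation_error")
  }
  if (is.null(df$treatment_id)) {
    df$treatment_id <- paste0("T", match(interaction(df$conc1, df$conc2, drop = TRUE),
                                         unique(interaction(df$conc1, df$conc2, drop = TRUE))))
  }
  df$percent_mobile <- percent_mobile(df$n_exposed, df$n_immobile)
  structure(as.data.frame(df), units = units,
            class = c("quantal_dataset", "data.frame"))
}

#' Aggregate a dataset to treatment means
#'
#' Averages replicate-level percent-mobile values within each treatment
#' (unique concentration pair). Treatment means are the default observation
#' unit for mixture-model fitting and for the likelihood-ratio sample size.
#'
#' @param dataset A [quantal_dataset()].
#' @return Data frame with one row per treatment: `treatment_id`, `conc1`,
#'   `conc2`, `percent_mobile` (mean), `n_replicates`.
#' @export
aggregate_treatments <- function(dataset) {
  key <- interaction(dataset$conc1, dataset$conc2, drop = TRUE)
  idx <- !duplicated(key)
  out <- data.frame(
    treatment_id = dataset$treatment_id[idx],
    conc1 = dataset$conc1[idx],
    conc2 = dataset$conc2[idx],
    percent_mobile = as.numeric(tapply(dataset$percent_mobile, key, mean)[as.character(key[idx])]),
    n_replicates = as.integer(table(key)[as.character(key[idx])]),
    stringsAsFactors = FALSE)
  out[order(out$conc1, out$conc2), , drop = FALSE]
}

#' Sum-of-squares objective for a mixture surface on a dataset
#'
#' SS = sum over observation units of (observed percent mobile - predicted
#' percent mobile)^2. By default the observation unit is the treatment mean;
#' single-chemical and control treatments are predicted by the corresponding
#' marginal log-logistic curve (to which both surfaces reduce exactly).
#'
#' @param params A [mixture_params()].
#' @param dataset A [quantal_dataset()].
#' @param base `"CA"` or `"IA"`.
#' @param aggregation `"treatment_mean"` (default) or `"replicate"`.
#' @return The scalar sum of squared residuals (percent^2 scale).
#' @export
objective_ss <- function(params, dataset, base = params$deviation$base,
                         aggregation = c("treatment_mean", "replicate")) {
  aggregation <- match.arg(aggregation)
  obs <- if (aggregation == "treatment_mean") aggregate_treatments(dataset)
         else dataset
  pred <- predict_surface(params, cbind(obs$conc1, obs$conc2), base = base)
  sum((obs$percent_mobile - pred)^2)
}

# deviation parameter layout per model kind
k_params_for <- function(kind) {
  switch(kind, NONE = 5L, SA = 6L, DR = 7L, DL = 7L)
}

#' Simultaneous least-squares fit of one mixture model
#'
#' Jointly estimates the shared control response `u_max`, both slopes, both
#' EC50s and the deviation parameters of the requested model from a dataset
#' containing single-chemical series and mixture rays, by minimizing the
#' treatment-mean sum of squared residuals (Gaussian maximum likelihood).
#' Multi-start: the two marginal single-chemical fits seed the shared
#' parameters; deviation parameters start at 0 and +/-1; the remaining
#' starts are Latin-hypercube perturbations.
#'
#' @param dataset A [quantal_dataset()].
#' @param base `"CA"` or `"IA"`.
#' @param kind Deviation kind: `"NONE"`, `"SA"`, `"DR"` or `"DL"`.
#' @param config A [run_config()].
#' @param lead_index Chemical carrying the dose-ratio coefficient.
#' @return Object of class `mixture_fit`: `params` ([mixture_params()]),
#'   `ss`, `n_obs` (observation units entering SS), `k_params`, `converged`.
#' @export
fit_model <- function(dataset, base = c("CA", "IA"),
                      kind = c("NONE", "SA", "DR", "DL"),
                      config = run_config(), lead_index = 1L) {
  base <- match.arg(base)
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "quantal_dataset"))
  obs <- if (config$aggregation == "treatment_mean") aggregate_treatments(dataset)
         else dataset[, c("treatment_id", "conc1", "conc2", "percent_mobile")]
  m <- cbind(obs$conc1, obs$conc2)
  pm <- obs$percent_mobile
  n_mix <- sum(m[, 1] > 0 & m[, 2] > 0)
  if (n_mix < 2L) {
    stop_raytox("dataset needs mixture treatments to fit a surface (found %d)",
                n_mix, class = "raytox_design_error")
  }

  # marginal single-chemical fits seed the shared parameters
  seed_fit <- function(chem) {
    other <- 3L - chem
    rows <- dataset[[paste0("conc", other)]] == 0
    d <- data.frame(conc = dataset[[paste0("conc", chem)]][rows],
                    replicate = dataset$replicate[rows],
                    n_exposed = dataset$n_exposed[rows],
                    n_immobile = dataset$n_immobile[rows])
    tryCatch(fit_single(d, n_starts = 8L, n_boot = 0L)$params,
             error = function(e) NULL)
  }
  s1 <- seed_fit(1L); s2 <- seed_fit(2L)
  u0 <- mean(c(s1$u_max %||% 95, s2$u_max %||% 95))
  b0 <- c(s1$beta %||% 2, s2$beta %||% 2)
  cpos1 <- m[m[, 1] > 0, 1]; cpos2 <- m[m[, 2] > 0, 2]
  e0 <- c(s1$ec50 %||% stats::median(cpos1), s2$ec50 %||% stats::median(cpos2))

  n_dev <- k_params_for(kind) - 5L
  spec0 <- deviation_spec(base, kind, lead_index = lead_index)
  obj <- function(th) {
    spec <- spec0
    if (n_dev >= 1L) spec$a <- th[6]
    if (n_dev == 2L) {
      if (kind == "DR") spec$b_dr <- th[7] else spec$b_dl <- th[7]
    }
    u <- th[1]; beta <- exp(th[2:3]); ec50 <- exp(th[4:5])
    pred <- if (base == "CA") ca_solve(u, beta, ec50, spec, m)
            else ia_eval(u, beta, ec50, spec, m)
    sum((pm - pred)^2)
  }

  core <- c(u0, log(b0), log(e0))
  dev_starts <- switch(as.character(n_dev),
    "0" = list(numeric(0)),
    "1" = list(0, 1, -1),
    "2" = list(c(0, 0), c(-1, 1), c(1, -1), c(1, 1), c(-1, -1)))
  starts <- lapply(dev_starts, function(d) c(core, d))
  n_extra <- max(0L, config$multistart - length(starts))
  if (n_extra > 0L) {
    cube <- with_preserved_seed(sum(utf8ToInt("mixture-starts")),
                                lhs::randomLHS(n_extra, 5L + n_dev))
    for (i in seq_len(n_extra)) {
      pert <- c(80 + 20 * cube[i, 1],
                log(b0) + (cube[i, 2:3] - 0.5) * 2,
                log(e0) + (cube[i, 4:5] - 0.5) * 2,
                if (n_dev) (cube[i, 5L + seq_len(n_dev)] - 0.5) * 6)
      starts[[length(starts) + 1L]] <- pert
    }
  }

  lo <- c(1, log(0.05), log(0.05),
          log(min(cpos1) / 50), log(min(cpos2) / 50),
          rep(-30, n_dev))
  hi <- c(100, log(50), log(50),
          log(max(cpos1) * 50), log(max(cpos2) * 50),
          rep(30, n_dev))

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(s, obj, lower = lo, upper = hi,
                    control = list(abs.tol = 1e-10, rel.tol = 1e-12,
                                   eval.max = 600, iter.max = 400)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) best <- res
  }
  if (is.null(best)) {
    stop_raytox("all optimizer starts failed for %s-%s", base, kind,
                class = "raytox_fit_error")
  }
  th <- best$par
  spec <- spec0
  if (n_dev >= 1L) spec$a <- th[6]
  if (n_dev == 2L) { if (kind == "DR") spec$b_dr <- th[7] else spec$b_dl <- th[7] }
  units <- attr(dataset, "units") %||% c("", "")
  structure(list(
    params = mixture_params(th[1], exp(th[2:3]), exp(th[4:5]), units = units,
                            deviation = spec),
    base = base, kind = kind,
    ss = best$objective, n_obs = nrow(obs),
    k_params = k_params_for(kind),
    converged = best$convergence == 0),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  lab <- if (x$kind == "NONE") x$base else paste0(x$base, "-", x$kind)
  cat(sprintf("Mixture fit %s: SS = %.4g on %d observation units (%d free parameters)%s\n",
              lab, x$ss, x$n_obs, x$k_params,
              if (x$converged) "" else " [not converged]"))
  print(x$params)
  invisible(x)
}

#' Likelihood-ratio chi-squared test between nested mixture fits
#'
#' Under Gaussian errors, minus twice the log-likelihood ratio of two nested
#' least-squares fits on the same n observation units is
#' \deqn{\chi^2 = n \ln(SS_{reduced} / SS_{extended}),}
#' referred to a chi-squared distribution with df = number of added
#' parameters. `SS_extended > SS_reduced` (possible only through optimizer
#' slack) clamps the statistic to 0.
#'
#' @param fit_reduced,fit_extended Nested [fit_model()] results on the same
#'   dataset (equal `n_obs`).
#' @return List of class `lrt_result` with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_extended) {
  stopifnot(inherits(fit_reduced, "mixture_fit"),
            inherits(fit_extended, "mixture_fit"))
  if (fit_reduced$n_obs != fit_extended$n_obs) {
    stop_raytox("fits use different observation counts (%d vs %d)",
                fit_reduced$n_obs, fit_extended$n_obs,
                class = "raytox_usage_error")
  }
  df <- fit_extended$k_params - fit_reduced$k_params
  if (df < 1L) {
    stop_raytox("extended model must add at least one parameter",
                class = "raytox_usage_error")
  }
  chi2 <- max(0, fit_reduced$n_obs * log(fit_reduced$ss / fit_extended$ss))
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

model_grid <- function() {
  data.frame(base = rep(c("CA", "IA"), each = 4L),
             kind = rep(c("NONE", "SA", "DR", "DL"), 2L),
             stringsAsFactors = FALSE)
}

model_label <- function(base, kind) {
  ifelse(kind == "NONE", base, paste0(base, "-", kind))
}

#' Fit and compare the full nested family of mixture models
#'
#' Fits all eight models (reference, S/A, DR, DL for each of CA and IA),
#' tests each extension against its base reference model (df = number of
#' added parameters: 1 for S/A, 2 for DR and DL), and selects the best
#' model: the significant extension (p < alpha) with the lowest SS if any
#' extension is significant, otherwise the reference model with the lower
#' SS. The stepwise S/A-to-DR and S/A-to-DL comparisons are also reported.
#'
#' @param dataset A [quantal_dataset()].
#' @param config A [run_config()] (significance level `alpha`, multi-start
#'   budget, aggregation).
#' @param lead_index Chemical carrying the dose-ratio coefficient.
#' @return Object of class `model_selection`: `fits` (named list of
#'   [fit_model()] results), `tests` (LRT of each extension vs its
#'   reference), `stepwise` (S/A vs DR/DL tests), `best` (model label),
#'   `alpha`, `errors` (fit failures, if any).
#' @export
select_model <- function(dataset, config = run_config(), lead_index = 1L) {
  grid <- model_grid()
  fits <- list(); errors <- list()
  for (i in seq_len(nrow(grid))) {
    lab <- model_label(grid$base[i], grid$kind[i])
    res <- tryCatch(
      fit_model(dataset, grid$base[i], grid$kind[i], config, lead_index),
      error = function(e) e)
    if (inherits(res, "error")) errors[[lab]] <- conditionMessage(res)
    else fits[[lab]] <- res
  }
  tests <- list(); stepwise <- list()
  for (b in c("CA", "IA")) {
    if (is.null(fits[[b]])) next
    for (k in c("SA", "DR", "DL")) {
      lab <- model_label(b, k)
      if (!is.null(fits[[lab]])) {
        tests[[lab]] <- likelihood_ratio_test(fits[[b]], fits[[lab]])
      }
    }
    salab <- model_label(b, "SA")
    for (k in c("DR", "DL")) {
      lab <- model_label(b, k)
      if (!is.null(fits[[salab]]) && !is.null(fits[[lab]])) {
        stepwise[[paste0(salab, "->", lab)]] <-
          likelihood_ratio_test(fits[[salab]], fits[[lab]])
      }
    }
  }

  ext <- names(tests)
  sig <- ext[vapply(tests, function(t) t$p < config$alpha, logical(1))]
  best <- if (length(sig)) {
    sig[which.min(vapply(sig, function(l) fits[[l]]$ss, numeric(1)))]
  } else {
    refs <- intersect(c("CA", "IA"), names(fits))
    refs[which.min(vapply(refs, function(l) fits[[l]]$ss, numeric(1)))]
  }
  structure(list(fits = fits, tests = tests, stepwise = stepwise,
                 best = best, alpha = config$alpha, errors = errors),
            class = "model_selection")
}

#' Tabulate a model selection in summary-table form
#'
#' One row per fitted model with the shared parameters, deviation
#' parameters, SS and the LRT against the base reference.
#'
#' @param selection A [select_model()] result.
#' @return Data frame with columns `model`, `base`, `kind`, `C_max`,
#'   `beta1`, `beta2`, `ec50_1`, `ec50_2`, `a`, `b_dr`, `b_dl`, `ss`,
#'   `chi2`, `df`, `p`, `best`.
#' @export
selection_table <- function(selection) {
  stopifnot(inherits(selection, "model_selection"))
  rows <- lapply(names(selection$fits), function(lab) {
    f <- selection$fits[[lab]]
    d <- f$params$deviation
    t <- selection$tests[[lab]]
    data.frame(model = lab, base = f$base, kind = f$kind,
               C_max = f$params$u_max,
               beta1 = f$params$beta[1], beta2 = f$params$beta[2],
               ec50_1 = f$params$ec50[1], ec50_2 = f$params$ec50[2],
               a = if (f$kind == "NONE") NA_real_ else d$a,
               b_dr = if (f$kind == "DR") d$b_dr else NA_real_,
               b_dl = if (f$kind == "DL") d$b_dl else NA_real_,
               ss = f$ss,
               chi2 = if (is.null(t)) NA_real_ else t$chi2,
               df = if (is.null(t)) NA_integer_ else t$df,
               p = if (is.null(t)) NA_real_ else t$p,
               best = lab == selection$best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.model_selection <- function(x, ...) {
  tab <- selection_table(x)
  cat("Nested mixture-model selection\n")
  print(format(tab[, c("model", "ss", "chi2", "df", "p")], digits = 4),
        row.names = FALSE)
  cat(sprintf("Best model at alpha = %.3g: %s\n", x$alpha, x$best))
  if (length(x$errors)) {
    cat("Fit failures:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
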