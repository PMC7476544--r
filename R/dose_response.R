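#' Log-logistic dose-response parameters
#'
#' Container for one chemical's three-parameter log-logistic curve on the
#' percent-mobile scale,
#' \deqn{y(c) = u_{max} / (1 + (c/EC_{50})^\beta),}
#' with the lower asymptote fixed at 0 (full immobilization achievable).
#' `u_max` is the fitted control response (the quantity tabulated as
#' \eqn{C_{max}} in mixture-model summaries; the two names refer to the same
#' parameter), `beta` the slope, and `ec50` the median-effect concentration in
#' the chemical's native unit.
#'
#' @param u_max Percent mobile in the control group, in (0, 100].
#' @param beta Dimensionless slope, > 0.
#' @param ec50 Median-effect concentration, > 0, in `unit`.
#' @param unit Free-text unit label (e.g. `"ug/L"`, `"mg/L"`).
#' @return An object of class `loglogistic_params`.
#' @examples
#' p <- loglogistic_params(u_max = 99.12, beta = 2.38, ec50 = 0.91, unit = "ug/L")
#' predict_mobility(p, c(0, 0.91, 1.82))
#' @export
loglogistic_params <- function(u_max, beta, ec50, unit = "") {
  stopifnot(is.numeric(u_max), length(u_max) == 1L, u_max > 0, u_max <= 100,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(ec50), length(ec50) == 1L, ec50 > 0)
  structure(list(u_max = u_max, beta = beta, ec50 = ec50, unit = unit),
            class = "loglogistic_params")
}

#' @export
print.loglogistic_params <- function(x, ...) {
  cat(sprintf("Log-logistic curve: u_max = %.4g%%, beta = %.4g, EC50 = %.4g %s\n",
              x$u_max, x$beta, x$ec50, x$unit))
  invisible(x)
}

#' Predicted percent mobile at a concentration
#'
#' Evaluates the log-logistic curve. At `c = 0` the prediction is exactly
#' `u_max`; at `c = ec50` it is exactly `u_max / 2`; the curve is strictly
#' decreasing in concentration.
#'
#' @param params A [loglogistic_params()] object.
#' @param conc Concentration(s) in the chemical's native unit, >= 0.
#' @return Numeric vector of predicted percent mobile, in (0, `u_max`].
#' @export
predict_mobility <- function(params, conc) {
  stopifnot(inherits(params, "loglogistic_params"), is.numeric(conc))
  if (any(conc < 0)) {
    stop_raytox("negative concentration supplied to predict_mobility",
                class = "raytox_domain_error")
  }
  params$u_max / (1 + (conc / params$ec50)^params$beta)
}

#' Effective concentration for a given effect level
#'
#' Inverts the log-logistic curve: the concentration producing an
#' `effect_percent`% reduction of mobility relative to the control, i.e.
#' \eqn{EC_x = EC_{50} (x/(100-x))^{1/\beta}}. `effect_percent = 50` returns
#' `ec50` exactly.
#'
#' @param params A [loglogistic_params()] object.
#' @param effect_percent Effect level x, in the open interval (0, 100).
#' @return Concentration(s) in the chemical's native unit.
#' @export
effective_concentration <- function(params, effect_percent) {
  stopifnot(inherits(params, "loglogistic_params"), is.numeric(effect_percent))
  if (any(effect_percent <= 0 | effect_percent >= 100)) {
    stop_raytox("effect_percent must lie strictly between 0 and 100",
                class = "raytox_domain_error")
  }
  params$ec50 * (effect_percent / (100 - effect_percent))^(1 / params$beta)
}

# Sum of squared residuals of a candidate (u_max, beta, ec50) on
# replicate-level percent-mobile observations.
ss_single <- function(u_max, beta, ec50, conc, pm) {
  pred <- u_max / (1 + (conc / ec50)^beta)
  sum((pm - pred)^2)
}

#' Least-squares fit of a single-chemical log-logistic curve
#'
#' Fits (`u_max`, `beta`, `ec50`) by minimizing the sum of squared residuals
#' on replicate-level percent-mobile values, using bounded multi-start local
#' optimization (Latin-hypercube starting points over `beta` in \[0.1, 20\],
#' `ec50` in \[min conc / 10, max conc * 10\], `u_max` in \[80, 100\]).
#' Confidence intervals for the EC50 are obtained by a nonparametric
#' bootstrap that resamples replicate wells within each treatment and refits.
#'
#' @param data Data frame with columns `conc`, `replicate`, `n_exposed`,
#'   `n_immobile` (one row per replicate well).
#' @param unit Unit label attached to the fitted EC50.
#' @param n_starts Number of multi-starts (>= 1; default 16).
#' @param n_boot Bootstrap draws for the EC50 percentile interval
#'   (default 999; `0` skips the bootstrap and returns `NA` bounds).
#' @param ci_level Confidence level for the bootstrap interval.
#' @return An object of class `single_fit`: list with `params`
#'   ([loglogistic_params()]), `ss`, `ci_ec50` (length-2 vector), `n_obs`,
#'   `n_boot`.
#' @export
fit_single <- function(data, unit = "", n_starts = 16L, n_boot = 999L,
                       ci_level = 0.95) {
  req <- c("conc", "n_exposed", "n_immobile")
  if (!all(req %in% names(data))) {
    stop_raytox("single-chemical data needs columns %s",
                paste(req, collapse = ", "), class = "raytox_schema_error")
  }
  if (is.null(data$replicate)) data$replicate <- seq_len(nrow(data))
  conc <- data$conc
  pm <- percent_mobile(data$n_exposed, data$n_immobile)

  n_levels <- length(unique(conc[conc > 0]))
  if (n_levels < 3L) {
    stop_raytox("need >= 3 distinct nonzero concentrations (got %d)",
                n_levels, class = "raytox_design_error")
  }
  if (!any(conc == 0)) {
    warning("no control (zero-concentration) observations; u_max fitted unconstrained")
  }
  if (length(unique(pm)) == 1L) {
    stop_raytox("all responses identical; dose-response parameters are not identifiable",
                class = "raytox_identifiability_error")
  }

  est <- fit_single_core(conc, pm, n_starts)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    groups <- split(seq_len(nrow(data)), conc)
    ec50s <- with_preserved_seed(sum(utf8ToInt("bootstrap")), {
      vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(groups, function(g) g[sample.int(length(g), length(g), replace = TRUE)]),
                      use.names = FALSE)
        bfit <- tryCatch(
          fit_single_core(conc[idx], pm[idx], n_starts = 1L, start = est$par),
          error = function(e) NULL)
        if (is.null(bfit)) NA_real_ else bfit$par[["ec50"]]
      }, numeric(1))
    })
    alpha <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(ec50s, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(list(
    params = loglogistic_params(est$par[["u_max"]], est$par[["beta"]],
                                est$par[["ec50"]], unit = unit),
    ss = est$ss, ci_ec50 = ci, n_obs = nrow(data), n_boot = n_boot),
    class = "single_fit")
}

# Core optimizer: bounded multi-start nlminb on (u_max, log beta, log ec50).
fit_single_core <- function(conc, pm, n_starts, start = NULL) {
  cpos <- conc[conc > 0]
  lo <- c(u_max = 1, lb = log(0.05), le = log(min(cpos) / 10))
  hi <- c(u_max = 100, lb = log(50), le = log(max(cpos) * 10))
  obj <- function(th) ss_single(th[1], exp(th[2]), exp(th[3]), conc, pm)

  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- c(start[["u_max"]], log(start[["beta"]]), log(start[["ec50"]]))
  } else {
    # data-driven start: control mean for u_max, level nearest 50% for ec50
    u0 <- if (any(conc == 0)) mean(pm[conc == 0]) else max(pm)
    u0 <- min(max(u0, 50), 100)
    lvl <- sort(unique(cpos))
    mresp <- vapply(lvl, function(l) mean(pm[conc == l]), numeric(1))
    e0 <- lvl[which.min(abs(mresp - u0 / 2))]
    starts[[1]] <- c(u0, log(2), log(e0))
    if (n_starts > 1L) {
      cube <- with_preserved_seed(sum(utf8ToInt("single-starts")),
                                  lhs::randomLHS(n_starts - 1L, 3L))
      for (i in seq_len(nrow(cube))) {
        starts[[i + 1L]] <- c(
          80 + 20 * cube[i, 1],
          log(0.1) + cube[i, 2] * (log(20) - log(0.1)),
          log(min(cpos) / 10) + cube[i, 3] * (log(max(cpos) * 10) - log(min(cpos) / 10)))
      }
    }
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::nlminb(s, obj, lower = lo, upper = hi,
                    control = list(abs.tol = 1e-10, rel.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) best <- res
  }
  if (is.null(best)) {
    stop_raytox("all optimizer starts failed", class = "raytox_fit_error")
  }
  list(par = c(u_max = best$par[[1]], beta = exp(best$par[[2]]),
               ec50 = exp(best$par[[3]])),
       ss = best$objective)
}

#' @export
print.single_fit <- function(x, ...) {
  cat("Single-chemical log-logistic fit\n")
  print(x$params)
  cat(sprintf("  SS = %.4g on %d replicate observations\n", x$ss, x$n_obs))
  if (!anyNA(x$ci_ec50)) {
    cat(sprintf("  EC50 bootstrap CI: [%.4g, %.4g] (%d draws)\n",
                x$ci_ec50[1], x$ci_ec50[2], x$n_boot))
  }
  invisible(x)
}
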