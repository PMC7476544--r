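#' Ray-design specification for a binary mixture bioassay
#'
#' Describes the experimental layout of an acute immobilization study on a
#' toxic-unit ray design: single-chemical dilution series for each
#' component, plus binary mixture rays at fixed toxic-unit ratios diluted
#' across a series of total-toxic-unit levels. Defaults reproduce the study
#' layout this package models: 6 log-spaced AgNO3 levels on 0.5-2.5 ug/L and
#' 7 log-spaced ZnO levels on 0.04-20 mg/L, three rays at TU ratios 5:5,
#' 3:7 and 7:3, seven log-spaced total-TU levels from 0.0625 to 2.0, eight
#' replicate wells of five animals per treatment, and one shared control --
#' 35 treatments in all.
#'
#' @param single_levels List of two numeric vectors: the nonzero
#'   single-chemical concentration levels for chemical 1 and chemical 2.
#' @param ray_ratios List of length-2 TU-fraction vectors, each summing to 1.
#' @param sum_tu_levels Total toxic-unit levels along each ray.
#' @param n_replicates Replicate wells per treatment.
#' @param n_per_replicate Animals per well.
#' @param include_control Include a both-zero control treatment.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(single_levels = list(lseq(0.5, 2.5, 6), lseq(0.04, 20, 7)),
                        ray_ratios = list(c(0.5, 0.5), c(0.3, 0.7), c(0.7, 0.3)),
                        sum_tu_levels = lseq(0.0625, 2, 7),
                        n_replicates = 8L, n_per_replicate = 5L,
                        include_control = TRUE) {
  stopifnot(length(single_levels) == 2L,
            all(vapply(single_levels, function(x) all(x > 0), logical(1))),
            all(vapply(ray_ratios, function(r) length(r) == 2L &&
                         abs(sum(r) - 1) < 1e-12 && all(r > 0), logical(1))),
            all(sum_tu_levels > 0), n_replicates >= 1L, n_per_replicate >= 1L)
  structure(list(single_levels = single_levels, ray_ratios = ray_ratios,
                 sum_tu_levels = sum_tu_levels,
                 n_replicates = as.integer(n_replicates),
                 n_per_replicate = as.integer(n_per_replicate),
                 include_control = isTRUE(include_control)),
            class = "design_spec")
}

#' Expand a design into treatment concentration pairs
#'
#' Mixture treatments are laid out along rays: at TU ratio (z1, z2) and
#' total toxic unit S, chemical i receives C_i = z_i * S * EC50_i. Single
#' chemical and control treatments come directly from the spec. The default
#' spec yields 21 mixture + 6 + 7 single + 1 control = 35 treatments.
#'
#' @param spec A [design_spec()].
#' @param ec50s Length-2 vector converting toxic units to concentrations.
#' @return Data frame: `treatment_id`, `type` (`control`/`single1`/
#'   `single2`/`mixture`), `ray` (label or `NA`), `sum_tu`, `conc1`, `conc2`.
#' @export
build_design <- function(spec, ec50s) {
  stopifnot(inherits(spec, "design_spec"), length(ec50s) == 2L, all(ec50s > 0))
  rows <- list()
  if (spec$include_control) {
    rows[[1]] <- data.frame(treatment_id = "CTRL", type = "control",
                            ray = NA_character_, sum_tu = 0,
                            conc1 = 0, conc2 = 0, stringsAsFactors = FALSE)
  }
  for (chem in 1:2) {
    lv <- spec$single_levels[[chem]]
    if (length(lv)) {
      d <- data.frame(
        treatment_id = sprintf("S%d_L%d", chem, seq_along(lv)),
        type = paste0("single", chem),
        ray = NA_character_,
        sum_tu = lv / ec50s[chem],
        conc1 = if (chem == 1L) lv else 0,
        conc2 = if (chem == 2L) lv else 0,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- d
    }
  }
  for (r in seq_along(spec$ray_ratios)) {
    z <- spec$ray_ratios[[r]]
    s <- spec$sum_tu_levels
    rows[[length(rows) + 1L]] <- data.frame(
      treatment_id = sprintf("MIX%d_L%d", r, seq_along(s)),
      type = "mixture",
      ray = sprintf("MIX%d", r),
      sum_tu = s,
      conc1 = z[1] * s * ec50s[1],
      conc2 = z[2] * s * ec50s[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a quantal bioassay dataset from a known surface
#'
#' For every treatment in the design and every replicate well, draws the
#' number of immobilized animals as Binomial(n_per_replicate, 1 - y/100),
#' where y is the percent mobile predicted by the supplied mixture surface
#' (single-chemical treatments fall on the marginal curves). The same seed
#' always reproduces the same dataset; the caller's RNG state is preserved.
#'
#' @param true_params A [mixture_params()] generating the data.
#' @param base `"CA"` or `"IA"` reference for the mixture predictions.
#' @param design A [design_spec()] (expanded with the generating EC50s) or a
#'   prebuilt [build_design()] table.
#' @param seed Integer seed.
#' @param n_replicates,n_per_replicate Override the replication of a
#'   prebuilt design table (defaults: the spec's values, or 8 x 5).
#' @return A [quantal_dataset()] with the design's `treatment_id`s.
#' @export
simulate_dataset <- function(true_params, base = true_params$deviation$base,
                             design = design_spec(), seed = 1L,
                             n_replicates = NULL, n_per_replicate = NULL) {
  stopifnot(inherits(true_params, "mixture_params"))
  is_spec <- inherits(design, "design_spec")
  tab <- if (is_spec) build_design(design, true_params$ec50) else design
  n_rep <- n_replicates %||% (if (is_spec) design$n_replicates else 8L)
  n_per <- n_per_replicate %||% (if (is_spec) design$n_per_replicate else 5L)

  y <- predict_surface(true_params, cbind(tab$conc1, tab$conc2), base = base)
  if (any(y < 0 | y > 100)) {
    stop_raytox("predicted mobility outside [0, 100]; invalid generating parameters",
                class = "raytox_internal_error")
  }
  p_imm <- pmin(pmax(1 - y / 100, 0), 1)

  df <- data.frame(
    treatment_id = rep(tab$treatment_id, each = n_rep),
    conc1 = rep(tab$conc1, each = n_rep),
    conc2 = rep(tab$conc2, each = n_rep),
    replicate = rep(seq_len(n_rep), times = nrow(tab)),
    n_exposed = n_per,
    stringsAsFactors = FALSE)
  df$n_immobile <- with_preserved_seed(seed,
    stats::rbinom(nrow(df), size = n_per, prob = rep(p_imm, each = n_rep)))
  quantal_dataset(df, units = true_params$units)
}

summarize_estimates <- function(est_mat, n_sims, seed, n_failed) {
  stats_tab <- data.frame(
    parameter = colnames(est_mat),
    median = apply(est_mat, 2, stats::median, na.rm = TRUE),
    q2.5 = apply(est_mat, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
    q97.5 = apply(est_mat, 2, stats::quantile, probs = 0.975, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = stats_tab, estimates = est_mat, n_sims = n_sims,
                 n_failed = n_failed, seed = seed),
            class = "recovery_summary")
}

#' Parameter-recovery study for a mixture model
#'
#' Repeatedly simulates datasets from known parameters and refits the same
#' model, summarizing each free parameter by its median and 2.5/97.5
#' percentiles across simulations. Each simulation uses an independent
#' substream derived from `seed`; failed fits are excluded and counted.
#'
#' @param true_params Generating [mixture_params()].
#' @param base Reference model used both to simulate and to fit.
#' @param design A [design_spec()].
#' @param n_sims Number of simulated datasets.
#' @param seed Integer master seed.
#' @param kind Deviation kind fitted (default: the generating kind).
#' @param config [run_config()] controlling the refits.
#' @return Object of class `recovery_summary`: `summary` data frame,
#'   `estimates` matrix (one row per successful simulation), `n_sims`,
#'   `n_failed`, `seed`.
#' @export
recovery_study <- function(true_params, base = true_params$deviation$base,
                           design = design_spec(), n_sims = 200L, seed = 1L,
                           kind = true_params$deviation$kind,
                           config = run_config(multistart = 8L)) {
  stopifnot(n_sims >= 1L)
  sub <- with_preserved_seed(seed, sample.int(2147483646L, n_sims))
  cols <- c("u_max", "beta1", "beta2", "ec50_1", "ec50_2",
            if (kind != "NONE") "a",
            if (kind == "DR") "b_dr", if (kind == "DL") "b_dl")
  est <- matrix(NA_real_, n_sims, length(cols), dimnames = list(NULL, cols))
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    ds <- simulate_dataset(true_params, base, design, seed = sub[i])
    fit <- tryCatch(fit_model(ds, base, kind, config,
                              lead_index = true_params$deviation$lead_index),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    p <- fit$params
    est[i, 1:5] <- c(p$u_max, p$beta, p$ec50)
    if (kind != "NONE") est[i, "a"] <- p$deviation$a
    if (kind == "DR") est[i, "b_dr"] <- p$deviation$b_dr
    if (kind == "DL") est[i, "b_dl"] <- p$deviation$b_dl
  }
  summarize_estimates(est, n_sims, seed, n_failed)
}

#' Parameter-recovery study for a single-chemical curve
#'
#' Simulates binomial immobilization data on a single-chemical dilution
#' series (plus control) from a known log-logistic curve and refits by least
#' squares, summarizing the recovered parameters across simulations.
#'
#' @param true_params Generating [loglogistic_params()].
#' @param levels Nonzero concentration levels.
#' @param n_replicates,n_per_replicate Wells per treatment and animals per
#'   well.
#' @param n_sims Number of simulated datasets.
#' @param seed Integer master seed.
#' @param n_starts Multi-starts per refit.
#' @return A `recovery_summary` over (`u_max`, `beta`, `ec50`).
#' @export
recovery_study_single <- function(true_params, levels,
                                  n_replicates = 8L, n_per_replicate = 5L,
                                  n_sims = 200L, seed = 1L, n_starts = 8L) {
  stopifnot(inherits(true_params, "loglogistic_params"), n_sims >= 1L)
  conc <- rep(c(0, levels), each = n_replicates)
  y <- predict_mobility(true_params, conc)
  p_imm <- pmin(pmax(1 - y / 100, 0), 1)
  sub <- with_preserved_seed(seed, sample.int(2147483646L, n_sims))
  est <- matrix(NA_real_, n_sims, 3L,
                dimnames = list(NULL, c("u_max", "beta", "ec50")))
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    n_imm <- with_preserved_seed(sub[i],
      stats::rbinom(length(conc), n_per_replicate, p_imm))
    d <- data.frame(conc = conc, replicate = seq_along(conc),
                    n_exposed = n_per_replicate, n_immobile = n_imm)
    fit <- tryCatch(fit_single(d, unit = true_params$unit,
                               n_starts = n_starts, n_boot = 0L),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est[i, ] <- c(fit$params$u_max, fit$params$beta, fit$params$ec50)
  }
  summarize_estimates(est, n_sims, seed, n_failed)
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulations (%d failed), seed %d\n",
              x$n_sims, x$n_failed, x$seed))
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}
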