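#' Deviation specification for a mixture reference model
#'
#' Describes how a binary-mixture response surface departs from its reference
#' model. The reference is either concentration addition (CA, Loewe
#' additivity) or independent action (IA, Bliss independence); the deviation
#' kind is one of
#' \describe{
#'   \item{`NONE`}{the pure reference, deviation function G identically 0;}
#'   \item{`SA`}{synergism/antagonism: G = a z1 z2, with a < 0 synergism
#'     (more toxic than the reference) and a > 0 antagonism;}
#'   \item{`DR`}{dose-ratio dependent: G = (a + b_DR z_lead) z1 z2, where
#'     z_lead is the toxic-unit fraction of the lead chemical. When `a` and
#'     `b_dr` have opposite signs the deviation changes sign at
#'     z_lead = -a / b_DR;}
#'   \item{`DL`}{dose-level dependent: G = a (1 - b_DL * s) z1 z2, where s is
#'     the EC50-based total toxic unit for a CA base and the reference effect
#'     fraction for an IA base. With a CA base, b_DL = 1 places the sign
#'     change exactly at the mixture EC50 level (sum TU = 1); with an IA
#'     base, b_DL = 2 places it at 50\% effect.}
#' }
#' z1, z2 are the toxic-unit fractions of the two chemicals (z1 + z2 = 1).
#'
#' @param base `"CA"` or `"IA"`.
#' @param kind `"NONE"`, `"SA"`, `"DR"` or `"DL"`.
#' @param a Dimensionless main deviation parameter.
#' @param b_dr Dose-ratio coefficient (used when `kind = "DR"`).
#' @param b_dl Dose-level coefficient (used when `kind = "DL"`).
#' @param lead_index Which chemical (1 or 2) carries `b_dr`; default 1.
#' @return An object of class `deviation_spec`.
#' @export
deviation_spec <- function(base = c("CA", "IA"),
                           kind = c("NONE", "SA", "DR", "DL"),
                           a = 0, b_dr = 0, b_dl = 0, lead_index = 1L) {
  base <- match.arg(base)
  kind <- match.arg(kind)
  stopifnot(is.numeric(a), is.numeric(b_dr), is.numeric(b_dl),
            lead_index %in% c(1L, 2L))
  structure(list(base = base, kind = kind, a = a, b_dr = b_dr, b_dl = b_dl,
                 lead_index = as.integer(lead_index)),
            class = "deviation_spec")
}

#' Parameters of a binary-mixture response surface
#'
#' One full parameter vector: a control response `u_max` shared by both
#' chemicals, per-chemical log-logistic slope and EC50, and a
#' [deviation_spec()].
#'
#' @param u_max Shared percent-mobile control response, in (0, 100].
#' @param beta Length-2 vector of slopes (> 0).
#' @param ec50 Length-2 vector of EC50s in each chemical's native unit (> 0).
#' @param units Length-2 character vector of unit labels.
#' @param deviation A [deviation_spec()]; default pure CA reference.
#' @return An object of class `mixture_params`. `$chem` holds the two
#'   single-chemical [loglogistic_params()] (sharing `u_max`).
#' @export
mixture_params <- function(u_max, beta, ec50, units = c("", ""),
                           deviation = deviation_spec()) {
  stopifnot(length(beta) == 2L, length(ec50) == 2L, all(beta > 0),
            all(ec50 > 0), u_max > 0, u_max <= 100,
            inherits(deviation, "deviation_spec"))
  chem <- list(loglogistic_params(u_max, beta[1], ec50[1], units[1]),
               loglogistic_params(u_max, beta[2], ec50[2], units[2]))
  structure(list(u_max = u_max, beta = beta, ec50 = ec50, units = units,
                 chem = chem, deviation = deviation),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  d <- x$deviation
  lab <- if (d$kind == "NONE") d$base else paste0(d$base, "-", d$kind)
  cat(sprintf("Binary mixture surface [%s]\n", lab))
  cat(sprintf("  u_max = %.4g%%\n", x$u_max))
  for (i in 1:2) {
    cat(sprintf("  chem %d: beta = %.4g, EC50 = %.4g %s\n",
                i, x$beta[i], x$ec50[i], x$units[i]))
  }
  if (d$kind != "NONE") {
    cat(sprintf("  deviation: a = %.4g", d$a))
    if (d$kind == "DR") cat(sprintf(", b_DR = %.4g (lead chemical %d)", d$b_dr, d$lead_index))
    if (d$kind == "DL") cat(sprintf(", b_DL = %.4g", d$b_dl))
    cat("\n")
  }
  invisible(x)
}

#' Toxic units and toxic-unit fractions of a concentration pair
#'
#' TU_i = C_i / EC50_i normalizes each component by its own potency; the
#' fractions z_i = TU_i / sum(TU) describe mixture composition along a ray.
#' At `concs = c(0, 0)` the composition is undefined: z is set to (0.5, 0.5)
#' and the state flagged degenerate (deviation functions return 0 there).
#'
#' @param concs Length-2 concentration vector (native units, >= 0).
#' @param ec50s Length-2 EC50 vector (> 0), same units respectively.
#' @return List of class `tu_state` with `tu`, `sum_tu`, `z`, `degenerate`.
#' @export
toxic_units <- function(concs, ec50s) {
  stopifnot(length(concs) == 2L, length(ec50s) == 2L,
            all(concs >= 0), all(ec50s > 0))
  tu <- concs / ec50s
  s <- sum(tu)
  degenerate <- s == 0
  z <- if (degenerate) c(0.5, 0.5) else tu / s
  structure(list(tu = tu, sum_tu = s, z = z, degenerate = degenerate),
            class = "tu_state")
}

#' Deviation function G
#'
#' Evaluates the deviation function of a [deviation_spec()] at a mixture
#' composition. G = 0 recovers the reference surface; the sign convention is
#' that G < 0 produces a surface more toxic than the reference (synergism)
#' and G > 0 less toxic (antagonism), for both CA and IA bases.
#'
#' @param spec A [deviation_spec()].
#' @param tu A `tu_state` from [toxic_units()].
#' @param ref_effect_fraction Reference-model effect fraction in \[0, 1\];
#'   required only for an IA base with `kind = "DL"`, ignored otherwise.
#' @return Dimensionless scalar G (finite; 0 for `NONE` or degenerate input).
#' @export
deviation_g <- function(spec, tu, ref_effect_fraction = NA_real_) {
  stopifnot(inherits(spec, "deviation_spec"), inherits(tu, "tu_state"))
  if (spec$kind == "DL" && spec$base == "IA" && anyNA(ref_effect_fraction)) {
    stop_raytox("IA-DL deviation needs the reference effect fraction",
                class = "raytox_usage_error")
  }
  g_vec(spec, tu$tu[1], tu$tu[2], ref_effect_fraction)
}

# Vectorized deviation function over parallel toxic-unit vectors.
g_vec <- function(spec, tu1, tu2, eref = NA_real_) {
  if (spec$kind == "NONE") return(rep(0, length(tu1)))
  s <- tu1 + tu2
  z1 <- ifelse(s > 0, tu1 / s, 0.5)
  z12 <- z1 * (1 - z1)
  g <- switch(spec$kind,
    SA = spec$a * z12,
    DR = {
      zl <- if (spec$lead_index == 1L) z1 else 1 - z1
      (spec$a + spec$b_dr * zl) * z12
    },
    DL = if (spec$base == "CA") {
      spec$a * (1 - spec$b_dl * s) * z12
    } else {
      spec$a * (1 - spec$b_dl * eref) * z12
    })
  g[s == 0] <- 0
  # guard exp(G) downstream against pathological parameter proposals
  pmax(pmin(g, 50), -50)
}

# --- surface predictions ----------------------------------------------------

as_conc_matrix <- function(concs) {
  m <- if (is.matrix(concs)) concs else matrix(concs, ncol = 2L, byrow = FALSE)
  if (ncol(m) != 2L) stop_raytox("concentrations must come in pairs",
                                 class = "raytox_usage_error")
  if (any(m < 0)) stop_raytox("negative concentration",
                              class = "raytox_domain_error")
  m
}

#' Concentration-addition surface prediction
#'
#' Solves the (possibly deviation-extended) Loewe additivity condition
#' \deqn{\sum_i c_i / EC_{Y,i} = \exp(G)}
#' for the mobility fraction Y by bisection, where
#' \eqn{EC_{Y,i} = EC50_i ((1-Y)/Y)^{1/\beta_i}} is the concentration at
#' which chemical i alone produces mobility fraction Y. The left-hand side is
#' strictly increasing in Y, so the root is unique. G uses EC50-based toxic
#' units, so it is constant during the solve. Returns `u_max * Y` in percent;
#' `concs = c(0, 0)` returns `u_max` exactly, and a single-chemical pair
#' reduces exactly to [predict_mobility()] of that chemical.
#'
#' @param params A [mixture_params()] (its deviation `base` should be `"CA"`;
#'   the `kind` and parameters are honoured regardless of the stored base
#'   label).
#' @param concs Length-2 vector or n x 2 matrix of concentration pairs.
#' @param max_iter Bisection iteration cap.
#' @return Predicted percent mobile (vector of length n).
#' @export
predict_ca <- function(params, concs, max_iter = 200L) {
  stopifnot(inherits(params, "mixture_params"))
  m <- as_conc_matrix(concs)
  ca_solve(params$u_max, params$beta, params$ec50, params$deviation, m,
           max_iter = max_iter)
}

# Vectorized bisection for the CA condition over all rows of `m` at once.
ca_solve <- function(u_max, beta, ec50, spec, m, max_iter = 200L) {
  n <- nrow(m)
  if (n == 0L) return(numeric(0))
  # a CA surface always uses the sum-TU dose-level form
  if (spec$kind == "DL" && spec$base != "CA") spec$base <- "CA"
  tu1 <- m[, 1] / ec50[1]; tu2 <- m[, 2] / ec50[2]
  rhs <- exp(g_vec(spec, tu1, tu2))
  active <- (tu1 + tu2) > 0
  out <- rep(u_max, n)
  if (!any(active)) return(out)
  c1 <- m[active, 1]; c2 <- m[active, 2]; r <- rhs[active]
  ib1 <- 1 / beta[1]; ib2 <- 1 / beta[2]
  lo <- rep(1e-12, length(c1)); hi <- rep(1 - 1e-12, length(c1))
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    rr <- (1 - mid) / mid
    fm <- c1 / (ec50[1] * rr^ib1) + c2 / (ec50[2] * rr^ib2) - r
    up <- fm > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (max(hi - lo) < 1e-14) break
  }
  y <- (lo + hi) / 2
  rr <- (1 - y) / y
  resid <- abs(c1 / (ec50[1] * rr^ib1) + c2 / (ec50[2] * rr^ib2) - r)
  if (any(resid > 1e-6)) {
    stop_raytox("CA bisection failed to converge", class = "raytox_numeric_error")
  }
  out[active] <- u_max * y
  out
}

#' Independent-action surface prediction
#'
#' Reference: y = u_max q1 q2, with q_i = 1 / (1 + (c_i/EC50_i)^beta_i) the
#' per-chemical non-response probability. Deviations enter as
#' \deqn{y = u_{max} (q_1 q_2)^{\exp(-G)},}
#' which recovers the reference at G = 0, keeps y in (0, u_max), and makes
#' G < 0 lower the surface (synergism) and G > 0 raise it (antagonism),
#' consistent with the CA sign convention. For IA-DL, G depends on the
#' reference effect fraction 1 - q1 q2.
#'
#' @inheritParams predict_ca
#' @return Predicted percent mobile (vector of length n).
#' @export
predict_ia <- function(params, concs) {
  stopifnot(inherits(params, "mixture_params"))
  m <- as_conc_matrix(concs)
  ia_eval(params$u_max, params$beta, params$ec50, params$deviation, m)
}

ia_eval <- function(u_max, beta, ec50, spec, m) {
  # an IA surface always uses the effect-fraction dose-level form
  if (spec$kind == "DL" && spec$base != "IA") spec$base <- "IA"
  q1 <- 1 / (1 + (m[, 1] / ec50[1])^beta[1])
  q2 <- 1 / (1 + (m[, 2] / ec50[2])^beta[2])
  qq <- q1 * q2
  g <- g_vec(spec, m[, 1] / ec50[1], m[, 2] / ec50[2], eref = 1 - qq)
  u_max * qq^exp(-g)
}

#' Predict from either reference surface
#'
#' Dispatches to [predict_ca()] or [predict_ia()] according to `base`
#' (default: the base stored in the parameters' deviation spec). Treatments
#' with one zero concentration reduce to the corresponding single-chemical
#' curve under both bases.
#'
#' @inheritParams predict_ca
#' @param base `"CA"` or `"IA"`; default taken from `params$deviation$base`.
#' @return Predicted percent mobile.
#' @export
predict_surface <- function(params, concs, base = params$deviation$base) {
  if (match.arg(base, c("CA", "IA")) == "CA") predict_ca(params, concs)
  else predict_ia(params, concs)
}

#' Locus where a DR or DL deviation changes sign
#'
#' For a dose-ratio deviation the sign change (antagonism/synergism switch)
#' sits at the toxic-unit fraction z_lead* = -a / b_DR of the lead chemical,
#' provided it lies in (0, 1) -- which requires `a` and `b_dr` of opposite
#' signs. For a dose-level deviation with a CA base the switch sits at total
#' toxic unit 1 / b_DL (requires b_DL > 0); with an IA base at reference
#' effect fraction 1 / b_DL (requires b_DL > 1, since effect fractions cannot
#' exceed 1).
#'
#' @param spec A [deviation_spec()] with `kind` `"DR"` or `"DL"`.
#' @param ec50s Length-2 EC50 vector (native units) used to express the DR
#'   switch as a concentration ratio.
#' @return List of class `switch_locus`: `exists` plus, when applicable,
#'   `z_lead` and `tu_ratio` = z_other/z_lead and
#'   `conc_ratio` = tu_ratio * EC50_other / EC50_lead (native units) for DR;
#'   `sum_tu_star` (CA-DL) or `effect_fraction_star` (IA-DL).
#' @examples
#' # fitted CA-DR deviation: switch at a ZnO:Ag toxic-unit ratio near 0.57
#' sl <- switch_locus(deviation_spec("CA", "DR", a = -2.39, b_dr = 3.74),
#'                    ec50s = c(0.91, 2.60))
#' sl$tu_ratio
#' @export
switch_locus <- function(spec, ec50s = c(1, 1)) {
  stopifnot(inherits(spec, "deviation_spec"))
  if (!spec$kind %in% c("DR", "DL")) {
    stop_raytox("switch_locus applies to DR or DL deviations only",
                class = "raytox_usage_error")
  }
  out <- list(exists = FALSE, z_lead = NA_real_, sum_tu_star = NA_real_,
              effect_fraction_star = NA_real_, tu_ratio = NA_real_,
              conc_ratio = NA_real_, kind = spec$kind, base = spec$base)
  if (spec$kind == "DR") {
    if (spec$b_dr != 0) {
      z <- -spec$a / spec$b_dr
      if (z > 0 && z < 1) {
        lead <- spec$lead_index; other <- 3L - lead
        out$exists <- TRUE
        out$z_lead <- z
        out$tu_ratio <- (1 - z) / z
        out$conc_ratio <- out$tu_ratio * ec50s[other] / ec50s[lead]
      }
    }
  } else if (spec$base == "CA") {
    if (spec$b_dl > 0) {
      out$exists <- TRUE
      out$sum_tu_star <- 1 / spec$b_dl
    }
  } else {
    if (spec$b_dl > 1) {
      out$exists <- TRUE
      out$effect_fraction_star <- 1 / spec$b_dl
    }
  }
  class(out) <- "switch_locus"
  out
}

#' @export
print.switch_locus <- function(x, ...) {
  if (!x$exists) {
    cat("No antagonism/synergism switch within the admissible range.\n")
  } else if (x$kind == "DR") {
    cat(sprintf(
      "DR switch at lead TU fraction z* = %.4g (TU ratio other:lead = %.4g; conc ratio %.4g, native units)\n",
      x$z_lead, x$tu_ratio, x$conc_ratio))
  } else if (x$base == "CA") {
    cat(sprintf("CA-DL switch at total toxic unit %.4g\n", x$sum_tu_star))
  } else {
    cat(sprintf("IA-DL switch at reference effect fraction %.4g\n",
                x$effect_fraction_star))
  }
  invisible(x)
}

#' Isobole contours of a mixture surface
#'
#' Evaluates the surface on a rectilinear concentration grid and extracts
#' iso-effect polylines (isoboles) at the requested percent-mobile levels.
#' Under the pure CA reference isoboles are straight lines joining the two
#' single-chemical effective concentrations; synergism bows them towards the
#' origin.
#'
#' @param params A [mixture_params()].
#' @param effect_levels Percent-mobile contour levels, each in (0, 100).
#' @param base `"CA"` or `"IA"`.
#' @param c1_max,c2_max Upper grid limits (defaults: 2.5 x each EC50).
#' @param n_grid Grid points per axis (default 101).
#' @return Data frame with columns `base`, `deviation`, `effect_percent`,
#'   `piece` (polyline id), `c1`, `c2`, `unit1`, `unit2`. Levels not attained
#'   on the grid yield no rows (with a warning).
#' @export
isobole_grid <- function(params, effect_levels, base = params$deviation$base,
                         c1_max = 2.5 * params$ec50[1],
                         c2_max = 2.5 * params$ec50[2], n_grid = 101L) {
  stopifnot(inherits(params, "mixture_params"), n_grid >= 2L)
  if (any(effect_levels <= 0 | effect_levels >= 100)) {
    stop_raytox("effect levels must lie strictly between 0 and 100",
                class = "raytox_domain_error")
  }
  empty <- data.frame(base = character(), deviation = character(),
                      effect_percent = numeric(), piece = integer(),
                      c1 = numeric(), c2 = numeric(),
                      unit1 = character(), unit2 = character(),
                      stringsAsFactors = FALSE)
  if (length(effect_levels) == 0L || c1_max <= 0 || c2_max <= 0) return(empty)
  x <- seq(0, c1_max, length.out = n_grid)
  y <- seq(0, c2_max, length.out = n_grid)
  grid <- as.matrix(expand.grid(c1 = x, c2 = y))
  z <- matrix(predict_surface(params, grid, base = base),
              nrow = n_grid, ncol = n_grid)
  kind <- params$deviation$kind
  pieces <- list()
  for (lev in effect_levels) {
    cl <- grDevices::contourLines(x, y, z, levels = lev)
    if (length(cl) == 0L) {
      warning(sprintf("effect level %.3g%% not attained on the grid", lev))
      next
    }
    for (k in seq_along(cl)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        base = base, deviation = kind, effect_percent = lev, piece = k,
        c1 = cl[[k]]$x, c2 = cl[[k]]$y,
        unit1 = params$units[1], unit2 = params$units[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(pieces) == 0L) return(empty)
  do.call(rbind, pieces)
}
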