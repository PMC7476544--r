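# Shared fixtures: published-parameter anchors and small builders.

# Single-chemical anchors (48-h immobilization): AgNO3 in ug/L, ZnO NPs in mg/L.
ag_params <- function() loglogistic_params(99.12, 2.38, 0.89, "ug/L")
zno_params <- function() loglogistic_params(99.12, 0.68, 2.28, "mg/L")

# CA reference column of the published mixture-fit summary.
mp_ca_ref <- function() {
  mixture_params(99.12, c(2.38, 0.68), c(0.91, 2.21), c("ug/L", "mg/L"),
                 deviation_spec("CA", "NONE"))
}

# CA-DR column (the best-fitting model): a = -2.39, b_DR = 3.74.
mp_ca_dr <- function() {
  mixture_params(98.05, c(2.37, 0.69), c(0.91, 2.60), c("ug/L", "mg/L"),
                 deviation_spec("CA", "DR", a = -2.39, b_dr = 3.74))
}

# Noise-free dataset: one pseudo-replicate per treatment whose percent-mobile
# equals the surface prediction exactly (n_exposed = 100, fractional counts).
noise_free_dataset <- function(params, base = params$deviation$base,
                               spec = design_spec()) {
  tab <- build_design(spec, params$ec50)
  y <- predict_surface(params, cbind(tab$conc1, tab$conc2), base = base)
  quantal_dataset(data.frame(
    treatment_id = tab$treatment_id, conc1 = tab$conc1, conc2 = tab$conc2,
    replicate = 1L, n_exposed = 100, n_immobile = 100 - y),
    units = params$units)
}

# Single-chemical replicate-level frame from exact curve values.
noise_free_single <- function(params, levels, n_rep = 2L) {
  conc <- rep(c(0, levels), each = n_rep)
  y <- predict_mobility(params, conc)
  data.frame(conc = conc, replicate = seq_along(conc),
             n_exposed = 100, n_immobile = 100 - y)
}

# A light config for tests that fit many models.
fast_config <- function(multistart = 4L) {
  run_config(multistart = multistart, bootstrap_draws = 0L)
}
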