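# minimal mixture_fit stand-in for testing the LRT arithmetic alone
fake_fit <- function(ss, k, n = 35L) {
  structure(list(ss = ss, n_obs = n, k_params = k), class = "mixture_fit")
}

test_that("SS objective is the squared distance on treatment means", {
  mp <- mp_ca_ref()
  ds <- noise_free_dataset(mp)
  expect_lt(objective_ss(mp, ds, base = "CA"), 1e-12)

  # shifting one treatment mean by 2 percentage points adds exactly 4
  ds2 <- ds
  ds2$n_immobile[5] <- ds2$n_immobile[5] + 2   # one replicate per treatment
  ds2$percent_mobile <- 100 * (1 - ds2$n_immobile / ds2$n_exposed)
  expect_equal(objective_ss(mp, ds2, base = "CA"), 4, tolerance = 1e-9)
})

test_that("likelihood-ratio chi-squared reproduces the published p-value row", {
  # six printed SS pairs, n = 35 treatment means, df = parameters added
  cases <- list(
    list(ss = c(534.7, 532.1), k = c(5L, 6L), p = 0.68),   # CA-S/A
    list(ss = c(534.7, 437.2), k = c(5L, 7L), p = 0.03),   # CA-DR
    list(ss = c(534.7, 509.8), k = c(5L, 7L), p = 0.43),   # CA-DL
    list(ss = c(664.5, 658.9), k = c(5L, 6L), p = 0.59),   # IA-S/A
    list(ss = c(664.5, 515.2), k = c(5L, 7L), p = 0.01),   # IA-DR
    list(ss = c(664.5, 656.7), k = c(5L, 7L), p = 0.81))   # IA-DL
  for (cs in cases) {
    t <- likelihood_ratio_test(fake_fit(cs$ss[1], cs$k[1]),
                               fake_fit(cs$ss[2], cs$k[2]))
    expect_identical(t$df, cs$k[2] - cs$k[1])
    expect_equal(round(t$p, 2), cs$p)
  }
  # the CA-DR statistic itself
  t <- likelihood_ratio_test(fake_fit(534.7, 5L), fake_fit(437.2, 7L))
  expect_equal(t$chi2, 35 * log(534.7 / 437.2), tolerance = 1e-12)
})

test_that("LRT degenerate and error contracts hold", {
  t <- likelihood_ratio_test(fake_fit(100, 5L), fake_fit(100, 6L))
  expect_identical(t$chi2, 0)
  expect_identical(t$p, 1)
  # a worse extended fit clamps to zero rather than going negative
  t2 <- likelihood_ratio_test(fake_fit(100, 5L), fake_fit(101, 6L))
  expect_identical(t2$chi2, 0)
  expect_error(likelihood_ratio_test(fake_fit(100, 5L, n = 35L),
                                     fake_fit(90, 6L, n = 34L)),
               class = "raytox_usage_error")
  # p decreases as chi2 grows at fixed df
  p1 <- likelihood_ratio_test(fake_fit(110, 5L), fake_fit(100, 6L))$p
  p2 <- likelihood_ratio_test(fake_fit(150, 5L), fake_fit(100, 6L))$p
  expect_gt(p1, p2)
})

test_that("noise-free mixture data return the generating parameters", {
  truth <- mp_ca_dr()
  ds <- noise_free_dataset(truth, base = "CA")
  fit <- fit_model(ds, "CA", "DR", fast_config())
  expect_lt(fit$ss, 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$k_params, 7L)
  p <- fit$params
  expect_equal(p$u_max, truth$u_max, tolerance = 1e-4)
  expect_equal(p$beta, truth$beta, tolerance = 1e-4)
  expect_equal(p$ec50, truth$ec50, tolerance = 1e-4)
  expect_equal(p$deviation$a, -2.39, tolerance = 1e-3)
  expect_equal(p$deviation$b_dr, 3.74, tolerance = 1e-3)
})

test_that("nested models never fit worse and selection behaves at extreme alpha", {
  truth <- mp_ca_dr()
  ds <- simulate_dataset(truth, "CA", design_spec(), seed = 515)
  cfg <- fast_config()
  fits <- list(ref = fit_model(ds, "CA", "NONE", cfg),
               sa = fit_model(ds, "CA", "SA", cfg),
               dr = fit_model(ds, "CA", "DR", cfg),
               dl = fit_model(ds, "CA", "DL", cfg))
  tol <- 1e-6
  expect_gte(fits$ref$ss, fits$sa$ss - tol)
  expect_gte(fits$sa$ss, fits$dr$ss - tol)
  expect_gte(fits$sa$ss, fits$dl$ss - tol)
  expect_identical(vapply(fits, function(f) f$k_params, integer(1)),
                   c(ref = 5L, sa = 6L, dr = 7L, dl = 7L))

  sel <- select_model(ds, run_config(alpha = 0.999999, multistart = 4L))
  best <- sel$fits[[sel$best]]
  expect_identical(best$k_params, 7L)   # any p < 1 admits the 7-parameter models
  expect_true(all(c("CA", "IA", "CA-SA", "CA-DR", "CA-DL",
                    "IA-SA", "IA-DR", "IA-DL") %in% names(sel$fits)))
  expect_length(sel$tests, 6L)
  expect_true(all(grepl("->", names(sel$stepwise))))
})

test_that("fitting S/A to additive data centres the deviation estimate on zero", {
  truth <- mixture_params(99.12, c(2.38, 0.68), c(0.91, 2.21),
                          c("ug/L", "mg/L"))   # reference CA, a = 0
  rs <- recovery_study(truth, "CA", design_spec(), n_sims = 50L, seed = 55,
                       kind = "SA", config = run_config(multistart = 6L))
  med_a <- rs$summary$median[rs$summary$parameter == "a"]
  expect_lt(abs(med_a), 0.4)   # ~4 standard errors of the median at this n
  # and the shared parameters stay unbiased
  expect_equal(rs$summary$median[rs$summary$parameter == "ec50_1"], 0.91,
               tolerance = 0.05)
})

test_that("p-values are invariant to rescaling one chemical's unit", {
  truth <- mp_ca_dr()
  ds <- simulate_dataset(truth, "CA", design_spec(), seed = 616)
  cfg <- fast_config()
  p_orig <- likelihood_ratio_test(fit_model(ds, "CA", "NONE", cfg),
                                  fit_model(ds, "CA", "SA", cfg))$p
  ds_mg <- ds
  ds_mg$conc2 <- ds_mg$conc2 * 1000   # mg/L -> ug/L
  ds_mg <- quantal_dataset(as.data.frame(ds_mg), units = c("ug/L", "ug/L"))
  p_scaled <- likelihood_ratio_test(fit_model(ds_mg, "CA", "NONE", cfg),
                                    fit_model(ds_mg, "CA", "SA", cfg))$p
  expect_equal(p_orig, p_scaled, tolerance = 1e-2)
})

test_that("selection table mirrors the summary-table layout", {
  truth <- mp_ca_dr()
  ds <- simulate_dataset(truth, "CA", design_spec(), seed = 717)
  sel <- select_model(ds, fast_config(2L))
  tab <- selection_table(sel)
  expect_setequal(names(tab),
                  c("model", "base", "kind", "C_max", "beta1", "beta2",
                    "ec50_1", "ec50_2", "a", "b_dr", "b_dl", "ss",
                    "chi2", "df", "p", "best"))
  expect_identical(nrow(tab), 8L)
  expect_true(all(is.na(tab$a[tab$kind == "NONE"])))
  expect_true(all(!is.na(tab$b_dr[tab$kind == "DR"])))
  expect_identical(sum(tab$best), 1L)
})
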