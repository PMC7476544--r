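test_that("toxic units and fractions follow their definitions", {
  tu <- toxic_units(c(0.89, 2.28), c(0.89, 2.28))
  expect_equal(tu$tu, c(1, 1))
  expect_equal(tu$sum_tu, 2)
  expect_equal(tu$z, c(0.5, 0.5))
  expect_false(tu$degenerate)

  tu2 <- toxic_units(c(0, 2.28), c(0.89, 2.28))
  expect_equal(tu2$z, c(0, 1))

  tu0 <- toxic_units(c(0, 0), c(0.89, 2.28))
  expect_true(tu0$degenerate)
  expect_equal(tu0$z, c(0.5, 0.5))
  expect_equal(tu0$sum_tu, 0)
})

test_that("deviation function G evaluates and reduces correctly", {
  tu_mid <- toxic_units(c(0.5 * 0.91, 0.5 * 2.21), c(0.91, 2.21))
  expect_equal(deviation_g(deviation_spec("CA", "SA", a = -2), tu_mid), -0.5)
  expect_equal(deviation_g(deviation_spec("CA", "NONE"), tu_mid), 0)

  # the fitted CA-DR deviation crosses zero at z_lead = 2.39/3.74
  zstar <- 2.39 / 3.74
  tu_star <- toxic_units(c(zstar * 0.91, (1 - zstar) * 2.60), c(0.91, 2.60))
  g <- deviation_g(deviation_spec("CA", "DR", a = -2.39, b_dr = 3.74), tu_star)
  expect_equal(g, 0, tolerance = 1e-12)

  # b_DL = 0 reduces the DL deviation to S/A, at any dose level
  for (stu in c(0.1, 1, 2)) {
    tu <- toxic_units(c(0.4 * stu * 0.91, 0.6 * stu * 2.21), c(0.91, 2.21))
    expect_equal(deviation_g(deviation_spec("CA", "DL", a = 0.7, b_dl = 0), tu),
                 deviation_g(deviation_spec("CA", "SA", a = 0.7), tu))
  }
  # degenerate composition forces G = 0
  tu0 <- toxic_units(c(0, 0), c(1, 1))
  expect_equal(deviation_g(deviation_spec("CA", "SA", a = 3), tu0), 0)
})

test_that("reference CA yields exactly 50% effect at total toxic unit 1", {
  mp <- mp_ca_ref()
  for (z1 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    concs <- c(z1 * mp$ec50[1], (1 - z1) * mp$ec50[2])
    expect_equal(predict_ca(mp, concs), mp$u_max / 2, tolerance = 1e-8)
  }
  # independent of the slopes
  mp2 <- mixture_params(95, c(5, 0.4), c(0.91, 2.21))
  expect_equal(predict_ca(mp2, c(0.5 * 0.91, 0.5 * 2.21)), 95 / 2,
               tolerance = 1e-8)
})

test_that("both surfaces reduce to the single-chemical curves on the axes", {
  mp <- mp_ca_ref()
  c1 <- c(0.2, 0.91, 1.7)
  c2 <- c(0.5, 2.21, 9)
  expect_equal(predict_ca(mp, cbind(c1, 0)), predict_mobility(mp$chem[[1]], c1),
               tolerance = 1e-9)
  expect_equal(predict_ca(mp, cbind(0, c2)), predict_mobility(mp$chem[[2]], c2),
               tolerance = 1e-9)
  expect_equal(predict_ia(mp, cbind(c1, 0)), predict_mobility(mp$chem[[1]], c1),
               tolerance = 1e-12)
  expect_equal(predict_ia(mp, cbind(0, c2)), predict_mobility(mp$chem[[2]], c2),
               tolerance = 1e-12)
  expect_equal(predict_ca(mp, c(0, 0)), mp$u_max)
  expect_equal(predict_ia(mp, c(0, 0)), mp$u_max)
})

test_that("sham additivity holds when the two components share a curve", {
  mp <- mixture_params(98, c(1.7, 1.7), c(1.3, 1.3))
  grid <- expand.grid(c1 = seq(0, 3, length.out = 7),
                      c2 = seq(0, 3, length.out = 7))
  single <- loglogistic_params(98, 1.7, 1.3)
  expect_equal(predict_ca(mp, as.matrix(grid)),
               predict_mobility(single, grid$c1 + grid$c2),
               tolerance = 1e-8)
})

test_that("IA reference multiplies non-response probabilities", {
  mp <- mp_ca_ref()
  expect_equal(predict_ia(mp, c(0.91, 2.21)), 99.12 / 4, tolerance = 1e-12)
  syn <- mixture_params(99.12, c(2.38, 0.68), c(0.91, 2.21),
                        deviation = deviation_spec("IA", "SA", a = -1))
  expect_lt(predict_ia(syn, c(0.91, 2.21)), 99.12 / 4)
})

test_that("sign of G moves each surface the documented way", {
  for (a in c(-1.5, 1.5)) {
    ca <- mixture_params(99, c(2.4, 0.7), c(0.9, 2.2),
                         deviation = deviation_spec("CA", "SA", a = a))
    ia <- mixture_params(99, c(2.4, 0.7), c(0.9, 2.2),
                         deviation = deviation_spec("IA", "SA", a = a))
    ref_ca <- mixture_params(99, c(2.4, 0.7), c(0.9, 2.2))
    concs <- c(0.4 * 0.9, 0.6 * 2.2)
    dca <- predict_ca(ca, concs) - predict_ca(ref_ca, concs)
    dia <- predict_ia(ia, concs) - predict_ia(ref_ca, concs)
    if (a > 0) {            # antagonism: above the reference
      expect_gt(dca, 0); expect_gt(dia, 0)
    } else {                # synergism: below the reference
      expect_lt(dca, 0); expect_lt(dia, 0)
    }
  }
})

test_that("reference surfaces are non-increasing in each concentration", {
  set.seed(77)
  for (i in 1:12) {
    mp <- mixture_params(runif(1, 85, 100), runif(2, 0.4, 5),
                         c(10^runif(1, -1, 1), 10^runif(1, -1, 1)))
    cs <- seq(0, 2.5 * mp$ec50[1], length.out = 12)
    fixed2 <- runif(1, 0, 2 * mp$ec50[2])
    expect_true(all(diff(predict_ca(mp, cbind(cs, fixed2))) <= 1e-8))
    expect_true(all(diff(predict_ia(mp, cbind(rep(0.6 * mp$ec50[1], 12),
                                              seq(0, 3 * mp$ec50[2],
                                                  length.out = 12)))) <= 1e-8))
  }
})

test_that("S/A surfaces are non-increasing in total dose along fixed-ratio rays", {
  # with the mixture ratio fixed, G is constant, so dilution strength can
  # only reduce the response -- for any S/A deviation size
  set.seed(78)
  for (i in 1:12) {
    a <- runif(1, -3, 3)
    mp <- mixture_params(runif(1, 85, 100), runif(2, 0.4, 5),
                         c(10^runif(1, -1, 1), 10^runif(1, -1, 1)),
                         deviation = deviation_spec("CA", "SA", a = a))
    z1 <- runif(1, 0.05, 0.95)
    s <- seq(0.01, 2.5, length.out = 15)
    ray <- cbind(z1 * s * mp$ec50[1], (1 - z1) * s * mp$ec50[2])
    expect_true(all(diff(predict_ca(mp, ray)) <= 1e-8))
    mp$deviation$base <- "IA"
    expect_true(all(diff(predict_ia(mp, ray)) <= 1e-8))
  }
})

test_that("bisection solver matches a fine grid-search oracle", {
  set.seed(99)
  for (i in 1:10) {
    mp <- mixture_params(runif(1, 85, 100), runif(2, 0.5, 4),
                         c(10^runif(1, -1, 1), 10^runif(1, -1, 1)),
                         deviation = deviation_spec("CA", "SA",
                                                    a = runif(1, -2, 2)))
    concs <- c(runif(1, 0.05, 2) * mp$ec50[1], runif(1, 0.05, 2) * mp$ec50[2])
    y <- predict_ca(mp, concs)
    # oracle: minimize the CA condition residual over a 1e-6-step Y grid
    yy <- seq(1e-6, 1 - 1e-6, by = 1e-6)
    r <- (1 - yy) / yy
    tu <- toxic_units(concs, mp$ec50)
    lhs <- concs[1] / (mp$ec50[1] * r^(1 / mp$beta[1])) +
           concs[2] / (mp$ec50[2] * r^(1 / mp$beta[2]))
    ystar <- yy[which.min(abs(lhs - exp(deviation_g(mp$deviation, tu))))]
    expect_equal(y, mp$u_max * ystar, tolerance = 1e-5 * mp$u_max)
  }
})

test_that("switch locus reproduces the fitted-model sign change", {
  sl <- switch_locus(deviation_spec("CA", "DR", a = -2.39, b_dr = 3.74),
                     ec50s = c(0.91, 2.60))
  expect_true(sl$exists)
  expect_equal(sl$z_lead, 2.39 / 3.74, tolerance = 1e-12)
  expect_equal(sl$tu_ratio, 0.5648536, tolerance = 1e-6)
  expect_equal(sl$conc_ratio, 0.5648536 * 2.60 / 0.91, tolerance = 1e-6)

  # same-sign coefficients never switch
  expect_false(switch_locus(deviation_spec("CA", "DR", a = -2, b_dr = -1))$exists)
  expect_false(switch_locus(deviation_spec("CA", "DR", a = 2, b_dr = 0))$exists)

  # dose-level switches
  expect_equal(switch_locus(deviation_spec("CA", "DL", a = 1, b_dl = 1))$sum_tu_star, 1)
  expect_equal(switch_locus(deviation_spec("IA", "DL", a = 1, b_dl = 2))$effect_fraction_star, 0.5)
  expect_false(switch_locus(deviation_spec("CA", "DL", a = 1, b_dl = -0.5))$exists)
  expect_false(switch_locus(deviation_spec("IA", "DL", a = 1, b_dl = 0.8))$exists)

  expect_error(switch_locus(deviation_spec("CA", "SA", a = 1)),
               class = "raytox_usage_error")
})

test_that("isoboles are straight under reference CA and bowed inward under synergism", {
  mp <- mp_ca_ref()
  ib <- isobole_grid(mp, 50, n_grid = 201)
  expect_true(all(c("base", "deviation", "effect_percent", "c1", "c2",
                    "unit1", "unit2") %in% names(ib)))
  # Loewe 50% isobole: c1/EC50_1 + c2/EC50_2 = 1
  stu <- ib$c1 / mp$ec50[1] + ib$c2 / mp$ec50[2]
  res <- 2.5 / 200  # grid resolution in EC50 units
  expect_lt(max(abs(stu - 1)), 4 * res)  # linear-interpolation slack

  syn <- mixture_params(99.12, c(2.38, 0.68), c(0.91, 2.21),
                        deviation = deviation_spec("CA", "SA", a = -2))
  ibs <- isobole_grid(syn, 50, n_grid = 201)
  interior <- ibs$c1 > 0.1 * syn$ec50[1] & ibs$c2 > 0.1 * syn$ec50[2]
  expect_true(any(interior))
  expect_true(all(ibs$c1[interior] / syn$ec50[1] +
                    ibs$c2[interior] / syn$ec50[2] < 1))

  expect_identical(nrow(isobole_grid(mp, numeric(0))), 0L)
  expect_warning(out <- isobole_grid(mp, 99.9, c1_max = 2, c2_max = 4),
                 "not attained")
  expect_identical(nrow(out), 0L)
})
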