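test_that("vegetation indices match hand evaluation and guard denominators", {
  vi <- vegetation_indices(0.05, 0.15, 0.1, 0.2, 0.4, 0.5)
  expect_equal(vi$ndvi, (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-4)
  expect_equal(vi$mcari, ((0.2 - 0.1) - 0.2 * (0.2 - 0.15)) * (0.2 / 0.1))
  expect_equal(vi$ndre, (0.5 - 0.2) / (0.5 + 0.2))
  expect_equal(vi$msrre, (0.5 / 0.2 - 1) / sqrt(0.5 / 0.2 + 1))
  same <- vegetation_indices(0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  expect_equal(c(same$ndvi, same$gndvi, same$ndre), c(0, 0, 0))
  zero <- vegetation_indices(0.1, 0.1, 0, 0.1, 0.1, 0)
  expect_true(is.na(zero$ndvi))
  expect_equal(zero$flag, "zero_denominator")
})

test_that("Norman-Jarvis inversion reproduces the hand-derived spot value", {
  # theta 0, fb 1, chi 1, a 0.9, tau 0.5: K = 0.504, A = 0.8607
  g <- gap_fraction_model("inverse", 0.5, zenith_deg = 0, fb = 1, chi = 1,
                          absorptivity = 0.9)
  expect_equal(g$K, 0.504, tolerance = 1e-3)
  expect_equal(g$A, 0.8607, tolerance = 1e-4)
  expect_equal(g$LAI, 1.507, tolerance = 0.01)
  f0 <- gap_fraction_model("forward", 0)
  expect_equal(f0$tau, 1)
  expect_equal(f0$fiPAR, 0)
  expect_error(gap_fraction_model("inverse", 0), "tau")
  expect_error(gap_fraction_model("inverse", 1.2), "tau")
})

test_that("gap-fraction forward and inverse are exact inverses on a grid", {
  for (theta in c(0, 20, 40, 60)) for (fb in c(0.2, 0.6, 1)) {
    for (tau in seq(0.1, 0.9, by = 0.2)) {
      lai <- gap_fraction_model("inverse", tau, theta, fb)$LAI
      back <- gap_fraction_model("forward", lai, theta, fb)$tau
      expect_lt(abs(back - tau), 1e-9)
    }
    for (lai in c(0.1, 1, 3, 6)) {
      tau <- gap_fraction_model("forward", lai, theta, fb)$tau
      back <- gap_fraction_model("inverse", tau, theta, fb)$LAI
      expect_lt(abs(back - lai), 1e-9)
    }
  }
})

test_that("daily interception calibrates porosity at noon and integrates", {
  # zero observed interception -> fully porous canopy, zero daily value
  d0 <- daily_fipar(3, 2, 90, 0, 41.5, 0.85, 205)
  expect_equal(d0$porosity, 1)
  expect_equal(d0$fiPAR_d, 0)
  # closed canopy: hedge as wide as the row spacing shades everything
  dc <- daily_fipar(3, 5, 90, 0.95, 41.5, 0.85, 205)
  expect_equal(dc$porosity, 0.05, tolerance = 1e-6)
  expect_equal(dc$fiPAR_d, 0.95, tolerance = 1e-6)
  # daily value is a convex combination of the hourly course
  d <- daily_fipar(4, 2.5, 90, 0.55, 41.5, 0.85, 205)
  day <- d$profile$fiPAR[d$profile$weight > 0]
  expect_gte(d$fiPAR_d, min(day))
  expect_lte(d$fiPAR_d, max(day))
  # observation above the geometric maximum clips porosity with a flag
  dover <- daily_fipar(0.5, 0.5, 90, 0.9, 41.5, 0.85, 205)
  expect_equal(dover$porosity, 0)
  expect_equal(dover$flag, "porosity_clipped")
  # monotone in hedge width (all else equal the canopy shades more ground)
  fd <- vapply(c(1, 2, 3, 4), function(w)
    daily_fipar(3, w, 90, 0.4, 41.5, 0.85, 205)$fiPAR_d, numeric(1))
  expect_true(all(diff(fd) > 0))
})

test_that("forward reflectance model honors its limits and ranges", {
  leaf <- list(N_leaf = 1.6, Cab = 40, Car = 10, Cbrown = 0.05,
               Cw = 0.007, Cdm = 0.007, average_leaf_angle_deg = 57,
               hotspot = 0.2)
  bare <- rt_forward(c(leaf, LAI = 0))
  expect_equal(bare$reflectance, rt_default_soil())
  expect_equal(bare$fiPAR, 0)
  # dense canopy saturates to the leaf spectrum (horizontal leaves, high K)
  leaf30 <- leaf; leaf30$average_leaf_angle_deg <- 30
  dense <- rt_forward(c(leaf30, LAI = 6))
  sparse <- rt_forward(c(leaf30, LAI = 5.9))
  expect_lt(max(abs(dense$reflectance - sparse$reflectance)), 1e-3)
  # NIR reflectance non-decreasing in LAI when leaf NIR > soil NIR
  nir <- vapply(seq(0, 6, 0.5), function(L)
    rt_forward(c(leaf, LAI = L))$reflectance[6], numeric(1))
  leaf_nir <- rt_forward(c(leaf, LAI = 6))$reflectance[6]
  if (leaf_nir > rt_default_soil()[6]) expect_true(all(diff(nir) >= 0))
  expect_error(rt_forward(c(leaf, LAI = 7)), "range")
  expect_error(rt_forward(list(LAI = 1)), "missing")
})

test_that("training sets are seed-reproducible and models serialize losslessly", {
  s1 <- rt_simulate(200, seed = 5)
  s2 <- rt_simulate(200, seed = 5)
  expect_identical(s1$reflectance, s2$reflectance)
  expect_identical(s1$params, s2$params)
  expect_error(rt_train(50), "n_samples")
  m <- rt_train(150, seed = 5, engine = "nnet", hidden = 4)
  f <- tempfile(fileext = ".json")
  rt_model_to_json(m, f)
  m2 <- rt_model_from_json(f)
  probe <- rt_simulate(20, seed = 6)$reflectance
  expect_equal(rt_predict(m2, probe), rt_predict(m, probe),
               tolerance = 1e-12)
  mk <- rt_train(150, seed = 5, engine = "knn")
  rt_model_to_json(mk, f)
  expect_equal(rt_predict(rt_model_from_json(f), probe),
               rt_predict(mk, probe), tolerance = 1e-12)
})

test_that("inversion recovers the intercepted fraction from held-out spectra", {
  m <- rt_train(2000, seed = 42)
  ho <- rt_simulate(300, seed = 43)
  pr <- rt_predict(m, ho$reflectance)
  expect_lt(sqrt(mean((pr$fiPAR - ho$fiPAR)^2)), 0.02)
  # predictions stay inside the training range of each target
  expect_true(all(pr$LAI >= 0 & pr$LAI <= 6))
  expect_true(all(pr$fiPAR >= 0 & pr$fiPAR <= 1))
})

test_that("k-NN engine memorizes training spectra and inputs are validated", {
  mk <- rt_train(200, seed = 8, engine = "knn")
  sim <- rt_simulate(200, seed = 8)
  pr <- rt_predict(mk, sim$reflectance[7, , drop = FALSE])
  expect_equal(pr$LAI, sim$params$LAI[7], tolerance = 1e-9)
  expect_error(rt_predict(mk, rep(0, 6)), "zero")
  expect_error(rt_predict(mk, c(0.1, 0.2, 0.3, 0.4, 0.5, 1.2)), "0, 1")
})

test_that("stepwise regression selects true predictors and rejects noise", {
  set.seed(21)
  n <- 60
  cand <- data.frame(NDVI = runif(n, 0.2, 0.9), GNDVI = runif(n, 0.2, 0.8),
                     MCARI = runif(n, 0, 0.3))
  y <- 2 + 3 * cand$NDVI
  # exact linear responses trip lm's perfect-fit warning by design
  eq <- suppressWarnings(stepwise_regression(y, cand))
  expect_setequal(names(eq$coefficients), "NDVI")
  expect_equal(eq$intercept, 2, tolerance = 1e-8)
  expect_equal(eq$coefficients[["NDVI"]], 3, tolerance = 1e-8)
  expect_equal(eq$r_squared, 1)
  # duplicated candidate: only one copy enters, the lower column index
  cand2 <- cand
  cand2$NDVI2 <- cand$NDVI
  eq2 <- suppressWarnings(stepwise_regression(y, cand2))
  expect_setequal(names(eq2$coefficients), "NDVI")
  expect_error(stepwise_regression(y[1:5], cand[1:5, ]), "10")
})

test_that("pure-noise responses enter at most at the nominal rate", {
  set.seed(31)
  n_rep <- 1000; n <- 30
  entered <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    eq <- stepwise_regression(rnorm(n), cand)
    entered[r, ] <- c("a", "b", "c") %in% names(eq$coefficients)
  }
  rate <- colMeans(entered)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_true(all(rate <= bound))
})

test_that("trait equations evaluate the published almond calibrations", {
  eqs <- almond_trait_equations()
  lai <- apply_trait_equation(eqs$lai,
                              list(NDRE = 0.5, NDVI = 0.8, Volume = 20))
  expect_equal(lai$value, 0.49 + 1.98 * 0.5 - 1.06 * 0.8 + 0.03 * 20,
               tolerance = 1e-12)
  expect_equal(lai$value, 1.232, tolerance = 1e-9)
  fip <- apply_trait_equation(eqs$fipar_d,
                              list(GNDVI = 0.6, MCARI = 0.1, NDRE = 0.4,
                                   NDVI = 0.7, Volume = 15))
  # hand arithmetic: -0.24 + 0.372 + 0.695 + 0.476 - 0.455 + 0.15
  expect_equal(fip$value, 0.998, tolerance = 1e-9)
  # all-zero inputs return the intercept; negative evaluations floor at 0
  z <- apply_trait_equation(eqs$lai, list(NDRE = 0, NDVI = 0, Volume = 0))
  expect_equal(z$value, 0.49)
  neg <- apply_trait_equation(eqs$lai, list(NDRE = 0, NDVI = 1, Volume = 0))
  expect_equal(neg$value, 0)
  expect_equal(neg$flag, "floored")
  expect_error(apply_trait_equation(eqs$lai, list(NDRE = 0.5)), "missing")
})
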