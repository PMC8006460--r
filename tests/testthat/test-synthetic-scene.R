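test_that("synthetic weather is reproducible and physically plausible", {
  w1 <- generate_weather(seed = 42)
  w2 <- generate_weather(seed = 42)
  expect_identical(w1$table, w2$table)
  # nighttime irradiance is exactly zero, midday peak near 930 W m-2
  night <- w1$table$Rs_Wm2[w1$table$decimal_hour < 4]
  expect_true(all(night == 0))
  expect_equal(max(w1$table$Rs_Wm2), 930, tolerance = 1e-6)
  # acquisition-time state: hot dry midday with VPD in 2-4 kPa
  expect_gt(w1$meteo$Ta, 273.15 + 30)
  expect_lt(w1$meteo$Ta, 273.15 + 35)
  expect_gte(w1$meteo$VPD, 2)
  expect_lte(w1$meteo$VPD, 4)
})

test_that("the orchard generator lays out trees and encodes stress in Tc", {
  cfg <- orchard_config(n_rows = 2, trees_per_row = 5)
  w <- generate_weather(seed = 7)
  sc <- generate_orchard(cfg, w, seed = 7)
  expect_equal(nrow(sc$truth), 10)
  expect_equal(nrow(sc$trees), 10)
  # bit-identical rasters from the same seed
  sc2 <- generate_orchard(cfg, w, seed = 7)
  expect_identical(sc$dsm$values, sc2$dsm$values)
  expect_identical(sc$thermal$values, sc2$thermal$values)
  expect_identical(sc$bands$bands[[3]]$values, sc2$bands$bands[[3]]$values)
  # truth invariants: unstressed canopy within 1 K of air; Tc monotone in s
  Ta <- w$meteo$Ta
  expect_true(all(sc$truth$Tc_true - Ta >= 1 - 1e-9))
  ord <- order(sc$truth$stress)
  expect_true(all(diff(sc$truth$Tc_true[ord]) >= 0))
  s0 <- generate_orchard(orchard_config(n_rows = 2, trees_per_row = 5,
                                        stress_range = c(0, 0)), w, seed = 7)
  expect_true(all(abs(s0$truth$Tc_true - Ta - 1) < 1e-9))
  # invalid configurations are rejected
  expect_error(orchard_config(height_range = c(2, 9)))
  expect_error(orchard_config(cell_ms = 0.13), "divide")
})

test_that("scene bundles roundtrip through the on-disk text layout", {
  cfg <- orchard_config(n_rows = 1, trees_per_row = 3)
  sc <- generate_orchard(cfg, generate_weather(seed = 3), seed = 3)
  d <- file.path(tempdir(), "scene-roundtrip")
  save_scene(sc, d)
  expect_true(all(file.exists(file.path(d, c("dsm.asc", "thermal.asc",
                                             "band_6.asc", "trees.csv",
                                             "truth.csv", "weather.csv",
                                             "config.yaml")))))
  sc2 <- load_scene(d)
  expect_identical(sc2$dsm$values, sc$dsm$values)
  expect_identical(sc2$thermal$values, sc$thermal$values)
  expect_equal(sc2$truth$LAI_true, sc$truth$LAI_true)
  expect_equal(sc2$trees$cell_xmin, sc$trees$cell_xmin)
  unlink(d, recursive = TRUE)
})

test_that("structure stage recovers generator heights within the noise budget", {
  res <- run_pipeline(seed = 42)
  st <- res$structure$structure
  truth <- res$scene$truth
  sigma <- res$scene$config$sigma_dsm
  ok <- st$flag == ""
  expect_gte(sum(ok), 30)
  rmse <- sqrt(mean((st$height_max[ok] - truth$height_true[ok])^2))
  expect_lte(rmse, 2 * sigma)
  # crown areas land within the geometric footprint of the half-ellipsoids
  foot <- pi * truth$crown_radius_true^2
  expect_gt(cor(st$crown_area[ok], foot[ok]), 0.8)
})

test_that("traits stage recovers tree LAI and fiPAR from noiseless spectra", {
  # 40 trees: low-LAI crowns near the NDVI threshold may legitimately go
  # undetected, and the recovery statistic needs >= 30 detected trees
  cfg <- orchard_config(n_rows = 4, sigma_reflectance = 1e-6)
  sc <- generate_orchard(cfg, generate_weather(seed = 42), seed = 42)
  st <- run_structure(sc)
  tr <- run_traits(sc, st)
  ok <- !is.na(tr$traits$LAI_rt_canopy)
  expect_gte(sum(ok), 30)
  rmse <- sqrt(mean((tr$traits$LAI_rt_canopy[ok] -
                       sc$truth$LAI_true[ok])^2))
  expect_lte(rmse, 0.4)
  # canopy fiPAR tracks the forward-model truth closely
  K <- extinction_coefficient(
    chi_from_leaf_angle(sc$leaf_params$average_leaf_angle_deg),
    sc$weather$zenith_deg)
  fip_true <- 1 - exp(-K * sc$truth$LAI_true)
  expect_lte(sqrt(mean((tr$traits$fiPAR_rt_canopy[ok] - fip_true[ok])^2)),
             0.05)
})

test_that("pipeline water stress rises with the imposed stress factor", {
  res <- run_pipeline(seed = 101)
  ws <- res$water_status[!is.na(res$water_status$CWSI), ]
  expect_gte(nrow(ws), 30)
  expect_true(all(ws$CWSI >= 0 & ws$CWSI <= 1))
  expect_gte(cor(ws$stress, ws$CWSI, method = "spearman"), 0.9)
  # unstressed vs fully stressed scenes separate cleanly in mean CWSI
  cfg <- orchard_config(n_rows = 2, trees_per_row = 5)
  w <- generate_weather(seed = 11)
  model <- res$traits$model
  lo <- run_pipeline(orchard_config(n_rows = 2, trees_per_row = 5,
                                    stress_range = c(0, 0)),
                     seed = 11, model = model)
  hi <- run_pipeline(orchard_config(n_rows = 2, trees_per_row = 5,
                                    stress_range = c(1, 1)),
                     seed = 11, model = model)
  expect_lt(mean(lo$water_status$CWSI, na.rm = TRUE) + 0.2,
            mean(hi$water_status$CWSI, na.rm = TRUE))
  # Tc - Ta diagnostic carries the same ordering
  expect_gt(cor(ws$stress, ws$Tc_minus_Ta), 0.9)
})
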