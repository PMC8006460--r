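test_that("canopy height model subtracts terrain, clips and propagates nodata", {
  dsm <- raster_grid(matrix(c(10, 7, 9, -9999), 2, 2), 1, origin = c(0, 2))
  dtm <- raster_grid(matrix(c(7.5, 7.5, -9999, 8), 2, 2), 1,
                     origin = c(0, 2))
  chm <- compute_chm(dsm, dtm)
  expect_equal(chm$values[1, 1], 2.5)
  expect_equal(chm$values[2, 1], 0)            # DSM below DTM clips to 0
  expect_equal(chm$values[1, 2], -9999)        # DTM nodata propagates
  expect_equal(chm$values[2, 2], -9999)        # DSM nodata propagates
  expect_error(compute_chm(dsm, uniform_raster(3, 3, 1)), "differ")
})

test_that("threshold classification assigns each pixel exactly one class", {
  sc <- toy_scene(data.frame(x = c(6, 14), y = c(7.5, 7.5)),
                  heights = c(4, 3), radii = c(1.5, 1.5), lais = c(1.8, 1.2))
  chm <- compute_chm(sc$dsm, sc$dtm)
  cls <- classify_scene(sc$bands, chm)
  v <- raster_values(cls$classes)
  expect_true(all(v[!is.na(v)] %in% 1:4))
  # crowns (from the forward model at LAI >= 1.2) come out vegetation
  expect_true(mean(v[sc$owner > 0] == 1) > 0.9)
  # bright bare soil is sunlit_soil (NIR 0.363 >= 0.15)
  expect_true(all(v[sc$owner == 0] == 3))
  # all-soil scene yields zero vegetation pixels
  soil_only <- toy_scene(data.frame(x = 6, y = 7.5), heights = 0.01,
                         radii = 0.01, lais = 0.1)
  v0 <- raster_values(classify_scene(soil_only$bands,
                                     compute_chm(soil_only$dsm,
                                                 soil_only$dtm))$classes)
  expect_equal(sum(v0 == 1, na.rm = TRUE), 0)
  # dark pixels with low NDVI go to shaded_soil
  dark <- lapply(1:6, function(b) uniform_raster(10, 10, 0.05))
  vd <- raster_values(classify_scene(band_stack(dark),
                                     uniform_raster(10, 10, 0))$classes)
  expect_true(all(vd == 4))
})

test_that("watershed splits two crowns near their generator footprints", {
  sc <- toy_scene(data.frame(x = c(6, 11), y = c(7.5, 7.5)),
                  heights = c(4, 3.5), radii = c(1.6, 1.4),
                  lais = c(1.8, 1.5))
  chm <- compute_chm(sc$dsm, sc$dtm)
  cls <- classify_scene(sc$bands, chm)
  crowns <- segment_crowns(cls, chm, sc$trees)
  lab <- raster_values(crowns$labels)
  expect_setequal(setdiff(unique(as.vector(lab)), 0), c(1, 2))
  for (k in 1:2) {
    got <- sum(lab == k) * sc$cell^2
    truth <- sum(sc$owner == k) * sc$cell^2
    expect_lt(abs(got - truth) / truth, 0.10)
  }
  expect_equal(crowns$flags, c("", ""))
})

test_that("an isolated crown collects all vegetation; bare scenes flag all trees", {
  sc <- toy_scene(data.frame(x = 10, y = 7.5), heights = 4, radii = 1.6,
                  lais = 1.8)
  chm <- compute_chm(sc$dsm, sc$dtm)
  cls <- classify_scene(sc$bands, chm)
  crowns <- segment_crowns(cls, chm, sc$trees)
  lab <- raster_values(crowns$labels)
  veg <- class_mask(cls, "vegetation")
  expect_equal(sum(lab == 1), sum(veg))
  # no vegetation at all
  soil_only <- toy_scene(data.frame(x = 10, y = 7.5), heights = 0.01,
                         radii = 0.01, lais = 0.1)
  chm0 <- compute_chm(soil_only$dsm, soil_only$dtm)
  cls0 <- classify_scene(soil_only$bands, chm0)
  cr0 <- segment_crowns(cls0, chm0, soil_only$trees)
  expect_equal(cr0$flags, "empty_crown")
  expect_true(all(raster_values(cr0$labels) == 0))
})

test_that("crown labels partition vegetation pixels", {
  sc <- toy_scene(data.frame(x = c(6, 11), y = c(7.5, 7.5)),
                  heights = c(4, 3.5), radii = c(1.6, 1.4),
                  lais = c(1.8, 1.5))
  chm <- compute_chm(sc$dsm, sc$dtm)
  cls <- classify_scene(sc$bands, chm)
  crowns <- segment_crowns(cls, chm, sc$trees)
  lab <- raster_values(crowns$labels)
  veg <- class_mask(cls, "vegetation")
  per_tree <- sum(lab > 0)
  unassigned <- sum(veg & lab == 0)
  expect_equal(per_tree + unassigned, sum(veg))
})

test_that("structure metrics follow the stated area/volume arithmetic", {
  # 100 crown pixels at 0.5 m cells (0.25 m2), uniform CHM 2 m
  lab <- matrix(0, 20, 20); lab[6:15, 6:15] <- 1
  labels <- raster_grid(lab, 0.5, origin = c(0, 10), nodata = -1)
  chm <- uniform_raster(20, 20, 2, cell = 0.5)
  trees <- data.frame(tree_id = "T1", insertion_height = 1)
  m <- tree_structure_metrics(list(labels = labels), chm, trees)
  expect_equal(m$crown_area, 25)
  expect_equal(m$volume_total, 50)
  expect_equal(m$volume_net, 50 - 25 * 1)
  expect_equal(m$height_max, 2)
  expect_equal(m$height_mean, 2)
  # 10 m2 crown of CHM 4, insertion 1 -> 40 total, 30 net; insertion 0
  lab2 <- matrix(0, 10, 10); lab2[1:10, 1] <- 1   # 10 px of 1 m2
  labels2 <- raster_grid(lab2, 1, origin = c(0, 10), nodata = -1)
  chm2 <- uniform_raster(10, 10, 4)
  m2 <- tree_structure_metrics(list(labels = labels2), chm2,
                               data.frame(tree_id = "a",
                                          insertion_height = 1))
  expect_equal(c(m2$volume_total, m2$volume_net), c(40, 30))
  m3 <- tree_structure_metrics(list(labels = labels2), chm2,
                               data.frame(tree_id = "a",
                                          insertion_height = 0))
  expect_equal(m3$volume_net, m3$volume_total)
  # empty crown: zero metrics plus flag
  m4 <- tree_structure_metrics(list(labels = labels2), chm2,
                               data.frame(tree_id = c("a", "b"),
                                          insertion_height = c(1, 1)))
  expect_equal(m4$flag[2], "empty_crown")
  expect_equal(m4$volume_total[2], 0)
  # metrics invariant to tree ordering
  sc <- toy_scene(data.frame(x = c(6, 11), y = c(7.5, 7.5)),
                  heights = c(4, 3.5), radii = c(1.6, 1.4),
                  lais = c(1.8, 1.5))
  chm5 <- compute_chm(sc$dsm, sc$dtm)
  cls5 <- classify_scene(sc$bands, chm5)
  cr5 <- segment_crowns(cls5, chm5, sc$trees)
  met <- tree_structure_metrics(cr5, chm5, sc$trees)
  trees_rev <- sc$trees[2:1, ]
  cr5r <- segment_crowns(cls5, chm5, trees_rev)
  met_r <- tree_structure_metrics(cr5r, chm5, trees_rev)
  expect_equal(met_r[match(met$tree_id, met_r$tree_id), "crown_area"],
               met$crown_area)
})
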