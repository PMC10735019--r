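test_that("area counts object pixels, holes excluded", {
  expect_equal(track_area(track_object(cbind(0, 0), 100)), 1)
  expect_equal(track_area(disk_object(3)), 29)

  ring <- expand.grid(row = 0:2, col = 0:2)
  ring <- ring[!(ring$row == 1 & ring$col == 1), ]
  expect_equal(track_area(track_object(as.matrix(ring), rep(80, 8))), 8)

  expect_error(track_object(cbind(numeric(0), numeric(0)), numeric(0)),
               "at least one pixel")
})

test_that("diameter is the longest centroid-crossing border chord", {
  expect_equal(track_diameter(track_object(cbind(0, 0), 100)), 0)
  row5 <- track_object(cbind(0, 0:4), rep(100, 5))
  expect_equal(track_diameter(row5), 4)
  expect_equal(track_diameter(disk_object(3)), 6)
})

test_that("aspect ratio follows the moment-equivalent ellipse", {
  expect_equal(track_aspect(disk_object(5)), 1, tolerance = 0.05)

  rect <- track_object(as.matrix(expand.grid(row = 0:2, col = 0:8)),
                       rep(100, 27))
  expect_equal(track_aspect(rect), 3, tolerance = 0.01)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    xy <- unique(cbind(sample(0:12, n, TRUE), sample(0:12, n, TRUE)))
    obj <- track_object(xy, rep(100, nrow(xy)))
    expect_gte(track_aspect(obj), 1)
  }
})

test_that("roundness is P^2 / (4 pi A) under the declared perimeter estimator", {
  # 3x9 rectangle: border chain of 20 unit steps
  rect <- track_object(as.matrix(expand.grid(row = 0:2, col = 0:8)),
                       rep(100, 27))
  expect_equal(track_perimeter(rect), 20)
  expect_equal(track_roundness(rect), 20^2 / (4 * pi * 27), tolerance = 1e-10)

  # digital disks approach the ideal circle value 1
  expect_gte(track_roundness(disk_object(8)), 0.95)
  expect_lte(track_roundness(disk_object(8)), 1.15)
  expect_gte(track_roundness(disk_object(20)), 0.95)
  expect_lte(track_roundness(disk_object(20)), 1.15)
})

test_that("heterogeneity counts pixels deviating more than 10% from the mean", {
  uni <- track_object(cbind(0, 0:9), rep(120, 10))
  expect_equal(track_heterogeneity(uni), 0)

  mix <- track_object(cbind(0, 0:9), c(rep(100, 9), 130))
  expect_equal(track_heterogeneity(mix), 0.1)

  alt <- track_object(cbind(0, 0:9), rep(c(10, 200), 5))
  expect_equal(track_heterogeneity(alt), 1)

  zero <- track_object(cbind(0, 0:3), rep(0, 4))
  expect_equal(track_heterogeneity(zero), 0)
})

test_that("clumpiness is heterogeneity after eroding the border rim", {
  # flat core with a gradient rim: rim heterogeneity vanishes after erosion
  xy <- disk_coords(5, c(5, 5))
  d <- sqrt((xy[, 1] - 5)^2 + (xy[, 2] - 5)^2)
  ints <- ifelse(d > 4, 150, 60)  # bright one-pixel rim band
  obj <- track_object(xy, ints)
  expect_gt(track_heterogeneity(obj), 0.2)
  expect_equal(track_clumpiness(obj), 0)

  # object smaller than the structuring element erodes to nothing
  tiny <- track_object(cbind(c(0, 0), c(0, 1)), c(100, 200))
  expect_equal(track_clumpiness(tiny), 0)

  # 5x5 uniform block with one deviant centre pixel: eroded core is 3x3
  xy5 <- as.matrix(expand.grid(row = 0:4, col = 0:4))
  ints5 <- rep(100, 25)
  ints5[xy5[, 1] == 2 & xy5[, 2] == 2] <- 190
  expect_equal(track_clumpiness(track_object(xy5, ints5)), 1 / 9)
})

test_that("descriptors are invariant under translation and 90-degree rotation", {
  set.seed(77)
  for (i in 1:10) {
    xy <- unique(cbind(sample(0:10, 25, TRUE), sample(0:10, 25, TRUE)))
    ints <- sample(40:160, nrow(xy), TRUE)
    obj <- track_object(xy, ints)
    shifted <- track_object(xy + matrix(c(7, 13), nrow(xy), 2, byrow = TRUE),
                            ints)
    rotated <- track_object(cbind(xy[, 2], max(xy[, 1]) - xy[, 1]), ints)

    d0 <- track_descriptors(obj)
    expect_equal(track_descriptors(shifted), d0)
    dr <- track_descriptors(rotated)
    expect_equal(dr[c("area", "heterogeneity", "clumpiness")],
                 d0[c("area", "heterogeneity", "clumpiness")])
    expect_equal(dr["diameter"], d0["diameter"], tolerance = 1e-8)
    expect_equal(dr["aspect"], d0["aspect"], tolerance = 1e-8)
    expect_equal(dr["roundness"], d0["roundness"], tolerance = 1e-8)
  }
})

test_that("summary statistics follow the declared interpolation rules", {
  const <- summarize_descriptor(rep(4.2, 7))
  expect_equal(unname(const[c("iqr", "sd")]), c(0, 0))
  expect_equal(unname(const[c("mean", "median", "p5", "p90")]), rep(4.2, 4))

  s <- summarize_descriptor(1:100)
  expect_equal(unname(s["median"]), 50.5)
  expect_equal(unname(s["p90"]), 90.1)
  expect_equal(unname(s["p5"]), 5.95)
  expect_equal(unname(s["iqr"]), 49.5)

  set.seed(13)
  for (i in 1:20) {
    v <- rnorm(sample(1:50, 1))
    s <- summarize_descriptor(v)
    expect_lte(s["p5"], s["median"])
    expect_lte(s["median"], s["p90"])
    expect_gte(s["iqr"], 0)
    expect_gte(s["sd"], 0)
  }

  expect_error(summarize_descriptor(numeric(0)), "empty")
})

test_that("featurize_image produces the 36-statistic record", {
  one <- disk_object(3)
  rec <- featurize_image(list(one))
  expect_setequal(setdiff(names(rec), c("track_count", "label", "name")),
                  feature_names())
  expect_equal(rec$track_count, 1)
  expect_equal(rec$mean_area, 29)
  expect_equal(rec$sd_area, 0)
  expect_equal(rec$p90_area, 29)

  # three hand-made objects: every cell equals the independent computation
  objs <- list(disk_object(2, intensity = 90),
               track_object(cbind(0, 0:4), c(100, 100, 100, 100, 140)),
               disk_object(4, intensity = 60))
  rec3 <- featurize_image(objs, name = "toy")
  desc <- sapply(objs, track_descriptors)
  for (d in rownames(desc)) {
    v <- desc[d, ]
    expect_equal(rec3[[paste0("mean_", d)]], mean(v))
    expect_equal(rec3[[paste0("median_", d)]], median(v))
    expect_equal(rec3[[paste0("iqr_", d)]], unname(quantile(v, 0.75) - quantile(v, 0.25)))
    expect_equal(rec3[[paste0("sd_", d)]], sd(v))
    expect_equal(rec3[[paste0("p5_", d)]], unname(quantile(v, 0.05)))
    expect_equal(rec3[[paste0("p90_", d)]], unname(quantile(v, 0.90)))
  }
  expect_equal(rec3$track_count, 3)

  expect_error(featurize_image(list()), "zero segmented objects")

  # purity: identical inputs give identical records
  expect_identical(featurize_image(objs), featurize_image(objs))
})

test_that("pixel areas convert to square micrometres via the field of view", {
  expect_equal(px_area_to_um2(0), 0)
  expect_equal(px_area_to_um2(1), (211 / 1280) * (158 / 962))
  expect_equal(px_area_to_um2(30), 30 * (211 / 1280) * (158 / 962))
  expect_equal(px_area_to_um2(1), 0.02708, tolerance = 1e-3)
  expect_error(px_area_to_um2(-1), "non-negative")
})

test_that("parameter histograms are normalized", {
  set.seed(3)
  objs <- lapply(1:12, function(i) disk_object(sample(2:5, 1),
                                               intensity = sample(50:90, 1)))
  h <- parameter_histograms(objs)
  for (d in names(h)) expect_equal(sum(h[[d]]$density), 1, tolerance = 1e-9)

  h1 <- parameter_histograms(list(disk_object(3)))
  for (d in names(h1)) expect_equal(sum(h1[[d]]$density > 0), 1)
})
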