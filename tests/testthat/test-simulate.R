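test_that("decay sampling reproduces the tabulated channel intensities", {
  ch <- bnc_channels()
  expect_equal(sum(ch$intensity), 1)
  expect_true(all(ch$alpha_energy > 0) && all(ch$li_energy > 0))

  draws <- sample_bnc_decay(10000, seed = 101)
  f <- mean(draws$channel == "alpha1_li1")
  se <- sqrt(0.937 * 0.063 / 10000)
  expect_lt(abs(f - 0.937), 3 * se)

  a1 <- draws[draws$channel == "alpha1_li1", ]
  expect_true(all(a1$alpha_energy == 1.471))
  expect_true(all(a1$li_energy == 0.839))
  a0 <- draws[draws$channel == "alpha0_li0", ]
  expect_true(all(a0$alpha_energy == 1.777))
  expect_true(all(a0$li_energy == 1.013))

  expect_error(sample_bnc_decay(0), "positive")
  expect_identical(sample_bnc_decay(50, seed = 7), sample_bnc_decay(50, seed = 7))
})

test_that("energy-to-area calibration interpolates the anchors and decreases", {
  expect_equal(energy_to_pit_area(1.47), 25)
  expect_equal(energy_to_pit_area(1.0), 33)
  expect_equal(energy_to_pit_area(0.5), 41)

  grid <- seq(0.5, 1.47, length.out = 50)
  areas <- energy_to_pit_area(grid)
  expect_true(all(diff(areas) < 0))

  # clamped outside the anchored range
  expect_equal(energy_to_pit_area(0.2), 41)
  expect_equal(energy_to_pit_area(2.0), 25)
  expect_error(energy_to_pit_area(-0.1), "non-negative")
  expect_error(energy_area_calibration(
    data.frame(energy = c(0.5, 1), area = c(30, 30))), "decreasing")
})

test_that("rendering an empty scene leaves no pixel near the threshold", {
  img <- render_image(data.frame(), acquisition_condition(),
                      width = 100, height = 80, seed = 2)
  expect_equal(dim(img$pixels), c(80, 100))
  expect_gt(min(img$pixels), 128 + 20)
  expect_equal(img$label, "Accepted")

  bad <- data.frame(center_row = 200, center_col = 10, semi_major = 3,
                    semi_minor = 3, orientation = 0, core_intensity = 60,
                    edge_width = 1.5)
  expect_error(render_image(bad, width = 100, height = 80), "within the frame")
})

test_that("a rendered pit round-trips through segmentation at its drawn size", {
  pits <- data.frame(center_row = 40, center_col = 50, semi_major = 4,
                     semi_minor = 3, orientation = 0.7, core_intensity = 60,
                     edge_width = 1.5)
  img <- render_image(pits, acquisition_condition(), width = 100, height = 80,
                      seed = 11)
  objs <- segment_image(img$pixels)
  expect_length(objs, 1)
  expect_lt(abs(track_area(objs[[1]]) - pi * 4 * 3) / (pi * 4 * 3), 0.2)
})

test_that("zero-magnitude corruption is the identity, pixel for pixel", {
  set.seed(6)
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_identical(apply_light_offset(img, 0), img)
  expect_identical(apply_defocus(img, 0), img)
})

test_that("light and focus corruption shift descriptors as observed", {
  sp <- sample_pit_specs(90, width = 480, height = 480, seed = 15)
  base <- render_image(sp, acquisition_condition(), width = 480, height = 480,
                       seed = 16)
  clamp8 <- function(x) matrix(as.integer(pmin(pmax(round(x), 0), 255)),
                               nrow(x), ncol(x))
  areas0 <- vapply(segment_image(base$pixels), track_area, numeric(1))

  over <- clamp8(apply_light_offset(base$pixels, 0.5))
  areas_over <- vapply(segment_image(over), track_area, numeric(1))
  expect_lt(mean(areas_over), mean(areas0))

  under <- clamp8(apply_light_offset(base$pixels, -0.5, seed = 17))
  areas_under <- vapply(segment_image(under), track_area, numeric(1))
  expect_gt(sum(areas_under <= 4), sum(areas0 <= 4))

  # defocus distorts the outlines of the resolved tracks (>= 5 px; the
  # isolated speckle pixels it also creates are a separate signature)
  defoc <- clamp8(apply_defocus(base$pixels, 2.5, seed = 18))
  objs_def <- segment_image(defoc)
  p90_round <- function(objs) {
    r <- vapply(objs, track_roundness, numeric(1))
    a <- vapply(objs, track_area, numeric(1))
    quantile(r[a >= 5], 0.9)
  }
  expect_gt(p90_round(objs_def), p90_round(segment_image(base$pixels)))
  expect_false(length(objs_def) == nrow(sp))
})

test_that("adequate scenes have their area-histogram mode in 30-40 px", {
  areas <- unlist(lapply(1:3, function(i) {
    sp <- sample_pit_specs(250, width = 640, height = 640, seed = 100 + i)
    img <- render_image(sp, acquisition_condition(), width = 640, height = 640,
                        seed = 200 + i)
    vapply(segment_image(img$pixels), track_area, numeric(1))
  }))
  h <- hist(areas, breaks = seq(0, max(areas) + 10, 10), plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  expect_gte(mode_mid, 30)
  expect_lte(mode_mid, 40)
})

test_that("dataset generation is seeded, exactly split and labelled", {
  d1 <- generate_dataset(6, fraction_adequate = 0.5, width = 160, height = 160,
                         seed = 5)
  d2 <- generate_dataset(6, fraction_adequate = 0.5, width = 160, height = 160,
                         seed = 5)
  expect_identical(lapply(d1, `[[`, "pixels"), lapply(d2, `[[`, "pixels"))
  labels <- vapply(d1, `[[`, character(1), "label")
  expect_equal(sum(labels == "Accepted"), 3)
  expect_equal(sum(labels == "Rejected"), 3)
  for (im in d1) {
    expect_equal(im$label,
                 if (is_adequate(im$condition)) "Accepted" else "Rejected")
  }
  expect_error(generate_dataset(4, fraction_adequate = 1.5), "fraction")
})

test_that("srm mode renders the bimodal reference-material pit sizes", {
  sp <- sample_pit_specs(400, width = 900, height = 900, mode = "srm",
                         seed = 61)
  areas <- pi * sp$semi_major * sp$semi_minor
  med <- as.numeric(tapply(areas, areas > 30, median))
  expect_equal(sort(med), c(12, 55), tolerance = 0.1)
  # two well-separated size populations
  expect_gt(mean(areas > 30), 0.3)
  expect_lt(mean(areas > 30), 0.7)
})

test_that("images survive a PNG and TIFF write/read round trip", {
  img <- render_image(sample_pit_specs(10, width = 120, height = 100, seed = 8),
                      acquisition_condition(), width = 120, height = 100,
                      seed = 9)
  fp <- tempfile(fileext = ".png")
  ft <- tempfile(fileext = ".tiff")
  write_gray_image(img, fp)
  write_gray_image(img, ft)
  expect_identical(read_gray_image(fp), img$pixels)
  expect_identical(read_gray_image(ft), img$pixels)
})
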