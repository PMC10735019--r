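#' Decay channels of the boron neutron capture reaction
#'
#' The \eqn{^{10}}B(n,\eqn{\alpha})\eqn{^{7}}Li reaction proceeds through two
#' channels: the dominant one (93.7%) leaves \eqn{^{7}}Li in its excited
#' state (alpha 1.471 MeV, Li 0.839 MeV); the minor one (6.3%) emits
#' alpha 1.777 MeV and Li 1.013 MeV.
#'
#' @return data frame with columns `channel`, `alpha_energy`, `li_energy`
#'   (MeV) and `intensity` (fractions summing to 1).
#' @export
bnc_channels <- function() {
  data.frame(
    channel = c("alpha0_li0", "alpha1_li1"),
    alpha_energy = c(1.777, 1.471),
    li_energy = c(1.013, 0.839),
    intensity = c(0.063, 0.937),
    stringsAsFactors = FALSE
  )
}

#' Sample boron neutron capture decays
#'
#' @param n number of decays (>= 1).
#' @param seed optional integer seed.
#' @return data frame with one row per decay: `channel`, `alpha_energy`,
#'   `li_energy` (the channel's tabulated energies, MeV).
#' @export
sample_bnc_decay <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    .stopf("`n` must be a positive count")
  }
  ch <- bnc_channels()
  with_seed(seed, {
    i <- sample.int(nrow(ch), n, replace = TRUE, prob = ch$intensity)
    data.frame(channel = ch$channel[i],
               alpha_energy = ch$alpha_energy[i],
               li_energy = ch$li_energy[i],
               stringsAsFactors = FALSE)
  })
}

#' Energy-to-pit-area calibration
#'
#' Anchored to monoenergetic alpha irradiations: mean pit areas of 41, 33 and
#' 25 px at 0.5, 1.0 and 1.47 MeV. Lower-energy particles deposit their energy
#' closer to the Bragg peak near the detector surface and etch into larger
#' pits, so mean area decreases strictly with energy over the anchored range.
#' Reference-material (SRM) pit-size anchors: alpha ~12 px, Li ~55 px.
#'
#' @param anchors data frame with `energy` (MeV) and `area` (px) columns.
#' @param srm_anchors named vector with elements `alpha` and `li` (px).
#' @param rel_sd relative standard deviation of per-pit area around the mean.
#' @return an `energy_area_calibration`.
#' @export
energy_area_calibration <- function(
    anchors = data.frame(energy = c(0.5, 1.0, 1.47), area = c(41, 33, 25)),
    srm_anchors = c(alpha = 12, li = 55),
    rel_sd = 0.22) {
  anchors <- anchors[order(anchors$energy), ]
  if (any(diff(anchors$area) >= 0)) {
    .stopf("mean pit area must be strictly decreasing in energy")
  }
  structure(list(anchors = anchors, srm_anchors = srm_anchors, rel_sd = rel_sd),
            class = "energy_area_calibration")
}

#' Mean pit area for a particle energy
#'
#' Piecewise-linear interpolation through the calibration anchors; energies
#' outside the anchored range are clamped to its ends.
#'
#' @param energy particle energy in MeV (vectorized, non-negative).
#' @param calibration an [energy_area_calibration()].
#' @return mean pit area in px.
#' @export
energy_to_pit_area <- function(energy, calibration = energy_area_calibration()) {
  if (any(energy < 0)) .stopf("energies must be non-negative")
  a <- calibration$anchors
  stats::approx(a$energy, a$area, xout = pmin(pmax(energy, min(a$energy)),
                                              max(a$energy)))$y
}

# Pit area model used by the generator. Above 0.5 MeV it follows the
# calibration; below it, shallow low-energy particles leave progressively
# smaller pits (linear down to ~6 px at zero energy), producing the
# small-area shoulder seen in adequate track images.
generator_pit_area <- function(energy, calibration) {
  a <- calibration$anchors
  e0 <- min(a$energy)
  out <- energy_to_pit_area(pmax(energy, e0), calibration)
  low <- energy < e0
  if (any(low)) {
    a0 <- a$area[a$energy == e0]
    out[low] <- 6 + (a0 - 6) * energy[low] / e0
  }
  out
}

# Residual energy at the detector surface for a particle emitted at a
# uniform depth within its range, with range ~ E^1.8 (alpha-like power law).
residual_energy <- function(e0, n) {
  e0 * (1 - runif(n))^(1 / 1.8)
}

#' The acquisition condition of a (synthetic) image
#'
#' `light_offset` 0 is adequate illumination; positive values over-light the
#' field (grey levels compressed towards white, tracks shrink), negative
#' values under-light it (background darkens and mottles, spurious small
#' objects appear). `defocus_sigma` is the Gaussian blur width in px of a
#' wrong lens-sample distance. `noise_sd` is the grey-level sd of sensor
#' noise.
#'
#' @param light_offset dimensionless, in \[-1, 1\].
#' @param defocus_sigma blur width in px, >= 0.
#' @param noise_sd grey levels.
#' @return an `acquisition_condition`.
#' @export
acquisition_condition <- function(light_offset = 0, defocus_sigma = 0,
                                  noise_sd = 6) {
  if (abs(light_offset) > 1) .stopf("`light_offset` must lie in [-1, 1]")
  if (defocus_sigma < 0) .stopf("`defocus_sigma` must be >= 0")
  structure(list(light_offset = light_offset, defocus_sigma = defocus_sigma,
                 noise_sd = noise_sd), class = "acquisition_condition")
}

# Tolerance band within which an image still counts as adequately acquired.
ADEQUATE_LIGHT_TOL <- 0.15
ADEQUATE_DEFOCUS_TOL <- 0.8

#' Is an acquisition condition within the adequate tolerance band?
#'
#' @param condition an [acquisition_condition()].
#' @return logical.
#' @export
is_adequate <- function(condition) {
  abs(condition$light_offset) <= ADEQUATE_LIGHT_TOL &&
    condition$defocus_sigma <= ADEQUATE_DEFOCUS_TOL
}

#' Sample pit render specs from the boron neutron capture size model
#'
#' Each track belongs to the alpha particle or the lithium ion of a capture
#' decay (equal chance of which partner entered the detector), with the
#' channel drawn from the tabulated intensities. The particle's residual
#' energy at the detector surface sets its mean pit area; the realized area
#' scatters log-normally around it. Aspect ratios peak near 1.1 and
#' orientations are uniform.
#'
#' @param n_pits number of pits.
#' @param width,height frame size in px.
#' @param calibration an [energy_area_calibration()].
#' @param mode `"bnc"` (both reaction products, continuous depth spread),
#'   `"monoenergetic"` (alphas at `energy` MeV) or `"srm"` (bimodal
#'   reference-material pit sizes).
#' @param energy nominal alpha energy for `mode = "monoenergetic"`.
#' @param seed optional integer seed.
#' @return data frame of pit render specs: `center_row`, `center_col`,
#'   `semi_major`, `semi_minor`, `orientation`, `core_intensity`,
#'   `edge_width`.
#' @export
sample_pit_specs <- function(n_pits, width = FRAME_WIDTH, height = FRAME_HEIGHT,
                             calibration = energy_area_calibration(),
                             mode = c("bnc", "monoenergetic", "srm"),
                             energy = 1.47, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    n <- n_pits
    if (n == 0) {
      return(data.frame(center_row = numeric(0), center_col = numeric(0),
                        semi_major = numeric(0), semi_minor = numeric(0),
                        orientation = numeric(0), core_intensity = numeric(0),
                        edge_width = numeric(0)))
    }
    mean_area <- switch(mode,
      bnc = {
        decays <- sample_bnc_decay(n)
        # the Li ion's higher LET gives it a higher registration
        # probability, so Li tracks slightly outnumber alpha tracks
        is_alpha <- runif(n) >= 0.6
        e0 <- ifelse(is_alpha, decays$alpha_energy, decays$li_energy)
        generator_pit_area(residual_energy(e0, n), calibration)
      },
      monoenergetic = rep(energy_to_pit_area(energy, calibration), n),
      srm = ifelse(runif(n) < 0.5, calibration$srm_anchors[["alpha"]],
                   calibration$srm_anchors[["li"]])
    )
    area <- mean_area * rlnorm(n, -calibration$rel_sd^2 / 2, calibration$rel_sd)
    area <- pmax(area, 2)
    aspect <- 1 + rlnorm(n, log(0.09), 0.6)
    semi_minor <- sqrt(area / (pi * aspect))
    data.frame(
      center_row = runif(n, 1, height - 2),
      center_col = runif(n, 1, width - 2),
      semi_major = aspect * semi_minor,
      semi_minor = semi_minor,
      orientation = runif(n, 0, pi),
      core_intensity = pmin(pmax(rnorm(n, 60, 10), 30), 95),
      edge_width = runif(n, 1, 2)
    )
  })
}

#' Render a synthetic autoradiographic image
#'
#' Pits are drawn as dark ellipses with a flat core and a linear radial
#' intensity gradient band of `edge_width` px at the rim (the grey level
#' crosses the midpoint between core and background at the nominal ellipse
#' boundary), on a bright background with additive sensor noise. The
#' acquisition condition's light offset and defocus are then applied.
#'
#' @param pits data frame of pit render specs (see [sample_pit_specs()]).
#' @param condition an [acquisition_condition()].
#' @param width,height frame size in px.
#' @param background background grey level.
#' @param seed optional integer seed.
#' @return a `synthetic_image`: list with `pixels` (integer matrix, 0-255),
#'   `pits`, `condition` and `label` (`"Accepted"` iff the condition lies in
#'   the adequate band).
#' @export
render_image <- function(pits, condition = acquisition_condition(),
                         width = FRAME_WIDTH, height = FRAME_HEIGHT,
                         background = 200, seed = NULL) {
  stopifnot(inherits(condition, "acquisition_condition"))
  if (nrow(pits) > 0 &&
      (any(pits$center_row < 0) || any(pits$center_row > height - 1) ||
       any(pits$center_col < 0) || any(pits$center_col > width - 1))) {
    .stopf("pit centers must lie within the frame")
  }
  with_seed(seed, {
    img <- matrix(background, height, width)
    for (i in seq_len(nrow(pits))) {
      img <- draw_pit(img, pits[i, ], background)
    }
    img <- img + rnorm(length(img), 0, condition$noise_sd)
    img <- apply_light_offset(img, condition$light_offset)
    img <- apply_defocus(img, condition$defocus_sigma)
    pixels <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), height, width)
    structure(list(pixels = pixels, pits = pits, condition = condition,
                   label = if (is_adequate(condition)) "Accepted" else "Rejected"),
              class = "synthetic_image")
  })
}

draw_pit <- function(img, pit, background) {
  a <- pit$semi_major; b <- pit$semi_minor
  ew <- pit$edge_width
  r0 <- pit$center_row; c0 <- pit$center_col
  ext <- ceiling(a + ew + 1)
  rows <- max(1, floor(r0 + 1 - ext)):min(nrow(img), ceiling(r0 + 1 + ext))
  cols <- max(1, floor(c0 + 1 - ext)):min(ncol(img), ceiling(c0 + 1 + ext))
  dr <- rows - 1 - r0
  dc <- cols - 1 - c0
  co <- cos(pit$orientation); si <- sin(pit$orientation)
  x <- outer(dr, dc, function(r, c) r * co + c * si)
  y <- outer(dr, dc, function(r, c) -r * si + c * co)
  rho <- sqrt((x / a)^2 + (y / b)^2)
  t_in <- (1 - rho) * b  # approximate inward distance from the rim, px
  f <- pmin(pmax(t_in / ew + 0.5, 0), 1)
  patch <- background + (pit$core_intensity - background) * f
  img[rows, cols] <- pmin(img[rows, cols], patch)
  img
}

#' Apply an illumination offset to an image
#'
#' Over-lighting (`offset > 0`) compresses grey levels towards white, so dark
#' pits shrink below the segmentation threshold and the faintest disappear.
#' Under-lighting (`offset < 0`) scales grey levels down and superimposes a
#' low-frequency mottle, so background patches dip below threshold and
#' appear as spurious small objects. `offset = 0` is the identity,
#' pixel-for-pixel.
#'
#' @param image grey-level matrix (numeric; may hold unclipped intermediate
#'   values during rendering).
#' @param offset dimensionless, in \[-1, 1\].
#' @param seed optional integer seed for the under-light mottle.
#' @return grey-level matrix.
#' @export
apply_light_offset <- function(image, offset, seed = NULL) {
  if (abs(offset) > 1) .stopf("`offset` must lie in [-1, 1]")
  if (offset == 0) return(image)
  if (offset > 0) {
    image + offset * 0.6 * (255 - image)
  } else {
    with_seed(seed, {
      dim_img <- image * (1 + 0.55 * offset)
      mottle <- low_frequency_field(nrow(image), ncol(image),
                                    sd = 45 * abs(offset))
      dim_img + mottle
    })
  }
}

# Smooth random field: coarse white noise upsampled to frame size.
low_frequency_field <- function(h, w, sd, cell = 12) {
  hc <- max(2, ceiling(h / cell)); wc <- max(2, ceiling(w / cell))
  coarse <- matrix(rnorm(hc * wc, 0, sd), hc, wc)
  up <- EBImage::resize(EBImage::Image(coarse), w = hc * cell, h = wc * cell)
  EBImage::imageData(up)[seq_len(h), seq_len(w)]
}

#' Defocus an image
#'
#' Gaussian blur of width `sigma` px followed by fresh sensor grain, which
#' leaves ragged thresholded boundaries and isolated foreground pixels around
#' the softened rims -- the signature of a wrong lens-sample distance.
#' `sigma = 0` is the identity, pixel-for-pixel.
#'
#' @param image grey-level matrix.
#' @param sigma blur width in px, >= 0.
#' @param grain_sd sd of the post-blur grain, grey levels.
#' @param seed optional integer seed.
#' @return grey-level matrix.
#' @export
apply_defocus <- function(image, sigma, grain_sd = 8, seed = NULL) {
  if (sigma < 0) .stopf("`sigma` must be >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, {
    blurred <- EBImage::imageData(EBImage::gblur(EBImage::Image(image),
                                                 sigma = sigma))
    blurred + rnorm(length(image), 0, grain_sd)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Adequate images are drawn inside the adequate tolerance band; degraded
#' images draw an over-light, under-light, defocus or combined corruption
#' well outside it. The accepted/rejected split is exact.
#'
#' @param n_images number of images.
#' @param fraction_adequate fraction (exactly) rendered under adequate
#'   conditions.
#' @param width,height frame size in px.
#' @param track_density expected pits per pixel; the default corresponds to
#'   roughly 200 tracks on the full 1280 x 962 frame.
#' @param calibration an [energy_area_calibration()].
#' @param mode pit size model, see [sample_pit_specs()].
#' @param seed optional integer master seed; images are rendered from seeds
#'   derived deterministically from it.
#' @return list of `synthetic_image`s.
#' @export
generate_dataset <- function(n_images, fraction_adequate = 0.5,
                             width = FRAME_WIDTH, height = FRAME_HEIGHT,
                             track_density = 200 / (1280 * 962),
                             calibration = energy_area_calibration(),
                             mode = "bnc", seed = NULL) {
  if (fraction_adequate < 0 || fraction_adequate > 1) {
    .stopf("`fraction_adequate` must lie in [0, 1]")
  }
  n_ok <- round(n_images * fraction_adequate)
  adequate <- rep(c(TRUE, FALSE), c(n_ok, n_images - n_ok))
  lapply(seq_len(n_images), function(i) {
    si <- derive_seed(seed, i)
    with_seed(si, {
      cond <- sample_condition(adequate[i])
      n_pits <- rpois(1, track_density * width * height)
      pits <- sample_pit_specs(n_pits, width = width, height = height,
                               calibration = calibration, mode = mode)
      render_image(pits, cond, width = width, height = height)
    })
  })
}

sample_condition <- function(adequate) {
  if (adequate) {
    acquisition_condition(light_offset = runif(1, -0.1, 0.1),
                          defocus_sigma = runif(1, 0, 0.5))
  } else {
    kind <- sample(c("overlight", "underlight", "defocus", "combined"), 1)
    light <- switch(kind,
      overlight = runif(1, 0.3, 0.7),
      underlight = -runif(1, 0.3, 0.7),
      defocus = 0,
      combined = sample(c(-1, 1), 1) * runif(1, 0.2, 0.5))
    sigma <- switch(kind,
      overlight = 0,
      underlight = 0,
      defocus = runif(1, 1.5, 3.5),
      combined = runif(1, 1.2, 2.5))
    acquisition_condition(light_offset = light, defocus_sigma = sigma)
  }
}

#' Segment and featurize a stream of synthetic images
#'
#' Renders `n_images` (without keeping pixel data in memory), segments each
#' with the default pipeline and returns the assembled feature table with
#' ground-truth labels. Images whose segmentation yields no objects are
#' dropped with a warning.
#'
#' @inheritParams generate_dataset
#' @param threshold segmentation grey threshold.
#' @param split apply watershed splitting.
#' @return feature table data frame (36 features + `track_count` + `label` +
#'   `name`).
#' @export
synthesize_features <- function(n_images, fraction_adequate = 0.5,
                                width = FRAME_WIDTH, height = FRAME_HEIGHT,
                                track_density = 200 / (1280 * 962),
                                calibration = energy_area_calibration(),
                                mode = "bnc", threshold = 128, split = TRUE,
                                seed = NULL) {
  n_ok <- round(n_images * fraction_adequate)
  adequate <- rep(c(TRUE, FALSE), c(n_ok, n_images - n_ok))
  rows <- vector("list", n_images)
  dropped <- 0L
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, i)
    img <- with_seed(si, {
      cond <- sample_condition(adequate[i])
      n_pits <- rpois(1, track_density * width * height)
      pits <- sample_pit_specs(n_pits, width = width, height = height,
                               calibration = calibration, mode = mode)
      render_image(pits, cond, width = width, height = height)
    })
    objects <- segment_image(img$pixels, threshold = threshold, split = split)
    if (length(objects) == 0) {
      dropped <- dropped + 1L
      next
    }
    rows[[i]] <- featurize_image(objects, name = sprintf("synthetic_%04d", i),
                                 label = img$label)
  }
  if (dropped > 0) {
    warning(sprintf("%d image(s) had no segmentable objects and were dropped",
                    dropped))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write the pixel grid of a synthetic image to disk
#'
#' @param image a `synthetic_image` or grey-level matrix.
#' @param path output path; `.png` or `.tif`/`.tiff` selects the format.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  px <- if (inherits(image, "synthetic_image")) image$pixels else image
  v <- pmin(pmax(px, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = 8)
  } else {
    .stopf("unsupported image format: %s", ext)
  }
  invisible(path)
}

#' Read an 8-bit grayscale image
#'
#' Multi-channel images are converted to luminance.
#'
#' @param path a PNG or TIFF file.
#' @return integer matrix of grey levels 0-255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) .stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    .stopf("unsupported image format: %s", ext)
  }
  if (length(dim(v)) == 3) {
    ch <- dim(v)[3]
    v <- if (ch >= 3) {
      0.2126 * v[, , 1] + 0.7152 * v[, , 2] + 0.0722 * v[, , 3]
    } else {
      v[, , 1]
    }
  }
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}
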