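#' Per-track descriptors
#'
#' The six measures used to characterize an etched track: area, diameter,
#' aspect ratio, roundness, heterogeneity and clumpiness.
#'
#' @name descriptors
#' @param obj a [track_object()].
NULL

#' @describeIn descriptors number of object pixels. Interior holes are not
#'   counted: the object is exactly the set of segmented pixels.
#' @export
track_area <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  nrow(obj$coords)
}

#' @describeIn descriptors longest line through the centroid connecting two
#'   opposite border pixels: the maximum centre-to-centre Euclidean distance
#'   between two border pixels whose connecting segment passes within half a
#'   pixel of the (intensity-unweighted) centroid. A single pixel has
#'   diameter 0. If no border pair's segment passes near the centroid (thin
#'   concave objects), the maximum border-pair distance is returned.
#' @export
track_diameter <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  n <- nrow(obj$coords)
  if (n == 1) return(0)
  b <- border_pixels(obj)
  if (nrow(b) < 2) return(0)
  # guard against degenerate huge blobs (badly lit backgrounds): an
  # even subsample of the border keeps the pair search tractable
  if (nrow(b) > 400) b <- b[seq(1, nrow(b), length.out = 400), , drop = FALSE]
  cen <- colMeans(obj$coords)
  pairs <- utils::combn(nrow(b), 2)
  p <- b[pairs[1, ], , drop = FALSE]
  q <- b[pairs[2, ], , drop = FALSE]
  v <- q - p
  len2 <- rowSums(v^2)
  w <- matrix(cen, nrow(p), 2, byrow = TRUE) - p
  t <- pmin(pmax(rowSums(w * v) / pmax(len2, 1e-12), 0), 1)
  closest <- p + v * t
  dcen <- sqrt(rowSums((matrix(cen, nrow(p), 2, byrow = TRUE) - closest)^2))
  d <- sqrt(len2)
  through <- dcen <= 0.5
  if (any(through)) max(d[through]) else max(d)
}

#' @describeIn descriptors ratio of the long to short axis of the
#'   second-central-moment equivalent ellipse; a per-pixel variance of 1/12 is
#'   added on each axis so 1-px-wide objects have a finite ratio. Always >= 1;
#'   1 for circularly symmetric objects.
#' @export
track_aspect <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  xy <- obj$coords
  n <- nrow(xy)
  mu <- colMeans(xy)
  d <- sweep(xy, 2, mu)
  cov <- crossprod(d) / n + diag(1 / 12, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev))
}

#' @describeIn descriptors circularity \eqn{P^2 / (4 \pi A)}: 1 for an ideal
#'   circle, larger for irregular outlines. The perimeter P is the weighted
#'   border-step estimate (straight step 1, diagonal step \eqn{\sqrt 2},
#'   corner \eqn{(1+\sqrt 2)/2}) of the outer boundary.
#' @export
track_roundness <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  p <- track_perimeter(obj)
  p^2 / (4 * pi * track_area(obj))
}

#' @describeIn descriptors perimeter estimate used by [track_roundness()].
#' @export
track_perimeter <- function(obj) {
  mask <- object_mask(obj, pad = 1L)
  perimeter_mask(mask)
}

# Weighted border-step perimeter of a padded binary mask.
perimeter_mask <- function(mask) {
  er <- mask &
    shift_mat(mask, -1, 0) & shift_mat(mask, 1, 0) &
    shift_mat(mask, 0, -1) & shift_mat(mask, 0, 1)
  border <- mask & !er
  if (!any(border)) return(0)
  b <- border * 1L
  code <- b +
    2L * (shift_mat(b, -1, 0) + shift_mat(b, 1, 0) +
          shift_mat(b, 0, -1) + shift_mat(b, 0, 1)) +
    10L * (shift_mat(b, -1, -1) + shift_mat(b, -1, 1) +
           shift_mat(b, 1, -1) + shift_mat(b, 1, 1))
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(w[code[border] + 1])
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(if (is.logical(m)) FALSE else 0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Border pixels: object pixels 8-adjacent to background (or frame edge).
border_pixels <- function(obj) {
  mask <- object_mask(obj, pad = 1L)
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & shift_mat(mask, dr, dc)
  }
  border <- mask & !interior
  idx <- which(border, arr.ind = TRUE)
  # translate back to the object's 0-based frame coordinates
  r0 <- min(obj$coords[, 1]) - 1L; c0 <- min(obj$coords[, 2]) - 1L
  cbind(idx[, 1] - 1L + r0, idx[, 2] - 1L + c0)
}

#' @describeIn descriptors fraction of pixels whose intensity differs by more
#'   than 10% from the mean intensity of the object. 0 for a homogeneous
#'   object, 1 when no pixel is close to the mean. An all-zero object returns
#'   0 (degenerate; cannot occur for dark pits segmented on a bright
#'   background).
#' @export
track_heterogeneity <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  heterogeneity_values(obj$intensity)
}

heterogeneity_values <- function(v) {
  m <- mean(v)
  if (m == 0) return(0)
  mean(abs(v - m) > 0.1 * m)
}

#' @describeIn descriptors heterogeneity recomputed after eroding the object
#'   by a 3x3 square structuring element, which removes the one-pixel border
#'   rim where the pit-to-background intensity gradient lives. Objects that
#'   erode away completely return 0.
#' @export
track_clumpiness <- function(obj) {
  stopifnot(inherits(obj, "track_object"))
  mask <- object_mask(obj, pad = 1L)
  eroded <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    eroded <- eroded & shift_mat(mask, dr, dc)
  }
  if (!any(eroded)) return(0)
  r0 <- min(obj$coords[, 1]) - 1L; c0 <- min(obj$coords[, 2]) - 1L
  keep <- eroded[cbind(obj$coords[, 1] - r0 + 1L, obj$coords[, 2] - c0 + 1L)]
  heterogeneity_values(obj$intensity[keep])
}

#' All six descriptors of one track
#'
#' @param obj a [track_object()].
#' @return named numeric vector `area`, `diameter`, `aspect`, `roundness`,
#'   `heterogeneity`, `clumpiness`.
#' @export
track_descriptors <- function(obj) {
  c(area = track_area(obj),
    diameter = track_diameter(obj),
    aspect = track_aspect(obj),
    roundness = track_roundness(obj),
    heterogeneity = track_heterogeneity(obj),
    clumpiness = track_clumpiness(obj))
}

DESCRIPTOR_NAMES <- c("area", "diameter", "aspect", "roundness",
                      "heterogeneity", "clumpiness")
STAT_NAMES <- c("mean", "median", "iqr", "sd", "p5", "p90")

#' Summary statistics of a descriptor distribution
#'
#' Mean, median, interquartile distance, standard deviation, 5th percentile
#' and 90th percentile. Percentiles use linear interpolation between closest
#' ranks (R quantile type 7). The standard deviation of a single value is 0.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector of the six statistics.
#' @export
summarize_descriptor <- function(values) {
  if (length(values) == 0) .stopf("cannot summarize an empty value list")
  q <- quantile(values, c(0.05, 0.5, 0.9), names = FALSE, type = 7)
  c(mean = mean(values),
    median = q[2],
    iqr = IQR(values, type = 7),
    sd = if (length(values) > 1) sd(values) else 0,
    p5 = q[1],
    p90 = q[3])
}

#' Names of the 36 per-image features
#'
#' `<stat>_<descriptor>` for the six statistics of the six descriptors.
#' @return character vector of length 36.
#' @export
feature_names <- function() {
  as.vector(t(outer(STAT_NAMES, DESCRIPTOR_NAMES, paste, sep = "_")))
}

#' Summarize the tracks of one image into its 36-feature record
#'
#' @param objects non-empty list of [track_object()]s.
#' @param name image identifier stored in the record.
#' @param label optional quality label (`"Accepted"` or `"Rejected"`).
#' @return one-row data frame: 36 feature columns, `track_count`, `label`,
#'   `name`.
#' @export
featurize_image <- function(objects, name = NA_character_, label = NA_character_) {
  if (length(objects) == 0) {
    .stopf("cannot featurize an image with zero segmented objects")
  }
  desc <- t(vapply(objects, track_descriptors, numeric(6)))
  feats <- unlist(lapply(DESCRIPTOR_NAMES, function(d) {
    s <- summarize_descriptor(desc[, d])
    stats::setNames(s, paste0(STAT_NAMES, "_", d))
  }))
  out <- as.data.frame(as.list(feats))
  out$track_count <- length(objects)
  out$label <- label
  out$name <- name
  out
}

#' Convert a pixel area to square micrometres
#'
#' Uses the stated field of view: 1280 x 962 px imaging 211 x 158 um, i.e.
#' one pixel is (211/1280) x (158/962) um^2.
#'
#' @param area_px pixel count (vectorized).
#' @return area in um^2.
#' @export
px_area_to_um2 <- function(area_px) {
  if (any(area_px < 0)) .stopf("pixel areas must be non-negative")
  area_px * UM_PER_PX_X * UM_PER_PX_Y
}

#' Normalized per-descriptor histograms of a track population
#'
#' @param objects non-empty list of [track_object()]s.
#' @param breaks named list of break vectors per descriptor; descriptors not
#'   named use `nbins` equal-width bins over the observed range.
#' @param nbins default number of bins.
#' @return named list; each element has `breaks`, `mids` and `density`
#'   (fractions summing to 1).
#' @export
parameter_histograms <- function(objects, breaks = list(), nbins = 30) {
  if (length(objects) == 0) .stopf("need at least one object")
  desc <- t(vapply(objects, track_descriptors, numeric(6)))
  out <- lapply(DESCRIPTOR_NAMES, function(d) {
    v <- desc[, d]
    br <- breaks[[d]]
    if (is.null(br)) {
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      br <- seq(rng[1], rng[2], length.out = nbins + 1)
    }
    v <- pmin(pmax(v, br[1]), br[length(br)])
    h <- hist(v, breaks = br, plot = FALSE)
    list(breaks = h$breaks, mids = h$mids, density = h$counts / length(v))
  })
  stats::setNames(out, DESCRIPTOR_NAMES)
}

#' @importFrom graphics hist
NULL
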