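#' Threshold-based binarization of a grayscale micrograph
#'
#' Etched pits are dark objects on a bright background, so a pixel is
#' foreground when its grey level is less than or equal to the threshold.
#'
#' @param image numeric or integer matrix of 8-bit grey levels (0 = dark,
#'   255 = bright), rows indexing image rows.
#' @param threshold grey level in \[0, 255\], or `"otsu"` for automatic
#'   selection by Otsu's criterion on the image histogram.
#' @return logical matrix of the same dimension; `TRUE` marks pit pixels.
#' @export
binarize <- function(image, threshold) {
  image <- as_gray_matrix(image)
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(image)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 255) {
    .stopf("`threshold` must be a single grey level in [0, 255] or \"otsu\"")
  }
  image <= threshold
}

#' Otsu's automatic threshold on the 0..255 grey histogram
#'
#' @param image grey-level matrix.
#' @return integer threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(image) {
  image <- as_gray_matrix(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2) - 1L
}

as_gray_matrix <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    .stopf("`image` must be a numeric matrix of grey levels")
  }
  if (any(image < 0 | image > 255)) {
    .stopf("grey levels must lie in [0, 255]")
  }
  image
}

#' Label 8-connected foreground components
#'
#' Maximal 8-connected components of a binary mask, labelled 1..n in raster
#' order (top-to-bottom, left-to-right) of each component's first pixel.
#'
#' @param mask logical matrix.
#' @return an `object_labeling`: list with `labels` (integer matrix, 0 =
#'   background) and `n_objects`.
#' @export
label_8connected <- function(mask) {
  if (!is.matrix(mask)) .stopf("`mask` must be a matrix")
  storage.mode(mask) <- "logical"
  lab <- .label8_cpp(mask)
  n <- attr(lab, "n_objects")
  attr(lab, "n_objects") <- NULL
  structure(list(labels = lab, n_objects = n), class = "object_labeling")
}

#' @export
print.object_labeling <- function(x, ...) {
  cat(sprintf("<object_labeling> %d x %d, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

#' Split overlapping tracks by watershed on the distance transform
#'
#' Components whose Euclidean distance transform carries several sufficiently
#' separated maxima (overlapping near-circular pits) are split along the
#' watershed lines; convex single-peak objects pass through unchanged. The
#' result always refines the input labeling: objects are never merged and the
#' split pieces partition the original component.
#'
#' @param labeling an `object_labeling`.
#' @param tolerance minimum height between a peak and the saddle towards a
#'   neighbouring peak for the two to count as distinct objects (px).
#' @param ext radius used when detecting neighbouring maxima (px).
#' @return a new `object_labeling` with deterministic raster-order labels.
#' @export
watershed_split <- function(labeling, tolerance = 0.5, ext = 1) {
  stopifnot(inherits(labeling, "object_labeling"))
  mask <- labeling$labels > 0L
  if (!any(mask)) return(labeling)
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(EBImage::watershed(d, tolerance = tolerance, ext = ext))
  # refine: intersect watershed basins with the original labels so a basin
  # can never bridge two pre-existing objects
  combined <- labeling$labels * (max(ws) + 1) + ws
  combined[!mask] <- 0
  relabel_raster(combined)
}

# Relabel an arbitrary label matrix to 1..n in raster order of first pixels.
relabel_raster <- function(lab) {
  nr <- nrow(lab)
  idx <- which(t(lab) != 0)  # raster (row-major) scan order
  vals <- t(lab)[idx]
  first <- !duplicated(vals)
  mapping <- stats::setNames(seq_len(sum(first)), vals[first])
  out <- matrix(0L, nr, ncol(lab))
  pos <- which(lab != 0)
  out[pos] <- as.integer(mapping[as.character(lab[pos])])
  structure(list(labels = out, n_objects = length(mapping)),
            class = "object_labeling")
}

#' Segment a micrograph into track objects
#'
#' Composition of [binarize()], [label_8connected()] and (optionally)
#' [watershed_split()]. Every object retains its pixel coordinates and the
#' original grey intensities. No minimum-size filter is applied: isolated dark
#' pixels are informative for quality classification of badly lit images.
#'
#' @param image grey-level matrix.
#' @param threshold grey level or `"otsu"`; see [binarize()].
#' @param split logical; apply watershed splitting of overlapping tracks.
#' @return list of `track_object`s (possibly empty).
#' @export
segment_image <- function(image, threshold = 128, split = TRUE) {
  mask <- binarize(image, threshold)
  labeling <- label_8connected(mask)
  if (split) labeling <- watershed_split(labeling)
  labeling_to_objects(labeling, image)
}

#' Extract track objects from a labeling
#'
#' @param labeling an `object_labeling`.
#' @param image the grey-level matrix the labeling came from.
#' @return list of `track_object`s. Coordinates are 0-based `(row, col)` with
#'   the origin at the top-left pixel.
#' @export
labeling_to_objects <- function(labeling, image) {
  stopifnot(inherits(labeling, "object_labeling"))
  lab <- labeling$labels
  if (labeling$n_objects == 0L) return(list())
  pos <- which(lab != 0L)
  rows <- (pos - 1L) %% nrow(lab)
  cols <- (pos - 1L) %/% nrow(lab)
  by_obj <- split(seq_along(pos), lab[pos])
  lapply(by_obj[as.character(seq_len(labeling$n_objects))], function(i) {
    track_object(cbind(row = rows[i], col = cols[i]),
                 as.numeric(image[pos[i]]))
  })
}

#' Construct a track object
#'
#' The unit every descriptor is computed on: one segmented pit as a set of
#' pixel coordinates with their original grey intensities.
#'
#' @param coords integer matrix with columns `row`, `col` (0-based).
#' @param intensity grey level per pixel, same length as `nrow(coords)`.
#' @return a `track_object`.
#' @export
track_object <- function(coords, intensity) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) .stopf("a track object must contain at least one pixel")
  if (ncol(coords) != 2) .stopf("`coords` must have two columns (row, col)")
  if (length(intensity) != nrow(coords)) {
    .stopf("`intensity` must match the number of pixels")
  }
  colnames(coords) <- c("row", "col")
  structure(list(coords = coords, intensity = as.numeric(intensity)),
            class = "track_object")
}

#' @export
print.track_object <- function(x, ...) {
  cat(sprintf("<track_object> %d px, mean grey %.1f\n",
              nrow(x$coords), mean(x$intensity)))
  invisible(x)
}

# Binary bounding-box mask of an object, padded by `pad` background pixels.
object_mask <- function(obj, pad = 1L) {
  r <- obj$coords[, 1]; c <- obj$coords[, 2]
  r0 <- min(r) - pad; c0 <- min(c) - pad
  m <- matrix(FALSE, max(r) - r0 + 1L + pad, max(c) - c0 + 1L + pad)
  m[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
  m
}
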