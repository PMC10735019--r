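# Independent oracles and small fixture builders used across test files.

# Coordinates (0-based) of the digital disk {(r,c): r^2 + c^2 <= radius^2}.
disk_coords <- function(radius, center = c(0, 0)) {
  g <- expand.grid(row = -radius:radius, col = -radius:radius)
  g <- g[g$row^2 + g$col^2 <= radius^2, ]
  cbind(row = g$row + center[1], col = g$col + center[2])
}

disk_object <- function(radius, intensity = 100, center = c(radius, radius)) {
  xy <- disk_coords(radius, center)
  track_object(xy, rep(intensity, nrow(xy)))
}

# Brute-force flood-fill connected-component labeling (8-connectivity),
# labels in raster order of each component's first pixel.
flood_label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    queue <- list(c(r, c))
    lab[r, c] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# AUC as the pairwise-comparison (Mann-Whitney) statistic: fraction of
# (positive, negative) pairs ranked correctly, ties counting one half.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == "Accepted"]
  neg <- scores[labels == "Rejected"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force confusion counts for rule "predict Accepted iff p > thr".
confusion_oracle <- function(labels, prob, thr) {
  pred <- ifelse(prob > thr, "Accepted", "Rejected")
  c(tp = sum(pred == "Accepted" & labels == "Accepted"),
    fp = sum(pred == "Accepted" & labels == "Rejected"),
    fn = sum(pred == "Rejected" & labels == "Accepted"),
    tn = sum(pred == "Rejected" & labels == "Rejected"))
}

# Shared synthetic feature table (moderate size), built once per test run.
.fixture_env <- new.env(parent = emptyenv())
shared_synthetic_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- synthesize_features(
      80, fraction_adequate = 0.5, width = 320, height = 320,
      track_density = 200 / (640 * 640), seed = 4242)
  }
  .fixture_env$features
}

shared_quality_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- train_quality_model(
      shared_synthetic_features(), model = "nn", seed = 99,
      nn_cfg = nn_config(seed = 77, max_epochs = 200))
  }
  .fixture_env$model
}
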