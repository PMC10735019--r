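LABEL_LEVELS <- c("Rejected", "Accepted")

normalize_labels <- function(x) {
  if (anyNA(x)) .stopf("missing label value(s)")
  out <- ifelse(tolower(trimws(as.character(x))) %in% c("accepted", "accept", "1"),
                "Accepted",
         ifelse(tolower(trimws(as.character(x))) %in% c("rejected", "reject", "0"),
                "Rejected", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    .stopf("unknown label value(s): %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

# Map a foreign header (e.g. the supplementary dataset's) onto the canonical
# `<stat>_<descriptor>` names by normalizing case/separators and accepting
# common statistic aliases.
canonical_column <- function(nm) {
  x <- tolower(gsub("[ .\\-]+", "_", trimws(nm)))
  x <- sub("^std_dev", "sd", x)
  x <- sub("^std", "sd", x)
  x <- sub("^stdev", "sd", x)
  x <- sub("^5th_percentile", "p5", x)
  x <- sub("^90th_percentile", "p90", x)
  x <- sub("^percentile_5", "p5", x)
  x <- sub("^percentile_90", "p90", x)
  x <- sub("^interquartile(_distance|_range)?", "iqr", x)
  x <- sub("_aspect_ratio$", "_aspect", x)
  x <- sub("_round(ness)?$", "_roundness", x)
  x <- sub("_het(erogeneity)?$", "_heterogeneity", x)
  x <- sub("_clump(iness)?$", "_clumpiness", x)
  x <- sub("^track_density$", "track_count", x)
  x <- sub("^n_tracks$", "track_count", x)
  x
}

#' Read a per-image feature table from CSV
#'
#' The file must contain the 36 feature columns (matched after header
#' normalization, so the supplementary dataset's header variants load
#' directly), a `label` column and a track count / track density column;
#' a `name` column is optional. Labels are normalized to
#' `"Accepted"`/`"Rejected"`.
#'
#' @param path CSV file path.
#' @return feature table data frame: 36 features, `track_count`, `label`,
#'   `name`.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) .stopf("feature CSV not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- canonical_column(names(raw))
  need <- feature_names()
  missing <- setdiff(c(need, "label", "track_count"), names(raw))
  if (length(missing) > 0) {
    .stopf("feature CSV is missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in c(need, "track_count")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) .stopf("column `%s` is not numeric", col)
      v <- vn
    }
    if (anyNA(v)) .stopf("column `%s` contains missing values", col)
    raw[[col]] <- v
  }
  out <- raw[, need, drop = FALSE]
  out$track_count <- raw$track_count
  out$label <- normalize_labels(raw$label)
  out$name <- if ("name" %in% names(raw)) as.character(raw$name) else
    sprintf("image_%05d", seq_len(nrow(raw)))
  out
}

#' Write a feature table to CSV
#'
#' Numeric columns are written with 17 significant digits so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table feature table data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- formatC(out[[col]], format = "g",
                                                      digits = 17)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_columns <- function(table) {
  intersect(feature_names(), names(table))
}

#' Drop uninformative feature columns
#'
#' The 5th percentiles of clumpiness and roundness carry no information for
#' quality classification (in both classes most tracks fall in the first bin
#' of both descriptors), so they are removed before modeling.
#'
#' @param table feature table.
#' @param columns columns to drop.
#' @return the table without those columns.
#' @export
drop_uninformative <- function(table,
                               columns = c("p5_clumpiness", "p5_roundness")) {
  absent <- setdiff(columns, names(table))
  if (length(absent) > 0) {
    .stopf("column(s) not present: %s", paste(absent, collapse = ", "))
  }
  table[, setdiff(names(table), columns), drop = FALSE]
}

#' Balance the two classes by random undersampling
#'
#' The majority class is randomly undersampled to the minority count, giving
#' a table of 2 x min(class counts) rows (a subset of the input, original
#' order preserved).
#'
#' @param table feature table with a `label` column.
#' @param seed optional integer seed.
#' @return balanced feature table.
#' @export
balance_classes <- function(table, seed = NULL) {
  tab <- table(table$label)
  if (length(tab) < 2) .stopf("both classes must be present to balance")
  m <- min(tab)
  keep <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      i <- which(table$label == cl)
      if (length(i) > m) sample(i, m) else i
    }))
  })
  table[sort(keep), , drop = FALSE]
}

#' Split a table into train / validation / test parts
#'
#' Defaults follow the study design: 20% held out for testing and 20% of the
#' remainder for validation (0.64 / 0.16 / 0.20 overall). Stratified by label
#' by default so each part preserves the class balance.
#'
#' @param table feature table.
#' @param fractions numeric vector of three fractions summing to 1
#'   (train, validation, test).
#' @param seed optional integer seed.
#' @param stratified stratify on `label`.
#' @return named list `train`, `validation`, `test` of disjoint row subsets
#'   whose union is the input.
#' @export
split_dataset <- function(table, fractions = c(train = 0.64, validation = 0.16,
                                               test = 0.20),
                          seed = NULL, stratified = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-8) .stopf("`fractions` must sum to 1")
  assign_part <- function(n) {
    counts <- floor(fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    sample(rep.int(1:3, counts))
  }
  part <- integer(nrow(table))
  with_seed(seed, {
    if (stratified && "label" %in% names(table)) {
      for (cl in unique(table$label)) {
        i <- which(table$label == cl)
        part[i] <- assign_part(length(i))
      }
    } else {
      part <- assign_part(nrow(table))
    }
  })
  list(train = table[part == 1, , drop = FALSE],
       validation = table[part == 2, , drop = FALSE],
       test = table[part == 3, , drop = FALSE])
}

#' Pearson correlation matrix of the feature columns
#'
#' @param table feature table.
#' @return symmetric correlation matrix with unit diagonal; entries involving
#'   constant columns are `NA` (flagged with a warning).
#' @export
feature_correlation <- function(table) {
  x <- as.matrix(table[, feature_columns(table), drop = FALSE])
  if (nrow(x) < 2) .stopf("need at least two rows")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("constant column(s) give undefined correlations: %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  suppressWarnings(cor(x))
}

#' Fit a standardized (correlation-matrix) PCA
#'
#' Features are z-scored on the training statistics, then decomposed; the
#' smallest number of leading components whose cumulative explained variance
#' reaches `variance_target` is retained. Zero-variance features are guarded
#' (unit scale, zero loading contribution).
#'
#' @param table feature table (training split).
#' @param variance_target fraction of variance to retain, default 0.999.
#' @param scale. standardize features (correlation PCA); set `FALSE` for
#'   raw-covariance PCA.
#' @return a `pca_transform`: centers, scales, orthonormal rotation,
#'   explained-variance fractions and `n_components`.
#' @export
pca_fit <- function(table, variance_target = 0.999, scale. = TRUE) {
  cols <- feature_columns(table)
  x <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(x) < 2) .stopf("need at least two rows to fit a PCA")
  center <- colMeans(x)
  scl <- if (scale.) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scl, "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  structure(list(feature_names = cols, center = center, scale = scl,
                 rotation = pc$rotation, explained = frac,
                 n_components = as.integer(k),
                 variance_target = variance_target),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> %d features -> %d components (%.4f%% variance)\n",
              length(x$feature_names), x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Project a feature table onto the retained principal components
#'
#' @param transform a `pca_transform`.
#' @param table feature table with the same feature columns the transform was
#'   fitted on.
#' @param n_components number of components (defaults to the retained count).
#' @return numeric matrix, one row per input row.
#' @export
pca_transform <- function(transform, table, n_components = transform$n_components) {
  stopifnot(inherits(transform, "pca_transform"))
  miss <- setdiff(transform$feature_names, names(table))
  if (length(miss) > 0) {
    .stopf("table lacks feature column(s): %s", paste(miss, collapse = ", "))
  }
  x <- as.matrix(table[, transform$feature_names, drop = FALSE])
  z <- sweep(sweep(x, 2, transform$center), 2, transform$scale, "/")
  z %*% transform$rotation[, seq_len(n_components), drop = FALSE]
}

#' Serialize / restore a PCA transform as JSON
#'
#' @param transform a `pca_transform`.
#' @param path JSON file path.
#' @return `pca_to_json` returns `path` invisibly; `pca_from_json` the
#'   restored transform.
#' @export
pca_to_json <- function(transform, path) {
  obj <- unclass(transform)
  obj$rotation <- list(values = as.vector(obj$rotation),
                       dim = dim(obj$rotation),
                       colnames = colnames(obj$rotation))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pca_to_json
#' @export
pca_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- matrix(obj$rotation$values, obj$rotation$dim[1], obj$rotation$dim[2])
  colnames(rot) <- obj$rotation$colnames
  rownames(rot) <- obj$feature_names
  structure(list(feature_names = obj$feature_names,
                 center = stats::setNames(obj$center, obj$feature_names),
                 scale = stats::setNames(obj$scale, obj$feature_names),
                 rotation = rot, explained = obj$explained,
                 n_components = as.integer(obj$n_components),
                 variance_target = obj$variance_target),
            class = "pca_transform")
}
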