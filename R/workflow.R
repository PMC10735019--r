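#' Train an image quality model end to end
#'
#' Assembles the full modeling pipeline on a labelled feature table: drop the
#' two uninformative percentile features, balance the classes, split
#' train/validation/test, fit the standardized PCA on the training split,
#' train the chosen classifier on the projected features, and select the
#' decision threshold on the validation split at the precision target.
#'
#' @param features feature table (36 features + `track_count` + `label`).
#' @param model `"nn"` or `"svm"`.
#' @param variance_target PCA explained-variance target.
#' @param target_precision precision target for threshold selection; if
#'   unachievable on the validation scores, the threshold falls back to 0.5
#'   with a warning.
#' @param balance balance classes by undersampling before splitting.
#' @param seed optional integer master seed.
#' @param svm_cfg,nn_cfg optional configuration overrides.
#' @return a `quality_model` bundle: PCA transform, fitted classifier,
#'   decision threshold, operating point and held-out test metrics.
#' @export
train_quality_model <- function(features, model = c("nn", "svm"),
                                variance_target = 0.999,
                                target_precision = 0.97,
                                balance = TRUE, seed = NULL,
                                svm_cfg = NULL, nn_cfg = NULL) {
  model <- match.arg(model)
  tab <- drop_uninformative(features)
  if (balance) tab <- balance_classes(tab, seed = derive_seed(seed, 1))
  parts <- split_dataset(tab, seed = derive_seed(seed, 2))
  pca <- pca_fit(parts$train, variance_target = variance_target)
  xtr <- pca_transform(pca, parts$train)
  xva <- pca_transform(pca, parts$validation)
  xte <- pca_transform(pca, parts$test)
  fit <- if (model == "svm") {
    cfg <- if (is.null(svm_cfg)) svm_config(seed = derive_seed(seed, 3)) else svm_cfg
    svm_search_and_train(xtr, parts$train$label, cfg)
  } else {
    cfg <- if (is.null(nn_cfg)) nn_config(seed = derive_seed(seed, 3)) else nn_cfg
    nn_train(xtr, parts$train$label, xva, parts$validation$label, cfg)
  }
  pva <- predict(fit, xva)
  op <- tryCatch(
    select_threshold_for_precision(parts$validation$label, pva,
                                   target = target_precision),
    error = function(e) {
      warning(conditionMessage(e), "; falling back to threshold 0.5")
      cm <- confusion(parts$validation$label, pva, 0.5)
      structure(list(threshold = 0.5, precision = precision(cm),
                     recall = recall(cm)), class = "operating_point")
    })
  pte <- predict(fit, xte)
  cm_test <- confusion(parts$test$label, pte, op$threshold)
  structure(list(
    model_kind = model, fit = fit, pca = pca, threshold = op$threshold,
    operating_point = op, dropped = c("p5_clumpiness", "p5_roundness"),
    validation = list(labels = parts$validation$label, prob = pva,
                      auc = attr(roc_curve(parts$validation$label, pva), "auc")),
    test = list(confusion = cm_test, accuracy = accuracy(cm_test),
                precision = precision(cm_test), recall = recall(cm_test))
  ), class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf(paste0("<quality_model> %s, threshold %.3f ",
                     "(val precision %.3f, recall %.3f; val AUC %.3f)\n"),
              toupper(x$model_kind), x$threshold, x$operating_point$precision,
              x$operating_point$recall, x$validation$auc))
  invisible(x)
}

#' Probabilities from a quality model for a feature table
#'
#' @param bundle a `quality_model`.
#' @param features feature table.
#' @return acceptance probabilities.
#' @export
quality_probability <- function(bundle, features) {
  stopifnot(inherits(bundle, "quality_model"))
  predict(bundle$fit, pca_transform(bundle$pca, features))
}

#' Verify a micrograph before quantification
#'
#' The intended production use: segment the image, featurize its tracks,
#' project onto the model's principal components, and accept or reject at
#' the bundle's decision threshold.
#'
#' @param image a grey-level matrix, a `synthetic_image`, or a path to a
#'   PNG/TIFF file.
#' @param bundle a `quality_model`.
#' @param threshold grey threshold for segmentation.
#' @param split apply watershed splitting.
#' @param name image name in the result (defaults to the file name when a
#'   path is given).
#' @return one-row data frame: `name`, `probability`, `decision`
#'   (`"Accepted"`/`"Rejected"`, consistent with probability > threshold),
#'   `track_count`, `threshold`. An image with no segmentable objects is
#'   reported as not classifiable (`NA` probability, decision
#'   `"NotClassifiable"`).
#' @export
classify_image <- function(image, bundle, threshold = 128, split = TRUE,
                           name = NULL) {
  stopifnot(inherits(bundle, "quality_model"))
  if (is.character(image)) {
    if (is.null(name)) name <- basename(image)
    image <- read_gray_image(image)
  } else if (inherits(image, "synthetic_image")) {
    image <- image$pixels
  }
  if (is.null(name)) name <- NA_character_
  objects <- segment_image(image, threshold = threshold, split = split)
  if (length(objects) == 0) {
    return(data.frame(name = name, probability = NA_real_,
                      decision = "NotClassifiable", track_count = 0L,
                      threshold = bundle$threshold))
  }
  feats <- featurize_image(objects, name = name)
  p <- quality_probability(bundle, feats)
  data.frame(name = name, probability = p,
             decision = ifelse(p > bundle$threshold, "Accepted", "Rejected"),
             track_count = length(objects), threshold = bundle$threshold)
}

#' Save / load a quality model bundle
#'
#' The bundle is serialized as plain JSON (plus the SVM's support-vector
#' representation), so a saved model reloads bit-exactly across sessions.
#'
#' @param bundle a `quality_model`.
#' @param dir bundle directory.
#' @return `save_quality_model` returns `dir` invisibly; `load_quality_model`
#'   the restored bundle.
#' @export
save_quality_model <- function(bundle, dir) {
  stopifnot(inherits(bundle, "quality_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pca_to_json(bundle$pca, file.path(dir, "pca.json"))
  meta <- list(model_kind = bundle$model_kind, threshold = bundle$threshold,
               operating_point = unclass(bundle$operating_point),
               dropped = bundle$dropped)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  if (bundle$model_kind == "nn") {
    layers <- lapply(bundle$fit$layers, function(l) {
      list(W = list(values = as.vector(l$W), dim = dim(l$W)), b = l$b)
    })
    jsonlite::write_json(list(layers = layers,
                              hidden = bundle$fit$config$hidden),
                         file.path(dir, "nn.json"), digits = NA,
                         auto_unbox = TRUE)
  } else {
    jsonlite::write_json(list(C = bundle$fit$C, gamma = bundle$fit$gamma),
                         file.path(dir, "svm.json"), digits = NA,
                         auto_unbox = TRUE)
    saveRDS(bundle$fit$fit, file.path(dir, "svm.rds"))
  }
  invisible(dir)
}

#' @rdname save_quality_model
#' @export
load_quality_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  pca <- pca_from_json(file.path(dir, "pca.json"))
  fit <- if (meta$model_kind == "nn") {
    nj <- jsonlite::read_json(file.path(dir, "nn.json"), simplifyVector = FALSE)
    layers <- lapply(nj$layers, function(l) {
      list(W = matrix(unlist(l$W$values), unlist(l$W$dim)[1],
                      unlist(l$W$dim)[2]),
           b = unlist(l$b))
    })
    structure(list(layers = layers,
                   config = nn_config(hidden = unlist(nj$hidden)),
                   history = NULL, n_epochs = NA_integer_),
              class = "track_nn")
  } else {
    structure(list(fit = readRDS(file.path(dir, "svm.rds"))),
              class = "track_svm")
  }
  structure(list(model_kind = meta$model_kind, fit = fit, pca = pca,
                 threshold = meta$threshold,
                 operating_point = structure(as.list(meta$operating_point),
                                             class = "operating_point"),
                 dropped = meta$dropped),
            class = "quality_model")
}

#' Run the configured end-to-end pipeline
#'
#' Reads a YAML configuration, validates its schema, then runs the stages:
#' simulate a labelled synthetic dataset, train the configured classifier,
#' evaluate it, and write metrics (JSON) and the feature table (CSV) to the
#' output directory. All randomness derives from the single `seed` entry.
#'
#' @param config_path path to a YAML file; see
#'   `system.file("extdata", "demo_config.yaml", package = "trackqc")`.
#' @return the metrics list, invisibly; artifacts are written to the
#'   configured `out_dir`.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path)) .stopf("config file not found: %s", config_path)
  cfg <- yaml::read_yaml(config_path)
  required <- c("seed", "out_dir", "simulate", "model")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    .stopf("config is missing field(s): %s", paste(missing, collapse = ", "))
  }
  sim_req <- c("n_images", "width", "height")
  sim_missing <- setdiff(sim_req, names(cfg$simulate))
  if (length(sim_missing) > 0) {
    .stopf("config field `simulate` is missing: %s",
           paste(sim_missing, collapse = ", "))
  }
  if (!cfg$model %in% c("nn", "svm")) {
    .stopf("config field `model` must be \"nn\" or \"svm\"")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  message(sprintf("[simulate] %d images (%dx%d)", cfg$simulate$n_images,
                  cfg$simulate$width, cfg$simulate$height))
  feats <- synthesize_features(
    n_images = cfg$simulate$n_images,
    fraction_adequate = cfg$simulate$fraction_adequate %||% 0.5,
    width = cfg$simulate$width, height = cfg$simulate$height,
    seed = derive_seed(cfg$seed, 10))
  write_feature_csv(feats, file.path(cfg$out_dir, "features.csv"))
  message(sprintf("[train] %s model", cfg$model))
  bundle <- train_quality_model(
    feats, model = cfg$model,
    target_precision = cfg$target_precision %||% 0.97,
    seed = derive_seed(cfg$seed, 20))
  save_quality_model(bundle, file.path(cfg$out_dir, "model"))
  metrics <- list(
    model = cfg$model,
    n_images = nrow(feats),
    threshold = bundle$threshold,
    validation_auc = bundle$validation$auc,
    operating_precision = bundle$operating_point$precision,
    operating_recall = bundle$operating_point$recall,
    test_accuracy = bundle$test$accuracy,
    test_precision = bundle$test$precision,
    test_recall = bundle$test$recall,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE)
  message(sprintf("[done] test accuracy %.3f, elapsed %.1fs",
                  metrics$test_accuracy, metrics$elapsed_sec))
  invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproduce the historical-dataset modeling study
#'
#' Runs the full modeling pipeline on the supplementary per-image feature
#' dataset of ~22349 historical micrographs (not distributed with this
#' package): drop the two uninformative features, balance, split
#' 0.64/0.16/0.20, fit the 99.9%-variance PCA, run the randomized SVM search
#' and train the dense network, then report the retained component count,
#' cross-validated and held-out metrics, AUCs, and the precision-targeted
#' operating points of both models.
#'
#' @param s1_path path to the supplementary feature CSV.
#' @param seed integer seed.
#' @param n_candidates SVM search candidates.
#' @return list of metrics.
#' @export
reproduce_study <- function(s1_path, seed = 1, n_candidates = 20) {
  tab <- read_feature_csv(s1_path)
  tab <- drop_uninformative(tab)
  bal <- balance_classes(tab, seed = derive_seed(seed, 1))
  parts <- split_dataset(bal, seed = derive_seed(seed, 2))
  pca <- pca_fit(parts$train)
  xtr <- pca_transform(pca, parts$train)
  xva <- pca_transform(pca, parts$validation)
  xte <- pca_transform(pca, parts$test)
  xcv <- rbind(xtr, xva)
  ycv <- c(parts$train$label, parts$validation$label)
  svm <- svm_search_and_train(xcv, ycv,
                              svm_config(n_candidates = n_candidates,
                                         seed = derive_seed(seed, 3)))
  cm_svm <- confusion(ycv, svm$cv_prob, 0.5)
  nn <- nn_train(xtr, parts$train$label, xva, parts$validation$label,
                 nn_config(seed = derive_seed(seed, 4)))
  pva <- predict(nn, xva)
  pte <- predict(nn, xte)
  cm_val <- confusion(parts$validation$label, pva, 0.5)
  cm_test <- confusion(parts$test$label, pte, 0.5)
  op_nn <- select_threshold_for_precision(parts$validation$label, pva, 0.97)
  op_svm <- select_threshold_for_precision(ycv, svm$cv_prob, 0.97)
  list(
    n_rows = nrow(tab), n_balanced = nrow(bal),
    pca_components = pca$n_components,
    svm_C = svm$C, svm_gamma = svm$gamma,
    svm_cv_accuracy = accuracy(cm_svm), svm_cv_precision = precision(cm_svm),
    svm_auc = attr(roc_curve(ycv, svm$cv_prob), "auc"),
    nn_epochs = nn$n_epochs,
    nn_val_accuracy = accuracy(cm_val), nn_val_precision = precision(cm_val),
    nn_test_accuracy = accuracy(cm_test), nn_test_precision = precision(cm_test),
    nn_auc = attr(roc_curve(parts$validation$label, pva), "auc"),
    nn_threshold = op_nn$threshold, nn_recall_at_97 = op_nn$recall,
    svm_recall_at_97 = op_svm$recall)
}
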