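#' SVM configuration
#'
#' Randomized search ranges for the RBF kernel hyperparameters. Cost C is
#' drawn log-uniformly, gamma uniformly.
#'
#' @param c_range range for the cost parameter C.
#' @param gamma_range range for the RBF width gamma.
#' @param n_candidates number of random (C, gamma) candidates.
#' @param cv_folds number of cross-validation folds.
#' @param seed optional integer seed.
#' @return an `svm_config`.
#' @export
svm_config <- function(c_range = c(0.1, 30), gamma_range = c(0.005, 0.3),
                       n_candidates = 50, cv_folds = 5, seed = NULL) {
  stopifnot(all(c_range > 0), all(gamma_range > 0))
  structure(list(c_range = c_range, gamma_range = gamma_range,
                 n_candidates = n_candidates, cv_folds = cv_folds,
                 seed = seed), class = "svm_config")
}

#' Randomized cross-validated search and training of the RBF SVM
#'
#' Random (C, gamma) candidates are scored by k-fold cross-validated
#' accuracy; the best pair is refit on the full training data. The
#' cross-validated decision values of the winning pair are retained so the
#' cross-validation confusion matrix can be reported.
#'
#' @param x numeric matrix of predictors (e.g. principal component scores).
#' @param y labels (`"Accepted"`/`"Rejected"`), both classes present.
#' @param config an [svm_config()].
#' @return a `track_svm`: fitted e1071 model, selected hyperparameters,
#'   candidate report, and cross-validated probabilities (`cv_prob`) aligned
#'   with the training rows.
#' @importFrom e1071 svm
#' @export
svm_search_and_train <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- normalize_labels(y)
  if (length(unique(y)) < 2) .stopf("training data must contain both classes")
  yf <- factor(y, levels = LABEL_LEVELS)
  n <- nrow(x)
  with_seed(config$seed, {
    cand <- data.frame(
      C = 10^runif(config$n_candidates, log10(config$c_range[1]),
                   log10(config$c_range[2])),
      gamma = runif(config$n_candidates, config$gamma_range[1],
                    config$gamma_range[2])
    )
    folds <- sample(rep_len(seq_len(config$cv_folds), n))
    cand$cv_accuracy <- NA_real_
    best <- NULL
    for (j in seq_len(nrow(cand))) {
      dv <- cv_decision_values(x, yf, folds, cand$C[j], cand$gamma[j])
      pred <- ifelse(dv > 0, "Accepted", "Rejected")
      cand$cv_accuracy[j] <- mean(pred == y)
      if (is.null(best) || cand$cv_accuracy[j] > best$acc) {
        best <- list(C = cand$C[j], gamma = cand$gamma[j],
                     acc = cand$cv_accuracy[j], dv = dv)
      }
    }
    fit <- e1071::svm(x, yf, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
    structure(list(fit = fit, C = best$C, gamma = best$gamma,
                   cv_accuracy = best$acc, candidates = cand,
                   cv_prob = plogis(best$dv), labels = y),
              class = "track_svm")
  })
}

# Signed decision values oriented so positive means "Accepted".
decision_values <- function(fit, x) {
  p <- predict(fit, x, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  # e1071 orients the decision value towards the first factor level seen in
  # the column name; flip so that Accepted is positive
  nm <- colnames(attr(p, "decision.values"))[1]
  if (startsWith(nm, "Rejected")) dv <- -dv
  dv
}

cv_decision_values <- function(x, yf, folds, C, gamma) {
  dv <- numeric(nrow(x))
  for (f in unique(folds)) {
    hold <- folds == f
    fit <- e1071::svm(x[!hold, , drop = FALSE], droplevels(yf[!hold]),
                      kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
    dv[hold] <- decision_values(fit, x[hold, , drop = FALSE])
  }
  dv
}

#' Acceptance probability from the SVM decision value
#'
#' A logistic transform of the signed decision value, monotone in it:
#' decision value 0 maps to probability 0.5.
#'
#' @param model a `track_svm`.
#' @param x predictor matrix.
#' @return acceptance probabilities in \[0, 1\].
#' @export
svm_probability <- function(model, x) {
  stopifnot(inherits(model, "track_svm"))
  plogis(decision_values(model$fit, as.matrix(x)))
}

#' @export
predict.track_svm <- function(object, newdata, ...) {
  svm_probability(object, newdata)
}

#' @export
print.track_svm <- function(x, ...) {
  cat(sprintf("<track_svm> RBF, C = %.3g, gamma = %.3g, CV accuracy %.3f\n",
              x$C, x$gamma, x$cv_accuracy))
  invisible(x)
}
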