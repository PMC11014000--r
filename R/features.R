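# Sub-band statistical features and cross-validated classification.

#' Sub-band statistical features of one segment
#'
#' For every axis and every terminal packet node: mean, root mean square
#' and variance (sample variance, `m - 1` denominator) of the node
#' coefficients, plus the per-axis pooled energy-to-Shannon-entropy ratio
#' replicated across that axis's nodes (`xi_mode = "pooled"`, the
#' default) or computed per node (`xi_mode = "per_node"`).  Features are
#' concatenated deterministically by (axis, node, feature) with names of
#' the form `{feature}_n{node}_{axis}`; at the defaults (level 3, three
#' axes) the vector has 4 x 8 x 3 = 96 entries.
#'
#' A degenerate ratio (zero energy or zero entropy) yields a 0 feature
#' with a warning rather than an error, so isolated flat windows do not
#' abort feature extraction.
#'
#' @param segment A `"har_segment"` (or plain matrix, one column per axis).
#' @param wavelet Wavelet name or `"wavelet_spec"`.
#' @param level Decomposition level (default 3).
#' @param xi_mode Granularity of the ratio feature.
#' @return Named numeric vector with attribute `"label"`.
#' @export
subband_features <- function(segment, wavelet, level = 3L,
                             xi_mode = c("pooled", "per_node")) {
  xi_mode <- match.arg(xi_mode)
  w <- wavelet_filters(wavelet)
  m <- if (inherits(segment, "har_segment")) segment$samples else as.matrix(segment)
  axes <- colnames(m)
  if (is.null(axes)) axes <- c("x", "y", "z")[seq_len(ncol(m))]
  n_nodes <- 2L^as.integer(level)

  safe_ratio <- function(pk) {
    tryCatch(energy_entropy_ratio(pk), mwselect_degenerate = function(cnd) {
      warning("degenerate energy-to-entropy ratio; feature set to 0")
      0
    })
  }

  vals <- numeric(0)
  nms <- character(0)
  for (a in seq_len(ncol(m))) {
    pk <- wpt_decompose(m[, a], w, level)
    xi_pooled <- if (xi_mode == "pooled") safe_ratio(pk) else NA_real_
    for (nd in seq_len(n_nodes)) {
      coefs <- pk$nodes[[nd]]
      xi <- if (xi_mode == "pooled") {
        xi_pooled
      } else {
        sub <- pk; sub$nodes <- pk$nodes[nd]
        safe_ratio(sub)
      }
      vals <- c(vals, mean(coefs), sqrt(mean(coefs^2)), stats::var(coefs), xi)
      nms <- c(nms, sprintf("%s_n%d_%s", c("mean", "rms", "var", "ratio"),
                            nd - 1L, axes[a]))
    }
  }
  names(vals) <- nms
  attr(vals, "label") <- if (inherits(segment, "har_segment")) segment$label else NA_character_
  vals
}

#' Feature matrix for a list of segments
#'
#' Applies [subband_features()] to every segment and assembles the result
#' as a data frame with one row per segment and a terminal `label` factor
#' column — the input shape expected by [crossval_evaluate()].
#'
#' @inheritParams subband_features
#' @param segments List of `"har_segment"` objects.
#' @return Data frame of features plus a `label` column.
#' @export
feature_matrix <- function(segments, wavelet, level = 3L,
                           xi_mode = c("pooled", "per_node")) {
  xi_mode <- match.arg(xi_mode)
  rows <- lapply(segments, subband_features, wavelet = wavelet,
                 level = level, xi_mode = xi_mode)
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- factor(vapply(rows, function(r) attr(r, "label"), character(1)))
  df
}

#' Classification metrics from true and predicted labels
#'
#' Builds the confusion matrix and the per-class precision, recall and F1
#' (harmonic mean of precision and recall), with the convention that a
#' 0/0 quotient is 0 (a class never predicted has precision 0; a class
#' with no true members has recall 0).  Balanced accuracy is the
#' unweighted mean of per-class recalls; macro F1 the unweighted mean of
#' per-class F1 scores.
#'
#' @param truth,predicted Equal-length label vectors (character or
#'   factor).  Classes are the union of levels seen in either.
#' @param classifier_name,n_folds,seed Optional provenance recorded in
#'   the report.
#' @return Object of class `"eval_report"`: list with `confusion_matrix`,
#'   `per_class` (data frame: class, precision, recall, f1, support),
#'   `balanced_accuracy`, `macro_f1`, `n_folds`, `classifier_name`,
#'   `seed`.
#' @export
classification_metrics <- function(truth, predicted,
                                   classifier_name = NA_character_,
                                   n_folds = NA_integer_,
                                   seed = NA_integer_) {
  if (length(truth) == 0L || length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must be non-empty and of equal length")
  }
  classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  tf <- factor(as.character(truth), levels = classes)
  pf <- factor(as.character(predicted), levels = classes)
  cm <- table(truth = tf, predicted = pf)

  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)

  structure(
    list(
      confusion_matrix = cm,
      per_class = data.frame(
        class = classes, precision = as.numeric(precision),
        recall = as.numeric(recall), f1 = as.numeric(f1),
        support = as.numeric(rowSums(cm)), stringsAsFactors = FALSE
      ),
      balanced_accuracy = mean(recall),
      macro_f1 = mean(f1),
      n_folds = n_folds,
      classifier_name = classifier_name,
      seed = seed
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s%s: balanced accuracy %.4f, macro F1 %.4f (%d instances)\n",
    x$classifier_name,
    if (!is.na(x$n_folds)) sprintf(", %d-fold CV", x$n_folds) else "",
    x$balanced_accuracy, x$macro_f1, sum(x$confusion_matrix)
  ))
  invisible(x)
}

# Seeded stratified fold assignment: within each class, indices are
# shuffled and dealt round-robin across folds.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      warning(sprintf(
        "class '%s' has %d < k = %d members; best-effort stratification",
        cl, length(idx), k
      ))
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_predict <- function(classifier, train, test) {
  # z-score scaling fitted on the training fold only (no leakage);
  # zero-variance columns pass through unscaled
  feat_cols <- setdiff(names(train), "label")
  mu <- vapply(train[feat_cols], mean, numeric(1))
  sdv <- vapply(train[feat_cols], stats::sd, numeric(1))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale_df <- function(df) {
    out <- as.data.frame(Map(function(col, m, s) (col - m) / s,
                             df[feat_cols], mu, sdv))
    names(out) <- feat_cols
    out
  }
  tr <- scale_df(train); tr$label <- droplevels(train$label)
  te <- scale_df(test)

  if (classifier == "dt") {
    fit <- rpart::rpart(label ~ ., data = tr, method = "class",
                        parms = list(split = "information"))
    as.character(predict(fit, te, type = "class"))
  } else {
    fit <- e1071::svm(label ~ ., data = tr, kernel = "radial", cost = 1,
                      scale = FALSE)
    as.character(predict(fit, te))
  }
}

#' Stratified k-fold cross-validated classification
#'
#' Evaluates a feature representation with a decision tree
#' (information-gain splitting via [rpart::rpart()]) or an RBF-kernel SVM
#' ([e1071::svm()], cost 1).  Folds are stratified by class; per fold,
#' the feature scaler and the classifier are fitted on the training folds
#' only and the held-out fold is predicted.  All out-of-fold predictions
#' are pooled into one [classification_metrics()] report.  The whole
#' procedure is deterministic given `seed`.
#'
#' @param features Data frame from [feature_matrix()]: numeric feature
#'   columns plus a `label` factor column.
#' @param classifier `"dt"` or `"svm"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed governing fold assignment.
#' @return An `"eval_report"`.
#' @export
crossval_evaluate <- function(features, classifier = c("dt", "svm"),
                              k = 10L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (!is.data.frame(features) || !"label" %in% names(features)) {
    stop("`features` must be a data frame with a `label` column")
  }
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  labels <- factor(features$label)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  features$label <- labels

  fold <- local({
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    .stratified_folds(as.character(labels), k)
  })

  predicted <- character(nrow(features))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0L) next
    predicted[test_idx] <- .fit_predict(
      classifier,
      features[fold != f, , drop = FALSE],
      features[test_idx, , drop = FALSE]
    )
  }
  classification_metrics(as.character(labels), predicted,
                         classifier_name = classifier, n_folds = k,
                         seed = as.integer(seed))
}

#' Compare wavelets by cross-validated classification performance
#'
#' Runs the full feature-extraction + cross-validation pipeline for every
#' requested (wavelet, classifier) pair and tabulates balanced accuracy
#' and macro F1 — the comparison that shows whether the mother wavelet
#' picked by the energy-to-entropy ranking also wins on classification.
#'
#' @param segments List of labelled `"har_segment"` objects.
#' @param wavelets Character vector of wavelet names.
#' @param classifiers Subset of `c("dt", "svm")`.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param level Decomposition level (default 3).
#' @param xi_mode Ratio-feature granularity, see [subband_features()].
#' @return Data frame: wavelet, classifier, balanced_accuracy, macro_f1.
#' @export
compare_wavelets_classification <- function(segments, wavelets,
                                            classifiers = c("dt", "svm"),
                                            k = 10L, seed = 1L, level = 3L,
                                            xi_mode = "pooled") {
  if (length(wavelets) < 1L) stop("need at least one wavelet")
  classifiers <- match.arg(classifiers, c("dt", "svm"), several.ok = TRUE)
  rows <- list()
  for (wname in wavelets) {
    feats <- feature_matrix(segments, wname, level = level, xi_mode = xi_mode)
    for (cls in classifiers) {
      rep <- crossval_evaluate(feats, cls, k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        wavelet = wname, classifier = cls,
        balanced_accuracy = rep$balanced_accuracy,
        macro_f1 = rep$macro_f1, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Export an evaluation report
#'
#' Writes the per-class table as CSV and the summary metrics as JSON next
#' to it (`<stem>.csv`, `<stem>.json`).
#'
#' @param report An `"eval_report"`.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_eval_report <- function(report, stem) {
  if (!inherits(report, "eval_report")) stop("`report` must be an eval_report")
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.csv(report$per_class, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      classifier = report$classifier_name,
      n_folds = report$n_folds,
      seed = report$seed,
      balanced_accuracy = report$balanced_accuracy,
      macro_f1 = report$macro_f1
    ),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, json))
}
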