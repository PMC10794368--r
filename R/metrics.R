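#' Confusion matrix
#'
#' Counts samples by (true class, predicted class) over a fixed class set.
#'
#' @param true,pred Equal-length label vectors, each element a member of
#'   `classes`.
#' @param classes Vector of all class labels (defines row/column order).
#' @return An integer matrix of class `confusion_matrix`, rows = true
#'   classes, columns = predicted classes.
#' @export
confusion <- function(true, pred, classes) {
  if (length(true) != length(pred)) {
    stop_dim("confusion: true and pred lengths differ (%d vs %d)",
             length(true), length(pred))
  }
  ti <- match(true, classes)
  pj <- match(pred, classes)
  if (anyNA(ti) || anyNA(pj)) {
    bad <- c(true[is.na(ti)], pred[is.na(pj)])[1L]
    stop(sprintf("confusion: invalid label '%s' outside the class set",
                 format(bad)), call. = FALSE)
  }
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(true = as.character(classes),
                                         pred = as.character(classes)))
  for (i in seq_along(ti)) cm[ti[i], pj[i]] <- cm[ti[i], pj[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, F1 `2*precision*sensitivity/(precision+sensitivity)`, and
#' one-vs-rest accuracy `(TP+TN)/total`. A 0/0 ratio is reported as 0 with
#' `flagged = TRUE`. Macro metrics are unweighted means over classes;
#' `accuracy` is plain top-1 (trace over total), the headline multiclass
#' reading.
#'
#' @param cm A [confusion()] matrix with at least one counted sample.
#' @return List with `per_class` (data frame), `macro` (list of macro
#'   precision/sensitivity/f1 and mean one-vs-rest accuracy), and `accuracy`
#'   (top-1).
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) {
    stop("classification_metrics: empty confusion matrix", call. = FALSE)
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * sensitivity, precision + sensitivity)
  ovr_accuracy <- (tp + tn) / total
  flagged <- (tp + fp) == 0 | (tp + fn) == 0
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    precision = as.numeric(precision),
    sensitivity = as.numeric(sensitivity),
    f1 = as.numeric(f1),
    accuracy = as.numeric(ovr_accuracy),
    flagged = as.logical(flagged),
    row.names = NULL
  )
  list(
    per_class = per_class,
    macro = list(precision = mean(precision),
                 sensitivity = mean(sensitivity),
                 f1 = mean(f1),
                 accuracy = mean(ovr_accuracy)),
    accuracy = sum(tp) / total
  )
}

#' Average Accuracy over stages learned so far
#'
#' The standard continual-learning score: the unweighted arithmetic mean of
#' the model's test accuracy on each stage's classes, taken after the latest
#' stage.
#'
#' @param per_stage_accuracies Non-empty numeric vector of accuracies in
#'   `[0, 1]`.
#' @return Their mean.
#' @export
average_accuracy <- function(per_stage_accuracies) {
  if (length(per_stage_accuracies) == 0L) {
    stop("average_accuracy: empty input", call. = FALSE)
  }
  if (any(per_stage_accuracies < 0 | per_stage_accuracies > 1)) {
    stop("average_accuracy: accuracies must lie in [0, 1]", call. = FALSE)
  }
  mean(per_stage_accuracies)
}

#' Export pre-head features for external embedding analysis
#'
#' Runs the model over a dataset split and returns one row per sample with
#' its id, label, and the D-dimensional class-token feature vector (the
#' penultimate representation, input of the classification head). Suitable
#' for t-SNE/UMAP in any external tool.
#'
#' @param model A trained [vit_model()].
#' @param x Image array `(B, C, S, S)`.
#' @param y Integer labels (optional, `NA` if absent).
#' @param ids Sample identifiers; defaults to `1..B`.
#' @param file Optional CSV path to write.
#' @return A data frame with columns `id`, `label`, `f1..fD` (invisibly when
#'   written to file).
#' @export
export_features <- function(model, x, y = NULL, ids = NULL, file = NULL) {
  B <- dim(x)[1]
  feats <- model_predict(model, x)$features
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  df <- data.frame(id = ids %||% seq_len(B),
                   label = if (is.null(y)) rep(NA_integer_, B) else y)
  df <- cbind(df, as.data.frame(feats))
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
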