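#' Train the max-margin classifier on CSP features
#'
#' Linear support-vector machine (margin penalty `cost`, default 1) on
#' standardized features; the mean and scale are learned from the
#' training split only and reapplied at prediction time.  An RBF kernel
#' is available for exploration but the linear kernel is the study
#' default: CSP log-variance features are close to linearly separable.
#'
#' @param features numeric matrix n_trials x n_features.
#' @param labels factor/character of length n_trials in `{hand, foot}`.
#' @param cost margin penalty C (default 1).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @return object of class `bci_classifier`.
#' @export
train_classifier <- function(features, labels, cost = 1,
                             kernel = c("linear", "radial")) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  labels <- factor(as.character(labels), levels = c("hand", "foot"))
  if (anyNA(labels)) stop("labels must all be 'hand' or 'foot'")
  if (nrow(features) != length(labels)) {
    stop("one label per feature row required")
  }
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present in the training labels")
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  z <- sweep(sweep(features, 2, center), 2, scale, "/")
  fit <- e1071::svm(z, labels, type = "C-classification", kernel = kernel,
                    cost = cost, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 kernel = kernel, cost = cost),
            class = "bci_classifier")
}

#' Predict trial labels
#'
#' @param object a [train_classifier()] model.
#' @param features matrix with the training feature dimension; a single
#'   trial may be given as a vector.
#' @param decision_values also attach the signed decision values as an
#'   attribute.
#' @param ... unused.
#' @return factor of predicted labels (levels `hand`, `foot`).
#' @export
predict.bci_classifier <- function(object, features,
                                   decision_values = FALSE, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != length(object$center)) {
    stop("feature dimension ", ncol(features), " does not match the model (",
         length(object$center), ")")
  }
  z <- sweep(sweep(features, 2, object$center), 2, object$scale, "/")
  pred <- stats::predict(object$fit, z, decision.values = decision_values)
  out <- factor(as.character(pred), levels = c("hand", "foot"))
  if (decision_values) {
    attr(out, "decision_values") <- drop(attr(pred, "decision.values"))
  }
  out
}

#' Confusion counts with hand as the positive class
#'
#' @param true_labels,predicted_labels equal-length vectors with values in
#'   `{hand, foot}`.
#' @return object of class `confusion_counts` with integer fields `TP`,
#'   `FN`, `TN`, `FP` (hand = positive, foot = negative).
#' @export
confusion <- function(true_labels, predicted_labels) {
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  if (length(tl) != length(pl)) stop("label vectors must have equal length")
  bad <- setdiff(unique(c(tl, pl)), c("hand", "foot"))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  structure(list(TP = sum(tl == "hand" & pl == "hand"),
                 FN = sum(tl == "hand" & pl == "foot"),
                 TN = sum(tl == "foot" & pl == "foot"),
                 FP = sum(tl == "foot" & pl == "hand"),
                 positive_class = "hand", negative_class = "foot"),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion (hand = positive): TP %d  FN %d  TN %d  FP %d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Classification performance measures
#'
#' Percentages at full precision: accuracy = 100 (TP + TN) / total,
#' sensitivity = 100 TP / (TP + FN), specificity = 100 TN / (TN + FP),
#' with right-hand imagery as the positive case.  A zero denominator is
#' an explicit error, never a silent zero.
#'
#' @param conf a [confusion()] result.
#' @return percentage in [0, 100].
#' @export
accuracy <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  total <- conf$TP + conf$FN + conf$TN + conf$FP
  if (total == 0) stop("accuracy undefined: no evaluated trials")
  100 * (conf$TP + conf$TN) / total
}

#' @rdname accuracy
#' @export
sensitivity <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  if (conf$TP + conf$FN == 0) {
    stop("sensitivity undefined: no positive (hand) trials")
  }
  100 * conf$TP / (conf$TP + conf$FN)
}

#' @rdname accuracy
#' @export
specificity <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  if (conf$TN + conf$FP == 0) {
    stop("specificity undefined: no negative (foot) trials")
  }
  100 * conf$TN / (conf$TN + conf$FP)
}
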