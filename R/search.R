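.search_modes <- c("left_all", "left_3", "right_all", "right_3", "both_6")

#' Enumerate ROI subsets for a search mode
#'
#' Reproduces the exhaustive designs of the analysis: every non-empty
#' subset of the nine left-lobe ROIs (`left_all`, 2^9 - 1 = 511 subsets)
#' or right-lobe ROIs (`right_all`); every 3-region subset per lobe
#' (`left_3` / `right_3`, C(9,3) = 84 each); and every 6-region subset of
#' all 18 ROIs (`both_6`, C(18,6) = 18564).  Order is deterministic:
#' increasing size, then lexicographic in the atlas's canonical region
#' order.
#'
#' @param atlas a [roi_atlas()].
#' @param mode one of `"left_all"`, `"left_3"`, `"right_all"`,
#'   `"right_3"`, `"both_6"`.
#' @return list of [roi_subset()] objects.
#' @export
enumerate_subsets <- function(atlas, mode) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!mode %in% .search_modes) {
    stop("unknown search mode '", mode, "'; expected one of: ",
         paste(.search_modes, collapse = ", "),
         " (sensor-space evaluation takes no subsets)")
  }
  ids <- switch(mode,
                left_all = , left_3 = atlas$regions$id[atlas$regions$lobe == "L"],
                right_all = , right_3 = atlas$regions$id[atlas$regions$lobe == "R"],
                both_6 = atlas$regions$id)
  sizes <- switch(mode,
                  left_all = , right_all = seq_along(ids),
                  left_3 = , right_3 = 3L,
                  both_6 = 6L)
  out <- list()
  for (k in sizes) {
    cmb <- utils::combn(length(ids), k)
    for (j in seq_len(ncol(cmb))) {
      out[[length(out) + 1L]] <- roi_subset(ids[cmb[, j]], atlas)
    }
  }
  out
}

# Fast evaluation core: class covariances and CSP from sliced per-trial
# covariance stacks, linear SVM on log-variance features, test metrics.
.eval_from_covs <- function(covs_tr, lab_tr, covs_te, lab_te, idx, m_pairs,
                            shrinkage = 1e-6, cost = 1) {
  k <- length(idx)
  str_tr <- covs_tr[idx, idx, , drop = FALSE]
  str_te <- covs_te[idx, idx, , drop = FALSE]
  cc <- .class_covariances(str_tr, lab_tr, shrinkage)
  dec <- .csp_decompose(cc$pos, cc$neg)
  sel <- c(seq_len(m_pairs), seq(k - m_pairs + 1L, k))
  feat <- function(stack) {
    t(vapply(seq_len(dim(stack)[3]),
             function(i) .csp_features_from_cov(stack[, , i], dec$filters, sel),
             numeric(2 * m_pairs)))
  }
  model <- train_classifier(feat(str_tr), lab_tr, cost = cost)
  pred <- predict(model, feat(str_te))
  conf <- confusion(lab_te, pred)
  list(accuracy = accuracy(conf), sensitivity = sensitivity(conf),
       specificity = specificity(conf), confusion = conf,
       eigenvalues = dec$eigenvalues)
}

#' Prepare band-passed ROI-space data for subset evaluation
#'
#' Runs the fixed front end of the pipeline once: band-pass the sensor
#' trials, apply the sLORETA inverse, and aggregate to one time course
#' per atlas ROI.  Subset evaluations then only select channels, which
#' makes exhaustive searches cheap.
#'
#' @param train,test sensor-space [trialset()]s.
#' @param op an [compute_inverse_operator()] result.
#' @param source_space the matching [source_space()].
#' @param band a [band_spec()] (or `NULL` to skip filtering).
#' @param atlas the [roi_atlas()]; all 18 ROIs are extracted.
#' @param method ROI aggregation method, see [extract_roi_timecourses()].
#' @return object of class `roi_data`: ROI trialsets plus cached
#'   per-trial covariance stacks and the band name.
#' @export
prepare_roi_data <- function(train, test, op, source_space,
                             band = band_spec("mu"), atlas = source_space$atlas,
                             method = "sign_aligned") {
  all_rois <- roi_subset(atlas$regions$id, atlas)
  if (!is.null(band)) {
    train <- bandpass(train, band)
    test <- bandpass(test, band)
  }
  roi_train <- build_roi_trialset(train, op, source_space, all_rois, method)
  roi_test <- build_roi_trialset(test, op, source_space, all_rois, method)
  structure(list(train = roi_train, test = roi_test,
                 covs_train = trial_cov_stack(roi_train),
                 covs_test = trial_cov_stack(roi_test),
                 band = if (is.null(band)) "none" else band$name,
                 atlas = atlas),
            class = "roi_data")
}

#' Evaluate one ROI subset through the full pipeline
#'
#' Band-pass, inverse mapping and ROI extraction (or reuse of a prepared
#' [prepare_roi_data()] bundle), CSP fit on the training split, linear
#' SVM training, and test-split metrics.
#'
#' @param subset a [roi_subset()].
#' @param m_pairs CSP filter pairs; must satisfy
#'   `m_pairs <= floor(|subset| / 2)`.
#' @param data a `roi_data` bundle from [prepare_roi_data()], or a list
#'   `list(train=, test=)` of sensor trialsets (then `op`,
#'   `source_space`, `band` are required).
#' @param op,source_space,band forward/inverse context when `data` holds
#'   sensor trialsets.
#' @return object of class `eval_result` with `accuracy`, `sensitivity`,
#'   `specificity` (percent), `confusion`, `subset`, `m_pairs`, `band`.
#' @export
evaluate_subset <- function(subset, m_pairs, data, op = NULL,
                            source_space = NULL, band = NULL) {
  stopifnot(inherits(subset, "roi_subset"))
  if (!inherits(data, "roi_data")) {
    if (is.null(op) || is.null(source_space)) {
      stop("sensor-space input needs `op` and `source_space`")
    }
    data <- prepare_roi_data(data$train, data$test, op, source_space, band)
  }
  k <- length(subset$roi_ids)
  if (m_pairs > floor(k / 2)) {
    stop("m_pairs = ", m_pairs, " exceeds floor(|subset| / 2) = ",
         floor(k / 2), " with one time course per ROI")
  }
  idx <- match(subset$roi_ids, data$train$channel_names)
  if (anyNA(idx)) {
    stop("subset contains ROIs absent from the prepared data: ",
         paste(subset$roi_ids[is.na(idx)], collapse = ", "))
  }
  ev <- .eval_from_covs(data$covs_train, data$train$labels,
                        data$covs_test, data$test$labels, idx, m_pairs)
  structure(list(accuracy = ev$accuracy, sensitivity = ev$sensitivity,
                 specificity = ev$specificity, confusion = ev$confusion,
                 subset = subset, m_pairs = as.integer(m_pairs),
                 band = data$band),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("EvalResult [%s band, m = %d, ROIs: %s]\n  acc %.2f%%  sens %.2f%%  spec %.2f%%\n",
              x$band, x$m_pairs, paste(x$subset$roi_ids, collapse = ", "),
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Exhaustive ROI subset search
#'
#' Evaluates every (subset, filter-pair) configuration of a search mode
#' on prepared ROI data, selecting the best by accuracy.  Ties are broken
#' deterministically: highest accuracy, then smallest subset, then
#' smallest `m_pairs`, then enumeration (lexicographic) order; all
#' configurations at the winning accuracy are kept in `tied`.
#' Filter-pair values exceeding `floor(|subset| / 2)` are skipped and
#' recorded.
#'
#' @param data a [prepare_roi_data()] bundle.
#' @param mode search mode, see [enumerate_subsets()].
#' @param m_grid integer vector of CSP filter-pair counts to try
#'   (default `c(1, 2, 3)`; the 6-region two-lobe analysis is typically
#'   pinned to a single configured value).
#' @return object of class `subset_report`: `results` (one row per
#'   evaluation), `best` (an [evaluate_subset()] result), `tied` (list of
#'   tied best subsets), `skipped`, `mode`, `band`.
#' @export
run_search <- function(data, mode, m_grid = c(1, 2, 3)) {
  stopifnot(inherits(data, "roi_data"))
  if (length(m_grid) == 0) stop("m_grid must be non-empty")
  subsets <- enumerate_subsets(data$atlas, mode)
  rows <- vector("list", length(subsets) * length(m_grid))
  skipped <- list()
  nrow_used <- 0L
  for (si in seq_along(subsets)) {
    sub <- subsets[[si]]
    k <- length(sub$roi_ids)
    idx <- match(sub$roi_ids, data$train$channel_names)
    for (m in m_grid) {
      if (m > floor(k / 2)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          subset = paste(sub$roi_ids, collapse = "+"), m_pairs = m,
          reason = sprintf("m_pairs %d > floor(%d / 2)", m, k))
        next
      }
      ev <- .eval_from_covs(data$covs_train, data$train$labels,
                            data$covs_test, data$test$labels, idx, m)
      nrow_used <- nrow_used + 1L
      rows[[nrow_used]] <- data.frame(
        order = si, subset = paste(sub$roi_ids, collapse = "+"),
        size = k, m_pairs = m, accuracy = ev$accuracy,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows[seq_len(nrow_used)])
  ord <- order(-results$accuracy, results$size, results$m_pairs, results$order)
  winner <- results[ord[1], ]
  best <- evaluate_subset(roi_subset(strsplit(winner$subset, "+", fixed = TRUE)[[1]],
                                     data$atlas),
                          winner$m_pairs, data)
  tied_rows <- results[results$accuracy == winner$accuracy, ]
  tied <- unique(tied_rows$subset)
  structure(list(results = results, best = best,
                 tied = lapply(tied, function(s) strsplit(s, "+", fixed = TRUE)[[1]]),
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
                 mode = mode, band = data$band),
            class = "subset_report")
}

#' @export
print.subset_report <- function(x, ...) {
  cat(sprintf("Subset search [%s, %s band]: %d evaluations\n",
              x$mode, x$band, nrow(x$results)))
  cat("  best: "); print(x$best)
  if (length(x$tied) > 1) {
    cat("  (", length(x$tied), "subsets tied at the best accuracy )\n")
  }
  invisible(x)
}

#' Tally ROI occurrences across best results
#'
#' Counts, for every atlas region, how often it appears in the
#' best-accuracy subsets of a collection of search reports (the
#' computation behind the occurrence charts).  With
#' `weight = "fractional"` (default) each report distributes 1/k to the
#' members of each of its k tied best subsets; `weight = "winner"` counts
#' only the single tie-broken winner.
#'
#' @param reports list of [run_search()] reports.
#' @param weight `"fractional"` or `"winner"`.
#' @param allow_mixed permit reports from different search modes
#'   (default FALSE: mixing modes without saying so is an error).
#' @return data.frame with `roi_id` and `count`, one row per atlas
#'   region, atlas order.
#' @export
tally_occurrences <- function(reports, weight = c("fractional", "winner"),
                              allow_mixed = FALSE) {
  weight <- match.arg(weight)
  if (length(reports) == 0) stop("at least one report required")
  if (inherits(reports, "subset_report")) reports <- list(reports)
  modes <- unique(vapply(reports, function(r) r$mode, character(1)))
  if (length(modes) > 1 && !allow_mixed) {
    stop("reports mix search modes (", paste(modes, collapse = ", "),
         "); pass allow_mixed = TRUE to group them anyway")
  }
  # union of region ids seen in the reports, enumeration order
  all_ids <- unique(unlist(lapply(reports, function(r)
    unlist(strsplit(r$results$subset, "+", fixed = TRUE)))))
  counts <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (r in reports) {
    if (weight == "winner") {
      counts[r$best$subset$roi_ids] <- counts[r$best$subset$roi_ids] + 1
    } else {
      k <- length(r$tied)
      for (s in r$tied) counts[s] <- counts[s] + 1 / k
    }
  }
  data.frame(roi_id = names(counts), count = as.numeric(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plain-text ROI occurrence chart
#'
#' @param tally a [tally_occurrences()] data.frame.
#' @param width maximum bar width in characters.
#' @return the chart lines, invisibly; printed to the console.
#' @export
occurrence_chart <- function(tally, width = 40) {
  mx <- max(tally$count, 1e-12)
  lines <- sprintf("%-7s %s %.2f", tally$roi_id,
                   vapply(tally$count, function(ct)
                     paste(rep("#", round(width * ct / mx)), collapse = ""),
                     character(1)),
                   tally$count)
  cat(lines, sep = "\n")
  invisible(lines)
}
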