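#' Ordered subset of atlas ROIs
#'
#' @param roi_ids character vector of atlas region ids (e.g. `"S1H_L"`),
#'   non-empty, no duplicates.
#' @param atlas the [roi_atlas()] the ids must belong to.
#' @return object of class `roi_subset` with `roi_ids` and `mode`
#'   (`"left"`, `"right"` or `"both"`).
#' @export
roi_subset <- function(roi_ids, atlas = roi_atlas()) {
  stopifnot(inherits(atlas, "roi_atlas"))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) == 0) stop("an ROI subset must be non-empty")
  if (anyDuplicated(roi_ids)) stop("duplicate ROI ids in subset")
  unknown <- setdiff(roi_ids, atlas$regions$id)
  if (length(unknown)) {
    stop("unknown ROI ids: ", paste(unknown, collapse = ", "))
  }
  lobes <- unique(atlas$regions$lobe[match(roi_ids, atlas$regions$id)])
  mode <- if (identical(lobes, "L")) "left" else if (identical(lobes, "R")) "right" else "both"
  structure(list(roi_ids = roi_ids, mode = mode), class = "roi_subset")
}

#' @export
print.roi_subset <- function(x, ...) {
  cat("ROI subset (", x$mode, "): ", paste(x$roi_ids, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Sign-aligned mean of member time courses (k x T): each member is flipped
# to correlate positively with the first principal direction of the
# member block before averaging, so antiphase members reinforce rather
# than cancel.  The principal direction's sign is fixed deterministically
# (largest-magnitude loading made positive).
.sign_aligned_mean <- function(X) {
  k <- nrow(X)
  if (k == 1) return(X[1, ])
  sv <- svd(X, nu = 1, nv = 1)
  u <- sv$u[, 1]
  u <- u * sign(u[which.max(abs(u))])
  signs <- sign(u)
  signs[signs == 0] <- 1
  colMeans(X * signs)
}

#' Collapse a source estimate to one time course per ROI
#'
#' For every ROI in the subset, aggregates the standardized time courses
#' of its member sources.  The default aggregator is the sign-aligned
#' mean; `"mean"` (plain average) and `"pc1"` (first principal component,
#' scaled to the mean member RMS) are available for sensitivity checks.
#'
#' @param source_estimate an [apply_inverse()] result.
#' @param source_space the matching [source_space()].
#' @param subset a [roi_subset()].
#' @param method `"sign_aligned"` (default), `"mean"`, or `"pc1"`.
#' @return matrix `n_rois x n_samples`, rows in subset order and named by
#'   ROI id.
#' @export
extract_roi_timecourses <- function(source_estimate, source_space, subset,
                                    method = c("sign_aligned", "mean", "pc1")) {
  stopifnot(inherits(source_estimate, "source_estimate"),
            inherits(source_space, "source_space"),
            inherits(subset, "roi_subset"))
  method <- match.arg(method)
  A <- source_estimate$amplitudes
  out <- matrix(0, length(subset$roi_ids), ncol(A),
                dimnames = list(subset$roi_ids, NULL))
  for (r in seq_along(subset$roi_ids)) {
    members <- which(source_space$roi_labels == subset$roi_ids[r])
    if (length(members) == 0) {
      stop("ROI has no member sources: ", subset$roi_ids[r])
    }
    X <- A[members, , drop = FALSE]
    out[r, ] <- switch(method,
      sign_aligned = .sign_aligned_mean(X),
      mean = colMeans(X),
      pc1 = {
        if (nrow(X) == 1) X[1, ] else {
          sv <- svd(X, nu = 1, nv = 1)
          v <- sv$v[, 1] * sv$d[1] / sqrt(nrow(X))
          u <- sv$u[, 1]
          v * sign(u[which.max(abs(u))])
        }
      })
  }
  out
}

#' Build an ROI-space trialset from sensor trials
#'
#' Applies the sLORETA inverse and ROI aggregation to every trial:
#' sensor epochs become one standardized time course per ROI.  Labels and
#' trial order are carried through; channel names are the subset's ROI
#' ids.
#'
#' @param ts sensor-space [trialset()] matching the operator's montage.
#' @param op an [compute_inverse_operator()] result.
#' @param source_space the matching [source_space()].
#' @param subset a [roi_subset()].
#' @param method aggregation method, see [extract_roi_timecourses()].
#' @return a [trialset()] with `space = "roi"`.
#' @export
build_roi_trialset <- function(ts, op, source_space, subset,
                               method = "sign_aligned") {
  stopifnot(inherits(ts, "trialset"))
  if (ts$space != "sensor") stop("expected a sensor-space trialset")
  d <- dim(ts$data)
  out <- array(0, dim = c(d[1], length(subset$roi_ids), d[3]))
  for (i in seq_len(d[1])) {
    est <- apply_inverse(op, trial_matrix(ts, i))
    out[i, , ] <- extract_roi_timecourses(est, source_space, subset,
                                          method = method)
  }
  trialset(out, ts$labels, ts$fs, "roi", channel_names = subset$roi_ids)
}
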