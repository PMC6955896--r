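#' Labeled epoched multichannel trials
#'
#' Container for a set of epoched trials in sensor, source or ROI space:
#' a numeric array `n_trials x n_channels x n_samples` with per-trial class
#' labels (`"hand"` / `"foot"`) and a sampling rate.
#'
#' @param data numeric array, dim `c(n_trials, n_channels, n_samples)`.
#' @param labels factor or character of length `n_trials` with levels
#'   `hand`, `foot`.
#' @param fs sampling rate in Hz.
#' @param space one of `"sensor"`, `"source"`, `"roi"`.
#' @param channel_names optional character, length `n_channels`.
#' @return object of class `trialset`.
#' @export
trialset <- function(data, labels, fs, space = c("sensor", "source", "roi"),
                     channel_names = NULL) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array: trials x channels x samples")
  }
  if (any(!is.finite(data))) stop("trial data must be finite")
  labels <- factor(as.character(labels), levels = c("hand", "foot"))
  if (anyNA(labels)) stop("labels must all be 'hand' or 'foot'")
  if (length(labels) != dim(data)[1]) {
    stop("one label per trial required (", dim(data)[1], " trials)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  if (length(channel_names) != dim(data)[2]) {
    stop("`channel_names` must have one entry per channel")
  }
  structure(list(data = data, labels = labels, fs = fs, space = space,
                 channel_names = channel_names),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("TrialSet (%s space): %d trials x %d channels x %d samples @ %g Hz [hand %d / foot %d]\n",
              x$space, d[1], d[2], d[3], x$fs,
              sum(x$labels == "hand"), sum(x$labels == "foot")))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$data)

n_trials <- function(ts) dim(ts$data)[1]

# Extract trial i as a channels x samples matrix.
trial_matrix <- function(ts, i) {
  m <- ts$data[i, , , drop = FALSE]
  dim(m) <- dim(ts$data)[2:3]
  m
}

#' Select channels of a trialset
#'
#' @param ts a [trialset()].
#' @param channels integer indices or channel names.
#' @return a [trialset()] with the selected channels, order as requested.
#' @export
select_channels <- function(ts, channels) {
  stopifnot(inherits(ts, "trialset"))
  if (is.character(channels)) {
    idx <- match(channels, ts$channel_names)
    if (anyNA(idx)) {
      stop("unknown channels: ",
           paste(channels[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1 | idx > dim(ts$data)[2])) stop("channel index out of range")
  }
  trialset(ts$data[, idx, , drop = FALSE], ts$labels, ts$fs, ts$space,
           ts$channel_names[idx])
}

#' Write / read a trialset archive
#'
#' Serializes a trialset as a plain-text archive: a JSON sidecar with
#' labels, sampling rate, space and channel names, plus one CSV of the
#' flattened data (rows = trials, columns = channel x sample in
#' column-major order).  `read_trialset()` inverts it.
#'
#' @param ts a [trialset()].
#' @param path base path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @return `write_trialset()` the base path, invisibly;
#'   `read_trialset()` a [trialset()].
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$data)
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               labels = as.character(ts$labels), fs = ts$fs,
               space = ts$space, channel_names = ts$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(ts$data, nrow = d[1])
  utils::write.table(flat, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a lead-field archive
#'
#' Plain-text export of a gain matrix with its montage metadata: a JSON
#' sidecar (electrode labels, source count and shell radius, series
#' truncation, referencing) plus a CSV of the matrix.  The reader
#' returns a `lead_field` usable by [compute_inverse_operator()] and
#' [project_sources()]; the full electrode/source objects are not
#' round-tripped, only their identifying metadata.
#'
#' @param lf a [compute_lead_field()] result.
#' @param path base path without extension.
#' @return `write_lead_field()` the base path invisibly;
#'   `read_lead_field()` a `lead_field`.
#' @export
write_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  meta <- list(electrode_labels = lf$electrode_ref$labels,
               n_sources = ncol(lf$matrix),
               source_radius = lf$source_ref$radius,
               source_seed = lf$source_ref$seed,
               n_terms = lf$n_terms,
               average_reference = lf$average_reference)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(lf$matrix, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(M) <- list(meta$electrode_labels, NULL)
  structure(list(matrix = M, electrode_ref = list(labels = meta$electrode_labels),
                 source_ref = list(radius = meta$source_radius,
                                   seed = meta$source_seed),
                 head_model = NULL, n_terms = meta$n_terms,
                 average_reference = meta$average_reference),
            class = "lead_field")
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  arr <- array(flat, dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  trialset(arr, meta$labels, meta$fs, meta$space, meta$channel_names)
}
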