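#' Analysis band definition
#'
#' The two study bands are the broadband range 0.1-30 Hz (delta through
#' beta) and the motor-related mu rhythm at 8-13 Hz; arbitrary custom
#' bands are allowed.  Validity against the sampling rate is checked when
#' the band is applied.
#'
#' @param name `"broadband"`, `"mu"`, or `"custom"` (then give `low`,
#'   `high`).
#' @param low,high band edges in Hz (required for `"custom"`).
#' @return object of class `band_spec` with fields `low`, `high`, `name`.
#' @export
#' @examples
#' band_spec("mu")
#' band_spec("custom", 4, 8)
band_spec <- function(name = c("broadband", "mu", "custom"),
                      low = NULL, high = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
                  broadband = c(0.1, 30),
                  mu = c(8, 13),
                  custom = c(low, high))
  if (length(edges) != 2L || is.null(edges[1]) || is.null(edges[2])) {
    stop("custom bands need both `low` and `high`")
  }
  if (!(edges[1] >= 0 && edges[1] < edges[2])) {
    stop("band edges must satisfy 0 <= low < high")
  }
  structure(list(low = edges[1], high = edges[2], name = name),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("Band '%s': %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

# Zero-phase band-pass of one signal: the filter is run forward and
# backward, each pass starting from the steady internal state for a
# constant input at the segment's first sample.  This suppresses startup
# transients of the slow low-edge poles on short epochs without any
# padding (reflect padding injects junction kinks whose pass-band energy
# rings across a 200-sample epoch).
.zero_phase_bandpass <- function(x, b, a) {
  dc <- sum(b) / sum(a)
  pass <- function(v) {
    signal::filter(b, a, v, init.x = rep(v[1], length(b) - 1),
                   init.y = rep(v[1] * dc, length(a) - 1))
  }
  rev(pass(rev(pass(x))))
}

#' Band-pass filter a trialset
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and
#' backward, so the effective magnitude response is the squared
#' Butterworth response and group delay is zero).  Each pass is
#' initialized at its steady state for the epoch's first sample, which
#' keeps the slow low-edge poles from ringing across short epochs.
#' Labels, shape and space are preserved.
#'
#' @param ts a [trialset()].
#' @param band a [band_spec()]; `high` must be below `fs / 2`.
#' @param order Butterworth order (default 4).
#' @return a filtered [trialset()].
#' @export
bandpass <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "trialset"), inherits(band, "band_spec"))
  fs <- ts$fs
  if (band$high >= fs / 2) {
    stop("band high edge (", band$high, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  }
  filt <- signal::butter(order, c(band$low, band$high) / (fs / 2),
                         type = "pass")
  if (max(Mod(base::polyroot(rev(filt$a)))) >= 1) {
    stop("band-pass design is unstable at these edges; widen the band or lower the order")
  }
  d <- dim(ts$data)
  out <- ts$data
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- .zero_phase_bandpass(ts$data[i, j, ], filt$b, filt$a)
    }
  }
  trialset(out, ts$labels, fs, ts$space, ts$channel_names)
}

#' Slice a fixed-length window out of every trial
#'
#' Cuts the contiguous window `[t_start_s, t_start_s + duration_s)` from
#' each epoch, e.g. the two-second imagery slice out of a 3.5 s cue
#' period.
#'
#' @param ts a [trialset()].
#' @param t_start_s window start relative to epoch start, seconds.
#' @param duration_s window length, seconds.
#' @return a [trialset()] with `duration_s * fs` samples per trial.
#' @export
slice_epoch <- function(ts, t_start_s, duration_s) {
  stopifnot(inherits(ts, "trialset"))
  fs <- ts$fs
  i0 <- round(t_start_s * fs) + 1L
  len <- round(duration_s * fs)
  if (t_start_s < 0 || len < 1 || i0 + len - 1L > dim(ts$data)[3]) {
    stop(sprintf("window [%g, %g) s is outside the %g s epoch",
                 t_start_s, t_start_s + duration_s, dim(ts$data)[3] / fs))
  }
  trialset(ts$data[, , i0:(i0 + len - 1L), drop = FALSE], ts$labels, fs,
           ts$space, ts$channel_names)
}
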