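# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic trial generator configuration
#'
#' Parameters of the synthetic motor-imagery study: class-dependent
#' mu-band oscillations planted in somatomotor ROIs on top of 1/f
#' background source activity and white sensor noise.  The default planted
#' configuration gives the hand class extra 8-13 Hz power in the left
#' hand areas (S1H_L, M1H_L) and the foot class extra power in the left
#' foot areas (S1F_L, M1F_L), with a 2:1 RMS contrast.
#'
#' @param n_train,n_test trials per split (defaults 200 / 100).
#' @param class_balance fraction of hand trials (default 0.5).
#' @param fs sampling rate, Hz (default 100).
#' @param epoch_s epoch length, seconds (default 2).
#' @param planted_effects list of effects, each a list with `roi_id`,
#'   `band` (Hz pair), `amplitude_hand`, `amplitude_foot` (RMS in units of
#'   the unit-RMS background).
#' @param background_exponent spectral slope of the 1/f^a background
#'   (default 1).
#' @param sensor_snr ratio of projected-signal RMS to sensor-noise RMS
#'   (default 1; `Inf` disables sensor noise).
#' @param seed integer RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_train = 200, n_test = 100,
                             class_balance = 0.5, fs = 100, epoch_s = 2,
                             planted_effects = default_planted_effects(),
                             background_exponent = 1, sensor_snr = 1,
                             seed = 1) {
  if (n_train <= 0 || n_test <= 0) stop("trial counts must be positive")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie strictly inside (0, 1)")
  }
  if (fs <= 0) stop("fs must be positive")
  if (epoch_s <= 0) stop("epoch_s must be positive")
  if (background_exponent < 0) stop("background_exponent must be >= 0")
  if (!(sensor_snr > 0)) stop("sensor_snr must be positive (Inf for noiseless)")
  for (eff in planted_effects) {
    if (!all(c("roi_id", "band", "amplitude_hand", "amplitude_foot") %in%
             names(eff))) {
      stop("each planted effect needs roi_id, band, amplitude_hand, amplitude_foot")
    }
    if (fs <= 2 * max(eff$band)) {
      stop("fs must exceed twice the upper band edge of every planted effect")
    }
    if (eff$band[1] >= eff$band[2] || eff$band[1] < 0) {
      stop("planted band edges must satisfy 0 <= low < high")
    }
  }
  structure(list(n_train = n_train, n_test = n_test,
                 class_balance = class_balance, fs = fs, epoch_s = epoch_s,
                 planted_effects = planted_effects,
                 background_exponent = background_exponent,
                 sensor_snr = sensor_snr, seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_planted_effects <- function() {
  list(
    list(roi_id = "S1H_L", band = c(8, 13), amplitude_hand = 2, amplitude_foot = 1),
    list(roi_id = "M1H_L", band = c(8, 13), amplitude_hand = 2, amplitude_foot = 1),
    list(roi_id = "S1F_L", band = c(8, 13), amplitude_hand = 1, amplitude_foot = 2),
    list(roi_id = "M1F_L", band = c(8, 13), amplitude_hand = 1, amplitude_foot = 2)
  )
}

#' 1/f background source activity
#'
#' Zero-mean Gaussian processes with power spectral density proportional
#' to `1/f^exponent`, independent across sources, unit expected RMS.
#' Synthesized by spectral shaping of white noise (DC fixed at zero);
#' draws from the current RNG stream.
#'
#' @param n_sources number of independent processes.
#' @param n_samples samples per process (>= 64).
#' @param exponent spectral slope `a >= 0` (0 = white).
#' @param fs sampling rate, Hz.
#' @return matrix `n_sources x n_samples`.
#' @export
generate_background <- function(n_sources, n_samples, exponent = 1, fs = 100) {
  if (n_samples < 64) stop("n_samples must be at least 64")
  if (exponent < 0) stop("exponent must be >= 0")
  x <- matrix(stats::rnorm(n_sources * n_samples), n_sources, n_samples)
  if (exponent == 0) return(x)
  freqs <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  freqs <- pmin(freqs, fs - freqs)      # two-sided bins
  w <- c(0, freqs[-1]^(-exponent / 2))  # kill DC
  w <- w / sqrt(mean(w^2))              # unit expected variance
  X <- t(stats::mvfft(t(x)))
  X <- sweep(X, 2, w, "*")
  Re(t(stats::mvfft(t(X), inverse = TRUE))) / n_samples
}

# Band-limited unit-RMS Gaussian waveform: white noise restricted to
# [band[1], band[2]] Hz by Fourier masking.  Draws from the current stream.
bandlimited_noise <- function(n_samples, band, fs) {
  x <- stats::rnorm(n_samples)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
  freqs <- pmin(freqs, fs - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("band contains no Fourier bins at this epoch length")
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n_samples
  y / stats::sd(y)
}

#' Plant a class-dependent band-limited signal in one ROI
#'
#' Returns a source-activity increment: a single band-pass-filtered white
#' Gaussian waveform, shared coherently by every source inside the ROI
#' (modeling a locally synchronous oscillating patch), scaled to RMS
#' `amplitude_hand` or `amplitude_foot` according to the trial label.
#' Draws from the current RNG stream.
#'
#' @param source_space a [source_space()].
#' @param effect list with `roi_id`, `band`, `amplitude_hand`,
#'   `amplitude_foot`.
#' @param label `"hand"` or `"foot"`.
#' @param n_samples samples in the epoch.
#' @param fs sampling rate, Hz.
#' @return matrix `n_sources x n_samples`, zero outside the ROI.
#' @export
plant_class_signal <- function(source_space, effect, label, n_samples, fs) {
  stopifnot(inherits(source_space, "source_space"))
  members <- which(source_space$roi_labels == effect$roi_id)
  if (length(members) == 0) {
    stop("unknown or empty ROI in planted effect: ", effect$roi_id)
  }
  amp <- switch(match.arg(label, c("hand", "foot")),
                hand = effect$amplitude_hand, foot = effect$amplitude_foot)
  wave <- bandlimited_noise(n_samples, effect$band, fs) * amp
  inc <- matrix(0, length(source_space$roi_labels), n_samples)
  inc[members, ] <- rep(wave, each = length(members))
  inc
}

# One split of n trials; draws sequentially from the current RNG stream.
.generate_split <- function(config, leadfield, source_space, n) {
  n_samples <- round(config$fs * config$epoch_s)
  n_hand <- round(n * config$class_balance)
  labels <- sample(rep(c("hand", "foot"), c(n_hand, n - n_hand)))
  n_elec <- nrow(leadfield$matrix)
  data <- array(0, dim = c(n, n_elec, n_samples))
  for (i in seq_len(n)) {
    S <- generate_background(length(source_space$roi_labels), n_samples,
                             config$background_exponent, config$fs)
    for (eff in config$planted_effects) {
      S <- S + plant_class_signal(source_space, eff, labels[i], n_samples,
                                  config$fs)
    }
    W <- project_sources(leadfield, S)
    if (is.finite(config$sensor_snr)) {
      sd_noise <- sqrt(mean(W^2)) / config$sensor_snr
      W <- W + matrix(stats::rnorm(length(W), sd = sd_noise), nrow(W), ncol(W))
    }
    data[i, , ] <- W
  }
  trialset(data, labels, config$fs, "sensor",
           channel_names = leadfield$electrode_ref$labels)
}

#' Generate a labeled synthetic train/test trial pair
#'
#' Draws each trial's 1/f background and planted class signals in source
#' space, projects them through the lead field (W = L S) and adds white
#' sensor noise at the configured SNR.  The training split is drawn first
#' and the test split continues the same seeded stream, so the two splits
#' are disjoint draws and the pair is fully reproducible from
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @param leadfield a [compute_lead_field()] result over `source_space`.
#' @param source_space the [source_space()] the lead field was built on.
#' @return list with elements `train` and `test`, both [trialset()]s in
#'   sensor space.
#' @export
generate_trialset <- function(config, leadfield, source_space) {
  stopifnot(inherits(config, "generator_config"),
            inherits(leadfield, "lead_field"),
            inherits(source_space, "source_space"))
  if (ncol(leadfield$matrix) != length(source_space$roi_labels)) {
    stop("leadfield and source_space disagree on the number of sources")
  }
  for (eff in config$planted_effects) {
    if (!any(source_space$roi_labels == eff$roi_id)) {
      stop("planted effect names an ROI with no sources: ", eff$roi_id)
    }
  }
  with_seed(config$seed, {
    train <- .generate_split(config, leadfield, source_space, config$n_train)
    test <- .generate_split(config, leadfield, source_space, config$n_test)
    list(train = train, test = test)
  })
}
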