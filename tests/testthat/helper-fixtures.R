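# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fix_head_model <- function() memo("hm", head_model())
fix_atlas <- function() memo("atlas", roi_atlas())
fix_electrodes <- function() memo("el", electrode_array(32, fix_head_model()))

# 500-source labeled space + lead field + inverse (default study geometry)
fix_sources <- function() {
  memo("ss", source_space(500, fix_head_model(), fix_atlas(), seed = 1))
}
fix_leadfield <- function() {
  memo("lf", compute_lead_field(fix_electrodes(), fix_sources(), fix_head_model()))
}
fix_inverse <- function() memo("op", compute_inverse_operator(fix_leadfield()))

# Small unlabeled localization grid (100 sources)
fix_sources100 <- function() {
  memo("ss100", source_space(100, fix_head_model(), atlas = NULL, seed = 1))
}
fix_leadfield100 <- function() {
  memo("lf100",
       compute_lead_field(fix_electrodes(), fix_sources100(), fix_head_model()))
}

# Default synthetic study (seed 1) and its mu-band ROI data
fix_study <- function() memo("study", simulate_study(generator_config(seed = 1)))
fix_roi_mu <- function() {
  memo("roi_mu", {
    st <- fix_study()
    prepare_roi_data(st$train, st$test, st$inverse_op, st$sources,
                     band_spec("mu"))
  })
}

planted_roi_ids <- c("S1H_L", "M1H_L", "S1F_L", "M1F_L")

# Random SPD matrix with unit trace
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) + diag(n) * 0.1
  S / sum(diag(S))
}

# Small trialset with white-noise data and given labels
noise_trialset <- function(n_trials, n_channels, n_samples, labels = NULL,
                           fs = 100, space = "sensor") {
  if (is.null(labels)) {
    labels <- rep(c("hand", "foot"), length.out = n_trials)
  }
  trialset(array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples)),
           labels, fs, space)
}

# Binomial 99% interval around 50% for n test trials, in percent
null_band <- function(n) {
  half <- 100 * stats::qnorm(0.995) * sqrt(0.25 / n)
  c(50 - half, 50 + half)
}
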