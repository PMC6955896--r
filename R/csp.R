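# Per-trial raw covariance stack: array n_ch x n_ch x n_trials of X X'.
trial_cov_stack <- function(ts) {
  d <- dim(ts$data)
  covs <- array(0, dim = c(d[2], d[2], d[1]))
  for (i in seq_len(d[1])) {
    X <- trial_matrix(ts, i)
    covs[, , i] <- tcrossprod(X)
  }
  covs
}

# Class-average covariances (each trial trace-normalized unless
# trace_norm = FALSE) with diagonal shrinkage delta toward (trace/n) I.
.class_covariances <- function(covs, labels, shrinkage, trace_norm = TRUE) {
  n_ch <- dim(covs)[1]
  avg <- function(idx) {
    C <- matrix(0, n_ch, n_ch)
    for (i in idx) {
      Ci <- covs[, , i]
      tr <- if (trace_norm) sum(diag(Ci)) else 1
      if (tr <= 0) stop("trial with zero power cannot be trace-normalized")
      C <- C + Ci / tr
    }
    C <- C / length(idx)
    (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / n_ch) * diag(n_ch)
  }
  list(pos = avg(which(labels == "hand")),
       neg = avg(which(labels == "foot")))
}

# Generalized eigendecomposition of (Cp, Cp + Cn) by whitening the
# composite covariance.  Returns filters (columns, descending eigenvalue)
# and eigenvalues in [0, 1].
.csp_decompose <- function(Cp, Cn, rank_tol = 1e-10) {
  Cc <- Cp + Cn
  ec <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)
  if (min(ec$values) <= rank_tol * max(ec$values)) {
    stop("composite covariance is rank deficient; increase shrinkage or trials")
  }
  Wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)       # whitener
  S <- Wh %*% Cp %*% t(Wh)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)           # descending
  filters <- t(Wh) %*% es$vectors
  lambda <- pmin(pmax(es$values, 0), 1)
  list(filters = filters, eigenvalues = lambda)
}

#' Fit common spatial pattern filters
#'
#' Two-class CSP: per-trial covariances are trace-normalized and averaged
#' within class (hand = positive class, foot = negative), lightly shrunk
#' toward a scaled identity, and the generalized eigenproblem
#' `C_pos w = lambda (C_pos + C_neg) w` is solved by whitening the
#' composite covariance.  Filters at the top of the eigenvalue spectrum
#' maximize hand-class variance, those at the bottom maximize foot-class
#' variance.
#'
#' @param ts a two-class [trialset()] with at least 2 trials per class.
#' @param m_pairs number of filter pairs to use as features
#'   (1 <= m_pairs <= floor(n_channels / 2)).
#' @param shrinkage diagonal shrinkage delta (default 1e-6).
#' @param trace_norm normalize each trial covariance by its trace before
#'   averaging (default TRUE, standard CSP practice; disable to make the
#'   decomposition exactly invariant to arbitrary invertible channel
#'   mixings rather than only to orthogonal ones).
#' @return object of class `csp_model`: `filters` (n_ch x n_ch, columns by
#'   descending eigenvalue), `eigenvalues` (in [0, 1]), `m_pairs`,
#'   `class_order = c("hand", "foot")`, `class_covs`.
#' @export
fit_csp <- function(ts, m_pairs = 1, shrinkage = 1e-6, trace_norm = TRUE) {
  stopifnot(inherits(ts, "trialset"))
  n_ch <- dim(ts$data)[2]
  if (n_ch < 2) stop("CSP needs at least 2 channels")
  if (m_pairs < 1 || m_pairs > floor(n_ch / 2)) {
    stop("m_pairs must lie in [1, floor(n_channels / 2)] = [1, ",
         floor(n_ch / 2), "]")
  }
  counts <- table(ts$labels)
  if (any(counts < 2)) {
    stop("both classes must be present with at least 2 trials each")
  }
  covs <- trial_cov_stack(ts)
  cc <- .class_covariances(covs, ts$labels, shrinkage, trace_norm)
  dec <- .csp_decompose(cc$pos, cc$neg)
  structure(list(filters = dec$filters, eigenvalues = dec$eigenvalues,
                 m_pairs = as.integer(m_pairs),
                 class_order = c(positive = "hand", negative = "foot"),
                 class_covs = cc, n_channels = n_ch),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("CSP model: %d channels, %d filter pair(s); eigenvalues %s\n",
              x$n_channels, x$m_pairs,
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

# Feature block from a covariance matrix and chosen filter columns.
.csp_features_from_cov <- function(C, filters, idx) {
  v <- vapply(idx, function(j) {
    w <- filters[, j]
    drop(crossprod(w, C %*% w))
  }, numeric(1))
  log(v / sum(v))
}

#' CSP log-variance features
#'
#' Projects every trial onto the `m_pairs` top and `m_pairs` bottom CSP
#' filters and returns the log of each projected variance normalized by
#' the sum of the `2 m_pairs` projected variances.
#'
#' @param model a [fit_csp()] result.
#' @param ts a [trialset()] with the model's channel count.
#' @param m_pairs optional override of the model's filter-pair count.
#' @return matrix `n_trials x (2 * m_pairs)`.
#' @export
transform_csp <- function(model, ts, m_pairs = model$m_pairs) {
  stopifnot(inherits(model, "csp_model"), inherits(ts, "trialset"))
  n_ch <- model$n_channels
  if (dim(ts$data)[2] != n_ch) {
    stop("trialset has ", dim(ts$data)[2], " channels; model expects ", n_ch)
  }
  if (m_pairs < 1 || 2 * m_pairs > n_ch) {
    stop("m_pairs exceeds the model's capacity (floor(n_channels / 2) = ",
         floor(n_ch / 2), ")")
  }
  idx <- c(seq_len(m_pairs), seq(n_ch - m_pairs + 1L, n_ch))
  covs <- trial_cov_stack(ts)
  t(vapply(seq_len(dim(covs)[3]),
           function(i) .csp_features_from_cov(covs[, , i], model$filters, idx),
           numeric(2 * m_pairs)))
}
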