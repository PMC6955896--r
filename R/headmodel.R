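#' Three-shell spherical head model
#'
#' Concentric-sphere conductor with scalp, skull and brain compartments.
#' Radii are outer shell radii in meters and must decrease strictly from
#' scalp to brain; conductivities are in S/m.  Defaults use the conventional
#' high scalp/brain conductivity with a resistive skull (scalp 1, skull
#' 0.0125, brain 1 S/m) and shell radii 0.090 / 0.085 / 0.080 m.
#'
#' @param radii numeric length 3: scalp, skull, brain outer radii (m),
#'   strictly decreasing.
#' @param conductivities numeric length 3: scalp, skull, brain (S/m),
#'   strictly positive.
#' @return object of class `head_model` with fields `radii` and
#'   `conductivities`, each named `c("scalp", "skull", "brain")`.
#' @export
#' @examples
#' hm <- head_model()
#' hm$conductivities
head_model <- function(radii = c(scalp = 0.090, skull = 0.085, brain = 0.080),
                       conductivities = c(scalp = 1, skull = 0.0125, brain = 1)) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != 3L || length(conductivities) != 3L) {
    stop("`radii` and `conductivities` must each have length 3 (scalp, skull, brain)")
  }
  if (any(!is.finite(radii)) || any(diff(radii) >= 0)) {
    stop("shell radii must be finite and strictly decreasing: scalp > skull > brain")
  }
  if (any(!is.finite(conductivities)) || any(conductivities <= 0)) {
    stop("conductivities must be finite and strictly positive")
  }
  names(radii) <- names(conductivities) <- c("scalp", "skull", "brain")
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_model")
}

# Quasi-uniform points on the upper unit hemisphere (z > 0), n >= 1.
# Golden-angle (Fibonacci) lattice; deterministic.  `az_offset` rotates the
# lattice about the z axis (radians).
fibonacci_hemisphere <- function(n, az_offset = 0) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  ga <- pi * (3 - sqrt(5))
  az <- i * ga + az_offset
  rxy <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rxy * cos(az), y = rxy * sin(az), z = z)
}

#' Electrode array on the scalp surface
#'
#' Builds a quasi-uniform upper-hemisphere montage of `n` electrodes on the
#' scalp sphere (average reference), or wraps explicit unit-direction
#' positions.  The default 32-channel lattice is adequate for synthetic
#' work; `n = 118` gives a dense montage comparable in channel count to
#' high-density 10-5 recordings (positions are a lattice approximation, not
#' the 10-5 standard).
#'
#' @param n number of electrodes (>= 4); ignored when `positions` given.
#' @param head_model a [head_model()]; electrodes sit at its scalp radius.
#' @param positions optional matrix (n x 3) of directions; rows are scaled
#'   to the scalp radius.
#' @param labels optional character vector of unique channel names.
#' @return object of class `electrode_array` with `labels`, `positions`
#'   (meters, rows on the scalp sphere) and `reference = "average"`.
#' @export
electrode_array <- function(n = 32, head_model = NULL,
                            positions = NULL, labels = NULL) {
  if (is.null(head_model)) head_model <- head_model()
  stopifnot(inherits(head_model, "head_model"))
  r_scalp <- head_model$radii[["scalp"]]
  if (is.null(positions)) {
    if (n < 4) stop("an electrode array needs at least 4 channels")
    positions <- fibonacci_hemisphere(n)
  } else {
    positions <- as.matrix(positions)
    if (ncol(positions) != 3L) stop("`positions` must be an n x 3 matrix")
    n <- nrow(positions)
    if (n < 4) stop("an electrode array needs at least 4 channels")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("electrode directions must be non-zero")
  positions <- positions / nrm * r_scalp
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(n))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (length(labels) != n) stop("`labels` length must match the number of electrodes")
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions,
                 reference = "average", scalp_radius = r_scalp),
            class = "electrode_array")
}

# Canonical somatomotor region ids, in homuncular order along the central
# sulcus (medial foot representation first within each functional strip).
.roi_base_ids <- c("S1F", "S1H", "CMA", "M1F", "M1H", "SMA", "pSMA", "PMd", "PMv")

# Default angular placement (degrees): `lat` = tilt from the vertex toward
# the lobe (left = -x), `ap` = anterior(+)/posterior(-) tilt.  Foot areas sit
# within 15 deg of the midline, hand areas 30-45 deg lateral; premotor
# regions are anterior to the motor strip, somatosensory regions posterior.
.roi_default_centers <- data.frame(
  id  = .roi_base_ids,
  lat = c(6, 40, 4, 8, 42, 8, 6, 32, 54),
  ap  = c(-17, -18, 9, -4, 0, 22, 35, 16, 10)
)

# Unit direction for (lat, ap) tilts in degrees; `side` = -1 left, +1 right.
.roi_direction <- function(lat, ap, side) {
  lat <- lat * pi / 180
  ap <- ap * pi / 180
  c(side * sin(lat), cos(lat) * sin(ap), cos(lat) * cos(ap))
}

#' Somatomotor ROI atlas on the cortical sphere
#'
#' Realizes the nine somatomotor regions used per hemisphere (S1F, S1H,
#' CMA, M1F, M1H, SMA, pSMA, PMd, PMv) as spherical caps, mirrored across
#' the midline plane (x = 0) to give 18 regions.  Region ids carry a lobe
#' suffix, e.g. `S1H_L`, `M1F_R`.
#'
#' @param angular_radius cap radius in degrees (default 6).
#' @param centers optional data.frame with columns `id`, `lat`, `ap`
#'   (degrees) overriding the default placement of the 9 base regions.
#' @return object of class `roi_atlas`: data.frame `regions` with columns
#'   `id`, `name`, `lobe` (`"L"`/`"R"`), unit-vector center columns
#'   `cx`, `cy`, `cz`, and `angular_radius` (degrees, per region).
#' @export
#' @examples
#' atlas <- roi_atlas()
#' table(atlas$regions$lobe)
roi_atlas <- function(angular_radius = 6, centers = NULL) {
  if (is.null(centers)) centers <- .roi_default_centers
  if (!all(c("id", "lat", "ap") %in% names(centers))) {
    stop("`centers` needs columns id, lat, ap")
  }
  if (!setequal(centers$id, .roi_base_ids)) {
    stop("`centers` must define exactly the 9 base regions: ",
         paste(.roi_base_ids, collapse = ", "))
  }
  centers <- centers[match(.roi_base_ids, centers$id), ]
  long_names <- c(
    S1F = "primary foot somatosensory area",
    S1H = "primary hand somatosensory area",
    CMA = "cingulate motor area",
    M1F = "primary foot motor area",
    M1H = "primary hand motor area",
    SMA = "supplementary motor area",
    pSMA = "presupplementary motor area",
    PMd = "dorsal premotor cortex",
    PMv = "ventral premotor cortex"
  )
  rows <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    for (k in seq_len(nrow(centers))) {
      d <- .roi_direction(centers$lat[k], centers$ap[k], sgn)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(centers$id[k], "_", side),
        name = long_names[[centers$id[k]]],
        lobe = side,
        cx = d[1], cy = d[2], cz = d[3],
        angular_radius = angular_radius,
        stringsAsFactors = FALSE
      )
    }
  }
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  # same-lobe caps must not overlap
  for (side in c("L", "R")) {
    sub <- regions[regions$lobe == side, ]
    C <- as.matrix(sub[, c("cx", "cy", "cz")])
    ang <- acos(pmin(pmax(tcrossprod(C), -1), 1)) * 180 / pi
    need <- outer(sub$angular_radius, sub$angular_radius, "+")
    diag(ang) <- Inf
    if (any(ang < need)) {
      bad <- which(ang < need, arr.ind = TRUE)[1, ]
      stop(sprintf("ROI caps %s and %s overlap (centers %.1f deg apart, radii sum %.1f deg)",
                   sub$id[bad[1]], sub$id[bad[2]], ang[bad[1], bad[2]],
                   need[bad[1], bad[2]]))
    }
  }
  structure(list(regions = regions), class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("ROI atlas:", nrow(x$regions), "spherical-cap regions (",
      sum(x$regions$lobe == "L"), "left /", sum(x$regions$lobe == "R"),
      "right )\n")
  invisible(x)
}

roi_ids <- function(atlas) atlas$regions$id

#' Cortical source space on a spherical shell
#'
#' Places `n_sources` quasi-uniform radial dipoles on an upper-hemisphere
#' shell at `cortical_fraction` of the brain radius and labels each with
#' the containing ROI cap (nearest cap center when caps from opposite
#' lobes overlap near the midline) or `"background"`.
#'
#' @param n_sources number of dipoles (>= 2 x number of atlas regions).
#' @param head_model a [head_model()].
#' @param atlas a [roi_atlas()], or `NULL` for an unlabeled space (all
#'   sources `"background"`, no coverage requirement) as used in
#'   localization benchmarks.
#' @param seed integer; rotates the deterministic lattice about the z axis
#'   so that distinct seeds give distinct (but reproducible) samplings.
#' @param cortical_fraction source shell radius as a fraction of the brain
#'   radius (default 0.85, keeping the truncated forward series well
#'   converged).
#' @return object of class `source_space`: `positions` (n x 3, meters),
#'   `orientations` (n x 3 radial unit vectors), `roi_labels` (character),
#'   `radius` (m), and the atlas used.
#' @export
source_space <- function(n_sources = 500, head_model = NULL,
                         atlas = roi_atlas(), seed = 1,
                         cortical_fraction = 0.85) {
  if (is.null(head_model)) head_model <- head_model()
  stopifnot(inherits(head_model, "head_model"))
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "roi_atlas"))
    n_regions <- nrow(atlas$regions)
    if (n_sources < 2 * n_regions) {
      stop("n_sources must be at least twice the number of atlas regions (",
           2 * n_regions, ")")
    }
  } else if (n_sources < 2) {
    stop("n_sources must be at least 2")
  }
  if (cortical_fraction <= 0 || cortical_fraction >= 1) {
    stop("cortical_fraction must lie strictly inside (0, 1)")
  }
  r_src <- cortical_fraction * head_model$radii[["brain"]]
  az_offset <- (as.integer(seed) %% 3600L) * (2 * pi / 3600)
  dirs <- fibonacci_hemisphere(n_sources, az_offset = az_offset)
  labels <- rep("background", n_sources)
  if (!is.null(atlas)) {
    C <- as.matrix(atlas$regions[, c("cx", "cy", "cz")])
    ang <- acos(pmin(pmax(dirs %*% t(C), -1), 1)) * 180 / pi # n_src x n_regions
    inside <- sweep(ang, 2, atlas$regions$angular_radius, "<=")
    hit <- which(rowSums(inside) > 0)
    for (i in hit) {
      cand <- which(inside[i, ])
      labels[i] <- atlas$regions$id[cand[which.min(ang[i, cand])]]
    }
    empty <- setdiff(atlas$regions$id, unique(labels))
    if (length(empty) > 0) {
      stop("source space leaves ROIs without any source: ",
           paste(empty, collapse = ", "),
           " -- increase n_sources or the cap radius")
    }
  }
  structure(list(positions = dirs * r_src, orientations = dirs,
                 roi_labels = labels, radius = r_src, atlas = atlas,
                 seed = as.integer(seed),
                 cortical_fraction = cortical_fraction),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat("Source space:", nrow(x$positions), "radial dipoles at",
      signif(x$radius, 3), "m;",
      sum(x$roi_labels != "background"), "inside ROIs\n")
  invisible(x)
}

# Legendre polynomials P_1..P_n evaluated by upward recurrence; returns the
# running accumulation sum_n coef[n] * P_n(x) for a matrix x of cos(gamma).
# coef is a matrix (n_terms x ncol(x)) when coefficients differ per column.
.legendre_accumulate <- function(cosg, coef) {
  acc <- matrix(0, nrow(cosg), ncol(cosg))
  p_prev <- matrix(1, nrow(cosg), ncol(cosg)) # P_0
  p_cur <- cosg                               # P_1
  n_terms <- nrow(coef)
  for (n in seq_len(n_terms)) {
    acc <- acc + p_cur * matrix(coef[n, ], nrow(cosg), ncol(cosg), byrow = TRUE)
    # advance P_{n} -> P_{n+1}
    p_next <- ((2 * n + 1) * cosg * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc
}

# Series coefficients c_n for the scalp-surface potential of a radial unit
# dipole at radius `b` (meters) in the three-shell model.  Works in radii
# scaled by the scalp radius for conditioning.  Returns numeric n_terms.
.three_sphere_coefs <- function(b, head_model, n_terms) {
  R <- head_model$radii[["scalp"]]
  rho1 <- head_model$radii[["brain"]] / R
  rho2 <- head_model$radii[["skull"]] / R
  rb <- b / R
  s1 <- head_model$conductivities[["brain"]]
  s2 <- head_model$conductivities[["skull"]]
  s3 <- head_model$conductivities[["scalp"]]
  coefs <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    sn <- n * rb^(n - 1) / (4 * pi * s1 * R^2)
    k <- n / (n + 1)
    # unknowns: A1, A2, B2, A3   (B3 = k * A3)
    M <- rbind(
      c(rho1^n, -rho1^n, -rho1^(-(n + 1)), 0),
      c(s1 * n * rho1^(n - 1), -s2 * n * rho1^(n - 1),
        s2 * (n + 1) * rho1^(-(n + 2)), 0),
      c(0, rho2^n, rho2^(-(n + 1)), -(rho2^n + k * rho2^(-(n + 1)))),
      c(0, s2 * n * rho2^(n - 1), -s2 * (n + 1) * rho2^(-(n + 2)),
        -s3 * n * (rho2^(n - 1) - rho2^(-(n + 2))))
    )
    rhs <- c(-sn * rho1^(-(n + 1)), s1 * (n + 1) * sn * rho1^(-(n + 2)), 0, 0)
    x <- solve(M, rhs)
    coefs[n] <- x[4] * (1 + k)  # A3 + B3 at the scalp surface
  }
  coefs
}

#' Lead field of the three-shell spherical head model
#'
#' Analytic scalp potential of radial unit dipoles in the concentric
#' three-sphere conductor, evaluated as a truncated Legendre series and
#' average-referenced across electrodes.  Gain units are V per A m of
#' dipole moment.
#'
#' @param electrodes an [electrode_array()] on the model's scalp radius.
#' @param sources a [source_space()]; all positions strictly inside the
#'   brain radius.
#' @param head_model the [head_model()] shared by both.
#' @param n_terms series truncation (default 60).
#' @param average_reference center each column across electrodes
#'   (default TRUE).
#' @param convergence_tol error if the last retained series term still
#'   contributes more than this fraction of the largest coefficient
#'   magnitude for any source (default 1e-2).
#' @return object of class `lead_field`: `matrix` (n_electrodes x
#'   n_sources), `electrode_ref`, `source_ref`, `n_terms`,
#'   `average_reference`.
#' @export
compute_lead_field <- function(electrodes, sources, head_model,
                               n_terms = 60, average_reference = TRUE,
                               convergence_tol = 1e-2) {
  stopifnot(inherits(electrodes, "electrode_array"),
            inherits(sources, "source_space"),
            inherits(head_model, "head_model"))
  if (n_terms < 2) stop("n_terms must be at least 2")
  E <- electrodes$positions
  P <- sources$positions
  r_brain <- head_model$radii[["brain"]]
  b <- sqrt(rowSums(P^2))
  if (any(b >= r_brain)) {
    stop("all sources must lie strictly inside the brain radius (",
         r_brain, " m)")
  }
  R <- head_model$radii[["scalp"]]
  if (max(abs(sqrt(rowSums(E^2)) - R)) > 1e-9) {
    stop("electrodes must sit on the scalp radius of this head model")
  }
  # coefficients per unique source radius
  ub <- unique(b)
  coef <- matrix(0, n_terms, length(b))
  for (bu in ub) {
    cs <- .three_sphere_coefs(bu, head_model, n_terms)
    tail_frac <- abs(cs[n_terms]) / max(abs(cs))
    if (!is.finite(tail_frac) || tail_frac > convergence_tol) {
      stop(sprintf(paste0("Legendre series not converged at n_terms = %d for ",
                          "source radius %.4f m (last-term fraction %.2e > %.0e); ",
                          "increase n_terms or move sources deeper"),
                   n_terms, bu, tail_frac, convergence_tol))
    }
    coef[, b == bu] <- cs
  }
  cosg <- (E %*% t(P)) / outer(rep(R, nrow(E)), b)
  cosg <- pmin(pmax(cosg, -1), 1)
  L <- .legendre_accumulate(cosg, coef)
  if (average_reference) L <- sweep(L, 2, colMeans(L))
  dimnames(L) <- list(electrodes$labels, NULL)
  structure(list(matrix = L,
                 electrode_ref = electrodes,
                 source_ref = sources,
                 head_model = head_model,
                 n_terms = n_terms,
                 average_reference = average_reference),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("Lead field:", nrow(x$matrix), "electrodes x", ncol(x$matrix),
      "sources (three-shell sphere,", x$n_terms, "series terms)\n")
  invisible(x)
}

#' Forward-project source activity to the sensors
#'
#' Applies the linear forward model W = L S: source amplitude time courses
#' become electrode potentials.
#'
#' @param leadfield a [compute_lead_field()] result.
#' @param source_activity matrix n_sources x n_samples.
#' @return matrix n_electrodes x n_samples.
#' @export
project_sources <- function(leadfield, source_activity) {
  stopifnot(inherits(leadfield, "lead_field"))
  source_activity <- as.matrix(source_activity)
  if (nrow(source_activity) != ncol(leadfield$matrix)) {
    stop("source_activity must have one row per source (",
         ncol(leadfield$matrix), ")")
  }
  leadfield$matrix %*% source_activity
}
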