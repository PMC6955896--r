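test_that("head model validates shells and conductivities", {
  hm <- head_model(conductivities = c(1, 0.0125, 1))
  expect_equal(unname(hm$conductivities), c(1, 0.0125, 1))
  expect_equal(unname(hm$radii), c(0.090, 0.085, 0.080))
  expect_error(head_model(radii = c(0.08, 0.085, 0.09)), "decreasing")
  expect_error(head_model(conductivities = c(1, 0, 1)), "positive")
  expect_error(head_model(conductivities = c(1, -0.1, 1)), "positive")
})

test_that("ROI atlas has 9 mirror-symmetric non-overlapping caps per lobe", {
  atlas <- fix_atlas()
  reg <- atlas$regions
  expect_equal(nrow(reg), 18L)
  expect_equal(as.vector(table(reg$lobe)), c(9L, 9L))
  base <- sub("_[LR]$", "", reg$id)
  expect_setequal(unique(base),
                  c("S1F", "S1H", "CMA", "M1F", "M1H", "SMA", "pSMA", "PMd", "PMv"))
  # mirror: negating x of left centers gives the right centers
  left <- reg[reg$lobe == "L", ]
  right <- reg[reg$lobe == "R", ]
  expect_equal(-left$cx, right$cx, tolerance = 1e-12)
  expect_equal(left$cy, right$cy)
  expect_equal(left$cz, right$cz)
  # homuncular ordering: foot areas medial, hand areas lateral
  lat_of <- function(id) asin(abs(reg$cx[reg$id == id])) * 180 / pi
  expect_lt(lat_of("S1F_L"), 15)
  expect_lt(lat_of("M1F_L"), 15)
  expect_gt(lat_of("S1H_L"), 30)
  expect_gt(lat_of("M1H_L"), 30)
  # growing the caps until they touch is a configuration error
  expect_error(roi_atlas(angular_radius = 12), "overlap")
})

test_that("source space covers every ROI, is deterministic, errors when too small", {
  ss <- fix_sources()
  labs <- ss$roi_labels[ss$roi_labels != "background"]
  expect_setequal(unique(labs), fix_atlas()$regions$id)
  expect_true(all(abs(sqrt(rowSums(ss$positions^2)) - ss$radius) < 1e-12))
  expect_lt(ss$radius, fix_head_model()$radii[["skull"]])
  expect_equal(sqrt(rowSums(ss$orientations^2)), rep(1, 500))
  ss2 <- source_space(500, fix_head_model(), fix_atlas(), seed = 1)
  expect_identical(ss, ss2)
  expect_error(source_space(36, fix_head_model(), fix_atlas(), seed = 1),
               "without any source")
  expect_error(source_space(10, fix_head_model(), fix_atlas(), seed = 1),
               "at least twice")
})

test_that("lead field matches the homogeneous-sphere closed form", {
  # with equal conductivities the scalp potential of a radial dipole at
  # scaled radius rb is sum_n rb^(n-1) (2n+1)/(4 pi sigma R^2) P_n(cos g)
  hm <- head_model(conductivities = c(2, 2, 2))
  el <- electrode_array(16, hm)
  ss <- source_space(40, hm, atlas = NULL, seed = 3, cortical_fraction = 0.6)
  lf <- compute_lead_field(el, ss, hm, n_terms = 80, average_reference = FALSE)
  R <- hm$radii[["scalp"]]
  b <- 0.6 * hm$radii[["brain"]]
  legendre_eval <- function(x, n_max) {
    out <- matrix(0, length(x), n_max)
    p0 <- rep(1, length(x)); p1 <- x
    for (n in seq_len(n_max)) {
      out[, n] <- p1
      p2 <- ((2 * n + 1) * x * p1 - n * p0) / (n + 1)
      p0 <- p1; p1 <- p2
    }
    out
  }
  cosg <- (el$positions %*% t(ss$positions)) / (R * b)
  n <- 1:80
  coefs <- (b / R)^(n - 1) * (2 * n + 1) / (4 * pi * 2 * R^2)
  ref <- matrix(0, nrow(cosg), ncol(cosg))
  for (j in seq_len(ncol(cosg))) {
    ref[, j] <- legendre_eval(cosg[, j], 80) %*% coefs
  }
  expect_equal(unname(lf$matrix), ref, tolerance = 1e-10)
})

test_that("lead field is average-referenced, converged and depth-attenuating", {
  lf <- fix_leadfield()
  # average-reference closure: columns sum to ~0 relative to their norm
  csums <- abs(colSums(lf$matrix)) / sqrt(colSums(lf$matrix^2))
  expect_lt(max(csums), 1e-10)
  # truncation self-convergence 60 vs 120 terms
  lf120 <- compute_lead_field(fix_electrodes(), fix_sources(),
                              fix_head_model(), n_terms = 120)
  rel <- sqrt(colSums((lf$matrix - lf120$matrix)^2)) /
    sqrt(colSums(lf120$matrix^2))
  expect_lt(max(rel), 1e-6)
  # depth attenuation on a radial sweep at fixed angular position
  hm <- fix_head_model()
  el <- fix_electrodes()
  fracs <- c(0.95, 0.8, 0.65, 0.5, 0.35)
  norms <- vapply(fracs, function(f) {
    ss <- source_space(10, hm, atlas = NULL, seed = 1, cortical_fraction = f)
    L <- compute_lead_field(el, ss, hm, n_terms = 120)$matrix
    sqrt(sum(L[, 5]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_gt(norms[1], norms[4]) # 0.95 x brain vs 0.5 x brain, same angle
})

test_that("lead field rejects out-of-bounds sources and unconverged series", {
  hm <- fix_head_model()
  el <- fix_electrodes()
  ss_out <- source_space(10, hm, atlas = NULL, seed = 1,
                         cortical_fraction = 0.99999)
  ss_out$positions <- ss_out$positions * 1.2
  expect_error(compute_lead_field(el, ss_out, hm), "inside the brain radius")
  ss_shallow <- source_space(10, hm, atlas = NULL, seed = 1,
                             cortical_fraction = 0.999)
  expect_error(compute_lead_field(el, ss_shallow, hm, n_terms = 10),
               "not converged")
})

test_that("mirror-image sources produce mirror-image sensor patterns", {
  hm <- fix_head_model()
  # montage symmetric under x -> -x: pair each electrode with its mirror
  base <- fibonacci_hemisphere(12)
  pos <- rbind(base, cbind(-base[, 1], base[, 2:3]))
  el <- electrode_array(head_model = hm, positions = pos)
  dirs <- rbind(c(-0.4, 0.2, 0.89), c(0.4, 0.2, 0.89))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ss <- source_space(24, hm, atlas = NULL, seed = 1)
  ss$positions[1:2, ] <- dirs * ss$radius
  L <- compute_lead_field(el, ss, hm)$matrix
  # column of source 1 at electrode i equals column of its mirror source
  # at the mirrored electrode i + 12
  expect_equal(unname(L[1:12, 1]), unname(L[13:24, 2]), tolerance = 1e-8)
  expect_equal(unname(L[13:24, 1]), unname(L[1:12, 2]), tolerance = 1e-8)
})

test_that("forward projection is the linear map W = L S", {
  set.seed(7)
  hm <- fix_head_model()
  ss <- source_space(6, hm, atlas = NULL, seed = 1, cortical_fraction = 0.6)
  el <- electrode_array(4, hm)
  lf <- compute_lead_field(el, ss, hm)
  S <- matrix(rnorm(6 * 10), 6, 10)
  expect_equal(project_sources(lf, S), lf$matrix %*% S, tolerance = 1e-12)
  # zero and unit-vector cases
  expect_equal(project_sources(lf, matrix(0, 6, 5)), matrix(0, 4, 5),
               ignore_attr = TRUE)
  e3 <- matrix(0, 6, 3); e3[3, ] <- 1
  expect_equal(unname(project_sources(lf, e3)),
               matrix(lf$matrix[, 3], 4, 3))
  # linearity over random scalar combinations
  for (rep in 1:5) {
    a <- rnorm(1); b <- rnorm(1)
    S1 <- matrix(rnorm(60), 6); S2 <- matrix(rnorm(60), 6)
    lhs <- project_sources(lf, a * S1 + b * S2)
    rhs <- a * project_sources(lf, S1) + b * project_sources(lf, S2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # every projected sample is average-referenced across electrodes
  W <- project_sources(lf, S)
  expect_lt(max(abs(colSums(W)) / sqrt(colSums(W^2))), 1e-9)
  expect_error(project_sources(lf, matrix(0, 5, 10)), "one row per source")
})
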