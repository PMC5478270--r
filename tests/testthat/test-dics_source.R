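# small shared geometry for forward/inverse tests
sensors_64 <- threatconn:::hemisphere_sensors(64, 0.12)

test_that("spherical leadfield: radial silence, linearity, oracle", {
  pos <- c(0.02, 0.01, 0.04)
  rhat <- pos / sqrt(sum(pos^2))
  q_tan <- c(-rhat[2], rhat[1], 0)
  q_tan <- q_tan / sqrt(sum(q_tan^2))
  l_rad <- sarvas_leadfield(pos, rhat, sensors_64$pos, sensors_64$ori)
  l_tan <- sarvas_leadfield(pos, q_tan, sensors_64$pos, sensors_64$ori)
  expect_lt(sqrt(sum(l_rad^2)) / sqrt(sum(l_tan^2)), 1e-10)
  # moment negation flips the leadfield exactly
  expect_equal(sarvas_leadfield(pos, -q_tan, sensors_64$pos,
                                sensors_64$ori), -l_tan)
  # independent oracle: for a spherical conductor the volume currents
  # are radially silent, so the radial projection equals the primary
  # dipole's magnetostatic (Biot-Savart) field
  bs_radial <- function(q, r0, sp, so) {
    vapply(seq_len(nrow(sp)), function(i) {
      a <- sp[i, ] - r0
      b <- 1e-7 * c(q[2] * a[3] - q[3] * a[2],
                    q[3] * a[1] - q[1] * a[3],
                    q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
      sum(b * so[i, ])
    }, numeric(1))
  }
  set.seed(51)
  for (i in 1:3) {
    p <- runif(3, -0.03, 0.03) + c(0, 0, 0.03)
    q <- rnorm(3)
    got <- sarvas_leadfield(p, q, sensors_64$pos, sensors_64$ori)
    ref <- bs_radial(q, p, sensors_64$pos, sensors_64$ori)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 0.01)
  }
  expect_error(sarvas_leadfield(c(0, 0, 0), q_tan, sensors_64$pos,
                                sensors_64$ori), "centre")
  expect_error(sarvas_leadfield(c(0, 0, 0.1), q_tan, sensors_64$pos,
                                sensors_64$ori), "outside")
})

test_that("compute_csd is Hermitian PSD with expected structure", {
  fs <- 300; n <- 600
  tt <- seq_len(n) / fs
  set.seed(53)
  # identical signal on two sensors: rank-1, off-diagonal = diagonal
  sig <- sin(2 * pi * 10 * tt + runif(1))
  ep <- array(0, c(4, 2, n))
  for (tr in 1:4) { ep[tr, 1, ] <- sig; ep[tr, 2, ] <- sig }
  C <- compute_csd(ep, band = c(9, 11), fs_hz = fs)$csd
  expect_lt(max(abs(C - Conj(t(C)))), 1e-14)
  expect_equal(Re(C[1, 2]), Re(C[1, 1]), tolerance = 1e-10)
  expect_equal(abs(eigen(C)$values[2]), 0, tolerance = 1e-10)
  # independent sensors: off-diagonal shrinks with trials
  ep2 <- array(rnorm(200 * 2 * n), c(200, 2, n))
  C2 <- compute_csd(ep2, band = c(9, 11), fs_hz = fs)$csd
  expect_lt(abs(C2[1, 2]) / sqrt(Re(C2[1, 1]) * Re(C2[2, 2])), 0.1)
  expect_true(all(Re(diag(C2)) >= 0))
  expect_error(compute_csd(ep, band = c(9, 11), fs_hz = fs,
                           trials = integer(0)), "empty")
})

test_that("DICS filters satisfy unit gain and the identity-CSD closed form", {
  model <- build_source_model(0.03, 0.085, sensors_64$pos,
                              sensors_64$ori)
  ns <- ncol(model$leadfield)
  # C = I: w = l' / (l'l)
  csd_i <- structure(list(csd = diag(64) + 0i), class = "csd_matrix")
  f <- dics_filters(csd_i, model, lambda = 0)
  for (s in c(1L, ns %/% 2L, ns)) {
    l <- model$leadfield[, s]
    expect_equal(f$weights[s, ], l / sum(l^2), tolerance = 1e-10)
  }
  # unit gain on a generic CSD
  set.seed(57)
  A <- matrix(rnorm(64 * 80), 64)
  csd <- structure(list(csd = tcrossprod(A) / 80 + 0i),
                   class = "csd_matrix")
  fw <- dics_filters(csd, model)
  gains <- vapply(seq_len(ns), function(s)
    sum(fw$weights[s, ] * model$leadfield[, s]), numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-10)
  # scaling the CSD leaves filters unchanged, scales power linearly
  csd_k <- structure(list(csd = 3.7 * csd$csd), class = "csd_matrix")
  fk <- dics_filters(csd_k, model)
  expect_equal(fk$weights, fw$weights, tolerance = 1e-10)
  expect_equal(project_source_power(fw, csd_k),
               3.7 * project_source_power(fw, csd), tolerance = 1e-10)
})

test_that("forward-then-inverse localizes a single dipole", {
  model <- build_source_model(0.02, 0.085, sensors_64$pos,
                              sensors_64$ori)
  set.seed(59)
  src <- 40L                            # arbitrary grid node
  fs <- 300; n <- 600
  tt <- seq_len(n) / fs
  l <- model$leadfield[, src]
  l <- l / sqrt(mean(l^2))
  ep <- array(0, c(100, 64, n))
  for (tr in 1:100) {
    ep[tr, , ] <- outer(l, 5 * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))) +
      matrix(rnorm(64 * n), 64, n)
  }
  csd <- compute_csd(ep, band = c(9, 11), fs_hz = fs)
  filt <- dics_filters(csd, model)
  pow <- project_source_power(filt, csd)
  expect_true(all(pow >= -1e-12))
  peak <- which.max(pow)
  dist_pk <- sqrt(sum((model$pos[peak, ] - model$pos[src, ])^2))
  expect_lte(dist_pk, model$spacing + 1e-9)
  # identical condition CSDs give identical power maps
  expect_equal(project_source_power(filt, csd),
               project_source_power(filt, csd))
  expect_error(project_source_power(filt, structure(
    list(csd = diag(10) + 0i), class = "csd_matrix")), "mismatch")
})

test_that("common filter differs from per-condition filters", {
  cfg <- tiny_meg_cfg(seed = 61, trials_per_condition = 20L)
  coh <- make_meg_cohort(cfg)
  p <- preprocess_epochs(coh$subjects[[1]])
  band <- c(coh$ground_truth$iaf_hz[1] - 1,
            coh$ground_truth$iaf_hz[1] + 1)
  csd_all <- compute_csd(p, band)
  csd_thr <- compute_csd(p, band,
                         trials = which(p$condition == "threat"))
  f_common <- dics_filters(csd_all, coh$source_model)
  f_thr <- dics_filters(csd_thr, coh$source_model)
  # condition power through the common filter is not the same as
  # through a condition-specific filter (the analysis mandates the
  # common filter precisely because these differ)
  p_common <- project_source_power(f_common, csd_thr)
  p_own <- project_source_power(f_thr, csd_thr)
  expect_gt(max(abs(p_common - p_own) / (p_own + 1e-30)), 1e-3)
})
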