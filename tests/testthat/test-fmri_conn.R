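test_that("censor_frames applies the 0.5 mm enorm rule", {
  # construct motion whose first-difference enorms are known
  mo <- matrix(0, 3, 6)
  mo[2, 1] <- 0.6                        # enorm 0.6 at frame 2
  mo[3, 1] <- 0.6 - 0.2                  # enorm 0.2 at frame 3
  cf <- censor_frames(mo)
  expect_identical(cf$censor, c(FALSE, TRUE, FALSE))
  expect_equal(cf$enorm, c(0, 0.6, 0.2))
  expect_identical(censor_frames(matrix(0, 5, 6))$censor, rep(FALSE, 5))
  # threshold 0 flags every frame with any motion
  expect_identical(censor_frames(mo, threshold = 0)$censor,
                   c(FALSE, TRUE, TRUE))
  # differencing restarts at run boundaries
  mo2 <- rbind(mo, mo)
  cf2 <- censor_frames(mo2, run = rep(1:2, each = 3))
  expect_identical(cf2$censor[4], FALSE)
  expect_error(censor_frames(matrix(0, 3, 5)), "6 columns")
})

test_that("shock_censor flags the shock TR plus the next 9", {
  n <- 200
  labels <- rep(c("safe", "threat"), each = 100)
  sc <- shock_censor(rep(FALSE, n), 100L, labels)
  expect_identical(which(sc$censor), 100:109)
  # shock near the end of a run is clipped at the run boundary
  run <- rep(1:2, each = 100)
  sc2 <- shock_censor(rep(FALSE, n), 98L, labels, run)
  expect_identical(which(sc2$censor), 98:100)
  sc3 <- shock_censor(rep(FALSE, n), integer(0), labels)
  expect_identical(sum(sc3$censor), 0L)
  expect_error(shock_censor(rep(FALSE, 10), 11L, labels[1:10]),
               "bounds")
})

test_that("matched_motion_censor greedily matches enorm", {
  enorm <- c(0.2, 0.4, 0.19, 0.41, 0.9)
  picked <- matched_motion_censor(c(1, 2), c(3, 4, 5), enorm)
  expect_setequal(picked, c(3, 4))
  # identical pools give exact matches
  en2 <- c(1, 2, 3, 1, 2, 3)
  p2 <- matched_motion_censor(1:3, 4:6, en2)
  expect_equal(sort(en2[p2]), en2[1:3])
  expect_error(matched_motion_censor(1:3, 4:5, en2[1:5]), "available")
  # matching beats random selection on mean |enorm difference|
  set.seed(8)
  en3 <- c(runif(20, 0, 1), runif(60, 0, 2))
  thr <- 1:20; pool <- 21:80
  p3 <- matched_motion_censor(thr, pool, en3)
  d_match <- mean(abs(sort(en3[p3]) - sort(en3[thr])))
  d_rand <- replicate(100, {
    r <- sample(pool, 20)
    mean(abs(sort(en3[r]) - sort(en3[thr])))
  })
  expect_true(all(d_match <= d_rand + 1e-12))
})

test_that("nuisance_regress removes spanned signals only", {
  n <- 120
  run <- rep(1:2, each = 60)
  tt1 <- seq(-1, 1, length.out = 60)
  cubic <- c(tt1^3, numeric(60))
  motion <- matrix(rnorm(n * 6, sd = 0.1), n, 6)
  X <- rbind(5 * cubic,                      # pure drift voxel
             motion[, 3],                    # motion copy voxel
             rnorm(n))                       # white noise voxel
  nr <- nuisance_regress(X, motion = motion, run = run,
                         frame_times = rep(seq(0, 118, 2), 2))
  expect_lt(max(abs(nr$residuals[1, ])), 1e-8)
  expect_lt(max(abs(nr$residuals[2, ])), 1e-8)
  expect_lte(var(nr$residuals[3, ]), var(X[3, ]))
  # rank deficiency is reported with the offending columns
  bad <- cbind(motion, motion[, 1])
  expect_error(nuisance_regress(X, motion = bad, run = run,
                                frame_times = rep(seq(0, 118, 2), 2)),
               "rank deficient")
})

test_that("smooth_within_mask preserves constants and normalizes kernels", {
  mask <- ellipsoid_mask(c(7, 7, 7), c(3, 3, 3))
  nv <- sum(mask)
  expect_equal(smooth_within_mask(rep(3.3, nv), mask, 6, 3),
               rep(3.3, nv), tolerance = 1e-12)
  # impulse response is the operator column (discrete kernel oracle:
  # per-row Gaussian weights, row-normalized over in-mask voxels)
  S <- smoothing_operator(mask, 6, 3)
  expect_equal(unname(rowSums(S)), rep(1, nv), tolerance = 1e-12)
  imp <- numeric(nv); imp[10] <- 1
  sm <- smooth_within_mask(imp, mask, 6, 3)
  expect_equal(sm, S[, 10], tolerance = 1e-12, ignore_attr = TRUE)
  co <- threatconn:::mask_coords(mask, 3)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  K <- exp(-as.matrix(dist(co))^2 / (2 * sigma^2))
  K[as.matrix(dist(co)) > 4 * sigma] <- 0
  oracle <- (K / rowSums(K))[, 10]
  expect_equal(sm, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # an impulse keeps all of its mass in-mask (none is lost outside);
  # row normalization trades exact mass conservation for exact
  # constant preservation, so the in-mask sum sits near 1
  ctr_vox <- which.min(rowSums((co - rep(colMeans(co),
                                         each = nv))^2))
  imp_c <- numeric(nv); imp_c[ctr_vox] <- 1
  resp <- smooth_within_mask(imp_c, mask, 6, 3)
  expect_true(all(resp >= 0))
  expect_identical(which.max(resp), ctr_vox)
  expect_gt(sum(resp), 0.9); expect_lt(sum(resp), 1.2)
  # fwhm below voxel size warns and approaches identity
  expect_warning(S0 <- smoothing_operator(mask, 0.5, 3), "FWHM")
  expect_equal(unname(diag(S0)), rep(1, nv), tolerance = 1e-3)
})

test_that("gbc_map equals the brute-force oracle and handles edge cases", {
  set.seed(13)
  for (i in 1:3) {
    X <- matrix(rnorm(5 * 40), 5, 40)
    g <- gbc_map(X, rep("safe", 40), "safe")
    expect_equal(g, gbc_oracle(X), tolerance = 1e-12)
  }
  # two orthogonal sinusoids have zero correlation hence zero GBC
  t2 <- seq_len(40)
  X2 <- rbind(sin(2 * pi * t2 / 8), cos(2 * pi * t2 / 8))
  g2 <- gbc_map(X2, rep("safe", 40), "safe")
  expect_equal(g2, c(0, 0), tolerance = 1e-10)
  # affine rescaling of voxel time courses leaves GBC unchanged
  X3 <- matrix(rnorm(6 * 50), 6, 50)
  sc <- diag(runif(6, 0.5, 4))
  expect_equal(gbc_map(X3, rep("safe", 50), "safe"),
               gbc_map(sc %*% X3 + 2, rep("safe", 50), "safe"),
               tolerance = 1e-10)
  # condition label symmetry
  lab <- rep(c("safe", "threat"), 25)
  expect_equal(gbc_map(X3, lab, "safe"),
               gbc_map(X3, ifelse(lab == "safe", "threat", "safe"),
                       "threat"))
  expect_error(gbc_map(rbind(X3, 0), rep("safe", 50), "safe"),
               "constant voxel")
  expect_error(gbc_map(X3, lab, "safe", min_frames = 30), "uncensored")
  # self-correlation inclusion toggle
  g_in <- gbc_map(X3, rep("safe", 50), "safe", exclude_self = FALSE)
  g_ex <- gbc_map(X3, rep("safe", 50), "safe")
  expect_equal(g_in, (g_ex * 5 + atanh(1 - 1e-7)) / 6, tolerance = 1e-10)
})

test_that("whole_brain_gbc is the unweighted mean", {
  expect_equal(whole_brain_gbc(numeric(10)), 0)
  expect_equal(whole_brain_gbc(rep(0.37, 5)), 0.37)
  expect_error(whole_brain_gbc(c(1, Inf)), "finite")
})

test_that("seed_connectivity matches brute force and clips self-correlation", {
  set.seed(14)
  X <- matrix(rnorm(6 * 60), 6, 60)
  lab <- rep("threat", 60)
  r <- seed_connectivity(X, roi = 2L, labels = lab,
                         condition = "threat")
  expect_equal(r$z[2], atanh(1 - 1e-7))
  bf <- vapply(seq_len(6), function(v)
    atanh(min(1 - 1e-7, cor(X[2, ], X[v, ]))), numeric(1))
  expect_equal(r$z, bf, tolerance = 1e-12)
  # multi-voxel ROI vs explicit mean-timecourse oracle
  roi <- c(1L, 4L, 5L)
  r2 <- seed_connectivity(X, roi, lab, "threat")
  seed_tc <- colMeans(X[roi, ])
  bf2 <- vapply(seq_len(6), function(v)
    atanh(pmin(1 - 1e-7, cor(seed_tc, X[v, ]))), numeric(1))
  expect_equal(r2$z, bf2, tolerance = 1e-12)
  expect_error(seed_connectivity(X, integer(0), lab, "threat"), "empty")
})
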