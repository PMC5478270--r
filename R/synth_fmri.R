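#' Configuration for the synthetic fMRI cohort
#'
#' Desk-scale stand-in for a whole-brain grey-matter-masked acquisition:
#' a 12x12x12 voxel grid (3 mm voxels) with an ellipsoidal mask of ~700
#' voxels, four 490 s runs at TR = 2 s (245 volumes each), alternating
#' 2-min safe/threat blocks without startle probes.
#'
#' Connectivity is injected through a shared latent signal: every in-mask
#' voxel loads on a global latent `g(t)` with weight `w0 = sqrt(rho0)`,
#' giving a baseline pairwise correlation `rho0`.  During threat frames
#' the loading of the designated hub voxels is raised to
#' `w_h = w0 + delta_rho / w0`, which raises each hub voxel's correlation
#' with every other voxel by exactly `delta_rho` (closed form for the
#' equicorrelated block), the analytic ground truth used by the recovery
#' tests.  The residual component is an AR(1)-in-time noise field whose
#' spatial correlation is shaped by the in-mask Gaussian smoothing
#' operator at `fwhm_mm`.
#'
#' @param n_subjects cohort size, default 12.
#' @param grid_shape voxels per axis, default `c(12, 12, 12)`.
#' @param voxel_mm isotropic voxel size, default 3 mm.
#' @param mask_semi_axes ellipsoid semi-axes in voxels, default 5.5.
#' @param tr_s,run_length_s,n_runs acquisition timing (2 s, 490 s, 4).
#' @param block_s block length in seconds, default 120.
#' @param n_hubs number of hub voxels (contiguous blob), default 20.
#' @param delta_rho injected hub correlation increase under threat,
#'   default 0.15; must satisfy `delta_rho < w0 * (1 - w0)` or the
#'   implied hub weight exceeds 1.
#' @param rho0 baseline pairwise correlation, default 0.25.
#' @param ar1_phi temporal AR(1) coefficient of the noise, default 0.3.
#' @param fwhm_mm spatial smoothness of the noise field, default 6 mm.
#' @param motion_sigma per-frame random-walk motion scale (mm), default
#'   0.05; `spike_rate` of frames get an extra `spike_mm` jump so the
#'   censoring rule has work to do.
#' @param shock_amp amplitude of the gamma-variate shock response added
#'   to every voxel (removed downstream by nuisance regression).
#' @param drift_amp amplitude of random per-run polynomial drift.
#' @param rating_effect threat-minus-safe shift of the per-TR anxiety
#'   rating (0-255 hue scale), default 100.
#' @param seed master RNG seed.
#' @return a validated `fmri_sim_config` list.
#' @export
fmri_sim_config <- function(n_subjects = 12L, grid_shape = c(12L, 12L, 12L),
                            voxel_mm = 3, mask_semi_axes = c(5.5, 5.5, 5.5),
                            tr_s = 2, run_length_s = 490, n_runs = 4L,
                            block_s = 120,
                            n_hubs = 20L, delta_rho = 0.15, rho0 = 0.25,
                            ar1_phi = 0.3, fwhm_mm = 6,
                            motion_sigma = 0.05, spike_rate = 0.02,
                            spike_mm = 0.8, shock_amp = 0.5,
                            drift_amp = 0.5, rating_effect = 100,
                            seed = 1L) {
  stopifnot_scalar_num(delta_rho, "delta_rho", 0, 1 - 1e-9)
  stopifnot_scalar_num(rho0, "rho0", 1e-6, 1 - 1e-6)
  stopifnot_scalar_num(tr_s, "tr_s", 1e-6)
  stopifnot_scalar_num(ar1_phi, "ar1_phi", -0.999, 0.999)
  w0 <- sqrt(rho0)
  w_h <- w0 + delta_rho / w0
  if (w_h >= 1)
    stop(sprintf(paste0(
      "delta_rho = %g is not attainable at rho0 = %g: implied hub weight ",
      "%.3f >= 1 (needs delta_rho < %.3f)"), delta_rho, rho0, w_h,
      w0 * (1 - w0)))
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 mask_semi_axes = mask_semi_axes, tr_s = tr_s,
                 run_length_s = run_length_s, n_runs = as.integer(n_runs),
                 block_s = block_s,
                 n_hubs = as.integer(n_hubs), delta_rho = delta_rho,
                 rho0 = rho0, w0 = w0, w_h = w_h, ar1_phi = ar1_phi,
                 fwhm_mm = fwhm_mm, motion_sigma = motion_sigma,
                 spike_rate = spike_rate, spike_mm = spike_mm,
                 shock_amp = shock_amp, drift_amp = drift_amp,
                 rating_effect = rating_effect, seed = as.integer(seed)),
            class = "fmri_sim_config")
}

#' Ellipsoidal analysis mask on a voxel grid
#'
#' @param grid_shape voxels per axis.
#' @param semi_axes ellipsoid semi-axes in voxel units.
#' @return logical 3-D array.
#' @export
ellipsoid_mask <- function(grid_shape, semi_axes = grid_shape / 2 - 0.5) {
  ctr <- (grid_shape + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
  d2 <- ((idx[, 1] - ctr[1]) / semi_axes[1])^2 +
        ((idx[, 2] - ctr[2]) / semi_axes[2])^2 +
        ((idx[, 3] - ctr[3]) / semi_axes[3])^2
  array(d2 <= 1, dim = grid_shape)
}

# Millimetre coordinates of in-mask voxels (rows follow which(mask) order).
mask_coords <- function(mask, voxel_mm = 1) {
  dims <- dim(mask)
  idx <- which(mask)
  coord <- cbind((idx - 1L) %% dims[1],
                 ((idx - 1L) %/% dims[1]) %% dims[2],
                 (idx - 1L) %/% (dims[1] * dims[2]))
  coord * voxel_mm
}

# Gamma-variate haemodynamic response, h(t) ~ t^8.6 exp(-t / 0.547),
# peak-normalized (peak at 8.6 * 0.547 = 4.70 s).
gamma_hrf <- function(t, p = 8.6, q = 0.547) {
  h <- ifelse(t <= 0, 0, (t / (p * q))^p * exp(p - t / q))
  h
}

# Convolve event onset times with the gamma HRF on a TR grid.
event_regressor <- function(onsets, frame_times, amp = 1) {
  reg <- numeric(length(frame_times))
  for (on in onsets) {
    reg <- reg + amp * gamma_hrf(frame_times - on)
  }
  reg
}

#' Generate a synthetic fMRI cohort with known injected connectivity
#'
#' See [fmri_sim_config()] for the generative model.  Reproducible from
#' `cfg$seed`; per-subject data carry per-frame condition labels, a
#' 6-parameter motion table, shock/button event tables and per-TR
#' anxiety ratings.
#'
#' @param cfg an `fmri_sim_config`.
#' @return list with `subjects` (list of `subject_timeseries`), `mask`,
#'   and `ground_truth` (hub voxel indices in `which(mask)` order, the
#'   injected `delta_rho`, and the atanh-scale target hub GBC increase).
#' @export
make_fmri_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "fmri_sim_config"))
  mask <- ellipsoid_mask(cfg$grid_shape, cfg$mask_semi_axes)
  n_vox <- sum(mask)
  coords <- mask_coords(mask, cfg$voxel_mm)
  # contiguous hub blob: voxels nearest an off-centre point inside the mask
  ctr <- colMeans(coords)
  hub_ctr <- ctr + cfg$voxel_mm * c(2, 2, 1)
  d2 <- rowSums((coords - rep(hub_ctr, each = n_vox))^2)
  hubs <- order(d2)[seq_len(cfg$n_hubs)]

  S <- smoothing_operator(mask, fwhm_mm = cfg$fwhm_mm,
                          voxel_mm = cfg$voxel_mm)
  row_scale <- 1 / sqrt(rowSums(S^2))

  seeds <- derive_seeds(cfg$seed, cfg$n_subjects)

  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    subjects[[s]] <- with_seed(seeds[s], {
      runs <- lapply(seq_len(cfg$n_runs), function(r)
        build_block_schedule("fmri", run_index = r, tr_s = cfg$tr_s,
                             run_length_s = cfg$run_length_s,
                             block_s = cfg$block_s,
                             seed = sample.int(2^30, 1)))
      n_per_run <- length(runs[[1]]$frame_times)
      n_frames <- n_per_run * cfg$n_runs
      labels <- unlist(lapply(runs, `[[`, "condition_per_frame"))
      run_id <- rep(seq_len(cfg$n_runs), each = n_per_run)
      frame_times <- unlist(lapply(runs, `[[`, "frame_times"))

      # weights: baseline w0 everywhere; hubs raised to w_h in threat frames
      W <- matrix(cfg$w0, n_vox, n_frames)
      W[hubs, labels == "threat"] <- cfg$w_h

      # global latent and spatially smooth AR(1) noise, per run
      g <- numeric(n_frames)
      E <- matrix(0, n_vox, n_frames)
      innov_sd <- sqrt(1 - cfg$ar1_phi^2)
      for (r in seq_len(cfg$n_runs)) {
        cols <- which(run_id == r)
        g[cols] <- as.numeric(stats::filter(
          stats::rnorm(length(cols), sd = innov_sd), cfg$ar1_phi,
          method = "recursive"))
        Wn <- matrix(stats::rnorm(n_vox * length(cols), sd = innov_sd),
                     n_vox, length(cols))
        for (j in seq_along(cols)[-1]) {
          Wn[, j] <- Wn[, j] + cfg$ar1_phi * Wn[, j - 1L]
        }
        E[, cols] <- (S %*% Wn) * row_scale
      }
      X <- W * rep(g, each = n_vox) + sqrt(1 - W^2) * E

      # nuisance structure: polynomial drift, shock responses, button events
      shocks <- data.frame(run = integer(0), time = numeric(0))
      buttons <- data.frame(run = integer(0), time = numeric(0))
      for (r in seq_len(cfg$n_runs)) {
        st <- runs[[r]]$shock_times
        if (length(st))
          shocks <- rbind(shocks, data.frame(run = r, time = st))
        bt <- sort(stats::runif(20, 0, cfg$run_length_s))
        buttons <- rbind(buttons, data.frame(run = r, time = bt))
        cols <- which(run_id == r)
        tt <- seq(-1, 1, length.out = length(cols))
        drift <- cbind(1, tt, tt^2, tt^3) %*% stats::rnorm(4, sd = cfg$drift_amp)
        ev <- event_regressor(st, runs[[r]]$frame_times,
                              amp = cfg$shock_amp) +
              event_regressor(bt, runs[[r]]$frame_times, amp = 0.2)
        X[, cols] <- X[, cols] +
          rep(drift + ev, each = n_vox)
      }

      # 6-parameter motion: random walk + occasional spikes
      incr <- matrix(stats::rnorm(n_frames * 6, sd = cfg$motion_sigma),
                     n_frames, 6)
      spikes <- which(stats::runif(n_frames) < cfg$spike_rate)
      if (length(spikes))
        incr[cbind(spikes, sample.int(6, length(spikes), TRUE))] <-
          cfg$spike_mm * sample(c(-1, 1), length(spikes), TRUE)
      motion <- matrix(0, n_frames, 6)
      for (r in seq_len(cfg$n_runs)) {
        cols <- which(run_id == r)
        motion[cols, ] <- apply(incr[cols, , drop = FALSE], 2L, cumsum)
        motion[cols[1], ] <- 0
      }
      colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

      # per-TR anxiety rating on the 0-255 hue scale
      base <- ifelse(labels == "threat", 60 + cfg$rating_effect, 60)
      rating <- base + stats::rnorm(1, sd = 10) +
        as.numeric(stats::filter(stats::rnorm(n_frames, sd = 3), 0.8,
                                 method = "recursive"))
      rating <- pmin(255, pmax(0, rating))

      structure(list(data = X, mask = mask, voxel_mm = cfg$voxel_mm,
                     labels = labels, run = run_id,
                     frame_times = frame_times, tr_s = cfg$tr_s,
                     motion = motion, shocks = shocks, buttons = buttons,
                     ratings = rating, schedules = runs, subject = s),
                class = "subject_timeseries")
    })
  }
  target_dz <- atanh(cfg$rho0 + cfg$delta_rho) - atanh(cfg$rho0)
  list(subjects = subjects, mask = mask,
       ground_truth = list(hub_voxels = hubs, delta_rho = cfg$delta_rho,
                           rho0 = cfg$rho0, target_hub_dz = target_dz,
                           config = cfg))
}
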