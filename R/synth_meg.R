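#' Configuration for the synthetic MEG cohort
#'
#' Scaled-down stand-in for a whole-head axial-gradiometer recording:
#' 64 radial sensors on an upper hemisphere of radius 12 cm around a
#' 9 cm spherical conductor, sources on a regular 2 cm grid.  Each
#' subject has an individual alpha frequency (IAF) drawn from
#' `iaf_range_hz`; the active source emits an alpha oscillation whose
#' amplitude is scaled by `alpha_mod` on threat trials (so the injected
#' threat/safe power ratio is `alpha_mod^2`).  A fraction
#' `artifact_rate` of trials receives a 110-140 Hz muscle burst.
#' Epochs are the 2 s windows preceding each startle probe, generated
#' directly at 600 Hz.
#'
#' @param n_subjects cohort size, default 12.
#' @param n_sensors radial sensors, default 64.
#' @param sensor_radius_m sensor shell radius, default 0.12.
#' @param conductor_radius_m conducting sphere radius, default 0.09.
#' @param source_spacing_m source grid spacing, default 0.02.
#' @param source_radius_m source grid radius, default 0.085.
#' @param active_pos target location of the active alpha source
#'   (snapped to the nearest grid node); default a left-parietal-like
#'   point.
#' @param iaf_range_hz range of subject IAFs, default `c(8.5, 11.5)`.
#' @param iaf_values optional explicit per-subject IAFs (recycled),
#'   overriding `iaf_range_hz`.
#' @param alpha_mod threat/safe alpha amplitude ratio, default 0.8
#'   (1 = null).
#' @param alpha_amp source alpha amplitude (nAm scale, arbitrary
#'   units), default 40.
#' @param n_background incoherent background sources, default 6.
#' @param background_amp background source amplitude, default 15.
#' @param sensor_noise_sd white sensor noise SD, default 1 (in the
#'   leadfield-scaled signal units).
#' @param epoch_length_s epoch length, default 2 s.
#' @param fs_hz raw sampling rate, default 600 Hz.
#' @param trials_per_condition scalar or `c(safe, threat)` trial
#'   counts, default 64 each (8 probes x 2 blocks x 4 runs).
#' @param artifact_rate fraction of trials with muscle bursts, default
#'   0.05.
#' @param artifact_amp muscle burst amplitude, default 8.
#' @param seed master RNG seed.
#' @return validated `meg_sim_config`.
#' @export
meg_sim_config <- function(n_subjects = 12L, n_sensors = 64L,
                           sensor_radius_m = 0.12,
                           conductor_radius_m = 0.09,
                           source_spacing_m = 0.02,
                           source_radius_m = 0.085,
                           active_pos = c(-0.035, -0.045, 0.055),
                           iaf_range_hz = c(8.5, 11.5), iaf_values = NULL,
                           alpha_mod = 0.8,
                           alpha_amp = 40, n_background = 6L,
                           background_amp = 15, sensor_noise_sd = 1,
                           epoch_length_s = 2, fs_hz = 600,
                           trials_per_condition = 64L,
                           artifact_rate = 0.05, artifact_amp = 8,
                           seed = 1L) {
  stopifnot_scalar_num(alpha_mod, "alpha_mod", 1e-9)
  stopifnot_scalar_num(artifact_rate, "artifact_rate", 0, 1)
  n_samp <- epoch_length_s * fs_hz
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("epoch_length_s * fs_hz must be an integer number of samples")
  if (sensor_radius_m <= conductor_radius_m)
    stop("sensors must lie outside the conducting sphere")
  if (length(trials_per_condition) == 1L)
    trials_per_condition <- rep(trials_per_condition, 2L)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sensors = as.integer(n_sensors),
                 sensor_radius_m = sensor_radius_m,
                 conductor_radius_m = conductor_radius_m,
                 source_spacing_m = source_spacing_m,
                 source_radius_m = source_radius_m,
                 active_pos = active_pos, iaf_range_hz = iaf_range_hz,
                 iaf_values = iaf_values,
                 alpha_mod = alpha_mod, alpha_amp = alpha_amp,
                 n_background = as.integer(n_background),
                 background_amp = background_amp,
                 sensor_noise_sd = sensor_noise_sd,
                 epoch_length_s = epoch_length_s, fs_hz = fs_hz,
                 n_samples = as.integer(round(n_samp)),
                 trials_per_condition = as.integer(trials_per_condition),
                 artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp, seed = as.integer(seed)),
            class = "meg_sim_config")
}

# Deterministic quasi-uniform sensor layout on the upper hemisphere
# (Fibonacci lattice), radial orientations.
hemisphere_sensors <- function(n, radius) {
  i <- seq_len(n)
  z <- (i - 0.5) / n * 0.85 + 0.1        # polar range away from rim/pole
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  pos <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z) *
    radius
  list(pos = pos, ori = pos / radius)
}

# Pink-ish band-limited noise: white noise shaped ~ 1/sqrt(f) up to
# fmax; one row per realization.
pink_noise_mat <- function(rows, n, fs, fmax = 45) {
  x <- matrix(stats::rnorm(rows * n), rows, n)
  fft_filter(x, fs, function(f)
    ifelse(f < 0.5, 0, 1 / sqrt(pmax(f, 1))) * cos_taper(f, fmax - 5, fmax))
}

#' Generate a synthetic MEG cohort with a known alpha modulation
#'
#' See [meg_sim_config()].  Sensor signals are the leadfield projection
#' of an amplitude-modulated alpha oscillator at the subject's IAF
#' (random phase per trial) plus incoherent background sources and
#' white sensor noise; `artifact_rate` of trials carry muscle bursts.
#'
#' @param cfg a `meg_sim_config`.
#' @return list with `subjects` (list of `sensor_epochs`),
#'   `source_model`, and `ground_truth` (per-subject IAF, active source
#'   index, `alpha_mod`, per-subject artifact-trial flags).
#' @export
make_meg_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "meg_sim_config"))
  geom <- meg_geometry(cfg)
  seeds <- derive_seeds(cfg$seed, cfg$n_subjects)
  subjects <- vector("list", cfg$n_subjects)
  iafs <- numeric(cfg$n_subjects)
  artifacts <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    res <- meg_subject_sim(cfg, geom, seeds[s], s)
    subjects[[s]] <- res$ep
    iafs[s] <- res$iaf
    artifacts[[s]] <- res$art
  }
  list(subjects = subjects, source_model = geom$model,
       ground_truth = list(iaf_hz = iafs, active_source = geom$active,
                           alpha_mod = cfg$alpha_mod,
                           artifact_trials = artifacts, config = cfg))
}

# Shared geometry: sensor layout, source model, active source node.
# Deterministic in the config, so cached for repeated simulation runs.
.geom_cache <- new.env(parent = emptyenv())
meg_geometry <- function(cfg) {
  key <- paste(cfg$n_sensors, cfg$sensor_radius_m, cfg$conductor_radius_m,
               cfg$source_spacing_m, cfg$source_radius_m,
               paste(cfg$active_pos, collapse = ","), sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  sens <- hemisphere_sensors(cfg$n_sensors, cfg$sensor_radius_m)
  model <- build_source_model(cfg$source_spacing_m, cfg$source_radius_m,
                              sens$pos, sens$ori,
                              conductor_radius = cfg$conductor_radius_m)
  active <- which.min(rowSums(sweep(model$pos, 2L, cfg$active_pos)^2))
  .geom_cache[[key]] <- list(sens = sens, model = model, active = active)
  .geom_cache[[key]]
}

# One subject's epochs; separated out so pipelines can generate
# subjects lazily instead of holding a whole raw cohort in memory.
meg_subject_sim <- function(cfg, geom, seed, subject_id) {
  n <- cfg$n_samples
  tt <- seq_len(n) / cfg$fs_hz
  model <- geom$model
  with_seed(seed, {
    iaf <- stats::runif(1, cfg$iaf_range_hz[1], cfg$iaf_range_hz[2])
    if (!is.null(cfg$iaf_values))
      iaf <- cfg$iaf_values[(subject_id - 1L) %%
                              length(cfg$iaf_values) + 1L]
    n_trials <- sum(cfg$trials_per_condition)
    condition <- sample(rep(c("safe", "threat"),
                            cfg$trials_per_condition))
    bg_idx <- sample(ncol(model$leadfield), cfg$n_background)
    art <- stats::runif(n_trials) < cfg$artifact_rate
    l_active <- model$leadfield[, geom$active]
    # normalize leadfield columns so amplitudes are in sensor units
    l_active <- l_active / sqrt(mean(l_active^2))
    Lbg <- model$leadfield[, bg_idx, drop = FALSE]
    Lbg <- sweep(Lbg, 2L, sqrt(colMeans(Lbg^2)), "/")
    amp <- cfg$alpha_amp *
      ifelse(condition == "threat", cfg$alpha_mod, 1) *
      stats::runif(n_trials, 0.8, 1.2)
    phase <- stats::runif(n_trials, 0, 2 * pi)
    # time x trial alpha signal, flattened time-fast to match the
    # sensors x (time, trial) layout below
    src_mat <- sin(outer(2 * pi * iaf * tt, rep(1, n_trials)) +
                     outer(rep(1, n), phase)) * rep(amp, each = n)
    # stack active + background source signals and project in one
    # matmul: sensors x (time * trial)
    SRC <- matrix(0, 1L + cfg$n_background, n * n_trials)
    SRC[1L, ] <- as.numeric(src_mat)
    for (b in seq_len(cfg$n_background)) {
      SRC[1L + b, ] <- cfg$background_amp *
        as.numeric(t(pink_noise_mat(n_trials, n, cfg$fs_hz)))
    }
    flat <- cbind(l_active, Lbg) %*% SRC
    flat <- flat + stats::rnorm(length(flat), sd = cfg$sensor_noise_sd)
    # flat is sensors x (time fast, trial slow)
    epochs <- aperm(array(flat, dim = c(cfg$n_sensors, n, n_trials)),
                    c(3L, 1L, 2L))
    burst_len <- round(0.3 * cfg$fs_hz)
    win <- 0.5 * (1 - cos(2 * pi * seq_len(burst_len) / burst_len))
    for (tr in which(art)) {
      at <- sample(n - burst_len, 1)
      span <- at:(at + burst_len - 1L)
      chan <- order(stats::runif(cfg$n_sensors))[1:8]
      burst <- fft_filter(matrix(stats::rnorm(8 * burst_len), 8),
                          cfg$fs_hz, bandpass_gain(110, 140, 6))
      epochs[tr, chan, span] <- epochs[tr, chan, span] +
        cfg$artifact_amp * burst * rep(win, each = 8)
    }
    list(ep = structure(list(epochs = epochs, fs_hz = cfg$fs_hz,
                             condition = condition,
                             reject = rep(FALSE, n_trials),
                             sensor_pos = geom$sens$pos,
                             sensor_ori = geom$sens$ori,
                             subject = subject_id),
                        class = "sensor_epochs"),
         iaf = iaf, art = art)
  })
}
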