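#' Configuration for the synthetic startle-EMG session
#'
#' Each startle probe elicits an eyeblink burst: a high-frequency
#' carrier under a Gaussian envelope peaking at a random latency inside
#' `blink_latency_ms` after probe onset.  Threat-probe bursts are
#' scaled by `threat_multiplier` (>= 1 injects positive
#' anxiety-potentiated startle).  Per-probe anxiety ratings are the
#' condition mean plus a subject offset and noise on the 0-255 hue
#' scale, shifted by `rating_effect` under threat.
#'
#' @param fs_hz sampling rate, default 600.
#' @param blink_latency_ms latency range of the envelope peak, must lie
#'   within the 20-100 ms scoring window; default `c(40, 80)`.
#' @param blink_amp_scale baseline blink amplitude (microvolts),
#'   default 50.
#' @param threat_multiplier threat/safe blink amplitude ratio,
#'   default 2.
#' @param amp_jitter_sd lognormal SD of per-probe blink amplitude
#'   jitter, default 0.6 (startle magnitudes are highly variable trial
#'   to trial).
#' @param noise_sigma baseline EMG noise SD (microvolts), default 0.5.
#' @param rating_effect threat-minus-safe rating shift, default 100.
#' @param rating_sigma rating noise SD, default 25.
#' @param subject_sd SD of the subject-level anxiety factor that scales
#'   both the startle potentiation and the rating shift (default 0.3);
#'   the shared factor is what makes anxiety-potentiated startle and
#'   rating differences correlate across subjects.
#' @param seed RNG seed.
#' @return validated `emg_sim_config`.
#' @export
emg_sim_config <- function(fs_hz = 600, blink_latency_ms = c(40, 80),
                           blink_amp_scale = 50, threat_multiplier = 2,
                           amp_jitter_sd = 0.6, noise_sigma = 0.5,
                           rating_effect = 100, rating_sigma = 25,
                           subject_sd = 0.3, seed = 1L) {
  if (blink_latency_ms[1] < 20 || blink_latency_ms[2] > 100)
    stop("blink_latency_ms must lie within the [20, 100] ms scoring window")
  stopifnot_scalar_num(threat_multiplier, "threat_multiplier", 0)
  structure(list(fs_hz = fs_hz, blink_latency_ms = blink_latency_ms,
                 blink_amp_scale = blink_amp_scale,
                 threat_multiplier = threat_multiplier,
                 amp_jitter_sd = amp_jitter_sd,
                 noise_sigma = noise_sigma, rating_effect = rating_effect,
                 rating_sigma = rating_sigma, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "emg_sim_config")
}

#' Generate one startle-EMG session with ratings
#'
#' Builds a continuous EMG trace covering the supplied probe schedule(s)
#' with a blink burst per probe and baseline noise, plus a per-probe
#' rating table sampled just prior to each probe.
#'
#' @param cfg an `emg_sim_config`.
#' @param schedule a `block_schedule` with probes (MEG mode), or a list
#'   of them (runs are concatenated with a 2 s gap).
#' @return list with `trace` (an [emg_trace()]), `ratings` (data.frame:
#'   probe, condition, habituation, rating), and `ground_truth`
#'   (per-probe true peak amplitude and latency, the multiplier and
#'   rating effect).
#' @export
make_emg_session <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "emg_sim_config"))
  runs <- if (inherits(schedule, "block_schedule")) list(schedule)
          else schedule
  if (!length(runs) || !all(vapply(runs, function(r)
    length(r$probe_times) > 0, logical(1))))
    stop("schedule must contain startle probes (MEG mode)")
  fs <- cfg$fs_hz
  gap <- 2
  with_seed(cfg$seed, {
    probe_t <- numeric(0); cond <- character(0); habit <- logical(0)
    offset <- 0
    for (r in runs) {
      probe_t <- c(probe_t, offset + r$probe_times)
      cond <- c(cond, r$probe_condition)
      habit <- c(habit, r$habituation)
      offset <- offset + r$run_length_s + gap
    }
    n <- ceiling((offset + 1) * fs)
    sig <- stats::rnorm(n, sd = cfg$noise_sigma)
    n_probes <- length(probe_t)
    # shared subject-level anxiety factor scales both effects
    anx <- max(0, stats::rnorm(1, 1, cfg$subject_sd))
    mult_s <- 1 + (cfg$threat_multiplier - 1) * anx
    reff_s <- cfg$rating_effect * anx
    lat <- stats::runif(n_probes, cfg$blink_latency_ms[1],
                        cfg$blink_latency_ms[2]) / 1000
    amp <- cfg$blink_amp_scale *
      exp(stats::rnorm(n_probes, sd = cfg$amp_jitter_sd)) *
      ifelse(cond == "threat", mult_s, 1)
    env_sd <- 0.010                      # 10 ms envelope width
    half <- ceiling(4 * env_sd * fs)
    for (p in seq_len(n_probes)) {
      ctr_i <- round((probe_t[p] + lat[p]) * fs)
      span <- max(1L, ctr_i - half):min(n, ctr_i + half)
      tloc <- (span - ctr_i) / fs
      carrier <- sin(2 * pi * 80 * tloc + stats::runif(1, 0, 2 * pi))
      sig[span] <- sig[span] +
        amp[p] * exp(-tloc^2 / (2 * env_sd^2)) * carrier
    }
    subj_off <- stats::rnorm(1, sd = 10)
    rating <- 60 + subj_off +
      ifelse(cond == "threat", reff_s, 0) +
      stats::rnorm(n_probes, sd = cfg$rating_sigma)
    rating <- pmin(255, pmax(0, rating))
    trace <- emg_trace(sig, fs, round(probe_t * fs), cond, habit)
    list(trace = trace,
         ratings = data.frame(probe = seq_len(n_probes), condition = cond,
                              habituation = habit, rating = rating),
         ground_truth = list(amplitude = amp, latency_s = lat,
                             threat_multiplier = cfg$threat_multiplier,
                             subject_multiplier = mult_s,
                             subject_rating_effect = reff_s,
                             rating_effect = cfg$rating_effect))
  })
}
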