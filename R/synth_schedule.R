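#' Build a safe/threat block schedule for one run
#'
#' Reproduces the experimental design structure: each run contains two
#' blocks each of safety and threat in alternating order.  In `"meg"`
#' mode the run opens with habituation startle probes, each block
#' contains `probes_per_block` startle probes separated by random
#' inter-probe intervals in `ipi_range_s`, and each interprobe interval
#' inside a threat block has probability `shock_prob` (default 1/12) of
#' containing a shock (delivered 2-4 s after the preceding probe), up to
#' `max_shocks` (default 2) per run.  In `"fmri"` mode blocks are fixed
#' 2-min epochs on a TR grid with no startle probes; any leading time
#' not covered by the four blocks is labelled `"pre"`, and between 0 and
#' `max_shocks` (default 3) shocks are placed at random times inside
#' threat blocks (each of the `max_shocks` slots filled with probability
#' `shock_prob`).
#'
#' @param mode `"fmri"` or `"meg"`.
#' @param run_index integer run label carried through to outputs.
#' @param tr_s repetition time in seconds (fMRI mode), default 2.
#' @param run_length_s fMRI run length, default 490 s (245 volumes).
#' @param block_s fMRI block length, default 120 s.
#' @param probes_per_block startle probes per block (MEG), default 8.
#' @param ipi_range_s inter-probe interval range, default `c(6, 14)` s.
#' @param habituation_probes leading habituation probes (MEG), default 4.
#' @param shock_prob per-opportunity shock probability; default 1/12
#'   (MEG interprobe intervals) or 1/2 (fMRI shock slots).
#' @param max_shocks per-run shock ceiling; default 2 (MEG) / 3 (fMRI).
#' @param first_block condition of the first block, default `"safe"`.
#' @param seed optional RNG seed (restores caller RNG state).
#' @return an object of class `block_schedule` with block table, probe
#'   and shock times, per-probe condition and habituation flags, and (in
#'   fMRI mode) per-frame times and condition labels.
#' @export
build_block_schedule <- function(mode = c("fmri", "meg"), run_index = 1L,
                                 tr_s = 2, run_length_s = 490, block_s = 120,
                                 probes_per_block = 8L,
                                 ipi_range_s = c(6, 14),
                                 habituation_probes = 4L,
                                 shock_prob = NULL, max_shocks = NULL,
                                 first_block = c("safe", "threat"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  first_block <- match.arg(first_block)
  conds <- if (first_block == "safe") c("safe", "threat", "safe", "threat")
           else c("threat", "safe", "threat", "safe")
  with_seed(seed, {
    if (mode == "fmri") {
      shock_prob <- shock_prob %||% 0.5
      max_shocks <- max_shocks %||% 3L
      if (run_length_s < 4 * block_s)
        stop(sprintf(
          "run_length_s = %g too short for four %g s blocks (need >= %g s)",
          run_length_s, block_s, 4 * block_s))
      pre_s <- run_length_s - 4 * block_s
      onsets <- pre_s + (0:3) * block_s
      blocks <- data.frame(onset = onsets, offset = onsets + block_s,
                           condition = conds)
      n_frames <- floor(run_length_s / tr_s)
      frame_times <- (seq_len(n_frames) - 1L) * tr_s
      cond_frame <- rep("pre", n_frames)
      for (b in seq_len(4L)) {
        sel <- frame_times >= blocks$onset[b] & frame_times < blocks$offset[b]
        cond_frame[sel] <- blocks$condition[b]
      }
      n_shock <- sum(stats::runif(max_shocks) < shock_prob)
      shock_times <- numeric(0)
      if (n_shock > 0) {
        tb <- blocks[blocks$condition == "threat", ]
        # uniform over the union of threat blocks, away from block edges
        u <- stats::runif(n_shock)
        pick <- sample(nrow(tb), n_shock, replace = TRUE)
        shock_times <- sort(tb$onset[pick] + 5 + u * (block_s - 15))
      }
      out <- list(mode = mode, run_index = as.integer(run_index),
                  tr_s = tr_s, run_length_s = run_length_s,
                  blocks = blocks, frame_times = frame_times,
                  condition_per_frame = cond_frame,
                  probe_times = numeric(0), probe_condition = character(0),
                  habituation = logical(0), shock_times = shock_times)
    } else {
      shock_prob <- shock_prob %||% (1 / 12)
      max_shocks <- max_shocks %||% 2L
      clock <- 0
      probe_times <- numeric(0)
      probe_condition <- character(0)
      habituation <- logical(0)
      shock_times <- numeric(0)
      n_shock <- 0L
      for (i in seq_len(habituation_probes)) {
        clock <- clock + stats::runif(1, ipi_range_s[1], ipi_range_s[2])
        probe_times <- c(probe_times, clock)
        probe_condition <- c(probe_condition, "pre")
        habituation <- c(habituation, TRUE)
      }
      onsets <- offs <- numeric(4)
      for (b in seq_len(4L)) {
        onsets[b] <- clock
        for (p in seq_len(probes_per_block)) {
          ipi <- stats::runif(1, ipi_range_s[1], ipi_range_s[2])
          if (conds[b] == "threat" && n_shock < max_shocks &&
              stats::runif(1) < shock_prob && length(probe_times) > 0) {
            shock_times <- c(shock_times, clock + stats::runif(1, 2, 4))
            n_shock <- n_shock + 1L
          }
          clock <- clock + ipi
          probe_times <- c(probe_times, clock)
          probe_condition <- c(probe_condition, conds[b])
          habituation <- c(habituation, FALSE)
        }
        offs[b] <- clock
      }
      blocks <- data.frame(onset = onsets, offset = offs, condition = conds)
      out <- list(mode = mode, run_index = as.integer(run_index),
                  tr_s = NA_real_, run_length_s = clock,
                  blocks = blocks, frame_times = numeric(0),
                  condition_per_frame = character(0),
                  probe_times = probe_times,
                  probe_condition = probe_condition,
                  habituation = habituation, shock_times = shock_times)
    }
    structure(out, class = "block_schedule")
  })
}
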