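# Shared tiny fixtures for the unit tests.  All cohorts are generated
# in code at desk scale; nothing is read from disk.

tiny_fmri_cfg <- function(seed = 1L, n_subjects = 3L, ...) {
  fmri_sim_config(n_subjects = n_subjects, grid_shape = c(8L, 8L, 8L),
                  mask_semi_axes = c(3.5, 3.5, 3.5), run_length_s = 250,
                  block_s = 60, n_runs = 2L, n_hubs = 6L, seed = seed,
                  ...)
}

tiny_meg_cfg <- function(seed = 1L, trials_per_condition = 12L, ...) {
  meg_sim_config(n_subjects = 2L, n_sensors = 24L,
                 trials_per_condition = trials_per_condition,
                 seed = seed, ...)
}

# probe schedule with habituation for EMG tests
tiny_schedule <- function(seed = 1L) {
  build_block_schedule("meg", seed = seed)
}

# brute-force Pearson + atanh GBC oracle
gbc_oracle <- function(X) {
  nv <- nrow(X)
  vapply(seq_len(nv), function(v)
    mean(vapply(setdiff(seq_len(nv), v), function(u)
      atanh(stats::cor(X[v, ], X[u, ])), numeric(1))), numeric(1))
}
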