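# Deposited source data (not shipped)

`behavioral_stats_from_source_data()` looks here for four CSV files
exported from the per-figure source-data spreadsheets deposited with
the original publication (download required; they are not
redistributable with this package):

- `meg_ratings.csv`  — anxiety ratings, MEG session
- `meg_startle.csv`  — startle magnitudes, MEG session
- `fmri_ratings.csv` — anxiety ratings, fMRI session
- `fmri_gbc.csv`     — whole-brain GBC means, fMRI session

Each file needs one row per subject with numeric `safe` and `threat`
columns of within-subject T-scores (or GBC means for `fmri_gbc.csv`).
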