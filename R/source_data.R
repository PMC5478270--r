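#' Behavioural statistics from deposited per-figure source data
#'
#' Recomputes the headline behavioural tests from the per-figure
#' source-data spreadsheets deposited alongside the original study
#' (exported to CSV).  Expected files under `dir`, one row per subject
#' with `safe` and `threat` columns of within-subject T-scores:
#' \describe{
#'   \item{`meg_ratings.csv`}{anxiety ratings, MEG session (n = 28)}
#'   \item{`meg_startle.csv`}{startle magnitudes, MEG session (n = 28)}
#'   \item{`fmri_ratings.csv`}{anxiety ratings, fMRI session (n = 25)}
#'   \item{`fmri_gbc.csv`}{whole-brain GBC means (n = 25)}
#' }
#' The source-data spreadsheets are distributed with the published
#' article and must be downloaded separately; they are not shipped with
#' this package.
#'
#' @param dir directory containing the four CSV files.
#' @return list of four paired-t results (statistic, df, p.value), one
#'   per file, named `meg_ratings`, `meg_startle`, `fmri_ratings`,
#'   `fmri_gbc`.
#' @export
behavioral_stats_from_source_data <- function(dir) {
  files <- c(meg_ratings = "meg_ratings.csv",
             meg_startle = "meg_startle.csv",
             fmri_ratings = "fmri_ratings.csv",
             fmri_gbc = "fmri_gbc.csv")
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing))
    stop("deposited source-data files not found under '", dir, "': ",
         paste(missing, collapse = ", "),
         " (download the per-figure source data from the published ",
         "article and export the safe/threat columns to CSV)")
  lapply(files, function(f) {
    d <- utils::read.csv(file.path(dir, f))
    if (!all(c("safe", "threat") %in% names(d)))
      stop(f, " must have 'safe' and 'threat' columns")
    paired_t(d$safe, d$threat)
  })
}
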