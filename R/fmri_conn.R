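#' Motion censoring ("scrubbing")
#'
#' Flags every frame whose motion derivative has Euclidean norm above
#' `threshold` (0.5 mm default): frame t is censored iff
#' `sqrt(sum_i(delta param_i(t))^2) > threshold`, where delta is the
#' first difference of the six realignment parameters within run (the
#' first frame of each run has delta = 0).
#'
#' @param motion numeric matrix, frames x 6 motion parameters (mm).
#' @param threshold censoring threshold in mm, default 0.5.
#' @param run optional integer run id per frame; differencing restarts
#'   at run boundaries.
#' @return list with logical `censor` flags and the per-frame `enorm`.
#' @export
censor_frames <- function(motion, threshold = 0.5, run = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns")
  if (anyNA(motion)) stop("missing frames in motion table")
  n <- nrow(motion)
  run <- run %||% rep(1L, n)
  d <- rbind(0, diff(motion))
  d[c(TRUE, diff(run) != 0), ] <- 0
  enorm <- sqrt(rowSums(d^2))
  list(censor = enorm > threshold, enorm = enorm)
}

#' Censor frames following shock delivery
#'
#' Extends an existing censor vector by flagging each shock frame and
#' the following `k - 1` frames (10 TRs total by default), clipped at
#' the end of the shock's run.
#'
#' @param censor logical censor flags per frame.
#' @param shock_frames integer frame indices (1-based) of shock onsets.
#' @param labels condition label per frame (for the per-condition counts).
#' @param run integer run id per frame.
#' @param k number of TRs censored per shock, default 10.
#' @return list with extended `censor` flags and `n_censored_by_condition`
#'   (newly censored frames, tabulated by condition label).
#' @export
shock_censor <- function(censor, shock_frames, labels, run = NULL, k = 10L) {
  n <- length(censor)
  run <- run %||% rep(1L, n)
  if (length(shock_frames) && (min(shock_frames) < 1 || max(shock_frames) > n))
    stop("shock frames outside run bounds")
  new <- logical(n)
  for (f in shock_frames) {
    span <- f:min(n, f + k - 1L)
    span <- span[run[span] == run[f]]
    new[span] <- TRUE
  }
  added <- new & !censor
  list(censor = censor | new,
       n_censored_by_condition = table(factor(labels[added],
                                              levels = unique(labels))))
}

#' Motion-matched censoring of safe frames
#'
#' For every censored threat frame, selects one safe frame whose motion
#' (enorm) is closest, without replacement, so the two conditions lose
#' equally many frames with closely matched motion.  Threat frames are
#' matched in decreasing order of enorm (greedy rank matching).
#'
#' @param threat_frames indices of censored threat frames.
#' @param safe_frames indices of candidate safe frames.
#' @param enorm per-frame motion Euclidean norm (full-length vector).
#' @return integer vector of safe frame indices to censor, same length
#'   as `threat_frames`.
#' @export
matched_motion_censor <- function(threat_frames, safe_frames, enorm) {
  if (length(safe_frames) < length(threat_frames))
    stop(sprintf("only %d safe frames available to match %d threat frames",
                 length(safe_frames), length(threat_frames)))
  pool <- safe_frames
  picked <- integer(0)
  for (f in threat_frames[order(enorm[threat_frames], decreasing = TRUE)]) {
    j <- which.min(abs(enorm[pool] - enorm[f]))
    picked <- c(picked, pool[j])
    pool <- pool[-j]
  }
  picked
}

# Legendre polynomials P0..P3 evaluated on [-1, 1].
legendre_basis <- function(n, order = 3L) {
  x <- seq(-1, 1, length.out = n)
  cbind(P0 = rep(1, n), P1 = x, P2 = (3 * x^2 - 1) / 2,
        P3 = (5 * x^3 - 3 * x) / 2)[, seq_len(order + 1L), drop = FALSE]
}

#' Nuisance regression of voxel time series
#'
#' Ordinary least squares per voxel against per-run Legendre polynomials
#' (orders 0-3, baseline drift), the six motion parameters, and event
#' regressors (shock and button-press onsets convolved with a
#' peak-normalized gamma-variate response).  Betas are estimated on
#' uncensored frames only and residuals returned for all frames.
#'
#' @param ts a `subject_timeseries`, or a voxels x frames matrix.
#' @param censor logical censor flags (default none).
#' @param poly_order polynomial drift order per run, default 3.
#' @param motion,run,frame_times,events used when `ts` is a bare matrix;
#'   `events` is a data.frame with columns `run`, `time`.
#' @return list with `residuals` (voxels x frames) and the `design`
#'   matrix.
#' @export
nuisance_regress <- function(ts, censor = NULL, poly_order = 3L,
                             motion = NULL, run = NULL, frame_times = NULL,
                             events = NULL) {
  if (inherits(ts, "subject_timeseries")) {
    motion <- motion %||% ts$motion
    run <- run %||% ts$run
    frame_times <- frame_times %||% ts$frame_times
    events <- events %||% rbind(ts$shocks, ts$buttons)
    X <- ts$data
  } else X <- as.matrix(ts)
  n <- ncol(X)
  censor <- censor %||% rep(FALSE, n)
  run <- run %||% rep(1L, n)
  runs <- unique(run)

  design <- NULL
  for (r in runs) {
    cols <- run == r
    poly <- matrix(0, n, poly_order + 1L)
    poly[cols, ] <- legendre_basis(sum(cols), poly_order)
    colnames(poly) <- paste0("run", r, "_poly", 0:poly_order)
    design <- cbind(design, poly)
  }
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    colnames(m) <- paste0("motion", seq_len(ncol(m)))
    design <- cbind(design, m)
  }
  if (!is.null(events) && nrow(events) > 0) {
    ev <- numeric(n)
    for (r in runs) {
      cols <- which(run == r)
      on <- events$time[events$run == r]
      if (length(on))
        ev[cols] <- event_regressor(on, frame_times[cols] -
                                      frame_times[cols][1])
    }
    design <- cbind(design, event = ev)
  }

  keep <- !censor
  Xd <- design[keep, , drop = FALSE]
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    drop_cols <- colnames(Xd)[qrd$pivot[(qrd$rank + 1L):ncol(Xd)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- t(qr.coef(qrd, t(X[, keep, drop = FALSE])))
  resid <- X - beta %*% t(design)
  list(residuals = resid, design = design)
}

#' In-mask Gaussian smoothing operator
#'
#' Dense voxels x voxels matrix applying an isotropic Gaussian kernel of
#' the given FWHM, renormalized over in-mask voxels only so there is no
#' bleed across the mask edge and a constant field is preserved exactly.
#'
#' @param mask logical 3-D array.
#' @param fwhm_mm kernel FWHM in mm.
#' @param voxel_mm voxel size in mm.
#' @return matrix with rows summing to 1 over in-mask voxels.
#' @export
smoothing_operator <- function(mask, fwhm_mm = 6, voxel_mm = 3) {
  if (fwhm_mm < voxel_mm)
    warning("FWHM below voxel size; smoothing is near-identity")
  coords <- mask_coords(mask, voxel_mm)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / (2 * sigma^2))
  K[d2 > (4 * sigma)^2] <- 0
  unname(K / rowSums(K))
}

#' Smooth a voxel time-series matrix within the mask
#'
#' @param data in-mask voxels x frames matrix (rows in `which(mask)`
#'   order) or a single vector.
#' @param mask logical 3-D array.
#' @param fwhm_mm,voxel_mm kernel size, defaults 6 mm / 3 mm.
#' @return smoothed data, same shape.
#' @export
smooth_within_mask <- function(data, mask, fwhm_mm = 6, voxel_mm = 3) {
  S <- smoothing_operator(mask, fwhm_mm, voxel_mm)
  if (is.null(dim(data))) drop(S %*% data) else S %*% data
}

# Select analysis frames for one condition and standardize voxel rows.
condition_frames <- function(labels, condition, censor, min_frames = 10L) {
  sel <- which(labels == condition & !censor)
  if (length(sel) < min_frames)
    stop(sprintf("only %d uncensored '%s' frames (need >= %d)",
                 length(sel), condition, min_frames))
  sel
}

#' Global brain connectivity map for one condition
#'
#' For each in-mask voxel, the Pearson correlation with every other
#' in-mask voxel over the condition's uncensored frames is computed,
#' clipped to `|r| <= 1 - 1e-7`, Fisher-Z transformed, and averaged over
#' the other N-1 voxels (self-correlation excluded by default).
#'
#' @param data voxels x frames matrix (or `subject_timeseries`).
#' @param labels condition label per frame (taken from the object if a
#'   `subject_timeseries` is given).
#' @param condition which condition to map (`"safe"` / `"threat"`).
#' @param censor logical censor flags, default none.
#' @param min_frames minimum uncensored frames required, default 10.
#' @param exclude_self drop the self-correlation from the average
#'   (default TRUE); with FALSE the clipped `atanh(1 - 1e-7)` self term
#'   is included in an N-voxel average.
#' @return numeric vector of per-voxel Fisher-Z GBC values.
#' @export
gbc_map <- function(data, labels = NULL, condition = "safe", censor = NULL,
                    min_frames = 10L, exclude_self = TRUE) {
  if (inherits(data, "subject_timeseries")) {
    labels <- labels %||% data$labels
    data <- data$data
  }
  n <- ncol(data)
  censor <- censor %||% rep(FALSE, n)
  sel <- condition_frames(labels, condition, censor, min_frames)
  X <- data[, sel, drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant voxel time course (voxel ",
         paste(which(sds == 0), collapse = ", "),
         "): correlation undefined")
  Xs <- (X - rowMeans(X)) / sds
  R <- tcrossprod(Xs) / (length(sel) - 1L)
  Z <- fisher_z(pmin(pmax(R, -1), 1))
  nv <- nrow(Z)
  if (exclude_self) (rowSums(Z) - diag(Z)) / (nv - 1L) else rowSums(Z) / nv
}

#' Whole-brain GBC
#'
#' Unweighted mean of a GBC map over in-mask voxels.
#'
#' @param map per-voxel Fisher-Z GBC values.
#' @return scalar mean GBC.
#' @export
whole_brain_gbc <- function(map) {
  if (any(!is.finite(map))) stop("GBC map contains non-finite values")
  mean(map)
}

#' Seed-based connectivity map
#'
#' The mean time course over the seed ROI voxels is correlated with
#' every in-mask voxel over the condition's uncensored frames and
#' Fisher-Z transformed.  ROI voxels are retained in the output.
#'
#' @param data voxels x frames matrix (or `subject_timeseries`).
#' @param roi integer indices of seed voxels (rows of `data`).
#' @param labels,condition,censor,min_frames as in [gbc_map()].
#' @return list with `z` (per-voxel Fisher-Z values) and `roi`.
#' @export
seed_connectivity <- function(data, roi, labels = NULL, condition = "safe",
                              censor = NULL, min_frames = 10L) {
  if (inherits(data, "subject_timeseries")) {
    labels <- labels %||% data$labels
    data <- data$data
  }
  if (length(roi) == 0) stop("empty seed ROI")
  censor <- censor %||% rep(FALSE, ncol(data))
  sel <- condition_frames(labels, condition, censor, min_frames)
  X <- data[, sel, drop = FALSE]
  seed <- colMeans(X[roi, , drop = FALSE])
  if (stats::sd(seed) == 0) stop("seed time course is constant")
  seed_s <- (seed - mean(seed)) / stats::sd(seed)
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant voxel time course (voxel ",
         paste(which(sds == 0), collapse = ", "), ")")
  Xs <- (X - rowMeans(X)) / sds
  r <- as.numeric(Xs %*% seed_s) / (length(sel) - 1L)
  list(z = fisher_z(pmin(pmax(r, -1), 1)), roi = roi)
}
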