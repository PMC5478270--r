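# End-to-end pipelines over synthetic cohorts: fMRI GBC chain, MEG
# alpha/DICS chain, startle/rating chain, plus report writing.  Every
# stochastic stage is seeded from the cohort config so a rerun with the
# same (config, seed) reproduces the stats JSON byte for byte.

#' Run the fMRI global-brain-connectivity pipeline
#'
#' Stages: motion censoring, nuisance regression, condition-wise GBC
#' maps, whole-brain GBC paired t, voxelwise paired t with an
#' ACF-matched Monte-Carlo cluster-size threshold, seed connectivity
#' from the significant GBC clusters with the same cluster correction,
#' and a robustness re-test (shock-TR censoring, motion-matched safe
#' censoring, motion ANCOVA at the cluster level).
#'
#' @param cfg an [fmri_sim_config()] (the cohort is generated), or a
#'   cohort list as returned by [make_fmri_cohort()].
#' @param voxel_p voxelwise two-sided alpha, default 0.005.
#' @param n_iter Monte-Carlo iterations for the cluster threshold,
#'   default 500 (desk scale).
#' @param alpha corrected cluster alpha, default 0.05.
#' @param out_dir optional output directory for maps/tables/JSON.
#' @param shock_censor_k TRs censored after each shock, default 10.
#' @return list with per-stage results (see the report for a summary).
#' @export
run_fmri_pipeline <- function(cfg, voxel_p = 0.005, n_iter = 500L,
                              alpha = 0.05, out_dir = NULL,
                              shock_censor_k = 10L) {
  cohort <- if (inherits(cfg, "fmri_sim_config")) make_fmri_cohort(cfg)
            else cfg
  cfg <- cohort$ground_truth$config
  mask <- cohort$mask
  subs <- cohort$subjects
  n_sub <- length(subs)
  n_vox <- nrow(subs[[1]]$data)
  coords <- mask_coords(mask, cfg$voxel_mm)
  coords_lpi <- sweep(coords, 2L, colMeans(coords))
  adjacency <- mask_adjacency(mask)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("fMRI pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  censors <- vector("list", n_sub)
  resids <- vector("list", n_sub)
  gbc_safe <- gbc_threat <- matrix(0, n_sub, n_vox)
  acf_pars <- matrix(0, n_sub, 3)
  for (s in seq_len(n_sub)) {
    ts <- subs[[s]]
    cf <- stage("censor", censor_frames(ts$motion, run = ts$run))
    censors[[s]] <- cf
    nr <- stage("nuisance", nuisance_regress(ts, censor = cf$censor))
    resids[[s]] <- nr$residuals
    gbc_safe[s, ] <- stage("gbc", gbc_map(nr$residuals, ts$labels,
                                          "safe", cf$censor))
    gbc_threat[s, ] <- stage("gbc", gbc_map(nr$residuals, ts$labels,
                                            "threat", cf$censor))
    af <- stage("acf", estimate_acf(nr$residuals, mask, cfg$voxel_mm,
                                    max_pairs = 20000L))
    acf_pars[s, ] <- c(af$a, af$b, af$c)
  }
  acf_mean <- colMeans(acf_pars)
  acf <- structure(list(a = acf_mean[1], b = acf_mean[2], c = acf_mean[3],
                        acf_fun = function(r)
                          acf_mean[1] * exp(-r^2 / (2 * acf_mean[2]^2)) +
                          (1 - acf_mean[1]) * exp(-r / acf_mean[3])),
                   class = "acf_model")

  wb <- stage("whole_brain",
              paired_t(rowMeans(gbc_safe), rowMeans(gbc_threat)))

  diffs <- gbc_threat - gbc_safe
  tmap <- apply(diffs, 2L, function(d) paired_t(d)$statistic)
  thr <- stage("cluster_threshold",
               simulate_cluster_threshold(mask, acf, voxel_p, n_iter,
                                          alpha, cfg$voxel_mm,
                                          seed = cfg$seed + 101L))
  cl <- stage("clusters", extract_clusters(tmap, adjacency,
                                           df = n_sub - 1L,
                                           node_p = voxel_p))
  cl$clusters$significant <-
    cl$clusters$size >= thr$min_cluster_size
  sig <- which(cl$clusters$significant)

  # seed connectivity from significant GBC clusters (largest first)
  seed_res <- NULL
  if (length(sig)) {
    roi <- sort(unique(unlist(cl$members[sig])))
    seed_safe <- seed_threat <- matrix(0, n_sub, n_vox)
    for (s in seq_len(n_sub)) {
      seed_safe[s, ] <- seed_connectivity(resids[[s]], roi,
                                          subs[[s]]$labels, "safe",
                                          censors[[s]]$censor)$z
      seed_threat[s, ] <- seed_connectivity(resids[[s]], roi,
                                            subs[[s]]$labels, "threat",
                                            censors[[s]]$censor)$z
    }
    st <- apply(seed_threat - seed_safe, 2L,
                function(d) paired_t(d)$statistic)
    scl <- extract_clusters(st, adjacency, df = n_sub - 1L,
                            node_p = voxel_p)
    scl$clusters$significant <-
      scl$clusters$size >= thr$min_cluster_size
    seed_res <- list(roi = roi, tmap = st, clusters = scl)
  }

  # robustness: shock censoring + motion-matched safe censoring + ANCOVA
  robust <- NULL
  if (length(sig)) {
    roi <- sort(unique(unlist(cl$members[sig])))
    d_adj <- mot_cov <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      ts <- subs[[s]]
      cf <- censors[[s]]
      shock_fr <- integer(0)
      for (r in unique(ts$run)) {
        st_r <- ts$shocks$time[ts$shocks$run == r]
        if (length(st_r)) {
          base <- which(ts$run == r)[1] - 1L
          shock_fr <- c(shock_fr, base + findInterval(st_r,
            ts$frame_times[ts$run == r]) + 1L)
        }
      }
      shock_fr <- shock_fr[shock_fr <= length(cf$censor)]
      sc <- shock_censor(cf$censor, shock_fr, ts$labels, ts$run,
                         k = shock_censor_k)
      cen <- sc$censor
      new_threat <- which(cen & !cf$censor & ts$labels == "threat")
      safe_pool <- which(ts$labels == "safe" & !cen)
      if (length(new_threat) && length(safe_pool) >= length(new_threat)) {
        cen[matched_motion_censor(new_threat, safe_pool, cf$enorm)] <- TRUE
      }
      zs <- gbc_map(resids[[s]], ts$labels, "safe", cen)
      zt <- gbc_map(resids[[s]], ts$labels, "threat", cen)
      d_adj[s] <- mean(zt[roi]) - mean(zs[roi])
      mot_cov[s] <- mean(cf$enorm[ts$labels == "threat" & !cen]) -
        mean(cf$enorm[ts$labels == "safe" & !cen])
    }
    robust <- list(ancova = ancova_on_differences(d_adj, mot_cov),
                   cluster_diff = d_adj, motion_covariate = mot_cov)
  }

  res <- list(arm = "fmri",
              config = list(seed = cfg$seed, n_subjects = n_sub,
                            delta_rho = cfg$delta_rho,
                            voxel_p = voxel_p, n_iter = n_iter,
                            alpha = alpha),
              whole_brain = list(t = wb$statistic, df = wb$df,
                                 p = wb$p.value),
              gbc = list(safe = gbc_safe, threat = gbc_threat,
                         tmap = tmap),
              acf = list(a = acf$a, b = acf$b, c = acf$c),
              cluster_threshold = thr$min_cluster_size,
              clusters = cl, seed_connectivity = seed_res,
              robustness = robust,
              ground_truth = cohort$ground_truth[c("hub_voxels",
                                                   "delta_rho",
                                                   "target_hub_dz")],
              coords_lpi = coords_lpi,
              sem = list(whole_brain = within_subject_sem(
                cbind(safe = rowMeans(gbc_safe),
                      threat = rowMeans(gbc_threat)))))
  if (!is.null(out_dir)) write_fmri_outputs(res, mask, cfg, out_dir)
  res
}

write_fmri_outputs <- function(res, mask, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tvol <- array(0, dim(mask)); tvol[mask] <- res$gbc$tmap
  write_nifti(tvol, file.path(out_dir, "gbc_paired_t.nii"), cfg$voxel_mm)
  write_nifti(array(as.numeric(mask), dim(mask)),
              file.path(out_dir, "mask.nii"), cfg$voxel_mm)
  write_tsv(cluster_table(res$clusters, res$coords_lpi),
            file.path(out_dir, "gbc_clusters.tsv"))
  if (!is.null(res$seed_connectivity))
    write_tsv(cluster_table(res$seed_connectivity$clusters,
                            res$coords_lpi),
              file.path(out_dir, "seed_clusters.tsv"))
  stats <- res[c("arm", "config", "whole_brain", "acf",
                 "cluster_threshold")]
  stats$n_significant_clusters <- sum(res$clusters$clusters$significant)
  if (!is.null(res$robustness))
    stats$robustness_ancova <- res$robustness$ancova[c("F", "df1", "df2",
                                                       "p.value")]
  jsonlite::write_json(stats, file.path(out_dir, "fmri_stats.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' Run the MEG alpha / DICS pipeline
#'
#' Stages: muscle-artifact rejection on raw epochs, filtering and
#' downsampling, survey multitaper spectra (1-20 Hz, single taper),
#' per-subject IAF with cohort-mean fallback, IAF-band power (two
#' tapers), sensor-level paired differences with a sign-flip
#' permutation cluster-mass test, DICS common-filter source projection
#' with the same test on the source grid, and a trial-count ANCOVA
#' robustness check.
#'
#' @param cfg a [meg_sim_config()] or a cohort from [make_meg_cohort()].
#' @param n_perm permutations, default 1000.
#' @param node_p node-level forming p, default 0.005.
#' @param alpha cluster alpha, default 0.05.
#' @param sensor_radius sensor adjacency radius (m), default 0.04.
#' @param out_dir optional output directory.
#' @param source_analysis run the DICS source stage (default TRUE);
#'   FALSE stops after the sensor-level test (e.g. for sensor-level
#'   calibration studies).
#' @return list with per-stage results.
#' @export
run_meg_pipeline <- function(cfg, n_perm = 1000L, node_p = 0.005,
                             alpha = 0.05, sensor_radius = 0.04,
                             out_dir = NULL, source_analysis = TRUE) {
  lazy <- inherits(cfg, "meg_sim_config")
  if (lazy) {
    geom <- meg_geometry(cfg)
    seeds <- derive_seeds(cfg$seed, cfg$n_subjects)
    model <- geom$model
    n_sub <- cfg$n_subjects
    gt <- list(iaf_hz = numeric(n_sub), active_source = geom$active,
               alpha_mod = cfg$alpha_mod)
    get_subject <- function(s) {
      r <- meg_subject_sim(cfg, geom, seeds[s], s)
      gt$iaf_hz[s] <<- r$iaf
      r$ep
    }
    sensor_pos <- geom$sens$pos
  } else {
    cohort <- cfg
    cfg <- cohort$ground_truth$config
    model <- cohort$source_model
    n_sub <- length(cohort$subjects)
    gt <- cohort$ground_truth[c("iaf_hz", "active_source", "alpha_mod")]
    get_subject <- function(s) cohort$subjects[[s]]
    sensor_pos <- cohort$subjects[[1]]$sensor_pos
  }
  n_sens <- cfg$n_sensors

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("MEG pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  profiles <- vector("list", n_sub)
  pre <- vector("list", n_sub)
  trial_counts <- matrix(0L, n_sub, 2,
                         dimnames = list(NULL, c("safe", "threat")))
  for (s in seq_len(n_sub)) {
    raw <- get_subject(s)
    cond <- stage("preprocess", condition_epochs_fast(raw))
    rej <- cond$reject
    p <- cond$pre
    keep <- !rej
    p$epochs <- p$epochs[keep, , , drop = FALSE]
    p$condition <- p$condition[keep]
    p$reject <- rej
    pre[[s]] <- p
    trial_counts[s, ] <- c(sum(p$condition == "safe"),
                           sum(p$condition == "threat"))
    sp <- stage("spectrum", mtm_spectrum(p, fmin = 1, fmax = 20,
                                         nw = 1, n_tapers = 1L))
    profiles[[s]] <- detect_iaf(sp)
    rm(raw, cond)
  }
  profiles <- stage("iaf", resolve_iaf(profiles))

  sens_safe <- sens_threat <- matrix(0, n_sub, n_sens)
  src_safe <- src_threat <- matrix(0, n_sub, ncol(model$leadfield))
  for (s in seq_len(n_sub)) {
    p <- pre[[s]]
    bp <- stage("band_power", iaf_band_power(p, profiles[[s]]))
    sens_safe[s, ] <- colMeans(bp[p$condition == "safe", , drop = FALSE])
    sens_threat[s, ] <- colMeans(bp[p$condition == "threat", ,
                                    drop = FALSE])
    if (source_analysis) {
      band <- profiles[[s]]$band
      csd_all <- stage("csd", compute_csd(p, band))
      filt <- stage("dics", dics_filters(csd_all, model))
      csd_s <- compute_csd(p, band, trials = which(p$condition == "safe"))
      csd_t <- compute_csd(p, band,
                           trials = which(p$condition == "threat"))
      src_safe[s, ] <- project_source_power(filt, csd_s)
      src_threat[s, ] <- project_source_power(filt, csd_t)
    }
  }

  adj_sens <- stage("adjacency",
                    sensor_adjacency(sensor_pos, sensor_radius))
  sens_test <- stage("sensor_cluster", permutation_cluster_test(
    sens_threat - sens_safe, adj_sens, n_perm = n_perm, node_p = node_p,
    alpha = alpha, seed = cfg$seed + 202L))

  src_test <- NULL
  if (source_analysis) {
    adj_src <- stage("adjacency", sensor_adjacency(
      model$pos, 1.5 * model$spacing))
    src_test <- stage("source_cluster", permutation_cluster_test(
      src_threat - src_safe, adj_src, n_perm = n_perm, node_p = node_p,
      alpha = alpha, seed = cfg$seed + 303L))
  }

  # trial-count ANCOVA on the mean sensor-power difference
  d_sens <- rowMeans(sens_threat - sens_safe)
  tc_diff <- trial_counts[, "threat"] - trial_counts[, "safe"]
  ancova <- if (n_sub >= 3L && stats::sd(tc_diff) > 0)
    ancova_on_differences(d_sens, tc_diff) else NULL

  res <- list(arm = "meg",
              config = list(seed = cfg$seed, n_subjects = n_sub,
                            alpha_mod = cfg$alpha_mod, n_perm = n_perm,
                            node_p = node_p, alpha = alpha),
              iaf = list(
                value = vapply(profiles, `[[`, numeric(1), "iaf_hz"),
                fallback = vapply(profiles, `[[`, logical(1),
                                  "fallback")),
              trial_counts = trial_counts,
              sensor = list(safe = sens_safe, threat = sens_threat,
                            test = sens_test),
              source = list(safe = src_safe, threat = src_threat,
                            test = src_test, pos = model$pos,
                            spacing = model$spacing),
              trial_count_ancova = ancova,
              ground_truth = gt,
              sem = list(sensor = within_subject_sem(
                cbind(safe = rowMeans(sens_safe),
                      threat = rowMeans(sens_threat)))))
  if (!is.null(out_dir)) write_meg_outputs(res, model, out_dir)
  res
}

write_meg_outputs <- function(res, model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cluster_table(res$sensor$test),
            file.path(out_dir, "sensor_clusters.tsv"))
  if (!is.null(res$source$test)) {
    write_tsv(cluster_table(res$source$test, model$pos * 100),
              file.path(out_dir, "source_clusters.tsv"))
    write_tsv(data.frame(x = model$pos[, 1], y = model$pos[, 2],
                         z = model$pos[, 3],
                         power_safe = colMeans(res$source$safe),
                         power_threat = colMeans(res$source$threat)),
              file.path(out_dir, "source_power.tsv"))
  }
  stats <- res[c("arm", "config")]
  stats$iaf <- res$iaf
  stats$n_significant_sensor_clusters <-
    sum(res$sensor$test$clusters$significant)
  stats$n_significant_source_clusters <-
    sum(res$source$test$clusters$significant)
  if (!is.null(res$trial_count_ancova))
    stats$trial_count_ancova <-
      res$trial_count_ancova[c("F", "df1", "df2", "p.value")]
  jsonlite::write_json(stats, file.path(out_dir, "meg_stats.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' Run the startle / rating pipeline
#'
#' Generates (or accepts) one EMG session per subject, scores every
#' non-habituation probe, T-scores startle and ratings within subject,
#' tests the threat-vs-safe difference with paired t-tests, and
#' correlates anxiety-potentiated startle with the rating difference
#' across subjects.
#'
#' @param n_subjects cohort size (when generating), default 12.
#' @param emg_cfg an [emg_sim_config()] template; per-subject seeds are
#'   derived from `seed`.
#' @param sessions optional pre-built list of sessions (as returned by
#'   [make_emg_session()]), overriding generation.
#' @param seed master seed for schedules and sessions, default 1.
#' @param n_runs runs per subject, default 4.
#' @param out_dir optional output directory.
#' @return list with per-subject tables and group stats.
#' @export
run_physio_pipeline <- function(n_subjects = 12L,
                                emg_cfg = emg_sim_config(),
                                sessions = NULL, seed = 1L, n_runs = 4L,
                                out_dir = NULL) {
  if (is.null(sessions)) {
    seeds <- derive_seeds(seed, 2L * n_subjects)
    sessions <- lapply(seq_len(n_subjects), function(s) {
      sched <- lapply(seq_len(n_runs), function(r)
        build_block_schedule("meg", run_index = r,
                             seed = seeds[s] %% 2^28 + r))
      cfg_s <- emg_cfg
      cfg_s$seed <- seeds[n_subjects + s]
      make_emg_session(cfg_s, sched)
    })
  }
  n_sub <- length(sessions)
  per_subject <- vector("list", n_sub)
  startle_safe <- startle_threat <- aps <- numeric(n_sub)
  rating_safe <- rating_threat <- rdiff <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    tr <- sessions[[s]]$trace
    peaks <- score_probes(tr)
    cs <- condition_summary(peaks, tr$condition, tr$habituation)
    rat <- sessions[[s]]$ratings
    cr <- condition_summary(rat$rating, rat$condition, rat$habituation)
    startle_safe[s] <- cs$mean_safe; startle_threat[s] <- cs$mean_threat
    aps[s] <- cs$diff
    rating_safe[s] <- cr$mean_safe; rating_threat[s] <- cr$mean_threat
    rdiff[s] <- cr$diff
    keep <- !tr$habituation
    per_subject[[s]] <- data.frame(
      subject = s, probe = which(keep), condition = tr$condition[keep],
      raw_peak = peaks[keep], t_score = cs$t_scores)
  }
  res <- list(arm = "physio",
              startle = list(t = paired_t(startle_safe, startle_threat),
                             aps = aps,
                             sem = within_subject_sem(
                               cbind(safe = startle_safe,
                                     threat = startle_threat))),
              ratings = list(t = paired_t(rating_safe, rating_threat),
                             diff = rdiff),
              aps_rating_cor = pearson_r(aps, rdiff),
              tables = per_subject)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(do.call(rbind, per_subject),
              file.path(out_dir, "startle_scores.tsv"))
    stats <- list(arm = "physio",
                  startle_t = res$startle$t[c("statistic", "df",
                                              "p.value")],
                  rating_t = res$ratings$t[c("statistic", "df",
                                             "p.value")],
                  aps_rating_cor = res$aps_rating_cor)
    jsonlite::write_json(stats, file.path(out_dir, "physio_stats.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  res
}

#' Write a combined human-readable report
#'
#' One text report across whichever arms were run: cluster tables,
#' group statistics, within-subject-SEM bar data, and provenance
#' (seed, package version).
#'
#' @param results list with any of `fmri`, `meg`, `physio` entries (the
#'   return values of the corresponding pipelines).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path) {
  ln <- c("threatconn analysis report",
          paste0("package version: ",
                 as.character(utils::packageVersion("threatconn"))), "")
  f3 <- function(x) formatC(x, digits = 3, format = "f")
  if (!is.null(results$fmri)) {
    r <- results$fmri
    ln <- c(ln, "== fMRI global brain connectivity ==",
            sprintf("whole-brain GBC paired t(%d) = %s, p = %s",
                    r$whole_brain$df, f3(r$whole_brain$t),
                    f3(r$whole_brain$p)),
            sprintf("cluster-size threshold: %d voxels (voxel p = %g)",
                    r$cluster_threshold, r$config$voxel_p),
            sprintf("significant GBC clusters: %d",
                    sum(r$clusters$clusters$significant)),
            sprintf("within-subject SEM (safe, threat): %s, %s",
                    f3(r$sem$whole_brain[1]), f3(r$sem$whole_brain[2])),
            "")
    if (!is.null(r$robustness))
      ln <- c(ln, sprintf(
        "robustness ANCOVA: F(%d, %d) = %s, p = %s",
        r$robustness$ancova$df1, r$robustness$ancova$df2,
        f3(r$robustness$ancova$F), f3(r$robustness$ancova$p.value)), "")
  }
  if (!is.null(results$meg)) {
    r <- results$meg
    ln <- c(ln, "== MEG alpha power ==",
            sprintf("IAF detected in %d/%d subjects (fallback for %d)",
                    sum(!r$iaf$fallback), length(r$iaf$value),
                    sum(r$iaf$fallback)),
            sprintf("significant sensor clusters: %d",
                    sum(r$sensor$test$clusters$significant)),
            sprintf("significant source clusters: %d",
                    sum(r$source$test$clusters$significant)), "")
  }
  if (!is.null(results$physio)) {
    r <- results$physio
    ln <- c(ln, "== Startle and ratings ==",
            sprintf("startle paired t(%d) = %s, p = %s",
                    r$startle$t$df, f3(r$startle$t$statistic),
                    f3(r$startle$t$p.value)),
            sprintf("rating paired t(%d) = %s, p = %s",
                    r$ratings$t$df, f3(r$ratings$t$statistic),
                    f3(r$ratings$t$p.value)),
            sprintf("APS x rating r(%d) = %s, p = %s",
                    r$aps_rating_cor$df, f3(r$aps_rating_cor$r),
                    f3(r$aps_rating_cor$p.value)), "")
  }
  if (!is.null(results$overlap)) {
    ov <- results$overlap
    ln <- c(ln, sprintf("fMRI/MEG cluster overlap: %d/%d voxels",
                        ov$intersection, ov$n_b), "")
  }
  writeLines(ln, path)
  invisible(path)
}
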