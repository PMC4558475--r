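# internal: tiny FNV-1a hash of a character string (config fingerprinting);
# 32-bit arithmetic carried in doubles, xor applied to the low byte
fnv1a <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay exact
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * 16777619) %% 65536) * 65536 + lo16 * 16777619) %%
      4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# internal: deterministic per-participant seed derived from the root seed
participant_seed <- function(root, i) (root + i * 100003L) %% 2147483647L

#' Pipeline configuration
#'
#' Assembles and validates every knob of [run_pipeline()]. The default
#' configuration runs a reduced-scale simulated study (6 participants,
#' 200 short / 100 early / 100 late trials each) that completes in minutes
#' on one CPU; pass a full-size [wm_design()] for the complete trial
#' counts.
#'
#' @param design a [wm_design()] template; each participant gets a seed
#'   derived deterministically from `seed`.
#' @param n_participants number of simulated participants.
#' @param baseline baseline-correction window, ms (half-open).
#' @param smooth_sd Gaussian smoothing SD, ms.
#' @param window_memory,window_impulse cluster-test analysis windows, ms.
#' @param n_perm,cluster_alpha,alpha permutation-test settings.
#' @param lags lag grid for [lag_correlation()], ms.
#' @param lag_window correlation window on the early time-course, ms.
#' @param shifts training-shift grid for [shifted_training_scan()], ms.
#' @param shift_summary_window memory-item-locked window over which each
#'   shift is summarized, ms.
#' @param nominal_onset_ms nominal impulse onset anchoring cross-epoch
#'   alignment.
#' @param compute_matrices compute the four generalization matrices?
#' @param matrix_stride time-grid stride for the matrices.
#' @param behavior_truth list of generating parameters for the simulated
#'   responses (`g_short`, `sigma_short`, `g_long`, `sigma_long`).
#' @param seed root seed; every stage's randomness derives from it.
#' @param out_dir optional output directory for text artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = wm_design(n_short = 200L,
                                               n_early = 100L,
                                               n_late = 100L),
                            n_participants = 6L,
                            baseline = c(-200, 0), smooth_sd = 8,
                            window_memory = c(0, 1400),
                            window_impulse = c(0, 800),
                            n_perm = 10000L, cluster_alpha = 0.01,
                            alpha = 0.05,
                            lags = seq(0, 120, by = 4),
                            lag_window = c(1370, 2170),
                            shifts = seq(-60, 60, by = 4),
                            shift_summary_window = c(1300, 1700),
                            nominal_onset_ms = 1200,
                            compute_matrices = TRUE,
                            matrix_stride = 8L,
                            behavior_truth = list(g_short = 0.074,
                                                  sigma_short = 4.272,
                                                  g_long = 0.073,
                                                  sigma_long = 4.927),
                            seed = 0L, out_dir = NULL) {
  stopifnot(inherits(design, "wm_design"), n_participants >= 1L,
            smooth_sd > 0, n_perm >= 1L,
            cluster_alpha > 0, cluster_alpha < 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> %d participants, seed %d, ",
                     "%d/%d/%d trials each\n"),
              x$n_participants, x$seed, x$design$n_short,
              x$design$n_early, x$design$n_late))
  invisible(x)
}

#' Run the full simulated experiment end-to-end
#'
#' Synthesizes one participant after another, preprocesses (baseline
#' correction, Gaussian smoothing, impulse-locked re-epoching), decodes
#' (multivariate and univariate, memory and impulse epochs), computes the
#' four cross-temporal generalization matrices, the shifted-training scans
#' and lag correlation, group cluster tests, and the behavioral mixture
#' fits with the short-vs-long comparison. Deterministic given
#' `config$seed`. If `config$out_dir` is set, plain-text artifacts
#' (CSV time-courses and matrices, JSON cluster tables and fits, a
#' manifest) are written there.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `wm_pipeline` with per-participant and group
#'   results (see the vignette for the layout).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  participants <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    design_i <- config$design
    design_i$seed <- participant_seed(config$seed, i)
    sim <- generate_epochs(design_i)

    prep <- function(e)
      smooth_gaussian(baseline_correct(e, config$baseline),
                      config$smooth_sd)
    short <- prep(sim$short)
    long <- prep(sim$long)
    mem_all <- combine_epochs(short, crop_epochs(long, c(-200, 1400)))
    imp <- reepoch_impulse(long)

    tc <- list(
      memory_mv = loo_discrimination(mem_all),
      impulse_mv = loo_discrimination(imp),
      memory_uv = univariate_discrimination(mem_all),
      impulse_uv = univariate_discrimination(imp))

    matrices <- NULL
    if (config$compute_matrices) {
      mem_long <- crop_epochs(long, c(-200, 1400))
      matrices <- list(
        memory_memory = generalization_matrix(
          mem_all, stride = config$matrix_stride),
        impulse_impulse = generalization_matrix(
          imp, stride = config$matrix_stride),
        impulse_memory = generalization_matrix(
          imp, mem_long, stride = config$matrix_stride),
        memory_impulse = generalization_matrix(
          mem_long, imp, stride = config$matrix_stride))
    }

    early_ids <- long$trials$trial_id[
      long$trials$impulse_onset_ms == config$design$impulse_onsets_ms[1L]]
    late_ids <- setdiff(long$trials$trial_id, early_ids)
    lag_cover <- c(min(config$lag_window[1L],
                       config$shift_summary_window[1L]) - 4,
                   config$lag_window[2L] + max(config$lags) + 4)
    scan_early <- shifted_training_scan(
      imp, long, shifts = config$shifts,
      nominal_onset_ms = config$nominal_onset_ms,
      test_window = lag_cover,
      summary_window = config$shift_summary_window,
      subset_ids = early_ids)
    scan_late <- shifted_training_scan(
      imp, long, shifts = config$shifts,
      nominal_onset_ms = config$nominal_onset_ms,
      test_window = lag_cover,
      summary_window = config$shift_summary_window,
      subset_ids = late_ids)
    tc$cross_early <- shifted_training_timecourse(
      imp, long, shift_ms = 0,
      nominal_onset_ms = config$nominal_onset_ms,
      test_window = lag_cover, subset_ids = early_ids)
    tc$cross_late <- shifted_training_timecourse(
      imp, long, shift_ms = 0,
      nominal_onset_ms = config$nominal_onset_ms,
      test_window = lag_cover, subset_ids = late_ids)

    bt <- config$behavior_truth
    trials <- sim$trials
    is_short <- trials$trial_type == "short"
    beh_seed <- participant_seed(config$seed + 5000L, i)
    trials[is_short, ] <- generate_behavior(trials[is_short, ],
                                            bt$g_short, bt$sigma_short,
                                            seed = beh_seed)
    trials[!is_short, ] <- generate_behavior(trials[!is_short, ],
                                             bt$g_long, bt$sigma_long,
                                             seed = beh_seed + 1L)
    fits <- list(short = fit_mixture(data = trials[is_short, ]),
                 long = fit_mixture(data = trials[!is_short, ]))

    participants[[i]] <- list(seed = design_i$seed, timecourses = tc,
                              matrices = matrices,
                              scan_early = scan_early,
                              scan_late = scan_late, fits = fits)
  }

  stack <- function(name)
    do.call(rbind, lapply(participants,
                          function(p) p$timecourses[[name]]$mean))
  tmem <- participants[[1L]]$timecourses$memory_mv$time_ms
  timp <- participants[[1L]]$timecourses$impulse_mv$time_ms
  tcross <- participants[[1L]]$timecourses$cross_early$time_ms
  stat_seed <- participant_seed(config$seed + 9000L, 1L)

  group <- list(
    cluster_memory = sign_permutation_cluster(
      stack("memory_mv"), tmem, window = config$window_memory,
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      alpha = config$alpha, seed = stat_seed),
    cluster_impulse = sign_permutation_cluster(
      stack("impulse_mv"), timp, window = config$window_impulse,
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      alpha = config$alpha, seed = stat_seed + 1L),
    cluster_impulse_increase = baseline_increase_test(
      stack("impulse_mv"), timp, window = config$window_impulse,
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      alpha = config$alpha, seed = stat_seed + 2L),
    cluster_memory_uv = sign_permutation_cluster(
      stack("memory_uv"), tmem, window = config$window_memory,
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      alpha = config$alpha, seed = stat_seed + 3L),
    cluster_impulse_uv = sign_permutation_cluster(
      stack("impulse_uv"), timp, window = config$window_impulse,
      n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
      alpha = config$alpha, seed = stat_seed + 4L),
    lag = lag_correlation(stack("cross_early"), stack("cross_late"),
                          tcross, window = config$lag_window,
                          lags = config$lags),
    best_shift_early = local({
      s <- colMeans(do.call(rbind, lapply(participants,
                                          function(p) p$scan_early$summary)))
      config$shifts[which.max(s)]
    }),
    best_shift_late = local({
      s <- colMeans(do.call(rbind, lapply(participants,
                                          function(p) p$scan_late$summary)))
      config$shifts[which.max(s)]
    }),
    behavior = compare_conditions(
      lapply(participants, function(p) p$fits$short),
      lapply(participants, function(p) p$fits$long)))

  cfg_txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  manifest <- list(
    package = "impulsewm",
    version = as.character(utils::packageVersion("impulsewm")),
    seed = config$seed,
    participant_seeds = vapply(participants, `[[`, numeric(1L), "seed"),
    config_hash = fnv1a(cfg_txt))

  result <- structure(list(participants = participants, group = group,
                           config = config, manifest = manifest),
                      class = "wm_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

#' @export
print.wm_pipeline <- function(x, ...) {
  cat(sprintf("<wm_pipeline> %d participants (config %s)\n",
              length(x$participants), x$manifest$config_hash))
  cat(sprintf("  lag-correlation peak: %g ms; best shifts: early %+d, late %+d ms\n",
              x$group$lag$peak_lag_ms, x$group$best_shift_early,
              x$group$best_shift_late))
  n_sig <- function(ct) sum(ct$clusters$significant)
  cat(sprintf("  significant clusters: memory %d, impulse %d, impulse increase %d\n",
              n_sig(x$group$cluster_memory), n_sig(x$group$cluster_impulse),
              n_sig(x$group$cluster_impulse_increase)))
  invisible(x)
}

# internal: plain-text artifact writer for run_pipeline
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- result$group
  tc_csv <- function(name, time_ms) {
    mat <- do.call(cbind, lapply(result$participants, function(p)
      p$timecourses[[name]]$mean))
    colnames(mat) <- paste0("participant_", seq_len(ncol(mat)))
    df <- data.frame(time_ms = time_ms, mat, mean = rowMeans(mat))
    write.csv(df, file.path(dir, paste0("timecourse_", name, ".csv")),
              row.names = FALSE)
  }
  p1 <- result$participants[[1L]]$timecourses
  tc_csv("memory_mv", p1$memory_mv$time_ms)
  tc_csv("impulse_mv", p1$impulse_mv$time_ms)
  tc_csv("memory_uv", p1$memory_uv$time_ms)
  tc_csv("impulse_uv", p1$impulse_uv$time_ms)
  tc_csv("cross_early", p1$cross_early$time_ms)
  tc_csv("cross_late", p1$cross_late$time_ms)

  if (!is.null(result$participants[[1L]]$matrices)) {
    for (nm in names(result$participants[[1L]]$matrices)) {
      mats <- lapply(result$participants, function(p)
        p$matrices[[nm]]$values)
      avg <- Reduce(`+`, mats) / length(mats)
      m1 <- result$participants[[1L]]$matrices[[nm]]
      df <- data.frame(train_time_ms = m1$train_time_ms, avg)
      colnames(df)[-1L] <- paste0("t", m1$test_time_ms)
      write.csv(df, file.path(dir, paste0("matrix_", nm, ".csv")),
                row.names = FALSE)
    }
  }

  cluster_json <- function(ct) list(settings = ct$settings,
                                    clusters = ct$clusters)
  jsonlite::write_json(
    list(memory = cluster_json(g$cluster_memory),
         impulse = cluster_json(g$cluster_impulse),
         impulse_increase = cluster_json(g$cluster_impulse_increase),
         memory_univariate = cluster_json(g$cluster_memory_uv),
         impulse_univariate = cluster_json(g$cluster_impulse_uv)),
    file.path(dir, "cluster_tests.json"), auto_unbox = TRUE, digits = NA)

  write.csv(data.frame(lag_ms = g$lag$lags, mean_z = g$lag$mean_z,
                       t(g$lag$z)), file.path(dir, "lag_correlation.csv"),
            row.names = FALSE)

  fits <- lapply(result$participants, function(p)
    list(short = as.list(coef(p$fits$short)),
         long = as.list(coef(p$fits$long))))
  jsonlite::write_json(
    list(per_participant = fits, comparison = g$behavior),
    file.path(dir, "behavior_fits.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
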