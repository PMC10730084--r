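#' Lag-recovery study: coupling lag between cAMP and transcription
#'
#' Simulates paired signalling/transcription traces under a gene preset and
#' signalling regime, estimates the cross-correlation lag on the
#' analysed-zone mean traces, and averages over seeds.
#'
#' @param preset a [gene_preset()].
#' @param mode signalling regime (`"wildtype"` or `"bpac"`).
#' @param seeds integer vector of simulation seeds.
#' @param duration_min trace length (3 h default).
#' @param period_min fixed oscillation period for `wildtype` mode.
#' @param pulse_interval_min pulse interval for `bpac` mode.
#' @return list with `mean_lag_s`, `lags_s` per seed and `n_frames`.
#' @export
run_lag_recovery <- function(preset, mode = c("wildtype", "bpac"),
                             seeds = 1:20, duration_min = 180,
                             period_min = 6, pulse_interval_min = 10) {
  mode <- match.arg(mode)
  lags <- vapply(seeds, function(s) {
    cfg <- if (mode == "wildtype") {
      niche_config(duration_min = duration_min,
                   wave_period_start_min = period_min,
                   wave_period_end_min = period_min, rng_seed = s)
    } else {
      niche_config(mode = "bpac", pulse_interval_min = pulse_interval_min,
                   duration_min = duration_min, rng_seed = s)
    }
    truth <- simulate_transcription(simulate_camp_field(cfg), preset)
    z <- zone_mean_traces(truth)
    estimate_lag(z$signal, z$txn,
                 frame_interval_s = cfg$frame_interval_s)$lag_s
  }, numeric(1))
  list(mean_lag_s = mean(lags), lags_s = lags,
       n_frames = floor(duration_min * 60 / 45) + 1L)
}

#' Colony benchmark: front speed and inter-mound interval statistics
#'
#' Renders colony time-lapses under the default configuration, runs
#' [track_front()], [detect_mound_events()] and [interval_stats()], and
#' averages the fitted speed and pooled median interval over seeds.
#'
#' @param seeds integer vector of simulation seeds.
#' @param cfg_fn function mapping a seed to a [colony_config()].
#' @return list with `mean_speed_um_min`, `mean_median_interval_h`, and the
#'   per-seed values.
#' @export
run_colony_benchmark <- function(seeds = 1:20,
                                 cfg_fn = function(s) colony_config(rng_seed = s)) {
  speeds <- numeric(length(seeds))
  medians <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- cfg_fn(seeds[i])
    sim <- simulate_colony(cfg)
    ft <- track_front(sim$stack, pixel_size_um = cfg$pixel_size_um,
                      frame_interval_min = cfg$frame_interval_min)
    ev <- detect_mound_events(sim$stack, pixel_size_um = cfg$pixel_size_um,
                              frame_interval_min = cfg$frame_interval_min)
    ist <- interval_stats(ev, section_width_px = cfg$section_width_px,
                          pixel_size_um = cfg$pixel_size_um)
    speeds[i] <- ft$speed_um_min
    medians[i] <- if (is.null(ist$stats)) NA_real_ else ist$stats$median
  }
  list(mean_speed_um_min = mean(speeds),
       mean_median_interval_h = mean(medians, na.rm = TRUE),
       speeds = speeds, medians = medians)
}

#' End-to-end jump and cAMP-dependence pipeline
#'
#' Runs the full single-cell analysis on a paired wild-type / acaA-null
#' fixture: normalisation, PCA (PC1 oriented against the ribosomal score),
#' density-gap jump detection, gene categorisation relative to the detected
#' boundary, and dependence classification against the knockout profiles
#' (ordered by their known collection time).
#'
#' @param cfg a [counts_config()] with both conditions.
#' @return list with the `jump_call`, `categories`, `dependence` table,
#'   `n_cells`, and the per-truth-category dependence counts
#'   (`n_pre_failed`, `n_jump_partial`, `n_post_retained`) with panel sizes.
#' @export
run_dependence_pipeline <- function(cfg = counts_config()) {
  if (!all(c("WT", "acaA_null") %in% cfg$conditions))
    stop_config("both conditions are required")
  sim <- simulate_counts(cfg)
  norm_wt <- normalize_counts(sim$conditions$WT)
  norm_ko <- normalize_counts(sim$conditions$acaA_null)
  ribo <- grep("^ribo", rownames(norm_wt$log_mat), value = TRUE)
  emb <- embed_cells(norm_wt, orient_genes = ribo)
  jump <- detect_jump(emb)
  if (!jump$jump) stop("no jump detected on the fixture")
  ord <- order(emb$scores[, 1])
  cats <- categorize_genes(norm_wt, ord, jump$n_pre)
  ko_ord <- order(norm_ko$cell_meta$pseudotime)
  dep <- classify_dependence(expression_profiles(norm_wt, ord),
                             expression_profiles(norm_ko, ko_ord), cats)
  truth <- sim$gene_truth
  dep$truth_category <- truth$category[match(dep$gene, truth$gene)]
  list(
    jump_call = jump, categories = cats, dependence = dep,
    n_cells = ncol(sim$conditions$WT$counts),
    embedding = emb, sim = sim,
    n_pre_failed = sum(dep$truth_category == "pre_jump" &
                         dep$dependence == "failed_repression"),
    n_pre = cfg$n_pre_jump,
    n_jump_partial = sum(dep$truth_category == "jump" &
                           dep$dependence == "partial_induction"),
    n_jump = cfg$n_jump,
    n_post_retained = sum(dep$truth_category == "post_jump" &
                            dep$dependence == "retained"),
    n_post = cfg$n_post_jump
  )
}

#' Induction-onset study under 6-min optogenetic pulsing
#'
#' Simulates the one-step reference gene under a 6-min bpac pulse train
#' with its default priming delay, detects induction on the
#' responsive-zone mean trace, and averages the onset over seeds.
#'
#' @param seeds integer vector of simulation seeds.
#' @param duration_min simulated duration.
#' @return list with `mean_onset_min` and per-seed `onsets_min`.
#' @export
run_induction_onset <- function(seeds = 1:20, duration_min = 180) {
  onsets <- vapply(seeds, function(s) {
    cfg <- niche_config(mode = "bpac", pulse_interval_min = 6,
                        duration_min = duration_min, rng_seed = s)
    truth <- simulate_transcription(simulate_camp_field(cfg), preset_carA())
    z <- zone_mean_traces(truth)
    res <- detect_induction(z$txn, frame_interval_s = cfg$frame_interval_s)
    if (!res$induced) NA_real_ else res$onset_min
  }, numeric(1))
  list(mean_onset_min = mean(onsets, na.rm = TRUE), onsets_min = onsets)
}
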