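#' Simulate a multi-subject searchlight RSA study with planted effects
#'
#' End-to-end driver for the planted-effect recovery analyses: for each
#' simulated subject it generates a subject-specific schedule and timeline
#' responses, simulates BOLD data with the requested integration (within
#' mode) or differentiation (between mode) strength, fits the matching
#' first-level GLM (model one for within, model two for between), computes
#' the searchlight model-correlation map with the temporal-proximity partial
#' covariate, and smooths it. The returned maps feed
#' [group_cluster_mass()].
#'
#' The default problem size is deliberately compact (one run of 16 episodes
#' with shortened inter-episode periods on a 16x16x16 grid) so that a
#' twelve-subject study runs in about a minute; the stimulus-period timing
#' of the episodes themselves keeps the standard interval structure.
#'
#' @param n_subjects Number of simulated subjects.
#' @param mode `"within"` (object-level integration) or `"between"`
#'   (episode-level differentiation).
#' @param strength Planted effect strength (0 = null data).
#' @param seed Integer seed; all subject-level seeds derive from it.
#' @param grid_shape Voxel grid.
#' @param amplitude,noise_sd BOLD event amplitude scale and AR(1) noise SD.
#' @param smooth_fwhm_mm Smoothing kernel FWHM (mm).
#' @return List with `maps` (list of 3-D subject maps), `mask`, `mode`,
#'   `signal_voxels` (truth for the first subject; the region is identical
#'   across subjects), and `strength`.
#' @export
simulate_rsa_study <- function(n_subjects = 12L,
                               mode = c("within", "between"),
                               strength = 0, seed = 1L,
                               grid_shape = c(16L, 16L, 16L),
                               amplitude = 12, noise_sd = 0.25,
                               smooth_fwhm_mm = 6) {
  mode <- match.arg(mode)
  set.seed(seed)
  subject_seeds <- sample.int(2^30, n_subjects * 3L)
  maps <- vector("list", n_subjects)
  mask <- NULL; signal_voxels <- NULL
  sl <- NULL
  for (s in seq_len(n_subjects)) {
    s3 <- subject_seeds[(s - 1L) * 3L + 1:3]
    des <- experiment_design(n_runs = 1L, cross_fixation = 3, odd_even = 3,
                             timeline_planning = 2, timeline_execution = 4,
                             rng_seed = s3[1])
    sch <- generate_schedule(des)
    pm <- participant_model(
      global_scaling_bias = 1,
      pattern_noise_sd = 0.25, scaling_jitter_sd = 0.15,
      episode_scaling_bias = if (mode == "between") stats::runif(1, 1.05, 1.25) else 1,
      episode_noise_sd = 30, rng_seed = s3[2])
    resp <- simulate_responses(sch, pm)
    spec <- bold_sim_spec(
      grid_shape = grid_shape,
      integration_strength = if (mode == "within") strength else 0,
      differentiation_strength = if (mode == "between") strength else 0,
      amplitude = amplitude, noise_sd = noise_sd, rng_seed = s3[3])
    sim <- simulate_bold(sch, resp, spec)
    if (is.null(mask)) {
      mask <- sim$mask
      signal_voxels <- sim$truth$signal_voxels
      sl <- build_searchlights(mask, voxel_size_mm = spec$voxel_size)
    }
    if (mode == "within") {
      des1 <- build_design(sch$events, "one", tr = spec$tr, n_frames = sim$n_frames)
      g <- fit_glm(sim$bold, des1)
      obj_rows <- grep("^object_", rownames(g$betas))
      ids <- as.integer(sub("^object_", "", rownames(g$betas)[obj_rows]))
      ord <- match(sch$objects$object_id, ids)
      ep_of <- sim$truth$episode_of_object
      pr <- pairs_within_episode(ep_of)
      sc1 <- sim$truth$scaling_p1
      mod <- model_rdm_within(pmax(0, 1 - sc1), pmax(0, sc1 - 1), ep_of, pr)
      cov <- lag_covariate(sch$objects$onset, pr)
      m <- searchlight_map(g$betas[obj_rows, , drop = FALSE][ord, , drop = FALSE],
                           g$residuals, sl, pr, mod, cov)
    } else {
      des2 <- build_design(sch$events, "two", tr = spec$tr, n_frames = sim$n_frames)
      g <- fit_glm(sim$bold, des2)
      stim_rows <- grep("^stimulus_", rownames(g$betas))
      eps <- as.integer(sub("^stimulus_r[0-9]+_e", "", rownames(g$betas)[stim_rows]))
      ord <- order(eps)
      pr <- pairs_between(length(stim_rows))
      mod <- model_rdm_between(sim$truth$exp_p2, pr)
      pos <- (sch$episodes$green_onset + sch$episodes$red_onset) / 2
      cov <- lag_covariate(pos, pr)
      m <- searchlight_map(g$betas[stim_rows, , drop = FALSE][ord, , drop = FALSE],
                           g$residuals, sl, pr, mod, cov)
    }
    maps[[s]] <- smooth_map(m, mask, fwhm_mm = smooth_fwhm_mm,
                            voxel_size_mm = spec$voxel_size)
  }
  list(maps = maps, mask = mask, mode = mode, strength = strength,
       signal_voxels = signal_voxels)
}
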