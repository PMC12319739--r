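#' BOLD simulation parameters
#'
#' Parameters for the planted-effect BOLD generator: voxel grid, acquisition
#' timing, AR(1) noise, strengths of the planted within-episode pattern
#' integration and between-episode pattern differentiation, and sustained
#' motion spikes for the DVARS tests.
#'
#' @param grid_shape Voxel counts along the three axes.
#' @param voxel_size Isotropic voxel size (mm, default 3).
#' @param tr Repetition time (seconds, default 2.57).
#' @param noise_sd Marginal SD of the AR(1) voxel noise.
#' @param ar1_coef AR(1) coefficient in (-1, 1).
#' @param integration_strength Coupling between an episode's measured
#'   within-episode compression and the mixture weight of the shared episode
#'   pattern in its object patterns (0 = no planted integration).
#' @param differentiation_strength Coupling between an episode's measured
#'   between-episode expansion and its displacement along a common pattern
#'   direction (0 = no planted differentiation).
#' @param n_motion_spikes Number of frames receiving a sustained global
#'   displacement (head moves and stays moved).
#' @param spike_magnitude Displacement SD in units of `noise_sd`.
#' @param signal_region_radius_mm Radius of the spherical region (centered
#'   in the grid) carrying the structured patterns; outside it event
#'   amplitudes are unstructured.
#' @param amplitude Scale of the event response amplitudes.
#' @param rng_seed Integer seed.
#' @return Object of class `tm_bold_spec`.
#' @export
bold_sim_spec <- function(grid_shape = c(16L, 16L, 16L), voxel_size = 3,
                          tr = 2.57, noise_sd = 1, ar1_coef = 0.4,
                          integration_strength = 0,
                          differentiation_strength = 0,
                          n_motion_spikes = 0L, spike_magnitude = 6,
                          signal_region_radius_mm = 12,
                          amplitude = 1, rng_seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            abs(ar1_coef) < 1, noise_sd >= 0, n_motion_spikes >= 0)
  out <- as.list(environment())
  out$grid_shape <- as.integer(grid_shape)
  out$n_motion_spikes <- as.integer(n_motion_spikes)
  out$rng_seed <- as.integer(rng_seed)
  class(out) <- "tm_bold_spec"
  out
}

#' Simulate BOLD data with planted integration/differentiation effects
#'
#' Each object event receives a latent spatial amplitude pattern inside a
#' central spherical signal region. Within an episode, object patterns are
#' mixtures of a shared episode pattern and object-unique patterns, with the
#' shared-pattern weight increasing as the episode's measured within-episode
#' scaling decreases (temporal compression), scaled by
#' `integration_strength`. Episode patterns are displaced along a common
#' direction in proportion to the episode's measured between-episode
#' expansion times `differentiation_strength`, so pairwise episode-pattern
#' distances track the absolute difference in expansion. Outside the signal
#' region, event amplitudes are unstructured. The voxel time series are the
#' HRF-convolved event regressors times these amplitudes, plus AR(1) noise
#' and optional sustained motion displacements.
#'
#' @param schedule A `tm_schedule`.
#' @param responses A `tm_responses` for the scanned participant (its
#'   timeline responses define the measured scaling values the effects are
#'   tied to).
#' @param spec A `tm_bold_spec`.
#' @return Object of class `tm_bold`: list with `bold` (frames x voxels
#'   matrix over the full grid), `mask` (3-D logical, all TRUE), `events`
#'   (the schedule's event table), `frame_run`, `n_frames` per run, `spec`,
#'   and `truth` (signal-region indices, per-episode scaling values, mixture
#'   weights, and the amplitude matrix).
#' @export
simulate_bold <- function(schedule, responses, spec = bold_sim_spec()) {
  stopifnot(inherits(schedule, "tm_schedule"), inherits(spec, "tm_bold_spec"))
  d <- schedule$design
  dims <- spec$grid_shape
  V <- prod(dims)
  mask <- array(TRUE, dims)
  if (V < 10L) stop("grid too small for the default searchlight size")
  set.seed(spec$rng_seed)

  # per-episode measured scaling values the planted effects are tied to
  eps <- schedule$episodes
  n_ep <- nrow(eps)
  scaling_p1 <- numeric(n_ep)
  exp_p2 <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    tt <- true_object_times(schedule, eps$run[k], eps$episode[k])
    t1 <- responses$timeline1[responses$timeline1$run == eps$run[k] &
                                responses$timeline1$episode == eps$episode[k], ]
    t1 <- t1[order(t1$object_index), ]
    dec <- decompose_pattern(tt, t1$placed_time)
    scaling_p1[k] <- if (is.na(dec$scaling)) 1 else dec$scaling
  }
  for (run in sort(unique(eps$run))) {
    pos <- episode_positions(schedule, run)
    t2 <- responses$timeline2[responses$timeline2$run == run, ]
    im <- item_measures(pos, t2$placed_time)
    exp_p2[eps$run == run] <- im$item_scaling_exp
  }

  # signal region: central sphere
  ctr <- (dims + 1) / 2
  coords <- arrayInd(seq_len(V), dims)
  dist_mm <- spec$voxel_size * sqrt((coords[, 1] - ctr[1])^2 +
                                      (coords[, 2] - ctr[2])^2 +
                                      (coords[, 3] - ctr[3])^2)
  signal_vox <- which(dist_mm <= spec$signal_region_radius_mm)
  Vb <- length(signal_vox)

  obj <- schedule$objects
  n_obj <- nrow(obj)
  ep_key <- paste(eps$run, eps$episode)
  episode_of_obj <- match(paste(obj$run, obj$episode), ep_key)

  # latent patterns inside the signal region
  common <- stats::rnorm(Vb, 0, 0.3)
  direction <- stats::rnorm(Vb); direction <- direction / sqrt(sum(direction^2)) * sqrt(Vb)
  ep_unique <- matrix(stats::rnorm(n_ep * Vb, 0, 0.7), n_ep, Vb)
  E <- matrix(common, n_ep, Vb, byrow = TRUE) +
    spec$differentiation_strength * exp_p2 %o% direction + ep_unique
  w <- pmin(0.95, pmax(0.05, 0.5 + spec$integration_strength * (1 - scaling_p1)))
  U <- matrix(stats::rnorm(n_obj * Vb), n_obj, Vb)
  A <- matrix(stats::rnorm(n_obj * V), n_obj, V)  # unstructured background
  A[, signal_vox] <- w[episode_of_obj] * E[episode_of_obj, , drop = FALSE] +
    (1 - w[episode_of_obj]) * U
  A <- A * spec$amplitude

  # object-event design (one regressor per object event)
  des <- build_design(schedule$events, variant = "one", tr = spec$tr)
  obj_cols <- grep("^object_", colnames(des$X))
  stopifnot(length(obj_cols) == n_obj)
  # columns are in event order per run; align with the objects table
  col_ids <- as.integer(sub("^object_", "", colnames(des$X)[obj_cols]))
  A_aligned <- A[match(col_ids, obj$object_id), , drop = FALSE]
  Y <- des$X[, obj_cols, drop = FALSE] %*% A_aligned

  # AR(1) noise, independent across runs
  Tn <- nrow(Y)
  if (spec$noise_sd > 0) {
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1_coef^2)
    noise <- matrix(0, Tn, V)
    run_lens <- as.integer(table(des$frame_run))
    row0 <- 0L
    for (len in run_lens) {
      e <- matrix(stats::rnorm(len * V, 0, innov_sd), len, V)
      e[1, ] <- stats::rnorm(V, 0, spec$noise_sd)
      for (t in 2:len) e[t, ] <- spec$ar1_coef * e[t - 1L, ] + e[t, ]
      noise[row0 + seq_len(len), ] <- e
      row0 <- row0 + len
    }
    Y <- Y + noise
  }

  spike_frames <- integer(0)
  if (spec$n_motion_spikes > 0L) {
    spike_frames <- sort(sample(5:(Tn - 5), spec$n_motion_spikes))
    for (f in spike_frames) {
      shift <- stats::rnorm(V, 0, spec$spike_magnitude * max(spec$noise_sd, 1e-3))
      Y[f:Tn, ] <- sweep(Y[f:Tn, , drop = FALSE], 2L, shift, `+`)
    }
  }
  Y <- Y + 100  # baseline signal level

  out <- list(bold = Y, mask = mask, events = schedule$events,
              frame_run = des$frame_run,
              n_frames = as.integer(table(des$frame_run)),
              spec = spec,
              truth = list(signal_voxels = signal_vox,
                           scaling_p1 = scaling_p1, exp_p2 = exp_p2,
                           mixture_weight = w, spike_frames = spike_frames,
                           episode_of_object = episode_of_obj,
                           amplitudes = A))
  class(out) <- "tm_bold"
  out
}

#' Reshape a frames x voxels matrix to a 4-D volume
#'
#' @param bold A `tm_bold` or a frames x voxels matrix.
#' @param dims Grid dimensions (taken from the object when a `tm_bold`).
#' @return 4-D numeric array (x, y, z, time).
#' @export
bold_to_volume <- function(bold, dims = NULL) {
  if (inherits(bold, "tm_bold")) {
    dims <- bold$spec$grid_shape
    bold <- bold$bold
  }
  aperm(array(t(bold), c(dims, nrow(bold))), c(1, 2, 3, 4))
}
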