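#' Participant distortion model
#'
#' Parameterizes how a simulated participant distorts the true temporal
#' patterns when reconstructing them on the timeline tests: a global
#' multiplicative scaling of recalled intervals about the pattern centroid
#' (< 1 compresses, > 1 expands), an additive translation, Gaussian pattern
#' noise, and a probability of swapping adjacent items. Episode placements on
#' the run timeline use the analogous `episode_*` parameters. Recognition and
#' association behavior is a simple Bernoulli hit/lure model.
#'
#' @param global_scaling_bias Scaling applied to recalled within-episode
#'   intervals (dimensionless, > 0).
#' @param translation_bias Additive shift of the recalled pattern (seconds).
#' @param pattern_noise_sd SD of i.i.d. Gaussian noise on each placed object
#'   time (seconds).
#' @param scaling_jitter_sd SD of the per-episode log-normal jitter on the
#'   within-episode scaling (episodes are genuinely compressed or expanded
#'   by different amounts around the global bias; 0 disables).
#' @param noise_scaling_exponent Couples placement noise to the episode's
#'   realized scaling: the per-episode noise SD is `pattern_noise_sd *
#'   scaling^exponent`, so a positive exponent makes compressed episodes
#'   (scaling < 1) more precisely encoded. 0 (default) decouples them.
#' @param order_swap_prob Probability that each adjacent object pair has its
#'   placed times exchanged (order and timing errors stay coupled, as in a
#'   drag-and-drop interface).
#' @param episode_scaling_bias,episode_noise_sd Same model for episode
#'   placements within runs.
#' @param recog_hit_rate,recog_fa_rate Probability of selecting a target /
#'   a lure in the recognition test.
#' @param assoc_accuracy Probability of choosing the correct object in each
#'   association trial.
#' @param rng_seed Integer seed used by [simulate_responses()].
#' @return Object of class `tm_participant`.
#' @export
participant_model <- function(global_scaling_bias = 1,
                              translation_bias = 0,
                              pattern_noise_sd = 0,
                              scaling_jitter_sd = 0,
                              noise_scaling_exponent = 0,
                              order_swap_prob = 0,
                              episode_scaling_bias = 1,
                              episode_noise_sd = 0,
                              recog_hit_rate = 0.8,
                              recog_fa_rate = 0.1,
                              assoc_accuracy = 0.7,
                              rng_seed = 1L) {
  stopifnot(global_scaling_bias > 0, episode_scaling_bias > 0,
            pattern_noise_sd >= 0, scaling_jitter_sd >= 0, episode_noise_sd >= 0,
            order_swap_prob >= 0, order_swap_prob <= 1,
            recog_hit_rate >= 0, recog_hit_rate <= 1,
            recog_fa_rate >= 0, recog_fa_rate <= 1,
            assoc_accuracy >= 0, assoc_accuracy <= 1)
  out <- as.list(environment())
  out$rng_seed <- as.integer(rng_seed)
  class(out) <- "tm_participant"
  out
}

# Affine-distort one true pattern: centroid-anchored scaling + translation +
# noise, clipped to the timeline bounds.
distort_pattern <- function(true_times, scaling, translation, noise_sd, bounds) {
  ctr <- mean(true_times)
  r <- ctr + scaling * (true_times - ctr) + translation
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  pmin(pmax(r, bounds[1]), bounds[2])
}

swap_adjacent <- function(times, swap_prob) {
  if (swap_prob <= 0) return(times)
  for (i in seq_len(length(times) - 1L)) {
    if (stats::runif(1) < swap_prob) {
      times[c(i, i + 1L)] <- times[c(i + 1L, i)]
    }
  }
  times
}

#' Simulate timeline, recognition, and association responses
#'
#' Applies a participant distortion model to every episode of a schedule.
#' Recalled object times are `centroid + global_scaling_bias * (true -
#' centroid) + translation_bias + noise`, clipped to the episode boundaries;
#' adjacent items then exchange placed times with `order_swap_prob`. Episode
#' placements on the run timeline are built the same way from the episode
#' stimulus-period midpoints. Recognition selections and per-episode
#' object-association choices follow the model's Bernoulli rates.
#'
#' @param schedule A `tm_schedule`.
#' @param participant A `tm_participant`.
#' @param participant_id Identifier stored in the output tables.
#' @return Object of class `tm_responses`: list with data.frames `timeline1`
#'   (`run`, `episode`, `object_index`, `object_id`, `true_time`,
#'   `placed_time`), `timeline2` (`run`, `episode`, `true_time`,
#'   `placed_time`), `recognition` (list of `selected_ids`, `target_ids`,
#'   `lure_ids`), `association` (`run`, `episode`, `chosen_id`, `correct_id`,
#'   `correct`), and `meta` (one row of participant covariates).
#' @export
simulate_responses <- function(schedule, participant = participant_model(),
                               participant_id = 1L) {
  stopifnot(inherits(schedule, "tm_schedule"), inherits(participant, "tm_participant"))
  p <- participant
  d <- schedule$design
  set.seed(p$rng_seed)
  t1 <- list(); t2 <- list()
  for (run in seq_len(d$n_runs)) {
    eps <- schedule$episodes[schedule$episodes$run == run, ]
    for (ep in eps$episode) {
      tt <- true_object_times(schedule, run, ep)
      bounds <- c(eps$green_onset[eps$episode == ep],
                  eps$red_onset[eps$episode == ep] + d$boundary_duration)
      ep_scaling <- p$global_scaling_bias *
        exp(if (p$scaling_jitter_sd > 0) stats::rnorm(1, 0, p$scaling_jitter_sd) else 0)
      ep_noise <- p$pattern_noise_sd * ep_scaling^p$noise_scaling_exponent
      placed <- distort_pattern(tt, ep_scaling, p$translation_bias,
                                ep_noise, bounds)
      placed <- swap_adjacent(placed, p$order_swap_prob)
      oo <- schedule$objects[schedule$objects$run == run & schedule$objects$episode == ep, ]
      t1[[length(t1) + 1L]] <- data.frame(
        participant = participant_id, run = run, episode = ep,
        object_index = oo$object_index, object_id = oo$object_id,
        true_time = tt, placed_time = placed)
    }
    pos <- episode_positions(schedule, run)
    rb <- run_bounds(schedule, run)
    placed2 <- distort_pattern(pos, p$episode_scaling_bias, 0, p$episode_noise_sd, rb)
    t2[[length(t2) + 1L]] <- data.frame(
      participant = participant_id, run = run, episode = eps$episode,
      true_time = pos, placed_time = placed2)
  }
  targets <- schedule$objects$object_id
  n_lures <- d$recognition_pool - d$recognition_targets
  lures <- if (n_lures > 0) max(targets) + seq_len(n_lures) else integer(0)
  selected <- c(targets[stats::runif(length(targets)) < p$recog_hit_rate],
                lures[stats::runif(length(lures)) < p$recog_fa_rate])

  assoc <- lapply(seq_len(d$n_runs), function(run) {
    oo <- schedule$objects[schedule$objects$run == run, ]
    correct_ids <- oo$object_id[oo$object_index == d$objects_per_episode]
    chosen <- vapply(seq_along(correct_ids), function(i) {
      if (stats::runif(1) < p$assoc_accuracy) correct_ids[i]
      else sample(correct_ids[-i], 1L)
    }, numeric(1))
    data.frame(participant = participant_id, run = run,
               episode = sort(unique(oo$episode)),
               chosen_id = chosen, correct_id = correct_ids,
               correct = chosen == correct_ids)
  })

  meta <- data.frame(
    participant = participant_id,
    age = sample(18:41, 1L),
    sex = sample(c("M", "F"), 1L),
    prior_fmri = stats::rbinom(1L, 1L, 0.2),
    timeline1_time = stats::rnorm(1L, 50.5, 13))
  strat <- as.data.frame(as.list(sample(1:9, 22L, replace = TRUE)))
  names(strat) <- paste0("strategy_", seq_len(22L))
  meta <- cbind(meta, strat)

  out <- list(participant = participant_id, model = p,
              timeline1 = do.call(rbind, t1),
              timeline2 = do.call(rbind, t2),
              recognition = list(selected_ids = selected, target_ids = targets,
                                 lure_ids = lures),
              association = do.call(rbind, assoc),
              meta = meta)
  class(out) <- "tm_responses"
  out
}

#' Simulate a cohort with compression coupled to response fidelity
#'
#' Draws one distortion model per participant with the within-episode scaling
#' bias, pattern noise, and order-swap probability coupled: participants who
#' compress time (scaling bias < 1) place objects with less noise and make
#' fewer order errors, and — via `noise_scaling_exponent` — individual
#' episodes that happen to be compressed are encoded more precisely than
#' expanded ones. This is the planted behavioral structure used to test the
#' mixed-model and mediation stages (compression -> better temporal pattern
#' -> better order), at both the participant and the trial level.
#'
#' @param n_participants Number of participants.
#' @param schedule A `tm_schedule`.
#' @param seed Integer seed.
#' @param scaling_range Range of the uniform scaling-bias draw.
#' @param noise_base,noise_slope Pattern noise (s) = `noise_base + noise_slope
#'   * (scaling_bias - min(scaling_range))`.
#' @param swap_base,swap_slope Order-swap probability = `swap_base +
#'   swap_slope * (pattern_noise - noise_base)`.
#' @param scaling_jitter_sd Per-episode scaling jitter passed to every
#'   participant model.
#' @param noise_scaling_exponent Trial-level compression/fidelity coupling
#'   passed to every participant model.
#' @param episode_noise_sd Episode-placement noise (seconds).
#' @return List of `tm_responses`, one per participant.
#' @export
simulate_cohort <- function(n_participants, schedule, seed = 1L,
                            scaling_range = c(0.6, 1.4),
                            noise_base = 0.15, noise_slope = 0.5,
                            swap_base = 0.05, swap_slope = 0.5,
                            scaling_jitter_sd = 0.2,
                            noise_scaling_exponent = 2,
                            episode_noise_sd = 40) {
  set.seed(seed)
  gb <- stats::runif(n_participants, scaling_range[1], scaling_range[2])
  eb <- stats::runif(n_participants, 0.7, 1.3)
  seeds <- sample.int(.Machine$integer.max, n_participants)
  lapply(seq_len(n_participants), function(i) {
    noise <- noise_base + noise_slope * (gb[i] - scaling_range[1])
    swap <- min(1, swap_base + swap_slope * (noise - noise_base))
    pm <- participant_model(global_scaling_bias = gb[i],
                            translation_bias = stats::rnorm(1, 0, 0.3),
                            pattern_noise_sd = noise,
                            scaling_jitter_sd = scaling_jitter_sd,
                            noise_scaling_exponent = noise_scaling_exponent,
                            order_swap_prob = swap,
                            episode_scaling_bias = eb[i],
                            episode_noise_sd = episode_noise_sd,
                            rng_seed = seeds[i])
    simulate_responses(schedule, pm, participant_id = i)
  })
}
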