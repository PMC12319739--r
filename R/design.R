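#' Experiment design parameters
#'
#' Bundles the timing and counting parameters of the episodic-memory timeline
#' paradigm: runs of unique episodes, each episode a green start screen, five
#' objects, and a red end screen, with six inter-stimulus gaps drawn half from
#' a short and half from a long uniform range so every episode carries a
#' unique temporal pattern.
#'
#' @param n_runs Number of runs.
#' @param episodes_per_run Episodes presented per run.
#' @param objects_per_episode Objects per episode.
#' @param object_duration Object presentation time (seconds).
#' @param boundary_duration Green/red boundary screen time (seconds).
#' @param short_interval_range Length-2 numeric, uniform range for the short
#'   gaps (seconds).
#' @param long_interval_range Length-2 numeric, uniform range for the long
#'   gaps (seconds).
#' @param n_short,n_long Number of gaps drawn from each range; must sum to
#'   `objects_per_episode + 1`.
#' @param cross_fixation Cross-fixation period after each episode (seconds).
#' @param odd_even Odd-even judgment period (seconds); used both after the
#'   cross-fixation and after the timeline test.
#' @param timeline_planning,timeline_execution Durations of the two phases of
#'   the within-episode timeline test (seconds).
#' @param recognition_pool Number of images in the final recognition test.
#' @param recognition_targets Number of previously presented objects in that
#'   pool.
#' @param rng_seed Integer seed used by [generate_schedule()].
#'
#' @return An object of class `tm_design` (a list of the above fields).
#' @export
experiment_design <- function(n_runs = 3L,
                              episodes_per_run = 16L,
                              objects_per_episode = 5L,
                              object_duration = 0.6,
                              boundary_duration = 0.6,
                              short_interval_range = c(0.1, 2.0),
                              long_interval_range = c(2.1, 3.5),
                              n_short = 3L,
                              n_long = 3L,
                              cross_fixation = 10,
                              odd_even = 10,
                              timeline_planning = 10,
                              timeline_execution = 40.5,
                              recognition_pool = 385L,
                              recognition_targets = 240L,
                              rng_seed = 1L) {
  stopifnot(n_runs >= 1, episodes_per_run >= 1, objects_per_episode >= 2)
  if (length(short_interval_range) != 2L || length(long_interval_range) != 2L)
    stop("interval ranges must have length 2")
  if (short_interval_range[1] >= short_interval_range[2] ||
      long_interval_range[1] >= long_interval_range[2])
    stop("invalid interval range: min must be < max")
  if (long_interval_range[1] <= short_interval_range[2])
    stop("interval ranges must not overlap")
  if (n_short + n_long != objects_per_episode + 1L)
    stop("n_short + n_long must equal objects_per_episode + 1 (one gap per transition)")
  if (recognition_targets > recognition_pool)
    stop("recognition_targets cannot exceed recognition_pool")
  out <- list(
    n_runs = as.integer(n_runs),
    episodes_per_run = as.integer(episodes_per_run),
    objects_per_episode = as.integer(objects_per_episode),
    object_duration = object_duration,
    boundary_duration = boundary_duration,
    short_interval_range = as.numeric(short_interval_range),
    long_interval_range = as.numeric(long_interval_range),
    n_short = as.integer(n_short),
    n_long = as.integer(n_long),
    cross_fixation = cross_fixation,
    odd_even = odd_even,
    timeline_planning = timeline_planning,
    timeline_execution = timeline_execution,
    recognition_pool = as.integer(recognition_pool),
    recognition_targets = as.integer(recognition_targets),
    rng_seed = as.integer(rng_seed)
  )
  class(out) <- "tm_design"
  out
}

#' Generate ground-truth episode schedules
#'
#' Lays out every run as a sequence of episode cycles (stimulus period,
#' cross-fixation, odd-even task, timeline test planning and execution,
#' closing odd-even task). Within each stimulus period the six gaps
#' (green to first object, between objects, last object to red) are drawn
#' uniformly, three from the short range and three from the long range, with
#' the assignment of ranges to gap positions a uniformly random permutation.
#'
#' @param design A `tm_design` from [experiment_design()].
#' @return An object of class `tm_schedule`: list with
#'   * `episodes`: data.frame, one row per episode (`run`, `episode`,
#'     `green_onset`, `red_onset`, `cycle_onset`, `cycle_end` in seconds from
#'     run start);
#'   * `objects`: data.frame, one row per object event (`run`, `episode`,
#'     `object_index`, `object_id`, `onset`);
#'   * `events`: data.frame of all run events in BIDS style (`run`, `episode`,
#'     `onset`, `duration`, `trial_type`, `object_index`, `object_id`);
#'   * `design`: the generating design.
#' @export
generate_schedule <- function(design = experiment_design()) {
  stopifnot(inherits(design, "tm_design"))
  d <- design
  set.seed(d$rng_seed)
  n_gaps <- d$objects_per_episode + 1L
  ep_rows <- list(); obj_rows <- list(); ev_rows <- list()
  next_object_id <- 1L
  for (run in seq_len(d$n_runs)) {
    t_cursor <- 0
    for (ep in seq_len(d$episodes_per_run)) {
      gap_kind <- sample(rep(c("short", "long"), c(d$n_short, d$n_long)))
      gaps <- ifelse(gap_kind == "short",
                     stats::runif(n_gaps, d$short_interval_range[1], d$short_interval_range[2]),
                     stats::runif(n_gaps, d$long_interval_range[1], d$long_interval_range[2]))
      green_onset <- t_cursor
      onsets <- numeric(d$objects_per_episode)
      t <- green_onset + d$boundary_duration
      for (i in seq_len(d$objects_per_episode)) {
        onsets[i] <- t + gaps[i]
        t <- onsets[i] + d$object_duration
      }
      red_onset <- t + gaps[n_gaps]
      stim_end <- red_onset + d$boundary_duration
      ids <- seq.int(next_object_id, length.out = d$objects_per_episode)
      next_object_id <- next_object_id + d$objects_per_episode

      fix_on <- stim_end
      oe1_on <- fix_on + d$cross_fixation
      plan_on <- oe1_on + d$odd_even
      exec_on <- plan_on + d$timeline_planning
      oe2_on <- exec_on + d$timeline_execution
      cycle_end <- oe2_on + d$odd_even

      ep_rows[[length(ep_rows) + 1L]] <- data.frame(
        run = run, episode = ep, green_onset = green_onset,
        red_onset = red_onset, cycle_onset = green_onset, cycle_end = cycle_end)
      obj_rows[[length(obj_rows) + 1L]] <- data.frame(
        run = run, episode = ep, object_index = seq_len(d$objects_per_episode),
        object_id = ids, onset = onsets)
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        run = run, episode = ep,
        onset = c(green_onset, onsets, red_onset, fix_on, oe1_on, plan_on, exec_on, oe2_on),
        duration = c(d$boundary_duration, rep(d$object_duration, d$objects_per_episode),
                     d$boundary_duration, d$cross_fixation, d$odd_even,
                     d$timeline_planning, d$timeline_execution, d$odd_even),
        trial_type = c("green", rep("object", d$objects_per_episode), "red",
                       "cross_fixation", "odd_even_1", "timeline_planning",
                       "timeline_execution", "odd_even_2"),
        object_index = c(NA, seq_len(d$objects_per_episode), rep(NA, 6L)),
        object_id = c(NA, ids, rep(NA, 6L)))
      t_cursor <- cycle_end
    }
  }
  out <- list(episodes = do.call(rbind, ep_rows),
              objects = do.call(rbind, obj_rows),
              events = do.call(rbind, ev_rows),
              design = d)
  class(out) <- "tm_schedule"
  out
}

#' @export
print.tm_schedule <- function(x, ...) {
  cat(sprintf("tm_schedule: %d runs x %d episodes x %d objects (%d episodes total)\n",
              x$design$n_runs, x$design$episodes_per_run,
              x$design$objects_per_episode, nrow(x$episodes)))
  invisible(x)
}

# True object times of one episode, seconds from run start.
true_object_times <- function(schedule, run, episode) {
  o <- schedule$objects
  o$onset[o$run == run & o$episode == episode]
}

# Episode reference positions on the run timeline (midpoint of the stimulus
# period), used by the between-episode timeline test.
episode_positions <- function(schedule, run) {
  e <- schedule$episodes
  e <- e[e$run == run, ]
  (e$green_onset + e$red_onset + schedule$design$boundary_duration) / 2
}

# Run timeline bounds for the between-episode test: start of the run to the
# end of the last stimulus period.
run_bounds <- function(schedule, run) {
  e <- schedule$episodes
  e <- e[e$run == run, ]
  c(0, max(e$red_onset) + schedule$design$boundary_duration)
}
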