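#' Recognition-test sampling score
#'
#' Implements the per-participant sampling score for the recognition test:
#' from the set of items the participant selected (targets and lures mixed),
#' `sample_size` items are drawn without replacement and the number of
#' non-lures (targets) is counted; this is repeated `n_draws` times.
#'
#' @param selected_ids Items the participant clicked.
#' @param target_ids Items actually presented during the experiment.
#' @param lure_ids Items never presented.
#' @param n_draws Number of sampling repetitions (default 50).
#' @param sample_size Items per draw (default 5).
#' @param seed Integer seed.
#' @return Integer vector of length `n_draws`: hits per draw.
#' @export
score_recognition <- function(selected_ids, target_ids, lure_ids,
                              n_draws = 50L, sample_size = 5L, seed = 1L) {
  if (length(selected_ids) == 0L) stop("empty selection")
  if (length(intersect(target_ids, lure_ids)) > 0L)
    stop("target and lure sets overlap")
  set.seed(seed)
  is_target <- selected_ids %in% target_ids
  replace <- length(selected_ids) < sample_size
  vapply(seq_len(n_draws), function(i) {
    idx <- sample.int(length(selected_ids), sample_size, replace = replace)
    sum(is_target[idx])
  }, integer(1))
}

#' Object-association correctness
#'
#' Binary correctness per episode for the association test (selecting the
#' held-out fifth object of each episode), plus the run-level proportion.
#'
#' @param grouping_response Chosen object id per episode.
#' @param true_grouping Correct object id per episode.
#' @return List with `correct` (logical per episode) and `proportion`.
#' @export
score_association <- function(grouping_response, true_grouping) {
  if (length(grouping_response) != length(true_grouping))
    stop("response and truth must have equal length")
  correct <- grouping_response == true_grouping
  list(correct = correct, proportion = mean(correct))
}

#' Assemble the trial-level measure table
#'
#' One row per (participant, run, episode) holding every decomposition,
#' item-level, order, recognition, and association score together with the
#' covariates used by the model stage (true-pattern interval variability,
#' episode duration, sequence numbers, timeline-test time, strategy scores,
#' demographics). Episodes missing from a participant's responses yield a
#' flagged all-NA row rather than a silent drop.
#'
#' @param schedule A `tm_schedule`.
#' @param responses A `tm_responses` or a list of them (one per participant).
#' @param window_set Window rule for the between-episode measures mapped back
#'   to episodes (default `"fours"`).
#' @return data.frame of class `tm_measure_table`.
#' @export
build_measure_table <- function(schedule, responses, window_set = "fours") {
  if (inherits(responses, "tm_responses")) responses <- list(responses)
  d <- schedule$design
  rows <- list()
  for (resp in responses) {
    pid <- resp$participant
    rec_hits <- mean(score_recognition(resp$recognition$selected_ids,
                                       resp$recognition$target_ids,
                                       resp$recognition$lure_ids,
                                       seed = pid))
    meta <- resp$meta
    for (run in seq_len(d$n_runs)) {
      eps <- schedule$episodes[schedule$episodes$run == run, ]
      t2 <- resp$timeline2[resp$timeline2$run == run, ]
      t2 <- t2[match(eps$episode, t2$episode), ]
      pos_true <- episode_positions(schedule, run)
      rb <- run_bounds(schedule, run)
      have_t2 <- nrow(t2) == nrow(eps) && !anyNA(t2$placed_time)
      if (have_t2) {
        dec2 <- decompose_pattern(pos_true, t2$placed_time, bounds = rb)
        im2 <- item_measures(pos_true, t2$placed_time)
        o2 <- order_score(pos_true, t2$placed_time)$deviations
        w2 <- windowed_between_measures(pos_true, t2$placed_time,
                                        windows = window_set, bounds = rb)
        # map each episode to its window's decomposition
        win_of <- integer(nrow(eps))
        for (w in seq_len(nrow(w2))) win_of[w2$first[w]:w2$last[w]] <- w
      }
      iv2 <- stats::sd(diff(pos_true))
      assoc <- resp$association[resp$association$run == run, ]
      for (k in seq_along(eps$episode)) {
        ep <- eps$episode[k]
        tt <- true_object_times(schedule, run, ep)
        t1 <- resp$timeline1[resp$timeline1$run == run & resp$timeline1$episode == ep, ]
        flagged <- nrow(t1) != length(tt) || anyNA(t1$placed_time)
        base <- data.frame(
          participant = pid, run = run, episode = ep,
          run_number = run, episode_number = ep,
          episode_duration = eps$red_onset[k] + d$boundary_duration - eps$green_onset[k],
          first_last_duration = max(tt) - min(tt),
          interval_variability_p1 = stats::sd(diff(tt)),
          interval_variability_p2 = iv2,
          flagged = flagged)
        if (!flagged) {
          t1 <- t1[order(t1$object_index), ]
          bounds <- c(eps$green_onset[k], eps$red_onset[k] + d$boundary_duration)
          dec <- decompose_pattern(tt, t1$placed_time, bounds = bounds)
          im <- item_measures(tt, t1$placed_time)
          o1 <- order_score(tt, t1$placed_time, ids = t1$object_id)
          p1 <- data.frame(
            translation_p1 = dec$translation,
            translation_p1_abs = abs(dec$translation),
            scaling_p1 = dec$scaling,
            scaling_p1_compr = dec$scaling_compr,
            scaling_p1_exp = dec$scaling_exp,
            pattern_p1 = dec$pattern_score,
            degenerate_p1 = dec$degenerate,
            object_translation_p1 = mean(im$item_translation),
            object_scaling_p1 = mean(im$item_scaling),
            object_scaling_p1_compr = mean(im$item_scaling_compr),
            object_scaling_p1_exp = mean(im$item_scaling_exp),
            order_o1 = o1$mean_deviation)
        } else {
          p1 <- data.frame(translation_p1 = NA_real_, translation_p1_abs = NA_real_,
                           scaling_p1 = NA_real_, scaling_p1_compr = NA_real_,
                           scaling_p1_exp = NA_real_, pattern_p1 = NA_real_,
                           degenerate_p1 = NA, object_translation_p1 = NA_real_,
                           object_scaling_p1 = NA_real_, object_scaling_p1_compr = NA_real_,
                           object_scaling_p1_exp = NA_real_, order_o1 = NA_real_)
        }
        if (have_t2) {
          w <- win_of[k]
          p2 <- data.frame(
            translation_p2 = dec2$translation, scaling_p2 = dec2$scaling,
            scaling_p2_compr = dec2$scaling_compr, scaling_p2_exp = dec2$scaling_exp,
            pattern_p2 = dec2$pattern_score,
            translation_p2_w = w2$translation[w], scaling_p2_w = w2$scaling[w],
            pattern_p2_w = w2$pattern_score[w],
            episode_translation_p2 = im2$item_translation[k],
            episode_scaling_p2 = im2$item_scaling[k],
            episode_scaling_p2_compr = im2$item_scaling_compr[k],
            episode_scaling_p2_exp = im2$item_scaling_exp[k],
            order_o2 = o2[k])
        } else {
          p2 <- data.frame(translation_p2 = NA_real_, scaling_p2 = NA_real_,
                           scaling_p2_compr = NA_real_, scaling_p2_exp = NA_real_,
                           pattern_p2 = NA_real_, translation_p2_w = NA_real_,
                           scaling_p2_w = NA_real_, pattern_p2_w = NA_real_,
                           episode_translation_p2 = NA_real_,
                           episode_scaling_p2 = NA_real_,
                           episode_scaling_p2_compr = NA_real_,
                           episode_scaling_p2_exp = NA_real_, order_o2 = NA_real_)
        }
        a_k <- assoc$correct[assoc$episode == ep]
        extras <- data.frame(
          association_correct = if (length(a_k) == 1L) as.numeric(a_k) else NA_real_,
          recognition_score = rec_hits,
          timeline1_time = meta$timeline1_time,
          age = meta$age, sex = meta$sex, prior_fmri = meta$prior_fmri)
        strat <- meta[, grep("^strategy_", names(meta)), drop = FALSE]
        rows[[length(rows) + 1L]] <- cbind(base, p1, p2, extras, strat)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tm_measure_table", "data.frame")
  out
}
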