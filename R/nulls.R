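#' Empirical 2-Wasserstein distance
#'
#' Quantile-coupling 2-Wasserstein distance between two empirical
#' distributions. For equal sample sizes this is
#' `sqrt(mean((sort(a) - sort(b))^2))`; for unequal sizes the squared
#' distance is integrated over a uniform grid of `n * m` quantile cells
#' (exact for step quantile functions; capped at 10^4 cells for very large
#' samples).
#'
#' @param a,b Numeric samples.
#' @return The distance (same units as the data).
#' @export
wasserstein2 <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty sample")
  if (n == m) return(sqrt(mean((a - b)^2)))
  k <- min(n * m, 10000L)
  p <- (seq_len(k) - 0.5) / k
  qa <- a[ceiling(p * n)]
  qb <- b[ceiling(p * m)]
  sqrt(mean((qa - qb)^2))
}

# Maximum-likelihood generalized Pareto fit to exceedances (y > 0).
# Returns list(shape, scale) or NULL on failure.
fit_gpd <- function(y) {
  y <- y[y > 0]
  if (length(y) < 10L) return(NULL)
  nll <- function(par) {
    xi <- par[1]; sigma <- exp(par[2])
    if (abs(xi) < 1e-8) return(length(y) * log(sigma) + sum(y) / sigma)
    z <- 1 + xi * y / sigma
    if (any(z <= 0)) return(Inf)
    length(y) * log(sigma) + (1 + 1 / xi) * sum(log(z))
  }
  fit <- tryCatch(
    stats::optim(c(0.1, log(mean(y))), nll, method = "Nelder-Mead"),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  list(shape = fit$par[1], scale = exp(fit$par[2]))
}

pgpd_tail <- function(q, shape, scale) {
  if (abs(shape) < 1e-8) return(exp(-q / scale))
  z <- 1 + shape * q / scale
  if (z <= 0) return(if (shape < 0) 0 else 1)
  z^(-1 / shape)
}

#' Two-sample 2-Wasserstein test with bootstrap null and GPD tail refinement
#'
#' Tests whether two score distributions differ using the empirical
#' 2-Wasserstein distance. The null distribution is built by resampling both
#' groups (with replacement, at their original sizes) from the pooled sample.
#' When the observed distance exceeds the 90th percentile of the null, the
#' tail p-value is refined by a maximum-likelihood generalized Pareto fit to
#' the null exceedances over that percentile; otherwise (or when the fit
#' fails) the plain empirical p-value is reported.
#'
#' @param a,b Numeric samples of size >= 8 each.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @return Object of class `tm_w2_test`: list with `wasserstein2`, `p_value`,
#'   `n_bootstrap`, `gpd_used`, `gpd_failed`, `auc`, `optimal_cutpoint`.
#' @export
wasserstein2_test <- function(a, b, n_boot = 5000L, seed = 1L) {
  if (length(a) < 8L || length(b) < 8L) stop("samples of size >= 8 are required")
  set.seed(seed)
  obs <- wasserstein2(a, b)
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  null <- vapply(seq_len(n_boot), function(i) {
    wasserstein2(sample(pooled, n, replace = TRUE),
                 sample(pooled, m, replace = TRUE))
  }, numeric(1))
  p_emp <- (1 + sum(null >= obs)) / (n_boot + 1)
  thr <- stats::quantile(null, 0.9, names = FALSE)
  gpd_used <- FALSE; gpd_failed <- FALSE
  p <- p_emp
  if (obs > thr) {
    fit <- fit_gpd(null[null > thr] - thr)
    if (is.null(fit)) {
      gpd_failed <- TRUE
      warning("GPD tail fit failed; reporting empirical p-value")
    } else {
      p_exc <- mean(null > thr)
      p <- max(p_exc * pgpd_tail(obs - thr, fit$shape, fit$scale),
               1 / (n_boot + 1))
      gpd_used <- TRUE
    }
  }
  roc <- roc_cutpoint(a, b)
  out <- list(wasserstein2 = obs, p_value = p, empirical_p = p_emp,
              n_bootstrap = n_boot, gpd_used = gpd_used, gpd_failed = gpd_failed,
              auc = roc$auc, optimal_cutpoint = roc$cutpoint)
  class(out) <- "tm_w2_test"
  out
}

#' @export
print.tm_w2_test <- function(x, ...) {
  cat(sprintf("2-Wasserstein = %.4f, p = %.4g (%s), AUC = %.3f\n",
              x$wasserstein2, x$p_value,
              if (x$gpd_used) "GPD tail" else "empirical", x$auc))
  invisible(x)
}

#' ROC curve, AUC, and Youden-optimal cutpoint for two score distributions
#'
#' @param a Scores under the correct labeling (treated as the positive
#'   class).
#' @param b Scores under the shuffled labeling.
#' @return List with `auc` (orientation-free, always >= 0.5), `cutpoint`
#'   (Youden-index optimal threshold), `sensitivity`, `specificity` at the
#'   cutpoint, and the full `curve` data.frame.
#' @export
roc_cutpoint <- function(a, b) {
  response <- c(rep(1L, length(a)), rep(0L, length(b)))
  r <- pROC::roc(response, c(a, b), quiet = TRUE, direction = "auto")
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  best <- best[1, , drop = FALSE]  # ties: first optimal threshold
  curve <- pROC::coords(r, "all", transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)),
       cutpoint = best$threshold,
       sensitivity = best$sensitivity,
       specificity = best$specificity,
       curve = curve)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control across a family of p-values.
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Correctly-labeled vs shuffled distribution pair for one measure
#'
#' Builds the two per-participant score distributions used by the separation
#' tests. The labeled distribution scores each response against its own true
#' pattern; the shuffled distribution is measure-specific:
#' * timing measures within episodes (`pattern_p1`, `translation_p1`,
#'   `scaling_p1`): each episode's response scored against every other
#'   episode's true pattern (47 comparisons per episode), averaged per
#'   participant;
#' * timing measures between episodes (`pattern_p2`, `translation_p2`,
#'   `scaling_p2`): each run's placements scored against the other runs'
#'   true patterns;
#' * order measures (`order_o1`, `order_o2`): random rank sequences scored
#'   against ordered sequences, 5000 repeats;
#' * `recognition`: labeled = the 50-draw sampling score per participant;
#'   shuffled = 5000 draws of 5 from the full encountered pool (targets and
#'   lures), counting targets;
#' * `association`: shuffled = random permutations of the 16 episode choices,
#'   5000 repeats.
#'
#' @param measure Measure name (see above).
#' @param schedule A `tm_schedule`.
#' @param responses A `tm_responses` or list of them.
#' @param n_shuffle Repeats for the order/recognition/association shuffles.
#' @param seed Integer seed for the shuffle draws.
#' @return Object of class `tm_distribution_pair`: list with `labeled`,
#'   `shuffled`, `measure_name`.
#' @export
build_pair <- function(measure, schedule, responses, n_shuffle = 5000L, seed = 1L) {
  if (inherits(responses, "tm_responses")) responses <- list(responses)
  d <- schedule$design
  set.seed(seed)
  timing_p1 <- c("pattern_p1", "translation_p1", "scaling_p1")
  timing_p2 <- c("pattern_p2", "translation_p2", "scaling_p2")
  pick <- function(dec, measure) {
    switch(sub("_p[12]$", "", measure),
           pattern = dec$pattern_score,
           translation = abs(dec$translation),
           scaling = dec$scaling)
  }
  if (measure %in% timing_p1) {
    # every pattern expressed relative to its own episode's green onset, so
    # responses can be compared against the 47 other episodes' true patterns
    eps_all <- schedule$episodes
    true_rel <- lapply(seq_len(nrow(eps_all)), function(k) {
      true_object_times(schedule, eps_all$run[k], eps_all$episode[k]) -
        eps_all$green_onset[k]
    })
    key <- function(resp) {
      resp_rel <- lapply(seq_len(nrow(eps_all)), function(k) {
        t1 <- resp$timeline1[resp$timeline1$run == eps_all$run[k] &
                               resp$timeline1$episode == eps_all$episode[k], ]
        t1 <- t1[order(t1$object_index), ]
        t1$placed_time - eps_all$green_onset[k]
      })
      lab <- vapply(seq_along(true_rel), function(k)
        pick(decompose_pattern(true_rel[[k]], resp_rel[[k]]), measure), numeric(1))
      shuf <- unlist(lapply(seq_along(true_rel), function(k) {
        vapply(setdiff(seq_along(true_rel), k), function(j)
          pick(decompose_pattern(true_rel[[j]], resp_rel[[k]]), measure), numeric(1))
      }))
      c(mean(lab, na.rm = TRUE), mean(shuf, na.rm = TRUE))
    }
    ms <- vapply(responses, key, numeric(2))
    labeled <- ms[1, ]; shuffled <- ms[2, ]
  } else if (measure %in% timing_p2) {
    # runs all start at zero, so run patterns are directly comparable
    labeled <- c(); shuffled <- c()
    for (resp in responses) {
      lab <- c(); shuf <- c()
      for (run in seq_len(d$n_runs)) {
        pos <- episode_positions(schedule, run)
        t2 <- resp$timeline2[resp$timeline2$run == run, ]
        lab <- c(lab, pick(decompose_pattern(pos, t2$placed_time), measure))
        for (other in setdiff(seq_len(d$n_runs), run)) {
          pos_o <- episode_positions(schedule, other)
          shuf <- c(shuf, pick(decompose_pattern(pos_o, t2$placed_time), measure))
        }
      }
      labeled <- c(labeled, mean(lab, na.rm = TRUE))
      shuffled <- c(shuffled, mean(shuf, na.rm = TRUE))
    }
  } else if (measure %in% c("order_o1", "order_o2")) {
    n_items <- if (measure == "order_o1") d$objects_per_episode else d$episodes_per_run
    labeled <- vapply(responses, function(resp) {
      if (measure == "order_o1") {
        devs <- by(resp$timeline1, list(resp$timeline1$run, resp$timeline1$episode),
                   function(df) order_score(df$true_time, df$placed_time)$mean_deviation)
        mean(unlist(devs))
      } else {
        devs <- by(resp$timeline2, resp$timeline2$run,
                   function(df) order_score(df$true_time, df$placed_time)$mean_deviation)
        mean(unlist(devs))
      }
    }, numeric(1))
    shuffled <- vapply(seq_len(n_shuffle), function(i) {
      mean(abs(sample.int(n_items) - seq_len(n_items)))
    }, numeric(1))
  } else if (measure == "recognition") {
    labeled <- vapply(seq_along(responses), function(i) {
      r <- responses[[i]]$recognition
      mean(score_recognition(r$selected_ids, r$target_ids, r$lure_ids, seed = i))
    }, numeric(1))
    pool_targets <- responses[[1]]$recognition$target_ids
    pool <- c(pool_targets, responses[[1]]$recognition$lure_ids)
    shuffled <- vapply(seq_len(n_shuffle), function(i) {
      sum(sample(pool, 5L) %in% pool_targets)
    }, numeric(1))
  } else if (measure == "association") {
    labeled <- vapply(responses, function(resp) mean(resp$association$correct),
                      numeric(1))
    n_ep <- d$episodes_per_run
    shuffled <- vapply(seq_len(n_shuffle), function(i) {
      mean(sample.int(n_ep) == seq_len(n_ep))
    }, numeric(1))
  } else {
    stop("unknown measure: ", measure)
  }
  out <- list(labeled = as.numeric(labeled), shuffled = as.numeric(shuffled),
              measure_name = measure)
  if (measure %in% timing_p1)
    out$n_shuffle_comparisons_per_episode <- nrow(schedule$episodes) - 1L
  class(out) <- "tm_distribution_pair"
  out
}
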