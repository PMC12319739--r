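#' Translation / scaling / pattern decomposition of a timeline response
#'
#' Decomposes a participant's placed times against the true presentation
#' times of the same items in three steps. Step 1 translates the recalled
#' pattern so its centroid matches the true centroid (the RMSD-optimal 1-D
#' translation); the reported translation is the inverse of the applied
#' shift, i.e. `mean(recalled) - mean(true)` (signed seconds). Step 2 finds
#' the least-squares scale `s*` mapping the centered recalled pattern onto
#' the centered true pattern; the reported scaling is `1 / s*`, so values
#' below 1 mean the participant's pattern is tighter than truth (compression
#' in memory) and above 1 expansion. Step 3 measures each aligned recalled
#' position against the closest true position (ties broken toward the
#' earlier true position), squares, sums, and negates: the temporal pattern
#' score (0 is perfect, more negative is worse).
#'
#' Correspondence for the translation and scale fit is by item identity (the
#' timeline test is drag-and-drop); only the residual uses closest-position
#' matching.
#'
#' @param true_times,recalled_times Numeric vectors of equal length >= 2,
#'   matched by item identity.
#' @param bounds Optional timeline bounds (length-2 numeric); when supplied,
#'   all times must fall within them.
#' @return Object of class `tm_decomposition`: list with `translation`,
#'   `scaling`, `scaling_compr` (`max(0, 1 - scaling)`), `scaling_exp`
#'   (`max(0, scaling - 1)`), `pattern_score`, `aligned` (the translated and
#'   scaled recalled pattern), `residuals`, and `degenerate` (TRUE when the
#'   recalled pattern has no spread or the fitted scale is non-positive; the
#'   scaling is then NA and residuals are computed at scale 1).
#' @export
decompose_pattern <- function(true_times, recalled_times, bounds = NULL) {
  n <- length(true_times)
  if (length(recalled_times) != n) stop("true and recalled patterns must have equal length")
  if (n < 2L) stop("at least two items are required")
  if (anyNA(true_times) || anyNA(recalled_times)) stop("missing times are not allowed")
  if (!is.null(bounds)) {
    if (any(true_times < bounds[1] - 1e-9) || any(true_times > bounds[2] + 1e-9) ||
        any(recalled_times < bounds[1] - 1e-9) || any(recalled_times > bounds[2] + 1e-9))
      stop("times fall outside the timeline bounds")
  }
  mu_t <- mean(true_times)
  mu_r <- mean(recalled_times)
  translation <- mu_r - mu_t
  c_t <- true_times - mu_t
  c_r <- recalled_times - mu_r
  ss_r <- sum(c_r^2)
  degenerate <- FALSE
  if (ss_r < 1e-12) {
    s_star <- 1
    degenerate <- TRUE
  } else {
    s_star <- sum(c_t * c_r) / ss_r
    if (s_star <= 0) {
      s_star <- 1
      degenerate <- TRUE
    }
  }
  aligned <- mu_t + s_star * c_r
  res <- vapply(aligned, function(a) {
    dists <- abs(true_times - a)
    a - true_times[which.min(dists)]  # which.min ties -> earlier true position
  }, numeric(1))
  scaling <- if (degenerate) NA_real_ else 1 / s_star
  out <- list(
    translation = translation,
    scaling = scaling,
    scaling_compr = if (is.na(scaling)) NA_real_ else max(0, 1 - scaling),
    scaling_exp = if (is.na(scaling)) NA_real_ else max(0, scaling - 1),
    pattern_score = -sum(res^2),
    aligned = aligned,
    residuals = res,
    degenerate = degenerate
  )
  class(out) <- "tm_decomposition"
  out
}

#' @export
print.tm_decomposition <- function(x, ...) {
  cat(sprintf("tm_decomposition: translation %.3f s, scaling %.3f, pattern score %.4f%s\n",
              x$translation, x$scaling, x$pattern_score,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Item-level translation and local scaling measures
#'
#' For each item, the absolute deviation between its placed and true time
#' (item translation), and the ratio of the smallest gap from its placed
#' time to its temporal neighbors in the recalled pattern over the
#' same-defined smallest gap in the true pattern (item scaling; < 1 local
#' compression, > 1 local expansion). Neighbors are the adjacent items in
#' each pattern's own temporal order.
#'
#' @inheritParams decompose_pattern
#' @return data.frame with one row per item: `item_translation`,
#'   `item_scaling`, `item_scaling_compr`, `item_scaling_exp`.
#' @export
item_measures <- function(true_times, recalled_times) {
  n <- length(true_times)
  if (length(recalled_times) != n) stop("true and recalled patterns must have equal length")
  if (n < 2L) stop("item scaling requires at least two items (neighbors undefined)")
  min_gap <- function(times) {
    ord <- order(times)
    pos <- integer(n); pos[ord] <- seq_len(n)  # rank of each item in its own pattern
    sorted <- times[ord]
    vapply(seq_len(n), function(i) {
      k <- pos[i]
      gaps <- c(if (k > 1L) sorted[k] - sorted[k - 1L],
                if (k < n) sorted[k + 1L] - sorted[k])
      min(gaps)
    }, numeric(1))
  }
  g_true <- min_gap(true_times)
  g_rec <- min_gap(recalled_times)
  sc <- g_rec / g_true
  data.frame(
    item_translation = abs(recalled_times - true_times),
    item_scaling = sc,
    item_scaling_compr = pmax(0, 1 - sc),
    item_scaling_exp = pmax(0, sc - 1)
  )
}

#' Order score: rank deviation per item
#'
#' Ranks are obtained by sorting placed times (ties broken by placement
#' order); the deviation for each item is the absolute difference between
#' its recalled and true sequence position. An item presented third but
#' placed first scores 2. The aggregate is the mean deviation over items
#' (0 = perfect order).
#'
#' @inheritParams decompose_pattern
#' @param ids Optional item identifiers; duplicated ids are an error.
#' @return List with `deviations` (per item, in presentation order) and
#'   `mean_deviation`.
#' @export
order_score <- function(true_times, recalled_times, ids = seq_along(true_times)) {
  n <- length(true_times)
  if (length(recalled_times) != n) stop("true and recalled patterns must have equal length")
  if (anyDuplicated(ids)) stop("duplicate item ids")
  true_rank <- rank(true_times, ties.method = "first")
  rec_rank <- rank(recalled_times, ties.method = "first")
  dev <- abs(rec_rank - true_rank)
  list(deviations = dev, mean_deviation = mean(dev))
}

#' Windowed between-episode decompositions
#'
#' Applies [decompose_pattern()] to sub-patterns of the 16 episode placements
#' in a run: fixed four-episode windows (1-4, 5-8, 9-12, 13-16), the
#' five-episode variants (1-5, 6-10, 12-16), or expanding windows (1-5, 1-6,
#' ..., 1-16). A custom list of index vectors is also accepted.
#'
#' @param run_true,run_recalled Episode positions and placements for one run,
#'   in presentation order.
#' @param windows `"fours"`, `"fives"`, `"expanding"`, or a list of integer
#'   index vectors.
#' @param bounds Optional run timeline bounds.
#' @return data.frame with one row per window: `window`, `first`, `last`,
#'   `translation`, `scaling`, `scaling_compr`, `scaling_exp`,
#'   `pattern_score`.
#' @export
windowed_between_measures <- function(run_true, run_recalled, windows = "fours",
                                      bounds = NULL) {
  n <- length(run_true)
  if (length(run_recalled) != n) stop("true and recalled patterns must have equal length")
  win_list <- if (is.list(windows)) {
    windows
  } else {
    switch(match.arg(windows, c("fours", "fives", "expanding")),
           fours = lapply(seq(1L, n, by = 4L), function(s) s:min(s + 3L, n)),
           fives = list(1:5, 6:10, 12:16),
           expanding = lapply(5:n, function(e) 1:e))
  }
  rows <- lapply(seq_along(win_list), function(w) {
    idx <- win_list[[w]]
    if (any(idx < 1L) || any(idx > n)) stop("window index outside 1..", n)
    dec <- decompose_pattern(run_true[idx], run_recalled[idx], bounds = bounds)
    data.frame(window = w, first = min(idx), last = max(idx),
               translation = dec$translation, scaling = dec$scaling,
               scaling_compr = dec$scaling_compr, scaling_exp = dec$scaling_exp,
               pattern_score = dec$pattern_score)
  })
  do.call(rbind, rows)
}
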