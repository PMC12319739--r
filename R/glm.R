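#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention canonical HRF: a positive gamma density peaking at 6 s
#' minus an undershoot gamma peaking at 16 s with ratio 1/6, sampled on a
#' fine time grid over 32 s and normalized to unit peak.
#'
#' @param dt Sampling step (seconds).
#' @param duration Kernel length (seconds).
#' @param peak_delay,undershoot_delay Gamma shape parameters (dispersion 1).
#' @param undershoot_ratio Undershoot amplitude relative to the peak.
#' @return List with `t` (time grid) and `values` (unit-peak kernel).
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h <- h / max(h)
  list(t = t, values = h)
}

# Convolve a set of boxcar events with the canonical HRF and sample at the
# frame times (all within one run; times in seconds from run start).
convolve_events <- function(onsets, durations, frame_times, dt = 0.1) {
  t_max <- max(frame_times) + dt
  grid <- seq(0, t_max, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    idx <- which(grid >= onsets[i] & grid < onsets[i] + durations[i])
    box[idx] <- 1
  }
  h <- canonical_hrf(dt = dt)$values
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  stats::approx(grid, conv, xout = frame_times, rule = 2)$y
}

#' Build a first-level design matrix
#'
#' Two variants of the event model. Variant `"one"` (object level): one
#' regressor per object event, plus one regressor each for the
#' cross-fixation period, the odd-even task following it, the timeline-test
#' planning period, and the timeline-test execution period, plus an
#' intercept. For the full default experiment (3 runs x 16 episodes x 5
#' objects) this gives 245 columns. Variant `"two"` (episode level): one
#' regressor per episode for each of the five modeled periods (stimulus,
#' cross-fixation, odd-even, planning, execution) plus an intercept: 241
#' columns for the full experiment. The odd-even period after the timeline
#' test is left unmodeled as an implicit baseline. All events are boxcars of
#' their stated durations convolved with the canonical HRF; runs are
#' concatenated along the time axis.
#'
#' @param events Events data.frame (`run`, `episode`, `onset`, `duration`,
#'   `trial_type`, `object_id`), e.g. `schedule$events`.
#' @param variant `"one"` or `"two"`.
#' @param tr Repetition time (seconds).
#' @param n_frames Optional integer vector of frames per run; defaults to
#'   covering the last event plus 20 s.
#' @return Object of class `tm_design_matrix`: list with `X` (frames x
#'   regressors), `frame_times`, `frame_run`, `columns` (metadata
#'   data.frame), `variant`, `tr`.
#' @export
build_design <- function(events, variant = c("one", "two"), tr = 2.57,
                         n_frames = NULL) {
  variant <- match.arg(variant)
  runs <- sort(unique(events$run))
  if (is.null(n_frames)) {
    n_frames <- vapply(runs, function(r) {
      e <- events[events$run == r, ]
      as.integer(ceiling((max(e$onset + e$duration) + 20) / tr))
    }, integer(1))
  }
  stopifnot(length(n_frames) == length(runs))

  # column specs: list of (name, run, rows of events to pool)
  specs <- list()
  add_spec <- function(name, run, ev) {
    if (nrow(ev) == 0L) return(invisible(NULL))
    ev <- ev[order(ev$run, ev$onset), ]
    for (r in unique(ev$run)) {
      er <- ev[ev$run == r, ]
      ends <- er$onset + er$duration
      if (nrow(er) > 1L && any(er$onset[-1] < ends[-nrow(er)] - 1e-9))
        stop("overlapping events within regressor ", name)
    }
    specs[[length(specs) + 1L]] <<- list(name = name, run = run, events = ev)
  }
  if (variant == "one") {
    obj <- events[events$trial_type == "object", ]
    for (i in seq_len(nrow(obj)))
      add_spec(paste0("object_", obj$object_id[i]), obj$run[i], obj[i, ])
    for (tt in c("cross_fixation", "odd_even_1", "timeline_planning",
                 "timeline_execution"))
      add_spec(tt, NA, events[events$trial_type == tt, ])
  } else {
    for (r in runs) {
      er <- events[events$run == r, ]
      for (ep in sort(unique(er$episode))) {
        ee <- er[er$episode == ep, ]
        stim <- ee[ee$trial_type %in% c("green", "object", "red"), ]
        stim_box <- data.frame(run = r, onset = min(stim$onset),
                               duration = max(stim$onset + stim$duration) - min(stim$onset))
        add_spec(sprintf("stimulus_r%d_e%d", r, ep), r, stim_box)
        for (tt in c("cross_fixation", "odd_even_1", "timeline_planning",
                     "timeline_execution"))
          add_spec(sprintf("%s_r%d_e%d", tt, r, ep), r, ee[ee$trial_type == tt, ])
      }
    }
  }

  frame_times_run <- lapply(seq_along(runs), function(i) (seq_len(n_frames[i]) - 1) * tr)
  total_frames <- sum(n_frames)
  X <- matrix(0, total_frames, length(specs))
  colnames(X) <- vapply(specs, `[[`, character(1), "name")
  offsets <- c(0L, cumsum(n_frames))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    target_runs <- if (is.na(sp$run)) runs else sp$run
    for (r in target_runs) {
      i <- match(r, runs)
      ev <- sp$events[sp$events$run == r, , drop = FALSE]
      if (nrow(ev) == 0L) next
      rows <- offsets[i] + seq_len(n_frames[i])
      X[rows, j] <- convolve_events(ev$onset, ev$duration, frame_times_run[[i]])
    }
  }
  X <- cbind(X, intercept = 1)
  columns <- data.frame(
    name = colnames(X),
    type = c(vapply(specs, function(s) sub("_(r[0-9]+_e[0-9]+|[0-9]+)$", "", s$name),
                    character(1)), "intercept"))
  out <- list(X = X,
              frame_times = unlist(frame_times_run),
              frame_run = rep(runs, n_frames),
              columns = columns, variant = variant, tr = tr)
  class(out) <- "tm_design_matrix"
  out
}

#' @export
print.tm_design_matrix <- function(x, ...) {
  cat(sprintf("tm_design_matrix (model %s): %d frames x %d regressors\n",
              x$variant, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' DVARS and motion-outlier flags
#'
#' DVARS at frame t is the root mean square over voxels of the frame-to-
#' frame signal difference (0 for the first frame). Frames are flagged as
#' outliers when their DVARS exceeds the box-plot fence (75th percentile +
#' 1.5 IQR) of the non-zero DVARS values.
#'
#' @param series Numeric matrix, frames x voxels.
#' @return List with `dvars` (per frame), `flags` (logical per frame), and
#'   `spike_regressors` (frames x n_flagged 0/1 matrix, one impulse column
#'   per flagged frame; NULL when none).
#' @export
compute_dvars <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2L) stop("need at least two frames")
  diffs <- series[-1, , drop = FALSE] - series[-n, , drop = FALSE]
  dvars <- c(0, sqrt(rowMeans(diffs^2)))
  vals <- dvars[-1]
  fence <- stats::quantile(vals, 0.75, names = FALSE) + 1.5 * stats::IQR(vals)
  flags <- dvars > fence
  spikes <- NULL
  if (any(flags)) {
    spikes <- matrix(0, n, sum(flags))
    spikes[cbind(which(flags), seq_len(sum(flags)))] <- 1
    colnames(spikes) <- paste0("dvars_spike_", which(flags))
  }
  list(dvars = dvars, flags = flags, spike_regressors = spikes)
}

#' Fit a voxel-wise GLM by ordinary least squares
#'
#' @param series Numeric matrix, frames x voxels.
#' @param design A `tm_design_matrix` or a plain design matrix.
#' @param extra_regressors Optional matrix of nuisance columns (e.g. DVARS
#'   spike regressors) appended to the design.
#' @return Object of class `tm_glm`: list with `betas` (regressors x
#'   voxels), `residuals` (frames x voxels), `design_columns`, `df_residual`.
#' @export
fit_glm <- function(series, design, extra_regressors = NULL) {
  X <- if (inherits(design, "tm_design_matrix")) design$X else as.matrix(design)
  if (!is.null(extra_regressors)) X <- cbind(X, extra_regressors)
  Y <- as.matrix(series)
  if (nrow(Y) != nrow(X)) stop("series and design have different frame counts")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  betas <- qr.coef(qr_x, Y)
  resid <- Y - X %*% betas
  out <- list(betas = betas, residuals = resid,
              design_columns = colnames(X),
              df_residual = nrow(X) - ncol(X))
  class(out) <- "tm_glm"
  out
}
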