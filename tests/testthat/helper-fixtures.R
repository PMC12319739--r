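# Small builders shared across test files.

tiny_design <- function(seed = 1L, n_runs = 1L, episodes_per_run = 4L) {
  experiment_design(n_runs = n_runs, episodes_per_run = episodes_per_run,
                    cross_fixation = 3, odd_even = 3,
                    timeline_planning = 2, timeline_execution = 4,
                    rng_seed = seed)
}

# Brute-force oracle: grid search over intercept/slope minimizing the RMSD
# of a + b * recalled against true (identity correspondence), refined to the
# requested resolution by repeated zooming.
grid_fit_oracle <- function(true_times, recalled_times, resolution = 1e-4) {
  b_range <- c(0.05, 8)
  a_range <- range(true_times) - mean(range(recalled_times)) * mean(b_range)
  a_range <- c(min(true_times) - max(recalled_times) * b_range[2],
               max(true_times) + max(abs(recalled_times)) * b_range[2])
  best <- c(a = NA, b = NA)
  for (round in 1:9) {
    a_grid <- seq(a_range[1], a_range[2], length.out = 61)
    b_grid <- seq(b_range[1], b_range[2], length.out = 61)
    rss <- outer(a_grid, b_grid, Vectorize(function(a, b)
      sum((a + b * recalled_times - true_times)^2)))
    idx <- arrayInd(which.min(rss), dim(rss))
    best <- c(a = a_grid[idx[1]], b = b_grid[idx[2]])
    a_step <- diff(a_grid[1:2]); b_step <- diff(b_grid[1:2])
    if (a_step < resolution && b_step < resolution) break
    a_range <- best[1] + c(-4, 4) * a_step
    b_range <- pmax(best[2] + c(-4, 4) * b_step, 1e-3)
  }
  list(intercept = unname(best[1]), slope = unname(best[2]),
       rmsd = sqrt(mean((best[1] + best[2] * recalled_times - true_times)^2)))
}

random_pattern <- function(n = 5L, span = 12) sort(stats::runif(n, 0, span))
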