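test_that("the canonical HRF has the expected shape", {
  h <- canonical_hrf()
  expect_equal(max(h$values), 1)
  peak_t <- h$t[which.max(h$values)]
  expect_gte(peak_t, 4.5)
  expect_lte(peak_t, 6.5)
  expect_lt(min(h$values), 0)             # undershoot
  expect_lt(abs(h$values[length(h$values)]), 0.01)  # decays by 32 s
})

test_that("design matrices have the prescribed regressor counts", {
  sch <- generate_schedule(experiment_design(rng_seed = 60))
  d1 <- build_design(sch$events, "one")
  expect_equal(ncol(d1$X), 245L)
  d2 <- build_design(sch$events, "two")
  expect_equal(ncol(d2$X), 241L)
  # single-episode toy: 1 intercept + 5 objects + 4 period regressors
  toy <- generate_schedule(tiny_design(seed = 61, episodes_per_run = 1L))
  dt <- build_design(toy$events, "one")
  expect_equal(ncol(dt$X), 10L)
  # two episodes whose cross-fixation periods collide within one regressor
  toy2 <- generate_schedule(tiny_design(seed = 61, episodes_per_run = 2L))
  ev <- toy2$events
  cf <- which(ev$trial_type == "cross_fixation")
  ev$onset[cf[2]] <- ev$onset[cf[1]]
  expect_error(build_design(ev, "one"), "overlapping")
})

test_that("DVARS flags exactly the displaced frames", {
  const <- matrix(5, 30, 12)
  r <- compute_dvars(const)
  expect_equal(r$dvars, rep(0, 30))
  expect_false(any(r$flags))
  expect_null(r$spike_regressors)

  set.seed(62)
  series <- matrix(rnorm(50 * 20), 50, 20)
  series[25:50, ] <- series[25:50, ] + 10  # sustained displacement at frame 25
  r2 <- compute_dvars(series)
  expect_true(r2$flags[25])
  expect_equal(sum(r2$flags), 1L)
  expect_equal(dim(r2$spike_regressors), c(50L, 1L))
  expect_equal(which(r2$spike_regressors[, 1] == 1), 25L)

  # 3-frame toy against the hand-computed root mean square
  toy <- rbind(c(0, 0), c(3, 4), c(3, 4))
  r3 <- compute_dvars(toy)
  expect_equal(r3$dvars, c(0, sqrt((9 + 16) / 2), 0))
})

test_that("planted motion spikes are recovered by the DVARS rule", {
  sch <- generate_schedule(tiny_design(seed = 63))
  resp <- simulate_responses(sch, participant_model(rng_seed = 64))
  sim <- simulate_bold(sch, resp,
                       bold_sim_spec(grid_shape = c(6L, 6L, 6L),
                                     n_motion_spikes = 3L, rng_seed = 65))
  r <- compute_dvars(sim$bold)
  expect_equal(which(r$flags), sim$truth$spike_frames)
})

test_that("OLS recovers noiseless betas and orthogonal residuals", {
  set.seed(66)
  X <- cbind(1, matrix(rnorm(60 * 4), 60, 4))
  colnames(X) <- c("intercept", paste0("r", 1:4))
  B <- matrix(rnorm(5 * 7), 5, 7)
  Y <- X %*% B
  g <- fit_glm(Y, X)
  expect_equal(g$betas, B, ignore_attr = TRUE)
  expect_lt(max(abs(g$residuals)), 1e-9)

  Yn <- Y + matrix(rnorm(60 * 7, 0, 0.5), 60, 7)
  gn <- fit_glm(Yn, X)
  expect_lt(max(abs(crossprod(X, gn$residuals))), 1e-8)

  Xbad <- cbind(X, dup = X[, 2])
  expect_error(fit_glm(Y, Xbad), "dup")
})

test_that("beta recovery error grows with the noise level", {
  set.seed(67)
  sch <- generate_schedule(tiny_design(seed = 68, episodes_per_run = 8L))
  resp <- simulate_responses(sch, participant_model(rng_seed = 69))
  err_at <- vapply(c(0.1, 0.5, 2), function(ns) {
    sim <- simulate_bold(sch, resp,
                         bold_sim_spec(grid_shape = c(6L, 6L, 6L), noise_sd = ns,
                                       amplitude = 5, ar1_coef = 0,
                                       rng_seed = 70))
    des <- build_design(sch$events, "one", n_frames = sim$n_frames)
    g <- fit_glm(sim$bold, des)
    obj <- grep("^object_", rownames(g$betas))
    ids <- as.integer(sub("^object_", "", rownames(g$betas)[obj]))
    truth_order <- match(ids, sch$objects$object_id)
    sqrt(mean((g$betas[obj, ] - sim$truth$amplitudes[truth_order, ])^2))
  }, numeric(1))
  expect_true(all(diff(err_at) > 0))
})
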