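make_lmm_data <- function(n_part = 30, n_trial = 20, beta = 0.5, u_sd = 1,
                          e_sd = 1, seed = 1) {
  set.seed(seed)
  pid <- rep(seq_len(n_part), each = n_trial)
  u <- rnorm(n_part, 0, u_sd)[pid]
  x <- rnorm(n_part * n_trial)
  data.frame(participant = pid, x = x, y = beta * x + u + rnorm(n_part * n_trial, 0, e_sd))
}

test_that("fit_lmm recovers planted fixed and random effects", {
  dat <- make_lmm_data(beta = 0.5, seed = 10)
  fit <- fit_lmm(dat, "y", "x")
  b <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(b$estimate - 0.5), 3 * b$se)
  expect_lt(b$p, 1e-6)
  expect_equal(fit$n_dropped, 0L)

  # pure random-intercept data: slope near zero, intercept variance recovered
  dat0 <- make_lmm_data(beta = 0, u_sd = 2, e_sd = 0.5, seed = 11)
  fit0 <- fit_lmm(dat0, "y", "x")
  b0 <- fit0$coefficients[fit0$coefficients$term == "x", ]
  expect_lt(abs(b0$estimate), 3 * b0$se)
  vc <- as.data.frame(lme4::VarCorr(fit0$fit))
  expect_equal(vc$sdcor[vc$grp == "participant"], 2, tolerance = 0.4)
})

test_that("a deterministic response gives slope one and the singular flag", {
  dat <- make_lmm_data(seed = 12)
  dat$y <- dat$x
  fit <- fit_lmm(dat, "y", "x")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 1,
               tolerance = 1e-6)
  expect_true(fit$singular)  # zero residual + zero intercept variance
  expect_error(fit_lmm(dat, "y", "y"), "response cannot appear")
  expect_error(fit_lmm(dat, "y", "nope"), "unknown columns")
})

test_that("missing rows are dropped with a count, never silently", {
  dat <- make_lmm_data(seed = 13)
  dat$x[c(3, 50, 101)] <- NA
  fit <- fit_lmm(dat, "y", "x")
  expect_equal(fit$n_dropped, 3L)
  expect_equal(fit$n_used, nrow(dat) - 3L)
})

test_that("forward AIC selection finds the true predictor among noise", {
  set.seed(14)
  dat <- make_lmm_data(beta = 0.6, seed = 14)
  for (k in 1:5) dat[[paste0("junk", k)]] <- rnorm(nrow(dat))
  sel <- stepwise_aic(dat, "y", c("x", paste0("junk", 1:5)))
  expect_true("x" %in% sel$selected)
  expect_lte(length(sel$selected), 3L)
  expect_equal(sel$path$term[2], "x")  # strongest term enters first
  # deterministic given the data
  sel2 <- stepwise_aic(dat, "y", c("x", paste0("junk", 1:5)))
  expect_identical(sel$selected, sel2$selected)
  # empty candidate pool: intercept-only model
  sel0 <- stepwise_aic(dat, "y", character(0))
  expect_equal(length(sel0$selected), 0L)
})

test_that("quadratic candidates capture a planted nonlinear relationship", {
  set.seed(15)
  dat <- make_lmm_data(beta = 0, seed = 15)
  dat$y <- dat$y + 0.8 * scale(dat$x, scale = FALSE)^2
  sel <- stepwise_aic(dat, "y", candidates = "x", quadratic_candidates = "x")
  expect_true(any(grepl("quadratic", sel$path$term)))
})

test_that("VIFs match the regression R-squared oracle", {
  set.seed(16)
  x1 <- rnorm(200); x2 <- rnorm(200); x3 <- 0.7 * x1 + 0.5 * x2 + rnorm(200, 0, 0.4)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_terms(X)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-8)
  expect_true(all(v >= 1))

  # orthogonal (mean-centered) predictors: VIF 1
  q <- qr.Q(qr(scale(matrix(rnorm(300), 100, 3), scale = FALSE)))
  expect_equal(unname(vif_terms(q)), rep(1, 3), tolerance = 1e-6)
  # near-duplicate predictor: VIF explodes
  x2b <- x1 + rnorm(200, 0, 0.01)
  expect_gt(vif_terms(cbind(a = x1, b = x2b))[["a"]], 100)
})

test_that("mediation recovers a planted indirect effect and gates null paths", {
  set.seed(17)
  n_part <- 40; n_trial <- 30
  pid <- rep(seq_len(n_part), each = n_trial)
  tr <- rnorm(n_part * n_trial)
  med <- 0.6 * tr + rnorm(n_part, 0, 0.3)[pid] + rnorm(n_part * n_trial, 0, 0.5)
  out <- 0.5 * med + rnorm(n_part, 0, 0.3)[pid] + rnorm(n_part * n_trial, 0, 0.5)
  dat <- data.frame(participant = pid, tr = tr, med = med, out = out)
  m <- mediate_lmm(dat, "tr", "med", "out", n_draws = 2000, seed = 18)
  expect_true(m$assessed)
  expect_equal(m$acme, 0.3, tolerance = 0.05)
  expect_true(m$acme_ci[1] < m$acme & m$acme < m$acme_ci[2])
  expect_true(m$ade_ci[1] < 0 & 0 < m$ade_ci[2])  # no direct effect planted
  expect_gt(m$proportion_mediated, 0.8)

  # mediator unrelated to treatment: gated out, ACME interval straddles 0
  dat$med2 <- rnorm(nrow(dat))
  m0 <- mediate_lmm(dat, "tr", "med2", "out", n_draws = 1000, seed = 19)
  expect_false(m0$assessed)
  expect_true(m0$acme_ci[1] < 0 & 0 < m0$acme_ci[2])
})

test_that("mediation interval width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n_part, seed) {
    set.seed(seed)
    n_trial <- 20
    pid <- rep(seq_len(n_part), each = n_trial)
    tr <- rnorm(n_part * n_trial)
    med <- 0.6 * tr + rnorm(n_part, 0, 0.2)[pid] + rnorm(n_part * n_trial, 0, 0.5)
    out <- 0.5 * med + rnorm(n_part, 0, 0.2)[pid] + rnorm(n_part * n_trial, 0, 0.5)
    dat <- data.frame(participant = pid, tr = tr, med = med, out = out)
    m <- mediate_lmm(dat, "tr", "med", "out", n_draws = 1000, seed = seed + 1)
    diff(m$acme_ci)
  }
  w_small <- mean(vapply(1:3, function(s) width_at(10, s), numeric(1)))
  w_large <- mean(vapply(1:3, function(s) width_at(90, s), numeric(1)))
  expect_equal(w_small / w_large, 3, tolerance = 0.8)
})

test_that("spearman matrix is exact on toys and monotone-invariant", {
  set.seed(20)
  x <- rnorm(25)
  df <- data.frame(participant = 1:25, a = x, b = exp(x), c = rnorm(25))
  sm <- spearman_matrix(df)
  expect_equal(diag(sm$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm$rho["a", "b"], 1)
  expect_true(isSymmetric(sm$q))
  # 5-point toy against the rank formula rho = 1 - 6 sum(d^2) / (n(n^2-1))
  u <- c(3.1, 0.2, 5.5, 2.2, 4.0)
  v <- c(2.0, 1.1, 4.9, 3.3, 0.7)
  d2 <- sum((rank(u) - rank(v))^2)
  sm2 <- spearman_matrix(data.frame(u = u, v = v))
  expect_equal(sm2$rho["u", "v"], 1 - 6 * d2 / (5 * 24))
})
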