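test_that("searchlights on a dense mask have 10 members within 10 mm", {
  mask <- array(TRUE, c(8L, 8L, 8L))
  sl <- build_searchlights(mask)
  expect_equal(length(sl$centers), 512L)
  expect_equal(length(sl$skipped), 0L)
  sizes <- vapply(sl$members, length, integer(1))
  expect_true(all(sizes == 10L))
  coords <- arrayInd(which(mask), dim(mask))
  for (s in c(1, 100, 300, 512)) {
    ctr <- arrayInd(sl$centers[s], dim(mask))
    mem <- coords[sl$members[[s]], , drop = FALSE]
    dmm <- 3 * sqrt(rowSums(sweep(mem, 2, as.integer(ctr))^2))
    expect_lte(max(dmm), 10)
    expect_true(any(dmm == 0))  # center belongs to its own searchlight
  }
})

test_that("too-small and too-sparse masks are rejected or reported", {
  small <- array(FALSE, c(4L, 4L, 4L))
  small[1:9] <- TRUE
  expect_error(build_searchlights(small), "fewer voxels")

  # a 1-voxel-thick line: interior voxels have < 10 in-mask neighbors in range
  line <- array(FALSE, c(30L, 3L, 3L))
  line[, 2L, 2L] <- TRUE
  sl <- build_searchlights(line)
  expect_gt(length(sl$skipped), 0L)
  expect_true(all(vapply(sl$members, length, integer(1)) == 10L))
})

test_that("prewhitening reduces to identity / per-voxel scaling when it should", {
  set.seed(80)
  n <- 60
  q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  # residuals with exactly identity sample covariance
  resid_id <- sqrt(n - 1) * sweep(q, 2, colMeans(q))  # still orthogonal-ish
  resid_id <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), scale = FALSE))) * sqrt(n - 1)
  betas <- matrix(rnorm(12), 3, 4)
  pw <- prewhiten(betas, resid_id)
  expect_equal(pw$whitened, betas, tolerance = 1e-6)

  # exactly diagonal covariance: whitening standardizes each voxel
  sds <- c(0.5, 2, 4, 1)
  resid_diag <- sweep(resid_id, 2, sds, `*`)
  pw2 <- prewhiten(betas, resid_diag)
  expect_equal(pw2$whitened, sweep(betas, 2, sds, `/`), tolerance = 1e-6)
})

test_that("prewhitening matches the closed-form 2-voxel inverse square root", {
  # build residuals with known sample covariance S
  S <- matrix(c(2, 0.6, 0.6, 1), 2, 2)
  n <- 40
  set.seed(81)
  z <- qr.Q(qr(scale(matrix(rnorm(n * 2), n, 2), scale = FALSE))) * sqrt(n - 1)
  resid <- z %*% chol(S)
  betas <- matrix(c(1, 0, 0, 1, 2, -1), 3, 2)
  pw <- prewhiten(betas, resid)
  Sigma <- (1 - pw$lambda) * S + pw$lambda * diag(diag(S))
  e <- eigen(Sigma, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  expect_equal(pw$whitened, betas %*% W, tolerance = 1e-8)
  # whitened distances are Mahalanobis distances under Sigma
  d12 <- pairwise_distances(pw$whitened, rbind(c(1, 2)))
  delta <- betas[1, ] - betas[2, ]
  expect_equal(d12, as.numeric(delta %*% solve(Sigma) %*% delta), tolerance = 1e-8)
})

test_that("shrinkage is forced and flagged when frames are scarce", {
  set.seed(82)
  betas <- matrix(rnorm(20), 2, 10)
  resid <- matrix(rnorm(8 * 10), 8, 10)  # fewer frames than voxels
  pw <- prewhiten(betas, resid)
  expect_gte(pw$lambda, 0.1)
})

test_that("pairwise distances match hand computations", {
  p <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0))
  pr <- rbind(c(1, 2), c(1, 3), c(2, 3))
  d <- pairwise_distances(p, pr)
  expect_equal(d, c(2, 0, 2))
  set.seed(83)
  pts <- matrix(rnorm(5 * 4), 5, 4)
  prs <- pairs_between(5)
  expect_equal(pairwise_distances(pts, prs),
               as.numeric(dist(pts)^2), tolerance = 1e-10)
})

test_that("pair builders respect episode structure", {
  ep <- rep(1:3, each = 4)
  pr <- pairs_within_episode(ep)
  expect_equal(nrow(pr), 3 * 6)
  expect_true(all(ep[pr[, 1]] == ep[pr[, 2]]))
  expect_equal(nrow(pairs_between(16)), 120L)
})

test_that("model correlations hit the Spearman extremes and flag constants", {
  obs <- c(1, 3, 2, 5, 4, 6)
  expect_equal(model_correlation(obs, obs)$rho, 1)
  expect_equal(model_correlation(obs, -obs)$rho, -1)
  expect_true(model_correlation(obs, rep(2, 6))$flagged)
  # monotone transform invariance
  set.seed(84)
  m <- runif(20)
  expect_equal(model_correlation(exp(m), m)$rho, 1)
})

test_that("partial correlation matches the residual-rank oracle", {
  set.seed(85)
  z <- rnorm(40)
  obs <- z + rnorm(40, 0, 0.3)
  mod <- z + rnorm(40, 0, 0.3)
  r <- model_correlation(obs, mod, covariate = z)
  res_o <- resid(lm(rank(obs) ~ rank(z)))
  res_m <- resid(lm(rank(mod) ~ rank(z)))
  expect_equal(r$rho, cor(res_o, res_m), tolerance = 1e-10)
  expect_lt(r$rho, cor(rank(obs), rank(mod)))  # confound removed
})

test_that("the batched searchlight map equals the per-searchlight loop", {
  set.seed(86)
  mask <- array(TRUE, c(5L, 5L, 5L))
  sl <- build_searchlights(mask)
  n_cond <- 12
  betas <- matrix(rnorm(n_cond * 125), n_cond, 125)
  resid <- matrix(rnorm(50 * 125), 50, 125)
  pr <- pairs_between(n_cond)
  model <- runif(nrow(pr))
  cov <- runif(nrow(pr))
  m <- searchlight_map(betas, resid, sl, pr, model, cov, fisher_z = FALSE)
  for (s in c(1, 40, 125)) {
    vox <- sl$members[[s]]
    pw <- prewhiten(betas[, vox], resid[, vox])
    d <- pairwise_distances(pw$whitened, pr)
    expect_equal(m[sl$centers[s]], model_correlation(d, model, cov)$rho,
                 tolerance = 1e-10)
  }
})

test_that("smoothing preserves constants, mass, and the kernel width", {
  mask <- array(TRUE, c(15L, 15L, 15L))
  const <- array(3.3, dim(mask))
  sm <- smooth_map(const, mask)
  expect_equal(sm, const, tolerance = 1e-9)

  delta <- array(0, dim(mask)); delta[8, 8, 8] <- 1
  sd_ <- smooth_map(delta, mask)
  expect_equal(sum(sd_), 1, tolerance = 1e-6)  # mass preserved
  # recover the FWHM along an axis through the peak
  prof <- sd_[, 8, 8]
  half <- max(prof) / 2
  above <- which(prof >= half)
  width_vox <- max(above) - min(above) + 1
  expect_equal(width_vox * 3, 6, tolerance = 3)  # 6 mm FWHM at 3 mm voxels
  sigma_fit <- sqrt(sum(((1:15 - 8) * 3)^2 * prof) / sum(prof))
  expect_equal(sigma_fit, 6 / 2.355, tolerance = 0.15)
})

test_that("group cluster inference is sign-symmetric and guards small samples", {
  set.seed(87)
  mask <- array(TRUE, c(6L, 6L, 6L))
  maps <- lapply(1:8, function(i) array(rnorm(216), dim(mask)))
  res <- group_cluster_mass(maps, mask, seed = 1)
  flipped <- lapply(maps, function(m) -m)
  res_f <- group_cluster_mass(flipped, mask, seed = 1)
  expect_equal(res_f$t_map, -res$t_map, tolerance = 1e-10)
  expect_true(all(res$clusters$p_corrected > 0))
  expect_error(group_cluster_mass(maps[1:4], mask), "at least 5")
})

test_that("a planted blob is detected and pure noise is not", {
  set.seed(88)
  mask <- array(TRUE, c(10L, 10L, 10L))
  blob <- array(0, dim(mask)); blob[4:7, 4:7, 4:7] <- 0.8
  maps <- lapply(1:10, function(i) blob + array(rnorm(1000, 0, 0.5), dim(mask)))
  res <- group_cluster_mass(maps, mask)
  expect_gt(nrow(res$clusters), 0)
  expect_lte(min(res$clusters$p_corrected), 0.05)
  top <- res$clusters$id[which.min(res$clusters$p_corrected)]
  top_vox <- which(res$cluster_map == top)
  expect_gt(mean(top_vox %in% which(blob > 0)), 0.8)

  # pure noise: whatever clusters arise carry far less mass than the blob
  noise_maps <- lapply(1:10, function(i) array(rnorm(1000, 0, 0.5), dim(mask)))
  res0 <- group_cluster_mass(noise_maps, mask)
  blob_mass <- max(res$clusters$mass)
  expect_true(nrow(res0$clusters) == 0 || max(res0$clusters$mass) < blob_mass / 2)
})
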