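#' Build fixed-size searchlights over a voxel mask
#'
#' For every in-mask voxel, the searchlight is its `n_voxels` nearest
#' in-mask voxels by Euclidean millimeter distance (center included), all
#' within `max_radius_mm`. Ties at the cutoff distance are broken by
#' lexicographic grid order. Nonspherical searchlights arise naturally at
#' mask borders; voxels with fewer than `n_voxels` in-mask neighbors within
#' the radius are skipped and reported.
#'
#' @param mask 3-D logical array.
#' @param n_voxels Searchlight size (default 10).
#' @param max_radius_mm Maximum member distance from the center (default 10).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @return Object of class `tm_searchlights`: list with `centers` (linear
#'   grid index per searchlight), `members` (list of index vectors into the
#'   masked-voxel ordering), `skipped` (linear grid indices), `mask`,
#'   `n_voxels`, `voxel_size_mm`.
#' @export
build_searchlights <- function(mask, n_voxels = 10L, max_radius_mm = 10,
                               voxel_size_mm = 3) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  in_mask <- which(mask)
  if (length(in_mask) < n_voxels)
    stop("mask has fewer voxels than the requested searchlight size")
  coords <- arrayInd(in_mask, dims)
  mask_index <- array(NA_integer_, dims)
  mask_index[in_mask] <- seq_along(in_mask)

  r_vox <- floor(max_radius_mm / voxel_size_mm)
  off <- as.matrix(expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox))
  dist_mm <- voxel_size_mm * sqrt(rowSums(off^2))
  keep <- dist_mm <= max_radius_mm + 1e-9
  off <- off[keep, , drop = FALSE]
  dist_mm <- dist_mm[keep]

  centers <- integer(0); members <- list(); skipped <- integer(0)
  for (v in seq_along(in_mask)) {
    cand <- sweep(off, 2L, coords[v, ], `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    lin <- cand[ok, 1] + (cand[ok, 2] - 1L) * dims[1] +
      (cand[ok, 3] - 1L) * dims[1] * dims[2]
    mi <- mask_index[lin]
    inm <- !is.na(mi)
    if (sum(inm) < n_voxels) {
      skipped <- c(skipped, in_mask[v])
      next
    }
    d <- dist_mm[ok][inm]
    lin_in <- lin[inm]
    ord <- order(d, lin_in)[seq_len(n_voxels)]
    centers <- c(centers, in_mask[v])
    members[[length(members) + 1L]] <- mi[inm][ord]
  }
  out <- list(centers = centers, members = members, skipped = skipped,
              mask = mask, n_voxels = as.integer(n_voxels),
              voxel_size_mm = voxel_size_mm, max_radius_mm = max_radius_mm)
  class(out) <- "tm_searchlights"
  out
}

#' @export
print.tm_searchlights <- function(x, ...) {
  cat(sprintf("tm_searchlights: %d searchlights of %d voxels (%d centers skipped)\n",
              length(x$centers), x$n_voxels, length(x$skipped)))
  invisible(x)
}

# Schafer-Strimmer analytic shrinkage intensity toward the diagonal target:
# lambda = sum_{i<j} Var(s_ij) / sum_{i<j} s_ij^2, with the pairwise sums
# computed in closed form from row sums of squares.
shrinkage_intensity <- function(resid_centered) {
  n <- nrow(resid_centered)
  S <- crossprod(resid_centered) / (n - 1)
  Q <- resid_centered^2
  # sum over pairs i<j and frames k of (x_ki x_kj)^2
  sum_w2 <- 0.5 * sum(rowSums(Q)^2 - rowSums(Q^2))
  # sum over pairs of (sum_k w_kij)^2 = (n-1)^2 * sum_{i<j} S_ij^2
  off2 <- 0.5 * (sum(S^2) - sum(diag(S)^2))
  sum_wbar2 <- (n - 1)^2 * off2
  if (off2 < 1e-12) return(0)
  var_sum <- n / (n - 1)^3 * (sum_w2 - sum_wbar2 / n)
  min(1, max(0, var_sum / off2))
}

#' Multivariate noise normalization of activity patterns
#'
#' Estimates the voxel covariance of the GLM residuals within one
#' searchlight, shrinks it toward its diagonal (analytic optimal-shrinkage
#' intensity), and multiplies the regression-coefficient patterns by the
#' inverse matrix square root, so that squared Euclidean distances on the
#' whitened patterns equal Mahalanobis distances.
#'
#' @param betas Conditions x voxels pattern matrix (searchlight voxels).
#' @param residuals Frames x voxels GLM residual matrix (same voxels).
#' @param min_shrinkage Lower bound on the shrinkage intensity enforced when
#'   there are fewer residual frames than voxels (flagged in the output).
#' @return List with `whitened` (conditions x voxels), `lambda`, `forced`
#'   (TRUE when shrinkage was forced), `whitener` (the inverse square root).
#' @export
prewhiten <- function(betas, residuals, min_shrinkage = 0.1) {
  betas <- as.matrix(betas); residuals <- as.matrix(residuals)
  stopifnot(ncol(betas) == ncol(residuals))
  rc <- scale(residuals, center = TRUE, scale = FALSE)
  lambda <- shrinkage_intensity(rc)
  forced <- FALSE
  if (nrow(residuals) < ncol(residuals) && lambda < min_shrinkage) {
    lambda <- min_shrinkage
    forced <- TRUE
  }
  S <- crossprod(rc) / (nrow(rc) - 1)
  Sigma <- (1 - lambda) * S + lambda * diag(diag(S), ncol(S))
  eig <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eig$values, 1e-10)
  W <- eig$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(eig$vectors)
  list(whitened = betas %*% W, lambda = lambda, forced = forced, whitener = W)
}

#' Condition pairs for the two RSA modes
#'
#' Within-episode mode: all object pairs from the same episode (10 pairs per
#' 5-object episode, no cross-episode pairs). Between-episode mode: all
#' episode pairs.
#'
#' @param episode_of Integer episode label per condition (within mode).
#' @param n_conditions Number of conditions (between mode).
#' @return Two-column integer matrix of condition indices.
#' @export
pairs_within_episode <- function(episode_of) {
  eps <- unique(episode_of)
  out <- lapply(eps, function(e) {
    idx <- which(episode_of == e)
    if (length(idx) < 2L) return(NULL)
    t(utils::combn(idx, 2L))
  })
  do.call(rbind, out)
}

#' @rdname pairs_within_episode
#' @export
pairs_between <- function(n_conditions) {
  t(utils::combn(seq_len(n_conditions), 2L))
}

#' Pairwise pattern dissimilarities
#'
#' Squared Euclidean distance between whitened activity patterns for a set
#' of condition pairs (equivalently, squared Mahalanobis distances on the
#' raw patterns).
#'
#' @param patterns Conditions x voxels matrix.
#' @param pairs Two-column matrix of condition indices.
#' @return Numeric vector of dissimilarities, one per pair.
#' @export
pairwise_distances <- function(patterns, pairs) {
  d <- patterns[pairs[, 1], , drop = FALSE] - patterns[pairs[, 2], , drop = FALSE]
  unname(rowSums(d^2))
}

#' Model dissimilarity vectors
#'
#' `model_rdm_within` assigns every same-episode object pair its episode's
#' signed scaling contrast `scaling_exp - scaling_compr`, predicting that
#' pattern dissimilarity increases with temporal expansion of the episode
#' (equivalently, patterns integrate when the episode is compressed).
#' `encoding = "binary"` uses the sign of the contrast.
#' `model_rdm_between` assigns every episode pair the absolute difference of
#' a per-episode scaling variable, predicting that episodes differing in
#' temporal expansion are represented more distinctly.
#'
#' @param scaling_compr,scaling_exp Per-episode compression/expansion
#'   magnitudes.
#' @param episode_of Episode label per condition.
#' @param pairs Pair matrix from [pairs_within_episode()].
#' @param encoding `"continuous"` or `"binary"`.
#' @return Numeric vector aligned with `pairs`.
#' @export
model_rdm_within <- function(scaling_compr, scaling_exp, episode_of, pairs,
                             encoding = c("continuous", "binary")) {
  encoding <- match.arg(encoding)
  ep1 <- episode_of[pairs[, 1]]
  ep2 <- episode_of[pairs[, 2]]
  if (any(ep1 != ep2)) stop("within-episode model requires same-episode pairs")
  contrast <- scaling_exp - scaling_compr
  v <- contrast[ep1]
  if (encoding == "binary") v <- sign(v)
  v
}

#' @rdname model_rdm_within
#' @param values Per-episode scaling variable (e.g. episode-level expansion).
#' @export
model_rdm_between <- function(values, pairs) {
  abs(values[pairs[, 1]] - values[pairs[, 2]])
}

#' Timing covariate for the within-episode partial correlation
#'
#' Absolute difference in presentation onset (milliseconds) between the two
#' objects of each pair, used to control for temporal proximity.
#'
#' @param onsets_s Object onsets in seconds, one per condition.
#' @param pairs Pair matrix.
#' @export
lag_covariate <- function(onsets_s, pairs) {
  abs(onsets_s[pairs[, 1]] - onsets_s[pairs[, 2]]) * 1000
}

#' Spearman correlation between observed and model dissimilarities
#'
#' Plain Spearman's rho, or — when a covariate is supplied — partial
#' Spearman correlation: both rank vectors are residualized on the ranked
#' covariate before correlating.
#'
#' @param observed Observed dissimilarities (one per pair).
#' @param model Model dissimilarities.
#' @param covariate Optional covariate (e.g. [lag_covariate()]).
#' @return List with `rho` and `flagged` (TRUE with `rho = NA` when the
#'   model or observed vector is constant).
#' @export
model_correlation <- function(observed, model, covariate = NULL) {
  if (stats::sd(model) < 1e-12 || stats::sd(observed) < 1e-12)
    return(list(rho = NA_real_, flagged = TRUE))
  r_obs <- rank(observed)
  r_mod <- rank(model)
  if (is.null(covariate)) {
    return(list(rho = stats::cor(r_obs, r_mod), flagged = FALSE))
  }
  r_cov <- rank(covariate)
  res_obs <- stats::lm.fit(cbind(1, r_cov), r_obs)$residuals
  res_mod <- stats::lm.fit(cbind(1, r_cov), r_mod)$residuals
  if (stats::sd(res_mod) < 1e-12) return(list(rho = NA_real_, flagged = TRUE))
  list(rho = stats::cor(res_obs, res_mod), flagged = FALSE)
}

#' Whole-brain searchlight model-correlation map for one subject
#'
#' Runs prewhitening, pairwise distances, and the (partial) Spearman model
#' correlation for every searchlight, writing each searchlight's rho to its
#' center voxel. The rank-based correlation step is vectorized across
#' searchlights.
#'
#' @param betas Conditions x all-masked-voxels pattern matrix.
#' @param residuals Frames x all-masked-voxels GLM residual matrix.
#' @param searchlights A `tm_searchlights`.
#' @param pairs Pair matrix (condition indices).
#' @param model Model dissimilarity vector.
#' @param covariate Optional covariate vector.
#' @param fisher_z Transform the map by `atanh` (default TRUE; standard
#'   before group t-tests).
#' @return 3-D array (mask dimensions) with the correlation at searchlight
#'   centers and NA elsewhere.
#' @export
searchlight_map <- function(betas, residuals, searchlights, pairs, model,
                            covariate = NULL, fisher_z = TRUE) {
  sl <- searchlights
  n_sl <- length(sl$centers)
  n_pairs <- nrow(pairs)
  D <- matrix(0, n_pairs, n_sl)
  for (s in seq_len(n_sl)) {
    vox <- sl$members[[s]]
    pw <- prewhiten(betas[, vox, drop = FALSE], residuals[, vox, drop = FALSE])
    D[, s] <- pairwise_distances(pw$whitened, pairs)
  }
  r_mod <- rank(model)
  R <- apply(D, 2L, rank)
  if (!is.null(covariate)) {
    H <- cbind(1, rank(covariate))
    proj <- H %*% solve(crossprod(H), t(H))
    R <- R - proj %*% R
    r_mod <- r_mod - proj %*% r_mod
  }
  r_mod <- r_mod - mean(r_mod)
  Rc <- sweep(R, 2L, colMeans(R))
  denom <- sqrt(colSums(Rc^2) * sum(r_mod^2))
  rho <- as.numeric(crossprod(Rc, r_mod)) / denom
  rho[denom < 1e-12] <- NA_real_
  if (fisher_z) rho <- atanh(pmin(pmax(rho, -0.999999), 0.999999))
  out <- array(NA_real_, dim(sl$mask))
  out[sl$centers] <- rho
  out
}

# 1-D Gaussian convolution along one axis of a 3-D array.
convolve_axis <- function(arr, kernel, axis) {
  dims <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kernel[ok]
  }
  res <- K %*% m
  out <- array(res, dim(a))
  aperm(out, order(perm))
}

#' Gaussian smoothing of a statistic map within a mask
#'
#' Separable Gaussian smoothing with the kernel renormalized inside the
#' mask (so values never bleed in from outside and a constant map is
#' unchanged). Applied at the single-subject level after the dissimilarity
#' estimation.
#'
#' @param map 3-D array (NA allowed outside the mask).
#' @param mask 3-D logical array.
#' @param fwhm_mm Kernel FWHM in millimeters (default 6).
#' @param voxel_size_mm Voxel size (default 3).
#' @return Smoothed 3-D array, NA outside the mask.
#' @export
smooth_map <- function(map, mask, fwhm_mm = 6, voxel_size_mm = 3) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  kernel <- stats::dnorm(-r:r, sd = sigma_vox)
  kernel <- kernel / sum(kernel)
  num <- map
  num[!mask | is.na(num)] <- 0
  den <- array(0, dim(mask))
  den[mask & !is.na(map)] <- 1
  for (ax in 1:3) {
    num <- convolve_axis(num, kernel, ax)
    den <- convolve_axis(den, kernel, ax)
  }
  out <- array(NA_real_, dim(mask))
  ok <- mask & den > 1e-8
  out[ok] <- num[ok] / den[ok]
  out
}

# Connected components (6-connectivity) of a set of linear voxel indices.
label_components <- function(idx, dims) {
  if (length(idx) == 0L) return(integer(0))
  coords <- arrayInd(idx, dims)
  pos <- stats::setNames(seq_along(idx), idx)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- coords
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dims[ax]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] + (nb[ok, 3] - 1L) * dims[1] * dims[2]
    hit <- !is.na(match(as.character(lin), names(pos)))
    if (any(hit)) {
      from <- which(ok)[hit]
      to <- pos[as.character(lin[hit])]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

#' Group-level sign-flip cluster-mass inference
#'
#' One-sample t-test per voxel across subjects, cluster formation at the t
#' value corresponding to the one-sided `cluster_p` threshold, cluster mass
#' = sum of t over members (6-connectivity), and a max-statistic null built
#' by sign-flipping whole subject maps: all 2^n flips when n <= 12,
#' otherwise `n_perm` Monte Carlo flips. Cluster-corrected p is the
#' proportion of the null max masses at least as large as the observed mass.
#'
#' @param subject_maps List of 3-D arrays (one per subject) or a subjects x
#'   voxels matrix (masked voxels).
#' @param mask 3-D logical array.
#' @param n_perm Monte Carlo flips when n > 12 (default 2000).
#' @param cluster_p Cluster-forming (uncorrected, one-sided) p (default
#'   0.001).
#' @param alpha Corrected significance level (default 0.05).
#' @param seed Integer seed for Monte Carlo flips.
#' @return Object of class `tm_cluster_result`: `t_map` (3-D), `clusters`
#'   (data.frame: id, n_voxels, mass, p_corrected, significant), `t_threshold`,
#'   `null_max_mass`, `cluster_map` (3-D integer labels).
#' @export
group_cluster_mass <- function(subject_maps, mask, n_perm = 2000L,
                               cluster_p = 0.001, alpha = 0.05, seed = 1L) {
  if (is.list(subject_maps)) {
    X <- t(vapply(subject_maps, function(m) m[mask], numeric(sum(mask))))
  } else {
    X <- as.matrix(subject_maps)
  }
  n <- nrow(X)
  if (n < 5L) stop("at least 5 subjects are required")
  X[is.na(X)] <- 0
  dims <- dim(mask)
  mask_idx <- which(mask)
  t_thr <- stats::qt(1 - cluster_p, df = n - 1)

  ss <- colSums(X^2)
  t_for <- function(signs) {
    m <- as.numeric(signs %*% X) / n
    v <- (ss - n * m^2) / (n - 1)
    m / sqrt(pmax(v, 1e-12) / n)
  }
  max_mass <- function(tv) {
    supra <- which(tv > t_thr)
    if (length(supra) == 0L) return(0)
    lab <- label_components(mask_idx[supra], dims)
    max(vapply(split(tv[supra], lab), sum, numeric(1)))
  }

  t_obs <- t_for(matrix(1, 1, n))
  supra <- which(t_obs > t_thr)
  clusters <- data.frame(id = integer(0), n_voxels = integer(0),
                         mass = numeric(0))
  cluster_map <- array(0L, dims)
  if (length(supra) > 0L) {
    lab <- label_components(mask_idx[supra], dims)
    masses <- vapply(split(t_obs[supra], lab), sum, numeric(1))
    sizes <- as.integer(table(lab))
    clusters <- data.frame(id = seq_along(masses), n_voxels = sizes,
                           mass = as.numeric(masses))
    cluster_map[mask_idx[supra]] <- lab
  }

  if (n <= 12L) {
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    signs_mat <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    signs_mat[1, ] <- 1  # include the identity flip
  }
  # batched t maps per chunk of flips; max cluster mass per flip
  null_max <- numeric(nrow(signs_mat))
  chunk <- 256L
  for (start in seq(1L, nrow(signs_mat), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(signs_mat))
    M <- (signs_mat[rows, , drop = FALSE] %*% X) / n
    Vm <- sweep(-n * M^2, 2L, ss, `+`) / (n - 1)
    Tm <- M / sqrt(pmax(Vm, 1e-12) / n)
    null_max[rows] <- vapply(seq_along(rows), function(i) max_mass(Tm[i, ]),
                             numeric(1))
  }

  if (nrow(clusters) > 0L) {
    clusters$p_corrected <- vapply(clusters$mass, function(m)
      mean(null_max >= m - 1e-12), numeric(1))
    clusters$significant <- clusters$p_corrected <= alpha
    clusters <- clusters[order(-clusters$mass), ]
    rownames(clusters) <- NULL
  } else {
    clusters$p_corrected <- numeric(0)
    clusters$significant <- logical(0)
  }
  t_map <- array(NA_real_, dims)
  t_map[mask_idx] <- t_obs
  out <- list(t_map = t_map, clusters = clusters, t_threshold = t_thr,
              null_max_mass = null_max, cluster_map = cluster_map,
              n_subjects = n, alpha = alpha)
  class(out) <- "tm_cluster_result"
  out
}

#' @export
print.tm_cluster_result <- function(x, ...) {
  cat(sprintf("tm_cluster_result: %d subjects, t threshold %.2f, %d clusters (%d significant)\n",
              x$n_subjects, x$t_threshold, nrow(x$clusters),
              sum(x$clusters$significant)))
  if (nrow(x$clusters) > 0) print(utils::head(x$clusters, 10), row.names = FALSE)
  invisible(x)
}
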