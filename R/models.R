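#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Trial-level inference engine for the measure table: a Gaussian linear
#' mixed model with a random intercept per participant, estimated by maximum
#' likelihood (not REML) so AIC values are comparable across fixed-effect
#' structures. Rows with missing values in any used column are dropped and
#' their count reported. Fixed-effect p-values are Wald z tests.
#'
#' @param table A data.frame (typically a `tm_measure_table`).
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param quadratic Subset of `fixed_terms` that also enter as centered
#'   squared terms.
#' @param group Grouping column for the random intercept.
#' @return Object of class `tm_lmm`: list with `coefficients` (data.frame of
#'   estimate, se, z, p per fixed effect), `aic`, `vif`, `singular`,
#'   `n_used`, `n_dropped`, `terms`, and the underlying `fit` (a `merMod`).
#' @export
fit_lmm <- function(table, response, fixed_terms = character(0),
                    quadratic = character(0), group = "participant") {
  stopifnot(response %in% names(table), group %in% names(table))
  missing_terms <- setdiff(c(fixed_terms, quadratic), names(table))
  if (length(missing_terms) > 0)
    stop("unknown columns: ", paste(missing_terms, collapse = ", "))
  if (response %in% fixed_terms)
    stop("response cannot appear among the fixed terms")
  used <- unique(c(response, fixed_terms, quadratic, group))
  cc <- stats::complete.cases(table[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  dat <- table[cc, used, drop = FALSE]
  if (length(unique(dat[[group]])) < 2L) stop("need >= 2 grouping levels")
  qterms <- if (length(quadratic) > 0)
    paste0("I(scale(", quadratic, ", scale = FALSE)^2)") else character(0)
  rhs <- paste(c(fixed_terms, qterms, sprintf("(1 | %s)", group)), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- lme4::lmer(form, data = dat, REML = FALSE)
  co <- lme4::fixef(fit)
  vc <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                 error = function(e) diag(NA_real_, length(co)))
  se <- sqrt(diag(vc))
  z <- co / se
  coefficients <- data.frame(term = names(co), estimate = unname(co),
                             se = unname(se), z = unname(z),
                             p = 2 * stats::pnorm(-abs(unname(z))))
  out <- list(coefficients = coefficients,
              aic = stats::AIC(fit),
              vif = if (length(c(fixed_terms, qterms)) >= 2L)
                vif_terms(stats::model.matrix(fit)[, -1, drop = FALSE]) else NULL,
              singular = lme4::isSingular(fit) || !all(is.finite(se)) ||
                stats::sigma(fit) < 1e-8,
              n_used = nrow(dat), n_dropped = n_dropped,
              terms = c(fixed_terms, qterms), fit = fit)
  class(out) <- "tm_lmm"
  out
}

#' @export
print.tm_lmm <- function(x, ...) {
  cat(sprintf("tm_lmm: %d fixed terms, AIC %.1f, n = %d (%d dropped)%s\n",
              length(x$terms), x$aic, x$n_used, x$n_dropped,
              if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Forward AIC selection of fixed effects
#'
#' Starting from an intercept-only random-intercept model, repeatedly adds
#' the candidate term (or its centered quadratic, when offered) whose
#' inclusion most improves the AIC, until no candidate improves it. The
#' selection path is logged.
#'
#' @inheritParams fit_lmm
#' @param candidates Candidate fixed-effect column names.
#' @param quadratic_candidates Candidates also offered as squared terms.
#' @return A `tm_lmm` for the selected model with an extra `path` data.frame
#'   (step, term added, AIC) and `selected` (chosen linear terms).
#' @export
stepwise_aic <- function(table, response, candidates,
                         quadratic_candidates = character(0),
                         group = "participant") {
  candidates <- setdiff(candidates, response)
  current <- character(0)
  current_quad <- character(0)
  base <- fit_lmm(table, response, current, current_quad, group)
  best_aic <- base$aic
  path <- data.frame(step = 0L, term = "(intercept only)", aic = best_aic)
  pool <- data.frame(term = c(candidates, quadratic_candidates),
                     quad = c(rep(FALSE, length(candidates)),
                              rep(TRUE, length(quadratic_candidates))),
                     stringsAsFactors = FALSE)
  repeat {
    if (nrow(pool) == 0L) break
    trial_aic <- vapply(seq_len(nrow(pool)), function(i) {
      lin <- union(current, pool$term[i])
      qd <- if (pool$quad[i]) union(current_quad, pool$term[i]) else current_quad
      tryCatch(fit_lmm(table, response, lin, qd, group)$aic,
               error = function(e) Inf)
    }, numeric(1))
    best <- which.min(trial_aic)
    if (trial_aic[best] >= best_aic) break
    if (pool$quad[best]) {
      current_quad <- union(current_quad, pool$term[best])
      current <- union(current, pool$term[best])
    } else {
      current <- union(current, pool$term[best])
    }
    best_aic <- trial_aic[best]
    path <- rbind(path, data.frame(
      step = nrow(path),
      term = paste0(pool$term[best], if (pool$quad[best]) " (+quadratic)" else ""),
      aic = best_aic))
    pool <- pool[-best, , drop = FALSE]
  }
  out <- fit_lmm(table, response, current, current_quad, group)
  out$path <- path
  out$selected <- current
  out
}

#' Variance inflation factors
#'
#' Classical VIFs computed from the inverse of the predictor correlation
#' matrix (`diag(solve(cor(X)))`), equivalent to `1 / (1 - R^2_j)` from
#' regressing each predictor on the others.
#'
#' @param x A numeric matrix or data.frame of predictors (>= 2 columns), or a
#'   data.frame plus `terms` selecting columns.
#' @param terms Optional column names to use.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif_terms <- function(x, terms = NULL) {
  if (!is.null(terms)) x <- x[, terms, drop = FALSE]
  x <- as.matrix(x)
  if (ncol(x) < 2L) return(stats::setNames(rep(1, ncol(x)), colnames(x)))
  v <- diag(solve(stats::cor(x)))
  stats::setNames(as.numeric(v), colnames(x))
}

#' Quasi-Bayesian causal mediation for mixed models
#'
#' Combines the mediator model (mediator ~ treatment, random intercept) and
#' the outcome model (outcome ~ treatment + mediator, random intercept),
#' both by maximum likelihood, and evaluates the indirect effect by
#' quasi-Bayesian Monte Carlo: coefficient vectors are drawn from the
#' asymptotic normal distribution of each fit; each draw's ACME is the
#' product of the treatment-to-mediator and mediator-to-outcome
#' coefficients, and its ADE the direct treatment coefficient. Percentile
#' 95% intervals are reported. The mediation is only assessed when both
#' gating coefficients are significant at `gate_p`; otherwise the result is
#' flagged `assessed = FALSE` (estimates are still returned for inspection).
#'
#' @inheritParams fit_lmm
#' @param treatment,mediator,outcome Column names.
#' @param covariates Extra fixed-effect columns included in both models.
#' @param n_draws Monte Carlo draws (default 5000).
#' @param seed Integer seed.
#' @param gate_p Significance gate on the two path coefficients.
#' @return Object of class `tm_mediation`: `acme`, `acme_ci`, `ade`,
#'   `ade_ci`, `proportion_mediated`, `n_draws`, `assessed`, `gate_p_values`.
#' @export
mediate_lmm <- function(table, treatment, mediator, outcome,
                        covariates = character(0), n_draws = 5000L, seed = 1L,
                        group = "participant", gate_p = 0.05) {
  m2 <- fit_lmm(table, mediator, c(treatment, covariates), group = group)
  m3 <- fit_lmm(table, outcome, c(treatment, mediator, covariates), group = group)
  p_a <- m2$coefficients$p[m2$coefficients$term == treatment]
  p_b <- m3$coefficients$p[m3$coefficients$term == mediator]
  assessed <- p_a < gate_p && p_b < gate_p
  set.seed(seed)
  draw_fixef <- function(m) {
    MASS::mvrnorm(n_draws, mu = lme4::fixef(m$fit),
                  Sigma = as.matrix(stats::vcov(m$fit)))
  }
  d2 <- draw_fixef(m2)
  d3 <- draw_fixef(m3)
  a <- d2[, treatment]
  b <- d3[, mediator]
  cprime <- d3[, treatment]
  acme_draws <- a * b
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  total <- acme_draws + cprime
  prop <- acme_draws / total
  out <- list(acme = mean(acme_draws), acme_ci = ci(acme_draws),
              ade = mean(cprime), ade_ci = ci(cprime),
              proportion_mediated = stats::median(prop[is.finite(prop)]),
              n_draws = n_draws, assessed = assessed,
              gate_p_values = c(treatment_to_mediator = p_a,
                                mediator_to_outcome = p_b),
              mediator_model = m2, outcome_model = m3)
  class(out) <- "tm_mediation"
  out
}

#' @export
print.tm_mediation <- function(x, ...) {
  cat(sprintf("ACME %.4f [%.4f, %.4f]; ADE %.4f [%.4f, %.4f]; prop. mediated %.3f%s\n",
              x$acme, x$acme_ci[1], x$acme_ci[2],
              x$ade, x$ade_ci[1], x$ade_ci[2], x$proportion_mediated,
              if (!x$assessed) " (gating models not significant: not assessed)" else ""))
  invisible(x)
}

#' Spearman correlation matrix over participant means
#'
#' Pairwise Spearman's rho between measures averaged per participant, with
#' Benjamini-Hochberg FDR across all measure pairs.
#'
#' @param participant_means data.frame of per-participant averages, one
#'   column per measure (an id column named `participant` is ignored).
#' @return List with matrices `rho`, `p`, `q`.
#' @export
spearman_matrix <- function(participant_means) {
  x <- participant_means[, setdiff(names(participant_means), "participant"),
                         drop = FALSE]
  x <- as.matrix(x)
  m <- ncol(x)
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  p <- matrix(NA_real_, m, m, dimnames = dimnames(rho))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) { p[i, j] <- 0; next }
      if (j < i) { p[i, j] <- p[j, i]; next }
      p[i, j] <- tryCatch(
        stats::cor.test(x[, i], x[, j], method = "spearman", exact = FALSE)$p.value,
        error = function(e) NA_real_)
    }
  }
  q <- p
  upper <- upper.tri(p)
  q[upper] <- fdr_adjust(p[upper])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q)
}
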