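#' Bias-corrected multivariable Mendelian randomization (MRBEE)
#'
#' Fits the multivariable MR model \eqn{\hat\alpha = \hat B \theta + e} for a
#' locus of p genes using m correlated cis-eQTL instruments, correcting the
#' regression "bread" matrix for the measurement error of the eQTL effect
#' estimates (weak-instrument bias):
#' \deqn{\hat\theta = (\hat B^\top R_\lambda^{-1} \hat B - m\Sigma)^{-1}
#'       \hat B^\top R_\lambda^{-1} \hat\alpha}
#' where \eqn{R_\lambda} is a (regularized) LD matrix and \eqn{\Sigma} the
#' error correlation of the eQTL z-scores across genes. All fitting happens
#' on the whitened scale (symmetric square root of \eqn{R_\lambda^{-1}}
#' applied to both sides), where the model becomes ordinary bias-corrected
#' least squares with independent errors.
#'
#' Instruments showing evidence of horizontal pleiotropy (a direct outcome
#' effect not mediated by the modelled genes) are removed by an iterative
#' residual chi-square test before the final fit (`prune = TRUE`).
#'
#' Inputs must be on the z-score scale (estimate / standard error) so that
#' \eqn{\Sigma}, a correlation matrix, is the correct error covariance.
#'
#' @param B m x p matrix of eQTL z-scores (no missing values; impute first),
#'   or a fully observed/completed [eqtl_matrix()].
#' @param alpha_vec m-vector of outcome z-scores (or an [outcome_vector()],
#'   converted with `alpha/se`).
#' @param R LD matrix for the m instruments ([ld_matrix()] or plain matrix);
#'   `NULL` for uncorrelated instruments (identity).
#' @param bias a [bias_matrix()]; `NULL` means no weak-instrument correction
#'   (\eqn{\Sigma = 0}), in which case the estimator is generalized IVW.
#' @param n_panel LD reference panel size used for the finite-panel
#'   inference correction; defaults to the `n` attribute of `R` when
#'   present. `NULL` disables the correction (exact LD).
#' @param prune remove pleiotropic instruments before the final fit?
#' @param p_threshold chi-square p-value threshold of the pleiotropy test
#'   (default 0.05).
#' @param bias_scale optional p x p matrix of effective instrument counts
#'   from [bias_scale_matrix()], replacing the uniform scale m when parts
#'   of `B` were unobserved/imputed; `NULL` uses m (fully observed data,
#'   the textbook estimator).
#' @param df_method residual degrees of freedom for the t-inference:
#'   `"m-1"` (univariable convention, default) or `"m-p"`.
#' @param pd_floor eigenvalue floor used if the bias-corrected bread matrix
#'   is not positive definite (weak-instrument overcorrection repair).
#'
#' @return An object of class `"mrbee"` with components `theta`,
#'   `cov_theta`, `se`, `L` (naive t-statistics), `L_tilde` (panel-corrected
#'   statistics, when `n_panel` is known), `pvals`, `df_resid`, `kept_ivs`,
#'   `locus_r2`, `pratt`, `n_panel`, `m`, `p`, and bookkeeping fields.
#'   Methods: [print.mrbee()], [summary.mrbee()], `coef`, `vcov`, `confint`,
#'   `fitted`, `residuals`, `predict`, `simulate`, `plot`.
#' @seealso [ivw_fit()] for the uncorrected baseline, [corrected_inference()]
#'   for the panel-size correction on its own.
#' @export
mrbee <- function(B, alpha_vec, R = NULL, bias = NULL, bias_scale = NULL,
                  n_panel = if (!is.null(R)) attr(R, "n") else NULL,
                  prune = TRUE, p_threshold = 0.05,
                  df_method = c("m-1", "m-p"), pd_floor = 1e-6) {
  cl <- match.call()
  df_method <- match.arg(df_method)
  if (inherits(B, "eqtl_matrix")) {
    if (!all(B$mask)) stop("eQTL matrix has missing entries; impute first")
    B <- eqtl_z(B)
  }
  B <- as.matrix(B)
  if (inherits(alpha_vec, "outcome_vector")) alpha_vec <- alpha_vec$alpha / alpha_vec$se
  y <- as.numeric(alpha_vec)
  m <- nrow(B); p <- ncol(B)
  if (length(y) != m) stop("'alpha_vec' length must match rows of 'B'")
  if (m < p) stop("need at least as many instruments as genes (m >= p)")
  if (anyNA(B) || anyNA(y)) stop("inputs must be complete")

  Rm <- if (is.null(R)) diag(m) else unclass_ld(R)
  M <- if (is.null(R)) diag(m) else sym_mat_power(Rm, -0.5)
  X <- M %*% B
  yw <- drop(M %*% y)
  Sigma <- if (is.null(bias)) matrix(0, p, p) else bias$Sigma
  # per-instrument noise covariance entering the bread correction
  Su <- if (is.null(bias_scale)) Sigma else (bias_scale / m) * Sigma

  kept <- seq_len(m)
  if (prune && p_threshold > 0) {
    kept <- pleiotropy_prune_whitened(X, yw, Su, Sigma, p_threshold, pd_floor)
  }
  fit <- mrbee_core(X[kept, , drop = FALSE], yw[kept], Su, pd_floor)

  mk <- length(kept)
  df_resid <- if (df_method == "m-1") mk - 1L else mk - p
  se <- sqrt(diag(fit$cov))
  L <- fit$theta / se
  if (!is.null(n_panel)) {
    ci <- corrected_inference(fit$theta, fit$cov, n_panel, mk, p,
                              df_method = df_method)
    L_tilde <- ci$L_tilde
    pvals <- ci$pvals
  } else {
    L_tilde <- NULL
    pvals <- 2 * stats::pt(-abs(L), df = df_resid)
  }
  fs <- locus_fit_stats_whitened(X[kept, , drop = FALSE], yw[kept], fit$theta)

  ids <- rownames(B)
  kept_ivs <- if (is.null(ids)) kept else ids[kept]
  theta <- fit$theta
  names(theta) <- colnames(B)
  dimnames(fit$cov) <- list(colnames(B), colnames(B))
  structure(list(theta = theta, cov_theta = fit$cov, se = se, L = L,
                 L_tilde = L_tilde, pvals = pvals, df_resid = df_resid,
                 kept_ivs = kept_ivs, kept_idx = kept,
                 locus_r2 = fs$locus_r2, pratt = stats::setNames(fs$pratt, colnames(B)),
                 n_panel = n_panel, m = mk, m_input = m, p = p,
                 Sigma = Sigma, bread_repaired = fit$repaired,
                 fitted_w = drop(X[kept, , drop = FALSE] %*% fit$theta),
                 residuals_w = yw[kept] - drop(X[kept, , drop = FALSE] %*% fit$theta),
                 B = B, y = y, R = Rm, call = cl),
            class = "mrbee")
}

# bias-corrected least squares on the whitened scale. `Su` is the
# per-instrument noise covariance (Sigma for complete data, an
# effective-count rescaling otherwise); the bread is G - m * Su. If the
# subtraction makes the bread indefinite (weak instruments or an
# overcorrecting Sigma estimate), the correction is capped at the largest
# fraction gamma that keeps a positive-definite margin -- a conservative,
# finite-variance fallback that partially attenuates instead of exploding
mrbee_core <- function(X, y, Su, pd_floor = 1e-6) {
  m <- nrow(X); p <- ncol(X)
  G <- crossprod(X)
  lam_max <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  margin <- max(pd_floor, 0.05 / m) * lam_max
  min_ev <- function(gamma)
    min(eigen(G - gamma * m * Su, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- FALSE
  gamma <- 1
  if (min_ev(1) <= margin) {
    repaired <- TRUE
    warning("bias-corrected bread matrix is not positive definite ",
            "(weak instruments / overcorrection); capping the correction")
    lo <- 0; hi <- 1
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (min_ev(mid) > margin) lo <- mid else hi <- mid
    }
    gamma <- lo
  }
  H <- G - gamma * m * Su
  Hinv <- solve(H)
  theta <- drop(Hinv %*% crossprod(X, y))
  # sandwich covariance: estimating-function contributions
  # h_j = x_j e_j + Su theta  (the correction term restores E[h_j] = 0
  # under measurement error in x_j)
  e <- y - drop(X %*% theta)
  Tj <- X * e + matrix(rep(drop(Su %*% theta), each = m), m, p)
  meat <- crossprod(Tj)
  cov <- Hinv %*% meat %*% Hinv
  list(theta = theta, cov = (cov + t(cov)) / 2, repaired = repaired)
}

# iterative residual chi-square pleiotropy filter on the whitened scale
pleiotropy_prune_whitened <- function(X, y, Su, Sigma, p_threshold, pd_floor,
                                      max_rounds = 30L) {
  m <- nrow(X); p <- ncol(X)
  kept <- seq_len(m)
  for (round in seq_len(max_rounds)) {
    if (length(kept) < p + 1)
      stop("pleiotropy pruning removed too many instruments ",
           "(fewer than p + 1 remain); locus cannot be fit")
    fit <- mrbee_core(X[kept, , drop = FALSE], y[kept], Su, pd_floor)
    res <- y[kept] - drop(X[kept, , drop = FALSE] %*% fit$theta)
    # residual variance: outcome noise (unit, z-scale) + theta-weighted
    # eQTL estimation error; eQTL/outcome error cross-covariance taken as 0
    # (non-overlapping samples)
    v <- 1 + drop(crossprod(fit$theta, Sigma %*% fit$theta))
    pv <- stats::pchisq(res^2 / v, df = 1, lower.tail = FALSE)
    drop_now <- pv < p_threshold
    if (!any(drop_now)) break
    kept <- kept[!drop_now]
  }
  kept
}

#' Iterative pleiotropy pruning of an instrument set
#'
#' Standalone interface to the instrument filter used by [mrbee()]: fit the
#' bias-corrected model, test each instrument's residual
#' \eqn{\hat\alpha_j - \hat\beta_j^\top\hat\theta} against
#' \eqn{\chi^2_1}, drop instruments with p < `p_threshold`, and repeat until
#' the kept set is stable (at most 30 rounds).
#'
#' @inheritParams mrbee
#' @return Integer vector of kept row indices of `B`.
#' @export
pleiotropy_prune <- function(B, alpha_vec, R = NULL, bias = NULL,
                             p_threshold = 0.05) {
  if (inherits(B, "eqtl_matrix")) B <- eqtl_z(B)
  B <- as.matrix(B)
  if (inherits(alpha_vec, "outcome_vector")) alpha_vec <- alpha_vec$alpha / alpha_vec$se
  m <- nrow(B)
  M <- if (is.null(R)) diag(m) else sym_mat_power(unclass_ld(R), -0.5)
  Sigma <- if (is.null(bias)) matrix(0, ncol(B), ncol(B)) else bias$Sigma
  pleiotropy_prune_whitened(M %*% B, drop(M %*% as.numeric(alpha_vec)),
                            Sigma, Sigma, p_threshold, 1e-6)
}

#' Finite-reference-panel correction of MR test statistics
#'
#' When the LD matrix of m instruments is estimated from a reference panel
#' of n individuals, the naive t-statistic \eqn{L = \hat\theta / SE} has
#' mis-specified residual degrees of freedom and rejects too often. The
#' corrected statistic
#' \deqn{\tilde L = \sqrt{(n - m + 1)/n}\; L}
#' restores a t reference distribution. Two-sided p-values are computed from
#' t with `m - 1` degrees of freedom (the univariable convention; `"m-p"`
#' is available).
#'
#' @param theta coefficient vector.
#' @param cov_theta its covariance matrix (or a vector of squared SEs).
#' @param n_panel LD reference panel size; must exceed `m - 1`.
#' @param m number of instruments used.
#' @param p number of exposures (genes).
#' @param df_method `"m-1"` (default) or `"m-p"`.
#' @return List with `L`, `L_tilde`, `pvals`, and `df`.
#' @export
corrected_inference <- function(theta, cov_theta, n_panel, m, p = length(theta),
                                df_method = c("m-1", "m-p")) {
  df_method <- match.arg(df_method)
  if (n_panel <= m - 1)
    stop("reference panel size must exceed m - 1; prune the instrument set")
  se <- if (is.matrix(cov_theta)) sqrt(diag(cov_theta)) else sqrt(cov_theta)
  L <- theta / se
  L_tilde <- sqrt((n_panel - m + 1) / n_panel) * L
  df <- if (df_method == "m-1") m - 1 else m - p
  if (df < 1) stop("non-positive residual degrees of freedom")
  list(L = L, L_tilde = L_tilde,
       pvals = 2 * stats::pt(-abs(L_tilde), df = df), df = df)
}

# fit statistics on the whitened scale, uncentered (no-intercept) moments:
# with an exact least-squares theta the Pratt indices sum to the R-squared
locus_fit_stats_whitened <- function(X, y, theta) {
  tss <- sum(y^2)
  if (tss <= 0) stop("outcome has zero variance in this locus; skipping")
  res <- y - drop(X %*% theta)
  r2 <- 1 - sum(res^2) / tss
  cx <- sqrt(colSums(X^2))
  r_marg <- drop(crossprod(X, y)) / (cx * sqrt(tss))
  theta_std <- theta * cx / sqrt(tss)
  list(locus_r2 = r2, pratt = theta_std * r_marg)
}

#' Locus R-squared and per-gene Pratt indices
#'
#' Measures of model fit for a fitted locus: the share of (whitened) outcome
#' variation explained by the gene expression effects, and its per-gene
#' Pratt decomposition \eqn{Pratt_k = \tilde\theta_k r_k} (standardized
#' coefficient times marginal correlation), which sums to the locus
#' R-squared when \eqn{\hat\theta} solves the least-squares normal
#' equations.
#'
#' @inheritParams mrbee
#' @param theta fitted coefficient vector.
#' @return List with `locus_r2` and `pratt` (p-vector).
#' @export
locus_fit_stats <- function(B, alpha_vec, theta, R = NULL) {
  if (inherits(B, "eqtl_matrix")) B <- eqtl_z(B)
  B <- as.matrix(B)
  if (inherits(alpha_vec, "outcome_vector")) alpha_vec <- alpha_vec$alpha / alpha_vec$se
  m <- nrow(B)
  M <- if (is.null(R)) diag(m) else sym_mat_power(unclass_ld(R), -0.5)
  locus_fit_stats_whitened(M %*% B, drop(M %*% as.numeric(alpha_vec)), theta)
}

#' Generalized inverse-variance weighted (IVW) regression
#'
#' The uncorrected MR baseline: generalized least squares of the outcome
#' associations on the exposure associations with LD weighting,
#' \eqn{\hat\theta = (B^\top R^{-1} B)^{-1} B^\top R^{-1} \hat\alpha}.
#' Identical to [mrbee()] with \eqn{\Sigma = 0}.
#'
#' Standard errors follow one of two conventions: `"fixed"` (the standard
#' fixed-effect convention on the z-score scale, residual variance fixed at
#' 1) or `"estimated"` (studentized; residual variance estimated from the
#' whitened residuals with m - p degrees of freedom). The finite-panel
#' correction of [corrected_inference()] is calibrated for the studentized
#' form.
#'
#' @param beta m-vector or m x p matrix of exposure z-scores.
#' @param alpha_vec m-vector of outcome z-scores.
#' @param R LD matrix (`NULL` = identity, classic IVW).
#' @param resid_var `"fixed"` or `"estimated"`.
#' @return List with `theta`, `se`, `cov_theta`, `sigma2` (residual variance
#'   used), `m`, `p`.
#' @export
ivw_fit <- function(beta, alpha_vec, R = NULL,
                    resid_var = c("fixed", "estimated")) {
  resid_var <- match.arg(resid_var)
  B <- as.matrix(beta)
  y <- as.numeric(alpha_vec)
  m <- nrow(B); p <- ncol(B)
  if (!is.null(R)) {
    ci <- chol(unclass_ld(R))
    Xw <- backsolve(ci, B, transpose = TRUE)
    yw <- backsolve(ci, y, transpose = TRUE)
  } else {
    Xw <- B; yw <- y
  }
  XtX <- crossprod(Xw)
  theta <- drop(solve(XtX, crossprod(Xw, yw)))
  res <- yw - drop(Xw %*% theta)
  sigma2 <- if (resid_var == "fixed") 1 else sum(res^2) / (m - p)
  cov <- sigma2 * solve(XtX)
  list(theta = theta, se = sqrt(diag(cov)), cov_theta = cov,
       sigma2 = sigma2, m = m, p = p)
}

# ---- S3 methods for "mrbee" ------------------------------------------------

#' @export
print.mrbee <- function(x, digits = 4, ...) {
  cat("Bias-corrected multivariable MR (MRBEE)\n")
  cat(sprintf("  %d instruments kept (of %d), %d genes, locus R-squared = %.3f\n",
              x$m, x$m_input, x$p, x$locus_r2))
  print(round(x$theta, digits))
  invisible(x)
}

#' Summarize a fitted MRBEE model
#'
#' @param object an `"mrbee"` fit.
#' @param ... unused.
#' @return An object of class `"summary.mrbee"`: the coefficient table plus
#'   fit statistics.
#' @export
summary.mrbee <- function(object, ...) {
  tab <- data.frame(estimate = object$theta,
                    se = object$se,
                    L = object$L,
                    row.names = names(object$theta))
  if (!is.null(object$L_tilde)) tab$L_tilde <- object$L_tilde
  tab$p_value <- object$pvals
  tab$pratt <- object$pratt
  structure(list(coefficients = tab, locus_r2 = object$locus_r2,
                 m = object$m, m_input = object$m_input, p = object$p,
                 n_panel = object$n_panel, df_resid = object$df_resid,
                 bread_repaired = object$bread_repaired, call = object$call),
            class = "summary.mrbee")
}

#' @export
print.summary.mrbee <- function(x, digits = 4, ...) {
  cat("Bias-corrected multivariable MR (MRBEE)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\nInstruments: %d kept of %d; genes: %d; residual df: %d\n",
              x$m, x$m_input, x$p, x$df_resid))
  if (!is.null(x$n_panel))
    cat(sprintf("LD reference panel size: %d (finite-panel corrected inference)\n",
                x$n_panel))
  if (x$bread_repaired)
    cat("NOTE: bias-corrected bread matrix required an eigenvalue repair\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nLocus R-squared: %.4f (Pratt sum %.4f)\n",
              x$locus_r2, sum(x$coefficients$pratt)))
  invisible(x)
}

#' @export
coef.mrbee <- function(object, ...) object$theta

#' @export
vcov.mrbee <- function(object, ...) object$cov_theta

#' @export
fitted.mrbee <- function(object, ...) object$fitted_w

#' @export
residuals.mrbee <- function(object, ...) object$residuals_w

#' @export
predict.mrbee <- function(object, newdata = NULL, ...) {
  B <- if (is.null(newdata)) object$B[object$kept_idx, , drop = FALSE]
       else as.matrix(newdata)
  drop(B %*% object$theta)
}

#' Simulate outcome association vectors from a fitted MRBEE model
#'
#' Draws \eqn{\alpha^{sim} \sim N(B\hat\theta, R)} on the z-score scale,
#' using the instruments kept in the fit.
#'
#' @param object an `"mrbee"` fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return m x nsim matrix of simulated outcome z-scores.
#' @export
simulate.mrbee <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- object$kept_idx
  mu <- drop(object$B[k, , drop = FALSE] %*% object$theta)
  cR <- chol(object$R[k, k, drop = FALSE])
  mu + crossprod(cR, matrix(stats::rnorm(length(k) * nsim), length(k), nsim))
}

#' @export
plot.mrbee <- function(x, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = x$df_resid)
  lo <- x$theta - q * x$se
  hi <- x$theta + q * x$se
  p <- length(x$theta)
  graphics::plot(x$theta, seq_len(p), xlim = range(c(lo, hi, 0)),
                 yaxt = "n", ylab = "", xlab = "causal effect (z-scale)",
                 pch = 19, ...)
  graphics::segments(lo, seq_len(p), hi, seq_len(p))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(p),
                 labels = names(x$theta) %||% seq_len(p), las = 1)
  invisible(x)
}

#' @export
confint.mrbee <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_resid)
  ci <- cbind(object$theta - q * object$se, object$theta + q * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  rownames(ci) <- names(object$theta)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

`%||%` <- function(a, b) if (is.null(a)) b else a
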