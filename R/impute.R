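#' @title Imputation of block-missing cis-eQTL effect matrices
#' @name impute
#' @description
#' Public cis-eQTL summary files only report SNP-gene pairs inside a cis
#' window, so the union instrument set of a multi-gene locus yields an
#' effect matrix with structured (banded) missingness. These functions
#' complete that matrix so every SNP in the union set can serve as an
#' instrument for every gene. All of them return an `"impute_result"`:
#' the completed matrix plus convergence bookkeeping.
NULL

impute_result <- function(completed, iterations, final_change, method,
                          converged = TRUE, extra = list()) {
  structure(c(list(completed = completed, iterations = iterations,
                   final_change = final_change, method = method,
                   converged = converged), extra),
            class = "impute_result")
}

#' @export
print.impute_result <- function(x, ...) {
  cat(sprintf("imputation (%s): %d x %d matrix, %d iteration(s), final change %.3g%s\n",
              x$method, nrow(x$completed), ncol(x$completed), x$iterations,
              x$final_change, if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# accept either an eqtl_matrix (values = z-scores beta/se) or a plain
# matrix with NAs marking missing entries
as_masked_matrix <- function(B) {
  if (inherits(B, "eqtl_matrix")) {
    list(x = eqtl_z(B), mask = B$mask)
  } else {
    x <- as.matrix(B)
    list(x = x, mask = !is.na(x))
  }
}

#' Zero imputation
#'
#' Sets every unobserved entry to 0 (the marginal null expectation of a
#' z-score outside the cis window).
#'
#' @param B an [eqtl_matrix()] (imputed on the z-score scale) or a numeric
#'   matrix with `NA`s marking missing entries.
#' @return An `"impute_result"`.
#' @export
zero_impute <- function(B) {
  mm <- as_masked_matrix(B)
  x <- mm$x
  x[!mm$mask] <- 0
  impute_result(x, 0L, 0, "zero")
}

# core iterative singular-value soft-thresholding loop: starts from `start`
# (missing entries already initialized), holds entries where `mask` is TRUE
# fixed at `targets` (defaults to their values in `start`).
svt_loop <- function(start, mask, lam, eps, max_iter, targets = NULL) {
  B <- start
  obs_vals <- if (is.null(targets)) start[mask] else targets
  it <- 0L
  change <- Inf
  history <- numeric(0)
  repeat {
    s <- svd(B)
    d <- pmax(s$d - lam, 0)
    Bn <- s$u %*% (d * t(s$v))
    Bn[mask] <- obs_vals
    change <- sqrt(sum((Bn - B)^2))
    B <- Bn
    it <- it + 1L
    history[it] <- change
    if (change <= eps || it >= max_iter) break
  }
  list(B = B, iterations = it, change = change, history = history)
}

# hold out 10% of observed entries and pick the lambda minimizing error on
# them; `fit` maps (matrix-with-NAs, lambda) to a completed matrix
select_lambda <- function(x, mask, lambda_grid, fit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- which(mask)
  if (length(obs) < 20L) return(lambda_grid[1])
  ho <- sample(obs, max(2L, round(0.1 * length(obs))))
  x_tr <- x
  x_tr[ho] <- NA_real_
  mask_tr <- mask
  mask_tr[ho] <- FALSE
  # guard: hold-out must not empty any column
  bad <- colSums(mask_tr) == 0
  if (any(bad)) {
    ho_col <- ((ho - 1L) %/% nrow(x)) + 1L
    put_back <- ho[ho_col %in% which(bad)]
    mask_tr[put_back] <- TRUE
    x_tr[put_back] <- x[put_back]
    ho <- setdiff(ho, put_back)
  }
  err <- vapply(lambda_grid, function(l) {
    comp <- fit(x_tr, mask_tr, l)
    sqrt(mean((comp[ho] - x[ho])^2))
  }, numeric(1))
  lambda_grid[which.min(err)]
}

default_lambda_grid <- function(x, mask) {
  x0 <- x
  x0[!mask] <- 0
  dmax <- svd(x0, nu = 0, nv = 0)$d[1]
  c(0, dmax * c(0.01, 0.025, 0.05, 0.1, 0.2, 0.4))
}

#' Soft-impute matrix completion
#'
#' Iterative singular-value soft-thresholding: replace missing entries with
#' the current low-rank reconstruction, observed entries stay fixed at their
#' input values, singular values are shrunk by \eqn{\lambda} each iteration
#' until the Frobenius change falls below `eps`.
#'
#' @inheritParams zero_impute
#' @param lam soft-threshold penalty \eqn{\lambda \ge 0}; `NULL` selects it
#'   by minimizing held-out error on 10\% of re-masked observed entries. A
#'   decreasing vector runs warm-started continuation (each penalty starts
#'   from the previous solution), the standard route to the
#'   minimal-nuclear-norm completion as \eqn{\lambda \to 0}.
#' @param eps convergence tolerance on the Frobenius change between
#'   iterations; default \eqn{10^{-6} \|B^{(0)}\|_F}.
#' @param max_iter iteration cap (default 500).
#' @param seed optional seed for the hold-out used in \eqn{\lambda}
#'   selection.
#' @return An `"impute_result"` with element `lambda`.
#' @export
soft_impute <- function(B, lam = NULL, eps = NULL, max_iter = 500L,
                        seed = NULL) {
  mm <- as_masked_matrix(B)
  x <- mm$x; mask <- mm$mask
  x0 <- x
  x0[!mask] <- 0
  if (is.null(eps)) eps <- 1e-6 * sqrt(sum(x0^2))
  if (is.null(lam)) {
    lam <- select_lambda(x, mask, default_lambda_grid(x, mask),
                         function(xt, mt, l) {
                           st <- xt; st[!mt] <- 0
                           svt_loop(st, mt, l, eps, max_iter)$B
                         }, seed = seed)
  }
  lam <- sort(lam, decreasing = TRUE)
  res <- svt_loop(x0, mask, lam[1], eps, max_iter)
  for (l in lam[-1]) res <- svt_loop(res$B, mask, l, eps, max_iter)
  if (res$iterations >= max_iter && res$change > eps)
    warning("soft_impute did not converge in ", max_iter, " iterations")
  impute_result(res$B, res$iterations, res$change, "soft",
                converged = res$change <= eps,
                extra = list(lambda = lam[length(lam)],
                             history = res$history))
}

#' LD- and noise-aware matrix completion (MV-Imp)
#'
#' Matrix completion for the whitened effect matrix
#' \eqn{\Theta^{1/2} \hat B} (\eqn{\Theta} = inverse LD matrix): after
#' zero-initializing missing entries and whitening, the total singular-value
#' mass is deflated by the estimation-noise share
#' \eqn{a = 1 - \sum_k \eta_k / \sum_k d_k}, where \eqn{\eta_k} are the
#' singular values of the scaled measurement-error matrix
#' \eqn{m\Sigma}. The deflated reconstruction initializes the missing
#' entries; iterative singular-value soft-thresholding then completes the
#' matrix on the whitened scale, holding the (raw whitened) observed entries
#' fixed, and the result is de-whitened with \eqn{\Theta^{-1/2}}. With a
#' fully observed matrix the procedure therefore returns its input exactly.
#'
#' If the noise mass exceeds the total signal (\eqn{a \le 0}) the method
#' falls back to zero imputation with a warning.
#'
#' @inheritParams soft_impute
#' @param Theta inverse LD matrix \eqn{\Theta = R_\lambda^{-1}} for the SNPs
#'   (rows) of `B`. Must be positive definite; see [regularize_pd()].
#' @param bias a [bias_matrix()] (or `NULL` for no deflation, \eqn{\eta = 0}).
#' @return An `"impute_result"` with elements `lambda` and `deflation`.
#' @export
mv_impute <- function(B, Theta, bias = NULL, lam = NULL, eps = NULL,
                      max_iter = 500L, seed = NULL) {
  mm <- as_masked_matrix(B)
  x <- mm$x; mask <- mm$mask
  m <- nrow(x); p <- ncol(x)
  Theta <- unclass_ld(Theta)
  ev <- eigen(Theta, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("Theta is not positive definite; regularize the LD matrix first ",
         "(regularize_pd) and invert that")
  Th_half <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  Th_neg_half <- ev$vectors %*% ((1 / sqrt(ev$values)) * t(ev$vectors))

  # noise singular values of the zero-filled whitened matrix: its expected
  # noise Gram is N o Sigma with N the effective co-observation counts
  if (is.null(bias)) {
    eta <- rep(0, p)
  } else {
    A <- Theta * solve(Theta)        # elementwise (R^-1)_ij R_ij
    N <- t(mask * 1) %*% A %*% (mask * 1)
    eta <- sqrt(pmax(eigen(N * bias$Sigma, symmetric = TRUE,
                           only.values = TRUE)$values, 0))
  }

  x0 <- x
  x0[!mask] <- 0
  W0 <- Th_half %*% x0               # whitened, zero-filled
  sv <- svd(W0)
  a <- 1 - sum(eta) / sum(sv$d)
  if (a <= 0) {
    warning("estimation-noise mass exceeds total signal (deflation factor <= 0); ",
            "falling back to zero imputation")
    res <- zero_impute(B)
    res$method <- "mv (zero fallback)"
    return(res)
  }
  a <- min(a, 1)
  W_init <- sv$u %*% ((a * sv$d) * t(sv$v))  # deflated initialization
  raw_obs <- W0[mask]                        # reset targets: raw whitened values

  if (is.null(eps)) eps <- 1e-6 * sqrt(sum(W0^2))
  if (is.null(lam)) {
    # lambda selected on the whitened scale by held-out error
    lam <- select_lambda(W0, mask, default_lambda_grid(W0, mask),
                         function(xt, mt, l) {
                           st <- xt; st[!mt] <- 0
                           svt_loop(st, mt, l, eps, max_iter)$B
                         }, seed = seed)
  }
  res <- svt_loop(W_init, mask, lam, eps, max_iter, targets = raw_obs)
  if (res$iterations >= max_iter && res$change > eps)
    warning("mv_impute did not converge in ", max_iter, " iterations")
  out <- Th_neg_half %*% res$B
  dimnames(out) <- dimnames(x)
  impute_result(out, res$iterations, res$change, "mv",
                converged = res$change <= eps,
                extra = list(lambda = lam, deflation = a,
                             history = res$history))
}

#' Conditional-normal (gene-pairwise) imputation
#'
#' Per gene, missing z-scores are imputed as their conditional mean given
#' the observed z-scores of the same gene under the null working model
#' \eqn{z \sim N(0, R)}:
#' \eqn{\hat z_{miss} = R_{mo} R_{oo}^{-1} z_{obs}}.
#'
#' @inheritParams zero_impute
#' @param R LD matrix covering the SNPs (rows) of `B`.
#' @param ridge added to the diagonal of \eqn{R_{oo}} if it is numerically
#'   singular (a minimal regularization; default 0, escalated automatically).
#' @return An `"impute_result"`.
#' @export
normal_impute <- function(B, R, ridge = 0) {
  mm <- as_masked_matrix(B)
  x <- mm$x; mask <- mm$mask
  R <- unclass_ld(R)
  if (nrow(R) != nrow(x)) stop("'R' must cover the SNPs of 'B'")
  out <- x
  for (k in seq_len(ncol(x))) {
    miss <- !mask[, k]
    if (!any(miss)) next
    obs <- which(!miss)
    if (length(obs) == 0L) { out[miss, k] <- 0; next }
    Roo <- R[obs, obs, drop = FALSE] + ridge * diag(length(obs))
    Rmo <- R[which(miss), obs, drop = FALSE]
    sol <- tryCatch(solve(Roo, x[obs, k]), error = function(e) NULL)
    if (is.null(sol)) {
      Roo_reg <- unclass_ld(regularize_pd(ld_matrix(stats::cov2cor(Roo)), 1e-3))
      sol <- solve(Roo_reg, x[obs, k])
    }
    out[which(miss), k] <- drop(Rmo %*% sol)
  }
  impute_result(out, 1L, 0, "normal")
}
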