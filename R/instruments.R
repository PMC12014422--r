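#' Measurement-error correlation of eQTL effect estimates
#'
#' Container for the p x p correlation matrix \eqn{\Sigma} of the estimation
#' errors of a SNP's vector of eQTL z-scores across p genes. Errors are
#' correlated across genes because the same individuals contribute to every
#' gene's GWAS. Scaled by the instrument count m, \eqn{m\Sigma} is the weak
#' instrument bias matrix whose singular values \eqn{\eta_k} drive both the
#' deflation step of [mv_impute()] and the bias correction of [mrbee()].
#'
#' @param Sigma symmetric positive semi-definite matrix with unit diagonal.
#' @return An object of class `"bias_matrix"`.
#' @export
bias_matrix <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma) || max(abs(Sigma - t(Sigma))) > 1e-8)
    stop("'Sigma' must be a symmetric square matrix")
  if (any(abs(diag(Sigma) - 1) > 1e-6))
    stop("'Sigma' must have unit diagonal (z-score error correlation)")
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("'Sigma' must be positive semi-definite")
  structure(list(Sigma = Sigma), class = "bias_matrix")
}

#' @export
print.bias_matrix <- function(x, ...) {
  p <- ncol(x$Sigma)
  off <- if (p > 1) max(abs(x$Sigma[upper.tri(x$Sigma)])) else 0
  cat(sprintf("measurement-error correlation: %d genes, max |off-diagonal| = %.3f\n",
              p, off))
  invisible(x)
}

# noise singular values implied by a scaled bias (Gram) matrix S: for an
# error matrix E with E[E'E] = S, the expected singular values of E are the
# square roots of the eigenvalues of S (a Gram matrix's eigenvalues live on
# the squared singular-value scale)
bias_eta <- function(bias, m) {
  sort(sqrt(m * pmax(svd(bias$Sigma, nu = 0, nv = 0)$d, 0)),
       decreasing = TRUE)
}

#' Estimate the measurement-error correlation from insignificant z-scores
#'
#' Uses the "insignificant eQTL effect estimates" device: SNP rows whose
#' squared z-scores are all below the `q`-quantile of \eqn{\chi^2_1} carry
#' (essentially) pure estimation noise, so their sample correlation across
#' genes estimates \eqn{\Sigma}. Rows must be null for *all* p genes to
#' enter.
#'
#' The raw sample correlation from few rows is itself noisy, and noise in
#' \eqn{\Sigma} translates directly into over- or under-correction of the
#' MRBEE bread matrix. The estimate is therefore shrunk towards the
#' identity with a Ledoit-Wolf intensity
#' \eqn{w = \min(1, \sum_{k \neq l} \widehat{Var}(r_{kl}) / \sum_{k \neq l}
#' r_{kl}^2)} before use (`shrink = FALSE` disables this).
#'
#' @param Z m x p matrix of eQTL z-scores (`NA`s allowed; rows with any `NA`
#'   are not used).
#' @param q chi-square quantile defining "insignificant" (default 0.95).
#' @param shrink apply Ledoit-Wolf shrinkage towards the identity?
#' @return A [bias_matrix()] with attributes `n_rows` (rows used) and
#'   `shrinkage`. If fewer than p + 1 usable rows exist the identity is
#'   returned with a warning.
#' @export
estimate_bias_matrix <- function(Z, q = 0.95, shrink = TRUE) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  cut <- stats::qchisq(q, df = 1)
  ok <- rowSums(is.na(Z)) > 0
  ok <- !ok & rowSums(Z^2 >= cut, na.rm = TRUE) == 0
  if (sum(ok) < p + 1) {
    warning("fewer than p + 1 fully insignificant SNP rows; ",
            "using the identity for the error correlation")
    out <- bias_matrix(diag(p))
    attr(out, "n_rows") <- sum(ok); attr(out, "shrinkage") <- 1
    return(out)
  }
  n_ok <- sum(ok)
  S <- stats::cor(Z[ok, , drop = FALSE])
  if (p == 1) S <- matrix(1, 1, 1)
  w <- 0
  if (shrink && p > 1) {
    r2 <- S[upper.tri(S)]^2
    v <- (1 - r2)^2 / n_ok
    w <- if (sum(r2) > 0) min(1, sum(v) / sum(r2)) else 1
    S <- (1 - w) * S + w * diag(p)
  }
  # guard against numerically indefinite sample correlations
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) {
    S <- unclass_ld(regularize_pd(ld_matrix(S), 1e-6))
  }
  out <- bias_matrix(S)
  attr(out, "n_rows") <- n_ok
  attr(out, "shrinkage") <- w
  out
}

#' Effective instrument counts for the weak-instrument correction
#'
#' With fully observed data the weak-instrument bias matrix is
#' \eqn{m\Sigma}. When some entries were unobserved (zero-filled or
#' imputed), those entries carry no fresh estimation noise, so the
#' effective noise Gram matrix is smaller: its (k, l) scale is
#' \eqn{N_{kl} = \sum_{i \in obs_k}\sum_{j \in obs_l} (R^{-1})_{ij} R_{ij}}
#' under LD whitening (which reduces to the co-observation count
#' \eqn{|obs_k \cap obs_l|} for R = I, and to m for complete data). The
#' elementwise product \eqn{N \circ \Sigma} replaces \eqn{m\Sigma} in
#' [mrbee()] and in the deflation step of [mv_impute()].
#'
#' @param mask m x p logical observation mask.
#' @param R optional LD matrix of the m SNPs (`NULL` = identity).
#' @return p x p matrix of effective counts.
#' @export
bias_scale_matrix <- function(mask, R = NULL) {
  mask <- as.matrix(mask) * 1
  if (is.null(R)) return(crossprod(mask))
  Rm <- unclass_ld(R)
  A <- solve(Rm) * Rm       # elementwise product of R^-1 and R
  t(mask) %*% A %*% mask
}

#' Joint test of association across all genes of a locus
#'
#' Tests whether a SNP is associated with at least one of the p gene
#' expressions via the quadratic form
#' \eqn{T_j = \hat\beta_j^\top \Sigma^{-1} \hat\beta_j}, compared to the
#' \eqn{(1-\alpha)}-quantile of \eqn{\chi^2_p}. Rows must be on the z-score
#' scale so that the error correlation \eqn{\Sigma} is their covariance
#' under the null.
#'
#' @param beta_row p-vector of z-scores for one SNP.
#' @param Sigma a [bias_matrix()] (or plain p x p matrix).
#' @param alpha significance level; the software default is genome-wide
#'   (5e-8). For locus-level screens a more permissive preset is common;
#'   see [joint_test_alpha()].
#' @return List with elements `statistic` and `selected`.
#' @export
joint_iv_test <- function(beta_row, Sigma, alpha = 5e-8) {
  S <- if (inherits(Sigma, "bias_matrix")) Sigma$Sigma else as.matrix(Sigma)
  p <- length(beta_row)
  stopifnot(ncol(S) == p)
  sol <- tryCatch(solve(S, beta_row), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular error correlation in joint test; using a regularized solve")
    S <- unclass_ld(regularize_pd(ld_matrix(S), 1e-6))
    sol <- solve(S, beta_row)
  }
  stat <- drop(crossprod(beta_row, sol))
  list(statistic = stat,
       selected = stat > stats::qchisq(1 - alpha, df = p))
}

#' Preset significance levels for the joint instrument test
#'
#' `"genomewide"` is the software default (5e-8); `"locus"` is the more
#' permissive application-scale preset (5e-3) appropriate when loci were
#' pre-selected by outcome significance.
#'
#' @param preset `"genomewide"` or `"locus"`.
#' @return Numeric significance level.
#' @export
joint_test_alpha <- function(preset = c("genomewide", "locus")) {
  switch(match.arg(preset), genomewide = 5e-8, locus = 5e-3)
}

#' Select instruments by the joint association test
#'
#' Applies [joint_iv_test()] to every row of a completed (no missing
#' entries) z-score matrix.
#'
#' @param Z m x p matrix of z-scores with no missing entries (e.g. the
#'   `completed` element of an `"impute_result"`), or a fully observed
#'   [eqtl_matrix()].
#' @param Sigma a [bias_matrix()].
#' @param alpha significance level (default genome-wide 5e-8).
#' @return Character vector of selected SNP ids (row names), or integer
#'   indices if the matrix has no row names. Empty selection gives a
#'   zero-length result with a message.
#' @export
select_ivs <- function(Z, Sigma, alpha = 5e-8) {
  if (inherits(Z, "eqtl_matrix")) {
    if (!all(Z$mask)) stop("eQTL matrix still has missing entries; impute first")
    Z <- eqtl_z(Z)
  }
  Z <- as.matrix(Z)
  if (anyNA(Z)) stop("'Z' must be complete (impute missing entries first)")
  S <- if (inherits(Sigma, "bias_matrix")) Sigma$Sigma else as.matrix(Sigma)
  crit <- stats::qchisq(1 - alpha, df = ncol(Z))
  Sinv_Zt <- solve(S, t(Z))
  stats_vec <- colSums(t(Z) * Sinv_Zt)
  sel <- stats_vec > crit
  if (!any(sel)) message("joint test selected no instruments at alpha = ", alpha)
  ids <- rownames(Z)
  if (is.null(ids)) which(sel) else ids[sel]
}

#' Filter instruments in LD with outside SNPs (correlated pleiotropy guard)
#'
#' Correlated horizontal pleiotropy arises when an instrument tags (is in LD
#' with) a causal SNP that is not itself in the instrument set. This filter
#' drops every instrument whose squared correlation with *any* non-instrument
#' SNP located within `flank` bp of the locus boundary exceeds `kappa`.
#'
#' @param S character vector of instrument SNP ids.
#' @param locus a `"locus"` object from [build_loci()] (or `NULL` to use
#'   every non-instrument SNP in `ld_source`).
#' @param ld_source an `"ld_panel"`, an [ld_matrix()], or a plain
#'   correlation matrix covering the instruments and flanking SNPs; row
#'   names are SNP ids.
#' @param snp_pos optional data frame (`id`, `pos`) giving positions used to
#'   restrict flanking SNPs to the window; without positions all
#'   non-instrument SNPs in `ld_source` are treated as flanking.
#' @param kappa squared-correlation threshold (default \eqn{0.5^2}).
#' @param flank flanking width in bp around the locus boundary (default
#'   2 Mb).
#' @return Character vector: the surviving instrument ids (subset of `S`).
#' @export
chp_filter <- function(S, locus = NULL, ld_source, snp_pos = NULL,
                       kappa = 0.25, flank = 2e6) {
  R <- if (inherits(ld_source, "ld_panel")) {
    unclass_ld(estimate_ld(ld_source))
  } else {
    unclass_ld(ld_source)
  }
  ids <- rownames(R)
  if (is.null(ids)) stop("'ld_source' must carry SNP ids as row names")
  S <- intersect(S, ids)
  outside <- setdiff(ids, S)
  if (!is.null(snp_pos) && !is.null(locus)) {
    lo <- locus$boundary$start - flank
    hi <- locus$boundary$end + flank
    pos <- snp_pos$pos[match(outside, snp_pos$id)]
    outside <- outside[!is.na(pos) & pos >= lo & pos <= hi]
  }
  if (length(outside) == 0L) {
    warning("no flanking non-instrument SNPs available; CHP filter is a no-op")
    return(S)
  }
  r2 <- R[S, outside, drop = FALSE]^2
  S[apply(r2, 1, max) <= kappa]
}
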