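#' Simulation configuration
#'
#' Bundles the study conditions of the validation experiments. Defaults are
#' the conditions of the published experiments: 500 eQTLs with AR(1)
#' LD at correlation 0.5 and a reference-panel (Wishart degrees of freedom)
#' grid for the inflation experiment; 9 genes, ~526 cis-eQTLs, a +/-1 Mb
#' cis window and AR(1) LD at 0.5 for the imputation experiment; 1000
#' replicates; causal effect 0.3 where one is needed.
#'
#' @param m number of SNPs.
#' @param p number of genes.
#' @param rho AR(1) LD correlation parameter (|rho| < 1).
#' @param df_grid Wishart degrees-of-freedom grid (= emulated reference
#'   panel sizes); `Inf` entries mean "use the true LD matrix".
#' @param n_reps simulation replicates.
#' @param theta true causal effect used where the design is non-null.
#' @param window cis-window half width in bp.
#' @param prune_r2 LD pruning threshold on r-squared.
#' @param level nominal test level.
#' @param m_impute number of cis-eQTLs in the imputation experiment locus.
#' @param signal_sd z-score scale of the true eQTL signal at signal-carrying
#'   SNPs in the imputation experiment.
#' @param support_frac fraction of SNP rows carrying eQTL signal (signals
#'   cluster; most SNPs in a window are null).
#' @param seed integer seed making every experiment exactly reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(m = 500, p = 9, rho = 0.5,
                       df_grid = c(500, 1000, 3000, 5000),
                       n_reps = 1000, theta = 0.3, window = 1e6,
                       prune_r2 = 0.09, level = 0.05, m_impute = 526,
                       signal_sd = 2, support_frac = 0.3, seed = 1) {
  stopifnot(m > 0, p > 0, abs(rho) < 1, n_reps > 0, level > 0, level < 1)
  structure(list(m = m, p = p, rho = rho, df_grid = df_grid,
                 n_reps = n_reps, theta = theta, window = window,
                 prune_r2 = prune_r2, level = level, m_impute = m_impute,
                 signal_sd = signal_sd, support_frac = support_frac,
                 seed = seed),
            class = "sim_config")
}

#' AR(1) LD matrix
#'
#' First-order autoregressive correlation structure
#' \eqn{R_{ij} = \rho^{|i-j|}}, the standard stylized model of local LD
#' decay along a chromosome.
#'
#' @param m dimension.
#' @param rho correlation parameter, |rho| < 1.
#' @return An exact [ld_matrix()] (no reference sample size).
#' @export
gen_ar1_ld <- function(m, rho) {
  stopifnot(abs(rho) < 1)
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ld_matrix(R)
}

#' Draw null standardized effects
#'
#' True eQTL and outcome standardized effect (z-score) vectors drawn from
#' independent multivariate normal distributions with mean 0 and covariance
#' R; under this null the true causal effect is 0.
#'
#' @param R LD matrix (positive definite).
#' @param p number of gene columns for the eQTL matrix.
#' @param seed optional seed.
#' @return List with `B` (m x p) and `alpha` (m-vector).
#' @export
gen_null_effects <- function(R, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Rm <- unclass_ld(R)
  m <- nrow(Rm)
  cR <- chol(Rm)
  draws <- crossprod(cR, matrix(stats::rnorm(m * (p + 1)), m, p + 1))
  list(B = draws[, seq_len(p), drop = FALSE], alpha = draws[, p + 1])
}

#' cis-window missingness mask
#'
#' `TRUE` (observed) exactly when SNP j lies within `window` bp of gene k's
#' TSS (closed window), reproducing the banded missingness of public
#' cis-eQTL summary files.
#'
#' @param m,p dimensions (consistency check against `positions`/`tss_list`).
#' @param positions SNP base-pair positions (length m).
#' @param tss_list gene TSS positions (length p).
#' @param window half width in bp (default 1 Mb).
#' @return m x p logical matrix.
#' @export
gen_cis_missing <- function(m, p, positions, tss_list, window = 1e6) {
  stopifnot(length(positions) == m, length(tss_list) == p)
  abs(outer(positions, tss_list, "-")) <= window
}

# fast univariable GLS slope on a pre-choleskied LD matrix; returns the
# standard fixed-effect z-scale statistic and the studentized one
ivw_both_stats <- function(beta, alpha, cholW) {
  bw <- backsolve(cholW, beta, transpose = TRUE)
  aw <- backsolve(cholW, alpha, transpose = TRUE)
  btb <- sum(bw^2)
  theta <- sum(bw * aw) / btb
  mk <- length(beta)
  rss <- sum((aw - bw * theta)^2)
  s2 <- rss / (mk - 1)
  c(theta = theta,
    L_fixed = theta * sqrt(btb),
    L_stud = theta / sqrt(s2 / btb))
}

#' Type-I error of MR tests under an LD matrix estimated from a finite panel
#'
#' Reproduces the LD-misspecification experiment: the true LD matrix of
#' `m` eQTLs is AR(1) with parameter `rho`; each replicate draws null
#' standardized effects from N(0, R), estimates LD by a Wishart draw with
#' the given degrees of freedom (= panel size), LD-prunes the instrument
#' set (priority = eQTL significance), and fits univariable IVW with the
#' estimated LD. Rejection of the causal null at the nominal level is
#' recorded for
#' \itemize{
#'   \item `L`: the standard IVW statistic (fixed-effect convention,
#'     residual variance 1 on the z-score scale) against t(m'-1), and
#'   \item `L_tilde`: the finite-panel-corrected statistic
#'     \eqn{\sqrt{(n-m'+1)/n}} times the studentized IVW t-statistic,
#'     against t(m'-1),
#' }
#' where m' is the post-pruning instrument count. The correction factor is
#' calibrated for the studentized form (see the methods vignette), which is
#' why the corrected statistic is built from it.
#'
#' `Inf` in the df grid runs the correctly-specified limit (true R used,
#' no correction), where both statistics are nominal.
#'
#' @param config a [sim_config()]; fields used: `m`, `rho`, `df_grid`,
#'   `n_reps`, `prune_r2`, `level`, `seed`.
#' @return A data.frame of class `"inflation_experiment"` with one row per
#'   df: rejection rates for both statistics, their binomial standard
#'   errors, and the mean post-pruning instrument count.
#' @export
run_inflation_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  m <- config$m
  R <- unclass_ld(gen_ar1_ld(m, config$rho))
  cR <- chol(R)
  crit_of <- function(mk) stats::qt(1 - config$level / 2, df = mk - 1)
  rows <- lapply(config$df_grid, function(df) {
    rejL <- rejLt <- logical(config$n_reps)
    mks <- integer(config$n_reps)
    for (r in seq_len(config$n_reps)) {
      eff <- gen_null_effects(R, p = 1)
      beta <- drop(eff$B); alpha <- eff$alpha
      if (is.finite(df)) {
        W <- stats::cov2cor(rwishart_chol(df, cR) / df)
      } else {
        W <- R
      }
      kept <- ld_prune(W, abs(beta), config$prune_r2)
      mk <- length(kept)
      mks[r] <- mk
      cholW <- chol(W[kept, kept, drop = FALSE])
      st <- ivw_both_stats(beta[kept], alpha[kept], cholW)
      crit <- crit_of(mk)
      rejL[r] <- abs(st["L_fixed"]) > crit
      cf <- if (is.finite(df)) sqrt((df - mk + 1) / df) else 1
      rejLt[r] <- abs(cf * st["L_stud"]) > crit
    }
    n <- config$n_reps
    data.frame(df = df,
               type1_L = mean(rejL),
               se_L = sqrt(mean(rejL) * (1 - mean(rejL)) / n),
               type1_L_tilde = mean(rejLt),
               se_L_tilde = sqrt(mean(rejLt) * (1 - mean(rejLt)) / n),
               mean_m_kept = mean(mks),
               n_reps = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inflation_experiment", "data.frame")
  out
}

# staircase locus geometry shared by the imputation experiment and tests:
# SNPs uniform over a region, TSSs evenly spaced in its interior so that
# the union set covers all SNPs while the intersection set is small
imputation_geometry <- function(m, p, window = 1e6, span_factor = 3.6) {
  span <- span_factor * window
  positions <- seq(1, span, length.out = m)
  tss <- seq(window, span - window, length.out = p)
  mask <- gen_cis_missing(m, p, positions, tss, window)
  list(positions = positions, tss = tss, mask = mask)
}

#' Imputation error and MVMR power across missing-data methods
#'
#' Reproduces the missing-data experiment: a locus of `p` genes and `m`
#' cis-eQTLs with AR(1) LD, whose true eQTL z-score matrix mixes low-rank
#' (co-regulation) structure with gene-specific signal (weight
#' `indep_frac`) plus LD-correlated estimation noise, and is masked
#' outside the +/-1 Mb cis window of each TSS. Each replicate imputes the
#' masked matrix with all four methods and records the Frobenius error over
#' the missing entries against the held-out z-scores. The replicate also
#' fits the bias-corrected MVMR model for a single causal gene (effect
#' `theta`) on (a) the imputed union instrument set and (b) the
#' complete-case intersection set, recording rejection of that gene's
#' causal null.
#'
#' @param config a [sim_config()]; fields used: `m_impute`, `p`, `rho`,
#'   `n_reps`, `theta`, `window`, `level`, `signal_sd`, `support_frac`,
#'   `seed`.
#' @param rank rank of the shared (co-regulation) signal component.
#' @param indep_frac share of signal variance that is gene-specific; keeps
#'   the MVMR design identifiable (a purely low-rank signal would make the
#'   gene columns collinear).
#' @param span_factor locus span as a multiple of the cis window; the
#'   default staircase geometry (3.6) yields the banded mask with a small
#'   complete-case core, while values of 2 or less make every pair
#'   observed.
#' @return A list of class `"imputation_experiment"`: `errors` (data frame
#'   of mean missing-entry Frobenius errors with Monte-Carlo SEs, by
#'   method), `power` (union vs intersection rejection rates with binomial
#'   SEs), and `missing_fraction`.
#' @export
run_imputation_experiment <- function(config = sim_config(), rank = 3,
                                      indep_frac = 0.3, span_factor = 3.6) {
  set.seed(config$seed)
  m <- config$m_impute
  p <- config$p
  geo <- imputation_geometry(m, p, config$window, span_factor)
  mask <- geo$mask
  R <- unclass_ld(gen_ar1_ld(m, config$rho))
  cR <- chol(R)
  Theta <- chol2inv(cR)
  Minv_half <- sym_mat_power(R, -0.5)      # whitening, fixed across reps
  Nmat <- bias_scale_matrix(mask, gen_ar1_ld(m, config$rho))
  inter <- which(rowSums(mask) == p)
  if (length(inter) <= p + 1)
    stop("intersection instrument set too small for the chosen geometry")
  methods <- c("mv", "zero", "soft", "normal")
  errs <- matrix(NA_real_, config$n_reps, length(methods),
                 dimnames = list(NULL, methods))
  rej_union <- rej_inter <- logical(config$n_reps)
  theta_true <- c(config$theta, rep(0, p - 1))
  crit <- stats::qnorm(1 - config$level / 2)
  for (r in seq_len(config$n_reps)) {
    # shared low-rank + gene-specific truth carried by a clustered minority
    # of SNP rows, plus LD-correlated estimation noise; all on the z scale
    support <- stats::runif(m) <= config$support_frac
    U <- matrix(stats::rnorm(m * rank), m, rank)
    U[!support, ] <- 0
    V <- matrix(stats::rnorm(p * rank), p, rank)
    D <- matrix(stats::rnorm(m * p), m, p) * support
    Btrue <- config$signal_sd *
      (sqrt(1 - indep_frac) * (U %*% t(V)) / sqrt(rank) +
         sqrt(indep_frac) * D)
    E <- crossprod(cR, matrix(stats::rnorm(m * p), m, p))
    Z <- Btrue + E
    Zmiss <- Z
    Zmiss[!mask] <- NA_real_

    Sigma_hat <- estimate_bias_matrix(Zmiss)
    imp <- list(
      mv = mv_impute(Zmiss, Theta, Sigma_hat, seed = config$seed + r,
                     max_iter = 200L),
      zero = zero_impute(Zmiss),
      soft = soft_impute(Zmiss, seed = config$seed + r, max_iter = 200L),
      normal = normal_impute(Zmiss, R))
    for (mt in methods)
      errs[r, mt] <- sqrt(sum((imp[[mt]]$completed[!mask] - Z[!mask])^2))

    # power: union (imputed) vs intersection (complete-case) instruments
    alpha_hat <- drop(Btrue %*% theta_true) + drop(crossprod(cR, stats::rnorm(m)))
    Bu <- imp$mv$completed
    fit_u <- mrbee_core(Minv_half %*% Bu, drop(Minv_half %*% alpha_hat),
                        (Nmat / m) * Sigma_hat$Sigma, 1e-6)
    rej_union[r] <- abs(fit_u$theta[1] / sqrt(fit_u$cov[1, 1])) > crit
    Ri <- R[inter, inter, drop = FALSE]
    Mi <- sym_mat_power(Ri, -0.5)
    fit_i <- mrbee_core(Mi %*% Z[inter, , drop = FALSE],
                        drop(Mi %*% alpha_hat[inter]),
                        Sigma_hat$Sigma, 1e-6)
    rej_inter[r] <- abs(fit_i$theta[1] / sqrt(fit_i$cov[1, 1])) > crit
  }
  n <- config$n_reps
  errors <- data.frame(method = methods,
                       mean_frobenius_error = colMeans(errs),
                       mc_se = apply(errs, 2, stats::sd) / sqrt(n),
                       row.names = NULL)
  power <- data.frame(iv_set = c("union_imputed", "intersection"),
                      power = c(mean(rej_union), mean(rej_inter)),
                      se = c(sqrt(mean(rej_union) * (1 - mean(rej_union)) / n),
                             sqrt(mean(rej_inter) * (1 - mean(rej_inter)) / n)),
                      n_ivs = c(m, length(inter)))
  structure(list(errors = errors, power = power,
                 missing_fraction = mean(!mask), n_reps = n),
            class = "imputation_experiment")
}

#' @export
print.imputation_experiment <- function(x, ...) {
  cat(sprintf("imputation experiment: %d replicates, %.1f%% entries missing\n",
              x$n_reps, 100 * x$missing_fraction))
  print(x$errors); cat("\n"); print(x$power)
  invisible(x)
}

#' Write an experiment table to TSV
#'
#' @param x an experiment result (data frame or list of data frames).
#' @param path output path; list components get a suffix per component.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    for (nm in names(x)[vapply(x, is.data.frame, logical(1))]) {
      utils::write.table(x[[nm]],
                         sub("(\\.[a-z]+)?$", paste0("_", nm, ".tsv"), path),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
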