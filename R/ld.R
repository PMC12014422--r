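#' LD correlation matrix
#'
#' Container for a SNP-by-SNP linkage-disequilibrium (LD) correlation matrix,
#' optionally carrying the sample size of the reference panel it was
#' estimated from. A missing (`NULL`) sample size marks an exact
#' (population/truth) matrix, as produced for example by [gen_ar1_ld()].
#'
#' @param R symmetric correlation matrix (unit diagonal, entries in
#'   \eqn{[-1, 1]}). Row/column names, if present, are SNP identifiers.
#' @param n integer reference-panel sample size, or `NULL` if `R` is exact.
#' @param is_regularized logical; has the matrix been shrunk towards the
#'   identity to enforce positive definiteness (see [regularize_pd()])?
#'
#' @return An object of class `"ld_matrix"`: the matrix itself with
#'   attributes `n` and `is_regularized`.
#' @seealso [estimate_ld()], [regularize_pd()], [sample_wishart_ld()]
#' @export
ld_matrix <- function(R, n = NULL, is_regularized = FALSE) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("'R' must be square")
  if (max(abs(R - t(R))) > 1e-8) stop("'R' must be symmetric")
  if (any(abs(diag(R)) - 1 > 1e-6)) stop("'R' must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-6) stop("LD correlations must lie in [-1, 1]")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n < 2L) stop("reference sample size 'n' must be >= 2")
  }
  structure(R, n = n, is_regularized = isTRUE(is_regularized),
            class = c("ld_matrix", "matrix", "array"))
}

#' @export
print.ld_matrix <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("LD correlation matrix: %d SNPs%s%s\n", nrow(x),
              if (is.null(n)) " (exact)" else sprintf(", reference n = %d", n),
              if (attr(x, "is_regularized")) ", regularized" else ""))
  invisible(x)
}

# strip class/attributes for plain linear algebra
unclass_ld <- function(R) {
  r <- as.matrix(R)
  attr(r, "n") <- NULL
  attr(r, "is_regularized") <- NULL
  class(r) <- c("matrix", "array")
  r
}

#' Read a PLINK 1 binary genotype fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (PLINK 1.00 binary format, SNP-major
#' layout) into a dosage matrix suitable for LD estimation. Dosages count
#' copies of the A1 allele of the `.bim` file (0, 1, 2); the 2-bit code `01`
#' is decoded as missing.
#'
#' @param prefix path prefix: `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#'
#' @return A list of class `"ld_panel"` with elements
#'   \item{genotypes}{individuals x SNPs numeric matrix of A1-allele dosages
#'     (with `NA` for missing calls), columns named by SNP id,}
#'   \item{snps}{data frame of SNP metadata (`id`, `chrom`, `pos`, `a1`,
#'     `a2`) aligned to the columns,}
#'   \item{n}{number of individuals.}
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  }
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bim_df) < 6) stop("malformed .bim file: expected 6 columns")
  snps <- data.frame(id = as.character(bim_df[[2]]),
                     chrom = as.character(bim_df[[1]]),
                     pos = as.numeric(bim_df[[4]]),
                     a1 = as.character(bim_df[[5]]),
                     a2 = as.character(bim_df[[6]]),
                     stringsAsFactors = FALSE)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  m <- nrow(snps)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) || raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK v1.00 .bed file (bad magic bytes)")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop("corrupt .bed file: size inconsistent with .bim/.fam")

  # 2-bit genotype codes (low bits = first individual):
  # 00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies
  code_map <- c(2, NA, 1, 0)
  byte_int <- as.integer(body)
  dim(byte_int) <- c(bytes_per_snp, m)
  geno <- matrix(NA_real_, n, m, dimnames = list(NULL, snps$id))
  idx_byte <- ((seq_len(n) - 1L) %/% 4L) + 1L
  shift <- 2L * ((seq_len(n) - 1L) %% 4L)
  for (s in seq_len(4L)) {
    pick <- shift == 2L * (s - 1L)
    if (!any(pick)) next
    codes <- (byte_int[idx_byte[pick], , drop = FALSE] %/% (4L^(s - 1L))) %% 4L
    geno[pick, ] <- code_map[codes + 1L]
  }
  structure(list(genotypes = geno, snps = snps, n = n), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD reference panel: %d individuals x %d SNPs\n",
              x$n, ncol(x$genotypes)))
  invisible(x)
}

#' Read a plain-text LD correlation matrix
#'
#' Alternative to a genotype panel: a whitespace-delimited square matrix with
#' a single header row of SNP identifiers.
#'
#' @param path file path (gzip transparent).
#' @param n optional reference sample size the matrix was estimated from.
#' @return An [ld_matrix()].
#' @export
read_ld_text <- function(path, n = NULL) {
  x <- utils::read.table(path, header = TRUE, check.names = FALSE)
  R <- as.matrix(x)
  rownames(R) <- colnames(R)
  ld_matrix(R, n = n)
}

#' Estimate LD correlations from a reference panel
#'
#' Pairwise Pearson correlation of genotype dosages. Missing genotypes are
#' mean-imputed per SNP before correlation, matching common reference-panel
#' practice. Monomorphic SNPs (zero dosage variance) cannot be correlated and
#' are removed with a warning.
#'
#' @param panel an `"ld_panel"` from [read_plink()], or any list with
#'   elements `genotypes` (individuals x SNPs matrix) and `n`.
#' @param snp_ids SNP identifiers to include, in the requested order.
#'   Defaults to all SNPs in the panel.
#' @return An [ld_matrix()] carrying the panel sample size.
#' @export
estimate_ld <- function(panel, snp_ids = NULL) {
  G <- panel$genotypes
  if (is.null(snp_ids)) snp_ids <- colnames(G)
  missing_ids <- setdiff(snp_ids, colnames(G))
  if (length(missing_ids))
    stop("SNPs not present in panel: ", paste(missing_ids, collapse = ", "))
  G <- G[, snp_ids, drop = FALSE]
  for (j in seq_len(ncol(G))) {
    na <- is.na(G[, j])
    if (any(na)) G[na, j] <- mean(G[, j], na.rm = TRUE)
  }
  v <- apply(G, 2, stats::var)
  mono <- !is.finite(v) | v <= 0
  if (any(mono)) {
    warning("removing monomorphic SNPs: ",
            paste(colnames(G)[mono], collapse = ", "))
    G <- G[, !mono, drop = FALSE]
  }
  if (ncol(G) == 0L) stop("no polymorphic SNPs left to correlate")
  ld_matrix(stats::cor(G), n = panel$n)
}

#' Greedy LD pruning
#'
#' Repeatedly keeps the highest-priority remaining SNP and discards every
#' remaining SNP whose squared correlation with it exceeds `r2_threshold`.
#' Ties in priority are broken deterministically by (original) index, so the
#' kept set does not depend on input row order.
#'
#' @param ld an [ld_matrix()] (or plain symmetric matrix).
#' @param priority numeric vector of significance scores, one per SNP
#'   (larger = kept earlier).
#' @param r2_threshold squared-correlation threshold above which a SNP is
#'   discarded. The conventional default \eqn{0.3^2} is used.
#' @return Integer vector of kept column indices, sorted increasingly.
#' @export
ld_prune <- function(ld, priority, r2_threshold = 0.09) {
  R <- unclass_ld(ld)
  m <- nrow(R)
  if (length(priority) != m)
    stop("'priority' must have one entry per SNP")
  R2 <- R^2
  remaining <- order(-priority, seq_len(m))
  keep <- integer(0)
  while (length(remaining)) {
    j <- remaining[1L]
    keep <- c(keep, j)
    remaining <- remaining[R2[j, remaining] <= r2_threshold]
  }
  sort(keep)
}

#' Shrink an LD matrix to positive definiteness
#'
#' Linear shrinkage towards the identity, \eqn{(1-s)\hat R + s I}, with the
#' minimal \eqn{s \in [0, 1]} such that the smallest eigenvalue of the result
#' is at least `floor`. `s` is available in closed form from the smallest
#' eigenvalue \eqn{\lambda_{\min}} of \eqn{\hat R}:
#' \eqn{s = (floor - \lambda_{\min}) / (1 - \lambda_{\min})} when
#' \eqn{\lambda_{\min} < floor}, else 0. The unit diagonal is preserved.
#'
#' @param ld an [ld_matrix()] or symmetric matrix.
#' @param floor target lower bound on the smallest eigenvalue (default 1e-3).
#' @return An [ld_matrix()] flagged as regularized, with attribute
#'   `shrinkage` giving the factor `s` used.
#' @export
regularize_pd <- function(ld, floor = 1e-3) {
  if (floor > 1) stop("'floor' must be <= 1")
  R <- unclass_ld(ld)
  lam_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  s <- if (lam_min >= floor) 0 else (floor - lam_min) / (1 - lam_min)
  s <- min(max(s, 0), 1)
  out <- (1 - s) * R + s * diag(nrow(R))
  dimnames(out) <- dimnames(R)
  res <- ld_matrix(out, n = attr(ld, "n"), is_regularized = TRUE)
  attr(res, "shrinkage") <- s
  res
}

#' Sample an estimated LD matrix from a Wishart distribution
#'
#' Emulates LD estimation from a finite reference panel of `df` individuals:
#' draws \eqn{W \sim Wishart(df, R/df)} by the Bartlett decomposition and
#' converts the draw to a correlation matrix. The returned matrix records
#' `df` as its reference sample size.
#'
#' @param R_true true (positive definite) LD matrix.
#' @param df Wishart degrees of freedom = emulated panel size; must be at
#'   least the matrix dimension.
#' @param seed optional integer seed for reproducibility.
#' @return An [ld_matrix()] with `n = df`.
#' @export
sample_wishart_ld <- function(R_true, df, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- unclass_ld(R_true)
  m <- nrow(R)
  if (df < m) stop("'df' must be at least the matrix dimension (singular draw)")
  cR <- chol(R)
  W <- rwishart_chol(df, cR)
  Rhat <- stats::cov2cor(W / df)
  dimnames(Rhat) <- dimnames(R)
  ld_matrix(Rhat, n = df)
}

# Bartlett-decomposition Wishart draw given chol(scale * df), i.e. chol(R):
# returns an (unscaled) Wishart(df, R) variate
rwishart_chol <- function(df, cholR) {
  m <- ncol(cholR)
  T <- matrix(0, m, m)
  diag(T) <- sqrt(stats::rchisq(m, df = df - seq_len(m) + 1))
  T[lower.tri(T)] <- stats::rnorm(m * (m - 1) / 2)
  A <- crossprod(cholR, T)    # t(cholR) %*% T
  tcrossprod(A)
}

# symmetric matrix power through the eigendecomposition; used for
# whitening (power = -1/2) and the imputation transform (power = 1/2)
sym_mat_power <- function(S, power, tol = NULL) {
  e <- eigen(S, symmetric = TRUE)
  vals <- e$values
  if (is.null(tol)) tol <- max(abs(vals)) * 1e-12
  if (power < 0 && min(vals) < tol)
    stop("matrix is numerically singular; regularize it first (regularize_pd)")
  vals <- pmax(vals, tol)
  e$vectors %*% (vals^power * t(e$vectors))
}
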