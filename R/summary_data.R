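#' cis-eQTL effect matrix with explicit missingness
#'
#' The central data container for locus-level multivariable MR: an m x p
#' matrix of SNP-expression association estimates (one column per gene) with
#' per-entry standard errors and a logical mask recording which SNP-gene
#' pairs actually carry an estimate. Public cis-eQTL summary files only
#' report pairs within a cis window of each gene's transcription start site
#' (TSS), so the mask is typically block/banded.
#'
#' @param snps data frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (one row per SNP, order defines rows).
#' @param genes data frame with columns `gene_id`, `chrom`, `tss`.
#' @param beta m x p matrix of association estimates.
#' @param se m x p matrix of positive standard errors.
#' @param mask m x p logical matrix, `TRUE` where (beta, se) are observed.
#'   Defaults to "everything observed".
#' @return An object of class `"eqtl_matrix"`.
#' @export
eqtl_matrix <- function(snps, genes, beta, se, mask = NULL) {
  beta <- as.matrix(beta); se <- as.matrix(se)
  m <- nrow(beta); p <- ncol(beta)
  if (is.null(mask)) mask <- matrix(TRUE, m, p)
  mask <- as.matrix(mask)
  stopifnot(nrow(snps) == m, nrow(genes) == p,
            all(dim(se) == c(m, p)), all(dim(mask) == c(m, p)))
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(snps)))
    stop("'snps' must have columns: ", paste(need, collapse = ", "))
  if (!all(c("gene_id", "chrom", "tss") %in% names(genes)))
    stop("'genes' must have columns: gene_id, chrom, tss")
  if (any(snps$pos <= 0) || any(genes$tss <= 0))
    stop("positions must be positive (1-based coordinates)")
  if (any(snps$effect_allele == snps$other_allele))
    stop("effect and other allele must differ")
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (any(!is.finite(beta[mask])) || any(!is.finite(se[mask])))
    stop("beta/se must be finite at observed entries")
  if (any(se[mask] <= 0)) stop("standard errors must be positive")
  if (any(colSums(mask) == 0))
    stop("every gene must have at least one observed eQTL")
  dimnames(beta) <- dimnames(se) <- dimnames(mask) <-
    list(snps$id, genes$gene_id)
  structure(list(snps = snps, genes = genes, beta = beta, se = se,
                 mask = mask),
            class = "eqtl_matrix")
}

#' @export
print.eqtl_matrix <- function(x, ...) {
  cat(sprintf("cis-eQTL matrix: %d SNPs x %d genes, %.1f%% observed\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.eqtl_matrix <- function(x) dim(x$beta)

#' Z-score matrix of an eQTL matrix
#'
#' `beta / se`, with unobserved entries `NA`.
#' @param x an [eqtl_matrix()].
#' @return m x p numeric matrix.
#' @export
eqtl_z <- function(x) {
  z <- x$beta / x$se
  z[!x$mask] <- NA_real_
  z
}

#' Outcome GWAS association vector
#'
#' SNP-outcome associations aligned (or alignable) to an [eqtl_matrix()].
#' p-values absent from the source file are recomputed from `alpha/se` as
#' two-sided normal.
#'
#' @param snps data frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`.
#' @param alpha numeric vector of association estimates.
#' @param se positive standard errors.
#' @param pval optional p-values; recomputed when `NULL`.
#' @return An object of class `"outcome_vector"`.
#' @export
outcome_vector <- function(snps, alpha, se, pval = NULL) {
  m <- length(alpha)
  stopifnot(nrow(snps) == m, length(se) == m)
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  if (any(!is.finite(alpha)) || any(!is.finite(se)) || any(se <= 0))
    stop("alpha/se must be finite with positive se (no missing outcome data)")
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(alpha / se))
  if (any(pval < 0 | pval > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  structure(list(snps = snps, alpha = as.numeric(alpha), se = as.numeric(se),
                 pval = as.numeric(pval)),
            class = "outcome_vector")
}

#' @export
print.outcome_vector <- function(x, ...) {
  cat(sprintf("outcome GWAS vector: %d SNPs, min p = %.3g\n",
              length(x$alpha), min(x$pval)))
  invisible(x)
}

# open a possibly-gzipped delimited file and read it as a data frame;
# delimiter is sniffed among tab/comma/whitespace
read_delim_auto <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty input file: ", path)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  close(con); on.exit()
  con <- gzfile(path, "rt")
  on.exit(close(con))
  utils::read.table(con, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

default_eqtl_columns <- function() {
  list(snp = "snp", gene = "gene", chrom = "chrom", pos = "pos",
       effect_allele = "effect_allele", other_allele = "other_allele",
       beta = "beta", se = "se", tss = "tss")
}

#' Read long-format cis-eQTL summary statistics
#'
#' Reads a delimited (tab/comma/whitespace; gzip transparent) file with one
#' row per SNP-gene pair and pivots it into an [eqtl_matrix()]. Absent
#' SNP-gene pairs become unobserved (mask `FALSE`); duplicate pairs are an
#' error because silent aggregation hides upstream problems.
#'
#' @param path file path; one file per chromosome is the expected layout.
#' @param column_map named list mapping the roles `snp`, `gene`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se` and optionally
#'   `tss` to column names in the file. Defaults to those same names.
#' @param cis_window cis-window half-width in base pairs (default 1 Mb,
#'   closed: \eqn{|pos - tss| \le} `cis_window`). Only used for validation
#'   when a TSS column is available; set to `NULL` to skip the check.
#' @param gene_tss optional data frame (`gene_id`, `chrom`, `tss`) supplying
#'   TSS coordinates when the file has no TSS column.
#' @return An [eqtl_matrix()].
#' @export
read_eqtl_summary <- function(path, column_map = default_eqtl_columns(),
                              cis_window = 1e6, gene_tss = NULL) {
  cm <- utils::modifyList(default_eqtl_columns(), as.list(column_map))
  df <- read_delim_auto(path)
  if (nrow(df) == 0L) stop("no rows in eQTL summary file: ", path)
  need <- c("snp", "gene", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se")
  for (role in need) {
    if (!cm[[role]] %in% names(df))
      stop(sprintf("mapped column '%s' (role '%s') not found in %s",
                   cm[[role]], role, path))
  }
  snp <- as.character(df[[cm$snp]])
  gene <- as.character(df[[cm$gene]])
  if (anyDuplicated(paste(snp, gene, sep = "\r")))
    stop("duplicate SNP-gene rows in ", path)
  beta <- as.numeric(df[[cm$beta]])
  se <- as.numeric(df[[cm$se]])
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("invalid beta/se in ", path, " (se must be positive and finite)")

  snp_ids <- unique(snp)
  gene_ids <- unique(gene)
  i <- match(snp, snp_ids)
  j <- match(gene, gene_ids)
  m <- length(snp_ids); p <- length(gene_ids)
  B <- matrix(NA_real_, m, p)
  S <- matrix(NA_real_, m, p)
  M <- matrix(FALSE, m, p)
  idx <- cbind(i, j)
  B[idx] <- beta; S[idx] <- se; M[idx] <- TRUE
  S[!M] <- 1  # placeholder; never read through the mask

  first_row <- !duplicated(snp)
  snps <- data.frame(id = snp_ids,
                     chrom = as.character(df[[cm$chrom]])[first_row],
                     pos = as.numeric(df[[cm$pos]])[first_row],
                     effect_allele = toupper(as.character(df[[cm$effect_allele]]))[first_row],
                     other_allele = toupper(as.character(df[[cm$other_allele]]))[first_row],
                     stringsAsFactors = FALSE)
  gene_first <- !duplicated(gene)
  genes <- data.frame(gene_id = gene_ids,
                      chrom = as.character(df[[cm$chrom]])[gene_first],
                      tss = NA_real_, stringsAsFactors = FALSE)
  if (cm$tss %in% names(df)) {
    genes$tss <- as.numeric(df[[cm$tss]])[gene_first]
  } else if (!is.null(gene_tss)) {
    genes$tss <- gene_tss$tss[match(gene_ids, gene_tss$gene_id)]
  }
  if (any(is.na(genes$tss))) {
    if (!is.null(cis_window))
      warning("no TSS available for some genes; cis-window check skipped")
    genes$tss[is.na(genes$tss)] <- 1  # must stay positive for the container
  } else if (!is.null(cis_window)) {
    d <- abs(outer(snps$pos, genes$tss, "-"))
    bad <- M & d > cis_window
    if (any(bad))
      warning(sprintf("%d observed SNP-gene pairs fall outside the %.0f bp cis window",
                      sum(bad), cis_window))
  }
  eqtl_matrix(snps, genes, B, S, M)
}

#' Read outcome GWAS summary statistics
#'
#' @param path delimited (gzip transparent) file with one row per SNP.
#' @param column_map named list mapping roles `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se` and optionally `pval`
#'   to column names.
#' @return An [outcome_vector()].
#' @export
read_outcome_summary <- function(path,
                                 column_map = list()) {
  cm <- utils::modifyList(
    list(snp = "snp", chrom = "chrom", pos = "pos",
         effect_allele = "effect_allele", other_allele = "other_allele",
         beta = "beta", se = "se", pval = "pval"),
    as.list(column_map))
  df <- read_delim_auto(path)
  if (nrow(df) == 0L) stop("no rows in outcome summary file: ", path)
  for (role in c("snp", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se")) {
    if (!cm[[role]] %in% names(df))
      stop(sprintf("mapped column '%s' (role '%s') not found in %s",
                   cm[[role]], role, path))
  }
  snps <- data.frame(id = as.character(df[[cm$snp]]),
                     chrom = as.character(df[[cm$chrom]]),
                     pos = as.numeric(df[[cm$pos]]),
                     effect_allele = toupper(as.character(df[[cm$effect_allele]])),
                     other_allele = toupper(as.character(df[[cm$other_allele]])),
                     stringsAsFactors = FALSE)
  pv <- if (cm$pval %in% names(df)) as.numeric(df[[cm$pval]]) else NULL
  outcome_vector(snps, as.numeric(df[[cm$beta]]), as.numeric(df[[cm$se]]), pv)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize eQTL and outcome summary statistics
#'
#' Restricts both datasets to their SNP intersection (in eQTL order), flips
#' the sign of the outcome association where the outcome's effect/other
#' alleles are swapped relative to the eQTL data, and drops SNPs whose
#' allele pairs cannot be reconciled by exact label matching. Strand flips
#' are not attempted; strand-ambiguous (A/T, C/G) SNPs are kept by default
#' and can be dropped with `drop_ambiguous = TRUE`.
#'
#' Harmonization is idempotent: applying it to an already-harmonized pair
#' returns the pair unchanged.
#'
#' @param eqtl an [eqtl_matrix()].
#' @param outcome an [outcome_vector()].
#' @param drop_ambiguous drop strand-ambiguous SNPs?
#' @return A list with elements `eqtl`, `outcome` (aligned), and `dropped`,
#'   a character vector of SNP ids removed for irreconcilable alleles.
#' @export
harmonize <- function(eqtl, outcome, drop_ambiguous = FALSE) {
  common <- intersect(eqtl$snps$id, outcome$snps$id)
  if (length(common) == 0L)
    stop("no SNP overlap between eQTL and outcome data")
  ei <- match(common, eqtl$snps$id)
  oi <- match(common, outcome$snps$id)
  e_ea <- eqtl$snps$effect_allele[ei]; e_oa <- eqtl$snps$other_allele[ei]
  o_ea <- outcome$snps$effect_allele[oi]; o_oa <- outcome$snps$other_allele[oi]
  same <- e_ea == o_ea & e_oa == o_oa
  swapped <- e_ea == o_oa & e_oa == o_ea
  ok <- same | swapped
  if (drop_ambiguous) ok <- ok & !is_strand_ambiguous(e_ea, e_oa)
  dropped <- common[!ok]
  if (length(dropped))
    message(length(dropped), " SNP(s) dropped during harmonization: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (!any(ok)) stop("no reconcilable SNPs after allele matching")
  keep <- which(ok)
  ei <- ei[keep]; oi <- oi[keep]
  sgn <- ifelse(swapped[keep], -1, 1)

  eq <- eqtl_matrix(eqtl$snps[ei, , drop = FALSE], eqtl$genes,
                    eqtl$beta[ei, , drop = FALSE],
                    eqtl$se[ei, , drop = FALSE],
                    eqtl$mask[ei, , drop = FALSE])
  out_snps <- outcome$snps[oi, , drop = FALSE]
  # after alignment the outcome is reported on the eQTL allele coding
  out_snps$effect_allele <- eq$snps$effect_allele
  out_snps$other_allele <- eq$snps$other_allele
  ov <- outcome_vector(out_snps, sgn * outcome$alpha[oi], outcome$se[oi],
                       outcome$pval[oi])
  list(eqtl = eq, outcome = ov, dropped = dropped)
}

#' Group genes into loci for joint analysis
#'
#' Genes are grouped by the transitive closure of the relation "share at
#' least one eQTL with eQTL p-value < `share_p` for both genes" (connected
#' components of the gene-gene shared-eQTL graph). A group is retained as a
#' locus only if at least one SNP in its union instrument set has outcome
#' p-value < `outcome_p`. eQTL p-values are computed from `beta/se` as
#' two-sided normal.
#'
#' @param eqtl harmonized [eqtl_matrix()].
#' @param outcome harmonized [outcome_vector()] (same SNP order).
#' @param outcome_p outcome significance threshold a locus must reach
#'   (default 0.005).
#' @param share_p eQTL sharing threshold (default 0.001).
#' @param cis_window half-width used for the locus boundary (default 1 Mb).
#' @return List of `"locus"` objects, each with `gene_ids`, `boundary`
#'   (`chrom`, `start`, `end`), `iv_union`, `iv_intersection`, and
#'   `iv_selected` (initialized to the union; downstream filters shrink it).
#'   May be empty.
#' @export
build_loci <- function(eqtl, outcome, outcome_p = 0.005, share_p = 0.001,
                       cis_window = 1e6) {
  if (!identical(eqtl$snps$id, outcome$snps$id))
    stop("eqtl and outcome must be harmonized (same SNP order); see harmonize()")
  z <- eqtl_z(eqtl)
  pz <- 2 * stats::pnorm(-abs(z))
  sig <- !is.na(pz) & pz < share_p
  p <- ncol(sig)

  # connected components of the shared-significant-eQTL gene graph
  comp <- seq_len(p)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]; i }
  if (p > 1) {
    for (a in seq_len(p - 1)) {
      for (b in seq((a + 1), p)) {
        if (any(sig[, a] & sig[, b])) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) comp[rb] <- ra
        }
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  loci <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    obs_any <- rowSums(eqtl$mask[, members, drop = FALSE]) > 0
    union_set <- eqtl$snps$id[obs_any]
    inter_set <- eqtl$snps$id[
      rowSums(eqtl$mask[, members, drop = FALSE]) == length(members)]
    if (!any(outcome$pval[obs_any] < outcome_p)) next
    tss <- eqtl$genes$tss[members]
    loci[[length(loci) + 1L]] <- structure(
      list(gene_ids = eqtl$genes$gene_id[members],
           boundary = list(chrom = eqtl$genes$chrom[members][1],
                           start = max(1, min(tss) - cis_window),
                           end = max(tss) + cis_window),
           iv_union = union_set,
           iv_intersection = inter_set,
           iv_selected = union_set),
      class = "locus")
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s:%.0f-%.0f | %d genes, |S_union| = %d, |S_inter| = %d, |S| = %d\n",
              x$boundary$chrom, x$boundary$start, x$boundary$end,
              length(x$gene_ids), length(x$iv_union),
              length(x$iv_intersection), length(x$iv_selected)))
  invisible(x)
}

#' Unpivot an eQTL matrix back to long format
#'
#' Inverse of [read_eqtl_summary()]'s pivot: one row per observed SNP-gene
#' pair.
#' @param x an [eqtl_matrix()].
#' @return data frame with columns `snp`, `gene`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `tss`, `beta`, `se`.
#' @export
eqtl_long <- function(x) {
  idx <- which(x$mask, arr.ind = TRUE)
  data.frame(snp = x$snps$id[idx[, 1]],
             gene = x$genes$gene_id[idx[, 2]],
             chrom = x$snps$chrom[idx[, 1]],
             pos = x$snps$pos[idx[, 1]],
             effect_allele = x$snps$effect_allele[idx[, 1]],
             other_allele = x$snps$other_allele[idx[, 1]],
             tss = x$genes$tss[idx[, 2]],
             beta = x$beta[idx],
             se = x$se[idx],
             stringsAsFactors = FALSE)
}
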