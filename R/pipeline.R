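#' Configuration for a locus-by-locus MVMR run
#'
#' Collects paths and thresholds for [run_pipeline()]. Threshold defaults
#' are the application-scale settings of a genome-wide screen: loci must
#' contain an outcome association with p < 0.005; genes are grouped when
#' they share an eQTL with p < 0.001; instruments enter by the joint
#' association test at its locus-level preset; LD pruning at
#' \eqn{r^2 < 0.7^2}; the correlated-pleiotropy filter at
#' \eqn{r^2 > 0.5^2} within a 2 Mb flank.
#'
#' @param eqtl_files character vector of cis-eQTL summary files (one per
#'   chromosome).
#' @param outcome_file outcome GWAS summary file.
#' @param ld LD source: a PLINK fileset prefix, a path to a plain-text
#'   correlation matrix, or an in-memory `"ld_panel"`/[ld_matrix()].
#' @param outcome_p,share_p locus construction thresholds (see
#'   [build_loci()]).
#' @param joint_alpha significance level of the joint instrument test.
#' @param prune_r2 LD pruning threshold.
#' @param chp_kappa,chp_flank correlated-pleiotropy filter settings (see
#'   [chp_filter()]).
#' @param impute_method `"mv"`, `"zero"`, `"soft"`, or `"normal"`.
#' @param pleiotropy_p threshold of the instrument-level pleiotropy test.
#' @param df_method residual df convention for inference (see [mrbee()]).
#' @param cis_window cis window half-width (bp).
#' @param network also estimate a co-regulation network per locus?
#' @param eqtl_columns,outcome_columns column maps for the readers.
#' @param gene_tss optional TSS table for [read_eqtl_summary()].
#' @param out_dir output directory for TSV results (`NULL` = do not write).
#' @param seed integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(eqtl_files, outcome_file, ld,
                       outcome_p = 0.005, share_p = 0.001,
                       joint_alpha = joint_test_alpha("locus"),
                       prune_r2 = 0.49, chp_kappa = 0.25, chp_flank = 2e6,
                       impute_method = c("mv", "zero", "soft", "normal"),
                       pleiotropy_p = 0.05, df_method = c("m-1", "m-p"),
                       cis_window = 1e6, network = FALSE,
                       eqtl_columns = default_eqtl_columns(),
                       outcome_columns = list(), gene_tss = NULL,
                       out_dir = NULL, seed = 1) {
  impute_method <- match.arg(impute_method)
  df_method <- match.arg(df_method)
  for (thr in c(outcome_p, share_p, joint_alpha, prune_r2, chp_kappa,
                pleiotropy_p))
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  structure(list(eqtl_files = eqtl_files, outcome_file = outcome_file,
                 ld = ld, outcome_p = outcome_p, share_p = share_p,
                 joint_alpha = joint_alpha, prune_r2 = prune_r2,
                 chp_kappa = chp_kappa, chp_flank = chp_flank,
                 impute_method = impute_method, pleiotropy_p = pleiotropy_p,
                 df_method = df_method, cis_window = cis_window,
                 network = network, eqtl_columns = eqtl_columns,
                 outcome_columns = outcome_columns, gene_tss = gene_tss,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

resolve_ld_source <- function(ld) {
  if (inherits(ld, c("ld_panel", "ld_matrix"))) return(ld)
  if (is.character(ld) && file.exists(paste0(ld, ".bed"))) return(read_plink(ld))
  if (is.character(ld) && file.exists(ld)) return(read_ld_text(ld))
  stop("cannot resolve LD source: ", ld)
}

ld_for_snps <- function(ld_source, snp_ids) {
  if (inherits(ld_source, "ld_panel")) {
    estimate_ld(ld_source, snp_ids)
  } else {
    ids <- intersect(snp_ids, rownames(ld_source))
    ld_matrix(unclass_ld(ld_source)[ids, ids, drop = FALSE],
              n = attr(ld_source, "n"))
  }
}

#' Run the full locus-by-locus MVMR pipeline
#'
#' Wires all components end to end: read and harmonize the summary data,
#' group genes into loci, and per locus impute the cis-eQTL matrix, select
#' and filter instruments, regularize LD, screen genes, fit the
#' bias-corrected MVMR model with pleiotropy pruning and finite-panel
#' corrected inference, and compute locus fit statistics (and optionally a
#' co-regulation network). Per-locus failures are logged and skipped, never
#' fatal to the run.
#'
#' @param config a [run_config()].
#' @return A list of class `"mvmr_run"` with `genes` (gene-level results
#'   table), `loci` (locus-level table), `skipped` (locus skip log),
#'   `networks` (list, if requested). When `config$out_dir` is set, the
#'   tables are also written as TSV files there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  ld_source <- resolve_ld_source(config$ld)
  outcome_all <- read_outcome_summary(config$outcome_file,
                                      config$outcome_columns)
  gene_rows <- list(); locus_rows <- list(); skip_rows <- list()
  networks <- list()
  locus_counter <- 0L

  for (ef in config$eqtl_files) {
    eqtl_chr <- read_eqtl_summary(ef, config$eqtl_columns,
                                  cis_window = config$cis_window,
                                  gene_tss = config$gene_tss)
    hm <- harmonize(eqtl_chr, outcome_all)
    loci <- build_loci(hm$eqtl, hm$outcome, config$outcome_p,
                       config$share_p, config$cis_window)
    for (locus in loci) {
      locus_counter <- locus_counter + 1L
      locus_id <- sprintf("locus_%03d", locus_counter)
      res <- tryCatch(
        analyze_locus(locus, hm$eqtl, hm$outcome, ld_source, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        skip_rows[[length(skip_rows) + 1L]] <-
          data.frame(locus = locus_id,
                     chrom = locus$boundary$chrom,
                     reason = conditionMessage(res))
        next
      }
      res$genes$locus <- locus_id
      res$locus$locus <- locus_id
      gene_rows[[length(gene_rows) + 1L]] <- res$genes
      locus_rows[[length(locus_rows) + 1L]] <- res$locus
      if (!is.null(res$network)) networks[[locus_id]] <- res$network
    }
  }
  bind <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  out <- structure(list(genes = bind(gene_rows), loci = bind(locus_rows),
                        skipped = bind(skip_rows), networks = networks,
                        config = config),
                   class = "mvmr_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("genes", "loci", "skipped")) {
      if (!is.null(out[[nm]]))
        utils::write.table(out[[nm]],
                           file.path(config$out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

# single-locus analysis; stops with an informative message on any
# unrecoverable condition (caught and logged by run_pipeline)
analyze_locus <- function(locus, eqtl, outcome, ld_source, config) {
  sel <- match(locus$iv_union, eqtl$snps$id)
  gsel <- match(locus$gene_ids, eqtl$genes$gene_id)
  Z <- eqtl_z(eqtl)[sel, gsel, drop = FALSE]
  av <- (outcome$alpha / outcome$se)[sel]
  snp_ids <- eqtl$snps$id[sel]
  rownames(Z) <- snp_ids

  # LD over the union set (needed for mv/normal imputation)
  R_union <- ld_for_snps(ld_source, snp_ids)
  if (nrow(R_union) < length(snp_ids)) {
    keep <- match(rownames(R_union), snp_ids)
    Z <- Z[keep, , drop = FALSE]; av <- av[keep]; snp_ids <- snp_ids[keep]
  }
  if (nrow(Z) <= ncol(Z)) stop("too few instruments with LD information")
  R_union_reg <- regularize_pd(R_union)

  Sigma <- estimate_bias_matrix(Z)
  comp <- switch(config$impute_method,
                 mv = mv_impute(Z, solve(unclass_ld(R_union_reg)), Sigma,
                                seed = config$seed),
                 zero = zero_impute(Z),
                 soft = soft_impute(Z, seed = config$seed),
                 normal = normal_impute(Z, R_union_reg))
  Zc <- comp$completed
  rownames(Zc) <- snp_ids

  ivs <- select_ivs(Zc, Sigma, config$joint_alpha)
  if (length(ivs) == 0L) stop("no instruments pass the joint association test")
  ivs <- chp_filter(ivs, locus, ld_source,
                    snp_pos = data.frame(id = eqtl$snps$id,
                                         pos = eqtl$snps$pos),
                    kappa = config$chp_kappa, flank = config$chp_flank)
  if (length(ivs) <= ncol(Zc)) stop("too few instruments after the CHP filter")

  R_iv <- ld_for_snps(ld_source, ivs)
  pri <- rowSums(Zc[ivs, , drop = FALSE]^2)
  kept <- ld_prune(R_iv, pri[rownames(R_iv)], config$prune_r2)
  ivs <- rownames(R_iv)[kept]
  if (length(ivs) <= ncol(Zc)) stop("too few instruments after LD pruning")
  R_fit <- regularize_pd(ld_for_snps(ld_source, ivs))

  # gene screening on the whitened scale
  M <- sym_mat_power(unclass_ld(R_fit), -0.5)
  Xw <- M %*% Zc[ivs, , drop = FALSE]
  yw <- drop(M %*% av[match(ivs, snp_ids)])
  scr <- gscreen(Xw, yw)
  genes_in <- if (length(scr$selected)) scr$selected else colnames(Zc)

  mask_iv <- eqtl$mask[sel, gsel, drop = FALSE][match(ivs, snp_ids),
                                                match(genes_in,
                                                      colnames(Zc)),
                                                drop = FALSE]
  fit <- mrbee(Zc[ivs, genes_in, drop = FALSE], av[match(ivs, snp_ids)],
               R = R_fit, bias = bias_matrix(Sigma$Sigma[genes_in, genes_in,
                                                         drop = FALSE]),
               bias_scale = bias_scale_matrix(mask_iv, R_fit),
               prune = TRUE, p_threshold = config$pleiotropy_p,
               df_method = config$df_method)

  genes <- data.frame(gene = locus$gene_ids,
                      screened_in = locus$gene_ids %in% genes_in,
                      n_ivs = fit$m,
                      theta = NA_real_, se = NA_real_, L = NA_real_,
                      L_tilde = NA_real_, p_value = NA_real_,
                      pratt = NA_real_,
                      locus_r2 = fit$locus_r2,
                      stringsAsFactors = FALSE)
  idx <- match(genes_in, genes$gene)
  genes$theta[idx] <- fit$theta
  genes$se[idx] <- fit$se
  genes$L[idx] <- fit$L
  genes$L_tilde[idx] <- if (is.null(fit$L_tilde)) NA_real_ else fit$L_tilde
  genes$p_value[idx] <- fit$pvals
  genes$pratt[idx] <- fit$pratt

  locus_row <- data.frame(chrom = locus$boundary$chrom,
                          start = locus$boundary$start,
                          end = locus$boundary$end,
                          n_genes = length(locus$gene_ids),
                          n_genes_screened_in = length(genes_in),
                          n_iv_union = length(locus$iv_union),
                          n_iv_final = fit$m,
                          locus_r2 = fit$locus_r2,
                          stringsAsFactors = FALSE)
  net <- NULL
  if (isTRUE(config$network) && length(genes_in) >= 2) {
    netZ <- cbind(Zc[ivs, genes_in, drop = FALSE],
                  outcome = av[match(ivs, snp_ids)])
    net <- tryCatch(fit_network(netZ, outcome = "outcome"),
                    error = function(e) NULL)
  }
  list(genes = genes, locus = locus_row, network = net)
}

#' @export
print.mvmr_run <- function(x, ...) {
  n_loc <- if (is.null(x$loci)) 0L else nrow(x$loci)
  n_skip <- if (is.null(x$skipped)) 0L else nrow(x$skipped)
  cat(sprintf("MVMR run: %d locus/loci analyzed, %d skipped\n", n_loc, n_skip))
  if (!is.null(x$genes)) {
    cat("\nGene-level results:\n")
    print(utils::head(x$genes, 20))
  }
  invisible(x)
}

#' Bonferroni-adjusted gene-level p-values for a run
#'
#' Adjusts the gene-level p-values of an [run_pipeline()] result for the
#' number of genes actually tested across all loci.
#'
#' @param run an `"mvmr_run"`.
#' @return The `genes` table with an extra `p_bonferroni` column.
#' @export
adjust_run_pvalues <- function(run) {
  g <- run$genes
  if (is.null(g)) return(NULL)
  tested <- !is.na(g$p_value)
  g$p_bonferroni <- NA_real_
  g$p_bonferroni[tested] <- stats::p.adjust(g$p_value[tested],
                                            method = "bonferroni")
  g
}
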