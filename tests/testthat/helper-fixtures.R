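# shared fixture builders; everything is generated in code at test time

# encode a dosage matrix (individuals x SNPs, NA = missing) as a PLINK 1
# binary fileset; independent of read_plink (used to test it)
write_plink_fixture <- function(dir, geno, snps) {
  prefix <- file.path(dir, "panel")
  n <- nrow(geno); m <- ncol(geno)
  # .fam / .bim
  writeLines(sprintf("F%d I%d 0 0 1 -9", seq_len(n), seq_len(n)),
             paste0(prefix, ".fam"))
  writeLines(sprintf("%s\t%s\t0\t%d\t%s\t%s",
                     snps$chrom, snps$id, snps$pos, snps$a1, snps$a2),
             paste0(prefix, ".bim"))
  # .bed: dosage -> 2-bit code (00 = 2 x A1, 10 = het, 11 = 0 x A1, 01 = NA)
  code_of <- function(g) {
    if (is.na(g)) 1L else if (g == 2) 0L else if (g == 1) 2L else 3L
  }
  bytes_per_snp <- ceiling(n / 4)
  out <- raw(3 + bytes_per_snp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pos <- 4L
  for (j in seq_len(m)) {
    codes <- vapply(geno[, j], code_of, integer(1))
    for (b in seq_len(bytes_per_snp)) {
      idx <- ((b - 1) * 4 + 1):min(b * 4, n)
      val <- 0L
      for (k in seq_along(idx)) {
        val <- val + codes[idx[k]] * 4L^(k - 1L)
      }
      out[pos] <- as.raw(val)
      pos <- pos + 1L
    }
  }
  writeBin(out, paste0(prefix, ".bed"))
  prefix
}

snp_frame <- function(ids, pos, chrom = "1", ea = "A", oa = "G") {
  data.frame(id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

# small fully-synthetic two-region dataset written as summary files; returns
# the file paths plus the generating truth for downstream checks
make_pipeline_fixture <- function(dir, seed = 7) {
  set.seed(seed)
  mk_region <- function(offset_bp, snp_prefix, genes, m, causal, rho = 0.45) {
    pos <- round(seq(offset_bp, offset_bp + 2.4e6, length.out = m))
    tss <- round(seq(offset_bp + 0.7e6, offset_bp + 1.7e6,
                     length.out = length(genes)))
    R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
    cR <- chol(R)
    p <- length(genes)
    # shared factor + gene-specific eQTLs near the centre, plus noise
    core <- which(pos > offset_bp + 0.9e6 & pos < offset_bp + 1.5e6)
    Btrue <- matrix(0, m, p)
    Btrue[sample(core, 8), ] <- rnorm(8, 0, 5)        # shared eQTLs
    for (k in seq_len(p)) {
      bump <- sample(core, 4)
      Btrue[bump, k] <- Btrue[bump, k] + rnorm(4, 0, 7)
    }
    Z <- Btrue + crossprod(cR, matrix(rnorm(m * p), m, p))
    theta <- rep(0, p); theta[causal] <- 0.6
    alpha <- drop(Btrue %*% theta) + drop(crossprod(cR, rnorm(m)))
    mask <- abs(outer(pos, tss, "-")) <= 1e6
    list(snps = sprintf("%s%03d", snp_prefix, seq_len(m)), pos = pos,
         genes = genes, tss = tss, Z = Z, alpha = alpha, mask = mask, R = R)
  }
  a <- mk_region(1e6, "rsA", c("G1", "G2", "G3"), 70, causal = 1)
  b <- mk_region(9e6, "rsB", c("G4", "G5"), 50, causal = 2)

  long <- do.call(rbind, lapply(list(a, b), function(r) {
    idx <- which(r$mask, arr.ind = TRUE)
    data.frame(snp = r$snps[idx[, 1]], gene = r$genes[idx[, 2]],
               chrom = "1", pos = r$pos[idx[, 1]],
               effect_allele = "A", other_allele = "G",
               beta = r$Z[idx], se = 1, tss = r$tss[idx[, 2]],
               stringsAsFactors = FALSE)
  }))
  eqtl_file <- file.path(dir, "eqtl_chr1.tsv")
  write.table(long, eqtl_file, sep = "\t", quote = FALSE, row.names = FALSE)

  out <- do.call(rbind, lapply(list(a, b), function(r) {
    data.frame(snp = r$snps, chrom = "1", pos = r$pos,
               effect_allele = "A", other_allele = "G",
               beta = r$alpha, se = 1, stringsAsFactors = FALSE)
  }))
  outcome_file <- file.path(dir, "outcome.tsv")
  write.table(out, outcome_file, sep = "\t", quote = FALSE, row.names = FALSE)

  all_ids <- c(a$snps, b$snps)
  Rall <- matrix(0, length(all_ids), length(all_ids),
                 dimnames = list(all_ids, all_ids))
  Rall[seq_along(a$snps), seq_along(a$snps)] <- a$R
  Rall[length(a$snps) + seq_along(b$snps),
       length(a$snps) + seq_along(b$snps)] <- b$R
  ld_file <- file.path(dir, "ld.txt")
  write.table(round(Rall, 8), ld_file, quote = FALSE, row.names = FALSE)

  list(eqtl_file = eqtl_file, outcome_file = outcome_file, ld_file = ld_file,
       regions = list(a = a, b = b))
}
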