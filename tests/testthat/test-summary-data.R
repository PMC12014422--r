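test_that("long-format pivot builds the matrix and mask by construction", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("snp,gene,chrom,pos,effect_allele,other_allele,beta,se",
               "rs1,GA,1,100,A,G,0.5,0.1",
               "rs1,GB,1,100,A,G,-0.2,0.2",
               "rs2,GA,1,200,T,C,0.1,0.1"), f)
  eq <- read_eqtl_summary(f, cis_window = NULL)
  expect_equal(dim(eq), c(2L, 2L))
  expect_equal(eq$beta["rs1", "GA"], 0.5)
  expect_equal(eq$beta["rs1", "GB"], -0.2)
  expect_false(eq$mask["rs2", "GB"])
  expect_equal(sum(eq$mask), 3L)
})

test_that("invalid rows are rejected: non-positive SEs and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("snp,gene,chrom,pos,effect_allele,other_allele,beta,se",
               "rs1,GA,1,100,A,G,0.5,0"), f)
  expect_error(read_eqtl_summary(f), "se")
  writeLines(c("snp,gene,chrom,pos,effect_allele,other_allele,beta,se",
               "rs1,GA,1,100,A,G,0.5,0.1",
               "rs1,GA,1,100,A,G,0.4,0.1"), f)
  expect_error(read_eqtl_summary(f), "duplicate")
  writeLines("snp,gene,chrom,pos,effect_allele,other_allele,beta,se", f)
  expect_error(read_eqtl_summary(f), "no rows")
  writeLines(c("snp,gene,chrom,pos,beta,se", "rs1,GA,1,100,0.5,0.1"), f)
  expect_error(read_eqtl_summary(f), "mapped column")
})

test_that("cis-window mask of a staircase fixture matches the distance oracle", {
  geo <- cismvmr:::imputation_geometry(526, 9, 1e6)
  idx <- which(geo$mask, arr.ind = TRUE)
  long <- data.frame(snp = sprintf("rs%04d", idx[, 1]),
                     gene = sprintf("G%d", idx[, 2]),
                     chrom = "1", pos = geo$positions[idx[, 1]],
                     effect_allele = "A", other_allele = "G",
                     beta = rnorm(nrow(idx)), se = 1,
                     tss = geo$tss[idx[, 2]])
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  eq <- read_eqtl_summary(f)
  # independent brute-force oracle on the parsed coordinates
  oracle <- matrix(FALSE, nrow(eq$beta), ncol(eq$beta))
  for (j in seq_len(nrow(eq$beta)))
    for (k in seq_len(ncol(eq$beta)))
      oracle[j, k] <- abs(eq$snps$pos[j] - eq$genes$tss[k]) <= 1e6
  expect_identical(unname(eq$mask), oracle)
})

test_that("pivot/unpivot round trip preserves every observed triple", {
  geo <- cismvmr:::imputation_geometry(60, 3, 1e6)
  set.seed(1)
  snps <- snp_frame(sprintf("rs%02d", 1:60), geo$positions)
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "1",
                      tss = geo$tss)
  eq <- eqtl_matrix(snps, genes, matrix(rnorm(180), 60, 3),
                    matrix(runif(180, 0.5, 1), 60, 3), geo$mask)
  long <- eqtl_long(eq)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  eq2 <- read_eqtl_summary(f)
  expect_equal(eq2$beta[eq2$mask], eq$beta[eq$mask])
  expect_equal(eq2$se[eq2$mask], eq$se[eq$mask])
  expect_identical(unname(eq2$mask), unname(eq$mask))
})

make_pair <- function(out_alleles, alpha = c(0.1, 0.2)) {
  snps_e <- snp_frame(c("rs1", "rs2"), c(100L, 200L),
                      ea = c("A", "T"), oa = c("G", "C"))
  eq <- eqtl_matrix(snps_e, data.frame(gene_id = "G1", chrom = "1", tss = 150),
                    matrix(c(1, 2), 2, 1), matrix(1, 2, 1))
  snps_o <- snp_frame(c("rs1", "rs2"), c(100L, 200L),
                      ea = out_alleles$ea, oa = out_alleles$oa)
  ov <- outcome_vector(snps_o, alpha, c(1, 1))
  list(eq = eq, ov = ov)
}

test_that("harmonization keeps, flips, and drops alleles correctly", {
  # identical alleles: untouched
  d <- make_pair(list(ea = c("A", "T"), oa = c("G", "C")))
  h <- harmonize(d$eq, d$ov)
  expect_equal(h$outcome$alpha, c(0.1, 0.2))
  expect_length(h$dropped, 0)

  # swapped alleles: sign flip
  d <- make_pair(list(ea = c("G", "T"), oa = c("A", "C")))
  h <- harmonize(d$eq, d$ov)
  expect_equal(h$outcome$alpha, c(-0.1, 0.2))

  # irreconcilable alleles: dropped and reported
  d <- make_pair(list(ea = c("A", "T"), oa = c("C", "C")))
  expect_message(h <- harmonize(d$eq, d$ov), "dropped")
  expect_equal(h$dropped, "rs1")
  expect_equal(h$eqtl$snps$id, "rs2")

  # empty overlap errors
  d <- make_pair(list(ea = c("A", "T"), oa = c("G", "C")))
  d$ov$snps$id <- c("rsX", "rsY")
  expect_error(harmonize(d$eq, d$ov), "overlap")
})

test_that("harmonization is idempotent", {
  d <- make_pair(list(ea = c("G", "T"), oa = c("A", "C")))
  h1 <- harmonize(d$eq, d$ov)
  h2 <- harmonize(h1$eqtl, h1$outcome)
  expect_equal(h2$eqtl$beta, h1$eqtl$beta)
  expect_equal(h2$outcome$alpha, h1$outcome$alpha)
  expect_length(h2$dropped, 0)
})

test_that("strand-ambiguous SNPs are droppable behind a flag", {
  snps_e <- snp_frame(c("rs1", "rs2"), c(100L, 200L),
                      ea = c("A", "A"), oa = c("T", "G"))
  eq <- eqtl_matrix(snps_e, data.frame(gene_id = "G1", chrom = "1", tss = 150),
                    matrix(c(1, 2), 2, 1), matrix(1, 2, 1))
  ov <- outcome_vector(snps_e, c(0.1, 0.2), c(1, 1))
  expect_equal(harmonize(eq, ov)$eqtl$snps$id, c("rs1", "rs2"))
  expect_message(h <- harmonize(eq, ov, drop_ambiguous = TRUE))
  expect_equal(h$eqtl$snps$id, "rs2")
})

# small helper constructing an eqtl/outcome pair from explicit z matrices
zpair <- function(Z, mask, alpha_z, pos = NULL, tss = NULL) {
  m <- nrow(Z); p <- ncol(Z)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(tss)) tss <- seq_len(p) * 1000L
  snps <- snp_frame(sprintf("rs%03d", seq_len(m)), pos)
  genes <- data.frame(gene_id = sprintf("G%d", seq_len(p)), chrom = "1",
                      tss = tss)
  eq <- eqtl_matrix(snps, genes, Z, matrix(1, m, p), mask)
  ov <- outcome_vector(snps, alpha_z, rep(1, m))
  list(eq = eq, ov = ov)
}

test_that("locus construction groups genes by shared significant eQTLs", {
  # genes 1,2 share a strong eQTL; gene 3 stands alone
  Z <- matrix(0.1, 6, 3)
  Z[1, 1] <- Z[1, 2] <- 8    # shared, p << 0.001
  Z[5, 3] <- 8
  d <- zpair(Z, matrix(TRUE, 6, 3), alpha_z = c(4, 0, 0, 0, 4, 0))
  loci <- build_loci(d$eq, d$ov)
  expect_length(loci, 2)
  sets <- lapply(loci, `[[`, "gene_ids")
  expect_true(any(vapply(sets, function(s) setequal(s, c("G1", "G2")), TRUE)))
  expect_true(any(vapply(sets, function(s) setequal(s, "G3"), TRUE)))

  # no outcome signal below the threshold: empty list
  d2 <- zpair(Z, matrix(TRUE, 6, 3), alpha_z = rep(0.5, 6))
  expect_length(build_loci(d2$eq, d2$ov), 0)
})

test_that("a shared-eQTL chain merges transitively into one locus", {
  # A-B share rs1, B-C share rs2, A and C share nothing directly
  Z <- matrix(0.1, 5, 3)
  Z[1, 1] <- Z[1, 2] <- 7
  Z[2, 2] <- Z[2, 3] <- 7
  d <- zpair(Z, matrix(TRUE, 5, 3), alpha_z = c(4, rep(0, 4)))
  loci <- build_loci(d$eq, d$ov)
  expect_length(loci, 1)
  expect_setequal(loci[[1]]$gene_ids, c("G1", "G2", "G3"))
  expect_true(all(loci[[1]]$iv_intersection %in% loci[[1]]$iv_union))
})

test_that("locus grouping equals a brute-force connected-components oracle", {
  set.seed(42)
  for (rep in 1:20) {
    m <- 12; p <- sample(3:6, 1)
    Z <- matrix(rnorm(m * p, 0, 2), m, p)
    mask <- matrix(runif(m * p) < 0.8, m, p)
    mask[1, ] <- TRUE            # keep every gene observed somewhere
    d <- zpair(Z, mask, alpha_z = rnorm(m, 0, 3))
    loci <- build_loci(d$eq, d$ov, outcome_p = 1)  # keep all components
    # oracle: explicit gene graph + BFS
    pz <- 2 * pnorm(-abs(Z)); pz[!mask] <- NA
    adj <- matrix(FALSE, p, p)
    for (a in 1:p) for (b in 1:p) if (a != b)
      adj[a, b] <- any(!is.na(pz[, a]) & !is.na(pz[, b]) &
                         pz[, a] < 0.001 & pz[, b] < 0.001)
    comp <- rep(NA_integer_, p); cid <- 0
    for (s in 1:p) {
      if (!is.na(comp[s])) next
      cid <- cid + 1; queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    oracle_sets <- split(sprintf("G%d", 1:p), comp)
    got_sets <- lapply(loci, `[[`, "gene_ids")
    expect_setequal(lapply(got_sets, sort), lapply(unname(oracle_sets), sort))
  }
})
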