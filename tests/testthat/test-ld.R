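test_that("PLINK binary filesets round-trip through the reader", {
  set.seed(3)
  n <- 10; m <- 7
  geno <- matrix(sample(c(0, 1, 2, NA), n * m, replace = TRUE,
                        prob = c(0.3, 0.3, 0.3, 0.1)), n, m)
  snps <- data.frame(id = sprintf("rs%d", 1:m), chrom = "1",
                     pos = (1:m) * 100L, a1 = "A", a2 = "G")
  prefix <- write_plink_fixture(withr::local_tempdir(), geno, snps)
  panel <- read_plink(prefix)
  expect_equal(panel$n, n)
  expect_identical(unname(panel$genotypes), unname(geno))
  expect_equal(colnames(panel$genotypes), snps$id)
  expect_equal(panel$snps$pos, as.numeric(snps$pos))
})

test_that("malformed .bed magic bytes are rejected", {
  dir <- withr::local_tempdir()
  prefix <- write_plink_fixture(dir, matrix(c(0, 1, 2, 0), 2, 2),
                                data.frame(id = c("a", "b"), chrom = "1",
                                           pos = 1:2, a1 = "A", a2 = "G"))
  bed <- readBin(paste0(prefix, ".bed"), "raw", 100)
  bed[1] <- as.raw(0)
  writeBin(bed, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
})

test_that("estimate_ld equals the textbook correlation oracle", {
  # 5-SNP toy panel of 6 individuals, complete data
  set.seed(4)
  G <- matrix(sample(0:2, 30, replace = TRUE), 6, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  G[1, 1] <- 2  # ensure polymorphic
  panel <- list(genotypes = G, n = 6)
  R <- estimate_ld(panel)
  # hand-rolled standardization + cross product
  Gs <- scale(G)
  oracle <- crossprod(Gs) / (nrow(G) - 1)
  expect_equal(unclass(R)[1:5, 1:5], oracle[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(R, "n"), 6L)
})

test_that("estimate_ld mean-imputes missing calls and flags monomorphic SNPs", {
  G <- cbind(a = c(1, 1, NA, 2), b = c(1, 1, 1, 1), d = c(0, 1, 2, 0))
  panel <- list(genotypes = G, n = 4)
  expect_warning(R <- estimate_ld(panel), "monomorphic")
  expect_equal(rownames(R), c("a", "d"))
  # mean imputation oracle for column a
  a_imp <- c(1, 1, mean(c(1, 1, 2)), 2)
  expect_equal(R["a", "d"], cor(a_imp, G[, "d"]))
})

test_that("duplicated and independent columns give the expected correlations", {
  set.seed(5)
  x <- sample(0:2, 1e4, replace = TRUE)
  panel <- list(genotypes = cbind(a = x, b = x,
                                  d = sample(0:2, 1e4, replace = TRUE)),
                n = 1e4)
  R <- estimate_ld(panel)
  expect_equal(R["a", "b"], 1)
  expect_lt(abs(R["a", "d"]), 0.05)
})

test_that("greedy pruning keeps the highest-priority representative", {
  expect_equal(ld_prune(diag(1), priority = 1, r2_threshold = 0.09), 1L)
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(ld_prune(R, priority = c(1, 5), 0.25), 2L)
  expect_equal(ld_prune(R, priority = c(5, 1), 0.25), 1L)
  # deterministic index tie-break
  expect_equal(ld_prune(R, priority = c(3, 3), 0.25), 1L)
})

test_that("pruning matches a brute-force greedy oracle on AR(1) LD", {
  R <- cismvmr:::unclass_ld(gen_ar1_ld(10, 0.9))
  set.seed(6)
  for (rep in 1:10) {
    pri <- rnorm(10)
    got <- ld_prune(R, pri, 0.09)
    # independent re-implementation: explicit availability bookkeeping
    avail <- rep(TRUE, 10); keep <- integer(0)
    while (any(avail)) {
      cand <- which(avail)
      j <- cand[order(-pri[cand], cand)][1]
      keep <- c(keep, j)
      for (i in which(avail)) if (R[j, i]^2 > 0.09) avail[i] <- FALSE
      avail[j] <- FALSE
    }
    expect_equal(got, sort(keep))
  }
})

test_that("pruning is invariant to row order given identical priorities", {
  R <- cismvmr:::unclass_ld(gen_ar1_ld(8, 0.8))
  pri <- c(3, 1, 4, 1, 5, 9, 2, 6)
  keep1 <- ld_prune(R, pri, 0.2)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  keep2 <- ld_prune(R[perm, perm], pri[perm], 0.2)
  expect_setequal(perm[keep2], keep1)
})

test_that("PD regularization shrinks minimally and preserves structure", {
  R <- gen_ar1_ld(5, 0.5)
  out <- regularize_pd(R, floor = 1e-3)
  expect_equal(attr(out, "shrinkage"), 0)
  expect_equal(unclass(out), unclass(R), ignore_attr = TRUE)

  # 2x2 closed form: eigenvalues 1 +/- |r|
  R2 <- matrix(c(1, 1, 1, 1), 2, 2)
  out2 <- regularize_pd(R2, floor = 0.01)
  s <- attr(out2, "shrinkage")
  expect_equal(s, (0.01 - 0) / (1 - 0))
  expect_equal(min(eigen(out2)$values), 0.01, tolerance = 1e-12)
  expect_equal(diag(out2), c(1, 1), ignore_attr = TRUE)

  # s = 1 limit gives the identity
  out3 <- regularize_pd(R2, floor = 1)
  expect_equal(unclass(out3), diag(2), ignore_attr = TRUE)
})

test_that("regularization output is symmetric PD with s monotone in floor", {
  set.seed(8)
  A <- matrix(rnorm(49), 7, 7); S <- cov2cor(crossprod(A) + diag(7) * 0.01)
  # make it indefinite by pushing correlations
  S[1, 2] <- S[2, 1] <- 0.999; S[1, 3] <- S[3, 1] <- -0.999
  S[2, 3] <- S[3, 2] <- 0.9
  floors <- c(1e-4, 1e-3, 1e-2, 0.1)
  s_prev <- -1
  for (f in floors) {
    out <- suppressWarnings(regularize_pd(ld_matrix(cov2cor(S)), f))
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), f - 1e-10)
    expect_equal(diag(out), rep(1, 7), ignore_attr = TRUE)
    expect_gte(attr(out, "shrinkage"), s_prev)
    s_prev <- attr(out, "shrinkage")
  }
})

test_that("Wishart-sampled LD is reproducible and consistent", {
  R <- gen_ar1_ld(5, 0.5)
  W1 <- sample_wishart_ld(R, df = 50, seed = 11)
  W2 <- sample_wishart_ld(R, df = 50, seed = 11)
  expect_identical(unclass(W1), unclass(W2))
  expect_equal(attr(W1, "n"), 50L)
  expect_error(sample_wishart_ld(R, df = 3), "singular")

  # df -> large: elementwise convergence to the truth
  Wbig <- sample_wishart_ld(R, df = 1e6, seed = 12)
  expect_lt(max(abs(unclass(Wbig) - unclass(R))), 0.01)
})

test_that("Wishart-derived correlations have the expected moments", {
  set.seed(13)
  df <- 50; nrep <- 2000
  R <- gen_ar1_ld(4, 0)          # identity truth
  offs <- replicate(nrep, {
    W <- sample_wishart_ld(R, df)
    W[upper.tri(W)]
  })
  expect_lt(abs(mean(offs)), 3 * sqrt(1 / df / length(offs)) + 0.005)
  # var of a correlation estimate around 0 is ~ 1/df
  expect_equal(mean(offs^2), 1 / df, tolerance = 0.1)
})

test_that("plain-text LD matrices round-trip", {
  R <- gen_ar1_ld(4, 0.3)
  dimnames(R) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(round(unclass(R), 10), f, quote = FALSE, row.names = FALSE)
  R2 <- read_ld_text(f, n = 99)
  expect_equal(unclass(R2), unclass(R), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rownames(R2), rownames(R))
  expect_equal(attr(R2, "n"), 99L)
})
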