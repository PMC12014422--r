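test_that("the estimator reduces to the OLS/IVW slope without bias correction", {
  set.seed(1)
  beta <- rnorm(10, 0, 2)
  alpha <- 0.4 * beta + rnorm(10, 0, 0.3)
  fit <- mrbee(matrix(beta), alpha, prune = FALSE)
  expect_equal(unname(fit$theta), sum(beta * alpha) / sum(beta^2),
               tolerance = 1e-12)
})

test_that("orthonormal designs are solved exactly", {
  Q <- qr.Q(qr(matrix(rnorm(40), 10, 4)))[, 1:2]
  alpha <- drop(Q %*% c(1, -2))
  fit <- mrbee(Q, alpha, prune = FALSE)
  expect_equal(unname(fit$theta), c(1, -2), tolerance = 1e-10)
  # Pratt identity and perfect fit
  expect_equal(fit$locus_r2, 1, tolerance = 1e-10)
  expect_equal(sum(fit$pratt), 1, tolerance = 1e-10)
})

test_that("the full estimator matches a direct matrix-expression oracle", {
  set.seed(2)
  m <- 5; p <- 2
  B <- matrix(rnorm(m * p, 0, 3), m, p)
  alpha <- rnorm(m, 0, 2)
  R <- gen_ar1_ld(m, 0.4)
  Sigma <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  fit <- mrbee(B, alpha, R = R, bias = bias_matrix(Sigma), prune = FALSE)
  # independent evaluation of the closed-form expression
  Rinv <- solve(cismvmr:::unclass_ld(R))
  oracle <- solve(t(B) %*% Rinv %*% B - m * Sigma, t(B) %*% Rinv %*% alpha)
  expect_equal(unname(fit$theta), drop(oracle), tolerance = 1e-10)
})

test_that("with Sigma = 0 the estimator equals generalized IVW exactly", {
  set.seed(3)
  for (rep in 1:5) {
    m <- 12; p <- 3
    B <- matrix(rnorm(m * p), m, p)
    alpha <- rnorm(m)
    R <- gen_ar1_ld(m, 0.5)
    fit <- mrbee(B, alpha, R = R, bias = NULL, prune = FALSE)
    ivw <- ivw_fit(B, alpha, R = R)
    expect_equal(unname(fit$theta), unname(ivw$theta), tolerance = 1e-10)
  }
})

test_that("ivw_fit matches a hand generalized-least-squares computation", {
  B <- matrix(c(1, 2, 3), 3, 1)
  alpha <- c(0.5, 0.8, 1.6)
  R <- matrix(c(1, 0.5, 0.25, 0.5, 1, 0.5, 0.25, 0.5, 1), 3, 3)
  ivw <- ivw_fit(B, alpha, ld_matrix(R))
  Rinv <- solve(R)
  theta_hand <- drop(t(B) %*% Rinv %*% alpha) / drop(t(B) %*% Rinv %*% B)
  expect_equal(unname(ivw$theta), theta_hand, tolerance = 1e-12)
  # fixed-effect convention: unit residual variance
  expect_equal(unname(ivw$se), sqrt(1 / drop(t(B) %*% Rinv %*% B)),
               tolerance = 1e-12)
  # identity LD reduces to the classic weighted slope
  ivw0 <- ivw_fit(B, alpha)
  expect_equal(unname(ivw0$theta), sum(B * alpha) / sum(B^2))
})

test_that("corrected statistics follow the stated closed form", {
  # worked value: n = 500, m = 100, L = 2
  ci <- corrected_inference(2, 1, n_panel = 500, m = 100)
  expect_equal(ci$L_tilde, 2 * sqrt(401 / 500), tolerance = 1e-12)
  expect_equal(ci$L_tilde, 1.7911, tolerance = 1e-4)
  expect_equal(ci$df, 99)

  # machine-precision identity on random fixtures
  set.seed(4)
  for (rep in 1:20) {
    p <- sample(1:4, 1)
    theta <- rnorm(p); se2 <- runif(p, 0.1, 2)
    m <- sample(10:200, 1); n <- m + sample(5:2000, 1)
    ci <- corrected_inference(theta, diag(se2, p), n, m, p)
    expect_equal(ci$L_tilde, sqrt((n - m + 1) / n) * ci$L, tolerance = 1e-15)
    expect_true(all(abs(ci$L_tilde) <= abs(ci$L) + 1e-15))
    expect_true(all(ci$pvals >= 0 & ci$pvals <= 1))
  }

  # n -> infinity restores the naive statistic
  ci_inf <- corrected_inference(1.5, 0.25, n_panel = 1e12, m = 50)
  expect_equal(ci_inf$L_tilde, ci_inf$L, tolerance = 1e-9)

  expect_error(corrected_inference(1, 1, n_panel = 99, m = 100), "prune")
})

test_that("locus fit statistics decompose variance as Pratt indices", {
  set.seed(5)
  # single regressor: pratt equals the R-squared
  beta <- rnorm(20); alpha <- 0.5 * beta + rnorm(20, 0, 0.5)
  fit <- mrbee(matrix(beta), alpha, prune = FALSE)
  expect_equal(unname(fit$pratt), fit$locus_r2, tolerance = 1e-10)

  # orthogonal columns: indices sum exactly to the locus R-squared
  Q <- qr.Q(qr(matrix(rnorm(60), 20, 3)))
  y <- drop(Q %*% c(1, 2, -1)) + rnorm(20, 0, 0.8)
  f2 <- mrbee(Q, y, prune = FALSE)
  expect_equal(sum(f2$pratt), f2$locus_r2, tolerance = 1e-8)

  # correlated two-gene toy against the textbook b * r computation
  B <- cbind(c(1, 2, 0, 1, 3), c(0.5, 1.5, 1, 0, 2))
  y2 <- c(0.7, 2.1, 0.4, 0.6, 2.9)
  f3 <- mrbee(B, y2, prune = FALSE)
  th <- unname(f3$theta)
  r_marg <- c(sum(B[, 1] * y2) / sqrt(sum(B[, 1]^2) * sum(y2^2)),
              sum(B[, 2] * y2) / sqrt(sum(B[, 2]^2) * sum(y2^2)))
  th_std <- th * sqrt(colSums(B^2) / sum(y2^2))
  expect_equal(unname(f3$pratt), th_std * r_marg, tolerance = 1e-10)
  expect_equal(sum(f3$pratt), f3$locus_r2, tolerance = 1e-10)
})

test_that("locus_fit_stats agrees with the values stored on the fit", {
  set.seed(6)
  B <- matrix(rnorm(30), 15, 2)
  y <- drop(B %*% c(0.3, -0.2)) + rnorm(15, 0, 0.5)
  R <- gen_ar1_ld(15, 0.3)
  fit <- mrbee(B, y, R = R, prune = FALSE)
  fs <- locus_fit_stats(B, y, fit$theta, R = R)
  expect_equal(fs$locus_r2, fit$locus_r2)
  expect_equal(fs$pratt, unname(fit$pratt))
})

test_that("pleiotropy pruning removes planted outliers and respects thresholds", {
  set.seed(7)
  m <- 60
  beta <- rnorm(m, 0, 2)
  alpha <- 0.3 * beta + rnorm(m)
  alpha[5] <- alpha[5] + 10          # gross direct effect
  kept <- pleiotropy_prune(matrix(beta), alpha, p_threshold = 0.05)
  expect_false(5 %in% kept)

  # threshold zero: no removals possible
  expect_equal(pleiotropy_prune(matrix(beta), alpha, p_threshold = 0),
               seq_len(m))
})

test_that("pleiotropy pruning drops about the nominal fraction under the null", {
  set.seed(8)
  drops <- replicate(40, {
    m <- 80
    beta <- rnorm(m, 0, 3)
    alpha <- 0.3 * beta + rnorm(m)
    1 - length(pleiotropy_prune(matrix(beta), alpha, p_threshold = 0.05)) / m
  })
  # iterated testing removes slightly more than 5%; allow a generous band
  expect_gt(mean(drops), 0.01)
  expect_lt(mean(drops), 0.12)
})

test_that("aggressive pruning aborts the locus with a diagnostic", {
  set.seed(9)
  B <- matrix(rnorm(8), 4, 2)
  alpha <- rnorm(4, 0, 10)
  expect_error(suppressWarnings(pleiotropy_prune(B, alpha, p_threshold = 0.9)),
               "p \\+ 1|instruments")
})

test_that("fit methods expose the model consistently", {
  set.seed(10)
  m <- 30
  B <- matrix(rnorm(m * 2), m, 2, dimnames = list(NULL, c("geneA", "geneB")))
  y <- drop(B %*% c(0.4, 0)) + rnorm(m, 0, 0.5)
  R <- regularize_pd(sample_wishart_ld(gen_ar1_ld(m, 0.3), df = 200, seed = 1))
  fit <- mrbee(B, y, R = R, prune = FALSE)

  expect_s3_class(fit, "mrbee")
  expect_named(coef(fit), c("geneA", "geneB"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(fit$se))
  expect_length(residuals(fit), m)
  expect_equal(fitted(fit) + residuals(fit),
               drop(cismvmr:::sym_mat_power(fit$R, -0.5) %*% fit$y),
               tolerance = 1e-10)
  expect_equal(predict(fit, diag(2)), unname(coef(fit)))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  # panel-corrected inference is attached because R carries its n
  expect_equal(fit$n_panel, 200L)
  expect_equal(unname(fit$L_tilde),
               unname(fit$L) * sqrt((200 - m + 1) / 200))
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(m, 3))
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("MRBEE", out)))
  expect_true(any(grepl("geneA", out)))
})

test_that("bias correction restores the causal effect under weak instruments", {
  set.seed(11)
  nrep <- 120; m <- 100
  R <- gen_ar1_ld(m, 0.5)
  cR <- chol(cismvmr:::unclass_ld(R))
  est_c <- est_n <- numeric(nrep)
  for (r in seq_len(nrep)) {
    b_true <- drop(crossprod(cR, rnorm(m, 0, 1))) * sqrt(14)
    B <- b_true + drop(crossprod(cR, rnorm(m)))
    alpha <- 0.3 * b_true + drop(crossprod(cR, rnorm(m)))
    est_c[r] <- mrbee(matrix(B), alpha, R = R,
                      bias = bias_matrix(matrix(1, 1, 1)),
                      prune = FALSE)$theta
    est_n[r] <- ivw_fit(matrix(B), alpha, R = R)$theta
  }
  mc_se <- sd(est_c) / sqrt(nrep)
  expect_lt(abs(mean(est_c) - 0.3), 3 * mc_se)
  # the naive estimator is attenuated towards zero
  expect_lt(mean(est_n), mean(est_c))
  expect_gt(mean(est_n), 0)
})
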