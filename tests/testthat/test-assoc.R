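test_that("null fit satisfies GLS orthogonality and matches dense algebra", {
  fx <- test_scan_null()
  ds <- fx$dataset
  fit <- fit_null(ds$traits[1, ], ds$covariates, ds$phi)
  # W' R = 0 (GLS normal equations)
  expect_lt(max(abs(crossprod(ds$covariates, fit$residual_r))),
            1e-8 * sqrt(sum(fit$residual_r^2)))
  # residual matches a dense solve of Sigma0^-1 (y - W beta0)
  sigma0 <- fit$sigma_e2 * diag(fit$n) + fit$sigma_a2 * ds$phi
  r_dense <- solve(sigma0, ds$traits[1, ] - drop(ds$covariates %*% fit$beta0))
  expect_equal(fit$residual_r, unname(r_dense), tolerance = 1e-8)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
  expect_true(all(c("sigma_e2", "sigma_a2", "loglik") %in% names(glance(fit))))
})

test_that("LS statistic equals the dense GLS score formula", {
  fx <- test_scan_null()
  ds <- fx$dataset
  for (j in c(2, 7)) {
    fit <- fit_null(ds$traits[j, ], ds$covariates, ds$phi)
    x <- ds$genotypes[j, ]
    res <- ls_test(x, fit)
    sigma0 <- fit$sigma_e2 * diag(fit$n) + fit$sigma_a2 * ds$phi
    vi <- solve(sigma0)
    W <- ds$covariates
    P <- vi - vi %*% W %*% solve(crossprod(W, vi %*% W), crossprod(W, vi))
    s_dense <- drop(crossprod(x, P %*% ds$traits[j, ]))^2 /
      drop(crossprod(x, P %*% x))
    expect_equal(res$s_stat, s_dense, tolerance = 1e-7)
    expect_equal(res$z_stat^2, res$s_stat, tolerance = 1e-12)
    expect_equal(res$p_value, pchisq(res$s_stat, 1, lower.tail = FALSE))
  }
})

test_that("independence limit recovers the OLS score test", {
  set.seed(61)
  n <- 1500
  W <- cbind(1, runif(n, 18, 80), rbinom(n, 1, 0.7))
  x <- rbinom(n, 2, 0.3)
  y <- drop(W %*% c(1, 0.5, 0.8)) + rnorm(n, sd = sqrt(1.5))
  fit <- fit_null(y, W, diag(n))
  # with Phi = I only the total variance is identifiable
  expect_lt(abs(fit$sigma_e2 + fit$sigma_a2 - 1.5), 0.15)
  expect_equal(unname(fit$beta0), unname(coef(lm(y ~ W - 1))), tolerance = 0.02)
  # classical OLS score statistic for adding x
  e <- resid(lm(y ~ W - 1))
  sig2 <- sum(e^2) / n
  M <- diag(n) - W %*% solve(crossprod(W), t(W))
  s_ols <- sum(x * e)^2 / (sig2 * drop(crossprod(x, M %*% x)))
  expect_equal(ls_test(x, fit)$s_stat, s_ols, tolerance = 0.02)
})

test_that("hand-computed QLS case gives exactly 8", {
  s <- qls_stat(c(2, 0, 2, 0), c(1, -1, 1, -1), diag(4), 0.5)
  expect_equal(s, 8)
})

test_that("orthogonal genotype gives a null test result", {
  fx <- test_scan_null()
  ds <- fx$dataset
  fit <- fit_null(ds$traits[3, ], ds$covariates, ds$phi)
  # x orthogonal to R by construction
  r <- fit$residual_r
  x <- rep(0, length(r)); x[1] <- 1; x[2] <- -r[1] / r[2]
  expect_equal(sum(x * r), 0, tolerance = 1e-12)
  res <- qls_test_safe <- qls_stat(x, r, ds$phi, 0.3)
  expect_equal(res, 0)
})

test_that("degenerate genotypes raise undefined-test errors", {
  fx <- test_scan_null()
  ds <- fx$dataset
  fit <- fit_null(ds$traits[4, ], ds$covariates, ds$phi)
  expect_error(ls_test(rep(1, fit$n), fit), "monomorphic|degenerate")
  expect_error(qls_test(rep(2, fit$n), fit), "boundary")
})

test_that("allele-label flip preserves S and flips Z", {
  fx <- test_scan_null()
  ds <- fx$dataset
  fit <- fit_null(ds$traits[6, ], ds$covariates, ds$phi)
  x <- ds$genotypes[6, ]
  a <- ls_test(x, fit); b <- ls_test(2 - x, fit)
  expect_equal(a$s_stat, b$s_stat, tolerance = 1e-9)
  expect_equal(a$z_stat, -b$z_stat, tolerance = 1e-9)
  qa <- qls_test(x, fit); qb <- qls_test(2 - x, fit)
  expect_equal(qa$s_stat, qb$s_stat, tolerance = 1e-9)
  expect_equal(qa$z_stat, -qb$z_stat, tolerance = 1e-9)
})

test_that("score statistics are invariant to trait rescaling", {
  fx <- test_scan_null()
  ds <- fx$dataset
  x <- ds$genotypes[8, ]
  f1 <- fit_null(ds$traits[8, ], ds$covariates, ds$phi)
  f2 <- fit_null(3.7 * ds$traits[8, ], ds$covariates, ds$phi)
  expect_equal(ls_test(x, f1)$s_stat, ls_test(x, f2)$s_stat, tolerance = 1e-5)
  expect_equal(qls_test(x, f1)$s_stat, qls_test(x, f2)$s_stat, tolerance = 1e-5)
})

test_that("genome scan agrees with per-SNP fits and is order-invariant", {
  fx <- test_scan_null()
  ds <- fx$dataset
  scan <- fx$scan
  expect_equal(nrow(scan), 400)
  for (j in c(10, 250)) {
    fit <- fit_null(ds$traits[j, ], ds$covariates, ds$phi)
    expect_equal(scan$s_ls[j], ls_test(ds$genotypes[j, ], fit)$s_stat,
                 tolerance = 1e-6)
    expect_equal(scan$s_qls[j], qls_test(ds$genotypes[j, ], fit)$s_stat,
                 tolerance = 1e-6)
  }
  # order invariance: scanning a reordered dataset gives identical rows
  ord <- rev(seq_len(50))
  ds_r <- subset_dataset(ds, ord)
  scan_r <- genome_scan(ds_r)
  # refinement brackets can shift by one grid cell between runs, so the
  # agreement is to optimizer tolerance, not machine precision
  expect_equal(scan_r$s_ls, scan$s_ls[ord], tolerance = 1e-5)
  expect_equal(scan_r$s_qls, scan$s_qls[ord], tolerance = 1e-5)
})

test_that("LS and QLS Z statistics are strongly correlated", {
  fx <- test_scan_null()
  ok <- fx$scan$flag == "ok"
  expect_gt(cor(fx$scan$z_ls[ok], fx$scan$z_qls[ok]), 0.9)
})

test_that("shared-trait scans reuse one null fit and rank the causal SNP first", {
  ped <- canonical_cohort(10)
  ds <- simulate_dataset(ped, sim_params(n_snps = 60, seed = 17, effect_k = 2.5),
                         shared_trait = TRUE)
  scan <- genome_scan(ds)
  expect_equal(length(unique(scan$sigma_e2_hat)), 1L)
  expect_equal(scan$snp_id[which.min(scan$p_ls)], "snp00001")
})

test_that("parameter recovery: variance components are estimated consistently", {
  ped <- canonical_cohort(10)
  est <- matrix(NA_real_, 60, 2)
  for (i in seq_len(nrow(est))) {
    ds <- simulate_dataset(ped, sim_params(n_snps = 1, seed = 9000 + i))
    fit <- fit_null(ds$traits[1, ], ds$covariates, ds$phi)
    est[i, ] <- c(fit$sigma_e2, fit$sigma_a2)
  }
  expect_lt(abs(mean(est[, 1]) - 1.5), 0.2)
  expect_lt(abs(mean(est[, 2]) - 2.5), 0.35)
})
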