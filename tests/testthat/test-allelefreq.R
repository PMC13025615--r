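test_that("naive counting estimators are exact fractions", {
  expect_equal(naive_af(rep(0, 6))$value, 0)
  expect_equal(naive_af(c(2, 1, 1, 0))$value, 0.5)
  expect_error(naive_af(c(1, 2), integer(0)), "non-empty")
})

test_that("whole-sample count decomposes exactly into founder and descendant counts", {
  ped <- canonical_family()
  part <- ped_partition(ped)
  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:2, 10, replace = TRUE)
    p_a <- naive_af(x)$value
    p_f <- naive_af(x, part$founders)$value
    p_d <- naive_af(x, part$descendants)$value
    expect_equal(10 * p_a, part$nf * p_f + part$nd * p_d)
  }
})

test_that("BLUE equals a brute-force GLS solve and collapses to naive for Phi = I", {
  ped <- test_cohort()
  phi <- test_phi()
  phi_inv <- solve(phi)
  set.seed(21)
  for (i in 1:10) {
    x <- as.vector(gene_drop(ped, 0.35, 1))
    est <- blue_af(x, phi)$value
    # numerical minimiser of (X - 2c 1)' Phi^-1 (X - 2c 1)
    obj <- function(cc) {
      r <- x - 2 * cc
      drop(crossprod(r, phi_inv %*% r))
    }
    gls <- optimize(obj, c(-1, 2))$minimum
    expect_equal(est, gls, tolerance = 1e-5)
  }
  x <- c(2, 1, 1, 0)
  expect_equal(blue_af(x, diag(4))$value, naive_af(x)$value)
  expect_equal(blue_af(rep(2, 10), kinship_matrix(canonical_family()))$value, 1)
})

test_that("analytic covariances reproduce the closed-form pedigree identities", {
  ped <- canonical_cohort(10)
  phi <- kinship_matrix(ped)
  part <- ped_partition(ped)
  n <- nrow(ped); nf <- part$nf; nd <- part$nd
  p <- 0.3
  sigma_x2 <- 2 * p * (1 - p)
  all_idx <- seq_len(n)
  # var(p_f): founders mutually unrelated -> binomial variance
  expect_equal(af_cov_analytic(phi, part$founders, part$founders, p),
               sigma_x2 / (4 * nf))
  # cov(p_f, p_d) = cov(p_a, p_f) = sigma_X^2 / (4 nf)
  expect_equal(af_cov_analytic(phi, part$founders, part$descendants, p),
               sigma_x2 / (4 * nf))
  expect_equal(af_cov_analytic(phi, all_idx, part$founders, p),
               sigma_x2 / (4 * nf))
  # cov(p_a, p_d) = sigma_X^2 / (4 nd) (1' Phi 1 / n - 1)
  expect_equal(af_cov_analytic(phi, all_idx, part$descendants, p),
               sigma_x2 / (4 * nd) * (sum(phi) / n - 1))
  # and it exceeds the founder-based covariances
  expect_gt(af_cov_analytic(phi, all_idx, part$descendants, p),
            af_cov_analytic(phi, part$founders, part$descendants, p))
})

test_that("analytic variance ordering: founders <= all <= descendants; BLUE best", {
  ped <- canonical_cohort(10)
  phi <- kinship_matrix(ped)
  part <- ped_partition(ped)
  all_idx <- seq_len(nrow(ped))
  for (p in c(0.1, 0.25, 0.4)) {
    v_f <- af_cov_analytic(phi, part$founders, part$founders, p)
    v_a <- af_cov_analytic(phi, all_idx, all_idx, p)
    v_d <- af_cov_analytic(phi, part$descendants, part$descendants, p)
    expect_lte(v_f, v_a)
    expect_lte(v_a, v_d)
    v_blue <- af_var_blue(phi, p)
    expect_lte(v_blue, v_f + 1e-12)
  }
})

test_that("within (1-w) p_f + w p_d the founder estimator is optimal on [0, 1]", {
  ped <- canonical_cohort(10)
  phi <- kinship_matrix(ped)
  part <- ped_partition(ped)
  p <- 0.3
  v_f <- af_cov_analytic(phi, part$founders, part$founders, p)
  v_d <- af_cov_analytic(phi, part$descendants, part$descendants, p)
  c_fd <- af_cov_analytic(phi, part$founders, part$descendants, p)
  var_w <- function(w) (1 - w)^2 * v_f + w^2 * v_d + 2 * w * (1 - w) * c_fd
  grid <- seq(0, 1, by = 0.01)
  expect_equal(which.min(var_w(grid)), 1L)
  # stationary point of the quadratic is at w = 0 (v_f equals c_fd here)
  w_star <- (v_f - c_fd) / (v_f + v_d - 2 * c_fd)
  expect_equal(w_star, 0)
})

test_that("Monte-Carlo estimator moments match the analytic oracle", {
  ped <- canonical_cohort(10)
  phi <- kinship_matrix(ped)
  part <- ped_partition(ped)
  all_idx <- seq_len(nrow(ped))
  p <- 0.3
  n_rep <- 1e5
  set.seed(2025)
  g <- gene_drop(ped, p, n_rep)
  p_a <- rowMeans(g) / 2
  p_f <- rowSums(g[, part$founders]) / (2 * part$nf)
  p_d <- rowSums(g[, part$descendants]) / (2 * part$nd)
  # unbiasedness within 3 Monte-Carlo SEs
  for (est in list(p_a, p_f, p_d)) {
    se <- sd(est) / sqrt(n_rep)
    expect_lt(abs(mean(est) - p), 3 * se)
  }
  # covariances within 3 SEs of the analytic values (SE of a sample covariance
  # approximated by sd of the centred cross-products / sqrt(n))
  pairs <- list(
    list(p_f, p_d, af_cov_analytic(phi, part$founders, part$descendants, p)),
    list(p_a, p_f, af_cov_analytic(phi, all_idx, part$founders, p)),
    list(p_a, p_d, af_cov_analytic(phi, all_idx, part$descendants, p)))
  for (pr in pairs) {
    cp <- (pr[[1]] - mean(pr[[1]])) * (pr[[2]] - mean(pr[[2]]))
    se <- sd(cp) / sqrt(n_rep)
    expect_lt(abs(cov(pr[[1]], pr[[2]]) - pr[[3]]), 3 * se)
  }
})

test_that("af_table assembles the four estimators consistently", {
  ped <- canonical_family()
  set.seed(4)
  x <- as.vector(gene_drop(ped, 0.4, 1))
  tab <- af_table(ped, x)
  expect_equal(tab$estimator_kind, c("all", "founders", "descendants", "blue"))
  expect_true(all(tab$value >= 0 & tab$value <= 1))
  expect_equal(tab$n_used, c(10, 4, 6, 10))
})
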