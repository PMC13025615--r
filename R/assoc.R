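#' Fit the null linear mixed model
#'
#' Fits Y = W beta0 + eps, eps ~ N(0, Sigma0), Sigma0 = sigma_e2 I +
#' sigma_a2 Phi, by full maximum likelihood. Phi is eigendecomposed once
#' (Phi = U Lambda U'); beta0 and the overall scale are profiled out and the
#' variance ratio delta = sigma_a2 / sigma_e2 is optimized by bounded scalar
#' search on log(delta) in \[-12, 12\] (tolerance 1e-8). A fit whose optimum
#' sits at the lower boundary is snapped to sigma_a2 = 0 and flagged.
#'
#' @param y Trait vector (length n).
#' @param W Covariate matrix (n x q, intercept included, full column rank).
#' @param phi Positive-definite kinship matrix.
#' @return An object of class `kin_nullfit`: coefficients `beta0`, variance
#'   components `sigma_e2`/`sigma_a2`, `delta`, `loglik`, the transformed
#'   phenotypic residual `residual_r` = Sigma0^-1 (y - W beta0), `boundary`
#'   flag, and the reusable eigen machinery.
#' @examples
#' ped <- canonical_cohort(2)
#' ds <- simulate_dataset(ped, sim_params(n_snps = 1, seed = 7))
#' fit <- fit_null(ds$traits[1, ], ds$covariates, ds$phi)
#' glance(fit)
#' @export
fit_null <- function(y, W, phi) {
  n <- length(y)
  W <- as.matrix(W)
  q <- ncol(W)
  if (n <= q) rlang::abort("need n > q observations")
  if (qr(W)$rank < q) rlang::abort("covariate matrix W is rank-deficient")
  eig <- eigen(phi, symmetric = TRUE)
  if (min(eig$values) <= 0) rlang::abort("kinship matrix is not positive definite")
  Wt <- crossprod(eig$vectors, W)
  yt <- drop(crossprod(eig$vectors, y))
  prof <- profile_delta(yt, Wt, eig$values, n)
  res <- null_from_delta(prof$delta, yt, Wt, eig$values, n)
  rt <- (yt - drop(Wt %*% res$beta0)) / (res$sigma_e2 * res$d)
  r <- drop(eig$vectors %*% rt)
  structure(list(beta0 = setNames(res$beta0, colnames(W)),
                 sigma_e2 = res$sigma_e2, sigma_a2 = res$sigma_a2,
                 delta = prof$delta, loglik = res$loglik,
                 residual_r = r, residual_rt = rt,
                 boundary = prof$boundary,
                 eig = eig, Wt = Wt, W = W, phi = phi, n = n, q = q),
            class = "kin_nullfit")
}

# profile log-likelihood of log(delta); shared by fit_null and genome_scan
profile_ll <- function(ld, yt, Wt, lam, n) {
  d <- 1 + exp(ld) * lam
  A <- crossprod(Wt, Wt / d)
  b <- crossprod(Wt, yt / d)
  beta <- solve(A, b)
  rss <- sum(yt^2 / d) - sum(b * beta)
  -0.5 * (n * log(rss / n) + sum(log(d)))
}

profile_delta <- function(yt, Wt, lam, n, lower = -12, upper = 12, tol = 1e-8) {
  opt <- optimize(profile_ll, c(lower, upper), maximum = TRUE,
                  yt = yt, Wt = Wt, lam = lam, n = n, tol = tol)
  ld <- opt$maximum
  boundary <- ld < lower + 0.01
  # a lower-boundary optimum means sigma_a2 ~ 0; use the exact limit
  if (boundary) {
    ll0 <- profile_ll(-Inf, yt, Wt, lam, n)
    if (ll0 >= opt$objective) return(list(delta = 0, boundary = TRUE))
  }
  list(delta = exp(ld), boundary = boundary)
}

null_from_delta <- function(delta, yt, Wt, lam, n) {
  d <- 1 + delta * lam
  A <- crossprod(Wt, Wt / d)
  b <- crossprod(Wt, yt / d)
  beta0 <- drop(solve(A, b))
  rss <- sum(yt^2 / d) - sum(b * beta0)
  sigma_e2 <- rss / n
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma_e2) + sum(log(d)) + n)
  list(beta0 = beta0, sigma_e2 = sigma_e2, sigma_a2 = delta * sigma_e2,
       d = d, loglik = loglik)
}

#' @export
print.kin_nullfit <- function(x, ...) {
  cat(sprintf("<kin_nullfit> n = %d, q = %d\n", x$n, x$q))
  cat("  beta0:   ", paste(format(x$beta0, digits = 4), collapse = "  "), "\n")
  cat(sprintf("  sigma_e2 = %.4f, sigma_a2 = %.4f%s, loglik = %.2f\n",
              x$sigma_e2, x$sigma_a2,
              if (x$boundary) " (boundary)" else "", x$loglik))
  invisible(x)
}

#' @rdname fit_null
#' @param x A `kin_nullfit` object.
#' @param ... Unused.
#' @method tidy kin_nullfit
#' @export
tidy.kin_nullfit <- function(x, ...) {
  tibble::tibble(term = names(x$beta0) %||% paste0("beta", seq_along(x$beta0) - 1),
                 estimate = unname(x$beta0))
}

#' @rdname fit_null
#' @method glance kin_nullfit
#' @export
glance.kin_nullfit <- function(x, ...) {
  tibble::tibble(sigma_e2 = x$sigma_e2, sigma_a2 = x$sigma_a2,
                 delta = x$delta, loglik = x$loglik,
                 boundary = x$boundary, n = x$n, q = x$q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_result_row <- function(kind, xtr, s) {
  z <- sign(xtr) * sqrt(s)
  tibble::tibble(test_kind = kind, xtr = xtr, z_stat = z, s_stat = s,
                 p_value = pchisq(s, df = 1, lower.tail = FALSE))
}

#' Prospective likelihood score (LS) test
#'
#' S_LS = (X'R)^2 / (X' P X) with P = Sigma0^-1 - Sigma0^-1 W
#' (W' Sigma0^-1 W)^-1 W' Sigma0^-1 evaluated at the null fit, R the
#' transformed phenotypic residual, and Z_LS = sign(X'R) sqrt(S_LS). Under the
#' null S_LS is chi-square with 1 degree of freedom.
#'
#' @param x Genotype vector (0/1/2), pedigree order.
#' @param fit A [fit_null()] object.
#' @return A one-row tibble: `test_kind`, `xtr`, `z_stat`, `s_stat`, `p_value`.
#' @export
ls_test <- function(x, fit) {
  stopifnot(inherits(fit, "kin_nullfit"), length(x) == fit$n)
  xt <- drop(crossprod(fit$eig$vectors, x))
  dv <- fit$sigma_e2 * (1 + fit$delta * fit$eig$values)
  denom <- ls_denominator(xt, fit$Wt, dv)
  if (denom <= 0) rlang::abort("LS test undefined: monomorphic or degenerate genotype")
  xtr <- sum(x * fit$residual_r)
  test_result_row("LS", xtr, xtr^2 / denom)
}

ls_denominator <- function(xt, Wt, dv) {
  a <- crossprod(Wt, xt / dv)
  M <- crossprod(Wt, Wt / dv)
  drop(sum(xt^2 / dv) - crossprod(a, solve(M, a)))
}

#' Retrospective quasi-likelihood score (QLS / MASTOR) test
#'
#' S_QLS = (R'X)^2 / (R' Phi R sigma_X^2), where sigma_X^2 = 2 p (1 - p) with
#' p the BLUE allele frequency of X on Phi. Z and the chi-square-1 p-value are
#' formed as for the LS test.
#'
#' @inheritParams ls_test
#' @return A one-row tibble as for [ls_test()], plus `p_blue`.
#' @export
qls_test <- function(x, fit) {
  stopifnot(inherits(fit, "kin_nullfit"), length(x) == fit$n)
  p_hat <- blue_af(x, fit$phi)$value
  if (p_hat <= 0 || p_hat >= 1) {
    rlang::abort("QLS test undefined: BLUE allele frequency at the boundary")
  }
  xtr <- sum(x * fit$residual_r)
  s <- qls_stat(x, fit$residual_r, fit$phi, p_hat)
  out <- test_result_row("QLS", xtr, s)
  out$p_blue <- p_hat
  out
}

#' Low-level QLS statistic
#'
#' Direct arithmetic form of the retrospective score statistic for a given
#' residual vector: (R'X)^2 / (R' Phi R * 2 p (1 - p)).
#'
#' @param x Genotype vector.
#' @param r Transformed phenotypic residual.
#' @param phi Kinship matrix.
#' @param p_hat Allele-frequency plug-in.
#' @return Scalar statistic.
#' @export
qls_stat <- function(x, r, phi, p_hat) {
  sigma_x2 <- 2 * p_hat * (1 - p_hat)
  if (sigma_x2 <= 0) rlang::abort("sigma_X^2 = 0: statistic undefined")
  sum(r * x)^2 / (drop(crossprod(r, phi %*% r)) * sigma_x2)
}
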