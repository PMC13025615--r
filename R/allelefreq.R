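#' Naive counting allele-frequency estimators
#'
#' Counts type-1 alleles over a subset of individuals: p-hat = sum(X_S) / (2 |S|).
#' With the subset equal to all individuals, the founders, or the descendants
#' this gives the estimators p_a, p_f and p_d; they satisfy the exact identity
#' n p_a = nf p_f + nd p_d.
#'
#' @param x Genotype vector (0/1/2 allele counts).
#' @param subset Integer indices of the individuals to count (default: all).
#' @param kind Label stored with the estimate (`"all"`, `"founders"`,
#'   `"descendants"` or any token).
#' @return A one-row tibble with columns `value`, `estimator_kind`, `n_used`.
#' @export
naive_af <- function(x, subset = seq_along(x), kind = "all") {
  if (length(subset) == 0) rlang::abort("`subset` must be non-empty")
  xs <- x[subset]
  stopifnot(all(xs %in% 0:2))
  tibble::tibble(value = sum(xs) / (2 * length(xs)),
                 estimator_kind = kind,
                 n_used = length(xs))
}

# scalar fast paths used in per-SNP loops
naive_af_value <- function(x, subset) sum(x[subset]) / (2 * length(subset))

blue_af_value <- function(x, phi_inv_one) {
  sum(phi_inv_one * x) / (2 * sum(phi_inv_one))
}

#' Best linear unbiased estimator (BLUE) of allele frequency
#'
#' The minimum-variance linear unbiased estimator of the allele frequency in a
#' pedigree with kinship matrix Phi:
#' p-hat = (1' Phi^-1 1)^-1 1' Phi^-1 X / 2. For Phi = I this reduces to the
#' naive all-individuals count. Finite-sample values can fall outside \[0, 1\];
#' the returned `value` is clipped (with a warning) for downstream use as a
#' variance plug-in while `raw_value` keeps the unclipped estimate.
#'
#' @param x Genotype vector (0/1/2).
#' @param phi Positive-definite kinship matrix.
#' @return A one-row tibble with `value`, `raw_value`, `estimator_kind`, `n_used`.
#' @export
blue_af <- function(x, phi) {
  stopifnot(length(x) == nrow(phi))
  phi_inv_one <- solve(phi, rep(1, nrow(phi)))
  raw <- blue_af_value(x, phi_inv_one)
  value <- raw
  if (raw < 0 || raw > 1) {
    rlang::warn(sprintf("BLUE allele frequency %.4f outside [0, 1]; clipped", raw))
    value <- min(max(raw, 0), 1)
  }
  tibble::tibble(value = value, raw_value = raw,
                 estimator_kind = "blue", n_used = length(x))
}

#' Analytic covariance of naive subset allele-frequency estimators
#'
#' For naive counting estimators over index sets S and T in a pedigree of
#' outbred individuals with kinship matrix Phi,
#' cov(p_S, p_T) = sigma_X^2 (1_S' Phi 1_T) / (4 |S| |T|), with
#' sigma_X^2 = 2 p (1 - p) under Hardy-Weinberg equilibrium. The familiar
#' special cases follow: var(p_f) = sigma_X^2 / (4 nf) (founders are mutually
#' unrelated), cov(p_f, p_d) = cov(p_a, p_f) = sigma_X^2 / (4 nf), and
#' cov(p_a, p_d) = sigma_X^2 / (4 nd) (1' Phi 1 / n - 1).
#'
#' @param phi Kinship matrix.
#' @param set_s,set_t Non-empty integer index sets.
#' @param p True allele frequency in (0, 1).
#' @return Scalar covariance.
#' @export
af_cov_analytic <- function(phi, set_s, set_t, p) {
  if (length(set_s) == 0 || length(set_t) == 0) {
    rlang::abort("index sets must be non-empty")
  }
  stopifnot(p > 0, p < 1)
  sigma_x2 <- 2 * p * (1 - p)
  sigma_x2 * sum(phi[set_s, set_t, drop = FALSE]) /
    (4 * length(set_s) * length(set_t))
}

#' Analytic variance of the BLUE allele-frequency estimator
#'
#' var(p_blue) = sigma_X^2 / (4 1' Phi^-1 1); by construction it is no larger
#' than the variance of any linear unbiased estimator, including the naive
#' subset counts.
#'
#' @inheritParams af_cov_analytic
#' @return Scalar variance.
#' @export
af_var_blue <- function(phi, p) {
  stopifnot(p > 0, p < 1)
  sigma_x2 <- 2 * p * (1 - p)
  one <- rep(1, nrow(phi))
  sigma_x2 / (4 * sum(solve(phi, one)))
}

#' Allele-frequency summary table for a cohort
#'
#' Convenience wrapper computing p_a, p_f, p_d and the BLUE for one genotype
#' vector on a pedigree.
#'
#' @inheritParams pedigree
#' @param x Genotype vector in pedigree order.
#' @return A tibble with one row per estimator.
#' @export
af_table <- function(ped, x) {
  part <- ped_partition(ped)
  phi <- kinship_matrix(ped)
  dplyr::bind_rows(
    naive_af(x, kind = "all"),
    naive_af(x, part$founders, kind = "founders"),
    naive_af(x, part$descendants, kind = "descendants"),
    blue_af(x, phi)[, c("value", "estimator_kind", "n_used")]
  )
}
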