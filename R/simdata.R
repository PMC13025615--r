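#' Simulation parameters
#'
#' Defaults reproduce the package's reference simulation conditions: covariate
#' effects beta = (1, 0.5, 0.8) for intercept, age and sex; residual variance
#' sigma_e2 = 1.5; additive polygenic variance sigma_a2 = 2.5; per-SNP minor
#' allele frequency drawn from Uniform(0.1, 0.5). `effect_k = 0` encodes the
#' null (alpha = 0); `effect_k = k > 0` draws the genetic effect alpha from the
#' symmetric uniform mixture on \[-0.5(k+1), -0.5k\] U \[0.5k, 0.5(k+1)\];
#' `effect_mode = "consistency"` instead uses \[-1.25, -0.25\] U \[0.25, 1.25\].
#'
#' @param beta Covariate fixed effects (length q, intercept first).
#' @param sigma_e2,sigma_a2 Variance components (> 0, >= 0).
#' @param maf_range Lower/upper bound of the MAF distribution, in (0, 0.5].
#' @param effect_k Effect-size level k (>= 0; 0 = null).
#' @param effect_mode `"power_grid"` or `"consistency"`.
#' @param n_snps Number of SNP replicates.
#' @param seed Master seed; component streams (covariates, genotypes, effects,
#'   trait noise) use seeds derived from it, so any component is reproducible
#'   on its own.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(beta = c(1, 0.5, 0.8),
                       sigma_e2 = 1.5,
                       sigma_a2 = 2.5,
                       maf_range = c(0.1, 0.5),
                       effect_k = 0,
                       effect_mode = c("power_grid", "consistency"),
                       n_snps = 5000,
                       seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(sigma_e2 > 0, sigma_a2 >= 0, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5, n_snps >= 1)
  if (effect_k < 0) rlang::abort("`effect_k` must be >= 0")
  structure(list(beta = beta, sigma_e2 = sigma_e2, sigma_a2 = sigma_a2,
                 maf_range = maf_range, effect_k = effect_k,
                 effect_mode = effect_mode, n_snps = as.integer(n_snps),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# deterministic per-component seed derived from the master seed
derive_seed <- function(seed, component) {
  offsets <- c(covariates = 11L, genotypes = 23L, effects = 37L, noise = 53L)
  (as.integer(seed) * 97L + offsets[[component]]) %% 2147483647L
}

#' Gene-drop genotypes along a pedigree
#'
#' Each founder receives two alleles i.i.d. Bernoulli(maf) for the counted
#' allele; each descendant inherits one uniformly chosen allele from each
#' parent. The genotype is the count of the type-1 allele (0/1/2). Under this
#' transmission model the cross-individual genotype correlation matrix equals
#' the pedigree kinship matrix.
#'
#' @inheritParams pedigree
#' @param maf Allele frequency (scalar or length `n_snps`), in \[0, 1\].
#' @param n_snps Number of independent SNP replicates to drop.
#' @return An `n_snps` x n integer matrix (one row per SNP, pedigree order).
#' @export
gene_drop <- function(ped, maf, n_snps = 1) {
  validate_pedigree(ped)
  n <- nrow(ped)
  stopifnot(all(maf >= 0), all(maf <= 1))
  maf <- rep_len(maf, n_snps)
  pos <- setNames(seq_len(n), paste(ped$fid, ped$iid))
  fa <- ifelse(ped$father == "0", NA_integer_, pos[paste(ped$fid, ped$father)])
  mo <- ifelse(ped$mother == "0", NA_integer_, pos[paste(ped$fid, ped$mother)])
  # allele matrices: n_snps x n, one column per individual
  a1 <- matrix(0L, n_snps, n)
  a2 <- matrix(0L, n_snps, n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      a1[, i] <- rbinom(n_snps, 1L, maf)
      a2[, i] <- rbinom(n_snps, 1L, maf)
    } else {
      pick_f <- runif(n_snps) < 0.5
      pick_m <- runif(n_snps) < 0.5
      a1[, i] <- ifelse(pick_f, a1[, fa[i]], a2[, fa[i]])
      a2[, i] <- ifelse(pick_m, a1[, mo[i]], a2[, mo[i]])
    }
  }
  g <- a1 + a2
  colnames(g) <- paste(ped$fid, ped$iid, sep = ":")
  g
}

#' Simulate non-genetic covariates
#'
#' Column 1 is the intercept; column 2 is age ~ Uniform(18, 80); column 3 is
#' sex ~ Bernoulli(0.7).
#'
#' @param n Number of individuals.
#' @return An n x 3 matrix with columns `intercept`, `age`, `sex`.
#' @export
simulate_covariates <- function(n) {
  stopifnot(n >= 1)
  W <- cbind(intercept = rep(1, n),
             age = runif(n, 18, 80),
             sex = rbinom(n, 1L, 0.7))
  W
}

#' Draw per-SNP genetic effects
#'
#' @param n Number of draws.
#' @param k Effect level (>= 0). `k = 0` returns exact zeros. For `k > 0` in
#'   `"power_grid"` mode, |alpha| ~ Uniform(0.5 k, 0.5 (k + 1)) with a fair
#'   independent sign. `"consistency"` mode ignores `k` and uses
#'   |alpha| ~ Uniform(0.25, 1.25).
#' @param mode `"power_grid"` or `"consistency"`.
#' @return Numeric vector of effects.
#' @export
sample_effect <- function(n, k = 0, mode = c("power_grid", "consistency")) {
  mode <- match.arg(mode)
  if (mode == "power_grid") {
    if (k < 0) rlang::abort("`k` must be >= 0")
    if (k == 0) return(rep(0, n))
    mag <- runif(n, 0.5 * k, 0.5 * (k + 1))
  } else {
    mag <- runif(n, 0.25, 1.25)
  }
  sign <- ifelse(runif(n) < 0.5, -1, 1)
  sign * mag
}

#' Simulate a full per-SNP association dataset
#'
#' For each SNP: draw a MAF from `maf_range`, gene-drop the genotype vector
#' down the pedigree, draw the effect alpha per `effect_k`/`effect_mode`, draw
#' the polygenic-plus-noise error eps ~ N(0, sigma_e2 I + sigma_a2 Phi) via the
#' Cholesky factor of the covariance, and set y = W beta + x alpha + eps. The
#' covariate matrix W is drawn once per dataset (covariates belong to
#' individuals, not SNPs); each SNP receives its own trait replicate.
#'
#' @inheritParams pedigree
#' @param params A [sim_params()] object.
#' @param shared_trait If `TRUE`, generate a single trait using the first SNP
#'   as the only causal variant (real-data-style workflow) instead of one
#'   trait replicate per SNP.
#' @return A list of class `sim_dataset` with elements `genotypes` and
#'   `traits` (`n_snps` x n matrices), `covariates` (n x 3), `true_alpha`,
#'   `true_maf`, `labels` (1 iff alpha != 0), `snp_id`, `ped`, `phi`, `params`.
#' @export
simulate_dataset <- function(ped, params = sim_params(), shared_trait = FALSE) {
  validate_pedigree(ped)
  n <- nrow(ped)
  m <- params$n_snps
  phi <- kinship_matrix(ped)

  set.seed(derive_seed(params$seed, "covariates"))
  W <- simulate_covariates(n)

  set.seed(derive_seed(params$seed, "genotypes"))
  maf <- runif(m, params$maf_range[1], params$maf_range[2])
  G <- gene_drop(ped, maf, m)

  set.seed(derive_seed(params$seed, "effects"))
  alpha <- sample_effect(m, params$effect_k, params$effect_mode)
  if (shared_trait) alpha[-1] <- 0

  set.seed(derive_seed(params$seed, "noise"))
  sigma <- params$sigma_e2 * diag(n) + params$sigma_a2 * phi
  cf <- t(chol(sigma))
  mu <- drop(W %*% params$beta)
  if (shared_trait) {
    eps <- drop(cf %*% rnorm(n))
    y <- mu + G[1, ] * alpha[1] + eps
    traits <- matrix(rep(y, each = m), m, n)
  } else {
    eps <- t(cf %*% matrix(rnorm(n * m), n, m))  # m x n
    traits <- matrix(mu, m, n, byrow = TRUE) + G * alpha + eps
  }
  colnames(traits) <- colnames(G)

  structure(list(genotypes = G, traits = traits, covariates = W,
                 true_alpha = alpha, true_maf = maf,
                 labels = as.integer(alpha != 0),
                 snp_id = sprintf("snp%05d", seq_len(m)),
                 ped = ped, phi = phi, params = params,
                 shared_trait = shared_trait),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d SNPs x %d individuals (k = %s, mode = %s, seed = %d)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              format(x$params$effect_k), x$params$effect_mode, x$params$seed))
  invisible(x)
}
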