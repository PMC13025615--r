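# Shared fixtures, memoised so expensive simulations and scans are built once
# per test run and reused across files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small two-family cohort for unit tests
test_cohort <- function() fixture("cohort2", function() canonical_cohort(2))

test_phi <- function() fixture("phi2", function() kinship_matrix(test_cohort()))

# modest scanned dataset (null) shared by assoc/emulator/evalrep unit tests
test_scan_null <- function() {
  fixture("scan_null", function() {
    ped <- canonical_cohort(10)
    ds <- simulate_dataset(ped, sim_params(n_snps = 400, seed = 42))
    list(dataset = ds, scan = genome_scan(ds))
  })
}

# acceptance-scale datasets: simulated + scanned once, reused across criteria
acceptance_data <- function(k, seed_base = 20260928) {
  key <- paste0("acc_k", k)
  fixture(key, function() {
    ped <- canonical_cohort(10)
    params <- sim_params(effect_k = k, n_snps = 5000,
                         seed = (seed_base + round(10 * k)) %% 2147483647)
    ds <- simulate_dataset(ped, params)
    list(dataset = ds, scan = genome_scan(ds))
  })
}

acceptance_consistency <- function(seed = 20260931) {
  fixture("acc_consistency", function() {
    ped <- canonical_cohort(10)
    params <- sim_params(effect_k = 1, effect_mode = "consistency",
                         n_snps = 5000, seed = seed)
    ds <- simulate_dataset(ped, params)
    list(dataset = ds, scan = genome_scan(ds))
  })
}

# subset a sim_dataset (and keep the class / metadata consistent)
subset_dataset <- function(ds, rows) {
  out <- ds
  out$genotypes <- ds$genotypes[rows, , drop = FALSE]
  out$traits <- ds$traits[rows, , drop = FALSE]
  out$true_alpha <- ds$true_alpha[rows]
  out$true_maf <- ds$true_maf[rows]
  out$labels <- ds$labels[rows]
  out$snp_id <- ds$snp_id[rows]
  out
}

subset_scan <- function(scan, rows) {
  out <- scan[rows, ]
  attr(out, "residuals") <- attr(scan, "residuals")[rows, , drop = FALSE]
  out
}
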