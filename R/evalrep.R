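#' Emulation accuracy metrics
#'
#' MAE, RMSE, R-squared (1 - SS_res / SS_tot about the mean of the true
#' values) and Pearson correlation between emulated and true statistics.
#'
#' @param z_pred,z_true Equal-length numeric vectors (>= 2 entries).
#' @param condition Label, e.g. `"H0"` or `"Ha"`.
#' @param emulator_kind Label for the emulator being scored.
#' @return A one-row tibble (`AccuracyReport`).
#' @export
accuracy_metrics <- function(z_pred, z_true, condition = NA_character_,
                             emulator_kind = NA_character_) {
  stopifnot(length(z_pred) == length(z_true), length(z_true) >= 2)
  if (var(z_true) == 0) rlang::abort("z_true has zero variance; R^2 undefined")
  diff <- z_pred - z_true
  tibble::tibble(
    mae = mean(abs(diff)),
    rmse = sqrt(mean(diff^2)),
    r_squared = 1 - sum(diff^2) / sum((z_true - mean(z_true))^2),
    correlation = cor(z_pred, z_true),
    condition = condition,
    emulator_kind = emulator_kind
  )
}

#' Empirical type-I error and power
#'
#' Rejection rates at a nominal level: type-I error is the rejection fraction
#' among null (label 0) SNPs, power among associated (label 1) SNPs. A class
#' with no SNPs yields `NA`, not 0.
#'
#' @param p_values P-values in (0, 1\].
#' @param labels Binary association labels (1 = truly associated).
#' @param level Nominal significance level (default 0.05).
#' @param method Optional method label.
#' @return A one-row tibble with `method`, `level`, `type1`, `power`,
#'   `n_null`, `n_assoc`.
#' @export
error_power <- function(p_values, labels, level = 0.05, method = NA_character_) {
  stopifnot(length(p_values) == length(labels))
  keep <- is.finite(p_values)
  p <- p_values[keep]; lab <- labels[keep]
  rate <- function(sel) if (sum(sel) == 0) NA_real_ else mean(p[sel] < level)
  tibble::tibble(method = method, level = level,
                 type1 = rate(lab == 0), power = rate(lab == 1),
                 n_null = sum(lab == 0), n_assoc = sum(lab == 1))
}

#' Chi-square(1) QQ calibration of null statistics
#'
#' Regresses the sorted observed statistics on the corresponding chi-square-1
#' theoretical quantiles (through the origin) and returns the slope; a
#' well-calibrated null gives slope ~ 1. Also reports the Kolmogorov-Smirnov
#' p-value against the chi-square-1 distribution.
#'
#' @param s Observed chi-square statistics under the null.
#' @return A one-row tibble with `slope`, `ks_p`, `n`.
#' @export
qq_calibration <- function(s) {
  s <- sort(s[is.finite(s)])
  n <- length(s)
  theo <- qchisq((seq_len(n) - 0.5) / n, df = 1)
  slope <- sum(theo * s) / sum(theo^2)
  ks <- suppressWarnings(ks.test(s, "pchisq", df = 1))
  tibble::tibble(slope = slope, ks_p = ks$p.value, n = n)
}

#' QQ plot data for null statistics
#'
#' @param s Observed statistics.
#' @param df Reference chi-square degrees of freedom.
#' @return A tibble with `theoretical` and `observed` quantiles.
#' @export
qq_data <- function(s, df = 1) {
  s <- sort(s[is.finite(s)])
  n <- length(s)
  tibble::tibble(theoretical = qchisq((seq_len(n) - 0.5) / n, df = df),
                 observed = s)
}

#' Train an emulator on a split of a scanned dataset and score the test half
#'
#' Convenience driver used throughout the evaluation study: builds features,
#' splits SNPs train:test, trains the network on the training split, and
#' returns held-out predictions next to the classical statistics.
#'
#' @inheritParams build_features
#' @param ratio Train:test ratio (default 4).
#' @param split_seed Seed for the split.
#' @param config An [emulator_config()].
#' @param seed Training seed.
#' @param bag Number of bagged networks.
#' @return A list with `model`, `split`, and `pred`: a tibble of held-out SNPs
#'   with `snp_id`, `z_true`, `z_pred`, `s_pred`, `p_pred`, `label`.
#' @export
emulate_split <- function(scan, dataset, variant = c("xr", "raw", "af"),
                          target = c("ls", "qls", "ens"),
                          ratio = 4, split_seed = 1,
                          config = emulator_config(), seed = 1, bag = 1) {
  variant <- match.arg(variant)
  target <- match.arg(target)
  fb <- build_features(scan, dataset, variant, target)
  split <- split_dataset(length(fb$rows), ratio = ratio, seed = split_seed)
  model <- train_emulator(fb$features[split$train, , drop = FALSE],
                          fb$target[split$train],
                          variant = variant, config = config,
                          seed = seed, bag = bag)
  pred <- predict(model, fb$features[split$test, , drop = FALSE])
  test_rows <- fb$rows[split$test]
  pred <- dplyr::bind_cols(
    tibble::tibble(snp_id = scan$snp_id[test_rows],
                   z_true = fb$target[split$test],
                   label = if ("label" %in% names(scan)) scan$label[test_rows] else NA_integer_),
    pred)
  list(model = model, split = split, pred = pred,
       variant = variant, target_kind = target)
}

#' Run the full simulation experiment
#'
#' Orchestrates simulate -> scan -> split -> train -> predict -> evaluate
#' across a grid of effect levels, for the classical LS and QLS tests and the
#' requested emulator variants (XR-input emulators of each test, the
#' allele-frequency-feature variants, and the max-statistic ensembles). Emits
#' tidy tables: per-method rejection rates by effect level, emulation accuracy
#' reports, null QQ calibration, and consistency scatter data.
#'
#' @inheritParams pedigree
#' @param k_grid Effect levels; 0 is the null and must be included for type-I
#'   error and QQ outputs.
#' @param n_snps SNPs simulated per effect level.
#' @param emulators Character vector of emulated methods to run; any of
#'   `"dnn_ls"`, `"dnn_qls"`, `"dnn_ls_af"`, `"dnn_qls_af"`, `"dnn_ens"`,
#'   `"dnn_ens_af"`, `"dnn_ls_raw"`, `"dnn_qls_raw"`.
#' @param level Nominal significance level.
#' @param seed Master seed (simulation, split and training seeds derive from it).
#' @param config An [emulator_config()].
#' @return A list of class `kin_experiment` with tibbles `rates`, `accuracy`,
#'   `qq`, `consistency`, and a `manifest`.
#' @export
run_experiment <- function(ped = canonical_cohort(10),
                           k_grid = c(0, 1, 1.5, 2, 2.5),
                           n_snps = 5000,
                           emulators = c("dnn_ls", "dnn_qls"),
                           level = 0.05, seed = 1,
                           config = emulator_config()) {
  stopifnot(0 %in% k_grid)
  emu_specs <- list(
    dnn_ls = list(variant = "xr", target = "ls"),
    dnn_qls = list(variant = "xr", target = "qls"),
    dnn_ls_raw = list(variant = "raw", target = "ls"),
    dnn_qls_raw = list(variant = "raw", target = "qls"),
    dnn_ls_af = list(variant = "af", target = "ls"),
    dnn_qls_af = list(variant = "af", target = "qls"),
    dnn_ens = list(variant = "xr", target = "ens"),
    dnn_ens_af = list(variant = "af", target = "ens")
  )
  emulators <- match.arg(emulators, names(emu_specs), several.ok = TRUE)

  rates <- list(); acc <- list(); qq <- NULL; consistency <- list()
  t0 <- Sys.time()
  for (k in k_grid) {
    params <- sim_params(effect_k = k, n_snps = n_snps,
                         seed = (seed * 1000 + round(10 * k)) %% 2147483647)
    ds <- simulate_dataset(ped, params)
    scan <- genome_scan(ds)
    split <- split_dataset(n_snps, seed = seed)
    held <- scan[split$test, ]
    cond <- if (k == 0) "H0" else "Ha"
    for (meth in c("ls", "qls")) {
      pcol <- held[[paste0("p_", meth)]]
      rates[[length(rates) + 1]] <- dplyr::mutate(
        error_power(pcol, held$label, level, toupper(meth)), k = k)
    }
    consistency[[length(consistency) + 1]] <- tibble::tibble(
      condition = cond, k = k, snp_id = held$snp_id,
      z_ls = held$z_ls, z_qls = held$z_qls)
    if (k == 0) qq <- dplyr::bind_rows(
      dplyr::mutate(qq_calibration(held$s_ls), method = "LS"),
      dplyr::mutate(qq_calibration(held$s_qls), method = "QLS"))
    for (meth in emulators) {
      spec <- emu_specs[[meth]]
      es <- emulate_split(scan, ds, spec$variant, spec$target,
                          split_seed = seed, config = config, seed = seed)
      rates[[length(rates) + 1]] <- dplyr::mutate(
        error_power(es$pred$p_pred, es$pred$label, level, toupper(gsub("_", "-", meth))),
        k = k)
      acc[[length(acc) + 1]] <- accuracy_metrics(
        es$pred$z_pred, es$pred$z_true, cond, toupper(gsub("_", "-", meth)))
    }
  }
  rates <- dplyr::bind_rows(rates)
  rate_table <- tidyr::pivot_wider(
    dplyr::transmute(rates, .data$method, .data$k,
                     rate = ifelse(.data$k == 0, .data$type1, .data$power)),
    names_from = "k", values_from = "rate", names_prefix = "k_")
  structure(list(rates = rates, rate_table = rate_table,
                 accuracy = dplyr::bind_rows(acc), qq = qq,
                 consistency = dplyr::bind_rows(consistency),
                 manifest = tibble::tibble(
                   seed = seed, n_snps = n_snps, level = level,
                   n_individuals = nrow(ped),
                   k_grid = paste(k_grid, collapse = ","),
                   emulators = paste(emulators, collapse = ","),
                   package_version = as.character(packageVersion("kinscore")),
                   runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
            class = "kin_experiment")
}

#' Write an experiment report bundle
#'
#' Writes each result table as TSV plus a YAML manifest into a directory.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("rates", "rate_table", "accuracy", "qq", "consistency")) {
    tab <- experiment[[nm]]
    if (!is.null(tab)) {
      write.table(tab, file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  yaml::write_yaml(as.list(experiment$manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.kin_experiment <- function(x, ...) {
  cat("<kin_experiment>\n")
  print(x$rate_table)
  invisible(x)
}
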