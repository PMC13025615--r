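#' Emulator hyperparameter configuration
#'
#' Defaults follow the package's reference training recipe: Adam with initial
#' learning rate 0.001, 200 epochs, batch size 16, L1 penalty 0.01 on dense
#' weights, hidden layers (64, 64, 32, 16) with batch normalization, ReLU
#' activations and per-layer dropout (0.1, 0.2, 0.2, 0.3), linear output, and
#' a variance-preserving loss term with weight 1. Variant-specific
#' architectures: `"raw"` inserts an extra 128-neuron hidden layer (dropout
#' 0.4) between hidden layers 1 and 2; `"af"` uses a single 8-neuron hidden
#' layer (dropout 0.1). The learning rate steps down by a factor of 10 at 50%
#' and again at 75% of the epoch budget.
#'
#' @param epochs,batch_size,learning_rate,l1,lambda_var,hidden,dropout,bn_momentum
#'   Training hyperparameters; `hidden`/`dropout` are the base (xr/ens)
#'   architecture and are resolved per variant by [resolve_architecture()].
#' @param pointwise_layers Number of leading hidden layers that share weights
#'   across individuals before the activation is flattened (`NULL`, the
#'   default, keeps every hidden layer shared; ignored for flat variants).
#' @return A list of class `emulator_config`.
#' @export
emulator_config <- function(epochs = 200, batch_size = 16,
                            learning_rate = 0.001, l1 = 0.01,
                            lambda_var = 1,
                            hidden = c(64, 64, 32, 16),
                            dropout = c(0.1, 0.2, 0.2, 0.3),
                            pointwise_layers = NULL,
                            bn_momentum = 0.9) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l1 = l1,
                 lambda_var = lambda_var, hidden = hidden, dropout = dropout,
                 pointwise_layers = if (is.null(pointwise_layers)) NULL
                                    else as.integer(pointwise_layers),
                 bn_momentum = bn_momentum,
                 optimizer = "adam", activation = "relu"),
            class = "emulator_config")
}

#' @rdname emulator_config
#' @param variant Feature variant: `"xr"`, `"raw"` or `"af"`.
#' @param config An [emulator_config()].
#' @export
resolve_architecture <- function(variant = c("xr", "raw", "af"),
                                 config = emulator_config()) {
  variant <- match.arg(variant)
  if (variant == "raw") {
    config$hidden <- append(config$hidden, 128, after = 1)
    config$dropout <- append(config$dropout, 0.4, after = 1)
  } else if (variant == "af") {
    config$hidden <- 8
    config$dropout <- 0.1
    config$pointwise_layers <- 0L
  }
  config
}

#' Per-SNP feature construction for emulator training
#'
#' Builds the emulator design matrix from a [genome_scan()] table and its
#' dataset. Variants: `"xr"` concatenates the genotype vector X and the
#' transformed phenotypic residual R in fixed pedigree order (2n features);
#' `"raw"` concatenates X, the two non-intercept covariates and the trait Y
#' (4n features, relatedness ignored); `"af"` uses the 3 summary features
#' (X'R, founder and descendant naive allele-frequency estimates). Targets are
#' the signed Z statistics of the designated test; `"ens"` targets the signed
#' square root of max(S_LS, S_QLS).
#'
#' SNPs flagged by the scan (monomorphic / degenerate) are dropped.
#'
#' @param scan A [genome_scan()] result (with residuals attached).
#' @param dataset The dataset the scan was run on.
#' @param variant `"xr"`, `"raw"` or `"af"`.
#' @param target `"ls"`, `"qls"` or `"ens"`.
#' @return A list with `features` (matrix), `target` (numeric), `rows`
#'   (row indices of `scan` used), `variant`, `target_kind`.
#' @export
build_features <- function(scan, dataset, variant = c("xr", "raw", "af"),
                           target = c("ls", "qls", "ens")) {
  variant <- match.arg(variant)
  target <- match.arg(target)
  y <- switch(target,
              ls = scan$z_ls,
              qls = scan$z_qls,
              ens = ensemble_target(scan$z_ls, scan$z_qls))
  keep <- which(scan$flag == "ok" & is.finite(y))
  feats <- switch(variant,
    xr = {
      R <- attr(scan, "residuals")
      if (is.null(R)) rlang::abort("scan has no residual matrix; rerun genome_scan()")
      cbind(dataset$genotypes, R)
    },
    raw = {
      W <- as.matrix(dataset$covariates)[, -1, drop = FALSE]
      n <- ncol(dataset$genotypes)
      m <- nrow(dataset$genotypes)
      cbind(dataset$genotypes,
            matrix(W[, 1], m, n, byrow = TRUE),
            matrix(W[, 2], m, n, byrow = TRUE),
            dataset$traits)
    },
    af = cbind(xtr = scan$xtr, p_f_hat = scan$p_f_hat, p_d_hat = scan$p_d_hat)
  )
  list(features = feats[keep, , drop = FALSE], target = y[keep],
       rows = keep, variant = variant, target_kind = target)
}

#' Signed max-statistic ensemble target
#'
#' The ensemble emulator learns the maximum of the LS and QLS chi-square
#' statistics in signed-Z form. Both tests share the sign of X'R, so
#' Z_ENS = sign(Z) * sqrt(max(Z_LS^2, Z_QLS^2)) = whichever of the two Z
#' statistics has the larger magnitude.
#'
#' @param z_ls,z_qls Signed Z statistics.
#' @return Signed ensemble Z.
#' @export
ensemble_target <- function(z_ls, z_qls) {
  ifelse(abs(z_ls) >= abs(z_qls), z_ls, z_qls)
}

#' Variance-preserving loss
#'
#' loss = mean((pred - target)^2) + lambda_var * (sd(pred) - sd(target))^2.
#' The second term discourages shrinkage of the predicted statistic's spread.
#'
#' @param pred,target Equal-length numeric vectors (length >= 2).
#' @param lambda_var Weight of the variance-preserving term (default 1).
#' @return Scalar loss.
#' @export
vp_loss <- function(pred, target, lambda_var = 1) {
  if (length(pred) < 2 || length(pred) != length(target)) {
    rlang::abort("`pred` and `target` must have equal length >= 2")
  }
  mean((pred - target)^2) + lambda_var * (sd(pred) - sd(target))^2
}

#' Train/test split of SNP indices
#'
#' @param n_snps Total number of SNPs (>= 5).
#' @param ratio Train:test ratio (default 4, i.e. 80/20).
#' @param seed RNG seed for the split.
#' @return List with disjoint `train` and `test` index vectors covering all SNPs.
#' @export
split_dataset <- function(n_snps, ratio = 4, seed = 1) {
  stopifnot(n_snps >= 5, ratio > 0)
  set.seed(seed)
  n_train <- round(n_snps * ratio / (ratio + 1))
  train <- sort(sample.int(n_snps, n_train))
  list(train = train, test = setdiff(seq_len(n_snps), train))
}

#' Train a test-statistic emulator network
#'
#' Fits the emulator network for the given feature variant on the supplied
#' training rows. For the `"xr"` and `"raw"` variants the per-SNP feature row
#' is viewed as an n x C matrix (C = 2 channels X, R; or C = 4 channels
#' X, W1, W2, Y) and the hidden dense layers share their weights across the n
#' individuals (pointwise application), with a final linear layer over the
#' flattened per-individual features; this weight sharing is what lets the
#' network represent inner-product structure such as X'R. The `"af"` variant
#' is a flat single-hidden-layer net on its 3 summary features.
#' Features are z-scored with training-set statistics
#' (stored in the model); constant features get unit scale. Training is fully
#' deterministic given `seed`. `bag > 1` trains `bag` networks on the same
#' data with consecutive seeds and averages their predictions (bootstrap-style
#' aggregation; default 1).
#'
#' @param features Training feature matrix (rows = SNPs).
#' @param targets Training targets (signed Z statistics).
#' @param variant `"xr"`, `"raw"` or `"af"` (resolves the architecture).
#' @param config An [emulator_config()].
#' @param seed Training seed.
#' @param bag Number of bagged networks.
#' @return An object of class `kin_emulator`.
#' @export
train_emulator <- function(features, targets, variant = c("xr", "raw", "af"),
                           config = emulator_config(), seed = 1, bag = 1) {
  variant <- match.arg(variant)
  stopifnot(nrow(features) == length(targets), nrow(features) >= 2)
  cfg <- resolve_architecture(variant, config)
  n_groups <- switch(variant, xr = ncol(features) %/% 2L,
                     raw = ncol(features) %/% 4L, af = 1L)
  center <- colMeans(features)
  scale <- apply(features, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- scale(features, center = center, scale = scale)
  nets <- vector("list", bag)
  histories <- vector("list", bag)
  for (b in seq_len(bag)) {
    set.seed((seed + b - 1L) %% 2147483647L)
    fit <- mlp_train_cpp(Xs, targets, as.integer(cfg$hidden),
                         rep_len(cfg$dropout, length(cfg$hidden)),
                         cfg$l1, cfg$learning_rate, cfg$epochs,
                         cfg$batch_size, cfg$lambda_var, cfg$bn_momentum,
                         TRUE, n_groups,
                         cfg$pointwise_layers %||% length(cfg$hidden))
    nets[[b]] <- fit[c("W", "b", "gamma", "beta", "run_mean", "run_var")]
    histories[[b]] <- fit$history
  }
  model <- structure(list(nets = nets, center = center, scale = scale,
                          config = cfg, variant = variant, seed = seed,
                          bag = bag, n_groups = n_groups,
                          calibration = c(0, 1),
                          history = histories[[1]], histories = histories,
                          n_train = nrow(features), feature_dim = ncol(features)),
                     class = "kin_emulator")
  # affine output calibration on the training split: after batch-norm
  # re-estimation the output layer sees slightly different activation
  # statistics than it was optimised for; a least-squares (a + b z) fit of
  # the training targets on the training predictions corrects the resulting
  # scale/location error without touching held-out data
  z_train <- predict(model, features)$z_pred
  if (sd(z_train) > 0) {
    b <- cov(z_train, targets) / var(z_train)
    a <- mean(targets) - b * mean(z_train)
    model$calibration <- c(a, b)
  }
  model
}

#' Predict emulated test statistics
#'
#' Forward pass with dropout disabled and batch normalization using the stored
#' running statistics; deterministic given the trained weights. Predicted Z is
#' squared into a chi-square-1 statistic and converted to an upper-tail
#' p-value.
#'
#' @param object A `kin_emulator`.
#' @param features Feature matrix built with the same [build_features()] spec.
#' @param ... Unused.
#' @return A tibble with `z_pred`, `s_pred`, `p_pred`.
#' @export
predict.kin_emulator <- function(object, features, ...) {
  if (ncol(features) != object$feature_dim) {
    rlang::abort(sprintf("feature dimension %d does not match model (%d)",
                         ncol(features), object$feature_dim))
  }
  Xs <- scale(features, center = object$center, scale = object$scale)
  pw <- object$config$pointwise_layers %||% length(object$config$hidden)
  preds <- lapply(object$nets,
                  function(p) mlp_predict_cpp(p, Xs, object$n_groups %||% 1L, pw))
  z <- Reduce(`+`, preds) / length(preds)
  cal <- object$calibration %||% c(0, 1)
  z <- cal[1] + cal[2] * z
  tibble::tibble(z_pred = z, s_pred = z^2,
                 p_pred = pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' @export
print.kin_emulator <- function(x, ...) {
  cat(sprintf("<kin_emulator> variant = %s, features = %d, hidden = (%s)\n",
              x$variant, x$feature_dim, paste(x$config$hidden, collapse = ", ")))
  cat(sprintf("  trained on %d rows, %d epochs, seed %d, bag %d; final loss %.4f\n",
              x$n_train, x$config$epochs, x$seed, x$bag,
              if (length(x$history)) x$history[length(x$history)] else NA_real_))
  invisible(x)
}

#' @rdname train_emulator
#' @param x A `kin_emulator`.
#' @param ... Unused.
#' @method tidy kin_emulator
#' @export
tidy.kin_emulator <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = as.numeric(x$history))
}

#' @rdname train_emulator
#' @method glance kin_emulator
#' @export
glance.kin_emulator <- function(x, ...) {
  n_par <- sum(vapply(x$nets[[1]]$W, length, numeric(1))) +
    sum(vapply(x$nets[[1]]$b, length, numeric(1)))
  tibble::tibble(variant = x$variant, feature_dim = x$feature_dim,
                 epochs = x$config$epochs, n_train = x$n_train,
                 n_weights = n_par, bag = x$bag,
                 final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_)
}

#' Save / load a trained emulator
#'
#' Serializes weights, feature standardization, configuration and seed to a
#' single JSON archive; loading restores bit-identical predictions.
#'
#' @param model A `kin_emulator`.
#' @param path File path (JSON).
#' @export
write_emulator <- function(model, path) {
  ser <- list(
    variant = model$variant, seed = model$seed, bag = model$bag,
    n_groups = model$n_groups, calibration = model$calibration,
    center = model$center, scale = model$scale,
    config = unclass(model$config),
    feature_dim = model$feature_dim, n_train = model$n_train,
    history = as.numeric(model$history),
    nets = lapply(model$nets, function(p) {
      lapply(p, function(comp) lapply(comp, function(x) {
        if (is.null(x)) NULL else list(dim = dim(x) %||% length(x), data = as.numeric(x))
      }))
    })
  )
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_emulator
#' @export
read_emulator <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  rebuild <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    d <- unlist(x$dim); v <- unlist(x$data)
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  nets <- lapply(ser$nets, function(p) lapply(p, function(comp) lapply(comp, rebuild)))
  cfg <- ser$config
  cfg$hidden <- unlist(cfg$hidden); cfg$dropout <- unlist(cfg$dropout)
  class(cfg) <- "emulator_config"
  structure(list(nets = nets,
                 center = unlist(ser$center), scale = unlist(ser$scale),
                 config = cfg, variant = ser$variant, seed = ser$seed,
                 bag = ser$bag, n_groups = ser$n_groups %||% 1L,
                 calibration = unlist(ser$calibration) %||% c(0, 1),
                 history = unlist(ser$history),
                 histories = list(unlist(ser$history)),
                 n_train = ser$n_train, feature_dim = ser$feature_dim),
            class = "kin_emulator")
}
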