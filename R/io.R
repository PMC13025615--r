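#' Read and write genotype matrices
#'
#' Canonical interchange format: tab-delimited text with a header row of SNP
#' IDs and one row per individual (first column = individual ID `fid:iid`),
#' entries in {0, 1, 2} with `NA` as the missing code. On read, the matrix is
#' returned SNPs-by-individuals to match the simulator; SNPs containing
#' missing entries are reported via the `missing_snps` attribute (tests skip
#' them).
#'
#' @param path File path.
#' @param genotypes SNPs x individuals matrix with `snp_id` rownames optional.
#' @param snp_id Optional SNP IDs (default `snp00001`, ...).
#' @return `read_genotypes()`: an m x n integer matrix (SNP rows), with
#'   attribute `missing_snps`.
#' @export
write_genotypes <- function(genotypes, path, snp_id = NULL) {
  m <- nrow(genotypes)
  if (is.null(snp_id)) snp_id <- rownames(genotypes) %||% sprintf("snp%05d", seq_len(m))
  df <- data.frame(id = colnames(genotypes) %||% paste0("ind", seq_len(ncol(genotypes))),
                   t(genotypes), check.names = FALSE)
  colnames(df) <- c("id", snp_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  g <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(g %in% c("0", "1", "2", "NA", "")) & !is.na(g)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(g)), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-{0,1,2} genotype at row %d, column %d", idx[1], idx[2] + 1L))
  }
  suppressWarnings(storage.mode(g) <- "integer")
  out <- t(g)
  colnames(out) <- ids
  attr(out, "missing_snps") <- unname(which(rowSums(is.na(out)) > 0))
  n_miss <- length(attr(out, "missing_snps"))
  if (n_miss > 0) rlang::inform(sprintf("%d SNP(s) contain missing genotypes", n_miss))
  out
}

#' Read and write phenotype/covariate tables
#'
#' Tab-delimited with columns `id` (`fid:iid`), `trait`, then covariates.
#' On read, rows are aligned to the pedigree order and an intercept column is
#' prepended to the covariates.
#'
#' @inheritParams pedigree
#' @param path File path.
#' @param trait Trait vector in pedigree order.
#' @param covariates n x q covariate matrix (intercept column included; the
#'   intercept is not written).
#' @return `read_phenotypes()`: list with `trait` and `covariates` (intercept
#'   prepended), both in pedigree order.
#' @export
write_phenotypes <- function(ped, trait, covariates, path) {
  covariates <- as.matrix(covariates)
  has_int <- all(covariates[, 1] == 1)
  covs <- if (has_int) covariates[, -1, drop = FALSE] else covariates
  df <- data.frame(id = paste(ped$fid, ped$iid, sep = ":"), trait = trait, covs,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path, ped) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (anyDuplicated(df$id)) {
    rlang::abort(paste("duplicate individual ID(s):",
                       paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  want <- paste(ped$fid, ped$iid, sep = ":")
  miss <- setdiff(want, df$id)
  if (length(miss) > 0) {
    rlang::abort(paste("pedigree individuals missing from phenotype file:",
                       paste(utils::head(miss, 5), collapse = ", ")))
  }
  df <- df[match(want, df$id), , drop = FALSE]
  covs <- as.matrix(df[, setdiff(names(df), c("id", "trait")), drop = FALSE])
  list(trait = df$trait,
       covariates = cbind(intercept = rep(1, nrow(df)), covs))
}

#' Write a simulated dataset to a directory
#'
#' Genotypes, traits (per-SNP rows) and phenotype table as delimited text,
#' pedigree as `.fam`, kinship matrix as TSV, and the generating parameters as
#' a YAML sidecar.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"),
                  dataset$snp_id)
  write.table(data.frame(snp_id = dataset$snp_id, dataset$traits,
                         check.names = FALSE),
              file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_phenotypes(dataset$ped, dataset$traits[1, ], dataset$covariates,
                   file.path(dir, "phenotypes.tsv"))
  write_fam(dataset$ped, file.path(dir, "pedigree.fam"))
  write_kinship(dataset$phi, file.path(dir, "kinship.tsv"))
  p <- dataset$params
  yaml::write_yaml(list(beta = p$beta, sigma_e2 = p$sigma_e2,
                        sigma_a2 = p$sigma_a2, maf_range = p$maf_range,
                        effect_k = p$effect_k, effect_mode = p$effect_mode,
                        n_snps = p$n_snps, seed = p$seed,
                        true_maf = dataset$true_maf,
                        true_alpha = dataset$true_alpha),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}
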