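#' Pedigrees as tibbles
#'
#' A pedigree is an ordinary tibble with one row per individual and columns
#' `fid` (family ID), `iid` (individual ID), `father`, `mother` (`"0"` when the
#' parent is not in the pedigree), `sex` (1 = male, 2 = female, 0 = unknown)
#' and `generation`. Rows are kept in topological order: every parent appears
#' before its children. Founders are the individuals with both parents coded
#' `"0"`; everyone else is a descendant.
#'
#' @param ped A pedigree tibble.
#' @return `validate_pedigree()` returns its input invisibly, or aborts with a
#'   structural error.
#' @name pedigree
NULL

ped_cols <- c("fid", "iid", "father", "mother", "sex", "generation")

#' @rdname pedigree
#' @export
validate_pedigree <- function(ped) {
  missing_cols <- setdiff(setdiff(ped_cols, "generation"), names(ped))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("pedigree is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  key <- paste(ped$fid, ped$iid)
  if (anyDuplicated(key)) rlang::abort("duplicate (fid, iid) in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father[i]; mo <- ped$mother[i]
    if (xor(fa == "0", mo == "0")) {
      rlang::abort(sprintf("individual %s has exactly one recorded parent", ped$iid[i]))
    }
    if (fa != "0") {
      for (par in c(fa, mo)) {
        pk <- paste(ped$fid[i], par)
        if (!pk %in% seen) {
          rlang::abort(sprintf(
            "parent %s of %s not found earlier in family %s (unresolved or non-topological)",
            par, ped$iid[i], ped$fid[i]))
        }
      }
    }
    seen <- c(seen, key[i])
  }
  invisible(ped)
}

#' Canonical three-generation family and multi-family cohort
#'
#' The canonical simulation unit is a 10-member outbred family spanning three
#' generations: a founder couple; two of their children, each married to a
#' founder spouse; and two children per second-generation couple. Each family
#' therefore has 4 founders and 6 descendants. `canonical_cohort()` replicates
#' the family with distinct family IDs; the default simulation cohort is 10
#' families (n = 100).
#'
#' @param family_id Family ID for the single family.
#' @param n_families Number of family replicates (>= 1).
#' @return A pedigree tibble (see [pedigree]).
#' @examples
#' ped <- canonical_cohort(2)
#' dplyr::count(ped, fid)
#' @export
canonical_family <- function(family_id = "F1") {
  tibble::tibble(
    fid = family_id,
    iid = c("gf", "gm", "c1", "s1", "c2", "s2", "k1", "k2", "k3", "k4"),
    father = c("0", "0", "gf", "0", "gf", "0", "c1", "c1", "s2", "s2"),
    mother = c("0", "0", "gm", "0", "gm", "0", "s1", "s1", "c2", "c2"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L),
    generation = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
}

#' @rdname canonical_family
#' @export
canonical_cohort <- function(n_families = 10) {
  if (!is.numeric(n_families) || n_families < 1) {
    rlang::abort("`n_families` must be >= 1")
  }
  dplyr::bind_rows(lapply(seq_len(n_families), function(f) {
    canonical_family(paste0("F", f))
  }))
}

#' Founder / descendant partition of a pedigree
#'
#' @inheritParams pedigree
#' @return A list with integer index vectors `founders` and `descendants`
#'   (against the pedigree row order) and counts `nf`, `nd`.
#' @export
ped_partition <- function(ped) {
  validate_pedigree(ped)
  is_founder <- ped$father == "0" & ped$mother == "0"
  list(founders = which(is_founder),
       descendants = which(!is_founder),
       nf = sum(is_founder),
       nd = sum(!is_founder))
}

#' Kinship matrix of a pedigree
#'
#' Computes the additive relationship matrix Phi from the classical recursion:
#' phi(i, i) = (1 + phi(mother(i), father(i))) / 2 and, for i below j in the
#' pedigree order, phi(i, j) = (phi(father(i), j) + phi(mother(i), j)) / 2,
#' with founders mutually unrelated and non-inbred. The returned matrix has
#' off-diagonal entries 2 * phi(i, j) (the genotype correlation scale for
#' outbred pairs) and diagonal 1 + h(i), where h(i) is the kinship of i's
#' parents (the inbreeding coefficient). Families occupy disjoint blocks, so
#' the cohort matrix is block-diagonal.
#'
#' @inheritParams pedigree
#' @return An n x n symmetric matrix with dimnames `fid:iid`.
#' @examples
#' phi <- kinship_matrix(canonical_family())
#' phi["F1:gf", "F1:k1"]   # grandparent-grandchild: 0.25
#' @export
kinship_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  key <- paste(ped$fid, ped$iid, sep = ":")
  pos <- setNames(seq_len(n), paste(ped$fid, ped$iid))
  fa <- ifelse(ped$father == "0", NA_integer_, pos[paste(ped$fid, ped$father)])
  mo <- ifelse(ped$mother == "0", NA_integer_, pos[paste(ped$fid, ped$mother)])
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
      for (j in seq_len(i - 1L)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
      }
    }
  }
  out <- 2 * phi
  diag(out) <- 2 * diag(phi)  # = 1 + h_i
  dimnames(out) <- list(key, key)
  out
}

#' Read and write PLINK-style .fam pedigree files
#'
#' Six whitespace-delimited columns: family ID, individual ID, father, mother,
#' sex, phenotype. Missing parents are coded `"0"`. The phenotype column is
#' written as `-9` and ignored on read; a `generation` column is reconstructed
#' as 1 + the maximum parental generation.
#'
#' @param path File path.
#' @param ped A pedigree tibble.
#' @return `read_fam()` returns a pedigree tibble; `write_fam()` returns `path`
#'   invisibly.
#' @export
read_fam <- function(path) {
  raw <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 5) rlang::abort("expected at least 5 columns in .fam file")
  ped <- tibble::tibble(
    fid = raw[[1]], iid = raw[[2]], father = raw[[3]], mother = raw[[4]],
    sex = suppressWarnings(as.integer(raw[[5]]))
  )
  gen <- integer(nrow(ped))
  pos <- setNames(seq_len(nrow(ped)), paste(ped$fid, ped$iid))
  for (i in seq_len(nrow(ped))) {
    if (ped$father[i] == "0") {
      gen[i] <- 1L
    } else {
      gen[i] <- 1L + max(gen[pos[paste(ped$fid[i], ped$father[i])]],
                         gen[pos[paste(ped$fid[i], ped$mother[i])]])
    }
  }
  ped$generation <- gen
  validate_pedigree(ped)
  ped
}

#' @rdname read_fam
#' @export
write_fam <- function(ped, path) {
  validate_pedigree(ped)
  out <- data.frame(ped$fid, ped$iid, ped$father, ped$mother, ped$sex, -9)
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export / import a kinship matrix as delimited text
#'
#' Tab-delimited with a `fid:iid` header row and ID first column, so the
#' matrix can be re-joined to a pedigree unambiguously.
#'
#' @param phi Kinship matrix as returned by [kinship_matrix()].
#' @param path File path.
#' @export
write_kinship <- function(phi, path) {
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
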