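#' Read a genotype table
#'
#' Reads an N x p table of minor-allele counts (0/1/2) into a genotype
#' tibble: one `sample_id` column followed by one integer column per SNP.
#' Three dialects are supported: plain TSV/CSV with a header row of SNP IDs
#' and the sample ID in the first column, and PLINK `.raw` files as produced
#' by `plink --recode A` (columns FID/IID/PAT/MAT/SEX/PHENOTYPE followed by
#' per-SNP dosages; IID becomes the sample ID).
#'
#' Genotypes must be hard calls: `.raw` dosages further than `tol` from an
#' integer, or any value outside \{0, 1, 2\}, raise a validation error.
#' Missing genotypes are an error under the default policy; with
#' `missing = "drop_sample"` any sample carrying a missing value is removed.
#'
#' @param path Path to the genotype file.
#' @param dialect One of `"tsv"`, `"csv"`, `"plink_raw"`.
#' @param missing Missing-genotype policy: `"error"` (default) or
#'   `"drop_sample"`.
#' @param tol Rounding tolerance for PLINK dosages (default 0.01).
#' @return A genotype tibble (`sample_id` + one integer column per SNP).
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv", "plink_raw"),
                           missing = c("error", "drop_sample"), tol = 0.01) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  raw <- switch(dialect,
    tsv = readr::read_tsv(path, col_types = readr::cols(), progress = FALSE),
    csv = readr::read_csv(path, col_types = readr::cols(), progress = FALSE),
    plink_raw = readr::read_delim(path, delim = " ", col_types = readr::cols(),
                                  progress = FALSE)
  )
  if (dialect == "plink_raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(raw))) {
      abort("PLINK .raw file must contain columns FID/IID/PAT/MAT/SEX/PHENOTYPE")
    }
    ids <- as.character(raw$IID)
    snp <- raw[, setdiff(names(raw), meta), drop = FALSE]
  } else {
    ids <- as.character(raw[[1]])
    snp <- raw[, -1, drop = FALSE]
  }
  if (ncol(snp) < 1) abort("no SNP columns found")
  g <- as.matrix(snp)
  storage.mode(g) <- "double"

  na_rows <- rowSums(is.na(g)) > 0
  if (any(na_rows)) {
    if (missing == "error") {
      abort(paste0(sum(na_rows), " sample(s) contain missing genotypes; ",
                   "set missing = \"drop_sample\" to remove them"))
    }
    warn(paste0("dropping ", sum(na_rows), " sample(s) with missing genotypes"))
    g <- g[!na_rows, , drop = FALSE]
    ids <- ids[!na_rows]
  }

  rounded <- round(g)
  off <- abs(g - rounded) > tol
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer genotype %.4f at row %d, SNP '%s' (tolerance %g)",
                  g[bad[1], bad[2]], bad[1], colnames(g)[bad[2]], tol))
  }
  g <- rounded
  out_of_range <- !(g %in% c(0, 1, 2))
  if (any(out_of_range)) {
    bad <- which(matrix(out_of_range, nrow(g)), arr.ind = TRUE)[1, ]
    abort(sprintf("genotype value %g at row %d, SNP '%s' is outside {0,1,2}",
                  g[bad[1], bad[2]], bad[1], colnames(g)[bad[2]]))
  }
  new_genotypes(g, sample_ids = ids, snp_ids = colnames(g))
}

#' Write a genotype tibble to TSV/CSV
#'
#' @param geno A genotype tibble as returned by [read_genotypes()] or
#'   [simulate_genotypes()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  geno <- validate_genotypes(geno)
  if (dialect == "tsv") readr::write_tsv(geno, path, progress = FALSE)
  else readr::write_csv(geno, path, progress = FALSE)
  invisible(path)
}

new_genotypes <- function(g, sample_ids, snp_ids, maf = NULL) {
  storage.mode(g) <- "integer"
  out <- as_tibble(as.data.frame(g), .name_repair = "minimal")
  names(out) <- snp_ids
  out <- dplyr::bind_cols(tibble(sample_id = as.character(sample_ids)), out)
  if (!is.null(maf)) attr(out, "maf") <- maf
  validate_genotypes(out)
}

#' Validate a genotype tibble
#'
#' Checks entries are in \{0,1,2\} with no missing values and that sample and
#' SNP IDs are unique.
#'
#' @param geno Genotype tibble (`sample_id` + SNP columns).
#' @return `geno`, invisibly usable, after validation.
#' @export
validate_genotypes <- function(geno) {
  if (!is.data.frame(geno) || !"sample_id" %in% names(geno)) {
    abort("genotypes must be a data frame with a 'sample_id' column")
  }
  if (anyDuplicated(geno$sample_id)) abort("duplicate sample IDs")
  snps <- setdiff(names(geno), "sample_id")
  if (length(snps) < 1) abort("no SNP columns")
  if (anyDuplicated(snps)) abort("duplicate SNP IDs")
  g <- as.matrix(geno[, snps, drop = FALSE])
  if (anyNA(g)) abort("missing genotype values")
  if (!all(g %in% c(0L, 1L, 2L))) abort("genotype entries must be in {0,1,2}")
  as_tibble(geno)
}

#' Extract the numeric genotype matrix from a genotype tibble
#'
#' @param geno Genotype tibble.
#' @return Numeric N x p matrix with sample IDs as row names.
#' @export
geno_matrix <- function(geno) {
  snps <- setdiff(names(geno), "sample_id")
  g <- as.matrix(geno[, snps, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- geno$sample_id
  g
}

#' Dominant-encode genotypes
#'
#' Recodes allele counts to the dominant mode of inheritance: an indicator
#' that at least one minor allele is present, `1(SNP > 0)`. Accepts either a
#' genotype tibble or a bare numeric matrix and returns the same shape.
#'
#' @param g Genotype tibble or numeric matrix of allele counts.
#' @return Object of the same shape with entries in \{0,1\}.
#' @export
dominant_encode <- function(g) {
  if (is.data.frame(g)) {
    snps <- setdiff(names(g), "sample_id")
    g[snps] <- lapply(g[snps], function(x) as.integer(x > 0))
    return(as_tibble(g))
  }
  m <- (g > 0) * 1
  dimnames(m) <- dimnames(g)
  m
}

#' Read a phenotype table
#'
#' Expects columns `sample_id`, `y`, `e`, then any number of confounder
#' columns. The outcome family is inferred (`binary` if `y` takes only the
#' values 0 and 1) unless given.
#'
#' @param path Path to the phenotype file.
#' @param dialect `"tsv"` or `"csv"`.
#' @param family `NULL` (infer), `"binary"` or `"continuous"`.
#' @return A phenotype tibble with attribute `family`.
#' @export
read_phenotypes <- function(path, dialect = c("tsv", "csv"), family = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  tbl <- if (dialect == "tsv") {
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_phenotypes(tbl, family = family)
}

#' Validate a phenotype tibble
#'
#' @param pheno Data frame with columns `sample_id`, `y`, `e` and optional
#'   confounders.
#' @param family `NULL` (infer), `"binary"` or `"continuous"`.
#' @return The validated phenotype tibble with a `family` attribute.
#' @export
validate_phenotypes <- function(pheno, family = NULL) {
  need <- c("sample_id", "y", "e")
  if (!is.data.frame(pheno) || !all(need %in% names(pheno))) {
    abort("phenotypes must contain columns sample_id, y, e")
  }
  if (anyDuplicated(pheno$sample_id)) abort("duplicate sample IDs")
  if (anyNA(pheno$y) || anyNA(pheno$e)) abort("missing values in y or e")
  if (is.null(family)) {
    family <- if (all(pheno$y %in% c(0, 1))) "binary" else "continuous"
  }
  family <- match.arg(family, c("binary", "continuous"))
  if (family == "binary" && !all(pheno$y %in% c(0, 1))) {
    abort("binary outcome must take values in {0,1}")
  }
  confs <- confounder_names(pheno)
  for (cc in confs) {
    if (anyNA(pheno[[cc]])) abort(paste0("missing values in confounder ", cc))
  }
  out <- as_tibble(pheno)
  attr(out, "family") <- family
  out
}

confounder_names <- function(pheno) {
  setdiff(names(pheno), c("sample_id", "y", "e"))
}

pheno_family <- function(pheno) {
  fam <- attr(pheno, "family")
  if (is.null(fam)) fam <- if (all(pheno$y %in% c(0, 1))) "binary" else "continuous"
  fam
}

#' Align genotype and phenotype tables by sample ID
#'
#' Joins the two tables on `sample_id`; the result is ordered by the
#' phenotype table. Samples present in only one table are an error.
#'
#' @param geno Genotype tibble.
#' @param pheno Phenotype tibble.
#' @return List with the row-aligned `geno` and `pheno`.
#' @export
align_samples <- function(geno, pheno) {
  if (!setequal(geno$sample_id, pheno$sample_id)) {
    abort("genotype and phenotype tables contain different sample IDs")
  }
  idx <- match(pheno$sample_id, geno$sample_id)
  list(geno = geno[idx, , drop = FALSE], pheno = pheno)
}

#' Assemble the interaction-test design
#'
#' Builds the design used by every GxE test in the package: intercept, the
#' genetic score (a single SNP or a GRS), the exposure `e`, their product,
#' and any confounders as main-effect covariates. The product column is the
#' interaction whose coefficient is Wald-tested.
#'
#' @param score Numeric vector, length N (SNP column or GRS).
#' @param pheno Phenotype tibble (provides `e` and confounders).
#' @return A list of class `gxe_design` with elements `data` (tibble of
#'   predictor columns `score`, `e`, `score_x_e`, confounders), `y`,
#'   `family`, and `interaction_term = "score_x_e"`.
#' @export
build_design <- function(score, pheno) {
  if (length(score) != nrow(pheno)) {
    abort("score length must equal the number of phenotype rows")
  }
  confs <- confounder_names(pheno)
  dat <- tibble(score = as.numeric(score),
                e = as.numeric(pheno$e),
                score_x_e = as.numeric(score) * as.numeric(pheno$e))
  for (cc in confs) dat[[cc]] <- as.numeric(pheno[[cc]])
  structure(list(data = dat, y = pheno$y, family = pheno_family(pheno),
                 interaction_term = "score_x_e"),
            class = "gxe_design")
}
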