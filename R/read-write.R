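#' Read a genotype matrix from VCF or a plain dosage table
#'
#' Two formats are supported. `format = "vcf"` reads a (optionally
#' gzipped) VCF via \pkg{vcfR} and converts bi-allelic GT fields to
#' additive alternate-allele dosages; sites whose alternate-allele
#' frequency exceeds 0.5 are recoded so that counts always refer to the
#' minor allele. `format = "matrix"` reads a tab-delimited table with
#' variants in rows: first column the variant identifier, remaining
#' columns one per sample, entries `0/1/2` or `.` for missing.
#'
#' Minor-allele recoding is performed once per file (not per tested set)
#' so that MAF-based weights are stable across sets.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` or `"matrix"`.
#' @param missing Missing-genotype policy: `"mean"` (default) imputes the
#'   variant mean dosage `2 * MAF` computed from observed entries;
#'   `"drop_variant"` removes any variant with a missing entry; `"fail"`
#'   errors on the first missing entry.
#' @return A [genotype_matrix()]. VCF variant identifiers are
#'   `chrom:pos:ref:alt` strings (the ID column is ignored for keying, so
#'   joins with set files are unambiguous); matrix-format identifiers are
#'   taken from the file.
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"),
                           missing = c("mean", "drop_variant", "fail")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") {
    read_genotypes_vcf(path, missing)
  } else {
    read_genotypes_matrix(path, missing)
  }
}

read_genotypes_vcf <- function(path, missing) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no GT genotypes in VCF: ", path)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sprintf("dropping %d multi-allelic site(s); split them upstream", sum(multi)))
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(gt) == 0L) stop("no bi-allelic sites left in VCF: ", path)
  # additive count of ALT alleles from the GT string, phase-agnostic
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  known <- alleles1 %in% c("0", "1") & alleles2 %in% c("0", "1")
  dose[known] <- (alleles1 == "1")[known] + (alleles2 == "1")[known]
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  rownames(dose) <- ids
  variants <- tibble::tibble(
    variant_id = ids,
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"])
  )
  finalize_genotypes(t(dose), variants, missing)
}

read_genotypes_matrix <- function(path, missing) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("genotype matrix needs an ID column and >= 2 samples: ", path)
  ids <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mat[mat == "."] <- NA
  dose <- matrix(suppressWarnings(as.numeric(mat)), nrow(mat), ncol(mat),
                 dimnames = list(ids, colnames(mat)))
  if (any(!is.na(dose) & !(dose %in% c(0, 1, 2)))) {
    stop("genotype matrix entries must be 0, 1, 2 or '.': ", path)
  }
  finalize_genotypes(t(dose), tibble::tibble(variant_id = ids), missing)
}

# shared missing-data resolution + minor-allele recoding
finalize_genotypes <- function(counts, variants, missing) {
  all_missing <- colSums(!is.na(counts)) == 0
  if (any(all_missing)) {
    stop(sprintf("%d variant(s) have no observed genotype", sum(all_missing)))
  }
  has_na <- colSums(is.na(counts)) > 0
  if (any(has_na)) {
    if (missing == "fail") {
      stop(sprintf("missing genotypes at %d variant(s) under policy 'fail'", sum(has_na)))
    }
    if (missing == "drop_variant") {
      warning(sprintf("dropping %d variant(s) with missing genotypes", sum(has_na)))
      counts <- counts[, !has_na, drop = FALSE]
      variants <- variants[!has_na, , drop = FALSE]
      if (ncol(counts) == 0L) stop("all variants dropped by missing policy")
    } else {
      for (j in which(has_na)) {
        obs <- counts[, j]
        counts[is.na(obs), j] <- mean(obs, na.rm = TRUE)
      }
    }
  }
  # recode toward the minor allele so the coded-allele frequency is <= 0.5
  af <- colMeans(counts) / 2
  flip <- af > 0.5
  if (any(flip)) counts[, flip] <- 2 - counts[, flip]
  genotype_matrix(counts, variants = variants)
}

#' Read a phenotype / covariate table
#'
#' @param path Tab-delimited file, first column the sample identifier,
#'   remaining columns named numeric variables.
#' @param pheno_col Name of the column holding the continuous phenotype.
#' @param covar_cols Character vector of covariate column names (may be
#'   empty for an intercept-only null model).
#' @return A tibble with columns `sample_id`, `y`, then one column per
#'   covariate, in the requested order.
#' @export
read_phenotypes <- function(path, pheno_col, covar_cols = character()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  names(tab)[1] <- "sample_id"
  missing_cols <- setdiff(c(pheno_col, covar_cols), names(tab))
  if (length(missing_cols)) {
    stop("phenotype file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(sample_id = as.character(tab$sample_id),
                        y = as.numeric(tab[[pheno_col]]))
  for (cc in covar_cols) out[[cc]] <- as.numeric(tab[[cc]])
  if (anyNA(out$y)) {
    warning("dropping samples with missing phenotype")
    out <- out[!is.na(out$y), , drop = FALSE]
  }
  out
}

#' Read variant-set definitions (SetID convention)
#'
#' @param path Tab-delimited two-column file: set name, variant identifier.
#'   No header. Duplicate identifiers within a set are dropped with a
#'   warning.
#' @return A named list of sets, each a list with `name` and `variant_ids`.
#' @export
read_variant_sets <- function(path) {
  if (!file.exists(path)) stop("set file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("set", "variant_id"),
                           colClasses = "character")
  sets <- split(tab$variant_id, tab$set)
  out <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    if (anyDuplicated(ids)) {
      warning(sprintf("set '%s': %d duplicate variant id(s) removed",
                      nm, sum(duplicated(ids))))
      ids <- unique(ids)
    }
    list(name = nm, variant_ids = ids)
  })
  names(out) <- names(sets)
  out
}

#' Write per-set association results
#'
#' Writes the tibble produced by [rv_test()] as a tab-delimited table with
#' a fixed column order (set, m_total, m_rare, one p-value column per
#' method, then the LRT/ReLRT variance-component ratio estimates).
#' P-values below 1e-3 are rendered in scientific notation. Machine
#' columns keep full precision; `human = TRUE` additionally renders
#' variance-ratio estimates below 1e-3 as `"<0.001"`.
#'
#' @param records Result tibble from [rv_test()].
#' @param path Output path.
#' @param human Render a human-readable report instead of the
#'   full-precision machine table.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, human = FALSE) {
  records <- tibble::as_tibble(records)
  fixed <- c("set", "m_total", "m_rare")
  pcols <- grep("^p_", names(records), value = TRUE)
  lcols <- grep("^lambda_", names(records), value = TRUE)
  hcols <- grep("^h2_", names(records), value = TRUE)
  other <- setdiff(names(records), c(fixed, pcols, lcols, hcols))
  records <- records[, c(intersect(fixed, names(records)), pcols, lcols, hcols, other)]
  out <- records
  fmt_p <- function(p) {
    trimws(ifelse(is.na(p), "NA",
                  ifelse(p < 1e-3, formatC(p, format = "e", digits = 2),
                         formatC(p, format = "g", digits = 6))))
  }
  for (cc in pcols) out[[cc]] <- fmt_p(records[[cc]])
  for (cc in c(lcols, hcols)) {
    v <- records[[cc]]
    out[[cc]] <- if (human) {
      ifelse(is.na(v), "NA", ifelse(v < 1e-3, "<0.001", trimws(formatC(v, format = "g", digits = 4))))
    } else {
      ifelse(is.na(v), "NA", trimws(formatC(v, format = "g", digits = 15)))
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix in the package's plain dosage format
#'
#' Inverse of `read_genotypes(format = "matrix")`: variants in rows, first
#' column `variant_id`, one column per sample.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(variant_id = g$variants$variant_id,
                    t(g$counts), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
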