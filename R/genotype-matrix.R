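#' Genotype matrix of minor-allele counts
#'
#' A `genotype_matrix` holds an n-samples by m-variants matrix of additive
#' minor-allele dosages (0/1/2) together with per-variant metadata and the
#' minor allele frequency (MAF) computed from the counts. All set-based
#' tests in this package consume this container.
#'
#' @param counts Integer matrix, samples in rows, variants in columns,
#'   entries in `{0, 1, 2}`. Row names are sample identifiers, column names
#'   variant identifiers (both generated if absent).
#' @param variants Optional tibble of per-variant metadata with at least a
#'   `variant_id` column; `chrom`/`pos` columns are carried through if
#'   present.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts` (the dosage matrix), `samples` (character vector),
#'   `variants` (tibble with `variant_id`, optional `chrom`/`pos`, and
#'   `maf`).
#' @export
genotype_matrix <- function(counts, variants = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("a genotype matrix needs at least 2 samples")
  if (ncol(counts) < 1L) stop("a genotype matrix needs at least 1 variant")
  storage.mode(counts) <- "double"
  if (anyNA(counts)) {
    stop("missing genotypes must be resolved before construction; ",
         "see `read_genotypes(missing = )`")
  }
  # observed dosages are 0/1/2; mean-imputed entries (2*MAF) are fractional
  if (any(counts < 0 | counts > 2)) {
    stop("genotype counts must be additive minor-allele dosages in [0, 2]")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("v", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate variant identifiers in genotype matrix")
  }
  if (is.null(variants)) {
    variants <- tibble::tibble(variant_id = colnames(counts))
  } else {
    variants <- tibble::as_tibble(variants)
    stopifnot("variant_id" %in% names(variants))
    if (nrow(variants) != ncol(counts)) {
      stop("variant metadata rows must match genotype columns")
    }
    variants$variant_id <- as.character(variants$variant_id)
    colnames(counts) <- variants$variant_id
  }
  variants$maf <- compute_maf(counts)
  structure(
    list(counts = counts, samples = rownames(counts), variants = variants),
    class = "genotype_matrix"
  )
}

#' Minor allele frequency from a dosage matrix
#'
#' @param counts Numeric matrix of 0/1/2 dosages (samples x variants).
#' @return Numeric vector of per-variant allele frequencies of the coded
#'   allele, `colMeans(counts) / 2`. Under the package's minor-allele
#'   coding convention these lie in `[0, 0.5]`.
#' @export
compute_maf <- function(counts) {
  unname(colMeans(counts) / 2)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants; MAF range [%.4g, %.4g]\n",
    nrow(x$counts), ncol(x$counts),
    min(x$variants$maf), max(x$variants$maf)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by variant
#'
#' @param g A [genotype_matrix()].
#' @param keep Logical or integer index over variants, or character
#'   variant identifiers.
#' @return A `genotype_matrix` restricted to the selected variants, order
#'   preserved as given by `keep`.
#' @export
subset_variants <- function(g, keep) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(keep)) keep <- match(keep, g$variants$variant_id)
  if (anyNA(keep)) stop("unknown variant identifiers in subset")
  counts <- g$counts[, keep, drop = FALSE]
  if (ncol(counts) == 0L) {
    stop("no variants left after subsetting; set is not testable")
  }
  genotype_matrix(counts, variants = g$variants[keep, , drop = FALSE])
}

#' Restrict a genotype matrix to rare variants
#'
#' Retains exactly the polymorphic variants with `0 < MAF < maf_threshold`.
#' Monomorphic variants (MAF 0) are dropped with a warning, matching the
#' convention that only polymorphic rare sites enter a set test.
#'
#' @param g A [genotype_matrix()].
#' @param maf_threshold Upper MAF bound, in `(0, 0.5]`. Default `0.01`, the
#'   usual rare-variant definition.
#' @return A `genotype_matrix` containing the surviving variants, original
#'   order preserved. Errors with class `rvlrt_empty_set` if none survive,
#'   which callers report as a "not testable" set.
#' @export
rare_filter <- function(g, maf_threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!(maf_threshold > 0 && maf_threshold <= 0.5)) {
    stop("maf_threshold must be in (0, 0.5]")
  }
  maf <- g$variants$maf
  mono <- maf == 0
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic variant(s)", sum(mono)))
  }
  keep <- !mono & maf < maf_threshold
  if (!any(keep)) {
    stop(structure(
      class = c("rvlrt_empty_set", "error", "condition"),
      list(message = sprintf(
        "no polymorphic variant with MAF < %g; set is not testable",
        maf_threshold
      ), call = sys.call(-1))
    ))
  }
  subset_variants(g, which(keep))
}

#' Align genotypes, phenotypes and a variant set
#'
#' Intersects samples between the genotype matrix and the phenotype table,
#' reorders both identically, and restricts the genotype columns to the
#' variants named by the set that are present in the data.
#'
#' @param g A [genotype_matrix()].
#' @param ph A phenotype table as returned by [read_phenotypes()]: a tibble
#'   with a `sample_id` column, a `y` column and zero or more covariate
#'   columns.
#' @param set Optional variant set: a list with `name` and `variant_ids`
#'   (as produced by [read_variant_sets()]), or a character vector of
#'   variant identifiers. `NULL` keeps all variants.
#' @return A list with elements `genotypes` (aligned `genotype_matrix`) and
#'   `phenotypes` (aligned tibble, same sample order).
#' @export
align_data <- function(g, ph, set = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ph <- tibble::as_tibble(ph)
  stopifnot("sample_id" %in% names(ph))
  shared <- intersect(g$samples, ph$sample_id)
  if (length(shared) < 2L) stop("fewer than 2 samples shared between genotypes and phenotypes")
  n_drop_g <- length(g$samples) - length(shared)
  n_drop_p <- nrow(ph) - length(shared)
  if (n_drop_g + n_drop_p > 0L) {
    message(sprintf("align: dropped %d genotype-only and %d phenotype-only sample(s)",
                    n_drop_g, n_drop_p))
  }
  counts <- g$counts[match(shared, g$samples), , drop = FALSE]
  ph <- ph[match(shared, ph$sample_id), , drop = FALSE]
  g2 <- genotype_matrix(counts, variants = g$variants)
  if (!is.null(set)) {
    ids <- if (is.list(set)) set$variant_ids else set
    ids <- unique(as.character(ids))
    present <- ids[ids %in% g2$variants$variant_id]
    if (length(present) == 0L) stop("none of the set's variants are present in the data")
    if (length(present) < length(ids)) {
      warning(sprintf("%d of %d set variant(s) absent from the genotype data",
                      length(ids) - length(present), length(ids)))
    }
    g2 <- subset_variants(g2, present)
  }
  list(genotypes = g2, phenotypes = ph)
}
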