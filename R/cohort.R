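#' Construct a genotype cohort
#'
#' A cohort bundles a diploid biallelic genotype matrix (alt-allele dosage
#' 0/1/2, `NA` for missing) with a sample metadata table and a variant table.
#' It is the universal input of the pipeline: QC, distances, PCA, admixture,
#' F-statistics and AMOVA all consume a cohort.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   values in `{0, 1, 2, NA}` counting alt alleles.
#' @param samples tibble with columns `id` (unique, non-empty), and optionally
#'   `population`, `subpopulation` (birthplace) and `panel` (study vs
#'   reference source tag). Missing metadata columns are filled with `NA`.
#' @param variants tibble with columns `chrom` (character), `pos` (1-based
#'   integer position), `id`, `ref`, `alt` (single-nucleotide alleles,
#'   `ref != alt`). The key `(chrom, pos, ref, alt)` must be unique.
#'
#' @return an object of class `cohort`.
#' @export
cohort <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- tibble::as_tibble(samples)
  variants <- tibble::as_tibble(variants)
  for (col in c("population", "subpopulation", "panel")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  if (!"id" %in% names(variants)) variants$id <- NA_character_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants <- variants[, c("chrom", "pos", "id", "ref", "alt")]
  obj <- structure(
    list(genotypes = genotypes, samples = samples, variants = variants),
    class = "cohort"
  )
  validate_cohort(obj)
}

validate_cohort <- function(x) {
  g <- x$genotypes
  if (nrow(g) != nrow(x$samples)) {
    stop("genotype rows (", nrow(g), ") != number of samples (",
         nrow(x$samples), ")", call. = FALSE)
  }
  if (ncol(g) != nrow(x$variants)) {
    stop("genotype columns (", ncol(g), ") != number of variants (",
         nrow(x$variants), ")", call. = FALSE)
  }
  bad <- g[!is.na(g) & !(g %in% 0:2)]
  if (length(bad) > 0) {
    stop("genotypes must be 0, 1, 2 or NA; found ", bad[1], call. = FALSE)
  }
  ids <- x$samples$id
  if (anyNA(ids) || any(!nzchar(ids))) stop("sample ids must be non-empty", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  lab_cols <- c("population", "subpopulation", "panel")
  for (col in lab_cols) {
    v <- x$samples[[col]]
    if (any(!is.na(v) & !nzchar(v))) {
      stop("sample ", col, " labels may be NA but not empty strings", call. = FALSE)
    }
  }
  v <- x$variants
  if (any(is.na(v$pos) | v$pos < 1L)) stop("variant pos must be >= 1 (1-based)", call. = FALSE)
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ", call. = FALSE)
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    stop("only single-nucleotide biallelic variants are supported", call. = FALSE)
  }
  if (anyDuplicated(variant_keys(x))) stop("duplicate variant keys (chrom,pos,ref,alt)", call. = FALSE)
  rownames(x$genotypes) <- ids
  colnames(x$genotypes) <- variant_keys(x)
  x
}

#' Variant keys of a cohort or variant table
#'
#' @param x a `cohort` or a data frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_keys <- function(x) {
  v <- if (inherits(x, "cohort")) x$variants else x
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", n_samples(x), " samples x ", n_variants(x), " variants\n", sep = "")
  pops <- table(x$samples$population, useNA = "no")
  if (length(pops) > 0) {
    cat("populations: ", paste(names(pops), pops, sep = "=", collapse = ", "), "\n", sep = "")
  }
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname cohort
#' @param x a cohort.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname cohort
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a cohort by samples and/or variants
#'
#' @param x a cohort.
#' @param samples logical/integer/character index into samples (character
#'   matches sample ids).
#' @param variants logical/integer/character index into variants (character
#'   matches `variant_keys()`).
#' @return a cohort. QC provenance (see [qc_report()]) is preserved.
#' @export
subset_cohort <- function(x, samples = NULL, variants = NULL) {
  si <- seq_len(n_samples(x))
  vi <- seq_len(n_variants(x))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$id) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, variant_keys(x)) else vi[variants]
    if (anyNA(vi)) stop("unknown variant key in subset", call. = FALSE)
  }
  out <- cohort(x$genotypes[si, vi, drop = FALSE],
                x$samples[si, , drop = FALSE],
                x$variants[vi, , drop = FALSE])
  attr(out, "qc_log") <- attr(x, "qc_log")
  out
}

#' Restrict a cohort to autosomal variants
#'
#' Distance, PCA and admixture default to autosomes only; sex chromosomes are
#' carried through I/O and can be retained with `autosomes_only = FALSE` in
#' the downstream functions.
#'
#' @param x a cohort.
#' @return a cohort containing only variants on chromosomes "1".."22".
#' @export
autosomes <- function(x) {
  keep <- x$variants$chrom %in% as.character(1:22)
  subset_cohort(x, variants = keep)
}

# Shared helper: pick working genotype matrix given the autosomes flag.
analysis_genotypes <- function(x, autosomes_only = TRUE) {
  if (autosomes_only) x <- autosomes(x)
  x$genotypes
}
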