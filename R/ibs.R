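#' Identity-by-state similarity between two genotype vectors
#'
#' Per locus with both genotypes non-missing, the shared-allele fraction of
#' two unphased diploid genotypes is `(2 - |g_x - g_y|) / 2`; the similarity
#' is its mean over such loci, and the dissimilarity used throughout the
#' pipeline is `1 - similarity`. Het-het pairs count as fully shared
#' (|1 - 1| = 0), the allele-sharing convention for unphased biallelic data.
#'
#' @param g_x,g_y genotype dosage vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
ibs_pair <- function(g_x, g_y) {
  ok <- !is.na(g_x) & !is.na(g_y)
  if (!any(ok)) stop("no pairwise non-missing loci: IBS undefined", call. = FALSE)
  mean((2 - abs(g_x[ok] - g_y[ok])) / 2)
}

#' Pairwise 1-IBS distance matrix of a cohort
#'
#' Computes all pairwise identity-by-state dissimilarities with
#' pairwise-complete deletion of missing genotypes (per-pair denominators).
#' The computation is cast as indicator-matrix products, so it scales to
#' thousands of samples.
#'
#' @param x a cohort with at least 2 samples.
#' @param autosomes_only restrict to chromosomes 1..22 (default `TRUE`).
#' @return symmetric matrix of `1 - IBS` distances with sample-id dimnames;
#'   zero diagonal, entries in `[0, 1]`.
#' @export
ibs_distance_matrix <- function(x, autosomes_only = TRUE) {
  g <- analysis_genotypes(x, autosomes_only)
  if (nrow(g) < 2) stop("need at least 2 samples", call. = FALSE)
  i0 <- (!is.na(g) & g == 0L) * 1
  i1 <- (!is.na(g) & g == 1L) * 1
  i2 <- (!is.na(g) & g == 2L) * 1
  nm <- i0 + i1 + i2                     # non-missing indicator
  # sum over loci of |g_x - g_y|: 0/1 and 1/2 pairs contribute 1, 0/2 pairs 2
  s01 <- tcrossprod(i0, i1)
  s12 <- tcrossprod(i1, i2)
  s02 <- tcrossprod(i0, i2)
  absdiff <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  n_overlap <- tcrossprod(nm)
  if (any(n_overlap[upper.tri(n_overlap)] == 0)) {
    bad <- which(n_overlap == 0 & upper.tri(n_overlap), arr.ind = TRUE)[1, ]
    stop("no overlapping loci for sample pair (",
         rownames(g)[bad[1]], ", ", rownames(g)[bad[2]], ")", call. = FALSE)
  }
  d <- absdiff / (2 * n_overlap)
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}
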