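#' Variant quality-control filters
#'
#' The QC stage mirrors standard genotype-array practice: remove variants by
#' missingness, by minor allele frequency, by an exact Hardy-Weinberg test,
#' and finally prune variants in linkage disequilibrium within sliding
#' windows. Each filter appends to the cohort's QC log (see [qc_report()]);
#' every filter is idempotent on its own output.
#'
#' @param x a cohort.
#' @param max_missing_rate variants with missing fraction strictly above
#'   this are removed (default 0.01, i.e. missingness > 1%).
#' @return the filtered cohort.
#' @export
filter_missingness <- function(x, max_missing_rate = 0.01) {
  miss <- colMeans(is.na(x$genotypes))
  keep <- miss <= max_missing_rate
  log_qc(subset_cohort(x, variants = keep), "missingness", sum(!keep),
         list(max_missing_rate = max_missing_rate))
}

#' @rdname filter_missingness
#' @param min_maf variants with minor allele frequency strictly below this
#'   are removed (default 0.01).
#' @export
filter_maf <- function(x, min_maf = 0.01) {
  p <- colMeans(x$genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0       # all-missing variant: treated as monomorphic
  keep <- maf >= min_maf
  log_qc(subset_cohort(x, variants = keep), "maf", sum(!keep),
         list(min_maf = min_maf))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, enumerate every
#' heterozygote count of the same parity, weight each by its probability
#' under random mating (the hypergeometric-type HWE distribution), and sum
#' the probabilities that do not exceed the observed configuration's.
#' Probabilities are built by the stable ratio recurrence from the modal
#' heterozygote count. A monomorphic sample yields p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (hom ref, het, hom alt).
#' @param midp use the mid-p variant (half weight on the observed
#'   configuration); default `FALSE`, the plain exact tail.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) stop("negative genotype count", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes", call. = FALSE)
  n_a <- n_Aa + 2 * n_aa                 # minor-ish allele count (alt)
  n_A <- n_Aa + 2 * n_AA
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)
  # possible het counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start at the modal het count and apply the ratio recurrence outward:
  # P(h+2)/P(h) = (nA - h)(na - h) / ((h + 2)(h + 1))   with nA+na = 2n
  mid <- hets[which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))]
  probs[hets == mid] <- 1
  i_mid <- which(hets == mid)
  if (i_mid < length(hets)) {
    for (i in i_mid:(length(hets) - 1)) {
      h <- hets[i]
      probs[i + 1] <- probs[i] * (n_A - h) * (n_a - h) / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in i_mid:2) {
      h <- hets[i]
      probs[i - 1] <- probs[i] * h * (h - 1) /
        ((n_A - h + 2) * (n_a - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_Aa]
  if (length(p_obs) == 0) stop("heterozygote count incompatible with allele counts", call. = FALSE)
  in_tail <- probs <= p_obs * (1 + 1e-12)
  p <- sum(probs[in_tail])
  if (midp) p <- p - p_obs / 2
  min(p, 1)
}

#' @rdname filter_missingness
#' @param alpha variants with exact HWE p-value strictly below `alpha` are
#'   removed (default 0.001). Genotype counts use non-missing samples.
#' @param midp passed to [hwe_exact_pvalue()].
#' @export
filter_hwe <- function(x, alpha = 0.001, midp = FALSE) {
  g <- x$genotypes
  n_AA <- colSums(g == 0L, na.rm = TRUE)
  n_Aa <- colSums(g == 1L, na.rm = TRUE)
  n_aa <- colSums(g == 2L, na.rm = TRUE)
  pvals <- purrr::pmap_dbl(list(n_AA, n_Aa, n_aa), hwe_exact_pvalue, midp = midp)
  keep <- pvals >= alpha
  log_qc(subset_cohort(x, variants = keep), "hwe", sum(!keep),
         list(alpha = alpha, midp = midp))
}

#' Squared genotype correlation between two variants
#'
#' Squared Pearson correlation of the dosage vectors over pairwise
#' non-missing samples — the r-squared used for LD pruning. A constant
#' vector has no defined correlation; for pruning it is treated as r2 = 0
#' and flagged with a warning.
#'
#' @param g_x,g_y genotype dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(g_x, g_y) {
  ok <- !is.na(g_x) & !is.na(g_y)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete observations", call. = FALSE)
  x <- g_x[ok]; y <- g_y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant genotype vector: r2 undefined, treated as 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Sliding window of `window_size` variants per chromosome (variants must be
#' sorted by position within chromosome). Within a window, pairs are scanned
#' greedily in position order; when a pair's genotype r-squared exceeds the
#' threshold, the variant with the lower minor allele frequency is removed
#' (ties broken by removing the later position). The window advances by
#' `step` variants; passes repeat until no window changes. The defaults
#' correspond to the common `--indep-pairwise 1000 10 0.4` parameterization.
#'
#' @param x a cohort with variants sorted by `(chrom, pos)`.
#' @param window_size window width in variants.
#' @param step window step in variants.
#' @param r2_threshold remove one of a pair when r2 strictly exceeds this.
#' @return list with `kept` and `removed` character vectors of variant keys.
#' @export
ld_prune <- function(x, window_size = 1000, step = 10, r2_threshold = 0.4) {
  v <- x$variants
  # chromosomes must form contiguous blocks with non-decreasing positions
  blocks <- rle(v$chrom)$values
  pos_sorted <- all(unlist(tapply(v$pos, factor(v$chrom, levels = unique(v$chrom)),
                                  function(p) !is.unsorted(p))))
  if (anyDuplicated(blocks) || !pos_sorted) {
    stop("variants must be sorted by (chrom, pos) before LD pruning", call. = FALSE)
  }
  g <- x$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keys <- variant_keys(x)
  keep <- rep(TRUE, ncol(g))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    repeat {
      changed <- FALSE
      starts <- seq(1L, max(1L, length(idx)), by = step)
      for (s in starts) {
        win <- idx[s:min(s + window_size - 1L, length(idx))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        r2 <- suppressWarnings(stats::cor(g[, win, drop = FALSE],
                                          use = "pairwise.complete.obs")^2)
        r2[is.na(r2)] <- 0    # constant or no-overlap columns: no LD signal
        for (i in seq_len(length(win) - 1L)) {
          if (!keep[win[i]]) next
          for (j in seq(i + 1L, length(win))) {
            if (!keep[win[j]]) next
            if (r2[i, j] > r2_threshold) {
              vi <- win[i]; vj <- win[j]
              drop <- if (maf[vi] < maf[vj]) vi
                      else if (maf[vj] < maf[vi]) vj
                      else if (v$pos[vi] > v$pos[vj]) vi else vj
              keep[drop] <- FALSE
              changed <- TRUE
              if (drop == vi) break
            }
          }
        }
        if (s + window_size - 1L >= length(idx)) break
      }
      if (!changed) break
    }
  }
  list(kept = keys[keep], removed = keys[!keep])
}

#' Run the full QC pipeline
#'
#' Applies missingness, MAF, HWE and LD-pruning filters in order with the
#' standard defaults and returns the filtered cohort plus its report.
#'
#' @param x a cohort.
#' @param max_missing_rate,min_maf,hwe_alpha,window_size,step,r2_threshold
#'   filter parameters (see the individual filters).
#' @return list with `cohort` (filtered) and `report` (the QC log tibble).
#' @export
run_qc <- function(x, max_missing_rate = 0.01, min_maf = 0.01,
                   hwe_alpha = 0.001, window_size = 1000, step = 10,
                   r2_threshold = 0.4) {
  x <- filter_missingness(x, max_missing_rate)
  x <- filter_maf(x, min_maf)
  x <- filter_hwe(x, hwe_alpha)
  pruned <- ld_prune(x, window_size, step, r2_threshold)
  x <- log_qc(subset_cohort(x, variants = pruned$kept), "ld_prune",
              length(pruned$removed),
              list(window_size = window_size, step = step,
                   r2_threshold = r2_threshold))
  list(cohort = x, report = qc_report(x))
}

log_qc <- function(x, filter, n_removed, params) {
  entry <- tibble::tibble(
    filter = filter,
    n_removed = as.integer(n_removed),
    n_out = n_variants(x),
    params = paste(names(params), unlist(params), sep = "=", collapse = ",")
  )
  attr(x, "qc_log") <- dplyr::bind_rows(attr(x, "qc_log"), entry)
  x
}

#' QC report of a filtered cohort
#'
#' @param x a cohort that has passed through one or more QC filters.
#' @return a tibble: one row per applied filter, with the variant count
#'   removed, the count remaining after it, and the parameters used.
#' @export
qc_report <- function(x) {
  log <- attr(x, "qc_log")
  if (is.null(log)) {
    return(tibble::tibble(filter = character(), n_removed = integer(),
                          n_out = integer(), params = character()))
  }
  log
}
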