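#' Weir-Cockerham FST variance components for one locus
#'
#' The 1984 moment estimator for diploid data: from per-population sample
#' sizes n_i, alt-allele frequencies p_i and observed heterozygote fractions
#' h_i, compute the among-population (a), among-individual (b) and
#' within-individual (c) variance components and theta = a / (a + b + c).
#' A locus monomorphic in every population has a = b = c = 0 and an
#' undefined theta.
#'
#' @param counts a matrix or data frame with one row per population and
#'   columns `n_AA`, `n_Aa`, `n_aa` (genotype counts).
#' @return named list with `a`, `b`, `c`, `theta` (`theta` is `NA` when the
#'   denominator is zero).
#' @export
wc_fst_locus <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 populations", call. = FALSE)
  n_i <- rowSums(counts)
  if (any(n_i < 1)) stop("each population needs at least 1 genotype", call. = FALSE)
  p_i <- (counts[, "n_Aa"] + 2 * counts[, "n_aa"]) / (2 * n_i)
  h_i <- counts[, "n_Aa"] / n_i
  comp <- wc_components(matrix(n_i, 1), matrix(p_i, 1), matrix(h_i, 1))
  list(a = comp$a[1], b = comp$b[1], c = comp$c[1], theta = comp$theta[1])
}

# Vectorized WC84 components; arguments are loci x populations matrices.
wc_components <- function(n, p, h) {
  r <- ncol(n)
  n_bar <- rowMeans(n)
  n_tot <- rowSums(n)
  n_c <- (n_tot - rowSums(n^2) / n_tot) / (r - 1)
  p_bar <- rowSums(n * p) / n_tot
  s2 <- rowSums(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n * h) / n_tot
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- ifelse(abs(denom) < 1e-300 | denom == 0, NA_real_, a / denom)
  theta[denom == 0] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta)
}

locus_count_arrays <- function(x, labels, pops) {
  g <- x$genotypes
  n <- p <- h <- matrix(NA_real_, nrow = ncol(g), ncol = length(pops))
  for (j in seq_along(pops)) {
    gp <- g[labels == pops[j], , drop = FALSE]
    nn <- colSums(!is.na(gp))
    n[, j] <- nn
    p[, j] <- colSums(gp, na.rm = TRUE) / (2 * nn)
    h[, j] <- colSums(gp == 1L, na.rm = TRUE) / nn
  }
  list(n = n, p = p, h = h)
}

#' Pairwise Weir-Cockerham FST between two populations
#'
#' Computes per-locus variance components over all loci where both
#' populations have at least one non-missing genotype, and reports both
#' summary estimators: `theta_mean`, the mean of per-locus theta over loci
#' with a defined denominator (the "mean FST" convention of the usual
#' command-line tool, used as the headline value), and `theta_wc`, the
#' ratio of sums `sum(a) / sum(a + b + c)` (the statistically preferred
#' weighting).
#'
#' @param x a cohort.
#' @param pop_a,pop_b population labels present in `label_col`.
#' @param label_col sample metadata column with the labels.
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return an object of class `fst_result`: `per_locus` tibble (`chrom`,
#'   `pos`, `a`, `b`, `c`, `theta`), `theta_mean`, `theta_wc`,
#'   `n_undefined` (loci excluded from `theta_mean`), `pops`.
#' @export
mean_fst <- function(x, pop_a, pop_b, label_col = "population",
                     autosomes_only = TRUE) {
  if (autosomes_only) x <- autosomes(x)
  labels <- x$samples[[label_col]]
  pops <- c(pop_a, pop_b)
  if (!all(pops %in% labels)) stop("population label absent from cohort", call. = FALSE)
  arr <- locus_count_arrays(x, labels, pops)
  usable <- rowSums(arr$n >= 1) == 2
  comp <- wc_components(arr$n[usable, , drop = FALSE],
                        arr$p[usable, , drop = FALSE],
                        arr$h[usable, , drop = FALSE])
  per_locus <- tibble::tibble(
    chrom = x$variants$chrom[usable], pos = x$variants$pos[usable],
    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta
  )
  defined <- !is.na(comp$theta)
  structure(
    list(per_locus = per_locus,
         theta_mean = mean(comp$theta[defined]),
         theta_wc = sum(comp$a[defined]) /
           sum(comp$a[defined] + comp$b[defined] + comp$c[defined]),
         n_undefined = sum(!defined),
         pops = pops),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result>", x$pops[1], "vs", x$pops[2],
      sprintf("| theta_mean = %.5f | theta_wc = %.5f | %d loci (%d undefined)\n",
              x$theta_mean, x$theta_wc, nrow(x$per_locus), x$n_undefined))
  invisible(x)
}

#' Pairwise mean-FST matrix over populations
#'
#' @param x a cohort.
#' @param label_col sample metadata column with population labels.
#' @param statistic `"theta_mean"` (default) or `"theta_wc"`.
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return symmetric matrix over populations, zero diagonal.
#' @export
pairwise_fst_matrix <- function(x, label_col = "population",
                                statistic = c("theta_mean", "theta_wc"),
                                autosomes_only = TRUE) {
  statistic <- match.arg(statistic)
  labels <- x$samples[[label_col]]
  pops <- sort(unique(labels[!is.na(labels)]))
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations", call. = FALSE)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      f <- mean_fst(x, pops[i], pops[j], label_col, autosomes_only)[[statistic]]
      out[i, j] <- f
      out[j, i] <- f
    }
  }
  out
}

#' Three-level AMOVA on allele-level data
#'
#' Partitions total allelic variance into among-population,
#' among-individual-within-population and within-individual strata. Per
#' locus, each non-missing diploid individual contributes two allele
#' copies; sums of squares and degrees of freedom are accumulated over loci
#' (a weighted average over loci), and variance components come from the
#' nested mean-square equations with size-weighted coefficients. The
#' fixation index is the among-population component over the total.
#'
#' @param x a cohort.
#' @param label_col sample metadata column giving the population (e.g.
#'   birthplace) grouping; default `"subpopulation"` with fallback to
#'   `"population"` when all subpopulation labels are missing.
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return an object of class `amova_result`: `table` tibble (`source`,
#'   `df`, `ss`, `variance`, `percentage`), `fst`, `n_pops`.
#' @export
amova <- function(x, label_col = "subpopulation", autosomes_only = TRUE) {
  if (autosomes_only) x <- autosomes(x)
  labels <- x$samples[[label_col]]
  if (all(is.na(labels)) && label_col == "subpopulation") {
    labels <- x$samples$population
  }
  keep <- !is.na(labels)
  g <- x$genotypes[keep, , drop = FALSE]
  labels <- labels[keep]
  pops <- unique(labels)
  if (length(pops) < 2) stop("need at least 2 populations", call. = FALSE)
  if (any(table(labels) < 2)) stop("each population needs >= 2 individuals", call. = FALSE)
  pop_idx <- split(seq_along(labels), labels)

  ss <- c(among_pop = 0, among_ind = 0, within_ind = 0)
  df <- c(among_pop = 0, among_ind = 0, within_ind = 0)
  s1 <- 0   # accumulated sum of 2*n_i over loci
  s2 <- 0   # accumulated sum of (2*n_i)^2 / (2*N) over loci
  n_coef_df <- 0
  pop_of <- rep(names(pop_idx), lengths(pop_idx))[order(unlist(pop_idx))]
  for (m in seq_len(ncol(g))) {
    gm <- g[, m]
    obs <- !is.na(gm)
    n_i <- vapply(pop_idx, function(ix) sum(obs[ix]), integer(1))
    use <- n_i > 0
    if (sum(use) < 2) next
    n_tot <- sum(n_i)
    y_bar <- sum(gm[obs]) / (2 * n_tot)               # grand allele mean
    ybar_ind <- gm[obs] / 2
    pop_obs <- pop_of[obs]
    ybar_pop <- vapply(names(pop_idx)[use], function(p) {
      mean(ybar_ind[pop_obs == p])
    }, numeric(1))
    ss["within_ind"] <- ss["within_ind"] + 0.5 * sum(gm[obs] == 1L)
    ss["among_ind"] <- ss["among_ind"] +
      2 * sum((ybar_ind - ybar_pop[pop_obs])^2)
    ss["among_pop"] <- ss["among_pop"] +
      2 * sum(n_i[use] * (ybar_pop - y_bar)^2)
    df["within_ind"] <- df["within_ind"] + n_tot
    df["among_ind"] <- df["among_ind"] + n_tot - sum(use)
    df["among_pop"] <- df["among_pop"] + sum(use) - 1
    copies <- 2 * n_i[use]
    s1 <- s1 + sum(copies)
    s2 <- s2 + sum(copies^2) / sum(copies)
    n_coef_df <- n_coef_df + sum(use) - 1
  }
  if (sum(ss) == 0) {
    tab <- tibble::tibble(
      source = c("Among populations", "Among individuals within populations",
                 "Within individuals"),
      df = as.numeric(df), ss = as.numeric(ss),
      variance = c(0, 0, 0), percentage = c(NA_real_, NA_real_, NA_real_)
    )
    return(structure(list(table = tab, fst = NA_real_, n_pops = length(pops)),
                     class = "amova_result"))
  }
  ms <- ss / pmax(df, 1)
  n_coef <- (s1 - s2) / n_coef_df       # coefficient of the among-pop component
  sigma_c <- ms[["within_ind"]]
  sigma_b <- (ms[["among_ind"]] - sigma_c) / 2
  sigma_a <- (ms[["among_pop"]] - sigma_c - 2 * sigma_b) / n_coef
  comps <- c(sigma_a, sigma_b, sigma_c)
  vp <- variance_percentages(comps)
  tab <- tibble::tibble(
    source = c("Among populations", "Among individuals within populations",
               "Within individuals"),
    df = as.numeric(df), ss = as.numeric(ss),
    variance = comps, percentage = vp$percentages
  )
  structure(list(table = tab, fst = vp$fst, n_pops = length(pops)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>", x$n_pops, "populations | Fst =",
      signif(x$fst, 4), "\n")
  print(x$table, ...)
  invisible(x)
}

#' Percentage variation and fixation index from variance components
#'
#' Given the three AMOVA variance components (among populations, among
#' individuals within populations, within individuals), returns each as a
#' percentage of their sum and the fixation index (among-population
#' component over the total). Negative components — which moment estimators
#' can produce — are truncated at zero for the percentage calculation; raw
#' values should be reported alongside.
#'
#' @param components numeric vector of the three variance components.
#' @return list with `percentages` (length 3, summing to 100) and `fst`.
#' @export
variance_percentages <- function(components) {
  stopifnot(length(components) == 3)
  trunc <- pmax(components, 0)
  total <- sum(trunc)
  if (total <= 0) stop("variance components sum to zero", call. = FALSE)
  list(percentages = 100 * trunc / total, fst = trunc[1] / total)
}

#' Slatkin linearized genetic distance
#'
#' `D = fst / (1 - fst)`: a transform of the fixation index approximately
#' linear in divergence time under the island model.
#'
#' @param fst fixation index values, each < 1.
#' @return linearized distances (>= 0 for `fst >= 0`).
#' @export
slatkin_distance <- function(fst) {
  if (any(fst >= 1)) stop("Slatkin distance undefined at fst = 1", call. = FALSE)
  fst / (1 - fst)
}
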