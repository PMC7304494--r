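#' Variance-standardized genotype matrix
#'
#' Per locus with alt frequency p (estimated from the cohort itself), each
#' dosage g becomes `(g - 2p) / sqrt(2 p (1 - p))` — the usual unit-variance
#' scaling under Hardy-Weinberg. Missing entries are set to 0 after
#' centering (imputation to the locus mean).
#'
#' @param x a cohort whose loci are polymorphic (run QC first).
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return numeric matrix, samples x loci.
#' @export
standardize_genotypes <- function(x, autosomes_only = TRUE) {
  g <- analysis_genotypes(x, autosomes_only)
  p <- colMeans(g, na.rm = TRUE) / 2
  if (any(is.nan(p) | p <= 0 | p >= 1)) {
    stop("monomorphic or all-missing locus: apply the QC filters first", call. = FALSE)
  }
  z <- sweep(g, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  z
}

#' Principal component analysis of standardized genotypes
#'
#' Eigen-decomposes the sample-by-sample covariance of the standardized
#' genotype matrix. Coordinates are eigenvectors scaled by the square root
#' of their eigenvalue, with the sign convention that each component's
#' largest-magnitude loading is positive.
#'
#' @param x a cohort (QC'd: polymorphic loci).
#' @param n_components number of components to retain (default 20; must not
#'   exceed the sample count).
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return an object of class `pca_result`: `ids`, `coords` (samples x
#'   components, columns `PC1..PCn`), `eigenvalues` (descending).
#' @export
run_pca <- function(x, n_components = 20, autosomes_only = TRUE) {
  z <- standardize_genotypes(x, autosomes_only)
  n <- nrow(z)
  if (n < n_components) stop("fewer samples than requested components", call. = FALSE)
  cov_s <- tcrossprod(z) / ncol(z)
  eig <- eigen(cov_s, symmetric = TRUE)
  idx <- seq_len(n_components)
  vals <- eig$values[idx]
  vecs <- eig$vectors[, idx, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in idx) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  coords <- sweep(vecs, 2, sqrt(pmax(vals, 0)), "*")
  colnames(coords) <- paste0("PC", idx)
  rownames(coords) <- x$samples$id
  structure(
    list(ids = x$samples$id, coords = coords, eigenvalues = vals),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", length(x$ids), " samples, ",
      ncol(x$coords), " components\n", sep = "")
  cat("top eigenvalues:", signif(utils::head(x$eigenvalues, 5), 4), "\n")
  invisible(x)
}

#' Reference-panel allele frequencies for supervised admixture
#'
#' Estimates the K x M frequency matrix F from labeled reference samples:
#' per population and locus, the alt-allele frequency over non-missing
#' genotypes, clamped to `[1e-6, 1 - 1e-6]` to keep the likelihood finite.
#'
#' @param x a cohort of reference samples.
#' @param label_col sample metadata column holding the population labels
#'   (default `"population"`).
#' @param autosomes_only restrict to chromosomes 1..22.
#' @return an object of class `admixture_model`: `pops`, `freqs` (K x M),
#'   `variant_keys`.
#' @export
estimate_panel_frequencies <- function(x, label_col = "population",
                                       autosomes_only = TRUE) {
  if (autosomes_only) x <- autosomes(x)
  labels <- x$samples[[label_col]]
  if (anyNA(labels)) stop("reference samples must all be labeled", call. = FALSE)
  pops <- sort(unique(labels))
  f <- t(vapply(pops, function(p) {
    colMeans(x$genotypes[labels == p, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(n_variants(x))))
  f[is.nan(f)] <- 0.5                    # population with no calls at a locus
  f <- clamp_freq(f)
  rownames(f) <- pops
  structure(
    list(pops = pops, freqs = f, variant_keys = variant_keys(x)),
    class = "admixture_model"
  )
}

#' @rdname estimate_panel_frequencies
#' @param freqs K x M matrix of allele frequencies with population rownames.
#' @param keys variant keys aligned to the matrix columns.
#' @export
admixture_model <- function(freqs, keys) {
  stopifnot(nrow(freqs) >= 1, ncol(freqs) == length(keys))
  structure(
    list(pops = rownames(freqs), freqs = clamp_freq(freqs),
         variant_keys = keys),
    class = "admixture_model"
  )
}

#' Supervised admixture estimation by EM
#'
#' With reference-panel frequencies F fixed, each sample's ancestry vector q
#' maximizes the binomial likelihood
#' `L(q) = sum_m [ g_m log(sum_k q_k f_km) + (2 - g_m) log(sum_k q_k (1 - f_km)) ]`
#' over the simplex. The EM update
#' `q_k <- (1 / 2M') sum_m [ g_m q_k f_km / p_m + (2 - g_m) q_k (1 - f_km) / (1 - p_m) ]`
#' (with `p_m = sum_j q_j f_jm` and M' the sample's non-missing locus count)
#' is monotone in the log-likelihood. Samples are optimized independently;
#' missing genotypes are dropped from the likelihood, not imputed.
#'
#' @param x a cohort, or a genotype matrix whose columns align with
#'   `model$variant_keys`.
#' @param model an `admixture_model`.
#' @param tol stop a sample when its log-likelihood improves by less than
#'   this (default 1e-6).
#' @param max_iter iteration cap per sample (default 1000).
#' @param autosomes_only restrict to chromosomes 1..22 (cohort input only).
#' @return an object of class `admixture_fit`: a tibble with `sample_id`,
#'   one ancestry column per model population, `loglik`, `iterations`,
#'   `converged`.
#' @export
fit_admixture <- function(x, model, tol = 1e-6, max_iter = 1000,
                          autosomes_only = TRUE) {
  if (inherits(x, "cohort")) {
    g <- analysis_genotypes(x, autosomes_only)
    idx <- match(model$variant_keys, colnames(g))
    if (anyNA(idx)) stop("model and cohort variant keys do not align", call. = FALSE)
    g <- g[, idx, drop = FALSE]
  } else {
    g <- as.matrix(x)
    if (ncol(g) != length(model$variant_keys)) {
      stop("genotype columns do not match model loci", call. = FALSE)
    }
  }
  if (any(rowSums(!is.na(g)) == 0)) stop("sample with all genotypes missing", call. = FALSE)
  f <- model$freqs
  k <- nrow(f)
  n <- nrow(g)
  gm <- g
  gm[is.na(gm)] <- 0L                     # masked below via `obs`
  obs <- (!is.na(g)) * 1
  g1 <- gm * obs                          # alt-allele counts, 0 where missing
  g0 <- (2 - gm) * obs                    # ref-allele counts, 0 where missing
  m_eff <- rowSums(obs)
  q <- matrix(1 / k, nrow = n, ncol = k)
  loglik_of <- function(q_rows, rows) {
    p <- q_rows %*% f
    rowSums(g1[rows, , drop = FALSE] * log(p) +
              g0[rows, , drop = FALSE] * log1p(-p))
  }
  ll <- loglik_of(q, seq_len(n))
  active <- rep(TRUE, n)
  iters <- integer(n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    a <- which(active)
    qa <- q[a, , drop = FALSE]
    p <- qa %*% f
    num <- (g1[a, , drop = FALSE] / p) %*% t(f) +
           (g0[a, , drop = FALSE] / (1 - p)) %*% t(1 - f)
    qa_new <- qa * num / (2 * m_eff[a])
    qa_new <- qa_new / rowSums(qa_new)    # guard tiny numerical drift
    q[a, ] <- qa_new
    ll_new <- loglik_of(q[a, , drop = FALSE], a)
    done <- (ll_new - ll[a]) < tol
    ll[a] <- ll_new
    iters[a] <- it
    active[a[done]] <- FALSE
  }
  out <- tibble::as_tibble(as.data.frame(q))
  names(out) <- model$pops
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(g) %||% sprintf("S%04d", seq_len(n))),
    out,
    tibble::tibble(loglik = ll, iterations = iters, converged = !active)
  )
  structure(out, class = c("admixture_fit", class(out)), pops = model$pops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ancestry proportions as a matrix
#'
#' @param fit an `admixture_fit`.
#' @return numeric matrix samples x populations with sample-id rownames.
#' @export
proportions_matrix <- function(fit) {
  pops <- attr(fit, "pops")
  m <- as.matrix(fit[, pops, drop = FALSE])
  rownames(m) <- fit$sample_id
  m
}

#' Fraction of samples dominated by one ancestry component
#'
#' @param fit an `admixture_fit`.
#' @param component a model population name.
#' @param threshold proportion cut-off (e.g. 0.99).
#' @return the fraction of samples whose `component` proportion exceeds
#'   `threshold`.
#' @export
proportion_summary <- function(fit, component, threshold) {
  if (nrow(fit) == 0) stop("empty proportions table", call. = FALSE)
  if (!component %in% attr(fit, "pops")) stop("unknown component", call. = FALSE)
  mean(fit[[component]] > threshold)
}

#' Cohort-level mean ancestry proportions
#'
#' The accumulated ancestral composition of the whole cohort (the pie-chart
#' summary): the arithmetic mean of the per-sample ancestry vectors, itself
#' on the simplex.
#'
#' @param fit an `admixture_fit`.
#' @return a tibble with `population` and `proportion`.
#' @export
aggregate_proportions <- function(fit) {
  if (nrow(fit) == 0) stop("empty proportions table", call. = FALSE)
  q <- proportions_matrix(fit)
  tibble::tibble(population = colnames(q), proportion = colMeans(q))
}

#' Write an admixture fit as a Q-matrix style TSV
#'
#' @param fit an `admixture_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_admixture_tsv <- function(fit, path) {
  readr::write_tsv(tibble::as_tibble(fit), path, progress = FALSE)
  invisible(path)
}
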