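# Small fixtures built in code, shared across test files.

# A fixed 3-sample x 4-variant cohort with one missing genotype.
tiny_cohort <- function() {
  g <- rbind(
    c(0L, 1L, 2L, 0L),
    c(1L, 1L, 2L, NA),
    c(2L, 0L, 2L, 1L)
  )
  cohort(
    g,
    tibble::tibble(id = c("A", "B", "C"),
                   population = c("P1", "P1", "P2")),
    tibble::tibble(chrom = c("1", "1", "2", "2"),
                   pos = c(100L, 200L, 100L, 300L),
                   id = paste0("v", 1:4),
                   ref = c("A", "C", "G", "T"),
                   alt = c("G", "T", "A", "C"))
  )
}

# Cohort built directly from a genotype matrix, variants spread on chrom 1.
matrix_cohort <- function(g, population = NULL, subpopulation = NULL,
                          chrom = NULL) {
  n <- nrow(g); m <- ncol(g)
  bases <- c("A", "C", "G", "T")
  cohort(
    g,
    tibble::tibble(
      id = sprintf("S%03d", seq_len(n)),
      population = population %||% rep(NA_character_, n),
      subpopulation = subpopulation %||% rep(NA_character_, n)
    ),
    tibble::tibble(
      chrom = chrom %||% rep("1", m),
      pos = seq_len(m) * 100L,
      id = sprintf("rs%d", seq_len(m)),
      ref = bases[rep_len(1:4, m)],
      alt = bases[rep_len(c(3L, 4L, 1L, 2L), m)]
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype matrix at given allele frequencies (HWE draws).
random_genotypes <- function(n, freqs) {
  m <- length(freqs)
  matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n)
}

# Independent enumeration oracle for the exact HWE test: direct multinomial
# probability of each heterozygote count given the allele counts.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- n_Aa + 2 * n_aa
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_alt - h) / 2
    nAA <- n - h - naa
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
      h * log(2) + lgamma(n_alt + 1) + lgamma(2 * n - n_alt + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Brute-force 1-IBS distance matrix (double loop over pairs and loci).
ibs_oracle <- function(g) {
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      sim <- mean((2 - abs(g[i, ok] - g[j, ok])) / 2)
      d[i, j] <- d[j, i] <- 1 - sim
    }
  }
  d
}

# Naive O(n^3) UPGMA oracle: explicit size-weighted agglomeration returning
# the merge heights in order.
upgma_oracle_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  active <- rep(TRUE, length(clusters))
  heights <- numeric(0)
  cdist <- function(a, b) {
    mean(d[clusters[[a]], clusters[[b]], drop = FALSE])
  }
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in idx) for (j in idx) if (i < j) {
      dd <- cdist(i, j)
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  heights
}

# Independent transcription of the Weir & Cockerham (1984) single-locus
# estimator, written from the component definitions (not shared with the
# package implementation).
wc_oracle <- function(counts) {
  counts <- as.matrix(counts)
  r <- nrow(counts)
  n_i <- rowSums(counts)
  p_i <- (counts[, 2] + 2 * counts[, 3]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Dirichlet draws for test fixtures.
rdirichlet_test <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

# Independent EM replay used only to verify likelihood monotonicity.
em_loglik_trace <- function(g, f, n_iter) {
  k <- nrow(f)
  q <- rep(1 / k, k)
  ll <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    p <- as.numeric(q %*% f)
    ll[it] <- sum(g * log(p) + (2 - g) * log(1 - p))
    w1 <- t(f) * rep(q, each = ncol(f)) / p
    w0 <- t(1 - f) * rep(q, each = ncol(f)) / (1 - p)
    q <- (colSums(g * w1) + colSums((2 - g) * w0)) / (2 * length(g))
    q <- q / sum(q)
  }
  ll
}
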