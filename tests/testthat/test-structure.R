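test_that("genotype standardization applies the unit-variance scaling", {
  # one locus at p = 0.5: g = 2 -> (2 - 1) / sqrt(0.5) = sqrt(2)
  g <- matrix(c(2L, 0L, 1L, 1L), ncol = 1)
  z <- standardize_genotypes(matrix_cohort(g))
  expect_equal(z[1, 1], sqrt(2))
  expect_equal(z[2, 1], -sqrt(2))
  expect_equal(z[3, 1], 0)                      # g = 2p exactly
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-9)

  g_na <- matrix(c(2L, 0L, NA, 1L, 1L, 1L), ncol = 2)
  z_na <- standardize_genotypes(matrix_cohort(g_na))
  expect_equal(z_na[3, 1], 0)                   # missing -> imputed to mean

  mono <- matrix_cohort(matrix(0L, 4, 1))
  expect_error(standardize_genotypes(mono), "monomorphic")
})

test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(31)
  g <- random_genotypes(20, runif(200, 0.1, 0.9))
  coh <- matrix_cohort(g)
  res <- run_pca(coh, n_components = 10)
  z <- standardize_genotypes(coh)
  oracle_vals <- eigen(tcrossprod(z) / ncol(z), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, oracle_vals[1:10], tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))
  # coordinate columns are mutually orthogonal
  cp <- crossprod(res$coords)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6 * max(diag(cp)))
  # sign convention: largest-magnitude loading positive
  for (j in 1:10) expect_gt(res$coords[which.max(abs(res$coords[, j])), j], 0)
})

test_that("PCA separates discrete populations and maps duplicates together", {
  anc <- simulate_ancestral_frequencies(2000, 2, 0.1, seed = 32)
  sim <- simulate_cohort(anc, design_discrete(c(100, 100)), seed = 33)
  coh <- filter_maf(sim$cohort, 0.01)           # PCA expects polymorphic loci
  res <- run_pca(coh, n_components = 5)
  pc1 <- res$coords[, 1]
  pop <- coh$samples$population
  r1 <- range(pc1[pop == "POP1"])
  r2 <- range(pc1[pop == "POP2"])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])   # zero overlap on PC1

  g_dup <- rbind(coh$genotypes, coh$genotypes[1, ])
  coh_dup <- matrix_cohort(g_dup)
  res_dup <- run_pca(coh_dup, n_components = 3)
  expect_equal(res_dup$coords[201, ], res_dup$coords[1, ],
               ignore_attr = TRUE, tolerance = 1e-6)

  expect_error(run_pca(matrix_cohort(random_genotypes(5, rep(0.5, 50))),
                       n_components = 10), "fewer samples")
})

test_that("panel frequency estimation agrees with grouped allele frequencies", {
  g <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 2L), c(2L, 2L))
  coh <- matrix_cohort(g, population = c("P1", "P1", "P2", "P2"))
  model <- estimate_panel_frequencies(coh)
  expect_equal(unname(model$freqs["P1", ]), c(0.5, 0.5))
  fp <- allele_freqs(coh, by_population = TRUE)
  for (p in c("P1", "P2")) {
    # model frequencies are the grouped frequencies, clamped off 0/1
    expect_equal(unname(model$freqs[p, ]),
                 pmin(pmax(dplyr::filter(fp, population == p)$freq, 1e-6),
                      1 - 1e-6))
  }
  # monomorphic loci are clamped away from 0/1
  mono <- matrix_cohort(matrix(0L, 3, 1), population = rep("P1", 3))
  expect_equal(unname(estimate_panel_frequencies(mono)$freqs[1, 1]), 1e-6)
})

test_that("supervised EM handles degenerate cases and is likelihood-monotone", {
  # K = 1: q = 1 immediately
  m1 <- admixture_model(matrix(0.4, 1, 10, dimnames = list("P1", NULL)),
                        paste0("1:", 1:10 * 100, ":A:G"))
  g <- matrix(rbinom(10, 2, 0.4), nrow = 1)
  f1 <- fit_admixture(g, m1)
  expect_equal(f1$P1, 1)
  expect_true(f1$converged)

  # opposite fixed panels force the assignment
  f_mat <- rbind(rep(1 - 1e-6, 20), rep(1e-6, 20))
  rownames(f_mat) <- c("HI", "LO")
  m2 <- admixture_model(f_mat, paste0("1:", 1:20 * 100, ":A:G"))
  f2 <- fit_admixture(matrix(2L, 1, 20), m2)
  expect_gt(f2$HI, 0.999)
  expect_lt(f2$LO, 0.001)

  # monotone log-likelihood on random instances (explicit EM replay)
  set.seed(41)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    m <- 300
    f <- matrix(runif(k * m, 0.05, 0.95), k, m,
                dimnames = list(paste0("P", 1:k), NULL))
    model <- admixture_model(f, paste0("1:", 1:m, ":A:G"))
    q_true <- as.numeric(rdirichlet_test(1, rep(1, k)))
    g <- matrix(rbinom(m, 2, as.numeric(q_true %*% f)), 1, m)
    ll <- em_loglik_trace(g[1, ], f, n_iter = 40)
    expect_true(all(diff(ll) >= -1e-8))
    fit <- fit_admixture(g, model)
    expect_equal(sum(as.matrix(fit[, model$pops])), 1, tolerance = 1e-6)
  }
})

test_that("EM fit is invariant to locus order and duplication", {
  set.seed(43)
  k <- 3; m <- 400
  f <- matrix(runif(k * m, 0.05, 0.95), k, m,
              dimnames = list(paste0("P", 1:k), NULL))
  keys <- paste0("1:", 1:m, ":A:G")
  model <- admixture_model(f, keys)
  g <- matrix(rbinom(m, 2, as.numeric(c(0.5, 0.3, 0.2) %*% f)), 1, m)
  q0 <- as.matrix(fit_admixture(g, model)[, 1:3 + 1])

  perm <- sample(m)
  q_perm <- as.matrix(fit_admixture(g[, perm, drop = FALSE],
                                    admixture_model(f[, perm], keys[perm]))[, 1:3 + 1])
  expect_equal(q_perm, q0, tolerance = 1e-6)

  q_dup <- as.matrix(fit_admixture(cbind(g, g),
                                   admixture_model(cbind(f, f),
                                                   c(keys, paste0("2:", 1:m, ":A:G"))))[, 1:3 + 1])
  expect_equal(q_dup, q0, tolerance = 1e-4)

  expect_error(fit_admixture(matrix(NA_integer_, 1, m), model), "all genotypes missing")
})

test_that("ancestry recovery, summaries and aggregation behave on simulated truth", {
  anc <- simulate_ancestral_frequencies(3000, 3, 0.15, seed = 51)
  sim <- simulate_cohort(anc, design_dirichlet(30, alpha = c(2, 1, 1)), seed = 52)
  model <- admixture_model(anc$freqs, variant_keys(sim$cohort))
  fit <- fit_admixture(sim$cohort, model, autosomes_only = FALSE)
  q_hat <- proportions_matrix(fit)
  q_true <- as.matrix(sim$truth$proportions[, -1])
  expect_lt(mean(abs(q_hat - q_true)), 0.03)

  expect_equal(proportion_summary(fit, "POP1", 1.0), 0)
  disc <- simulate_cohort(anc, design_discrete(c(20, 20, 10)), seed = 53)
  fit_d <- fit_admixture(disc$cohort, model, autosomes_only = FALSE)
  expect_equal(proportion_summary(fit_d, "POP1", 0.9), 0.4, tolerance = 0.1)

  agg <- aggregate_proportions(fit)
  expect_equal(sum(agg$proportion), 1, tolerance = 1e-9)
  expect_equal(agg$proportion, colMeans(q_hat), ignore_attr = TRUE)

  # two one-hot samples average to (0.5, 0.5)
  m2 <- admixture_model(rbind(A = rep(0.999999, 50), B = rep(1e-6, 50)),
                        paste0("1:", 1:50, ":A:G"))
  g2 <- rbind(rep(2L, 50), rep(0L, 50))
  fit2 <- fit_admixture(g2, m2)
  agg2 <- aggregate_proportions(fit2)
  expect_equal(agg2$proportion, c(0.5, 0.5), tolerance = 1e-3,
               ignore_attr = TRUE)
})
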