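counts_mat <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("n_AA", "n_Aa", "n_aa")
  m
}

test_that("Weir-Cockerham locus estimator handles canonical configurations", {
  # fixed difference: theta = 1
  fixed <- wc_fst_locus(counts_mat(c(50, 0, 0), c(0, 0, 50)))
  expect_equal(fixed$theta, 1)

  # identical genotype count vectors: theta <= 0, exact oracle value
  same <- counts_mat(c(30, 40, 30), c(30, 40, 30))
  res <- wc_fst_locus(same)
  orc <- wc_oracle(same)
  expect_equal(res$theta, orc$theta, tolerance = 1e-12)
  expect_lte(res$theta, 0)

  # monomorphic across populations: all components zero, theta undefined
  mono <- wc_fst_locus(counts_mat(c(50, 0, 0), c(30, 0, 0)))
  expect_equal(mono$a, 0)
  expect_equal(mono$b, 0)
  expect_equal(mono$c, 0)
  expect_true(is.na(mono$theta))

  expect_error(wc_fst_locus(counts_mat(c(10, 5, 5))), "2 populations")
})

test_that("locus estimator matches the independent formula transcription broadly", {
  set.seed(91)
  for (i in 1:1000) {
    r <- sample(2:5, 1)
    cm <- matrix(sample(0:30, 3 * r, replace = TRUE), nrow = r)
    cm[rowSums(cm) == 0, 1] <- 1
    colnames(cm) <- c("n_AA", "n_Aa", "n_aa")
    res <- wc_fst_locus(cm)
    orc <- wc_oracle(cm)
    expect_equal(res$a, orc$a, tolerance = 1e-12)
    expect_equal(res$b, orc$b, tolerance = 1e-12)
    expect_equal(res$c, orc$c, tolerance = 1e-12)
    if (!is.na(orc$theta)) expect_equal(res$theta, orc$theta, tolerance = 1e-12)
  }
})

test_that("pairwise mean FST recovers simulated divergence and is symmetric", {
  anc <- simulate_ancestral_frequencies(2000, 2, 0.1, seed = 92)
  sim <- simulate_cohort(anc, design_discrete(c(100, 100)), seed = 93)
  res <- mean_fst(sim$cohort, "POP1", "POP2")
  expect_lt(abs(res$theta_wc - 0.1), 0.02)

  res_ba <- mean_fst(sim$cohort, "POP2", "POP1")
  expect_equal(res$theta_wc, res_ba$theta_wc)
  expect_equal(res$theta_mean, res_ba$theta_mean)

  # null: an arbitrary split of one panmictic population
  anc0 <- simulate_ancestral_frequencies(2000, 1, 0.2, seed = 94)
  sim0 <- simulate_cohort(anc0, design_discrete(150), seed = 95)
  coh0 <- sim0$cohort
  coh0$samples$population <- rep(c("A", "B"), length.out = 150)
  expect_lt(abs(mean_fst(coh0, "A", "B")$theta_mean), 0.01)

  # single-locus cohort reduces to the locus estimator
  g1 <- cbind(c(rep(0L, 20), rep(2L, 20)))
  coh1 <- matrix_cohort(g1, population = rep(c("X", "Y"), each = 20))
  one <- mean_fst(coh1, "X", "Y")
  expect_equal(one$theta_mean,
               wc_fst_locus(counts_mat(c(20, 0, 0), c(0, 0, 20)))$theta)
})

test_that("pairwise FST matrix ordering follows simulated divergence", {
  anc <- simulate_ancestral_frequencies(1500, 2, 0.2, seed = 96)
  nested <- anc
  nested$freqs <- rbind(P1 = anc$freqs[1, ],
                        P2 = 0.85 * anc$freqs[1, ] + 0.15 * anc$freqs[2, ],
                        P3 = anc$freqs[2, ])
  nested$pop_names <- c("P1", "P2", "P3")
  sim <- simulate_cohort(nested, design_discrete(c(60, 60, 60)), seed = 97)
  fm <- pairwise_fst_matrix(sim$cohort)
  expect_equal(fm, t(fm))
  expect_equal(diag(fm), c(P1 = 0, P2 = 0, P3 = 0))
  expect_lt(fm["P1", "P2"], fm["P1", "P3"])
  expect_lt(fm["P2", "P3"], fm["P1", "P3"])
})

test_that("AMOVA handles degenerate inputs per contract", {
  g_same <- matrix(1L, nrow = 8, ncol = 5)
  coh <- matrix_cohort(g_same, subpopulation = rep(c("A", "B"), each = 4))
  res <- amova(coh)
  # all individuals identical: zero heterozygote variance aside, the
  # among-strata sums of squares vanish
  expect_equal(res$table$ss[1], 0)
  expect_equal(res$table$ss[2], 0)

  one_pop <- matrix_cohort(random_genotypes(6, rep(0.4, 10)),
                           subpopulation = rep("A", 6))
  expect_error(amova(one_pop), "at least 2 populations")

  g_const <- matrix(0L, nrow = 6, ncol = 4)
  coh_const <- matrix_cohort(g_const, subpopulation = rep(c("A", "B"), 3))
  res_const <- amova(coh_const)
  expect_true(is.na(res_const$fst))
})

test_that("AMOVA Fst tracks the Weir-Cockerham ratio-of-sums on simulations", {
  anc <- simulate_ancestral_frequencies(2000, 4, 0.05, seed = 98)
  sim <- simulate_cohort(anc, design_discrete(rep(50, 4)), seed = 99)
  coh <- sim$cohort
  coh$samples$subpopulation <- coh$samples$population
  res <- amova(coh)
  expect_equal(sum(res$table$percentage), 100, tolerance = 1e-6)
  # df accumulate over loci: (n_pops - 1) per locus with data in >= 2 pops
  expect_equal(res$table$df[1], 3 * 2000)
  expect_gt(res$fst, 0)

  # cross-estimator consistency: AMOVA Fst ~ WC theta (ratio of sums)
  thetas <- c(mean_fst(coh, "POP1", "POP2")$theta_wc,
              mean_fst(coh, "POP1", "POP3")$theta_wc,
              mean_fst(coh, "POP2", "POP4")$theta_wc)
  expect_lt(abs(res$fst - mean(thetas)), 0.015)
})

test_that("variance percentages and fixation index follow the component shares", {
  # published three-component worked example
  vp <- variance_percentages(c(86.21332, 980.57196, 34266.7071))
  expect_equal(vp$percentages, c(0.24400, 2.77519, 96.98081), tolerance = 1e-5)
  expect_equal(vp$fst, 0.00244, tolerance = 1e-3)

  expect_equal(variance_percentages(c(0, 0, 7))$percentages, c(0, 0, 100))
  expect_equal(variance_percentages(c(0, 0, 7))$fst, 0)
  expect_equal(variance_percentages(c(2, 2, 2))$percentages,
               rep(100 / 3, 3), tolerance = 1e-12)
  # negative components are truncated for reporting
  expect_equal(variance_percentages(c(-1, 0, 3))$percentages, c(0, 0, 100))
  expect_error(variance_percentages(c(0, 0, 0)), "zero")
})

test_that("Slatkin distance linearizes and inverts the fixation index", {
  expect_equal(slatkin_distance(0), 0)
  expect_equal(slatkin_distance(0.5), 1)
  expect_equal(slatkin_distance(0.00244), 0.0024460, tolerance = 1e-4)
  fst <- c(0.01, 0.1, 0.3)
  d <- slatkin_distance(fst)
  expect_equal(d / (1 + d), fst, tolerance = 1e-12)
  expect_true(all(diff(d) > 0))
  expect_error(slatkin_distance(1), "fst = 1")
})
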