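fit_fixture <- function(q, ids = sprintf("S%03d", seq_len(nrow(q)))) {
  pops <- colnames(q)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids),
    tibble::as_tibble(as.data.frame(q)),
    tibble::tibble(loglik = 0, iterations = 1L, converged = TRUE)
  )
  structure(tab, class = c("admixture_fit", class(tibble::tibble())),
            pops = pops)
}

pca_fixture <- function(n, seed = 1) {
  set.seed(seed)
  coords <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC2")))
  structure(list(ids = sprintf("S%03d", 1:n), coords = coords,
                 eigenvalues = c(2, 1)),
            class = "pca_result")
}

test_that("pie glyph scene encodes ancestry fractions as arc angles", {
  q <- rbind(c(0.5, 0.3, 0.2))
  colnames(q) <- c("A", "B", "C")
  fit <- fit_fixture(q, ids = "S001")
  pca <- pca_fixture(1)
  scene <- admixture_pca_scene(pca, fit, radius = 0.1)
  arcs <- attr(scene, "arcs")
  # arc spans in degrees: (180, 108, 72)
  expect_equal(360 * (arcs$frac_end - arcs$frac_start), c(180, 108, 72),
               ignore_attr = TRUE)
  expect_equal(arcs$frac, c(0.5, 0.3, 0.2), ignore_attr = TRUE)
  # all vertices lie within radius of the center
  expect_lte(max(sqrt((scene$x - pca$coords[1, 1])^2 +
                        (scene$y - pca$coords[1, 2])^2)), 0.1 + 1e-9)

  # single-component sample: one full disc
  q1 <- rbind(c(1, 0)); colnames(q1) <- c("A", "B")
  scene1 <- admixture_pca_scene(pca_fixture(1), fit_fixture(q1, "S001"), 0.1)
  expect_equal(unique(scene1$population), "A")
  arcs1 <- attr(scene1, "arcs")
  expect_equal(arcs1$frac_end[1] - arcs1$frac_start[1], 1, ignore_attr = TRUE)
})

test_that("admixture PCA plot draws one glyph per fitted sample", {
  set.seed(5)
  q <- rdirichlet_test(7, c(1, 1, 1))
  colnames(q) <- c("A", "B", "C")
  fit <- fit_fixture(q)
  pca <- pca_fixture(10)
  ctx <- setNames(c("A", "B"), c("S009", "S010"))
  p <- plot_admixture_pca(pca, fit, context_labels = ctx)
  scene <- attr(p, "scene")
  expect_equal(length(unique(scene$sample_id)), 7)
  expect_s3_class(p, "ggplot")
  # per-sample fractions in the scene sum to 1
  arcs <- attr(scene, "arcs")
  sums <- tapply(arcs$frac, arcs$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, 7), tolerance = 1e-6)

  # a sample with proportions but no coordinates errors
  fit_bad <- fit_fixture(q, ids = c(sprintf("S%03d", 1:6), "GHOST"))
  expect_error(plot_admixture_pca(pca, fit_bad), "no PCA coordinates")
})

test_that("bar plot order equals dendrogram leaf order and bars stack to 1", {
  set.seed(6)
  q <- rdirichlet_test(6, c(2, 1))
  colnames(q) <- c("A", "B")
  fit <- fit_fixture(q)
  d <- as.matrix(dist(q))
  dimnames(d) <- list(fit$sample_id, fit$sample_id)
  h <- upgma(d)
  p <- plot_admixture_bars(h, fit)
  scene <- attr(p, "scene")
  expect_equal(levels(scene$sample_id), leaf_order(h))
  heights <- tapply(scene$proportion, scene$sample_id, sum)
  expect_equal(as.numeric(heights), rep(1, 6), tolerance = 1e-9)

  h_extra <- upgma(d[1:5, 1:5])
  expect_error(plot_admixture_bars(h_extra, fit[1:4, ]), "without ancestry")
})

test_that("argmax-ancestry groups are contiguous along the dendrogram order", {
  anc <- simulate_ancestral_frequencies(1000, 3, 0.3, seed = 7)
  sim <- simulate_cohort(anc, design_discrete(c(15, 15, 15)), seed = 8)
  model <- admixture_model(anc$freqs, variant_keys(sim$cohort))
  fit <- fit_admixture(sim$cohort, model, autosomes_only = FALSE)
  d <- ibs_distance_matrix(sim$cohort)
  h <- upgma(d)
  ord <- leaf_order(h)
  amax <- attr(fit, "pops")[max.col(proportions_matrix(fit))]
  names(amax) <- fit$sample_id
  runs <- rle(unname(amax[ord]))
  # 3 discrete clusters: at most a stray sample or two breaks contiguity
  expect_lte(length(runs$lengths), 5)
})

test_that("distance heatmap is ordered, symmetric, with data-range colorbar", {
  pd <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.3, 0.4, 0.3, 0), 3, 3,
               dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  p <- plot_distance_heatmap(pd)
  scene <- attr(p, "scene")
  expect_equal(levels(scene$row), leaf_order(upgma(pd)))
  # every rendered cell carries the matrix value, symmetrically
  expect_equal(scene$distance,
               pd[cbind(as.character(scene$row), as.character(scene$col))],
               ignore_attr = TRUE)
  expect_equal(scene$distance,
               pd[cbind(as.character(scene$col), as.character(scene$row))],
               ignore_attr = TRUE)
  expect_equal(p$scales$scales[[1]]$limits, range(pd))
})

test_that("chromosome histogram scene conserves totals per chromosome", {
  dens <- tibble::tibble(chrom = c("1", "1", "2"),
                         bin_start = c(1, 1e6 + 1, 1),
                         n = c(5L, 3L, 2L))
  p <- plot_chromosome_density(dens, 1e6)
  scene <- attr(p, "scene")
  expect_equal(sum(scene$n), 10)
  expect_equal(sum(scene$n[scene$chrom == "1"]), 8)
  expect_s3_class(p, "ggplot")
})

test_that("tidiers return tibbles with the documented shapes", {
  anc <- simulate_ancestral_frequencies(300, 2, 0.2, seed = 9)
  sim <- simulate_cohort(anc, design_discrete(c(10, 10)), seed = 10)
  full <- sim$cohort
  sim$cohort <- filter_maf(full, 0.01)
  pca <- run_pca(sim$cohort, n_components = 5)
  td <- tidy(pca)
  expect_named(td, c("sample_id", paste0("PC", 1:5)))
  expect_equal(nrow(td), 20)
  expect_equal(glance(pca)$n_components, 5)

  kept <- match(variant_keys(sim$cohort), variant_keys(full))
  model <- admixture_model(anc$freqs[, kept], variant_keys(sim$cohort))
  fit <- fit_admixture(sim$cohort, model, autosomes_only = FALSE)
  expect_named(tidy(fit), c("sample_id", "population", "proportion"))
  expect_true(glance(fit)$all_converged)

  coh <- sim$cohort
  coh$samples$subpopulation <- coh$samples$population
  am <- amova(coh)
  expect_equal(nrow(tidy(am)), 3)
  expect_equal(glance(am)$slatkin, slatkin_distance(am$fst))

  fst <- mean_fst(coh, "POP1", "POP2")
  expect_named(glance(fst),
               c("pop_a", "pop_b", "theta_mean", "theta_wc", "n_loci",
                 "n_undefined"))

  d <- ibs_distance_matrix(coh)
  labels <- setNames(coh$samples$population, coh$samples$id)
  div <- resampled_diversity(d, labels, "POP1", n_per_pop = 8, n_reps = 5,
                             seed = 11)
  expect_equal(tidy(div), div$summary)
  expect_s3_class(autoplot(div), "ggplot")
  expect_s3_class(autoplot(pca, labels = labels), "ggplot")
})
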