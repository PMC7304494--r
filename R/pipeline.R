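#' End-to-end pipeline on a simulated cohort
#'
#' Drives every stage of the package on a self-generated synthetic cohort
#' and writes all tables, trees and figures to a directory, together with a
#' JSON manifest (parameters, seed, output file hashes). Two runs with the
#' same configuration and seed produce identical manifests.
#'
#' Stages: simulate (ancestral frequencies, admixed cohort, reference
#' frequency panels) -> QC (missingness, MAF, HWE, LD pruning) -> allele
#' frequencies -> IBS distances -> PCA -> supervised admixture -> UPGMA +
#' neighbor joining -> resampled diversity report -> pairwise FST -> AMOVA
#' -> Z-score screen -> plots.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing every random stage.
#' @param n_samples total study samples (split over `n_pops` Dirichlet
#'   clusters plus a gradient tail; default 500).
#' @param n_loci simulated loci (default 2000).
#' @param n_pops ancestral populations (default 3).
#' @param fst_param Balding-Nichols divergence of the ancestral populations.
#' @param missing_rate genotype missingness rate.
#' @param qc,diversity,zscreen_opts named lists overriding stage parameters:
#'   `qc` (max_missing_rate, min_maf, hwe_alpha, window_size, step,
#'   r2_threshold), `diversity` (n_per_pop, n_reps, exclude),
#'   `zscreen_opts` (threshold, n_panels, jitter_sd, n_divergent, delta).
#' @param make_plots write PDF figures (default `TRUE`).
#' @return invisibly, a list of the main in-memory results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_samples = 500, n_loci = 2000,
                         n_pops = 3, fst_param = 0.1, missing_rate = 0.005,
                         qc = list(), diversity = list(),
                         zscreen_opts = list(), make_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  qc <- utils::modifyList(list(max_missing_rate = 0.01, min_maf = 0.01,
                               hwe_alpha = 0.001, window_size = 1000,
                               step = 10, r2_threshold = 0.4), qc)
  diversity <- utils::modifyList(list(n_per_pop = 100, n_reps = 100,
                                      exclude = character()), diversity)
  zs <- utils::modifyList(list(threshold = 4, n_panels = 6, jitter_sd = 0.02,
                               n_divergent = 25, delta = 0.12), zscreen_opts)
  path <- function(f) file.path(out_dir, f)

  # --- simulate -------------------------------------------------------------
  sizes <- rep(n_samples %/% n_pops, n_pops)
  sizes[1] <- sizes[1] + n_samples %% n_pops
  anc <- simulate_ancestral_frequencies(n_loci, n_pops, fst_param, seed = seed)
  sim <- simulate_cohort(anc, design_discrete(sizes, n_subpops = n_pops),
                         missing_rate = missing_rate, seed = seed + 1L)
  coh <- sim$cohort
  write_truth_tsv(sim$truth, path("truth_proportions.tsv"))
  write_genotype_table(coh, path("genotypes.tsv"))

  # --- qc -------------------------------------------------------------------
  qc_run <- run_qc(coh, qc$max_missing_rate, qc$min_maf, qc$hwe_alpha,
                   qc$window_size, qc$step, qc$r2_threshold)
  coh_qc <- qc_run$cohort
  readr::write_tsv(qc_run$report, path("qc_report.tsv"), progress = FALSE)

  # --- frequencies ----------------------------------------------------------
  freqs <- allele_freqs(coh_qc)
  readr::write_tsv(freqs, path("allele_freqs.tsv"), progress = FALSE)

  # --- distances, trees -----------------------------------------------------
  d <- ibs_distance_matrix(coh_qc)
  write_distance_tsv(d, path("ibs_distance.tsv"))
  dend <- upgma(d)
  write_newick(dend, path("upgma.nwk"))
  nj_tree <- neighbor_joining(d)
  write_newick(nj_tree, path("nj.nwk"))

  # --- pca, admixture -------------------------------------------------------
  pca <- run_pca(coh_qc, n_components = min(20, n_samples(coh_qc)))
  readr::write_tsv(tidy(pca), path("pca_coords.tsv"), progress = FALSE)
  model <- estimate_panel_frequencies(coh_qc)
  fit <- fit_admixture(coh_qc, model)
  write_admixture_tsv(fit, path("admixture_q.tsv"))

  # --- diversity ------------------------------------------------------------
  labels <- stats::setNames(coh_qc$samples$population, coh_qc$samples$id)
  focal <- coh_qc$samples$population[1]
  report <- resampled_diversity(d, labels, focal,
                                n_per_pop = diversity$n_per_pop,
                                n_reps = diversity$n_reps,
                                exclude = diversity$exclude,
                                seed = seed + 2L)
  write_diversity_tsv(report, path("diversity_report.tsv"))
  pop_d <- population_distance_matrix(d, labels)
  write_distance_tsv(pop_d, path("population_distance.tsv"))

  # --- fst, amova -----------------------------------------------------------
  fst_m <- pairwise_fst_matrix(coh_qc)
  write_distance_tsv(fst_m, path("fst_matrix.tsv"))
  am <- amova(coh_qc, label_col = "subpopulation")
  readr::write_tsv(tidy(am), path("amova.tsv"), progress = FALSE)

  # --- zscreen --------------------------------------------------------------
  set.seed(seed + 3L)
  div_idx <- sample(which(freqs$freq > 0.2 & freqs$freq < 0.8),
                    min(zs$n_divergent, sum(freqs$freq > 0.2 & freqs$freq < 0.8)))
  divergence <- dplyr::mutate(freqs[div_idx, c("chrom", "pos", "ref", "alt")],
                              delta = zs$delta)
  panels <- simulate_reference_panels(freqs, n_panels = zs$n_panels,
                                      divergence = divergence,
                                      jitter_sd = zs$jitter_sd,
                                      seed = seed + 4L)
  screen <- zscreen(panels$table, threshold = zs$threshold)
  readr::write_tsv(zscreen_summary(screen), path("zscreen_summary.tsv"),
                   progress = FALSE)
  write_frequency_vcf(screen, path("zscreen.vcf"))
  dens <- chromosome_density(screen, bin_size_bp = 1e5)
  readr::write_tsv(dens, path("chromosome_density.tsv"), progress = FALSE)

  # --- plots ----------------------------------------------------------------
  if (make_plots) {
    save_pdf <- function(p, f, width = 8, height = 6) {
      grDevices::pdf(path(f), width = width, height = height)
      print(p)
      grDevices::dev.off()
    }
    save_pdf(plot_admixture_pca(pca, fit), "admixture_pca.pdf")
    save_pdf(plot_admixture_bars(dend, fit), "admixture_bars.pdf", width = 10)
    save_pdf(plot_distance_heatmap(pop_d), "population_heatmap.pdf")
    if (nrow(dens) > 0) {
      save_pdf(plot_chromosome_density(dens, 1e5), "chromosome_density.pdf",
               width = 10, height = 8)
    }
  }

  # --- manifest -------------------------------------------------------------
  # PDFs embed creation timestamps, so only data artifacts are hashed
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  outputs <- outputs[!grepl("\\.pdf$", outputs)]
  manifest <- list(
    seed = seed,
    parameters = list(n_samples = n_samples, n_loci = n_loci, n_pops = n_pops,
                      fst_param = fst_param, missing_rate = missing_rate,
                      qc = qc, diversity = diversity, zscreen = zs),
    n_variants_post_qc = n_variants(coh_qc),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  )
  manifest_path <- path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = coh_qc, qc_report = qc_run$report, distance = d,
                 pca = pca, admixture = fit, diversity = report,
                 fst_matrix = fst_m, amova = am, zscreen = screen,
                 manifest_path = manifest_path))
}
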