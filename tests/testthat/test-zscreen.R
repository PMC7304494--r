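freq_tab <- function(pos, freq, chrom = "1", ref = "A", alt = "G") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 freq = freq)
}

test_that("frequency-table join is an inner join with conservation accounting", {
  study <- freq_tab(1:5 * 100, seq(0.1, 0.5, 0.1))
  refs <- list(R1 = freq_tab(1:5 * 100, rep(0.2, 5)),
               R2 = freq_tab(1:5 * 100, rep(0.3, 5)))
  j <- join_frequency_tables(study, refs)
  expect_equal(nrow(j), 5)
  expect_named(j, c("chrom", "pos", "ref", "alt", "study_freq", "R1", "R2"))

  # mismatched alt at one locus drops it; retained + dropped = study rows
  refs_bad <- refs
  refs_bad$R2$alt[3] <- "T"
  expect_message(j2 <- join_frequency_tables(study, refs_bad), "dropped")
  expect_equal(nrow(j2), 4)
  expect_equal(nrow(j2) + attr(j2, "n_dropped"), nrow(study))

  dup <- dplyr::bind_rows(study, study[1, ])
  expect_error(join_frequency_tables(dup, refs), "duplicate")
})

test_that("Z-score follows the sample-SD definition with a floor", {
  # refs (0.1, 0.2, 0.3): mean 0.2, sample SD 0.1; study 0.6 -> Z = 4
  expect_equal(zscore(0.6, c(0.1, 0.2, 0.3)), 4)
  expect_equal(zscore(0.2, c(0.1, 0.2, 0.3)), 0)
  expect_true(is.na(zscore(0.5, c(0.2, 0.2, 0.2))))
  expect_error(zscore(0.5, c(0.1, 0.2)), ">= 3 reference")
  # vectorized over loci
  refs <- rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(zscore(c(0.6, 0.5), refs), c(4, 0))
})

test_that("Z-score p-values match the two-sided normal tail", {
  expect_equal(zscore_pvalue(4), 6.3e-5, tolerance = 1e-2)
  expect_equal(signif(zscore_pvalue(4), 2), 6.3e-5)
  expect_equal(zscore_pvalue(0), 1)
  expect_equal(zscore_pvalue(1.959964), 0.05, tolerance = 1e-4)
  expect_equal(zscore_pvalue(-3), zscore_pvalue(3))
})

test_that("screen flags partition loci and recover injected divergence", {
  set.seed(101)
  m <- 5000
  study <- freq_tab(1:m * 100, runif(m, 0.2, 0.8),
                    chrom = rep(as.character(1:10), length.out = m))
  sigma <- 0.02
  n_inject <- 50
  inject_idx <- sample(m, n_inject)
  div <- dplyr::mutate(study[inject_idx, c("chrom", "pos", "ref", "alt")],
                       delta = 6 * sigma)
  panels <- simulate_reference_panels(study, n_panels = 8, divergence = div,
                                      jitter_sd = sigma, seed = 102)
  screen <- zscreen(panels$table, threshold = 4)

  summ <- zscreen_summary(screen)
  n_of <- function(cl) summ$n[summ$class == cl]
  expect_equal(n_of("flagged"), n_of("low") + n_of("high"))
  expect_equal(sum(summ$n[summ$class %in% c("flagged", "null", "uninformative")]),
               nrow(screen))

  # sensitivity on injected loci (expected Z ~ 6)
  keys <- paste(screen$chrom, screen$pos, sep = ":")
  inj_keys <- paste(div$chrom, div$pos, sep = ":")
  hit <- screen$flag[keys %in% inj_keys]
  expect_gte(mean(hit == "high"), 0.9)

  # null loci flagged at about the two-sided normal tail rate
  null_flags <- screen$flag[!keys %in% inj_keys]
  p_tail <- 2 * pnorm(-4)
  # the sample SD over 8 panels fattens the tail relative to the ideal
  # normal rate; bound the false-positive fraction loosely instead
  expect_lt(mean(null_flags != "null"), 0.01)

  # threshold at infinity flags nothing
  screen_inf <- zscreen(panels$table, threshold = Inf)
  expect_equal(zscreen_summary(screen_inf)$n[3], 0)
})

test_that("effect tabulation cross-classifies flags with conservation", {
  tab <- tibble::tibble(
    chrom = "1", pos = 1:6 * 100L, ref = "A", alt = "G",
    study_freq = c(0.9, 0.9, 0.05, 0.5, 0.5, 0.5),
    R1 = c(0.2, 0.2, 0.5, 0.5, 0.5, 0.5),
    R2 = c(0.25, 0.25, 0.55, 0.45, 0.55, 0.45),
    R3 = c(0.3, 0.3, 0.6, 0.55, 0.45, 0.55)
  )
  screen <- zscreen(tab, threshold = 4)
  expect_equal(screen$flag[1:3], c("high", "high", "low"))
  ann <- tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L), ref = "A",
                        alt = "G",
                        effect = c("Non-synonymous coding", "Intron", "Intron"))
  eff <- tabulate_effects(screen, ann)
  flagged_row <- eff[eff$class == "flagged", ]
  expect_equal(flagged_row$total, 3)
  expect_equal(flagged_row$`Non-synonymous coding`, 1)
  expect_equal(flagged_row$Intron, 2)
  # row sums over categories equal the class totals
  cat_cols <- setdiff(names(eff), c("class", "total"))
  expect_equal(rowSums(eff[, cat_cols]), eff$total, ignore_attr = TRUE)

  empty <- zscreen(tab[0, ], threshold = 4, ref_cols = c("R1", "R2", "R3"))
  eff0 <- tabulate_effects(empty, ann)
  expect_equal(eff0$total, c(0, 0, 0))
})

test_that("chromosome density bins conserve flagged totals", {
  tab <- tibble::tibble(
    chrom = c("1", "1", "2"), pos = c(150L, 999999L, 5L), ref = "A", alt = "G",
    study_freq = c(0.9, 0.9, 0.9),
    R1 = 0.2, R2 = 0.25, R3 = 0.3
  )
  screen <- zscreen(tab, threshold = 4)
  dens <- chromosome_density(screen, bin_size_bp = 1e6)
  expect_equal(sum(dens$n), 3)
  expect_equal(dens$n[dens$chrom == "1"], 2)  # both chrom-1 loci in bin [1, 1e6)
  expect_equal(dens$bin_start[dens$chrom == "2"], 1)

  # uniform positions give a roughly flat histogram
  set.seed(103)
  m <- 2000
  tab_u <- tibble::tibble(chrom = "7", pos = sample.int(1e7, m), ref = "A",
                          alt = "G", study_freq = 0.95,
                          R1 = 0.2, R2 = 0.25, R3 = 0.3)
  dens_u <- chromosome_density(zscreen(tab_u, threshold = 4), bin_size_bp = 1e6)
  expect_equal(sum(dens_u$n), m)
  chisq <- sum((dens_u$n - m / 10)^2 / (m / 10))
  expect_lt(chisq, qchisq(0.999, df = 9))
})

test_that("frequency VCF round trip preserves the screen table", {
  tab <- tibble::tibble(
    chrom = c("1", "2"), pos = c(100L, 200L), ref = c("A", "C"),
    alt = c("G", "T"), study_freq = c(0.912345, 0.05),
    GNOMAD_AFR = c(0.21, 0.5), GNOMAD_NFE = c(0.25, 0.45), GME = c(0.3, 0.55)
  )
  screen <- zscreen(tab, threshold = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_frequency_vcf(screen, path)
  lines <- readLines(path)
  expect_true(any(grepl("##INFO=<ID=ZSCORE", lines, fixed = TRUE)))
  expect_true(any(grepl("##INFO=<ID=AF_GME", lines, fixed = TRUE)))
  expect_equal(lines[1], "##fileformat=VCFv4.2")

  back <- read_frequency_vcf(path)
  expect_equal(back$study_freq, tab$study_freq, tolerance = 1e-5)
  expect_equal(back$GME, tab$GME, tolerance = 1e-5)
  expect_equal(back$z, screen$z, tolerance = 1e-4)
  expect_equal(back$flag, screen$flag)
})
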