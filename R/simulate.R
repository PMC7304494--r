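#' Simulate diverged ancestral allele frequencies (Balding-Nichols model)
#'
#' Draws a common-pool frequency per locus, then diverges each of `n_pops`
#' populations from it under the Balding-Nichols model: population frequency
#' ~ Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p (1-p).
#' `fst_param` is therefore the expected FST between any two populations and
#' gives a closed-form target for recovery tests of downstream estimators.
#'
#' @param n_loci number of loci M (>= 1).
#' @param n_pops number of ancestral populations K (>= 1).
#' @param fst_param divergence parameter F in (0, 1).
#' @param base_freq_range range for the uniform common-pool frequency draw;
#'   kept away from 0/1 so loci are informative.
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and the seed.
#' @return an object of class `ancestral_freqs`: `pop_names`, `freqs`
#'   (K x M matrix, clamped to `[1e-6, 1 - 1e-6]`), `base_freqs` (length M),
#'   `fst_param`.
#' @export
simulate_ancestral_frequencies <- function(n_loci, n_pops, fst_param,
                                           base_freq_range = c(0.05, 0.95),
                                           seed = 1L) {
  stopifnot(n_loci >= 1, n_pops >= 1)
  if (!(fst_param > 0 && fst_param < 1)) stop("fst_param must be in (0,1)", call. = FALSE)
  if (base_freq_range[1] <= 0 || base_freq_range[2] >= 1 ||
      base_freq_range[1] > base_freq_range[2]) {
    stop("base_freq_range must be within (0,1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- stats::runif(n_loci, base_freq_range[1], base_freq_range[2])
  lambda <- (1 - fst_param) / fst_param
  freqs <- matrix(
    stats::rbeta(n_pops * n_loci,
                 shape1 = rep(p * lambda, each = n_pops),
                 shape2 = rep((1 - p) * lambda, each = n_pops)),
    nrow = n_pops, ncol = n_loci
  )
  freqs <- clamp_freq(freqs)
  pop_names <- paste0("POP", seq_len(n_pops))
  rownames(freqs) <- pop_names
  structure(
    list(pop_names = pop_names, freqs = freqs, base_freqs = p,
         fst_param = fst_param),
    class = "ancestral_freqs"
  )
}

clamp_freq <- function(f, lo = 1e-6) pmin(pmax(f, lo), 1 - lo)

#' Cohort design specifications
#'
#' Three ancestry designs for [simulate_cohort()]:
#' * `design_discrete()`: each sample belongs 100% to one ancestral
#'   population (`sizes` is a named or unnamed vector of per-population
#'   counts).
#' * `design_dirichlet()`: each sample's ancestry vector q is an independent
#'   Dirichlet(alpha) draw — an admixed cohort without spatial structure.
#' * `design_gradient()`: q interpolates linearly between two vertex
#'   populations along the sample index, emulating a continuous admixture
#'   gradient between two ancestries.
#'
#' @param sizes integer vector of samples per population (discrete design).
#' @param n number of samples.
#' @param alpha Dirichlet concentration vector, length K.
#' @param from,to 1-based indices of the two vertex populations.
#' @param n_subpops number of subpopulation/birthplace labels to assign
#'   (round-robin); 0 for none.
#' @return a design object consumed by [simulate_cohort()].
#' @name cohort_designs
NULL

#' @rdname cohort_designs
#' @export
design_discrete <- function(sizes, n_subpops = 0L) {
  stopifnot(all(sizes >= 1))
  structure(list(type = "discrete", sizes = sizes, n_subpops = n_subpops),
            class = "cohort_design")
}

#' @rdname cohort_designs
#' @export
design_dirichlet <- function(n, alpha, n_subpops = 0L) {
  stopifnot(n >= 1, all(alpha > 0))
  structure(list(type = "dirichlet", n = n, alpha = alpha, n_subpops = n_subpops),
            class = "cohort_design")
}

#' @rdname cohort_designs
#' @export
design_gradient <- function(n, from = 1L, to = 2L, n_subpops = 0L) {
  stopifnot(n >= 1, from != to)
  structure(list(type = "gradient", n = n, from = from, to = to,
                 n_subpops = n_subpops),
            class = "cohort_design")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

design_proportions <- function(design, n_pops) {
  switch(design$type,
    discrete = {
      if (length(design$sizes) != n_pops) {
        stop("design sizes length != number of ancestral populations", call. = FALSE)
      }
      q <- matrix(0, nrow = sum(design$sizes), ncol = n_pops)
      pop_idx <- rep(seq_len(n_pops), design$sizes)
      q[cbind(seq_len(nrow(q)), pop_idx)] <- 1
      q
    },
    dirichlet = {
      if (length(design$alpha) != n_pops) {
        stop("alpha length != number of ancestral populations", call. = FALSE)
      }
      rdirichlet(design$n, design$alpha)
    },
    gradient = {
      if (design$from > n_pops || design$to > n_pops) {
        stop("gradient vertex index exceeds number of populations", call. = FALSE)
      }
      q <- matrix(0, nrow = design$n, ncol = n_pops)
      w <- if (design$n == 1) 0.5 else seq(0, 1, length.out = design$n)
      q[, design$from] <- 1 - w
      q[, design$to] <- w
      q
    },
    stop("unknown design type", call. = FALSE)
  )
}

#' Simulate a genotyped cohort with known admixture ground truth
#'
#' Given ancestral allele frequencies and a design, draws each genotype as
#' Binomial(2, sum_k q_ik f_km) — the standard admixture likelihood — and
#' inserts missing genotypes i.i.d. at `missing_rate`. The returned truth
#' record holds every sample's true ancestry vector, so estimator recovery
#' is directly checkable.
#'
#' @param anc an `ancestral_freqs` object.
#' @param design a design from [design_discrete()], [design_dirichlet()] or
#'   [design_gradient()].
#' @param missing_rate probability in `[0, 1)` that an entry is missing.
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample ids.
#' @param population_labels optional per-sample population label override;
#'   defaults to the argmax ancestral component for discrete designs and
#'   `"ADMIXED"` otherwise.
#' @return list with elements `cohort` (a [cohort()]) and `truth` (class
#'   `sim_truth`): `proportions` tibble (`sample_id`, `q_<pop>` columns),
#'   `seed`, `params`.
#' @export
simulate_cohort <- function(anc, design, missing_rate = 0, seed = 1L,
                            sample_prefix = "S", population_labels = NULL) {
  stopifnot(inherits(anc, "ancestral_freqs"), inherits(design, "cohort_design"))
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- nrow(anc$freqs)
  m <- ncol(anc$freqs)
  q <- design_proportions(design, k)
  n <- nrow(q)
  dose <- q %*% anc$freqs                       # n x m expected alt frequency
  g <- matrix(stats::rbinom(n * m, size = 2L, prob = dose), nrow = n, ncol = m)
  if (missing_rate > 0) {
    g[stats::runif(n * m) < missing_rate] <- NA_integer_
  }
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n))
  if (is.null(population_labels)) {
    population_labels <- if (design$type == "discrete") {
      anc$pop_names[max.col(q)]
    } else rep("ADMIXED", n)
  }
  subpop <- rep(NA_character_, n)
  if (design$n_subpops > 0) {
    subpop <- paste0("SUBPOP", rep_len(seq_len(design$n_subpops), n))
  }
  variants <- sim_variant_table(m, seed = seed)
  coh <- cohort(
    g,
    tibble::tibble(id = ids, population = population_labels,
                   subpopulation = subpop, panel = "study"),
    variants
  )
  props <- tibble::as_tibble(as.data.frame(q))
  names(props) <- paste0("q_", anc$pop_names)
  props <- dplyr::bind_cols(tibble::tibble(sample_id = ids), props)
  truth <- structure(
    list(proportions = props, seed = as.integer(seed),
         params = list(design = design$type, missing_rate = missing_rate,
                       fst_param = anc$fst_param)),
    class = "sim_truth"
  )
  list(cohort = coh, truth = truth)
}

# Deterministic variant table: loci in contiguous blocks over 22 autosomes
# (sorted by chromosome then position), alternating allele pairs.
sim_variant_table <- function(m, seed = 1L) {
  chrom <- as.character(sort(rep_len(1:22, m)))
  idx <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  pos <- idx * 1000L
  bases <- c("A", "C", "G", "T")
  ref <- bases[rep_len(c(1L, 2L, 3L, 4L), m)]
  alt <- bases[rep_len(c(3L, 4L, 1L, 2L), m)]
  tibble::tibble(chrom = chrom, pos = pos,
                 id = sprintf("rs%06d", seq_len(m)), ref = ref, alt = alt)
}

#' Simulate reference allele-frequency panels with injected divergent loci
#'
#' Emulates the multi-panel reference columns of the Z-score screen: each
#' reference panel's frequency is the consensus (the supplied study
#' frequency) plus Gaussian jitter of SD `jitter_sd`, clamped to `[0, 1]`;
#' the study column itself is shifted by `delta` at the loci named in
#' `divergence`, so those loci are true positives with expected
#' Z ~ delta / jitter_sd.
#'
#' @param study_freqs tibble with `chrom`, `pos`, `ref`, `alt`, `freq`
#'   (the study cohort's allele frequencies, e.g. from [allele_freqs()]).
#' @param n_panels number of reference panels (>= 3; the screen's sample SD
#'   needs at least three values).
#' @param divergence tibble with `chrom`, `pos`, `ref`, `alt`, `delta`
#'   naming loci whose study frequency is shifted by `delta`; may be empty.
#' @param jitter_sd SD of the reference-panel jitter around the consensus.
#' @param study_jitter_sd SD of Gaussian jitter applied to the study column
#'   itself (default 0: the study column is the exact consensus plus any
#'   injected `delta`, so injected loci have expected Z = delta / jitter_sd;
#'   set it equal to `jitter_sd` to emulate a study cohort drawn from the
#'   same noise process as the panels, under which the null Z is standard
#'   normal up to the sample-SD correction).
#' @param seed integer seed.
#' @param panel_names optional panel column names; default `REF1..REFP`.
#' @return list with `table` (tibble: key columns, `study_freq`, one column
#'   per panel) and `truth` (tibble of flagged loci with their `delta`).
#' @export
simulate_reference_panels <- function(study_freqs, n_panels = 6L,
                                      divergence = NULL, jitter_sd = 0.02,
                                      study_jitter_sd = 0, seed = 1L,
                                      panel_names = NULL) {
  if (n_panels < 3) stop("need at least 3 reference panels for a sample SD", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(panel_names)) panel_names <- paste0("REF", seq_len(n_panels))
  stopifnot(length(panel_names) == n_panels)
  m <- nrow(study_freqs)
  consensus <- study_freqs$freq
  out <- study_freqs[, c("chrom", "pos", "ref", "alt")]
  out$study_freq <- consensus
  if (study_jitter_sd > 0) {
    out$study_freq <- pmin(pmax(
      out$study_freq + stats::rnorm(m, 0, study_jitter_sd), 0), 1)
  }
  if (is.null(divergence)) {
    divergence <- tibble::tibble(chrom = character(), pos = integer(),
                                 ref = character(), alt = character(),
                                 delta = numeric())
  }
  if (nrow(divergence) > 0) {
    idx <- match(paste(divergence$chrom, divergence$pos, divergence$ref,
                       divergence$alt, sep = ":"),
                 variant_keys(out))
    if (anyNA(idx)) stop("divergence names loci absent from study_freqs", call. = FALSE)
    shifted <- out$study_freq[idx] + divergence$delta
    if (any(shifted < -1e-9 | shifted > 1 + 1e-9)) {
      stop("delta drives a study frequency outside [0, 1]", call. = FALSE)
    }
    out$study_freq[idx] <- pmin(pmax(shifted, 0), 1)
  }
  for (pn in panel_names) {
    out[[pn]] <- pmin(pmax(consensus + stats::rnorm(m, 0, jitter_sd), 0), 1)
  }
  list(table = tibble::as_tibble(out),
       truth = tibble::as_tibble(divergence))
}

#' Write simulation ground truth to TSV
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth$proportions, path)
  invisible(path)
}
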