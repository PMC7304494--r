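#' Population stratification statistics on a distance matrix
#'
#' Three statistics summarize how well a labeled population clusters in a
#' pairwise 1-IBS distance matrix:
#' * **heterogeneity** — the mean distance over all unordered pairs of
#'   members of one population (within-population diversity);
#' * **separation** — for a pair of populations, the mean distance over all
#'   cross-population pairs; for one population, the unweighted mean of its
#'   pairwise separations to every other (non-excluded) population;
#' * **compactness** — separation divided by heterogeneity. Values near 1
#'   mean the population is about as diverse internally as it is distant
#'   from others, i.e. weak stratification; values well above 1 mean a
#'   tight, well-separated cluster.
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param members character vector of member sample ids (>= 2).
#' @return scalar statistic.
#' @export
heterogeneity <- function(d, members) {
  idx <- match(members, rownames(d))
  if (anyNA(idx)) stop("member id absent from distance matrix", call. = FALSE)
  if (length(idx) < 2) stop("heterogeneity needs at least 2 members", call. = FALSE)
  sub <- d[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' @rdname heterogeneity
#' @param members_a,members_b disjoint member id vectors of two populations.
#' @export
separation_pair <- function(d, members_a, members_b) {
  ia <- match(members_a, rownames(d))
  ib <- match(members_b, rownames(d))
  if (anyNA(ia) || anyNA(ib)) stop("member id absent from distance matrix", call. = FALSE)
  if (length(ia) == 0 || length(ib) == 0) stop("empty population", call. = FALSE)
  if (length(intersect(ia, ib)) > 0) stop("populations must be disjoint", call. = FALSE)
  mean(d[ia, ib, drop = FALSE])
}

#' @rdname heterogeneity
#' @param pop focal population label.
#' @param membership named list mapping population label -> member ids.
#' @param exclude population labels omitted from the counterpart set (the
#'   unbiased-separation exclusion).
#' @export
separation <- function(d, pop, membership, exclude = character()) {
  others <- setdiff(names(membership), c(pop, exclude))
  if (length(others) == 0) stop("no counterpart populations remain", call. = FALSE)
  mean(vapply(others, function(o) {
    separation_pair(d, membership[[pop]], membership[[o]])
  }, numeric(1)))
}

#' @rdname heterogeneity
#' @param separation_value,heterogeneity_value the two statistics.
#' @export
compactness <- function(separation_value, heterogeneity_value) {
  if (any(heterogeneity_value <= 0)) stop("heterogeneity must be positive", call. = FALSE)
  separation_value / heterogeneity_value
}

membership_list <- function(labels, ids) {
  stopifnot(length(labels) == length(ids))
  keep <- !is.na(labels)
  split(ids[keep], labels[keep])
}

#' Resampled stratification report
#'
#' Down-samples every population to `n_per_pop` members (populations at or
#' below the cap are used in full), computes heterogeneity, separation and
#' compactness per population, and repeats `n_reps` times to estimate the
#' replicate variance. Each population's compactness replicates are then
#' compared to the focal population's by a two-sided Welch t-test; the focal
#' population against itself gives t = 0, p = 1 by construction.
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param labels per-sample population labels, aligned with `rownames(d)`
#'   or given as a named vector (names = sample ids). `NA` labels are
#'   ignored.
#' @param focal_pop the population against which all t-tests are run.
#' @param n_per_pop per-population subsample size per replicate (default 100).
#' @param n_reps number of replicates (default 100).
#' @param exclude populations omitted from every separation counterpart set
#'   and from the report.
#' @param seed integer seed; the whole report is deterministic given it.
#' @return an object of class `diversity_report`: `replicates` (tibble:
#'   `population`, `rep`, `heterogeneity`, `separation`, `compactness`),
#'   `summary` (tibble: per-population means/SDs, `t`, `p`), `params`.
#' @export
resampled_diversity <- function(d, labels, focal_pop, n_per_pop = 100,
                                n_reps = 100, exclude = character(),
                                seed = 1L) {
  ids <- rownames(d)
  if (!is.null(names(labels))) labels <- labels[ids]
  if (length(labels) != length(ids)) {
    stop("labels must align with the distance matrix ids", call. = FALSE)
  }
  membership <- membership_list(labels, ids)
  membership <- membership[setdiff(names(membership), exclude)]
  if (!focal_pop %in% names(membership)) {
    stop("focal population '", focal_pop, "' absent from labels", call. = FALSE)
  }
  if (any(lengths(membership) < 2)) {
    stop("every population needs at least 2 members", call. = FALSE)
  }
  pops <- names(membership)
  set.seed(as.integer(seed))
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sub <- lapply(membership, function(m) {
      if (length(m) <= n_per_pop) m else sample(m, n_per_pop)
    })
    purrr::map_dfr(pops, function(p) {
      het <- heterogeneity(d, sub[[p]])
      sep <- separation(d, p, sub)
      tibble::tibble(population = p, rep = r, heterogeneity = het,
                     separation = sep, compactness = compactness(sep, het))
    })
  })
  focal_c <- reps$compactness[reps$population == focal_pop]
  summ <- reps |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      compactness_mean = mean(.data$compactness),
      compactness_sd = stats::sd(.data$compactness),
      heterogeneity_mean = mean(.data$heterogeneity),
      heterogeneity_sd = stats::sd(.data$heterogeneity),
      separation_mean = mean(.data$separation),
      separation_sd = stats::sd(.data$separation),
      .groups = "drop"
    )
  tests <- purrr::map_dfr(summ$population, function(p) {
    xs <- reps$compactness[reps$population == p]
    if (p == focal_pop) {
      tibble::tibble(population = p, t = 0, p_value = 1)
    } else {
      tt <- welch_t(xs, focal_c)
      tibble::tibble(population = p, t = tt$t, p_value = tt$p)
    }
  })
  summ <- dplyr::left_join(summ, tests, by = "population")
  summ <- dplyr::arrange(summ, .data$compactness_mean)
  structure(
    list(replicates = reps, summary = summ,
         params = list(focal_pop = focal_pop, n_per_pop = n_per_pop,
                       n_reps = n_reps, exclude = exclude,
                       seed = as.integer(seed))),
    class = "diversity_report"
  )
}

# Two-sided Welch t-test that tolerates zero-variance replicate vectors
# (exhaustive subsamples make every replicate identical): equal means give
# t = 0, p = 1; unequal means with no variance give t = +/-Inf, p = 0.
welch_t <- function(x, y) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  delta <- mean(x) - mean(y)
  if (se2 <= .Machine$double.eps * max(1, abs(mean(x)), abs(mean(y)))) {
    if (abs(delta) <= .Machine$double.eps * max(1, abs(mean(x)))) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(delta) * Inf, p = 0))
  }
  t_stat <- delta / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df))
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> focal =", x$params$focal_pop,
      "| n_per_pop =", x$params$n_per_pop,
      "| n_reps =", x$params$n_reps, "\n")
  print(x$summary, ...)
  invisible(x)
}

#' Population-level separation distance matrix
#'
#' The pairwise separation values between populations form a new distance
#' matrix over populations, suitable for UPGMA clustering and heatmaps.
#'
#' @param d sample-level distance matrix.
#' @param labels per-sample population labels (aligned or named as in
#'   [resampled_diversity()]).
#' @return symmetric matrix over populations with zero diagonal.
#' @export
population_distance_matrix <- function(d, labels) {
  ids <- rownames(d)
  if (!is.null(names(labels))) labels <- labels[ids]
  membership <- membership_list(labels, ids)
  pops <- names(membership)
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- separation_pair(d, membership[[pops[i]]], membership[[pops[j]]])
      out[i, j] <- s
      out[j, i] <- s
    }
  }
  out
}

#' Write a diversity report summary as TSV
#'
#' Columns mirror the standard report layout: population, compactness mean
#' and SD, heterogeneity mean, separation mean, t, p.
#'
#' @param report a `diversity_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(report, path) {
  readr::write_tsv(report$summary, path, progress = FALSE)
  invisible(path)
}
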