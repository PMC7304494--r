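#' Tidiers for fitted result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns one row
#' per elementary unit of the result (sample x component, population,
#' stratum, locus), `glance()` a one-row model summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name popstructr-tidiers
NULL

#' @rdname popstructr-tidiers
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::as_tibble(x$coords) |>
    dplyr::mutate(sample_id = x$ids, .before = 1)
}

#' @rdname popstructr-tidiers
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$ids),
    n_components = ncol(x$coords),
    total_eigenvalue = sum(x$eigenvalues),
    pc1_share = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

#' @rdname popstructr-tidiers
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  pops <- attr(x, "pops")
  tibble::as_tibble(x)[, c("sample_id", pops)] |>
    tidyr::pivot_longer(dplyr::all_of(pops), names_to = "population",
                        values_to = "proportion")
}

#' @rdname popstructr-tidiers
#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_populations = length(attr(x, "pops")),
    mean_loglik = mean(x$loglik),
    mean_iterations = mean(x$iterations),
    all_converged = all(x$converged)
  )
}

#' @rdname popstructr-tidiers
#' @method tidy diversity_report
#' @export
tidy.diversity_report <- function(x, ...) {
  x$summary
}

#' @rdname popstructr-tidiers
#' @method glance diversity_report
#' @export
glance.diversity_report <- function(x, ...) {
  tibble::tibble(
    focal_pop = x$params$focal_pop,
    n_populations = nrow(x$summary),
    n_per_pop = x$params$n_per_pop,
    n_reps = x$params$n_reps,
    min_compactness = min(x$summary$compactness_mean),
    least_compact = x$summary$population[which.min(x$summary$compactness_mean)]
  )
}

#' @rdname popstructr-tidiers
#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) {
  x$per_locus
}

#' @rdname popstructr-tidiers
#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(
    pop_a = x$pops[1], pop_b = x$pops[2],
    theta_mean = x$theta_mean, theta_wc = x$theta_wc,
    n_loci = nrow(x$per_locus), n_undefined = x$n_undefined
  )
}

#' @rdname popstructr-tidiers
#' @method tidy amova_result
#' @export
tidy.amova_result <- function(x, ...) {
  x$table
}

#' @rdname popstructr-tidiers
#' @method glance amova_result
#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(
    fst = x$fst,
    slatkin = if (is.na(x$fst)) NA_real_ else slatkin_distance(x$fst),
    n_pops = x$n_pops
  )
}
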