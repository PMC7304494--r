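#' Pie-glyph scene for an admixture-informed PCA plot
#'
#' Builds the polygon data behind [plot_admixture_pca()]: one pie glyph per
#' study sample at its (PC1, PC2) coordinate, with arc fractions exactly
#' equal to the sample's ancestry proportions. Exposed separately so tests
#' can assert on positions and arc fractions without rasterizing anything.
#'
#' @param pca a `pca_result`.
#' @param fit an `admixture_fit`; its sample ids must appear in `pca`.
#' @param radius glyph radius in PC units (> 0).
#' @param n_arc_points points per full circle used to draw the arcs.
#' @return tibble of polygon vertices: `sample_id`, `population`, `x`, `y`,
#'   with attribute `arcs` (tibble of per-segment start/end fractions).
#' @export
admixture_pca_scene <- function(pca, fit, radius = 0.02, n_arc_points = 64) {
  if (radius <= 0) stop("glyph radius must be positive", call. = FALSE)
  idx <- match(fit$sample_id, pca$ids)
  if (anyNA(idx)) {
    stop("sample with proportions but no PCA coordinates: ",
         fit$sample_id[which(is.na(idx))[1]], call. = FALSE)
  }
  q <- proportions_matrix(fit)
  pops <- colnames(q)
  centers <- pca$coords[idx, 1:2, drop = FALSE]
  arcs <- purrr::map_dfr(seq_len(nrow(q)), function(i) {
    ends <- cumsum(q[i, ])
    tibble::tibble(sample_id = fit$sample_id[i], population = pops,
                   frac = q[i, ], frac_start = c(0, ends[-length(ends)]),
                   frac_end = ends)
  })
  verts <- purrr::map_dfr(seq_len(nrow(arcs)), function(r) {
    a <- arcs[r, ]
    if (a$frac <= 0) return(NULL)
    i <- match(a$sample_id, fit$sample_id)
    theta <- 2 * pi * seq(a$frac_start, a$frac_end,
                          length.out = max(3, ceiling(a$frac * n_arc_points)))
    tibble::tibble(
      sample_id = a$sample_id, population = a$population,
      piece = paste(a$sample_id, a$population, sep = "."),
      x = c(centers[i, 1], centers[i, 1] + radius * sin(theta)),
      y = c(centers[i, 2], centers[i, 2] + radius * cos(theta))
    )
  })
  attr(verts, "arcs") <- arcs
  verts
}

#' Admixture-informed PCA plot
#'
#' Scatter of the first two principal components in which each study sample
#' is drawn as a pie glyph whose sectors are proportional to its estimated
#' ancestry components, while context (reference) samples are plain points
#' colored by their population label. This combines the projection view and
#' the admixture view in a single figure and guards against over-reading
#' cluster gaps in a bare PCA.
#'
#' @param pca a `pca_result` covering study and context samples.
#' @param fit an `admixture_fit` for the study samples.
#' @param context_labels named character vector (sample id -> population)
#'   for context samples, or `NULL`.
#' @param radius pie glyph radius in PC units; default 2% of the PC1 span.
#' @param colors optional named population -> color vector; defaults to a
#'   stable hue assignment sorted by population name.
#' @return a ggplot object; the glyph scene is attached as attribute
#'   `scene`.
#' @export
plot_admixture_pca <- function(pca, fit, context_labels = NULL,
                               radius = NULL, colors = NULL) {
  if (is.null(radius)) {
    radius <- 0.02 * diff(range(pca$coords[, 1]))
  }
  scene <- admixture_pca_scene(pca, fit, radius)
  pops <- attr(fit, "pops")
  all_pops <- sort(unique(c(pops, unname(context_labels))))
  if (is.null(colors)) {
    colors <- stats::setNames(grDevices::hcl.colors(length(all_pops), "Dark 3"),
                              all_pops)
  }
  p <- ggplot2::ggplot()
  if (!is.null(context_labels)) {
    ctx_idx <- match(names(context_labels), pca$ids)
    if (anyNA(ctx_idx)) stop("context sample absent from PCA", call. = FALSE)
    ctx <- tibble::tibble(x = pca$coords[ctx_idx, 1],
                          y = pca$coords[ctx_idx, 2],
                          population = unname(context_labels))
    p <- p + ggplot2::geom_point(
      data = ctx, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$population),
      size = 1.5, show.legend = TRUE
    )
  }
  p <- p +
    ggplot2::geom_polygon(
      data = scene,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$piece,
                   fill = .data$population),
      colour = "grey20", linewidth = 0.1
    ) +
    ggplot2::scale_fill_manual(values = colors, name = "ancestry")
  if (!is.null(context_labels)) {
    p <- p + ggplot2::scale_colour_manual(values = colors, name = "population")
  }
  p <- p +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  attr(p, "scene") <- scene
  p
}

#' Dendrogram-ordered admixture bar plot
#'
#' Stacked ancestry bars arranged in the leaf order of a dendrogram, so
#' that genetic similarity (small cophenetic distance) translates into bar
#' adjacency and the makeup of clusters is immediately visible.
#'
#' @param h an `hclust`/`upgma` dendrogram over the fitted samples.
#' @param fit an `admixture_fit`.
#' @param colors optional named population -> color vector.
#' @return a ggplot object; the ordered long-format bar data are attached
#'   as attribute `scene`.
#' @export
plot_admixture_bars <- function(h, fit, colors = NULL) {
  ord <- leaf_order(h)
  missing_ids <- setdiff(ord, fit$sample_id)
  if (length(missing_ids) > 0) {
    stop("dendrogram leaf without ancestry proportions: ", missing_ids[1],
         call. = FALSE)
  }
  pops <- attr(fit, "pops")
  long <- tibble::as_tibble(fit)[, c("sample_id", pops)] |>
    tidyr::pivot_longer(dplyr::all_of(pops), names_to = "population",
                        values_to = "proportion") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = ord)) |>
    dplyr::arrange(.data$sample_id)
  if (is.null(colors)) {
    colors <- stats::setNames(grDevices::hcl.colors(length(pops), "Dark 3"),
                              sort(pops))
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                          y = .data$proportion,
                                          fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = colors) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  attr(p, "scene") <- long
  p
}

#' Dendrogram-ordered distance heatmap
#'
#' Renders a symmetric distance (or FST) matrix with rows and columns in
#' dendrogram leaf order.
#'
#' @param d symmetric matrix with id dimnames (e.g. from
#'   [population_distance_matrix()] or [pairwise_fst_matrix()]).
#' @param h optional `hclust` over the same ids; default UPGMA of `d`.
#' @return a ggplot object; the ordered long-format cells are attached as
#'   attribute `scene`.
#' @export
plot_distance_heatmap <- function(d, h = NULL) {
  if (is.null(h)) h <- upgma(d)
  ord <- leaf_order(h)
  long <- tibble::as_tibble(d, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "distance") |>
    dplyr::mutate(row = factor(.data$row, levels = ord),
                  col = factor(.data$col, levels = ord))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = range(d)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  attr(p, "scene") <- long
  p
}

#' Per-chromosome histogram of flagged-variant density
#'
#' One panel per chromosome, bars = binned counts from
#' [chromosome_density()].
#'
#' @param density tibble with `chrom`, `bin_start`, `n`.
#' @param bin_size_bp the bin width used (for bar widths).
#' @return a ggplot object; the input is attached as attribute `scene`.
#' @export
plot_chromosome_density <- function(density, bin_size_bp = 1e6) {
  density <- dplyr::mutate(
    density,
    chrom = factor(.data$chrom,
                   levels = unique(.data$chrom[order(suppressWarnings(as.numeric(.data$chrom)),
                                                     .data$chrom)]))
  )
  p <- ggplot2::ggplot(density, ggplot2::aes(x = .data$bin_start, y = .data$n)) +
    ggplot2::geom_col(width = bin_size_bp, fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "flagged variants") +
    ggplot2::theme_minimal()
  attr(p, "scene") <- density
  p
}

#' @rdname plot_admixture_pca
#' @param object a `pca_result`.
#' @param labels optional named sample id -> population vector for point
#'   coloring.
#' @param ... ignored.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, labels = NULL, ...) {
  dat <- tibble::tibble(sample_id = object$ids,
                        PC1 = object$coords[, 1], PC2 = object$coords[, 2])
  if (!is.null(labels)) dat$population <- unname(labels[dat$sample_id])
  aes <- if (is.null(labels)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$population)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' @rdname plot_admixture_pca
#' @method autoplot diversity_report
#' @export
autoplot.diversity_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$population, y = .data$compactness)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(y = "compactness (separation / heterogeneity)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
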