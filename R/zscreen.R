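#' Join study and reference allele-frequency tables
#'
#' Inner join on the variant key `(chrom, pos, ref, alt)`: loci absent from
#' any reference table are dropped, with the dropped count reported via a
#' message and the `n_dropped` attribute. Duplicate keys within one table
#' are an error.
#'
#' @param study tibble with key columns and `freq` (the study frequencies).
#' @param references a named list of tibbles with key columns and `freq`,
#'   one per reference panel; each contributes a column named after it.
#' @return tibble with key columns, `study_freq`, one column per reference.
#' @export
join_frequency_tables <- function(study, references) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  check_keys <- function(tab, what) {
    if (anyDuplicated(tab[, key_cols])) {
      stop("duplicate variant keys in ", what, " table", call. = FALSE)
    }
  }
  check_keys(study, "study")
  out <- dplyr::select(study, dplyr::all_of(key_cols), study_freq = "freq")
  for (nm in names(references)) {
    ref <- references[[nm]]
    check_keys(ref, nm)
    ref <- dplyr::select(ref, dplyr::all_of(key_cols), !!nm := "freq")
    out <- dplyr::inner_join(out, ref, by = key_cols)
  }
  n_dropped <- nrow(study) - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped, " locus/loci dropped at frequency-table join")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Allele-frequency divergence Z-score
#'
#' The divergence of a study frequency from a set of reference-panel
#' frequencies, in units of the cross-panel spread:
#' `Z = (p_study - mean(ref)) / sd(ref)` with the sample SD (n - 1
#' denominator). At least three reference values are required; when the
#' reference SD falls below `sd_floor` the score is undefined (`NA`) and
#' the locus is uninformative for the screen.
#'
#' @param study_freq study-cohort allele frequency (scalar or vector).
#' @param ref_freqs numeric vector (one locus) or matrix (loci x panels) of
#'   reference frequencies.
#' @param sd_floor smallest usable reference SD (default 1e-6).
#' @return signed Z (NA where undefined).
#' @export
zscore <- function(study_freq, ref_freqs, sd_floor = 1e-6) {
  if (is.vector(ref_freqs)) ref_freqs <- matrix(ref_freqs, nrow = 1)
  if (ncol(ref_freqs) < 3) stop("need >= 3 reference values for a sample SD", call. = FALSE)
  mu <- rowMeans(ref_freqs)
  sdv <- row_sample_sd(ref_freqs)
  ifelse(sdv >= sd_floor, (study_freq - mu) / sdv, NA_real_)
}

#' Two-sided normal p-value of a Z-score
#'
#' `p = 2 (1 - Phi(|z|))`; at the conventional screen threshold |Z| = 4 this
#' is 6.3e-5.
#'
#' @param z Z-score(s).
#' @return p-values in (0, 1].
#' @export
zscore_pvalue <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Allele-frequency divergence screen
#'
#' Scores every joined locus, flags it as `"low"` (Z < -threshold),
#' `"null"` (|Z| <= threshold), `"high"` (Z > threshold) or
#' `"uninformative"` (reference SD below the floor), and attaches the
#' two-sided normal p-value.
#'
#' @param joined output of [join_frequency_tables()] (or any tibble with
#'   the key columns, `study_freq` and reference columns).
#' @param threshold flag cut-off on |Z| (default 4).
#' @param ref_cols reference column names entering the mean/SD; default all
#'   columns beyond the key and `study_freq`.
#' @param sd_floor smallest usable reference SD.
#' @return an object of class `zscreen_table` (a tibble): the input plus
#'   `ref_mean`, `ref_sd`, `z`, `p_value`, `flag`.
#' @export
zscreen <- function(joined, threshold = 4, ref_cols = NULL, sd_floor = 1e-6) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  if (is.null(ref_cols)) {
    ref_cols <- setdiff(names(joined), c(key_cols, "study_freq"))
  }
  if (length(ref_cols) < 3) stop("need >= 3 reference columns", call. = FALSE)
  refs <- as.matrix(joined[, ref_cols, drop = FALSE])
  mu <- rowMeans(refs)
  sdv <- row_sample_sd(refs)
  z <- ifelse(sdv >= sd_floor, (joined$study_freq - mu) / sdv, NA_real_)
  flag <- dplyr::case_when(
    is.na(z) ~ "uninformative",
    z < -threshold ~ "low",
    z > threshold ~ "high",
    TRUE ~ "null"
  )
  out <- dplyr::mutate(joined, ref_mean = mu, ref_sd = sdv, z = z,
                       p_value = zscore_pvalue(z), flag = flag)
  structure(out, class = c("zscreen_table", class(tibble::tibble())),
            threshold = threshold, ref_cols = ref_cols)
}

#' Flag-class counts of a screen
#'
#' @param screen a `zscreen_table`.
#' @return tibble with rows `low` (Z < -T), `high` (Z > T), `flagged`
#'   (|Z| > T), `null` and `uninformative`, and their counts.
#' @export
zscreen_summary <- function(screen) {
  n_low <- sum(screen$flag == "low")
  n_high <- sum(screen$flag == "high")
  tibble::tibble(
    class = c("low", "high", "flagged", "null", "uninformative"),
    n = c(n_low, n_high, n_low + n_high,
          sum(screen$flag == "null"),
          sum(screen$flag == "uninformative"))
  )
}

#' Cross-tabulate screen flags by variant effect category
#'
#' @param screen a `zscreen_table`.
#' @param annotations tibble with the key columns and an `effect` column
#'   (e.g. functional categories from an external annotation engine); loci
#'   without an annotation fall into `"Others"`.
#' @return tibble of counts: one row per flag class (`low`, `high`,
#'   `flagged`), one column per effect category plus `total`.
#' @export
tabulate_effects <- function(screen, annotations) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  ann <- dplyr::select(annotations, dplyr::all_of(key_cols), "effect")
  tab <- dplyr::left_join(tibble::as_tibble(screen), ann, by = key_cols)
  tab$effect[is.na(tab$effect)] <- "Others"
  count_class <- function(rows, label) {
    counts <- table(tab$effect[rows])
    row <- tibble::tibble(class = label, total = sum(rows))
    if (length(counts) > 0) {
      row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(counts)))
    }
    row
  }
  out <- dplyr::bind_rows(
    count_class(tab$flag == "low", "low"),
    count_class(tab$flag == "high", "high"),
    count_class(tab$flag %in% c("low", "high"), "flagged")
  )
  out[is.na(out)] <- 0L
  out
}

#' Per-chromosome binned counts of flagged loci
#'
#' Histograms the flagged (|Z| > threshold) loci along each chromosome in
#' half-open bins `[start, start + bin_size)`.
#'
#' @param screen a `zscreen_table`.
#' @param bin_size_bp bin width in base pairs.
#' @return tibble with `chrom`, `bin_start`, `n`.
#' @export
chromosome_density <- function(screen, bin_size_bp = 1e6) {
  flagged <- dplyr::filter(tibble::as_tibble(screen),
                           .data$flag %in% c("low", "high"))
  if (nrow(flagged) == 0) {
    return(tibble::tibble(chrom = character(), bin_start = numeric(),
                          n = integer()))
  }
  flagged |>
    dplyr::mutate(bin_start = (.data$pos - 1) %/% bin_size_bp * bin_size_bp + 1) |>
    dplyr::count(.data$chrom, .data$bin_start, name = "n")
}

#' Write a screen table as a sites-only VCF
#'
#' VCF 4.2 without genotype columns; the study frequency, each reference
#' column, the Z-score and the flag are emitted as INFO fields
#' (`AF_STUDY`, `AF_<panel>`, `ZSCORE`, `ZFLAG`) with matching `##INFO`
#' header lines. Numeric fields use 6 significant digits.
#'
#' @param screen a `zscreen_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frequency_vcf <- function(screen, path) {
  ref_cols <- attr(screen, "ref_cols")
  info_defs <- c(
    '##INFO=<ID=AF_STUDY,Number=1,Type=Float,Description="Study cohort alt allele frequency">',
    sprintf('##INFO=<ID=AF_%s,Number=1,Type=Float,Description="Reference panel %s alt allele frequency">',
            ref_cols, ref_cols),
    '##INFO=<ID=ZSCORE,Number=1,Type=Float,Description="Allele frequency divergence Z-score">',
    '##INFO=<ID=ZFLAG,Number=1,Type=String,Description="Divergence flag: low, null, high, uninformative">'
  )
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.6g", v))
  info <- paste0("AF_STUDY=", fmt(screen$study_freq))
  for (rc in ref_cols) {
    info <- paste0(info, ";AF_", rc, "=", fmt(screen[[rc]]))
  }
  info <- paste0(info, ";ZSCORE=", fmt(screen$z), ";ZFLAG=", screen$flag)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=popstructr zscreen",
    info_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(screen$chrom, screen$pos, ".", screen$ref, screen$alt, ".", ".",
          info, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a sites-only frequency VCF
#'
#' @param path a VCF written by [write_frequency_vcf()].
#' @return tibble with key columns, `study_freq`, reference columns, `z`,
#'   `flag`.
#' @export
read_frequency_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(fields, `[[`, character(1), 8)
  parse_info <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[[`, character(1), 2),
                    vapply(kv, `[[`, character(1), 1))
  }
  recs <- lapply(info, parse_info)
  keys <- names(recs[[1]])
  num <- setdiff(keys, "ZFLAG")
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    pos = as.integer(vapply(fields, `[[`, character(1), 2)),
    ref = vapply(fields, `[[`, character(1), 4),
    alt = vapply(fields, `[[`, character(1), 5)
  )
  for (k in num) {
    v <- vapply(recs, function(r) r[[k]], character(1))
    out[[k]] <- suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  }
  out$flag <- vapply(recs, function(r) r[["ZFLAG"]], character(1))
  names(out)[names(out) == "AF_STUDY"] <- "study_freq"
  names(out)[names(out) == "ZSCORE"] <- "z"
  names(out) <- sub("^AF_", "", names(out))
  out
}

# Row-wise sample SD (n - 1 denominator); safe on zero-row input.
row_sample_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}
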