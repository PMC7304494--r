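#' Read a cohort's genotypes from VCF
#'
#' Reads GT fields from a VCF 4.x file (via vcfR). Only biallelic SNP
#' records are kept; multi-allelic or non-SNP records are skipped with a
#' warning that reports the count. `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`,
#' `./. -> NA`; the phase separator (`|`) is accepted and ignored.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [cohort()] with empty metadata labels.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    warning(n_skipped, " multi-allelic or non-SNP record(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  g <- apply(gt, c(1, 2), parse_gt)
  coh <- cohort(
    t(g),
    tibble::tibble(id = colnames(gt)),
    tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   id = ifelse(fix$ID == ".", NA_character_, fix$ID),
                   ref = fix$REF, alt = fix$ALT)
  )
  attr(coh, "n_skipped_records") <- n_skipped
  coh
}

parse_gt <- function(x) {
  if (is.na(x)) return(NA_integer_)
  alleles <- strsplit(x, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  if (!all(alleles %in% c("0", "1")) || length(alleles) != 2L) {
    stop("malformed GT field: '", x, "'", call. = FALSE)
  }
  sum(alleles == "1")
}

#' Write a cohort's genotypes as VCF 4.2
#'
#' Writes an uncompressed VCF with GT fields only. `write` then
#' [read_vcf_genotypes()] is lossless for genotypes, coordinates and
#' alleles.
#'
#' @param x a cohort.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(x, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- x$genotypes
  body <- matrix(gt_codes[g + 1L], nrow = nrow(g))
  body[is.na(g)] <- "./."
  v <- x$variants
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=popstructr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$id), collapse = "\t"),
    paste(v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref, v$alt,
          ".", ".", ".", "GT",
          apply(body, 2, paste, collapse = "\t"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a cohort as a genotype TSV table
#'
#' The TSV dialect: columns `chrom`, `pos`, `id`, `ref`, `alt`, then one
#' column per sample holding 0/1/2/NA; one row per variant. The round trip
#' is lossless for genotypes, variants and sample ids.
#'
#' @param path file path.
#' @return a [cohort()] (read) or `path` invisibly (write).
#' @export
read_genotype_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    id = readr::col_character(), ref = readr::col_character(),
    alt = readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  sample_ids <- setdiff(names(tab), c("chrom", "pos", "id", "ref", "alt"))
  if (length(sample_ids) == 0) stop("no sample columns found", call. = FALSE)
  gvals <- as.matrix(tab[, sample_ids, drop = FALSE])
  ok <- is.na(gvals) | gvals %in% c("0", "1", "2")
  if (!all(ok)) {
    stop("non-integer genotype token: '", gvals[!ok][1], "'", call. = FALSE)
  }
  g <- matrix(as.integer(gvals), nrow = nrow(gvals))
  cohort(t(g), tibble::tibble(id = sample_ids),
         tab[, c("chrom", "pos", "id", "ref", "alt")])
}

#' @rdname read_genotype_table
#' @param x a cohort.
#' @export
write_genotype_table <- function(x, path) {
  tab <- dplyr::bind_cols(
    x$variants,
    tibble::as_tibble(t(x$genotypes), .name_repair = ~ x$samples$id)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Alternate-allele frequencies of a cohort
#'
#' Per variant (optionally per population): alt-allele frequency over
#' non-missing genotypes, with the alt allele count and the non-missing
#' diploid sample count, so `freq == alt_count / (2 * n_obs)` is
#' recomputable. Variants with all genotypes missing get `freq = NA` and
#' `all_missing = TRUE`.
#'
#' @param x a cohort.
#' @param by_population compute per population label instead of overall.
#' @return a tibble with `chrom`, `pos`, `ref`, `alt`, optional
#'   `population`, `alt_count`, `n_obs`, `freq`, `all_missing`.
#' @export
allele_freqs <- function(x, by_population = FALSE) {
  freq_block <- function(g, vtab) {
    n_obs <- colSums(!is.na(g))
    alt_count <- colSums(g, na.rm = TRUE)
    tibble::tibble(
      chrom = vtab$chrom, pos = vtab$pos, ref = vtab$ref, alt = vtab$alt,
      alt_count = as.integer(alt_count), n_obs = as.integer(n_obs),
      freq = ifelse(n_obs > 0, alt_count / (2 * n_obs), NA_real_),
      all_missing = n_obs == 0L
    )
  }
  if (n_samples(x) == 0 || n_variants(x) == 0) stop("empty cohort", call. = FALSE)
  if (!by_population) return(freq_block(x$genotypes, x$variants))
  pops <- unique(x$samples$population)
  purrr::map_dfr(pops, function(p) {
    sel <- which(x$samples$population %in% p)
    dplyr::mutate(freq_block(x$genotypes[sel, , drop = FALSE], x$variants),
                  population = p, .before = "alt_count")
  })
}

#' Merge two cohorts on intersecting variants
#'
#' Variants are matched on `(chrom, pos)`. Alleles are harmonized: an exact
#' `(ref, alt)` match is kept as-is; a swapped pair in `b` is recoded
#' `g -> 2 - g`; any other allele pair (including strand-ambiguous
#' mismatches) is dropped, with a message reporting the count. Sample
#' metadata are concatenated; sample id sets must be disjoint.
#'
#' @param a,b cohorts.
#' @return the merged cohort; attribute `n_dropped_alleles` counts loci
#'   dropped for allele mismatch.
#' @export
merge_cohorts <- function(a, b) {
  if (length(intersect(a$samples$id, b$samples$id)) > 0) {
    stop("duplicate sample id across cohorts", call. = FALSE)
  }
  pk_a <- paste(a$variants$chrom, a$variants$pos, sep = ":")
  pk_b <- paste(b$variants$chrom, b$variants$pos, sep = ":")
  common <- intersect(pk_a, pk_b)
  ia <- match(common, pk_a)
  ib <- match(common, pk_b)
  va <- a$variants[ia, ]
  vb <- b$variants[ib, ]
  exact <- va$ref == vb$ref & va$alt == vb$alt
  swapped <- va$ref == vb$alt & va$alt == vb$ref
  keep <- exact | swapped
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " locus/loci dropped at merge for allele mismatch")
  }
  if (sum(keep) == 0) warning("no variants shared between cohorts", call. = FALSE)
  ia <- ia[keep]; ib <- ib[keep]
  swapped <- swapped[keep]
  ga <- a$genotypes[, ia, drop = FALSE]
  gb <- b$genotypes[, ib, drop = FALSE]
  if (any(swapped)) {
    gb[, swapped] <- 2L - gb[, swapped, drop = FALSE]
  }
  out <- cohort(rbind(ga, gb),
                dplyr::bind_rows(a$samples, b$samples),
                a$variants[ia, ])
  attr(out, "n_dropped_alleles") <- n_dropped
  out
}

#' Read/write a symmetric distance matrix as TSV
#'
#' TSV with an `id` header column and one column per id; entries must be
#' symmetric with a zero diagonal.
#'
#' @param d symmetric numeric matrix with dimnames (as produced by
#'   [ibs_distance_matrix()]).
#' @param path file path.
#' @return the matrix (read) or `path` invisibly (write).
#' @export
write_distance_tsv <- function(d, path) {
  tab <- dplyr::bind_cols(tibble::tibble(id = rownames(d)),
                          tibble::as_tibble(d, .name_repair = "minimal"))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$id
  check_distance_matrix(d)
  d
}

check_distance_matrix <- function(d, tol = 1e-12) {
  if (nrow(d) != ncol(d)) stop("distance matrix not square", call. = FALSE)
  if (anyNA(d)) stop("NaN/NA in distance matrix", call. = FALSE)
  if (max(abs(d - t(d))) > tol) stop("distance matrix not symmetric", call. = FALSE)
  if (max(abs(diag(d))) > tol) stop("distance matrix diagonal not zero", call. = FALSE)
  invisible(d)
}

#' Read a frequency table TSV
#'
#' Accepts either the package's own layout (`chrom`, `pos`, `ref`, `alt`,
#' `freq`, ...) or PLINK `.frq`-style columns (`CHR`, `SNP`, `A1`, `A2`,
#' `MAF`, `NCHROBS`), which are renamed into the package layout.
#'
#' @param path TSV file.
#' @return a tibble keyed by `(chrom, pos, ref, alt)` where available.
#' @export
read_frequency_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("CHR", "A1", "A2", "MAF") %in% names(tab))) {
    tab <- dplyr::rename(tab, chrom = "CHR", alt = "A1", ref = "A2", freq = "MAF")
    tab$chrom <- as.character(tab$chrom)
    if ("NCHROBS" %in% names(tab)) tab$n_obs <- as.integer(tab$NCHROBS / 2)
  }
  tibble::as_tibble(tab)
}
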