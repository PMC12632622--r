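# Readers and writers for the plain-text formats the pipeline exchanges.

#' Read and write barcode count matrices
#'
#' One replicate per file: a tab-delimited matrix with a `strain_id` column
#' and one column per timepoint labelled `T0`, `T1`, ...
#'
#' @param counts Long count table (`strain_id`, `replicate`, `timepoint`,
#'   `reads`) restricted to one replicate.
#' @param path File path.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- normalise_counts(counts)
  if (dplyr::n_distinct(counts$replicate) > 1) {
    abort("write one replicate per file; filter `counts` first")
  }
  wide <- counts |>
    dplyr::arrange(.data$timepoint) |>
    dplyr::mutate(tp = tp_label(.data$timepoint)) |>
    tidyr::pivot_wider(id_cols = "strain_id", names_from = "tp",
                       values_from = "reads")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @param replicate Replicate label to attach on read.
#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, replicate = "R01") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-"strain_id", names_to = "timepoint",
                        values_to = "reads") |>
    dplyr::mutate(timepoint = as.integer(sub("^T", "", .data$timepoint)),
                  replicate = replicate,
                  reads = as.integer(.data$reads)) |>
    dplyr::select("strain_id", "replicate", "timepoint", "reads")
}

#' Read a samtools-depth table
#'
#' Three tab-delimited columns without header: chromosome, 1-based
#' position, depth (the `samtools depth -a` dialect).
#'
#' @param path File path.
#' @return A tibble `chrom`, `pos`, `depth`.
#' @export
read_depth_table <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                  col_types = "cii", progress = FALSE)
}

#' Read a BED-style blacklist
#'
#' 0-based half-open intervals, at least three tab-delimited columns
#' (chrom, start, end), no header.
#'
#' @param path File path.
#' @return A tibble `chrom`, `start`, `end`.
#' @export
read_blacklist_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         show_col_types = FALSE)
  tibble(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
         end = as.integer(bed[[3]]))
}

#' Read and write long variant tables
#'
#' The flattened tab-delimited export consumed by [filter_variants()]:
#' columns `chrom`, `pos`, `ref`, `alt`, `sample`, `gt`, `ad_ref`,
#' `ad_alt`, `dp`, `gq`.
#'
#' @param variants Long variant tibble.
#' @param path File path.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", sample = "c", gt = "c",
    ad_ref = "i", ad_alt = "i", dp = "i", gq = "i"), progress = FALSE)
}

#' Read a multi-sample VCF into the long variant-table shape
#'
#' Parses a VCF with per-sample GT, AD, DP and GQ fields (via the vcfR
#' package) into the flattened tibble the filtering and classification
#' functions consume.
#'
#' @param path VCF file path (plain or gzipped).
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `sample`, `gt`,
#'   `ad_ref`, `ad_alt`, `dp`, `gq`.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  samples <- colnames(gt)
  rows <- purrr::map(samples, function(sm) {
    ad_split <- strsplit(ad[, sm], ",", fixed = TRUE)
    tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, sample = sm,
      gt = unname(gsub("|", "/", gt[, sm], fixed = TRUE)),
      ad_ref = as.integer(unname(vapply(ad_split,
                                        function(x) x[1] %||% NA_character_,
                                        character(1)))),
      ad_alt = as.integer(unname(vapply(
        ad_split,
        function(x) if (length(x) >= 2) x[2] else NA_character_,
        character(1)))),
      dp = as.integer(unname(dp[, sm])), gq = as.integer(unname(gq[, sm])))
  })
  dplyr::bind_rows(rows)
}
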