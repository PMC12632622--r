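#' Simulate merged amplicon reads from a count table
#'
#' Fixture generator for the barcode-extraction stage: emits one read per
#' count unit, with the sample's index pair and the strain's barcode filled
#' into the template slots, and uniform substitution errors applied at
#' `per_base_error`. With `per_base_error = 0` the downstream counter
#' reproduces the input counts exactly.
#'
#' @param counts Tibble `strain_id`, `replicate`, `timepoint`, `reads`.
#' @param template A [read_template()].
#' @param catalog Tibble `strain_id`, `barcode`; barcode length must equal
#'   the template's barcode slot.
#' @param sample_map Tibble `index1`, `index2`, `replicate`, `timepoint`.
#' @param per_base_error Substitution probability per base, in [0, 0.1].
#' @param seed Optional integer seed.
#' @return A tibble `read_id`, `sequence` (zero rows when all counts are
#'   zero). Write to disk with [write_fastq()].
#' @export
simulate_amplicon_reads <- function(counts, template, catalog, sample_map,
                                    per_base_error = 0, seed = NULL) {
  counts <- normalise_counts(counts)
  assert_scalar_number(per_base_error, "per_base_error", lower = 0, upper = 0.1)
  if (!inherits(template, "read_template")) {
    abort("`template` must be a read_template()")
  }
  bc_seg <- template[template$type == "barcode", ]
  bad_bc <- nchar(catalog$barcode) != bc_seg$length
  if (any(bad_bc)) {
    abort(sprintf("barcode(s) do not fit the %d-bp template slot: %s",
                  bc_seg$length,
                  paste(head(catalog$strain_id[bad_bc], 3), collapse = ", ")))
  }
  set_stage_seed(seed, "amplicon")

  df <- counts |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::inner_join(catalog, by = "strain_id") |>
    dplyr::inner_join(sample_map, by = c("replicate", "timepoint"))
  if (nrow(df) == 0) {
    return(tibble(read_id = character(), sequence = character()))
  }

  idx_segs <- template[template$type == "index", ]
  build_one <- function(barcode, index1, index2) {
    pieces <- character(nrow(template))
    slot_i <- 0L
    for (k in seq_len(nrow(template))) {
      if (template$type[k] == "const") {
        pieces[k] <- template$sequence[k]
      } else if (template$type[k] == "barcode") {
        pieces[k] <- barcode
      } else {
        slot_i <- slot_i + 1L
        pieces[k] <- if (slot_i == 1L) index1 else index2
      }
    }
    paste(pieces, collapse = "")
  }
  proto <- purrr::pmap_chr(df[, c("barcode", "index1", "index2")],
                           function(barcode, index1, index2)
                             build_one(barcode, index1, index2))
  seqs <- rep(proto, times = df$reads)

  if (per_base_error > 0 && length(seqs) > 0) {
    L <- template_length(template)
    n <- length(seqs)
    n_err <- rbinom(n, size = L, prob = per_base_error)
    hit <- which(n_err > 0)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      pos <- sample.int(L, n_err[i])
      for (p in pos) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
      }
    }
  }
  tibble(read_id = sprintf("read_%07d", seq_along(seqs)), sequence = seqs)
}

#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings. [write_fastq()] writes constant quality
#' (`I` = Q40) since the simulator does not model per-base qualities;
#' [read_fastq()] returns a named character vector of sequences.
#'
#' @param reads Tibble `read_id`, `sequence` (or named character vector).
#' @param path File path (a `.gz` suffix gzips on write).
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    seqs <- setNames(reads$sequence, reads$read_id)
  } else {
    seqs <- reads
  }
  dss <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::PhredQuality(
    vapply(Biostrings::width(dss),
           function(w) paste(rep("I", w), collapse = ""), character(1)))
  qdss <- Biostrings::QualityScaledDNAStringSet(dss, qual)
  Biostrings::writeQualityScaledXStringSet(qdss, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), names(dss))
}
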