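#' Read templates for barcode amplicons
#'
#' A template describes the fixed layout of a merged amplicon read as an
#' ordered set of segments: constant regions (matched with a per-segment
#' mismatch tolerance), index slots (demultiplexing) and one barcode slot.
#' Constant regions anchor the slot positions.
#'
#' @param ... Named segments in read order: a character string for a
#'   constant region, or [index_slot()] / [barcode_slot()] for slots.
#' @param const_max_mismatch Mismatch tolerance for constant regions
#'   (degenerate bases such as `N` count as mismatches).
#' @return A `read_template`: tibble `segment`, `type`, `sequence`,
#'   `length`, `start`, `end`, `max_mismatch`.
#' @examples
#' tpl <- read_template(index1 = index_slot(6), c1 = "GTCGAC",
#'                      barcode = barcode_slot(20), c2 = "ATAACT",
#'                      index2 = index_slot(6))
#' @export
read_template <- function(..., const_max_mismatch = 1L) {
  segs <- list(...)
  if (length(segs) == 0) abort("template needs at least one segment")
  if (is.null(names(segs)) || any(names(segs) == "")) {
    abort("all template segments must be named")
  }
  rows <- purrr::imap(segs, function(x, nm) {
    if (is.character(x) && length(x) == 1L) {
      if (nchar(x) == 0) abort(sprintf("constant region `%s` is empty", nm))
      tibble(segment = nm, type = "const", sequence = toupper(x),
             length = nchar(x), max_mismatch = as.integer(const_max_mismatch))
    } else if (inherits(x, "template_slot")) {
      tibble(segment = nm, type = x$type, sequence = NA_character_,
             length = x$length, max_mismatch = 0L)
    } else {
      abort(sprintf("segment `%s` must be a string, index_slot() or barcode_slot()", nm))
    }
  })
  tpl <- dplyr::bind_rows(rows)
  if (sum(tpl$type == "barcode") != 1L) {
    abort("template must contain exactly one barcode_slot()")
  }
  tpl$end <- cumsum(tpl$length)
  tpl$start <- tpl$end - tpl$length + 1L
  class(tpl) <- c("read_template", class(tpl))
  tpl
}

#' @param length Slot length in bp.
#' @rdname read_template
#' @export
index_slot <- function(length) {
  structure(list(type = "index", length = as.integer(length)),
            class = "template_slot")
}

#' @rdname read_template
#' @export
barcode_slot <- function(length = 20L) {
  structure(list(type = "barcode", length = as.integer(length)),
            class = "template_slot")
}

#' Default amplicon template used by the simulator
#'
#' Layout: forward index (6 bp), constant priming region, 20-bp barcode,
#' constant region, reverse index (6 bp).
#'
#' @param barcode_length Barcode slot length.
#' @param index_length Index slot length.
#' @export
default_template <- function(barcode_length = 20L, index_length = 6L) {
  read_template(
    index1 = index_slot(index_length),
    const1 = "GTCGACCTGCAGCGTACG",
    barcode = barcode_slot(barcode_length),
    const2 = "ATAACTTCGTATAATGTATGC",
    index2 = index_slot(index_length)
  )
}

template_length <- function(template) sum(template$length)

# Per-position mismatch counting of a fixed-position constant segment,
# vectorised over reads of equal length.
count_mismatches <- function(reads, start, seq) {
  L <- nchar(seq)
  sub <- substr(reads, start, start + L - 1L)
  mism <- integer(length(reads))
  chars <- strsplit(seq, "")[[1]]
  for (j in seq_len(L)) {
    mism <- mism + (substr(sub, j, j) != chars[j])
  }
  mism
}

#' Parse merged amplicon reads against a template
#'
#' Matches each constant region at its template position allowing up to its
#' mismatch tolerance, and extracts the index pair and barcode by position.
#' Reads whose length differs from the template are rejected with reason
#' `length`; constant-region failures with reason `constant_mismatch`.
#'
#' @param reads Character vector of read sequences (or named vector from
#'   [read_fastq()]).
#' @param template A [read_template()].
#' @return A tibble `read`, `index1`, `index2`, `barcode`, `reason`
#'   (`NA` for accepted reads).
#' @export
parse_reads <- function(reads, template) {
  if (!inherits(template, "read_template")) {
    abort("`template` must be a read_template()")
  }
  reads <- toupper(as.character(reads))
  n <- length(reads)
  exp_len <- template_length(template)
  reason <- rep(NA_character_, n)
  reason[nchar(reads) != exp_len] <- "length"
  ok <- is.na(reason)

  consts <- template[template$type == "const", ]
  for (i in seq_len(nrow(consts))) {
    if (!any(ok)) break
    mism <- count_mismatches(reads[ok], consts$start[i], consts$sequence[i])
    bad <- mism > consts$max_mismatch[i]
    idx <- which(ok)[bad]
    reason[idx] <- "constant_mismatch"
    ok[idx] <- FALSE
  }

  idx_segs <- template[template$type == "index", ]
  bc_seg <- template[template$type == "barcode", ]
  out <- tibble(
    read = reads,
    index1 = NA_character_, index2 = NA_character_,
    barcode = NA_character_, reason = reason
  )
  if (nrow(idx_segs) >= 1) {
    out$index1[ok] <- substr(reads[ok], idx_segs$start[1], idx_segs$end[1])
  }
  if (nrow(idx_segs) >= 2) {
    out$index2[ok] <- substr(reads[ok], idx_segs$start[2], idx_segs$end[2])
  }
  out$barcode[ok] <- substr(reads[ok], bc_seg$start[1], bc_seg$end[1])
  out
}

#' Assign observed barcodes to catalog strains by edit distance
#'
#' Returns the unique catalog entry within edit distance `max_dist` of each
#' observed barcode; observations with no catalog entry in range, or with
#' two entries tied at the minimum distance, are left unassigned (`NA`) --
#' the assigner never guesses.
#'
#' @param observed Character vector of observed barcode sequences.
#' @param catalog Tibble `strain_id`, `barcode` (unique, equal-length
#'   barcodes).
#' @param max_dist Maximum Levenshtein distance (default 1).
#' @return Character vector of strain ids (`NA` = unassigned).
#' @export
assign_barcode <- function(observed, catalog, max_dist = 1L) {
  assert_columns(catalog, c("strain_id", "barcode"), "catalog")
  if (anyDuplicated(catalog$barcode)) abort("catalog barcodes must be unique")
  bc_len <- unique(nchar(catalog$barcode))
  if (length(bc_len) != 1) abort("catalog barcodes must all have the same length")

  uo <- unique(observed)
  res <- setNames(rep(NA_character_, length(uo)), uo)
  # exact matches first
  hit <- match(uo, catalog$barcode)
  res[!is.na(hit)] <- catalog$strain_id[hit[!is.na(hit)]]
  todo <- uo[is.na(hit) & !is.na(uo) & nchar(uo) == bc_len]
  if (length(todo) > 0 && max_dist > 0) {
    d <- adist(todo, catalog$barcode)
    for (i in seq_along(todo)) {
      dm <- min(d[i, ])
      if (dm <= max_dist && sum(d[i, ] == dm) == 1L) {
        res[todo[i]] <- catalog$strain_id[which.min(d[i, ])]
      }
    }
  }
  unname(res[observed])
}

#' Count strain barcodes per sample from merged amplicon reads
#'
#' One pass over the reads: parse against the template, demultiplex by the
#' index pair through `sample_map`, assign barcodes to catalog strains
#' within `max_dist`, and tabulate. Per-sample accounting guarantees
#' assigned + unassigned = total; reads whose index pair is absent from
#' `sample_map` are counted under sample `unknown` with reason
#' `unknown_sample`.
#'
#' @param reads Character vector of read sequences, or a FASTQ file path.
#' @param template A [read_template()].
#' @param catalog Tibble `strain_id`, `barcode`.
#' @param sample_map Tibble `index1`, `index2`, `replicate`, `timepoint`
#'   covering the expected index pairs.
#' @param max_dist Barcode edit-distance tolerance (indices are matched
#'   exactly).
#' @return A list with `counts` (tibble `strain_id`, `replicate`,
#'   `timepoint`, `reads`, complete over catalog x samples with zero fill)
#'   and `qc` (per-sample tibble `replicate`, `timepoint`, `total`,
#'   `assigned`, plus per-reason reject counts).
#' @export
count_barcodes <- function(reads, template, catalog, sample_map,
                           max_dist = 1L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  assert_columns(sample_map, c("index1", "index2", "replicate", "timepoint"),
                 "sample_map")
  parsed <- parse_reads(reads, template)
  parsed <- dplyr::left_join(parsed, sample_map, by = c("index1", "index2"))
  known <- is.na(parsed$reason) & !is.na(parsed$replicate)
  parsed$reason[is.na(parsed$reason) & !known] <- "unknown_sample"
  parsed$strain_id <- NA_character_
  parsed$strain_id[known] <- assign_barcode(parsed$barcode[known], catalog,
                                            max_dist = max_dist)
  parsed$reason[known & is.na(parsed$strain_id)] <- "barcode_unassigned"

  samples <- dplyr::distinct(sample_map[, c("replicate", "timepoint")])
  grid <- tidyr::expand_grid(strain_id = catalog$strain_id, samples)
  counted <- parsed |>
    dplyr::filter(!is.na(.data$strain_id)) |>
    dplyr::count(.data$strain_id, .data$replicate, .data$timepoint,
                 name = "reads")
  counts <- grid |>
    dplyr::left_join(counted, by = c("strain_id", "replicate", "timepoint")) |>
    dplyr::mutate(reads = as.integer(tidyr::replace_na(.data$reads, 0L)))

  qc <- parsed |>
    dplyr::mutate(
      replicate = tidyr::replace_na(.data$replicate, "unknown"),
      timepoint = tidyr::replace_na(.data$timepoint, -1L),
      outcome = dplyr::if_else(is.na(.data$reason), "assigned", .data$reason)
    ) |>
    dplyr::count(.data$replicate, .data$timepoint, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in c("assigned", "barcode_unassigned", "constant_mismatch",
                "length", "unknown_sample")) {
    if (!col %in% names(qc)) qc[[col]] <- 0L
  }
  qc$total <- qc$assigned + qc$barcode_unassigned + qc$constant_mismatch +
    qc$length + qc$unknown_sample

  list(counts = counts, qc = qc)
}
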