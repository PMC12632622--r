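#' Coverage profile from a per-base depth table
#'
#' Summarises a complete per-base depth table (samtools-depth dialect:
#' `chrom`, `pos` 1-based, `depth`, every position present) into
#' per-chromosome medians, a genome-wide median, and per-bin (default 1 kb)
#' mean depths; the last partial bin of each chromosome is averaged over
#' its actual length.
#'
#' @param depth_table Tibble `chrom`, `pos`, `depth` (one sample).
#' @param bin_size Bin width in bp.
#' @param exclude Contig names excluded from the genome median (e.g.
#'   mitochondria and plasmids, whose copy number does not follow nuclear
#'   ploidy); they are profiled but not used for normalisation.
#' @return A `coverage_profile`: list with `chrom` (tibble `chrom`,
#'   `length`, `median_depth`), `bins` (tibble `chrom`, `start` 1-based,
#'   `end`, `mean_depth`), `genome_median`, `bin_size`.
#' @export
coverage_profile <- function(depth_table, bin_size = 1000L,
                             exclude = character()) {
  assert_columns(depth_table, c("chrom", "pos", "depth"), "depth_table")
  assert_scalar_number(bin_size, "bin_size", lower = 1)
  chroms <- unique(depth_table$chrom)
  bins <- list()
  chrom_rows <- list()
  for (ch in chroms) {
    d <- depth_table[depth_table$chrom == ch, ]
    if (nrow(d) == 0) abort(sprintf("chromosome `%s` has no positions", ch))
    if (d$pos[1] != 1L || (nrow(d) > 1 && any(diff(d$pos) != 1L))) {
      first_bad <- if (d$pos[1] != 1L) d$pos[1] else
        d$pos[which(diff(d$pos) != 1L)[1] + 1L]
      abort(sprintf("depth table is gapped or unsorted at %s:%d (need complete 1-based positions)",
                    ch, first_bad))
    }
    chrom_rows[[ch]] <- tibble(chrom = ch, length = nrow(d),
                               median_depth = median(d$depth))
    bin_id <- (d$pos - 1L) %/% as.integer(bin_size)
    means <- tapply(d$depth, bin_id, mean)
    starts <- as.integer(names(means)) * as.integer(bin_size) + 1L
    bins[[ch]] <- tibble(chrom = ch, start = starts,
                         end = pmin(starts + as.integer(bin_size) - 1L,
                                    nrow(d)),
                         mean_depth = as.numeric(means))
  }
  chrom_tbl <- dplyr::bind_rows(chrom_rows)
  usable <- chrom_tbl[!chrom_tbl$chrom %in% exclude, ]
  genome_median <- median(
    depth_table$depth[!depth_table$chrom %in% exclude])
  structure(list(chrom = chrom_tbl, bins = dplyr::bind_rows(bins),
                 genome_median = genome_median, bin_size = bin_size,
                 excluded = exclude),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d chromosome(s), genome median %.1fx, %d-bp bins\n",
              nrow(x$chrom), x$genome_median, x$bin_size))
  invisible(x)
}

#' Call whole-chromosome copy ratios (karyotype)
#'
#' For samples with genome median depth strictly above `min_median`, each
#' chromosome's median depth is normalised to the genome median and rounded
#' to the nearest 0.5 (exact halves round away from zero), giving copy
#' ratios in {0, 0.5, 1, 1.5, ...}: 1.0 is euploid, 1.5 a trisomy on a
#' diploid baseline, 0.5 a monosomy. Shallow samples are flagged
#' ineligible and receive no ratios.
#'
#' @param profile A [coverage_profile()].
#' @param min_median Minimum genome median depth (strict) for eligibility.
#' @return A list with `ratios` (tibble `chrom`, `median_depth`,
#'   `normalized`, `ratio`), `eligible`, `genome_median`.
#' @export
call_karyotype <- function(profile, min_median = 6) {
  stopifnot(inherits(profile, "coverage_profile"))
  eligible <- profile$genome_median > min_median
  ratios <- profile$chrom |>
    dplyr::mutate(
      normalized = .data$median_depth / profile$genome_median,
      ratio = if (eligible) round_to_half(.data$normalized) else NA_real_)
  list(ratios = ratios, eligible = eligible,
       genome_median = profile$genome_median)
}

#' Call segmental amplifications and deletions from binned coverage
#'
#' Scans each chromosome's normalised bin depths for maximal runs of at
#' least `min_bins` consecutive bins deviating from the chromosome's
#' whole-chromosome baseline ratio by at least `delta`, reporting each run
#' with its mean ratio -- a simple run-length segmenter for large (tens of
#' kb) amplifications that do not span the whole chromosome.
#'
#' @param profile A [coverage_profile()].
#' @param karyotype Output of [call_karyotype()] (supplies the per-
#'   chromosome baseline ratio; must be eligible).
#' @param min_bins Minimum run length in bins.
#' @param delta Minimum absolute deviation from baseline.
#' @return A tibble `chrom`, `start` (0-based), `end` (half-open),
#'   `n_bins`, `mean_ratio`, `direction` (`"gain"`/`"loss"`).
#' @export
call_segments <- function(profile, karyotype, min_bins = 20L, delta = 0.4) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (!karyotype$eligible) abort("karyotype is ineligible (genome median too low)")
  baselines <- setNames(karyotype$ratios$ratio, karyotype$ratios$chrom)
  segs <- list()
  for (ch in unique(profile$bins$chrom)) {
    b <- profile$bins[profile$bins$chrom == ch, ]
    norm <- b$mean_depth / profile$genome_median
    dev <- norm - baselines[ch]
    flag <- abs(dev) >= delta
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_bins) next
      i <- starts[k]:ends[k]
      segs[[length(segs) + 1L]] <- tibble(
        chrom = ch,
        start = b$start[i[1]] - 1L,
        end = b$end[i[length(i)]],
        n_bins = length(i),
        mean_ratio = mean(norm[i]),
        direction = if (mean(dev[i]) > 0) "gain" else "loss")
    }
  }
  if (length(segs) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_bins = integer(), mean_ratio = double(),
                  direction = character()))
  }
  dplyr::bind_rows(segs)
}
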