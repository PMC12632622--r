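# Small fixture builders shared across test files.

# Deterministic two-strain trajectory counts: one selected strain at s,
# one reference at 0, noiseless negative-binomial means rounded to counts.
two_strain_counts <- function(s, g = 8, n_timepoints = 6, f0 = 0.1,
                              depth = 1e8) {
  t <- 0:(n_timepoints - 1)
  w <- f0 * exp(g * s * t)
  f_sel <- w / (w + (1 - f0))
  f_ref <- 1 - f_sel
  tibble::tibble(
    strain_id = rep(c("SEL", "REF01"), each = n_timepoints),
    replicate = "R01",
    timepoint = rep(t, 2),
    reads = as.integer(round(c(f_sel, f_ref) * depth))
  )
}

# Tiny barcode catalog with pairwise edit distance >= 3.
tiny_catalog <- function() {
  tibble::tibble(
    strain_id = c("S001", "S002", "REF01"),
    barcode = c("AAAAACCCCCGGGGGTTTTT",
                "ACGTACGTACGTACGTACGT",
                "TTTTTGGGGGCCCCCAAAAA")
  )
}

tiny_sample_map <- function() {
  tibble::tibble(
    index1 = c("AACCGG", "AACCGG"),
    index2 = c("TTGGCC", "CCAATT"),
    replicate = "R01",
    timepoint = c(0L, 1L)
  )
}

# Long variant table builder: one site across samples, from alt fractions.
variant_site <- function(chrom, pos, fracs, dp = 30L, gq = 99L,
                         ref = "A", alt = "T") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    sample = names(fracs),
    gt = dplyr::case_when(fracs < 0.2 ~ "0/0", fracs > 0.8 ~ "1/1",
                          TRUE ~ "0/1"),
    ad_alt = as.integer(round(unname(fracs) * dp)),
    ad_ref = as.integer(dp - round(unname(fracs) * dp)),
    dp = as.integer(dp), gq = as.integer(gq)
  )
}

# Uniform-depth table for one sample.
flat_depth <- function(chrom_sizes, depth) {
  dplyr::bind_rows(purrr::imap(chrom_sizes, function(len, ch)
    tibble::tibble(chrom = ch, pos = seq_len(len),
                   depth = as.integer(depth))))
}
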