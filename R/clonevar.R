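#' Filter evolved-clone variants
#'
#' Applies, in order, the quality filters used before classifying de novo
#' variation in evolved clones sequenced alongside their ancestor:
#' multiallelic sites, sites that cannot be confidently called in the
#' ancestor (missing/uncalled genotype, genotype quality below `min_gq`, or
#' failing the depth rule in the ancestor), per-record depth (keep
#' `min_depth <= DP <= max_depth_mult x` the sample's median depth; strictly
#' more than double is removed), genotype quality (keep `GQ >= min_gq`), and
#' a region blacklist (mitochondria, telomeres, rDNA, mobile elements,
#' centromeres, pseudogenes and the like). Each removed row is attributed to
#' the first rule that caught it, so the report's removed counts are
#' additive.
#'
#' @param variants Long variant table: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `sample`, `gt`, `ad_ref`, `ad_alt`, `dp`, `gq`.
#' @param ancestor Sample id of the ancestor.
#' @param sample_median_depth Optional named vector of per-sample median
#'   depths (e.g. from genome-wide coverage); defaults to the median `dp`
#'   per sample within `variants`.
#' @param blacklist Optional interval tibble `chrom`, `start`, `end`
#'   (BED-style, 0-based half-open).
#' @param min_depth,max_depth_mult,min_gq Filter thresholds.
#' @return A list with `variants` (surviving rows) and `report` (tibble
#'   `rule`, `removed`, plus a `surviving` attribute row order:
#'   multiallelic, ancestor_uncertain, depth_low, depth_high, gq,
#'   blacklist).
#' @export
filter_variants <- function(variants, ancestor = "ancestor",
                            sample_median_depth = NULL, blacklist = NULL,
                            min_depth = 5, max_depth_mult = 2, min_gq = 99) {
  assert_columns(variants,
                 c("chrom", "pos", "ref", "alt", "sample", "gt",
                   "ad_ref", "ad_alt", "dp", "gq"), "variants")
  if (any(variants$pos < 1)) abort("positions must be 1-based (>= 1)")
  if (any(variants$ad_ref + variants$ad_alt > variants$dp, na.rm = TRUE)) {
    abort(sprintf("allele depths exceed total depth at row %d",
                  which(variants$ad_ref + variants$ad_alt > variants$dp)[1]))
  }
  if (is.null(sample_median_depth)) {
    med <- variants |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(m = median(.data$dp), .groups = "drop")
    sample_median_depth <- setNames(med$m, med$sample)
  }
  if (any(sample_median_depth <= 0)) abort("sample median depths must be > 0")

  v <- variants
  v$.site <- paste(v$chrom, v$pos, sep = ":")
  v$.rule <- NA_character_

  # multiallelic: more than one alt allele at a site, or a comma in ALT
  multi_sites <- unique(c(
    v$.site[grepl(",", v$alt)],
    {
      tab <- dplyr::distinct(v, .data$.site, .data$alt)
      tab$.site[tab$.site %in% tab$.site[duplicated(tab$.site)]]
    }))
  v$.rule[v$.site %in% multi_sites] <- "multiallelic"

  # record-level quality, used both for the ancestor-confidence rule and
  # for the per-record depth/GQ rules
  med_v <- unname(sample_median_depth[v$sample])
  rec_depth_low <- v$dp < min_depth
  rec_depth_high <- v$dp > max_depth_mult * med_v
  rec_gq <- v$gq < min_gq
  rec_uncalled <- is.na(v$gt) | v$gt == "./."

  anc <- v$sample == ancestor
  anc_bad_sites <- unique(v$.site[anc & (rec_depth_low | rec_depth_high |
                                           rec_gq | rec_uncalled)])
  anc_bad_sites <- union(anc_bad_sites, setdiff(unique(v$.site),
                                                unique(v$.site[anc])))
  sel <- is.na(v$.rule) & v$.site %in% anc_bad_sites
  v$.rule[sel] <- "ancestor_uncertain"

  sel <- is.na(v$.rule) & rec_depth_low
  v$.rule[sel] <- "depth_low"
  sel <- is.na(v$.rule) & rec_depth_high
  v$.rule[sel] <- "depth_high"
  sel <- is.na(v$.rule) & rec_gq
  v$.rule[sel] <- "gq"

  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    assert_columns(blacklist, c("chrom", "start", "end"), "blacklist")
    bl <- GenomicRanges::GRanges(
      blacklist$chrom,
      IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end))
    vr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    hit <- IRanges::overlapsAny(vr, bl)
    sel <- is.na(v$.rule) & hit
    v$.rule[sel] <- "blacklist"
  }

  rules <- c("multiallelic", "ancestor_uncertain", "depth_low",
             "depth_high", "gq", "blacklist")
  report <- tibble(
    rule = rules,
    removed = vapply(rules, function(r) sum(v$.rule == r, na.rm = TRUE),
                     integer(1)))
  surviving <- v[is.na(v$.rule), setdiff(names(v), c(".site", ".rule"))]
  report <- dplyr::bind_rows(report,
                             tibble(rule = "surviving",
                                    removed = nrow(surviving)))
  list(variants = surviving, report = report)
}

#' Classify variants of one evolved clone against its ancestor
#'
#' Classification is by alt-allele fraction computed from allele depths
#' (`ad_alt / (ad_ref + ad_alt)`), not genotype calls. With `a` the focal
#' clone's fraction and "outside" the ancestor plus all other clones:
#' \describe{
#'   \item{`de_novo_het`}{`a` in the closed interval [0.2, 0.8] while every
#'     outside sample is < 0.2 or > 0.8.}
#'   \item{`de_novo_hom`}{`a > 0.8` while every outside sample is < 0.2, or
#'     the mirror image.}
#'   \item{`LOH`}{`a < 0.2` or `a > 0.8` while every outside sample is
#'     strictly inside (0.2, 0.8) -- a heterozygous site resolved to one
#'     homozygous allele in the focal clone only.}
#'   \item{`none`}{anything else.}
#' }
#' Boundary conventions (closed focal het interval, strict LOH interval)
#' are recorded in the `conventions` attribute of the result. The same
#' fraction thresholds handle triploid ancestors, whose expected het
#' fractions 1/3 and 2/3 fall inside (0.2, 0.8).
#'
#' @param variants (Filtered) long variant table.
#' @param focal Sample id of the clone of interest.
#' @param ancestor Ancestor sample id (must differ from `focal`).
#' @param others Other sample ids; default all remaining samples.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `clone`, `category`,
#'   `focal_fraction`, `ancestor_fraction`, `resolved_allele` (for LOH /
#'   de_novo_hom: `"ref"` or `"alt"`).
#' @export
classify_variants <- function(variants, focal, ancestor = "ancestor",
                              others = NULL) {
  if (identical(focal, ancestor)) abort("`focal` must differ from `ancestor`")
  assert_columns(variants, c("chrom", "pos", "ref", "alt", "sample",
                             "ad_ref", "ad_alt"), "variants")
  others <- others %||% setdiff(unique(variants$sample), c(focal, ancestor))

  v <- variants |>
    dplyr::filter(.data$sample %in% c(focal, ancestor, others)) |>
    dplyr::mutate(frac = dplyr::if_else(
      .data$ad_ref + .data$ad_alt > 0,
      .data$ad_alt / (.data$ad_ref + .data$ad_alt), NA_real_))
  wide <- v |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample", "frac") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "frac")

  out_samples <- intersect(c(ancestor, others), names(wide))
  a_focal <- wide[[focal]]
  out_m <- as.matrix(wide[, out_samples, drop = FALSE])

  no_na <- function(x) ifelse(is.na(x), FALSE, x)
  all_extreme <- no_na(rowSums(out_m < 0.2 | out_m > 0.8) ==
                         length(out_samples))
  all_low <- no_na(rowSums(out_m < 0.2) == length(out_samples))
  all_high <- no_na(rowSums(out_m > 0.8) == length(out_samples))
  all_mid <- no_na(rowSums(out_m > 0.2 & out_m < 0.8) == length(out_samples))

  focal_het <- no_na(a_focal >= 0.2 & a_focal <= 0.8)
  focal_extreme <- no_na(a_focal < 0.2 | a_focal > 0.8)

  category <- rep("none", nrow(wide))
  category[!is.na(a_focal) & focal_het & all_extreme] <- "de_novo_het"
  category[!is.na(a_focal) &
             ((a_focal > 0.8 & all_low) | (a_focal < 0.2 & all_high))] <-
    "de_novo_hom"
  category[!is.na(a_focal) & focal_extreme & all_mid] <- "LOH"
  category[is.na(a_focal)] <- NA_character_

  res <- tibble(
    chrom = wide$chrom, pos = wide$pos, ref = wide$ref, alt = wide$alt,
    clone = focal, category = category,
    focal_fraction = a_focal,
    ancestor_fraction = if (ancestor %in% names(wide)) wide[[ancestor]] else NA_real_,
    resolved_allele = dplyr::case_when(
      category %in% c("LOH", "de_novo_hom") & a_focal > 0.8 ~ "alt",
      category %in% c("LOH", "de_novo_hom") & a_focal < 0.2 ~ "ref",
      TRUE ~ NA_character_))
  attr(res, "conventions") <- c(
    de_novo_het_focal = "[0.2, 0.8] closed",
    loh_outside = "(0.2, 0.8) strict")
  res
}

#' @describeIn classify_variants Classify every clone in the table against
#'   the ancestor.
#' @param clones Clone sample ids; default all non-ancestor samples.
#' @export
classify_clones <- function(variants, clones = NULL, ancestor = "ancestor") {
  clones <- clones %||% setdiff(unique(variants$sample), ancestor)
  purrr::map(clones, function(cl)
    classify_variants(variants, focal = cl, ancestor = ancestor)) |>
    dplyr::bind_rows()
}

#' Gene-level parallelism of high-impact de novo variants
#'
#' Counts, for each gene and (ancestral strain, environment) group, the
#' number of distinct evolved clones carrying at least one qualifying
#' variant (category not `none`, impact in `impact_filter`). Genes hit in
#' two or more groups are flagged as cross-group parallel; hits spanning
#' different ancestral backgrounds are additionally flagged, since such
#' overlap across backgrounds is the rarest form of convergence.
#'
#' @param classified Output of [classify_variants()]/[classify_clones()].
#' @param annotations Tibble `chrom`, `pos`, `alt`, `gene`, `impact`.
#' @param groups Tibble `clone`, `ancestor_strain`, `environment`.
#' @param impact_filter Impact labels that qualify (default frameshift and
#'   nonsense: the high-impact protein-coding classes).
#' @return A list with `tally` (tibble `gene`, `ancestor_strain`,
#'   `environment`, `n_clones`), `parallel` (tibble `gene`, `n_groups`,
#'   `n_backgrounds`, `cross_group`, `cross_background`) and `n_skipped`
#'   (variants without annotation).
#' @export
tally_parallel_genes <- function(classified, annotations, groups,
                                 impact_filter = c("frameshift", "nonsense")) {
  assert_columns(annotations, c("chrom", "pos", "alt", "gene", "impact"),
                 "annotations")
  assert_columns(groups, c("clone", "ancestor_strain", "environment"),
                 "groups")
  hits <- classified |>
    dplyr::filter(!is.na(.data$category), .data$category != "none") |>
    dplyr::left_join(annotations, by = c("chrom", "pos", "alt"))
  n_skipped <- sum(is.na(hits$gene))
  hits <- hits |>
    dplyr::filter(!is.na(.data$gene), .data$impact %in% impact_filter) |>
    dplyr::inner_join(groups, by = "clone")

  tally <- hits |>
    dplyr::distinct(.data$gene, .data$ancestor_strain, .data$environment,
                    .data$clone) |>
    dplyr::count(.data$gene, .data$ancestor_strain, .data$environment,
                 name = "n_clones")
  parallel <- tally |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      n_backgrounds = dplyr::n_distinct(.data$ancestor_strain),
      .groups = "drop") |>
    dplyr::mutate(cross_group = .data$n_groups >= 2,
                  cross_background = .data$n_backgrounds >= 2)
  list(tally = tally, parallel = parallel, n_skipped = n_skipped)
}

#' Compare the direction of coincident LOH events between two groups
#'
#' At a locus where clones from two groups (e.g. the same ancestor evolved
#' in two environments) both underwent LOH, reports whether they resolved
#' to the same homozygous allele: `convergent` (all clones in both groups
#' resolve the same allele), `divergent` (each group internally consistent
#' but the groups differ), `mixed` (disagreement within a group), or
#' `insufficient` (a group has no LOH call at the locus).
#'
#' @param classified Output of [classify_clones()].
#' @param chrom,pos Locus.
#' @param group_a,group_b Character vectors of clone ids.
#' @return A list with `direction` and `resolved` (tibble `clone`, `group`,
#'   `allele`).
#' @export
compare_loh_direction <- function(classified, chrom, pos, group_a, group_b) {
  loh <- classified |>
    dplyr::filter(.data$chrom == !!chrom, .data$pos == !!pos,
                  .data$category == "LOH",
                  .data$clone %in% c(group_a, group_b)) |>
    dplyr::mutate(group = dplyr::if_else(.data$clone %in% group_a, "a", "b"))
  resolved <- loh[, c("clone", "group", "resolved_allele")]
  names(resolved)[3] <- "allele"
  a <- unique(resolved$allele[resolved$group == "a"])
  b <- unique(resolved$allele[resolved$group == "b"])
  direction <- if (length(a) == 0 || length(b) == 0) {
    "insufficient"
  } else if (length(a) > 1 || length(b) > 1) {
    "mixed"
  } else if (a == b) {
    "convergent"
  } else {
    "divergent"
  }
  list(direction = direction, resolved = resolved)
}
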