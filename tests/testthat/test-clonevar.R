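# A small multi-sample table with known filtering outcomes.
filter_fixture <- function() {
  dplyr::bind_rows(
    variant_site("chrI", 100, c(ancestor = 0.5, clone1 = 0.0)),       # ok
    variant_site("chrI", 200, c(ancestor = 0.5, clone1 = 0.5)),       # ok
    variant_site("chrI", 300, c(ancestor = 0.5, clone1 = 0.5)) |>
      dplyr::mutate(alt = dplyr::if_else(sample == "clone1", "G,T", alt)),
    variant_site("chrI", 400, c(ancestor = 0.5, clone1 = 0.5), dp = 30L) |>
      dplyr::mutate(dp = dplyr::if_else(sample == "clone1", 4L, dp),
                    ad_ref = dplyr::if_else(sample == "clone1", 2L, ad_ref),
                    ad_alt = dplyr::if_else(sample == "clone1", 2L, ad_alt)),
    variant_site("chrI", 500, c(ancestor = 0.5, clone1 = 0.5)) |>
      dplyr::mutate(gq = dplyr::if_else(sample == "clone1", 98L, gq)),
    variant_site("chrI", 600, c(ancestor = 0.5, clone1 = 0.5)) |>
      dplyr::mutate(gq = dplyr::if_else(sample == "ancestor", 50L, gq)),
    variant_site("chrI", 700, c(ancestor = 0.5, clone1 = 0.5), dp = 60L),
    variant_site("chrI", 800, c(ancestor = 0.5, clone1 = 0.5)) |>
      dplyr::mutate(dp = dplyr::if_else(sample == "clone1", 61L, dp)),
    variant_site("chrII", 50, c(ancestor = 0.5, clone1 = 0.5))        # blacklisted
  )
}

test_that("variant filters apply the stated thresholds in order", {
  v <- filter_fixture()
  med <- c(ancestor = 30, clone1 = 30)
  bl <- tibble::tibble(chrom = "chrII", start = 0L, end = 1000L)
  res <- filter_variants(v, sample_median_depth = med, blacklist = bl)
  rep <- setNames(res$report$removed, res$report$rule)
  expect_equal(unname(rep["multiallelic"]), 2L)       # both rows at the site
  expect_equal(unname(rep["ancestor_uncertain"]), 2L) # pos 600
  expect_equal(unname(rep["depth_low"]), 1L)          # clone1 at pos 400
  expect_equal(unname(rep["depth_high"]), 1L)         # clone1 at 61 > 2 x 30
  expect_equal(unname(rep["gq"]), 1L)                 # clone1 at pos 500
  expect_equal(unname(rep["blacklist"]), 2L)          # chrII site
  expect_equal(sum(res$report$removed[res$report$rule != "surviving"]) +
                 nrow(res$variants), nrow(v))
  # depth exactly 2 x median is kept ("more than double" is strict)
  expect_true(any(res$variants$pos == 700 & res$variants$dp == 60))
  # coverage less than 5 removed, GQ < 99 removed
  expect_false(any(res$variants$pos == 400 & res$variants$sample == "clone1"))
  expect_false(any(res$variants$pos == 500 & res$variants$sample == "clone1"))
})

test_that("filtering is idempotent", {
  v <- filter_fixture()
  med <- c(ancestor = 30, clone1 = 30)
  once <- filter_variants(v, sample_median_depth = med)
  twice <- filter_variants(once$variants, sample_median_depth = med)
  expect_equal(twice$variants, once$variants)
  expect_equal(sum(twice$report$removed[twice$report$rule != "surviving"]), 0)
})

test_that("blacklist intervals are interpreted as 0-based half-open", {
  v <- dplyr::bind_rows(
    variant_site("chrI", 10, c(ancestor = 0.5, clone1 = 0.5)),
    variant_site("chrI", 11, c(ancestor = 0.5, clone1 = 0.5)))
  # BED [0, 10) covers 1-based positions 1..10 only
  bl <- tibble::tibble(chrom = "chrI", start = 0L, end = 10L)
  res <- filter_variants(v, sample_median_depth = c(ancestor = 30, clone1 = 30),
                         blacklist = bl)
  expect_false(any(res$variants$pos == 10))
  expect_true(any(res$variants$pos == 11))
})

test_that("classification follows the allele-fraction threshold rules", {
  v <- dplyr::bind_rows(
    variant_site("chrI", 1, c(ancestor = 0.0, clone1 = 0.5, clone2 = 0.0)),
    variant_site("chrI", 2, c(ancestor = 0.5, clone1 = 0.02, clone2 = 0.5)),
    variant_site("chrI", 3, c(ancestor = 0.5, clone1 = 0.5, clone2 = 0.5)),
    variant_site("chrI", 4, c(ancestor = 0.0, clone1 = 1.0, clone2 = 0.0)),
    variant_site("chrI", 5, c(ancestor = 0.5, clone1 = 0.97, clone2 = 0.5)))
  cl <- classify_variants(v, focal = "clone1")
  expect_equal(cl$category[cl$pos == 1], "de_novo_het")
  expect_equal(cl$category[cl$pos == 2], "LOH")
  expect_equal(cl$resolved_allele[cl$pos == 2], "ref")
  expect_equal(cl$category[cl$pos == 3], "none")
  expect_equal(cl$category[cl$pos == 4], "de_novo_hom")
  expect_equal(cl$category[cl$pos == 5], "LOH")
  expect_equal(cl$resolved_allele[cl$pos == 5], "alt")
  expect_error(classify_variants(v, focal = "ancestor"), "differ")
})

test_that("classification assigns exactly one category per surviving row", {
  set.seed(7)
  fracs <- replicate(50, setNames(sample(c(0, 0.02, 0.3, 0.5, 0.7, 0.97, 1), 3,
                                         replace = TRUE),
                                  c("ancestor", "clone1", "clone2")),
                     simplify = FALSE)
  v <- dplyr::bind_rows(purrr::imap(fracs, function(f, i)
    variant_site("chrI", i, f)))
  cl <- classify_variants(v, focal = "clone1")
  expect_equal(nrow(cl), 50)
  expect_true(all(cl$category %in%
                    c("de_novo_het", "de_novo_hom", "LOH", "none")))
})

test_that("injected events are recovered end to end at zero depth noise", {
  events <- tibble::tibble(
    clone = c(1, 1, 1, 2, 2),
    type = c("het_snv", "hom_snv", "loh_tract", "loh_tract", "loh_tract"),
    chrom = c("chrI", "chrI", "chrII", "chrI", "chrII"),
    start = c(5000, 9000, 20000, 40000, 100000),
    end = c(NA, NA, 60000, 80000, 140000),
    allele = c(NA, NA, "ref", "alt", "ref"))
  gg <- make_clone_genomes(2, events = events, depth_noise = "none",
                           emit_depth = FALSE, seed = 71)
  cl <- classify_clones(gg$variants)

  # expected LOH sites: ancestral het sites inside each clone's tracts
  anc <- gg$variants[gg$variants$sample == "ancestor", ]
  het_sites <- anc[anc$ad_alt / anc$dp > 0.2 & anc$ad_alt / anc$dp < 0.8, ]
  for (cl_id in c("clone1", "clone2")) {
    tr <- events[events$type == "loh_tract" &
                   sprintf("clone%d", events$clone) == cl_id, ]
    expected <- purrr::pmap(tr, function(chrom, start, end, ...) {
      het_sites[het_sites$chrom == chrom & het_sites$pos >= start &
                  het_sites$pos <= end, c("chrom", "pos")]
    }) |> dplyr::bind_rows()
    got <- cl[cl$clone == cl_id & cl$category == "LOH" & !is.na(cl$category),
              c("chrom", "pos")]
    expect_equal(dplyr::arrange(got, chrom, pos),
                 dplyr::arrange(expected, chrom, pos), ignore_attr = TRUE)
  }
  # injected SNVs called with the right category, and nothing else
  c1 <- cl[cl$clone == "clone1", ]
  expect_equal(c1$category[c1$chrom == "chrI" & c1$pos == 5000], "de_novo_het")
  expect_equal(c1$category[c1$chrom == "chrI" & c1$pos == 9000], "de_novo_hom")
  expect_equal(sum(c1$category %in% c("de_novo_het", "de_novo_hom")), 2)
})

test_that("an LOH tract with no underlying het sites is skipped with a warning", {
  events <- tibble::tibble(clone = 1, type = "loh_tract", chrom = "chrI",
                           start = 1, end = 50, allele = "ref")
  expect_warning(
    gg <- make_clone_genomes(1, events = events, het_density = 1e-5,
                             depth_noise = "none", emit_depth = FALSE,
                             seed = 3),
    "skipped")
  expect_equal(gg$truth$status, "skipped")
})

test_that("clones with no events are identical to the ancestor", {
  gg <- make_clone_genomes(2, depth_noise = "none", emit_depth = FALSE,
                           seed = 5)
  wide <- gg$variants |>
    dplyr::select(chrom, pos, sample, ad_alt, dp) |>
    tidyr::pivot_wider(names_from = sample, values_from = c(ad_alt, dp))
  expect_equal(wide$ad_alt_clone1, wide$ad_alt_ancestor)
  expect_equal(wide$ad_alt_clone2, wide$ad_alt_ancestor)
  cl <- classify_clones(gg$variants)
  expect_true(all(cl$category == "none"))
})

test_that("gene tallies count clones, not variants, and flag parallelism", {
  classified <- tibble::tibble(
    chrom = "chrI", pos = c(10, 20, 30, 40, 50),
    ref = "A", alt = "T",
    clone = c("c1", "c1", "c2", "c3", "c4"),
    category = c("de_novo_het", "de_novo_het", "de_novo_hom", "de_novo_het",
                 "de_novo_het"),
    focal_fraction = 0.5, ancestor_fraction = 0,
    resolved_allele = NA_character_)
  annotations <- tibble::tibble(
    chrom = "chrI", pos = c(10, 20, 30, 40, 50), alt = "T",
    gene = c("SKG3", "SKG3", "SKG3", "PKH", "SKG3"),
    impact = c("frameshift", "nonsense", "frameshift", "frameshift",
               "missense"))
  groups <- tibble::tibble(
    clone = c("c1", "c2", "c3", "c4"),
    ancestor_strain = c("AMA", "BEP", "AMA", "AMA"),
    environment = c("M3", "M3", "M3-5GLU", "M3"))
  res <- tally_parallel_genes(classified, annotations, groups)
  # c1 has two qualifying SKG3 variants but counts once
  expect_equal(res$tally$n_clones[res$tally$gene == "SKG3" &
                                    res$tally$ancestor_strain == "AMA"], 1L)
  skg3 <- res$parallel[res$parallel$gene == "SKG3", ]
  expect_true(skg3$cross_group)
  expect_true(skg3$cross_background)
  pkh <- res$parallel[res$parallel$gene == "PKH", ]
  expect_false(pkh$cross_group)
  # the missense variant (c4) does not qualify
  expect_false(any(res$tally$gene == "SKG3" & res$tally$n_clones > 1))
})

test_that("parallel genes injected in simulation are exactly the flagged ones", {
  events <- tibble::tibble(
    clone = c(1, 2, 3, 3),
    type = "het_snv",
    chrom = c("chrI", "chrI", "chrI", "chrII"),
    start = c(1000, 2000, 3000, 1000))
  gg <- make_clone_genomes(3, events = events, depth_noise = "none",
                           emit_depth = FALSE, seed = 9)
  cl <- classify_clones(gg$variants)
  annotations <- tibble::tibble(
    chrom = c("chrI", "chrI", "chrI", "chrII"),
    pos = c(1000, 2000, 3000, 1000),
    alt = gg$variants$alt[match(paste(chrom, pos),
                                paste(gg$variants$chrom, gg$variants$pos))],
    gene = c("GENE_A", "GENE_A", "GENE_A", "GENE_B"),
    impact = "frameshift")
  groups <- tibble::tibble(clone = c("clone1", "clone2", "clone3"),
                           ancestor_strain = c("X", "Y", "X"),
                           environment = c("E1", "E1", "E2"))
  res <- tally_parallel_genes(cl, annotations, groups)
  expect_setequal(res$parallel$gene[res$parallel$cross_group],
                  "GENE_A")
  expect_setequal(res$parallel$gene[res$parallel$cross_background],
                  "GENE_A")
})

test_that("coincident LOH direction is compared across groups", {
  base <- tibble::tibble(
    chrom = "chrI", pos = 100, ref = "A", alt = "T",
    category = "LOH", focal_fraction = NA_real_,
    ancestor_fraction = 0.5)
  mk <- function(clone, allele) dplyr::mutate(base, clone = clone,
                                              resolved_allele = allele)
  cl_div <- dplyr::bind_rows(mk("a1", "ref"), mk("a2", "ref"),
                             mk("b1", "alt"), mk("b2", "alt"))
  expect_equal(compare_loh_direction(cl_div, "chrI", 100,
                                     c("a1", "a2"), c("b1", "b2"))$direction,
               "divergent")
  cl_conv <- dplyr::bind_rows(mk("a1", "alt"), mk("b1", "alt"))
  expect_equal(compare_loh_direction(cl_conv, "chrI", 100, "a1", "b1")$direction,
               "convergent")
  cl_mixed <- dplyr::bind_rows(mk("a1", "ref"), mk("a2", "alt"),
                               mk("b1", "ref"))
  expect_equal(compare_loh_direction(cl_mixed, "chrI", 100,
                                     c("a1", "a2"), "b1")$direction,
               "mixed")
  expect_equal(compare_loh_direction(cl_conv, "chrI", 100, "a1", "zz")$direction,
               "insufficient")
})
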