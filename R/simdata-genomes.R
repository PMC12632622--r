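#' Synthetic evolved-clone genomes with injected mutations
#'
#' Generates an ancestor plus `n_clones` evolved-clone genomes over a small
#' yeast-like genome, emitting (i) a multi-sample variant table with
#' genotype, allele depths, total depth and genotype quality, (ii) per-base
#' depth tables consistent with injected aneuploidies and segmental
#' amplifications, and (iii) a truth log of every injected event -- the
#' ground truth for validating the variant classifier and karyotype caller.
#'
#' The ancestor carries heterozygous sites at density `het_density`
#' (alt-allele fraction `1/base_ploidy`). Injectable events (rows of
#' `events`):
#' \describe{
#'   \item{`het_snv`}{new heterozygous SNV in the focal clone at `start`.}
#'   \item{`hom_snv`}{new homozygous SNV (fraction 1) at `start`.}
#'   \item{`loh_tract`}{ancestral het sites in `[start, end]` become
#'     homozygous for `allele` (`"ref"` or `"alt"`); tracts covering no het
#'     site are skipped with a warning and logged as `skipped`.}
#'   \item{`aneuploidy`}{whole-chromosome copy number set to `copies`,
#'     scaling expected depth by `copies / base_ploidy`.}
#'   \item{`segmental_amp`}{copy number `copies` over `[start, end]` only.}
#' }
#'
#' @param n_clones Number of evolved clones.
#' @param events Tibble `clone` (1-based index or `"cloneN"` id), `type`,
#'   `chrom`, `start`, `end`, `copies`, `allele`; `NULL` for none.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param het_density Ancestral heterozygous sites per bp.
#' @param base_ploidy Ancestral ploidy (2 = diploid; 3 supported).
#' @param depth_mean Mean sequencing depth at copy ratio 1.
#' @param depth_noise `"poisson"` or `"none"` (exact expected depths).
#' @param gq Genotype quality written for all calls.
#' @param emit_depth If `FALSE`, skip the (large) per-base depth table.
#' @param seed Optional integer seed.
#' @return A list `variants` (long tibble `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `gt`, `ad_ref`, `ad_alt`, `dp`, `gq`), `depth` (tibble
#'   `sample`, `chrom`, `pos`, `depth`), `truth` (event log with `status`
#'   and `n_sites`).
#' @export
make_clone_genomes <- function(n_clones, events = NULL,
                               chrom_sizes = c(chrI = 150000, chrII = 200000,
                                               chrIII = 120000, chrIV = 180000),
                               het_density = 5e-4, base_ploidy = 2,
                               depth_mean = 30,
                               depth_noise = c("poisson", "none"),
                               gq = 99L, emit_depth = TRUE, seed = NULL) {
  assert_scalar_number(n_clones, "n_clones", lower = 1)
  assert_scalar_number(het_density, "het_density", lower = 0)
  assert_scalar_number(depth_mean, "depth_mean", lower = 0, strict_lower = TRUE)
  depth_noise <- match.arg(depth_noise)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    abort("`chrom_sizes` must be a named vector")
  }
  set_stage_seed(seed, "genomes")
  n_clones <- as.integer(n_clones)
  clones <- sprintf("clone%d", seq_len(n_clones))
  samples <- c("ancestor", clones)
  bases <- c("A", "C", "G", "T")

  # ancestral heterozygous sites
  anc <- purrr::imap(chrom_sizes, function(len, chrom) {
    n_het <- rbinom(1L, size = as.integer(len), prob = het_density)
    if (n_het == 0) return(NULL)
    pos <- sort(sample.int(as.integer(len), n_het))
    ref <- sample(bases, n_het, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
           ancestral_het = TRUE)
  })
  sites <- dplyr::bind_rows(anc)
  if (nrow(sites) == 0) {
    sites <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), ancestral_het = logical())
  }

  # normalise events
  if (!is.null(events) && nrow(events) > 0) {
    assert_columns(events, c("clone", "type", "chrom"), "events")
    events$clone_id <- ifelse(grepl("^clone", as.character(events$clone)),
                              as.character(events$clone),
                              sprintf("clone%d", as.integer(events$clone)))
    for (col in c("start", "end", "copies", "allele")) {
      if (!col %in% names(events)) events[[col]] <- NA
    }
    bad <- !events$chrom %in% names(chrom_sizes)
    if (any(bad)) abort(sprintf("event chrom not in genome: %s",
                                paste(unique(events$chrom[bad]), collapse = ", ")))
    oob <- !is.na(events$start) &
      (events$start < 1 | events$start > chrom_sizes[events$chrom])
    if (any(oob)) abort("event coordinates outside chromosome bounds")
  } else {
    events <- tibble(clone = integer(), type = character(),
                     chrom = character(), start = double(), end = double(),
                     copies = double(), allele = character(),
                     clone_id = character())
  }

  # new SNV sites
  snv_ev <- events[events$type %in% c("het_snv", "hom_snv"), ]
  if (nrow(snv_ev) > 0) {
    ref <- sample(bases, nrow(snv_ev), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    new_sites <- tibble(chrom = snv_ev$chrom, pos = as.integer(snv_ev$start),
                        ref = ref, alt = unname(alt), ancestral_het = FALSE)
    sites <- dplyr::bind_rows(sites, new_sites) |>
      dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  }
  sites <- dplyr::arrange(sites, match(.data$chrom, names(chrom_sizes)),
                          .data$pos)
  n_sites <- nrow(sites)

  # true alt-allele fraction per sample x site
  het_frac <- 1 / base_ploidy
  frac <- matrix(0, nrow = n_sites, ncol = length(samples),
                 dimnames = list(NULL, samples))
  frac[sites$ancestral_het, ] <- het_frac

  # copy-ratio multipliers per sample (chrom-wide and segmental)
  chrom_mult <- matrix(1, nrow = length(chrom_sizes), ncol = length(samples),
                       dimnames = list(names(chrom_sizes), samples))
  seg_mult <- list()  # per sample: list of (chrom, start, end, ratio)

  truth_rows <- list()
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    cl <- ev$clone_id
    status <- "injected"
    ns <- NA_integer_
    if (ev$type %in% c("het_snv", "hom_snv")) {
      i <- which(sites$chrom == ev$chrom & sites$pos == as.integer(ev$start))
      frac[i, cl] <- if (ev$type == "het_snv") het_frac else 1
      ns <- 1L
    } else if (ev$type == "loh_tract") {
      i <- which(sites$chrom == ev$chrom & sites$ancestral_het &
                   sites$pos >= ev$start & sites$pos <= ev$end)
      if (length(i) == 0) {
        warn(sprintf("LOH tract %s:%g-%g covers no ancestral het site; skipped",
                     ev$chrom, ev$start, ev$end))
        status <- "skipped"
      } else {
        allele <- if (is.na(ev$allele)) sample(c("ref", "alt"), 1L) else ev$allele
        frac[i, cl] <- if (allele == "alt") 1 else 0
        events$allele[k] <- allele
        ns <- length(i)
      }
    } else if (ev$type == "aneuploidy") {
      chrom_mult[ev$chrom, cl] <- ev$copies / base_ploidy
    } else if (ev$type == "segmental_amp") {
      seg_mult[[length(seg_mult) + 1L]] <-
        list(sample = cl, chrom = ev$chrom, start = ev$start, end = ev$end,
             ratio = ev$copies / base_ploidy)
    } else {
      abort(sprintf("unknown event type `%s`", ev$type))
    }
    truth_rows[[k]] <- tibble(
      clone = cl, type = ev$type, chrom = ev$chrom,
      start = ev$start, end = ev$end, copies = ev$copies,
      allele = events$allele[k], n_sites = ns, status = status)
  }
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble(clone = character(), type = character(), chrom = character(),
           start = double(), end = double(), copies = double(),
           allele = character(), n_sites = integer(), status = character())

  # local copy ratio at a site for a sample
  site_ratio <- function(sample) {
    r <- chrom_mult[sites$chrom, sample]
    for (sg in seg_mult) {
      if (sg$sample != sample) next
      i <- sites$chrom == sg$chrom & sites$pos >= sg$start & sites$pos <= sg$end
      r[i] <- sg$ratio
    }
    r
  }

  # variant table
  var_rows <- purrr::map(samples, function(sm) {
    a <- frac[, sm]
    exp_dp <- depth_mean * site_ratio(sm)
    if (depth_noise == "poisson") {
      dp <- rpois(n_sites, exp_dp)
      ad_alt <- rbinom(n_sites, size = dp, prob = a)
    } else {
      dp <- as.integer(round(exp_dp))
      ad_alt <- as.integer(round(a * dp))
    }
    gt <- dplyr::case_when(
      dp == 0 ~ "./.",
      ad_alt / pmax(dp, 1) < 0.2 ~ "0/0",
      ad_alt / pmax(dp, 1) > 0.8 ~ "1/1",
      TRUE ~ "0/1")
    tibble(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
           alt = sites$alt, sample = sm, gt = gt,
           ad_ref = as.integer(dp - ad_alt), ad_alt = as.integer(ad_alt),
           dp = as.integer(dp), gq = as.integer(gq))
  })
  variants <- dplyr::bind_rows(var_rows)

  # per-base depth tables
  depth <- NULL
  if (emit_depth) {
    depth <- purrr::map(samples, function(sm) {
      per_chrom <- purrr::imap(chrom_sizes, function(len, chrom) {
        len <- as.integer(len)
        mult <- rep(chrom_mult[chrom, sm], len)
        for (sg in seg_mult) {
          if (sg$sample == sm && sg$chrom == chrom) {
            mult[sg$start:min(sg$end, len)] <- sg$ratio
          }
        }
        d <- if (depth_noise == "poisson") rpois(len, depth_mean * mult)
             else as.integer(round(depth_mean * mult))
        tibble(sample = sm, chrom = chrom, pos = seq_len(len),
               depth = as.integer(d))
      })
      dplyr::bind_rows(per_chrom)
    })
    depth <- dplyr::bind_rows(depth)
  }

  list(variants = variants, depth = depth, truth = truth)
}
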