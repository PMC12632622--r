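#' Distribution specifications for synthetic strain pools
#'
#' Constructors returning sampler functions used by [make_pool()]. The
#' default wild-strain fitness model is a mixture of a normal bulk and an
#' exponential right tail, reflecting pooled natural isolates in which most
#' strains sit near the pool average while a few carry a large advantage in
#' a given environment.
#'
#' @param mean,sd Bulk component: mean and standard deviation of the
#'   per-generation selection coefficient (natural-log units).
#' @param tail_frac Fraction of strains drawn from the exponential tail.
#' @param tail_mean Mean of the exponential tail component (added to `mean`).
#' @return A function of `n` returning `n` draws.
#' @export
fitness_mixture <- function(mean = 0, sd = 0.03, tail_frac = 0.05,
                            tail_mean = 0.05) {
  assert_scalar_number(sd, "sd", lower = 0)
  assert_scalar_number(tail_frac, "tail_frac", lower = 0, upper = 1)
  assert_scalar_number(tail_mean, "tail_mean", lower = 0)
  force(mean)
  function(n) {
    in_tail <- runif(n) < tail_frac
    x <- rnorm(n, mean = mean, sd = sd)
    x[in_tail] <- mean + rexp(sum(in_tail), rate = 1 / max(tail_mean, 1e-12))
    x
  }
}

#' @param sdlog Log-scale standard deviation of initial-frequency draws
#'   (renormalised, so only the spread matters).
#' @rdname fitness_mixture
#' @export
freq_lognormal <- function(sdlog = 1) {
  assert_scalar_number(sdlog, "sdlog", lower = 0)
  function(n) stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' @rdname fitness_mixture
#' @export
freq_uniform <- function() {
  function(n) rep(1, n)
}

# Random unique barcodes with a guaranteed minimum pairwise edit distance,
# as barcode libraries are designed to tolerate sequencing errors.
random_barcodes <- function(n, length = 20L, min_dist = 3L, max_tries = 50L) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
    cand <- unique(cand)
    for (bc in cand) {
      if (length(out) == 0L || min(adist(bc, out)) >= min_dist) {
        out <- c(out, bc)
        if (length(out) == n) break
      }
    }
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("could not generate enough barcodes at the requested `min_dist`; lower it or shorten the pool")
    }
  }
  out
}

#' Generate a synthetic barcoded strain pool
#'
#' Builds a pool of wild strains plus neutral reference barcodes, mimicking a
#' pooled competition inoculum in which a barcoded lab reference strain is
#' spiked in at a fixed mass fraction (default 9:1 wild:reference) to anchor
#' the fitness scale and calibrate sequencing noise.
#'
#' @param n_wild Number of wild strains (>= 1).
#' @param n_reference Number of reference barcodes; these share
#'   `reference_mass` equally and have true fitness 0 by construction.
#' @param reference_mass Total initial frequency of the reference barcodes,
#'   in (0, 1). Default 0.1 (a 9:1 wild:reference mix).
#' @param fitness,freq Sampler functions for wild-strain fitness and
#'   (unnormalised) initial frequency; see [fitness_mixture()].
#' @param barcode_length Barcode length in bp.
#' @param barcode_min_dist Minimum pairwise edit distance among barcodes.
#' @param seed Optional integer seed.
#' @return A tibble with columns `strain_id`, `barcode`, `true_fitness`,
#'   `init_freq`, `is_reference`; `init_freq` sums to 1.
#' @examples
#' pool <- make_pool(n_wild = 20, n_reference = 3, seed = 1)
#' sum(pool$init_freq)
#' @export
make_pool <- function(n_wild, n_reference = 6L, reference_mass = 0.1,
                      fitness = fitness_mixture(), freq = freq_lognormal(),
                      barcode_length = 20L, barcode_min_dist = 3L,
                      seed = NULL) {
  assert_scalar_number(n_wild, "n_wild", lower = 1)
  assert_scalar_number(n_reference, "n_reference", lower = 0)
  assert_scalar_number(reference_mass, "reference_mass",
                       lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (!is.function(fitness)) abort("`fitness` must be a sampler function; see fitness_mixture()")
  if (!is.function(freq)) abort("`freq` must be a sampler function; see freq_lognormal()")
  set_stage_seed(seed, "pool")

  n_wild <- as.integer(n_wild)
  n_reference <- as.integer(n_reference)
  s_wild <- fitness(n_wild)
  w <- freq(n_wild)
  if (any(!is.finite(w)) || any(w < 0) || sum(w) == 0) {
    abort("`freq` sampler returned non-finite or negative weights")
  }
  f_wild <- w / sum(w) * (1 - reference_mass)

  barcodes <- random_barcodes(n_wild + n_reference, length = barcode_length,
                              min_dist = barcode_min_dist)
  wild_ids <- sprintf("S%03d", seq_len(n_wild))
  ref_ids <- if (n_reference > 0) sprintf("REF%02d", seq_len(n_reference)) else character(0)

  tibble(
    strain_id = c(wild_ids, ref_ids),
    barcode = barcodes,
    true_fitness = c(s_wild, rep(0, n_reference)),
    init_freq = c(f_wild, rep(reference_mass / max(n_reference, 1), n_reference)),
    is_reference = c(rep(FALSE, n_wild), rep(TRUE, n_reference))
  )
}

#' Simulate a serial-dilution pooled competition
#'
#' Propagates lineage frequencies through repeated batch-growth/dilution
#' cycles. Each cycle applies deterministic selection
#' \eqn{f_i \propto f_i e^{g s_i}} followed by renormalisation; a finite
#' bottleneck then resamples the next cycle's founding frequencies
#' multinomially (the source of drift). Beneficial mutations found new
#' sublineages whose fitness is the parent's plus an exponential increment;
#' sublineages are tracked internally but observations are always aggregated
#' per founding barcode, because barcodes -- not mutations -- are sequenced.
#'
#' @param pool A pool tibble from [make_pool()].
#' @param n_transfers Number of transfers (>= 1).
#' @param g Generations per transfer; default 8 (`round(log2(250))` for a
#'   1:250 dilution).
#' @param bottleneck Cells transferred per cycle; `Inf` for deterministic
#'   dynamics. Default `1e5`, a desk-scale stand-in for the much larger
#'   experimental bottleneck.
#' @param mutation_rate Per-lineage per-transfer probability of founding a
#'   beneficial sublineage (requires a finite bottleneck; new sublineages
#'   start at frequency `1/bottleneck`).
#' @param dfe_mean Mean of the exponential fitness-increment distribution.
#' @param seed Optional integer seed.
#' @return A `competition_trajectory`: list with `freq` (lineage x timepoint
#'   matrix, columns `T0..Tn`, each summing to 1), `lineages` (tibble
#'   `lineage_id`, `strain_id`, `fitness`), `mutation_log`, `g`, `bottleneck`.
#' @examples
#' pool <- make_pool(10, 2, seed = 1)
#' traj <- simulate_competition(pool, n_transfers = 5, bottleneck = Inf)
#' colSums(traj$freq)
#' @export
simulate_competition <- function(pool, n_transfers, g = 8,
                                 bottleneck = 1e5, mutation_rate = 0,
                                 dfe_mean = 0.05, seed = NULL) {
  assert_columns(pool, c("strain_id", "true_fitness", "init_freq"), "pool")
  assert_scalar_number(n_transfers, "n_transfers", lower = 1)
  assert_scalar_number(g, "g", lower = 0, strict_lower = TRUE)
  if (!identical(bottleneck, Inf)) {
    assert_scalar_number(bottleneck, "bottleneck", lower = 1)
  }
  assert_scalar_number(mutation_rate, "mutation_rate", lower = 0)
  if (mutation_rate > 0 && is.infinite(bottleneck)) {
    abort("`mutation_rate` > 0 requires a finite `bottleneck` (new sublineages start at 1/bottleneck)")
  }
  set_stage_seed(seed, "compete")

  n_transfers <- as.integer(n_transfers)
  lineage_id <- pool$strain_id
  founder <- pool$strain_id
  s <- pool$true_fitness
  f <- pool$init_freq / sum(pool$init_freq)

  freq_cols <- vector("list", n_transfers + 1L)
  freq_cols[[1L]] <- f
  mut_log <- list()

  for (t in seq_len(n_transfers)) {
    # deterministic within-cycle selection
    w <- f * exp(g * s)
    f <- w / sum(w)
    # bottleneck drift
    if (is.finite(bottleneck)) {
      n <- as.vector(rmultinom(1L, size = as.integer(bottleneck), prob = f))
      f <- n / bottleneck
    }
    # beneficial mutations found new sublineages
    if (mutation_rate > 0) {
      alive <- which(f > 0)
      mutated <- alive[runif(length(alive)) < mutation_rate]
      for (i in mutated) {
        inc <- rexp(1L, rate = 1 / dfe_mean)
        new_id <- sprintf("%s.m%d", lineage_id[i], length(mut_log) + 1L)
        seed_f <- 1 / bottleneck
        if (f[i] <= seed_f) next  # parent too rare to seed a cell
        f[i] <- f[i] - seed_f
        lineage_id <- c(lineage_id, new_id)
        founder <- c(founder, founder[i])
        s <- c(s, s[i] + inc)
        f <- c(f, seed_f)
        mut_log[[length(mut_log) + 1L]] <- tibble(
          transfer = t, parent_lineage = lineage_id[i],
          new_lineage = new_id, fitness_increment = inc
        )
      }
    }
    freq_cols[[t + 1L]] <- f
  }

  n_lin <- length(lineage_id)
  freq <- matrix(0, nrow = n_lin, ncol = n_transfers + 1L,
                 dimnames = list(lineage_id, tp_label(0:n_transfers)))
  for (t in seq_len(n_transfers + 1L)) {
    v <- freq_cols[[t]]
    freq[seq_along(v), t] <- v
  }

  structure(
    list(
      freq = freq,
      lineages = tibble(lineage_id = lineage_id, strain_id = founder,
                        fitness = s),
      mutation_log = if (length(mut_log)) dplyr::bind_rows(mut_log) else
        tibble(transfer = integer(), parent_lineage = character(),
               new_lineage = character(), fitness_increment = double()),
      g = g, bottleneck = bottleneck
    ),
    class = "competition_trajectory"
  )
}

#' @export
print.competition_trajectory <- function(x, ...) {
  cat(sprintf(
    "<competition_trajectory> %d lineages (%d founders), %d transfers, g = %g, bottleneck = %s\n",
    nrow(x$freq), dplyr::n_distinct(x$lineages$strain_id),
    ncol(x$freq) - 1L, x$g,
    if (is.finite(x$bottleneck)) format(x$bottleneck) else "Inf"))
  invisible(x)
}

#' Observable per-barcode frequencies of a simulated trajectory
#'
#' Aggregates sublineages by their founding barcode: the quantity an
#' amplicon-sequencing readout can actually observe.
#'
#' @param traj A `competition_trajectory`.
#' @return A tibble `strain_id`, `timepoint` (integer transfer index),
#'   `freq`.
#' @export
barcode_frequencies <- function(traj) {
  stopifnot(inherits(traj, "competition_trajectory"))
  long <- as_tibble(traj$freq, rownames = "lineage_id") |>
    tidyr::pivot_longer(-"lineage_id", names_to = "timepoint",
                        values_to = "freq") |>
    dplyr::mutate(timepoint = as.integer(sub("^T", "", .data$timepoint))) |>
    dplyr::left_join(traj$lineages[, c("lineage_id", "strain_id")],
                     by = "lineage_id")
  long |>
    dplyr::group_by(.data$strain_id, .data$timepoint) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop")
}

#' Simulate amplicon read counts from a trajectory
#'
#' Draws per-barcode read counts under the observation model the fitness
#' inference assumes: the count for barcode *b* at timepoint *t* is a
#' negative-binomial variable with mean \eqn{f_b(t) R_t} and variance
#' \eqn{\kappa_t f_b(t) R_t} (Gamma-Poisson construction); `dispersion = 1`
#' degenerates to Poisson. With `condition_total = TRUE` the column totals
#' are exactly `depth` (multinomial over Gamma-perturbed frequencies).
#'
#' @param traj A `competition_trajectory`.
#' @param depth Total reads per timepoint; scalar or vector over timepoints.
#' @param dispersion Variance-to-mean ratio kappa (>= 1); scalar or vector
#'   over timepoints.
#' @param condition_total If `TRUE`, condition each timepoint's counts on
#'   summing exactly to its depth.
#' @param seed Optional integer seed.
#' @return A tibble `strain_id`, `timepoint`, `reads`, with attributes
#'   `depth` and `dispersion`.
#' @export
sample_reads <- function(traj, depth, dispersion = 1,
                         condition_total = FALSE, seed = NULL) {
  stopifnot(inherits(traj, "competition_trajectory"))
  n_tp <- ncol(traj$freq)
  depth <- rep_len(depth, n_tp)
  dispersion <- rep_len(dispersion, n_tp)
  if (any(depth < 0)) abort("`depth` must be non-negative")
  if (any(dispersion < 1)) abort("`dispersion` (kappa) must be >= 1")
  set_stage_seed(seed, "reads")

  bc <- barcode_frequencies(traj)
  wide <- tidyr::pivot_wider(bc, names_from = "timepoint",
                             values_from = "freq")
  f <- as.matrix(wide[, -1, drop = FALSE])
  counts <- matrix(0L, nrow = nrow(f), ncol = n_tp)
  for (t in seq_len(n_tp)) {
    mu <- f[, t] * depth[t]
    kap <- dispersion[t]
    if (condition_total) {
      w <- if (kap > 1) {
        shape <- mu / (kap - 1)
        v <- numeric(length(mu))
        pos <- shape > 0
        v[pos] <- rgamma(sum(pos), shape = shape[pos], scale = kap - 1)
        v
      } else mu
      if (sum(w) == 0) next
      counts[, t] <- as.vector(rmultinom(1L, size = as.integer(round(depth[t])),
                                         prob = w / sum(w)))
    } else {
      pos <- mu > 0
      if (kap > 1) {
        counts[pos, t] <- rnbinom(sum(pos), mu = mu[pos],
                                  size = mu[pos] / (kap - 1))
      } else {
        counts[pos, t] <- rpois(sum(pos), lambda = mu[pos])
      }
    }
  }
  out <- tibble(
    strain_id = rep(wide$strain_id, times = n_tp),
    timepoint = rep(0:(n_tp - 1L), each = nrow(f)),
    reads = as.integer(counts)
  )
  attr(out, "depth") <- depth
  attr(out, "dispersion") <- dispersion
  out
}

#' Simulate a replicated pooled competition experiment
#'
#' Convenience wrapper running [simulate_competition()] and [sample_reads()]
#' once per biological replicate (independent drift, shared pool), returning
#' a single long count table in the shape the downstream modules consume.
#'
#' @inheritParams simulate_competition
#' @inheritParams sample_reads
#' @param n_replicates Number of biological replicates.
#' @param timepoints Which transfer indices to report (default all).
#' @return A list with `counts` (tibble `strain_id`, `replicate`,
#'   `timepoint`, `reads`), `trajectories` (list of
#'   `competition_trajectory`), and the `pool`.
#' @export
simulate_replicates <- function(pool, n_replicates, n_transfers, g = 8,
                                bottleneck = 1e5, mutation_rate = 0,
                                dfe_mean = 0.05, depth = 1e6, dispersion = 1,
                                timepoints = NULL, seed = NULL) {
  trajs <- vector("list", n_replicates)
  counts <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sr <- if (is.null(seed)) NULL else derive_seed(seed, "replicate", r)
    trajs[[r]] <- simulate_competition(pool, n_transfers, g = g,
                                       bottleneck = bottleneck,
                                       mutation_rate = mutation_rate,
                                       dfe_mean = dfe_mean, seed = sr)
    cr <- sample_reads(trajs[[r]], depth = depth, dispersion = dispersion,
                       seed = if (is.null(sr)) NULL else sr + 1L)
    cr$replicate <- sprintf("R%02d", r)
    counts[[r]] <- cr
  }
  counts <- dplyr::bind_rows(counts)
  if (!is.null(timepoints)) {
    counts <- dplyr::filter(counts, .data$timepoint %in% timepoints)
  }
  list(counts = counts[, c("strain_id", "replicate", "timepoint", "reads")],
       trajectories = trajs, pool = pool)
}
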