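#' Number of strains composing a given mass of the pool (N99)
#'
#' The minimal number of strains whose summed frequencies reach `mass`
#' (default 99%) of the pool: a diversity-decay summary robust to the long
#' tail of near-extinct lineages.
#'
#' @param freqs Numeric vector of per-strain frequencies summing to 1.
#' @param mass Target cumulative mass in (0, 1].
#' @return An integer count.
#' @examples
#' n99(c(0.5, 0.3, 0.15, 0.04, 0.01))
#' @export
n99 <- function(freqs, mass = 0.99) {
  if (mass <= 0 || mass > 1) abort("`mass` must be in (0, 1]")
  if (abs(sum(freqs) - 1) > 1e-6) {
    abort("`freqs` must sum to 1")
  }
  cs <- cumsum(sort(freqs, decreasing = TRUE))
  as.integer(which(cs >= mass - 1e-12)[1])
}

#' Diversity decay over time
#'
#' Applies [n99()] per replicate and timepoint and summarises per timepoint
#' with the median and interquartile range across replicates.
#'
#' @param freq Frequency table (`strain_id`, `replicate`, `timepoint`,
#'   `freq`).
#' @param mass Cumulative mass threshold.
#' @return A list with `by_replicate` (tibble `replicate`, `timepoint`,
#'   `n99`) and `summary` (tibble `timepoint`, `median`, `q25`, `q75`).
#' @export
diversity_series <- function(freq, mass = 0.99) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  by_rep <- freq |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(n99 = n99(.data$freq, mass = mass), .groups = "drop")
  summary <- by_rep |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(
      median = median(.data$n99),
      q25 = quantile(.data$n99, 0.25),
      q75 = quantile(.data$n99, 0.75),
      .groups = "drop")
  list(by_replicate = by_rep, summary = summary)
}

#' Frequency of the most abundant strain over time
#'
#' @param freq Frequency table (`strain_id`, `replicate`, `timepoint`,
#'   `freq`).
#' @return A list with `by_replicate` (tibble `replicate`, `timepoint`,
#'   `top_strain`, `top_freq`) and `summary` (tibble `timepoint`, `mean`,
#'   `sd` across replicates).
#' @export
top_strain_frequency <- function(freq) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  by_rep <- freq |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(
      top_strain = .data$strain_id[which.max(.data$freq)],
      top_freq = max(.data$freq),
      .groups = "drop")
  summary <- by_rep |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(mean = mean(.data$top_freq),
                     sd = sd(.data$top_freq), .groups = "drop")
  list(by_replicate = by_rep, summary = summary)
}

#' Coefficient of variation of a strain's frequency across replicates
#'
#' Sample standard deviation divided by the mean of the strain's frequency
#' across replicates at each timepoint; undefined (NA) where the mean is 0.
#'
#' @param freq Frequency table.
#' @param strain_id Strain to summarise.
#' @return A tibble `timepoint`, `mean`, `sd`, `cv`, `n_replicates`.
#' @export
replicate_cv <- function(freq, strain_id) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  fs <- freq[freq$strain_id == strain_id, ]
  if (nrow(fs) == 0) abort(sprintf("unknown strain `%s`", strain_id))
  if (dplyr::n_distinct(fs$replicate) < 2) {
    abort("`replicate_cv` needs at least 2 replicates")
  }
  fs |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(
      mean = mean(.data$freq),
      sd = sd(.data$freq),
      cv = dplyr::if_else(mean > 0, .data$sd / mean, NA_real_),
      n_replicates = dplyr::n(),
      .groups = "drop")
}

#' Call the finalists of a competition
#'
#' A strain is a finalist in an environment if it is present at a frequency
#' at or above `threshold` (default 1%) in at least one replicate at that
#' replicate's last available timepoint. Replicates may end at different
#' transfers; by default each replicate's own maximum observed timepoint is
#' used.
#'
#' @param freq Frequency table.
#' @param last_timepoints Optional tibble `replicate`, `timepoint` naming
#'   each replicate's final timepoint; defaults to the maximum observed per
#'   replicate.
#' @param threshold Frequency threshold, inclusive at the boundary.
#' @return A tibble `strain_id`, `max_final_freq`,
#'   `n_replicates_above`, `threshold`, sorted by descending
#'   `max_final_freq`.
#' @export
call_finalists <- function(freq, last_timepoints = NULL, threshold = 0.01) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  if (is.null(last_timepoints)) {
    last_timepoints <- freq |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(timepoint = max(.data$timepoint), .groups = "drop")
  } else {
    assert_columns(last_timepoints, c("replicate", "timepoint"),
                   "last_timepoints")
    have <- dplyr::semi_join(last_timepoints, freq,
                             by = c("replicate", "timepoint"))
    missing <- dplyr::anti_join(last_timepoints, have,
                                by = c("replicate", "timepoint"))
    if (nrow(missing) > 0) {
      abort(sprintf("last timepoint missing from `freq` for replicate(s): %s",
                    paste(sprintf("%s (T%d)", missing$replicate,
                                  missing$timepoint), collapse = ", ")))
    }
  }
  final <- dplyr::inner_join(freq, last_timepoints,
                             by = c("replicate", "timepoint"))
  final |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      max_final_freq = max(.data$freq),
      n_replicates_above = sum(.data$freq >= threshold),
      .groups = "drop") |>
    dplyr::filter(.data$n_replicates_above >= 1) |>
    dplyr::mutate(threshold = threshold) |>
    dplyr::arrange(dplyr::desc(.data$max_final_freq))
}

#' Strains in the top fitness percentile
#'
#' Returns the strains whose fitness estimate is at or above the
#' `q`-quantile (linear interpolation between order statistics) of all
#' defined estimates, with each strain's percentile rank. Optionally checks
#' containment of a candidate set (e.g. the finalists) in the top set.
#'
#' @param estimates A tibble with columns `strain_id` and `s_hat` (e.g.
#'   [pool_estimates()] output), or a `fitness_fit`.
#' @param q Quantile in (0, 1); default 0.95.
#' @param check_ids Optional strain ids to test for membership.
#' @return A list with `top` (tibble `strain_id`, `s_hat`, `percentile`),
#'   `cutoff`, and (when `check_ids` given) `containment` (tibble
#'   `strain_id`, `in_top_set`).
#' @export
top_percentile_set <- function(estimates, q = 0.95, check_ids = NULL) {
  if (inherits(estimates, "fitness_fit")) estimates <- pool_estimates(estimates)
  assert_columns(estimates, c("strain_id", "s_hat"), "estimates")
  assert_scalar_number(q, "q", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  e <- estimates |> dplyr::filter(is.finite(.data$s_hat))
  if (nrow(e) < 2) abort("need at least 2 defined estimates")
  cutoff <- quantile(e$s_hat, q, names = FALSE)  # type 7: linear interpolation
  ranks <- rank(e$s_hat, ties.method = "average") / nrow(e)
  e$percentile <- ranks
  top <- e[e$s_hat >= cutoff, c("strain_id", "s_hat", "percentile")]
  out <- list(top = dplyr::arrange(top, dplyr::desc(.data$s_hat)),
              cutoff = cutoff)
  if (!is.null(check_ids)) {
    out$containment <- tibble(strain_id = check_ids,
                              in_top_set = check_ids %in% top$strain_id)
  }
  out
}
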