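#' Barcode frequencies from a count table
#'
#' Converts read counts to (optionally pseudocounted) frequencies per
#' sample: \eqn{f = (r + p) / (R + pB)} where `R` is the sample's total
#' reads and `B` the number of barcodes. With `pseudocount = 0` zeros
#' propagate; columns always sum to 1.
#'
#' @param counts Tibble with columns `strain_id`, `timepoint`, `reads` and
#'   optionally `replicate` (a single replicate is assumed if absent).
#' @param pseudocount Non-negative pseudocount `p`.
#' @return A tibble `strain_id`, `replicate`, `timepoint`, `reads`, `freq`.
#' @examples
#' counts <- tibble::tibble(strain_id = c("a", "b"), timepoint = 0,
#'                          reads = c(50L, 50L))
#' frequencies(counts)$freq
#' @export
frequencies <- function(counts, pseudocount = 0) {
  counts <- normalise_counts(counts)
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  out <- counts |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::mutate(
      freq = (.data$reads + pseudocount) /
        (sum(.data$reads) + pseudocount * dplyr::n())
    ) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
    dplyr::filter(.data$total == 0)
  if (nrow(bad) > 0 && pseudocount == 0) {
    abort(sprintf("sample(s) with zero total reads: %s",
                  paste(sprintf("%s/T%d", bad$replicate, bad$timepoint),
                        collapse = ", ")))
  }
  out[, c("strain_id", "replicate", "timepoint", "reads", "freq")]
}

# Ensure a counts/frequency table carries a replicate column.
normalise_counts <- function(counts) {
  assert_columns(counts, c("strain_id", "timepoint", "reads"), "counts")
  if (!"replicate" %in% names(counts)) counts$replicate <- "R01"
  counts
}

#' Population mean fitness from reference barcodes
#'
#' The reference strain has fitness 0 by definition, so any systematic decay
#' of its summed frequency measures the population mean fitness: over an
#' interval from transfer `t` to `t'`,
#' \eqn{\bar{x} = \ln(F_{ref}(t)/F_{ref}(t')) / (g (t' - t))}
#' in per-generation log units, where \eqn{F_{ref}} is the summed
#' reference-barcode frequency. Anchoring on the reference breaks the gauge
#' freedom of the relative-fitness model.
#'
#' @param freq Frequency table from [frequencies()].
#' @param reference_ids Character vector of reference barcode ids.
#' @param g Generations per transfer.
#' @param floor Intervals where the summed reference frequency falls at or
#'   below this floor at either end are marked undefined.
#' @return A tibble `replicate`, `t_from`, `t_to`, `generations`, `xbar`,
#'   `defined`.
#' @export
estimate_mean_fitness <- function(freq, reference_ids, g = 8, floor = 1e-9) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  if (length(reference_ids) == 0 ||
      !any(freq$strain_id %in% reference_ids)) {
    abort("no reference barcodes found in `freq`")
  }
  assert_scalar_number(g, "g", lower = 0, strict_lower = TRUE)
  fref <- freq |>
    dplyr::filter(.data$strain_id %in% reference_ids) |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(f_ref = sum(.data$freq), .groups = "drop") |>
    dplyr::arrange(.data$replicate, .data$timepoint)
  fref |>
    dplyr::group_by(.data$replicate) |>
    dplyr::reframe(
      t_from = head(.data$timepoint, -1),
      t_to = tail(.data$timepoint, -1),
      generations = g * diff(.data$timepoint),
      defined = head(.data$f_ref, -1) > floor & tail(.data$f_ref, -1) > floor,
      xbar = ifelse(.data$defined,
                    log(head(.data$f_ref, -1) / tail(.data$f_ref, -1)) /
                      .data$generations,
                    NA_real_)
    )
}

#' Sequencing noise (negative-binomial dispersion) from reference barcodes
#'
#' The reference barcodes are biologically identical, so the spread of their
#' per-interval log frequency changes beyond counting noise measures the
#' technical overdispersion of the readout. For each interval the deviations
#' \eqn{d_i = \ln(f_i(t')/f_i(t))} are centred on their median and
#' \eqn{\kappa = \mathrm{Var}(d_i) / \mathrm{mean}_i(1/r_i(t) + 1/r_i(t'))},
#' floored at 1 (Poisson); the pooled estimate is the median over intervals.
#'
#' @param counts Count table (`strain_id`, `replicate`, `timepoint`,
#'   `reads`).
#' @param reference_ids Reference barcode ids; at least 3 must have nonzero
#'   counts at both ends of an interval for it to be usable.
#' @return An object of class `nb_noise`: list with `intervals` (tibble
#'   `replicate`, `t_from`, `t_to`, `kappa`, `n_ref`) and `pooled` (tibble
#'   `replicate`, `kappa`).
#' @export
estimate_dispersion <- function(counts, reference_ids) {
  counts <- normalise_counts(counts)
  ref <- counts |>
    dplyr::filter(.data$strain_id %in% reference_ids)
  if (nrow(ref) == 0) abort("no reference barcodes found in `counts`")
  totals <- counts |>
    dplyr::group_by(.data$replicate, .data$timepoint) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
  ref <- dplyr::left_join(ref, totals, by = c("replicate", "timepoint"))

  rows <- list()
  for (rep_id in unique(ref$replicate)) {
    rr <- ref[ref$replicate == rep_id, ]
    tps <- sort(unique(rr$timepoint))
    for (k in seq_len(length(tps) - 1L)) {
      t1 <- tps[k]; t2 <- tps[k + 1L]
      a <- rr[rr$timepoint == t1, ]
      b <- rr[rr$timepoint == t2, ]
      m <- dplyr::inner_join(a, b, by = "strain_id",
                             suffix = c("_1", "_2")) |>
        dplyr::filter(.data$reads_1 > 0, .data$reads_2 > 0)
      if (nrow(m) < 3) next
      d <- log((m$reads_2 / m$total_2) / (m$reads_1 / m$total_1))
      d <- d - median(d)
      expected <- mean(1 / m$reads_1 + 1 / m$reads_2)
      kap <- max(1, var(d) / expected)
      rows[[length(rows) + 1L]] <- tibble(
        replicate = rep_id, t_from = t1, t_to = t2,
        kappa = kap, n_ref = nrow(m)
      )
    }
  }
  if (length(rows) == 0) {
    abort("fewer than 3 reference barcodes with nonzero counts at both ends of any interval")
  }
  intervals <- dplyr::bind_rows(rows)
  pooled <- intervals |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(kappa = median(.data$kappa), .groups = "drop")
  structure(list(intervals = intervals, pooled = pooled),
            class = "nb_noise")
}

#' @export
print.nb_noise <- function(x, ...) {
  cat("<nb_noise> pooled dispersion per replicate:\n")
  print(x$pooled)
  invisible(x)
}

#' Negative-binomial log-likelihood of a barcode trajectory
#'
#' The observation model behind [infer_fitness()], exposed so the optimiser
#' can be validated against an exhaustive grid search. The predicted
#' frequency follows
#' \eqn{f(t_k) = f_0 \exp(g \sum_{j<k} (t_{j+1}-t_j)(s - \bar{x}_j))}
#' and each timepoint contributes the negative-binomial log pmf with mean
#' \eqn{f(t_k) R_k} and variance \eqn{\kappa_k} times the mean
#' (\eqn{\kappa = 1} is Poisson). Predicted means are clipped below at
#' \eqn{10^{-12} R_k} to keep the log pmf finite.
#'
#' @param s Selection coefficient (per generation, relative to reference).
#' @param f0 Initial frequency, in (0, 1).
#' @param reads Integer reads per timepoint.
#' @param depth Total sample reads per timepoint.
#' @param xbar Mean fitness per inter-timepoint interval (length
#'   `length(reads) - 1`), per-generation units; must be finite.
#' @param kappa Dispersion per timepoint (scalar or vector, >= 1).
#' @param g Generations per transfer.
#' @param timepoints Transfer indices of the observations (default
#'   consecutive).
#' @return The log-likelihood (a single number).
#' @export
negbin_loglik <- function(s, f0, reads, depth, xbar, kappa = 1, g = 8,
                          timepoints = NULL) {
  n <- length(reads)
  timepoints <- timepoints %||% (0:(n - 1L))
  depth <- rep_len(depth, n)
  kappa <- rep_len(kappa, n)
  if (f0 <= 0 || f0 >= 1) return(-Inf)
  if (length(xbar) != n - 1L || any(!is.finite(xbar))) {
    abort("`xbar` must be finite with one value per inter-timepoint interval")
  }
  dgen <- g * diff(timepoints)
  logf <- log(f0) + c(0, cumsum(dgen * (s - xbar)))
  mu <- pmax(exp(logf) * depth, 1e-12 * depth)
  ll <- numeric(n)
  pois <- kappa <= 1 + 1e-9
  if (any(pois)) {
    ll[pois] <- dpois(reads[pois], lambda = mu[pois], log = TRUE)
  }
  if (any(!pois)) {
    ll[!pois] <- dnbinom(reads[!pois], mu = mu[!pois],
                         size = mu[!pois] / (kappa[!pois] - 1), log = TRUE)
  }
  sum(ll)
}

#' Maximum-likelihood selection coefficients from barcode trajectories
#'
#' Fits, per barcode and replicate, the selection coefficient `s` and
#' initial frequency `f0` maximising [negbin_loglik()] over a window of
#' timepoints, with the population mean fitness estimated from the
#' reference barcodes ([estimate_mean_fitness()]) and the dispersion from
#' [estimate_dispersion()]. Optimisation is bounded quasi-Newton
#' (`L-BFGS-B` on `(s, log f0)`) started from a closed-form log-linear
#' regression of pseudocounted frequencies on cumulative generations;
#' standard errors come from the observed-information (numerical Hessian)
#' diagonal. Barcodes with all-zero counts in the window are flagged
#' `extinct` and receive no estimate.
#'
#' @param counts Count table (`strain_id`, `replicate`, `timepoint`,
#'   `reads`).
#' @param reference_ids Reference barcode ids (fitness 0 by definition).
#' @param g Generations per transfer.
#' @param fit_window Timepoints (transfer indices) to fit over; default
#'   `0:5`, the early window in which frequency changes reflect initial
#'   fitness rather than de novo adaptation.
#' @param pseudocount Pseudocount used for the mean-fitness track and the
#'   regression start (the final likelihood uses raw counts).
#' @param kappa Optional fixed dispersion overriding the reference-based
#'   estimate (scalar).
#' @param s_bounds Box bounds for `s` in the optimiser.
#' @return A `fitness_fit` object: list with `estimates` (tibble
#'   `strain_id`, `replicate`, `s_hat`, `f0_hat`, `se`, `loglik`,
#'   `n_timepoints`, `flag`), `mean_fitness`, `noise`, `g`, `window`.
#'   Use [tidy()] / [glance()] / [pool_estimates()] to extract results.
#' @examples
#' pool <- make_pool(20, 4, seed = 7)
#' sim <- simulate_replicates(pool, n_replicates = 1, n_transfers = 5,
#'                            bottleneck = Inf, depth = 1e5, seed = 7)
#' fit <- infer_fitness(sim$counts, reference_ids = pool$strain_id[pool$is_reference])
#' tidy(fit)
#' @export
infer_fitness <- function(counts, reference_ids, g = 8, fit_window = 0:5,
                          pseudocount = 0.5, kappa = NULL,
                          s_bounds = c(-2, 2)) {
  counts <- normalise_counts(counts)
  counts <- dplyr::filter(counts, .data$timepoint %in% fit_window)
  tps_avail <- sort(unique(counts$timepoint))
  if (length(tps_avail) < 3) {
    abort("`fit_window` must cover at least 3 available timepoints")
  }
  freq_pc <- frequencies(counts, pseudocount = max(pseudocount, 1e-9))
  mean_fit <- estimate_mean_fitness(freq_pc, reference_ids, g = g)
  if (any(!mean_fit$defined)) {
    abort("mean fitness undefined on an interval inside the fit window; shrink the window")
  }
  noise <- NULL
  if (is.null(kappa)) {
    noise <- tryCatch(estimate_dispersion(counts, reference_ids),
                      error = function(e) NULL)
    if (is.null(noise)) {
      warn("too few reference barcodes to estimate dispersion; assuming kappa = 1 (Poisson)")
      kappa <- 1
    }
  }

  est_rows <- list()
  for (rep_id in unique(counts$replicate)) {
    cr <- counts[counts$replicate == rep_id, ]
    tps <- sort(unique(cr$timepoint))
    depth <- cr |>
      dplyr::group_by(.data$timepoint) |>
      dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
      dplyr::arrange(.data$timepoint)
    depth_v <- depth$total
    mf <- mean_fit[mean_fit$replicate == rep_id, ]
    mf <- mf[order(mf$t_from), ]
    xbar <- mf$xbar
    kap <- if (is.null(noise)) kappa else
      noise$pooled$kappa[noise$pooled$replicate == rep_id]
    if (length(kap) == 0) kap <- 1

    wide <- cr |>
      dplyr::arrange(.data$timepoint) |>
      tidyr::pivot_wider(id_cols = "strain_id", names_from = "timepoint",
                         values_from = "reads", values_fill = 0L)
    reads_m <- as.matrix(wide[, -1, drop = FALSE])
    # cumulative corrections shared by every barcode in this replicate
    dgen <- g * diff(tps)
    cum_xbar <- c(0, cumsum(dgen * xbar))
    gen_axis <- g * (tps - tps[1])

    for (i in seq_len(nrow(wide))) {
      r <- reads_m[i, ]
      sid <- wide$strain_id[i]
      if (all(r == 0)) {
        est_rows[[length(est_rows) + 1L]] <- tibble(
          strain_id = sid, replicate = rep_id, s_hat = NA_real_,
          f0_hat = NA_real_, se = NA_real_, loglik = NA_real_,
          n_timepoints = 0L, flag = "extinct")
        next
      }
      f_pc <- (r + pseudocount) / (depth_v + pseudocount * nrow(wide))
      y <- log(f_pc) + cum_xbar
      cf <- coef(lm(y ~ gen_axis))
      s0 <- min(max(cf[2], s_bounds[1] + 1e-6), s_bounds[2] - 1e-6)
      lf0 <- min(max(cf[1], log(1e-12)), log(1 - 1e-6))

      nll <- function(par) {
        -negbin_loglik(par[1], exp(par[2]), r, depth_v, xbar, kap, g,
                       timepoints = tps)
      }
      opt <- tryCatch(
        optim(c(s0, lf0), nll, method = "L-BFGS-B",
              lower = c(s_bounds[1], log(1e-12)),
              upper = c(s_bounds[2], log(1 - 1e-6)),
              control = list(maxit = 500, ndeps = c(1e-6, 1e-6))),
        error = function(e) NULL)
      if (is.null(opt)) {
        est_rows[[length(est_rows) + 1L]] <- tibble(
          strain_id = sid, replicate = rep_id, s_hat = s0,
          f0_hat = exp(lf0), se = NA_real_, loglik = NA_real_,
          n_timepoints = length(r), flag = "nonconv")
        next
      }
      flag <- "ok"
      if (opt$convergence != 0) flag <- "nonconv"
      if (any(abs(opt$par[1] - s_bounds) < 1e-6)) flag <- "boundary"
      se <- tryCatch({
        H <- optimHess(opt$par, nll)
        cov <- solve(H)
        sqrt(max(cov[1, 1], 0))
      }, error = function(e) NA_real_)
      est_rows[[length(est_rows) + 1L]] <- tibble(
        strain_id = sid, replicate = rep_id, s_hat = opt$par[1],
        f0_hat = exp(opt$par[2]), se = se, loglik = -opt$value,
        n_timepoints = sum(!is.na(r)), flag = flag)
    }
  }

  structure(
    list(estimates = dplyr::bind_rows(est_rows),
         mean_fitness = mean_fit,
         noise = noise,
         g = g, window = tps_avail, pseudocount = pseudocount),
    class = "fitness_fit")
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf("<fitness_fit> %d barcodes x %d replicate(s), window T%d-T%d, g = %g\n",
              dplyr::n_distinct(x$estimates$strain_id),
              dplyr::n_distinct(x$estimates$replicate),
              min(x$window), max(x$window), x$g))
  invisible(x)
}

#' @describeIn infer_fitness Per-barcode, per-replicate estimates as a tibble.
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @method tidy fitness_fit
#' @export
tidy.fitness_fit <- function(x, ...) x$estimates

#' @describeIn infer_fitness One-row model summary (replicates, barcodes,
#'   pooled dispersion, flag counts).
#' @method glance fitness_fit
#' @export
glance.fitness_fit <- function(x, ...) {
  e <- x$estimates
  tibble(
    n_strains = dplyr::n_distinct(e$strain_id),
    n_replicates = dplyr::n_distinct(e$replicate),
    n_ok = sum(e$flag == "ok"),
    n_extinct = sum(e$flag == "extinct"),
    kappa = if (is.null(x$noise)) NA_real_ else median(x$noise$pooled$kappa),
    g = x$g
  )
}

#' Combine per-replicate fitness estimates per strain
#'
#' Inverse-variance-weighted mean of `s_hat` across replicates, with the
#' combined standard error, alongside the unweighted mean.
#'
#' @param fit A `fitness_fit`.
#' @return A tibble `strain_id`, `s_hat` (weighted), `se`, `s_mean`,
#'   `n_replicates`.
#' @export
pool_estimates <- function(fit) {
  stopifnot(inherits(fit, "fitness_fit"))
  fit$estimates |>
    dplyr::filter(.data$flag %in% c("ok", "boundary"),
                  is.finite(.data$s_hat)) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      s_hat = if (all(is.finite(.data$se)) && all(.data$se > 0))
        sum(.data$s_hat / .data$se^2) / sum(1 / .data$se^2)
      else mean(.data$s_hat),
      se = if (all(is.finite(.data$se)) && all(.data$se > 0))
        sqrt(1 / sum(1 / .data$se^2)) else NA_real_,
      s_mean = mean(.data$s_hat),
      n_replicates = dplyr::n(),
      .groups = "drop")
}

#' Interval fitness as log fold change between two timepoints
#'
#' For later stages of a competition, when the maximum-likelihood early-window
#' model no longer applies, fitness relative to the population mean is
#' summarised as the log fold change in a strain's frequency between two
#' timepoints, conditioned on the strain not having gone extinct. Both the
#' raw log fold change and the per-generation rate are returned.
#'
#' @param freq Frequency table from [frequencies()].
#' @param t1,t2 Transfer indices with `t2 > t1`.
#' @param g Generations per transfer.
#' @return A tibble `strain_id`, `replicate`, `lfc`, `rate` (`lfc / (g
#'   (t2 - t1))`); strains at zero frequency at either endpoint get `NA`.
#' @export
interval_fitness <- function(freq, t1, t2, g = 8) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  if (t1 == t2) abort("`t1` and `t2` must differ")
  if (t2 < t1) abort("`t2` must be after `t1`")
  a <- dplyr::filter(freq, .data$timepoint == t1)
  b <- dplyr::filter(freq, .data$timepoint == t2)
  m <- dplyr::inner_join(a, b, by = c("strain_id", "replicate"),
                         suffix = c("_1", "_2"))
  m |>
    dplyr::mutate(
      lfc = dplyr::if_else(.data$freq_1 > 0 & .data$freq_2 > 0,
                           log(.data$freq_2 / .data$freq_1), NA_real_),
      rate = .data$lfc / (g * (t2 - t1))
    ) |>
    dplyr::select("strain_id", "replicate", "lfc", "rate")
}
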