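#' Singlet gating of cytometry events
#'
#' Keeps events whose forward-scatter area/height ratio lies in
#' `[lo, hi]` (default [0.9, 1.03], inclusive); doublets and clumps fall
#' outside. Events with non-positive height (no ratio) are removed and
#' counted. Gating is idempotent.
#'
#' @param events Event tibble with columns `fsc_a`, `fsc_h` (plus any
#'   others, passed through).
#' @param lo,hi Gate bounds on the area/height ratio.
#' @return The gated tibble, with attributes `n_removed` and
#'   `n_zero_height`.
#' @export
gate_singlets <- function(events, lo = 0.9, hi = 1.03) {
  assert_columns(events, c("fsc_a", "fsc_h"), "events")
  zero_h <- !(events$fsc_h > 0)
  ratio <- events$fsc_a / events$fsc_h
  keep <- !zero_h & ratio >= lo & ratio <= hi
  out <- events[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_zero_height") <- sum(zero_h)
  out
}

#' Calibrate a fluorescence threshold from pure control cultures
#'
#' Given gated events from a 100% GFP control and a 100% dark (unlabelled)
#' control, picks the threshold minimising the total misclassification of
#' the two controls (dark events should fall below the threshold, GFP
#' events at or above it). When the controls separate perfectly the
#' midpoint of the optimal separating interval is returned. Controls that
#' classify better with the opposite orientation are rejected as swapped;
#' residual misclassification above `max_misclass` is rejected as
#' inseparable.
#'
#' @param gfp_control,dark_control Gated event tibbles.
#' @param channel Fluorescence column name (default `"bl1_h"`).
#' @param max_misclass Maximum tolerated total misclassification rate.
#' @return A list `threshold`, `misclass_gfp`, `misclass_dark`.
#' @export
calibrate_threshold <- function(gfp_control, dark_control,
                                channel = "bl1_h", max_misclass = 0.4) {
  g <- gfp_control[[channel]]
  d <- dark_control[[channel]]
  if (length(g) == 0 || length(d) == 0) {
    abort("both control event tables must be non-empty after gating")
  }
  vals <- sort(unique(c(g, d)))
  cand <- c(vals[1] - 1, (head(vals, -1) + tail(vals, -1)) / 2,
            vals[length(vals)] + 1)
  err <- vapply(cand, function(t) sum(d >= t) + sum(g < t), numeric(1))
  err_flip <- vapply(cand, function(t) sum(g >= t) + sum(d < t), numeric(1))
  if (min(err_flip) < min(err)) {
    abort("controls separate better with the opposite orientation; GFP and dark labels appear swapped")
  }
  best <- which(err == min(err))
  thr <- mean(range(cand[best]))  # midpoint of the optimal interval
  mis_d <- mean(d >= thr)
  mis_g <- mean(g < thr)
  if ((sum(d >= thr) + sum(g < thr)) / (length(d) + length(g)) > max_misclass) {
    abort(sprintf("controls are inseparable (misclassification > %.0f%%); re-acquire controls",
                  100 * max_misclass))
  }
  list(threshold = thr, misclass_gfp = mis_g, misclass_dark = mis_d)
}

#' Dark (unlabelled) fraction of a gated sample
#'
#' The fraction of events below the calibrated fluorescence threshold: the
#' strain of interest in a competition against a GFP-labelled reference.
#'
#' @param events Gated event tibble.
#' @param threshold Fluorescence threshold from [calibrate_threshold()].
#' @param channel Fluorescence column name.
#' @param min_events Minimum events for a reliable estimate; below this
#'   the value is flagged.
#' @return A number in [0, 1] with attribute `low_events`.
#' @export
dark_fraction <- function(events, threshold, channel = "bl1_h",
                          min_events = 10000L) {
  x <- events[[channel]]
  if (length(x) == 0) abort("no events")
  out <- mean(x < threshold)
  attr(out, "low_events") <- length(x) < min_events
  if (length(x) < min_events) {
    warn(sprintf("only %d events (< %d); dark fraction flagged", length(x),
                 min_events))
  }
  out
}

#' Relative fitness from dark-fraction trajectories (area under curve)
#'
#' Integrates each strain's dark-fraction-versus-time series by the
#' trapezoid rule over the common time window (linear interpolation to the
#' union grid) and returns AUC(clone) - AUC(ancestor): positive when the
#' evolved clone holds a higher frequency against the GFP competitor than
#' its ancestor does. Antisymmetric in its arguments; zero for identical
#' series.
#'
#' @param series_clone,series_ancestor Tibbles `day`, `dark_fraction` with
#'   strictly increasing days.
#' @return Relative fitness (arbitrary units: fraction x days).
#' @export
auc_fitness <- function(series_clone, series_ancestor) {
  for (s in list(series_clone, series_ancestor)) {
    assert_columns(s, c("day", "dark_fraction"), "series")
    if (is.unsorted(s$day, strictly = TRUE)) {
      abort("series days must be strictly increasing")
    }
  }
  lo <- max(min(series_clone$day), min(series_ancestor$day))
  hi <- min(max(series_clone$day), max(series_ancestor$day))
  if (lo >= hi) abort("series time windows are disjoint")
  grid <- sort(unique(c(series_clone$day, series_ancestor$day)))
  grid <- grid[grid >= lo & grid <= hi]
  yc <- approx(series_clone$day, series_clone$dark_fraction, xout = grid)$y
  ya <- approx(series_ancestor$day, series_ancestor$dark_fraction,
               xout = grid)$y
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  trap(grid, yc) - trap(grid, ya)
}

#' Flocculation score from settled-culture optical densities
#'
#' After blank subtraction, flocculant cultures settle so the top fraction
#' retains little optical density relative to the bottom fraction. With
#' the default `precedence = "denominator"` the score is
#' \deqn{1 - \frac{OD_{top} - OD_{blank}}{0.8\,(OD_{bottom} - OD_{blank})}}
#' so a non-flocculant whose top fraction retains 80% of the bottom density
#' scores 0; `precedence = "product"` instead computes
#' `1 - (top/bottom) * 0.8`. The interpretation used is recorded in the
#' `precedence` attribute. Blank subtraction first makes the score
#' invariant to adding a constant to all three ODs.
#'
#' @param od_top,od_bottom OD600 of the top and bottom culture fractions
#'   (vectorised).
#' @param od_blank Blank media OD.
#' @param factor Calibration factor (default 0.8).
#' @param precedence `"denominator"` (default) or `"product"`.
#' @return Numeric score(s); `NA` with a warning where the blank-subtracted
#'   bottom OD is non-positive.
#' @export
flocculation_score <- function(od_top, od_bottom, od_blank = 0,
                               factor = 0.8,
                               precedence = c("denominator", "product")) {
  precedence <- match.arg(precedence)
  top <- od_top - od_blank
  bottom <- od_bottom - od_blank
  bad <- !(bottom > 0)
  if (any(bad)) {
    warn(sprintf("%d sample(s) with non-positive blank-subtracted bottom OD; score undefined", sum(bad)))
  }
  score <- if (precedence == "denominator") {
    1 - top / (bottom * factor)
  } else {
    1 - (top / bottom) * factor
  }
  score[bad] <- NA_real_
  attr(score, "precedence") <- precedence
  score
}

#' Ploidy class from total-DNA fluorescence
#'
#' Places a sample's median DNA-stain fluorescence on the linear scale
#' defined by known haploid and diploid controls (1N at the haploid value,
#' 2N at the diploid value) and assigns ploidy 1, 2, or `"higher"` by the
#' midpoints between successive integer ploidies on that scale.
#'
#' @param sample_median_fluor Sample median fluorescence (vectorised).
#' @param haploid_ctrl,diploid_ctrl Control medians with
#'   `diploid_ctrl > haploid_ctrl > 0`.
#' @return Character vector in `c("1", "2", "higher")`.
#' @export
ploidy_score <- function(sample_median_fluor, haploid_ctrl, diploid_ctrl) {
  if (!(diploid_ctrl > haploid_ctrl && haploid_ctrl > 0)) {
    abort("controls inverted: need diploid_ctrl > haploid_ctrl > 0")
  }
  n <- 1 + (sample_median_fluor - haploid_ctrl) / (diploid_ctrl - haploid_ctrl)
  dplyr::case_when(n < 1.5 ~ "1", n < 2.5 ~ "2", TRUE ~ "higher")
}
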