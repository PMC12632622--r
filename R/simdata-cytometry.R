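#' Simulate a flow-cytometry event table for a GFP competition assay
#'
#' Events carry forward-scatter area and height, side-scatter area and one
#' fluorescence channel. Singlets have an area/height ratio inside the
#' [0.9, 1.03] gate; doublets are drawn with a ratio well outside it (area
#' roughly twice height). Fluorescence is a two-component log-normal
#' mixture: a dark (unlabelled) component and a GFP component, with the
#' dark fraction set by `frac_dark`. Truth columns (`is_dark`,
#' `is_doublet`) are included for validation and are not used by the
#' analysis functions.
#'
#' @param n_events Number of events (>= 1).
#' @param frac_dark Fraction of singlet events from the dark component.
#' @param doublet_frac Fraction of events that are doublets.
#' @param dark_meanlog,dark_sdlog Log-normal parameters of the dark
#'   fluorescence component.
#' @param gfp_meanlog,gfp_sdlog Log-normal parameters of the GFP component.
#' @param seed Optional integer seed.
#' @return A tibble `fsc_a`, `fsc_h`, `ssc_a`, `bl1_h`, `is_dark`,
#'   `is_doublet`.
#' @export
make_cytometry_events <- function(n_events, frac_dark = 0.5,
                                  doublet_frac = 0,
                                  dark_meanlog = log(150), dark_sdlog = 0.35,
                                  gfp_meanlog = log(8000), gfp_sdlog = 0.35,
                                  seed = NULL) {
  assert_scalar_number(n_events, "n_events", lower = 1)
  assert_scalar_number(frac_dark, "frac_dark", lower = 0, upper = 1)
  assert_scalar_number(doublet_frac, "doublet_frac", lower = 0, upper = 1)
  set_stage_seed(seed, "cytometry")
  n <- as.integer(n_events)

  is_doublet <- runif(n) < doublet_frac
  is_dark <- runif(n) < frac_dark

  fsc_h <- stats::rlnorm(n, meanlog = log(5e4), sdlog = 0.25)
  ratio <- 0.9 + 0.13 * stats::rbeta(n, 2, 2)  # singlets: inside [0.9, 1.03]
  ratio[is_doublet] <- runif(sum(is_doublet), 1.6, 2.2)
  fsc_a <- fsc_h * ratio
  ssc_a <- stats::rlnorm(n, meanlog = log(3e4), sdlog = 0.3)

  bl1 <- numeric(n)
  bl1[is_dark] <- stats::rlnorm(sum(is_dark), dark_meanlog, dark_sdlog)
  bl1[!is_dark] <- stats::rlnorm(sum(!is_dark), gfp_meanlog, gfp_sdlog)
  # doublets containing a GFP cell fluoresce regardless of the second cell
  tibble(fsc_a = fsc_a, fsc_h = fsc_h, ssc_a = ssc_a, bl1_h = bl1,
         is_dark = is_dark, is_doublet = is_doublet)
}
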