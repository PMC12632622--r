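test_that("frequencies implements the pseudocount formula", {
  counts <- tibble::tibble(strain_id = c("a", "b"), timepoint = 0L,
                           reads = c(50L, 50L))
  expect_equal(frequencies(counts)$freq, c(0.5, 0.5))
  counts2 <- tibble::tibble(strain_id = c("a", "b"), timepoint = 0L,
                            reads = c(0L, 100L))
  expect_equal(frequencies(counts2, pseudocount = 0.5)$freq,
               c(0.5 / 101, 100.5 / 101))
  expect_error(frequencies(counts2 |> dplyr::mutate(reads = 0L)), "T0")
})

test_that("frequency columns sum to one for random tables", {
  set.seed(1)
  counts <- tidyr::expand_grid(strain_id = sprintf("s%02d", 1:30),
                               replicate = c("R01", "R02"),
                               timepoint = 0:4) |>
    dplyr::mutate(reads = rpois(dplyr::n(), 100))
  for (pc in c(0, 0.5)) {
    f <- frequencies(counts, pc)
    sums <- f |>
      dplyr::group_by(replicate, timepoint) |>
      dplyr::summarise(s = sum(freq), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-9))
  }
})

test_that("mean fitness tracks the reference decay", {
  # constant reference -> xbar 0
  counts <- tibble::tibble(strain_id = rep(c("REF01", "a"), each = 3),
                           timepoint = rep(0:2, 2),
                           reads = c(100L, 100L, 100L, 900L, 900L, 900L))
  f <- frequencies(counts)
  mf <- estimate_mean_fitness(f, "REF01", g = 8)
  expect_equal(mf$xbar, c(0, 0))
  # reference frequency halves over one transfer -> xbar = ln(2)/8
  counts2 <- tibble::tibble(strain_id = rep(c("REF01", "a"), each = 2),
                            timepoint = rep(0:1, 2),
                            reads = c(200L, 100L, 800L, 900L))
  mf2 <- estimate_mean_fitness(frequencies(counts2), "REF01", g = 8)
  expect_equal(mf2$xbar, log(2) / 8, tolerance = 1e-12)
  expect_error(estimate_mean_fitness(f, "NOPE"), "reference")
})

test_that("mean fitness recovers the true population mean on simulated data", {
  pool <- make_pool(100, 6, seed = 31)
  g <- 8
  traj <- simulate_competition(pool, 5, g = g, bottleneck = Inf)
  cnt <- sample_reads(traj, depth = 1e6, dispersion = 1, seed = 32)
  mf <- estimate_mean_fitness(frequencies(cnt, 0.5),
                              pool$strain_id[pool$is_reference], g = g)
  # truth: per-interval mean fitness = (1/g) log of mean growth factor
  f <- traj$freq
  s <- pool$true_fitness[match(rownames(f), pool$strain_id)]
  truth <- vapply(1:5, function(t) {
    log(sum(f[, t] * exp(g * s))) / g
  }, numeric(1))
  expect_lt(max(abs(mf$xbar - truth)), 3e-3)
})

test_that("dispersion estimates are floored and track the truth", {
  # identical reference counts -> zero variance -> floored at 1
  counts <- tidyr::expand_grid(strain_id = c(sprintf("REF%02d", 1:4), "a"),
                               timepoint = 0:3) |>
    dplyr::mutate(reads = dplyr::if_else(grepl("REF", strain_id), 100L, 600L))
  nm <- estimate_dispersion(counts, sprintf("REF%02d", 1:4))
  expect_true(all(nm$intervals$kappa == 1))
  expect_error(estimate_dispersion(counts, "REF01"), "reference")
})

test_that("dispersion calibration recovers kappa in simulation", {
  refs <- sprintf("REF%02d", 1:6)
  sim_kappa <- function(kappa_true, seed) {
    set.seed(seed)
    mu <- 1000
    rows <- tidyr::expand_grid(strain_id = c(refs, "bulk"), timepoint = 0:5)
    rows$reads <- ifelse(
      rows$strain_id == "bulk", 1e6L,
      if (kappa_true > 1)
        rnbinom(sum(rows$strain_id != "bulk"), mu = mu,
                size = mu / (kappa_true - 1))
      else rpois(sum(rows$strain_id != "bulk"), mu))
    estimate_dispersion(rows, refs)$pooled$kappa
  }
  k1 <- vapply(1:40, function(i) sim_kappa(1, i), numeric(1))
  expect_gte(median(k1), 1)
  expect_lte(median(k1), 2)
  k4 <- vapply(1:100, function(i) sim_kappa(4, 1000 + i), numeric(1))
  expect_gte(median(k4), 2.5)
  expect_lte(median(k4), 6)
})

test_that("the likelihood reaches the Poisson saturated value at kappa = 1", {
  g <- 8
  s <- log(2) / g          # doubling per transfer
  f0 <- 1e-3
  R <- 1e6
  reads <- as.integer(f0 * R * 2^(0:5))
  ll <- negbin_loglik(s, f0, reads, R, xbar = rep(0, 5), kappa = 1, g = g)
  saturated <- sum(dpois(reads, reads, log = TRUE))
  expect_equal(ll, saturated, tolerance = 1e-6)
})

test_that("the likelihood is invariant under a joint shift of s and xbar", {
  reads <- c(120L, 150L, 90L, 200L)
  xbar <- c(0.01, -0.02, 0.005)
  base <- negbin_loglik(0.05, 1e-3, reads, 1e5, xbar, kappa = 2)
  for (const in c(-0.1, 0.03, 1)) {
    shifted <- negbin_loglik(0.05 + const, 1e-3, reads, 1e5, xbar + const,
                             kappa = 2)
    expect_equal(shifted, base, tolerance = 1e-10)
  }
})

test_that("the profile likelihood is unimodal in s on noiseless data", {
  counts <- two_strain_counts(s = 0.08, depth = 1e6)
  reads <- counts$reads[counts$strain_id == "SEL"]
  grid <- seq(-0.2, 0.3, by = 0.002)
  ll <- vapply(grid, function(s)
    negbin_loglik(s, 0.1, reads, 1e6, xbar = rep(0, 5), kappa = 1),
    numeric(1))
  peak <- which.max(ll)
  expect_true(all(diff(ll[1:peak]) > 0))
  expect_true(all(diff(ll[peak:length(ll)]) < 0))
})

test_that("noiseless two-strain data recovers s exactly", {
  counts <- two_strain_counts(s = 0.1, g = 8, depth = 1e8)
  fit <- suppressWarnings(
    infer_fitness(counts, reference_ids = "REF01", g = 8, fit_window = 0:5))
  est <- tidy(fit)
  s_sel <- est$s_hat[est$strain_id == "SEL"]
  expect_equal(s_sel, 0.1, tolerance = 1e-6)
  expect_equal(est$f0_hat[est$strain_id == "SEL"], 0.1, tolerance = 1e-4)
})

test_that("reference barcodes estimate near zero and truth is recovered", {
  pool <- make_pool(50, 6, seed = 41)
  sim <- simulate_replicates(pool, n_replicates = 1, n_transfers = 5,
                             bottleneck = Inf, depth = 1e6, dispersion = 2,
                             seed = 41)
  refs <- pool$strain_id[pool$is_reference]
  fit <- infer_fitness(sim$counts, refs, g = 8, fit_window = 0:5)
  est <- tidy(fit)
  ref_est <- est[est$strain_id %in% refs & est$flag == "ok", ]
  expect_true(all(abs(ref_est$s_hat) <= 2 * ref_est$se + 1e-3))
  m <- dplyr::inner_join(est, pool, by = "strain_id") |>
    dplyr::filter(flag == "ok", f0_hat > 1e-5)
  rmse <- sqrt(mean((m$s_hat - m$true_fitness)^2))
  expect_lt(rmse, 0.01)
})

test_that("estimate error shrinks with sequencing depth", {
  pool <- make_pool(60, 6, seed = 55)
  refs <- pool$strain_id[pool$is_reference]
  traj <- simulate_competition(pool, 5, bottleneck = Inf, seed = 55)
  rmse <- vapply(c(1e4, 1e5, 1e6), function(R) {
    cnt <- sample_reads(traj, depth = R, dispersion = 1, seed = 56)
    est <- tidy(infer_fitness(cnt, refs, g = 8, fit_window = 0:5))
    m <- dplyr::inner_join(est, pool, by = "strain_id") |>
      dplyr::filter(flag == "ok", true_fitness != 0, f0_hat > 1e-4)
    sqrt(mean((m$s_hat - m$true_fitness)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("tidy, glance and pooled estimates expose the fit", {
  pool <- make_pool(15, 4, seed = 61)
  sim <- simulate_replicates(pool, n_replicates = 2, n_transfers = 5,
                             bottleneck = Inf, depth = 1e5, seed = 61)
  fit <- infer_fitness(sim$counts, pool$strain_id[pool$is_reference])
  td <- tidy(fit)
  expect_true(all(c("strain_id", "replicate", "s_hat", "se", "flag") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_replicates, 2)
  pe <- pool_estimates(fit)
  expect_true(all(pe$n_replicates <= 2))
  expect_true(all(is.finite(pe$s_hat)))
})

test_that("interval fitness is the log fold change over the window", {
  freq <- tibble::tibble(
    strain_id = rep(c("a", "b", "c"), 2), replicate = "R01",
    timepoint = rep(c(5L, 9L), each = 3),
    freq = c(0.10, 0.30, 0, 0.20, 0.30, 0.1))
  iv <- interval_fitness(freq, 5, 9, g = 8)
  expect_equal(iv$lfc[iv$strain_id == "a"], log(2))
  expect_equal(iv$rate[iv$strain_id == "a"], log(2) / 32)
  expect_equal(iv$lfc[iv$strain_id == "b"], 0)
  expect_true(is.na(iv$lfc[iv$strain_id == "c"]))  # extinct at t1
  expect_error(interval_fitness(freq, 5, 5), "differ")
})

test_that("interval fitness telescopes over a partition of the window", {
  freq <- tibble::tibble(
    strain_id = "a", replicate = "R01", timepoint = c(0L, 3L, 7L),
    freq = c(0.1, 0.25, 0.4))
  full <- interval_fitness(freq, 0, 7)$lfc
  parts <- interval_fitness(freq, 0, 3)$lfc + interval_fitness(freq, 3, 7)$lfc
  expect_equal(parts, full, tolerance = 1e-12)
})
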